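# Reading and writing measurement tables.

#' Write a MID time series to CSV
#'
#' Wide layout: `fragment_id`, `time_h`, `m0`..`mk` (NA beyond a fragment's
#' mass range) and `sigma`, the *relative* standard deviation of the
#' measurement model (per-point absolute sigmas are reconstructed on read via
#' [measurement_sigma()]).
#'
#' @param mid A `mid_timeseries` tibble (long layout).
#' @param path Output CSV path.
#' @param rel_sigma Relative sd stored in the `sigma` column (default 0.02).
#' @return `path`, invisibly.
#' @export
write_mid_csv <- function(mid, path, rel_sigma = 0.02) {
  wide <- mid |>
    dplyr::mutate(mass = paste0("m", .data$mass)) |>
    dplyr::select(dplyr::all_of(c("fragment_id", "time_h", "mass", "fraction"))) |>
    tidyr::pivot_wider(names_from = "mass", values_from = "fraction")
  wide$sigma <- rel_sigma
  readr::write_csv(wide, path)
  invisible(path)
}

#' Read a MID time series from CSV
#'
#' Inverse of [write_mid_csv()]: returns the long layout with an absolute
#' per-point `sigma` column.
#'
#' @param path CSV path.
#' @param sigma_floor Absolute sd floor (default 0.002).
#' @return A `mid_timeseries` tibble.
#' @export
read_mid_csv <- function(path, sigma_floor = 0.002) {
  wide <- readr::read_csv(path, show_col_types = FALSE)
  mcols <- grep("^m[0-9]+$", names(wide), value = TRUE)
  out <- wide |>
    tidyr::pivot_longer(dplyr::all_of(mcols), names_to = "mass",
                        values_to = "fraction", values_drop_na = TRUE) |>
    dplyr::mutate(mass = as.integer(sub("^m", "", .data$mass)))
  out$sigma <- measurement_sigma(out$fraction, out$sigma %||% 0.02,
                                 sigma_floor)
  out <- out[, c("fragment_id", "time_h", "mass", "fraction", "sigma")]
  out <- out[order(out$fragment_id, out$time_h, out$mass), ]
  class(out) <- c("mid_timeseries", class(out))
  out
}
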