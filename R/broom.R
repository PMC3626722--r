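# Tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a flux fit
#'
#' One row per estimated parameter (free directed fluxes and unmeasured
#' pools), with linearized standard deviations, 95% confidence bounds and
#' identifiability flags.
#'
#' @param x A `flux_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.flux_fit <- function(x, ...) {
  x$parameters
}

#' One-row summary of a flux fit
#'
#' @param x A `flux_fit`.
#' @param ... Unused.
#' @return A tibble with SSR, measurement/parameter counts, degrees of
#'   freedom, the 95% chi-square threshold, and the acceptance verdict.
#' @export
glance.flux_fit <- function(x, ...) {
  tibble::tibble(ssr = x$ssr, n_measurements = x$n_measurements,
                 n_parameters = x$n_parameters, dof = x$dof,
                 chi2_threshold = x$threshold, accepted = x$accepted,
                 converged = x$converged, seed = x$seed)
}

#' Tidy a NET analysis result
#'
#' @param x A `net_result`.
#' @param ... Unused.
#' @return The range tibble with the feasibility verdict attached as a
#'   column.
#' @export
tidy.net_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$feasible <- attr(x, "feasible")
  out
}

#' One-row summary of a NET analysis
#'
#' @param x A `net_result`.
#' @param ... Unused.
#' @return A tibble with feasibility, counts of tightened ranges, and any
#'   violated reactions (comma-separated).
#' @export
glance.net_result <- function(x, ...) {
  tibble::tibble(feasible = attr(x, "feasible"),
                 n_metabolites = nrow(x),
                 n_tightened = sum(x$tightened),
                 violated = paste(attr(x, "violated"), collapse = ","))
}
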