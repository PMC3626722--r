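# Correction of raw MS mass-isotopomer data for natural isotope abundance
# and derivatization carbons.

#' Default natural isotope abundance table
#'
#' Mass-shift distributions (relative to the monoisotopic species) for the
#' elements commonly present in derivatized metabolite ions. Values are the
#' standard terrestrial abundances; 13C is 1.07%.
#'
#' @return Named list: per element, numeric vector of abundances by mass
#'   shift (index 1 = +0).
#' @export
default_isotopes <- function() {
  list(
    C  = c(0.9893, 0.0107),
    H  = c(0.999885, 0.000115),
    N  = c(0.99636, 0.00364),
    O  = c(0.99757, 0.00038, 0.00205),
    Si = c(0.92223, 0.04685, 0.03092),
    S  = c(0.9499, 0.0075, 0.0425),
    P  = c(1))
}

#' Read an isotope abundance table from YAML
#'
#' The file maps element symbols to abundance vectors by mass shift.
#' @param path Path to the YAML file.
#' @return Named list as in [default_isotopes()].
#' @export
read_isotopes <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y, as.numeric)
}

parse_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  counts <- list()
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (n == "") 1L else as.integer(n)
    counts[[el]] <- (counts[[el]] %||% 0L) + n
  }
  counts
}

# mass-shift distribution of a set of atoms at natural abundance
atoms_distribution <- function(counts, abundances, max_shift) {
  dist <- 1
  for (el in names(counts)) {
    ab <- abundances[[el]]
    if (is.null(ab)) stop("no abundance data for element: ", el, call. = FALSE)
    for (i in seq_len(counts[[el]])) {
      dist <- mid_convolve(list(dist, ab))
      if (length(dist) > max_shift + 1) dist <- dist[seq_len(max_shift + 1)]
    }
  }
  length(dist) <- max_shift + 1
  dist[is.na(dist)] <- 0
  dist
}

#' Correction matrix for a fragment ion
#'
#' Column `j` (j = 0..k artificially labeled carbons) is the mass
#' distribution of the ion when `j` of the `k` skeleton carbons carry a 13C
#' label: a shift by `j`, convolved with natural 13C on the remaining `k - j`
#' skeleton carbons and with the natural-abundance distribution of all other
#' atoms (derivatization carbons, H, N, O, Si, ...).
#'
#' @param k Number of skeleton (fragment) carbons.
#' @param formula Elemental formula of the detected ion (includes the skeleton
#'   carbons and any derivatization atoms). `NA` means skeleton carbons only.
#' @param abundances Isotope table, see [default_isotopes()].
#' @param n_rows Number of measured mass channels (>= k + 1).
#' @return `n_rows` x `(k+1)` matrix.
#' @export
correction_matrix <- function(k, formula = NA, abundances = default_isotopes(),
                              n_rows = k + 1) {
  stopifnot(n_rows >= k + 1)
  counts <- if (is.na(formula)) list(C = k) else parse_formula(formula)
  if ((counts$C %||% 0) < k) {
    stop("ion formula has fewer carbons than the fragment", call. = FALSE)
  }
  counts$C <- counts$C - k      # non-skeleton atoms at natural abundance
  base <- atoms_distribution(counts, abundances, n_rows - 1)
  M <- matrix(0, n_rows, k + 1)
  for (j in 0:k) {
    rest <- atoms_distribution(list(C = k - j), abundances, n_rows - 1)
    col <- mid_convolve(list(base, rest))[seq_len(n_rows)]
    shifted <- c(rep(0, j), col)[seq_len(n_rows)]
    shifted[is.na(shifted)] <- 0
    M[, j + 1] <- shifted
  }
  M
}

#' Correct a raw MID for natural abundance
#'
#' Removes natural-abundance and derivatization mass shifts from a measured
#' intensity vector by least squares against the correction matrix, clamps
#' small negative fractions, and renormalizes to sum 1.
#'
#' @param raw Numeric vector of measured fractions (length >= k+1; extra
#'   trailing channels capture heteroatom isotope tails).
#' @param k Number of skeleton carbons of the fragment.
#' @param formula Ion formula (see [correction_matrix()]).
#' @param abundances Isotope table.
#' @param clamp_tol Warn if corrected fractions fall below `-clamp_tol`.
#' @return Numeric vector of length k+1, the carbon-labeling MID (sums to 1).
#' @export
correct_natural_abundance <- function(raw, k, formula = NA,
                                      abundances = default_isotopes(),
                                      clamp_tol = 1e-6) {
  M <- correction_matrix(k, formula, abundances, n_rows = length(raw))
  x <- qr.solve(M, raw)
  if (any(x < -clamp_tol)) {
    warning("corrected MID has negative fraction(s) down to ",
            signif(min(x), 3), "; clamping to 0", call. = FALSE)
  }
  x <- pmax(x, 0)
  x / sum(x)
}
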