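# Seeded generators for ground-truth flux/pool configurations and noisy
# measurement datasets with the statistical structure of a 13C wash-in
# chemostat experiment.

#' Labeling experiment design
#'
#' Defaults mirror the glucose-methanol chemostat study the package is built
#' around: glucose fed as 80% \[1-13C1\] + 20% \[U-13C6\], methanol 100% 13C,
#' 20 sampling times from 5 s to 6 h at exponentially increasing intervals
#' (`t_k = 5s * (6h/5s)^(k/19)`), and a 2% relative measurement standard
#' deviation.
#'
#' @param feed A `feed_labeling` (default [pichia_feed()]).
#' @param times Sampling times in hours.
#' @param rel_sigma Relative measurement sd (default 0.02).
#' @param sigma_floor Absolute sd floor (default 0.002).
#' @param replicates Number of replicate datasets.
#' @param seed RNG seed recorded in every generated output.
#' @return List of class `experiment_design`.
#' @export
experiment_design <- function(feed = pichia_feed(),
                              times = exp_time_grid(),
                              rel_sigma = 0.02, sigma_floor = 0.002,
                              replicates = 1, seed = 1) {
  stopifnot(all(diff(times) > 0), times[1] >= 0, rel_sigma >= 0,
            sigma_floor > 0)
  structure(list(feed = feed, times = times, rel_sigma = rel_sigma,
                 sigma_floor = sigma_floor, replicates = replicates,
                 seed = seed),
            class = "experiment_design")
}

#' Exponentially spaced sampling grid
#'
#' @param t_first First sampling time, h (default 5 s).
#' @param t_last Last sampling time, h (default 6 h).
#' @param n Number of samples (default 20).
#' @return Numeric vector of times, strictly increasing.
#' @export
exp_time_grid <- function(t_first = 5 / 3600, t_last = 6, n = 20) {
  t_first * (t_last / t_first)^((seq_len(n) - 1) / (n - 1))
}

#' Sample a steady-state ground truth
#'
#' Draws free directed fluxes uniformly within bounds, completes them to a
#' full steady-state flux distribution, and rejects draws that require
#' negative directed fluxes. Pool sizes are drawn log-uniformly within
#' `pool_range` for every balanced metabolite without a supplied value.
#'
#' @param basis A `flux_basis`.
#' @param seed RNG seed.
#' @param flux_bounds Two-column matrix or list `list(lower=, upper=)` of
#'   bounds on the free directed fluxes (defaults: lower 0, upper 2
#'   mmol/gCDW/h, or named vectors covering `basis$free`).
#' @param pools Optional named vector of fixed pool sizes (umol/gCDW).
#' @param pool_range Log-uniform sampling range for remaining pools
#'   (default 0.01..20 umol/gCDW).
#' @param max_tries Rejection-sampling cap.
#' @return List of class `ground_truth` with `fluxes`
#'   (`flux_distribution`), `pools` (named vector covering all balanced
#'   metabolites) and `seed`.
#' @export
sample_ground_truth <- function(basis, seed = 1,
                                flux_bounds = list(lower = 0, upper = 2),
                                pools = NULL, pool_range = c(0.01, 20),
                                max_tries = 1000) {
  set.seed(seed)
  free <- basis$free
  lo <- rep_len(if (is.null(names(flux_bounds$lower))) flux_bounds$lower
                else flux_bounds$lower[free], length(free))
  hi <- rep_len(if (is.null(names(flux_bounds$upper))) flux_bounds$upper
                else flux_bounds$upper[free], length(free))
  fx <- NULL
  for (i in seq_len(max_tries)) {
    fv <- stats::setNames(stats::runif(length(free), lo, hi), free)
    fx <- tryCatch(complete_fluxes(basis, fv), error = function(e) NULL)
    if (!is.null(fx)) break
  }
  if (is.null(fx)) {
    stop("no feasible flux distribution found in ", max_tries,
         " draws; check constraint values and bounds", call. = FALSE)
  }
  mets <- basis$network$metabolites
  bal <- mets$id[!mets$is_boundary]
  p <- stats::setNames(rep(NA_real_, length(bal)), bal)
  if (!is.null(pools)) p[intersect(names(pools), bal)] <-
      pools[intersect(names(pools), bal)]
  n_miss <- sum(is.na(p))
  p[is.na(p)] <- exp(stats::runif(n_miss, log(pool_range[1]),
                                  log(pool_range[2])))
  structure(list(fluxes = fx, pools = p, seed = seed),
            class = "ground_truth")
}

#' Generate a noisy labeling dataset
#'
#' Simulates the instationary MIDs of the system's fragments under the
#' ground truth, then perturbs every fraction with independent Gaussian noise
#' of sd `rel_sigma * value` (floored), truncates at zero and renormalizes
#' each MID to sum 1. With `rel_sigma = 0` the output equals the simulation
#' exactly.
#'
#' @param truth A `ground_truth`.
#' @param system A `labeling_system`.
#' @param design An `experiment_design`.
#' @param seed RNG seed (defaults to `design$seed`).
#' @param renormalize Truncate noisy fractions at zero and rescale each MID
#'   to sum 1 (default TRUE, matching how measured MIDs are normalized).
#'   Truncation and renormalization correlate the noise within a MID and
#'   shrink it slightly, so residuals at the truth sit a little below the
#'   nominal chi-square level; set FALSE for strictly independent untruncated
#'   Gaussian noise (the model under which chi-square calibration is exact).
#' @return A `mid_timeseries` tibble with a `sigma` column, ready for
#'   [fit_fluxes()]; the seed is recorded as attribute `seed`.
#' @export
generate_labeling_dataset <- function(truth, system, design,
                                      seed = design$seed, renormalize = TRUE) {
  sim <- simulate_inst(system, truth$fluxes, truth$pools, design$feed,
                       design$times)
  set.seed(seed)
  out <- sim
  if (design$rel_sigma > 0) {
    noise_sd <- pmax(design$rel_sigma * out$fraction, design$sigma_floor)
    out$fraction <- out$fraction + stats::rnorm(nrow(out), 0, noise_sd)
    if (renormalize) {
      # physical dataset: truncate at zero and rescale each MID to sum 1
      out$fraction <- pmax(out$fraction, 0)
      out <- out |>
        dplyr::mutate(fraction = .data$fraction / sum(.data$fraction),
                      .by = c("fragment_id", "time_h"))
    }
  }
  out$sigma <- measurement_sigma(out$fraction, design$rel_sigma,
                                 design$sigma_floor)
  attr(out, "seed") <- seed
  attr(out, "final_state") <- NULL
  out
}

#' Generate a replicate concentration table
#'
#' Adds lognormal replicate noise to true concentrations and summarizes as
#' mean/sd/n, the layout consumed by [concentration_ranges()].
#'
#' @param concentrations Named vector of true pool sizes, umol/gCDW (> 0).
#' @param n_replicates Replicates per metabolite (default 3).
#' @param rel_sigma Relative (lognormal) noise level (default 0.1).
#' @param seed RNG seed.
#' @return Tibble with `metabolite`, `mean`, `sd`, `n`; seed as attribute.
#' @export
generate_concentration_dataset <- function(concentrations, n_replicates = 3,
                                           rel_sigma = 0.1, seed = 1) {
  stopifnot(all(concentrations > 0), n_replicates >= 2)
  set.seed(seed)
  rows <- lapply(names(concentrations), function(m) {
    reps <- concentrations[[m]] *
      exp(stats::rnorm(n_replicates, 0, rel_sigma))
    if (rel_sigma == 0) reps <- rep(concentrations[[m]], n_replicates)
    tibble::tibble(metabolite = m, mean = mean(reps), sd = stats::sd(reps),
                   n = n_replicates)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  out
}

#' Generate a macroscopic rates dataset from a ground truth
#'
#' Reads the boundary fluxes of the ground truth (substrate uptakes, CO2
#' excretion, biomass precursor drains), derives the biomass rate in Cmol and
#' the oxygen uptake implied by the degree-of-reduction balance, and perturbs
#' every rate with relative Gaussian noise. The noise-free rates are exactly
#' carbon-balanced by construction.
#'
#' @param truth A `ground_truth`.
#' @param network The `mfa_network` the truth lives on.
#' @param rel_sigma Relative noise (default 0.01).
#' @param seed RNG seed.
#' @param composition Biomass elemental composition.
#' @param glucose,methanol,co2 Reaction ids of glucose uptake, methanol
#'   uptake and CO2 excretion.
#' @param drain_prefix Prefix identifying biomass drain reactions.
#' @return A `macro_rates` tibble; seed as attribute.
#' @export
generate_rates_dataset <- function(truth, network, rel_sigma = 0.01, seed = 1,
                                   composition = biomass_composition(),
                                   glucose = "upt1", methanol = "upt2",
                                   co2 = "co2out", drain_prefix = "bm_") {
  v <- stats::setNames(truth$fluxes$net, truth$fluxes$reaction)
  drains <- grep(paste0("^", drain_prefix), names(v), value = TRUE)
  carbons <- vapply(drains, function(r) {
    sub <- network$transitions[[r]]$subs[[1]]
    length(sub$atoms)
  }, numeric(1))
  q_bio <- sum(v[drains] * carbons)                     # mCmol/gCDW/h
  q_glc <- -v[[glucose]]; q_meoh <- -v[[methanol]]; cer <- v[[co2]]
  our <- -(24 * abs(q_glc) + 6 * abs(q_meoh) - composition$gamma * q_bio) / 4
  vals <- c(q_glucose = q_glc, q_methanol = q_meoh, our = our,
            cer = cer, q_biomass = q_bio)
  set.seed(seed)
  if (rel_sigma > 0) {
    vals <- vals * (1 + stats::rnorm(length(vals), 0, rel_sigma))
  }
  sds <- pmax(rel_sigma, 0.005) * abs(vals)
  out <- macro_rates(vals[["q_glucose"]], vals[["q_methanol"]], vals[["our"]],
                     vals[["cer"]], vals[["q_biomass"]],
                     sd = stats::setNames(sds, names(vals)))
  attr(out, "seed") <- seed
  out
}
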