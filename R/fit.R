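# Weighted least-squares estimation of free fluxes and unmeasured pool sizes
# from mass-isotopomer time courses.

#' Measurement uncertainty of mass-isotopomer fractions
#'
#' The accuracy of MID measurements is described by a constant relative
#' standard deviation (default 2% of the measured value), floored at a small
#' absolute value so that fractions near zero do not receive infinite weight.
#'
#' @param value Measured fraction(s).
#' @param rel Relative standard deviation (default 0.02).
#' @param floor Absolute lower bound on sigma (default 0.002).
#' @return Numeric vector of standard deviations.
#' @export
measurement_sigma <- function(value, rel = 0.02, floor = 0.002) {
  pmax(rel * abs(value), floor)
}

#' Weighted sum of squared residuals between simulated and measured MIDs
#'
#' @param simulated A `mid_timeseries` (or `mid_set`) tibble with columns
#'   `fragment_id`, (`time_h`,) `mass`, `fraction`.
#' @param measured Same layout plus a `sigma` column.
#' @return The scalar SSR
#'   \eqn{\sum ((x_{sim}-x_{meas})/\sigma)^2}.
#' @export
weighted_residual <- function(simulated, measured) {
  sum(weighted_residual_vector(simulated, measured)^2)
}

weighted_residual_vector <- function(simulated, measured) {
  if (!"sigma" %in% names(measured)) {
    stop("measured data must carry a 'sigma' column", call. = FALSE)
  }
  if (any(measured$sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  keys <- intersect(c("fragment_id", "time_h", "mass"), names(measured))
  keys <- intersect(keys, names(simulated))
  j <- dplyr::inner_join(measured, simulated, by = keys,
                         suffix = c("_meas", "_sim"))
  if (nrow(j) != nrow(measured)) {
    stop("simulated data do not cover every measured point ",
         "(fragment/time/mass index mismatch)", call. = FALSE)
  }
  (j$fraction_sim - j$fraction_meas) / j$sigma
}

#' Chi-square acceptance test for a flux fit
#'
#' A fit is statistically acceptable when its minimal weighted residual lies
#' below the chi-square quantile at the 1-alpha confidence level for
#' `n_measurements - n_parameters` degrees of freedom.
#'
#' @param ssr Weighted sum of squared residuals.
#' @param n_measurements Number of fitted data points (all reported
#'   mass-isotopomer fractions at all times).
#' @param n_parameters Number of estimated parameters.
#' @param alpha Significance level (default 0.05, i.e. a 95% test).
#' @return A list with `dof`, `threshold`, `accepted`.
#' @examples
#' chi2_acceptance(1508.54, 1600, 34)  # accepted: threshold 1659.2 at dof 1566
#' @export
chi2_acceptance <- function(ssr, n_measurements, n_parameters, alpha = 0.05) {
  dof <- n_measurements - n_parameters
  if (dof <= 0) stop("degrees of freedom must be positive", call. = FALSE)
  threshold <- stats::qchisq(1 - alpha, df = dof)
  list(dof = dof, threshold = threshold, accepted = ssr <= threshold)
}

# residual closure over parameters theta = c(free directed fluxes,
# log10 unmeasured pools); infeasible completions (negative directed fluxes)
# contribute smooth penalty residuals instead of hard failures
make_residual_fn <- function(basis, system, measured, feed,
                             pools_fixed, pool_par, penalty = 1e3) {
  free <- basis$free
  times <- sort(unique(measured$time_h))
  sim_index <- NULL  # measured-row -> simulated-row map, built on first use
  function(theta) {
    fv <- stats::setNames(theta[seq_along(free)], free)
    lp <- theta[-seq_along(free)]
    pools <- pools_fixed
    if (length(pool_par)) pools[pool_par] <- 10^lp
    w <- basis$w0
    if (basis$n_free > 0) {
      Nf <- basis$N[free, , drop = FALSE]
      alpha <- solve(Nf, fv - basis$w0[free])
      w <- basis$w0 + drop(basis$N %*% alpha)
    }
    pen <- penalty * pmin(w, 0)
    # floor at a tiny positive flux so that EMUs never disconnect abruptly at
    # the feasibility boundary; the penalty drives the optimizer back inside
    wc <- pmax(w, 1e-9)
    fx <- directed_to_distribution(basis$network, wc)
    sim <- tryCatch(
      simulate_inst(system, fx, pools, feed, times),
      error = function(e) NULL)
    if (is.null(sim)) {
      return(c(rep(penalty, nrow(measured)), pen))
    }
    if (is.null(sim_index)) {
      key <- function(d) paste(d$fragment_id, format(d$time_h, digits = 12),
                               d$mass)
      sim_index <<- match(key(measured), key(sim))
      if (anyNA(sim_index)) {
        stop("simulated data do not cover every measured point", call. = FALSE)
      }
    }
    c((sim$fraction[sim_index] - measured$fraction) / measured$sigma, pen)
  }
}

#' Fit free fluxes and unmeasured pools to labeling time courses
#'
#' Multi-start bounded Levenberg-Marquardt minimization of the weighted
#' residual between simulated and measured mass-isotopomer fractions. Free
#' parameters are the free directed fluxes of the constrained network (which
#' bound exchange fluxes through their box constraints) and the base-10
#' logarithms of the unmeasured pool sizes.
#'
#' @param basis A `flux_basis` from [free_flux_basis()].
#' @param system A `labeling_system` covering the measured fragments.
#' @param measured A `mid_timeseries` tibble with a `sigma` column.
#' @param feed A `feed_labeling`.
#' @param pools Named vector of measured pool sizes (umol/gCDW); hosts of the
#'   EMU system that are absent or `NA` here are treated as unmeasured and
#'   estimated.
#' @param config List of fitting options: `starts` (number of random starts,
#'   default 10), `seed` (default 1), `flux_lower`/`flux_upper` (bounds on
#'   free directed fluxes, scalar or named, default 0 and 10),
#'   `pool_bounds` (default `c(1e-3, 50)` umol/gCDW), `maxiter` (default 50),
#'   `start_values` (optional named vector used as first start), `stop_ssr`
#'   (optional: stop the multi-start scan once a start reaches this SSR).
#' @return An object of class `flux_fit`: estimates with standard deviations
#'   and 95% confidence intervals, SSR, chi-square acceptance, covariance,
#'   identifiability flags, per-point residuals, and the fitted
#'   `flux_distribution`.
#' @export
fit_fluxes <- function(basis, system, measured, feed, pools = NULL,
                       config = list()) {
  cfg <- utils::modifyList(list(starts = 10, seed = 1, flux_lower = 0,
                                flux_upper = 10, pool_bounds = c(1e-3, 50),
                                maxiter = 50, start_values = NULL,
                                stop_ssr = NULL), config)
  free <- basis$free
  hosts <- unique(system$emus$met[!system$emus$is_input])
  pools_fixed <- stats::setNames(rep(NA_real_, length(hosts)), hosts)
  if (!is.null(pools)) pools_fixed[intersect(names(pools), hosts)] <-
      pools[intersect(names(pools), hosts)]
  pool_par <- names(pools_fixed)[is.na(pools_fixed)]

  n_par <- length(free) + length(pool_par)
  lower <- c(rep_len(cfg$flux_lower, length(free)),
             rep(log10(cfg$pool_bounds[1]), length(pool_par)))
  upper <- c(if (is.null(names(cfg$flux_upper))) rep_len(cfg$flux_upper, length(free))
             else cfg$flux_upper[free],
             rep(log10(cfg$pool_bounds[2]), length(pool_par)))
  par_names <- c(free, if (length(pool_par)) paste0("pool:", pool_par))

  resfn <- make_residual_fn(basis, system, measured, feed, pools_fixed, pool_par)

  if (n_par == 0) {
    r <- resfn(numeric(0))
    ssr <- sum(r^2)
    chi <- list(dof = nrow(measured),
                threshold = stats::qchisq(0.95, nrow(measured)),
                accepted = ssr <= stats::qchisq(0.95, nrow(measured)))
    fit <- list(parameters = tibble::tibble(term = character(0)),
                ssr = ssr, n_measurements = nrow(measured), n_parameters = 0,
                dof = chi$dof, threshold = chi$threshold,
                accepted = chi$accepted, converged = TRUE,
                fluxes = complete_fluxes(basis, numeric(0)),
                pools = pools_fixed, seed = cfg$seed)
    class(fit) <- "flux_fit"
    return(fit)
  }

  # candidate screening: a single residual evaluation is cheap compared to a
  # Levenberg-Marquardt run, so seeded random candidates (plus the box
  # midpoint and any user start) are ranked by SSR first and the local
  # optimizer is launched only from the most promising ones
  set.seed(cfg$seed)
  n_cand <- max(cfg$screen %||% (5 * cfg$starts), cfg$starts)
  cands <- lapply(seq_len(n_cand), function(i) {
    stats::runif(n_par, lower, upper)
  })
  cands[[1]] <- (lower + upper) / 2
  if (!is.null(cfg$start_values)) {
    cands[[length(cands) + 1L]] <- cfg$start_values
  }
  cand_ssr <- vapply(cands, function(p) sum(resfn(p)^2), numeric(1))
  starts <- cands[order(cand_ssr)][seq_len(cfg$starts)]

  best <- NULL
  diagnostics <- character(0)
  for (st in starts) {
    out <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper, fn = resfn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = cfg$maxiter, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(out)) { diagnostics <- c(diagnostics, "start failed"); next }
    if (is.null(best) || out$deviance < best$deviance) best <- out
    # optional early exit once a start reaches an acceptable residual, so
    # well-behaved fits do not pay for the full multi-start budget
    if (!is.null(cfg$stop_ssr) && best$deviance <= cfg$stop_ssr) break
  }
  if (is.null(best)) stop("all optimization starts failed", call. = FALSE)

  theta <- best$par
  names(theta) <- par_names
  r <- resfn(theta)
  r_data <- r[seq_len(nrow(measured))]
  ssr <- sum(r_data^2)
  chi <- chi2_acceptance(ssr, nrow(measured), n_par)

  # linearized error propagation at the optimum
  ci <- linearized_covariance(resfn, theta, n_data = nrow(measured))
  sd <- sqrt(pmax(diag(ci$cov), 0))
  est <- theta
  pool_rows <- grepl("^pool:", par_names)

  # pools are estimated on the log10 scale; report them on the natural scale
  # with delta-method sds and log-symmetric confidence bounds
  sd_th <- sd
  est_nat <- ifelse(pool_rows, 10^est, est)
  sd_nat <- ifelse(pool_rows, log(10) * 10^est * sd_th, sd_th)
  lo_nat <- ifelse(pool_rows, 10^(est - 1.96 * sd_th), est - 1.96 * sd_th)
  hi_nat <- ifelse(pool_rows, 10^(est + 1.96 * sd_th), est + 1.96 * sd_th)
  parameters <- tibble::tibble(
    term = par_names, estimate = est_nat, sd = sd_nat, sd_theta = sd_th,
    conf_low = lo_nat, conf_high = hi_nat, identifiable = ci$identifiable)

  fv <- stats::setNames(theta[seq_along(free)], free)
  fluxes <- complete_fluxes(basis, fv, nonneg_tol = 1e-4)
  pools_out <- pools_fixed
  if (length(pool_par)) pools_out[pool_par] <- 10^theta[-seq_along(free)]

  resid_tbl <- measured
  resid_tbl$residual <- r_data

  fit <- list(parameters = parameters, ssr = ssr,
              n_measurements = nrow(measured), n_parameters = n_par,
              dof = chi$dof, threshold = chi$threshold, accepted = chi$accepted,
              converged = best$info %in% 1:4, info = best$message,
              cov = ci$cov, fluxes = fluxes, pools = pools_out,
              residuals = resid_tbl, seed = cfg$seed,
              residual_fn = resfn, theta = theta)
  class(fit) <- "flux_fit"
  fit
}

# covariance of theta by finite-difference Jacobian of the weighted residual
# vector; rank-deficient directions are flagged unidentifiable and handled by
# pseudo-inverse rather than failing
linearized_covariance <- function(resfn, theta, n_data, h = 1e-5) {
  n <- length(theta)
  r0 <- resfn(theta)[seq_len(n_data)]
  J <- matrix(0, n_data, n)
  for (j in seq_len(n)) {
    step <- h * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + step
    J[, j] <- (resfn(tp)[seq_len(n_data)] - r0) / step
  }
  JtJ <- crossprod(J)
  ev <- eigen(JtJ, symmetric = TRUE)
  tol <- max(ev$values) * 1e-10
  pos <- ev$values > tol
  inv_vals <- ifelse(pos, 1 / ev$values, 0)
  cov <- ev$vectors %*% (inv_vals * t(ev$vectors))
  # a parameter is unidentifiable if it loads on a null direction
  null_load <- if (all(pos)) rep(0, n) else
    sqrt(rowSums(ev$vectors[, !pos, drop = FALSE]^2))
  identifiable <- null_load < 1e-3
  cov[!identifiable, ] <- NA_real_
  cov[, !identifiable] <- NA_real_
  diag(cov)[!identifiable] <- Inf
  list(cov = cov, identifiable = identifiable, J = J)
}

#' Linearized confidence intervals of a fitted model
#'
#' Recomputes the parameter covariance `(J' W J)^-1` from the sensitivity of
#' all predicted fractions to the parameters at the optimum (the residuals
#' are already weighted by `1/sigma`, so `W` is built in), and returns
#' per-parameter standard deviations and 95% confidence intervals.
#' Rank-deficient directions are flagged as structurally unidentifiable and
#' receive unbounded intervals.
#'
#' @param fit A `flux_fit` from [fit_fluxes()].
#' @return Tibble with `term`, `estimate`, `sd`, `conf_low`, `conf_high`,
#'   `identifiable`.
#' @export
confidence_intervals <- function(fit) {
  stopifnot(inherits(fit, "flux_fit"))
  fit$parameters[, c("term", "estimate", "sd", "conf_low", "conf_high",
                     "identifiable")]
}

#' @export
print.flux_fit <- function(x, ...) {
  cat("<flux_fit> SSR = ", format(x$ssr, digits = 6),
      " on ", x$n_measurements, " points, ", x$n_parameters, " parameters\n",
      "  dof = ", x$dof, ", chi2(95%) = ", format(x$threshold, digits = 6),
      " -> ", if (x$accepted) "accepted" else "rejected", "\n", sep = "")
  invisible(x)
}
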