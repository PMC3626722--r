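# Network-embedded thermodynamic (NET) analysis: second-law consistency of
# metabolite concentrations with assumed flux directions, range tightening,
# mass-action ratios, and minimum cofactor ratios.

GAS_CONSTANT <- 8.314462618e-3  # kJ/mol/K

#' Construct a thermodynamic reaction model
#'
#' @param reactions Named list; each element is a named numeric vector of
#'   stoichiometric coefficients (negative = substrate, positive = product),
#'   over metabolite and cofactor ids. Water and protons are left out by
#'   convention (their activity is absorbed in the transformed standard Gibbs
#'   energies).
#' @param drg0 Named numeric vector of transformed standard reaction Gibbs
#'   energies (kJ/mol) at the model's pH and ionic strength, one per reaction.
#' @param temperature Kelvin (default 298.15).
#' @param ph Cytosolic pH (default 7.2; must lie in 6..9).
#' @param ionic_strength mol/L (default 0.15).
#' @param cell_volume Cell volume used to convert biomass-specific pools to
#'   concentrations, ml/gCDW (default 1.7).
#' @return An object of class `thermo_model`.
#' @export
thermo_model <- function(reactions, drg0, temperature = 298.15, ph = 7.2,
                         ionic_strength = 0.15, cell_volume = 1.7) {
  stopifnot(is.list(reactions), length(reactions) > 0)
  if (ph < 6 || ph > 9) stop("pH must lie in [6, 9]", call. = FALSE)
  if (cell_volume <= 0) stop("cell volume must be positive", call. = FALSE)
  missing <- setdiff(names(reactions), names(drg0))
  if (length(missing)) {
    stop("missing drg0 for reaction(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(reactions = reactions, drg0 = drg0[names(reactions)],
                 temperature = temperature, ph = ph,
                 ionic_strength = ionic_strength, cell_volume = cell_volume),
            class = "thermo_model")
}

#' Read a thermodynamic model from YAML
#'
#' The file holds `temperature`, `ph`, `ionic_strength`, `cell_volume` and a
#' `reactions` mapping: per reaction a `stoich` mapping (metabolite ->
#' coefficient) and `drg0`, either a scalar (kJ/mol) or a mapping from pH
#' scenario (as string, e.g. `"7.2"`) to kJ/mol.
#'
#' @param path Path to the YAML file.
#' @param ph Optional pH scenario to select; defaults to the file's `ph`.
#' @return A `thermo_model`.
#' @export
read_thermo_model <- function(path, ph = NULL) {
  y <- yaml::read_yaml(path)
  ph <- ph %||% (y$ph %||% 7.2)
  reactions <- lapply(y$reactions, function(e) unlist(e$stoich))
  drg0 <- vapply(y$reactions, function(e) {
    d <- e$drg0
    if (is.list(d) || length(d) > 1) {
      key <- format(ph, nsmall = 1)
      d <- unlist(d)
      if (!key %in% names(d)) {
        stop("no drg0 entry for pH scenario ", key, call. = FALSE)
      }
      d[[key]]
    } else as.numeric(d)
  }, numeric(1))
  names(reactions) <- names(drg0) <- names(y$reactions)
  thermo_model(reactions, drg0,
               temperature = y$temperature %||% 298.15, ph = ph,
               ionic_strength = y$ionic_strength %||% 0.15,
               cell_volume = y$cell_volume %||% 1.7)
}

#' Convert biomass-specific pools to molar concentrations
#'
#' @param pool Pool size(s), umol/gCDW.
#' @param volume Cell volume, ml/gCDW (default 1.7).
#' @return Concentration in mM (`pool / volume`).
#' @export
to_molar <- function(pool, volume = 1.7) {
  if (volume <= 0) stop("volume must be positive", call. = FALSE)
  if (any(pool <= 0)) stop("pool sizes must be positive", call. = FALSE)
  pool / volume
}

#' @rdname to_molar
#' @param conc Concentration in mM.
#' @export
from_molar <- function(conc, volume = 1.7) {
  if (volume <= 0) stop("volume must be positive", call. = FALSE)
  conc * volume
}

#' Concentration range from replicate measurements
#'
#' Lower and upper limits of a measured concentration defined by a Student-t
#' confidence interval (default 80%) around the replicate mean:
#' `mean +/- t((1+c)/2, n-1) * sd / sqrt(n)`.
#'
#' @param mean,sd Replicate mean and standard deviation.
#' @param n Number of replicates (>= 2).
#' @param confidence Central confidence level (default 0.80).
#' @return Numeric vector `c(lower, upper)`.
#' @export
student_t_range <- function(mean, sd, n, confidence = 0.80) {
  if (n < 2) stop("need at least 2 replicates", call. = FALSE)
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  half <- stats::qt((1 + confidence) / 2, df = n - 1) * sd / sqrt(n)
  c(mean - half, mean + half)
}

#' Build concentration ranges for NET analysis
#'
#' Measured pools (umol/gCDW, replicate mean/sd/n) become mM ranges via the
#' cell volume and a Student-t interval; metabolites of `all_ids` without
#' measurements receive the default range.
#'
#' @param measurements Tibble/data.frame with columns `metabolite`, `mean`,
#'   `sd`, `n` (pools in umol/gCDW).
#' @param all_ids Metabolite ids that need a range (defaults to the measured
#'   ones).
#' @param volume Cell volume, ml/gCDW.
#' @param confidence Student-t confidence level.
#' @param default_range A-priori range for unmeasured metabolites, mM.
#' @param min_mM Positivity floor for lower bounds, mM.
#' @return Tibble with `metabolite`, `lower`, `upper` (mM), `source`.
#' @export
concentration_ranges <- function(measurements, all_ids = NULL, volume = 1.7,
                                 confidence = 0.80,
                                 default_range = c(1e-3, 10), min_mM = 1e-6) {
  meas <- tibble::as_tibble(measurements)
  rows <- lapply(seq_len(nrow(meas)), function(i) {
    r <- student_t_range(meas$mean[i], meas$sd[i], meas$n[i], confidence)
    tibble::tibble(metabolite = meas$metabolite[i],
                   lower = max(r[1] / volume, min_mM),
                   upper = max(r[2] / volume, min_mM),
                   source = "measured")
  })
  out <- dplyr::bind_rows(rows)
  extra <- setdiff(all_ids %||% character(0), out$metabolite)
  if (length(extra)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      metabolite = extra, lower = default_range[1], upper = default_range[2],
      source = "default"))
  }
  out
}

#' Mass-action ratio of a reaction
#'
#' `Q = prod(products^nu) / prod(substrates^nu)` on the molar scale, water
#' and protons excluded. For an isomerization this is simply the
#' product/substrate concentration ratio.
#'
#' @param stoich Named numeric vector of stoichiometric coefficients.
#' @param concentrations Named numeric vector of concentrations in mM.
#' @return The dimensionless ratio Q.
#' @export
mass_action_ratio <- function(stoich, concentrations) {
  ids <- names(stoich)
  missing <- setdiff(ids, names(concentrations))
  if (length(missing)) {
    stop("missing concentration for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  c_M <- concentrations[ids] / 1000
  if (any(c_M <= 0)) {
    stop("non-positive concentration for: ",
         paste(ids[c_M <= 0], collapse = ", "), call. = FALSE)
  }
  prod(c_M^stoich)
}

#' Transformed Gibbs energy of reaction at given concentrations
#'
#' `drG' = drG'0 + R T ln Q`. A reaction can only proceed in the direction of
#' negative drG'.
#'
#' @param model A `thermo_model`.
#' @param reaction Reaction id in the model.
#' @param concentrations Named vector of concentrations, mM.
#' @return drG' in kJ/mol.
#' @export
reaction_gibbs <- function(model, reaction, concentrations) {
  if (!reaction %in% names(model$reactions)) {
    stop("unknown reaction: ", reaction, call. = FALSE)
  }
  Q <- mass_action_ratio(model$reactions[[reaction]], concentrations)
  model$drg0[[reaction]] + GAS_CONSTANT * model$temperature * log(Q)
}

# box-constrained LP: optimize obj'x subject to A x <= b, lower <= x <= upper.
# Shifts to non-negative variables for pracma's simplex solver. The solver
# breaks pivoting ties randomly, so the RNG state is isolated (results must
# not depend on the caller's seed) and a few fixed seeds are retried before
# declaring failure.
lp_box <- function(obj, A, b, lower, upper, maximize = FALSE) {
  n <- length(obj)
  if (is.null(A)) A <- matrix(0, 0, n)
  b_sh <- b - drop(A %*% lower)
  A_all <- rbind(A, diag(n))
  b_all <- c(b_sh, upper - lower)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })

  res <- NULL
  for (lp_seed in 1:5) {
    set.seed(lp_seed)
    res <- tryCatch(
      suppressWarnings(
        pracma::linprog(cc = obj, A = A_all, b = b_all, maximize = maximize,
                        maxiter = 1000)),
      error = function(e) NULL)
    if (!is.null(res) && !is.null(res$errno) && res$errno == 1 &&
        !anyNA(res$x)) break
    res <- NULL
  }
  if (is.null(res)) {
    return(list(ok = FALSE, x = NULL, value = NA_real_))
  }
  list(ok = TRUE, x = res$x + lower, value = res$fval + sum(obj * lower))
}

# assemble the NET constraint system in x = ln(c in M):
# for each reaction with direction d != 0:  d * (drg0 + RT * S'x) <= -eps
net_constraints <- function(model, directions, ids, eps = 1e-6) {
  RT <- GAS_CONSTANT * model$temperature
  rows <- list(); rhs <- numeric(0); labels <- character(0)
  for (rid in names(directions)) {
    d <- directions[[rid]]
    if (d == 0) next
    st <- model$reactions[[rid]]
    if (is.null(st)) stop("direction given for unknown reaction: ", rid,
                          call. = FALSE)
    missing <- setdiff(names(st), ids)
    if (length(missing)) {
      stop("reaction '", rid, "' involves metabolite(s) without a ",
           "concentration range: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    row <- stats::setNames(numeric(length(ids)), ids)
    row[names(st)] <- d * RT * st
    rows[[length(rows) + 1L]] <- row
    rhs <- c(rhs, -eps - d * model$drg0[[rid]])
    labels <- c(labels, rid)
  }
  A <- do.call(rbind, rows)
  if (is.null(A)) A <- matrix(0, 0, length(ids), dimnames = list(NULL, ids))
  rownames(A) <- labels
  list(A = A, b = rhs)
}

#' Network-embedded thermodynamic feasibility and range tightening
#'
#' Solves, in log-concentration space, the minimum and maximum of each
#' metabolite concentration subject to (i) the input concentration ranges and
#' (ii) `drG' < 0` for every reaction with a nonzero assumed direction — a
#' linear program per bound. Output ranges are always contained in the input
#' ranges. If the constraint system is infeasible, the violated reaction set
#' is identified by minimizing a common slack.
#'
#' @param model A `thermo_model`.
#' @param directions Named vector over reaction ids: +1 (forward), -1
#'   (backward) or 0 (ignored / near-equilibrium).
#' @param ranges Tibble from [concentration_ranges()] covering every
#'   metabolite of every directed reaction.
#' @return Object of class `net_result`: tibble with input and tightened
#'   ranges (mM) and a `feasible` attribute; when infeasible, attribute
#'   `violated` names the incompatible reactions and the range columns carry
#'   the input ranges unchanged.
#' @export
net_feasibility <- function(model, directions, ranges) {
  ids <- ranges$metabolite
  lower <- log(ranges$lower / 1000)
  upper <- log(ranges$upper / 1000)
  cs <- net_constraints(model, directions, ids)

  # feasibility via the minimum common slack: s* = 0 means the directed
  # constraint system admits a concentration vector within the input boxes;
  # s* > 0 localizes the violated constraints
  nA <- nrow(cs$A)
  A2 <- cbind(cs$A, rep(-1, nA))
  obj <- c(rep(0, length(ids)), 1)
  sl <- lp_box(obj, A2, cs$b, c(lower, 0), c(upper, 1e6))
  if (!sl$ok) stop("LP solver failed on the NET constraint system",
                   call. = FALSE)
  if (sl$value > 1e-7) {
    margins <- drop(cs$A %*% sl$x[seq_along(ids)]) - cs$b
    violated <- rownames(cs$A)[margins > -1e-9]
    out <- tibble::tibble(metabolite = ids,
                          lower = ranges$lower, upper = ranges$upper,
                          lower_net = ranges$lower, upper_net = ranges$upper,
                          tightened = FALSE)
    attr(out, "feasible") <- FALSE
    attr(out, "violated") <- violated
    class(out) <- c("net_result", class(out))
    return(out)
  }

  lo_net <- hi_net <- numeric(length(ids))
  for (i in seq_along(ids)) {
    obj <- numeric(length(ids)); obj[i] <- 1
    lo <- lp_box(obj, cs$A, cs$b, lower, upper, maximize = FALSE)
    hi <- lp_box(obj, cs$A, cs$b, lower, upper, maximize = TRUE)
    if (!lo$ok || !hi$ok) {
      stop("LP failed while tightening range of ", ids[i], call. = FALSE)
    }
    lo_net[i] <- exp(lo$x[i]) * 1000
    hi_net[i] <- exp(hi$x[i]) * 1000
  }
  out <- tibble::tibble(metabolite = ids,
                        lower = ranges$lower, upper = ranges$upper,
                        lower_net = pmax(lo_net, ranges$lower),
                        upper_net = pmin(hi_net, ranges$upper))
  out$tightened <- out$lower_net > out$lower * (1 + 1e-9) |
    out$upper_net < out$upper * (1 - 1e-9)
  attr(out, "feasible") <- TRUE
  attr(out, "violated") <- character(0)
  class(out) <- c("net_result", class(out))
  out
}

#' @export
print.net_result <- function(x, ...) {
  if (attr(x, "feasible")) {
    cat("<net_result> feasible;", sum(x$tightened), "of", nrow(x),
        "ranges tightened\n")
  } else {
    cat("<net_result> INFEASIBLE; violated constraints:",
        paste(attr(x, "violated"), collapse = ", "), "\n")
  }
  NextMethod()
}

#' Minimum thermodynamically feasible cofactor ratio
#'
#' Minimizes `ln(c_ox) - ln(c_red)` over the NET-feasible concentration
#' space, e.g. the minimum NAD+/NADH ratio compatible with the measured
#' metabolome and the assumed flux directions.
#'
#' @param model A `thermo_model`.
#' @param directions Directed reaction set as in [net_feasibility()].
#' @param ranges Concentration ranges covering both couple members.
#' @param couple Character vector `c(oxidized, reduced)`.
#' @return List with `ratio` (minimum feasible ox/red ratio), `log_ratio`,
#'   and `bounded` (FALSE when no directed reaction couples the pair, in
#'   which case the ratio only reflects the input ranges).
#' @export
min_cofactor_ratio <- function(model, directions, ranges,
                               couple = c("NAD", "NADH")) {
  ids <- ranges$metabolite
  if (!all(couple %in% ids)) {
    stop("ranges must cover both couple members: ",
         paste(couple, collapse = "/"), call. = FALSE)
  }
  active <- names(directions)[directions != 0]
  coupled <- any(vapply(active, function(rid) {
    any(couple %in% names(model$reactions[[rid]]))
  }, logical(1)))
  cs <- net_constraints(model, directions, ids)
  obj <- stats::setNames(numeric(length(ids)), ids)
  obj[couple[1]] <- 1; obj[couple[2]] <- -1
  res <- lp_box(unname(obj), cs$A, cs$b,
                log(ranges$lower / 1000), log(ranges$upper / 1000))
  if (!res$ok) stop("NET constraint system infeasible", call. = FALSE)
  lr <- res$x[match(couple[1], ids)] - res$x[match(couple[2], ids)]
  list(ratio = exp(lr), log_ratio = lr, bounded = coupled)
}
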