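# Macroscopic chemostat rates: respiratory quotient, carbon recovery,
# elemental-balance reconciliation, and cofactor/ATP bookkeeping on a fitted
# flux distribution.

#' Macroscopic chemostat rates
#'
#' @param q_glucose,q_methanol Substrate uptake rates, mmol/gCDW/h (negative
#'   for uptake).
#' @param our Oxygen uptake rate, mmol/gCDW/h (negative).
#' @param cer Carbon dioxide evolution rate, mmol/gCDW/h (positive).
#' @param q_biomass Biomass formation rate, mCmol/gCDW/h (positive).
#' @param sd Named numeric vector of standard deviations (same names as the
#'   rates).
#' @param dilution Chemostat dilution rate, 1/h (default 0.09).
#' @return A tibble of class `macro_rates` with columns `rate`, `value`,
#'   `sd`, plus a `dilution` attribute.
#' @examples
#' macro_rates(-0.71, -0.94, -2.57, 2.03, 3.14,
#'             sd = c(q_glucose = 0.01, q_methanol = 0.02, our = 0.03,
#'                    cer = 0.03, q_biomass = 0.04))
#' @export
macro_rates <- function(q_glucose, q_methanol, our, cer, q_biomass,
                        sd = NULL, dilution = 0.09) {
  values <- c(q_glucose = q_glucose, q_methanol = q_methanol, our = our,
              cer = cer, q_biomass = q_biomass)
  if (q_glucose > 0 || q_methanol > 0 || our > 0) {
    stop("uptake rates (glucose, methanol, O2) must be negative", call. = FALSE)
  }
  if (cer < 0 || q_biomass < 0) {
    stop("production rates (CO2, biomass) must be positive", call. = FALSE)
  }
  sds <- stats::setNames(rep(NA_real_, 5), names(values))
  if (!is.null(sd)) sds[names(sd)] <- sd
  if (any(!is.na(sds) & sds <= 0)) stop("sds must be > 0", call. = FALSE)
  out <- tibble::tibble(rate = names(values), value = unname(values),
                        sd = unname(sds))
  attr(out, "dilution") <- dilution
  class(out) <- c("macro_rates", class(out))
  out
}

#' Read macroscopic rates from CSV
#'
#' Columns `rate`, `value`, `sd`; rates named `q_glucose`, `q_methanol`,
#' `our`, `cer`, `q_biomass`.
#' @param path CSV file path.
#' @param dilution Dilution rate, 1/h.
#' @return A `macro_rates` tibble.
#' @export
read_rates <- function(path, dilution = 0.09) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  v <- stats::setNames(d$value, d$rate)
  s <- stats::setNames(d$sd, d$rate)
  macro_rates(v[["q_glucose"]], v[["q_methanol"]], v[["our"]], v[["cer"]],
              v[["q_biomass"]], sd = s, dilution = dilution)
}

rate_value <- function(rates, name) rates$value[match(name, rates$rate)]

#' Respiratory quotient
#'
#' @param rates A `macro_rates` tibble.
#' @return RQ = CER / |OUR|.
#' @export
respiratory_quotient <- function(rates) {
  our <- rate_value(rates, "our")
  if (our == 0) stop("OUR is zero", call. = FALSE)
  rate_value(rates, "cer") / abs(our)
}

#' Carbon recovery of measured rates
#'
#' Fraction of the carbon taken up (6 C per glucose, 1 C per methanol) that
#' is recovered in biomass and CO2.
#'
#' @param rates A `macro_rates` tibble.
#' @return Recovery in percent.
#' @export
carbon_recovery <- function(rates) {
  c_in <- 6 * abs(rate_value(rates, "q_glucose")) +
    abs(rate_value(rates, "q_methanol"))
  if (c_in == 0) stop("no carbon uptake", call. = FALSE)
  100 * (rate_value(rates, "q_biomass") + rate_value(rates, "cer")) / c_in
}

#' Default biomass elemental composition
#'
#' Per-Cmol composition CH1.76O0.63N0.14 (a typical yeast value; the degree
#' of reduction relative to NH3 as nitrogen source follows as
#' 4 + H - 2 O - 3 N).
#' @return Named list with `H`, `O`, `N` and `gamma`.
#' @export
biomass_composition <- function() {
  comp <- list(H = 1.76, O = 0.63, N = 0.14)
  comp$gamma <- 4 + comp$H - 2 * comp$O - 3 * comp$N
  comp
}

# elemental balance matrix over (q_glucose, q_methanol, our, cer, q_biomass):
# carbon and degree-of-reduction conservation
elemental_matrix <- function(composition = biomass_composition()) {
  rbind(carbon = c(6, 1, 0, 1, 1),
        redox  = c(24, 6, -4, 0, composition$gamma))
}

#' Reconcile measured rates against elemental balances
#'
#' Weighted least-squares projection of the measured rate vector onto the
#' subspace satisfying carbon and degree-of-reduction conservation, with a
#' chi-square consistency test on the balance residuals (gross measurement
#' error detection).
#'
#' @param rates A `macro_rates` tibble with sds for every rate.
#' @param composition Biomass elemental composition, see
#'   [biomass_composition()].
#' @param alpha Significance level of the consistency test (default 0.05).
#' @return A list with `reconciled` (a `macro_rates` tibble), `h` (test
#'   statistic), `dof`, `threshold`, `consistent` (logical), and `residuals`
#'   (the balance residuals of the measured rates).
#' @export
reconcile_rates <- function(rates, composition = biomass_composition(),
                            alpha = 0.05) {
  if (anyNA(rates$sd)) stop("reconciliation needs an sd for every rate",
                            call. = FALSE)
  y <- rates$value
  E <- elemental_matrix(composition)
  Sig <- diag(rates$sd^2)
  ESE <- E %*% Sig %*% t(E)
  if (rcond(ESE) < 1e-12) stop("singular covariance of balance residuals",
                               call. = FALSE)
  eps <- drop(E %*% y)
  K <- solve(ESE)
  h <- drop(t(eps) %*% K %*% eps)
  y_hat <- y - drop(Sig %*% t(E) %*% K %*% eps)
  dof <- nrow(E)
  threshold <- stats::qchisq(1 - alpha, df = dof)
  rec <- rates
  rec$value <- y_hat
  list(reconciled = rec, h = h, dof = dof, threshold = threshold,
       consistent = h <= threshold, residuals = eps)
}

#' Cofactor stoichiometry of a reaction network
#'
#' @param coefficients Named list of named numeric vectors: per cofactor
#'   (`NADH`, `NADPH`, `ATP`, `FADH2`), production coefficients per reaction
#'   id (mol cofactor per mol reaction flux; consumption negative). Reactions
#'   not listed contribute zero.
#' @param po_ratio P/O ratio, mol ATP per mol O reduced in oxidative
#'   phosphorylation (default 1.48).
#' @param growth_atp Growth-associated ATP demand, mmol ATP/gCDW/h at the
#'   operating growth rate.
#' @return An object of class `cofactor_stoichiometry`.
#' @export
cofactor_stoichiometry <- function(coefficients, po_ratio = 1.48,
                                   growth_atp = 0) {
  if (po_ratio <= 0) stop("P/O ratio must be positive", call. = FALSE)
  stopifnot(is.list(coefficients))
  structure(list(coefficients = coefficients, po_ratio = po_ratio,
                 growth_atp = growth_atp),
            class = "cofactor_stoichiometry")
}

#' Read cofactor stoichiometry from YAML
#'
#' Keys: `po_ratio`, `growth_atp`, and per-cofactor mappings reaction ->
#' coefficient.
#' @param path YAML file path.
#' @return A `cofactor_stoichiometry`.
#' @export
read_cofactors <- function(path) {
  y <- yaml::read_yaml(path)
  po <- y$po_ratio %||% 1.48
  ga <- y$growth_atp %||% 0
  y$po_ratio <- NULL; y$growth_atp <- NULL
  cofactor_stoichiometry(lapply(y, unlist), po_ratio = po, growth_atp = ga)
}

#' Net cofactor production rates from a flux distribution
#'
#' `rate(cofactor) = sum_j coeff_j * v_net_j` over all reactions.
#'
#' @param fluxes A `flux_distribution`.
#' @param stoich A `cofactor_stoichiometry`.
#' @return Named numeric vector of net production rates, mmol/gCDW/h.
#' @export
cofactor_rates <- function(fluxes, stoich) {
  v <- stats::setNames(fluxes$net, fluxes$reaction)
  vapply(stoich$coefficients, function(cf) {
    missing <- setdiff(names(cf), names(v))
    if (length(missing)) {
      stop("cofactor coefficients name unknown reaction(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    sum(cf * v[names(cf)])
  }, numeric(1))
}

#' Theoretical oxygen consumption from surplus redox equivalents
#'
#' Assumes every NADH (and FADH2) not reconsumed within the network is
#' reoxidized by the respiratory chain: each pair of electrons reduces one O
#' atom, so `qO2 = (NADH + FADH2) / 2`.
#'
#' @param nadh_surplus,fadh2_surplus Net production rates, mmol/gCDW/h
#'   (must be >= 0; a negative surplus signals an upstream cofactor
#'   imbalance).
#' @param measured_our Optional measured oxygen uptake rate (signed,
#'   mmol/gCDW/h) to express the theoretical rate as a percentage of.
#' @return List with `qO2` (mmol O2/gCDW/h) and, if `measured_our` is given,
#'   `percent_of_measured`.
#' @export
theoretical_qO2 <- function(nadh_surplus, fadh2_surplus = 0,
                            measured_our = NULL) {
  if (nadh_surplus < 0 || fadh2_surplus < 0) {
    stop("negative redox surplus: cofactor balance is inconsistent upstream",
         call. = FALSE)
  }
  qO2 <- (nadh_surplus + fadh2_surplus) / 2
  out <- list(qO2 = qO2)
  if (!is.null(measured_our)) {
    out$percent_of_measured <- 100 * qO2 / abs(measured_our)
  }
  out
}

#' ATP generation and maintenance accounting
#'
#' Oxidative phosphorylation yields `2 * (P/O) * qO2` (each O2 carries two O
#' atoms); substrate-level ATP follows from the reaction stoichiometry and
#' net fluxes; the non-growth-associated maintenance is what remains after
#' subtracting the growth-associated demand.
#'
#' @param fluxes A `flux_distribution`.
#' @param stoich A `cofactor_stoichiometry` (its `ATP` coefficients give
#'   substrate-level phosphorylation; `growth_atp` the growth demand).
#' @param qO2_used Oxygen consumption attributed to respiration,
#'   mmol O2/gCDW/h.
#' @return List with `total`, `substrate_level`, `oxphos`,
#'   `substrate_fraction`, `oxphos_fraction`, `maintenance`, and
#'   `maintenance_negative` (flag; a negative maintenance is reported, not
#'   clamped).
#' @export
atp_accounting <- function(fluxes, stoich, qO2_used) {
  sub <- if (is.null(stoich$coefficients$ATP)) 0 else
    unname(cofactor_rates(fluxes, stoich)[["ATP"]])
  oxphos <- 2 * stoich$po_ratio * qO2_used
  total <- sub + oxphos
  maintenance <- total - stoich$growth_atp
  list(total = total, substrate_level = sub, oxphos = oxphos,
       substrate_fraction = if (total > 0) sub / total else NA_real_,
       oxphos_fraction = if (total > 0) oxphos / total else NA_real_,
       maintenance = maintenance,
       maintenance_negative = maintenance < 0)
}
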