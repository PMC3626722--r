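# Configuration-driven orchestration of the analysis stages:
# simulate -> fit -> chi-square -> confidence intervals -> NET -> balances.
# Every stage reads a YAML (or list) configuration, writes JSON/CSV reports
# into an output directory, and embeds the configuration hash and the seed so
# that runs are reproducible and auditable.

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

config_stamp <- function(config, seed) {
  list(config_hash = rlang::hash(config), seed = seed,
       package = as.character(utils::packageVersion("instaflux")))
}

resolve_path <- function(x, what) {
  if (is.null(x)) stop("config is missing the '", what, "' entry", call. = FALSE)
  if (!file.exists(x)) stop(what, " file not found: ", x, call. = FALSE)
  x
}

# shared loading of network/constraints/fragments (+ demo shortcuts)
load_model_inputs <- function(cfg) {
  if (identical(cfg$network, "pichia") || is.null(cfg$network)) {
    network <- pichia_network()
    constraints <- pichia_constraints()
    fragments <- pichia_fragments()
  } else {
    network <- parse_network(resolve_path(cfg$network, "network"))
    constraints <- if (is.null(cfg$constraints)) flux_constraints() else
      read_constraints(resolve_path(cfg$constraints, "constraints"))
    fragments <- read_fragments(resolve_path(cfg$fragments, "fragments"))
  }
  list(network = network, constraints = constraints, fragments = fragments)
}

load_fluxes <- function(cfg, basis) {
  if (identical(cfg$fluxes %||% "demo", "demo")) return(pichia_demo_fluxes())
  d <- readr::read_csv(resolve_path(cfg$fluxes, "fluxes"),
                       show_col_types = FALSE)
  complete_fluxes(basis, stats::setNames(d$value, d$term))
}

load_pools <- function(cfg) {
  if (identical(cfg$pools %||% "demo", "demo")) return(pichia_demo_pools())
  d <- readr::read_csv(resolve_path(cfg$pools, "pools"), show_col_types = FALSE)
  stats::setNames(d$pool, d$metabolite)
}

# feed spec in a config: mapping substrate -> list of {pattern, fraction}
config_feed <- function(cfg) {
  if (is.null(cfg$feed)) return(pichia_feed())
  feed_labeling(lapply(cfg$feed, function(entries) {
    lapply(entries, function(e) {
      list(pattern = as.numeric(unlist(e$pattern)), fraction = e$fraction)
    })
  }))
}

config_times <- function(cfg) {
  tc <- cfg$times %||% list()
  exp_time_grid(t_first = (tc$first_s %||% 5) / 3600,
                t_last = tc$last_h %||% 6, n = tc$n %||% 20)
}

write_report <- function(report, out_dir, name) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, name)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Simulate labeling dynamics from a configuration
#'
#' Config keys: `network`/`constraints`/`fragments` (paths, or `network:
#' pichia` for the shipped model), `fluxes` (`demo` or CSV of free-flux
#' values), `pools` (`demo` or CSV), `times` (`n`, `first_s`, `last_h`),
#' `noise` (`rel_sigma`; 0 = noise-free), `seed`.
#'
#' @param config YAML path or list.
#' @param out_dir Output directory (default `config$out` or "instaflux_out").
#' @param seed Overrides `config$seed`.
#' @return List with the simulated table and file paths, invisibly.
#' @export
run_simulate <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- read_run_config(config)
  seed <- seed %||% cfg$seed %||% 1
  out_dir <- out_dir %||% cfg$out %||% "instaflux_out"
  mi <- load_model_inputs(cfg)
  basis <- free_flux_basis(mi$network, mi$constraints)
  fluxes <- load_fluxes(cfg, basis)
  pools <- load_pools(cfg)
  system <- emu_decompose(mi$network, mi$fragments)
  design <- experiment_design(feed = config_feed(cfg),
                              times = config_times(cfg),
                              rel_sigma = cfg$noise$rel_sigma %||% 0,
                              seed = seed)
  truth <- structure(list(fluxes = fluxes, pools = pools, seed = seed),
                     class = "ground_truth")
  mid <- generate_labeling_dataset(truth, system, design, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "mid_timeseries.csv")
  write_mid_csv(mid, csv, rel_sigma = max(design$rel_sigma, 0.02))
  report <- c(config_stamp(cfg, seed),
              list(n_fragments = nrow(mi$fragments),
                   n_times = length(design$times),
                   n_points = nrow(mid),
                   rel_sigma = design$rel_sigma,
                   mid_csv = csv))
  write_report(report, out_dir, "simulate_report.json")
  invisible(list(mid = mid, report = report))
}

#' Fit fluxes and pools from a configuration
#'
#' Additional config keys over [run_simulate()]: `data` (measured MID CSV),
#' `fit` (`starts`, `maxiter`, `flux_upper`, `pool_bounds`). Measured pool
#' sizes are taken from `pools_measured` (CSV) or the shipped table.
#'
#' @inheritParams run_simulate
#' @return List with the `flux_fit` and report paths, invisibly.
#' @export
run_fit <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- read_run_config(config)
  seed <- seed %||% cfg$seed %||% 1
  out_dir <- out_dir %||% cfg$out %||% "instaflux_out"
  mi <- load_model_inputs(cfg)
  basis <- free_flux_basis(mi$network, mi$constraints)
  system <- emu_decompose(mi$network, mi$fragments)
  measured <- read_mid_csv(resolve_path(cfg$data, "data"))
  pools <- if (!is.null(cfg$pools_measured)) {
    d <- readr::read_csv(resolve_path(cfg$pools_measured, "pools_measured"),
                         show_col_types = FALSE)
    stats::setNames(d$pool, d$metabolite)
  } else pichia_pools()
  fc <- cfg$fit %||% list()
  fit <- fit_fluxes(basis, system, measured, config_feed(cfg),
                    pools = pools,
                    config = list(starts = fc$starts %||% 10, seed = seed,
                                  maxiter = fc$maxiter %||% 50,
                                  flux_upper = fc$flux_upper %||% 10,
                                  pool_bounds = fc$pool_bounds %||% c(1e-3, 50)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(fit$residuals, file.path(out_dir, "residuals.csv"))
  report <- c(config_stamp(cfg, seed),
              list(ssr = fit$ssr, n_measurements = fit$n_measurements,
                   n_parameters = fit$n_parameters, dof = fit$dof,
                   chi2_threshold = fit$threshold, accepted = fit$accepted,
                   converged = fit$converged,
                   parameters = tidy(fit)[, c("term", "estimate", "sd",
                                              "conf_low", "conf_high",
                                              "identifiable")]))
  write_report(report, out_dir, "fit_report.json")
  invisible(list(fit = fit, report = report))
}

#' NET thermodynamic analysis from a configuration
#'
#' Config keys: `thermo` (model YAML; default the shipped one), `ph`
#' (scenario), `concentrations` (CSV mean/sd/n in umol/gCDW; default
#' shipped), `directions` (mapping reaction -> -1/0/1), `couple` (optional,
#' e.g. `[NAD, NADH]`), `confidence` (Student-t level, default 0.8).
#'
#' @inheritParams run_simulate
#' @return List with the `net_result` and report, invisibly.
#' @export
run_thermo <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- read_run_config(config)
  seed <- seed %||% cfg$seed %||% 1
  out_dir <- out_dir %||% cfg$out %||% "instaflux_out"
  model <- read_thermo_model(
    if (is.null(cfg$thermo)) instaflux_example("pichia_thermo.yaml")
    else resolve_path(cfg$thermo, "thermo"),
    ph = cfg$ph)
  conc_path <- if (is.null(cfg$concentrations))
    instaflux_example("pichia_concentrations.csv")
  else resolve_path(cfg$concentrations, "concentrations")
  meas <- readr::read_csv(conc_path, show_col_types = FALSE)
  all_ids <- unique(unlist(lapply(model$reactions, names)))
  ranges <- concentration_ranges(meas, all_ids = all_ids,
                                 volume = model$cell_volume,
                                 confidence = cfg$confidence %||% 0.8)
  directions <- unlist(cfg$directions %||%
                         lapply(model$reactions, function(x) 1))
  net <- net_feasibility(model, directions, ranges)
  report <- c(config_stamp(cfg, seed),
              list(ph = model$ph, feasible = attr(net, "feasible"),
                   violated = attr(net, "violated"),
                   n_tightened = sum(net$tightened),
                   ranges = tibble::as_tibble(net)))
  if (!is.null(cfg$couple)) {
    mc <- min_cofactor_ratio(model, directions, ranges,
                             couple = unlist(cfg$couple))
    report$min_cofactor_ratio <- mc$ratio
    report$cofactor_ratio_bounded <- mc$bounded
  }
  write_report(report, out_dir, "thermo_report.json")
  txt <- file.path(out_dir, "thermo_report.txt")
  writeLines(c(
    sprintf("NET analysis at pH %.1f: %s", model$ph,
            if (attr(net, "feasible")) "feasible" else
              paste("INFEASIBLE; violated:",
                    paste(attr(net, "violated"), collapse = ", "))),
    utils::capture.output(print(tibble::as_tibble(net), n = Inf))), txt)
  invisible(list(net = net, report = report))
}

#' Macroscopic and cofactor balances from a configuration
#'
#' Config keys: `rates` (CSV; default shipped Table-1-like rates),
#' `cofactors` (YAML; default shipped), `fluxes` (`demo` or free-flux CSV).
#'
#' @inheritParams run_simulate
#' @return List with the balance report, invisibly.
#' @export
run_balance <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- read_run_config(config)
  seed <- seed %||% cfg$seed %||% 1
  out_dir <- out_dir %||% cfg$out %||% "instaflux_out"
  rates <- read_rates(if (is.null(cfg$rates))
    instaflux_example("pichia_rates.csv") else resolve_path(cfg$rates, "rates"))
  stoich <- read_cofactors(if (is.null(cfg$cofactors))
    instaflux_example("pichia_cofactors.yaml")
    else resolve_path(cfg$cofactors, "cofactors"))
  mi <- load_model_inputs(cfg)
  basis <- free_flux_basis(mi$network, mi$constraints)
  fluxes <- load_fluxes(cfg, basis)

  rq <- respiratory_quotient(rates)
  recovery <- carbon_recovery(rates)
  rec <- reconcile_rates(rates)
  cof <- cofactor_rates(fluxes, stoich)
  nadh_surplus <- max(cof[["NADH"]], 0)
  qo2 <- theoretical_qO2(nadh_surplus, max(cof[["FADH2"]], 0),
                         measured_our = rate_value(rates, "our"))
  atp <- atp_accounting(fluxes, stoich, qo2$qO2)
  report <- c(config_stamp(cfg, seed),
              list(rq = rq, carbon_recovery_percent = recovery,
                   reconciliation = list(h = rec$h, dof = rec$dof,
                                         threshold = rec$threshold,
                                         consistent = rec$consistent,
                                         reconciled = rec$reconciled),
                   cofactor_rates = as.list(cof),
                   qO2_theoretical = qo2$qO2,
                   qO2_percent_of_measured = qo2$percent_of_measured,
                   atp = atp))
  write_report(report, out_dir, "balance_report.json")
  invisible(list(report = report))
}

#' Generate a synthetic dataset bundle from a configuration
#'
#' Samples (or loads) a ground truth and writes the noisy labeling, rates and
#' concentration tables in the dialects the other stages consume.
#'
#' @inheritParams run_simulate
#' @return List with the ground truth and file paths, invisibly.
#' @export
run_synth <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- read_run_config(config)
  seed <- seed %||% cfg$seed %||% 1
  out_dir <- out_dir %||% cfg$out %||% "instaflux_out"
  mi <- load_model_inputs(cfg)
  basis <- free_flux_basis(mi$network, mi$constraints)
  system <- emu_decompose(mi$network, mi$fragments)
  truth <- if (identical(cfg$truth %||% "demo", "demo")) {
    structure(list(fluxes = load_fluxes(cfg, basis),
                   pools = load_pools(cfg), seed = seed),
              class = "ground_truth")
  } else {
    sample_ground_truth(basis, seed = seed)
  }
  design <- experiment_design(feed = config_feed(cfg),
                              times = config_times(cfg),
                              rel_sigma = cfg$noise$rel_sigma %||% 0.02,
                              seed = seed)
  mid <- generate_labeling_dataset(truth, system, design, seed = seed)
  conc <- generate_concentration_dataset(truth$pools, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_mid_csv(mid, file.path(out_dir, "synthetic_mids.csv"),
                rel_sigma = design$rel_sigma)
  readr::write_csv(conc, file.path(out_dir, "synthetic_concentrations.csv"))
  # rates need the uptake/excretion reaction ids; generated only when the
  # network carries them (configurable through rates_map)
  rmap <- utils::modifyList(list(glucose = "upt1", methanol = "upt2",
                                 co2 = "co2out", drain_prefix = "bm_"),
                            cfg$rates_map %||% list())
  has_rates <- all(c(rmap$glucose, rmap$methanol, rmap$co2) %in%
                     mi$network$reactions$id)
  if (has_rates) {
    rates <- generate_rates_dataset(truth, mi$network, seed = seed,
                                    glucose = rmap$glucose,
                                    methanol = rmap$methanol, co2 = rmap$co2,
                                    drain_prefix = rmap$drain_prefix)
    readr::write_csv(rates, file.path(out_dir, "synthetic_rates.csv"))
  }
  report <- c(config_stamp(cfg, seed),
              list(n_points = nrow(mid), rel_sigma = design$rel_sigma))
  write_report(report, out_dir, "synth_report.json")
  invisible(list(truth = truth, report = report))
}
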