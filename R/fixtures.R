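# Shipped example data: the reduced P. pastoris glucose-methanol network and
# its companion tables.

#' Path to a shipped example file
#'
#' @param file File name under the package's `extdata` directory; `NULL`
#'   lists the available files.
#' @return Full path (or a vector of file names).
#' @export
instaflux_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "instaflux"))
  } else {
    system.file("extdata", file, package = "instaflux", mustWork = TRUE)
  }
}

#' The reduced P. pastoris glucose-methanol network
#'
#' Parses the shipped atom-transition network: 37 balanced metabolites and 79
#' reactions counting bidirectional fluxes and both members of each
#' symmetric-product pair.
#' @return An `mfa_network`.
#' @export
pichia_network <- function() {
  parse_network(instaflux_example("pichia_glcmeoh.net"))
}

#' Chemostat flux constraints of the shipped network
#'
#' Measured glucose and methanol uptake, nine biomass precursor drains, and
#' the unlabeled pyruvate source/sink tie.
#' @return A `flux_constraints` object.
#' @export
pichia_constraints <- function() {
  read_constraints(instaflux_example("pichia_constraints.yaml"))
}

#' Measured pool sizes of the shipped network
#'
#' 27 of the 37 balanced metabolites carry measured pools (umol/gCDW); the
#' remaining 10 (CO2, the PDH-bypass intermediates, formaldehyde/formate,
#' dihydroxyacetone, oxaloacetate and mitochondrial pyruvate) are left to
#' parameter estimation.
#' @return Named numeric vector.
#' @export
pichia_pools <- function() {
  d <- readr::read_csv(instaflux_example("pichia_pools.csv"),
                       show_col_types = FALSE)
  stats::setNames(d$pool, d$metabolite)
}

#' Measured fragment definitions of the shipped network
#'
#' @return Tibble of fragment specs (see [fragment_spec()]).
#' @export
pichia_fragments <- function() {
  read_fragments(instaflux_example("pichia_fragments.yaml"))
}

#' A paper-like demonstration flux distribution
#'
#' A feasible steady-state flux distribution on the shipped network whose
#' headline ratios mirror the study's fitted flux map: about 55% of
#' glucose-6-phosphate enters the oxidative PPP, about 54% of assimilated
#' methanol is directly dissimilated to CO2, trehalose cycling carries about
#' 1.5% of the glucose uptake, and the unlabeled mitochondrial pyruvate
#' source runs at 1.2 mmol/gCDW/h. These are demonstration settings for
#' examples and synthetic-data generation, not fitted results.
#'
#' @return A `flux_distribution`.
#' @export
pichia_demo_fluxes <- function() {
  basis <- free_flux_basis(pichia_network(), pichia_constraints())
  free_vals <- c(
    emp1_b = 1.4993774, emp2 = 0.1447047, emp4_b = 0.061295295,
    emp5_b = 0.075041051, emp6_b = 0.10804105, emp8 = 1.0869589,
    pyrT = 0.51870823, emp11D = 1.2, ppp1 = 0.3887548, ppp3 = 0.39983635,
    ppp4 = 0.079541053, ppp5 = 0.079541053, ppp6 = 0.09954105,
    ppp7 = 0.059541053, met2 = 0.50949151, tca5.b_b = 0.18402053,
    tca6.a = 0.40025145, tca7 = 0.66766067, tca7_b = 0.30733933,
    aa_ala = 0.36, aa_glu = 0.405, aa_asp = 0.46854394,
    aa_asp_b = 0.29145606, sto1 = 0.0052999999)
  complete_fluxes(basis, free_vals)
}

#' Demonstration pool sizes covering all balanced metabolites
#'
#' The measured pools of [pichia_pools()] plus plausible values for the ten
#' unmeasured pools (used as ground truth in examples and synthetic data).
#' @return Named numeric vector, umol/gCDW.
#' @export
pichia_demo_pools <- function() {
  c(pichia_pools(),
    c(CO2 = 0.05, AcAld = 0.05, Ace = 0.3, ACCoAc = 0.08, ACCoAm = 0.12,
      Form = 0.15, FOR = 0.25, DHA = 0.2, OAA = 0.1, PyrM = 0.5))
}
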