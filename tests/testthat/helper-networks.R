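# Shared toy networks and feeds for the test suite.

# linear chain A -> B -> C with full carbon carry-over
chain_net <- function() {
  parse_network(paste(
    "@boundary: S.ext P.ext",
    "u: S.ext(ab) -> A(ab)",
    "r1: A(ab) -> B(ab)",
    "r2: B(ab) -> C(ab)",
    "out: C(ab) -> P.ext(ab)",
    sep = "\n"))
}

# branched 3-carbon network with a decarboxylation and one reversible step;
# 2 free fluxes (branch split + exchange) once uptake is fixed
branch_net <- function() {
  parse_network(paste(
    "@boundary: S.ext P.ext Q.ext CO2.ext",
    "u: S.ext(abc) -> A(abc)",
    "f1: A(abc) -> B(abc)",
    "f2: A(abc) -> C(bc) + CO2.ext(a)",
    "f3: B(abc) <-> D(cba)",
    "f4: D(abc) -> P.ext(abc)",
    "f5: C(ab) -> Q.ext(ab)",
    sep = "\n"))
}

branch_feed <- function() {
  feed_labeling(list(
    S.ext = list(list(pattern = c(1, 0, 0), fraction = 0.5),
                 list(pattern = c(1, 1, 1), fraction = 0.5))))
}

# uptake 0.01 mmol/gCDW/h against pools of a few umol/gCDW gives turnover
# times of ~0.2-1.5 h, so the labeling transient spans the sampling window
branch_truth <- function(split = 0.6, exch = 0.003, uptake = 0.01,
                         pools = NULL) {
  net <- branch_net()
  basis <- free_flux_basis(net, flux_constraints(fixed = c(u = uptake)))
  f1 <- split * uptake
  fx <- flux_distribution(
    net,
    net = c(u = uptake, f1 = f1, f2 = uptake - f1, f3 = f1, f4 = f1,
            f5 = uptake - f1),
    exchange = c(f3 = exch))
  if (is.null(pools)) {
    pools <- c(A = 5, B = 8, C = 3, D = 15)
  }
  list(net = net, basis = basis, fluxes = fx, pools = pools)
}

branch_fragments <- function() {
  dplyr::bind_rows(
    fragment_spec("D_full", "D", 1:3),
    fragment_spec("C_full", "C", 1:2),
    fragment_spec("B_c12", "B", 1:2))
}

# condensation toy: two C3 units condense to a C6 (aldol-like)
aldol_net <- function() {
  parse_network(paste(
    "@boundary: S.ext P.ext",
    "u: S.ext(abc) -> T(abc)",
    "cond: T(abc) + T(def) -> H(abcdef)",
    "out: H(abcdef) -> P.ext(abcdef)",
    sep = "\n"))
}

# scrambling toy: symmetric 4-carbon intermediate with two 1:1 atom maps
scramble_net <- function() {
  parse_network(paste(
    "@boundary: S.ext P.ext",
    "u: S.ext(abcd) -> A(abcd)",
    "s1: A(abcd) -> F(abcd) | F(dcba)",
    "s2: F(abcd) -> B(abcd)",
    "out: B(abcd) -> P.ext(abcd)",
    sep = "\n"))
}
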