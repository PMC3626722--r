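test_that("decomposition produces the minimal EMU structure", {
  # single pool, whole-molecule target: one balanced EMU
  net <- parse_network("@boundary: S.ext P.ext\nu: S.ext(ab) -> A(ab)\no: A(ab) -> P.ext(ab)")
  sys <- emu_decompose(net, fragment_spec("a", "A", 1:2))
  expect_equal(sum(!sys$emus$is_input), 1)

  # aldol condensation: the C6 target is fed by a convolution of two size-3
  # EMUs of the same precursor pool
  an <- aldol_net()
  sysa <- emu_decompose(an, fragment_spec("h", "H", 1:6))
  conv <- Filter(function(ch) length(ch$sources) == 2, sysa$channels)
  expect_equal(length(conv), 1)
  sizes <- sys_sizes <- sysa$emus$size[match(conv[[1]]$sources, sysa$emus$key)]
  expect_equal(sort(sizes), c(3, 3))

  # EMU state count stays below the full positional-isotopomer count
  tr <- branch_truth()
  sysb <- emu_decompose(tr$net, branch_fragments())
  n_emu_states <- sum(sysb$emus$size[!sysb$emus$is_input] + 1)
  n_iso_states <- sum(2^tr$net$metabolites$n_carbons[!tr$net$metabolites$is_boundary])
  expect_lt(n_emu_states, n_iso_states)

  # unreachable target
  expect_error(emu_decompose(net, fragment_spec("x", "S.ext", 1)), NA)
  net2 <- parse_network("@boundary: S.ext P.ext\nu: S.ext(a) -> A(a)\no: A(a) -> P.ext(a)\nd: B(a) -> P.ext(a)\nd2: P.ext(a) -> B(a)")
  expect_error(emu_decompose(net2, fragment_spec("b", "Zz", 1)), "unknown")
})

test_that("EMU simulation matches the brute-force isotopomer oracle", {
  times <- c(0.05, 0.2, 0.5, 1, 3)

  tr <- branch_truth()
  sys <- emu_decompose(tr$net, branch_fragments())
  emu <- simulate_inst(sys, tr$fluxes, tr$pools, branch_feed(), times)
  orc <- oracle_simulate(tr$net, tr$fluxes, tr$pools, branch_feed(), times,
                         branch_fragments())
  j <- dplyr::inner_join(emu, orc, by = c("fragment_id", "time_h", "mass"))
  expect_equal(nrow(j), nrow(emu))
  expect_lt(max(abs(j$fraction.x - j$fraction.y)), 1e-6)

  # symmetric-product scrambling
  sn <- scramble_net()
  basis <- free_flux_basis(sn, flux_constraints(fixed = c(u = 0.01)))
  fx <- complete_fluxes(basis, stats::setNames(numeric(0), character(0)))
  frag <- fragment_spec("B", "B", 1:4)
  syss <- emu_decompose(sn, frag)
  feeds <- feed_labeling(list(S.ext = list(list(pattern = c(1, 1, 0, 0),
                                                fraction = 1))))
  pools <- c(A = 2, F = 3, B = 4)
  es <- simulate_inst(syss, fx, pools, feeds, times)
  os <- oracle_simulate(sn, fx, pools, feeds, times, frag)
  j2 <- dplyr::inner_join(es, os, by = c("fragment_id", "time_h", "mass"))
  expect_lt(max(abs(j2$fraction.x - j2$fraction.y)), 1e-6)

  # condensation (12 carbons total in the network)
  an <- aldol_net()
  fba <- free_flux_basis(an, flux_constraints(fixed = c(u = 0.01)))
  fxa <- complete_fluxes(fba, stats::setNames(numeric(0), character(0)))
  fraga <- fragment_spec("H", "H", 1:6)
  sysa <- emu_decompose(an, fraga)
  feeda <- feed_labeling(list(
    S.ext = list(list(pattern = c(1, 0, 0), fraction = 0.7),
                 list(pattern = c(1, 1, 1), fraction = 0.3))))
  poolsa <- c(T = 4, H = 9)
  ea <- simulate_inst(sysa, fxa, poolsa, feeda, times)
  oa <- oracle_simulate(an, fxa, poolsa, feeda, times, fraga)
  j3 <- dplyr::inner_join(ea, oa, by = c("fragment_id", "time_h", "mass"))
  expect_lt(max(abs(j3$fraction.x - j3$fraction.y)), 1e-6)
})

test_that("single-pool wash-in follows the closed form 1 - exp(-t)", {
  net <- parse_network("@boundary: S.ext P.ext\nu: S.ext(a) -> A(a)\no: A(a) -> P.ext(a)")
  sys <- emu_decompose(net, fragment_spec("a", "A", 1))
  fx <- flux_distribution(net, c(u = 0.001, o = 0.001))  # v/c = 1 per hour
  feed <- feed_labeling(list(S.ext = list(list(pattern = 1, fraction = 1))))
  times <- c(0.25, 0.5, 1, 2, 4)
  ts <- simulate_inst(sys, fx, c(A = 1), feed, times)
  lab <- ts$fraction[ts$mass == 1]
  expect_equal(lab, 1 - exp(-times), tolerance = 1e-7)
})

test_that("initial condition is fully unlabeled at t = 0", {
  tr <- branch_truth()
  sys <- emu_decompose(tr$net, branch_fragments())
  ts <- simulate_inst(sys, tr$fluxes, tr$pools, branch_feed(), c(0, 0.5))
  at0 <- ts[ts$time_h == 0, ]
  expect_true(all(at0$fraction[at0$mass == 0] == 1))
  expect_true(all(at0$fraction[at0$mass > 0] == 0))
})

test_that("steady state equals the long-horizon transient limit", {
  tr <- branch_truth()
  sys <- emu_decompose(tr$net, branch_fragments())
  ss <- simulate_steady(sys, tr$fluxes, branch_feed())
  # 50 / (min v/c): slowest turnover here is ~2.1/h, use t = 50 h
  ts <- simulate_inst(sys, tr$fluxes, tr$pools, branch_feed(), 50)
  j <- dplyr::inner_join(ss, ts, by = c("fragment_id", "mass"))
  expect_lt(max(abs(j$fraction.x - j$fraction.y)), 1e-6)
})

test_that("chains equilibrate to the feed at steady state", {
  chain <- chain_net()
  fx <- flux_distribution(chain, c(u = 1, r1 = 1, r2 = 1, out = 1))
  feed <- feed_labeling(list(S.ext = list(list(pattern = c(1, 1), fraction = 1))))
  sys <- emu_decompose(chain, dplyr::bind_rows(
    fragment_spec("B", "B", 1:2), fragment_spec("C", "C", 1:2)))
  ss <- simulate_steady(sys, fx, feed)
  expect_true(all(abs(ss$fraction[ss$mass == 2] - 1) < 1e-10))

  # a reversible pair with exchange carries identical steady MIDs
  revnet <- parse_network(paste(
    "@boundary: S.ext P.ext",
    "u: S.ext(ab) -> A(ab)",
    "r: A(ab) <-> B(ba)",
    "o: B(ab) -> P.ext(ab)", sep = "\n"))
  fxr <- flux_distribution(revnet, c(u = 1, r = 1, o = 1),
                           exchange = c(r = 2))
  feed2 <- feed_labeling(list(S.ext = list(
    list(pattern = c(1, 0), fraction = 0.4),
    list(pattern = c(0, 0), fraction = 0.6))))
  sysr <- emu_decompose(revnet, dplyr::bind_rows(
    fragment_spec("A", "A", 1:2), fragment_spec("B", "B", 1:2)))
  ssr <- simulate_steady(sysr, fxr, feed2)
  a <- ssr$fraction[ssr$fragment_id == "A"]
  b <- ssr$fraction[ssr$fragment_id == "B"]
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("simulated MIDs stay normalized and monotone where theory demands", {
  set.seed(42)
  for (i in 1:5) {
    tr <- branch_truth(split = runif(1, 0.2, 0.8), exch = runif(1, 0, 0.01))
    pools <- c(A = runif(1, 1, 20), B = runif(1, 1, 20),
               C = runif(1, 1, 20), D = runif(1, 1, 20))
    sys <- emu_decompose(tr$net, branch_fragments())
    ts <- simulate_inst(sys, tr$fluxes, pools, branch_feed(),
                        c(0.1, 0.5, 2, 6))
    sums <- ts |>
      dplyr::summarise(s = sum(fraction), .by = c(fragment_id, time_h))
    expect_true(all(abs(sums$s - 1) < 1e-8))
  }

  # irreversible chain, fully labeled feed: labeling is non-decreasing in
  # time and downstream pools never lead their sole precursor
  chain <- chain_net()
  fx <- flux_distribution(chain, c(u = 0.01, r1 = 0.01, r2 = 0.01, out = 0.01))
  feed <- feed_labeling(list(S.ext = list(list(pattern = c(1, 1), fraction = 1))))
  sys <- emu_decompose(chain, dplyr::bind_rows(
    fragment_spec("A", "A", 1:2), fragment_spec("B", "B", 1:2),
    fragment_spec("C", "C", 1:2)))
  ts <- simulate_inst(sys, fx, c(A = 4, B = 6, C = 3), feed,
                      exp_time_grid(n = 12))
  labeled <- ts |>
    dplyr::filter(mass == 2) |>
    tidyr::pivot_wider(names_from = fragment_id, values_from = fraction)
  expect_true(all(diff(labeled$A) > -1e-9))
  expect_true(all(diff(labeled$B) > -1e-9))
  expect_true(all(diff(labeled$C) > -1e-9))
  expect_true(all(labeled$B <= labeled$A + 1e-9))
  expect_true(all(labeled$C <= labeled$B + 1e-9))
})

test_that("degenerate inputs raise informative errors", {
  tr <- branch_truth()
  sys <- emu_decompose(tr$net, branch_fragments())
  expect_error(
    simulate_inst(sys, tr$fluxes, c(A = 5, B = 8, C = 3, D = 0),
                  branch_feed(), 1),
    "non-positive pool")
  expect_error(
    simulate_inst(sys, tr$fluxes, c(A = 5, B = 8, C = 3), branch_feed(), 1),
    "missing pool")
  # zero flux into a measured pool: flux-disconnected
  fx0 <- flux_distribution(
    tr$net, net = c(u = 1, f1 = 1, f2 = 0, f3 = 1, f4 = 1, f5 = 0))
  expect_error(simulate_steady(sys, fx0, branch_feed()), "disconnected")
})

test_that("TCA-cycle fragments equilibrate more slowly than upper glycolysis", {
  # on the shipped network with demonstration fluxes and pools, the time to
  # reach 95% of the steady-state enrichment is an order of magnitude longer
  # for alpha-ketoglutarate than for the Glc6P C3-C6 fragment
  net <- pichia_network()
  frs <- dplyr::bind_rows(fragment_spec("glc6p_c3c6", "Glc6P", 3:6),
                          fragment_spec("akg", "AKG", 1:5))
  sys <- emu_decompose(net, frs)
  fx <- pichia_demo_fluxes()
  pools <- pichia_demo_pools()
  times <- exp_time_grid(t_first = 0.002, t_last = 6, n = 12)
  ts <- simulate_inst(sys, fx, pools, pichia_feed(), times, n_dense = 1000)
  ss <- simulate_steady(sys, fx, pichia_feed())
  labeled <- function(d, f) 1 - d$fraction[d$fragment_id == f & d$mass == 0]
  t95 <- vapply(c("glc6p_c3c6", "akg"), function(f) {
    times[min(which(labeled(ts, f) >= 0.95 * labeled(ss, f)))]
  }, numeric(1))
  expect_gt(t95[["akg"]], t95[["glc6p_c3c6"]])
})
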