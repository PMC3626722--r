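test_that("pool-to-concentration conversion uses the cell volume", {
  expect_equal(to_molar(1.7, 1.7), 1.0)
  expect_equal(to_molar(0.17, 1.7), 0.1)
  expect_equal(from_molar(to_molar(3.3)), 3.3)
  expect_error(to_molar(-1), "positive")
  expect_error(to_molar(1, 0), "positive")
})

test_that("reaction Gibbs energy follows drG0 + RT ln Q", {
  m <- thermo_model(list(r = c(A = -1, B = 1)), c(r = 5))
  expect_equal(reaction_gibbs(m, "r", c(A = 1, B = 1)), 5)     # Q = 1
  m0 <- thermo_model(list(r = c(A = -1, B = 1)), c(r = 0))
  expect_equal(reaction_gibbs(m0, "r", c(A = 1, B = 10)), 5.708,
               tolerance = 1e-4)                               # RT ln 10
  g_f <- reaction_gibbs(m0, "r", c(A = 2, B = 0.5))
  g_b <- reaction_gibbs(m0, "r", c(A = 0.5, B = 2))
  expect_equal(g_f, -g_b)                                      # symmetry
  expect_error(reaction_gibbs(m0, "r", c(A = 1)), "missing")
})

test_that("mass-action ratios match the measured-pool benchmark", {
  # PGI on the shipped pools: Fru6P/Glc6P ~ 0.22
  conc <- to_molar(pichia_pools())
  q <- mass_action_ratio(c(Glc6P = -1, Fru6P = 1), conc)
  expect_equal(q, 0.22, tolerance = 0.01)

  expect_equal(mass_action_ratio(c(A = -1, B = 1), c(A = 2, B = 2)), 1)
  qf <- mass_action_ratio(c(A = -1, B = 1), c(A = 1.3, B = 0.4))
  qb <- mass_action_ratio(c(B = -1, A = 1), c(A = 1.3, B = 0.4))
  expect_equal(qf * qb, 1)
  expect_error(mass_action_ratio(c(A = -1, B = 1), c(A = 0, B = 1)),
               "non-positive")
})

test_that("Student-t ranges follow the textbook formula", {
  expect_equal(student_t_range(1, 0, 5), c(1, 1))
  r <- student_t_range(1, 0.1, 3, confidence = 0.80)
  expect_equal(r, 1 + c(-1, 1) * 1.885618 * 0.1 / sqrt(3), tolerance = 1e-6)
  big <- student_t_range(0, 1, 1e6, confidence = 0.95)
  expect_equal(big[2], qnorm(0.975) / sqrt(1e6), tolerance = 1e-3)
  expect_error(student_t_range(1, 0.1, 1), "replicates")
})

test_that("second law tightens and rejects concentration ranges", {
  m <- thermo_model(list(r = c(A = -1, B = 1)), c(r = 0))
  # A fixed at 1 mM, B a-priori 1e-3..10 mM: B must stay below A
  ranges <- tibble::tibble(metabolite = c("A", "B"),
                           lower = c(1, 1e-3), upper = c(1, 10),
                           source = c("measured", "default"))
  out <- net_feasibility(m, c(r = 1), ranges)
  expect_true(attr(out, "feasible"))
  expect_lt(out$upper_net[out$metabolite == "B"], 1)
  expect_true(out$tightened[out$metabolite == "B"])

  # measured B above A with A -> B directed: infeasible, reaction named
  bad <- tibble::tibble(metabolite = c("A", "B"),
                        lower = c(1, 2), upper = c(1.1, 3),
                        source = "measured")
  outb <- net_feasibility(m, c(r = 1), bad)
  expect_false(attr(outb, "feasible"))
  expect_true("r" %in% attr(outb, "violated"))
  # input ranges pass through unchanged on infeasibility
  expect_equal(outb$lower_net, bad$lower)
})

test_that("tightened ranges agree with an exhaustive grid scan", {
  # 3-metabolite toy: A -> B -> C, both steps directed
  m <- thermo_model(list(r1 = c(A = -1, B = 1), r2 = c(B = -1, C = 1)),
                    c(r1 = 1.5, r2 = -2))
  ranges <- tibble::tibble(metabolite = c("A", "B", "C"),
                           lower = c(0.05, 0.01, 0.01),
                           upper = c(5, 8, 2), source = "default")
  out <- net_feasibility(m, c(r1 = 1, r2 = 1), ranges)
  expect_true(attr(out, "feasible"))

  # brute force on a 30^3 log grid
  RT <- 8.314462618e-3 * 298.15
  grids <- lapply(1:3, function(i) {
    exp(seq(log(ranges$lower[i] / 1000), log(ranges$upper[i] / 1000),
            length.out = 30))
  })
  feas <- array(FALSE, c(30, 30, 30))
  for (i in 1:30) for (j in 1:30) for (k in 1:30) {
    g1 <- 1.5 + RT * (log(grids[[2]][j]) - log(grids[[1]][i]))
    g2 <- -2 + RT * (log(grids[[3]][k]) - log(grids[[2]][j]))
    feas[i, j, k] <- g1 < 0 && g2 < 0
  }
  idx <- which(feas, arr.ind = TRUE)
  grid_bounds <- rbind(
    A = range(grids[[1]][idx[, 1]]) * 1000,
    B = range(grids[[2]][idx[, 2]]) * 1000,
    C = range(grids[[3]][idx[, 3]]) * 1000)
  # the LP bounds must bracket the grid bounds, and agree up to the grid
  # resolution (about one log step, factor exp(log-range/29))
  for (met in c("A", "B", "C")) {
    lp_lo <- out$lower_net[out$metabolite == met]
    lp_hi <- out$upper_net[out$metabolite == met]
    expect_lte(lp_lo, grid_bounds[met, 1] * 1.0001)
    expect_gte(lp_hi, grid_bounds[met, 2] * 0.9999)
    i <- match(met, ranges$metabolite)
    step <- exp(log(ranges$upper[i] / ranges$lower[i]) / 29)
    expect_gte(lp_lo * step, grid_bounds[met, 1])
    expect_lte(lp_hi / step, grid_bounds[met, 2])
  }
})

test_that("NET tightening is monotone and idempotent", {
  m <- thermo_model(list(r1 = c(A = -1, B = 1), r2 = c(B = -1, C = 1)),
                    c(r1 = 0.5, r2 = 0.5))
  ranges <- tibble::tibble(metabolite = c("A", "B", "C"),
                           lower = c(0.2, 1e-3, 1e-3),
                           upper = c(2, 10, 10), source = "default")
  out1 <- net_feasibility(m, c(r1 = 1, r2 = 1), ranges)
  expect_true(all(out1$lower_net >= out1$lower - 1e-12))
  expect_true(all(out1$upper_net <= out1$upper + 1e-12))

  # adding a constraint (directing r2 as well as r1) never widens anything
  out_r1 <- net_feasibility(m, c(r1 = 1, r2 = 0), ranges)
  expect_true(all(out1$upper_net <= out_r1$upper_net + 1e-9))
  expect_true(all(out1$lower_net >= out_r1$lower_net - 1e-9))

  # rerunning on the tightened output changes nothing
  ranges2 <- tibble::tibble(metabolite = out1$metabolite,
                            lower = out1$lower_net, upper = out1$upper_net,
                            source = "net")
  out2 <- net_feasibility(m, c(r1 = 1, r2 = 1), ranges2)
  expect_equal(out2$lower_net, out1$lower_net, tolerance = 1e-6)
  expect_equal(out2$upper_net, out1$upper_net, tolerance = 1e-6)

  # any feasible point from the LP satisfies dG < 0 pointwise
  mid <- exp((log(out1$lower_net) + log(out1$upper_net)) / 2)
  # midpoints of tightened ranges need not be feasible jointly, but the LP
  # bound solutions are; check the returned extreme concentrations
  conc <- stats::setNames(out1$lower_net, out1$metabolite)
  conc["A"] <- out1$upper_net[out1$metabolite == "A"]
  g1 <- reaction_gibbs(m, "r1", conc)
  expect_lt(g1, 0)
})

test_that("minimum cofactor ratio matches the single-constraint closed form", {
  RT <- 8.314462618e-3 * 298.15
  m <- thermo_model(list(dh = c(S = -1, NAD = -1, P = 1, NADH = 1)),
                    c(dh = 20))
  ranges <- tibble::tibble(
    metabolite = c("S", "P", "NAD", "NADH"),
    lower = c(1, 1, 1e-4, 1e-4), upper = c(1, 1, 100, 100),
    source = "default")
  mc <- min_cofactor_ratio(m, c(dh = 1), ranges, couple = c("NAD", "NADH"))
  expect_true(mc$bounded)
  expect_equal(mc$ratio, exp(20 / RT), tolerance = 1e-4)

  # a couple not touched by any directed reaction is reported unbounded
  m2 <- thermo_model(list(iso = c(S = -1, P = 1)), c(iso = 0))
  mc2 <- min_cofactor_ratio(m2, c(iso = 1), dplyr::bind_rows(
    ranges[ranges$metabolite %in% c("NAD", "NADH"), ],
    tibble::tibble(metabolite = c("S", "P"), lower = c(1, 0.1),
                   upper = c(1, 0.5), source = "default")),
    couple = c("NAD", "NADH"))
  expect_false(mc2$bounded)
})

test_that("the channelled transketolase/transaldolase variant can restore feasibility", {
  # classical two-step lumping with a transaldolase step forced forward
  # against its mass-action ratio is infeasible; the channelled one-step
  # variant bypasses the sedoheptulose-7P pool and is feasible
  classical <- thermo_model(
    list(tal = c(Sed7P = -1, GA3P = -1, E4P = 1, Fru6P = 1)),
    c(tal = 0))
  ranges <- tibble::tibble(
    metabolite = c("Sed7P", "GA3P", "E4P", "Fru6P", "Xul5P", "Rib5P"),
    lower = c(0.30, 0.018, 0.03, 0.32, 0.039, 0.078),
    upper = c(0.34, 0.023, 0.05, 0.35, 0.043, 0.086),
    source = "measured")
  out_c <- net_feasibility(classical, c(tal = 1), ranges)
  expect_false(attr(out_c, "feasible"))
  expect_true("tal" %in% attr(out_c, "violated"))

  channelled <- thermo_model(
    list(chan = c(Xul5P = -1, Rib5P = -1, Fru6P = 1, E4P = 1)),
    c(chan = -5))
  out_h <- net_feasibility(channelled, c(chan = 1), ranges)
  expect_true(attr(out_h, "feasible"))
})

test_that("minimum NAD+/NADH ratio decreases with increasing pH", {
  ratios <- vapply(c(7.0, 7.2, 7.5), function(ph) {
    m <- read_thermo_model(instaflux_example("pichia_thermo.yaml"), ph = ph)
    conc <- readr::read_csv(instaflux_example("pichia_concentrations.csv"),
                            show_col_types = FALSE)
    ids <- unique(unlist(lapply(m$reactions, names)))
    ranges <- concentration_ranges(conc, all_ids = ids,
                                   volume = m$cell_volume)
    dirs <- stats::setNames(rep(1, length(m$reactions)), names(m$reactions))
    min_cofactor_ratio(m, dirs, ranges, c("NAD", "NADH"))$ratio
  }, numeric(1))
  expect_gt(ratios[1], ratios[2])
  expect_gt(ratios[2], ratios[3])
})
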