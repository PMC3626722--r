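table1_rates <- function() read_rates(instaflux_example("pichia_rates.csv"))

test_that("respiratory quotient and carbon recovery match the chemostat data", {
  rates <- table1_rates()
  expect_equal(round(respiratory_quotient(rates), 2), 0.79)
  expect_gte(carbon_recovery(rates), 98)
  expect_equal(carbon_recovery(rates), 100 * (3.14 + 2.03) / (6 * 0.71 + 0.94))

  even <- macro_rates(-1, -1, -1, 1, 6, dilution = 0.09)
  expect_equal(respiratory_quotient(even), 1)
  expect_equal(carbon_recovery(even), 100)

  # both quantities are invariant under rescaling all rates
  doubled <- macro_rates(-1.42, -1.88, -5.14, 4.06, 6.28)
  expect_equal(respiratory_quotient(doubled), respiratory_quotient(rates))
  expect_equal(carbon_recovery(doubled), carbon_recovery(rates))
})

test_that("rate constructors enforce sign conventions", {
  expect_error(macro_rates(0.71, -0.94, -2.57, 2.03, 3.14), "negative")
  expect_error(macro_rates(-0.71, -0.94, -2.57, -2.03, 3.14), "positive")
  expect_error(macro_rates(-1, -1, -1, 1, 6, sd = c(cer = -0.1)), "> 0")
})

test_that("reconciliation projects onto the balance subspace", {
  # exactly balanced synthetic rates pass unchanged
  comp <- biomass_composition()
  q_glc <- -1; q_meoh <- -1
  q_bio <- 4
  cer <- -(6 * q_glc + q_meoh + q_bio)
  our <- (24 * q_glc + 6 * q_meoh + comp$gamma * q_bio) / 4
  rates <- macro_rates(q_glc, q_meoh, our, cer, q_bio,
                       sd = c(q_glucose = 0.01, q_methanol = 0.01,
                              our = 0.03, cer = 0.03, q_biomass = 0.05))
  rec <- reconcile_rates(rates)
  expect_true(rec$consistent)
  expect_lt(rec$h, 1e-10)
  expect_equal(rec$reconciled$value, rates$value, tolerance = 1e-12)

  # reconciled rates satisfy every balance almost exactly and close carbon
  noisy <- rates; noisy$value <- noisy$value + c(0.01, -0.01, 0.05, -0.04, 0.08)
  noisy <- macro_rates(noisy$value[1], noisy$value[2], noisy$value[3],
                       noisy$value[4], noisy$value[5],
                       sd = stats::setNames(rates$sd, rates$rate))
  rec2 <- reconcile_rates(noisy)
  E <- instaflux:::elemental_matrix(comp)
  expect_lt(max(abs(E %*% rec2$reconciled$value)), 1e-10)
  expect_equal(carbon_recovery(rec2$reconciled), 100, tolerance = 1e-9)

  # applying the projection twice equals applying it once
  rec3 <- reconcile_rates(rec2$reconciled)
  expect_equal(rec3$reconciled$value, rec2$reconciled$value,
               tolerance = 1e-10)

  # a 5-sigma gross error on CER is detected
  bad_cer <- cer + 5 * 0.03
  bad <- macro_rates(q_glc, q_meoh, our, bad_cer, q_bio,
                     sd = stats::setNames(rates$sd, rates$rate))
  expect_false(reconcile_rates(bad)$consistent)
})

test_that("cofactor rates are the stoichiometric dot product and linear", {
  net <- chain_net()
  st <- cofactor_stoichiometry(list(NADH = c(r1 = 1, r2 = 1),
                                    NADPH = c(r1 = 2),
                                    ATP = c(r2 = -1, out = 1)))
  fx <- flux_distribution(net, c(u = 1, r1 = 0.4, r2 = 0.3, out = 0.3))
  cr <- cofactor_rates(fx, st)
  expect_equal(cr[["NADH"]], 0.7)
  expect_equal(cr[["NADPH"]], 0.8)
  expect_equal(cr[["ATP"]], 0.0)

  zero <- flux_distribution(net, c(u = 0, r1 = 0, r2 = 0, out = 0))
  expect_true(all(cofactor_rates(zero, st) == 0))

  # linearity over random flux pairs
  set.seed(8)
  for (i in 1:5) {
    v1 <- runif(4); v2 <- runif(4)
    names(v1) <- names(v2) <- c("u", "r1", "r2", "out")
    a <- runif(1, 0.1, 3)
    f1 <- flux_distribution(net, v1); f2 <- flux_distribution(net, v2)
    fsum <- flux_distribution(net, v1 + a * v2)
    expect_equal(cofactor_rates(fsum, st),
                 cofactor_rates(f1, st) + a * cofactor_rates(f2, st),
                 tolerance = 1e-12)
  }

  expect_error(cofactor_rates(fx, cofactor_stoichiometry(list(NADH = c(zz = 1)))),
               "unknown reaction")
})

test_that("theoretical oxygen uptake pools electron donors", {
  expect_equal(theoretical_qO2(4.0)$qO2, 2.0)
  expect_equal(theoretical_qO2(0, 0)$qO2, 0)
  q <- theoretical_qO2(3, 1, measured_our = -2.5)
  expect_equal(q$qO2, 2)
  expect_equal(q$percent_of_measured, 80)
  expect_error(theoretical_qO2(-0.1), "inconsistent")
})

test_that("ATP accounting splits oxidative and substrate-level generation", {
  net <- chain_net()
  st <- cofactor_stoichiometry(list(ATP = c(r1 = 1, r2 = 1)),
                               po_ratio = 1.48, growth_atp = 1)
  fx <- flux_distribution(net, c(u = 1, r1 = 1, r2 = 1, out = 1))
  atp <- atp_accounting(fx, st, qO2_used = 1.0)
  expect_equal(atp$oxphos, 2.96)          # 2 * P/O * qO2
  expect_equal(atp$substrate_level, 2)    # net coefficient sum x flux
  expect_equal(atp$total, 4.96)
  expect_equal(atp$maintenance, 3.96)
  expect_false(atp$maintenance_negative)

  zero <- flux_distribution(net, c(u = 0, r1 = 0, r2 = 0, out = 0))
  atp0 <- atp_accounting(zero, st, 0)
  expect_equal(atp0$total, 0)

  # negative maintenance is flagged, not clamped
  st2 <- cofactor_stoichiometry(list(ATP = c(r1 = 1)), growth_atp = 10)
  atp2 <- atp_accounting(fx, st2, 0.5)
  expect_true(atp2$maintenance_negative)
  expect_lt(atp2$maintenance, 0)
})
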