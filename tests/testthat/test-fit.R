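test_that("weighted residual reduces to the naive per-point sum", {
  tr <- branch_truth()
  sys <- emu_decompose(tr$net, branch_fragments())
  sim <- simulate_inst(sys, tr$fluxes, tr$pools, branch_feed(), c(0.2, 1))
  meas <- sim
  meas$sigma <- measurement_sigma(meas$fraction)

  expect_equal(weighted_residual(sim, meas), 0)

  # single displaced point: ((0.51-0.50)/0.01)^2 = 1
  one <- tibble::tibble(fragment_id = "f", time_h = 1, mass = 0,
                        fraction = 0.50, sigma = 0.01)
  sim1 <- tibble::tibble(fragment_id = "f", time_h = 1, mass = 0,
                         fraction = 0.51)
  expect_equal(weighted_residual(sim1, one), 1)

  # random dataset equals an explicit loop
  set.seed(3)
  meas$fraction <- pmax(meas$fraction + rnorm(nrow(meas), 0, 0.01), 0)
  ssr <- weighted_residual(sim, meas)
  acc <- 0
  for (i in seq_len(nrow(meas))) {
    s <- sim$fraction[sim$fragment_id == meas$fragment_id[i] &
                        sim$time_h == meas$time_h[i] &
                        sim$mass == meas$mass[i]]
    acc <- acc + ((s - meas$fraction[i]) / meas$sigma[i])^2
  }
  expect_equal(ssr, acc)

  # index mismatch is an error
  expect_error(weighted_residual(sim[-1, ], meas), "mismatch")
  expect_error(weighted_residual(sim, dplyr::select(meas, -sigma)), "sigma")
})

test_that("chi-square acceptance reproduces the reference arithmetic", {
  res <- chi2_acceptance(1508.54, 1600, 34)
  expect_equal(res$dof, 1566)
  expect_equal(round(res$threshold, 1), 1659.2)
  expect_true(res$accepted)

  expect_false(chi2_acceptance(res$threshold + 1, 1600, 34)$accepted)
  expect_error(chi2_acceptance(10, 30, 30), "positive")

  # threshold grows with dof at fixed alpha
  th <- vapply(c(10, 100, 1000), function(n) {
    chi2_acceptance(0, n, 0)$threshold
  }, numeric(1))
  expect_true(all(diff(th) > 0))
})

test_that("noise-free data return the generating parameters exactly", {
  tr <- branch_truth(split = 0.6, exch = 0.003)
  sys <- emu_decompose(tr$net, branch_fragments())
  design <- experiment_design(feed = branch_feed(), rel_sigma = 0, seed = 1)
  truth <- structure(list(fluxes = tr$fluxes, pools = tr$pools, seed = 1),
                     class = "ground_truth")
  meas <- generate_labeling_dataset(truth, sys, design)
  fit <- fit_fluxes(tr$basis, sys, meas, branch_feed(),
                    pools = tr$pools[c("A", "B", "C")],
                    config = list(starts = 2, seed = 1, maxiter = 80,
                                  flux_upper = 0.03))
  expect_lt(fit$ssr, 1e-6)
  est <- stats::setNames(fit$parameters$estimate, fit$parameters$term)
  expect_equal(est[["f1"]], 0.006, tolerance = 1e-3)
  expect_equal(est[["f3"]], 0.009, tolerance = 1e-3)
  expect_equal(est[["pool:D"]], 15, tolerance = 1e-3)
  expect_true(fit$accepted)
})

test_that("a fully constrained system returns immediately with 0 parameters", {
  chain <- chain_net()
  basis <- free_flux_basis(chain, flux_constraints(fixed = c(u = 0.01)))
  sys <- emu_decompose(chain, fragment_spec("C", "C", 1:2))
  feed <- feed_labeling(list(S.ext = list(list(pattern = c(1, 1), fraction = 1))))
  fx <- complete_fluxes(basis, stats::setNames(numeric(0), character(0)))
  sim <- simulate_inst(sys, fx, c(A = 4, B = 6, C = 3), feed,
                       exp_time_grid(n = 6))
  sim$sigma <- measurement_sigma(sim$fraction)
  fit <- fit_fluxes(basis, sys, sim, feed, pools = c(A = 4, B = 6, C = 3))
  expect_equal(fit$n_parameters, 0)
  expect_lt(fit$ssr, 1e-10)
  expect_true(fit$accepted)
})

test_that("fitting is bit-reproducible for a fixed seed", {
  tr <- branch_truth()
  sys <- emu_decompose(tr$net, branch_fragments())
  design <- experiment_design(feed = branch_feed(), rel_sigma = 0.02, seed = 5)
  truth <- structure(list(fluxes = tr$fluxes, pools = tr$pools, seed = 5),
                     class = "ground_truth")
  meas <- generate_labeling_dataset(truth, sys, design)
  cfg <- list(starts = 2, seed = 9, maxiter = 40, flux_upper = 0.03)
  f1 <- fit_fluxes(tr$basis, sys, meas, branch_feed(),
                   pools = tr$pools[c("A", "B", "C")], config = cfg)
  f2 <- fit_fluxes(tr$basis, sys, meas, branch_feed(),
                   pools = tr$pools[c("A", "B", "C")], config = cfg)
  expect_identical(f1$ssr, f2$ssr)
  expect_identical(f1$parameters$estimate, f2$parameters$estimate)
})

test_that("linearized covariance matches the scalar closed form", {
  # y = theta * t with known sigma: sd(theta) = (sum t^2 / sigma^2)^(-1/2)
  t_pts <- c(1, 2, 3, 4)
  sigma <- 0.1
  y <- 0.7 * t_pts
  resfn <- function(theta) (theta[1] * t_pts - y) / sigma
  ci <- instaflux:::linearized_covariance(resfn, c(0.7), n_data = 4)
  expect_equal(sqrt(ci$cov[1, 1]), (sum(t_pts^2) / sigma^2)^(-1 / 2),
               tolerance = 1e-6)
  expect_true(ci$identifiable)
})

test_that("rank-deficient directions are flagged unidentifiable", {
  # two parameters entering only through their sum cannot be separated
  t_pts <- 1:5
  y <- 0.4 * t_pts
  resfn <- function(theta) ((theta[1] + theta[2]) * t_pts - y) / 0.05
  ci <- instaflux:::linearized_covariance(resfn, c(0.2, 0.2), n_data = 5)
  expect_false(any(ci$identifiable))
  expect_true(all(is.infinite(diag(ci$cov))))
})
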