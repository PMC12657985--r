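test_that("capture efficiency matches the reported per-sampler column", {
  eta <- table1_eta
  eff <- capture_efficiency(eta)
  reported <- c(0.785, 1.979, 0.496, 1.295)
  expect_equal(unname(eff), reported, tolerance = 0.01)
  expect_equal(unname(capture_efficiency(rep(-3, 4))), rep(1, 4))
  expect_equal(prod(eff), 1, tolerance = 1e-12)
  # invariance under a common shift: only relative efficiency is defined
  expect_equal(capture_efficiency(eta + 2.7), eff)
  # draw-wise centering for matrices
  m <- rbind(eta, eta + 1)
  em <- capture_efficiency(m)
  expect_equal(unname(em[1, ]), unname(eff))
  expect_equal(unname(em[2, ]), unname(eff))
})

test_that("dilution factors follow exp(-eta) and are not shift invariant", {
  d <- dilution_factor(table1_eta)
  expect_equal(unname(d$per_sampler["ptfe"]), exp(9.53))
  expect_equal(unname(d$per_sampler["ptfe"]), 13760, tolerance = 1e-3)
  expect_equal(d$overall, exp(-mean(table1_eta)))
  expect_equal(dilution_factor(c(0, 0, 0, 0))$overall, 1)
  # smaller eta (stronger dilution) gives strictly larger factors
  expect_true(all(order(table1_eta) == order(d$per_sampler,
                                             decreasing = TRUE)))
  shifted <- dilution_factor(table1_eta + 1)
  expect_false(isTRUE(all.equal(shifted$per_sampler, d$per_sampler)))
  # draws interface propagates uncertainty draw-wise
  set.seed(1)
  draws <- sapply(table1_eta, function(e) rnorm(500, e, 0.1))
  dd <- dilution_factor(draws)
  expect_equal(dd$per_sampler$mean, colMeans(exp(-draws)))
  expect_true(all(dd$per_sampler$lower < dd$per_sampler$upper))
})

test_that("the integrated eDNA factor converts to copies per litre", {
  pt <- omega_to_copies(9.578)
  expect_equal(pt$mean, exp(9.578))
  expect_gt(pt$mean, 12000)
  expect_lt(pt$mean, 18000)
  expect_equal(omega_to_copies(0)$median, 1)
  expect_gt(omega_to_copies(5)$mean, omega_to_copies(4)$mean)
  set.seed(2)
  dr <- rnorm(4000, 9.578, 0.115)
  s <- omega_to_copies(dr)
  expect_equal(s$mean, mean(exp(dr)))
  expect_lt(s$lower, s$median)
  expect_gt(s$upper, s$median)
})

test_that("trajectory summaries track the latent fish density", {
  sf <- shared_small_fit()
  tr <- trajectory_summary(sf$fit)
  expect_equal(nrow(tr), 6)
  expect_true(all(tr$lower < tr$mean & tr$mean < tr$upper))
  avg <- attr(tr, "average")
  expect_true(avg$lower < avg$mean && avg$mean < avg$upper)
  # draw-wise averaging, never summary-of-summaries
  X <- exp(param_draws(sf$fit, "lnX"))
  expect_equal(avg$mean, mean(rowMeans(X)))
  expect_equal(tr$mean, unname(colMeans(X)))
})

test_that("a noise-poor constant run is recovered within tight bounds", {
  cfg <- sim_config(true_X = rep(100, 6), tau = rep(0.05, 4),
                    rho = rep(0.05, 2), phi = 1e6, seed = 17)
  sim <- simulate_edna_dataset(cfg)
  fit <- edna_fit(sim, phi = 1e6, n_chains = 2, n_warmup = 400,
                  n_sampling = 400, seed = 17)
  tr <- trajectory_summary(fit)
  counted <- sim$counts$E > 0
  expect_true(all(tr$mean[counted] > 95 & tr$mean[counted] < 105))
  # the zero-effort first date is informed only through the eDNA streams
  # and the shared omega, so its posterior is wider
  expect_true(all(tr$mean[!counted] > 90 & tr$mean[!counted] < 115))
})

test_that("halving the counting effort widens the density intervals", {
  width <- function(seed, efforts) {
    sim <- simulate_edna_dataset(sim_config(efforts = efforts, seed = seed))
    fit <- edna_fit(sim, n_chains = 2, n_warmup = 300, n_sampling = 300,
                    seed = seed)
    a <- attr(trajectory_summary(fit), "average")
    a$upper - a$lower
  }
  seeds <- 1:3
  full <- vapply(seeds, width, numeric(1),
                 efforts = c(0L, 7L, 7L, 7L, 7L, 7L))
  half <- vapply(seeds, width, numeric(1),
                 efforts = c(0L, 3L, 3L, 3L, 3L, 3L))
  expect_gt(mean(half), mean(full))
})
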