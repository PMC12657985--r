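test_that("fits are deterministic given seed and carry full diagnostics", {
  sim <- simulate_edna_dataset(sim_config(seed = 5))
  f1 <- edna_fit(sim, n_chains = 2, n_warmup = 150, n_sampling = 150,
                 seed = 12)
  f2 <- edna_fit(sim, n_chains = 2, n_warmup = 150, n_sampling = 150,
                 seed = 12)
  expect_identical(f1$draws, f2$draws)
  expect_identical(coef(f1), coef(f2))
  expect_identical(capture.output(summary(f1)),
                   capture.output(summary(f2)))
  # draw bookkeeping and diagnostics defined for every parameter
  expect_equal(dim(f1$draws), c(150, 2, length(f1$parameters)))
  expect_equal(length(f1$rhat), length(f1$parameters))
  expect_equal(length(f1$ess), length(f1$parameters))
  expect_identical(f1$n_divergent, 0L)
  expect_identical(f1$treedepth_saturations, 0L)
  expect_true(all(is.finite(f1$lp)))
})

test_that("near-degenerate data pin the transfer intercepts at truth", {
  cfg <- sim_config(tau = rep(1e-3, 4), rho = rep(1e-3, 2),
                    calib = qpcr_calibration(0.3, 40, c(-1.44, -1.42),
                                             log(0.02), 0),
                    n_tech_reps = 4L, seed = 31)
  sim <- simulate_edna_dataset(cfg)
  fit <- edna_fit(sim, n_chains = 2, n_warmup = 500, n_sampling = 500,
                  seed = 31)
  eta_hat <- colMeans(param_draws(fit, "eta"))
  expect_true(all(abs(eta_hat - cfg$eta) < 0.05),
              info = paste(round(eta_hat - cfg$eta, 3), collapse = ", "))
})

test_that("sum-to-zero holds exactly in every posterior draw", {
  sf <- shared_small_fit()
  dev <- replicate_deviations(sf$fit)
  expect_equal(max(abs(dev[, , , 1] + dev[, , , 2])), 0)
})

test_that("omega is anchored by the count stream", {
  sim <- simulate_edna_dataset(sim_config(seed = 4))
  with_counts <- edna_fit(sim, n_chains = 2, n_warmup = 400,
                          n_sampling = 400, seed = 4)
  no_counts <- edna_fit(edna_data(NULL, sim$metadata, sim$plate),
                        n_chains = 2, n_warmup = 400, n_sampling = 400,
                        seed = 4)
  ov_with <- prior_sensitivity(with_counts)
  ov_without <- prior_sensitivity(no_counts)
  o_w <- ov_with$overlap[ov_with$parameter == "omega"]
  o_n <- ov_without$overlap[ov_without$parameter == "omega"]
  # counts removed: omega reverts toward its prior (wide, structure-bound)
  expect_gt(o_n, 0.3)
  expect_gt(o_n, 10 * o_w)
  expect_gt(sd(param_draws(no_counts, "omega")),
            10 * sd(param_draws(with_counts, "omega")))
})

test_that("missing streams degrade gracefully", {
  sim <- simulate_edna_dataset(sim_config(seed = 6))
  md_w <- sim$metadata[sim$metadata$class == "water", ]
  pl_w <- sim$plate[sim$plate$class != "air", ]
  expect_warning(
    fit <- edna_fit(edna_data(sim$counts, md_w, pl_w), n_chains = 2,
                    n_warmup = 200, n_sampling = 200, seed = 1),
    "count \\+ water")
  expect_false(fit$frame$has_air)
  expect_error(param_draws(fit, "eta"), "no such parameter")
  # PPC reports the air stream as empty rather than failing
  ppc <- posterior_predictive_check(fit, n_rep = 50)
  expect_true(ppc$ct_air$empty)
  expect_false(ppc$ct_water$empty)
  # no environmental samples at all is an error
  expect_error(
    edna_fit(edna_data(sim$counts,
                       sim$metadata[0, ],
                       sim$plate[sim$plate$class == "standard", ])),
    "no environmental samples")
})

test_that("fit methods produce usable output", {
  sf <- shared_small_fit()
  fit <- sf$fit
  expect_output(print(fit), "integrated eDNA factor")
  co <- coef(fit)
  expect_true(all(c("omega", "theta", "beta0") %in% names(co)))
  expect_false(any(grepl("^eps", names(co))))
  res <- residuals(fit)
  expect_equal(nrow(res$counts), sum(sf$sim$counts$E > 0))
  expect_lt(max(abs(res$counts$pearson)), 4)
  expect_lt(mean(abs(res$ct$standardized)), 2)
  reps <- simulate(fit, nsim = 2, seed = 1)
  expect_length(reps, 2)
  expect_equal(nrow(reps[[1]]$plate), nrow(sf$sim$plate))
  pw <- predict(fit, X = c(1, 10), type = "water")
  expect_equal(pw$mean[2], 10 * pw$mean[1], tolerance = 1e-8)
  pa <- predict(fit, X = 1, type = "air")
  expect_equal(nrow(pa), 4)
  pdf(NULL)
  expect_silent(plot(fit))
  expect_silent(plot(fit, which = "trace"))
  dev.off()
})
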