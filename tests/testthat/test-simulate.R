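test_that("count simulator matches the NB mean-variance relation", {
  expect_identical(simulate_counts(100, 0, 20), 0L)
  n <- 1e5
  draws <- simulate_counts(rep(160.4, n), rep(1L, n), phi = 20, seed = 2)
  mu <- 160.4
  v <- mu + mu^2 / 20  # 1446.8
  expect_lt(abs(mean(draws) - mu), 4 * sqrt(v / n))
  expect_equal(var(draws), v, tolerance = 0.05)
  # Poisson limit: variance/mean ratio tends to one
  d2 <- simulate_counts(rep(160.4, n), rep(1L, n), phi = 1e9, seed = 3)
  expect_equal(var(d2) / mean(d2), 1, tolerance = 0.05)
  expect_error(simulate_counts(10, 1, phi = 0), "positive")
})

test_that("water concentrations are deterministic and proportional", {
  expect_equal(simulate_water(1, 9.578), exp(9.578))
  expect_gt(simulate_water(1, 9.578), 12000)
  expect_lt(simulate_water(1, 9.578), 18000)
  expect_equal(simulate_water(c(2, 4), 0), c(2, 4))
  expect_equal(simulate_water(1e-9, 5), 1e-9 * exp(5))
})

test_that("air simulator reproduces the noise-free transfer closed form", {
  W <- exp(9.578)
  air <- simulate_air(W, table1_eta, tau = rep(1e-12, 4),
                      rho = rep(1e-12, 2), seed = 1)
  got <- as.vector(tapply(air$A, air$j, mean))
  expect_equal(got, W * exp(table1_eta), tolerance = 1e-6)
  # consistent with the printed per-sampler deposition magnitudes
  expect_equal(got, c(0.415, 1.043, 0.261, 0.687), tolerance = 0.02)
  # zero intercept makes air equal water
  a0 <- simulate_air(c(5, 50), rep(0, 4), rep(1e-12, 4), rep(1e-12, 2),
                     seed = 1)
  expect_equal(a0$A[a0$j == 3], c(5, 50), tolerance = 1e-6)
  expect_error(simulate_air(W, table1_eta[1:3], table1_tau, table1_rho),
               "length 4")
})

test_that("replicate deviations recover their generative scale", {
  # many deployments at tiny transfer noise isolate delta; the replicate
  # log-ratio is delta_1 - delta_2 ~ N(0, rho * sqrt(2))
  n <- 5000
  air <- simulate_air(rep(1000, n), rep(0, 4), rep(1e-12, 4),
                      rho = c(0.386, 0.154), seed = 4)
  g <- air[air$sampler == "gelatin", ]
  d <- log(g$A[g$b == 1]) - log(g$A[g$b == 2])
  rho_hat <- sd(d) / sqrt(2)
  expect_lt(abs(rho_hat - 0.386), 4 * 0.386 / sqrt(2 * n))
})

test_that("standard series follows the replication scheme", {
  std <- make_standard_series()
  expect_equal(sum(std$n_rep), 16)
  expect_equal(std$K, c(1e5, 1e4, 1e3, 1e2, 1e1))
  expect_equal(std$n_rep, c(3L, 3L, 3L, 4L, 3L))
  expect_equal(attr(std, "stock"), 1e6)
  over <- make_standard_series(c("100" = 2))
  expect_equal(over$K, 100)
  expect_equal(over$n_rep, 2L)
  expect_true(all(std$K > 0) && all(diff(std$K) < 0))
})

test_that("qPCR simulator respects detection and Ct moments", {
  cal <- default_calib()
  ntc <- simulate_qpcr(rep(0, 50), cal, seed = 1)
  expect_true(all(ntc$Z == 0L))
  expect_true(all(is.na(ntc$Ct)))
  n <- 1e4
  hi <- simulate_qpcr(rep(1e5, n), qpcr_calibration(0.1, 40, -1.44, -0.3,
                                                    -0.15),
                      seed = 2)
  expect_equal(mean(hi$Z), 1)
  mu <- 40 - 1.44 * log(1e5)
  sg <- exp(-0.3 - 0.15 * log(1e5))
  expect_lt(abs(mean(hi$Ct) - mu), 4 * sg / sqrt(n))
})

test_that("the full dataset generator is deterministic and self-consistent", {
  cfg <- sim_config(seed = 21)
  a <- simulate_edna_dataset(cfg)
  b <- simulate_edna_dataset(cfg)
  expect_identical(a, b)
  # different seeds change the realization
  c2 <- simulate_edna_dataset(sim_config(seed = 22))
  expect_false(identical(a$plate$Ct, c2$plate$Ct))
  # every environmental well joins exactly one metadata row
  env <- a$plate[a$plate$class %in% c("water", "air"), ]
  expect_true(all(env$sample_id %in% a$metadata$sample_id))
  expect_false(anyDuplicated(a$metadata$sample_id) > 0)
  # controls never amplify; standards follow the series counts
  expect_true(all(a$plate$Z[a$plate$class == "control"] == 0L))
  expect_equal(sum(a$plate$class == "standard"), 16 * cfg$n_plates)
  # replicated samplers carry two rows per time point, others one
  md_air <- a$metadata[a$metadata$class == "air", ]
  per <- table(md_air$sampler)
  expect_equal(unname(per[c("gelatin", "ptfe")]), c(12L, 12L),
               ignore_attr = TRUE)
  expect_equal(unname(per[c("mce_air", "mce_di")]), c(6L, 6L),
               ignore_attr = TRUE)
  # validates cleanly
  expect_s3_class(as_edna_data(a), "edna_data")
})
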