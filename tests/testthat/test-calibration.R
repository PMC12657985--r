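test_that("detection probability follows the exponential saturation curve", {
  expect_identical(detection_probability(0, theta = 1), 0)
  expect_equal(detection_probability(1, theta = log(2)), 0.5)
  # strictly increasing over decades for several theta
  for (theta in c(0.01, 0.3, 2)) {
    psi <- detection_probability(10^(1:6), theta)
    expect_true(all(diff(psi) > 0 | psi[-6] == 1))
    expect_true(all(psi >= 0 & psi <= 1))
  }
  # doubling theta never decreases detection
  K <- 10^seq(-1, 5, by = 0.5)
  expect_true(all(detection_probability(K, 0.2) >=
                    detection_probability(K, 0.1)))
  expect_error(detection_probability(-1, 0.5), "non-negative")
  expect_error(detection_probability(10, 0), "positive")
})

test_that("Ct moments are linear in log concentration with log-linear sd", {
  cal <- qpcr_calibration(0.3, beta0 = 40, beta1 = -1.44,
                          gamma0 = -1, gamma1 = 0)
  m <- ct_moments(exp(10), cal)
  expect_equal(m$mean, 40 - 14.4)
  expect_equal(m$sd, exp(-1))  # slope-free sd is constant
  # per-decade Ct drop = |beta1| * ln 10; beta1 = -1.4427 is the
  # perfect-efficiency slope giving the textbook 3.32 cycles per decade
  cal2 <- qpcr_calibration(0.3, 40, -1.4427, -0.3, 0)
  drop_per_decade <- ct_moments(1e3, cal2)$mean - ct_moments(1e4, cal2)$mean
  expect_equal(drop_per_decade, 1.4427 * log(10), tolerance = 1e-12)
  expect_equal(drop_per_decade, 3.322, tolerance = 1e-3)
  expect_error(ct_moments(1e3, cal, plate = 2), "unknown plate")
  expect_error(ct_moments(0, cal), "strictly positive")
})

test_that("observation log-likelihood is an additive sum of well terms", {
  cal <- default_calib()
  expect_identical(observation_loglik(data.frame(), numeric(0), cal), 0)
  # single non-amplified well, closed form ln(1 - psi)
  one <- data.frame(Z = 0L, Ct = NA_real_, plate = 1L)
  expect_equal(observation_loglik(one, 1, qpcr_calibration(log(2), 40, -1.4,
                                                           0, 0)),
               log(0.5))
  # brute-force additivity over a small random record set
  set.seed(42)
  n <- 8
  rec <- data.frame(Z = rbinom(n, 1, 0.7), Ct = NA_real_,
                    plate = sample(1:2, n, TRUE))
  rec$Ct[rec$Z == 1] <- rnorm(sum(rec$Z), 30, 3)
  K <- 10^runif(n, 0, 4)
  total <- observation_loglik(rec, K, cal)
  by_hand <- sum(vapply(seq_len(n), function(i) {
    psi <- 1 - exp(-K[i] * cal$theta)
    ll <- dbinom(rec$Z[i], 1, psi, log = TRUE)
    if (rec$Z[i] == 1) {
      mu <- cal$beta0 + cal$beta1[rec$plate[i]] * log(K[i])
      sg <- exp(cal$gamma0 + cal$gamma1 * log(K[i]))
      ll <- ll + dnorm(rec$Ct[i], mu, sg, log = TRUE)
    }
    ll
  }, numeric(1)))
  expect_equal(total, by_hand)
  expect_error(
    observation_loglik(data.frame(Z = 1L, Ct = NA_real_, plate = 1L), 10,
                       cal),
    "missing Ct")
})

test_that("detection curve tabulates a strictly increasing psi", {
  tab <- detection_curve(qpcr_calibration(0.1, 40, -1.4, 0, 0),
                         c(10, 100))
  expect_equal(tab$psi, c(1 - exp(-1), 1 - exp(-10)))
  grid <- 10^seq(0, 2, by = 0.25)
  tab2 <- detection_curve(0.05, grid)
  expect_true(all(diff(tab2$psi) > 0))
  expect_true(all(tab2$psi < 1))
})

test_that("calibration constructor validates and warns on rising slopes", {
  expect_error(qpcr_calibration(-0.1, 40, -1.4, 0, 0), "positive")
  expect_warning(qpcr_calibration(0.3, 40, c(-1.4, 0.2), 0, 0),
                 "non-negative")
})

test_that("maximum likelihood on pooled standards recovers the calibration", {
  truth <- default_calib()
  std <- make_standard_series()
  # 25 pooled standard series per plate
  K <- rep(rep(std$K, std$n_rep), times = 25)
  rec <- data.frame(K = c(K, K), plate = rep(1:2, each = length(K)))
  zy <- simulate_qpcr(rec$K, truth, rec$plate, seed = 99)
  rec$Z <- zy$Z
  rec$Ct <- zy$Ct
  ml <- fit_calibration(rec)
  expect_equal(ml$convergence, 0)
  est <- with(ml$calib, c(theta, beta0, beta1, gamma0, gamma1))
  tru <- with(truth, c(theta, beta0, beta1, gamma0, gamma1))
  expect_true(all(abs(est - tru) < 3 * ml$se),
              info = paste("z =", paste(round((est - tru) / ml$se, 2),
                                        collapse = ", ")))
})
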