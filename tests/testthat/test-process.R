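test_that("expected count is effort times rate, linear, zero at zero effort", {
  expect_equal(expected_count(160.4, 1), 160.4)
  expect_equal(expected_count(100, 0), 0)
  expect_equal(expected_count(2 * 77, 3), 2 * expected_count(77, 3))
})

test_that("count log-likelihood is a proper NB pmf with Poisson limit", {
  lam <- 160.4
  phi <- 20
  # normalization: pmf over a wide support sums to one
  lp <- vapply(0:100000, function(n) count_loglik(n, lam, phi), numeric(1))
  expect_equal(sum(exp(lp)), 1, tolerance = 1e-8)
  # Poisson limit at huge phi
  expect_equal(count_loglik(150, lam, 1e8),
               dpois(150, lam, log = TRUE), tolerance = 1e-4)
  # moment oracle: simulated variance matches lambda + lambda^2 / phi
  set.seed(1)
  draws <- rnbinom(1e5, size = phi, mu = lam)
  expect_equal(var(draws), lam + lam^2 / phi, tolerance = 0.05)
  expect_error(count_loglik(3, 0, phi), "strictly positive")
  expect_error(count_loglik(3, 10, -1), "positive")
})

test_that("water concentration is the exponentiated integrated eDNA factor", {
  w <- water_concentration(1, 9.578)
  expect_equal(w, exp(9.578))
  expect_gt(w, 12000)
  expect_lt(w, 18000)
  expect_equal(water_concentration(c(2, 4), 0), c(2, 4))
  expect_true(water_concentration(2, 5) > water_concentration(1, 5))
  expect_true(water_concentration(1, 6) > water_concentration(1, 5))
})

test_that("air log mean has unit slope in log water concentration", {
  lnA <- air_log_mean(exp(9.578), -9.53)
  expect_equal(lnA, 9.578 - 9.53)
  expect_equal(exp(lnA), 1.049, tolerance = 1e-2)
  expect_equal(air_log_mean(123, 0), log(123))
  # slope-1 consequence: sampler differences independent of W
  for (W in c(1, 1e3, 1e7))
    expect_equal(air_log_mean(W, -10.45) - air_log_mean(W, -9.53),
                 -10.45 + 9.53)
})

test_that("replicate parameterization enforces the sum-to-zero constraint", {
  r <- replicate_log_conc(2.5, 0.1)
  expect_equal(unname(r), c(2.6, 2.4))
  expect_equal(mean(r), 2.5)
  expect_equal(unname(replicate_log_conc(1, 0)), c(1, 1))
  # rho recovery from iid generated pairs: pair difference has sd rho*sqrt(2)
  set.seed(7)
  rho <- 0.154
  n <- 1000
  d <- matrix(rnorm(2 * n, 0, rho), ncol = 2)
  rho_hat <- sd(d[, 1] - d[, 2]) / sqrt(2)
  se <- rho / sqrt(2 * n)
  expect_lt(abs(rho_hat - rho), 3 * se)
})

test_that("reaction-volume normalizations follow the design constants", {
  expect_equal(reaction_conc_water(14443, 1, 10), 1444.3)
  expect_equal(reaction_conc_water(500, 7, 7), 500)
  expect_equal(reaction_conc_water(500, 2, 10),
               2 * reaction_conc_water(500, 1, 10))
  expect_equal(reaction_conc_air(1, 16, 1, 10), 1.6)
  expect_equal(reaction_conc_air(1, 750, 1, 10), 75)
  base <- reaction_conc_air(2, 16, 3, 10)
  expect_equal(reaction_conc_air(4, 16, 3, 10), 2 * base)
  expect_equal(reaction_conc_air(2, 32, 3, 10), 2 * base)
  expect_equal(reaction_conc_air(2, 16, 6, 10), 2 * base)
  expect_equal(reaction_conc_air(2, 16, 3, 20), base / 2)
})

test_that("joint log-density equals the hand-computed sum of its terms", {
  dat <- tiny_data()
  par <- tiny_params()
  pr <- edna_priors()
  got <- joint_log_density(par, dat, pr, phi = 20)

  # --- independent hand computation ---------------------------------
  # priors
  ll <- sum(dnorm(par$ln_X, 5, 3, log = TRUE)) +
    dnorm(par$omega_log, 0, 10, log = TRUE) +
    sum(dnorm(par$eta, 0, 5, log = TRUE)) +
    sum(dnorm(par$tau, 0, 2, log = TRUE) + log(2)) +
    sum(dnorm(par$rho, 0, 2, log = TRUE) + log(2)) +
    dexp(par$calib$theta, 0.5, log = TRUE) +
    dnorm(par$calib$beta0, 40, 5, log = TRUE) +
    sum(dnorm(par$calib$beta1, -1.44, 0.5, log = TRUE)) +
    dnorm(par$calib$gamma0, 0, 2, log = TRUE) +
    dnorm(par$calib$gamma1, 0, 1, log = TRUE)
  # counts: only t = 2 has effort
  X <- exp(par$ln_X)
  ll <- ll + dnbinom(900, size = 20, mu = X[2] * 7, log = TRUE)
  # transfer residuals and replicate deviations
  ll <- ll + sum(dnorm(par$eps, 0, rep(par$tau, each = 2), log = TRUE)) +
    sum(dnorm(par$delta1, 0, rep(par$rho / sqrt(2), each = 2), log = TRUE))
  # wells
  W <- X * exp(par$omega_log)
  U1 <- W[1] * 1 / 10
  Q1 <- exp(par$eta[3] + log(W[1]) + par$eps[1, 3]) * 16 * 1 / 10
  cal <- par$calib
  well <- function(K, Z, Ct) {
    psi <- 1 - exp(-K * cal$theta)
    out <- dbinom(Z, 1, psi, log = TRUE)
    if (Z == 1)
      out <- out + dnorm(Ct, cal$beta0 + cal$beta1[1] * log(K),
                         exp(cal$gamma0 + cal$gamma1 * log(K)), log = TRUE)
    out
  }
  ll <- ll + well(1e4, 1, 27.1) + well(1e2, 1, 33.8) +
    well(U1, 1, 23.5) + well(Q1, 0, NA)
  expect_equal(got, ll)
})

test_that("joint log-density ignores empty plates and penalizes bad Ct", {
  dat <- tiny_data()
  par <- tiny_params()
  base <- joint_log_density(par, dat, phi = 20)
  # appending no-template control wells (K = 0, no amplification) adds
  # exactly zero log-likelihood
  with_ctl <- dat
  with_ctl$plate <- rbind(dat$plate, data.frame(
    sample_id = "ntc", class = "control", plate = 1L, rep = 1:3, K = 0,
    Z = 0L, Ct = NA_real_))
  expect_equal(joint_log_density(par, with_ctl, phi = 20), base)
  # moving one observed Ct ten cycles off its mean lowers the density
  off <- dat
  off$plate$Ct[3] <- off$plate$Ct[3] + 10
  expect_lt(joint_log_density(par, off, phi = 20), base)
})

test_that("the joint density is maximal at the generating truth when noise collapses", {
  cfg <- sim_config(tau = rep(1e-9, 4), rho = rep(1e-9, 2),
                    calib = qpcr_calibration(0.3, 40, c(-1.44, -1.42),
                                             log(0.01), 0),
                    seed = 11)
  sim <- simulate_edna_dataset(cfg)
  dat <- as_edna_data(sim)
  par0 <- list(ln_X = log(cfg$true_X), omega_log = cfg$omega_log,
               eta = cfg$eta, tau = rep(1e-3, 4), rho = rep(1e-3, 2),
               eps = matrix(0, 6, 4), delta1 = matrix(0, 6, 2),
               calib = cfg$calib)
  # noise scales in the density are held small but fixed; only omega and
  # eta move on the grid
  base <- joint_log_density(par0, dat, phi = cfg$phi)
  expect_true(is.finite(base))
  for (dlt in c(-0.05, 0.05)) {
    p <- par0
    p$omega_log <- p$omega_log + dlt
    expect_lt(joint_log_density(p, dat, phi = cfg$phi), base)
    for (j in 1:4) {
      p <- par0
      p$eta[j] <- p$eta[j] + dlt
      expect_lt(joint_log_density(p, dat, phi = cfg$phi), base)
    }
  }
})
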