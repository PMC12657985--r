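#' qPCR calibration parameters
#'
#' Bundles the parameters of the qPCR observation model shared between
#' standards and environmental samples: a per-copy Bernoulli detection rate
#' `theta` (detection probability `1 - exp(-K * theta)` for a reaction holding
#' `K` copies/uL), a shared Ct intercept `beta0` with plate-specific slopes
#' `beta1`, and a log-linear model for the Ct standard deviation with
#' intercept `gamma0` and slope `gamma1` (`sigma = exp(gamma0 + gamma1 *
#' log(K))`).
#'
#' @param theta Positive per-copy detection rate.
#' @param beta0 Ct intercept (cycles).
#' @param beta1 Numeric vector of plate-specific Ct slopes (cycles per unit
#'   `log(K)`); one element per plate. A functioning assay has negative
#'   slopes (Ct falls as template rises); positive values trigger a warning,
#'   not an error.
#' @param gamma0,gamma1 Intercept and slope of the log Ct standard deviation.
#' @return An object of class `qpcr_calibration` (a validated list).
#' @examples
#' qpcr_calibration(theta = 0.3, beta0 = 40, beta1 = c(-1.44, -1.42),
#'                  gamma0 = -0.3, gamma1 = -0.15)
#' @export
qpcr_calibration <- function(theta, beta0, beta1, gamma0, gamma1) {
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta))
  if (theta <= 0) stop("'theta' must be strictly positive")
  stopifnot(is.numeric(beta0), length(beta0) == 1L, is.finite(beta0))
  stopifnot(is.numeric(beta1), length(beta1) >= 1L, all(is.finite(beta1)))
  stopifnot(is.numeric(gamma0), length(gamma0) == 1L, is.finite(gamma0))
  stopifnot(is.numeric(gamma1), length(gamma1) == 1L, is.finite(gamma1))
  if (any(beta1 >= 0)) {
    warning("some plate slopes 'beta1' are non-negative; ",
            "Ct should decrease with template concentration")
  }
  structure(list(theta = theta, beta0 = beta0, beta1 = beta1,
                 gamma0 = gamma0, gamma1 = gamma1),
            class = "qpcr_calibration")
}

#' @export
print.qpcr_calibration <- function(x, ...) {
  cat("qPCR calibration\n")
  cat(sprintf("  detection rate theta : %.4g per copy/uL\n", x$theta))
  cat(sprintf("  Ct intercept beta0   : %.3f cycles\n", x$beta0))
  cat(sprintf("  plate slopes beta1   : %s\n",
              paste(sprintf("%.3f", x$beta1), collapse = ", ")))
  cat(sprintf("  log-sd gamma0, gamma1: %.3f, %.3f\n", x$gamma0, x$gamma1))
  invisible(x)
}

#' Probability that a qPCR reaction amplifies
#'
#' Detection follows an exponential-saturation curve in template
#' concentration: `psi = 1 - exp(-K * theta)`. At `K = 0` (no template) the
#' probability is exactly zero; it increases strictly with `K` and
#' approaches one as `K` grows.
#'
#' @param K Non-negative template concentration(s), copies/uL of reaction.
#' @param theta Positive per-copy detection rate.
#' @return Detection probabilities in `[0, 1)`, same length as `K`.
#' @examples
#' detection_probability(c(0, 1, 10), theta = log(2))
#' @export
detection_probability <- function(K, theta) {
  stopifnot(is.numeric(K), is.numeric(theta), length(theta) == 1L)
  if (theta <= 0) stop("'theta' must be strictly positive")
  if (any(K < 0)) stop("'K' must be non-negative")
  -expm1(-K * theta)
}

#' Conditional Ct mean and standard deviation
#'
#' Given that a reaction amplified, its Ct value is Normal with mean
#' `beta0 + beta1[plate] * log(K)` and standard deviation
#' `exp(gamma0 + gamma1 * log(K))`.
#'
#' @param K Positive concentration(s), copies/uL of reaction.
#' @param calib A [qpcr_calibration()] object.
#' @param plate Plate index (into `calib$beta1`); length 1 or `length(K)`.
#' @return A list with components `mean` and `sd`.
#' @examples
#' cal <- qpcr_calibration(0.3, 40, -1.44, -0.3, -0.15)
#' ct_moments(1e4, cal, plate = 1)
#' @export
ct_moments <- function(K, calib, plate = 1L) {
  stopifnot(inherits(calib, "qpcr_calibration"), is.numeric(K))
  if (any(K <= 0)) stop("'K' must be strictly positive for Ct moments")
  plate <- as.integer(plate)
  if (any(is.na(plate)) || any(plate < 1L) || any(plate > length(calib$beta1)))
    stop("unknown plate index; calibration has ", length(calib$beta1),
         " plate slope(s)")
  lk <- log(K)
  list(mean = calib$beta0 + calib$beta1[plate] * lk,
       sd   = exp(calib$gamma0 + calib$gamma1 * lk))
}

#' Joint log-likelihood of qPCR plate records
#'
#' Sums, over wells, the Bernoulli log-likelihood of the amplification flag
#' and -- for amplified wells -- the Normal log-likelihood of the observed Ct
#' under the calibration model. Concentrations are supplied per well: the
#' known standard concentration for standards, or the (possibly latent)
#' per-reaction concentration for environmental samples.
#'
#' @param records Data frame with columns `Z` (0/1 amplification flag), `Ct`
#'   (numeric, `NA` where `Z = 0`) and `plate` (integer plate index).
#' @param concs Numeric vector of per-reaction concentrations (copies/uL),
#'   one per record row.
#' @param calib A [qpcr_calibration()] object.
#' @return A single finite numeric value (0 for an empty record set).
#' @export
observation_loglik <- function(records, concs, calib) {
  stopifnot(inherits(calib, "qpcr_calibration"))
  if (NROW(records) == 0L) return(0)
  stopifnot(all(c("Z", "Ct", "plate") %in% names(records)),
            length(concs) == nrow(records))
  Z <- records$Z
  if (any(!Z %in% c(0, 1))) stop("'Z' must be 0 or 1")
  if (any(Z == 1 & is.na(records$Ct)))
    stop("amplified well (Z = 1) with missing Ct")
  psi <- detection_probability(concs, calib$theta)
  ll <- sum(stats::dbinom(Z, 1L, psi, log = TRUE))
  amp <- which(Z == 1)
  if (length(amp)) {
    m <- ct_moments(concs[amp], calib, records$plate[amp])
    ll <- ll + sum(stats::dnorm(records$Ct[amp], m$mean, m$sd, log = TRUE))
  }
  ll
}

#' Tabulate the detection-probability curve
#'
#' Evaluates detection probability over a concentration grid. The curve
#' replaces fixed limit-of-detection / limit-of-quantification thresholds:
#' assay sensitivity is reported as a continuous function of template
#' concentration.
#'
#' @param calib A [qpcr_calibration()] object (or a bare positive `theta`).
#' @param K_grid Positive, sorted concentration grid (copies/uL).
#' @return Data frame with columns `K` and `psi`.
#' @examples
#' detection_curve(qpcr_calibration(0.1, 40, -1.44, -0.3, 0), 10^(0:5))
#' @export
detection_curve <- function(calib, K_grid) {
  theta <- if (inherits(calib, "qpcr_calibration")) calib$theta else calib
  stopifnot(is.numeric(K_grid), all(K_grid > 0), !is.unsorted(K_grid))
  data.frame(K = K_grid, psi = detection_probability(K_grid, theta))
}

#' Fit calibration parameters to standards by maximum likelihood
#'
#' Estimates the observation-model parameters (`theta`, `beta0`,
#' plate-specific `beta1`, `gamma0`, `gamma1`) from standard-curve wells
#' alone, maximizing [observation_loglik()]. Useful for assay QC before a
#' joint fit, and as a frequentist cross-check of the calibration
#' compartment. Standard errors come from the observed information
#' (inverted Hessian); `theta` is optimized on the log scale for
#' positivity.
#'
#' @param records Standards plate rows: columns `K` (known copies/uL,
#'   positive), `plate`, `Z`, `Ct`.
#' @param start Optional named list of starting values.
#' @return List with `calib` (a [qpcr_calibration()]), `se` (named vector),
#'   `loglik` and `convergence` (0 = success).
#' @export
fit_calibration <- function(records, start = NULL) {
  stopifnot(all(c("K", "plate", "Z", "Ct") %in% names(records)),
            all(records$K > 0))
  plates <- sort(unique(records$plate))
  P <- length(plates)
  rec <- data.frame(Z = records$Z, Ct = records$Ct,
                    plate = match(records$plate, plates))
  if (is.null(start))
    start <- list(log_theta = 0, beta0 = 40, beta1 = rep(-1.4, P),
                  gamma0 = 0, gamma1 = 0)
  unpack <- function(p) qpcr_calibration(
    theta = exp(max(p[1], -300)), beta0 = p[2], beta1 = p[3:(2 + P)],
    gamma0 = p[3 + P], gamma1 = p[4 + P])
  nll <- function(p) {
    ll <- tryCatch(
      observation_loglik(rec, records$K, suppressWarnings(unpack(p))),
      error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  p0 <- c(start$log_theta, start$beta0, start$beta1, start$gamma0,
          start$gamma1)
  opt <- stats::optim(p0, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500))
  se <- sqrt(diag(solve(opt$hessian)))
  # delta method for theta back on the natural scale
  se[1] <- se[1] * exp(opt$par[1])
  names(se) <- c("theta", "beta0", paste0("beta1[", seq_len(P), "]"),
                 "gamma0", "gamma1")
  list(calib = suppressWarnings(unpack(opt$par)), se = se,
       loglik = -opt$value, convergence = opt$convergence)
}
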