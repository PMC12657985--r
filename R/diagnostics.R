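# Convergence diagnostics: rank-normalized split R-hat and bulk effective
# sample size, following the modern (rank-based) definitions. Implemented
# here rather than taken from coda so the split/rank-normalized flavor is
# exactly specified; coda serves as an independent cross-check in the tests.

split_chains <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- n %/% 2L
  if (h < 2L) stop("need at least 4 iterations per chain")
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1L):n, , drop = FALSE])
}

z_scale <- function(x) {
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  array(z, dim = dim(x))
}

rhat_basic <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  mu <- colMeans(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(mu)
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Rank-normalized split R-hat
#'
#' Gelman-Rubin potential scale reduction computed on rank-normalized,
#' split chains; the reported value is the larger of the bulk statistic and
#' the folded (tail-sensitive) statistic. Constant chains have no defined
#' scale reduction and return `NA`.
#'
#' @param x Matrix of draws, iterations x chains (at least two chains).
#' @return A single numeric R-hat, or `NA` for constant input.
#' @export
compute_rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("R-hat requires at least two chains")
  if (diff(range(x)) == 0) return(NA_real_)
  s <- split_chains(x)
  max(rhat_basic(z_scale(s)),
      rhat_basic(z_scale(abs(s - stats::median(s)))))
}

acov_fft <- function(y) {
  n <- length(y)
  y <- y - mean(y)
  M <- stats::nextn(2L * n)
  f <- stats::fft(c(y, rep(0, M - n)))
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (M * n)
}

#' Bulk effective sample size
#'
#' Autocorrelation-based ESS on rank-normalized split chains, combining
#' per-chain autocovariances with Geyer's initial monotone positive
#' sequence. Independent draws give an ESS close to the total draw count
#' (slightly above is possible for antithetic chains).
#'
#' @param x Matrix of draws, iterations x chains (at least two chains).
#' @return A single numeric ESS, or `NA` for constant input.
#' @export
compute_ess <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("ESS requires at least two chains")
  if (diff(range(x)) == 0) return(NA_real_)
  z <- z_scale(split_chains(x))
  n <- nrow(z)
  m <- ncol(z)
  acov <- apply(z, 2, acov_fft)
  mean_var <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n + stats::var(colMeans(z))
  if (!is.finite(var_plus) || var_plus <= 0) return(NA_real_)

  # Geyer initial positive sequence over lag pairs
  rho_hat <- rep(0, n)
  rho_hat[1] <- 1
  rho_hat[2] <- 1 - (mean_var - mean(acov[2, ])) / var_plus
  t <- 0L
  rho_even <- rho_hat[1]
  rho_odd <- rho_hat[2]
  while (t < n - 4L && (rho_even + rho_odd) > 0) {
    t <- t + 2L
    rho_even <- 1 - (mean_var - mean(acov[t + 1L, ])) / var_plus
    rho_odd <- 1 - (mean_var - mean(acov[t + 2L, ])) / var_plus
    if (!is.finite(rho_even + rho_odd)) break
    if ((rho_even + rho_odd) >= 0) {
      rho_hat[t + 1L] <- rho_even
      rho_hat[t + 2L] <- rho_odd
    }
  }
  max_t <- t
  # enforce monotone decreasing pair sums
  t <- 0L
  while (t <= max_t - 4L) {
    t <- t + 2L
    if (rho_hat[t + 1L] + rho_hat[t + 2L] >
        rho_hat[t - 1L] + rho_hat[t]) {
      rho_hat[t + 1L] <- (rho_hat[t - 1L] + rho_hat[t]) / 2
      rho_hat[t + 2L] <- rho_hat[t + 1L]
    }
  }
  total <- n * m
  tau_hat <- -1 + 2 * sum(rho_hat[seq_len(max(max_t, 1L))]) +
    rho_hat[max_t + 1L]
  tau_hat <- max(tau_hat, 1 / log10(total))
  total / tau_hat
}

#' Overlap coefficient of two empirical distributions
#'
#' Integral of the pointwise minimum of two kernel density estimates on a
#' common grid; 1 for identical distributions, near 0 for disjoint ones.
#' Symmetric in its arguments.
#'
#' @param x,y Numeric samples.
#' @param n_grid Grid resolution.
#' @return Overlap in `[0, 1]`.
#' @export
overlap_coefficient <- function(x, y, n_grid = 1024L) {
  lo <- min(x, y)
  hi <- max(x, y)
  if (hi <= lo) return(1)
  dx <- stats::density(x, from = lo, to = hi, n = n_grid)
  dy <- stats::density(y, from = lo, to = hi, n = n_grid)
  ovl <- sum(pmin(dx$y, dy$y)) * (hi - lo) / (n_grid - 1)
  min(max(ovl, 0), 1)
}

sample_prior <- function(priors, what, n) {
  p <- priors
  switch(what,
         ln_X = stats::rnorm(n, p$ln_X[1], p$ln_X[2]),
         omega = stats::rnorm(n, p$omega_log[1], p$omega_log[2]),
         eta = stats::rnorm(n, p$eta[1], p$eta[2]),
         tau = abs(stats::rnorm(n, 0, p$tau)),
         rho = abs(stats::rnorm(n, 0, p$rho)),
         theta = stats::rexp(n, p$theta_rate),
         beta0 = stats::rnorm(n, p$beta0[1], p$beta0[2]),
         beta1 = stats::rnorm(n, p$beta1[1], p$beta1[2]),
         gamma0 = stats::rnorm(n, p$gamma0[1], p$gamma0[2]),
         gamma1 = stats::rnorm(n, p$gamma1[1], p$gamma1[2]),
         stop("no prior sampler for ", what))
}

#' Prior-versus-posterior overlap report
#'
#' For each top-level parameter, computes the overlap coefficient between
#' its marginal posterior and its prior. High overlap (above `flag_above`)
#' flags a parameter the data did not inform.
#'
#' @param fit An `edna_fit`.
#' @param priors Prior configuration; defaults to the one used in the fit.
#' @param n_prior Prior sample size per parameter.
#' @param flag_above Overlap threshold for the data-uninformed flag.
#' @param seed Seed for the prior draws.
#' @return Data frame with columns `parameter`, `overlap`,
#'   `data_uninformed`.
#' @export
prior_sensitivity <- function(fit, priors = fit$priors, n_prior = 4000L,
                              flag_above = 0.9, seed = 1L) {
  stopifnot(inherits(fit, "edna_fit"))
  set.seed(seed)
  base_of <- function(nm) sub("\\[.*$", "", nm)
  prior_kind <- c(lnX = "ln_X", omega = "omega", eta = "eta", tau = "tau",
                  rho = "rho", theta = "theta", beta0 = "beta0",
                  beta1 = "beta1", gamma0 = "gamma0", gamma1 = "gamma1")
  keep <- fit$parameters[base_of(fit$parameters) %in% names(prior_kind)]
  ov <- vapply(keep, function(nm) {
    post <- as.vector(param_draws(fit, sub("\\].*", "]", nm))[, nm])
    pri <- sample_prior(priors, prior_kind[[base_of(nm)]], n_prior)
    overlap_coefficient(post, pri)
  }, numeric(1))
  data.frame(parameter = keep, overlap = unname(ov),
             data_uninformed = unname(ov > flag_above),
             row.names = NULL)
}

#' Posterior predictive check
#'
#' Draws replicate datasets from the fitted model -- counts, amplification
#' flags and Ct values at the observed design -- and reports, per data
#' stream, the central predictive interval coverage of the observations.
#' Ct streams use per-well intervals; amplification is summarized as the
#' observed detection rate against its predictive interval (binary wells
#' have no useful per-well interval). An absent stream yields an
#' empty-stream marker (`n = 0`, `coverage = NA`), not an error.
#'
#' @param fit An `edna_fit`.
#' @param n_rep Number of posterior draws used for replication.
#' @param level Predictive interval level.
#' @param seed Seed for the replication noise.
#' @return An object of class `edna_ppc`: per-stream lists with `n`,
#'   `coverage` (or `covered` for detection rates) and interval tables.
#' @export
posterior_predictive_check <- function(fit, n_rep = 200L, level = 0.95,
                                       seed = 1L) {
  stopifnot(inherits(fit, "edna_fit"))
  set.seed(seed)
  fr <- fit$frame
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  idx <- unique(round(seq(1L, n_draws(fit), length.out = n_rep)))
  pars <- lapply(idx, function(i) params_from_draw(fit, i))

  empty <- list(n = 0L, coverage = NA_real_, empty = TRUE)

  # counts
  counts_stream <- empty
  if (fr$has_counts) {
    cts <- fr$counts
    lam <- vapply(pars, function(p)
      exp(p$ln_X[cts$t]) * cts$E, numeric(nrow(cts)))
    reps <- matrix(stats::rnbinom(length(lam), size = fit$phi, mu = lam),
                   nrow = nrow(cts))
    qs <- apply(reps, 1, stats::quantile, probs = probs)
    cov <- cts$N >= qs[1, ] & cts$N <= qs[2, ]
    counts_stream <- list(n = nrow(cts), coverage = mean(cov),
                          table = data.frame(t = cts$t, N = cts$N,
                                             lower = qs[1, ],
                                             upper = qs[2, ]),
                          empty = FALSE)
  }

  conc_for_wells <- function(cls) {
    # matrix wells x draws of per-reaction concentrations
    if (cls == "standard") {
      matrix(fr$std$K, nrow(fr$std), length(pars))
    } else if (cls == "water") {
      vapply(pars, function(p) {
        W <- exp(p$ln_X + p$omega_log)
        U <- W[fr$wmd$t] * fr$wmd$F_l / fr$wmd$V_ul
        U[fr$ww$s]
      }, numeric(nrow(fr$ww$rows)))
    } else {
      vapply(pars, function(p) {
        W <- exp(p$ln_X + p$omega_log)
        lnQ <- p$eta[fr$ja] + log(W[fr$amd$t]) +
          p$eps[cbind(fr$amd$t, fr$ja)] +
          fr$bsign * p$delta1[cbind(fr$amd$t, fr$jrep)]
        Q <- exp(lnQ) * fr$amd$S_cm2 * fr$amd$P_days / fr$amd$V_ul
        Q[fr$aw$s]
      }, numeric(nrow(fr$aw$rows)))
    }
  }

  stream_for <- function(cls, rows) {
    if (is.null(rows) || nrow(rows) == 0L)
      return(list(ct = empty, det = empty))
    conc <- conc_for_wells(cls)
    theta <- vapply(pars, function(p) p$calib$theta, numeric(1))
    psi <- -expm1(-sweep(conc, 2, theta, `*`))
    zrep <- matrix(stats::rbinom(length(psi), 1L, psi), nrow = nrow(conc))
    rate_rep <- colMeans(zrep)
    rate_int <- stats::quantile(rate_rep, probs = probs)
    det <- list(n = nrow(rows), observed = mean(rows$Z),
                lower = unname(rate_int[1]), upper = unname(rate_int[2]),
                covered = mean(rows$Z) >= rate_int[1] &&
                  mean(rows$Z) <= rate_int[2],
                empty = FALSE)
    has_ct <- which(!is.na(rows$Ct))
    ct <- empty
    if (length(has_ct)) {
      cc <- conc[has_ct, , drop = FALSE]
      lk <- log(cc)
      b0 <- vapply(pars, function(p) p$calib$beta0, numeric(1))
      g0 <- vapply(pars, function(p) p$calib$gamma0, numeric(1))
      g1 <- vapply(pars, function(p) p$calib$gamma1, numeric(1))
      b1 <- vapply(seq_along(pars), function(k)
        pars[[k]]$calib$beta1[rows$plate[has_ct]], numeric(length(has_ct)))
      if (is.null(dim(b1))) b1 <- matrix(b1, nrow = length(has_ct))
      mu <- sweep(b1 * lk, 2, b0, `+`)
      sg <- exp(sweep(sweep(lk, 2, g1, `*`), 2, g0, `+`))
      yrep <- matrix(stats::rnorm(length(mu), mu, sg), nrow = nrow(mu))
      qs <- apply(yrep, 1, stats::quantile, probs = probs)
      covd <- rows$Ct[has_ct] >= qs[1, ] & rows$Ct[has_ct] <= qs[2, ]
      ct <- list(n = length(has_ct), coverage = mean(covd),
                 table = data.frame(Ct = rows$Ct[has_ct], lower = qs[1, ],
                                    upper = qs[2, ]),
                 empty = FALSE)
    }
    list(ct = ct, det = det)
  }

  std <- stream_for("standard", fr$std)
  wat <- if (fr$has_water) stream_for("water", fr$ww$rows)
         else list(ct = empty, det = empty)
  air <- if (fr$has_air) stream_for("air", fr$aw$rows)
         else list(ct = empty, det = empty)

  structure(list(counts = counts_stream,
                 ct_standard = std$ct, ct_water = wat$ct, ct_air = air$ct,
                 det_standard = std$det, det_water = wat$det,
                 det_air = air$det,
                 level = level, n_rep = length(idx)),
            class = "edna_ppc")
}

#' @export
print.edna_ppc <- function(x, ...) {
  cat(sprintf("Posterior predictive check (%d replicate draws, %.0f%% intervals)\n",
              x$n_rep, 100 * x$level))
  fmt <- function(nm, s) {
    if (isTRUE(s$empty)) return(sprintf("  %-12s: empty stream\n", nm))
    if (!is.null(s$coverage))
      sprintf("  %-12s: coverage %.2f (n = %d)\n", nm, s$coverage, s$n)
    else
      sprintf("  %-12s: observed rate %.2f in [%.2f, %.2f]: %s\n", nm,
              s$observed, s$lower, s$upper,
              if (s$covered) "covered" else "NOT covered")
  }
  for (nm in c("counts", "ct_standard", "ct_water", "ct_air"))
    cat(fmt(nm, x[[nm]]))
  for (nm in c("det_standard", "det_water", "det_air"))
    cat(fmt(nm, x[[nm]]))
  invisible(x)
}
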