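# S3 methods for fitted models: summary (Table-1-shaped sampler table plus
# the integrated eDNA factor), plot, simulate (posterior predictive
# replicates), residuals and predict.

#' Summarize a fitted joint model
#'
#' @param object An `edna_fit`.
#' @param level Credible level for intervals.
#' @param ... Unused.
#' @return An object of class `summary.edna_fit`: a per-sampler table
#'   (transfer intercept `eta`, residual sd `tau`, replicate sd `rho`,
#'   capture efficiency), the integrated eDNA factor on both scales, the
#'   latent trajectory, and convergence diagnostics.
#' @export
summary.edna_fit <- function(object, level = 0.95, ...) {
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  sm <- function(x) c(mean(x), stats::quantile(x, probs = probs))
  omega <- as.vector(param_draws(object, "omega"))

  samplers <- NULL
  if (object$frame$has_air) {
    eta <- param_draws(object, "eta")
    tau <- param_draws(object, "tau")
    rho <- param_draws(object, "rho")
    eff <- capture_efficiency(eta)
    samplers <- data.frame(
      sampler = SAMPLER_TYPES,
      eta = colMeans(eta), eta_lower = apply(eta, 2, stats::quantile, probs[1]),
      eta_upper = apply(eta, 2, stats::quantile, probs[2]),
      tau = colMeans(tau),
      rho = c(colMeans(rho), NA, NA),
      efficiency = colMeans(eff),
      efficiency_lower = apply(eff, 2, stats::quantile, probs[1]),
      efficiency_upper = apply(eff, 2, stats::quantile, probs[2]),
      row.names = NULL)
  }
  structure(list(
    samplers = samplers,
    omega = sm(omega),
    omega_copies = omega_to_copies(omega, level),
    trajectory = trajectory_summary(object, level),
    rhat_max = max(object$rhat, na.rm = TRUE),
    ess_min = min(object$ess, na.rm = TRUE),
    n_divergent = object$n_divergent,
    converged = convergence_pass(object),
    level = level), class = "summary.edna_fit")
}

#' @export
print.summary.edna_fit <- function(x, digits = 3, ...) {
  cat("Joint eDNA state-space model: posterior summary\n\n")
  om <- x$omega
  oc <- x$omega_copies
  cat(sprintf("Integrated eDNA factor omega (log scale): %.3f [%.3f, %.3f]\n",
              om[1], om[2], om[3]))
  cat(sprintf("  => %.0f copies/L per fish/day [%.0f, %.0f]\n\n",
              oc$mean, oc$lower, oc$upper))
  if (!is.null(x$samplers)) {
    cat("Air samplers (transfer eta, residual tau, replicate rho, efficiency):\n")
    print(format(x$samplers, digits = digits), row.names = FALSE)
    cat("\n")
  }
  avg <- attr(x$trajectory, "average")
  cat(sprintf("Latent fish density: across-time mean %.1f fish/day [%.1f, %.1f]\n",
              avg$mean, avg$lower, avg$upper))
  cat(sprintf("Diagnostics: max R-hat %.3f, min ESS %.0f, %d divergences (%s)\n",
              x$rhat_max, x$ess_min, x$n_divergent,
              if (x$converged) "pass" else "inspect"))
  invisible(x)
}

#' Plot a fitted joint model
#'
#' `which = "trajectory"` draws the posterior fish-density trajectory with
#' credible bands and, where available, the effort-normalized counts;
#' `which = "trace"` draws trace plots for the headline parameters.
#'
#' @param x An `edna_fit`.
#' @param which `"trajectory"` or `"trace"`.
#' @param ... Passed to the underlying plotting calls.
#' @export
plot.edna_fit <- function(x, which = c("trajectory", "trace"), ...) {
  which <- match.arg(which)
  if (which == "trajectory") {
    tr <- trajectory_summary(x)
    ylim <- range(tr$lower, tr$upper)
    if (x$frame$has_counts) {
      cts <- x$frame$counts
      ylim <- range(ylim, cts$N / cts$E)
    }
    plot(tr$t, tr$mean, type = "b", pch = 16, ylim = ylim,
         xlab = "time point", ylab = "fish / day",
         main = "Latent daily accumulation rate", ...)
    graphics::arrows(tr$t, tr$lower, tr$t, tr$upper, angle = 90, code = 3,
                     length = 0.04)
    if (x$frame$has_counts) {
      cts <- x$frame$counts
      graphics::points(cts$t, cts$N / cts$E, col = "firebrick", pch = 17)
      graphics::legend("topright", pch = c(16, 17),
                       col = c("black", "firebrick"),
                       legend = c("posterior X", "counts / effort"),
                       bty = "n")
    }
  } else {
    pars <- c("omega", "theta", "beta0", "gamma0",
              if (x$frame$has_air) c("eta[1]", "tau[1]"))
    op <- graphics::par(mfrow = c(ceiling(length(pars) / 2), 2),
                        mar = c(3, 4, 2, 1))
    on.exit(graphics::par(op))
    for (p in pars) {
      d <- param_draws(x, p, merge = FALSE)
      graphics::matplot(d[, , 1], type = "l", lty = 1, ylab = p,
                        main = p, ...)
    }
  }
  invisible(x)
}

#' Posterior predictive replicate datasets
#'
#' Draws `nsim` replicate datasets (counts, amplification flags, Ct values)
#' at the observed design, each generated from one posterior draw of the
#' parameters and latent states.
#'
#' @param object An `edna_fit`.
#' @param nsim Number of replicate datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of length `nsim`; each element has `counts` and `plate`
#'   data frames shaped like the input data.
#' @export
simulate.edna_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fr <- object$frame
  total <- n_draws(object)
  picks <- sample.int(total, nsim, replace = nsim > total)
  lapply(picks, function(i) {
    p <- params_from_draw(object, i)
    X <- exp(p$ln_X)
    cts <- NULL
    if (fr$has_counts) {
      cts <- fr$counts
      cts$N <- stats::rnbinom(nrow(cts), size = object$phi,
                              mu = X[cts$t] * cts$E)
    }
    pl <- object$data$plate
    concs <- numeric(nrow(pl))
    stdc <- pl$class %in% c("standard", "control")
    concs[stdc] <- pl$K[stdc]
    env <- which(!stdc)
    if (length(env)) {
      md <- object$data$metadata
      row <- md[match(pl$sample_id[env], md$sample_id), ]
      W <- exp(p$ln_X + p$omega_log)
      is_w <- row$class == "water"
      concs[env[is_w]] <- W[row$t[is_w]] * row$F_l[is_w] / row$V_ul[is_w]
      if (any(!is_w)) {
        rw <- row[!is_w, ]
        j <- match(rw$sampler, SAMPLER_TYPES)
        lnA <- p$eta[j] + log(W[rw$t]) + p$eps[cbind(rw$t, j)]
        has_rep <- j %in% REPLICATED_SAMPLERS & !is.na(rw$b)
        dev <- numeric(nrow(rw))
        if (any(has_rep)) {
          d1 <- p$delta1[cbind(rw$t[has_rep], j[has_rep])]
          dev[has_rep] <- ifelse(rw$b[has_rep] == 1L, d1, -d1)
        }
        concs[env[!is_w]] <- exp(lnA + dev) * rw$S_cm2 * rw$P_days / rw$V_ul
      }
    }
    zy <- simulate_qpcr(concs, p$calib, pl$plate)
    pl$Z <- zy$Z
    pl$Ct <- zy$Ct
    list(counts = cts, plate = pl)
  })
}

#' Residuals of a fitted joint model
#'
#' Pearson residuals for the count stream (`(N - lambda) / sqrt(lambda +
#' lambda^2 / phi)` at the posterior mean trajectory) and standardized Ct
#' residuals (`(Ct - mu) / sigma` at posterior-mean parameters and latent
#' concentrations) for the qPCR streams.
#'
#' @param object An `edna_fit`.
#' @param ... Unused.
#' @return List with `counts` and `ct` data frames.
#' @export
residuals.edna_fit <- function(object, ...) {
  fr <- object$frame
  pm <- params_from_posterior_mean(object)
  out <- list(counts = NULL, ct = NULL)
  X <- exp(pm$ln_X)
  if (fr$has_counts) {
    lam <- X[fr$counts$t] * fr$counts$E
    out$counts <- data.frame(
      t = fr$counts$t, N = fr$counts$N, expected = lam,
      pearson = (fr$counts$N - lam) / sqrt(lam + lam^2 / object$phi))
  }
  pl <- object$data$plate
  has_ct <- which(!is.na(pl$Ct))
  if (length(has_ct)) {
    concs <- well_concentrations(object, pm)[has_ct]
    m <- ct_moments(concs, pm$calib, pl$plate[has_ct])
    out$ct <- data.frame(class = pl$class[has_ct], Ct = pl$Ct[has_ct],
                         mu = m$mean,
                         standardized = (pl$Ct[has_ct] - m$mean) / m$sd)
  }
  out
}

# posterior-mean parameter list in joint_log_density form
params_from_posterior_mean <- function(fit) {
  fr <- fit$frame
  mean_of <- function(base, n) {
    if (n == 0L) return(numeric(0))
    colMeans(param_draws(fit, base))[seq_len(n)]
  }
  Tn <- fr$Tn
  par <- list(ln_X = mean_of("lnX", Tn),
              omega_log = mean(param_draws(fit, "omega")))
  if (fr$has_air) {
    par$eta <- mean_of("eta", 4L)
    par$tau <- mean_of("tau", 4L)
    par$rho <- mean_of("rho", 2L)
    par$eps <- matrix(colMeans(param_draws(fit, "eps")), Tn, 4L)
    par$delta1 <- matrix(colMeans(param_draws(fit, "d1")), Tn, 2L)
  } else {
    par$eta <- numeric(0); par$tau <- numeric(0); par$rho <- numeric(0)
    par$eps <- matrix(0, Tn, 0L); par$delta1 <- matrix(0, Tn, 0L)
  }
  par$calib <- qpcr_calibration(
    theta = mean(param_draws(fit, "theta")),
    beta0 = mean(param_draws(fit, "beta0")),
    beta1 = mean_of("beta1", fr$n_plates),
    gamma0 = mean(param_draws(fit, "gamma0")),
    gamma1 = mean(param_draws(fit, "gamma1")))
  par
}

# per-well reaction concentrations implied by a parameter list
well_concentrations <- function(fit, params) {
  pl <- fit$data$plate
  md <- fit$data$metadata
  concs <- numeric(nrow(pl))
  stdc <- pl$class %in% c("standard", "control")
  concs[stdc] <- pl$K[stdc]
  env <- which(!stdc)
  if (length(env)) {
    row <- md[match(pl$sample_id[env], md$sample_id), ]
    W <- exp(params$ln_X + params$omega_log)
    is_w <- row$class == "water"
    concs[env[is_w]] <- W[row$t[is_w]] * row$F_l[is_w] / row$V_ul[is_w]
    if (any(!is_w)) {
      rw <- row[!is_w, ]
      j <- match(rw$sampler, SAMPLER_TYPES)
      lnA <- params$eta[j] + log(W[rw$t]) + params$eps[cbind(rw$t, j)]
      has_rep <- j %in% REPLICATED_SAMPLERS & !is.na(rw$b)
      dev <- numeric(nrow(rw))
      if (any(has_rep)) {
        d1 <- params$delta1[cbind(rw$t[has_rep], j[has_rep])]
        dev[has_rep] <- ifelse(rw$b[has_rep] == 1L, d1, -d1)
      }
      concs[env[!is_w]] <- exp(lnA + dev) * rw$S_cm2 * rw$P_days / rw$V_ul
    }
  }
  concs
}

#' Predicted eDNA concentrations for given fish densities
#'
#' Propagates posterior draws of the integrated eDNA factor (and, for air,
#' the sampler transfer intercepts) through the process model at
#' user-supplied accumulation rates.
#'
#' @param object An `edna_fit`.
#' @param X Positive fish/day value(s).
#' @param type `"water"` (copies/L) or `"air"` (copies/cm^2/day, per
#'   sampler at the transfer mean, residual noise not added).
#' @param level Credible level.
#' @param ... Unused.
#' @return Data frame of posterior mean and interval per `X` (and per
#'   sampler for `type = "air"`).
#' @export
predict.edna_fit <- function(object, X = 1, type = c("water", "air"),
                             level = 0.95, ...) {
  type <- match.arg(type)
  stopifnot(all(X > 0))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  om <- as.vector(param_draws(object, "omega"))
  if (type == "water") {
    out <- do.call(rbind, lapply(X, function(x) {
      w <- x * exp(om)
      q <- stats::quantile(w, probs)
      data.frame(X = x, mean = mean(w), lower = q[1], upper = q[2])
    }))
    rownames(out) <- NULL
    return(out)
  }
  if (!object$frame$has_air) stop("fit has no air stream")
  eta <- param_draws(object, "eta")
  out <- do.call(rbind, lapply(X, function(x) {
    w <- x * exp(om)
    a <- exp(eta + log(w))
    q <- apply(a, 2, stats::quantile, probs)
    data.frame(X = x, sampler = SAMPLER_TYPES, mean = colMeans(a),
               lower = q[1, ], upper = q[2, ])
  }))
  rownames(out) <- NULL
  out
}
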