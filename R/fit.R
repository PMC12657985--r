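# Model fitting via JAGS. The model's joint density has one canonical
# definition (joint_log_density); the JAGS program below is its transcription
# for sampling, assembled block by block so that data variants (no counts,
# no air stream) drop the corresponding likelihood terms.

build_jags_model <- function(has_counts, has_water, has_air,
                             estimate_phi = FALSE) {
  blocks <- c("model {",
    if (estimate_phi) "  phi ~ dnorm(0, 0.0004) T(0,)",
    "  omega ~ dnorm(pr_om_m, pr_om_p)",
    # the sampler walks in lnW = lnX + omega (unit-Jacobian change of
    # variables): qPCR wells pin lnW tightly while counts inform
    # lnX = lnW - omega, so omega's full conditional is wide and Gibbs
    # updates do not crawl along the lnX + omega ridge
    "  for (t in 1:Tn) {",
    "    lnW[t] ~ dnorm(pr_lnX_m + omega, pr_lnX_p)",
    "    lnX[t] <- lnW[t] - omega",
    "    X[t] <- exp(lnX[t])",
    "    W[t] <- exp(lnW[t])",
    "  }",
    "  theta ~ dexp(pr_theta_rate)",
    "  beta0 ~ dnorm(pr_b0_m, pr_b0_p)",
    "  for (p in 1:n_plates) { beta1[p] ~ dnorm(pr_b1_m, pr_b1_p) }",
    "  gamma1 ~ dnorm(pr_g1_m, pr_g1_p)",
    # log-sd regression sampled with a centered covariate (g0c is the log
    # sd at the mean standard log-concentration lnKc); exact change of
    # variables from the gamma0 prior, removing the intercept-slope
    # correlation that stalls componentwise updates
    "  g0c ~ dnorm(pr_g0_m + gamma1 * lnKc, pr_g0_p)",
    "  gamma0 <- g0c - gamma1 * lnKc")
  if (has_counts) blocks <- c(blocks,
    # mean/overdispersion NB via JAGS (p, r): p = phi / (phi + lambda)
    "  for (i in 1:n_count) {",
    "    N[i] ~ dnegbin(phi / (phi + X[tc[i]] * Ec[i]), phi)",
    "  }")
  if (has_water) blocks <- c(blocks,
    "  for (s in 1:n_wsamp) { Uw[s] <- W[tw[s]] * Fw[s] / Vw[s] }",
    "  for (w in 1:n_wwell) {",
    "    Zw[w] ~ dbern(1 - exp(-Uw[sw[w]] * theta))",
    "  }",
    "  for (w in 1:n_wwell_ct) {",
    "    Yw[w] ~ dnorm(beta0 + beta1[pw_ct[w]] * log(Uw[sw_ct[w]]),",
    "                  pow(exp(gamma0 + gamma1 * log(Uw[sw_ct[w]])), -2))",
    "  }")
  if (has_air) blocks <- c(blocks,
    "  for (j in 1:4) {",
    "    eta[j] ~ dnorm(pr_eta_m, pr_eta_p)",
    "    tau[j] ~ dnorm(0, pr_tau_p) T(0,)",
    "    for (t in 1:Tn) {",
    # centered parameterization: sampling lnA directly (rather than the
    # residual eps) removes the eta + eps ridge that stalls Gibbs updates
    "      lnA[t, j] ~ dnorm(eta[j] + log(W[t]), pow(tau[j], -2))",
    "      eps[t, j] <- lnA[t, j] - eta[j] - log(W[t])",
    "    }",
    "  }",
    # replicate deviations: two iid N(0, rho) draws conditioned on summing
    # to zero leave delta_1 ~ N(0, rho / sqrt(2)), i.e. precision 2 / rho^2
    "  for (j in 1:2) {",
    "    rho[j] ~ dnorm(0, pr_rho_p) T(0,)",
    "    for (t in 1:Tn) { d1[t, j] ~ dnorm(0, 2 * pow(rho[j], -2)) }",
    "  }",
    "  for (s in 1:n_asamp) {",
    "    lnQs[s] <- lnA[ta[s], ja[s]] + bsign[s] * d1[ta[s], jrep[s]]",
    "    Qa[s] <- exp(lnQs[s]) * Sa[s] * Pa[s] / Va[s]",
    "  }",
    "  for (w in 1:n_awell) {",
    "    Za[w] ~ dbern(1 - exp(-Qa[sa[w]] * theta))",
    "  }",
    "  for (w in 1:n_awell_ct) {",
    "    Ya[w] ~ dnorm(beta0 + beta1[pa_ct[w]] * log(Qa[sa_ct[w]]),",
    "                  pow(exp(gamma0 + gamma1 * log(Qa[sa_ct[w]])), -2))",
    "  }")
  blocks <- c(blocks,
    "  for (w in 1:n_std) {",
    "    Zs[w] ~ dbern(1 - exp(-Ks[w] * theta))",
    "  }",
    "  for (w in 1:n_std_ct) {",
    "    Ys[w] ~ dnorm(beta0 + beta1[ps_ct[w]] * log(Ks_ct[w]),",
    "                  pow(exp(gamma0 + gamma1 * log(Ks_ct[w])), -2))",
    "  }",
    "}")
  paste(blocks, collapse = "\n")
}

# Index structures shared by the sampler, the native log density evaluated
# on draws, and the posterior predictive machinery.
build_model_frame <- function(data, priors, phi) {
  md <- data$metadata
  pl <- data$plate
  Tn <- max(c(md$t, if (!is.null(data$counts)) data$counts$t))
  n_plates <- max(pl$plate)

  counts <- NULL
  if (!is.null(data$counts)) {
    keep <- data$counts$E > 0
    if (any(keep)) counts <- data$counts[keep, , drop = FALSE]
  }

  wmd <- md[md$class == "water", , drop = FALSE]
  amd <- md[md$class == "air", , drop = FALSE]
  ja <- match(amd$sampler, SAMPLER_TYPES)
  repd <- ja %in% REPLICATED_SAMPLERS & !is.na(amd$b)
  bsign <- ifelse(repd, ifelse(amd$b == 1L, 1, -1), 0)
  jrep <- ifelse(repd, ja, 1L)

  wells <- function(cls, ids) {
    rows <- pl[pl$class == cls, , drop = FALSE]
    s_idx <- match(rows$sample_id, ids)
    list(rows = rows, s = s_idx, ct = !is.na(rows$Ct))
  }
  std <- pl[pl$class == "standard", , drop = FALSE]
  ww <- wells("water", wmd$sample_id)
  aw <- wells("air", amd$sample_id)

  list(Tn = Tn, n_plates = n_plates, counts = counts, phi = phi,
       wmd = wmd, amd = amd, ja = ja, bsign = bsign, jrep = jrep,
       std = std, ww = ww, aw = aw,
       has_counts = !is.null(counts) && nrow(counts) > 0L,
       has_water = nrow(wmd) > 0L, has_air = nrow(amd) > 0L,
       priors = priors)
}

jags_data_from_frame <- function(fr) {
  p <- fr$priors
  prec <- function(s) 1 / s^2
  dat <- list(Tn = fr$Tn, n_plates = fr$n_plates,
              pr_lnX_m = p$ln_X[1], pr_lnX_p = prec(p$ln_X[2]),
              pr_om_m = p$omega_log[1], pr_om_p = prec(p$omega_log[2]),
              pr_theta_rate = p$theta_rate,
              pr_b0_m = p$beta0[1], pr_b0_p = prec(p$beta0[2]),
              pr_b1_m = p$beta1[1], pr_b1_p = prec(p$beta1[2]),
              pr_g0_m = p$gamma0[1], pr_g0_p = prec(p$gamma0[2]),
              pr_g1_m = p$gamma1[1], pr_g1_p = prec(p$gamma1[2]))
  std <- fr$std
  sct <- !is.na(std$Ct)
  dat <- c(dat, list(n_std = nrow(std), Ks = std$K, Zs = std$Z,
                     n_std_ct = sum(sct), Ks_ct = std$K[sct],
                     Ys = std$Ct[sct], ps_ct = std$plate[sct],
                     lnKc = if (any(sct)) mean(log(std$K[sct])) else 0))
  if (fr$has_counts)
    dat <- c(dat, list(phi = fr$phi, n_count = nrow(fr$counts),
                       N = fr$counts$N, tc = fr$counts$t,
                       Ec = fr$counts$E))
  if (fr$has_water) {
    ww <- fr$ww
    dat <- c(dat, list(n_wsamp = nrow(fr$wmd), tw = fr$wmd$t,
                       Fw = fr$wmd$F_l, Vw = fr$wmd$V_ul,
                       n_wwell = nrow(ww$rows), sw = ww$s, Zw = ww$rows$Z,
                       n_wwell_ct = sum(ww$ct), sw_ct = ww$s[ww$ct],
                       Yw = ww$rows$Ct[ww$ct], pw_ct = ww$rows$plate[ww$ct]))
  }
  if (fr$has_air) {
    aw <- fr$aw
    dat <- c(dat, list(pr_eta_m = p$eta[1], pr_eta_p = prec(p$eta[2]),
                       pr_tau_p = prec(p$tau), pr_rho_p = prec(p$rho),
                       n_asamp = nrow(fr$amd), ta = fr$amd$t, ja = fr$ja,
                       bsign = fr$bsign, jrep = fr$jrep,
                       Sa = fr$amd$S_cm2, Pa = fr$amd$P_days,
                       Va = fr$amd$V_ul,
                       n_awell = nrow(aw$rows), sa = aw$s, Za = aw$rows$Z,
                       n_awell_ct = sum(aw$ct), sa_ct = aw$s[aw$ct],
                       Ya = aw$rows$Ct[aw$ct], pa_ct = aw$rows$plate[aw$ct]))
  }
  dat
}

jags_inits <- function(fr, n_chains, seed, estimate_phi = FALSE) {
  lnX0 <- rep(fr$priors$ln_X[1], fr$Tn)
  if (fr$has_counts) {
    rate <- fr$counts$N / fr$counts$E
    lnX0[fr$counts$t] <- log(pmax(rate, 1))
  }
  lapply(seq_len(n_chains), function(ch) {
    # theta starts small so no initial detection probability rounds to 1
    # (dbern density would vanish at an observed Z = 0)
    ini <- list(lnW = lnX0 + 8, omega = 8, theta = 1e-4, beta0 = 38,
                beta1 = rep(-1.4, fr$n_plates), g0c = -0.5, gamma1 = 0,
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = (as.numeric(seed) * 1009 + ch) %% 2147483647)
    if (estimate_phi) ini$phi <- 20
    if (fr$has_air) {
      ini$eta <- rep(-8, 4); ini$tau <- rep(1, 4); ini$rho <- rep(0.5, 2)
      ini$lnA <- matrix(0, fr$Tn, 4)
      ini$d1 <- matrix(0, fr$Tn, 2)
    }
    ini
  })
}

#' Fit the joint count / water-eDNA / air-eDNA model by MCMC
#'
#' Samples the posterior defined by [joint_log_density()] using JAGS
#' (Gibbs/slice sampling). Defaults follow the study's run configuration:
#' four independent chains with 5000 warm-up and 5000 sampling iterations.
#' Convergence is not guaranteed -- inspect `rhat`, `ess` and
#' [convergence_pass()]. Given identical data, seed and backend version the
#' fit is deterministic.
#'
#' @param data An [edna_data()] or `edna_sim` object. Missing streams are
#'   tolerated: without air rows the count + water variant is fitted;
#'   without a counts table the latent density is informed by eDNA alone.
#' @param priors An [edna_priors()].
#' @param phi Fixed Negative Binomial overdispersion (default 20; estimated
#'   only if `estimate_phi = TRUE`, for richer count series).
#' @param estimate_phi Estimate `phi` with a half-Normal(0, 50) prior
#'   instead of fixing it.
#' @param n_chains Number of chains (at least 2, for split R-hat).
#' @param n_warmup,n_sampling Warm-up (adaptation + burn-in) and retained
#'   iterations per chain.
#' @param thin Thinning interval.
#' @param seed Integer seed controlling initial values and all chain RNGs.
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `edna_fit` with elements `draws` (array
#'   `iterations x chains x parameters`), `parameters`, `rhat`, `ess`,
#'   `n_divergent`, `treedepth_saturations` (both identically zero for this
#'   gradient-free backend: divergences and tree-depth saturation are
#'   Hamiltonian-sampler events that cannot occur under Gibbs/slice
#'   updates), `lp` (thinned log-posterior trace from the native density),
#'   `data`, `priors`, and the run configuration.
#' @examples
#' \donttest{
#' sim <- simulate_edna_dataset(sim_config(seed = 1))
#' fit <- edna_fit(sim, n_warmup = 200, n_sampling = 200, seed = 1)
#' fit
#' }
#' @export
edna_fit <- function(data, priors = edna_priors(), phi = 20,
                     estimate_phi = FALSE, n_chains = 4L,
                     n_warmup = 5000L, n_sampling = 5000L, thin = 1L,
                     seed = 1L, quiet = TRUE) {
  data <- as_edna_data(data)
  stopifnot(n_chains >= 2L, n_warmup > 0L, n_sampling > 0L, thin >= 1L)
  fr <- build_model_frame(data, priors, phi)
  if (!fr$has_water && !fr$has_air)
    stop("no environmental samples: nothing links the latent state to qPCR")
  if (!fr$has_air)
    warning("no air samples: fitting the count + water model variant")

  model_code <- build_jags_model(fr$has_counts, fr$has_water, fr$has_air,
                                 estimate_phi)
  jd <- jags_data_from_frame(fr)
  if (estimate_phi) jd$phi <- NULL

  monitors <- c("lnX", "omega", "theta", "beta0", "beta1", "gamma0",
                "gamma1")
  if (fr$has_air) monitors <- c(monitors, "eta", "tau", "rho", "eps", "d1")
  if (estimate_phi) monitors <- c(monitors, "phi")

  # block sampling of the linear-Gaussian calibration coefficients
  rjags::load.module("glm", quiet = TRUE)
  n_adapt <- min(1000L, n_warmup)
  jm <- rjags::jags.model(textConnection(model_code), data = jd,
                          inits = jags_inits(fr, n_chains, seed,
                                             estimate_phi),
                          n.chains = n_chains, n.adapt = n_adapt,
                          quiet = quiet)
  if (n_warmup > n_adapt)
    update(jm, n.iter = n_warmup - n_adapt,
           progress.bar = if (quiet) "none" else "text")
  samp <- rjags::coda.samples(jm, variable.names = monitors,
                              n.iter = n_sampling * thin, thin = thin,
                              progress.bar = if (quiet) "none" else "text")

  pars <- coda::varnames(samp)
  n_iter <- nrow(samp[[1]])
  draws <- array(NA_real_, dim = c(n_iter, n_chains, length(pars)),
                 dimnames = list(NULL, NULL, pars))
  for (ch in seq_len(n_chains)) draws[, ch, ] <- as.matrix(samp[[ch]])

  fit <- structure(list(draws = draws, parameters = pars, frame = fr,
                        data = data, priors = priors, phi = phi,
                        estimate_phi = estimate_phi,
                        model_code = model_code,
                        mcmc = list(n_chains = n_chains,
                                    n_warmup = n_warmup,
                                    n_sampling = n_sampling, thin = thin,
                                    seed = as.integer(seed)),
                        n_divergent = 0L, treedepth_saturations = 0L),
                   class = "edna_fit")
  fit$rhat <- apply(draws, 3, compute_rhat)
  fit$ess <- apply(draws, 3, compute_ess)
  fit$lp <- log_posterior_trace(fit)
  fit
}

# -- draw accessors -----------------------------------------------------

#' Extract posterior draws for a parameter
#'
#' @param fit An `edna_fit`.
#' @param par Parameter name, either a scalar (`"omega"`) or a vector base
#'   name (`"eta"` returns all `eta[j]` columns in index order).
#' @param merge Merge chains into one long matrix (default) or keep an
#'   `iterations x chains x columns` array.
#' @return A matrix (draws in rows, parameter columns) or 3-d array.
#' @export
param_draws <- function(fit, par, merge = TRUE) {
  stopifnot(inherits(fit, "edna_fit"))
  idx <- which(fit$parameters == par |
                 startsWith(fit$parameters, paste0(par, "[")))
  if (!length(idx)) stop("no such parameter: ", par)
  x <- fit$draws[, , idx, drop = FALSE]
  dimnames(x)[[3]] <- fit$parameters[idx]
  if (!merge) return(x)
  out <- matrix(x, nrow = dim(x)[1] * dim(x)[2], ncol = length(idx))
  colnames(out) <- fit$parameters[idx]
  out
}

#' Number of retained posterior draws (all chains)
#' @param fit An `edna_fit`.
#' @export
n_draws <- function(fit) dim(fit$draws)[1] * dim(fit$draws)[2]

# reconstruct a joint_log_density parameter list from one flattened draw
params_from_draw <- function(fit, i) {
  fr <- fit$frame
  d <- dim(fit$draws)
  it <- ((i - 1L) %% d[1]) + 1L
  ch <- ((i - 1L) %/% d[1]) + 1L
  v <- fit$draws[it, ch, ]
  pick <- function(base, n) {
    if (n == 1L && base %in% names(v)) return(unname(v[base]))
    unname(v[paste0(base, "[", seq_len(n), "]")])
  }
  Tn <- fr$Tn
  par <- list(ln_X = pick("lnX", Tn), omega_log = unname(v["omega"]))
  if (fr$has_air) {
    par$eta <- pick("eta", 4L)
    par$tau <- pick("tau", 4L)
    par$rho <- pick("rho", 2L)
    eps <- matrix(NA_real_, Tn, 4L)
    d1 <- matrix(NA_real_, Tn, 2L)
    for (j in 1:4) eps[, j] <- unname(v[paste0("eps[", seq_len(Tn), ",", j, "]")])
    for (j in 1:2) d1[, j] <- unname(v[paste0("d1[", seq_len(Tn), ",", j, "]")])
    par$eps <- eps
    par$delta1 <- d1
  } else {
    par$eta <- numeric(0); par$tau <- numeric(0); par$rho <- numeric(0)
    par$eps <- matrix(0, Tn, 0L); par$delta1 <- matrix(0, Tn, 0L)
  }
  par$calib <- qpcr_calibration(
    theta = unname(v["theta"]), beta0 = unname(v["beta0"]),
    beta1 = pick("beta1", fr$n_plates),
    gamma0 = unname(v["gamma0"]), gamma1 = unname(v["gamma1"]))
  par
}

#' Log-posterior trace from the canonical density
#'
#' Evaluates [joint_log_density()] on a thinned subset of retained draws,
#' giving a backend-independent log-posterior trace.
#'
#' @param fit An `edna_fit`.
#' @param every Evaluate every `every`-th retained iteration.
#' @return Matrix (thinned iterations x chains).
#' @export
log_posterior_trace <- function(fit, every = NULL) {
  d <- dim(fit$draws)
  if (is.null(every)) every <- max(1L, d[1] %/% 50L)
  its <- seq(1L, d[1], by = every)
  out <- matrix(NA_real_, length(its), d[2])
  phi <- fit$phi
  for (ch in seq_len(d[2]))
    for (k in seq_along(its)) {
      i <- (ch - 1L) * d[1] + its[k]
      out[k, ch] <- suppressWarnings(
        joint_log_density(params_from_draw(fit, i), fit$data, fit$priors,
                          phi = phi))
    }
  out
}

#' Replicate deviations with the sum-to-zero constraint applied
#'
#' Expands the sampled first-replicate deviations into both replicates
#' (`delta_2 = -delta_1`), so every posterior draw satisfies
#' `sum_b delta_tjb = 0` exactly.
#'
#' @param fit An `edna_fit` including the air stream.
#' @return Array `draws x timepoints x 2 (sampler) x 2 (replicate)`.
#' @export
replicate_deviations <- function(fit) {
  stopifnot(inherits(fit, "edna_fit"))
  if (!fit$frame$has_air) stop("fit has no air stream")
  Tn <- fit$frame$Tn
  d1 <- param_draws(fit, "d1")
  nd <- nrow(d1)
  out <- array(NA_real_, dim = c(nd, Tn, 2L, 2L))
  for (j in 1:2)
    for (t in seq_len(Tn)) {
      v <- d1[, paste0("d1[", t, ",", j, "]")]
      out[, t, j, 1L] <- v
      out[, t, j, 2L] <- -v
    }
  out
}

#' Did the fit meet the diagnostic protocol?
#'
#' Pass requires every R-hat below 1.05, every effective sample size above
#' 1000, zero divergent transitions and no tree-depth saturation.
#'
#' @param fit An `edna_fit`.
#' @param rhat_max,ess_min Thresholds.
#' @return Logical flag.
#' @export
convergence_pass <- function(fit, rhat_max = 1.05, ess_min = 1000) {
  all(fit$rhat < rhat_max, na.rm = TRUE) &&
    all(fit$ess > ess_min, na.rm = TRUE) &&
    fit$n_divergent == 0L && fit$treedepth_saturations == 0L
}

#' @export
print.edna_fit <- function(x, ...) {
  cat("Joint eDNA state-space model fit (JAGS)\n")
  cat(sprintf("  %d chains x %d retained iterations (%d warm-up)\n",
              x$mcmc$n_chains, x$mcmc$n_sampling, x$mcmc$n_warmup))
  cat(sprintf("  streams: counts=%s water=%s air=%s\n",
              x$frame$has_counts, x$frame$has_water, x$frame$has_air))
  cat(sprintf("  max R-hat %.3f, min ESS %.0f, %d divergences\n",
              max(x$rhat, na.rm = TRUE), min(x$ess, na.rm = TRUE),
              x$n_divergent))
  om <- mean(param_draws(x, "omega"))
  cat(sprintf("  integrated eDNA factor omega = %.3f (%.0f copies/L per fish/day)\n",
              om, exp(om)))
  invisible(x)
}

#' @export
coef.edna_fit <- function(object, ...) {
  keep <- !grepl("^(gmix|eps|d1)\\[", object$parameters)
  colMeans(matrix(object$draws[, , keep],
                  nrow = dim(object$draws)[1] * dim(object$draws)[2],
                  dimnames = list(NULL, object$parameters[keep])))
}
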