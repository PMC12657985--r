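#' @keywords internal
"_PACKAGE"

#' Passive air sampler types
#'
#' Sampler order used throughout the package: gelatin and PTFE filters carry
#' two biological replicates per deployment; the air-suspended MCE filter and
#' the open deionized-water tray (MCE DI) are single samples.
#' @export
SAMPLER_TYPES <- c("gelatin", "ptfe", "mce_air", "mce_di")

#' @rdname SAMPLER_TYPES
#' @export
REPLICATED_SAMPLERS <- 1:2

#' Expected accumulated fish count
#'
#' The latent daily accumulation rate `X_t` (fish/day) times the counting
#' effort `E_t` (days since the previous gate opening) gives the expected
#' number of fish accumulated below the gate, `lambda_t = X_t * E_t`.
#' Zero effort forces a zero expectation.
#'
#' @param X Positive daily accumulation rate(s), fish/day.
#' @param E Non-negative effort(s), days.
#' @return Expected counts, `X * E`.
#' @export
expected_count <- function(X, E) {
  stopifnot(is.numeric(X), is.numeric(E), all(X > 0), all(E >= 0))
  X * E
}

#' Negative Binomial count log-likelihood
#'
#' Log probability mass of observed counts under the mean/overdispersion
#' Negative Binomial: mean `lambda`, variance `lambda + lambda^2 / phi`.
#' Rows with `lambda = 0` (zero effort) carry no information and must be
#' excluded upstream; passing one is an error.
#'
#' @param N Non-negative integer count(s).
#' @param lambda Positive expected count(s).
#' @param phi Positive overdispersion (the limit `phi -> Inf` is Poisson).
#' @return Sum of log pmf values.
#' @export
count_loglik <- function(N, lambda, phi) {
  stopifnot(is.numeric(N), all(N >= 0), all(N == round(N)),
            is.numeric(phi), length(phi) == 1L)
  if (phi <= 0) stop("'phi' must be strictly positive")
  if (any(lambda <= 0))
    stop("'lambda' must be strictly positive; zero-effort rows are excluded")
  sum(stats::dnbinom(N, size = phi, mu = lambda, log = TRUE))
}

#' Water eDNA concentration implied by fish density
#'
#' The integrated eDNA factor aggregates per-fish shedding, decay, transport
#' and dilution into one conversion: `W = X * exp(omega_log)` copies/L per
#' (fish/day), deterministic in the process model. `omega_log` is carried on
#' the natural-log scale so that `exp(omega_log)` is the copies/L produced by
#' an accumulation rate of one fish per day.
#'
#' @param X Positive daily accumulation rate(s), fish/day.
#' @param omega_log Log-scale integrated eDNA factor.
#' @return Water concentration(s), copies/L.
#' @export
water_concentration <- function(X, omega_log) {
  stopifnot(is.numeric(X), all(X > 0), is.numeric(omega_log),
            length(omega_log) == 1L)
  X * exp(omega_log)
}

#' Mean log air deposition for a sampler
#'
#' Air eDNA deposition is a log-linear function of the water concentration
#' with sampler-specific intercept and unit slope:
#' `ln A = eta_j + ln W`. The unit slope is a structural assumption, not an
#' estimable parameter, so differences between samplers are independent of
#' `W`.
#'
#' @param W Positive water concentration(s), copies/L.
#' @param eta_j Sampler-specific transfer (dilution) intercept, log scale.
#' @return Log deposition(s), log copies/cm^2/day.
#' @export
air_log_mean <- function(W, eta_j) {
  stopifnot(is.numeric(W), all(W > 0), is.numeric(eta_j), length(eta_j) == 1L)
  eta_j + log(W)
}

#' Biological-replicate log concentrations under the sum-to-zero constraint
#'
#' For samplers deployed in duplicate the two replicate deviations satisfy
#' `delta_1 + delta_2 = 0`, so the pair is parameterized by `delta_1` alone:
#' replicate logs are `logA + delta_1` and `logA - delta_1`, and their mean
#' equals `logA` exactly.
#'
#' @param logA Sample-level mean log concentration.
#' @param delta1 Deviation of the first replicate.
#' @return Numeric vector of length 2 (or a 2-column matrix for vector
#'   input): the per-replicate log concentrations.
#' @export
replicate_log_conc <- function(logA, delta1) {
  stopifnot(is.numeric(logA), is.numeric(delta1),
            length(logA) == length(delta1))
  out <- cbind(rep1 = logA + delta1, rep2 = logA - delta1)
  if (length(logA) == 1L) drop(out) else out
}

#' Per-reaction concentration of a water sample
#'
#' Normalizes a water-column concentration to the qPCR reaction:
#' `U = W * F / V`, with `F` the filtered volume (L) and `V` the reaction
#' volume (uL).
#'
#' @param W Water concentration, copies/L.
#' @param F_l Filtered volume, L.
#' @param V_ul Reaction volume, uL.
#' @param extraction_efficiency Optional multiplier for DNA recovered through
#'   extraction/elution; defaults to 1 (the normalization as defined).
#' @return Reaction concentration, copies/uL.
#' @export
reaction_conc_water <- function(W, F_l, V_ul, extraction_efficiency = 1) {
  stopifnot(all(W > 0), all(F_l > 0), all(V_ul > 0),
            extraction_efficiency > 0)
  W * F_l / V_ul * extraction_efficiency
}

#' Per-reaction concentration of a passive air sample
#'
#' Normalizes an areal deposition rate to the qPCR reaction:
#' `Q = A * S * P / V`, with `S` the active collection surface (cm^2), `P`
#' the deployment time (days) and `V` the reaction volume (uL). `A` is per
#' day, so deployment time multiplies the collected material.
#'
#' @param A Deposition rate, copies/cm^2/day.
#' @param S_cm2 Collection surface, cm^2 (16 for filters, 750 for the tray).
#' @param P_days Deployment time, days.
#' @param V_ul Reaction volume, uL.
#' @param extraction_efficiency Optional recovery multiplier, defaults to 1.
#' @return Reaction concentration, copies/uL.
#' @export
reaction_conc_air <- function(A, S_cm2, P_days, V_ul,
                              extraction_efficiency = 1) {
  stopifnot(all(A > 0), all(S_cm2 > 0), all(P_days > 0), all(V_ul > 0),
            extraction_efficiency > 0)
  A * S_cm2 * P_days / V_ul * extraction_efficiency
}

#' Prior configuration for the joint model
#'
#' Weakly informative defaults centered on qPCR physics: the Ct intercept
#' near 40 cycles, plate slopes near the perfect-efficiency value
#' `-1/log(10) * log(10) = -1.44` cycles per log-unit, half-Normal scales for
#' the transfer residual and replicate deviations, and an Exponential prior
#' on the per-copy detection rate. Every entry can be overridden.
#'
#' @param ln_X `c(location, scale)` of the Normal prior on `log X_t`.
#' @param omega_log `c(location, scale)` Normal prior on the integrated eDNA
#'   factor (log scale).
#' @param eta `c(location, scale)` Normal prior on each sampler intercept.
#' @param tau,rho Half-Normal scale (single positive number) for transfer
#'   residual sd and replicate-deviation sd.
#' @param theta_rate Rate of the Exponential prior on the detection rate.
#' @param beta0,beta1,gamma0,gamma1 `c(location, scale)` Normal priors on
#'   the Ct model parameters.
#' @return An object of class `edna_priors`.
#' @export
edna_priors <- function(ln_X = c(5, 3), omega_log = c(0, 10),
                        eta = c(0, 5), tau = 2, rho = 2,
                        theta_rate = 0.5, beta0 = c(40, 5),
                        beta1 = c(-1.44, 0.5), gamma0 = c(0, 2),
                        gamma1 = c(0, 1)) {
  chk2 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 2L || x[2] <= 0)
      stop("'", nm, "' must be c(location, scale) with scale > 0")
    x
  }
  chk1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || x <= 0)
      stop("'", nm, "' must be a single positive scale")
    x
  }
  structure(list(
    ln_X = chk2(ln_X, "ln_X"), omega_log = chk2(omega_log, "omega_log"),
    eta = chk2(eta, "eta"), tau = chk1(tau, "tau"), rho = chk1(rho, "rho"),
    theta_rate = chk1(theta_rate, "theta_rate"),
    beta0 = chk2(beta0, "beta0"), beta1 = chk2(beta1, "beta1"),
    gamma0 = chk2(gamma0, "gamma0"), gamma1 = chk2(gamma1, "gamma1")),
    class = "edna_priors")
}

half_normal_logpdf <- function(x, scale) {
  ifelse(x > 0, stats::dnorm(x, 0, scale, log = TRUE) + log(2), -Inf)
}

prior_log_density <- function(params, priors) {
  p <- priors
  ll <- sum(stats::dnorm(params$ln_X, p$ln_X[1], p$ln_X[2], log = TRUE)) +
    stats::dnorm(params$omega_log, p$omega_log[1], p$omega_log[2], log = TRUE) +
    sum(stats::dnorm(params$eta, p$eta[1], p$eta[2], log = TRUE)) +
    sum(half_normal_logpdf(params$tau, p$tau)) +
    stats::dexp(params$calib$theta, p$theta_rate, log = TRUE) +
    stats::dnorm(params$calib$beta0, p$beta0[1], p$beta0[2], log = TRUE) +
    sum(stats::dnorm(params$calib$beta1, p$beta1[1], p$beta1[2], log = TRUE)) +
    stats::dnorm(params$calib$gamma0, p$gamma0[1], p$gamma0[2], log = TRUE) +
    stats::dnorm(params$calib$gamma1, p$gamma1[1], p$gamma1[2], log = TRUE)
  if (!is.null(params$rho) && length(params$rho))
    ll <- ll + sum(half_normal_logpdf(params$rho, p$rho))
  ll
}

#' Joint log-density of the full state-space model
#'
#' Canonical (sampler-independent) implementation of the model's joint
#' unnormalized posterior log-density: Negative Binomial count terms (rows
#' with zero effort excluded), Normal transfer residual and
#' replicate-deviation terms, the qPCR observation likelihood over every
#' plate well (standards at their known concentrations, environmental wells
#' at the latent per-reaction concentrations implied by the state), and the
#' prior log-densities. Used for oracle checks, log-posterior traces, and as
#' the contract any sampling backend must target.
#'
#' @param params Named list: `ln_X` (length `T`), `omega_log`, `eta`
#'   (length 4), `tau` (length 4), `rho` (length 2, may be empty when no
#'   replicated sampler is present), `eps` (`T x 4` matrix of transfer
#'   residuals), `delta1` (`T x 2` matrix of first-replicate deviations) and
#'   `calib` (a [qpcr_calibration()]).
#' @param data An [edna_data()] object (counts, metadata, plate table).
#' @param priors An [edna_priors()] object.
#' @param phi Fixed Negative Binomial overdispersion (default 20).
#' @return A single numeric; an assertion fails if it is non-finite at
#'   finite inputs within the support.
#' @export
joint_log_density <- function(params, data, priors = edna_priors(),
                              phi = 20) {
  stopifnot(inherits(data, "edna_data"))
  ll <- prior_log_density(params, priors)

  X <- exp(params$ln_X)
  counts <- data$counts
  if (!is.null(counts) && nrow(counts)) {
    keep <- counts$E > 0
    if (any(keep))
      ll <- ll + count_loglik(counts$N[keep],
                              expected_count(X[counts$t[keep]],
                                             counts$E[keep]), phi)
  }

  W <- water_concentration(X, params$omega_log)

  md <- data$metadata
  air_md <- md[md$class == "air", , drop = FALSE]
  J <- length(params$eta)
  if (nrow(air_md)) {
    ll <- ll + sum(stats::dnorm(params$eps, 0,
                                rep(params$tau, each = nrow(params$eps)),
                                log = TRUE))
    # delta_1 under the sum-to-zero constraint: conditioning the iid
    # N(0, rho) replicate pair on a zero sum halves the variance
    if (length(params$rho))
      ll <- ll + sum(stats::dnorm(params$delta1, 0,
                                  rep(params$rho / sqrt(2),
                                      each = nrow(params$delta1)),
                                  log = TRUE))
  }

  # latent per-reaction concentration for every environmental sample
  conc_of_sample <- function(sid) {
    row <- md[match(sid, md$sample_id), , drop = FALSE]
    if (anyNA(row$sample_id)) stop("plate row references unknown sample_id")
    out <- numeric(nrow(row))
    is_w <- row$class == "water"
    if (any(is_w))
      out[is_w] <- reaction_conc_water(W[row$t[is_w]], row$F_l[is_w],
                                       row$V_ul[is_w])
    if (any(!is_w)) {
      rw <- row[!is_w, , drop = FALSE]
      j <- match(rw$sampler, SAMPLER_TYPES)
      lnA <- params$eta[j] + log(W[rw$t]) + params$eps[cbind(rw$t, j)]
      rep_dev <- numeric(nrow(rw))
      has_rep <- j %in% REPLICATED_SAMPLERS & !is.na(rw$b)
      if (any(has_rep)) {
        d1 <- params$delta1[cbind(rw$t[has_rep], j[has_rep])]
        rep_dev[has_rep] <- ifelse(rw$b[has_rep] == 1L, d1, -d1)
      }
      out[!is_w] <- reaction_conc_air(exp(lnA + rep_dev), rw$S_cm2,
                                      rw$P_days, rw$V_ul)
    }
    out
  }

  pl <- data$plate
  if (nrow(pl)) {
    concs <- numeric(nrow(pl))
    std <- pl$class %in% c("standard", "control")
    concs[std] <- pl$K[std]
    env <- !std
    if (any(env)) concs[env] <- conc_of_sample(pl$sample_id[env])
    ll <- ll + observation_loglik(pl[, c("Z", "Ct", "plate")], concs,
                                  params$calib)
  }

  stopifnot(is.finite(ll) || any(!is.finite(unlist(params[c(
    "ln_X", "omega_log", "eta", "tau", "rho")]))))
  ll
}
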