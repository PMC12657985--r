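#' Deterministic per-stage child seed
#'
#' One root seed drives the whole simulation; each stochastic stage draws
#' from its own child seed derived by hashing the stage name, so stages are
#' reproducible and mutually independent.
#' @noRd
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483563
  as.integer((h + as.numeric(seed) * 7919) %% 2147483563)
}

#' Simulation configuration
#'
#' Ground-truth parameters and design constants for the forward simulator.
#' Defaults emulate the study conditions the model was built for: six weekly
#' sampling dates at a hatchery fish ladder (first effort zero, then 7-day
#' intervals), a fall-run accumulation trajectory averaging about 160
#' fish/day with a peak near 286 and a trough near 78, an integrated eDNA
#' factor of `exp(9.578)` copies/L per fish/day, and the four passive air
#' samplers with their posterior-mean transfer intercepts, residual scales
#' and replicate deviations.
#'
#' @param n_timepoints Number of sampling dates.
#' @param efforts Non-negative integer days between gate openings
#'   (`efforts[1] = 0`: the first count precedes any accumulation interval
#'   and is excluded from the likelihood).
#' @param true_X Positive fish/day trajectory, length `n_timepoints`.
#' @param omega_log Integrated eDNA factor, natural-log scale.
#' @param eta Length-4 transfer intercepts in [SAMPLER_TYPES] order.
#' @param tau Length-4 positive residual sds.
#' @param rho Length-2 positive replicate-deviation sds (gelatin, PTFE).
#' @param phi Positive Negative Binomial overdispersion, fixed at 20.
#' @param calib A [qpcr_calibration()]: the true observation parameters.
#' @param F_l,V_ul,P_days Filtered water volume (L), reaction volume (uL)
#'   and deployment time (days).
#' @param S_cm2 Named length-4 vector of collection surfaces (cm^2).
#' @param n_tech_reps Technical qPCR replicates per environmental sample.
#' @param n_plates Number of qPCR plates (each runs its own standard series
#'   and no-template controls).
#' @param n_controls No-template control wells per plate.
#' @param standards Standard dilution series, see [make_standard_series()].
#' @param seed Root integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_timepoints = 6L,
                       efforts = c(0L, 7L, 7L, 7L, 7L, 7L),
                       true_X = c(120, 286, 210, 150, 118, 78),
                       omega_log = 9.578,
                       eta = c(-10.45, -9.53, -10.91, -9.95),
                       tau = c(0.473, 0.570, 0.949, 1.780),
                       rho = c(0.386, 0.154),
                       phi = 20,
                       calib = qpcr_calibration(theta = 0.3, beta0 = 40,
                                                beta1 = c(-1.44, -1.42),
                                                gamma0 = -0.3,
                                                gamma1 = -0.15),
                       F_l = 1, V_ul = 10, P_days = 1,
                       S_cm2 = c(gelatin = 16, ptfe = 16, mce_air = 16,
                                 mce_di = 750),
                       n_tech_reps = 3L, n_plates = NULL, n_controls = 3L,
                       standards = make_standard_series(),
                       seed = 1L) {
  if (is.null(n_plates)) n_plates <- length(calib$beta1)
  stopifnot(length(true_X) == n_timepoints,
            length(efforts) == n_timepoints,
            all(true_X > 0), all(efforts >= 0),
            length(eta) == 4L, length(tau) == 4L, length(rho) == 2L,
            all(tau > 0), all(rho > 0), phi > 0,
            inherits(calib, "qpcr_calibration"),
            n_plates == length(calib$beta1),
            F_l > 0, V_ul > 0, P_days > 0, all(S_cm2 > 0),
            n_tech_reps >= 1L, n_controls >= 0L)
  structure(list(n_timepoints = as.integer(n_timepoints),
                 efforts = as.integer(efforts), true_X = true_X,
                 omega_log = omega_log, eta = eta, tau = tau, rho = rho,
                 phi = phi, calib = calib, F_l = F_l, V_ul = V_ul,
                 P_days = P_days, S_cm2 = S_cm2,
                 n_tech_reps = as.integer(n_tech_reps),
                 n_plates = as.integer(n_plates),
                 n_controls = as.integer(n_controls),
                 standards = standards, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate visual fish counts
#'
#' Draws accumulated counts from a Negative Binomial with mean
#' `lambda_t = X_t * E_t` and variance `lambda + lambda^2 / phi`. Zero-effort
#' entries return 0 deterministically (no accumulation interval).
#'
#' @param true_X Positive fish/day vector.
#' @param efforts Non-negative day vector, same length.
#' @param phi Positive overdispersion.
#' @param seed Optional integer seed.
#' @return Integer count vector.
#' @export
simulate_counts <- function(true_X, efforts, phi, seed = NULL) {
  stopifnot(length(true_X) == length(efforts), all(true_X > 0),
            all(efforts >= 0))
  if (phi <= 0) stop("'phi' must be strictly positive")
  if (!is.null(seed)) set.seed(seed)
  N <- integer(length(true_X))
  pos <- efforts > 0
  if (any(pos))
    N[pos] <- stats::rnbinom(sum(pos), size = phi,
                             mu = true_X[pos] * efforts[pos])
  N
}

#' Deterministic water eDNA concentration
#'
#' @inheritParams water_concentration
#' @return Copies/L vector, `X * exp(omega_log)`.
#' @export
simulate_water <- function(true_X, omega_log) {
  water_concentration(true_X, omega_log)
}

#' Simulate passive-air deposition concentrations
#'
#' For each time point and sampler draws the sample-level log deposition
#' `ln A_tj = eta_j + ln W_t + eps_tj`, `eps_tj ~ N(0, tau_j)`; replicated
#' samplers (gelatin, PTFE) additionally get two biological replicates with
#' independent deviations `delta ~ N(0, rho_j)`. Generation draws the
#' deviations unconstrained; the sum-to-zero constraint is an inference-side
#' identification device.
#'
#' @param W Positive water concentrations, copies/L (one per time point).
#' @param eta Length-4 transfer intercepts.
#' @param tau Length-4 positive residual sds.
#' @param rho Length-2 positive replicate sds.
#' @param seed Optional integer seed.
#' @return Data frame with columns `t`, `sampler`, `j`, `b`, `A`
#'   (copies/cm^2/day); `b` is `NA` for single-sample samplers.
#' @export
simulate_air <- function(W, eta, tau, rho, seed = NULL) {
  stopifnot(all(W > 0))
  if (length(eta) != 4L || length(tau) != 4L || length(rho) != 2L)
    stop("'eta' and 'tau' must have length 4 and 'rho' length 2")
  stopifnot(all(tau > 0), all(rho > 0))
  if (!is.null(seed)) set.seed(seed)
  Tn <- length(W)
  rows <- list()
  for (j in seq_along(SAMPLER_TYPES)) {
    eps <- stats::rnorm(Tn, 0, tau[j])
    lnA <- eta[j] + log(W) + eps
    if (j %in% REPLICATED_SAMPLERS) {
      delta <- matrix(stats::rnorm(2L * Tn, 0, rho[j]), ncol = 2L)
      rows[[length(rows) + 1L]] <- data.frame(
        t = rep(seq_len(Tn), 2L), sampler = SAMPLER_TYPES[j], j = j,
        b = rep(1:2, each = Tn), A = exp(c(lnA + delta[, 1], lnA + delta[, 2])))
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        t = seq_len(Tn), sampler = SAMPLER_TYPES[j], j = j, b = NA_integer_,
        A = exp(lnA))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$t, out$j, out$b), ]
  rownames(out) <- NULL
  out
}

#' Standard-curve dilution series
#'
#' The default replication scheme: 1e5, 1e4 and 1e3 copies/uL in triplicate,
#' 1e2 in quadruplicate and 1e1 in triplicate (16 reactions), serially
#' diluted from a stock designated 1e6 copies/uL.
#'
#' @param reps Optional named numeric vector overriding the scheme; names
#'   are concentrations (copies/uL), values replicate counts.
#' @param stock Stock designation recorded as an attribute, copies/uL.
#' @return Data frame with columns `K` (decreasing) and `n_rep`, with
#'   attribute `stock`.
#' @examples
#' sum(make_standard_series()$n_rep)       # 16
#' make_standard_series(c("100" = 2))
#' @export
make_standard_series <- function(reps = NULL, stock = 1e6) {
  if (is.null(reps))
    reps <- c("1e+05" = 3, "10000" = 3, "1000" = 3, "100" = 4, "10" = 3)
  K <- as.numeric(names(reps))
  if (anyNA(K) || any(K <= 0)) stop("replicate names must be positive concentrations")
  out <- data.frame(K = K, n_rep = as.integer(unname(reps)))
  out <- out[order(-out$K), ]
  rownames(out) <- NULL
  attr(out, "stock") <- stock
  out
}

#' Simulate qPCR wells
#'
#' Each well amplifies with probability `1 - exp(-K * theta)`; amplified
#' wells report a Normal Ct with the calibration's concentration-dependent
#' mean and sd, non-amplified wells report a missing Ct. Zero concentration
#' (no-template control) never amplifies.
#'
#' @param concs Non-negative per-well concentrations, copies/uL.
#' @param calib A [qpcr_calibration()].
#' @param plate Plate index per well (length 1 or `length(concs)`).
#' @param seed Optional integer seed.
#' @return Data frame with columns `Z` (0/1) and `Ct` (`NA` where `Z = 0`).
#' @export
simulate_qpcr <- function(concs, calib, plate = 1L, seed = NULL) {
  stopifnot(inherits(calib, "qpcr_calibration"), all(concs >= 0))
  if (!is.null(seed)) set.seed(seed)
  n <- length(concs)
  plate <- rep_len(as.integer(plate), n)
  psi <- detection_probability(concs, calib$theta)
  Z <- stats::rbinom(n, 1L, psi)
  Ct <- rep(NA_real_, n)
  amp <- which(Z == 1L)
  if (length(amp)) {
    m <- ct_moments(concs[amp], calib, plate[amp])
    Ct[amp] <- stats::rnorm(length(amp), m$mean, m$sd)
  }
  data.frame(Z = Z, Ct = Ct)
}

#' Forward-simulate a complete joint dataset
#'
#' Produces every input the fitting pipeline consumes -- the visual-count
#' series, the sample metadata table, and the long qPCR plate table holding
#' standards, water wells, air wells and no-template controls -- using the
#' exact generative structure the model assumes, plus an echo of the truth.
#'
#' @param config A [sim_config()].
#' @return An object of class `edna_sim`: a list with elements `counts`,
#'   `metadata`, `plate` (all data frames), and `truth` (the config plus the
#'   realized latent water and air concentrations).
#' @examples
#' sim <- simulate_edna_dataset(sim_config(seed = 42))
#' str(sim$counts)
#' @export
simulate_edna_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  Tn <- cf$n_timepoints

  N <- simulate_counts(cf$true_X, cf$efforts, cf$phi,
                       seed = stage_seed(cf$seed, "counts"))
  counts <- data.frame(t = seq_len(Tn), N = N, E = cf$efforts)

  W <- simulate_water(cf$true_X, cf$omega_log)
  air <- simulate_air(W, cf$eta, cf$tau, cf$rho,
                      seed = stage_seed(cf$seed, "air"))

  water_md <- data.frame(
    sample_id = sprintf("w_t%02d", seq_len(Tn)), class = "water",
    t = seq_len(Tn), sampler = NA_character_, b = NA_integer_,
    F_l = cf$F_l, V_ul = cf$V_ul, S_cm2 = NA_real_, P_days = NA_real_)
  air_md <- data.frame(
    sample_id = sprintf("a_t%02d_%s_b%d", air$t, air$sampler,
                        ifelse(is.na(air$b), 1L, air$b)),
    class = "air", t = air$t, sampler = air$sampler, b = air$b,
    F_l = NA_real_, V_ul = cf$V_ul, S_cm2 = unname(cf$S_cm2[air$sampler]),
    P_days = cf$P_days)
  metadata <- rbind(water_md, air_md)
  rownames(metadata) <- NULL

  # per-sample reaction concentrations
  U <- reaction_conc_water(W, cf$F_l, cf$V_ul)
  Q <- reaction_conc_air(air$A, unname(cf$S_cm2[air$sampler]), cf$P_days,
                         cf$V_ul)
  env_conc <- c(U, Q)
  env_id <- c(water_md$sample_id, air_md$sample_id)
  env_class <- c(rep("water", Tn), rep("air", nrow(air_md)))
  # assign each environmental sample's technical replicates to one plate,
  # alternating plates across samples
  env_plate <- ((seq_along(env_id) - 1L) %% cf$n_plates) + 1L

  std <- cf$standards
  plate_rows <- list()
  for (p in seq_len(cf$n_plates)) {
    kk <- rep(std$K, std$n_rep)
    plate_rows[[length(plate_rows) + 1L]] <- data.frame(
      sample_id = sprintf("std_p%d_%s", p, format(kk, scientific = TRUE,
                                                  trim = TRUE)),
      class = "standard", plate = p,
      rep = unlist(lapply(std$n_rep, seq_len)), K = kk)
    if (cf$n_controls > 0L)
      plate_rows[[length(plate_rows) + 1L]] <- data.frame(
        sample_id = sprintf("ntc_p%d", p), class = "control", plate = p,
        rep = seq_len(cf$n_controls), K = 0)
  }
  env_rows <- data.frame(
    sample_id = rep(env_id, each = cf$n_tech_reps),
    class = rep(env_class, each = cf$n_tech_reps),
    plate = rep(env_plate, each = cf$n_tech_reps),
    rep = rep(seq_len(cf$n_tech_reps), length(env_id)),
    K = NA_real_)
  plate_tab <- rbind(do.call(rbind, plate_rows), env_rows)
  rownames(plate_tab) <- NULL

  well_conc <- ifelse(plate_tab$class %in% c("standard", "control"),
                      plate_tab$K,
                      env_conc[match(plate_tab$sample_id, env_id)])
  zy <- simulate_qpcr(well_conc, cf$calib, plate_tab$plate,
                      seed = stage_seed(cf$seed, "qpcr"))
  plate_tab$Z <- zy$Z
  plate_tab$Ct <- zy$Ct

  truth <- c(unclass(cf), list(W = W, air = air))
  out <- structure(list(counts = counts, metadata = metadata,
                        plate = plate_tab, truth = truth),
                   class = "edna_sim")
  out
}

#' @export
print.edna_sim <- function(x, ...) {
  cat("Synthetic joint eDNA dataset\n")
  cat(sprintf("  %d time points, %d environmental samples, %d qPCR wells\n",
              nrow(x$counts), nrow(x$metadata), nrow(x$plate)))
  cat(sprintf("  wells: %d standards, %d water, %d air, %d controls\n",
              sum(x$plate$class == "standard"), sum(x$plate$class == "water"),
              sum(x$plate$class == "air"), sum(x$plate$class == "control")))
  invisible(x)
}
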