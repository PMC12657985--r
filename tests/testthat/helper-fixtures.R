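# Shared fixtures: everything is generated in code at test time.

default_calib <- function() {
  qpcr_calibration(theta = 0.3, beta0 = 40, beta1 = c(-1.44, -1.42),
                   gamma0 = -0.3, gamma1 = -0.15)
}

table1_eta <- c(-10.45, -9.53, -10.91, -9.95)
table1_tau <- c(0.473, 0.570, 0.949, 1.780)
table1_rho <- c(0.386, 0.154)

# one small shared fit, computed lazily and reused across test files
.fit_cache <- new.env(parent = emptyenv())

shared_small_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    sim <- simulate_edna_dataset(sim_config(seed = 5))
    .fit_cache$sim <- sim
    .fit_cache$fit <- edna_fit(sim, n_chains = 4, n_warmup = 500,
                               n_sampling = 500, seed = 5)
  }
  list(sim = .fit_cache$sim, fit = .fit_cache$fit)
}

# hand-built minimal dataset: 2 time points, one water sample, one
# unreplicated air sample, 2 standards + 1 water well + 1 air well
tiny_data <- function() {
  counts <- data.frame(t = 1:2, N = c(0L, 900L), E = c(0L, 7L))
  metadata <- data.frame(
    sample_id = c("w1", "a1"), class = c("water", "air"), t = c(1L, 1L),
    sampler = c(NA, "mce_air"), b = NA_integer_,
    F_l = c(1, NA), V_ul = 10, S_cm2 = c(NA, 16), P_days = c(NA, 1))
  plate <- data.frame(
    sample_id = c("s1", "s2", "w1", "a1"),
    class = c("standard", "standard", "water", "air"),
    plate = 1L, rep = 1L, K = c(1e4, 1e2, NA, NA),
    Z = c(1L, 1L, 1L, 0L), Ct = c(27.1, 33.8, 23.5, NA))
  edna_data(counts, metadata, plate)
}

# matching parameter list for tiny_data (4 samplers as always)
tiny_params <- function() {
  list(ln_X = c(4.8, 5.1), omega_log = 9.5,
       eta = c(-10.4, -9.5, -10.9, -9.9), tau = c(0.5, 0.6, 0.9, 1.8),
       rho = c(0.4, 0.15),
       eps = matrix(c(0.1, -0.2, 0, 0.3, -0.1, 0.2, 0.05, -0.05), 2, 4),
       delta1 = matrix(c(0.05, -0.02, 0.01, 0), 2, 2),
       calib = qpcr_calibration(0.3, 40, -1.44, -0.3, -0.15))
}
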