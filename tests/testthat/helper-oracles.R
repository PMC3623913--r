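# Independent brute-force oracles and small fixture builders.
# Oracles use explicit per-trial/per-sample loops on raw angles so they
# share no code path with the vectorized implementations they check.

oracle_itc <- function(phi_mat) {
  ns <- ncol(phi_mat); n <- nrow(phi_mat)
  out <- numeric(ns)
  for (t in seq_len(ns)) {
    cs <- 0; sn <- 0
    for (i in seq_len(n)) {
      cs <- cs + cos(phi_mat[i, t])
      sn <- sn + sin(phi_mat[i, t])
    }
    out[t] <- sqrt((cs / n)^2 + (sn / n)^2)
  }
  out
}

oracle_plv <- function(phi, x, y) oracle_itc(phi[, x, ] - phi[, y, ])
oracle_pcv <- function(phi, x, y) oracle_itc(phi[, x, ] + phi[, y, ])
oracle_plcv <- function(phi, x, y) {
  oracle_pcv(phi, x, y) * (1 - oracle_plv(phi, x, y))
}
oracle_te <- function(phi_t, phi_n, x, y) {
  oracle_plcv(phi_t, x, y) - oracle_plcv(phi_n, x, y)
}

# wrap a bare [trials, channels, samples] angle array as a phase tensor
phase_from_array <- function(phi, fs = 200, t0 = 0, is_target = NULL) {
  n_tr <- dim(phi)[1]
  if (is.null(is_target)) is_target <- rep(c(TRUE, FALSE), length.out = n_tr)
  events <- data.frame(onset = seq_len(n_tr) * 0.175, code = rep(1:12, length.out = n_tr),
                       is_target = is_target, block = 0L,
                       repetition = seq_len(n_tr) - 1L)
  mont <- default_montage(max(dim(phi)[2], 2))
  mont$labels <- mont$labels[seq_len(dim(phi)[2])]
  structure(list(phi = phi, amplitude = NULL, fs = fs, t0 = t0,
                 window_s = dim(phi)[3] / fs, events = events,
                 montage = mont),
            class = "phase_tensor")
}

random_phase_array <- function(trials, channels, samples, seed = 1) {
  withr::with_seed(seed,
    array(runif(trials * channels * samples, -pi, pi),
          dim = c(trials, channels, samples)))
}

# small simulated session used across suites
tiny_session <- function(seed = 1, n_channels = 8, n_blocks = 2, fs = 200,
                         relevant_channels = 1:3, kappa = 5, ...) {
  simulate_session(sim_config(
    n_channels = n_channels, n_blocks = n_blocks, fs = fs,
    relevant_channels = relevant_channels, kappa = kappa, seed = seed, ...))
}

# scripted second implementation of the recursive elimination (plain loops,
# no hclust) mirroring the published pseudocode step by step
scripted_rfe <- function(S) {
  n <- nrow(S)
  sc <- seq_len(n)
  R <- integer(0)
  while (length(sc) > 1) {
    k <- length(sc)
    best <- NULL; bv <- Inf
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (S[sc[a], sc[b]] < bv - 1e-15) { bv <- S[sc[a], sc[b]]; best <- c(sc[a], sc[b]) }
      }
    }
    trv_vals <- sapply(best, function(x) mean(S[x, setdiff(sc, x)]))
    w <- if (trv_vals[1] < trv_vals[2] - 1e-15) best[1]
         else if (trv_vals[2] < trv_vals[1] - 1e-15) best[2]
         else min(best)
    R <- c(w, R)
    sc <- setdiff(sc, w)
  }
  c(sc, R)
}
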