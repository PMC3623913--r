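#' Simulator configuration
#'
#' Parameters of the seeded row/column speller simulator. The paradigm
#' follows the standard protocol: a 6x6 matrix, 12 row/column
#' intensifications of 100 ms separated by 75 ms blanks (175 ms
#' stimulus-onset asynchrony), 15 repetitions per character block, a 2.5 s
#' blank before each block, and 80 blocks per session, giving 2,400 target
#' and 12,000 non-target trials.
#'
#' Signals follow the oscillatory account of the P300: each channel mixes
#' ongoing band-limited oscillators (sinusoids with Brownian phase drift)
#' plus 1/f background and white sensor noise. At each *target* stimulus,
#' the sources feeding `relevant_channels` have their phase redrawn from a
#' von Mises distribution (`mu_reset`, `kappa`) at `reset_latency_s` after
#' onset, blended in over a raised-cosine ramp of `reset_duration_s`, then
#' resume free-running. An additive fixed-latency evoked bump
#' (`evoked_amplitude > 0`) is available as the competing generation model.
#'
#' @param n_channels number of channels (default 16; use 32 to mirror the
#'   full montage).
#' @param n_blocks character blocks per session (default 80).
#' @param n_repetitions repetitions per block (default 15).
#' @param fs sampling rate, Hz (default 1000).
#' @param relevant_channels indices receiving the target phase reset.
#' @param kappa von Mises concentration of the post-reset phase (default 5).
#' @param reset_latency_s,reset_duration_s reset timing, s (defaults 0.3
#'   and 0.05).
#' @param mu_reset mean reset direction, radians (default 0).
#' @param mixing `channels x sources` matrix (default identity: one private
#'   source per channel). Rows sharing a source define homologous pairs.
#' @param osc_freqs per-source oscillator frequencies, Hz; default `NULL`
#'   draws them uniformly from `osc_freq_range` at simulation time.
#' @param osc_freq_range frequency range for drawn oscillators, Hz
#'   (default 2-7 Hz, the delta/theta band carrying the P300).
#' @param osc_amplitude oscillation amplitude, microvolts (default 5).
#' @param phase_diffusion Brownian phase-drift rate, rad/sqrt(s)
#'   (default 1.5); keeps ongoing phase unrelated to the stimulus schedule.
#' @param background_sd 1/f background noise SD, microvolts (default 2).
#' @param noise_sd white sensor noise SD, microvolts (default 2).
#' @param evoked_amplitude additive evoked bump amplitude, microvolts
#'   (default 0 = pure phase-reset model).
#' @param evoked_latency_s,evoked_width_s evoked bump peak latency and
#'   Gaussian width, s.
#' @param target_characters intended characters (one per block); default
#'   `NULL` draws them from the grid.
#' @param montage a [montage()]; default [default_montage()] labels.
#' @param seed integer seed; same seed, same session, bit for bit.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(n_channels = 16, n_blocks = 80, n_repetitions = 15,
                       fs = 1000, relevant_channels = 1:4, kappa = 5,
                       reset_latency_s = 0.3, reset_duration_s = 0.05,
                       mu_reset = 0, mixing = NULL, osc_freqs = NULL,
                       osc_freq_range = c(2, 7), osc_amplitude = 5,
                       phase_diffusion = 1.5, background_sd = 2,
                       noise_sd = 2, evoked_amplitude = 0,
                       evoked_latency_s = 0.3, evoked_width_s = 0.05,
                       target_characters = NULL, montage = NULL,
                       seed = NULL) {
  check_that(kappa >= 0, "kappa must be >= 0")
  check_that(n_channels >= 2, "need at least 2 channels")
  if (length(relevant_channels)) {
    check_that(all(relevant_channels >= 1 & relevant_channels <= n_channels),
               "relevant channel index out of range 1..%d", n_channels)
  }
  if (is.null(mixing)) mixing <- diag(n_channels)
  mixing <- as.matrix(mixing)
  check_that(nrow(mixing) == n_channels,
             "mixing must have %d rows (one per channel)", n_channels)
  check_that(all(is.finite(mixing)), "mixing must be finite")
  if (!is.null(osc_freqs)) {
    check_that(length(osc_freqs) == ncol(mixing),
               "need one oscillator frequency per source")
  }
  if (is.null(montage)) montage <- default_montage(n_channels)
  check_that(length(montage$labels) == n_channels,
             "montage length must equal n_channels")
  structure(list(
    n_channels = n_channels, n_blocks = n_blocks,
    n_repetitions = n_repetitions, fs = fs,
    relevant_channels = as.integer(relevant_channels), kappa = kappa,
    reset_latency_s = reset_latency_s, reset_duration_s = reset_duration_s,
    mu_reset = mu_reset, mixing = mixing, osc_freqs = osc_freqs,
    osc_freq_range = osc_freq_range, osc_amplitude = osc_amplitude,
    phase_diffusion = phase_diffusion, background_sd = background_sd,
    noise_sd = noise_sd, evoked_amplitude = evoked_amplitude,
    evoked_latency_s = evoked_latency_s, evoked_width_s = evoked_width_s,
    target_characters = target_characters, montage = montage, seed = seed),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d ch, %d blocks x %d reps @ %g Hz; ",
                     "relevant {%s}, kappa = %g, seed = %s\n"),
              x$n_channels, x$n_blocks, x$n_repetitions, x$fs,
              paste(x$relevant_channels, collapse = ","), x$kappa,
              x$seed %||% "none"))
  invisible(x)
}

# paradigm timing constants (seconds)
SOA_S <- 0.175          # 100 ms flash + 75 ms blank
PRE_BLANK_S <- 2.5      # blank matrix before each block
TAIL_S <- 2.0           # recording tail so the last epochs (+ padding) fit

#' Build the row/column stimulus schedule
#'
#' @param n_blocks,n_repetitions paradigm counts.
#' @param target_characters one character per block.
#' @param grid character matrix.
#' @return event data frame (see [validate_events()]); codes are randomly
#'   permuted within each repetition, exactly two targets per repetition.
#' @export
build_schedule <- function(n_blocks, n_repetitions, target_characters,
                           grid = speller_grid()) {
  block_len <- PRE_BLANK_S + n_repetitions * 12 * SOA_S
  rows <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    tc <- grid_codes(target_characters[b], grid)
    codes <- unlist(lapply(seq_len(n_repetitions), function(r) sample(12L)))
    onset <- (b - 1) * block_len + PRE_BLANK_S +
      (seq_len(n_repetitions * 12) - 1) * SOA_S
    rows[[b]] <- data.frame(
      onset = onset, code = codes, is_target = codes %in% tc,
      block = b - 1L,
      repetition = rep(seq_len(n_repetitions) - 1L, each = 12L))
  }
  do.call(rbind, rows)
}

# 1/f amplitude-shaped Gaussian noise, unit SD
pink_noise <- function(n) {
  n2 <- stats::nextn(max(n, 2L))
  spec <- stats::fft(stats::rnorm(n2))
  f <- c(1, seq_len(n2 - 1))
  f <- pmin(f, n2 - (f - 1))              # symmetric frequency index
  spec <- spec / sqrt(pmax(f, 1))
  x <- Re(stats::fft(spec, inverse = TRUE)) / n2
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

#' Simulate a P300 speller session
#'
#' See [sim_config()] for the generative model. All randomness flows from
#' `config$seed` through one R random stream with a fixed draw order
#' (characters, schedule, oscillators, resets, noise), so equal seeds give
#' bit-identical sessions; the global RNG state is left untouched.
#'
#' @param config a [sim_config()].
#' @return a [speller_session()] with `ground_truth` annotations
#'   (relevant channels and sources, mixing, oscillator frequencies).
#' @export
simulate_session <- function(config) {
  check_that(inherits(config, "sim_config"), "config must be a sim_config")
  with_seed(config$seed, simulate_session_impl(config))
}

simulate_session_impl <- function(cfg) {
  fs <- cfg$fs
  grid <- speller_grid()
  chars <- cfg$target_characters %||%
    sample(as.vector(grid), cfg$n_blocks, replace = TRUE)
  check_that(length(chars) == cfg$n_blocks,
             "need one target character per block")
  events <- build_schedule(cfg$n_blocks, cfg$n_repetitions, chars, grid)
  block_len <- PRE_BLANK_S + cfg$n_repetitions * 12 * SOA_S
  n <- round((cfg$n_blocks * block_len + TAIL_S) * fs)

  n_src <- ncol(cfg$mixing)
  f0 <- cfg$osc_freqs %||%
    stats::runif(n_src, cfg$osc_freq_range[1], cfg$osc_freq_range[2])
  relevant_sources <- which(colSums(
    abs(cfg$mixing[cfg$relevant_channels, , drop = FALSE])) > 0)

  target_onsets <- events$onset[events$is_target]
  reset_idx <- round((target_onsets + cfg$reset_latency_s) * fs) + 1L
  ramp_len <- max(2L, round(cfg$reset_duration_s * fs))
  ramp <- (1 - cos(pi * (seq_len(ramp_len) - 1) / (ramp_len - 1))) / 2

  X <- matrix(0, cfg$n_channels, n)
  for (s in seq_len(n_src)) {
    theta <- stats::runif(1, -pi, pi) +
      cumsum(2 * pi * f0[s] / fs +
             stats::rnorm(n, 0, cfg$phase_diffusion / sqrt(fs)))
    if (s %in% relevant_sources && length(reset_idx)) {
      psi <- rvonmises(length(reset_idx), cfg$mu_reset, cfg$kappa)
      # sequential offsets: each reset snaps the running phase to psi, the
      # oscillator then free-runs with the accumulated offset
      deltas <- numeric(length(reset_idx))
      running <- 0
      for (e in seq_along(reset_idx)) {
        deltas[e] <- wrap_angle(psi[e] - (theta[reset_idx[e]] + running))
        running <- running + deltas[e]
      }
      imp <- numeric(n)
      for (e in seq_along(reset_idx)) imp[reset_idx[e]] <- imp[reset_idx[e]] + deltas[e]
      offset <- cumsum(imp)
      for (e in seq_along(reset_idx)) {   # raised-cosine blend, no phase jump
        span <- reset_idx[e]:min(reset_idx[e] + ramp_len - 1L, n)
        offset[span] <- offset[span] - deltas[e] * (1 - ramp[seq_along(span)])
      }
      theta <- theta + offset
    }
    xs <- cfg$osc_amplitude * cos(theta)
    for (ch in which(cfg$mixing[, s] != 0)) {
      X[ch, ] <- X[ch, ] + cfg$mixing[ch, s] * xs
    }
  }

  if (cfg$evoked_amplitude > 0 && length(cfg$relevant_channels)) {
    klen <- round((cfg$evoked_latency_s + 4 * cfg$evoked_width_s) * fs)
    tk <- (seq_len(klen) - 1) / fs
    kern <- cfg$evoked_amplitude *
      exp(-(tk - cfg$evoked_latency_s)^2 / (2 * cfg$evoked_width_s^2))
    onset_idx <- round(target_onsets * fs) + 1L
    for (o in onset_idx) {
      span <- o:min(o + klen - 1L, n)
      X[cfg$relevant_channels, span] <-
        X[cfg$relevant_channels, span, drop = FALSE] +
        rep(kern[seq_along(span)], each = length(cfg$relevant_channels))
    }
  }

  for (ch in seq_len(cfg$n_channels)) {
    X[ch, ] <- X[ch, ] + cfg$background_sd * pink_noise(n) +
      stats::rnorm(n, 0, cfg$noise_sd)
  }

  shared <- which(colSums(cfg$mixing != 0) >= 2)
  hp <- do.call(rbind, lapply(shared, function(s) {
    ch <- which(cfg$mixing[, s] != 0)
    t(utils::combn(ch, 2))
  }))
  ground_truth <- list(
    relevant_channels = cfg$relevant_channels,
    relevant_sources = relevant_sources,
    homologous_pairs = if (is.null(hp)) matrix(integer(0), 0, 2) else hp,
    mixing = cfg$mixing, osc_freqs = f0, config = cfg)
  speller_session(X, fs, events, cfg$montage, chars, grid, ground_truth)
}

#' Ground-truth table of a simulated session
#'
#' @param session a session produced by [simulate_session()].
#' @return list with `relevance` (data frame: `channel`, `label`,
#'   `relevant`) and `homologous_pairs` (data frame of channel index pairs
#'   sharing a source: expected high PLV, low PLCV).
#' @export
ground_truth_report <- function(session) {
  check_that(inherits(session, "speller_session") &&
               !is.null(session$ground_truth),
             "session carries no ground truth (not simulator-produced)")
  gt <- session$ground_truth
  labels <- session$montage$labels
  relevance <- data.frame(
    channel = seq_along(labels), label = labels,
    relevant = seq_along(labels) %in% gt$relevant_channels,
    stringsAsFactors = FALSE)
  hp <- as.data.frame(gt$homologous_pairs)
  if (nrow(hp)) names(hp) <- c("x", "y") else hp <- data.frame(x = integer(0), y = integer(0))
  list(relevance = relevance, homologous_pairs = hp)
}
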