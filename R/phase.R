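#' Analytic signal of a real vector (FFT Hilbert transform)
#'
#' @param x real numeric vector.
#' @return complex vector `x + i * H(x)`.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  h <- hilbert_weights(n)
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

hilbert_weights <- function(n) {
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  h
}

#' Instantaneous phase of an epoch set
#'
#' Computes the analytic signal per trial and channel via the FFT-based
#' Hilbert transform and returns its argument (phase in `(-pi, pi]`) and,
#' optionally, its modulus (amplitude envelope). Epochs extracted with
#' padding (`t0 < 0`) keep their padding here; [crop_phase()] trims back to
#' the response window so Hilbert edge artifacts stay outside the analysis.
#'
#' @param epochs an [epoch_set()] at the phase-analysis rate (200 Hz in the
#'   standard chain).
#' @param keep_amplitude store the amplitude envelope as well (doubles the
#'   memory footprint).
#' @return an object of class `"phase_tensor"`: list with `phi`
#'   `[trials, channels, samples]`, `amplitude` (or `NULL`), `fs`, `t0`,
#'   `events`, `montage`.
#' @export
analytic_phase <- function(epochs, keep_amplitude = FALSE) {
  check_that(inherits(epochs, "epoch_set"), "epochs must be an epoch_set")
  check_that(!anyNA(epochs$data), "epoch data contain NA")
  d <- dim(epochs$data)
  # one FFT per (trial, channel): fold both into columns of one matrix
  m <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[3])
  h <- hilbert_weights(d[3])
  a <- stats::mvfft(stats::mvfft(m) * h, inverse = TRUE) / d[3]
  phi <- aperm(array(Arg(a), dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  amp <- NULL
  if (keep_amplitude) {
    amp <- aperm(array(Mod(a), dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  }
  structure(list(phi = phi, amplitude = amp, fs = epochs$fs, t0 = epochs$t0,
                 window_s = epochs$window_s, events = epochs$events,
                 montage = epochs$montage),
            class = "phase_tensor")
}

#' @export
print.phase_tensor <- function(x, ...) {
  d <- dim(x$phi)
  cat(sprintf("<phase_tensor> %d trials x %d channels x %d samples @ %g Hz, t0 = %g s\n",
              d[1], d[2], d[3], x$fs, x$t0))
  invisible(x)
}

#' Crop a phase tensor to a time window
#'
#' @param phase a `phase_tensor`.
#' @param window `c(start_s, end_s)` relative to stimulus onset; defaults to
#'   the response window `[0, window_s)`.
#' @return a `phase_tensor` restricted to the window (`t0` = window start).
#' @export
crop_phase <- function(phase, window = NULL) {
  if (is.null(window)) window <- c(0, phase$window_s)
  t <- phase$t0 + (seq_len(dim(phase$phi)[3]) - 1L) / phase$fs
  keep <- which(t >= window[1] - 1e-9 & t < window[2] - 1e-9)
  check_that(length(keep) > 0, "empty crop window [%g, %g]", window[1], window[2])
  out <- phase
  out$phi <- phase$phi[, , keep, drop = FALSE]
  if (!is.null(phase$amplitude))
    out$amplitude <- phase$amplitude[, , keep, drop = FALSE]
  out$t0 <- t[keep[1]]
  out
}

phase_times <- function(phase) {
  phase$t0 + (seq_len(dim(phase$phi)[3]) - 1L) / phase$fs
}

check_channel <- function(phase, x) {
  n <- dim(phase$phi)[2]
  check_that(length(x) == 1 && x >= 1 && x <= n,
             "channel index %s out of range 1..%d", paste(x, collapse = ","), n)
  as.integer(x)
}

pair_series <- function(kind, pair, values, phase) {
  structure(list(kind = kind, pair = pair, values = as.numeric(values),
                 fs = phase$fs, t0 = phase$t0),
            class = "pair_metric_series")
}

#' @export
print.pair_metric_series <- function(x, ...) {
  cat(sprintf("<pair_metric_series> %s(%s) over %d samples @ %g Hz, range [%.3f, %.3f]\n",
              x$kind, paste(x$pair, collapse = ","), length(x$values), x$fs,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.pair_metric_series <- function(x, ...) {
  data.frame(time = x$t0 + (seq_along(x$values) - 1L) / x$fs,
             value = x$values)
}

# mean resultant length over trials of exp(1i * theta), per sample
circ_mean_len <- function(theta_mat) {
  Mod(colMeans(exp(1i * theta_mat)))
}

# [trials, samples] matrix of one channel's phase, robust to size-1 dims
chan_mat <- function(phase, x) {
  d <- dim(phase$phi)
  matrix(phase$phi[, x, , drop = FALSE], nrow = d[1], ncol = d[3])
}

#' Phase locking value between two channels
#'
#' `PLV_{x,y}(t) = | (1/n) sum_trials exp(i (phi_x(t) - phi_y(t))) |`:
#' the across-trial consistency of the phase *difference*. High when the
#' two channels keep a constant lag, i.e. reflect a common (homologous)
#' source, regardless of whether either phase is locked to the stimulus.
#'
#' @param phase a `phase_tensor` from [analytic_phase()].
#' @param x,y channel indices (montage order).
#' @return a `pair_metric_series` with values in `[0, 1]`.
#' @export
plv <- function(phase, x, y) {
  x <- check_channel(phase, x); y <- check_channel(phase, y)
  v <- circ_mean_len(chan_mat(phase, x) - chan_mat(phase, y))
  pair_series("PLV", c(x, y), v, phase)
}

#' Inter-trial coherence of one channel
#'
#' `ITC_x(t) = | (1/n) sum_trials exp(i phi_x(t)) |`: the across-trial
#' concentration of a single channel's phase, the classic measure of
#' stimulus phase locking under the oscillatory (phase-reset) account of
#' event-related potentials.
#'
#' @inheritParams plv
#' @return a `pair_metric_series` (pair `c(x, x)`) with values in `[0, 1]`.
#' @export
itc <- function(phase, x) {
  x <- check_channel(phase, x)
  v <- circ_mean_len(chan_mat(phase, x))
  pair_series("ITC", c(x, x), v, phase)
}

#' Phase concentration value of a channel pair
#'
#' Extends ITC to two channels through the joint phase
#' `theta_{x,y}(t) = phi_x(t) + phi_y(t)`:
#' `PCV_{x,y}(t) = | (1/n) sum_trials exp(i (phi_x(t) + phi_y(t))) |`.
#' The sum makes PCV insensitive to a constant inter-channel lag (which
#' only rotates the mean direction) but high only when both phases are
#' concentrated across trials, i.e. when the pair is phase-synchronized to
#' the task. `pcv(phase, x, x)` is the ITC of the doubled phase.
#'
#' @inheritParams plv
#' @return a `pair_metric_series` with values in `[0, 1]`.
#' @export
pcv <- function(phase, x, y) {
  x <- check_channel(phase, x); y <- check_channel(phase, y)
  v <- circ_mean_len(chan_mat(phase, x) + chan_mat(phase, y))
  pair_series("PCV", c(x, y), v, phase)
}

#' Phase locking and concentration value
#'
#' `PLCV_{x,y}(t) = PCV_{x,y}(t) * (1 - PLV_{x,y}(t))`. The `1 - PLV`
#' factor down-weights homologous pairs: channels mirroring one source are
#' redundant for recognition no matter how task-locked they are. The
#' product form makes `PLCV(x, x) = 0` exactly, since `PLV(x, x) = 1`.
#' High PLCV marks a pair of heterologous channels jointly synchronized to
#' the task.
#'
#' @inheritParams plv
#' @return a `pair_metric_series` with values in `[0, 1]`.
#' @export
plcv <- function(phase, x, y) {
  x <- check_channel(phase, x); y <- check_channel(phase, y)
  px <- chan_mat(phase, x)
  py <- chan_mat(phase, y)
  v <- circ_mean_len(px + py) * (1 - circ_mean_len(px - py))
  pair_series("PLCV", c(x, y), v, phase)
}

#' Target effect of phase locking and concentration
#'
#' `TE_{x,y}(t) = PLCV_target(t) - PLCV_nontarget(t)`, each PLCV computed
#' over its own trial set. Positive TE means the pair's joint phase
#' concentration is specifically tied to target stimuli; TE of a channel
#' with itself is identically zero (same source).
#'
#' @param phase_target,phase_nontarget `phase_tensor`s sharing channels and
#'   sample grid; trial counts may differ.
#' @param x,y channel indices.
#' @return a `pair_metric_series` with values in `[-1, 1]`.
#' @export
te <- function(phase_target, phase_nontarget, x, y) {
  check_that(identical(dim(phase_target$phi)[2:3], dim(phase_nontarget$phi)[2:3]),
             "target and nontarget tensors must share channels and samples")
  check_that(abs(phase_target$fs - phase_nontarget$fs) < 1e-9,
             "target and nontarget tensors must share the sampling rate")
  vt <- plcv(phase_target, x, y)$values
  vn <- plcv(phase_nontarget, x, y)$values
  pair_series("TE", c(check_channel(phase_target, x),
                      check_channel(phase_target, y)), vt - vn, phase_target)
}

#' Split a phase tensor by trial condition
#'
#' @param phase a `phase_tensor` whose `events` carry `is_target`.
#' @return list with elements `target` and `nontarget`.
#' @export
split_phase <- function(phase) {
  sel <- phase$events$is_target
  check_that(sum(sel) >= 1 && sum(!sel) >= 1,
             "need at least one target and one nontarget trial")
  sub <- function(keep) {
    out <- phase
    out$phi <- phase$phi[keep, , , drop = FALSE]
    if (!is.null(phase$amplitude))
      out$amplitude <- phase$amplitude[keep, , , drop = FALSE]
    out$events <- phase$events[keep, , drop = FALSE]
    out
  }
  list(target = sub(which(sel)), nontarget = sub(which(!sel)))
}

#' Phase tensor of a session at the phase-analysis rate
#'
#' Full chain: band-pass 0.1-40 Hz, decimate to `fs_phase`, extract padded
#' epochs, analytic signal, crop to the response window.
#'
#' @param session a [speller_session()].
#' @param fs_phase phase-analysis rate, Hz (default 200).
#' @param window_s response window, seconds (default 0.7).
#' @param pad_s Hilbert padding, seconds (default 1).
#' @return a cropped `phase_tensor`.
#' @export
session_phase <- function(session, fs_phase = 200, window_s = 0.7, pad_s = 1) {
  prep <- preprocess_session(session, target_fs = fs_phase)
  ep <- extract_epochs(prep, window_s = window_s, pad_s = pad_s)
  crop_phase(analytic_phase(ep))
}
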