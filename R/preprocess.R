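#' Zero-phase band-pass filter
#'
#' Band-pass via a cascade of a 2nd-order Butterworth high-pass (low edge)
#' and a 6th-order Butterworth low-pass (high edge), each applied
#' forward-backward (`filtfilt`). The cascade keeps the very low high-pass
#' edge (0.1 Hz at typical EEG rates) numerically stable, and zero-phase
#' filtering guarantees the filter adds no phase shift that would bias the
#' circular statistics downstream.
#'
#' @param x numeric matrix `[channels, samples]` or a vector.
#' @param fs sampling rate in Hz.
#' @param low_hz,high_hz band edges in Hz (defaults 0.1 and 40).
#' @return filtered signal, same shape as `x`.
#' @export
bandpass <- function(x, fs, low_hz = 0.1, high_hz = 40) {
  check_that(high_hz < fs / 2,
             "high_hz (%g) must be below the Nyquist rate (%g)", high_hz, fs / 2)
  check_that(low_hz > 0 && low_hz < high_hz, "need 0 < low_hz < high_hz")
  hp <- signal::butter(2, low_hz / (fs / 2), type = "high")
  lp <- signal::butter(6, high_hz / (fs / 2), type = "low")
  f1 <- function(v) filtfilt_pad(lp, filtfilt_pad(hp, v))
  if (is.matrix(x)) t(apply(x, 1, f1)) else f1(x)
}

# forward-backward filtering with odd-reflection end padding, which keeps
# start-up transients out of the returned samples
filtfilt_pad <- function(filt, v) {
  n <- length(v)
  p <- min(n - 1L, 3L * (max(length(filt$b), length(filt$a)) - 1L) * 4L)
  if (p < 1) return(signal::filtfilt(filt, v))
  head_pad <- 2 * v[1] - v[(p + 1):2]
  tail_pad <- 2 * v[n] - v[(n - 1):(n - p)]
  y <- signal::filtfilt(filt, c(head_pad, v, tail_pad))
  y[(p + 1):(p + n)]
}

#' Anti-aliased decimation
#'
#' Low-pass filters at 80% of the target Nyquist rate (8th-order Chebyshev
#' type I, 0.05 dB ripple, applied forward-backward so the operation is
#' zero-phase) and keeps every `fs/target_fs`-th sample.
#'
#' @param x numeric matrix `[channels, samples]` or a vector.
#' @param fs current sampling rate; must be an integer multiple of
#'   `target_fs`.
#' @param target_fs output sampling rate.
#' @return list with `x` (decimated signal) and `fs` (= `target_fs`).
#' @export
decimate_signal <- function(x, fs, target_fs) {
  q <- fs / target_fs
  check_that(abs(q - round(q)) < 1e-9,
             "fs (%g) must be an integer multiple of target_fs (%g)", fs, target_fs)
  q <- as.integer(round(q))
  if (q == 1L) return(list(x = x, fs = target_fs))
  cf <- signal::cheby1(8, 0.05, 0.8 / q, type = "low")
  cf$b <- cf$b / (sum(cf$b) / sum(cf$a))   # unit DC gain despite ripple
  f1 <- function(v) {
    y <- filtfilt_pad(cf, v)
    y[seq(1L, length(y), by = q)]
  }
  out <- if (is.matrix(x)) t(apply(x, 1, f1)) else f1(x)
  list(x = out, fs = target_fs)
}

#' Preprocess a session for phase analysis or classification
#'
#' Applies the standard chain: band-pass 0.1-40 Hz on the continuous
#' signals, then decimation to the requested rate (200 Hz for phase
#' measurement; a further stage to 20 Hz for classification features).
#'
#' @param session a [speller_session()].
#' @param target_fs output rate in Hz. When the session rate is not a
#'   multiple of `target_fs` but is a multiple of `200 * k`, decimation is
#'   staged through 200 Hz (the classification chain 1000 -> 200 -> 20 Hz).
#' @param low_hz,high_hz band-pass edges, see [bandpass()].
#' @return a new [speller_session()] with filtered, decimated signals.
#' @export
preprocess_session <- function(session, target_fs = 200,
                               low_hz = 0.1, high_hz = 40) {
  x <- bandpass(session$signals, session$fs, low_hz, high_hz)
  fs <- session$fs
  if (fs > 200 && target_fs < 200 && (fs / 200) %% 1 == 0) {
    d <- decimate_signal(x, fs, 200)
    x <- d$x; fs <- d$fs
  }
  d <- decimate_signal(x, fs, target_fs)
  speller_session(d$x, d$fs, session$events, session$montage,
                  session$target_characters, session$grid,
                  session$ground_truth)
}
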