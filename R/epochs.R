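#' Stimulus event table
#'
#' Validates a data frame of row/column intensification events. Columns:
#' `onset` (seconds from session start), `code` (integer 1-12: codes 1-6 are
#' rows, 7-12 are columns), `is_target` (logical), `block` (0-based character
#' block index), `repetition` (0-based repetition index within the block,
#' 0-14 in the standard paradigm).
#'
#' @param events data frame with the columns above.
#' @param duration_s optional recording duration; onsets must lie in
#'   `[0, duration_s)`.
#' @return the validated data frame (invisibly usable as-is).
#' @export
validate_events <- function(events, duration_s = NULL) {
  need <- c("onset", "code", "is_target", "block", "repetition")
  miss <- setdiff(need, names(events))
  check_that(length(miss) == 0, "event table missing columns: %s",
             paste(miss, collapse = ", "))
  check_that(all(events$code %in% 1:12), "stimulus codes must be in 1..12")
  check_that(is.logical(events$is_target) || all(events$is_target %in% 0:1),
             "is_target must be logical or 0/1")
  events$is_target <- as.logical(events$is_target)
  check_that(all(events$block >= 0) && all(events$repetition >= 0),
             "block and repetition indices are 0-based and non-negative")
  if (!is.null(duration_s)) {
    bad <- which(events$onset < 0 | events$onset >= duration_s)
    check_that(length(bad) == 0,
               "event %d onset %.3f s lies outside the recording (0..%.3f s)",
               if (length(bad)) bad[1] else 0L,
               if (length(bad)) events$onset[bad[1]] else 0, duration_s)
  }
  # onsets strictly increasing within each block
  for (b in unique(events$block)) {
    o <- events$onset[events$block == b]
    check_that(all(diff(o) > 0), "onsets not strictly increasing in block %d", b)
  }
  events
}

#' Epoched EEG container
#'
#' The unit all phase statistics and classifiers consume: a real tensor of
#' stimulus-locked responses with per-trial event metadata.
#'
#' @param data numeric array `[trials, channels, samples]`, in microvolts.
#' @param fs sampling rate in Hz.
#' @param events one row per trial, see [validate_events()].
#' @param montage a [montage()]; `dim(data)[2]` must equal its length.
#' @param t0 time of the first sample relative to stimulus onset, seconds.
#'   Negative when epochs carry padding for analytic-signal estimation.
#' @param window_s length of the nominal response window, seconds (0.7 in
#'   the standard paradigm). The padded tensor may be longer; phase metrics
#'   crop back to `[0, window_s)`.
#' @return an object of class `"epoch_set"`.
#' @export
epoch_set <- function(data, fs, events, montage, t0 = 0, window_s = NULL) {
  check_that(length(dim(data)) == 3, "data must be a 3-d array [trials, channels, samples]")
  events <- validate_events(events)
  check_that(dim(data)[1] == nrow(events),
             "trials (%d) must match events rows (%d)", dim(data)[1], nrow(events))
  check_that(dim(data)[2] == length(montage$labels),
             "channels (%d) must match montage length (%d)",
             dim(data)[2], length(montage$labels))
  if (is.null(window_s)) window_s <- dim(data)[3] / fs + t0
  structure(list(data = data, fs = fs, t0 = t0, window_s = window_s,
                 events = events, montage = montage),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz (%d target)\n",
              d[1], d[2], d[3], x$fs, sum(x$events$is_target)))
  invisible(x)
}

#' Speller session container
#'
#' A full paradigm record: continuous signals, the stimulus schedule, the
#' intended characters and the 6x6 grid. Produced by [simulate_session()] or
#' ingested from files via [read_session()].
#'
#' @param signals numeric matrix `[channels, samples]` (microvolts).
#' @param fs sampling rate, Hz.
#' @param events stimulus schedule, see [validate_events()].
#' @param montage a [montage()].
#' @param target_characters character vector, one intended character per block.
#' @param grid the character matrix (6x6 by default, see [speller_grid()]).
#' @param ground_truth optional simulator annotations (relevant channels,
#'   source mixing); `NULL` for ingested recordings.
#' @return an object of class `"speller_session"`.
#' @export
speller_session <- function(signals, fs, events, montage, target_characters,
                            grid = speller_grid(), ground_truth = NULL) {
  signals <- as.matrix(signals)
  check_that(nrow(signals) == length(montage$labels),
             "signals rows (%d) must match montage length (%d)",
             nrow(signals), length(montage$labels))
  events <- validate_events(events, duration_s = ncol(signals) / fs)
  n_blocks <- length(unique(events$block))
  check_that(length(target_characters) == n_blocks,
             "need one target character per block (%d blocks, %d characters)",
             n_blocks, length(target_characters))
  structure(list(signals = signals, fs = fs, events = events,
                 montage = montage, target_characters = target_characters,
                 grid = grid, ground_truth = ground_truth),
            class = "speller_session")
}

#' @export
print.speller_session <- function(x, ...) {
  cat(sprintf("<speller_session> %d channels, %.1f s @ %g Hz, %d blocks, %d events\n",
              nrow(x$signals), ncol(x$signals) / x$fs,
              x$fs, length(unique(x$events$block)), nrow(x$events)))
  invisible(x)
}

#' Default 6x6 character grid
#'
#' Rows and columns of the Farwell-Donchin matrix. Code `r` (1-6) flashes
#' row `r`; code `6 + c` flashes column `c`; the attended character is the
#' intersection cell.
#'
#' @return a 6x6 character matrix (A-Z then 0-9, filled row-wise).
#' @export
speller_grid <- function() {
  matrix(c(LETTERS, as.character(0:9)), nrow = 6, ncol = 6, byrow = TRUE)
}

#' Locate a character on the grid
#'
#' @param ch single character present in `grid`.
#' @param grid character matrix.
#' @return integer vector `c(row_code, col_code)` with `row_code` in 1..6
#'   and `col_code` in 7..12.
#' @export
grid_codes <- function(ch, grid = speller_grid()) {
  idx <- which(grid == ch, arr.ind = TRUE)
  check_that(nrow(idx) == 1, "character '%s' not on the grid", ch)
  c(row_code = idx[1, "row"], col_code = 6L + idx[1, "col"])
}

#' Extract stimulus-locked epochs from a session
#'
#' Cuts one window per stimulus event from the continuous signals. Windows
#' overlap freely (the 175 ms stimulus-onset asynchrony is shorter than the
#' 700 ms response window). With `pad_s > 0` each epoch carries symmetric
#' padding so the analytic signal can be computed away from window edges and
#' cropped afterwards; `t0` of the result is then `-pad_s`.
#'
#' @param session a [speller_session()] with continuous signals.
#' @param window_s response window length in seconds (default 0.7).
#' @param pad_s symmetric padding in seconds (default 0).
#' @return an [epoch_set()] with `trials = nrow(session$events)`.
#' @export
extract_epochs <- function(session, window_s = 0.7, pad_s = 0) {
  check_that(inherits(session, "speller_session"), "session must be a speller_session")
  fs <- session$fs
  n_samp <- ncol(session$signals)
  ev <- session$events
  n_win <- round((window_s + 2 * pad_s) * fs)
  start <- round((ev$onset - pad_s) * fs) + 1L
  stop_ <- start + n_win - 1L
  bad <- which(start < 1L | stop_ > n_samp)
  if (length(bad)) {
    stop(sprintf(
      "epoch window for event %d (onset %.3f s, code %d) exceeds the recording",
      bad[1], ev$onset[bad[1]], ev$code[bad[1]]), call. = FALSE)
  }
  n_tr <- nrow(ev)
  n_ch <- nrow(session$signals)
  data <- array(0, dim = c(n_tr, n_ch, n_win))
  for (i in seq_len(n_tr)) {
    data[i, , ] <- session$signals[, start[i]:stop_[i]]
  }
  epoch_set(data, fs, ev, session$montage, t0 = -pad_s, window_s = window_s)
}
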