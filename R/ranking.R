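#' Target-effect series for all channel pairs
#'
#' Computes `TE_{x,y}(t)` for every unordered channel pair in one pass over
#' unit-modulus complex phases. Pairwise TE does not depend on which other
#' channels are present, so this is computed once and subset during the
#' recursive elimination.
#'
#' @param phase_target,phase_nontarget `phase_tensor`s split by condition
#'   (see [split_phase()]).
#' @return numeric array `[n, n, samples]`; `[x, y, ]` equals `[y, x, ]` and
#'   the diagonal is identically zero.
#' @export
te_all_pairs <- function(phase_target, phase_nontarget) {
  check_that(identical(dim(phase_target$phi)[2:3], dim(phase_nontarget$phi)[2:3]),
             "target and nontarget tensors must share channels and samples")
  n <- dim(phase_target$phi)[2]
  ns <- dim(phase_target$phi)[3]
  Et <- exp(1i * phase_target$phi)
  En <- exp(1i * phase_nontarget$phi)
  out <- array(0, dim = c(n, n, ns))
  for (x in seq_len(n - 1)) {
    ex_t <- Et[, x, , drop = TRUE]; ex_n <- En[, x, , drop = TRUE]
    if (is.null(dim(ex_t))) { ex_t <- matrix(ex_t, nrow = 1); ex_n <- matrix(ex_n, nrow = 1) }
    for (y in (x + 1):n) {
      ey_t <- Et[, y, , drop = TRUE]; ey_n <- En[, y, , drop = TRUE]
      if (is.null(dim(ey_t))) { ey_t <- matrix(ey_t, nrow = 1); ey_n <- matrix(ey_n, nrow = 1) }
      plcv_t <- Mod(colMeans(ex_t * ey_t)) * (1 - Mod(colMeans(ex_t * Conj(ey_t))))
      plcv_n <- Mod(colMeans(ex_n * ey_n)) * (1 - Mod(colMeans(ex_n * Conj(ey_n))))
      v <- plcv_t - plcv_n
      out[x, y, ] <- v
      out[y, x, ] <- v
    }
  }
  out
}

#' Similarity matrix from time-varying target effects
#'
#' TE varies over the response window; the similarity between channels `x`
#' and `y` is its maximum over a post-stimulus time window:
#' `S[x, y] = max_{t in window} TE_{x,y}(t)`, with `S[x, x] = 0`.
#'
#' @param te_array `[n, n, samples]` array from [te_all_pairs()].
#' @param fs sampling rate of the TE series, Hz.
#' @param t0 time of the first TE sample relative to stimulus onset, s.
#' @param window `c(start_s, end_s)`; default the full series.
#' @param labels optional channel labels.
#' @return object of class `"similarity_matrix"`: list with `S` (symmetric,
#'   zero diagonal), `window`, `labels`.
#' @export
similarity_matrix <- function(te_array, fs, t0 = 0, window = NULL,
                              labels = NULL) {
  ns <- dim(te_array)[3]
  t <- t0 + (seq_len(ns) - 1L) / fs
  if (is.null(window)) window <- c(t[1], t[ns] + 1 / fs)
  keep <- which(t >= window[1] - 1e-9 & t < window[2] - 1e-9)
  check_that(length(keep) > 0, "empty similarity window [%g, %g]",
             window[1], window[2])
  S <- apply(te_array[, , keep, drop = FALSE], c(1, 2), max)
  diag(S) <- 0
  if (!is.null(labels)) dimnames(S) <- list(labels, labels)
  structure(list(S = S, window = window, labels = labels),
            class = "similarity_matrix")
}

#' Task relativity value
#'
#' For a surviving channel `x`, the mean similarity to the `k - 1` other
#' surviving channels: `TRV_x = (1/(k-1)) sum_{y in SC, y != x} S[x, y]`.
#' `k` decreases along the recursion (initially the channel count), so TRV
#' is always an average over the current survivor set. A channel whose
#' pairwise target effects are high scores high; a redundant duplicate
#' (near-zero S row) scores low.
#'
#' @param S numeric similarity matrix (full montage indexing) or a
#'   `"similarity_matrix"` object.
#' @param x channel index, must be a member of `sc`.
#' @param sc integer vector of surviving channel indices (default: all).
#' @return scalar TRV.
#' @export
trv <- function(S, x, sc = NULL) {
  if (inherits(S, "similarity_matrix")) S <- S$S
  if (is.null(sc)) sc <- seq_len(nrow(S))
  check_that(x %in% sc, "channel %d is not in the surviving set", x)
  check_that(length(sc) >= 2, "need at least 2 surviving channels")
  partners <- setdiff(sc, x)
  mean(S[x, partners])
}

# minimum-entry pair of a symmetric matrix, lexicographic tie-break
min_pair <- function(S) {
  n <- nrow(S)
  best <- c(NA_integer_, NA_integer_); bv <- Inf
  for (x in seq_len(n - 1)) {
    for (y in (x + 1):n) {
      if (S[x, y] < bv - 1e-15) { bv <- S[x, y]; best <- c(x, y) }
    }
  }
  list(pair = best, value = bv)
}

#' Recursive feature elimination on a similarity matrix
#'
#' One full PLCV-RFE recursion given a precomputed similarity matrix.
#' Each iteration: (1) build a single-linkage hierarchy Z over the
#' surviving channels, treating S as a distance so the lowest-similarity
#' (most redundant) pair merges first; (2) cut Z into `k - 1` classes --
#' exactly one class has two members, and it is the global minimum-S couple
#' `C = [p, q]`; (3) compute the TRV of `p` and `q` over the survivors and
#' eliminate the lower-TRV member (ties: eliminate the lower montage
#' index), prepending it to the rank list. An earlier-eliminated channel
#' therefore ranks lower; the last survivor ranks first.
#'
#' @param S `"similarity_matrix"` object or plain symmetric matrix.
#' @param labels channel labels (defaults to those stored in `S`).
#' @param recompute optional function `f(sc) -> matrix` returning a freshly
#'   computed similarity matrix over the surviving subset `sc` (full-montage
#'   indexing). Since pairwise TE is independent of the other channels this
#'   must equal plain subsetting; the hook exists as a fidelity check.
#' @return list with `rank` (labels, most important first), `rank_index`
#'   (montage indices) and `log` (one row per elimination step: `iteration`,
#'   `k`, `eliminated`, `couple_p`, `couple_q`, `trv_p`, `trv_q`, `min_s`,
#'   `cluster_agrees`).
#' @export
plcv_rfe <- function(S, labels = NULL, recompute = NULL) {
  if (inherits(S, "similarity_matrix")) {
    if (is.null(labels)) labels <- S$labels
    S <- S$S
  }
  n <- nrow(S)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  check_that(n >= 2, "need at least 2 channels to rank")
  sc <- seq_len(n)
  rank_index <- integer(0)
  log_rows <- vector("list", n)
  it <- 0L
  while (length(sc) > 1) {
    it <- it + 1L
    k <- length(sc)
    Ssub <- if (is.null(recompute)) S[sc, sc, drop = FALSE] else {
      full <- recompute(sc)
      full[sc, sc, drop = FALSE]
    }
    # hierarchy over survivors; shift to non-negative values, which leaves
    # single-linkage merge order unchanged
    Z <- stats::hclust(stats::as.dist(Ssub - min(Ssub)), method = "single")
    cl <- stats::cutree(Z, k = k - 1L)
    sizes <- table(cl)
    two <- as.integer(names(sizes)[sizes == 2])
    couple_tree <- if (length(two) == 1) unname(sort(which(cl == two[1]))) else NULL
    mp <- min_pair(Ssub)
    cluster_agrees <- !is.null(couple_tree) &&
      identical(as.integer(couple_tree), as.integer(sort(mp$pair)))
    p <- sc[mp$pair[1]]; q <- sc[mp$pair[2]]
    trv_p <- trv(S, p, sc); trv_q <- trv(S, q, sc)
    w <- if (trv_p < trv_q - 1e-15) p else if (trv_q < trv_p - 1e-15) q else min(p, q)
    rank_index <- c(w, rank_index)
    log_rows[[it]] <- data.frame(
      iteration = it, k = k, eliminated = labels[w],
      couple_p = labels[p], couple_q = labels[q],
      trv_p = trv_p, trv_q = trv_q, min_s = mp$value,
      cluster_agrees = cluster_agrees, stringsAsFactors = FALSE)
    sc <- setdiff(sc, w)
  }
  # degenerate single survivor: no clustering, it simply heads the list
  it <- it + 1L
  rank_index <- c(sc, rank_index)
  log_rows[[it]] <- data.frame(
    iteration = it, k = 1L, eliminated = labels[sc],
    couple_p = NA_character_, couple_q = NA_character_,
    trv_p = NA_real_, trv_q = NA_real_, min_s = NA_real_,
    cluster_agrees = NA, stringsAsFactors = FALSE)
  list(rank = labels[rank_index], rank_index = rank_index,
       log = do.call(rbind, log_rows))
}

#' PLCV-RFE channel ranking from epoched data
#'
#' Computes per-trial instantaneous phase, splits trials by condition,
#' builds the all-pairs TE similarity matrix over a post-stimulus window
#' and runs the recursive elimination.
#'
#' @param epochs an [epoch_set()] at the phase-analysis rate whose events
#'   carry `is_target`; epochs extracted with padding are cropped to the
#'   response window after the analytic signal is taken.
#' @param window similarity window `c(start_s, end_s)` (default the full
#'   0-0.7 s response window).
#' @param recompute_similarity recompute the similarity matrix from phases
#'   on each surviving subset instead of subsetting the initial matrix
#'   (numerically identical; fidelity check).
#' @return as [plcv_rfe()], plus `S` (the initial `"similarity_matrix"`).
#' @export
plcv_rfe_rank <- function(epochs, window = NULL, recompute_similarity = FALSE) {
  check_that(inherits(epochs, "epoch_set"), "epochs must be an epoch_set")
  check_that(dim(epochs$data)[2] >= 2, "need at least 2 channels to rank")
  n_t <- sum(epochs$events$is_target)
  check_that(n_t >= 1 && n_t < nrow(epochs$events),
             "need at least one target and one nontarget trial")
  ph <- analytic_phase(epochs)
  if (ph$t0 < 0) ph <- crop_phase(ph)
  if (is.null(window)) window <- c(ph$t0, ph$t0 + dim(ph$phi)[3] / ph$fs)
  parts <- split_phase(ph)
  te_arr <- te_all_pairs(parts$target, parts$nontarget)
  S <- similarity_matrix(te_arr, fs = ph$fs, t0 = ph$t0, window = window,
                         labels = epochs$montage$labels)
  recompute <- NULL
  if (recompute_similarity) {
    recompute <- function(sc) {
      sub <- function(p) { p$phi <- p$phi[, sc, , drop = FALSE]; p }
      te_sub <- te_all_pairs(sub(parts$target), sub(parts$nontarget))
      full <- matrix(0, dim(ph$phi)[2], dim(ph$phi)[2])
      full[sc, sc] <- similarity_matrix(te_sub, fs = ph$fs, t0 = ph$t0,
                                        window = window)$S
      full
    }
  }
  res <- plcv_rfe(S$S, labels = epochs$montage$labels, recompute = recompute)
  res$S <- S
  res
}

#' Rank channels of a speller session
#'
#' Full pipeline: band-pass, decimate to the phase rate, padded epoch
#' extraction, analytic phase, all-pairs TE, recursive elimination.
#'
#' @param session a [speller_session()].
#' @param window similarity window `c(start_s, end_s)` (default 0-0.7 s).
#' @param fs_phase phase-analysis rate, Hz.
#' @param window_s response window length, s.
#' @param pad_s Hilbert padding, s.
#' @param recompute_similarity see [plcv_rfe_rank()].
#' @return as [plcv_rfe_rank()].
#' @export
rank_channels <- function(session, window = NULL, fs_phase = 200,
                          window_s = 0.7, pad_s = 1,
                          recompute_similarity = FALSE) {
  prep <- preprocess_session(session, target_fs = fs_phase)
  ep <- extract_epochs(prep, window_s = window_s, pad_s = pad_s)
  plcv_rfe_rank(ep, window = window,
                recompute_similarity = recompute_similarity)
}

#' Aggregate rank lists into per-channel weights
#'
#' Within each list, channels are scored by rank position (best = highest),
#' standardized to zero mean and unit variance (z-scores), then averaged
#' across lists. Higher weight = more important.
#'
#' @param rank_lists list of character vectors, each a permutation of the
#'   same channel labels, best-ranked first.
#' @return data frame with columns `label` and `weight`, sorted by
#'   decreasing weight.
#' @export
aggregate_channel_weights <- function(rank_lists) {
  check_that(length(rank_lists) >= 1, "need at least one rank list")
  ref <- sort(rank_lists[[1]])
  zmat <- vapply(rank_lists, function(r) {
    check_that(identical(sort(r), ref),
               "all rank lists must be permutations of the same montage")
    k <- length(r)
    score <- numeric(k)
    score[match(r, ref)] <- k:1          # best-ranked channel scores highest
    as.numeric(scale(score))
  }, numeric(length(ref)))
  w <- rowMeans(zmat)
  out <- data.frame(label = ref, weight = w, stringsAsFactors = FALSE)
  out <- out[order(-out$weight), , drop = FALSE]
  rownames(out) <- NULL
  out
}
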