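#' Decode one spelled character from discriminant scores
#'
#' Scores are summed per stimulus code over the first `n_reps` repetitions
#' of a block; the decoded character is the grid cell at the intersection
#' of the argmax row (codes 1-6) and argmax column (codes 7-12). Ties are
#' broken toward the lowest code index.
#'
#' @param scores per-trial discriminant scores for one block.
#' @param codes stimulus code (1-12) per trial.
#' @param repetitions 0-based repetition index per trial.
#' @param n_reps number of repetitions to use (1-15).
#' @param grid character matrix, see [speller_grid()].
#' @return single decoded character.
#' @export
decode_character <- function(scores, codes, repetitions, n_reps,
                             grid = speller_grid()) {
  keep <- repetitions < n_reps
  check_that(any(keep), "no trials within the first %d repetitions", n_reps)
  codes <- codes[keep]; scores <- scores[keep]; reps <- repetitions[keep]
  for (r in unique(reps)) {
    miss <- setdiff(1:12, codes[reps == r])
    check_that(length(miss) == 0, "repetition %d is missing code(s) %s",
               r, paste(miss, collapse = ","))
  }
  sums <- vapply(1:12, function(k) sum(scores[codes == k]), 0)
  row <- which.max(sums[1:6])            # which.max takes the first maximum
  col <- which.max(sums[7:12])
  grid[row, col]
}

#' Character-recognition-error curve over channel subsets and repetitions
#'
#' For each channel-subset size `n` (the top `n` of the rank list) and each
#' repetition count, an FLDA is trained on the training epochs restricted
#' to those channels and every test block is decoded; the entry is the
#' fraction of wrongly decoded characters.
#'
#' @param train,test outputs of [classification_features()] for the
#'   training and test halves.
#' @param rank_index channel indices (montage order), best-ranked first.
#' @param truth true character per test block, in block order.
#' @param n_channels_grid subset sizes to evaluate (default `1:n`).
#' @param reps repetition counts to evaluate (default `1:15`).
#' @param grid character matrix.
#' @return object of class `"cre_curve"`: matrix
#'   `[length(n_channels_grid), length(reps)]` with dimnames, values in
#'   `[0, 1]`.
#' @export
cre_curve <- function(train, test, rank_index, truth,
                      n_channels_grid = NULL, reps = 1:15,
                      grid = speller_grid()) {
  n_ch <- length(train$montage$labels)
  check_that(length(rank_index) == n_ch && setequal(rank_index, seq_len(n_ch)),
             "rank_index must be a permutation of 1..%d", n_ch)
  if (is.null(n_channels_grid)) n_channels_grid <- seq_len(n_ch)
  blocks <- sort(unique(test$events$block))
  check_that(length(blocks) >= 1, "empty test set")
  check_that(length(truth) == length(blocks),
             "need one true character per test block (%d blocks, %d given)",
             length(blocks), length(truth))
  cre <- matrix(NA_real_, length(n_channels_grid), length(reps),
                dimnames = list(n_channels = n_channels_grid, reps = reps))
  block_rows <- lapply(blocks, function(b) which(test$events$block == b))
  for (i in seq_along(n_channels_grid)) {
    chans <- rank_index[seq_len(n_channels_grid[i])]
    cols <- feature_columns(chans, train$n_samples)
    model <- flda_train(train$features[, cols, drop = FALSE],
                        train$events$is_target)
    scores <- predict(model, test$features[, cols, drop = FALSE])
    for (j in seq_along(reps)) {
      decoded <- vapply(seq_along(blocks), function(bi) {
        rows <- block_rows[[bi]]
        decode_character(scores[rows], test$events$code[rows],
                         test$events$repetition[rows], reps[j], grid)
      }, "")
      cre[i, j] <- mean(decoded != truth)
    }
  }
  structure(cre, class = c("cre_curve", "matrix"))
}

#' @export
print.cre_curve <- function(x, ...) {
  cat(sprintf("<cre_curve> %d channel subsets x %d repetition counts; min CRE %.3f\n",
              nrow(x), ncol(x), min(x)))
  invisible(x)
}

#' Optimal channel subset
#'
#' The smallest subset size attaining the minimum character recognition
#' error at a given repetition count: least test error with the least
#' number of channels.
#'
#' @param curve a [cre_curve()].
#' @param n_reps repetition count (must be a column of the curve).
#' @return list with `size` (subset size) and `cre` (error there).
#' @export
ocs <- function(curve, n_reps) {
  j <- match(as.character(n_reps), colnames(curve))
  check_that(!is.na(j), "repetition count %s not in the curve", n_reps)
  col <- curve[, j]
  i <- which(col <= min(col) + 1e-12)[1]
  list(size = as.integer(rownames(curve)[i]), cre = unname(col[i]))
}

#' Evaluate a channel ranking on a session
#'
#' Splits blocks into train/test halves (ranking and training on the first
#' part, errors on the second), builds 20 Hz features and computes the CRE
#' curve plus the OCS per repetition count.
#'
#' @param session a [speller_session()] with known `target_characters`.
#' @param rank channel rank: labels or montage indices, best first.
#' @param split fraction of blocks used for training (default 0.5, the
#'   first-half/second-half protocol).
#' @param reps repetition counts (default `1:15`, capped at the session's
#'   repetition count).
#' @param n_channels_grid subset sizes (default all).
#' @return list with `curve` (a [cre_curve()]) and `ocs` (data frame:
#'   `reps`, `ocs_size`, `cre`).
#' @export
evaluate_channels <- function(session, rank, split = 0.5, reps = NULL,
                              n_channels_grid = NULL) {
  labels <- session$montage$labels
  if (is.character(rank)) {
    check_that(setequal(rank, labels), "rank labels do not match the montage")
    rank_index <- match(rank, labels)
  } else rank_index <- as.integer(rank)
  max_rep <- max(session$events$repetition) + 1L
  if (is.null(reps)) reps <- seq_len(min(15L, max_rep))
  blocks <- sort(unique(session$events$block))
  n_train <- max(1L, floor(length(blocks) * split))
  check_that(n_train < length(blocks), "split leaves no test blocks")
  train_blocks <- blocks[seq_len(n_train)]
  feat <- classification_features(session)
  in_train <- feat$events$block %in% train_blocks
  subset_feat <- function(keep) {
    list(features = feat$features[keep, , drop = FALSE],
         events = feat$events[keep, , drop = FALSE],
         montage = feat$montage, n_samples = feat$n_samples)
  }
  test_blocks <- setdiff(blocks, train_blocks)
  truth <- session$target_characters[match(test_blocks, blocks)]
  curve <- cre_curve(subset_feat(in_train), subset_feat(!in_train),
                     rank_index, truth, n_channels_grid, reps, session$grid)
  ocs_df <- do.call(rbind, lapply(seq_along(reps), function(j) {
    o <- ocs(curve, reps[j])
    data.frame(reps = reps[j], ocs_size = o$size, cre = o$cre)
  }))
  list(curve = curve, ocs = ocs_df)
}

#' Export a CRE curve as TSV
#'
#' @param curve a [cre_curve()].
#' @param path output path; rows = channel subset sizes, columns =
#'   repetition counts.
#' @return `path`, invisibly.
#' @export
write_cre_curve <- function(curve, path) {
  df <- data.frame(n_channels = rownames(curve),
                   unclass(curve)[, , drop = FALSE], check.names = FALSE)
  names(df)[-1] <- paste0("rep", colnames(curve))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
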