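#' Fisher's linear discriminant for target/non-target responses
#'
#' Binary FLDA: `w = (Sw + lambda I)^{-1} (mu_target - mu_nontarget)` with
#' pooled within-class covariance `Sw` and a small additive ridge
#' `lambda = shrinkage * trace(Sw) / d`. Feature dimension in the speller
#' (14 samples x channels, up to 448) is near the trial count, so the
#' pooled covariance is near-singular without the ridge. The bias places
#' the decision threshold midway between class means; higher scores are
#' more target-like.
#'
#' @param features numeric matrix `[trials, d]` of classification features
#'   (concatenated 20 Hz samples per channel, montage order).
#' @param labels logical (or 0/1) vector: `TRUE` = target.
#' @param shrinkage relative ridge weight (default `1e-6`).
#' @return object of class `"flda"`: list with `w`, `b`, `lambda`.
#' @export
flda_train <- function(features, labels, shrinkage = 1e-6) {
  features <- as.matrix(features)
  labels <- as.logical(labels)
  check_that(any(labels) && any(!labels), "both classes must be present")
  d <- ncol(features)
  check_that(d >= 1, "need at least one feature")
  x1 <- features[labels, , drop = FALSE]
  x0 <- features[!labels, , drop = FALSE]
  mu1 <- colMeans(x1); mu0 <- colMeans(x0)
  c1 <- sweep(x1, 2, mu1); c0 <- sweep(x0, 2, mu0)
  n <- nrow(features)
  Sw <- (crossprod(c1) + crossprod(c0)) / max(n - 2, 1)
  lambda <- shrinkage * sum(diag(Sw)) / d
  if (lambda <= 0) lambda <- shrinkage    # all-constant features fallback
  w <- solve(Sw + diag(lambda, d), mu1 - mu0)
  b <- -sum(w * (mu1 + mu0)) / 2
  structure(list(w = as.numeric(w), b = b, lambda = lambda), class = "flda")
}

#' @export
print.flda <- function(x, ...) {
  cat(sprintf("<flda> %d features, |w| = %.4g, b = %.4g\n",
              length(x$w), sqrt(sum(x$w^2)), x$b))
  invisible(x)
}

#' Discriminant scores
#'
#' @param object an `"flda"` model.
#' @param newdata feature matrix `[trials, d]`.
#' @param ... unused.
#' @return numeric score per trial; higher = more target-like.
#' @export
predict.flda <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata) %*% object$w + object$b)
}

#' Classification features of a session
#'
#' Band-pass 0.1-40 Hz, decimate in two stages to 20 Hz, extract 0.7 s
#' epochs (14 samples per channel) and flatten each trial to a feature
#' vector in montage order (channel 1 samples, channel 2 samples, ...).
#'
#' @param session a [speller_session()].
#' @param fs_feat classification rate, Hz (default 20).
#' @param window_s response window, s (default 0.7).
#' @return list with `features` `[trials, channels * samples]`, `events`,
#'   `montage`, `n_samples` (samples per channel).
#' @export
classification_features <- function(session, fs_feat = 20, window_s = 0.7) {
  prep <- preprocess_session(session, target_fs = fs_feat)
  ep <- extract_epochs(prep, window_s = window_s)
  d <- dim(ep$data)
  feats <- matrix(0, d[1], d[2] * d[3])
  for (ch in seq_len(d[2])) {
    feats[, ((ch - 1) * d[3] + 1):(ch * d[3])] <- ep$data[, ch, ]
  }
  list(features = feats, events = ep$events, montage = ep$montage,
       n_samples = d[3])
}

# column indices of the feature blocks for a channel subset
feature_columns <- function(channels, n_samples) {
  unlist(lapply(channels, function(ch) ((ch - 1) * n_samples + 1):(ch * n_samples)))
}
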