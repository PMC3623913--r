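test_that("FLDA recovers closed-form discriminant directions", {
  # 1-D classes, means 0 and 1, equal variance: w proportional to +1
  set.seed(30)
  x <- matrix(c(rnorm(200, 0, 1), rnorm(200, 1, 1)), ncol = 1)
  y <- rep(c(FALSE, TRUE), each = 200)
  m <- flda_train(x, y)
  expect_gt(m$w[1], 0)
  expect_equal(m$w[1] * 1, m$w[1])        # 1-D: direction is the sign
  # 2-D Gaussian toy: w parallel to Sw^{-1} (mu1 - mu0)
  n <- 500
  A <- matrix(c(1, 0.6, 0, 0.8), 2, 2)
  x0 <- matrix(rnorm(2 * n), ncol = 2) %*% A
  x1 <- sweep(matrix(rnorm(2 * n), ncol = 2) %*% A, 2, c(1.0, 0.5), "+")
  X <- rbind(x0, x1); y2 <- rep(c(FALSE, TRUE), each = n)
  m2 <- flda_train(X, y2)
  mu0 <- colMeans(x0); mu1 <- colMeans(x1)
  c0 <- sweep(x0, 2, mu0); c1 <- sweep(x1, 2, mu1)
  Sw <- (crossprod(c0) + crossprod(c1)) / (2 * n - 2)
  w_ref <- solve(Sw, mu1 - mu0)
  cosine <- sum(m2$w * w_ref) / sqrt(sum(m2$w^2) * sum(w_ref^2))
  expect_gte(cosine, 0.999)
})

test_that("FLDA agrees with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(31)
  X <- matrix(rnorm(300 * 4), ncol = 4)
  y <- X[, 1] + 0.5 * X[, 3] + rnorm(300) > 0
  m <- flda_train(X, y)
  ld <- MASS::lda(X, grouping = y)$scaling[, 1]
  cosine <- abs(sum(m$w * ld)) / sqrt(sum(m$w^2) * sum(ld^2))
  expect_gte(cosine, 0.999)
})

test_that("FLDA separates a linearly separable toy perfectly", {
  set.seed(32)
  X <- rbind(matrix(rnorm(100, 0, 0.1), ncol = 2),
             matrix(rnorm(100, 3, 0.1), ncol = 2))
  y <- rep(c(FALSE, TRUE), each = 50)
  m <- flda_train(X, y)
  expect_identical(predict(m, X) > 0, y)
  expect_error(flda_train(X, rep(TRUE, 100)), "both classes")
})

test_that("character decoding follows summed scores and tie rules", {
  g <- speller_grid()
  # one block of 15 repetitions with a known target
  codes <- unlist(lapply(1:15, function(r) sample(12)))
  reps <- rep(0:14, each = 12)
  target <- grid_codes("K", g)
  oracle_scores <- as.numeric(codes %in% target)
  expect_identical(decode_character(oracle_scores, codes, reps, 15, g), "K")
  expect_identical(decode_character(oracle_scores, codes, reps, 1, g), "K")
  # all-equal scores: lowest row and column codes win -> cell (1, 1)
  expect_identical(decode_character(rep(0, length(codes)), codes, reps, 15, g),
                   g[1, 1])
  # noisy scores match an exhaustive per-code argmax oracle
  set.seed(33)
  noisy <- rnorm(length(codes))
  sums <- sapply(1:12, function(k) sum(noisy[codes == k & reps < 8]))
  expected <- g[which.max(sums[1:6]), which.max(sums[7:12])]
  expect_identical(decode_character(noisy, codes, reps, 8, g), expected)
  # a repetition missing a code is rejected
  expect_error(decode_character(noisy[-1], codes[-1], reps[-1], 15, g),
               "missing code")
})

test_that("chance-level scores decode at ~ 1/36 accuracy", {
  set.seed(34)
  g <- speller_grid()
  n_blocks <- 360
  wrong <- 0
  for (b in seq_len(n_blocks)) {
    codes <- unlist(lapply(1:5, function(r) sample(12)))
    reps <- rep(0:4, each = 12)
    decoded <- decode_character(rnorm(60), codes, reps, 5, g)
    if (decoded != "A") wrong <- wrong + 1
  }
  expect_equal(wrong / n_blocks, 35 / 36, tolerance = 0.04)
})

# build feature lists for cre_curve directly: target trials carry a bump on
# every channel, scaled so the classes are trivially separable
perfect_features <- function(n_blocks, n_ch = 3, n_samp = 4, sep = 10,
                             seed = 40, grid = speller_grid()) {
  set.seed(seed)
  truth <- sample(as.vector(grid), n_blocks, replace = TRUE)
  ev_list <- lapply(seq_len(n_blocks), function(b) {
    codes <- unlist(lapply(1:5, function(r) sample(12)))
    tc <- grid_codes(truth[b], grid)
    data.frame(onset = 0, code = codes, is_target = codes %in% tc,
               block = b - 1L, repetition = rep(0:4, each = 12))
  })
  ev <- do.call(rbind, ev_list)
  ev$onset <- seq_len(nrow(ev))            # keep onsets increasing
  feats <- matrix(rnorm(nrow(ev) * n_ch * n_samp, sd = 0.1),
                  nrow(ev), n_ch * n_samp)
  feats[ev$is_target, ] <- feats[ev$is_target, ] + sep
  m <- default_montage(n_ch)
  list(data = list(features = feats, events = ev, montage = m,
                   n_samples = n_samp),
       truth = truth)
}

test_that("CRE is zero under perfect separation and reproducible", {
  tr <- perfect_features(6, seed = 41)
  te_ <- perfect_features(6, seed = 42)
  curve <- cre_curve(tr$data, te_$data, rank_index = 1:3, truth = te_$truth,
                     reps = 1:5)
  expect_true(all(curve == 0))
  expect_equal(dim(curve), c(3, 5))
  curve2 <- cre_curve(tr$data, te_$data, rank_index = 1:3, truth = te_$truth,
                      reps = 1:5)
  expect_identical(unclass(curve), unclass(curve2))  # deterministic
})

test_that("an uninformative extra channel leaves decoding unchanged", {
  tr <- perfect_features(4, n_ch = 2, seed = 43)
  te_ <- perfect_features(4, n_ch = 2, seed = 44)
  # zero out channel 2 everywhere: its FLDA weights stay ~0
  cols <- 5:8
  tr$data$features[, cols] <- 0
  te_$data$features[, cols] <- 0
  c1 <- cre_curve(tr$data, te_$data, 1:2, te_$truth, n_channels_grid = 1, reps = 1:3)
  c2 <- cre_curve(tr$data, te_$data, 1:2, te_$truth, n_channels_grid = 2, reps = 1:3)
  expect_equal(unname(unclass(c1)[1, ]), unname(unclass(c2)[1, ]))
})

test_that("OCS picks the smallest subset attaining the minimum error", {
  curve <- matrix(0.5, 16, 1, dimnames = list(1:16, 8))
  curve[10, 1] <- 0.1; curve[12, 1] <- 0.1
  class(curve) <- c("cre_curve", "matrix")
  o <- ocs(curve, 8)
  expect_identical(o$size, 10L)
  expect_equal(o$cre, 0.1)
  # constant curve: size 1; strictly decreasing: full channel count
  const <- matrix(0.3, 5, 1, dimnames = list(1:5, 1))
  class(const) <- c("cre_curve", "matrix")
  expect_identical(ocs(const, 1)$size, 1L)
  dec <- matrix(seq(0.5, 0.1, length.out = 5), 5, 1, dimnames = list(1:5, 1))
  class(dec) <- c("cre_curve", "matrix")
  expect_identical(ocs(dec, 1)$size, 5L)
  # invariant: cre at the OCS equals the row minimum, no smaller n attains it
  set.seed(45)
  rnd <- matrix(runif(30), 10, 3, dimnames = list(1:10, 1:3))
  class(rnd) <- c("cre_curve", "matrix")
  for (r in 1:3) {
    o <- ocs(rnd, r)
    expect_equal(o$cre, min(rnd[, r]))
    smaller <- rnd[as.integer(rownames(rnd)) < o$size, r]
    expect_true(all(smaller > o$cre))
  }
})

test_that("end-to-end evaluation beats chance on a simulated session", {
  s <- tiny_session(seed = 46, n_channels = 8, n_blocks = 8,
                    relevant_channels = 1:3, kappa = 8)
  res <- rank_channels(s)
  ev <- evaluate_channels(s, res$rank)
  expect_equal(dim(ev$curve), c(8, 15))
  expect_true(all(ev$curve >= 0 & ev$curve <= 1))
  expect_identical(names(ev$ocs), c("reps", "ocs_size", "cre"))
  # with 15 repetitions, recognition must be far better than the 35/36
  # chance error
  expect_lt(ev$curve[8, 15], 0.6)
})
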