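make_epochs <- function(data, fs = 200) {
  n_tr <- dim(data)[1]
  ev <- data.frame(onset = seq_len(n_tr) * 0.2, code = rep(1:12, length.out = n_tr),
                   is_target = rep(c(TRUE, FALSE), length.out = n_tr),
                   block = 0L, repetition = seq_len(n_tr) - 1L)
  m <- default_montage(32)
  m$labels <- m$labels[seq_len(dim(data)[2])]
  epoch_set(data, fs, ev, m)
}

test_that("analytic phase advances linearly for a pure cosine", {
  fs <- 200; f <- 8
  t <- (0:279) / fs
  data <- array(0, dim = c(1, 2, length(t)))
  data[1, 1, ] <- cos(2 * pi * f * t)
  data[1, 2, ] <- sin(2 * pi * f * t)
  ph <- analytic_phase(make_epochs(data, fs))
  mid <- 60:220
  dphi <- diff(ph$phi[1, 1, mid])
  dphi <- (dphi + pi) %% (2 * pi) - pi
  expect_lt(max(abs(dphi - 2 * pi * f / fs)), 0.01)
  # sin lags cos by pi/2 at the same frequency
  offs <- ph$phi[1, 2, mid] - ph$phi[1, 1, mid]
  offs <- (offs + pi) %% (2 * pi) - pi
  expect_lt(max(abs(offs - (-pi / 2))), 0.05)
})

test_that("amplitude times cos(phase) reconstructs the signal", {
  set.seed(10)
  fs <- 200
  n <- 400
  # band-limited random trial
  x <- as.numeric(stats::filter(rnorm(n + 200), rep(1 / 15, 15), sides = 2))
  x <- x[!is.na(x)][seq_len(n)]
  data <- array(0, dim = c(1, 2, n))
  data[1, 1, ] <- x
  data[1, 2, ] <- rev(x)
  ph <- analytic_phase(make_epochs(data, fs), keep_amplitude = TRUE)
  recon <- ph$amplitude[1, 1, ] * cos(ph$phi[1, 1, ])
  mid <- 100:300
  expect_lt(max(abs(recon[mid] - x[mid])), 1e-6)
})

test_that("analytic_phase rejects NA input", {
  data <- array(rnorm(2 * 2 * 10), c(2, 2, 10))
  data[1, 1, 3] <- NA
  expect_error(analytic_phase(make_epochs(data)), "NA")
})

test_that("PLV attains its extremes on constructed cases", {
  # identical channels: zero phase difference, PLV = 1 at every sample (the
  # maximum attainable value)
  phi <- random_phase_array(20, 2, 30, seed = 2)
  phi[, 2, ] <- phi[, 1, ]
  pt <- phase_from_array(phi)
  expect_true(all(abs(plv(pt, 1, 2)$values - 1) < 1e-12))
  # four trials with differences 0, pi/2, pi, 3pi/2: vanishing resultant
  phi2 <- array(0, c(4, 2, 3))
  phi2[, 1, ] <- 0.3
  phi2[, 2, ] <- 0.3 - matrix(c(0, pi / 2, pi, 3 * pi / 2), 4, 3)
  expect_equal(plv(phase_from_array(phi2), 1, 2)$values, rep(0, 3),
               tolerance = 1e-12)
})

test_that("PLV/PCV/ITC/PLCV match brute-force loop oracles", {
  phi <- random_phase_array(100, 3, 12, seed = 3)
  pt <- phase_from_array(phi)
  expect_equal(plv(pt, 1, 2)$values, oracle_plv(phi, 1, 2), tolerance = 1e-12)
  expect_equal(pcv(pt, 1, 3)$values, oracle_pcv(phi, 1, 3), tolerance = 1e-12)
  expect_equal(itc(pt, 2)$values, oracle_itc(phi[, 2, ]), tolerance = 1e-12)
  expect_equal(plcv(pt, 2, 3)$values, oracle_plcv(phi, 2, 3), tolerance = 1e-12)
})

test_that("ITC extremes and the von Mises mean resultant length", {
  phi <- array(0, c(6, 2, 4))
  phi[, 1, ] <- 1.1
  expect_equal(itc(phase_from_array(phi), 1)$values, rep(1, 4))
  phi[, 2, ] <- matrix(seq(-pi, pi, length.out = 7)[1:6], 6, 4)
  expect_equal(itc(phase_from_array(phi), 2)$values, rep(0, 4),
               tolerance = 1e-12)
  # 1000 von Mises(kappa = 2) draws: ITC ~ I1(2)/I0(2) = 0.6977
  kappa <- 2
  draws <- withr::with_seed(4, rvonmises(1000, 0, kappa))
  phi3 <- array(draws, c(1000, 2, 1))
  expected <- besselI(kappa, 1) / besselI(kappa, 0)
  expect_equal(itc(phase_from_array(phi3), 1)$values, expected,
               tolerance = 0.05)
})

test_that("PCV extremes: joint concentration, not locking", {
  # both channels constant over trials -> 1
  phi <- array(0, c(8, 2, 5)); phi[, 1, ] <- 0.4; phi[, 2, ] <- -1.0
  expect_equal(pcv(phase_from_array(phi), 1, 2)$values, rep(1, 5))
  # channel x equally spaced across trials, y constant -> joint phase
  # equally spaced -> 0
  phi[, 1, ] <- matrix(2 * pi * (0:7) / 8, 8, 5)
  expect_equal(pcv(phase_from_array(phi), 1, 2)$values, rep(0, 5),
               tolerance = 1e-12)
})

test_that("PLCV separates homologous from task-synchronized pairs", {
  # exact copy: PLV = 1 so PLCV = 0
  phi <- random_phase_array(30, 2, 8, seed = 5)
  phi[, 2, ] <- phi[, 1, ]
  expect_true(all(plcv(phase_from_array(phi), 1, 2)$values < 1e-12))
  # anti-correlated construction phi_x = c + d_i, phi_y = c - d_i with d_i
  # equally spaced: PLV = 0, PCV = 1, PLCV = 1
  n <- 8
  d <- 2 * pi * (0:(n - 1)) / n
  phi2 <- array(0, c(n, 2, 3))
  phi2[, 1, ] <- 0.7 + matrix(d / 2, n, 3)
  phi2[, 2, ] <- 0.7 - matrix(d / 2, n, 3)
  pt <- phase_from_array(phi2)
  expect_equal(plv(pt, 1, 2)$values, rep(0, 3), tolerance = 1e-12)
  expect_equal(pcv(pt, 1, 2)$values, rep(1, 3), tolerance = 1e-12)
  expect_equal(plcv(pt, 1, 2)$values, rep(1, 3), tolerance = 1e-12)
})

test_that("TE is zero for self-pairs and identical conditions", {
  phi_t <- random_phase_array(40, 3, 10, seed = 6)
  phi_n <- random_phase_array(200, 3, 10, seed = 7)
  pt <- phase_from_array(phi_t); pn <- phase_from_array(phi_n)
  expect_true(all(abs(te(pt, pn, 2, 2)$values) < 1e-12))
  expect_true(all(abs(te(pt, pt, 1, 3)$values) < 1e-12))
  expect_equal(te(pt, pn, 1, 3)$values, oracle_te(phi_t, phi_n, 1, 3),
               tolerance = 1e-12)
})

test_that("TE detects a target-only joint phase reset", {
  # target trials: channels 1 and 2 drawn concentrated around +d and -d;
  # nontarget: uniform. TE > 0 in the reset window, matches the oracle.
  set.seed(8)
  n_t <- 150; n_n <- 600; ns <- 20
  phi_t <- random_phase_array(n_t, 3, ns, seed = 9)
  phi_n <- random_phase_array(n_n, 3, ns, seed = 10)
  win <- 8:14
  for (s in win) {
    d <- runif(n_t, -pi, pi)             # spread differences: PLV ~ 0
    jit <- rvonmises(n_t, 0, 20)
    phi_t[, 1, s] <- 0.5 + d / 2         # sum concentrated: PCV ~ 1
    phi_t[, 2, s] <- 0.5 - d / 2 + 0.2 * jit
  }
  tser <- te(phase_from_array(phi_t), phase_from_array(phi_n), 1, 2)
  expect_equal(tser$values, oracle_te(phi_t, phi_n, 1, 2), tolerance = 1e-12)
  expect_gt(mean(tser$values[win]), 0.5)
  expect_lt(max(abs(tser$values[1:5])), 0.3)
})

test_that("TE rejects mismatched tensors", {
  pt <- phase_from_array(random_phase_array(10, 2, 8, seed = 11))
  pn <- phase_from_array(random_phase_array(10, 2, 9, seed = 12))
  expect_error(te(pt, pn, 1, 2), "share channels and samples")
})

test_that("circular-statistic bounds, symmetry and identities hold", {
  phi <- random_phase_array(20, 5, 50, seed = 13)
  pt <- phase_from_array(phi)
  for (x in 1:4) {
    for (y in (x + 1):5) {
      v1 <- plv(pt, x, y)$values; v2 <- plv(pt, y, x)$values
      expect_true(all(v1 >= 0 & v1 <= 1))
      expect_equal(v1, v2, tolerance = 1e-14)
      p1 <- pcv(pt, x, y)$values
      expect_true(all(p1 >= 0 & p1 <= 1))
      expect_equal(p1, pcv(pt, y, x)$values, tolerance = 1e-14)
      l1 <- plcv(pt, x, y)$values
      expect_true(all(l1 >= 0 & l1 <= 1))
      # vectorized implementations equal loop oracles
      expect_equal(v1, oracle_plv(phi, x, y), tolerance = 1e-10)
      expect_equal(p1, oracle_pcv(phi, x, y), tolerance = 1e-10)
      expect_equal(l1, oracle_plcv(phi, x, y), tolerance = 1e-10)
    }
  }
  # PLV equals ITC applied to the per-trial phase-difference series
  dphi <- array(phi[, 1, ] - phi[, 2, ], c(20, 1, 50))
  dpt <- phase_from_array(dphi)
  expect_equal(plv(pt, 1, 2)$values, itc(dpt, 1)$values, tolerance = 1e-12)
  # adding a common constant to both channels leaves PLV unchanged
  phi_c <- phi; phi_c[, 1, ] <- phi[, 1, ] + 1.3; phi_c[, 2, ] <- phi[, 2, ] + 1.3
  expect_equal(plv(phase_from_array(phi_c), 1, 2)$values,
               plv(pt, 1, 2)$values, tolerance = 1e-12)
})

test_that("phase tensors crop to the response window and export to TSV", {
  s <- tiny_session(seed = 14, n_blocks = 1, n_channels = 4,
                    relevant_channels = 1:2)
  prep <- preprocess_session(s, target_fs = 200)
  ep <- extract_epochs(prep, window_s = 0.7, pad_s = 1)
  expect_equal(dim(ep$data)[3], round(2.7 * 200))
  ph <- crop_phase(analytic_phase(ep))
  expect_equal(dim(ph$phi)[3], 140)
  expect_equal(ph$t0, 0)
  ser <- plv(ph, 1, 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pair_metric(ser, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 140)
  expect_equal(back$value, ser$values, tolerance = 1e-9)
  expect_equal(back$time[1], 0)
})
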