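test_that("projective fit recovers identity and known homographies", {
  set.seed(5)
  p <- cbind(runif(8, 1, 60), runif(8, 1, 60))
  T_id <- fit_projective(p, p)
  expect_lt(max(abs(T_id$H - diag(3))), 1e-8)
  H_true <- rbind(c(1.05, 0.02, 2), c(-0.03, 0.98, -1.5),
                  c(1e-4, -2e-4, 1))
  q <- apply_homography(H_true, p)
  fit <- fit_projective(p, q)
  expect_lt(max(abs(fit$H - H_true)), 1e-6)
  expect_lt(fit$rms, 1e-8)
  expect_error(fit_projective(p[1:3, ], q[1:3, ]), "at least 4")
  coll <- cbind(1:5, 2 * (1:5))
  expect_error(fit_projective(coll, coll + 1), "degenerate")
})

make_movie <- function(h, w, nt, fs = 5, fill = 0) {
  chromophore_movie(HbO2 = matrix(fill, h * w, nt),
                    HbR = matrix(fill, h * w, nt), dim = c(h, w), fs = fs)
}

test_that("movie warping handles identity, translation and inversion", {
  h <- 24; w <- 24
  mv <- make_movie(h, w, 3)
  mv$HbO2[(10 - 1) * h + 12, 2] <- 1  # impulse at (row 12, col 10)
  id <- fit_projective(cbind(c(1, 1, 20, 20), c(1, 20, 1, 20)),
                       cbind(c(1, 1, 20, 20), c(1, 20, 1, 20)))
  expect_lt(max(abs(warp_movie(mv, id)$HbO2 - mv$HbO2), na.rm = TRUE), 1e-8)
  # pure translation by +2 columns
  src <- cbind(c(2, 2, 18, 18), c(2, 18, 2, 18))
  tr <- fit_projective(src, cbind(src[, 1], src[, 2] + 2))
  wv <- warp_movie(mv, tr)
  expect_equal(wv$HbO2[(12 - 1) * h + 12, 2], 1, tolerance = 1e-6)
  # warp then inverse warp approximates identity away from borders
  set.seed(8)
  sm <- make_movie(h, w, 2)
  base <- outer(seq_len(h), seq_len(w),
                function(i, j) sin(i / 24) * cos(j / 30))
  sm$HbO2[] <- as.vector(base)
  sm$HbR[] <- as.vector(base)
  H_small <- rbind(c(1.02, 0.01, 0.5), c(-0.01, 0.99, -0.3), c(0, 0, 1))
  fwd <- structure(list(H = H_small), class = "projective_transform")
  bwd <- structure(list(H = solve(H_small)), class = "projective_transform")
  rt <- warp_movie(warp_movie(sm, fwd), bwd)
  interior <- as.vector(outer(5:(h - 4), 5:(w - 4),
                              function(i, j) (j - 1) * h + i))
  err <- abs(rt$HbO2[interior, 1] - sm$HbO2[interior, 1])
  expect_lt(max(err, na.rm = TRUE), 1e-3 * diff(range(base)))
})

test_that("nuisance regression produces orthogonal residuals", {
  mask <- make_cortex_mask(32, 32, 2)
  nt <- 300
  ph <- simulate_physiology(nt, 5, rng_seed = 3L)
  mv <- make_movie(32, 32, nt)
  # pixel equal to a regressor: residual vanishes
  hr <- (ph$heart_rate - mean(ph$heart_rate)) / sd(ph$heart_rate)
  mv$HbO2[] <- matrix(hr, 32 * 32, nt, byrow = TRUE)
  mv$HbR[] <- 1  # constant: intercept absorbs it
  res <- regress_nuisance(mv, ph, mask, global = FALSE)
  expect_lt(max(abs(res$HbO2)), 1e-10)
  expect_lt(max(abs(res$HbR)), 1e-10)
  # intercept only: residual is the demeaned series
  set.seed(2)
  mv2 <- make_movie(32, 32, nt)
  mv2$HbO2[] <- rnorm(32 * 32 * nt)
  mv2$HbR[] <- rnorm(32 * 32 * nt)
  res2 <- regress_nuisance(mv2, ph, mask, regressors = character(0),
                           global = FALSE)
  expect_lt(max(abs(res2$HbO2 - (mv2$HbO2 - rowMeans(mv2$HbO2)))), 1e-10)
  # random data: residuals orthogonal to every design column
  res3 <- regress_nuisance(mv2, ph, mask, global = TRUE)
  gs <- colMeans(mv2$HbO2[which(mask$mask), ])
  X <- nuisance_design(ph, nt, 5, global_signal = gs)
  ip <- res3$HbO2[1:50, ] %*% X
  expect_lt(max(abs(ip)), 1e-7)
})

test_that("collinear nuisance regressors are dropped with a warning", {
  nt <- 100
  ph <- simulate_physiology(nt, 5, rng_seed = 1L)
  ph$ecg <- ph$heart_rate  # exact collinearity after standardization
  expect_warning(X <- nuisance_design(ph, nt, 5), "collinear")
  expect_identical(qr(X)$rank, ncol(X))
})

test_that("spatial smoothing preserves constants and mass, shapes impulses", {
  mv <- make_movie(32, 32, 2, fill = 3.7)
  sm <- smooth_spatial(mv, 11, 3)
  expect_lt(max(abs(sm$HbO2 - 3.7)), 1e-10)
  # impulse in the interior: Gaussian profile, mass preserved
  mv2 <- make_movie(32, 32, 1)
  mv2$HbO2[(16 - 1) * 32 + 16, 1] <- 1
  sm2 <- smooth_spatial(mv2, 11, 3, use_mask = FALSE)
  img <- matrix(sm2$HbO2[, 1], 32, 32)
  expect_equal(img[16, 16] / img[17, 16], exp(1 / 18), tolerance = 1e-10)
  expect_equal(sum(img), 1, tolerance = 1e-6)
})

test_that("band-pass filter meets its frequency-response specification", {
  fs <- 5; nt <- 2100
  t <- (seq_len(nt) - 1) / fs
  # steady-state region: the filter settles over roughly fs/low samples at
  # each end of the record (identical behavior to the reference
  # forward-backward implementations)
  mid <- 300:1000
  # DC is removed entirely
  dc <- bandpass(matrix(1, 2, nt), fs = fs)
  expect_lt(max(abs(dc)), 1e-6)
  # mid-band sinusoid passes at unit gain with zero lag
  x <- sin(2 * pi * 0.04 * t)
  y <- drop(bandpass(matrix(x, 1), fs = fs))
  expect_lt(abs(max(abs(y[mid])) - 1), 0.05)
  cc <- ccf(y, x, lag.max = 12, plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0)
  # 1 Hz is deep in the stop band
  y1 <- drop(bandpass(matrix(sin(2 * pi * 1 * t), 1), fs = fs))
  expect_lt(max(abs(y1[mid])), 0.01)
  # mid-record agreement with an independent direct-form reference pass
  # over the identically padded series
  set.seed(6)
  z <- rnorm(nt)
  yz <- drop(bandpass(matrix(z, 1), fs = fs))
  bt <- signal::butter(4, c(0.009, 0.08) / (fs / 2), "pass")
  zc <- z - mean(z)
  npad <- 1667
  xe <- c(2 * zc[1] - zc[(npad + 1):2], zc,
          2 * zc[nt] - zc[(nt - 1):(nt - npad)])
  ref <- as.numeric(signal::filter(bt, xe))
  ref <- rev(as.numeric(signal::filter(bt, rev(ref))))
  ref <- ref[(npad + 1):(npad + nt)]
  # the two realizations are algebraically identical; the narrow-band
  # recursion amplifies rounding differences, hence the loose tolerance
  expect_lt(max(abs(yz[mid] - ref[mid])), 1e-3 * sd(z))
})

test_that("band-pass validates record length and band edges", {
  expect_error(bandpass(matrix(0, 1, 100), fs = 5), "record too short")
  expect_error(bandpass(matrix(0, 1, 5000), low = 0.1, high = 3, fs = 5),
               "Nyquist")
})
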