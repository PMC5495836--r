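# identity-system configuration: E = extinction * pathlength * 1e-6 = I
identity_optics <- function() {
  optics_config(wavelengths = c(500, 600),
                extinction = matrix(c(1e6, 0, 0, 1e6), 2, 2,
                                    dimnames = list(NULL, c("HbO2", "HbR"))),
                pathlength = c(1, 1), noise_sd = 0)
}

make_stack <- function(I, I0, wl = c(525, 590, 630), fs = 5) {
  structure(list(intensities = I, wavelengths = wl,
                 I0 = rep(I0, length.out = length(wl)), fs = fs,
                 dim = c(nrow(I[[1]]), 1L), mask = NULL),
            class = "optical_stack")
}

test_that("optical density follows the base-10 definition", {
  I0 <- 1000
  I <- list(matrix(I0, 4, 3), matrix(I0 / 10, 4, 3), matrix(2 * I0, 4, 3))
  od <- optical_density(make_stack(I, I0))
  expect_lt(max(abs(od$od[[1]])), 1e-12)
  expect_lt(max(abs(od$od[[2]] - 1)), 1e-12)
  expect_lt(max(abs(od$od[[3]] + log10(2))), 1e-12)
})

test_that("non-positive intensities are rejected with a count", {
  I <- list(matrix(c(-1, 2, 3, -4), 2, 2))
  expect_error(optical_density(make_stack(I, 10, wl = 525)),
               "2 pixel-frames")
})

test_that("identity extinction system has identity pseudoinverse", {
  sys <- build_extinction_system(identity_optics())
  expect_lt(max(abs(sys$E - diag(2))), 1e-12)
  expect_lt(max(abs(sys$pinv - diag(2))), 1e-12)
})

test_that("rank-deficient extinction systems are rejected", {
  cfg <- optics_config(wavelengths = c(500, 600),
                       extinction = matrix(c(1, 2, 2, 4), 2, 2,
                                           dimnames = list(NULL,
                                                           c("HbO2", "HbR"))),
                       pathlength = c(1, 1))
  expect_error(build_extinction_system(cfg), "rank deficient")
})

test_that("overdetermined unmixing matches the normal-equations oracle", {
  cfg <- optics_config()  # 3 wavelengths, 2 chromophores
  sys <- build_extinction_system(cfg)
  # consistent right-hand side: exact recovery
  c_true <- c(HbO2 = 1.3, HbR = -0.4)
  od_vec <- drop(sys$E %*% c_true)
  od <- structure(list(od = lapply(od_vec, function(v) matrix(v, 1, 1)),
                       wavelengths = cfg$wavelengths, fs = 5,
                       dim = c(1L, 1L), mask = NULL),
                  class = "od_movie")
  rec <- unmix(od, sys)
  expect_lt(abs(rec$HbO2[1, 1] - c_true["HbO2"]), 1e-10)
  expect_lt(abs(rec$HbR[1, 1] - c_true["HbR"]), 1e-10)
  # noisy single pixel: least squares equals solve(E'E) E' od
  set.seed(7)
  od_n <- od_vec + rnorm(3, sd = 0.01)
  oracle <- solve(crossprod(sys$E), crossprod(sys$E, od_n))
  od$od <- lapply(od_n, function(v) matrix(v, 1, 1))
  rec_n <- unmix(od, sys)
  expect_lt(abs(rec_n$HbO2[1, 1] - oracle[1]), 1e-10)
  expect_lt(abs(rec_n$HbR[1, 1] - oracle[2]), 1e-10)
})

test_that("duplicated wavelength rows act as least-squares weights", {
  # a duplicated, rescaled row changes the solution exactly like the
  # normal-equations oracle predicts
  E3 <- matrix(c(1, 0.5, 1, 0.2, 1.4, 0.2), 3, 2)
  cfg <- optics_config(wavelengths = c(500, 550, 600),
                       extinction = E3 * 1e6,
                       pathlength = c(1, 1, 1))
  sys <- build_extinction_system(cfg)
  set.seed(1)
  od_n <- rnorm(3)
  oracle <- solve(crossprod(E3), crossprod(E3, od_n))
  od <- structure(list(od = lapply(od_n, function(v) matrix(v, 1, 1)),
                       wavelengths = cfg$wavelengths, fs = 5,
                       dim = c(1L, 1L), mask = NULL),
                  class = "od_movie")
  rec <- unmix(od, sys)
  expect_lt(max(abs(c(rec$HbO2[1, 1], rec$HbR[1, 1]) - drop(oracle))), 1e-10)
})

test_that("zero OD unmixes to zero and wavelength mismatch errors", {
  cfg <- optics_config()
  sys <- build_extinction_system(cfg)
  od <- structure(list(od = lapply(1:3, function(i) matrix(0, 5, 4)),
                       wavelengths = cfg$wavelengths, fs = 5,
                       dim = c(5L, 1L), mask = NULL),
                  class = "od_movie")
  rec <- unmix(od, sys)
  expect_true(all(rec$HbO2 == 0) && all(rec$HbR == 0))
  od$wavelengths <- c(525, 590, 700)
  expect_error(unmix(od, sys), "do not match")
})

test_that("forward optics then unmixing is the identity on noiseless data", {
  atlas <- tiny_atlas()
  ch <- suppressWarnings(
    simulate_chromophores(atlas, tiny_truth(seed = 12L), 100, 5))
  cfg <- optics_config(noise_sd = 0)
  rec <- unmix(optical_density(forward_optics(ch, cfg, 1)),
               build_extinction_system(cfg))
  expect_lt(max(abs(rec$HbO2 - ch$HbO2)), 1e-8)
  expect_lt(max(abs(rec$HbR - ch$HbR)), 1e-8)
})

test_that("unmixing is linear and residuals are orthogonal to the system", {
  cfg <- optics_config()
  sys <- build_extinction_system(cfg)
  set.seed(3)
  mk_od <- function(M) structure(
    list(od = M, wavelengths = cfg$wavelengths, fs = 5,
         dim = c(nrow(M[[1]]), 1L), mask = NULL), class = "od_movie")
  od1 <- mk_od(lapply(1:3, function(i) matrix(rnorm(20), 4, 5)))
  od2 <- mk_od(lapply(1:3, function(i) matrix(rnorm(20), 4, 5)))
  comb <- mk_od(Map(function(a, b) 2 * a - 3 * b, od1$od, od2$od))
  r1 <- unmix(od1, sys); r2 <- unmix(od2, sys); rc <- unmix(comb, sys)
  expect_lt(max(abs(rc$HbO2 - (2 * r1$HbO2 - 3 * r2$HbO2))), 1e-12)
  expect_lt(max(abs(rc$HbR - (2 * r1$HbR - 3 * r2$HbR))), 1e-12)
  # residual orthogonality per pixel-frame
  fit <- lapply(1:3, function(l)
    sys$E[l, 1] * r1$HbO2 + sys$E[l, 2] * r1$HbR)
  for (jcol in 1:2) {
    ip <- Reduce(`+`, Map(function(o, f, e) (o - f) * e,
                          od1$od, fit, as.list(sys$E[, jcol])))
    expect_lt(max(abs(ip)), 1e-8)
  }
})
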