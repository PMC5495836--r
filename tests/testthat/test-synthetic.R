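test_that("cortex mask is symmetric, simply connected and deterministic", {
  m1 <- make_cortex_mask(64, 64, 4)
  expect_identical(m1$mask, m1$mask[, ncol(m1$mask):1])
  expect_identical(m1$mask, make_cortex_mask(64, 64, 4)$mask)
  expect_identical(max(label_components(m1$mask, 8)), 1L)
  expect_identical(m1$n_pixels, sum(m1$mask))
  expect_error(make_cortex_mask(8, 8, 4), "at least 32")
})

test_that("default seed atlas has 8 seeds of exactly 17 pixels each", {
  atlas <- make_seed_atlas(make_cortex_mask(128, 128, 6))
  expect_length(atlas$seed_names, 8)
  expect_true(all(vapply(atlas$members, length, 1L) == 17L))
  expect_length(atlas$homotopic_pairs, 4)
  expect_setequal(names(atlas$homotopic_pairs), c("M", "C", "S", "R"))
})

test_that("custom atlas records homotopic pairs only where both hemispheres exist", {
  mask <- make_cortex_mask(64, 64, 4)
  atlas <- make_seed_atlas(mask, list(A_L = c(30, 20), A_R = c(30, 45),
                                      B_L = c(45, 25), Cx = c(20, 32)),
                           n_pixels = 9)
  expect_length(atlas$seed_names, 4)
  expect_length(atlas$homotopic_pairs, 1)
  expect_identical(atlas$homotopic_pairs$A, c("A_L", "A_R"))
})

test_that("atlas construction rejects bad seed placements", {
  mask <- make_cortex_mask(64, 64, 4)
  expect_error(make_seed_atlas(mask, list(X = c(1, 1))), "outside")
  # a center whose surroundings hold too few in-mask pixels
  sliver <- mask
  sliver$mask[] <- FALSE
  sliver$mask[30:32, 30:33] <- TRUE
  expect_error(make_seed_atlas(sliver, list(X = c(31, 31)), n_pixels = 17),
               "fewer than")
  expect_error(make_seed_atlas(mask, list(A = c(32, 30), B = c(32, 31)),
                               n_pixels = 9),
               "overlap")
})

test_that("simulated seed-pair correlations follow the coupling matrix", {
  atlas <- tiny_atlas()
  nfr <- 2100
  # identity coupling: near-zero empirical correlation
  tr0 <- tiny_truth(coupling = 0, seed = 3L)
  ch0 <- simulate_chromophores(atlas, tr0, nfr, 5)
  tc0 <- extract_seed_timecourses(ch0, atlas)
  expect_lt(abs(cor(tc0$tc$HbO2[, 1], tc0$tc$HbO2[, 2])), 0.2)
  # strong coupling: empirical r within 0.15 of the 0.8 target over seeds
  errs <- vapply(1:20, function(s) {
    tr <- tiny_truth(coupling = 0.8, seed = 100L + s)
    ch <- simulate_chromophores(atlas, tr, nfr, 5)
    tc <- extract_seed_timecourses(ch, atlas, "HbO2")
    cor(tc$tc$HbO2[, 1], tc$tc$HbO2[, 2]) - 0.8
  }, 1)
  expect_lt(max(abs(errs)), 0.15)
  # full attenuation: homotopic correlation collapses
  tri <- tiny_truth("injured", lesion = 1, kappa = 1, coupling = 0.8,
                    seed = 9L)
  chi <- simulate_chromophores(atlas, tri, nfr, 5)
  tci <- extract_seed_timecourses(chi, atlas, "HbO2")
  expect_lt(abs(cor(tci$tc$HbO2[, 1], tci$tc$HbO2[, 2])), 0.2)
})

test_that("empirical coupling error is small on average across replicates", {
  atlas <- tiny_atlas()
  errs <- vapply(1:50, function(s) {
    tr <- tiny_truth(coupling = 0.7, seed = 200L + s)
    ch <- simulate_chromophores(atlas, tr, 2100, 5)
    tc <- extract_seed_timecourses(ch, atlas, "HbO2")
    abs(cor(tc$tc$HbO2[, 1], tc$tc$HbO2[, 2]) - 0.7)
  }, 1)
  expect_lt(mean(errs), 0.05)
})

test_that("latent signal power is confined to the passband", {
  atlas <- tiny_atlas()
  ch <- simulate_chromophores(atlas, tiny_truth(seed = 5L), 2100, 5)
  L <- ch$latents[, 1]
  sp <- Mod(fft(L - mean(L)))^2
  n <- length(L)
  f <- (seq_len(n) - 1) / n * 5
  f <- pmin(f, 5 - f)
  inband <- f >= 0.009 & f <= 0.08
  expect_lt(sum(sp[!inband]) / sum(sp), 0.01)
})

test_that("HbR is anti-correlated with HbO2 within pixels", {
  atlas <- tiny_atlas()
  ch <- simulate_chromophores(atlas, tiny_truth(seed = 6L), 1000, 5)
  px <- atlas$members$A_L[1]
  expect_lt(cor(ch$HbO2[px, ], ch$HbR[px, ]), -0.3)
})

test_that("chromophore simulation is reproducible and flags non-PSD couplings", {
  atlas <- tiny_atlas()
  tr <- tiny_truth(seed = 8L)
  ch1 <- simulate_chromophores(atlas, tr, 600, 5)
  ch2 <- simulate_chromophores(atlas, tr, 600, 5)
  expect_identical(ch1$HbO2, ch2$HbO2)
  sn <- c("A_L", "A_R", "B_L")
  C <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3,
              dimnames = list(sn, sn))
  expect_error(ground_truth(C, "control"), "positive semidefinite")
  # record shorter than the slowest in-band period is rejected
  expect_error(suppressWarnings(simulate_chromophores(atlas, tr, 40, 5)),
               "too short")
})

test_that("physiology traces are reproducible with the right structure", {
  p1 <- simulate_physiology(2100, 5, rng_seed = 4L)
  p2 <- simulate_physiology(2100, 5, rng_seed = 4L)
  expect_identical(p1, p2)
  expect_identical(nrow(p1), 2100L)
  # respiration spectral peak near the configured 1 Hz rate
  x <- p1$resp_signal - mean(p1$resp_signal)
  sp <- Mod(fft(x))^2
  n <- length(x)
  f <- (seq_len(n) - 1) / n * 5
  peak <- f[f > 0 & f <= 2.5][which.max(sp[f > 0 & f <= 2.5])]
  expect_lt(abs(peak - 1), 0.15)
})

test_that("forward optics matches the Beer-Lambert model", {
  atlas <- tiny_atlas()
  ch <- simulate_chromophores(atlas, tiny_truth(seed = 2L), 600, 5)
  cfg <- optics_config(noise_sd = 0)
  # zero concentrations give the reference intensity everywhere
  ch0 <- ch
  ch0$HbO2[] <- 0; ch0$HbR[] <- 0
  st0 <- forward_optics(ch0, cfg, 1)
  for (l in seq_along(st0$intensities))
    expect_lt(max(abs(st0$intensities[[l]] - cfg$I0[l])), 1e-9)
  # doubling concentrations doubles every optical density
  st1 <- forward_optics(ch, cfg, 1)
  ch2 <- ch; ch2$HbO2 <- 2 * ch$HbO2; ch2$HbR <- 2 * ch$HbR
  st2 <- forward_optics(ch2, cfg, 1)
  od1 <- -log10(st1$intensities[[1]] / cfg$I0[1])
  od2 <- -log10(st2$intensities[[1]] / cfg$I0[1])
  expect_lt(max(abs(od2 - 2 * od1)), 1e-10)
})

test_that("cohorts have the configured composition and are reproducible", {
  d <- cohort_design(height = 32, width = 32, margin = 2, n_frames = 400)
  co <- simulate_cohort(8, 5, d, 42)
  expect_identical(nrow(co$subjects), 13L)
  expect_identical(sum(co$subjects$group == "control"), 8L)
  expect_true(all(co$subjects$lesion_fraction[co$subjects$group ==
                                                "control"] == 0))
  lf <- co$subjects$lesion_fraction[co$subjects$group == "injured"]
  expect_true(all(lf >= 0.6 & lf <= 1))
  co2 <- simulate_cohort(8, 5, d, 42)
  s1 <- suppressWarnings(subject_data(co, 2))
  s2 <- suppressWarnings(subject_data(co2, 2))
  expect_identical(s1$stack$intensities, s2$stack$intensities)
  expect_identical(s1$physio, s2$physio)
  # injured ground-truth homotopic coupling is attenuated
  hemi_pairs <- co$atlas$homotopic_pairs
  eff <- function(i) {
    C <- oiconnect:::effective_coupling(co$truths[[i]],
                                        co$atlas$seed_names)
    mean(vapply(hemi_pairs, function(p) C[p[1], p[2]], 1))
  }
  mean_ctrl <- mean(vapply(which(co$subjects$group == "control"), eff, 1))
  mean_inj <- mean(vapply(which(co$subjects$group == "injured"), eff, 1))
  expect_lt(mean_inj, mean_ctrl)
})

test_that("feature-level cohort attenuates interhemispheric couplings with lesion size", {
  fc <- simulate_connectivity_features(20, rng_seed = 3)
  expect_identical(dim(fc$features), c(20L, 56L))
  expect_identical(sum(fc$labels == "control"), 10L)
  homo <- grep("^HbO2_M_L_M_R$", colnames(fc$features))
  expect_length(homo, 1)
  expect_lt(cor(fc$features[, homo], fc$lesion_fraction), -0.8)
})
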