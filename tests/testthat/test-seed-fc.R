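test_that("fisher z matches its closed form and is odd", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3), tolerance = 1e-14)
  expect_true(is.finite(fisher_z(1)))
  expect_error(fisher_z(1.2), "outside")
})

test_that("seed time courses average exactly the member pixels", {
  atlas <- small_atlas()
  nt <- 20
  npx <- prod(atlas$mask$height, atlas$mask$width)
  mv <- chromophore_movie(matrix(rnorm(npx * nt), npx, nt),
                          matrix(0, npx, nt),
                          dim = c(atlas$mask$height, atlas$mask$width),
                          fs = 5)
  tc <- extract_seed_timecourses(mv, atlas)
  expect_true(all(vapply(atlas$members, length, 1L) == 17L))
  sn <- atlas$seed_names[3]
  expect_equal(tc$tc$HbO2[, sn],
               colMeans(mv$HbO2[atlas$members[[sn]], ]), tolerance = 1e-12)
  # constant frames give the constant in every seed
  mv$HbO2[] <- rep(seq_len(nt), each = npx)
  tc2 <- extract_seed_timecourses(mv, atlas, "HbO2")
  expect_equal(unname(tc2$tc$HbO2[, 1]), as.numeric(seq_len(nt)),
               tolerance = 1e-12)
  # one-pixel seed reproduces that pixel
  a1 <- make_seed_atlas(atlas$mask, list(P_L = c(24, 12)), n_pixels = 1)
  tc3 <- extract_seed_timecourses(mv, a1, "HbO2")
  expect_equal(unname(tc3$tc$HbO2[, 1]), mv$HbO2[a1$members$P_L, ],
               tolerance = 1e-12)
})

test_that("seed-to-seed correlation matches the Pearson formula", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  m <- seed_to_seed(cbind(a = x, b = y, c = -x))
  expect_equal(unname(diag(m$r)), c(1, 1, 1))
  expect_equal(m$r["a", "b"], 0.8, tolerance = 1e-12)
  expect_equal(m$r["a", "c"], -1, tolerance = 1e-12)
  expect_lt(max(abs(m$r - t(m$r))), 1e-15)
  expect_equal(m$z["a", "b"], atanh(0.8), tolerance = 1e-12)
  expect_error(seed_to_seed(cbind(a = x, flat = rep(1, 4))), "flat")
})

test_that("homotopic connectivity returns one z per bilateral pair", {
  atlas <- small_atlas()
  set.seed(1)
  tc <- matrix(rnorm(100 * 8), 100, 8,
               dimnames = list(NULL, atlas$seed_names))
  m <- seed_to_seed(tc)
  hz <- homotopic_connectivity(m, atlas)
  expect_length(hz, 4)
  expect_equal(hz[["M"]], m$z["M_L", "M_R"], tolerance = 1e-14)
  # identity correlation matrix: all homotopic z are zero
  m0 <- m
  m0$r <- diag(8); m0$z <- fisher_z(diag(8) * 0)
  dimnames(m0$z) <- list(atlas$seed_names, atlas$seed_names)
  expect_true(all(homotopic_connectivity(m0, atlas) == 0))
  # missing partner
  m2 <- seed_to_seed(tc[, 1:7])
  expect_error(homotopic_connectivity(m2, atlas), "missing hemisphere")
})

test_that("seed-to-pixel maps are normalized and rank self pixels highest", {
  atlas <- tiny_atlas()
  ch <- simulate_chromophores(atlas, tiny_truth(coupling = 0.3, seed = 21L),
                              600, 5)
  tc <- extract_seed_timecourses(ch, atlas, "HbO2")
  mp <- seed_to_pixel_map(ch$HbO2, tc$tc$HbO2[, "A_L"], atlas$mask)
  v <- mp$values[!is.na(mp$values)]
  expect_lt(abs(mean(v)), 1e-10)
  expect_lt(abs(sd(v) - 1), 1e-10)
  # pre-normalization: the seed's own pixels carry near-maximal z
  raw <- seed_to_pixel_map(ch$HbO2, tc$tc$HbO2[, "A_L"], atlas$mask,
                           normalize = FALSE)
  own <- mean(raw$values[atlas$members$A_L])
  other <- mean(raw$values[atlas$members$A_R])
  expect_gt(own, other)
  expect_gt(own, stats::quantile(raw$values, 0.95, na.rm = TRUE))
  # batch version agrees with the single-seed path
  mps <- seed_to_pixel_maps(ch$HbO2, tc$tc$HbO2, atlas$mask)
  expect_equal(mps$A_L$values, mp$values, tolerance = 1e-12)
})

test_that("group t-maps match the one-sample t oracle and flag degeneracy", {
  mk_map <- function(vals, mask) structure(
    list(values = vals, dim = dim(mask), mask = mask, normalized = TRUE),
    class = "fc_map")
  mask <- matrix(TRUE, 2, 2)
  vals <- list(c(0.9, 0, 1, 0), c(1.1, 0, 1, 0), c(1.0, 0, 1, 0),
               c(1.2, 0, 1, 0))
  gt <- group_tmap(lapply(vals, mk_map, mask = mask))
  # direct oracle for (0.9, 1.1, 1.0, 1.2)
  ref <- t.test(c(0.9, 1.1, 1.0, 1.2))
  expect_equal(gt$t_map[1], unname(ref$statistic), tolerance = 1e-10)
  expect_equal(gt$t_map[1], 16.2665, tolerance = 1e-4)
  expect_equal(gt$p_map[1], ref$p.value, tolerance = 1e-10)
  # all-zero pixels are a genuine null, not degenerate
  expect_identical(gt$t_map[2], 0)
  expect_identical(gt$p_map[2], 1)
  # constant non-zero pixels are degenerate -> invalid, not infinite
  expect_true(is.na(gt$t_map[3]))
  expect_identical(gt$t_map[4], 0)
})

test_that("threshold_map applies BH height and cluster-extent rules", {
  h <- 32; w <- 32
  mask <- matrix(TRUE, h, w)
  p_map <- rep(1, h * w)
  # one 96-pixel cluster (12x8) and one 4-pixel cluster (2x2), separated
  big <- as.vector(outer(3:14, 3:10, function(i, j) (j - 1) * h + i))
  small <- as.vector(outer(25:26, 25:26, function(i, j) (j - 1) * h + i))
  p_map[c(big, small)] <- 1e-12
  st <- structure(list(t_map = rep(0, h * w), p_map = p_map, n = 5,
                       dim = c(h, w), mask = mask),
                  class = "group_map_stats")
  out <- threshold_map(st, q = 0.05, extent_frac = 0.05)
  expect_identical(out$n_height, 100L)
  expect_identical(sum(out$supra_mask), 96L)     # 4 < 5 removed
  expect_equal(out$spatial_extent, 96 / (h * w), tolerance = 1e-12)
  # extent definition: 45 surviving of 100 cortex pixels
  mask2 <- matrix(FALSE, h, w); mask2[1:10, 1:10] <- TRUE
  p2 <- rep(NA_real_, h * w)
  p2[which(mask2)] <- 1
  p2[as.vector(outer(1:9, 1:5, function(i, j) (j - 1) * h + i))] <- 1e-12
  st2 <- structure(list(t_map = rep(0, h * w), p_map = p2, n = 5,
                        dim = c(h, w), mask = mask2),
                   class = "group_map_stats")
  out2 <- threshold_map(st2, q = 0.05, extent_frac = 0.05)
  expect_equal(out2$spatial_extent, 0.45, tolerance = 1e-12)
  # nothing survives: extent 0, no error
  st$p_map <- rep(0.5, h * w)
  expect_identical(threshold_map(st)$spatial_extent, 0)
})

test_that("cluster filtering is monotone in the extent fraction", {
  set.seed(9)
  h <- 32; w <- 32
  mask <- matrix(TRUE, h, w)
  p_map <- runif(h * w)^3
  st <- structure(list(t_map = rep(0, h * w), p_map = p_map, n = 5,
                       dim = c(h, w), mask = mask),
                  class = "group_map_stats")
  survived <- vapply(c(0, 0.02, 0.05, 0.1, 0.3),
                     function(fr) sum(threshold_map(st, 0.2, fr)$supra_mask),
                     1)
  expect_true(all(diff(survived) <= 0))
  # only clusters strictly smaller than the threshold are removed
  out <- threshold_map(st, 0.2, 0.05)
  expect_true(all(out$clusters$size >= 0.05 * out$n_height))
})

test_that("coupled networks have larger spatial extent than null cohorts", {
  # cohorts with realistic between-subject coupling variability: in the
  # coupled group the homotopic network is consistently high, in the null
  # group it fluctuates around zero and loses group-level significance
  mask <- make_cortex_mask(32, 32, 2)
  atlas <- make_seed_atlas(mask, list(A_L = c(12, 10), A_R = c(12, 23),
                                      B_L = c(21, 10), B_R = c(21, 23)),
                           n_pixels = 5)
  sn <- atlas$seed_names
  run_group <- function(coupling, seed0) {
    movies <- lapply(1:6, function(s) {
      set.seed(seed0 + s)
      C <- oiconnect:::jitter_coupling(
        default_coupling_matrix(sn, homotopic = coupling,
                                ipsilateral = coupling / 3,
                                contralateral = coupling / 4), 0.1)
      tr <- ground_truth(C, "control", rng_seed = seed0 + s)
      ch <- simulate_chromophores(atlas, tr, 800, 5)
      bandpass(smooth_spatial(ch, 7, 2), 0.02, 0.08)
    })
    spatial_extent_by_network(movies, atlas, contrasts = "HbO2")
  }
  ext_strong <- run_group(0.8, 300L)
  ext_null <- run_group(0, 400L)
  expect_true(all(ext_strong$extent >= 0 & ext_strong$extent <= 1))
  expect_gt(mean(ext_strong$extent), mean(ext_null$extent))
})
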