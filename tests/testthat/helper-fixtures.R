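# Small fixtures shared across tests; everything is generated in code.

# minimal bilateral atlas: one homotopic pair on a 32x32 mask
tiny_atlas <- function(n_pixels = 5) {
  mask <- make_cortex_mask(32, 32, 2)
  make_seed_atlas(mask, list(A_L = c(14, 10), A_R = c(14, 23)),
                  n_pixels = n_pixels)
}

# default 8-seed atlas at desk-test scale
small_atlas <- function(size = 48) {
  make_seed_atlas(make_cortex_mask(size, size, 4))
}

tiny_truth <- function(group = "control", lesion = 0, kappa = 1,
                       coupling = 0.6, seed = 1L) {
  C <- default_coupling_matrix(c("A_L", "A_R"), homotopic = coupling)
  ground_truth(C, group, lesion, kappa, rng_seed = seed)
}

# brute-force Benjamini-Hochberg step-up used as the independent oracle
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  rejected <- rep(FALSE, m)
  if (length(k) > 0) rejected[o[seq_len(max(k))]] <- TRUE
  rejected
}
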