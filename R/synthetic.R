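# Synthetic multispectral OIS cohorts with known network coupling.
#
# The generator emulates the acquisition geometry of a rodent intrinsic
# optical imaging rig (three wavelengths, 5 Hz full-frame rate, (14.7 mm)^2
# field of view) and the statistical structure assumed by seed-based
# functional-connectivity analysis: band-limited (0.009-0.08 Hz) Gaussian
# network fluctuations with a prescribed seed-to-seed correlation matrix,
# anti-correlated HbR, physiological nuisance traces, and a two-group
# (control vs injured) cohort in which injury multiplicatively attenuates
# interhemispheric coupling in proportion to lesion size.

#' Optics configuration for the forward model and spectral unmixing
#'
#' Bundles the wavelengths, chromophore extinction coefficients, differential
#' pathlength factors, reference intensity and sensor noise used both to
#' synthesize reflectance movies and to invert them. Extinction defaults are
#' approximate literature values for oxy-/deoxy-hemoglobin at 525/590/630 nm
#' (base-10 molar extinction, cm^-1 M^-1); pathlength defaults are of the
#' order reported for scattering cortical tissue in the green-red range.
#' Both tables are configuration, intended to be replaced by the user's own
#' calibrated values.
#'
#' @param wavelengths illumination wavelengths in nm.
#' @param extinction matrix (wavelengths x 2) of extinction coefficients,
#'   columns \code{HbO2} and \code{HbR}, in cm^-1 M^-1 (base-10 convention).
#' @param pathlength differential pathlength factor D(lambda) per wavelength,
#'   in cm.
#' @param correction_weights per-wavelength scalar sensor/LED correction
#'   factors applied to the extinction system (identity by default).
#' @param baseline_concentrations baseline chromophore concentrations in uM
#'   (carried as metadata; the differential model works in changes only).
#' @param I0 reference intensity in camera counts.
#' @param noise_sd additive Gaussian intensity noise, in counts.
#' @return an object of class \code{optics_config}.
#' @export
optics_config <- function(wavelengths = c(525, 590, 630),
                          extinction = NULL,
                          pathlength = NULL,
                          correction_weights = NULL,
                          baseline_concentrations = c(HbO2 = 60, HbR = 40),
                          I0 = 3000,
                          noise_sd = 5) {
  nl <- length(wavelengths)
  if (is.null(extinction)) {
    stopifnot(identical(as.numeric(wavelengths), c(525, 590, 630)))
    extinction <- matrix(c(48640, 11500, 610,      # HbO2
                           47500, 26600, 5149),    # HbR
                         nrow = 3, ncol = 2,
                         dimnames = list(NULL, c("HbO2", "HbR")))
  }
  if (is.null(pathlength)) {
    stopifnot(nl == nrow(extinction))
    pathlength <- seq(0.15, 0.45, length.out = nl)
  }
  if (is.null(correction_weights)) correction_weights <- rep(1, nl)
  stopifnot(nrow(extinction) == nl, length(pathlength) == nl,
            all(pathlength > 0), length(correction_weights) == nl,
            length(I0) %in% c(1L, nl), all(I0 > 0), noise_sd >= 0)
  structure(list(wavelengths = as.numeric(wavelengths),
                 extinction = extinction,
                 pathlength = as.numeric(pathlength),
                 correction_weights = as.numeric(correction_weights),
                 baseline_concentrations = baseline_concentrations,
                 I0 = rep(as.numeric(I0), length.out = nl),
                 noise_sd = as.numeric(noise_sd)),
            class = "optics_config")
}

#' @export
print.optics_config <- function(x, ...) {
  cat("<optics_config> ", length(x$wavelengths), " wavelengths (",
      paste(x$wavelengths, collapse = "/"), " nm), I0 = ",
      paste(signif(x$I0, 4), collapse = "/"),
      " counts, noise sd = ", x$noise_sd, "\n", sep = "")
  invisible(x)
}

#' Ground truth for one simulated subject
#'
#' @param coupling_matrix symmetric positive semidefinite seed-by-seed
#'   correlation target with unit diagonal.
#' @param group_label \code{"control"} or \code{"injured"}.
#' @param lesion_fraction fractional lesion volume in [0, 1]; must be 0 for
#'   control subjects.
#' @param kappa injury attenuation gain (>= 0): interhemispheric couplings
#'   of injured subjects are multiplied by \code{1 - kappa * lesion_fraction}
#'   (clipped to [0, 1]).
#' @param rng_seed integer seed that makes the subject reproducible.
#' @return an object of class \code{ground_truth}.
#' @export
ground_truth <- function(coupling_matrix, group_label = c("control", "injured"),
                         lesion_fraction = 0, kappa = 1, rng_seed = 1L) {
  group_label <- match.arg(group_label)
  C <- as.matrix(coupling_matrix)
  stopifnot(nrow(C) == ncol(C), max(abs(C - t(C))) < 1e-10,
            max(abs(diag(C) - 1)) < 1e-10, all(abs(C) <= 1 + 1e-12))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("coupling_matrix is not positive semidefinite (min eigenvalue ",
         signif(min(ev), 3), ")")
  stopifnot(lesion_fraction >= 0, lesion_fraction <= 1, kappa >= 0)
  if (group_label == "control" && lesion_fraction != 0)
    stop("control subjects must have lesion_fraction = 0")
  structure(list(coupling_matrix = C, group_label = group_label,
                 lesion_fraction = lesion_fraction, kappa = kappa,
                 rng_seed = as.integer(rng_seed)),
            class = "ground_truth")
}

#' Elliptical bilaterally-symmetric cortex mask
#'
#' Builds a simply connected boolean mask, symmetric about the vertical
#' midline, standing in for the registered cortical field of view.
#'
#' @param height,width image dimensions in pixels (>= 32).
#' @param margin clearance between the mask and the image border, in pixels.
#' @return an object of class \code{cortex_mask} with elements \code{mask}
#'   (logical matrix), \code{height}, \code{width} and \code{n_pixels}.
#' @export
make_cortex_mask <- function(height, width, margin = 4) {
  if (height < 32 || width < 32)
    stop("mask dimensions must be at least 32 x 32 pixels")
  stopifnot(margin >= 0, 2 * margin < height, 2 * margin < width)
  cy <- (height + 1) / 2
  cx <- (width + 1) / 2
  a <- height / 2 - margin
  b <- width / 2 - margin
  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  mask <- ((rows - cy) / a)^2 + ((cols - cx) / b)^2 <= 1
  structure(list(mask = mask, height = as.integer(height),
                 width = as.integer(width), n_pixels = sum(mask)),
            class = "cortex_mask")
}

#' @export
print.cortex_mask <- function(x, ...) {
  cat("<cortex_mask> ", x$height, "x", x$width, ", ", x$n_pixels,
      " cortical pixels\n", sep = "")
  invisible(x)
}

#' Default 8-seed bilateral atlas geometry
#'
#' Seed centers for motor (M), cingulate (C), somatosensory (S) and
#' retrosplenial (R) cortex in both hemispheres, expressed as fractions of
#' the mask dimensions and mirrored about the vertical midline.
#'
#' @param mask a \code{cortex_mask}.
#' @return named list of \code{c(row, col)} centers.
#' @export
default_seed_spec <- function(mask) {
  h <- mask$height; w <- mask$width
  rel <- list(M = c(0.30, 0.32), C = c(0.42, 0.40),
              S = c(0.54, 0.24), R = c(0.72, 0.40))
  out <- list()
  for (nm in names(rel)) {
    r <- round(rel[[nm]][1] * h)
    cl <- round(rel[[nm]][2] * w)
    out[[paste0(nm, "_L")]] <- c(r, cl)
    out[[paste0(nm, "_R")]] <- c(r, w + 1 - cl)
  }
  out
}

#' Construct a seed atlas on a cortex mask
#'
#' Each seed is the set of the \code{n_pixels} in-mask pixels nearest its
#' center (Euclidean distance, ties broken by polar angle then row-major
#' order), mimicking the small circular regions whose average time course
#' anchors seed-based connectivity. Homotopic pairs are recorded for seed
#' names of the form \code{<name>_L} / \code{<name>_R}.
#'
#' @param mask a \code{cortex_mask}.
#' @param seed_spec named list of \code{c(row, col)} centers; defaults to
#'   \code{\link{default_seed_spec}}.
#' @param n_pixels number of member pixels per seed (default 17, roughly a
#'   0.2 mm disk at the study's scaled pixel pitch).
#' @return an object of class \code{seed_atlas}.
#' @export
make_seed_atlas <- function(mask, seed_spec = default_seed_spec(mask),
                            n_pixels = 17) {
  stopifnot(inherits(mask, "cortex_mask"), n_pixels >= 1)
  h <- mask$height; w <- mask$width
  m <- mask$mask
  in_idx <- which(m)
  in_row <- ((in_idx - 1) %% h) + 1
  in_col <- ((in_idx - 1) %/% h) + 1
  members <- list()
  centers <- matrix(NA_real_, length(seed_spec), 2,
                    dimnames = list(names(seed_spec), c("row", "col")))
  max_radius <- sqrt(n_pixels / pi) + 1
  for (nm in names(seed_spec)) {
    ctr <- seed_spec[[nm]]
    stopifnot(length(ctr) == 2)
    if (ctr[1] < 1 || ctr[1] > h || ctr[2] < 1 || ctr[2] > w ||
        !m[ctr[1], ctr[2]])
      stop("seed '", nm, "' center (", ctr[1], ",", ctr[2],
           ") is outside the cortex mask")
    d2 <- (in_row - ctr[1])^2 + (in_col - ctr[2])^2
    if (sum(d2 <= max_radius^2) < n_pixels)
      stop("seed '", nm, "' has fewer than ", n_pixels,
           " in-mask pixels within radius ", signif(max_radius, 3),
           "; move it away from the mask border")
    ang <- atan2(in_row - ctr[1], in_col - ctr[2])
    ord <- order(d2, ang, in_idx)
    members[[nm]] <- sort(in_idx[ord[seq_len(n_pixels)]])
    centers[nm, ] <- ctr
  }
  all_members <- unlist(members)
  if (anyDuplicated(all_members))
    stop("seed pixel sets overlap; increase seed spacing or reduce n_pixels")
  base <- sub("_(L|R)$", "", names(seed_spec))
  pairs <- list()
  for (bn in unique(base)) {
    ln <- paste0(bn, "_L"); rn <- paste0(bn, "_R")
    if (ln %in% names(seed_spec) && rn %in% names(seed_spec))
      pairs[[bn]] <- c(ln, rn)
  }
  structure(list(seed_names = names(seed_spec), centers = centers,
                 members = members, homotopic_pairs = pairs,
                 n_pixels = as.integer(n_pixels), mask = mask),
            class = "seed_atlas")
}

#' @export
print.seed_atlas <- function(x, ...) {
  cat("<seed_atlas> ", length(x$seed_names), " seeds (",
      paste(x$seed_names, collapse = ", "), "), ", x$n_pixels,
      " pixels each, ", length(x$homotopic_pairs),
      " homotopic pairs\n", sep = "")
  invisible(x)
}

#' Default seed-to-seed coupling matrix
#'
#' Correlation targets for the default 8-seed atlas: strong homotopic
#' coupling, moderate ipsilateral coupling between networks of the same
#' hemisphere, weak non-homotopic interhemispheric coupling. The matrix is
#' checked for positive semidefiniteness.
#'
#' @param seed_names seed names (default 8 bilateral seeds).
#' @param homotopic,ipsilateral,contralateral coupling values for the three
#'   classes of seed pairs.
#' @return a symmetric unit-diagonal correlation matrix.
#' @export
default_coupling_matrix <- function(seed_names = c("M_L", "M_R", "C_L", "C_R",
                                                   "S_L", "S_R", "R_L", "R_R"),
                                    homotopic = 0.7, ipsilateral = 0.3,
                                    contralateral = 0.2) {
  k <- length(seed_names)
  base <- sub("_(L|R)$", "", seed_names)
  hemi <- sub("^.*_", "", seed_names)
  C <- matrix(contralateral, k, k, dimnames = list(seed_names, seed_names))
  same_h <- outer(hemi, hemi, "==")
  same_b <- outer(base, base, "==")
  C[same_h] <- ipsilateral
  C[same_b & !same_h] <- homotopic
  diag(C) <- 1
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("default coupling matrix is not positive semidefinite")
  C
}

# Effective per-subject coupling after injury attenuation: interhemispheric
# entries multiplied by clip01(1 - kappa * lesion_fraction).
effective_coupling <- function(truth, seed_names) {
  C <- truth$coupling_matrix
  if (is.null(dimnames(C))) dimnames(C) <- list(seed_names, seed_names)
  if (truth$group_label == "injured") {
    fac <- min(1, max(0, 1 - truth$kappa * truth$lesion_fraction))
    hemi <- sub("^.*_", "", seed_names)
    inter <- outer(hemi, hemi, "!=")
    C[inter] <- C[inter] * fac
  }
  C
}

# Symmetric PSD square root; errors naming the most implicated seed pair
# when the matrix has a materially negative eigenvalue.
psd_sqrt <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    v <- e$vectors[, which.min(e$values)]
    contrib <- abs(outer(v, v)); diag(contrib) <- 0
    ij <- which(contrib == max(contrib), arr.ind = TRUE)[1, ]
    nms <- rownames(C) %||% as.character(seq_len(nrow(C)))
    stop("effective coupling matrix is not positive semidefinite; ",
         "most implicated pair: (", nms[ij[1]], ", ", nms[ij[2]], ")")
  }
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# Orthonormal real Fourier basis restricted to [low, high] Hz.
inband_basis <- function(n, fs, low, high) {
  k <- seq_len(floor(n / 2))
  f <- k / n * fs
  keep <- which(f >= low & f <= high)
  if (length(keep) == 0)
    stop("record too short to contain any Fourier mode inside [",
         low, ", ", high, "] Hz; need at least ", ceiling(fs / high),
         " samples")
  t <- seq_len(n) - 1
  B <- matrix(0, n, 2 * length(keep))
  for (i in seq_along(keep)) {
    w <- 2 * pi * keep[i] * t / n
    B[, 2 * i - 1] <- cos(w)
    B[, 2 * i] <- sin(w)
  }
  sweep(B, 2, sqrt(colSums(B^2)), "/")
}

# Band-limited Gaussian noise matrix (n x m) with per-sample sd ~ sd.
inband_noise <- function(n, m, fs, low, high, sd) {
  B <- inband_basis(n, fs, low, high)
  X <- B %*% matrix(rnorm(ncol(B) * m), ncol(B), m)
  X * (sd * sqrt(n / ncol(B)))
}

#' Simulate chromophore concentration movies with known coupling
#'
#' Generates per-network latent signals as zero-mean Gaussian processes
#' strictly band-limited to \code{band}, colored so that the empirical
#' correlation matrix of the latents equals the effective coupling matrix
#' exactly (the realized white noise is whitened before coloring). Every
#' cortical pixel carries the latent of its nearest seed's network plus
#' independent band-limited pixel noise; HbR is an anti-correlated scaled
#' copy of the HbO2 network signal plus independent band-limited noise.
#' Injured subjects have interhemispheric couplings attenuated by
#' \code{1 - kappa * lesion_fraction} (clipped to [0, 1]).
#'
#' @param atlas a \code{seed_atlas}.
#' @param truth a \code{ground_truth}.
#' @param n_frames number of frames.
#' @param fs sampling rate in Hz (default 5, the full-frame rate).
#' @param amplitude latent fluctuation amplitude in uM (default 1).
#' @param pixel_noise_sd sd of independent in-band pixel noise, as a
#'   fraction of \code{amplitude}.
#' @param hbr_ratio HbR = \code{hbr_ratio} x HbO2 network signal (+ noise).
#' @param hbr_noise_sd sd of the independent in-band HbR noise, as a
#'   fraction of \code{amplitude}.
#' @param band passband in Hz.
#' @param network_sigma_frac spatial width (Gaussian sigma) of each
#'   network's cortical patch, as a fraction of the smaller image
#'   dimension; resting-state networks are focal patches around their
#'   seeds, and pixels far from every seed carry noise only.
#' @return an object of class \code{chromophore_movie}: matrices
#'   \code{HbO2} and \code{HbR} of size (height*width) x n_frames in uM,
#'   plus geometry and sampling metadata.
#' @export
simulate_chromophores <- function(atlas, truth, n_frames, fs = 5,
                                  amplitude = 1, pixel_noise_sd = 0.5,
                                  hbr_ratio = -0.5, hbr_noise_sd = 0.3,
                                  band = c(0.009, 0.08),
                                  network_sigma_frac = 0.05) {
  stopifnot(inherits(atlas, "seed_atlas"), inherits(truth, "ground_truth"))
  n_frames <- stop_if_not_scalar_count(n_frames, "n_frames")
  if (n_frames / fs < 100)
    warning("recording shorter than 100 s; correlation estimates will be noisy")
  seed_names <- atlas$seed_names
  K <- length(seed_names)
  stopifnot(nrow(truth$coupling_matrix) == K)
  Ceff <- effective_coupling(truth, seed_names)
  S <- psd_sqrt(Ceff)

  set.seed(truth$rng_seed)
  # latent network signals: band-limited, then empirically whitened so the
  # realized correlation matrix equals Ceff exactly
  # validates record length: whitening needs at least K in-band dimensions
  if (ncol(inband_basis(n_frames, fs, band[1], band[2])) < K)
    stop("record too short to support ", K,
         " independent band-limited network signals")
  Z <- band_limit_columns(matrix(rnorm(n_frames * K), n_frames, K),
                          fs, band[1], band[2])
  Sz <- crossprod(sweep(Z, 2, colMeans(Z))) / (n_frames - 1)
  W <- backsolve(chol(Sz), diag(K))
  L <- (Z %*% W) %*% S * amplitude   # n_frames x K, sd = amplitude

  h <- atlas$mask$height; w <- atlas$mask$width
  npx <- h * w
  m <- atlas$mask$mask
  in_idx <- which(m)
  in_row <- ((in_idx - 1) %% h) + 1
  in_col <- ((in_idx - 1) %/% h) + 1
  d2 <- outer(in_row, atlas$centers[, 1], "-")^2 +
    outer(in_col, atlas$centers[, 2], "-")^2
  # Gaussian network patches around the seeds; far pixels are noise only
  sig <- network_sigma_frac * min(h, w)
  Wnet <- exp(-d2 / (2 * sig^2))      # in-mask pixels x K

  S_net <- Wnet %*% t(L)              # npx_in x n_frames network signal
  hbo <- matrix(0, npx, n_frames)
  hbo[in_idx, ] <- S_net +
    t(inband_noise(n_frames, length(in_idx), fs, band[1], band[2],
                   pixel_noise_sd * amplitude))
  hbr <- matrix(0, npx, n_frames)
  hbr[in_idx, ] <- hbr_ratio * S_net +
    t(inband_noise(n_frames, length(in_idx), fs, band[1], band[2],
                   hbr_noise_sd * amplitude))
  rm(S_net)

  chromophore_movie(HbO2 = hbo, HbR = hbr, dim = c(h, w), fs = fs,
                    latents = L, mask = m)
}

#' Chromophore movie container
#'
#' @param HbO2,HbR (height*width) x n_frames matrices of concentration
#'   changes in uM (column-major pixel order).
#' @param dim image dimensions \code{c(height, width)}.
#' @param fs sampling rate in Hz.
#' @param latents optional latent network signals (simulation only).
#' @param mask optional logical validity/cortex matrix.
#' @param residualized whether nuisance regression has been applied.
#' @return an object of class \code{chromophore_movie}.
#' @export
chromophore_movie <- function(HbO2, HbR, dim, fs, latents = NULL,
                              mask = NULL, residualized = FALSE) {
  stopifnot(is.matrix(HbO2), is.matrix(HbR),
            all(base::dim(HbO2) == base::dim(HbR)),
            nrow(HbO2) == prod(dim))
  structure(list(HbO2 = HbO2, HbR = HbR, dim = as.integer(dim),
                 fs = fs, latents = latents, mask = mask,
                 residualized = residualized),
            class = "chromophore_movie")
}

#' @export
print.chromophore_movie <- function(x, ...) {
  cat("<chromophore_movie> ", x$dim[1], "x", x$dim[2], " px, ",
      ncol(x$HbO2), " frames @ ", x$fs, " Hz",
      if (isTRUE(x$residualized)) ", nuisance-regressed" else "",
      "\n", sep = "")
  invisible(x)
}

#' Simulate physiological monitoring traces
#'
#' Heart rate and respiration rate are slow drifts around rodent-typical
#' baselines; the respiration signal is quasi-periodic at the instantaneous
#' respiration rate; the ECG trace is quasi-periodic at the instantaneous
#' heart rate (aliased by the frame rate, as in a trace resampled to frame
#' times).
#'
#' @param n_frames number of samples.
#' @param fs sampling rate in Hz.
#' @param rng_seed integer seed.
#' @param heart_rate_bpm,resp_rate_bpm baseline rates (beats / breaths per
#'   minute).
#' @return an object of class \code{physio_traces}: a data frame with
#'   columns \code{t}, \code{heart_rate}, \code{resp_signal}, \code{ecg},
#'   \code{resp_rate}; sampling rate in \code{attr(, "fs")}.
#' @export
simulate_physiology <- function(n_frames, fs, rng_seed = 1L,
                                heart_rate_bpm = 450, resp_rate_bpm = 60) {
  n_frames <- stop_if_not_scalar_count(n_frames, "n_frames")
  stopifnot(fs > 0)
  set.seed(as.integer(rng_seed))
  t <- (seq_len(n_frames) - 1) / fs
  drift <- function(sd) {
    z <- band_limit_columns(matrix(rnorm(n_frames)), fs,
                            max(0.5 / (n_frames / fs), 1e-4), 0.02)
    s <- stats::sd(z)
    if (s == 0) rep(0, n_frames) else as.numeric(z) / s * sd
  }
  heart_rate <- heart_rate_bpm + drift(12)
  resp_rate <- resp_rate_bpm + drift(3)
  phase_r <- 2 * pi * cumsum(resp_rate / 60) / fs
  resp_signal <- sin(phase_r) + 0.05 * rnorm(n_frames)
  phase_h <- 2 * pi * cumsum(heart_rate / 60) / fs
  ecg <- sin(phase_h) + 0.3 * sin(2 * phase_h) + 0.05 * rnorm(n_frames)
  out <- data.frame(t = t, heart_rate = heart_rate,
                    resp_signal = resp_signal, ecg = ecg,
                    resp_rate = resp_rate)
  attr(out, "fs") <- fs
  class(out) <- c("physio_traces", "data.frame")
  out
}

#' Forward optics: chromophore movie to multispectral reflectance
#'
#' Applies the modified Beer-Lambert law in the forward direction:
#' \deqn{\Delta OD(\lambda, t) = \sum_i \epsilon_i(\lambda) C_i(t) D(\lambda)}
#' with base-10 optical density, then
#' \eqn{I = I_0 10^{-\Delta OD}} plus additive Gaussian sensor noise.
#'
#' @param chromo a \code{chromophore_movie} (concentrations in uM).
#' @param cfg an \code{optics_config}.
#' @param rng_seed integer seed for the sensor noise.
#' @param negative how to treat intensities that end up non-positive after
#'   noise: \code{"clamp"} (to a small positive floor, with a warning giving
#'   the count) or \code{"error"}.
#' @return an object of class \code{optical_stack}.
#' @export
forward_optics <- function(chromo, cfg, rng_seed = 1L,
                           negative = c("clamp", "error")) {
  stopifnot(inherits(chromo, "chromophore_movie"),
            inherits(cfg, "optics_config"))
  negative <- match.arg(negative)
  set.seed(as.integer(rng_seed))
  nl <- length(cfg$wavelengths)
  intensities <- vector("list", nl)
  names(intensities) <- as.character(cfg$wavelengths)
  n_clamped <- 0L
  ln10 <- log(10)
  for (l in seq_len(nl)) {
    # uM -> M
    od <- (cfg$extinction[l, "HbO2"] * cfg$pathlength[l] * 1e-6) * chromo$HbO2 +
      (cfg$extinction[l, "HbR"] * cfg$pathlength[l] * 1e-6) * chromo$HbR
    I <- cfg$I0[l] * exp(-ln10 * od)
    if (cfg$noise_sd > 0)
      I <- I + rnorm(length(I), sd = cfg$noise_sd)
    bad <- I <= 0
    if (any(bad)) {
      if (negative == "error")
        stop(sum(bad), " non-positive intensities after noise")
      n_clamped <- n_clamped + sum(bad)
      I[bad] <- cfg$I0[l] * 1e-6
    }
    dim(I) <- dim(od)
    intensities[[l]] <- I
  }
  if (n_clamped > 0)
    warning(n_clamped, " non-positive intensities clamped to a positive floor")
  structure(list(intensities = intensities,
                 wavelengths = cfg$wavelengths,
                 I0 = cfg$I0, fs = chromo$fs, dim = chromo$dim,
                 mask = chromo$mask),
            class = "optical_stack")
}

#' @export
print.optical_stack <- function(x, ...) {
  cat("<optical_stack> ", x$dim[1], "x", x$dim[2], " px, ",
      ncol(x$intensities[[1]]), " frames @ ", x$fs, " Hz, wavelengths ",
      paste(x$wavelengths, collapse = "/"), " nm\n", sep = "")
  invisible(x)
}

#' Cohort design parameters
#'
#' The defaults mirror the study conditions this generator emulates: a
#' 13-animal cohort (8 control, 5 injured), 7 min of 5 Hz acquisition
#' (2100 frames), a (14.7 mm)^2 field of view rendered at 128 x 128 pixels,
#' homotopic coupling 0.7 attenuated in injured subjects with kappa = 1 and
#' lesion fractions drawn from [0.6, 1].
#'
#' @param height,width image size in pixels.
#' @param margin cortex-mask margin in pixels.
#' @param n_frames frames per subject.
#' @param fs frame rate, Hz.
#' @param field_of_view_mm lateral field of view, mm.
#' @param coupling base seed coupling matrix.
#' @param coupling_jitter_sd sd of symmetric between-subject jitter added to
#'   off-diagonal couplings (eigenvalue-clipped back to PSD).
#' @param kappa injury attenuation gain.
#' @param lesion_range range of injured lesion fractions.
#' @param amplitude,pixel_noise_sd,hbr_ratio,hbr_noise_sd,band see
#'   \code{\link{simulate_chromophores}}.
#' @param optics an \code{optics_config}.
#' @param n_seed_pixels pixels per seed.
#' @return a list of class \code{cohort_design}.
#' @export
cohort_design <- function(height = 128, width = 128, margin = 6,
                          n_frames = 2100, fs = 5, field_of_view_mm = 14.7,
                          coupling = default_coupling_matrix(),
                          coupling_jitter_sd = 0.1,
                          kappa = 1, lesion_range = c(0.6, 1),
                          amplitude = 1, pixel_noise_sd = 0.5,
                          hbr_ratio = -0.5, hbr_noise_sd = 0.3,
                          band = c(0.009, 0.08),
                          network_sigma_frac = 0.05,
                          optics = optics_config(),
                          n_seed_pixels = 17) {
  structure(as.list(environment()), class = "cohort_design")
}

# Symmetric jitter on off-diagonal couplings, projected back to the PSD
# cone (eigenvalues clipped at a small floor, diagonal renormalized).
jitter_coupling <- function(C, sd) {
  if (sd <= 0) return(C)
  k <- nrow(C)
  E <- matrix(rnorm(k * k, sd = sd), k, k)
  E <- (E + t(E)) / 2
  diag(E) <- 0
  Cj <- pmin(pmax(C + E, -1), 1)
  e <- eigen(Cj, symmetric = TRUE)
  vals <- pmax(e$values, 1e-6)
  Cj <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(Cj))
  Cj <- Cj / outer(d, d)
  dimnames(Cj) <- dimnames(C)
  (Cj + t(Cj)) / 2
}

#' Simulate a two-group OIS cohort
#'
#' Builds the cohort skeleton (mask, atlas, per-subject ground truth with
#' jittered coupling and drawn lesion fractions, per-subject RNG streams).
#' Subject raw data are materialized on demand with
#' \code{\link{subject_data}} so that arbitrarily large cohorts can be
#' processed one subject at a time; materialization is bit-reproducible
#' given the cohort's \code{rng_seed}.
#'
#' @param n_control,n_injured group sizes (total >= 4).
#' @param design a \code{\link{cohort_design}}.
#' @param rng_seed master integer seed.
#' @return an object of class \code{cohort_dataset} with elements
#'   \code{subjects} (data frame: id, group, lesion_fraction, rng_seed),
#'   \code{truths}, \code{atlas}, \code{mask}, \code{design}.
#' @export
simulate_cohort <- function(n_control = 8, n_injured = 5,
                            design = cohort_design(), rng_seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  if (n_control + n_injured < 4)
    stop("cohort must have at least 4 subjects")
  mask <- make_cortex_mask(design$height, design$width, design$margin)
  atlas <- make_seed_atlas(mask, n_pixels = design$n_seed_pixels)
  n <- n_control + n_injured
  group <- rep(c("control", "injured"), c(n_control, n_injured))
  sseed <- vapply(seq_len(n), function(i) derive_seed(rng_seed, i), 1L)
  set.seed(derive_seed(rng_seed, 0L))
  lesion <- ifelse(group == "injured",
                   runif(n, design$lesion_range[1], design$lesion_range[2]),
                   0)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(sseed[i], 1L))
    Ci <- jitter_coupling(design$coupling, design$coupling_jitter_sd)
    truths[[i]] <- ground_truth(Ci, group[i], lesion[i],
                                kappa = design$kappa, rng_seed = sseed[i])
  }
  subjects <- data.frame(id = sprintf("S%02d", seq_len(n)), group = group,
                         lesion_fraction = lesion, rng_seed = sseed,
                         stringsAsFactors = FALSE)
  structure(list(subjects = subjects, truths = truths, atlas = atlas,
                 mask = mask, design = design, rng_seed = as.integer(rng_seed)),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset> ", nrow(x$subjects), " subjects (",
      sum(x$subjects$group == "control"), " control, ",
      sum(x$subjects$group == "injured"), " injured), ",
      x$design$height, "x", x$design$width, " px, ",
      x$design$n_frames, " frames @ ", x$design$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Materialize one subject's raw data
#'
#' @param cohort a \code{cohort_dataset}.
#' @param i subject index.
#' @param keep_chromophores also return the noiseless ground-truth
#'   chromophore movie (doubles memory use).
#' @return list with \code{stack} (\code{optical_stack}), \code{physio}
#'   (\code{physio_traces}), \code{truth} (\code{ground_truth}) and
#'   optionally \code{chromo}.
#' @export
subject_data <- function(cohort, i, keep_chromophores = FALSE) {
  stopifnot(inherits(cohort, "cohort_dataset"),
            i >= 1, i <= nrow(cohort$subjects))
  d <- cohort$design
  truth <- cohort$truths[[i]]
  chromo <- simulate_chromophores(cohort$atlas, truth, d$n_frames, d$fs,
                                  amplitude = d$amplitude,
                                  pixel_noise_sd = d$pixel_noise_sd,
                                  hbr_ratio = d$hbr_ratio,
                                  hbr_noise_sd = d$hbr_noise_sd,
                                  band = d$band,
                                  network_sigma_frac = d$network_sigma_frac)
  physio <- simulate_physiology(d$n_frames, d$fs,
                                rng_seed = derive_seed(truth$rng_seed, 2L))
  stack <- forward_optics(chromo, d$optics,
                          rng_seed = derive_seed(truth$rng_seed, 3L))
  out <- list(stack = stack, physio = physio, truth = truth)
  if (keep_chromophores) out$chromo <- chromo
  out
}

#' Simulate a serial-section histology stack with a known ventricle
#'
#' Produces coronal grayscale sections through an ellipsoidal brain phantom
#' containing a bright concentric ellipsoidal ventricle whose analytic
#' volume is \code{lesion_fraction} times the brain volume. Defaults follow
#' the quantification geometry: 228 px/mm, 50 um section thickness, 300 um
#' section spacing.
#'
#' @param lesion_fraction ventricle/brain volume ratio in [0, 1].
#' @param n_slices number of sections; \code{NULL} spans the whole brain.
#' @param px_per_mm spatial sampling of the scanned sections.
#' @param slice_thickness section thickness in um.
#' @param slice_spacing distance between consecutive sections in um.
#' @param rng_seed integer seed for pixel noise.
#' @param brain_semiaxes_mm ellipsoid semi-axes \code{c(ap, ml, dv)} in mm.
#' @param noise_sd grayscale noise sd (intensities: background ~0.05,
#'   tissue ~0.55, ventricle ~0.95).
#' @return an object of class \code{histology_stack}; analytic brain and
#'   ventricle volumes are stored in \code{$analytic}.
#' @export
simulate_histology <- function(lesion_fraction, n_slices = NULL,
                               px_per_mm = 228, slice_thickness = 50,
                               slice_spacing = 300, rng_seed = 1L,
                               brain_semiaxes_mm = c(ap = 3.0, ml = 2.5,
                                                     dv = 2.0),
                               noise_sd = 0.01) {
  stopifnot(lesion_fraction >= 0, lesion_fraction <= 1, px_per_mm > 0)
  set.seed(as.integer(rng_seed))
  a <- brain_semiaxes_mm[["ap"]]; b <- brain_semiaxes_mm[["ml"]]
  cc <- brain_semiaxes_mm[["dv"]]
  sp_mm <- slice_spacing / 1000
  if (is.null(n_slices)) n_slices <- floor(2 * a / sp_mm) + 1
  # slice AP positions centered on the brain
  z <- (seq_len(n_slices) - (n_slices + 1) / 2) * sp_mm
  s <- lesion_fraction^(1 / 3)  # concentric ventricle scale factor
  margin_mm <- 0.5
  wpx <- ceiling(2 * (b + margin_mm) * px_per_mm)
  hpx <- ceiling(2 * (cc + margin_mm) * px_per_mm)
  xs <- (seq_len(wpx) - (wpx + 1) / 2) / px_per_mm
  ys <- (seq_len(hpx) - (hpx + 1) / 2) / px_per_mm
  X2 <- matrix((xs / b)^2, hpx, wpx, byrow = TRUE)
  Y2 <- matrix((ys / cc)^2, hpx, wpx)
  slices <- vector("list", n_slices)
  for (k in seq_len(n_slices)) {
    rem <- 1 - (z[k] / a)^2
    img <- matrix(0.05, hpx, wpx)
    if (rem > 0) {
      img[X2 + Y2 <= rem] <- 0.55
      if (s > 0) {
        rem_v <- s^2 - (z[k] / a)^2
        if (rem_v > 0) img[X2 + Y2 <= rem_v] <- 0.95
      }
    }
    slices[[k]] <- img + matrix(rnorm(hpx * wpx, sd = noise_sd), hpx, wpx)
  }
  structure(list(slices = slices, px_per_mm = px_per_mm,
                 slice_thickness = slice_thickness,
                 slice_spacing = slice_spacing,
                 analytic = list(
                   brain_volume_mm3 = 4 / 3 * pi * a * b * cc,
                   ventricle_volume_mm3 = lesion_fraction * 4 / 3 * pi * a * b * cc,
                   lesion_fraction = lesion_fraction)),
            class = "histology_stack")
}

#' @export
print.histology_stack <- function(x, ...) {
  cat("<histology_stack> ", length(x$slices), " sections of ",
      nrow(x$slices[[1]]), "x", ncol(x$slices[[1]]), " px at ",
      x$px_per_mm, " px/mm; thickness ", x$slice_thickness,
      " um, spacing ", x$slice_spacing, " um\n", sep = "")
  invisible(x)
}

#' Simulate a feature-level connectivity cohort
#'
#' Generates seed-pair Fisher-z feature vectors directly (bypassing the
#' imaging forward model) for machine-learning checks: interhemispheric
#' couplings are attenuated linearly in the lesion fraction, all features
#' carry additive Gaussian noise.
#'
#' @param n_subjects total subjects; half are controls (lesion 0).
#' @param rng_seed integer seed.
#' @param coupling base coupling matrix.
#' @param kappa attenuation gain of the linear fc-to-lesion map.
#' @param lesion_range range of injured lesion fractions.
#' @param noise_frac noise sd as a fraction of the homotopic Fisher-z
#'   coupling (0.1 = "10% noise").
#' @param contrasts contrast names to replicate the feature block over.
#' @return list with \code{features} (subjects x features matrix with
#'   canonical names), \code{labels} (factor control/injured) and
#'   \code{lesion_fraction}.
#' @export
simulate_connectivity_features <- function(n_subjects = 20, rng_seed = 1L,
                                           coupling = default_coupling_matrix(),
                                           kappa = 1,
                                           lesion_range = c(0.2, 1),
                                           noise_frac = 0.1,
                                           contrasts = c("HbO2", "HbR")) {
  set.seed(as.integer(rng_seed))
  # canonical feature ordering: sorted seed names, upper-triangle pairs
  seed_names <- sort(rownames(coupling))
  coupling <- coupling[seed_names, seed_names]
  hemi <- sub("^.*_", "", seed_names)
  inter <- outer(hemi, hemi, "!=")
  ut <- upper.tri(coupling)
  pair_names <- outer(seed_names, seed_names,
                      function(a, b) paste(a, b, sep = "_"))[ut]
  n_inj <- floor(n_subjects / 2)
  lesion <- c(rep(0, n_subjects - n_inj),
              runif(n_inj, lesion_range[1], lesion_range[2]))
  labels <- factor(rep(c("control", "injured"), c(n_subjects - n_inj, n_inj)),
                   levels = c("control", "injured"))
  z_homo <- fisher_z(max(coupling[inter]))
  feats <- vector("list", length(contrasts))
  for (ci in seq_along(contrasts)) {
    M <- matrix(NA_real_, n_subjects, sum(ut))
    for (i in seq_len(n_subjects)) {
      Ci <- coupling
      fac <- min(1, max(0, 1 - kappa * lesion[i]))
      Ci[inter] <- Ci[inter] * fac
      z <- fisher_z(Ci[ut])
      M[i, ] <- z + rnorm(length(z), sd = noise_frac * z_homo)
    }
    colnames(M) <- paste(contrasts[ci], pair_names, sep = "_")
    feats[[ci]] <- M
  }
  list(features = do.call(cbind, feats), labels = labels,
       lesion_fraction = lesion)
}
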