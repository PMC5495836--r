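# Preprocessing of chromophore movies: projective registration to a
# reference atlas, GLM nuisance regression against physiological traces and
# the global cortical signal, spatial Gaussian smoothing, and zero-phase
# Butterworth band-pass filtering of the low-frequency hemodynamic band.

#' Fit a projective (homography) transform from control points
#'
#' Normalized direct linear transform: both point sets are translated and
#' scaled to mean distance sqrt(2) from the origin, the homography is the
#' right singular vector of the DLT system, and the normalization is
#' undone. The returned matrix is scaled so \code{H[3,3] = 1}.
#'
#' @param src,dst n x 2 matrices of \code{(row, col)} control points,
#'   n >= 4, not all collinear.
#' @return an object of class \code{projective_transform} with elements
#'   \code{H} (3 x 3) and \code{rms} (reprojection root-mean-square error).
#' @export
fit_projective <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 4 || nrow(dst) != nrow(src) || ncol(src) != 2 ||
      ncol(dst) != 2)
    stop("at least 4 source/target control-point pairs are required")
  normalize <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    T <- rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
    list(T = T, p = cbind(s * (p[, 1] - ctr[1]), s * (p[, 2] - ctr[2])))
  }
  ns <- normalize(src); nd <- normalize(dst)
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- ns$p[i, 1]; y <- ns$p[i, 2]
    u <- nd$p[i, 1]; v <- nd$p[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  sv <- svd(A, nu = 0, nv = 9)
  if (sv$d[8] < 1e-10 * sv$d[1])
    stop("degenerate control-point configuration (collinear points?)")
  H <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% H %*% ns$T
  if (abs(H[3, 3]) < 1e-12) stop("degenerate homography")
  H <- H / H[3, 3]
  mapped <- apply_homography(H, src)
  rms <- sqrt(mean(rowSums((mapped - dst)^2)))
  structure(list(H = H, rms = rms, control_points = list(src = src, dst = dst)),
            class = "projective_transform")
}

#' @export
print.projective_transform <- function(x, ...) {
  cat("<projective_transform> RMS reprojection error ",
      signif(x$rms, 4), " px\n", sep = "")
  print(signif(x$H, 5))
  invisible(x)
}

#' Apply a homography to points
#'
#' @param H 3 x 3 homography matrix.
#' @param p n x 2 matrix of \code{(row, col)} points.
#' @return n x 2 matrix of mapped points.
#' @export
apply_homography <- function(H, p) {
  p <- as.matrix(p)
  q <- cbind(p, 1) %*% t(H)
  q[, 1:2, drop = FALSE] / q[, 3]
}

#' Warp a chromophore movie with a projective transform
#'
#' Inverse mapping with bilinear interpolation. Output pixels that map
#' outside the source grid are flagged invalid (and excluded from the
#' warped cortex mask).
#'
#' @param movie a \code{chromophore_movie}.
#' @param transform a \code{projective_transform} mapping source to target
#'   coordinates.
#' @param out_dim output \code{c(height, width)}; defaults to the input.
#' @return a warped \code{chromophore_movie}; invalid pixels are NA and
#'   recorded in the movie's \code{mask}.
#' @export
warp_movie <- function(movie, transform, out_dim = movie$dim) {
  stopifnot(inherits(movie, "chromophore_movie"),
            inherits(transform, "projective_transform"))
  h_out <- out_dim[1]; w_out <- out_dim[2]
  h_in <- movie$dim[1]; w_in <- movie$dim[2]
  grid <- cbind(rep(seq_len(h_out), times = w_out),
                rep(seq_len(w_out), each = h_out))
  srcp <- apply_homography(solve(transform$H), grid)
  r <- srcp[, 1]; cl <- srcp[, 2]
  valid <- r >= 1 & r <= h_in & cl >= 1 & cl <= w_in
  r0 <- pmin(pmax(floor(r), 1), h_in - 1)
  c0 <- pmin(pmax(floor(cl), 1), w_in - 1)
  fr <- r - r0; fc <- cl - c0
  i00 <- (c0 - 1) * h_in + r0
  warp_one <- function(M) {
    out <- matrix(NA_real_, h_out * w_out, ncol(M))
    v00 <- M[i00, , drop = FALSE]
    v10 <- M[i00 + 1, , drop = FALSE]
    v01 <- M[i00 + h_in, , drop = FALSE]
    v11 <- M[i00 + h_in + 1, , drop = FALSE]
    W <- (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
      (1 - fr) * fc * v01 + fr * fc * v11
    out[valid, ] <- W[valid, , drop = FALSE]
    out
  }
  mask_out <- matrix(valid, h_out, w_out)
  if (!is.null(movie$mask)) {
    mv <- warp_one(matrix(as.numeric(movie$mask), ncol = 1))
    mask_out <- mask_out & matrix(!is.na(mv) & mv > 0.5, h_out, w_out)
  }
  chromophore_movie(HbO2 = warp_one(movie$HbO2), HbR = warp_one(movie$HbR),
                    dim = c(h_out, w_out), fs = movie$fs,
                    mask = mask_out, residualized = movie$residualized)
}

#' Build the nuisance design matrix
#'
#' Intercept plus standardized physiological regressors resampled to frame
#' times by linear interpolation, optionally plus the standardized global
#' cortical mean of the series being regressed. Collinear columns are
#' dropped with a warning.
#'
#' @param physio a \code{physio_traces} data frame.
#' @param n_frames,fs frame count and rate of the movie.
#' @param regressors character subset of
#'   \code{c("heart_rate","resp_signal","ecg","resp_rate")}.
#' @param global_signal optional numeric vector (length n_frames) to add as
#'   the global-signal regressor.
#' @return design matrix (n_frames x k) with named columns, intercept first.
#' @export
nuisance_design <- function(physio, n_frames, fs,
                            regressors = c("heart_rate", "resp_signal",
                                           "ecg", "resp_rate"),
                            global_signal = NULL) {
  t_out <- (seq_len(n_frames) - 1) / fs
  cols <- list(intercept = rep(1, n_frames))
  for (rg in regressors) {
    if (!rg %in% names(physio)) stop("physio trace '", rg, "' not found")
    v <- approx(physio$t, physio[[rg]], xout = t_out, rule = 2)$y
    s <- sd(v)
    cols[[rg]] <- if (s > 0) (v - mean(v)) / s else v * 0
  }
  if (!is.null(global_signal)) {
    s <- sd(global_signal)
    cols[["global"]] <- if (s > 0) (global_signal - mean(global_signal)) / s
      else global_signal * 0
  }
  X <- do.call(cbind, cols)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_idx <- qrX$pivot[-seq_len(qrX$rank)]
    warning("dropping collinear nuisance regressors: ",
            paste(colnames(X)[drop_idx], collapse = ", "))
    X <- X[, -drop_idx, drop = FALSE]
  }
  X
}

#' Regress physiological nuisance signals out of a chromophore movie
#'
#' Per-pixel ordinary least squares of each chromophore time series on the
#' nuisance design (physiological traces plus the global cortical mean of
#' the chromophore being regressed); the residual movie is returned.
#' Residuals are orthogonal to every design column.
#'
#' @param movie a \code{chromophore_movie}.
#' @param physio a \code{physio_traces}.
#' @param mask a \code{cortex_mask} (or logical matrix) defining the cortex
#'   pixels used for the global signal.
#' @param regressors physiological regressors to include.
#' @param global include the global cortical mean regressor.
#' @return the residual \code{chromophore_movie} (flag
#'   \code{residualized = TRUE}).
#' @export
regress_nuisance <- function(movie, physio, mask,
                             regressors = c("heart_rate", "resp_signal",
                                            "ecg", "resp_rate"),
                             global = TRUE) {
  stopifnot(inherits(movie, "chromophore_movie"))
  m <- if (inherits(mask, "cortex_mask")) mask$mask else mask
  stopifnot(is.matrix(m), all(dim(m) == movie$dim))
  if (!any(m)) stop("cortex mask is empty")
  in_idx <- which(m)
  nt <- ncol(movie$HbO2)
  out <- movie
  for (ch in c("HbO2", "HbR")) {
    Y <- movie[[ch]]
    gs <- if (global) colMeans(Y[in_idx, , drop = FALSE]) else NULL
    X <- nuisance_design(physio, nt, movie$fs, regressors,
                         global_signal = gs)
    XtX <- crossprod(X)
    YX <- Y %*% X                       # npx x k
    Mcoef <- YX %*% solve(XtX)          # npx x k (= t(beta))
    out[[ch]] <- Y - Mcoef %*% t(X)
  }
  out$residualized <- TRUE
  out
}

# Separable truncated-Gaussian smoothing operator along one dimension,
# returned as a dense n x n band matrix (unnormalized).
gauss_band <- function(n, size, sigma) {
  half <- (size - 1) %/% 2
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  S <- matrix(0, n, n)
  for (d in (-half):half) {
    idx <- seq_len(n - abs(d))
    if (d >= 0) S[cbind(idx + d, idx)] <- k[d + half + 1]
    else S[cbind(idx, idx - d)] <- k[-d + half + 1]
  }
  S
}

#' Spatially smooth a chromophore movie
#'
#' Per-frame 2-D Gaussian convolution with a truncated \code{size x size}
#' kernel of standard deviation \code{sigma} pixels, normalized to unit sum.
#' Near borders (and near the cortex-mask edge when a mask is present) the
#' kernel is renormalized over the available in-mask support, so constant
#' images are preserved exactly.
#'
#' @param movie a \code{chromophore_movie}.
#' @param size odd kernel size in pixels (default 11).
#' @param sigma kernel standard deviation in pixels (default 3).
#' @param use_mask restrict support to the movie's mask if present.
#' @return the smoothed \code{chromophore_movie}.
#' @export
smooth_spatial <- function(movie, size = 11, sigma = 3, use_mask = TRUE) {
  stopifnot(inherits(movie, "chromophore_movie"), size %% 2 == 1)
  h <- movie$dim[1]; w <- movie$dim[2]
  if (size >= h || size >= w) stop("kernel must be smaller than the image")
  Sh <- gauss_band(h, size, sigma)
  Sw <- gauss_band(w, size, sigma)
  m <- if (use_mask && !is.null(movie$mask)) movie$mask
       else matrix(TRUE, h, w)
  supp <- matrix(as.numeric(m), h, w)
  denom <- Sh %*% supp %*% t(Sw)      # kernel mass over in-mask support
  denom[denom == 0] <- 1
  nt <- ncol(movie$HbO2)
  smooth_one <- function(M) {
    M[!as.vector(m), ] <- 0
    A <- M
    dim(A) <- c(h, w * nt)
    A <- Sh %*% A                      # along rows
    dim(A) <- c(h, w, nt)
    A <- aperm(A, c(2, 1, 3))
    dim(A) <- c(w, h * nt)
    A <- Sw %*% A                      # along cols
    dim(A) <- c(w, h, nt)
    A <- aperm(A, c(2, 1, 3))
    dim(A) <- c(h * w, nt)
    A <- A / as.vector(denom)
    A[!as.vector(m), ] <- M[!as.vector(m), ]
    A
  }
  out <- movie
  out$HbO2 <- smooth_one(movie$HbO2)
  out$HbR <- smooth_one(movie$HbR)
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' Fourth-order (by default) Butterworth band-pass applied forward and
#' backward (squared magnitude response, zero phase). The temporal mean is
#' removed first, and each series is extended by odd reflection before
#' filtering to suppress edge transients; the effective settling length is
#' about \code{fs / low} samples at each end.
#'
#' @param movie a \code{chromophore_movie}, or a plain matrix of series in
#'   rows (then \code{fs} must be given).
#' @param low,high band edges in Hz (defaults 0.009 and 0.08, the canonical
#'   resting-state band).
#' @param order filter order (the forward-backward pass doubles the
#'   effective magnitude order).
#' @param fs sampling rate, required when \code{movie} is a matrix.
#' @return the filtered object (same class as the input).
#' @export
bandpass <- function(movie, low = 0.009, high = 0.08, order = 4, fs = NULL) {
  is_movie <- inherits(movie, "chromophore_movie")
  if (is_movie) fs <- movie$fs
  if (is.null(fs)) stop("`fs` is required when filtering a plain matrix")
  if (high >= fs / 2)
    stop("high band edge (", high, " Hz) must be below the Nyquist rate ",
         fs / 2, " Hz")
  if (low <= 0 || low >= high) stop("band edges must satisfy 0 < low < high")
  nt <- if (is_movie) ncol(movie$HbO2) else ncol(movie)
  settle <- ceiling(fs / low)
  if (nt < 3 * settle)
    stop("record too short for the ", low, " Hz cutoff: need at least ",
         3 * settle, " samples, got ", nt)
  bt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  npad <- min(nt - 1, 3 * settle)
  filt <- function(M) {
    M <- M - rowMeans(M)
    cpp_filtfilt_rows(M, bt$b, bt$a, as.integer(npad))
  }
  if (!is_movie) return(filt(as.matrix(movie)))
  out <- movie
  out$HbO2 <- filt(movie$HbO2)
  out$HbR <- filt(movie$HbR)
  out
}
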