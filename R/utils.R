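`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child RNG seed
#'
#' Mixes a master seed with a stream index so that parallel entities
#' (subjects, replicates) get independent, reproducible streams. The result
#' always fits in a 32-bit signed integer.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index.
#' @return an integer seed.
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), is.numeric(index), length(master) == 1L)
  v <- (abs(as.double(master)) * 48271 + as.double(index) * 40503 + 1) %%
    2147483647
  as.integer(v)
}

#' Moore-Penrose pseudoinverse
#'
#' SVD-based pseudoinverse; singular values below \code{tol} times the
#' largest are treated as zero.
#'
#' @param A numeric matrix.
#' @param tol relative singular-value cutoff.
#' @return the pseudoinverse of \code{A}.
#' @export
pinv <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Label connected components of a binary image
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default) neighbourhood.
#' @return integer matrix of component labels; background pixels are 0.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  storage.mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  cpp_label_components(mask, as.integer(connectivity))
}

#' Fill holes in a binary mask
#'
#' Background regions not connected to the image border (4-connectivity on
#' the background, the dual of 8-connected foreground) are set to foreground.
#'
#' @param mask logical matrix.
#' @return logical matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "logical"
  bg <- cpp_label_components(!mask, 4L)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0]
  mask | (bg > 0 & !(bg %in% border_labels))
}

#' Otsu threshold of a grayscale image
#'
#' Maximizes between-class variance over a histogram of \code{n_bins} bins.
#'
#' @param x numeric vector or matrix of intensities.
#' @param n_bins histogram resolution.
#' @return the threshold value (foreground is \code{> threshold}).
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  br <- seq(r[1], r[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  # empty gaps give a plateau of maximizers; take its centre
  mean(mids[between >= max(between) - 1e-12 * max(between)])
}

# Band-limit the columns of a matrix by zeroing FFT coefficients outside
# [low, high] Hz (two-sided); the DC and out-of-band bins are removed exactly.
band_limit_columns <- function(x, fs, low, high) {
  x <- as.matrix(x)
  n <- nrow(x)
  freq <- (seq_len(n) - 1) / n * fs
  freq <- pmin(freq, fs - freq)  # two-sided
  keep <- freq >= low & freq <= high
  xf <- mvfft(x)
  xf[!keep, ] <- 0
  Re(mvfft(xf, inverse = TRUE)) / n
}

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 ||
      x != round(x))
    stop(sprintf("`%s` must be a positive integer scalar", name),
         call. = FALSE)
  invisible(as.integer(x))
}
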