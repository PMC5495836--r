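# Modified Beer-Lambert spectral unmixing.
#
# Reflectance is converted to differential optical density
# dOD = log10(I0 / I) per wavelength, and the linear system
# dOD(lambda, t) = sum_i eps_i(lambda) C_i(t) D(lambda) is solved for the
# two chromophore concentration changes (HbO2, HbR) by Moore-Penrose
# pseudoinverse. Base-10 OD is paired with base-10 molar extinction
# coefficients; the forward and inverse models share the same convention,
# which the round-trip tests enforce.

#' Convert a reflectance stack to optical density
#'
#' \eqn{\Delta OD = \log_{10}(I_0 / I)} elementwise. The reference
#' \eqn{I_0} is either the stored illumination reference of the stack or
#' the temporal mean of each pixel (the usual choice for differential
#' resting-state analysis when no reference frame was acquired).
#'
#' @param stack an \code{optical_stack}.
#' @param reference \code{"stored"} (default when the stack carries an
#'   \code{I0}) or \code{"temporal_mean"}.
#' @return an object of class \code{od_movie}: per-wavelength
#'   (height*width) x n_frames matrices of dimensionless absorbance.
#' @export
optical_density <- function(stack,
                            reference = c("stored", "temporal_mean")) {
  stopifnot(inherits(stack, "optical_stack"))
  reference <- match.arg(reference)
  if (reference == "stored" && is.null(stack$I0))
    reference <- "temporal_mean"
  od <- vector("list", length(stack$wavelengths))
  names(od) <- names(stack$intensities)
  for (l in seq_along(stack$intensities)) {
    I <- stack$intensities[[l]]
    n_bad <- sum(I <= 0)
    if (n_bad > 0)
      stop("non-positive intensities at ", stack$wavelengths[l], " nm: ",
           n_bad, " pixel-frames; clean or clamp the stack first")
    I0 <- if (reference == "stored") stack$I0[l] else rowMeans(I)
    if (any(I0 <= 0)) stop("non-positive reference intensity I0")
    od[[l]] <- (log(I0) - log(I)) / log(10)
  }
  structure(list(od = od, wavelengths = stack$wavelengths, fs = stack$fs,
                 dim = stack$dim, mask = stack$mask),
            class = "od_movie")
}

#' @export
print.od_movie <- function(x, ...) {
  cat("<od_movie> ", x$dim[1], "x", x$dim[2], " px, ", ncol(x$od[[1]]),
      " frames, wavelengths ", paste(x$wavelengths, collapse = "/"),
      " nm\n", sep = "")
  invisible(x)
}

#' Build the extinction system and its pseudoinverse
#'
#' Forms the corrected system matrix
#' \eqn{E = \mathrm{diag}(w) [\epsilon_i(\lambda) D(\lambda)]} (in OD per
#' uM, i.e. the molar coefficients are scaled by 1e-6) and caches its
#' Moore-Penrose pseudoinverse. Sensor/LED spectral response is reduced to
#' the per-wavelength scalar weights \code{correction_weights} of the
#' configuration.
#'
#' @param cfg an \code{optics_config} with at least 2 wavelengths.
#' @return an object of class \code{extinction_system} with elements
#'   \code{E} (wavelengths x 2) and \code{pinv} (2 x wavelengths).
#' @export
build_extinction_system <- function(cfg) {
  stopifnot(inherits(cfg, "optics_config"))
  if (length(cfg$wavelengths) < 2)
    stop("at least 2 wavelengths are required to unmix 2 chromophores")
  E <- cfg$extinction * cfg$pathlength * 1e-6  # OD per uM
  E <- E * cfg$correction_weights
  s <- svd(E)
  if (s$d[2] < 1e-10 * s$d[1])
    stop("extinction system is rank deficient; wavelength rows are ",
         "proportional and HbO2/HbR cannot be separated")
  P <- pinv(E)
  if (max(abs(P %*% E - diag(2))) > 1e-10)
    stop("pseudoinverse failed the identity check")
  rownames(P) <- colnames(E)
  structure(list(E = E, pinv = P, wavelengths = cfg$wavelengths),
            class = "extinction_system")
}

#' @export
print.extinction_system <- function(x, ...) {
  cat("<extinction_system> ", nrow(x$E), " wavelengths x ", ncol(x$E),
      " chromophores; condition number ",
      signif(svd(x$E)$d[1] / svd(x$E)$d[2], 4), "\n", sep = "")
  invisible(x)
}

#' Unmix optical density into chromophore concentration changes
#'
#' Per pixel and frame solves the (possibly overdetermined) linear system
#' in the least-squares sense: \eqn{C = E^{+} \Delta OD}. With three
#' wavelengths and two chromophores the residual is orthogonal to the
#' column space of \eqn{E}.
#'
#' @param od an \code{od_movie}.
#' @param system an \code{extinction_system} whose wavelengths match.
#' @param keep_residual also return the per-pixel root-mean-square residual
#'   OD.
#' @return a \code{chromophore_movie} (uM).
#' @export
unmix <- function(od, system, keep_residual = FALSE) {
  stopifnot(inherits(od, "od_movie"), inherits(system, "extinction_system"))
  if (!isTRUE(all.equal(as.numeric(od$wavelengths),
                        as.numeric(system$wavelengths))))
    stop("wavelengths of the OD movie (",
         paste(od$wavelengths, collapse = "/"),
         ") do not match the extinction system (",
         paste(system$wavelengths, collapse = "/"), ")")
  P <- system$pinv
  hbo <- P[1, 1] * od$od[[1]]
  hbr <- P[2, 1] * od$od[[1]]
  for (l in seq_along(od$od)[-1]) {
    hbo <- hbo + P[1, l] * od$od[[l]]
    hbr <- hbr + P[2, l] * od$od[[l]]
  }
  out <- chromophore_movie(HbO2 = hbo, HbR = hbr, dim = od$dim, fs = od$fs,
                           mask = od$mask)
  if (keep_residual) {
    rss <- 0
    for (l in seq_along(od$od)) {
      fit <- system$E[l, 1] * hbo + system$E[l, 2] * hbr
      rss <- rss + rowSums((od$od[[l]] - fit)^2)
    }
    out$residual_rms <- sqrt(rss / (length(od$od) * ncol(hbo)))
  }
  out
}
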