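# Ventricular-volume quantification from serial coronal sections:
# threshold, binarize, fill holes, count pixels, convert with the scan
# resolution, and sum over sections. Fractional (ventricle / brain) volume
# normalizes away brain-size variability and the slice-summation
# convention.

#' Segment a region in one histology section
#'
#' Global threshold (Otsu by default, or a fixed value), binarization, and
#' morphological hole filling.
#'
#' @param slice grayscale image matrix.
#' @param method list: \code{type} = \code{"otsu"} or \code{"fixed"};
#'   \code{value} for the fixed threshold; \code{polarity} =
#'   \code{"bright"} (foreground above threshold, default) or
#'   \code{"dark"}.
#' @param min_contrast minimum intensity range for Otsu segmentation; a
#'   flatter section (noise only, no object) yields an empty mask instead
#'   of a noise split.
#' @return logical mask (possibly empty; an all-background section is not
#'   an error).
#' @export
segment_region <- function(slice, method = list(type = "otsu"),
                           min_contrast = 0.2) {
  stopifnot(is.matrix(slice), length(slice) > 0)
  type <- method$type %||% "otsu"
  polarity <- method$polarity %||% "bright"
  if (type == "otsu" && diff(range(slice)) < min_contrast)
    return(matrix(FALSE, nrow(slice), ncol(slice)))
  thr <- switch(type,
                otsu = otsu_threshold(slice),
                fixed = method$value %||% stop("fixed threshold needs $value"),
                stop("unknown threshold method '", type, "'"))
  mask <- if (polarity == "bright") slice > thr else slice < thr
  fill_holes(mask)
}

#' Volume from per-section masks
#'
#' Pixel counts are converted to areas with the scan resolution and summed
#' over sections: \eqn{V = \sum_k A_k \, d} where \eqn{d} is the section
#' thickness (the literal slice-summation rule) or the section spacing
#' (Cavalieri estimation; use this when sections sample a continuous
#' structure). Fractional volumes cancel the convention when it is applied
#' consistently to numerator and denominator.
#'
#' @param masks list of logical masks, one per section.
#' @param stack a \code{histology_stack} carrying \code{px_per_mm},
#'   \code{slice_thickness} and \code{slice_spacing} (um).
#' @param convention \code{"thickness"} (default) or \code{"spacing"}.
#' @return volume in mm^3.
#' @export
volume_from_masks <- function(masks, stack,
                              convention = c("thickness", "spacing")) {
  convention <- match.arg(convention)
  stopifnot(inherits(stack, "histology_stack"))
  if (is.null(stack$px_per_mm) || is.null(stack$slice_thickness))
    stop("stack metadata (px_per_mm / slice thickness) missing")
  d_mm <- switch(convention,
                 thickness = stack$slice_thickness / 1000,
                 spacing = stack$slice_spacing / 1000)
  areas <- vapply(masks, sum, numeric(1)) / stack$px_per_mm^2
  sum(areas) * d_mm
}

#' Fractional volume
#'
#' @param ventricle ventricular volume, mm^3.
#' @param brain brain volume, mm^3 (> 0).
#' @return the ratio; values above 1 are flagged with a warning.
#' @export
fractional_volume <- function(ventricle, brain) {
  if (!is.finite(brain) || brain <= 0) stop("brain volume must be positive")
  if (ventricle < 0) stop("ventricular volume must be non-negative")
  fr <- ventricle / brain
  if (fr > 1) warning("fractional volume exceeds 1; check the segmentation")
  fr
}

#' Quantify ventricular and brain volume of a histology stack
#'
#' Convenience pipeline: segment the brain silhouette (Otsu) and the
#' bright ventricular region (fixed threshold between the tissue and
#' ventricle intensities by default) on each section, then convert to
#' volumes and the fractional lesion volume.
#'
#' @param stack a \code{histology_stack}.
#' @param ventricle_method,brain_method threshold specs for
#'   \code{\link{segment_region}}.
#' @param convention slice-summation convention, see
#'   \code{\link{volume_from_masks}}.
#' @return list with \code{ventricle_mm3}, \code{brain_mm3},
#'   \code{fraction}, and the per-section masks.
#' @export
quantify_histology <- function(stack,
                               ventricle_method = list(type = "fixed",
                                                       value = 0.75),
                               brain_method = list(type = "otsu"),
                               convention = c("thickness", "spacing")) {
  convention <- match.arg(convention)
  stopifnot(inherits(stack, "histology_stack"))
  vmasks <- lapply(stack$slices, segment_region, method = ventricle_method)
  bmasks <- lapply(stack$slices, segment_region, method = brain_method)
  v <- volume_from_masks(vmasks, stack, convention)
  b <- volume_from_masks(bmasks, stack, convention)
  list(ventricle_mm3 = v, brain_mm3 = b,
       fraction = fractional_volume(v, b),
       ventricle_masks = vmasks, brain_masks = bmasks)
}
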