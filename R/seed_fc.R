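# Seed-based functional connectivity: seed time courses, seed-to-seed and
# seed-to-pixel Pearson correlation, Fisher z transformation, map
# normalization, group one-sample t-maps with FDR height thresholding and
# cluster-extent filtering, homotopic connectivity, and the spatial-extent
# statistic (suprathreshold cortex fraction).

#' Fisher z transform of correlation values
#'
#' \eqn{z = \tfrac{1}{2}\ln\frac{1+r}{1-r}}. Values with \eqn{|r| = 1}
#' (e.g. self-correlation pixels) are clipped to \eqn{\pm(1 - 10^{-7})}
#' before the transform so the result stays finite.
#'
#' @param r correlations in [-1, 1] (vector, matrix or array).
#' @param clip clipping margin at the boundary.
#' @return z values, same shape as \code{r}.
#' @export
fisher_z <- function(r, clip = 1e-7) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("correlations outside [-1, 1]")
  r <- pmin(pmax(r, -(1 - clip)), 1 - clip)
  atanh(r)
}

#' Extract seed time courses
#'
#' Per seed, the unweighted mean over its member pixels at each frame.
#'
#' @param movie a \code{chromophore_movie}.
#' @param atlas a \code{seed_atlas}.
#' @param contrasts which chromophore contrasts to extract.
#' @return an object of class \code{seed_timecourses}: per contrast an
#'   n_frames x n_seeds matrix with seed names as columns.
#' @export
extract_seed_timecourses <- function(movie, atlas,
                                     contrasts = c("HbO2", "HbR")) {
  stopifnot(inherits(movie, "chromophore_movie"),
            inherits(atlas, "seed_atlas"))
  out <- list()
  for (ch in contrasts) {
    M <- movie[[ch]]
    tc <- vapply(atlas$members, function(idx) {
      block <- M[idx, , drop = FALSE]
      if (anyNA(block))
        stop("seed contains invalid (NA) pixels in contrast ", ch)
      colMeans(block)
    }, numeric(ncol(M)))
    out[[ch]] <- tc
  }
  structure(list(tc = out, seed_names = atlas$seed_names, fs = movie$fs),
            class = "seed_timecourses")
}

#' @export
print.seed_timecourses <- function(x, ...) {
  cat("<seed_timecourses> ", length(x$seed_names), " seeds x ",
      nrow(x$tc[[1]]), " frames, contrasts: ",
      paste(names(x$tc), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Seed-to-seed connectivity matrix
#'
#' Pearson correlation between all seed pairs, with Fisher z values.
#'
#' @param tc an n_frames x n_seeds matrix of seed time courses (or a
#'   \code{seed_timecourses}, together with \code{contrast}).
#' @param contrast contrast name used when \code{tc} is a
#'   \code{seed_timecourses}, and recorded in the result.
#' @return an object of class \code{connectivity_matrix} with elements
#'   \code{r}, \code{z}, \code{seed_names}, \code{contrast}.
#' @export
seed_to_seed <- function(tc, contrast = NULL) {
  if (inherits(tc, "seed_timecourses")) {
    contrast <- contrast %||% names(tc$tc)[1]
    tc <- tc$tc[[contrast]]
  }
  tc <- as.matrix(tc)
  if (nrow(tc) < 3) stop("at least 3 frames are required")
  sds <- apply(tc, 2, sd)
  if (any(sds == 0))
    stop("zero-variance seed trace: ",
         paste(colnames(tc)[sds == 0], collapse = ", "))
  r <- cor(tc)
  structure(list(r = r, z = fisher_z(r), seed_names = colnames(tc),
                 contrast = contrast),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", nrow(x$r), " seeds",
      if (!is.null(x$contrast)) paste0(", contrast ", x$contrast), "\n",
      sep = "")
  print(round(x$r, 3))
  invisible(x)
}

#' Homotopic connectivity
#'
#' Fisher z connectivity of each left/right homotopic seed pair.
#'
#' @param m a \code{connectivity_matrix}.
#' @param atlas a \code{seed_atlas} defining the homotopic pairs.
#' @return named numeric vector of z values, one per bilateral pair.
#' @export
homotopic_connectivity <- function(m, atlas) {
  stopifnot(inherits(m, "connectivity_matrix"),
            inherits(atlas, "seed_atlas"))
  if (length(atlas$homotopic_pairs) == 0)
    stop("atlas defines no homotopic pairs")
  vapply(atlas$homotopic_pairs, function(pr) {
    if (!all(pr %in% m$seed_names))
      stop("missing hemisphere partner for pair (",
           paste(pr, collapse = ", "), ")")
    m$z[pr[1], pr[2]]
  }, numeric(1))
}

#' Seed-to-pixel correlation map
#'
#' Pearson correlation of every cortex pixel's time course with a seed time
#' course, Fisher z transformed, then normalized to zero mean and unit
#' standard deviation over the valid in-mask pixels. Zero-variance pixels
#' are marked invalid and excluded from the normalization.
#'
#' @param movie_mat (height*width) x n_frames matrix of one contrast.
#' @param seed_trace numeric vector of length n_frames.
#' @param mask a \code{cortex_mask} or logical matrix.
#' @param normalize normalize the map (mean 0, sd 1 in-mask).
#' @return an object of class \code{fc_map}: \code{values} is a full-length
#'   vector (height*width) with NA outside the mask and at invalid pixels.
#' @export
seed_to_pixel_map <- function(movie_mat, seed_trace, mask, normalize = TRUE) {
  m <- if (inherits(mask, "cortex_mask")) mask$mask else mask
  npx <- nrow(movie_mat)
  stopifnot(length(m) == npx, length(seed_trace) == ncol(movie_mat))
  if (sd(seed_trace) == 0) stop("zero-variance seed trace")
  in_idx <- which(m)
  Y <- movie_mat[in_idx, , drop = FALSE]
  nt <- ncol(Y)
  Yc <- Y - rowMeans(Y)
  ss <- sqrt(rowSums(Yc^2))
  sc <- seed_trace - mean(seed_trace)
  sn <- sqrt(sum(sc^2))
  valid <- ss > 0 & is.finite(ss)
  r <- rep(NA_real_, length(in_idx))
  r[valid] <- (Yc[valid, , drop = FALSE] %*% sc) / (ss[valid] * sn)
  z <- fisher_z(r)
  if (normalize) {
    mu <- mean(z[valid])
    sdev <- sd(z[valid])
    if (!is.finite(sdev) || sdev == 0)
      stop("cannot normalize a constant correlation map")
    z <- (z - mu) / sdev
  }
  values <- rep(NA_real_, npx)
  values[in_idx] <- z
  structure(list(values = values, dim = dim(m), mask = m,
                 normalized = normalize),
            class = "fc_map")
}

#' @export
print.fc_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat("<fc_map> ", x$dim[1], "x", x$dim[2], " px, ", length(v),
      " valid pixels, range [", signif(min(v), 3), ", ",
      signif(max(v), 3), "]",
      if (isTRUE(x$normalized)) ", normalized", "\n", sep = "")
  invisible(x)
}

#' All seed-to-pixel maps of one contrast in a single pass
#'
#' Equivalent to calling \code{\link{seed_to_pixel_map}} for every seed,
#' but standardizes the pixel time series once, so the cost is one matrix
#' product for all seeds.
#'
#' @param movie_mat (height*width) x n_frames matrix of one contrast.
#' @param tc n_frames x n_seeds matrix of seed time courses.
#' @param mask a \code{cortex_mask} or logical matrix.
#' @param normalize normalize each map (mean 0, sd 1 in-mask).
#' @return named list of \code{fc_map} objects, one per seed.
#' @export
seed_to_pixel_maps <- function(movie_mat, tc, mask, normalize = TRUE) {
  m <- if (inherits(mask, "cortex_mask")) mask$mask else mask
  tc <- as.matrix(tc)
  stopifnot(length(m) == nrow(movie_mat), nrow(tc) == ncol(movie_mat))
  in_idx <- which(m)
  Y <- movie_mat[in_idx, , drop = FALSE]
  Yc <- Y - rowMeans(Y)
  ss <- sqrt(rowSums(Yc^2))
  valid <- ss > 0 & is.finite(ss)
  Tc <- sweep(tc, 2, colMeans(tc))
  tn <- sqrt(colSums(Tc^2))
  if (any(tn == 0)) stop("zero-variance seed trace")
  R <- (Yc %*% Tc) / outer(ss, tn)
  R[!valid, ] <- NA_real_
  out <- vector("list", ncol(tc))
  names(out) <- colnames(tc)
  for (j in seq_len(ncol(tc))) {
    z <- fisher_z(R[, j])
    if (normalize) {
      mu <- mean(z[valid]); sdev <- sd(z[valid])
      if (!is.finite(sdev) || sdev == 0)
        stop("cannot normalize a constant correlation map")
      z <- (z - mu) / sdev
    }
    values <- rep(NA_real_, length(m))
    values[in_idx] <- z
    out[[j]] <- structure(list(values = values, dim = dim(m), mask = m,
                               normalized = normalize),
                          class = "fc_map")
  }
  out
}

#' Group one-sample t-map
#'
#' Per pixel, a two-tailed one-sample t test of the subjects' (normalized)
#' z values against zero, df = n - 1. Pixels with fewer than 3 valid
#' subjects, or with zero variance around a non-zero mean, are invalid; a
#' pixel where every subject is exactly zero is a genuine null (t = 0,
#' p = 1).
#'
#' @param maps list of \code{fc_map} objects, one per subject, on a common
#'   mask.
#' @return an object of class \code{group_map_stats} with \code{t_map},
#'   \code{p_map} (full-length vectors), \code{n}, \code{dim}, \code{mask}.
#' @export
group_tmap <- function(maps) {
  stopifnot(length(maps) >= 3, all(vapply(maps, inherits, TRUE, "fc_map")))
  V <- vapply(maps, function(m) m$values, numeric(length(maps[[1]]$values)))
  mask <- maps[[1]]$mask
  nv <- rowSums(!is.na(V))
  mu <- rowMeans(V, na.rm = TRUE)
  sdv <- apply(V, 1, sd, na.rm = TRUE)
  t_map <- p_map <- rep(NA_real_, nrow(V))
  ok <- nv >= 3 & is.finite(sdv) & sdv > 0
  t_map[ok] <- mu[ok] / (sdv[ok] / sqrt(nv[ok]))
  p_map[ok] <- 2 * pt(-abs(t_map[ok]), df = nv[ok] - 1)
  null_px <- nv >= 3 & sdv == 0 & mu == 0
  t_map[null_px] <- 0
  p_map[null_px] <- 1
  structure(list(t_map = t_map, p_map = p_map, n = length(maps),
                 dim = maps[[1]]$dim, mask = mask),
            class = "group_map_stats")
}

#' Height-threshold and cluster-extent filter a group map
#'
#' Benjamini-Hochberg FDR over the in-mask p values at level \code{q}
#' defines the height mask; its connected components are labeled and
#' clusters with fewer pixels than \code{extent_frac} times the number of
#' height-surviving pixels are removed. The spatial extent is the ratio of
#' surviving pixels to cortex-mask pixels.
#'
#' @param stats a \code{group_map_stats}.
#' @param q FDR level (default 0.05).
#' @param extent_frac minimum cluster size as a fraction of the
#'   height-surviving pixel count (default 0.05).
#' @param connectivity 4 or 8 (default) for cluster labeling.
#' @return \code{stats} augmented with \code{supra_mask} (logical matrix),
#'   \code{clusters} (data frame of surviving cluster sizes),
#'   \code{spatial_extent}, and the thresholds used.
#' @export
threshold_map <- function(stats, q = 0.05, extent_frac = 0.05,
                          connectivity = 8) {
  stopifnot(inherits(stats, "group_map_stats"))
  mask <- stats$mask
  n_cortex <- sum(mask)
  in_idx <- which(as.vector(mask) & !is.na(stats$p_map))
  height <- matrix(FALSE, stats$dim[1], stats$dim[2])
  if (length(in_idx) > 0) {
    res <- bh_fdr(stats$p_map[in_idx], q)
    height[in_idx[res$rejected]] <- TRUE
  }
  n_height <- sum(height)
  lab <- label_components(height, connectivity)
  sizes <- tabulate(lab[lab > 0])
  min_size <- extent_frac * n_height
  keep <- which(sizes >= min_size)
  supra <- matrix(lab %in% keep & lab > 0, stats$dim[1], stats$dim[2])
  clusters <- data.frame(label = keep, size = sizes[keep])
  stats$supra_mask <- supra
  stats$clusters <- clusters
  stats$n_height <- n_height
  stats$spatial_extent <- if (n_cortex > 0) sum(supra) / n_cortex else 0
  stats$q <- q
  stats$extent_frac <- extent_frac
  stats
}

#' @export
print.group_map_stats <- function(x, ...) {
  cat("<group_map_stats> n = ", x$n, " subjects", sep = "")
  if (!is.null(x$spatial_extent))
    cat(", ", x$n_height, " height-surviving px, spatial extent ",
        signif(100 * x$spatial_extent, 4), "%", sep = "")
  cat("\n")
  invisible(x)
}

#' Per-seed spatial extent of group connectivity maps
#'
#' For every seed and contrast, forms the subjects' normalized seed-to-pixel
#' maps, the group one-sample t-map, applies the FDR + cluster-extent
#' threshold and records the spatial extent.
#'
#' @param subject_movies list of preprocessed \code{chromophore_movie}
#'   objects (one per subject in the group).
#' @param atlas a \code{seed_atlas}.
#' @param contrasts contrasts to analyze.
#' @param q,extent_frac,connectivity see \code{\link{threshold_map}}.
#' @return data frame with columns \code{seed}, \code{contrast},
#'   \code{extent}.
#' @export
spatial_extent_by_network <- function(subject_movies, atlas,
                                      contrasts = c("HbO2", "HbR"),
                                      q = 0.05, extent_frac = 0.05,
                                      connectivity = 8) {
  maps <- group_fc_maps(subject_movies, atlas, contrasts)
  spatial_extent_from_maps(maps, q = q, extent_frac = extent_frac,
                           connectivity = connectivity)
}

#' Subjects' normalized seed-to-pixel maps for every seed and contrast
#'
#' @param subject_movies list of preprocessed \code{chromophore_movie}s.
#' @param atlas a \code{seed_atlas}.
#' @param contrasts contrasts to analyze.
#' @return nested list \code{maps[[contrast]][[seed]]} = list of
#'   \code{fc_map} per subject.
#' @export
group_fc_maps <- function(subject_movies, atlas,
                          contrasts = c("HbO2", "HbR")) {
  maps <- list()
  for (ch in contrasts) maps[[ch]] <-
    setNames(vector("list", length(atlas$seed_names)), atlas$seed_names)
  for (s in seq_along(subject_movies)) {
    mv <- subject_movies[[s]]
    tcs <- extract_seed_timecourses(mv, atlas, contrasts)
    for (ch in contrasts) {
      smaps <- seed_to_pixel_maps(mv[[ch]], tcs$tc[[ch]], atlas$mask)
      for (sn in atlas$seed_names)
        maps[[ch]][[sn]][[s]] <- smaps[[sn]]
    }
  }
  maps
}

#' Spatial extents from precomputed group maps
#'
#' @param maps nested list as returned by \code{\link{group_fc_maps}}.
#' @param q,extent_frac,connectivity see \code{\link{threshold_map}}.
#' @return data frame with columns \code{seed}, \code{contrast},
#'   \code{extent}.
#' @export
spatial_extent_from_maps <- function(maps, q = 0.05, extent_frac = 0.05,
                                     connectivity = 8) {
  out <- NULL
  for (ch in names(maps)) {
    for (sn in names(maps[[ch]])) {
      gs <- threshold_map(group_tmap(maps[[ch]][[sn]]), q, extent_frac,
                          connectivity)
      out <- rbind(out, data.frame(seed = sn, contrast = ch,
                                   extent = gs$spatial_extent))
    }
  }
  out
}
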