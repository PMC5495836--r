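# End-to-end orchestration: simulate a cohort, run every subject through
# unmixing and preprocessing, compute seed connectivity, group maps and
# spatial extents, group statistics, and the machine-learning stages;
# write all artifacts with a checksummed manifest.

#' Pipeline configuration
#'
#' A single serializable document holding every stage parameter. Stage
#' toggles allow any preprocessing step to be skipped; the analysis order
#' is fixed: unmix, nuisance regression, spatial smoothing, band-pass,
#' seed analysis.
#'
#' @param n_control,n_injured cohort sizes.
#' @param rng_seed master seed for the whole run.
#' @param design named list of \code{\link{cohort_design}} overrides
#'   (e.g. \code{list(height = 64, width = 64)}).
#' @param regressors physiological regressors for the GLM stage.
#' @param global_signal include the global cortical mean regressor.
#' @param smooth_size,smooth_sigma Gaussian kernel parameters (px).
#' @param band band-pass edges in Hz.
#' @param filter_order Butterworth order.
#' @param q,extent_frac,connectivity thresholding parameters.
#' @param stages logical toggles: \code{regress}, \code{smooth},
#'   \code{bandpass}.
#' @param run_ml run the SVM/ANN stage.
#' @param svm_k,svm_repeats,svm_cost_grid,svm_sigma_grid,svm_inner_k SVM
#'   cross-validation settings.
#' @param ann_hidden,ann_k ANN settings.
#' @param write_maps write group t-maps as TIFF images.
#' @return a list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(n_control = 8, n_injured = 5, rng_seed = 1L,
                            design = list(),
                            regressors = c("heart_rate", "resp_signal",
                                           "ecg", "resp_rate"),
                            global_signal = TRUE,
                            smooth_size = 11, smooth_sigma = 3,
                            band = c(0.009, 0.08), filter_order = 4,
                            q = 0.05, extent_frac = 0.05, connectivity = 8,
                            stages = list(regress = TRUE, smooth = TRUE,
                                          bandpass = TRUE),
                            run_ml = TRUE,
                            svm_k = 10, svm_repeats = 10,
                            svm_cost_grid = 2^seq(-5, 15, by = 2),
                            svm_sigma_grid = 2^seq(-3, 9, by = 2),
                            svm_inner_k = 5,
                            ann_hidden = 20, ann_k = NULL,
                            write_maps = TRUE) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  d <- do.call(cohort_design, cfg$design)
  if (cfg$band[2] >= d$fs / 2)
    stop("band high edge (", cfg$band[2],
         " Hz) must be below the Nyquist rate ", d$fs / 2, " Hz")
  if (cfg$band[1] <= 0 || cfg$band[1] >= cfg$band[2])
    stop("band edges must satisfy 0 < low < high")
  if (cfg$smooth_size %% 2 != 1) stop("smooth_size must be odd")
  stopifnot(cfg$q > 0, cfg$q < 1, cfg$extent_frac >= 0,
            cfg$connectivity %in% c(4, 8))
  invisible(cfg)
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path file path; format chosen by extension.
#' @return a \code{pipeline_config}.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Preprocess one subject's stack into an analysis-ready movie
#'
#' Optical density, pseudoinverse unmixing, then the configured subset of
#' nuisance regression, spatial smoothing and band-pass filtering, in that
#' order.
#'
#' @param stack an \code{optical_stack}.
#' @param physio the subject's \code{physio_traces}.
#' @param mask the \code{cortex_mask}.
#' @param cfg a \code{pipeline_config}.
#' @param optics the \code{optics_config} used for the extinction system.
#' @return a preprocessed \code{chromophore_movie}.
#' @export
process_subject <- function(stack, physio, mask, cfg, optics) {
  system <- build_extinction_system(optics)
  movie <- unmix(optical_density(stack), system)
  movie$mask <- mask$mask
  if (isTRUE(cfg$stages$regress))
    movie <- regress_nuisance(movie, physio, mask,
                              regressors = cfg$regressors,
                              global = cfg$global_signal)
  if (isTRUE(cfg$stages$smooth))
    movie <- smooth_spatial(movie, cfg$smooth_size, cfg$smooth_sigma)
  if (isTRUE(cfg$stages$bandpass))
    movie <- bandpass(movie, cfg$band[1], cfg$band[2], cfg$filter_order)
  movie
}

write_matrix_csv <- function(m, path) {
  write.csv(as.data.frame(m), path, row.names = TRUE)
}

#' Write a map as a 32-bit TIFF image
#'
#' Values are affinely rescaled to [0, 1] for storage; the original range
#' is recorded in a JSON sidecar so the map can be reconstructed.
#'
#' @param values numeric matrix (NAs stored as 0 and flagged).
#' @param path output path (.tif).
#' @export
write_map_tiff <- function(values, path) {
  v <- values
  rng <- range(v, na.rm = TRUE)
  if (!all(is.finite(rng))) rng <- c(0, 1)
  scaled <- (v - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  scaled[!is.finite(scaled)] <- 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  jsonlite::write_json(list(range = rng, na_stored_as = 0),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates the cohort, processes each subject (one at a time, so memory
#' scales with a single subject), computes seed-to-seed connectivity and
#' per-seed group spatial extents, the group statistics table, and the
#' machine-learning stage, writing every artifact plus a checksummed
#' manifest into \code{out_dir}.
#'
#' @param cfg a \code{pipeline_config}.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with the in-memory results: \code{extents},
#'   \code{stats}, \code{features}, \code{svm}, \code{ann},
#'   \code{manifest_path}.
#' @export
run_pipeline <- function(cfg, out_dir) {
  validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    cat(msg, "\n", file = log_path, append = TRUE)
    message(msg)
  }
  artifacts <- character(0)
  add_artifact <- function(p) artifacts <<- c(artifacts, p)
  status <- "complete"
  result <- list()
  tryCatch({
    design <- do.call(cohort_design, cfg$design)
    logf("simulating cohort: ", cfg$n_control, " control + ",
         cfg$n_injured, " injured, ", design$height, "x", design$width,
         " px, ", design$n_frames, " frames")
    cohort <- simulate_cohort(cfg$n_control, cfg$n_injured, design,
                              cfg$rng_seed)
    atlas <- cohort$atlas
    n <- nrow(cohort$subjects)
    contrasts <- c("HbO2", "HbR")
    maps <- list(control = NULL, injured = NULL)
    features <- NULL
    conn_dir <- file.path(out_dir, "connectivity")
    dir.create(conn_dir, showWarnings = FALSE)
    for (i in seq_len(n)) {
      sid <- cohort$subjects$id[i]
      grp <- cohort$subjects$group[i]
      logf("subject ", sid, " (", grp, ")")
      sdat <- subject_data(cohort, i)
      movie <- process_subject(sdat$stack, sdat$physio, cohort$mask, cfg,
                               design$optics)
      tcs <- extract_seed_timecourses(movie, atlas, contrasts)
      conns <- lapply(contrasts, function(ch) seed_to_seed(tcs, ch))
      names(conns) <- contrasts
      for (ch in contrasts) {
        p <- file.path(conn_dir, paste0(sid, "_", ch, "_r.csv"))
        write_matrix_csv(conns[[ch]]$r, p); add_artifact(p)
      }
      features <- rbind(features, build_feature_vector(conns, contrasts))
      smaps <- list()
      for (ch in contrasts)
        smaps[[ch]] <- seed_to_pixel_maps(movie[[ch]], tcs$tc[[ch]],
                                          atlas$mask)
      if (is.null(maps[[grp]])) {
        maps[[grp]] <- lapply(smaps, function(x) lapply(x, list))
      } else {
        for (ch in contrasts) for (sn in atlas$seed_names)
          maps[[grp]][[ch]][[sn]] <-
            c(maps[[grp]][[ch]][[sn]], list(smaps[[ch]][[sn]]))
      }
      rm(sdat, movie); gc(FALSE)
    }
    rownames(features) <- cohort$subjects$id
    fpath <- file.path(out_dir, "features.csv")
    write.csv(data.frame(id = cohort$subjects$id,
                         group = cohort$subjects$group,
                         lesion_fraction = cohort$subjects$lesion_fraction,
                         features, check.names = FALSE),
              fpath, row.names = FALSE)
    add_artifact(fpath)

    logf("group maps and spatial extents")
    extents <- NULL
    map_dir <- file.path(out_dir, "maps")
    if (isTRUE(cfg$write_maps)) dir.create(map_dir, showWarnings = FALSE)
    for (grp in names(maps)) {
      for (ch in contrasts) {
        for (sn in atlas$seed_names) {
          gs <- threshold_map(group_tmap(maps[[grp]][[ch]][[sn]]),
                              cfg$q, cfg$extent_frac, cfg$connectivity)
          extents <- rbind(extents,
                           data.frame(group = grp, contrast = ch, seed = sn,
                                      extent = gs$spatial_extent))
          if (isTRUE(cfg$write_maps)) {
            tm <- matrix(gs$t_map, gs$dim[1], gs$dim[2])
            p <- file.path(map_dir,
                           paste0("tmap_", grp, "_", ch, "_", sn, ".tif"))
            write_map_tiff(tm, p); add_artifact(p)
          }
        }
      }
    }
    epath <- file.path(out_dir, "spatial_extent.csv")
    write.csv(extents, epath, row.names = FALSE); add_artifact(epath)

    logf("group statistics")
    pairs <- lapply(setNames(contrasts, contrasts), function(ch) {
      list(a = extents$extent[extents$group == "control" &
                                extents$contrast == ch],
           b = extents$extent[extents$group == "injured" &
                                extents$contrast == ch])
    })
    stats_tab <- group_comparison_table(pairs, q = cfg$q)
    spath <- file.path(out_dir, "group_stats.csv")
    write.csv(stats_tab, spath, row.names = FALSE); add_artifact(spath)

    svm_rep <- ann_rep <- NULL
    if (isTRUE(cfg$run_ml)) {
      logf("machine learning: SVM classification")
      y <- factor(cohort$subjects$group, c("control", "injured"))
      svm_rep <- cross_validate_svm(features, y, k = cfg$svm_k,
                                    repeats = cfg$svm_repeats,
                                    rng_seed = derive_seed(cfg$rng_seed, 101),
                                    cost_grid = cfg$svm_cost_grid,
                                    sigma_grid = cfg$svm_sigma_grid,
                                    inner_k = cfg$svm_inner_k)
      logf("machine learning: ANN lesion regression")
      ann_rep <- cross_validate_ann(features,
                                    cohort$subjects$lesion_fraction,
                                    k = cfg$ann_k,
                                    rng_seed = derive_seed(cfg$rng_seed, 102),
                                    hidden = cfg$ann_hidden)
      mlpath <- file.path(out_dir, "ml_reports.json")
      jsonlite::write_json(list(
        svm = list(metrics = as.list(svm_rep$metrics),
                   aggregate_metrics = as.list(svm_rep$aggregate_metrics),
                   confusion = as.data.frame.matrix(svm_rep$confusion)),
        ann = list(r = ann_rep$r, rmsep = ann_rep$rmsep,
                   predictions = ann_rep$predictions,
                   targets = ann_rep$targets)),
        mlpath, auto_unbox = TRUE, digits = NA)
      add_artifact(mlpath)
    }
    result <- list(extents = extents, stats = stats_tab,
                   features = features, svm = svm_rep, ann = ann_rep,
                   subjects = cohort$subjects)
  }, error = function(e) {
    status <<- paste("failed:", conditionMessage(e))
    logf("ERROR: ", conditionMessage(e))
  })
  manifest <- list(
    package = "oiconnect",
    version = as.character(utils::packageVersion("oiconnect")),
    status = status,
    rng_seed = cfg$rng_seed,
    config = unclass(cfg)[!vapply(unclass(cfg), is.function, TRUE)],
    artifacts = lapply(artifacts, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  if (status != "complete")
    stop("pipeline run failed; partial manifest written to ", mpath)
  result$manifest_path <- mpath
  invisible(result)
}

#' Summarize a completed run directory
#'
#' Collects the extent, statistics and ML artifacts of a run into summary
#' tables and writes a plain-text report; missing artifacts are listed and
#' a partial report is produced.
#'
#' @param run_dir directory written by \code{\link{run_pipeline}}.
#' @return (invisibly) list of tables; a \code{summary.md} file is written
#'   into the run directory.
#' @export
report_run <- function(run_dir) {
  out <- list(missing = character(0))
  grab_csv <- function(name) {
    p <- file.path(run_dir, name)
    if (file.exists(p)) read.csv(p)
    else { out$missing <<- c(out$missing, name); NULL }
  }
  out$extents <- grab_csv("spatial_extent.csv")
  out$stats <- grab_csv("group_stats.csv")
  mlp <- file.path(run_dir, "ml_reports.json")
  out$ml <- if (file.exists(mlp)) jsonlite::fromJSON(mlp) else NULL
  lines <- c("# Run summary", "")
  if (!is.null(out$extents)) {
    agg <- stats::aggregate(extent ~ group + contrast, out$extents, mean)
    agg$extent_pct <- round(100 * agg$extent, 2)
    lines <- c(lines, "## Mean spatial extent (% of cortex)", "",
               utils::capture.output(print(agg, row.names = FALSE)), "")
    out$extent_summary <- agg
  }
  if (!is.null(out$stats))
    lines <- c(lines, "## Group statistics", "",
               utils::capture.output(print(out$stats, row.names = FALSE)), "")
  if (!is.null(out$ml))
    lines <- c(lines, "## Machine learning", "",
               paste0("SVM mean accuracy: ",
                      signif(out$ml$svm$metrics$Acc, 4)),
               paste0("ANN r = ", signif(out$ml$ann$r, 4),
                      ", RMSEP = ", signif(out$ml$ann$rmsep, 4)), "")
  if (length(out$missing))
    lines <- c(lines, "## Missing artifacts", "", out$missing)
  writeLines(lines, file.path(run_dir, "summary.md"))
  invisible(out)
}
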