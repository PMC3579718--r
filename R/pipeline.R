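# Pipeline orchestration: simulate -> preprocess -> z-map -> ROI stats ->
# group comparison, with on-disk stage artifacts, JSON provenance sidecars
# and a plain-text report, so that every stage is independently re-entrant.

#' Assemble a pipeline configuration
#'
#' Defaults mirror the analysis conventions throughout the package: Z
#' threshold 1, homoscedastic two-tailed t-tests at alpha = 0.05, median
#' denoising, NMI-driven affine registration.
#'
#' @param atlas_volume,atlas_labels,roi_table paths to the atlas template
#'   NIfTI, label NIfTI and ROI-table CSV (NULL when `simulate` is set).
#' @param manifest path to a cohort manifest CSV (NULL when simulating).
#' @param output_dir run directory, created by [run_pipeline()].
#' @param z_threshold suprathreshold cut in Z units (default 1).
#' @param denoise_method,denoise_radius see [denoise()].
#' @param metric,restarts registration options, see [register_affine()].
#' @param register set FALSE to skip registration and use manifest
#'   `labels_path` ground-truth labels (phantom shortcut).
#' @param alpha significance level.
#' @param master_seed seed for every stochastic choice in the run.
#' @param simulate optional list of simulation settings (grid_shape,
#'   voxel_spacing, n_per_group, bounds) to generate the cohort in-run.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(atlas_volume = NULL, atlas_labels = NULL,
                            roi_table = NULL, manifest = NULL,
                            output_dir = "memriz_run",
                            z_threshold = 1, denoise_method = "median3d",
                            denoise_radius = 1L, metric = "nmi",
                            restarts = 3L, register = TRUE, alpha = 0.05,
                            master_seed = 1L, simulate = NULL) {
  cfg <- list(atlas_volume = atlas_volume, atlas_labels = atlas_labels,
              roi_table = roi_table, manifest = manifest,
              output_dir = output_dir, z_threshold = z_threshold,
              denoise_method = denoise_method,
              denoise_radius = denoise_radius, metric = metric,
              restarts = restarts, register = register, alpha = alpha,
              master_seed = master_seed, simulate = simulate)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[intersect(names(vals),
                                          names(formals(pipeline_config)))])
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

write_provenance <- function(path, stage, cfg, seed = NULL, extra = NULL) {
  side <- paste0(path, ".json")
  jsonlite::write_json(c(list(stage = stage, config_hash = config_hash(cfg),
                              seed = seed, package = "memriz",
                              version = as.character(utils::packageVersion("memriz"))),
                         extra),
                       side, auto_unbox = TRUE, null = "null")
  invisible(side)
}

#' Read an artifact's provenance sidecar
#' @param path artifact path.
#' @return named list (stage, config_hash, seed, ...).
#' @export
read_provenance <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("no provenance sidecar for ", path)
  jsonlite::read_json(side)
}

#' Check that an artifact was produced by the expected stage
#'
#' Stage-order violations (e.g. z-mapping a raw, un-preprocessed volume)
#' are refused with a provenance message.
#'
#' @param path artifact path (its sidecar is `path.json`).
#' @param expected_stage required producing stage.
#' @export
require_stage <- function(path, expected_stage) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("no provenance sidecar for ", path,
         "; run the '", expected_stage, "' stage first")
  prov <- jsonlite::read_json(side)
  if (!identical(prov$stage, expected_stage))
    stop("stage-order violation: ", path, " was produced by stage '",
         prov$stage, "', expected '", expected_stage, "'")
  invisible(TRUE)
}

#' Preprocess one subject: mask, denoise, register, propagate labels
#'
#' @param volume_path,mask_path subject NIfTI paths.
#' @param atlas an `atlas_phantom` or list with `template` and `labels`.
#' @param cfg a [pipeline_config()].
#' @param out_dir directory for the preprocessed artifacts.
#' @param subject_id id used in filenames.
#' @return list with paths `volume` (masked+denoised NIfTI), `labels`
#'   (subject-space label NIfTI) and `transform` (text file), plus the
#'   in-memory objects.
#' @export
preprocess_subject <- function(volume_path, mask_path, atlas, cfg, out_dir,
                               subject_id) {
  vol <- read_volume(volume_path)
  mask <- read_mask(mask_path)
  vol <- apply_brain_mask(vol, mask)
  vol <- denoise(vol, cfg$denoise_method, radius = cfg$denoise_radius,
                 mask = mask)
  if (isTRUE(cfg$register)) {
    tr <- register_affine(atlas$template, vol, metric = cfg$metric,
                          restarts = cfg$restarts,
                          seed = cfg$master_seed)
    labs <- warp_labels(atlas$labels, tr, vol)
  } else if (!is.null(attr(atlas, "truth_labels_path"))) {
    # registration disabled with phantom ground truth available: use the
    # subject-space true labels directly
    tr <- affine_identity()
    nii <- read_nifti_ras(attr(atlas, "truth_labels_path"))
    aff <- structure(RNifti::xform(nii), code = NULL)
    lv <- as.array(nii)
    labs <- label_vol(array(as.integer(lv), dim(lv)),
                      atlas$labels$roi_table,
                      sqrt(colSums(aff[1:3, 1:3]^2)), aff)
  } else {
    tr <- affine_identity()
    labs <- warp_labels(atlas$labels, tr, vol)
  }
  vp <- file.path(out_dir, paste0(subject_id, "_preproc.nii.gz"))
  lp <- file.path(out_dir, paste0(subject_id, "_labels.nii.gz"))
  tp <- file.path(out_dir, paste0(subject_id, "_affine.txt"))
  write_volume(vol, vp)
  write_labels(labs, lp)
  write_transform(tr, tp)
  for (p in c(vp, lp, tp)) write_provenance(p, "preprocess", cfg)
  list(volume = vp, labels = lp, transform = tp,
       vol = vol, labs = labs, mask = mask, tr = tr)
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> preprocess -> z-map -> ROI/sub-region
#' statistics -> group comparison, writing per-subject z-maps (NIfTI), ROI
#' and sub-region CSVs, group-comparison CSVs, a histogram census CSV, the
#' effective configuration, a run log, and a plain-text report. Any stage
#' failure aborts naming the subject and stage.
#'
#' @param cfg a [pipeline_config()].
#' @return the run directory path, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$output_dir, "run.log")
  logf <- function(...) cat(sprintf("[%s] ", format(Sys.time())), ...,
                            "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("memriz ", as.character(utils::packageVersion("memriz")),
       " run, master seed ", cfg$master_seed)

  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    atlas <- build_atlas_phantom(
      grid_shape = sim$grid_shape %||% c(128L, 128L, 64L),
      voxel_spacing = sim$voxel_spacing %||% c(0.2, 0.156, 0.3),
      geometry_seed = cfg$master_seed)
    sim_dir <- file.path(cfg$output_dir, "simulated")
    man <- simulate_cohort(atlas, n_per_group = sim$n_per_group %||% 5L,
                           master_seed = cfg$master_seed, dir = sim_dir,
                           bounds = sim$bounds %||%
                             list(translation = 1, rotation = 10,
                                  scale = 0.1, shear = 0.1))
    logf("simulated cohort of ", nrow(man), " subjects in ", sim_dir)
  } else {
    if (is.null(cfg$atlas_volume) || !file.exists(cfg$atlas_volume))
      stop("atlas volume missing: ",
           if (is.null(cfg$atlas_volume)) "(not set)" else cfg$atlas_volume)
    if (is.null(cfg$atlas_labels) || !file.exists(cfg$atlas_labels))
      stop("atlas labels missing: ",
           if (is.null(cfg$atlas_labels)) "(not set)" else cfg$atlas_labels)
    atlas <- list(template = read_volume(cfg$atlas_volume),
                  labels = read_labels(cfg$atlas_labels, cfg$roi_table))
    man <- read_manifest(cfg$manifest)
  }

  pre_dir <- file.path(cfg$output_dir, "preprocessed")
  z_dir <- file.path(cfg$output_dir, "zmaps")
  dir.create(pre_dir, showWarnings = FALSE)
  dir.create(z_dir, showWarnings = FALSE)

  roi_rows <- list(); sub_rows <- list(); zmaps <- list()
  for (i in seq_len(nrow(man))) {
    sid <- man$subject_id[i]
    stage <- "preprocess"
    res <- tryCatch({
      if (!isTRUE(cfg$register) && !is.null(man$labels_path))
        attr(atlas, "truth_labels_path") <- man$labels_path[i]
      pre <- preprocess_subject(man$volume_path[i], man$mask_path[i],
                                atlas, cfg, pre_dir, sid)
      stage <- "zmap"
      zm <- zscore_normalize(pre$vol, pre$mask)
      zt <- threshold_map(zm, cfg$z_threshold)
      zp <- file.path(z_dir, paste0(sid, "_zmap.nii.gz"))
      write_zmap(zt, zp)
      write_provenance(zp, "zmap", cfg,
                       extra = list(z_threshold = cfg$z_threshold,
                                    brain_mean = zm$brain_mean,
                                    brain_sd = zm$brain_sd))
      stage <- "analyze"
      rr <- roi_metrics_all(zt, pre$labs, subject_id = sid,
                            group = man$group[i])
      sr <- subregion_metrics(pre$vol, pre$labs, pre$mask,
                              subject_id = sid, group = man$group[i])
      list(zm = zm, rr = rr, sr = sr)
    }, error = function(e)
      stop("pipeline failed for subject ", sid, " at stage '", stage,
           "': ", conditionMessage(e), call. = FALSE))
    zmaps[[sid]] <- res$zm
    roi_rows[[sid]] <- res$rr
    sub_rows[[sid]] <- res$sr
    logf("subject ", sid, " processed")
  }

  roi_tab <- do.call(rbind, roi_rows)
  sub_tab <- do.call(rbind, sub_rows)
  census <- histogram_census(zmaps, groups = man$group,
                             subjects = man$subject_id)
  cmp_z <- compare_cohort(roi_tab, "mean_supra_z", alpha = cfg$alpha)
  cmp_v <- compare_cohort(roi_tab, "active_volume_mm3", alpha = cfg$alpha)

  paths <- c(roi = "roi_metrics.csv", subregion = "subregion_metrics.csv",
             census = "histogram_census.csv",
             cmp_z = "compare_mean_supra_z.csv",
             cmp_v = "compare_active_volume.csv")
  meta <- function(df) {
    df$z_threshold_cfg <- cfg$z_threshold
    df
  }
  write_table(meta(roi_tab), file.path(cfg$output_dir, paths["roi"]))
  write_table(meta(sub_tab), file.path(cfg$output_dir, paths["subregion"]))
  write_table(meta(census$counts), file.path(cfg$output_dir, paths["census"]))
  write_table(meta(as.data.frame(cmp_z)),
              file.path(cfg$output_dir, paths["cmp_z"]))
  write_table(meta(as.data.frame(cmp_v)),
              file.path(cfg$output_dir, paths["cmp_v"]))
  for (p in paths)
    write_provenance(file.path(cfg$output_dir, p), "analyze", cfg,
                     seed = cfg$master_seed)
  yaml::write_yaml(unclass(cfg), file.path(cfg$output_dir, "config.yaml"))
  render_report(cfg$output_dir)
  logf("run complete")
  invisible(cfg$output_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a plain-text report from a run directory
#'
#' Summarizes whichever result tables are present (histogram census, per-ROI
#' comparisons, sub-region metrics, segmented volumes) and lists any missing
#' sections rather than failing on partial runs.
#'
#' @param run_dir a [run_pipeline()] output directory.
#' @return report path, invisibly.
#' @export
render_report <- function(run_dir) {
  rp <- file.path(run_dir, "report.txt")
  con <- file(rp, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("memriz pipeline report")
  w("======================")
  sect <- function(file, title, render) {
    path <- file.path(run_dir, file)
    w("")
    w(title)
    w(strrep("-", nchar(title)))
    if (!file.exists(path)) {
      w("  [missing: ", file, "]")
      return(invisible(NULL))
    }
    render(utils::read.csv(path, stringsAsFactors = FALSE))
  }
  sect("histogram_census.csv", "Z-score histogram census", function(d) {
    supra <- stats::aggregate(count ~ subject + group,
                              d[d$bin_lo >= 1, ], sum)
    tot <- stats::aggregate(count ~ subject, d, sum)
    supra$fraction <- supra$count / tot$count[match(supra$subject,
                                                   tot$subject)]
    g <- stats::aggregate(fraction ~ group, supra, mean)
    for (i in seq_len(nrow(g)))
      w(sprintf("  %s: %.1f%% of brain voxels at Z >= 1",
                g$group[i], 100 * g$fraction[i]))
  })
  cmp_sect <- function(d, label) {
    sig <- d[d$significant %in% TRUE, ]
    w(sprintf("  %d ROIs tested; significant (p <= alpha): %s", nrow(d),
              if (nrow(sig)) paste(sprintf("%s (t_%d=%.3g, p=%.3g)",
                                           sig$roi, sig$df, sig$t, sig$p),
                                   collapse = ", ") else "none"))
  }
  sect("compare_mean_supra_z.csv", "Mean suprathreshold Z by ROI",
       function(d) cmp_sect(d, "mean Z"))
  sect("compare_active_volume.csv", "Active volume (mm^3) by ROI",
       function(d) cmp_sect(d, "active volume"))
  sect("subregion_metrics.csv", "Hippocampal sub-regions", function(d) {
    for (g in unique(d$group))
      w(sprintf(paste0("  %s: CA1 rel %.3f, DG rel %.3f, CA1:DG %.3f, ",
                       "thickness %.2f mm, hippocampus %.2f mm^3"),
                g, mean(d$rel_intensity_CA1[d$group == g]),
                mean(d$rel_intensity_DG[d$group == g]),
                mean(d$ca1_dg_ratio[d$group == g]),
                mean(d$hippocampal_thickness_mm[d$group == g], na.rm = TRUE),
                mean(d$hippocampus_volume_mm3[d$group == g])))
    both <- c("mutant", "control") %in% d$group
    if (all(both)) {
      r <- group_volume_ratio(d$hippocampus_volume_mm3[d$group == "mutant"],
                              d$hippocampus_volume_mm3[d$group == "control"])
      w(sprintf("  hippocampus volume, mutant vs control: %.1f%%", r))
    }
  })
  invisible(rp)
}
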