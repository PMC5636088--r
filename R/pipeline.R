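# Pipeline orchestration: chains label segmentation, skeletonization,
# matching, growth-field quantification and ROI aggregation; file-level
# report generators with provenance; synthetic-study writer.

#' Run the full MAR pipeline on a labeled image
#'
#' Normalizes and separates the fluorochrome channels, binarizes and cleans
#' each mask, skeletonizes with pruning, matches alizarin to calcein
#' skeletal pixels under the distance cap, builds the growth field, and
#' computes MAR (pooled, per growth region, and per ROI when ROIs are
#' given), plus total label length/area.
#'
#' @param image A \code{\link{labeled_image}}.
#' @param config A \code{\link{pipeline_config}}.
#' @param rois Optional list of \code{\link{roi_spec}}s.
#' @param subject_id Identifier used in ROI summaries.
#' @return List with \code{mar} (region table from
#'   \code{\link{compute_mar}}), \code{roi_mar}, \code{region_summary},
#'   \code{field}, \code{matches}, \code{masks}, \code{skeletons},
#'   \code{label_measurements}.
#' @export
run_mar_pipeline <- function(image, config = pipeline_config(), rois = NULL,
                             subject_id = "subject") {
  stopifnot(inherits(image, "labeled_image"),
            inherits(config, "pipeline_config"))
  norm <- suppressWarnings(normalize_channels(
    image, config$background_percentile, config$saturation_percentile
  ))
  sep <- separate_channels(norm, alpha = config$crosstalk_alpha,
                           beta = config$crosstalk_beta)
  px <- image$pixel_size_um
  masks <- lapply(c(alizarin = "alizarin", calcein = "calcein"), function(role) {
    raw <- threshold_mask(get_channel(sep, role),
                          method = config$threshold_method,
                          fixed_value = config$fixed_threshold,
                          pixel_size_um = px, fluorochrome = role)
    clean_mask(raw, smooth_radius_um = config$smooth_radius_um,
               min_area_um2 = config$min_area_um2,
               min_length_um = config$min_length_um,
               max_hole_area_um2 = config$max_hole_area_um2)
  })
  skels <- lapply(masks, skeletonize_pruned,
                  prune_length_um = config$prune_length_um)
  matches <- match_skeletons(skels$alizarin, skels$calcein,
                             max_distance_um = config$max_distance_um)
  field <- build_growth_field(matches)
  mar <- compute_mar(field, interval_days = config$interval_days)
  roi_mar <- NULL
  region_summary <- NULL
  if (!is.null(rois)) {
    roi_mar <- mar_by_roi(field, rois, interval_days = config$interval_days,
                          subject_id = subject_id)
    region_summary <- summarize_by_region(roi_mar)
  }
  list(
    mar = mar, roi_mar = roi_mar, region_summary = region_summary,
    field = field, matches = matches, masks = masks, skeletons = skels,
    label_measurements = lapply(masks, function(m) {
      measure_labels(m, skeletonize_pruned(m, prune_length_um = config$prune_length_um))
    })
  )
}

provenance_record <- function(config, inputs) {
  list(
    package = "histomar",
    version = as.character(utils::packageVersion("histomar")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    inputs = lapply(inputs, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
}

#' File-level MAR report
#'
#' Reads an image (and optionally ROI polygons), runs the pipeline, and
#' writes: per-region and pooled MAR CSV, per-ROI CSV when ROIs are given,
#' the growth field as sparse CSV, a pseudo-colored overlay PNG, and a
#' provenance JSON (package version, full configuration, input checksums).
#'
#' @param image_path TIFF path.
#' @param out_dir Output directory (created if needed).
#' @param roi_path Optional ROI JSON path.
#' @param config A \code{\link{pipeline_config}}.
#' @param subject_id Identifier used in summaries and file names.
#' @return Invisibly, the named list of files written.
#' @export
mar_report <- function(image_path, out_dir, roi_path = NULL,
                       config = pipeline_config(), subject_id = "subject") {
  image <- read_labeled_image(
    image_path,
    pixel_size_um = if (is.na(config$pixel_size_um)) NULL else config$pixel_size_um
  )
  rois <- if (!is.null(roi_path)) read_roi_json(roi_path)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop_input("cannot create output directory: ", out_dir)
  }
  res <- run_mar_pipeline(image, config, rois, subject_id)
  files <- list()
  f <- file.path(out_dir, paste0(subject_id, "_mar.csv"))
  utils::write.csv(res$mar, f, row.names = FALSE)
  files$mar <- f
  if (!is.null(res$roi_mar)) {
    f <- file.path(out_dir, paste0(subject_id, "_mar_by_roi.csv"))
    utils::write.csv(res$roi_mar, f, row.names = FALSE)
    files$roi_mar <- f
    f <- file.path(out_dir, paste0(subject_id, "_mar_by_class.csv"))
    utils::write.csv(res$region_summary, f, row.names = FALSE)
    files$region_summary <- f
  }
  f <- file.path(out_dir, paste0(subject_id, "_growth_field.csv"))
  write_growth_field_csv(res$field, f)
  files$growth_field <- f
  f <- file.path(out_dir, paste0(subject_id, "_overlay.png"))
  write_overlay_png(render_overlay(res$field, image), f)
  files$overlay <- f
  prov <- provenance_record(config, c(image_path, roi_path))
  prov$subject_id <- subject_id
  f <- file.path(out_dir, paste0(subject_id, "_provenance.json"))
  jsonlite::write_json(prov, f, auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  files$provenance <- f
  invisible(files)
}

#' Generate a synthetic study on disk
#'
#' Writes \code{n_images} double-label images (TIFF + ground-truth JSON),
#' a synthetic callus-volume study table (CSV), and a manifest JSON listing
#' every artifact with the seed it was generated from. Byte-identical
#' across runs with the same arguments.
#'
#' @param out_dir Output directory.
#' @param config A \code{\link{pipeline_config}} (supplies the base seed and
#'   pixel size).
#' @param n_images Number of image/ground-truth pairs.
#' @param spec A \code{\link{band_spec}} template; image i uses
#'   \code{seed + i - 1}.
#' @param image_size_px Image size.
#' @param study_params List of \code{\link{group_params}} for the study
#'   table (default: the published callus-volume summaries).
#' @return Invisibly, the manifest as a list.
#' @export
simulate_to_dir <- function(out_dir, config = pipeline_config(pixel_size_um = 5),
                            n_images = 1L,
                            spec = band_spec(70, 10),
                            image_size_px = c(256L, 256L),
                            study_params = canine_callus_volume_params()) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop_input("cannot create output directory: ", out_dir)
  }
  px <- if (is.na(config$pixel_size_um)) 5 else config$pixel_size_um
  manifest <- list(seed = config$seed, pixel_size_um = px, files = list())
  for (i in seq_len(n_images)) {
    s <- spec
    s$seed <- config$seed + i - 1L
    gen <- generate_double_label_image(s, image_size_px, px,
                                       interval_days = config$interval_days)
    img_f <- file.path(out_dir, sprintf("image_%03d.tif", i))
    write_labeled_image(gen$image, img_f)
    gt_f <- file.path(out_dir, sprintf("image_%03d_truth.json", i))
    jsonlite::write_json(
      list(separation_um = gen$truth$separation_um,
           interval_days = gen$truth$interval_days,
           mar_mm_per_day = gen$truth$mar_mm_per_day,
           spec = unclass(s)),
      gt_f, auto_unbox = TRUE, digits = NA
    )
    manifest$files[[length(manifest$files) + 1L]] <-
      list(path = basename(img_f), truth = basename(gt_f), seed = s$seed)
  }
  tab <- generate_study_table(study_params, seed = config$seed)
  tab_f <- file.path(out_dir, "study_table.csv")
  write_study_table(tab, tab_f)
  manifest$files[[length(manifest$files) + 1L]] <-
    list(path = basename(tab_f), seed = config$seed)
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' File-level statistics report
#'
#' Runs the requested design on a study-table CSV and writes tidy CSV
#' results plus a short human-readable summary. For the repeated-measures
#' design, fold changes of each treatment group mean over the control group
#' mean are reported per timepoint.
#'
#' @param table_path Study table CSV.
#' @param out_dir Output directory.
#' @param variable Variable to analyze.
#' @param design "rm2way" (two-way repeated measures) or "oneway".
#' @param alpha Significance level.
#' @param reference_group Group used as the fold-change denominator.
#' @return Invisibly, the list of result objects.
#' @export
stats_report <- function(table_path, out_dir, variable = "callus_volume",
                         design = c("rm2way", "oneway"), alpha = 0.05,
                         reference_group = "control") {
  design <- match.arg(design)
  tab <- read_study_table(table_path)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop_input("cannot create output directory: ", out_dir)
  }
  res <- list()
  if (design == "rm2way") {
    fit <- rm_anova_tukey(tab, variable, alpha = alpha)
    utils::write.csv(fit$anova, file.path(out_dir, "anova.csv"),
                     row.names = FALSE)
    utils::write.csv(fit$tukey, file.path(out_dir, "tukey.csv"),
                     row.names = FALSE)
    df <- tab[tab$variable == variable, ]
    fc <- do.call(rbind, lapply(split(df, df$timepoint_weeks), function(d) {
      ref <- mean(d$value[d$group == reference_group])
      if (!is.finite(ref) || ref <= 0) return(NULL)
      other <- setdiff(unique(d$group), reference_group)
      do.call(rbind, lapply(other, function(g) {
        f <- fold_change(mean(d$value[d$group == g]), ref)
        data.frame(timepoint_weeks = d$timepoint_weeks[1], group = g,
                   fold = f$fold, unrounded = f$unrounded)
      }))
    }))
    rownames(fc) <- NULL
    if (!is.null(fc)) {
      utils::write.csv(fc, file.path(out_dir, "fold_changes.csv"),
                       row.names = FALSE)
    }
    res <- list(anova = fit, fold_changes = fc)
    summ <- c(
      sprintf("Two-way repeated-measures ANOVA on '%s' (n = %d subjects)",
              variable, fit$n_subjects),
      utils::capture.output(print(fit$anova, row.names = FALSE)),
      "", "Fold changes vs control:",
      if (!is.null(fc)) utils::capture.output(print(fc, row.names = FALSE))
    )
  } else {
    df <- tab[tab$variable == variable, ]
    groups <- split(df$value, df$group)
    fit <- one_way_anova_tukey(groups, alpha = alpha)
    utils::write.csv(
      data.frame(effect = "group", df = fit$df, df_error = fit$df_error,
                 F = fit$F, p = fit$p),
      file.path(out_dir, "anova.csv"), row.names = FALSE
    )
    utils::write.csv(fit$tukey, file.path(out_dir, "tukey.csv"),
                     row.names = FALSE)
    res <- list(anova = fit)
    summ <- c(
      sprintf("One-way ANOVA on '%s': F(%d, %d) = %.4g, p = %.4g",
              variable, fit$df, fit$df_error, fit$F, fit$p),
      utils::capture.output(print(fit$tukey, row.names = FALSE))
    )
  }
  writeLines(summ, file.path(out_dir, "summary.txt"))
  invisible(res)
}
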