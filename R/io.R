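# Readers and writers: TIFF images and masks, ROI JSON, study-table CSV,
# growth-field / MAR CSV, configuration and provenance JSON.

#' Pipeline configuration
#'
#' One flat document holding every physical parameter of the measurement
#' pipeline; serializes losslessly to JSON. Command-line flags override file
#' values.
#'
#' @param pixel_size_um Physical pixel size (um); may be NA when the image
#'   carries its own calibration.
#' @param interval_days Inter-label interval (default 7).
#' @param max_distance_um Matching cap (default 100).
#' @param background_percentile,saturation_percentile Normalization
#'   percentiles.
#' @param threshold_method "otsu" or "fixed".
#' @param fixed_threshold Threshold when method is "fixed".
#' @param smooth_radius_um,min_area_um2,min_length_um,max_hole_area_um2 Mask
#'   cleanup parameters (see \code{\link{clean_mask}}).
#' @param prune_length_um Skeleton spur-pruning length.
#' @param crosstalk_alpha,crosstalk_beta Linear unmixing coefficients.
#' @param seed Seed for any randomized step.
#' @param output_dir Default output directory.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(pixel_size_um = NA_real_, interval_days = 7,
                            max_distance_um = 100,
                            background_percentile = 1,
                            saturation_percentile = 99.9,
                            threshold_method = "otsu", fixed_threshold = 0.5,
                            smooth_radius_um = 0, min_area_um2 = 100,
                            min_length_um = 50, max_hole_area_um2 = Inf,
                            prune_length_um = 30, crosstalk_alpha = 0,
                            crosstalk_beta = 0, seed = 1L,
                            output_dir = ".") {
  stopifnot(interval_days > 0, max_distance_um > 0,
            is.na(pixel_size_um) || pixel_size_um > 0,
            smooth_radius_um >= 0, min_area_um2 >= 0, min_length_um >= 0,
            prune_length_um >= 0,
            threshold_method %in% c("otsu", "fixed"))
  structure(
    list(
      pixel_size_um = as.numeric(pixel_size_um),
      interval_days = as.numeric(interval_days),
      max_distance_um = as.numeric(max_distance_um),
      background_percentile = as.numeric(background_percentile),
      saturation_percentile = as.numeric(saturation_percentile),
      threshold_method = threshold_method,
      fixed_threshold = as.numeric(fixed_threshold),
      smooth_radius_um = as.numeric(smooth_radius_um),
      min_area_um2 = as.numeric(min_area_um2),
      min_length_um = as.numeric(min_length_um),
      max_hole_area_um2 = as.numeric(max_hole_area_um2),
      prune_length_um = as.numeric(prune_length_um),
      crosstalk_alpha = as.numeric(crosstalk_alpha),
      crosstalk_beta = as.numeric(crosstalk_beta),
      seed = as.integer(seed),
      output_dir = output_dir
    ),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param path File path.
#' @return \code{read_config} returns a \code{pipeline_config}.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$max_hole_area_um2 <- ifelse(is.infinite(x$max_hole_area_um2), "Inf",
                                x$max_hole_area_um2)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  x <- jsonlite::fromJSON(path)
  if (identical(x$max_hole_area_um2, "Inf")) x$max_hole_area_um2 <- Inf
  if (is.null(x$pixel_size_um)) x$pixel_size_um <- NA_real_
  do.call(pipeline_config, x)
}

#' Write a labeled image as multi-page TIFF with a JSON sidecar
#'
#' Each channel becomes one TIFF page; the pixel size (um) and channel roles
#' travel in a JSON sidecar next to the image.
#'
#' @param image A \code{\link{labeled_image}}.
#' @param path Output TIFF path; the sidecar is \code{<path>.json}.
#' @export
write_labeled_image <- function(image, path) {
  stopifnot(inherits(image, "labeled_image"))
  pages <- lapply(seq_len(dim(image$pixels)[3]),
                  function(i) image$pixels[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_size_um = image$pixel_size_um,
         channel_roles = image$channel_roles),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a labeled image from TIFF
#'
#' Accepts multi-page (one channel per page) or single-page RGB TIFF. Pixel
#' size is resolved in order of precedence: the \code{pixel_size_um}
#' argument, the JSON sidecar, the TIFF resolution tag.
#'
#' @param path TIFF path.
#' @param pixel_size_um Optional explicit pixel size override (um).
#' @return A \code{\link{labeled_image}}.
#' @export
read_labeled_image <- function(path, pixel_size_um = NULL) {
  if (!file.exists(path)) stop_input("image file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) {
                      stop_input("cannot read TIFF '", path, "': ",
                                 conditionMessage(e))
                    })
  roles <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(sidecar)
    if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
    roles <- meta$channel_roles
  }
  if (is.null(pixel_size_um)) {
    res <- attr(pages[[1]], "x.resolution")
    unit <- attr(pages[[1]], "resolution.unit")
    if (!is.null(res) && res > 0) {
      per_um <- switch(ifelse(is.null(unit), "none", unit),
                       cm = res / 1e4, inch = res / 25400, NA_real_)
      if (!is.na(per_um)) pixel_size_um <- 1 / per_um
    }
  }
  if (is.null(pixel_size_um) || is.na(pixel_size_um)) {
    stop_input("pixel size unavailable for '", path,
               "': pass pixel_size_um explicitly")
  }
  if (length(pages) == 1L && length(dim(pages[[1]])) == 3L) {
    px <- pages[[1]]
  } else {
    px <- array(unlist(lapply(pages, as.matrix)),
                dim = c(dim(pages[[1]])[1:2], length(pages)))
  }
  labeled_image(px, pixel_size_um, roles)
}

#' Write / read a binary mask TIFF
#'
#' @param mask A \code{fluoro_mask} or 0/1 matrix.
#' @param path File path.
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "fluoro_mask")) mask$mask else as_binary_matrix(mask)
  tiff::writeTIFF(m * 1.0, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read ROI polygons from JSON
#'
#' Schema: \code{{"rois": [{"name": "H1", "polygon": [[x, y], ...]}, ...]}}.
#'
#' @param path JSON path.
#' @return List of \code{\link{roi_spec}}s.
#' @export
read_roi_json <- function(path) {
  if (!file.exists(path)) stop_input("ROI file not found: ", path)
  x <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
                error = function(e) {
                  stop_input("invalid ROI JSON '", path, "': ",
                             conditionMessage(e))
                })
  if (is.null(x$rois)) stop_input("ROI JSON lacks a 'rois' array: ", path)
  lapply(x$rois, function(r) {
    poly <- if (is.matrix(r$polygon)) r$polygon else
      do.call(rbind, lapply(r$polygon, unlist))
    roi_spec(r$name, poly)
  })
}

#' @rdname read_roi_json
#' @param rois List of \code{roi_spec}s to write.
#' @export
write_roi_json <- function(rois, path) {
  jsonlite::write_json(
    list(rois = lapply(rois, function(r) {
      list(name = r$name,
           polygon = lapply(seq_len(nrow(r$polygon)),
                            function(i) unname(r$polygon[i, ])))
    })),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read / write a long study table CSV
#'
#' Columns: subject_id, group, timepoint_weeks, variable, value. Schema
#' violations are reported with the offending row numbers.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) stop_input("study table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "timepoint_weeks", "variable", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_input("study table '", path, "' lacks columns: ",
               paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) stop_input("study table '", path, "' is empty")
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$value))))
  if (length(bad)) {
    stop_input("non-numeric value at row(s): ",
               paste(utils::head(bad, 10), collapse = ", "))
  }
  bad_tp <- which(!df$timepoint_weeks %in% c(2, 4, 8))
  if (length(bad_tp)) {
    stop_input("timepoint_weeks must be 2, 4 or 8; offending row(s): ",
               paste(utils::head(bad_tp, 10), collapse = ", "))
  }
  df$value <- as.numeric(df$value)
  df
}

#' @rdname read_study_table
#' @param table data.frame to write.
#' @export
write_study_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a growth field as sparse CSV (row, col, distance_um)
#'
#' @param field A \code{growth_field}.
#' @param path CSV path.
#' @export
write_growth_field_csv <- function(field, path) {
  stopifnot(inherits(field, "growth_field"))
  df <- field$axis
  df$region_id <- field$region_id
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an overlay raster as PNG
#'
#' @param overlay Output of \code{\link{render_overlay}}.
#' @param path PNG path.
#' @export
write_overlay_png <- function(overlay, path) {
  png::writePNG(overlay, path)
  invisible(path)
}
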