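# Region-of-interest aggregation. Eight anatomical ROIs per slide are
# analyzed: H1/H2 (proximal and distal host bone), C1/C2 (callus), J1/J2
# (graft-host junctions), A1/A2 (allograft cortices); paired ROIs of a class
# are pooled pixel-weighted into one per-class summary per subject.

ROI_CLASSES <- c(
  H1 = "host", H2 = "host", C1 = "callus", C2 = "callus",
  J1 = "junction", J2 = "junction", A1 = "allograft", A2 = "allograft"
)

# Signed polygon area (shoelace).
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

# Do segments p1-p2 and p3-p4 properly intersect?
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

#' Define a region of interest
#'
#' @param name One of H1, H2, C1, C2, J1, J2, A1, A2. The anatomical class
#'   (host / callus / junction / allograft) follows from the name.
#' @param polygon n x 2 matrix or list of (x, y) vertices in image
#'   coordinates (x = column, y = row, 0-based pixel centers). Must be a
#'   simple polygon with nonzero area.
#' @return An \code{roi_spec}.
#' @export
roi_spec <- function(name, polygon) {
  if (!name %in% names(ROI_CLASSES)) {
    stop_input("unknown ROI name '", name, "'; expected one of ",
               paste(names(ROI_CLASSES), collapse = ", "))
  }
  if (is.list(polygon)) polygon <- do.call(rbind, lapply(polygon, unlist))
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L) {
    stop_input("polygon must have >= 3 (x, y) vertices")
  }
  if (abs(polygon_area(polygon)) < .Machine$double.eps) {
    stop_input("degenerate polygon: zero area")
  }
  n <- nrow(polygon)
  v <- rbind(polygon, polygon[1, ])
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1L || abs(i - j) == n - 1L) next
      if (segments_cross(v[i, ], v[i + 1, ], v[j, ], v[j + 1, ])) {
        stop_input("polygon is self-intersecting")
      }
    }
  }
  structure(
    list(name = name, polygon = polygon,
         region_class = unname(ROI_CLASSES[name])),
    class = "roi_spec"
  )
}

# Vectorized point-in-polygon, boundary-inclusive (even-odd ray casting plus
# an explicit on-edge test).
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- c(xs[-1], xs[1]); ye <- c(ys[-1], ys[1])
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    x1 <- xs[i]; y1 <- ys[i]; x2 <- xe[i]; y2 <- ye[i]
    cross <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, cross & !is.na(cross))
    seglen2 <- (x2 - x1)^2 + (y2 - y1)^2
    if (seglen2 == 0) next
    t <- ((px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)) / seglen2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (px - (x1 + t * (x2 - x1)))^2 + (py - (y1 + t * (y2 - y1)))^2
    onedge <- onedge | d2 < 1e-18
  }
  inside | onedge
}

#' Clip a growth field to a region of interest
#'
#' Axis pixels whose centers fall inside the ROI polygon (boundary
#' inclusive) are retained; connected regions are relabeled on the clipped
#' skeleton.
#'
#' @param field A \code{growth_field}.
#' @param roi An \code{\link{roi_spec}}.
#' @return A clipped \code{growth_field} (empty, with a warning, if the ROI
#'   misses the field).
#' @export
clip_field_to_roi <- function(field, roi) {
  stopifnot(inherits(field, "growth_field"), inherits(roi, "roi_spec"))
  d <- dim(field$growth_mask)
  xr <- range(roi$polygon[, 1]); yr <- range(roi$polygon[, 2])
  if (xr[2] < 0 || xr[1] > d[2] - 1 || yr[2] < 0 || yr[1] > d[1] - 1) {
    warning("ROI ", roi$name, " lies outside the image", call. = FALSE)
  }
  out <- field
  if (nrow(field$axis) == 0L) return(out)
  keep <- point_in_polygon(field$axis$col, field$axis$row, roi$polygon)
  skel <- matrix(0L, d[1], d[2])
  skel[cbind(field$axis$row[keep] + 1L, field$axis$col[keep] + 1L)] <- 1L
  out$skeleton <- skel
  out$axis <- field$axis[keep, , drop = FALSE]
  rownames(out$axis) <- NULL
  if (sum(keep) == 0L) {
    warning("ROI ", roi$name, " contains no growth-field pixels",
            call. = FALSE)
    out$regions <- field$regions[0, ]
    out$region_id <- integer(0)
    return(out)
  }
  lab <- label8(skel)
  rid <- lab[cbind(out$axis$row + 1L, out$axis$col + 1L)]
  px <- field$pixel_size_um
  lens <- component_lengths_px(lab) * px
  out$regions <- do.call(rbind, lapply(sort(unique(rid)), function(k) {
    data.frame(
      region_id = k,
      length_um = lens[k],
      n_pixels = sum(rid == k),
      mean_distance_um = mean(out$axis$distance_um[rid == k])
    )
  }))
  out$region_id <- rid
  out
}

#' Per-ROI MAR measurements for one slide
#'
#' Clips the growth field to each ROI and reports the pooled MAR inside it.
#'
#' @param field A \code{growth_field}.
#' @param rois List of \code{\link{roi_spec}}s.
#' @param interval_days Inter-label interval in days.
#' @param subject_id Identifier carried into the output.
#' @return data.frame with one row per ROI: \code{subject_id}, \code{roi},
#'   \code{region_class}, \code{mean_mar_mm_per_day}, \code{sd_mar},
#'   \code{n_pixels}.
#' @export
mar_by_roi <- function(field, rois, interval_days = 7, subject_id = "subject") {
  rows <- lapply(rois, function(roi) {
    clipped <- suppressWarnings(clip_field_to_roi(field, roi))
    d <- clipped$axis$distance_um
    k <- 1 / interval_days / 1000
    data.frame(
      subject_id = subject_id,
      roi = roi$name,
      region_class = roi$region_class,
      mean_mar_mm_per_day = if (length(d)) mean(d) * k else NA_real_,
      sd_mar = if (length(d) > 1) stats::sd(d) * k else 0,
      n_pixels = length(d)
    )
  })
  do.call(rbind, rows)
}

# Exact pooled mean/sd from per-group (mean, sd, n) summaries; equals the
# statistics of the concatenated raw values.
pool_measurements <- function(means, sds, ns) {
  keep <- ns > 0
  means <- means[keep]; sds <- sds[keep]; ns <- ns[keep]
  n <- sum(ns)
  m <- sum(ns * means) / n
  if (n < 2) return(list(mean = m, sd = 0, n = n))
  ss <- sum((ns - 1) * sds^2 + ns * (means - m)^2)
  list(mean = m, sd = sqrt(ss / (n - 1)), n = n)
}

#' Pool paired ROIs into per-class MAR summaries
#'
#' The two ROIs of each anatomical class (e.g. H1 + H2) are combined by a
#' pixel-weighted mean; the pooled SD is reconstructed exactly from the
#' per-ROI means/SDs/pixel counts. A class with one missing or empty ROI is
#' summarized from the remaining one and flagged; a class with both missing
#' is omitted with a warning.
#'
#' @param roi_measurements Output of \code{\link{mar_by_roi}}.
#' @return data.frame with one row per region class: \code{subject_id},
#'   \code{region_class}, \code{mean_mar_mm_per_day}, \code{sd},
#'   \code{n_pixels}, \code{n_regions_pooled}, \code{partial} (TRUE when
#'   only one ROI of the pair contributed).
#' @export
summarize_by_region <- function(roi_measurements) {
  stopifnot(is.data.frame(roi_measurements))
  out <- list()
  for (sid in unique(roi_measurements$subject_id)) {
    sub <- roi_measurements[roi_measurements$subject_id == sid, ]
    for (cls in unique(unname(ROI_CLASSES))) {
      rows <- sub[sub$region_class == cls & !is.na(sub$mean_mar_mm_per_day) &
                    sub$n_pixels > 0, ]
      expected <- sum(sub$region_class == cls)
      if (nrow(rows) == 0L) {
        if (expected > 0) {
          warning("subject ", sid, ": no usable ROI for class '", cls,
                  "'; omitted", call. = FALSE)
        }
        next
      }
      p <- pool_measurements(rows$mean_mar_mm_per_day, rows$sd_mar,
                             rows$n_pixels)
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sid, region_class = cls,
        mean_mar_mm_per_day = p$mean, sd = p$sd, n_pixels = p$n,
        n_regions_pooled = nrow(rows), partial = nrow(rows) < 2L
      )
    }
  }
  if (!length(out)) {
    return(data.frame(
      subject_id = character(0), region_class = character(0),
      mean_mar_mm_per_day = numeric(0), sd = numeric(0),
      n_pixels = integer(0), n_regions_pooled = integer(0),
      partial = logical(0)
    ))
  }
  do.call(rbind, out)
}
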