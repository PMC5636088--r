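# Core mineral apposition rate (MAR) quantification: distance-capped
# nearest-neighbor matching of alizarin to calcein skeletal pixels, growth
# mask construction, medial-axis distance quantification, and conversion to
# mm/day over the inter-label interval.

#' Match alizarin skeletal pixels to their nearest calcein skeletal pixels
#'
#' Every alizarin foreground pixel is matched to the closest calcein
#' foreground pixel if and only if their Euclidean distance (in physical
#' micrometres) does not exceed \code{max_distance_um}; pixels with no
#' calcein neighbor within the cap are recorded as unmatched. Matching is
#' directional (old label to new label); a calcein pixel may receive several
#' matches. Equidistant candidates are resolved to the smallest (row,
#' column) calcein coordinate, which makes the result deterministic.
#'
#' @param alizarin,calcein \code{skeleton_mask}s on the same pixel grid.
#' @param max_distance_um Matching cap, default 100 um.
#' @param pixel_size_um Physical pixel size; taken from the skeletons if
#'   absent.
#' @return A \code{match_set}: list with \code{pairs} (data.frame of 0-based
#'   \code{a_row, a_col, c_row, c_col} and \code{distance_um}),
#'   \code{n_unmatched}, \code{unmatched_fraction}, \code{max_distance_um},
#'   \code{pixel_size_um}, \code{dim}.
#' @export
match_skeletons <- function(alizarin, calcein, max_distance_um = 100,
                            pixel_size_um = NULL) {
  am <- if (inherits(alizarin, "skeleton_mask")) alizarin$mask else as_binary_matrix(alizarin)
  cm <- if (inherits(calcein, "skeleton_mask")) calcein$mask else as_binary_matrix(calcein)
  if (is.null(pixel_size_um)) {
    pixel_size_um <- if (inherits(alizarin, "skeleton_mask")) alizarin$pixel_size_um else NULL
  }
  if (is.null(pixel_size_um)) stop_input("pixel_size_um is required")
  stopifnot(identical(dim(am), dim(cm)), max_distance_um > 0, pixel_size_um > 0)

  empty <- data.frame(
    a_row = integer(0), a_col = integer(0),
    c_row = integer(0), c_col = integer(0), distance_um = numeric(0)
  )
  a_xy <- which(am == 1, arr.ind = TRUE) - 1L # 0-based
  c_xy <- which(cm == 1, arr.ind = TRUE) - 1L
  n_a <- nrow(a_xy)
  res <- structure(
    list(pairs = empty, n_unmatched = n_a, unmatched_fraction = 1,
         max_distance_um = max_distance_um, pixel_size_um = pixel_size_um,
         dim = dim(am)),
    class = "match_set"
  )
  if (n_a == 0L || nrow(c_xy) == 0L) return(res)

  # lexicographic (row, col) order so that the *first* minimum is the tie
  # winner; squared pixel distances are exact integers, so ties are exact
  ord <- order(c_xy[, 1], c_xy[, 2])
  c_xy <- c_xy[ord, , drop = FALSE]
  cap2 <- (max_distance_um / pixel_size_um)^2

  idx <- integer(n_a)
  d2min <- numeric(n_a)
  chunk <- max(1L, as.integer(5e6 / max(1L, nrow(c_xy))))
  for (s in seq(1L, n_a, by = chunk)) {
    e <- min(n_a, s + chunk - 1L)
    d2 <- outer(a_xy[s:e, 1], c_xy[, 1], "-")^2 +
      outer(a_xy[s:e, 2], c_xy[, 2], "-")^2
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    d2min[s:e] <- d2[cbind(seq_len(e - s + 1L), j)]
  }
  keep <- d2min <= cap2 + 1e-9
  pairs <- data.frame(
    a_row = a_xy[keep, 1], a_col = a_xy[keep, 2],
    c_row = c_xy[idx[keep], 1], c_col = c_xy[idx[keep], 2],
    distance_um = sqrt(d2min[keep]) * pixel_size_um
  )
  res$pairs <- pairs
  res$n_unmatched <- n_a - nrow(pairs)
  res$unmatched_fraction <- res$n_unmatched / n_a
  res
}

#' @export
print.match_set <- function(x, ...) {
  cat("<match_set>", nrow(x$pairs), "pairs (cap", x$max_distance_um, "um),",
      x$n_unmatched, "unmatched alizarin pixels\n")
  invisible(x)
}

# Identify axis pixels whose EDT value is governed by a growth-region
# terminus rather than by the ribbon sides: pixels whose geodesic distance
# along the skeleton to the nearest open endpoint is smaller than their own
# EDT. Returns a logical keep-mask over the skeleton's foreground pixels
# (TRUE = interior, valid width measurement).
interior_axis_pixels <- function(skel, edt) {
  deg <- neighbor_count(skel)
  fg <- skel == 1
  geod <- matrix(Inf, nrow(skel), ncol(skel))
  frontier <- (fg & deg <= 1) * 1L
  geod[frontier == 1] <- 0
  visited <- frontier == 1
  maxit <- ceiling(max(edt[fg])) + 2L
  k <- 0L
  while (sum(frontier) > 0 && k <= maxit) {
    k <- k + 1L
    newpix <- fg & neighbor_count(frontier) > 0 & !visited
    geod[newpix] <- k
    visited <- visited | newpix
    frontier <- newpix * 1L
  }
  geod[fg] >= edt[fg] - 1e-9
}

# Rasterize the straight segment between two 0-based pixel coordinates;
# returns an n x 2 matrix of 1-based (row, col) indices.
raster_segment <- function(r1, c1, r2, c2) {
  n <- max(abs(r2 - r1), abs(c2 - c1)) + 1L
  cbind(round(seq(r1, r2, length.out = n)),
        round(seq(c1, c2, length.out = n))) + 1L
}

#' Build the bone-growth field between matched labeling lines
#'
#' The growth mask is the union of the rasterized segments joining each
#' matched alizarin-calcein pixel pair, sealed with a small morphological
#' closing. The mask is skeletonized and the Euclidean distance transform of
#' the mask, evaluated along that skeleton, gives the per-pixel growth
#' distance: twice the medial-axis half-width, minus a 1.5 px discretization
#' correction (0.5 px from distance-to-background-center vs. the mask
#' boundary, and 1 px because the rasterized ribbon spans both bounding
#' medial axes inclusively), which makes the estimator unbiased to about
#' half a pixel. Skeleton spurs arising at the ribbon ends are pruned at the
#' ribbon half-width scale.
#'
#' @param matches A \code{\link{match_skeletons}} result.
#' @param close_radius_um Radius of the sealing closing. The default is a
#'   quarter of the matching cap: label-dropout gaps well below the cap are
#'   sealed, while distinct growth surfaces (separated by more than the cap)
#'   are never merged.
#' @return A \code{growth_field}: list with \code{growth_mask},
#'   \code{skeleton}, \code{axis} (data.frame of 0-based \code{row},
#'   \code{col}, \code{distance_um}), \code{regions} (data.frame of
#'   \code{region_id}, \code{length_um}, \code{n_pixels},
#'   \code{mean_distance_um}), \code{region_id} per axis pixel, and
#'   \code{pixel_size_um}.
#' @export
build_growth_field <- function(matches, close_radius_um = NULL) {
  stopifnot(inherits(matches, "match_set"))
  px <- matches$pixel_size_um
  d <- matches$dim
  gm <- matrix(0L, d[1], d[2])
  field <- structure(
    list(growth_mask = gm, skeleton = gm,
         axis = data.frame(row = integer(0), col = integer(0),
                           distance_um = numeric(0)),
         regions = data.frame(region_id = integer(0), length_um = numeric(0),
                              n_pixels = integer(0),
                              mean_distance_um = numeric(0),
                              degenerate = logical(0)),
         region_id = integer(0), pixel_size_um = px),
    class = "growth_field"
  )
  p <- matches$pairs
  if (nrow(p) == 0L) {
    warning("empty match set: empty growth field", call. = FALSE)
    return(field)
  }
  for (i in seq_len(nrow(p))) {
    gm[raster_segment(p$a_row[i], p$a_col[i], p$c_row[i], p$c_col[i])] <- 1L
  }
  if (is.null(close_radius_um)) close_radius_um <- matches$max_distance_um / 4
  r_px <- um_to_px(close_radius_um, px)
  if (r_px > 0) {
    brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
    gm <- as_binary_matrix(EBImage::closing(gm, brush))
  }

  edt <- EBImage::distmap(gm, metric = "euclidean")
  skel <- thin_binary(gm)
  # prune spurs produced by boundary raggedness and at the ribbon ends:
  # genuine medial-axis branches of such artifacts live at the scale of the
  # ribbon width (twice the maximal EDT value)
  prune_px <- 2 * max(edt[skel == 1]) + 2
  skel <- prune_spurs(skel, prune_px)
  if (sum(skel) == 0) skel <- thin_binary(gm) # pruning degenerate fields

  # axis pixels whose EDT reflects a region terminus measure the terminus,
  # not the inter-label distance; exclude them, falling back to the
  # maximal-EDT pixels for regions too short to have an interior
  keep <- interior_axis_pixels(skel, edt)
  on_axis_all <- which(skel == 1, arr.ind = TRUE)
  lab <- label8(skel)
  rid_all <- lab[on_axis_all]
  degenerate <- integer(0)
  for (k in unique(rid_all)) {
    in_k <- rid_all == k
    if (!any(keep[in_k])) {
      e <- edt[on_axis_all][in_k]
      keep[in_k] <- e >= max(e) - 1e-9
      degenerate <- c(degenerate, k)
    }
  }
  on_axis <- on_axis_all[keep, , drop = FALSE]
  dist_um <- pmax(2 * edt[on_axis] - 1.5, 0) * px
  rid <- rid_all[keep]
  lens <- component_lengths_px(lab) * px
  regions <- do.call(rbind, lapply(sort(unique(rid)), function(k) {
    data.frame(
      region_id = k,
      length_um = lens[k],
      n_pixels = sum(rid == k),
      mean_distance_um = mean(dist_um[rid == k]),
      degenerate = k %in% degenerate
    )
  }))
  field$growth_mask <- gm
  field$skeleton <- skel
  field$axis <- data.frame(row = on_axis[, 1] - 1L, col = on_axis[, 2] - 1L,
                           distance_um = dist_um)
  field$regions <- regions
  field$region_id <- rid
  field
}

#' @export
print.growth_field <- function(x, ...) {
  cat("<growth_field>", nrow(x$axis), "axis pixels in",
      nrow(x$regions), "region(s); mean distance",
      if (nrow(x$axis)) round(mean(x$axis$distance_um), 2) else NA,
      "um\n")
  invisible(x)
}

#' Compute mineral apposition rates from a growth field
#'
#' Converts per-pixel growth distances (um laid down over the inter-label
#' interval) to mm/day, per connected growth region and pooled over the
#' whole field.
#'
#' @param field A \code{\link{build_growth_field}} result.
#' @param interval_days Days between the two label injections (default 7:
#'   alizarin at day -8, calcein at day -1).
#' @return A data.frame with one row per region plus a \code{"pooled"} row:
#'   \code{region_id}, \code{mean_mar_mm_per_day}, \code{sd_mar},
#'   \code{n_pixels}, \code{length_um}, \code{interval_days}.
#' @export
compute_mar <- function(field, interval_days = 7) {
  stopifnot(inherits(field, "growth_field"), interval_days > 0)
  k <- 1 / interval_days / 1000 # um per interval -> mm/day
  d <- field$axis$distance_um
  if (length(d) == 0L) {
    warning("growth field has no axis pixels", call. = FALSE)
    return(data.frame(
      region_id = character(0), mean_mar_mm_per_day = numeric(0),
      sd_mar = numeric(0), n_pixels = integer(0), length_um = numeric(0),
      interval_days = numeric(0)
    ))
  }
  rows <- lapply(seq_len(nrow(field$regions)), function(i) {
    k_id <- field$regions$region_id[i]
    di <- d[field$region_id == k_id]
    data.frame(
      region_id = as.character(k_id),
      mean_mar_mm_per_day = mean(di) * k,
      sd_mar = if (length(di) > 1) stats::sd(di) * k else 0,
      n_pixels = length(di),
      length_um = field$regions$length_um[i],
      interval_days = interval_days
    )
  })
  pooled <- data.frame(
    region_id = "pooled",
    mean_mar_mm_per_day = mean(d) * k,
    sd_mar = if (length(d) > 1) stats::sd(d) * k else 0,
    n_pixels = length(d),
    length_um = sum(field$regions$length_um),
    interval_days = interval_days
  )
  rbind(do.call(rbind, rows), pooled)
}

#' Total length and area of a fluorochrome label
#'
#' @param mask A \code{fluoro_mask}.
#' @param skeleton Optional \code{skeleton_mask} derived from \code{mask};
#'   computed if absent.
#' @return List with \code{total_length_um} (skeleton curve length, with the
#'   sqrt(2) correction for diagonal steps) and \code{total_area_um2}.
#' @export
measure_labels <- function(mask, skeleton = NULL) {
  stopifnot(inherits(mask, "fluoro_mask"))
  px <- mask$pixel_size_um
  if (is.null(skeleton)) skeleton <- skeletonize_pruned(mask, prune_length_um = 0)
  sk <- if (inherits(skeleton, "skeleton_mask")) skeleton$mask else as_binary_matrix(skeleton)
  list(
    total_length_um = skeleton_length_px(sk) * px,
    total_area_um2 = sum(mask$mask) * px^2
  )
}

#' Pseudo-colored growth-distance overlay
#'
#' Renders the growth field's axis pixels colored by growth distance on a
#' grayscale version of the input image, with a vertical color-bar strip
#' appended at the right edge. Purely for reporting; no measurement depends
#' on it.
#'
#' @param field A \code{growth_field}.
#' @param image The source \code{labeled_image}.
#' @param palette Function \code{n -> colors}; default viridis.
#' @param range_um Distance range mapped onto the palette (default the
#'   field's own range).
#' @param colorbar Append a color-bar strip (default TRUE).
#' @return An rows x cols x 3 RGB array in [0, 1], with attribute
#'   \code{"legend"} (list of \code{range_um} and \code{colors}).
#' @export
render_overlay <- function(field, image,
                           palette = function(n) grDevices::hcl.colors(n, "viridis"),
                           range_um = NULL, colorbar = TRUE) {
  stopifnot(inherits(field, "growth_field"), inherits(image, "labeled_image"))
  gray <- apply(image$pixels, c(1, 2), mean)
  gray <- gray - min(gray)
  if (max(gray) > 0) gray <- gray / max(gray)
  out <- array(gray, dim = c(dim(gray), 3L))
  cols <- palette(256L)
  rgbm <- grDevices::col2rgb(cols) / 255
  if (nrow(field$axis) > 0) {
    d <- field$axis$distance_um
    if (is.null(range_um)) range_um <- range(d)
    span <- max(range_um[2] - range_um[1], .Machine$double.eps)
    ci <- pmin(pmax(floor((d - range_um[1]) / span * 255) + 1L, 1L), 256L)
    ij <- cbind(field$axis$row + 1L, field$axis$col + 1L)
    for (ch in 1:3) {
      pl <- out[, , ch]
      pl[ij] <- rgbm[ch, ci]
      out[, , ch] <- pl
    }
  } else {
    range_um <- c(0, 0)
  }
  if (colorbar) {
    nr <- dim(out)[1]
    bar_ci <- pmin(pmax(ceiling(rev(seq_len(nr)) / nr * 256), 1L), 256L)
    bar <- array(0, dim = c(nr, 12L, 3L))
    for (ch in 1:3) bar[, 3:10, ch] <- matrix(rgbm[ch, bar_ci], nr, 8L)
    out2 <- array(0, dim = dim(out) + c(0L, 12L, 0L))
    out2[, seq_len(dim(out)[2]), ] <- out
    out2[, dim(out)[2] + 1:12, ] <- bar
    out <- out2
  }
  attr(out, "legend") <- list(range_um = range_um, colors = cols)
  out
}
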