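# Label segmentation: from a raw fluorescence micrograph to clean
# per-fluorochrome binary masks (normalization, channel separation,
# thresholding, boundary smoothing / hole filling / area-length filters).

#' Construct a labeled fluorescence image
#'
#' @param pixels 2-D matrix (single channel) or 3-D array (rows x cols x
#'   channels) of intensities in [0, 1].
#' @param pixel_size_um Physical pixel size in micrometres.
#' @param channel_roles Character vector, one of "alizarin", "calcein",
#'   "other" per channel. For plain RGB input use \code{c("other", "other",
#'   "other")} (or omit) and let \code{\link{separate_channels}} unmix.
#' @return A \code{labeled_image}.
#' @export
labeled_image <- function(pixels, pixel_size_um, channel_roles = NULL) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  stopifnot(length(dim(pixels)) == 3L, pixel_size_um > 0)
  nch <- dim(pixels)[3]
  if (is.null(channel_roles)) channel_roles <- rep("other", nch)
  stopifnot(length(channel_roles) == nch,
            all(channel_roles %in% c("alizarin", "calcein", "other")))
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         channel_roles = channel_roles),
    class = "labeled_image"
  )
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<labeled_image>", d[1], "x", d[2], "px,", d[3], "channel(s) [",
      paste(x$channel_roles, collapse = ", "), "] @",
      x$pixel_size_um, "um/px\n")
  invisible(x)
}

# Pull a single named channel out of a labeled image.
get_channel <- function(image, role) {
  i <- which(image$channel_roles == role)
  if (length(i) != 1L) {
    stop_input("image must have exactly one '", role, "' channel")
  }
  image$pixels[, , i]
}

#' Percentile normalization of fluorescence channels
#'
#' Each channel is independently rescaled so that its
#' \code{background_percentile} maps to 0 and its
#' \code{saturation_percentile} maps to 1, with clipping. Order-statistic
#' (type 1) quantiles are used, which makes the operation exactly
#' idempotent. A channel with no intensity spread is returned unchanged and
#' flagged.
#'
#' @param image A \code{\link{labeled_image}}.
#' @param background_percentile,saturation_percentile Percentiles in
#'   [0, 100], background strictly below saturation.
#' @return A \code{labeled_image} with attribute \code{"constant_channels"}
#'   (integer vector of unnormalizable channels, if any).
#' @export
normalize_channels <- function(image, background_percentile = 1,
                               saturation_percentile = 99.9) {
  stopifnot(inherits(image, "labeled_image"),
            background_percentile >= 0,
            saturation_percentile <= 100,
            background_percentile < saturation_percentile)
  px <- image$pixels
  flagged <- integer(0)
  for (i in seq_len(dim(px)[3])) {
    v <- px[, , i]
    q <- stats::quantile(
      v, c(background_percentile, saturation_percentile) / 100,
      type = 1, names = FALSE
    )
    if (q[2] - q[1] <= .Machine$double.eps) {
      flagged <- c(flagged, i)
      next
    }
    px[, , i] <- pmin(pmax((v - q[1]) / (q[2] - q[1]), 0), 1)
  }
  if (length(flagged)) {
    warning("channel(s) ", paste(flagged, collapse = ", "),
            " have no intensity spread; returned unchanged", call. = FALSE)
  }
  out <- labeled_image(px, image$pixel_size_um, image$channel_roles)
  attr(out, "constant_channels") <- flagged
  out
}

#' Separate alizarin and calcein channels
#'
#' For an image with declared fluorochrome roles the channels are passed
#' through. For plain RGB input the fluorochromes are unmixed linearly:
#' alizarin = red - alpha * green, calcein = green - beta * red, floored at
#' zero; \code{alpha}/\code{beta} are cross-talk (bleed) coefficients.
#'
#' @param image A \code{\link{labeled_image}}.
#' @param alpha,beta Cross-talk coefficients (default 0).
#' @return A 2-channel \code{labeled_image} with roles alizarin, calcein.
#' @export
separate_channels <- function(image, alpha = 0, beta = 0) {
  stopifnot(inherits(image, "labeled_image"))
  roles <- image$channel_roles
  if ("alizarin" %in% roles && "calcein" %in% roles) {
    a <- get_channel(image, "alizarin")
    c_ <- get_channel(image, "calcein")
  } else if (dim(image$pixels)[3] == 3L) {
    r <- image$pixels[, , 1]; g <- image$pixels[, , 2]
    a <- pmax(r - alpha * g, 0)
    c_ <- pmax(g - beta * r, 0)
  } else if (dim(image$pixels)[3] == 1L) {
    stop_input("single-channel image: cannot attribute fluorochromes")
  } else {
    stop_input("image needs channel roles or 3 RGB channels")
  }
  labeled_image(array(c(a, c_), dim = c(dim(a), 2L)),
                image$pixel_size_um, c("alizarin", "calcein"))
}

#' Binarize a fluorochrome channel
#'
#' @param channel Numeric matrix in [0, 1] (one channel of a normalized
#'   image).
#' @param method "otsu" (parameter-free, default) or "fixed".
#' @param fixed_value Threshold for \code{method = "fixed"}; pixels strictly
#'   above it are foreground.
#' @param pixel_size_um Physical pixel size carried into the mask.
#' @param fluorochrome "alizarin", "calcein" or "other".
#' @return A \code{fluoro_mask}: list with \code{mask} (0/1 matrix),
#'   \code{fluorochrome}, \code{pixel_size_um} and a \code{provenance}
#'   record of the binarization.
#' @export
threshold_mask <- function(channel, method = c("otsu", "fixed"),
                           fixed_value = NULL, pixel_size_um = 1,
                           fluorochrome = "other") {
  method <- match.arg(method)
  stopifnot(is.matrix(channel), pixel_size_um > 0)
  if (method == "otsu") {
    if (max(channel) - min(channel) <= .Machine$double.eps) {
      warning("constant channel: Otsu threshold undefined, mask is empty",
              call. = FALSE)
      thr <- Inf
    } else {
      thr <- EBImage::otsu(EBImage::Image(channel), range = c(0, 1))
    }
  } else {
    if (is.null(fixed_value)) stop_input("fixed_value required")
    thr <- fixed_value
  }
  structure(
    list(
      mask = (channel > thr) * 1L,
      fluorochrome = fluorochrome,
      pixel_size_um = pixel_size_um,
      provenance = list(step = "threshold", method = method, threshold = thr)
    ),
    class = "fluoro_mask"
  )
}

#' @export
print.fluoro_mask <- function(x, ...) {
  cat("<fluoro_mask>", x$fluorochrome, ":", sum(x$mask), "fg pixels,",
      nrow(x$mask), "x", ncol(x$mask), "@", x$pixel_size_um, "um/px\n")
  invisible(x)
}

#' Morphological cleanup of a fluorochrome mask
#'
#' Boundary smoothing (morphological closing then opening with a disc),
#' interior hole filling, and removal of connected components below an area
#' or skeleton-length threshold. All geometric parameters are physical
#' (micrometres) and converted to pixels through the mask's pixel size. With
#' all parameters zero the mask is returned unchanged.
#'
#' @param mask A \code{fluoro_mask}.
#' @param smooth_radius_um Disc radius for closing/opening; 0 disables.
#' @param min_area_um2 Components with area below this are removed.
#' @param min_length_um Components whose medial-axis length is below this
#'   are removed.
#' @param max_hole_area_um2 Interior holes up to this area are filled
#'   (default \code{Inf}: fill all; 0 disables).
#' @return A cleaned \code{fluoro_mask} with updated provenance.
#' @export
clean_mask <- function(mask, smooth_radius_um = 0, min_area_um2 = 100,
                       min_length_um = 50, max_hole_area_um2 = Inf) {
  stopifnot(inherits(mask, "fluoro_mask"),
            smooth_radius_um >= 0, min_area_um2 >= 0, min_length_um >= 0,
            max_hole_area_um2 >= 0)
  px <- mask$pixel_size_um
  m <- as_binary_matrix(mask$mask)

  r_px <- um_to_px(smooth_radius_um, px)
  if (r_px > 0 && sum(m) > 0) {
    brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
    m <- as_binary_matrix(EBImage::opening(EBImage::closing(m, brush), brush))
  }

  if (max_hole_area_um2 > 0 && sum(m) > 0) {
    filled <- as_binary_matrix(EBImage::fillHull(m))
    holes <- filled - m
    if (sum(holes) > 0 && is.finite(max_hole_area_um2)) {
      lab <- EBImage::bwlabel(holes)
      sizes <- tabulate(lab[lab > 0])
      keep_fill <- which(sizes * px^2 <= max_hole_area_um2)
      m[lab %in% keep_fill] <- 1L
    } else {
      m <- filled
    }
  }

  if ((min_area_um2 > 0 || min_length_um > 0) && sum(m) > 0) {
    lab <- EBImage::bwlabel(m)
    ncomp <- max(lab)
    if (ncomp > 0) {
      areas <- tabulate(lab[lab > 0], nbins = ncomp) * px^2
      drop <- areas < min_area_um2
      if (min_length_um > 0) {
        sk_lab <- thin_binary(m) * lab
        lens <- component_lengths_px(sk_lab, ncomp) * px
        drop <- drop | lens < min_length_um
      }
      if (any(drop)) m[lab %in% which(drop)] <- 0L
    }
  }

  structure(
    list(
      mask = m, fluorochrome = mask$fluorochrome, pixel_size_um = px,
      provenance = c(mask["provenance"], list(clean = list(
        smooth_radius_um = smooth_radius_um, min_area_um2 = min_area_um2,
        min_length_um = min_length_um, max_hole_area_um2 = max_hole_area_um2
      )))
    ),
    class = "fluoro_mask"
  )
}
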