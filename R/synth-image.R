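# Synthetic double-label image generator.
#
# Emulates a fluorescence micrograph of an alizarin-red / calcein-green
# double-labeled bone surface: two quasi-parallel fluorescent bands whose
# medial axes are a known distance apart, the distance laid down over the
# inter-label interval (7 days by default). Because the medial-axis
# separation is known exactly, every downstream stage of the measurement
# pipeline can be validated against ground truth.

#' Specification of a synthetic double-label band pair
#'
#' @param separation_um Center-to-center (medial axis to medial axis)
#'   distance between the alizarin and calcein bands, in micrometres.
#' @param band_thickness_um Thickness of each fluorescent band, um.
#' @param curvature Reciprocal radius of the band arcs in 1/um; 0 gives
#'   straight bands. Mimics the curvature of a cortical surface.
#' @param gap_fraction Fraction in [0, 1) of each band's length erased in
#'   random runs, simulating label dropout.
#' @param gap_run_um Length of each erased run along the band (um). Default
#'   50 um: dropout in real sections occurs over surface patches of tens of
#'   micrometres, not single pixels.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise
#'   (intensities are clipped to [0, 1]).
#' @param background_level Background intensity in [0, 1).
#' @param seed Integer seed; images generated from the same spec and seed
#'   are bit-identical.
#' @return A \code{band_spec} list.
#' @export
band_spec <- function(separation_um, band_thickness_um, curvature = 0,
                      gap_fraction = 0, gap_run_um = 50, noise_sd = 0,
                      background_level = 0.05, seed = 1L) {
  stopifnot(
    separation_um > 0, band_thickness_um > 0,
    gap_fraction >= 0, gap_fraction < 1, gap_run_um > 0,
    noise_sd >= 0, background_level >= 0, background_level < 1,
    curvature >= 0
  )
  structure(
    list(
      separation_um = separation_um, band_thickness_um = band_thickness_um,
      curvature = curvature, gap_fraction = gap_fraction,
      gap_run_um = gap_run_um, noise_sd = noise_sd,
      background_level = background_level, seed = as.integer(seed)
    ),
    class = "band_spec"
  )
}

# Choose the axis-parameter blocks to erase. Dropout is a property of the
# bone surface patch (a quiescent patch binds neither dye), so the same
# blocks are erased from both labels. Blocks are drawn in random order and
# the prefix whose pixel total is closest to gap_fraction of the band is
# erased, so the realized fraction is exact to half a block.
choose_erased_blocks <- function(block_ids, gap_fraction) {
  if (gap_fraction <= 0) return(integer(0))
  sizes <- table(block_ids)
  blocks <- as.integer(names(sizes))
  ord <- sample(length(blocks))
  cum <- cumsum(as.integer(sizes)[ord])
  k <- which.min(abs(cum - gap_fraction * sum(sizes)))
  blocks[ord[seq_len(k)]]
}

#' Generate a synthetic double-label fluorescence image
#'
#' Renders two bands (channel 1 = alizarin red, channel 2 = calcein green)
#' whose medial axes are \code{separation_um} apart everywhere: straight
#' parallel lines for zero curvature, concentric arcs otherwise. Label
#' dropout erases the same axis runs from both bands (dropout reflects a
#' quiescent or damaged surface patch, which binds neither dye). Two
#' derived RNG streams are used (\code{seed} for dropout, \code{seed + 1}
#' for noise) so that changing \code{gap_fraction} alone leaves the noise
#' field identical.
#'
#' @param spec A \code{\link{band_spec}}.
#' @param image_size_px Integer pair (rows, cols).
#' @param pixel_size_um Physical pixel size, um.
#' @param interval_days Inter-label interval used for the ground-truth MAR
#'   record (default 7 days: alizarin 8 days and calcein 1 day before
#'   sacrifice).
#' @return A list with \code{image} (a \code{\link{labeled_image}}),
#'   \code{truth} (true separation, MAR in mm/day, band footprints as 0/1
#'   matrices), and the spec.
#' @export
generate_double_label_image <- function(spec, image_size_px = c(256L, 256L),
                                        pixel_size_um = 5,
                                        interval_days = 7) {
  stopifnot(inherits(spec, "band_spec"), pixel_size_um > 0,
            length(image_size_px) == 2L, interval_days > 0)
  nr <- as.integer(image_size_px[1]); nc <- as.integer(image_size_px[2])
  sep <- spec$separation_um; th <- spec$band_thickness_um
  if (sep <= th) {
    stop_input("bands would overlap: separation_um (", sep,
               ") must exceed band_thickness_um (", th, ")")
  }
  if (th < pixel_size_um) {
    stop_input("band_thickness_um (", th, ") is below one pixel (",
               pixel_size_um, " um): bands are not resolvable")
  }
  if (th < 2 * pixel_size_um || sep < 2 * pixel_size_um) {
    warning("bands thinner than 2 pixels are at the resolution limit",
            call. = FALSE)
  }
  extent_um <- sep + th + 4 * pixel_size_um
  if (extent_um > nr * pixel_size_um || extent_um > nc * pixel_size_um) {
    stop_input("image too small to contain both bands: need at least ",
               ceiling(extent_um / pixel_size_um), " px per side")
  }

  # pixel-center coordinates in um (row-major, 0-based pixel centers)
  y <- (seq_len(nr) - 1) * pixel_size_um
  x <- (seq_len(nc) - 1) * pixel_size_um
  yy <- matrix(y, nr, nc)
  xx <- matrix(x, nr, nc, byrow = TRUE)
  cy <- (nr - 1) * pixel_size_um / 2
  cx <- (nc - 1) * pixel_size_um / 2

  if (spec$curvature == 0) {
    # horizontal straight bands: axis distance is the vertical offset
    d1 <- abs(yy - (cy - sep / 2))
    d2 <- abs(yy - (cy + sep / 2))
    tpar <- xx / max(x) # axis parameter for dropout blocks
  } else {
    r0 <- 1 / spec$curvature
    # concentric arcs centered below the image so the arcs open downward
    ccy <- cy + r0
    rr <- sqrt((yy - ccy)^2 + (xx - cx)^2)
    d1 <- abs(rr - (r0 + sep / 2))
    d2 <- abs(rr - (r0 - sep / 2))
    tpar <- (atan2(xx - cx, ccy - yy) / pi + 1) / 2
  }
  band1 <- d1 <= th / 2 # alizarin (laid down first)
  band2 <- d2 <= th / 2 # calcein

  # dropout: erased runs of gap_run_um along the band axis, one RNG stream
  # per channel
  block_len <- spec$gap_run_um / (max(x) + pixel_size_um)
  block_id <- pmin(floor(tpar / block_len), ceiling(1 / block_len))
  erased <- with_seed(
    spec$seed,
    choose_erased_blocks(block_id[band1 | band2], spec$gap_fraction)
  )
  g1 <- band1 & !(block_id %in% erased)
  g2 <- band2 & !(block_id %in% erased)

  bg <- spec$background_level
  ch1 <- matrix(bg, nr, nc); ch1[g1] <- 0.9
  ch2 <- matrix(bg, nr, nc); ch2[g2] <- 0.9
  if (spec$noise_sd > 0) {
    with_seed((spec$seed + 1L) %% .Machine$integer.max, {
      ch1 <- ch1 + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
      ch2 <- ch2 + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    })
    ch1 <- pmin(pmax(ch1, 0), 1)
    ch2 <- pmin(pmax(ch2, 0), 1)
  }

  img <- labeled_image(
    pixels = array(c(ch1, ch2), dim = c(nr, nc, 2L)),
    pixel_size_um = pixel_size_um,
    channel_roles = c("alizarin", "calcein")
  )
  truth <- list(
    separation_um = sep,
    interval_days = interval_days,
    mar_mm_per_day = sep / interval_days / 1000,
    alizarin_band = band1 * 1L,
    calcein_band = band2 * 1L,
    alizarin_after_gaps = g1 * 1L,
    calcein_after_gaps = g2 * 1L
  )
  list(image = img, truth = truth, spec = spec)
}
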