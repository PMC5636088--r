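#' @keywords internal
#' @importFrom stats quantile rnorm sd var aov TukeyHSD qf cor.test
#' @importFrom utils read.csv write.csv head capture.output packageVersion
#' @importFrom grDevices hcl.colors col2rgb
#' @importFrom tools md5sum
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Physical micrometres -> integer pixel count. Values that round to zero are
# kept at zero (the corresponding operation is skipped); positive values are
# at least one pixel.
um_to_px <- function(um, pixel_size_um) {
  stopifnot(is.numeric(um), length(um) == 1L, um >= 0, pixel_size_um > 0)
  if (um == 0) return(0L)
  max(0L, as.integer(round(um / pixel_size_um)))
}

# Shift a matrix by (dr, dc) filling vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Count of foreground 8-neighbors for every pixel of a 0/1 matrix.
neighbor_count <- function(m) {
  shift_mat(m, -1, 0) + shift_mat(m, 1, 0) + shift_mat(m, 0, -1) +
    shift_mat(m, 0, 1) + shift_mat(m, -1, -1) + shift_mat(m, -1, 1) +
    shift_mat(m, 1, -1) + shift_mat(m, 1, 1)
}

# Curve length of a binary skeleton in pixels: pixel count plus a sqrt(2)
# correction for each diagonal step that is not part of an orthogonal path.
skeleton_length_px <- function(m) {
  if (sum(m) == 0) return(0)
  diag1 <- sum(m * shift_mat(m, 1, 1))
  diag2 <- sum(m * shift_mat(m, 1, -1))
  sum(m) + (sqrt(2) - 1) * (diag1 + diag2)
}

# Per-component skeleton curve lengths (pixels) for a labeled skeleton; one
# pass over the image instead of one per component. Diagonal edges are
# attributed to the component of their upper pixel (both ends share it).
component_lengths_px <- function(lab, ncomp = max(lab)) {
  if (ncomp == 0) return(numeric(0))
  m <- (lab > 0) * 1L
  npx <- tabulate(lab[lab > 0], nbins = ncomp)
  d1 <- m * shift_mat(m, 1, 1)
  d2 <- m * shift_mat(m, 1, -1)
  ed <- tabulate(lab[d1 == 1], nbins = ncomp) +
    tabulate(lab[d2 == 1], nbins = ncomp)
  npx + (sqrt(2) - 1) * ed
}

# 8-connected component labeling (EBImage::bwlabel is 4-connected, which
# would split skeleton curves at every diagonal step): label the 3x3
# dilation, then restrict to the original foreground.
label8 <- function(m) {
  m <- as_binary_matrix(m)
  if (sum(m) == 0) return(m)
  fat <- as_binary_matrix(EBImage::dilate(m, EBImage::makeBrush(3, "box")))
  lab <- EBImage::bwlabel(fat)
  lab[m == 0] <- 0
  # compact label ids
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) && !identical(ids, seq_along(ids))) {
    lab[] <- match(lab, c(0, ids)) - 1L
  }
  lab
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("histomar_input_error", "error")))
}

as_binary_matrix <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  d <- dim(x)
  m <- as.integer(x != 0)
  dim(m) <- d[1:2]
  m
}
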