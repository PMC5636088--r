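# Medial-axis skeletonization (Zhang-Suen thinning) and spur pruning.
#
# The labeling lines laid down by alizarin and calcein are band-shaped; the
# algorithm reduces each band mask to a 1-pixel-thick curve along its medial
# axis, then iteratively removes side branches ("spurs") shorter than a
# physical length threshold, which arise from boundary roughness.

# One Zhang-Suen pass; `step` is 1 or 2. Returns the updated 0/1 matrix.
zs_pass <- function(m, step) {
  p2 <- shift_mat(m, -1, 0); p3 <- shift_mat(m, -1, 1)
  p4 <- shift_mat(m, 0, 1); p5 <- shift_mat(m, 1, 1)
  p6 <- shift_mat(m, 1, 0); p7 <- shift_mat(m, 1, -1)
  p8 <- shift_mat(m, 0, -1); p9 <- shift_mat(m, -1, -1)
  b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  # number of 0->1 transitions in the circular sequence p2,p3,...,p9,p2
  a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
    (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
    (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
  if (step == 1L) {
    c1 <- p2 * p4 * p6 == 0
    c2 <- p4 * p6 * p8 == 0
  } else {
    c1 <- p2 * p4 * p8 == 0
    c2 <- p2 * p6 * p8 == 0
  }
  del <- m == 1 & b >= 2 & b <= 6 & a == 1 & c1 & c2
  m[del] <- 0L
  m
}

# Thin a binary mask to a 1-pixel-wide, 8-connected skeleton.
thin_binary <- function(mask) {
  m <- as_binary_matrix(mask)
  repeat {
    before <- sum(m)
    m <- zs_pass(m, 1L)
    m <- zs_pass(m, 2L)
    if (sum(m) == before) break
  }
  m
}

# Trace the branch starting at endpoint (r, c) until a junction, an endpoint,
# or a loop closure. Returns list(pixels = n x 2, length_px, at_junction).
trace_branch <- function(m, deg, r, c) {
  nbr <- rbind(
    c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
    c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)
  )
  nr <- nrow(m); nc <- ncol(m)
  path <- matrix(c(r, c), 1, 2)
  len <- 0
  prev <- c(NA_integer_, NA_integer_)
  cur <- c(r, c)
  repeat {
    cand <- cbind(cur[1] + nbr[, 1], cur[2] + nbr[, 2])
    ok <- cand[, 1] >= 1 & cand[, 1] <= nr & cand[, 2] >= 1 & cand[, 2] <= nc
    cand <- cand[ok, , drop = FALSE]
    fg <- cand[m[cand] == 1, , drop = FALSE]
    if (!is.na(prev[1])) {
      keep <- !(fg[, 1] == prev[1] & fg[, 2] == prev[2])
      # also exclude any pixel already on the path (guards tight turns)
      keep <- keep & !(paste(fg[, 1], fg[, 2]) %in% paste(path[, 1], path[, 2]))
      fg <- fg[keep, , drop = FALSE]
    }
    if (nrow(fg) == 0L) {
      return(list(pixels = path, length_px = len, at_junction = FALSE))
    }
    if (nrow(fg) > 1L) {
      # current pixel touches multiple continuations: treat as junction here
      return(list(pixels = path, length_px = len, at_junction = TRUE))
    }
    nxt <- fg[1, ]
    step <- if (abs(nxt[1] - cur[1]) + abs(nxt[2] - cur[2]) == 2) sqrt(2) else 1
    if (deg[nxt[1], nxt[2]] >= 3) {
      return(list(pixels = path, length_px = len + step, at_junction = TRUE))
    }
    path <- rbind(path, nxt)
    len <- len + step
    prev <- cur
    cur <- nxt
  }
}

# Remove skeleton side branches shorter than `prune_px` (curve length in
# pixels), iterating until no further branch qualifies. Branches are only
# pruned when attached to a junction, so an isolated simple curve (the
# labeling line itself) is never consumed.
prune_spurs <- function(skel, prune_px) {
  m <- as_binary_matrix(skel)
  if (prune_px <= 0 || sum(m) == 0) return(m)
  repeat {
    deg <- neighbor_count(m)
    ends <- which(m == 1 & deg == 1, arr.ind = TRUE)
    if (nrow(ends) == 0L) break
    removed <- FALSE
    for (i in seq_len(nrow(ends))) {
      r <- ends[i, 1]; c <- ends[i, 2]
      if (m[r, c] == 0) next # consumed by an earlier removal this round
      br <- trace_branch(m, deg, r, c)
      if (br$at_junction && br$length_px < prune_px) {
        m[br$pixels] <- 0L
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  # re-thin: pruning can leave junction pixels with redundant neighbors
  thin_binary(m)
}

#' Skeletonize a fluorochrome mask with spur pruning
#'
#' Reduces a binary label mask to a 1-pixel-thick medial-axis curve and
#' iteratively removes side branches shorter than \code{prune_length_um},
#' which typically arise from boundary roughness of the band rather than
#' genuine label geometry.
#'
#' @param mask A \code{fluoro_mask} (see \code{\link{threshold_mask}}) or a
#'   binary matrix.
#' @param prune_length_um Branches (measured as curve length) shorter than
#'   this are removed. Default 30 um, below the thickness of a genuine
#'   labeling line; set to 0 to disable pruning.
#' @param pixel_size_um Physical pixel size in micrometres; taken from the
#'   mask if it carries one.
#' @param fluorochrome Label carried through to the result.
#' @return A \code{skeleton_mask}: list with \code{mask} (0/1 matrix),
#'   \code{fluorochrome}, \code{branch_pruned}, \code{pixel_size_um}.
#' @export
skeletonize_pruned <- function(mask, prune_length_um = 30,
                               pixel_size_um = NULL, fluorochrome = NULL) {
  if (inherits(mask, "fluoro_mask")) {
    if (is.null(pixel_size_um)) pixel_size_um <- mask$pixel_size_um
    if (is.null(fluorochrome)) fluorochrome <- mask$fluorochrome
    mask <- mask$mask
  }
  if (is.null(pixel_size_um)) stop_input("pixel_size_um is required")
  stopifnot(pixel_size_um > 0, prune_length_um >= 0)
  m <- as_binary_matrix(mask)
  skel <- thin_binary(m)
  skel <- prune_spurs(skel, prune_length_um / pixel_size_um)
  structure(
    list(
      mask = skel,
      fluorochrome = if (is.null(fluorochrome)) "other" else fluorochrome,
      branch_pruned = TRUE,
      pixel_size_um = pixel_size_um
    ),
    class = "skeleton_mask"
  )
}

#' @export
print.skeleton_mask <- function(x, ...) {
  cat(
    "<skeleton_mask>", x$fluorochrome, ":", sum(x$mask), "pixels,",
    nrow(x$mask), "x", ncol(x$mask), "grid @", x$pixel_size_um, "um/px\n"
  )
  invisible(x)
}
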