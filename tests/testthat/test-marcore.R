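# Matching, growth field, MAR computation, label measurement, overlay.

skel_from <- function(m, px) {
  structure(list(mask = histomar:::as_binary_matrix(m), fluorochrome = "other",
                 branch_pruned = TRUE, pixel_size_um = px),
            class = "skeleton_mask")
}

test_that("single-pair geometry and the distance cap behave as specified", {
  a <- matrix(0L, 20, 20); a[1, 1] <- 1L
  c_ <- matrix(0L, 20, 20); c_[1, 6] <- 1L
  ms <- match_skeletons(skel_from(a, 10), skel_from(c_, 10))
  expect_equal(nrow(ms$pairs), 1L)
  expect_equal(ms$pairs$distance_um, 50)
  expect_equal(ms$pairs$c_col, 5) # 0-based
  # nearest calcein 150 um away -> unmatched under the 100 um cap
  c2 <- matrix(0L, 20, 20); c2[1, 16] <- 1L
  ms2 <- match_skeletons(skel_from(a, 10), skel_from(c2, 10))
  expect_equal(nrow(ms2$pairs), 0L)
  expect_equal(ms2$n_unmatched, 1L)
  # empty calcein skeleton
  ms3 <- match_skeletons(skel_from(a, 10), skel_from(matrix(0L, 20, 20), 10))
  expect_equal(nrow(ms3$pairs), 0L)
})

test_that("equidistant candidates resolve to the smallest (row, col) coordinate", {
  a <- matrix(0L, 11, 11); a[6, 6] <- 1L
  c_ <- matrix(0L, 11, 11)
  c_[3, 6] <- 1L; c_[9, 6] <- 1L; c_[6, 3] <- 1L; c_[6, 9] <- 1L # all at d = 3
  ms <- match_skeletons(skel_from(a, 10), skel_from(c_, 10))
  expect_equal(c(ms$pairs$c_row, ms$pairs$c_col), c(2, 5)) # 0-based (3, 6)
})

test_that("matching equals the brute-force oracle on random instances", {
  set.seed(42)
  for (rep in 1:25) {
    n_a <- sample(5:300, 1); n_c <- sample(5:300, 1)
    a <- matrix(0L, 60, 60); c_ <- matrix(0L, 60, 60)
    a[sample(3600, n_a)] <- 1L
    c_[sample(3600, n_c)] <- 1L
    cap <- sample(c(30, 80, 150), 1)
    ms <- match_skeletons(skel_from(a, 10), skel_from(c_, 10),
                          max_distance_um = cap)
    ora <- oracle_match(which(a == 1, arr.ind = TRUE) - 1L,
                        which(c_ == 1, arr.ind = TRUE) - 1L, cap / 10)
    if (is.null(ora)) {
      expect_equal(nrow(ms$pairs), 0L)
    } else {
      got <- as.matrix(ms$pairs[order(ms$pairs$a_row, ms$pairs$a_col),
                                c("a_row", "a_col", "c_row", "c_col")])
      want <- ora[order(ora[, 1], ora[, 2]), 1:4, drop = FALSE]
      expect_equal(unname(got), unname(want))
      expect_equal(sort(ms$pairs$distance_um), sort(ora[, 5] * 10))
    }
  }
})

test_that("raising the cap never loses matches; unit scaling is exact", {
  set.seed(7)
  a <- matrix(0L, 50, 50); c_ <- matrix(0L, 50, 50)
  a[sample(2500, 80)] <- 1L; c_[sample(2500, 80)] <- 1L
  counts <- vapply(c(20, 50, 100, 200, 500), function(cap) {
    nrow(match_skeletons(skel_from(a, 10), skel_from(c_, 10), cap)$pairs)
  }, 1L)
  expect_true(all(diff(counts) >= 0))
  # doubling pixel size doubles all reported distances exactly
  m1 <- match_skeletons(skel_from(a, 5), skel_from(c_, 5), 1e4)
  m2 <- match_skeletons(skel_from(a, 10), skel_from(c_, 10), 2e4)
  expect_equal(m2$pairs$distance_um, 2 * m1$pairs$distance_um)
})

test_that("parallel fully matched lines give a midway axis measuring the separation", {
  bands <- make_parallel_bands(60L, 120L, row_a = 20L, row_c = 34L, half_th = 0L)
  ms <- match_skeletons(skel_from(bands$a, 5), skel_from(bands$c, 5))
  expect_equal(unique(ms$pairs$distance_um), 70)
  f <- build_growth_field(ms)
  rows <- f$axis$row + 1L
  expect_true(all(abs(rows - 27) <= 1)) # midway between rows 20 and 34
  expect_true(all(abs(f$axis$distance_um - 70) <= 5 + 1e-9)) # one pixel
  # the two distance estimators agree
  expect_lt(abs(mean(f$axis$distance_um) - mean(ms$pairs$distance_um)) /
              mean(ms$pairs$distance_um), 0.1)
})

test_that("a single matched pair yields one degenerate region whose length matches the pair distance", {
  a <- matrix(0L, 40, 40); a[10, 20] <- 1L
  c_ <- matrix(0L, 40, 40); c_[24, 20] <- 1L
  ms <- match_skeletons(skel_from(a, 5), skel_from(c_, 5))
  f <- build_growth_field(ms, close_radius_um = 0)
  expect_equal(nrow(f$regions), 1L)
  # the region's medial axis spans the rasterized segment joining the pair
  expect_equal(f$regions$length_um, ms$pairs$distance_um, tolerance = 0.15)
})

test_that("empty match sets give empty fields and MAR warns", {
  ms <- match_skeletons(skel_from(matrix(0L, 5, 5), 5),
                        skel_from(matrix(0L, 5, 5), 5))
  expect_warning(f <- build_growth_field(ms), "empty")
  expect_warning(mar <- compute_mar(f), "no axis pixels")
  expect_equal(nrow(mar), 0L)
})

test_that("MAR arithmetic converts distances to mm/day over the interval", {
  f <- structure(
    list(axis = data.frame(row = 0:1, col = 0:1, distance_um = c(35, 105)),
         regions = data.frame(region_id = 1L, length_um = 10, n_pixels = 2L,
                              mean_distance_um = 70, degenerate = FALSE),
         region_id = c(1L, 1L), pixel_size_um = 5,
         growth_mask = matrix(0L, 2, 2), skeleton = matrix(0L, 2, 2)),
    class = "growth_field"
  )
  mar <- compute_mar(f, interval_days = 7)
  pooled <- mar[mar$region_id == "pooled", ]
  expect_equal(pooled$mean_mar_mm_per_day, 0.01)
  expect_equal(pooled$n_pixels, 2L)
  # constant field: zero SD
  f$axis$distance_um <- c(70, 70)
  mar2 <- compute_mar(f, 7)
  expect_equal(mar2$mean_mar_mm_per_day, c(0.01, 0.01))
  expect_equal(mar2$sd_mar, c(0, 0))
  expect_error(compute_mar(f, interval_days = 0))
})

test_that("MAR is invariant to which dye is treated as first", {
  gen <- generate_double_label_image(band_spec(70, 10, seed = 3), c(96L, 200L), 5)
  ska <- skeletonize_pruned(gen$truth$alizarin_band, 30, 5)
  skc <- skeletonize_pruned(gen$truth$calcein_band, 30, 5)
  m_ac <- compute_mar(build_growth_field(match_skeletons(ska, skc)))
  m_ca <- compute_mar(build_growth_field(match_skeletons(skc, ska)))
  expect_equal(m_ac$mean_mar_mm_per_day[nrow(m_ac)],
               m_ca$mean_mar_mm_per_day[nrow(m_ca)], tolerance = 1e-9)
})

test_that("label length and area measurements are physical", {
  m <- matrix(0L, 30, 120)
  m[15, 11:110] <- 1L # 100-px line
  fm <- structure(list(mask = m, fluorochrome = "calcein", pixel_size_um = 10,
                       provenance = list()), class = "fluoro_mask")
  meas <- measure_labels(fm, skel_from(m, 10))
  expect_equal(meas$total_length_um, 1000)
  band <- matrix(0L, 30, 120); band[10:14, 11:110] <- 1L
  fb <- structure(list(mask = band, fluorochrome = "calcein",
                       pixel_size_um = 10, provenance = list()),
                  class = "fluoro_mask")
  expect_equal(measure_labels(fb, skel_from(matrix(0L, 30, 120), 10))$total_area_um2,
               50000)
  # 45-degree diagonal of n pixels measures n * sqrt(2) * px within 2%
  n <- 80L
  d <- matrix(0L, 100, 100); d[cbind(5:(4 + n), 5:(4 + n))] <- 1L
  md <- measure_labels(structure(list(mask = d, fluorochrome = "other",
                                      pixel_size_um = 10, provenance = list()),
                                 class = "fluoro_mask"), skel_from(d, 10))
  expect_equal(md$total_length_um, n * sqrt(2) * 10, tolerance = 0.02)
})

test_that("overlays leave the grayscale untouched off-axis and color the axis by distance", {
  gen <- generate_double_label_image(band_spec(70, 10, seed = 3), c(96L, 128L), 5)
  res <- run_mar_pipeline(gen$image, pipeline_config(pixel_size_um = 5))
  ov <- render_overlay(res$field, gen$image, colorbar = FALSE)
  expect_equal(dim(ov), c(96L, 128L, 3L))
  gray <- apply(gen$image$pixels, c(1, 2), mean)
  gray <- (gray - min(gray)) / (max(gray) - min(gray))
  off <- matrix(TRUE, 96, 128)
  off[cbind(res$field$axis$row + 1L, res$field$axis$col + 1L)] <- FALSE
  for (ch in 1:3) expect_equal(ov[, , ch][off], gray[off])
  # empty field: pure grayscale
  ms0 <- match_skeletons(skel_from(matrix(0L, 96, 128), 5),
                         skel_from(matrix(0L, 96, 128), 5))
  f0 <- suppressWarnings(build_growth_field(ms0))
  ov0 <- render_overlay(f0, gen$image, colorbar = FALSE)
  for (ch in 1:3) expect_equal(ov0[, , ch], gray)
  # constant-distance field paints a single color
  ovc <- render_overlay(res$field, gen$image, range_um = c(0, 140),
                        colorbar = TRUE)
  expect_equal(dim(ovc)[2], 128L + 12L) # color bar appended
})
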