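# Synthetic double-label image and study-table generators.

test_that("straight bands at coarse resolution give 1-px stripes 7 px apart and MAR 0.01", {
  gen <- suppressWarnings(generate_double_label_image(
    band_spec(70, 10, seed = 1), c(64L, 64L), pixel_size_um = 10
  ))
  expect_equal(gen$truth$mar_mm_per_day, 0.01)
  a_rows <- which(rowSums(gen$truth$alizarin_band) > 0)
  c_rows <- which(rowSums(gen$truth$calcein_band) > 0)
  expect_length(a_rows, 1L)
  expect_length(c_rows, 1L)
  expect_equal(abs(a_rows - c_rows), 7L)
  # full-width stripes
  expect_true(all(gen$truth$alizarin_band[a_rows, ] == 1))
})

test_that("image generation is bit-identical for the same spec and seed", {
  spec <- band_spec(50, 10, noise_sd = 0.08, gap_fraction = 0.2, seed = 9)
  g1 <- generate_double_label_image(spec, c(96L, 128L), 5)
  g2 <- generate_double_label_image(spec, c(96L, 128L), 5)
  expect_identical(g1$image$pixels, g2$image$pixels)
})

test_that("gap erasure zeroes the stated fraction of band pixels and nothing else", {
  g0 <- generate_double_label_image(band_spec(70, 10, gap_fraction = 0, seed = 4),
                                    c(96L, 1000L), 2)
  g3 <- generate_double_label_image(band_spec(70, 10, gap_fraction = 0.3, seed = 4),
                                    c(96L, 1000L), 2)
  p0 <- g0$image$pixels; p3 <- g3$image$pixels
  changed <- p0 != p3
  # changed pixels are exactly band pixels set back to background
  expect_true(all(p3[changed] == g3$spec$background_level))
  band_px <- sum(g0$truth$alizarin_band) + sum(g0$truth$calcein_band)
  expect_equal(sum(changed) / band_px, 0.3, tolerance = 0.02 / 0.3)
})

test_that("noise field is unaffected by the gap fraction (separate RNG streams)", {
  g0 <- generate_double_label_image(band_spec(70, 10, noise_sd = 0.1, seed = 4),
                                    c(96L, 200L), 5)
  g3 <- generate_double_label_image(
    band_spec(70, 10, noise_sd = 0.1, gap_fraction = 0.3, seed = 4),
    c(96L, 200L), 5
  )
  same <- g3$truth$alizarin_after_gaps == g3$truth$alizarin_band &
    g3$truth$calcein_after_gaps == g3$truth$calcein_band
  expect_identical(g0$image$pixels[, , 1][same[]], g3$image$pixels[, , 1][same[]])
})

test_that("generator rejects overlapping bands and too-small images", {
  expect_error(generate_double_label_image(band_spec(10, 12), c(96L, 96L), 2),
               "overlap")
  expect_error(generate_double_label_image(band_spec(300, 10), c(32L, 32L), 2),
               "too small")
  expect_error(generate_double_label_image(band_spec(20, 10), c(96L, 96L), 15),
               "resolvable")
})

test_that("medial-axis separation of generated bands matches the spec (self-consistency)", {
  for (sep in c(40, 70, 90)) {
    gen <- generate_double_label_image(band_spec(sep, 10, seed = 2),
                                       c(96L, 200L), 5)
    ska <- skeletonize_pruned(gen$truth$alizarin_band, 30, 5)
    skc <- skeletonize_pruned(gen$truth$calcein_band, 30, 5)
    a_xy <- which(ska$mask == 1, arr.ind = TRUE)
    c_xy <- which(skc$mask == 1, arr.ind = TRUE)
    d <- vapply(seq_len(nrow(a_xy)), function(i) {
      min(sqrt((a_xy[i, 1] - c_xy[, 1])^2 + (a_xy[i, 2] - c_xy[, 2])^2))
    }, 1) * 5
    expect_lt(abs(stats::median(d) - sep), 5 + 1e-9) # within one pixel
  }
})

test_that("curved bands keep constant medial-axis separation", {
  gen <- generate_double_label_image(band_spec(70, 10, curvature = 1 / 500, seed = 2),
                                     c(300L, 300L), 5)
  ska <- skeletonize_pruned(gen$truth$alizarin_band, 30, 5)
  skc <- skeletonize_pruned(gen$truth$calcein_band, 30, 5)
  a_xy <- which(ska$mask == 1, arr.ind = TRUE)
  c_xy <- which(skc$mask == 1, arr.ind = TRUE)
  d <- vapply(seq_len(nrow(a_xy)), function(i) {
    min(sqrt((a_xy[i, 1] - c_xy[, 1])^2 + (a_xy[i, 2] - c_xy[, 2])^2))
  }, 1) * 5
  expect_lt(abs(stats::median(d) - 70), 5 + 1e-9)
})

test_that("study table honors cell means, structural zeros and subject identity", {
  params <- canine_callus_volume_params()
  tab <- generate_study_table(params, seed = 3)
  expect_true(all(tab$value[tab$timepoint_weeks == 2] == 0))
  expect_true(all(tab$value >= 0))
  # subjects appear at every timepoint
  expect_true(all(table(tab$subject_id) == 3L))
  # degenerate sd: values equal the mean exactly
  p0 <- list(group_params("control", 4, mean = 123.4, sd = 0, n = 5))
  t0 <- generate_study_table(p0, seed = 1)
  expect_true(all(t0$value == 123.4))
  # duplicate cells rejected
  expect_error(generate_study_table(c(p0, p0), seed = 1), "duplicate")
})

test_that("study-table sample means track specified means", {
  # large-n convergence
  pl <- list(group_params("pth", 4, mean = 4849, sd = 2638, n = 10000))
  tl <- generate_study_table(pl, seed = 5, truncate_at_zero = FALSE)
  expect_equal(mean(tl$value), 4849, tolerance = 0.01)
  # across 200 seeds at n = 6 the sample mean stays within sampling error
  se <- 1386 / sqrt(6)
  devs <- vapply(1:200, function(s) {
    t6 <- generate_study_table(
      list(group_params("control", 4, mean = 1854, sd = 1386, n = 6)),
      seed = s
    )
    mean(t6$value) - 1854
  }, 1)
  expect_gt(mean(abs(devs) < 2 * se), 0.85)
  # redrawn truncation keeps the mean close despite mass near zero
  expect_lt(abs(mean(devs)), se)
})

test_that("torsion curves are deterministic, parametric and flag no-failure", {
  t1 <- generate_torsion_curve(11.2, 22.3, 34.6, seed = 1)
  t2 <- generate_torsion_curve(11.2, 22.3, 34.6, seed = 2)
  expect_identical(t1$torque, t2$torque) # noiseless: seed irrelevant
  expect_true(all(diff(t1$rotation) > 0))
  # initial slope equals rigidity
  expect_equal(t1$torque[2] / t1$rotation[2], 11.2, tolerance = 1e-9)
  expect_equal(max(t1$torque), 34.6, tolerance = 1e-3)
  expect_error(generate_torsion_curve(-1, 10, 20), "positive")
  # monotone curve with no peak
  lin <- torsion_curve(seq(0, 2, length.out = 50), seq(0, 20, length.out = 50))
  m <- extract_torsion_metrics(lin)
  expect_true(m$no_failure)
  expect_equal(m$ultimate_torque, 20)
})
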