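# Study statistics: ICC, ANOVA designs, Tukey HSD, correlation, fold change,
# torsion metric extraction.

test_that("ICC(2,1) matches the aov-based oracle and handles edge cases", {
  set.seed(11)
  item <- rnorm(25, 10, 2)
  mat <- cbind(item + rnorm(25, 0, 0.8), item + rnorm(25, 0, 0.8),
               item + rnorm(25, 0, 0.8))
  r <- icc_two_way(mat)
  expect_equal(r$icc, oracle_icc21(mat), tolerance = 1e-10)
  expect_true(r$lower < r$icc && r$icc < r$upper)
  # perfect agreement
  expect_equal(icc_two_way(cbind(1:10, 1:10))$icc, 1)
  # independent raters: near-zero concordance
  set.seed(2)
  big <- cbind(rnorm(1000), rnorm(1000))
  expect_lt(abs(icc_two_way(big)$icc), 0.1)
  # zero between-item variance
  expect_warning(z <- icc_two_way(matrix(5, 4, 3) + rep(c(0, 1, 2), each = 4)),
                 "zero between-item")
  expect_equal(z$icc, 0)
  expect_error(icc_two_way(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
})

test_that("synthetic raters built for a target concordance of 0.89 are recovered", {
  # item variance 1, rater noise variance chosen so ICC = 1 / (1 + v) = 0.89
  v <- 1 / 0.89 - 1
  set.seed(31)
  item <- rnorm(300)
  mat <- cbind(item + rnorm(300, 0, sqrt(v)), item + rnorm(300, 0, sqrt(v)))
  r <- icc_two_way(mat)
  expect_true(r$lower <= 0.89 && 0.89 <= r$upper)
  expect_equal(r$icc, 0.89, tolerance = 0.05)
})

test_that("repeated-measures ANOVA matches the mean-squares oracle on a balanced fixture", {
  set.seed(5)
  params <- list()
  for (g in c("control", "pth", "delayed_pth")) {
    for (tp in c(2, 4, 8)) {
      params[[length(params) + 1L]] <-
        group_params(g, tp, mean = 10 + 3 * (tp == 8) + 2 * (g == "pth"),
                     sd = 2, n = 3)
    }
  }
  tab <- generate_study_table(params, seed = 5, truncate_at_zero = FALSE)
  fit <- rm_anova_tukey(tab, "value")
  ora <- oracle_rm_anova(data.frame(
    subject_id = tab$subject_id, group = tab$group,
    timepoint_weeks = tab$timepoint_weeks, value = tab$value
  ))
  expect_equal(fit$anova$F[fit$anova$effect == "group"], ora$F_group,
               tolerance = 1e-10)
  expect_equal(fit$anova$F[fit$anova$effect == "time"], ora$F_time,
               tolerance = 1e-10)
  expect_equal(fit$anova$F[fit$anova$effect == "group:time"],
               ora$F_interaction, tolerance = 1e-10)
})

test_that("identical groups give null Tukey contrasts; structural zeros are dropped; incomplete subjects excluded", {
  params <- list(
    group_params("control", 4, 10, 1, 4), group_params("control", 8, 12, 1, 4),
    group_params("pth", 4, 10, 1, 4), group_params("pth", 8, 12, 1, 4)
  )
  tab <- generate_study_table(params, seed = 1)
  # make the two groups literally identical observation for observation
  tab$value[tab$group == "pth"] <- tab$value[tab$group == "control"]
  fit <- rm_anova_tukey(tab, "value")
  expect_equal(fit$tukey$diff, c(0, 0))
  expect_equal(fit$tukey$p_adj, c(1, 1), tolerance = 1e-12)
  # structural-zero timepoint dropped
  tabz <- rbind(tab, data.frame(subject_id = unique(tab$subject_id),
                                group = rep(c("control", "pth"), each = 4),
                                timepoint_weeks = 2, variable = "value",
                                value = 0))
  expect_message(fitz <- rm_anova_tukey(tabz, "value"), "constant timepoint")
  expect_equal(fitz$timepoints_used, c(4, 8))
  # incomplete subject excluded listwise
  tab_inc <- tab[!(tab$subject_id == "pth_01" & tab$timepoint_weeks == 8), ]
  expect_warning(fit2 <- rm_anova_tukey(tab_inc, "value"), "incomplete")
  expect_equal(fit2$n_subjects, 7L)
})

test_that("group separation of 3 SD is detected at n = 6", {
  hits <- vapply(1:60, function(s) {
    params <- list(
      group_params("control", 4, 10, 1, 6), group_params("control", 8, 10, 1, 6),
      group_params("pth", 4, 13, 1, 6), group_params("pth", 8, 13, 1, 6)
    )
    tab <- generate_study_table(params, seed = 1000 + s, truncate_at_zero = FALSE)
    fit <- rm_anova_tukey(tab, "value")
    fit$anova$p[fit$anova$effect == "group"] < 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.95)
})

test_that("one-way ANOVA and Tukey match hand computation", {
  # identical groups: F = 0, p = 1
  g0 <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  f0 <- one_way_anova_tukey(g0)
  expect_equal(f0$F, 0)
  expect_equal(f0$p, 1)
  expect_equal(f0$tukey$diff, 0)
  # textbook 3-group fixture, F computed by hand from the mean squares
  g <- list(a = c(6, 8, 4, 5, 3, 4), b = c(8, 12, 9, 11, 6, 8),
            c = c(13, 9, 11, 8, 7, 12))
  fit <- one_way_anova_tukey(g)
  ora <- oracle_oneway(g)
  expect_equal(fit$F, ora$F, tolerance = 1e-12)
  expect_equal(fit$p, ora$p, tolerance = 1e-12)
  tk <- oracle_tukey(g)
  got <- fit$tukey[match(tk$contrast, fit$tukey$contrast), ]
  expect_equal(got$diff, tk$diff, tolerance = 1e-12)
  expect_equal(got$lwr, tk$lwr, tolerance = 1e-10)
  expect_equal(got$upr, tk$upr, tolerance = 1e-10)
  expect_equal(got$p_adj, tk$p_adj, tolerance = 1e-8)
  expect_error(one_way_anova_tukey(list(a = c(1, 1), b = c(2, 2))),
               "zero within-group variance")
})

test_that("correlations match their oracles and degenerate inputs error", {
  x <- c(1, 2.5, 3, 4.2, 7, 9)
  expect_equal(correlate(x, 2 * x + 1, "pearson")$estimate, 1)
  y <- exp(x)
  expect_equal(correlate(x, y, "spearman")$estimate, 1)
  expect_lt(correlate(x, y, "pearson")$estimate, 1)
  # tied ranks: equals rank-transform then Pearson
  xt <- c(1, 2, 2, 3, 4, 4, 4, 6)
  yt <- c(2, 1, 3, 3, 5, 4, 6, 7)
  expect_equal(correlate(xt, yt, "spearman")$estimate, oracle_spearman(xt, yt),
               tolerance = 1e-12)
  expect_equal(correlate(xt, yt, "pearson")$estimate, oracle_pearson(xt, yt),
               tolerance = 1e-12)
  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("fold changes reproduce ratio arithmetic and reject bad references", {
  expect_equal(fold_change(5, 5)$fold, 1.0)
  expect_equal(fold_change(4849, 1854)$fold, 2.6)
  expect_equal(fold_change(8124, 4305)$fold, 1.9)
  expect_error(fold_change(3, 0), "positive")
  expect_error(fold_change(3, -2), "positive")
})

test_that("torsion metrics recover parametric curves and simple closed forms", {
  # ideal elastic / perfectly plastic: slope 10 to a plateau at 30
  rot <- seq(0, 6, length.out = 400)
  tq <- pmin(10 * rot, 30)
  m <- extract_torsion_metrics(torsion_curve(rot, tq))
  expect_equal(m$rigidity, 10, tolerance = 1e-9)
  expect_equal(m$ultimate_torque, 30)
  # triangle to (1, 20) then back down: work to peak = area = 10
  rot2 <- seq(0, 2, length.out = 401)
  tq2 <- ifelse(rot2 <= 1, 20 * rot2, 20 - 20 * (rot2 - 1))
  m2 <- extract_torsion_metrics(torsion_curve(rot2, tq2))
  expect_equal(m2$work_to_ult, 10, tolerance = 1e-3)
  expect_equal(m2$ultimate_torque, 20)
  # generator round trip within 2% for several parameter triples
  for (p in list(c(11.2, 22.3, 34.6), c(3.45, 3.62, 6.24), c(8, 15, 20))) {
    cur <- generate_torsion_curve(p[1], p[2], p[3])
    mm <- extract_torsion_metrics(cur)
    expect_equal(mm$rigidity, p[1], tolerance = 0.02)
    expect_equal(mm$yield_torque, p[2], tolerance = 0.02)
    expect_equal(mm$ultimate_torque, p[3], tolerance = 0.02)
    tr <- attr(cur, "truth")
    expect_equal(mm$work_to_ult, tr$work_to_ult, tolerance = 0.02)
  }
})

test_that("torsion extraction is invariant to resampling density", {
  base <- generate_torsion_curve(11.2, 22.3, 34.6, n_samples = 2000L)
  m1 <- extract_torsion_metrics(base)
  dense <- generate_torsion_curve(11.2, 22.3, 34.6, n_samples = 501L)
  m2 <- extract_torsion_metrics(dense)
  for (f in c("rigidity", "yield_torque", "ultimate_torque", "work_to_ult")) {
    expect_equal(m1[[f]], m2[[f]], tolerance = 0.01)
  }
})
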