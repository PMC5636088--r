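# Independent oracles: deliberately simple, loop-based implementations used
# only to validate the package's vectorized/model-based code paths.

# Brute-force nearest-neighbor matching with the lexicographic tie rule:
# every alizarin pixel against every calcein pixel, smallest distance wins,
# exact ties broken by smallest (row, col).
oracle_match <- function(a_xy, c_xy, cap_px) {
  out <- NULL
  for (i in seq_len(nrow(a_xy))) {
    d2 <- (a_xy[i, 1] - c_xy[, 1])^2 + (a_xy[i, 2] - c_xy[, 2])^2
    cand <- which(d2 == min(d2))
    cand <- cand[order(c_xy[cand, 1], c_xy[cand, 2])]
    best <- c_xy[cand[1], ]
    if (sqrt(min(d2)) <= cap_px) {
      out <- rbind(out, c(a_xy[i, ], best, sqrt(min(d2))))
    }
  }
  out
}

# One-way ANOVA F from explicit mean squares.
oracle_oneway <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  dfb <- length(groups) - 1
  dfw <- length(all_v) - length(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE))
}

# Tukey-Kramer pairwise contrasts from explicit pooled mean squares.
oracle_tukey <- function(groups, conf = 0.95) {
  k <- length(groups)
  ns <- vapply(groups, length, 1L)
  ms <- vapply(groups, mean, 1)
  dfe <- sum(ns) - k
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1)) / dfe
  qcrit <- stats::qtukey(conf, k, dfe)
  out <- NULL
  for (j in seq_len(k)) {
    for (i in seq_len(k)) {
      if (i <= j) next
      d <- ms[i] - ms[j]
      se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
      out <- rbind(out, data.frame(
        contrast = paste(names(groups)[i], names(groups)[j], sep = "-"),
        diff = d, lwr = d - qcrit * se, upr = d + qcrit * se,
        p_adj = stats::ptukey(abs(d) / se, k, dfe, lower.tail = FALSE)
      ))
    }
  }
  out
}

# Balanced mixed-design (between = group, within = time) F statistics from
# explicit sums of squares.
oracle_rm_anova <- function(df) {
  grand <- mean(df$value)
  subj <- unique(df[, c("subject_id", "group")])
  n_t <- length(unique(df$timepoint_weeks))
  n_s <- nrow(subj)
  n_g <- length(unique(df$group))
  m_s <- tapply(df$value, df$subject_id, mean)
  m_g <- tapply(df$value, df$group, mean)
  m_t <- tapply(df$value, df$timepoint_weeks, mean)
  m_gt <- tapply(df$value, list(df$group, df$timepoint_weeks), mean)
  n_per_g <- table(subj$group)
  ss_subj <- n_t * sum((m_s - grand)^2)
  ss_group <- n_t * sum(n_per_g * (m_g[names(n_per_g)] - grand)^2)
  ss_subj_err <- ss_subj - ss_group
  ss_time <- n_s * sum((m_t - grand)^2)
  ss_gt <- 0
  for (g in rownames(m_gt)) {
    for (t in colnames(m_gt)) {
      ss_gt <- ss_gt + n_per_g[[g]] *
        (m_gt[g, t] - m_g[[g]] - m_t[[t]] + grand)^2
    }
  }
  ss_tot <- sum((df$value - grand)^2)
  ss_we <- ss_tot - ss_subj - ss_time - ss_gt
  df_g <- n_g - 1; df_se <- n_s - n_g
  df_t <- n_t - 1; df_we <- (n_s - n_g) * (n_t - 1)
  list(
    F_group = (ss_group / df_g) / (ss_subj_err / df_se),
    F_time = (ss_time / df_t) / (ss_we / df_we),
    F_interaction = (ss_gt / (df_g * df_t)) / (ss_we / df_we)
  )
}

oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

oracle_spearman <- function(x, y) {
  oracle_pearson(rank(x), rank(y)) # average ranks for ties
}

# ICC(2,1) through a route independent of the package's closed-form code:
# mean squares extracted from a fitted two-way aov.
oracle_icc21 <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  d <- data.frame(
    value = as.vector(mat),
    item = factor(rep(seq_len(n), k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  tab <- summary(stats::aov(value ~ item + rater, data = d))[[1]]
  msr <- tab["item", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Two parallel horizontal band footprints as a quick fixture.
make_parallel_bands <- function(nr = 60L, nc = 120L, row_a = 20L, row_c = 34L,
                                half_th = 1L) {
  a <- matrix(0L, nr, nc); c_ <- matrix(0L, nr, nc)
  a[(row_a - half_th):(row_a + half_th), ] <- 1L
  c_[(row_c - half_th):(row_c + half_th), ] <- 1L
  list(a = a, c = c_)
}
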