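# Study-level statistics: intraclass correlation for rater concordance,
# two-way repeated-measures ANOVA with Tukey HSD for longitudinal measures,
# one-way ANOVA with Tukey HSD for endpoint measures, Pearson/Spearman
# correlation, fold changes, and torque-twist metric extraction.

#' Two-way random-effects intraclass correlation, single rater, absolute
#' agreement (ICC(2,1))
#'
#' The conservative standard for quantifying concordance of two (or more)
#' blinded raters scoring the same items: a two-way random-effects model in
#' which both item and rater are random, and absolute agreement (not mere
#' consistency) is required. Computed from the two-way ANOVA mean squares,
#' with the F-distribution confidence bounds of McGraw & Wong.
#'
#' @param mat Items x raters numeric matrix, complete (no missing cells),
#'   >= 2 items and >= 2 raters.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return List with \code{icc}, \code{lower}, \code{upper},
#'   \code{conf_level}, and the mean squares (\code{msr}, \code{msc},
#'   \code{mse}).
#' @export
icc_two_way <- function(mat, conf_level = 0.95) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop_input("rater matrix must be complete")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) stop_input("need >= 2 items and >= 2 raters")
  grand <- mean(mat)
  row_m <- rowMeans(mat); col_m <- colMeans(mat)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((mat - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps * max(1, abs(grand))) {
    warning("zero between-item variance: ICC defined as 0", call. = FALSE)
    return(list(icc = 0, lower = NA_real_, upper = NA_real_,
                conf_level = conf_level, msr = msr, msc = msc, mse = mse))
  }
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- if (denom <= 0) 0 else (msr - mse) / denom
  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    # perfect agreement: degenerate interval
    return(list(icc = icc, lower = icc, upper = icc,
                conf_level = conf_level, msr = msr, msc = msc, mse = mse))
  }
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  list(icc = icc, lower = lower, upper = upper, conf_level = conf_level,
       msr = msr, msc = msc, mse = mse)
}

# Validate and reshape a long study table for one variable.
prepare_rm_data <- function(table, variable) {
  need <- c("subject_id", "group", "timepoint_weeks", "variable", "value")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop_input("study table lacks columns: ",
                               paste(miss, collapse = ", "))
  df <- table[table$variable == variable, ]
  if (nrow(df) == 0L) stop_input("no rows for variable '", variable, "'")
  grp <- unique(df[, c("subject_id", "group")])
  if (anyDuplicated(grp$subject_id)) {
    stop_input("subjects must be nested in exactly one group")
  }
  df
}

#' Two-way repeated-measures ANOVA with Tukey HSD post hoc
#'
#' Mixed between-within design: treatment group is the between-subject
#' factor, timepoint the within-subject factor. The group effect is tested
#' against the between-subject (subject within group) error; time and the
#' group x time interaction against the within-subject error. No sphericity
#' correction is applied by default. Tukey HSD contrasts between groups are
#' computed at each timepoint using the between-group error at that
#' timepoint.
#'
#' Timepoints at which every observation is identical (structural zeros,
#' e.g. pre-callus scans) carry no information and are dropped by default.
#' Subjects with incomplete timepoint series are excluded listwise.
#'
#' @param table Long study table (see \code{\link{generate_study_table}}).
#' @param variable Variable to analyze.
#' @param alpha Significance level reported alongside Tukey intervals.
#' @param drop_constant_timepoints Drop zero-variance timepoints (default
#'   TRUE).
#' @return List with \code{anova} (data.frame: effect, df, df_error, F, p),
#'   \code{tukey} (data.frame of pairwise group contrasts per timepoint),
#'   \code{n_subjects}, \code{timepoints_used}, \code{excluded_subjects}.
#' @export
rm_anova_tukey <- function(table, variable, alpha = 0.05,
                           drop_constant_timepoints = TRUE) {
  df <- prepare_rm_data(table, variable)
  if (drop_constant_timepoints) {
    keep_tp <- vapply(split(df$value, df$timepoint_weeks),
                      function(v) stats::var(v) > 0, TRUE)
    dropped <- names(keep_tp)[!keep_tp]
    if (length(dropped)) {
      message("dropping constant timepoint(s): ",
              paste(dropped, collapse = ", "))
    }
    df <- df[df$timepoint_weeks %in% as.numeric(names(keep_tp)[keep_tp]), ]
  }
  tps <- sort(unique(df$timepoint_weeks))
  if (length(tps) < 2) stop_input("need >= 2 usable timepoints")
  cnt <- table(df$subject_id)
  complete <- names(cnt)[cnt == length(tps)]
  excluded <- setdiff(names(cnt), complete)
  if (length(excluded)) {
    warning("excluding incomplete subject(s): ",
            paste(excluded, collapse = ", "), call. = FALSE)
  }
  df <- df[df$subject_id %in% complete, ]
  if (length(unique(df$group)) < 2) stop_input("need >= 2 groups")
  df$subject_id <- factor(df$subject_id)
  df$group <- factor(df$group)
  df$time <- factor(df$timepoint_weeks)

  fit <- stats::aov(value ~ group * time + Error(subject_id), data = df)
  s <- summary(fit)
  btw <- s[["Error: subject_id"]][[1]]
  wth <- s[["Error: Within"]][[1]]
  pick <- function(tab, name) {
    i <- which(trimws(rownames(tab)) == name)
    ierr <- which(trimws(rownames(tab)) == "Residuals")
    data.frame(
      effect = name, df = tab[i, "Df"], df_error = tab[ierr, "Df"],
      F = tab[i, "F value"], p = tab[i, "Pr(>F)"]
    )
  }
  anova_tab <- rbind(pick(btw, "group"), pick(wth, "time"),
                     pick(wth, "group:time"))

  tukey <- do.call(rbind, lapply(tps, function(tp) {
    sub <- df[df$timepoint_weeks == tp, ]
    tk <- stats::TukeyHSD(stats::aov(value ~ group, data = sub),
                          conf.level = 1 - alpha)$group
    data.frame(
      timepoint_weeks = tp, contrast = rownames(tk),
      diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
      p_adj = tk[, "p adj"], row.names = NULL
    )
  }))
  list(anova = anova_tab, tukey = tukey,
       n_subjects = length(unique(df$subject_id)),
       timepoints_used = tps, excluded_subjects = excluded)
}

#' One-way ANOVA with Tukey HSD
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param alpha Significance level for Tukey intervals.
#' @return List with \code{F}, \code{p}, \code{df}, \code{df_error},
#'   \code{tukey} (data.frame of pairwise contrasts).
#' @export
one_way_anova_tukey <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 1L) >= 2))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 1L)))
  )
  if (all(vapply(groups, stats::var, 1) == 0)) {
    stop_input("zero within-group variance everywhere: F undefined")
  }
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  list(
    F = tab["group", "F value"], p = tab["group", "Pr(>F)"],
    df = tab["group", "Df"], df_error = tab["Residuals", "Df"],
    tukey = data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                       lwr = tk[, "lwr"], upr = tk[, "upr"],
                       p_adj = tk[, "p adj"], row.names = NULL)
  )
}

#' Pearson or Spearman correlation
#'
#' Spearman uses average ranks for ties; p-values are the standard
#' \code{cor.test} ones (asymptotic for tied Spearman data).
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @param method "pearson" or "spearman".
#' @return List with \code{estimate}, \code{p}, \code{method}, \code{n}.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_input("correlation undefined: zero variance")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE)
  )
  list(estimate = unname(ct$estimate), p = ct$p.value, method = method,
       n = length(x))
}

#' Fold change between two group means
#'
#' @param mean_treatment,mean_reference Group means; reference must be
#'   positive.
#' @return List with \code{fold} (rounded to one decimal, as reported) and
#'   \code{unrounded}.
#' @export
fold_change <- function(mean_treatment, mean_reference) {
  if (!is.finite(mean_reference) || mean_reference <= 0) {
    stop_input("reference mean must be positive")
  }
  r <- mean_treatment / mean_reference
  list(fold = round(r, 1), unrounded = r)
}

#' Extract torsion metrics from a torque-twist curve
#'
#' Torsion rigidity is the slope of the best-fit line over the steepest
#' contiguous window spanning \code{window_fraction} of the pre-peak
#' samples. Yield torque is the torque at the first pre-peak point falling
#' below that line shifted right by \code{offset_fraction} of the rotation
#' at peak (an offset-method yield rule; the quantity has no universal
#' operational definition). Ultimate torque is the curve maximum, and work
#' to ultimate is the trapezoidal integral of torque over rotation up to the
#' peak. A curve that never drops after its maximum is flagged
#' \code{no_failure}, with the ultimate taken at the final sample.
#'
#' @param curve A \code{\link{torsion_curve}}.
#' @param window_fraction Fraction of pre-peak samples in the stiffness
#'   window (default 0.2).
#' @param offset_fraction Rotation offset of the yield line, as a fraction
#'   of peak rotation (default 0.002).
#' @return List with \code{yield_torque}, \code{ultimate_torque},
#'   \code{rigidity}, \code{work_to_ult}, \code{no_failure}.
#' @export
extract_torsion_metrics <- function(curve, window_fraction = 0.2,
                                    offset_fraction = 0.002) {
  stopifnot(inherits(curve, "torsion_curve"))
  rot <- curve$rotation; tq <- curve$torque
  n <- length(rot)
  i_ult <- which.max(tq)
  no_failure <- i_ult == n
  ultimate <- tq[i_ult]

  m <- max(2L, as.integer(ceiling(window_fraction * i_ult)))
  if (i_ult < m) m <- i_ult
  # OLS slope of every contiguous window of m pre-peak samples, via
  # cumulative sums
  cx <- cumsum(rot[1:i_ult]); cy <- cumsum(tq[1:i_ult])
  cxx <- cumsum(rot[1:i_ult]^2); cxy <- cumsum(rot[1:i_ult] * tq[1:i_ult])
  starts <- seq_len(i_ult - m + 1L)
  wsum <- function(cs) cs[starts + m - 1L] - c(0, cs)[starts]
  sx <- wsum(cx); sy <- wsum(cy); sxx <- wsum(cxx); sxy <- wsum(cxy)
  slope <- (m * sxy - sx * sy) / (m * sxx - sx^2)
  best <- which.max(slope)
  rigidity <- slope[best]
  intercept <- (sy[best] - rigidity * sx[best]) / m

  theta0 <- offset_fraction * rot[i_ult]
  line_val <- rigidity * (rot[1:i_ult] - theta0) + intercept
  tol <- 1e-6 * max(abs(ultimate), 1)
  below <- which(tq[1:i_ult] < line_val - tol)
  below <- below[below >= best + m - 1L] # past the fitted stiffness window
  yield <- if (length(below)) tq[below[1]] else ultimate

  work <- sum(diff(rot[1:i_ult]) * (tq[1:i_ult][-1] + tq[1:i_ult][-i_ult]) / 2)
  list(yield_torque = yield, ultimate_torque = ultimate, rigidity = rigidity,
       work_to_ult = work, no_failure = no_failure)
}
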