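# Synthetic study tables and torque-twist curves with known parameters, so
# the statistical layer can be exercised without the study's animal data.

#' Group-cell parameters for a synthetic study table
#'
#' @param group One of "control", "pth", "delayed_pth".
#' @param timepoint_weeks One of 2, 4, 8.
#' @param mean,sd Cell mean and standard deviation (sd >= 0).
#' @param n Number of subjects in the group (>= 2 for any ANOVA use).
#' @param variable Measured variable name (default "value").
#' @return A \code{group_params} list.
#' @export
group_params <- function(group, timepoint_weeks, mean, sd, n,
                         variable = "value") {
  stopifnot(group %in% c("control", "pth", "delayed_pth"),
            timepoint_weeks %in% c(2, 4, 8), sd >= 0, n >= 1)
  structure(
    list(group = group, timepoint_weeks = timepoint_weeks, mean = mean,
         sd = sd, n = as.integer(n), variable = variable),
    class = "group_params"
  )
}

#' Generate a synthetic per-subject study table
#'
#' Draws per-subject values from the normal distribution of each
#' (group, timepoint, variable) cell. Subject identities are consistent
#' across timepoints (repeated measures). Negative draws are redrawn (not
#' clamped) when \code{truncate_at_zero} is TRUE, so sample moments stay
#' close to the specified ones without a point mass at zero; cells with
#' mean 0 and sd 0 are exact structural zeros.
#'
#' @param params List of \code{\link{group_params}}, one per cell.
#' @param seed Integer seed.
#' @param truncate_at_zero Redraw negative values (suitable for volumes).
#' @return data.frame with columns \code{subject_id}, \code{group},
#'   \code{timepoint_weeks}, \code{variable}, \code{value}.
#' @export
generate_study_table <- function(params, seed = 1L, truncate_at_zero = TRUE) {
  stopifnot(length(params) > 0, all(vapply(params, inherits, TRUE, "group_params")))
  keys <- vapply(params, function(p) {
    paste(p$group, p$timepoint_weeks, p$variable)
  }, "")
  if (anyDuplicated(keys)) {
    stop_input("duplicate (group, timepoint, variable) cells: ",
               paste(keys[duplicated(keys)], collapse = "; "))
  }
  with_seed(seed, {
    rows <- lapply(params, function(p) {
      v <- p$mean + p$sd * stats::rnorm(p$n)
      if (truncate_at_zero && p$sd > 0) {
        while (any(v < 0)) {
          bad <- v < 0
          v[bad] <- p$mean + p$sd * stats::rnorm(sum(bad))
        }
      }
      data.frame(
        subject_id = sprintf("%s_%02d", p$group, seq_len(p$n)),
        group = p$group,
        timepoint_weeks = p$timepoint_weeks,
        variable = p$variable,
        value = v
      )
    })
    do.call(rbind, rows)
  })
}

#' Published callus-volume group summaries
#'
#' Group mean and SD of mineralized callus volume at 2, 4 and 8 weeks for
#' the three treatment arms of the canine femoral allograft study (placebo,
#' continuous PTH, delayed PTH), with the number of dogs completing the
#' study. Two-week volumes are structural zeros (no callus has formed).
#' Units are carried symbolically as reported.
#'
#' @param n Per-group sample sizes, default c(5, 6, 6) (study completers).
#' @return List of \code{\link{group_params}}.
#' @export
canine_callus_volume_params <- function(n = c(control = 5L, pth = 6L,
                                              delayed_pth = 6L)) {
  means <- list(
    control = c(`2` = 0, `4` = 1854, `8` = 4305),
    pth = c(`2` = 0, `4` = 4849, `8` = 6985),
    delayed_pth = c(`2` = 0, `4` = 4689, `8` = 8124)
  )
  sds <- list(
    control = c(`2` = 0, `4` = 1386, `8` = 1856),
    pth = c(`2` = 0, `4` = 2638, `8` = 2791),
    delayed_pth = c(`2` = 0, `4` = 2055, `8` = 2350)
  )
  out <- list()
  for (g in names(means)) {
    for (tp in c(2, 4, 8)) {
      out[[length(out) + 1L]] <- group_params(
        g, tp, means[[g]][[as.character(tp)]], sds[[g]][[as.character(tp)]],
        n[[g]], variable = "callus_volume"
      )
    }
  }
  out
}

#' Published torsion-test group summaries
#'
#' Mean and SD of yield torque (N.m), ultimate torque (N.m), torsion
#' rigidity (N.m/(rad/m)) and work to ultimate torque ((N.m)*(rad/m)) at 8
#' weeks, including the contralateral (intact) femurs of the placebo group.
#'
#' @return data.frame with columns \code{group}, \code{metric}, \code{mean},
#'   \code{sd}.
#' @export
canine_torsion_params <- function() {
  g <- c("contralateral", "control", "pth", "delayed_pth")
  data.frame(
    group = rep(g, each = 4),
    metric = rep(c("yield_torque", "ultimate_torque", "rigidity",
                   "work_to_ult"), 4),
    mean = c(22.3, 34.6, 11.2, 81.3,
             3.62, 6.24, 3.45, 8.29,
             4.20, 7.20, 3.60, 12.94,
             2.76, 4.08, 1.69, 10.89),
    sd = c(2.71, 3.70, 0.63, 13.0,
           3.08, 6.36, 3.42, 7.86,
           3.61, 6.10, 2.23, 10.17,
           0.96, 1.32, 0.91, 10.22)
  )
}

#' Construct a torque-twist curve
#'
#' @param rotation Normalized rotation (rad/m), strictly increasing, >= 10
#'   samples.
#' @param torque Torque (N.m).
#' @return A \code{torsion_curve} data.frame.
#' @export
torsion_curve <- function(rotation, torque) {
  stopifnot(length(rotation) == length(torque), length(rotation) >= 10)
  if (any(diff(rotation) <= 0)) stop_input("rotation must be strictly increasing")
  structure(data.frame(rotation = rotation, torque = torque),
            class = c("torsion_curve", "data.frame"))
}

#' Generate a synthetic torque-twist curve
#'
#' Piecewise parametric failure curve: a linear elastic segment of slope
#' \code{rigidity} up to the yield torque, a quadratic softening segment
#' whose tangent drops to \code{post_yield_modulus_fraction * rigidity} at
#' the yield knee and to zero at the ultimate (peak) torque, then a linear
#' failure drop. The knee in slope at yield is the physical signature the
#' offset yield rule detects.
#'
#' @param rigidity Elastic slope, N.m/(rad/m); must be positive.
#' @param yield_torque,ultimate_torque Yield and peak torque, N.m
#'   (ultimate >= yield).
#' @param seed Seed for the noise stream.
#' @param noise_sd SD of additive Gaussian torque noise (N.m).
#' @param n_samples Number of samples (uniform rotation grid).
#' @param post_yield_modulus_fraction Tangent-modulus fraction just past
#'   yield, in (0, 1).
#' @param drop_to Post-failure torque as a fraction of ultimate.
#' @return A \code{torsion_curve} with attribute \code{"truth"} (the input
#'   parameters and the analytic work to the ultimate point).
#' @export
generate_torsion_curve <- function(rigidity, yield_torque, ultimate_torque,
                                   seed = 1L, noise_sd = 0, n_samples = 500L,
                                   post_yield_modulus_fraction = 0.5,
                                   drop_to = 0.6) {
  if (rigidity <= 0) stop_input("rigidity must be positive")
  stopifnot(ultimate_torque >= yield_torque, yield_torque > 0,
            n_samples >= 10, post_yield_modulus_fraction > 0,
            post_yield_modulus_fraction < 1)
  th_y <- yield_torque / rigidity
  kappa <- post_yield_modulus_fraction
  d <- if (ultimate_torque > yield_torque) {
    2 * (ultimate_torque - yield_torque) / (kappa * rigidity)
  } else {
    0
  }
  th_u <- th_y + d
  a <- if (d > 0) kappa * rigidity / (2 * d) else 0
  th_end <- th_u + 0.3 * th_u
  rot <- seq(0, th_end, length.out = n_samples)
  torque <- ifelse(
    rot <= th_y, rigidity * rot,
    ifelse(rot <= th_u, ultimate_torque - a * (th_u - rot)^2,
           ultimate_torque - (ultimate_torque * (1 - drop_to)) *
             (rot - th_u) / (th_end - th_u))
  )
  if (noise_sd > 0) {
    with_seed(seed, torque <- torque + stats::rnorm(n_samples, 0, noise_sd))
  }
  # analytic work to the peak: triangle + integral of the quadratic segment
  work <- yield_torque * th_y / 2 +
    if (d > 0) ultimate_torque * d - a * d^3 / 3 else 0
  out <- torsion_curve(rot, torque)
  attr(out, "truth") <- list(
    rigidity = rigidity, yield_torque = yield_torque,
    ultimate_torque = ultimate_torque, work_to_ult = work,
    rotation_at_ultimate = th_u
  )
  out
}
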