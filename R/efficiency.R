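#' Average daily gain from serial body weights
#'
#' ADG is the ordinary least-squares slope of body weight (kg) regressed on
#' test day, using every serial weighing (typically biweekly). Requires at
#' least 3 weighings.
#'
#' @param day Numeric vector of test days.
#' @param weight_kg Body weights, kg, same length.
#' @return List with `adg` (kg/d), `intercept` (kg, weight at day 0), and
#'   `mid_wt` (predicted weight at the test midpoint, used for metabolic
#'   body weight).
#' @examples
#' d <- seq(0, 84, by = 14)
#' compute_adg(d, 260 + 0.9 * d)$adg # 0.9
#' @export
compute_adg <- function(day, weight_kg) {
  stopifnot(length(day) == length(weight_kg))
  keep <- is.finite(day) & is.finite(weight_kg)
  day <- day[keep]; weight_kg <- weight_kg[keep]
  if (length(day) < 3) stop("need at least 3 weighings to regress ADG")
  fit <- .lm.fit(cbind(1, day), weight_kg)
  b <- fit$coefficients
  mid <- (min(day) + max(day)) / 2
  list(adg = b[2], intercept = b[1], mid_wt = b[1] + b[2] * mid)
}

#' Metabolic body weight
#'
#' @param bw_kg Body weight, kg (mid-test weight by convention).
#' @return BW^0.75, kg^0.75.
#' @export
metabolic_weight <- function(bw_kg) {
  stopifnot(all(bw_kg > 0))
  bw_kg^0.75
}

#' Standardize dry matter intake to a reference dietary energy density
#'
#' Converts DMI to metabolizable-energy-intake equivalents on a reference
#' diet of `reference` MJ ME per kg DM (default 10):
#' MEI = DMI * diet_ME / reference. This puts intakes measured on diets of
#' different energy density on a common scale.
#'
#' @param dmi_kg_d Dry matter intake, kg/d (>= 0).
#' @param diet_me Diet ME density, MJ/kg DM (> 0), e.g. from [me_from_tdn()].
#' @param reference Reference ME density, MJ/kg DM.
#' @return Standardized intake (kg/d of reference-diet equivalents).
#' @examples
#' standardize_mei(9.12, 8.66) # 7.90 at 2 dp
#' @export
standardize_mei <- function(dmi_kg_d, diet_me, reference = 10) {
  if (any(!is.finite(dmi_kg_d)) || any(dmi_kg_d < 0)) {
    stop("`dmi_kg_d` must be nonnegative")
  }
  if (any(!is.finite(diet_me)) || any(diet_me <= 0) || reference <= 0) {
    stop("`diet_me` and `reference` must be positive")
  }
  dmi_kg_d * diet_me / reference
}

#' Residual feed intake and residual body gain models for one fit group
#'
#' Fits, within one year-by-regime group, the two companion OLS models
#' \deqn{MEI_j = b0 + b1 ADG_j + b2 MWT_j + b3 dBF_j + e_j}
#' \deqn{ADG_j = b4 + b5 MEI_j + b6 MWT_j + b7 dBF_j + e_j}
#' whose residuals are residual feed intake (RFI; intake not explained by
#' growth, size and fatness change — lower is better) and residual body
#' gain (RBG; gain not explained by intake, size and fatness change —
#' higher is better). Residuals are mean-zero by construction and are also
#' returned standardized by the within-group SD; residual intake-and-gain
#' combines them as RIG = -RFI_s + RBG_s.
#'
#' The intake response defaults to the energy-standardized MEI (set
#' `response = "dmi"` for raw DMI).
#'
#' @param records Data.frame with columns `animal_id`, `mei` (or `dmi`),
#'   `adg`, `mwt`, `d_bkft`.
#' @param response `"mei"` (default) or `"dmi"`.
#' @return Object of class `residual_fit`: list with `coef_intake` (b0..b3),
#'   `coef_gain` (b4..b7), and data.frame `indices` (`animal_id`, `rfi`,
#'   `rbg`, `rfi_s`, `rbg_s`, `rig`).
#' @export
fit_residual_models <- function(records, response = c("mei", "dmi")) {
  response <- match.arg(response)
  df <- as.data.frame(records)
  needed <- c("animal_id", response, "adg", "mwt", "d_bkft")
  stopifnot(all(needed %in% names(df)))
  if (nrow(df) < 6) stop("need at least 6 animals per fit group")
  y_int <- df[[response]]
  X_int <- cbind(1, adg = df$adg, mwt = df$mwt, d_bkft = df$d_bkft)
  X_gain <- cbind(1, intake = y_int, mwt = df$mwt, d_bkft = df$d_bkft)
  for (X in list(X_int, X_gain)) {
    if (qr(X)$rank < ncol(X)) {
      warning("collinear regressors in residual model; ",
              "coefficients not uniquely determined")
    }
  }
  f1 <- .lm.fit(X_int, y_int)
  f2 <- .lm.fit(X_gain, df$adg)
  rfi <- f1$residuals
  rbg <- f2$residuals
  rfi_s <- rfi / sd(rfi)
  rbg_s <- rbg / sd(rbg)
  structure(list(
    coef_intake = setNames(f1$coefficients,
                           c("b0", "b1_adg", "b2_mwt", "b3_dbkft")),
    coef_gain = setNames(f2$coefficients,
                         c("b4", "b5_intake", "b6_mwt", "b7_dbkft")),
    indices = data.frame(animal_id = df$animal_id, rfi = rfi, rbg = rbg,
                         rfi_s = rfi_s, rbg_s = rbg_s,
                         rig = compute_rig(rfi_s, rbg_s),
                         stringsAsFactors = FALSE)),
    class = "residual_fit")
}

#' Residual intake and gain
#'
#' RIG = -RFI_s + RBG_s, combining the standardized residual indices so
#' that higher values mean more gain on less feed.
#'
#' @param rfi_s,rbg_s Standardized RFI and RBG from the same fit group.
#' @return RIG values.
#' @export
compute_rig <- function(rfi_s, rbg_s) {
  stopifnot(length(rfi_s) == length(rbg_s))
  -1 * rfi_s + rbg_s
}

#' Classify animals into efficient / neutral / inefficient classes
#'
#' Animals more than `half_sd` SD from the group mean are labelled
#' according to the trait's direction of merit: for RFI lower is more
#' efficient (`direction = "lower"`), for RBG and RIG higher is
#' (`direction = "higher"`). Values exactly on a boundary fall in the
#' neutral band. A zero-SD group is all neutral, with a warning.
#'
#' @param values Numeric index values for one fit group (>= 3 animals).
#' @param direction `"lower"` or `"higher"`: which tail is efficient.
#' @param half_sd Band half-width in SD units, default 0.5.
#' @return Factor with levels `inefficient`, `neutral`, `efficient`.
#' @export
classify_efficiency <- function(values, direction = c("lower", "higher"),
                                half_sd = 0.5) {
  direction <- match.arg(direction)
  if (length(values) < 3) stop("need at least 3 animals")
  sdv <- sd(values)
  lab <- rep("neutral", length(values))
  if (!is.finite(sdv) || sdv == 0) {
    warning("zero SD: all animals classed neutral")
  } else {
    m <- mean(values)
    lo <- values < m - half_sd * sdv
    hi <- values > m + half_sd * sdv
    if (direction == "lower") {
      lab[lo] <- "efficient"; lab[hi] <- "inefficient"
    } else {
      lab[hi] <- "efficient"; lab[lo] <- "inefficient"
    }
  }
  factor(lab, levels = c("inefficient", "neutral", "efficient"))
}

#' Per-animal growth, intake and efficiency traits for one regime
#'
#' Convenience wrapper that takes raw performance records (serial weights,
#' daily intake, backfat), computes ADG, mid-test metabolic weight, mean
#' DMI, standardized MEI, FCR (= DMI/ADG) and FCE (= ADG/DMI), then fits
#' the residual models within each year group and attaches the indices and
#' the three efficiency classifications.
#'
#' @param performance Data.frame with one row per animal: `animal_id`,
#'   `year`, `regime`, `pen`, `dmi` (mean kg/d), `d_bkft` (mm), and serial
#'   weights supplied via `weights` (long data.frame `animal_id`, `day`,
#'   `weight_kg`).
#' @param weights Long data.frame of serial weighings.
#' @param diet_me Diet ME density (MJ/kg DM) for MEI standardization.
#' @return Data.frame with one row per animal carrying all traits, indices
#'   and classes.
#' @export
efficiency_traits <- function(performance, weights, diet_me) {
  perf <- as.data.frame(performance)
  wts <- as.data.frame(weights)
  stopifnot(all(c("animal_id", "year", "dmi", "d_bkft") %in% names(perf)),
            all(c("animal_id", "day", "weight_kg") %in% names(wts)))
  adg_by <- lapply(split(wts, wts$animal_id), function(d) {
    a <- compute_adg(d$day, d$weight_kg)
    data.frame(animal_id = d$animal_id[1], adg = a$adg,
               mwt = metabolic_weight(a$mid_wt), stringsAsFactors = FALSE)
  })
  adg_tab <- do.call(rbind, adg_by)
  perf <- merge(perf, adg_tab, by = "animal_id")
  perf$mei <- standardize_mei(perf$dmi, diet_me)
  perf$fcr <- perf$dmi / perf$adg
  perf$fce <- perf$adg / perf$dmi
  out <- lapply(split(perf, perf$year), function(grp) {
    fit <- fit_residual_models(grp)
    grp <- merge(grp, fit$indices, by = "animal_id")
    grp$rfi_class <- classify_efficiency(grp$rfi, "lower")
    grp$rbg_class <- classify_efficiency(grp$rbg, "higher")
    grp$rig_class <- classify_efficiency(grp$rig, "higher")
    grp
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
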