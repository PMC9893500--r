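#' Fit a single-component 24-h cosinor to one animal-day of temperature
#'
#' Fits y(t) = k + alpha * cos(2*pi*(t - phi_h)/period) by least squares,
#' where k is the MESOR (rhythm-adjusted mean), alpha the amplitude (half the
#' peak-to-trough range) and phi_h the acrophase expressed as the clock time
#' of the daily peak, hours after local midnight. The fit uses the exact
#' linear reparameterization y = k + b1*cos(wt) + b2*sin(wt) with
#' alpha = sqrt(b1^2 + b2^2) and phase atan2(b2, b1); for a single fixed
#' period this is algebraically identical to the nonlinear least-squares fit,
#' and alpha is nonnegative by construction.
#'
#' Rhythmicity is assessed by the 2-df F-test of b1 = b2 = 0 (cosinor vs
#' intercept-only model). A perfectly constant series has no rhythm signal
#' and is reported with `alpha = 0`, `p_rhythm = 1`.
#'
#' @param time_h Sample times in hours (clock hours after local midnight;
#'   values outside \[0, 24) are wrapped implicitly by the cosine).
#' @param temp_c Temperatures, degrees C, same length as `time_h`.
#' @param period Rhythm period in hours; fixed, default 24.
#' @return An object of class `cosinor_fit`: list with `mesor`, `amplitude`,
#'   `acrophase_rad` (in \[0, 2*pi)), `peak_time` (hours in \[0, 24)),
#'   `p_rhythm`, `n_obs`, `rss`, `tss`, `ok` (logical; `FALSE` for
#'   rank-deficient designs, e.g. all samples at one timepoint).
#' @examples
#' t <- seq(0, 24 - 1 / 12, by = 1 / 12)
#' y <- 39.8 + 0.25 * cos(2 * pi * (t - 16) / 24)
#' fit_cosinor_day(t, y)
#' @export
fit_cosinor_day <- function(time_h, temp_c, period = 24) {
  stopifnot(length(time_h) == length(temp_c), period > 0)
  keep <- is.finite(time_h) & is.finite(temp_c)
  t <- time_h[keep]
  y <- temp_c[keep]
  n <- length(y)
  fail <- function() {
    structure(list(mesor = NA_real_, amplitude = NA_real_,
                   acrophase_rad = NA_real_, peak_time = NA_real_,
                   p_rhythm = NA_real_, n_obs = n, rss = NA_real_,
                   tss = NA_real_, ok = FALSE), class = "cosinor_fit")
  }
  if (n < 3 || length(unique(round(t, 10))) < 3) return(fail())
  w <- 2 * pi / period
  X <- cbind(1, cos(w * t), sin(w * t))
  if (qr(X)$rank < 3) return(fail())
  fit <- .lm.fit(X, y)
  b <- fit$coefficients
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  amp <- sqrt(b[2]^2 + b[3]^2)
  phase <- atan2(b[3], b[2]) %% (2 * pi)
  # F-test of the 2-df rhythm hypothesis; a flat series (tss ~ 0) carries no
  # evidence of rhythm and is assigned p = 1
  if (tss <= .Machine$double.eps * max(1, sum(y^2))) {
    p <- 1
    amp <- 0
    phase <- 0
  } else {
    fstat <- ((tss - rss) / 2) / (rss / (n - 3))
    p <- if (!is.finite(fstat)) 0 else pf(fstat, 2, n - 3, lower.tail = FALSE)
  }
  structure(list(mesor = b[1], amplitude = amp, acrophase_rad = phase,
                 peak_time = (phase / w) %% period, p_rhythm = p,
                 n_obs = n, rss = rss, tss = tss, ok = TRUE),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  if (!x$ok) {
    cat("cosinor fit failed (rank-deficient or too few timepoints)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "cosinor fit: MESOR %.3f C, amplitude %.3f C, peak %.2f h, p = %.3g (n = %d)\n",
    x$mesor, x$amplitude, x$peak_time, x$p_rhythm, x$n_obs))
  invisible(x)
}

#' Rhythmicity p-value of a fitted cosinor day
#'
#' Convenience accessor for the zero-amplitude F-test already carried by a
#' [fit_cosinor_day()] result. Days with p > `alpha` are treated as having no
#' detectable rhythm and are excluded from regime summaries; a day with
#' p exactly equal to `alpha` is retained (the exclusion rule is strict
#' inequality).
#'
#' @param fit A `cosinor_fit`.
#' @param alpha Exclusion level, default 0.05.
#' @return List with `p_value` and `rhythmic` (logical: keep the day).
#' @export
rhythmicity_test <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "cosinor_fit"))
  if (!fit$ok || fit$n_obs <= 3) {
    return(list(p_value = NA_real_, rhythmic = FALSE))
  }
  list(p_value = fit$p_rhythm, rhythmic = fit$p_rhythm <= alpha)
}

#' Fit daily cosinors for every animal-device-day in a telemetry set
#'
#' Splits cleaned telemetry into animal-device-date groups, fits each day
#' with [fit_cosinor_day()], and marks days as valid when the fit succeeded,
#' used at least `min_obs` retained samples, and passed the rhythmicity
#' screen at level `alpha`.
#'
#' @param telemetry Data.frame with columns `animal_id`, `device`, `regime`,
#'   `timestamp` (POSIXct) or (`date`, `time_h`), `temp_c`, and optionally
#'   `flag` (samples with flag other than `"ok"`/`"imputed"` are ignored).
#' @param period Rhythm period, hours.
#' @param alpha Rhythmicity exclusion level (days with p > alpha dropped).
#' @param min_obs Minimum retained samples per day.
#' @return Data.frame of daily fits: `animal_id`, `device`, `regime`, `date`,
#'   `mesor`, `amplitude`, `peak_time`, `p_rhythm`, `n_obs`, `valid`.
#' @export
fit_cosinor_daily <- function(telemetry, period = 24, alpha = 0.05,
                              min_obs = 20) {
  df <- as.data.frame(telemetry)
  if ("flag" %in% names(df)) df <- df[df$flag %in% c("ok", "imputed"), ]
  if (!"time_h" %in% names(df)) {
    stopifnot("timestamp" %in% names(df))
    lt <- as.POSIXlt(df$timestamp)
    df$date <- as.Date(df$timestamp)
    df$time_h <- lt$hour + lt$min / 60 + lt$sec / 3600
  }
  if (!"regime" %in% names(df)) df$regime <- NA_character_
  key <- interaction(df$animal_id, df$device, df$date, drop = TRUE)
  pieces <- split(df, key)
  rows <- lapply(pieces, function(d) {
    f <- fit_cosinor_day(d$time_h, d$temp_c, period = period)
    data.frame(animal_id = d$animal_id[1], device = d$device[1],
               regime = d$regime[1], date = d$date[1],
               mesor = f$mesor, amplitude = f$amplitude,
               peak_time = f$peak_time, p_rhythm = f$p_rhythm,
               n_obs = f$n_obs,
               valid = f$ok && f$n_obs >= min_obs &&
                 is.finite(f$p_rhythm) && f$p_rhythm <= alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Circular mean of clock times
#'
#' Averages times-of-day on the circle so that e.g. 23.5 h and 0.5 h average
#' to 0.0 h rather than 12.0 h.
#'
#' @param hours Numeric vector of clock times in hours.
#' @param period Circle length in hours, default 24.
#' @return Mean time in \[0, period).
#' @export
circular_mean_hours <- function(hours, period = 24) {
  hours <- hours[is.finite(hours)]
  if (!length(hours)) return(NA_real_)
  w <- 2 * pi / period
  out <- (atan2(mean(sin(w * hours)), mean(cos(w * hours))) / w) %% period
  # a tiny negative angle would otherwise wrap to period - epsilon
  if (period - out < 1e-9) out <- 0
  out
}

#' Summarize daily cosinor fits per animal within a regime
#'
#' Per animal-device-regime means of MESOR and amplitude over valid days,
#' with the peak time averaged circularly, plus the count of valid days.
#' Animals with zero valid days are dropped and reported via the
#' `excluded_animals` attribute.
#'
#' @param daily_fits Output of [fit_cosinor_daily()].
#' @return Data.frame: `animal_id`, `device`, `regime`, `mean_mesor`,
#'   `mean_amplitude`, `mean_peak_time`, `n_valid_days`. Attribute
#'   `excluded_animals` lists animal-device pairs with no valid day.
#' @export
summarize_regime <- function(daily_fits) {
  df <- as.data.frame(daily_fits)
  needed <- c("animal_id", "device", "regime", "mesor", "amplitude",
              "peak_time", "valid")
  stopifnot(all(needed %in% names(df)))
  key_all <- unique(df[, c("animal_id", "device", "regime")])
  ok <- df[df$valid, ]
  pieces <- split(ok, interaction(ok$animal_id, ok$device, ok$regime,
                                  drop = TRUE))
  rows <- lapply(pieces, function(d) {
    data.frame(animal_id = d$animal_id[1], device = d$device[1],
               regime = d$regime[1],
               mean_mesor = mean(d$mesor),
               mean_amplitude = mean(d$amplitude),
               mean_peak_time = circular_mean_hours(d$peak_time),
               n_valid_days = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(animal_id = character(), device = character(),
                      regime = character(), mean_mesor = numeric(),
                      mean_amplitude = numeric(), mean_peak_time = numeric(),
                      n_valid_days = integer())
  }
  rownames(out) <- NULL
  got <- paste(out$animal_id, out$device, out$regime)
  want <- paste(key_all$animal_id, key_all$device, key_all$regime)
  attr(out, "excluded_animals") <- key_all[!(want %in% got), , drop = FALSE]
  out
}

#' Classify animals as high / medium / low on a circadian summary value
#'
#' Within each regime-device stratum the values are compared with the
#' stratum mean: label `high` if value > mean + `half_sd`*SD, `low` if
#' value < mean - `half_sd`*SD, else `medium`. Values exactly on a boundary
#' are `medium` (the middle band is closed). A zero-SD stratum yields all
#' `medium` with a warning.
#'
#' @param values Numeric vector (e.g. per-animal mean MESOR).
#' @param stratum Optional factor of the same length (regime-device); a
#'   single stratum if omitted.
#' @param half_sd Band half-width in SD units, default 0.5.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
classify_by_mesor <- function(values, stratum = NULL, half_sd = 0.5) {
  if (is.null(stratum)) stratum <- rep(1L, length(values))
  stopifnot(length(stratum) == length(values))
  out <- rep(NA_character_, length(values))
  for (s in split(seq_along(values), stratum)) {
    v <- values[s]
    if (length(v) < 3) stop("need at least 3 animals per stratum")
    sdv <- sd(v)
    if (!is.finite(sdv) || sdv == 0) {
      warning("zero SD in stratum: all animals classed medium")
      out[s] <- "medium"
      next
    }
    m <- mean(v)
    lab <- rep("medium", length(v))
    lab[v > m + half_sd * sdv] <- "high"
    lab[v < m - half_sd * sdv] <- "low"
    out[s] <- lab
  }
  factor(out, levels = c("low", "medium", "high"))
}
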