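#' Simulation configuration for a two-year, two-regime steer trial
#'
#' Bundles the study-design constants the generators emulate: 80 steers
#' per year over 2 years, multi-sire breeding groups of 24 sires per year
#' with a third shared across years, one dam per steer per year with a
#' small shared fraction, Fall-Winter (FW) and Winter-Spring (WS) test
#' windows of 85 and 78 calendar days, 5-min telemetry sampling, and
#' genetic (G0) / residual (R0) 2x2 covariance matrices for the FW/WS
#' expressions of the simulated trait. The default G0/R0 are anchored to a
#' rumen MESOR-like trait: additive variances 0.013 and 0.007 deg C^2 with
#' genetic correlation ~0.69, residual variances chosen so heritabilities
#' are ~0.78 (FW) and ~0.50 (WS).
#'
#' @param n_years Number of cohort years.
#' @param n_steers_per_year Steers recruited per year.
#' @param n_sires Sires per breeding year.
#' @param n_dams Dams per breeding year.
#' @param sire_overlap_fraction,dam_overlap_fraction Fraction of a year's
#'   parents reused from the previous year.
#' @param regime_days Named vector of calendar test days per regime.
#' @param sampling_interval Telemetry sampling interval, minutes.
#' @param G0,R0 2x2 additive and residual covariance matrices (symmetric,
#'   positive definite).
#' @param ambient_coupling Slope of body temperature on ambient anomaly,
#'   deg C body per deg C ambient (negative: colder days, warmer core).
#' @param artifact_rate Drinking-bout events per day.
#' @param glitch_rate Fraction of samples replaced by out-of-range sensor
#'   glitches.
#' @param dropout_rate Probability a whole animal-day of telemetry is lost.
#' @param noise_sd Within-day measurement noise SD, deg C.
#' @param seed Integer seed used by the generators.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(n_years = 2, n_steers_per_year = 80,
                              n_sires = 24, n_dams = 80,
                              sire_overlap_fraction = 8 / 24,
                              dam_overlap_fraction = 19 / 80,
                              regime_days = c(FW = 85, WS = 78),
                              sampling_interval = 5,
                              G0 = matrix(c(0.013, 0.0066, 0.0066, 0.007),
                                          2, 2),
                              R0 = matrix(c(0.0037, 0.0030, 0.0030, 0.0070),
                                          2, 2),
                              ambient_coupling = -0.011,
                              artifact_rate = 6, glitch_rate = 0.002,
                              dropout_rate = 0.08, noise_sd = 0.05,
                              seed = 1L) {
  counts <- c(n_years, n_steers_per_year, n_sires, n_dams)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("counts must be positive integers")
  }
  props <- c(sire_overlap_fraction, dam_overlap_fraction, dropout_rate,
             glitch_rate)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (sampling_interval <= 0) stop("sampling_interval must be positive")
  if (any(regime_days < 1) || is.null(names(regime_days))) {
    stop("regime_days must be a named vector of positive counts")
  }
  .check_psd(G0, "G0")
  .check_psd(R0, "R0")
  structure(list(
    n_years = as.integer(n_years),
    n_steers_per_year = as.integer(n_steers_per_year),
    n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
    sire_overlap_fraction = sire_overlap_fraction,
    dam_overlap_fraction = dam_overlap_fraction,
    regime_days = regime_days, sampling_interval = sampling_interval,
    G0 = G0, R0 = R0, ambient_coupling = ambient_coupling,
    artifact_rate = artifact_rate, glitch_rate = glitch_rate,
    dropout_rate = dropout_rate, noise_sd = noise_sd,
    seed = as.integer(seed)), class = "sim_config")
}

# symmetric positive *semi*definite check (a zero matrix is a legitimate
# degenerate setting for variance-component recovery tests)
.check_psd <- function(S, name) {
  if (!is.matrix(S) || any(dim(S) != c(2, 2)) ||
      max(abs(S - t(S))) > 1e-8) {
    stop("`", name, "` must be a symmetric 2x2 matrix")
  }
  if (min(eigen(S, TRUE, TRUE)$values) < -1e-10) {
    stop("`", name, "` must be positive semidefinite")
  }
  invisible(TRUE)
}

#' Simulate daily winter weather for a test window
#'
#' Daily dry-bulb temperature follows a seasonal sinusoid (coldest in
#' mid-January) plus Gaussian day-to-day noise; relative humidity follows a
#' weaker counter-phase sinusoid clipped to \[0, 100\]. The sinusoid is
#' parameterized so that window means land near -11.7 C / 82% RH for a
#' mid-November-to-mid-February window and -0.8 C / 73% for late-February-
#' to-mid-May, typical prairie backgrounding seasons. The THI column is
#' derived with [thi()].
#'
#' @param start_date Date of the first test day.
#' @param n_days Number of days.
#' @param temp_noise_sd Day-to-day temperature SD, deg C.
#' @param seed Optional integer seed.
#' @return Data.frame: `date`, `dry_bulb`, `relative_humidity`, `thi`.
#' @export
simulate_weather <- function(start_date, n_days, temp_noise_sd = 4.5,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dates <- as.Date(start_date) + seq_len(n_days) - 1
  doy <- as.integer(format(dates, "%j"))
  phase <- 2 * pi * (doy - 15) / 365
  temp <- 2.97 - 16.3 * cos(phase) + rnorm(n_days, 0, temp_noise_sd)
  rh <- 77 + 5 * cos(phase) + rnorm(n_days, 0, 4)
  rh <- pmin(100, pmax(0, rh))
  data.frame(date = dates, dry_bulb = temp, relative_humidity = rh,
             thi = thi(temp, rh))
}
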