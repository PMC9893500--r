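#' Simulate a multi-sire, multi-year pedigree
#'
#' Builds a pedigree with the structure of a two-year steer trial: each
#' year `n_steers_per_year` steers are produced by that year's breeding
#' group of `n_sires` sires and `n_dams` dams. A configured fraction of a
#' year's sires and dams is carried over from the previous year, and every
#' parent in a year's group produces at least one calf that year, so the
#' realized between-year overlap equals the configured one exactly (within
#' rounding). Founders (sires and dams) have unknown parents. Deterministic
#' under the config seed.
#'
#' @param config A [simulation_config()].
#' @return Sorted pedigree data.frame (`animal`, `sire`, `dam`) with
#'   attributes `steers` (data.frame animal/year) and `founders`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_keep_s <- round(config$sire_overlap_fraction * config$n_sires)
  n_keep_d <- round(config$dam_overlap_fraction * config$n_dams)
  if (n_keep_s > config$n_sires || n_keep_d > config$n_dams) {
    stop("infeasible overlap: more shared parents than exist in a year")
  }
  if (config$n_dams > config$n_steers_per_year) {
    stop("n_dams per year cannot exceed steers per year ",
         "(every dam must calve)")
  }
  sires_prev <- dams_prev <- character(0)
  next_s <- next_d <- 1L
  rows <- list()
  steers <- list()
  for (yr in seq_len(config$n_years)) {
    reuse_s <- if (yr > 1) sample(sires_prev, n_keep_s) else character(0)
    reuse_d <- if (yr > 1) sample(dams_prev, n_keep_d) else character(0)
    new_s <- sprintf("S%03d", seq(next_s, length.out = config$n_sires -
                                    length(reuse_s)))
    new_d <- sprintf("D%03d", seq(next_d, length.out = config$n_dams -
                                    length(reuse_d)))
    next_s <- next_s + length(new_s)
    next_d <- next_d + length(new_d)
    sires <- c(reuse_s, new_s)
    dams <- c(reuse_d, new_d)
    n <- config$n_steers_per_year
    # every sire gets a base allocation; every dam calves at most... exactly
    # floor(n/n_dams) or +1 times so all are used
    sire_of <- sample(rep(sires, length.out = n))
    dam_of <- sample(rep(dams, length.out = n))
    ids <- sprintf("Y%dA%03d", yr, seq_len(n))
    rows[[yr]] <- data.frame(animal = ids, sire = sire_of, dam = dam_of,
                             stringsAsFactors = FALSE)
    steers[[yr]] <- data.frame(animal = ids, year = yr,
                               stringsAsFactors = FALSE)
    sires_prev <- sires
    dams_prev <- dams
  }
  ped <- sort_pedigree(do.call(rbind, rows))
  attr(ped, "steers") <- do.call(rbind, steers)
  ped
}

# symmetric matrix square root tolerating zero eigenvalues
.sym_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate genetically structured FW/WS phenotypes over a pedigree
#'
#' Draws additive genetic values for every pedigree animal so that
#' cov(a) = A (x) G0 (via the Cholesky factor of the additive relationship
#' matrix), adds i.i.d. residual pairs with covariance R0 for the
#' phenotyped animals, and returns phenotype = mean + a + e. G0 and R0 may
#' be positive semidefinite (a zero G0 yields phenotypes that are pure
#' noise); indefinite matrices are rejected.
#'
#' @param pedigree Pedigree data.frame (sorted internally).
#' @param G0,R0 2x2 symmetric PSD covariance matrices.
#' @param mean_fw,mean_ws Trait means for the two regimes.
#' @param phenotyped Character vector of animal IDs that get records;
#'   default all non-founders.
#' @param seed Optional integer seed.
#' @return List: `additive` (data.frame animal_id, a_fw, a_ws for all
#'   pedigree animals) and `phenotypes` (animal_id, fw, ws, e_fw, e_ws).
#' @export
simulate_genetic_values <- function(pedigree, G0, R0, mean_fw = 0,
                                    mean_ws = 0, phenotyped = NULL,
                                    seed = NULL) {
  .check_psd(G0, "G0")
  .check_psd(R0, "R0")
  if (!is.null(seed)) set.seed(seed)
  ped <- sort_pedigree(pedigree)
  A <- additive_relationship_matrix(ped)
  q <- nrow(A)
  # L_A Z L_G' has cov(a_i, a_j) = A_ij * G0
  LA <- t(chol(A + diag(1e-10, q)))
  LG <- .sym_sqrt(G0)
  a <- LA %*% matrix(rnorm(2 * q), q, 2) %*% t(LG)
  if (is.null(phenotyped)) {
    phenotyped <- ped$animal[!(is.na(ped$sire) & is.na(ped$dam))]
  }
  idx <- match(phenotyped, ped$animal)
  if (anyNA(idx)) stop("phenotyped animals not in pedigree")
  LR <- .sym_sqrt(R0)
  e <- matrix(rnorm(2 * length(idx)), ncol = 2) %*% t(LR)
  list(additive = data.frame(animal_id = ped$animal, a_fw = a[, 1],
                             a_ws = a[, 2], stringsAsFactors = FALSE),
       phenotypes = data.frame(animal_id = phenotyped,
                               fw = mean_fw + a[idx, 1] + e[, 1],
                               ws = mean_ws + a[idx, 2] + e[, 2],
                               e_fw = e[, 1], e_ws = e[, 2],
                               stringsAsFactors = FALSE))
}

#' Simulate a 5-min body-temperature telemetry stream for one animal
#'
#' Generates `days` days of samples every `sampling_interval` minutes:
#' a cosine rhythm around a day-specific MESOR (AR(1) wander about the
#' animal mean), an ambient-coupling term, Gaussian measurement noise,
#' drinking-bout artifacts (instantaneous 0.5-2.0 C drop with ~20-min
#' exponential recovery half-life, onset times Poisson at `artifact_rate`
#' per day), sporadic out-of-range glitches, and whole-day dropout. Every
#' corruption is recorded in truth columns so cleaning can be scored
#' against ground truth.
#'
#' @param animal_id Animal identifier.
#' @param mesor,amplitude,acrophase Rhythm parameters: MESOR deg C,
#'   amplitude >= 0 deg C, acrophase (peak clock time) in \[0, 24).
#' @param days Number of days.
#' @param config A [simulation_config()] (sampling interval, noise,
#'   artifact/glitch/dropout rates, ambient coupling).
#' @param ambient Optional data.frame from [simulate_weather()] with one
#'   row per day; its `dry_bulb` anomaly (about its own mean) feeds the
#'   coupling term.
#' @param device,regime Labels copied into the output.
#' @param start_date First day.
#' @param mesor_ar1_rho,mesor_ar1_sd Day-to-day MESOR wander: AR(1)
#'   autocorrelation and innovation SD (deg C).
#' @param seed Optional integer seed.
#' @return Data.frame: `animal_id`, `device`, `regime`, `date`, `time_h`,
#'   `timestamp`, `temp_c`, plus truth columns `truth_clean` (uncorrupted
#'   value), `truth_artifact`, `truth_glitch` (logicals) and `truth_mesor`
#'   (the day's true MESOR).
#' @export
simulate_temperature_series <- function(animal_id, mesor, amplitude,
                                        acrophase, days, config,
                                        ambient = NULL, device = "rumen",
                                        regime = "FW",
                                        start_date = as.Date("2016-11-16"),
                                        mesor_ar1_rho = 0.7,
                                        mesor_ar1_sd = 0.03, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), amplitude >= 0,
            acrophase >= 0, acrophase < 24, days >= 1)
  if (config$sampling_interval <= 0) stop("nonpositive sampling interval")
  if (!is.null(seed)) set.seed(seed)
  dt_h <- config$sampling_interval / 60
  per_day <- round(24 / dt_h)
  tod <- (seq_len(per_day) - 1) * dt_h
  # day-level MESOR wander, stationary AR(1) around the animal mean
  wander <- numeric(days)
  sd_stat <- mesor_ar1_sd / sqrt(1 - mesor_ar1_rho^2)
  wander[1] <- rnorm(1, 0, sd_stat)
  if (days > 1) {
    for (d in 2:days) {
      wander[d] <- mesor_ar1_rho * wander[d - 1] + rnorm(1, 0, mesor_ar1_sd)
    }
  }
  amb_anom <- if (!is.null(ambient)) {
    stopifnot(nrow(ambient) >= days)
    ambient$dry_bulb[seq_len(days)] - mean(ambient$dry_bulb[seq_len(days)])
  } else {
    rep(0, days)
  }
  drop_day <- runif(days) < config$dropout_rate
  rows <- vector("list", days)
  for (d in seq_len(days)) {
    if (drop_day[d]) next
    k_day <- mesor + wander[d]
    clean <- k_day + amplitude * cos(2 * pi * (tod - acrophase) / 24) +
      config$ambient_coupling * amb_anom[d]
    y <- clean + rnorm(per_day, 0, config$noise_sd)
    art_effect <- numeric(per_day)
    n_bouts <- stats::rpois(1, config$artifact_rate)
    if (n_bouts > 0) {
      onsets <- sort(sample.int(per_day, min(n_bouts, per_day)))
      for (o in onsets) {
        depth <- runif(1, 0.5, 2.0)
        span <- o:per_day
        dt_min <- (span - o) * config$sampling_interval
        art_effect[span] <- art_effect[span] - depth * 2^(-dt_min / 20)
      }
    }
    is_art <- art_effect < -2 * config$noise_sd
    y <- y + art_effect
    is_glitch <- runif(per_day) < config$glitch_rate
    if (any(is_glitch)) {
      n_g <- sum(is_glitch)
      y[is_glitch] <- ifelse(runif(n_g) < 0.5, runif(n_g, 5, 31.5),
                             runif(n_g, 42.5, 70))
    }
    date_d <- start_date + d - 1
    rows[[d]] <- data.frame(
      animal_id = animal_id, device = device, regime = regime,
      date = date_d, time_h = tod,
      timestamp = as.POSIXct(date_d, tz = "UTC") + tod * 3600,
      temp_c = y, truth_clean = clean, truth_artifact = is_art,
      truth_glitch = is_glitch, truth_mesor = k_day,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("all simulated days dropped out; lower dropout_rate or add days")
  }
  rownames(out) <- NULL
  out
}

#' Simulate performance records (weights, intake, backfat) for a cohort
#'
#' For each animal: serial body weights every 14 days along a linear growth
#' trajectory with measurement noise; daily dry matter intake generated as
#' a linear function of true ADG, mid-test metabolic weight and backfat
#' change plus an animal-specific intake residual (the true RFI channel);
#' truth values are retained so index-recovery can be scored.
#'
#' @param animal_id Character vector of animal IDs.
#' @param adg_true True ADG per animal, kg/d (recycled if scalar).
#' @param start_wt Starting body weight per animal, kg.
#' @param test_days Test length in days.
#' @param beta Generating coefficients `c(intercept, adg, mwt, d_bkft)` of
#'   the intake model, kg DM/d per unit.
#' @param rfi_sd SD of the true intake residual, kg DM/d.
#' @param wt_noise_sd Weighing noise SD, kg.
#' @param d_bkft_mean,d_bkft_sd Backfat change distribution, mm.
#' @param year,regime,pen Labels copied into the output.
#' @param seed Optional integer seed.
#' @return List: `performance` (one row per animal: `animal_id`, `year`,
#'   `regime`, `pen`, `start_wt`, `dmi`, `d_bkft`), `weights` (long
#'   data.frame `animal_id`, `day`, `weight_kg`), `truth` (`animal_id`,
#'   `adg_true`, `rfi_true`, `mwt_true`).
#' @export
simulate_performance <- function(animal_id, adg_true, start_wt,
                                 test_days = 84,
                                 beta = c(0.5, 2.2, 0.09, 0.05),
                                 rfi_sd = 0.5, wt_noise_sd = 4,
                                 d_bkft_mean = 2, d_bkft_sd = 1,
                                 year = 1, regime = "FW", pen = 1,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(animal_id)
  adg_true <- rep_len(adg_true, n)
  start_wt <- rep_len(start_wt, n)
  stopifnot(test_days >= 28, length(beta) == 4)
  wt_days <- unique(c(seq(0, test_days, by = 14), test_days))
  weights <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(animal_id = animal_id[i], day = wt_days,
               weight_kg = start_wt[i] + adg_true[i] * wt_days +
                 rnorm(length(wt_days), 0, wt_noise_sd),
               stringsAsFactors = FALSE)
  }))
  mid_wt <- start_wt + adg_true * test_days / 2
  mwt <- metabolic_weight(mid_wt)
  d_bkft <- rnorm(n, d_bkft_mean, d_bkft_sd)
  # RFI is a cohort-level residual by definition, so the truth channel
  # records the component of the drawn intake deviation orthogonal (in this
  # cohort) to the true regressors; it is exactly mean zero
  rfi_draw <- rnorm(n, 0, rfi_sd)
  rfi_true <- if (n >= 5) {
    .lm.fit(cbind(1, adg_true, mwt, d_bkft), rfi_draw)$residuals
  } else {
    rfi_draw - mean(rfi_draw)
  }
  dmi <- beta[1] + beta[2] * adg_true + beta[3] * mwt + beta[4] * d_bkft +
    rfi_true
  list(performance = data.frame(animal_id = animal_id, year = year,
                                regime = regime, pen = pen,
                                start_wt = start_wt, dmi = dmi,
                                d_bkft = d_bkft, stringsAsFactors = FALSE),
       weights = weights,
       truth = data.frame(animal_id = animal_id, adg_true = adg_true,
                          rfi_true = rfi_true, mwt_true = mwt,
                          stringsAsFactors = FALSE))
}
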