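#' Read temperature telemetry from CSV
#'
#' Expects columns `animal_id`, `device`, `timestamp` (ISO-8601), `temp_c`,
#' and optionally `regime`. Malformed rows (unparseable timestamp or
#' temperature) and duplicated animal-device timestamps are not silently
#' dropped: they are removed from the returned samples but counted and
#' returned in the `errors` attribute (for duplicates the first occurrence
#' is kept).
#'
#' @param path CSV file path.
#' @param tz Time zone for timestamp parsing, default `"UTC"`.
#' @return Data.frame sorted by animal, device, timestamp with a per-sample
#'   `flag` column initialized to `"ok"`; attributes `errors` (data.frame of
#'   row, reason) and `n_malformed`.
#' @export
read_telemetry <- function(path, tz = "UTC") {
  if (!file.exists(path)) stop("telemetry file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("animal_id", "device", "timestamp", "temp_c")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("telemetry file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  # strptime yields NA for malformed strings instead of aborting the read
  ts <- as.POSIXct(strptime(raw$timestamp, "%Y-%m-%dT%H:%M:%S", tz = tz))
  alt <- is.na(ts)
  if (any(alt)) {
    ts[alt] <- as.POSIXct(strptime(raw$timestamp[alt], "%Y-%m-%d %H:%M:%S",
                                   tz = tz))
  }
  temp <- suppressWarnings(as.numeric(raw$temp_c))
  errors <- data.frame(row = integer(), reason = character())
  bad_ts <- which(is.na(ts))
  bad_temp <- setdiff(which(is.na(temp)), bad_ts)
  if (length(bad_ts)) {
    errors <- rbind(errors, data.frame(row = bad_ts,
                                       reason = "unparseable timestamp"))
  }
  if (length(bad_temp)) {
    errors <- rbind(errors, data.frame(row = bad_temp,
                                       reason = "non-numeric temperature"))
  }
  keep <- !is.na(ts) & !is.na(temp)
  df <- data.frame(animal_id = as.character(raw$animal_id[keep]),
                   device = as.character(raw$device[keep]),
                   timestamp = ts[keep], temp_c = temp[keep],
                   stringsAsFactors = FALSE)
  if ("regime" %in% names(raw)) df$regime <- as.character(raw$regime[keep])
  ord <- order(df$animal_id, df$device, df$timestamp)
  df <- df[ord, ]
  dup <- duplicated(df[, c("animal_id", "device", "timestamp")])
  if (any(dup)) {
    errors <- rbind(errors, data.frame(
      row = which(keep)[ord][dup],
      reason = "duplicate animal-device timestamp (later copy dropped)"))
    df <- df[!dup, ]
  }
  df$flag <- "ok"
  rownames(df) <- NULL
  attr(df, "errors") <- errors
  attr(df, "n_malformed") <- nrow(errors)
  df
}

#' Write telemetry to CSV (round-trip companion of [read_telemetry()])
#'
#' Temperatures are written with 3 decimal places.
#'
#' @param telemetry Telemetry data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_telemetry <- function(telemetry, path) {
  df <- as.data.frame(telemetry)
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  df$temp_c <- sprintf("%.3f", df$temp_c)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flag temperatures outside the physiological range
#'
#' Samples strictly below `low` or strictly above `high` degrees C are
#' flagged `out_of_range`; the boundary values themselves are retained
#' (the rule is "below"/"above", i.e. an inclusive interval). Flagged
#' samples stay in the table for audit but are excluded by every downstream
#' computation. Idempotent.
#'
#' @param telemetry Telemetry data.frame with `temp_c` and `flag`.
#' @param low,high Physiological bounds, default 32 and 42 C.
#' @return The telemetry with updated `flag`; attribute `n_out_of_range`
#'   counts newly and previously flagged samples.
#' @export
filter_physiological_range <- function(telemetry, low = 32, high = 42) {
  if (low >= high) stop("`low` must be strictly less than `high`")
  df <- as.data.frame(telemetry)
  stopifnot("temp_c" %in% names(df))
  if (!nrow(df)) stop("empty telemetry")
  if (!"flag" %in% names(df)) df$flag <- "ok"
  oor <- df$temp_c < low | df$temp_c > high
  df$flag[oor & df$flag == "ok"] <- "out_of_range"
  attr(df, "n_out_of_range") <- sum(df$flag == "out_of_range")
  df
}

#' Detect (and optionally impute) drinking-bout artifacts
#'
#' Drinking bouts cool the reticulo-rumen and appear as a sharp negative
#' excursion followed by an exponential recovery toward baseline. Each
#' animal-device stream is screened with a rolling autoregressive
#' one-step-ahead prediction: AR(`ar_order`) coefficients and a local mean
#' are refitted every `window` samples (default 24 h at 5-min sampling),
#' predictions are formed recursively from the *clean* series (flagged
#' samples are replaced by their prediction before feeding the next step,
#' so the whole excursion is visible against the baseline, not just its
#' onset), and a sample is flagged when its residual falls below
#' `-z_threshold` robust SDs. Once an excursion has started, flagging
#' continues with a hysteresis exit at one robust SD so that the recovery
#' tail is captured. Only negative excursions are targeted: positive spikes
#' are never flagged. Flagged samples are either excluded (`action =
#' "drop"`) or replaced by the prediction and flagged `imputed`
#' (`action = "impute"`). Clean data pass through unchanged (idempotent
#' within tolerance).
#'
#' Streams with fewer than 50 retained samples are returned unchanged with
#' a warning.
#'
#' @param telemetry Telemetry data.frame (one or more animal-device streams).
#' @param ar_order Autoregressive order, default 4.
#' @param z_threshold Residual z-score entry threshold, default 3.
#' @param window Rolling refit window in samples; default 288 (24 h at
#'   5-min sampling).
#' @param action `"drop"` (flag only) or `"impute"` (replace by prediction).
#' @return Telemetry with updated `flag` (and `temp_c` under `"impute"`);
#'   attribute `n_artifact` counts flagged samples.
#' @export
remove_drinking_artifacts <- function(telemetry, ar_order = 4,
                                      z_threshold = 3, window = 288,
                                      action = c("drop", "impute")) {
  action <- match.arg(action)
  stopifnot(ar_order >= 1, z_threshold > 0, window > 4 * ar_order)
  df <- as.data.frame(telemetry)
  if (!"flag" %in% names(df)) df$flag <- "ok"
  key <- interaction(df$animal_id, df$device, drop = TRUE)
  for (idx in split(seq_len(nrow(df)), key)) {
    ok_idx <- idx[df$flag[idx] == "ok"]
    if (length(ok_idx) < 50) {
      warning("stream too short for artifact screening (",
              length(ok_idx), " samples); returned unchanged")
      next
    }
    y_ok <- df$temp_c[ok_idx]
    scr <- .screen_stream(y_ok, ar_order, z_threshold, window)
    # the forward pass has no history for a bout at the very start of the
    # stream; a reverse-time pass over the first window closes that blind
    # spot (a dip is a negative excursion in either time direction)
    head_n <- min(window, length(y_ok))
    rev_scr <- .screen_stream(rev(y_ok[seq_len(head_n)]), ar_order,
                              z_threshold, window)
    new_head <- rev(rev_scr$flagged) & !scr$flagged[seq_len(head_n)]
    scr$flagged[seq_len(head_n)][new_head] <- TRUE
    scr$xhat[seq_len(head_n)][new_head] <-
      rev(rev_scr$xhat)[new_head]
    hit_rows <- ok_idx[scr$flagged]
    df$flag[hit_rows] <- if (action == "impute") "imputed" else "artifact"
    if (action == "impute") df$temp_c[hit_rows] <- scr$xhat[scr$flagged]
  }
  attr(df, "n_artifact") <- sum(df$flag %in% c("artifact", "imputed"))
  df
}

# Recursive AR screen of one stream. Returns flagged logical vector and the
# reconstructed (prediction-substituted) series xhat.
#
# AR coefficients and the local mean are refitted per window on the
# reconstructed series; the noise scale is the robust MAD of plain
# one-step residuals of the *raw* series (never of the smoothed
# reconstruction, whose residuals shrink with every substitution). Dip
# runs are force-closed after max_run samples: drinking-bout transients
# decay within a couple of hours, and an unbounded hysteresis run could
# otherwise swallow genuine baseline shifts (72 samples = 6 h at 5-min sampling).
.screen_stream <- function(y, p, z, window, max_run = 72) {
  n <- length(y)
  flagged <- logical(n)
  xhat <- y
  one_step_scale <- function(seg, cf, mu) {
    m <- length(seg)
    if (m <= p + 5) return(NA_real_)
    segc <- seg - mu
    pr <- vapply((p + 1):m, function(i) sum(cf * segc[(i - 1):(i - p)]),
                 numeric(1))
    r <- segc[(p + 1):m] - pr
    sc <- stats::mad(r)
    if (!is.finite(sc) || sc == 0) sc <- stats::sd(r)
    sc
  }
  refit <- function(seg_clean, seg_raw) {
    mu <- mean(seg_clean)
    cf <- tryCatch({
      fit <- stats::ar.yw(seg_clean, order.max = p, aic = FALSE,
                          demean = TRUE)
      if (length(fit$ar)) fit$ar else NULL
    }, error = function(e) NULL)
    if (is.null(cf)) return(NULL)
    sc <- one_step_scale(seg_raw, cf, mean(seg_raw))
    list(mu = mu, cf = cf, sc = sc)
  }
  first <- 1:min(window, n)
  fit <- refit(y[first], y[first])
  if (is.null(fit) || !is.finite(fit$sc) || fit$sc == 0) {
    return(list(flagged = flagged, xhat = xhat))
  }
  sc <- fit$sc
  in_dip <- FALSE
  run <- 0L
  clear <- 0L # consecutive in-dip samples back above the exit threshold
  for (i in (p + 1):n) {
    if (i %% window == 0 && i + p < n) {
      span <- max(1, i - window + 1):i
      new_fit <- refit(xhat[span], y[span])
      if (!is.null(new_fit)) {
        fit <- new_fit
        if (is.finite(new_fit$sc) && new_fit$sc > 0) sc <- new_fit$sc
      }
    }
    pred <- fit$mu + sum(fit$cf * (xhat[(i - 1):(i - p)] - fit$mu))
    res <- y[i] - pred
    thr <- if (in_dip) -1 * sc else -z * sc
    if (res < thr && (!in_dip || run < max_run)) {
      if (!in_dip) {
        # back-flag the ramp into the excursion: samples just before the
        # entry that already sit below the entry-time baseline (a slow
        # slide tracked by the one-step predictor would otherwise escape)
        j <- i - 1L
        while (j >= 1L && !flagged[j] && (i - j) <= max_run &&
               y[j] < pred - sc) {
          flagged[j] <- TRUE
          xhat[j] <- pred
          j <- j - 1L
        }
      }
      flagged[i] <- TRUE
      xhat[i] <- pred
      in_dip <- TRUE
      run <- run + 1L
      clear <- 0L
    } else {
      xhat[i] <- y[i]
      if (in_dip && res < 0 && clear < 1L && run < max_run) {
        # debounce: one isolated upcrossing does not end the excursion
        clear <- clear + 1L
      } else {
        in_dip <- FALSE
        run <- 0L
        clear <- 0L
      }
    }
  }
  list(flagged = flagged, xhat = xhat)
}

#' Daily completeness of a telemetry stream
#'
#' Fraction of expected samples actually retained (flag `ok` or `imputed`);
#' an animal-device stream passes when the fraction is at least
#' `min_fraction` (default 0.80, i.e. streams with less than 80% of the
#' complete record are excluded downstream).
#'
#' @param n_retained Count of retained samples.
#' @param expected_samples Expected count (> 0), e.g. 288 per day at 5-min
#'   sampling.
#' @param min_fraction Pass threshold, default 0.80.
#' @return List with `fraction` and `pass`.
#' @export
completeness_check <- function(n_retained, expected_samples,
                               min_fraction = 0.80) {
  stopifnot(expected_samples > 0, n_retained >= 0)
  frac <- n_retained / expected_samples
  list(fraction = frac, pass = frac >= min_fraction)
}

#' @importFrom stats mad ar.yw
NULL
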