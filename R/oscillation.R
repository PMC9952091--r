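# Period-band decomposition of single-cell signaling and morphology series.
#
# Signals are detrended by subtracting a long centered moving average, then
# decomposed with a zero-phase discrete-Fourier brick-wall filter retaining
# only oscillation periods inside a band. Per-cell amplitude is sqrt(2)
# times the RMS of the filtered series, which equals the peak amplitude for
# a single tone.

#' A period band
#'
#' @param period_low,period_high band limits in minutes; oscillations with
#'   period between the limits (inclusive) are retained.
#' @param dt sampling interval, minutes (for the Nyquist check).
#' @return list of class `band_spec`.
#' @export
band_spec <- function(period_low, period_high, dt = 4) {
  if (!(2 * dt < period_low && period_low < period_high)) {
    stop("band requires 2*dt < period_low < period_high")
  }
  structure(list(period_low = period_low, period_high = period_high),
            class = "band_spec")
}

#' Short- and long-wave default bands
#'
#' 28-60 min for short Akt/ERK waves (the period range of reported ERK
#' pulses) and 92-124 min for long waves (matching the period range of
#' morphological aspect ratios).
#' @param dt sampling interval, minutes.
#' @return named list of [band_spec()]s.
#' @export
default_bands <- function(dt = 4) {
  list(short = band_spec(28, 60, dt), long = band_spec(92, 124, dt))
}

#' Detrend a uniformly sampled series
#'
#' Subtracts a centered moving average with a 200 min window (longer than
#' any analyzed band, so in-band oscillations pass nearly unchanged). Series
#' shorter than the trend window fall back to removing a global linear fit;
#' the result carries attribute `method`.
#'
#' @param x numeric series; interior NA gaps are linearly interpolated
#'   before trend estimation.
#' @param dt sampling interval, minutes.
#' @param trend_window trend window, minutes.
#' @return detrended series (attribute `method` = "moving_average" or
#'   "linear").
#' @export
detrend <- function(x, dt = 4, trend_window = 200) {
  x <- interpolate_gaps(x)
  n <- length(x)
  w <- round(trend_window / dt)
  if (n <= w) {
    t_ <- seq_len(n)
    fit <- stats::lm.fit(cbind(1, t_), x)
    out <- x - fit$fitted.values
    attr(out, "method") <- "linear"
    return(out)
  }
  out <- x - moving_average(x, w)
  attr(out, "method") <- "moving_average"
  out
}

interpolate_gaps <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- which(!is.na(x))
  if (length(idx) < 2) stop("series has fewer than 2 finite values")
  stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
}

#' Brick-wall bandpass filter
#'
#' Discrete Fourier transform filter retaining frequencies f with
#' `1/period_high <= f <= 1/period_low`, zeroing all other bins (including
#' DC), and transforming back. Zero phase shift by construction.
#'
#' @param x detrended, uniformly sampled series.
#' @param band a [band_spec()].
#' @param dt sampling interval, minutes.
#' @return filtered series.
#' @export
bandpass <- function(x, band, dt = 4) {
  stopifnot(inherits(band, "band_spec"))
  if (2 * dt >= band$period_low) stop("band violates the Nyquist limit for this dt")
  n <- length(x)
  f <- (seq_len(n) - 1) / (n * dt)
  f <- pmin(f, 1 / dt - f)   # two-sided spectrum: frequency of each bin
  keep <- f >= 1 / band$period_high & f <= 1 / band$period_low
  X <- stats::fft(x)
  X[!keep] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Band amplitude of a filtered series
#'
#' sqrt(2) times the root mean square; equals the peak amplitude of a
#' single tone.
#'
#' @param x band-filtered series.
#' @return nonnegative scalar amplitude.
#' @export
band_amplitude <- function(x) sqrt(2) * rms(x)

#' Per-cell band amplitudes and mean speed
#'
#' For every track meeting the minimum-length rule, computes the short- and
#' long-band amplitudes of Akt and ERK, the long-band aspect-ratio
#' amplitude, and the mean migration speed.
#'
#' @param tracks track table (columns track_id or cell_id, frame, t_min,
#'   x_um, y_um, erk_ktr, akt_ktr, aspect_ratio).
#' @param bands named list with `short` and `long` [band_spec()]s.
#' @param dt sampling interval, minutes.
#' @param min_len minimum number of observations per track.
#' @param max_gap longest interior NA run that is interpolated; cells with
#'   longer gaps are excluded rather than imputed.
#' @return data.frame (one row per cell): `cell_id`, `akt_short`,
#'   `erk_short`, `akt_long`, `erk_long`, `ar_amp`, `mean_speed`.
#' @export
band_amplitudes <- function(tracks, bands = default_bands(dt), dt = 4,
                            min_len = 60L, max_gap = 2L) {
  tracks <- as_track_table(tracks)
  res <- lapply(split(tracks, tracks$track_id), function(d) {
    d <- d[order(d$t_min), , drop = FALSE]
    if (nrow(d) < min_len) return(NULL)
    if (longest_na_run(d$erk_ktr) > max_gap ||
        longest_na_run(d$akt_ktr) > max_gap ||
        longest_na_run(d$aspect_ratio) > max_gap) return(NULL)
    erk <- detrend(d$erk_ktr, dt)
    akt <- detrend(d$akt_ktr, dt)
    ar <- detrend(d$aspect_ratio, dt)
    data.frame(
      cell_id = d$track_id[1],
      akt_short = band_amplitude(bandpass(akt, bands$short, dt)),
      erk_short = band_amplitude(bandpass(erk, bands$short, dt)),
      akt_long = band_amplitude(bandpass(akt, bands$long, dt)),
      erk_long = band_amplitude(bandpass(erk, bands$long, dt)),
      ar_amp = band_amplitude(bandpass(ar, bands$long, dt)),
      mean_speed = compute_speeds(d)$mean_speed)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

longest_na_run <- function(x) {
  if (!anyNA(x)) return(0L)
  r <- rle(is.na(x))
  max(c(0L, r$lengths[r$values]))
}

#' Correlation of band amplitude with speed across center periods
#'
#' For each center period c, the band [c - half_width, c + half_width] is
#' applied to the Akt and ERK series of every qualifying cell; the Pearson
#' correlation of per-cell amplitude with mean speed is reported with a
#' 95 percent Fisher-z confidence interval.
#'
#' @param tracks track table.
#' @param center_periods vector of band centers, minutes.
#' @param half_width band half width, minutes.
#' @param dt sampling interval, minutes.
#' @param min_len,min_cells qualification rules.
#' @return data.frame: center, signal ("akt"/"erk"), r, ci_lo, ci_hi, n.
#' @export
amplitude_sweep <- function(tracks, center_periods, half_width = 16, dt = 4,
                            min_len = 60L, min_cells = 10L) {
  tracks <- as_track_table(tracks)
  keep <- names(which(table(tracks$track_id) >= min_len))
  tracks <- tracks[tracks$track_id %in% keep, , drop = FALSE]
  cells <- split(tracks, tracks$track_id)
  if (length(cells) < min_cells) stop("fewer than min_cells qualifying cells")
  speeds <- vapply(cells, function(d) compute_speeds(d)$mean_speed, 0)
  detr <- lapply(cells, function(d) {
    d <- d[order(d$t_min), ]
    list(erk = detrend(d$erk_ktr, dt), akt = detrend(d$akt_ktr, dt))
  })
  rows <- list()
  for (cp in center_periods) {
    lo <- cp - half_width
    if (2 * dt >= lo) { message("center period ", cp, " skipped: band below Nyquist"); next }
    band <- band_spec(lo, cp + half_width, dt)
    for (sig in c("akt", "erk")) {
      amp <- vapply(detr, function(s) band_amplitude(bandpass(s[[sig]], band, dt)), 0)
      ct <- stats::cor.test(amp, speeds, conf.level = 0.95)
      rows[[length(rows) + 1L]] <- data.frame(
        center = cp, signal = sig, r = unname(ct$estimate),
        ci_lo = ct$conf.int[1], ci_hi = ct$conf.int[2], n = length(amp))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Coerce supported inputs to a plain track table
#'
#' Accepts a `synth_result`, a `cell_tracks` object, or a data.frame with a
#' `track_id` or `cell_id` column.
#'
#' @param x input object.
#' @return data.frame with a `track_id` column.
#' @export
as_track_table <- function(x) {
  if (inherits(x, "synth_result")) x <- x$tracks
  if (inherits(x, "cell_tracks")) x <- x$observations
  stopifnot(is.data.frame(x))
  if (!"track_id" %in% names(x)) {
    stopifnot_cols(x, "cell_id", "track table")
    x$track_id <- x$cell_id
  }
  x
}
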