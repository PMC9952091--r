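# Aspect-ratio peak events: isolation, alignment, and polarization strata.
#
# Each aspect-ratio peak of each cell is isolated, paired with its
# preceding minimum, and aligned to time zero. The nearest detrended-ERK
# local minimum gives the signaling lag; the drop in ERK and rise in
# aspect ratio over the elongation, the nuclear polarization at the peak,
# and the normalized instantaneous speed trace complete the event record.

#' Event-detection parameters
#'
#' @param prom_min minimum peak prominence of the smoothed aspect ratio.
#' @param sep_min minimum separation between retained peaks, minutes.
#' @param smooth_frames moving-average width for peak detection, frames.
#' @param erk_window search window for the ERK minimum, minutes.
#' @param erk_smooth smoothing window applied to the detrended ERK before
#'   minima detection, minutes; set to roughly the short-wave period so
#'   short pulses do not mask the long-wave minima the aspect-ratio cycle
#'   aligns with.
#' @param window half-width of the aligned event window, minutes.
#' @return list of class `event_params`.
#' @export
event_params <- function(prom_min = 0.1, sep_min = 48, smooth_frames = 3L,
                         erk_window = 60, erk_smooth = 40, window = 60) {
  structure(list(prom_min = prom_min, sep_min = sep_min,
                 smooth_frames = as.integer(smooth_frames),
                 erk_window = erk_window, erk_smooth = erk_smooth,
                 window = window),
            class = "event_params")
}

# local maxima / minima indices of a series (strict on the right to break
# plateau ties deterministically)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}
local_minima <- function(x) local_maxima(-x)

peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- if (p > 1) x[seq_len(p - 1)] else numeric(0)
    right <- if (p < length(x)) x[(p + 1):length(x)] else numeric(0)
    base_left <- prominence_base(rev(left), h)
    base_right <- prominence_base(right, h)
    h - max(base_left, base_right)
  }, 0)
}

# lowest point between the peak and the first higher sample (or series end)
prominence_base <- function(side, h) {
  if (!length(side)) return(-Inf)
  higher <- which(side > h)
  stretch <- if (length(higher)) side[seq_len(higher[1] - 1L)] else side
  if (!length(stretch)) return(h)
  min(stretch)
}

#' Detect aspect-ratio peaks in one track
#'
#' Local maxima of the 3-frame moving-average aspect ratio with prominence
#' at least `prom_min` and mutual separation at least `sep_min` minutes;
#' each retained peak is paired with the preceding local minimum.
#'
#' @param track observation rows of one track (ordered by time).
#' @param params an [event_params()].
#' @return data.frame: `t_peak`, `idx_peak`, `t_min_prev`, `idx_min_prev`
#'   (NA when no preceding minimum exists).
#' @export
detect_ar_peaks <- function(track, params = event_params()) {
  track <- track[order(track$t_min), , drop = FALSE]
  ar <- moving_average(track$aspect_ratio, params$smooth_frames)
  t_min <- track$t_min
  peaks <- local_maxima(ar)
  if (!length(peaks)) {
    return(data.frame(t_peak = numeric(), idx_peak = integer(),
                      t_min_prev = numeric(), idx_min_prev = integer()))
  }
  prom <- peak_prominence(ar, peaks)
  peaks <- peaks[prom >= params$prom_min]
  # greedy separation: keep the most prominent peaks first
  if (length(peaks) > 1) {
    ord <- peaks[order(-ar[peaks])]
    kept <- integer(0)
    for (p in ord) {
      if (!length(kept) || all(abs(t_min[p] - t_min[kept]) >= params$sep_min)) {
        kept <- c(kept, p)
      }
    }
    peaks <- sort(kept)
  }
  mins <- local_minima(ar)
  prev_min <- vapply(peaks, function(p) {
    before <- mins[mins < p]
    if (length(before)) before[length(before)] else NA_integer_
  }, 0L)
  data.frame(t_peak = t_min[peaks], idx_peak = peaks,
             t_min_prev = ifelse(is.na(prev_min), NA_real_, t_min[prev_min]),
             idx_min_prev = prev_min)
}

#' Align events of one track
#'
#' For every aspect-ratio peak: the signed lag to the nearest detrended-ERK
#' local minimum within the search window, the ERK difference between the
#' peak time and the preceding aspect-ratio minimum time, the aspect-ratio
#' difference over the same interval, the polarization at the peak, and the
#' aligned window series (detrended ERK, aspect ratio, speed/mean-speed).
#'
#' @param track observation rows of one track.
#' @param peaks output of [detect_ar_peaks()] for the same track.
#' @param params an [event_params()].
#' @param dt sampling interval, minutes.
#' @return list: `events` data.frame and `windows` (list of matrices
#'   `erk`, `ar`, `speed_ratio`, one row per event) on `window_times`.
#' @export
align_events <- function(track, peaks, params = event_params(), dt = 4) {
  track <- track[order(track$t_min), , drop = FALSE]
  n <- nrow(track)
  erk_d <- detrend(track$erk_ktr, dt)
  # minima/differences are long-wave features: average out short pulses
  erk_s <- moving_average(as.numeric(erk_d),
                          max(1L, round(params$erk_smooth / dt)))
  ar <- track$aspect_ratio
  sp <- compute_speeds(track)
  mean_speed <- sp$mean_speed
  # instantaneous speed indexed to interval start frames
  speed_at <- rep(NA_real_, n)
  speed_at[seq_len(n - 1L)] <- sp$speed$speed
  erk_mins <- local_minima(erk_s)
  hw <- as.integer(round(params$window / dt))
  offs <- seq(-hw, hw)
  ev <- vector("list", nrow(peaks))
  win_erk <- win_ar <- win_sp <- matrix(NA_real_, nrow(peaks), length(offs))
  for (e in seq_len(nrow(peaks))) {
    p <- peaks$idx_peak[e]
    cand <- erk_mins[abs(track$t_min[erk_mins] - peaks$t_peak[e]) <= params$erk_window]
    dt_erk <- if (length(cand)) {
      lag <- track$t_min[cand] - peaks$t_peak[e]
      lag[which.min(abs(lag))]
    } else NA_real_
    pm <- peaks$idx_min_prev[e]
    d_erk <- if (!is.na(pm)) erk_s[p] - erk_s[pm] else NA_real_
    d_ar <- if (!is.na(pm)) ar[p] - ar[pm] else NA_real_
    idx <- p + offs
    valid <- idx >= 1L & idx <= n
    win_erk[e, valid] <- erk_d[idx[valid]]
    win_ar[e, valid] <- ar[idx[valid]]
    win_sp[e, valid] <- speed_at[idx[valid]] / mean_speed
    ev[[e]] <- data.frame(
      t_peak = peaks$t_peak[e], dt_erk_min = dt_erk,
      d_erk = d_erk, d_ar = d_ar,
      polarization_at_peak = track$polarization[p],
      mean_speed = mean_speed)
  }
  events <- do.call(rbind, ev)
  if (is.null(events)) {
    events <- data.frame(t_peak = numeric(), dt_erk_min = numeric(),
                         d_erk = numeric(), d_ar = numeric(),
                         polarization_at_peak = numeric(), mean_speed = numeric())
  }
  list(events = events,
       windows = list(erk = win_erk, ar = win_ar, speed_ratio = win_sp),
       window_times = offs * dt)
}

#' Detect and align events across all tracks
#'
#' @param tracks track table.
#' @param params an [event_params()].
#' @param dt sampling interval, minutes.
#' @param min_len minimum track length (frames) to analyze.
#' @return list of class `peak_events`: `events` (with `cell_id`),
#'   `windows`, `window_times`, and `n_rejected` (peaks without a usable
#'   event record).
#' @export
collect_events <- function(tracks, params = event_params(), dt = 4,
                           min_len = 60L) {
  tracks <- as_track_table(tracks)
  ids <- unique(tracks$track_id)
  evs <- list(); wins_erk <- list(); wins_ar <- list(); wins_sp <- list()
  wt <- NULL; n_rejected <- 0L
  for (id in ids) {
    d <- tracks[tracks$track_id == id, , drop = FALSE]
    if (nrow(d) < min_len) next
    pk <- detect_ar_peaks(d, params)
    if (!nrow(pk)) next
    al <- align_events(d, pk, params, dt)
    wt <- al$window_times
    ok <- is.finite(al$events$d_ar)
    n_rejected <- n_rejected + sum(!ok)
    if (!any(ok)) next
    ev <- al$events[ok, , drop = FALSE]
    ev$cell_id <- id
    evs[[length(evs) + 1L]] <- ev
    wins_erk[[length(wins_erk) + 1L]] <- al$windows$erk[ok, , drop = FALSE]
    wins_ar[[length(wins_ar) + 1L]] <- al$windows$ar[ok, , drop = FALSE]
    wins_sp[[length(wins_sp) + 1L]] <- al$windows$speed_ratio[ok, , drop = FALSE]
  }
  structure(list(events = do.call(rbind, evs),
                 windows = list(erk = do.call(rbind, wins_erk),
                                ar = do.call(rbind, wins_ar),
                                speed_ratio = do.call(rbind, wins_sp)),
                 window_times = wt, n_rejected = n_rejected),
            class = "peak_events")
}

#' Mean aligned traces for polarized vs non-polarized events
#'
#' Events are stratified at the polarization quartiles: the top stratum
#' (polarization above the `q_high` quantile) represents polarized nuclei,
#' the bottom stratum non-polarized ones. Each event's speed trace is the
#' instantaneous speed divided by the cell's overall mean speed; traces
#' are further normalized by the average of that ratio over non-polarized
#' events, so the non-polarized stratum has unit mean by construction.
#'
#' @param ev a `peak_events` object (>= 40 events).
#' @param q_low,q_high stratification quantiles.
#' @return list: `window_times`, `polarized` and `non_polarized` (each a
#'   list of mean traces `erk`, `ar`, `speed`), and stratum sizes.
#' @export
stratify_by_polarization <- function(ev, q_low = 0.25, q_high = 0.75) {
  stopifnot(inherits(ev, "peak_events"))
  events <- ev$events
  if (is.null(events) || nrow(events) < 40) stop("need at least 40 events to stratify")
  pol <- events$polarization_at_peak
  lo <- stats::quantile(pol, q_low, names = FALSE)
  hi <- stats::quantile(pol, q_high, names = FALSE)
  top <- which(pol >= hi); bottom <- which(pol <= lo)
  if (!length(top) || !length(bottom)) stop("empty polarization stratum")
  base <- mean(ev$windows$speed_ratio[bottom, , drop = FALSE], na.rm = TRUE)
  trace <- function(rows) list(
    erk = colMeans(ev$windows$erk[rows, , drop = FALSE], na.rm = TRUE),
    ar = colMeans(ev$windows$ar[rows, , drop = FALSE], na.rm = TRUE),
    speed = colMeans(ev$windows$speed_ratio[rows, , drop = FALSE], na.rm = TRUE) / base)
  list(window_times = ev$window_times,
       polarized = trace(top), non_polarized = trace(bottom),
       n_polarized = length(top), n_non_polarized = length(bottom))
}

#' Quantile regressions linking polarization to signaling and speed
#'
#' Fits (i) polarization vs ERK difference, (ii) polarization vs
#' aspect-ratio difference, and (iii) the cell's mean speed vs
#' polarization, each at the 20th/50th/80th quantiles.
#'
#' @param ev a `peak_events` object.
#' @param taus quantiles.
#' @param B bootstrap replicates passed to [quantile_regress()].
#' @param seed bootstrap seed.
#' @return named list of `quantile_fits`: `pol_vs_d_erk`, `pol_vs_d_ar`,
#'   `speed_vs_pol`.
#' @export
polarization_regressions <- function(ev, taus = c(0.2, 0.5, 0.8),
                                     B = 500L, seed = 1L) {
  stopifnot(inherits(ev, "peak_events"))
  events <- ev$events
  list(
    pol_vs_d_erk = quantile_regress(events$d_erk, events$polarization_at_peak,
                                    taus, B = B, seed = seed),
    pol_vs_d_ar = quantile_regress(events$d_ar, events$polarization_at_peak,
                                   taus, B = B, seed = seed),
    speed_vs_pol = quantile_regress(events$polarization_at_peak, events$mean_speed,
                                    taus, B = B, seed = seed))
}
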