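# Ground-truthed synthetic single-cell chemotaxis data.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: per-cell oscillatory ERK/Akt reporter signals with distinct short-
# and long-period components, aspect-ratio oscillations anti-phased with the
# long ERK component, nuclear-polarization-gated speed bursts lagging the
# aspect-ratio peaks, a per-cell amplitude-to-speed linear coupling, and
# population motion following an advection-diffusion law.

#' Configuration for the synthetic chemotaxis generator
#'
#' Units are micrometres and minutes throughout; pixels appear only at render
#' time. Defaults describe a 24 h movie at 4 min frame interval of
#' mesenchymal-like cells (minor axis ~15 um, speeds ~0.3-0.7 um/min) with a
#' 40 min short signaling wave and a 108 min long wave (the centres of the
#' 28-60 min and 92-124 min analysis bands).
#'
#' @param n_cells number of cells.
#' @param duration movie length, minutes. Must be at least `2 * long_period`.
#' @param dt frame interval, minutes.
#' @param field_size c(width, height) of the field, um.
#' @param D_true diffusivity of the random-migration component, um^2/min.
#' @param v_true advective (directed-motion) velocity c(vx, vy), um/min.
#' @param short_period,long_period periods of the two signaling waves, min.
#' @param amp_short_dist,amp_long_dist per-cell amplitude distributions;
#'   lists with `family` ("lognormal" or "constant") and parameters
#'   (`meanlog`, `sdlog` / `value`). Log-normal by default: measured
#'   amplitude distributions are right-skewed.
#' @param baseline per-cell reporter baseline, log2 cytoplasm/nucleus units.
#' @param akt_scale global scaling of Akt amplitudes relative to the draws
#'   (Akt shares phases with ERK but has independent amplitude draws).
#' @param speed_coupling c(intercept, slope_short): prescribed per-cell mean
#'   speed `intercept + slope_short * A_short` (um/min). NULL disables the
#'   coupling and leaves motion purely advective-diffusive (use this for any
#'   diffusivity-sensitive study).
#' @param ar_baseline resting aspect ratio.
#' @param ar_coupling relative coupling of the aspect-ratio oscillation to
#'   the long ERK wave: AR amplitude = `ar_coupling * A_long`, anti-phased
#'   (AR maxima at long-ERK minima).
#' @param burst_lag lag of the speed burst after an aspect-ratio peak, min.
#' @param burst_gain fractional peak height of the speed burst (0.25 = a
#'   25 percent increase over baseline speed).
#' @param burst_half_width half-width of the raised-cosine burst kernel, min.
#' @param polarization_coupling scale linking `A_long` to the nuclear
#'   polarization magnitude of polarized events.
#' @param polarized_fraction probability that any given aspect-ratio peak is
#'   a polarized event (nucleus displaced, burst fires).
#' @param polarization_baseline resting nuclear polarization.
#' @param noise_sd named vector of Gaussian noise SDs for channels
#'   `erk`, `akt`, `aspect_ratio` (signal units).
#' @param mitosis_rate per-cell division rate, events/min (0 disables).
#' @param init initial placement: "uniform" over the field (minus `margin`)
#'   or "gaussian" blob at the field centre with SD `init_sigma`.
#' @param init_sigma SD of the gaussian placement, um.
#' @param min_separation minimum initial center-to-center spacing for
#'   uniform placement, um (plated cells exclude each other).
#' @param exclusion_radius hard-core center-to-center exclusion distance
#'   maintained during motion, um; adherent cells deform rather than
#'   interpenetrate. Set 0 to realize the pure advection-diffusion law
#'   exactly (use 0 for any diffusivity-recovery study).
#' @param margin reflective boundary margin, um.
#' @param cell_area_mean,cell_area_sd per-cell area distribution, um^2.
#' @param rng_seed integer seed; fixed seed gives bit-identical output.
#' @return object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_cells = 50,
                         duration = 1440,
                         dt = 4,
                         field_size = c(560, 560),
                         D_true = 0.25,
                         v_true = c(0, 0),
                         short_period = 40,
                         long_period = 108,
                         amp_short_dist = list(family = "lognormal",
                                               meanlog = log(0.22), sdlog = 0.45),
                         amp_long_dist = list(family = "lognormal",
                                              meanlog = log(0.25), sdlog = 0.45),
                         baseline = 0.5,
                         akt_scale = 0.8,
                         speed_coupling = c(intercept = 0.2, slope_short = 1.2),
                         ar_baseline = 1.6,
                         ar_coupling = 1.0,
                         burst_lag = 20,
                         burst_gain = 0.25,
                         burst_half_width = 20,
                         polarization_coupling = 1.0,
                         polarized_fraction = 0.5,
                         polarization_baseline = 0.05,
                         noise_sd = c(erk = 0.05, akt = 0.05, aspect_ratio = 0.04),
                         mitosis_rate = 0,
                         init = c("uniform", "gaussian"),
                         init_sigma = NULL,
                         min_separation = 30,
                         exclusion_radius = 16,
                         margin = 30,
                         cell_area_mean = 500,
                         cell_area_sd = 60,
                         rng_seed = 1L) {
  init <- match.arg(init)
  cfg <- list(n_cells = as.integer(n_cells), duration = duration, dt = dt,
              field_size = field_size, D_true = D_true, v_true = v_true,
              short_period = short_period, long_period = long_period,
              amp_short_dist = amp_short_dist, amp_long_dist = amp_long_dist,
              baseline = baseline, akt_scale = akt_scale,
              speed_coupling = speed_coupling,
              ar_baseline = ar_baseline, ar_coupling = ar_coupling,
              burst_lag = burst_lag, burst_gain = burst_gain,
              burst_half_width = burst_half_width,
              polarization_coupling = polarization_coupling,
              polarized_fraction = polarized_fraction,
              polarization_baseline = polarization_baseline,
              noise_sd = noise_sd, mitosis_rate = mitosis_rate,
              init = init, init_sigma = init_sigma,
              min_separation = min_separation,
              exclusion_radius = exclusion_radius, margin = margin,
              cell_area_mean = cell_area_mean, cell_area_sd = cell_area_sd,
              rng_seed = as.integer(rng_seed))
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$dt <= 0) stop("dt must be > 0")
  if (cfg$duration < 2 * cfg$long_period) {
    stop("duration must be at least 2 * long_period; the long band is unresolvable otherwise")
  }
  if (cfg$n_cells < 0) stop("n_cells must be >= 0")
  if (cfg$D_true < 0) stop("D_true must be >= 0")
  scales <- c(cfg$ar_coupling, cfg$burst_gain, cfg$polarization_coupling,
              cfg$noise_sd, cfg$mitosis_rate, cfg$polarization_baseline)
  if (any(scales < 0)) stop("all scale parameters must be >= 0")
  if (cfg$short_period >= cfg$long_period) stop("short_period must be < long_period")
  if (cfg$short_period <= 2 * cfg$dt) stop("short_period must exceed 2 * dt (Nyquist)")
  invisible(cfg)
}

draw_amplitudes <- function(dist, n) {
  switch(dist$family,
         lognormal = rlnorm(n, dist$meanlog, dist$sdlog),
         constant = rep(dist$value, n),
         stop("unknown amplitude distribution family: ", dist$family))
}

#' Generate ground-truthed synthetic cell tracks
#'
#' Produces a track table (one row per cell per frame) together with the
#' ground truth used to create it. Positions follow
#' `x[t+dt] = x[t] + v*dt + sqrt(2*D*dt)*eta` with standard-normal `eta`;
#' the reporter signals are sums of a long and a short sinusoid with
#' per-cell amplitudes and phases; the aspect ratio oscillates anti-phased
#' with the long ERK component; polarized aspect-ratio peaks carry a
#' raised-cosine speed burst lagging the peak.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_result` with elements `tracks` (data.frame
#'   with columns cell_id, frame, t_min, x_um, y_um, nuc_x_um, nuc_y_um,
#'   erk_ktr, akt_ktr, aspect_ratio, polarization plus morphology columns
#'   used by the renderer) and `truth` (per-cell parameters, per-event
#'   peak table, motion parameters, mitosis events, config).
#' @export
generate_tracks <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  with_seed(config$rng_seed, generate_tracks_impl(config))
}

generate_tracks_impl <- function(cfg) {
  n <- cfg$n_cells
  t_min <- seq(0, cfg$duration - cfg$dt, by = cfg$dt)
  nt <- length(t_min)
  empty <- data.frame(cell_id = integer(), frame = integer(), t_min = numeric(),
                      x_um = numeric(), y_um = numeric(),
                      nuc_x_um = numeric(), nuc_y_um = numeric(),
                      erk_ktr = numeric(), akt_ktr = numeric(),
                      aspect_ratio = numeric(), polarization = numeric(),
                      major_um = numeric(), minor_um = numeric(),
                      orientation = numeric(), area_um2 = numeric())
  if (n == 0L) {
    return(structure(list(tracks = empty,
                          truth = list(cells = NULL, peaks = NULL,
                                       D = cfg$D_true, v = cfg$v_true,
                                       mitosis = NULL, config = cfg)),
                     class = "synth_result"))
  }

  cells <- data.frame(
    cell_id = seq_len(n),
    A_short_erk = draw_amplitudes(cfg$amp_short_dist, n),
    A_long_erk = draw_amplitudes(cfg$amp_long_dist, n),
    A_short_akt = cfg$akt_scale * draw_amplitudes(cfg$amp_short_dist, n),
    A_long_akt = cfg$akt_scale * draw_amplitudes(cfg$amp_long_dist, n),
    phase_long = runif(n, 0, 2 * pi),
    phase_short = runif(n, 0, 2 * pi),
    area_um2 = pmax(rnorm(n, cfg$cell_area_mean, cfg$cell_area_sd), 150)
  )
  cells$ar_amp <- cfg$ar_coupling * cells$A_long_erk
  cells$target_speed <- if (is.null(cfg$speed_coupling)) NA_real_ else {
    cfg$speed_coupling[["intercept"]] +
      cfg$speed_coupling[["slope_short"]] * cells$A_short_erk
  }

  # initial placement
  fw <- cfg$field_size[1]; fh <- cfg$field_size[2]; mg <- cfg$margin
  if (cfg$init == "uniform") {
    # plated cells exclude each other: rejection-sample a minimum spacing
    x0 <- numeric(n); y0 <- numeric(n)
    for (c in seq_len(n)) {
      for (try in 1:200) {
        xc <- runif(1, mg, fw - mg); yc <- runif(1, mg, fh - mg)
        if (c == 1L ||
            min((x0[seq_len(c - 1L)] - xc)^2 + (y0[seq_len(c - 1L)] - yc)^2) >=
              cfg$min_separation^2) break
      }
      x0[c] <- xc; y0[c] <- yc
    }
  } else {
    sigma <- cfg$init_sigma %||% (min(fw, fh) / 8)
    x0 <- rnorm(n, fw / 2, sigma); y0 <- rnorm(n, fh / 2, sigma)
  }

  omega_l <- 2 * pi / cfg$long_period
  omega_s <- 2 * pi / cfg$short_period

  # True aspect-ratio peak times of cell c: maxima of
  # sin(omega_l * t + phase_long + pi), i.e. omega_l*t + phase + pi = pi/2 + 2*pi*k.
  peak_list <- lapply(seq_len(n), function(c) {
    t1 <- ((pi / 2 - cells$phase_long[c] - pi) %% (2 * pi)) / omega_l
    tp <- seq(t1, cfg$duration, by = cfg$long_period)
    tp <- tp[tp >= 0 & tp < cfg$duration]
    if (!length(tp)) return(NULL)
    data.frame(cell_id = c, t_peak = tp)
  })
  peaks <- do.call(rbind, peak_list)
  peaks$polarized <- runif(nrow(peaks)) < cfg$polarized_fraction
  # polarization is graded: non-polarized peaks still show a weak coupling
  # to the long-wave amplitude, polarized peaks the full one
  peaks$pol_mag <- cfg$polarization_baseline +
    ifelse(peaks$polarized, 1, 0.15) *
      cfg$polarization_coupling * cells$A_long_erk[peaks$cell_id]

  noise <- function(name) {
    sd <- if (name %in% names(cfg$noise_sd)) cfg$noise_sd[[name]] else 0
    if (sd > 0) rnorm(nt, 0, sd) else numeric(nt)
  }

  # mitosis event times (optional)
  mitosis <- NULL
  if (cfg$mitosis_rate > 0) {
    n_div <- rpois(n, cfg$mitosis_rate * cfg$duration)
    div_cell <- which(n_div > 0)
    if (length(div_cell)) {
      mitosis <- data.frame(cell_id = div_cell,
                            t_div = runif(length(div_cell),
                                          0.25 * cfg$duration, 0.9 * cfg$duration),
                            frame_div = NA_integer_)
    }
  }

  rows <- vector("list", n)
  next_id <- n + 1L
  mito_rows <- list()
  sig_erk <- sig_akt <- sig_ar <- sig_pol <- matrix(NA_real_, nt, n)
  step_x <- step_y <- matrix(0, nt - 1L, n)
  orient_all <- matrix(0, nt, n)
  for (c in seq_len(n)) {
    erk <- cfg$baseline +
      cells$A_long_erk[c] * sin(omega_l * t_min + cells$phase_long[c]) +
      cells$A_short_erk[c] * sin(omega_s * t_min + cells$phase_short[c]) +
      noise("erk")
    akt <- cfg$baseline +
      cells$A_long_akt[c] * sin(omega_l * t_min + cells$phase_long[c]) +
      cells$A_short_akt[c] * sin(omega_s * t_min + cells$phase_short[c]) +
      noise("akt")
    ar <- cfg$ar_baseline +
      cells$ar_amp[c] * sin(omega_l * t_min + cells$phase_long[c] + pi) +
      noise("aspect_ratio")
    ar <- clamp(ar, lo = 1.02)

    pk <- peaks[peaks$cell_id == c, , drop = FALSE]

    # polarization trace: raised-cosine bumps around each peak
    pol <- rep(cfg$polarization_baseline, nt)
    if (nrow(pk)) {
      for (e in seq_len(nrow(pk))) {
        bump <- raised_cosine(t_min - pk$t_peak[e], cfg$long_period / 4)
        pol <- pol + (pk$pol_mag[e] - cfg$polarization_baseline) * bump
      }
    }
    pol <- clamp(pol, lo = 0)

    # burst factor on instantaneous speed, lagging polarized peaks
    burst <- rep(1, nt)
    if (nrow(pk) && cfg$burst_gain > 0) {
      for (e in which(pk$polarized)) {
        burst <- burst + cfg$burst_gain *
          raised_cosine(t_min - pk$t_peak[e] - cfg$burst_lag, cfg$burst_half_width)
      }
    }

    # motion: advection + scaled diffusion, burst-modulated steps
    step_sd <- sqrt(2 * cfg$D_true * cfg$dt)
    dx <- rnorm(nt - 1L, 0, step_sd)
    dy <- rnorm(nt - 1L, 0, step_sd)
    if (!is.null(cfg$speed_coupling)) {
      # rescale by the realized mean step length so the cell's mean
      # instantaneous speed equals its prescribed target exactly
      realized <- mean(sqrt(dx^2 + dy^2)) / cfg$dt
      scl <- cells$target_speed[c] / realized
      dx <- dx * scl; dy <- dy * scl
    }
    step_x[, c] <- (dx + cfg$v_true[1] * cfg$dt) * burst[-nt]
    step_y[, c] <- (dy + cfg$v_true[2] * cfg$dt) * burst[-nt]
    sig_erk[, c] <- erk; sig_akt[, c] <- akt
    sig_ar[, c] <- ar; sig_pol[, c] <- pol
    orient_all[, c] <- (cumsum(rnorm(nt, 0, 0.05)) + runif(1, 0, pi)) %% pi
  }

  # joint position simulation: step, resolve hard-core overlaps, reflect
  xs <- ys <- matrix(NA_real_, nt, n)
  xs[1, ] <- x0; ys[1, ] <- y0
  excl <- cfg$exclusion_radius
  for (f in seq_len(nt - 1L)) {
    xn <- xs[f, ] + step_x[f, ]
    yn <- ys[f, ] + step_y[f, ]
    if (excl > 0 && n > 1L) {
      for (iter in 1:3) {
        dmat <- as.matrix(dist(cbind(xn, yn)))
        dmat[lower.tri(dmat, diag = TRUE)] <- Inf
        hit <- which(dmat < excl, arr.ind = TRUE)
        if (!nrow(hit)) break
        for (r in seq_len(nrow(hit))) {
          i <- hit[r, 1]; j <- hit[r, 2]
          ddx <- xn[j] - xn[i]; ddy <- yn[j] - yn[i]
          dd <- sqrt(ddx^2 + ddy^2)
          if (dd < 1e-9) { ddx <- 1; ddy <- 0; dd <- 1 }
          push <- (excl - dd) / 2
          xn[i] <- xn[i] - push * ddx / dd; yn[i] <- yn[i] - push * ddy / dd
          xn[j] <- xn[j] + push * ddx / dd; yn[j] <- yn[j] + push * ddy / dd
        }
      }
    }
    xs[f + 1L, ] <- reflect_into(xn, mg, fw - mg)
    ys[f + 1L, ] <- reflect_into(yn, mg, fh - mg)
  }

  for (c in seq_len(n)) {
    erk <- sig_erk[, c]; akt <- sig_akt[, c]
    ar <- sig_ar[, c]; pol <- sig_pol[, c]
    x <- xs[, c]; y <- ys[, c]
    # ellipse geometry; orientation drifts slowly
    minor <- sqrt(4 * cells$area_um2[c] / (pi * ar))
    major <- ar * minor
    orient <- orient_all[, c]

    # nucleus offset along the direction of motion, scaled by polarization
    ux <- c(diff(x), utils::tail(diff(x), 1))
    uy <- c(diff(y), utils::tail(diff(y), 1))
    nrm <- sqrt(ux^2 + uy^2)
    ok <- nrm > 1e-12
    ux[ok] <- ux[ok] / nrm[ok]; uy[ok] <- uy[ok] / nrm[ok]
    ux[!ok] <- 1; uy[!ok] <- 0
    nuc_x <- x + pol * minor * ux
    nuc_y <- y + pol * minor * uy

    df <- data.frame(cell_id = c, frame = seq_len(nt) - 1L, t_min = t_min,
                     x_um = x, y_um = y, nuc_x_um = nuc_x, nuc_y_um = nuc_y,
                     erk_ktr = erk, akt_ktr = akt, aspect_ratio = ar,
                     polarization = pol, major_um = major, minor_um = minor,
                     orientation = orient, area_um2 = cells$area_um2[c])

    # optional mitosis: truncate parent at division, spawn two daughters
    if (!is.null(mitosis) && c %in% mitosis$cell_id) {
      t_div <- mitosis$t_div[match(c, mitosis$cell_id)]
      f_div <- findInterval(t_div, t_min)
      if (f_div > 4L && f_div < nt - 4L) {
        parent <- df[seq_len(f_div), , drop = FALSE]
        after <- df[(f_div + 1L):nt, , drop = FALSE]
        for (side in c(-1, 1)) {
          dgt <- after
          dgt$cell_id <- next_id
          dgt$x_um <- dgt$x_um + side * 6
          dgt$nuc_x_um <- dgt$nuc_x_um + side * 6
          dgt$area_um2 <- dgt$area_um2 / 2
          dgt$minor_um <- dgt$minor_um / sqrt(2)
          dgt$major_um <- dgt$major_um / sqrt(2)
          mito_rows[[length(mito_rows) + 1L]] <- dgt
          next_id <- next_id + 1L
        }
        mitosis$frame_div[match(c, mitosis$cell_id)] <- f_div - 1L
        df <- parent
      }
    }
    rows[[c]] <- df
  }
  tracks <- do.call(rbind, c(rows, mito_rows))
  rownames(tracks) <- NULL

  structure(list(tracks = tracks,
                 truth = list(cells = cells, peaks = peaks,
                              D = cfg$D_true, v = cfg$v_true,
                              mitosis = mitosis, config = cfg)),
            class = "synth_result")
}

# Reflect coordinates into [lo, hi] (handles multiple bounces).
reflect_into <- function(x, lo, hi) {
  if (hi <= lo) stop("empty reflection interval")
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  y <- ifelse(y > span, 2 * span - y, y)
  y + lo
}
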