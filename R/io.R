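# Track-table I/O and the end-to-end pipeline runner.

TRACK_COLUMNS <- c("cell_id", "frame", "t_min", "x_um", "y_um",
                   "nuc_x_um", "nuc_y_um", "erk_ktr", "akt_ktr",
                   "aspect_ratio", "polarization")

#' Write a track table to CSV
#'
#' Numeric columns are written with 17 significant digits so a write/read
#' round trip is lossless; unit annotations go into `#` header comments.
#'
#' @param tracks track table (data.frame).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(is.data.frame(tracks))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# chemotaxr track table",
               "# units: positions um, time min, KTR log2 cytoplasm/nucleus",
               "# frames are 0-based"), con)
  fmt <- vapply(tracks, function(col) {
    if (is.numeric(col) && !is.integer(col)) sprintf("%.17g", col)
    else as.character(col)
  }, character(nrow(tracks)))
  if (nrow(tracks) == 1L) fmt <- matrix(fmt, nrow = 1L)
  writeLines(paste(names(tracks), collapse = ","), con)
  if (nrow(tracks)) writeLines(apply(fmt, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Read a track table from CSV
#'
#' @param path CSV path (comment lines starting with `#` are skipped).
#' @param one_based set TRUE for tables from tools using 1-based frame
#'   numbers; frames are converted to the package's 0-based convention.
#' @return data.frame; empty files yield an empty table with a warning.
#' @export
read_tracks <- function(path, one_based = FALSE) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!nrow(df)) {
    warning("empty track file: ", path)
    return(df)
  }
  stopifnot_cols(df, c("cell_id", "frame", "t_min", "x_um", "y_um"), "track file")
  if (one_based) df$frame <- df$frame - 1L
  # uniform sampling check per track
  for (id in unique(df$cell_id)) {
    tt <- sort(df$t_min[df$cell_id == id])
    if (length(tt) > 1) {
      dts <- diff(tt)
      base <- min(dts)
      if (any(abs(dts / base - round(dts / base)) > 1e-6)) {
        stop("non-uniform frame interval in track for cell_id ", id)
      }
    }
  }
  df
}

#' Default pipeline configuration
#'
#' Bundles the stage parameters of a full synthetic-study run. Any element
#' can be overridden; a YAML file with the same structure can be loaded
#' with [read_pipeline_config()].
#'
#' @param synth a [synth_config()].
#' @param dt frame interval, minutes (taken from `synth`).
#' @param taus regression quantiles.
#' @param bootstrap_B bootstrap replicates for regression inference.
#' @param gradient_axis chemoattractant gradient direction.
#' @param vsi_h,vsi_sigma,vsi_dt_agg density-field grid spacing, smoothing
#'   bandwidth (um) and temporal aggregation (min).
#' @param seed master seed for every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(), dt = synth$dt,
                            taus = c(0.2, 0.5, 0.8), bootstrap_B = 200L,
                            gradient_axis = c(1, 0),
                            vsi_h = 25, vsi_sigma = 50, vsi_dt_agg = 20,
                            seed = 1L) {
  structure(list(synth = synth, dt = dt, taus = taus,
                 bootstrap_B = as.integer(bootstrap_B),
                 gradient_axis = gradient_axis, vsi_h = vsi_h,
                 vsi_sigma = vsi_sigma, vsi_dt_agg = vsi_dt_agg,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected so typos do not silently fall back to
#' defaults.
#'
#' @param path YAML file; top-level key `synth` holds [synth_config()]
#'   arguments, the remaining keys are [pipeline_config()] arguments.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  synth_args <- raw$synth %||% list()
  unknown <- setdiff(names(synth_args), names(formals(synth_config)))
  if (length(unknown)) stop("unknown synth config key(s): ", paste(unknown, collapse = ", "))
  other <- raw[setdiff(names(raw), "synth")]
  unknown <- setdiff(names(other), names(formals(pipeline_config)))
  if (length(unknown)) stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(synth_args$v_true)) synth_args$v_true <- as.numeric(synth_args$v_true)
  if (!is.null(synth_args$field_size)) synth_args$field_size <- as.numeric(synth_args$field_size)
  do.call(pipeline_config, c(list(synth = do.call(synth_config, synth_args)), other))
}

#' Run the full synthetic-study pipeline
#'
#' simulate -> band amplitudes -> heterogeneity statistics -> aspect-ratio
#' peak events -> motility inference -> report. All artifacts are plain
#' CSV/JSON and are reproducible from the configuration seed alone.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param stages subset of c("simulate", "oscillate", "stats", "events",
#'   "vsi", "report") to run; earlier stage outputs must exist in
#'   `out_dir` for later stages.
#' @return invisibly, the report list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = c("simulate", "oscillate", "stats",
                                    "events", "vsi", "report")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dt <- config$dt
  report <- list(seed = config$seed)
  tracks_path <- file.path(out_dir, "tracks.csv")
  amp_path <- file.path(out_dir, "amplitudes.csv")

  if ("simulate" %in% stages) {
    cfg <- config$synth
    cfg$rng_seed <- config$seed
    sim <- generate_tracks(cfg)
    write_tracks(sim$tracks, tracks_path)
  }
  if (!file.exists(tracks_path)) {
    stop("missing upstream artifact tracks.csv: run the 'simulate' stage first")
  }
  tracks <- read_tracks(tracks_path)

  amp <- NULL
  if ("oscillate" %in% stages) {
    amp <- band_amplitudes(tracks, default_bands(dt), dt)
    utils::write.csv(amp, amp_path, row.names = FALSE)
  }
  if (any(c("stats", "report") %in% stages) && is.null(amp) && file.exists(amp_path)) {
    amp <- utils::read.csv(amp_path)
  }

  if ("stats" %in% stages) {
    if (is.null(amp)) stop("missing upstream artifact amplitudes.csv: run the 'oscillate' stage first")
    vars <- c("akt_short", "erk_short", "akt_long", "erk_long", "ar_amp")
    fits <- lapply(vars, function(v) {
      f <- quantile_regress(amp[[v]], amp$mean_speed, config$taus,
                            B = config$bootstrap_B, seed = config$seed)
      as.list(f[f$tau == 0.5, c("slope", "intercept", "slope_se", "p_value")])
    })
    names(fits) <- vars
    report$speed_regressions <- fits
    report$top_quartile <- lapply(stats::setNames(vars, vars), function(v) {
      top_quartile_proportion(amp$mean_speed, amp[[v]])
    })
    ph <- polar_histogram(tracks, gradient_axis = config$gradient_axis)
    report$polar_histogram <- as.integer(ph)
  }

  if ("events" %in% stages) {
    ev <- collect_events(tracks, dt = dt)
    utils::write.csv(ev$events, file.path(out_dir, "events.csv"), row.names = FALSE)
    report$n_events <- nrow(ev$events)
    if (!is.null(ev$events) && nrow(ev$events) >= 40) {
      strat <- stratify_by_polarization(ev)
      peak_i <- which.max(strat$polarized$speed)
      report$burst <- list(
        lag_min = strat$window_times[peak_i],
        height = max(strat$polarized$speed),
        baseline = mean(strat$non_polarized$speed, na.rm = TRUE))
      report$median_erk_lag_min = stats::median(ev$events$dt_erk_min, na.rm = TRUE)
    }
  }

  if ("vsi" %in% stages) {
    den <- build_density(tracks, config$synth$field_size, h = config$vsi_h,
                         sigma = config$vsi_sigma, dt_agg = config$vsi_dt_agg)
    fit <- infer_motility(den, config$gradient_axis)
    report$motility <- list(D = fit$D, v_par = fit$v_par, v_perp = fit$v_perp,
                            residual = fit$residual, condition = fit$condition)
  }

  if ("report" %in% stages) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
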