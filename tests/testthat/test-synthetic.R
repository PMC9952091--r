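# Ground-truthed generator: determinism, analytic signal recovery, and the
# Brownian / advective motion statistics downstream inference relies on.

test_that("fixed seed gives bit-identical tracks, different seeds differ", {
  cfg <- synth_config(n_cells = 6, duration = 400, rng_seed = 11)
  s1 <- generate_tracks(cfg)
  s2 <- generate_tracks(cfg)
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$truth$cells, s2$truth$cells)
  cfg2 <- synth_config(n_cells = 6, duration = 400, rng_seed = 12)
  expect_false(identical(generate_tracks(cfg2)$tracks, s1$tracks))
})

test_that("config invariants are enforced", {
  expect_error(synth_config(duration = 150), "2 \\* long_period")
  expect_error(synth_config(dt = 0), "dt")
  expect_error(synth_config(short_period = 120, long_period = 108), "short_period")
  expect_error(synth_config(burst_gain = -1), ">= 0")
})

test_that("noise-free signals equal their analytic definitions at sample times", {
  cfg <- quiet_config(n_cells = 4, duration = 400, rng_seed = 3)
  sim <- generate_tracks(cfg)
  cells <- sim$truth$cells
  for (c in cells$cell_id) {
    d <- sim$tracks[sim$tracks$cell_id == c, ]
    t <- d$t_min
    erk_expect <- cfg$baseline +
      cells$A_long_erk[c] * sin(2 * pi * t / cfg$long_period + cells$phase_long[c]) +
      cells$A_short_erk[c] * sin(2 * pi * t / cfg$short_period + cells$phase_short[c])
    expect_equal(d$erk_ktr, erk_expect, tolerance = 1e-12)
    ar_expect <- pmax(cfg$ar_baseline + cfg$ar_coupling * cells$A_long_erk[c] *
                        sin(2 * pi * t / cfg$long_period + cells$phase_long[c] + pi), 1.02)
    expect_equal(d$aspect_ratio, ar_expect, tolerance = 1e-12)
  }
})

test_that("a noise-free unit short tone yields unit band amplitude in every cell", {
  cfg <- quiet_config(n_cells = 5, rng_seed = 2,
                      amp_short_dist = list(family = "constant", value = 1),
                      amp_long_dist = list(family = "constant", value = 0))
  sim <- generate_tracks(cfg)
  for (c in unique(sim$tracks$cell_id)) {
    erk <- detrend(sim$tracks$erk_ktr[sim$tracks$cell_id == c], cfg$dt)
    amp <- band_amplitude(bandpass(erk, band_spec(28, 60), cfg$dt))
    expect_equal(amp, 1, tolerance = 0.03)
    leak <- band_amplitude(bandpass(erk, band_spec(92, 124), cfg$dt))
    expect_lt(leak, 0.05)
  }
})

test_that("free Brownian motion reproduces the closed-form MSD and drift", {
  cfg <- quiet_config(n_cells = 500, duration = 260, D_true = 1,
                      v_true = c(0, 0), speed_coupling = NULL,
                      exclusion_radius = 0, init = "gaussian",
                      field_size = c(3000, 3000), init_sigma = 100,
                      rng_seed = 8)
  tr <- generate_tracks(cfg)$tracks
  p0 <- tr[tr$frame == 0, ]; p1 <- tr[tr$frame == 50, ]
  msd <- mean((p1$x_um - p0$x_um)^2 + (p1$y_um - p0$y_um)^2)
  t_el <- 50 * cfg$dt
  expected <- 4 * cfg$D_true * t_el
  se <- stats::sd((p1$x_um - p0$x_um)^2 + (p1$y_um - p0$y_um)^2) / sqrt(nrow(p0))
  expect_lt(abs(msd - expected), 3 * se)

  cfg_v <- quiet_config(n_cells = 500, duration = 260, D_true = 0.25,
                        v_true = c(0.1, -0.05), speed_coupling = NULL,
                        exclusion_radius = 0, init = "gaussian",
                        field_size = c(3000, 3000), init_sigma = 100,
                        rng_seed = 9)
  trv <- generate_tracks(cfg_v)$tracks
  q0 <- trv[trv$frame == 0, ]; q1 <- trv[trv$frame == 50, ]
  for (ax in 1:2) {
    col <- c("x_um", "y_um")[ax]
    drift <- mean(q1[[col]] - q0[[col]])
    se_d <- stats::sd(q1[[col]] - q0[[col]]) / sqrt(nrow(q0))
    expect_lt(abs(drift - cfg_v$v_true[ax] * t_el), 3 * se_d)
  }
})

test_that("prescribed per-cell mean speed is realized", {
  cfg <- quiet_config(n_cells = 30, duration = 400, rng_seed = 5,
                      speed_coupling = c(intercept = 0.2, slope_short = 1.2))
  sim <- generate_tracks(cfg)
  truth <- sim$truth$cells
  for (c in sample(truth$cell_id, 10)) {
    ms <- compute_speeds(sim$tracks[sim$tracks$cell_id == c, ])$mean_speed
    expect_equal(ms, truth$target_speed[c], tolerance = 0.04)
  }
})

test_that("hard-core exclusion keeps cell centers separated", {
  cfg <- synth_config(n_cells = 40, duration = 400, rng_seed = 6)
  tr <- generate_tracks(cfg)$tracks
  for (f in c(0, 50, 99)) {
    p <- tr[tr$frame == f, ]
    d <- as.matrix(dist(cbind(p$x_um, p$y_um)))
    diag(d) <- Inf
    expect_gte(min(d), cfg$exclusion_radius - 1e-9)
  }
})

test_that("mitosis ground truth is consistent with emitted tracks", {
  cfg <- synth_config(n_cells = 10, rng_seed = 4, mitosis_rate = 1 / 1500)
  sim <- generate_tracks(cfg)
  mito <- sim$truth$mitosis
  done <- mito[!is.na(mito$frame_div), ]
  expect_gt(nrow(done), 0)
  for (k in seq_len(nrow(done))) {
    par <- sim$tracks[sim$tracks$cell_id == done$cell_id[k], ]
    expect_equal(max(par$frame), done$frame_div[k])
  }
  # identity labels unique per (cell, frame)
  expect_false(any(duplicated(sim$tracks[, c("cell_id", "frame")])))
})

test_that("empty and degenerate configurations behave", {
  sim0 <- generate_tracks(synth_config(n_cells = 0))
  expect_identical(nrow(sim0$tracks), 0L)
})
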