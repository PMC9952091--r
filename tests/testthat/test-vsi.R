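# Density-field construction and weak-form advection-diffusion inference.

test_that("density fields conserve mass and reject degenerate input", {
  tk <- data.frame(track_id = 1L, frame = 0:9, t_min = seq(0, 36, 4),
                   x_um = 200, y_um = 200)
  den <- build_density(tk, c(400, 400), h = 20, sigma = 40, dt_agg = 12)
  expect_true(all(abs(integrate_density(den) - 1) < 0.01))
  expect_error(build_density(tk[tk$frame < 2, ], c(400, 400)), "3 frames")
})

test_that("a uniform plating smooths to a low-variation field", {
  set.seed(2)
  n <- 1000
  tk <- data.frame(track_id = rep(1:n, each = 3), frame = rep(0:2, n),
                   t_min = rep(c(0, 4, 8), n),
                   x_um = rep(runif(n, 0, 800), each = 3),
                   y_um = rep(runif(n, 0, 800), each = 3))
  den <- build_density(tk, c(800, 800), h = 20, sigma = 80, dt_agg = 12)
  m <- den$frames[[1]]
  core <- m[6:35, 6:35]  # away from boundary smoothing loss
  expect_lt(stats::sd(core) / mean(core), 0.2)
})

test_that("weak form recovers closed-form diffusion and advection", {
  fd <- diffusing_gaussian_field(D = 1)
  f <- infer_motility(fd)
  expect_equal(f$D, 1, tolerance = 0.05)
  expect_lt(sqrt(f$v_x^2 + f$v_y^2), 0.01)
  expect_false(f$model_inadequate)

  fa <- translating_gaussian_field(v = 0.05)
  f2 <- infer_motility(fa)
  expect_equal(f2$v_par, 0.05, tolerance = 0.1)
  expect_lt(abs(f2$v_perp), 0.005)

  # gradient axis rotation maps the same speed into (v_par, v_perp)
  f3 <- infer_motility(fa, gradient_axis = c(0, 1))
  expect_equal(f3$v_perp, -0.05, tolerance = 0.01)
  expect_lt(abs(f3$v_par), 0.005)
})

test_that("spatially uniform density is rejected as uninformative", {
  x <- seq(0, 120, 10)
  frames <- lapply(1:4, function(i) matrix(1, 13, 13))
  df <- density_field(x, x, times = seq(0, 60, 20), frames = frames)
  expect_error(infer_motility(df), "uninformative|rank-deficient")
})

test_that("inference is invariant to track translation by a grid period", {
  cfg <- quiet_config(n_cells = 400, duration = 240, D_true = 1,
                      v_true = c(0.05, 0), speed_coupling = NULL,
                      exclusion_radius = 0, init = "gaussian",
                      init_sigma = 60, field_size = c(800, 800), rng_seed = 5)
  sim <- generate_tracks(cfg)
  den1 <- build_density(sim$tracks, c(800, 800), h = 20, sigma = 40)
  tr2 <- sim$tracks
  tr2$x_um <- tr2$x_um + 40; tr2$y_um <- tr2$y_um - 20
  den2 <- build_density(tr2, c(800, 800), h = 20, sigma = 40)
  f1 <- infer_motility(den1); f2 <- infer_motility(den2)
  expect_equal(f1$D, f2$D, tolerance = 0.02)
  expect_equal(f1$v_par, f2$v_par, tolerance = 0.02)
})

test_that("weak-form estimates converge with grid and time refinement", {
  errs <- vapply(c(8, 4, 2), function(h) {
    fd <- diffusing_gaussian_field(D = 1, h = h, half = 64,
                                   times = seq(50, 100, length.out = 3 * 8 / h))
    abs(infer_motility(fd)$D - 1)
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("weak form agrees with a strong-form finite-difference oracle", {
  strong_form_fit <- function(df) {
    nx <- length(df$x); ny <- length(df$y); h <- df$h
    X <- NULL; Y <- NULL
    for (p in seq_len(length(df$frames) - 1)) {
      dtp <- df$times[p + 1] - df$times[p]
      rb <- (df$frames[[p]] + df$frames[[p + 1]]) / 2
      dr <- (df$frames[[p + 1]] - df$frames[[p]]) / dtp
      i <- 3:(nx - 2); j <- 3:(ny - 2)
      lap <- (rb[i + 1, j] + rb[i - 1, j] + rb[i, j + 1] + rb[i, j - 1] -
                4 * rb[i, j]) / h^2
      gx <- (rb[i + 1, j] - rb[i - 1, j]) / (2 * h)
      gy <- (rb[i, j + 1] - rb[i, j - 1]) / (2 * h)
      X <- rbind(X, cbind(as.vector(lap), -as.vector(gx), -as.vector(gy)))
      Y <- c(Y, as.vector(dr[i, j]))
    }
    stats::lm.fit(X, Y)$coefficients
  }
  fd <- diffusing_gaussian_field(D = 1)
  weak <- infer_motility(fd)
  strong <- strong_form_fit(fd)
  expect_equal(weak$D, strong[1], tolerance = 0.1, ignore_attr = TRUE)
  fa <- translating_gaussian_field(v = 0.05)
  expect_equal(infer_motility(fa)$v_x,
               strong_form_fit(fa)[2], tolerance = 0.1, ignore_attr = TRUE)
})

test_that("backward elimination keeps only the operating mechanisms", {
  fd <- diffusing_gaussian_field(D = 1)
  sel <- select_terms(fd)
  expect_identical(sel$active, "diffusion")
  fa <- translating_gaussian_field(v = 0.05)
  sel2 <- select_terms(fa)
  expect_true("advection_x" %in% sel2$active)
  expect_false("advection_y" %in% sel2$active)
  # infinite tolerance never eliminates
  sel3 <- select_terms(fd, tol = Inf)
  expect_setequal(sel3$active, c("diffusion", "advection_x", "advection_y"))
})

test_that("drug-vs-control normalization applies the ratio formulas", {
  ctrl <- structure(list(D = 1, v_x = 0.05, v_y = 0.01, v_par = 0.05,
                         v_perp = 0.01, residual = 0, rss = 0, condition = 1,
                         n_equations = 10, model_inadequate = FALSE),
                    class = "motility_params")
  expect_equal(unclass(normalize_conditions(ctrl, ctrl))[1:2],
               list(normalized_random_migration = 1,
                    normalized_directed_motion = 1))
  half <- ctrl; half$D <- 0.5
  nm <- normalize_conditions(half, ctrl)
  expect_equal(nm$normalized_random_migration, 0.5)
  expect_equal(nm$normalized_directed_motion, 1)
  # no directed motion in control: ratio flagged undefined
  still <- ctrl; still$v_par <- 0; still$v_perp <- 0
  nd <- normalize_conditions(half, still)
  expect_true(is.na(nd$normalized_directed_motion))
  expect_false(nd$directed_motion_defined)
})
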