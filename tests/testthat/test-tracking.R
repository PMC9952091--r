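# Assignment solver, frame linking, gap closing, mitosis, and speeds.

test_that("assignment solver equals exhaustive matching", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(2:7, 1)
    cost <- matrix(runif(n * n), n)
    if (rep %% 3 == 0) cost[sample(n * n, n)] <- 1e9  # forbidden-like entries
    a <- solve_assignment(cost)
    oracle <- brute_force_assignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), a)]), oracle$cost, tolerance = 1e-12)
  }
})

test_that("a single slow cell yields one full-length track", {
  cfg <- quiet_config(n_cells = 1, duration = 400, rng_seed = 2)
  obs <- generate_tracks(cfg)$tracks
  obs$cell_id <- NULL
  tr <- build_tracks(obs)
  expect_equal(tr$stats$n_tracks, 1L)
  expect_equal(nrow(tr$observations), 100L)
  expect_identical(tr$tracks$ended_by, "end_of_movie")
})

test_that("crossing cells keep identity through the morphology term", {
  # two cells swap proximity; pure distance would mis-link, the 2x area
  # difference resolves it (verified against exhaustive assignment)
  obs_a <- data.frame(frame = 0L, t_min = 0,
                      x_um = c(0, 16), y_um = c(0, 0),
                      nuc_x_um = c(0, 16), nuc_y_um = c(0, 0),
                      area_um2 = c(200, 400))
  obs_b <- data.frame(frame = 1L, t_min = 4,
                      x_um = c(12, 4), y_um = c(0, 0),
                      nuc_x_um = c(12, 4), nuc_y_um = c(0, 0),
                      area_um2 = c(210, 395))
  res <- link_frames(obs_a, obs_b)
  # detection 1 (area 210) belongs to cell 1 (area 200); a distance-only
  # cost would prefer the swapped matching
  expect_equal(res$pairs$j[res$pairs$i == 1], 1L)
  expect_equal(res$pairs$j[res$pairs$i == 2], 2L)
  p <- track_params()
  cost <- chemotaxr:::link_cost_matrix(obs_a, obs_b, p$d_gate, p$w_a)
  oracle <- brute_force_assignment(cost)
  expect_equal(oracle$assignment, c(1L, 2L))
  dist_only <- chemotaxr:::link_cost_matrix(obs_a, obs_b, p$d_gate, w_a = 0)
  expect_equal(brute_force_assignment(dist_only)$assignment, c(2L, 1L))
})

test_that("a missed detection is bridged by gap closing", {
  cfg <- quiet_config(n_cells = 1, duration = 400, rng_seed = 7)
  obs <- generate_tracks(cfg)$tracks
  obs$cell_id <- NULL
  obs <- obs[obs$frame != 50L, ]
  tr <- build_tracks(obs)
  expect_equal(tr$stats$n_tracks, 1L)
  expect_equal(tr$stats$n_gap_bridges, 1L)
  expect_equal(range(tr$observations$frame), c(0L, 99L))
})

test_that("a gap beyond max_gap closes the track as lost", {
  cfg <- quiet_config(n_cells = 1, duration = 400, rng_seed = 7)
  obs <- generate_tracks(cfg)$tracks
  obs$cell_id <- NULL
  obs <- obs[!(obs$frame %in% 50:52), ]  # 3 > max_gap = 2
  tr <- build_tracks(obs)
  expect_equal(tr$stats$n_tracks, 2L)
  expect_true("lost" %in% tr$tracks$ended_by)
})

test_that("every detection lands in exactly one track", {
  cfg <- synth_config(n_cells = 25, duration = 400, rng_seed = 13)
  obs <- generate_tracks(cfg)$tracks
  obs$true_id <- obs$cell_id; obs$cell_id <- NULL
  tr <- build_tracks(obs)
  expect_equal(nrow(tr$observations), nrow(obs))
  expect_false(anyNA(tr$observations$track_id))
})

test_that("frame-to-frame links match ground-truth identities", {
  cfg <- synth_config(n_cells = 30, duration = 480, rng_seed = 19)
  obs <- generate_tracks(cfg)$tracks
  obs$true_id <- obs$cell_id; obs$cell_id <- NULL
  tr <- build_tracks(obs)
  o <- tr$observations[order(tr$observations$track_id, tr$observations$frame), ]
  link <- diff(o$track_id) == 0
  expect_gt(mean(o$true_id[-1][link] == o$true_id[-nrow(o)][link]), 0.95)
})

test_that("instantaneous and mean speeds follow the displacement contract", {
  tk <- data.frame(t_min = c(0, 4), x_um = c(0, 3), y_um = c(0, 4))
  sp <- compute_speeds(tk)
  expect_equal(sp$speed$speed, 1.25)
  expect_equal(sp$mean_speed, 1.25)
  still <- data.frame(t_min = seq(0, 40, 4), x_um = rep(1, 11), y_um = rep(2, 11))
  expect_true(all(compute_speeds(still)$speed$speed == 0))
  expect_true(is.na(compute_speeds(tk[1, ])$mean_speed))
  # gap contributes displacement / elapsed time
  gap <- data.frame(t_min = c(0, 4, 12), x_um = c(0, 4, 12), y_um = 0)
  expect_equal(compute_speeds(gap)$speed$speed, c(1, 1))
})

test_that("divisions trim the parent and create daughters", {
  cfg <- synth_config(n_cells = 12, rng_seed = 3, mitosis_rate = 1 / 2000)
  sim <- generate_tracks(cfg)
  mito <- sim$truth$mitosis
  done <- mito[!is.na(mito$frame_div), ]
  expect_gt(nrow(done), 0)
  obs <- sim$tracks; obs$true_id <- obs$cell_id; obs$cell_id <- NULL
  tr <- resolve_mitosis(build_tracks(obs))
  expect_equal(sum(tr$tracks$ended_by == "mitosis"), nrow(done))
  expect_equal(sum(!is.na(tr$tracks$parent_id)), 2L * nrow(done))
  p <- track_params()
  for (k in seq_len(nrow(done))) {
    pid <- tr$observations$track_id[match(TRUE,
      tr$observations$true_id == done$cell_id[k])]
    end_f <- tr$tracks$end_frame[tr$tracks$track_id == pid]
    expect_lte(end_f, done$frame_div[k] - p$trim_k + 1L)
  }
})

test_that("movies without division are left unchanged by mitosis resolution", {
  cfg <- quiet_config(n_cells = 8, duration = 400, rng_seed = 21)
  obs <- generate_tracks(cfg)$tracks
  obs$cell_id <- NULL
  tr <- build_tracks(obs)
  tr2 <- resolve_mitosis(tr)
  expect_equal(nrow(tr2$observations), nrow(tr$observations))
  expect_false(any(tr2$tracks$ended_by == "mitosis"))
})
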