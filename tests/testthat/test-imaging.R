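# Rendering and segmentation: intensity contracts, mask geometry, and the
# render -> segment -> quantify round trip.

make_obs <- function(x, y, major, minor, orientation = 0, erk = 1, akt = 1,
                     pol = 0, id = 1L) {
  data.frame(cell_id = id, x_um = x, y_um = y,
             nuc_x_um = x + pol * minor, nuc_y_um = y,
             erk_ktr = erk, akt_ktr = akt,
             major_um = major, minor_um = minor, orientation = orientation,
             aspect_ratio = major / minor, polarization = pol,
             area_um2 = pi * major * minor / 4)
}

clean_model <- intensity_model(noise = "none", blur_sigma = 0)

test_that("rendered intensities encode the KTR value exactly", {
  obs <- make_obs(40, 40, 30, 30, erk = 2, akt = 0.5)
  fr <- render_frame(obs, pixel_size = 1, field_size = c(80, 80), clean_model)
  cyto <- fr$cell_mask == 1 & fr$nuc_mask == 0
  nuc <- fr$nuc_mask == 1
  expect_equal(mean(fr$erk[cyto]) / mean(fr$erk[nuc]), 4, tolerance = 1e-9)
  expect_equal(mean(fr$akt[cyto]) / mean(fr$akt[nuc]), sqrt(2), tolerance = 1e-9)
})

test_that("a blank field renders pure background and segments to zero objects", {
  fr <- render_frame(make_obs(1, 1, 1, 1)[0, ], pixel_size = 1,
                     field_size = c(60, 60), clean_model)
  expect_true(all(fr$nuclear == clean_model$background))
  noisy <- fr$nuclear + rnorm(length(fr$nuclear), 0, 15)
  expect_equal(max(segment_nuclei(matrix(noisy, 60, 60))), 0)
})

test_that("well-separated cells yield matching component counts (flood-fill oracle)", {
  xs <- rep(seq(30, 270, by = 60), 2)
  ys <- rep(c(60, 160), each = 5)
  obs <- do.call(rbind, lapply(1:10, function(i) {
    make_obs(xs[i], ys[i], 28, 18, id = i)
  }))
  fr <- render_frame(obs, pixel_size = 1, field_size = c(300, 220), clean_model)
  expect_equal(flood_fill_count(fr$nuc_mask > 0), 10)
  nuclei <- segment_nuclei(fr$nuclear)
  expect_equal(max(nuclei), 10)
  cells <- segment_cells(fr$akt, fr$erk, nuclei)
  expect_equal(length(unique(cells[cells > 0])), 10)
  # centroids within 1 px of truth
  found <- measure_frame(fr$nuclear, fr$akt, fr$erk)
  idx <- match_to_truth(found, obs)
  expect_true(all(!is.na(idx)))
  expect_lt(max(sqrt((found$x_um - obs$x_um[idx])^2 +
                     (found$y_um - obs$y_um[idx])^2)), 1)
})

test_that("foreground blobs without a seed nucleus are excluded", {
  obs <- make_obs(40, 40, 30, 20)
  fr <- render_frame(obs, pixel_size = 1, field_size = c(120, 80), clean_model)
  akt <- fr$akt; erk <- fr$erk
  blob <- chemotaxr:::ellipse_pixels(90, 40, 24, 24, 0, 1, 80, 120)$idx
  akt[blob] <- 2000; erk[blob] <- 2000  # bright nucleus-free debris
  nuclei <- segment_nuclei(fr$nuclear)
  cells <- segment_cells(akt, erk, nuclei)
  expect_identical(sort(unique(cells[cells > 0])), 1L)
  expect_true(all(cells[blob] == 0))
})

test_that("touching cells with two nuclei split into two matching regions", {
  obs <- rbind(make_obs(50, 40, 30, 22, id = 1L),
               make_obs(74, 40, 30, 22, id = 2L))
  fr <- render_frame(obs, pixel_size = 1, field_size = c(130, 80), clean_model)
  nuclei <- segment_nuclei(fr$nuclear)
  expect_equal(max(nuclei), 2)
  cells <- segment_cells(fr$akt, fr$erk, nuclei)
  expect_equal(length(unique(cells[cells > 0])), 2)
  # pixel agreement with ground-truth masks
  agree <- mean((cells > 0) == (fr$cell_mask > 0))
  expect_gt(agree, 0.95)
  for (id in 1:2) {
    inter <- sum(cells == id & fr$cell_mask == id)
    uni <- sum(cells == id | fr$cell_mask == id)
    expect_gt(inter / uni, 0.9)
  }
})

test_that("KTR quantification follows the log2 cytoplasm/nucleus contract", {
  cellm <- matrix(FALSE, 40, 40); cellm[5:35, 5:35] <- TRUE
  nucm <- matrix(FALSE, 40, 40); nucm[15:25, 15:25] <- TRUE
  img <- matrix(200, 40, 40); img[nucm] <- 50
  expect_equal(quantify_ktr(img, cellm, nucm, erode_px = 0L), 2)
  expect_equal(quantify_ktr(matrix(123, 40, 40), cellm, nucm, erode_px = 0L), 0)
  # degenerate: nucleus fills the cell -> no cytoplasm
  expect_true(is.na(quantify_ktr(img, nucm, nucm, erode_px = 0L)))
})

test_that("moment ellipse fit recovers analytic shapes", {
  circ <- matrix(FALSE, 60, 60)
  circ[chemotaxr:::ellipse_pixels(30, 30, 40, 40, 0, 1, 60, 60)$idx] <- TRUE
  nuc <- matrix(FALSE, 60, 60)
  nuc[chemotaxr:::ellipse_pixels(30, 30, 10, 10, 0, 1, 60, 60)$idx] <- TRUE
  m <- measure_morphology(circ, nuc, 1)
  expect_equal(m$aspect_ratio, 1, tolerance = 0.02)
  expect_equal(m$polarization, 0, tolerance = 0.01)

  ell <- matrix(FALSE, 80, 80)
  ell[chemotaxr:::ellipse_pixels(40, 40, 40, 20, 0, 1, 80, 80)$idx] <- TRUE
  nuc2 <- matrix(FALSE, 80, 80)
  nuc2[chemotaxr:::ellipse_pixels(45, 40, 8, 8, 0, 1, 80, 80)$idx] <- TRUE
  m2 <- measure_morphology(ell, nuc2, 1)
  expect_equal(m2$aspect_ratio, 2, tolerance = 0.02)
  expect_equal(m2$major_axis, 40, tolerance = 1)
  # nucleus offset 5 um, minor axis 20 um -> polarization 0.25
  expect_equal(m2$polarization, 5 / m2$minor_axis, tolerance = 1e-6)
  expect_equal(m2$polarization, 0.25, tolerance = 0.02)
})

test_that("aspect ratio is rotation invariant within discretization error", {
  base <- NULL
  for (th in c(0, pi / 7, pi / 4, 2)) {
    ell <- matrix(FALSE, 100, 100)
    ell[chemotaxr:::ellipse_pixels(50, 50, 44, 22, th, 1, 100, 100)$idx] <- TRUE
    m <- measure_morphology(ell, ell & FALSE, 1)
    if (is.null(base)) base <- m$aspect_ratio
    expect_equal(m$aspect_ratio, base, tolerance = 0.02)
  }
})

test_that("render -> segment -> quantify round trip is accurate at default SNR", {
  cfg <- synth_config(n_cells = 25, duration = 240, rng_seed = 17)
  sim <- generate_tracks(cfg)
  obs <- suppressWarnings(measure_movie(sim, pixel_size = 1, frames = c(0, 30),
                                        seed = 99))
  for (f in c(0, 30)) {
    ob <- obs[obs$frame == f, ]
    tr <- sim$tracks[sim$tracks$frame == f, ]
    expect_gte(nrow(ob), 0.95 * nrow(tr))
    idx <- match_to_truth(ob, tr)
    keep <- !is.na(idx)
    expect_lt(sqrt(mean((ob$erk_ktr[keep] - tr$erk_ktr[idx[keep]])^2, na.rm = TRUE)), 0.05)
    expect_lt(sqrt(mean((ob$akt_ktr[keep] - tr$akt_ktr[idx[keep]])^2, na.rm = TRUE)), 0.05)
    rel <- (ob$aspect_ratio[keep] - tr$aspect_ratio[idx[keep]]) / tr$aspect_ratio[idx[keep]]
    expect_lt(sqrt(mean(rel^2)), 0.05)
  }
})

test_that("stack TIFF round trip preserves intensities to 16-bit precision", {
  cfg <- quiet_config(n_cells = 3, duration = 240, rng_seed = 1)
  sim <- generate_tracks(cfg)
  stack <- render_images(sim, pixel_size = 2, model = clean_model, frames = 0:1)
  dir <- withr::local_tempdir()
  write_stack(stack, dir)
  back <- read_stack_channel(file.path(dir, "erk.tif"))
  expect_length(back, 2)
  # one 16-bit count of quantization error
  expect_lt(max(abs(back[[1]] - stack$frames[[1]]$erk)), 1)
})
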