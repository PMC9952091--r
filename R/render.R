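# Rendering synthetic multi-channel reporter movies from tracks.
#
# Three channels mirror the reporter set used for live-cell chemotaxis
# imaging: a nuclear marker (histone), and two KTR channels (Akt, ERK) whose
# cytoplasm/nucleus intensity ratio encodes kinase activity. Intensities are
# set so that log2(cytoplasm mean / nucleus mean) equals the track's true
# KTR value exactly before noise and blur.

#' Intensity model for the synthetic renderer
#'
#' @param background background level, counts.
#' @param nuclear_marker nucleus intensity in the nuclear channel, counts.
#' @param ktr_nucleus nucleus intensity in the KTR channels, counts; the
#'   cytoplasm is drawn at `ktr_nucleus * 2^ktr`.
#' @param blur_sigma Gaussian optical blur, pixels (0 disables).
#' @param noise "none", "gaussian" or "poisson".
#' @param gaussian_sd SD of additive Gaussian noise, counts.
#' @return list of class `intensity_model`.
#' @export
intensity_model <- function(background = 200, nuclear_marker = 3000,
                            ktr_nucleus = 1000, blur_sigma = 0.7,
                            noise = c("gaussian", "none", "poisson"),
                            gaussian_sd = 15) {
  noise <- match.arg(noise)
  structure(list(background = background, nuclear_marker = nuclear_marker,
                 ktr_nucleus = ktr_nucleus, blur_sigma = blur_sigma,
                 noise = noise, gaussian_sd = gaussian_sd),
            class = "intensity_model")
}

# Fill an ellipse into a matrix (by reference semantics: returns indices).
# cx, cy in um; a = major axis, b = minor axis (full lengths, um);
# theta = orientation (radians, x-axis to major axis); ps = um/px.
# Matrix layout: img[row, col] with x = (col - 0.5) * ps, y = (row - 0.5) * ps.
ellipse_pixels <- function(cx, cy, a, b, theta, ps, nrow_px, ncol_px) {
  rx <- a / 2; ry <- b / 2
  half <- max(rx, ry)
  c0 <- max(1L, floor((cx - half) / ps)); c1 <- min(ncol_px, ceiling((cx + half) / ps) + 1L)
  r0 <- max(1L, floor((cy - half) / ps)); r1 <- min(nrow_px, ceiling((cy + half) / ps) + 1L)
  if (c0 > c1 || r0 > r1) return(list(idx = integer(0), metric = numeric(0)))
  cols <- c0:c1; rows <- r0:r1
  px <- (rep(cols, each = length(rows)) - 0.5) * ps - cx
  py <- (rep(rows, times = length(cols)) - 0.5) * ps - cy
  u <- (px * cos(theta) + py * sin(theta)) / rx
  w <- (-px * sin(theta) + py * cos(theta)) / ry
  m <- u * u + w * w
  inside <- m <= 1
  idx <- rep(rows, times = length(cols)) + (rep(cols, each = length(rows)) - 1L) * nrow_px
  list(idx = idx[inside], metric = m[inside])
}

#' Render one frame of a synthetic movie
#'
#' Cells are drawn as filled ellipses; the nucleus as a disc offset from the
#' cell centroid by the polarization vector (clamped to stay inside the
#' cell). Ground-truth label masks are returned alongside the intensity
#' rasters.
#'
#' @param frame_obs rows of a synthetic track table for one frame.
#' @param pixel_size um per pixel.
#' @param field_size c(width, height), um.
#' @param model an [intensity_model()].
#' @return list with matrices `nuclear`, `akt`, `erk` (counts) and
#'   integer label masks `nuc_mask`, `cell_mask` keyed by `cell_id`.
#' @export
render_frame <- function(frame_obs, pixel_size, field_size,
                         model = intensity_model()) {
  ncol_px <- ceiling(field_size[1] / pixel_size)
  nrow_px <- ceiling(field_size[2] / pixel_size)
  bg <- model$background
  nuclear <- matrix(bg, nrow_px, ncol_px)
  akt <- matrix(bg, nrow_px, ncol_px)
  erk <- matrix(bg, nrow_px, ncol_px)
  nuc_mask <- matrix(0L, nrow_px, ncol_px)
  cell_mask <- matrix(0L, nrow_px, ncol_px)

  if (nrow(frame_obs)) {
    # density warning: nuclei drawn closer than their diameters overlap
    if (nrow(frame_obs) > 1) {
      d <- as.matrix(dist(cbind(frame_obs$nuc_x_um, frame_obs$nuc_y_um)))
      diag(d) <- Inf
      rad <- 0.22 * frame_obs$minor_um
      if (any(d < outer(rad, rad, `+`))) {
        warning("overlapping nuclei in rendered frame; tracking ambiguity expected")
      }
    }
    # adherent cells exclude area rather than overlap: contested pixels go
    # to the cell whose normalized ellipse metric is smallest
    claim <- matrix(Inf, nrow_px, ncol_px)
    for (k in seq_len(nrow(frame_obs))) {
      o <- frame_obs[k, ]
      ep <- ellipse_pixels(o$x_um, o$y_um, o$major_um, o$minor_um,
                           o$orientation, pixel_size, nrow_px, ncol_px)
      win <- ep$metric < claim[ep$idx]
      claim[ep$idx[win]] <- ep$metric[win]
      cell_mask[ep$idx[win]] <- o$cell_id
    }
    for (k in seq_len(nrow(frame_obs))) {
      o <- frame_obs[k, ]
      cell_px <- which(cell_mask == o$cell_id)
      if (!length(cell_px)) next
      r_nuc <- 0.22 * o$minor_um
      # clamp the nucleus offset so the disc stays inside the cell ellipse
      off_x <- o$nuc_x_um - o$x_um; off_y <- o$nuc_y_um - o$y_um
      off <- sqrt(off_x^2 + off_y^2)
      max_off <- max(0, o$minor_um / 2 - r_nuc - pixel_size)
      if (off > max_off && off > 0) {
        off_x <- off_x * max_off / off; off_y <- off_y * max_off / off
      }
      # the nucleus is a distinct organelle: draw it fully (it wins any
      # contested pixels, keeping nucleus k inside cell k in the masks)
      nuc_px <- ellipse_pixels(o$x_um + off_x, o$y_um + off_y,
                               2 * r_nuc, 2 * r_nuc, 0,
                               pixel_size, nrow_px, ncol_px)$idx
      cell_mask[nuc_px] <- o$cell_id
      cell_px <- union(cell_px, nuc_px)
      cyto_px <- setdiff(cell_px, nuc_px)
      nuclear[nuc_px] <- model$nuclear_marker
      akt[nuc_px] <- model$ktr_nucleus
      akt[cyto_px] <- model$ktr_nucleus * 2^o$akt_ktr
      erk[nuc_px] <- model$ktr_nucleus
      erk[cyto_px] <- model$ktr_nucleus * 2^o$erk_ktr
      nuc_mask[nuc_px] <- o$cell_id
    }
  }

  post <- function(img) {
    if (model$blur_sigma > 0) {
      img <- as.matrix(EBImage::gblur(EBImage::Image(img), model$blur_sigma))
    }
    img <- switch(model$noise,
                  none = img,
                  gaussian = img + rnorm(length(img), 0, model$gaussian_sd),
                  poisson = matrix(rpois(length(img), pmax(img, 0)),
                                   nrow(img), ncol(img)))
    clamp(img, 0, 65535)
  }
  list(nuclear = post(nuclear), akt = post(akt), erk = post(erk),
       nuc_mask = nuc_mask, cell_mask = cell_mask)
}

#' Render a synthetic movie as an in-memory stack
#'
#' Suitable for short movies; long movies should be processed frame by
#' frame with [measure_movie()] to bound memory.
#'
#' @param sim a `synth_result` from [generate_tracks()] (or a track table).
#' @param pixel_size um per pixel.
#' @param model an [intensity_model()].
#' @param frames optional integer vector of frame indices (0-based) to render.
#' @param seed optional seed for the rendering noise.
#' @return list of class `frame_stack`: per-frame render lists plus metadata.
#' @export
render_images <- function(sim, pixel_size = 1, model = intensity_model(),
                          frames = NULL, seed = NULL) {
  tracks <- if (inherits(sim, "synth_result")) sim$tracks else sim
  cfg <- if (inherits(sim, "synth_result")) sim$truth$config else NULL
  field_size <- cfg$field_size %||% c(max(tracks$x_um) + 30, max(tracks$y_um) + 30)
  all_frames <- sort(unique(tracks$frame))
  frames <- frames %||% all_frames
  out <- with_seed(seed, lapply(frames, function(f) {
    render_frame(tracks[tracks$frame == f, , drop = FALSE],
                 pixel_size, field_size, model)
  }))
  structure(list(frames = out, frame_index = frames, pixel_size = pixel_size,
                 field_size = field_size, model = model),
            class = "frame_stack")
}

#' Write a rendered stack to multi-page 16-bit TIFF files
#'
#' One file per channel (`nuclear.tif`, `akt.tif`, `erk.tif`) and per
#' ground-truth mask (`nuc_mask.tif`, `cell_mask.tif`).
#'
#' @param stack a `frame_stack` from [render_images()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (ch in c("nuclear", "akt", "erk")) {
    pages <- lapply(stack$frames, function(fr) fr[[ch]] / 65535)
    path <- file.path(dir, paste0(ch, ".tif"))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    files <- c(files, path)
  }
  for (mk in c("nuc_mask", "cell_mask")) {
    pages <- lapply(stack$frames, function(fr) fr[[mk]] / 65535)
    path <- file.path(dir, paste0(mk, ".tif"))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    files <- c(files, path)
  }
  invisible(files)
}

#' Read a multi-page TIFF channel written by [write_stack()]
#'
#' @param path TIFF file path.
#' @return list of numeric matrices in counts (0..65535).
#' @export
read_stack_channel <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) p * 65535)
}
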