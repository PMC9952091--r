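# Segmentation and per-cell quantification of reporter movies.
#
# Nuclei are detected by local-mean adaptive thresholding of the nuclear
# marker channel; cells by nucleus-seeded region growing (CellProfiler-style
# seeded watershed, EBImage::propagate) on the summed KTR channels. Kinase
# activity is the log2 cytoplasm/nucleus mean-intensity ratio; morphology
# comes from second central moments of the cell region.

#' Segmentation parameters
#'
#' @param pixel_size um per pixel.
#' @param nucleus_diameter_um expected nucleus diameter; the adaptive
#'   threshold window is ~3x this value.
#' @param cell_diameter_um expected cell diameter; sets the cell threshold
#'   window.
#' @param offset_frac adaptive threshold offset, as a fraction of the
#'   channel's robust intensity spread (99th percentile minus median).
#' @param min_nucleus_area_um2,min_cell_area_um2 objects smaller than these
#'   are discarded.
#' @param erode_px pixels eroded off the cell boundary (and dilated around
#'   the nucleus) before intensity averaging, to keep partial-volume edge
#'   pixels out of the KTR ratio.
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(pixel_size = 1,
                                nucleus_diameter_um = 8,
                                cell_diameter_um = 28,
                                offset_frac = 0.1,
                                min_nucleus_area_um2 = 30,
                                min_cell_area_um2 = 100,
                                erode_px = 2L) {
  structure(list(pixel_size = pixel_size,
                 nucleus_diameter_um = nucleus_diameter_um,
                 cell_diameter_um = cell_diameter_um,
                 offset_frac = offset_frac,
                 min_nucleus_area_um2 = min_nucleus_area_um2,
                 min_cell_area_um2 = min_cell_area_um2,
                 erode_px = as.integer(erode_px)),
            class = "segmentation_params")
}

adaptive_foreground <- function(img, window_px, offset_frac) {
  # spread between the bulk (median) and the bright tail sets the contrast
  # scale; a 3*MAD noise floor keeps sensor noise below threshold even in
  # sparse or blank fields
  rng <- stats::quantile(img, c(0.5, 0.999), names = FALSE)
  offset <- max(offset_frac * (rng[2] - rng[1]),
                3 * stats::mad(img),
                .Machine$double.eps)
  half <- max(2L, as.integer(round(window_px / 2)))
  half <- min(half, as.integer((min(dim(img)) - 1) / 2))  # small-frame guard
  fg <- EBImage::thresh(EBImage::Image(img), w = half, h = half, offset = offset)
  fg <- EBImage::fillHull(fg)
  fg
}

drop_small <- function(labels, min_px) {
  tab <- tabulate(labels[labels > 0])
  kill <- which(tab < min_px)
  if (length(kill)) labels[labels %in% kill] <- 0L
  labels
}

#' Segment nuclei by adaptive thresholding
#'
#' Local-mean adaptive threshold (window ~3x the expected nucleus
#' diameter), hole filling, removal of objects below the minimum area, and
#' connected-component labeling.
#'
#' @param nuclear_channel numeric matrix of intensities.
#' @param params a [segmentation_params()].
#' @return integer label matrix (0 = background).
#' @export
segment_nuclei <- function(nuclear_channel, params = segmentation_params()) {
  stopifnot(length(nuclear_channel) > 0)
  window_px <- 3 * params$nucleus_diameter_um / params$pixel_size
  fg <- adaptive_foreground(nuclear_channel, window_px, params$offset_frac)
  lab <- EBImage::bwlabel(fg)
  min_px <- params$min_nucleus_area_um2 / params$pixel_size^2
  lab <- drop_small(as.matrix(lab), min_px)
  relabel_consecutive(lab)
}

relabel_consecutive <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (!length(u)) return(matrix(0L, nrow(lab), ncol(lab)))
  out <- matrix(match(lab, u, nomatch = 0L), nrow(lab), ncol(lab))
  storage.mode(out) <- "integer"
  out
}

#' Segment cells seeded by their nuclei
#'
#' Cell foreground is an adaptive threshold of the summed KTR channels;
#' foreground is then partitioned among the nucleus seeds by intensity-aware
#' region growing. Each cell label equals its seed nucleus label; foreground
#' blobs without a seed are discarded, and seeds falling outside the
#' foreground are dropped with a warning.
#'
#' @param akt_channel,erk_channel numeric intensity matrices.
#' @param nuclei integer label matrix from [segment_nuclei()].
#' @param params a [segmentation_params()].
#' @return integer label matrix; labels match `nuclei`.
#' @export
segment_cells <- function(akt_channel, erk_channel, nuclei,
                          params = segmentation_params()) {
  stopifnot(all(dim(akt_channel) == dim(erk_channel)),
            all(dim(akt_channel) == dim(nuclei)))
  total <- akt_channel + erk_channel
  window_px <- 3 * params$cell_diameter_um / params$pixel_size
  fg <- adaptive_foreground(total, window_px, params$offset_frac)
  fg_mat <- as.matrix(fg) > 0 | nuclei > 0   # nuclei always belong to their cell
  seeds <- nuclei
  seed_ids <- sort(unique(seeds[seeds > 0]))
  lost <- vapply(seed_ids, function(id) sum(fg_mat[seeds == id]) == 0, logical(1))
  if (any(lost)) {
    warning(sprintf("%d nucleus seed(s) outside cell foreground; cells dropped: %s",
                    sum(lost), paste(seed_ids[lost], collapse = ",")))
  }
  lab <- EBImage::propagate(EBImage::Image(total / max(total)),
                            seeds = EBImage::Image(seeds),
                            mask = EBImage::Image(fg_mat))
  lab <- as.matrix(lab)
  storage.mode(lab) <- "integer"
  min_px <- params$min_cell_area_um2 / params$pixel_size^2
  counts <- tabulate(lab[lab > 0], nbins = max(lab, 1L))
  kill <- which(counts > 0 & counts < min_px)
  if (length(kill)) lab[lab %in% kill] <- 0L
  lab
}

#' Quantify KTR activity for one cell
#'
#' log2 of the mean cytoplasmic to mean nuclear intensity. The cytoplasm is
#' the cell region minus the (dilated) nucleus, with the cell boundary
#' eroded to exclude partial-volume pixels.
#'
#' @param channel intensity matrix.
#' @param cell_mask,nucleus_mask logical matrices for this cell.
#' @param erode_px boundary erosion/dilation width in pixels.
#' @return log2 cytoplasm/nucleus ratio, or NA if degenerate.
#' @export
quantify_ktr <- function(channel, cell_mask, nucleus_mask, erode_px = 1L) {
  if (erode_px > 0) {
    brush <- EBImage::makeBrush(2L * erode_px + 1L, "diamond")
    cell_core <- as.matrix(EBImage::erode(EBImage::Image(cell_mask * 1), brush)) > 0
    nuc_wide <- as.matrix(EBImage::dilate(EBImage::Image(nucleus_mask * 1), brush)) > 0
    nuc_core <- as.matrix(EBImage::erode(EBImage::Image(nucleus_mask * 1), brush)) > 0
    if (!any(nuc_core)) nuc_core <- nucleus_mask
    if (!any(cell_core)) cell_core <- cell_mask
  } else {
    cell_core <- cell_mask; nuc_wide <- nucleus_mask; nuc_core <- nucleus_mask
  }
  cyto <- cell_core & !nuc_wide
  if (!any(cyto) || !any(nuc_core)) return(NA_real_)
  nuc_mean <- mean(channel[nuc_core])
  if (!is.finite(nuc_mean) || nuc_mean <= 0) return(NA_real_)
  log2(mean(channel[cyto]) / nuc_mean)
}

#' Ellipse fit and polarization from region masks
#'
#' Best-fit ellipse from second central moments of the cell region pixel
#' coordinates (axes of a solid ellipse are four times the square root of
#' the principal variances). Nuclear polarization is the distance from
#' nucleus centroid to cell centroid normalized to the cell's minor axis.
#'
#' @param cell_mask,nucleus_mask logical matrices for this cell.
#' @param pixel_size um per pixel.
#' @return list: centroids (um), major/minor axes (um), orientation (rad),
#'   aspect_ratio, area_um2, polarization; or NULL for degenerate regions.
#' @export
measure_morphology <- function(cell_mask, nucleus_mask, pixel_size = 1) {
  idx <- which(cell_mask)
  if (length(idx) < 4) return(NULL)
  nr <- nrow(cell_mask)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  x <- (cols - 0.5) * pixel_size
  y <- (rows - 0.5) * pixel_size
  cx <- mean(x); cy <- mean(y)
  # pixel-discretisation correction: each pixel carries 1/12 px^2 variance
  sxx <- mean((x - cx)^2) + pixel_size^2 / 12
  syy <- mean((y - cy)^2) + pixel_size^2 / 12
  sxy <- mean((x - cx) * (y - cy))
  tr <- sxx + syy; det_ <- sxx * syy - sxy^2
  disc <- sqrt(max(tr^2 / 4 - det_, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l2 <= 0) return(NULL)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  orientation <- 0.5 * atan2(2 * sxy, sxx - syy)
  nidx <- which(nucleus_mask)
  pol <- NA_real_; ncx <- NA_real_; ncy <- NA_real_
  if (length(nidx)) {
    nrows <- ((nidx - 1L) %% nr) + 1L
    ncols <- ((nidx - 1L) %/% nr) + 1L
    ncx <- mean((ncols - 0.5) * pixel_size)
    ncy <- mean((nrows - 0.5) * pixel_size)
    pol <- sqrt((ncx - cx)^2 + (ncy - cy)^2) / minor
  }
  list(cell_centroid = c(cx, cy), nuc_centroid = c(ncx, ncy),
       major_axis = major, minor_axis = minor, orientation = orientation,
       aspect_ratio = major / minor,
       area_um2 = length(idx) * pixel_size^2, polarization = pol)
}

#' Segment and quantify one frame
#'
#' @param nuclear_channel,akt_channel,erk_channel intensity matrices.
#' @param t frame time, minutes.
#' @param params a [segmentation_params()].
#' @return data.frame of per-cell observations (provisional `cell_id` =
#'   segmentation label; centroids in um; `akt_ktr`, `erk_ktr` in log2
#'   cytoplasm/nucleus units).
#' @export
measure_frame <- function(nuclear_channel, akt_channel, erk_channel, t = 0,
                          params = segmentation_params()) {
  nuclei <- segment_nuclei(nuclear_channel, params)
  cells <- segment_cells(akt_channel, erk_channel, nuclei, params)
  labels <- sort(unique(cells[cells > 0]))
  nr <- nrow(cells)
  # bounding boxes per label so mask morphology runs on small crops
  lab_idx <- which(cells > 0)
  lab_of <- cells[lab_idx]
  rows_of <- ((lab_idx - 1L) %% nr) + 1L
  cols_of <- ((lab_idx - 1L) %/% nr) + 1L
  out <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    k <- labels[i]
    sel <- lab_of == k
    r0 <- max(1L, min(rows_of[sel]) - 3L); r1 <- min(nr, max(rows_of[sel]) + 3L)
    c0 <- max(1L, min(cols_of[sel]) - 3L); c1 <- min(ncol(cells), max(cols_of[sel]) + 3L)
    cells_c <- cells[r0:r1, c0:c1, drop = FALSE]
    cm <- cells_c == k
    nm <- nuclei[r0:r1, c0:c1, drop = FALSE] == k & cm
    if (!any(nm)) next
    morph <- measure_morphology(cm, nm, params$pixel_size)
    if (is.null(morph)) next
    # shift crop-local centroids back to frame coordinates
    shift <- c((c0 - 1L), (r0 - 1L)) * params$pixel_size
    morph$cell_centroid <- morph$cell_centroid + shift
    morph$nuc_centroid <- morph$nuc_centroid + shift
    akt <- quantify_ktr(akt_channel[r0:r1, c0:c1, drop = FALSE], cm, nm, params$erode_px)
    erk <- quantify_ktr(erk_channel[r0:r1, c0:c1, drop = FALSE], cm, nm, params$erode_px)
    out[[i]] <- data.frame(
      cell_id = k, t_min = t,
      x_um = morph$cell_centroid[1], y_um = morph$cell_centroid[2],
      nuc_x_um = morph$nuc_centroid[1], nuc_y_um = morph$nuc_centroid[2],
      major_um = morph$major_axis, minor_um = morph$minor_axis,
      orientation = morph$orientation, aspect_ratio = morph$aspect_ratio,
      area_um2 = morph$area_um2, akt_ktr = akt, erk_ktr = erk,
      polarization = morph$polarization)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(cell_id = integer(), t_min = numeric(), x_um = numeric(),
                      y_um = numeric(), nuc_x_um = numeric(), nuc_y_um = numeric(),
                      major_um = numeric(), minor_um = numeric(),
                      orientation = numeric(), aspect_ratio = numeric(),
                      area_um2 = numeric(), akt_ktr = numeric(),
                      erk_ktr = numeric(), polarization = numeric())
  }
  rownames(res) <- NULL
  res
}

#' Render, segment and quantify a synthetic movie frame by frame
#'
#' Streams the movie (render one frame, measure it, discard the rasters) so
#' memory stays bounded for long movies.
#'
#' @param sim a `synth_result` from [generate_tracks()].
#' @param pixel_size um per pixel.
#' @param model an [intensity_model()].
#' @param params a [segmentation_params()] (its `pixel_size` is overridden).
#' @param frames 0-based frame indices to process (default: all).
#' @param seed seed for rendering noise.
#' @return data.frame of observations across frames, with a `frame` column.
#' @export
measure_movie <- function(sim, pixel_size = 1, model = intensity_model(),
                          params = segmentation_params(), frames = NULL,
                          seed = NULL) {
  stopifnot(inherits(sim, "synth_result"))
  params$pixel_size <- pixel_size
  cfg <- sim$truth$config
  frames <- frames %||% sort(unique(sim$tracks$frame))
  res <- with_seed(seed, lapply(frames, function(f) {
    fr <- render_frame(sim$tracks[sim$tracks$frame == f, , drop = FALSE],
                       pixel_size, cfg$field_size, model)
    obs <- measure_frame(fr$nuclear, fr$akt, fr$erk,
                         t = f * cfg$dt, params = params)
    if (nrow(obs)) obs$frame <- f else obs$frame <- integer(0)
    obs
  }))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
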