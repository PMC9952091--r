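# Heterogeneity statistics across cells and conditions.
#
# Quantile regression characterizes the conditional 20th/50th/80th
# percentiles of a response (typically migration speed) against a per-cell
# amplitude; one-dimensional earth mover's distance (Wasserstein-1)
# quantifies distribution shifts between conditions, normalized by the
# distance between control replicates.

# ---- quantile regression ------------------------------------------------

pinball_loss <- function(res, tau) sum(res * (tau - (res < 0)))

# Exact fit by enumerating candidate lines through pairs of observations:
# for the intercept+slope model an optimal solution interpolates two data
# points with distinct x. Evaluated in blocks to bound memory.
qr_fit_pairs <- function(x, y, tau) {
  n <- length(x)
  ij <- which(upper.tri(diag(n)), arr.ind = TRUE)
  dx <- x[ij[, 2]] - x[ij[, 1]]
  ok <- abs(dx) > .Machine$double.eps^0.5
  ij <- ij[ok, , drop = FALSE]; dx <- dx[ok]
  b <- (y[ij[, 2]] - y[ij[, 1]]) / dx
  a <- y[ij[, 1]] - b * x[ij[, 1]]
  best <- c(Inf, NA, NA)
  block <- 4000L
  for (s in seq(1L, length(a), by = block)) {
    e <- min(s + block - 1L, length(a))
    pred <- outer(a[s:e], rep(1, n)) + outer(b[s:e], x)
    res <- matrix(y, e - s + 1L, n, byrow = TRUE) - pred
    loss <- rowSums(res * (tau - (res < 0)))
    k <- which.min(loss)
    if (loss[k] < best[1] - 1e-12 ||
        (abs(loss[k] - best[1]) <= 1e-12 &&
         (b[s + k - 1L] < best[3] - 1e-12 ||
          (abs(b[s + k - 1L] - best[3]) <= 1e-12 && a[s + k - 1L] < best[2])))) {
      best <- c(loss[k], a[s + k - 1L], b[s + k - 1L])
    }
  }
  c(intercept = best[2], slope = best[3])
}

# weighted tau-quantile: smallest c with cumulative weight >= p * total
weighted_quantile_point <- function(v, w, p) {
  o <- order(v)
  cw <- cumsum(w[o])
  v[o][which(cw >= p * cw[length(cw)] - 1e-12)[1]]
}

# Coordinate descent: alternates the exact 1D minimizers for intercept
# (tau-quantile of residuals) and slope (weighted quantile of r/x).
qr_fit_cd <- function(x, y, tau, init, maxit = 60L) {
  a <- unname(init[1]); b <- unname(init[2])
  loss_old <- pinball_loss(y - a - b * x, tau)
  nz <- abs(x) > .Machine$double.eps^0.5
  for (it in seq_len(maxit)) {
    r <- sort(y - b * x)
    k <- max(1L, ceiling(tau * length(r)))
    a <- r[k]
    r2 <- y - a
    v <- r2[nz] / x[nz]
    w <- abs(x[nz])
    l <- ifelse(x[nz] > 0, tau * w, (1 - tau) * w)
    p <- sum(l) / sum(w)
    b_new <- weighted_quantile_point(v, w, p)
    loss_new <- pinball_loss(y - a - b_new * x, tau)
    if (loss_new <= loss_old - 1e-12) { b <- b_new; loss_old <- loss_new } else {
      loss_a <- pinball_loss(y - a - b * x, tau)
      if (loss_a < loss_old - 1e-12) loss_old <- loss_a else break
    }
  }
  c(intercept = a, slope = b)
}

qr_fit <- function(x, y, tau, exact_cap = 350L) {
  n <- length(x)
  if (n <= exact_cap) return(qr_fit_pairs(x, y, tau))
  # large n: candidate lines from a deterministic quantile-spread subsample,
  # loss evaluated on all data, then coordinate-descent polish
  sub <- unique(round(seq(1L, n, length.out = exact_cap)))
  o <- order(x, y)
  fit0 <- qr_fit_pairs(x[o][sub], y[o][sub], tau)
  qr_fit_cd(x, y, tau, fit0)
}

#' Linear quantile regression with bootstrap inference
#'
#' Minimizes the pinball (check) loss `sum(rho_tau(y - a - b x))` at each
#' requested quantile. For moderate n the fit is exact (enumeration of
#' candidate lines through data-point pairs); for large n an exact fit on a
#' deterministic subsample is polished by coordinate descent on the full
#' loss. Standard errors and 99 percent confidence intervals come from a
#' seeded case-resampling bootstrap; the p-value (slope != 0) uses a normal
#' approximation on the bootstrap SE.
#'
#' @param x predictor (e.g. per-cell amplitude).
#' @param y response (e.g. per-cell mean speed).
#' @param taus quantiles to fit.
#' @param B bootstrap replicates.
#' @param seed bootstrap seed.
#' @param ci_level confidence level for the percentile interval.
#' @return data.frame of class `quantile_fits`: tau, intercept, slope,
#'   slope_se, p_value, ci99_lo, ci99_hi, intercept_ci_lo, intercept_ci_hi, n.
#' @export
quantile_regress <- function(x, y, taus = c(0.2, 0.5, 0.8), B = 1000L,
                             seed = 1L, ci_level = 0.99) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("quantile regression needs at least 3 paired finite observations")
  if (stats::sd(x) < .Machine$double.eps^0.5) {
    stop("degenerate predictor: zero variance in x")
  }
  if (stats::sd(y) < .Machine$double.eps^0.5) {
    stop("degenerate response: zero variance in y")
  }
  alpha <- (1 - ci_level) / 2
  fits <- lapply(taus, function(tau) {
    fit <- qr_fit(x, y, tau)
    boots <- with_seed(seed, {
      vapply(seq_len(B), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        xb <- x[idx]; yb <- y[idx]
        if (stats::sd(xb) < .Machine$double.eps^0.5) return(c(NA_real_, NA_real_))
        fb <- if (n <= 60L) qr_fit_pairs(xb, yb, tau) else qr_fit_cd(xb, yb, tau, fit)
        c(fb[["intercept"]], fb[["slope"]])
      }, numeric(2))
    })
    sl <- boots[2, ]; ic <- boots[1, ]
    se <- stats::sd(sl, na.rm = TRUE)
    p <- 2 * stats::pnorm(-abs(fit[["slope"]]) / max(se, .Machine$double.eps))
    data.frame(tau = tau, intercept = fit[["intercept"]], slope = fit[["slope"]],
               slope_se = se, p_value = p,
               ci99_lo = stats::quantile(sl, alpha, na.rm = TRUE, names = FALSE),
               ci99_hi = stats::quantile(sl, 1 - alpha, na.rm = TRUE, names = FALSE),
               intercept_ci_lo = stats::quantile(ic, alpha, na.rm = TRUE, names = FALSE),
               intercept_ci_hi = stats::quantile(ic, 1 - alpha, na.rm = TRUE, names = FALSE),
               n = n)
  })
  out <- do.call(rbind, fits)
  class(out) <- c("quantile_fits", class(out))
  out
}

# ---- top-quartile proportion -------------------------------------------

#' Proportion of fast cells that are also high-amplitude cells
#'
#' P(amplitude > 75th percentile | speed > 75th percentile); quartiles are
#' computed on each marginal by linear interpolation of order statistics,
#' membership is by strict inequality.
#'
#' @param speeds,amplitudes paired per-cell vectors (n >= 8).
#' @return fraction in [0, 1].
#' @export
top_quartile_proportion <- function(speeds, amplitudes) {
  keep <- is.finite(speeds) & is.finite(amplitudes)
  speeds <- speeds[keep]; amplitudes <- amplitudes[keep]
  stopifnot(length(speeds) >= 8)
  qs <- stats::quantile(speeds, 0.75, names = FALSE)
  qa <- stats::quantile(amplitudes, 0.75, names = FALSE)
  fast <- speeds > qs
  if (!any(fast)) return(NA_real_)
  mean(amplitudes[fast] > qa)
}

# ---- earth mover's distance --------------------------------------------

#' One-dimensional earth mover's distance (Wasserstein-1)
#'
#' Computed as the integral of |F_a - F_b| between the empirical (possibly
#' weighted) cumulative distribution functions.
#'
#' @param a,b sample vectors.
#' @param wa,wb optional nonnegative weights (default: uniform); weights
#'   are normalized to total mass 1.
#' @return nonnegative distance in the units of the samples.
#' @export
emd_1d <- function(a, b, wa = NULL, wb = NULL) {
  stopifnot(length(a) > 0, length(b) > 0)
  wa <- wa %||% rep(1, length(a)); wb <- wb %||% rep(1, length(b))
  wa <- wa / sum(wa); wb <- wb / sum(wb)
  grid <- sort(unique(c(a, b)))
  Fa <- ecdf_weighted(a, wa, grid)
  Fb <- ecdf_weighted(b, wb, grid)
  k <- length(grid)
  if (k < 2) return(0)
  sum(abs(Fa - Fb)[-k] * diff(grid))
}

ecdf_weighted <- function(x, w, grid) {
  o <- order(x)
  xs <- x[o]; cw <- cumsum(w[o])
  idx <- findInterval(grid, xs)
  c(0, cw)[idx + 1L]
}

#' EMD of a test condition normalized to control replicates
#'
#' Mean EMD of the test samples to each control replicate, divided by the
#' mean EMD among the control replicates themselves. Values near 1 mean
#' the test condition differs from control no more than replicates differ
#' from one another.
#'
#' @param test sample vector for the test condition. If `test` is itself
#'   one of the control replicates it is excluded from the numerator
#'   average, so re-testing a control against the panel scores 1.
#' @param controls list of >= 2 control sample vectors (biological
#'   replicates).
#' @return dimensionless normalized EMD.
#' @export
normalized_emd <- function(test, controls) {
  stopifnot(is.list(controls), length(controls) >= 2)
  others <- controls[!vapply(controls, identical, logical(1), y = test)]
  if (!length(others)) others <- controls
  num <- mean(vapply(others, function(ctrl) emd_1d(test, ctrl), 0))
  pairs <- utils::combn(length(controls), 2)
  den <- mean(apply(pairs, 2, function(p) emd_1d(controls[[p[1]]], controls[[p[2]]])))
  if (den <= 0) stop("control replicates are identical: normalized EMD undefined")
  num / den
}

# ---- polar histogram ----------------------------------------------------

#' Polar histogram of net track displacement directions
#'
#' The angle of each track's net displacement (end minus start) is taken
#' relative to the gradient axis and binned into equal sectors, the first
#' sector centered on the forward (up-gradient) direction.
#'
#' @param tracks track table.
#' @param n_bins number of angular sectors.
#' @param gradient_axis unit vector of the chemoattractant gradient.
#' @return integer bin counts (attributes: `centers` in radians,
#'   `n_skipped` zero-displacement tracks).
#' @export
polar_histogram <- function(tracks, n_bins = 12L, gradient_axis = c(1, 0)) {
  tracks <- as_track_table(tracks)
  g <- gradient_axis / sqrt(sum(gradient_axis^2))
  disp <- t(vapply(split(tracks, tracks$track_id), function(d) {
    d <- d[order(d$t_min), ]
    c(d$x_um[nrow(d)] - d$x_um[1], d$y_um[nrow(d)] - d$y_um[1])
  }, numeric(2)))
  r <- sqrt(rowSums(disp^2))
  skipped <- sum(r == 0)
  disp <- disp[r > 0, , drop = FALSE]
  theta <- atan2(disp[, 2], disp[, 1]) - atan2(g[2], g[1])
  width <- 2 * pi / n_bins
  bin <- floor(((theta + width / 2) %% (2 * pi)) / width) + 1L
  counts <- tabulate(bin, nbins = n_bins)
  attr(counts, "centers") <- (seq_len(n_bins) - 1L) * width
  attr(counts, "n_skipped") <- skipped
  counts
}
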