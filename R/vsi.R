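# Weak-form inference of advection-diffusion motility parameters.
#
# Cell populations are treated as continuous density fields rho(x, t)
# governed by d(rho)/dt = D lap(rho) - v . grad(rho): the diffusivity D
# measures random migration, the advective velocity v directed motion.
# Testing the residual against bilinear nodal functions on interior grid
# nodes (integration by parts on the diffusion term only) turns each
# (node, frame-pair) into one linear equation in (D, vx, vy), solved by
# ordinary least squares.

#' Build a density field from tracks
#'
#' Per frame, a 2D histogram of cell positions on a uniform node grid
#' (density = counts / h^2) smoothed with a Gaussian kernel; frames are
#' aggregated in time blocks by averaging to suppress detection noise in
#' the time derivative.
#'
#' @param tracks track table.
#' @param field_size c(width, height), um.
#' @param h grid spacing, um.
#' @param sigma Gaussian smoothing bandwidth, um (default `2 * h`).
#' @param dt_agg temporal aggregation interval, minutes (default 20).
#' @return list of class `density_field`: node coordinates `x`, `y`,
#'   spacing `h`, `times` (minutes), `frames` (list of Nx x Ny matrices,
#'   cells/um^2).
#' @export
build_density <- function(tracks, field_size, h = 25, sigma = 2 * h,
                          dt_agg = 20) {
  tracks <- as_track_table(tracks)
  frames_all <- sort(unique(tracks$frame))
  if (length(frames_all) < 3) stop("need at least 3 frames to build a density field")
  nx <- floor(field_size[1] / h) + 1L
  ny <- floor(field_size[2] / h) + 1L
  x <- (seq_len(nx) - 1L) * h
  y <- (seq_len(ny) - 1L) * h
  dt <- min(diff(sort(unique(tracks$t_min))))
  per_block <- max(1L, round(dt_agg / dt))
  block <- (match(tracks$frame, frames_all) - 1L) %/% per_block
  kern <- gauss_kernel(sigma / h)
  agg <- lapply(split(seq_len(nrow(tracks)), block), function(rows) {
    d <- tracks[rows, ]
    sub <- split(seq_along(rows), d$frame)
    mats <- lapply(sub, function(rr) {
      ix <- clamp(round(d$x_um[rr] / h) + 1L, 1L, nx)
      iy <- clamp(round(d$y_um[rr] / h) + 1L, 1L, ny)
      m <- matrix(0, nx, ny)
      tab <- table(factor(ix + (iy - 1L) * nx, levels = seq_len(nx * ny)))
      m[] <- as.numeric(tab) / h^2
      smooth2d(m, kern)
    })
    list(time = mean(d$t_min), mat = Reduce(`+`, mats) / length(mats))
  })
  structure(list(x = x, y = y, h = h,
                 times = vapply(agg, `[[`, 0, "time"),
                 frames = lapply(agg, `[[`, "mat"),
                 sigma = sigma),
            class = "density_field")
}

#' Construct a density field from matrices (e.g. analytic solutions)
#'
#' @param x,y node coordinates (uniform spacing).
#' @param times frame times, minutes.
#' @param frames list of Nx x Ny density matrices.
#' @return `density_field` object.
#' @export
density_field <- function(x, y, times, frames) {
  h <- diff(x)[1]
  stopifnot(all(abs(diff(x) - h) < 1e-9), all(abs(diff(y) - h) < 1e-9),
            length(frames) == length(times))
  structure(list(x = x, y = y, h = h, times = times, frames = frames,
                 sigma = NA_real_), class = "density_field")
}

gauss_kernel <- function(sigma_nodes) {
  if (sigma_nodes <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_nodes))
  k <- exp(-0.5 * ((-r):r / sigma_nodes)^2)
  k / sum(k)
}

smooth2d <- function(m, kern) {
  if (length(kern) == 1) return(m)
  m <- apply_conv(m, kern, 1L)
  apply_conv(m, kern, 2L)
}

apply_conv <- function(m, kern, margin) {
  r <- (length(kern) - 1L) / 2L
  n <- dim(m)[margin]
  out <- matrix(0, nrow(m), ncol(m))
  for (k in seq_along(kern)) {
    off <- k - r - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    if (margin == 1L) out[ok, ] <- out[ok, ] + kern[k] * m[src[ok], ]
    else out[, ok] <- out[, ok] + kern[k] * m[, src[ok]]
  }
  out
}

#' Spatial integral of each density frame
#'
#' @param df a `density_field`.
#' @return numeric vector, cells per frame.
#' @export
integrate_density <- function(df) {
  vapply(df$frames, function(m) sum(m) * df$h^2, 0)
}

# 3-point separable stencils for bilinear finite elements on spacing h:
# mass M = h * (1/6, 2/3, 1/6); stiffness K = (1/h) * (-1, 2, -1);
# first-derivative G = (-1/2, 0, 1/2).
stencil_apply <- function(m, wx, wy) {
  # out = (Wx (x) Wy) m, evaluated on all nodes (edges use available terms)
  tmp <- apply_stencil_1d(m, wx, 1L)
  apply_stencil_1d(tmp, wy, 2L)
}

apply_stencil_1d <- function(m, w, margin) {
  n <- dim(m)[margin]
  out <- matrix(0, nrow(m), ncol(m))
  for (k in 1:3) {
    off <- k - 2L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    if (margin == 1L) out[ok, ] <- out[ok, ] + w[k] * m[src[ok], ]
    else out[, ok] <- out[, ok] + w[k] * m[, src[ok]]
  }
  out
}

#' Infer diffusivity and advective velocity from a density field
#'
#' Weak-form least squares for the constant-coefficient model
#' `d(rho)/dt = D lap(rho) - v . grad(rho)`. For every interior bilinear
#' nodal test function w and consecutive (aggregated) frame pair, the
#' scalar equation
#' `int w (rho1 - rho0)/dt = -D int grad(w).grad(rbar) - v . int w grad(rbar)`
#' (rbar the midpoint average) contributes one row; the stacked system is
#' solved by OLS. A one-element boundary band is excluded, sidestepping the
#' unknown chamber boundary conditions.
#'
#' @param df a `density_field` with at least 2 frames and a grid of at
#'   least 5 x 5 nodes.
#' @param gradient_axis unit vector of the chemoattractant gradient.
#' @param active character subset of c("diffusion", "advection_x",
#'   "advection_y") to fit (others fixed at 0).
#' @return list of class `motility_params`: `D`, `v_x`, `v_y`, `v_par`,
#'   `v_perp`, `residual` (norm), `rss`, `condition`, `n_equations`,
#'   `model_inadequate` (TRUE when D < 0).
#' @export
infer_motility <- function(df, gradient_axis = c(1, 0),
                           active = c("diffusion", "advection_x", "advection_y")) {
  stopifnot(inherits(df, "density_field"))
  nf <- length(df$frames)
  if (nf < 2) stop("need at least 2 aggregated frames")
  nx <- length(df$x); ny <- length(df$y)
  if (nx < 5 || ny < 5) stop("grid too small: need at least 5 x 5 nodes for interior test functions")
  h <- df$h
  M <- h * c(1 / 6, 2 / 3, 1 / 6)
  K <- (1 / h) * c(-1, 2, -1)
  G <- c(-1 / 2, 0, 1 / 2)
  interior_x <- 3:(nx - 2); interior_y <- 3:(ny - 2)
  rows_y <- list(); rows_b <- list(); rows_c <- list(); rows_d <- list()
  for (p in seq_len(nf - 1L)) {
    dt_p <- df$times[p + 1L] - df$times[p]
    rbar <- (df$frames[[p]] + df$frames[[p + 1L]]) / 2
    drho <- (df$frames[[p + 1L]] - df$frames[[p]]) / dt_p
    a <- stencil_apply(drho, M, M)
    b <- apply_stencil_1d(rbar, K, 1L) |> apply_stencil_1d(M, 2L)
    b <- b + (apply_stencil_1d(rbar, M, 1L) |> apply_stencil_1d(K, 2L))
    cx <- apply_stencil_1d(rbar, G, 1L) |> apply_stencil_1d(M, 2L)
    cy <- apply_stencil_1d(rbar, M, 1L) |> apply_stencil_1d(G, 2L)
    rows_y[[p]] <- as.vector(a[interior_x, interior_y])
    rows_b[[p]] <- as.vector(b[interior_x, interior_y])
    rows_c[[p]] <- as.vector(cx[interior_x, interior_y])
    rows_d[[p]] <- as.vector(cy[interior_x, interior_y])
  }
  yv <- unlist(rows_y)
  X_full <- cbind(diffusion = -unlist(rows_b),
                  advection_x = -unlist(rows_c),
                  advection_y = -unlist(rows_d))
  X <- X_full[, active, drop = FALSE]
  cn <- sqrt(colSums(X^2))
  if (any(cn < 1e-300)) {
    stop("uninformative operator(s): ", paste(active[cn < 1e-300], collapse = ", "),
         " (density has no corresponding structure)")
  }
  sv <- svd(X, nu = 0, nv = 0)$d
  if (sv[length(sv)] / sv[1] < 1e-12) {
    stop("rank-deficient weak-form system; density field does not separate the requested operators")
  }
  fit <- stats::lm.fit(X, yv)
  coefs <- stats::setNames(rep(0, 3), c("diffusion", "advection_x", "advection_y"))
  coefs[active] <- fit$coefficients
  g <- gradient_axis / sqrt(sum(gradient_axis^2))
  v <- c(coefs[["advection_x"]], coefs[["advection_y"]])
  res <- yv - X %*% fit$coefficients
  structure(list(D = coefs[["diffusion"]],
                 v_x = v[1], v_y = v[2],
                 v_par = sum(v * g), v_perp = v[1] * (-g[2]) + v[2] * g[1],
                 residual = sqrt(sum(res^2)), rss = sum(res^2),
                 condition = sv[1] / sv[length(sv)],
                 n_equations = length(yv),
                 model_inadequate = coefs[["diffusion"]] < 0),
            class = "motility_params")
}

#' Backward elimination over the advection-diffusion operator library
#'
#' Starting from the full set {diffusion, advection_x, advection_y},
#' repeatedly drops the operator whose removal increases the residual sum
#' of squares by the smallest relative factor, stopping when the smallest
#' factor exceeds `tol`; the surviving set is refit.
#'
#' @param df a `density_field`.
#' @param tol relative RSS-increase threshold that stops elimination.
#' @param gradient_axis gradient direction.
#' @return list: `active` (character), `fit` (`motility_params` of the
#'   surviving model), `history` (data.frame of drops and factors).
#' @export
select_terms <- function(df, tol = 1.5, gradient_axis = c(1, 0)) {
  active <- c("diffusion", "advection_x", "advection_y")
  fit <- infer_motility(df, gradient_axis, active)
  history <- data.frame(dropped = character(), factor = numeric())
  if (is.infinite(tol) && tol > 0) {
    # infinite tolerance disables elimination: full model kept
    return(list(active = active, fit = fit, history = history))
  }
  while (length(active) > 1L) {
    rss0 <- fit$rss
    cand <- lapply(active, function(op) {
      tryCatch(infer_motility(df, gradient_axis, setdiff(active, op)),
               error = function(e) NULL)
    })
    ok <- !vapply(cand, is.null, TRUE)
    if (!any(ok)) break
    factors <- vapply(cand[ok], function(f) f$rss / max(rss0, 1e-300), 0)
    k <- which.min(factors)
    if (factors[k] > tol) break
    dropped <- active[ok][k]
    history <- rbind(history, data.frame(dropped = dropped, factor = factors[k]))
    active <- setdiff(active, dropped)
    fit <- cand[ok][[k]]
  }
  list(active = active, fit = fit, history = history)
}

#' Drug-vs-control normalization of motility parameters
#'
#' Normalized random migration is the diffusivity ratio
#' `D_drug / D_control`; normalized directed motion is the ratio of
#' gradient-aligned velocity fractions
#' `(v_par / |v|)_drug / (v_par / |v|)_control`.
#'
#' @param drug,control `motility_params` objects.
#' @param min_fraction smallest control directed-motion fraction treated
#'   as meaningful; below it the directed-motion ratio is NA (flagged).
#' @return list of class `normalized_motility`:
#'   `normalized_random_migration`, `normalized_directed_motion`,
#'   `directed_motion_defined`.
#' @export
normalize_conditions <- function(drug, control, min_fraction = 1e-6) {
  stopifnot(inherits(drug, "motility_params"), inherits(control, "motility_params"))
  if (control$D <= 0) stop("control diffusivity must be positive")
  frac <- function(m) {
    nv <- sqrt(m$v_par^2 + m$v_perp^2)
    if (nv == 0) return(NA_real_)
    m$v_par / nv
  }
  fc <- frac(control); fd <- frac(drug)
  defined <- is.finite(fc) && abs(fc) > min_fraction
  structure(list(
    normalized_random_migration = drug$D / control$D,
    normalized_directed_motion = if (defined && is.finite(fd)) fd / fc else NA_real_,
    directed_motion_defined = defined), class = "normalized_motility")
}
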