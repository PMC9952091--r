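# Frame-to-frame linking of cell detections into tracks.
#
# Linking is a gated minimum-cost bipartite assignment on nuclear positions
# with a morphology (area) penalty, solved by the Jonker-Volgenant shortest
# augmenting path algorithm. Unmatched tracks enter gap closing with an
# inflated gate; division events are resolved afterwards and parent tracks
# trimmed around mitosis.

#' Tracking parameters
#'
#' @param d_gate maximum nucleus displacement per frame interval, um.
#' @param w_a weight of the relative area-change term in the link cost
#'   `(d/d_gate)^2 + w_a * |dA| / mean(A)`.
#' @param cost_unmatched assignment cost of leaving a detection or track
#'   unmatched; slightly above the cost of a full-gate displacement.
#' @param max_gap maximum number of consecutive missed frames bridged by
#'   gap closing (gate inflated by sqrt(gap + 1)).
#' @param mitosis_gate search radius for daughter cells at a track end, um.
#' @param area_tol relative tolerance on combined daughter area vs parent.
#' @param trim_k frames trimmed off the parent track before a division.
#' @param min_track_len minimum frames for a track to enter oscillation
#'   analysis (long enough to hold two cycles of the long band).
#' @return list of class `track_params`.
#' @export
track_params <- function(d_gate = 30, w_a = 1, cost_unmatched = 1.05,
                         max_gap = 2L, mitosis_gate = 25, area_tol = 0.3,
                         trim_k = 3L, min_track_len = 60L) {
  structure(list(d_gate = d_gate, w_a = w_a, cost_unmatched = cost_unmatched,
                 max_gap = as.integer(max_gap), mitosis_gate = mitosis_gate,
                 area_tol = area_tol, trim_k = as.integer(trim_k),
                 min_track_len = as.integer(min_track_len)),
            class = "track_params")
}

#' Minimum-cost rectangular assignment
#'
#' Jonker-Volgenant shortest augmenting path algorithm (O(n^2 m)).
#' Entries of `Inf` mark forbidden pairs.
#'
#' @param cost numeric cost matrix.
#' @return integer vector `a` with `a[i]` the column assigned to row `i`
#'   (NA where infeasible rows exist is an error; use finite dummy costs to
#'   model unmatched options).
#' @export
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(integer(0))
  transposed <- FALSE
  if (n > m) { cost <- t(cost); n <- nrow(cost); m <- ncol(cost); transposed <- TRUE }
  u <- numeric(n); v <- numeric(m)
  col4row <- rep(NA_integer_, n); row4col <- rep(NA_integer_, m)
  for (cur in seq_len(n)) {
    shortest <- rep(Inf, m)
    came_from <- rep(NA_integer_, m)
    SR <- logical(n); SC <- logical(m)
    sink <- NA_integer_; min_val <- 0; i <- cur
    while (is.na(sink)) {
      SR[i] <- TRUE
      open <- which(!SC)
      r <- min_val + cost[i, open] - u[i] - v[open]
      upd <- r < shortest[open]
      if (any(upd)) {
        shortest[open[upd]] <- r[upd]
        came_from[open[upd]] <- i
      }
      jbest <- open[which.min(shortest[open])]
      if (!is.finite(shortest[jbest])) stop("assignment infeasible: all remaining pairs forbidden")
      min_val <- shortest[jbest]
      SC[jbest] <- TRUE
      if (is.na(row4col[jbest])) sink <- jbest else i <- row4col[jbest]
    }
    u[cur] <- u[cur] + min_val
    others <- which(SR); others <- others[others != cur]
    if (length(others)) u[others] <- u[others] + min_val - shortest[col4row[others]]
    scanned <- which(SC)
    v[scanned] <- v[scanned] - (min_val - shortest[scanned])
    j <- sink
    repeat {
      i <- came_from[j]
      row4col[j] <- i
      jnext <- col4row[i]
      col4row[i] <- j
      if (i == cur) break
      j <- jnext
    }
  }
  if (transposed) row4col else col4row
}

# Link cost matrix between two observation sets; Inf outside the gate.
link_cost_matrix <- function(obs_a, obs_b, d_gate, w_a) {
  ax <- obs_a$nuc_x_um %||% obs_a$x_um; ay <- obs_a$nuc_y_um %||% obs_a$y_um
  bx <- obs_b$nuc_x_um %||% obs_b$x_um; by <- obs_b$nuc_y_um %||% obs_b$y_um
  d2 <- outer(ax, bx, `-`)^2 + outer(ay, by, `-`)^2
  cost <- d2 / (d_gate^2)
  if (w_a > 0 && "area_um2" %in% names(obs_a) && "area_um2" %in% names(obs_b)) {
    dA <- abs(outer(obs_a$area_um2, obs_b$area_um2, `-`))
    Abar <- outer(obs_a$area_um2, obs_b$area_um2, `+`) / 2
    cost <- cost + w_a * dA / Abar
  }
  cost[d2 > d_gate^2] <- Inf
  cost
}

#' Link two frames of detections
#'
#' Gated minimum-cost one-to-one assignment. Unmatched options carry cost
#' `cost_unmatched` each; pairs beyond the gate are forbidden.
#'
#' @param obs_a,obs_b observation data.frames for consecutive frames.
#' @param params a [track_params()].
#' @param d_gate optional gate override (used for gap closing), um.
#' @return list with `pairs` (data.frame i, j, cost), `unmatched_a`,
#'   `unmatched_b` (row indices).
#' @export
link_frames <- function(obs_a, obs_b, params = track_params(), d_gate = NULL) {
  na <- nrow(obs_a); nb <- nrow(obs_b)
  if (na == 0L || nb == 0L) {
    return(list(pairs = data.frame(i = integer(), j = integer(), cost = numeric()),
                unmatched_a = seq_len(na), unmatched_b = seq_len(nb)))
  }
  gate <- d_gate %||% params$d_gate
  cost <- link_cost_matrix(obs_a, obs_b, gate, params$w_a)
  big <- 1e9
  cu <- params$cost_unmatched
  n <- na + nb
  padded <- matrix(big, n, n)
  real <- cost
  real[!is.finite(real)] <- big
  padded[seq_len(na), seq_len(nb)] <- real
  padded[cbind(seq_len(na), nb + seq_len(na))] <- cu
  padded[cbind(na + seq_len(nb), seq_len(nb))] <- cu
  padded[na + seq_len(nb), nb + seq_len(na)] <- 0
  a <- solve_assignment(padded)
  i <- seq_len(na)
  j <- a[i]
  keep <- j <= nb & is.finite(cost[cbind(i, pmin(j, nb))])
  pairs <- data.frame(i = i[keep], j = j[keep],
                      cost = cost[cbind(i[keep], j[keep])])
  list(pairs = pairs,
       unmatched_a = setdiff(i, pairs$i),
       unmatched_b = setdiff(seq_len(nb), pairs$j))
}

#' Build tracks from per-frame observations
#'
#' Sequential frame-by-frame linking with gap closing: tracks missing a
#' match stay active for up to `max_gap` frames with the gate inflated by
#' sqrt(gap + 1); unmatched detections open new tracks.
#'
#' @param obs observation data.frame with columns `frame`, `t_min`,
#'   positions (and optionally `area_um2`, nuclear centroids).
#' @param params a [track_params()].
#' @return object of class `cell_tracks`: list with `observations` (the
#'   input rows plus `track_id`), `tracks` (per-track summary with
#'   `ended_by`), and `stats` (link/gap/new counts).
#' @export
build_tracks <- function(obs, params = track_params()) {
  stopifnot_cols(obs, c("frame", "t_min", "x_um", "y_um"), "observations")
  obs <- obs[order(obs$frame), , drop = FALSE]
  # iterate the full frame range so empty frames age the gap counters
  frames <- seq(min(obs$frame), max(obs$frame))
  obs$track_id <- NA_integer_
  obs$.row <- seq_len(nrow(obs))
  active <- list()   # each: id, row (index into obs), gap
  next_id <- 1L
  n_links <- 0L; n_gaps <- 0L
  closed <- list()
  for (f in frames) {
    det_rows <- which(obs$frame == f)
    det <- obs[det_rows, , drop = FALSE]
    if (length(active)) {
      last_rows <- vapply(active, `[[`, 0L, "row")
      gaps <- vapply(active, `[[`, 0L, "gap")
      prev <- obs[last_rows, , drop = FALSE]
      # per-track inflated gate: handled by scaling distances row-wise
      gate_scale <- sqrt(gaps + 1)
      cost <- link_cost_matrix(prev, det, params$d_gate, params$w_a)
      # re-gate with the inflated per-track radius
      d2 <- outer(prev$nuc_x_um %||% prev$x_um, det$nuc_x_um %||% det$x_um, `-`)^2 +
            outer(prev$nuc_y_um %||% prev$y_um, det$nuc_y_um %||% det$y_um, `-`)^2
      allowed <- sweep(sqrt(d2), 1, params$d_gate * gate_scale, `<=`)
      cost[!allowed] <- Inf
      res <- link_with_cost(cost, params$cost_unmatched)
      matched_tracks <- res$pairs$i
      for (k in seq_len(nrow(res$pairs))) {
        tr <- res$pairs$i[k]; dj <- res$pairs$j[k]
        id <- active[[tr]]$id
        obs$track_id[det_rows[dj]] <- id
        if (active[[tr]]$gap > 0) n_gaps <- n_gaps + 1L
        active[[tr]]$row <- det_rows[dj]
        active[[tr]]$gap <- 0L
        n_links <- n_links + 1L
      }
      # age unmatched tracks; close those beyond max_gap
      keep <- rep(TRUE, length(active))
      for (tr in res$unmatched_a) {
        active[[tr]]$gap <- active[[tr]]$gap + 1L
        if (active[[tr]]$gap > params$max_gap) {
          closed[[length(closed) + 1L]] <- list(id = active[[tr]]$id,
                                                ended_by = "lost")
          keep[tr] <- FALSE
        }
      }
      active <- active[keep]
      new_det <- res$unmatched_b
    } else {
      new_det <- seq_len(nrow(det))
    }
    for (dj in new_det) {
      obs$track_id[det_rows[dj]] <- next_id
      active[[length(active) + 1L]] <- list(id = next_id, row = det_rows[dj], gap = 0L)
      next_id <- next_id + 1L
    }
  }
  for (a in active) {
    ended <- if (obs$frame[a$row] == max(frames)) "end_of_movie" else "lost"
    closed[[length(closed) + 1L]] <- list(id = a$id, ended_by = ended)
  }
  ends <- data.frame(track_id = vapply(closed, `[[`, 0L, "id"),
                     ended_by = vapply(closed, `[[`, "", "ended_by"))
  obs$.row <- NULL
  summ <- do.call(rbind, lapply(split(obs, obs$track_id), function(d) {
    data.frame(track_id = d$track_id[1], start_frame = min(d$frame),
               end_frame = max(d$frame), n_obs = nrow(d))
  }))
  summ$ended_by <- ends$ended_by[match(summ$track_id, ends$track_id)]
  rownames(summ) <- NULL
  structure(list(observations = obs, tracks = summ,
                 stats = list(n_links = n_links, n_gap_bridges = n_gaps,
                              n_tracks = next_id - 1L)),
            class = "cell_tracks")
}

# assignment given a prepared (possibly Inf-gated) cost matrix
link_with_cost <- function(cost, cost_unmatched) {
  na <- nrow(cost); nb <- ncol(cost)
  big <- 1e9
  n <- na + nb
  padded <- matrix(big, n, n)
  real <- cost; real[!is.finite(real)] <- big
  padded[seq_len(na), seq_len(nb)] <- real
  padded[cbind(seq_len(na), nb + seq_len(na))] <- cost_unmatched
  padded[cbind(na + seq_len(nb), seq_len(nb))] <- cost_unmatched
  padded[na + seq_len(nb), nb + seq_len(na)] <- 0
  a <- solve_assignment(padded)
  i <- seq_len(na); j <- a[i]
  keep <- j <= nb & is.finite(cost[cbind(i, pmin(j, nb))])
  pairs <- data.frame(i = i[keep], j = j[keep])
  list(pairs = pairs, unmatched_a = setdiff(i, pairs$i),
       unmatched_b = setdiff(seq_len(nb), pairs$j))
}

#' Detect divisions and trim parent tracks
#'
#' A track ending at frame f is called a division when one or two new
#' tracks start within `mitosis_gate` of its terminus in the following
#' frames and the combined daughter area matches the parent area within
#' `area_tol` (half the parent area for a single visible daughter). The
#' parent's last `trim_k` frames are removed, signaling and morphology
#' being unreliable during mitosis. Three or more candidates are ambiguous
#' and the track is left as lost.
#'
#' @param tr a `cell_tracks` object.
#' @param params a [track_params()].
#' @return the modified `cell_tracks`; trimmed rows are dropped, parents
#'   get `ended_by = "mitosis"` and daughters a `parent_id` column.
#' @export
resolve_mitosis <- function(tr, params = track_params()) {
  stopifnot(inherits(tr, "cell_tracks"))
  obs <- tr$observations; summ <- tr$tracks
  summ$parent_id <- NA_integer_
  drop_rows <- integer(0)
  for (k in which(summ$ended_by == "lost")) {
    pid <- summ$track_id[k]
    f_end <- summ$end_frame[k]
    last <- obs[obs$track_id == pid & obs$frame == f_end, , drop = FALSE]
    cand <- summ[summ$start_frame > f_end & summ$start_frame <= f_end + 2L &
                   summ$track_id != pid, , drop = FALSE]
    if (!nrow(cand)) next
    first_obs <- obs[obs$track_id %in% cand$track_id &
                       obs$frame == ave(obs$frame, obs$track_id, FUN = min), , drop = FALSE]
    first_obs <- first_obs[match(cand$track_id, first_obs$track_id), , drop = FALSE]
    d <- sqrt((first_obs$x_um - last$x_um)^2 + (first_obs$y_um - last$y_um)^2)
    near <- which(d <= params$mitosis_gate)
    if (length(near) == 0L) next
    if (length(near) > 2L) next  # ambiguous: leave as lost
    ok <- FALSE
    if ("area_um2" %in% names(obs)) {
      A_par <- last$area_um2
      A_dgt <- sum(first_obs$area_um2[near])
      target <- if (length(near) == 2L) A_par else A_par / 2
      ok <- abs(A_dgt - target) <= params$area_tol * A_par
    } else ok <- length(near) == 2L
    if (!ok) next
    summ$ended_by[k] <- "mitosis"
    summ$parent_id[match(cand$track_id[near], summ$track_id)] <- pid
    par_rows <- which(obs$track_id == pid)
    par_frames <- obs$frame[par_rows]
    drop_rows <- c(drop_rows, par_rows[par_frames > f_end - params$trim_k])
  }
  if (length(drop_rows)) obs <- obs[-drop_rows, , drop = FALSE]

  # second pattern: the tracker linked the parent straight into one
  # daughter (small displacement beats the area penalty). Signature: a new
  # track starts within the mitosis gate of a continuing track whose area
  # halves across the same frame. Split the continuing track there.
  if ("area_um2" %in% names(obs)) {
    next_id <- max(summ$track_id) + 1L
    for (k in order(summ$start_frame)) {
      did <- summ$track_id[k]
      f_start <- summ$start_frame[k]
      if (f_start == min(obs$frame) || !is.na(summ$parent_id[k])) next
      first <- obs[obs$track_id == did & obs$frame == f_start, , drop = FALSE]
      prev <- obs[obs$frame == f_start - 1L & obs$track_id != did, , drop = FALSE]
      if (!nrow(prev)) next
      d <- sqrt((prev$x_um - first$x_um)^2 + (prev$y_um - first$y_um)^2)
      near <- which(d <= params$mitosis_gate)
      if (length(near) != 1L) next
      pid <- prev$track_id[near]
      A_par <- prev$area_um2[near]
      cont <- obs[obs$track_id == pid & obs$frame == f_start, , drop = FALSE]
      if (!nrow(cont)) next
      halved <- abs(cont$area_um2 - A_par / 2) <= params$area_tol * A_par &
        abs(first$area_um2 - A_par / 2) <= params$area_tol * A_par
      if (!halved) next
      # split: frames >= f_start of pid become a new daughter track
      tail_rows <- which(obs$track_id == pid & obs$frame >= f_start)
      obs$track_id[tail_rows] <- next_id
      summ <- rbind(summ, data.frame(
        track_id = next_id, start_frame = f_start,
        end_frame = summ$end_frame[summ$track_id == pid],
        n_obs = length(tail_rows),
        ended_by = summ$ended_by[summ$track_id == pid],
        parent_id = pid))
      pk <- which(summ$track_id == pid)
      summ$ended_by[pk] <- "mitosis"
      summ$parent_id[k] <- pid
      trim <- which(obs$track_id == pid & obs$frame > f_start - 1L - params$trim_k)
      if (length(trim)) obs <- obs[-trim, , drop = FALSE]
      next_id <- next_id + 1L
    }
  }

  # refresh per-track frame ranges after trimming/splitting
  keep_ids <- unique(obs$track_id)
  summ <- summ[summ$track_id %in% keep_ids, , drop = FALSE]
  newest <- vapply(split(obs$frame, obs$track_id), max, 0)
  oldest <- vapply(split(obs$frame, obs$track_id), min, 0)
  summ$end_frame <- newest[as.character(summ$track_id)]
  summ$start_frame <- oldest[as.character(summ$track_id)]
  rownames(summ) <- NULL
  tr$observations <- obs
  tr$tracks <- summ
  tr
}

#' Instantaneous and mean speed of a track
#'
#' Speed is displacement over elapsed time between consecutive retained
#' observations; bridged gaps contribute displacement divided by the full
#' elapsed time.
#'
#' @param track observation rows of one track, ordered by time.
#' @return list with `speed` (data.frame `t_min`, `speed`; the speed over
#'   the interval starting at `t_min`) and `mean_speed` (um/min), NA for
#'   tracks shorter than 2 observations.
#' @export
compute_speeds <- function(track) {
  track <- track[order(track$t_min), , drop = FALSE]
  n <- nrow(track)
  if (n < 2L) return(list(speed = data.frame(t_min = numeric(), speed = numeric()),
                          mean_speed = NA_real_))
  dtv <- diff(track$t_min)
  disp <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  s <- disp / dtv
  list(speed = data.frame(t_min = track$t_min[-n], speed = s),
       mean_speed = sum(disp) / sum(dtv))
}
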