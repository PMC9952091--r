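# Independent oracles used across the suite. These deliberately take the
# slow, obviously-correct route (enumeration, greedy transport, grid
# search) and stay independent of the package's implementations.

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in perms(n - 1L)) out[[length(out) + 1L]] <- c(i, rest[p])
  }
  out
}

# exhaustive minimum-cost perfect matching on a square matrix
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  best <- Inf; best_p <- NULL
  for (p in perms(n)) {
    s <- sum(cost[cbind(seq_len(n), p)])
    if (s < best) { best <- s; best_p <- p }
  }
  list(cost = best, assignment = best_p)
}

# 1D optimal transport by the north-west-corner rule on sorted atoms
# (optimal for convex costs in one dimension)
transport_emd <- function(a, wa, b, wb) {
  oa <- order(a); ob <- order(b)
  a <- a[oa]; wa <- wa[oa] / sum(wa)
  b <- b[ob]; wb <- wb[ob] / sum(wb)
  i <- 1L; j <- 1L; tot <- 0
  while (i <= length(a) && j <= length(b)) {
    m <- min(wa[i], wb[j])
    tot <- tot + m * abs(a[i] - b[j])
    wa[i] <- wa[i] - m; wb[j] <- wb[j] - m
    if (wa[i] <= 1e-15) i <- i + 1L
    if (j <= length(b) && wb[j] <= 1e-15) j <- j + 1L
  }
  tot
}

pinball <- function(res, tau) sum(res * (tau - (res < 0)))

# best pinball loss over an (a, b) grid
grid_pinball_loss <- function(x, y, tau, a_range = c(-5, 5),
                              b_range = c(-5, 5), step = 0.01) {
  as_ <- seq(a_range[1], a_range[2], by = step)
  bs <- seq(b_range[1], b_range[2], by = step)
  best <- Inf
  for (b in bs) {
    res <- outer(as_, y - b * x, function(a, r) r - a)
    L <- rowSums(res * (tau - (res < 0)))
    m <- min(L)
    if (m < best) best <- m
  }
  best
}

# connected components of a binary mask by queue-based flood fill
flood_fill_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    count <- count + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      p <- queue[length(queue)]; queue <- queue[-length(queue)]
      r <- ((p - 1L) %% nr) + 1L; c <- ((p - 1L) %/% nr) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
          q <- rr + (cc - 1L) * nr
          if (mask[q] && !seen[q]) { seen[q] <- TRUE; queue <- c(queue, q) }
        }
      }
    }
  }
  count
}

# analytic solutions of the advection-diffusion equation on a node grid
diffusing_gaussian_field <- function(D = 1, h = 3, half = 60, times = seq(50, 100, 10)) {
  x <- seq(-half, half, by = h)
  frames <- lapply(times, function(t) {
    outer(x, x, function(a, b) exp(-(a^2 + b^2) / (4 * D * t)) / (4 * pi * D * t))
  })
  density_field(x, x, times, frames)
}

translating_gaussian_field <- function(v = 0.05, s2 = 400, h = 3, half = 60,
                                       times = seq(50, 100, 10)) {
  x <- seq(-half, half, by = h)
  frames <- lapply(times, function(t) {
    outer(x, x, function(a, b) exp(-((a - v * t)^2 + b^2) / (2 * s2)) / (2 * pi * s2))
  })
  density_field(x, x, times, frames)
}

# match measured observations of one frame to ground-truth rows by nearest
# cell centroid; returns truth row indices (NA where no truth within gate)
match_to_truth <- function(obs, truth, gate = 10) {
  if (!nrow(obs)) return(integer(0))
  d2 <- outer(obs$x_um, truth$x_um, `-`)^2 + outer(obs$y_um, truth$y_um, `-`)^2
  idx <- apply(d2, 1, which.min)
  idx[sqrt(d2[cbind(seq_len(nrow(obs)), idx)]) > gate] <- NA_integer_
  idx
}

# small deterministic movie configs used by several test files
quiet_config <- function(...) {
  synth_config(noise_sd = c(erk = 0, akt = 0, aspect_ratio = 0),
               burst_gain = 0, polarization_coupling = 0, ...)
}
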