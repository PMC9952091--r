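# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library calls do not perturb the
#' caller's random stream. All exported stochastic functions route their
#' seeding through this helper, which is what makes pipeline runs
#' reproducible from a config seed alone.
#'
#' @param seed integer seed, or NULL to leave the RNG stream untouched.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Raised-cosine bump: 1 at u = 0, 0 outside |u| > half_width.
raised_cosine <- function(u, half_width) {
  k <- numeric(length(u))
  inside <- abs(u) <= half_width
  k[inside] <- 0.5 * (1 + cos(pi * u[inside] / half_width))
  k
}

rms <- function(x) sqrt(mean(x^2))

clamp <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

# Centered moving average returning a full-length series; edge windows use
# the available samples only (partial means), so no frames are lost.
moving_average <- function(x, width) {
  n <- length(x)
  width <- min(width, n)
  if (width %% 2 == 0) width <- width + 1L
  half <- (width - 1L) / 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_cols <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
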