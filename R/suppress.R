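#' Logarithmically shrinking window schedule for suppression
#'
#' The suppression window starts at half-width `hwi` and shrinks
#' logarithmically over the iterations, ending at a half-width of 1 point
#' (full window = centre +/- 1). Half-widths are `ceiling(10^d)` with `d`
#' stepping linearly from `log10(hwi)` down to 0 across the `it` iterations;
#' with `it = 1` the single half-width is `hwi` itself.
#'
#' @param hwi Initial window half-width in subsampled points, a positive
#'   integer. A good starting value is half the width of the widest peak,
#'   measured in buckets.
#' @param it Number of suppression iterations (each iteration is one
#'   left-to-right plus one right-to-left sweep). Positive integer.
#' @return Integer vector of `it` non-increasing half-widths; the last equals
#'   1 whenever `it >= 2`.
#' @examples
#' window_schedule(15, 20)
#' window_schedule(100, 3)  # 100, 10, 1
#' @export
window_schedule <- function(hwi, it) {
  hwi <- as.integer(hwi)
  it <- as.integer(it)
  if (length(hwi) != 1L || is.na(hwi) || hwi < 1L) abort("`hwi` must be a positive integer.")
  if (length(it) != 1L || is.na(it) || it < 1L) abort("`it` must be a positive integer.")
  d <- seq(log10(hwi), 0, length.out = it)
  # round() guards against ~1e-15 floating-point excess in 10^log10(hwi)
  # pushing the ceiling one point too high
  as.integer(ceiling(round(10^d, 9)))
}

#' One directional suppression sweep
#'
#' Moves a window of the given half-width across the vector in one direction,
#' replacing each value by the minimum of itself and the window mean. The
#' vector is updated in place as the window moves, so each window mean uses
#' values already updated earlier in the same sweep. Near the ends the window
#' is symmetrically shrunk so it stays centred on the cursor.
#'
#' @param v Numeric vector (a subsampled spectrum), non-empty.
#' @param halfwidth Window half-width in points, a positive integer.
#' @param direction `"left-to-right"` or `"right-to-left"`.
#' @return The updated vector; no element ever increases.
#' @examples
#' suppress_sweep(c(0, 0, 10, 0, 0), 1, "left-to-right")  # c(0, 0, 10/3, 0, 0)
#' @export
suppress_sweep <- function(v, halfwidth, direction = c("left-to-right", "right-to-left")) {
  direction <- match.arg(direction)
  if (!is.numeric(v) || length(v) == 0L) abort("`v` must be a non-empty numeric vector.")
  halfwidth <- as.integer(halfwidth)
  if (length(halfwidth) != 1L || is.na(halfwidth) || halfwidth < 1L) {
    abort("`halfwidth` must be a positive integer.")
  }
  n <- length(v)
  idx <- if (direction == "left-to-right") seq_len(n) else rev(seq_len(n))
  for (j in idx) {
    a <- min(halfwidth, j - 1L, n - j)
    m <- mean(v[(j - a):(j + a)])
    if (m < v[j]) v[j] <- m
  }
  v
}

#' Iterative bidirectional suppression
#'
#' The core of the peak-filling estimator: for each half-width in the shrinking
#' schedule, the spectrum is swept left-to-right and then right-to-left with
#' the min(current, window mean) update. Sweeping both ways avoids a biased
#' estimate around peaks; the in-place update speeds convergence.
#'
#' @param v Numeric vector (a subsampled spectrum), non-empty.
#' @param schedule Integer vector of half-widths, typically from
#'   [window_schedule()].
#' @return The suppressed vector; pointwise no larger than the input.
#' @examples
#' suppress(c(0, 0, 10, 0, 0), 1L)  # c(0, 0, 10/9, 0, 0)
#' @export
suppress <- function(v, schedule) {
  if (!is.numeric(schedule) || length(schedule) == 0L || anyNA(schedule) ||
      any(schedule < 1)) {
    abort("`schedule` must be a non-empty vector of positive half-widths.")
  }
  for (hw in schedule) {
    v <- suppress_sweep(v, hw, "left-to-right")
    v <- suppress_sweep(v, hw, "right-to-left")
  }
  v
}
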