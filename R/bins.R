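#' Build a bucket (bin) scheme over the channel index
#'
#' Partitions the channels `1:n_channels` into contiguous buckets, either
#' `bins` near-equal-width buckets or explicit user-supplied edges. During
#' subsampling the minimum intensity in each bucket represents the bucket;
#' during stretching the estimate is anchored at each bucket's centre.
#'
#' @param n_channels Number of channels in the spectra.
#' @param bins Either a single positive integer (number of equal-width
#'   buckets, at least 2 and at most `n_channels`) or a two-column matrix /
#'   data frame of 1-based inclusive `(start, end)` channel indices (see
#'   [read_bin_edges()]). Explicit edges must be ordered, non-overlapping, and
#'   jointly cover every channel.
#'
#' @return A tibble of class `bin_scheme` with columns `bin`, `start`, `end`
#'   (inclusive channel indices) and `centre` (midpoint of the index range,
#'   possibly half-integral), and attribute `n_channels`. Centres are strictly
#'   increasing.
#'
#' @details With a count, the base width is `floor(n_channels / bins)` and the
#'   remainder channels widen the trailing buckets by one channel each, so
#'   widths differ by at most one channel.
#'
#' @examples
#' make_bins(8, 2)            # [1..4], [5..8]; centres 2.5 and 6.5
#' make_bins(10, rbind(c(1, 3), c(4, 10)))
#' @export
make_bins <- function(n_channels, bins) {
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 1L) abort("`n_channels` must be a positive integer.")
  if (is.matrix(bins) || is.data.frame(bins)) {
    edges <- as.matrix(bins)
    if (ncol(edges) != 2L) abort("Explicit `bins` edges must have two columns (start, end).")
    storage.mode(edges) <- "integer"
    if (anyNA(edges)) abort("Explicit `bins` edges contain missing values.")
    start <- edges[, 1L]
    end <- edges[, 2L]
    if (any(end < start)) abort("Each bin must have end >= start.")
    if (start[1L] != 1L) abort(sprintf("bins: edges must start at channel 1, got %d.", start[1L]))
    if (end[length(end)] != n_channels) {
      abort(sprintf("bins: edges must end at channel %d, got %d.", n_channels, end[length(end)]))
    }
    if (length(start) > 1L) {
      gap <- start[-1L] - end[-length(end)]
      if (any(gap > 1L)) abort("bins: gap between consecutive bin edges.")
      if (any(gap < 1L)) abort("bins: overlapping bin edges.")
    }
  } else {
    b <- as.integer(bins)
    if (length(b) != 1L || is.na(b) || b < 2L) {
      abort("`bins` must be an integer >= 2 or a two-column matrix of edges.")
    }
    if (b > n_channels) {
      abort(sprintf("bins (%d) must not exceed the number of channels (%d).", b, n_channels))
    }
    w <- n_channels %/% b
    r <- n_channels %% b
    widths <- c(rep(w, b - r), rep(w + 1L, r))
    end <- cumsum(widths)
    start <- c(1L, head(end, -1L) + 1L)
  }
  scheme <- tibble(
    bin = seq_along(start),
    start = as.integer(start),
    end = as.integer(end),
    centre = (start + end) / 2
  )
  class(scheme) <- c("bin_scheme", class(scheme))
  attr(scheme, "n_channels") <- n_channels
  scheme
}

n_bins <- function(scheme) nrow(scheme)

#' Subsample a spectrum by bucket minima
#'
#' Replaces each bucket of the spectrum by its minimum value, the local
#' representative used by the suppression stage. Using minima simplifies the
#' spectrum while retaining the basic shape of the baseline.
#'
#' @param y Numeric vector; its length must equal the scheme's channel count.
#' @param scheme A [make_bins()] scheme.
#' @return Numeric vector with one value per bucket.
#' @examples
#' subsample_min(c(3, 1, 4, 1, 5, 9, 2, 6), make_bins(8, 2))  # c(1, 2)
#' @export
subsample_min <- function(y, scheme) {
  if (!inherits(scheme, "bin_scheme")) abort("`scheme` must come from make_bins().")
  nc <- attr(scheme, "n_channels")
  if (length(y) != nc) {
    abort(sprintf("`y` has %d channels but the bin scheme covers %d.", length(y), nc))
  }
  vapply(
    seq_len(nrow(scheme)),
    function(j) min(y[scheme$start[j]:scheme$end[j]]),
    numeric(1)
  )
}

# Axis value at a (possibly fractional) channel position, by linear
# interpolation of the axis vector.
axis_at <- function(axis, pos) {
  if (length(axis) == 1L) return(rep(axis, length(pos)))
  approx(seq_along(axis), axis, xout = pos, rule = 2)$y
}
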