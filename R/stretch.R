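#' Stretch a bucket-resolution baseline back to full resolution
#'
#' Places the suppressed values at the bucket centres and interpolates the
#' remaining channels, either piecewise-linearly (fast and robust) or with a
#' shape-preserving piecewise-cubic spline (Fritsch-Carlson monotone Hermite:
#' smooth, and never overshooting beyond adjacent knot values). Channels
#' before the first centre or after the last take the terminal knot value
#' (constant extension).
#'
#' @param suppressed Numeric vector, one value per bucket of `scheme`.
#' @param scheme A [make_bins()] scheme.
#' @param n_channels Number of output channels; defaults to the scheme's.
#' @param method `"linear"` or `"spline"`.
#' @param at Positions (on the channel-index axis) at which to evaluate the
#'   baseline; defaults to the integer channels `1:n_channels`. Evaluating at
#'   the bucket centres reproduces `suppressed`.
#' @return Numeric vector of baseline values, one per element of `at`.
#' @examples
#' sch <- make_bins(8, 2)
#' stretch(c(1, 3), sch)  # c(1, 1, 1.25, 1.75, 2.25, 2.75, 3, 3)
#' @export
stretch <- function(suppressed, scheme, n_channels = attr(scheme, "n_channels"),
                    method = c("linear", "spline"), at = NULL) {
  if (!inherits(scheme, "bin_scheme")) abort("`scheme` must come from make_bins().")
  if (is.character(method) && length(method) == 1L &&
      !method %in% c("linear", "spline")) {
    abort(sprintf("Unknown interpolation method \"%s\"; use \"linear\" or \"spline\".", method))
  }
  method <- match.arg(method)
  if (length(suppressed) != nrow(scheme)) {
    abort(sprintf(
      "`suppressed` has %d values but the scheme has %d bins.",
      length(suppressed), nrow(scheme)
    ))
  }
  if (is.null(at)) at <- seq_len(n_channels)
  x <- scheme$centre
  if (length(x) == 1L) return(rep(as.double(suppressed), length(at)))
  # constant extension past the terminal knots
  at_clamped <- pmin(pmax(at, x[1L]), x[length(x)])
  if (method == "linear") {
    approx(x, suppressed, xout = at_clamped, method = "linear")$y
  } else {
    splinefun(x, suppressed, method = "monoH.FC")(at_clamped)
  }
}
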