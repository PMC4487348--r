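#' Estimate spectral baselines by 4S peak filling
#'
#' Runs the full peak-filling pipeline on each spectrum: (1) smoothing with a
#' Whittaker second-derivative penalty, (2) subsampling into buckets by the
#' bucket minimum, (3) iterative bidirectional moving-window suppression with
#' a logarithmically shrinking window, (4) stretching back to full resolution
#' by interpolation at the bucket centres. All spectra in the set share one
#' bin scheme and one window schedule; rows are processed independently.
#'
#' @param data Spectra: a [spectra_set()], a long data frame with columns
#'   `axis`, `intensity` and optionally `spectrum` (see [as_spectra()]), a
#'   numeric matrix (rows = spectra), or a single numeric vector.
#' @param hwi Initial suppression window half-width in buckets (positive
#'   integer). No universal default exists: start from half the width of the
#'   widest peak, measured in buckets.
#' @param lambda Whittaker penalty on the log10 scale (default 4, i.e.
#'   \eqn{10^4}, which typically centres the baseline in the noise band);
#'   `NULL` or `NA` skips smoothing, placing the baseline at the bottom of the
#'   noise band.
#' @param bins Number of equal-width buckets, or a two-column matrix of
#'   1-based inclusive `(start, end)` channel edges for variable-width
#'   buckets. Default: one bucket per 10 channels (`round(n/10)`).
#' @param it Number of suppression iterations (default 10).
#' @param interp Stretching method, `"linear"` (default) or `"spline"`
#'   (shape-preserving cubic).
#' @param ... Passed between methods.
#'
#' @return An object of class `peakfill_fit` with elements `spectra`,
#'   `scheme` (the [make_bins()] scheme), `schedule` (the [window_schedule()]),
#'   `params`, and matrices `smoothed`, `subsampled`, `suppressed` (one row
#'   per spectrum; the last two have one column per bucket) and `baseline`
#'   (full resolution). Use [tidy()] for a long per-channel tibble, [glance()]
#'   for a one-row summary, [subtract_baseline()] for correction, and
#'   [autoplot()] to visualise.
#'
#' @details Suppression never raises a value, so `suppressed <= subsampled`
#'   bucket-wise, and the stretched baseline equals the suppressed value at
#'   every bucket centre. Spectra shorter than twice the number of buckets
#'   are rejected. The estimator is deterministic.
#'
#' @examples
#' y <- 50 * exp(-(1:600) / 300) + dnorm(1:600, 300, 8) * 400
#' fit <- fill_peaks(y, hwi = 4, lambda = NA, bins = 60, it = 10)
#' head(tidy(fit))
#' glance(fit)
#' @export
fill_peaks <- function(data, ...) UseMethod("fill_peaks")

#' @rdname fill_peaks
#' @export
fill_peaks.data.frame <- function(data, ...) fill_peaks(as_spectra(data), ...)

#' @rdname fill_peaks
#' @export
fill_peaks.numeric <- function(data, ...) fill_peaks(spectra_set(data), ...)

#' @rdname fill_peaks
#' @export
fill_peaks.matrix <- function(data, ...) fill_peaks(spectra_set(data), ...)

#' @rdname fill_peaks
#' @export
fill_peaks.spectra_set <- function(data, hwi, lambda = 4, bins = NULL, it = 10,
                                   interp = c("linear", "spline"), ...) {
  nc <- n_channels(data)
  ns <- n_spectra(data)
  if (missing(hwi)) abort("`hwi` is required: half the width of the widest peak, in buckets.")
  if (is.null(bins)) bins <- max(2L, as.integer(round(nc / 10)))
  if (!(is.matrix(bins) || is.data.frame(bins))) {
    if (nc < 2L * as.integer(bins)) {
      abort(sprintf(
        "Spectra have %d channels, fewer than 2 x bins (%d); reduce `bins`.",
        nc, as.integer(bins)
      ))
    }
  }
  if (is.character(interp) && length(interp) == 1L &&
      !interp %in% c("linear", "spline")) {
    abort(sprintf("Unknown interp method \"%s\"; use \"linear\" or \"spline\".", interp))
  }
  interp <- match.arg(interp)
  scheme <- make_bins(nc, bins)
  schedule <- window_schedule(hwi, it)

  nb <- nrow(scheme)
  smoothed <- matrix(NA_real_, ns, nc)
  subsampled <- matrix(NA_real_, ns, nb)
  suppressed <- matrix(NA_real_, ns, nb)
  baseline <- matrix(NA_real_, ns, nc)
  for (i in seq_len(ns)) {
    z <- whittaker_smooth(data$intensities[i, ], lambda)
    s <- subsample_min(z, scheme)
    p <- suppress(s, schedule)
    smoothed[i, ] <- z
    subsampled[i, ] <- s
    suppressed[i, ] <- p
    baseline[i, ] <- stretch(p, scheme, nc, method = interp)
  }
  structure(
    list(
      spectra = data, scheme = scheme, schedule = schedule,
      params = list(
        lambda = if (is.null(lambda)) NA_real_ else as.double(lambda),
        bins = nb, hwi = as.integer(hwi), it = as.integer(it), interp = interp
      ),
      smoothed = smoothed, subsampled = subsampled,
      suppressed = suppressed, baseline = baseline
    ),
    class = "peakfill_fit"
  )
}

#' @export
print.peakfill_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    paste0(
      "<peakfill_fit: %d spectrum/spectra x %d channels>\n",
      "  lambda(log10) = %s, bins = %d, hwi = %d, it = %d, interp = %s\n",
      "  window schedule: %s\n"
    ),
    n_spectra(x$spectra), n_channels(x$spectra),
    if (is.na(p$lambda)) "none" else format(p$lambda), p$bins, p$hwi, p$it, p$interp,
    paste(x$schedule, collapse = " ")
  ))
  invisible(x)
}

#' Subtract an estimated baseline from the original spectra
#'
#' Corrected intensities are `original - baseline`, channel by channel.
#' Negative values are expected and preserved: with smoothing enabled the
#' baseline runs through the middle of the noise band, so corrected noise
#' scatters around zero.
#'
#' @param data The original [spectra_set()] (or anything [fill_peaks()]
#'   accepts).
#' @param fit The corresponding `peakfill_fit`.
#' @return A [spectra_set()] of corrected spectra on the same axis.
#' @export
subtract_baseline <- function(data, fit) {
  if (!inherits(fit, "peakfill_fit")) abort("`fit` must be a peakfill_fit object.")
  if (is.data.frame(data)) data <- as_spectra(data)
  if (!inherits(data, "spectra_set")) data <- spectra_set(data)
  if (!all(dim(data$intensities) == dim(fit$baseline))) {
    abort(sprintf(
      "Shape mismatch: spectra are %d x %d but the baseline is %d x %d.",
      nrow(data$intensities), ncol(data$intensities),
      nrow(fit$baseline), ncol(fit$baseline)
    ))
  }
  spectra_set(data$intensities - fit$baseline, axis = data$axis)
}

#' Tidy a peak-filling fit into a long per-channel tibble
#'
#' @param x A `peakfill_fit`.
#' @param ... Unused.
#' @return A tibble with one row per (spectrum, channel): `spectrum`,
#'   `channel`, `axis`, `intensity`, `smoothed`, `baseline`, `corrected`.
#' @export
tidy.peakfill_fit <- function(x, ...) {
  out <- tidy(x$spectra)
  out$smoothed <- as.vector(t(x$smoothed))
  out$baseline <- as.vector(t(x$baseline))
  out$corrected <- out$intensity - out$baseline
  out
}

#' One-row summary of a peak-filling fit
#'
#' @param x A `peakfill_fit`.
#' @param ... Unused.
#' @return A one-row tibble: the parameters, the final window half-width, and
#'   the mean estimated baseline level.
#' @export
glance.peakfill_fit <- function(x, ...) {
  p <- x$params
  tibble(
    n_spectra = n_spectra(x$spectra),
    n_channels = n_channels(x$spectra),
    n_bins = p$bins,
    lambda = p$lambda,
    hwi = p$hwi,
    it = p$it,
    interp = p$interp,
    final_halfwidth = x$schedule[length(x$schedule)],
    mean_baseline = mean(x$baseline)
  )
}

#' Plot spectra with their estimated baselines
#'
#' @param object A `peakfill_fit`.
#' @param spectrum Which spectra (row indices) to show; default all.
#' @param corrected Also show the corrected signal panel? Default `TRUE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.peakfill_fit <- function(object, spectrum = NULL, corrected = TRUE, ...) {
  df <- tidy(object)
  if (!is.null(spectrum)) df <- df[df$spectrum %in% spectrum, ]
  long <- tidyr::pivot_longer(
    df,
    cols = c("intensity", "baseline", if (corrected) "corrected"),
    names_to = "series", values_to = "value"
  )
  long$panel <- ifelse(long$series == "corrected", "corrected", "spectrum + baseline")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$axis, y = .data$value, colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(
      ggplot2::vars(.data$panel),
      ggplot2::vars(.data$spectrum),
      scales = "free_y"
    ) +
    ggplot2::labs(x = "axis", y = "intensity", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Root-mean-square error of an estimated baseline against a known truth
#'
#' Scoring hook for simulations: compares a fitted baseline with the
#' generator's stored ground truth, optionally restricted to peak-free
#' channels.
#'
#' @param fit A `peakfill_fit` or a numeric baseline vector.
#' @param truth Numeric vector of true baseline values.
#' @param mask Optional logical vector marking the channels to score (e.g. the
#'   peak-free mask from [generate_spectra()]); default all channels.
#' @param spectrum Row of the fit to score when `fit` holds several spectra.
#' @return The RMSE, a single number.
#' @export
baseline_rmse <- function(fit, truth, mask = NULL, spectrum = 1L) {
  est <- if (inherits(fit, "peakfill_fit")) fit$baseline[spectrum, ] else as.double(fit)
  if (length(est) != length(truth)) abort("Estimate and truth lengths differ.")
  if (is.null(mask)) mask <- rep(TRUE, length(truth))
  sqrt(mean((est[mask] - truth[mask])^2))
}
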