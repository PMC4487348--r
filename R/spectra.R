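#' Construct a set of spectra on a common axis
#'
#' A `spectra_set` holds one or more 1-D spectra sampled on a shared, strictly
#' increasing axis (m/z, wavelength in nm, or plain channel index). It is the
#' input and output currency of the baseline-estimation functions.
#'
#' @param intensities Numeric matrix (one row per spectrum, one column per
#'   channel) or a numeric vector for a single spectrum.
#' @param axis Numeric vector of axis values, one per channel, strictly
#'   increasing. Defaults to the channel index `1:n`.
#'
#' @return An object of class `spectra_set`: a list with elements `axis`
#'   (numeric vector) and `intensities` (numeric matrix).
#'
#' @details All values must be finite; non-finite intensities or axis values
#'   are rejected, as is a non-increasing axis.
#'
#' @examples
#' s <- spectra_set(rbind(sin(1:100), cos(1:100)), axis = seq(400, 500, length.out = 100))
#' s
#' tidy(s)
#' @export
spectra_set <- function(intensities, axis = NULL) {
  if (is.data.frame(intensities)) intensities <- as.matrix(intensities)
  if (is.vector(intensities) && is.numeric(intensities)) {
    intensities <- matrix(intensities, nrow = 1L)
  }
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    abort("`intensities` must be a numeric matrix or vector.")
  }
  storage.mode(intensities) <- "double"
  n <- ncol(intensities)
  if (n < 1L) abort("`intensities` must have at least one channel.")
  if (is.null(axis)) axis <- as.double(seq_len(n))
  axis <- as.double(axis)
  if (length(axis) != n) {
    abort(sprintf("`axis` has %d values but there are %d channels.", length(axis), n))
  }
  if (anyNA(axis) || any(!is.finite(axis))) abort("`axis` contains non-finite values.")
  if (n > 1L && any(diff(axis) <= 0)) abort("`axis` must be strictly increasing.")
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    abort("`intensities` contains missing or non-finite values.")
  }
  dimnames(intensities) <- NULL
  structure(list(axis = axis, intensities = intensities), class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf(
    "<spectra_set: %d spectrum/spectra x %d channels, axis [%g, %g]>\n",
    nrow(x$intensities), ncol(x$intensities), x$axis[1], x$axis[length(x$axis)]
  ))
  invisible(x)
}

n_channels <- function(x) ncol(x$intensities)
n_spectra <- function(x) nrow(x$intensities)

#' Convert a long data frame of spectra to a `spectra_set`
#'
#' Expects one row per (spectrum, channel) observation with columns giving the
#' axis position and intensity, and optionally a spectrum identifier. All
#' spectra must share the same axis.
#'
#' @param data A data frame.
#' @param axis,intensity,spectrum Column names (strings) holding the axis
#'   values, intensities, and the spectrum identifier. `spectrum` may be absent
#'   for a single spectrum.
#' @return A [spectra_set()].
#' @examples
#' df <- tibble::tibble(axis = 1:50, intensity = exp(-(1:50) / 20))
#' as_spectra(df)
#' @export
as_spectra <- function(data, axis = "axis", intensity = "intensity",
                       spectrum = "spectrum") {
  if (inherits(data, "spectra_set")) return(data)
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  for (col in c(axis, intensity)) {
    if (!col %in% names(data)) abort(sprintf("Column `%s` not found in `data`.", col))
  }
  if (!spectrum %in% names(data)) {
    data[[spectrum]] <- 1L
  }
  wide <- tidyr::pivot_wider(
    data[, c(spectrum, axis, intensity)],
    names_from = dplyr::all_of(axis), values_from = dplyr::all_of(intensity)
  )
  ax <- as.double(names(wide)[-1L])
  if (anyNA(ax)) abort("Axis values must be numeric and shared across spectra.")
  m <- as.matrix(wide[, -1L, drop = FALSE])
  if (anyNA(m)) abort("Spectra do not share a common axis (missing cells after widening).")
  o <- order(ax)
  spectra_set(m[, o, drop = FALSE], axis = ax[o])
}

#' Tidy a `spectra_set` into a long tibble
#'
#' @param x A [spectra_set()].
#' @param ... Unused.
#' @return A tibble with columns `spectrum`, `channel`, `axis`, `intensity`.
#' @export
tidy.spectra_set <- function(x, ...) {
  ns <- n_spectra(x)
  nc <- n_channels(x)
  tibble(
    spectrum = rep(seq_len(ns), each = nc),
    channel = rep(seq_len(nc), times = ns),
    axis = rep(x$axis, times = ns),
    intensity = as.vector(t(x$intensities))
  )
}

#' Read spectra from a delimited text file
#'
#' The on-disk format is one row per spectrum, one column per channel,
#' comma- or tab-separated (detected automatically), with an optional first
#' header row holding the axis values.
#'
#' @param path Path to the file.
#' @param header Logical: does the first row hold axis values? Default `TRUE`.
#' @return A [spectra_set()].
#' @seealso [write_spectra()] for the inverse; the round trip preserves 15
#'   significant digits.
#' @export
read_spectra <- function(path, header = TRUE) {
  if (!file.exists(path)) abort(sprintf("Input file not found: %s", path))
  dt <- data.table::fread(path, header = FALSE, sep = "auto", data.table = FALSE)
  m <- as.matrix(dt)
  if (!is.numeric(m)) abort(sprintf("Non-numeric values in spectra file: %s", path))
  if (header) {
    if (nrow(m) < 2L) abort("File has a header row but no spectra.")
    spectra_set(m[-1L, , drop = FALSE], axis = m[1L, ])
  } else {
    spectra_set(m)
  }
}

fmt_row <- function(x, sep) paste(sprintf("%.15g", x), collapse = sep)

#' Write spectra to a delimited text file
#'
#' @param x A [spectra_set()] or numeric matrix.
#' @param path Output path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @param header Write the axis values as a first row? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path, sep = ",", header = TRUE) {
  if (!inherits(x, "spectra_set")) x <- spectra_set(x)
  lines <- apply(x$intensities, 1L, fmt_row, sep = sep)
  if (header) lines <- c(fmt_row(x$axis, sep), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read custom bin edges from a two-column delimited file
#'
#' Each row gives the 1-based inclusive (start, end) channel indices of one
#' bucket; buckets must be ordered, non-overlapping, and jointly cover every
#' channel of the spectra they are applied to.
#'
#' @param path Path to a two-column comma- or tab-separated file.
#' @return A two-column integer matrix with columns `start`, `end`.
#' @export
read_bin_edges <- function(path) {
  if (!file.exists(path)) abort(sprintf("Bin-edges file not found: %s", path))
  dt <- data.table::fread(path, header = FALSE, sep = "auto", data.table = FALSE)
  if (ncol(dt) != 2L) abort("Bin-edges file must have exactly two columns (start, end).")
  m <- as.matrix(dt)
  storage.mode(m) <- "integer"
  colnames(m) <- c("start", "end")
  m
}
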