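#' Construct a labelled Raman spectrum
#'
#' A spectrum is a strictly increasing wavenumber axis (cm^-1) paired with an
#' intensity vector in arbitrary counts, plus an optional species label.
#' Axes supplied in descending order are reordered ascending together with
#' their intensities.
#'
#' @param wavenumber Numeric vector of wavenumbers (cm^-1), length >= 2.
#' @param intensity Numeric vector of intensities, same length as `wavenumber`.
#' @param label Species name; empty string for unlabelled spectra.
#' @return An object of class `raman_spectrum` with fields `wavenumber`,
#'   `intensity` and `label`.
#' @export
raman_spectrum <- function(wavenumber, intensity, label = "") {
  if (length(wavenumber) != length(intensity)) {
    stop_ramanmf("axis and intensity lengths differ (%d vs %d)",
                 length(wavenumber), length(intensity),
                 class = "ramanmf_size_error")
  }
  if (length(wavenumber) < 2) {
    stop_ramanmf("a spectrum needs at least 2 points, got %d",
                 length(wavenumber), class = "ramanmf_size_error")
  }
  if (anyNA(wavenumber) || anyNA(intensity) ||
      any(!is.finite(wavenumber)) || any(!is.finite(intensity))) {
    stop_ramanmf("non-finite values in spectrum", class = "ramanmf_value_error")
  }
  if (anyDuplicated(wavenumber)) {
    stop_ramanmf("duplicate wavenumbers in spectrum axis",
                 class = "ramanmf_axis_error")
  }
  ord <- order(wavenumber)
  structure(
    list(wavenumber = as.numeric(wavenumber[ord]),
         intensity = as.numeric(intensity[ord]),
         label = as.character(label)),
    class = "raman_spectrum")
}

#' @exportS3Method base::print
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %s: %d points, %.1f-%.1f cm^-1\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' @exportS3Method base::length
length.raman_spectrum <- function(x) length(x$wavenumber)

#' Resample a spectrum onto a target wavenumber axis
#'
#' Linear interpolation; extrapolation outside the source axis is refused so
#' that reference spectra are never invented beyond their measured range.
#'
#' @param s A `raman_spectrum`.
#' @param axis Target wavenumbers, all within `range(s$wavenumber)`.
#' @return A `raman_spectrum` on `axis` with the same label.
#' @export
resample_to_axis <- function(s, axis) {
  stopifnot(inherits(s, "raman_spectrum"))
  axis <- sort(as.numeric(axis))
  if (min(axis) < min(s$wavenumber) || max(axis) > max(s$wavenumber)) {
    stop_ramanmf(
      "target axis [%g, %g] extends beyond spectrum range [%g, %g]",
      min(axis), max(axis), min(s$wavenumber), max(s$wavenumber),
      class = "ramanmf_range_error")
  }
  y <- stats::approx(s$wavenumber, s$intensity, xout = axis,
                     method = "linear", ties = "ordered")$y
  structure(list(wavenumber = axis, intensity = y, label = s$label),
            class = "raman_spectrum")
}

#' Construct a hyperspectral cube
#'
#' The cube is the experimental data matrix handed to NMF: one row per pixel,
#' one column per wavenumber. Pixels are stored row-major with the origin at
#' the top-left corner and x varying fastest, so row `(iy - 1) * nx + ix`
#' holds pixel `(ix, iy)`.
#'
#' @param intensity Numeric matrix, `nx * ny` rows by `length(axis)` columns.
#' @param axis Wavenumber axis (cm^-1), strictly increasing.
#' @param nx,ny Grid dimensions in pixels.
#' @param step_x,step_y Stage step sizes in micrometres (metadata only).
#' @param excitation_nm Laser excitation wavelength (metadata only).
#' @return An object of class `hyper_cube`.
#' @export
hyper_cube <- function(intensity, axis, nx, ny,
                       step_x = 1, step_y = 1, excitation_nm = 785) {
  intensity <- as.matrix(intensity)
  if (nx < 1 || ny < 1) {
    stop_ramanmf("grid dimensions must be >= 1", class = "ramanmf_size_error")
  }
  if (nrow(intensity) != nx * ny) {
    stop_ramanmf("cube has %d rows but nx * ny = %d", nrow(intensity),
                 nx * ny, class = "ramanmf_size_error")
  }
  if (ncol(intensity) != length(axis)) {
    stop_ramanmf("cube has %d columns but axis length %d", ncol(intensity),
                 length(axis), class = "ramanmf_size_error")
  }
  if (is.unsorted(axis, strictly = TRUE)) {
    ord <- order(axis)
    axis <- axis[ord]
    intensity <- intensity[, ord, drop = FALSE]
  }
  structure(
    list(intensity = unname(intensity), axis = as.numeric(axis),
         nx = as.integer(nx), ny = as.integer(ny),
         step_x = step_x, step_y = step_y,
         excitation_nm = excitation_nm),
    class = "hyper_cube")
}

#' @exportS3Method base::print
print.hyper_cube <- function(x, ...) {
  cat(sprintf(
    "<hyper_cube> %d x %d pixels (%d spectra), %d wavenumbers, %g nm excitation\n",
    x$nx, x$ny, nrow(x$intensity), length(x$axis), x$excitation_nm))
  invisible(x)
}

#' @exportS3Method base::dim
dim.hyper_cube <- function(x) dim(x$intensity)

#' Convert between pixel coordinates and cube row index
#'
#' The linearization is bijective: `pixel_index(ix, iy, nx)` maps grid
#' coordinates to the cube row, `pixel_coords` inverts it.
#'
#' @param ix,iy 1-based pixel column (x) and row (y) indices.
#' @param nx Grid width in pixels.
#' @return `pixel_index`: integer row index; `pixel_coords`: list with `ix`,
#'   `iy`.
#' @export
pixel_index <- function(ix, iy, nx) {
  (as.integer(iy) - 1L) * as.integer(nx) + as.integer(ix)
}

#' @rdname pixel_index
#' @param row Cube row index.
#' @export
pixel_coords <- function(row, nx) {
  row <- as.integer(row) - 1L
  list(ix = row %% as.integer(nx) + 1L, iy = row %/% as.integer(nx) + 1L)
}

#' Build a reference spectral library
#'
#' All reference spectra are resampled onto a common axis (typically the
#' cube's axis restricted to the overlap of every reference's range) so that
#' cosine scoring compares vectors of equal length.
#'
#' @param spectra List of labelled `raman_spectrum` objects; labels unique.
#' @param axis Optional common axis. Default: axis of the first spectrum
#'   restricted to the range shared by all spectra.
#' @return An object of class `reference_library`.
#' @export
reference_library <- function(spectra, axis = NULL) {
  if (length(spectra) < 1) {
    stop_ramanmf("reference library needs at least one spectrum",
                 class = "ramanmf_size_error")
  }
  labels <- vapply(spectra, function(s) s$label, character(1))
  if (any(!nzchar(labels))) {
    stop_ramanmf("all library spectra must be labelled",
                 class = "ramanmf_value_error")
  }
  if (anyDuplicated(labels)) {
    stop_ramanmf("duplicate labels in reference library: %s",
                 paste(labels[duplicated(labels)], collapse = ", "),
                 class = "ramanmf_value_error")
  }
  lo <- max(vapply(spectra, function(s) min(s$wavenumber), numeric(1)))
  hi <- min(vapply(spectra, function(s) max(s$wavenumber), numeric(1)))
  if (lo >= hi) {
    stop_ramanmf("reference spectra share no common wavenumber range",
                 class = "ramanmf_axis_error")
  }
  if (is.null(axis)) {
    ax <- spectra[[1]]$wavenumber
    axis <- ax[ax >= lo & ax <= hi]
  } else {
    axis <- sort(as.numeric(axis))
    if (min(axis) < lo || max(axis) > hi) {
      stop_ramanmf("library axis [%g, %g] outside shared range [%g, %g]",
                   min(axis), max(axis), lo, hi,
                   class = "ramanmf_range_error")
    }
  }
  spectra <- lapply(spectra, resample_to_axis, axis = axis)
  names(spectra) <- labels
  structure(list(spectra = spectra, axis = axis, labels = labels),
            class = "reference_library")
}

#' @exportS3Method base::print
print.reference_library <- function(x, ...) {
  cat(sprintf("<reference_library> %d species on %d-point axis: %s\n",
              length(x$spectra), length(x$axis),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

# internal: classed condition helper so callers can test on error class
stop_ramanmf <- function(fmt, ..., class) {
  dots <- list(...)
  msg <- if (length(dots)) do.call(sprintf, c(list(fmt), dots)) else fmt
  stop(errorCondition(msg, class = c(class, "ramanmf_error")))
}
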