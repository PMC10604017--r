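#' Read a long-format hyperspectral map
#'
#' Parses the text dialect exported by mapping spectrometers: one line per
#' (pixel, wavenumber) pair with columns X (um), Y (um), wavenumber (cm^-1)
#' and intensity (counts). Tab or comma delimiters are auto-detected and an
#' optional header line is skipped. Pixels are normalized to row-major order
#' (origin top-left, x fastest) regardless of the acquisition raster order,
#' and the axis is sorted ascending.
#'
#' @param path Path to the map file.
#' @param columns Integer vector of length 4 giving the positions of the
#'   x, y, wavenumber and intensity columns. Default `1:4`.
#' @param excitation_nm Excitation wavelength stored as metadata.
#' @return A [hyper_cube()].
#' @export
read_map_text <- function(path, columns = 1:4, excitation_nm = 785) {
  if (!file.exists(path)) {
    stop_ramanmf("map file not found: %s", path, class = "ramanmf_io_error")
  }
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first)) {
    stop_ramanmf("map file is empty: %s", path, class = "ramanmf_io_error")
  }
  sep <- detect_sep(first)
  fields <- strsplit(trimws(first), if (sep == " ") "[ \t]+" else sep)[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(fields[columns[1]])))
  dat <- utils::read.table(path, sep = if (sep == " ") "" else sep,
                           header = has_header, colClasses = "numeric")
  x <- dat[[columns[1]]]
  y <- dat[[columns[2]]]
  wn <- dat[[columns[3]]]
  iv <- dat[[columns[4]]]

  xs <- sort(unique(x))
  ys <- sort(unique(y))
  axis <- sort(unique(wn))
  nx <- length(xs)
  ny <- length(ys)
  nw <- length(axis)
  if (nrow(dat) != nx * ny * nw) {
    # locate one missing pixel for the error message
    have <- unique(paste(x, y))
    want <- as.vector(outer(xs, ys, paste))
    missing <- setdiff(want, have)
    if (length(missing)) {
      stop_ramanmf("incomplete grid: no spectrum at (x, y) = (%s)",
                   sub(" ", ", ", missing[1]),
                   class = "ramanmf_grid_error")
    }
    stop_ramanmf(
      "inconsistent wavenumber axes across pixels (%d lines for %d x %d x %d grid)",
      nrow(dat), nx, ny, nw, class = "ramanmf_axis_error")
  }
  ix <- match(x, xs)
  iy <- match(y, ys)
  iw <- match(wn, axis)
  row <- pixel_index(ix, iy, nx)
  cell <- (row - 1L) * nw + iw
  if (anyDuplicated(cell)) {
    stop_ramanmf("duplicate (pixel, wavenumber) entries in %s", path,
                 class = "ramanmf_grid_error")
  }
  mat <- matrix(NA_real_, nrow = nx * ny, ncol = nw)
  mat[cbind(row, iw)] <- iv
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    pc <- pixel_coords(bad[1], nx)
    stop_ramanmf(
      "inconsistent wavenumber axes: pixel (x = %g, y = %g) lacks %g cm^-1",
      xs[pc$ix], ys[pc$iy], axis[bad[2]], class = "ramanmf_axis_error")
  }
  step_x <- if (nx > 1) stats::median(diff(xs)) else 1
  step_y <- if (ny > 1) stats::median(diff(ys)) else 1
  hyper_cube(mat, axis, nx, ny, step_x = step_x, step_y = step_y,
             excitation_nm = excitation_nm)
}

#' Write a hyperspectral cube as long-format map text
#'
#' Inverse of [read_map_text()]: emits one line per (pixel, wavenumber) pair
#' in row-major pixel order, so a read/write round trip reproduces the
#' intensity matrix exactly.
#'
#' @param cube A [hyper_cube()].
#' @param path Output path.
#' @param sep Field delimiter.
#' @export
write_map_text <- function(cube, path, sep = "\t") {
  stopifnot(inherits(cube, "hyper_cube"))
  nw <- length(cube$axis)
  np <- nrow(cube$intensity)
  pc <- pixel_coords(seq_len(np), cube$nx)
  # %.17g keeps doubles bit-exact through the text round trip
  df <- data.frame(
    x = sprintf("%.17g", rep((pc$ix - 1) * cube$step_x, each = nw)),
    y = sprintf("%.17g", rep((pc$iy - 1) * cube$step_y, each = nw)),
    wavenumber = sprintf("%.17g", rep(cube$axis, times = np)),
    intensity = sprintf("%.17g", as.vector(t(cube$intensity))))
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-column reference spectrum
#'
#' @param path Path to a delimited text file with wavenumber and intensity
#'   columns (no header, or a header line that is skipped automatically).
#' @param label Species name to attach.
#' @return A labelled [raman_spectrum()], axis ascending.
#' @export
read_reference <- function(path, label = "") {
  if (!file.exists(path)) {
    stop_ramanmf("reference file not found: %s", path,
                 class = "ramanmf_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    stop_ramanmf("reference file is empty: %s", path,
                 class = "ramanmf_io_error")
  }
  sep <- detect_sep(lines[[1]])
  split_fields <- function(line) {
    strsplit(trimws(line), if (sep == " ") "[ \t]+" else sep,
             fixed = sep != " ")[[1]]
  }
  start <- 1L
  probe <- split_fields(lines[[1]])
  if (is.na(suppressWarnings(as.numeric(probe[1])))) start <- 2L
  if (length(lines) - start + 1L < 2) {
    stop_ramanmf("reference needs at least 2 data rows, got %d",
                 length(lines) - start + 1L, class = "ramanmf_size_error")
  }
  n <- length(lines) - start + 1L
  wn <- numeric(n)
  iv <- numeric(n)
  for (i in seq_len(n)) {
    fields <- split_fields(lines[[start + i - 1L]])
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (anyNA(vals)) {
      stop_ramanmf("non-numeric value at line %d of %s: '%s'",
                   start + i - 1L, path, lines[[start + i - 1L]],
                   class = "ramanmf_parse_error")
    }
    wn[i] <- vals[1]
    iv[i] <- vals[2]
  }
  raman_spectrum(wn, iv, label = label)
}

#' Write a similarity grid as a delimited table
#'
#' Produces the human-readable table (scores rounded to 2 decimals, matching
#' the conventional presentation of similarity grids) plus an unrounded
#' machine copy alongside it.
#'
#' @param grid A `similarity_grid` (see [score_ladder()]).
#' @param path Output CSV path for the rounded table.
#' @param raw_path Path for the unrounded copy; default inserts `_raw`
#'   before the extension.
#' @return Invisibly, `c(path, raw_path)`.
#' @export
write_similarity_table <- function(grid, path, raw_path = NULL) {
  stopifnot(inherits(grid, "similarity_grid"))
  df <- grid$scores
  if (!nrow(df)) {
    stop_ramanmf("refusing to write an empty similarity grid",
                 class = "ramanmf_size_error")
  }
  if (is.null(raw_path)) {
    raw_path <- sub("(\\.[A-Za-z0-9]+)?$", "_raw\\1", path)
    if (identical(raw_path, path)) raw_path <- paste0(path, "_raw")
  }
  rounded <- df
  score_cols <- setdiff(names(df), c("model_k", "component"))
  rounded[score_cols] <- lapply(rounded[score_cols], round, digits = 2)
  utils::write.csv(rounded, path, row.names = FALSE, quote = TRUE)
  utils::write.csv(df, raw_path, row.names = FALSE, quote = TRUE)
  invisible(c(path, raw_path))
}

#' Read a similarity table back into a similarity grid
#'
#' Accepts tables written by [write_similarity_table()] as well as
#' externally transcribed grids (e.g. a published similarity table), with
#' columns `model_k`, `component` and one score column per reference label.
#'
#' @param path CSV path.
#' @return A `similarity_grid`.
#' @export
read_similarity_table <- function(path) {
  if (!file.exists(path)) {
    stop_ramanmf("similarity table not found: %s", path,
                 class = "ramanmf_io_error")
  }
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("model_k", "component")
  if (!all(need %in% names(df))) {
    stop_ramanmf("similarity table must have columns model_k and component",
                 class = "ramanmf_parse_error")
  }
  labels <- setdiff(names(df), need)
  if (!length(labels)) {
    stop_ramanmf("similarity table has no reference columns",
                 class = "ramanmf_parse_error")
  }
  similarity_grid(df[c(need, labels)])
}

#' Bundled example similarity table
#'
#' Path to the similarity grid for an immobilized pantothenate kinase (PanK)
#' on acrylamide resin mapped under 785 nm excitation: ten NMF models (1 to
#' 10 components) scored against four references (glass substrate, resin,
#' PanK, Bis-Tris). Useful as a worked example for the selection rules
#' without refitting anything.
#'
#' @return Path to the CSV inside the installed package.
#' @export
example_similarity_table <- function() {
  system.file("extdata", "pank_ac785_similarity.csv", package = "ramanmf",
              mustWork = TRUE)
}

# internal: tab wins if present, else comma, else whitespace
detect_sep <- function(line) {
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else " "
}
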