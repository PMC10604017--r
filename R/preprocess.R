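#' Preprocessing parameters
#'
#' Bundles the tunables of the spectral preprocessing chain. The
#' Savitzky-Golay defaults (window 11, polynomial order 3) are the values
#' used for Raman maps of immobilized-enzyme beads; the asymmetric
#' least-squares (AsLS) defaults are the classic Eilers settings for
#' Raman-scale fluorescence baselines.
#'
#' @param als_lambda Smoothness weight of the AsLS baseline (> 0). Larger
#'   values give stiffer baselines; 1e5 suits spectra of a few hundred
#'   channels with broad fluorescence backgrounds.
#' @param als_p Asymmetry weight in (0, 1): points above the baseline get
#'   weight `p`, points below get `1 - p`. Small values (0.01) let peaks sit
#'   above the baseline.
#' @param als_iterations Number of reweighting iterations (>= 1).
#' @param sg_window Savitzky-Golay window length, odd, >= 5.
#' @param sg_polyorder Savitzky-Golay polynomial order, < `sg_window`.
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(als_lambda = 1e5, als_p = 0.01,
                              als_iterations = 10,
                              sg_window = 11, sg_polyorder = 3) {
  if (als_lambda <= 0) {
    stop_ramanmf("als_lambda must be > 0", class = "ramanmf_param_error")
  }
  if (als_p <= 0 || als_p >= 1) {
    stop_ramanmf("als_p must lie in (0, 1)", class = "ramanmf_param_error")
  }
  if (als_iterations < 1) {
    stop_ramanmf("als_iterations must be >= 1", class = "ramanmf_param_error")
  }
  if (sg_window %% 2 == 0) {
    stop_ramanmf("sg_window must be odd, got %d", sg_window,
                 class = "ramanmf_param_error")
  }
  if (sg_window < 5) {
    stop_ramanmf("sg_window must be >= 5", class = "ramanmf_param_error")
  }
  if (sg_polyorder >= sg_window) {
    stop_ramanmf("sg_polyorder must be < sg_window",
                 class = "ramanmf_param_error")
  }
  structure(list(als_lambda = als_lambda, als_p = als_p,
                 als_iterations = as.integer(als_iterations),
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder)),
            class = "preprocess_params")
}

#' Asymmetric least-squares baseline estimation
#'
#' Eilers-Boelens scheme: the baseline z minimizes
#' `sum(w_i * (y_i - z_i)^2) + lambda * sum(diff(z, differences = 2)^2)`
#' with asymmetric weights `w_i = p` where `y_i > z_i` and `1 - p`
#' elsewhere, re-estimated for `als_iterations` rounds. The second-difference
#' penalty leaves constants and straight lines unpenalized, so those are
#' recovered exactly.
#'
#' @param y Intensity vector, length >= 5, finite.
#' @param params A [preprocess_params()].
#' @return The estimated baseline, same length as `y`.
#' @export
als_baseline <- function(y, params = preprocess_params()) {
  if (any(!is.finite(y))) {
    stop_ramanmf("non-finite values in input to als_baseline",
                 class = "ramanmf_value_error")
  }
  n <- length(y)
  if (n < 5) {
    stop_ramanmf("als_baseline needs at least 5 points, got %d", n,
                 class = "ramanmf_size_error")
  }
  DtD <- als_penalty(n, params$als_lambda)
  als_solve(y, DtD, params$als_p, params$als_iterations)
}

# internal: lambda * t(D2) %*% D2 as a sparse matrix, reusable across pixels
als_penalty <- function(n, lambda) {
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  lambda * Matrix::crossprod(D)
}

# internal: one AsLS solve given the precomputed penalty. `cache` (an
# environment) keeps the symbolic Cholesky factorization, whose sparsity
# pattern is identical for every pixel and reweighting round.
als_solve <- function(y, DtD, p, iterations, cache = new.env()) {
  n <- length(y)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(iterations)) {
    C <- DtD + Matrix::Diagonal(n, x = w)
    if (is.null(cache$ch)) {
      cache$ch <- Matrix::Cholesky(C, LDL = FALSE)
    } else {
      cache$ch <- Matrix::update(cache$ch, C)
    }
    z <- as.numeric(Matrix::solve(cache$ch, w * y))
    w <- ifelse(y > z, p, 1 - p)
  }
  z
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing via [signal::sgolayfilt()].
#' Exactly reproduces polynomials up to `sg_polyorder`, including at the
#' endpoints.
#'
#' @param y Intensity vector with `length(y) > sg_window`.
#' @param params A [preprocess_params()].
#' @return Smoothed vector of the same length.
#' @export
savgol_smooth <- function(y, params = preprocess_params()) {
  if (params$sg_window >= length(y)) {
    stop_ramanmf("sg_window (%d) must be smaller than the spectrum (%d)",
                 params$sg_window, length(y), class = "ramanmf_size_error")
  }
  signal::sgolayfilt(y, p = params$sg_polyorder, n = params$sg_window)
}

#' Min-max normalization to [0, 1]
#'
#' Rescales so the minimum maps to 0 and the maximum to 1. Applied to both
#' spectra of a pair immediately before cosine scoring; constant spectra are
#' rejected rather than silently zeroed because they carry no shape to
#' compare.
#'
#' @param y Numeric vector, length >= 2.
#' @return `(y - min(y)) / (max(y) - min(y))`.
#' @export
minmax_normalize <- function(y) {
  if (length(y) < 2) {
    stop_ramanmf("minmax_normalize needs at least 2 points",
                 class = "ramanmf_size_error")
  }
  rng <- range(y)
  if (rng[1] == rng[2]) {
    stop_ramanmf("degenerate spectrum: constant intensity %g", rng[1],
                 class = "ramanmf_degenerate_error")
  }
  (y - rng[1]) / (rng[2] - rng[1])
}

#' Preprocess every pixel of a hyperspectral cube
#'
#' Per-pixel chain: AsLS baseline subtraction, then Savitzky-Golay
#' smoothing, then clipping of negative residuals to zero so the output
#' satisfies the non-negativity NMF requires of its input. Min-max
#' normalization is deliberately not applied here; it belongs to similarity
#' scoring, not to factorization.
#'
#' @param cube A [hyper_cube()].
#' @param params A [preprocess_params()].
#' @return A new `hyper_cube`; the input is not modified.
#' @export
preprocess_cube <- function(cube, params = preprocess_params()) {
  stopifnot(inherits(cube, "hyper_cube"))
  n <- length(cube$axis)
  DtD <- als_penalty(n, params$als_lambda)
  cache <- new.env()
  out <- cube$intensity
  for (i in seq_len(nrow(out))) {
    y <- out[i, ]
    res <- tryCatch({
      corrected <- y - als_solve(y, DtD, params$als_p,
                                 params$als_iterations, cache)
      pmax(savgol_smooth(corrected, params), 0)
    }, error = function(e) {
      pc <- pixel_coords(i, cube$nx)
      stop_ramanmf("preprocessing failed at pixel (ix = %d, iy = %d): %s",
                   pc$ix, pc$iy, conditionMessage(e),
                   class = "ramanmf_pixel_error")
    })
    out[i, ] <- res
  }
  hyper_cube(out, cube$axis, cube$nx, cube$ny, step_x = cube$step_x,
             step_y = cube$step_y, excitation_nm = cube$excitation_nm)
}

#' Preprocess a single spectrum with the same chain as the cube
#'
#' Used for reference spectra so that resolved components and references are
#' compared on an equal footing (baseline-free, smoothed, non-negative).
#'
#' @param s A [raman_spectrum()].
#' @param params A [preprocess_params()].
#' @return A preprocessed `raman_spectrum`.
#' @export
preprocess_spectrum <- function(s, params = preprocess_params()) {
  stopifnot(inherits(s, "raman_spectrum"))
  y <- s$intensity - als_baseline(s$intensity, params)
  y <- pmax(savgol_smooth(y, params), 0)
  structure(list(wavenumber = s$wavenumber, intensity = y, label = s$label),
            class = "raman_spectrum")
}
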