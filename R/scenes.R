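#' Band specification for synthetic pure spectra
#'
#' @param center Band position (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1), > 0.
#' @param height Peak height (a.u.), >= 0.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return A list of class `band_spec`.
#' @export
band_spec <- function(center, fwhm, height = 1,
                      shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  if (fwhm <= 0) {
    stop_ramanmf("band fwhm must be > 0", class = "ramanmf_param_error")
  }
  if (height < 0) {
    stop_ramanmf("band height must be >= 0", class = "ramanmf_param_error")
  }
  structure(list(center = center, fwhm = fwhm, height = height,
                 shape = shape), class = "band_spec")
}

#' Evaluate a sum of bands as a pure-component spectrum
#'
#' Bands whose centre lies outside the axis are skipped with a warning
#' rather than silently clipped, since they cannot contribute a visible
#' peak.
#'
#' @param bands List of [band_spec()]s (may be empty: zero spectrum).
#' @param axis Ascending wavenumber axis.
#' @param label Species label.
#' @return A [raman_spectrum()], non-negative.
#' @export
make_pure_spectrum <- function(bands, axis, label = "") {
  if (is.unsorted(axis, strictly = TRUE)) {
    stop_ramanmf("axis must be strictly increasing",
                 class = "ramanmf_axis_error")
  }
  y <- numeric(length(axis))
  for (b in bands) {
    if (b$center < min(axis) || b$center > max(axis)) {
      warning(sprintf("band at %g cm^-1 outside axis [%g, %g]; skipped",
                      b$center, min(axis), max(axis)))
      next
    }
    if (b$shape == "gaussian") {
      sigma <- b$fwhm / (2 * sqrt(2 * log(2)))
      y <- y + b$height * exp(-0.5 * ((axis - b$center) / sigma)^2)
    } else {
      gamma <- b$fwhm / 2
      y <- y + b$height * gamma^2 / ((axis - b$center)^2 + gamma^2)
    }
  }
  raman_spectrum(axis, y, label = label)
}

#' Band presets for the four species of an immobilized-enzyme scene
#'
#' Roles rather than measured constants: the enzyme preset carries the
#' phenylalanine marker at 1003 cm^-1 plus C-H deformation (1454) and amide
#' I (1662) bands it shares with the resin; the resin adds carrier bands;
#' the glass substrate is one broad band near 1400 cm^-1 (as seen under
#' 785 nm excitation); the wash residue (a Bis-Tris-like buffer) has bands
#' in the 800-900, 1000-1100 and 1400-1500 cm^-1 regions.
#'
#' @return Named list of band lists for species `resin`, `glass`, `enzyme`
#'   and `wash`.
#' @export
scene_band_presets <- function() {
  list(
    resin = list(band_spec(845, 16, 0.60), band_spec(1120, 18, 0.85),
                 band_spec(1454, 18, 1.00), band_spec(1662, 24, 0.55)),
    glass = list(band_spec(1400, 220, 1.00, shape = "lorentzian"),
                 band_spec(1100, 120, 0.30, shape = "lorentzian")),
    enzyme = list(band_spec(1003, 9, 1.00), band_spec(1250, 32, 0.25),
                  band_spec(1454, 16, 0.30), band_spec(1662, 24, 0.45)),
    wash = list(band_spec(860, 14, 0.80), band_spec(1040, 15, 1.00),
                band_spec(1065, 12, 0.55), band_spec(1460, 18, 0.45)))
}

#' Generate the ground truth for a default four-species scene
#'
#' Emulates an immobilized-enzyme bead field on a glass slide: resin beads
#' as disks, glass substrate as the exact complement of the beads, enzyme in
#' a subset of the beads and wash residue inside beads where enzyme
#' loading is low (the two are spatially anti-correlated, as residue
#' survives where the enzyme did not displace it). Deterministic per seed.
#'
#' @param nx,ny Grid dimensions (pixels), both >= 16.
#' @param seed Integer seed.
#' @param axis Wavenumber axis; default 600..1798 cm^-1 in 2 cm^-1 steps.
#' @param baseline_amplitude Scale of the smooth per-pixel baseline relative
#'   to unit peak height. The default (4) makes raw spectra
#'   baseline-dominated, so unmixing only succeeds after preprocessing.
#' @param noise_sd Additive Gaussian noise sd (a.u.). Default 0.05, i.e.
#'   roughly 20:1 peak signal-to-noise.
#' @param shot_scale Scale of signal-dependent (shot-like) noise, applied
#'   as `shot_scale * sqrt(signal)` extra sd. Default 0.02.
#' @return An object of class `scene_truth` with pure spectra, abundance
#'   maps (ny x nx matrices), bead masks and the noise/baseline parameters.
#' @export
default_scene <- function(nx = 32, ny = 32, seed = 0,
                          axis = seq(600, 1798, by = 2),
                          baseline_amplitude = 4,
                          noise_sd = 0.05, shot_scale = 0.02) {
  if (nx < 16 || ny < 16) {
    stop_ramanmf("scene grid must be at least 16 x 16, got %d x %d", nx, ny,
                 class = "ramanmf_param_error")
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)

  presets <- scene_band_presets()
  pure <- lapply(names(presets), function(sp) {
    make_pure_spectrum(presets[[sp]], axis, label = sp)
  })
  names(pure) <- names(presets)

  # bead field: disks with per-bead enzyme / wash loadings. Separability of
  # the species rests on across-bead variation: some beads carry no enzyme
  # at all, and wash residue is strongest exactly in those (the wash
  # survives where the enzyme did not displace it), giving the inverse
  # enzyme/wash correlation seen in immobilization experiments.
  n_beads <- max(4L, round(nx * ny / 120))
  radii <- stats::runif(n_beads, 0.13, 0.19) * min(nx, ny)
  cx <- stats::runif(n_beads, 0.12, 0.88) * nx
  cy <- stats::runif(n_beads, 0.12, 0.88) * ny
  gx <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  gy <- matrix(rep(seq_len(ny), times = nx), ny, nx)

  # ~30% of beads carry no enzyme; at least one of each kind. A dense
  # enzyme coat scatters strongly, so its signal dominates the (porous,
  # partly buffer-filled) resin matrix where it is present; unloaded beads
  # keep most of their wash residue, deposited as patches inside the bead.
  e_load <- ifelse(stats::runif(n_beads) < 0.7,
                   stats::runif(n_beads, 2.5, 4.0), 0)
  if (all(e_load == 0)) e_load[1] <- 3
  if (all(e_load > 0)) e_load[n_beads] <- 0
  w_load <- ifelse(e_load > 0, stats::runif(n_beads, 0.1, 0.4),
                   stats::runif(n_beads, 0.8, 1.0))

  bead_mask <- matrix(FALSE, ny, nx)
  bead_id <- matrix(0L, ny, nx)
  resin <- matrix(0, ny, nx)
  enzyme <- matrix(0, ny, nx)
  wash <- matrix(0, ny, nx)
  for (b in seq_len(n_beads)) {
    d2 <- (gx - cx[b])^2 + (gy - cy[b])^2
    t <- d2 / radii[b]^2
    inside <- t <= 1
    new_px <- inside & !bead_mask
    resin[new_px] <- (1 - 0.2 * t)[new_px]
    bead_id[new_px] <- b
    # wash patch: an off-centre blob inside the bead, not a full-bead dome
    px <- stats::runif(1, -0.4, 0.4) * radii[b]
    py <- stats::runif(1, -0.4, 0.4) * radii[b]
    blob <- exp(-((gx - cx[b] - px)^2 + (gy - cy[b] - py)^2) /
                  (2 * (0.35 * radii[b])^2))
    wash[new_px] <- (2.5 * w_load[b] * blob)[new_px]
    bead_mask <- bead_mask | inside
  }
  glass <- ifelse(bead_mask, 0, 1)

  # surface-bound enzyme forms a ring at the bead boundary; at the pixel
  # scale the coat spills slightly past the rim onto the substrate, so rim
  # pixels carry enzyme without resin (partial-volume effect)
  for (b in which(e_load > 0)) {
    d2 <- (gx - cx[b])^2 + (gy - cy[b])^2
    t <- d2 / radii[b]^2
    ring <- e_load[b] * exp(-((sqrt(t) - 0.85) / 0.15)^2)
    sel <- (t <= 1.45) & (bead_id == b | !bead_mask)
    enzyme[sel] <- enzyme[sel] + ring[sel]
  }

  # residue of the final wash also dries onto the slide outside the beads
  n_spots <- max(2L, n_beads %/% 2L)
  for (s in seq_len(n_spots)) {
    sx <- stats::runif(1, 0.1, 0.9) * nx
    sy <- stats::runif(1, 0.1, 0.9) * ny
    r <- stats::runif(1, 0.05, 0.09) * min(nx, ny)
    blob <- stats::runif(1, 1.2, 2.0) *
      exp(-((gx - sx)^2 + (gy - sy)^2) / (2 * r^2))
    sel <- !bead_mask
    wash[sel] <- wash[sel] + blob[sel]
  }

  structure(
    list(axis = axis, pure = pure,
         abundance = list(resin = resin, glass = glass,
                          enzyme = enzyme, wash = wash),
         bead_mask = bead_mask,
         baseline_amplitude = baseline_amplitude,
         noise_sd = noise_sd, shot_scale = shot_scale,
         nx = as.integer(nx), ny = as.integer(ny), seed = as.integer(seed)),
    class = "scene_truth")
}

#' @exportS3Method base::print
print.scene_truth <- function(x, ...) {
  cat(sprintf(
    "<scene_truth> %d x %d pixels, %d species, %d channels, seed %d\n",
    x$nx, x$ny, length(x$pure), length(x$axis), x$seed))
  invisible(x)
}

#' Render a synthetic scene into a hyperspectral cube
#'
#' Forward model: per pixel, intensity = sum over species of
#' abundance x pure spectrum, plus a smooth cubic baseline with per-pixel
#' jittered coefficients, plus Gaussian and shot-like noise. With zero noise
#' and zero baseline this is exactly the bilinear mixing model NMF assumes,
#' which is what makes parameter recovery testable.
#'
#' @param truth A [default_scene()] result.
#' @return A [hyper_cube()] with the scene's axis and geometry.
#' @export
render_cube <- function(truth) {
  stopifnot(inherits(truth, "scene_truth"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(truth$seed + 1L)

  nw <- length(truth$axis)
  np <- truth$nx * truth$ny
  # abundance maps are ny x nx; cube rows are row-major with x fastest,
  # which matches column-major traversal of the transposed map
  Wtrue <- vapply(truth$abundance, function(m) as.vector(t(m)), numeric(np))
  Strue <- t(vapply(truth$pure, function(s) s$intensity, numeric(nw)))
  clean <- Wtrue %*% Strue

  u <- seq(0, 1, length.out = nw)
  base <- matrix(0, np, nw)
  if (truth$baseline_amplitude > 0) {
    for (i in seq_len(np)) {
      co <- c(0.55, -0.35, 0.25, -0.1) * (1 + stats::rnorm(4, 0, 0.1))
      prof <- co[1] + co[2] * u + co[3] * u^2 + co[4] * u^3
      base[i, ] <- truth$baseline_amplitude * pmax(prof, 0.05)
    }
  }
  signal <- clean + base
  noise <- matrix(stats::rnorm(np * nw, 0, truth$noise_sd), np, nw) +
    matrix(stats::rnorm(np * nw), np, nw) *
      truth$shot_scale * sqrt(pmax(signal, 0))
  hyper_cube(signal + noise, truth$axis, truth$nx, truth$ny)
}

#' Write a scene to disk as plain-text pipeline inputs
#'
#' Emits the long-format map text, one two-column reference file per
#' species (the noise-free pure spectra) and a JSON ground-truth summary,
#' i.e. exactly what a real acquisition plus reference session would
#' provide, with truth on the side for validation.
#'
#' @param truth A [default_scene()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a list of written paths (`map`, `references`,
#'   `truth`).
#' @export
write_scene <- function(truth, dir) {
  stopifnot(inherits(truth, "scene_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cube <- render_cube(truth)
  map_path <- file.path(dir, "map.txt")
  write_map_text(cube, map_path)
  ref_paths <- vapply(names(truth$pure), function(sp) {
    p <- file.path(dir, paste0("reference_", sp, ".txt"))
    utils::write.table(
      data.frame(truth$axis, truth$pure[[sp]]$intensity), p,
      sep = "\t", row.names = FALSE, col.names = FALSE)
    p
  }, character(1))
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(nx = truth$nx, ny = truth$ny, seed = truth$seed,
         species = names(truth$pure),
         baseline_amplitude = truth$baseline_amplitude,
         noise_sd = truth$noise_sd, shot_scale = truth$shot_scale,
         abundance = lapply(truth$abundance, function(m) unname(as.matrix(m)))),
    truth_path, auto_unbox = TRUE, digits = 10)
  invisible(list(map = map_path, references = ref_paths,
                 truth = truth_path))
}
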