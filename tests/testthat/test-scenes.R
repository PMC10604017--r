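test_that("make_pure_spectrum evaluates band profiles correctly", {
  axis <- seq(600, 1800, 1)
  s <- make_pure_spectrum(list(band_spec(1003, 10, 1)), axis)
  expect_equal(max(s$intensity), 1, tolerance = 1e-6)
  expect_equal(axis[which.max(s$intensity)], 1003)
  # half maximum at center +/- fwhm/2
  expect_equal(s$intensity[axis == 1008], 0.5, tolerance = 1e-3)

  z <- make_pure_spectrum(list(), axis)
  expect_true(all(z$intensity == 0))

  # overlapping gaussians merge into a single maximum between the centers
  two <- make_pure_spectrum(list(band_spec(1450, 20), band_spec(1454, 20)),
                            axis)
  peaks <- which(diff(sign(diff(two$intensity))) == -2) + 1
  expect_length(peaks, 1)
  expect_true(axis[peaks] >= 1450 && axis[peaks] <= 1454)

  expect_warning(make_pure_spectrum(list(band_spec(100, 10)), axis),
                 "outside axis")
  expect_error(band_spec(1000, -1), class = "ramanmf_param_error")
})

test_that("default_scene is deterministic and spatially structured as specified", {
  t1 <- default_scene(32, 32, seed = 0)
  t2 <- default_scene(32, 32, seed = 0)
  expect_identical(t1, t2)

  # enzyme and wash residue anti-correlate across the field
  expect_lt(cor(as.vector(t1$abundance$enzyme),
                as.vector(t1$abundance$wash)), 0)

  # glass and resin have complementary supports
  expect_equal(sum(t1$abundance$glass * t1$abundance$resin), 0)

  # every pixel carries at least one species
  total <- Reduce(`+`, t1$abundance)
  expect_true(all(total > 0))

  expect_error(default_scene(8, 8), class = "ramanmf_param_error")
})

test_that("render_cube implements the exact bilinear forward model", {
  tr <- default_scene(16, 16, seed = 2, baseline_amplitude = 0,
                      noise_sd = 0, shot_scale = 0)
  # single species: zero all but resin
  for (sp in c("glass", "enzyme", "wash")) {
    tr$abundance[[sp]][] <- 0
  }
  cube <- render_cube(tr)
  resin_vec <- as.vector(t(tr$abundance$resin))
  pure <- tr$pure$resin$intensity
  for (i in which(resin_vec > 0)) {
    expect_equal(cube$intensity[i, ], resin_vec[i] * pure,
                 tolerance = 1e-12)
  }
  expect_true(all(cube$intensity[resin_vec == 0, ] == 0))
})

test_that("render_cube is deterministic per seed and noise behaves as configured", {
  tr <- default_scene(16, 16, seed = 3)
  expect_identical(render_cube(tr)$intensity, render_cube(tr)$intensity)
  tr0 <- default_scene(16, 16, seed = 3, noise_sd = 0, shot_scale = 0,
                       baseline_amplitude = 0)
  c0 <- render_cube(tr0)
  expect_lte(max(abs(c0$intensity -
    sapply(seq_along(tr0$axis), function(j) {
      Reduce(`+`, lapply(names(tr0$abundance), function(sp)
        as.vector(t(tr0$abundance[[sp]])) * tr0$pure[[sp]]$intensity[j]))
    }))), 1e-12)
})

test_that("halving the noise never hurts the best similarity of any species", {
  for (sd in 1:3) {
    sims <- sapply(c(1, 0.5), function(f) {
      tr <- default_scene(24, 24, seed = sd, noise_sd = 0.05 * f)
      cube <- render_cube(tr)
      pre <- preprocess_cube(cube)
      lib <- reference_library(lapply(tr$pure, preprocess_spectrum),
                               axis = cube$axis)
      m <- nmf_fit(pre, 5, seed = sd)
      vapply(lib$spectra, function(r)
        max(apply(m$S, 1, function(s) cosine_similarity(s, r$intensity))),
        numeric(1))
    })
    expect_true(all(sims[, 2] >= sims[, 1] - 0.01))
  }
})

test_that("write_scene emits map, references and truth for the pipeline", {
  tr <- default_scene(16, 16, seed = 5)
  dir <- tempfile()
  paths <- write_scene(tr, dir)
  expect_true(file.exists(paths$map))
  expect_length(paths$references, 4)
  expect_true(all(file.exists(paths$references)))
  cube <- read_map_text(paths$map)
  expect_equal(cube$nx, 16L)
  expect_equal(cube$ny, 16L)
  truth <- jsonlite::read_json(paths$truth)
  expect_equal(truth$seed, 5L)
  expect_setequal(unlist(truth$species),
                  c("resin", "glass", "enzyme", "wash"))
})
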