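test_that("read_map_text assembles rectangular grids of any raster order", {
  p <- write_toy_map(2, 2, axis = c(100, 200, 300))
  cube <- read_map_text(p)
  expect_s3_class(cube, "hyper_cube")
  expect_equal(dim(cube$intensity), c(4L, 3L))
  expect_equal(cube$nx, 2L)
  expect_equal(cube$ny, 2L)

  # shuffled line order normalizes to the same cube
  set.seed(42)
  p2 <- write_toy_map(3, 4, shuffle = TRUE)
  p3 <- write_toy_map(3, 4, shuffle = FALSE)
  expect_equal(read_map_text(p2)$intensity, read_map_text(p3)$intensity)

  # comma dialect reads identically
  p4 <- write_toy_map(2, 3, sep = ",")
  expect_equal(read_map_text(p4)$intensity,
               read_map_text(write_toy_map(2, 3))$intensity)
})

test_that("map grids of realistic acquisition sizes count spectra correctly", {
  p <- write_toy_map(53, 63, axis = c(100, 200))
  expect_equal(nrow(read_map_text(p)$intensity), 3339L)
})

test_that("incomplete or inconsistent map files raise structural errors", {
  p <- write_toy_map(2, 2, axis = c(100, 200))
  lines <- readLines(p)
  # drop both channels of the last pixel -> missing pixel, named in message
  writeLines(lines[1:6], p)
  err <- expect_error(read_map_text(p), class = "ramanmf_grid_error")
  expect_match(conditionMessage(err), "1.5")
  # drop a single channel of one pixel -> axis mismatch
  p2 <- write_toy_map(2, 2, axis = c(100, 200))
  writeLines(readLines(p2)[-8], p2)
  expect_error(read_map_text(p2), class = "ramanmf_axis_error")
})

test_that("map read/write round trip preserves intensities exactly", {
  set.seed(7)
  iv <- matrix(runif(6 * 4), 6, 4)
  cube <- hyper_cube(iv, c(600, 700, 800, 900), nx = 3, ny = 2)
  p <- tempfile(fileext = ".txt")
  write_map_text(cube, p)
  back <- read_map_text(p)
  expect_identical(back$intensity, cube$intensity)
  expect_equal(back$axis, cube$axis)
})

test_that("pixel linearization is bijective for all small grids", {
  for (nx in 1:8) {
    for (ny in 1:8) {
      rows <- pixel_index(rep(seq_len(nx), times = ny),
                          rep(seq_len(ny), each = nx), nx)
      expect_equal(sort(rows), seq_len(nx * ny))
      pc <- pixel_coords(rows, nx)
      expect_equal(pc$ix, rep(seq_len(nx), times = ny))
      expect_equal(pc$iy, rep(seq_len(ny), each = nx))
    }
  }
})

test_that("read_reference parses, sorts and rejects malformed files", {
  p <- tempfile()
  writeLines(c("100,1.0", "200,2.0"), p)
  s <- read_reference(p, label = "x")
  expect_equal(s$wavenumber, c(100, 200))
  expect_equal(s$intensity, c(1, 2))
  expect_equal(s$label, "x")

  # descending axis is reordered ascending with intensities
  writeLines(c("300,3", "200,2", "100,1"), p)
  s2 <- read_reference(p)
  expect_equal(s2$wavenumber, c(100, 200, 300))
  expect_equal(s2$intensity, c(1, 2, 3))

  writeLines(c("100,a", "200,2"), p)
  err <- expect_error(read_reference(p), class = "ramanmf_parse_error")
  expect_match(conditionMessage(err), "line 1")

  writeLines("100,1", p)
  expect_error(read_reference(p), class = "ramanmf_size_error")
})

test_that("resample_to_axis interpolates linearly and refuses extrapolation", {
  s <- raman_spectrum(c(100, 200), c(0, 2))
  expect_equal(resample_to_axis(s, c(150, 200))$intensity, c(1, 2))
  # identity on own axis
  s3 <- raman_spectrum(c(100, 150, 200), c(1, 5, 2))
  expect_equal(resample_to_axis(s3, s3$wavenumber)$intensity, s3$intensity)
  # hand-computed interior points
  s4 <- raman_spectrum(c(100, 200, 300), c(0, 2, 0))
  expect_equal(resample_to_axis(s4, c(150, 250))$intensity, c(1, 1))
  expect_error(resample_to_axis(s4, c(50, 150)),
               class = "ramanmf_range_error")
})

test_that("similarity tables round-trip with a rounded and a raw copy", {
  g <- table1_grid()
  expect_equal(nrow(g$scores), 55L)
  expect_equal(nrow(g$scores) * length(g$labels), 220L)
  p <- tempfile(fileext = ".csv")
  paths <- write_similarity_table(g, p)
  expect_true(all(file.exists(paths)))
  back <- read_similarity_table(p)
  expect_equal(back$scores, g$scores)
  expect_equal(back$labels, g$labels)

  empty <- similarity_grid(data.frame(model_k = integer(0),
                                      component = integer(0),
                                      a = numeric(0)))
  expect_error(write_similarity_table(empty, tempfile()),
               class = "ramanmf_size_error")
})

test_that("reference libraries enforce labels and share one axis", {
  a <- raman_spectrum(seq(100, 300, 10), sin(1:21) + 2, label = "a")
  b <- raman_spectrum(seq(120, 280, 5), cos(1:33) + 2, label = "b")
  lib <- reference_library(list(a, b))
  expect_equal(lib$labels, c("a", "b"))
  expect_true(all(lib$axis >= 120 & lib$axis <= 280))
  expect_equal(length(lib$spectra$a$intensity), length(lib$axis))
  expect_error(reference_library(list(a, a)), class = "ramanmf_value_error")
  expect_error(reference_library(list(raman_spectrum(1:5, 1:5))),
               class = "ramanmf_value_error")
})
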