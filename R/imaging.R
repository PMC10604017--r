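#' Reshape one concentration column into a chemical image
#'
#' A column of `W` holds one value per pixel in the cube's row-major order
#' (x fastest); the image is the ny x nx matrix with `image[iy, ix]` the
#' abundance at pixel `(ix, iy)`. No interpolation is applied.
#'
#' @param model An `nmf_model` fitted on `cube`.
#' @param cube The [hyper_cube()] the model was fitted on.
#' @param component Component index, `1..model$k`.
#' @param label Species label to attach (e.g. from an assignment).
#' @return An object of class `chemical_image`: list with `values`
#'   (ny x nx matrix), `label`, `model_k`, `component`.
#' @export
concentration_image <- function(model, cube, component, label = "") {
  stopifnot(inherits(model, "nmf_model"), inherits(cube, "hyper_cube"))
  if (component < 1 || component > model$k) {
    stop_ramanmf("component %d out of range 1..%d", component, model$k,
                 class = "ramanmf_param_error")
  }
  if (nrow(model$W) != cube$nx * cube$ny) {
    stop_ramanmf("model has %d pixels but cube grid is %d x %d",
                 nrow(model$W), cube$nx, cube$ny,
                 class = "ramanmf_size_error")
  }
  w <- model$W[, component]
  values <- matrix(w, nrow = cube$ny, ncol = cube$nx, byrow = TRUE)
  structure(list(values = values, label = label,
                 model_k = model$k, component = as.integer(component)),
            class = "chemical_image")
}

#' @exportS3Method base::print
print.chemical_image <- function(x, ...) {
  cat(sprintf("<chemical_image> %s: %d x %d, k = %d component %d\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              ncol(x$values), nrow(x$values), x$model_k, x$component))
  invisible(x)
}

#' Flatten a chemical image back to a concentration column
#'
#' Inverse of [concentration_image()]: row-major traversal recovers the `W`
#' column exactly.
#'
#' @param image A `chemical_image`.
#' @return Numeric vector of length nx * ny.
#' @export
flatten_image <- function(image) {
  stopifnot(inherits(image, "chemical_image"))
  as.vector(t(image$values))
}

#' Write a chemical image as PNG and CSV
#'
#' The PNG is a grayscale rendering min-max scaled per image (for display);
#' the CSV keeps the raw abundance values for quantitative use.
#'
#' @param image A `chemical_image`.
#' @param stem Output path without extension.
#' @return Invisibly, the two paths written.
#' @export
write_chemical_image <- function(image, stem) {
  stopifnot(inherits(image, "chemical_image"))
  v <- image$values
  rng <- range(v)
  scaled <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  png_path <- paste0(stem, ".png")
  csv_path <- paste0(stem, ".csv")
  png::writePNG(scaled, png_path)
  utils::write.table(v, csv_path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(c(png_path, csv_path))
}

#' Render the summary panels for a completed run
#'
#' Writes, per assigned species of the selected model: the chemical image
#' (PNG + CSV) and an overlay of the resolved spectrum on its reference
#' with the cosine similarity annotated. Also writes the RRE-versus-k plot,
#' the similarity-versus-k plot (one series per reference) and the report
#' JSON. Spatial agreement with the optical image is left to the viewer:
#' the panels are rendered side by side, never scored.
#'
#' @param report A `selection_report` with `status == "ok"`.
#' @param models The fitted `nmf_ladder`.
#' @param cube The preprocessed [hyper_cube()].
#' @param library The [reference_library()] used for scoring.
#' @param grid The `similarity_grid`.
#' @param out_dir Output directory (created if absent).
#' @param dataset Dataset name used as the file-name prefix.
#' @return Invisibly, character vector of files written.
#' @export
render_summary <- function(report, models, cube, library, grid, out_dir,
                           dataset = "scene") {
  stopifnot(inherits(report, "selection_report"))
  if (report$status != "ok") {
    stop_ramanmf("cannot render summary for an unresolved report",
                 class = "ramanmf_param_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  k_star <- report$k_star
  model <- normalize_gauge(models[[k_star]])
  asg <- report$assignments[[as.character(k_star)]]

  for (i in seq_len(nrow(asg))) {
    sp <- asg$reference[i]
    comp <- asg$component[i]
    stem <- file.path(out_dir, sprintf("%s_%s_k%d_c%d", dataset, sp,
                                       k_star, comp))
    img <- concentration_image(model, cube, comp, label = sp)
    files <- c(files, write_chemical_image(img, stem))

    spec_path <- paste0(stem, "_spectrum.png")
    grDevices::png(spec_path, width = 700, height = 400)
    graphics::par(mar = c(4, 4, 2, 1))
    resolved <- minmax_normalize(model$S[comp, ])
    ref <- minmax_normalize(library$spectra[[sp]]$intensity)
    graphics::plot(cube$axis, resolved, type = "l", col = "firebrick",
                   xlab = expression(paste("wavenumber (", cm^-1, ")")),
                   ylab = "normalized intensity",
                   main = sprintf("%s: resolved (k=%d, c%d) vs reference",
                                  sp, k_star, comp))
    graphics::lines(library$axis, ref, col = "grey40", lty = 2)
    graphics::legend("topright", bty = "n",
                     legend = sprintf("cosine similarity %.2f", asg$score[i]))
    grDevices::dev.off()
    files <- c(files, spec_path)
  }

  if (!is.null(report$rre_per_k)) {
    p <- file.path(out_dir, sprintf("%s_rre_vs_k.png", dataset))
    grDevices::png(p, width = 600, height = 400)
    graphics::par(mar = c(4, 4, 2, 1))
    graphics::plot(seq_along(report$rre_per_k), report$rre_per_k,
                   type = "b", pch = 19, xlab = "number of components",
                   ylab = "relative reconstruction error",
                   main = "RRE vs model order")
    graphics::abline(v = k_star, lty = 3)
    grDevices::dev.off()
    files <- c(files, p)
  }

  p <- file.path(out_dir, sprintf("%s_similarity_vs_k.png", dataset))
  grDevices::png(p, width = 600, height = 400)
  graphics::par(mar = c(4, 4, 2, 1))
  ks <- grid$models
  cols <- grDevices::hcl.colors(length(report$labels), "Dark 3")
  graphics::plot(NULL, xlim = range(ks), ylim = c(0, 1),
                 xlab = "number of components", ylab = "assigned similarity",
                 main = "similarity vs model order")
  for (j in seq_along(report$labels)) {
    prof <- stability_profile(grid, report$labels[j], report$params)
    if (length(prof$scores)) {
      graphics::lines(as.integer(names(prof$scores)), prof$scores,
                      type = "b", pch = 19, col = cols[j])
    }
  }
  graphics::abline(h = report$params$tau, lty = 3)
  graphics::legend("bottomright", legend = report$labels, col = cols,
                   lty = 1, pch = 19, bty = "n")
  grDevices::dev.off()
  files <- c(files, p)

  rp <- file.path(out_dir, sprintf("%s_report.json", dataset))
  write_report_json(report, rp)
  files <- c(files, rp)
  invisible(files)
}
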