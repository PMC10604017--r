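#' Build a run configuration
#'
#' Collects every tunable of the pipeline in one validated object. Any field
#' can also be supplied through a YAML file (see [read_run_config()]); the
#' keys mirror the argument names (`preprocess.als_lambda`, `nmf.k_max`,
#' `selection.tau`, ...).
#'
#' @param map Path to the long-format map text file.
#' @param references Named character vector of reference-spectrum paths
#'   (names are the species labels).
#' @param out_dir Output directory.
#' @param dataset Dataset name used for file prefixes.
#' @param preprocess A [preprocess_params()].
#' @param preprocess_references Apply the same baseline/smoothing chain to
#'   the reference spectra before scoring (default `TRUE`).
#' @param k_max,seed,tol,max_iter,init NMF ladder settings (see
#'   [fit_ladder()]).
#' @param selection A [selection_params()].
#' @param excitation_nm Metadata recorded in the cube.
#' @return A list of class `run_config`.
#' @export
run_config <- function(map, references, out_dir, dataset = "run",
                       preprocess = preprocess_params(),
                       preprocess_references = TRUE,
                       k_max = 10, seed = 0, tol = 1e-7, max_iter = 5000,
                       init = "nndsvda",
                       selection = selection_params(),
                       excitation_nm = 785) {
  if (is.null(names(references)) || any(!nzchar(names(references)))) {
    stop_ramanmf("references must be a named vector (names = species)",
                 class = "ramanmf_param_error")
  }
  structure(list(map = map, references = references, out_dir = out_dir,
                 dataset = dataset, preprocess = preprocess,
                 preprocess_references = isTRUE(preprocess_references),
                 k_max = as.integer(k_max), seed = as.integer(seed),
                 tol = tol, max_iter = as.integer(max_iter), init = init,
                 selection = selection, excitation_nm = excitation_nm),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with keys `map`, `references` (mapping label to
#'   path), `out_dir` and optional `dataset`, `preprocess.*`, `nmf.*`,
#'   `selection.*` sections.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pp <- do.call(preprocess_params, as.list(y$preprocess %||% list()))
  sel <- do.call(selection_params, as.list(y$selection %||% list()))
  nmf <- y$nmf %||% list()
  run_config(
    map = y$map,
    references = unlist(y$references),
    out_dir = y$out_dir %||% "ramanmf_out",
    dataset = y$dataset %||% "run",
    preprocess = pp,
    preprocess_references = y$preprocess_references %||% TRUE,
    k_max = nmf$k_max %||% 10,
    seed = nmf$seed %||% 0,
    tol = nmf$tol %||% 1e-7,
    max_iter = nmf$max_iter %||% 5000,
    init = nmf$init %||% "nndsvda",
    selection = sel,
    excitation_nm = y$excitation_nm %||% 785)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full unmixing pipeline
#'
#' Read map and references, preprocess, fit the NMF ladder, score it against
#' the library, select the optimal model and render the summary artifacts.
#' The report (including the "no model resolves all species" outcome, which
#' is a structured result rather than an error) is returned and written to
#' `out_dir`.
#'
#' @param config A [run_config()].
#' @param render Write image/plot artifacts (default `TRUE`; the report
#'   JSON and similarity tables are always written).
#' @return The `selection_report`, invisibly augmented with `grid`,
#'   `ladder` and `cube` attributes for programmatic use.
#' @export
run_pipeline <- function(config, render = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  cube <- read_map_text(config$map, excitation_nm = config$excitation_nm)
  refs <- lapply(names(config$references), function(lbl) {
    read_reference(config$references[[lbl]], label = lbl)
  })

  pre <- preprocess_cube(cube, config$preprocess)
  if (config$preprocess_references) {
    refs <- lapply(refs, preprocess_spectrum, params = config$preprocess)
  }
  lo <- max(vapply(refs, function(s) min(s$wavenumber), numeric(1)))
  hi <- min(vapply(refs, function(s) max(s$wavenumber), numeric(1)))
  axis <- pre$axis[pre$axis >= lo & pre$axis <= hi]
  library <- reference_library(refs, axis = axis)
  keep <- pre$axis %in% axis
  fit_mat <- pre$intensity[, keep, drop = FALSE]

  ladder <- fit_ladder(fit_mat, k_max = config$k_max, seed = config$seed,
                       tol = config$tol, max_iter = config$max_iter,
                       init = config$init)
  grid <- score_ladder(ladder, library)
  write_similarity_table(
    grid, file.path(config$out_dir,
                    sprintf("%s_similarity.csv", config$dataset)))
  report <- select_optimal(grid, rre_per_k = attr(ladder, "rre"),
                           params = config$selection)

  if (report$status == "ok" && render) {
    pre_fit <- hyper_cube(fit_mat, axis, pre$nx, pre$ny,
                          step_x = pre$step_x, step_y = pre$step_y,
                          excitation_nm = pre$excitation_nm)
    render_summary(report, ladder, pre_fit, library, grid,
                   config$out_dir, dataset = config$dataset)
  } else {
    write_report_json(report, file.path(
      config$out_dir, sprintf("%s_report.json", config$dataset)))
  }
  attr(report, "grid") <- grid
  attr(report, "ladder") <- ladder
  attr(report, "cube") <- pre
  report
}
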