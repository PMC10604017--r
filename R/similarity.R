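#' Selection parameters for the optimal-model criteria
#'
#' @param tau Resolution threshold on cosine similarity in (0, 1). Scores of
#'   resolved components against absent species fall below 0.5 in practice,
#'   which motivates the default.
#' @param epsilon Parsimony tolerance in `[0, 1)`: a model whose worst
#'   assigned similarity is within `epsilon` of the best achievable is
#'   considered equivalent, and the smallest such model wins. The default
#'   0.05 encodes the judgment that a gain of a few hundredths of cosine
#'   similarity does not justify extra components.
#' @param delta Optional argmax margin in `[0, 1)`: a component is only
#'   eligible for a reference if its best score beats its second-best
#'   reference by at least `delta`. Default 0 (no margin requirement).
#' @return A list of class `selection_params`.
#' @export
selection_params <- function(tau = 0.5, epsilon = 0.05, delta = 0) {
  if (tau <= 0 || tau >= 1) {
    stop_ramanmf("tau must lie in (0, 1)", class = "ramanmf_param_error")
  }
  if (epsilon < 0 || epsilon >= 1) {
    stop_ramanmf("epsilon must lie in [0, 1)", class = "ramanmf_param_error")
  }
  if (delta < 0 || delta >= 1) {
    stop_ramanmf("delta must lie in [0, 1)", class = "ramanmf_param_error")
  }
  structure(list(tau = tau, epsilon = epsilon, delta = delta),
            class = "selection_params")
}

#' Cosine similarity between two spectra
#'
#' Both vectors are min-max normalized to `[0, 1]` and then scored as
#' `sum(a * b) / (||a|| * ||b||)`. For non-negative inputs the score lies in
#' `[0, 1]`, reaching 1 only for identical shapes.
#'
#' @param a,b Numeric vectors of equal length (intensities on a common
#'   axis), or `raman_spectrum` objects.
#' @param normalize Min-max normalize before scoring (default `TRUE`; set
#'   `FALSE` if the inputs are already normalized).
#' @return Cosine similarity score.
#' @export
cosine_similarity <- function(a, b, normalize = TRUE) {
  if (inherits(a, "raman_spectrum")) a <- a$intensity
  if (inherits(b, "raman_spectrum")) b <- b$intensity
  if (length(a) != length(b)) {
    stop_ramanmf("spectra have different lengths (%d vs %d)",
                 length(a), length(b), class = "ramanmf_size_error")
  }
  if (normalize) {
    a <- minmax_normalize(a)
    b <- minmax_normalize(b)
  }
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop_ramanmf("zero-norm spectrum in cosine similarity",
                 class = "ramanmf_degenerate_error")
  }
  sum(a * b) / (na * nb)
}

#' Construct a similarity grid
#'
#' The machine form of a published similarity table: one row per
#' (model k, component) pair, one score column per reference label.
#'
#' @param scores Data frame with columns `model_k`, `component`, then one
#'   numeric column per reference.
#' @return An object of class `similarity_grid`.
#' @export
similarity_grid <- function(scores) {
  need <- c("model_k", "component")
  stopifnot(all(need %in% names(scores)))
  labels <- setdiff(names(scores), need)
  scores$model_k <- as.integer(scores$model_k)
  scores$component <- as.integer(scores$component)
  scores <- scores[order(scores$model_k, scores$component), , drop = FALSE]
  rownames(scores) <- NULL
  structure(list(scores = scores, labels = labels,
                 models = sort(unique(scores$model_k))),
            class = "similarity_grid")
}

#' @exportS3Method base::print
print.similarity_grid <- function(x, ...) {
  cat(sprintf(
    "<similarity_grid> models k = %s; %d references (%s); %d scores\n",
    paste(range(x$models), collapse = ".."), length(x$labels),
    paste(x$labels, collapse = ", "), nrow(x$scores) * length(x$labels)))
  invisible(x)
}

#' Score every component of a model ladder against a reference library
#'
#' Each model's gauge is fixed (unit-maximum component spectra), then every
#' resolved spectrum is min-max normalized and scored by cosine similarity
#' against every (equally normalized) reference. A ladder of k = 1..10
#' against four references yields the familiar 220-score grid.
#'
#' @param models An `nmf_ladder` (or list of `nmf_model`s).
#' @param library A [reference_library()] whose axis matches the axis the
#'   models were fitted on.
#' @param axis Optional wavenumber axis of the fitted data, used to check
#'   the library matches; if the library axis differs in length from the
#'   model spectra an error is raised regardless.
#' @return A `similarity_grid`.
#' @export
score_ladder <- function(models, library, axis = NULL) {
  stopifnot(inherits(library, "reference_library"))
  if (!is.null(axis) && !isTRUE(all.equal(axis, library$axis))) {
    stop_ramanmf("library axis does not match the cube axis",
                 class = "ramanmf_axis_error")
  }
  refs <- lapply(library$spectra, function(s) minmax_normalize(s$intensity))
  rows <- list()
  for (model in models) {
    model <- normalize_gauge(model)
    if (ncol(model$S) != length(library$axis)) {
      stop_ramanmf(
        "model spectra have %d channels but library axis has %d",
        ncol(model$S), length(library$axis), class = "ramanmf_axis_error")
    }
    for (comp in seq_len(model$k)) {
      comp_norm <- minmax_normalize(model$S[comp, ])
      sc <- vapply(refs, function(r) {
        cosine_similarity(comp_norm, r, normalize = FALSE)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- c(model_k = model$k, component = comp, sc)
    }
  }
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("model_k", "component", library$labels)
  similarity_grid(df)
}

#' Assign components of one model to reference species
#'
#' Each component's candidate species is its best-scoring reference. A
#' candidate is eligible only if the score reaches `tau` and beats the
#' component's second-best reference by at least `delta`. References are
#' then claimed greedily in order of descending eligible score, each
#' reference by at most one component, so the assignment is injective.
#'
#' @param grid A `similarity_grid`.
#' @param k Which model of the grid to assign.
#' @param params A [selection_params()].
#' @return Data frame with columns `reference`, `component`, `score`; zero
#'   rows when nothing is resolved.
#' @export
assign_components <- function(grid, k, params = selection_params()) {
  stopifnot(inherits(grid, "similarity_grid"))
  sub <- grid$scores[grid$scores$model_k == k, , drop = FALSE]
  if (!nrow(sub)) {
    stop_ramanmf("grid has no model with k = %d", k,
                 class = "ramanmf_param_error")
  }
  labels <- grid$labels
  cand <- data.frame(component = integer(0), reference = character(0),
                     score = numeric(0))
  for (i in seq_len(nrow(sub))) {
    sc <- as.numeric(sub[i, labels])
    ord <- order(sc, decreasing = TRUE)
    best <- sc[ord[1]]
    second <- if (length(sc) > 1) sc[ord[2]] else 0
    if (best >= params$tau && (best - second) >= params$delta) {
      cand <- rbind(cand, data.frame(
        component = sub$component[i], reference = labels[ord[1]],
        score = best))
    }
  }
  # greedy claim: descending score, ties broken by lower component index
  cand <- cand[order(-cand$score, cand$component), , drop = FALSE]
  taken_ref <- character(0)
  taken_comp <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$reference[i] %in% taken_ref) &&
        !(cand$component[i] %in% taken_comp)) {
      keep[i] <- TRUE
      taken_ref <- c(taken_ref, cand$reference[i])
      taken_comp <- c(taken_comp, cand$component[i])
    }
  }
  out <- cand[keep, c("reference", "component", "score"), drop = FALSE]
  out <- out[order(match(out$reference, labels)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Smallest model resolving each reference
#'
#' @param grid A `similarity_grid` covering a full ladder.
#' @param params A [selection_params()].
#' @return Named integer vector over the grid's references; `NA` where a
#'   reference is never assigned by any model.
#' @export
first_resolution <- function(grid, params = selection_params()) {
  stopifnot(inherits(grid, "similarity_grid"))
  out <- stats::setNames(rep(NA_integer_, length(grid$labels)), grid$labels)
  for (k in grid$models) {
    asg <- assign_components(grid, k, params)
    hit <- asg$reference[asg$reference %in% names(out)]
    newly <- hit[is.na(out[hit])]
    out[newly] <- k
    if (!anyNA(out)) break
  }
  out
}

#' Select the optimal NMF model from a scored ladder
#'
#' Implements the data-driven criteria: (1) a candidate model must resolve
#' every reference species; (2) among candidates, models are ranked by their
#' worst assigned similarity `m(k)`, and (3, parsimony) the smallest
#' candidate within `epsilon` of the best `m(k)` is selected. The RRE
#' sequence is carried through the report so the traditional elbow choice
#' can be displayed alongside; agreement of the resolved spatial maps with
#' the optical image remains a human judgment and is never scored.
#'
#' @param grid A `similarity_grid` over the ladder.
#' @param rre_per_k Optional numeric vector of relative reconstruction
#'   errors indexed by model k (e.g. `attr(ladder, "rre")`).
#' @param params A [selection_params()].
#' @return An object of class `selection_report` with fields `status`
#'   (`"ok"` or `"unresolved"`), `k_star`, `assignments` (list by model k),
#'   `first_resolution`, `m_per_k`, `candidates`, `stability` and
#'   `rre_per_k`. When no model resolves every species, `status` is
#'   `"unresolved"` and `k_star` is `NA` (no exception is thrown).
#' @export
select_optimal <- function(grid, rre_per_k = NULL,
                           params = selection_params()) {
  stopifnot(inherits(grid, "similarity_grid"))
  ks <- grid$models
  assignments <- lapply(ks, function(k) assign_components(grid, k, params))
  names(assignments) <- as.character(ks)
  nref <- length(grid$labels)

  m_per_k <- stats::setNames(vapply(assignments, function(a) {
    if (nrow(a) == nref) min(a$score) else NA_real_
  }, numeric(1)), as.character(ks))
  candidates <- ks[!is.na(m_per_k)]

  fr <- first_resolution(grid, params)

  if (!length(candidates)) {
    report <- structure(
      list(status = "unresolved", k_star = NA_integer_,
           assignments = assignments, first_resolution = fr,
           m_per_k = m_per_k, candidates = integer(0),
           stability = NULL, rre_per_k = rre_per_k, params = params,
           labels = grid$labels,
           message = paste("no model resolves all species;",
                           "consider increasing k_max")),
      class = "selection_report")
    return(report)
  }

  best_m <- max(m_per_k[as.character(candidates)])
  ok <- candidates[m_per_k[as.character(candidates)] >= best_m - params$epsilon]
  k_star <- min(ok)

  stability <- do.call(rbind, lapply(grid$labels, function(ref) {
    sc <- vapply(as.character(candidates), function(kc) {
      a <- assignments[[kc]]
      a$score[a$reference == ref]
    }, numeric(1))
    data.frame(reference = ref, mean = mean(sc),
               sd = if (length(sc) > 1) stats::sd(sc) else 0,
               min = min(sc), max = max(sc))
  }))

  structure(
    list(status = "ok", k_star = k_star, assignments = assignments,
         first_resolution = fr, m_per_k = m_per_k,
         candidates = candidates, stability = stability,
         rre_per_k = rre_per_k, params = params, labels = grid$labels,
         message = NULL),
    class = "selection_report")
}

#' @exportS3Method base::print
print.selection_report <- function(x, ...) {
  if (x$status == "unresolved") {
    cat("<selection_report> UNRESOLVED:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("<selection_report> optimal model: k* = %d\n", x$k_star))
  a <- x$assignments[[as.character(x$k_star)]]
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  %-12s component %d, similarity %.2f\n",
                a$reference[i], a$component[i], a$score[i]))
  }
  fr <- x$first_resolution
  cat("  first resolved at k:",
      paste(sprintf("%s=%s", names(fr), fr), collapse = ", "), "\n")
  invisible(x)
}

#' Assigned-similarity profile of one reference across the ladder
#'
#' Once a species is resolved its assigned similarity should stay high and
#' unfluctuating; this extracts that profile (models at or above the first
#' resolution) together with its standard deviation.
#'
#' @param grid A `similarity_grid`.
#' @param reference Reference label.
#' @param params A [selection_params()].
#' @return List with `scores` (named by model k; `NA` where the reference
#'   is not assigned in that model), `mean` and `sd` over the assigned
#'   models. Empty profile (`scores` length 0) for a never-resolved
#'   reference.
#' @export
stability_profile <- function(grid, reference, params = selection_params()) {
  stopifnot(inherits(grid, "similarity_grid"))
  if (!reference %in% grid$labels) {
    stop_ramanmf("reference '%s' not in grid (have: %s)", reference,
                 paste(grid$labels, collapse = ", "),
                 class = "ramanmf_param_error")
  }
  fr <- first_resolution(grid, params)[[reference]]
  if (is.na(fr)) {
    return(list(scores = stats::setNames(numeric(0), character(0)),
                mean = NA_real_, sd = NA_real_))
  }
  ks <- grid$models[grid$models >= fr]
  scores <- vapply(ks, function(k) {
    a <- assign_components(grid, k, params)
    s <- a$score[a$reference == reference]
    if (length(s)) s else NA_real_
  }, numeric(1))
  names(scores) <- as.character(ks)
  ok <- scores[!is.na(scores)]
  list(scores = scores, mean = mean(ok),
       sd = if (length(ok) > 1) stats::sd(ok) else 0)
}

#' Serialize a selection report to JSON
#'
#' @param report A `selection_report`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "selection_report"))
  asg <- lapply(report$assignments, function(a) {
    if (!nrow(a)) return(stats::setNames(list(), character(0)))
    stats::setNames(lapply(seq_len(nrow(a)), function(i) {
      list(component = a$component[i], score = a$score[i])
    }), a$reference)
  })
  fr <- as.list(report$first_resolution)
  fr <- lapply(fr, function(v) if (is.na(v)) NULL else v)
  obj <- list(
    status = report$status,
    k_star = if (is.na(report$k_star)) NULL else report$k_star,
    assignments = asg,
    first_resolution = fr,
    m_per_k = as.list(report$m_per_k),
    rre_per_k = if (is.null(report$rre_per_k)) NULL else
      as.list(stats::setNames(report$rre_per_k,
                              seq_along(report$rre_per_k))),
    stability = report$stability,
    params = unclass(report$params),
    message = report$message)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10,
                       null = "null", pretty = TRUE)
  invisible(path)
}
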