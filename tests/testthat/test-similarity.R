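test_that("cosine similarity matches hand values and rejects degenerates", {
  s <- sin(seq(0, 6, 0.1)) + 2
  expect_equal(cosine_similarity(s, s), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1), normalize = FALSE), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1), normalize = FALSE),
               1 / sqrt(2), tolerance = 1e-4)
  expect_error(cosine_similarity(c(0, 0), c(1, 2), normalize = FALSE),
               class = "ramanmf_degenerate_error")
  expect_error(cosine_similarity(1:3, 1:4), class = "ramanmf_size_error")
})

test_that("scoring is invariant to per-component scale and finds planted references", {
  axis <- seq(600, 798, 2)
  a <- make_pure_spectrum(list(band_spec(650, 12), band_spec(720, 20, 0.5)),
                          axis, "a")
  b <- make_pure_spectrum(list(band_spec(760, 15)), axis, "b")
  lib <- reference_library(list(a, b))
  S <- rbind(a$intensity * 37, b$intensity * 0.01)  # arbitrary gauges
  model <- structure(list(k = 2L, W = matrix(1, 4, 2), S = S),
                     class = "nmf_model")
  g <- score_ladder(list(model), lib)
  expect_equal(g$scores$a[1], 1.0, tolerance = 1e-9)
  expect_equal(g$scores$b[2], 1.0, tolerance = 1e-9)
  expect_true(all(g$scores[c("a", "b")] >= 0 & g$scores[c("a", "b")] <= 1))
})

test_that("a k=1..10 ladder against 4 references yields 220 scores", {
  set.seed(10)
  axis <- seq(600, 1798, 2)
  presets <- scene_band_presets()
  pure <- lapply(names(presets), function(sp)
    make_pure_spectrum(presets[[sp]], axis, sp))
  lib <- reference_library(pure)
  W <- random_nonneg(30, 4, 10)
  A <- W %*% t(vapply(pure, function(s) s$intensity, numeric(length(axis))))
  lad <- fit_ladder(A, k_max = 10, seed = 10, tol = 1e-5, max_iter = 500)
  g <- score_ladder(lad, lib)
  expect_equal(nrow(g$scores), 55L)
  expect_equal(nrow(g$scores) * length(g$labels), 220L)
})

test_that("component assignment reproduces the worked example grid", {
  g <- table1_grid()
  a8 <- assign_components(g, 8)
  expect_equal(nrow(a8), 4)
  got <- setNames(a8$component, a8$reference)
  expect_equal(got[["resin"]], 1)
  expect_equal(got[["glass"]], 2)
  expect_equal(got[["Bis-Tris"]], 3)
  expect_equal(got[["PanK"]], 7)
  sc <- setNames(a8$score, a8$reference)
  expect_equal(sc[["resin"]], 0.98)
  expect_equal(sc[["glass"]], 0.97)
  expect_equal(sc[["Bis-Tris"]], 0.84)
  expect_equal(sc[["PanK"]], 0.77)

  a2 <- assign_components(g, 2)
  expect_setequal(a2$reference, c("resin", "glass"))
  expect_equal(a2$score[a2$reference == "resin"], 0.99)
  expect_equal(a2$score[a2$reference == "glass"], 0.96)
})

test_that("components below the resolution threshold stay unassigned", {
  df <- data.frame(model_k = 1L, component = 1L, a = 0.4, b = 0.4)
  g <- similarity_grid(df)
  expect_equal(nrow(assign_components(g, 1)), 0)
})

test_that("assignment is injective in both directions", {
  # components 1 and 2 both best-match reference a; only the stronger one
  # claims it, and component 2 is left unassigned (its second-best
  # reference is not a candidate under the argmax rule)
  df <- data.frame(model_k = 3L, component = 1:3,
                   a = c(0.90, 0.85, 0.20), b = c(0.60, 0.20, 0.55))
  g <- similarity_grid(df)
  a <- assign_components(g, 3)
  expect_equal(anyDuplicated(a$reference), 0)
  expect_equal(anyDuplicated(a$component), 0)
  expect_equal(a$component[a$reference == "a"], 1)
  expect_equal(a$component[a$reference == "b"], 3)
  expect_false(2 %in% a$component)
})

test_that("first_resolution finds the smallest resolving model", {
  g <- table1_grid()
  fr <- first_resolution(g)
  expect_equal(fr[["resin"]], 1L)
  expect_equal(fr[["glass"]], 2L)
  expect_equal(fr[["Bis-Tris"]], 3L)
  expect_equal(fr[["PanK"]], 6L)

  low <- similarity_grid(data.frame(model_k = rep(1:2, 1:2),
                                    component = c(1L, 1L, 2L),
                                    a = rep(0.3, 3), b = rep(0.2, 3)))
  expect_true(all(is.na(first_resolution(low))))
})

test_that("select_optimal applies resolution, best-score and parsimony criteria", {
  g <- table1_grid()
  rep <- select_optimal(g)
  expect_equal(rep$status, "ok")
  expect_equal(rep$k_star, 8L)
  expect_setequal(rep$candidates, 6:10)
  a <- rep$assignments[["8"]]
  expect_equal(a$score[a$reference == "PanK"], 0.77)
  expect_equal(unname(rep$m_per_k[["8"]]), 0.77)

  # parsimony: a small model within epsilon of the best wins
  df <- data.frame(model_k = rep(2:4, 2:4),
                   component = c(1:2, 1:3, 1:4),
                   a = c(0.95, 0.2, 0.95, 0.2, 0.1, 0.95, 0.2, 0.1, 0.1),
                   b = c(0.2, 0.90, 0.2, 0.91, 0.1, 0.2, 0.92, 0.1, 0.1))
  g2 <- similarity_grid(df)
  expect_equal(select_optimal(g2)$k_star, 2L)

  # single-model, single-reference ladder
  g3 <- similarity_grid(data.frame(model_k = 1L, component = 1L, a = 0.99))
  r3 <- select_optimal(g3)
  expect_equal(r3$k_star, 1L)

  # nothing resolves everything -> structured unresolved outcome
  g4 <- similarity_grid(data.frame(model_k = 1L, component = 1L,
                                   a = 0.99, b = 0.2))
  r4 <- select_optimal(g4)
  expect_equal(r4$status, "unresolved")
  expect_true(is.na(r4$k_star))
  expect_match(r4$message, "k_max")
})

test_that("selection is invariant to reference order and component relabeling", {
  g <- table1_grid()
  base <- select_optimal(g)

  sc <- g$scores[, c("model_k", "component", "Bis-Tris", "PanK",
                     "resin", "glass")]
  r1 <- select_optimal(similarity_grid(sc))
  expect_equal(r1$k_star, base$k_star)
  expect_equal(sort(names(r1$first_resolution)),
               sort(names(base$first_resolution)))

  # relabel components within each model (reverse order)
  sc2 <- g$scores
  sc2$component <- ave(sc2$component, sc2$model_k,
                       FUN = function(x) rev(x))
  sc2 <- sc2[order(sc2$model_k, sc2$component), ]
  r2 <- select_optimal(similarity_grid(sc2))
  expect_equal(r2$k_star, base$k_star)
  expect_equal(r2$m_per_k, base$m_per_k)
})

test_that("stability profiles are high and flat once a species resolves", {
  g <- table1_grid()
  resin <- stability_profile(g, "resin")
  expect_true(all(resin$scores >= 0.98, na.rm = TRUE))
  expect_lt(resin$sd, 0.01)

  bistris <- stability_profile(g, "Bis-Tris")
  expect_true(all(bistris$scores >= 0.81, na.rm = TRUE))

  low <- similarity_grid(data.frame(model_k = 1L, component = 1L,
                                    a = 0.3, b = 0.9))
  prof <- stability_profile(low, "a")
  expect_length(prof$scores, 0)
  expect_error(stability_profile(g, "nope"), class = "ramanmf_param_error")
})

test_that("reports serialize to JSON with the documented keys", {
  g <- table1_grid()
  rep <- select_optimal(g, rre_per_k = seq(0.5, 0.05, length.out = 10))
  p <- tempfile(fileext = ".json")
  write_report_json(rep, p)
  j <- jsonlite::read_json(p)
  expect_equal(j$k_star, 8L)
  expect_named(j, c("status", "k_star", "assignments", "first_resolution",
                    "m_per_k", "rre_per_k", "stability", "params",
                    "message"), ignore.order = TRUE)
  expect_equal(j$assignments[["8"]]$PanK$score, 0.77)
})
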