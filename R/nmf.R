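#' Fit one non-negative matrix factorization model
#'
#' Factorizes a non-negative data matrix `A` (pixels x wavenumbers) into
#' `W %*% S` with `W` (pixels x k) holding per-pixel concentrations and `S`
#' (k x wavenumbers) holding component spectra, by Lee-Seung multiplicative
#' updates minimizing the squared Frobenius norm `0.5 * ||A - W S||_F^2`.
#' The objective is non-increasing at every iteration; convergence is
#' declared when the decrease over a 10-iteration window, relative to the
#' initial objective, falls below `tol`.
#'
#' Initialization is NNDSVD-a by default (non-negative double singular value
#' decomposition with zeros replaced by the data mean), which is
#' deterministic; `init = "random"` draws uniform factors from the given
#' seed.
#'
#' Components are returned ordered by descending total concentration
#' `colSums(W)` so that "component 1" is stable across runs.
#'
#' @param A Non-negative numeric matrix (or a [hyper_cube()], whose
#'   intensity matrix is used).
#' @param k Number of components, `1 <= k <= min(dim(A))`.
#' @param seed Integer seed (used by random init; recorded always).
#' @param tol Relative objective-change tolerance. Default 1e-7: multiplicative
#'   updates approach the concentration maps of strongly overlapped species
#'   slowly, so a loose tolerance leaves W under-converged even when the
#'   spectra already look right.
#' @param max_iter Iteration cap. Default 5000.
#' @param init `"nndsvda"` (default), `"nndsvd"` or `"random"`.
#' @param keep_trace If `TRUE`, record the objective after every iteration
#'   in `$trace` (used to verify monotonicity).
#' @return An object of class `nmf_model` with fields `k`, `W`, `S`, `rre`,
#'   `objective`, `n_iter`, `converged`, `seed` and optionally `trace`.
#' @export
nmf_fit <- function(A, k, seed = 0, tol = 1e-7, max_iter = 5000,
                    init = c("nndsvda", "nndsvd", "random"),
                    keep_trace = FALSE) {
  if (inherits(A, "hyper_cube")) A <- A$intensity
  A <- as.matrix(A)
  init <- match.arg(init)
  if (any(A < 0)) {
    stop_ramanmf("NMF input must be non-negative; min(A) = %g", min(A),
                 class = "ramanmf_domain_error")
  }
  if (k < 1 || k > min(dim(A))) {
    stop_ramanmf("k = %d out of range [1, %d]", k, min(dim(A)),
                 class = "ramanmf_param_error")
  }
  normA2 <- sum(A^2)
  if (normA2 == 0) {
    stop_ramanmf("NMF input is identically zero",
                 class = "ramanmf_degenerate_error")
  }

  fac <- nmf_init(A, k, init, seed)
  W <- fac$W
  S <- fac$S

  eps <- .Machine$double.eps
  obj0 <- 0.5 * sum((A - W %*% S)^2)
  obj_prev_check <- obj0
  obj <- obj0
  trace <- if (keep_trace) numeric(max_iter) else NULL
  n_iter <- 0L
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    # W <- W * (A S^T) / (W S S^T)
    StS <- tcrossprod(S)
    W <- W * (tcrossprod(A, S)) / (W %*% StS + eps)
    # S <- S * (W^T A) / (W^T W S)
    WtW <- crossprod(W)
    WtA <- crossprod(W, A)
    S <- S * WtA / (WtW %*% S + eps)
    # objective from the cached Gram products (exact for current W, S)
    obj <- 0.5 * (normA2 - 2 * sum(WtA * S) + sum(WtW * tcrossprod(S)))
    n_iter <- it
    if (keep_trace) trace[it] <- obj
    if (it %% 10L == 0L) {
      if ((obj_prev_check - obj) / obj0 < tol) {
        converged <- TRUE
        break
      }
      obj_prev_check <- obj
    }
  }

  # order components by total concentration, largest first
  ord <- order(colSums(W), decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  S <- S[ord, , drop = FALSE]

  resid <- A - W %*% S
  model <- structure(
    list(k = as.integer(k), W = W, S = S,
         rre = sqrt(sum(resid^2) / normA2),
         objective = obj, n_iter = n_iter, converged = converged,
         seed = as.integer(seed), init = init,
         trace = if (keep_trace) trace[seq_len(n_iter)] else NULL),
    class = "nmf_model")
  model
}

#' @exportS3Method base::print
print.nmf_model <- function(x, ...) {
  cat(sprintf(
    "<nmf_model> k = %d, RRE = %.4g, %d iterations (%s), init = %s\n",
    x$k, x$rre, x$n_iter,
    if (x$converged) "converged" else "max_iter reached", x$init))
  invisible(x)
}

# internal: deterministic NNDSVD / NNDSVD-a, or seeded random init
nmf_init <- function(A, k, init, seed) {
  n <- nrow(A)
  m <- ncol(A)
  if (init == "random") {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
    scale <- sqrt(mean(A) / k)
    return(list(W = matrix(stats::runif(n * k), n, k) * scale,
                S = matrix(stats::runif(k * m), k, m) * scale))
  }
  sv <- svd(A, nu = k, nv = k)
  W <- matrix(0, n, k)
  S <- matrix(0, k, m)
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  S[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      u <- sv$u[, j]
      v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
      nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
      if (nup * nvp >= nun * nvn) {
        sigma <- nup * nvp
        if (sigma > 0) {
          W[, j] <- sqrt(sv$d[j] * sigma) * up / nup
          S[j, ] <- sqrt(sv$d[j] * sigma) * vp / nvp
        }
      } else {
        sigma <- nun * nvn
        if (sigma > 0) {
          W[, j] <- sqrt(sv$d[j] * sigma) * un / nun
          S[j, ] <- sqrt(sv$d[j] * sigma) * vn / nvn
        }
      }
    }
  }
  if (init == "nndsvda") {
    avg <- mean(A)
    W[W == 0] <- avg
    S[S == 0] <- avg
  }
  list(W = W, S = S)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Reconstruct the data matrix from a fitted model
#'
#' @param model An `nmf_model`.
#' @return `W %*% S`, with the shape of the original data matrix.
#' @export
reconstruct <- function(model) {
  stopifnot(inherits(model, "nmf_model"))
  model$W %*% model$S
}

#' Relative reconstruction error
#'
#' `||A - W S||_F / ||A||_F`: zero for a perfect fit, one when the model
#' reconstructs nothing. The conventional diagnostic plotted against the
#' number of components to look for an elbow.
#'
#' @param A The data matrix the model was fitted on (or a [hyper_cube()]).
#' @param model An `nmf_model`.
#' @return A scalar in [0, 1] for non-negative `A`.
#' @export
rre <- function(A, model) {
  if (inherits(A, "hyper_cube")) A <- A$intensity
  A <- as.matrix(A)
  if (!all(dim(A) == c(nrow(model$W), ncol(model$S)))) {
    stop_ramanmf("shape mismatch: A is %d x %d, model reconstructs %d x %d",
                 nrow(A), ncol(A), nrow(model$W), ncol(model$S),
                 class = "ramanmf_size_error")
  }
  nA <- sqrt(sum(A^2))
  if (nA == 0) {
    stop_ramanmf("||A||_F = 0: relative error undefined",
                 class = "ramanmf_degenerate_error")
  }
  sqrt(sum((A - reconstruct(model))^2)) / nA
}

#' Fit a ladder of NMF models with 1..K components
#'
#' Each model is fitted independently from its own deterministic
#' initialization; nothing is warm-started, so the ladder reproduces the
#' protocol of constructing K independent models and comparing them.
#'
#' @param A Non-negative matrix or [hyper_cube()].
#' @param k_max Largest component count; models are fitted for k = 1..k_max.
#' @param seed,tol,max_iter,init Passed to [nmf_fit()].
#' @return A list of class `nmf_ladder` of `nmf_model`s in ascending k, with
#'   an `rre` attribute vector.
#' @export
fit_ladder <- function(A, k_max = 10, seed = 0, tol = 1e-7, max_iter = 5000,
                       init = "nndsvda") {
  if (inherits(A, "hyper_cube")) A <- A$intensity
  A <- as.matrix(A)
  if (k_max > min(dim(A))) {
    stop_ramanmf("k_max = %d exceeds min(dim(A)) = %d", k_max, min(dim(A)),
                 class = "ramanmf_param_error")
  }
  models <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    models[[k]] <- tryCatch(
      nmf_fit(A, k, seed = seed, tol = tol, max_iter = max_iter, init = init),
      error = function(e) {
        stop_ramanmf("ladder failed at k = %d: %s", k, conditionMessage(e),
                     class = "ramanmf_ladder_error")
      })
  }
  structure(models, class = "nmf_ladder",
            rre = vapply(models, function(m) m$rre, numeric(1)))
}

#' @exportS3Method base::print
print.nmf_ladder <- function(x, ...) {
  cat(sprintf("<nmf_ladder> %d models (k = 1..%d)\n", length(x), length(x)))
  cat("  RRE:", paste(sprintf("%.3f", attr(x, "rre")), collapse = " "), "\n")
  invisible(x)
}

#' Fix the scale gauge of an NMF model
#'
#' NMF is invariant to rescaling a column of `W` by `alpha` and the matching
#' row of `S` by `1/alpha`. The canonical gauge scales every component
#' spectrum to unit maximum (`max(S[c, ]) = 1`), compensating in `W`, so
#' spectra are comparable across components and models before similarity
#' scoring.
#'
#' @param model An `nmf_model`.
#' @return The model with the gauge fixed; reconstruction is unchanged.
#' @export
normalize_gauge <- function(model) {
  stopifnot(inherits(model, "nmf_model"))
  for (c in seq_len(model$k)) {
    m <- max(model$S[c, ])
    if (m > 0) {
      model$S[c, ] <- model$S[c, ] / m
      model$W[, c] <- model$W[, c] * m
    }
  }
  model
}
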