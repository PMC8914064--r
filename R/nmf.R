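#' Nonnegative matrix factorization by multiplicative updates
#'
#' Factorizes a nonnegative feature-by-sample matrix `V` (M x N) as
#' `V ~ W H` with `W >= 0` (M x k) and `H >= 0` (k x N), minimizing the
#' Frobenius objective `||V - WH||_F^2` with the classic multiplicative
#' update rules (denominator guard 1e-10). Iteration stops when the
#' relative RSS change falls below `tol` or at `max_iter` sweeps. On
#' return, columns of `W` are scaled to unit Euclidean norm with the
#' compensation absorbed into `H`, which pins down the scale of the
#' component scores.
#'
#' @param V Nonnegative numeric matrix (features x samples), or a feature
#'   tibble with a `sample_id` column (transposed internally).
#' @param k Rank, `1 <= k < min(M, N)`.
#' @param seed Integer seed for the uniform random initialization.
#' @param max_iter,tol Stopping rule (defaults 2000 sweeps, 1e-6 relative
#'   RSS change).
#' @return An object of class `nmf_fit`: `W`, `H`, `k`, `rss`,
#'   `rss_history`, `n_iter`, `converged`, `seed`.
#' @examples
#' V <- matrix(runif(20 * 12), 20)
#' fit <- nmf_fit(V, k = 3, seed = 1)
#' fit$rss
#' @export
nmf_fit <- function(V, k, seed = 1L, max_iter = 2000L, tol = 1e-6) {
  V <- as_feature_matrix(V)
  M <- nrow(V); N <- ncol(V)
  if (any(V < 0)) abort("`V` must be elementwise nonnegative.")
  if (k < 1L || k >= min(M, N)) {
    abort("`k` must satisfy 1 <= k < min(nrow, ncol).")
  }
  init <- with_seed(seed, {
    list(W = matrix(runif(M * k), M) * mean(V) + 1e-9,
         H = matrix(runif(k * N), k) * mean(V) + 1e-9)
  })
  res <- nmf_mu_cpp(V, init$W, init$H, as.integer(max_iter), tol, 1e-10)
  W <- res$W; H <- res$H
  norms <- sqrt(colSums(W^2))
  norms[norms == 0] <- 1
  W <- sweep(W, 2, norms, `/`)
  H <- H * norms
  rownames(W) <- rownames(V)
  colnames(H) <- colnames(V)
  colnames(W) <- rownames(H) <- paste0("component_", seq_len(k))
  structure(
    list(W = W, H = H, k = as.integer(k),
         rss = res$rss_history[length(res$rss_history)],
         rss_history = res$rss_history,
         n_iter = res$n_iter, converged = res$converged,
         seed = as.integer(seed)),
    class = "nmf_fit"
  )
}

as_feature_matrix <- function(V) {
  if (inherits(V, "data.frame")) V <- features_to_matrix(V)
  if (!is.matrix(V)) abort("`V` must be a matrix or a feature tibble.")
  storage.mode(V) <- "double"
  V
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("<nmf_fit> k = %d, rss = %.6g after %d iterations (%s)\n",
              x$k, x$rss, x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an NMF fit into a long loading/score table
#'
#' @param x An `nmf_fit`.
#' @param matrix `"W"` for feature loadings or `"H"` for sample scores.
#' @param ... Unused.
#' @return A tibble: `component` plus `feature`/`loading` or
#'   `sample_id`/`score`.
#' @method tidy nmf_fit
#' @export
tidy.nmf_fit <- function(x, matrix = c("W", "H"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "W") {
    as_tibble(x$W, rownames = "feature") |>
      tidyr::pivot_longer(-"feature", names_to = "component",
                          values_to = "loading")
  } else {
    as_tibble(t(x$H), rownames = "sample_id") |>
      tidyr::pivot_longer(-"sample_id", names_to = "component",
                          values_to = "score")
  }
}

#' @rdname tidy.nmf_fit
#' @method glance nmf_fit
#' @export
glance.nmf_fit <- function(x, ...) {
  tibble(k = x$k, rss = x$rss, n_iter = x$n_iter, converged = x$converged,
         seed = x$seed)
}

#' Residual-sum-of-squares curve over candidate ranks
#'
#' Runs `n_restarts` seeded factorizations per rank on a grid of candidate
#' ranks and keeps the best (lowest) RSS per rank. Restart seeds derive
#' deterministically from the master seed and the (k, restart) index, so
#' the curve is reproducible bit for bit.
#'
#' @inheritParams nmf_fit
#' @param k_min,k_max Rank grid (defaults 2..10).
#' @param n_restarts Random restarts per rank (the study protocol uses 100).
#' @return A tibble of class `nmf_rss_curve`: `k`, `rss`, `best_seed`,
#'   `n_restarts`.
#' @export
nmf_rss_curve <- function(V, k_min = 2L, k_max = 10L, n_restarts = 100L,
                          seed = 1L, max_iter = 2000L, tol = 1e-6) {
  V <- as_feature_matrix(V)
  if (k_max >= min(dim(V))) abort("`k_max` must be < min(dim(V)).")
  if (k_min < 1L || k_min > k_max) abort("Need 1 <= k_min <= k_max.")
  rows <- purrr::map(seq.int(k_min, k_max), function(k) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      s <- derive_seed(seed, k, r)
      fit <- nmf_fit(V, k, seed = s, max_iter = max_iter, tol = tol)
      if (is.null(best) || fit$rss < best$rss) {
        best <- list(rss = fit$rss, seed = s)
      }
    }
    tibble(k = k, rss = best$rss, best_seed = best$seed,
           n_restarts = as.integer(n_restarts))
  })
  out <- purrr::list_rbind(rows)
  class(out) <- c("nmf_rss_curve", class(out))
  out
}

#' Select the rank at the inflection of the RSS curve
#'
#' The chosen rank maximizes the discrete second difference
#' `rss(k-1) - 2 rss(k) + rss(k+1)` over interior grid points — the first
#' bend of the curve; ties break toward the smaller rank. A flat curve
#' returns the smallest rank with a warning.
#'
#' @param curve An [nmf_rss_curve()] (or any tibble with `k` and `rss`,
#'   ordered by `k`).
#' @return The selected rank (integer).
#' @export
select_rank <- function(curve) {
  if (nrow(curve) < 3L) abort("Rank selection needs at least 3 grid points.")
  k <- curve$k; rss <- curve$rss
  if (max(rss) - min(rss) <= 1e-12 * max(abs(rss), 1)) {
    warn("RSS curve is flat; returning the smallest rank.")
    return(k[1])
  }
  d2 <- rss[-c(length(rss) - 1L, length(rss))] -
    2 * rss[-c(1L, length(rss))] + rss[-(1:2)]
  k[-c(1L, length(k))][which.max(d2)]
}

#' Refit the best factorization at a chosen rank
#'
#' @param V Feature matrix or tibble (as in [nmf_fit()]).
#' @param curve An [nmf_rss_curve()].
#' @param k Rank to refit (default: [select_rank()] of the curve).
#' @param ... Passed to [nmf_fit()].
#' @return An `nmf_fit` reproduced from the stored best restart seed.
#' @export
nmf_best_fit <- function(V, curve, k = NULL, ...) {
  if (is.null(k)) k <- select_rank(curve)
  row <- which(curve$k == k)
  if (!length(row)) abort("`k` is not on the curve's grid.")
  nmf_fit(V, k, seed = curve$best_seed[row], ...)
}

#' @method autoplot nmf_rss_curve
#' @export
autoplot.nmf_rss_curve <- function(object, ...) {
  k_sel <- tryCatch(select_rank(object), warning = function(w) NA_integer_)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$rss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = k_sel, linetype = 2, colour = "red") +
    ggplot2::labs(x = "rank k", y = "best residual sum of squares",
                  title = "NMF rank selection (RSS inflection)") +
    ggplot2::theme_minimal()
}

#' Standardize component scores to training z-scores
#'
#' Each row of `H` is centred and scaled to mean 0, SD 1 across the
#' training samples (population SD); the per-row parameters are stored so
#' new cohorts can be mapped onto the frozen training scale.
#'
#' @param H A k x N score matrix, or an `nmf_fit`.
#' @return An object of class `component_scores`: `z` (k x N), `center`,
#'   `scale`.
#' @export
standardize_scores <- function(H) {
  if (inherits(H, "nmf_fit")) H <- H$H
  if (ncol(H) < 2L) abort("Need at least 2 samples to standardize.")
  ctr <- rowMeans(H)
  scl <- sqrt(rowMeans((H - ctr)^2))
  if (any(scl <= 0)) abort("Zero-variance component score row.")
  z <- (H - ctr) / scl
  structure(list(z = z, center = ctr, scale = scl),
            class = "component_scores")
}

#' Apply frozen standardization parameters to new scores
#'
#' @param scores A `component_scores` carrying the training parameters.
#' @param H_new k x N score matrix for the new cohort.
#' @return The z-scored matrix on the frozen training scale.
#' @export
apply_standardization <- function(scores, H_new) {
  if (nrow(H_new) != length(scores$center)) {
    abort("`H_new` has a different number of components than the training fit.")
  }
  (H_new - scores$center) / scores$scale
}

#' Project a new cohort onto trained components
#'
#' Solves, per sample, the nonnegative least-squares problem
#' `min_{h >= 0} ||v - W h||^2` with the trained (unit-norm) loading matrix
#' `W`, giving validation component scores without refitting.
#'
#' @param W Trained M x k loading matrix (or an `nmf_fit`).
#' @param V_new M x N nonnegative matrix (or feature tibble) with rows
#'   aligned to the features of `W`.
#' @return k x N score matrix.
#' @export
project_cohort <- function(W, V_new) {
  if (inherits(W, "nmf_fit")) W <- W$W
  V_new <- as_feature_matrix(V_new)
  if (!is.null(rownames(W)) && !is.null(rownames(V_new))) {
    if (!identical(rownames(W), rownames(V_new))) {
      miss <- setdiff(rownames(W), rownames(V_new))
      extra <- setdiff(rownames(V_new), rownames(W))
      abort(paste0(
        "Feature mismatch between trained W and the new cohort.",
        if (length(miss)) paste0(" Missing: ", paste(miss, collapse = ", "), "."),
        if (length(extra)) paste0(" Unexpected: ", paste(extra, collapse = ", "), ".")
      ))
    }
  } else if (nrow(W) != nrow(V_new)) {
    abort("Feature mismatch: W and V_new have different numbers of rows.")
  }
  if (any(V_new < 0)) abort("`V_new` must be nonnegative.")
  H <- apply(V_new, 2, function(v) {
    if (all(v == 0)) return(rep(0, ncol(W)))
    pracma::lsqnonneg(W, v)$x
  })
  H <- matrix(H, nrow = ncol(W), dimnames = list(colnames(W), colnames(V_new)))
  H
}
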