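#' Assemble per-sample feature rows into one feature table
#'
#' Binds one-row feature tibbles (as produced by [extract_all()]) and orders
#' them by the declared sample ids. All rows must share the same feature
#' names in the same order.
#'
#' @param feature_rows List of one-row feature tibbles, or a single tibble.
#' @param sample_ids Declared sample order; defaults to the ids present.
#' @return A tibble with `sample_id` and one column per feature.
#' @export
assemble_features <- function(feature_rows, sample_ids = NULL) {
  tbl <- if (inherits(feature_rows, "data.frame")) {
    as_tibble(feature_rows)
  } else {
    nm <- lapply(feature_rows, names)
    if (!all(vapply(nm, identical, logical(1), nm[[1]]))) {
      abort("All feature rows must share the same feature names and order.")
    }
    purrr::list_rbind(lapply(feature_rows, as_tibble))
  }
  if (anyDuplicated(tbl$sample_id)) abort("Duplicate sample ids.")
  if (is.null(sample_ids)) sample_ids <- tbl$sample_id
  if (!setequal(sample_ids, tbl$sample_id) ||
      length(sample_ids) != nrow(tbl)) {
    abort("`sample_ids` must be a permutation of the ids present.")
  }
  tbl[match(sample_ids, tbl$sample_id), ]
}

#' Drop highly collinear features
#'
#' Greedy elimination on pairwise Pearson correlation: constant features are
#' dropped first; then, while any pair of remaining features has
#' `|r| > r_threshold`, the member of the most-correlated pair with the
#' larger mean absolute correlation to all remaining features is dropped
#' (ties go to the later feature in column order). A second pass at the
#' same threshold drops nothing.
#'
#' @param features Feature tibble (rows = samples, `sample_id` column).
#' @param r_threshold Absolute Pearson correlation above which a pair is
#'   considered collinear (default 0.9).
#' @return A list of class `rad_collinearity`: `features` (filtered tibble),
#'   `dropped` (character), `r_threshold`.
#' @export
filter_collinear <- function(features, r_threshold = 0.9) {
  V <- features_to_matrix(features) # M x N
  if (ncol(V) < 3L) abort("Need at least 3 samples to assess collinearity.")
  sds <- apply(V, 1, sd)
  dropped <- rownames(V)[sds == 0]
  keep <- rownames(V)[sds > 0]
  X <- t(V[keep, , drop = FALSE])
  cm <- abs(suppressWarnings(cor(X)))
  diag(cm) <- 0
  repeat {
    if (nrow(cm) < 2L) break
    mx <- max(cm)
    if (mx <= r_threshold) break
    hit <- which(cm == mx, arr.ind = TRUE)[1, ]
    a <- rownames(cm)[hit[1]]; b <- rownames(cm)[hit[2]]
    ma <- mean(cm[a, ]); mb <- mean(cm[b, ])
    # drop the member more correlated with everything else; on a tie the
    # later one in the declared column order goes
    drop <- if (ma > mb) a else if (mb > ma) b else {
      ord <- match(c(a, b), keep)
      c(a, b)[which.max(ord)]
    }
    dropped <- c(dropped, drop)
    cm <- cm[rownames(cm) != drop, colnames(cm) != drop, drop = FALSE]
  }
  if (nrow(cm) < 2L) {
    abort("Fewer than 2 features survive the collinearity filter.")
  }
  survivors <- keep[keep %in% rownames(cm)]
  structure(
    list(
      features = features[, c("sample_id", survivors)],
      dropped = dropped,
      r_threshold = r_threshold
    ),
    class = "rad_collinearity"
  )
}

#' Min-max scale features to the unit interval
#'
#' Scales each feature to `[0, 1]` using its training minimum and maximum,
#' the nonnegativity mapping the factorization requires. The parameters are
#' retained so a validation cohort can be projected onto the training
#' scale; out-of-range values clip to `[0, 1]`.
#'
#' @param features Feature tibble (rows = samples).
#' @return A list of class `rad_scaling`: `features` (scaled tibble),
#'   `params` (tibble `feature`, `min`, `max`).
#' @export
scale_unit <- function(features) {
  V <- features_to_matrix(features)
  rng <- t(apply(V, 1, range))
  if (any(rng[, 1] == rng[, 2])) {
    abort(paste0("Constant features cannot be min-max scaled: ",
                 paste(rownames(V)[rng[, 1] == rng[, 2]], collapse = ", ")))
  }
  params <- tibble(feature = rownames(V), min = rng[, 1], max = rng[, 2])
  scaled <- (V - rng[, 1]) / (rng[, 2] - rng[, 1])
  structure(
    list(features = matrix_to_features(scaled), params = params),
    class = "rad_scaling"
  )
}

#' Apply frozen scaling parameters to a new cohort
#'
#' @param features Feature tibble of the new cohort; must contain exactly
#'   the features named in `params`.
#' @param params Scaling parameters from [scale_unit()] (`$params`).
#' @return Scaled feature tibble, entries clipped to `[0, 1]`.
#' @export
apply_scaling <- function(features, params) {
  have <- setdiff(names(features), "sample_id")
  miss <- setdiff(params$feature, have)
  if (length(miss)) {
    abort(paste0("New cohort is missing features: ",
                 paste(miss, collapse = ", ")))
  }
  V <- features_to_matrix(features[, c("sample_id", params$feature)])
  scaled <- (V - params$min) / (params$max - params$min)
  scaled[scaled < 0] <- 0
  scaled[scaled > 1] <- 1
  matrix_to_features(scaled)
}

# inverse of scale_unit for a scaled matrix, used in round-trip checks
unscale_unit <- function(features, params) {
  V <- features_to_matrix(features[, c("sample_id", params$feature)])
  matrix_to_features(V * (params$max - params$min) + params$min)
}
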