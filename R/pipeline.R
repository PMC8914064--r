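#' Configuration for a full training run
#'
#' @param r_threshold Collinearity threshold for [filter_collinear()].
#' @param k_min,k_max Candidate rank grid for the RSS curve.
#' @param n_restarts Random restarts per rank (the study protocol uses
#'   100; smaller values are adequate for small matrices).
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.
#' @param cutoff `"youden"` to derive the z-score cutoff from the training
#'   ROC, or a fixed number (e.g. 0.2, the cutoff the motivating study
#'   froze for both cohorts).
#' @param horizon_months Horizon of the binary failure label.
#' @param n_bins Calibration bins.
#' @param max_iter,tol NMF stopping rule.
#' @return A list of class `run_config`.
#' @export
run_config <- function(r_threshold = 0.9, k_min = 2L, k_max = 10L,
                       n_restarts = 100L, seed = 42L, cutoff = "youden",
                       horizon_months = 12, n_bins = 3,
                       max_iter = 2000L, tol = 1e-6) {
  if (!(identical(cutoff, "youden") || is_scalar_number(cutoff))) {
    abort('`cutoff` must be "youden" or a single number.')
  }
  structure(
    list(r_threshold = r_threshold, k_min = as.integer(k_min),
         k_max = as.integer(k_max), n_restarts = as.integer(n_restarts),
         seed = as.integer(seed), cutoff = cutoff,
         horizon_months = horizon_months, n_bins = n_bins,
         max_iter = as.integer(max_iter), tol = tol),
    class = "run_config"
  )
}

#' Train the full radiomics-NMF model on a cohort
#'
#' Runs the training pipeline end to end: collinearity filtering, min-max
#' scaling to the nonnegative unit interval, the restarted NMF RSS curve
#' over the rank grid, rank selection at the curve's inflection, component
#' z-scoring, Cox-based selection of the most prognostic component, cutoff
#' determination, and the full performance evaluation. Everything needed to
#' score a new cohort without refitting (feature list, scaling parameters,
#' loading matrix, score standardization, selected component, Cox fit and
#' cutoff) is frozen in the returned model.
#'
#' @param features Feature tibble (rows = samples, `sample_id` + numeric
#'   columns), e.g. from [extract_cohort()] or [make_cohort()].
#' @param clinical Clinical tibble: `sample_id`, `time_months`, `event`,
#'   `failure_12mo`, aligned by `sample_id`.
#' @param config A [run_config()].
#' @return An object of class `radnmf_model`.
#' @examples
#' \donttest{
#' ch <- make_cohort(cohort_spec(seed = 7))
#' model <- run_training(ch$features, ch$clinical,
#'                       run_config(n_restarts = 5, seed = 7))
#' glance(model$evaluation)
#' }
#' @export
run_training <- function(features, clinical, config = run_config()) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config.")
  clinical <- check_clinical(clinical)
  if (!setequal(features$sample_id, clinical$sample_id)) {
    abort("run_training: feature and clinical tables cover different samples.")
  }
  clinical <- clinical[match(features$sample_id, clinical$sample_id), ]

  filt <- filter_collinear(features, config$r_threshold)
  scal <- scale_unit(filt$features)
  V <- features_to_matrix(scal$features)

  curve <- nmf_rss_curve(V, k_min = config$k_min, k_max = config$k_max,
                         n_restarts = config$n_restarts,
                         seed = derive_seed(config$seed, 1L),
                         max_iter = config$max_iter, tol = config$tol)
  k <- select_rank(curve)
  fit <- nmf_best_fit(V, curve, k, max_iter = config$max_iter,
                      tol = config$tol)
  # every cohort, training included, is scored through the same map:
  # NNLS projection onto the trained loadings; this keeps training and
  # validation scoring functions identical
  H_train <- project_cohort(fit, V)
  scores <- standardize_scores(H_train)
  sel <- select_component(scores, clinical)
  z_sel <- scores$z[sel$index, ]
  if (sel$flipped) z_sel <- -z_sel

  cox <- cox_fit(clinical, z_sel)
  cutoff <- if (identical(config$cutoff, "youden")) {
    youden_cutoff(z_sel, clinical$failure_12mo)$cutoff
  } else {
    config$cutoff
  }
  ev <- evaluate_scores(z_sel, clinical, cutoff, cox = cox,
                        horizon_months = config$horizon_months,
                        n_bins = config$n_bins)
  structure(
    list(config = config, dropped = filt$dropped,
         feature_names = setdiff(names(filt$features), "sample_id"),
         scaling = scal$params, rss_curve = curve, k = k, nmf = fit,
         scores = scores, selection = sel, component = sel$index,
         flipped = sel$flipped, cox = cox, cutoff = cutoff,
         train_z = z_sel, train_clinical = clinical, evaluation = ev),
    class = "radnmf_model"
  )
}

#' @export
print.radnmf_model <- function(x, ...) {
  cat(sprintf(
    paste0("<radnmf_model> %d features kept (%d dropped), rank %d, ",
           "component %d%s, cutoff %.3g\n"),
    length(x$feature_names), length(x$dropped), x$k, x$component,
    if (x$flipped) " (flipped)" else "", x$cutoff))
  print(x$evaluation)
  invisible(x)
}

#' Score and evaluate a new cohort with a frozen model
#'
#' Applies the training-frozen feature list, min-max parameters,
#' nonnegative least-squares projection onto the trained loadings, frozen
#' z-standardization, frozen component choice and frozen cutoff to a new
#' cohort; nothing is refit. Calibration risks use the training Cox fit and
#' baseline hazard.
#'
#' @param model A `radnmf_model` from [run_training()].
#' @param features Feature tibble of the new cohort (must contain every
#'   retained training feature).
#' @param clinical Clinical tibble of the new cohort.
#' @return A `rad_eval` report (with the projected scores in `$scores`).
#' @export
run_validation <- function(model, features, clinical) {
  if (!inherits(model, "radnmf_model")) abort("`model` must be a radnmf_model.")
  clinical <- check_clinical(clinical)
  if (nrow(features) == 0L) abort("Validation cohort is empty.")
  if (!setequal(features$sample_id, clinical$sample_id)) {
    abort("run_validation: feature and clinical tables cover different samples.")
  }
  clinical <- clinical[match(features$sample_id, clinical$sample_id), ]
  miss <- setdiff(model$feature_names, names(features))
  if (length(miss)) {
    abort(paste0("Validation cohort is missing trained features: ",
                 paste(miss, collapse = ", ")))
  }
  scaled <- apply_scaling(features[, c("sample_id", model$feature_names)],
                          model$scaling)
  H_new <- project_cohort(model$nmf, scaled)
  z <- apply_standardization(model$scores, H_new)
  z_sel <- z[model$component, ]
  if (model$flipped) z_sel <- -z_sel
  evaluate_scores(z_sel, clinical, model$cutoff, cox = model$cox,
                  train_scores = model$train_z,
                  train_cohort = model$train_clinical,
                  horizon_months = model$config$horizon_months,
                  n_bins = model$config$n_bins)
}

check_clinical <- function(clinical) {
  need <- c("sample_id", "time_months", "event", "failure_12mo")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) {
    abort(paste0("Clinical table is missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  if (any(clinical$time_months <= 0)) abort("Times must be positive.")
  bad <- clinical$failure_12mo == 1 &
    !(clinical$event == 1 & clinical$time_months <= 12 + 1e-9)
  if (any(bad)) {
    abort("`failure_12mo` must equal 1 exactly when event = 1 and time <= 12.")
  }
  clinical
}
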