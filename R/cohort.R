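#' Specify a synthetic radiomics cohort
#'
#' Describes a nonnegative feature-by-sample matrix with a planted low-rank
#' structure, one component of which drives an exponential
#' proportional-hazards failure process with administrative censoring. The
#' defaults emulate the training cohort of the motivating study: about one
#' hundred samples with an 11% one-year failure rate; set
#' `n_samples = 24, target_failure = 0.46` for a validation-like cohort.
#'
#' @param n_samples Cohort size N.
#' @param n_features Number of features M.
#' @param k_true Planted rank (number of true components); must be smaller
#'   than `min(M, N)`.
#' @param component_sparsity Fraction of zero loadings per true component.
#'   Supports are allocated from a random permutation of the features in
#'   consecutive blocks, so at the default (0.8 with 54 features and rank
#'   5) the components are nearly disjoint — distinct radiomic signatures
#'   of comparable energy, which is what makes the planted rank
#'   identifiable from the RSS curve.
#' @param noise_sd SD of the additive Gaussian noise on the feature scale;
#'   noise is truncated (clipped) at zero so V stays nonnegative.
#' @param hazard_component Index of the true component whose z-scored sample
#'   scores drive the hazard.
#' @param log_hazard_ratio Log hazard ratio per unit z-score of the hazard
#'   component.
#' @param target_failure Marginal probability of failure before
#'   `failure_horizon`; the baseline hazard is calibrated to it unless
#'   `baseline_hazard` is given.
#' @param baseline_hazard Events/month for a sample at z = 0; `NULL` (the
#'   default) solves for the rate matching `target_failure`.
#' @param censoring_time Administrative censoring time, months.
#' @param failure_horizon Horizon (months) defining the binary failure label.
#' @param seed Integer master seed.
#' @return A validated spec of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 104L,
                        n_features = 54L,
                        k_true = 5L,
                        component_sparsity = 0.8,
                        noise_sd = 0.05,
                        hazard_component = 3L,
                        log_hazard_ratio = 0.9,
                        target_failure = 0.11,
                        baseline_hazard = NULL,
                        censoring_time = 36,
                        failure_horizon = 12,
                        seed = 1L) {
  n_samples <- as.integer(n_samples); n_features <- as.integer(n_features)
  k_true <- as.integer(k_true)
  if (k_true < 1L || k_true >= min(n_features, n_samples)) {
    abort("`k_true` must satisfy 1 <= k_true < min(n_features, n_samples).")
  }
  if (component_sparsity < 0 || component_sparsity >= 1) {
    abort("`component_sparsity` must be in [0, 1).")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  hazard_component <- as.integer(hazard_component)
  if (hazard_component < 1L || hazard_component > k_true) {
    abort("`hazard_component` must index a true component.")
  }
  if (!is.null(baseline_hazard)) check_positive(baseline_hazard, "baseline_hazard")
  check_positive(censoring_time, "censoring_time")
  check_positive(failure_horizon, "failure_horizon")
  if (is.null(baseline_hazard) &&
      (target_failure <= 0 || target_failure >= 1)) {
    abort("`target_failure` must be in (0, 1).")
  }
  structure(
    list(n_samples = n_samples, n_features = n_features, k_true = k_true,
         component_sparsity = component_sparsity, noise_sd = noise_sd,
         hazard_component = hazard_component,
         log_hazard_ratio = log_hazard_ratio,
         target_failure = target_failure, baseline_hazard = baseline_hazard,
         censoring_time = censoring_time, failure_horizon = failure_horizon,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort with planted components
#'
#' Draws sparse nonnegative factors `W_true` (M x k, unit-norm columns) and
#' `H_true` (k x N, gamma-distributed scores), forms
#' `V = W_true H_true + noise` clipped at zero, and simulates
#' recurrence-free survival from an exponential proportional-hazards model
#' on the z-scored hazard-component row of `H_true`. When
#' `baseline_hazard` is unset it is calibrated so the expected fraction of
#' failures before the horizon equals `target_failure` for the realized
#' scores.
#'
#' @param spec A [cohort_spec()].
#' @param truth Optional `rad_cohort` (typically the training draw): its
#'   planted loading matrix `true_W` is reused so the new cohort shares the
#'   training cohort's component structure, as a validation cohort from the
#'   same population would; sample scores, noise and outcomes are drawn
#'   fresh from `spec`.
#' @return A list of class `rad_cohort`: `features` (tibble, one row per
#'   sample: `sample_id` + feature columns), `clinical` (tibble:
#'   `sample_id`, `time_months`, `event`, `failure_12mo`), the planted
#'   `true_W`/`true_H`, the calibrated `baseline_hazard`, and a `degenerate`
#'   flag set when the draw has zero events or zero censored subjects.
#' @examples
#' ch <- make_cohort(cohort_spec(n_samples = 40, seed = 7))
#' mean(ch$clinical$failure_12mo)
#' @export
make_cohort <- function(spec, truth = NULL) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec.")
  M <- spec$n_features; N <- spec$n_samples; k <- spec$k_true
  if (!is.null(truth)) {
    W <- if (inherits(truth, "rad_cohort")) truth$true_W else truth
    if (!is.matrix(W) || nrow(W) != M || ncol(W) != k) {
      abort("`truth` must carry an M x k_true loading matrix matching the spec.")
    }
  } else {
    # supports are consecutive blocks of a random feature permutation, so
    # components are near-disjoint and carry comparable energy
    W <- with_seed(derive_seed(spec$seed, 11L), {
      w <- matrix(0, nrow = M, ncol = k)
      supp_size <- max(2L, as.integer(round((1 - spec$component_sparsity) * M)))
      perm <- sample.int(M)
      for (j in seq_len(k)) {
        pos <- ((seq_len(supp_size) + (j - 1L) * supp_size - 1L) %% M) + 1L
        w[perm[pos], j] <- rexp(supp_size)
      }
      w
    })
    W <- sweep(W, 2, sqrt(colSums(W^2)), `/`)
  }

  H <- with_seed(derive_seed(spec$seed, 12L),
                 matrix(stats::rgamma(k * N, shape = 2, scale = 0.5), nrow = k))
  V <- W %*% H
  if (spec$noise_sd > 0) {
    V <- V + with_seed(derive_seed(spec$seed, 13L),
                       matrix(rnorm(M * N, sd = spec$noise_sd), nrow = M))
    V[V < 0] <- 0
  }

  z <- as.numeric(scale(H[spec$hazard_component, ]))
  beta <- spec$log_hazard_ratio
  lam0 <- spec$baseline_hazard
  if (is.null(lam0)) {
    # calibrate the baseline rate so the mean failure probability at the
    # horizon matches the configured target for the realized scores
    horizon <- spec$failure_horizon
    f <- function(l) mean(1 - exp(-horizon * l * exp(beta * z))) - spec$target_failure
    lam0 <- uniroot(f, c(1e-10, 10), tol = 1e-12)$root
  }
  rate <- lam0 * exp(beta * z)
  t_event <- with_seed(derive_seed(spec$seed, 14L), rexp(N, rate = rate))
  event <- as.integer(t_event <= spec$censoring_time)
  time_months <- pmin(t_event, spec$censoring_time)
  failure <- as.integer(t_event <= spec$failure_horizon)

  degenerate <- sum(event) == 0L || sum(event) == N
  if (degenerate) {
    warn("Cohort draw is degenerate: zero events or zero censored subjects.")
  }

  sample_id <- sprintf("S%03d", seq_len(N))
  feature_names <- sprintf("feat_%03d", seq_len(M))
  rownames(W) <- feature_names
  colnames(H) <- sample_id
  feats <- as_tibble(t(V), .name_repair = "minimal")
  names(feats) <- feature_names
  features <- dplyr::bind_cols(tibble(sample_id = sample_id), feats)
  clinical <- tibble(
    sample_id = sample_id,
    time_months = time_months,
    event = event,
    failure_12mo = failure
  )
  structure(
    list(features = features, clinical = clinical,
         true_W = W, true_H = H, baseline_hazard = lam0,
         degenerate = degenerate, spec = spec),
    class = "rad_cohort"
  )
}

#' @export
print.rad_cohort <- function(x, ...) {
  cat(sprintf(
    "<rad_cohort> %d samples x %d features, planted rank %d; %d events (%d before %g mo)\n",
    nrow(x$features), ncol(x$features) - 1L, x$spec$k_true,
    sum(x$clinical$event), sum(x$clinical$failure_12mo),
    x$spec$failure_horizon
  ))
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Writes `features.csv` (one row per feature, one column per sample, first
#' column `feature`) and `clinical.csv` (`sample_id`, `time_months`,
#' `event`, `failure_12mo`).
#'
#' @param cohort A `rad_cohort` or a list with `features`/`clinical` tibbles.
#' @param dir Output directory (created if missing).
#' @return The two file paths, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fm <- features_to_matrix(cohort$features)
  fpath <- file.path(dir, "features.csv")
  cpath <- file.path(dir, "clinical.csv")
  df <- data.frame(feature = rownames(fm), fm, check.names = FALSE)
  utils::write.csv(df, fpath, row.names = FALSE)
  utils::write.csv(as.data.frame(cohort$clinical), cpath, row.names = FALSE)
  invisible(c(features = fpath, clinical = cpath))
}

#' Read a feature table written by [write_cohort_csv()]
#'
#' @param path CSV with one row per feature and one column per sample.
#' @return A tibble with `sample_id` and one column per feature.
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df[[1]]
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(sample_id = rownames(m)), out)
}

#' Read a clinical table
#'
#' @param path CSV with columns `sample_id`, `time_months`, `event`,
#'   `failure_12mo`.
#' @return A tibble.
#' @export
read_clinical_csv <- function(path) {
  df <- as_tibble(utils::read.csv(path))
  need <- c("sample_id", "time_months", "event", "failure_12mo")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0("Clinical table is missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  df$sample_id <- as.character(df$sample_id)
  df
}

# features tibble (rows = samples) -> M x N numeric matrix
features_to_matrix <- function(features) {
  if (!"sample_id" %in% names(features)) {
    abort("Feature table must have a `sample_id` column.")
  }
  ids <- as.character(features$sample_id)
  if (anyDuplicated(ids)) abort("Duplicate sample ids in feature table.")
  m <- as.matrix(features[setdiff(names(features), "sample_id")])
  if (!is.numeric(m)) abort("Feature columns must be numeric.")
  rownames(m) <- ids
  t(m)
}

# M x N matrix -> features tibble (rows = samples)
matrix_to_features <- function(V) {
  out <- as_tibble(t(V), .name_repair = "minimal")
  dplyr::bind_cols(tibble(sample_id = colnames(V)), out)
}
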