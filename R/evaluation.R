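#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive
#' outscores a random negative, with score ties counting one half.
#'
#' @param scores Numeric predictor (higher = more likely positive).
#' @param labels 0/1 outcome labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present.")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Sensitivity/specificity at every observed threshold (positive call when
#' `score >= cutoff`), plus the degenerate endpoints.
#'
#' @inheritParams roc_auc
#' @return A tibble: `cutoff`, `sensitivity`, `specificity`, `youden_j`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  cuts <- sort(unique(scores))
  rows <- purrr::map(cuts, function(ct) {
    cf <- confusion_at(scores, labels, ct)
    tibble(cutoff = ct, sensitivity = cf$sensitivity,
           specificity = cf$specificity)
  })
  out <- purrr::list_rbind(rows)
  out$youden_j <- out$sensitivity + out$specificity - 1
  out
}

#' Youden-optimal classification cutoff
#'
#' Scans every observed score as a candidate cutoff (positive when
#' `score >= cutoff`) and returns the one maximizing Youden's
#' J = sensitivity + specificity - 1; ties go to the smallest cutoff.
#'
#' @inheritParams roc_auc
#' @return A list: `cutoff`, `j`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) abort("Both classes must be present.")
  pts <- roc_points(scores, labels)
  best <- which.max(pts$youden_j) # first maximum = smallest cutoff
  list(cutoff = pts$cutoff[best], j = pts$youden_j[best])
}

#' Confusion matrix and derived rates at a cutoff
#'
#' Positive call when `score >= cutoff` (the boundary is inclusive).
#'
#' @inheritParams roc_auc
#' @param cutoff Decision threshold on the score scale.
#' @return A list of class `rad_confusion`: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `accuracy`, `cutoff`.
#' @export
confusion_at <- function(scores, labels, cutoff) {
  if (!is_scalar_number(cutoff)) abort("`cutoff` must be a finite number.")
  labels <- as.integer(labels)
  call_pos <- scores >= cutoff
  tp <- sum(call_pos & labels == 1); fn <- sum(!call_pos & labels == 1)
  tn <- sum(!call_pos & labels == 0); fp <- sum(call_pos & labels == 0)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         accuracy = (tp + tn) / length(labels), cutoff = cutoff),
    class = "rad_confusion"
  )
}

#' @export
print.rad_confusion <- function(x, ...) {
  cat(sprintf(
    "<confusion @ %.3g> TP %d FP %d TN %d FN %d | sens %.3f spec %.3f\n",
    x$cutoff, x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity))
  invisible(x)
}

#' Kaplan-Meier product-limit estimate per group
#'
#' @param cohort Data frame with `time_months` and `event`.
#' @param groups Group label per row (single group if omitted).
#' @return A tibble of class `rad_km`: per group and distinct time,
#'   `n_risk`, `n_event`, `n_censor`, `surv`; attribute `median` holds the
#'   per-group median survival (earliest time with estimate <= 0.5, `NA`
#'   when never reached).
#' @export
km_estimate <- function(cohort, groups = NULL) {
  time <- cohort$time_months; event <- cohort$event
  if (is.null(groups)) groups <- rep("all", length(time))
  groups <- as.character(groups)
  if (any(!nzchar(groups)) || length(groups) != length(time)) {
    abort("`groups` must label every row.")
  }
  out <- purrr::map(sort(unique(groups)), function(g) {
    sel <- groups == g
    if (!any(sel)) abort("Empty group.")
    tt <- time[sel]; ee <- event[sel]
    ut <- sort(unique(tt))
    n_risk <- vapply(ut, function(u) sum(tt >= u), numeric(1))
    n_event <- vapply(ut, function(u) sum(tt == u & ee == 1), numeric(1))
    n_censor <- vapply(ut, function(u) sum(tt == u & ee == 0), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    tibble(group = g, time = ut, n_risk = n_risk, n_event = n_event,
           n_censor = n_censor, surv = surv)
  })
  res <- purrr::list_rbind(out)
  med <- vapply(sort(unique(groups)), function(g) {
    sub <- res[res$group == g, ]
    hit <- which(sub$surv <= 0.5)
    if (length(hit)) sub$time[hit[1]] else NA_real_
  }, numeric(1))
  attr(res, "median") <- med
  class(res) <- c("rad_km", class(res))
  res
}

#' Two-group log-rank test
#'
#' Standard chi-square statistic with one degree of freedom from the
#' observed-minus-expected events in the first group, with the
#' hypergeometric variance at each distinct event time.
#'
#' @param cohort Data frame with `time_months` and `event`.
#' @param groups Two-level group label per row.
#' @return A list: `statistic`, `p_value`, `observed`, `expected` (per
#'   group).
#' @export
logrank_test <- function(cohort, groups) {
  time <- cohort$time_months; event <- cohort$event
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  if (length(lv) != 2L) abort("Log-rank test needs exactly 2 groups.")
  if (sum(event) < 1L) abort("Log-rank test needs at least one event.")
  g1 <- groups == lv[1]
  ut <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) abort("Degenerate grouping: no variance in the log-rank statistic.")
  stat <- (O1 - E1)^2 / V
  O <- c(O1, sum(event) - O1)
  E <- c(E1, sum(event) - E1)
  names(O) <- names(E) <- lv
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Predicted failure-by-horizon risk from a Cox fit
#'
#' Converts a fitted single-covariate Cox model into absolute risks at a
#' horizon via the Breslow estimate of the baseline cumulative hazard:
#' `risk = 1 - exp(-H0(h) exp(beta x))`.
#'
#' @param fit A [cox_fit()].
#' @param covariate The covariate values used in the fit (training), or
#'   new values on the same scale.
#' @param cohort The training cohort the baseline hazard is estimated from.
#' @param train_covariate Covariate values of `cohort` (defaults to
#'   `covariate`).
#' @param horizon_months Risk horizon.
#' @return Numeric vector of predicted risks in `[0, 1]`.
#' @export
cox_risk_at <- function(fit, covariate, cohort, train_covariate = covariate,
                        horizon_months = 12) {
  time <- cohort$time_months; event <- cohort$event
  w <- exp(fit$beta * as.numeric(train_covariate))
  ut <- sort(unique(time[event == 1]))
  H0 <- 0
  for (t in ut) {
    if (t > horizon_months) break
    d <- sum(time == t & event == 1)
    H0 <- H0 + d / sum(w[time >= t])
  }
  1 - exp(-H0 * exp(fit$beta * as.numeric(covariate)))
}

#' Calibration of predicted against observed failure risk
#'
#' Samples are cut into quantile bins of predicted risk; each bin
#' contributes its mean predicted risk and the Kaplan-Meier estimate of the
#' observed failure fraction at the horizon.
#'
#' @param predicted_risk Predicted failure-by-horizon probabilities in
#'   `[0, 1]`.
#' @param cohort Data frame with `time_months` and `event`.
#' @param horizon_months Horizon the risks refer to.
#' @param n_bins Number of quantile bins (default 3; small cohorts).
#' @return A tibble: `bin`, `n`, `mean_predicted`, `observed`.
#' @export
calibration_curve <- function(predicted_risk, cohort, horizon_months = 12,
                              n_bins = 3) {
  if (any(predicted_risk < 0 | predicted_risk > 1)) {
    abort("`predicted_risk` must be in [0, 1].")
  }
  if (horizon_months > max(cohort$time_months)) {
    warn("Horizon is beyond the last observed time; observed fractions are extrapolated KM plateaus.")
  }
  br <- unique(quantile(predicted_risk, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(br) > 2) {
    cut(predicted_risk, br, include.lowest = TRUE, labels = FALSE)
  } else {
    rep(1L, length(predicted_risk))
  }
  rows <- purrr::map(sort(unique(bin)), function(b) {
    sel <- bin == b
    km <- km_estimate(cohort[sel, , drop = FALSE])
    below <- km$surv[km$time <= horizon_months]
    s_h <- if (length(below)) below[length(below)] else 1
    tibble(bin = b, n = sum(sel),
           mean_predicted = mean(predicted_risk[sel]),
           observed = 1 - s_h)
  })
  purrr::list_rbind(rows)
}

#' Decision-curve net benefit
#'
#' At threshold probability `p_t`, calling positive when
#' `predicted_risk >= p_t`: net benefit `TP/n - FP/n * p_t / (1 - p_t)`,
#' with the treat-all and treat-none references.
#'
#' @param predicted_risk Predicted probabilities in `[0, 1]`.
#' @param labels 0/1 outcome labels.
#' @param thresholds Threshold probabilities in `(0, 1)` (values of 1 are
#'   excluded).
#' @return A tibble: `threshold`, `net_benefit`, `treat_all`, `treat_none`.
#' @export
decision_curve <- function(predicted_risk, labels,
                           thresholds = seq(0.05, 0.95, by = 0.05)) {
  labels <- as.integer(labels)
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  n <- length(labels)
  prev <- mean(labels)
  rows <- purrr::map(thresholds, function(pt) {
    pos <- predicted_risk >= pt
    tp <- sum(pos & labels == 1); fp <- sum(pos & labels == 0)
    odds <- pt / (1 - pt)
    tibble(threshold = pt,
           net_benefit = tp / n - fp / n * odds,
           treat_all = prev - (1 - prev) * odds,
           treat_none = 0)
  })
  purrr::list_rbind(rows)
}

#' Intraclass correlation for repeated measurements
#'
#' Two-way mixed-effects, absolute-agreement, single-measurement ICC from
#' the standard ANOVA decomposition, the form used to assess
#' intra-observer reproducibility of repeated lesion segmentations.
#'
#' @param ratings Numeric matrix, subjects x repeated measurements.
#' @return ICC value (0, with a warning, when there is no between-subject
#'   variance).
#' @export
icc <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) abort("ICC needs >= 2 subjects and >= 2 measurements.")
  mu <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  SSR <- k * sum((row_m - mu)^2)
  SSC <- n * sum((col_m - mu)^2)
  SST <- sum((ratings - mu)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR <= MSE) {
    warn("No between-subject variance beyond error; ICC reported as 0.")
    return(0)
  }
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

#' Evaluate selected-component scores against cohort outcomes
#'
#' Bundles the whole performance assessment of a risk score: ROC/AUC,
#' confusion metrics at a cutoff, Harrell's C-index, Kaplan-Meier risk
#' groups split at the cutoff with the log-rank test, a calibration curve
#' of Cox-predicted against observed failure risk, and the decision curve.
#'
#' @param scores z-scores of the selected component, one per sample.
#' @param cohort Data frame with `time_months`, `event`, `failure_12mo`.
#' @param cutoff Decision cutoff on the z-score scale.
#' @param cox Optional [cox_fit()] used for absolute risk predictions; when
#'   omitted the predicted risks (and calibration/decision curves) are
#'   computed from a fit on this cohort.
#' @param train_scores,train_cohort Score vector and cohort the Cox
#'   baseline is anchored to (default: this cohort — pass the training pair
#'   when evaluating a validation cohort with frozen parameters).
#' @param horizon_months Horizon of the binary failure label.
#' @param n_bins Calibration bins.
#' @return An object of class `rad_eval`; see [tidy.rad_eval()].
#' @export
evaluate_scores <- function(scores, cohort, cutoff, cox = NULL,
                            train_scores = scores, train_cohort = cohort,
                            horizon_months = 12, n_bins = 3) {
  labels <- cohort$failure_12mo
  if (is.null(cox)) cox <- cox_fit(cohort, scores)
  auc <- roc_auc(scores, labels)
  conf <- confusion_at(scores, labels, cutoff)
  ci <- c_index(scores, cohort)
  groups <- ifelse(scores >= cutoff, "high", "low")
  km <- km_estimate(cohort, groups)
  lr <- if (length(unique(groups)) == 2L) {
    logrank_test(cohort, groups)
  } else {
    NULL
  }
  risk <- cox_risk_at(cox, scores, train_cohort,
                      train_covariate = train_scores,
                      horizon_months = horizon_months)
  cal <- calibration_curve(risk, cohort, horizon_months, n_bins)
  dc <- decision_curve(risk, labels)
  structure(
    list(scores = scores, labels = labels,
         auc = auc, cutoff = cutoff, confusion = conf,
         sensitivity = conf$sensitivity, specificity = conf$specificity,
         c_index = ci, km = km, km_groups = groups, logrank = lr,
         calibration = cal, decision = dc, predicted_risk = risk,
         horizon_months = horizon_months),
    class = "rad_eval"
  )
}

#' @export
print.rad_eval <- function(x, ...) {
  cat(sprintf(
    paste0("<rad_eval> AUC %.3f | cutoff %.3g: sens %.3f spec %.3f | ",
           "C-index %.3f | log-rank p %s\n"),
    x$auc, x$cutoff, x$sensitivity, x$specificity, x$c_index,
    if (is.null(x$logrank)) "NA (one group)" else
      format.pval(x$logrank$p_value, digits = 3)))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x A `rad_eval`.
#' @param ... Unused.
#' @return A tibble of metric/value pairs.
#' @method tidy rad_eval
#' @export
tidy.rad_eval <- function(x, ...) {
  tibble(
    metric = c("auc", "cutoff", "tp", "fp", "tn", "fn", "sensitivity",
               "specificity", "accuracy", "c_index", "logrank_statistic",
               "logrank_p"),
    value = c(x$auc, x$cutoff, x$confusion$tp, x$confusion$fp,
              x$confusion$tn, x$confusion$fn, x$sensitivity, x$specificity,
              x$confusion$accuracy, x$c_index,
              if (is.null(x$logrank)) NA_real_ else x$logrank$statistic,
              if (is.null(x$logrank)) NA_real_ else x$logrank$p_value)
  )
}

#' @rdname tidy.rad_eval
#' @method glance rad_eval
#' @export
glance.rad_eval <- function(x, ...) {
  tibble(auc = x$auc, sensitivity = x$sensitivity,
         specificity = x$specificity, c_index = x$c_index,
         logrank_p = if (is.null(x$logrank)) NA_real_ else x$logrank$p_value,
         cutoff = x$cutoff)
}

#' @method autoplot rad_km
#' @export
autoplot.rad_km <- function(object, ...) {
  start <- dplyr::distinct(object, .data$group) |>
    dplyr::mutate(time = 0, surv = 1)
  df <- dplyr::bind_rows(start,
                         object[, c("group", "time", "surv")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "recurrence-free survival",
                  colour = "risk group") +
    ggplot2::theme_minimal()
}

#' @method autoplot rad_eval
#' @export
autoplot.rad_eval <- function(object, which = c("roc", "km", "calibration",
                                                "decision"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    pts <- roc_points(object$scores, object$labels)
    df <- rbind(
      data.frame(fpr = 1, tpr = 1),
      data.frame(fpr = 1 - pts$specificity, tpr = pts$sensitivity),
      data.frame(fpr = 0, tpr = 0)
    )
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
        ggplot2::geom_abline(linetype = 2, colour = "grey") +
        ggplot2::geom_step() +
        ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                      title = sprintf("ROC (AUC = %.3f)", object$auc)) +
        ggplot2::theme_minimal()
    )
  }
  if (which == "km") return(autoplot(object$km))
  if (which == "calibration") {
    return(
      ggplot2::ggplot(object$calibration,
                      ggplot2::aes(x = .data$mean_predicted,
                                   y = .data$observed)) +
        ggplot2::geom_abline(linetype = 2, colour = "grey") +
        ggplot2::geom_point() + ggplot2::geom_line() +
        ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
        ggplot2::labs(x = "mean predicted risk", y = "observed failure fraction") +
        ggplot2::theme_minimal()
    )
  }
  if (which == "decision") {
    df <- tidyr::pivot_longer(object$decision, -"threshold",
                              names_to = "strategy", values_to = "net_benefit")
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold,
                                       y = .data$net_benefit,
                                       colour = .data$strategy)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "threshold probability", y = "net benefit") +
        ggplot2::theme_minimal()
    )
  }
  NULL
}
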