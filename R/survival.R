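#' Fit a single-covariate Cox proportional-hazards model
#'
#' Newton-Raphson maximization of the Cox partial likelihood with Efron
#' correction for tied event times (Breslow available by flag). Convergence
#' when the step size drops below 1e-8, capped at 50 iterations. A monotone
#' partial likelihood (perfect separation) caps the coefficient at |beta|
#' = 20 and flags the fit.
#'
#' @param cohort Data frame with `time_months` and `event` columns (plus
#'   anything else; rows aligned with `covariate`).
#' @param covariate Numeric covariate vector, one value per row of
#'   `cohort`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return An object of class `cox_fit`: `beta`, `se`, `loglik` (at the
#'   estimate), `loglik_null`, `c_index`, `n`, `n_events`, `converged`,
#'   `separation`.
#' @export
cox_fit <- function(cohort, covariate, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  time <- cohort$time_months
  event <- cohort$event
  x <- as.numeric(covariate)
  if (length(x) != length(time)) {
    abort("`covariate` must have one value per cohort row.")
  }
  if (any(time <= 0)) abort("Event/censoring times must be positive.")
  if (sum(event) < 2L) abort("Need at least 2 events to fit a Cox model.")
  if (sd(x) == 0) abort("`covariate` is constant; no information.")

  beta <- 0
  separation <- FALSE
  converged <- FALSE
  for (iter in seq_len(50L)) {
    gr <- cox_partial_derivs(beta, time, event, x, ties)
    if (gr$info <= 0) { separation <- TRUE; break }
    step <- gr$score / gr$info
    beta_new <- beta + step
    if (abs(beta_new) > 20) {
      beta <- sign(beta_new) * 20
      separation <- TRUE
      break
    }
    beta <- beta_new
    if (abs(step) < 1e-8) { converged <- TRUE; break }
  }
  if (separation) {
    warn("Monotone partial likelihood (perfect separation); beta capped.")
  }
  gr <- cox_partial_derivs(beta, time, event, x, ties)
  gr0 <- cox_partial_derivs(0, time, event, x, ties)
  structure(
    list(beta = beta, se = if (gr$info > 0) 1 / sqrt(gr$info) else NA_real_,
         loglik = gr$loglik, loglik_null = gr0$loglik,
         c_index = c_index(x, cohort),
         n = length(x), n_events = sum(event),
         converged = converged, separation = separation, ties = ties),
    class = "cox_fit"
  )
}

# log partial likelihood, score and information for a single covariate
cox_partial_derivs <- function(beta, time, event, x, ties) {
  o <- order(time)
  time <- time[o]; event <- event[o]; x <- x[o]
  eta <- beta * x
  w <- exp(eta)
  n <- length(x)
  # risk-set cumulatives from the end (time ascending)
  S0 <- rev(cumsum(rev(w)))
  S1 <- rev(cumsum(rev(w * x)))
  S2 <- rev(cumsum(rev(w * x^2)))
  ll <- 0; score <- 0; info <- 0
  ut <- unique(time[event == 1])
  for (t in ut) {
    at <- which(time == t)
    first <- at[1]
    dset <- at[event[at] == 1]
    d <- length(dset)
    sw <- w[dset]; sx <- x[dset]
    ll <- ll + sum(eta[dset])
    if (ties == "breslow" || d == 1L) {
      ll <- ll - d * log(S0[first])
      score <- score + sum(sx) - d * S1[first] / S0[first]
      info <- info + d * (S2[first] / S0[first] - (S1[first] / S0[first])^2)
    } else {
      # Efron: the tied events each see the risk set minus an average
      # share of the tied group
      dS0 <- sum(sw); dS1 <- sum(sw * sx); dS2 <- sum(sw * sx^2)
      for (l in seq_len(d) - 1L) {
        f <- l / d
        a0 <- S0[first] - f * dS0
        a1 <- S1[first] - f * dS1
        a2 <- S2[first] - f * dS2
        ll <- ll - log(a0)
        score <- score - a1 / a0
        info <- info + a2 / a0 - (a1 / a0)^2
      }
      score <- score + sum(sx)
    }
  }
  list(loglik = ll, score = score, info = info)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "<cox_fit> beta = %.4f (se %.4f), C-index = %.3f, %d events / %d subjects\n",
    x$beta, x$se, x$c_index, x$n_events, x$n))
  invisible(x)
}

#' @rdname cox_fit
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, ...) {
  tibble(term = "covariate", estimate = x$beta, std.error = x$se,
         statistic = x$beta / x$se,
         p.value = 2 * stats::pnorm(-abs(x$beta / x$se)))
}

#' @rdname cox_fit
#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, beta = x$beta, se = x$se,
         loglik = x$loglik, loglik_null = x$loglik_null,
         c_index = x$c_index, converged = x$converged,
         separation = x$separation)
}

#' Harrell's concordance index
#'
#' Over all comparable pairs (the pair member with the shorter time had an
#' observed event), the fraction in which the higher risk score belongs to
#' the subject failing earlier; score ties count one half.
#'
#' @param scores Numeric risk scores (higher = higher risk).
#' @param cohort Data frame with `time_months` and `event`.
#' @return Concordance in `[0, 1]`.
#' @export
c_index <- function(scores, cohort) {
  time <- cohort$time_months; event <- cohort$event
  s <- as.numeric(scores)
  n <- length(s)
  conc <- 0; comp <- 0
  # vectorized over the earlier member of each pair
  for (i in which(event == 1)) {
    later <- time > time[i]
    m <- sum(later)
    if (!m) next
    comp <- comp + m
    conc <- conc + sum(s[later] < s[i]) + 0.5 * sum(s[later] == s[i])
  }
  if (comp == 0) abort("No comparable pairs for the concordance index.")
  conc / comp
}

#' Select the metafeature most predictive of recurrence
#'
#' Fits a single-covariate Cox model to each z-scored component row and
#' returns the component with the highest Harrell C-index (ties toward the
#' smaller index). If the winner's C-index is below 0.5 its sign is flipped
#' so that a higher score means higher risk, and the flip is recorded; a
#' maximum C-index below 0.6 is flagged as weak signal.
#'
#' @param scores A `component_scores` object (or a k x N z-score matrix).
#' @param cohort Data frame with `time_months` and `event`, columns aligned
#'   with the score matrix.
#' @return A list of class `component_selection`: `index`, `table` (tibble
#'   with per-component beta, se, C-index), `flipped`, `weak_signal`.
#' @export
select_component <- function(scores, cohort) {
  z <- if (inherits(scores, "component_scores")) scores$z else scores
  if (nrow(z) < 2L) abort("Component selection needs k >= 2 components.")
  fits <- lapply(seq_len(nrow(z)), function(i) cox_fit(cohort, z[i, ]))
  tbl <- purrr::list_rbind(lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    tibble(component = i, beta = f$beta, se = f$se, c_index = f$c_index,
           n_events = f$n_events, separation = f$separation)
  }))
  idx <- which.max(tbl$c_index) # which.max takes the first maximum
  flipped <- FALSE
  if (tbl$c_index[idx] < 0.5) {
    flipped <- TRUE
    warn("Selected component had C-index < 0.5; sign flipped so higher score = higher risk.")
  }
  weak <- max(tbl$c_index) < 0.6
  if (weak) {
    inform("Maximum component C-index < 0.6: weak prognostic signal.")
  }
  structure(
    list(index = idx, table = tbl, flipped = flipped, weak_signal = weak),
    class = "component_selection"
  )
}

#' @export
print.component_selection <- function(x, ...) {
  cat(sprintf("<component_selection> component %d (C-index %.3f)%s\n",
              x$index, x$table$c_index[x$index],
              if (x$flipped) ", sign flipped" else ""))
  print(x$table)
  invisible(x)
}
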