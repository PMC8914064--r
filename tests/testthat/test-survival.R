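test_that("degenerate covariates and cohorts are rejected", {
  ch <- toy_cohort()
  expect_error(cox_fit(ch, rep(1, 6)), "constant")
  ch0 <- ch; ch0$event <- c(1, 0, 0, 0, 0, 0)
  expect_error(cox_fit(ch0, toy_covariate), "2 events")
})

test_that("negating the covariate negates beta and mirrors the C-index", {
  ch <- toy_cohort()
  x <- c(2.0, 0.5, 1.0, 1.2, 0.3, 1.5)
  f1 <- cox_fit(ch, x)
  f2 <- cox_fit(ch, -x)
  expect_equal(f2$beta, -f1$beta, tolerance = 1e-8)
  expect_equal(f2$c_index, 1 - f1$c_index, tolerance = 1e-12)
})

test_that("the 6-subject toy fit matches the survival package to 1e-6", {
  skip_if_not_installed("survival")
  ch <- toy_cohort()
  # well-posed covariate: the second event does not dominate its risk set
  x <- c(2.0, 0.5, 1.0, 1.2, 0.3, 1.5)
  ref_efron <- survival::coxph(
    survival::Surv(time_months, event) ~ x,
    data = cbind(ch, x = x), ties = "efron")
  f <- cox_fit(ch, x)
  expect_equal(f$beta, unname(stats::coef(ref_efron)), tolerance = 1e-6)
  expect_equal(f$se, unname(sqrt(stats::vcov(ref_efron)[1, 1])),
               tolerance = 1e-6)
  expect_equal(f$loglik, ref_efron$loglik[2], tolerance = 1e-6)
  ref_bres <- survival::coxph(
    survival::Surv(time_months, event) ~ x,
    data = cbind(ch, x = x), ties = "breslow")
  fb <- cox_fit(ch, x, ties = "breslow")
  expect_equal(fb$beta, unname(stats::coef(ref_bres)), tolerance = 1e-6)
})

test_that("a covariate that perfectly ranks the events is flagged by both fitters", {
  skip_if_not_installed("survival")
  # every event carries the largest covariate in its risk set: the partial
  # likelihood is monotone and the true estimate is unbounded
  ch <- toy_cohort()
  expect_warning(f <- cox_fit(ch, toy_covariate), "separation")
  expect_true(f$separation)
  ref <- suppressWarnings(survival::coxph(
    survival::Surv(time_months, event) ~ x,
    data = cbind(ch, x = toy_covariate)))
  expect_gt(unname(stats::coef(ref)), 10) # reference also runs away
})

test_that("tied event times are handled like the survival package (Efron)", {
  skip_if_not_installed("survival")
  set.seed(11)
  n <- 60
  x <- rnorm(n)
  ch <- tibble::tibble(
    time_months = sample(1:8, n, replace = TRUE), # heavy month-level ties
    event = rbinom(n, 1, 0.6)
  )
  ref <- survival::coxph(survival::Surv(ch$time_months, ch$event) ~ x,
                         ties = "efron")
  f <- cox_fit(ch, x)
  expect_equal(f$beta, unname(stats::coef(ref)), tolerance = 1e-6)
  expect_equal(f$se, unname(sqrt(stats::vcov(ref)[1, 1])), tolerance = 1e-6)
})

test_that("perfect separation is capped and flagged instead of diverging", {
  ch <- tibble::tibble(
    time_months = c(1, 2, 3, 10, 11, 12),
    event = c(1, 1, 1, 0, 0, 0)
  )
  expect_warning(f <- cox_fit(ch, c(5, 4, 3, 0.2, 0.1, 0)), "separation")
  expect_true(f$separation)
  expect_lte(abs(f$beta), 20)
})

test_that("the concordance index agrees with the all-pairs double loop", {
  set.seed(21)
  for (rep in 1:3) {
    n <- 30
    s <- round(rnorm(n), 1) # induce some score ties
    time <- sample(1:20, n, replace = TRUE)
    event <- rbinom(n, 1, 0.7)
    ch <- tibble::tibble(time_months = time, event = event)
    expect_equal(c_index(s, ch), oracle_c_index(s, time, event))
  }
})

test_that("the concordance index hits its boundary values", {
  ch <- tibble::tibble(time_months = c(4, 3, 2, 1), event = rep(1, 4))
  expect_equal(c_index(1:4, ch), 1)        # higher score, shorter time
  expect_equal(c_index(rep(2, 4), ch), 0.5) # all tied scores
  expect_equal(c_index(1:4, ch) + c_index(-(1:4), ch), 1)
  expect_error(c_index(1:2, tibble::tibble(time_months = c(1, 1),
                                           event = c(1, 1))),
               "comparable")
})

test_that("component selection finds the planted hazard-driving component", {
  hits <- vapply(1:20, function(s) {
    ch <- make_cohort(cohort_spec(target_failure = 0.2, seed = s))
    V <- radnmf:::features_to_matrix(ch$features)
    fit <- nmf_fit(V, 5, seed = 3000 + s)
    sel <- suppressMessages(
      select_component(standardize_scores(fit$H), ch$clinical))
    # map the selected recovered component back to the planted one
    cs <- crossprod(ch$true_W, fit$W)
    unname(which.max(cs[, sel$index]) == ch$spec$hazard_component)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("an informative component beats pure noise at k = 2", {
  hits <- vapply(1:10, function(s) {
    ch <- make_cohort(cohort_spec(n_features = 30, k_true = 2,
                                  hazard_component = 2L,
                                  target_failure = 0.25,
                                  log_hazard_ratio = 1.2, seed = s))
    z <- standardize_scores(ch$true_H)
    sel <- suppressMessages(select_component(z, ch$clinical))
    sel$index == 2L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("all-noise components still yield one index, flagged as weak", {
  set.seed(50)
  ch <- tibble::tibble(time_months = rexp(80, 0.05) + 0.5,
                       event = rbinom(80, 1, 0.5))
  z <- matrix(rnorm(3 * 80), nrow = 3)
  sel <- suppressMessages(suppressWarnings(select_component(z, ch)))
  expect_true(sel$index %in% 1:3)
  # by construction the winner's C-index bounds the others
  expect_true(all(sel$table$c_index <= sel$table$c_index[sel$index]))
})

test_that("Cox beta is recovered without material bias at N = 200", {
  beta_true <- 0.7
  est <- vapply(1:50, function(s) {
    set.seed(7000 + s)
    n <- 200
    x <- rnorm(n)
    t_ev <- rexp(n, rate = 0.04 * exp(beta_true * x))
    cens <- 13 # administrative censoring tuned to ~40% events
    ch <- tibble::tibble(time_months = pmin(t_ev, cens),
                         event = as.integer(t_ev <= cens))
    cox_fit(ch, x)$beta
  }, numeric(1))
  expect_lt(abs(mean(est) - beta_true), 0.1)
})
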