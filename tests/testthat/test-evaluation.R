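test_that("AUC hits its boundary values and rejects one-class input", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "Both classes")
})

test_that("AUC equals trapezoidal integration of the empirical ROC", {
  set.seed(4)
  for (rep in 1:3) {
    s <- round(rnorm(20), 1)
    l <- rbinom(20, 1, 0.4)
    if (length(unique(l)) < 2) l[1:2] <- c(0, 1)
    expect_equal(roc_auc(s, l), oracle_auc(s, l), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(9)
  s <- rnorm(30); l <- rbinom(30, 1, 0.5)
  if (length(unique(l)) < 2) l[1:2] <- c(0, 1)
  a <- roc_auc(s, l)
  expect_equal(roc_auc(exp(s), l), a)
  expect_equal(roc_auc(5 * s - 3, l), a)
  expect_equal(roc_auc(rank(s), l), a)
})

test_that("the Youden cutoff equals the exhaustive threshold scan", {
  expect_equal(youden_cutoff(c(0.1, 0.9), c(0, 1)),
               list(cutoff = 0.9, j = 1))
  set.seed(13)
  for (rep in 1:3) {
    s <- round(rnorm(30), 1)
    l <- rbinom(30, 1, 0.5)
    if (length(unique(l)) < 2) l[1:2] <- c(0, 1)
    expect_equal(youden_cutoff(s, l), oracle_youden(s, l))
  }
  # labels independent of balanced scores: J stays near zero
  set.seed(14)
  js <- vapply(1:20, function(i) {
    s <- rnorm(200)
    l <- rep(0:1, each = 100)
    youden_cutoff(s, l)$j
  }, numeric(1))
  expect_lt(mean(js), 0.2)
})

test_that("confusion identities hold across a cutoff sweep", {
  set.seed(15)
  s <- rnorm(40); l <- rbinom(40, 1, 0.3)
  if (length(unique(l)) < 2) l[1:2] <- c(0, 1)
  for (ct in c(min(s) - 1, quantile(s, c(0.1, 0.5, 0.9)), max(s) + 1)) {
    cf <- confusion_at(s, l, ct)
    expect_equal(cf$tp + cf$fn, sum(l == 1))
    expect_equal(cf$tn + cf$fp, sum(l == 0))
    expect_equal(cf$sensitivity, cf$tp / (cf$tp + cf$fn))
    expect_equal(cf$specificity, cf$tn / (cf$tn + cf$fp))
  }
  low <- confusion_at(s, l, min(s) - 1)
  expect_equal(low$sensitivity, 1)
  expect_equal(low$specificity, 0)
})

test_that("the KM estimator matches the survival package on a textbook set", {
  skip_if_not_installed("survival")
  time <- c(6, 6, 6, 7, 10, 13, 16, 22, 23, 6)
  event <- c(1, 1, 1, 1, 0, 1, 1, 1, 1, 0)
  ch <- tibble::tibble(time_months = time, event = event)
  km <- km_estimate(ch)
  ref <- survival::survfit(survival::Surv(time, event) ~ 1)
  expect_equal(km$surv, ref$surv[match(km$time, ref$time)], tolerance = 1e-10)
  # no censoring: step function equals the empirical survival fraction
  ch2 <- tibble::tibble(time_months = c(1, 2, 2, 5), event = rep(1, 4))
  km2 <- km_estimate(ch2)
  expect_equal(km2$surv, c(3 / 4, 1 / 4, 0))
})

test_that("an all-censored group stays at 1 with undefined median", {
  ch <- tibble::tibble(time_months = c(3, 6, 9), event = c(0, 0, 0))
  km <- km_estimate(ch)
  expect_true(all(km$surv == 1))
  expect_true(is.na(attr(km, "median")[["all"]]))
})

test_that("the log-rank test matches survdiff and its closed forms", {
  skip_if_not_installed("survival")
  set.seed(31)
  time <- c(rexp(40, 0.05), rexp(40, 0.15)) + 0.1
  event <- rbinom(80, 1, 0.8)
  grp <- rep(c("a", "b"), each = 40)
  ch <- tibble::tibble(time_months = time, event = event)
  lr <- logrank_test(ch, grp)
  ref <- survival::survdiff(survival::Surv(time, event) ~ grp)
  expect_equal(lr$statistic, ref$chisq, tolerance = 1e-10)
  expect_equal(lr$p_value, stats::pchisq(ref$chisq, 1, lower.tail = FALSE))
  # identical groups: statistic 0, p 1
  t2 <- c(1, 3, 5, 1, 3, 5)
  e2 <- c(1, 0, 1, 1, 0, 1)
  lr0 <- logrank_test(tibble::tibble(time_months = t2, event = e2),
                      rep(c("a", "b"), each = 3))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)
})

test_that("a single death time reproduces the hypergeometric variance formula", {
  # groups a: times 2, 5 (event at 2); b: times 2+, 5+ all censored later
  ch <- tibble::tibble(time_months = c(2, 5, 4, 6), event = c(1, 0, 0, 0))
  grp <- c("a", "a", "b", "b")
  lr <- logrank_test(ch, grp)
  # at t = 2: n = 4, n1 = 2, d = 1 -> E1 = 0.5, V = 1 * .5 * .5 * 3/3 = 0.25
  expect_equal(lr$statistic, (1 - 0.5)^2 / 0.25)
})

test_that("strongly separated hazards are detected by the log-rank test", {
  hits <- vapply(1:20, function(s) {
    set.seed(800 + s)
    t1 <- rexp(50, 0.02); t2 <- rexp(50, 0.10) # hazard ratio 5
    cens <- 40
    ch <- tibble::tibble(time_months = pmin(c(t1, t2), cens) + 1e-9,
                         event = as.integer(c(t1, t2) <= cens))
    logrank_test(ch, rep(c("lo", "hi"), each = 50))$p_value < 0.005
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("well-specified predicted risks calibrate to the diagonal", {
  set.seed(61)
  n <- 400
  x <- rnorm(n)
  beta <- 0.8; lam <- 0.03
  t_ev <- rexp(n, rate = lam * exp(beta * x))
  ch <- tibble::tibble(time_months = pmin(t_ev, 36),
                       event = as.integer(t_ev <= 36))
  fit <- cox_fit(ch, x)
  risk <- cox_risk_at(fit, x, ch, horizon_months = 12)
  cal <- calibration_curve(risk, ch, horizon_months = 12, n_bins = 3)
  for (b in seq_len(nrow(cal))) {
    se <- sqrt(cal$mean_predicted[b] * (1 - cal$mean_predicted[b]) / cal$n[b])
    expect_lt(abs(cal$observed[b] - cal$mean_predicted[b]), 3.5 * se + 0.02)
  }
})

test_that("degenerate calibration inputs collapse to a single sensible point", {
  ch <- tibble::tibble(time_months = c(2, 5, 8, 14, 20, 30),
                       event = c(1, 1, 0, 1, 0, 0))
  cal <- calibration_curve(rep(0.3, 6), ch, horizon_months = 12, n_bins = 3)
  expect_equal(nrow(cal), 1L)
  km <- km_estimate(ch)
  s12 <- km$surv[max(which(km$time <= 12))]
  expect_equal(cal$observed, 1 - s12)
  one <- calibration_curve(seq(0.1, 0.6, 0.1), ch, horizon_months = 12,
                           n_bins = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$mean_predicted, mean(seq(0.1, 0.6, 0.1)))
})

test_that("net benefit matches hand arithmetic and its reference curves", {
  set.seed(71)
  risk <- runif(50)
  labels <- rbinom(50, 1, risk) # informative predictions
  dc <- decision_curve(risk, labels, thresholds = c(0.2, 0.5))
  pos <- risk >= 0.2
  tp <- sum(pos & labels == 1); fp <- sum(pos & labels == 0)
  expect_equal(dc$net_benefit[1], tp / 50 - fp / 50 * 0.25)
  expect_true(all(dc$treat_none == 0))
  # as the threshold approaches 0 the treat-all benefit approaches prevalence
  tiny <- decision_curve(risk, labels, thresholds = 0.001)
  expect_equal(tiny$treat_all, mean(labels), tolerance = 0.01)
  expect_equal(nrow(decision_curve(risk, labels, thresholds = c(0.5, 1))), 1L)
})

test_that("the ICC matches the frozen mixed-effects reference value", {
  m <- cbind(c(10.2, 11.5, 9.8, 14.1, 12.0, 8.7, 13.3, 10.9, 12.8, 9.4),
             c(10.6, 11.2, 10.1, 13.8, 12.5, 8.9, 13.0, 11.4, 12.3, 9.9))
  # two-way mixed, absolute agreement, single measurement; reference value
  # computed once with an established implementation
  expect_equal(icc(m), 0.97177662525630, tolerance = 1e-8)
  expect_equal(icc(cbind(m[, 1], m[, 1])), 1)
  set.seed(81)
  vals <- vapply(1:30, function(i) {
    suppressWarnings(icc(matrix(rnorm(40), 20)))
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.15)
})
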