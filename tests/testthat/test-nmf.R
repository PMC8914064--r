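test_that("an exact rank-1 matrix factorizes to machine residual at k = 1", {
  set.seed(2)
  V <- outer(runif(20, 0.5, 2), runif(12, 0.5, 2))
  fit <- nmf_fit(V, 1, seed = 4)
  expect_lt(fit$rss, 1e-8 * sum(V^2))
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
  expect_equal(colSums(fit$W^2), 1, ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("the multiplicative-update objective never increases", {
  set.seed(5)
  for (case in 1:4) {
    V <- matrix(runif(30 * 18), 30) * sample(c(0.1, 1, 10), 1)
    fit <- nmf_fit(V, sample(2:5, 1), seed = case, max_iter = 300)
    expect_true(all(diff(fit$rss_history) <= 1e-10 * fit$rss_history[1]))
  }
})

test_that("noiseless planted factors are reconstructed at the true rank", {
  ch <- make_cohort(cohort_spec(n_samples = 60, n_features = 40, k_true = 4,
                                noise_sd = 0, seed = 8))
  V <- radnmf:::features_to_matrix(ch$features)
  fit <- nmf_fit(V, 4, seed = 21, max_iter = 5000, tol = 1e-10)
  rel <- sqrt(fit$rss / sum(V^2))
  expect_lt(rel, 1e-3)
})

test_that("recovered components align with the planted ones by cosine matching", {
  ch <- make_cohort(cohort_spec(seed = 3))
  V <- radnmf:::features_to_matrix(ch$features)
  curve <- nmf_rss_curve(V, k_min = 5, k_max = 5, n_restarts = 5, seed = 6)
  fit <- nmf_best_fit(V, curve, 5)
  cs <- crossprod(ch$true_W, fit$W) # planted columns are unit norm
  best <- apply(cs, 1, max)
  expect_true(all(best > 0.95))
  # every planted component is matched by a distinct recovered one
  expect_equal(sort(apply(cs, 1, which.max)), 1:5)
})

test_that("more restarts can only improve the best RSS", {
  set.seed(9)
  V <- matrix(runif(25 * 15), 25)
  c1 <- nmf_rss_curve(V, k_min = 2, k_max = 4, n_restarts = 2, seed = 7)
  c2 <- nmf_rss_curve(V, k_min = 2, k_max = 4, n_restarts = 4, seed = 7)
  expect_true(all(c2$rss <= c1$rss + 1e-12))
})

test_that("the RSS curve is bit-reproducible under a fixed master seed", {
  ch <- make_cohort(cohort_spec(n_samples = 30, n_features = 20, k_true = 3,
                                seed = 12))
  V <- radnmf:::features_to_matrix(ch$features)
  a <- nmf_rss_curve(V, k_min = 2, k_max = 5, n_restarts = 3, seed = 19)
  b <- nmf_rss_curve(V, k_min = 2, k_max = 5, n_restarts = 3, seed = 19)
  expect_identical(a, b)
})

test_that("rank selection maximizes the discrete second difference", {
  curve <- tibble::tibble(k = 2:6, rss = c(50, 20, 18, 17, 16.5))
  expect_equal(select_rank(curve), 3)
  lin <- tibble::tibble(k = 2:6, rss = c(50, 40, 30, 20, 10))
  expect_equal(select_rank(lin), 3) # ties break toward the smallest interior k
  flat <- tibble::tibble(k = 2:6, rss = rep(5, 5))
  expect_warning(expect_equal(select_rank(flat), 2), "flat")
})

test_that("the planted rank is recovered from the RSS inflection", {
  hits <- vapply(1:20, function(s) {
    ch <- make_cohort(cohort_spec(seed = s)) # M = 54, N = 104, noise 0.05
    V <- radnmf:::features_to_matrix(ch$features)
    select_rank(nmf_rss_curve(V, n_restarts = 4, seed = 1000 + s))
  }, integer(1))
  expect_gte(mean(hits == 5L), 0.9)
})

test_that("score standardization matches the closed form and freezes cleanly", {
  H <- matrix(c(1, 2, 3), nrow = 1)
  sc <- standardize_scores(H)
  expect_equal(as.numeric(sc$z), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-4)
  expect_equal(sc$z[1, 2], 0)
  # re-applying the frozen parameters reproduces the training z
  expect_equal(apply_standardization(sc, H), sc$z)
  # a new value equal to the training mean scores 0
  expect_equal(as.numeric(apply_standardization(sc, matrix(2))), 0)
  expect_error(standardize_scores(matrix(c(1, 1, 1), nrow = 1)), "variance")
})

test_that("NNLS projection recovers scores for columns spanned by W", {
  set.seed(33)
  W <- matrix(runif(30 * 3), 30)
  W <- sweep(W, 2, sqrt(colSums(W^2)), `/`)
  # a sample equal to component 2 projects to the unit coefficient
  h <- project_cohort(W, W[, 2, drop = FALSE])
  expect_equal(as.numeric(h), c(0, 1, 0), tolerance = 1e-8)
  # an all-zero sample projects to zero scores
  h0 <- project_cohort(W, matrix(0, 30, 1))
  expect_equal(as.numeric(h0), c(0, 0, 0))
  # projecting noiseless planted data recovers the planted H
  ch <- make_cohort(cohort_spec(n_samples = 40, n_features = 36, k_true = 3,
                                noise_sd = 0, seed = 14))
  V <- radnmf:::features_to_matrix(ch$features)
  Hp <- project_cohort(ch$true_W, V)
  expect_lt(max(abs(Hp - ch$true_H)) / max(ch$true_H), 1e-2)
  expect_error(project_cohort(W, matrix(1, 29, 2)), "mismatch")
})

test_that("tidy and glance summarise a fit consistently", {
  V <- matrix(runif(20 * 10), 20,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:10)))
  fit <- nmf_fit(V, 2, seed = 3)
  tw <- tidy(fit, "W")
  expect_equal(nrow(tw), 40L)
  expect_setequal(unique(tw$component), c("component_1", "component_2"))
  g <- glance(fit)
  expect_equal(g$k, 2L)
  expect_equal(g$rss, fit$rss)
})
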