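# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use naive algorithms (double loops,
# exhaustive scans) and never call the code paths they check.

# AUC by trapezoidal integration of the empirical ROC over all thresholds
oracle_auc <- function(scores, labels) {
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- fpr <- numeric(length(cuts))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  for (i in seq_along(cuts)) {
    pos <- scores >= cuts[i]
    tpr[i] <- sum(pos & labels == 1) / n1
    fpr[i] <- sum(pos & labels == 0) / n0
  }
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Harrell's C by an explicit double loop over ordered pairs
oracle_c_index <- function(scores, time, event) {
  conc <- comp <- 0
  n <- length(scores)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (event[i] == 1 && time[i] < time[j]) {
        comp <- comp + 1
        if (scores[i] > scores[j]) conc <- conc + 1
        if (scores[i] == scores[j]) conc <- conc + 0.5
      }
    }
  }
  conc / comp
}

# Youden cutoff by exhaustive scan over observed scores
oracle_youden <- function(scores, labels) {
  best_j <- -Inf; best_c <- NA
  for (ct in sort(unique(scores))) {
    pos <- scores >= ct
    sens <- sum(pos & labels == 1) / sum(labels == 1)
    spec <- sum(!pos & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (j > best_j) { best_j <- j; best_c <- ct }
  }
  list(cutoff = best_c, j = best_j)
}

# greedy collinearity elimination, re-implemented literally from the rule
oracle_collinear <- function(X, names, threshold) {
  keep <- names
  dropped <- character(0)
  repeat {
    cm <- abs(stats::cor(X[, keep, drop = FALSE]))
    diag(cm) <- 0
    if (length(keep) < 2 || max(cm) <= threshold) break
    hit <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    a <- keep[hit[1]]; b <- keep[hit[2]]
    ma <- mean(cm[hit[1], ]); mb <- mean(cm[hit[2], ])
    drop <- if (ma > mb) a else if (mb > ma) b else {
      c(a, b)[which.max(match(c(a, b), names))]
    }
    dropped <- c(dropped, drop)
    keep <- setdiff(keep, drop)
  }
  list(keep = keep, dropped = dropped)
}

# naive GLCM counts for one offset by looping over every voxel pair
oracle_glcm_counts <- function(levels, off) {
  d <- dim(levels)
  lv <- sort(unique(levels[!is.na(levels)]))
  P <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- levels[x, y, z]
    if (is.na(a)) next
    X <- x + off[1]; Y <- y + off[2]; Z <- z + off[3]
    if (X < 1 || X > d[1] || Y < 1 || Y > d[2] || Z < 1 || Z > d[3]) next
    b <- levels[X, Y, Z]
    if (is.na(b)) next
    P[as.character(a), as.character(b)] <- P[as.character(a), as.character(b)] + 1
  }
  P + t(P)
}

# naive run extraction: walk every line of direction `off` voxel by voxel
oracle_glrlm_runs <- function(levels, off) {
  d <- dim(levels)
  runs <- list()
  starts <- which(array(TRUE, d), arr.ind = TRUE)
  is_start <- function(p) {
    q <- p - off
    any(q < 1) || any(q > d)
  }
  for (r in seq_len(nrow(starts))) {
    p <- starts[r, ]
    if (!is_start(p)) next
    cur_lv <- NA; cur_len <- 0
    while (all(p >= 1) && all(p <= d)) {
      v <- levels[p[1], p[2], p[3]]
      if (!is.na(v) && !is.na(cur_lv) && v == cur_lv) {
        cur_len <- cur_len + 1
      } else {
        if (!is.na(cur_lv)) runs[[length(runs) + 1]] <- c(cur_lv, cur_len)
        cur_lv <- v; cur_len <- if (is.na(v)) 0 else 1
      }
      p <- p + off
    }
    if (!is.na(cur_lv)) runs[[length(runs) + 1]] <- c(cur_lv, cur_len)
  }
  do.call(rbind, runs)
}

# small random test ROI embedded in a grid, NA outside the mask
random_level_array <- function(dims, n_levels, p_mask = 0.8, seed = 1) {
  set.seed(seed)
  lv <- array(sample.int(n_levels, prod(dims), replace = TRUE), dim = dims)
  lv[runif(prod(dims)) > p_mask] <- NA
  if (all(is.na(lv))) lv[1] <- 1L
  lv
}

# deterministic little cohort for survival tests
toy_cohort <- function() {
  tibble::tibble(
    sample_id = paste0("P", 1:6),
    time_months = c(5, 8, 12, 9, 20, 14),
    event = c(1, 1, 1, 0, 1, 0),
    failure_12mo = as.integer(c(1, 1, 1, 0, 0, 0))
  )
}
toy_covariate <- c(2.0, 1.5, 1.0, 1.2, 0.3, 0.5)
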