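#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats quantile rnorm runif rexp sd cor uniroot pchisq qnorm
#' @importFrom utils head tail
NULL

# Evaluate `code` with a locally seeded RNG, restoring global state after.
# All stochastic code in the package funnels through this; nothing touches
# the caller's .Random.seed.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed from a master seed plus integer tags; stays
# within 32-bit range (R integers) and well below 2^53 during arithmetic.
derive_seed <- function(master, ...) {
  tags <- c(...)
  h <- as.numeric(master) %% 2147483647
  for (t in tags) {
    h <- (h * 48271 + as.numeric(t) + 1) %% 2147483647
  }
  as.integer(h)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be strictly positive and finite.", name))
  }
  invisible(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# log2 with 0 * log(0) = 0 convention used by all entropy-type features
xlog2 <- function(p) ifelse(p > 0, log2(p), 0)
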