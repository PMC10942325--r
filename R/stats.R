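#' Resampling and exact tests
#'
#' All tests return a uniform `tachy_test` record with fields `statistic`,
#' `p_value`, `n`, `method`, `n_iterations`, `seed`, serialisable to JSON
#' with [test_to_json()]. Monte-Carlo p-values use the +1 continuity
#' correction (the observed statistic counts among the permutations), so
#' `p_value` is always in (0, 1]. Small problems switch automatically to
#' exhaustive enumeration.
#'
#' @name tachy_tests
NULL

new_test_result <- function(statistic, p_value, n, method, n_iterations,
                            seed = NA_integer_) {
  structure(list(statistic = statistic, p_value = p_value, n = n,
                 method = method, n_iterations = n_iterations, seed = seed),
            class = "tachy_test")
}

#' @export
print.tachy_test <- function(x, ...) {
  cat(sprintf("<tachy_test:%s> statistic = %.4g, p = %.4g (n = %d, %s iter)\n",
              x$method, x$statistic, x$p_value, x$n,
              format(x$n_iterations, big.mark = ",")))
  invisible(x)
}

#' Serialise a test result to a JSON record
#' @param x A `tachy_test`.
#' @return A JSON string.
#' @export
test_to_json <- function(x) {
  stopifnot(inherits(x, "tachy_test"))
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA, na = "null")
}

#' Paired permutation test
#'
#' Tests whether the mean paired difference `mean(a - b)` differs from
#' zero by randomly flipping the signs of the paired differences. When all
#' `2^n` sign patterns fit within `n_iter`, the test enumerates them
#' exhaustively (exact); otherwise it Monte-Carlo samples `n_iter` flips
#' and applies the +1 correction. Two-sided by absolute statistic.
#'
#' @param a,b Paired numeric vectors of equal length >= 2.
#' @param n_iter Number of iterations (default 100000).
#' @param seed RNG seed for the Monte-Carlo path.
#' @return A `tachy_test` with `method = "paired_permutation"`.
#' @examples
#' paired_permutation_test(c(4, 5, 6), c(3, 3, 3), n_iter = 10000)
#' @export
paired_permutation_test <- function(a, b, n_iter = 100000, seed = 1L) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  obs <- mean(d)
  if (2^n <= n_iter) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null <- as.vector(signs %*% d) / n
    p <- mean(abs(null) >= abs(obs) - 1e-12)
    return(new_test_result(obs, p, n, "paired_permutation", 2L^n))
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  flips <- matrix(sample(c(-1, 1), n * n_iter, replace = TRUE), n_iter, n)
  null <- as.vector(flips %*% d) / n
  p <- (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (n_iter + 1)
  new_test_result(obs, p, n, "paired_permutation", as.integer(n_iter),
                  as.integer(seed))
}

#' Unpaired randomization test for a difference in means
#'
#' Null distribution built by randomly reassigning the pooled observations
#' to the two groups. Two-sided by absolute statistic with +1 correction.
#'
#' @param x,y Numeric vectors (possibly of different lengths).
#' @param n_iter Iterations (default 100000).
#' @param seed RNG seed.
#' @return A `tachy_test` with `method = "randomization"` and
#'   `statistic = mean(x) - mean(y)`.
#' @export
randomization_test <- function(x, y, n_iter = 100000, seed = 1L) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  pooled <- c(x, y)
  nx <- length(x)
  obs <- mean(x) - mean(y)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  null <- replicate(n_iter, {
    idx <- sample.int(length(pooled), nx)
    mean(pooled[idx]) - mean(pooled[-idx])
  })
  p <- (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (n_iter + 1)
  new_test_result(obs, p, length(pooled), "randomization",
                  as.integer(n_iter), as.integer(seed))
}

#' Exact binomial test
#'
#' Exact tail probabilities for `k` successes in `n` Bernoulli(`p0`)
#' trials. The two-sided p-value uses minimum-likelihood tail summation
#' (sum of the probabilities of all outcomes no more likely than the
#' observed one), matching `stats::binom.test()`. For directional
#' hypotheses fixed a priori — e.g. "the rise-point difference has the
#' predicted sign in k of n participants" — use `alternative = "greater"`
#' or `"less"`.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Null success probability (default 0.5).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A `tachy_test` with `method = "binomial"` and
#'   `statistic = k / n`.
#' @examples
#' binomial_test(9, 11, alternative = "greater")  # one-sided sign test
#' @export
binomial_test <- function(k, n, p0 = 0.5,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(k >= 0, k <= n, n >= 1, p0 > 0, p0 < 1)
  p <- switch(
    alternative,
    greater = stats::pbinom(k - 1, n, p0, lower.tail = FALSE),
    less = stats::pbinom(k, n, p0),
    two.sided = {
      dens <- stats::dbinom(0:n, n, p0)
      min(1, sum(dens[dens <= stats::dbinom(k, n, p0) * (1 + 1e-7)]))
    }
  )
  new_test_result(k / n, p, as.integer(n), "binomial", 0L)
}

#' Pearson correlation with a permutation p-value
#'
#' Statistic is the Pearson r; the null distribution is built by permuting
#' `y` against `x`. Exhaustive over all `n!` permutations when that count
#' fits within `n_iter`; otherwise Monte-Carlo with +1 correction.
#' Two-sided by absolute r.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param n_iter Iterations (default 100000).
#' @param seed RNG seed.
#' @return A `tachy_test` with `method = "correlation_permutation"`.
#' @export
correlation_with_permutation <- function(x, y, n_iter = 100000, seed = 1L) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  n <- length(x)
  obs <- stats::cor(x, y)
  if (factorial(n) <= n_iter) {
    perms <- all_permutations(n)
    null <- apply(perms, 1, function(idx) stats::cor(x, y[idx]))
    p <- mean(abs(null) >= abs(obs) - 1e-12)
    return(new_test_result(obs, p, n, "correlation_permutation",
                           as.integer(factorial(n))))
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  null <- replicate(n_iter, stats::cor(x, y[sample.int(n)]))
  p <- (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (n_iter + 1)
  new_test_result(obs, p, n, "correlation_permutation",
                  as.integer(n_iter), as.integer(seed))
}

# all n! permutations of 1..n, by inserting n into every position of each
# permutation of 1..(n-1)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (r in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      out[row, ] <- append(sub[r, ], n, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' Ordinary least-squares simple linear regression
#'
#' Thin wrapper over `stats::lm(y ~ x)` returning slope, intercept and
#' fitted values; the intercept is the model's prediction at `x = 0`.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return List `slope`, `intercept`, `predictions`, `r_squared`.
#' @export
linear_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       predictions = unname(stats::fitted(fit)),
       r_squared = suppressWarnings(summary(fit)$r.squared))
}
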