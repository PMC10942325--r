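#' Clopper-Pearson exact binomial confidence interval
#'
#' Vectorised closed form via beta quantiles. Conservative (exact) and
#' identical to the interval reported by `stats::binom.test()`.
#'
#' @param k Successes (vector).
#' @param n Trials (vector).
#' @param level Confidence level (default 0.95).
#' @return Two-column matrix `cbind(low, high)`; rows with `n = 0` are NA.
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  stopifnot(length(level) == 1, level > 0, level < 1)
  alpha <- 1 - level
  low <- ifelse(k == 0, 0, stats::qbeta(alpha / 2, k, n - k + 1))
  high <- ifelse(k == n, 1, stats::qbeta(1 - alpha / 2, k + 1, n - k))
  low[n == 0] <- NA_real_
  high[n == 0] <- NA_real_
  cbind(low = low, high = high)
}

#' Compute a tachometric curve
#'
#' Fraction of correct choices as a function of raw processing time (rPT),
#' on a grid of sliding bins stepped every `bin_step` ms. Bin membership is
#' a closed interval: a trial with `|rpt - center| <= bin_width / 2` counts
#' (so each trial contributes to `bin_width / bin_step` consecutive bins
#' away from the grid edges). Bins with no trials are undefined (`NA`),
#' never zero. Per-bin confidence intervals are exact Clopper-Pearson.
#'
#' @param x A `tachy_trials` table (already filtered as desired).
#' @param bin_width Bin width in ms; 31 for aggregate curves, 41 for
#'   single participants.
#' @param bin_step Grid step in ms (default 1).
#' @param grid Numeric `c(min, max)` of bin centers, default `c(0, 300)`.
#' @param ci_level Confidence level for the per-bin binomial CIs.
#' @return A `tachometric_curve`: data.frame with columns `center`,
#'   `n_total`, `n_correct`, `frac_correct`, `ci_low`, `ci_high`.
#' @examples
#' tr <- generate_trials(n = 2000, seed = 1)
#' cv <- compute_curve(apply_filter(tr), bin_width = 31)
#' head(cv[cv$n_total > 0, ])
#' @export
compute_curve <- function(x, bin_width = 31, bin_step = 1,
                          grid = c(0, 300), ci_level = 0.95) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (bin_step <= 0) stop("bin_step must be > 0")
  centers <- seq(grid[1], grid[2], by = bin_step)
  half <- bin_width / 2

  # counts via sorted rPTs: membership in [c - w/2, c + w/2] (closed)
  rpt <- sort(x$rpt)
  rpt_c <- sort(x$rpt[x$correct])
  count_in <- function(v, lo, hi) {
    findInterval(hi, v) - findInterval(lo, v, left.open = TRUE)
  }
  n_total <- count_in(rpt, centers - half, centers + half)
  n_correct <- count_in(rpt_c, centers - half, centers + half)

  frac <- ifelse(n_total > 0, n_correct / n_total, NA_real_)
  ci <- clopper_pearson(n_correct, n_total, ci_level)
  out <- data.frame(center = centers, n_total = n_total,
                    n_correct = n_correct, frac_correct = frac,
                    ci_low = ci[, "low"], ci_high = ci[, "high"])
  attr(out, "bin_width") <- bin_width
  attr(out, "bin_step") <- bin_step
  attr(out, "ci_level") <- ci_level
  attr(out, "n_trials") <- nrow(x)
  class(out) <- c("tachometric_curve", "data.frame")
  out
}

#' Pool trial sets into one tachometric curve
#'
#' Pooling is at the trial level, not an average of per-set curves: the
#' result is identical to [compute_curve()] on the concatenated trials.
#'
#' @param trial_sets A list of `tachy_trials` tables.
#' @param ... Passed to [compute_curve()].
#' @return A `tachometric_curve`.
#' @export
pool_curves <- function(trial_sets, ...) {
  stopifnot(is.list(trial_sets), length(trial_sets) >= 1)
  pooled <- do.call(rbind, lapply(trial_sets, as.data.frame))
  class(pooled) <- c("tachy_trials", "data.frame")
  compute_curve(pooled, ...)
}

#' Write a curve to CSV
#'
#' Columns: `center_ms,n_total,n_correct,frac_correct,ci_low,ci_high`.
#'
#' @param curve A `tachometric_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  df <- as.data.frame(curve)
  names(df)[names(df) == "center"] <- "center_ms"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.tachometric_curve <- function(x, ...) {
  def <- sum(x$n_total > 0)
  cat(sprintf(paste0("<tachometric_curve> %d bins (%d defined), width %g ms,",
                     " step %g ms, %d trials\n"),
              nrow(x), def, attr(x, "bin_width"), attr(x, "bin_step"),
              attr(x, "n_trials")))
  invisible(x)
}
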