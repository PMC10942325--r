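#' Derive the exogenous response window from paired curves
#'
#' The exogenous (luminance-driven) deflection pulls pro and anti accuracy
#' in opposite directions: mirroring the anti curve about chance
#' (`p -> 1 - p`) superimposes the two trajectories while capture lasts.
#' The window is found by locating the strongest common deviation from
#' 0.5 where the pro curve and the mirrored anti curve agree in sign, and
#' extending it outward to their crossings of 0.5. With several
#' experiment pairs the per-pair windows are intersected.
#'
#' @param curve_pro,curve_anti `tachometric_curve`s on a shared grid
#'   covering at least 50-200 ms; alternatively pass `pairs`, a list of
#'   `list(pro = , anti = )` pairs.
#' @param pairs Optional list of curve pairs; overrides the two curves.
#' @param search rPT range searched, default `c(50, 200)` ms.
#' @return Numeric `c(lo, hi)` in ms, or `NULL` (with a message) when no
#'   consistent deviation from chance exists.
#' @export
derive_capture_window <- function(curve_pro = NULL, curve_anti = NULL,
                                  pairs = NULL, search = c(50, 200)) {
  if (is.null(pairs)) pairs <- list(list(pro = curve_pro, anti = curve_anti))
  windows <- lapply(pairs, function(pr) {
    one_capture_window(pr$pro, pr$anti, search)
  })
  if (any(vapply(windows, is.null, TRUE))) {
    message("derive_capture_window: no consistent deviation from chance")
    return(NULL)
  }
  lo <- max(vapply(windows, `[`, 0, 1))
  hi <- min(vapply(windows, `[`, 0, 2))
  if (lo >= hi) {
    message("derive_capture_window: per-pair windows do not intersect")
    return(NULL)
  }
  c(lo, hi)
}

one_capture_window <- function(pro, anti, search) {
  sel <- pro$center >= search[1] & pro$center <= search[2] &
    pro$n_total > 0 & anti$n_total > 0
  if (!any(sel)) return(NULL)
  stopifnot(all(pro$center == anti$center))
  x <- pro$center[sel]
  d_pro <- pro$frac_correct[sel] - 0.5
  d_anti <- (1 - anti$frac_correct[sel]) - 0.5  # mirrored about chance
  same <- sign(d_pro) == sign(d_anti) & d_pro != 0 & d_anti != 0
  if (!any(same)) return(NULL)
  joint <- abs(d_pro + d_anti) / 2
  joint[!same] <- -Inf
  peak <- which.max(joint)
  lo <- peak
  while (lo > 1 && same[lo - 1] && sign(d_pro[lo - 1]) == sign(d_pro[peak])) {
    lo <- lo - 1
  }
  hi <- peak
  while (hi < length(x) && same[hi + 1] &&
         sign(d_pro[hi + 1]) == sign(d_pro[peak])) {
    hi <- hi + 1
  }
  c(x[lo], x[hi])
}

#' Fraction correct inside the exogenous response window
#'
#' Tallies pro and anti trials whose rPT lies inside the closed window
#' (default 83-124 ms) and returns fractions correct with exact binomial
#' CIs. Under pure luminance-driven capture, pro and anti deviate from
#' chance by the same amount in opposite directions; `symmetry_p` reports
#' a randomization test of that equality, run on the per-trial indicator
#' "saccade toward the high-luminance stimulus" (equal capture means this
#' indicator has the same rate in pro and anti trials).
#'
#' @param x A `tachy_trials` table (filtered; typically one experiment).
#' @param window Closed rPT interval, ms.
#' @param bright Which stimulus carries the higher luminance: `"cue"`
#'   (Experiment 3), `"noncue"` (Experiment 4) or `"none"` (Experiments
#'   1-2; symmetry test skipped).
#' @param ci_level Level for the Clopper-Pearson intervals.
#' @param n_iter,seed Randomization-test settings.
#' @return A `capture_result` list with counts, fractions, CIs and
#'   `symmetry_p`.
#' @export
capture_fraction <- function(x, window = c(83, 124),
                             bright = c("none", "cue", "noncue"),
                             ci_level = 0.95, n_iter = 10000, seed = 1L) {
  bright <- match.arg(bright)
  inw <- x[!x$excluded & x$rpt >= window[1] & x$rpt <= window[2], ,
           drop = FALSE]
  tally <- function(tt) {
    sub <- inw[inw$trial_type == tt, , drop = FALSE]
    k <- sum(sub$correct); n <- nrow(sub)
    ci <- clopper_pearson(k, n, ci_level)
    list(n = n, k = k, frac = if (n > 0) k / n else NA_real_,
         ci = c(ci[1, "low"], ci[1, "high"]))
  }
  pro <- tally("pro"); anti <- tally("anti")

  symmetry_p <- NA_real_
  if (bright != "none" && pro$n > 0 && anti$n > 0) {
    # toward-bright indicator: in Exp-3 style (bright cue) a correct pro
    # saccade goes to the bright stimulus and a correct anti saccade to
    # the dim one; Exp 4 is the reverse.
    toward_cue <- inw$choice_side == inw$cue_side
    toward_bright <- if (bright == "cue") toward_cue else !toward_cue
    tst <- randomization_test(as.numeric(toward_bright[inw$trial_type == "pro"]),
                              as.numeric(toward_bright[inw$trial_type == "anti"]),
                              n_iter = n_iter, seed = seed)
    symmetry_p <- tst$p_value
  }
  structure(list(window = window,
                 n_pro = pro$n, n_anti = anti$n,
                 frac_correct_pro = pro$frac, frac_correct_anti = anti$frac,
                 ci_pro = pro$ci, ci_anti = anti$ci,
                 symmetry_p = symmetry_p),
            class = "capture_result")
}

#' @export
print.capture_result <- function(x, ...) {
  cat(sprintf(paste0("<capture_result> window [%g, %g] ms: pro %.3f ",
                     "(n=%d), anti %.3f (n=%d), symmetry p = %s\n"),
              x$window[1], x$window[2], x$frac_correct_pro, x$n_pro,
              x$frac_correct_anti, x$n_anti, format(x$symmetry_p)))
  invisible(x)
}

#' Guessing bias toward the cue
#'
#' Over all trials (pro and anti combined) with rPT at or below `max_rpt`
#' (default 75 ms) — saccades launched before the stimuli could inform the
#' choice — counts choices landing on the cue side versus the non-cue
#' side, irrespective of trial type or correctness. A fraction above 0.5
#' indicates uninformed saccades are biased toward the attended location.
#'
#' @param x A `tachy_trials` table.
#' @param max_rpt Inclusive rPT ceiling for a guess, ms.
#' @param ci_level Level for the binomial CI.
#' @return A `guess_bias` list: `n_toward_cue`, `n_toward_noncue`,
#'   `frac_toward_cue`, `ci`.
#' @export
guess_bias <- function(x, max_rpt = 75, ci_level = 0.95) {
  g <- x[!x$excluded & x$rpt <= max_rpt, , drop = FALSE]
  toward <- sum(g$choice_side == g$cue_side)
  away <- nrow(g) - toward
  ci <- clopper_pearson(toward, nrow(g), ci_level)
  structure(list(n_toward_cue = toward, n_toward_noncue = away,
                 frac_toward_cue = if (nrow(g) > 0) toward / nrow(g)
                                   else NA_real_,
                 ci = c(ci[1, "low"], ci[1, "high"]), max_rpt = max_rpt),
            class = "guess_bias")
}

#' @export
print.guess_bias <- function(x, ...) {
  cat(sprintf(paste0("<guess_bias> %d toward cue vs %d toward non-cue ",
                     "(frac %.3f, rPT <= %g ms)\n"),
              x$n_toward_cue, x$n_toward_noncue, x$frac_toward_cue,
              x$max_rpt))
  invisible(x)
}

#' Antisaccade processing-time cost and motor bias from paired fits
#'
#' The shared accuracy criterion is the larger of the two fitted halfway
#' levels `(A + B) / 2`; the cost `delta_rpt` is the rPT at which the anti
#' curve attains that criterion minus the rPT at which the pro curve
#' attains it. The motor bias `delta_bias` is the pro baseline minus the
#' anti baseline (`B_pro - B_anti`): uninformed guesses biased toward the
#' cue raise the pro baseline and depress the anti baseline by the same
#' mechanism.
#'
#' @param fit_pro,fit_anti `sigmoid_fit`s for the same participant(s).
#' @param require_gate Require both fits to pass the modulation gate
#'   (default `TRUE`).
#' @return A `bias_cost` list: `delta_rpt` (ms; `NA` when the criterion
#'   exceeds one curve's asymptote), `delta_bias`, `criterion_level`,
#'   `rpt_pro`, `rpt_anti`, `fits`.
#' @export
antisaccade_cost <- function(fit_pro, fit_anti, require_gate = TRUE) {
  stopifnot(inherits(fit_pro, "sigmoid_fit"), inherits(fit_anti, "sigmoid_fit"))
  if (require_gate && !(fit_pro$quality$passes && fit_anti$quality$passes)) {
    stop("both fits must pass the modulation gate (set require_gate = FALSE ",
         "to override)")
  }
  crit <- max((fit_pro$A + fit_pro$B) / 2, (fit_anti$A + fit_anti$B) / 2)
  rpt_pro <- rpt_at_criterion(fit_pro, crit)
  rpt_anti <- rpt_at_criterion(fit_anti, crit)
  structure(list(delta_rpt = rpt_anti - rpt_pro,
                 delta_bias = fit_pro$B - fit_anti$B,
                 criterion_level = crit,
                 rpt_pro = rpt_pro, rpt_anti = rpt_anti,
                 fits = list(pro = fit_pro, anti = fit_anti)),
            class = "bias_cost")
}

#' @export
print.bias_cost <- function(x, ...) {
  cat(sprintf(paste0("<bias_cost> criterion %.3f: anti cost %.1f ms, ",
                     "motor bias %.3f\n"),
              x$criterion_level, x$delta_rpt, x$delta_bias))
  invisible(x)
}

#' Assign trials to the four chronometric rPT ranges
#'
#' G (guessing, rPT <= 75), C (capture, 83 <= rPT <= 124), T (transition,
#' 135 <= rPT < 200) and A (asymptotic, rPT >= 200); trials falling in
#' the gaps (75, 83) and (124, 135) belong to no range.
#'
#' @param rpt Numeric rPTs, ms.
#' @param config An [analysis_config()].
#' @return Character vector `"G"`, `"C"`, `"T"`, `"A"` or `NA`.
#' @export
rpt_range <- function(rpt, config = analysis_config()) {
  out <- rep(NA_character_, length(rpt))
  out[rpt <= config$guessing_max_rpt] <- "G"
  out[rpt >= config$capture_window[1] & rpt <= config$capture_window[2]] <- "C"
  out[rpt >= config$transition_range[1] & rpt < config$transition_range[2]] <- "T"
  out[rpt >= config$asymptotic_min_rpt] <- "A"
  out
}

#' Fraction correct in the four rPT ranges
#'
#' For each participant x experiment x trial type cell, the fraction of
#' correct choices in each range, with counts — a four-bin discretised
#' version of the tachometric curve.
#'
#' @param x A `tachy_trials` table.
#' @param config An [analysis_config()].
#' @return A `data.frame` with columns `participant`, `experiment`,
#'   `trial_type`, `range`, `n`, `n_correct`, `frac_correct`.
#' @export
range_summary <- function(x, config = analysis_config()) {
  x <- x[!x$excluded, , drop = FALSE]
  rng <- rpt_range(x$rpt, config)
  keep <- !is.na(rng)
  x <- x[keep, , drop = FALSE]
  rng <- factor(rng[keep], levels = c("G", "C", "T", "A"))
  key <- interaction(x$participant, x$experiment, x$trial_type, rng,
                     drop = TRUE, sep = "\r")
  n <- tapply(x$correct, key, length)
  k <- tapply(x$correct, key, sum)
  parts <- do.call(rbind, strsplit(names(n), "\r", fixed = TRUE))
  out <- data.frame(participant = parts[, 1],
                    experiment = as.integer(parts[, 2]),
                    trial_type = parts[, 3],
                    range = parts[, 4],
                    n = as.integer(n), n_correct = as.integer(k),
                    frac_correct = as.numeric(k / n),
                    stringsAsFactors = FALSE)
  out <- out[order(out$participant, out$experiment, out$trial_type,
                   match(out$range, c("G", "C", "T", "A"))), ]
  rownames(out) <- NULL
  out
}

#' Per-participant pro-minus-anti differences in two ranges
#'
#' Companion to [range_summary()] for the bias-cost relationship: for each
#' participant (pooled across experiments), the difference in fraction
#' correct between pro and anti trials within the transition range
#' (a discretised antisaccade cost) and within the guessing range (a
#' discretised motor bias).
#'
#' @param x A `tachy_trials` table.
#' @param config An [analysis_config()].
#' @return A data.frame with columns `participant`, `diff_G`, `diff_T`.
#' @export
range_bias_cost <- function(x, config = analysis_config()) {
  x <- x[!x$excluded, , drop = FALSE]
  rng <- rpt_range(x$rpt, config)
  per <- function(pid, r) {
    sel <- x$participant == pid & !is.na(rng) & rng == r
    pro <- x$correct[sel & x$trial_type == "pro"]
    anti <- x$correct[sel & x$trial_type == "anti"]
    if (!length(pro) || !length(anti)) return(NA_real_)
    mean(pro) - mean(anti)
  }
  pids <- sort(unique(x$participant))
  data.frame(participant = pids,
             diff_G = vapply(pids, per, 0, r = "G"),
             diff_T = vapply(pids, per, 0, r = "T"),
             stringsAsFactors = FALSE)
}

#' Identify reliable performers from easy trials
#'
#' A participant qualifies when their fraction of correct choices on easy,
#' non-urgent trials (gap < 0) strictly exceeds `config$performance_criterion`
#' in all 8 cells (4 experiments x pro/anti).
#'
#' @param x A `tachy_trials` table containing easy trials.
#' @param config An [analysis_config()].
#' @return Character vector of qualifying participant ids.
#' @export
reliable_performers <- function(x, config = analysis_config()) {
  easy <- apply_filter(x, trial_filter(urgency = "easy_only"))
  ok <- vapply(sort(unique(x$participant)), function(pid) {
    sub <- easy[easy$participant == pid, , drop = FALSE]
    cells <- expand.grid(experiment = 1:4, trial_type = TRIAL_TYPES,
                         stringsAsFactors = FALSE)
    all(vapply(seq_len(nrow(cells)), function(i) {
      cc <- sub$correct[sub$experiment == cells$experiment[i] &
                          sub$trial_type == cells$trial_type[i]]
      length(cc) > 0 && mean(cc) > config$performance_criterion
    }, TRUE))
  }, TRUE)
  names(ok)[ok]
}
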