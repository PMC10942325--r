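#' Evaluate the four-parameter sigmoid
#'
#' `s(x) = B + (A - B) / (1 + exp(-(x - C) / D))`, where `B` is the
#' baseline, `A` the asymptote, `C` the rise point (the rPT at which the
#' curve is halfway between baseline and asymptote) and `D` sets the slope
#' of the rise.
#'
#' @param x rPT values, ms.
#' @param params Numeric `c(A, B, C, D)` (named or positional).
#' @return `s(x)`, a value between `min(A, B)` and `max(A, B)`.
#' @examples
#' sigmoid_eval(150, c(A = 1, B = 0.5, C = 150, D = 20))  # (A + B) / 2
#' @export
sigmoid_eval <- function(x, params) {
  p <- as_abcd(params)
  if (p[["D"]] == 0) stop("D must be nonzero")
  p[["B"]] + (p[["A"]] - p[["B"]]) * stats::plogis((x - p[["C"]]) / p[["D"]])
}

as_abcd <- function(params) {
  p <- unlist(params, use.names = TRUE)
  if (is.null(names(p)) || !all(c("A", "B", "C", "D") %in% names(p))) {
    stopifnot(length(p) >= 4)
    names(p)[1:4] <- c("A", "B", "C", "D")
  }
  p[c("A", "B", "C", "D")]
}

# Unconstrained <-> bounded reparameterisation used by the simplex search:
# fractions A, B live in [0,1] via logit; D in (0, 200] via scaled logit.
theta_to_abcd <- function(theta) {
  c(A = stats::plogis(theta[1]), B = stats::plogis(theta[2]),
    C = theta[3], D = 200 * stats::plogis(theta[4]))
}
abcd_to_theta <- function(p) {
  clamp <- function(v) min(max(v, 1e-4), 1 - 1e-4)
  c(stats::qlogis(clamp(p[["A"]])), stats::qlogis(clamp(p[["B"]])),
    p[["C"]], stats::qlogis(clamp(p[["D"]] / 200)))
}

#' Fit the sigmoid to a tachometric curve
#'
#' Minimises the mean absolute error between the empirical curve and the
#' sigmoid over the defined (n > 0) bins inside `range`, with a
#' derivative-free Nelder-Mead simplex search (the same family of
#' optimiser as MATLAB's `fminsearch`). Because the raw simplex is
#' unconstrained, `A` and `B` are kept in \[0, 1\] and `D` in (0, 200\] via a
#' logit transform. Three jittered restarts of the data-driven
#' initialisation are run and the best objective kept; given `init`,
#' `seed` and the data the result is deterministic.
#'
#' Default initialisation: `B0` = mean fraction over bins with center
#' < 100 ms, `A0` = mean over centers > 250 ms, `C0` = first center whose
#' fraction reaches `(A0 + B0) / 2`, `D0 = 25` ms.
#'
#' @param curve A `tachometric_curve`.
#' @param init Optional `c(A, B, C, D)` starting point; `NULL` for auto.
#' @param range rPT fitting range, default `c(0, 300)` ms.
#' @param n_starts Number of jittered restarts (default 3).
#' @param seed Seed for the restart jitter.
#' @return A `sigmoid_fit` list: `A`, `B`, `C`, `D`, `mae`, `range`,
#'   `convergence`, `quality` (a [fit_quality()] result).
#' @export
fit_sigmoid <- function(curve, init = NULL, range = c(0, 300),
                        n_starts = 3, seed = 1L) {
  sel <- curve$n_total > 0 & curve$center >= range[1] & curve$center <= range[2]
  if (sum(sel) < 10) {
    stop("fit error: fewer than 10 defined bins in the fitting range")
  }
  xs <- curve$center[sel]
  fs <- curve$frac_correct[sel]

  objective <- function(theta) {
    p <- theta_to_abcd(theta)
    mean(abs(p[["B"]] + (p[["A"]] - p[["B"]]) *
               stats::plogis((xs - p[["C"]]) / p[["D"]]) - fs))
  }

  if (is.null(init)) {
    b0 <- mean(fs[xs < 100])
    a0 <- mean(fs[xs > 250])
    if (!is.finite(b0)) b0 <- fs[1]
    if (!is.finite(a0)) a0 <- fs[length(fs)]
    half <- (a0 + b0) / 2
    c0 <- xs[which(fs >= half)[1]]
    if (is.na(c0)) c0 <- stats::median(xs)
    init <- c(A = a0, B = b0, C = c0, D = 25)
  } else {
    init <- as_abcd(init)
  }

  theta0 <- abcd_to_theta(init)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  best <- NULL
  for (s in seq_len(n_starts)) {
    th <- if (s == 1) theta0 else theta0 + stats::rnorm(4, 0, c(0.3, 0.3, 15, 0.3))
    opt <- stats::optim(th, objective, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-8))
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  p <- theta_to_abcd(best$par)
  fit <- structure(list(A = unname(p[["A"]]), B = unname(p[["B"]]),
                        C = unname(p[["C"]]), D = unname(p[["D"]]),
                        mae = best$value, range = range,
                        convergence = best$convergence),
                   class = "sigmoid_fit")
  fit$quality <- fit_quality(fit, curve, range = range)
  fit
}

#' Fit-quality gate: curve modulation and fit error
#'
#' `delta_s` is the modulation of the fitted sigmoid, `max(s) - min(s)`
#' over the defined bins in `range`; `e` is the mean absolute error
#' between fit and empirical curve over the same bins; curves qualify for
#' rise-point analysis when the ratio `delta_s / e` exceeds `threshold`
#' (default 2.5), i.e. when they are both strongly modulated and well fit.
#'
#' @param fit A `sigmoid_fit` (or `c(A, B, C, D)`).
#' @param curve The empirical `tachometric_curve`.
#' @param range Evaluation range, ms.
#' @param threshold Qualification threshold on `delta_s / e`.
#' @return List `delta_s`, `e`, `ratio`, `passes`.
#' @export
fit_quality <- function(fit, curve, range = c(0, 300), threshold = 2.5) {
  p <- if (inherits(fit, "sigmoid_fit")) {
    c(A = fit$A, B = fit$B, C = fit$C, D = fit$D)
  } else {
    as_abcd(fit)
  }
  sel <- curve$n_total > 0 & curve$center >= range[1] & curve$center <= range[2]
  s <- sigmoid_eval(curve$center[sel], p)
  e <- mean(abs(s - curve$frac_correct[sel]))
  delta_s <- max(s) - min(s)
  # a modulation below 1% correct is unresolvable: treat as flat rather
  # than risk a spuriously large ratio from a near-zero fit error
  ratio <- if (delta_s < 0.01) 0 else if (e > 0) delta_s / e else Inf
  list(delta_s = delta_s, e = e, ratio = ratio,
       passes = ratio > threshold)
}

#' Rise point of a fitted sigmoid
#'
#' The rPT at which the fitted curve reaches the midpoint between its
#' minimum and maximum values; by construction this is the parameter `C`.
#'
#' @param fit A `sigmoid_fit`.
#' @return `C`, in ms.
#' @export
rise_point <- function(fit) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  fit$C
}

#' rPT at a fixed accuracy criterion
#'
#' Closed-form inverse of the sigmoid: the rPT at which the fitted curve
#' first exceeds `theta`. Defined only when `B < theta < A` (for a rising
#' curve); `NA` when the asymptote never reaches the criterion.
#'
#' @param fit A `sigmoid_fit` or `c(A, B, C, D)`.
#' @param theta Accuracy criterion in (0, 1), default 0.7.
#' @return rPT in ms, or `NA_real_`.
#' @examples
#' f <- list(A = 1, B = 0.5, C = 150, D = 20)
#' rpt_at_criterion(c(A = 1, B = 0.5, C = 150, D = 20), 0.7)
#' @export
rpt_at_criterion <- function(fit, theta = 0.7) {
  stopifnot(theta > 0, theta < 1)
  p <- if (inherits(fit, "sigmoid_fit")) {
    c(A = fit$A, B = fit$B, C = fit$C, D = fit$D)
  } else {
    as_abcd(fit)
  }
  lo <- min(p[["A"]], p[["B"]]); hi <- max(p[["A"]], p[["B"]])
  if (theta <= lo || theta >= hi) return(NA_real_)
  unname(p[["C"]] + p[["D"]] *
           log((theta - p[["B"]]) / (p[["A"]] - theta)))
}

#' Bootstrap confidence intervals for sigmoid parameters
#'
#' Resamples the trials with replacement, recomputes the tachometric curve
#' and refits the sigmoid for each replicate; 95% CIs are the 2.5 and 97.5
#' percentiles of the replicate distributions. Replicates whose fit fails
#' or is degenerate (no modulation) are excluded from the percentiles and
#' counted in `n_failed`. Each replicate is refit from the original fit's
#' parameters with a single start, which is standard for bootstrap refits
#' and keeps the cost linear in `n_reps`.
#'
#' @param x A `tachy_trials` table (the trials behind the curve).
#' @param n_reps Number of bootstrap replicates (>= 1; canonical use is
#'   1000-10000).
#' @param bin_width,bin_step,grid,range Curve and fit settings, as in
#'   [compute_curve()] and [fit_sigmoid()].
#' @param seed RNG seed; results are reproducible given the seed.
#' @return A `bootstrap_result` list: `n_reps`, `n_failed`,
#'   `param_samples` (data.frame of A, B, C, D per successful replicate),
#'   `ci95` (4 x 2 matrix), `fit` (the fit to the original data).
#' @export
bootstrap_fit <- function(x, n_reps = 1000, bin_width = 31, bin_step = 1,
                          grid = c(0, 300), range = c(0, 300), seed = 1L) {
  stopifnot(n_reps >= 1)
  n <- nrow(x)
  base_curve <- compute_curve(x, bin_width, bin_step, grid)
  base_fit <- fit_sigmoid(base_curve, range = range, seed = seed)
  init <- c(A = base_fit$A, B = base_fit$B, C = base_fit$C, D = base_fit$D)

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  samples <- matrix(NA_real_, n_reps, 4,
                    dimnames = list(NULL, c("A", "B", "C", "D")))
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    cv <- compute_curve(x[idx, , drop = FALSE], bin_width, bin_step, grid)
    ft <- tryCatch(
      fit_sigmoid(cv, init = init, range = range, n_starts = 1, seed = r),
      error = function(e) NULL
    )
    if (is.null(ft) || ft$quality$delta_s < 1e-3) {
      n_failed <- n_failed + 1L
    } else {
      samples[r, ] <- c(ft$A, ft$B, ft$C, ft$D)
    }
  }
  keep <- stats::complete.cases(samples)
  if (!any(keep)) {
    warning("all bootstrap replicates failed or were degenerate")
    ci <- matrix(NA_real_, 4, 2, dimnames = list(c("A", "B", "C", "D"),
                                                 c("lo", "hi")))
  } else {
    if (n_failed > 0) {
      warning(sprintf("%d of %d bootstrap replicates failed/degenerate",
                      n_failed, n_reps))
    }
    ci <- t(apply(samples[keep, , drop = FALSE], 2, stats::quantile,
                  probs = c(0.025, 0.975)))
    colnames(ci) <- c("lo", "hi")
  }
  structure(list(n_reps = n_reps, n_failed = n_failed,
                 param_samples = as.data.frame(samples[keep, , drop = FALSE]),
                 ci95 = ci, fit = base_fit, seed = as.integer(seed)),
            class = "bootstrap_result")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(paste0("<sigmoid_fit> A=%.3f B=%.3f C=%.1f ms D=%.1f ms ",
                     "(MAE %.4f; delta_s/e = %.2f, %s)\n"),
              x$A, x$B, x$C, x$D, x$mae, x$quality$ratio,
              if (x$quality$passes) "qualifies" else "below gate"))
  invisible(x)
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %d reps (%d failed), seed %d\n",
              x$n_reps, x$n_failed, x$seed))
  print(round(x$ci95, 3))
  invisible(x)
}

# Save/restore the global RNG so seeded internals do not perturb the
# caller's random stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
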