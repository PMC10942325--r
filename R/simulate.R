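#' Ground-truth generative parameters for the trial simulator
#'
#' The simulator composes the accuracy model
#' `p(correct | rPT) = sigmoid + capture bump` that the analysis pipeline
#' assumes:
#' * uninformed guesses biased toward the cue (`baseline_bias` maps to the
#'   pro baseline `B_pro = bias` and the anti baseline
#'   `B_anti = 1 - bias`);
#' * a transient luminance-driven capture deflection, an additive
#'   Gaussian bump `amp * exp(-(rPT - center)^2 / (2 * halfwidth^2))`
#'   whose sign per trial type follows the luminance condition (positive
#'   amplitude raises accuracy for the trial type whose target is the
#'   brighter stimulus and lowers it for the other);
#' * a sigmoidal endogenous rise toward `endo_A`, whose rise point is
#'   `endo_C_anti - endo_C_pro` ms later (default 30) for anti than for
#'   pro trials.
#'
#' Defaults reflect the task's published statistical structure: guess bias
#' around 0.56, capture centred near 100 ms, rise points 165/195 ms, and
#' asymptotic accuracy above 90%. Parameter combinations whose composed
#' accuracy leaves \[0, 1\] anywhere are rejected at construction.
#'
#' @param baseline_bias Fraction of uninformed guesses toward the cue.
#' @param capture_amp Capture bump amplitude (fraction); applied with the
#'   sign implied by the experiment's luminances.
#' @param capture_center,capture_halfwidth Bump centre and Gaussian width
#'   (ms).
#' @param endo_A Asymptotic accuracy.
#' @param endo_C_pro,endo_C_anti Rise points (ms) of the endogenous
#'   sigmoid for pro and anti trials.
#' @param endo_D Sigmoid slope scale, ms.
#' @param rt_mean,rt_sd,rt_range Truncated-normal RT distribution (ms);
#'   defaults (280, 60, \[100, 600\]) populate the full rPT axis across
#'   the gap set.
#' @param gap_set Candidate gap durations, ms.
#' @param gap_weights Sampling weights over `gap_set` (default uniform).
#' @return A `generative_params` list.
#' @export
generative_params <- function(baseline_bias = 0.56,
                              capture_amp = 0.35,
                              capture_center = 100,
                              capture_halfwidth = 20,
                              endo_A = 0.93,
                              endo_C_pro = 165,
                              endo_C_anti = 195,
                              endo_D = 15,
                              rt_mean = 280, rt_sd = 60,
                              rt_range = c(100, 600),
                              gap_set = GAP_SET,
                              gap_weights = NULL) {
  p <- list(baseline_bias = baseline_bias, capture_amp = capture_amp,
            capture_center = capture_center,
            capture_halfwidth = capture_halfwidth,
            endo_A = endo_A, endo_C_pro = endo_C_pro,
            endo_C_anti = endo_C_anti, endo_D = endo_D,
            rt_mean = rt_mean, rt_sd = rt_sd, rt_range = rt_range,
            gap_set = gap_set,
            gap_weights = gap_weights %||% rep(1, length(gap_set)))
  stopifnot(p$baseline_bias > 0, p$baseline_bias < 1,
            p$endo_A > 0, p$endo_A <= 1, p$endo_D > 0,
            p$capture_halfwidth > 0,
            length(p$gap_weights) == length(p$gap_set))
  class(p) <- "generative_params"
  # composed accuracy must stay inside [0, 1] for every experiment/type;
  # clipping would distort the planted curve, so reject instead.
  grid <- seq(0, 800, by = 1)
  for (exp_id in 1:4) {
    for (tt in TRIAL_TYPES) {
      acc <- accuracy_function(grid, p, tt, exp_id)
      if (any(acc < 0 | acc > 1)) {
        stop("composed accuracy leaves [0, 1] for experiment ", exp_id,
             ", ", tt, " trials; adjust amplitudes/baselines")
      }
    }
  }
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Capture sign implied by an experiment's luminance condition
#'
#' Experiments 1 and 2 use equal cue/non-cue luminance (no net capture);
#' in Experiment 3 the cue is the bright stimulus (capture toward the
#' cue: helps pro, hurts anti) and in Experiment 4 the non-cue is bright
#' (the reverse).
#'
#' @param experiment Integer 1-4.
#' @param trial_type `"pro"` or `"anti"`.
#' @return -1, 0 or +1 multiplier for the capture amplitude.
#' @export
capture_sign <- function(experiment, trial_type) {
  stopifnot(all(experiment %in% 1:4))
  n <- max(length(experiment), length(trial_type))
  toward_cue <- rep_len(c(0, 0, 1, -1)[experiment], n)
  ifelse(rep_len(trial_type, n) == "pro", toward_cue, -toward_cue)
}

#' Planted accuracy model
#'
#' Evaluates the ground-truth `p(correct | rPT)` for a trial type under a
#' luminance condition: the endogenous sigmoid (baseline from
#' `baseline_bias`, asymptote `endo_A`, type-specific rise point) plus
#' the signed capture bump.
#'
#' @param rpt rPT values, ms.
#' @param params A [generative_params()].
#' @param trial_type `"pro"` or `"anti"`.
#' @param experiment Integer 1-4 (sets the capture sign).
#' @return Accuracy values in \[0, 1\].
#' @export
accuracy_function <- function(rpt, params, trial_type = "pro",
                              experiment = 1) {
  stopifnot(inherits(params, "generative_params") || is.list(params))
  B <- if (trial_type == "pro") params$baseline_bias else 1 - params$baseline_bias
  C <- if (trial_type == "pro") params$endo_C_pro else params$endo_C_anti
  endo <- B + (params$endo_A - B) * stats::plogis((rpt - C) / params$endo_D)
  s <- capture_sign(experiment, trial_type)
  endo + s * params$capture_amp *
    exp(-(rpt - params$capture_center)^2 / (2 * params$capture_halfwidth^2))
}

rtruncnorm <- function(n, mean, sd, range) {
  lo <- stats::pnorm(range[1], mean, sd)
  hi <- stats::pnorm(range[2], mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

#' Simulate urgent pro/antisaccade trials
#'
#' Draws trials with the task's structure: gaps sampled from the 11-value
#' gap set, RTs from a truncated normal, cue side fixed within 150-trial
#' blocks (alternating across blocks), trial type randomised per trial,
#' and correctness drawn from the planted [accuracy_function()].
#' Correctness is sampled first and the choice side derived from it, so
#' the realised accuracy curve is exactly the planted one.
#'
#' @param params A [generative_params()].
#' @param n Number of trials.
#' @param experiment Integer 1-4 (luminance condition).
#' @param participant Participant id for the table.
#' @param seed RNG seed; identical seeds give identical tables.
#' @return A `tachy_trials` table.
#' @examples
#' tr <- generate_trials(n = 500, experiment = 3, seed = 42)
#' table(tr$trial_type, tr$correct)
#' @export
generate_trials <- function(params = generative_params(), n = 1000,
                            experiment = 1, participant = "S1", seed = 1L) {
  stopifnot(n >= 0)
  if (n == 0) {
    return(trials(participant = character(0), experiment = integer(0),
                  trial_type = character(0), cue_side = character(0),
                  gap = numeric(0), rt = numeric(0),
                  choice_side = character(0), correct = logical(0)))
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  block <- (seq_len(n) - 1) %/% 150
  cue_side <- ifelse(block %% 2 == 0, "left", "right")
  gap <- sample(params$gap_set, n, replace = TRUE, prob = params$gap_weights)
  trial_type <- sample(TRIAL_TYPES, n, replace = TRUE)
  rt <- rtruncnorm(n, params$rt_mean, params$rt_sd, params$rt_range)
  rpt <- rt - gap
  p_correct <- numeric(n)
  for (tt in TRIAL_TYPES) {
    sel <- trial_type == tt
    p_correct[sel] <- accuracy_function(rpt[sel], params, tt, experiment)
  }
  correct <- stats::runif(n) < p_correct
  target_side <- ifelse(trial_type == "pro", cue_side,
                        ifelse(cue_side == "left", "right", "left"))
  choice_side <- ifelse(correct, target_side,
                        ifelse(target_side == "left", "right", "left"))
  trials(participant = participant, experiment = experiment,
         trial_type = trial_type, cue_side = cue_side, gap = gap, rt = rt,
         choice_side = choice_side, correct = correct)
}

#' Simulate a 1 kHz eye-position trace for one trial
#'
#' Gaussian fixation noise around the origin, then a minimum-jerk
#' horizontal saccade of `amplitude` degrees toward `choice_side` with
#' movement onset at `go_time + rt`. The attributes record the kinematic
#' ground truth used by detection tests: `onset_true` (movement start)
#' and `onset_threshold` (the analytic time at which the minimum-jerk
#' speed profile crosses `velocity_threshold`; for an 8 degree, 40 ms
#' saccade this is ~3.6 ms after movement start). An optional blink
#' interval marks samples invalid.
#'
#' @param go_time Fixation-offset time, ms from trace start.
#' @param rt Reaction time, ms.
#' @param gap Gap duration, ms (`cue_on_time = go_time + gap`).
#' @param choice_side `"left"` or `"right"`.
#' @param cue_side Cue location (carried through to scoring).
#' @param amplitude Saccade amplitude, degrees (default 8).
#' @param duration Saccade duration, ms (default 40).
#' @param noise_sd Fixation/pursuit position noise SD, degrees.
#' @param blink Optional `c(start, end)` ms interval of invalid samples.
#' @param velocity_threshold Criterion used for the recorded analytic
#'   crossing time, deg/s.
#' @param t_max Trace length, ms (default covers the saccade + 100 ms).
#' @param seed RNG seed.
#' @return An `eye_trace` (see [eye_trace()]).
#' @export
generate_trace <- function(go_time = 600, rt = 250, gap = 100,
                           choice_side = "right", cue_side = "right",
                           amplitude = 8, duration = 40, noise_sd = 0.02,
                           blink = NULL, velocity_threshold = 40,
                           t_max = NULL, seed = 1L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  onset <- go_time + rt
  t_max <- t_max %||% (onset + duration + 100)
  t <- seq(0, t_max, by = 1)
  sgn <- if (choice_side == "right") 1 else -1
  tau <- pmin(pmax((t - onset) / duration, 0), 1)
  x <- sgn * amplitude * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  y <- numeric(length(t))
  if (noise_sd > 0) {
    x <- x + stats::rnorm(length(t), 0, noise_sd)
    y <- y + stats::rnorm(length(t), 0, noise_sd)
  }
  valid <- rep(TRUE, length(t))
  if (!is.null(blink)) valid[t >= blink[1] & t <= blink[2]] <- FALSE

  # analytic first crossing of the speed criterion:
  # v(tau) = 30 A / T * tau^2 (1 - tau)^2, so tau (1 - tau) = sqrt(vth T / (30 A))
  r <- sqrt(velocity_threshold * (duration / 1000) / (30 * amplitude))
  onset_thr <- if (4 * r <= 1) {
    onset + duration * (1 - sqrt(1 - 4 * r)) / 2
  } else {
    NA_real_  # peak speed never reaches the criterion
  }

  tr <- eye_trace(t = t, x = x, y = y, valid = valid, go_time = go_time,
                  cue_on_time = go_time + gap, cue_side = cue_side)
  attr(tr, "onset_true") <- onset
  attr(tr, "onset_threshold") <- onset_thr
  attr(tr, "amplitude_true") <- amplitude
  tr
}
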