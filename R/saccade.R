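#' Construct an eye-position trace
#'
#' Uniformly sampled gaze positions (nominal 1 kHz) for one trial, in
#' degrees of visual angle, with the trial's event times attached.
#'
#' @param t Sample times, ms; strictly increasing and uniform.
#' @param x,y Gaze position, degrees.
#' @param valid Logical; `FALSE` marks missing/blink samples.
#' @param go_time Fixation-point offset time, ms.
#' @param cue_on_time Cue/non-cue onset time, ms (`go_time + gap`).
#' @param cue_side `"left"` or `"right"`.
#' @param target_x Horizontal eccentricity of the choice targets, degrees
#'   (default 8).
#' @return An `eye_trace` data.frame with the events as attributes.
#' @export
eye_trace <- function(t, x, y, valid = NULL, go_time, cue_on_time,
                      cue_side, target_x = 8) {
  stopifnot(length(t) == length(x), length(t) == length(y), length(t) >= 3)
  dt <- diff(t)
  if (any(dt <= 0) || diff(range(dt)) > 1e-3) {
    stop("input error: trace sampling must be uniform and increasing")
  }
  if (go_time < t[1] || go_time > t[length(t)] ||
      cue_on_time < t[1] || cue_on_time > t[length(t)]) {
    stop("go_time and cue_on_time must fall within the trace")
  }
  stopifnot(cue_side %in% SIDES)
  tr <- data.frame(t = t, x = x, y = y,
                   valid = if (is.null(valid)) rep(TRUE, length(t)) else valid)
  attr(tr, "go_time") <- go_time
  attr(tr, "cue_on_time") <- cue_on_time
  attr(tr, "cue_side") <- cue_side
  attr(tr, "target_x") <- target_x
  class(tr) <- c("eye_trace", "data.frame")
  tr
}

#' Read a trace from CSV/TSV plus its sidecar metadata
#'
#' Trace columns: `t_ms,x_deg,y_deg,valid`. The sidecar (JSON) carries
#' `go_time`, `cue_on_time` (or `gap`), `cue_side` and optional
#' `target_x`.
#'
#' @param path Trace file (`.csv` or `.tsv`).
#' @param sidecar JSON file with the trial metadata; default
#'   `<path>.json`.
#' @return An `eye_trace`.
#' @export
read_trace <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("t_ms", "x_deg", "y_deg")
  if (!all(need %in% names(df))) {
    stop("trace file must have columns t_ms,x_deg,y_deg[,valid]")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  cue_on <- meta$cue_on_time %||% (meta$go_time + meta$gap)
  eye_trace(t = df$t_ms, x = df$x_deg, y = df$y_deg,
            valid = if ("valid" %in% names(df)) as.logical(df$valid) else NULL,
            go_time = meta$go_time, cue_on_time = cue_on,
            cue_side = meta$cue_side, target_x = meta$target_x %||% 8)
}

#' Eye speed from a position trace
#'
#' Positions are smoothed with a short centred moving average (default 5
#' samples) and differentiated by central differences; speed is the
#' Euclidean norm of the two velocity components, in deg/s.
#'
#' @param trace An `eye_trace`.
#' @param smooth_samples Moving-average window length (odd; default 5).
#' @return Numeric speed per sample (first/last samples use one-sided
#'   differences).
#' @export
eye_speed <- function(trace, smooth_samples = 5) {
  stopifnot(smooth_samples >= 1)
  dt <- (trace$t[2] - trace$t[1]) / 1000  # s
  xs <- moving_average(trace$x, smooth_samples)
  ys <- moving_average(trace$y, smooth_samples)
  vx <- central_diff(xs, dt)
  vy <- central_diff(ys, dt)
  sqrt(vx^2 + vy^2)
}

moving_average <- function(v, k) {
  if (k <= 1) return(v)
  half <- k %/% 2
  cs <- cumsum(c(0, v))
  n <- length(v)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

central_diff <- function(v, dt) {
  n <- length(v)
  out <- numeric(n)
  out[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  out[1] <- (v[2] - v[1]) / dt
  out[n] <- (v[n] - v[n - 1]) / dt
  out
}

#' Detect the first saccade after the go signal
#'
#' Scans for the first sample after `go_time` whose speed strictly
#' exceeds `velocity_threshold` (default 40 deg/s). The saccade ends at
#' the first subsequent sample whose speed falls back below the
#' threshold; direction and amplitude are computed from the positions at
#' onset and end. Returns `NULL` when the speed never exceeds the
#' threshold (e.g. a trial with no saccade).
#'
#' @param trace An `eye_trace`.
#' @param velocity_threshold Criterion speed, deg/s.
#' @param smooth_samples Passed to [eye_speed()].
#' @return A `saccade_event` list (`onset_time`, `end_time`,
#'   `direction_deg` — signed angle from horizontal toward the chosen
#'   stimulus, `amplitude`, `choice_side`) or `NULL`.
#' @export
detect_saccade <- function(trace, velocity_threshold = 40,
                           smooth_samples = 5) {
  stopifnot(inherits(trace, "eye_trace"), velocity_threshold > 0)
  speed <- eye_speed(trace, smooth_samples)
  go <- attr(trace, "go_time")
  after <- which(trace$t > go & speed > velocity_threshold)
  if (!length(after)) return(NULL)
  onset <- after[1]
  below <- which(speed < velocity_threshold & seq_along(speed) > onset)
  end <- if (length(below)) below[1] else length(speed)
  dx <- trace$x[end] - trace$x[onset]
  dy <- trace$y[end] - trace$y[onset]
  structure(list(onset_time = trace$t[onset], end_time = trace$t[end],
                 direction_deg = atan2(dy, dx) * 180 / pi,
                 amplitude = sqrt(dx^2 + dy^2),
                 choice_side = if (dx >= 0) "right" else "left"),
            class = "saccade_event")
}

#' Detect blink intervals in a trace
#'
#' Runs of invalid (missing) samples, padded by `pad_ms` on each side.
#'
#' @param trace An `eye_trace`.
#' @param pad_ms Padding margin, ms (default 25).
#' @return A list of `c(start, end)` ms intervals (empty when none).
#' @export
detect_blinks <- function(trace, pad_ms = 25) {
  bad <- !trace$valid
  if (!any(bad)) return(list())
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values)
  lapply(idx, function(i) {
    c(trace$t[starts[i]] - pad_ms, trace$t[ends[i]] + pad_ms)
  })
}

#' Score one trial from its trace and detected saccade
#'
#' Applies the scoring and exclusion rules: `rt = onset - go_time`,
#' `rpt = onset - cue_on_time`; the choice side is the sign of the
#' horizontal displacement; trials whose first saccade deviates more than
#' 60 degrees from the horizontal axis through the stimuli are excluded
#' as near-vertical; a missing saccade is an abort; a blink overlapping
#' \[go, onset\] excludes the trial. Completed trials are retained even
#' when the RT exceeds the task deadline, and no amplitude criterion is
#' applied unless `min_amplitude` is set (a robustness-check option).
#'
#' @param event A `saccade_event` or `NULL`.
#' @param trace The trial's `eye_trace`.
#' @param trial_type `"pro"` or `"anti"`.
#' @param experiment Integer 1-4.
#' @param participant Participant id.
#' @param max_angle_deg Near-vertical exclusion threshold (default 60).
#' @param min_amplitude Optional minimum amplitude, degrees (`NULL` = no
#'   amplitude exclusion).
#' @param blink_pad_ms Padding for [detect_blinks()].
#' @return A one-row `tachy_trials` table. When the trial is excluded the
#'   gap is snapped to the nearest permitted value so the row remains
#'   schema-valid.
#' @export
score_trial <- function(event, trace, trial_type, experiment = 1,
                        participant = "P1", max_angle_deg = 60,
                        min_amplitude = NULL, blink_pad_ms = 25) {
  go <- attr(trace, "go_time")
  cue_on <- attr(trace, "cue_on_time")
  cue_side <- attr(trace, "cue_side")
  gap <- cue_on - go
  gap_canon <- GAP_SET[which.min(abs(GAP_SET - gap))]

  excluded <- FALSE
  reason <- "none"
  if (is.null(event)) {
    excluded <- TRUE
    reason <- "abort"
    rt <- 0
    choice_side <- cue_side   # placeholder; excluded rows never analysed
    correct <- trial_type == "pro"
  } else {
    rt <- event$onset_time - go
    choice_side <- event$choice_side
    angle <- abs(event$direction_deg)
    angle <- min(angle, 180 - angle)  # deviation from the horizontal axis
    blinks <- detect_blinks(trace, blink_pad_ms)
    blink_hit <- any(vapply(blinks, function(b) {
      b[1] <= event$onset_time && b[2] >= go
    }, TRUE))
    if (blink_hit) {
      excluded <- TRUE; reason <- "blink"
    } else if (angle > max_angle_deg) {
      excluded <- TRUE; reason <- "near_vertical"
    } else if (!is.null(min_amplitude) && event$amplitude < min_amplitude) {
      excluded <- TRUE; reason <- "abort"
    }
    toward_cue <- choice_side == cue_side
    correct <- if (trial_type == "pro") toward_cue else !toward_cue
  }
  trials(participant = participant, experiment = experiment,
         trial_type = trial_type, cue_side = cue_side,
         gap = gap_canon, rt = max(rt, 0), choice_side = choice_side,
         correct = correct, excluded = excluded, exclusion_reason = reason)
}
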