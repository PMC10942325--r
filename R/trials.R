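#' @keywords internal
"_PACKAGE"

GAP_SET <- c(-200, -100, 0, 75, 100, 125, 150, 175, 200, 250, 350)
SIDES <- c("left", "right")
TRIAL_TYPES <- c("pro", "anti")
EXCLUSION_REASONS <- c("none", "abort", "blink", "near_vertical")

CANONICAL_COLS <- c("participant", "experiment", "trial_type", "cue_side",
                    "gap", "rt", "choice_side", "correct", "excluded",
                    "exclusion_reason")

#' Construct a canonical trial table
#'
#' One row per completed urgent-choice trial. `rpt` is always recomputed as
#' `rt - gap`; the raw processing time is definitional, so a stored value
#' is never trusted over the recomputation. `correct` must agree with the
#' task rule: a pro trial is correct when the saccade lands on the cue
#' side, an anti trial when it lands on the opposite side.
#'
#' @param participant Character vector of participant ids.
#' @param experiment Integer in 1..4 (the four luminance conditions).
#' @param trial_type `"pro"` or `"anti"`.
#' @param cue_side,choice_side `"left"` or `"right"`.
#' @param gap Gap duration in ms; one of the task's 11 values
#'   (-200, -100, 0, 75, 100, 125, 150, 175, 200, 250, 350).
#' @param rt Reaction time in ms (go signal to saccade onset), `>= 0`.
#' @param correct Logical; checked against the task rule.
#' @param excluded Logical; excluded trials never enter an analysis.
#' @param exclusion_reason One of `"none"`, `"abort"`, `"blink"`,
#'   `"near_vertical"`.
#' @param check Validate invariants (default `TRUE`).
#' @return A `data.frame` of class `tachy_trials` with an additional
#'   `rpt = rt - gap` column.
#' @examples
#' trials(participant = "P1", experiment = 1, trial_type = "pro",
#'        cue_side = "left", gap = 100, rt = 300, choice_side = "left",
#'        correct = TRUE)
#' @export
trials <- function(participant, experiment, trial_type, cue_side, gap, rt,
                   choice_side, correct,
                   excluded = FALSE, exclusion_reason = "none",
                   check = TRUE) {
  n <- length(rt)
  excluded <- rep_len(excluded, n)
  exclusion_reason <- rep_len(exclusion_reason, n)
  df <- data.frame(
    participant = as.character(participant),
    experiment = as.integer(experiment),
    trial_type = as.character(trial_type),
    cue_side = as.character(cue_side),
    gap = as.numeric(gap),
    rt = as.numeric(rt),
    rpt = as.numeric(rt) - as.numeric(gap),
    choice_side = as.character(choice_side),
    correct = as.logical(correct),
    excluded = as.logical(excluded),
    exclusion_reason = as.character(exclusion_reason),
    stringsAsFactors = FALSE
  )
  class(df) <- c("tachy_trials", "data.frame")
  if (check) validate_trials(df)
  df
}

#' Validate a trial table against its invariants
#'
#' Checks the enumerated fields, the gap set, `rpt = rt - gap`, and the
#' correctness rule `correct == (choice toward cue) xor (anti trial)`.
#'
#' @param x A `tachy_trials` table (or plain data.frame with the columns).
#' @return `x`, invisibly; stops with a descriptive error on violation.
#' @export
validate_trials <- function(x) {
  miss <- setdiff(c(CANONICAL_COLS, "rpt"), names(x))
  if (length(miss)) stop("missing trial columns: ", paste(miss, collapse = ", "))
  if (nrow(x) == 0) return(invisible(x))
  bad <- function(cond, what) {
    if (any(cond)) {
      stop(sprintf("invalid %s in rows: %s", what,
                   paste(utils::head(which(cond), 5), collapse = ", ")))
    }
  }
  bad(!(x$experiment %in% 1:4), "experiment")
  bad(!(x$trial_type %in% TRIAL_TYPES), "trial_type")
  bad(!(x$cue_side %in% SIDES), "cue_side")
  bad(!(x$choice_side %in% SIDES), "choice_side")
  bad(!(x$gap %in% GAP_SET), "gap (outside permitted set)")
  bad(!is.finite(x$rt) | x$rt < 0, "rt")
  bad(abs(x$rpt - (x$rt - x$gap)) > 0.5, "rpt (rt - gap mismatch > 0.5 ms)")
  bad(!(x$exclusion_reason %in% EXCLUSION_REASONS), "exclusion_reason")
  toward_cue <- x$choice_side == x$cue_side
  expect_correct <- ifelse(x$trial_type == "pro", toward_cue, !toward_cue)
  bad(!is.na(x$correct) & x$correct != expect_correct,
      "correct (inconsistent with task rule)")
  invisible(x)
}

#' Read trials from a canonical CSV file
#'
#' The canonical dialect has the header
#' `participant,experiment,trial_type,cue_side,gap,rt,choice_side,correct,excluded,exclusion_reason`
#' (an `rpt` column may be present and is checked, but the recomputation
#' `rpt = rt - gap` is authoritative). External files with other column
#' names can be mapped onto the schema through `col_map`.
#'
#' Malformed rows (unparseable numbers, out-of-range enums, rule
#' violations) are dropped and reported; the returned table carries the
#' per-line messages in `attr(, "parse_errors")`.
#'
#' @param path CSV file path.
#' @param col_map Optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(participant = "subj_id")`.
#' @return A validated `tachy_trials` table.
#' @export
read_trials <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(raw)) {
        stop("col_map names absent column: ", col_map[[canon]])
      }
      names(raw)[names(raw) == col_map[[canon]]] <- canon
    }
  }
  miss <- setdiff(CANONICAL_COLS, names(raw))
  if (length(miss)) {
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "))
  }

  n <- nrow(raw)
  errs <- character(0)
  note <- function(i, msg) sprintf("line %d: %s", i + 1L, msg)  # +1 = header

  gap <- suppressWarnings(as.numeric(raw$gap))
  rt <- suppressWarnings(as.numeric(raw$rt))
  correct <- parse_logical(raw$correct)
  excluded <- parse_logical(raw$excluded)
  experiment <- suppressWarnings(as.integer(raw$experiment))

  ok <- rep(TRUE, n)
  flag <- function(cond, msg) {
    cond <- which(cond & ok)
    errs <<- c(errs, vapply(cond, note, "", msg = msg))
    ok[cond] <<- FALSE
  }
  flag(is.na(gap) | !(gap %in% GAP_SET), "bad gap value")
  flag(is.na(rt) | rt < 0, "bad rt value")
  flag(is.na(correct), "bad correct flag")
  flag(is.na(excluded), "bad excluded flag")
  flag(is.na(experiment) | !(experiment %in% 1:4), "bad experiment")
  flag(!(raw$trial_type %in% TRIAL_TYPES), "bad trial_type")
  flag(!(raw$cue_side %in% SIDES), "bad cue_side")
  flag(!(raw$choice_side %in% SIDES), "bad choice_side")
  flag(!(raw$exclusion_reason %in% EXCLUSION_REASONS), "bad exclusion_reason")
  toward_cue <- raw$choice_side == raw$cue_side
  expect_correct <- ifelse(raw$trial_type == "pro", toward_cue, !toward_cue)
  flag(!is.na(correct) & correct != expect_correct,
       "correct flag contradicts task rule")
  if ("rpt" %in% names(raw)) {
    stored <- suppressWarnings(as.numeric(raw$rpt))
    bad_rpt <- !is.na(stored) & abs(stored - (rt - gap)) > 0.5
    if (any(bad_rpt & ok)) {
      stop("integrity error: stored rpt deviates from rt - gap by > 0.5 ms ",
           "at line(s) ", paste(utils::head(which(bad_rpt & ok) + 1L, 5),
                                collapse = ", "))
    }
  }

  keep <- which(ok)
  out <- trials(
    participant = raw$participant[keep],
    experiment = experiment[keep],
    trial_type = raw$trial_type[keep],
    cue_side = raw$cue_side[keep],
    gap = gap[keep],
    rt = rt[keep],
    choice_side = raw$choice_side[keep],
    correct = correct[keep],
    excluded = excluded[keep],
    exclusion_reason = raw$exclusion_reason[keep]
  )
  attr(out, "parse_errors") <- errs
  tachy_log("read", "%d rows read, %d kept, %d malformed", n, length(keep),
            length(errs))
  out
}

parse_logical <- function(x) {
  lx <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Write trials to the canonical CSV dialect
#'
#' Round-trips bit-exactly with [read_trials()] for the canonical columns.
#'
#' @param x A `tachy_trials` table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(x, path) {
  validate_trials(x)
  cols <- c(CANONICAL_COLS[1:6], "rpt", CANONICAL_COLS[7:10])
  utils::write.csv(as.data.frame(x)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Trial selection filter
#'
#' A declarative description of which trials an analysis uses. Applying a
#' filter never mutates records; it only selects. Records with
#' `excluded = TRUE` are always dropped.
#'
#' @param urgency `"urgent_only"` (gap >= 0), `"easy_only"` (gap < 0) or
#'   `"all"`.
#' @param rpt_min,rpt_max Optional inclusive rPT bounds in ms.
#' @param trial_types Subset of `c("pro", "anti")`.
#' @param experiments Subset of `1:4`.
#' @param participants `NULL` (all) or a character vector of ids.
#' @return A `tachy_filter` object.
#' @export
trial_filter <- function(urgency = c("urgent_only", "easy_only", "all"),
                         rpt_min = NULL, rpt_max = NULL,
                         trial_types = TRIAL_TYPES,
                         experiments = 1:4,
                         participants = NULL) {
  urgency <- match.arg(urgency)
  stopifnot(all(trial_types %in% TRIAL_TYPES), all(experiments %in% 1:4))
  structure(list(urgency = urgency, rpt_min = rpt_min, rpt_max = rpt_max,
                 trial_types = trial_types,
                 experiments = as.integer(experiments),
                 participants = participants),
            class = "tachy_filter")
}

#' Apply a trial filter
#'
#' @param x A `tachy_trials` table.
#' @param f A [trial_filter()].
#' @return The selected rows, order preserved.
#' @export
apply_filter <- function(x, f = trial_filter()) {
  stopifnot(inherits(f, "tachy_filter"))
  keep <- !x$excluded
  keep <- keep & switch(f$urgency,
                        urgent_only = x$gap >= 0,
                        easy_only = x$gap < 0,
                        all = TRUE)
  if (!is.null(f$rpt_min)) keep <- keep & x$rpt >= f$rpt_min
  if (!is.null(f$rpt_max)) keep <- keep & x$rpt <= f$rpt_max
  keep <- keep & x$trial_type %in% f$trial_types
  keep <- keep & x$experiment %in% f$experiments
  if (!is.null(f$participants)) keep <- keep & x$participant %in% f$participants
  out <- x[keep, , drop = FALSE]
  tachy_log("filter", "%d of %d trials selected", nrow(out), nrow(x))
  out
}

#' @export
print.tachy_trials <- function(x, ...) {
  cat(sprintf("<tachy_trials> %d trials, %d participants, experiments {%s}\n",
              nrow(x), length(unique(x$participant)),
              paste(sort(unique(x$experiment)), collapse = ",")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}
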