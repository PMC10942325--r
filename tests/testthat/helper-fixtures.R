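# Hand-constructable trial tables for unit tests.

# A trial row where correctness is derived from the sides, so fixtures can
# never violate the task rule by accident.
make_trials <- function(rpt, correct, trial_type = "pro", cue_side = "left",
                        gap = 0, participant = "P1", experiment = 1L,
                        excluded = FALSE, exclusion_reason = "none") {
  n <- length(rpt)
  trial_type <- rep_len(trial_type, n)
  cue_side <- rep_len(cue_side, n)
  gap <- rep_len(gap, n)
  correct <- rep_len(correct, n)
  target <- ifelse(trial_type == "pro", cue_side,
                   ifelse(cue_side == "left", "right", "left"))
  choice <- ifelse(correct, target, ifelse(target == "left", "right", "left"))
  trials(participant = rep_len(participant, n),
         experiment = rep_len(experiment, n),
         trial_type = trial_type, cue_side = cue_side,
         gap = gap, rt = rpt + gap, choice_side = choice,
         correct = as.logical(correct),
         excluded = rep_len(excluded, n),
         exclusion_reason = rep_len(exclusion_reason, n))
}

# Brute-force tachometric bin count: the independent oracle for the
# sliding-bin machinery.
brute_bin <- function(rpt, correct, center, width) {
  inb <- abs(rpt - center) <= width / 2
  c(n = sum(inb), k = sum(correct[inb]))
}
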