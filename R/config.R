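#' Analysis configuration
#'
#' Bundles every tunable parameter of the pipeline in one validated list.
#' The defaults reproduce the canonical analysis settings: sliding rPT bins
#' stepped every 1 ms, 31 ms wide for aggregate curves (41 ms for single
#' participants), a 0.7 accuracy criterion, a modulation-to-error ratio
#' gate of 2.5 for accepting sigmoid fits, the fixed exogenous-capture
#' window of 83-124 ms, a guessing range of rPT <= 75 ms, a transition
#' range of 135 <= rPT < 200 ms and an asymptotic range of rPT >= 200 ms.
#'
#' @param bin_width_aggregate Bin width (ms) for curves pooled across
#'   participants.
#' @param bin_width_single Bin width (ms) for single-participant curves.
#' @param bin_step Grid step (ms) between consecutive bin centers.
#' @param criterion_theta Accuracy criterion for `rpt_at_criterion()`.
#' @param performance_criterion Fraction correct that easy (gap < 0) trials
#'   must strictly exceed, in all 8 experiment x trial-type cells, for a
#'   participant to count as a reliable performer.
#' @param modulation_ratio_threshold Minimum delta_s / e ratio for a
#'   sigmoid fit to qualify.
#' @param capture_window Closed rPT interval (ms) used to quantify
#'   exogenous capture.
#' @param guessing_max_rpt Upper (inclusive) rPT bound of the guessing
#'   range, ms.
#' @param transition_range rPT interval of the transition range,
#'   inclusive at the lower bound and exclusive at the upper bound.
#' @param asymptotic_min_rpt Lower (inclusive) rPT bound of the asymptotic
#'   range, ms.
#' @param fit_rpt_range rPT interval (ms) over which sigmoid fits and their
#'   quality metrics are evaluated.
#' @param ci_level Confidence level for binomial intervals.
#' @param n_bootstrap Number of bootstrap replicates for fit CIs.
#' @param n_permutations Number of Monte-Carlo iterations for permutation
#'   and randomization tests.
#' @param rng_seed Integer seed used by seeded operations when no explicit
#'   seed is supplied.
#' @return An object of class `tachy_config` (a named list).
#' @examples
#' cfg <- analysis_config()
#' cfg$capture_window
#' @export
analysis_config <- function(bin_width_aggregate = 31,
                            bin_width_single = 41,
                            bin_step = 1,
                            criterion_theta = 0.7,
                            performance_criterion = 0.7,
                            modulation_ratio_threshold = 2.5,
                            capture_window = c(83, 124),
                            guessing_max_rpt = 75,
                            transition_range = c(135, 200),
                            asymptotic_min_rpt = 200,
                            fit_rpt_range = c(0, 300),
                            ci_level = 0.95,
                            n_bootstrap = 1000,
                            n_permutations = 100000,
                            rng_seed = 1L) {
  cfg <- list(
    bin_width_aggregate = bin_width_aggregate,
    bin_width_single = bin_width_single,
    bin_step = bin_step,
    criterion_theta = criterion_theta,
    performance_criterion = performance_criterion,
    modulation_ratio_threshold = modulation_ratio_threshold,
    capture_window = as.numeric(capture_window),
    guessing_max_rpt = guessing_max_rpt,
    transition_range = as.numeric(transition_range),
    asymptotic_min_rpt = asymptotic_min_rpt,
    fit_rpt_range = as.numeric(fit_rpt_range),
    ci_level = ci_level,
    n_bootstrap = as.integer(n_bootstrap),
    n_permutations = as.integer(n_permutations),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  class(cfg) <- "tachy_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$bin_width_aggregate > 0, cfg$bin_width_single > 0, cfg$bin_step > 0,
    cfg$criterion_theta > 0, cfg$criterion_theta < 1,
    cfg$performance_criterion > 0, cfg$performance_criterion < 1,
    cfg$modulation_ratio_threshold > 0,
    length(cfg$capture_window) == 2,
    cfg$capture_window[1] < cfg$capture_window[2],
    length(cfg$transition_range) == 2,
    cfg$transition_range[1] < cfg$transition_range[2],
    length(cfg$fit_rpt_range) == 2,
    cfg$fit_rpt_range[1] < cfg$fit_rpt_range[2],
    cfg$ci_level > 0, cfg$ci_level < 1,
    cfg$n_bootstrap >= 1, cfg$n_permutations >= 1
  )
  invisible(cfg)
}

#' Read an analysis configuration from a YAML or JSON file
#'
#' The file holds a subset of `analysis_config()` argument names; unnamed
#' parameters keep their defaults. Entries named by CLI flags always
#' override the file (handled by the CLI layer).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `tachy_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  }
  do.call(analysis_config, vals)
}

#' @export
print.tachy_config <- function(x, ...) {
  cat("<tachy_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-26s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

# Internal structured logger: per-stage record counts etc.  Quiet unless
# options(tachycurve.verbose = TRUE).
tachy_log <- function(stage, ...) {
  if (isTRUE(getOption("tachycurve.verbose", FALSE))) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  invisible(NULL)
}
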