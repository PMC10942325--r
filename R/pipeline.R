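#' Run the full chronometric analysis pipeline
#'
#' Orchestrates the stages end-to-end: load (or simulate) trials, filter
#' to urgent trials, build pro and anti tachometric curves, fit sigmoids,
#' compute the headline metrics (rise points, rPT at criterion,
#' antisaccade cost, motor bias, guessing bias, capture fractions, range
#' summary) and write every artefact plus a run manifest to `out_dir`.
#' Identical inputs, config and seed give byte-identical outputs.
#'
#' @param trials_path Canonical trial CSV to analyse; `NULL` to simulate.
#' @param out_dir Output directory (created if needed).
#' @param config An [analysis_config()].
#' @param simulate When `trials_path` is `NULL`: a list with elements
#'   `n`, `experiment`, `params` ([generative_params()]) and `seed`.
#' @param bright Luminance condition for the capture symmetry test; see
#'   [capture_fraction()].
#' @return A `run_manifest` list (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(trials_path = NULL, out_dir, config = analysis_config(),
                         simulate = NULL, bright = "none") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  if (is.null(trials_path)) {
    sim <- utils::modifyList(
      list(n = 5000, experiment = 1, params = generative_params(),
           seed = config$rng_seed),
      simulate %||% list()
    )
    tr <- generate_trials(sim$params, n = sim$n, experiment = sim$experiment,
                          seed = sim$seed)
    trials_path <- file.path(out_dir, "trials.csv")
    write_trials(tr, trials_path)
    paths$trials <- trials_path
    tachy_log("simulate", "%d trials written to %s", nrow(tr), trials_path)
  } else {
    if (!file.exists(trials_path)) {
      stop("stage 'load': input path not found: ", trials_path)
    }
    tr <- read_trials(trials_path)
  }

  urgent <- apply_filter(tr, trial_filter(urgency = "urgent_only"))
  if (nrow(urgent) == 0) stop("stage 'filter': no urgent trials")

  fits <- list(); curves <- list()
  for (tt in TRIAL_TYPES) {
    sub <- urgent[urgent$trial_type == tt, , drop = FALSE]
    cv <- compute_curve(sub, bin_width = config$bin_width_aggregate,
                        bin_step = config$bin_step,
                        grid = config$fit_rpt_range,
                        ci_level = config$ci_level)
    curves[[tt]] <- cv
    paths[[paste0("curve_", tt)]] <- file.path(out_dir,
                                               paste0("curve_", tt, ".csv"))
    write_curve(cv, paths[[paste0("curve_", tt)]])
    fits[[tt]] <- tryCatch(
      fit_sigmoid(cv, range = config$fit_rpt_range, seed = config$rng_seed),
      error = function(e) stop("stage 'fit' (", tt, "): ",
                               conditionMessage(e))
    )
  }

  cost <- tryCatch(
    antisaccade_cost(fits$pro, fits$anti, require_gate = FALSE),
    error = function(e) NULL
  )
  gb <- guess_bias(urgent, max_rpt = config$guessing_max_rpt,
                   ci_level = config$ci_level)
  cap <- capture_fraction(urgent, window = config$capture_window,
                          bright = bright, ci_level = config$ci_level,
                          seed = config$rng_seed)
  rs <- range_summary(urgent, config)
  paths$ranges <- file.path(out_dir, "range_summary.csv")
  utils::write.csv(rs, paths$ranges, row.names = FALSE, quote = FALSE)

  report <- list(
    n_trials = nrow(tr), n_urgent = nrow(urgent),
    fit_pro = fits$pro[c("A", "B", "C", "D", "mae")],
    fit_anti = fits$anti[c("A", "B", "C", "D", "mae")],
    quality_pro = fits$pro$quality, quality_anti = fits$anti$quality,
    rise_point_pro = rise_point(fits$pro),
    rise_point_anti = rise_point(fits$anti),
    rise_point_difference = rise_point(fits$anti) - rise_point(fits$pro),
    rpt_at_criterion_pro = rpt_at_criterion(fits$pro, config$criterion_theta),
    rpt_at_criterion_anti = rpt_at_criterion(fits$anti, config$criterion_theta),
    antisaccade_cost = if (!is.null(cost)) cost$delta_rpt else NA_real_,
    motor_bias = if (!is.null(cost)) cost$delta_bias else NA_real_,
    guess_bias = unclass(gb),
    capture = unclass(cap)
  )
  paths$report <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("tachycurve")),
    config = unclass(config),
    seed = config$rng_seed,
    input = trials_path,
    input_md5 = unname(tools::md5sum(trials_path)),
    outputs = paths
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  manifest$outputs <- paths
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  class(manifest) <- "run_manifest"
  invisible(manifest)
}
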