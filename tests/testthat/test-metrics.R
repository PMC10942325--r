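mirror_pair <- function(frac_pro, grid = 50:200) {
  # build an exactly mirrored pro/anti curve pair on a shared grid
  mk <- function(fr) {
    structure(data.frame(center = grid, n_total = 100,
                         n_correct = round(fr * 100), frac_correct = fr,
                         ci_low = NA, ci_high = NA),
              class = c("tachometric_curve", "data.frame"))
  }
  list(pro = mk(frac_pro), anti = mk(1 - frac_pro))
}

test_that("derive_capture_window recovers a constructed window exactly", {
  grid <- 50:200
  # deviation from chance only inside (80, 126): curves cross 0.5 at the
  # boundary samples
  bump <- ifelse(grid > 80 & grid < 126,
                 0.3 * sin(pi * (grid - 80) / 46), 0)
  pair <- mirror_pair(0.5 + bump)
  w <- derive_capture_window(pair$pro, pair$anti)
  expect_equal(w, c(81, 125))

  # flat curves at chance -> no window
  flat <- mirror_pair(rep(0.5, length(grid)))
  expect_message(w0 <- derive_capture_window(flat$pro, flat$anti),
                 "no consistent deviation")
  expect_null(w0)
})

test_that("derive_capture_window brackets a planted capture bump", {
  p <- generative_params()
  win <- lapply(c(3, 4), function(ex) {
    tr <- generate_trials(p, n = 20000, experiment = ex, seed = ex)
    u <- apply_filter(tr, trial_filter(urgency = "urgent_only"))
    list(pro = compute_curve(u[u$trial_type == "pro", ], 31),
         anti = compute_curve(u[u$trial_type == "anti", ], 31))
  })
  w <- derive_capture_window(pairs = win)
  expect_false(is.null(w))
  expect_lt(w[1], p$capture_center)
  expect_gt(w[2], p$capture_center)
})

test_that("capture_fraction tallies by hand and respects the closed window", {
  tr <- make_trials(rpt = c(83, 90, 100, 124, 124.5, 82.9, 110, 120),
                    correct = c(1, 1, 0, 1, 1, 0, 0, 1),
                    trial_type = c("pro", "pro", "pro", "pro",
                                   "pro", "anti", "anti", "anti"))
  res <- capture_fraction(tr, window = c(83, 124))
  # in-window pro: 83, 90, 100, 124 (124.5 out) -> 3/4 correct
  expect_equal(res$n_pro, 4)
  expect_equal(res$frac_correct_pro, 0.75)
  # in-window anti: 110, 120 (82.9 out) -> 1/2 correct
  expect_equal(res$n_anti, 2)
  expect_equal(res$frac_correct_anti, 0.5)

  # saturated capture: all pro correct, all anti incorrect
  sat <- make_trials(rpt = rep(100, 40), correct = rep(c(TRUE, FALSE), 20),
                     trial_type = rep(c("pro", "anti"), 20))
  res2 <- capture_fraction(sat)
  expect_equal(res2$frac_correct_pro, 1)
  expect_equal(res2$frac_correct_anti, 0)
})

test_that("planted capture is symmetric between pro and anti", {
  tr <- generate_trials(generative_params(), n = 20000, experiment = 3,
                        seed = 17)
  u <- apply_filter(tr, trial_filter(urgency = "urgent_only"))
  res <- capture_fraction(u, bright = "cue", n_iter = 2000, seed = 1)
  expect_gt(res$frac_correct_pro, 0.5)
  expect_lt(res$frac_correct_anti, 0.5)
  dev_pro <- res$frac_correct_pro - 0.5
  dev_anti <- 0.5 - res$frac_correct_anti
  se <- sqrt(0.25 / res$n_pro + 0.25 / res$n_anti)
  expect_lt(abs(dev_pro - dev_anti), 3 * se)
  expect_gt(res$symmetry_p, 0.001)
})

test_that("guess_bias counts choices toward the cue regardless of type", {
  # 6-trial hand tally: pro-correct and anti-incorrect both go toward cue
  tr <- make_trials(rpt = rep(60, 6),
                    correct = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
                    trial_type = c("pro", "pro", "pro", "anti", "anti",
                                   "anti"))
  # toward cue: pro & correct (2) + anti & !correct (2) = 4 of 6
  gb <- guess_bias(tr, max_rpt = 75)
  expect_equal(gb$n_toward_cue, 4)
  expect_equal(gb$n_toward_noncue, 2)
  expect_equal(gb$frac_toward_cue, 2 / 3)

  # bound is inclusive at 75 ms and trials above are ignored
  tr2 <- make_trials(rpt = c(75, 76), correct = c(TRUE, TRUE))
  expect_equal(guess_bias(tr2)$n_toward_cue + guess_bias(tr2)$n_toward_noncue,
               1)

  # paper-scale pooled counts reproduce the published fraction
  expect_equal(9015 / (9015 + 7154), 0.5575, tolerance = 5e-4)

  # equal counts -> 0.5
  bal <- make_trials(rpt = rep(50, 10), correct = rep(c(TRUE, FALSE), 5))
  expect_equal(guess_bias(bal)$frac_toward_cue, 0.5)
})

test_that("guess_bias is unbiased when the planted bias is 0.5", {
  tr <- generate_trials(generative_params(baseline_bias = 0.5), n = 8000,
                        seed = 23)
  gb <- guess_bias(apply_filter(tr, trial_filter(urgency = "urgent_only")))
  expect_gte(0.5, gb$ci[1])
  expect_lte(0.5, gb$ci[2])
})

test_that("antisaccade_cost combines fits per the shared-criterion rule", {
  mk_fit <- function(p) {
    f <- structure(list(A = p[1], B = p[2], C = p[3], D = p[4], mae = 0,
                        range = c(0, 300), convergence = 0L,
                        quality = list(delta_s = p[1] - p[2], e = 1e-3,
                                       ratio = 1e3, passes = TRUE)),
                   class = "sigmoid_fit")
    f
  }
  pro <- mk_fit(c(0.95, 0.60, 165, 20))
  anti <- mk_fit(c(0.95, 0.40, 195, 20))
  res <- antisaccade_cost(pro, anti)
  expect_equal(res$criterion_level, 0.775)  # max halfway value (pro)
  expect_equal(res$delta_bias, 0.20)
  # closed-form logistic inverse oracle
  inv <- function(p, th) p[3] + p[4] * log((th - p[2]) / (p[1] - th))
  expect_equal(res$delta_rpt,
               inv(c(0.95, 0.40, 195, 20), 0.775) -
                 inv(c(0.95, 0.60, 165, 20), 0.775), tolerance = 1e-9)

  # identical fits -> zero cost and zero bias
  same <- antisaccade_cost(pro, pro)
  expect_equal(same$delta_rpt, 0)
  expect_equal(same$delta_bias, 0)

  # criterion above one curve's asymptote -> undefined cost
  low_anti <- mk_fit(c(0.60, 0.40, 195, 20))
  res3 <- antisaccade_cost(pro, low_anti)
  expect_true(is.na(res3$delta_rpt))

  # gate enforcement
  bad <- mk_fit(c(0.55, 0.50, 165, 20))
  bad$quality$passes <- FALSE
  expect_error(antisaccade_cost(pro, bad), "modulation gate")
})

test_that("range assignment and summary match a hand tally", {
  expect_equal(rpt_range(c(75, 80, 83, 124, 130, 135, 199.5, 200, 60)),
               c("G", NA, "C", "C", NA, "T", "T", "A", "G"))

  rpts <- c(60, 70, 90, 100, 150, 180, 220, 250, 80, 130, 199, 200)
  tr <- make_trials(rpt = rpts,
                    correct = c(1, 0, 1, 1, 0, 1, 1, 1, 1, 0, 1, 0),
                    trial_type = rep(c("pro", "anti"), 6))
  rs <- range_summary(tr)
  get <- function(tt, r) rs[rs$trial_type == tt & rs$range == r, ]
  # hand tally: pro trials at 60(G,1), 90(C,1), 150(T,0), 220(A,1),
  #             80(none), 199(T,1); anti at 70(G,0), 100(C,1), 180(T,1),
  #             250(A,1), 130(none), 200(A,0)
  expect_equal(get("pro", "G")$n, 1)
  expect_equal(get("pro", "T")$frac_correct, 0.5)
  expect_equal(get("anti", "A")$n, 2)
  expect_equal(get("anti", "A")$frac_correct, 0.5)
  expect_equal(sum(rs$n), 10)  # 80 and 130 fall in no range

  # trials only at 150 populate only the T cell
  only_t <- range_summary(make_trials(rpt = rep(150, 5), correct = TRUE))
  expect_equal(unique(only_t$range), "T")
})

test_that("range_bias_cost yields per-participant G and T differences", {
  tr <- rbind(
    make_trials(rpt = c(60, 150), correct = c(TRUE, TRUE),
                trial_type = "pro", participant = "P1"),
    make_trials(rpt = c(60, 150), correct = c(FALSE, FALSE),
                trial_type = "anti", participant = "P1")
  )
  bc <- range_bias_cost(tr)
  expect_equal(bc$diff_G[bc$participant == "P1"], 1)
  expect_equal(bc$diff_T[bc$participant == "P1"], 1)
})

test_that("reliable performers are those above 0.7 in all 8 easy cells", {
  set.seed(3)
  mk_easy <- function(pid, acc) {
    do.call(rbind, lapply(1:4, function(ex) {
      make_trials(rpt = runif(40, 300, 500), correct = runif(40) < acc,
                  trial_type = rep(c("pro", "anti"), 20), gap = -100,
                  participant = pid, experiment = ex)
    }))
  }
  tr <- rbind(mk_easy("GOOD", 0.95), mk_easy("BAD", 0.55))
  rp <- reliable_performers(tr)
  expect_true("GOOD" %in% rp)
  expect_false("BAD" %in% rp)
})
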