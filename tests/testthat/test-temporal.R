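two_cycle_events <- function() {
  tibble::tibble(cycle = rep(1:2, each = 3),
                 label = rep(c("TO", "MSV", "HS"), 2),
                 time_s = c(0.10, 0.30, 0.60, 1.12, 1.32, 1.62))
}

test_that("swing, stance and stride follow the event-difference definitions", {
  st <- stride_intervals(two_cycle_events())
  expect_equal(st$duration_s[st$metric == "swing"], c(0.50, 0.50))
  expect_equal(st$duration_s[st$metric == "stance"], 0.52)  # TO(2) - HS(1)
  expect_equal(st$duration_s[st$metric == "stride"], 1.02)  # MSV(2) - MSV(1)
  # counts: k swings, k-1 stances and strides
  expect_equal(sum(st$metric == "swing"), 2)
  expect_equal(sum(st$metric == "stance"), 1)
  expect_equal(sum(st$metric == "stride"), 1)
})

test_that("ordering violations and incomplete series raise invalid-events errors", {
  bad <- two_cycle_events()
  bad$time_s[2] <- 0.05   # MSV before TO
  expect_error(stride_intervals(bad), class = "gaitcog_invalid_events")
  one_cycle <- two_cycle_events()[1:3, ]
  expect_error(stride_intervals(one_cycle), class = "gaitcog_invalid_events")
})

test_that("stride telescopes to swing + stance within two sample periods", {
  for (seed in 1:3) {
    ppl <- walk_through_pipeline(noise_free_params(stride_jitter_cov = 4), seed)
    st <- stride_intervals(ppl$events)
    wide <- tidyr::pivot_wider(st, names_from = "metric",
                               values_from = "duration_s")
    ok <- stats::complete.cases(wide[c("swing", "stance", "stride")])
    gap <- abs(wide$stride[ok] - (wide$swing[ok] + wide$stance[ok]))
    expect_lte(max(gap), 2 / 200)
  }
})

test_that("the 2-SD rule matches hand arithmetic on a known series", {
  tbl <- tibble::tibble(metric = "stride", cycle = 1:10,
                        duration_s = c(rep(1, 9), 3))
  out <- remove_turn_artifact(tbl)
  # mean 1.2, sample SD 0.6325; only the 3.0 deviates (2.85 SD)
  expect_equal(sum(out$removed), 1)
  expect_true(out$removed[out$duration_s == 3])
  expect_equal(mean(out$duration_s[!out$removed]), 1.0)
  expect_equal(out$reason[out$removed], "turn_outlier")
})

test_that("an all-equal series and short series produce no removals", {
  flat <- tibble::tibble(metric = "stride", cycle = 1:5, duration_s = rep(1, 5))
  expect_equal(sum(remove_turn_artifact(flat)$removed), 0)
  short <- tibble::tibble(metric = "stride", cycle = 1:2, duration_s = c(1, 2))
  expect_warning(out <- remove_turn_artifact(short))
  expect_equal(sum(out$removed), 0)
})

test_that("turn removal discards at most 10% of strides on realistic walks", {
  for (seed in 1:5) {
    w <- simulate_walk(stride_params(stride_jitter_cov = 5), seed = seed)
    st <- remove_turn_artifact(stride_intervals(w$truth$events))
    frac <- mean(st$removed[st$metric == "stride"])
    expect_lte(frac, 0.10)
  }
})

test_that("velocity and CoV equal their closed forms", {
  expect_equal(walk_velocity(20), 1.0)
  expect_equal(walk_velocity(10), 2.0)
  expect_equal(round(walk_velocity(14.8), 2), 1.35)
  expect_error(walk_velocity(0), class = "gaitcog_invalid_parameter")

  expect_equal(stride_cov(c(0.9, 1.0, 1.1)), 10, tolerance = 1e-12)
  expect_equal(stride_cov(rep(1.3, 5)), 0)
  expect_error(stride_cov(1), class = "gaitcog_invalid_parameter")
  expect_error(stride_cov(c(-1, 1)), class = "gaitcog_invalid_parameter")

  # brute-force recomputation to 1e-12 on a fixed series
  x <- c(1.01, 0.98, 1.07, 1.00, 0.95)
  manual <- 100 * sqrt(sum((x - mean(x))^2) / (length(x) - 1)) / mean(x)
  expect_equal(stride_cov(x), manual, tolerance = 1e-12)
  expect_equal(walk_velocity(sum(x)), 20 / sum(x), tolerance = 1e-12)
})

test_that("walk summaries agree with generator ground truth", {
  ppl <- walk_through_pipeline(noise_free_params(), seed = 4)
  truth <- ppl$walk$truth
  s <- suppressWarnings(summarize_walk(ppl$clean, ppl$events))
  expect_equal(s$stride_s, mean(truth$stride_s), tolerance = 0.01)
  true_swing <- ppl$walk$params$swing_s * truth$cycle_s /
    (ppl$walk$params$swing_s + ppl$walk$params$stance_s)
  expect_equal(s$swing_s, true_swing, tolerance = 0.01)
  expect_equal(s$n_removed, 1)   # the turn pseudo-stride

  # no turn, zero jitter: nothing to remove
  w <- simulate_walk(noise_free_params(), seed = 2, turn = FALSE)
  clean <- preprocess_recording(w$recording)
  s2 <- suppressWarnings(summarize_walk(clean, detect_gait_events(clean)))
  expect_equal(s2$n_removed, 0)
  # events-only time basis excludes lead-in padding, so velocity is higher
  s3 <- suppressWarnings(summarize_walk(clean, detect_gait_events(clean),
                                        time_basis = "events"))
  expect_gt(s3$velocity_mps, s2$velocity_mps)
})

test_that("a missing component fails the summary", {
  ppl <- walk_through_pipeline(noise_free_params(), seed = 4)
  expect_error(summarize_walk(NULL, ppl$events),
               class = "gaitcog_incomplete_summary")
})
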