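test_that("stride waveform has the expected morphology and exact event offsets", {
  p <- noise_free_params()
  w <- stride_waveform(p, fs = 200)
  expect_equal(nrow(w$template), round((p$swing_s + p$stance_s) * 200))
  expect_equal(w$cycle_s, 1.01)
  # offsets are ordered TO < MSV < HS inside the cycle
  ev <- setNames(w$events$offset_s, w$events$label)
  expect_true(ev[["TO"]] < ev[["MSV"]] && ev[["MSV"]] < ev[["HS"]])
  # noise-free: offsets coincide exactly with sampled template extrema
  expect_equal(ev[["MSV"]], w$template$time_s[which.max(w$template$signal)])
  before <- w$template[w$template$time_s < ev[["MSV"]], ]
  after <- w$template[w$template$time_s > ev[["MSV"]], ]
  expect_equal(ev[["TO"]], before$time_s[which.min(before$signal)])
  expect_equal(ev[["HS"]], after$time_s[which.min(after$signal)])
  # MSV is the single dominant positive peak
  expect_equal(sum(w$template$signal > 0.5 * max(w$template$signal)) > 0, TRUE)
})

test_that("invalid stride parameters and low sampling rates are refused", {
  expect_error(stride_params(swing_s = -0.1), class = "gaitcog_invalid_parameter")
  expect_error(stride_params(stance_s = 0), class = "gaitcog_invalid_parameter")
  expect_error(stride_params(noise_sd = -1), class = "gaitcog_invalid_parameter")
  expect_error(stride_waveform(stride_params(), fs = 40), class = "gaitcog_low_rate")
  expect_error(simulate_walk(stride_params(), fs = 30), class = "gaitcog_low_rate")
})

test_that("a jitter-free walk at 1 m/s covers 20 m in exactly 20 s of walking", {
  w <- simulate_walk(noise_free_params(velocity_mps = 1), seed = 1)
  expect_equal(sum(w$truth$stride_s), 20, tolerance = 1e-12)
  expect_equal(w$truth$velocity_mps, 1, tolerance = 1e-12)
})

test_that("walk simulation is deterministic under a fixed seed", {
  a <- simulate_walk(stride_params(), seed = 7)
  b <- simulate_walk(stride_params(), seed = 7)
  expect_identical(a$recording$signal, b$recording$signal)
  expect_identical(a$truth$events, b$truth$events)
})

test_that("ground-truth events are strictly ordered TO < MSV < HS per cycle", {
  for (seed in 1:5) {
    w <- simulate_walk(stride_params(stride_jitter_cov = 4), seed = seed)
    ev <- w$truth$events
    expect_true(all(diff(ev$time_s) > 0))
    wide <- tidyr::pivot_wider(ev, names_from = "label", values_from = "time_s")
    expect_true(all(wide$TO < wide$MSV & wide$MSV < wide$HS))
  }
})

test_that("the turn pseudo-stride is a >= 3 SD outlier in the stride series", {
  for (seed in 1:5) {
    w <- simulate_walk(stride_params(), seed = seed)
    st <- stride_intervals(w$truth$events)
    stride <- st$duration_s[st$metric == "stride"]
    dev <- abs(stride - mean(stride)) / sd(stride)
    turn_cycle <- unique(w$truth$events$cycle[w$truth$events$in_turn])
    expect_gte(dev[which(st$cycle[st$metric == "stride"] == turn_cycle)], 3)
  }
})

test_that("generator stride jitter reproduces the requested CoV", {
  # brute-force CoV over the pooled true stride lists of many walks
  strides <- unlist(lapply(1:30, function(s)
    simulate_walk(stride_params(stride_jitter_cov = 3), seed = s)$truth$stride_s))
  covs <- 100 * sd(strides) / mean(strides)
  expect_equal(covs, 3, tolerance = 0.35)
})

test_that("cohort generation is reproducible and respects the group design", {
  a <- simulate_cohort(cohort_config(n_control = 10, n_t2dm = 20), seed = 3)
  b <- simulate_cohort(cohort_config(n_control = 10, n_t2dm = 20), seed = 3)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$gait, b$gait)
  expect_equal(nrow(a$cohort), 30)
  expect_equal(nrow(a$gait), 30 * 6)
  expect_true(all(a$cohort$moca_total >= 0 & a$cohort$moca_total <= 30))
})

test_that("default calibration couples MoCA to normal-walk velocity moderately", {
  ch <- simulate_cohort(cohort_config(), seed = 11)
  v <- ch$gait |>
    dplyr::filter(task == "normal") |>
    dplyr::group_by(subject) |>
    dplyr::summarise(v = mean(velocity_mps))
  r <- cor(v$v[match(ch$cohort$subject, v$subject)], ch$cohort$moca_total)
  expect_gte(r, 0.3)
  expect_lte(r, 0.5)
  # T2DM walks slower on the normal task by about 0.23 m/s (left foot)
  gl <- ch$gait |>
    dplyr::filter(task == "normal", foot == "left") |>
    dplyr::group_by(group) |>
    dplyr::summarise(v = mean(velocity_mps))
  diffv <- gl$v[gl$group == "control"] - gl$v[gl$group == "t2dm"]
  expect_equal(diffv, 0.23, tolerance = 0.08)
})

test_that("zero linkage decouples cognition from gait", {
  ch <- simulate_cohort(cohort_config(linkage = 0), seed = 2)
  v <- ch$gait |>
    dplyr::filter(task == "normal") |>
    dplyr::group_by(subject) |>
    dplyr::summarise(v = mean(velocity_mps))
  r <- cor(v$v[match(ch$cohort$subject, v$subject)], ch$cohort$moca_total)
  expect_lt(abs(r), 0.2)
})

test_that("cohort config validation rejects bad designs", {
  expect_error(cohort_config(n_control = 0), class = "gaitcog_invalid_parameter")
  expect_error(cohort_config(residual_sd = 0), class = "gaitcog_invalid_parameter")
  bad <- cohort_config()$gait_profile
  bad$v_sd[1] <- -1
  expect_error(cohort_config(gait_profile = bad), class = "gaitcog_invalid_parameter")
})
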