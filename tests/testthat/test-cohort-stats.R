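test_that("identical groups show no difference; degenerate data errors", {
  set.seed(1)
  x <- rnorm(40)
  d <- tibble::tibble(v = c(x, x), group = rep(c("a", "b"), each = 40))
  res <- compare_groups(d, "v")
  expect_gt(res$p_value, 0.95)

  flat <- tibble::tibble(v = rep(1, 20), group = rep(c("a", "b"), each = 10))
  expect_error(compare_groups(flat, "v"), class = "gaitcog_range")
  tiny <- tibble::tibble(v = rnorm(4), group = c("a", "a", "b", "b"))
  expect_error(compare_groups(tiny, "v"), class = "gaitcog_range")
})

test_that("a one-SD shift is detected with near-certain power at the study sizes", {
  set.seed(42)
  hits <- vapply(1:100, function(i) {
    d <- tibble::tibble(v = c(rnorm(44, 0), rnorm(94, 1)),
                        group = rep(c("a", "b"), c(44, 94)))
    compare_groups(d, "v")$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.99)
})

test_that("skewed data routes to the Mann-Whitney branch", {
  set.seed(7)
  picks <- vapply(1:50, function(i) {
    d <- tibble::tibble(v = c(rexp(44), rexp(94)),
                        group = rep(c("a", "b"), c(44, 94)))
    compare_groups(d, "v")$test
  }, "")
  expect_gte(mean(picks == "mann-whitney"), 0.95)
})

test_that("the adjusted group effect has near-nominal CI coverage", {
  set.seed(33)
  truth <- -0.16
  covered <- vapply(1:200, function(i) {
    n <- 138
    g <- rep(c("control", "t2dm"), c(44, 94))
    d <- tibble::tibble(
      group = g, age = rnorm(n, 52, 8),
      sex = sample(c("female", "male"), n, replace = TRUE),
      bmi = rnorm(n, 29, 6), education_yr = rnorm(n, 17, 3),
      velocity = 1.35 + truth * (g == "t2dm") + rnorm(n, 0, 0.16)
    )
    eff <- adjusted_effect(d, "velocity")
    eff$conf.low <= truth && truth <= eff$conf.high
  }, TRUE)
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("a constant group indicator is not estimable", {
  d <- tibble::tibble(group = rep("a", 20), age = rnorm(20),
                      sex = rep("f", 20), bmi = rnorm(20),
                      education_yr = rnorm(20), v = rnorm(20))
  expect_error(adjusted_effect(d, "v"), class = "gaitcog_collinear")
})

test_that("screening matches the covariance-formula oracle and the threshold rule", {
  set.seed(3)
  d <- tibble::tibble(x = rnorm(50), z = rnorm(50))
  d$y <- d$x   # exact linear dependence
  sc <- screen_correlations(d, c("x", "z"), "y")
  expect_equal(sc$r[sc$gait_var == "x"], 1)
  expect_true(sc$selected[sc$gait_var == "x"])

  # direct covariance-formula recomputation
  r_manual <- sum((d$z - mean(d$z)) * (d$y - mean(d$y))) /
    sqrt(sum((d$z - mean(d$z))^2) * sum((d$y - mean(d$y))^2))
  expect_equal(sc$r[sc$gait_var == "z"], r_manual, tolerance = 1e-12)

  # sign symmetry: negation flips r, not selection
  d$negx <- -d$x
  sc2 <- screen_correlations(d, c("x", "negx"), "y")
  expect_equal(sc2$r[sc2$gait_var == "negx"], -sc2$r[sc2$gait_var == "x"])
  expect_equal(sc2$selected[sc2$gait_var == "negx"],
               sc2$selected[sc2$gait_var == "x"])
})

test_that("independent noise at n = 138 is almost never selected", {
  set.seed(11)
  sel <- vapply(1:100, function(i) {
    d <- tibble::tibble(x = rnorm(138), y = rnorm(138))
    screen_correlations(d, "x", "y")$selected
  }, TRUE)
  expect_gte(mean(!sel), 0.95)
})

test_that("constant columns are flagged degenerate, not selected", {
  d <- tibble::tibble(x = rep(1, 30), y = rnorm(30))
  sc <- screen_correlations(d, "x", "y")
  expect_true(sc$degenerate)
  expect_true(is.na(sc$r))
  expect_false(sc$selected)
  expect_error(screen_correlations(d[1:2, ], "x", "y"), class = "gaitcog_range")
})

test_that("the default cohort selects normal-walk velocity but not stride CoV", {
  w <- small_model_cohort(seed = 5)
  sc <- screen_correlations(
    w, c("velocity_mps_normal_left", "velocity_mps_normal_right",
         "cov_pct_normal_left", "cov_pct_normal_right"), "moca_total")
  expect_true(all(sc$selected[grepl("velocity", sc$gait_var)]))
  expect_false(any(sc$selected[grepl("cov_pct", sc$gait_var)]))
})
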