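test_that("standardization is exact, invertible and leakage-safe", {
  X <- tibble::tibble(a = c(0, 2, 4), b = c(10, 20, 60))
  std <- standardizer(X)
  Z <- zstandardize(X, std)
  expect_equal(unname(colMeans(Z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), c(1, 1), tolerance = 1e-12)
  back <- zstandardize(Z, std, invert = TRUE)
  expect_equal(unname(back), unname(as.matrix(X)), tolerance = 1e-12)
  expect_error(standardizer(tibble::tibble(a = rep(1, 5))),
               class = "gaitcog_invalid_parameter")
})

test_that("the linear model recovers noiseless generating coefficients exactly", {
  set.seed(8)
  d <- tibble::tibble(v1 = rnorm(50), v2 = rnorm(50), v3 = rnorm(50))
  d$moca_total <- 20 + 3 * d$v1 - 2 * d$v2 + 0.5 * d$v3
  fit <- fit_moca_mlr(d, c("v1", "v2", "v3"))
  est <- suppressWarnings(tidy(fit)$estimate)
  expect_equal(unname(est), c(20, 3, -2, 0.5), tolerance = 1e-9)
  expect_equal(predict(fit, d), d$moca_total, tolerance = 1e-9)
  expect_equal(suppressWarnings(glance(fit))$nobs, 50)

  d$v4 <- d$v1 + d$v2   # collinear
  expect_error(fit_moca_mlr(d, c("v1", "v2", "v4")), class = "gaitcog_collinear")
  expect_error(fit_moca_mlr(d[1:3, ], c("v1", "v2", "v3")), class = "gaitcog_range")
})

test_that("the fixed-coefficient predictor is linear and checks arity", {
  pred <- moca_predictor(c(a = 2, b = -1), intercept = 5)
  expect_equal(predict(pred, c(1, 1)), 6)
  expect_equal(predict(pred, c(0, 0)), 5)
  v1 <- c(1, 2); v2 <- c(3, -1)
  expect_equal(predict(pred, v1 + v2),
               predict(pred, v1) + predict(pred, v2) - 5)
  expect_error(predict(pred, c(1, 2, 3)), class = "gaitcog_invalid_parameter")
  # data-frame input uses named columns
  nd <- tibble::tibble(b = c(0, 1), a = c(1, 0))
  expect_equal(predict(pred, nd), c(7, 4))
})

test_that("the reference predictor reproduces its published intercept at zero input", {
  ref <- reference_moca_predictor()
  expect_identical(predict(ref, rep(0, 6)), 21.2)
  cf <- reference_moca_coefficients()
  expect_equal(nrow(cf), 7)
  expect_equal(cf$estimate[cf$term == "(Intercept)"], 21.2)
})

test_that("the network architecture descends by one node per layer", {
  spec <- build_nn(6)
  expect_equal(spec$widths, c(5, 4, 3, 2, 1))
  # weights+biases counted by hand: 6*5+5 + 5*4+4 + 4*3+3 + 3*2+2 + 2*1+1
  expect_equal(spec$n_params, 35 + 24 + 15 + 8 + 3)
  expect_equal(build_nn(2)$widths, 1)   # single output node after input
  expect_error(build_nn(1), class = "gaitcog_invalid_parameter")
  # closed-form count for any n
  for (n in 3:8) {
    widths <- seq(n - 1, 1)
    expect_equal(build_nn(n)$n_params,
                 sum(c(n, head(widths, -1)) * widths + widths))
  }
})

test_that("network training reduces loss, is seed-deterministic and stops early", {
  set.seed(2)
  n <- 80
  X <- matrix(rnorm(n * 3), n, 3)
  y <- stats::plogis(X %*% c(1, -1, 0.5))[, 1]
  spec <- build_nn(3)
  fit <- train_nn(spec, X, y, X, y, max_epochs = 500, seed = 4)
  w0 <- gaitcog:::nn_init(spec, seed = 4)
  fw0 <- gaitcog:::nn_forward(w0, X)
  loss0 <- mean((fw0[[length(fw0)]][, 1] - y)^2)
  expect_lt(fit$val_loss[fit$best_epoch], loss0)

  fit2 <- train_nn(spec, X, y, X, y, max_epochs = 500, seed = 4)
  expect_identical(fit$weights, fit2$weights)

  # pure-noise target: patience triggers long before the epoch cap
  stops <- vapply(1:3, function(s) {
    yn <- runif(n, 0.2, 0.8)
    idx <- 1:60
    train_nn(spec, X[idx, ], yn[idx], X[-idx, ], yn[-idx],
             max_epochs = 10000, patience = 50, seed = s)$epochs_run
  }, 0)
  expect_true(all(stops < 5000))
})

test_that("the cohort-level network wrapper round-trips score units", {
  w <- small_model_cohort(seed = 5)
  vel <- velocity_inputs(w)
  fit <- fit_moca_nn(w[1:110, ], vel, val_data = w[111:138, ],
                     max_epochs = 2000, seed = 3)
  pr <- predict(fit, w[111:138, ])
  expect_true(all(is.finite(pr)))
  # predictions land in score units, not (0, 1)
  expect_gt(mean(pr), 20)
  expect_lt(mean(abs(pr - w$moca_total[111:138])), 3)
  expect_equal(glance(fit)$n_params, 85)
})

test_that("hold-out validation reports zero error for a perfect model", {
  set.seed(6)
  d <- tibble::tibble(v1 = rnorm(60), v2 = rnorm(60))
  d$moca_total <- 24 + 2 * d$v1 - d$v2
  rep_ <- validate_model(d, c("v1", "v2"), model = "mlr", repeats = 5, seed = 1)
  expect_true(all(tidy(rep_)$mae < 1e-8))
})

test_that("validation MAE approaches the Gaussian mean absolute deviation", {
  set.seed(13)
  sigma <- 1.5
  d <- tibble::tibble(v1 = rnorm(150), v2 = rnorm(150))
  d$moca_total <- 24 + 2 * d$v1 - d$v2 + rnorm(150, 0, sigma)
  rep_ <- validate_model(d, c("v1", "v2"), model = "mlr", repeats = 20, seed = 2)
  expect_equal(rep_$mean_mae, sigma * sqrt(2 / pi), tolerance = 0.12)
})

test_that("validation is invariant to row order under a fixed seed", {
  w <- small_model_cohort(seed = 7, n_control = 20, n_t2dm = 40)
  vel <- velocity_inputs(w)
  a <- validate_model(w, vel, model = "mlr", repeats = 5, seed = 3)
  set.seed(99)
  b <- validate_model(w[sample.int(nrow(w)), ], vel, model = "mlr",
                      repeats = 5, seed = 3)
  expect_equal(a$mae$mae, b$mae$mae, tolerance = 1e-12)
})

test_that("paired MAE comparison yields the expected verdicts", {
  mk <- function(maes) structure(
    list(model = "mlr", mae = tibble::tibble(rep = seq_along(maes), mae = maes),
         mean_mae = mean(maes), repeats = length(maes)),
    class = "validation_report")
  a <- mk(c(1.2, 1.4, 1.3, 1.1, 1.25))
  expect_equal(compare_models(a, a)$mean_diff, 0)
  expect_equal(compare_models(a, a)$verdict, "ns")
  worse <- mk(c(1.2, 1.4, 1.3, 1.1, 1.25) + 1)
  cmp <- compare_models(worse, a)
  expect_equal(cmp$mean_diff, 1)
  expect_equal(cmp$verdict, "significant")
  expect_error(compare_models(a, mk(c(1, 2))), class = "gaitcog_invalid_parameter")
})
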