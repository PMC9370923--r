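# Predicting MoCA from gait velocities: multivariable linear regression
# and a descending-width sigmoid neural network, compared by mean absolute
# error under repeated 80/20 hold-out validation.

#' Fit a z-score standardizer
#'
#' Stores per-variable mean and SD (from the training data only, to avoid
#' leakage) for later application and inversion.
#'
#' @param data A data frame or matrix of numeric variables.
#' @return An object of class `standardizer` (`mu`, `sigma`).
#' @export
standardizer <- function(data) {
  X <- as.matrix(data)
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  if (any(sigma == 0))
    abort("Zero-variance variable; cannot standardize.",
          class = "gaitcog_invalid_parameter")
  structure(list(mu = mu, sigma = sigma), class = "standardizer")
}

#' Apply or invert a standardizer
#'
#' @param object A [standardizer()].
#' @param data Data with the same columns.
#' @param invert If `TRUE`, map z-scores back to the original scale.
#' @return A matrix of (de-)standardized values.
#' @export
zstandardize <- function(data, object, invert = FALSE) {
  X <- as.matrix(data)[, names(object$mu), drop = FALSE]
  if (invert) {
    sweep(sweep(X, 2, object$sigma, "*"), 2, object$mu, "+")
  } else {
    sweep(sweep(X, 2, object$mu, "-"), 2, object$sigma, "/")
  }
}

#' Multivariable linear regression for a cognitive score
#'
#' Ordinary least-squares fit of the target (MoCA by default) on the
#' selected gait variables, with 95% confidence intervals for every
#' parameter.
#'
#' @param data Training data (rows > number of inputs + 1).
#' @param inputs Character vector of predictor column names.
#' @param target Response column name.
#' @return An object of class `moca_mlr`; supports [predict()], [tidy()]
#'   and [glance()].
#' @export
fit_moca_mlr <- function(data, inputs, target = "moca_total") {
  if (nrow(data) <= length(inputs) + 1L)
    abort("Too few rows to fit the regression.", class = "gaitcog_range")
  fit <- lm(stats::reformulate(inputs, response = target), data = data)
  if (anyNA(coef(fit)))
    abort("Rank-deficient design: drop collinear inputs.",
          class = "gaitcog_collinear")
  structure(list(fit = fit, inputs = inputs, target = target),
            class = "moca_mlr")
}

#' @export
predict.moca_mlr <- function(object, newdata, ...) {
  unname(predict(object$fit, newdata = tibble::as_tibble(newdata)))
}

#' @exportS3Method generics::tidy
tidy.moca_mlr <- function(x, conf_level = 0.95, ...) {
  cf <- summary(x$fit)$coefficients
  ci <- confint(x$fit, level = conf_level)
  tibble::tibble(term = rownames(cf), estimate = cf[, 1],
                 std.error = cf[, 2], statistic = cf[, 3], p.value = cf[, 4],
                 conf.low = ci[, 1], conf.high = ci[, 2])
}

#' @exportS3Method generics::glance
glance.moca_mlr <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
                 sigma = s$sigma, nobs = stats::nobs(x$fit),
                 df.residual = x$fit$df.residual)
}

#' @export
print.moca_mlr <- function(x, ...) {
  cat("<moca_mlr>", x$target, "~", paste(x$inputs, collapse = " + "), "\n")
  print(tidy(x))
  invisible(x)
}

#' Build a linear cognitive-score predictor from fixed coefficients
#'
#' Constructs the linear predictor `score = sum(beta_i * V_i) + intercept`
#' directly from given slopes, without fitting — used for worked examples
#' with published parameter estimates.
#'
#' @param coefficients Named numeric vector of slopes (names are the input
#'   variables).
#' @param intercept Intercept term.
#' @return An object of class `moca_predictor`.
#' @seealso [reference_moca_predictor()]
#' @export
moca_predictor <- function(coefficients, intercept) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            is.numeric(intercept), length(intercept) == 1L)
  structure(list(coefficients = coefficients, intercept = intercept),
            class = "moca_predictor")
}

#' @export
predict.moca_predictor <- function(object, newdata, ...) {
  k <- length(object$coefficients)
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    if (length(newdata) != k)
      abort(sprintf("Expected %d inputs, got %d.", k, length(newdata)),
            class = "gaitcog_invalid_parameter")
    return(sum(object$coefficients * newdata) + object$intercept)
  }
  X <- as.matrix(as.data.frame(newdata)[, names(object$coefficients), drop = FALSE])
  as.numeric(X %*% object$coefficients + object$intercept)
}

#' Reference six-velocity MoCA predictor
#'
#' The linear MoCA predictor with the parameter estimates reported for a
#' 138-participant midlife cohort (healthy controls and uncomplicated
#' T2DM): slopes for the left/right-foot walking velocities of the normal,
#' fast and dual-task walks, plus an intercept of 21.2 MoCA points. Useful
#' as a worked example and as a fixed benchmark predictor.
#'
#' @return A [moca_predictor()] with six velocity slopes and the intercept.
#' @examples
#' ref <- reference_moca_predictor()
#' predict(ref, rep(0, 6))  # the intercept, 21.2
#' @export
reference_moca_predictor <- function() {
  moca_predictor(
    coefficients = c(velocity_mps_normal_left = 5.74,
                     velocity_mps_normal_right = -4.39,
                     velocity_mps_fast_left = 1.03,
                     velocity_mps_fast_right = 0.61,
                     velocity_mps_dual_left = 1.01,
                     velocity_mps_dual_right = 1.21),
    intercept = 21.2
  )
}

#' Reported confidence intervals for the reference predictor
#'
#' @return A tibble of the published parameter estimates and their 95%
#'   confidence intervals (beta1..beta6 are the velocity slopes in the
#'   order of [reference_moca_predictor()]; beta7 is the intercept). Note
#'   the third slope is reported with an interval that does not bracket its
#'   own point estimate in the source table; the values are carried
#'   verbatim.
#' @export
reference_moca_coefficients <- function() {
  ref <- reference_moca_predictor()
  tibble::tibble(
    term = c(names(ref$coefficients), "(Intercept)"),
    estimate = c(unname(ref$coefficients), ref$intercept),
    conf.low = c(1.79, -8.09, 1.79, -2.33, -0.45, -0.38, 18.74),
    conf.high = c(9.69, -0.69, 3.83, 3.59, 2.46, 2.79, 23.68)
  )
}

# ---- neural network -------------------------------------------------------

#' Descending-width sigmoid network architecture
#'
#' Fully connected layers whose widths descend by one from the number of
#' inputs down to a single output node (e.g. 6 inputs -> hidden 5, 4, 3, 2
#' -> output 1), sigmoid activation at every node, mean-squared-error loss
#' and the Adam optimizer.
#'
#' @param n_inputs Number of input variables (>= 2).
#' @return An object of class `nn_spec` with `widths` (layer output widths)
#'   and `n_params` (total weights + biases).
#' @examples
#' build_nn(6)$widths   # 5 4 3 2 1
#' build_nn(6)$n_params # 85
#' @export
build_nn <- function(n_inputs) {
  assert_scalar_number(n_inputs, "n_inputs", lower = 2)
  n_inputs <- as.integer(n_inputs)
  widths <- seq.int(n_inputs - 1L, 1L)
  dims_in <- c(n_inputs, head(widths, -1))
  structure(list(n_inputs = n_inputs, widths = widths,
                 n_params = sum(dims_in * widths + widths)),
            class = "nn_spec")
}

nn_init <- function(spec, seed = NULL) {
  dims_in <- c(spec$n_inputs, head(spec$widths, -1))
  with_seed(seed, {
    W <- purrr::map2(dims_in, spec$widths, function(a, b) {
      lim <- sqrt(6 / (a + b))   # Glorot uniform
      matrix(runif(a * b, -lim, lim), a, b)
    })
    b <- purrr::map(spec$widths, function(bw) numeric(bw))
    list(W = W, b = b)
  })
}

nn_forward <- function(wts, X) {
  a <- X
  acts <- vector("list", length(wts$W))
  for (l in seq_along(wts$W)) {
    a <- stats::plogis(sweep(a %*% wts$W[[l]], 2, wts$b[[l]], "+"))
    acts[[l]] <- a
  }
  acts
}

#' Train the sigmoid network with Adam and early stopping
#'
#' Full-batch gradient descent with the Adam optimizer on mean squared
#' error. Training stops at `max_epochs` or once the validation loss has
#' failed to improve for `patience` consecutive epochs; the weights of the
#' best validation epoch are retained. Inputs are expected standardized and
#' the target scaled into (0, 1) (see [fit_moca_nn()] for the full
#' wrapper).
#'
#' @param spec A [build_nn()] architecture.
#' @param X,y Training inputs (matrix) and target in (0, 1).
#' @param X_val,y_val Validation data monitored for early stopping.
#' @param max_epochs Maximum passes over the data (default 10000).
#' @param patience Early-stopping patience in epochs (default 50).
#' @param lr Adam learning rate (default 0.001; beta1 0.9, beta2 0.999).
#' @param seed Seed for weight initialization; fixed seeds give identical
#'   fits.
#' @return A list: best `weights`, `epochs_run`, `best_epoch`, per-epoch
#'   `val_loss`.
#' @export
train_nn <- function(spec, X, y, X_val, y_val, max_epochs = 10000,
                     patience = 50, lr = 1e-3, seed = NULL) {
  stopifnot(inherits(spec, "nn_spec"))
  X <- as.matrix(X); X_val <- as.matrix(X_val)
  y <- as.numeric(y); y_val <- as.numeric(y_val)
  wts <- nn_init(spec, seed)
  L <- length(wts$W)
  mW <- purrr::map(wts$W, function(w) w * 0); vW <- mW
  mb <- purrr::map(wts$b, function(bb) bb * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  n <- nrow(X)
  best <- list(loss = Inf, wts = wts, epoch = 0L)
  stall <- 0L
  val_hist <- numeric(0)
  for (epoch in seq_len(max_epochs)) {
    acts <- nn_forward(wts, X)
    out <- acts[[L]][, 1]
    if (!all(is.finite(out)))
      abort("Divergent training loss (non-finite activations).",
            class = "gaitcog_divergence")
    delta <- matrix((2 / n) * (out - y) * out * (1 - out), ncol = 1)
    for (l in seq(L, 1)) {
      a_prev <- if (l == 1) X else acts[[l - 1]]
      gW <- crossprod(a_prev, delta)
      gb <- colSums(delta)
      if (l > 1) {
        delta <- (delta %*% t(wts$W[[l]])) * a_prev * (1 - a_prev)
      }
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
      corr1 <- 1 - b1^epoch; corr2 <- 1 - b2^epoch
      wts$W[[l]] <- wts$W[[l]] - lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
      wts$b[[l]] <- wts$b[[l]] - lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
    }
    val_out <- nn_forward(wts, X_val)[[L]][, 1]
    val_loss <- mean((val_out - y_val)^2)
    val_hist[epoch] <- val_loss
    if (is.finite(val_loss) && val_loss < best$loss - 1e-12) {
      best <- list(loss = val_loss, wts = wts, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  list(weights = best$wts, epochs_run = length(val_hist),
       best_epoch = best$epoch, val_loss = val_hist)
}

# Min-max scaling of the target into (lo, hi), fit on training data; the
# sigmoid output node cannot reach the raw MoCA range.
target_scaler <- function(y, lo = 0.05, hi = 0.95) {
  rng <- range(y)
  if (diff(rng) == 0)
    abort("Constant target; cannot scale.", class = "gaitcog_invalid_parameter")
  list(min = rng[1], max = rng[2], lo = lo, hi = hi)
}
scale_target <- function(y, sc) sc$lo + (y - sc$min) / (sc$max - sc$min) * (sc$hi - sc$lo)
unscale_target <- function(z, sc) sc$min + (z - sc$lo) / (sc$hi - sc$lo) * (sc$max - sc$min)

#' Fit the sigmoid network on a cohort table
#'
#' Wraps [train_nn()]: standardizes the inputs (on the training rows only,
#' by default), min-max scales the target into (0.05, 0.95), trains with
#' early stopping monitored on `val_data`, and returns a predictor whose
#' outputs are inverse-scaled back to score units.
#'
#' @param data Training rows.
#' @param inputs,target Column names.
#' @param val_data Validation rows for the early-stopping monitor (defaults
#'   to the training rows).
#' @param standardize_on `"train"` (leakage-free, default) or `"all"` (fit
#'   the standardizer on train + validation).
#' @param ... Passed to [train_nn()] (`max_epochs`, `patience`, `lr`,
#'   `seed`).
#' @return An object of class `moca_nn`; supports [predict()] and
#'   [glance()].
#' @export
fit_moca_nn <- function(data, inputs, target = "moca_total", val_data = NULL,
                        standardize_on = c("train", "all"), ...) {
  standardize_on <- match.arg(standardize_on)
  val_data <- val_data %||% data
  std_src <- if (standardize_on == "train") data else
    dplyr::bind_rows(data[inputs], val_data[inputs])
  std <- standardizer(std_src[inputs])
  sc <- target_scaler(data[[target]])
  spec <- build_nn(length(inputs))
  fit <- train_nn(spec,
                  X = zstandardize(data[inputs], std),
                  y = scale_target(data[[target]], sc),
                  X_val = zstandardize(val_data[inputs], std),
                  y_val = scale_target(val_data[[target]], sc),
                  ...)
  structure(list(spec = spec, weights = fit$weights, standardizer = std,
                 scaler = sc, inputs = inputs, target = target,
                 epochs_run = fit$epochs_run, best_epoch = fit$best_epoch),
            class = "moca_nn")
}

#' @export
predict.moca_nn <- function(object, newdata, ...) {
  Z <- zstandardize(tibble::as_tibble(newdata)[object$inputs], object$standardizer)
  out <- nn_forward(object$weights, Z)[[length(object$weights$W)]][, 1]
  unscale_target(out, object$scaler)
}

#' @exportS3Method generics::glance
glance.moca_nn <- function(x, ...) {
  tibble::tibble(n_params = x$spec$n_params, epochs_run = x$epochs_run,
                 best_epoch = x$best_epoch,
                 layers = paste(c(x$spec$n_inputs, x$spec$widths), collapse = "-"))
}

#' @export
print.moca_nn <- function(x, ...) {
  cat("<moca_nn>", x$target, "~", paste(x$inputs, collapse = " + "), "\n")
  print(glance(x))
  invisible(x)
}

# ---- validation -----------------------------------------------------------

#' Repeated 80/20 hold-out validation of a cognition model
#'
#' Twenty (by default) independent random 80/20 splits of the
#' complete-case cohort; on each repeat the model is fit on the training
#' 80% and the mean absolute error (MAE) is measured on the held-out 20%.
#' Reports the per-repeat MAEs with their mean and a t-based 95%
#' confidence interval.
#'
#' @param data Cohort table (complete cases on `inputs` and `target` are
#'   used).
#' @param inputs,target Column names.
#' @param model `"mlr"` or `"nn"`.
#' @param repeats Number of random splits (default 20).
#' @param train_frac Training fraction (default 0.8).
#' @param seed Master seed; split r uses a seed derived from it, so MAEs
#'   are invariant to row order and reproducible.
#' @param ... Passed to the model fitter (e.g. `max_epochs`, `patience` for
#'   the network).
#' @return An object of class `validation_report`; see [tidy()] /
#'   [glance()] and [compare_models()].
#' @export
validate_model <- function(data, inputs, target = "moca_total",
                           model = c("mlr", "nn"), repeats = 20,
                           train_frac = 0.8, seed = 1, ...) {
  model <- match.arg(model)
  cc <- stats::complete.cases(data[c(inputs, target)])
  data <- dplyr::arrange(tibble::as_tibble(data)[cc, ],
                         dplyr::across(dplyr::all_of(c(target, inputs))))
  n <- nrow(data)
  n_train <- floor(train_frac * n)
  if (n_train < length(inputs) + 2L || n_train >= n)
    abort("Too few rows for a nonempty 80/20 split.", class = "gaitcog_range")
  maes <- purrr::map_dbl(seq_len(repeats), function(rep_i) {
    rs <- stage_seed(seed, paste0("split", rep_i))
    idx <- with_seed(rs, sample.int(n, n_train))
    train <- data[idx, ]; hold <- data[-idx, ]
    pred <- if (model == "mlr") {
      predict(fit_moca_mlr(train, inputs, target), hold)
    } else {
      fit <- fit_moca_nn(train, inputs, target, val_data = hold,
                         seed = stage_seed(rs, "init"), ...)
      predict(fit, hold)
    }
    mean(abs(pred - hold[[target]]))
  })
  ci <- mae_ci(maes)
  structure(list(model = model, inputs = inputs, target = target,
                 mae = tibble::tibble(rep = seq_len(repeats), mae = maes),
                 mean_mae = mean(maes), conf.low = ci[1], conf.high = ci[2],
                 repeats = repeats, train_frac = train_frac, seed = seed,
                 n = n),
            class = "validation_report")
}

mae_ci <- function(x, level = 0.95) {
  m <- mean(x); s <- sd(x) / sqrt(length(x))
  tq <- qt(1 - (1 - level) / 2, length(x) - 1)
  c(m - tq * s, m + tq * s)
}

#' @exportS3Method generics::tidy
tidy.validation_report <- function(x, ...) x$mae

#' @exportS3Method generics::glance
glance.validation_report <- function(x, ...) {
  tibble::tibble(model = x$model, mean_mae = x$mean_mae,
                 conf.low = x$conf.low, conf.high = x$conf.high,
                 repeats = x$repeats, n = x$n)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s: MAE %.3f [95%% CI %.3f-%.3f] over %d repeats (n = %d)\n",
              x$model, x$mean_mae, x$conf.low, x$conf.high, x$repeats, x$n))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.validation_report <- function(object, ...) {
  ggplot2::ggplot(object$mae, ggplot2::aes(x = .data$rep, y = .data$mae)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_mae, linetype = 2) +
    ggplot2::labs(x = "repeat", y = "hold-out MAE",
                  title = sprintf("%s: mean MAE %.2f", object$model, object$mean_mae)) +
    ggplot2::theme_minimal()
}

#' Compare two validation reports by paired MAE differences
#'
#' Pairs the per-repeat MAEs of two models validated with the same number
#' of repeats, and reports the mean difference with a t-based 95%
#' confidence interval. The verdict is `"ns"` when the interval covers
#' zero.
#'
#' @param rep_a,rep_b Two [validate_model()] reports with equal repeats.
#' @return A one-row tibble: `model_a`, `model_b`, `mean_diff`, `conf.low`,
#'   `conf.high`, `verdict`.
#' @export
compare_models <- function(rep_a, rep_b) {
  stopifnot(inherits(rep_a, "validation_report"),
            inherits(rep_b, "validation_report"))
  if (rep_a$repeats != rep_b$repeats)
    abort("Reports have different repeat counts.", class = "gaitcog_invalid_parameter")
  d <- rep_a$mae$mae - rep_b$mae$mae
  if (sd(d) == 0) {
    ci <- c(mean(d), mean(d))
  } else {
    ci <- mae_ci(d)
  }
  verdict <- if (ci[1] <= 0 && ci[2] >= 0) "ns" else "significant"
  tibble::tibble(model_a = rep_a$model, model_b = rep_b$model,
                 mean_diff = mean(d), conf.low = ci[1], conf.high = ci[2],
                 verdict = verdict)
}
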