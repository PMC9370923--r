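# Cohort-level statistics: normality-gated group comparisons,
# covariate-adjusted effects of group on gait, and Pearson screening of
# gait variables against cognitive scores.

#' Compare a gait variable between groups
#'
#' Shapiro-Wilk normality tests (alpha = 0.05) on each group choose the
#' branch: an unpaired Student t-test when both groups look normal, a
#' Mann-Whitney U test otherwise. Two-sided throughout.
#'
#' @param data A data frame with the variable and a two-level group column.
#' @param variable Name of the numeric variable to compare.
#' @param group Name of the grouping column (two levels, >= 3 observations
#'   each).
#' @param alpha Normality-test level used to pick the branch.
#' @return A one-row tibble: `variable`, `test` (`"t"` or
#'   `"mann-whitney"`), `statistic`, `p_value`, and the two Shapiro-Wilk
#'   p-values.
#' @export
compare_groups <- function(data, variable, group = "group", alpha = 0.05) {
  x <- data[[variable]]
  g <- as.factor(data[[group]])
  if (nlevels(g) != 2L)
    abort("`group` must have exactly two levels.", class = "gaitcog_invalid_parameter")
  xs <- split(x, g)
  if (any(vapply(xs, length, 0L) < 3L))
    abort("Need at least 3 observations per group.", class = "gaitcog_range")
  if (all(vapply(xs, sd, 0) == 0))
    abort("Degenerate variance in both groups; no test possible.",
          class = "gaitcog_range")
  sw_p <- vapply(xs, function(v) {
    if (sd(v) == 0 || length(v) < 3 || length(v) > 5000) return(0)  # non-normal branch
    shapiro.test(v)$p.value
  }, 0)
  if (all(sw_p > alpha)) {
    tt <- t.test(xs[[1]], xs[[2]], var.equal = TRUE)
    res <- c(test = "t", statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    wt <- suppressWarnings(wilcox.test(xs[[1]], xs[[2]], exact = FALSE))
    res <- c(test = "mann-whitney", statistic = unname(wt$statistic), p = wt$p.value)
  }
  tibble::tibble(variable = variable, test = res[["test"]],
                 statistic = as.numeric(res[["statistic"]]),
                 p_value = as.numeric(res[["p"]]),
                 shapiro_p_1 = sw_p[[1]], shapiro_p_2 = sw_p[[2]])
}

#' Covariate-adjusted group effect on a gait variable
#'
#' Ordinary least squares of the gait variable on the group indicator plus
#' age, sex, BMI and education, returning the group coefficient with its
#' 95% confidence interval — the adjusted-model column of a group
#' comparison table.
#'
#' @param data A data frame containing the gait variable, `group` and the
#'   covariates.
#' @param gait_var Name of the gait variable (response).
#' @param group Name of the group column.
#' @param covariates Covariate column names.
#' @param conf_level Confidence level for the interval.
#' @return A one-row tibble: `term`, `estimate`, `conf.low`, `conf.high`,
#'   `p.value`, `n`.
#' @export
adjusted_effect <- function(data, gait_var, group = "group",
                            covariates = c("age", "sex", "bmi", "education_yr"),
                            conf_level = 0.95) {
  if (length(unique(data[[group]])) < 2L)
    abort("Group indicator is constant; effect not identifiable.",
          class = "gaitcog_collinear")
  fml <- stats::reformulate(c(group, covariates), response = gait_var)
  fit <- lm(fml, data = data)
  if (anyNA(coef(fit)))
    abort("Collinear design: some coefficients are not estimable.",
          class = "gaitcog_collinear")
  cf <- summary(fit)$coefficients
  term <- grep(paste0("^", group), rownames(cf), value = TRUE)[1]
  ci <- confint(fit, term, level = conf_level)
  tibble::tibble(term = term, estimate = cf[term, 1],
                 conf.low = ci[1], conf.high = ci[2],
                 p.value = cf[term, 4], n = stats::nobs(fit))
}

#' Pearson screening of gait variables against cognitive scores
#'
#' Computes the Pearson correlation of every gait variable with every
#' cognitive score on the pooled cohort (both groups together) and flags
#' the pairs whose |r| reaches the moderate-correlation threshold
#' (inclusive, default 0.3) for use as prediction-model inputs. Constant
#' columns yield an undefined r and are flagged `degenerate`.
#'
#' @param data A wide data frame, one row per subject.
#' @param gait_vars,cog_vars Column names to correlate.
#' @param threshold Absolute-correlation selection threshold.
#' @return A tibble: `gait_var`, `cog_var`, `r`, `n`, `selected`,
#'   `degenerate`. At least 3 complete pairs are required per cell.
#' @export
screen_correlations <- function(data, gait_vars, cog_vars, threshold = 0.3) {
  grid <- tidyr::expand_grid(gait_var = gait_vars, cog_var = cog_vars)
  res <- purrr::pmap(grid, function(gait_var, cog_var) {
    x <- data[[gait_var]]; y <- data[[cog_var]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3L)
      abort(sprintf("Fewer than 3 complete pairs for %s vs %s.", gait_var, cog_var),
            class = "gaitcog_range")
    degen <- sd(x[ok]) == 0 || sd(y[ok]) == 0
    r <- if (degen) NA_real_ else cor(x[ok], y[ok])
    tibble::tibble(gait_var = gait_var, cog_var = cog_var, r = r, n = n,
                   selected = !degen && abs(r) >= threshold,
                   degenerate = degen)
  })
  out <- dplyr::bind_rows(res)
  attr(out, "threshold") <- threshold
  out
}

#' Heat map of screening correlations
#'
#' @param screening Output of [screen_correlations()].
#' @return A ggplot tile plot of Pearson r.
#' @export
plot_correlation_heatmap <- function(screening) {
  ggplot2::ggplot(screening,
                  ggplot2::aes(x = .data$cog_var, y = .data$gait_var,
                               fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
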