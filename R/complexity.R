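# Multiscale entropy: coarse-graining, sample entropy (Rcpp-backed
# template counting), the MSE curve and its area (complexity index).

#' Coarse-grain a time series
#'
#' Scale-\eqn{\tau} coarse-graining replaces consecutive non-overlapping
#' blocks of length \eqn{\tau} by their means; the trailing remainder is
#' dropped, so the result has `floor(length(x)/tau)` points. Scale 1 is the
#' original series.
#'
#' @param x Numeric vector.
#' @param tau Integer timescale, `1 <= tau <= length(x)`.
#' @return Numeric vector of block means.
#' @examples
#' coarse_grain(1:6, 2)  # 1.5 3.5 5.5
#' @export
coarse_grain <- function(x, tau) {
  assert_scalar_number(tau, "tau", lower = 1)
  tau <- as.integer(tau)
  if (tau > length(x))
    abort("`tau` exceeds the series length.", class = "gaitcog_invalid_parameter")
  if (tau == 1L) return(as.numeric(x))
  nb <- length(x) %/% tau
  colMeans(matrix(x[seq_len(nb * tau)], nrow = tau))
}

#' Sample entropy
#'
#' The negative natural log of the conditional probability that sequences
#' matching for `m` points (Chebyshev distance at most `r_abs`,
#' self-matches excluded) also match for `m + 1` points. A constant series
#' has sample entropy 0; when no `m + 1` template pair matches the value is
#' undefined and `NA` is returned (callers treat the scale as invalid).
#'
#' @param x Numeric vector of length at least `m + 2`.
#' @param m Template length (default 2).
#' @param r_abs Absolute tolerance, same units as `x` (> 0). Note this is
#'   the absolute radius; [mse_curve()] derives it once from the scale-1 SD.
#' @return Sample entropy in nats, or `NA` when undefined.
#' @export
sample_entropy <- function(x, m = 2, r_abs) {
  assert_scalar_number(m, "m", lower = 1)
  assert_scalar_number(r_abs, "r_abs", lower = 0, strict = TRUE)
  if (length(x) < m + 2)
    abort("Series too short for sample entropy (need length >= m + 2).",
          class = "gaitcog_range")
  counts <- sampen_counts(as.numeric(x), as.integer(m), r_abs)
  if (!is.finite(counts[["B"]]) || counts[["B"]] == 0 || counts[["A"]] == 0)
    return(NA_real_)
  -log(counts[["A"]] / counts[["B"]])
}

#' Multiscale entropy curve
#'
#' Computes sample entropy on coarse-grained copies of the signal at
#' scales 1 to `tau_max` (default 40). The tolerance is fixed once as
#' `r * SD` of the scale-1 series and reused at every scale, which makes
#' the resulting complexity index invariant to affine rescaling of the
#' input. Scales whose coarse series is shorter than `10 * m` points, or
#' whose entropy is undefined, are marked invalid and excluded from the
#' area.
#'
#' @param x Numeric vector (the unsmoothed 200 Hz signal in the gait
#'   pipeline).
#' @param m Template length (default 2).
#' @param r Tolerance as a fraction of the scale-1 standard deviation
#'   (default 0.2).
#' @param tau_max Number of scales (default 40).
#' @return An object of class `mse_curve`: a tibble with `scale`,
#'   `n_points`, `sampen`, `valid` and attributes `m`, `r`, `r_abs`.
#' @export
mse_curve <- function(x, m = 2, r = 0.2, tau_max = 40) {
  assert_scalar_number(r, "r", lower = 0, strict = TRUE)
  if (r >= 1) abort("`r` must be a fraction (< 1) of the scale-1 SD.",
                    class = "gaitcog_invalid_parameter")
  assert_scalar_number(tau_max, "tau_max", lower = 1)
  if (length(x) < m + 2)
    abort("Series too short for any scale.", class = "gaitcog_range")
  s1 <- sd(x)
  if (s1 == 0)
    abort("Constant signal: tolerance would be zero.", class = "gaitcog_range")
  r_abs <- r * s1
  rows <- purrr::map(seq_len(tau_max), function(tau) {
    n_pts <- length(x) %/% tau
    if (n_pts < m + 2)
      return(tibble::tibble(scale = tau, n_points = n_pts,
                            sampen = NA_real_, valid = FALSE))
    se <- sample_entropy(coarse_grain(x, tau), m = m, r_abs = r_abs)
    tibble::tibble(scale = tau, n_points = n_pts, sampen = se,
                   valid = is.finite(se) && n_pts >= 10 * m)
  })
  out <- dplyr::bind_rows(rows)
  if (!any(out$valid))
    abort("All scales invalid; signal too short or too regular.",
          class = "gaitcog_range")
  if (any(!out$valid))
    warn(sprintf("%d of %d scales invalid and excluded from the complexity index.",
                 sum(!out$valid), nrow(out)))
  structure(out, class = c("mse_curve", class(out)),
            m = m, r = r, r_abs = r_abs)
}

#' Complexity index: area under the MSE curve
#'
#' Trapezoidal area of sample entropy over the valid scales, with the
#' scale axis in units of \eqn{\tau}. Higher values indicate richer
#' point-to-point structure across timescales; 1/f-like signals score
#' higher than white noise of equal variance.
#'
#' @param curve An [mse_curve()] object (at least 2 valid scales).
#' @return The area (a non-negative scalar for non-negative entropy
#'   curves).
#' @export
complexity_index <- function(curve) {
  stopifnot(inherits(curve, "mse_curve") || is.data.frame(curve))
  v <- curve[curve$valid, ]
  if (nrow(v) < 2L)
    abort("Need at least 2 valid scales for the complexity index.",
          class = "gaitcog_range")
  sum(diff(v$scale) * (head(v$sampen, -1) + tail(v$sampen, -1)) / 2)
}

#' @describeIn mse_curve Plot the MSE curve; invalid scales are hollow.
#' @param object An `mse_curve` object.
#' @param ... Ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.mse_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$scale, y = .data$sampen)) +
    ggplot2::geom_line(data = object[object$valid, ], colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$valid)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(x = expression(scale ~ tau), y = "sample entropy (nats)") +
    ggplot2::theme_minimal()
}
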