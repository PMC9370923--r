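# Temporal gait parameters from labelled events:
#   swing(n)  = HS(n)   - TO(n)
#   stance(n) = TO(n+1) - HS(n)
#   stride(n) = MSV(n+1) - MSV(n)
# plus the two-standard-deviation turning-artifact rule, walk velocity and
# the stride-time coefficient of variation.

#' Per-cycle swing, stance and stride times
#'
#' Computes the three temporal gait parameters from a labelled event
#' series. With k complete cycles there are k swing times and k-1 stance
#' and stride times (the last cycle has no successor).
#'
#' @param events An event series tibble (`cycle`, `label`, `time_s`) with
#'   at least 2 complete cycles.
#' @return A long stride table: `metric` (`swing`/`stance`/`stride`),
#'   `cycle`, `duration_s`.
#' @export
stride_intervals <- function(events) {
  need <- c("cycle", "label", "time_s")
  if (!all(need %in% names(events)))
    abort("`events` must have columns cycle, label, time_s.",
          class = "gaitcog_invalid_events")
  wide <- events |>
    dplyr::select(dplyr::all_of(need)) |>
    tidyr::pivot_wider(names_from = "label", values_from = "time_s") |>
    dplyr::arrange(.data$cycle)
  if (!all(c("TO", "MSV", "HS") %in% names(wide)) || nrow(wide) < 2L ||
        anyNA(wide[c("TO", "MSV", "HS")]))
    abort("Need at least 2 complete (TO, MSV, HS) cycles.",
          class = "gaitcog_invalid_events")
  if (any(wide$TO >= wide$MSV | wide$MSV >= wide$HS) ||
        any(head(wide$HS, -1) >= tail(wide$TO, -1)))
    abort("Event ordering violated: expected TO < MSV < HS < next TO.",
          class = "gaitcog_invalid_events")
  out <- dplyr::bind_rows(
    tibble::tibble(metric = "swing", cycle = wide$cycle,
                   duration_s = wide$HS - wide$TO),
    tibble::tibble(metric = "stance", cycle = head(wide$cycle, -1),
                   duration_s = tail(wide$TO, -1) - head(wide$HS, -1)),
    tibble::tibble(metric = "stride", cycle = head(wide$cycle, -1),
                   duration_s = diff(wide$MSV))
  )
  if (any(out$duration_s >= 5))
    warn("Stride table contains durations of 5 s or more; check the events.")
  out
}

#' Flag turning-artifact outliers in a stride table
#'
#' Applies the two-standard-deviation rule independently to each duration
#' series (swing, stance, stride): values deviating from the series mean by
#' more than twice its sample standard deviation are flagged
#' `turn_outlier`. Mean and SD are computed once over the unfiltered
#' series (single pass, no iteration).
#'
#' @param strides A stride table from [stride_intervals()].
#' @param n_sd Deviation threshold in standard deviations (default 2).
#' @return The stride table with logical `removed` and character `reason`
#'   columns. Series with fewer than 3 values are left untouched with a
#'   warning.
#' @export
remove_turn_artifact <- function(strides, n_sd = 2) {
  flag_series <- function(x, metric) {
    if (length(x) < 3L) {
      warn(sprintf("Fewer than 3 %s values; turn-artifact rule skipped.", metric))
      return(rep(FALSE, length(x)))
    }
    s <- sd(x)
    s > 0 & abs(x - mean(x)) > n_sd * s
  }
  strides |>
    dplyr::group_by(.data$metric) |>
    dplyr::mutate(removed = flag_series(.data$duration_s, .data$metric[1]),
                  reason = ifelse(.data$removed, "turn_outlier", NA_character_)) |>
    dplyr::ungroup() |>
    dplyr::select("metric", "cycle", "duration_s", "removed", "reason")
}

#' Average walking velocity of a 20 m task
#'
#' @param total_time_s Total walking time in seconds (> 0).
#' @param distance_m Walking distance, default 20 m.
#' @return Velocity in m/s (`distance_m / total_time_s`).
#' @examples
#' walk_velocity(14.8)  # ~1.35 m/s
#' @export
walk_velocity <- function(total_time_s, distance_m = 20) {
  if (!is.numeric(total_time_s) || any(total_time_s <= 0))
    abort("`total_time_s` must be positive.", class = "gaitcog_invalid_parameter")
  distance_m / total_time_s
}

#' Stride-time coefficient of variation
#'
#' `100 * sample SD / mean` of the stride times — the stride-regularity
#' measure reported alongside the temporal means.
#'
#' @param stride_times Numeric vector of stride times (>= 2 values).
#' @return CoV in percent.
#' @examples
#' stride_cov(c(0.9, 1.0, 1.1))  # 10
#' @export
stride_cov <- function(stride_times) {
  if (length(stride_times) < 2L)
    abort("Need at least 2 stride times.", class = "gaitcog_invalid_parameter")
  m <- mean(stride_times)
  if (m == 0)
    abort("Mean stride time is zero; CoV undefined.",
          class = "gaitcog_invalid_parameter")
  100 * sd(stride_times) / m
}

#' Summarise one walk into a single gait-summary row
#'
#' Assembles the per-walk summary: velocity, mean swing/stance/stride after
#' turning-artifact removal, stride-time CoV, the multiscale-entropy
#' complexity index, and the number of strides removed by the 2-SD rule.
#'
#' @param clean A preprocessed recording (for the total walking time).
#' @param events A labelled event series.
#' @param mse Optional `mse_curve` object; its complexity index is carried
#'   into the summary.
#' @param subject,foot,task Identifiers for the row; taken from the
#'   recording's metadata when present.
#' @param time_basis `"recording"` uses the trimmed recording duration as
#'   total walking time (the turn stays in the clock); `"events"` uses the
#'   first-to-last event span.
#' @param distance_m Walk distance, default 20 m.
#' @return A one-row tibble with columns `subject`, `foot`, `task`,
#'   `velocity_mps`, `swing_s`, `stance_s`, `stride_s`, `cov_pct`,
#'   `complexity`, `n_removed`, `n_strides`.
#' @export
summarize_walk <- function(clean, events, mse = NULL, subject = NA_character_,
                           foot = NULL, task = NULL,
                           time_basis = c("recording", "events"),
                           distance_m = 20) {
  if (is.null(clean) || is.null(events))
    abort("Both the clean signal and the event series are required.",
          class = "gaitcog_incomplete_summary")
  time_basis <- match.arg(time_basis)
  meta <- attr(clean, "meta") %||% list()
  foot <- foot %||% meta$foot %||% NA_character_
  task <- task %||% meta$task %||% NA_character_
  total_time <- if (time_basis == "recording") {
    nrow(clean) / rec_fs(clean)
  } else diff(range(events$time_s))
  flagged <- remove_turn_artifact(stride_intervals(events))
  kept <- flagged[!flagged$removed, ]
  mean_of <- function(mm) mean(kept$duration_s[kept$metric == mm])
  stride_kept <- kept$duration_s[kept$metric == "stride"]
  cx <- if (is.null(mse)) NA_real_ else complexity_index(mse)
  tibble::tibble(
    subject = subject, foot = foot, task = task,
    velocity_mps = walk_velocity(total_time, distance_m),
    swing_s = mean_of("swing"), stance_s = mean_of("stance"),
    stride_s = mean_of("stride"),
    cov_pct = if (length(stride_kept) >= 2) stride_cov(stride_kept) else NA_real_,
    complexity = cx,
    n_removed = sum(flagged$removed[flagged$metric == "stride"]),
    n_strides = sum(flagged$metric == "stride")
  )
}
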