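# Event detection: candidate extrema by prominence, then labelling of the
# dominant mid-swing peaks (MSV) and their flanking troughs (TO before,
# HS after).

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# Topographic prominence of a local maximum: height above the higher of
# the two key saddles separating it from taller terrain (or the boundary).
peak_prominence <- function(x, idx) {
  vapply(idx, function(i) {
    left <- x[seq_len(i - 1)]
    higher_l <- which(left > x[i])
    base_l <- min(x[(if (length(higher_l)) max(higher_l) else 1):i])
    right <- x[i:length(x)]
    higher_r <- which(right > x[i])
    base_r <- min(x[i:(i - 1 + (if (length(higher_r)) min(higher_r) else length(right)))])
    x[i] - max(base_l, base_r)
  }, 0)
}

#' Detect candidate peaks and troughs
#'
#' Finds local maxima and minima of the smoothed signal whose topographic
#' prominence is at least `min_prominence_frac` times the signal standard
#' deviation, enforcing a minimum pairwise separation within each type
#' (more prominent extrema win).
#'
#' @param clean A smoothed single-axis recording (see [smooth_recording()]),
#'   at least 2 s long.
#' @param min_prominence_frac Prominence threshold as a fraction of the
#'   signal SD.
#' @param min_separation_s Minimum separation between kept extrema of the
#'   same type, seconds. The default (0.25 s) is shorter than any plausible
#'   half-stride even at fast walk.
#' @return A tibble `time_s`, `value`, `type` (`"peak"`/`"trough"`),
#'   `prominence`, ordered in time; zero rows when nothing qualifies.
#' @export
detect_extrema <- function(clean, min_prominence_frac = 0.5,
                           min_separation_s = 0.25) {
  fs <- rec_fs(clean)
  if (nrow(clean) < 2 * fs)
    abort("Signal must be at least 2 s long for event detection.",
          class = "gaitcog_range")
  x <- clean$signal
  s <- sd(x)
  if (s == 0) {
    return(tibble::tibble(time_s = numeric(), value = numeric(),
                          type = character(), prominence = numeric()))
  }
  one_type <- function(sig, type) {
    idx <- local_maxima(sig)
    if (!length(idx)) return(NULL)
    prom <- peak_prominence(sig, idx)
    keep <- prom >= min_prominence_frac * s
    idx <- idx[keep]; prom <- prom[keep]
    if (!length(idx)) return(NULL)
    # greedy separation: most prominent first
    ord <- order(-prom)
    kept <- integer()
    for (k in ord) {
      if (!length(kept) ||
            all(abs(clean$time_s[idx[k]] - clean$time_s[idx[kept]]) >= min_separation_s))
        kept <- c(kept, k)
    }
    tibble::tibble(time_s = clean$time_s[idx[kept]],
                   value = x[idx[kept]], type = type,
                   prominence = prom[kept])
  }
  out <- dplyr::bind_rows(one_type(x, "peak"), one_type(-x, "trough"))
  if (!nrow(out)) {
    return(tibble::tibble(time_s = numeric(), value = numeric(),
                          type = character(), prominence = numeric()))
  }
  dplyr::arrange(out, .data$time_s)
}

#' Label gait events from candidate extrema
#'
#' Each dominant positive peak is labelled max swing velocity (MSV); its
#' nearest preceding trough becomes toe-off (TO) and its nearest following
#' trough heel strike (HS). Peaks without a flanking trough on either side
#' (incomplete leading/trailing cycles) are dropped. The result satisfies
#' TO(n) < MSV(n) < HS(n) < TO(n+1) for every cycle n.
#'
#' @param extrema Candidate extrema from [detect_extrema()] (at least 3).
#' @return An event series tibble: `cycle`, `label` (`TO`/`MSV`/`HS`),
#'   `time_s`, strictly increasing in time.
#' @export
label_events <- function(extrema) {
  if (nrow(extrema) < 3L)
    abort("Need at least 3 candidate extrema to label gait events.",
          class = "gaitcog_insufficient_gait")
  peaks <- extrema[extrema$type == "peak", ]
  troughs <- extrema[extrema$type == "trough", ]
  # Dominance: assign flanking troughs to peaks in descending prominence;
  # a peak whose nearest flanking trough is already claimed by a more
  # prominent peak is a secondary ripple (e.g. a stance-baseline bump), not
  # a mid-swing peak, and is dropped.
  claimed <- numeric()
  rows <- purrr::map(order(-peaks$prominence), function(i) {
    tm <- peaks$time_s[i]
    before <- troughs$time_s[troughs$time_s < tm]
    after <- troughs$time_s[troughs$time_s > tm]
    if (!length(before) || !length(after)) return(NULL)
    to <- max(before); hs <- min(after)
    if (to %in% claimed || hs %in% claimed) return(NULL)
    claimed <<- c(claimed, to, hs)
    tibble::tibble(label = c("TO", "MSV", "HS"), time_s = c(to, tm, hs))
  })
  rows <- purrr::compact(rows)
  rows <- rows[order(vapply(rows, function(r) r$time_s[2], 0))]
  if (length(rows) < 2L)
    abort("Fewer than 2 complete gait cycles detected.",
          class = "gaitcog_insufficient_gait")
  out <- dplyr::bind_rows(rows, .id = "cycle")
  out$cycle <- as.integer(out$cycle)
  # a trough shared by two peaks would break strict ordering; guard
  if (any(diff(out$time_s) <= 0))
    abort("Labelled events are not strictly ordered; detection failed.",
          class = "gaitcog_insufficient_gait")
  out[, c("cycle", "label", "time_s")]
}

#' Detect and label gait events in one call
#'
#' Convenience wrapper: [detect_extrema()] then [label_events()].
#'
#' @inheritParams detect_extrema
#' @return An event series tibble (`cycle`, `label`, `time_s`).
#' @export
detect_gait_events <- function(clean, min_prominence_frac = 0.5,
                               min_separation_s = 0.25) {
  label_events(detect_extrema(clean, min_prominence_frac, min_separation_s))
}

#' Plot a smoothed signal with labelled gait events
#'
#' @param clean A smoothed recording.
#' @param events An event series from [label_events()].
#' @return A ggplot object.
#' @export
plot_events <- function(clean, events) {
  ev <- dplyr::mutate(events,
                      value = approx(clean$time_s, clean$signal, .data$time_s)$y)
  ggplot2::ggplot(clean, ggplot2::aes(x = .data$time_s, y = .data$signal)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = ev,
                        ggplot2::aes(colour = .data$label), size = 2) +
    ggplot2::labs(x = "time (s)", y = "shank signal", colour = NULL) +
    ggplot2::theme_minimal()
}
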