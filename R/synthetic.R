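#' Stride parameters for the walk simulator
#'
#' Bundles the per-walk ground-truth parameters of the synthetic shank
#' signal: phase durations, walking speed, waveform amplitude, additive
#' noise and stride-to-stride timing variability. Defaults follow the
#' temporal gait values typical of healthy middle-aged adults walking at
#' self-selected pace (swing ~0.50 s, stance ~0.51 s, velocity ~1.35 m/s).
#'
#' @param swing_s Swing time in seconds (toe-off to heel-strike); > 0.
#' @param stance_s Stance time in seconds (heel-strike to next toe-off); > 0.
#' @param velocity_mps Walking velocity in m/s; > 0.
#' @param amplitude Waveform amplitude in arbitrary signal units.
#' @param noise_sd Standard deviation of additive Gaussian noise, same units
#'   as `amplitude`; >= 0.
#' @param stride_jitter_cov Stride-to-stride timing variability as a
#'   coefficient of variation in percent of the mean stride time; >= 0.
#' @return An object of class `stride_params`.
#' @examples
#' stride_params()
#' stride_params(velocity_mps = 1.12, noise_sd = 0.09)
#' @export
stride_params <- function(swing_s = 0.50, stance_s = 0.51, velocity_mps = 1.35,
                          amplitude = 1, noise_sd = 0.05,
                          stride_jitter_cov = 3) {
  assert_scalar_number(swing_s, "swing_s", lower = 0, strict = TRUE)
  assert_scalar_number(stance_s, "stance_s", lower = 0, strict = TRUE)
  assert_scalar_number(velocity_mps, "velocity_mps", lower = 0, strict = TRUE)
  assert_scalar_number(amplitude, "amplitude", lower = 0, strict = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(stride_jitter_cov, "stride_jitter_cov", lower = 0)
  structure(
    list(swing_s = swing_s, stance_s = stance_s, velocity_mps = velocity_mps,
         amplitude = amplitude, noise_sd = noise_sd,
         stride_jitter_cov = stride_jitter_cov),
    class = "stride_params"
  )
}

#' @export
print.stride_params <- function(x, ...) {
  cat("<stride_params> swing", x$swing_s, "s | stance", x$stance_s,
      "s | velocity", x$velocity_mps, "m/s | jitter", x$stride_jitter_cov,
      "% | noise sd", x$noise_sd, "\n")
  invisible(x)
}

# One gait cycle as a smooth unit-amplitude shape on phase [0, 1):
# a dominant positive mid-swing peak (MSV) flanked by a toe-off trough
# before it and a heel-strike trough after it, with a flat stance tail.
# Event phases: TO at p_to, MSV at p_to + swing/2, HS at p_to + swing
# (all as fractions of the cycle), so swing = HS - TO by construction.
unit_cycle <- function(phase, swing_frac, p_to = 0.06) {
  p_msv <- p_to + swing_frac / 2
  p_hs <- p_to + swing_frac
  sm <- swing_frac / 7
  st <- swing_frac / 11
  exp(-(phase - p_msv)^2 / (2 * sm^2)) -
    0.55 * exp(-(phase - p_to)^2 / (2 * st^2)) -
    0.50 * exp(-(phase - p_hs)^2 / (2 * st^2))
}

event_phases <- function(swing_frac, p_to = 0.06) {
  c(TO = p_to, MSV = p_to + swing_frac / 2, HS = p_to + swing_frac)
}

# Snap a nominal event time to the nearest sampled extremum of the
# noise-free signal, searching a small window around the nominal time.
refine_event <- function(time_s, value, t_nominal, kind, halfwin_s) {
  idx <- which(time_s >= t_nominal - halfwin_s & time_s <= t_nominal + halfwin_s)
  if (length(idx) == 0L) return(t_nominal)
  pick <- if (kind == "max") idx[which.max(value[idx])] else idx[which.min(value[idx])]
  time_s[pick]
}

#' One-cycle stride waveform template
#'
#' Samples a single gait cycle of the synthetic shank signal at rate `fs`
#' and returns the template together with the within-cycle event offsets
#' (toe-off, max swing velocity, heel strike) taken at the template's own
#' sampled extrema.
#'
#' @param params A [stride_params()] object.
#' @param fs Sampling rate in Hz; must be at least 50.
#' @param seed Optional seed for the additive noise draw.
#' @return A list with `template` (tibble: `time_s`, `signal`) and `events`
#'   (tibble: `label`, `offset_s`), plus the cycle duration `cycle_s`.
#' @examples
#' w <- stride_waveform(stride_params(noise_sd = 0))
#' w$events
#' @export
stride_waveform <- function(params, fs = 200, seed = NULL) {
  stopifnot(inherits(params, "stride_params"))
  if (fs < 50)
    abort("`fs` must be at least 50 Hz to resolve gait events.",
          class = "gaitcog_low_rate")
  cycle_s <- params$swing_s + params$stance_s
  swing_frac <- params$swing_s / cycle_s
  n <- round(cycle_s * fs)
  time_s <- (seq_len(n) - 1) / fs
  clean <- params$amplitude * unit_cycle(time_s / cycle_s, swing_frac)
  ph <- event_phases(swing_frac)
  halfwin <- max(0.04 * cycle_s, 3 / fs)
  offsets <- c(
    refine_event(time_s, clean, ph[["TO"]] * cycle_s, "min", halfwin),
    refine_event(time_s, clean, ph[["MSV"]] * cycle_s, "max", halfwin),
    refine_event(time_s, clean, ph[["HS"]] * cycle_s, "min", halfwin)
  )
  signal <- if (params$noise_sd > 0) {
    with_seed(seed, clean + rnorm(n, 0, params$noise_sd))
  } else clean
  list(
    template = tibble::tibble(time_s = time_s, signal = signal),
    events = tibble::tibble(label = c("TO", "MSV", "HS"), offset_s = offsets),
    cycle_s = cycle_s
  )
}

#' Simulate a 20 m walking task with known ground truth
#'
#' Generates a uniformly sampled shank motion signal for a straight walk of
#' `distance_m` metres split into two halves by a turn, at the stride
#' parameters in `params`. The turn is modelled as a single long-duration,
#' low-amplitude pseudo-stride, which is what the downstream
#' two-standard-deviation artifact rule is designed to remove. The returned
#' ground truth lists every event timestamp (turn pseudo-events flagged
#' `in_turn`), the turn interval, the true stride durations and the true
#' average velocity (distance over the summed stride times, turn excluded).
#'
#' @param params A [stride_params()] object.
#' @param task Task tag: `"normal"`, `"fast"` or `"dual"`.
#' @param fs Sampling rate in Hz (>= 50).
#' @param seed Optional integer seed; the same seed reproduces the walk
#'   bit-for-bit.
#' @param distance_m Total walking distance in metres (default 20: 10 m out,
#'   turn, 10 m back).
#' @param turn Insert the turn pseudo-stride? (default `TRUE`).
#' @param foot Which foot the virtual sensor is strapped to.
#' @param lead_s Quiet baseline padding before and after the walk, seconds.
#' @param turn_scale Turn pseudo-stride duration as a multiple of the mean
#'   stride time.
#' @return A list of class `gait_walk` with elements `recording` (tibble:
#'   `time_s`, `signal`; sampling rate in `attr(, "fs")`) and `truth`
#'   (events tibble, turn interval, true stride times, true velocity).
#' @examples
#' w <- simulate_walk(stride_params(noise_sd = 0, stride_jitter_cov = 0), seed = 1)
#' w$truth$velocity_mps
#' @export
simulate_walk <- function(params, task = c("normal", "fast", "dual"), fs = 200,
                          seed = NULL, distance_m = 20, turn = TRUE,
                          foot = "left", lead_s = 0.4, turn_scale = 2.5) {
  stopifnot(inherits(params, "stride_params"))
  task <- match.arg(task)
  if (fs < 50)
    abort("`fs` must be at least 50 Hz to resolve gait events.",
          class = "gaitcog_low_rate")
  cycle0 <- params$swing_s + params$stance_s
  half_time <- (distance_m / 2) / params$velocity_mps
  n_half <- max(2L, as.integer(round(half_time / cycle0)))
  cycle_s <- half_time / n_half            # snap so strides tile each 10 m half
  swing_frac <- params$swing_s / cycle0

  with_seed(seed, {
    n_str <- 2L * n_half
    dur <- cycle_s * pmax(0.7, 1 + rnorm(n_str, 0, params$stride_jitter_cov / 100))
    amp <- rep(params$amplitude, n_str)
    is_turn <- rep(FALSE, n_str)
    if (turn) {
      at <- n_half
      dur <- append(dur, turn_scale * cycle_s, after = at)
      amp <- append(amp, 0.35 * params$amplitude, after = at)
      is_turn <- append(is_turn, TRUE, after = at)
    }
    start <- lead_s + cumsum(c(0, head(dur, -1)))
    total <- lead_s + sum(dur) + lead_s
    n <- round(total * fs)
    time_s <- (seq_len(n) - 1) / fs
    clean <- numeric(n)
    ev <- vector("list", length(dur))
    for (k in seq_along(dur)) {
      idx <- which(time_s >= start[k] & time_s < start[k] + dur[k])
      # Stride-duration variation loads on the stance phase only: the swing
      # (TO -> MSV -> HS) keeps its absolute duration in every cycle,
      # including the turn, whose long pause is pure stance. This keeps the
      # MSV anchor at a fixed offset after TO, and makes the turn elevate
      # exactly one MSV-to-MSV interval.
      sc <- cycle_s / dur[k]
      sfk <- swing_frac * sc
      clean[idx] <- clean[idx] +
        amp[k] * unit_cycle((time_s[idx] - start[k]) / dur[k], sfk,
                            p_to = 0.06 * sc)
      nominal <- start[k] + event_phases(sfk, p_to = 0.06 * sc) * dur[k]
      halfwin <- max(0.03 * dur[k], 3 / fs)
      ev[[k]] <- tibble::tibble(
        cycle = k,
        label = c("TO", "MSV", "HS"),
        time_s = c(
          refine_event(time_s, clean, nominal[["TO"]], "min", halfwin),
          refine_event(time_s, clean, nominal[["MSV"]], "max", halfwin),
          refine_event(time_s, clean, nominal[["HS"]], "min", halfwin)
        ),
        in_turn = is_turn[k]
      )
    }
    events <- dplyr::bind_rows(ev)
    signal <- clean + if (params$noise_sd > 0) rnorm(n, 0, params$noise_sd) else 0
    rec <- tibble::tibble(time_s = time_s, signal = signal)
    attr(rec, "fs") <- fs
    attr(rec, "meta") <- list(foot = foot, task = task)
    truth <- list(
      events = events,
      turn_interval = if (turn) c(start = start[is_turn], end = start[is_turn] + dur[is_turn]) else NULL,
      stride_s = dur[!is_turn],
      velocity_mps = distance_m / sum(dur[!is_turn]),
      cycle_s = cycle_s,
      distance_m = distance_m
    )
    structure(list(recording = rec, truth = truth, params = params,
                   task = task, foot = foot, fs = fs),
              class = "gait_walk")
  })
}

# Group-level simulation profile anchored to published temporal gait values
# for healthy controls vs uncomplicated midlife T2DM across the three tasks
# and both feet (velocity, swing, stance means +- SD; stride-time CoV;
# complexity index). One widely noted oddity in the source table - a
# normal-walk velocity SD printed as 1.17 amid SDs of 0.15-0.31 - is
# treated as 0.17.
default_gait_profile <- function() {
  tibble::tribble(
    ~group, ~task, ~foot, ~v_mean, ~v_sd, ~swing_mean, ~swing_sd, ~stance_mean, ~stance_sd, ~cov_mean, ~cov_sd, ~cx_mean, ~cx_sd,
    "control", "normal", "left",  1.35, 0.16, 0.50, 0.04, 0.51, 0.07, 3.14, 1.76, 41.1, 17.2,
    "control", "normal", "right", 1.38, 0.15, 0.52, 0.04, 0.50, 0.07, 2.59, 1.16, 40.9, 16.5,
    "control", "fast",   "left",  1.72, 0.19, 0.48, 0.05, 0.42, 0.07, 4.40, 5.14, 25.0, 14.1,
    "control", "fast",   "right", 1.76, 0.18, 0.47, 0.04, 0.41, 0.06, 4.54, 2.72, 22.2, 10.8,
    "control", "dual",   "left",  1.34, 0.24, 0.54, 0.07, 0.53, 0.12, 5.21, 3.32, 42.1, 25.4,
    "control", "dual",   "right", 1.36, 0.25, 0.54, 0.07, 0.53, 0.11, 5.33, 3.78, 41.6, 26.8,
    "t2dm",    "normal", "left",  1.12, 0.17, 0.52, 0.05, 0.54, 0.07, 3.11, 1.51, 55.2, 26.2,
    "t2dm",    "normal", "right", 1.23, 0.17, 0.53, 0.05, 0.53, 0.06, 2.98, 1.27, 48.7, 22.9,
    "t2dm",    "fast",   "left",  1.53, 0.27, 0.50, 0.07, 0.44, 0.07, 4.32, 4.13, 30.5, 20.0,
    "t2dm",    "fast",   "right", 1.56, 0.25, 0.49, 0.05, 0.45, 0.08, 4.26, 2.41, 27.9, 17.5,
    "t2dm",    "dual",   "left",  1.21, 0.31, 0.55, 0.09, 0.56, 0.10, 5.80, 4.88, 55.7, 34.1,
    "t2dm",    "dual",   "right", 1.21, 0.27, 0.54, 0.11, 0.59, 0.14, 5.20, 3.56, 51.9, 30.5
  )
}

default_covariates <- function() {
  tibble::tribble(
    ~group, ~age_mean, ~age_sd, ~female_frac, ~bmi_mean, ~bmi_sd, ~edu_mean, ~edu_sd,
    "control", 51.9, 8.1, 0.43, 26.6, 3.2, 17.7, 2.2,
    "t2dm",    52.8, 8.3, 0.53, 32.4, 7.8, 17.2, 3.0
  )
}

default_moca_domains <- function() {
  tibble::tribble(
    ~domain, ~max, ~control_mean, ~control_sd, ~t2dm_mean, ~t2dm_sd,
    "visuospatial", 5, 4.9, 0.29, 4.5, 0.74,
    "naming",       3, 3.0, 0.05, 3.0, 0.10,
    "attention",    6, 6.0, 0.05, 5.7, 0.61,
    "language",     3, 3.0, 0.21, 2.8, 0.49,
    "abstraction",  2, 2.0, 0.05, 1.9, 0.30,
    "delayed_recall", 5, 4.2, 0.79, 3.9, 1.21,
    "orientation",  6, 5.9, 0.25, 5.9, 0.24
  )
}

#' Cohort simulation configuration
#'
#' Defines the study conditions for [simulate_cohort()]: group sizes (44
#' healthy controls vs 94 uncomplicated midlife T2DM by default), per-group
#' stride-parameter distributions for the three walking tasks and two feet,
#' covariate distributions (age, sex, BMI, education years), and the
#' gait-to-cognition linkage. Total MoCA is generated as
#' `intercept + linkage * (mean normal-walk velocity) + N(0, residual_sd)`,
#' truncated to \[0, 30\] and rounded last. The default linkage (4 MoCA
#' points per m/s with residual SD 1.5) is calibrated so the pooled-cohort
#' Pearson correlation between normal-walk velocity and MoCA falls in the
#' moderate band (about 0.3-0.5) at n = 138.
#'
#' @param n_control,n_t2dm Group sizes; >= 1.
#' @param gait_profile Per group/task/foot distribution table; see
#'   `default_gait_profile()` used when `NULL`.
#' @param linkage MoCA points per m/s of mean normal-walk velocity.
#' @param intercept MoCA intercept (points).
#' @param residual_sd Residual SD of the continuous MoCA draw; > 0.
#' @param cross_task_rho Within-subject correlation of velocities across
#'   tasks/feet via a shared walker factor, in \[0, 1\].
#' @param noise_sd_control,noise_sd_t2dm Additive signal noise SD per group
#'   (the T2DM default is higher, driving higher signal complexity).
#' @param cantab_loading Velocity loading of the six CANTAB z-scores; the
#'   default (0.15) stays below the 0.3 screening threshold.
#' @param seed Default seed used by [simulate_cohort()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 44, n_t2dm = 94, gait_profile = NULL,
                          linkage = 4, intercept = 23, residual_sd = 1.5,
                          cross_task_rho = 0.7, noise_sd_control = 0.05,
                          noise_sd_t2dm = 0.09, cantab_loading = 0.15,
                          seed = 1L) {
  assert_scalar_number(n_control, "n_control", lower = 1)
  assert_scalar_number(n_t2dm, "n_t2dm", lower = 1)
  assert_scalar_number(residual_sd, "residual_sd", lower = 0, strict = TRUE)
  if (cross_task_rho < 0 || cross_task_rho > 1)
    abort("`cross_task_rho` must lie in [0, 1].", class = "gaitcog_invalid_parameter")
  gait_profile <- gait_profile %||% default_gait_profile()
  needed <- c("group", "task", "foot", "v_mean", "v_sd", "swing_mean",
              "swing_sd", "stance_mean", "stance_sd", "cov_mean", "cov_sd",
              "cx_mean", "cx_sd")
  if (!all(needed %in% names(gait_profile)))
    abort("`gait_profile` is missing required columns.",
          class = "gaitcog_invalid_parameter")
  if (any(gait_profile$v_sd < 0 | gait_profile$swing_sd < 0 |
            gait_profile$stance_sd < 0 | gait_profile$cov_sd < 0))
    abort("Distribution SDs must all be >= 0.", class = "gaitcog_invalid_parameter")
  structure(
    list(n_control = as.integer(n_control), n_t2dm = as.integer(n_t2dm),
         gait_profile = gait_profile, covariates = default_covariates(),
         moca_domains = default_moca_domains(),
         linkage = linkage, intercept = intercept, residual_sd = residual_sd,
         cross_task_rho = cross_task_rho,
         noise_sd = c(control = noise_sd_control, t2dm = noise_sd_t2dm),
         cantab_loading = cantab_loading, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Simulate a two-group gait and cognition cohort
#'
#' Draws a cohort under a [cohort_config()]: per-subject covariates, true
#' per-walk gait summaries for every task and foot, MoCA total and
#' subdomains coupled to normal-walk velocity, and CANTAB z-scores with a
#' sub-threshold velocity loading. With `signals = TRUE` the true stride
#' parameters are additionally rendered into raw recordings with
#' ground-truth events via [simulate_walk()], so the full processing chain
#' can run end to end.
#'
#' @param config A [cohort_config()].
#' @param signals Also generate raw recordings? (slower; default `FALSE`).
#' @param seed Integer seed; defaults to `config$seed`. Fixed seeds make the
#'   cohort bit-reproducible.
#' @param fs Sampling rate for generated recordings, Hz.
#' @return A list of class `gait_cohort` with `cohort` (one row per
#'   subject), `gait` (one row per subject/foot/task with columns
#'   `velocity_mps`, `swing_s`, `stance_s`, `stride_s`, `cov_pct`,
#'   `complexity`), and, when `signals = TRUE`, `recordings` (named list of
#'   `gait_walk` objects keyed `subject_foot_task`).
#' @examples
#' ch <- simulate_cohort(cohort_config(n_control = 5, n_t2dm = 10), seed = 7)
#' head(ch$gait)
#' @export
simulate_cohort <- function(config = cohort_config(), signals = FALSE,
                            seed = config$seed, fs = 200) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    n <- config$n_control + config$n_t2dm
    subject <- sprintf("S%03d", seq_len(n))
    group <- c(rep("control", config$n_control), rep("t2dm", config$n_t2dm))
    cov <- config$covariates[match(group, config$covariates$group), ]
    cohort <- tibble::tibble(
      subject = subject, group = group,
      age = round(rnorm(n, cov$age_mean, cov$age_sd), 1),
      sex = ifelse(rbinom(n, 1, cov$female_frac) == 1, "female", "male"),
      bmi = round(pmax(16, rnorm(n, cov$bmi_mean, cov$bmi_sd)), 1),
      education_yr = round(pmax(6, rnorm(n, cov$edu_mean, cov$edu_sd)))
    )

    rho <- config$cross_task_rho
    walker <- rnorm(n)   # shared per-subject mobility factor
    prof <- config$gait_profile
    grid <- tidyr::expand_grid(subject = subject,
                               task = c("normal", "fast", "dual"),
                               foot = c("left", "right"))
    grid$group <- group[match(grid$subject, subject)]
    grid <- dplyr::left_join(grid, prof, by = c("group", "task", "foot"))
    # one task-level innovation shared by both feet, plus a small foot term
    task_eps <- rnorm(n * 3)
    names(task_eps) <- paste(rep(subject, each = 3),
                             rep(c("normal", "fast", "dual"), n), sep = ".")
    eps_t <- task_eps[paste(grid$subject, grid$task, sep = ".")]
    u <- walker[match(grid$subject, subject)]
    gait <- grid |>
      dplyr::mutate(
        velocity_mps = pmax(0.4, .data$v_mean + .data$v_sd *
                              (rho * u + sqrt(1 - rho^2) * eps_t) +
                              0.2 * .data$v_sd * rnorm(dplyr::n())),
        swing_s = pmax(0.25, .data$swing_mean + .data$swing_sd *
                         (-0.3 * u + sqrt(1 - 0.3^2) * rnorm(dplyr::n()))),
        stance_s = pmax(0.25, .data$stance_mean + .data$stance_sd *
                          (-0.4 * u + sqrt(1 - 0.4^2) * rnorm(dplyr::n()))),
        stride_s = .data$swing_s + .data$stance_s,
        cov_pct = pmax(0.5, .data$cov_mean + (.data$cov_sd / 2) * rnorm(dplyr::n())),
        complexity = pmax(1, .data$cx_mean + .data$cx_sd * rnorm(dplyr::n()))
      ) |>
      dplyr::select("subject", "group", "task", "foot", "velocity_mps",
                    "swing_s", "stance_s", "stride_s", "cov_pct", "complexity")

    v_norm <- gait |>
      dplyr::filter(.data$task == "normal") |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(v = mean(.data$velocity_mps), .groups = "drop")
    v_norm <- v_norm$v[match(subject, v_norm$subject)]
    moca_cont <- config$intercept + config$linkage * v_norm +
      rnorm(n, 0, config$residual_sd)
    cohort$moca_total <- round(pmin(30, pmax(0, moca_cont)))

    dom <- config$moca_domains
    for (i in seq_len(nrow(dom))) {
      m <- ifelse(group == "control", dom$control_mean[i], dom$t2dm_mean[i])
      s <- ifelse(group == "control", dom$control_sd[i], dom$t2dm_sd[i])
      cohort[[paste0("moca_", dom$domain[i])]] <-
        pmin(dom$max[i], pmax(0, round(rnorm(n, m, s))))
    }
    lam <- config$cantab_loading
    zv <- as.numeric(scale(v_norm))
    for (task_nm in c("pal", "swm", "prm", "rti", "ots", "rvp")) {
      cohort[[paste0("cantab_", task_nm)]] <-
        round(lam * zv + sqrt(1 - lam^2) * rnorm(n), 3)
    }

    recordings <- NULL
    if (signals) {
      keys <- paste(gait$subject, gait$foot, gait$task, sep = "_")
      recordings <- purrr::map(seq_len(nrow(gait)), function(i) {
        row <- gait[i, ]
        p <- stride_params(
          swing_s = row$swing_s, stance_s = row$stance_s,
          velocity_mps = row$velocity_mps,
          noise_sd = unname(config$noise_sd[[row$group]]),
          stride_jitter_cov = row$cov_pct
        )
        simulate_walk(p, task = row$task, fs = fs, foot = row$foot,
                      seed = stage_seed(seed, keys[i]))
      })
      names(recordings) <- keys
    }
    structure(list(cohort = cohort, gait = gait, recordings = recordings,
                   config = config, seed = seed),
              class = "gait_cohort")
  })
}

#' Widen a per-walk gait table to one row per subject
#'
#' Pivots the long `gait` table from [simulate_cohort()] (or a pipeline run)
#' to one row per subject with columns named `<metric>_<task>_<foot>`, e.g.
#' `velocity_mps_normal_left` — the layout used for correlation screening
#' and the cognition models.
#'
#' @param gait A tibble with columns `subject`, `task`, `foot` and gait
#'   metric columns.
#' @param metrics Metric columns to spread.
#' @return A wide tibble, one row per subject.
#' @export
widen_gait <- function(gait, metrics = c("velocity_mps", "swing_s", "stance_s",
                                         "stride_s", "cov_pct", "complexity")) {
  metrics <- intersect(metrics, names(gait))
  gait |>
    dplyr::select("subject", "task", "foot", dplyr::all_of(metrics)) |>
    tidyr::pivot_wider(names_from = c("task", "foot"),
                       values_from = dplyr::all_of(metrics),
                       names_sep = "_")
}
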