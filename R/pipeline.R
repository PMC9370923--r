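# Orchestration: simulate (or load) -> preprocess -> events -> temporal
# features -> complexity -> screening -> model validation, as one
# reproducible run with a manifest.

#' Read a recording from a delimited text file
#'
#' Expects a tab-separated file with a `time_s` column plus one or more
#' numeric signal columns (e.g. `ax`, `ay`, `az`). The sampling rate is
#' inferred from the median sample interval; non-monotone or non-uniform
#' (> 1% jitter) time columns are rejected.
#'
#' @param path File path.
#' @return A validated recording tibble (see [as_recording()]).
#' @export
read_recording <- function(path) {
  if (!file.exists(path))
    abort(sprintf("Recording file not found: %s", path), class = "gaitcog_format")
  tryCatch(
    as_recording(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)),
    error = function(e) abort(sprintf("Invalid recording %s: %s",
                                      path, conditionMessage(e)),
                              class = "gaitcog_format"))
}

#' Write a recording to a delimited text file
#'
#' @param rec A recording tibble.
#' @param path Output path (tab-separated text).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  readr::write_tsv(rec, path, progress = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end run. The default simulated
#' cohort is intentionally small (12 subjects in the same 1:2
#' control-to-T2DM ratio as the full design); pass a larger
#' [cohort_config()] for bigger runs, or `input_dir` to process recordings
#' from disk (written by [write_recording()], with a `cohort.tsv` metadata
#' table).
#'
#' @param out_dir Output directory for all stage outputs and the manifest.
#' @param cohort A [cohort_config()] for simulation mode.
#' @param input_dir Optional directory of existing recordings (overrides
#'   simulation).
#' @param seed Master seed; per-stage seeds are derived from it by stage
#'   name, so adding a stage does not perturb earlier stages' draws.
#' @param cutoff_hz Butterworth low-pass cutoff.
#' @param trim Optional `c(start, end)` trim window applied to every
#'   recording.
#' @param min_prominence_frac,min_separation_s Event-detection settings.
#' @param sampen_m,sampen_r,tau_max Multiscale-entropy settings.
#' @param screen_threshold Absolute-correlation selection threshold.
#' @param repeats Validation repeats for the cognition models.
#' @param nn_max_epochs,nn_patience Network training settings.
#' @param run_models Fit and validate the cognition models? (needs enough
#'   subjects).
#' @param verbose Print stage progress.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, cohort = cohort_config(n_control = 4, n_t2dm = 8),
                            input_dir = NULL, seed = 1L, cutoff_hz = 10,
                            trim = NULL, min_prominence_frac = 0.5,
                            min_separation_s = 0.25, sampen_m = 2,
                            sampen_r = 0.2, tau_max = 40,
                            screen_threshold = 0.3, repeats = 20,
                            nn_max_epochs = 10000, nn_patience = 50,
                            run_models = TRUE, verbose = FALSE) {
  structure(list(out_dir = out_dir, cohort = cohort, input_dir = input_dir,
                 seed = as.integer(seed), cutoff_hz = cutoff_hz, trim = trim,
                 min_prominence_frac = min_prominence_frac,
                 min_separation_s = min_separation_s, sampen_m = sampen_m,
                 sampen_r = sampen_r, tau_max = tau_max,
                 screen_threshold = screen_threshold, repeats = repeats,
                 nn_max_epochs = nn_max_epochs, nn_patience = nn_patience,
                 run_models = run_models, verbose = verbose),
            class = "pipeline_config")
}

say <- function(cfg, ...) if (isTRUE(cfg$verbose)) message(...)

# Process one recording through preprocess -> events -> summary, wrapping
# failures with the offending subject/foot/task.
process_recording <- function(rec, cfg, subject, foot, task) {
  tryCatch({
    clean <- preprocess_recording(rec, trim = cfg$trim, cutoff_hz = cfg$cutoff_hz)
    events <- detect_gait_events(clean, cfg$min_prominence_frac,
                                 cfg$min_separation_s)
    mse <- suppressWarnings(
      mse_curve(clean$signal_raw, m = cfg$sampen_m, r = cfg$sampen_r,
                tau_max = cfg$tau_max))
    suppressWarnings(
      summarize_walk(clean, events, mse, subject = subject,
                     foot = foot, task = task))
  }, error = function(e) {
    abort(sprintf("Stage failed for %s/%s/%s: %s", subject, foot, task,
                  conditionMessage(e)),
          class = "gaitcog_pipeline", parent = e)
  })
}

load_input_dir <- function(dir) {
  cohort_path <- file.path(dir, "cohort.tsv")
  if (!file.exists(cohort_path))
    abort("`input_dir` must contain a cohort.tsv metadata table.",
          class = "gaitcog_format")
  cohort <- readr::read_tsv(cohort_path, show_col_types = FALSE, progress = FALSE)
  files <- list.files(dir, pattern = "_(left|right)_(normal|fast|dual)\\.tsv$",
                      full.names = TRUE)
  recs <- purrr::map(files, function(f) {
    parts <- strsplit(sub("\\.tsv$", "", basename(f)), "_")[[1]]
    np <- length(parts)
    list(rec = read_recording(f),
         subject = paste(parts[seq_len(np - 2)], collapse = "_"),
         foot = parts[np - 1], task = parts[np])
  })
  list(cohort = cohort, recs = recs)
}

#' Run the full gait-to-cognition pipeline
#'
#' Executes every stage under a master seed and writes all outputs to
#' `cfg$out_dir`: `cohort.tsv` (subject covariates and cognitive scores),
#' `gait_summaries.tsv` (one row per subject/foot/task), `screening.tsv`
#' (Pearson screening of gait variables against MoCA), `validation.json`
#' (MLR vs network MAE reports and their paired comparison) and
#' `manifest.json` (parameters, outputs, counts). Reruns with the same
#' configuration and seed reproduce every output byte-identically.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `pipeline_run` with the in-memory tables and
#'   the manifest, invisibly writable artifacts already on disk.
#' @export
run_gait_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(cfg$input_dir)) {
    say(cfg, "simulating cohort")
    sim <- simulate_cohort(cfg$cohort, signals = TRUE,
                           seed = stage_seed(cfg$seed, "simulate"))
    cohort <- sim$cohort
    recs <- purrr::imap(sim$recordings, function(w, key) {
      list(rec = w$recording, subject = strsplit(key, "_")[[1]][1],
           foot = w$foot, task = w$task)
    })
  } else {
    say(cfg, "loading recordings from ", cfg$input_dir)
    inp <- load_input_dir(cfg$input_dir)
    cohort <- inp$cohort
    recs <- inp$recs
  }

  say(cfg, "extracting gait summaries from ", length(recs), " recordings")
  summaries <- dplyr::bind_rows(purrr::map(recs, function(r)
    process_recording(r$rec, cfg, r$subject, r$foot, r$task)))

  wide <- widen_gait(summaries)
  joined <- dplyr::inner_join(cohort, wide, by = "subject")
  gait_cols <- setdiff(names(wide), "subject")
  cog_cols <- intersect(c("moca_total"), names(joined))
  say(cfg, "screening correlations")
  screening <- if (nrow(joined) >= 3) {
    screen_correlations(joined, gait_cols, cog_cols,
                        threshold = cfg$screen_threshold)
  } else {
    tibble::tibble(gait_var = character(), cog_var = character(),
                   r = numeric(), n = integer(), selected = logical(),
                   degenerate = logical())
  }

  validation <- NULL
  comparison <- NULL
  if (isTRUE(cfg$run_models)) {
    say(cfg, "validating cognition models")
    vel_inputs <- grep("^velocity_mps_", gait_cols, value = TRUE)
    rep_mlr <- validate_model(joined, vel_inputs, "moca_total", model = "mlr",
                              repeats = cfg$repeats,
                              seed = stage_seed(cfg$seed, "validate_mlr"))
    rep_nn <- validate_model(joined, vel_inputs, "moca_total", model = "nn",
                             repeats = cfg$repeats,
                             seed = stage_seed(cfg$seed, "validate_nn"),
                             max_epochs = cfg$nn_max_epochs,
                             patience = cfg$nn_patience)
    comparison <- compare_models(rep_nn, rep_mlr)
    validation <- list(mlr = glance(rep_mlr), nn = glance(rep_nn),
                       per_repeat = list(mlr = rep_mlr$mae$mae,
                                         nn = rep_nn$mae$mae),
                       comparison = comparison)
  }

  readr::write_tsv(cohort, file.path(cfg$out_dir, "cohort.tsv"), progress = FALSE)
  readr::write_tsv(summaries, file.path(cfg$out_dir, "gait_summaries.tsv"),
                   progress = FALSE)
  readr::write_tsv(screening, file.path(cfg$out_dir, "screening.tsv"),
                   progress = FALSE)
  if (!is.null(validation))
    jsonlite::write_json(validation, file.path(cfg$out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")

  manifest <- list(
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("cohort", "verbose"))],
    n_subjects = nrow(cohort),
    n_recordings = length(recs),
    n_summaries = nrow(summaries),
    outputs = c("cohort.tsv", "gait_summaries.tsv", "screening.tsv",
                if (!is.null(validation)) "validation.json")
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  structure(list(cohort = cohort, summaries = summaries, screening = screening,
                 validation = validation, comparison = comparison,
                 manifest = manifest, config = cfg),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>", x$manifest$n_subjects, "subjects,",
      x$manifest$n_summaries, "gait summaries ->", x$config$out_dir, "\n")
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
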