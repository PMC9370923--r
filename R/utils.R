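# Internal helpers shared across modules.

# Deterministic per-stage seed derived from a master seed and a stage name,
# so adding a stage never perturbs the draws of earlier stages.
stage_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 7919 + h) %% 2147483647L)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; NULL seed
# leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

assert_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "gaitcog_invalid_parameter")
  if ((strict && x <= lower) || (!strict && x < lower))
    abort(sprintf("`%s` must be %s %s.", name, if (strict) ">" else ">=", lower),
          class = "gaitcog_invalid_parameter")
  invisible(x)
}

#' Coloured (power-law) noise generator
#'
#' Generates Gaussian noise whose power spectral density follows
#' \eqn{1/f^{\alpha}}: `alpha = 0` is white noise, `alpha = 1` is pink
#' (1/f) noise. Used to exercise the multiscale-entropy machinery, whose
#' defining behaviour is that 1/f noise carries more multiscale complexity
#' than white noise of equal variance.
#'
#' @param n Number of samples.
#' @param alpha Spectral exponent (0 = white, 1 = pink).
#' @param sd Target standard deviation of the output.
#' @param seed Optional integer seed.
#' @return A numeric vector of length `n` with (sample) mean 0 and standard
#'   deviation `sd`.
#' @examples
#' w <- colored_noise(1000, alpha = 0, seed = 1)
#' p <- colored_noise(1000, alpha = 1, seed = 1)
#' @export
colored_noise <- function(n, alpha = 1, sd = 1, seed = NULL) {
  assert_scalar_number(n, "n", lower = 2, strict = FALSE)
  assert_scalar_number(sd, "sd", lower = 0, strict = TRUE)
  with_seed(seed, {
    if (alpha == 0) {
      x <- rnorm(n)
    } else {
      # Spectral synthesis: scale white-noise Fourier amplitudes by f^(-alpha/2).
      white <- rnorm(n)
      spec <- fft(white)
      freq <- c(1, seq_len(n - 1))          # guard DC, symmetric tail handled by fft
      f <- pmin(freq, n - freq + 1)         # two-sided frequency index
      spec <- spec * f^(-alpha / 2)
      x <- Re(fft(spec, inverse = TRUE)) / n
    }
    as.numeric(scale(x)) * sd
  })
}
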