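# Internal helpers shared across the package.

# Evaluate `code` under a deterministic RNG state without disturbing the
# caller's stream. `seed = NULL` means "use the current stream as-is".
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

check_positive <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= 0) {
    stop(sprintf("'%s' must be a single finite positive number", field),
         call. = FALSE)
  }
  invisible(value)
}

check_non_negative <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value < 0) {
    stop(sprintf("'%s' must be a single finite non-negative number", field),
         call. = FALSE)
  }
  invisible(value)
}

# Half-power level in dB: 20*log10(sqrt(2)), not the rounded 3.0.
HALF_POWER_DB <- 10 * log10(2)

fmt_num <- function(x) sprintf("%.15g", x)
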