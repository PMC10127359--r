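# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-stage seed derived from the run seed and a stage name, so
# adding a stage never perturbs the draws of earlier stages.
substream_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1)
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 1987654321
  as.integer(((as.numeric(seed) %% 65011 + 1) * 29023 + h) %% .Machine$integer.max)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict) x > lower else x >= lower
  hi_ok <- if (strict) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` = %g is outside its allowed range.", name, x))
  }
  if (integer && abs(x - round(x)) > 1e-8) {
    abort(sprintf("`%s` must be an integer.", name))
  }
  invisible(x)
}

# Significance stars used throughout fit reports.
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "NS"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
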