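# Internal helpers shared across modules.

# Deterministic sub-stream seed derived from a root seed and string keys.
# Polynomial rolling hash mod (2^31 - 1); all intermediates stay below 2^53
# so the arithmetic is exact in doubles on every platform.
derive_seed <- function(seed, ...) {
  m <- 2147483647
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% m
  as.integer(h)
}

# Evaluate `expr` under a derived seed without disturbing the caller's RNG.
with_substream <- function(seed, keys, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(do.call(derive_seed, c(list(seed), as.list(keys))))
  force(expr)
}

stop_wormsleep <- function(..., class = "wormsleep_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && is.na(x))) {
    stop_wormsleep(sprintf("`%s` must be a single number", name))
  }
  if (!is.na(x) && (x < lower || x > upper)) {
    stop_wormsleep(sprintf("`%s` must be in [%s, %s], got %s",
                           name, lower, upper, format(x)))
  }
  invisible(x)
}

check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_wormsleep(sprintf("%s is missing column%s: %s", what,
                           if (length(missing) > 1L) "s" else "",
                           paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Two-sided p-value for a t (or normal, df = Inf) statistic, with the exact
# degenerate conventions used throughout: a zero contrast with zero error
# gives p = 1, a nonzero contrast with zero error gives p = 0.
two_sided_p <- function(estimate, se, df = Inf) {
  if (se == 0 || !is.finite(se)) {
    return(if (abs(estimate) < 1e-12) 1 else 0)
  }
  stat <- estimate / se
  if (is.finite(df)) 2 * pt(-abs(stat), df) else 2 * pnorm(-abs(stat))
}
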