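# Internal helpers: argument validation and scoped RNG control.

stop_petloop <- function(msg, class) {
  rlang::abort(msg, class = paste0("petloop_", class))
}

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_petloop(sprintf("`%s` must be a single finite number.", name), "validation")
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    stop_petloop(
      sprintf("`%s` must be %s %s.", name, if (strict) ">" else ">=", lower),
      "validation"
    )
  }
  invisible(x)
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a child seed from a base seed and a stage name, staying inside the
# 32-bit integer range so downstream set.seed() calls are portable.
child_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- digest::digest(list(seed = as.integer(seed), stage = stage), algo = "crc32")
  (strtoi(substr(h, 1, 7), base = 16L) %% .Machine$integer.max) + 1L
}

# Column-wise check that `df` contains `cols`.
check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_petloop(
      sprintf("`%s` is missing column(s): %s.", name, paste(missing, collapse = ", ")),
      "validation"
    )
  }
  invisible(df)
}
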