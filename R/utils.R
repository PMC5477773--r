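# Internal helpers shared across modules.

# scalar checks ---------------------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE, allow_equal_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name),
          class = "xylevo_parameter_error")
  }
  ok_lo <- if (allow_equal_lower) x >= lower else x > lower
  ok_hi <- if (allow_equal_upper) x <= upper else x < upper
  if (!ok_lo || !ok_hi) {
    abort(sprintf(
      "`%s` = %g is outside the allowed range %s%g, %g%s.",
      name, x,
      if (allow_equal_lower) "[" else "(", lower, upper,
      if (allow_equal_upper) "]" else ")"
    ), class = "xylevo_parameter_error")
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) {
    abort(sprintf("`%s` must be a whole number.", name),
          class = "xylevo_parameter_error")
  }
  invisible(as.integer(x))
}

check_data_frame <- function(x, name, cols) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame.", name),
          class = "xylevo_input_error")
  }
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols)) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  name, paste(missing_cols, collapse = ", ")),
          class = "xylevo_input_error")
  }
  invisible(x)
}

# seeded evaluation ------------------------------------------------------------

# Runs `expr` under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# fixed per-stage offsets so one global seed fans out reproducibly
stage_seed <- function(seed, stage) {
  offsets <- c(growth_sim = 101L, expression_sim = 211L, correlation = 307L,
               panel = 401L)
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

`%||%` <- function(x, y) if (is.null(x)) y else x
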