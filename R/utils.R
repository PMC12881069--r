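# Internal helpers shared across modules.

# Stop unless `cond` is a single TRUE; `msg` is sprintf-style.
assert_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) rlang::abort(sprintf(msg, ...))
  invisible(TRUE)
}

# Require that `data` contains all of `cols`; names the offender.
check_columns <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so package functions never clobber user state.
with_seed <- function(seed, expr) {
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "`seed` must be a single finite number")
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
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stage offset, kept below 2^31.
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 97 + offset) %% 2147483629L)
}

# Two-sided p-value and t CI bounds for a coefficient table.
t_ci <- function(estimate, se, df, level = 0.95) {
  q <- stats::qt(1 - (1 - level) / 2, df = df)
  tibble::tibble(
    conf.low = estimate - q * se,
    conf.high = estimate + q * se,
    p.value = 2 * stats::pt(-abs(estimate / se), df = df)
  )
}
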