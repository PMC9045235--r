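#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' random-number state afterwards, so seeded package functions do not
#' perturb the user's session RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# stop() with the offending field named; used by config/schema validators
stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

#' Round half away from zero
#'
#' Decimal rounding with halves rounded away from zero (so 0.25 -> 0.3 at
#' one decimal), the convention used when formatting reported rates and
#' ratios. Base `round()` rounds half to even, which would print 0.2.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(1.45, 1)   # 1.5
#' round_half_up(-30.05, 1) # -30.1 (away from zero)
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# check a data.frame has exactly the documented columns (order-free)
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
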