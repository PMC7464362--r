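#' @keywords internal
"_PACKAGE"

## Internal validation helpers shared across modules.

stop_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
          sprintf("`%s` must be a single finite number", name))
  stop_if(x < lower || x > upper,
          sprintf("`%s` must be in [%s, %s]", name, lower, upper))
  invisible(x)
}

assert_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  stop_if(length(missing) > 0,
          sprintf("`%s` is missing column(s): %s", name,
                  paste(missing, collapse = ", ")))
  invisible(df)
}

## message() wrapper so stage logging can be silenced in tests
log_msg <- function(...) {
  if (!isTRUE(getOption("mimnet.quiet", FALSE))) message(sprintf(...))
  invisible(NULL)
}
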