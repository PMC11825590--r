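#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds up), used for the one-decimal
#' percentages in reports. Base [round()] rounds half to even, which would
#' turn e.g. 12.45 into 12.4.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5 + 1e-12) / m
}

# package code uses data.table syntax on data.table objects
.datatable.aware <- TRUE

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fast check that a data.frame has (at least) the named columns
require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_input("%s is missing column(s): %s", what, paste(missing, collapse = ", "))
  }
  invisible(df)
}
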