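# Internal helpers shared across modules.

# Round half away from zero (round() rounds half to even, which is wrong for
# reporting percentages and for reconstructing counts from printed statistics).
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

# Scalar/vector numeric validation with a named error message.
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, allow_na = FALSE) {
  if (!is.numeric(x)) {
    stop_invalid(sprintf("'%s' must be numeric", name))
  }
  bad_na <- is.na(x) & !allow_na
  if (any(bad_na)) {
    stop_invalid(sprintf("'%s' contains missing values", name))
  }
  ok <- is.na(x) | (x >= lower & x <= upper)
  if (!all(ok)) {
    stop_invalid(sprintf("'%s' must be in [%s, %s]", name,
                         format(lower), format(upper)))
  }
  if (integer && any(!is.na(x) & x != floor(x))) {
    stop_invalid(sprintf("'%s' must be a whole number", name))
  }
  invisible(x)
}

# Accept logical, or 0/1 numeric, and return logical.
as_flag <- function(x, name) {
  if (is.logical(x)) {
    if (anyNA(x)) stop_invalid(sprintf("'%s' contains missing values", name))
    return(x)
  }
  if (is.numeric(x) && all(x %in% c(0, 1))) {
    return(x == 1)
  }
  stop_invalid(sprintf("'%s' must be logical or 0/1", name))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
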