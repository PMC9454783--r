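# internal numeric helpers

clip01 <- function(x) pmin(1, pmax(0, x))

# round half away from zero (presentation rounding for percent tables);
# base round() rounds half to even
halfUpRound <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# round half up for split sizes (non-negative inputs)
halfUpInt <- function(x) as.integer(floor(x + 0.5 + 1e-9))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_unit <- function(v, what = "value") {
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop(sprintf("%s must lie in [0,1]", what), call. = FALSE)
  invisible(v)
}
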