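#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves going up (away from zero for
#' the non-negative quantities used throughout this package), the convention
#' used for all reported percentages. Base [round()] rounds halves to even,
#' which would turn e.g. 127.5 into 128 but 26.745 into 26.74.
#'
#' @param x numeric vector (assumed non-negative).
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
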