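#' Print a p-value at one significant digit, scientific
#'
#' Formats `10^log10_p` in the style of published rule tables:
#' one-significant-digit scientific notation with the leading digit
#' truncated toward zero (1.5e-185 prints as `1e-185`, 2.4e-172 as
#' `2e-172`).  Working from `log10_p` keeps the format exact far below
#' the double underflow threshold.
#'
#' @param log10_p base-10 log of the p-value (`<= 0`).
#' @return character scalar such as `"1e-196"` or `"1e+0"`.
#' @examples
#' format_p_printed(-195.81)
#' @export
format_p_printed <- function(log10_p) {
  stopifnot(length(log10_p) == 1L, is.finite(log10_p))
  if (log10_p >= 0) return("1e+0")
  e <- floor(log10_p + 1e-9)
  mant <- 10^(log10_p - e)
  d <- floor(mant + 1e-6)
  if (d >= 10) { d <- 1; e <- e + 1 }
  sprintf("%de%+d", d, e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
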