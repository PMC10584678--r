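#' Static-field context for a nucleus
#'
#' Bundles the spectrometer field (expressed, as is conventional, by the
#' proton Larmor frequency in MHz) with the observed nucleus and the
#' resulting ppm-to-angular-frequency conversion.  At 850 MHz the amide
#' nitrogen Larmor frequency is about 86.1 MHz.
#'
#' @param h1_mhz Proton Larmor frequency of the spectrometer, MHz.
#' @param nucleus `"15N"` or `"1HN"`.
#' @return An object of class `field_context` with elements `h1_mhz`,
#'   `nucleus`, `larmor_mhz` (magnitude of the nucleus Larmor frequency)
#'   and `ppm2rad` (rad/s per ppm).
#' @examples
#' f <- field_context(850, "15N")
#' f$larmor_mhz  # ~86.1
#' @export
field_context <- function(h1_mhz, nucleus = c("15N", "1HN")) {
  assert_num(h1_mhz, "h1_mhz", positive = TRUE, len = 1)
  nucleus <- match.arg(nucleus)
  # gyromagnetic ratio quotient |gamma_X / gamma_1H|
  ratio <- switch(nucleus, "15N" = 0.10136767, "1HN" = 1.0)
  larmor <- h1_mhz * ratio
  structure(
    list(h1_mhz = h1_mhz, nucleus = nucleus, larmor_mhz = larmor,
         ppm2rad = 2 * pi * larmor),
    class = "field_context"
  )
}

#' @export
print.field_context <- function(x, ...) {
  cat(sprintf("<field_context> %s at %.0f MHz 1H (Larmor %.2f MHz, %.1f rad/s per ppm)\n",
              x$nucleus, x$h1_mhz, x$larmor_mhz, x$ppm2rad))
  invisible(x)
}
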