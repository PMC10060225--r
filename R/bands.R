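#' Canonical frequency band definitions
#'
#' The eight analysis bands conventionally used for anesthesia iEEG spectra
#' (slow 0.1-1, delta 1-4, theta 4-8, alpha 8-15, beta 15-25, gamma 25-55,
#' low gamma 25-40, upper gamma 40-55 Hz) plus the narrow 3-4 Hz band used
#' for the posteromedial-cortex rhythm. Band intervals are half-open
#' `[f_lo, f_hi)` so adjacent bands never share a frequency bin.
#'
#' @param include_3_4hz Include the narrow 3-4 Hz band (default `TRUE`).
#' @return A tibble with columns `band`, `f_lo`, `f_hi`.
#' @examples
#' ieeg_bands()
#' @export
ieeg_bands <- function(include_3_4hz = TRUE) {
  b <- tibble::tribble(
    ~band,         ~f_lo, ~f_hi,
    "slow",          0.1,     1,
    "delta",           1,     4,
    "theta",           4,     8,
    "alpha",           8,    15,
    "beta",           15,    25,
    "gamma",          25,    55,
    "low_gamma",      25,    40,
    "upper_gamma",    40,    55)
  if (include_3_4hz) {
    b <- dplyr::bind_rows(b, tibble::tibble(band = "3-4Hz", f_lo = 3, f_hi = 4))
  }
  b
}

# validate a single (f_lo, f_hi) band against a Nyquist limit
check_band <- function(f_lo, f_hi, nyquist = Inf) {
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo < 0 || f_hi <= f_lo) {
    stop("band must satisfy 0 <= f_lo < f_hi", call. = FALSE)
  }
  if (f_hi > nyquist) {
    stop(sprintf("band upper edge %g Hz exceeds the Nyquist frequency %g Hz",
                 f_hi, nyquist), call. = FALSE)
  }
  invisible(c(f_lo, f_hi))
}
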