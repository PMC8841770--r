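# Daubechies scaling (lowpass synthesis) filters, full double precision.
# dbN has N vanishing moments and 2N taps. The remaining three filters of the
# orthogonal two-channel bank follow from the quadrature-mirror relations.
.db_scaling <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314453416, 0.8365163037378079,
          0.2241438680420134, -0.12940952255126037),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032),
  db8 = c(0.05441584224310401, 0.31287159091429995, 0.6756307362972898,
          0.5853546836542067, -0.015829105256349306, -0.2840155429615469,
          0.0004724845739132828, 0.12874742662047847, -0.017369301001807547,
          -0.044088253930794755, 0.013981027917398282, 0.008746094047405777,
          -0.004870352993451574, -0.00039174037337694705,
          0.0006754494064505693, -0.00011747678412476953)
)

#' Orthogonal wavelet filter bank
#'
#' Returns the four finite impulse responses of the two-channel analysis /
#' synthesis bank for a named Daubechies wavelet. `rec_lo` is the scaling
#' filter; `dec_lo` is its time reverse, and the highpass pair follows from the
#' alternating-sign quadrature-mirror construction.
#'
#' @param wavelet Wavelet name, one of `"db1"`, `"db2"`, `"db4"`, `"db8"`.
#' @return A list with components `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi`
#'   (numeric vectors of equal length) and `length`, the number of taps.
#' @examples
#' f <- wavelet_filters("db8")
#' f$length          # 16 taps (8 vanishing moments)
#' sum(f$rec_lo)     # sqrt(2)
#' @export
wavelet_filters <- function(wavelet = "db8") {
  if (!is.character(wavelet) || length(wavelet) != 1L ||
      !wavelet %in% names(.db_scaling)) {
    stop("unknown wavelet '", paste(wavelet, collapse = ","),
         "'; available: ", paste(names(.db_scaling), collapse = ", "))
  }
  h <- .db_scaling[[wavelet]]
  L <- length(h)
  rec_hi <- (-1)^(seq_len(L) - 1L) * rev(h)
  list(
    dec_lo = rev(h),
    dec_hi = rev(rec_hi),
    rec_lo = h,
    rec_hi = rec_hi,
    length = L
  )
}
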