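## Daubechies-4 decomposition low-pass filter (8 taps), standard normalization
## (coefficients sum to sqrt(2)).
DB4_DEC_LO <- c(-0.010597401785069032, 0.0328830116668852,
                0.030841381835560764, -0.18703481171909309,
                -0.027983769416859854, 0.6308807679298589,
                0.7148465705529157, 0.2303778133088965)

## One analysis step: half-sample symmetric extension by L-1 on both sides,
## valid convolution with the low-pass filter, dyadic downsampling. Output
## length floor((n + L - 1) / 2).
dwt_approx_step <- function(x, lo = DB4_DEC_LO) {
  L <- length(lo)
  n <- length(x)
  if (n < L - 1L) stop("segment too short for the wavelet filter")
  pad <- c(rev(x[seq_len(L - 1L)]), x, rev(x[seq(n - L + 2L, n)]))
  m <- length(pad) - L + 1L
  out <- numeric(m)
  flip <- rev(lo)
  for (j in seq_len(L)) out <- out + flip[j] * pad[j:(j + m - 1L)]
  out[seq(2L, m, by = 2L)][seq_len((n + L - 1L) %/% 2L)]
}

#' Level-k wavelet approximation coefficients
#'
#' Cascaded Daubechies-4 analysis (symmetric padding) keeping only the
#' approximation (low-pass) branch. At 100 Hz and level 4 the approximation
#' band is roughly 0-3.1 Hz, the locomotor band.
#'
#' @param x numeric segment.
#' @param level decomposition depth.
#' @return numeric vector of level-`level` approximation coefficients.
#' @export
dwt_approx <- function(x, level = 4) {
  for (i in seq_len(level)) x <- dwt_approx_step(x)
  x
}
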