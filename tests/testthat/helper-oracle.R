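# Independent single-level DWT reference: explicit boundary extension,
# plain-loop convolution with the analysis filters, dyadic downsampling.
# Deliberately written with scalar loops, sharing no code with the package
# internals.
oracle_dwt_level <- function(x, wavelet = "db8") {
  f <- wavelet_filters(wavelet)
  L <- f$length
  n <- length(x)
  ext <- c(x[(L - 1):1], x, x[n:(n - L + 2)])   # half-sample symmetric
  n_coef <- (n + L - 1) %/% 2
  cA <- numeric(n_coef)
  cD <- numeric(n_coef)
  for (k in seq_len(n_coef)) {
    sa <- 0
    sd <- 0
    for (j in seq_len(L)) {
      v <- ext[2 * k + L - j]
      sa <- sa + f$dec_lo[j] * v
      sd <- sd + f$dec_hi[j] * v
    }
    cA[k] <- sa
    cD[k] <- sd
  }
  list(approx = cA, detail = cD)
}

oracle_dwt_multilevel <- function(x, levels, wavelet = "db8") {
  details <- vector("list", levels)
  a <- x
  for (i in seq_len(levels)) {
    step <- oracle_dwt_level(a, wavelet)
    details[[i]] <- step$detail
    a <- step$approx
  }
  list(approx = a, details = details)
}

# shared phantom model for imaging tests (built once per session)
.test_model_env <- new.env()
test_model <- function() {
  if (is.null(.test_model_env$model)) {
    .test_model_env$model <- build_sensitivity(800)
  }
  .test_model_env$model
}

# spectral band power helper (rectangular-window periodogram)
band_power <- function(x, fs, lo, hi) {
  sp <- Mod(stats::fft(x))^2
  fr <- (seq_along(x) - 1) * fs / length(x)
  sum(sp[fr >= lo & fr <= hi])
}
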