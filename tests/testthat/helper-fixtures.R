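# Factor sets of the two studied layouts
factorial_factors <- chamomile_factors("factorial")
ccd_factors <- chamomile_factors("ccd")

# A balanced one-factor spectra layout with a compact absorption band whose
# amplitude differs by level; support exactly [band_lo, band_hi] nm.
make_band_spectra <- function(n_rep = 4, noise_sd = 0.03, seed = 1,
                              wavelengths = 220:400, band_lo = 330,
                              band_hi = 370, amplitudes = c(1.6, 1.0, 0.6)) {
  fct <- data.frame(T = rep(c("15", "20", "25"), each = n_rep))
  shape <- exp(-0.5 * ((wavelengths - (band_lo + band_hi) / 2) / 12)^2) *
    (wavelengths >= band_lo & wavelengths <= band_hi)
  amp <- stats::setNames(amplitudes, c("15", "20", "25"))
  set.seed(seed)
  X <- outer(amp[fct$T], shape) +
    matrix(stats::rnorm(nrow(fct) * length(wavelengths), 0, noise_sd), nrow(fct))
  colnames(X) <- wavelengths
  list(X = X, factors = fct, wavelengths = wavelengths,
       in_band = wavelengths >= band_lo & wavelengths <= band_hi)
}

# Balanced 3x3x3 layout of factor labels (one run per cell, or n_rep each)
balanced_labels <- function(n_rep = 1) {
  g <- expand.grid(A = c("a1", "a2", "a3"), B = c("b1", "b2", "b3"),
                   C = c("c1", "c2", "c3"), stringsAsFactors = FALSE)
  g[rep(seq_len(nrow(g)), each = n_rep), , drop = FALSE]
}
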