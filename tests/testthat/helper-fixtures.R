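# Shared fixtures: analytic spectra and standard scenarios built in code.

# Ideal Lorentzian magnitude spectrum in dB on the default sweep grid,
# built directly from the closed form (independent of run_sweep).
lorentzian_spectrum <- function(fs, D, freqs = seq(9.98e6, 10.02e6,
                                                  length.out = 200),
                                offset_db = 0) {
  x <- 2 * (freqs - fs) / (D * fs)
  magnitude_spectrum(freqs, offset_db - 10 * log10(1 + x^2))
}

# A clean coagulation scenario; override fields as needed.
test_scenario <- function(sigmoid_center_t = 360, seed = 1, ...) {
  trace_scenario(sigmoid_center_t = sigmoid_center_t, seed = seed, ...)
}
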