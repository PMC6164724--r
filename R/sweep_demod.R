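#' Frequency-sweep configuration
#'
#' Defaults follow the measurement protocol for a 10 MHz crystal: 200
#' frequency points swept linearly from 9.98 MHz to 10.02 MHz, endpoints
#' included.
#'
#' @param f_start,f_stop Sweep limits, Hz, `f_start < f_stop`.
#' @param n_points Number of frequency points, >= 8.
#' @return An object of class `"sweep_config"`.
#' @export
sweep_config <- function(f_start = 9.98e6, f_stop = 10.02e6, n_points = 200) {
  check_positive(f_start, "f_start")
  check_positive(f_stop, "f_stop")
  if (f_start >= f_stop) stop("'f_start' must be below 'f_stop'", call. = FALSE)
  if (n_points < 8) stop("'n_points' must be at least 8", call. = FALSE)
  structure(list(f_start = f_start, f_stop = f_stop,
                 n_points = as.integer(n_points)),
            class = "sweep_config")
}

sweep_frequencies <- function(config) {
  seq(config$f_start, config$f_stop, length.out = config$n_points)
}

#' Device model for the sweep emulator
#'
#' Bundles a loaded resonator with the signal-path gains of the measurement
#' electronics: the transfer function seen on the measurement (QCM)
#' pathway, the unit-gain reference of the calibration pathway, and a
#' constant offset voltage present on every acquisition (removed by the
#' dark-noise calibration). Voltages are in arbitrary units; only ratios
#' between the measurement and calibration pathways enter the magnitude.
#'
#' @param res A [resonator_params()]; its `f0` is the loaded resonance.
#' @param loaded_D Loaded dissipation factor of the resonance.
#' @param gain_meas,gain_cal Pathway gains (arbitrary voltage units).
#' @param dark_offset Length-2 constant offset on the (0 deg, 90 deg)
#'   channels, volts.
#' @return An object of class `"qcm_device"` with a transfer function
#'   `tf(freq)` returning complex values.
#' @export
qcm_device <- function(res, loaded_D, gain_meas = 1, gain_cal = 1,
                       dark_offset = c(0, 0)) {
  stopifnot(inherits(res, "resonator_params"), length(dark_offset) == 2L)
  check_positive(loaded_D, "loaded_D")
  check_positive(gain_meas, "gain_meas")
  check_positive(gain_cal, "gain_cal")
  structure(list(res = res, loaded_D = loaded_D,
                 gain_meas = gain_meas, gain_cal = gain_cal,
                 dark_offset = as.numeric(dark_offset),
                 tf = function(freq) magnitude_response(res, loaded_D, freq)),
            class = "qcm_device")
}

#' Quadrature demodulation of one pathway at one frequency
#'
#' Emulates the per-point protocol of the measurement electronics: the
#' excitation and a reference of the same frequency are mixed and low-pass
#' filtered, once with the reference at 0 deg phase and once at 90 deg,
#' yielding the in-phase and quadrature voltages of the selected pathway.
#' With open switches (`"dark"`) only the offset and noise remain; the
#' calibration pathway returns the unit-gain reference; the measurement
#' pathway returns the resonator response scaled by the measurement gain.
#'
#' @param device A [qcm_device()].
#' @param freq Excitation frequency, Hz.
#' @param pathway One of `"dark"`, `"calibration"`, `"measurement"`.
#' @param noise_sd Gaussian noise sd added to each voltage, volts.
#' @param seed Optional seed making the two noise draws reproducible;
#'   `NULL` draws from the current RNG stream.
#' @return Named numeric vector `c(v_0, v_90)`, volts.
#' @export
demodulate_point <- function(device, freq, pathway,
                             noise_sd = 0, seed = NULL) {
  stopifnot(inherits(device, "qcm_device"))
  check_positive(freq, "freq")
  check_non_negative(noise_sd, "noise_sd")
  signal <- switch(pathway,
    dark = c(0, 0),
    calibration = c(device$gain_cal, 0),
    measurement = {
      H <- device$tf(freq)
      device$gain_meas * Mod(H) * c(cos(Arg(H)), sin(Arg(H)))
    },
    stop(sprintf("unknown pathway '%s'", pathway), call. = FALSE)
  )
  noise <- if (noise_sd > 0) {
    with_preserved_seed(seed, stats::rnorm(2, 0, noise_sd))
  } else {
    c(0, 0)
  }
  v <- device$dark_offset + signal + noise
  names(v) <- c("v_0", "v_90")
  v
}

#' Acquire the full six-voltage tuple at one frequency
#'
#' Runs the three pathways (dark, calibration, measurement) of the
#' per-point protocol and returns one sweep-record row.
#'
#' @inheritParams demodulate_point
#' @return One-row data frame with columns `freq_hz`, `v_dark_0`,
#'   `v_dark_90`, `v_cali_0`, `v_cali_90`, `v_mea_0`, `v_mea_90`.
#' @export
acquire_point <- function(device, freq, noise_sd = 0, seed = NULL) {
  acquire <- function() {
    dark <- demodulate_point(device, freq, "dark", noise_sd)
    cali <- demodulate_point(device, freq, "calibration", noise_sd)
    mea <- demodulate_point(device, freq, "measurement", noise_sd)
    data.frame(freq_hz = freq,
               v_dark_0 = dark[[1L]], v_dark_90 = dark[[2L]],
               v_cali_0 = cali[[1L]], v_cali_90 = cali[[2L]],
               v_mea_0 = mea[[1L]], v_mea_90 = mea[[2L]])
  }
  with_preserved_seed(seed, acquire())
}

#' Calibrated magnitude at one frequency point
#'
#' Converts a six-voltage quadrature record into the calibrated magnitude
#' in dB: each pathway's dark-corrected vector length is taken in dB,
#' \eqn{M_x = 20 \log_{10} \sqrt{(V_{x,0}-V_{dark,0})^2 +
#' (V_{x,90}-V_{dark,90})^2}}, and the device magnitude is
#' \eqn{M_{mea} - M_{cali}}, so 0 dB means the measurement pathway equals
#' the calibration pathway. A dark-corrected measurement vector of exactly
#' zero returns the documented floor sentinel of -200 dB (rather than
#' -Inf) to keep downstream fitting total; a zero dark-corrected
#' calibration vector is a calibration error.
#'
#' @param point A data frame (one or more rows) with the six voltage
#'   columns of [acquire_point()].
#' @return Numeric vector of relative magnitudes, dB.
#' @export
magnitude_at <- function(point) {
  need <- c("v_dark_0", "v_dark_90", "v_cali_0", "v_cali_90",
            "v_mea_0", "v_mea_90")
  if (!all(need %in% names(point))) {
    stop("'point' must contain the six voltage columns", call. = FALSE)
  }
  if (!all(vapply(point[need], function(v) all(is.finite(v)), TRUE))) {
    stop("voltages must all be finite", call. = FALSE)
  }
  cal <- sqrt((point$v_cali_0 - point$v_dark_0)^2 +
                (point$v_cali_90 - point$v_dark_90)^2)
  mea <- sqrt((point$v_mea_0 - point$v_dark_0)^2 +
                (point$v_mea_90 - point$v_dark_90)^2)
  if (any(cal == 0)) {
    stop("calibration error: dark-corrected calibration vector is zero",
         call. = FALSE)
  }
  ifelse(mea == 0, -200, 20 * log10(mea) - 20 * log10(cal))
}

#' Magnitude spectrum container
#'
#' @param freqs Frequencies, Hz, strictly increasing.
#' @param magnitudes Calibrated magnitudes, dB, same length.
#' @return A data frame of class `"magnitude_spectrum"` with columns
#'   `freq_hz` and `magnitude_db`.
#' @export
magnitude_spectrum <- function(freqs, magnitudes) {
  freqs <- as.numeric(freqs)
  magnitudes <- as.numeric(magnitudes)
  if (length(freqs) != length(magnitudes)) {
    stop("'freqs' and 'magnitudes' lengths differ", call. = FALSE)
  }
  if (any(diff(freqs) <= 0)) {
    stop("'freqs' must be strictly increasing", call. = FALSE)
  }
  structure(data.frame(freq_hz = freqs, magnitude_db = magnitudes),
            class = c("magnitude_spectrum", "data.frame"))
}

#' Run a full calibrated frequency sweep
#'
#' Executes the per-point protocol at `n_points` equally spaced
#' frequencies (endpoints included) and assembles the calibrated magnitude
#' spectrum. Deterministic given `seed`.
#'
#' @param config A [sweep_config()].
#' @param device A [qcm_device()].
#' @param noise_sd Per-voltage Gaussian noise sd, volts.
#' @param seed Optional integer seed for the noise draws.
#' @return A [magnitude_spectrum()].
#' @examples
#' dev <- qcm_device(resonator_params(f0 = 1e7), loaded_D = 1e-4)
#' spec <- run_sweep(sweep_config(), dev)
#' @export
run_sweep <- function(config, device, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(config, "sweep_config"), inherits(device, "qcm_device"))
  freqs <- sweep_frequencies(config)
  mags <- with_preserved_seed(seed, {
    vapply(freqs, function(f) {
      magnitude_at(acquire_point(device, f, noise_sd))
    }, numeric(1L))
  })
  magnitude_spectrum(freqs, mags)
}
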