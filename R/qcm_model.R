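#' Shear-wave sensing depth of a QCM sensor in liquid
#'
#' The thickness-shear wave launched by the crystal decays evanescently in a
#' Newtonian liquid; the decay length limits how far from the electrode the
#' sensor can "see". It is
#' \deqn{\delta = \sqrt{\eta / (\pi f_0 \rho)},}
#' with \eqn{\eta} the liquid viscosity, \eqn{\rho} its density and
#' \eqn{f_0} the resonant frequency. For blood plasma on a 10 MHz crystal
#' this is about 210 nm, which is why a thin adhesive coating at the
#' electrode is needed to couple the forming fibrin network to the sensor.
#'
#' @param liquid A [liquid_params()] object.
#' @param f0 Resonant frequency, Hz.
#' @return Sensing (penetration) depth in metres.
#' @examples
#' sensing_depth(liquid_params(eta = 1.42e-3, rho = 1.03e3), f0 = 1e7)
#' @export
sensing_depth <- function(liquid, f0) {
  stopifnot(inherits(liquid, "liquid_params"))
  check_positive(f0, "f0")
  check_positive(liquid$eta, "eta")
  check_positive(liquid$rho, "rho")
  sqrt(liquid$eta / (pi * f0 * liquid$rho))
}

#' Kelvin--Voigt dissipation shift of a film-loaded QCM in liquid
#'
#' Dissipation shift of a crystal carrying a thin viscoelastic film
#' (Kelvin--Voigt solid: shear elasticity `mu1` and viscosity `eta1` in
#' parallel) immersed in a semi-infinite Newtonian liquid:
#' \deqn{\Delta D \approx \frac{1}{\pi f_0 \rho_0 h_0}\left\{
#'   \frac{\eta}{\delta} + 2 h_1 \left(\frac{\eta}{\delta}\right)^2
#'   \frac{\eta_1 \omega}{\mu_1^2 + \omega^2 \eta_1^2}\right\},}
#' where \eqn{\delta} is the sensing depth in the bulk liquid and
#' \eqn{\omega = 2\pi f_0}. The first term is the bulk-liquid loading; the
#' second, non-negative term is the film contribution, linear in film
#' thickness `h1` and vanishing for `h1 = 0`.
#'
#' @param res A [resonator_params()] object.
#' @param liquid A [liquid_params()] object.
#' @param film A [film_params()] object.
#' @return Dissipation shift, dimensionless (typically reported in units of
#'   1e-6).
#' @examples
#' res <- resonator_params()
#' liq <- liquid_params()
#' # bare crystal in plasma: bulk-liquid term only
#' dissipation_shift_kelvin_voigt(res, liq, film_params())
#' @export
dissipation_shift_kelvin_voigt <- function(res, liquid, film) {
  stopifnot(inherits(res, "resonator_params"),
            inherits(liquid, "liquid_params"),
            inherits(film, "film_params"))
  if (film$h1 > 0 && film$mu1 == 0 && film$eta1 == 0) {
    stop("degenerate film: h1 > 0 requires mu1 > 0 or eta1 > 0",
         call. = FALSE)
  }
  delta <- sensing_depth(liquid, res$f0)
  omega <- 2 * pi * res$f0
  eta_over_delta <- liquid$eta / delta
  film_term <- if (film$h1 > 0) {
    2 * film$h1 * eta_over_delta^2 *
      film$eta1 * omega / (film$mu1^2 + omega^2 * film$eta1^2)
  } else {
    0
  }
  (eta_over_delta + film_term) / (pi * res$f0 * res$rho0 * res$h0)
}

#' Complex magnitude response of the loaded resonator
#'
#' Single-peak Lorentzian transfer function used by the sweep emulator. The
#' normative contract is the 3 dB rule: the magnitude peaks at `fs`
#' (the resonator's `f0`), the phase crosses zero there, and the full width
#' at half power equals exactly `loaded_D * fs`, so that the dissipation
#' factor recovered from the curve is the programmed one.
#'
#' @param res A [resonator_params()] object; its `f0` is the loaded resonant
#'   frequency of the curve.
#' @param loaded_D Total loaded dissipation factor (1/Q of the loaded
#'   resonance), dimensionless, > 0.
#' @param freq Frequency (Hz) at which to evaluate; vectorised.
#' @return Complex transfer value(s); `Mod()` gives the magnitude (peak
#'   value 1), `Arg()` the phase in radians.
#' @examples
#' res <- resonator_params(f0 = 1e7)
#' H <- magnitude_response(res, loaded_D = 1e-4, freq = 1e7 + c(-500, 0, 500))
#' 20 * log10(Mod(H))  # half-power points 3.01 dB down
#' @export
magnitude_response <- function(res, loaded_D, freq) {
  stopifnot(inherits(res, "resonator_params"))
  check_positive(loaded_D, "loaded_D")
  if (any(freq <= 0)) stop("'freq' must be positive", call. = FALSE)
  fs <- res$f0
  # |H| = 1/sqrt(1 + x^2) with x = 2 (f - fs) / (D fs): -3 dB at f = fs +/- D fs / 2
  x <- 2 * (freq - fs) / (loaded_D * fs)
  1 / (1 + 1i * x)
}

#' Coagulation trace scenario
#'
#' Parameter set for the seeded simulator of dissipation-vs-time curves
#' during a clotting assay. The morphology follows the canonical shape of a
#' QCM-D coagulation record: a stable (slightly drifting) baseline under
#' liquid load, a short loading-fluctuation artifact when the trigger
#' reagent is pipetted in, a slow dissipation gain while fibrin begins to
#' form, a rapid sigmoidal rise as the thrombin burst accelerates fibrin
#' polymerisation, and a plateau once coagulation completes. White Gaussian
#' noise is added on the dissipation channel.
#'
#' Defaults represent a plasma assay on a 10 MHz crystal: baseline
#' dissipation 5e-4 (the bulk-plasma Kelvin--Voigt loading of such a
#' crystal), drift 2e-6/min (the stability level of a settled chip),
#' noise sd 2.5e-6 (liquid-phase short-term stability; use 1e-6 for a dry
#' chip), a coagulation rise of 1e-4 total over a burst of width 2.5 s, and
#' a frequency channel falling 10 Hz per 2.5e-6 of dissipation rise (the
#' viscoelastic coagulation regime).
#'
#' @param sigmoid_center_t Centre of the logistic rapid rise, s; this is the
#'   ground-truth clot end point. Required.
#' @param seed Integer seed; required, so every simulated trace is
#'   reproducible by construction.
#' @param baseline_D Dissipation at settle, dimensionless.
#' @param drift_rate Baseline drift, dissipation per minute.
#' @param artifact_amplitude,artifact_duration Half-sine loading bump after
#'   the start event: peak height (dimensionless) and length (s).
#' @param slow_rise_rate Pre-burst fibrin-formation slope, dissipation per s.
#' @param sigmoid_amplitude Total rapid-rise dissipation change.
#' @param sigmoid_width Logistic time scale, s.
#' @param noise_sd Gaussian noise sd on the dissipation channel.
#' @param event_times Named numeric vector of reagent-addition instants, s;
#'   must include the start event (default label `"starter"`).
#' @param sample_interval Sampling period, s.
#' @param duration Total record length, s.
#' @param freq_coupling Frequency drop per unit dissipation rise, Hz.
#' @return An object of class `"trace_scenario"`.
#' @export
trace_scenario <- function(sigmoid_center_t,
                           seed,
                           baseline_D = 5e-4,
                           drift_rate = 2e-6,
                           artifact_amplitude = 5e-6,
                           artifact_duration = 8,
                           slow_rise_rate = 1e-7,
                           sigmoid_amplitude = 1e-4,
                           sigmoid_width = 2.5,
                           noise_sd = 2.5e-6,
                           event_times = c(starter = 60),
                           sample_interval = 1,
                           duration = 600,
                           freq_coupling = 4e6) {
  check_positive(sample_interval, "sample_interval")
  check_positive(duration, "duration")
  check_positive(sigmoid_width, "sigmoid_width")
  check_non_negative(noise_sd, "noise_sd")
  check_non_negative(artifact_amplitude, "artifact_amplitude")
  check_non_negative(artifact_duration, "artifact_duration")
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("'seed' must be supplied as a single integer", call. = FALSE)
  }
  if (length(event_times) < 1L || is.null(names(event_times)) ||
      any(!nzchar(names(event_times)))) {
    stop("'event_times' must be a named numeric vector", call. = FALSE)
  }
  if (any(event_times < 0) || any(event_times >= duration)) {
    stop("scenario error: event times must lie within [0, duration)",
         call. = FALSE)
  }
  start_t <- event_times[[1L]]
  if (sigmoid_center_t <= start_t) {
    stop("scenario error: 'sigmoid_center_t' must fall after the start event",
         call. = FALSE)
  }
  structure(list(
    baseline_D = baseline_D, drift_rate = drift_rate,
    artifact_amplitude = artifact_amplitude,
    artifact_duration = artifact_duration,
    slow_rise_rate = slow_rise_rate,
    sigmoid_amplitude = sigmoid_amplitude,
    sigmoid_center_t = sigmoid_center_t,
    sigmoid_width = sigmoid_width,
    noise_sd = noise_sd,
    event_times = event_times,
    sample_interval = sample_interval,
    duration = duration,
    freq_coupling = freq_coupling,
    seed = as.integer(seed)
  ), class = "trace_scenario")
}

# Noiseless dissipation curve of a scenario on a time grid; the artifact
# component can be dropped to define the artifact-free ground truth.
scenario_curve <- function(sc, t, with_artifact = TRUE) {
  start_t <- sc$event_times[[1L]]
  d <- sc$baseline_D + (sc$drift_rate / 60) * t +
    sc$slow_rise_rate * pmax(0, t - start_t) +
    sc$sigmoid_amplitude * stats::plogis((t - sc$sigmoid_center_t) /
                                           sc$sigmoid_width)
  if (with_artifact && sc$artifact_amplitude > 0 && sc$artifact_duration > 0) {
    u <- (t - start_t) / sc$artifact_duration
    bump <- ifelse(u > 0 & u < 1,
                   sc$artifact_amplitude * sin(pi * u), 0)
    d <- d + bump
  }
  d
}

#' Simulate a coagulation dissipation trace
#'
#' Generates a [dissipation_trace()] from a [trace_scenario()]:
#' noiseless morphology (baseline + drift + loading artifact + slow rise +
#' logistic burst) plus white Gaussian noise on the dissipation channel, and
#' a frequency channel `f0 - freq_coupling * (D(t) - baseline_D)`. The
#' output is fully determined by the scenario's seed.
#'
#' The ground-truth clot end point returned alongside the trace is the
#' instant of maximum first derivative of the noiseless, artifact-free
#' curve (the loading artifact is an acquisition nuisance, excluded from
#' the truth just as endpoint detection excludes it by blanking); for a
#' logistic burst this is the logistic centre, up to the drift and
#' slow-rise contributions.
#'
#' @param scenario A [trace_scenario()].
#' @param f0 Carrier resonant frequency for the frequency channel, Hz.
#' @return A list of class `"qcm_simulation"` with elements
#'   `trace` (a [dissipation_trace()]), `truth_end_time` (s),
#'   `truth_clot_time` (s, end point minus start event) and `scenario`.
#' @examples
#' sim <- simulate_trace(trace_scenario(sigmoid_center_t = 360, seed = 1))
#' sim$truth_clot_time
#' @export
simulate_trace <- function(scenario, f0 = 1e7) {
  stopifnot(inherits(scenario, "trace_scenario"))
  t <- seq(0, scenario$duration, by = scenario$sample_interval)
  clean <- scenario_curve(scenario, t, with_artifact = TRUE)
  noise <- with_preserved_seed(scenario$seed,
                               stats::rnorm(length(t), 0, scenario$noise_sd))
  d <- clean + noise
  freq <- f0 - scenario$freq_coupling * (d - scenario$baseline_D)
  events <- data.frame(label = names(scenario$event_times),
                       time = as.numeric(scenario$event_times),
                       stringsAsFactors = FALSE)
  trace <- dissipation_trace(times = t, dissipation = d,
                             frequency = freq, events = events)

  # truth: argmax of the artifact-free noiseless derivative past the start
  truth_curve <- scenario_curve(scenario, t, with_artifact = FALSE)
  dd <- diff(truth_curve) / diff(t)
  mid <- (t[-1] + t[-length(t)]) / 2
  ok <- mid > scenario$event_times[[1L]]
  truth_end <- mid[ok][which.max(dd[ok])]
  structure(list(trace = trace,
                 truth_end_time = truth_end,
                 truth_clot_time = truth_end - scenario$event_times[[1L]],
                 scenario = scenario),
            class = "qcm_simulation")
}

#' @export
print.qcm_simulation <- function(x, ...) {
  cat(sprintf("Simulated coagulation trace: %d samples over %g s, noise sd %g\n",
              length(x$trace$times), x$scenario$duration, x$scenario$noise_sd))
  cat(sprintf("  ground-truth end point %g s (clot time %g s)\n",
              x$truth_end_time, x$truth_clot_time))
  invisible(x)
}
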