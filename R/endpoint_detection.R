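#' Dissipation time series with reagent-addition events
#'
#' Container for a recorded (or simulated) dissipation trace: sampling
#' times, the dimensionless dissipation channel, an optional resonant
#' frequency channel, and the labelled instants at which reagents were
#' added (the APTT starter, the PT reagent, ...).
#'
#' @param times Sampling times, s, strictly increasing.
#' @param dissipation Dissipation factor values, same length as `times`.
#' @param frequency Optional resonant-frequency channel, Hz, same length.
#' @param events A data frame with columns `label` (character) and `time`
#'   (s); every event time must lie within the sampled span.
#' @return An object of class `"dissipation_trace"`.
#' @export
dissipation_trace <- function(times, dissipation, frequency = NULL,
                              events = data.frame(label = character(),
                                                  time = numeric())) {
  times <- as.numeric(times)
  dissipation <- as.numeric(dissipation)
  if (length(times) < 2L) {
    stop("a trace needs at least two samples", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("non-monotone time: 'times' must be strictly increasing",
         call. = FALSE)
  }
  if (length(dissipation) != length(times)) {
    stop("'dissipation' and 'times' lengths differ", call. = FALSE)
  }
  if (!is.null(frequency)) {
    frequency <- as.numeric(frequency)
    if (length(frequency) != length(times)) {
      stop("'frequency' and 'times' lengths differ", call. = FALSE)
    }
  }
  if (!is.data.frame(events) || !all(c("label", "time") %in% names(events))) {
    stop("'events' must be a data frame with columns 'label' and 'time'",
         call. = FALSE)
  }
  events$label <- as.character(events$label)
  events$time <- as.numeric(events$time)
  bad <- events$time < times[1L] | events$time > times[length(times)]
  if (any(bad)) {
    stop(sprintf("event '%s' at t = %g s lies outside the sampled span",
                 events$label[which(bad)[1L]], events$time[which(bad)[1L]]),
         call. = FALSE)
  }
  structure(list(times = times, dissipation = dissipation,
                 frequency = frequency, events = events),
            class = "dissipation_trace")
}

#' @export
print.dissipation_trace <- function(x, ...) {
  cat(sprintf("Dissipation trace: %d samples, t in [%g, %g] s%s\n",
              length(x$times), x$times[1L], x$times[length(x$times)],
              if (is.null(x$frequency)) "" else ", with frequency channel"))
  if (nrow(x$events)) {
    cat("  events:",
        paste(sprintf("%s @ %g s", x$events$label, x$events$time),
              collapse = ", "), "\n")
  }
  invisible(x)
}

event_time <- function(trace, label) {
  i <- match(label, trace$events$label)
  if (is.na(i)) {
    stop(sprintf("no event labelled '%s' in trace", label), call. = FALSE)
  }
  trace$events$time[i]
}

#' Baseline stability gate
#'
#' Before a reagent is added, the chip must show a stable dissipation
#' baseline; the acceptance level used in practice is a variation of about
#' 2e-6 per minute. A straight line is fitted by least squares to the last
#' `window` seconds preceding the first event; the trace passes when the
#' absolute drift slope does not exceed `threshold` and the peak-to-peak
#' residual stays within the drift allowance over the window
#' (`threshold * window / 60`).
#'
#' @param trace A [dissipation_trace()] with at least one event.
#' @param window Baseline window length, s, ending at the first event.
#' @param threshold Maximum allowed drift, dissipation per minute.
#' @return A list with `pass` (logical), `drift_per_min` (signed fitted
#'   slope, dissipation/min), `ptp_residual`, and `n` (samples used).
#' @export
baseline_stable <- function(trace, window = 60, threshold = 2e-6) {
  stopifnot(inherits(trace, "dissipation_trace"))
  check_positive(window, "window")
  check_positive(threshold, "threshold")
  if (nrow(trace$events) == 0L) {
    stop("trace has no events; baseline window is undefined", call. = FALSE)
  }
  t_ev <- min(trace$events$time)
  if (t_ev - window < trace$times[1L]) {
    stop("insufficient baseline: window exceeds the pre-event data span",
         call. = FALSE)
  }
  sel <- trace$times >= (t_ev - window) & trace$times < t_ev
  if (sum(sel) < 5L) {
    stop("insufficient baseline: fewer than 5 samples in the pre-event window",
         call. = FALSE)
  }
  t <- trace$times[sel]
  d <- trace$dissipation[sel]
  fit <- stats::lm.fit(cbind(1, t), d)
  slope_per_min <- fit$coefficients[2L] * 60
  ptp <- diff(range(fit$residuals))
  list(pass = abs(slope_per_min) <= threshold &&
              ptp <= threshold * window / 60,
       drift_per_min = unname(slope_per_min),
       ptp_residual = ptp,
       n = sum(sel))
}

#' Smoothed first derivative of the dissipation channel
#'
#' Moving-average smoothing (centred window, shrinking symmetrically at the
#' edges) followed by central finite differences; the first and last points
#' use one-sided differences. Output length equals input length.
#'
#' @param trace A [dissipation_trace()].
#' @param smooth_window Moving-average width in samples; odd, >= 3 and
#'   shorter than the series.
#' @return Numeric vector of derivative values, dissipation per second.
#' @export
smoothed_derivative <- function(trace, smooth_window = 11) {
  stopifnot(inherits(trace, "dissipation_trace"))
  n <- length(trace$times)
  if (smooth_window %% 2 != 1 || smooth_window < 3 || smooth_window >= n) {
    stop("'smooth_window' must be odd, >= 3 and shorter than the trace",
         call. = FALSE)
  }
  h <- (smooth_window - 1) / 2
  cs <- cumsum(c(0, trace$dissipation))
  idx <- seq_len(n)
  lo <- pmax(1L, idx - h)
  hi <- pmin(n, idx + h)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  t <- trace$times
  d <- numeric(n)
  d[1L] <- (sm[2L] - sm[1L]) / (t[2L] - t[1L])
  d[n] <- (sm[n] - sm[n - 1L]) / (t[n] - t[n - 1L])
  mid <- 2:(n - 1L)
  d[mid] <- (sm[mid + 1L] - sm[mid - 1L]) / (t[mid + 1L] - t[mid - 1L])
  d
}

#' Detect the clot end point from the dissipation derivative peak
#'
#' Implements the clot-time rule used for APTT/PT readout: the start point
#' is the instant the trigger reagent was added (the APTT starter or the PT
#' reagent), the end point is the peak of the first derivative of the
#' (smoothed) dissipation curve, restricted to times later than
#' `start + blanking` so that the pipetting/loading fluctuation immediately
#' after reagent addition cannot masquerade as the burst. The clot time is
#' end minus start.
#'
#' @param trace A [dissipation_trace()].
#' @param start_event_label Label of the start event; default `"starter"`.
#' @param blanking Dead time after the start event excluded from the peak
#'   search, s.
#' @param smooth_window Moving-average width for [smoothed_derivative()].
#' @param baseline_window,baseline_threshold Passed to [baseline_stable()];
#'   a failed (or uncheckable) baseline is recorded as a QC flag, not an
#'   error.
#' @param min_peak_slope Minimum derivative peak accepted without a
#'   `"low_peak_slope"` flag; `NULL` derives it as 5 times the robust noise
#'   scale (MAD) of the pre-start derivative when at least 10 pre-start
#'   samples exist, else 0.
#' @return An object of class `"clot_result"`: `start_time`, `end_time`,
#'   `clot_time` (s), `peak_slope` (dissipation/s), `blanking_used`,
#'   `qc_flags` (character vector), and `start_convention`
#'   (`"start-event-addition"`).
#' @export
detect_endpoint <- function(trace, start_event_label = "starter",
                            blanking = 10, smooth_window = 11,
                            baseline_window = 60, baseline_threshold = 2e-6,
                            min_peak_slope = NULL) {
  stopifnot(inherits(trace, "dissipation_trace"))
  check_non_negative(blanking, "blanking")
  start_time <- event_time(trace, start_event_label)
  t <- trace$times
  if (t[length(t)] <= start_time + blanking) {
    stop("trace ends before the blanking window after the start event",
         call. = FALSE)
  }
  qc <- character()
  bl <- tryCatch(baseline_stable(trace, baseline_window, baseline_threshold),
                 error = function(e) NULL)
  if (is.null(bl)) {
    qc <- c(qc, "baseline_unchecked")
  } else if (!bl$pass) {
    qc <- c(qc, "baseline_drift")
  }

  deriv <- smoothed_derivative(trace, smooth_window)
  ok <- which(t > start_time + blanking)
  # rounding in the moving average can leave ~eps-scale ripples on an
  # exactly flat trace; anything below this floor is "no positive slope"
  flat_tol <- 1e-12 * max(abs(trace$dissipation)) / stats::median(diff(t))
  if (max(deriv[ok]) <= flat_tol) {
    stop("no clot detected: dissipation never rises after the start event",
         call. = FALSE)
  }
  k <- ok[which.max(deriv[ok])]
  peak_slope <- deriv[k]
  if (k == ok[1L] || k == ok[length(ok)]) qc <- c(qc, "peak_at_boundary")

  if (is.null(min_peak_slope)) {
    pre <- which(t < start_time)
    min_peak_slope <- if (length(pre) >= 10L) {
      5 * stats::mad(deriv[pre])
    } else {
      0
    }
  }
  if (peak_slope < min_peak_slope) qc <- c(qc, "low_peak_slope")

  structure(list(start_time = start_time,
                 end_time = t[k],
                 clot_time = t[k] - start_time,
                 peak_slope = peak_slope,
                 blanking_used = blanking,
                 qc_flags = qc,
                 start_convention = "start-event-addition"),
            class = "clot_result")
}

#' @export
print.clot_result <- function(x, ...) {
  cat(sprintf("Clot time: %g s (start %g s -> end %g s), peak slope %.3g /s\n",
              x$clot_time, x$start_time, x$end_time, x$peak_slope))
  if (length(x$qc_flags)) cat("  QC flags:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Sauerbrey rigidity check
#'
#' A frequency shift can be read as adsorbed mass (Sauerbrey regime) only
#' for a rigid film, indicated by a dissipation-to-frequency-change ratio
#' strictly below 1e-6 per 10 Hz. During coagulation the ratio rises to
#' about 2.5e-6 per 10 Hz, i.e. firmly viscoelastic, which is why the
#' dissipation factor rather than the frequency shift is the traced
#' quantity.
#'
#' @param delta_D Dissipation change, dimensionless.
#' @param delta_f Frequency change, Hz; must be non-zero.
#' @return A list with `classification` (`"rigid"` or `"viscoelastic"`) and
#'   `ratio` (dissipation change per 10 Hz of frequency change).
#' @examples
#' rigidity_check(delta_D = 2.5e-6, delta_f = -10)  # coagulation regime
#' @export
rigidity_check <- function(delta_D, delta_f) {
  if (!is.numeric(delta_f) || length(delta_f) != 1L || delta_f == 0) {
    stop("undefined ratio: 'delta_f' must be a single non-zero number",
         call. = FALSE)
  }
  ratio <- abs(delta_D) / (abs(delta_f) / 10)
  list(classification = if (ratio < 1e-6) "rigid" else "viscoelastic",
       ratio = ratio)
}
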