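#' Fit a resonance curve and extract fs, BW and the dissipation factor
#'
#' Turns a swept magnitude spectrum into the three descriptors of the
#' resonance: the resonant frequency `fs`, the 3 dB (half-power) bandwidth
#' `bw`, and the dissipation factor `D = bw / fs` (the reciprocal of the
#' loaded quality factor).
#'
#' A third-order polynomial is fitted by least squares to the measured
#' curve around the peak, in the reciprocal-power domain: with the
#' magnitudes converted from dB to linear power, the quantity
#' `y = 1 / power` of an ideal Lorentzian resonance is exactly a parabola
#' in frequency, so a cubic fitted to `y` represents the whole peak and
#' both flanks (the cubic term absorbing mild asymmetry), which a cubic in
#' the dB domain cannot. The resonant frequency is the minimiser of the
#' fitted polynomial, the peak level its value there, and the two
#' half-power frequencies are the roots of `y = 2 * y_min` on either side
#' of the peak, so `bw` is read off the same fitted curve. The half-power
#' level is exactly `20*log10(sqrt(2))` (about 3.0103 dB), not a rounded
#' 3.0. Ties between equal-magnitude grid maxima resolve to the lowest
#' frequency.
#'
#' The fit window is the contiguous run of points within `window_db` of
#' the grid maximum (default 30 dB; the reciprocal-power parabola is
#' global, so a wide window is both usable and statistically helpful),
#' falling back to the nearest 25% of points on each side of the peak when
#' that run is shorter than 8 points.
#'
#' @param spectrum A [magnitude_spectrum()] (or data frame with columns
#'   `freq_hz`, `magnitude_db`) holding at least 8 points with a strict
#'   interior maximum.
#' @param window_db Window depth below the peak, dB.
#' @return An object of class `"resonance_fit"` with fields `fs` (Hz),
#'   `bw` (Hz), `dissipation` (`bw/fs`), `peak_db`, `fit_window`
#'   (`c(lo, hi)` Hz actually used), and `rms_residual` (dB, over the
#'   window).
#' @examples
#' dev <- qcm_device(resonator_params(f0 = 1e7), loaded_D = 1e-4)
#' fit <- fit_resonance(run_sweep(sweep_config(), dev))
#' fit$dissipation
#' @export
fit_resonance <- function(spectrum, window_db = 30) {
  if (!all(c("freq_hz", "magnitude_db") %in% names(spectrum))) {
    stop("'spectrum' must have columns 'freq_hz' and 'magnitude_db'",
         call. = FALSE)
  }
  freqs <- spectrum$freq_hz
  mags <- spectrum$magnitude_db
  n <- length(freqs)
  if (n < 8L) stop("spectrum has fewer than 8 points", call. = FALSE)
  if (any(diff(freqs) <= 0)) {
    stop("'freq_hz' must be strictly increasing", call. = FALSE)
  }
  i <- which.max(mags)  # first (lowest-frequency) maximum on ties
  if (i == 1L || i == n) {
    stop("no resonance: spectrum has no interior maximum", call. = FALSE)
  }
  peak_grid <- mags[i]

  sel <- which(mags >= peak_grid - window_db)
  runs <- split(sel, cumsum(c(1, diff(sel) != 1L)))
  w <- runs[[which(vapply(runs, function(r) i %in% r, logical(1L)))]]
  if (length(w) < 8L) {
    w <- max(1L, i - ceiling(0.25 * n)):min(n, i + ceiling(0.25 * n))
  }

  solve_window <- function(w) {
    # reciprocal normalized power; scaling keeps the design matrix conditioned
    y <- 10^(-mags[w] / 10)
    f_ref <- freqs[i]
    sc <- diff(range(freqs))
    x <- (freqs[w] - f_ref) / sc
    X <- cbind(1, x, x^2, x^3)
    cf <- stats::lm.fit(X, y)$coefficients
    cf[is.na(cf)] <- 0
    pv <- function(z) cf[1L] + z * (cf[2L] + z * (cf[3L] + z * cf[4L]))
    opt <- stats::optimize(pv, range(x), tol = .Machine$double.eps^0.5)
    z0 <- opt$minimum
    ymin <- opt$objective
    if (ymin <= 0) stop("no resonance: degenerate fitted curve", call. = FALSE)
    g <- function(z) pv(z) - 2 * ymin
    bracket <- function(a, b) {
      if (g(a) <= 0) return(NA_real_)
      stats::uniroot(g, c(a, b), tol = .Machine$double.eps^0.5)$root
    }
    z_lo <- bracket(min(x), z0)
    z_hi <- bracket(max(x), z0)
    list(ok = !is.na(z_lo) && !is.na(z_hi),
         fs = f_ref + z0 * sc,
         bw = if (!is.na(z_lo) && !is.na(z_hi)) (z_hi - z_lo) * sc else NA_real_,
         peak_db = -10 * log10(ymin),
         window = range(freqs[w]),
         pv = pv, x = x, w = w, f_ref = f_ref, sc = sc)
  }

  ans <- solve_window(w)
  if (!ans$ok && !identical(w, seq_len(n))) {
    # half-power points outside the local window: refit on the full sweep
    ans <- solve_window(seq_len(n))
  }
  if (!ans$ok) {
    stop("bandwidth exceeds sweep: half-power level not crossed within span",
         call. = FALSE)
  }

  fitted_db <- -10 * log10(pmax(ans$pv(ans$x), .Machine$double.xmin))
  rms <- sqrt(mean((mags[ans$w] - fitted_db)^2))
  structure(list(fs = ans$fs,
                 bw = ans$bw,
                 dissipation = ans$bw / ans$fs,
                 peak_db = ans$peak_db,
                 fit_window = ans$window,
                 rms_residual = rms),
            class = "resonance_fit")
}

#' Dissipation factor from a resonance fit
#'
#' The dissipation factor is the reciprocal of the loaded quality factor:
#' `D = 1/Q = bw / fs`, with `bw` the 3 dB bandwidth and `fs` the resonant
#' frequency, both read from the fitted resonance curve.
#'
#' @param fit A `"resonance_fit"` from [fit_resonance()].
#' @return Dissipation factor, dimensionless.
#' @export
dissipation_from_fit <- function(fit) {
  stopifnot(inherits(fit, "resonance_fit"))
  fit$bw / fit$fs
}

#' @export
print.resonance_fit <- function(x, ...) {
  cat(sprintf("Resonance fit: fs = %.6f MHz, BW = %.2f Hz, D = %.4g (Q = %.0f)\n",
              x$fs / 1e6, x$bw, x$dissipation, 1 / x$dissipation))
  cat(sprintf("  peak %.2f dB, window [%.6g, %.6g] Hz, rms residual %.3g dB\n",
              x$peak_db, x$fit_window[1L], x$fit_window[2L], x$rms_residual))
  invisible(x)
}
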