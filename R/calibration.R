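#' Cross-calibrate device clot times against a reference analyzer
#'
#' Clot times read from the dissipation-derivative peak are proportional
#' to, but longer than, the reference values reported by a clinical
#' hemostasis analyzer (room-temperature operation consistently prolongs
#' them, and the device endpoint is a kinetic rather than optical
#' criterion). Because the prolongation is consistent, an affine map
#' suffices: ordinary least squares of reference times on device times.
#' The reported `r_squared` is the adjusted R-squared (the plain
#' coefficient of determination is kept alongside), and the consistent
#' temperature prolongation is absorbed by the fitted slope and intercept
#' rather than modelled separately.
#'
#' @param device_times Device clot times, s.
#' @param reference_times Reference-analyzer clot times, s, same length.
#' @return An object of class `"qcm_calibration"` with `slope`,
#'   `intercept` (s), `r_squared` (adjusted), `r_squared_plain`, `n`, and
#'   `residual_sd` (s).
#' @examples
#' m <- fit_calibration(c(60, 70, 80, 90), c(10, 12, 14, 16))
#' apply_calibration(m, 75)
#' @export
fit_calibration <- function(device_times, reference_times) {
  device_times <- as.numeric(device_times)
  reference_times <- as.numeric(reference_times)
  if (length(device_times) != length(reference_times)) {
    stop("'device_times' and 'reference_times' lengths differ", call. = FALSE)
  }
  n <- length(device_times)
  if (n < 3L) {
    stop("at least 3 pairs are required (adjusted R-squared needs n >= 3)",
         call. = FALSE)
  }
  if (anyNA(device_times) || anyNA(reference_times)) {
    stop("clot-time pairs must not contain missing values", call. = FALSE)
  }
  if (diff(range(device_times)) == 0) {
    stop("degenerate fit: device times are constant", call. = FALSE)
  }
  fit <- stats::lm(reference_times ~ device_times)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$adj.r.squared,
                 r_squared_plain = sm$r.squared,
                 n = n,
                 residual_sd = sm$sigma),
            class = "qcm_calibration")
}

#' Map a device clot time onto the reference scale
#'
#' @param model A `"qcm_calibration"` from [fit_calibration()].
#' @param device_time Device clot time(s), s; vectorised.
#' @return Reference-scale time(s), s.
#' @export
apply_calibration <- function(model, device_time) {
  stopifnot(inherits(model, "qcm_calibration"))
  model$slope * as.numeric(device_time) + model$intercept
}

#' Invert a calibration model
#'
#' Algebraic inverse of [apply_calibration()]: the device time that maps
#' to a given reference-scale time. Round-tripping is identity up to
#' floating tolerance.
#'
#' @param model A `"qcm_calibration"`.
#' @param reference_time Reference-scale time(s), s.
#' @return Device-scale time(s), s.
#' @export
invert_calibration <- function(model, reference_time) {
  stopifnot(inherits(model, "qcm_calibration"))
  if (model$slope == 0) stop("calibration slope is zero", call. = FALSE)
  (as.numeric(reference_time) - model$intercept) / model$slope
}

#' @export
print.qcm_calibration <- function(x, ...) {
  cat(sprintf("Clot-time calibration (n = %d): reference = %.4g * device %+.4g s\n",
              x$n, x$slope, x$intercept))
  cat(sprintf("  adjusted R-squared %.4f (plain %.4f), residual sd %.3g s\n",
              x$r_squared, x$r_squared_plain, x$residual_sd))
  invisible(x)
}
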