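#' Resonator, liquid and film parameter sets
#'
#' Constructors for the three parameter groups entering the loaded-resonator
#' physics: the unloaded quartz crystal, the bulk liquid in contact with its
#' working electrode, and the viscoelastic (Kelvin--Voigt) protein film that
#' forms on the electrode as fibrin accumulates.
#'
#' The crystal defaults describe a 10 MHz fundamental-mode AT-cut quartz
#' blank: density 2648 kg/m3 and thickness 1.67e-4 m (shear velocity
#' ~3340 m/s over twice the resonant frequency). These are textbook AT-cut
#' values supplied as reasonable defaults, not measured properties of any
#' particular device. The liquid defaults are blood-plasma values
#' (viscosity 1.42e-3 Pa s, density 1.03e3 kg/m3).
#'
#' @param f0 Fundamental resonant frequency, Hz.
#' @param Q0 Intrinsic (unloaded) quality factor, dimensionless.
#' @param rho0 Crystal density, kg/m3.
#' @param h0 Crystal thickness, m.
#' @return `resonator_params()` returns an object of class
#'   `"resonator_params"`; its intrinsic dissipation is `1/Q0`.
#' @examples
#' res <- resonator_params()
#' liq <- liquid_params()
#' film <- film_params(h1 = 1e-7, mu1 = 1e5, eta1 = 1e-3)
#' @export
resonator_params <- function(f0 = 1e7, Q0 = 1e5, rho0 = 2648, h0 = 1.67e-4) {
  check_positive(f0, "f0")
  check_positive(Q0, "Q0")
  check_positive(rho0, "rho0")
  check_positive(h0, "h0")
  structure(list(f0 = f0, Q0 = Q0, rho0 = rho0, h0 = h0),
            class = "resonator_params")
}

#' @rdname resonator_params
#' @param eta Bulk-liquid viscosity, Pa s.
#' @param rho Bulk-liquid density, kg/m3.
#' @export
liquid_params <- function(eta = 1.42e-3, rho = 1.03e3) {
  check_positive(eta, "eta")
  check_positive(rho, "rho")
  structure(list(eta = eta, rho = rho), class = "liquid_params")
}

#' @rdname resonator_params
#' @param h1 Film thickness, m.
#' @param mu1 Film shear elasticity, Pa.
#' @param eta1 Film shear viscosity, Pa s.
#' @export
film_params <- function(h1 = 0, mu1 = 0, eta1 = 0) {
  check_non_negative(h1, "h1")
  check_non_negative(mu1, "mu1")
  check_non_negative(eta1, "eta1")
  if (h1 > 0 && mu1 == 0 && eta1 == 0) {
    stop("degenerate film: h1 > 0 requires mu1 > 0 or eta1 > 0",
         call. = FALSE)
  }
  structure(list(h1 = h1, mu1 = mu1, eta1 = eta1), class = "film_params")
}

#' @export
print.resonator_params <- function(x, ...) {
  cat(sprintf("QCM resonator: f0 = %.6g Hz, Q0 = %.4g (D0 = %.3g), rho0 = %g kg/m3, h0 = %g m\n",
              x$f0, x$Q0, 1 / x$Q0, x$rho0, x$h0))
  invisible(x)
}

#' @export
print.liquid_params <- function(x, ...) {
  cat(sprintf("Bulk liquid: eta = %g Pa s, rho = %g kg/m3\n", x$eta, x$rho))
  invisible(x)
}

#' @export
print.film_params <- function(x, ...) {
  cat(sprintf("Kelvin-Voigt film: h1 = %g m, mu1 = %g Pa, eta1 = %g Pa s\n",
              x$h1, x$mu1, x$eta1))
  invisible(x)
}
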