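#' @keywords internal
"_PACKAGE"

## Boltzmann constant (exact, SI)
.kB <- 1.380649e-23

#' Boltzmann constant
#'
#' The exact SI value of the Boltzmann constant used throughout the package.
#'
#' @return Scalar, J/K.
#' @export
kB <- function() .kB

#' Passive membrane mechanics parameters
#'
#' Container for the mechanical parameters of the equatorial membrane contour:
#' effective surface tension, bending modulus, membrane microviscosity, the
#' effective membrane thickness, mean equatorial radius and bath temperature.
#' The basal passive rigidity \code{G0} defaults to \code{kB*T/Sigma0^2}, the
#' harmonic stiffness implied by the basal (fully passivated) fluctuation
#' amplitude \code{Sigma0}.
#'
#' Defaults describe a healthy human discocyte at 37 C: mean radius 3.6 um,
#' basal amplitude 8 nm (so G0 of about 67 uN/m), tension 4e-5 N/m, bending
#' modulus 2e-19 J and membrane-scale microviscosity 1 Pa s, which place the
#' tension/bending diffusive crossover near 300 rad/s.
#'
#' @param gamma Surface tension (N/m), >= 0.
#' @param kappa Bending modulus (J), >= 0.
#' @param eta Membrane microviscosity (Pa s), > 0.
#' @param d Effective membrane thickness (m).
#' @param R_bar Mean equatorial radius (m), > 0.
#' @param T Bath temperature (K), >= 0.
#' @param G0 Basal passive rigidity (N/m); default \code{kB*T/Sigma0^2}.
#' @param Sigma0 Basal fluctuation amplitude (m) used for the G0 default.
#' @return An object of class \code{membrane_params}.
#' @export
membrane_params <- function(gamma = 4e-5, kappa = 2e-19, eta = 1.0,
                            d = 8e-8, R_bar = 3.6e-6, T = 310.15,
                            G0 = NULL, Sigma0 = 8e-9) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma),
            is.numeric(kappa), length(kappa) == 1L, is.finite(kappa),
            is.numeric(eta), length(eta) == 1L, is.finite(eta))
  if (gamma < 0 || kappa < 0)
    stop("gamma and kappa must be non-negative")
  if (gamma == 0 && kappa == 0)
    stop("at least one of gamma, kappa must be strictly positive")
  if (eta <= 0) stop("eta must be positive")
  if (!is.finite(R_bar) || R_bar <= 0) stop("R_bar must be positive")
  if (!is.finite(T) || T < 0) stop("T must be non-negative")
  if (!is.finite(d) || d <= 0) stop("d must be positive")
  if (is.null(G0)) {
    if (!is.finite(Sigma0) || Sigma0 <= 0) stop("Sigma0 must be positive")
    G0 <- .kB * T / Sigma0^2
  }
  if (!is.finite(G0) || G0 < 0) stop("G0 must be non-negative")
  structure(list(gamma = gamma, kappa = kappa, eta = eta, d = d,
                 R_bar = R_bar, T = T, G0 = G0, Sigma0 = Sigma0),
            class = "membrane_params")
}

#' @export
print.membrane_params <- function(x, ...) {
  cat("Membrane parameters (equatorial contour model)\n")
  cat(sprintf("  gamma  %.3e N/m   kappa %.3e J   eta %.3g Pa s\n",
              x$gamma, x$kappa, x$eta))
  cat(sprintf("  R_bar  %.3g um     d     %.3g nm      T  %.2f K\n",
              x$R_bar * 1e6, x$d * 1e9, x$T))
  cat(sprintf("  G0     %.3g uN/m (basal rigidity)\n", x$G0 * 1e6))
  invisible(x)
}

#' Active kicker parameters
#'
#' Parameters of the dichotomous ("telegraph") cytoskeletal kickers of the Gov
#' model of non-thermal membrane fluctuations: a fraction \code{phi} of contour
#' emplacements carries a force that switches between +f0 and -f0 at rate
#' \code{omega_A}, pushing the membrane toward excursions of scale
#' \code{Lambda0} against the local milieu friction.
#'
#' With \code{rate_mode = "log_uniform_ensemble"} (the default) each kicker
#' draws its own switching rate log-uniformly over \code{rate_span}; the
#' superposition of equal-power telegraph Lorentzians with log-uniform corner
#' rates produces the ~1/omega ("pink") active spectrum in that window. With
#' \code{"single_rate"} every kicker switches at \code{omega_A}, giving the
#' single-Lorentzian active spectrum.
#'
#' Defaults are the healthy-cell conditions: phi = 0.3 (20-40% of sites
#' active), kicking displacement Lambda0 = 50 nm (= 2 Sigma of active cells),
#' f0 = 2.5 pN so that the kicking energy f0*Lambda0 is about 29 kB*T, a
#' switching-rate band of 5-500 rad/s around omega_A = 50 rad/s, and milieu
#' viscosity eta0 = 1e-3 Pa s.
#'
#' @param phi Fraction of emplacements that are kickers, in [0, 1].
#' @param p_on Duty cycle of the kicker activated state, in [0, 1].
#' @param f0 Kicking force magnitude (N), >= 0.
#' @param Lambda0 Kicking displacement scale (m), >= 0.
#' @param omega_A Kicking (switching) rate (rad/s), > 0.
#' @param rate_mode Either \code{"log_uniform_ensemble"} or \code{"single_rate"}.
#' @param rate_span Length-2 band (rad/s) for the ensemble mode, low < high.
#' @param eta0 Milieu viscosity (Pa s) setting the kicker friction 6*pi*L*eta0.
#' @return An object of class \code{activity_params}.
#' @export
activity_params <- function(phi = 0.3, p_on = 1, f0 = 2.5e-12, Lambda0 = 5e-8,
                            omega_A = 50,
                            rate_mode = c("log_uniform_ensemble", "single_rate"),
                            rate_span = c(5, 500), eta0 = 1e-3) {
  rate_mode <- match.arg(rate_mode)
  if (!is.finite(phi) || phi < 0 || phi > 1) stop("phi must be in [0, 1]")
  if (!is.finite(p_on) || p_on < 0 || p_on > 1) stop("p_on must be in [0, 1]")
  if (!is.finite(f0) || f0 < 0) stop("f0 must be non-negative")
  if (!is.finite(Lambda0) || Lambda0 < 0) stop("Lambda0 must be non-negative")
  if (!is.finite(omega_A) || omega_A <= 0) stop("omega_A must be positive")
  if (length(rate_span) != 2L || !all(is.finite(rate_span)) ||
      rate_span[1] <= 0 || rate_span[1] >= rate_span[2])
    stop("rate_span must satisfy 0 < low < high")
  if (!is.finite(eta0) || eta0 <= 0) stop("eta0 must be positive")
  structure(list(phi = phi, p_on = p_on, f0 = f0, Lambda0 = Lambda0,
                 omega_A = omega_A, rate_mode = rate_mode,
                 rate_span = as.numeric(rate_span), eta0 = eta0),
            class = "activity_params")
}

#' @export
print.activity_params <- function(x, ...) {
  cat("Active kicker parameters\n")
  cat(sprintf("  phi %.2f   p_on %.2f   f0 %.3g pN   Lambda0 %.3g nm\n",
              x$phi, x$p_on, x$f0 * 1e12, x$Lambda0 * 1e9))
  cat(sprintf("  omega_A %.3g rad/s   mode %s", x$omega_A, x$rate_mode))
  if (x$rate_mode == "log_uniform_ensemble")
    cat(sprintf("  span [%.3g, %.3g] rad/s", x$rate_span[1], x$rate_span[2]))
  cat(sprintf("\n  kicking energy f0*Lambda0 = %.3g kB*T(310 K)\n",
              x$f0 * x$Lambda0 / (.kB * 310.15)))
  invisible(x)
}

## Run expr with a local, restorable RNG state seeded by `seed`.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

## Deterministic sub-stream seeds derived from a root seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}
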