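#' Gas constant in kcal mol^-1 K^-1
#'
#' Value used throughout for converting free energies (kcal/mol) into
#' equilibrium constants.
#' @keywords internal
R_KCAL <- 1.987204e-3

#' Default experimental temperature (kelvin)
#'
#' Equilibrium unfolding is assumed to be measured at 25 degrees C unless
#' stated otherwise.
#' @keywords internal
DEFAULT_TEMPERATURE_K <- 298.15

#' Thermodynamic description of a single unfolding transition
#'
#' Under the linear extrapolation method (LEM) the free energy of an
#' unfolding transition varies linearly with denaturant concentration:
#' \deqn{\Delta G([D]) = \Delta G^0 - m [D].}
#'
#' @param dg0 Free energy of unfolding at zero denaturant, kcal/mol.
#' @param m Denaturant dependence (m-value), kcal mol^-1 M^-1; must be
#'   positive for a physically meaningful unfolding transition.
#' @return An object of class `transition_thermo`.
#' @examples
#' transition_thermo(5.7, 6.3)
#' @export
transition_thermo <- function(dg0, m) {
  stopifnot(is.numeric(dg0), length(dg0) == 1L, is.finite(dg0))
  stopifnot(is.numeric(m), length(m) == 1L, is.finite(m))
  if (m <= 0) {
    stop("m-value must be positive (got ", m, ")", call. = FALSE)
  }
  structure(list(dg0 = as.numeric(dg0), m = as.numeric(m)),
            class = "transition_thermo")
}

#' @export
print.transition_thermo <- function(x, ...) {
  cat(sprintf("Unfolding transition: dG0 = %.3g kcal/mol, m = %.3g kcal/mol/M, Cm = %.3g M\n",
              x$dg0, x$m, midpoint(x)))
  invisible(x)
}

#' Three-state N-I-U equilibrium model parameters
#'
#' Parameter set for a three-state unfolding equilibrium with a molten
#' globule intermediate, N <-> I <-> U, plus the per-state observable
#' baselines needed to predict a spectroscopic signal (e.g. the tryptophan
#' fluorescence emission maximum in nm).
#'
#' @param ni `transition_thermo` for the N <-> I transition.
#' @param iu `transition_thermo` for the I <-> U transition.
#' @param baseline_n,baseline_i,baseline_u Observable value of the pure
#'   native, intermediate and unfolded state (signal units, e.g. nm).
#' @param baseline_slope_n,baseline_slope_i,baseline_slope_u Optional linear
#'   denaturant dependence of each baseline (signal units per M); default 0.
#' @param temperature Temperature in kelvin; default 298.15 K (25 C).
#' @return An object of class `three_state_params`.
#' @examples
#' p <- three_state_params(transition_thermo(5.7, 6.3),
#'                         transition_thermo(7.8, 3.9),
#'                         336, 341, 355)
#' predicted_signal(p, 1.5)
#' @export
three_state_params <- function(ni, iu, baseline_n, baseline_i, baseline_u,
                               baseline_slope_n = 0, baseline_slope_i = 0,
                               baseline_slope_u = 0,
                               temperature = DEFAULT_TEMPERATURE_K) {
  stopifnot(inherits(ni, "transition_thermo"), inherits(iu, "transition_thermo"))
  b <- c(baseline_n, baseline_i, baseline_u,
         baseline_slope_n, baseline_slope_i, baseline_slope_u)
  stopifnot(is.numeric(b), all(is.finite(b)))
  if (!is.numeric(temperature) || temperature <= 0) {
    stop("temperature must be positive (kelvin)", call. = FALSE)
  }
  structure(list(ni = ni, iu = iu,
                 baseline_n = as.numeric(baseline_n),
                 baseline_i = as.numeric(baseline_i),
                 baseline_u = as.numeric(baseline_u),
                 baseline_slope_n = as.numeric(baseline_slope_n),
                 baseline_slope_i = as.numeric(baseline_slope_i),
                 baseline_slope_u = as.numeric(baseline_slope_u),
                 temperature = as.numeric(temperature)),
            class = "three_state_params")
}

#' Two-state N-U equilibrium model parameters
#'
#' Degenerate limit of the three-state model with no populated intermediate;
#' used for model selection against the three-state fit.
#'
#' @param nu `transition_thermo` for the N <-> U transition.
#' @param baseline_n,baseline_u Observable value of the pure native and
#'   unfolded state (signal units).
#' @param baseline_slope_n,baseline_slope_u Optional linear baseline slopes
#'   (signal units per M); default 0.
#' @param temperature Temperature in kelvin; default 298.15 K.
#' @return An object of class `two_state_params`.
#' @export
two_state_params <- function(nu, baseline_n, baseline_u,
                             baseline_slope_n = 0, baseline_slope_u = 0,
                             temperature = DEFAULT_TEMPERATURE_K) {
  stopifnot(inherits(nu, "transition_thermo"))
  b <- c(baseline_n, baseline_u, baseline_slope_n, baseline_slope_u)
  stopifnot(is.numeric(b), all(is.finite(b)))
  if (!is.numeric(temperature) || temperature <= 0) {
    stop("temperature must be positive (kelvin)", call. = FALSE)
  }
  structure(list(nu = nu,
                 baseline_n = as.numeric(baseline_n),
                 baseline_u = as.numeric(baseline_u),
                 baseline_slope_n = as.numeric(baseline_slope_n),
                 baseline_slope_u = as.numeric(baseline_slope_u),
                 temperature = as.numeric(temperature)),
            class = "two_state_params")
}

#' Transition free energy at a given denaturant concentration
#'
#' Evaluates the LEM form dG([D]) = dG0 - m [D].
#'
#' @param t A `transition_thermo` object.
#' @param conc Denaturant concentration(s), M; must be >= 0. Vectorized.
#' @return Free energy in kcal/mol, same length as `conc`.
#' @examples
#' delta_g_at_denaturant(transition_thermo(5.7, 6.3), 0)     # 5.7
#' delta_g_at_denaturant(transition_thermo(7.8, 3.9), 1.0)   # 3.9
#' @export
delta_g_at_denaturant <- function(t, conc) {
  stopifnot(inherits(t, "transition_thermo"), is.numeric(conc), all(conc >= 0))
  t$dg0 - t$m * conc
}

#' Equilibrium constant from a free energy
#'
#' K = exp(-dG / (R T)) with R = 1.987204e-3 kcal mol^-1 K^-1. The exponent
#' is clamped at |x| = 700 to avoid floating-point overflow; a warning is
#' issued when the clamp engages.
#'
#' @param dg Free energy, kcal/mol. Vectorized.
#' @param temperature Temperature, kelvin (> 0).
#' @return Dimensionless equilibrium constant(s).
#' @examples
#' equilibrium_constant(0, 298.15)   # 1
#' @export
equilibrium_constant <- function(dg, temperature = DEFAULT_TEMPERATURE_K) {
  stopifnot(is.numeric(dg), is.numeric(temperature), temperature > 0)
  x <- -dg / (R_KCAL * temperature)
  if (any(abs(x) > 700)) {
    warning("exponent clamped at |x| = 700 in equilibrium_constant",
            call. = FALSE)
    x <- pmin(pmax(x, -700), 700)
  }
  exp(x)
}

#' Equilibrium state populations of the three-state model
#'
#' With K1 the N <-> I and K2 the I <-> U equilibrium constant at
#' concentration `conc`, the Boltzmann-weighted populations are
#' f_N = 1/Z, f_I = K1/Z, f_U = K1 K2 / Z with Z = 1 + K1 + K1 K2.
#'
#' @param p A `three_state_params` object.
#' @param conc Denaturant concentration(s), M, >= 0. Vectorized.
#' @return A data.frame with columns `conc`, `f_n`, `f_i`, `f_u`; rows sum
#'   to 1.
#' @export
state_fractions_three_state <- function(p, conc) {
  stopifnot(inherits(p, "three_state_params"), is.numeric(conc), all(conc >= 0))
  k1 <- equilibrium_constant(delta_g_at_denaturant(p$ni, conc), p$temperature)
  k2 <- equilibrium_constant(delta_g_at_denaturant(p$iu, conc), p$temperature)
  z <- 1 + k1 + k1 * k2
  data.frame(conc = conc, f_n = 1 / z, f_i = k1 / z, f_u = k1 * k2 / z)
}

#' Equilibrium state populations of the two-state model
#'
#' @param p A `two_state_params` object.
#' @param conc Denaturant concentration(s), M, >= 0. Vectorized.
#' @return A data.frame with columns `conc`, `f_n`, `f_i` (always 0), `f_u`.
#' @export
state_fractions_two_state <- function(p, conc) {
  stopifnot(inherits(p, "two_state_params"), is.numeric(conc), all(conc >= 0))
  k <- equilibrium_constant(delta_g_at_denaturant(p$nu, conc), p$temperature)
  data.frame(conc = conc, f_n = 1 / (1 + k), f_i = 0 * k, f_u = k / (1 + k))
}

#' Population-weighted observable signal
#'
#' The observed signal at each denaturant concentration is modelled as the
#' population-weighted mean of the per-state baselines,
#' Y([D]) = sum_s f_s([D]) (baseline_s + slope_s [D]). For an emission
#' maximum (lambda max) readout this linear mixing is an approximation to
#' the peak of the mixed spectrum; it is the form conventionally fitted to
#' such transition curves.
#'
#' @param p A `three_state_params` or `two_state_params` object.
#' @param conc Denaturant concentration(s), M, >= 0. Vectorized.
#' @return Predicted signal, same length as `conc`.
#' @export
predicted_signal <- function(p, conc) {
  if (inherits(p, "three_state_params")) {
    f <- state_fractions_three_state(p, conc)
    f$f_n * (p$baseline_n + p$baseline_slope_n * conc) +
      f$f_i * (p$baseline_i + p$baseline_slope_i * conc) +
      f$f_u * (p$baseline_u + p$baseline_slope_u * conc)
  } else if (inherits(p, "two_state_params")) {
    f <- state_fractions_two_state(p, conc)
    f$f_n * (p$baseline_n + p$baseline_slope_n * conc) +
      f$f_u * (p$baseline_u + p$baseline_slope_u * conc)
  } else {
    stop("p must be three_state_params or two_state_params", call. = FALSE)
  }
}

#' Transition midpoint concentration
#'
#' Cm = dG0 / m, the denaturant concentration at which the transition free
#' energy is zero.
#'
#' @param t A `transition_thermo` object.
#' @return Midpoint concentration, M.
#' @examples
#' midpoint(transition_thermo(7.8, 3.9))  # 2
#' @export
midpoint <- function(t) {
  stopifnot(inherits(t, "transition_thermo"))
  t$dg0 / t$m
}
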