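#' @keywords internal
"_PACKAGE"

# Physical constants for the internal unit system.
#
# Internally every energy-like quantity is carried as an angular frequency in
# rad/ps (i.e. E/hbar), and time in ps. With that choice hbar never appears
# explicitly: phases are omega*t, the scaled derivative-coupling kernels
# F(t)/hbar and D(t)/hbar^2 come out directly in ps^-1 and ps^-2, and rates in
# ps^-1. In reduced mode (k_B = hbar = omega_c = 1) numbers are used as given.
.const <- list(
  c_cm_ps = 2.99792458e-2,          # speed of light, cm/ps
  kB_cm1  = 0.695034800,            # Boltzmann constant, cm^-1 / K
  eV_cm1  = 8065.543937             # 1 eV in cm^-1
)

#' Convert a wavenumber to an internal angular frequency
#'
#' @param x numeric, wavenumbers in cm^-1.
#' @return angular frequency in rad/ps.
#' @export
cm1_to_angfreq <- function(x) 2 * pi * .const$c_cm_ps * x

#' Convert an internal angular frequency to a wavenumber
#' @param x numeric, rad/ps.
#' @return wavenumbers in cm^-1.
#' @export
angfreq_to_cm1 <- function(x) x / (2 * pi * .const$c_cm_ps)

#' Convert an energy in eV to an internal angular frequency
#' @param x numeric, eV.
#' @return angular frequency in rad/ps.
#' @export
ev_to_angfreq <- function(x) cm1_to_angfreq(x * .const$eV_cm1)

# Validation error with a condition class the CLI can map to exit code 2.
ndc_stop <- function(..., class = "ndcrate_validation_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

ndc_stop_convergence <- function(...) {
  ndc_stop(..., class = "ndcrate_convergence_error")
}

#' Thermodynamic state of the bath
#'
#' Bundles the temperature and the derived inverse thermal frequency
#' `beta_hbar` (so that thermal occupation factors are
#' `coth(beta_hbar * omega / 2)`). Two unit systems are supported:
#' `"kelvin"` (physical: temperature in K, frequencies in rad/ps) and
#' `"reduced"` (k_B = hbar = omega_c = 1, where the single thermal parameter
#' is theta = beta * hbar * omega_c and the temperature is 1/theta).
#'
#' @param temperature temperature in kelvin (units = "kelvin") or in units of
#'   hbar*omega_c/k_B (units = "reduced"). Give either this or `theta`.
#' @param theta dimensionless beta*hbar*omega_c; only meaningful (and only
#'   accepted) in reduced units.
#' @param units `"kelvin"` or `"reduced"`.
#' @return an object of class `ndc_thermo` with fields `units`, `temperature`,
#'   `theta` (reduced only) and `beta_hbar` (ps in physical units, 1/omega_c
#'   in reduced units).
#' @examples
#' thermo_state(300)                      # room temperature, physical units
#' thermo_state(theta = 1, units = "reduced")
#' @export
thermo_state <- function(temperature = NULL, theta = NULL,
                         units = c("kelvin", "reduced")) {
  units <- match.arg(units)
  if (!is.null(theta)) {
    if (units != "reduced")
      ndc_stop("theta can only be given in reduced units")
    if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0)
      ndc_stop("theta must be a single positive finite number")
    temperature <- 1 / theta
  }
  if (is.null(temperature))
    ndc_stop("either temperature or theta must be given")
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    ndc_stop("temperature must be a single positive finite number")
  beta_hbar <- if (units == "kelvin") {
    1 / cm1_to_angfreq(.const$kB_cm1 * temperature)  # ps
  } else {
    1 / temperature                                  # units of 1/omega_c
  }
  structure(
    list(units = units, temperature = temperature,
         theta = if (units == "reduced") 1 / temperature else NULL,
         beta_hbar = beta_hbar),
    class = "ndc_thermo"
  )
}

#' @export
print.ndc_thermo <- function(x, ...) {
  if (x$units == "kelvin") {
    cat(sprintf("<ndc_thermo> T = %g K (beta*hbar = %.6g ps)\n",
                x$temperature, x$beta_hbar))
  } else {
    cat(sprintf("<ndc_thermo> reduced units, theta = %g\n", x$theta))
  }
  invisible(x)
}

#' Uniform time grid for correlation functions and rate integrals
#'
#' @param t_max largest time (ps in physical units, 1/omega_c in reduced).
#' @param n number of intervals; the grid has `n + 1` points including t = 0.
#' @param dt alternatively, the spacing (overrides `n`).
#' @return object of class `ndc_grid` with fields `t` (vector, `t[1] = 0`),
#'   `dt` and `t_max`.
#' @export
time_grid <- function(t_max, n = 2048L, dt = NULL) {
  if (!is.numeric(t_max) || length(t_max) != 1L || !is.finite(t_max) || t_max <= 0)
    ndc_stop("t_max must be a single positive finite number")
  if (!is.null(dt)) {
    if (!is.finite(dt) || dt <= 0 || dt > t_max)
      ndc_stop("dt must satisfy 0 < dt <= t_max")
    n <- max(1L, as.integer(ceiling(t_max / dt)))
  }
  n <- as.integer(n)
  if (n < 1L) ndc_stop("n must be >= 1")
  dt <- t_max / n
  structure(list(t = seq(0, t_max, length.out = n + 1L), dt = dt, t_max = t_max),
            class = "ndc_grid")
}

#' @export
print.ndc_grid <- function(x, ...) {
  cat(sprintf("<ndc_grid> %d points, dt = %.6g, t_max = %.6g\n",
              length(x$t), x$dt, x$t_max))
  invisible(x)
}

# coth with a series-safe small-argument branch (coth x ~ 1/x + x/3).
.coth <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  out[small] <- 1 / x[small] + x[small] / 3
  out[!small] <- 1 / tanh(x[!small])
  out
}
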