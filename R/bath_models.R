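# Bath spectral densities.
#
# Convention (documented in the methods vignette): spectral densities are
# carried internally as angular-frequency densities with
#   J(omega)   = pi * sum_j omega_j^2 g_j^2    delta(omega - omega_j)
#   J_D(omega) = pi * sum_j omega_j^2 f_j^2    delta(omega - omega_j)
#   J_F(omega) = pi * sum_j omega_j^2 g_j f_j  delta(omega - omega_j)
# so that the reorganization-type functional (1/pi) Int J(omega)/omega domega
# recovers the coupling strengths exactly: lambda = sum_j hbar omega_j g_j^2,
# and analogously D = eta_D hbar omega_c + s_D hbar omega_h,
# F = eta_F hbar omega_c + s_F hbar omega_h for the Ohmic+delta family.
# The Ohmic component is A * omega * exp(-omega/omega_c) with A = pi * eta,
# which pins lambda_l = eta * hbar * omega_c through the same functional.
# Delta components are never discretized: they are carried as point masses
# (omega_j, g_j^2, f_j^2, g_j f_j) and summed analytically downstream.

#' Parameters of the Ohmic-plus-delta bath family
#'
#' The three model spectral densities share an Ohmic-with-exponential-cutoff
#' low-frequency part and a single high-frequency delta peak:
#' \deqn{J(\omega) = \pi\eta\,\omega e^{-\omega/\omega_c}
#'       + \pi s_h \omega_h^2 \delta(\omega-\omega_h)}
#' and similarly for the squared derivative-coupling density (coefficients
#' `eta_D`, `s_D`) and the signed cross density (`eta_F`, `s_F`).
#'
#' Because the delta peak originates from a single molecular vibration, the
#' cross coefficient is pinned by `s_F^2 = s_h * s_D` (its sign is free); the
#' Ohmic cross coefficient is only bounded, `|eta_F| <= eta_D / 2`.
#'
#' @param eta dimensionless Ohmic Franck-Condon coupling (>= 0).
#' @param omega_c Ohmic cutoff frequency (cm^-1, or omega_c units in reduced mode).
#' @param s_h Huang-Rhys factor of the high-frequency mode (>= 0).
#' @param omega_h high-frequency mode position (same units as `omega_c`);
#'   required when any of `s_h`, `s_D`, `s_F` is nonzero.
#' @param eta_D dimensionless Ohmic squared-NDC magnitude (>= 0).
#' @param s_D delta-peak squared-NDC magnitude (>= 0).
#' @param eta_F signed dimensionless Ohmic cross coupling, `|eta_F| <= eta_D/2`.
#' @param s_F signed delta-peak cross coupling; defaults to `+sqrt(s_h*s_D)`
#'   and must satisfy `s_F^2 = s_h*s_D`.
#' @param units `"cm1"` for physical wavenumber inputs or `"reduced"` for the
#'   k_B = hbar = omega_c = 1 system.
#' @return object of class `ndc_params`.
#' @examples
#' ohmic_delta_params(eta = 1, omega_c = 200, s_h = 1, omega_h = 1000, s_D = 4)
#' @export
ohmic_delta_params <- function(eta, omega_c, s_h = 0, omega_h = NULL,
                               eta_D = 0, s_D = 0, eta_F = 0, s_F = NULL,
                               units = c("cm1", "reduced")) {
  units <- match.arg(units)
  for (nm in c("eta", "omega_c", "s_h", "eta_D", "s_D", "eta_F")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      ndc_stop("parameter '", nm, "' must be a single finite number")
  }
  if (eta < 0)   ndc_stop("invariant violated: eta >= 0")
  if (omega_c <= 0) ndc_stop("invariant violated: omega_c > 0")
  if (s_h < 0)   ndc_stop("invariant violated: s_h >= 0")
  if (eta_D < 0) ndc_stop("invariant violated: eta_D >= 0")
  if (s_D < 0)   ndc_stop("invariant violated: s_D >= 0")
  if (abs(eta_F) > eta_D / 2 + 1e-12 * max(1, eta_D))
    ndc_stop("invariant violated: |eta_F| <= eta_D/2 (cross-coupling bound), got |",
             eta_F, "| > ", eta_D / 2)
  if (is.null(s_F)) s_F <- sqrt(s_h * s_D)
  if (!is.numeric(s_F) || length(s_F) != 1L || !is.finite(s_F))
    ndc_stop("parameter 's_F' must be a single finite number")
  if (abs(s_F^2 - s_h * s_D) > 1e-8 * max(1, s_h * s_D))
    ndc_stop("invariant violated: s_F^2 = s_h * s_D (single-mode origin of the ",
             "delta peak), got s_F^2 = ", s_F^2, " vs s_h*s_D = ", s_h * s_D)
  needs_h <- (s_h > 0 || s_D > 0 || abs(s_F) > 0)
  if (needs_h) {
    if (is.null(omega_h) || !is.numeric(omega_h) || length(omega_h) != 1L ||
        !is.finite(omega_h) || omega_h <= 0)
      ndc_stop("invariant violated: omega_h > 0 is required when the delta peak carries weight")
  } else if (is.null(omega_h)) {
    omega_h <- omega_c  # placeholder position for a weightless peak
  }
  conv <- if (units == "cm1") cm1_to_angfreq else identity
  structure(
    list(eta = eta, omega_c = omega_c, s_h = s_h, omega_h = omega_h,
         eta_D = eta_D, s_D = s_D, eta_F = eta_F, s_F = s_F,
         units = units,
         omega_c_i = conv(omega_c), omega_h_i = conv(omega_h)),
    class = "ndc_params"
  )
}

#' @export
print.ndc_params <- function(x, ...) {
  cat(sprintf(
    "<ndc_params> units=%s\n  eta=%g omega_c=%g | s_h=%g omega_h=%g\n  eta_D=%g s_D=%g | eta_F=%g s_F=%g\n",
    x$units, x$eta, x$omega_c, x$s_h, x$omega_h, x$eta_D, x$s_D, x$eta_F, x$s_F))
  invisible(x)
}

#' Discrete normal-mode set
#'
#' Per-mode frequencies, dimensionless vibronic couplings `g` (the Huang-Rhys
#' factor of mode j is `g[j]^2`) and signed dimensionless derivative-coupling
#' projections `f` (carrying the purely imaginary momentum coupling
#' `i * f[j]`; only the relative sign against `g[j]` is observable, through
#' the cross spectral density).
#'
#' @param omega per-mode frequencies (cm^-1, or omega_c units when reduced);
#'   strictly positive and finite.
#' @param g per-mode vibronic couplings (same length; finite).
#' @param f per-mode derivative-coupling projections (same length; finite).
#' @param labels optional per-mode identifiers.
#' @param units `"cm1"` or `"reduced"`.
#' @return object of class `ndc_modes`. Empty sets (length 0) are allowed.
#' @export
discrete_modes <- function(omega, g = numeric(length(omega)),
                           f = numeric(length(omega)), labels = NULL,
                           units = c("cm1", "reduced")) {
  units <- match.arg(units)
  n <- length(omega)
  if (length(g) != n || length(f) != n)
    ndc_stop("omega, g and f must have the same length (got ",
             n, ", ", length(g), ", ", length(f), ")")
  if (n > 0L) {
    if (!is.numeric(omega) || any(!is.finite(omega)) || any(omega <= 0))
      ndc_stop("all mode frequencies must be strictly positive and finite")
    if (!is.numeric(g) || any(!is.finite(g)))
      ndc_stop("all vibronic couplings g must be finite")
    if (!is.numeric(f) || any(!is.finite(f)))
      ndc_stop("all derivative-coupling projections f must be finite")
  }
  if (!is.null(labels) && length(labels) != n)
    ndc_stop("labels must match the number of modes")
  conv <- if (units == "cm1") cm1_to_angfreq else identity
  structure(
    list(omega = as.numeric(omega), g = as.numeric(g), f = as.numeric(f),
         labels = labels, units = units, omega_i = conv(as.numeric(omega))),
    class = "ndc_modes"
  )
}

#' @export
print.ndc_modes <- function(x, ...) {
  cat(sprintf("<ndc_modes> %d modes (%s), lambda = %.6g, D-strength = %.6g\n",
              length(x$omega), x$units,
              reorganization_energy(x), ndc_strength(x)))
  invisible(x)
}

# Internal constructor for the evaluable triple.
new_spectral_triple <- function(kind, units, Jc = NULL, deltas = NULL,
                                gamma = NULL, params = NULL, omega_scale = NULL) {
  zero <- function(omega) numeric(length(omega))
  if (is.null(Jc)) Jc <- list(J = zero, J_D = zero, J_F = zero)
  if (is.null(deltas))
    deltas <- data.frame(omega = numeric(0), g2 = numeric(0),
                         f2 = numeric(0), gf = numeric(0))
  structure(
    list(kind = kind, units = units, Jc = Jc, deltas = deltas,
         gamma = gamma, params = params,
         has_continuum = !is.null(omega_scale),
         omega_scale = omega_scale),
    class = "ndc_triple"
  )
}

#' Build the evaluable spectral-density triple of a parametric bath
#'
#' @param params an [ohmic_delta_params()] object.
#' @return object of class `ndc_triple` with kind `"parametric"`: continuous
#'   Ohmic components plus an analytic point mass at `omega_h`.
#' @export
parametric_triple <- function(params) {
  if (!inherits(params, "ndc_params")) ndc_stop("params must be an ndc_params object")
  wc <- params$omega_c_i
  mk <- function(coef) {
    force(coef)
    function(omega) pi * coef * omega * exp(-omega / wc)
  }
  deltas <- data.frame(omega = params$omega_h_i,
                       g2 = params$s_h, f2 = params$s_D, gf = params$s_F)
  deltas <- deltas[deltas$g2 > 0 | deltas$f2 > 0 | deltas$gf != 0, , drop = FALSE]
  new_spectral_triple(
    "parametric", params$units,
    Jc = list(J = mk(params$eta), J_D = mk(params$eta_D), J_F = mk(params$eta_F)),
    deltas = deltas, params = params,
    omega_scale = if (params$eta > 0 || params$eta_D > 0 || params$eta_F != 0) wc else NULL
  )
}

#' Evaluate the three parametric spectral densities at given frequencies
#'
#' Returns the continuous (Ohmic) parts of J, J_D and J_F pointwise; the delta
#' components are returned as tagged point masses, never as spiked grid values.
#'
#' @param params an [ohmic_delta_params()] object.
#' @param omega frequencies (>= 0), in the unit system of `params`.
#' @return list with vectors `J`, `J_D`, `J_F` (continuous parts at `omega`)
#'   and data frame `deltas` with columns `omega`, `wJ`, `wJD`, `wJF` (the
#'   point-mass weights `pi*omega_h^2*s_h` etc., internal angular-frequency
#'   convention).
#' @export
eval_parametric_triple <- function(params, omega) {
  triple <- parametric_triple(params)
  eval_triple(triple, omega)
}

#' Evaluate a spectral triple at given frequencies
#'
#' @param triple an `ndc_triple`.
#' @param omega frequencies (>= 0) in the triple's unit system.
#' @return list of continuous density values `J`, `J_D`, `J_F` at `omega` plus
#'   the analytic point masses in `deltas` (empty for broadened baths).
#' @export
eval_triple <- function(triple, omega) {
  if (!inherits(triple, "ndc_triple")) ndc_stop("triple must be an ndc_triple object")
  if (!is.numeric(omega) || any(!is.finite(omega)))
    ndc_stop("omega must be finite")
  if (any(omega < 0))
    ndc_stop("domain error: omega must be >= 0")
  conv <- if (triple$units == "cm1") cm1_to_angfreq else identity
  w <- conv(omega)
  d <- triple$deltas
  list(J = triple$Jc$J(w), J_D = triple$Jc$J_D(w), J_F = triple$Jc$J_F(w),
       deltas = data.frame(omega = d$omega, wJ = pi * d$omega^2 * d$g2,
                           wJD = pi * d$omega^2 * d$f2, wJF = pi * d$omega^2 * d$gf))
}

#' Normalized Brownian-oscillator lineshape
#'
#' The broadened stand-in for a delta-function mode at `omega_j`:
#' \deqn{J_\gamma(\omega;\omega_j) = A_j \frac{\gamma\omega}
#'   {(\omega^2-\omega_j^2)^2 + \gamma^2\omega^2}}
#' with the closed-form normalization constant `A_j` chosen so the integral
#' over \eqn{[0,\infty)} is exactly one. The lineshape rises linearly at
#' `omega -> 0+` and decays as `omega^-3`, which keeps every correlation
#' integral of this package finite.
#'
#' @param omega evaluation frequencies (>= 0).
#' @param omega_j mode position (> 0).
#' @param gamma friction parameter (> 0), same units as `omega`.
#' @return density values; all inputs in a common (arbitrary but consistent)
#'   frequency unit, the result carrying its inverse.
#' @export
bo_lineshape <- function(omega, omega_j, gamma) {
  if (!is.numeric(omega_j) || length(omega_j) != 1L || !is.finite(omega_j) || omega_j <= 0)
    ndc_stop("omega_j must be a single positive number")
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    ndc_stop("gamma must be a single positive number; for the gamma -> 0 limit use ",
             "the unbroadened discrete path")
  if (any(omega < 0)) ndc_stop("domain error: omega must be >= 0")
  A <- bo_norm_const(omega_j, gamma)
  A * gamma * omega / ((omega^2 - omega_j^2)^2 + gamma^2 * omega^2)
}

# Closed-form normalization: 1 / Int_0^inf gamma*w / ((w^2-wj^2)^2 + g^2 w^2) dw.
# With u = w^2 the integral is (gamma/2) Int_0^inf du / (u^2 + b u + c),
# b = gamma^2 - 2 wj^2, c = wj^4.
bo_norm_const <- function(omega_j, gamma) {
  b <- gamma^2 - 2 * omega_j^2
  disc <- 4 * omega_j^2 - gamma^2          # (4c - b^2) / gamma^2
  if (disc > 1e-10 * omega_j^2) {          # underdamped: complex roots
    s <- gamma * sqrt(disc)
    I <- (gamma / s) * (pi / 2 - atan(b / s))
  } else if (disc < -1e-10 * omega_j^2) {  # overdamped: two negative real roots
    r <- sqrt(b^2 - 4 * omega_j^4)
    p <- (b - r) / 2; q <- (b + r) / 2
    I <- (gamma / 2) * log(q / p) / (q - p)
  } else {                                 # critically damped
    I <- gamma / (2 * (b / 2))
  }
  1 / I
}

#' Build a spectral triple from discrete mode data
#'
#' Without broadening the result carries exact per-mode point masses (kind
#' `"discrete"`); with a Brownian-oscillator friction `gamma` each point mass
#' is replaced by the normalized [bo_lineshape()] centred at the mode
#' frequency with the same integrated weight (kind `"bo_broadened"`).
#'
#' @param modes an [discrete_modes()] object; may be empty (identically zero
#'   triple).
#' @param gamma optional BO friction (> 0), in the unit system of `modes`.
#' @return an `ndc_triple`.
#' @export
triple_from_modes <- function(modes, gamma = NULL) {
  if (!inherits(modes, "ndc_modes")) ndc_stop("modes must be an ndc_modes object")
  deltas <- data.frame(omega = modes$omega_i, g2 = modes$g^2,
                       f2 = modes$f^2, gf = modes$g * modes$f)
  if (is.null(gamma)) {
    return(new_spectral_triple("discrete", modes$units, deltas = deltas))
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    ndc_stop("gamma must be a single positive number")
  conv <- if (modes$units == "cm1") cm1_to_angfreq else identity
  gamma_i <- conv(gamma)
  if (nrow(deltas) == 0L)
    return(new_spectral_triple("bo_broadened", modes$units, gamma = gamma_i))
  A <- vapply(deltas$omega, bo_norm_const, numeric(1), gamma = gamma_i)
  mk <- function(wcol) {
    weights <- pi * deltas$omega^2 * deltas[[wcol]]   # integrated weight per mode
    force(weights)
    function(omega) {
      out <- numeric(length(omega))
      for (j in seq_along(weights)) {
        if (weights[j] == 0) next
        wj <- deltas$omega[j]
        out <- out + weights[j] * A[j] * gamma_i * omega /
          ((omega^2 - wj^2)^2 + gamma_i^2 * omega^2)
      }
      out
    }
  }
  out <- new_spectral_triple("bo_broadened", modes$units,
                             Jc = list(J = mk("g2"), J_D = mk("f2"), J_F = mk("gf")),
                             gamma = gamma_i,
                             omega_scale = max(c(deltas$omega, gamma_i)))
  out$deltas_src <- deltas   # exact per-mode weights behind the broadening
  out
}

#' Build a spectral triple from tabulated densities
#'
#' Accepts monotone-frequency tables (e.g. densities derived from molecular
#' dynamics) with linear interpolation between rows and zero density beyond
#' the last tabulated frequency (the explicit high-frequency cutoff).
#'
#' @param table data frame with columns `omega`, `J`, `J_D`, `J_F` (missing
#'   density columns are taken as zero), frequencies strictly increasing.
#' @param units `"cm1"` or `"reduced"`.
#' @return an `ndc_triple` of kind `"tabulated"`.
#' @export
triple_from_table <- function(table, units = c("cm1", "reduced")) {
  units <- match.arg(units)
  if (!is.data.frame(table) || !("omega" %in% names(table)))
    ndc_stop("table must be a data frame with an 'omega' column")
  if (any(diff(table$omega) <= 0) || any(table$omega < 0))
    ndc_stop("table frequencies must be nonnegative and strictly increasing")
  conv <- if (units == "cm1") cm1_to_angfreq else identity
  w <- conv(table$omega)
  mk <- function(col) {
    y <- if (col %in% names(table)) table[[col]] else numeric(length(w))
    if (any(!is.finite(y))) ndc_stop("non-finite density values in column ", col)
    fn <- stats::approxfun(c(0, w), c(0, y), yleft = 0, yright = 0, rule = 1)
    function(omega) { v <- fn(omega); v[is.na(v)] <- 0; v }
  }
  new_spectral_triple("tabulated", units,
                      Jc = list(J = mk("J"), J_D = mk("J_D"), J_F = mk("J_F")),
                      omega_scale = max(w))
}

#' Check the cross spectral-density bound
#'
#' For parametric baths this is the constraint `|eta_F| <= eta_D / 2` together
#' with `s_F^2 = s_h * s_D`; for triples and mode sets it is the pointwise
#' Cauchy-Schwarz consistency `J_F(omega)^2 <= J(omega) * J_D(omega)` (which a
#' microscopic per-mode construction saturates and can never violate).
#'
#' @param x an `ndc_params`, `ndc_modes` or `ndc_triple` object.
#' @param n_grid number of grid points for the pointwise check on continuous
#'   densities.
#' @return list of class `ndc_bound_check` with elements `pass` (logical) and
#'   `margin` (parametric: `eta_D/2 - |eta_F|`; pointwise: the minimum of
#'   `sqrt(J*J_D) - |J_F|` over the probed support, in density units).
#' @export
check_cross_bound <- function(x, n_grid = 2001L) {
  if (inherits(x, "ndc_params")) {
    margin <- x$eta_D / 2 - abs(x$eta_F)
    sat <- abs(x$s_F^2 - x$s_h * x$s_D) <= 1e-8 * max(1, x$s_h * x$s_D)
    res <- list(pass = margin >= -1e-12 && sat, margin = margin,
                kind = "parametric")
    return(structure(res, class = "ndc_bound_check"))
  }
  if (inherits(x, "ndc_modes")) x <- triple_from_modes(x)
  if (!inherits(x, "ndc_triple"))
    ndc_stop("x must be ndc_params, ndc_modes or ndc_triple")
  margins <- numeric(0)
  if (x$has_continuum) {
    wmax <- 10 * x$omega_scale
    w <- seq(wmax / n_grid, wmax, length.out = n_grid)
    J <- x$Jc$J(w); JD <- x$Jc$J_D(w); JF <- x$Jc$J_F(w)
    margins <- c(margins, sqrt(pmax(J * JD, 0)) - abs(JF))
  }
  if (nrow(x$deltas) > 0L) {
    d <- x$deltas
    margins <- c(margins, (sqrt(pmax(d$g2 * d$f2, 0)) - abs(d$gf)) * pi * d$omega^2)
  }
  m <- if (length(margins)) min(margins) else Inf
  scale <- if (length(margins)) max(abs(margins), 1) else 1
  structure(list(pass = m >= -1e-9 * scale, margin = m, kind = "pointwise"),
            class = "ndc_bound_check")
}

#' @export
print.ndc_bound_check <- function(x, ...) {
  cat(sprintf("<ndc_bound_check> %s (%s margin = %.6g)\n",
              if (x$pass) "PASS" else "FAIL", x$kind, x$margin))
  invisible(x)
}

#' Total reorganization energy of a bath
#'
#' Evaluates the standard functional
#' \eqn{\lambda = (1/\pi)\int_0^\infty J(\omega)/\omega \, d\omega}
#' (plus exact point-mass sums). For parametric input this equals
#' `eta*omega_c + s_h*omega_h` identically.
#'
#' @param x `ndc_params`, `ndc_modes` or `ndc_triple`.
#' @return reorganization energy in cm^-1 (physical) or omega_c units (reduced).
#' @export
reorganization_energy <- function(x) {
  strength_functional(x, "J")
}

#' Integrated derivative-coupling strength of a bath
#'
#' The analogous functional of `J_D` (parametric value
#' `eta_D*omega_c + s_D*omega_h`).
#' @inheritParams reorganization_energy
#' @return strength in cm^-1 (physical) or omega_c units (reduced).
#' @export
ndc_strength <- function(x) {
  strength_functional(x, "J_D")
}

strength_functional <- function(x, which = c("J", "J_D", "J_F")) {
  which <- match.arg(which)
  if (inherits(x, "ndc_params")) {
    val_i <- switch(which,
      J   = x$eta   * x$omega_c_i + x$s_h * x$omega_h_i,
      J_D = x$eta_D * x$omega_c_i + x$s_D * x$omega_h_i,
      J_F = x$eta_F * x$omega_c_i + x$s_F * x$omega_h_i)
    units <- x$units
  } else if (inherits(x, "ndc_modes")) {
    coefs <- switch(which, J = x$g^2, J_D = x$f^2, J_F = x$g * x$f)
    val_i <- sum(x$omega_i * coefs)
    units <- x$units
  } else if (inherits(x, "ndc_triple")) {
    d <- x$deltas
    coefs <- switch(which, J = d$g2, J_D = d$f2, J_F = d$gf)
    val_i <- sum(d$omega * coefs)
    if (x$has_continuum) {
      f <- x$Jc[[which]]
      wmax <- 60 * x$omega_scale
      I <- tryCatch(
        pracma::integral(function(w) f(w) / w, 1e-12 * x$omega_scale, wmax,
                         reltol = 1e-10),
        error = function(e) NA_real_)
      tail_probe <- f(wmax) / wmax * wmax  # crude scale of the omitted tail
      if (!is.finite(I) || (is.finite(tail_probe) &&
                            abs(tail_probe) > 1e-6 * max(abs(I), 1e-300)))
        ndc_stop("reorganization integral did not converge (slowly decaying ",
                 "or divergent user density); probed up to omega = ", wmax,
                 class = "ndcrate_numerical_error")
      val_i <- val_i + I / pi
    }
    units <- x$units
  } else {
    ndc_stop("x must be ndc_params, ndc_modes or ndc_triple")
  }
  if (units == "cm1") angfreq_to_cm1(val_i) else val_i
}
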