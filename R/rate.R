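# Golden-rule rate assembly.
#
# The rate is the one-sided real-part time integral
#   k = 2 Re Int_0^tmax exp(i (gap - lambda) t) exp(-g(t)) [ D(t) + F(t)^2 ] dt
# with the hbar-scaled kernels of correlation.R (so k comes out in ps^-1, or
# in omega_c units in reduced mode). `gap` is the adiabatic energy gap between
# the minima of the initial and final surfaces (the experimentally quoted 0-0
# gap); the reorganization shift lambda carried by the correlation set moves
# it to the phase-factor energy of the displaced-oscillator formulation.
# The Condon reference freezes the non-Condon bracket at its t = 0 value,
# which is the real constant D(0) (F(0) vanishes identically).

gap_to_internal <- function(gap, gap_units, corr) {
  if (is.null(gap_units))
    gap_units <- if (corr$units == "reduced") "reduced" else "cm1"
  gap_units <- match.arg(gap_units, c("cm1", "ev", "reduced"))
  if ((gap_units == "reduced") != (corr$units == "reduced"))
    ndc_stop("gap unit '", gap_units, "' is inconsistent with a correlation ",
             "set in '", corr$units, "' units")
  switch(gap_units,
         cm1 = cm1_to_angfreq(gap),
         ev = ev_to_angfreq(gap),
         reduced = gap)
}

# Slowly varying part of the integrand (everything except the gap phase).
slow_integrand <- function(corr, kern = NULL, t = corr$grid$t,
                           gaussian_damping = NULL) {
  if (is.null(kern)) kern <- list(g = corr$g, F = corr$F, D = corr$D)
  C <- exp(-kern$g) * (kern$D + kern$F^2)
  if (!is.null(gaussian_damping)) {
    if (!is.numeric(gaussian_damping) || gaussian_damping <= 0)
      ndc_stop("gaussian_damping must be a positive time constant")
    C <- C * exp(-(t / gaussian_damping)^2)
  }
  C
}

#' Composite rate integrand on the time grid
#'
#' Returns \eqn{C(t) = e^{i(\Delta-\lambda)t} e^{-g(t)} [D(t) + F(t)^2]} on
#' the grid of the correlation set, with `gap` the adiabatic energy gap
#' \eqn{\Delta}. This is the quantity whose one-sided real-part integral is
#' the rate.
#'
#' @param corr an `ndc_corr` object.
#' @param gap energy gap (positive for a downhill transition), in `gap_units`.
#' @param gap_units `"cm1"`, `"ev"` or `"reduced"`; defaults to `"cm1"` for
#'   physical correlation sets and `"reduced"` for reduced ones.
#' @return complex vector on `corr$grid$t`.
#' @export
assemble_integrand <- function(corr, gap, gap_units = NULL) {
  if (!inherits(corr, "ndc_corr")) ndc_stop("corr must be an ndc_corr object")
  delta <- gap_to_internal(gap, gap_units, corr) - corr$lambda
  exp(1i * delta * corr$grid$t) * slow_integrand(corr)
}

trapz_uniform <- function(y, dt) {
  dt * (sum(y) - (y[1] + y[length(y)]) / 2)
}

# Shared machinery: integrate phase * spline(C_slow) on a fine uniform grid
# satisfying the oscillation-resolution requirement, with a dt/2 Richardson
# consistency value.
rate_engine <- function(corr, gap_i, C_slow, per_period = 20) {
  tg <- corr$grid
  delta <- gap_i - corr$lambda
  dt_req <- 2 * pi / (per_period * max(abs(gap_i) + corr$omega_max,
                                       1e-12 / tg$dt))
  re_f <- stats::splinefun(tg$t, Re(C_slow))
  im_f <- stats::splinefun(tg$t, Im(C_slow))
  dt_f <- min(tg$dt, dt_req)
  n_f <- ceiling(tg$t_max / dt_f)
  integral_at <- function(n) {
    tf <- seq(0, tg$t_max, length.out = n + 1L)
    Cf <- complex(real = re_f(tf), imaginary = im_f(tf))
    trapz_uniform(exp(1i * delta * tf) * Cf, tf[2] - tf[1])
  }
  I1 <- integral_at(n_f)
  I2 <- integral_at(2L * n_f)
  list(I = I2, k = 2 * Re(I2),
       richardson_rel = abs(2 * Re(I2) - 2 * Re(I1)) /
         max(abs(2 * Re(I2)), 1e-300),
       n_fine = 2L * n_f)
}

#' Fermi golden-rule rate for a momentum-coupled transition
#'
#' Integrates the composite correlation function on a uniform grid fine
#' enough to resolve the gap phase (trapezoidal rule, with a spacing-halved
#' Richardson consistency check), and reports the non-Condon rate, the Condon
#' reference (non-Condon kernel frozen at t = 0), and convergence
#' diagnostics.
#'
#' Purely discrete (undamped) baths have recurring integrands and no
#' well-defined rate; such correlation sets are refused unless an explicit,
#' physically artificial `gaussian_damping` time constant is supplied.
#'
#' @inheritParams assemble_integrand
#' @param gaussian_damping optional Gaussian window time constant (same time
#'   units as the grid); exploratory use only, off by default.
#' @param tail_tol largest acceptable relative magnitude of the slow
#'   integrand at `t_max`; beyond it the rate is deemed non-converged.
#' @param per_period time points per period of the fastest phase oscillation.
#' @param two_sided logical; also evaluate the kernels at negative times
#'   (through the correlation set's evaluator) and report the imaginary
#'   residual of the full two-sided integral as a consistency diagnostic.
#' @param on_nonconverged `"error"` (default) or `"flag"`.
#' @return object of class `ndc_rate` with fields `k`, `k_condon`, `gap`,
#'   `integrand_tail`, `imag_residual`, `richardson_rel`, `converged`, `units`.
#' @export
fgr_rate <- function(corr, gap, gap_units = NULL, gaussian_damping = NULL,
                     tail_tol = 1e-6, per_period = 20, two_sided = TRUE,
                     on_nonconverged = c("error", "flag")) {
  if (!inherits(corr, "ndc_corr")) ndc_stop("corr must be an ndc_corr object")
  on_nonconverged <- match.arg(on_nonconverged)
  if (!is.numeric(gap) || length(gap) != 1L || !is.finite(gap))
    ndc_stop("gap must be a single finite number")
  if (corr$undamped && is.null(gaussian_damping))
    ndc_stop_convergence(
      "the bath is purely discrete (undamped): the integrand never decays and ",
      "no rate is defined. Broaden the bath (Brownian-oscillator gamma or an ",
      "Ohmic component) or pass an explicit gaussian_damping window.")
  tg <- corr$grid
  if (tg$t_max < 20 * tg$dt) ndc_stop("time grid too coarse: t_max < 20 dt")
  gap_i <- gap_to_internal(gap, gap_units, corr)
  C_slow <- slow_integrand(corr, gaussian_damping = gaussian_damping)
  peak <- max(abs(C_slow))
  if (peak == 0) {   # no derivative coupling at all: the rate is exactly zero
    return(structure(
      list(k = 0, k_condon = 0, gap = gap, units = corr$units,
           integrand_tail = 0, imag_residual = 0, richardson_rel = 0,
           converged = TRUE,
           meta = list(lambda = corr$lambda, method = corr$method,
                       n_fine = 0L, gaussian_damping = gaussian_damping)),
      class = "ndc_rate"))
  }
  tail <- max(abs(C_slow[length(C_slow)]), abs(C_slow[length(C_slow) - 1L])) / peak
  eng <- rate_engine(corr, gap_i, C_slow, per_period)
  engc <- rate_engine(corr, gap_i,
                      exp(-corr$g) * Re(corr$D[1]) *
                        (if (is.null(gaussian_damping)) 1 else
                           exp(-(tg$t / gaussian_damping)^2)),
                      per_period)
  imag_residual <- NA_real_
  if (two_sided && !is.null(corr$evalfun)) {
    kern_neg <- corr$evalfun(-tg$t)
    C_neg <- slow_integrand(corr, kern = kern_neg, gaussian_damping = gaussian_damping)
    # integral over [-t_max, 0]: substitute t -> -t
    re_f <- stats::splinefun(tg$t, Re(C_neg))
    im_f <- stats::splinefun(tg$t, Im(C_neg))
    delta <- gap_i - corr$lambda
    tf <- seq(0, tg$t_max, length.out = eng$n_fine + 1L)
    Cf <- complex(real = re_f(tf), imaginary = im_f(tf))
    I_neg <- trapz_uniform(exp(-1i * delta * tf) * Cf, tf[2] - tf[1])
    I_two <- eng$I + I_neg
    imag_residual <- abs(Im(I_two)) / max(abs(Re(I_two)), 1e-300)
  }
  converged <- is.finite(eng$k) && tail <= tail_tol &&
    eng$richardson_rel < 1e-3 &&
    (is.na(imag_residual) || imag_residual < 1e-6)
  if (!converged && on_nonconverged == "error" && tail > tail_tol)
    ndc_stop_convergence(
      "rate integral not converged: relative integrand tail ", signif(tail, 3),
      " at t_max = ", signif(tg$t_max, 6),
      ". Increase t_max or add bath broadening.")
  structure(
    list(k = eng$k, k_condon = engc$k, gap = gap, units = corr$units,
         integrand_tail = tail, imag_residual = imag_residual,
         richardson_rel = eng$richardson_rel, converged = converged,
         meta = list(lambda = corr$lambda, method = corr$method,
                     n_fine = eng$n_fine,
                     gaussian_damping = gaussian_damping)),
    class = "ndc_rate")
}

#' @export
print.ndc_rate <- function(x, ...) {
  unit <- if (x$units == "reduced") "omega_c" else "ps^-1"
  cat(sprintf("<ndc_rate> gap = %g: k = %.6g %s (Condon %.6g)\n",
              x$gap, x$k, unit, x$k_condon))
  if (x$units != "reduced")
    cat(sprintf("  = %.6g ns^-1 (Condon %.6g ns^-1)\n",
                1000 * x$k, 1000 * x$k_condon))
  cat(sprintf("  tail %.3g | Richardson %.3g | imag residual %.3g | converged: %s\n",
              x$integrand_tail, x$richardson_rel, x$imag_residual, x$converged))
  invisible(x)
}

#' Condon reference rate
#'
#' The rate with the non-Condon kernel frozen at its initial value
#' (effective Condon coupling D(0)), sharing the lineshape integral machinery
#' of [fgr_rate()].
#'
#' @inheritParams fgr_rate
#' @return the Condon rate (scalar), in the units of [fgr_rate()].
#' @export
condon_rate <- function(corr, gap, gap_units = NULL, gaussian_damping = NULL,
                        tail_tol = 1e-6, per_period = 20) {
  fgr_rate(corr, gap, gap_units, gaussian_damping, tail_tol, per_period,
           two_sided = FALSE, on_nonconverged = "flag")$k_condon
}

#' Energy-gap scan of golden-rule rates
#'
#' Reuses one correlation set across a monotone grid of energy gaps (the gap
#' enters only through the phase factor).
#'
#' @inheritParams fgr_rate
#' @param gaps monotone numeric vector of energy gaps in `gap_units`.
#' @return data frame of class `ndc_scan` with columns `gap`, `k`,
#'   `k_condon`, `ln_k_scaled` (natural log of the rate in internal units;
#'   the Fig-style scaled logarithm in reduced mode) and `converged`.
#'   Non-converged points are flagged, not fatal.
#' @export
gap_scan <- function(corr, gaps, gap_units = NULL, gaussian_damping = NULL,
                     tail_tol = 1e-6, per_period = 20) {
  if (!is.numeric(gaps) || length(gaps) < 1L || any(!is.finite(gaps)))
    ndc_stop("gaps must be a finite numeric vector")
  if (inherits(corr, "ndc_corr") && corr$undamped && is.null(gaussian_damping))
    ndc_stop_convergence(
      "the bath is purely discrete (undamped): no rate is defined. ",
      "Broaden the bath or pass an explicit gaussian_damping window.")
  if (is.unsorted(gaps) && is.unsorted(rev(gaps)))
    ndc_stop("gaps must be monotone")
  rows <- lapply(seq_along(gaps), function(i) {
    r <- tryCatch(
      fgr_rate(corr, gaps[i], gap_units, gaussian_damping, tail_tol,
               per_period, two_sided = (i == 1L), on_nonconverged = "flag"),
      ndcrate_convergence_error = function(e) NULL)
    if (is.null(r))
      return(data.frame(gap = gaps[i], k = NA_real_, k_condon = NA_real_,
                        ln_k_scaled = NA_real_, converged = FALSE))
    data.frame(gap = r$gap, k = r$k, k_condon = r$k_condon,
               ln_k_scaled = if (r$k > 0) log(r$k) else NA_real_,
               converged = r$converged)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ndc_scan", "data.frame")
  attr(out, "units") <- corr$units
  out
}
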