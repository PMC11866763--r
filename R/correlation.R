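# Bath time-correlation functions.
#
# The three kernels of the rate integral, per mode j with vibronic coupling
# g_j, derivative-coupling projection f_j and thermal factor
# c_j = coth(beta*hbar*omega_j/2):
#   g(t) = sum_j g_j^2 [ c_j (1 - cos w_j t) + i (sin w_j t - w_j t) ]
#   F(t) = sum_j (w_j g_j f_j / sqrt(2)) [ c_j (1 - cos w_j t) + i sin w_j t ]
#   D(t) = sum_j (w_j^2 f_j^2 / 2)       [ c_j cos w_j t       - i sin w_j t ]
# (F and D are the hbar-scaled kernels, ps^-1 and ps^-2.) These exact sums were
# validated against a numerically exact truncated-Fock-space computation of
# the full correlation function (see tests/testthat/helper-oracles.R).
# Continuous spectral densities are reduced to the same sums by converting
# quadrature nodes into point masses g2 = J(w) dw / (pi w^2) etc., so the
# spectral, discrete and Brownian-oscillator paths share one engine and
# delta components are always handled analytically.

# ---- kernel engine ---------------------------------------------------------

# Exact kernel sums over point masses. omega: internal angular frequencies;
# g2, f2, gf: per-mass dimensionless weights; t may be any sign.
sum_kernels <- function(omega, g2, f2, gf, beta_hbar, t, chunk_floats = 1e7) {
  n_t <- length(t)
  g <- complex(n_t); FF <- complex(n_t); DD <- complex(n_t)
  if (length(omega) == 0L) return(list(g = g, F = FF, D = DD))
  cth <- .coth(beta_hbar * omega / 2)
  # weight columns for the two trig reductions
  Wc <- cbind(g2 * cth, omega * gf * cth, omega^2 * f2 * cth)  # with cos
  Ws <- cbind(g2, omega * gf, omega^2 * f2)                    # with sin
  s_g2c <- sum(g2 * cth); s_gfc <- sum(omega * gf * cth)
  lam <- sum(omega * g2)
  chunk <- max(16L, floor(chunk_floats / length(omega)))
  i0 <- 1L
  while (i0 <= n_t) {
    i1 <- min(n_t, i0 + chunk - 1L)
    ph <- omega %o% t[i0:i1]
    cosM <- cos(ph); sinM <- sin(ph)
    rc <- crossprod(cosM, Wc)   # n_chunk x 3
    rs <- crossprod(sinM, Ws)
    tt <- t[i0:i1]
    g[i0:i1]  <- (s_g2c - rc[, 1]) + 1i * (rs[, 1] - lam * tt)
    FF[i0:i1] <- ((s_gfc - rc[, 2]) + 1i * rs[, 2]) / sqrt(2)
    DD[i0:i1] <- (rc[, 3] - 1i * rs[, 3]) / 2
    i0 <- i1 + 1L
  }
  # g(0) = 0 and F(0) = 0 hold identically; remove summation roundoff
  z <- t == 0
  g[z] <- 0 + 0i; FF[z] <- 0 + 0i; DD[z] <- Re(DD[z]) + 0i
  list(g = g, F = FF, D = DD, lambda = lam)
}

# Quadrature node set for the continuous part of a triple, as point masses.
# Node placement must resolve the integrand oscillation exp(i omega t) up to
# t_max (about `per_period` nodes per period) and the spectral envelope.
continuum_masses <- function(triple, t_max, per_period = 10, tol = 1e-8) {
  if (!triple$has_continuum)
    return(data.frame(omega = numeric(0), g2 = numeric(0),
                      f2 = numeric(0), gf = numeric(0)))
  if (triple$kind == "bo_broadened") return(bo_masses(triple, t_max))
  scale <- triple$omega_scale
  omega_cut <- if (triple$kind == "tabulated") scale else
    scale * max(38, ceiling(-log(max(tol, 1e-14) * 1e-4)))
  panel <- min(scale / 4, 2 * pi / (max(t_max, 1e-12) * per_period / 8))
  n_panel <- min(8000L, max(24L, ceiling(omega_cut / panel)))
  gl <- pracma::gaussLegendre(8, 0, 1)
  edges <- seq(0, omega_cut, length.out = n_panel + 1L)
  h <- diff(edges)
  w_nodes <- as.vector(vapply(seq_len(n_panel),
                              function(k) edges[k] + h[k] * gl$x, numeric(8)))
  w_wts <- as.vector(vapply(seq_len(n_panel),
                            function(k) h[k] * gl$w, numeric(8)))
  J <- triple$Jc$J(w_nodes); JD <- triple$Jc$J_D(w_nodes); JF <- triple$Jc$J_F(w_nodes)
  conv <- w_wts / (pi * w_nodes^2)
  data.frame(omega = w_nodes, g2 = J * conv, f2 = JD * conv, gf = JF * conv)
}

# Node set for Brownian-oscillator broadened modes: fine windows around each
# mode position (finer than the fake-recurrence limit 2*pi/t_max), a wider
# intermediate window, and a coarse tail. Masses are renormalized per mode so
# broadening conserves the integrated weight exactly.
bo_masses <- function(triple, t_max) {
  gam <- triple$gamma
  d <- triple$deltas_src
  dnu_fine <- 2 * pi / (3 * max(t_max, 1e-12))
  nodes <- numeric(0)
  for (j in seq_len(nrow(d))) {
    wj <- d$omega[j]
    w1 <- 12 * gam; w2 <- 120 * gam
    fine <- seq(max(dnu_fine / 2, wj - w1), wj + w1, by = min(dnu_fine, gam / 6))
    mid <- c(seq(max(dnu_fine / 2, wj - w2), max(dnu_fine, wj - w1), length.out = 60),
             seq(wj + w1, wj + w2, length.out = 60))
    nodes <- c(nodes, fine, mid)
  }
  wmax <- max(d$omega) * 6 + 60 * gam
  nodes <- c(nodes, seq(dnu_fine / 2, wmax, length.out = 400))
  nodes <- sort(unique(nodes[nodes > 0 & nodes <= wmax]))
  # midpoint cell weights
  edges <- c(0, (nodes[-1] + nodes[-length(nodes)]) / 2, wmax)
  cellw <- diff(edges)
  out <- data.frame(omega = nodes, g2 = 0, f2 = 0, gf = 0)
  for (j in seq_len(nrow(d))) {
    wj <- d$omega[j]
    B <- bo_lineshape(nodes, wj, gam) * cellw
    B <- B / sum(B)                     # conserve integrated weight exactly
    out$g2 <- out$g2 + d$g2[j] * wj^2 * B / nodes^2
    out$f2 <- out$f2 + d$f2[j] * wj^2 * B / nodes^2
    out$gf <- out$gf + d$gf[j] * wj^2 * B / nodes^2
  }
  out
}

# ---- correlation set -------------------------------------------------------

new_corr <- function(grid, kern, thermo, method, units, undamped, omega_max,
                     evalfun, meta = list()) {
  structure(
    list(grid = grid, g = kern$g, F = kern$F, D = kern$D,
         lambda = kern$lambda, thermo = thermo, method = method,
         units = units, undamped = undamped, omega_max = omega_max,
         evalfun = evalfun, meta = meta),
    class = "ndc_corr")
}

#' @export
print.ndc_corr <- function(x, ...) {
  cat(sprintf(
    "<ndc_corr> method=%s, %d time points (dt=%.4g, t_max=%.4g), units=%s\n",
    x$method, length(x$grid$t), x$grid$dt, x$grid$t_max, x$units))
  cat(sprintf("  lambda/hbar = %.6g, D(0) = %.6g, undamped = %s\n",
              x$lambda, Re(x$D[1]), x$undamped))
  invisible(x)
}

#' @export
as.data.frame.ndc_corr <- function(x, ...) {
  data.frame(t = x$grid$t,
             Re_g = Re(x$g), Im_g = Im(x$g),
             Re_F = Re(x$F), Im_F = Im(x$F),
             Re_D = Re(x$D), Im_D = Im(x$D))
}

check_corr_inputs <- function(thermo, grid) {
  if (!inherits(thermo, "ndc_thermo")) ndc_stop("thermo must be an ndc_thermo object")
  if (!inherits(grid, "ndc_grid")) ndc_stop("grid must be an ndc_grid object")
}

#' Correlation functions by spectral-density quadrature
#'
#' Evaluates g(t), F(t) and D(t) from a spectral triple on a uniform time
#' grid. Continuous components are integrated on Gauss-Legendre nodes dense
#' enough to resolve the oscillatory factors up to `t_max`; delta components
#' are summed analytically; Brownian-oscillator broadened modes use adapted
#' node windows around each mode with exactly conserved integrated weight.
#'
#' @param triple an `ndc_triple`.
#' @param thermo an [thermo_state()] object in the same unit system.
#' @param grid an [time_grid()] object.
#' @param per_period quadrature nodes per oscillation period of the slowest
#'   resolved factor (accuracy control; default resolves `exp(i*omega*t_max)`
#'   comfortably).
#' @param tol relative envelope tolerance used when choosing the
#'   high-frequency cutoff of the quadrature.
#' @return object of class `ndc_corr` carrying complex vectors `g`, `F`, `D`
#'   (`F` and `D` are the hbar-scaled kernels, in ps^-1 / ps^-2 for physical
#'   units), the reorganization drift `lambda`, and an evaluator usable at
#'   arbitrary (also negative) times for diagnostics.
#' @export
corr_from_spectrum <- function(triple, thermo, grid, per_period = 10, tol = 1e-8) {
  if (!inherits(triple, "ndc_triple")) ndc_stop("triple must be an ndc_triple object")
  check_corr_inputs(thermo, grid)
  if ((triple$units == "reduced") != (thermo$units == "reduced"))
    ndc_stop("triple and thermo use different unit systems")
  cont <- continuum_masses(triple, grid$t_max, per_period = per_period, tol = tol)
  d <- triple$deltas
  masses <- rbind(cont,
                  data.frame(omega = d$omega, g2 = d$g2, f2 = d$f2, gf = d$gf))
  bh <- thermo$beta_hbar
  evalfun <- local({
    m <- masses; bh0 <- bh
    function(t) sum_kernels(m$omega, m$g2, m$f2, m$gf, bh0, t)
  })
  kern <- evalfun(grid$t)
  undamped <- !(triple$has_continuum && sum(cont$g2) > 0)
  omega_max <- switch(triple$kind,
    parametric  = max(c(d$omega, 20 * triple$omega_scale)),
    tabulated   = triple$omega_scale,
    bo_broadened = max(triple$deltas_src$omega) + 12 * triple$gamma,
    max(c(d$omega, if (nrow(cont)) max(cont$omega), 0)))
  new_corr(grid, kern, thermo, "quadrature", triple$units, undamped,
           omega_max = omega_max, evalfun = evalfun,
           meta = list(kind = triple$kind, n_nodes = nrow(cont)))
}

#' @rdname corr_from_spectrum
#' @return `g_from_spectrum`, `F_from_spectrum` and `D_from_spectrum` return
#'   the corresponding complex vector on the grid.
#' @export
g_from_spectrum <- function(triple, thermo, grid, per_period = 10, tol = 1e-8) {
  corr_from_spectrum(triple, thermo, grid, per_period, tol)$g
}

#' @rdname corr_from_spectrum
#' @export
F_from_spectrum <- function(triple, thermo, grid, per_period = 10, tol = 1e-8) {
  corr_from_spectrum(triple, thermo, grid, per_period, tol)$F
}

#' @rdname corr_from_spectrum
#' @export
D_from_spectrum <- function(triple, thermo, grid, per_period = 10, tol = 1e-8) {
  corr_from_spectrum(triple, thermo, grid, per_period, tol)$D
}

#' Correlation functions by exact discrete-mode summation
#'
#' The finite-sum evaluation over normal modes; algebraically identical to the
#' spectral path with exact delta functions for all three densities.
#'
#' @param modes an [discrete_modes()] object.
#' @inheritParams corr_from_spectrum
#' @return an `ndc_corr` (method `"discrete"`). A purely discrete bath never
#'   dephases completely, so the result is flagged as undamped and the rate
#'   stage will demand explicit broadening.
#' @export
corr_from_discrete <- function(modes, thermo, grid) {
  if (!inherits(modes, "ndc_modes")) ndc_stop("modes must be an ndc_modes object")
  check_corr_inputs(thermo, grid)
  if (length(modes$omega) == 0L)
    warning("empty mode set: g = F = D = 0")
  bh <- thermo$beta_hbar
  evalfun <- local({
    m <- modes; bh0 <- bh
    function(t) sum_kernels(m$omega_i, m$g^2, m$f^2, m$g * m$f, bh0, t)
  })
  kern <- evalfun(grid$t)
  new_corr(grid, kern, thermo, "discrete", modes$units, undamped = TRUE,
           omega_max = max(c(modes$omega_i, 0)), evalfun = evalfun,
           meta = list(n_modes = length(modes$omega)))
}

# ---- closed forms for the Ohmic + delta family -----------------------------

# Thermal sums over n >= 1 with tau_n = omega_c * t / (1 + n * theta),
# evaluated as `n_exact` direct terms plus the closed-form Euler-Maclaurin
# midpoint tail (exact integral of the continuum closure from n_exact + 1/2).
# With n_exact = 2 this is the interpolation-style approximation built on the
# arctangent integral; with large n_exact it converges to the exact sum.
ohmic_thermal_sums <- function(wct, theta, n_exact) {
  n_t <- length(wct)
  Sg <- numeric(n_t); SD <- numeric(n_t); SF <- numeric(n_t)
  denom <- 1 + seq_len(n_exact) * theta
  inv_d <- 1 / denom
  # direct part, vectorized over (n, t) in chunks
  chunk <- max(8L, floor(4e6 / n_exact))
  i0 <- 1L
  while (i0 <= n_t) {
    i1 <- min(n_t, i0 + chunk - 1L)
    tau <- inv_d %o% wct[i0:i1]          # n_exact x n_chunk
    tau2 <- tau^2
    Sg[i0:i1] <- colSums(log1p(tau2))
    SD[i0:i1] <- colSums((1 - tau2) * inv_d^2 / (1 + tau2)^2)
    SF[i0:i1] <- colSums(tau2 * inv_d / (1 + tau2))
    i0 <- i1 + 1L
  }
  # midpoint tail from n0 = n_exact + 1/2 (closed forms; see vignette)
  taum <- wct / (1 + (n_exact + 0.5) * theta)
  nz <- wct != 0
  tg <- numeric(n_t); tD <- numeric(n_t); tF <- numeric(n_t)
  tg[nz] <- (wct[nz] / theta) *
    (2 * atan(taum[nz]) - log1p(taum[nz]^2) / taum[nz])
  tD[nz] <- taum[nz] / (theta * wct[nz] * (1 + taum[nz]^2))
  tF <- log1p(taum^2) / (2 * theta)
  list(Sg = Sg + tg, SD = SD + tD, SF = SF + tF)
}

closed_form_kernels <- function(params, thermo, t, use_approx = FALSE,
                                n_exact = 4000L) {
  wc <- params$omega_c_i; wh <- params$omega_h_i
  theta <- thermo$beta_hbar * wc
  if (use_approx) n_exact <- 2L
  ta <- abs(t); sg <- sign(t)
  wct <- wc * ta
  tau0 <- wct
  S <- ohmic_thermal_sums(wct, theta, n_exact)
  # Ohmic components
  re_g <- params$eta * (0.5 * log1p(tau0^2) + S$Sg)
  im_g <- params$eta * (atan(tau0) - tau0)
  re_D <- (params$eta_D * wc^2 / 2) *
    ((1 - tau0^2) / (1 + tau0^2)^2 + 2 * S$SD)
  im_D <- -params$eta_D * wc^2 * tau0 / (1 + tau0^2)^2
  re_F <- (params$eta_F * wc / sqrt(2)) * (tau0^2 / (1 + tau0^2) + 2 * S$SF)
  im_F <- (params$eta_F * wc / sqrt(2)) * tau0 / (1 + tau0^2)
  # delta components (exact single-mode thermal kernels)
  cth <- .coth(thermo$beta_hbar * wh / 2)
  cwt <- cos(wh * ta); swt <- sin(wh * ta)
  re_g <- re_g + params$s_h * cth * (1 - cwt)
  im_g <- im_g + params$s_h * (swt - wh * ta)
  re_D <- re_D + (wh^2 * params$s_D / 2) * cth * cwt
  im_D <- im_D - (wh^2 * params$s_D / 2) * swt
  re_F <- re_F + (wh * params$s_F / sqrt(2)) * cth * (1 - cwt)
  im_F <- im_F + (wh * params$s_F / sqrt(2)) * swt
  # Hermitian extension to negative times: even real parts, odd imaginary
  list(g = complex(real = re_g, imaginary = sg * im_g),
       F = complex(real = re_F, imaginary = sg * im_F),
       D = complex(real = re_D, imaginary = sg * im_D),
       lambda = params$eta * wc + params$s_h * wh)
}

#' Correlation functions in closed form for the Ohmic + delta bath
#'
#' The analytic real and imaginary parts of g(t), F(t) and D(t) for the
#' parametric family, built from `tau_n = omega_c t / (1 + n theta)` thermal
#' sums (`theta = beta hbar omega_c`) plus the exact single-mode kernels of
#' the delta peak. By default the thermal sums are evaluated essentially
#' exactly (direct terms plus a closed-form midpoint tail);
#' `use_eq_approx = TRUE` switches to the short interpolation built on the
#' arctangent-integral closure after the first two terms, a documented
#' few-percent approximation.
#'
#' @param params an [ohmic_delta_params()] object.
#' @inheritParams corr_from_spectrum
#' @param use_eq_approx logical; use the interpolation approximation for the
#'   Ohmic thermal sums.
#' @param n_exact number of directly summed thermal terms before the tail
#'   closure (accuracy control for the exact path).
#' @return an `ndc_corr` (method `"closed_form"`).
#' @export
corr_closed_form <- function(params, thermo, grid, use_eq_approx = FALSE,
                             n_exact = 4000L) {
  if (!inherits(params, "ndc_params")) ndc_stop("params must be an ndc_params object")
  check_corr_inputs(thermo, grid)
  evalfun <- local({
    p <- params; th <- thermo; ua <- use_eq_approx; ne <- n_exact
    function(t) closed_form_kernels(p, th, t, ua, ne)
  })
  kern <- evalfun(grid$t)
  new_corr(grid, kern, thermo, "closed_form", params$units,
           undamped = params$eta == 0,
           omega_max = max(params$omega_h_i,
                           params$omega_c_i * 20),
           evalfun = evalfun,
           meta = list(use_eq_approx = use_eq_approx, n_exact = n_exact))
}

#' @rdname corr_closed_form
#' @return `closed_form_g`, `closed_form_F`, `closed_form_D` return the
#'   corresponding complex vector on the grid.
#' @export
closed_form_g <- function(params, thermo, grid, use_eq_approx = FALSE,
                          n_exact = 4000L) {
  corr_closed_form(params, thermo, grid, use_eq_approx, n_exact)$g
}

#' @rdname corr_closed_form
#' @export
closed_form_F <- function(params, thermo, grid, use_eq_approx = FALSE,
                          n_exact = 4000L) {
  corr_closed_form(params, thermo, grid, use_eq_approx, n_exact)$F
}

#' @rdname corr_closed_form
#' @export
closed_form_D <- function(params, thermo, grid, use_eq_approx = FALSE,
                          n_exact = 4000L) {
  corr_closed_form(params, thermo, grid, use_eq_approx, n_exact)$D
}

#' Add two correlation sets componentwise
#'
#' Composes independent bath contributions (e.g. molecular modes plus an
#' environmental Ohmic bath coupled only through g). Both sets must share the
#' grid, thermodynamic state and unit system.
#'
#' @param a,b `ndc_corr` objects.
#' @return an `ndc_corr` with summed kernels; it is damped if either
#'   component is damped.
#' @export
corr_add <- function(a, b) {
  if (!inherits(a, "ndc_corr") || !inherits(b, "ndc_corr"))
    ndc_stop("corr_add needs two ndc_corr objects")
  if (length(a$grid$t) != length(b$grid$t) ||
      max(abs(a$grid$t - b$grid$t)) > 1e-12 * a$grid$t_max)
    ndc_stop("correlation sets live on different time grids")
  if (abs(a$thermo$beta_hbar - b$thermo$beta_hbar) >
      1e-9 * a$thermo$beta_hbar || a$units != b$units)
    ndc_stop("correlation sets have inconsistent thermodynamic state or units")
  ea <- a$evalfun; eb <- b$evalfun
  evalfun <- function(t) {
    ka <- ea(t); kb <- eb(t)
    list(g = ka$g + kb$g, F = ka$F + kb$F, D = ka$D + kb$D,
         lambda = ka$lambda + kb$lambda)
  }
  new_corr(a$grid,
           list(g = a$g + b$g, F = a$F + b$F, D = a$D + b$D,
                lambda = a$lambda + b$lambda),
           a$thermo, paste(unique(c(a$method, b$method)), collapse = "+"),
           a$units, undamped = a$undamped && b$undamped,
           omega_max = max(a$omega_max, b$omega_max),
           evalfun = evalfun,
           meta = list(components = list(a$meta, b$meta)))
}
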