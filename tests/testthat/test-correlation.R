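# Correlation-function tests. The deepest checks compare the package's
# composite correlation function against a numerically exact truncated-Fock-
# space computation (helper-oracles.R), which is independent of every
# analytic kernel here.

test_that("composite correlation function matches the exact Fock-space oracle", {
  tpts <- c(0.35, 1.2, 2.8, 6.1)
  # single mode
  m1 <- discrete_modes(1.3, g = 0.7, f = 1.0, units = "reduced")
  ex1 <- fock_corr_exact(1.3, 0.7, 1.0, beta = 0.9, tpts, nmax = 90L)
  an1 <- pkg_corr_composite(m1, beta = 0.9, tpts)
  expect_rel_close(an1, ex1, 1e-7, scale = max(abs(ex1)))
  # two modes with opposite-sign NDC projections (pins the sign structure of
  # the cross kernel F, which single-mode checks cannot see)
  m2 <- discrete_modes(c(1.0, 1.7), g = c(0.6, 0.5), f = c(0.8, -0.45),
                       units = "reduced")
  ex2 <- fock_corr_exact(c(1.0, 1.7), c(0.6, 0.5), c(0.8, -0.45),
                         beta = 1.1, tpts, nmax = 24L)
  an2 <- pkg_corr_composite(m2, beta = 1.1, tpts)
  expect_rel_close(an2, ex2, 1e-5, scale = max(abs(ex2)))
})

test_that("kernels vanish correctly at t = 0 and D(0) is the thermal strength sum", {
  m <- random_modeset(25, lambda = 400, D_strength = 60, seed = 3)
  th <- thermo_state(250)
  corr <- corr_from_discrete(m, th, time_grid(1, n = 64))
  expect_identical(corr$g[1], 0 + 0i)
  expect_identical(corr$F[1], 0 + 0i)
  expect_identical(Im(corr$D[1]), 0)
  w <- m$omega_i
  D0 <- sum(w^2 * m$f^2 / 2 / tanh(th$beta_hbar * w / 2))
  expect_rel_close(Re(corr$D[1]), D0, 1e-12)
})

test_that("closed-form and quadrature paths agree to 1e-6 for parametric baths", {
  for (id in c("I-A", "I-B")) {
    case <- table2_case(id)
    grid <- time_grid(10, n = 250)
    cc <- corr_closed_form(case$params, case$thermo, grid)
    cq <- corr_from_spectrum(parametric_triple(case$params), case$thermo, grid)
    sel <- grid$t > 0
    expect_rel_close(cq$g[sel], cc$g[sel], 1e-6)
    expect_rel_close(cq$F[sel], cc$F[sel], 1e-6, scale = max(abs(cc$F)))
    expect_rel_close(cq$D[sel], cc$D[sel], 1e-6, scale = max(abs(cc$D)))
    expect_equal(cq$lambda, cc$lambda, tolerance = 1e-10)
  }
})

test_that("discrete sums equal the spectral path with analytic deltas to 1e-10", {
  m <- random_modeset(30, lambda = 600, D_strength = 90, seed = 5)
  th <- thermo_state(300)
  grid <- time_grid(0.8, n = 300)
  cd <- corr_from_discrete(m, th, grid)
  cs <- corr_from_spectrum(triple_from_modes(m), th, grid)
  expect_lt(max(abs(cd$g - cs$g)), 1e-10)
  expect_lt(max(abs(cd$F - cs$F)), 1e-10)
  expect_lt(max(abs(cd$D - cs$D)), 1e-10)
})

test_that("single-mode lineshape recurs at the vibrational period in the cold limit", {
  m <- discrete_modes(1, g = 1, f = 0, units = "reduced")
  th <- thermo_state(theta = 50, units = "reduced")   # essentially T = 0
  grid <- time_grid(2 * pi, n = 360)
  corr <- corr_from_discrete(m, th, grid)
  amp <- abs(exp(-(corr$g + 1i * corr$lambda * grid$t)))  # drop the trivial drift
  expect_equal(amp[1], 1)
  expect_lt(abs(amp[length(amp)] - 1), 1e-9)            # |exp(-g(2 pi / w))| = 1
  expect_lt(min(amp), 0.2)                              # deep collapse in between
})

test_that("imaginary part of g drifts as -lambda t at long times", {
  p <- ohmic_delta_params(1.7, 1, units = "reduced")
  th <- thermo_state(theta = 1, units = "reduced")
  grid <- time_grid(100, n = 500)
  g <- closed_form_g(p, th, grid)
  sel <- grid$t >= 50
  slope <- stats::coef(stats::lm(Im(g[sel]) ~ grid$t[sel]))[[2]]
  expect_rel_close(slope, -1.7, 2e-4)
})

test_that("the interpolation approximation stays within its documented bound", {
  p <- ohmic_delta_params(1, 1, eta_D = 4, eta_F = 2, units = "reduced")
  th <- thermo_state(theta = 1, units = "reduced")
  grid <- time_grid(10, n = 400)
  sel <- grid$t >= 0.1
  for (fn in list(closed_form_g, closed_form_F, closed_form_D)) {
    exact <- fn(p, th, grid)
    approx <- fn(p, th, grid, use_eq_approx = TRUE)
    expect_lt(max(abs(approx[sel] - exact[sel]) / abs(exact[sel])), 0.02)
  }
})

test_that("F is odd in the cross couplings and zero without them", {
  th <- thermo_state(theta = 1, units = "reduced")
  grid <- time_grid(8, n = 200)
  pp <- ohmic_delta_params(1, 1, s_h = 1, omega_h = 5, eta_D = 15, s_D = 1,
                           eta_F = 2, s_F = 1, units = "reduced")
  pm <- ohmic_delta_params(1, 1, s_h = 1, omega_h = 5, eta_D = 15, s_D = 1,
                           eta_F = -2, s_F = -1, units = "reduced")
  expect_equal(closed_form_F(pm, th, grid), -closed_form_F(pp, th, grid))
  p0 <- ohmic_delta_params(1, 1, s_h = 1, omega_h = 5, units = "reduced")
  expect_true(all(closed_form_F(p0, th, grid) == 0))
  expect_true(all(closed_form_D(p0, th, grid) == 0))
  # all f_j = 0 leaves g unchanged and kills F and D
  m <- random_modeset(10, lambda = 300, seed = 2)
  corr <- corr_from_discrete(m, thermo_state(300), time_grid(1, n = 100))
  expect_true(all(corr$F == 0) && all(corr$D == 0))
  expect_gt(max(abs(corr$g)), 0)
})

test_that("kernels obey Hermitian time-reversal symmetry", {
  case <- table2_case("II-B")
  grid <- time_grid(6, n = 100)
  corr <- corr_closed_form(case$params, case$thermo, grid)
  neg <- corr$evalfun(-grid$t)
  expect_lt(max(abs(neg$g - Conj(corr$g))), 1e-12)
  expect_lt(max(abs(neg$F - Conj(corr$F))), 1e-12)
  expect_lt(max(abs(neg$D - Conj(corr$D))), 1e-12)
  m <- random_modeset(15, lambda = 200, D_strength = 40, seed = 9)
  corr2 <- corr_from_discrete(m, thermo_state(200), time_grid(0.5, n = 80))
  neg2 <- corr2$evalfun(-corr2$grid$t)
  expect_lt(max(abs(neg2$D - Conj(corr2$D))), 1e-10)
})

test_that("Ohmic Re g is monotone and approaches the classical form at high T", {
  th <- thermo_state(theta = 1, units = "reduced")
  p <- ohmic_delta_params(1, 1, units = "reduced")
  g <- closed_form_g(p, th, time_grid(20, n = 800))
  expect_true(all(diff(Re(g)) >= -1e-12))
  # theta -> 0: Re g ~ lambda * kT * t^2 at short times
  th0 <- thermo_state(theta = 0.01, units = "reduced")
  grid <- time_grid(0.05, n = 20)
  g0 <- closed_form_g(p, th0, grid)
  tt <- grid$t[-1]
  expect_rel_close(Re(g0[-1]), 100 * tt^2, 2e-3, scale = 100 * tt^2)
})

test_that("empty mode sets warn and return identically zero kernels", {
  th <- thermo_state(300)
  expect_warning(
    corr <- corr_from_discrete(discrete_modes(numeric(0)), th, time_grid(1, n = 50)),
    "empty")
  expect_true(all(corr$g == 0) && all(corr$F == 0) && all(corr$D == 0))
})
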