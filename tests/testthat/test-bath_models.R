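test_that("parameter invariants are enforced with informative errors", {
  expect_error(ohmic_delta_params(-1, 200), "eta >= 0")
  expect_error(ohmic_delta_params(1, 0), "omega_c > 0")
  expect_error(ohmic_delta_params(1, 200, s_h = -0.1, omega_h = 1000), "s_h >= 0")
  expect_error(ohmic_delta_params(1, 200, s_h = 1, omega_h = 1000, s_D = 4, s_F = 1),
               "s_F\\^2 = s_h \\* s_D")
  expect_error(ohmic_delta_params(1, 200, eta_D = 4, eta_F = 2.01),
               "cross-coupling bound")
  expect_error(ohmic_delta_params(1, 200, s_h = 1), "omega_h > 0")
  # s_F defaults to the positive saturated value
  p <- ohmic_delta_params(1, 200, s_h = 1, omega_h = 1000, s_D = 4)
  expect_equal(p$s_F, 2)
})

test_that("reorganization functional reproduces the strength mappings exactly", {
  p <- ohmic_delta_params(1, 200, s_h = 1, omega_h = 1000, s_D = 4)
  expect_equal(reorganization_energy(p), 1200)
  expect_equal(ndc_strength(p), 4000)
  # Ohmic-only: lambda_l = eta * omega_c
  expect_equal(reorganization_energy(ohmic_delta_params(1, 200)), 200)
  expect_equal(reorganization_energy(ohmic_delta_params(0, 200)), 0)
  # quadrature over the continuous triple agrees with the exact mapping
  tr <- parametric_triple(ohmic_delta_params(2, 150, eta_D = 4, eta_F = 1))
  expect_rel_close(reorganization_energy(tr), 300, 1e-8)
  # discrete: equals the direct per-mode sum to near machine precision
  m <- random_modeset(40, lambda = 700, D_strength = 120, seed = 11)
  expect_rel_close(reorganization_energy(m), sum(m$omega * m$g^2), 1e-12)
  expect_rel_close(ndc_strength(m), sum(m$omega * m$f^2), 1e-12)
})

test_that("parametric densities: zero at origin, Ohmic peak at omega_c, tagged deltas", {
  p <- ohmic_delta_params(1, 200, s_h = 1, omega_h = 1000, s_D = 4)
  at0 <- eval_parametric_triple(p, 0)
  expect_identical(c(at0$J, at0$J_D, at0$J_F), c(0, 0, 0))
  expect_error(eval_parametric_triple(p, -1), "domain error")
  # argmax of the Ohmic profile on a dense grid sits at omega_c
  w <- seq(1, 2000, length.out = 1e5)
  ev <- eval_parametric_triple(p, w)
  expect_lt(abs(w[which.max(ev$J)] - 200), 0.02)
  # delta component is a tagged point mass, never a grid spike
  expect_equal(nrow(ev$deltas), 1L)
  expect_equal(ev$deltas$omega, cm1_to_angfreq(1000))
  expect_rel_close(ev$deltas$wJ, pi * cm1_to_angfreq(1000)^2 * 1, 1e-12)
  expect_rel_close(ev$deltas$wJD, pi * cm1_to_angfreq(1000)^2 * 4, 1e-12)
})

test_that("parametric and single-mode constructions give identical delta weights", {
  p <- ohmic_delta_params(0, 200, s_h = 0.7, omega_h = 900, s_D = 2.1,
                          s_F = -sqrt(0.7 * 2.1))
  m <- discrete_modes(900, g = sqrt(0.7), f = -sqrt(2.1))
  dp <- parametric_triple(p)$deltas
  dm <- triple_from_modes(m)$deltas
  expect_equal(dp$omega, dm$omega)
  expect_equal(dp$g2, dm$g2)
  expect_equal(dp$f2, dm$f2)
  expect_equal(dp$gf, dm$gf, tolerance = 1e-12)
})

test_that("Brownian-oscillator lineshape is normalized with correct limits", {
  # closed-form normalization vs adaptive quadrature, under- and overdamped
  for (gam in c(10, 400, 1900, 2500)) {
    f <- function(w) bo_lineshape(w, 1000, gam)
    I <- pracma::integral(f, 0, 1e5, reltol = 1e-11) +
      pracma::integral(f, 1e5, 1e9, reltol = 1e-9)
    expect_lt(abs(I - 1), 1e-6)
  }
  expect_identical(bo_lineshape(0, 1000, 400), 0)
  # narrow lineshape: first moment stays at the mode position
  m1 <- pracma::integral(function(w) w * bo_lineshape(w, 1000, 10),
                         0, 1e5, reltol = 1e-10)
  expect_gt(m1, 990); expect_lt(m1, 1010)
  # log-log slopes: +1 at omega -> 0+, -3 far above the mode
  lo <- c(1e-3, 2e-3); hi <- c(2e5, 4e5)
  slope <- function(w) diff(log(bo_lineshape(w, 1000, 400))) / diff(log(w))
  expect_lt(abs(slope(lo) - 1), 1e-3)
  expect_lt(abs(slope(hi) + 3), 1e-2)
  expect_error(bo_lineshape(100, 1000, 0), "gamma")
  expect_error(bo_lineshape(100, 1000, -5), "gamma")
})

test_that("broadened triples keep integrated weight and asymptotic slopes", {
  m <- discrete_modes(c(600, 1400), g = c(0.5, 0.3), f = c(0.1, -0.2))
  tr <- triple_from_modes(m, gamma = 400)
  expect_equal(tr$kind, "bo_broadened")
  # integrated J equals the sum of the point-mass weights to 1e-8 relative
  target <- pi * sum(cm1_to_angfreq(m$omega)^2 * m$g^2)
  I <- pracma::integral(tr$Jc$J, 0, 1e7, reltol = 1e-10)
  expect_rel_close(I, target, 1e-8)
  # J_F inherits mixed signs
  w <- cm1_to_angfreq(c(600, 1400))
  expect_gt(tr$Jc$J_F(w[1]), 0)
  expect_lt(tr$Jc$J_F(w[2]), 0)
  # empty set: identically zero triple
  tr0 <- triple_from_modes(discrete_modes(numeric(0)))
  expect_identical(eval_triple(tr0, c(0, 100, 500))$J, c(0, 0, 0))
})

test_that("cross-coupling bound check distinguishes valid and violating inputs", {
  expect_true(check_cross_bound(table2_case("I-B")$params)$pass)
  ok <- check_cross_bound(ohmic_delta_params(1, 200, eta_D = 4, eta_F = 0))
  expect_true(ok$pass)
  expect_equal(ok$margin, 2)   # maximal margin at eta_F = 0
  # a violating parameter set cannot be built by the constructor; forge one
  bad <- structure(list(eta = 1, omega_c = 200, s_h = 0, omega_h = 200,
                        eta_D = 4, s_D = 0, eta_F = 2.01, s_F = 0,
                        units = "cm1",
                        omega_c_i = cm1_to_angfreq(200),
                        omega_h_i = cm1_to_angfreq(200)),
                   class = "ndc_params")
  chk <- check_cross_bound(bad)
  expect_false(chk$pass)
  expect_lt(chk$margin, 0)
})

test_that("microscopic constructions can never violate the cross bound", {
  for (seed in 1:5) {
    m <- random_modeset(30, lambda = 500, D_strength = 80,
                        F_target = 10 * (seed - 3), seed = seed)
    expect_true(check_cross_bound(m)$pass)
    expect_true(check_cross_bound(triple_from_modes(m, gamma = 300))$pass)
  }
})

test_that("nonnegativity of J and J_D on a dense grid; J_F sign follows couplings", {
  tr <- parametric_triple(table2_case("I-C")$params)
  w <- seq(0, 40, length.out = 2001)
  ev <- eval_triple(tr, w)
  expect_true(all(ev$J >= 0))
  expect_true(all(ev$J_D >= 0))
  # I-C: positive Ohmic cross, negative delta cross
  expect_true(all(ev$J_F >= 0))
  expect_lt(ev$deltas$wJF, 0)
})

test_that("tabulated densities interpolate with an explicit cutoff", {
  tab <- data.frame(omega = c(100, 200, 400), J = c(1, 2, 0.5), J_D = c(0, 1, 1))
  tr <- triple_from_table(tab, units = "cm1")
  wi <- cm1_to_angfreq(150)
  expect_rel_close(tr$Jc$J(wi), 1.5, 1e-9)
  expect_identical(tr$Jc$J(cm1_to_angfreq(500)), 0)   # beyond the cutoff
  expect_identical(tr$Jc$J_F(wi), 0)                  # absent column is zero
  expect_error(triple_from_table(data.frame(omega = c(2, 1), J = c(1, 1))),
               "increasing")
})
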