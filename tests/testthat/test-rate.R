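reduced_corr <- function(id, t_max = 60, n = 3000) {
  case <- table2_case(id)
  corr_closed_form(case$params, case$thermo, time_grid(t_max, n = n))
}

test_that("zero derivative coupling gives exactly zero rate", {
  th <- thermo_state(theta = 1, units = "reduced")
  p <- ohmic_delta_params(1, 1, s_h = 1, omega_h = 5, units = "reduced")
  corr <- corr_closed_form(p, th, time_grid(40, n = 2000))
  expect_true(all(assemble_integrand(corr, 10) == 0))
  r <- fgr_rate(corr, 10)
  expect_identical(r$k, 0)
  expect_identical(r$k_condon, 0)
})

test_that("integrand is real at t = 0 and Hermitian in time", {
  corr <- reduced_corr("I-B")
  C <- assemble_integrand(corr, 12)
  expect_identical(Im(C[1]), 0)
  expect_equal(Re(C[1]), Re(corr$D[1]))
  # C(-t) = C*(t) through the kernel symmetries
  kern_neg <- corr$evalfun(-corr$grid$t)
  C_neg <- exp(1i * (12 - corr$lambda) * (-corr$grid$t)) *
    exp(-kern_neg$g) * (kern_neg$D + kern_neg$F^2)
  expect_lt(max(abs(C_neg - Conj(C))), 1e-10 * max(abs(C)))
})

test_that("concentrating the NDC weight at vanishing frequency recovers the Condon rate", {
  th <- thermo_state(theta = 1, units = "reduced")
  corr_g <- corr_closed_form(ohmic_delta_params(1, 1, units = "reduced"),
                             th, time_grid(40, n = 3000))
  m_low <- discrete_modes(1e-3, g = 0, f = sqrt(0.5 / 1e-3), units = "reduced")
  corr <- corr_add(corr_g, corr_from_discrete(m_low, th, corr_g$grid))
  r <- fgr_rate(corr, 6, on_nonconverged = "flag")
  expect_lt(abs(r$k / r$k_condon - 1), 0.01)
})

test_that("high-temperature strong-coupling Condon rate approaches the Marcus formula", {
  th <- thermo_state(theta = 0.05, units = "reduced")
  p <- ohmic_delta_params(eta = 50, omega_c = 1, eta_D = 0.2, units = "reduced")
  corr <- corr_closed_form(p, th, time_grid(2, n = 3000))
  lam <- 50; kT <- 20
  D0 <- Re(corr$D[1])
  for (gap in c(30, 80, 120)) {
    k <- condon_rate(corr, gap, tail_tol = 1e-5)
    k_marcus <- D0 * sqrt(pi / (lam * kT)) * exp(-(gap - lam)^2 / (4 * lam * kT))
    expect_lt(abs(k / k_marcus - 1), 0.05)
  }
})

test_that("Condon reference obeys detailed balance across temperatures", {
  for (theta in c(0.5, 1, 2)) {
    th <- thermo_state(theta = theta, units = "reduced")
    p <- ohmic_delta_params(2, 1, eta_D = 1, units = "reduced")
    corr <- corr_closed_form(p, th, time_grid(80, n = 5000))
    gap <- 4
    ratio <- condon_rate(corr, gap) / condon_rate(corr, -gap)
    expect_lt(abs(ratio / exp(theta * gap) - 1), 0.01)
  }
})

test_that("cases differing only in the delta cross sign share the Condon rate", {
  cB <- reduced_corr("I-B"); cC <- reduced_corr("I-C")
  kB <- condon_rate(cB, 20); kC <- condon_rate(cC, 20)
  expect_equal(kB, kC, tolerance = 1e-9)
})

test_that("non-Condon momentum terms enhance rates at large gaps", {
  corr <- reduced_corr("I-A")
  ratios <- vapply(c(10, 15, 20, 25), function(gap) {
    r <- fgr_rate(corr, gap)
    r$k / r$k_condon
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))   # enhancement ratio grows with the gap
  expect_gt(ratios[3], 1)              # clear enhancement by gap = 20
})

test_that("rates are nonnegative across a seeded family of valid baths", {
  th <- thermo_state(theta = 1, units = "reduced")
  set.seed(42)
  for (rep in 1:6) {
    eta_D <- stats::runif(1, 0, 10)
    p <- ohmic_delta_params(
      eta = stats::runif(1, 0.5, 3), omega_c = 1,
      s_h = stats::runif(1, 0, 1.5), omega_h = stats::runif(1, 3, 12),
      eta_D = eta_D, s_D = stats::runif(1, 0, 3),
      eta_F = stats::runif(1, -0.5, 0.5) * eta_D, units = "reduced")
    corr <- corr_closed_form(p, th, time_grid(50, n = 2500))
    for (gap in c(3, 11, 24)) {
      k <- fgr_rate(corr, gap, on_nonconverged = "flag", two_sided = FALSE)$k
      expect_gte(k, -1e-9 * abs(k))
    }
  }
})

test_that("converged rates are insensitive to halving dt or doubling t_max", {
  case <- table2_case("I-A")
  k1 <- fgr_rate(corr_closed_form(case$params, case$thermo,
                                  time_grid(60, n = 3000)), 20)$k
  k2 <- fgr_rate(corr_closed_form(case$params, case$thermo,
                                  time_grid(60, n = 6000)), 20)$k
  k3 <- fgr_rate(corr_closed_form(case$params, case$thermo,
                                  time_grid(120, n = 6000)), 20)$k
  expect_lt(abs(k2 - k1) / k1, 1e-3)
  expect_lt(abs(k3 - k1) / k1, 1e-3)
})

test_that("undamped discrete baths are refused unless explicitly damped", {
  m <- random_modeset(10, lambda = 300, D_strength = 50, seed = 4)
  corr <- corr_from_discrete(m, thermo_state(300), time_grid(2, n = 2000))
  expect_error(fgr_rate(corr, 15000), class = "ndcrate_convergence_error")
  r <- fgr_rate(corr, 15000, gaussian_damping = 0.3, on_nonconverged = "flag")
  expect_true(is.finite(r$k))
})

test_that("diagnostics expose convergence state honestly", {
  corr <- reduced_corr("I-B")
  r <- fgr_rate(corr, 18)
  expect_true(r$converged)
  expect_lt(r$integrand_tail, 1e-6)
  expect_lt(r$imag_residual, 1e-6)
  expect_lt(r$richardson_rel, 1e-3)
  # truncating the integration window is reported as non-convergence
  short <- corr_closed_form(table2_case("I-B")$params,
                            thermo_state(theta = 1, units = "reduced"),
                            time_grid(1.2, n = 600))
  expect_error(fgr_rate(short, 18), class = "ndcrate_convergence_error")
  expect_false(fgr_rate(short, 18, on_nonconverged = "flag")$converged)
})

test_that("gap scans reuse the correlation set and flag failures per point", {
  corr <- reduced_corr("II-A", t_max = 40, n = 2500)
  sc <- gap_scan(corr, seq(20, 40, by = 2), per_period = 50)
  expect_s3_class(sc, "ndc_scan")
  expect_true(all(sc$converged))
  expect_equal(sc$ln_k_scaled, log(sc$k))
  one <- fgr_rate(corr, 30, per_period = 50)
  expect_equal(sc$k[sc$gap == 30], one$k, tolerance = 1e-12)
  expect_error(gap_scan(corr, c(1, 3, 2)), "monotone")
})
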