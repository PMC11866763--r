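# Numerically exact oracle: the full bath correlation function
#   C(t) = Tr{ rho e^{+iH1 t} V e^{-iH2 t} V }
# evaluated in a truncated Fock space for one or two displaced harmonic
# modes, with H2 = H1 + sum_j w_j g_j (a_j + a_j^+) and the momentum coupling
# V = sum_j f_j sqrt(w_j) p_j (dimensionless-projection convention). This is
# independent of every analytic kernel in the package and is used to pin the
# exp(-g) [D + F^2] structure, including relative signs of mixed-sign NDC
# projections. hbar = 1 throughout; reduced-style units.
fock_corr_exact <- function(omega, g, f, beta, t, nmax = 40L) {
  stopifnot(length(omega) %in% c(1L, 2L))
  n <- 0:(nmax - 1L)
  a1m <- matrix(0, nmax, nmax); a1m[cbind(n[-1], n[-1] + 1L)] <- sqrt(n[-1])
  if (length(omega) == 1L) {
    a <- list(a1m); Id <- NULL
    ediag <- omega[1] * n
  } else {
    a <- list(kronecker(a1m, diag(nmax)), kronecker(diag(nmax), a1m))
    ediag <- omega[1] * rep(n, each = nmax) + omega[2] * rep(n, nmax)
  }
  H1 <- diag(ediag)
  B <- Reduce(`+`, lapply(seq_along(a), function(j)
    omega[j] * g[j] * (a[[j]] + t(a[[j]]))))
  H2 <- H1 + B
  V <- Reduce(`+`, lapply(seq_along(a), function(j)
    f[j] * sqrt(omega[j]) * 1i * sqrt(omega[j] / 2) * (t(a[[j]]) - a[[j]])))
  rho <- exp(-beta * ediag); rho <- rho / sum(rho)
  eig2 <- eigen(H2, symmetric = TRUE)
  Vt <- Conj(t(eig2$vectors))
  vapply(t, function(tt) {
    U2 <- eig2$vectors %*% (exp(-1i * eig2$values * tt) * Vt)
    M <- (rho * exp(1i * ediag * tt)) * (V %*% U2 %*% V)
    sum(diag(M))
  }, complex(1))
}

# Analytic composite correlation function from a correlation set, matching
# the oracle's conventions.
pkg_corr_composite <- function(modes, beta, t) {
  th <- thermo_state(1 / beta, units = "reduced")
  kern <- corr_from_discrete(modes, th, time_grid(max(t), n = 8L))$evalfun(t)
  # the oracle's H2 omits the constant reorganization shift, which exactly
  # cancels the linear drift carried in Im g
  exp(-kern$g) * (kern$D + kern$F^2)
}

expect_rel_close <- function(actual, expected, tol, scale = NULL) {
  s <- if (is.null(scale)) pmax(abs(expected), 1e-300) else scale
  expect_lt(max(abs(actual - expected) / s), tol)
}
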