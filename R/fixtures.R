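# Built-in inputs: the six named model cases, seeded random mode sets, and a
# synthetic azulene-like mode set. Everything is generated in code; no data
# files are shipped.

.table2 <- list(
  "I-A"  = list(r = 5,  s_h = 1,   eta_D = 0,  eta_F = 0, s_D = 4,   s_F = 2),
  "I-B"  = list(r = 5,  s_h = 1,   eta_D = 15, eta_F = 2, s_D = 1,   s_F = 1),
  "I-C"  = list(r = 5,  s_h = 1,   eta_D = 15, eta_F = 2, s_D = 1,   s_F = -1),
  # the II-A cross coefficient is pinned by s_F^2 = s_h * s_D (sign immaterial
  # because eta_F = 0)
  "II-A" = list(r = 15, s_h = 0.2, eta_D = 0,  eta_F = 0, s_D = 1,   s_F = sqrt(0.2)),
  "II-B" = list(r = 15, s_h = 0.2, eta_D = 12, eta_F = 2, s_D = 0.2, s_F = 0.2),
  "II-C" = list(r = 15, s_h = 0.2, eta_D = 12, eta_F = 2, s_D = 0.2, s_F = -0.2)
)

#' Named model cases of the Ohmic + delta bath
#'
#' The six reduced-unit parameter sets of the model-calculation study
#' (omega_h/omega_c of 5 or 15; derivative coupling carried either by the
#' high-frequency mode alone, case A, or dominated by the Ohmic part with
#' either cross-coupling sign, cases B/C), with eta = 1 and
#' k_B T / (hbar omega_c) = 1.
#'
#' @param id one of `"I-A"`, `"I-B"`, `"I-C"`, `"II-A"`, `"II-B"`, `"II-C"`.
#' @return list of class `ndc_case` with elements `id`, `params`
#'   (reduced-unit [ohmic_delta_params()]) and `thermo` (theta = 1).
#' @export
table2_case <- function(id) {
  if (!is.character(id) || length(id) != 1L || !(id %in% names(.table2)))
    ndc_stop("unknown case id '", paste(id, collapse = ","), "'; valid ids: ",
             paste(names(.table2), collapse = ", "))
  p <- .table2[[id]]
  structure(
    list(id = id,
         params = ohmic_delta_params(
           eta = 1, omega_c = 1, s_h = p$s_h, omega_h = p$r,
           eta_D = p$eta_D, s_D = p$s_D, eta_F = p$eta_F, s_F = p$s_F,
           units = "reduced"),
         thermo = thermo_state(theta = 1, units = "reduced")),
    class = "ndc_case")
}

#' @export
print.ndc_case <- function(x, ...) {
  cat(sprintf("<ndc_case> %s (reduced units, theta = %g)\n", x$id, x$thermo$theta))
  print(x$params)
  invisible(x)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Random synthetic mode set with prescribed integrated strengths
#'
#' Draws `n` frequencies log-uniformly and assigns vibronic couplings and
#' derivative-coupling projections so that the reorganization energy and the
#' integrated squared-NDC strength match the requested envelope exactly
#' (deterministically for a fixed seed). Cross strength is controlled by the
#' sign pattern of `f`: with `F_target = NULL` all projections are positive
#' (per-mode Cauchy-Schwarz saturation, the maximal cross strength);
#' otherwise mode signs are flipped greedily to approach the target.
#'
#' @param n number of modes (>= 0).
#' @param lambda target reorganization energy (cm^-1 or reduced; >= 0).
#' @param D_strength target integrated squared-NDC strength (same units, >= 0).
#' @param F_target optional target cross strength; must satisfy
#'   `|F_target| <=` the per-mode bound `sum omega |g f|`.
#' @param omega_range frequency range for the log-uniform draw.
#' @param seed integer seed; all randomness flows through it.
#' @param units `"cm1"` or `"reduced"`.
#' @return an [discrete_modes()] object.
#' @export
random_modeset <- function(n, lambda = 0, D_strength = 0, F_target = NULL,
                           omega_range = c(50, 2000), seed = 1L,
                           units = c("cm1", "reduced")) {
  units <- match.arg(units)
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
    ndc_stop("n must be a nonnegative integer")
  if (lambda < 0 || D_strength < 0)
    ndc_stop("envelope strengths must be nonnegative")
  if (n == 0L) {
    if (lambda > 0 || D_strength > 0)
      ndc_stop("cannot match a nonzero envelope with zero modes")
    return(discrete_modes(numeric(0), units = units))
  }
  with_seed(seed, {
    omega <- sort(exp(stats::runif(n, log(omega_range[1]), log(omega_range[2]))))
    ug <- stats::runif(n); uf <- stats::runif(n)
    g2 <- if (lambda > 0) lambda * ug / sum(omega * ug) else numeric(n)
    f2 <- if (D_strength > 0) D_strength * uf / sum(omega * uf) else numeric(n)
    g <- sqrt(g2); f <- sqrt(f2)
    if (!is.null(F_target)) {
      fmax <- sum(omega * g * abs(f))
      if (abs(F_target) > fmax * (1 + 1e-12))
        ndc_stop("impossible envelope: |F_target| = ", abs(F_target),
                 " exceeds the per-mode cross bound ", fmax)
      # flip signs greedily, largest cross contribution first
      contrib <- omega * g * f
      ord <- order(contrib, decreasing = TRUE)
      total <- sum(contrib)
      for (j in ord) {
        if (total <= F_target) break
        if (total - 2 * contrib[j] >= F_target - 1e-12 * max(1, abs(F_target))) {
          f[j] <- -f[j]
          total <- total - 2 * contrib[j]
        }
      }
    }
    discrete_modes(omega, g, f, units = units)
  })
}

# Synthetic azulene-like mode table (48 in-plane/out-of-plane modes of an
# 18-atom bicyclic frame). The distribution, not the values, is the point:
# Franck-Condon activity concentrated in ring modes below 1600 cm^-1, the
# derivative coupling dominated by the single 1924 cm^-1 mode, and nearly
# silent CH stretches near 3050 cm^-1. The overall NDC scale is calibrated so
# the five environmental bath settings give rates of order 0.1-10 ns^-1 in
# the 1.78-1.82 eV gap window at 300 K; no agreement with any ab initio mode
# set is claimed.
azulene_mode_table <- function() {
  freq <- c(170, 189, 240, 306, 331, 406, 486, 542, 562, 649,
            678, 712, 731, 766, 795, 823, 862, 900, 941, 957,
            972, 987, 1012, 1049, 1117, 1160, 1210, 1268, 1300, 1378,
            1396, 1443, 1480, 1536, 1575, 1608, 1651, 1712, 1781, 1924,
            3020, 3036, 3052, 3067, 3079, 3086, 3097, 3110)
  g2 <- c(0.100, 0.020, 0.060, 0.040, 0.015, 0.450, 0.090, 0.030, 0.020, 0.275,
          0.100, 0.060, 0.015, 0.040, 0.020, 0.300, 0.125, 0.060, 0.080, 0.040,
          0.020, 0.015, 0.100, 0.040, 0.050, 0.060, 0.150, 0.040, 0.030, 0.200,
          0.150, 0.140, 0.050, 0.040, 0.125, 0.030, 0.020, 0.003, 0.002, 0.0010,
          2e-4, 1e-4, 2e-4, 1e-4, 1e-4, 2e-4, 1e-4, 1e-4)
  # signed NDC projections, dimensionless; dominated by the 1924 cm^-1 mode
  f_rel <- c(0.020, -0.012, 0.016, -0.010, 0.008, 0.030, -0.022, 0.012, -0.008, 0.035,
             -0.018, 0.010, 0.006, -0.012, 0.008, 0.030, -0.015, 0.010, -0.020, 0.008,
             -0.006, 0.004, 0.018, -0.008, 0.012, -0.014, 0.028, -0.010, 0.006, 0.030,
             -0.024, 0.020, -0.008, 0.006, 0.022, -0.006, 0.004, -0.004, 0.003, 1.000,
             0.002, -0.001, 0.002, -0.001, 0.001, -0.002, 0.001, -0.001)
  f_scale <- 0.035   # overall NDC magnitude (calibrated once; see above)
  data.frame(freq = freq, g = sqrt(g2), f = f_scale * f_rel)
}

#' Synthetic azulene-like surrogate input
#'
#' A fixed 48-mode set emulating the qualitative structure reported for the
#' S1 -> S0 transition of azulene: the derivative coupling dominated by one
#' mode at 1924 cm^-1, Huang-Rhys weight concentrated below 1600 cm^-1, and
#' nearly negligible CH-stretch contributions. This is a statistical
#' surrogate built in code, not quantum-chemistry data; rate magnitudes are
#' comparable to, but not reproductions of, published azulene estimates.
#'
#' @return list of class `ndc_surrogate` with elements `modes`
#'   (an [discrete_modes()] object, cm^-1), `gap_bounds_ev` (the experimental
#'   solution-phase gap window, `c(1.7816, 1.8176)` eV) and `temperature`
#'   (300 K) as recommended scan defaults.
#' @export
azulene_surrogate <- function() {
  tb <- azulene_mode_table()
  structure(
    list(modes = discrete_modes(tb$freq, tb$g, tb$f,
                                labels = sprintf("mode%02d", seq_len(nrow(tb))),
                                units = "cm1"),
         gap_bounds_ev = c(1.7816, 1.8176),
         temperature = 300),
    class = "ndc_surrogate")
}

#' @export
print.ndc_surrogate <- function(x, ...) {
  cat("<ndc_surrogate> synthetic azulene-like mode set\n")
  print(x$modes)
  cat(sprintf("  scan defaults: gap in [%g, %g] eV at %g K\n",
              x$gap_bounds_ev[1], x$gap_bounds_ev[2], x$temperature))
  invisible(x)
}

#' Environmental bath settings for the surrogate study
#'
#' The five environment models used with the azulene-like surrogate: a weak
#' and a strong low-frequency Ohmic bath coupled through g only (`eta`,
#' `nu_c` in cm^-1), a weak and a strong Brownian-oscillator broadening of
#' every mode (`gamma` in cm^-1), and their combination.
#'
#' @return data frame with columns `bath` (A-E), `eta`, `nu_c`, `gamma`.
#' @export
surrogate_bath_settings <- function() {
  data.frame(bath = c("A", "B", "C", "D", "E"),
             eta   = c(1,  0,  10,  0, 10),
             nu_c  = c(10, NA, 200, NA, 200),
             gamma = c(NA, 10, NA, 400, 400))
}
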