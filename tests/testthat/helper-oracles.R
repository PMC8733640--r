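# Independent brute-force oracles and shared fixture builders.

# Max ECDF-vs-normal gap (two-sided Kolmogorov statistic with estimated
# parameters), by explicit loop over sorted sample points.
brute_ks_normal <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- mean(x)
  s <- sd(x)
  dmax <- 0
  for (i in seq_len(n)) {
    Fi <- pnorm(x[i], m, s)
    dmax <- max(dmax, abs(i / n - Fi), abs((i - 1) / n - Fi))
  }
  dmax
}

# Mann-Whitney pair-count AUC (ties scored 1/2), cases-high convention.
brute_auc <- function(scores, cases) {
  xs <- scores[cases]
  ys <- scores[!cases]
  tot <- 0
  for (xi in xs) for (yj in ys) {
    tot <- tot + (xi > yj) + 0.5 * (xi == yj)
  }
  tot / (length(xs) * length(ys))
}

# DeLong variance of the AUC difference by explicit double loops.
brute_delong <- function(s1, s2, cases) {
  xs1 <- s1[cases]; ys1 <- s1[!cases]
  xs2 <- s2[cases]; ys2 <- s2[!cases]
  m <- sum(cases); n <- sum(!cases)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- function(xs, ys) sapply(xs, function(x) mean(psi(x, ys)))
  v01 <- function(xs, ys) sapply(ys, function(y) mean(psi(xs, y)))
  a1 <- v10(xs1, ys1); b1 <- v01(xs1, ys1)
  a2 <- v10(xs2, ys2); b2 <- v01(xs2, ys2)
  s10 <- cov(cbind(a1, a2)); s01 <- cov(cbind(b1, b2))
  list(auc1 = mean(a1), auc2 = mean(a2),
       var = (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
         (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n)
}

# Group configs with SDs shrunk by `factor`: a clearly separable cohort.
separable_configs <- function(factor = 0.25) {
  gc <- cohort_defaults()
  for (g in names(gc)) {
    for (v in names(gc[[g]])) gc[[g]][[v]]["sd"] <- gc[[g]][[v]]["sd"] * factor
  }
  gc
}

# Healthy-mean template subject for single-exam tests.
template_subject <- function(E = 0.35, seed = 42L, R = 7.75, t = 0.5345) {
  list(subject_id = "tmpl", E_true = E, R = R, t = t, nu = 0.49,
       bIOP = 15.3, seed = seed)
}

# Build an exam whose central-zone fit curvature crosses zero at exactly
# `target_A1T` ms: the applanation deformation delta* is a pure geometry
# property, so the stiffness k = f(target)/delta* places the crossing.
construct_applanation_exam <- function(target_A1T, seed = 1L,
                                       sigma_noise = 0,
                                       airpuff = airpuff_config(),
                                       geometry = cornea_geometry(7.75, 0.5345)) {
  sub <- template_subject(E = 0.35, seed = seed,
                          R = geometry$R, t = geometry$t)
  probe <- simulate_examination(sub, airpuff,
                                sim_config(sigma_noise = 0))
  delta_star <- probe$truth$delta_applanation
  k <- apex_force(airpuff, target_A1T) / delta_star
  sub$E_true <- elastic_modulus(k, geometry, airpuff$rp)$E
  simulate_examination(sub, airpuff,
                       sim_config(sigma_noise = sigma_noise))
}
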