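# Shallow-spherical-shell relation between the air-puff force/apex
# displacement slope and the corneal elastic modulus.
#
# The cornea is treated as a thin shallow spherical cap of midsurface
# radius R - t/2, thickness t and Poisson ratio nu.  Axisymmetric bending
# of such a cap is equivalent (Reissner) to a flat plate on an elastic
# foundation,  D lap^2 w + (E t / R^2) w = p,  whose characteristic length
# l = (D R^2 / (E t))^(1/4) turns the dimensionless load radius mu = rp / l
# into the only shape parameter of the apex-stiffness problem.  mu is
# exactly the quantity written out in compute_mu().

#' Corneal geometry for the shell relation
#'
#' @param R central anterior curvature radius, mm.  Sanity bounds 4--10 mm
#'   span keratoconic to healthy corneas.
#' @param t central corneal thickness (CCT), mm; bounds 0.3--0.7 mm.
#' @param nu Poisson ratio, dimensionless, in (0, 0.5).  The cornea is
#'   nearly incompressible; 0.49 is the conventional value.
#' @return object of class `cornea_geometry`.
#' @export
cornea_geometry <- function(R, t, nu = 0.49) {
  stop_if_not_number(R, "R", 4, 10)
  stop_if_not_number(t, "t", 0.3, 0.7)
  stop_if_not_number(nu, "nu")
  if (nu <= 0 || nu >= 0.5) stop("nu must lie in (0, 0.5)", call. = FALSE)
  if (t >= R) stop("shell assumption requires t < R", call. = FALSE)
  structure(list(R = R, t = t, nu = nu), class = "cornea_geometry")
}

#' @export
print.cornea_geometry <- function(x, ...) {
  cat(sprintf("Cornea geometry: R = %.4g mm, t = %.4g mm, nu = %.3g\n",
              x$R, x$t, x$nu))
  invisible(x)
}

#' Kelvin function kei(x)
#'
#' `kei(x) = Im K0(x e^{i pi/4})`, evaluated from the complex power series
#' of the modified Bessel function K0.  Accurate for the moderate arguments
#' (x <= ~10) that arise in the shallow-shell validity band.
#'
#' @param x non-negative numeric vector.
#' @return kei(x); `kei(0) = -pi/4`.
#' @export
kelvin_kei <- function(x) {
  stop_if_not_number(x, "x", lower = 0)
  vapply(x, function(xi) {
    if (xi == 0) return(-pi / 4)
    z2 <- (complex(real = 0, imaginary = 1) * xi^2) / 4  # (z/2)^2, z = x e^{i pi/4}
    # K0(z) = -(log(z/2)+gamma) I0(z) + sum_{k>=1} (z^2/4)^k / (k!)^2 * H_k
    gamma <- 0.57721566490153286
    logz2 <- log(xi / 2) + complex(real = 0, imaginary = pi / 4)
    term <- complex(real = 1)     # (z^2/4)^k / (k!)^2, k = 0
    i0 <- term
    s <- complex(real = 0)
    hk <- 0
    for (k in seq_len(120L)) {
      term <- term * z2 / (k * k)
      hk <- hk + 1 / k
      i0 <- i0 + term
      s <- s + term * hk
      if (Mod(term) < 1e-17 * max(Mod(i0), 1)) break
    }
    Im(-(logz2 + gamma) * i0 + s)
  }, numeric(1))
}

#' Disc-load stiffness factor of the shallow shell
#'
#' Ratio of the apex stiffness under a uniform disc load of dimensionless
#' radius `mu` to the concentrated-load (mu -> 0) stiffness of the same
#' shell.  From the plate-on-foundation Green's function
#' `w(r) = -kei(r/l) / (2 pi sqrt(D k))` the factor is
#' \deqn{\phi(\mu) = \frac{\pi \mu^2}{8 \int_0^\mu (-\mathrm{kei}(s))\, s\, ds}.}
#' `phi(0) = 1` and `phi` grows with `mu`: spreading the same total force
#' over a wider disc deflects the apex less.
#'
#' @param mu dimensionless disc radius (vectorized).
#' @return stiffness factor `phi(mu) >= 1`.
#' @export
disc_load_factor <- function(mu) {
  stop_if_not_number(mu, "mu", lower = 0)
  vapply(mu, function(m) {
    if (m < 1e-8) return(1)
    I <- stats::integrate(function(s) -kelvin_kei(s) * s, 0, m,
                          rel.tol = 1e-10, abs.tol = 0)$value
    pi * m^2 / (8 * I)
  }, numeric(1))
}

#' Dimensionless shell parameter mu
#'
#' \deqn{\mu = r_p \left[\frac{12 (1 - \nu^2)}{(R - t/2)^2 t^2}\right]^{1/4},}
#' i.e. the effective puff radius measured in units of the shell's bending
#' characteristic length.  Linear in `rp`.
#'
#' @param geometry a [cornea_geometry()].
#' @param rp effective puff radius, mm; `rp >= 0`.
#' @return mu, dimensionless.
#' @export
compute_mu <- function(geometry, rp) {
  stopifnot(inherits(geometry, "cornea_geometry"))
  stop_if_not_number(rp, "rp", lower = 0)
  if (geometry$t >= 2 * geometry$R) {
    stop("invalid geometry: t >= 2R", call. = FALSE)
  }
  Rmid <- geometry$R - geometry$t / 2
  rp * (12 * (1 - geometry$nu^2) / (Rmid^2 * geometry$t^2))^0.25
}

#' Quadratic-correction coefficient c1 of the stiffness relation
#'
#' The elastic-modulus relation carries a correction factor `(1 - c1 mu^2)`
#' accounting for the finite footprint of the air puff.  Here `c1` is
#' identified from the Reissner shallow-shell solution for a uniform disc
#' load by writing the apex-stiffness factor as
#' `phi(mu) = 1 - c1(mu) mu^2`, i.e. `c1 = (1 - phi(mu)) / mu^2`.  `c1`
#' is negative (a disc load is stiffer than a point load) and varies only
#' weakly (logarithmically) with `mu`; the correction factor itself tends
#' to 1 as `rp -> 0`.  For `mu` below `mu_floor` the value at `mu_floor` is
#' returned, which keeps `c1 * mu^2 -> 0` while avoiding the logarithmic
#' small-`mu` divergence of the coefficient itself.
#'
#' The coefficient is exposed (and overridable throughout the package via
#' `c1_fun` arguments) so that an alternative closed-form `c1` can be
#' substituted without touching the rest of the relation.
#'
#' @inheritParams compute_mu
#' @param mu_max upper edge of the shallow-shell validity band; larger `mu`
#'   triggers a warning attribute on the result (default 5).
#' @param mu_floor small-`mu` evaluation floor (default 1e-3).
#' @return c1, dimensionless, with attribute `valid` set to `FALSE` when
#'   `mu > mu_max`.
#' @export
compute_c1 <- function(geometry, rp, mu_max = 5, mu_floor = 1e-3) {
  mu <- compute_mu(geometry, rp)
  mu_eval <- max(mu, mu_floor)
  c1 <- (1 - disc_load_factor(mu_eval)) / mu_eval^2
  attr(c1, "valid") <- mu <= mu_max
  c1
}

# Stiffness (mN/mm) per unit modulus (kPa): the geometric core of the
# slope <-> E relation.  Numerator grouping is fixed here so that an
# alternative published grouping could be swapped in one place:
#   E[kPa] = slope * (R - t/2) * sqrt(12 (1 - nu^2)) / (pi t) / (1 - c1 mu^2)
stiffness_per_kpa <- function(geometry, rp, c1_fun = compute_c1) {
  mu <- compute_mu(geometry, rp)
  c1 <- as.numeric(c1_fun(geometry, rp))
  corr <- 1 - c1 * mu^2
  if (corr <= 0) {
    stop("invalid regime: correction factor 1 - c1*mu^2 <= 0", call. = FALSE)
  }
  Rmid <- geometry$R - geometry$t / 2
  list(coef = pi * geometry$t * corr /
         (Rmid * sqrt(12 * (1 - geometry$nu^2))),
       mu = mu, c1 = c1, correction = corr)
}

#' Corneal elastic modulus from the force-displacement slope
#'
#' Converts the fitted slope `S_TSC = df/ddelta` (mN/mm) of the air-puff
#' force versus apex-displacement curve into an elastic modulus through the
#' shallow-spherical-shell relation
#' \deqn{E = \frac{\Delta f}{\Delta \delta}\;
#'   \frac{(R - t/2)\,\sqrt{12 (1 - \nu^2)}}{\pi\, t\, (1 - c_1 \mu^2)},}
#' with `mu` from [compute_mu()] and `c1` from [compute_c1()].  The numeric
#' value of the right-hand side, with slope in mN/mm and lengths in mm, is
#' read in kPa and reported in MPa; this unit convention is applied in this
#' one function only.  `E` is exactly linear in the slope at fixed
#' geometry.
#'
#' @param slope force-displacement slope `S_TSC`, mN/mm; must be `>= 0`.
#' @inheritParams compute_mu
#' @param c1_fun correction-coefficient callable with the signature of
#'   [compute_c1()]; replace it to substitute an alternative shell solution.
#' @return object of class `elastic_result`: a list with `E` (MPa), `mu`,
#'   `c1`, `correction`, `slope_used`, `geometry`, `rp_used` and `valid`.
#' @examples
#' g <- cornea_geometry(R = 7.75, t = 0.5345)
#' elastic_modulus(25.64, g, rp = 1.25)$E
#' @export
elastic_modulus <- function(slope, geometry, rp, c1_fun = compute_c1) {
  stop_if_not_number(slope, "slope", lower = 0)
  cf <- stiffness_per_kpa(geometry, rp, c1_fun)
  E_kpa <- slope / cf$coef
  structure(
    list(E = E_kpa / 1000, mu = cf$mu, c1 = cf$c1,
         correction = cf$correction, slope_used = slope,
         geometry = geometry, rp_used = rp,
         valid = cf$correction > 0),
    class = "elastic_result"
  )
}

#' @export
print.elastic_result <- function(x, ...) {
  cat(sprintf(
    "E = %.4g MPa  (slope %.4g mN/mm, mu %.4g, c1 %.4g, correction %.4g, rp %.3g mm)\n",
    x$E, x$slope_used, x$mu, x$c1, x$correction, x$rp_used))
  invisible(x)
}

#' Forward stiffness: slope implied by a known elastic modulus
#'
#' Algebraic inverse of [elastic_modulus()], used by the simulator to turn
#' a ground-truth modulus into the linear-regime force-displacement slope.
#' `elastic_modulus(forward_stiffness(E, g, rp), g, rp)$E == E` to machine
#' precision.
#'
#' @param E elastic modulus, MPa; `E >= 0`.
#' @inheritParams elastic_modulus
#' @return slope in mN/mm.
#' @export
forward_stiffness <- function(E, geometry, rp, c1_fun = compute_c1) {
  stop_if_not_number(E, "E", lower = 0)
  cf <- stiffness_per_kpa(geometry, rp, c1_fun)
  E * 1000 * cf$coef
}

#' Elastic result as a flat row
#'
#' @param x an `elastic_result`.
#' @return one-row data frame with all intermediates for audit.
#' @export
as.data.frame.elastic_result <- function(x, ...) {
  data.frame(E = x$E, mu = x$mu, c1 = x$c1, correction = x$correction,
             slope_used = x$slope_used, R = x$geometry$R, t = x$geometry$t,
             nu = x$geometry$nu, rp_used = x$rp_used, valid = x$valid)
}
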