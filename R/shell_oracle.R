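# Finite-difference reference solution of the shallow-shell bending
# problem.  Deliberately independent of the Kelvin-function route used by
# disc_load_factor()/compute_c1(): it discretizes the axisymmetric
# plate-on-foundation equation directly and is used to validate the
# closed-form correction factor.

#' Numerical apex stiffness of a shallow shell under a uniform disc load
#'
#' Solves the axisymmetric Reissner shallow-shell (plate on elastic
#' foundation) equation
#' \deqn{D \nabla^4 w + \frac{E t}{R_m^2} w = p(r), \qquad
#'   D = \frac{E t^3}{12 (1 - \nu^2)}, \quad R_m = R - t/2,}
#' with a uniform pressure over `r <= rp` and a clamped far boundary, by
#' second-order finite differences on the split system `lap w = v`,
#' `D lap v + k w = p`.  Returns the apex stiffness (total force divided by
#' apex deflection).
#'
#' The modulus enters only as an overall scale, so the default `E = 1` MPa
#' suffices when the result is used as a shape (mu-dependence) reference.
#'
#' @inheritParams compute_mu
#' @param E elastic modulus, MPa (scale only).
#' @param n_per_l radial grid points per characteristic length (default 40).
#' @param domain_l domain radius in characteristic lengths (default 15;
#'   large enough that the clamped edge is mechanically invisible).
#' @return list with `stiffness` (mN/mm), `w0` (apex deflection per unit
#'   total force), `l` (characteristic length, mm) and `mu` (`rp / l`).
#' @export
shell_disc_stiffness_fd <- function(geometry, rp, E = 1,
                                    n_per_l = 40, domain_l = 15) {
  stopifnot(inherits(geometry, "cornea_geometry"))
  stop_if_not_number(rp, "rp", lower = .Machine$double.eps)
  E_kpa <- E * 1000                       # kPa = mN/mm^2
  t <- geometry$t
  Rmid <- geometry$R - t / 2
  D <- E_kpa * t^3 / (12 * (1 - geometry$nu^2))   # mN mm
  kf <- E_kpa * t / Rmid^2                        # mN / mm^3
  l <- (D / kf)^0.25
  rmax <- max(domain_l * l, 3 * rp)
  h <- l / n_per_l
  n <- ceiling(rmax / h)
  r <- h * (0:n)

  # Conservative Laplacian (1/r)(r w')' on nodes 0..n with symmetry at 0.
  # Row i of L couples w_{i-1}, w_i, w_{i+1}; at i = 0: lap = 4 (w1 - w0)/h^2.
  ii <- jj <- vv <- list()
  add <- function(i, j, v) {
    ii[[length(ii) + 1L]] <<- i; jj[[length(jj) + 1L]] <<- j
    vv[[length(vv) + 1L]] <<- v
  }
  add(1L, 1L, -4 / h^2); add(1L, 2L, 4 / h^2)
  idx <- 2:(n + 1)                        # interior + last node (node i-1)
  i_int <- 2:n
  rm_ <- r[i_int] - h / 2
  rp_ <- r[i_int] + h / 2
  add(i_int, i_int - 1L, rm_ / (r[i_int] * h^2))
  add(i_int, i_int, -(rm_ + rp_) / (r[i_int] * h^2))
  add(i_int, i_int + 1L, rp_ / (r[i_int] * h^2))
  L <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(n + 1, n + 1))

  N <- n + 1L
  # Unknowns: w_0..w_n, v_0..v_n.  Equations:
  #  (a) v - L w = 0 at i = 0..n-1        (ghost-free rows of L)
  #  (b) D L v + kf w = p at i = 0..n-1
  #  (c) w_n = 0 (clamped edge), v rows at i = n use one-sided closure:
  #      w'(rmax) = 0 ghost => L w at n with w_{n+1} = w_{n-1}.
  Ln <- Matrix::sparseMatrix(
    i = c(1L, 1L), j = c(n, n + 1L),
    x = c((r[n + 1] - h / 2 + r[n + 1] + h / 2) / (r[n + 1] * h^2),
          -(2 * r[n + 1]) / (r[n + 1] * h^2)),
    dims = c(1L, n + 1L))
  # Assemble block system
  Zp <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(N, N))
  I_N <- Matrix::Diagonal(N)
  top_rows <- cbind(-L[1:n, , drop = FALSE], I_N[1:n, , drop = FALSE])
  rowA_n <- cbind(-Ln, I_N[N, , drop = FALSE])       # v_n - (L w)_n = 0
  bot_rows <- cbind(kf * I_N[1:n, , drop = FALSE], D * L[1:n, , drop = FALSE])
  roww_n <- cbind(I_N[N, , drop = FALSE], Zp[N, , drop = FALSE]) # w_n = 0
  A <- rbind(top_rows, rowA_n, bot_rows, roww_n)

  # Uniform pressure p0 over r <= rp (nodal weights by annulus area).
  p0 <- 1
  pvec <- ifelse(r <= rp, p0, 0)
  # partial coverage of the cell straddling rp
  str <- which(r > rp & r - h < rp)
  if (length(str) == 1L) pvec[str] <- p0 * (rp - (r[str] - h)) / h
  area <- c(pi * (h / 2)^2,
            pi * ((r[2:n] + h / 2)^2 - (r[2:n] - h / 2)^2),
            pi * (r[n + 1]^2 - (r[n + 1] - h / 2)^2))
  f_total <- sum(pvec * area)

  rhs <- c(rep(0, N), pvec[1:n], 0)
  sol <- Matrix::solve(A, rhs)
  w0 <- as.numeric(sol[1])
  list(stiffness = f_total / w0, w0 = w0 / f_total, l = l, mu = rp / l)
}
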