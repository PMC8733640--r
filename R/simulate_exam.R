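# Forward model of a single air-puff examination: quasi-static apex
# response delta(t) = softclip(f(t) / k), a compactly supported lateral
# deformation bump, quadratic whole-eye motion, and sensor noise.

#' Simulation configuration for synthetic examinations
#'
#' @param nx number of lateral samples across the chord (odd keeps a
#'   sample exactly at the apex).
#' @param chord_mm lateral extent of the recorded anterior-surface edge
#'   (8 mm chord by convention).
#' @param bump_width Gaussian core width `w` (mm) of the deformation bump
#'   `g(x) = exp(-x^2 / (2 w^2))`.
#' @param bump_taper two radii (mm): the bump is smoothly tapered to zero
#'   between them (raised-cosine), so deformation is strictly local and the
#'   peripheral zone carries only whole-eye motion.  The outer radius must
#'   stay inside the peripheral zone used by [extract_apex_trace()].
#' @param eye_motion_a quadratic whole-eye motion coefficient `a` in
#'   `d_eye(t) = a t^2` (mm/ms^2).
#' @param sigma_noise zero-mean Gaussian elevation noise SD per surface
#'   sample, mm (default 2 um).
#' @param da_max_frac saturation cap as a fraction of `R`:
#'   `DA_max = da_max_frac * R` (softer, steeper corneas deform further
#'   before the concavity plateau).
#' @param knee_frac fraction of `DA_max` up to which the response is exactly
#'   linear; beyond the knee a smooth exponential saturation approaches
#'   `DA_max`.  The knee must sit above the 0.2--0.4 mm slope window for
#'   the linear-regime identity to hold.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(nx = 141, chord_mm = 8, bump_width = 2.0,
                       bump_taper = c(2.2, 2.8), eye_motion_a = 1e-4,
                       sigma_noise = 0.002, da_max_frac = 0.25,
                       knee_frac = 0.55) {
  stopifnot(nx >= 21, chord_mm > 0, bump_width > 0,
            length(bump_taper) == 2, bump_taper[1] < bump_taper[2],
            sigma_noise >= 0, da_max_frac > 0,
            knee_frac > 0, knee_frac < 1)
  structure(list(nx = as.integer(nx), chord_mm = chord_mm,
                 bump_width = bump_width, bump_taper = bump_taper,
                 eye_motion_a = eye_motion_a, sigma_noise = sigma_noise,
                 da_max_frac = da_max_frac, knee_frac = knee_frac),
            class = "sim_config")
}

# Identity below the knee, smooth (C^1) exponential saturation towards
# `cap` above it.
softclip <- function(x, cap, knee) {
  stopifnot(cap > 0, knee > 0, knee < cap)
  out <- x
  over <- x > knee
  out[over] <- cap - (cap - knee) * exp(-(x[over] - knee) / (cap - knee))
  out
}

# Raised-cosine taper: 1 inside r1, 0 outside r2.
taper_window <- function(x, r1, r2) {
  ax <- abs(x)
  w <- numeric(length(x))
  w[ax <= r1] <- 1
  mid <- ax > r1 & ax < r2
  w[mid] <- 0.5 * (1 + cos(pi * (ax[mid] - r1) / (r2 - r1)))
  w
}

# Deformation bump shape g(x), unit apex amplitude.  The Gaussian core
# width scales with the anterior radius (the indentation zone of a steeper,
# smaller cornea is narrower); `bump_width` is the width at the reference
# radius 7.75 mm.
bump_shape <- function(x, sim, R = 7.75) {
  w <- sim$bump_width * R / 7.75
  exp(-x^2 / (2 * w^2)) *
    taper_window(x, sim$bump_taper[1], sim$bump_taper[2])
}

# Undeformed anterior arc, apex at y = 0, periphery below.
arc_profile <- function(x, R) sqrt(pmax(R^2 - x^2, 0)) - R

#' Simulate one air-puff examination
#'
#' Builds a time-resolved anterior-surface elevation field
#' `y(x, t) = arc(x) - delta(t) g(x) + d_eye(t) + noise`, where the apex
#' deformation follows the quasi-static linear response
#' `delta(t) = f(t) / k` with `k = forward_stiffness(E_true, geometry, rp)`,
#' smoothly saturated at `DA_max` (concavity plateau).  The examination
#' carries a full ground-truth block so extraction error can be measured
#' without re-simulation.
#'
#' @param subject one cohort row (data frame or list) with at least
#'   `E_true`, `R`, `t`, `nu` and optionally `subject_id`, `bIOP`, `seed`.
#' @param airpuff an [airpuff_config()].
#' @param sim a [sim_config()].
#' @param seed RNG seed for the noise draw; defaults to `subject$seed`.
#' @return object of class `corvis_exam`: list with `subject_id`, `time`
#'   (ms), `x` (mm), `surface` (`nx` x `n_frames` elevation matrix, mm) and
#'   a `truth` list (`E_true`, `k_true`, `delta_true`, `eye_motion`,
#'   `sigma_noise`, `geometry`, `rp`, `A1T_true`, `saturated`).
#' @export
simulate_examination <- function(subject, airpuff = airpuff_config(),
                                 sim = sim_config(), seed = NULL) {
  subject <- as.list(subject)
  geometry <- cornea_geometry(subject$R, subject$t,
                              subject$nu %||% 0.49)
  seed <- seed %||% subject$seed %||% 1L
  k <- forward_stiffness(subject$E_true, geometry, airpuff$rp)
  tt <- airpuff_time_grid(airpuff)
  xx <- seq(-sim$chord_mm / 2, sim$chord_mm / 2, length.out = sim$nx)
  ff <- apex_force(airpuff, tt)

  cap <- sim$da_max_frac * geometry$R
  knee <- sim$knee_frac * cap
  if (knee < 0.4) {
    warning("saturation knee below the 0.4 mm slope window; ",
            "stiffness estimation may be biased", call. = FALSE)
  }
  delta_lin <- ff / k
  delta <- softclip(delta_lin, cap, knee)
  saturated <- any(delta_lin > knee)

  g <- bump_shape(xx, sim, geometry$R)
  d_eye <- sim$eye_motion_a * tt^2
  base <- arc_profile(xx, geometry$R)
  clean <- outer(base, rep(1, length(tt))) - outer(g, delta) +
    outer(rep(1, length(xx)), d_eye)
  noise <- if (sim$sigma_noise > 0) {
    with_seed(seed, matrix(stats::rnorm(length(clean), 0, sim$sigma_noise),
                           nrow = nrow(clean)))
  } else {
    0
  }

  # Ground-truth first-applanation time under the same central-zone
  # quadratic-fit curvature convention the extractor uses, computed on the
  # noiseless field: curvature is affine in delta, so the crossing is exact.
  kap <- central_curvature_components(xx, base, g)
  A1T_true <- NA_real_
  if (kap$bump > 0) {
    delta_star <- -kap$arc / kap$bump
    if (delta_star > 0 && max(delta) > delta_star) {
      A1T_true <- stats::approx(delta[seq_len(which.max(delta))],
                                tt[seq_len(which.max(delta))],
                                xout = delta_star, ties = "ordered")$y
    }
  }

  structure(
    list(subject_id = subject$subject_id %||% "subject",
         time = tt, x = xx, surface = clean + noise,
         bIOP = subject$bIOP %||% NA_real_,
         truth = list(E_true = subject$E_true, k_true = k,
                      delta_true = delta, delta_linear = delta_lin,
                      eye_motion = d_eye, sigma_noise = sim$sigma_noise,
                      geometry = geometry, rp = airpuff$rp,
                      A1T_true = A1T_true, delta_applanation = if (kap$bump > 0)
                        -kap$arc / kap$bump else NA_real_,
                      saturated = saturated),
         sim = sim, airpuff = airpuff),
    class = "corvis_exam"
  )
}

# Quadratic-fit curvature (2 * x^2 coefficient) of the arc and of the unit
# bump over the central zone |x| <= halfwidth.  The surface curvature at
# deformation delta is kap$arc + delta * kap$bump.
central_curvature_components <- function(x, base, g, halfwidth = 1) {
  sel <- abs(x) <= halfwidth
  X <- cbind(1, x[sel], x[sel]^2)
  proj <- solve(crossprod(X), t(X))
  c_arc <- 2 * (proj %*% base[sel])[3]          # < 0 for a convex cap
  c_bump <- 2 * (proj %*% (-g[sel]))[3]          # > 0 per unit delta
  list(arc = c_arc, bump = c_bump)
}

#' @export
print.corvis_exam <- function(x, ...) {
  cat(sprintf(
    "Examination %s: %d frames x %d columns, E_true %.3g MPa, DA %.3g mm%s\n",
    x$subject_id, length(x$time), length(x$x), x$truth$E_true,
    max(x$truth$delta_true),
    if (isTRUE(x$truth$saturated)) " (saturating)" else ""))
  invisible(x)
}

#' Write / read an examination as a plain-text container
#'
#' One directory per examination: `time.csv`, `x.csv`, `surface.csv`
#' (columns = frames) and `meta.json` (subject id, bIOP, ground truth).
#'
#' @param exam a `corvis_exam`.
#' @param dir directory to create/fill.
#' @return the directory (write) or a `corvis_exam` (read).
#' @export
write_examination <- function(exam, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(time_ms = exam$time),
                   file.path(dir, "time.csv"), row.names = FALSE)
  utils::write.csv(data.frame(x_mm = exam$x),
                   file.path(dir, "x.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(exam$surface),
                   file.path(dir, "surface.csv"), row.names = FALSE)
  truth <- exam$truth
  truth$geometry <- unclass(truth$geometry)
  meta <- list(subject_id = exam$subject_id, bIOP = exam$bIOP,
               truth = truth, sim = unclass(exam$sim),
               airpuff = unclass(exam$airpuff))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_examination
#' @export
read_examination <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  truth <- meta$truth
  truth$geometry <- do.call(cornea_geometry, as.list(truth$geometry))
  structure(
    list(subject_id = meta$subject_id,
         time = utils::read.csv(file.path(dir, "time.csv"))$time_ms,
         x = utils::read.csv(file.path(dir, "x.csv"))$x_mm,
         surface = as.matrix(utils::read.csv(file.path(dir, "surface.csv"))),
         bIOP = meta$bIOP %||% NA_real_,
         truth = truth,
         sim = do.call(sim_config, as.list(meta$sim)),
         airpuff = do.call(airpuff_config, as.list(meta$airpuff))),
    class = "corvis_exam"
  )
}
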