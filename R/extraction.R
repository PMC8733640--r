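# DCR extraction: whole-eye-motion-corrected apex displacement,
# applanation/highest-concavity events, force-displacement curve, and the
# 0.2--0.4 mm loading-window stiffness slope.

#' Whole-eye-motion-corrected apex displacement trace
#'
#' Whole-eye motion is estimated per frame as the mean elevation change
#' (relative to frame 0) over the peripheral zones `|x| >= x_periph`,
#' where the air-puff deformation has decayed to zero; the corrected apex
#' deformation (positive inward) is
#' `deformation(t) = -[ (y_apex(t) - y_apex(0)) - eye_motion(t) ]`.
#'
#' @param exam a `corvis_exam` (or any list with `time`, `x`, `surface`).
#' @param x_periph inner radius of the peripheral zone, mm.
#' @return object of class `apex_trace`: data frame with columns `time`,
#'   `raw_apex` (apex elevation change, mm), `eye_motion` (mm) and
#'   `deformation` (mm).
#' @export
extract_apex_trace <- function(exam, x_periph = 3.5) {
  periph <- abs(exam$x) >= x_periph
  if (!any(periph)) {
    stop("peripheral zone |x| >= x_periph is empty on this x grid",
         call. = FALSE)
  }
  apex_col <- which.min(abs(exam$x))
  raw <- exam$surface[apex_col, ] - exam$surface[apex_col, 1]
  per <- colMeans(exam$surface[periph, , drop = FALSE]) -
    mean(exam$surface[periph, 1])
  out <- data.frame(time = exam$time, raw_apex = raw, eye_motion = per,
                    deformation = -(raw - per))
  attr(out, "x_periph") <- x_periph
  class(out) <- c("apex_trace", "data.frame")
  out
}

# Central-zone quadratic-fit curvature per frame: 2 * x^2 coefficient.
central_curvature_series <- function(exam, halfwidth = 1) {
  sel <- abs(exam$x) <= halfwidth
  if (sum(sel) < 5) stop("central zone too narrow on this x grid",
                         call. = FALSE)
  X <- cbind(1, exam$x[sel], exam$x[sel]^2)
  proj <- solve(crossprod(X), t(X))
  2 * as.numeric(proj[3, , drop = FALSE] %*% exam$surface[sel, , drop = FALSE])
}

# Sub-frame zero crossing: local linear fit of kappa(t) over +/- `span`
# frames around the sign-change bracket (robust against per-frame noise).
crossing_time <- function(tt, kappa, i_lo, span = 2L) {
  sel <- max(1L, i_lo - span):min(length(tt), i_lo + 1L + span)
  fit <- stats::lm.fit(cbind(1, tt[sel]), kappa[sel])
  tc <- -fit$coefficients[1] / fit$coefficients[2]
  # fall back to two-point interpolation if the local fit misbehaves
  if (!is.finite(tc) || tc < tt[i_lo] - diff(tt[1:2]) ||
      tc > tt[i_lo + 1L] + diff(tt[1:2])) {
    k0 <- kappa[i_lo]; k1 <- kappa[i_lo + 1L]
    tc <- tt[i_lo] + (tt[i_lo + 1L] - tt[i_lo]) * k0 / (k0 - k1)
  }
  unname(tc)
}

#' Detect applanation and highest-concavity events
#'
#' Applanation is located where the best-fit quadratic curvature of the
#' central zone (`|x| <= 1` mm) crosses zero: the first crossing during
#' loading gives the first applanation time `A1T`, the crossing during
#' recovery gives `A2T`; both are refined to sub-frame precision by a
#' local linear fit of curvature against time.  Velocities `A1V`/`A2V` are
#' central finite differences of the corrected deformation interpolated at
#' the event times (mm/ms, numerically equal to m/s).  `HCT` and `DA` are
#' the time and amplitude of maximum deformation; `PD` is the lateral
#' distance between the two highest surface crests flanking the apex at
#' the highest-concavity frame (ties broken toward larger `|x|`).  When
#' `bIOP` is available, `SPA1 = (P(A1T) in mmHg - bIOP) / deformation(A1T)`.
#'
#' @param trace an [extract_apex_trace()] result.
#' @param exam the `corvis_exam` the trace came from.
#' @param airpuff optional [airpuff_config()] (defaults to `exam$airpuff`)
#'   used for the SP-A1 pressure lookup.
#' @param bIOP biomechanically corrected IOP, mmHg (defaults to
#'   `exam$bIOP`); `NA` suppresses SP-A1.
#' @param central_halfwidth half-width of the applanation fit zone, mm.
#' @return object of class `dcr_params`: list with `A1T`, `A1V`, `A2T`,
#'   `A2V`, `HCT`, `DA`, `PD`, `SPA1` and `quality_flags`.
#' @export
detect_events <- function(trace, exam, airpuff = NULL, bIOP = NULL,
                          central_halfwidth = 1) {
  airpuff <- airpuff %||% exam$airpuff
  bIOP <- bIOP %||% exam$bIOP
  tt <- trace$time
  defo <- trace$deformation
  if (max(defo) <= 0 || which.max(defo) %in% c(1L, length(defo))) {
    stop("no concave phase: deformation has no interior maximum",
         call. = FALSE)
  }
  kappa <- central_curvature_series(exam, central_halfwidth)
  sgn <- sign(kappa)
  up <- which(sgn[-length(sgn)] < 0 & sgn[-1] >= 0)
  down <- which(sgn[-length(sgn)] >= 0 & sgn[-1] < 0)
  i_peak <- which.max(defo)
  up <- up[up <= i_peak]
  down <- down[down >= i_peak - 1L]
  if (length(up) == 0L || length(down) == 0L) {
    stop("not applanated: central curvature never crosses zero",
         call. = FALSE)
  }
  A1T <- crossing_time(tt, kappa, up[1])
  A2T <- crossing_time(tt, kappa, down[length(down)])

  vel <- c(NA, (defo[-(1:2)] - defo[-((length(defo) - 1):length(defo))]) /
             (tt[3] - tt[1]), NA)
  vel_at <- function(tq) stats::approx(tt[-c(1, length(tt))],
                                       vel[-c(1, length(vel))],
                                       xout = tq, rule = 2)$y
  A1V <- vel_at(A1T)
  A2V <- vel_at(A2T)

  # sub-frame highest concavity by quadratic refinement around the maximum
  HCT <- tt[i_peak]
  if (i_peak > 1L && i_peak < length(tt)) {
    y3 <- defo[(i_peak - 1):(i_peak + 1)]
    denom <- y3[1] - 2 * y3[2] + y3[3]
    if (denom < 0) HCT <- tt[i_peak] + 0.5 * (y3[1] - y3[3]) / denom * (tt[2] - tt[1])
  }
  DA <- max(defo)

  PD <- peak_distance(exam, i_peak)

  flags <- character(0)
  if (A1V <= 0) flags <- c(flags, "A1V_nonpositive")
  if (A2V >= 0) flags <- c(flags, "A2V_nonnegative")
  if (!(A1T < HCT && HCT < A2T)) flags <- c(flags, "event_order_violated")

  SPA1 <- NA_real_
  d_a1 <- stats::approx(tt, defo, xout = A1T)$y
  if (is.finite(bIOP %||% NA_real_) && d_a1 > 0) {
    SPA1 <- (kpa_to_mmhg(pressure_at(airpuff, A1T)) - bIOP) / d_a1
  }

  structure(list(A1T = A1T, A1V = A1V, A2T = A2T, A2V = A2V, HCT = HCT,
                 DA = DA, PD = PD, SPA1 = SPA1, quality_flags = flags),
            class = "dcr_params")
}

# Peak distance at the highest-concavity frame: lateral distance between
# the two local surface maxima flanking the apex (light smoothing for
# noise robustness; ties toward larger |x|).
peak_distance <- function(exam, frame_idx, smooth_k = 5L) {
  y <- exam$surface[, frame_idx]
  if (smooth_k > 1L) {
    y <- stats::filter(y, rep(1 / smooth_k, smooth_k), sides = 2)
    y[is.na(y)] <- exam$surface[, frame_idx][is.na(y)]
  }
  x <- exam$x
  apex <- which.min(abs(x))
  side_peak <- function(idx) {
    if (length(idx) < 3L) return(NA_real_)
    yy <- y[idx]
    loc <- which(diff(sign(diff(yy))) < 0) + 1L
    if (length(loc) == 0L) return(NA_real_)
    best <- loc[yy[loc] == max(yy[loc])]
    x[idx][best[which.max(abs(x[idx][best]))]]
  }
  xl <- side_peak(seq_len(apex - 1L))
  xr <- side_peak((apex + 1L):length(x))
  if (is.na(xl) || is.na(xr)) return(NA_real_)
  xr - xl
}

#' @export
print.dcr_params <- function(x, ...) {
  cat(sprintf(
    "DCR: A1T %.3f ms (A1V %.3f), HCT %.3f ms, A2T %.3f ms (A2V %.3f), DA %.3f mm, PD %.3f mm%s\n",
    x$A1T, x$A1V, x$HCT, x$A2T, x$A2V, x$DA, x$PD,
    if (length(x$quality_flags)) paste0(" [", paste(x$quality_flags,
                                                    collapse = ","), "]") else ""))
  invisible(x)
}

#' Force-displacement curve
#'
#' Pairs the corrected apex deformation with the apex force at the same
#' frame times and flags the loading phase (up to the deformation
#' maximum).
#'
#' @param trace an [extract_apex_trace()] result.
#' @param airpuff an [airpuff_config()] whose time grid matches the trace.
#' @return object of class `fd_curve`: data frame with columns `delta`
#'   (mm), `force` (mN) and `phase` (`"loading"`/`"unloading"`).
#' @export
force_displacement <- function(trace, airpuff) {
  tt_cfg <- airpuff_time_grid(airpuff)
  if (length(tt_cfg) != nrow(trace) ||
      max(abs(tt_cfg - trace$time)) > 1e-9) {
    stop("trace and air-puff time grids are not aligned", call. = FALSE)
  }
  i_peak <- which.max(trace$deformation)
  out <- data.frame(delta = trace$deformation,
                    force = apex_force(airpuff, trace$time),
                    phase = ifelse(seq_len(nrow(trace)) <= i_peak,
                                   "loading", "unloading"))
  class(out) <- c("fd_curve", "data.frame")
  out
}

#' Stiffness slope S_TSC over the linear loading window
#'
#' Ordinary least-squares slope of force on displacement restricted to
#' loading-phase samples with `delta` inside the window (0.2--0.4 mm by
#' default, the approximately linear stretch of the loading curve).
#'
#' @param curve an [force_displacement()] result.
#' @param window displacement window, mm.
#' @return object of class `stiffness_result`: list with `S_TSC` (mN/mm),
#'   `window_used`, `fit_r2` and `n_points`.
#' @export
stiffness_slope <- function(curve, window = c(0.2, 0.4)) {
  sel <- curve$phase == "loading" &
    curve$delta >= window[1] & curve$delta <= window[2]
  n <- sum(sel)
  if (n < 3L) {
    stop(structure(class = c("insufficient_window", "error", "condition"),
                   list(message = sprintf(
                     "only %d loading samples inside the %.2g-%.2g mm window",
                     n, window[1], window[2]), call = NULL)))
  }
  dd <- curve$delta[sel]
  ff <- curve$force[sel]
  vx <- stats::var(dd)
  if (vx == 0) {
    stop(structure(class = c("insufficient_window", "error", "condition"),
                   list(message = "in-window displacements are constant",
                        call = NULL)))
  }
  slope <- stats::cov(dd, ff) / vx
  r2 <- if (stats::var(ff) == 0) 1 else stats::cor(dd, ff)^2
  structure(list(S_TSC = slope, window_used = window, fit_r2 = r2,
                 n_points = n),
            class = "stiffness_result")
}

#' Effective puff radius from the first-applanation frame
#'
#' By convention the radius of the flattened central zone at first
#' applanation serves as the effective air-puff radius: the half-width of
#' the contiguous central region where the local (sliding quadratic fit)
#' curvature magnitude stays below `flat_tol`.
#'
#' @param exam a `corvis_exam`.
#' @param A1T first applanation time, ms.
#' @param flat_tol flatness tolerance on curvature, 1/mm.
#' @param fallback_rp radius returned (with a warning) when no flattened
#'   zone is found.
#' @param fit_halfwidth half-width (mm) of the sliding quadratic fit.
#' @return rp in mm.
#' @export
effective_puff_radius <- function(exam, A1T, flat_tol = 0.01,
                                  fallback_rp = exam$airpuff$rp,
                                  fit_halfwidth = 0.5) {
  frame_idx <- which.min(abs(exam$time - A1T))
  y <- exam$surface[, frame_idx]
  x <- exam$x
  # local curvature via sliding quadratic fit
  kap <- vapply(seq_along(x), function(i) {
    sel <- abs(x - x[i]) <= fit_halfwidth
    if (sum(sel) < 5) return(NA_real_)
    X <- cbind(1, x[sel] - x[i], (x[sel] - x[i])^2)
    2 * stats::lm.fit(X, y[sel])$coefficients[3]
  }, numeric(1))
  apex <- which.min(abs(x))
  if (is.na(kap[apex]) || abs(kap[apex]) >= flat_tol) {
    warning("no flattened central zone found; using configured rp",
            call. = FALSE)
    return(fallback_rp)
  }
  flat <- abs(kap) < flat_tol & !is.na(kap)
  i_hi <- apex
  while (i_hi < length(x) && flat[i_hi + 1L]) i_hi <- i_hi + 1L
  i_lo <- apex
  while (i_lo > 1L && flat[i_lo - 1L]) i_lo <- i_lo - 1L
  # a window centred fit_halfwidth inside the plateau edge is the last one
  # that sees only flat surface, so add the half-width back
  (x[i_hi] - x[i_lo]) / 2 + fit_halfwidth
}

# Algebraic (Kasa) circle fit of the frame-0 anterior surface: returns the
# fitted curvature radius R-hat in mm.
fit_anterior_radius <- function(exam) {
  x <- exam$x
  y <- exam$surface[, 1]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- stats::lm.fit(A, b)$coefficients
  sqrt(sol[3] + sol[1]^2 + sol[2]^2)
}

#' Extract all per-subject quantities from one examination
#'
#' Runs the full extraction chain (trace, events, force-displacement
#' curve, window slope, elastic modulus) and returns a flat row.  The
#' anterior curvature radius entering the shell relation is re-fitted from
#' the frame-0 edge curve; the central thickness is taken from the
#' supplied metadata (pachymetry is not recoverable from a single anterior
#' edge).  Subjects whose slope window cannot be fitted are flagged, not
#' dropped.
#'
#' @param exam a `corvis_exam`.
#' @param airpuff an [airpuff_config()]; defaults to the one embedded in
#'   the exam.
#' @param window slope window, mm.
#' @param use_measured_rp if `TRUE`, replace the configured `rp` by the
#'   measured first-applanation flattened-zone radius.
#' @param use_fitted_R if `TRUE` (default), use the circle-fitted anterior
#'   radius; otherwise the ground-truth geometry radius.
#' @param t_mm central thickness used in the shell relation; defaults to
#'   the exam's geometry metadata.
#' @return one-row data frame with DCR parameters, `S_TSC`, `fit_r2`,
#'   `E` (MPa), `mu`, `c1`, `rp_used`, `R_fit` and `quality_flags`.
#' @export
extract_subject <- function(exam, airpuff = NULL, window = c(0.2, 0.4),
                            use_measured_rp = FALSE, use_fitted_R = TRUE,
                            t_mm = NULL) {
  airpuff <- airpuff %||% exam$airpuff
  trace <- extract_apex_trace(exam)
  flags <- character(0)
  dcr <- tryCatch(detect_events(trace, exam, airpuff = airpuff),
                  error = function(e) {
                    flags <<- c(flags, conditionMessage(e))
                    NULL
                  })
  curve <- force_displacement(trace, airpuff)
  stiff <- tryCatch(stiffness_slope(curve, window),
                    error = function(e) {
                      flags <<- c(flags, conditionMessage(e))
                      NULL
                    })
  R_fit <- unname(fit_anterior_radius(exam))
  t_mm <- t_mm %||% exam$truth$geometry$t
  nu <- exam$truth$geometry$nu
  rp_used <- airpuff$rp
  if (use_measured_rp && !is.null(dcr)) {
    rp_used <- effective_puff_radius(exam, dcr$A1T)
  }
  E <- mu <- c1 <- NA_real_
  if (!is.null(stiff)) {
    geom <- cornea_geometry(if (use_fitted_R) min(max(R_fit, 4), 10)
                            else exam$truth$geometry$R, t_mm, nu)
    er <- elastic_modulus(stiff$S_TSC, geom, rp_used)
    E <- er$E; mu <- er$mu; c1 <- er$c1
  }
  if (!is.null(dcr)) flags <- c(flags, dcr$quality_flags)
  data.frame(
    subject_id = exam$subject_id,
    A1T = dcr$A1T %||% NA_real_, A1V = dcr$A1V %||% NA_real_,
    A2T = dcr$A2T %||% NA_real_, A2V = dcr$A2V %||% NA_real_,
    HCT = dcr$HCT %||% NA_real_, DA = dcr$DA %||% NA_real_,
    PD = dcr$PD %||% NA_real_, SPA1 = dcr$SPA1 %||% NA_real_,
    S_TSC = if (is.null(stiff)) NA_real_ else stiff$S_TSC,
    fit_r2 = if (is.null(stiff)) NA_real_ else stiff$fit_r2,
    E = E, mu = mu, c1 = c1, rp_used = rp_used, R_fit = R_fit,
    quality_flags = paste(flags, collapse = "; "),
    stringsAsFactors = FALSE)
}

#' Extract a whole cohort of examinations
#'
#' @param exams list of `corvis_exam` objects.
#' @param ... passed to [extract_subject()].
#' @return data frame with one row per examination.
#' @export
extract_cohort <- function(exams, ...) {
  do.call(rbind, lapply(exams, extract_subject, ...))
}
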