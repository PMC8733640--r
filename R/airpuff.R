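# Air-puff pressure pulse and the force it applies on the corneal apex.

#' Air-puff pulse configuration
#'
#' Parameterizes the pressure pulse an air-puff tonometer fires at the
#' cornea and the effective radius `rp` over which that pressure acts.  The
#' pulse is modelled as a smooth, unimodal Gaussian-shaped transient: the
#' exact pressure-time profile of a real device must be measured externally,
#' so the defaults here are conventions chosen to place simulated
#' deformations in the physiological range, not device facts.  All fields
#' are overridable.
#'
#' `pulse_halfwidth` is the half width at half maximum (HWHM), so
#' `pressure_at(config, peak_time + pulse_halfwidth)` is exactly half the
#' peak pressure.
#'
#' @param peak_pressure peak pulse pressure, kPa.
#' @param peak_time time of the pressure peak, ms.
#' @param pulse_halfwidth HWHM of the pulse, ms.
#' @param rp effective puff radius, mm; by convention the radius of the
#'   flattened zone at first applanation may be substituted (see
#'   [effective_puff_radius()]).
#' @param duration examination duration, ms.
#' @param sample_rate frames per ms of the recording (140 frames over 32 ms
#'   by default, a common dynamic Scheimpflug convention).
#' @return an object of class `airpuff_config`.
#' @examples
#' cfg <- airpuff_config()
#' pressure_at(cfg, cfg$peak_time)     # equals peak_pressure
#' apex_force(cfg, cfg$peak_time)      # peak force in mN
#' @export
airpuff_config <- function(peak_pressure = 9.5, peak_time = 15,
                           pulse_halfwidth = 6, rp = 1.25,
                           duration = 32, sample_rate = 140 / 32) {
  stop_if_not_number(peak_pressure, "peak_pressure")
  stop_if_not_number(peak_time, "peak_time")
  stop_if_not_number(pulse_halfwidth, "pulse_halfwidth")
  stop_if_not_number(rp, "rp")
  stop_if_not_number(duration, "duration")
  stop_if_not_number(sample_rate, "sample_rate")
  if (peak_pressure <= 0) stop("peak_pressure must be > 0", call. = FALSE)
  if (pulse_halfwidth <= 0) stop("pulse_halfwidth must be > 0", call. = FALSE)
  if (rp <= 0) stop("rp must be > 0", call. = FALSE)
  if (peak_time <= 0 || peak_time >= duration) {
    stop("peak_time must lie strictly inside (0, duration)", call. = FALSE)
  }
  structure(
    list(peak_pressure = peak_pressure, peak_time = peak_time,
         pulse_halfwidth = pulse_halfwidth, rp = rp,
         duration = duration, sample_rate = sample_rate),
    class = "airpuff_config"
  )
}

#' @export
print.airpuff_config <- function(x, ...) {
  cat(sprintf(
    "Air-puff pulse: peak %.3g kPa at %.3g ms (HWHM %.3g ms), rp %.3g mm, %g ms @ %.4g fr/ms\n",
    x$peak_pressure, x$peak_time, x$pulse_halfwidth, x$rp,
    x$duration, x$sample_rate))
  invisible(x)
}

#' Pulse pressure at a given time
#'
#' Baseline-subtracted Gaussian pulse: with
#' \eqn{\varphi(t) = \exp(-(t - t_{peak})^2 / (2\sigma^2))},
#' \eqn{\sigma = \mathrm{HWHM}/\sqrt{2\ln 2}} and
#' \eqn{b = \varphi(0)},
#' \deqn{P(t) = P_{peak} \, \max(\varphi(t) - b, 0) / (1 - b),}
#' so the cornea is genuinely unloaded at the first frame
#' (`pressure_at(config, 0) == 0`), the pulse is continuous and unimodal,
#' attains exactly `peak_pressure` at `peak_time`, and scales linearly in
#' `peak_pressure`.
#'
#' @param config an [airpuff_config()].
#' @param time time(s) in ms; must lie in `[0, duration]`.
#' @return pressure in kPa (vectorized over `time`).
#' @export
pressure_at <- function(config, time) {
  stopifnot(inherits(config, "airpuff_config"))
  stop_if_not_number(time, "time")
  if (any(time < 0 | time > config$duration)) {
    stop("time outside [0, duration]", call. = FALSE)
  }
  sigma <- config$pulse_halfwidth / sqrt(2 * log(2))
  phi <- exp(-(time - config$peak_time)^2 / (2 * sigma^2))
  b <- exp(-config$peak_time^2 / (2 * sigma^2))
  config$peak_pressure * pmax(phi - b, 0) / (1 - b)
}

#' Air-puff force on the corneal apex
#'
#' The pulse is treated as a uniform surface pressure over a disc of radius
#' `rp`, so the apex force is `pressure * pi * rp^2`.  With pressure in kPa
#' and `rp` in mm the product is in mN.
#'
#' @inheritParams pressure_at
#' @param rp optional override of the effective puff radius in mm (defaults
#'   to `config$rp`), e.g. a measured first-applanation radius.
#' @return force in mN (vectorized over `time`).
#' @export
apex_force <- function(config, time, rp = config$rp) {
  stop_if_not_number(rp, "rp", lower = .Machine$double.eps)
  pressure_at(config, time) * pi * rp^2
}

#' Frame time grid of an examination
#'
#' @inheritParams pressure_at
#' @return uniformly spaced frame times in ms covering `[0, duration]`.
#' @export
airpuff_time_grid <- function(config) {
  stopifnot(inherits(config, "airpuff_config"))
  n <- max(2L, round(config$duration * config$sample_rate))
  seq(0, config$duration, length.out = n)
}

#' Tabulate (and optionally export) the pressure pulse
#'
#' @inheritParams pressure_at
#' @param path optional CSV path; when given, a two-column table
#'   `(time_ms, pressure_kPa)` is written.
#' @return data frame with columns `time_ms` and `pressure_kPa`, invisibly
#'   when `path` is given.
#' @export
pulse_table <- function(config, path = NULL) {
  tt <- airpuff_time_grid(config)
  out <- data.frame(time_ms = tt, pressure_kPa = pressure_at(config, tt))
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
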