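# Internal helpers: seeded evaluation, unit conversion, argument checks.

#' Convert pressures between mmHg and kPa
#'
#' Pressures are kept in kPa internally; device-style readings (for example
#' bIOP) arrive in mmHg and are converted at the I/O boundary with
#' 1 mmHg = 0.133322 kPa.
#'
#' @param x numeric vector of pressures.
#' @return numeric vector in the target unit.
#' @export
mmhg_to_kpa <- function(x) x * 0.133322

#' @rdname mmhg_to_kpa
#' @export
kpa_to_mmhg <- function(x) x / 0.133322

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic fan-out of a master seed into per-subject seeds.  A plain
# affine counter keeps every derived seed inside the 32-bit integer range so
# a single subject can be re-simulated in isolation.
derive_seed <- function(master_seed, counter) {
  as.integer((as.numeric(master_seed) %% 65011 + 1) * 32003 +
               17 * as.numeric(counter)) %% 2147483647L
}

stop_if_not_number <- function(x, name, lower = -Inf, upper = Inf,
                               allow_zero_len = FALSE) {
  if (!is.numeric(x) || (!allow_zero_len && length(x) == 0L) || anyNA(x)) {
    stop(sprintf("`%s` must be a non-missing numeric value", name),
         call. = FALSE)
  }
  if (any(x < lower) || any(x > upper)) {
    stop(sprintf("`%s` must lie in [%g, %g]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
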