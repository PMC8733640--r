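# Optional rasterize-then-redetect round trip: renders each frame's edge
# curve as a bright band in a grayscale image and recovers it by
# sub-pixel, intensity-weighted edge detection.

#' Image rendering configuration
#'
#' @param mm_per_px vertical pixel pitch, mm/pixel.
#' @param band_px Gaussian band thickness (SD) in pixels; must be >= 1 so
#'   the band is representable on the pixel grid.
#' @param band_intensity peak band intensity.
#' @param noise_sd additive pixel noise SD.
#' @param pad_mm vertical padding above/below the surface range.
#' @return list of class `image_config`.
#' @export
image_config <- function(mm_per_px = 0.02, band_px = 3, band_intensity = 1,
                         noise_sd = 0, pad_mm = 0.5) {
  if (band_px < 1) {
    stop("band thinner than 1 pixel cannot be represented", call. = FALSE)
  }
  stopifnot(mm_per_px > 0, band_intensity >= 0, noise_sd >= 0, pad_mm >= 0)
  structure(list(mm_per_px = mm_per_px, band_px = band_px,
                 band_intensity = band_intensity, noise_sd = noise_sd,
                 pad_mm = pad_mm),
            class = "image_config")
}

#' Rasterize an examination into grayscale frames
#'
#' Each frame becomes an `ny` x `nx` intensity matrix with a bright
#' Gaussian band centred on the anterior-surface elevation `y(x, t)`.
#' Pixel geometry is recorded so detection is invertible.
#'
#' @param exam a `corvis_exam`.
#' @param config an [image_config()].
#' @param seed seed for pixel noise.
#' @return object of class `frame_stack`: list with `frames` (list of
#'   matrices), `x`, `y0_mm` (elevation of pixel row 1), `mm_per_px`,
#'   `config`.
#' @export
rasterize_frames <- function(exam, config = image_config(), seed = 1L) {
  stopifnot(inherits(exam, "corvis_exam"))
  rng <- range(exam$surface)
  y_lo <- rng[1] - config$pad_mm
  y_hi <- rng[2] + config$pad_mm
  ny <- ceiling((y_hi - y_lo) / config$mm_per_px) + 1L
  y_px <- y_lo + (seq_len(ny) - 1L) * config$mm_per_px
  band_mm <- config$band_px * config$mm_per_px
  frames <- with_seed(seed, {
    lapply(seq_along(exam$time), function(j) {
      img <- config$band_intensity *
        exp(-(outer(y_px, exam$surface[, j], "-"))^2 / (2 * band_mm^2))
      if (config$noise_sd > 0) {
        img <- img + matrix(stats::rnorm(length(img), 0, config$noise_sd),
                            nrow = ny)
      }
      img
    })
  })
  structure(list(frames = frames, x = exam$x, y0_mm = y_lo,
                 mm_per_px = config$mm_per_px, config = config),
            class = "frame_stack")
}

#' Detect the anterior-surface edge in one grayscale frame
#'
#' Per-column, sub-pixel edge detection: locate the brightest pixel, then
#' take the intensity-weighted centroid of the band around it.  Columns
#' whose maximum intensity falls below `threshold` raise a no-edge error.
#'
#' @param frame `ny` x `nx` intensity matrix.
#' @param y0_mm elevation of pixel row 1, mm.
#' @param mm_per_px vertical pixel pitch, mm.
#' @param threshold minimum acceptable column maximum intensity.
#' @param halfwindow_px centroid half-window around the brightest pixel.
#' @return numeric vector: edge elevation `y(x)` in mm per column.
#' @export
detect_edge <- function(frame, y0_mm, mm_per_px, threshold = 0.2,
                        halfwindow_px = 6L) {
  stopifnot(is.matrix(frame))
  ny <- nrow(frame)
  apply(frame, 2, function(col) {
    pk <- which.max(col)
    if (!is.finite(col[pk]) || col[pk] < threshold) {
      stop("no edge detected: column intensity below threshold",
           call. = FALSE)
    }
    win <- max(1L, pk - halfwindow_px):min(ny, pk + halfwindow_px)
    wts <- pmax(col[win], 0)
    y0_mm + (sum(wts * (win - 1L)) / sum(wts)) * mm_per_px
  })
}

#' Re-detect the full surface from a rasterized stack
#'
#' @param stack a `frame_stack`.
#' @inheritParams detect_edge
#' @return `nx` x `n_frames` elevation matrix (same layout as
#'   `corvis_exam$surface`).
#' @export
redetect_surface <- function(stack, threshold = 0.2) {
  stopifnot(inherits(stack, "frame_stack"))
  vapply(stack$frames, detect_edge, numeric(length(stack$x)),
         y0_mm = stack$y0_mm, mm_per_px = stack$mm_per_px,
         threshold = threshold)
}
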