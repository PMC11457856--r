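#' Elliptical two-lung pixel mask
#'
#' Builds a boolean lung mask on a square pixel grid from two ellipses in a
#' thorax-shaped cross-section, in the standard EIT image orientation: row
#' 1 is the most ventral row and column 1 is the subject's right side.
#'
#' @param nrow,ncol Grid size in pixels (default 32 x 32).
#' @return Logical matrix; `TRUE` marks lung pixels.
#' @export
lung_mask_grid <- function(nrow = 32, ncol = 32) {
  r <- (row(matrix(0, nrow, ncol)) - 0.5) / nrow   # 0 ventral -> 1 dorsal
  c <- (col(matrix(0, nrow, ncol)) - 0.5) / ncol   # 0 right -> 1 left
  inside <- function(cc) ((c - cc) / 0.18)^2 + ((r - 0.55) / 0.30)^2 <= 1
  inside(0.28) | inside(0.72)
}

#' Ground-truth regional ventilation map
#'
#' Distributes the global tidal signal over lung pixels.  `regional_share`
#' is the fraction of the respiratory-system compliance attributed to each
#' pixel; it is non-negative, zero outside the lung and sums to 1 over the
#' mask.
#'
#' @param weights Non-negative matrix of per-pixel weights (any scale);
#'   normalized internally.  Non-lung pixels are forced to zero.
#' @param lung_mask Logical matrix of the same shape.
#' @return Object of class `regional_map` with elements `regional_share`,
#'   `lung_mask`.
#' @export
regional_map <- function(weights, lung_mask) {
  .assert(is.matrix(weights) && is.matrix(lung_mask) &&
            all(dim(weights) == dim(lung_mask)),
          "'weights' and 'lung_mask' must be matrices of the same shape")
  .assert(all(weights >= 0), "'weights' must be non-negative")
  weights[!lung_mask] <- 0
  tot <- sum(weights)
  .assert(tot > 0, "map has zero total weight over the lung mask")
  structure(list(regional_share = weights / tot, lung_mask = lung_mask),
            class = "regional_map")
}

#' Parametric regional map with gravity and right-left skew
#'
#' Convenience builder for study-like ventilation distributions: a linear
#' ventral-dorsal gradient and a configurable right-lung share on top of a
#' uniform base.
#'
#' @param lung_mask Logical pixel mask (default [lung_mask_grid()]).
#' @param vd_skew Linear gradient along the ventral-dorsal axis; negative
#'   values favor the ventral (non-gravity-dependent) lung.  0 = uniform.
#' @param right_share Fraction of total signal assigned to the right half
#'   of the mask bounding box (0.5 = symmetric).
#' @return A [regional_map()].
#' @export
#' @examples
#' m <- default_regional_map(vd_skew = -0.3, right_share = 0.55)
#' sum(m$regional_share)
default_regional_map <- function(lung_mask = lung_mask_grid(), vd_skew = 0,
                                 right_share = 0.5) {
  .assert(abs(vd_skew) < 2, "'vd_skew' must lie in (-2, 2) to keep weights positive")
  .assert(right_share > 0 && right_share < 1, "'right_share' must be in (0, 1)")
  rows <- which(apply(lung_mask, 1, any))
  x <- if (length(rows) > 1) (row(lung_mask) - min(rows)) / diff(range(rows)) else 0.5
  w <- matrix(1, nrow(lung_mask), ncol(lung_mask)) + vd_skew * (x - 0.5)
  w[w < 0] <- 0
  cols <- which(apply(lung_mask, 2, any))
  mid <- mean(range(cols))
  right <- col(lung_mask) <= mid
  w_r <- sum(w[lung_mask & right]); w_l <- sum(w[lung_mask & !right])
  if (w_r > 0 && w_l > 0) {
    w[right] <- w[right] * right_share / w_r
    w[!right] <- w[!right] * (1 - right_share) / w_l
  }
  regional_map(w, lung_mask)
}

#' Synthesize an EIT frame series from a waveform recording
#'
#' Projects the global volume signal of a recording onto a regional map:
#' each frame's pixel value is `regional_share * volume(t) * gain`, with
#' optional additive Gaussian pixel noise, resampled to the EIT frame rate
#' (48 frames/s by default).  Frames are in arbitrary impedance-like units
#' when `gain != 1`; calibration back to mL is the job of
#' [calibrate_delta_vl()].
#'
#' @param recording A `vent_recording`.
#' @param map A [regional_map()].
#' @param frame_rate Frame rate, Hz.
#' @param gain Global impedance gain, au/mL.
#' @param noise_sd Additive Gaussian pixel noise SD, au.
#' @param seed Seed, required when `noise_sd > 0`.
#' @return Object of class `eit_frames`: `frames` (array rows x cols x
#'   frames, row 1 most ventral), `time`, `frame_rate`, `lung_mask`, and
#'   the generating `map`.
#' @export
synthesize_eit <- function(recording, map, frame_rate = 48, gain = 1,
                           noise_sd = 0, seed = NULL) {
  .assert(inherits(map, "regional_map"), "'map' must be a regional_map")
  .assert(.finite_pos(frame_rate), "'frame_rate' must be positive (Hz)")
  tf <- seq(0, max(recording$time), by = 1 / frame_rate)
  vol <- approx(recording$time, recording$volume, xout = tf, rule = 2)$y
  d <- dim(map$regional_share)
  frames <- array(as.vector(map$regional_share) %o% (vol * gain),
                  dim = c(d[1], d[2], length(tf)))
  if (noise_sd > 0) {
    .assert(!is.null(seed), "'seed' is required when 'noise_sd' > 0")
    frames <- frames + .with_seed(seed, array(rnorm(length(frames), 0, noise_sd),
                                              dim = dim(frames)))
  }
  structure(list(frames = frames, time = tf, frame_rate = frame_rate,
                 lung_mask = map$lung_mask, map = map, gain = gain),
            class = "eit_frames")
}

#' @export
print.eit_frames <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("EIT frame series: %d x %d pixels, %d frames at %g Hz (%d lung pixels)\n",
              d[1], d[2], d[3], x$frame_rate, sum(x$lung_mask)))
  invisible(x)
}

#' Global (whole-lung) EIT signal
#'
#' Sum of all lung-mask pixels per frame - the EIT analogue of the global
#' volume signal, in the frame series' units.
#'
#' @param frames An `eit_frames` object.
#' @return Numeric vector, one value per frame.
#' @export
eit_global_signal <- function(frames) {
  .assert(inherits(frames, "eit_frames"), "'frames' must be an eit_frames object")
  apply(frames$frames, 3, function(f) sum(f[frames$lung_mask]))
}
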