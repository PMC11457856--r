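#' Tidal ventilation image from an EIT frame series
#'
#' Per-pixel tidal amplitude: end-inspiratory minus end-expiratory pixel
#' value, averaged over the breaths in the analysis window.  Breath timing
#' is taken from waveform segmentation when available; otherwise
#' end-inspiration/expiration are detected as extrema of the global lung
#' signal.  Negative pixel amplitudes (reconstruction artifacts in real
#' data, noise here) are clipped to zero and counted.
#'
#' @param frames An `eit_frames` object.
#' @param segments Optional [segment_breaths()] output from the source
#'   recording (times are matched to the nearest frame).
#' @param window Optional time window `c(t0, t1)` restricting the breaths
#'   used.
#' @return Object of class `tidal_image`: `amplitude` matrix, `lung_mask`,
#'   region masks (`ventral`/`central`/`dorsal` thirds and `right`/`left`
#'   halves of the mask bounding box), `n_breaths`, `n_clipped`.
#' @export
tidal_image <- function(frames, segments = NULL, window = NULL) {
  .assert(inherits(frames, "eit_frames"), "'frames' must be an eit_frames object")
  g <- eit_global_signal(frames)
  tf <- frames$time
  if (!is.null(segments)) {
    .assert(nrow(segments) > 0, "no complete breath in 'segments'")
    t_ei <- segments$t_insp_end
    t_ee <- segments$t_onset
  } else {
    # extrema of the global signal, with a prominence guard
    dg <- diff(g)
    pk <- which(dg[-length(dg)] > 0 & dg[-1] <= 0) + 1L
    tr <- which(dg[-length(dg)] < 0 & dg[-1] >= 0) + 1L
    keep <- g[pk] > min(g) + 0.25 * diff(range(g))
    pk <- pk[keep]
    .assert(length(pk) >= 1, "window does not contain a full breath")
    t_ei <- tf[pk]
    t_ee <- vapply(pk, function(p) {
      cand <- tr[tr < p]
      if (length(cand)) tf[max(cand)] else tf[1]
    }, numeric(1))
  }
  if (!is.null(window)) {
    keep <- t_ee >= window[1] & t_ei <= window[2]
    t_ei <- t_ei[keep]; t_ee <- t_ee[keep]
  }
  .assert(length(t_ei) >= 1, "window does not contain a full breath")
  nearest <- function(t) pmin(pmax(round(t * frames$frame_rate) + 1L, 1L), length(tf))
  i_ei <- nearest(t_ei); i_ee <- nearest(t_ee)
  d <- dim(frames$frames)
  amp <- matrix(0, d[1], d[2])
  for (k in seq_along(i_ei)) amp <- amp + frames$frames[, , i_ei[k]] - frames$frames[, , i_ee[k]]
  amp <- amp / length(i_ei)
  amp[!frames$lung_mask] <- 0
  n_clip <- sum(amp < 0)
  amp[amp < 0] <- 0

  mask <- frames$lung_mask
  rows <- range(which(apply(mask, 1, any)))
  cols <- range(which(apply(mask, 2, any)))
  rx <- (row(mask) - rows[1]) / max(rows[2] - rows[1], 1L)
  thirds <- list(ventral = rx < 1 / 3, central = rx >= 1 / 3 & rx < 2 / 3,
                 dorsal = rx >= 2 / 3)
  midc <- mean(cols)
  regions <- c(lapply(thirds, function(m) m & mask),
               list(right = (col(mask) <= midc) & mask,
                    left = (col(mask) > midc) & mask))
  structure(list(amplitude = amp, lung_mask = mask, regions = regions,
                 n_breaths = length(i_ei), n_clipped = n_clip),
            class = "tidal_image")
}

#' @export
print.tidal_image <- function(x, ...) {
  cat(sprintf("Tidal ventilation image: %d x %d, %d lung pixels, %d breath(s) averaged\n",
              nrow(x$amplitude), ncol(x$amplitude), sum(x$lung_mask), x$n_breaths))
  cat(sprintf("  total amplitude %.4g, %d negative pixel(s) clipped\n",
              sum(x$amplitude), x$n_clipped))
  invisible(x)
}

#' @export
plot.tidal_image <- function(x, ...) {
  # display with ventral row at the top
  image(t(x$amplitude[nrow(x$amplitude):1, ]), axes = FALSE,
        main = "Tidal ventilation", ...)
  mtext("ventral", 3, 0); mtext("dorsal", 1, 0)
  mtext("right", 2, 0); mtext("left", 4, 0)
  invisible(x)
}

.axis_coord <- function(mask, axis) {
  # pixel coordinate along the axis, 0..100 over the lung-mask bounding box;
  # VD: 0 = most ventral row, RL: 0 = subject-right extreme (column 1 side)
  if (axis == "VD") {
    rng <- range(which(apply(mask, 1, any)))
    if (rng[1] == rng[2]) return(matrix(50, nrow(mask), ncol(mask)))
    (row(mask) - rng[1]) / (rng[2] - rng[1]) * 100
  } else {
    rng <- range(which(apply(mask, 2, any)))
    if (rng[1] == rng[2]) return(matrix(50, nrow(mask), ncol(mask)))
    (col(mask) - rng[1]) / (rng[2] - rng[1]) * 100
  }
}

#' Center of ventilation
#'
#' Amplitude-weighted center of the tidal distribution along the
#' ventral-dorsal (`"VD"`) or right-left (`"RL"`) axis, as a percentage of
#' the lung-mask bounding-box extent: 0% = most ventral / most right, 100%
#' = most dorsal / most left.  Values below the uniform reference
#' ([uniform_cov()]) indicate ventilation favoring the ventral
#' (non-gravity-dependent) or right lung.  The default is the standard
#' centroid; `method = "geometric"` gives the log-scale geometric mean of
#' the pixel coordinates instead.
#'
#' @param image A [tidal_image()].
#' @param axis `"VD"` or `"RL"`.
#' @param method `"centroid"` (default) or `"geometric"`.
#' @return CoV, percent in `[0, 100]`.
#' @export
center_of_ventilation <- function(image, axis = c("VD", "RL"),
                                  method = c("centroid", "geometric")) {
  axis <- match.arg(axis); method <- match.arg(method)
  .assert(inherits(image, "tidal_image"), "'image' must be a tidal_image")
  w <- image$amplitude[image$lung_mask]
  .assert(sum(w) > 0, "all-zero tidal image")
  x <- .axis_coord(image$lung_mask, axis)[image$lung_mask]
  if (method == "centroid") sum(w * x) / sum(w)
  else exp(sum(w * log(x + 1)) / sum(w)) - 1 # shift by 1% avoids log(0) at the extreme
}

#' Uniform-ventilation CoV reference
#'
#' Center of ventilation of a perfectly uniform distribution over the lung
#' mask (unit weight per pixel) - the dotted-line reference against which
#' measured CoV values are read.
#'
#' @param lung_mask Logical pixel mask.
#' @param axis `"VD"` or `"RL"`.
#' @return Percent in `[0, 100]`.
#' @export
uniform_cov <- function(lung_mask, axis = c("VD", "RL")) {
  axis <- match.arg(axis)
  x <- .axis_coord(lung_mask, axis)[lung_mask]
  mean(x)
}

#' Relative aeration per lung region
#'
#' Ratio of a region's share of the tidal (or aeration) signal to its share
#' of lung pixels; 1.0 in every region means a perfectly uniform
#' distribution relative to anatomical size.
#'
#' @param image A [tidal_image()].
#' @param regions Named list of logical region masks; defaults to the
#'   image's ventral/central/dorsal thirds and right/left halves.
#' @return Named numeric vector of ratios.
#' @export
relative_aeration <- function(image, regions = NULL) {
  .assert(inherits(image, "tidal_image"), "'image' must be a tidal_image")
  if (is.null(regions)) regions <- image$regions
  tot_w <- sum(image$amplitude[image$lung_mask])
  tot_n <- sum(image$lung_mask)
  .assert(tot_w > 0, "all-zero tidal image")
  vapply(regions, function(m) {
    m <- m & image$lung_mask
    .assert(sum(m) > 0, "empty region")
    (sum(image$amplitude[m]) / tot_w) / (sum(m) / tot_n)
  }, numeric(1))
}

#' Unventilated (silent) lung fraction
#'
#' Percentage of lung pixels whose tidal amplitude is strictly below
#' `threshold_fraction` times the mean amplitude of the non-zero lung
#' pixels (the "silent space" convention; the threshold definition is
#' returned alongside the value).
#'
#' @param image A [tidal_image()].
#' @param threshold_fraction Fraction of the mean non-zero amplitude.
#' @return Numeric percentage with attributes `threshold` (absolute
#'   amplitude used) and `definition`.
#' @export
unventilated_fraction <- function(image, threshold_fraction = 0.10) {
  .assert(inherits(image, "tidal_image"), "'image' must be a tidal_image")
  w <- image$amplitude[image$lung_mask]
  .assert(max(w) > 0, "all-zero tidal image")
  thr <- threshold_fraction * mean(w[w > 0])
  structure(100 * mean(w < thr), threshold = thr,
            definition = sprintf("amplitude < %.3g x mean non-zero lung amplitude",
                                 threshold_fraction))
}

#' Regional ventilation summary
#'
#' One-row summary of a tidal image: CoV along both axes with uniform
#' references, per-region relative aeration and unventilated fraction - the
#' regional metrics reported per subject and epoch.
#'
#' @param image A [tidal_image()].
#' @param threshold_fraction Passed to [unventilated_fraction()].
#' @return One-row data frame.
#' @export
regional_summary <- function(image, threshold_fraction = 0.10) {
  ra <- relative_aeration(image)
  data.frame(CoV_VD = center_of_ventilation(image, "VD"),
             CoV_RL = center_of_ventilation(image, "RL"),
             uniform_CoV_VD = uniform_cov(image$lung_mask, "VD"),
             uniform_CoV_RL = uniform_cov(image$lung_mask, "RL"),
             ra_ventral = ra[["ventral"]], ra_central = ra[["central"]],
             ra_dorsal = ra[["dorsal"]], ra_right = ra[["right"]],
             ra_left = ra[["left"]],
             unventilated_pct = as.numeric(unventilated_fraction(image, threshold_fraction)))
}
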