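#' Segment a recording into breaths by flow crossings
#'
#' Breath boundaries are defined on the flow channel, not the ventilator
#' clock, so the analyzer is device-agnostic.  Inspiration onset is a
#' positive-going crossing of `+flow_tolerance`; inspiration end is the
#' subsequent negative-going crossing of `-flow_tolerance` (hysteresis
#' band); the breath ends at the next onset.  Inspirations shorter than
#' `min_insp_duration` and partial first/last breaths are discarded.
#'
#' @param recording A `vent_recording` (or any list with `time`, `flow`,
#'   `sample_rate`).
#' @param min_insp_duration Minimum inspiratory duration, s.
#' @param flow_tolerance Hysteresis threshold, L/min.  Default 0.1, about
#'   1% of a typical bias flow.
#' @param smoothing_window Centered moving-average window (samples)
#'   applied to the flow channel for crossing detection only, so sensor
#'   noise cannot create spurious crossings; metrics are always computed
#'   on the raw channels.  Use 0 to disable.
#' @param min_exp_duration Minimum expiratory duration, s; candidate
#'   breaths with a shorter expiratory phase are treated as detection
#'   artifacts and discarded.
#' @return A data frame of class `breath_segments` with one row per
#'   complete breath: sample indices `i_onset`, `i_insp_end`, `i_exp_end`
#'   (exclusive) and the corresponding times.  Zero rows when no complete
#'   breath is present.
#' @export
#' @examples
#' rec <- simulate_ventilation(vent_settings(bias_flow = 8), lung_params(),
#'                             duration = 5)
#' segment_breaths(rec)
segment_breaths <- function(recording, min_insp_duration = 0.05,
                            flow_tolerance = 0.1, smoothing_window = 7,
                            min_exp_duration = 0.05) {
  .assert(!is.null(recording$flow), "recording has no flow channel")
  x <- recording$flow
  if (smoothing_window >= 2 && length(x) > smoothing_window) {
    xs <- as.numeric(stats::filter(x, rep(1 / smoothing_window, smoothing_window),
                                   sides = 2))
    x <- ifelse(is.na(xs), x, xs)
  }
  sr <- recording$sample_rate
  n <- length(x)
  empty <- structure(data.frame(breath = integer(0), i_onset = integer(0),
                                i_insp_end = integer(0), i_exp_end = integer(0),
                                t_onset = numeric(0), t_insp_end = numeric(0),
                                t_exp_end = numeric(0)),
                     class = c("breath_segments", "data.frame"),
                     sample_rate = sr)
  if (n < 3) return(empty)

  # state machine with hysteresis: idle -> insp (x > +tol) -> exp (x < -tol).
  # The onset index is the last sample at or below the threshold (the
  # crossing sample), so pressure/volume there still reflect the
  # end-expiratory state; the inspiratory end is the first sample beyond
  # the negative-going crossing.
  onsets <- integer(0); insp_ends <- integer(0)
  state <- "idle"
  for (i in seq_len(n)) {
    if (state != "insp" && x[i] > flow_tolerance) {
      onsets <- c(onsets, max(i - 1L, 1L))
      state <- "insp"
    } else if (state == "insp" && x[i] < -flow_tolerance) {
      insp_ends <- c(insp_ends, i)
      state <- "exp"
    }
  }
  if (length(onsets) < 2) return(empty)

  segs <- empty[0, , drop = FALSE]
  b <- 0L
  for (k in seq_len(length(onsets) - 1L)) {
    i0 <- onsets[k]; i2 <- onsets[k + 1L]
    i1 <- insp_ends[insp_ends > i0 & insp_ends <= i2]
    if (!length(i1)) next                      # no expiratory phase: partial
    i1 <- i1[1]
    if ((i1 - i0) / sr < min_insp_duration) next
    if ((i2 - i1) / sr < min_exp_duration) next
    b <- b + 1L
    segs[b, ] <- list(b, i0, i1, i2,
                      recording$time[i0], recording$time[i1], recording$time[i2])
  }
  structure(segs, class = c("breath_segments", "data.frame"), sample_rate = sr)
}

#' @export
print.breath_segments <- function(x, ...) {
  cat(sprintf("%d complete breath(s)", nrow(x)))
  if (nrow(x)) cat(sprintf(", median duration %.3g s, median Ti %.3g s",
                           median(x$t_exp_end - x$t_onset),
                           median(x$t_insp_end - x$t_onset)))
  cat("\n")
  if (nrow(x)) print.data.frame(head(x, 5))
  invisible(x)
}

.channel <- function(recording, channel) {
  channel <- match.arg(channel, c("pressure", "volume", "flow"))
  recording[[channel]]
}

#' Time to inspiratory peak
#'
#' Time from inspiration onset to the channel's maximum within each breath,
#' with ties broken to the earliest sample.  On pressure this measures how
#' long the airway pressure wave takes to reach its peak; lower bias flows
#' charge the circuit more slowly and lengthen it.
#'
#' @param recording A `vent_recording`.
#' @param segments [segment_breaths()] output; computed if `NULL`.
#' @param channel `"pressure"`, `"volume"` or `"flow"`.
#' @return Numeric vector, one value (s) per breath.
#' @export
time_to_peak <- function(recording, segments = NULL, channel = "pressure") {
  if (is.null(segments)) segments <- segment_breaths(recording)
  .assert(nrow(segments) > 0, "no complete breath found")
  x <- .channel(recording, channel)
  vapply(seq_len(nrow(segments)), function(j) {
    i0 <- segments$i_onset[j]; i2 <- segments$i_exp_end[j]
    w <- x[i0:(i2 - 1L)]
    (which.max(w) - 1L) / recording$sample_rate
  }, numeric(1))
}

.sg_derivative <- function(x, sr, window, order) {
  # centered Savitzky-Golay first derivative (units/s)
  signal::sgolayfilt(x, p = order, n = window, m = 1) * sr
}

#' Maximum slope of a waveform within a breath phase
#'
#' The first derivative is estimated on the channel with a centered
#' Savitzky-Golay polynomial filter (default window 7 samples, order 2) so
#' the estimate is not noise-dominated.  For the inspiratory phase the
#' maximum (signed) derivative is returned; for the expiratory phase the
#' maximum magnitude of the derivative, i.e. the fastest rate of change
#' regardless of direction.  Ties break to the earliest sample.
#'
#' @inheritParams time_to_peak
#' @param phase `"insp"` or `"exp"`.
#' @param smoothing_window Filter window length, samples (odd, >= 5).
#' @param smoothing_order Polynomial order of the filter.
#' @return Data frame per breath: `slope_max` (channel units/s) and
#'   `t_at_slope_max` (s from inspiration onset).
#' @export
max_slope <- function(recording, segments = NULL, channel = "pressure",
                      phase = c("insp", "exp"), smoothing_window = 7,
                      smoothing_order = 2) {
  phase <- match.arg(phase)
  if (is.null(segments)) segments <- segment_breaths(recording)
  .assert(nrow(segments) > 0, "no complete breath found")
  .assert(smoothing_window %% 2 == 1 && smoothing_window >= 5,
          "'smoothing_window' must be odd and >= 5")
  x <- .channel(recording, channel)
  sr <- recording$sample_rate
  out <- data.frame(breath = segments$breath, slope_max = NA_real_,
                    t_at_slope_max = NA_real_)
  for (j in seq_len(nrow(segments))) {
    i0 <- segments$i_onset[j]
    rng <- if (phase == "insp") i0:(segments$i_insp_end[j] - 1L)
           else segments$i_insp_end[j]:(segments$i_exp_end[j] - 1L)
    .assert(length(rng) >= 5, "phase too short (< 5 samples)")
    .assert(smoothing_window <= length(rng), "smoothing window larger than phase")
    d <- .sg_derivative(x[rng], sr, smoothing_window, smoothing_order)
    if (phase == "exp") d <- abs(d)
    # earliest-sample tie rule, robust to floating-point residue
    k <- which(d >= max(d) - 1e-9 * max(abs(d)))[1]
    out$slope_max[j] <- d[k]
    out$t_at_slope_max[j] <- (rng[k] - i0) / sr
  }
  out
}

#' Per-breath tidal lung-motion metrics
#'
#' Applies [time_to_peak()] and [max_slope()] to the pressure, volume and
#' flow channels of every complete breath, both phases, and returns a tidy
#' table.  These are the waveform speed-of-motion metrics: time to
#' inspiratory peak, maximum inspiratory slope (on flow, the acceleration
#' of lung volume) and its timing, and the maximum expiratory rate of
#' change.
#'
#' @inheritParams max_slope
#' @param flow_tolerance Passed to [segment_breaths()] when `segments` is
#'   `NULL`.
#' @return Data frame: `subject_id`, `breath_index`, `channel`, `phase`,
#'   `T_peak_s` (inspiratory rows), `slope_max`, `t_at_slope_max_s`.
#' @export
motion_metrics <- function(recording, segments = NULL, smoothing_window = 7,
                           smoothing_order = 2, flow_tolerance = 0.1) {
  if (is.null(segments)) segments <- segment_breaths(recording, flow_tolerance = flow_tolerance)
  .assert(nrow(segments) > 0, "no complete breath found")
  rows <- list()
  for (ch in c("pressure", "volume", "flow")) {
    tp <- time_to_peak(recording, segments, ch)
    for (ph in c("insp", "exp")) {
      ms <- max_slope(recording, segments, ch, phase = ph,
                      smoothing_window = smoothing_window,
                      smoothing_order = smoothing_order)
      rows[[paste(ch, ph)]] <- data.frame(
        subject_id = recording$subject_id, breath_index = segments$breath,
        channel = ch, phase = ph,
        T_peak_s = if (ph == "insp") tp else NA_real_,
        slope_max = ms$slope_max, t_at_slope_max_s = ms$t_at_slope_max)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
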