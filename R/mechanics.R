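#' Per-breath lung mechanics
#'
#' Ratio-based mechanics for every complete breath: peak inflation pressure,
#' PEEP measured at inspiratory onset (robust to intrinsic PEEP), driving
#' pressure `dP = PIP - PEEP`, tidal volume (volume at inspiration end minus
#' volume at onset), weight-normalized dynamic compliance `C_dyn = V_T/dP`
#' and peak inspiratory flow.  Breaths with non-positive tidal volume are
#' kept but flagged (`degenerate`); a regression-based alternative to the
#' ratio compliance is available through [fit_eom()].
#'
#' @param recording A `vent_recording`.
#' @param segments [segment_breaths()] output; computed if `NULL`.
#' @param weight Body weight, kg; defaults to the recording's.
#' @return Data frame per breath: `PIP`, `PEEP_measured`, `dP` (cmH2O),
#'   `V_T` (mL), `V_T_mlkg`, `C_dyn` (mL/cmH2O/kg), `Flow_peak` (L/min),
#'   `degenerate`.
#' @export
breath_mechanics <- function(recording, segments = NULL, weight = recording$weight) {
  if (is.null(segments)) segments <- segment_breaths(recording)
  .assert(nrow(segments) > 0, "no complete breath found")
  .assert(.finite_pos(weight), "'weight' must be positive (kg)")
  out <- data.frame(breath = segments$breath, PIP = NA_real_,
                    PEEP_measured = NA_real_, dP = NA_real_, V_T = NA_real_,
                    V_T_mlkg = NA_real_, C_dyn = NA_real_, Flow_peak = NA_real_,
                    degenerate = FALSE)
  for (j in seq_len(nrow(segments))) {
    i0 <- segments$i_onset[j]; i1 <- segments$i_insp_end[j]; i2 <- segments$i_exp_end[j]
    p <- recording$pressure[i0:(i2 - 1L)]
    out$PIP[j] <- max(p)
    out$PEEP_measured[j] <- recording$pressure[i0]
    dP <- out$PIP[j] - out$PEEP_measured[j]
    .assert(dP > 0, "non-positive driving pressure: not a valid breath")
    vt <- recording$volume[i1] - recording$volume[i0]
    out$dP[j] <- dP
    out$V_T[j] <- vt
    out$V_T_mlkg[j] <- vt / weight
    out$C_dyn[j] <- max(vt, 0) / dP / weight
    out$Flow_peak[j] <- max(recording$flow[i0:(i1 - 1L)])
    out$degenerate[j] <- vt <= 0
  }
  out
}

#' Fit the single-compartment equation of motion
#'
#' Least-squares fit of the linear equation of motion of the respiratory
#' system, `P_ao(t) = V(t)/C + R * Q(t) + P0`, over the selected breaths.
#' Returns compliance (mL/cmH2O), resistance (cmH2O.s/mL) and the static
#' recoil offset `P0` (cmH2O, the effective PEEP), as a classed model
#' object with the usual accessors.
#'
#' @param recording A `vent_recording`.
#' @param segments [segment_breaths()] output; computed if `NULL`.
#' @param breaths Optional integer vector of breath indices to fit
#'   (default: all complete breaths).
#' @return An object of class `eom_fit` with `coef()` (`C`, `R`, `P0`),
#'   `summary()`, `predict()` and `residuals()` methods.
#' @export
#' @examples
#' rec <- simulate_ventilation(vent_settings(bias_flow = 8), lung_params(),
#'                             duration = 5)
#' coef(fit_eom(rec))
fit_eom <- function(recording, segments = NULL, breaths = NULL) {
  if (is.null(segments)) segments <- segment_breaths(recording)
  .assert(nrow(segments) > 0, "no complete breath found")
  if (!is.null(breaths)) segments <- segments[segments$breath %in% breaths, , drop = FALSE]
  idx <- unlist(lapply(seq_len(nrow(segments)), function(j)
    segments$i_onset[j]:(segments$i_exp_end[j] - 1L)))
  .assert(length(idx) >= 20, "breath too short to fit (< 20 samples)")
  dat <- data.frame(paw = recording$pressure[idx],
                    vol = recording$volume[idx],
                    q_mls = recording$flow[idx] * 1000 / 60)
  X <- cbind(1, dat$vol, dat$q_mls)
  sv <- svd(scale(X, center = FALSE,
                  scale = apply(abs(X), 2, max) + .Machine$double.eps))$d
  .assert(qr(X)$rank == 3L && sv[3] / sv[1] > 1e-8,
          "rank-deficient design: volume and flow are linearly dependent (or constant)")
  fit <- lm(paw ~ vol + q_mls, data = dat)
  b <- coef(fit)
  .assert(is.finite(b["vol"]) && b["vol"] != 0, "degenerate fit: zero elastance")
  structure(list(coefficients = c(C = unname(1 / b["vol"]), R = unname(b["q_mls"]),
                                  P0 = unname(b["(Intercept)"])),
                 lm = fit, n = nrow(dat), n_breaths = nrow(segments),
                 rms = sqrt(mean(residuals(fit)^2))),
            class = "eom_fit")
}

#' @export
coef.eom_fit <- function(object, ...) object$coefficients

#' @export
print.eom_fit <- function(x, ...) {
  cat("Single-compartment equation-of-motion fit\n")
  cat(sprintf("  C = %.4g mL/cmH2O, R = %.4g cmH2O.s/mL, P0 = %.4g cmH2O\n",
              x$coefficients["C"], x$coefficients["R"], x$coefficients["P0"]))
  cat(sprintf("  %d samples over %d breath(s); residual RMS %.3g cmH2O\n",
              x$n, x$n_breaths, x$rms))
  invisible(x)
}

#' @export
summary.eom_fit <- function(object, ...) {
  s <- summary(object$lm)
  out <- list(coefficients = object$coefficients, rms = object$rms,
              r_squared = s$r.squared, lm_coefficients = s$coefficients,
              n = object$n, n_breaths = object$n_breaths)
  class(out) <- "summary.eom_fit"
  out
}

#' @export
print.summary.eom_fit <- function(x, ...) {
  cat("Equation-of-motion fit: P_ao = V/C + R*Q + P0\n")
  cat(sprintf("  C  = %.5g mL/cmH2O\n  R  = %.5g cmH2O.s/mL\n  P0 = %.5g cmH2O\n",
              x$coefficients["C"], x$coefficients["R"], x$coefficients["P0"]))
  cat(sprintf("  residual RMS %.3g cmH2O, R^2 %.5f (%d samples, %d breaths)\n",
              x$rms, x$r_squared, x$n, x$n_breaths))
  invisible(x)
}

#' @export
predict.eom_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(predict(object$lm))
  .assert(all(c("volume", "flow") %in% names(newdata)),
          "'newdata' needs 'volume' (mL) and 'flow' (L/min)")
  predict(object$lm, data.frame(vol = newdata$volume,
                                q_mls = newdata$flow * 1000 / 60))
}

#' @export
residuals.eom_fit <- function(object, ...) residuals(object$lm)

#' Inspiratory pressure-volume energy per breath
#'
#' Trapezoidal integral of `(P_ao - PEEP) dV` over the inspiratory phase of
#' each breath, i.e. the tidal energy delivered above the end-expiratory
#' working point, converted to joule (1 cmH2O.mL = 98.0665e-6 J).  PEEP is
#' the pressure measured at inspiratory onset.  A negative integral signals
#' phase mislabelling and raises an error.
#'
#' @inheritParams breath_mechanics
#' @param reference `"peep"` (default) integrates pressure above measured
#'   PEEP, isolating tidal energy; `"atmosphere"` integrates absolute
#'   airway pressure.
#' @return Numeric vector of per-breath energies, J.
#' @export
energy_per_breath <- function(recording, segments = NULL,
                              reference = c("peep", "atmosphere")) {
  reference <- match.arg(reference)
  if (is.null(segments)) segments <- segment_breaths(recording)
  .assert(nrow(segments) > 0, "no complete breath found")
  vapply(seq_len(nrow(segments)), function(j) {
    i0 <- segments$i_onset[j]; i1 <- segments$i_insp_end[j]
    .assert(i1 - i0 >= 2, "inspiratory phase not resolvable")
    p <- recording$pressure[i0:i1]
    if (reference == "peep") p <- p - recording$pressure[i0]
    v <- recording$volume[i0:i1]
    e <- sum(0.5 * (p[-1] + p[-length(p)]) * diff(v)) * CMH2O_ML_TO_J
    .assert(e >= -1e-9 * CMH2O_ML_TO_J * max(abs(v)) - 1e-15,
            "negative inspiratory energy: check phase labelling")
    max(e, 0)
  }, numeric(1))
}

#' Tidal mechanical power
#'
#' Per-breath inspiratory energy times respiratory rate, normalized to
#' weight: `MP_tidal = E_breath * rate / weight` (J/min/kg).  This is the
#' dynamic, PEEP-referenced tidal form; see [energy_per_breath()] for the
#' atmosphere-referenced variant.
#'
#' @param E_breath Energy per breath, J (e.g. from [energy_per_breath()]).
#' @param rate Respiratory rate, breaths/min.
#' @param weight Body weight, kg.
#' @return Mechanical power, J/min/kg.
#' @export
#' @examples
#' mp_tidal(0.0196, rate = 60, weight = 1)
mp_tidal <- function(E_breath, rate, weight) {
  .assert(all(E_breath >= 0), "'E_breath' must be >= 0 (J)")
  .assert(.finite_pos(rate) && .finite_pos(weight), "'rate' and 'weight' must be positive")
  E_breath * rate / weight
}

#' Mechanical energy of the respiratory system per breath
#'
#' Closed-form elastic energy per breath normalized to weight:
#' `ME_RS = (0.5 * dP * V_T + PEEP * V_T)` converted to J/kg - the
#' triangular tidal elastic energy plus the work of displacing the tidal
#' volume against PEEP.  This constant form is a documented substitute for
#' supplementary-literature formulas and can be swapped via `form`.
#'
#' @param V_T Tidal volume, mL.
#' @param dP Driving pressure, cmH2O.
#' @param PEEP Positive end-expiratory pressure, cmH2O.
#' @param weight Body weight, kg.
#' @param form `"elastic"` (default, includes the PEEP term) or
#'   `"driving_only"` (`0.5 * dP * V_T` alone).
#' @return Energy, J/kg.
#' @export
#' @examples
#' me_rs(V_T = 10, dP = 20, PEEP = 8, weight = 1)
me_rs <- function(V_T, dP, PEEP, weight, form = c("elastic", "driving_only")) {
  form <- match.arg(form)
  .assert(all(V_T > 0) && all(dP > 0), "'V_T' and 'dP' must be positive")
  .assert(all(PEEP >= 0), "'PEEP' must be >= 0")
  .assert(.finite_pos(weight), "'weight' must be positive (kg)")
  e <- 0.5 * dP * V_T + if (form == "elastic") PEEP * V_T else 0
  e * CMH2O_ML_TO_J / weight
}

#' Ventilatory efficiency index
#'
#' `VEI = K / (dP * rate * PaCO2)` with the literature constant `K = 3800`.
#' Higher values mean more CO2 cleared per unit of driving pressure and
#' rate; doubling any input halves the index.
#'
#' @param dP Driving pressure, cmH2O.
#' @param rate Respiratory rate, breaths/min.
#' @param PaCO2 Arterial CO2 tension, mmHg.
#' @param K Dimensional constant (default 3800).
#' @return A list of class `vei_result`: `VEI` plus the inputs.
#' @export
#' @examples
#' vei(dP = 20, rate = 60, PaCO2 = 50)$VEI   # 3800/60000
vei <- function(dP, rate, PaCO2, K = 3800) {
  .assert(all(dP > 0) && all(rate > 0) && all(PaCO2 > 0) && K > 0,
          "all of 'dP', 'rate', 'PaCO2', 'K' must be positive")
  structure(list(VEI = K / (dP * rate * PaCO2),
                 dP = dP, rate = rate, PaCO2 = PaCO2, K = K),
            class = "vei_result")
}

#' @export
print.vei_result <- function(x, ...) {
  cat(sprintf("VEI = %.4g  (K=%g, dP=%.3g cmH2O, rate=%.3g /min, PaCO2=%.3g mmHg)\n",
              x$VEI[1], x$K, x$dP[1], x$rate[1], x$PaCO2[1]))
  if (length(x$VEI) > 1) cat(sprintf("  (+%d more)\n", length(x$VEI) - 1))
  invisible(x)
}

#' Static pressure-volume maneuver on the model lung
#'
#' Generates the inflation limb of a quasi-static pressure-volume curve by
#' holding the model lung at each pressure step until equilibrium
#' (`V = C_rs * P` for the linear single compartment, with an exponential
#' approach over the hold time).
#'
#' @param lung A [lung_params()].
#' @param pressure_steps Pressure steps, cmH2O (default 0 to 35 by 5).
#' @param hold_time Hold at each step, s.
#' @return Data frame `pressure` (cmH2O), `volume` (mL).
#' @export
static_pv_maneuver <- function(lung, pressure_steps = seq(0, 35, by = 5),
                               hold_time = 3) {
  .assert(inherits(lung, "lung_params"), "'lung' must be a lung_params object")
  tau <- lung$R_aw * lung$C_rs
  v <- 0
  out <- data.frame(pressure = pressure_steps, volume = NA_real_)
  for (i in seq_along(pressure_steps)) {
    v_inf <- lung$C_rs * pressure_steps[i]
    v <- v_inf + (v - v_inf) * exp(-hold_time / tau)
    out$volume[i] <- v
  }
  out
}

#' Summarize a static pressure-volume curve
#'
#' Total lung capacity is the interpolated volume at 35 cmH2O per kg; chord
#' compliances are volume differences over configurable pressure pairs.  If
#' the maneuver did not reach 35 cmH2O the value is linearly extrapolated
#' from the last segment and flagged.
#'
#' @param pressure,volume Inflation-limb pressure (cmH2O) and volume (mL)
#'   steps.
#' @param weight Body weight, kg.
#' @param chords List of pressure pairs (cmH2O) for chord compliances.
#' @param tlc_pressure Pressure defining total lung capacity, cmH2O.
#' @param monotone_tol Tolerated non-monotonicity of the inflation limb as
#'   a fraction of the volume range.
#' @return List: `TLC_mlkg`, `extrapolated`, and a `chords` data frame of
#'   chord compliances (mL/cmH2O/kg).
#' @export
#' @examples
#' analyze_pv_curve(seq(0, 35, 5), 2 * seq(0, 35, 5), weight = 1)
analyze_pv_curve <- function(pressure, volume, weight,
                             chords = list(c(0, 10), c(10, 20), c(20, 35)),
                             tlc_pressure = 35, monotone_tol = 0.01) {
  .assert(length(pressure) == length(volume) && length(pressure) >= 2,
          "'pressure' and 'volume' must be equal-length vectors (>= 2 points)")
  .assert(.finite_pos(weight), "'weight' must be positive (kg)")
  o <- order(pressure)
  pressure <- pressure[o]; volume <- volume[o]
  vr <- diff(range(volume))
  .assert(all(diff(volume) >= -monotone_tol * max(vr, .Machine$double.eps)),
          "inflation limb is non-monotone beyond tolerance")
  interp <- function(p) {
    if (p <= max(pressure)) approx(pressure, volume, xout = p, ties = "ordered")$y
    else { # linear extrapolation from last segment
      k <- length(pressure)
      volume[k] + (p - pressure[k]) * (volume[k] - volume[k - 1]) /
        (pressure[k] - pressure[k - 1])
    }
  }
  tlc <- interp(tlc_pressure) / weight
  ch <- do.call(rbind, lapply(chords, function(pr) {
    data.frame(p_lo = pr[1], p_hi = pr[2],
               compliance = (interp(pr[2]) - interp(pr[1])) / (pr[2] - pr[1]) / weight)
  }))
  list(TLC_mlkg = tlc, extrapolated = tlc_pressure > max(pressure), chords = ch)
}

#' Calibrate a global impedance signal to volume
#'
#' Applies the linear scale `s = V_ref / dZ_ref` obtained from a static
#' pressure-volume reference point to an arbitrary-unit global impedance
#' time series, returning the series in mL with the scale recorded in the
#' `"scale_ml_per_au"` attribute.
#'
#' @param signal Global impedance signal, arbitrary units.
#' @param dZ_ref Impedance change of the reference maneuver, au.
#' @param V_ref Volume change of the reference maneuver, mL.
#' @return `signal * V_ref/dZ_ref`, mL.
#' @export
#' @examples
#' calibrate_delta_vl(c(0, 500, 1000), dZ_ref = 1000, V_ref = 40)
calibrate_delta_vl <- function(signal, dZ_ref, V_ref) {
  .assert(.finite_pos(dZ_ref), "'dZ_ref' must be positive")
  .assert(is.numeric(V_ref) && is.finite(V_ref), "'V_ref' must be a finite volume (mL)")
  s <- V_ref / dZ_ref
  structure(signal * s, scale_ml_per_au = s)
}
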