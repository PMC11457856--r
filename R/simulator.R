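#' Ventilator settings for the bias-flow circuit model
#'
#' Bundles the settings of a pressure-limited continuous-bias-flow
#' ventilator.  The circuit is charged by the bias flow and an ideal relief
#' valve caps circuit pressure at the set inflation pressure during
#' inspiration and at set PEEP during expiration, so the rate of pressure
#' rise at the airway opening is limited by the bias flow itself.
#'
#' @param bias_flow Continuous fresh-gas flow through the circuit, L/min.
#'   Zero is allowed (no gas supplied; the lung cannot inflate).
#' @param set_PIP Set peak inflation pressure, cmH2O.
#' @param set_PEEP Set positive end-expiratory pressure, cmH2O.
#' @param Ti Set inspiratory time, s.  Phase switching is clock-driven
#'   (apnoeic, intubated subject): inspiration lasts exactly `Ti`.
#' @param rate Ventilator rate, breaths/min.
#' @param PIP_max Pressure ceiling the controller may never exceed, cmH2O.
#' @param circuit_compliance Lumped compliance of the patient circuit,
#'   mL/cmH2O.  Default 0.3 corresponds to a rigid low-volume neonatal
#'   circuit; gas charging the circuit is gas that does not reach the lung,
#'   so this value sets how closely peak inspiratory flow approaches the
#'   bias flow.
#'
#' @return An object of class `vent_settings`.
#' @seealso [lung_params()], [simulate_ventilation()]
#' @export
#' @examples
#' vent_settings(bias_flow = 8)
vent_settings <- function(bias_flow, set_PIP = 22, set_PEEP = 8, Ti = 0.5,
                          rate = 60, PIP_max = 40, circuit_compliance = 0.3) {
  .assert(.finite_nonneg(bias_flow), "'bias_flow' must be a finite number >= 0 (L/min)")
  .assert(.finite_pos(set_PIP), "'set_PIP' must be a finite positive number (cmH2O)")
  .assert(.finite_nonneg(set_PEEP), "'set_PEEP' must be finite and >= 0 (cmH2O)")
  .assert(set_PIP > set_PEEP, "'set_PIP' must exceed 'set_PEEP'")
  .assert(.finite_pos(rate), "'rate' must be a finite positive number (breaths/min)")
  .assert(.finite_pos(Ti) && Ti < 60 / rate,
          "'Ti' must satisfy 0 < Ti < 60/rate (inspiration shorter than the breath)")
  .assert(.finite_pos(PIP_max) && set_PIP <= PIP_max, "'set_PIP' must not exceed 'PIP_max'")
  .assert(.finite_pos(circuit_compliance), "'circuit_compliance' must be positive (mL/cmH2O)")
  structure(list(bias_flow = bias_flow, set_PIP = set_PIP, set_PEEP = set_PEEP,
                 Ti = Ti, rate = rate, PIP_max = PIP_max,
                 circuit_compliance = circuit_compliance),
            class = "vent_settings")
}

#' @export
print.vent_settings <- function(x, ...) {
  cat("Ventilator settings (continuous bias flow, pressure limited)\n")
  cat(sprintf("  bias flow %.3g L/min | PIP %.3g / PEEP %.3g cmH2O (ceiling %.3g)\n",
              x$bias_flow, x$set_PIP, x$set_PEEP, x$PIP_max))
  cat(sprintf("  Ti %.3g s | rate %.3g /min | circuit compliance %.3g mL/cmH2O\n",
              x$Ti, x$rate, x$circuit_compliance))
  invisible(x)
}

#' Single-compartment lung model parameters
#'
#' Ground-truth parameters for the simulated preterm respiratory system: a
#' single compartment with linear compliance `C_rs` filling through a total
#' airway + endotracheal tube resistance `R_aw`, so filling and emptying are
#' exponential with time constant `R_aw * C_rs`.  Surfactant treatment is
#' modelled solely through its mechanical consequence, a multiplicative step
#' in compliance at `surfactant_time`.
#'
#' Defaults describe a poorly compliant late-gestation preterm lamb:
#' 2.5 kg, respiratory-system compliance 0.5 mL/cmH2O/kg and a resistance of
#' 25 cmH2O/L/s typical of a narrow endotracheal tube (time constant
#' ~31 ms).
#'
#' @param C_rs Respiratory-system compliance, mL/cmH2O.
#' @param R_aw Airway + tube resistance, cmH2O.s/mL.
#' @param weight Body weight, kg.
#' @param dead_space Series (anatomical + apparatus) dead space, mL.
#'   Default 2.2 mL/kg.
#' @param surfactant_time Time of the compliance step, s, or `NULL` for no
#'   surfactant.
#' @param surfactant_factor Multiplier (>= 1) applied to `C_rs` from
#'   `surfactant_time` on.
#'
#' @return An object of class `lung_params`.
#' @export
#' @examples
#' lung_params()
lung_params <- function(C_rs = 1.25, R_aw = 0.025, weight = 2.5,
                        dead_space = 2.2 * weight,
                        surfactant_time = NULL, surfactant_factor = 1) {
  .assert(.finite_pos(C_rs), "'C_rs' must be positive (mL/cmH2O)")
  .assert(.finite_pos(R_aw), "'R_aw' must be positive (cmH2O.s/mL)")
  .assert(.finite_pos(weight), "'weight' must be positive (kg)")
  .assert(.finite_nonneg(dead_space), "'dead_space' must be >= 0 (mL)")
  .assert(is.null(surfactant_time) || .finite_nonneg(surfactant_time),
          "'surfactant_time' must be NULL or a time in seconds")
  .assert(is.numeric(surfactant_factor) && surfactant_factor >= 1,
          "'surfactant_factor' must be >= 1")
  structure(list(C_rs = C_rs, R_aw = R_aw, weight = weight,
                 dead_space = dead_space, surfactant_time = surfactant_time,
                 surfactant_factor = surfactant_factor),
            class = "lung_params")
}

#' @export
print.lung_params <- function(x, ...) {
  cat("Single-compartment lung\n")
  cat(sprintf("  C_rs %.4g mL/cmH2O | R_aw %.4g cmH2O.s/mL | tau %.1f ms\n",
              x$C_rs, x$R_aw, 1000 * x$C_rs * x$R_aw))
  cat(sprintf("  weight %.3g kg | dead space %.3g mL\n", x$weight, x$dead_space))
  if (!is.null(x$surfactant_time))
    cat(sprintf("  surfactant at %.3g s (C_rs x %.3g)\n",
                x$surfactant_time, x$surfactant_factor))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Closed-form breath solution.
#
# Two-node model in pressures relative to set PEEP (p = P_circ - PEEP):
#   circuit : Cc * dp/dt = f - Q - Q_valve   (ideal valve keeps p <= p_set)
#   lung    : dV/dt = Q = (p - V/Cr) / R
# Within each valve regime the system is linear time-invariant, so each
# stage integrates exactly:
#   charging  : u = p - V/Cr relaxes to u_inf = f*R*Cr/(Cc+Cr) with the fast
#               time constant R*Cc*Cr/(Cc+Cr), while total stored charge
#               Cc*p + V ramps as f*t (gas conservation);
#   clamped   : p = dP_set, V relaxes to Cr*dP_set with tau = R*Cr;
#   expiration: valve dumps the circuit to PEEP, V decays with tau = R*Cr.
# The clamp (relief-valve) time is the root of p(t) = dP_set, located by
# uniroot to 1e-12 s.  p is nondecreasing during charging (Q < f always),
# so the root is unique and peak inspiratory flow can never exceed the
# bias flow when a breath starts from circuit pressure = PEEP.

.breath_solution <- function(f_mls, dPset, Ti, Tb, Cc, Cr, R, V0) {
  tau_f <- R * Cc * Cr / (Cc + Cr)
  u_inf <- f_mls * R * Cr / (Cc + Cr)
  u0 <- -V0 / Cr
  u_of <- function(t) u_inf + (u0 - u_inf) * exp(-t / tau_f)
  p_of <- function(t) (V0 + f_mls * t + Cr * u_of(t)) / (Cc + Cr)
  tau <- R * Cr
  V_inf <- Cr * dPset

  t_clamp <- if (p_of(Ti) >= dPset) {
    if (p_of(0) >= dPset) 0 else
      uniroot(function(t) p_of(t) - dPset, c(0, Ti), tol = 1e-12)$root
  } else Inf

  if (is.finite(t_clamp)) {
    V_clamp <- Cr * (p_of(t_clamp) - u_of(t_clamp))
    V_Ti <- V_inf + (V_clamp - V_inf) * exp(-(Ti - t_clamp) / tau)
  } else {
    V_clamp <- NA_real_
    V_Ti <- Cr * (p_of(Ti) - u_of(Ti))
  }
  V_end <- V_Ti * exp(-(Tb - Ti) / tau)
  # flow rises monotonically until the clamp, then decays
  Q_peak <- u_of(min(t_clamp, Ti)) / R

  list(t_clamp = t_clamp, V_Ti = V_Ti, V_end = V_end, Q_peak = Q_peak,
       eval = function(trel) {
         p <- V <- Q <- numeric(length(trel))
         a <- trel < min(t_clamp, Ti)
         if (any(a)) {
           pa <- p_of(trel[a]); ua <- u_of(trel[a])
           p[a] <- pa; V[a] <- Cr * (pa - ua); Q[a] <- ua / R
         }
         b <- !a & trel < Ti
         if (any(b)) {
           Vb <- V_inf + (V_clamp - V_inf) * exp(-(trel[b] - t_clamp) / tau)
           p[b] <- dPset; V[b] <- Vb; Q[b] <- (V_inf - Vb) / tau
         }
         e <- trel >= Ti
         if (any(e)) {
           Ve <- V_Ti * exp(-(trel[e] - Ti) / tau)
           p[e] <- 0; V[e] <- Ve; Q[e] <- -Ve / tau
         }
         list(p = p, V = V, Q = Q)
       })
}

#' Simulate pressure-limited bias-flow ventilation
#'
#' Solves the two-node circuit-lung model breath by breath: the bias flow
#' charges the circuit compliance, an ideal relief valve holds circuit
#' pressure at the set inflation pressure (inspiration) or set PEEP
#' (expiration), and the lung fills through its resistance.  Each valve
#' regime is piecewise linear and is integrated in closed form; the valve
#' clamp time within each breath is located to 1e-12 s.  Airway-opening
#' pressure equals circuit pressure, flow is the flow into the lung
#' (positive inspiratory), and volume is lung volume above the
#' end-expiratory level.
#'
#' @param settings A [vent_settings()] object.
#' @param lung A [lung_params()] object.  A surfactant compliance step is
#'   applied at the first breath boundary at or after
#'   `lung$surfactant_time`.
#' @param duration Recording length, s.  Must cover at least one breath.
#' @param sample_rate Output sampling rate, Hz (>= 100, and at least 20
#'   samples per inspiration).
#' @param noise Optional named numeric vector of additive Gaussian sensor
#'   noise SDs, e.g. `c(pressure = 0.1, flow = 0.05, volume = 0.15)` in
#'   cmH2O, L/min and mL.  Default none.
#' @param seed Seed for the noise generator; required when `noise` is
#'   non-zero.
#' @param subject_id,group_label Metadata carried on the recording.
#'
#' @return A `vent_recording`: list with uniform `time` (s), `pressure`
#'   (cmH2O), `flow` (L/min), `volume` (mL), `sample_rate`, metadata, and a
#'   `truth` data frame of per-breath ground truth (onset time, time to
#'   reach set PIP, tidal volume, peak inspiratory flow, compliance in
#'   effect).
#' @export
#' @examples
#' rec <- simulate_ventilation(vent_settings(bias_flow = 8), lung_params(),
#'                             duration = 5)
#' head(rec$truth)
simulate_ventilation <- function(settings, lung, duration, sample_rate = 200,
                                 noise = NULL, seed = NULL,
                                 subject_id = "S1", group_label = NA_character_) {
  .assert(inherits(settings, "vent_settings"), "'settings' must be a vent_settings object")
  .assert(inherits(lung, "lung_params"), "'lung' must be a lung_params object")
  .assert(.finite_pos(duration), "'duration' must be positive (s)")
  Tb <- 60 / settings$rate
  .assert(duration >= Tb, "'duration' must cover at least one breath (60/rate)")
  .assert(.finite_pos(sample_rate) && sample_rate >= 100,
          "'sample_rate' must be >= 100 Hz")
  .assert(settings$Ti * sample_rate >= 20,
          "'sample_rate' too low to resolve Ti (< 20 samples per inspiration)")

  f_mls <- settings$bias_flow * 1000 / 60
  dPset <- settings$set_PIP - settings$set_PEEP
  Cc <- settings$circuit_compliance
  R <- lung$R_aw

  n <- floor(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  n_breath <- ceiling(duration / Tb)

  pressure <- flow <- volume <- numeric(n)
  truth <- data.frame(breath = seq_len(n_breath), t_onset = (seq_len(n_breath) - 1) * Tb,
                      t_to_pip = NA_real_, V_T = NA_real_, flow_peak = NA_real_,
                      C_rs = NA_real_)
  V0 <- 0
  Cr <- lung$C_rs
  for (k in seq_len(n_breath)) {
    t0 <- (k - 1) * Tb
    if (!is.null(lung$surfactant_time) && t0 >= lung$surfactant_time)
      Cr <- lung$C_rs * lung$surfactant_factor
    sol <- .breath_solution(f_mls, dPset, settings$Ti, Tb, Cc, Cr, R, V0)
    idx <- which(t >= t0 & t < t0 + Tb)
    if (length(idx)) {
      ev <- sol$eval(t[idx] - t0)
      pressure[idx] <- ev$p + settings$set_PEEP
      volume[idx] <- ev$V
      flow[idx] <- ev$Q * 60 / 1000
    }
    truth$t_to_pip[k] <- if (is.finite(sol$t_clamp)) sol$t_clamp else NA_real_
    truth$V_T[k] <- sol$V_Ti - V0
    truth$flow_peak[k] <- sol$Q_peak * 60 / 1000
    truth$C_rs[k] <- Cr
    V0 <- sol$V_end
  }

  if (!is.null(noise)) {
    .assert(is.numeric(noise) && !is.null(names(noise)) &&
              all(names(noise) %in% c("pressure", "flow", "volume")) &&
              all(noise >= 0),
            "'noise' must be a named vector of non-negative SDs (pressure/flow/volume)")
    if (any(noise > 0)) {
      .assert(!is.null(seed), "'seed' is required when sensor noise is requested")
      sds <- c(pressure = 0, flow = 0, volume = 0)
      sds[names(noise)] <- noise
      .with_seed(seed, {
        if (sds[["pressure"]] > 0) pressure <- pressure + rnorm(n, 0, sds[["pressure"]])
        if (sds[["flow"]] > 0) flow <- flow + rnorm(n, 0, sds[["flow"]])
        if (sds[["volume"]] > 0) volume <- volume + rnorm(n, 0, sds[["volume"]])
      })
    }
  }
  rec <- structure(list(time = t, pressure = pressure, flow = flow,
                        volume = volume, sample_rate = sample_rate,
                        subject_id = subject_id, weight = lung$weight,
                        group_label = group_label, settings = settings,
                        lung = lung, truth = truth),
                   class = "vent_recording")
  rec
}

#' @export
print.vent_recording <- function(x, ...) {
  cat(sprintf("Ventilator waveform recording '%s'%s\n", x$subject_id,
              if (!is.na(x$group_label)) paste0(" [", x$group_label, "]") else ""))
  cat(sprintf("  %.3g s at %g Hz (%d samples), weight %.3g kg\n",
              length(x$time) / x$sample_rate, x$sample_rate, length(x$time), x$weight))
  cat(sprintf("  pressure %.3g-%.3g cmH2O | peak flow %.3g L/min | V_T ~%.3g mL\n",
              min(x$pressure), max(x$pressure), max(x$flow),
              if (!is.null(x$truth)) median(x$truth$V_T) else max(x$volume)))
  invisible(x)
}

#' @export
as.data.frame.vent_recording <- function(x, ...) {
  data.frame(time_s = x$time, paw_cmH2O = x$pressure, flow_lpm = x$flow,
             vol_ml = x$volume)
}

#' @export
plot.vent_recording <- function(x, xlim = NULL, ...) {
  op <- par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1), mgp = c(2.2, 0.7, 0))
  on.exit(par(op))
  if (is.null(xlim)) xlim <- range(x$time)
  plot(x$time, x$pressure, type = "l", xlab = "", ylab = "Paw (cmH2O)", xlim = xlim, ...)
  plot(x$time, x$flow, type = "l", xlab = "", ylab = "Flow (L/min)", xlim = xlim, ...)
  abline(h = 0, lty = 3)
  plot(x$time, x$volume, type = "l", xlab = "time (s)", ylab = "Volume (mL)", xlim = xlim, ...)
  invisible(x)
}

#' Brute-force explicit-Euler reference integrator
#'
#' Steps the raw circuit-lung ODE with an explicit Euler scheme at a very
#' small time step (default 10 microseconds), applying the relief-valve
#' clamp after every step.  This is deliberately independent of the
#' closed-form solver in [simulate_ventilation()] and exists to validate
#' it; it is far too slow for routine use.
#'
#' @inheritParams simulate_ventilation
#' @param n_breaths Number of consecutive breaths to integrate.
#' @param dt Euler step, s.
#' @return Data frame with one row per breath: `t_to_pip` (s, time at which
#'   airway pressure first reaches set PIP, `NA` if never), `V_T` (mL),
#'   `flow_peak` (L/min) and `V_end` (mL, volume at end of breath).
#' @export
simulate_ventilation_euler <- function(settings, lung, n_breaths = 1, dt = 1e-5) {
  .assert(inherits(settings, "vent_settings"), "'settings' must be a vent_settings object")
  .assert(inherits(lung, "lung_params"), "'lung' must be a lung_params object")
  f <- settings$bias_flow * 1000 / 60
  PIP <- settings$set_PIP; PEEP <- settings$set_PEEP
  Ti <- settings$Ti; Tb <- 60 / settings$rate
  Cc <- settings$circuit_compliance; Cr <- lung$C_rs; R <- lung$R_aw
  out <- data.frame(breath = seq_len(n_breaths), t_to_pip = NA_real_,
                    V_T = NA_real_, flow_peak = NA_real_, V_end = NA_real_)
  V <- 0
  nstep <- round(Tb / dt)
  for (k in seq_len(n_breaths)) {
    P <- PEEP
    V0 <- V
    tpip <- NA_real_; qmax <- 0; vti <- NA_real_
    tt <- 0
    for (i in seq_len(nstep)) {
      Pset <- if (tt < Ti) PIP else PEEP
      Q <- (P - PEEP - V / Cr) / R
      V <- V + dt * Q
      P <- P + dt * (f - Q) / Cc
      if (P > Pset) P <- Pset
      tt <- tt + dt
      if (tt <= Ti) {
        if (is.na(tpip) && P >= PIP - 1e-9) tpip <- tt
        if (Q > qmax) qmax <- Q
      } else if (is.na(vti)) vti <- V
    }
    out$t_to_pip[k] <- tpip
    out$V_T[k] <- vti - V0
    out$flow_peak[k] <- qmax * 60 / 1000
    out$V_end[k] <- V
  }
  out
}
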