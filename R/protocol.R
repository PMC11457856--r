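#' Arterial CO2 state
#'
#' Minimal gas-exchange state used by the closed-loop protocol controller.
#' The model emulates, rather than estimates, physiology: PaCO2 relaxes
#' first-order toward an equilibrium inversely proportional to alveolar
#' minute ventilation.
#'
#' @param PaCO2 Arterial CO2 tension, mmHg.
#' @param alveolar_minute_ventilation Alveolar minute ventilation, mL/min.
#' @return An object of class `gas_state`.
#' @export
gas_state <- function(PaCO2 = 70, alveolar_minute_ventilation = 0) {
  .assert(.finite_pos(PaCO2), "'PaCO2' must be positive (mmHg)")
  .assert(.finite_nonneg(alveolar_minute_ventilation),
          "'alveolar_minute_ventilation' must be >= 0 (mL/min)")
  structure(list(PaCO2 = PaCO2,
                 alveolar_minute_ventilation = alveolar_minute_ventilation),
            class = "gas_state")
}

#' @export
print.gas_state <- function(x, ...) {
  cat(sprintf("PaCO2 %.1f mmHg (V_A %.0f mL/min)\n",
              x$PaCO2, x$alveolar_minute_ventilation))
  invisible(x)
}

#' First-order CO2 kinetics update
#'
#' Alveolar minute ventilation is `rate * max(V_T - dead_space, 0)`; PaCO2
#' relaxes exponentially toward the equilibrium `k_CO2 / V_A` with time
#' constant `tau`.  When `V_A` is zero (apnoea or all-dead-space breaths)
#' PaCO2 relaxes toward a configured apnoeic ceiling instead, so the update
#' saturates rather than diverging.
#'
#' @param state A [gas_state()].
#' @param V_T Tidal volume, mL.
#' @param rate Respiratory rate, breaths/min.
#' @param dead_space Series dead space, mL.
#' @param dt Time elapsed, s.
#' @param k_CO2 CO2 production/transport constant, mmHg.mL/min: the
#'   equilibrium PaCO2 at alveolar minute ventilation `V_A` is `k_CO2/V_A`.
#'   Default 36000 gives ~50 mmHg at the simulator's default ventilation
#'   (60/min x 12 mL alveolar).
#' @param tau Relaxation time constant, s.
#' @param apnoeic_ceiling Equilibrium PaCO2 when `V_A = 0`, mmHg.
#' @return Updated [gas_state()].
#' @export
#' @examples
#' s <- gas_state(PaCO2 = 70)
#' update_gas_state(s, V_T = 17.5, rate = 60, dead_space = 5.5, dt = 300)
update_gas_state <- function(state, V_T, rate, dead_space, dt,
                             k_CO2 = 36000, tau = 60, apnoeic_ceiling = 130) {
  .assert(inherits(state, "gas_state"), "'state' must be a gas_state object")
  .assert(.finite_pos(dt), "'dt' must be positive (s)")
  V_A <- rate * max(V_T - dead_space, 0)
  eq <- if (V_A > 0) k_CO2 / V_A else apnoeic_ceiling
  eq <- min(eq, apnoeic_ceiling)
  gas_state(PaCO2 = eq + (state$PaCO2 - eq) * exp(-dt / tau),
            alveolar_minute_ventilation = V_A)
}

#' Inspiratory-time titration rule
#'
#' Applies the bedside rule used with continuous-flow pressure-limited
#' ventilation: if the terminal span of inspiration with essentially zero
#' flow exceeds a fraction (default 20%, strict inequality) of the
#' inspiratory time, the inspiratory time is shortened to the moment flow
#' fell to zero plus a small margin; otherwise it is unchanged.
#'
#' @param recording A `vent_recording`.
#' @param segments Breath segmentation from [segment_breaths()]; computed
#'   if `NULL`.
#' @param threshold_fraction Zero-flow fraction of Ti that triggers
#'   shortening (strict `>`).
#' @param flow_tolerance Absolute flow below which flow counts as zero,
#'   L/min.
#' @param margin Safety margin added to the shortened Ti, s.
#' @return Data frame per breath: measured `Ti`, terminal
#'   `zero_flow_fraction`, recommended `Ti_new` and whether it was
#'   `shortened`.
#' @export
titrate_Ti <- function(recording, segments = NULL, threshold_fraction = 0.20,
                       flow_tolerance = 0.1, margin = 0.02) {
  if (is.null(segments)) segments <- segment_breaths(recording, flow_tolerance = flow_tolerance)
  .assert(nrow(segments) > 0, "no breaths to titrate")
  sr <- recording$sample_rate
  out <- data.frame(breath = segments$breath, Ti = NA_real_,
                    zero_flow_fraction = NA_real_, Ti_new = NA_real_,
                    shortened = FALSE)
  for (j in seq_len(nrow(segments))) {
    i0 <- segments$i_onset[j]; i1 <- segments$i_insp_end[j]
    .assert(i1 > i0, "breath without an inspiratory phase")
    Ti <- (i1 - i0) / sr
    insp <- recording$flow[i0:(i1 - 1)]
    zero <- abs(insp) < flow_tolerance
    # terminal contiguous zero-flow run
    run <- 0L
    for (i in rev(seq_along(zero))) { if (!zero[i]) break; run <- run + 1L }
    frac <- (run / sr) / Ti
    out$Ti[j] <- Ti
    out$zero_flow_fraction[j] <- frac
    if (frac > threshold_fraction) {
      t_fall <- (length(zero) - run) / sr # time from onset at which flow fell to zero
      out$Ti_new[j] <- t_fall + margin
      out$shortened[j] <- TRUE
    } else out$Ti_new[j] <- Ti
  }
  out
}

#' Closed-loop protocol configuration
#'
#' Targets and cadence for [run_protocol()]: tidal volume target in mL/kg
#' (pressure control), a PaCO2 band (rate control), and the adjustment
#' interval emulating intermittent blood-gas sampling.
#'
#' @param target_VT Target tidal volume, mL/kg.
#' @param VT_deadband Tolerated deviation from target before the controller
#'   acts, mL/kg.
#' @param PaCO2_band Two-element acceptable PaCO2 range, mmHg.
#' @param interval Adjustment interval, s.
#' @param duration Total run length, s.
#' @param initial_PaCO2 PaCO2 at ventilation onset, mmHg (fetal-transition
#'   values are high).
#' @param rate_min,rate_max Limits on the rate controller, breaths/min.
#' @param k_CO2,tau,apnoeic_ceiling CO2 kinetics constants; see
#'   [update_gas_state()].
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(target_VT = 7, VT_deadband = 0.25,
                            PaCO2_band = c(45, 55), interval = 30,
                            duration = 300, initial_PaCO2 = 70,
                            rate_min = 20, rate_max = 120,
                            k_CO2 = 36000, tau = 60, apnoeic_ceiling = 130) {
  .assert(.finite_pos(target_VT), "'target_VT' must be positive (mL/kg)")
  .assert(length(PaCO2_band) == 2 && PaCO2_band[1] < PaCO2_band[2],
          "'PaCO2_band' must be an increasing pair (mmHg)")
  .assert(.finite_pos(interval) && .finite_pos(duration) && interval <= duration,
          "'interval' and 'duration' must be positive with interval <= duration")
  structure(list(target_VT = target_VT, VT_deadband = VT_deadband,
                 PaCO2_band = PaCO2_band, interval = interval,
                 duration = duration, initial_PaCO2 = initial_PaCO2,
                 rate_min = rate_min, rate_max = rate_max,
                 k_CO2 = k_CO2, tau = tau, apnoeic_ceiling = apnoeic_ceiling),
            class = "protocol_config")
}

#' Run a closed-loop ventilation protocol
#'
#' Emulates the study protocol: every adjustment interval, PIP is stepped
#' +/- 1 cmH2O toward the tidal-volume target (never above `PIP_max`, never
#' below `PEEP + 2`) and rate is stepped +/- 5/min toward the PaCO2 band,
#' with Ti fixed.  A surfactant compliance step in `lung` takes effect at
#' its set time.  Unreachable targets are flagged in the event log, never
#' raised as errors.
#'
#' @param settings Initial [vent_settings()].
#' @param lung [lung_params()] (with optional `surfactant_time`).
#' @param protocol A [protocol_config()].
#' @param sample_rate Waveform sampling rate, Hz.
#' @param noise,seed Sensor noise passed to [simulate_ventilation()].
#' @return A list of class `protocol_run`: `recording` (the concatenated
#'   waveforms), `events` (time-stamped adjustment log), `gas` (PaCO2
#'   trace), and `settings_trace` (PIP/rate per interval).
#' @export
run_protocol <- function(settings, lung, protocol = protocol_config(),
                         sample_rate = 200, noise = NULL, seed = NULL) {
  .assert(inherits(protocol, "protocol_config"), "'protocol' must be a protocol_config")
  n_epoch <- ceiling(protocol$duration / protocol$interval)
  PIP <- settings$set_PIP
  rate <- settings$rate
  gas <- gas_state(PaCO2 = protocol$initial_PaCO2)
  events <- data.frame(time_s = numeric(0), parameter = character(0),
                       from = numeric(0), to = numeric(0), note = character(0))
  log_event <- function(t, par, from, to, note = "") {
    events[nrow(events) + 1L, ] <<- list(t, par, from, to, note)
  }
  trace <- data.frame(epoch = seq_len(n_epoch), t_start = NA_real_, PIP = NA_real_,
                      rate = NA_real_, VT_mlkg = NA_real_, PaCO2 = NA_real_)
  recs <- vector("list", n_epoch)
  surf_applied <- FALSE
  base_Crs <- lung$C_rs

  for (e in seq_len(n_epoch)) {
    t0 <- (e - 1) * protocol$interval
    len <- min(protocol$interval, protocol$duration - t0)
    if (!is.null(lung$surfactant_time) && !surf_applied && t0 >= lung$surfactant_time) {
      surf_applied <- TRUE
      log_event(t0, "C_rs", base_Crs, base_Crs * lung$surfactant_factor, "surfactant")
    }
    lung_e <- lung_params(C_rs = base_Crs * if (surf_applied) lung$surfactant_factor else 1,
                          R_aw = lung$R_aw, weight = lung$weight,
                          dead_space = lung$dead_space)
    set_e <- vent_settings(bias_flow = settings$bias_flow, set_PIP = PIP,
                           set_PEEP = settings$set_PEEP, Ti = settings$Ti,
                           rate = rate, PIP_max = settings$PIP_max,
                           circuit_compliance = settings$circuit_compliance)
    rec <- simulate_ventilation(set_e, lung_e, duration = len,
                                sample_rate = sample_rate, noise = noise,
                                seed = if (is.null(seed)) NULL else seed + e)
    rec$time <- rec$time + t0
    recs[[e]] <- rec

    vt_mlkg <- mean(rec$truth$V_T) / lung$weight
    gas <- update_gas_state(gas, V_T = mean(rec$truth$V_T), rate = rate,
                            dead_space = lung$dead_space, dt = len,
                            k_CO2 = protocol$k_CO2, tau = protocol$tau,
                            apnoeic_ceiling = protocol$apnoeic_ceiling)
    trace[e, ] <- list(e, t0, PIP, rate, vt_mlkg, gas$PaCO2)

    if (e == n_epoch) break
    t_adj <- t0 + len
    err <- protocol$target_VT - vt_mlkg
    if (abs(err) > protocol$VT_deadband) {
      new_PIP <- PIP + sign(err)
      new_PIP <- min(max(new_PIP, settings$set_PEEP + 2), settings$PIP_max)
      if (new_PIP != PIP) {
        log_event(t_adj, "PIP", PIP, new_PIP,
                  sprintf("V_T %.2f mL/kg vs target %.2f", vt_mlkg, protocol$target_VT))
        PIP <- new_PIP
      } else {
        log_event(t_adj, "PIP", PIP, PIP,
                  sprintf("target V_T unreachable at limit (V_T %.2f mL/kg)", vt_mlkg))
      }
    }
    if (gas$PaCO2 > protocol$PaCO2_band[2]) {
      new_rate <- min(rate + 5, protocol$rate_max)
      if (new_rate != rate) {
        log_event(t_adj, "rate", rate, new_rate, sprintf("PaCO2 %.1f above band", gas$PaCO2))
        rate <- new_rate
      } else log_event(t_adj, "rate", rate, rate, "PaCO2 above band at rate_max")
    } else if (gas$PaCO2 < protocol$PaCO2_band[1]) {
      new_rate <- max(rate - 5, protocol$rate_min)
      if (new_rate != rate) {
        log_event(t_adj, "rate", rate, new_rate, sprintf("PaCO2 %.1f below band", gas$PaCO2))
        rate <- new_rate
      } else log_event(t_adj, "rate", rate, rate, "PaCO2 below band at rate_min")
    }
  }

  recording <- recs[[1]]
  recording$time <- do.call(c, lapply(recs, `[[`, "time"))
  recording$pressure <- do.call(c, lapply(recs, `[[`, "pressure"))
  recording$flow <- do.call(c, lapply(recs, `[[`, "flow"))
  recording$volume <- do.call(c, lapply(recs, `[[`, "volume"))
  recording$truth <- NULL # per-epoch truths are in $epochs
  structure(list(recording = recording, events = events, gas = trace[, c("t_start", "PaCO2")],
                 settings_trace = trace, epochs = recs),
            class = "protocol_run")
}

#' @export
print.protocol_run <- function(x, ...) {
  cat(sprintf("Closed-loop protocol run: %d intervals, %d adjustments logged\n",
              nrow(x$settings_trace), nrow(x$events)))
  cat(sprintf("  final PIP %.3g cmH2O, rate %.3g /min, PaCO2 %.1f mmHg\n",
              tail(x$settings_trace$PIP, 1), tail(x$settings_trace$rate, 1),
              tail(x$settings_trace$PaCO2, 1)))
  invisible(x)
}
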