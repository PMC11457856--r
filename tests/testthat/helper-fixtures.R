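# Shared fixtures: hand-built recordings/segments and a cached default
# simulated recording so slow simulations run once per test session.

manual_recording <- function(time, pressure = NULL, flow = NULL, volume = NULL,
                             sample_rate = NULL, weight = 1,
                             subject_id = "fix") {
  n <- length(time)
  if (is.null(sample_rate)) sample_rate <- 1 / median(diff(time))
  zero <- rep(0, n)
  structure(list(time = time,
                 pressure = if (is.null(pressure)) zero else pressure,
                 flow = if (is.null(flow)) zero else flow,
                 volume = if (is.null(volume)) zero else volume,
                 sample_rate = sample_rate, subject_id = subject_id,
                 weight = weight, group_label = NA_character_,
                 settings = NULL, lung = NULL, truth = NULL),
            class = "vent_recording")
}

manual_segments <- function(i_onset, i_insp_end, i_exp_end, recording) {
  structure(data.frame(breath = seq_along(i_onset), i_onset = i_onset,
                       i_insp_end = i_insp_end, i_exp_end = i_exp_end,
                       t_onset = recording$time[i_onset],
                       t_insp_end = recording$time[i_insp_end],
                       t_exp_end = recording$time[i_exp_end]),
            class = c("breath_segments", "data.frame"),
            sample_rate = recording$sample_rate)
}

.fixture_env <- new.env(parent = emptyenv())

default_recording <- function() {
  if (is.null(.fixture_env$rec)) {
    .fixture_env$rec <- simulate_ventilation(vent_settings(bias_flow = 8),
                                             lung_params(), duration = 10)
    .fixture_env$segs <- segment_breaths(.fixture_env$rec)
  }
  .fixture_env$rec
}

default_segments <- function() {
  default_recording()
  .fixture_env$segs
}

# n matched lungs simulated at each bias flow; returns per-group mean motion
# metrics (used by the group-contrast properties)
matched_flow_groups <- function(flows = c(4, 6, 8), n = 10, duration = 30,
                                noise = c(pressure = 0.1, flow = 0.05, volume = 0.15),
                                seed = 42) {
  pars <- withr::with_seed(seed, list(
    C_rs = rlnorm(n, log(1.25), sqrt(log(1 + 0.2^2))),
    R_aw = rlnorm(n, log(0.025), sqrt(log(1 + 0.2^2))),
    weight = rlnorm(n, log(2.5), sqrt(log(1 + 0.1^2)))))
  out <- list()
  for (F in flows) {
    m <- sapply(seq_len(n), function(i) {
      st <- vent_settings(bias_flow = F,
                          set_PIP = 8 + 7 * pars$weight[i] / pars$C_rs[i])
      lu <- lung_params(C_rs = pars$C_rs[i], R_aw = pars$R_aw[i],
                        weight = pars$weight[i])
      rec <- simulate_ventilation(st, lu, duration, noise = noise,
                                  seed = seed * 1000 + i)
      segs <- segment_breaths(rec)
      mm <- motion_metrics(rec, segs)
      mech <- breath_mechanics(rec, segs)
      ins <- mm$phase == "insp"; exs <- mm$phase == "exp"
      ch <- mm$channel
      c(T_peak_pressure = mean(mm$T_peak_s[ins & ch == "pressure"]),
        T_peak_volume = mean(mm$T_peak_s[ins & ch == "volume"]),
        slope_max_pressure = mean(mm$slope_max[ins & ch == "pressure"]),
        slope_max_volume = mean(mm$slope_max[ins & ch == "volume"]),
        slope_max_flow = mean(mm$slope_max[ins & ch == "flow"]),
        exp_slope_max_pressure = mean(mm$slope_max[exs & ch == "pressure"]),
        exp_slope_max_volume = mean(mm$slope_max[exs & ch == "volume"]),
        exp_slope_max_flow = mean(mm$slope_max[exs & ch == "flow"]),
        Flow_peak = mean(mech$Flow_peak), n_breaths = sum(ins & ch == "pressure"))
    })
    out[[paste0("F", F)]] <- rowMeans(m)
  }
  do.call(cbind, out)
}
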