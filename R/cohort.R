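#' Cohort simulation scenario
#'
#' Describes a simulated study: bias-flow groups, inter-subject log-normal
#' variability of lung mechanics and weight, common ventilator settings,
#' sensor noise and the tidal-volume target.  When `match_VT` is `TRUE`
#' each subject's set PIP is chosen (capped at `PIP_max`) so the plateau
#' tidal volume hits `target_VT` mL/kg, emulating the pressure titration of
#' a volume-targeted protocol and producing flow groups matched for V_T and
#' driving pressure.
#'
#' @param groups Named numeric vector of bias flows, L/min (defaults to the
#'   4 / 6 / 8 L/min study arms).
#' @param n_per_group Subjects per group.
#' @param duration,sample_rate Recording length (s) and sampling rate (Hz).
#' @param C_rs,R_aw,weight Lists `list(median =, cv =)` giving the
#'   log-normal median and coefficient of variation of each parameter
#'   (units as in [lung_params()]).
#' @param settings_base [vent_settings()] template; the per-subject bias
#'   flow (and PIP when `match_VT`) override it.
#' @param target_VT Tidal-volume target, mL/kg.
#' @param match_VT Titrate PIP per subject to the target (default TRUE).
#' @param noise Sensor noise SDs (see [simulate_ventilation()]); the
#'   defaults are ~1% of typical full-scale signals.
#' @param eit_map Parameters of the shared ground-truth regional map:
#'   `list(vd_skew =, right_share =)`.
#' @return List of class `cohort_scenario`.
#' @export
cohort_scenario <- function(groups = c(F4 = 4, F6 = 6, F8 = 8),
                            n_per_group = 10, duration = 30, sample_rate = 200,
                            C_rs = list(median = 1.25, cv = 0.2),
                            R_aw = list(median = 0.025, cv = 0.2),
                            weight = list(median = 2.5, cv = 0.1),
                            settings_base = vent_settings(bias_flow = 8),
                            target_VT = 7, match_VT = TRUE,
                            noise = c(pressure = 0.1, flow = 0.05, volume = 0.15),
                            eit_map = list(vd_skew = -0.3, right_share = 0.55)) {
  .assert(length(groups) >= 1 && !is.null(names(groups)) && all(groups >= 0),
          "'groups' must be a named vector of bias flows (L/min)")
  .assert(n_per_group >= 2, "'n_per_group' must be at least 2")
  for (p in list(C_rs, R_aw, weight))
    .assert(is.list(p) && .finite_pos(p$median) && .finite_nonneg(p$cv),
            "parameter distributions need positive 'median' and non-negative 'cv'")
  structure(list(groups = groups, n_per_group = n_per_group, duration = duration,
                 sample_rate = sample_rate, C_rs = C_rs, R_aw = R_aw,
                 weight = weight, settings_base = settings_base,
                 target_VT = target_VT, match_VT = match_VT, noise = noise,
                 eit_map = eit_map),
            class = "cohort_scenario")
}

.rlnorm_med_cv <- function(n, median, cv) {
  if (cv <= 0) return(rep(median, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

#' Simulate a labelled cohort with ground truth
#'
#' Draws per-subject lung parameters from the scenario's log-normal
#' distributions, titrates PIP to the tidal-volume target when requested,
#' simulates every subject's recording and returns the recordings together
#' with the ground-truth parameter table for recovery tests.  Fully
#' reproducible: the same seed gives a bit-identical cohort.
#'
#' @param scenario A [cohort_scenario()].
#' @param seed Integer seed (mandatory).
#' @param n_per_group Override of the scenario's group size.
#' @return Object of class `vent_cohort`: `recordings` (list, one
#'   `vent_recording` per subject), `truth` (data frame of subject, group,
#'   bias flow, drawn parameters and set PIP), `scenario`, `seed`.
#' @export
#' @examples
#' co <- make_cohort(cohort_scenario(n_per_group = 2, duration = 5), seed = 1)
#' co$truth
make_cohort <- function(scenario = cohort_scenario(), seed,
                        n_per_group = scenario$n_per_group) {
  .assert(inherits(scenario, "cohort_scenario"), "'scenario' must be a cohort_scenario")
  .assert(!missing(seed), "'seed' is mandatory for cohort generation")
  .assert(n_per_group >= 2, "'n_per_group' must be at least 2")
  ng <- length(scenario$groups)
  n <- ng * n_per_group
  draws <- .with_seed(seed, {
    list(C_rs = .rlnorm_med_cv(n, scenario$C_rs$median, scenario$C_rs$cv),
         R_aw = .rlnorm_med_cv(n, scenario$R_aw$median, scenario$R_aw$cv),
         weight = .rlnorm_med_cv(n, scenario$weight$median, scenario$weight$cv),
         sub_seed = sample.int(.Machine$integer.max - 1L, n))
  })
  base <- scenario$settings_base
  truth <- data.frame(subject_id = sprintf("%s_%02d", rep(names(scenario$groups),
                                                          each = n_per_group),
                                           rep(seq_len(n_per_group), ng)),
                      group = rep(names(scenario$groups), each = n_per_group),
                      bias_flow = rep(unname(scenario$groups), each = n_per_group),
                      C_rs = draws$C_rs, R_aw = draws$R_aw, weight = draws$weight,
                      set_PIP = NA_real_, sub_seed = draws$sub_seed)
  recordings <- vector("list", n)
  names(recordings) <- truth$subject_id
  for (i in seq_len(n)) {
    PIP <- if (isTRUE(scenario$match_VT))
      min(base$set_PEEP + scenario$target_VT * truth$weight[i] / truth$C_rs[i],
          base$PIP_max)
    else base$set_PIP
    truth$set_PIP[i] <- PIP
    st <- vent_settings(bias_flow = truth$bias_flow[i], set_PIP = PIP,
                        set_PEEP = base$set_PEEP, Ti = base$Ti, rate = base$rate,
                        PIP_max = base$PIP_max,
                        circuit_compliance = base$circuit_compliance)
    lg <- lung_params(C_rs = truth$C_rs[i], R_aw = truth$R_aw[i],
                      weight = truth$weight[i])
    recordings[[i]] <- simulate_ventilation(st, lg, duration = scenario$duration,
                                            sample_rate = scenario$sample_rate,
                                            noise = scenario$noise,
                                            seed = truth$sub_seed[i],
                                            subject_id = truth$subject_id[i],
                                            group_label = truth$group[i])
  }
  structure(list(recordings = recordings, truth = truth, scenario = scenario,
                 seed = seed),
            class = "vent_cohort")
}

#' @export
print.vent_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d subjects in %d group(s) [%s], %.3g s each\n",
              nrow(x$truth), length(x$scenario$groups),
              paste(names(x$scenario$groups), collapse = ", "),
              x$scenario$duration))
  invisible(x)
}
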