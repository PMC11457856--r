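#' Build the long-format cohort metric table
#'
#' Runs the per-subject analysis chain (segmentation, motion metrics,
#' mechanics, energetics, CO2 equilibrium, VEI) on every recording of a
#' cohort and stacks the per-epoch means into the long table consumed by
#' the statistics layer.  The recording is split into `n_epochs` equal
#' time bins standing in for the study's repeated measurement timepoints.
#'
#' @param cohort A [make_cohort()] result.
#' @param n_epochs Number of equal-duration epochs per subject.
#' @param k_CO2,tau CO2 kinetics constants used for the equilibrium PaCO2
#'   attributed to each subject (see [update_gas_state()]).
#' @param smoothing_window Savitzky-Golay window for slope metrics.
#' @return Data frame `subject_id`, `group`, `time_s`, `metric`, `value`
#'   with metrics `T_peak_pressure`, `T_peak_volume`, `T_peak_flow`,
#'   `slope_max_pressure`, `slope_max_volume`, `slope_max_flow`,
#'   `exp_slope_max_pressure/volume/flow`, `Flow_peak`, `dP`, `V_T_mlkg`,
#'   `C_dyn`, `MP_tidal`, `ME_RS`, `VEI`, `PaCO2`.
#' @export
cohort_metric_table <- function(cohort, n_epochs = 2, k_CO2 = 36000, tau = 60,
                                smoothing_window = 7) {
  .assert(inherits(cohort, "vent_cohort"), "'cohort' must be a vent_cohort")
  rows <- list()
  for (sid in names(cohort$recordings)) {
    rec <- cohort$recordings[[sid]]
    segs <- segment_breaths(rec)
    .assert(nrow(segs) >= n_epochs, "too few breaths for the requested epochs")
    mm <- motion_metrics(rec, segs, smoothing_window = smoothing_window)
    mech <- breath_mechanics(rec, segs)
    E <- energy_per_breath(rec, segs)
    dur <- segs$t_exp_end - segs$t_onset
    rate_b <- 60 / dur
    epoch_len <- max(rec$time) / n_epochs
    epoch <- pmin(floor(segs$t_onset / epoch_len), n_epochs - 1) + 1
    truth <- cohort$truth[cohort$truth$subject_id == sid, ]
    for (e in seq_len(n_epochs)) {
      b <- which(epoch == e)
      if (!length(b)) next
      rate_e <- mean(rate_b[b])
      vt_e <- mean(mech$V_T[b])
      gs <- update_gas_state(gas_state(PaCO2 = 70), V_T = vt_e, rate = rate_e,
                             dead_space = rec$lung$dead_space, dt = 1e6,
                             k_CO2 = k_CO2, tau = tau)
      mp <- mean(mp_tidal(E[b], rate_e, rec$weight))
      me <- mean(me_rs(mech$V_T[b], mech$dP[b], mech$PEEP_measured[b], rec$weight))
      vei_e <- vei(mean(mech$dP[b]), rate_e, gs$PaCO2)$VEI
      ins <- mm$phase == "insp" & mm$breath_index %in% b
      exs <- mm$phase == "exp" & mm$breath_index %in% b
      vals <- c(
        T_peak_pressure = mean(mm$T_peak_s[ins & mm$channel == "pressure"]),
        T_peak_volume = mean(mm$T_peak_s[ins & mm$channel == "volume"]),
        T_peak_flow = mean(mm$T_peak_s[ins & mm$channel == "flow"]),
        slope_max_pressure = mean(mm$slope_max[ins & mm$channel == "pressure"]),
        slope_max_volume = mean(mm$slope_max[ins & mm$channel == "volume"]),
        slope_max_flow = mean(mm$slope_max[ins & mm$channel == "flow"]),
        exp_slope_max_pressure = mean(mm$slope_max[exs & mm$channel == "pressure"]),
        exp_slope_max_volume = mean(mm$slope_max[exs & mm$channel == "volume"]),
        exp_slope_max_flow = mean(mm$slope_max[exs & mm$channel == "flow"]),
        Flow_peak = mean(mech$Flow_peak[b]),
        dP = mean(mech$dP[b]),
        V_T_mlkg = mean(mech$V_T_mlkg[b]),
        C_dyn = mean(mech$C_dyn[b]),
        MP_tidal = mp, ME_RS = me, VEI = vei_e, PaCO2 = gs$PaCO2)
      rows[[paste(sid, e)]] <- data.frame(
        subject_id = sid, group = truth$group, time_s = round((e - 0.5) * epoch_len, 6),
        metric = names(vals), value = unname(vals))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-subject EIT regional summary for a cohort
#'
#' Synthesizes an EIT frame series (48 frames/s) for each recording from
#' the scenario's ground-truth regional map, computes the tidal image over
#' all complete breaths and returns the regional summary per subject.
#'
#' @param cohort A [make_cohort()] result.
#' @param frame_rate EIT frame rate, Hz.
#' @param noise_sd Pixel noise SD (au); seeded per subject.
#' @return Data frame: one [regional_summary()] row per subject plus
#'   `subject_id`, `group`.
#' @export
cohort_eit_summary <- function(cohort, frame_rate = 48, noise_sd = 0) {
  .assert(inherits(cohort, "vent_cohort"), "'cohort' must be a vent_cohort")
  em <- cohort$scenario$eit_map
  map <- default_regional_map(vd_skew = em$vd_skew, right_share = em$right_share)
  rows <- lapply(names(cohort$recordings), function(sid) {
    rec <- cohort$recordings[[sid]]
    truth <- cohort$truth[cohort$truth$subject_id == sid, ]
    fr <- synthesize_eit(rec, map, frame_rate = frame_rate, noise_sd = noise_sd,
                         seed = if (noise_sd > 0) truth$sub_seed + 1L else NULL)
    img <- tidal_image(fr, segments = segment_breaths(rec))
    cbind(data.frame(subject_id = sid, group = truth$group), regional_summary(img))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.fmt_num <- function(x) formatC(x, format = "g", digits = 10)

#' Run the full synthetic-study pipeline
#'
#' The end-to-end analogue of the study's analysis: simulate a cohort of
#' bias-flow groups, compute per-breath motion metrics, mechanics and
#' energetics, synthesize and summarize EIT regional ventilation, run the
#' cohort statistics appropriate to the group count, and write a report
#' bundle (CSV tables, JSON metadata with config hash and seed, markdown
#' report).  Fully deterministic for a given scenario and seed.
#'
#' @param scenario A [cohort_scenario()] (or path to a scenario file).
#' @param out_dir Output directory.
#' @param seed Integer seed (mandatory).
#' @param n_epochs Timepoint bins per subject (see
#'   [cohort_metric_table()]).
#' @param eit Include the EIT regional stage.
#' @return Invisibly, a list: `table`, `eit`, `summary`, `rm` (group x time
#'   results where computable) and `paths` of all written artifacts.
#' @export
run_pipeline <- function(scenario, out_dir, seed, n_epochs = 2, eit = TRUE) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  .assert(inherits(scenario, "cohort_scenario"), "'scenario' must be a cohort_scenario")
  .assert(!missing(seed), "'seed' is mandatory")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  scen_path <- file.path(out_dir, "scenario.json")
  write_scenario(scenario, scen_path)
  cfg_hash <- unname(tools::md5sum(scen_path))
  paths$scenario <- scen_path

  cohort <- make_cohort(scenario, seed = seed)
  tab <- cohort_metric_table(cohort, n_epochs = n_epochs)
  summ <- summarize_cohort(tab)

  rm_res <- list()
  if (n_epochs >= 2) {
    for (m in c("T_peak_pressure", "V_T_mlkg", "MP_tidal"))
      rm_res[[m]] <- tryCatch(rm_group_time(tab, m), error = function(e) NULL)
    rm_res <- Filter(Negate(is.null), rm_res)
  }
  eit_tab <- if (eit) cohort_eit_summary(cohort) else NULL

  tab_out <- tab; tab_out$value <- .fmt_num(tab_out$value)
  write.csv(tab_out, file.path(out_dir, "cohort_table.csv"), row.names = FALSE, quote = FALSE)
  paths$table <- file.path(out_dir, "cohort_table.csv")
  s_out <- summ$summary
  s_out$mean <- .fmt_num(s_out$mean); s_out$sd <- .fmt_num(s_out$sd)
  write.csv(s_out, file.path(out_dir, "group_summary.csv"), row.names = FALSE, quote = FALSE)
  paths$summary <- file.path(out_dir, "group_summary.csv")
  if (!is.null(eit_tab)) {
    e_out <- eit_tab
    for (c in names(e_out)) if (is.numeric(e_out[[c]])) e_out[[c]] <- .fmt_num(e_out[[c]])
    write.csv(e_out, file.path(out_dir, "eit_regional.csv"), row.names = FALSE, quote = FALSE)
    paths$eit <- file.path(out_dir, "eit_regional.csv")
  }

  comp <- lapply(summ$comparisons, function(cr)
    list(test = cr$test, statistic = cr$statistic, df = as.list(cr$df),
         p_value = cr$p_value, estimate = cr$estimate,
         pairwise = cr$pairwise))
  rmj <- lapply(rm_res, function(cr) list(test = cr$test, terms = cr$terms,
                                          pairwise = cr$pairwise))
  jsonlite::write_json(list(comparisons = comp, group_time = rmj),
                       file.path(out_dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  paths$comparisons <- file.path(out_dir, "comparisons.json")

  meta <- list(package = "ventmotion",
               version = as.character(utils::packageVersion("ventmotion")),
               seed = seed, config_md5 = cfg_hash, n_epochs = n_epochs,
               n_subjects = nrow(cohort$truth))
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  paths$metadata <- file.path(out_dir, "metadata.json")

  rep <- c("# Synthetic bias-flow study report", "",
           sprintf("- groups: %s (n = %d/group)",
                   paste(sprintf("%s = %g L/min", names(scenario$groups),
                                 scenario$groups), collapse = ", "),
                   scenario$n_per_group),
           sprintf("- seed: %d | config md5: %s", seed, cfg_hash), "",
           "## Group means (mean +/- SD)", "")
  s <- summ$summary
  for (m in unique(s$metric)) {
    d <- s[s$metric == m, ]
    rep <- c(rep, sprintf("- %s: %s", m,
                          paste(sprintf("%s %s +/- %s", d$group, .fmt_num(d$mean),
                                        .fmt_num(d$sd)), collapse = " | ")))
  }
  rep <- c(rep, "", "## Comparisons", "")
  for (m in names(summ$comparisons))
    rep <- c(rep, sprintf("- %s: %s, p = %s", m, summ$comparisons[[m]]$test,
                          .fmt_num(summ$comparisons[[m]]$p_value)))
  if (!is.null(eit_tab)) {
    rep <- c(rep, "", "## EIT regional ventilation (group means)", "")
    for (g in unique(eit_tab$group)) {
      d <- eit_tab[eit_tab$group == g, ]
      rep <- c(rep, sprintf("- %s: CoV_VD %s%% (uniform %s%%), CoV_RL %s%%, unventilated %s%%",
                            g, .fmt_num(mean(d$CoV_VD)), .fmt_num(mean(d$uniform_CoV_VD)),
                            .fmt_num(mean(d$CoV_RL)), .fmt_num(mean(d$unventilated_pct))))
    }
  }
  writeLines(rep, file.path(out_dir, "report.md"))
  paths$report <- file.path(out_dir, "report.md")

  invisible(list(table = tab, eit = eit_tab, summary = summ, rm = rm_res,
                 cohort = cohort, paths = paths))
}
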