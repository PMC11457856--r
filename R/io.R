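#' Write / read a waveform recording as CSV
#'
#' The on-disk format is one CSV per subject with columns `time_s`,
#' `paw_cmH2O`, `flow_lpm`, `vol_ml`, plus an optional JSON sidecar
#' (`<path>.json`) carrying sample rate, subject metadata and, for
#' simulated recordings, the generating settings and lung parameters.
#' Round trips are lossless to the stated precision (15 significant
#' digits).
#'
#' @param recording A `vent_recording`.
#' @param path Output CSV path.
#' @param sidecar Write the JSON metadata sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(recording, path, sidecar = TRUE) {
  df <- as.data.frame(recording)
  df[] <- lapply(df, function(x) sprintf("%.15g", x))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- list(sample_rate = recording$sample_rate,
                 subject_id = recording$subject_id,
                 weight = recording$weight,
                 group_label = recording$group_label,
                 settings = unclass(recording$settings),
                 lung = unclass(recording$lung))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_waveform_csv
#' @param tolerance Maximum relative deviation of the sampling interval
#'   from uniformity.
#' @return For `read_waveform_csv()`, a `vent_recording`.
#' @export
read_waveform_csv <- function(path, sidecar = TRUE, tolerance = 1e-6) {
  df <- read.csv(path)
  required <- c("time_s", "paw_cmH2O", "flow_lpm", "vol_ml")
  missing_cols <- setdiff(required, names(df))
  .assert(length(missing_cols) == 0,
          sprintf("malformed waveform CSV: missing column(s) %s",
                  paste(missing_cols, collapse = ", ")))
  bad <- which(!vapply(df[required], is.numeric, logical(1)))
  .assert(length(bad) == 0,
          sprintf("non-numeric values in column(s) %s",
                  paste(required[bad], collapse = ", ")))
  dt <- diff(df$time_s)
  .assert(length(dt) > 0 && all(dt > 0), "time must be strictly increasing")
  dt0 <- median(dt)
  .assert(max(abs(dt - dt0)) <= tolerance * dt0 + 1e-12,
          sprintf("non-uniform timestamps: max gap %.6g s vs nominal %.6g s",
                  max(dt), dt0))
  meta <- list()
  sc <- paste0(path, ".json")
  if (sidecar && file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  structure(list(time = df$time_s, pressure = df$paw_cmH2O, flow = df$flow_lpm,
                 volume = df$vol_ml,
                 sample_rate = if (!is.null(meta$sample_rate)) meta$sample_rate else 1 / dt0,
                 subject_id = if (!is.null(meta$subject_id)) meta$subject_id else
                   sub("\\.csv$", "", basename(path)),
                 weight = if (!is.null(meta$weight)) meta$weight else NA_real_,
                 group_label = if (!is.null(meta$group_label)) meta$group_label else NA_character_,
                 settings = meta$settings, lung = meta$lung, truth = NULL),
            class = "vent_recording")
}

#' Write / read an EIT frame series as a CSV-per-frame directory
#'
#' Text container for frame series: `frame_000001.csv` ... hold one matrix
#' per frame (row 1 most ventral), `lung_mask.csv` the 0/1 mask, and
#' `meta.json` the frame rate and times.
#'
#' @param frames An `eit_frames` object.
#' @param dir Output directory (created if needed).
#' @return `dir` (write) or an `eit_frames` object (read).
#' @export
write_eit_frames <- function(frames, dir) {
  .assert(inherits(frames, "eit_frames"), "'frames' must be an eit_frames object")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(frames$frames)
  for (k in seq_len(d[3]))
    write.table(format(frames$frames[, , k], digits = 15, trim = TRUE),
                file.path(dir, sprintf("frame_%06d.csv", k)),
                sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  write.table(frames$lung_mask * 1L, file.path(dir, "lung_mask.csv"),
              sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(frame_rate = frames$frame_rate, time = frames$time,
                            gain = frames$gain),
                       file.path(dir, "meta.json"), digits = NA)
  invisible(dir)
}

#' @rdname write_eit_frames
#' @export
read_eit_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.csv$", full.names = TRUE))
  .assert(length(files) > 0, "no frame_*.csv files found")
  mats <- lapply(files, function(f) as.matrix(read.csv(f, header = FALSE)))
  mask <- as.matrix(read.csv(file.path(dir, "lung_mask.csv"), header = FALSE)) == 1
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  frames <- array(unlist(mats), dim = c(nrow(mats[[1]]), ncol(mats[[1]]), length(mats)))
  structure(list(frames = frames, time = meta$time, frame_rate = meta$frame_rate,
                 lung_mask = unname(mask), map = NULL, gain = meta$gain),
            class = "eit_frames")
}

#' Read / write a cohort scenario configuration
#'
#' Scenario files are YAML (or JSON) mirrors of [cohort_scenario()]:
#' groups, distribution medians/CVs, ventilator settings, noise and
#' EIT-map parameters.  Unknown fields are rejected.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `cohort_scenario`.
#' @export
read_scenario <- function(path) {
  .assert(file.exists(path), sprintf("scenario file '%s' not found", path))
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("groups", "n_per_group", "duration", "sample_rate", "C_rs", "R_aw",
               "weight", "settings", "target_VT", "match_VT", "noise", "eit_map")
  extra <- setdiff(names(raw), allowed)
  .assert(length(extra) == 0,
          sprintf("unknown scenario field(s): %s", paste(extra, collapse = ", ")))
  .assert(!is.null(raw$groups) && length(raw$groups) > 0 && !is.null(names(raw$groups)),
          "scenario must define named flow groups")
  .assert(all(lengths(raw$groups) == 1) && all(unlist(raw$groups) >= 0),
          "every scenario group needs a single non-negative bias flow")
  args <- list(groups = unlist(raw$groups))
  for (f in c("n_per_group", "duration", "sample_rate", "target_VT", "match_VT"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  for (f in c("C_rs", "R_aw", "weight")) if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  if (!is.null(raw$noise)) args$noise <- unlist(raw$noise)
  if (!is.null(raw$eit_map)) args$eit_map <- raw$eit_map
  if (!is.null(raw$settings)) args$settings_base <- do.call(vent_settings, raw$settings)
  do.call(cohort_scenario, args)
}

#' @rdname read_scenario
#' @param scenario A [cohort_scenario()].
#' @export
write_scenario <- function(scenario, path) {
  .assert(inherits(scenario, "cohort_scenario"), "'scenario' must be a cohort_scenario")
  out <- list(groups = as.list(scenario$groups),
              n_per_group = scenario$n_per_group,
              duration = scenario$duration, sample_rate = scenario$sample_rate,
              C_rs = scenario$C_rs, R_aw = scenario$R_aw, weight = scenario$weight,
              settings = unclass(scenario$settings_base),
              target_VT = scenario$target_VT, match_VT = scenario$match_VT,
              noise = as.list(scenario$noise), eit_map = scenario$eit_map)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(out, path)
  else jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
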