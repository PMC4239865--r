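# Trial persistence: one CSV of samples plus a JSON sidecar of labels.
#
# CSV dialect: header row, '.' decimal separator, UTF-8; columns `t_ms`, then
# per location `<loc>_gyro_dps`, `<loc>_angle_deg`, `<loc>_mag`.
# Sidecar (same path with .json extension):
#   {subject_id, trial_id, path_label, reference_onset_ms|null,
#    walk_start_ms, sample_rate_hz}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Write a trial to CSV + JSON sidecar
#'
#' Persists the sample matrix as CSV (one row per sample; values rounded to 6
#' decimals) and the labels as a JSON sidecar next to it. The round trip
#' through [read_trial()] reproduces every field at that precision.
#'
#' @param trial A [trial_recording].
#' @param path Output CSV path (the sidecar replaces `.csv` with `.json`).
#' @return Invisibly, the CSV path.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "trial_recording"))
  cols <- list(t_ms = round(signal_times_ms(trial$signals[[1]]), 6))
  for (loc in names(trial$signals)) {
    s <- trial$signals[[loc]]
    cols[[paste0(loc, "_gyro_dps")]] <- round(s$angular_velocity, 6)
    cols[[paste0(loc, "_angle_deg")]] <- round(s$angle, 6)
    cols[[paste0(loc, "_mag")]] <- round(s$mag_heading, 6)
  }
  utils::write.csv(as.data.frame(cols), path, row.names = FALSE)
  meta <- list(subject_id = trial$subject_id,
               trial_id = trial$trial_id,
               path_label = trial$path_label,
               reference_onset_ms = if (is.null(trial$reference_onset_ms)) NULL
                                    else round(trial$reference_onset_ms, 6),
               walk_start_ms = round(trial$walk_start_ms, 6),
               sample_rate_hz = trial$signals[[1]]$sample_rate)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Read a trial from CSV + JSON sidecar
#'
#' @param path CSV path written by [write_trial()].
#' @return A [trial_recording].
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("trial sidecar not found: ", sp)
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (f in c("subject_id", "trial_id", "path_label", "walk_start_ms", "sample_rate_hz"))
    if (is.null(meta[[f]])) stop("trial sidecar is missing field: ", f)
  if (!"t_ms" %in% names(df)) stop("trial CSV is missing column: t_ms")
  locs <- unique(sub("_(gyro_dps|angle_deg|mag)$", "",
                     grep("_(gyro_dps|angle_deg|mag)$", names(df), value = TRUE)))
  if (!length(locs)) stop("trial CSV declares no sensor locations")
  signals <- list()
  for (loc in locs) {
    for (suffix in c("_gyro_dps", "_angle_deg", "_mag")) {
      col <- paste0(loc, suffix)
      if (!col %in% names(df))
        stop("trial CSV is missing column: ", col)
    }
    signals[[loc]] <- va_signals(df[[paste0(loc, "_gyro_dps")]],
                                 df[[paste0(loc, "_angle_deg")]],
                                 df[[paste0(loc, "_mag")]],
                                 sample_rate = meta$sample_rate_hz)
  }
  ref <- meta$reference_onset_ms
  if (!is.null(ref) && (length(ref) == 0L || is.na(ref))) ref <- NULL
  trial_recording(meta$subject_id, meta$trial_id, meta$path_label, signals,
                  reference_onset_ms = ref, walk_start_ms = meta$walk_start_ms)
}

#' Write a cohort of trials and its manifest
#'
#' Writes each trial with [write_trial()] into `dir` and a manifest JSON
#' listing trial files grouped by subject.
#'
#' @param trials List of [trial_recording] objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  by_subject <- split(trials, vapply(trials, `[[`, "", "subject_id"))
  manifest <- lapply(by_subject, function(ts) {
    vapply(ts, function(tr) {
      f <- file.path(dir, paste0(tr$trial_id, ".csv"))
      write_trial(tr, f)
      basename(f)
    }, "")
  })
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = FALSE, digits = NA)
  invisible(mpath)
}

#' Read a cohort from a manifest
#'
#' @param manifest_path Path to a `manifest.json` written by [write_cohort()]
#'   (trial paths are resolved relative to the manifest's directory).
#' @return List of [trial_recording] objects, in manifest order.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  trials <- list()
  for (subject in names(manifest))
    for (f in manifest[[subject]])
      trials[[length(trials) + 1L]] <- read_trial(file.path(dir, f))
  trials
}
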