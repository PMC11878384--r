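# Plain-text formats: BIDS-dialect events TSV (onset, duration,
# trial_type), ROI time-series TSV (time + one column per ROI), nuisance
# TSV and ground-truth JSON. Readers validate schemas and report the file,
# row and column of the first offending cell.

read_tsv_checked <- function(path, numeric_cols) {
  if (!file.exists(path)) stop_invalid("path", paste("file not found:", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad) > 0)
      stop(sprintf("%s: non-numeric value '%s' in column '%s', row %d",
                   basename(path), df[[col]][bad[1]], col, bad[1]),
           call. = FALSE)
    df[[col]] <- v
  }
  df
}

#' Write / read a BIDS-dialect events table
#'
#' Columns `onset`, `duration` (seconds, origin at the first retained
#' volume) and `trial_type`.
#'
#' @param design A [stimulus_design()].
#' @param path Output TSV path.
#' @export
write_events <- function(design, path) {
  ev <- design$events
  utils::write.table(
    data.frame(onset = ev$onset, duration = ev$duration,
               trial_type = ev$condition),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @param tr,n_volumes Run geometry for the resulting design.
#' @return `read_events` returns a [stimulus_design()].
#' @export
read_events <- function(path, tr, n_volumes) {
  df <- read_tsv_checked(path, c("onset", "duration"))
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: missing columns: %s", basename(path),
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  stimulus_design(tr, n_volumes,
                  data.frame(onset = df$onset, duration = df$duration,
                             condition = df$trial_type,
                             stringsAsFactors = FALSE))
}

#' Write / read an ROI time-series table
#'
#' First column `time` in seconds, then one numeric column per ROI.
#'
#' @param ts A [roi_ts()].
#' @param path TSV path.
#' @export
write_roits <- function(ts, path) {
  df <- data.frame(time = ts$times, ts$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roits
#' @return `read_roits` returns a [roi_ts()].
#' @export
read_roits <- function(path) {
  df <- read_tsv_checked(path, NULL)
  if (names(df)[1] != "time")
    stop(sprintf("%s: first column must be 'time'", basename(path)),
         call. = FALSE)
  for (col in names(df)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0)
      stop(sprintf("%s: non-numeric value '%s' in column '%s', row %d",
                   basename(path), df[[col]][bad[1]], col, bad[1]),
           call. = FALSE)
    df[[col]] <- v
  }
  times <- df$time
  tr <- if (length(times) > 1) stats::median(diff(times)) else 1
  roi_ts(times, as.matrix(df[, -1, drop = FALSE]), tr,
         provenance = paste0("read:", basename(path)))
}

#' Write a nuisance-regressor table
#' @param nuisance Numeric matrix, time x regressor.
#' @param path TSV path.
#' @export
write_nuisance <- function(nuisance, path) {
  utils::write.table(as.data.frame(nuisance), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_nuisance
#' @export
read_nuisance <- function(path) {
  df <- read_tsv_checked(path, NULL)
  as.matrix(df)
}

#' Write a full synthetic dataset to a directory
#'
#' Emits `roits.tsv`, `events.tsv`, `nuisance.tsv` and `truth.json`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_roits(dataset$signals, file.path(dir, "roits.tsv"))
  write_events(dataset$design, file.path(dir, "events.tsv"))
  write_nuisance(dataset$nuisance, file.path(dir, "nuisance.tsv"))
  truth <- dataset$truth
  truth$response_amplitude <- as.data.frame(truth$response_amplitude)
  jsonlite::write_json(
    c(unclass(truth), list(rng_seed = dataset$rng_seed,
                           tr = dataset$design$tr,
                           n_volumes = dataset$design$n_volumes)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @return `read_dataset` returns a list mirroring a `synthetic_dataset`.
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  design <- read_events(file.path(dir, "events.tsv"), meta$tr, meta$n_volumes)
  signals <- read_roits(file.path(dir, "roits.tsv"))
  amp <- as.matrix(meta$response_amplitude)
  truth <- ground_truth(meta$roi_names, meta$subnetwork_label, amp,
                        seed_name = meta$seed_name,
                        suppression_factor = meta$suppression_factor,
                        latent_coupling = meta$latent_coupling,
                        latent_private_sd = meta$latent_private_sd,
                        interaction_strength = meta$interaction_strength,
                        ar_coefficient = meta$ar_coefficient,
                        noise_sd = meta$noise_sd,
                        drift_slope = meta$drift_slope,
                        n_motion_regressors = meta$n_motion_regressors)
  if (!is.null(meta$baseline_level)) truth$baseline_level <- meta$baseline_level
  structure(list(design = design, signals = signals,
                 nuisance = read_nuisance(file.path(dir, "nuisance.tsv")),
                 truth = truth, rng_seed = meta$rng_seed),
            class = "synthetic_dataset")
}
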