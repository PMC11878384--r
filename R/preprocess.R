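# Time-series conditioning: initial-volume discard, linear detrend +
# demean, PCA-based nuisance selection, confound regression and zero-phase
# Chebyshev Type II low-pass filtering.

#' ROI time-series container
#'
#' @param times Acquisition times, s; strictly increasing with constant
#'   step equal to `tr`.
#' @param values Numeric matrix, time x ROI, with column names.
#' @param tr Repetition time, s.
#' @param provenance Character vector of transforms applied so far.
#' @return Object of class `roi_ts`.
#' @export
roi_ts <- function(times, values, tr, provenance = character()) {
  values <- as.matrix(values)
  if (length(times) != nrow(values))
    stop_invalid("times", "length must equal nrow(values)")
  d <- diff(times)
  if (length(d) > 0 && (any(d <= 0) || any(abs(d - tr) > 1e-6)))
    stop_invalid("times", "must increase in constant steps of tr")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("roi", seq_len(ncol(values)))
  structure(list(times = as.numeric(times), values = values, tr = tr,
                 provenance = provenance), class = "roi_ts")
}

#' Discard initial volumes
#'
#' Removes the first `n_discard` volumes (the pre-steady-state scans) and
#' re-anchors time at the first retained volume; the shift is recorded in
#' the provenance so stimulus onsets can be moved consistently.
#'
#' @param ts A [roi_ts()].
#' @param n_discard Number of leading volumes to drop.
#' @return A `roi_ts`.
#' @export
discard_initial <- function(ts, n_discard = 5) {
  stopifnot(inherits(ts, "roi_ts"))
  check_scalar(n_discard, "n_discard", lower = 0)
  n_discard <- as.integer(n_discard)
  if (n_discard >= nrow(ts$values))
    stop_invalid("n_discard", "must be smaller than the number of volumes")
  if (n_discard == 0) return(ts)
  keep <- (n_discard + 1):nrow(ts$values)
  shift <- ts$times[n_discard + 1] - ts$times[1]
  roi_ts(ts$times[keep] - shift, ts$values[keep, , drop = FALSE], ts$tr,
         provenance = c(ts$provenance,
                        sprintf("discard_initial:%d(shift=%gs)", n_discard, shift)))
}

#' Shift stimulus onsets after discarding volumes
#'
#' @param design A [stimulus_design()].
#' @param n_discard Volumes discarded from the front of the run.
#' @return A `stimulus_design` with onsets shifted earlier by
#'   `n_discard * tr` and events that no longer fit dropped.
#' @export
shift_design <- function(design, n_discard = 5) {
  shift <- n_discard * design$tr
  ev <- design$events
  ev$onset <- ev$onset - shift
  ev <- ev[ev$onset >= 0, , drop = FALSE]
  stimulus_design(design$tr, design$n_volumes - n_discard, ev,
                  design$baseline_temperature, design$stim_temperature)
}

#' Linear detrend and demean
#'
#' Per column: subtract the ordinary-least-squares straight-line fit, then
#' the residual mean. Output columns have zero mean and zero best-fit
#' slope.
#'
#' @param ts A [roi_ts()] or a plain numeric matrix/vector.
#' @return Same type as the input.
#' @export
detrend_demean <- function(ts) {
  mat_in <- !inherits(ts, "roi_ts")
  vals <- if (mat_in) as.matrix(ts) else ts$values
  if (nrow(vals) < 3) stop_invalid("ts", "need at least 3 time points")
  t0 <- seq_len(nrow(vals))
  X <- cbind(1, t0)
  res <- vals - X %*% qr.coef(qr(X), vals)
  res <- sweep(res, 2, colMeans(res))
  if (mat_in) return(res)
  roi_ts(ts$times, res, ts$tr, provenance = c(ts$provenance, "detrend_demean"))
}

#' Leading principal components reaching a cumulative variance target
#'
#' Computes PCA on the column-demeaned signals and returns the smallest
#' leading set of component time courses whose cumulative explained
#' variance reaches `cum_var`. Used to turn white-matter/CSF voxel signals
#' into nuisance regressors.
#'
#' @param signals Numeric matrix, time x voxel.
#' @param cum_var Cumulative explained-variance target, fraction.
#' @return Matrix time x component of PC scores.
#' @export
select_nuisance_components <- function(signals, cum_var = 0.70) {
  signals <- as.matrix(signals)
  check_scalar(cum_var, "cum_var", lower = 0, upper = 1,
               allow_equal_lower = FALSE)
  if (nrow(signals) < 2 || ncol(signals) < 1)
    stop_invalid("signals", "need >= 2 time points and >= 1 column")
  centred <- sweep(signals, 2, colMeans(signals))
  if (all(abs(centred) < 1e-12))
    stop_invalid("signals", "all columns are constant")
  sv <- svd(centred)
  var_exp <- sv$d^2 / sum(sv$d^2)
  k <- which(cumsum(var_exp) >= cum_var - 1e-12)[1]
  if (is.na(k)) k <- length(var_exp)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- paste0("pc", seq_len(k))
  scores
}

#' Regress confounds out of ROI time series
#'
#' Returns the residuals of each column after OLS on an intercept plus the
#' confound columns; residuals are orthogonal to every confound.
#'
#' @param ts A [roi_ts()].
#' @param confounds Numeric matrix, time x regressor.
#' @return A `roi_ts` of residuals.
#' @export
regress_out <- function(ts, confounds) {
  stopifnot(inherits(ts, "roi_ts"))
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(ts$values))
    stop_invalid("confounds", "row count must match the time series")
  X <- cbind(intercept = 1, confounds)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_invalid("confounds",
                 paste("collinear columns:", paste(dropped, collapse = ", ")))
  }
  res <- ts$values - X %*% qr.coef(qx, ts$values)
  roi_ts(ts$times, res, ts$tr,
         provenance = c(ts$provenance,
                        sprintf("regress_out:%d", ncol(confounds))))
}

#' Zero-phase Chebyshev Type II low-pass filter
#'
#' Designs a low-pass Chebyshev Type II filter and applies it forward and
#' backward (zero phase). When the requested cutoff reaches the Nyquist
#' frequency -- as 0.25 Hz does at TR = 2 s -- the stopband edge is clamped
#' to 0.995 x Nyquist with a warning, keeping the design well posed.
#'
#' @param ts A [roi_ts()].
#' @param cutoff Low-pass stopband edge, Hz.
#' @param order Filter order.
#' @param stop_atten Stopband attenuation, dB.
#' @return A filtered `roi_ts`.
#' @export
lowpass_filter <- function(ts, cutoff = 0.25, order = 5, stop_atten = 40) {
  stopifnot(inherits(ts, "roi_ts"))
  nyquist <- 1 / (2 * ts$tr)
  if (cutoff > nyquist + 1e-12)
    stop_invalid("cutoff", sprintf("exceeds the Nyquist frequency %g Hz", nyquist))
  eff <- cutoff
  if (cutoff >= 0.995 * nyquist) {
    eff <- 0.995 * nyquist
    warning(sprintf(
      "cutoff %g Hz is at/near Nyquist (%g Hz); clamping stopband edge to %g Hz",
      cutoff, nyquist, eff))
  }
  des <- cheby2_lowpass(order, stop_atten, eff / nyquist)
  vals <- apply(ts$values, 2, function(x) filtfilt_fb(des$b, des$a, x))
  roi_ts(ts$times, vals, ts$tr,
         provenance = c(ts$provenance,
                        sprintf("lowpass:cheby2(%d,%gdB,%gHz)", order,
                                stop_atten, eff)))
}

#' Standard preprocessing chain
#'
#' Discard initial volumes, detrend + demean, regress out confounds (plus
#' PCA components of any nuisance-voxel signals), and low-pass filter.
#'
#' @param ts A [roi_ts()].
#' @param design Matching [stimulus_design()]; returned shifted.
#' @param confounds Optional confound matrix (full run; rows are trimmed
#'   with the discarded volumes).
#' @param nuisance_signals Optional time x voxel matrix fed through
#'   [select_nuisance_components()].
#' @param n_discard,cum_var,cutoff,order,stop_atten Stage parameters.
#' @return List with `ts` (processed `roi_ts`) and `design` (shifted).
#' @export
preprocess_run <- function(ts, design, confounds = NULL,
                           nuisance_signals = NULL, n_discard = 5,
                           cum_var = 0.70, cutoff = 0.25, order = 5,
                           stop_atten = 40) {
  out <- discard_initial(ts, n_discard)
  design2 <- shift_design(design, n_discard)
  out <- detrend_demean(out)
  conf <- NULL
  if (!is.null(confounds))
    conf <- as.matrix(confounds)[-seq_len(n_discard), , drop = FALSE]
  if (!is.null(nuisance_signals)) {
    nui <- as.matrix(nuisance_signals)[-seq_len(n_discard), , drop = FALSE]
    pcs <- select_nuisance_components(nui, cum_var)
    conf <- if (is.null(conf)) pcs else cbind(conf, pcs)
  }
  if (!is.null(conf) && ncol(conf) > 0) out <- regress_out(out, conf)
  out <- lowpass_filter(out, cutoff, order, stop_atten)
  list(ts = out, design = design2)
}
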