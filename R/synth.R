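# Synthetic block-design BOLD generator. Plants the statistical structure
# the downstream analysis assumes: HRF-convolved boxcar responses per
# condition, a seed region whose evoked response under the combined
# heat + ultrasound condition is multiplicatively suppressed (together with
# the region's subnetwork partners), subnetwork-shared latent signals that
# induce block-structured inter-ROI correlation, AR(1) noise, linear drift
# and smooth motion-like nuisance series.

#' Block-design stimulus schedule
#'
#' @param tr Repetition time, s.
#' @param n_volumes Number of acquired volumes.
#' @param events Data frame with columns `onset` (s), `duration` (s),
#'   `condition`.
#' @param baseline_temperature,stim_temperature Probe temperatures, deg C
#'   (metadata).
#' @return Object of class `stimulus_design`.
#' @export
stimulus_design <- function(tr, n_volumes, events,
                            baseline_temperature = 32,
                            stim_temperature = 47.5) {
  check_scalar(tr, "tr", lower = 0, allow_equal_lower = FALSE)
  check_scalar(n_volumes, "n_volumes", lower = 1)
  stopifnot(is.data.frame(events),
            all(c("onset", "duration", "condition") %in% names(events)))
  events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL
  if (any(events$onset < 0)) stop_invalid("events", "onsets must be >= 0")
  if (any(events$duration <= 0)) stop_invalid("events", "durations must be > 0")
  if (nrow(events) > 1) {
    ends <- events$onset + events$duration
    if (any(ends[-nrow(events)] > events$onset[-1] + 1e-9))
      stop_invalid("events", "blocks overlap")
  }
  if (any(events$onset + events$duration > tr * n_volumes + 1e-9))
    stop_invalid("events", "an event extends past the end of the run")
  structure(list(tr = tr, n_volumes = as.integer(n_volumes), events = events,
                 baseline_temperature = baseline_temperature,
                 stim_temperature = stim_temperature),
            class = "stimulus_design")
}

#' Default randomized block schedule
#'
#' 16-s stimulation blocks interleaved with 30-s rests, three conditions
#' (`heat`, `heat_fus`, `fus`) each repeated `reps` times in a seeded random
#' order after a 30-s lead-in rest. By default `n_volumes` covers the whole
#' schedule; passing a smaller value (e.g. 337 at TR 2 s) truncates trailing
#' events that no longer fit.
#'
#' @param rng_seed Integer seed controlling the condition order.
#' @param tr Repetition time, s.
#' @param block_s Stimulus block duration, s.
#' @param rest_s Rest duration between blocks, s.
#' @param reps Repetitions per condition.
#' @param conditions Condition labels.
#' @param n_volumes Optional run length in volumes.
#' @return A [stimulus_design()].
#' @export
default_design <- function(rng_seed = 1, tr = 2, block_s = 16, rest_s = 30,
                           reps = 7,
                           conditions = c("heat", "heat_fus", "fus"),
                           n_volumes = NULL) {
  order <- with_seed(rng_seed, sample(rep(conditions, reps)))
  n_ev <- length(order)
  onsets <- rest_s + (seq_len(n_ev) - 1) * (block_s + rest_s)
  if (is.null(n_volumes))
    n_volumes <- ceiling((rest_s + n_ev * (block_s + rest_s)) / tr)
  events <- data.frame(onset = onsets, duration = block_s, condition = order,
                       stringsAsFactors = FALSE)
  keep <- events$onset + events$duration <= tr * n_volumes
  stimulus_design(tr, n_volumes, events[keep, , drop = FALSE])
}

#' Ground-truth parameters of the generator
#'
#' @param roi_names Region names; the first entry is the thalamic seed by
#'   default.
#' @param subnetwork_label Integer subnetwork id per ROI.
#' @param response_amplitude ROI x condition matrix of evoked PSC
#'   amplitudes.
#' @param seed_name Seed region name.
#' @param suppression_factor Fraction in \[0, 1\] multiplying seed-coupled
#'   amplitudes under `heat_fus` (as `1 - suppression_factor`).
#' @param latent_coupling Weight of the latent (non-evoked) signals: each
#'   ROI receives `latent_coupling * (gain(t) * shared + private)` where
#'   `shared` is its subnetwork's common N(0,1) series and `private` its
#'   own N(0, latent_private_sd) series. For seed-coupled ROIs (other than
#'   the seed itself) the shared gain drops to `1 - suppression_factor`
#'   during heat_fus cycles, so inter-ROI correlation power falls with the
#'   suppression.
#' @param latent_private_sd Standard deviation of each ROI's private
#'   latent component (keeps within-subnetwork correlations below 1).
#' @param interaction_strength Strength of the planted psychophysiological
#'   interaction: each seed-coupled ROI receives
#'   `interaction_strength * g_c * mask_c(t) * task_c(t) * seed(t)`
#'   (demeaned HRF-convolved boxcar times the seed's intrinsic series,
#'   masked to condition-c cycles), with `g_heat = 1` and
#'   `g_heat_fus = 1 - suppression_factor`. This is the condition-specific
#'   multiplicative seed-target coupling that the PPI regression estimates.
#' @param ar_coefficient Lag-1 autocorrelation of the noise, in \[0, 1).
#' @param noise_sd Marginal noise standard deviation, signal units.
#' @param drift_slope Linear drift, units per volume.
#' @param n_motion_regressors Number of motion-like nuisance series.
#' @param baseline_level Additive raw-signal baseline; with the default 100
#'   the evoked amplitudes are directly in percent-signal-change units
#'   after PSC conversion. Set 0 for analyses on the evoked component
#'   itself.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(roi_names, subnetwork_label, response_amplitude,
                         seed_name = roi_names[1], suppression_factor = 0.6,
                         latent_coupling = 1, latent_private_sd = 0.5,
                         interaction_strength = 0.5,
                         ar_coefficient = 0.3,
                         noise_sd = 0.2, drift_slope = 0.002,
                         n_motion_regressors = 6, baseline_level = 100) {
  if (length(roi_names) == 0L) stop_invalid("roi_names", "must be non-empty")
  if (!seed_name %in% roi_names)
    stop_invalid("seed_name", "must be one of roi_names")
  check_scalar(suppression_factor, "suppression_factor", lower = 0, upper = 1)
  check_scalar(ar_coefficient, "ar_coefficient", lower = 0, upper = 1,
               allow_equal_upper = FALSE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  stopifnot(length(subnetwork_label) == length(roi_names))
  response_amplitude <- as.matrix(response_amplitude)
  stopifnot(nrow(response_amplitude) == length(roi_names))
  rownames(response_amplitude) <- roi_names
  structure(list(roi_names = roi_names,
                 subnetwork_label = stats::setNames(as.integer(subnetwork_label),
                                                    roi_names),
                 response_amplitude = response_amplitude,
                 seed_name = seed_name,
                 suppression_factor = suppression_factor,
                 latent_coupling = latent_coupling,
                 latent_private_sd = latent_private_sd,
                 interaction_strength = interaction_strength,
                 ar_coefficient = ar_coefficient, noise_sd = noise_sd,
                 drift_slope = drift_slope,
                 n_motion_regressors = as.integer(n_motion_regressors),
                 baseline_level = baseline_level),
            class = "ground_truth")
}

#' Default ground truth: thalamic seed plus 19 cortical regions
#'
#' The seed (VPL) and the first nine cortical regions form subnetwork 1;
#' the remaining ten form subnetwork 2, mirroring a two-subnetwork
#' thalamocortical organisation. Evoked amplitudes default to 1 PSC unit
#' for both heat conditions and 0 for the ultrasound-only condition.
#'
#' @inheritParams ground_truth
#' @param amplitude Evoked PSC amplitude for heat and heat_fus blocks.
#' @param ... Passed to [ground_truth()].
#' @export
default_truth <- function(amplitude = 0.25, suppression_factor = 0.6, ...) {
  rois <- c("VPL",
            "MST", "TP", "latOFC", "MT", "ar8A", "ar5", "SI", "STGr", "BAAC",
            "vlPFC", "caudOFC", "ar7", "areaTE", "V4", "cAAC", "DPC", "LMC",
            "SII", "STGc")
  labels <- c(rep(1L, 10), rep(2L, 10))
  amp <- cbind(heat = rep(amplitude, length(rois)),
               heat_fus = rep(amplitude, length(rois)),
               fus = rep(0, length(rois)))
  ground_truth(rois, labels, amp, seed_name = "VPL",
               suppression_factor = suppression_factor, ...)
}

# ROIs whose heat_fus amplitude is scaled by (1 - suppression): the seed
# and every ROI sharing its subnetwork label.
coupled_rois <- function(truth) {
  seed_label <- truth$subnetwork_label[truth$seed_name]
  names(truth$subnetwork_label)[truth$subnetwork_label == seed_label]
}

ar1_noise <- function(n, phi, sd) {
  if (sd == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - phi^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                           method = "recursive"))
}

# Smooth motion-like series: integrated white noise, mildly smoothed and
# scaled to unit sd.
motion_series <- function(n, k) {
  if (k == 0) return(matrix(0, n, 0))
  m <- sapply(seq_len(k), function(i) {
    x <- cumsum(stats::rnorm(n, 0, 1))
    x <- stats::filter(x, rep(1 / 5, 5), sides = 2)
    x[is.na(x)] <- 0
    x <- x - mean(x)
    s <- stats::sd(x)
    if (s > 0) x / s else x
  })
  colnames(m) <- paste0("motion", seq_len(k))
  m
}

#' Simulate an ROI-level BOLD run
#'
#' For each ROI the neural signal is the sum over conditions of
#' `amplitude(roi, condition) * boxcar`, with seed-coupled amplitudes
#' multiplied by `1 - suppression_factor` under `heat_fus`, convolved with
#' the canonical double-gamma HRF. Subnetwork-shared latent Gaussian
#' signals (weight `latent_coupling`), AR(1) noise, linear drift and a
#' small projection of the motion-like nuisance series are added on top.
#'
#' @param design A [stimulus_design()].
#' @param truth A [ground_truth()].
#' @param rng_seed Integer seed; output is bit-reproducible given the seed.
#' @param hrf HRF kernel used for the evoked responses.
#' @return Object of class `synthetic_dataset`: `design`, `signals`
#'   (a `roi_ts`), `nuisance` (volumes x regressors), `truth`, `rng_seed`.
#' @export
simulate_dataset <- function(design, truth, rng_seed = 1,
                             hrf = canonical_hrf()) {
  stopifnot(inherits(design, "stimulus_design"), inherits(truth, "ground_truth"))
  if (length(truth$roi_names) == 0L) stop_invalid("roi_names", "empty ROI set")
  n <- design$n_volumes
  rois <- truth$roi_names
  conds <- colnames(truth$response_amplitude)
  reg <- condition_regressors(design, hrf, conditions = conds)
  amp <- truth$response_amplitude
  if (truth$suppression_factor > 0 && "heat_fus" %in% conds) {
    cp <- coupled_rois(truth)
    amp[cp, "heat_fus"] <- amp[cp, "heat_fus"] * (1 - truth$suppression_factor)
  }
  neural <- reg %*% t(amp)
  cp <- coupled_rois(truth)
  times <- (seq_len(n) - 1) * design$tr
  cyc <- cycle_condition(design, times)
  # per-condition interaction gains on the seed-target coupling
  g_cond <- c(heat = 1, heat_fus = 1 - truth$suppression_factor, fus = 0)
  hf_mask <- as.numeric(cyc == "heat_fus")
  out <- with_seed(rng_seed, {
    labels <- truth$subnetwork_label
    latent <- sapply(sort(unique(labels)),
                     function(s) stats::rnorm(n, 0, 1))
    private <- matrix(stats::rnorm(n * length(rois), 0,
                                   truth$latent_private_sd), n)
    noise <- sapply(seq_along(rois), function(j)
      ar1_noise(n, truth$ar_coefficient, truth$noise_sd))
    if (truth$noise_sd == 0) noise <- matrix(0, n, length(rois))
    subnet_of <- match(labels, sort(unique(labels)))
    jseed <- match(truth$seed_name, rois)
    # the seed's intrinsic series: evoked + latents + its own noise
    seed_series <- neural[, jseed] +
      truth$latent_coupling * (latent[, subnet_of[jseed]] + private[, jseed]) +
      noise[, jseed]
    interaction <- numeric(n)
    for (cond in intersect(conds, names(g_cond))) {
      w_dm <- reg[, cond] - mean(reg[, cond])
      interaction <- interaction +
        g_cond[[cond]] * ifelse(cyc == cond, w_dm * seed_series, 0)
    }
    vals <- neural
    for (j in seq_along(rois)) {
      coupled_target <- rois[j] %in% cp && j != jseed
      gain <- if (coupled_target) 1 - truth$suppression_factor * hf_mask else 1
      vals[, j] <- vals[, j] +
        truth$latent_coupling *
          (gain * latent[, subnet_of[j]] + private[, j]) + noise[, j] +
        truth$drift_slope * (seq_len(n) - 1)
      if (coupled_target)
        vals[, j] <- vals[, j] + truth$interaction_strength * interaction
    }
    motion <- motion_series(n, truth$n_motion_regressors)
    if (ncol(motion) > 0) {
      load <- matrix(stats::rnorm(length(rois) * ncol(motion), 0, 0.05),
                     ncol(motion), length(rois))
      vals <- vals + motion %*% load
    }
    list(vals = vals, motion = motion)
  })
  colnames(out$vals) <- rois
  out$vals <- out$vals + truth$baseline_level
  signals <- roi_ts((seq_len(n) - 1) * design$tr, out$vals, design$tr,
                    provenance = "simulated")
  structure(list(design = design, signals = signals, nuisance = out$motion,
                 truth = truth, rng_seed = rng_seed),
            class = "synthetic_dataset")
}

#' Expand an ROI dataset into a small 4D voxel volume
#'
#' Places each ROI as a run of `voxels_per_roi` face-contiguous voxels
#' along a serpentine raster through the grid (with one background voxel
#' between consecutive ROIs); every ROI voxel carries the ROI time series
#' plus independent Gaussian noise, background voxels carry noise only.
#'
#' @param dataset A `synthetic_dataset`.
#' @param voxels_per_roi Voxels per region.
#' @param grid_shape Integer 3-vector.
#' @param noise_sd Per-voxel independent noise sd (default: truth noise_sd).
#' @param rng_seed Seed for the voxel noise.
#' @return List with `volume` (4D array x,y,z,t) and `mask` (3D integer
#'   array; 0 = background, i = i-th ROI), plus `roi_names`.
#' @export
simulate_volume <- function(dataset, voxels_per_roi, grid_shape,
                            noise_sd = dataset$truth$noise_sd, rng_seed = 1) {
  stopifnot(inherits(dataset, "synthetic_dataset"), length(grid_shape) == 3)
  rois <- dataset$truth$roi_names
  nvox <- prod(grid_shape)
  needed <- length(rois) * voxels_per_roi + (length(rois) - 1)
  if (needed > nvox)
    stop_invalid("grid_shape",
                 sprintf("grid too small: need %d voxels, have %d", needed, nvox))
  path <- serpentine_path(grid_shape)
  mask_lin <- integer(nvox)
  pos <- 1L
  for (j in seq_along(rois)) {
    mask_lin[path[pos:(pos + voxels_per_roi - 1)]] <- j
    pos <- pos + voxels_per_roi + 1L  # leave one background voxel as a gap
  }
  n <- dataset$design$n_volumes
  vol <- with_seed(rng_seed, {
    v <- matrix(stats::rnorm(nvox * n, 0, noise_sd), nvox, n)
    for (j in seq_along(rois)) {
      vox <- which(mask_lin == j)
      v[vox, ] <- v[vox, ] +
        matrix(dataset$signals$values[, j], length(vox), n, byrow = TRUE)
    }
    v
  })
  list(volume = array(t(vol), dim = c(n, grid_shape)) |> aperm(c(2, 3, 4, 1)),
       mask = array(mask_lin, dim = grid_shape), roi_names = rois)
}

# Linear indices of a serpentine raster: consecutive entries are always
# face-adjacent (x snakes within y, y snakes within z).
serpentine_path <- function(shape) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  idx <- integer(nx * ny * nz)
  k <- 1L
  forward <- TRUE  # x direction continues across row and slice boundaries
  for (z in seq_len(nz)) {
    ys <- if (z %% 2 == 1) seq_len(ny) else rev(seq_len(ny))
    for (y in ys) {
      xs <- if (forward) seq_len(nx) else rev(seq_len(nx))
      idx[k:(k + nx - 1)] <- (z - 1) * nx * ny + (y - 1) * nx + xs
      k <- k + nx
      forward <- !forward
    }
  }
  idx
}
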