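# Psychophysiological-interaction (PPI) effective connectivity: seed
# extraction from suprathreshold voxels, PPI regressor construction at the
# BOLD level (no deconvolution, matching the condition-specific
# cycle-concatenation approach), per-run GLM, two-stage group inference and
# rank-sum condition comparison.

#' Extract the seed time course
#'
#' ROI mode: pass a multi-ROI `roi_ts` of PSC values and the seed ROI name.
#' Voxel mode: pass a 4D PSC array plus an `activation_map` and a logical
#' seed mask; the seed is the mean over voxels that are both inside the
#' mask and suprathreshold. The extracted series is detrended and demeaned.
#'
#' @param psc A `roi_ts` (ROI mode) or a 4D array x,y,z,t (voxel mode).
#' @param seed_roi Seed ROI name (ROI mode).
#' @param activation An `activation_map` (voxel mode).
#' @param seed_mask Logical 3D array (voxel mode).
#' @return Object of class `seed_signal` with zero-mean, zero-slope
#'   `values`, `source_voxel_count`, `seed_roi`, `preprocessing`.
#' @export
extract_seed <- function(psc, seed_roi = NULL, activation = NULL,
                         seed_mask = NULL) {
  if (inherits(psc, "roi_ts")) {
    if (is.null(seed_roi) || !seed_roi %in% colnames(psc$values))
      stop_invalid("seed_roi", "not present in the ROI time series")
    vals <- psc$values[, seed_roi]
    nvox <- 1L
    prov <- c(psc$provenance, "extract_seed:roi")
  } else {
    stopifnot(inherits(activation, "activation_map"), !is.null(seed_mask))
    qual <- which(seed_mask & activation$mask)
    if (length(qual) == 0L)
      stop("empty seed: no suprathreshold voxels inside the seed mask",
           call. = FALSE)
    dims <- dim(psc)
    flat <- matrix(psc, prod(dims[1:3]), dims[4])
    vals <- colMeans(flat[qual, , drop = FALSE])
    nvox <- length(qual)
    prov <- "extract_seed:voxel"
    if (is.null(seed_roi)) seed_roi <- "seed"
  }
  vals <- drop(detrend_demean(matrix(vals, ncol = 1)))
  structure(list(values = vals, source_voxel_count = nvox,
                 seed_roi = seed_roi, preprocessing = prov),
            class = "seed_signal")
}

#' HRF kernel from a two-gamma fit
#'
#' Converts a fitted cycle-average model into a unit-peak convolution
#' kernel for the PPI task regressor.
#'
#' @param fit A `two_gamma_fit`.
#' @param dt Sampling step, s.
#' @param duration Kernel support, s (default: fitted window).
#' @return An `hrf_kernel`.
#' @export
two_gamma_kernel <- function(fit, dt = 0.1, duration = NULL) {
  stopifnot(inherits(fit, "two_gamma_fit"))
  if (is.null(duration)) duration <- max(fit$window_times)
  t <- seq(0, duration, by = dt)
  par <- c(amp1 = fit$amp1, amp2 = fit$amp2, lag1 = fit$lag1,
           dlag = fit$lag2 - fit$lag1, k1 = fit$k1, k2 = fit$k2,
           theta1 = fit$theta1, theta2 = fit$theta2)
  h <- two_gamma_model(t, par)
  pk <- max(abs(h))
  if (pk == 0) stop_invalid("fit", "fitted kernel is identically zero")
  structure(list(t = t, h = h / pk, dt = dt), class = "hrf_kernel")
}

# Assign each volume to the stimulation cycle (block + following rest) it
# falls in; returns the cycle's condition ("" before the first block).
cycle_condition <- function(design, times) {
  ev <- design$events[order(design$events$onset), , drop = FALSE]
  gaps <- diff(ev$onset)
  cycle_len <- if (length(gaps) > 0) stats::median(gaps) else
    ev$duration[1] + 30
  total <- design$tr * design$n_volumes
  cond <- character(length(times))
  for (i in seq_len(nrow(ev))) {
    end <- if (i < nrow(ev)) ev$onset[i + 1] else ev$onset[i] + cycle_len
    if (i == nrow(ev) && end > total + 1e-9) next  # drop partial trailing cycle
    cond[times >= ev$onset[i] & times < end] <- ev$condition[i]
  }
  cond
}

#' Build PPI regressors from a seed signal
#'
#' Per condition: a boxcar (1 during that condition's blocks) is demeaned
#' over the full run, convolved with `hrf`, sampled at the volume times and
#' multiplied element-wise with the seed time course. Condition-specific
#' vectors keep the product only on that condition's cycles (block +
#' following rest) and are zero elsewhere, so they have disjoint supports;
#' `ppi_full` is their sum.
#'
#' @param seed A `seed_signal`.
#' @param design A [stimulus_design()] aligned with the seed.
#' @param hrf An `hrf_kernel` (canonical or from [two_gamma_kernel()]).
#' @param conditions Conditions to build regressors for.
#' @return Object of class `ppi_regressors` with `ppi_full`,
#'   `ppi_by_condition`, `task_convolved`, `hrf_used`.
#' @export
build_ppi <- function(seed, design, hrf = canonical_hrf(),
                      conditions = c("heat", "heat_fus")) {
  stopifnot(inherits(seed, "seed_signal"), inherits(design, "stimulus_design"))
  if (length(seed$values) != design$n_volumes)
    stop_invalid("seed", "length must equal the design's volume count")
  times <- (seq_len(design$n_volumes) - 1) * design$tr
  dt <- hrf$dt
  fine_t <- seq(0, design$tr * design$n_volumes - dt, by = dt)
  vol_idx <- round(times / dt) + 1L
  cyc <- cycle_condition(design, times)
  task_conv <- matrix(0, design$n_volumes, length(conditions),
                      dimnames = list(NULL, conditions))
  ppi_cond <- task_conv
  for (cond in conditions) {
    ev <- design$events[design$events$condition == cond, , drop = FALSE]
    if (nrow(ev) == 0L)
      stop_invalid("conditions", sprintf("condition '%s' has no events", cond))
    box <- numeric(length(fine_t))
    for (i in seq_len(nrow(ev)))
      box[fine_t >= ev$onset[i] & fine_t < ev$onset[i] + ev$duration[i]] <- 1
    box <- box - mean(box)
    conv <- convolve(box, rev(hrf$h), type = "open")[seq_along(fine_t)] * dt
    task_conv[, cond] <- conv[vol_idx]
    prod_full <- task_conv[, cond] * seed$values
    ppi_cond[, cond] <- ifelse(cyc == cond, prod_full, 0)
  }
  structure(list(ppi_full = rowSums(ppi_cond), ppi_by_condition = ppi_cond,
                 task_convolved = task_conv, hrf_used = hrf,
                 cycle_condition = cyc),
            class = "ppi_regressors")
}

#' Condition-specific effective connectivity via PPI regression
#'
#' Per-ROI OLS of the BOLD series on the base design (task main effects,
#' confounds, intercept) augmented with one PPI column per condition; the
#' effective-connectivity beta for a condition is the coefficient on that
#' condition's PPI column.
#'
#' @param Y Time x ROI matrix or `roi_ts`.
#' @param ppi A `ppi_regressors`.
#' @param X_base A `design_matrix` (or plain matrix) of non-PPI columns.
#' @param run_id,subject_id Identifiers carried into group analysis.
#' @param collinearity_limit Error if any |correlation| between a PPI
#'   column and a base column exceeds this.
#' @return Object of class `efc_result` with `table` (roi, condition,
#'   beta, se, t, p), `glm`, `run_id`, `subject_id`.
#' @export
fit_efc <- function(Y, ppi, X_base, run_id = "run1", subject_id = "subj1",
                    collinearity_limit = 0.999) {
  if (inherits(Y, "roi_ts")) Y <- Y$values
  Xb <- if (inherits(X_base, "design_matrix")) X_base$X else as.matrix(X_base)
  P <- ppi$ppi_by_condition
  colnames(P) <- paste0("ppi_", colnames(P))
  varying <- apply(Xb, 2, function(x) stats::sd(x) > 0)
  cors <- suppressWarnings(abs(stats::cor(P, Xb[, varying, drop = FALSE])))
  if (any(cors > collinearity_limit, na.rm = TRUE)) {
    worst <- which(cors == max(cors, na.rm = TRUE), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "PPI column '%s' is collinear with base column '%s' (|r| = %.4f)",
      rownames(cors)[worst[1]], colnames(cors)[worst[2]],
      max(cors, na.rm = TRUE)), call. = FALSE)
  }
  X <- cbind(Xb, P)
  fit <- fit_glm(Y, X)
  conds <- colnames(ppi$ppi_by_condition)
  tab <- do.call(rbind, lapply(conds, function(cond) {
    col <- paste0("ppi_", cond)
    data.frame(roi = rownames(fit$beta), condition = cond,
               beta = fit$beta[, col], se = fit$se[, col],
               t = fit$t[, col], p = fit$p[, col],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, glm = fit, run_id = run_id,
                 subject_id = subject_id), class = "efc_result")
}

#' Two-stage group-level inference on EFC betas
#'
#' Run-level betas are first averaged within subject (runs are treated as
#' repeated measures, unweighted by run count), then a one-sample t-test is
#' applied across the subject means per ROI and condition. With a single
#' subject the test falls back to run-level inference with a warning.
#'
#' @param results List of `efc_result` objects.
#' @return Data frame: roi, condition, n_subjects, n_runs, mean_beta, t, p.
#' @export
group_level <- function(results) {
  stopifnot(length(results) >= 1, all(vapply(results, inherits, TRUE, "efc_result")))
  long <- do.call(rbind, lapply(results, function(r)
    cbind(r$table, run_id = r$run_id, subject_id = r$subject_id)))
  subjects <- unique(long$subject_id)
  if (length(subjects) < 2)
    warning("single subject: falling back to run-level inference")
  # stage 1: subject means (or run-level values when only one subject)
  unit_col <- if (length(subjects) >= 2) "subject_id" else "run_id"
  agg <- stats::aggregate(beta ~ roi + condition + long[[unit_col]],
                          data = long, FUN = mean)
  names(agg)[3] <- "unit"
  out <- do.call(rbind, lapply(split(agg, list(agg$roi, agg$condition),
                                     drop = TRUE), function(d) {
    n <- nrow(d)
    m <- mean(d$beta)
    if (n >= 2) {
      s <- stats::sd(d$beta) / sqrt(n)
      tt <- if (s > 0) m / s else sign(m) * Inf
      p <- 2 * stats::pt(-abs(tt), df = n - 1)
    } else {
      tt <- NA_real_; p <- NA_real_
    }
    data.frame(roi = d$roi[1], condition = d$condition[1],
               n_units = n, mean_beta = m, t = tt, p = p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$n_subjects <- length(subjects)
  out$n_runs <- length(unique(long$run_id))
  out[order(out$condition, out$roi), ]
}

#' Mann-Whitney-Wilcoxon rank-sum comparison
#'
#' Tie-corrected U statistic; the p-value is exact (permutation
#' enumeration) for combined sample sizes up to `exact_max`, otherwise a
#' tie-corrected normal approximation with continuity correction.
#'
#' @param a,b Numeric samples.
#' @param exact_max Largest combined n for exact enumeration.
#' @return List with `U` (for sample `a`), `p`, `effect_direction`
#'   (`"a>b"`, `"a<b"` or `"none"`), `method`.
#' @export
compare_mww <- function(a, b, exact_max = 20) {
  if (length(a) == 0 || length(b) == 0)
    stop_invalid("a/b", "both samples must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (N <= exact_max) {
    combos <- utils::combn(N, n1)
    Us <- apply(combos, 2, function(ix) sum(rk[ix]) - n1 * (n1 + 1) / 2)
    p <- min(1, 2 * min(mean(Us <= U + 1e-9), mean(Us >= U - 1e-9)))
    method <- "exact"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
    z <- (U - mu - sign(U - mu) * 0.5) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  dir <- if (U > mu) "a>b" else if (U < mu) "a<b" else "none"
  list(U = U, p = p, effect_direction = dir, method = method)
}
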