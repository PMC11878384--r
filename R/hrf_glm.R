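# Canonical double-gamma HRF, design-matrix construction, mass-univariate
# OLS GLM, percent-signal-change conversion, cycle averaging and the
# two-gamma parameterization of cycle-averaged responses.

#' Haemodynamic response function specification
#'
#' Conventional canonical double-gamma parameters: response peaking ~6 s
#' after onset with a late undershoot ~16 s, both with 1-s dispersion, and
#' an undershoot one sixth of the peak.
#'
#' @param peak_delay,undershoot_delay Gamma mode delays, s.
#' @param peak_dispersion,undershoot_dispersion Gamma scale parameters, s.
#' @param undershoot_ratio Undershoot amplitude relative to the peak.
#' @param dt Sampling step of the kernel, s.
#' @param duration Kernel support, s.
#' @return Object of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16,
                     peak_dispersion = 1, undershoot_dispersion = 1,
                     undershoot_ratio = 1 / 6, dt = 0.1, duration = 32) {
  for (f in c("peak_delay", "undershoot_delay", "peak_dispersion",
              "undershoot_dispersion", "dt", "duration"))
    check_scalar(get(f), f, lower = 0, allow_equal_lower = FALSE)
  check_scalar(undershoot_ratio, "undershoot_ratio", lower = 0)
  if (duration < undershoot_delay)
    stop_invalid("duration", "must cover the undershoot delay")
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio, dt = dt,
                 duration = duration), class = "hrf_spec")
}

#' Sampled canonical double-gamma HRF kernel
#'
#' Difference of two gamma densities (positive lobe first), rescaled so the
#' kernel peak equals 1; h(0) = 0.
#'
#' @param spec An [hrf_spec()].
#' @return List with `t` (sample times, s) and `h` (kernel values), class
#'   `hrf_kernel`.
#' @export
canonical_hrf <- function(spec = hrf_spec()) {
  stopifnot(inherits(spec, "hrf_spec"))
  t <- seq(0, spec$duration, by = spec$dt)
  shape1 <- spec$peak_delay / spec$peak_dispersion
  shape2 <- spec$undershoot_delay / spec$undershoot_dispersion
  h <- dgamma(t, shape = shape1, scale = spec$peak_dispersion) -
    spec$undershoot_ratio *
      dgamma(t, shape = shape2, scale = spec$undershoot_dispersion)
  h <- h / max(h)
  structure(list(t = t, h = h, dt = spec$dt), class = "hrf_kernel")
}

# HRF-convolved boxcar regressors, one column per condition, sampled at the
# volume acquisition times. Convolution is done on the kernel's fine grid
# and then decimated to the TR grid.
condition_regressors <- function(design, hrf = canonical_hrf(),
                                 conditions = NULL) {
  stopifnot(inherits(design, "stimulus_design"), inherits(hrf, "hrf_kernel"))
  if (is.null(conditions)) conditions <- unique(design$events$condition)
  dt <- hrf$dt
  total <- design$tr * design$n_volumes
  fine_t <- seq(0, total - dt, by = dt)  # the run spans [0, total)
  vol_t <- (seq_len(design$n_volumes) - 1) * design$tr
  vol_idx <- round(vol_t / dt) + 1L
  out <- matrix(0, design$n_volumes, length(conditions),
                dimnames = list(NULL, conditions))
  for (cond in conditions) {
    ev <- design$events[design$events$condition == cond, , drop = FALSE]
    box <- numeric(length(fine_t))
    for (i in seq_len(nrow(ev)))
      box[fine_t >= ev$onset[i] & fine_t < ev$onset[i] + ev$duration[i]] <- 1
    conv <- convolve(box, rev(hrf$h), type = "open")[seq_along(fine_t)] * dt
    out[, cond] <- conv[vol_idx]
  }
  out
}

#' Build a GLM design matrix from a stimulus design
#'
#' One HRF-convolved boxcar column per condition, plus optional confound
#' columns and an intercept.
#'
#' @param design A [stimulus_design()].
#' @param hrf An `hrf_kernel` (default canonical).
#' @param confounds Optional numeric matrix (volumes x regressors).
#' @param conditions Conditions to model (default: all present).
#' @return List with `X` (matrix), `times`, `condition_map` (named vector
#'   mapping task columns to conditions), class `design_matrix`.
#' @export
build_design <- function(design, hrf = canonical_hrf(), confounds = NULL,
                         conditions = NULL) {
  task <- condition_regressors(design, hrf, conditions)
  X <- cbind(intercept = 1, task)
  cmap <- stats::setNames(colnames(task), colnames(task))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != design$n_volumes)
      stop_invalid("confounds", "row count must equal n_volumes")
    if (is.null(colnames(confounds)))
      colnames(confounds) <- paste0("confound", seq_len(ncol(confounds)))
    X <- cbind(X, confounds)
  }
  if (qr(X)$rank < ncol(X))
    stop_invalid("design", "design matrix is rank deficient")
  structure(list(X = X, times = (seq_len(design$n_volumes) - 1) * design$tr,
                 condition_map = cmap), class = "design_matrix")
}

#' Mass-univariate ordinary least squares GLM
#'
#' Fits every column of `Y` against the same design matrix; standard errors
#' use the per-series residual variance with `nrow - ncol` degrees of
#' freedom, and p-values are two-sided from the t distribution.
#'
#' @param Y Numeric matrix, time x series (voxels or ROIs).
#' @param X A `design_matrix` or plain numeric matrix.
#' @return List of class `glm_result` with `beta`, `se`, `t`, `p`
#'   (series x regressor matrices), `dof`, `residual_variance`, `residuals`.
#' @export
fit_glm <- function(Y, X) {
  if (inherits(X, "design_matrix")) X <- X$X
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X)) stop_invalid("Y", "row count must match the design")
  dof <- nrow(X) - ncol(X)
  if (dof <= 0) stop_invalid("X", "no residual degrees of freedom")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop_invalid("X", "design matrix is rank deficient")
  beta <- qr.coef(qx, Y)
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / dof
  xtx_inv_diag <- diag(chol2inv(qr.R(qx)))
  se <- sqrt(outer(sigma2, xtx_inv_diag))
  beta_t <- t(beta)
  colnames(se) <- colnames(beta_t)
  tval <- beta_t / se
  tval[se == 0] <- 0
  p <- 2 * stats::pt(-abs(tval), df = dof)
  structure(list(beta = beta_t, se = se, t = tval, p = p, dof = dof,
                 residual_variance = sigma2, residuals = res,
                 cov_unscaled = chol2inv(qr.R(qx))),
            class = "glm_result")
}

#' t-test of a linear contrast of GLM coefficients
#'
#' @param fit A `glm_result`.
#' @param contrast Numeric vector (length = number of regressors) or a
#'   named vector giving weights for a subset of regressors.
#' @return Data frame per series: estimate, se, t, p.
#' @export
contrast_test <- function(fit, contrast) {
  stopifnot(inherits(fit, "glm_result"))
  k <- ncol(fit$beta)
  if (!is.null(names(contrast))) {
    cv <- stats::setNames(numeric(k), colnames(fit$beta))
    bad <- setdiff(names(contrast), colnames(fit$beta))
    if (length(bad)) stop_invalid("contrast",
                                  paste("unknown regressors:",
                                        paste(bad, collapse = ", ")))
    cv[names(contrast)] <- contrast
  } else {
    if (length(contrast) != k)
      stop_invalid("contrast", "length must match the regressor count")
    cv <- as.numeric(contrast)
  }
  est <- drop(fit$beta %*% cv)
  var_c <- drop(t(cv) %*% fit$cov_unscaled %*% cv)
  se <- sqrt(var_c * fit$residual_variance)
  tt <- ifelse(se > 0, est / se, 0)
  series <- rownames(fit$beta)
  if (is.null(series)) series <- paste0("series", seq_len(nrow(fit$beta)))
  data.frame(series = series, estimate = est, se = se, t = tt,
             p = 2 * stats::pt(-abs(tt), df = fit$dof), row.names = NULL)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjustment; rejection at level `q` uses the monotonized adjusted
#' p-values.
#'
#' @param p Vector of p-values in \[0, 1\] (NAs passed through).
#' @param q FDR level.
#' @return List with `adjusted` and logical `reject`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_invalid("p", "p-values must lie in [0, 1]")
  check_scalar(q, "q", lower = 0, upper = 1)
  adjusted <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m > 0) {
    o <- order(p[ok], decreasing = TRUE)
    ro <- ok[o]
    adjusted[ro] <- pmin(1, cummin(p[ro] * m / (m:1)))
  }
  list(adjusted = adjusted, reject = !is.na(adjusted) & adjusted <= q)
}

#' Percent signal change relative to a rest baseline
#'
#' Converts each ROI column to 100 * (y - baseline) / baseline where the
#' baseline is the mean over rest volumes. By default only the final 10 s
#' of each rest period enter the baseline, avoiding contamination by the
#' post-stimulus undershoot; set `baseline = "all_rest"` to use every rest
#' volume.
#'
#' @param ts A `roi_ts`.
#' @param design The [stimulus_design()] aligned with `ts`.
#' @param baseline `"final10s"` or `"all_rest"`.
#' @param final_s Length of the tail of each rest period used when
#'   `baseline = "final10s"`.
#' @return A `roi_ts` in PSC units.
#' @export
compute_psc <- function(ts, design, baseline = c("final10s", "all_rest"),
                        final_s = 10) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(ts, "roi_ts"))
  idx <- rest_baseline_index(ts$times, design, baseline, final_s)
  if (length(idx) == 0L) stop_invalid("design", "no rest volumes for baseline")
  base <- colMeans(ts$values[idx, , drop = FALSE])
  if (any(base == 0)) stop_invalid("ts", "zero baseline mean in some ROI")
  vals <- 100 * sweep(sweep(ts$values, 2, base, "-"), 2, base, "/")
  roi_ts(ts$times, vals, ts$tr,
         provenance = c(ts$provenance, paste0("psc:", baseline)))
}

# Indices of volumes belonging to rest periods (complement of stimulus
# blocks), optionally restricted to the last `final_s` seconds of each
# rest period.
rest_baseline_index <- function(times, design, baseline, final_s) {
  ev <- design$events[order(design$events$onset), , drop = FALSE]
  total <- design$tr * design$n_volumes
  starts <- c(0, ev$onset + ev$duration)
  ends <- c(ev$onset, total)
  keep <- starts < ends
  starts <- starts[keep]; ends <- ends[keep]
  idx <- integer(0)
  for (i in seq_along(starts)) {
    lo <- if (baseline == "final10s") max(starts[i], ends[i] - final_s) else starts[i]
    idx <- c(idx, which(times >= lo & times < ends[i]))
  }
  sort(unique(idx))
}

#' Cycle-averaged response for one condition
#'
#' Epochs the series at every onset of `condition`, keeps epochs fully
#' inside the run, and averages pointwise; the standard error is computed
#' across cycles.
#'
#' @param ts A `roi_ts` (typically in PSC units) with a single column, or a
#'   numeric vector paired with `times`.
#' @param design The [stimulus_design()].
#' @param condition Condition whose blocks anchor the epochs.
#' @param window_s Epoch length (block + rest), s.
#' @return Object of class `cycle_average` with `window_times`, `mean_psc`,
#'   `se_psc`, `n_cycles`, `condition`.
#' @export
cycle_average <- function(ts, design, condition, window_s = 46) {
  stopifnot(inherits(ts, "roi_ts"))
  if (ncol(ts$values) != 1L)
    stop_invalid("ts", "cycle_average expects a single-series roi_ts")
  y <- ts$values[, 1L]
  onsets <- design$events$onset[design$events$condition == condition]
  nw <- floor(window_s / ts$tr)
  epochs <- list()
  for (o in onsets) {
    i0 <- which.min(abs(ts$times - o))
    if (abs(ts$times[i0] - o) > ts$tr / 2 + 1e-9) next
    if (i0 + nw - 1 > length(y)) next
    epochs[[length(epochs) + 1L]] <- y[i0:(i0 + nw - 1)]
  }
  n <- length(epochs)
  if (n == 0L) stop_invalid("condition", "no complete cycles inside the run")
  em <- do.call(rbind, epochs)
  mean_psc <- colMeans(em)
  se_psc <- if (n > 1) apply(em, 2, stats::sd) / sqrt(n) else rep(0, nw)
  structure(list(window_times = (seq_len(nw) - 1) * ts$tr,
                 mean_psc = mean_psc, se_psc = se_psc, n_cycles = n,
                 condition = condition), class = "cycle_average")
}

# Unit-peak gamma bump: gamma density shifted by `lag`, rescaled so its
# maximum is 1 (so amplitudes are in the data's units).
gamma_bump <- function(t, lag, shape, scale) {
  tt <- t - lag
  out <- numeric(length(t))
  pos <- tt > 0
  mode <- max((shape - 1) * scale, .Machine$double.eps)
  peak <- stats::dgamma(mode, shape = shape, scale = scale)
  out[pos] <- stats::dgamma(tt[pos], shape = shape, scale = scale) / peak
  out
}

two_gamma_model <- function(t, par) {
  par["amp1"] * gamma_bump(t, par["lag1"], par["k1"], par["theta1"]) -
    par["amp2"] * gamma_bump(t, par["lag1"] + par["dlag"], par["k2"],
                             par["theta2"])
}

#' Two-gamma parameterization of a cycle-averaged response
#'
#' Bounded nonlinear least squares of
#' `amp1 * G(t - lag1; k1, theta1) - amp2 * G(t - lag2; k2, theta2)`
#' (each G a unit-peak gamma bump, lag2 = lag1 + dlag so lag1 < lag2 by
#' construction) with amplitudes >= 0, lags inside the window, shapes in
#' \[1, 12\] and scales in \[0.1, 4\] s. Three seeded starts (one
#' data-driven, two jittered); the best residual sum of squares wins and
#' the convergence flag is honest.
#'
#' @param cycle A `cycle_average`.
#' @param rng_seed Seed for the jittered restarts.
#' @param n_starts Number of optimizer starts.
#' @return Object of class `two_gamma_fit` with `amp1`, `amp2`, `lag1`,
#'   `lag2`, `k1`, `k2`, `theta1`, `theta2`, `rss`, `converged`, `fitted`.
#' @export
fit_two_gamma <- function(cycle, rng_seed = 1, n_starts = 5) {
  stopifnot(inherits(cycle, "cycle_average"))
  t <- cycle$window_times
  y <- cycle$mean_psc
  if (length(t) < 10L) stop_invalid("cycle", "window must have >= 10 samples")
  W <- max(t)
  lower <- c(amp1 = 0, amp2 = 0, lag1 = 0, dlag = 0.5,
             k1 = 1, k2 = 1, theta1 = 0.1, theta2 = 0.1)
  upper <- c(amp1 = 10 * max(abs(y), 0.1), amp2 = 10 * max(abs(y), 0.1),
             lag1 = W, dlag = W, k1 = 12, k2 = 12, theta1 = 4, theta2 = 4)
  obj <- function(p) {
    names(p) <- names(lower)
    sum((y - two_gamma_model(t, p))^2)
  }
  imax <- which.max(y)
  start0 <- c(amp1 = max(max(y), 0.05), amp2 = max(-min(y), 0.02),
              lag1 = max(t[imax] - 5, 0), dlag = 10,
              k1 = 6, k2 = 6, theta1 = 1, theta2 = 1)
  start0 <- pmin(pmax(start0, lower), upper)
  # fixed canonical starts guard against the zero-amplitude local optimum
  # that the data-driven start can fall into on noisy cycle averages
  start_fix1 <- pmin(pmax(c(amp1 = max(abs(y)), amp2 = max(abs(y)) / 3,
                            lag1 = 1, dlag = 10, k1 = 6, k2 = 6,
                            theta1 = 1, theta2 = 1), lower), upper)
  start_fix2 <- pmin(pmax(c(amp1 = max(abs(y)), amp2 = max(abs(y)) / 3,
                            lag1 = 5, dlag = 15, k1 = 3, k2 = 3,
                            theta1 = 2, theta2 = 2), lower), upper)
  fits <- with_seed(rng_seed, {
    lapply(seq_len(n_starts), function(i) {
      st <- start0
      if (i == 2) st <- start_fix1
      if (i == 3) st <- start_fix2
      if (i > 3) {
        st <- start0 * exp(stats::rnorm(length(start0), 0, 0.25))
        st <- pmin(pmax(st, lower), upper)
      }
      tryCatch(stats::optim(st, obj, method = "L-BFGS-B", lower = lower,
                            upper = upper,
                            control = list(maxit = 500, factr = 1e7)),
               error = function(e) NULL)
    })
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) stop("two-gamma optimisation failed from all starts")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  p <- best$par
  names(p) <- names(lower)
  structure(list(amp1 = unname(p["amp1"]), amp2 = unname(p["amp2"]),
                 lag1 = unname(p["lag1"]), lag2 = unname(p["lag1"] + p["dlag"]),
                 k1 = unname(p["k1"]), k2 = unname(p["k2"]),
                 theta1 = unname(p["theta1"]), theta2 = unname(p["theta2"]),
                 rss = best$value, converged = best$convergence == 0,
                 fitted = two_gamma_model(t, p), window_times = t),
            class = "two_gamma_fit")
}
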