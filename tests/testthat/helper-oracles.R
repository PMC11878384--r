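# Independent oracles and small fixture builders used across the suite.

# Brute-force WPGMA: every cluster carries explicit per-leaf weights
# (halved at each merge); cluster-cluster distance is recomputed from the
# ORIGINAL leaf distance matrix at every step. Independent of the
# recursive update used by wpgma().
brute_wpgma <- function(D) {
  n <- nrow(D)
  labels <- rownames(D)
  clusters <- lapply(seq_len(n), function(i) list(leaves = i, w = 1))
  heights <- numeric(n - 1)
  coph <- matrix(0, n, n, dimnames = dimnames(D))
  cdist <- function(a, b) {
    s <- 0
    for (i in seq_along(a$leaves)) for (j in seq_along(b$leaves))
      s <- s + a$w[i] * b$w[j] * D[a$leaves[i], b$leaves[j]]
    s
  }
  for (step in seq_len(n - 1)) {
    m <- length(clusters)
    best <- c(1, 2); dmin <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      d <- cdist(clusters[[i]], clusters[[j]])
      if (d < dmin - 1e-12) { dmin <- d; best <- c(i, j) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    heights[step] <- dmin
    for (i in a$leaves) for (j in b$leaves) coph[i, j] <- coph[j, i] <- dmin
    merged <- list(leaves = c(a$leaves, b$leaves), w = c(a$w / 2, b$w / 2))
    clusters <- c(clusters[-best], list(merged))
  }
  list(heights = heights, cophenetic = coph)
}

# Exhaustive Mann-Whitney oracle: U from pairwise comparisons, null
# distribution by enumerating every split of the pooled values.
enum_mww <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  u_of <- function(x, y) {
    s <- 0
    for (xi in x) for (yi in y) s <- s + (xi > yi) + 0.5 * (xi == yi)
    s
  }
  U <- u_of(a, b)
  pooled <- c(a, b)
  combos <- utils::combn(N, n1)
  Us <- apply(combos, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  p <- min(1, 2 * min(mean(Us <= U + 1e-9), mean(Us >= U - 1e-9)))
  list(U = U, p = p)
}

# Tiny deterministic roi_ts fixture.
toy_ts <- function(n = 24, rois = c("A", "B", "C"), tr = 2, seed = 1) {
  vals <- fusefc:::with_seed(seed,
    matrix(stats::rnorm(n * length(rois)), n,
           dimnames = list(NULL, rois)))
  roi_ts((seq_len(n) - 1) * tr, vals, tr)
}

# Ground truth with every stochastic term switched off.
quiet_truth <- function(...) {
  default_truth(noise_sd = 0, latent_coupling = 0, suppression_factor = 0,
                interaction_strength = 0, drift_slope = 0,
                n_motion_regressors = 0, baseline_level = 0, ...)
}

# A small fast design: 3 conditions x `reps`, TR 2 s.
small_design <- function(seed = 1, reps = 2, n_volumes = NULL)
  default_design(seed, reps = reps, n_volumes = n_volumes)

# Direct (non-pipeline) PPI path used by recovery experiments.
ppi_betas <- function(ds, rng_seed = 1, kernel = NULL) {
  ts <- discard_initial(ds$signals, 5)
  design <- shift_design(ds$design, 5)
  psc <- compute_psc(ts, design)
  clean <- detrend_demean(psc)
  if (!is.null(ds$nuisance) && ncol(ds$nuisance) > 0)
    clean <- regress_out(clean, ds$nuisance[-(1:5), , drop = FALSE])
  clean <- suppressWarnings(lowpass_filter(clean, 0.25, 5, 40))
  seed_sig <- extract_seed(clean, seed_roi = ds$truth$seed_name)
  if (is.null(kernel)) {
    seed_ts <- roi_ts(clean$times,
                      matrix(seed_sig$values,
                             dimnames = list(NULL, ds$truth$seed_name)),
                      clean$tr)
    kernel <- tryCatch(
      two_gamma_kernel(fit_two_gamma(cycle_average(seed_ts, design, "heat"),
                                     rng_seed = rng_seed)),
      error = function(e) canonical_hrf())
  }
  ppi <- build_ppi(seed_sig, design, kernel)
  dm <- build_design(design, conditions = unique(design$events$condition))
  fit_efc(clean, ppi, dm)$table
}
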