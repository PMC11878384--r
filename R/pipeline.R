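# End-to-end pipeline runner: preprocessing -> activation GLM -> PSC and
# cycle averages -> two-gamma seed kernel -> PPI effective connectivity ->
# WPGMA clustering -> network comparison, emitting one deterministic
# report.

#' Pipeline configuration
#'
#' Defaults follow the analysis conventions: discard 5 volumes, 70 percent
#' cumulative-variance nuisance PCA, 0.25 Hz Chebyshev II low-pass, t > 2
#' with FDR q 0.05 and 2-voxel contiguity for activation, dendrogram cut at
#' cophenetic distance 0.7, inter-ROI matrix threshold r > 0.3, Dice
#' validity delta-r 0.15 and edge export above r > 0.5.
#'
#' @param ... Overrides of any default listed below.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(n_discard = 5, cum_var = 0.70, cutoff = 0.25, filter_order = 5,
              stop_atten = 40, t_min = 2, q_max = 0.05, min_contig = 2,
              connectivity = 6, cut_height = 0.7, r_threshold = 0.3,
              delta_r = 0.15, r_min = 0.5, window_s = 46,
              psc_baseline = "final10s", hrf_source = "two_gamma",
              seed_roi = "VPL", conditions = c("heat", "heat_fus"),
              rng_seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_invalid("config", paste("unknown parameters:",
                                 paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  check_scalar(cfg$n_discard, "n_discard", lower = 0)
  check_scalar(cfg$cum_var, "cum_var", lower = 0, upper = 1,
               allow_equal_lower = FALSE)
  check_scalar(cfg$cutoff, "cutoff", lower = 0, allow_equal_lower = FALSE)
  check_scalar(cfg$q_max, "q_max", lower = 0, upper = 1)
  check_scalar(cfg$cut_height, "cut_height", lower = 0)
  check_scalar(cfg$delta_r, "delta_r", lower = 0)
  if (!cfg$hrf_source %in% c("two_gamma", "canonical"))
    stop_invalid("hrf_source", "must be 'two_gamma' or 'canonical'")
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys override [pipeline_config()] defaults.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline on one dataset
#'
#' Stages: initial-volume discard and PSC conversion; detrend/demean,
#' nuisance regression and low-pass filtering; condition GLM on the ROI
#' series; seed extraction, cycle averaging and two-gamma kernel fitting;
#' PPI effective-connectivity GLM; per-condition feature clustering
#' (WPGMA), cophenetic statistics and cut at the configured height;
#' condition-masked inter-ROI correlation matrices; Dice similarity,
#' correlation-power change, per-subnetwork rank-sum comparisons and edge
#' export.
#'
#' @param dataset A `synthetic_dataset` (or the list returned by
#'   [read_dataset()]).
#' @param config A [pipeline_config()].
#' @return Report list of class `efc_report`; serialize with
#'   [report_json()].
#' @export
run_pipeline <- function(dataset, config = pipeline_config()) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  conds <- config$conditions
  seed0 <- config$rng_seed

  ts <- discard_initial(dataset$signals, config$n_discard)
  design <- shift_design(dataset$design, config$n_discard)
  psc <- compute_psc(ts, design, baseline = config$psc_baseline)
  conf <- dataset$nuisance
  if (!is.null(conf) && nrow(conf) > 0 && config$n_discard > 0)
    conf <- conf[-seq_len(config$n_discard), , drop = FALSE]
  clean <- detrend_demean(psc)
  if (!is.null(conf) && ncol(conf) > 0) clean <- regress_out(clean, conf)
  clean <- suppressWarnings(
    lowpass_filter(clean, config$cutoff, config$filter_order,
                   config$stop_atten))

  dm <- build_design(design, conditions = unique(design$events$condition))
  act_glm <- fit_glm(clean$values, dm)
  activation <- lapply(stats::setNames(conds, conds), function(cond) {
    fdr <- bh_fdr(act_glm$p[, cond], config$q_max)
    data.frame(roi = rownames(act_glm$beta), beta = act_glm$beta[, cond],
               t = act_glm$t[, cond], q = fdr$adjusted,
               active = fdr$reject & act_glm$t[, cond] > config$t_min,
               row.names = NULL)
  })

  seed_sig <- extract_seed(clean, seed_roi = config$seed_roi)
  seed_ts <- roi_ts(clean$times,
                    matrix(seed_sig$values, dimnames = list(NULL, config$seed_roi)),
                    clean$tr)
  seed_cycle <- cycle_average(seed_ts, design, "heat", config$window_s)
  seed_fit <- fit_two_gamma(seed_cycle, rng_seed = derive_seed(seed0, 1))
  kernel <- if (config$hrf_source == "two_gamma") {
    tryCatch(two_gamma_kernel(seed_fit), error = function(e) {
      warning("degenerate two-gamma seed fit; using the canonical HRF")
      canonical_hrf()
    })
  } else canonical_hrf()

  ppi <- build_ppi(seed_sig, design, kernel, conditions = conds)
  efc <- fit_efc(clean, ppi, dm, run_id = paste0("seed", dataset$rng_seed))

  # clustering and inter-ROI comparison cover the cortical targets: the
  # seed anchors the EFC analysis but is not itself a network member
  rois <- setdiff(colnames(clean$values), config$seed_roi)
  clean_t <- roi_ts(clean$times, clean$values[, rois, drop = FALSE], clean$tr)
  corr <- lapply(stats::setNames(conds, conds), function(cond)
    inter_roi_corr(clean_t, config$r_threshold, design, cond))

  cluster_one <- function(cond, stage) {
    cycles <- lapply(stats::setNames(rois, rois), function(r) {
      one <- roi_ts(clean$times, clean$values[, r, drop = FALSE], clean$tr)
      cycle_average(one, design, cond, config$window_s)
    })
    fits <- lapply(stats::setNames(rois, rois), function(r)
      fit_two_gamma(cycles[[r]], rng_seed = derive_seed(seed0, stage + match(r, rois))))
    eb <- efc$table[efc$table$condition == cond, ]
    betas <- stats::setNames(eb$beta, eb$roi)
    feat <- build_features(fits, betas, cycles)
    dendro <- wpgma(feat)
    coph <- cophenetic_distances(dendro)
    part <- cut_dendrogram(dendro, config$cut_height)
    list(dendrogram = dendro, newick = to_newick(dendro),
         cophenetic_correlation = coph$correlation, partition = part)
  }
  clus <- list(heat = cluster_one("heat", 100),
               heat_fus = cluster_one("heat_fus", 200))

  dice <- dice_similarity(corr$heat, corr$heat_fus, config$delta_r,
                          config$r_threshold)
  power <- correlation_power_change(corr$heat, corr$heat_fus)
  subnet <- withCallingHandlers(
    subnetwork_stats(clus$heat$partition, corr$heat, corr$heat_fus),
    warning = function(w) invokeRestart("muffleWarning"))
  edges <- export_edges(corr$heat, clus$heat$partition, config$r_min)

  structure(list(
    config = unclass(config),
    n_volumes_analysed = nrow(clean$values),
    activation = activation,
    efc = efc$table,
    seed_fit = seed_fit[c("amp1", "amp2", "lag1", "lag2", "rss", "converged")],
    cophenetic_correlation = lapply(clus, `[[`, "cophenetic_correlation"),
    newick = lapply(clus, `[[`, "newick"),
    partition = lapply(clus, function(cl) as.list(cl$partition$labels)),
    n_subnetworks = lapply(clus, function(cl) max(cl$partition$labels)),
    inter_roi_corr = lapply(corr, function(cc) round(cc$r, 10)),
    dice = dice[c("dice", "n_x", "n_y", "n_overlap", "empty")],
    power_change_pct = power,
    subnetwork_stats = subnet,
    edges = edges,
    rng_seed = seed0
  ), class = "efc_report")
}

#' Serialize a pipeline report to canonical JSON
#'
#' Deterministic: the same dataset, configuration and seed produce a
#' byte-identical string.
#'
#' @param report An `efc_report`.
#' @param path Optional file to write.
#' @return The JSON string, invisibly when `path` is given.
#' @export
report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = 10,
                         dataframe = "columns", na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
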