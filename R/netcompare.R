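# Network similarity statistics between the two stimulation conditions:
# Dice overlap of suprathreshold edge sets (with a |delta r| validity
# criterion), percentage change in correlation power (sum of squared
# inter-ROI correlations), per-subnetwork summaries with rank-sum
# comparison, and weighted edge export for graph rendering.

upper_pairs <- function(corr) {
  r <- corr$r
  ut <- which(upper.tri(r), arr.ind = TRUE)
  data.frame(from = rownames(r)[ut[, 1]], to = colnames(r)[ut[, 2]],
             r = r[ut], stringsAsFactors = FALSE)
}

check_same_rois <- function(corrH, corrHF) {
  stopifnot(inherits(corrH, "inter_roi_corr"), inherits(corrHF, "inter_roi_corr"))
  if (!identical(rownames(corrH$r), rownames(corrHF$r)))
    stop_invalid("corrHF", "ROI sets/ordering differ between conditions")
}

#' Dice similarity between two condition networks
#'
#' X and Y are the upper-triangle edge sets whose correlation exceeds
#' `edge_threshold` in each condition; a pair counts as overlapping when it
#' is suprathreshold in both conditions AND its correlations differ by at
#' most `delta_r`. Dice = 2|X n Y| / (|X| + |Y|).
#'
#' @param corrH,corrHF `inter_roi_corr` objects for the two conditions.
#' @param delta_r Validity criterion on |r_H - r_HF|.
#' @param edge_threshold Suprathreshold criterion on r (signed).
#' @return List with `dice` (NA when both edge sets are empty), `n_x`,
#'   `n_y`, `n_overlap`, `empty`, `edges` (per-pair table).
#' @export
dice_similarity <- function(corrH, corrHF, delta_r = 0.15,
                            edge_threshold = 0.3) {
  check_same_rois(corrH, corrHF)
  eh <- upper_pairs(corrH)
  ef <- upper_pairs(corrHF)
  edges <- data.frame(from = eh$from, to = eh$to, r_heat = eh$r,
                      r_heat_fus = ef$r, stringsAsFactors = FALSE)
  edges$in_x <- edges$r_heat > edge_threshold
  edges$in_y <- edges$r_heat_fus > edge_threshold
  edges$overlap <- edges$in_x & edges$in_y &
    abs(edges$r_heat - edges$r_heat_fus) <= delta_r + 1e-12
  nx <- sum(edges$in_x); ny <- sum(edges$in_y); nov <- sum(edges$overlap)
  empty <- (nx + ny) == 0
  list(dice = if (empty) NA_real_ else 2 * nov / (nx + ny),
       n_x = nx, n_y = ny, n_overlap = nov, empty = empty, edges = edges)
}

#' Percentage change in correlation power between conditions
#'
#' `100 * sum(r_H^2 - r_HF^2) / sum(r_H^2)` over a chosen upper-triangle
#' edge set; positive values mean the second condition lost correlation
#' power.
#'
#' @param corrH,corrHF `inter_roi_corr` objects.
#' @param edge_set `"heat_suprathreshold"` (default; pairs above threshold
#'   under the first condition), `"all"` pairs, or `"union"` of the two
#'   suprathreshold sets.
#' @return Percentage (scalar).
#' @export
correlation_power_change <- function(corrH, corrHF,
                                     edge_set = c("heat_suprathreshold",
                                                  "all", "union")) {
  edge_set <- match.arg(edge_set)
  check_same_rois(corrH, corrHF)
  ut <- upper.tri(corrH$r)
  rH <- corrH$r[ut]; rHF <- corrHF$r[ut]
  keep <- switch(edge_set,
                 heat_suprathreshold = rH > corrH$threshold,
                 all = rep(TRUE, length(rH)),
                 union = rH > corrH$threshold | rHF > corrHF$threshold)
  denom <- sum(rH[keep]^2)
  if (denom == 0) stop_invalid("corrH", "edge set has zero correlation power")
  100 * sum(rH[keep]^2 - rHF[keep]^2) / denom
}

#' Per-subnetwork correlation summaries and condition comparison
#'
#' For each subnetwork with at least two ROIs: the within-subnetwork
#' upper-triangle correlations per condition, their median and quartiles,
#' and a Mann-Whitney-Wilcoxon comparison between conditions.
#'
#' @param partition A `partition` covering the ROI set.
#' @param corrH,corrHF `inter_roi_corr` objects.
#' @return Data frame with one row per subnetwork: sizes, medians,
#'   quartiles, `mww_p`, `degenerate` (TRUE when only one pair exists per
#'   condition). Subnetworks of size < 2 are dropped with a warning.
#' @export
subnetwork_stats <- function(partition, corrH, corrHF) {
  stopifnot(inherits(partition, "partition"))
  check_same_rois(corrH, corrHF)
  rois <- rownames(corrH$r)
  if (!all(rois %in% names(partition$labels)))
    stop_invalid("partition", "does not cover the ROI set")
  labs <- partition$labels[rois]
  out <- list()
  for (s in sort(unique(labs))) {
    members <- rois[labs == s]
    if (length(members) < 2) {
      warning(sprintf("subnetwork %d has < 2 ROIs; excluded", s))
      next
    }
    ut <- upper.tri(corrH$r[members, members])
    vh <- corrH$r[members, members][ut]
    vf <- corrHF$r[members, members][ut]
    mww <- compare_mww(vh, vf)
    qs_h <- stats::quantile(vh, c(0.25, 0.5, 0.75), names = FALSE)
    qs_f <- stats::quantile(vf, c(0.25, 0.5, 0.75), names = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      subnetwork = s, n_rois = length(members), n_pairs = length(vh),
      heat_q1 = qs_h[1], heat_median = qs_h[2], heat_q3 = qs_h[3],
      heat_fus_q1 = qs_f[1], heat_fus_median = qs_f[2], heat_fus_q3 = qs_f[3],
      mww_U = mww$U, mww_p = mww$p, degenerate = length(vh) < 2)
  }
  do.call(rbind, out)
}

#' Export suprathreshold edges for graph rendering
#'
#' @param corr An `inter_roi_corr`.
#' @param partition Optional `partition` supplying endpoint subnetwork ids.
#' @param r_min Minimum correlation for an edge to be exported.
#' @return Data frame: from, to, weight, sub_from, sub_to.
#' @export
export_edges <- function(corr, partition = NULL, r_min = 0.5) {
  stopifnot(inherits(corr, "inter_roi_corr"))
  e <- upper_pairs(corr)
  e <- e[e$r > r_min, , drop = FALSE]
  names(e)[names(e) == "r"] <- "weight"
  if (!is.null(partition)) {
    e$sub_from <- unname(partition$labels[e$from])
    e$sub_to <- unname(partition$labels[e$to])
  } else {
    e$sub_from <- NA_integer_
    e$sub_to <- NA_integer_
  }
  rownames(e) <- NULL
  e
}
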