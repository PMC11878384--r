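# WPGMA hierarchical clustering of ROI feature vectors under a
# correlation metric, cophenetic distances/correlation, dendrogram cutting
# into subnetworks, condition-masked inter-ROI correlation matrices and
# Newick export.

#' Per-ROI feature vectors for clustering
#'
#' Concatenates, per ROI: two-gamma amplitudes and lags, the mean EFC beta,
#' and the cycle-averaged PSC samples. Each feature dimension is z-scored
#' across ROIs (constant dimensions are set to zero), so heterogeneous
#' units (PSC %, seconds, beta) are commensurable before the correlation
#' distance.
#'
#' @param fits Named list of `two_gamma_fit`, one per ROI.
#' @param betas Named numeric vector of mean EFC betas per ROI (or an
#'   `efc_result`, in which case betas are averaged over conditions).
#' @param cycles Named list of `cycle_average`, one per ROI.
#' @return Numeric matrix, ROI x feature, z-scored columns.
#' @export
build_features <- function(fits, betas, cycles) {
  if (inherits(betas, "efc_result"))
    betas <- tapply(betas$table$beta, betas$table$roi, mean)
  rois <- names(fits)
  missing_beta <- setdiff(rois, names(betas))
  missing_cyc <- setdiff(rois, names(cycles))
  if (length(missing_beta) || length(missing_cyc))
    stop_invalid("betas/cycles",
                 paste("missing ROIs:",
                       paste(union(missing_beta, missing_cyc), collapse = ", ")))
  feat <- t(vapply(rois, function(r) {
    f <- fits[[r]]
    c(amp1 = f$amp1, amp2 = f$amp2, lag1 = f$lag1, lag2 = f$lag2,
      mean_beta = unname(betas[r]),
      stats::setNames(cycles[[r]]$mean_psc,
                      paste0("psc", seq_along(cycles[[r]]$mean_psc))))
  }, numeric(5 + length(cycles[[rois[1]]]$mean_psc))))
  mu <- colMeans(feat)
  sdv <- apply(feat, 2, stats::sd)
  z <- sweep(feat, 2, mu)
  z <- sweep(z, 2, ifelse(sdv > 0, sdv, 1), "/")
  z[, sdv == 0] <- 0
  rownames(z) <- rois
  z
}

# Pearson-correlation distance between matrix rows: d = 1 - r.
correlation_distance <- function(feat) {
  if (nrow(feat) < 2) stop_invalid("features", "need at least 2 items")
  sds <- apply(feat, 1, stats::sd)
  if (any(sds == 0))
    stop_invalid("features", paste("constant feature vector for:",
                                   paste(rownames(feat)[sds == 0], collapse = ", ")))
  1 - stats::cor(t(feat))
}

#' WPGMA hierarchical clustering
#'
#' Iteratively merges the closest pair of clusters; the merged cluster's
#' distance to any other cluster is the unweighted mean of its two parts'
#' distances (the weighted pair-group rule, in which the two merged
#' branches count equally regardless of size). Ties are broken
#' deterministically by the lexicographically smallest leaf names.
#'
#' @param x Either a feature matrix (ROI x feature; distances are
#'   `1 - Pearson r` between rows) or a symmetric distance matrix /
#'   `dist` object.
#' @param is_distance Set TRUE to force `x` to be treated as distances.
#' @return Object of class `efc_dendrogram` with `merges` (n-1 x 2,
#'   hclust convention: negative = leaf index), `heights`, `labels`, and
#'   the input `distance` matrix.
#' @export
wpgma <- function(x, is_distance = inherits(x, "dist") ||
                    (is.matrix(x) && isSymmetric(unname(x)) &&
                       all(abs(diag(x)) < 1e-12))) {
  D <- if (inherits(x, "dist")) as.matrix(x)
       else if (is_distance) as.matrix(x)
       else correlation_distance(x)
  n <- nrow(D)
  if (n < 2) stop_invalid("x", "need at least 2 items")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("item", seq_len(n))
  dimnames(D) <- list(labels, labels)
  active_id <- -seq_len(n)            # hclust convention
  active_min <- labels                # smallest leaf name per cluster
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(active_id)
    dmin <- Inf; best <- NULL
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      dij <- D[i, j]
      if (dij < dmin - 1e-12) {
        dmin <- dij; best <- c(i, j)
      } else if (abs(dij - dmin) <= 1e-12) {
        # lexicographic tie-break on the pair of smallest leaf names
        cand <- sort(c(active_min[i], active_min[j]))
        cur <- sort(c(active_min[best[1]], active_min[best[2]]))
        if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
          dmin <- dij; best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- dmin
    pair <- active_id[c(i, j)]
    ord <- order(active_min[c(i, j)])
    merges[step, ] <- pair[ord]
    newd <- (D[i, ] + D[j, ]) / 2
    newmin <- min(active_min[i], active_min[j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    active_id <- c(active_id[keep], step)
    active_min <- c(active_min[keep], newmin)
  }
  structure(list(merges = merges, heights = heights, labels = labels,
                 distance = if (inherits(x, "dist") || is_distance)
                   as.matrix(x) else correlation_distance(x)),
            class = "efc_dendrogram")
}

# Leaf index sets below each merge node.
merge_leafsets <- function(dendro) {
  n <- length(dendro$labels)
  sets <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    grab <- function(id) if (id < 0) -id else sets[[id]]
    sets[[k]] <- c(grab(dendro$merges[k, 1]), grab(dendro$merges[k, 2]))
  }
  sets
}

#' Convert to a stats::hclust object
#'
#' @param dendro An `efc_dendrogram`.
#' @return An object of class `hclust` (usable with plot, cutree, ...).
#' @export
as_hclust <- function(dendro) {
  sets <- merge_leafsets(dendro)
  ord <- sets[[length(sets)]]
  structure(list(merge = dendro$merges, height = dendro$heights,
                 order = ord, labels = dendro$labels, method = "mcquitty",
                 call = match.call(), dist.method = "correlation"),
            class = "hclust")
}

#' Cophenetic distances and cophenetic correlation
#'
#' The cophenetic distance of a pair of leaves is the height of their
#' lowest common merge; the cophenetic correlation is the Pearson
#' correlation between upper-triangle cophenetic and original distances.
#'
#' @param dendro An `efc_dendrogram`.
#' @param original_dist Optional distance matrix (defaults to the one
#'   stored in the dendrogram).
#' @return List with `matrix` (cophenetic distances), `correlation`
#'   (NA with `degenerate = TRUE` when fewer than 3 leaves give a single
#'   pair), and `degenerate`.
#' @export
cophenetic_distances <- function(dendro, original_dist = dendro$distance) {
  n <- length(dendro$labels)
  cm <- matrix(0, n, n, dimnames = list(dendro$labels, dendro$labels))
  sets <- merge_leafsets(dendro)
  # process merges in order: first time a pair is joined sets its height
  done <- matrix(FALSE, n, n)
  for (k in seq_len(n - 1)) {
    left <- if (dendro$merges[k, 1] < 0) -dendro$merges[k, 1] else
      sets[[dendro$merges[k, 1]]]
    right <- if (dendro$merges[k, 2] < 0) -dendro$merges[k, 2] else
      sets[[dendro$merges[k, 2]]]
    for (a in left) for (b in right) {
      cm[a, b] <- cm[b, a] <- dendro$heights[k]
    }
  }
  ut <- upper.tri(cm)
  degenerate <- sum(ut) < 2
  corr <- if (degenerate) NA_real_ else {
    od <- as.matrix(original_dist)
    if (stats::sd(cm[ut]) == 0 || stats::sd(od[ut]) == 0) NA_real_
    else stats::cor(cm[ut], od[ut])
  }
  list(matrix = cm, correlation = corr, degenerate = degenerate)
}

#' Cut a dendrogram into subnetworks
#'
#' Clusters are the connected subtrees all of whose internal merges lie
#' strictly below `height`. Labels are assigned in order of each cluster's
#' first leaf, so the labelling is deterministic.
#'
#' @param dendro An `efc_dendrogram`.
#' @param height Cut height (cophenetic distance units).
#' @return Object of class `partition`: `cut_height` and named integer
#'   `labels`.
#' @export
cut_dendrogram <- function(dendro, height = 0.7) {
  check_scalar(height, "height", lower = 0)
  n <- length(dendro$labels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  sets <- merge_leafsets(dendro)
  for (k in seq_len(n - 1)) {
    if (dendro$heights[k] >= height) next
    leaves <- sets[[k]]
    r <- find(leaves[1])
    for (l in leaves[-1]) parent[find(l)] <- r
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- unique(roots)
  labels <- match(roots, ids)
  structure(list(cut_height = height,
                 labels = stats::setNames(as.integer(labels), dendro$labels)),
            class = "partition")
}

#' Inter-ROI correlation matrix
#'
#' Pearson correlation between ROI time courses, optionally restricted to
#' one condition's stimulation cycles (block + following rest). Entries at
#' or below the threshold stay in the matrix but are flagged
#' sub-threshold in `supra`.
#'
#' @param ts A `roi_ts`.
#' @param threshold Reporting threshold on r.
#' @param design Optional [stimulus_design()] for condition masking.
#' @param condition Condition whose cycles to keep (requires `design`).
#' @return Object of class `inter_roi_corr`: `r`, `supra` (logical),
#'   `threshold`, `condition`, `n_timepoints`.
#' @export
inter_roi_corr <- function(ts, threshold = 0.3, design = NULL,
                           condition = NULL) {
  stopifnot(inherits(ts, "roi_ts"))
  vals <- ts$values
  if (!is.null(condition)) {
    if (is.null(design)) stop_invalid("design", "needed for condition masking")
    cyc <- cycle_condition(design, ts$times)
    vals <- vals[cyc == condition, , drop = FALSE]
  }
  if (nrow(vals) < 3) stop_invalid("ts", "need >= 3 time points after masking")
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0))
    stop_invalid("ts", paste("constant ROI column:",
                             paste(colnames(vals)[sds == 0], collapse = ", ")))
  r <- stats::cor(vals)
  structure(list(r = r, supra = r > threshold, threshold = threshold,
                 condition = if (is.null(condition)) NA_character_ else condition,
                 n_timepoints = nrow(vals)),
            class = "inter_roi_corr")
}

#' Export a dendrogram as a Newick string
#'
#' Ultrametric convention: each internal node sits at half its merge
#' height, so the path length between two leaves equals their cophenetic
#' distance. A two-leaf tree at height h renders as `(A:h/2,B:h/2);`.
#'
#' @param dendro An `efc_dendrogram`.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string (terminated with `;`).
#' @export
to_newick <- function(dendro, digits = 10) {
  node_h <- dendro$heights / 2
  render <- function(id, parent_h) {
    if (id < 0) {
      sprintf("%s:%.*g", dendro$labels[-id], digits, parent_h)
    } else {
      h <- node_h[id]
      sprintf("(%s,%s):%.*g",
              render(dendro$merges[id, 1], h),
              render(dendro$merges[id, 2], h),
              digits, parent_h - h)
    }
  }
  root <- length(dendro$heights)
  h <- node_h[root]
  sprintf("(%s,%s);",
          render(dendro$merges[root, 1], h),
          render(dendro$merges[root, 2], h))
}
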