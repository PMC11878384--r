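# Voxelwise activation detection: FDR over in-mask voxels, conjunctive
# t-threshold, and cluster-extent filtering under configurable 3D
# connectivity.

neighbour_offsets <- function(connectivity) {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  dist <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  keep <- switch(as.character(connectivity),
                 "6" = dist == 1,
                 "18" = dist <= 2,
                 "26" = rep(TRUE, nrow(offs)),
                 stop_invalid("connectivity", "must be 6, 18 or 26"))
  as.matrix(offs[keep, ])
}

# Label connected components of a logical 3D array via breadth-first
# search over the chosen neighbourhood.
label_components <- function(flag, connectivity = 6) {
  dims <- dim(flag)
  offs <- neighbour_offsets(connectivity)
  labels <- array(0L, dims)
  nxt <- 0L
  idx <- which(flag, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    if (labels[v[1], v[2], v[3]] != 0L) next
    nxt <- nxt + 1L
    queue <- matrix(v, 1)
    labels[v[1], v[2], v[3]] <- nxt
    while (nrow(queue) > 0) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        nb <- cur + offs[k, ]
        if (any(nb < 1) || any(nb > dims)) next
        if (flag[nb[1], nb[2], nb[3]] && labels[nb[1], nb[2], nb[3]] == 0L) {
          labels[nb[1], nb[2], nb[3]] <- nxt
          queue <- rbind(queue, nb)
        }
      }
    }
  }
  labels
}

#' Detect stimulus-driven activation in statistical maps
#'
#' Applies Benjamini-Hochberg FDR across in-mask voxels, keeps voxels
#' passing both the t threshold and the FDR level conjunctively, labels
#' connected components under the chosen voxel connectivity, and removes
#' clusters smaller than `min_contig` voxels.
#'
#' @param t_map,p_map 3D numeric arrays of matching shape.
#' @param brain_mask Optional logical array restricting the FDR family
#'   (default: all voxels).
#' @param t_min t threshold (voxels must exceed it).
#' @param q_max FDR level.
#' @param min_contig Minimum cluster extent, voxels.
#' @param connectivity 6 (faces), 18 or 26.
#' @return Object of class `activation_map` with `t_map`, `q_map`, `mask`
#'   (logical array of retained voxels), `cluster_labels` and `thresholds`.
#' @export
detect_activation <- function(t_map, p_map, brain_mask = NULL, t_min = 2,
                              q_max = 0.05, min_contig = 2, connectivity = 6) {
  t_map <- as.array(t_map); p_map <- as.array(p_map)
  if (!identical(dim(t_map), dim(p_map)))
    stop_invalid("p_map", "shape must match t_map")
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim(t_map))
  if (!identical(dim(brain_mask), dim(t_map)))
    stop_invalid("brain_mask", "shape must match t_map")
  q_map <- array(NA_real_, dim(t_map))
  inb <- which(brain_mask)
  fdr <- bh_fdr(p_map[inb], q_max)
  q_map[inb] <- fdr$adjusted
  supra <- array(FALSE, dim(t_map))
  supra[inb] <- fdr$reject & t_map[inb] > t_min
  labels <- label_components(supra, connectivity)
  if (max(labels) > 0) {
    sizes <- tabulate(labels[labels > 0])
    small <- which(sizes < min_contig)
    supra[labels %in% small] <- FALSE
    labels[labels %in% small] <- 0L
    # relabel compactly
    keepers <- sort(unique(labels[labels > 0]))
    relab <- integer(max(c(labels, 1L)))
    relab[keepers] <- seq_along(keepers)
    labels[labels > 0] <- relab[labels[labels > 0]]
  }
  structure(list(t_map = t_map, q_map = q_map, mask = supra,
                 cluster_labels = labels,
                 thresholds = list(t_min = t_min, q_max = q_max,
                                   min_contig = min_contig,
                                   connectivity = connectivity)),
            class = "activation_map")
}
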