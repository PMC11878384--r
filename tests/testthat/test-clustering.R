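test_that("build_features concatenates, z-scores, and is scale invariant", {
  t <- seq(0, 44, 2)
  mk_fit <- function(a1) structure(list(amp1 = a1, amp2 = 0.2, lag1 = 2,
                                        lag2 = 12, k1 = 6, k2 = 6,
                                        theta1 = 1, theta2 = 1, rss = 0,
                                        converged = TRUE),
                                   class = "two_gamma_fit")
  mk_cyc <- function(scale) structure(list(window_times = t,
                                           mean_psc = scale * sin(t / 5),
                                           se_psc = rep(0, length(t)),
                                           n_cycles = 7, condition = "heat"),
                                      class = "cycle_average")
  fits <- list(A = mk_fit(1), B = mk_fit(2), C = mk_fit(3))
  cycles <- list(A = mk_cyc(1), B = mk_cyc(2), C = mk_cyc(0.5))
  betas <- c(A = 0.1, B = 0.3, C = 0.2)
  f <- build_features(fits, betas, cycles)
  expect_equal(rownames(f), c("A", "B", "C"))
  nontrivial <- apply(f, 2, sd) > 0
  expect_equal(unname(colMeans(f)), rep(0, ncol(f)), tolerance = 1e-12)
  expect_equal(unname(apply(f[, nontrivial], 2, sd)),
               rep(1, sum(nontrivial)), tolerance = 1e-12)
  # scaling every PSC by 10 leaves the z-scored features unchanged
  cycles10 <- lapply(cycles, function(cc) { cc$mean_psc <- 10 * cc$mean_psc; cc })
  expect_equal(build_features(fits, betas, cycles10), f, tolerance = 1e-10)
  expect_error(build_features(fits, betas[1:2], cycles), "missing ROIs")
})

test_that("wpgma reproduces a pencil-and-paper 4-point linkage", {
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 1
  D["A", "C"] <- D["C", "A"] <- 4
  D["A", "D"] <- D["D", "A"] <- 5
  D["B", "C"] <- D["C", "B"] <- 4
  D["B", "D"] <- D["D", "B"] <- 5
  D["C", "D"] <- D["D", "C"] <- 2
  dd <- wpgma(D, is_distance = TRUE)
  # merges: (A,B)@1, (C,D)@2, then ((AB),(CD)) at (4+5)/2 = 4.5
  expect_equal(dd$heights, c(1, 2, 4.5))
  expect_equal(dd$merges[1, ], c(-1, -2))
  expect_equal(dd$merges[2, ], c(-3, -4))
  expect_equal(sort(dd$merges[3, ]), c(1, 2))
})

test_that("wpgma handles identical and anti-correlated feature vectors", {
  f <- rbind(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4), C = c(4, 3, 2, 1))
  dd <- wpgma(f)
  expect_equal(dd$heights[1], 0)            # identical pair merges first
  expect_equal(max(dd$heights), 2)          # d = 1 - (-1) for the anti pair
  expect_error(wpgma(rbind(A = c(1, 1, 1), B = c(1, 2, 3))), "constant")
  expect_error(wpgma(matrix(1, 1, 3)), "at least 2")
})

test_that("wpgma agrees with stats::hclust(method = 'mcquitty')", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(3:7, 1)
    D <- as.matrix(dist(matrix(runif(n * 3), n)))
    dimnames(D) <- list(letters[1:n], letters[1:n])
    mine <- wpgma(D, is_distance = TRUE)
    ref <- hclust(as.dist(D), method = "mcquitty")
    expect_equal(sort(mine$heights), sort(ref$height), tolerance = 1e-10)
    cref <- as.matrix(stats::cophenetic(ref))[letters[1:n], letters[1:n]]
    expect_equal(cophenetic_distances(mine)$matrix, cref, tolerance = 1e-10)
  }
})

test_that("cophenetic distances are max-ultrametric and faithful", {
  set.seed(5)
  D <- as.matrix(dist(matrix(runif(18), 6)))
  dimnames(D) <- list(letters[1:6], letters[1:6])
  cm <- cophenetic_distances(wpgma(D, is_distance = TRUE))$matrix
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(cm[i, k], max(cm[i, j], cm[j, k]) + 1e-12)
  # a perfectly ultrametric input is reproduced with correlation 1
  co <- cophenetic_distances(wpgma(cm, is_distance = TRUE), cm)
  expect_equal(co$matrix, cm, tolerance = 1e-10)
  expect_equal(co$correlation, 1, tolerance = 1e-10)
  # two leaves: a single pair has no defined correlation
  d2 <- wpgma(matrix(c(0, 1, 1, 0), 2,
                     dimnames = list(c("A", "B"), c("A", "B"))),
              is_distance = TRUE)
  co2 <- cophenetic_distances(d2)
  expect_true(co2$degenerate)
  expect_true(is.na(co2$correlation))
})

test_that("cut_dendrogram spans singletons to one cluster and is stable", {
  set.seed(9)
  X <- matrix(rnorm(6 * 4), 6, dimnames = list(letters[1:6], NULL))
  dd <- wpgma(X)
  expect_equal(max(cut_dendrogram(dd, max(dd$heights) + 1)$labels), 1)
  expect_equal(max(cut_dendrogram(dd, 0)$labels), 6)
  # invariance to leaf input order (up to relabelling)
  p <- sample(6)
  dd2 <- wpgma(X[p, ])
  l1 <- cut_dendrogram(dd, 0.8)$labels
  l2 <- cut_dendrogram(dd2, 0.8)$labels[names(l1)]
  expect_equal(adjusted_rand_index(l1, l2), 1)
})

test_that("inter_roi_corr matches hand-computed Pearson r", {
  x <- c(1, 3, 2, 5, 4, 6); y <- c(2, 2, 3, 6, 4, 5)
  ts <- roi_ts(0:5, cbind(A = x, B = y, C = x), 1)
  ic <- inter_roi_corr(ts, threshold = 0.3)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ic$r["A", "B"], r_hand, tolerance = 1e-12)
  expect_equal(diag(ic$r), c(A = 1, B = 1, C = 1))
  expect_equal(ic$r["A", "C"], 1)
  expect_true(isSymmetric(ic$r))
  expect_error(inter_roi_corr(roi_ts(0:5, cbind(A = x, B = rep(1, 6)), 1)),
               "constant")
})

test_that("condition masking restricts the correlation window", {
  tr <- default_truth(noise_sd = 0.05)
  ds <- simulate_dataset(small_design(3, reps = 2), tr, rng_seed = 8)
  ih <- inter_roi_corr(ds$signals, design = ds$design, condition = "heat")
  expect_lt(ih$n_timepoints, ds$design$n_volumes)
  expect_equal(ih$condition, "heat")
})

test_that("newick export round-trips through an independent parser", {
  # two leaves at height h: (A:h/2,B:h/2);
  d2 <- wpgma(matrix(c(0, 1.2, 1.2, 0), 2,
                     dimnames = list(c("A", "B"), c("A", "B"))),
              is_distance = TRUE)
  expect_equal(to_newick(d2), "(A:0.6,B:0.6);")
  skip_if_not_installed("ape")
  set.seed(13)
  D <- as.matrix(dist(matrix(runif(15), 5)))
  dimnames(D) <- list(paste0("r", 1:5), paste0("r", 1:5))
  dd <- wpgma(D, is_distance = TRUE)
  tre <- ape::read.tree(text = to_newick(dd))
  cm <- ape::cophenetic.phylo(tre)
  mine <- cophenetic_distances(dd)$matrix
  expect_equal(cm[rownames(mine), colnames(mine)], mine, tolerance = 1e-8)
})

test_that("dendrogram heights stay inside [0, 2] under correlation distance", {
  set.seed(17)
  for (i in 1:10) {
    f <- matrix(rnorm(5 * 8), 5, dimnames = list(letters[1:5], NULL))
    h <- wpgma(f)$heights
    expect_true(all(h >= -1e-12 & h <= 2 + 1e-12))
    expect_true(all(diff(h) >= -1e-12))  # monotone merge heights
  }
})
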