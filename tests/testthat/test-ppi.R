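test_that("extract_seed averages qualifying voxels and centres the result", {
  # 4-voxel toy: half the voxels suprathreshold
  dims <- c(2, 2, 1); n <- 30
  series <- matrix(rnorm(4 * n), 4)
  vol <- array(t(series), c(n, dims))
  vol <- aperm(vol, c(2, 3, 4, 1))
  t_map <- array(c(5, 5, 0, 0), dims)
  p_map <- array(c(1e-5, 1e-5, 0.9, 0.9), dims)
  act <- detect_activation(t_map, p_map, min_contig = 1)
  seed_mask <- array(TRUE, dims)
  s <- extract_seed(vol, activation = act, seed_mask = seed_mask)
  expect_equal(s$source_voxel_count, 2)
  expected <- drop(detrend_demean(matrix(colMeans(series[1:2, ]), ncol = 1)))
  expect_equal(s$values, expected, tolerance = 1e-10)
  # zero mean and zero OLS slope by construction
  expect_lt(abs(mean(s$values)), 1e-10)
  expect_lt(abs(coef(lm(s$values ~ seq_len(n)))[2]), 1e-10)
  # no qualifying voxels -> explicit error
  act0 <- detect_activation(array(0, dims), array(0.9, dims), min_contig = 1)
  expect_error(extract_seed(vol, activation = act0, seed_mask = seed_mask),
               "empty seed")
})

test_that("identical seed voxels reduce to a single voxel's series", {
  dims <- c(2, 1, 1); n <- 20
  one <- rnorm(n)
  vol <- array(0, c(dims, n))
  vol[1, 1, 1, ] <- one; vol[2, 1, 1, ] <- one
  act <- detect_activation(array(5, dims), array(1e-5, dims), min_contig = 1)
  s <- extract_seed(vol, activation = act, seed_mask = array(TRUE, dims))
  expect_equal(s$values, drop(detrend_demean(matrix(one, ncol = 1))),
               tolerance = 1e-10)
})

test_that("build_ppi follows the mask-and-multiply arithmetic on a toy run", {
  # TR 1 s, delta kernel: the convolved task equals the demeaned boxcar
  ev <- data.frame(onset = c(2, 6), duration = 2,
                   condition = c("heat", "heat_fus"))
  d <- stimulus_design(1, 10, ev)
  delta <- structure(list(t = 0, h = 1, dt = 1), class = "hrf_kernel")
  seed_vals <- c(0.5, -1, 2, 1, -0.5, 0.25, 1, -2, 0.75, 0)
  seed <- structure(list(values = seed_vals, source_voxel_count = 1,
                         seed_roi = "VPL", preprocessing = "toy"),
                    class = "seed_signal")
  ppi <- build_ppi(seed, d, delta)
  box_h <- c(0, 0, 1, 1, 0, 0, 0, 0, 0, 0)
  box_f <- c(0, 0, 0, 0, 0, 0, 1, 1, 0, 0)
  # cycles: heat owns volumes 2..5 (onset to next onset), heat_fus the rest
  cyc_h <- c(rep(FALSE, 2), rep(TRUE, 4), rep(FALSE, 4))
  cyc_f <- c(rep(FALSE, 6), rep(TRUE, 4))
  expect_equal(ppi$ppi_by_condition[, "heat"],
               ifelse(cyc_h, (box_h - 0.2) * seed_vals, 0), tolerance = 1e-10)
  expect_equal(ppi$ppi_by_condition[, "heat_fus"],
               ifelse(cyc_f, (box_f - 0.2) * seed_vals, 0), tolerance = 1e-10)
  # disjoint supports and additivity
  expect_false(any(ppi$ppi_by_condition[, 1] != 0 &
                     ppi$ppi_by_condition[, 2] != 0))
  expect_equal(ppi$ppi_full, rowSums(ppi$ppi_by_condition))
  # zero seed -> zero regressors
  seed0 <- seed; seed0$values <- rep(0, 10)
  expect_true(all(build_ppi(seed0, d, delta)$ppi_full == 0))
})

test_that("seed equal to the convolved task squares on its support", {
  ev <- data.frame(onset = c(2, 6), duration = 2,
                   condition = c("heat", "heat_fus"))
  d <- stimulus_design(1, 10, ev)
  delta <- structure(list(t = 0, h = 1, dt = 1), class = "hrf_kernel")
  conv_h <- c(0, 0, 1, 1, 0, 0, 0, 0, 0, 0) - 0.2
  seed <- structure(list(values = conv_h, source_voxel_count = 1,
                         seed_roi = "VPL", preprocessing = "toy"),
                    class = "seed_signal")
  ppi <- build_ppi(seed, d, delta)
  cyc_h <- c(rep(FALSE, 2), rep(TRUE, 4), rep(FALSE, 4))
  expect_equal(ppi$ppi_by_condition[, "heat"], ifelse(cyc_h, conv_h^2, 0),
               tolerance = 1e-10)
})

test_that("fit_efc recovers a planted interaction coefficient exactly", {
  tr <- default_truth()
  ds <- simulate_dataset(small_design(1, reps = 2), tr, rng_seed = 6)
  design <- ds$design
  seed_sig <- extract_seed(detrend_demean(ds$signals), seed_roi = "VPL")
  ppi <- build_ppi(seed_sig, design, canonical_hrf())
  dm <- build_design(design, conditions = unique(design$events$condition))
  y <- 3 * ppi$ppi_by_condition[, "heat"]
  efc <- fit_efc(matrix(y, dimnames = list(NULL, "target")), ppi, dm)
  tab <- efc$table
  expect_equal(tab$beta[tab$condition == "heat"], 3, tolerance = 1e-8)
  expect_lt(abs(tab$beta[tab$condition == "heat_fus"]), 1e-8)
})

test_that("a pure task response yields null PPI betas", {
  tr <- default_truth()
  ds <- simulate_dataset(small_design(2, reps = 2), tr, rng_seed = 7)
  design <- ds$design
  seed_sig <- extract_seed(detrend_demean(ds$signals), seed_roi = "VPL")
  ppi <- build_ppi(seed_sig, design, canonical_hrf())
  dm <- build_design(design, conditions = unique(design$events$condition))
  y <- 2 * dm$X[, "heat"] + fusefc:::with_seed(1, rnorm(design$n_volumes, 0, 0.1))
  efc <- fit_efc(matrix(y, dimnames = list(NULL, "t1")), ppi, dm)
  tab <- efc$table
  expect_true(all(abs(tab$beta) < 2 * tab$se + 1e-9))
})

test_that("group_level averages runs within subject before inference", {
  mk <- function(betas, run, subj) {
    tab <- data.frame(roi = "SI", condition = "heat", beta = betas,
                      se = 0.1, t = 1, p = 0.5)
    structure(list(table = tab, run_id = run, subject_id = subj),
              class = "efc_result")
  }
  # identical betas: zero variance, exact mean
  g <- group_level(list(mk(2, "r1", "s1"), mk(2, "r2", "s1"),
                        mk(2, "r3", "s2")))
  expect_equal(g$mean_beta, 2)
  # two subjects with means 1 and 3
  g2 <- group_level(list(mk(1, "r1", "s1"), mk(3, "r2", "s2")))
  expect_equal(g2$mean_beta, 2)
  # unbalanced runs: subject means unweighted by run count (6,4,6,8 runs)
  runs <- c(6, 4, 6, 8); subj_means <- c(10, 20, 30, 40)
  results <- list()
  for (s in seq_along(runs)) for (r in seq_len(runs[s]))
    results[[length(results) + 1]] <-
      mk(subj_means[s], sprintf("s%dr%d", s, r), paste0("s", s))
  g3 <- group_level(results)
  expect_equal(g3$mean_beta, mean(subj_means))  # 25, not the run-weighted 26.7
  expect_warning(group_level(list(mk(1, "r1", "s1"), mk(2, "r2", "s1"))),
                 "single subject")
})

test_that("compare_mww matches enumeration, wilcox.test and is symmetric", {
  r <- compare_mww(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$effect_direction, "a<b")
  same <- compare_mww(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  # swapping samples flips direction, keeps p
  r2 <- compare_mww(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$p, r$p)
  expect_equal(r2$effect_direction, "a>b")
  # matches exact wilcox.test for tie-free samples
  set.seed(12)
  for (i in 1:15) {
    a <- rnorm(sample(2:5, 1)); b <- rnorm(sample(2:5, 1))
    w <- wilcox.test(a, b, exact = TRUE)
    expect_equal(compare_mww(a, b)$p, w$p.value, tolerance = 1e-10)
  }
  expect_error(compare_mww(numeric(0), 1), "non-empty")
})
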