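test_that("canonical HRF starts at zero, peaks in 4-7 s, undershoots late", {
  h <- canonical_hrf()
  expect_equal(h$h[1], 0)
  expect_equal(max(h$h), 1)
  peak_t <- h$t[which.max(h$h)]
  expect_gte(peak_t, 4); expect_lte(peak_t, 7)
  expect_lt(min(h$h), 0)  # undershoot present
  h0 <- canonical_hrf(hrf_spec(undershoot_ratio = 0))
  expect_true(all(h0$h >= 0))
})

test_that("design construction matches a direct convolution oracle", {
  d <- stimulus_design(2, 60, data.frame(onset = 20, duration = 16,
                                         condition = "heat"))
  hrf <- canonical_hrf()
  X <- build_design(d, hrf, conditions = "heat")
  col <- X$X[, "heat"]
  # no response before onset, peak lags onset by at least the peak delay
  expect_true(all(abs(col[X$times < 20]) < 1e-12))
  expect_gte(X$times[which.max(col)], 20 + 4)
  # oracle: direct Riemann-sum convolution at the volume times
  oracle <- vapply(X$times, function(tt) {
    tau <- hrf$t
    box <- as.numeric((tt - tau) >= 20 & (tt - tau) < 36)
    sum(box * hrf$h) * hrf$dt
  }, numeric(1))
  expect_equal(col, oracle, tolerance = 1e-6)
})

test_that("conditions with disjoint blocks have near-disjoint support", {
  ev <- data.frame(onset = c(10, 120), duration = 16,
                   condition = c("heat", "fus"))
  d <- stimulus_design(2, 100, ev)
  X <- build_design(d, conditions = c("heat", "fus"))
  on_heat <- abs(X$X[, "heat"]) > 1e-6
  on_fus <- abs(X$X[, "fus"]) > 1e-6
  expect_false(any(on_heat & on_fus))
})

test_that("fit_glm matches the normal-equations oracle to 1e-8", {
  set.seed(4)
  for (i in 1:20) {
    X <- cbind(1, matrix(rnorm(10 * 2), 10))
    Y <- matrix(rnorm(10 * 3), 10)
    fit <- fit_glm(Y, X)
    beta_o <- solve(t(X) %*% X, t(X) %*% Y)        # normal equations
    res <- Y - X %*% beta_o
    s2 <- colSums(res^2) / (10 - 3)
    se_o <- sqrt(outer(s2, diag(solve(t(X) %*% X))))
    expect_equal(unname(fit$beta), unname(t(beta_o)), tolerance = 1e-8)
    expect_equal(unname(fit$se), unname(se_o), tolerance = 1e-8)
  }
})

test_that("fit_glm recovers exact coefficients and nulls", {
  d <- small_design(1, reps = 2)
  X <- build_design(d, conditions = c("heat", "fus"))
  y_exact <- 2 * X$X[, "heat"]
  fit <- fit_glm(matrix(y_exact), X)
  expect_equal(unname(fit$beta[1, "heat"]), 2, tolerance = 1e-10)
  conf <- sin(seq_len(nrow(X$X)) / 3)
  X2 <- cbind(X$X, conf = conf)
  fit2 <- fit_glm(matrix(5 * conf), X2)
  expect_lt(abs(fit2$beta[1, "heat"]), 1e-10)
  expect_error(fit_glm(matrix(rnorm(3)), cbind(1, diag(3))), "degrees of freedom")
})

test_that("simulated betas are unbiased within Monte-Carlo error", {
  d <- small_design(1, reps = 2)
  X <- build_design(d, conditions = "heat")
  truth <- 1.5
  ests <- fusefc:::with_seed(99, vapply(1:300, function(i) {
    y <- truth * X$X[, "heat"] + rnorm(nrow(X$X), 0, 1)
    fit_glm(matrix(y), X)$beta[1, "heat"]
  }, numeric(1)))
  se_mc <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - truth), 2 * se_mc + 1e-9)
})

test_that("bh_fdr reproduces the step-up rule and matches p.adjust", {
  r <- bh_fdr(c(0.01), 0.05)
  expect_equal(r$adjusted, 0.01)
  expect_true(r$reject)
  r2 <- bh_fdr(c(0.01, 0.02, 0.03, 0.9), 0.05)
  expect_equal(r2$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(r2$adjusted, c(0.04, 0.04, 0.04, 0.9))
  expect_false(any(bh_fdr(rep(1, 10))$reject))
  set.seed(8)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p)$adjusted, p.adjust(p, "BH"))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("compute_psc converts to percent change about the rest baseline", {
  d <- stimulus_design(2, 50, data.frame(onset = 30, duration = 16,
                                         condition = "heat"))
  ts <- roi_ts(seq(0, 98, 2), matrix(100, 50, 1), 2)
  expect_equal(compute_psc(ts, d)$values[, 1], rep(0, 50))
  v <- matrix(100, 50, 1); v[16:23] <- 102
  ts2 <- roi_ts(seq(0, 98, 2), v, 2)
  psc <- compute_psc(ts2, d)
  expect_equal(max(psc$values), 2)
  # scale invariance of PSC
  ts3 <- roi_ts(seq(0, 98, 2), 2 * v, 2)
  expect_equal(compute_psc(ts3, d)$values, psc$values)
  expect_error(compute_psc(roi_ts(seq(0, 98, 2), matrix(0, 50, 1), 2), d),
               "zero baseline")
})

test_that("cycle_average aligns epochs and scales SE like 1/sqrt(n)", {
  d <- default_design(1, reps = 3)
  hrf <- canonical_hrf()
  reg <- fusefc:::condition_regressors(d, hrf, "heat")
  ts <- roi_ts((seq_len(d$n_volumes) - 1) * 2, reg, 2)
  ca <- cycle_average(ts, d, "heat")
  expect_equal(ca$n_cycles, 3)
  # cycles are near-identical; the residual SE reflects the ~2 s of HRF
  # tail (block 16 s + kernel 32 s > 46 s spacing) bleeding across cycles
  expect_lt(max(abs(ca$se_psc)), 1e-2)
  # pure-noise cycles: pointwise SE approaches c4(n) / sqrt(n), where
  # c4 corrects the small-sample bias of the sd estimator (c4(3) = 0.886)
  se_all <- fusefc:::with_seed(5, vapply(1:200, function(i) {
    tsn <- roi_ts(ts$times, matrix(rnorm(d$n_volumes)), 2)
    mean(cycle_average(tsn, d, "heat")$se_psc)
  }, numeric(1)))
  c4 <- sqrt(2 / 2) * gamma(3 / 2) / gamma(1)
  expect_equal(mean(se_all), c4 / sqrt(3), tolerance = 0.1)
  expect_error(cycle_average(ts, d, "nope"), "no complete cycles")
})

test_that("two-gamma fit recovers noiseless parameters and scales linearly", {
  t <- seq(0, 44, 2)
  truepar <- c(amp1 = 1, amp2 = 0.3, lag1 = 2, dlag = 10, k1 = 6, k2 = 6,
               theta1 = 1, theta2 = 1)
  y <- fusefc:::two_gamma_model(t, truepar)
  cyc <- structure(list(window_times = t, mean_psc = y,
                        se_psc = rep(0, length(t)), n_cycles = 7,
                        condition = "heat"), class = "cycle_average")
  f <- fit_two_gamma(cyc, rng_seed = 1)
  expect_true(f$converged)
  expect_equal(f$amp1, 1, tolerance = 0.01)
  expect_equal(f$amp2, 0.3, tolerance = 0.01)
  expect_lt(abs(f$lag1 - 2), 0.5)
  expect_lt(abs(f$lag2 - 12), 0.5)
  expect_lt(f$lag1, f$lag2)
  # amplitude linearity
  cyc3 <- cyc; cyc3$mean_psc <- 3 * y
  f3 <- fit_two_gamma(cyc3, rng_seed = 1)
  expect_equal(f3$amp1 / f$amp1, 3, tolerance = 0.02)
  expect_lt(abs(f3$lag1 - f$lag1), 0.25)
  # all-zero input collapses the amplitudes
  cyc0 <- cyc; cyc0$mean_psc <- rep(0, length(t))
  f0 <- fit_two_gamma(cyc0, rng_seed = 1)
  expect_lt(max(abs(fusefc:::two_gamma_model(
    t, c(amp1 = f0$amp1, amp2 = f0$amp2, lag1 = f0$lag1,
         dlag = f0$lag2 - f0$lag1, k1 = f0$k1, k2 = f0$k2,
         theta1 = f0$theta1, theta2 = f0$theta2)))), 1e-4)
})

test_that("contrast_test reproduces single-coefficient inference", {
  set.seed(2)
  X <- cbind(intercept = 1, a = rnorm(20), b = rnorm(20))
  Y <- matrix(rnorm(20 * 2), 20)
  fit <- fit_glm(Y, X)
  ct <- contrast_test(fit, c(a = 1))
  expect_equal(ct$t, unname(fit$t[, "a"]), tolerance = 1e-12)
  expect_equal(ct$p, unname(fit$p[, "a"]), tolerance = 1e-12)
})
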