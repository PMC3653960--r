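test_that("Stouffer statistic closed forms", {
  expect_equal(stouffer_statistic(c(0, 0, 0)), 0)
  expect_equal(stouffer_statistic(c(1, 1, 1)), sqrt(3))
  expect_equal(stouffer_statistic(c(1, -1, 0)), 0)
  expect_error(stouffer_statistic(numeric(0)))
  m <- rbind(c(1, 1, 1), c(2, 0, -2))
  expect_equal(stouffer_statistic(m), c(sqrt(3), 0))
})

test_that("null-gene selection thresholds exactly and guards tiny sets", {
  expect_equal(select_null_genes(c(0.5, -0.3, 2.7), 1), c(1L, 2L))
  expect_equal(select_null_genes(c(0.5, -0.3, 2.7), Inf), 1:3)
  expect_error(select_null_genes(c(5, 6, 7), 1), "increase x0")
  set.seed(2)
  s <- rnorm(4000)
  expect_lt(abs(length(select_null_genes(s, 1)) / 4000 - (2 * pnorm(1) - 1)),
            0.03)
})

test_that("covariance estimation: perfect dependence, independence, shared control", {
  z <- cbind(a = rnorm(200), b = 0)
  z[, 2] <- z[, 1]
  est <- estimate_covariance(z)
  expect_equal(est$rho_hat[1, 2], 1)
  expect_equal(est$sigma_hat[1, 2], var(z[, 1]))

  set.seed(11)
  zi <- matrix(rnorm(3e4), ncol = 3)
  ri <- estimate_covariance(zi)$rho_hat
  expect_true(all(abs(ri[upper.tri(ri)]) < 0.05))

  sim <- simulate_experiment(sim_config(n_genes = 3800, n_degs = 0,
                                        replicates_per_arm = 20, seed = 13))
  zs <- compute_partial_t(sim$experiment)$z_score
  rs <- estimate_covariance(zs)$rho_hat
  expect_true(all(rs[upper.tri(rs)] > 0.35 & rs[upper.tri(rs)] < 0.60))

  expect_error(estimate_covariance(cbind(rnorm(100), 1)), "zero-variance")
  expect_error(estimate_covariance(matrix(rnorm(9), 3)), "at least")
})

test_that("combined variance: independence, equicorrelation, total dependence", {
  expect_equal(combined_variance(diag(3)), 1)
  rho5 <- matrix(0.5, 3, 3); diag(rho5) <- 1
  expect_equal(combined_variance(rho5), 2)
  expect_equal(combined_variance(matrix(1, 3, 3)), 3)
  expect_error(combined_variance(matrix(c(1, 2, 3, 4), 2)), "symmetric")
})

test_that("Stouffer p-values: quantiles, monotonicity, classical limit", {
  expect_equal(stouffer_pvalues(0, 1), 1)
  expect_equal(stouffer_pvalues(1.95996 * 1.7, 1.7), 0.05, tolerance = 1e-4)
  s <- seq(0, 5, by = 0.25)
  expect_true(all(diff(stouffer_pvalues(s, 2)) < 0))
  expect_error(stouffer_pvalues(1, 0), "positive")
  # sigma = 1 forced reproduces the classical Stouffer test exactly
  z <- matrix(rnorm(300), ncol = 3)
  st <- stouffer_statistic(z)
  expect_equal(stouffer_pvalues(st, 1), 2 * pnorm(-abs(st)), tolerance = 1e-12)
})

test_that("dependence fit recovers the shared-control variance; de-truncation works", {
  sim <- simulate_experiment(sim_config(n_genes = 4000, n_degs = 0,
                                        replicates_per_arm = 20, seed = 17))
  z <- compute_partial_t(sim$experiment)$z_score
  fit_all <- fit_dependence(z)                      # x0 = Inf
  expect_lt(abs(fit_all$var_hat - 2), 0.15)

  # a finite window shrinks the raw variance; the correction undoes it
  raw <- fit_dependence(z, x0 = 2, detruncate = FALSE)
  expect_lt(raw$var_hat, 1.2)
  cor2 <- fit_dependence(z, x0 = 2, detruncate = TRUE)
  expect_lt(abs(cor2$var_hat - 2), 0.3)
  cor3 <- fit_dependence(z, x0 = 3 * sqrt(2), detruncate = TRUE)
  expect_lt(abs(cor3$var_hat - 2), 0.2)
  # too-narrow window refuses instead of returning a wild inversion
  expect_error(fit_dependence(z, x0 = 0.3), "increase x0")

  # quantile rule picks the requested fraction of genes
  fq <- fit_dependence(z, x0_quantile = 0.68, detruncate = TRUE)
  expect_equal(fq$n_null / 4000, 0.68, tolerance = 0.01)

  # independent arms: variance estimate near the classical value 1
  zi <- do.call(cbind, lapply(1:3, function(i) {
    si <- simulate_experiment(sim_config(n_genes = 2000, n_degs = 0,
                                         n_compounds = 1,
                                         replicates_per_arm = 20,
                                         seed = 40 + i))
    compute_partial_t(si$experiment)$z_score[, 1]
  }))
  expect_lt(abs(fit_dependence(zi)$var_hat - 1), 0.1)
})

test_that("pipeline is calibrated on null data and location invariant", {
  sim <- simulate_experiment(sim_config(n_genes = 4000, n_degs = 0,
                                        replicates_per_arm = 20, seed = 19))
  fit <- run_stouffer_pipeline(sim$experiment)
  expect_true(mean(fit$scores$p_value <= 0.05) >= 0.04 &&
              mean(fit$scores$p_value <= 0.05) <= 0.06)
  # empirical spread of the combined statistic matches the estimate
  expect_lt(abs(var(fit$scores$statistic) / fit$model$var_hat - 1), 0.1)

  shifted <- expression_experiment(sim$experiment$expr + 7,
                                   as.character(sim$experiment$arms))
  fit2 <- run_stouffer_pipeline(shifted)
  expect_equal(fit2$scores$p_value, fit$scores$p_value, tolerance = 1e-12)

  expect_true(all(fit$scores$is_null_set_member))   # x0 = Inf keeps all genes
  expect_s3_class(fit$scores, "combined_scores")
})
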