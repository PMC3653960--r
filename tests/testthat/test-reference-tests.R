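test_that("combining functions: closed forms and null laws", {
  expect_equal(tippett_statistic(c(1, 1, 1)), 1)
  expect_equal(tippett_statistic(c(0.3, 0.05, 0.7)), 0.05)
  expect_error(tippett_statistic(numeric(0)))
  expect_equal(fisher_statistic(c(1, 1, 1)), 0)
  expect_equal(fisher_statistic(c(0.05, 0.05, 0.05)), -6 * log(0.05))
  expect_warning(f0 <- fisher_statistic(c(0, 0.5)), "Inf")
  expect_equal(f0, Inf)

  set.seed(5)
  u <- matrix(runif(3e4), ncol = 3)
  tip <- apply(u, 1, tippett_statistic)
  expect_gt(stats::ks.test(tip, function(q) 1 - (1 - q)^3)$p.value, 0.01)
})

test_that("permutation p-values match exhaustive enumeration on a toy design", {
  set.seed(8)
  x <- rnorm(6) + c(0, 0, 1, 1, 0, 0)
  arms <- c("control", "control", "compound_1", "compound_1",
            "compound_2", "compound_2")
  oracle <- enumerate_perm_pvalues(x, arms)

  exp1 <- expression_experiment(matrix(x, 1, dimnames = list("g1", paste0("s", 1:6))),
                                arms)
  res <- permutation_tests(exp1, perm_matrix = all_perms(6))
  expect_equal(res$fisher$p_value, unname(oracle["fisher"]), tolerance = 1e-12)
  expect_equal(res$tippett$p_value, unname(oracle["tippett"]), tolerance = 1e-12)

  # exhaustive p-values are invariant to within-arm relabeling
  swap <- c(2, 1, 4, 3, 6, 5)
  exp2 <- expression_experiment(matrix(x[swap], 1,
                                       dimnames = list("g1", paste0("s", 1:6))),
                                arms)
  res2 <- permutation_tests(exp2, perm_matrix = all_perms(6))
  expect_equal(res2$fisher$p_value, res$fisher$p_value)
  expect_equal(res2$tippett$p_value, res$tippett$p_value)
})

test_that("permutation machinery: add-one bounds, determinism, pooling", {
  sim <- simulate_experiment(sim_config(n_genes = 300, n_degs = 30,
                                        replicates_per_arm = 5,
                                        effect_size = 3, seed = 23))
  res <- permutation_tests(sim$experiment, B = 99, seed = 1)
  B <- 99
  expect_true(all(res$fisher$p_value >= 1 / (B + 1)))
  expect_true(all(res$fisher$p_value <= 1))
  # strong DEGs beat every permutation: the add-one floor is attained
  expect_equal(min(res$fisher$p_value), 1 / (B + 1))

  res_again <- permutation_tests(sim$experiment, B = 99, seed = 1)
  expect_identical(res_again$fisher$p_value, res$fisher$p_value)

  pooled <- permutation_tests(sim$experiment, B = 99, seed = 1,
                              pool_genes = TRUE)
  expect_true(min(pooled$fisher$p_value) < 1 / (B + 1))   # finer resolution
  expect_gt(cor(rank(pooled$fisher$p_value), rank(res$fisher$p_value)), 0.95)

  expect_warning(permutation_pvalues(sim$experiment, "fisher", B = 9,
                                     seed = 1, alpha = 0.05),
                 "cannot resolve")
})

test_that("Bonferroni bound holds for the observed minimum p-value under the null", {
  sim <- simulate_experiment(sim_config(n_genes = 4000, n_degs = 0,
                                        replicates_per_arm = 10, seed = 29))
  pt <- compute_partial_t(sim$experiment)
  minp <- apply(pt$p_two_sided, 1, tippett_statistic)
  for (alpha in c(0.05, 0.2))
    expect_lt(mean(3 * minp <= alpha),
              alpha + 3 * sqrt(alpha * (1 - alpha) / 4000))
})

test_that("Dunnett test: single-compound limit, sentinels, and bounds", {
  sim1 <- simulate_experiment(sim_config(n_genes = 500, n_degs = 25,
                                         n_compounds = 1,
                                         replicates_per_arm = 8, seed = 37))
  d1 <- dunnett_test(sim1$experiment, n_draws = 2e5, seed = 2)
  pt1 <- compute_partial_t(sim1$experiment)
  expect_lt(max(abs(d1$p_value - pt1$p_two_sided[, 1])), 0.005)

  sim3 <- simulate_experiment(sim_config(n_genes = 400, n_degs = 20,
                                         replicates_per_arm = 5, seed = 38))
  d3 <- dunnett_test(sim3$experiment, n_draws = 1e5, seed = 3)
  dof <- 4 * (5 - 1)
  bonf <- pmin(1, 3 * 2 * pt(-d3$statistic, dof))
  unadj <- 2 * pt(-d3$statistic, dof)
  expect_true(all(d3$p_value <= bonf + 0.01))
  expect_true(all(d3$p_value >= unadj - 0.01))
  expect_identical(dunnett_test(sim3$experiment, n_draws = 1e5, seed = 3)$p_value,
                   d3$p_value)
})

test_that("Dunnett Monte Carlo null agrees with the multivariate-t oracle", {
  skip_if_not_installed("mvtnorm")
  dof <- 76; n <- 3
  corr <- matrix(0.5, n, n); diag(corr) <- 1
  oracle_p <- function(c0)
    1 - mvtnorm::pmvt(lower = rep(-c0, n), upper = rep(c0, n),
                      df = dof, corr = corr,
                      algorithm = mvtnorm::GenzBretz(abseps = 1e-5))[1]
  sn <- zcombine:::dunnett_null_sample(n, dof, 2e5, seed = 7)
  for (c0 in c(1.5, 2.41, 3.0)) {
    mc_p <- (1 + sum(sn >= c0)) / (length(sn) + 1)
    expect_lt(abs(mc_p - oracle_p(c0)), 0.005)
  }
})

test_that("unbalanced designs are rejected by the balanced-only methods", {
  X <- matrix(rnorm(30), 5, 6, dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  exp_u <- expression_experiment(X, c("control", "control", "control",
                                      "compound_1", "compound_1", "compound_1"))
  X2 <- matrix(rnorm(35), 5, 7, dimnames = list(paste0("g", 1:5), paste0("s", 1:7)))
  exp_bad <- expression_experiment(X2, c("control", "control", "control",
                                         "compound_1", "compound_1",
                                         "compound_1", "compound_1"))
  expect_error(dunnett_test(exp_bad), "equal replicate")
  expect_error(permutation_tests(exp_bad), "equal replicate")
  expect_silent(invisible(dunnett_test(exp_u, n_draws = 1e3, seed = 1)))
})
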