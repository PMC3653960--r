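#' Tippett minimum-p combining function
#'
#' \eqn{T^T = \min_i p_i}.  Under independent continuous partial nulls the
#' minimum of n uniforms has CDF \eqn{1 - (1 - x)^n}; with dependent partial
#' tests the null is approximated by permutation (see
#' [permutation_pvalues()]).
#'
#' @param p Numeric vector of partial p-values in `[0, 1]`.
#' @return `min(p)`.
#' @export
tippett_statistic <- function(p) {
  if (length(p) < 1) stop("need at least one p-value")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  min(p)
}

#' Fisher omnibus combining function
#'
#' \eqn{T^F = -2 \sum_i \log p_i}.  Under independent continuous partial
#' nulls it is chi-squared with 2n degrees of freedom; with dependent
#' partial tests the null is approximated by permutation.  A zero p-value
#' yields an `Inf` sentinel (with a warning) rather than an error.
#'
#' @param p Numeric vector of partial p-values in `[0, 1]`.
#' @return `-2 * sum(log(p))`.
#' @export
fisher_statistic <- function(p) {
  if (length(p) < 1) stop("need at least one p-value")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) warning("zero partial p-value; Fisher statistic is Inf")
  -2 * sum(log(p))
}

# Per-gene Fisher and Tippett statistics for one block of label
# permutations, computed through the same pooled-t + t-CDF machinery as the
# observed data.  `membership` is samples x ((n_compounds + 1) * n_perms),
# arm-major within each permutation (control column first).  Partial
# p-values are handled on the log scale so the Fisher statistic never
# overflows.  Returns genes x n_perms matrices.
perm_block_stats <- function(X, X2, membership, k, n_compounds, dof) {
  n_arm <- n_compounds + 1L
  C <- ncol(membership) / n_arm
  mns <- (X %*% membership) / k
  ssq <- X2 %*% membership - k * mns^2
  ic <- seq(1L, n_arm * C, by = n_arm)   # control columns
  fisher <- 0
  log_tippett <- NULL
  for (j in seq_len(n_compounds)) {
    s2p <- (ssq[, ic, drop = FALSE] + ssq[, ic + j, drop = FALSE]) / dof
    tt <- (mns[, ic + j, drop = FALSE] - mns[, ic, drop = FALSE]) /
      sqrt(2 * s2p / k)
    lp <- log(2) + pt(-abs(tt), dof, log.p = TRUE)
    fisher <- fisher - 2 * lp
    log_tippett <- if (is.null(log_tippett)) lp else pmin(log_tippett, lp)
  }
  list(fisher = fisher, tippett = exp(log_tippett))
}

#' Permutation-calibrated Tippett and Fisher combined tests
#'
#' Approximates the null distribution of the combined statistics by
#' whole-column label permutation: in each of `B` permutations the
#' sample-to-arm labels are permuted jointly across all samples (a single
#' permutation applied to every gene), the partial pooled t-tests, their
#' p-values and the combined statistic are recomputed, and the per-gene
#' p-value is the add-one estimator
#' \eqn{(1 + \#\{\mathrm{perm\ at\ least\ as\ extreme}\})/(B + 1)}
#' ("at least as extreme" means `>=` the observed Fisher statistic, `<=` the
#' observed Tippett statistic).  With `pool_genes = TRUE` the permutation
#' statistics of all genes form one pooled null, giving p-value resolution
#' `1 / (G * B + 1)` instead of `1 / (B + 1)` at the price of assuming the
#' null statistics are exchangeable across genes.
#'
#' Both combining functions are computed in one pass over the permutations,
#' which is why this returns a list; [permutation_pvalues()] is the
#' single-method wrapper.
#'
#' @param experiment A balanced [expression_experiment()].
#' @param methods Subset of `c("tippett", "fisher")`.
#' @param B Number of permutations (ignored when `perm_matrix` is given).
#' @param seed Integer seed for the permutation draws.
#' @param pool_genes Pool permutation statistics across genes?
#' @param perm_matrix Optional integer matrix, one permutation of
#'   `1:n_samples` per row, replacing the random draws (e.g. an exhaustive
#'   enumeration on a small design).
#' @param chunk Permutations per BLAS block (memory/speed trade-off).
#' @return Named list of [combined_scores()] data frames, one per method.
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 80, n_degs = 8,
#'                                       replicates_per_arm = 3, seed = 4))
#' res <- permutation_tests(sim$experiment, B = 99, seed = 1)
#' head(res$fisher)
#' @export
permutation_tests <- function(experiment, methods = c("tippett", "fisher"),
                              B = 5000, seed = 1, pool_genes = FALSE,
                              perm_matrix = NULL, chunk = 100) {
  methods <- match.arg(methods, several.ok = TRUE)
  k <- check_balanced(experiment)
  X <- experiment$expr
  X2 <- X * X
  S <- ncol(X)
  nC <- experiment$n_compounds
  dof <- 2 * k - 2
  membership <- 1 * outer(as.integer(experiment$arms),
                          seq_len(nC + 1L), "==")
  if (is.null(perm_matrix)) {
    if (B < 1) stop("need B >= 1 permutations")
    perm_matrix <- with_seed(seed, function()
      matrix(replicate(B, sample.int(S)), nrow = B, byrow = TRUE))
  } else {
    perm_matrix <- as.matrix(perm_matrix)
    if (ncol(perm_matrix) != S)
      stop("`perm_matrix` must have one column per sample")
    B <- nrow(perm_matrix)
    if (B < 1) stop("need B >= 1 permutations")
  }
  obs <- perm_block_stats(X, X2, membership, k, nC, dof)
  G <- nrow(X)
  cnt_f <- numeric(G); cnt_t <- numeric(G)
  n_blocks <- ceiling(B / chunk)
  pool_f <- if (pool_genes) vector("list", n_blocks)
  pool_t <- if (pool_genes) vector("list", n_blocks)
  for (blk in seq_len(n_blocks)) {
    rows <- ((blk - 1L) * chunk + 1L):min(blk * chunk, B)
    Mc <- do.call(cbind, lapply(rows, function(b)
      membership[perm_matrix[b, ], , drop = FALSE]))
    st <- perm_block_stats(X, X2, Mc, k, nC, dof)
    if (pool_genes) {
      pool_f[[blk]] <- as.vector(st$fisher)
      pool_t[[blk]] <- as.vector(st$tippett)
    } else {
      cnt_f <- cnt_f + rowSums(st$fisher >= obs$fisher[, 1])
      cnt_t <- cnt_t + rowSums(st$tippett <= obs$tippett[, 1])
    }
  }
  if (pool_genes) {
    null_f <- sort(unlist(pool_f)); null_t <- sort(unlist(pool_t))
    M <- length(null_f)
    cnt_f <- M - findInterval(obs$fisher[, 1], null_f, left.open = TRUE)
    cnt_t <- findInterval(obs$tippett[, 1], null_t)
    denom <- M + 1
  } else denom <- B + 1
  out <- list()
  gid <- rownames(X)
  if ("fisher" %in% methods)
    out$fisher <- combined_scores(gid, "fisher", obs$fisher[, 1],
                                  (1 + cnt_f) / denom)
  if ("tippett" %in% methods)
    out$tippett <- combined_scores(gid, "tippett", obs$tippett[, 1],
                                   (1 + cnt_t) / denom)
  out
}

#' Permutation p-values for one combining function
#'
#' Single-method wrapper around [permutation_tests()]; see there for the
#' permutation scheme and the add-one p-value estimator.  Warns when `B` is
#' too small to resolve the requested significance level
#' (`1 / (B + 1) > alpha`).
#'
#' @inheritParams permutation_tests
#' @param combine `"tippett"` or `"fisher"`.
#' @param alpha Significance level used only for the resolution warning.
#' @return A [combined_scores()] data frame.
#' @export
permutation_pvalues <- function(experiment, combine = c("tippett", "fisher"),
                                B = 5000, seed = 1, pool_genes = FALSE,
                                perm_matrix = NULL, alpha = 0.05) {
  combine <- match.arg(combine)
  if (!pool_genes && 1 / (B + 1) > alpha)
    warning("B = ", B, " cannot resolve p-values below alpha = ", alpha)
  permutation_tests(experiment, methods = combine, B = B, seed = seed,
                    pool_genes = pool_genes,
                    perm_matrix = perm_matrix)[[combine]]
}

# Sorted Monte Carlo sample of the null max-|t| many-to-one statistic:
# T_i = (Z_i - Z0) / (sqrt(2) * W), W^2 ~ chi^2_dof / dof shared across the
# n comparisons, giving the equicorrelated (rho = 1/2) multivariate t.
dunnett_null_sample <- function(n_compounds, dof, n_draws, seed) {
  with_seed(seed, function() {
    z0 <- rnorm(n_draws)
    w <- sqrt(rchisq(n_draws, df = dof) / dof)
    mx <- abs(rnorm(n_draws) - z0)
    for (i in seq_len(n_compounds - 1L))
      mx <- pmax(mx, abs(rnorm(n_draws) - z0))
    sort(mx / (sqrt(2) * w))
  })
}

#' Dunnett's many-to-one test per gene
#'
#' For each gene, the statistic is \eqn{\max_i |t_i|} where
#' \eqn{t_i = (\bar X_i - \bar X_0) / \sqrt{2 s^2 / k}} uses the variance
#' pooled across *all* arms (degrees of freedom \eqn{(n+1)(k-1)}).  Under
#' the gene-level null the vector of \eqn{t_i} follows the equicorrelated
#' multivariate t with correlation 1/2 (induced by the shared control and
#' the common denominator), and the two-sided simultaneous p-value
#' \eqn{\Pr(\max_i |T_i| \ge \mathrm{obs})} is evaluated by a seeded Monte
#' Carlo sample of that joint representation, shared across genes.
#'
#' @param experiment A balanced [expression_experiment()].
#' @param n_draws Monte Carlo sample size for the null (default `1e5`).
#' @param seed Seed for the null sample.
#' @return A [combined_scores()] data frame (method `"dunnett"`).
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 100, n_degs = 10,
#'                                       replicates_per_arm = 5, seed = 5))
#' head(dunnett_test(sim$experiment))
#' @export
dunnett_test <- function(experiment, n_draws = 1e5, seed = 1) {
  k <- check_balanced(experiment)
  cols <- arm_columns(experiment)
  X <- experiment$expr
  nC <- experiment$n_compounds
  dof <- (nC + 1) * (k - 1)
  mns <- vapply(cols, function(ci) rowMeans(X[, ci, drop = FALSE]),
                numeric(nrow(X)))
  ssw <- vapply(cols, function(ci) {
    xi <- X[, ci, drop = FALSE]
    rowSums((xi - rowMeans(xi))^2)
  }, numeric(nrow(X)))
  s2 <- rowSums(ssw) / dof
  tmat <- (mns[, -1, drop = FALSE] - mns[, 1]) / sqrt(2 * s2 / k)
  obs <- apply(abs(tmat), 1, max)
  null_sorted <- dunnett_null_sample(nC, dof, n_draws, seed)
  cnt <- n_draws - findInterval(obs, null_sorted, left.open = TRUE)
  p <- (1 + cnt) / (n_draws + 1)
  combined_scores(rownames(X), "dunnett", obs, p)
}
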