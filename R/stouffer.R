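#' Stouffer combined statistic
#'
#' The Stouffer (Liptak) combination \eqn{T^S = \sum_{i=1}^n z_i / \sqrt n}
#' of \eqn{n} signed z-scores.  With independent standard-normal scores it is
#' standard normal; with dependent scores it is still normal with mean zero,
#' and its variance \eqn{\sigma^2 = (1/n) \sum_{i,j} \sigma_{ij}} is the only
#' unknown.
#'
#' @param z Numeric vector of z-scores, or a genes x compounds matrix (one
#'   combined statistic per row).
#' @return A single statistic, or one per row of a matrix input.
#' @examples
#' stouffer_statistic(c(1, 1, 1))   # sqrt(3)
#' @export
stouffer_statistic <- function(z) {
  if (is.matrix(z)) {
    if (ncol(z) < 1) stop("need at least one z-score column")
    if (any(!is.finite(z))) stop("z-scores must be finite")
    return(rowSums(z) / sqrt(ncol(z)))
  }
  if (length(z) < 1) stop("need at least one z-score")
  if (any(!is.finite(z))) stop("z-scores must be finite")
  sum(z) / sqrt(length(z))
}

#' Select putative null genes by central thresholding
#'
#' The zero assumption: genes whose combined statistic sits near zero are
#' almost surely equally expressed, so they can serve to estimate the null
#' dependence structure.  This returns exactly the genes with
#' \eqn{|T^S_g| \le x_0}.
#'
#' @param stouffer_stats Named (or unnamed) numeric vector of per-gene
#'   combined statistics.
#' @param x0 Positive threshold on the combined-statistic scale; `Inf`
#'   selects every gene.
#' @param n_min Minimum usable selection size; defaults to one more than the
#'   number of compounds so a sample covariance is estimable.
#' @return Integer indices (named if `stouffer_stats` is named) of the
#'   selected genes.
#' @export
select_null_genes <- function(stouffer_stats, x0, n_min = 2L) {
  if (!is.numeric(x0) || length(x0) != 1 || is.na(x0) || x0 <= 0)
    stop("`x0` must be a single positive threshold")
  sel <- which(abs(stouffer_stats) <= x0)
  if (length(sel) < n_min)
    stop("only ", length(sel), " genes satisfy |T^S| <= x0 = ", x0,
         "; increase x0 (need at least ", n_min, ")")
  sel
}

#' Sample covariance and correlation of partial z-scores over genes
#'
#' Treats genes as replicates of the n-vector of partial z-scores and
#' computes their sample covariance matrix (mean-subtracted, denominator
#' count - 1) and the corresponding correlation matrix.  Applied to genes
#' satisfying the zero assumption this estimates the common null dependence
#' structure induced by the shared control arm.
#'
#' @param z_matrix Numeric matrix, genes x compounds, usually restricted to
#'   the selected null genes.
#' @return A list with `sigma_hat` (covariance) and `rho_hat` (correlation).
#' @export
estimate_covariance <- function(z_matrix) {
  z_matrix <- as.matrix(z_matrix)
  n <- ncol(z_matrix)
  if (nrow(z_matrix) < n + 1)
    stop("need at least ", n + 1, " genes to estimate an ", n, "x", n,
         " covariance")
  sigma_hat <- cov(z_matrix)
  if (any(diag(sigma_hat) == 0))
    stop("zero-variance z-score column: degenerate partial scores")
  list(sigma_hat = sigma_hat, rho_hat = cov2cor(sigma_hat))
}

#' Null variance of the Stouffer statistic from a z-score covariance
#'
#' \eqn{\widehat\sigma^2 = (1/n) \sum_{i,j} \widehat\Sigma_{ij}}, i.e.
#' \eqn{1 + (2/n)\sum_{i<j} \rho_{ij}} when the diagonal is 1.  Independence
#' gives 1 (the classical Stouffer test); total positive dependence gives
#' \eqn{n}; a shared equal-sized control between every pair gives
#' \eqn{\rho_{ij} \approx 1/2}.
#'
#' @param sigma_hat Symmetric n x n covariance matrix of the z-scores.
#' @return The variance estimate (a scalar).
#' @export
combined_variance <- function(sigma_hat) {
  sigma_hat <- as.matrix(sigma_hat)
  if (!isTRUE(all.equal(sigma_hat, t(sigma_hat), tolerance = 1e-8)))
    stop("`sigma_hat` must be symmetric")
  v <- sum(sigma_hat) / ncol(sigma_hat)
  if (v < 0)
    stop("negative combined variance estimate (", format(v),
         "); covariance matrix is not usable")
  v
}

#' Two-sided p-values for Stouffer statistics
#'
#' \eqn{p_g = 2(1 - \Phi(|T^S_g| / \widehat\sigma))}: the final reference
#' distribution is normal with mean zero and the estimated null variance.
#'
#' @param stats Numeric vector of combined statistics.
#' @param sigma Estimated null standard deviation \eqn{\widehat\sigma > 0}.
#' @return p-values in `[0, 1]`, strictly decreasing in `|stats|`.
#' @export
stouffer_pvalues <- function(stats, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive value")
  2 * pnorm(-abs(stats) / sigma)
}

# Variance-shrinkage factor of a centred normal truncated to [-a, a] sd units.
truncation_factor <- function(a) {
  if (!is.finite(a)) return(1)
  1 - 2 * a * dnorm(a) / (2 * pnorm(a) - 1)
}

#' Fit the null dependence model of the Stouffer statistic
#'
#' Runs the two-step null-variance estimation: select genes with
#' \eqn{|T^S_g| \le x_0} (the zero assumption), then estimate the z-score
#' covariance over the selected genes and collapse it to the combined
#' variance.  With the default `x0 = Inf` every gene enters the covariance:
#' this is the estimator of choice when the null proportion is close to one,
#' since contamination by true DEGs only inflates the variance and errs on
#' the conservative side.
#'
#' For a finite `x0` the raw sample covariance of the retained genes is
#' biased: conditioning on a central window of \eqn{T^S} shrinks the
#' variance along the sum direction (a window of \eqn{\pm a} null standard
#' deviations retains only \eqn{1 - 2a\phi(a)/(2\Phi(a)-1)} of it).  When
#' `detruncate = TRUE` (the default) the covariance is corrected by a
#' rank-one update along the sum direction, solving a one-dimensional fixed
#' point for the de-truncated variance under a normal working model.  The
#' observable truncated variance cannot exceed \eqn{x_0^2/3}; if the
#' estimate approaches that ceiling the window is too narrow to invert and
#' an error asks for a larger `x0`.
#'
#' @param z_matrix Genes x compounds matrix of partial z-scores.
#' @param stouffer_stats Per-gene combined statistics (defaults to
#'   `stouffer_statistic(z_matrix)`).
#' @param x0 Central selection threshold; `Inf` (default) uses all genes.
#'   Alternatively set `x0_quantile`.
#' @param x0_quantile If non-`NULL`, overrides `x0` with the given quantile
#'   of `|stouffer_stats|` (e.g. `0.68`).
#' @param detruncate Correct the truncation bias of a finite window
#'   (default `TRUE`; no-op when `x0 = Inf`).
#' @return A list of class `dependence_model` with `x0`, `null_gene_ids`,
#'   `sigma_hat`, `rho_hat`, `var_hat`, `n_null`, and `detruncated`.
#' @export
fit_dependence <- function(z_matrix, stouffer_stats = NULL, x0 = Inf,
                           x0_quantile = NULL, detruncate = TRUE) {
  z_matrix <- as.matrix(z_matrix)
  n <- ncol(z_matrix)
  if (is.null(stouffer_stats)) stouffer_stats <- stouffer_statistic(z_matrix)
  if (!is.null(x0_quantile)) {
    if (x0_quantile <= 0 || x0_quantile >= 1)
      stop("`x0_quantile` must lie in (0, 1)")
    x0 <- as.vector(quantile(abs(stouffer_stats), x0_quantile))
  }
  sel <- select_null_genes(stouffer_stats, x0, n_min = n + 1L)
  est <- estimate_covariance(z_matrix[sel, , drop = FALSE])
  sigma_hat <- est$sigma_hat
  detruncated <- FALSE
  if (detruncate && is.finite(x0)) {
    v_c <- sum(sigma_hat) / n            # truncated variance of T^S
    ceiling_v <- x0^2 / 3
    if (v_c >= 0.95 * ceiling_v)
      stop("selection window too narrow to de-truncate (observed variance ",
           format(v_c), " near its ceiling ", format(ceiling_v),
           "); increase x0")
    f <- function(v) v * truncation_factor(x0 / sqrt(v)) - v_c
    v_hat <- uniroot(f, lower = v_c, upper = 1e4 * max(v_c, 1),
                     tol = 1e-10)$root
    tau <- truncation_factor(x0 / sqrt(v_hat))
    rs <- rowSums(sigma_hat)             # Sigma_c 1
    sigma_hat <- sigma_hat + ((1 - tau) / tau) * tcrossprod(rs) / sum(sigma_hat)
    detruncated <- TRUE
  }
  var_hat <- combined_variance(sigma_hat)
  if (var_hat < 1)
    warning("estimated combined variance ", format(var_hat),
            " is below the independence value 1; kept as estimated")
  ids <- if (!is.null(rownames(z_matrix))) rownames(z_matrix)[sel] else sel
  structure(
    list(x0 = x0, null_gene_ids = ids, sigma_hat = sigma_hat,
         rho_hat = cov2cor(sigma_hat), var_hat = var_hat,
         n_null = length(sel), detruncated = detruncated),
    class = "dependence_model")
}

#' @export
print.dependence_model <- function(x, ...) {
  cat("dependence_model: n =", ncol(x$sigma_hat), "compounds\n")
  cat("  x0 =", format(x$x0), "->", x$n_null, "null-set genes",
      if (x$detruncated) "(de-truncated)" else "", "\n")
  cat("  var_hat =", format(x$var_hat, digits = 4), "\n")
  off <- x$rho_hat[upper.tri(x$rho_hat)]
  cat("  rho_hat (off-diagonal):",
      paste(format(off, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

#' Combined-scores table
#'
#' Standard result container shared by every method in the package: one row
#' per gene with the combined statistic, its p-value, and the Storey
#' q-value.
#'
#' @param gene_id Character vector of gene identifiers.
#' @param method Method tag (`"stouffer"`, `"tippett"`, `"fisher"`,
#'   `"dunnett"`).
#' @param statistic Per-gene combined statistic.
#' @param p_value Per-gene p-values.
#' @param q_value Per-gene q-values (computed with [storey_qvalue()] if
#'   omitted).
#' @return A data frame of class `combined_scores`.
#' @export
combined_scores <- function(gene_id, method, statistic, p_value,
                            q_value = NULL) {
  if (any(p_value < 0 | p_value > 1, na.rm = TRUE))
    stop("p-values outside [0, 1]")
  if (is.null(q_value)) q_value <- storey_qvalue(p_value)
  structure(
    data.frame(gene_id = gene_id, method = method, statistic = statistic,
               p_value = p_value, q_value = q_value,
               stringsAsFactors = FALSE),
    class = c("combined_scores", "data.frame"))
}

#' Run the full Stouffer z-score pipeline
#'
#' The end-to-end procedure: (S1) partial pooled t-tests of every compound
#' against the shared control and their signed z-scores; (S2) the per-gene
#' Stouffer statistic; (S3) null-gene selection by central thresholding
#' (all genes by default, see [fit_dependence()]); (S4) the combined-variance
#' estimate from the z-score covariance over the selected genes; (S5)
#' two-sided p-values against the normal null with the estimated variance,
#' plus Storey q-values.  Fully deterministic: no resampling anywhere.
#'
#' @param experiment An [expression_experiment()].
#' @param x0,x0_quantile,detruncate Passed to [fit_dependence()].
#' @return A list with `scores` (a [combined_scores()] data frame, method
#'   `"stouffer"`, with an extra logical column `is_null_set_member`),
#'   `model` (the fitted `dependence_model`), and `partial` (the
#'   [compute_partial_t()] table).
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 300, n_degs = 15,
#'                                       replicates_per_arm = 5, seed = 3))
#' fit <- run_stouffer_pipeline(sim$experiment)
#' fit$model$var_hat
#' @export
run_stouffer_pipeline <- function(experiment, x0 = Inf, x0_quantile = NULL,
                                  detruncate = TRUE) {
  partial <- compute_partial_t(experiment)                    # S1
  stats <- stouffer_statistic(partial$z_score)                # S2
  model <- fit_dependence(partial$z_score, stats, x0 = x0,    # S3 + S4
                          x0_quantile = x0_quantile,
                          detruncate = detruncate)
  p <- stouffer_pvalues(stats, sqrt(model$var_hat))           # S5
  scores <- combined_scores(rownames(experiment$expr), "stouffer", stats, p)
  scores$is_null_set_member <- scores$gene_id %in% model$null_gene_ids
  list(scores = scores, model = model, partial = partial)
}
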