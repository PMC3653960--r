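#' Storey q-values with a fixed lambda
#'
#' The canonical fixed-lambda form: the null proportion is estimated as
#' \eqn{\widehat\pi_0 = \min(1, \#\{p > \lambda\} / (m(1-\lambda)))} and the
#' q-value of the i-th smallest p-value is the step-up envelope
#' \eqn{q_{(i)} = \min_{j \ge i} \widehat\pi_0\, m\, p_{(j)} / j}.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param lambda Tuning constant in `[0, 1)` for the null-proportion
#'   estimate (default 0.5).
#' @return q-values in `[0, 1]`, in the input order, monotone in `p`.
#' @examples
#' storey_qvalue(c(0.01, 0.2, 0.6, 0.8))   # 0.04 0.40 0.80 0.80
#' @export
storey_qvalue <- function(p, lambda = 0.5) {
  if (length(p) < 1) stop("need at least one p-value")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (lambda < 0 || lambda >= 1) stop("`lambda` must lie in [0, 1)")
  m <- length(p)
  pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  o <- order(p, decreasing = TRUE)
  pmin(1, cummin(pi0 * m * p[o] / (m:1)))[order(o)]
}

#' Ranking AUC of a score against known truth
#'
#' Probability that a randomly chosen DEG receives a smaller p-value than a
#' randomly chosen EEG (ties counted half), i.e. the area under the ROC
#' curve of the p-value ranking.  Computed from ranks (the Wilcoxon
#' statistic), so it is exact including ties.
#'
#' @param p Per-gene p-values (or any score where smaller = more significant).
#' @param is_deg Logical truth vector.
#' @return AUC in `[0, 1]`; 1 is perfect separation, 0.5 is chance.
#' @export
ranking_auc <- function(p, is_deg) {
  is_deg <- as.logical(is_deg)
  m1 <- sum(is_deg); m0 <- sum(!is_deg)
  if (m1 == 0 || m0 == 0) stop("need both DEGs and EEGs")
  r <- rank(p)
  (sum(r[!is_deg]) - m0 * (m0 + 1) / 2) / (m0 * m1)
}

#' Averaged ROC curve over simulated datasets
#'
#' For each dataset, sweeps the p-value threshold over all observed values:
#' \eqn{\widehat{FPR}(c) = \#\{\mathrm{EEG}: p \le c\}/\#\mathrm{EEG}} and
#' \eqn{\widehat{TPR}(c)} analogously for DEGs.  Each dataset's step curve
#' is interpolated onto a common FPR grid and the TPR is averaged pointwise
#' across datasets, which is how a simulation-average ROC is usually drawn.
#'
#' @param p_list List of per-gene p-value vectors, one per dataset.
#' @param truth_list List of logical DEG indicator vectors, aligned with
#'   `p_list`.
#' @param grid_size Number of FPR grid points (default 512).
#' @return A list of class `roc_result` with `fpr` (grid), `tpr` (averaged),
#'   `auc` (per-dataset ranking AUCs), and `n_datasets`.
#' @export
roc_points <- function(p_list, truth_list, grid_size = 512) {
  if (length(p_list) < 1) stop("need at least one dataset")
  if (length(p_list) != length(truth_list))
    stop("`p_list` and `truth_list` must have the same length")
  grid <- seq(0, 1, length.out = grid_size + 1)
  tpr_mat <- vapply(seq_along(p_list), function(d) {
    p <- p_list[[d]]; truth <- as.logical(truth_list[[d]])
    if (length(p) != length(truth)) stop("dataset ", d, ": truth mismatch")
    if (!any(truth) || all(truth)) stop("dataset ", d, ": need DEGs and EEGs")
    ord <- order(p)
    keep <- c(diff(p[ord]) > 0, TRUE)   # last index of each distinct p
    fpr <- c(0, cumsum(!truth[ord])[keep] / sum(!truth))
    tpr <- c(0, cumsum(truth[ord])[keep] / sum(truth))
    # step interpolation: best TPR attained at or below each grid FPR
    approx(fpr, tpr, xout = grid, method = "constant", ties = max,
           yleft = 0, rule = 2)$y
  }, numeric(length(grid)))
  structure(
    list(fpr = grid, tpr = rowMeans(tpr_mat),
         auc = vapply(seq_along(p_list), function(d)
           ranking_auc(p_list[[d]], truth_list[[d]]), numeric(1)),
         n_datasets = length(p_list)),
    class = "roc_result")
}

#' Rank statistics of the true DEGs
#'
#' Ranks all genes by ascending p-value (average ranks on ties) and
#' summarizes the ranks of the true DEGs by their first quartile, median,
#' mean, third quartile and maximum.  Lower ranks mean higher
#' detectability; with m genes and d DEGs the ideal mean rank is
#' `(d + 1) / 2`.
#'
#' @param p Per-gene p-values.
#' @param is_deg Logical truth vector (at least one `TRUE`).
#' @return Named numeric vector `(q1, median, mean, q3, max)`.
#' @examples
#' deg_rank_stats(c(0.001, 0.002, 0.4, 0.9), c(TRUE, TRUE, FALSE, FALSE))
#' @export
deg_rank_stats <- function(p, is_deg) {
  is_deg <- as.logical(is_deg)
  if (!any(is_deg)) stop("need at least one DEG in `is_deg`")
  r <- rank(p, ties.method = "average")[is_deg]
  c(q1 = as.vector(quantile(r, 0.25)), median = median(r), mean = mean(r),
    q3 = as.vector(quantile(r, 0.75)), max = max(r))
}

#' Realized false discovery proportion at a q-value target
#'
#' Rejects every gene with `q <= target` and returns the proportion of
#' rejected genes that are truly equally expressed — the "true FDR" of the
#' procedure, computable only when the truth is known.  Zero rejections
#' give 0.
#'
#' @param q Per-gene q-values.
#' @param is_deg Logical truth vector.
#' @param target Target FDR level in `(0, 1)`.
#' @return The realized false discovery proportion.
#' @export
true_fdr_at_target <- function(q, is_deg, target) {
  if (target <= 0 || target >= 1) stop("`target` must lie in (0, 1)")
  is_deg <- as.logical(is_deg)
  rej <- q <= target
  if (!any(rej)) return(0)
  mean(!is_deg[rej])
}
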