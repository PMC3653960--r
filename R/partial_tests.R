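#' Per-gene partial t-tests of each compound against the shared control
#'
#' Computes, for every gene and every compound arm, the pooled-variance
#' two-sample t-statistic of that compound versus the control arm.  The
#' pooled statistic is used (rather than Welch's) because the z-score
#' transform requires a partial statistic with a known exact null CDF: under
#' normal errors the pooled t is exactly t-distributed with
#' \eqn{k_{ctrl} + k_{cmp} - 2} degrees of freedom.  Positive statistics mean
#' the compound mean exceeds the control mean.
#'
#' Degenerate genes are handled explicitly: if a gene has zero pooled
#' variance and zero mean difference for some compound the statistic is set
#' to 0 (with a warning); zero pooled variance with a nonzero difference
#' yields a `+/-Inf` sentinel, which [z_transform()] clips to the largest
#' representable z-score.
#'
#' @param experiment An [expression_experiment()].
#' @return A list of class `partial_test_table` with elements `t_stat`
#'   (genes x compounds), `dof` (per compound), `p_two_sided`
#'   (`2 * (1 - F_dof(|t|))`), and `z_score` (signed probability-integral
#'   transform of `t_stat`, see [z_transform()]).
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 50, n_degs = 5,
#'                                       replicates_per_arm = 5, seed = 2))
#' pt <- compute_partial_t(sim$experiment)
#' head(pt$t_stat)
#' @export
compute_partial_t <- function(experiment) {
  cols <- arm_columns(experiment)
  X <- experiment$expr
  ctrl <- cols[[1]]
  k0 <- length(ctrl)
  m0 <- rowMeans(X[, ctrl, drop = FALSE])
  ss0 <- rowSums((X[, ctrl, drop = FALSE] - m0)^2)
  nC <- experiment$n_compounds
  t_stat <- matrix(NA_real_, nrow(X), nC,
                   dimnames = list(rownames(X),
                                   levels(experiment$arms)[-1]))
  dof <- numeric(nC)
  degenerate_zero <- FALSE
  for (i in seq_len(nC)) {
    ci <- cols[[i + 1]]
    ki <- length(ci)
    mi <- rowMeans(X[, ci, drop = FALSE])
    ssi <- rowSums((X[, ci, drop = FALSE] - mi)^2)
    dof[i] <- k0 + ki - 2
    s2p <- (ss0 + ssi) / dof[i]
    se <- sqrt(s2p * (1 / k0 + 1 / ki))
    d <- mi - m0
    ti <- d / se
    zero_se <- se == 0
    if (any(zero_se)) {
      # no within-arm spread: 0/0 -> statistic 0, d/0 -> signed infinity
      ti[zero_se & d == 0] <- 0
      ti[zero_se & d != 0] <- sign(d[zero_se & d != 0]) * Inf
      degenerate_zero <- degenerate_zero || any(zero_se & d == 0)
    }
    t_stat[, i] <- ti
  }
  if (degenerate_zero)
    warning("gene(s) with zero pooled variance and zero mean difference; ",
            "t set to 0")
  if (any(is.infinite(t_stat)))
    warning("gene(s) with zero pooled variance but nonzero mean difference; ",
            "t set to +/-Inf (z-scores will be clipped)")
  p <- 2 * pt(-abs(t_stat), df = rep(dof, each = nrow(t_stat)))
  z <- z_transform(t_stat, rep(dof, each = nrow(t_stat)))
  structure(list(t_stat = t_stat, dof = dof, p_two_sided = p, z_score = z),
            class = "partial_test_table")
}

#' Signed z-score transform of a t-statistic
#'
#' The exact probability-integral transform \eqn{z = \Phi^{-1}(F_{\nu}(t))}
#' through the central t CDF and the standard-normal quantile.  Under the
#' partial null the result is exactly standard normal, which is what makes
#' the Stouffer combination's null mean zero and its variance estimable.
#' The transform is carried out on the log-probability scale in the tail
#' that matters, so it stays accurate far beyond |t| of a few units;
#' non-finite statistics map to the double-precision-safe sentinel
#' `|z| = 8.2`.
#'
#' @param t Numeric vector (or matrix) of t-statistics.
#' @param dof Degrees of freedom (recycled against `t`), all positive.
#' @param clip Largest absolute z-score returned (default 8.2).
#' @return z-scores with the same shape as `t`; `sign(z) == sign(t)`.
#' @examples
#' z_transform(2.776, 4)   # ~ 1.95996: matching 97.5th percentiles
#' z_transform(0, 10)      # 0
#' @export
z_transform <- function(t, dof, clip = 8.2) {
  if (any(dof <= 0)) stop("`dof` must be positive")
  z <- t
  neg <- !is.na(t) & t <= 0
  pos <- !is.na(t) & t > 0
  # mirror the positive branch through the negative one for exact symmetry
  z[neg] <- qnorm(pt(t[neg], rep(dof, length.out = length(t))[neg],
                     log.p = TRUE), log.p = TRUE)
  z[pos] <- -qnorm(pt(-t[pos], rep(dof, length.out = length(t))[pos],
                      log.p = TRUE), log.p = TRUE)
  pmin(pmax(z, -clip), clip)
}
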