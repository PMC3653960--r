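#' Run one method on one experiment
#'
#' Dispatch helper used by the benchmark harness and the command-line
#' interface.
#'
#' @param experiment An [expression_experiment()].
#' @param method One of `"stouffer"`, `"tippett"`, `"fisher"`, `"dunnett"`.
#' @param B Permutations for the permutation-calibrated methods.
#' @param seed Seed for any resampling (permutations, Dunnett null draws).
#' @param pool_genes Pool permutation statistics across genes?
#' @param x0,x0_quantile Null-selection threshold for the Stouffer pipeline.
#' @return A [combined_scores()] data frame.
#' @export
run_method <- function(experiment,
                       method = c("stouffer", "tippett", "fisher", "dunnett"),
                       B = 5000, seed = 1, pool_genes = FALSE,
                       x0 = Inf, x0_quantile = NULL) {
  method <- match.arg(method)
  switch(method,
         stouffer = run_stouffer_pipeline(experiment, x0 = x0,
                                          x0_quantile = x0_quantile)$scores,
         dunnett = dunnett_test(experiment, seed = seed),
         permutation_pvalues(experiment, combine = method, B = B,
                             seed = seed, pool_genes = pool_genes))
}

#' Full simulation benchmark: rank statistics, realized FDR, and ROC
#'
#' Simulates `n_datasets` experiments per error family and replicate count,
#' runs the requested methods on each, and aggregates (i) the DEG rank
#' statistics (mean and SD of each quantile over datasets), (ii) the
#' realized false discovery proportion when Storey q-values are thresholded
#' at each target, and (iii) the averaged ROC with per-dataset AUCs.  Every
#' random stage is seeded deterministically from `seed` (dataset d of
#' condition c uses `seed + d`, permutation streams are offset from it), so
#' two runs with the same configuration are identical.
#'
#' @param families Error families to simulate (see [sim_config()]).
#' @param replicates Vector of replicates-per-arm values (paper-style 5, 20).
#' @param methods Methods to compare, see [run_method()].
#' @param n_datasets Simulated datasets per condition (default 20).
#' @param n_genes,n_degs,n_compounds,effect_size Passed to [sim_config()].
#' @param B Permutations for Tippett/Fisher.
#' @param fdr_targets Storey q-value thresholds evaluated (default 0.1, 0.2).
#' @param seed Master seed.
#' @param pool_genes Pool permutation statistics across genes?
#' @param out_dir If non-`NULL`, writes `rank_stats.tsv` (Table-2-shaped),
#'   `true_fdr.tsv` (Table-3-shaped) and `roc.tsv` there.
#' @param verbose Print one progress line per dataset?
#' @return A list with data frames `rank_stats`, `true_fdr`, `roc`, and the
#'   per-condition `auc` table.
#' @export
run_full_benchmark <- function(families = "normal", replicates = 20,
                               methods = c("stouffer", "tippett", "fisher",
                                           "dunnett"),
                               n_datasets = 20, n_genes = 4000, n_degs = 200,
                               n_compounds = 3, effect_size = 1.5, B = 5000,
                               fdr_targets = c(0.1, 0.2), seed = 1,
                               pool_genes = FALSE, out_dir = NULL,
                               verbose = FALSE) {
  rank_rows <- list(); fdr_rows <- list(); roc_rows <- list()
  auc_rows <- list()
  for (fam in families) for (k in replicates) {
    per_method_p <- setNames(vector("list", length(methods)), methods)
    truths <- vector("list", n_datasets)
    for (d in seq_len(n_datasets)) {
      cfg <- sim_config(n_genes = n_genes, n_degs = n_degs,
                        n_compounds = n_compounds, replicates_per_arm = k,
                        effect_size = effect_size, error_family = fam,
                        seed = seed + d)
      sim <- simulate_experiment(cfg)
      truths[[d]] <- sim$truth$is_deg
      for (m in methods) {
        sc <- run_method(sim$experiment, m, B = B, seed = seed + d,
                         pool_genes = pool_genes)
        per_method_p[[m]][[d]] <- sc$p_value
      }
      if (verbose)
        message(fam, " k=", k, " dataset ", d, "/", n_datasets, " done")
    }
    for (m in methods) {
      p_list <- per_method_p[[m]]
      rk <- t(vapply(seq_len(n_datasets), function(d)
        deg_rank_stats(p_list[[d]], truths[[d]]), numeric(5)))
      rank_rows[[length(rank_rows) + 1L]] <- data.frame(
        family = fam, replicates = k, method = m,
        stat = colnames(rk), mean = colMeans(rk), sd = apply(rk, 2, sd),
        row.names = NULL)
      for (tgt in fdr_targets) {
        fdp <- vapply(seq_len(n_datasets), function(d)
          true_fdr_at_target(storey_qvalue(p_list[[d]]), truths[[d]], tgt),
          numeric(1))
        fdr_rows[[length(fdr_rows) + 1L]] <- data.frame(
          family = fam, replicates = k, method = m, target = tgt,
          mean_true_fdr = mean(fdp), sd_true_fdr = sd(fdp))
      }
      roc <- roc_points(p_list, truths)
      roc_rows[[length(roc_rows) + 1L]] <- data.frame(
        family = fam, replicates = k, method = m,
        fpr = roc$fpr, tpr = roc$tpr)
      auc_rows[[length(auc_rows) + 1L]] <- data.frame(
        family = fam, replicates = k, method = m,
        mean_auc = mean(roc$auc), sd_auc = sd(roc$auc))
    }
  }
  out <- list(rank_stats = do.call(rbind, rank_rows),
              true_fdr = do.call(rbind, fdr_rows),
              roc = do.call(rbind, roc_rows),
              auc = do.call(rbind, auc_rows))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(out$rank_stats, file.path(out_dir, "rank_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(out$true_fdr, file.path(out_dir, "true_fdr.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(out$roc, file.path(out_dir, "roc.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(out$auc, file.path(out_dir, "auc.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
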