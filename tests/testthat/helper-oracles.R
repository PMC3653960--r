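# Shared fixtures and independent oracles, built in code at test time.

# Tiny experiment from a list of per-arm matrices (control first).
make_experiment <- function(arm_mats) {
  X <- do.call(cbind, arm_mats)
  arms <- rep(c("control", paste0("compound_", seq_along(arm_mats)[-1] - 1)),
              vapply(arm_mats, ncol, integer(1)))
  colnames(X) <- paste0("s", seq_len(ncol(X)))
  rownames(X) <- paste0("g", seq_len(nrow(X)))
  expression_experiment(X, arms)
}

# All permutations of 1:n, one per row (exhaustive enumeration oracle).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(seq_len(n)[-i][sub], nrow(sub)))))
}

# Brute-force permutation p-values for a one-gene experiment, using
# stats::t.test as an independent engine for the partial tests.
enumerate_perm_pvalues <- function(x, arms) {
  arms <- as.character(arms)
  comb_stats <- function(values) {
    ctrl <- values[arms == "control"]
    ps <- vapply(setdiff(unique(arms), "control"), function(a)
      stats::t.test(values[arms == a], ctrl, var.equal = TRUE)$p.value,
      numeric(1))
    c(fisher = -2 * sum(log(ps)), tippett = min(ps))
  }
  perms <- all_perms(length(x))
  stats_mat <- t(apply(perms, 1, function(idx) comb_stats(x[idx])))
  obs <- comb_stats(x)
  B <- nrow(perms)
  c(fisher = (1 + sum(stats_mat[, "fisher"] >= obs["fisher"])) / (B + 1),
    tippett = (1 + sum(stats_mat[, "tippett"] <= obs["tippett"])) / (B + 1))
}

# Memoised expensive simulation runs shared between acceptance blocks.
.acc_cache <- new.env(parent = emptyenv())
acc_stouffer_runs <- function(k, family = "normal", seed = 101) {
  key <- paste0("stouffer_", family, "_k", k, "_s", seed)
  if (is.null(.acc_cache[[key]])) {
    p_list <- list(); q_list <- list(); truths <- list()
    for (d in 1:20) {
      sim <- simulate_experiment(sim_config(replicates_per_arm = k,
                                            error_family = family,
                                            seed = seed + d))
      fit <- run_stouffer_pipeline(sim$experiment)
      p_list[[d]] <- fit$scores$p_value
      q_list[[d]] <- fit$scores$q_value
      truths[[d]] <- sim$truth$is_deg
    }
    .acc_cache[[key]] <- list(p = p_list, q = q_list, truth = truths)
  }
  .acc_cache[[key]]
}
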