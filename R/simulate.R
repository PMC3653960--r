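#' Configuration of a synthetic multi-arm experiment
#'
#' Describes the generative model used throughout the package's numerical
#' experiments: `n_genes` genes measured in one control arm and
#' `n_compounds` compound arms with `replicates_per_arm` replicates each.
#' Expression is pure noise for every gene in the control arm; for the
#' `n_degs` differentially expressed genes (DEGs) an additive effect
#' `effect_size` is applied in *every* compound arm.  Errors are IID from
#' the standard normal, the t-distribution with 5 degrees of freedom, or the
#' gamma distribution with shape 3 and rate 1 (uncentered: a location shift
#' common to all arms cancels from every two-sample comparison).
#'
#' @param n_genes Total number of genes (default 4000).
#' @param n_degs Number of differentially expressed genes (default 200).
#' @param n_compounds Number of compound arms sharing the control (default 3).
#' @param replicates_per_arm Replicates per arm, \eqn{k \ge 2} (default 20).
#' @param effect_size Additive effect \eqn{\delta} in expression units applied
#'   to DEGs in all compound arms (default 1.5).
#' @param error_family One of `"normal"`, `"t5"`, `"gamma_3_1"`.
#' @param seed Integer seed; the same seed and configuration reproduce the
#'   experiment bit for bit.
#' @param shuffle Should gene rows be shuffled so DEGs are not the leading
#'   block? (default `TRUE`; controlled by `seed`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 4000, n_degs = 200, n_compounds = 3,
                       replicates_per_arm = 20, effect_size = 1.5,
                       error_family = c("normal", "t5", "gamma_3_1"),
                       seed = 1, shuffle = TRUE) {
  error_family <- match.arg(error_family)
  if (n_genes < 1 || n_degs < 0 || n_degs > n_genes)
    stop("need 0 <= n_degs <= n_genes with n_genes >= 1")
  if (replicates_per_arm < 2) stop("replicates_per_arm must be >= 2")
  if (n_compounds < 1) stop("n_compounds must be >= 1")
  structure(
    list(n_genes = as.integer(n_genes), n_degs = as.integer(n_degs),
         n_compounds = as.integer(n_compounds),
         replicates_per_arm = as.integer(replicates_per_arm),
         effect_size = effect_size, error_family = error_family,
         seed = as.integer(seed), shuffle = isTRUE(shuffle)),
    class = "sim_config")
}

error_sampler <- function(family) {
  switch(family,
         normal    = function(n) rnorm(n),
         t5        = function(n) rt(n, df = 5),
         gamma_3_1 = function(n) rgamma(n, shape = 3, rate = 1),
         stop("unknown error family: ", family))
}

#' Simulate a multi-arm expression experiment with known truth
#'
#' Draws an experiment from the model described in [sim_config()]: control
#' entries are pure error draws, compound entries are error draws plus
#' `effect_size` for the DEG rows.  DEG status is attached as a truth table
#' so downstream evaluation (ROC, rank statistics, realized FDR) can be
#' computed without any external data.
#'
#' @param config A [sim_config()] object.
#' @return A list with components
#'   \describe{
#'     \item{experiment}{an [expression_experiment()] of dimension
#'       `n_genes` x `(n_compounds + 1) * replicates_per_arm`;}
#'     \item{truth}{a data frame with columns `gene_id` and `is_deg`
#'       (logical, exactly `n_degs` are `TRUE`), rows aligned with the
#'       expression matrix, plus the generating `config` as an attribute.}
#'   }
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 100, n_degs = 5,
#'                                       replicates_per_arm = 3, seed = 7))
#' sum(sim$truth$is_deg)
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config")) stop("`config` must be a sim_config")
  G <- config$n_genes; k <- config$replicates_per_arm
  nC <- config$n_compounds; S <- (nC + 1L) * k
  rerr <- error_sampler(config$error_family)
  out <- with_seed(config$seed, function() {
    X <- matrix(rerr(G * S), nrow = G, ncol = S)
    if (config$n_degs > 0)
      X[seq_len(config$n_degs), (k + 1L):S] <-
        X[seq_len(config$n_degs), (k + 1L):S] + config$effect_size
    is_deg <- c(rep(TRUE, config$n_degs), rep(FALSE, G - config$n_degs))
    if (config$shuffle) {
      ord <- sample.int(G)
      X <- X[ord, , drop = FALSE]
      is_deg <- is_deg[ord]
    }
    list(X = X, is_deg = is_deg)
  })
  gene_id <- sprintf("g%0*d", max(4L, nchar(G)), seq_len(G))
  arms <- rep(c("control", paste0("compound_", seq_len(nC))), each = k)
  sample_id <- paste0(rep(c("ctrl", paste0("cmp", seq_len(nC))), each = k),
                      "_r", rep(seq_len(k), nC + 1L))
  dimnames(out$X) <- list(gene_id, sample_id)
  truth <- data.frame(gene_id = gene_id, is_deg = out$is_deg,
                      stringsAsFactors = FALSE)
  attr(truth, "config") <- config
  list(experiment = expression_experiment(out$X, arms), truth = truth)
}
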