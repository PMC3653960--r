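#' Multi-arm expression experiment
#'
#' Container for a normalized (log-scale) expression matrix together with the
#' sample-to-arm assignment.  Exactly one arm must be named `"control"`; the
#' remaining arms are the compound (treatment) arms, conventionally labelled
#' `"compound_1"`, `"compound_2"`, ...  Every arm needs at least two samples,
#' and the design methods in this package assume an equal number of
#' replicates per arm.
#'
#' @param expr Numeric matrix, genes in rows and samples in columns.  Row
#'   names are gene identifiers, column names are sample identifiers.
#' @param arms Character or factor vector of arm labels, one per column of
#'   `expr`.
#' @return An object of class `expression_experiment`: a list with elements
#'   `expr` (the matrix), `arms` (factor, control first), `n_compounds`, and
#'   `replicates` (replicates per arm).
#' @examples
#' x <- matrix(rnorm(40), 10, 4,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' expression_experiment(x, c("control", "control", "compound_1", "compound_1"))
#' @export
expression_experiment <- function(expr, arms) {
  expr <- as.matrix(expr)
  if (!is.numeric(expr)) stop("`expr` must be a numeric matrix")
  if (length(arms) != ncol(expr))
    stop("`arms` must have one label per sample column")
  if (anyNA(expr)) stop("`expr` contains missing values; see load_experiment()")
  arms <- as.character(arms)
  if (sum(arms == "control") == 0) stop("exactly one arm must be named \"control\"")
  compound_levels <- unique(arms[arms != "control"])
  if (length(compound_levels) < 1) stop("need at least one compound arm")
  counts <- table(arms)
  if (any(counts < 2)) {
    bad <- names(counts)[counts < 2]
    stop("every arm needs >= 2 samples; offending arm(s): ",
         paste(bad, collapse = ", "))
  }
  if (is.null(rownames(expr)))
    rownames(expr) <- sprintf("g%0*d", nchar(nrow(expr)), seq_len(nrow(expr)))
  if (anyDuplicated(rownames(expr)))
    stop("duplicated gene identifiers in `expr`")
  arms <- factor(arms, levels = c("control", compound_levels))
  structure(
    list(expr = expr,
         arms = arms,
         n_compounds = length(compound_levels),
         replicates = as.vector(counts)[match(levels(arms), names(counts))]),
    class = "expression_experiment")
}

#' @export
print.expression_experiment <- function(x, ...) {
  cat("expression_experiment:", nrow(x$expr), "genes x", ncol(x$expr),
      "samples\n")
  cat("  arms:", paste(sprintf("%s (%d)", levels(x$arms),
                               table(x$arms)), collapse = ", "), "\n")
  invisible(x)
}

# Column indices of each arm, control first.
arm_columns <- function(experiment) {
  lapply(levels(experiment$arms), function(a) which(experiment$arms == a))
}

# Stop unless all arms have the same number of replicates.
check_balanced <- function(experiment) {
  k <- unique(experiment$replicates)
  if (length(k) != 1)
    stop("this method requires equal replicate counts in every arm")
  k
}
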