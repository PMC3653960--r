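#' Load an experiment from expression and design TSV files
#'
#' The expression file is tab-separated with a header row of sample
#' identifiers and gene identifiers in the first column; the design file has
#' columns `sample_id` and `arm` (`"control"` or `"compound_1"`,
#' `"compound_2"`, ...).  Sample identifiers in the design must match the
#' expression header exactly (the expression columns are reordered to the
#' design order).  Genes with any missing value are dropped with a message
#' reporting the count; duplicated gene identifiers, unknown samples, or an
#' arm with fewer than two replicates are hard errors.
#'
#' Expression values are assumed to be already normalized (e.g. RMA-style
#' log-scale intensities); no preprocessing is applied.
#'
#' @param expr_path Path to the expression TSV.
#' @param design_path Path to the design TSV.
#' @return An [expression_experiment()].
#' @export
load_experiment <- function(expr_path, design_path) {
  if (!file.exists(expr_path)) stop("expression file not found: ", expr_path)
  if (!file.exists(design_path)) stop("design file not found: ", design_path)
  expr_df <- read.delim(expr_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  design <- read.delim(design_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "arm") %in% names(design)))
    stop("design file needs columns `sample_id` and `arm`")
  gene_id <- as.character(expr_df[[1]])
  dup <- duplicated(gene_id)
  if (any(dup))
    stop("duplicated gene identifier(s) in ", expr_path, ": ",
         paste(unique(gene_id[dup]), collapse = ", "),
         " (first duplicate at data line ", which(dup)[1], ")")
  X <- as.matrix(expr_df[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- gene_id
  bad_arm <- !grepl("^(control|compound_[0-9]+)$", design$arm)
  if (any(bad_arm))
    stop("design line ", which(bad_arm)[1], ": unknown arm label \"",
         design$arm[bad_arm][1],
         "\" (expected \"control\" or \"compound_<i>\")")
  missing_sample <- setdiff(design$sample_id, colnames(X))
  if (length(missing_sample) > 0)
    stop("design line ", which(design$sample_id == missing_sample[1]),
         ": sample \"", missing_sample[1],
         "\" not present in the expression matrix")
  X <- X[, design$sample_id, drop = FALSE]
  ok <- !apply(X, 1, anyNA)
  if (any(!ok)) {
    message("dropping ", sum(!ok), " gene(s) with missing values")
    X <- X[ok, , drop = FALSE]
  }
  expression_experiment(X, design$arm)
}

#' Write an experiment (and optional truth) as TSV files
#'
#' Writes `<prefix>_expr.tsv` (gene_id + one column per sample),
#' `<prefix>_design.tsv` (`sample_id`, `arm`), and, when truth is supplied,
#' `<prefix>_truth.tsv` (`gene_id`, `is_deg`).  Round-trips through
#' [load_experiment()] exactly.
#'
#' @param experiment An [expression_experiment()].
#' @param prefix Output path prefix.
#' @param truth Optional truth data frame from [simulate_experiment()].
#' @return Invisibly, the vector of files written.
#' @export
write_experiment <- function(experiment, prefix, truth = NULL) {
  expr_path <- paste0(prefix, "_expr.tsv")
  design_path <- paste0(prefix, "_design.tsv")
  df <- data.frame(gene_id = rownames(experiment$expr),
                   experiment$expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = colnames(experiment$expr),
                         arm = as.character(experiment$arms)),
              design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(expr_path, design_path)
  if (!is.null(truth)) {
    truth_path <- paste0(prefix, "_truth.tsv")
    write.table(truth[, c("gene_id", "is_deg")], truth_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- c(paths, truth_path)
  }
  invisible(paths)
}

#' Write a combined-scores table as TSV
#'
#' Columns: `gene_id`, `method`, `statistic`, `p_value`, `q_value`, plus
#' `is_null_set_member` when present (Stouffer pipeline output).
#'
#' @param scores A [combined_scores()] data frame.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_scores <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth TSV written by [write_experiment()]
#'
#' @param path Path to a `*_truth.tsv` file.
#' @return Data frame with `gene_id` and logical `is_deg`.
#' @export
read_truth <- function(path) {
  truth <- read.delim(path, stringsAsFactors = FALSE)
  truth$is_deg <- as.logical(truth$is_deg)
  truth
}
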