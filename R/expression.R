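#' Construct an expression dataset
#'
#' Bundles a strictly positive genes-by-samples matrix of linear-scale
#' expression values with a case/norm group label per sample. The norm
#' (reference) group must contain at least two samples so that a sample
#' standard deviation is defined for the tolerance-interval filter, and
#' at least one case sample is required.
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples
#'   in columns (unique colnames), all values > 0.
#' @param labels named character vector mapping every sample (column name)
#'   to `"case"` or `"norm"`.
#' @param pseudocount non-negative value added to every matrix entry
#'   before positivity is checked (default 0; positivity is enforced, not
#'   silently floored, because log fold-changes are taken downstream).
#' @return object of class `pas_expression`: list with `values` (matrix),
#'   `labels`, `case_samples`, `norm_samples`.
#' @export
pas_expression <- function(values, labels, pseudocount = 0) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene row: ",
         rownames(values)[duplicated(rownames(values))][1L],
         " (collapse probes to genes before loading)")
  }
  if (anyDuplicated(colnames(values))) stop("duplicate sample column")
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1L,
            pseudocount >= 0)
  values <- values + pseudocount
  labels <- labels[colnames(values)]
  if (any(is.na(labels))) {
    stop("sample(s) missing from labels: ",
         paste(colnames(values)[is.na(labels)], collapse = ", "))
  }
  if (!all(labels %in% c("case", "norm"))) {
    stop("labels must be 'case' or 'norm'")
  }
  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("nonpositive or non-finite expression value for gene '",
         rownames(values)[bad[1L, 1L]], "', sample '",
         colnames(values)[bad[1L, 2L]], "' (after pseudocount)")
  }
  norm_samples <- names(labels)[labels == "norm"]
  case_samples <- names(labels)[labels == "case"]
  if (length(norm_samples) < 2L) {
    stop("need >= 2 norm samples (sample SD must be defined), got ",
         length(norm_samples))
  }
  if (length(case_samples) < 1L) stop("need >= 1 case sample")
  structure(list(values = values, labels = labels,
                 case_samples = case_samples,
                 norm_samples = norm_samples),
            class = "pas_expression")
}

#' @export
print.pas_expression <- function(x, ...) {
  cat("pas_expression: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", length(x$case_samples), " case, ",
      length(x$norm_samples), " norm)\n", sep = "")
  invisible(x)
}

#' Read an expression matrix and its sample labels
#'
#' The matrix file is UTF-8 TSV with first header column `gene` and the
#' remaining header fields sample identifiers; values are linear-scale
#' (not log) expression. The labels file is TSV with header
#' `sample<TAB>group`, group in \{case, norm\}. `#` comment lines are
#' skipped in both files.
#'
#' @param matrix_path path to the expression TSV.
#' @param labels_path path to the labels TSV.
#' @param pseudocount passed to [pas_expression()].
#' @return a `pas_expression`.
#' @export
load_expression <- function(matrix_path, labels_path, pseudocount = 0) {
  if (!file.exists(matrix_path)) stop("expression file not found: ",
                                      matrix_path)
  if (!file.exists(labels_path)) stop("labels file not found: ",
                                      labels_path)
  m <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                         quote = "", comment.char = "#",
                         check.names = FALSE)
  if (names(m)[1L] != "gene") {
    stop("first column of '", matrix_path, "' must be named 'gene'")
  }
  if (anyDuplicated(m$gene)) {
    stop("duplicate gene row in '", matrix_path, "': ",
         m$gene[duplicated(m$gene)][1L])
  }
  vals <- as.matrix(m[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression values in ",
                              matrix_path)
  rownames(vals) <- as.character(m$gene)
  lab <- utils::read.delim(labels_path, header = TRUE, sep = "\t",
                           quote = "", comment.char = "#",
                           colClasses = "character", check.names = FALSE)
  if (!all(c("sample", "group") %in% names(lab))) {
    stop("labels file '", labels_path,
         "' must have header columns sample, group")
  }
  labels <- stats::setNames(lab$group, lab$sample)
  pas_expression(vals, labels, pseudocount = pseudocount)
}

#' Case-to-norm expression ratio (CNR) of one gene in one case sample
#'
#' CNR is the gene's expression in the case sample divided by the
#' arithmetic mean of its expression over the norm (reference) samples.
#'
#' @param dataset a `pas_expression`.
#' @param gene gene symbol present in the dataset.
#' @param case_sample case sample identifier.
#' @return strictly positive scalar.
#' @export
compute_cnr <- function(dataset, gene, case_sample) {
  stopifnot(inherits(dataset, "pas_expression"))
  if (!gene %in% rownames(dataset$values)) {
    stop("gene not in dataset: ", gene)
  }
  if (!case_sample %in% dataset$case_samples) {
    stop("not a case sample: ", case_sample)
  }
  v <- dataset$values[gene, ]
  v[[case_sample]] / mean(v[dataset$norm_samples])
}

#' Beyond-tolerance-interval flag (BTIF) of one gene in one case sample
#'
#' The flag is 1 only when both inclusion criteria hold:
#' (i) the case-to-norm ratio deviates from 1 by at least `fold_cutoff`
#' on the linear CNR axis, i.e. `CNR <= 1 - fold_cutoff` or
#' `CNR >= 1 + fold_cutoff` (default 0.5: outside `[0.5, 1.5]`); and
#' (ii) the case expression differs from the norm mean by more than
#' `sd_multiplier` norm-group sample standard deviations (n - 1
#' denominator). Genes failing either criterion are treated as within
#' normal variation and contribute nothing to BTIF-gated scores.
#'
#' @param dataset a `pas_expression`.
#' @param gene gene symbol.
#' @param case_sample case sample identifier.
#' @param fold_cutoff fold-change criterion half-width on the CNR axis
#'   (default 0.5).
#' @param sd_multiplier SD criterion multiplier (default 2).
#' @return 0 or 1 (integer).
#' @export
compute_btif <- function(dataset, gene, case_sample, fold_cutoff = 0.5,
                         sd_multiplier = 2) {
  stopifnot(inherits(dataset, "pas_expression"))
  if (!gene %in% rownames(dataset$values)) {
    stop("gene not in dataset: ", gene)
  }
  v <- dataset$values[gene, ]
  nv <- v[dataset$norm_samples]
  m <- mean(nv)
  s <- stats::sd(nv)
  x <- v[[case_sample]]
  cnr <- x / m
  crit_fold <- cnr <= (1 - fold_cutoff) || cnr >= (1 + fold_cutoff)
  crit_sd <- abs(x - m) > sd_multiplier * s
  as.integer(crit_fold && crit_sd)
}

#' Per-gene norm statistics, CNR and BTIF for a whole dataset
#'
#' Vectorized driver behind the scoring engine: for every gene it
#' computes the norm-group mean and sample SD and, for every case sample,
#' the case-to-norm ratio and the beyond-tolerance-interval flag.
#'
#' @param dataset a `pas_expression`.
#' @inheritParams compute_btif
#' @return object of class `pas_gene_stats`: list with `genes`,
#'   `norm_mean`, `norm_sd` (named vectors), and `cnr`, `btif` (genes x
#'   case-samples matrices), plus the filter parameters used.
#' @export
dataset_gene_stats <- function(dataset, fold_cutoff = 0.5,
                               sd_multiplier = 2) {
  stopifnot(inherits(dataset, "pas_expression"))
  vals <- dataset$values
  nv <- vals[, dataset$norm_samples, drop = FALSE]
  cv <- vals[, dataset$case_samples, drop = FALSE]
  norm_mean <- rowMeans(nv)
  norm_sd <- apply(nv, 1L, stats::sd)
  cnr <- cv / norm_mean
  crit_fold <- cnr <= (1 - fold_cutoff) | cnr >= (1 + fold_cutoff)
  crit_sd <- abs(cv - norm_mean) > sd_multiplier * norm_sd
  btif <- (crit_fold & crit_sd) * 1L
  structure(list(genes = rownames(vals), norm_mean = norm_mean,
                 norm_sd = norm_sd, cnr = cnr, btif = btif,
                 case_samples = dataset$case_samples,
                 fold_cutoff = fold_cutoff,
                 sd_multiplier = sd_multiplier),
            class = "pas_gene_stats")
}
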