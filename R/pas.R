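#' Construct a per-pathway weight vector
#'
#' A weight vector assigns a non-negative importance factor to every
#' member gene of one pathway. Vectors whose `source` is `"sensitivity"`
#' or `"stiffness"` are rescaled to mean 1 over the pathway's genes at
#' construction so that weighted PAS values stay on the scale of the
#' unweighted score; `"uniform"` vectors must be all ones, and
#' `"perturbation"` vectors (random robustness weights) are deliberately
#' left unscaled because the analysis measures the moment of the raw
#' weight distribution.
#'
#' @param pathway pathway name.
#' @param weights named non-negative numeric vector, one entry per
#'   pathway gene.
#' @param source one of `"uniform"`, `"sensitivity"`, `"stiffness"`,
#'   `"perturbation"`.
#' @return object of class `pas_weights`.
#' @export
pas_weights <- function(pathway, weights,
                        source = c("uniform", "sensitivity", "stiffness",
                                   "perturbation")) {
  source <- match.arg(source)
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be finite and >= 0")
  }
  if (source == "uniform" && any(weights != 1)) {
    stop("uniform weight vectors must be all 1")
  }
  if (source %in% c("sensitivity", "stiffness")) {
    m <- mean(weights)
    if (m <= 0) stop("cannot rescale an all-zero weight vector")
    weights <- weights / m
  }
  structure(list(pathway = pathway, weights = weights, source = source),
            class = "pas_weights")
}

#' Uniform (all-ones) weight vector for a pathway
#'
#' @param pathway pathway name.
#' @param genes gene symbols of the pathway's members.
#' @return a `pas_weights` with every weight exactly 1.
#' @export
uniform_weights <- function(pathway, genes) {
  pas_weights(pathway, stats::setNames(rep(1, length(genes)), genes),
              source = "uniform")
}

#' Overall signal outcome (SO) of a pathway
#'
#' The multiplicative counterpart of PAS: the product of the expression
#' levels of the pathway's activator members divided by the product over
#' its repressor members. Only the sign of the role is used here
#' (activator arr > 0, repressor arr < 0); neutral members are ignored.
#' `log10(SO)` equals the unweighted, unfiltered PAS when all roles have
#' magnitude 1 and the levels supplied are case-to-norm ratios.
#'
#' @param pathway data frame with columns `gene`, `arr` (see
#'   [catalog_pathway()]).
#' @param levels named positive numeric vector of expression levels; must
#'   cover every pathway gene with a nonzero role.
#' @return strictly positive scalar.
#' @export
compute_signal_outcome <- function(pathway, levels) {
  stopifnot(is.data.frame(pathway), all(c("gene", "arr") %in%
                                        names(pathway)))
  act <- pathway$gene[pathway$arr > 0]
  rep_ <- pathway$gene[pathway$arr < 0]
  missing <- setdiff(c(act, rep_), names(levels))
  if (length(missing) > 0L) {
    stop("no expression level for pathway gene(s): ",
         paste(missing, collapse = ", "))
  }
  lv <- levels[c(act, rep_)]
  if (any(!is.finite(lv)) || any(lv <= 0)) {
    stop("expression levels must be finite and > 0")
  }
  prod(levels[act]) / prod(levels[rep_])
}

#' Pathway activation strength (PAS) of one pathway in one case sample
#'
#' PAS is the signed sum over pathway member genes of
#' `arr * btif * w * log10(cnr)`: the activator/repressor role times the
#' beyond-tolerance-interval flag (when `apply_btif` is on; 1 otherwise)
#' times the gene's importance weight times the log10 case-to-norm ratio.
#' Positive PAS means the pathway is up-activated in the case sample
#' relative to the norm group, negative PAS down-regulated, with the
#' magnitude proportional to the strength of the deviation.
#'
#' Pathway genes absent from the expression dataset contribute 0 and are
#' counted in `n_missing` (real platforms never cover every pathway
#' member); fractional roles (+/-0.5) enter the sum as real
#' coefficients.
#'
#' @param pathway data frame with columns `gene`, `arr`.
#' @param stats a `pas_gene_stats` from [dataset_gene_stats()].
#' @param sample case sample identifier.
#' @param weights a `pas_weights` covering every pathway gene, or `NULL`
#'   for uniform weights.
#' @param apply_btif gate each gene's term by its BTIF flag (default
#'   `TRUE`, the filtered form; `FALSE` gives the simplified unfiltered
#'   score).
#' @param pathway_name pathway identifier recorded in the result.
#' @return one-row data frame: `pathway`, `sample`, `pas`, `n_btif_pass`
#'   (member genes present with BTIF = 1), `n_missing`.
#' @export
compute_pas <- function(pathway, stats, sample, weights = NULL,
                        apply_btif = TRUE, pathway_name = NA_character_) {
  stopifnot(inherits(stats, "pas_gene_stats"))
  if (!sample %in% stats$case_samples) {
    stop("unknown case sample: ", sample)
  }
  genes <- pathway$gene
  if (is.null(weights)) {
    w <- rep(1, length(genes))
  } else {
    stopifnot(inherits(weights, "pas_weights"))
    miss_w <- setdiff(genes, names(weights$weights))
    if (length(miss_w) > 0L) {
      stop("weight vector missing pathway gene(s): ",
           paste(miss_w, collapse = ", "))
    }
    w <- unname(weights$weights[genes])
  }
  present <- genes %in% stats$genes
  n_missing <- sum(!present)
  g <- genes[present]
  cnr <- stats$cnr[g, sample]
  btif <- stats$btif[g, sample]
  gate <- if (apply_btif) btif else rep(1, length(g))
  pas <- sum(pathway$arr[present] * gate * w[present] * log10(cnr))
  data.frame(pathway = pathway_name, sample = sample, pas = pas,
             n_btif_pass = as.integer(sum(btif)),
             n_missing = as.integer(n_missing),
             stringsAsFactors = FALSE)
}

#' Score every pathway of a catalog in every case sample
#'
#' Batch driver: computes PAS for each (pathway, case sample) pair.
#' Output rows follow catalog order crossed with case-sample order.
#'
#' @param catalog a `pas_catalog`.
#' @param dataset a `pas_expression`.
#' @param weights optional named list of `pas_weights`, one per pathway
#'   name; pathways without an entry get uniform weights.
#' @param apply_btif gate terms by the BTIF filter (default `TRUE`).
#' @inheritParams compute_btif
#' @return data frame with columns `pathway`, `sample`, `pas`,
#'   `n_btif_pass`, `n_missing`.
#' @export
score_catalog <- function(catalog, dataset, weights = NULL,
                          apply_btif = TRUE, fold_cutoff = 0.5,
                          sd_multiplier = 2) {
  stopifnot(inherits(catalog, "pas_catalog"),
            inherits(dataset, "pas_expression"))
  st <- dataset_gene_stats(dataset, fold_cutoff = fold_cutoff,
                           sd_multiplier = sd_multiplier)
  pws <- unique(catalog$pathway)
  rows <- vector("list", length(pws) * length(dataset$case_samples))
  i <- 0L
  for (p in pws) {
    pw <- catalog_pathway(catalog, p)
    wv <- if (!is.null(weights) && p %in% names(weights)) weights[[p]]
          else NULL
    for (s in dataset$case_samples) {
      i <- i + 1L
      rows[[i]] <- compute_pas(pw, st, s, weights = wv,
                               apply_btif = apply_btif, pathway_name = p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read per-pathway gene weights from a TSV file
#'
#' File format: header `pathway<TAB>gene<TAB>weight`. Weights are taken
#' as-is (source `"sensitivity"` rescales to mean 1 per pathway; pass
#' `source = "perturbation"` to keep raw values).
#'
#' @param path weight file path.
#' @param source source tag applied to every pathway's vector.
#' @return named list of `pas_weights`, keyed by pathway.
#' @export
load_weights <- function(path, source = "sensitivity") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", check.names = FALSE)
  if (!all(c("pathway", "gene", "weight") %in% names(df))) {
    stop("weight file '", path,
         "' must have header columns pathway, gene, weight")
  }
  out <- lapply(split(df, df$pathway), function(d) {
    pas_weights(d$pathway[1L],
                stats::setNames(as.numeric(d$weight), d$gene),
                source = source)
  })
  out[unique(df$pathway)]
}

#' Write per-pathway gene weights to a TSV file
#'
#' @param weights named list of `pas_weights`.
#' @param path output file path.
#' @param header_lines optional `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path, header_lines = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines) > 0L) writeLines(header_lines, con)
  writeLines("pathway\tgene\tweight", con)
  for (wv in weights) {
    writeLines(paste(wv$pathway, names(wv$weights),
                     format(wv$weights, digits = 10, trim = TRUE,
                            scientific = FALSE), sep = "\t"), con)
  }
  invisible(path)
}

#' Write a PAS score table to a TSV file
#'
#' @param scores data frame from [score_catalog()].
#' @param path output file path.
#' @param header_lines optional `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_pas_table <- function(scores, path, header_lines = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines) > 0L) writeLines(header_lines, con)
  writeLines("pathway\tsample\tpas\tn_btif_pass\tn_missing", con)
  writeLines(paste(scores$pathway, scores$sample,
                   formatC(scores$pas, digits = 8, format = "g"),
                   scores$n_btif_pass, scores$n_missing, sep = "\t"),
             con)
  invisible(path)
}
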