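#' Configuration of the stochastic robustness analysis
#'
#' Defaults reproduce the published perturbation setting: 98 independent
#' trials of per-gene log-normal weights `w = 2^x` with
#' `x ~ Normal(mean = 0, sd = 0.5)`.
#'
#' @param n_trials number of independent trials (default 98).
#' @param sigma standard deviation of the normal exponent (default 0.5;
#'   0 is accepted as the degenerate no-perturbation case).
#' @param mean expected value of the normal exponent (default 0).
#' @param seed integer seed; trials are reproducible individually.
#' @return object of class `pas_perturbation_config`.
#' @export
perturbation_config <- function(n_trials = 98, sigma = 0.5, mean = 0,
                                seed = 1) {
  stopifnot(n_trials >= 1, sigma >= 0, is.finite(mean))
  structure(list(n_trials = as.integer(n_trials), sigma = sigma,
                 mean = mean, seed = as.integer(seed)),
            class = "pas_perturbation_config")
}

# counter-based per-trial substream: a fixed 32-bit LCG mix of (seed,
# trial) keys R's generator, so trial t is reproducible without drawing
# trials 1..t-1; the caller's RNG state is untouched
.trial_seed <- function(seed, trial_index) {
  s <- (as.double(seed) %% 2147483647) + 1
  t <- as.double(trial_index) %% 2147483647
  as.integer((s * 69069 + t * 104729 + 12345) %% 2147483647)
}

#' Draw one trial's random per-gene perturbation weights
#'
#' Each gene receives an independent weight `w = 2^x`,
#' `x ~ Normal(mean, sigma^2)` — log-normally distributed, strictly
#' positive, with `E[w] = exp((sigma * ln 2)^2 / 2)` at mean 0 (about
#' 1.0619 at the default sigma = 0.5). Weights are reproducible from
#' `(seed, trial_index)` alone and are *not* rescaled to mean 1: the
#' robustness analysis measures the raw moment of the weight
#' distribution through the APAS-vs-PAS slope.
#'
#' @param genes character vector of gene symbols.
#' @param config a [perturbation_config()].
#' @param trial_index trial number (1-based).
#' @return a `pas_weights` with source `"perturbation"`.
#' @export
draw_perturbation_weights <- function(genes, config, trial_index = 1) {
  stopifnot(inherits(config, "pas_perturbation_config"))
  x <- .with_seed(.trial_seed(config$seed, trial_index),
                  stats::rnorm(length(genes), mean = config$mean,
                               sd = config$sigma))
  pas_weights("(all)", stats::setNames(2^x, genes),
              source = "perturbation")
}

#' Robustness of PAS to random gene importance factors
#'
#' Re-scores every pathway in every case sample `n_trials` times, each
#' trial using fresh random log-normal per-gene weights (one weight per
#' gene per trial: a gene shared by several pathways gets the same
#' weight in all of them within a trial). The resulting set of alternate
#' PAS values (APAS) is summarized per (pathway, sample) by its mean and
#' sample SD next to the unperturbed PAS. Because PAS is linear in the
#' weights, `E[APAS] = E[w] * PAS`; a regression of `apas_mean` on
#' `pas_unperturbed` across pathways should have slope close to `E[w]`
#' (about 1.0619 at defaults), and SD bars small enough that the
#' proportional trend stays visible — the published robustness argument
#' for the simplified (unweighted) score.
#'
#' @param catalog a `pas_catalog`.
#' @param dataset a `pas_expression`.
#' @param config a [perturbation_config()].
#' @param apply_btif gate terms by the BTIF filter (default `TRUE`,
#'   matching the scoring default).
#' @param keep_trials return the per-trial APAS matrix in attribute
#'   `trials` (rows = pathway/sample pairs, columns = trials).
#' @inheritParams compute_btif
#' @return data frame with columns `pathway`, `sample`,
#'   `pas_unperturbed`, `apas_mean`, `apas_sd` (sample SD over trials; 0
#'   when `n_trials = 1`).
#' @export
run_robustness <- function(catalog, dataset, config = perturbation_config(),
                           apply_btif = TRUE, keep_trials = FALSE,
                           fold_cutoff = 0.5, sd_multiplier = 2) {
  stopifnot(inherits(catalog, "pas_catalog"),
            inherits(dataset, "pas_expression"),
            inherits(config, "pas_perturbation_config"))
  st <- dataset_gene_stats(dataset, fold_cutoff = fold_cutoff,
                           sd_multiplier = sd_multiplier)
  pws <- unique(catalog$pathway)
  samples <- dataset$case_samples
  genes_all <- unique(catalog$gene)

  # per (pathway, sample) term vectors: arr * gate * lg(cnr) per member
  # gene present in the dataset; APAS is then a weighted sum of terms
  combos <- expand.grid(sample = samples, pathway = pws,
                        stringsAsFactors = FALSE)[, c("pathway", "sample")]
  terms <- vector("list", nrow(combos))
  pas0 <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    pw <- catalog_pathway(catalog, combos$pathway[i])
    present <- pw$gene %in% st$genes
    g <- pw$gene[present]
    s <- combos$sample[i]
    gate <- if (apply_btif) st$btif[g, s] else rep(1, length(g))
    tv <- pw$arr[present] * gate * log10(st$cnr[g, s])
    terms[[i]] <- stats::setNames(tv, g)
    pas0[i] <- sum(tv)
  }

  apas <- matrix(0, nrow = nrow(combos), ncol = config$n_trials)
  for (t in seq_len(config$n_trials)) {
    wv <- draw_perturbation_weights(genes_all, config, trial_index = t)
    w <- wv$weights
    apas[, t] <- vapply(terms, function(tv) {
      if (length(tv) == 0L) 0 else sum(tv * w[names(tv)])
    }, numeric(1))
  }
  out <- data.frame(pathway = combos$pathway, sample = combos$sample,
                    pas_unperturbed = pas0,
                    apas_mean = rowMeans(apas),
                    apas_sd = if (config$n_trials > 1)
                      apply(apas, 1L, stats::sd) else rep(0, nrow(apas)),
                    stringsAsFactors = FALSE)
  if (keep_trials) attr(out, "trials") <- apas
  out
}

#' Write a robustness summary table as TSV
#'
#' @param result data frame from [run_robustness()].
#' @param path output path.
#' @param header_lines optional `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_robustness <- function(result, path, header_lines = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines) > 0L) writeLines(header_lines, con)
  writeLines("pathway\tsample\tpas_unperturbed\tapas_mean\tapas_sd", con)
  writeLines(paste(result$pathway, result$sample,
                   formatC(result$pas_unperturbed, digits = 8,
                           format = "g"),
                   formatC(result$apas_mean, digits = 8, format = "g"),
                   formatC(result$apas_sd, digits = 8, format = "g"),
                   sep = "\t"), con)
  invisible(path)
}
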