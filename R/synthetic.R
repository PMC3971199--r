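#' Specification of a synthetic pathway/expression scenario
#'
#' Describes the synthetic fixtures the package can generate without any
#' external database or accession: a multi-pathway signed-role catalog
#' drawn over a shared gene pool and a case/norm expression cohort with
#' log-normal baseline expression, multiplicative noise, and optional
#' planted pathway activation.
#'
#' Defaults mirror the published analysis scale where one is stated (68
#' pathways); cohort shape and noise are chosen as a plausible
#' microarray-like setting: a reference group of 10 norm samples, 3 case
#' samples, per-gene baselines log-uniform over 10–1000 intensity units,
#' and multiplicative log-normal noise with sdlog 0.25.
#'
#' @param n_pathways number of pathways (default 68).
#' @param genes_per_pathway length-2 integer range of member counts.
#' @param activator_fraction probability that a member's role is
#'   positive (default 0.6).
#' @param half_role_fraction probability that a nonzero role has
#'   magnitude 0.5 rather than 1 (default 0.25).
#' @param gene_pool size of the shared gene universe; pathways sample
#'   members from this pool, so smaller pools give more gene sharing
#'   across pathways (default 500).
#' @param n_norm,n_case cohort sizes (defaults 10 and 3).
#' @param baseline_range length-2 positive range of per-gene baseline
#'   expression (log-uniform; default 10–1000).
#' @param noise_sdlog standard deviation of the per-value log-normal
#'   noise (natural-log scale; default 0.25).
#' @param planted named numeric vector pathway -> planted fold change;
#'   a fold f > 1 activates the pathway in every case sample (activator
#'   members multiplied by f, repressor members by 1/f), f < 1
#'   suppresses it; pathways not named are left unperturbed.
#' @param seed integer seed driving all generation.
#' @return object of class `pas_synthesis_spec`.
#' @export
synthesis_spec <- function(n_pathways = 68,
                           genes_per_pathway = c(10L, 30L),
                           activator_fraction = 0.6,
                           half_role_fraction = 0.25,
                           gene_pool = 500L,
                           n_norm = 10L, n_case = 3L,
                           baseline_range = c(10, 1000),
                           noise_sdlog = 0.25,
                           planted = numeric(), seed = 1L) {
  stopifnot(n_pathways >= 1, length(genes_per_pathway) == 2L,
            genes_per_pathway[1L] >= 1,
            genes_per_pathway[2L] >= genes_per_pathway[1L],
            activator_fraction >= 0, activator_fraction <= 1,
            half_role_fraction >= 0, half_role_fraction <= 1,
            gene_pool >= genes_per_pathway[2L],
            n_norm >= 2, n_case >= 1,
            length(baseline_range) == 2L, all(baseline_range > 0),
            noise_sdlog >= 0, all(planted > 0))
  structure(list(n_pathways = as.integer(n_pathways),
                 genes_per_pathway = as.integer(genes_per_pathway),
                 activator_fraction = activator_fraction,
                 half_role_fraction = half_role_fraction,
                 gene_pool = as.integer(gene_pool),
                 n_norm = as.integer(n_norm),
                 n_case = as.integer(n_case),
                 baseline_range = baseline_range,
                 noise_sdlog = noise_sdlog,
                 planted = planted, seed = as.integer(seed)),
            class = "pas_synthesis_spec")
}

#' Generate a synthetic pathway catalog
#'
#' Pathways `SP01..SPnn` sample their members without replacement from a
#' shared pool of genes `G0001..`, so genes recur across pathways.
#' Roles are drawn from \{-1, -0.5, 0.5, 1\}: sign positive with
#' probability `activator_fraction`, magnitude 0.5 with probability
#' `half_role_fraction`. Fully deterministic given the spec's seed.
#'
#' @param spec a [synthesis_spec()].
#' @return a `pas_catalog`.
#' @export
generate_catalog <- function(spec) {
  stopifnot(inherits(spec, "pas_synthesis_spec"))
  .with_seed(spec$seed, {
    pool <- sprintf("G%04d", seq_len(spec$gene_pool))
    pw_names <- sprintf("SP%02d", seq_len(spec$n_pathways))
    rows <- lapply(seq_len(spec$n_pathways), function(i) {
      sizes <- seq.int(spec$genes_per_pathway[1L],
                       spec$genes_per_pathway[2L])
      n <- sizes[sample.int(length(sizes), 1L)]
      genes <- sample(pool, n)
      sign <- ifelse(stats::runif(n) < spec$activator_fraction, 1, -1)
      mag <- ifelse(stats::runif(n) < spec$half_role_fraction, 0.5, 1)
      data.frame(pathway = pw_names[i], gene = genes, arr = sign * mag,
                 stringsAsFactors = FALSE)
    })
    pas_catalog(do.call(rbind, rows))
  })
}

#' Generate a synthetic case/norm expression cohort
#'
#' Every catalog gene gets a baseline expression level drawn
#' log-uniformly over `baseline_range`; each sample's value is the
#' baseline times log-normal noise (`sdlog = noise_sdlog`). In case
#' samples, pathways named in `spec$planted` have their activator
#' members multiplied by the planted fold and their repressor members
#' by its reciprocal, emulating genuine pathway activation (or
#' suppression for folds < 1). A gene planted through several pathways
#' accumulates the product of the implied folds, as a single transcript
#' would.
#'
#' @param spec a [synthesis_spec()].
#' @param catalog a `pas_catalog`, typically from [generate_catalog()].
#' @return a `pas_expression` with samples `norm01.., case01..`.
#' @export
generate_expression <- function(spec, catalog) {
  stopifnot(inherits(spec, "pas_synthesis_spec"),
            inherits(catalog, "pas_catalog"))
  unknown <- setdiff(names(spec$planted), unique(catalog$pathway))
  if (length(unknown) > 0L) {
    stop("planted pathway(s) not in catalog: ",
         paste(unknown, collapse = ", "))
  }
  .with_seed(spec$seed + 1L, {
    genes <- unique(catalog$gene)
    ng <- length(genes)
    baseline <- exp(stats::runif(ng, log(spec$baseline_range[1L]),
                                 log(spec$baseline_range[2L])))
    names(baseline) <- genes

    fold <- rep(1, ng)
    names(fold) <- genes
    for (p in names(spec$planted)) {
      f <- spec$planted[[p]]
      pw <- catalog_pathway(catalog, p)
      up <- pw$gene[pw$arr > 0]
      dn <- pw$gene[pw$arr < 0]
      fold[up] <- fold[up] * f
      fold[dn] <- fold[dn] / f
    }

    samples <- c(sprintf("norm%02d", seq_len(spec$n_norm)),
                 sprintf("case%02d", seq_len(spec$n_case)))
    labels <- stats::setNames(rep(c("norm", "case"),
                                  c(spec$n_norm, spec$n_case)), samples)
    noise <- matrix(exp(stats::rnorm(ng * length(samples),
                                     sd = spec$noise_sdlog)),
                    nrow = ng)
    vals <- baseline * noise
    case_cols <- which(labels == "case")
    vals[, case_cols] <- vals[, case_cols] * fold
    dimnames(vals) <- list(genes, samples)
    pas_expression(vals, labels)
  })
}

#' Generate a linear activation cascade kinetic model
#'
#' Builds an `n_steps`-tier mass-action cascade: a constitutively active
#' stimulus `S` catalyses activation of tier 1; the active form of tier
#' `i` catalyses activation of tier `i + 1`; every tier deactivates at a
#' first-order rate. Each tier is a conservation group of its inactive
#' (`X<i>`) and active (`X<i>a`) forms with total `tier_total`; the
#' effector is the last tier's active form. With `n_steps = 1` and unit
#' parameters the active fraction follows the closed form
#' `Ea(t) = kf S / (kf S + kb) * (1 - exp(-(kf S + kb) t))`.
#'
#' @param n_steps number of cascade tiers (>= 1).
#' @param k_forward activation rate constant per tier (default 1).
#' @param k_backward deactivation rate constant per tier (default 1).
#' @param stimulus_conc stimulus concentration (default 1).
#' @param tier_total total concentration per tier (default 1).
#' @return a `kinetic_model` with effector `X<n_steps>a`.
#' @export
generate_cascade <- function(n_steps, k_forward = 1, k_backward = 1,
                             stimulus_conc = 1, tier_total = 1) {
  stopifnot(n_steps >= 1, k_forward > 0, k_backward > 0,
            stimulus_conc > 0, tier_total > 0)
  inactive <- sprintf("X%d", seq_len(n_steps))
  active <- sprintf("X%da", seq_len(n_steps))
  species <- data.frame(
    name = c("S", rbind(inactive, active)),
    conc = c(stimulus_conc, rbind(rep(tier_total, n_steps),
                                  rep(0, n_steps))),
    stringsAsFactors = FALSE)
  reactions <- list()
  for (i in seq_len(n_steps)) {
    upstream <- if (i == 1L) "S" else active[i - 1L]
    reactions[[length(reactions) + 1L]] <-
      list(reactants = inactive[i], products = active[i],
           modifiers = upstream, k = k_forward)
    reactions[[length(reactions) + 1L]] <-
      list(reactants = active[i], products = inactive[i],
           modifiers = character(), k = k_backward)
  }
  conservation <- lapply(seq_len(n_steps), function(i)
    list(name = sprintf("tier%d", i),
         members = c(inactive[i], active[i])))
  kinetic_model(species, reactions, effector = active[n_steps],
                conservation = conservation)
}

#' Generate a noisy synthetic effector time series
#'
#' Simulates the model, samples the effector concentration at the
#' requested times, and adds Gaussian measurement noise (clipped at 0),
#' emulating an experimental effector-activation readout such as a
#' Western-blot time series. The returned table feeds
#' [objective_hessian()].
#'
#' @param model a `kinetic_model`.
#' @param times measurement times (> 0, within the horizon).
#' @param sigma Gaussian noise SD, also recorded as the per-point
#'   measurement error (a small floor of 1e-6 is recorded when
#'   `sigma = 0` so downstream chi-square weights stay finite).
#' @param seed integer seed.
#' @param rtol,atol integrator tolerances.
#' @return data frame with columns `time`, `eff`, `sigma`.
#' @export
generate_effector_experiment <- function(model, times, sigma, seed = 1L,
                                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "kinetic_model"), all(times > 0), sigma >= 0)
  times <- sort(times)
  course <- simulate_network(model, rtol = rtol, atol = atol,
                             times = sort(unique(c(0, times))))
  eff <- course$eff[match(times, course$times)]
  noisy <- .with_seed(seed,
                      pmax(0, eff + stats::rnorm(length(eff),
                                                 sd = sigma)))
  data.frame(time = times, eff = noisy,
             sigma = rep(max(sigma, 1e-6), length(times)))
}

#' Read an effector measurement table from a TSV file
#'
#' File format: header `time<TAB>eff<TAB>sigma`.
#'
#' @param path file path.
#' @return data frame with columns `time`, `eff`, `sigma`.
#' @export
load_effector_experiment <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", check.names = FALSE)
  if (!all(c("time", "eff", "sigma") %in% names(df))) {
    stop("effector data file '", path,
         "' must have header columns time, eff, sigma")
  }
  df[, c("time", "eff", "sigma")]
}

#' Write an expression dataset to matrix + labels TSV files
#'
#' @param dataset a `pas_expression`.
#' @param matrix_path,labels_path output paths.
#' @param header_lines optional `#`-prefixed comment lines (written to
#'   both files).
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(dataset, matrix_path, labels_path,
                             header_lines = character()) {
  stopifnot(inherits(dataset, "pas_expression"))
  con <- file(matrix_path, "w", encoding = "UTF-8")
  if (length(header_lines) > 0L) writeLines(header_lines, con)
  writeLines(paste(c("gene", colnames(dataset$values)), collapse = "\t"),
             con)
  writeLines(vapply(seq_len(nrow(dataset$values)), function(i)
    paste(c(rownames(dataset$values)[i],
            formatC(dataset$values[i, ], digits = 10, format = "g")),
          collapse = "\t"), character(1)), con)
  close(con)
  con <- file(labels_path, "w", encoding = "UTF-8")
  if (length(header_lines) > 0L) writeLines(header_lines, con)
  writeLines("sample\tgroup", con)
  writeLines(paste(names(dataset$labels), dataset$labels, sep = "\t"),
             con)
  close(con)
  invisible(matrix_path)
}
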