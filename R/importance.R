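# resolve a species or group name to its conservation-group name
.resolve_group <- function(model, species) {
  if (species %in% names(model$groups)) return(species)
  for (g in names(model$groups)) {
    if (species %in% model$groups[[g]]) return(g)
  }
  stop("unknown species or conservation group: ", species)
}

# species (forms) whose initial value can influence the effector:
# breadth-first search on the structural influence graph, where a form
# influences every form produced/consumed by a reaction it enters as
# reactant or modifier
.influences_effector <- function(model, group) {
  members <- model$groups[[group]]
  frontier <- members
  seen <- members
  repeat {
    new <- character()
    for (r in model$reactions) {
      if (any(c(r$reactants, r$modifiers) %in% frontier)) {
        touched <- c(r$reactants, r$products)
        new <- c(new, setdiff(touched, seen))
      }
    }
    new <- unique(new)
    if (length(new) == 0L) break
    seen <- c(seen, new)
    frontier <- new
  }
  model$effector %in% seen
}

#' Sensitivity-based importance factor of one protein total
#'
#' The sensitivity importance `w1` of a protein (conservation group) is
#' the time average, from 0 to the steady-state time `T`, of the
#' absolute log-sensitivity of the effector trajectory to that protein's
#' total concentration:
#' `w1 = (1/T) * integral_0^T |d ln EFF(t) / d ln C_tot| dt`.
#'
#' The log-derivative is estimated by a multiplicative central
#' difference: the model is re-simulated with the group total scaled by
#' `(1 + rel_step)` and `(1 - rel_step)`, on the *same* time grid over
#' `[0, T]` as the base run, and the integral is taken by the trapezoid
#' rule on that grid. Grid points where the base effector concentration
#' has not yet risen above `atol` are excluded (the log-derivative at
#' `EFF = 0` is an artifact of the initial condition, not of
#' sensitivity). Group totals with no structural path of reactions to
#' the effector return 0 exactly, without simulation.
#'
#' @param model a `kinetic_model`.
#' @param species protein/group name (a conservation group, or any
#'   member form, resolved to its group).
#' @param rel_step relative displacement of the total (default 1e-3).
#' @param horizon,rtol,atol,n_grid simulation controls, see
#'   [simulate_network()].
#' @param ss_tol steady-state detection tolerance, see
#'   [detect_steady_state()].
#' @param t_end optional explicit upper integration limit `T`; when
#'   `NULL` the detected steady-state time is used. Supply a large value
#'   to probe the steady-state (large-`T`) limit of the average.
#' @return non-negative scalar `w1`, with attributes `T` (the upper
#'   limit used) and `n_grid_used`.
#' @export
sensitivity_importance <- function(model, species, rel_step = 1e-3,
                                   horizon = 1e4, rtol = 1e-8,
                                   atol = 1e-10, ss_tol = 1e-6,
                                   n_grid = 200, t_end = NULL) {
  stopifnot(inherits(model, "kinetic_model"), rel_step > 0,
            rel_step < 1)
  group <- .resolve_group(model, species)
  if (sum(model$conc0[model$groups[[group]]]) <= 0) {
    stop("group '", group, "' has C_tot = 0; log-derivative undefined")
  }
  if (!.influences_effector(model, group)) {
    return(structure(0, T = NA_real_, n_grid_used = 0L))
  }
  if (is.null(t_end)) {
    base <- simulate_network(model, horizon = horizon, rtol = rtol,
                             atol = atol, n_grid = n_grid)
    t_end <- detect_steady_state(base, tol = ss_tol)
    if (is.na(t_end)) {
      stop("steady state not reached within horizon ", horizon,
           "; increase the horizon or supply t_end")
    }
    if (t_end <= 0) t_end <- base$times[2L]
  }
  grid <- log_time_grid(t_end, n_grid)
  run <- function(m) simulate_network(m, rtol = rtol, atol = atol,
                                      times = grid)$eff
  eff0 <- run(model)
  if (all(eff0 <= atol)) {
    stop("effector is identically ~0; log-sensitivity undefined")
  }
  effp <- run(scale_total(model, group, 1 + rel_step))
  effm <- run(scale_total(model, group, 1 - rel_step))
  keep <- eff0 > atol & effp > 0 & effm > 0
  dln <- abs(log(effp[keep]) - log(effm[keep])) /
    (log1p(rel_step) - log1p(-rel_step))
  tt <- grid[keep]
  if (length(tt) < 2L) stop("too few valid grid points for the integral")
  integral <- sum(diff(tt) * (dln[-1L] + dln[-length(dln)]) / 2)
  structure(integral / t_end, T = t_end, n_grid_used = length(tt))
}

#' Hessian of the effector-fit objective over total concentrations
#'
#' Builds the least-squares objective
#' `S(C_tot) = sum_k (EFF(C_tot, t_k) - EFF_exp_k)^2 / sigma_k^2`
#' comparing the simulated effector concentration at measurement times
#' `t_k` with measured values, and returns its Hessian with respect to
#' the vector of conservation-group totals, estimated by central second
#' differences with per-coordinate multiplicative step
#' `rel_step * C_tot_i` and symmetrized as `(H + t(H)) / 2`.
#'
#' @param model a `kinetic_model`.
#' @param exp_times measurement times (within the simulation horizon).
#' @param exp_values measured effector concentrations.
#' @param exp_sigmas per-point measurement errors, all > 0.
#' @param rel_step relative step for the finite differences (default
#'   0.01; second differences need a larger step than first differences
#'   to stay above integrator noise).
#' @param rtol,atol integrator tolerances.
#' @param groups optional subset of group names to differentiate over
#'   (default: all conservation groups, in model order).
#' @return symmetric matrix with group names as dimnames and attribute
#'   `S0` (objective value at the unperturbed totals).
#' @export
objective_hessian <- function(model, exp_times, exp_values, exp_sigmas,
                              rel_step = 0.01, rtol = 1e-8,
                              atol = 1e-10, groups = NULL) {
  stopifnot(inherits(model, "kinetic_model"),
            length(exp_times) == length(exp_values),
            length(exp_times) == length(exp_sigmas))
  if (any(exp_sigmas <= 0)) stop("all measurement sigmas must be > 0")
  if (any(exp_times < 0)) stop("measurement times must be >= 0")
  if (is.null(groups)) groups <- names(model$groups)
  ord <- order(exp_times)
  tk <- exp_times[ord]
  vk <- exp_values[ord]
  sk <- exp_sigmas[ord]
  sim_times <- sort(unique(c(0, tk)))
  objective <- function(m) {
    course <- simulate_network(m, rtol = rtol, atol = atol,
                               times = sim_times)
    eff <- course$eff[match(tk, course$times)]
    if (any(!is.finite(eff))) stop("non-finite effector at a displaced ",
                                   "total-concentration point")
    sum((eff - vk)^2 / sk^2)
  }
  displace <- function(f) {
    # f: named vector of multiplicative factors per group
    m <- model
    for (g in names(f)) m <- scale_total(m, g, f[[g]])
    m
  }
  n <- length(groups)
  totals <- model_totals(model)[groups]
  h <- rel_step * totals
  S0 <- objective(model)
  H <- matrix(0, n, n, dimnames = list(groups, groups))
  for (i in seq_len(n)) {
    fp <- stats::setNames(1 + rel_step, groups[i])
    fm <- stats::setNames(1 - rel_step, groups[i])
    Sp <- objective(displace(fp))
    Sm <- objective(displace(fm))
    H[i, i] <- (Sp - 2 * S0 + Sm) / h[i]^2
    if (i < n) for (j in seq.int(i + 1L, n)) {
      gpair <- groups[c(i, j)]
      Spp <- objective(displace(stats::setNames(
        c(1 + rel_step, 1 + rel_step), gpair)))
      Spm <- objective(displace(stats::setNames(
        c(1 + rel_step, 1 - rel_step), gpair)))
      Smp <- objective(displace(stats::setNames(
        c(1 - rel_step, 1 + rel_step), gpair)))
      Smm <- objective(displace(stats::setNames(
        c(1 - rel_step, 1 - rel_step), gpair)))
      H[i, j] <- H[j, i] <- (Spp - Spm - Smp + Smm) / (4 * h[i] * h[j])
    }
  }
  H <- (H + t(H)) / 2
  attr(H, "S0") <- S0
  H
}

#' Stiffness-based importance factors from an objective Hessian
#'
#' Eigendecomposes the (symmetric) Hessian of the effector-fit
#' objective and returns, for every protein total, the absolute
#' component of the unit eigenvector along the stiffest direction — the
#' eigenvector whose eigenvalue has the largest absolute value. Stiff
#' directions are those along which the fit degrades fastest, so large
#' components mark the proteins that matter most for the pathway
#' output. The returned values are components of a unit-norm vector:
#' `sum(w2^2) = 1`.
#'
#' @param hessian symmetric numeric matrix with group dimnames.
#' @param sym_tol asymmetry tolerance relative to the largest entry.
#' @return named vector `w2` of absolute stiffest-eigenvector
#'   components, with attributes `lambda` (the stiffest eigenvalue) and
#'   `eigenvalues` (full spectrum, decreasing).
#' @export
stiffness_importance <- function(hessian, sym_tol = 1e-8) {
  stopifnot(is.matrix(hessian), nrow(hessian) == ncol(hessian))
  scale <- max(abs(hessian), 1e-300)
  if (max(abs(hessian - t(hessian))) > sym_tol * scale) {
    stop("Hessian is not symmetric within tolerance")
  }
  H <- (hessian + t(hessian)) / 2
  e <- eigen(H, symmetric = TRUE)
  av <- abs(e$values)
  mx <- max(av)
  cand <- which(av >= mx * (1 - 1e-12))
  if (length(cand) > 1L) {
    # tie on |lambda|: prefer the eigenvector whose first nonzero
    # component sits at the smallest species index
    firstnz <- vapply(cand, function(k) {
      nz <- which(abs(e$vectors[, k]) > 1e-12)
      if (length(nz) == 0L) nrow(H) + 1L else nz[1L]
    }, integer(1))
    cand <- cand[order(firstnz, cand)]
  }
  s <- cand[1L]
  w2 <- abs(e$vectors[, s])
  names(w2) <- rownames(hessian)
  structure(w2, lambda = e$values[s], eigenvalues = e$values)
}

#' Read a gene-to-species map from a TSV file
#'
#' File format: header `gene<TAB>species`; each gene maps to exactly one
#' modeled species/conservation group.
#'
#' @param path map file path.
#' @return named character vector, gene -> species.
#' @export
load_gene_species_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", colClasses = "character",
                          check.names = FALSE)
  if (!all(c("gene", "species") %in% names(df))) {
    stop("gene-species map '", path,
         "' must have header columns gene, species")
  }
  if (anyDuplicated(df$gene)) {
    stop("gene mapped to more than one species: ",
         df$gene[duplicated(df$gene)][1L])
  }
  stats::setNames(df$species, df$gene)
}

#' Map species importance factors onto a pathway's gene weights
#'
#' Pathway genes mapped to a modeled species receive that species'
#' importance factor; unmapped genes receive the mean factor of the
#' mapped genes (most pathway members are absent from any tractable
#' kinetic model, and the neutral fallback keeps the weighted score
#' comparable to the unweighted one). The resulting vector is rescaled
#' to mean 1 by the [pas_weights()] constructor.
#'
#' @param importance named numeric vector of importance factors per
#'   species/group (e.g. `w1` values, or a [stiffness_importance()]
#'   result).
#' @param map named character vector gene -> species (see
#'   [load_gene_species_map()]).
#' @param pathway data frame with columns `gene`, `arr`.
#' @param method `"sensitivity"` or `"stiffness"`; recorded as the
#'   weight vector's source.
#' @param pathway_name name recorded in the weight vector.
#' @return a `pas_weights` with attribute `n_unmapped`.
#' @export
map_importance_to_weights <- function(importance, map, pathway,
                                      method = c("sensitivity",
                                                 "stiffness"),
                                      pathway_name = "pathway") {
  method <- match.arg(method)
  genes <- pathway$gene
  sp <- map[genes]
  mapped <- !is.na(sp) & sp %in% names(importance)
  if (!any(mapped)) {
    stop("no pathway gene maps to a modeled species")
  }
  w <- rep(NA_real_, length(genes))
  w[mapped] <- unname(importance[sp[mapped]])
  w[!mapped] <- mean(w[mapped])
  wv <- pas_weights(pathway_name, stats::setNames(w, genes),
                    source = method)
  attr(wv, "n_unmapped") <- sum(!mapped)
  wv
}
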