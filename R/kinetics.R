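#' Construct a mass-action kinetic model of a signaling pathway
#'
#' The model is a set of named species (state variables, one per
#' molecular form) with initial concentrations, a list of irreversible
#' mass-action reactions, a designated effector form whose concentration
#' trajectory `EFF(t)` is the pathway readout, and conservation groups:
#' sets of interconverting forms of one protein whose concentrations sum
#' to a fixed total `C_tot`. A group's `C_tot` is the sum of its members'
#' initial concentrations; species not listed in any group form implicit
#' singleton groups named after themselves. Perturbing a protein's total
#' (as the sensitivity and stiffness analyses do) scales all member
#' initial concentrations by a common factor, preserving the initial
#' active fractions.
#'
#' Reaction rates follow the mass action law: rate = `k` times the
#' product of reactant concentrations (with multiplicity) times the
#' product of modifier concentrations. Modifiers (e.g. an upstream active
#' kinase catalysing an activation step) enter the rate but are not
#' consumed. Reversible steps are written as two reactions.
#'
#' @param species data frame with columns `name` (unique) and `conc`
#'   (initial concentration, >= 0).
#' @param reactions list of lists with elements `reactants` (character
#'   vector, multiset), `products` (character vector), optional
#'   `modifiers`, and rate constant `k > 0`.
#' @param effector species name whose concentration is EFF(t).
#' @param conservation optional list of lists with elements `name`
#'   (group/protein identifier) and `members` (species names); groups
#'   must be disjoint.
#' @return object of class `kinetic_model`.
#' @export
kinetic_model <- function(species, reactions, effector,
                          conservation = list()) {
  stopifnot(is.data.frame(species),
            all(c("name", "conc") %in% names(species)))
  nm <- as.character(species$name)
  conc <- as.numeric(species$conc)
  if (anyDuplicated(nm)) stop("duplicate species name")
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("initial concentrations must be finite and >= 0")
  }
  names(conc) <- nm
  if (!effector %in% nm) stop("effector '", effector,
                              "' is not a declared species")
  for (i in seq_along(reactions)) {
    r <- reactions[[i]]
    if (is.null(r$k) || !is.finite(r$k) || r$k <= 0) {
      stop("reaction ", i, ": rate constant must be finite and > 0")
    }
    refs <- c(r$reactants, r$products, r$modifiers)
    bad <- setdiff(refs, nm)
    if (length(bad) > 0L) {
      stop("reaction ", i, " references unknown species: ",
           paste(bad, collapse = ", "))
    }
    if (length(r$reactants) == 0L && length(r$products) == 0L) {
      stop("reaction ", i, " has neither reactants nor products")
    }
  }
  grouped <- character()
  groups <- list()
  for (g in conservation) {
    if (is.null(g$name) || is.null(g$members)) {
      stop("conservation groups need 'name' and 'members'")
    }
    bad <- setdiff(g$members, nm)
    if (length(bad) > 0L) stop("conservation group '", g$name,
                               "' references unknown species: ",
                               paste(bad, collapse = ", "))
    if (any(g$members %in% grouped)) {
      stop("species cannot belong to two conservation groups")
    }
    grouped <- c(grouped, g$members)
    groups[[g$name]] <- g$members
  }
  for (s in setdiff(nm, grouped)) {
    if (s %in% names(groups)) stop("group name clashes with species: ", s)
    groups[[s]] <- s
  }
  # stoichiometry and rate bookkeeping precomputed once
  nr <- length(reactions)
  stoich <- matrix(0, nrow = length(nm), ncol = max(nr, 1L),
                   dimnames = list(nm, NULL))
  for (i in seq_len(nr)) {
    r <- reactions[[i]]
    for (sp in r$reactants) stoich[sp, i] <- stoich[sp, i] - 1
    for (sp in r$products) stoich[sp, i] <- stoich[sp, i] + 1
  }
  structure(list(species = nm, conc0 = conc, reactions = reactions,
                 effector = effector, groups = groups, stoich = stoich),
            class = "kinetic_model")
}

#' Total concentrations of a model's conservation groups
#'
#' @param model a `kinetic_model`.
#' @return named vector of group totals (sums of member initial
#'   concentrations).
#' @export
model_totals <- function(model) {
  stopifnot(inherits(model, "kinetic_model"))
  vapply(model$groups, function(m) sum(model$conc0[m]), numeric(1))
}

#' Rescale one conservation group's total concentration
#'
#' Multiplies the initial concentrations of every member form of the
#' group by `factor`, so the group's `C_tot` scales while initial active
#' fractions are preserved. Used by the sensitivity and stiffness
#' analyses to displace the total-concentration vector.
#'
#' @param model a `kinetic_model`.
#' @param group group name (a conservation group or a singleton species).
#' @param factor positive scale factor.
#' @return a new `kinetic_model`.
#' @export
scale_total <- function(model, group, factor) {
  stopifnot(inherits(model, "kinetic_model"), factor > 0)
  if (!group %in% names(model$groups)) {
    stop("unknown conservation group: ", group)
  }
  members <- model$groups[[group]]
  model$conc0[members] <- model$conc0[members] * factor
  model
}

#' Read a kinetic model from a JSON file
#'
#' Expected structure:
#' \preformatted{
#' {"species":   [{"name": "R", "conc": 1.0}, ...],
#'  "reactions": [{"reactants": ["E"], "products": ["Ea"],
#'                 "modifiers": ["R"], "k": 1.0}, ...],
#'  "effector": "Ea",
#'  "conservation": [{"name": "E_tot", "members": ["E", "Ea"]}]}
#' }
#'
#' @param path path to the model file.
#' @return a `kinetic_model`.
#' @export
load_kinetic_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(j$species) || is.null(j$effector)) {
    stop("model file needs 'species' and 'effector' fields: ", path)
  }
  species <- data.frame(
    name = vapply(j$species, function(s) as.character(s$name),
                  character(1)),
    conc = vapply(j$species, function(s) as.numeric(s$conc), numeric(1)),
    stringsAsFactors = FALSE)
  reactions <- lapply(j$reactions, function(r) {
    list(reactants = as.character(unlist(r$reactants)),
         products = as.character(unlist(r$products)),
         modifiers = as.character(unlist(r$modifiers)),
         k = as.numeric(r$k))
  })
  conservation <- lapply(j$conservation, function(g) {
    list(name = as.character(g$name),
         members = as.character(unlist(g$members)))
  })
  kinetic_model(species, reactions, as.character(j$effector),
                conservation)
}

#' Write a kinetic model to a JSON file
#'
#' @param model a `kinetic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kinetic_model <- function(model, path) {
  stopifnot(inherits(model, "kinetic_model"))
  explicit <- Filter(function(g) length(model$groups[[g]]) > 1L ||
                       g != model$groups[[g]][1L], names(model$groups))
  j <- list(
    species = lapply(model$species, function(s)
      list(name = s, conc = unname(model$conc0[s]))),
    reactions = lapply(model$reactions, function(r)
      list(reactants = as.list(r$reactants),
           products = as.list(r$products),
           modifiers = as.list(r$modifiers), k = r$k)),
    effector = model$effector,
    conservation = lapply(explicit, function(g)
      list(name = g, members = as.list(model$groups[[g]]))))
  writeLines(jsonlite::toJSON(j, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

# mass-action rate vector at state y
.reaction_rates <- function(model, y) {
  vapply(model$reactions, function(r) {
    r$k * prod(y[r$reactants]) * prod(y[r$modifiers])
  }, numeric(1))
}

# dy/dt = S %*% v(y)
.mass_action_rhs <- function(t, y, model) {
  if (length(model$reactions) == 0L) {
    return(list(rep(0, length(y))))
  }
  v <- .reaction_rates(model, y)
  list(as.vector(model$stoich[, seq_along(v), drop = FALSE] %*% v))
}

#' Log-spaced output grid from 0 to a horizon
#'
#' 0 followed by `n - 1` log-spaced points spanning six decades up to
#' `horizon`; signaling cascades mix fast early phosphorylation
#' transients with slow approach to steady state, so a log grid resolves
#' both.
#'
#' @param horizon final time, > 0.
#' @param n number of grid points (default 200).
#' @return increasing numeric vector starting at 0.
#' @export
log_time_grid <- function(horizon, n = 200) {
  stopifnot(horizon > 0, n >= 2)
  c(0, 10^seq(log10(horizon) - 6, log10(horizon), length.out = n - 1L))
}

#' Simulate a kinetic model
#'
#' Integrates the mass-action ODE system with a stiff-capable solver
#' (`deSolve::lsoda`) on a log-spaced output grid and verifies that
#' conservation groups stay at their totals within integration
#' tolerance.
#'
#' @param model a `kinetic_model`.
#' @param horizon integration end time (default 1e4 time units).
#' @param rtol,atol relative/absolute integrator tolerances.
#' @param times optional explicit increasing output grid starting at 0
#'   (overrides `horizon`/`n_grid`).
#' @param n_grid number of output points for the default grid.
#' @return object of class `pas_timecourse`: list with `times`,
#'   `concentrations` (times x species matrix), `effector`, `eff`
#'   (effector trajectory), `model`.
#' @export
simulate_network <- function(model, horizon = 1e4, rtol = 1e-8,
                             atol = 1e-10, times = NULL, n_grid = 200) {
  stopifnot(inherits(model, "kinetic_model"))
  if (is.null(times)) {
    times <- log_time_grid(horizon, n_grid)
  } else {
    stopifnot(times[1L] == 0, !is.unsorted(times, strictly = TRUE))
  }
  sol <- deSolve::lsoda(y = model$conc0, times = times,
                        func = .mass_action_rhs, parms = model,
                        rtol = rtol, atol = atol)
  diagn <- attributes(sol)$istate
  if (!is.null(diagn) && diagn[1L] < 0) {
    stop("ODE integration failed (lsoda istate = ", diagn[1L], ")")
  }
  if (nrow(sol) < length(times)) {
    stop("ODE integration stopped early at t = ", sol[nrow(sol), 1L])
  }
  conc <- sol[, model$species, drop = FALSE]
  neg_tol <- 100 * atol
  if (any(conc < -neg_tol)) {
    stop("negative concentration beyond tolerance during integration")
  }
  conc[conc < 0] <- 0
  totals <- model_totals(model)
  if (length(model$reactions) > 0L) {
    for (g in names(model$groups)) {
      members <- model$groups[[g]]
      # only structurally conserved groups are invariants of the flow;
      # implicit singletons of consumed species are totals, not laws
      net <- colSums(model$stoich[members, , drop = FALSE])
      if (any(net != 0)) next
      gsum <- rowSums(conc[, members, drop = FALSE])
      scale <- max(1, abs(totals[[g]]))
      if (any(abs(gsum - totals[[g]]) > 100 * (atol + rtol * scale))) {
        stop("conservation violated for group '", g, "'")
      }
    }
  }
  structure(list(times = times, concentrations = conc,
                 effector = model$effector,
                 eff = conc[, model$effector],
                 rtol = rtol, atol = atol, model = model),
            class = "pas_timecourse")
}

#' Detect the steady-state time of a simulated trajectory
#'
#' Returns the first output time at which the scaled derivative norm
#' `max_j |dC_j/dt| / (atol + |C_j|)` falls below `tol` and stays below
#' it for the remainder of the horizon, or `NA` if the system never
#' settles within the simulated window. This time is the upper limit of
#' the sensitivity integral.
#'
#' @param course a `pas_timecourse`.
#' @param tol settling tolerance on the scaled derivative norm (default
#'   1e-6 per time unit).
#' @param atol derivative scaling floor (defaults to the course's
#'   integration atol).
#' @return time `T`, or `NA_real_` if not reached.
#' @export
detect_steady_state <- function(course, tol = 1e-6, atol = NULL) {
  stopifnot(inherits(course, "pas_timecourse"))
  if (is.null(atol)) atol <- course$atol
  model <- course$model
  norms <- vapply(seq_along(course$times), function(i) {
    y <- course$concentrations[i, ]
    dy <- .mass_action_rhs(course$times[i], y, model)[[1L]]
    max(abs(dy) / (atol + abs(y)))
  }, numeric(1))
  below <- norms < tol
  # first index from which the condition persists to the end
  persists <- rev(cumprod(rev(below))) > 0
  if (!any(persists)) return(NA_real_)
  course$times[which(persists)[1L]]
}

#' Write a simulated time course as TSV
#'
#' @param course a `pas_timecourse`.
#' @param path output path.
#' @param header_lines optional `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(course, path, header_lines = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines) > 0L) writeLines(header_lines, con)
  cols <- colnames(course$concentrations)
  writeLines(paste(c("time", cols), collapse = "\t"), con)
  body <- cbind(course$times, course$concentrations)
  writeLines(apply(body, 1L, function(r)
    paste(formatC(r, digits = 10, format = "g"), collapse = "\t")), con)
  invisible(path)
}
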