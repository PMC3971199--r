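# shared in-code fixtures; nothing is read from disk unless a test
# writes it first

# two-pathway catalog: P1 mixed roles, P2 pure activators
fix_catalog <- function() {
  pas_catalog(data.frame(
    pathway = c("P1", "P1", "P1", "P1", "P2", "P2"),
    gene = c("G1", "G2", "G3", "G4", "G1", "G5"),
    arr = c(1, -1, 0.5, 0, 1, 1),
    stringsAsFactors = FALSE))
}

# deterministic dataset: tight norms around stated means, case values
# chosen per test via the `case` argument (named by gene)
fix_dataset <- function(case = c(G1 = 20, G2 = 10, G3 = 10, G4 = 10,
                                 G5 = 10),
                        norms = list(G1 = c(9, 11), G2 = c(9, 11),
                                     G3 = c(9, 11), G4 = c(9, 11),
                                     G5 = c(9, 11))) {
  genes <- names(norms)
  n_norm <- length(norms[[1L]])
  vals <- cbind(do.call(rbind, norms),
                matrix(case[genes], ncol = 1))
  colnames(vals) <- c(sprintf("n%d", seq_len(n_norm)), "c1")
  rownames(vals) <- genes
  labels <- stats::setNames(c(rep("norm", n_norm), "case"),
                            colnames(vals))
  pas_expression(vals, labels)
}

# one-step activation cascade and its closed-form trajectory
fix_onestep <- function(kf = 1, kb = 1, S = 1, total = 1) {
  generate_cascade(1, k_forward = kf, k_backward = kb,
                   stimulus_conc = S, tier_total = total)
}

onestep_exact <- function(t, kf = 1, kb = 1, S = 1, total = 1) {
  b <- kf * S + kb
  kf * S * total / b * (1 - exp(-b * t))
}

# undamped Lotka-Volterra predator-prey loop: mass-action network that
# never reaches a steady state from a non-equilibrium start
fix_oscillator <- function() {
  kinetic_model(
    data.frame(name = c("X", "Y"), conc = c(1, 0.5)),
    list(list(reactants = "X", products = c("X", "X"), k = 1),
         list(reactants = c("X", "Y"), products = c("Y", "Y"), k = 1),
         list(reactants = "Y", products = character(), k = 1)),
    effector = "Y")
}

# independent eigen oracle: power iteration for the largest-|lambda|
# eigenpair of a symmetric matrix
power_iteration <- function(H, n_iter = 5000, tol = 1e-13) {
  v <- rep(1, nrow(H)) / sqrt(nrow(H))
  lambda <- 0
  for (i in seq_len(n_iter)) {
    hv <- H %*% v
    nv <- sqrt(sum(hv^2))
    if (nv == 0) return(list(lambda = 0, vector = v))
    v_new <- as.vector(hv / nv)
    lambda_new <- sum(v_new * (H %*% v_new))
    if (max(abs(abs(v_new) - abs(v))) < tol) {
      return(list(lambda = lambda_new, vector = v_new))
    }
    v <- v_new
    lambda <- lambda_new
  }
  list(lambda = lambda, vector = v)
}
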