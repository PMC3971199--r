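test_that("sensitivity importance recovers closed-form log-sensitivities", {
  m <- fix_onestep()
  # the effector scales linearly with its own tier total, so the
  # log-sensitivity is 1 at every time
  w1_e <- sensitivity_importance(m, "tier1")
  expect_equal(as.numeric(w1_e), 1, tolerance = 1e-3)
  # at large T the time average approaches the steady-state value
  # d ln EFF / d ln S = k2 / (k1 S + k2) = 0.5
  w1_s <- sensitivity_importance(m, "S", t_end = 100)
  expect_equal(as.numeric(w1_s), 0.5, tolerance = 1e-2)
})

test_that("totals with no reaction path to the effector get w1 = 0 exactly", {
  m <- fix_onestep()
  sp <- rbind(data.frame(name = m$species, conc = unname(m$conc0)),
              data.frame(name = "Z", conc = 5))
  m2 <- kinetic_model(sp, m$reactions, m$effector,
                      list(list(name = "tier1",
                                members = c("X1", "X1a"))))
  expect_identical(as.numeric(sensitivity_importance(m2, "Z")), 0)
})

test_that("w1 is invariant under rescaling the unit of time", {
  slow <- generate_cascade(2, k_forward = 0.8, k_backward = 0.5)
  fast <- generate_cascade(2, k_forward = 8, k_backward = 5)
  w_slow <- sensitivity_importance(slow, "tier1", t_end = 40)
  w_fast <- sensitivity_importance(fast, "tier1", t_end = 4)
  expect_equal(as.numeric(w_slow), as.numeric(w_fast),
               tolerance = 1e-6)
})

test_that("the objective Hessian is exact on a quadratic degenerate model", {
  # effector equals its own conserved total: EFF(C, t) = C, so
  # S(C) = (C - c0)^2 / sigma^2 and the Hessian is the constant 2/sigma^2
  m <- kinetic_model(data.frame(name = "C", conc = 2), list(), "C")
  H <- objective_hessian(m, exp_times = 1, exp_values = 2,
                         exp_sigmas = 1)
  expect_equal(unname(H[1, 1]), 2, tolerance = 1e-9)
  H2 <- objective_hessian(m, exp_times = 1, exp_values = 2,
                          exp_sigmas = 0.5)
  expect_equal(unname(H2[1, 1]), 8, tolerance = 1e-8)
  expect_error(objective_hessian(m, 1, 2, 0), "sigmas")
})

test_that("totals that cannot move the effector zero their Hessian row", {
  m <- kinetic_model(data.frame(name = c("C", "Z"), conc = c(2, 7)),
                     list(), "C")
  H <- objective_hessian(m, exp_times = c(1, 2), exp_values = c(2, 2),
                         exp_sigmas = c(1, 1))
  expect_identical(unname(H["Z", ]), c(0, 0))
  expect_identical(unname(H[, "Z"]), c(0, 0))
  expect_gt(H["C", "C"], 0)
})

test_that("the finite-difference Hessian agrees with an independent oracle", {
  m <- generate_cascade(2, k_forward = 1.5, k_backward = 0.8)
  ed <- generate_effector_experiment(m, times = c(0.5, 1, 2, 4, 8),
                                     sigma = 0.05, seed = 42)
  H <- objective_hessian(m, ed$time, ed$eff, ed$sigma, rel_step = 0.02)
  # independent brute-force second differences at half the step
  groups <- names(m$groups)
  S_of <- function(factors) {
    mm <- m
    for (g in names(factors)) mm <- scale_total(mm, g, factors[[g]])
    co <- simulate_network(mm, times = sort(unique(c(0, ed$time))))
    eff <- co$eff[match(sort(ed$time), co$times)]
    sum((eff - ed$eff[order(ed$time)])^2 / ed$sigma[order(ed$time)]^2)
  }
  h <- 0.01
  Hb <- matrix(0, length(groups), length(groups),
               dimnames = list(groups, groups))
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      fi <- groups[i]; fj <- groups[j]
      if (i == j) {
        Hb[i, i] <- (S_of(stats::setNames(1 + h, fi)) -
                       2 * S_of(stats::setNames(1, fi)) +
                       S_of(stats::setNames(1 - h, fi))) /
          (h * model_totals(m)[[fi]])^2
      } else {
        Hb[i, j] <- (S_of(stats::setNames(c(1 + h, 1 + h), c(fi, fj))) -
                       S_of(stats::setNames(c(1 + h, 1 - h),
                                            c(fi, fj))) -
                       S_of(stats::setNames(c(1 - h, 1 + h),
                                            c(fi, fj))) +
                       S_of(stats::setNames(c(1 - h, 1 - h),
                                            c(fi, fj)))) /
          (4 * h^2 * model_totals(m)[[fi]] * model_totals(m)[[fj]])
      }
    }
  }
  expect_equal(H[groups, groups], Hb, tolerance = 1e-2)
  expect_lt(max(abs(H - t(H))), 1e-12)
})

test_that("stiffness importance picks the largest-|lambda| unit eigenvector", {
  expect_equal(as.numeric(stiffness_importance(matrix(2, 1, 1,
                                                      dimnames = list("a",
                                                                      "a")))),
               1)
  H <- diag(c(9, 1))
  dimnames(H) <- list(c("a", "b"), c("a", "b"))
  expect_equal(as.numeric(stiffness_importance(H)), c(1, 0))
  # negative eigenvalue of larger magnitude wins
  H2 <- diag(c(3, -5))
  dimnames(H2) <- list(c("a", "b"), c("a", "b"))
  w <- stiffness_importance(H2)
  expect_equal(as.numeric(w), c(0, 1))
  expect_equal(attr(w, "lambda"), -5)
  expect_error(stiffness_importance(matrix(c(1, 2, 3, 4), 2)),
               "not symmetric")
})

test_that("stiffest eigenpairs agree with a power-iteration oracle", {
  set.seed(404)
  for (i in 1:20) {
    A <- matrix(rnorm(25), 5)
    H <- (A + t(A)) / 2
    dimnames(H) <- list(letters[1:5], letters[1:5])
    w2 <- stiffness_importance(H)
    expect_equal(sum(w2^2), 1, tolerance = 1e-12)
    lam <- attr(w2, "lambda")
    # eigen residual against the reported pair
    ev <- eigen(H, symmetric = TRUE)
    k <- which.max(abs(ev$values))
    expect_lt(max(abs(H %*% ev$vectors[, k] -
                        ev$values[k] * ev$vectors[, k])), 1e-9)
    # independent oracle
    po <- power_iteration(H)
    expect_equal(abs(lam), abs(po$lambda), tolerance = 1e-8)
    expect_equal(as.numeric(w2), abs(as.numeric(po$vector)), tolerance = 1e-6)
  }
})

test_that("w2 is invariant under a common rescaling of measurement errors", {
  m <- generate_cascade(2)
  ed <- generate_effector_experiment(m, times = c(0.5, 1, 2, 4),
                                     sigma = 0.05, seed = 7)
  H1 <- objective_hessian(m, ed$time, ed$eff, ed$sigma)
  H2 <- objective_hessian(m, ed$time, ed$eff, 3 * ed$sigma)
  expect_equal(unname(H2), unname(H1) / 9, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(stiffness_importance(H1), stiffness_importance(H2),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("both importance methods agree on a single-influencer model", {
  m <- kinetic_model(data.frame(name = c("C", "Z"), conc = c(2, 7)),
                     list(), "C")
  w1 <- vapply(c("C", "Z"), function(g)
    as.numeric(sensitivity_importance(m, g)), numeric(1))
  H <- objective_hessian(m, c(1, 2), c(2, 2), c(1, 1))
  w2 <- stiffness_importance(H)
  expect_identical(names(which.max(w1)), "C")
  expect_identical(names(which.max(w2)), "C")
})

test_that("species importance maps onto pathway weights with mean-1 scale", {
  pw <- data.frame(gene = c("gA", "gB"), arr = c(1, -1))
  map <- c(gA = "spA", gB = "spB")
  wv <- map_importance_to_weights(c(spA = 2, spB = 4), map, pw,
                                  method = "sensitivity")
  expect_equal(unname(wv$weights), c(2 / 3, 4 / 3))
  # an unmapped gene gets the mean of the mapped genes before rescaling
  pw3 <- data.frame(gene = c("gA", "gB", "gX"), arr = c(1, -1, 1))
  wv3 <- map_importance_to_weights(c(spA = 1, spB = 3), map, pw3,
                                   method = "stiffness")
  expect_equal(unname(wv3$weights), c(0.5, 1.5, 1))
  expect_identical(attr(wv3, "n_unmapped"), 1L)
  expect_error(map_importance_to_weights(c(spQ = 1), map, pw,
                                         method = "sensitivity"),
               "no pathway gene maps")
  # all genes mapped with equal importance: uniform after rescaling
  wvu <- map_importance_to_weights(c(spA = 5, spB = 5), map, pw,
                                   method = "sensitivity")
  expect_equal(unname(wvu$weights), c(1, 1))
})
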