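test_that("signal outcome is the activator product over the repressor product", {
  pw <- data.frame(gene = c("A1", "A2", "R1"), arr = c(1, 0.5, -1))
  expect_equal(compute_signal_outcome(pw, c(A1 = 2, A2 = 5, R1 = 10)),
               1.0)
  pw2 <- data.frame(gene = "A1", arr = 1)
  expect_equal(compute_signal_outcome(pw2, c(A1 = 3)), 3.0)
  expect_equal(compute_signal_outcome(pw, c(A1 = 1, A2 = 1, R1 = 1)),
               1.0)
  expect_error(compute_signal_outcome(pw, c(A1 = 2, A2 = 5)),
               "no expression level")
})

test_that("PAS terms multiply role, BTIF gate, weight and lg CNR", {
  # norms {10,10} are exactly the mean, so cnr = case/10
  norms <- list(G1 = c(10, 10), G2 = c(10, 10), G3 = c(10, 10),
                G4 = c(10, 10), G5 = c(10, 10))
  mk <- function(case) dataset_gene_stats(fix_dataset(case, norms),
                                          sd_multiplier = 0)
  one <- data.frame(gene = "G1", arr = 1)
  st <- mk(c(G1 = 100, G2 = 10, G3 = 10, G4 = 10, G5 = 10))
  expect_equal(compute_pas(one, st, "c1")$pas, 1.0)
  expect_equal(compute_pas(data.frame(gene = "G1", arr = -1), st,
                           "c1")$pas, -1.0)
  two <- data.frame(gene = c("G1", "G2"), arr = c(1, 1))
  st2 <- mk(c(G1 = 100, G2 = 1000, G3 = 10, G4 = 10, G5 = 10))
  wv <- pas_weights("P", c(G1 = 2, G2 = 0.5), source = "perturbation")
  expect_equal(compute_pas(two, st2, "c1", weights = wv)$pas,
               2 * 1 + 0.5 * 2)
  expect_error(compute_pas(two, st2, "c1",
                           weights = pas_weights("P", c(G1 = 2),
                                                 source = "perturbation")),
               "missing pathway gene")
  expect_error(compute_pas(two, st2, "nope"), "unknown case sample")
})

test_that("PAS with unit roles is lg of the signal outcome on CNR levels", {
  spec <- synthesis_spec(n_pathways = 6, half_role_fraction = 0,
                         gene_pool = 80, seed = 11)
  ct <- generate_catalog(spec)
  ds <- generate_expression(spec, ct)
  st <- dataset_gene_stats(ds)
  for (p in unique(ct$pathway)) {
    pw <- catalog_pathway(ct, p)
    for (s in ds$case_samples) {
      cnr <- stats::setNames(st$cnr[pw$gene, s], pw$gene)
      pas <- compute_pas(pw, st, s, apply_btif = FALSE)$pas
      expect_equal(pas, log10(compute_signal_outcome(pw, cnr)),
                   tolerance = 1e-12)
    }
  }
})

test_that("negating every role negates PAS exactly", {
  spec <- synthesis_spec(n_pathways = 4, gene_pool = 60, seed = 12)
  ct <- generate_catalog(spec)
  ds <- generate_expression(spec, ct)
  st <- dataset_gene_stats(ds)
  for (p in unique(ct$pathway)) {
    pw <- catalog_pathway(ct, p)
    neg <- pw; neg$arr <- -neg$arr
    for (btif in c(TRUE, FALSE)) {
      expect_identical(compute_pas(neg, st, "case01",
                                   apply_btif = btif)$pas,
                       -compute_pas(pw, st, "case01",
                                    apply_btif = btif)$pas)
    }
  }
})

test_that("neutral members never change PAS", {
  ds <- fix_dataset()
  st <- dataset_gene_stats(ds)
  pw <- data.frame(gene = c("G1", "G2"), arr = c(1, -1))
  pw0 <- rbind(pw, data.frame(gene = c("G3", "G5"), arr = c(0, 0)))
  expect_identical(compute_pas(pw0, st, "c1")$pas,
                   compute_pas(pw, st, "c1")$pas)
})

test_that("a pathway gene absent from the platform contributes exactly 0", {
  ds <- fix_dataset()
  st <- dataset_gene_stats(ds)
  pw <- data.frame(gene = c("G1", "G2", "ABSENT"), arr = c(1, -1, 1))
  r <- compute_pas(pw, st, "c1", apply_btif = FALSE)
  expect_identical(r$n_missing, 1L)
  r2 <- compute_pas(pw[1:2, ], st, "c1", apply_btif = FALSE)
  expect_identical(r$pas, r2$pas)
  # removing a measured gene removes exactly its former term
  r3 <- compute_pas(pw[c(1, 3), ], st, "c1", apply_btif = FALSE)
  term_g2 <- -1 * log10(st$cnr["G2", "c1"])
  expect_equal(r$pas - r3$pas, term_g2)
})

test_that("with the BTIF gate on, only flagged genes drive PAS", {
  spec <- synthesis_spec(n_pathways = 5, gene_pool = 60, seed = 13,
                         planted = c(SP02 = 10))
  ct <- generate_catalog(spec)
  ds <- generate_expression(spec, ct)
  st <- dataset_gene_stats(ds)
  for (p in unique(ct$pathway)) {
    pw <- catalog_pathway(ct, p)
    flagged <- pw[st$btif[pw$gene, "case01"] == 1, , drop = FALSE]
    full <- compute_pas(pw, st, "case01", apply_btif = TRUE)
    expect_identical(full$n_btif_pass, nrow(flagged))
    if (nrow(flagged) == 0L) {
      expect_identical(full$pas, 0)
    } else {
      expect_equal(full$pas,
                   compute_pas(flagged, st, "case01",
                               apply_btif = FALSE)$pas)
    }
  }
})

test_that("score_catalog enumerates pathway x case sample and is closed-form
           shiftable under case doubling", {
  ct <- fix_catalog()
  spec <- synthesis_spec(n_pathways = 2, n_case = 3L, seed = 5)
  # catalog of 2 pathways, 3 case samples -> 6 rows in catalog order
  ds <- generate_expression(spec, ct)
  sc <- score_catalog(ct, ds)
  expect_identical(nrow(sc), 6L)
  expect_identical(sc$pathway, rep(c("P1", "P2"), each = 3))

  # a case sample sitting exactly on the norm mean scores 0 everywhere
  vals <- ds$values
  nm <- rowMeans(vals[, ds$norm_samples])
  vals[, "case01"] <- nm
  sc0 <- score_catalog(pas_catalog(ct), pas_expression(vals, ds$labels))
  expect_true(all(sc0$pas[sc0$sample == "case01"] == 0))

  # doubling every case value of a pure-activator pathway shifts its
  # PAS by n_genes * lg 2 (gate off; verified against recomputation)
  pure <- pas_catalog(data.frame(pathway = "PURE",
                                 gene = c("G1", "G2", "G5"),
                                 arr = c(1, 1, 1)))
  base <- score_catalog(pure, ds, apply_btif = FALSE)
  vals2 <- ds$values
  vals2[c("G1", "G2", "G5"), ds$case_samples] <-
    vals2[c("G1", "G2", "G5"), ds$case_samples] * 2
  shifted <- score_catalog(pure, pas_expression(vals2, ds$labels),
                           apply_btif = FALSE)
  expect_equal(shifted$pas, base$pas + 3 * log10(2), tolerance = 1e-12)
})
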