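make_panel <- function(...) sim_pharmaco(...)

test_that("feature assembly concatenates blocks over shared cell lines", {
  cells <- paste0("CL", 1:6)
  mut <- matrix(rbinom(18, 1, 0.5), 3, 6,
                dimnames = list(paste0("G", 1:3), cells))
  cna <- matrix(rbinom(12, 1, 0.5), 2, 6,
                dimnames = list(paste0("R", 1:2), cells))
  fm <- assemble_features(mut, cna, NULL)
  expect_equal(nrow(fm$X), 5L)
  expect_equal(fm$info$kind, c(rep("gene_mutation", 3), rep("focal_cna", 2)))

  # 710 CFE rows + 78 CAA rows give the full 788-feature panel
  cfe <- matrix(0L, 710, 3,
                dimnames = list(paste0("CFE", 1:710), paste0("CL", 1:3)))
  calls <- matrix(0L, 3, 39,
                  dimnames = list(paste0("CL", 1:3),
                                  caa_arm_model()$arm_id[caa_arm_model()$included]))
  fm <- assemble_features(cfe, NULL, caa_matrix(calls))
  expect_equal(nrow(fm$X), 788L)
  expect_equal(sum(fm$info$kind == "caa"), 78L)
  expect_equal(fm$info$arm[fm$info$feature == "+17p"], "17p")
  expect_equal(fm$info$direction[fm$info$feature == "-8q"], "loss")

  dup <- mut
  rownames(dup) <- c("G1", "G1", "G3")
  expect_error(assemble_features(dup, NULL, NULL), "duplicate")
  bad <- mut
  bad[1, 1] <- 2L
  expect_error(assemble_features(bad, NULL, NULL), "binary")
  cna2 <- cna
  colnames(cna2) <- paste0("XX", 1:6)
  expect_error(assemble_features(mut, cna2, NULL), "intersection")
})

test_that("drugs are filtered by their sensitive-call fraction", {
  calls <- rbind(
    D1 = c(rep("sensitive", 4), rep("resistant", 16)),   # 20%
    D2 = c(rep("sensitive", 2), rep("resistant", 18)),   # 10%
    D3 = c(rep("sensitive", 3), rep("resistant", 17)))   # 15% exactly
  kept <- filter_drugs_by_sensitivity(calls)
  expect_setequal(kept, c("D1", "D3"))
  allna <- rbind(calls, D4 = rep(NA_character_, 20))
  expect_warning(kept <- filter_drugs_by_sensitivity(allna), "D4")
  expect_false("D4" %in% kept)
})

test_that("kNN imputation fills gaps without touching observed values", {
  ic50 <- rbind(D1 = c(NA, 1, 2, 3, 4),
                D2 = c(5, 1, 2, 3, 4),
                D3 = c(5, 1, 2, 3, 4),
                D4 = c(5, 1, 2, 3, 4),
                D5 = c(5, 1, 2, 3, 4))
  colnames(ic50) <- paste0("CL", 1:5)
  out <- impute_ic50_knn(ic50)
  expect_equal(out["D1", "CL1"], 5)  # all four neighbours agree
  expect_equal(out[-1, ], ic50[-1, ])

  # no missing entries: identity
  expect_identical(impute_ic50_knn(ic50[-1, ]), ic50[-1, ])

  # a zero-distance neighbour dominates
  ic2 <- rbind(D1 = c(NA, 1, 2), D2 = c(9, 1, 2), D3 = c(7, 5, 5),
               D4 = c(6, 4, 4), D5 = c(5, 3, 3))
  colnames(ic2) <- paste0("CL", 1:3)
  out <- impute_ic50_knn(ic2)
  expect_equal(out["D1", "CL1"], 9)

  # fewer than k neighbours: fall back with a warning
  ic3 <- rbind(D1 = c(NA, 1), D2 = c(4, 1))
  colnames(ic3) <- c("CL1", "CL2")
  expect_warning(out <- impute_ic50_knn(ic3), "fewer than 4")
  expect_equal(out["D1", "CL1"], 4)
})

test_that("Glass' delta uses the unaltered group's standard deviation", {
  # altered mean 1.5, wild-type mean 0.5: delta = 1 / sd(wild-type)
  wt <- c(0, 1, 0, 1)
  expect_equal(glass_delta(c(1.5, 1.5, wt), c(1, 1, 0, 0, 0, 0)),
               1 / sd(wt), tolerance = 1e-12)
  expect_equal(glass_delta(c(5, 5, 5, 5), c(1, 1, 0, 0)), 0)
  expect_warning(d <- glass_delta(c(2, 1), c(1, 0)), "fewer than 2")
  expect_true(is.na(d))
  expect_warning(d <- glass_delta(c(2, 1, 1), c(1, 0, 0)), "zero spread")
  expect_true(is.na(d))
})

test_that("feature pair enumeration is complete and deterministic", {
  expect_equal(enumerate_feature_pairs(matrix(0, 4, 1))$count, 6)
  out <- enumerate_feature_pairs(matrix(0, 2, 1))
  expect_equal(out$count, 1)
  expect_equal(nrow(out$pairs), 1L)
  for (F_ in c(2, 17, 100, 788)) {
    expect_equal(enumerate_feature_pairs(seq_len(F_))$count,
                 F_ * (F_ - 1) / 2)
  }
  expect_equal(enumerate_feature_pairs(seq_len(788))$count, 310078)
  expect_error(enumerate_feature_pairs(matrix(0, 1, 1)), "at least 2")
})

test_that("the SL/SR screen calls a strongly enriched planted table", {
  # 10 pair-positive lines with 9 sensitive vs 30 pair-negative with 3
  cells <- paste0("CL", 1:40)
  X <- rbind(FA = c(rep(1L, 10), rep(0L, 30)),
             FB = c(rep(1L, 10), rep(0L, 30)))
  colnames(X) <- cells
  calls <- matrix("resistant", 1, 40, dimnames = list("D1", cells))
  calls[1, c(1:9, 11:13)] <- "sensitive"
  res <- sl_sr_screen(X, calls)
  row <- res[res$feature1 == "FA" & res$feature2 == "FB", ]
  expect_equal(c(row$n_pp_sens, row$n_pp_res, row$n_pn_sens, row$n_pn_res),
               c(9, 1, 3, 27))
  expect_equal(row$p, fisher.test(matrix(c(9, 3, 1, 27), 2))$p.value,
               tolerance = 1e-12)
  expect_equal(row$class, "synthetic_lethal")
  # margins reconcile with the non-missing call count
  expect_equal(row$n_pp_sens + row$n_pp_res + row$n_pn_sens + row$n_pn_res,
               40)
})

test_that("the screen skips degenerate tables and honours missing calls", {
  cells <- paste0("CL", 1:20)
  X <- rbind(FA = c(rep(1L, 10), rep(0L, 10)),
             FB = c(rep(0L, 10), rep(1L, 10)))  # never co-occur
  colnames(X) <- cells
  calls <- matrix(rep(c("sensitive", "resistant"), 10), 1, 20,
                  dimnames = list("D1", cells))
  res <- sl_sr_screen(X, calls)
  expect_equal(nrow(res), 0L)
  expect_gte(attr(res, "skipped"), 1L)

  # missing calls are excluded listwise
  calls[1, 1:5] <- NA
  X2 <- rbind(X, FC = rep(c(1L, 0L), 10))
  res <- sl_sr_screen(X2, calls)
  if (nrow(res)) {
    expect_true(all(res$n_pp_sens + res$n_pp_res + res$n_pn_sens +
                      res$n_pn_res == 15))
  }
})

test_that("a null pharmacogenomic panel yields no interaction calls", {
  sim <- make_panel(n_cell_lines = 120, n_features = 8, n_drugs = 3,
                    seed = 91)
  res <- sl_sr_screen(sim$features, sim$calls)
  expect_equal(sum(res$class != "none"), 0L)
})

test_that("a strong planted pair is recovered as synthetic lethal", {
  planted <- data.frame(feature1 = "F1", feature2 = "F2", drug = "D1",
                        odds_ratio = 20)
  sim <- make_panel(n_cell_lines = 200, n_features = 8, n_drugs = 2,
                    planted_pair_effects = planted, seed = 7)
  res <- sl_sr_screen(sim$features, sim$calls)
  hit <- res[res$feature1 == "F1" & res$feature2 == "F2" &
               res$drug == "D1" & res$group == "pan-cancer", ]
  expect_equal(hit$class, "synthetic_lethal")
  others <- res[!(res$feature1 == "F1" & res$feature2 == "F2" &
                    res$drug == "D1"), ]
  expect_equal(sum(others$class != "none"), 0L)
})

test_that("focal hits explain CAA hits only on a full four-key match", {
  caa_hits <- data.frame(
    arm = c("17p", "17p", "8q"), direction = c("loss", "loss", "gain"),
    drug = c("MCL1i", "MCL1i", "DrugX"),
    cancer_type = c("LAML", "BRCA", "LAML"), stringsAsFactors = FALSE)
  focal_hits <- data.frame(
    arm = c("17p", "8q"), direction = c("loss", "loss"),
    drug = c("MCL1i", "DrugX"), cancer_type = c("LAML", "LAML"),
    stringsAsFactors = FALSE)
  out <- focal_explains_caa(caa_hits, focal_hits)
  expect_equal(out$explained,
               c("explained",     # same arm, direction, drug, type
                 "independent",   # different cancer type
                 "independent"))  # same arm but opposite direction
  focal_na <- focal_hits
  focal_na$arm[1] <- NA
  expect_warning(out <- focal_explains_caa(caa_hits, focal_na), "arm")
  expect_equal(out$explained[1], "independent")
})

test_that("F1 is the harmonic mean with zero-degenerate inputs", {
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0.8, 0.5), 8 / 13, tolerance = 1e-12)
  expect_equal(f1_score(0, 0.9), 0)
  expect_equal(f1_score(0.9, 0), 0)
  expect_error(f1_score(1.2, 0.5), "0, 1")
  # symmetry and the harmonic <= arithmetic mean bound
  set.seed(5)
  p <- runif(50); r <- runif(50)
  expect_equal(f1_score(p, r), f1_score(r, p))
  expect_true(all(f1_score(p, r) <= (p + r) / 2 + 1e-12))
})
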