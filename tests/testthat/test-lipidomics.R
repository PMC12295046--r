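test_that("blank filter removes contaminated features with a strict boundary", {
  X <- rbind(
    c(0, 0, 0, 100),     # blank-only feature -> removed
    c(100, 120, 110, 0), # absent from blank -> retained
    c(100, 100, 100, 10),# exactly at the 0.1 threshold -> retained (strict >)
    c(100, 100, 100, 11) # just above -> removed
  )
  tab <- tiny_feature_table(X, roles = c("study", "study", "study", "blank"))
  out <- remove_blank_features(tab, blank_fraction = 0.1)
  expect_setequal(out$features$feature_id, c("F02", "F03"))
  expect_match(provenance(out), "blank filter", all = FALSE)
})

test_that("QC CV filter removes above 20% strictly, zero-mean separately", {
  qc1 <- c(100, 100, 100)                 # CV 0 -> retained
  qc2 <- c(100, 200, 150)                 # CV 33.3% -> removed
  qc3 <- c(100, 100, 100) * c(0.8, 1, 1.2)  # CV 20.0% -> retained (strict >)
  qc0 <- c(0, 0, 0)                       # zero mean -> removed, own reason
  X <- cbind(c(1, 1, 1, 1), rbind(qc1, qc2, qc3, qc0))
  cv3 <- 100 * stats::sd(qc3) / mean(qc3)
  expect_equal(cv3, 20)
  tab <- tiny_feature_table(X, roles = c("study", "qc", "qc", "qc"))
  out <- qc_cv_filter(tab, max_cv_percent = 20)
  expect_setequal(out$features$feature_id, c("F01", "F03"))
  expect_match(provenance(out), "zero-mean", all = FALSE)

  # two-replicate arithmetic: (100, 200) -> sd 70.71, mean 150, CV 47.1%
  tab2 <- tiny_feature_table(rbind(c(1, 100, 200)),
                             roles = c("study", "qc", "qc"))
  expect_equal(nrow(qc_cv_filter(tab2)$features), 0)
  expect_equal(100 * stats::sd(c(100, 200)) / mean(c(100, 200)), 47.14045,
               tolerance = 1e-6)
})

test_that("CV filtering is invariant to global intensity rescaling", {
  ft <- make_feature_table(seed = 31)
  t1 <- qc_cv_filter(ft$table)
  scaled <- feature_table(ft$table$features, ft$table$samples,
                          ft$table$intensities * 1e3)
  t2 <- qc_cv_filter(scaled)
  expect_identical(t1$features$feature_id, t2$features$feature_id)
})

test_that("normalization divides study columns only, errors on bad factors", {
  X <- cbind(10, 20, 30)
  tab <- tiny_feature_table(rbind(c(10, 20, 30)),
                            roles = c("study", "study", "qc"))
  tab$samples$quantity <- c(2, 1, 5)
  out <- normalize_table(tab, "quantity")
  expect_equal(unname(out$intensities[1, ]), c(5, 20, 30))  # qc untouched
  # identity factors
  tab$samples$quantity <- 1
  expect_equal(normalize_table(tab, "quantity")$intensities, tab$intensities)
  # missing factor names the sample
  tab$samples$quantity <- c(NA, 1, 1)
  expect_error(normalize_table(tab, "quantity"), "S01")
  expect_error(normalize_table(tab, "nope"), "nope")
})

test_that("adduct annotation hits the stated mass arithmetic", {
  ref <- data.frame(name = "PE(34:1)", class = "glycerophospholipid",
                    monoisotopic_mass = 717.530876)
  tab <- tiny_feature_table(rbind(1), roles = "study", mz = 718.5380)
  ann <- annotate_adducts(tab, ref, ppm_tol = 10)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$adduct, "M+H")
  expect_equal(ann$theoretical_mz, 718.538152)
  expect_lt(abs(ann$ppm_error), 0.3)

  # 25 ppm away: no match at 10 ppm
  far <- tiny_feature_table(rbind(1), roles = "study",
                            mz = 718.538152 * (1 + 25e-6))
  expect_equal(nrow(annotate_adducts(far, ref)), 0)

  # empty reference: empty output
  expect_equal(nrow(annotate_adducts(tab, ref[0, ])), 0)
})

test_that("features synthesized at 0 ppm are fully re-annotated", {
  ft <- make_feature_table(seed = 17)
  ann <- annotate_adducts(ft$table, ft$reference)
  ok <- vapply(ft$table$features$feature_id, function(fid) {
    rows <- ann[ann$feature_id == fid, ]
    any(rows$adduct == ft$planted$adduct[[fid]] & abs(rows$ppm_error) < 1e-6)
  }, logical(1))
  expect_true(all(ok))
})

test_that("class composition percentages, fold changes and sentinels", {
  X <- rbind(c(30, 30), c(10, 10), c(0, 5))
  tab <- tiny_feature_table(X, roles = c("study", "study"),
                            groups = c("WT", "mut"))
  ann <- data.frame(feature_id = c("F01", "F02", "F03"),
                    candidate_name = c("a", "b", "c"),
                    lipid_class = c("glycerolipid", "fatty_acyl", "sterol"),
                    adduct = "M+H", theoretical_mz = 1, ppm_error = 0)
  cc <- class_composition(tab, ann, reference_group = "WT")
  wt <- cc[cc$group == "WT", ]
  expect_equal(wt$percent[wt$lipid_class == "glycerolipid"], 75)
  expect_equal(wt$percent[wt$lipid_class == "fatty_acyl"], 25)
  # class absent in reference but present in the mutant: capped sentinel
  mut <- cc[cc$group == "mut", ]
  expect_true(mut$capped[mut$lipid_class == "sterol"])
  expect_equal(mut$fold_change[mut$lipid_class == "sterol"], 1000)

  # single-class table reports 100%
  ann1 <- ann[1, ]
  cc1 <- class_composition(tiny_feature_table(rbind(c(10, 10)),
                                              roles = c("study", "study"),
                                              groups = c("WT", "mut")),
                           ann1, reference_group = "WT")
  expect_equal(cc1$percent[cc1$group == "WT" & cc1$lipid_class == "glycerolipid"],
               100)
  # unannotated features fall into "unidentified"
  cc2 <- class_composition(tab, ann[1:2, ], reference_group = "WT")
  expect_true("unidentified" %in% cc2$lipid_class)
})

test_that("PCA separates planted clusters and satisfies Q2 <= R2", {
  set.seed(5)
  X <- rbind(matrix(rnorm(5 * 30, 10), 5), matrix(rnorm(5 * 30, 16), 5))
  tab <- tiny_feature_table(t(X), roles = rep("study", 10),
                            groups = rep(c("A", "B"), each = 5))
  m <- fit_pca(tab, n_components = 2)
  expect_gt(m$r2_cum, 0.5)
  expect_lte(m$q2_cum, m$r2_cum + 1e-9)
  # first component splits the clusters
  pc1 <- m$scores[, 1]
  expect_true(all(pc1[1:5] < 0) != all(pc1[1:5] > 0) ||
              max(pc1[1:5]) < min(pc1[6:10]) || min(pc1[1:5]) > max(pc1[6:10]))
  # full-rank reconstruction explains everything
  mfull <- fit_pca(tab, n_components = 9, scaling = "none")
  expect_gt(mfull$r2_cum, 1 - 1e-9)
})

test_that("PLS-DA finds structure when planted and none when absent", {
  ft <- make_feature_table(groups = c("WT", "mutA", "mutB"), n_replicates = 4,
                           group_effects = list(mutA = 10, mutB = 0.1),
                           noise_sdlog = 0.2, seed = 51)
  tt <- qc_cv_filter(remove_blank_features(ft$table))
  strong <- fit_plsda(tt)
  expect_gt(strong$q2_cum, 0.5)
  expect_lt(strong$cv_anova_p, 0.05)
  expect_false(strong$no_model)
  expect_lte(strong$q2_cum, strong$r2_cum + 1e-9)

  nullft <- make_feature_table(seed = 52)
  weak <- fit_plsda(qc_cv_filter(remove_blank_features(nullft$table)))
  expect_lte(weak$q2_cum, 0)
  expect_equal(weak$cv_anova_p, 1)
  expect_true(weak$no_model)
})

test_that("label permutation destroys the PLS-DA model", {
  ft <- make_feature_table(groups = c("WT", "mutA", "mutB"), n_replicates = 4,
                           group_effects = list(mutA = 10, mutB = 0.1),
                           noise_sdlog = 0.2, seed = 53)
  tt <- qc_cv_filter(remove_blank_features(ft$table))
  study <- tt$samples$role == "study"
  set.seed(99)
  q2_perm <- replicate(30, {
    perm <- tt
    perm$samples$group[study] <- sample(perm$samples$group[study])
    fit_plsda(perm)$q2_cum
  })
  expect_lte(median(q2_perm), 0)
})

test_that("a single perfectly separating feature yields Q2 near 1", {
  X <- rbind(c(rep(1, 5), rep(100, 5)))
  tab <- tiny_feature_table(X, roles = rep("study", 10),
                            groups = rep(c("A", "B"), each = 5))
  m <- fit_plsda(tab, n_components = 1)
  expect_gt(m$q2_cum, 0.9)
})

test_that("filters only remove features and log their provenance", {
  ft <- make_feature_table(seed = 61)
  t1 <- remove_blank_features(ft$table)
  t2 <- qc_cv_filter(t1)
  expect_true(all(t2$features$feature_id %in% t1$features$feature_id))
  expect_true(all(t1$features$feature_id %in% ft$table$features$feature_id))
  expect_length(provenance(t2), 3)  # blank + zero-mean + CV messages
  removed <- attr(t2, "removed")
  expect_equal(nrow(ft$table$features),
               nrow(t2$features) + length(removed))
})

test_that("univariate screening returns BH-adjusted Welch tests", {
  ft <- make_feature_table(groups = c("WT", "mutA"), n_replicates = 4,
                           group_effects = list(mutA = 8), seed = 71)
  res <- univariate_tests(ft$table)
  expect_true(all(c("feature_id", "group", "log2_fold_change", "p", "p_adj")
                  %in% names(res)))
  expect_true(all(res$p_adj >= res$p - 1e-12, na.rm = TRUE))
  expect_equal(res$p_adj, stats::p.adjust(res$p, "BH"))
  # planted 8x features trend positive in log2 fold change
  aff <- ft$planted$affected$mutA
  expect_gt(mean(res$log2_fold_change[aff]), 2)
})
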