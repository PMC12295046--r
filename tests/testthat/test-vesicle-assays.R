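test_that("spectrum AUC integrates the trapezoid exactly", {
  wl <- seq(200, 320, 2)
  expect_equal(spectrum_auc(uv_spectrum(wl, rep(0.5, length(wl)))), 60)
  expect_equal(spectrum_auc(uv_spectrum(wl, rep(0, length(wl)))), 0)
  ramp <- seq(0, 1, length.out = length(wl))
  expect_equal(spectrum_auc(uv_spectrum(wl, ramp)), 60)
})

test_that("AUC is linear in absorbance and stable under refinement", {
  wl <- seq(200, 320, 2)
  a <- exp(-(wl - 260)^2 / 500)
  s1 <- uv_spectrum(wl, a)
  expect_equal(spectrum_auc(uv_spectrum(wl, 3 * a)), 3 * spectrum_auc(s1))
  # piecewise-linear refinement of the same trace changes nothing
  wl_fine <- seq(200, 320, 0.5)
  a_fine <- approx(wl, a, xout = wl_fine)$y
  expect_equal(spectrum_auc(uv_spectrum(wl_fine, a_fine)), spectrum_auc(s1),
               tolerance = 1e-9)
})

test_that("spectrum validation enforces the recording conventions", {
  expect_error(uv_spectrum(c(200, 200, 204), c(1, 1, 1)))   # not increasing
  expect_error(uv_spectrum(c(100, 200), c(1, 1)))           # out of range
  expect_error(uv_spectrum(c(200, 202), c(1, 1, 1)))        # length mismatch
})

test_that("Warburg-Christian estimate uses 1.55/0.76 with a zero floor", {
  expect_equal(warburg_christian_protein(0, 0), 0)
  expect_equal(warburg_christian_protein(1.0, 0.5), 1.17)
  expect_equal(warburg_christian_protein(0.1, 1.0), 0)  # nucleic-acid-dominated
  # vectorized and overridable
  expect_equal(warburg_christian_protein(c(1, 2), c(0, 0)), c(1.55, 3.10))
  expect_equal(warburg_christian_protein(1, 1, coefficients = c(2, 1)), 1)
})

test_that("normalization divides by mass x OD600", {
  expect_equal(normalize_assay(60, mass = 1, od600 = 2), 30)
  expect_equal(normalize_assay(10, 2, 1), normalize_assay(10, 1, 2))
  expect_equal(normalize_assay(10, 1, 2), 2 * normalize_assay(10, 1, 4))
  expect_equal(normalize_assay(0, 1, 1), 0)
  expect_error(normalize_assay(1, 0, 1))
})

test_that("group comparison: ANOVA F, pooled contrasts, Sidak adjustment", {
  # identical groups: F ~ 0, nothing significant
  same <- list(WT = c(1, 1.01, 0.99), A = c(1, 1.01, 0.99), B = c(1, 1.01, 0.99))
  cmp <- compare_groups(same, "WT")
  expect_lt(cmp$anova_F, 1e-10)
  expect_false(any(cmp$contrasts$significant))

  # a single contrast: Sidak is the identity
  two <- list(WT = c(1, 2, 3), A = c(2, 3, 4))
  cmp2 <- compare_groups(two, "WT")
  expect_equal(cmp2$contrasts$sidak_adjusted_p, cmp2$contrasts$p_raw)

  # adjusted p is monotone in raw p and in the contrast count m
  p <- seq(0.01, 0.9, length.out = 20)
  for (m in 1:4) {
    adj <- 1 - (1 - p)^m
    expect_true(all(diff(adj) > 0))
    expect_true(all(adj >= p - 1e-12))
    if (m > 1) expect_true(all(adj >= 1 - (1 - p)^(m - 1)))
  }

  # contract: groups need n >= 2
  expect_error(compare_groups(list(WT = c(1, 2), A = 1), "WT"), "fewer than 2")
  expect_error(compare_groups(list(WT = c(1, 2)), "WT"))
})

test_that("contrast arithmetic agrees with a direct pooled-t computation", {
  set.seed(3)
  vals <- list(WT = rnorm(3, 10), A = rnorm(3, 13), B = rnorm(4, 10.5))
  cmp <- compare_groups(vals, "WT")
  fit <- stats::aov(value ~ group,
                    data = data.frame(value = unlist(vals),
                                      group = rep(names(vals), lengths(vals))))
  mse <- stats::anova(fit)["Residuals", "Mean Sq"]
  dfe <- stats::anova(fit)["Residuals", "Df"]
  tA <- (mean(vals$A) - mean(vals$WT)) / sqrt(mse * (1 / 3 + 1 / 3))
  pA <- 2 * stats::pt(abs(tA), dfe, lower.tail = FALSE)
  row <- cmp$contrasts[cmp$contrasts$group == "A", ]
  expect_equal(row$t, tA)
  expect_equal(row$sidak_adjusted_p, 1 - (1 - pA)^2)
})

test_that("planted fold changes are recovered exactly at zero noise", {
  st <- make_assay_study(noise_cv = 0, seed = 5)
  sm <- suppressWarnings(summarize_assay_study(st))  # zero noise: perfect fit
  means <- tapply(sm$samples$auc_norm, sm$samples$group, mean)
  expect_equal(as.numeric(means[st$groups$name] / means[["WT"]]),
               st$groups$vesicle_fold, tolerance = 1e-9)
  pmeans <- tapply(sm$samples$protein_norm, sm$samples$group, mean)
  expect_equal(as.numeric(pmeans[st$groups$name] / pmeans[["WT"]]),
               st$groups$protein_fold, tolerance = 1e-6)
})

test_that("a realistic noisy study flags every overproducer", {
  st <- make_assay_study(noise_cv = 0.15, seed = 8)
  sm <- summarize_assay_study(st)
  expect_true(all(sm$vesicles$contrasts$significant))
  expect_lt(sm$vesicles$anova_p, 1e-3)
})

test_that("spectra CSV round-trips through the long format", {
  st <- make_assay_study(seed = 2)
  p <- tempfile(fileext = ".csv")
  write_spectra(st$spectra, p)
  back <- read_spectra(p)
  expect_setequal(names(back), names(st$spectra))
  sid <- names(st$spectra)[1]
  expect_equal(back[[sid]]$absorbance, st$spectra[[sid]]$absorbance)
})
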