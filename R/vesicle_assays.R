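# Vesicle quantification from UV absorbance spectra.
#
# Relative vesicle abundance is the area under the 200-320 nm absorbance
# curve; protein content is the classical Warburg-Christian estimate from
# A280/A260; both are normalized to sample mass x OD600 before group
# comparison by one-way ANOVA with Sidak-corrected contrasts against the
# reference (wild-type) group.

#' Construct a UV absorbance spectrum
#'
#' @param wavelengths strictly increasing wavelengths in nm within
#'   \[190, 340\] (the recording convention is 200-320 nm at 2 nm steps)
#' @param absorbance absorbance values (AU), same length
#' @return a `uv_spectrum`
#' @export
uv_spectrum <- function(wavelengths, absorbance) {
  stopifnot(length(wavelengths) == length(absorbance),
            length(wavelengths) >= 2,
            all(diff(wavelengths) > 0),
            min(wavelengths) >= 190, max(wavelengths) <= 340)
  structure(list(wavelengths = as.numeric(wavelengths),
                 absorbance = as.numeric(absorbance)),
            class = "uv_spectrum")
}

#' Area under a UV spectrum
#'
#' Trapezoidal integral over the recorded range, no smoothing.
#' @param spectrum a [uv_spectrum()]
#' @return area in AU nm
#' @export
spectrum_auc <- function(spectrum) {
  stopifnot(inherits(spectrum, "uv_spectrum"))
  pracma::trapz(spectrum$wavelengths, spectrum$absorbance)
}

#' Warburg-Christian protein estimate
#'
#' Protein concentration from absorbances at 280 nm (protein) and 260 nm
#' (nucleic-acid correction): `1.55 A280 - 0.76 A260`, floored at zero.
#' The coefficients are from the classical spectrophotometric method and can
#' be overridden.
#'
#' @param a280,a260 absorbances (AU), nonnegative; vectorized
#' @param coefficients numeric `c(protein, nucleic)` pair
#' @return protein concentration in mg/mL
#' @export
warburg_christian_protein <- function(a280, a260,
                                      coefficients = c(1.55, 0.76)) {
  stopifnot(all(a280 >= 0), all(a260 >= 0), length(coefficients) == 2)
  pmax(coefficients[1] * a280 - coefficients[2] * a260, 0)
}

#' Normalize an assay value to sample mass and OD600
#'
#' Divides by the product mass x OD600, the single joint divisor correcting
#' for culture amount and growth differences between sample groups.
#' @param value assay value(s) (e.g. spectrum AUC or protein concentration)
#' @param mass sample mass in g (> 0)
#' @param od600 culture OD600 (> 0)
#' @return normalized value(s)
#' @export
normalize_assay <- function(value, mass, od600) {
  stopifnot(all(mass > 0), all(od600 > 0))
  value / (mass * od600)
}

#' One-way ANOVA with Sidak-corrected contrasts against a reference group
#'
#' Fits a one-way ANOVA across all groups, then tests each non-reference
#' group against the reference using the pooled error term; the m reference
#' contrasts are Sidak-adjusted, `p_adj = 1 - (1 - p)^m`.
#'
#' @param values named list (group -> numeric vector) or data.frame with
#'   columns `group`, `value`; every group needs n >= 2
#' @param reference name of the reference group
#' @param alpha significance level for the adjusted contrasts (default 0.05)
#' @return list with `anova_F`, `anova_p`, and `contrasts` (data.frame:
#'   group, mean_diff, t, p_raw, sidak_adjusted_p, significant)
#' @export
compare_groups <- function(values, reference, alpha = 0.05) {
  if (is.data.frame(values)) {
    values <- split(values$value, values$group)
  }
  stopifnot(reference %in% names(values), length(values) >= 2)
  n_per <- vapply(values, length, integer(1))
  if (any(n_per < 2)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(values)[n_per < 2], collapse = ", "))
  }
  df <- data.frame(
    value = unlist(values, use.names = FALSE),
    group = factor(rep(names(values), n_per), levels = names(values)))
  fit <- stats::aov(value ~ group, data = df)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  df_err <- an["Residuals", "Df"]
  means <- tapply(df$value, df$group, mean)
  others <- setdiff(names(values), reference)
  m <- length(others)
  contrasts <- do.call(rbind, lapply(others, function(g) {
    diff <- means[[g]] - means[[reference]]
    se <- sqrt(mse * (1 / n_per[[g]] + 1 / n_per[[reference]]))
    tval <- diff / se
    p <- 2 * stats::pt(abs(tval), df_err, lower.tail = FALSE)
    data.frame(group = g, mean_diff = diff, t = tval, p_raw = p,
               sidak_adjusted_p = 1 - (1 - p)^m,
               stringsAsFactors = FALSE)
  }))
  contrasts$significant <- contrasts$sidak_adjusted_p < alpha
  list(anova_F = an["group", "F value"], anova_p = an["group", "Pr(>F)"],
       contrasts = contrasts, alpha = alpha, reference = reference)
}

#' Read spectra from a long-format CSV
#'
#' @param path CSV with columns `sample_id`, `wavelength_nm`, `absorbance`
#' @return named list of [uv_spectrum()] objects
#' @export
read_spectra <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "wavelength_nm", "absorbance") %in% names(d)))
  lapply(split(d, d$sample_id), function(s) {
    s <- s[order(s$wavelength_nm), ]
    uv_spectrum(s$wavelength_nm, s$absorbance)
  })
}

#' Write spectra to a long-format CSV
#' @param spectra named list of [uv_spectrum()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_spectra <- function(spectra, path) {
  d <- do.call(rbind, lapply(names(spectra), function(sid) {
    s <- spectra[[sid]]
    data.frame(sample_id = sid, wavelength_nm = s$wavelengths,
               absorbance = s$absorbance, stringsAsFactors = FALSE)
  }))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

# Full study summarization used by tests and the acceptance workflow: per
# sample normalized AUC + protein, then group comparison on normalized AUC.
summarize_assay_study <- function(study, alpha = 0.05) {
  meta <- study$meta
  auc <- vapply(meta$sample_id, function(sid) spectrum_auc(study$spectra[[sid]]),
                numeric(1))
  a280 <- vapply(meta$sample_id, function(sid) {
    s <- study$spectra[[sid]]
    s$absorbance[match(280, s$wavelengths)]
  }, numeric(1))
  a260 <- vapply(meta$sample_id, function(sid) {
    s <- study$spectra[[sid]]
    s$absorbance[match(260, s$wavelengths)]
  }, numeric(1))
  meta$auc_norm <- normalize_assay(auc, meta$mass_g, meta$od600)
  meta$protein_norm <- normalize_assay(warburg_christian_protein(a280, a260),
                                       meta$mass_g, meta$od600)
  ref <- study$groups$name[1]
  list(samples = meta,
       vesicles = compare_groups(
         data.frame(group = meta$group, value = meta$auc_norm), ref, alpha),
       protein = compare_groups(
         data.frame(group = meta$group, value = meta$protein_norm), ref, alpha))
}
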