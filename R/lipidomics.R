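# Post-acquisition lipidomics pipeline.
#
# Starts from an exported LC-MS feature table (feature x sample intensity
# matrix with study / pooled-QC / solvent-blank roles) and provides the
# standard post-processing chain: blank-feature removal, QC coefficient-of-
# variation filtering (CV > 20% convention), per-sample normalization,
# adduct-based annotation against a lipid reference table (10 ppm, positive
# mode M+H / M+NH4 / M+Cl), lipid-class composition and fold changes, and
# multivariate modelling: PCA and PLS-DA with cross-validated Q2 and the
# CV-ANOVA significance test. A PLS-DA fit with Q2 <= 0 is a "no model"
# verdict and its CV-ANOVA p-value is clamped to 1.

#' Construct an LC-MS feature table
#'
#' @param features data.frame with columns `feature_id`, `mz`, `rt`
#' @param samples data.frame with columns `sample_id`, `role` (one of
#'   `"study"`, `"qc"`, `"blank"`), `group` (NA for qc/blank), plus any
#'   per-sample normalization factor columns (e.g. `quantity`,
#'   `sample_volume`)
#' @param intensities nonnegative numeric matrix, features x samples
#' @return a `feature_table`
#' @export
feature_table <- function(features, samples, intensities) {
  stopifnot(nrow(intensities) == nrow(features),
            ncol(intensities) == nrow(samples),
            all(samples$role %in% c("study", "qc", "blank")),
            all(intensities >= 0))
  rownames(intensities) <- features$feature_id
  colnames(intensities) <- samples$sample_id
  structure(list(features = features, samples = samples,
                 intensities = intensities),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$features), " features x ", nrow(x$samples),
      " samples (", sum(x$samples$role == "study"), " study, ",
      sum(x$samples$role == "qc"), " qc, ", sum(x$samples$role == "blank"),
      " blank)\n", sep = "")
  prov <- attr(x, "provenance")
  for (p in prov) cat("  - ", p, "\n", sep = "")
  invisible(x)
}

log_provenance <- function(table, msg) {
  attr(table, "provenance") <- c(attr(table, "provenance"), msg)
  table
}

#' Filtering provenance of a feature table
#' @param table a [feature_table()]
#' @return character vector of filter log messages
#' @export
provenance <- function(table) attr(table, "provenance") %||% character(0)

drop_features <- function(table, drop_ids, reason) {
  keep <- !(table$features$feature_id %in% drop_ids)
  out <- feature_table(table$features[keep, , drop = FALSE], table$samples,
                       table$intensities[keep, , drop = FALSE])
  attr(out, "provenance") <- attr(table, "provenance")
  attr(out, "removed") <- c(attr(table, "removed"),
                            stats::setNames(rep(reason, length(drop_ids)), drop_ids))
  log_provenance(out, paste0(reason, ": removed ", length(drop_ids),
                             " feature(s), ", sum(keep), " remain"))
}

#' Remove features attributable to the solvent blank
#'
#' Drops every feature whose mean blank intensity exceeds
#' `blank_fraction x mean study intensity` (strictly greater; a feature
#' sitting exactly at the threshold is retained).
#'
#' @param table a [feature_table()] with >= 1 blank sample
#' @param blank_fraction tolerated blank-to-study signal ratio (default 0.1)
#' @return the filtered [feature_table()]; removals are logged in the
#'   table's provenance
#' @export
remove_blank_features <- function(table, blank_fraction = 0.1) {
  stopifnot(inherits(table, "feature_table"),
            sum(table$samples$role == "blank") >= 1)
  bl <- table$intensities[, table$samples$role == "blank", drop = FALSE]
  st <- table$intensities[, table$samples$role == "study", drop = FALSE]
  bad <- rowMeans(bl) > blank_fraction * rowMeans(st)
  drop_features(table, table$features$feature_id[bad], "blank filter")
}

#' Filter features by QC coefficient of variation
#'
#' Per feature, CV% = 100 sd/mean over the pooled-QC injections (sample sd,
#' n-1 denominator). Features with CV strictly above `max_cv_percent` are
#' removed; a CV exactly at the threshold is retained. Features with zero
#' mean QC intensity are removed with a distinct logged reason.
#'
#' @param table a [feature_table()] with >= 2 qc samples
#' @param max_cv_percent CV threshold in percent (default 20, the usual
#'   QC-repeatability convention)
#' @return the filtered [feature_table()]
#' @export
qc_cv_filter <- function(table, max_cv_percent = 20) {
  stopifnot(inherits(table, "feature_table"),
            sum(table$samples$role == "qc") >= 2)
  qc <- table$intensities[, table$samples$role == "qc", drop = FALSE]
  mu <- rowMeans(qc)
  sdv <- apply(qc, 1, stats::sd)
  zero <- mu == 0
  cv <- ifelse(zero, Inf, 100 * sdv / mu)
  out <- drop_features(table, table$features$feature_id[zero], "qc zero-mean filter")
  drop_features(out, out$features$feature_id[cv[!zero] > max_cv_percent],
                sprintf("qc CV > %g%% filter", max_cv_percent))
}

#' Normalize study intensities by a per-sample factor
#'
#' Each study column is divided by its value of the named factor (a column
#' of the sample table, e.g. vesicle `quantity` or `sample_volume`); qc and
#' blank columns are untouched.
#'
#' @param table a [feature_table()]
#' @param factor_name name of the sample-table column holding the factor
#' @return the normalized [feature_table()]
#' @export
normalize_table <- function(table, factor_name) {
  stopifnot(inherits(table, "feature_table"))
  if (!factor_name %in% names(table$samples)) {
    stop("unknown normalization factor '", factor_name, "'")
  }
  study <- which(table$samples$role == "study")
  f <- table$samples[[factor_name]][study]
  bad <- is.na(f) | f <= 0
  if (any(bad)) {
    stop("missing or nonpositive factor '", factor_name, "' for sample(s): ",
         paste(table$samples$sample_id[study][bad], collapse = ", "))
  }
  X <- table$intensities
  X[, study] <- sweep(X[, study, drop = FALSE], 2, f, `/`)
  out <- feature_table(table$features, table$samples, X)
  attr(out, "provenance") <- attr(table, "provenance")
  log_provenance(out, paste0("normalized study samples by '", factor_name, "'"))
}

#' Positive-mode adduct mass shifts
#'
#' Monoisotopic shifts added to the neutral mass M: +1.007276 (M+H),
#' +18.033823 (M+NH4), +34.969402 (M+Cl, 35Cl).
#' @return named numeric vector
#' @export
adduct_mass_shifts <- function() {
  c(`M+H` = 1.007276, `M+NH4` = 18.033823, `M+Cl` = 34.969402)
}

#' Annotate features against a lipid reference table
#'
#' For each feature and adduct, the theoretical m/z is the reference
#' monoisotopic mass plus the adduct shift; all matches within the ppm
#' tolerance are returned (no uniqueness is forced).
#'
#' @param table a [feature_table()]
#' @param reference data.frame with columns `name`, `class`,
#'   `monoisotopic_mass`
#' @param ppm_tol tolerance in parts per million (default 10)
#' @param adducts subset of `names(adduct_mass_shifts())`
#' @return data.frame: feature_id, candidate_name, lipid_class, adduct,
#'   theoretical_mz, ppm_error
#' @export
annotate_adducts <- function(table, reference, ppm_tol = 10,
                             adducts = names(adduct_mass_shifts())) {
  stopifnot(inherits(table, "feature_table"),
            all(c("name", "class", "monoisotopic_mass") %in% names(reference)),
            all(adducts %in% names(adduct_mass_shifts())))
  shifts <- adduct_mass_shifts()[adducts]
  if (!nrow(reference)) {
    return(data.frame(feature_id = character(0), candidate_name = character(0),
                      lipid_class = character(0), adduct = character(0),
                      theoretical_mz = numeric(0), ppm_error = numeric(0)))
  }
  out <- list()
  for (a in names(shifts)) {
    theo <- reference$monoisotopic_mass + shifts[[a]]
    for (i in seq_len(nrow(table$features))) {
      ppm <- (table$features$mz[i] - theo) / theo * 1e6
      hit <- which(abs(ppm) <= ppm_tol)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          feature_id = table$features$feature_id[i],
          candidate_name = reference$name[hit],
          lipid_class = reference$class[hit],
          adduct = a, theoretical_mz = theo[hit], ppm_error = ppm[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(feature_id = character(0), candidate_name = character(0),
                      lipid_class = character(0), adduct = character(0),
                      theoretical_mz = numeric(0), ppm_error = numeric(0)))
  }
  do.call(rbind, out)
}

#' Lipid-class composition per group, with fold changes vs a reference
#'
#' Each feature contributes its summed intensity to one lipid class (first
#' annotation match; ambiguous features are logged in the `ambiguous`
#' attribute). Unannotated features are reported as `"unidentified"`.
#' Fold change of a class = group share / reference share; classes absent
#' from the reference but present in a group get the capped sentinel
#' `fold_cap` with `capped = TRUE`.
#'
#' @param table a [feature_table()]
#' @param annotations output of [annotate_adducts()]
#' @param reference_group group used as the fold-change denominator;
#'   defaults to the first study group
#' @param fold_cap sentinel replacing infinite fold changes (default 1000)
#' @return data.frame: group, lipid_class, percent, fold_change, capped,
#'   signed_change (percentage-point difference vs reference, the quantity
#'   heat maps display)
#' @export
class_composition <- function(table, annotations, reference_group = NULL,
                              fold_cap = 1000) {
  stopifnot(inherits(table, "feature_table"))
  study <- table$samples$role == "study"
  groups <- unique(table$samples$group[study])
  if (is.null(reference_group)) reference_group <- groups[1]
  stopifnot(reference_group %in% groups)

  cls <- rep("unidentified", nrow(table$features))
  names(cls) <- table$features$feature_id
  amb <- character(0)
  if (nrow(annotations)) {
    for (fid in unique(annotations$feature_id)) {
      hits <- unique(annotations$lipid_class[annotations$feature_id == fid])
      if (length(hits) > 1) amb <- c(amb, fid)
      if (fid %in% names(cls)) cls[fid] <- hits[1]
    }
  }
  shares <- lapply(groups, function(g) {
    cols <- study & table$samples$group == g
    tot <- rowSums(table$intensities[, cols, drop = FALSE])
    s <- tapply(tot, cls, sum)
    100 * s / sum(s)
  })
  names(shares) <- groups
  all_cls <- sort(unique(unlist(lapply(shares, names))))
  ref <- shares[[reference_group]]
  out <- do.call(rbind, lapply(groups, function(g) {
    p <- shares[[g]][all_cls]; p[is.na(p)] <- 0
    r <- ref[all_cls]; r[is.na(r)] <- 0
    fc <- ifelse(r > 0, p / r, ifelse(p > 0, Inf, NA_real_))
    capped <- is.infinite(fc)
    fc[capped] <- fold_cap
    data.frame(group = g, lipid_class = all_cls, percent = unname(p),
               fold_change = unname(fc), capped = unname(capped),
               signed_change = unname(p - r), stringsAsFactors = FALSE)
  }))
  attr(out, "ambiguous") <- amb
  out
}

## ---- multivariate modelling ------------------------------------------------

scale_matrix <- function(X, scaling, center = NULL, scale_vec = NULL) {
  if (is.null(center)) center <- colMeans(X)
  X <- sweep(X, 2, center, `-`)
  if (is.null(scale_vec)) {
    scale_vec <- switch(scaling,
                        uv = apply(X, 2, stats::sd),
                        pareto = sqrt(apply(X, 2, stats::sd)),
                        none = rep(1, ncol(X)))
    scale_vec[scale_vec < 1e-12] <- 1
  }
  list(X = sweep(X, 2, scale_vec, `/`), center = center, scale = scale_vec)
}

model_matrix_of <- function(table, roles) {
  cols <- table$samples$role %in% roles
  t(table$intensities[, cols, drop = FALSE])
}

#' Principal component analysis of a feature table
#'
#' Centered (and scaled) PCA of study and pooled-QC samples together, so QC
#' clustering — the stability readout of the analytical platform — is
#' inspectable on the same score plot. `r2_cum` is the cumulative explained
#' variance of the retained components; `q2_cum` is a cross-validated
#' reconstruction statistic: each held-out sample is projected onto the
#' loadings of a model fitted without it and `Q2 = 1 - PRESS/TSS`
#' (leave-one-out up to 20 samples, 7-fold beyond).
#'
#' @param table a [feature_table()] with >= 3 study+qc samples
#' @param n_components number of components (default 2)
#' @param scaling `"uv"` (unit variance, default), `"pareto"`, or `"none"`
#' @return a `multivariate_model`: kind `"pca"`, `scores`, `loadings`,
#'   `r2_cum`, `q2_cum`, `sample_role`
#' @export
fit_pca <- function(table, n_components = 2, scaling = c("uv", "pareto", "none")) {
  scaling <- match.arg(scaling)
  X <- model_matrix_of(table, c("study", "qc"))
  n <- nrow(X)
  stopifnot(n >= 3)
  n_components <- min(n_components, n - 1, ncol(X))
  sc <- scale_matrix(X, scaling)
  pc <- stats::prcomp(sc$X, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  r2 <- sum(ev[seq_len(n_components)]) / sum(ev)

  folds <- if (n <= 20) seq_len(n) else ((seq_len(n) - 1L) %% 7L) + 1L
  press <- 0; tss <- 0
  for (f in unique(folds)) {
    hold <- which(folds == f)
    sc_tr <- scale_matrix(X[-hold, , drop = FALSE], scaling)
    pc_tr <- stats::prcomp(sc_tr$X, center = FALSE, scale. = FALSE)
    k <- min(n_components, ncol(pc_tr$rotation))
    V <- pc_tr$rotation[, seq_len(k), drop = FALSE]
    X0 <- scale_matrix(X[hold, , drop = FALSE], scaling,
                       center = sc_tr$center, scale_vec = sc_tr$scale)$X
    Xhat <- X0 %*% V %*% t(V)
    press <- press + sum((X0 - Xhat)^2)
    tss <- tss + sum(X0^2)
  }
  structure(list(kind = "pca", n_components = n_components,
                 scores = pc$x[, seq_len(n_components), drop = FALSE],
                 loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
                 r2_cum = r2, q2_cum = 1 - press / tss,
                 sample_role = table$samples$role[table$samples$role %in% c("study", "qc")],
                 cv_anova_p = NULL),
            class = "multivariate_model")
}

# NIPALS PLS2. X (n x p), Y (n x q), both already centered/scaled.
# Returns W, P, Q and the regression coefficient matrix B.
nipals_pls <- function(X, Y, ncomp, tol = 1e-10, max_iter = 500) {
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); Q <- matrix(0, q, ncomp)
  Tm <- matrix(0, n, ncomp)
  for (a in seq_len(ncomp)) {
    u <- Y[, which.max(apply(Y, 2, stats::var))]
    if (all(abs(u) < 1e-12)) break
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(X, u); w <- w / sqrt(sum(w^2))
      tt <- X %*% w
      qv <- crossprod(Y, tt) / sum(tt^2)
      u <- Y %*% qv / sum(qv^2)
      if (sum((tt - t_old)^2) < tol * sum(tt^2)) break
      t_old <- tt
    }
    pv <- crossprod(X, tt) / sum(tt^2)
    X <- X - tt %*% t(pv)
    Y <- Y - tt %*% t(qv)
    W[, a] <- w; P[, a] <- pv; Q[, a] <- qv; Tm[, a] <- tt
  }
  B <- W %*% solve(t(P) %*% W, t(Q))
  list(W = W, P = P, Q = Q, scores = Tm, B = B)
}

one_hot <- function(labels) {
  f <- factor(labels)
  Y <- stats::model.matrix(~ f - 1)
  colnames(Y) <- levels(f)
  Y
}

#' Partial least squares discriminant analysis with Q2 and CV-ANOVA
#'
#' PLS2 regression (NIPALS) of unit-variance-scaled intensities on one-hot
#' group membership. `r2_cum` is the variance of Y explained by the fit;
#' `q2_cum = 1 - PRESS/TSS` from k-fold cross-validation (venetian-blind
#' assignment in sample order); the CV-ANOVA p-value is an F-test of the
#' cross-validated residuals against the total response variation,
#' `F = ((TSS - PRESS)/A) / (PRESS/(N-1-A))` on (A, N-1-A) degrees of
#' freedom for A components and N samples. When `q2_cum <= 0` the fit is a
#' "no model" verdict and the p-value is clamped to 1.
#'
#' @param table a [feature_table()]; only study samples enter
#' @param n_components number of latent components (default 2)
#' @param cv_folds cross-validation folds (default 7; reduced to the number
#'   of samples if larger)
#' @param scaling predictor scaling as in [fit_pca()]
#' @return a `multivariate_model`: kind `"plsda"`, `scores`, `r2_cum`,
#'   `q2_cum`, `cv_anova_p`, `no_model` flag
#' @export
fit_plsda <- function(table, n_components = 2, cv_folds = 7,
                      scaling = c("uv", "pareto", "none")) {
  scaling <- match.arg(scaling)
  study <- table$samples$role == "study"
  X <- model_matrix_of(table, "study")
  labels <- table$samples$group[study]
  tab <- table(labels)
  stopifnot(length(tab) >= 2, all(tab >= 2))
  n <- nrow(X)
  A <- min(n_components, n - 2, ncol(X))

  sx <- scale_matrix(X, scaling)
  Y <- one_hot(labels)
  cy <- colMeans(Y)
  Yc <- sweep(Y, 2, cy, `-`)
  fit <- nipals_pls(sx$X, Yc, A)
  Yhat <- sx$X %*% fit$B
  rss <- sum((Yc - Yhat)^2)
  tss <- sum(Yc^2)
  r2 <- 1 - rss / tss

  k <- min(cv_folds, n)
  folds <- ((seq_len(n) - 1L) %% k) + 1L
  press <- 0
  for (f in unique(folds)) {
    hold <- which(folds == f)
    sx_tr <- scale_matrix(X[-hold, , drop = FALSE], scaling)
    Ytr <- Y[-hold, , drop = FALSE]
    cy_tr <- colMeans(Ytr)
    fit_tr <- nipals_pls(sx_tr$X, sweep(Ytr, 2, cy_tr, `-`),
                         min(A, nrow(sx_tr$X) - 1))
    X0 <- scale_matrix(X[hold, , drop = FALSE], scaling,
                       center = sx_tr$center, scale_vec = sx_tr$scale)$X
    Y0hat <- sweep(X0 %*% fit_tr$B, 2, cy_tr, `+`)
    press <- press + sum((Y[hold, , drop = FALSE] - Y0hat)^2)
  }
  tss_cv <- sum(sweep(Y, 2, colMeans(Y), `-`)^2)
  q2 <- 1 - press / tss_cv

  no_model <- q2 <= 0
  # CV-ANOVA: F-test of cross-validated residual variation; by construction
  # Q2 <= 0 means the CV residuals exceed the total variation, so the test
  # cannot reject and p is 1 (degrees of freedom: A model, N-1-A residual).
  if (no_model || n - 1 - A <= 0) {
    p_cv <- 1
  } else {
    Fv <- ((tss_cv - press) / A) / (press / (n - 1 - A))
    p_cv <- stats::pf(Fv, A, n - 1 - A, lower.tail = FALSE)
  }
  structure(list(kind = "plsda", n_components = A,
                 scores = fit$scores, r2_cum = r2, q2_cum = q2,
                 cv_anova_p = p_cv, no_model = no_model,
                 groups = levels(factor(labels))),
            class = "multivariate_model")
}

#' @export
print.multivariate_model <- function(x, ...) {
  cat("<multivariate_model> ", x$kind, ", ", x$n_components, " component(s)\n",
      "  R2(cum) = ", round(x$r2_cum, 3), "  Q2(cum) = ", round(x$q2_cum, 3),
      sep = "")
  if (!is.null(x$cv_anova_p)) {
    cat("  CV-ANOVA p = ", format.pval(x$cv_anova_p), sep = "")
    if (isTRUE(x$no_model)) cat("  [no model]")
  }
  cat("\n")
  invisible(x)
}

#' Per-feature univariate tests vs a reference group
#'
#' Welch t-tests of each non-reference group against the reference for every
#' feature, Benjamini-Hochberg adjusted across all tests. Reported as a
#' screening table; group-level claims rest on the multivariate models.
#'
#' @param table a [feature_table()]
#' @param reference_group reference (wild-type) group; defaults to the first
#' @return data.frame: feature_id, group, log2_fold_change, p, p_adj
#' @export
univariate_tests <- function(table, reference_group = NULL) {
  study <- table$samples$role == "study"
  groups <- unique(table$samples$group[study])
  if (is.null(reference_group)) reference_group <- groups[1]
  ref_cols <- study & table$samples$group == reference_group
  out <- list()
  for (g in setdiff(groups, reference_group)) {
    g_cols <- study & table$samples$group == g
    for (i in seq_len(nrow(table$features))) {
      x <- table$intensities[i, g_cols]
      y <- table$intensities[i, ref_cols]
      p <- tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        feature_id = table$features$feature_id[i], group = g,
        log2_fold_change = log2((mean(x) + 1e-12) / (mean(y) + 1e-12)),
        p = p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res
}
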