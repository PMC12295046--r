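# Seeded generators for every input the pipeline consumes, each with planted
# ground truth so that the corresponding analysis stage can be verified
# without any external data. All generators are deterministic under a fixed
# seed and leave the caller's RNG state untouched.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a toy vesiculation network with planted ground truth
#'
#' The network mimics, at miniature scale, the structure the strain-design
#' pipeline assumes: a carbon uptake exchange, a gene-gated transporter,
#' several gene-gated biomass routes of limited capacity, membrane-lipid
#' branches (PE, PG, COLIPA) with cytosol-to-periplasm translocators and
#' periplasmic sinks, and a gene-gated decoy drain. Because biomass routes
#' are capacity-limited, deleting biomass-route genes lowers the inner
#' (biomass) optimum and frees carbon for the membrane-material branches —
#' the mechanism by which knockouts raise vesiculation under growth coupling
#' while no deletion can raise it in a fixed LP.
#'
#' @param n_pathway_branches number of parallel gene-gated biomass routes
#'   (>= 2)
#' @param include_omv_branch include the PE/PG/COLIPA branches (disable to
#'   exercise the "empty class" contract)
#' @param plant_optimal_knockout certify a planted optimal deletion set by
#'   running [brute_force_optknock()] at generation time
#' @param max_deletions deletion budget used for the planted certificate
#' @param uptake carbon uptake capacity (mmol/gDW/h)
#' @param seed RNG seed
#' @return list with `network`, and `ground_truth`: wild-type biomass and
#'   vesiculation optima, candidate genes, and (when planted) the certified
#'   optimal knockout with its outer value.
#' @export
make_toy_network <- function(n_pathway_branches = 3, include_omv_branch = TRUE,
                             plant_optimal_knockout = TRUE, max_deletions = 1L,
                             uptake = 10, seed = 1L) {
  stopifnot(n_pathway_branches >= 2)
  with_seed(seed, {
    # biomass route capacities: keep total strictly below uptake so that
    # leftover carbon exists at the wild-type biomass optimum
    caps <- sample(2:4, n_pathway_branches, replace = TRUE)
    while (sum(caps) >= uptake) caps[which.max(caps)] <- caps[which.max(caps)] - 1
    isozyme_branch <- sample(n_pathway_branches, 1)  # one route gets an OR pair
    and_branch <- if (n_pathway_branches > 2)
      sample(setdiff(seq_len(n_pathway_branches), isozyme_branch), 1) else 0

    mets <- data.frame(
      id = c("carbon_e", "carbon_c", "prec_c", "waste_c"),
      name = c("carbon source (extracellular)", "carbon source (cytosol)",
               "biomass precursor", "waste"),
      compartment = c("e", "c", "c", "c"), stringsAsFactors = FALSE)
    rxns <- list(
      list(id = "EX_carbon", stoichiometry = c(carbon_e = -1),
           lower_bound = -uptake, upper_bound = 1000),
      list(id = "T_carbon", stoichiometry = c(carbon_e = -1, carbon_c = 1),
           lower_bound = 0, upper_bound = 1000, gpr = "gT"),
      list(id = "BIOMASS", stoichiometry = c(prec_c = -1),
           lower_bound = 0, upper_bound = 1000, objective_coefficient = 1),
      list(id = "DRAIN", stoichiometry = c(carbon_c = -1, waste_c = 1),
           lower_bound = 0, upper_bound = 1000, gpr = "gdrain"),
      list(id = "DM_waste", stoichiometry = c(waste_c = -1),
           lower_bound = 0, upper_bound = 1000)
    )
    branch_genes <- character(0)
    for (i in seq_len(n_pathway_branches)) {
      gpr <- paste0("gbio", i)
      if (i == isozyme_branch) gpr <- paste0("gbio", i, " or gbio", i, "b")
      if (i == and_branch) gpr <- paste0("gbio", i, " and gbio", i, "c")
      branch_genes <- c(branch_genes, paste0("gbio", i))
      rxns[[length(rxns) + 1L]] <- list(
        id = paste0("R_bio", i), stoichiometry = c(carbon_c = -1, prec_c = 1),
        lower_bound = 0, upper_bound = caps[i], gpr = gpr)
    }
    if (include_omv_branch) {
      for (cls in c("pe160", "pg160", "colipa")) {
        g <- paste0("g", sub("160", "", cls))
        mets <- rbind(mets, data.frame(
          id = paste0(cls, c("_c", "_p")), name = paste0(cls, c(" (cytosol)", " (periplasm)")),
          compartment = c("c", "p"), stringsAsFactors = FALSE))
        st_syn <- stats::setNames(c(-1, 1), c("carbon_c", paste0(cls, "_c")))
        st_tr <- stats::setNames(c(-1, 1), paste0(cls, c("_c", "_p")))
        st_sk <- stats::setNames(-1, paste0(cls, "_p"))
        rxns <- c(rxns, list(
          list(id = paste0("SYN_", cls), stoichiometry = st_syn,
               lower_bound = 0, upper_bound = 1000, gpr = g),
          list(id = paste0("TR_", cls), stoichiometry = st_tr,
               lower_bound = 0, upper_bound = 1000),
          list(id = paste0("SK_", cls), stoichiometry = st_sk,
               lower_bound = 0, upper_bound = 1000)))
      }
    }
    net <- metabolic_network(mets, rxns, biomass_reaction_id = "BIOMASS")

    gt <- list(branch_capacities = caps, uptake = uptake,
               candidates = c(branch_genes, "gdrain", if (include_omv_branch) "gpe"))
    gt$wt_biomass <- solve_fba(net, biomass_objective(net))$objective_value
    if (include_omv_branch) {
      sets <- identify_omv_reactions(net)
      obj <- build_omv_objective(sets)
      gt$omv_objective <- obj
      gt$omv_sets <- sets
      gt$wt_vesiculation_max <- vesiculation_flux(net, obj)
      prog <- bilevel_program(net, obj, candidates = gt$candidates,
                              max_deletions = max_deletions)
      gt$wt_vesiculation_at_growth <- evaluate_design(prog, character(0))$outer_value
      if (plant_optimal_knockout) {
        best <- brute_force_optknock(prog)
        gt$planted_optimal_knockout <- best[[1]]$deleted_genes
        gt$planted_outer_value <- best[[1]]$outer_value
        gt$program <- prog
      }
    }
    list(network = net, ground_truth = gt)
  })
}

#' Generate a knockout phenotype panel with planted inconsistencies
#'
#' Starting from a toy network, plants growth-concordance errors of both
#' kinds with known minimal fixes: growth-where-none-observed (GNG) mutants
#' are created by adding removable ungated bypass reactions to the network,
#' and no-growth-where-observed (NGG) mutants by withholding a required
#' reaction into the universal database. Consistent mutants (both GG and
#' NGNG) are included so reconciliation has a consistency set to protect.
#'
#' @param toy result of [make_toy_network()] (with OMV branches)
#' @param n_consistent number of consistent mutants (>= 2: at least one GG
#'   and one NGNG)
#' @param n_planted_gng,n_planted_ngg planted inconsistency counts
#' @param threshold growth cutoff passed through to classification
#' @param seed RNG seed
#' @return list with `network` (bypasses added, prec2 requirement wired in),
#'   `panel` (data.frame: mutant_id, genes, observed_growth), `universal`
#'   (a [metabolic_network()] of candidate additions), and `expected_fixes`
#'   (list: `suppressed` reaction ids, `added` reaction ids)
#' @export
make_phenotype_panel <- function(toy, n_consistent = 4, n_planted_gng = 1,
                                 n_planted_ngg = 1, threshold = 0.01,
                                 seed = 1L) {
  stopifnot(n_consistent >= 2)
  net <- toy$network
  gt <- toy$ground_truth
  # all genes appearing in any biomass-route GPR: deleting this closure is
  # what actually shuts every route (isozyme "or" pairs included)
  branch_rxns <- grep("^R_bio", net$reactions$id)
  branch_genes <- sort(unique(unlist(
    lapply(net$reactions$gpr[branch_rxns], function(g) gpr_genes(parse_gpr(g))))))
  with_seed(seed, {
    mets <- net$metabolites
    rxn_list <- reactions_as_list(net)

    # NGG machinery: biomass additionally requires a second precursor whose
    # only native producer is gene-gated; the alternative producer is
    # withheld into the universal database.
    mets <- rbind(mets, data.frame(id = "prec2_c", name = "second biomass precursor",
                                   compartment = "c", formula = NA_character_,
                                   charge = NA_integer_, stringsAsFactors = FALSE))
    bi <- which(vapply(rxn_list, function(r) r$id == "BIOMASS", logical(1)))
    rxn_list[[bi]]$stoichiometry <- c(rxn_list[[bi]]$stoichiometry, prec2_c = -1)
    rxn_list[[length(rxn_list) + 1L]] <- list(
      id = "R_prec2", stoichiometry = c(carbon_c = -1, prec2_c = 1),
      lower_bound = 0, upper_bound = 1000, gpr = "gp2")

    # GNG machinery: ungated bypass routes to the first precursor
    bypass_ids <- character(0)
    for (k in seq_len(n_planted_gng)) {
      id <- paste0("BYPASS_", k)
      bypass_ids <- c(bypass_ids, id)
      rxn_list[[length(rxn_list) + 1L]] <- list(
        id = id, stoichiometry = c(carbon_c = -1, prec_c = 1),
        lower_bound = 0, upper_bound = 2)
    }
    net2 <- metabolic_network(mets, rxn_list, biomass_reaction_id = "BIOMASS")

    # universal database: the withheld producer plus decoys that cannot help
    uni_mets <- data.frame(
      id = c("carbon_c", "prec2_c", "waste_c", "junk_c"),
      name = c("carbon source (cytosol)", "second biomass precursor", "waste", "junk"),
      compartment = "c", stringsAsFactors = FALSE)
    uni_rxns <- list(
      list(id = "U_prec2_alt", stoichiometry = c(carbon_c = -1, prec2_c = 1),
           lower_bound = 0, upper_bound = 1000),
      list(id = "U_decoy1", stoichiometry = c(carbon_c = -1, junk_c = 1),
           lower_bound = 0, upper_bound = 1000),
      list(id = "U_decoy2", stoichiometry = c(junk_c = -1, waste_c = 1),
           lower_bound = 0, upper_bound = 1000))
    universal <- metabolic_network(uni_mets, uni_rxns)

    # panel assembly --------------------------------------------------------
    decoys <- c("gdrain", "gpe", "gpg")
    n_gg <- max(1L, ceiling(n_consistent / 2))
    n_ngng <- n_consistent - n_gg
    panel <- list()
    push <- function(id, genes, obs) {
      panel[[length(panel) + 1L]] <<- data.frame(
        mutant_id = id, genes = paste(genes, collapse = ";"),
        observed_growth = obs, stringsAsFactors = FALSE)
    }
    push("wt", character(0), TRUE)
    for (k in seq_len(n_gg - 1L)) {
      push(paste0("gg_", k), sample(decoys, 1), TRUE)
    }
    for (k in seq_len(n_ngng)) {
      extra <- if (runif(1) < 0.5) sample(decoys, 1) else character(0)
      push(paste0("ngng_", k), c("gT", extra), FALSE)
    }
    for (k in seq_len(n_planted_gng)) {
      extra <- if (runif(1) < 0.5) sample(decoys, 1) else character(0)
      push(paste0("gng_", k), c(branch_genes, extra), FALSE)
    }
    for (k in seq_len(n_planted_ngg)) {
      extra <- if (runif(1) < 0.5) sample(decoys, 1) else character(0)
      push(paste0("ngg_", k), c("gp2", extra), TRUE)
    }
    panel <- do.call(rbind, panel)

    list(network = net2, panel = panel, universal = universal,
         expected_fixes = list(suppressed = bypass_ids,
                               added = if (n_planted_ngg > 0) "U_prec2_alt"
                                       else character(0)),
         threshold = threshold)
  })
}

# Re-expand a network into the constructor's reaction-list form (used by the
# generators when editing a network structurally).
reactions_as_list <- function(net) {
  lapply(seq_len(nrow(net$reactions)), function(j) {
    r <- net$reactions[j, ]
    st <- net$stoichiometry[, j]
    st <- st[st != 0]
    list(id = r$id, name = r$name, stoichiometry = stats::setNames(as.numeric(st), names(st)),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         gpr = r$gpr, objective_coefficient = r$objective_coefficient)
  })
}

#' Generate a synthetic vesicle-recovery study
#'
#' Emulates a UV-quantified vesicle recovery experiment: per sample a smooth
#' nonnegative absorbance spectrum (200-320 nm, 2 nm steps) whose area under
#' the curve equals `base_auc x fold x mass x OD600 x (1 + noise)`, so that
#' after mass/OD normalization the expected group ratios equal the planted
#' fold changes exactly (and do so exactly at zero noise). The spectrum is a
#' mixture of protein-like (280 nm) and nucleic-acid-like (260 nm) Gaussian
#' bands on a decaying background; band weights are solved per sample so the
#' Warburg-Christian protein estimate tracks the planted protein fold.
#'
#' @param groups data.frame with columns `name`, `n_replicates`,
#'   `vesicle_fold`, `protein_fold`; the first row is the reference group
#'   and must have both folds equal to 1. Default mirrors a wild type plus
#'   four overproducing mutants (folds 7, 10, 7, 7; protein up in three).
#' @param noise_cv coefficient of variation of the multiplicative noise on
#'   the vesicle signal (default 0.15)
#' @param seed RNG seed
#' @return list with `spectra` (named list of `uv_spectrum`), `meta`
#'   (data.frame sample_id, group, mass_g, od600, replicate), and the
#'   planted `groups` table
#' @export
make_assay_study <- function(groups = NULL, noise_cv = 0.15, seed = 1L) {
  if (is.null(groups)) {
    groups <- data.frame(
      name = c("WT", "mutA", "mutB", "mutC", "mutD"),
      n_replicates = 3L,
      vesicle_fold = c(1, 7, 10, 7, 7),
      protein_fold = c(1, 3, 3, 1, 3),
      stringsAsFactors = FALSE)
  }
  stopifnot(groups$vesicle_fold[1] == 1, groups$protein_fold[1] == 1)
  wl <- seq(200, 320, by = 2)
  shape_prot <- exp(-(wl - 280)^2 / (2 * 12^2)) + 0.8 * exp(-(wl - 215)^2 / (2 * 10^2))
  shape_na <- exp(-(wl - 260)^2 / (2 * 14^2)) + 0.6 * exp(-(wl - 210)^2 / (2 * 9^2))
  auc_of <- function(s) pracma::trapz(wl, s)
  I_p <- auc_of(shape_prot); I_n <- auc_of(shape_na)
  at <- function(s, x) s[match(x, wl)]
  base_auc <- 30; base_protein <- 0.6

  with_seed(seed, {
    spectra <- list(); meta <- list()
    for (gi in seq_len(nrow(groups))) {
      g <- groups[gi, ]
      for (r in seq_len(g$n_replicates)) {
        sid <- paste0(g$name, "_", r)
        mass <- round(runif(1, 0.8, 1.2), 3)
        od <- round(runif(1, 1.5, 2.5), 3)
        eps <- if (noise_cv > 0) stats::rnorm(1, 0, noise_cv) else 0
        target_auc <- base_auc * g$vesicle_fold * (1 + eps) * mass * od
        eps_p <- if (noise_cv > 0) stats::rnorm(1, 0, noise_cv) else 0
        target_prot <- base_protein * g$protein_fold * (1 + eps_p) * mass * od
        # solve c_p, c_n: AUC and Warburg-Christian protein hit their targets
        wc <- c(1.55 * at(shape_prot, 280) - 0.76 * at(shape_prot, 260),
                1.55 * at(shape_na, 280) - 0.76 * at(shape_na, 260))
        M <- rbind(c(I_p, I_n), wc)
        cf <- solve(M, c(target_auc, target_prot))
        if (any(cf < 0)) {  # keep spectra nonnegative: fall back to pure mix
          cf <- pmax(cf, 0)
          cf[1] <- (target_auc - cf[2] * I_n) / I_p
        }
        spec <- uv_spectrum(wl, cf[1] * shape_prot + cf[2] * shape_na)
        spectra[[sid]] <- spec
        meta[[length(meta) + 1L]] <- data.frame(
          sample_id = sid, group = g$name, mass_g = mass, od600 = od,
          replicate = r, stringsAsFactors = FALSE)
      }
    }
    list(spectra = spectra, meta = do.call(rbind, meta), groups = groups)
  })
}

#' Generate a synthetic LC-MS lipidomics feature table
#'
#' Produces a feature-by-sample intensity table with planted structure for
#' every filtering and modelling stage: a lipid reference table whose
#' classes follow `class_mix`; feature m/z synthesized from reference
#' monoisotopic masses under randomly assigned adducts (M+H, M+NH4, M+Cl) at
#' 0 ppm; log-normal study intensities with optional per-group effects; QC
#' replicates constructed so their sample coefficient of variation is
#' exactly the planted value (a fixed unit-variance pattern scaled by the
#' target CV); and a known subset of blank-contaminated features.
#'
#' @param n_features number of features
#' @param class_mix named fractions of lipid classes (defaults mirror an
#'   outer-membrane-vesicle profile dominated by glycerolipids with
#'   glycerophospholipids second)
#' @param groups character vector of study group names (first = reference)
#' @param n_replicates study replicates per group
#' @param n_qc,n_blank pooled QC injections and solvent blanks
#' @param group_effects named list: group -> multiplicative effect applied
#'   to a random half of the features (empty list = null structure, no
#'   group separation)
#' @param frac_high_cv fraction of features given QC CV above 20%
#' @param frac_blank fraction of features planted as blank contamination
#' @param noise_sdlog log-scale replicate noise
#' @param seed RNG seed
#' @return list with `table` (a [feature_table()]), `reference` (lipid
#'   reference data.frame: name, class, monoisotopic_mass), and
#'   `planted`: ids of high-CV features, blank features, per-feature adduct
#' @export
make_feature_table <- function(n_features = 120,
                               class_mix = c(glycerolipid = 0.52,
                                             glycerophospholipid = 0.12,
                                             polyketide = 0.06,
                                             fatty_acyl = 0.05,
                                             prenol = 0.04,
                                             unassigned = 0.21),
                               groups = c("WT", "mutA", "mutB", "mutC", "mutD"),
                               n_replicates = 3L, n_qc = 4L, n_blank = 2L,
                               group_effects = list(),
                               frac_high_cv = 0.15, frac_blank = 0.1,
                               noise_sdlog = 0.25, seed = 1L) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-8, n_qc >= 2, n_blank >= 1)
  adduct_names <- names(adduct_mass_shifts())
  with_seed(seed, {
    classes <- sample(names(class_mix), n_features, replace = TRUE, prob = class_mix)
    mass <- round(runif(n_features, 400, 900), 6)
    reference <- data.frame(
      name = sprintf("lipid_%03d", seq_len(n_features)),
      class = classes, monoisotopic_mass = mass, stringsAsFactors = FALSE)
    adduct <- sample(adduct_names, n_features, replace = TRUE)
    mz <- mass + adduct_mass_shifts()[adduct]
    rt <- round(runif(n_features, 0.5, 30.5), 2)

    sample_ids <- c(
      paste0(rep(groups, each = n_replicates), "_", seq_len(n_replicates)),
      paste0("QC_", seq_len(n_qc)), paste0("BLANK_", seq_len(n_blank)))
    roles <- c(rep("study", length(groups) * n_replicates),
               rep("qc", n_qc), rep("blank", n_blank))
    grp <- c(rep(groups, each = n_replicates), rep(NA_character_, n_qc + n_blank))

    base <- stats::rlnorm(n_features, meanlog = 11, sdlog = 1)
    X <- matrix(0, n_features, length(sample_ids),
                dimnames = list(sprintf("F%03d", seq_len(n_features)), sample_ids))
    affected <- stats::setNames(vector("list", length(group_effects)), names(group_effects))
    for (g in names(group_effects)) {
      affected[[g]] <- sort(sample(n_features, ceiling(n_features / 2)))
    }
    for (j in which(roles == "study")) {
      eff <- rep(1, n_features)
      g <- grp[j]
      if (g %in% names(group_effects)) {
        eff[affected[[g]]] <- group_effects[[g]]
      }
      X[, j] <- base * eff * stats::rlnorm(n_features, 0, noise_sdlog)
    }
    # QC: exact planted CVs via a fixed zero-mean unit-sd pattern
    n_high <- round(frac_high_cv * n_features)
    high_cv_idx <- sort(sample(n_features, n_high))
    cv_planted <- stats::runif(n_features, 0.02, 0.15)
    cv_planted[high_cv_idx] <- stats::runif(n_high, 0.25, 0.45)
    patt <- seq_len(n_qc) - mean(seq_len(n_qc))
    patt <- patt / stats::sd(patt)  # sample sd = 1, mean = 0
    for (i in seq_len(n_features)) {
      X[i, roles == "qc"] <- base[i] * (1 + cv_planted[i] * patt)
    }
    # blanks: planted contamination at half the study mean, others zero
    blank_idx <- sort(sample(n_features, round(frac_blank * n_features)))
    X[blank_idx, roles == "blank"] <- base[blank_idx] * 0.5
    # high-CV and blank sets are kept disjoint so each filter's planted
    # outcome is unambiguous
    overlap <- intersect(blank_idx, high_cv_idx)
    if (length(overlap)) {
      cv_planted[overlap] <- stats::runif(length(overlap), 0.02, 0.15)
      for (i in overlap) X[i, roles == "qc"] <- base[i] * (1 + cv_planted[i] * patt)
      high_cv_idx <- setdiff(high_cv_idx, overlap)
    }

    samples <- data.frame(sample_id = sample_ids, role = roles, group = grp,
                          quantity = stats::runif(length(sample_ids), 0.8, 1.2),
                          sample_volume = 1, stringsAsFactors = FALSE)
    features <- data.frame(feature_id = rownames(X), mz = unname(mz), rt = rt,
                           stringsAsFactors = FALSE)
    tab <- feature_table(features, samples, X)
    list(table = tab, reference = reference,
         planted = list(high_cv = rownames(X)[high_cv_idx],
                        blank = rownames(X)[blank_idx],
                        adduct = stats::setNames(adduct, rownames(X)),
                        cv_percent = 100 * cv_planted,
                        affected = affected))
  })
}
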