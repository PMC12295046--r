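# Vesiculation objective.
#
# Outer membrane vesicles bud from the Gram-negative outer membrane, so a
# flux proxy for vesicle production is the synthesis of membrane material —
# phosphatidylethanolamines (PE), phosphatidylglycerols (PG) and the core
# oligosaccharide lipid A (COLIPA, the LPS precursor) — together with its
# translocation from the cytosol into the periplasm. The objective is a
# weighted linear combination of the fluxes of those reaction classes.

#' Metabolite matching rules for the vesiculation objective
#'
#' Patterns are regular expressions matched against metabolite ids with the
#' compartment suffix (`"_c"`, `"_p"`, ...) stripped. The shipped defaults
#' follow BiGG-style nomenclature (`pe160_c`, `pg160_p`, `colipa_c`, ...).
#'
#' @param pe,pg,colipa regex vectors naming the species of each lipid class
#' @param cytosol,periplasm compartment codes
#' @return a list of matching rules for [identify_omv_reactions()]
#' @export
omv_patterns <- function(pe = "^pe[0-9]*$", pg = "^pg[0-9]*$",
                         colipa = "^colipa$", cytosol = "c", periplasm = "p") {
  list(pe = pe, pg = pg, colipa = colipa,
       cytosol = cytosol, periplasm = periplasm)
}

#' Weights of the vesiculation objective
#'
#' @param pe,pg,colipa,translocation nonnegative class weights; the default
#'   weighs the four classes equally (class weights are not dictated by the
#'   biology, so equal weighting with within-class normalization is the
#'   neutral choice; both are configurable).
#' @param normalize_within_class divide each class weight by the class size,
#'   so a class's total contribution is independent of how many reactions
#'   realize it
#' @return an `omv_objective_spec`
#' @export
omv_objective_spec <- function(pe = 1, pg = 1, colipa = 1, translocation = 1,
                               normalize_within_class = TRUE) {
  w <- c(pe = pe, pg = pg, colipa = colipa, translocation = translocation)
  stopifnot(all(w >= 0))
  if (all(w == 0)) stop("at least one class weight must be positive")
  structure(list(weights = w, normalize_within_class = normalize_within_class),
            class = "omv_objective_spec")
}

strip_compartment <- function(met_id) sub("_[A-Za-z0-9]+$", "", met_id)
met_compartment <- function(net, met_id) {
  net$metabolites$compartment[match(met_id, net$metabolites$id)]
}

#' Identify the reactions entering the vesiculation objective
#'
#' Synthesis classes (`pe`, `pg`, `colipa`) collect reactions that produce a
#' matched metabolite in the cytosol; the translocation class collects
#' reactions that consume a matched metabolite in the cytosol and produce a
#' matched metabolite in the periplasm. A reaction can belong to a lipid
#' class and to translocation, but translocators are not counted as
#' synthesis.
#'
#' @param net a [metabolic_network()]
#' @param patterns matching rules from [omv_patterns()]
#' @param spec optional [omv_objective_spec()]; classes with positive weight
#'   that match nothing raise an "empty class" error (zero-weight classes are
#'   exempt).
#' @return list of reaction-id sets: `pe`, `pg`, `colipa`, `translocation`
#' @export
identify_omv_reactions <- function(net, patterns = omv_patterns(),
                                   spec = omv_objective_spec()) {
  stopifnot(inherits(net, "metabolic_network"))
  base_id <- strip_compartment(net$metabolites$id)
  comp <- net$metabolites$compartment
  S <- as.matrix(net$stoichiometry)

  match_class <- function(regexes) {
    hits <- rep(FALSE, length(base_id))
    for (rx in regexes) hits <- hits | grepl(rx, base_id)
    hits
  }
  any_lipid <- match_class(unlist(patterns[c("pe", "pg", "colipa")]))

  translocation <- character(0)
  consumed_cyt <- (S < 0) & rep(any_lipid & comp == patterns$cytosol, ncol(S))
  produced_per <- (S > 0) & rep(any_lipid & comp == patterns$periplasm, ncol(S))
  translocation <- colnames(S)[apply(consumed_cyt, 2, any) & apply(produced_per, 2, any)]

  synth <- function(regexes) {
    hit <- match_class(regexes) & comp == patterns$cytosol
    ids <- colnames(S)[apply((S > 0) & rep(hit, ncol(S)), 2, any)]
    setdiff(ids, translocation)
  }

  sets <- list(pe = synth(patterns$pe), pg = synth(patterns$pg),
               colipa = synth(patterns$colipa), translocation = translocation)
  for (cls in names(sets)) {
    if (spec$weights[[cls]] > 0 && !length(sets[[cls]])) {
      stop("empty class '", cls, "': no reaction matches its patterns but its ",
           "objective weight is positive")
    }
  }
  sets
}

#' Assemble the vesiculation objective vector
#'
#' The coefficient of a reaction is the sum, over the classes containing it,
#' of the class weight (divided by the class size under within-class
#' normalization). Sense is maximize.
#'
#' @param sets reaction-id sets from [identify_omv_reactions()]
#' @param spec an [omv_objective_spec()]
#' @return an [objective_vector()]
#' @export
build_omv_objective <- function(sets, spec = omv_objective_spec()) {
  coef <- numeric(0)
  for (cls in names(spec$weights)) {
    w <- spec$weights[[cls]]
    ids <- sets[[cls]]
    if (w > 0 && !length(ids)) stop("empty class '", cls, "' with positive weight")
    if (!length(ids) || w == 0) next
    wj <- if (spec$normalize_within_class) w / length(ids) else w
    add <- stats::setNames(rep(wj, length(ids)), ids)
    coef <- c(coef, add)
  }
  if (!length(coef)) stop("vesiculation objective is identically zero")
  coef <- c(tapply(coef, names(coef), sum))  # reactions in several classes add up
  objective_vector(coef[order(names(coef))], "maximize")
}

#' Optimal vesiculation flux of a network
#'
#' @param net a [metabolic_network()]
#' @param objective vesiculation [objective_vector()] from
#'   [build_omv_objective()]
#' @return the FBA optimum of the vesiculation objective (weighted
#'   mmol/gDW/h); 0 when the LP is infeasible only through closed medium is
#'   not special-cased — status is propagated as an error.
#' @export
vesiculation_flux <- function(net, objective) {
  sol <- solve_fba(net, objective)
  if (sol$status != "optimal") stop("vesiculation FBA not optimal: ", sol$status)
  sol$objective_value
}
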