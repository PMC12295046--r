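# Flux balance analysis: LP over the steady-state flux cone.
#
#   max / min  c'v   s.t.  S v = 0,   lb <= v <= ub
#
# Objective values are the contract; individual fluxes of degenerate
# alternate optima are not (FBA optima are generically non-unique).

#' Construct an objective vector
#'
#' @param coefficients named numeric vector of reaction weights `c_j`
#' @param sense `"maximize"` or `"minimize"`
#' @return an `objective_vector` object
#' @export
objective_vector <- function(coefficients, sense = c("maximize", "minimize")) {
  sense <- match.arg(sense)
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            all(nzchar(names(coefficients))))
  structure(list(coefficients = coefficients, sense = sense),
            class = "objective_vector")
}

#' Biomass objective of a network
#' @param net a [metabolic_network()]
#' @return an [objective_vector()] maximizing the biomass reaction
#' @export
biomass_objective <- function(net) {
  if (is.na(net$biomass_reaction_id)) stop("network has no biomass reaction")
  objective_vector(stats::setNames(1, net$biomass_reaction_id), "maximize")
}

#' Solve a flux balance analysis LP
#'
#' @param net a [metabolic_network()]
#' @param objective an [objective_vector()]; default is the network's stored
#'   objective coefficients (usually biomass).
#' @return a `flux_solution`: list with `status` (`"optimal"`, `"infeasible"`),
#'   `objective_value`, and `fluxes` (named numeric over all reactions).
#'   When optimal, mass balance |S v| and bound violations are within 1e-6.
#' @export
solve_fba <- function(net, objective = NULL) {
  stopifnot(inherits(net, "metabolic_network"))
  if (is.null(objective)) {
    co <- net$reactions$objective_coefficient
    if (all(co == 0)) stop("network carries no objective coefficients")
    objective <- objective_vector(
      stats::setNames(co[co != 0], net$reactions$id[co != 0]), "maximize")
  }
  stopifnot(inherits(objective, "objective_vector"))
  bad <- setdiff(names(objective$coefficients), net$reactions$id)
  if (length(bad)) stop("objective references unknown reaction(s): ",
                        paste(bad, collapse = ", "))
  if (all(objective$coefficients == 0)) stop("objective is identically zero")

  n <- nrow(net$reactions)
  obj <- numeric(n)
  obj[match(names(objective$coefficients), net$reactions$id)] <- objective$coefficients
  S <- as.matrix(net$stoichiometry)
  res <- lp_solve(obj, A = S, dir = rep("=", nrow(S)), rhs = rep(0, nrow(S)),
                  lb = net$reactions$lower_bound, ub = net$reactions$upper_bound,
                  maximize = objective$sense == "maximize")
  if (res$status == "error") stop("LP solver failure: ", res$message %||% "unknown")
  fluxes <- stats::setNames(res$x, net$reactions$id)
  structure(list(status = res$status,
                 objective_value = if (res$status == "optimal") res$objective else NA_real_,
                 fluxes = fluxes),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status:", x$status, " objective:",
      format(x$objective_value, digits = 6), "\n")
  invisible(x)
}

#' Growth call for a deletion mutant
#'
#' Runs FBA with the biomass objective on the knocked-out network and
#' classifies growth against a rate threshold; an infeasible LP is reported
#' as rate 0, no growth. The boundary is inclusive: rate equal to the
#' threshold counts as growth.
#' @param net a [metabolic_network()]
#' @param deleted character vector of deleted gene ids
#' @param threshold growth/no-growth cutoff in 1/h (must be > 0); the
#'   default 1e-2 is a conventional cutoff for binary growth screens.
#' @return list with `rate` (1/h), `grows` (logical), `threshold`
#' @export
growth_call <- function(net, deleted = character(0), threshold = 0.01) {
  stopifnot(threshold > 0)
  sol <- solve_fba(suppressWarnings(delete_genes(net, deleted)),
                   biomass_objective(net))
  rate <- if (sol$status == "optimal") sol$objective_value else 0
  list(rate = rate, grows = rate >= threshold, threshold = threshold)
}

#' Growth calls for a panel of deletion mutants
#'
#' @param net a [metabolic_network()]
#' @param panel list of gene-id vectors (one mutant each); order preserved.
#' @param threshold growth cutoff in 1/h
#' @return list of [growth_call()] results, same order as `panel`
#' @export
knockout_panel <- function(net, panel, threshold = 0.01) {
  stopifnot(length(panel) >= 1)
  lapply(panel, function(genes) growth_call(net, genes, threshold))
}

# Assert the FluxSolution invariants (used throughout the test suite).
check_flux_solution <- function(net, sol, tol = 1e-6) {
  if (sol$status != "optimal") return(invisible(TRUE))
  v <- sol$fluxes
  imbalance <- max(abs(as.matrix(net$stoichiometry) %*% v))
  if (imbalance > tol) stop("mass balance violated: max |S v| = ", imbalance)
  if (any(v < net$reactions$lower_bound - tol) ||
      any(v > net$reactions$upper_bound + tol)) {
    stop("flux bound violated")
  }
  invisible(TRUE)
}
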