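# Stoichiometric network data model and I/O.
#
# A `metabolic_network` holds the stoichiometric matrix S (metabolites x
# reactions, sparse), per-reaction flux bounds in mmol/gDW/h, gene-protein-
# reaction (GPR) boolean rules, and compartment assignments. Sign convention:
# negative stoichiometry = consumed, and exchange uptake is negative flux
# (the dominant convention in constraint-based modelling).

#' Construct a metabolic network
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   and optionally `formula`, `charge`.
#' @param reactions list of reactions, each a list with elements `id`,
#'   `stoichiometry` (named numeric, names are metabolite ids, negative =
#'   consumed), `lower_bound`, `upper_bound`, and optionally `name`, `gpr`
#'   (a boolean rule string such as `"g1 and (g2 or g3)"`),
#'   `objective_coefficient`.
#' @param biomass_reaction_id id of the biomass reaction (`NA` allowed for
#'   partial networks such as universal reaction databases).
#' @param genes character vector of gene ids; defaults to the union of genes
#'   appearing in GPR rules.
#' @param compartments character vector of compartment codes; defaults to
#'   those used by `metabolites`.
#' @return An object of class `metabolic_network` with fields `metabolites`,
#'   `reactions` (data.frame: id, name, lower_bound, upper_bound, gpr, kind,
#'   objective_coefficient), `stoichiometry` (sparse metabolites x reactions
#'   matrix), `genes`, `biomass_reaction_id`, `compartments`.
#' @export
metabolic_network <- function(metabolites, reactions,
                              biomass_reaction_id = NA_character_,
                              genes = NULL, compartments = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$charge)) metabolites$charge <- NA_integer_
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  stopifnot(!anyDuplicated(metabolites$id))

  rxn_ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction ids: ",
                                   paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  get0c <- function(r, f, d) if (is.null(r[[f]])) d else r[[f]]

  # dangling metabolite references are a validation error
  all_mets <- unique(unlist(lapply(reactions, function(r) names(r$stoichiometry))))
  dangling <- setdiff(all_mets, metabolites$id)
  if (length(dangling)) {
    stop("reaction stoichiometry references undeclared metabolite(s): ",
         paste(dangling, collapse = ", "))
  }

  trip <- do.call(rbind, lapply(seq_along(reactions), function(j) {
    st <- reactions[[j]]$stoichiometry
    if (!length(st)) stop("reaction '", rxn_ids[j], "' has empty stoichiometry")
    cbind(i = match(names(st), metabolites$id), j = j, x = as.numeric(st))
  }))
  S <- Matrix::sparseMatrix(i = trip[, "i"], j = trip[, "j"], x = trip[, "x"],
                            dims = c(nrow(metabolites), length(reactions)),
                            dimnames = list(metabolites$id, rxn_ids))

  rdf <- data.frame(
    id = rxn_ids,
    name = vapply(reactions, function(r) get0c(r, "name", r$id), character(1)),
    lower_bound = vapply(reactions, function(r) as.numeric(get0c(r, "lower_bound", -1000)), numeric(1)),
    upper_bound = vapply(reactions, function(r) as.numeric(get0c(r, "upper_bound", 1000)), numeric(1)),
    gpr = vapply(reactions, function(r) as.character(get0c(r, "gpr", "")), character(1)),
    objective_coefficient = vapply(reactions, function(r)
      as.numeric(get0c(r, "objective_coefficient", 0)), numeric(1)),
    stringsAsFactors = FALSE
  )
  if (any(rdf$lower_bound > rdf$upper_bound)) {
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(rdf$id[rdf$lower_bound > rdf$upper_bound], collapse = ", "))
  }

  gpr_gene_list <- lapply(rdf$gpr, function(g) gpr_genes(parse_gpr(g)))
  if (is.null(genes)) genes <- sort(unique(unlist(gpr_gene_list)))
  missing_genes <- setdiff(unlist(gpr_gene_list), genes)
  if (length(missing_genes)) {
    stop("GPR rules use gene(s) not in the gene set: ",
         paste(missing_genes, collapse = ", "))
  }
  if (is.null(compartments)) compartments <- sort(unique(metabolites$compartment))
  if (!all(metabolites$compartment %in% compartments)) {
    stop("metabolite compartment not in declared compartment set")
  }
  if (!is.na(biomass_reaction_id) && !biomass_reaction_id %in% rdf$id) {
    stop("biomass_reaction_id '", biomass_reaction_id, "' does not resolve")
  }

  net <- structure(list(
    metabolites = metabolites[, c("id", "name", "compartment", "formula", "charge")],
    reactions = rdf,
    stoichiometry = S,
    genes = as.character(genes),
    biomass_reaction_id = biomass_reaction_id,
    compartments = compartments
  ), class = "metabolic_network")
  net$reactions$kind <- infer_reaction_kinds(net)
  net
}

# Reaction kind classification: biomass (declared), exchange (single
# metabolite in the extracellular compartment or EX_ prefix), sink/demand
# (other single-metabolite reactions), transport (spans >= 2 compartments),
# internal otherwise.
infer_reaction_kinds <- function(net) {
  S <- net$stoichiometry
  comp <- net$metabolites$compartment
  vapply(seq_len(ncol(S)), function(j) {
    id <- colnames(S)[j]
    if (!is.na(net$biomass_reaction_id) && id == net$biomass_reaction_id) return("biomass")
    touched <- which(S[, j] != 0)
    if (length(touched) == 1L) {
      if (grepl("^(EX|R_EX)_", id) || comp[touched] %in% c("e", "extracellular"))
        return("exchange")
      return("sink")
    }
    if (length(unique(comp[touched])) > 1L) return("transport")
    "internal"
  }, character(1))
}

#' Validate network invariants
#'
#' Checks id resolution of stoichiometry, GPR genes and the biomass reaction,
#' bound ordering, and the single-metabolite property of exchange reactions.
#' @param net a `metabolic_network`
#' @return `net`, invisibly; errors describe the offending ids.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  stopifnot(identical(rownames(net$stoichiometry), net$metabolites$id),
            identical(colnames(net$stoichiometry), net$reactions$id))
  bad <- net$reactions$lower_bound > net$reactions$upper_bound
  if (any(bad)) stop("bounds reversed for: ", paste(net$reactions$id[bad], collapse = ", "))
  used <- unique(unlist(lapply(net$reactions$gpr, function(g) gpr_genes(parse_gpr(g)))))
  if (!all(used %in% net$genes)) {
    stop("GPR gene(s) missing from gene set: ",
         paste(setdiff(used, net$genes), collapse = ", "))
  }
  ex <- which(net$reactions$kind == "exchange")
  n_mets <- Matrix::colSums(net$stoichiometry[, ex, drop = FALSE] != 0)
  if (any(n_mets != 1)) stop("exchange reaction touching != 1 metabolite: ",
                             paste(net$reactions$id[ex][n_mets != 1], collapse = ", "))
  invisible(net)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions, ", length(x$genes), " genes\n", sep = "")
  cat("  compartments: ", paste(x$compartments, collapse = ", "),
      "; biomass: ", x$biomass_reaction_id, "\n", sep = "")
  invisible(x)
}

#' Ids of exchange reactions
#' @param net a `metabolic_network`
#' @return character vector of exchange reaction ids
#' @export
exchange_reactions <- function(net) {
  net$reactions$id[net$reactions$kind == "exchange"]
}

## ---- GPR rules -------------------------------------------------------------

#' Parse a gene-protein-reaction rule
#'
#' Accepts `and`/`or` (case-insensitive, also `&`/`|`) with parentheses.
#' @param text rule string; empty or `NA` yields `NULL` (no gene requirement).
#' @return An AST: a gene id (character scalar) or `list(op = "and"|"or",
#'   args = list(...))`; `NULL` for an empty rule.
#' @export
parse_gpr <- function(text) {
  if (is.null(text)) return(NULL)
  if (is.list(text)) return(text)  # already an AST
  if (length(text) == 0 || is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- regmatches(text, gregexpr("\\(|\\)|&&|\\|\\||&|\\||[^()&|[:space:]]+", text))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  is_op <- function(t, what) {
    !is.na(t) && ((what == "and" && tolower(t) %in% c("and", "&", "&&")) ||
                  (what == "or"  && tolower(t) %in% c("or", "|", "||")))
  }
  parse_expr <- function() {
    args <- list(parse_term())
    while (is_op(peek(), "or")) { advance(); args[[length(args) + 1L]] <- parse_term() }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (is_op(peek(), "and")) { advance(); args[[length(args) + 1L]] <- parse_factor() }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("malformed GPR rule: unexpected end in '", text, "'")
    if (t == "(") {
      advance()
      e <- parse_expr()
      if (!identical(peek(), ")")) stop("malformed GPR rule: missing ')' in '", text, "'")
      advance()
      return(e)
    }
    if (t == ")" || is_op(t, "and") || is_op(t, "or")) {
      stop("malformed GPR rule: unexpected '", t, "' in '", text, "'")
    }
    advance()
  }
  ast <- parse_expr()
  if (pos <= length(toks)) stop("malformed GPR rule: trailing '", toks[pos], "' in '", text, "'")
  ast
}

#' Genes referenced by a GPR AST
#' @param ast result of [parse_gpr()]
#' @return character vector of gene ids
#' @export
gpr_genes <- function(ast) {
  if (is.null(ast)) return(character(0))
  if (is.character(ast)) return(ast)
  unique(unlist(lapply(ast$args, gpr_genes)))
}

# Render an AST back to canonical rule text.
deparse_gpr <- function(ast) {
  if (is.null(ast)) return("")
  if (is.character(ast)) return(ast)
  parts <- vapply(ast$args, function(a) {
    s <- deparse_gpr(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", ast$op, " "))
}

#' Evaluate a GPR rule under a gene deletion set
#'
#' Deleted genes evaluate `FALSE`, all others `TRUE`; `and`/`or` follow
#' boolean semantics; an empty rule is `TRUE` (the reaction is not deletable
#' through genes).
#' @param gpr rule string or AST from [parse_gpr()]
#' @param deleted character vector of deleted gene ids
#' @return logical scalar: is the reaction still available?
#' @export
evaluate_gpr <- function(gpr, deleted = character(0)) {
  ast <- if (is.character(gpr) && length(gpr) == 1) parse_gpr(gpr) else gpr
  if (is.null(ast)) return(TRUE)
  ev <- function(a) {
    if (is.character(a)) return(!(a %in% deleted))
    vals <- vapply(a$args, ev, logical(1))
    if (a$op == "and") all(vals) else any(vals)
  }
  ev(ast)
}

## ---- Editing operations ----------------------------------------------------

#' Simulate gene deletions
#'
#' Reactions whose GPR rule evaluates `FALSE` under the deletion set get both
#' flux bounds set to 0; everything else is untouched. The input network is
#' not modified. Deletions accumulate: the network records its deletion set
#' (`net$deleted_genes`), and GPRs are always re-evaluated against the union,
#' so `delete_genes(delete_genes(M, A), B)` equals `delete_genes(M, A u B)`
#' (an isozyme pair deleted one gene at a time still shuts its reaction).
#' Unknown gene ids produce a warning, not an error (phenotype panels
#' routinely contain genes absent from any model).
#' @param net a `metabolic_network`
#' @param genes character vector of gene ids to delete
#' @return the knocked-out network
#' @export
delete_genes <- function(net, genes) {
  stopifnot(inherits(net, "metabolic_network"))
  genes <- unique(as.character(genes))
  unknown <- setdiff(genes, net$genes)
  if (length(unknown)) {
    warning("ignoring gene id(s) absent from the model: ",
            paste(unknown, collapse = ", "))
  }
  genes <- setdiff(genes, unknown)
  if (!length(genes)) return(net)
  total <- union(net$deleted_genes %||% character(0), genes)
  off <- !vapply(net$reactions$gpr, evaluate_gpr, logical(1), deleted = total)
  net$reactions$lower_bound[off] <- 0
  net$reactions$upper_bound[off] <- 0
  net$deleted_genes <- total
  net
}

#' Apply a growth medium
#'
#' Listed exchange reactions take the given bounds; all unlisted exchanges
#' are closed to uptake (lower bound 0) but stay open to secretion.
#' Non-exchange reactions are untouched. Idempotent for a fixed medium.
#' @param net a `metabolic_network`
#' @param medium a data.frame with columns `reaction_id`, `lower_bound`,
#'   `upper_bound`, or a named list of `c(lb, ub)` pairs keyed by exchange
#'   reaction id. An empty medium closes all uptake.
#' @return the constrained network
#' @export
apply_medium <- function(net, medium) {
  stopifnot(inherits(net, "metabolic_network"))
  if (is.list(medium) && !is.data.frame(medium)) {
    medium <- data.frame(
      reaction_id = names(medium),
      lower_bound = vapply(medium, `[`, numeric(1), 1),
      upper_bound = vapply(medium, `[`, numeric(1), 2),
      stringsAsFactors = FALSE
    )
  }
  ex <- exchange_reactions(net)
  bad <- setdiff(medium$reaction_id, ex)
  if (length(bad)) stop("medium key(s) not exchange reactions: ",
                        paste(bad, collapse = ", "))
  closed <- setdiff(ex, medium$reaction_id)
  i <- match(closed, net$reactions$id)
  net$reactions$lower_bound[i] <- pmax(net$reactions$lower_bound[i], 0)
  j <- match(medium$reaction_id, net$reactions$id)
  net$reactions$lower_bound[j] <- medium$lower_bound
  net$reactions$upper_bound[j] <- medium$upper_bound
  net
}

#' Read a medium definition from CSV
#' @param path CSV with columns `reaction_id`, `lower_bound`, `upper_bound`
#' @return data.frame suitable for [apply_medium()]
#' @export
read_medium <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("reaction_id", "lower_bound", "upper_bound") %in% names(m)))
  m
}
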