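# Bilevel knockout design (OptKnock).
#
# Outer problem: choose up to K gene deletions maximizing the vesiculation
# objective. Inner problem: the cell maximizes biomass given the deletions.
# The bilevel program is collapsed to a single MILP via strong duality of
# the inner LP: primal feasibility, dual feasibility, and primal objective =
# dual objective are imposed simultaneously, with knockout-dependent bound
# terms (mu * z products) linearized exactly through big-M constraints, and
# gene binaries linked to reaction availability through linearized GPR
# (and -> min, or -> max) constraints. The formulation is optimistic: among
# inner-optimal flux distributions, the one most favourable to the outer
# objective is selected — matching the tie handling of the brute-force
# oracle, which fixes biomass at its optimum and then maximizes the outer
# objective.

#' Define a bilevel knockout-design program
#'
#' @param net a [metabolic_network()]
#' @param outer_objective [objective_vector()] maximized by the designer
#'   (e.g. the vesiculation objective)
#' @param inner_objective [objective_vector()] maximized by the cell;
#'   defaults to biomass
#' @param candidates ordered character vector of knockable gene ids
#' @param max_deletions K, the deletion budget (>= 0; 0 is the degenerate
#'   wild-type program)
#' @param min_growth_fraction viability floor f: designs must retain biomass
#'   >= f x wild-type optimum. Default 0.1.
#' @param duality_gap_tol tolerance on the inner primal/dual gap at reported
#'   designs (hard error when exceeded)
#' @return a `bilevel_program`
#' @export
bilevel_program <- function(net, outer_objective, inner_objective = NULL,
                            candidates = net$genes, max_deletions = 5L,
                            min_growth_fraction = 0.1,
                            duality_gap_tol = 1e-6) {
  stopifnot(inherits(net, "metabolic_network"), max_deletions >= 0,
            min_growth_fraction > 0, min_growth_fraction <= 1)
  if (is.null(inner_objective)) inner_objective <- biomass_objective(net)
  stopifnot(all(candidates %in% net$genes))
  wt <- solve_fba(net, inner_objective)
  if (wt$status != "optimal" || wt$objective_value <= 0) {
    stop("wild-type inner objective must be positive under the program's medium")
  }
  structure(list(network = net, outer_objective = outer_objective,
                 inner_objective = inner_objective,
                 candidates = as.character(candidates),
                 max_deletions = as.integer(max_deletions),
                 min_growth_fraction = min_growth_fraction,
                 duality_gap_tol = duality_gap_tol,
                 wild_type_inner = wt$objective_value),
            class = "bilevel_program")
}

objective_dense <- function(objective, net) {
  out <- numeric(nrow(net$reactions))
  out[match(names(objective$coefficients), net$reactions$id)] <- objective$coefficients
  out
}

# Evaluate one deletion set under the program's optimistic tie handling:
# solve the inner LP; check the viability floor; fix the inner objective at
# its optimum (within tie_tol) and maximize the outer objective.
evaluate_design <- function(program, genes, tie_tol = 1e-8) {
  net_ko <- suppressWarnings(delete_genes(program$network, genes))
  inner <- solve_fba(net_ko, program$inner_objective)
  floor_val <- program$min_growth_fraction * program$wild_type_inner
  if (inner$status != "optimal" || inner$objective_value < floor_val - 1e-9) {
    return(list(deleted_genes = sort(genes),
                outer_value = NA_real_, inner_value = if (inner$status == "optimal")
                  inner$objective_value else 0,
                feasible = FALSE))
  }
  c_in <- objective_dense(program$inner_objective, net_ko)
  c_out <- objective_dense(program$outer_objective, net_ko)
  S <- as.matrix(net_ko$stoichiometry)
  A <- rbind(S, c_in)
  res <- lp_solve(c_out, A,
                  dir = c(rep("=", nrow(S)), ">="),
                  rhs = c(rep(0, nrow(S)), inner$objective_value - tie_tol),
                  lb = net_ko$reactions$lower_bound,
                  ub = net_ko$reactions$upper_bound, maximize = TRUE)
  if (res$status != "optimal") stop("outer LP at fixed inner optimum failed: ", res$status)
  list(deleted_genes = sort(genes), outer_value = res$objective,
       inner_value = inner$objective_value, feasible = TRUE)
}

order_designs <- function(designs) {
  if (!length(designs)) return(designs)
  key_outer <- vapply(designs, function(d) -d$outer_value, numeric(1))
  key_size <- vapply(designs, function(d) length(d$deleted_genes), numeric(1))
  key_lex <- vapply(designs, function(d) paste(d$deleted_genes, collapse = ";"),
                    character(1))
  designs[order(key_outer, key_size, key_lex)]
}

#' Brute-force oracle for the bilevel program
#'
#' Enumerates every deletion subset of size <= K, applies the viability
#' floor, and evaluates the outer objective at the inner optimum. Intended
#' as the ground-truth oracle for [solve_optknock()] on small programs.
#'
#' @param program a [bilevel_program()]
#' @return list of feasible designs, ordered by outer value (descending),
#'   then size, then gene ids
#' @export
brute_force_optknock <- function(program) {
  cand <- program$candidates
  K <- min(program$max_deletions, length(cand))
  n_sub <- sum(vapply(0:K, function(k) choose(length(cand), k), numeric(1)))
  if (n_sub > 1e5) stop("brute force would enumerate ", n_sub, " subsets; refusing")
  subsets <- list(character(0))
  for (k in seq_len(K)) {
    if (k > length(cand)) break
    cm <- utils::combn(cand, k, simplify = FALSE)
    subsets <- c(subsets, cm)
  }
  designs <- lapply(subsets, function(g) evaluate_design(program, g))
  designs <- Filter(function(d) d$feasible, designs)
  order_designs(designs)
}

#' Solve the bilevel program as a strong-duality MILP
#'
#' @param program a [bilevel_program()]
#' @param enumerate number of top designs to return; alternatives beyond the
#'   first are generated by integer-cut exclusion of already-found deletion
#'   sets. Default 1.
#' @param big_m bound on the inner LP's dual multipliers used in the
#'   linearization (valid for the toy-scale networks this package targets;
#'   the post-solve duality-gap check errors out if it ever binds wrongly).
#' @return list of designs `list(deleted_genes, outer_value, inner_value,
#'   feasible)`, ordered as in [brute_force_optknock()]. Empty list (with a
#'   `diagnostic` attribute) when no viable design exists.
#' @export
solve_optknock <- function(program, enumerate = 1L, big_m = 1000) {
  stopifnot(inherits(program, "bilevel_program"))
  net <- program$network
  n <- nrow(net$reactions); m <- nrow(net$metabolites)
  cand <- program$candidates
  if (program$max_deletions == 0L || !length(cand)) {
    return(order_designs(list(evaluate_design(program, character(0)))))
  }
  c_in <- objective_dense(program$inner_objective, net)
  c_out <- objective_dense(program$outer_objective, net)
  lb <- net$reactions$lower_bound; ub <- net$reactions$upper_bound

  asts <- lapply(net$reactions$gpr, parse_gpr)
  gated <- which(vapply(asts, function(a) length(intersect(gpr_genes(a), cand)) > 0,
                        logical(1)))

  # ---- variable layout -----------------------------------------------------
  idx <- list(); n_var <- 0L
  alloc <- function(k) { out <- n_var + seq_len(k); n_var <<- n_var + k; out }
  idx$v <- alloc(n)
  idx$lambda <- alloc(m)
  idx$mu_lb <- alloc(n)
  idx$mu_ub <- alloc(n)
  idx$z <- stats::setNames(alloc(length(gated)), gated)       # availability
  idx$w_lb <- stats::setNames(alloc(length(gated)), gated)    # mu_lb * z
  idx$w_ub <- stats::setNames(alloc(length(gated)), gated)    # mu_ub * z
  idx$y <- stats::setNames(alloc(length(cand)), cand)         # 1 = deleted
  idx$a <- stats::setNames(alloc(length(cand)), cand)         # 1 - y
  node_vars <- integer(0)                                     # GPR internals

  var_lb <- numeric(0); var_ub <- numeric(0)
  grow <- function(lbv, ubv) { var_lb <<- c(var_lb, lbv); var_ub <<- c(var_ub, ubv) }
  grow(pmin(lb, 0), pmax(ub, 0))              # v (gated reactions may close)
  grow(rep(-big_m, m), rep(big_m, m))         # lambda
  grow(rep(0, n), rep(big_m, n))              # mu_lb
  grow(rep(0, n), rep(big_m, n))              # mu_ub
  grow(rep(0, length(gated)), rep(1, length(gated)))  # z
  grow(rep(0, length(gated)), rep(big_m, length(gated)))  # w_lb
  grow(rep(0, length(gated)), rep(big_m, length(gated)))  # w_ub
  grow(rep(0, length(cand)), rep(1, length(cand)))    # y
  grow(rep(0, length(cand)), rep(1, length(cand)))    # a
  # ungated reactions keep their own bounds on v
  ungated <- setdiff(seq_len(n), gated)
  var_lb[idx$v[ungated]] <- lb[ungated]
  var_ub[idx$v[ungated]] <- ub[ungated]

  cb_rows <- list(); cb_dir <- character(0); cb_rhs <- numeric(0)
  add_row <- function(ii, vv, dir, rhs) {
    cb_rows[[length(cb_rows) + 1L]] <<- list(i = ii, v = vv)
    cb_dir[length(cb_dir) + 1L] <<- dir
    cb_rhs[length(cb_rhs) + 1L] <<- rhs
  }
  new_node_var <- function() {
    v <- n_var + 1L
    n_var <<- n_var + 1L
    var_lb <<- c(var_lb, 0); var_ub <<- c(var_ub, 1)
    node_vars <<- c(node_vars, v)
    v
  }

  # GPR availability: returns a variable index, or a constant via list(const=)
  # Leaves: candidate gene -> a_g; other gene -> constant 1.
  gpr_var <- function(ast) {
    if (is.character(ast)) {
      if (ast %in% cand) return(idx$a[[ast]])
      return(list(const = 1))
    }
    kids <- lapply(ast$args, gpr_var)
    consts <- vapply(kids, function(k) is.list(k), logical(1))
    cvals <- vapply(kids[consts], function(k) k$const, numeric(1))
    vars <- unlist(kids[!consts])
    if (ast$op == "and") {
      if (length(cvals) && any(cvals == 0)) return(list(const = 0))
      if (!length(vars)) return(list(const = 1))
      if (length(vars) == 1L) return(vars)
      t <- new_node_var()
      for (vv in vars) add_row(c(t, vv), c(1, -1), "<=", 0)      # t <= child
      add_row(c(t, vars), c(1, rep(-1, length(vars))), ">=", -(length(vars) - 1))
      return(t)
    }
    # or
    if (length(cvals) && any(cvals == 1)) return(list(const = 1))
    if (!length(vars)) return(list(const = 0))
    if (length(vars) == 1L) return(vars)
    t <- new_node_var()
    for (vv in vars) add_row(c(t, vv), c(1, -1), ">=", 0)        # t >= child
    add_row(c(t, vars), c(1, rep(-1, length(vars))), "<=", 0)
    t
  }

  # ---- constraints ---------------------------------------------------------
  S <- as.matrix(net$stoichiometry)
  for (i in seq_len(m)) {                                   # S v = 0
    jj <- which(S[i, ] != 0)
    add_row(idx$v[jj], S[i, jj], "=", 0)
  }
  for (r in gated) {                                        # knockout bounds
    zr <- idx$z[[as.character(r)]]
    add_row(c(idx$v[r], zr), c(1, -ub[r]), "<=", 0)
    add_row(c(idx$v[r], zr), c(1, -lb[r]), ">=", 0)
  }
  for (r in seq_len(n)) {                                   # dual feasibility
    ii <- which(S[, r] != 0)
    add_row(c(idx$lambda[ii], idx$mu_ub[r], idx$mu_lb[r]),
            c(S[ii, r], 1, -1), "=", c_in[r])
  }
  # w = mu * z linearization (exact for binary z)
  for (r in gated) {
    rc <- as.character(r)
    for (pair in list(c(idx$w_lb[[rc]], idx$mu_lb[r]), c(idx$w_ub[[rc]], idx$mu_ub[r]))) {
      w <- pair[1]; mu <- pair[2]; zr <- idx$z[[rc]]
      add_row(c(w, mu), c(1, -1), "<=", 0)                  # w <= mu
      add_row(c(w, zr), c(1, -big_m), "<=", 0)              # w <= M z
      add_row(c(w, mu, zr), c(1, -1, -big_m), ">=", -big_m) # w >= mu - M(1-z)
    }
  }
  # strong duality: c_in' v = dual objective
  ii <- integer(0); vv <- numeric(0)
  for (r in seq_len(n)) {
    if (r %in% gated) {
      rc <- as.character(r)
      ii <- c(ii, idx$w_ub[[rc]], idx$w_lb[[rc]]); vv <- c(vv, ub[r], -lb[r])
    } else {
      ii <- c(ii, idx$mu_ub[r], idx$mu_lb[r]); vv <- c(vv, ub[r], -lb[r])
    }
  }
  nz <- which(c_in != 0)
  add_row(c(idx$v[nz], ii), c(-c_in[nz], vv), "=", 0)
  # viability floor
  add_row(idx$v[nz], c_in[nz], ">=",
          program$min_growth_fraction * program$wild_type_inner)
  # GPR linking: a + y = 1; z_r = gpr value
  for (g in cand) add_row(c(idx$a[[g]], idx$y[[g]]), c(1, 1), "=", 1)
  for (r in gated) {
    res <- gpr_var(asts[[r]])
    zr <- idx$z[[as.character(r)]]
    if (is.list(res)) {
      var_lb[zr] <- res$const; var_ub[zr] <- res$const
    } else {
      add_row(c(zr, res), c(1, -1), "=", 0)
    }
  }
  # deletion budget
  add_row(idx$y, rep(1, length(cand)), "<=", program$max_deletions)

  assemble <- function(extra_rows = list()) {
    rows <- c(cb_rows, lapply(extra_rows, `[[`, "row"))
    A <- matrix(0, length(rows), n_var)
    for (i in seq_along(rows)) A[i, rows[[i]]$i] <- rows[[i]]$v
    list(A = A,
         dir = c(cb_dir, vapply(extra_rows, `[[`, character(1), "dir")),
         rhs = c(cb_rhs, vapply(extra_rows, `[[`, numeric(1), "rhs")))
  }

  obj <- numeric(n_var)
  obj[idx$v] <- c_out

  cuts <- list()
  designs <- list()
  for (rep_i in seq_len(enumerate)) {
    prob <- assemble(cuts)
    sol <- milp_solve(obj, prob$A, prob$dir, prob$rhs, var_lb, var_ub,
                      binary_idx = unname(idx$y), maximize = TRUE)
    if (sol$status != "optimal") break
    y <- round(sol$x[idx$y])
    genes <- cand[y == 1]
    des <- evaluate_design(program, genes)
    # strong-duality certificate: the MILP's inner value must match a fresh
    # inner LP on the knocked-out network
    milp_inner <- sum(c_in * sol$x[idx$v])
    if (!des$feasible || abs(milp_inner - des$inner_value) > program$duality_gap_tol) {
      stop("duality gap ", format(abs(milp_inner - des$inner_value)),
           " exceeds tolerance at design {", paste(genes, collapse = ", "), "}")
    }
    designs[[length(designs) + 1L]] <- des
    # integer cut excluding this deletion set
    coefs <- ifelse(cand %in% genes, 1, -1)
    cuts[[length(cuts) + 1L]] <- list(
      row = list(i = unname(idx$y), v = coefs), dir = "<=",
      rhs = sum(coefs > 0) - 1)
  }
  if (!length(designs)) {
    out <- list()
    attr(out, "diagnostic") <- "MILP infeasible: no viable design under the growth floor"
    return(out)
  }
  order_designs(designs)
}

#' Filter and post-process knockout designs
#'
#' Applies, in order: deduplication by deletion set; a minimum-improvement
#' margin of the outer value over the wild-type outer value; a gene exclusion
#' list; and optionally decomposition of multi-gene designs into their
#' single-gene members, re-evaluated through the inner/outer solve (the
#' single-knockout follow-up used when multi-deletion designs are carried to
#' the bench one gene at a time). Order is stable.
#'
#' @param designs list of designs from [solve_optknock()] or
#'   [brute_force_optknock()]
#' @param program the originating [bilevel_program()] (needed for the
#'   wild-type reference and re-evaluation)
#' @param min_improvement drop designs with `outer_value` less than
#'   wild-type outer + margin (default 0: passthrough of feasible designs)
#' @param exclude_genes drop designs deleting any of these genes
#' @param decompose_singletons also return each deleted gene as a re-evaluated
#'   single-gene design
#' @return filtered (and possibly extended) design list, stable order
#' @export
filter_designs <- function(designs, program, min_improvement = 0,
                           exclude_genes = character(0),
                           decompose_singletons = FALSE) {
  wt_outer <- evaluate_design(program, character(0))$outer_value
  seen <- character(0)
  out <- list()
  for (d in designs) {
    key <- paste(sort(d$deleted_genes), collapse = ";")
    if (key %in% seen) next
    seen <- c(seen, key)
    if (!isTRUE(d$feasible)) next
    if (length(intersect(d$deleted_genes, exclude_genes))) next
    if (d$outer_value < wt_outer + min_improvement - 1e-9) next
    out[[length(out) + 1L]] <- d
  }
  if (decompose_singletons) {
    singles <- unique(unlist(lapply(out, `[[`, "deleted_genes")))
    for (g in singles) {
      key <- g
      if (key %in% seen) next
      seen <- c(seen, key)
      d1 <- evaluate_design(program, g)
      if (d1$feasible) out[[length(out) + 1L]] <- d1
    }
  }
  out
}

#' Export designs as a report table
#' @param designs list of designs
#' @param program the originating [bilevel_program()]
#' @return data.frame with deleted_genes, outer_value, inner_value,
#'   wild_type_outer, fold_improvement
#' @export
design_report <- function(designs, program) {
  wt_outer <- evaluate_design(program, character(0))$outer_value
  data.frame(
    deleted_genes = vapply(designs, function(d) paste(d$deleted_genes, collapse = ";"),
                           character(1)),
    outer_value = vapply(designs, `[[`, numeric(1), "outer_value"),
    inner_value = vapply(designs, `[[`, numeric(1), "inner_value"),
    wild_type_outer = wt_outer,
    fold_improvement = vapply(designs, `[[`, numeric(1), "outer_value") /
      ifelse(wt_outer == 0, NA_real_, wt_outer),
    stringsAsFactors = FALSE)
}
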