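make_program <- function(seed, K = 2, branches = 3) {
  toy <- make_toy_network(n_pathway_branches = branches, max_deletions = K,
                          plant_optimal_knockout = FALSE, seed = seed)
  gt <- toy$ground_truth
  bilevel_program(toy$network, gt$omv_objective, candidates = gt$candidates,
                  max_deletions = K)
}

test_that("degenerate programs return the wild-type design", {
  prog <- make_program(seed = 21, K = 0)
  d <- solve_optknock(prog)
  expect_length(d, 1)
  expect_length(d[[1]]$deleted_genes, 0)
  expect_true(d[[1]]$feasible)
  # empty candidate list behaves the same for the oracle
  prog2 <- bilevel_program(prog$network, prog$outer_objective,
                           candidates = character(0), max_deletions = 3)
  expect_length(brute_force_optknock(prog2), 1)
})

test_that("the strong-duality MILP matches the brute-force oracle", {
  for (s in c(31, 32, 33, 34, 35, 36)) {
    prog <- make_program(seed = s, K = 1 + (s %% 3), branches = 2 + (s %% 3))
    bf <- brute_force_optknock(prog)
    mk <- solve_optknock(prog)
    expect_equal(mk[[1]]$outer_value, bf[[1]]$outer_value, tolerance = 1e-5)
    # viability at every reported design
    floor_val <- prog$min_growth_fraction * prog$wild_type_inner
    for (d in list(bf[[1]], mk[[1]])) {
      expect_gte(d$inner_value, floor_val - 1e-6)
    }
  }
})

test_that("reported designs carry a tight inner primal/dual certificate", {
  prog <- make_program(seed = 41, K = 2)
  mk <- solve_optknock(prog, enumerate = 3)
  for (d in mk) {
    inner <- solve_fba(suppressWarnings(delete_genes(prog$network, d$deleted_genes)),
                       prog$inner_objective)
    expect_equal(d$inner_value, inner$objective_value, tolerance = 1e-6)
  }
})

test_that("best outer value is monotone in the deletion budget", {
  vals <- vapply(0:3, function(K) {
    prog <- make_program(seed = 22, K = K)
    solve_optknock(prog)[[1]]$outer_value
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-9))
})

test_that("a full viability floor admits only the wild type", {
  # a chain network where every candidate deletion kills growth outright:
  # with f = 1 only the empty design survives the floor
  net <- chain_network()
  outer <- objective_vector(c(R_AB = 1), "maximize")
  prog <- bilevel_program(net, outer, candidates = c("gT", "g1"),
                          max_deletions = 2, min_growth_fraction = 1.0)
  bf <- brute_force_optknock(prog)
  expect_length(bf, 1)
  expect_length(bf[[1]]$deleted_genes, 0)
  mk <- solve_optknock(prog)
  expect_length(mk[[1]]$deleted_genes, 0)

  # on the vesiculation toys, f = 1 admits exactly the designs that keep the
  # inner optimum at the wild-type value
  toy <- make_toy_network(seed = 23, plant_optimal_knockout = FALSE)
  gt <- toy$ground_truth
  prog2 <- bilevel_program(toy$network, gt$omv_objective,
                           candidates = gt$candidates,
                           max_deletions = 2, min_growth_fraction = 1.0)
  for (d in brute_force_optknock(prog2)) {
    expect_equal(d$inner_value, prog2$wild_type_inner, tolerance = 1e-6)
  }
})

test_that("integer-cut enumeration returns distinct ordered designs", {
  prog <- make_program(seed = 25, K = 2)
  mk <- solve_optknock(prog, enumerate = 4)
  keys <- vapply(mk, function(d) paste(d$deleted_genes, collapse = ";"),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
  outs <- vapply(mk, `[[`, numeric(1), "outer_value")
  expect_true(all(diff(outs) <= 1e-9))
})

test_that("filter_designs deduplicates, applies margins, excludes, decomposes", {
  prog <- make_program(seed = 26, K = 2)
  designs <- brute_force_optknock(prog)
  wt_outer <- omvflux:::evaluate_design(prog, character(0))$outer_value

  dup <- c(designs, designs[1])
  expect_length(filter_designs(dup, prog), length(designs))

  # margin 0 passes all feasible designs through
  expect_length(filter_designs(designs, prog, min_improvement = 0),
                length(designs))
  # a positive margin drops the wild type and everything not above it
  improved <- filter_designs(designs, prog, min_improvement = 1e-6)
  expect_true(all(vapply(improved, `[[`, numeric(1), "outer_value") > wt_outer))

  # exclusion list
  ex <- filter_designs(designs, prog, exclude_genes = "gbio1")
  expect_false(any(vapply(ex, function(d) "gbio1" %in% d$deleted_genes,
                          logical(1))))

  # decomposition re-evaluates each member gene as a singleton design
  multi <- Filter(function(d) length(d$deleted_genes) >= 2, designs)
  dec <- filter_designs(multi[1], prog, decompose_singletons = TRUE)
  singles <- Filter(function(d) length(d$deleted_genes) == 1, dec)
  expect_length(singles, length(multi[[1]]$deleted_genes))
  for (d in singles) {
    expect_equal(d$outer_value,
                 omvflux:::evaluate_design(prog, d$deleted_genes)$outer_value)
  }
})

test_that("design_report computes fold improvements over the wild type", {
  prog <- make_program(seed = 27, K = 1)
  rep <- design_report(solve_optknock(prog), prog)
  expect_true(all(c("deleted_genes", "outer_value", "inner_value",
                    "wild_type_outer", "fold_improvement") %in% names(rep)))
  expect_equal(rep$fold_improvement,
               rep$outer_value / rep$wild_type_outer)
})
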