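# Exhaustive subset enumeration, the independent oracle for the minimal-fix
# MILPs: all suppression (or addition) subsets up to a size cap, checked with
# plain growth calls.
oracle_min_suppressions <- function(net, mutant_genes, consistency_set,
                                    candidates, threshold = 0.01, max_size = 2) {
  valid <- list()
  for (k in 0:max_size) {
    for (sub in utils::combn(candidates, k, simplify = FALSE)) {
      net2 <- suppress_reactions(net, sub)
      if (growth_call(net2, mutant_genes, threshold)$grows) next
      ok <- all(vapply(consistency_set, function(g)
        growth_call(net2, g, threshold)$grows, logical(1)))
      if (ok) valid[[length(valid) + 1L]] <- sort(sub)
    }
    if (length(valid)) return(valid)  # minimum cardinality reached
  }
  valid
}

oracle_min_additions <- function(net, mutant_genes, universal, consistency_set,
                                 threshold = 0.01, max_size = 2) {
  ids <- universal$reactions$id
  valid <- list()
  for (k in 0:max_size) {
    for (sub in utils::combn(ids, k, simplify = FALSE)) {
      net2 <- omvflux:::merge_universal(net, universal, sub)
      if (!growth_call(net2, mutant_genes, threshold)$grows) next
      ok <- all(vapply(consistency_set, function(g)
        !growth_call(net2, g, threshold)$grows, logical(1)))
      if (ok) valid[[length(valid) + 1L]] <- sort(sub)
    }
    if (length(valid)) return(valid)
  }
  valid
}

fixture <- function(seed_net = 2, seed_panel = 7, ...) {
  toy <- make_toy_network(seed = seed_net, plant_optimal_knockout = FALSE)
  make_phenotype_panel(toy, seed = seed_panel, ...)
}

test_that("concordance classification covers all four classes", {
  pp <- fixture()
  rep <- classify_concordance(pp$network, pp$panel)
  expect_equal(sum(rep$counts), nrow(pp$panel))
  expect_equal(unname(rep$counts[c("GNG", "NGG")]), c(1, 1))
  expect_true(rep$counts["GG"] >= 1 && rep$counts["NGNG"] >= 1)
  # the planted mutants carry their intended classes
  expect_equal(unname(rep$per_mutant["gng_1"]), "GNG")
  expect_equal(unname(rep$per_mutant["ngg_1"]), "NGG")

  # empty panel: vacuous zero counts
  empty <- pp$panel[0, ]
  rep0 <- classify_concordance(pp$network, empty)
  expect_equal(unname(rep0$counts), rep(0L, 4))
})

test_that("resolve_gng matches exhaustive subset enumeration", {
  pp <- fixture()
  gng_genes <- omvflux:::parse_genes(
    pp$panel$genes[pp$panel$mutant_id == "gng_1"])
  gg <- list(character(0))
  fix <- resolve_gng(pp$network, gng_genes, gg)
  expect_equal(fix, pp$expected_fixes$suppressed)

  net_mut <- suppressWarnings(delete_genes(pp$network, gng_genes))
  cands <- pp$network$reactions$id[
    omvflux:::default_suppression_candidates(net_mut)]
  oracle <- oracle_min_suppressions(pp$network, gng_genes, gg, cands)
  expect_gt(length(oracle), 0)
  expect_length(fix, length(oracle[[1]]))
  expect_true(any(vapply(oracle, identical, logical(1), y = fix)))
})

test_that("resolve_gng rejects small fixes that kill consistency mutants", {
  # two parallel bypasses feed the inconsistent mutant: cutting the shared
  # carbon transporter is the unique size-1 fix, but it starves the protected
  # wild type, so under protection the larger two-bypass fix must win
  pp <- fixture(n_planted_gng = 2)
  gng_genes <- omvflux:::parse_genes(
    pp$panel$genes[pp$panel$mutant_id == "gng_1"])
  cands <- c("T_carbon", "BYPASS_1", "BYPASS_2")
  unprotected <- resolve_gng(pp$network, gng_genes, consistency_set = list(),
                             candidates = cands)
  expect_equal(unprotected, "T_carbon")
  protected <- resolve_gng(pp$network, gng_genes,
                           consistency_set = list(character(0)),
                           candidates = cands)
  expect_equal(protected, c("BYPASS_1", "BYPASS_2"))
  net2 <- suppress_reactions(pp$network, "T_carbon")
  expect_false(growth_call(net2, character(0))$grows)  # why T_carbon is invalid
})

test_that("resolve_gng on an already non-growing mutant is a no-op", {
  pp <- fixture()
  ngng_genes <- omvflux:::parse_genes(
    pp$panel$genes[pp$panel$mutant_id == "ngng_1"])
  expect_equal(resolve_gng(pp$network, ngng_genes, list(character(0))),
               character(0))
})

test_that("resolve_ngg matches enumeration and honors protections", {
  pp <- fixture()
  ngg_genes <- omvflux:::parse_genes(
    pp$panel$genes[pp$panel$mutant_id == "ngg_1"])
  ngng <- list(omvflux:::parse_genes(
    pp$panel$genes[pp$panel$mutant_id == "ngng_1"]))
  fix <- resolve_ngg(pp$network, ngg_genes, pp$universal, ngng)
  expect_equal(fix, pp$expected_fixes$added)

  oracle <- oracle_min_additions(pp$network, ngg_genes, pp$universal, ngng)
  expect_length(fix, length(oracle[[1]]))
  expect_true(any(vapply(oracle, identical, logical(1), y = fix)))

  # already growing mutant: nothing to add
  expect_equal(resolve_ngg(pp$network, "gdrain", pp$universal, ngng),
               character(0))
})

test_that("alternative equal-size additions are enumerable", {
  pp <- fixture()
  # duplicate the withheld producer under another id
  rl <- omvflux:::reactions_as_list(pp$universal)
  rl[[length(rl) + 1L]] <- list(id = "U_prec2_alt2",
                                stoichiometry = c(carbon_c = -1, prec2_c = 1),
                                lower_bound = 0, upper_bound = 1000)
  uni2 <- metabolic_network(pp$universal$metabolites, rl)
  alts <- resolve_ngg(pp$network, "gp2", uni2, enumerate_all = TRUE)
  expect_length(alts, 2)
  expect_setequal(vapply(alts, paste, character(1)),
                  c("U_prec2_alt", "U_prec2_alt2"))
})

test_that("reconcile recovers planted fixes and raises consistency by two", {
  pp <- fixture()
  rec <- reconcile(pp$network, pp$panel, pp$universal)
  expect_setequal(rec$removed_or_suppressed, pp$expected_fixes$suppressed)
  expect_setequal(rec$added, pp$expected_fixes$added)
  expect_equal(omvflux:::consistency_count(rec$report_after),
               omvflux:::consistency_count(rec$report_before) + 2)
  expect_equal(unname(rec$report_after$counts[c("GNG", "NGG")]), c(0L, 0L))
  expect_setequal(rec$resolved, c("gng_1", "ngg_1"))
  expect_length(rec$unresolved, 0)
  # the refined network still grows the wild type
  expect_true(growth_call(rec$network, character(0))$grows)
  # report writer
  p <- tempfile(fileext = ".csv")
  write_reconciliation_report(rec, p)
  expect_true(file.exists(p))
})

test_that("a fully consistent panel reconciles as a fixpoint", {
  pp <- fixture(n_planted_gng = 0, n_planted_ngg = 0)
  rec <- reconcile(pp$network, pp$panel, pp$universal)
  expect_length(rec$removed_or_suppressed, 0)
  expect_length(rec$added, 0)
  expect_equal(rec$report_after$counts, rec$report_before$counts)
})

test_that("contradictory mutants are reported unresolved, others still fixed", {
  pp <- fixture()
  # an impossible observation: the unmodified wild type observed as no-growth;
  # any suppression killing it would break the protected wild-type GG mutant
  contradiction <- data.frame(mutant_id = "impossible", genes = "",
                              observed_growth = FALSE)
  panel2 <- rbind(pp$panel, contradiction)
  rec <- reconcile(pp$network, panel2, pp$universal)
  expect_true("impossible" %in% rec$unresolved)
  expect_setequal(rec$resolved, c("gng_1", "ngg_1"))
})

test_that("reconciliation is deterministic for a fixed order", {
  pp <- fixture()
  r1 <- reconcile(pp$network, pp$panel, pp$universal, order = "gng_first")
  r2 <- reconcile(pp$network, pp$panel, pp$universal, order = "gng_first")
  expect_identical(r1$removed_or_suppressed, r2$removed_or_suppressed)
  expect_identical(r1$added, r2$added)
  expect_identical(r1$log, r2$log)
})
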