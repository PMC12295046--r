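test_that("network construction validates ids, bounds and GPR genes", {
  net <- chain_network()
  expect_s3_class(net, "metabolic_network")
  expect_equal(nrow(net$metabolites), 3)
  expect_equal(net$reactions$kind,
               c("exchange", "transport", "internal", "biomass"))
  expect_silent(validate_network(net))

  # dangling metabolite reference is named in the error
  expect_error(
    metabolic_network(
      data.frame(id = "A_c", name = "A", compartment = "c"),
      list(list(id = "R1", stoichiometry = c(A_c = -1, X = 1),
                lower_bound = 0, upper_bound = 1))),
    "X")
  # reversed bounds
  expect_error(
    metabolic_network(
      data.frame(id = "A_c", name = "A", compartment = "c"),
      list(list(id = "R1", stoichiometry = c(A_c = -1),
                lower_bound = 5, upper_bound = 1))),
    "R1")
  # empty stoichiometry
  expect_error(
    metabolic_network(
      data.frame(id = "A_c", name = "A", compartment = "c"),
      list(list(id = "R1", stoichiometry = numeric(0),
                lower_bound = 0, upper_bound = 1))),
    "empty stoichiometry")
})

test_that("GPR parsing and evaluation follow boolean semantics", {
  expect_false(evaluate_gpr("g1 and g2", "g1"))
  expect_true(evaluate_gpr("g1 or g2", "g1"))
  expect_true(evaluate_gpr("", "g1"))                      # empty rule
  expect_true(evaluate_gpr("g1 and (g2 or g3)", "g2"))
  expect_false(evaluate_gpr("g1 and (g2 or g3)", c("g2", "g3")))
  expect_false(evaluate_gpr("(g1 or g2) and (g3 or g4)", c("g1", "g2")))
  # operator spellings
  expect_false(evaluate_gpr("g1 & g2", "g2"))
  expect_true(evaluate_gpr("g1 | g2", "g2"))
  # malformed rules raise parse errors
  expect_error(parse_gpr("g1 and"), "malformed")
  expect_error(parse_gpr("(g1 or g2"), "malformed")
  expect_error(parse_gpr("g1 g2"), "malformed")
  # round trip through the deparser
  ast <- parse_gpr("g1 and (g2 or g3)")
  expect_equal(omvflux:::deparse_gpr(ast), "g1 and (g2 or g3)")
})

test_that("delete_genes zeroes bounds, warns on unknowns, composes as union", {
  net <- chain_network()
  ko <- delete_genes(net, c("g2", "g3"))
  i <- match("R_AB", ko$reactions$id)
  expect_equal(ko$reactions$lower_bound[i], 0)
  expect_equal(ko$reactions$upper_bound[i], 0)
  # original untouched, empty deletion is identity
  expect_equal(net$reactions$upper_bound[i], 5)
  expect_identical(delete_genes(net, character(0)), net)
  expect_warning(ko2 <- delete_genes(net, "gX"), "gX")
  expect_equal(ko2$reactions, net$reactions)

  # sequential deletion equals deletion of the union
  set.seed(11)
  for (i in 1:10) {
    a <- sample(net$genes, sample(0:2, 1))
    b <- sample(net$genes, sample(0:2, 1))
    seq_del <- delete_genes(delete_genes(net, a), b)
    unn_del <- delete_genes(net, union(a, b))
    expect_equal(seq_del$reactions, unn_del$reactions)
  }
})

test_that("apply_medium closes unlisted uptake, keeps secretion, idempotent", {
  net <- chain_network()
  m1 <- apply_medium(net, list(EX_A = c(-3, 1000)))
  expect_equal(m1$reactions$lower_bound[m1$reactions$id == "EX_A"], -3)
  # empty medium closes the system
  m0 <- apply_medium(net, stats::setNames(list(), character(0)))
  expect_equal(m0$reactions$lower_bound[m0$reactions$id == "EX_A"], 0)
  expect_equal(m0$reactions$upper_bound[m0$reactions$id == "EX_A"], 1000)
  expect_equal(solve_fba(m0)$objective_value, 0)
  # idempotence
  med <- data.frame(reaction_id = "EX_A", lower_bound = -2, upper_bound = 50)
  expect_equal(apply_medium(apply_medium(net, med), med)$reactions,
               apply_medium(net, med)$reactions)
  # non-exchange key rejected
  expect_error(apply_medium(net, list(R_AB = c(-1, 1))), "R_AB")
})

test_that("models round-trip losslessly through JSON and SBML", {
  toy <- make_toy_network(seed = 4, plant_optimal_knockout = FALSE)
  net <- toy$network
  for (fmt in c("json", "sbml")) {
    path <- tempfile(fileext = if (fmt == "json") ".json" else ".xml")
    write_model(net, path, fmt)
    back <- read_model(path, fmt)
    expect_equal(back$metabolites$id, net$metabolites$id)
    expect_equal(back$metabolites$compartment, net$metabolites$compartment)
    expect_equal(back$reactions$id, net$reactions$id)
    expect_equal(back$reactions$lower_bound, net$reactions$lower_bound)
    expect_equal(back$reactions$upper_bound, net$reactions$upper_bound)
    expect_equal(back$reactions$gpr, net$reactions$gpr)
    expect_equal(back$reactions$objective_coefficient,
                 net$reactions$objective_coefficient)
    expect_equal(as.matrix(back$stoichiometry), as.matrix(net$stoichiometry))
    expect_equal(back$genes, net$genes)
    expect_equal(back$biomass_reaction_id, net$biomass_reaction_id)
    # write(read(write(x))) is a fixpoint
    path2 <- tempfile(fileext = if (fmt == "json") ".json" else ".xml")
    write_model(back, path2, fmt)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("shipped example model loads and grows", {
  path <- system.file("extdata", "toy_vesiculation_network.json",
                      package = "omvflux")
  net <- read_model(path)
  expect_s3_class(net, "metabolic_network")
  expect_gt(solve_fba(net)$objective_value, 0)
})

test_that("medium CSV reader round-trips", {
  p <- tempfile(fileext = ".csv")
  med <- data.frame(reaction_id = "EX_A", lower_bound = -5, upper_bound = 100)
  utils::write.csv(med, p, row.names = FALSE)
  expect_equal(read_medium(p), med)
})
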