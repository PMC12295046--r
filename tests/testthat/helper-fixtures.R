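# Small networks used across the suite.

# Linear chain: EX_A (uptake u) -> A_c -> B_c -> sink, bottleneck on R_AB.
chain_network <- function(uptake = 10, bottleneck = 5) {
  metabolic_network(
    metabolites = data.frame(
      id = c("A_e", "A_c", "B_c"),
      name = c("A (extracellular)", "A (cytosol)", "B"),
      compartment = c("e", "c", "c")),
    reactions = list(
      list(id = "EX_A", stoichiometry = c(A_e = -1),
           lower_bound = -uptake, upper_bound = 1000),
      list(id = "T_A", stoichiometry = c(A_e = -1, A_c = 1),
           lower_bound = 0, upper_bound = 1000, gpr = "gT"),
      list(id = "R_AB", stoichiometry = c(A_c = -1, B_c = 1),
           lower_bound = 0, upper_bound = bottleneck, gpr = "g1 and (g2 or g3)"),
      list(id = "BIO", stoichiometry = c(B_c = -1),
           lower_bound = 0, upper_bound = 1000, objective_coefficient = 1)),
    biomass_reaction_id = "BIO")
}

# Two parallel routes with different yields: optimum = u * max yield.
branch_network <- function(uptake = 10) {
  metabolic_network(
    metabolites = data.frame(
      id = c("A_e", "A_c", "B_c"),
      name = c("A ext", "A cyt", "B"),
      compartment = c("e", "c", "c")),
    reactions = list(
      list(id = "EX_A", stoichiometry = c(A_e = -1),
           lower_bound = -uptake, upper_bound = 1000),
      list(id = "T_A", stoichiometry = c(A_e = -1, A_c = 1),
           lower_bound = 0, upper_bound = 1000),
      list(id = "R1", stoichiometry = c(A_c = -1, B_c = 1),
           lower_bound = 0, upper_bound = 1000, gpr = "gR1"),
      list(id = "R2", stoichiometry = c(A_c = -1, B_c = 2),
           lower_bound = 0, upper_bound = 1000, gpr = "gR2"),
      list(id = "BIO", stoichiometry = c(B_c = -1),
           lower_bound = 0, upper_bound = 1000, objective_coefficient = 1)),
    biomass_reaction_id = "BIO")
}

# A feature table built directly from a matrix, for the lipidomics tests.
tiny_feature_table <- function(X, roles, groups = NULL, mz = NULL, rt = NULL) {
  n_f <- nrow(X); n_s <- ncol(X)
  if (is.null(groups)) groups <- ifelse(roles == "study", "G1", NA_character_)
  features <- data.frame(
    feature_id = sprintf("F%02d", seq_len(n_f)),
    mz = if (is.null(mz)) 500 + seq_len(n_f) else mz,
    rt = if (is.null(rt)) seq_len(n_f) else rt)
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_s)),
    role = roles, group = groups,
    quantity = 1, sample_volume = 1)
  feature_table(features, samples, X)
}
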