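Package: omvflux
Title: Constraint-Based Strain Design and Assay Statistics for Outer
    Membrane Vesicle Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing hyper-vesiculating bacterial strains from
    genome-scale metabolic models and for analysing the accompanying wet-lab
    readouts. Provides stoichiometric network input/output (SBML Level 3 FBC
    and a documented JSON dialect), flux balance analysis with gene-knockout
    simulation, a membrane-material (phosphatidylethanolamine,
    phosphatidylglycerol, core-oligosaccharide lipid A) vesiculation
    objective, GrowMatch-style reconciliation of growth predictions against
    knockout phenotype panels, OptKnock bilevel knockout design via a
    strong-duality MILP reformulation with a brute-force oracle, UV-spectrum
    vesicle quantification with Warburg-Christian protein estimates and
    Sidak-corrected group comparisons, and a post-acquisition lipidomics
    pipeline (blank and QC coefficient-of-variation filtering, adduct
    annotation, lipid-class composition, PCA and PLS-DA with Q2 and
    CV-ANOVA). Seeded synthetic-data generators with planted ground truth
    make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    pracma,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
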