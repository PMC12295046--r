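---
title: "Methods: strain design and assay statistics for vesicle overproduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain design and assay statistics for vesicle overproduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omvflux)
```

`omvflux` models a strain-engineering campaign for bacterial outer membrane
vesicles (OMVs): design gene deletions on a metabolic network that raise the
synthesis and periplasmic delivery of membrane material, then analyse the
measurements such a campaign produces (UV-quantified vesicle recovery,
protein content, LC-MS lipidomics). This vignette documents the models, the
numerical choices, and the limits of what the package's synthetic studies
can show.

## Constraint-based core

A network is the stoichiometric matrix $S$ (metabolites $\times$ reactions),
flux bounds $lb \le v \le ub$ in mmol gDW$^{-1}$ h$^{-1}$, and boolean
gene-protein-reaction (GPR) rules. Flux balance analysis solves

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; lb \le v \le ub,$$

and a knockout sets the bounds of every reaction whose GPR evaluates false
to zero. Deletions accumulate on the network object, so deleting an isozyme
pair one gene at a time is equivalent to deleting the union at once. Growth
calls use a configurable threshold $\varepsilon$ (default $10^{-2}$
h$^{-1}$, a conventional binary-growth cutoff; the boundary is inclusive).
Two serialization formats round-trip the full model: SBML Level 3 with the
FBC package, and a versioned JSON dialect (`omvflux-network`, version 1)
that mirrors the same content and is easy to write by hand for small test
networks.

Degenerate alternate optima are a fact of FBA: the objective value is the
contract, individual fluxes are not, and all tests are written against
objective values or against properties that hold across the optimal face.

### The LP/MILP engine

No linear-programming package is assumed; the package carries a small dense
two-phase primal simplex plus depth-first branch-and-bound, sized for the
toy networks it targets (tens of reactions, at most a dozen binaries).
Three numerical choices matter and were each adopted after observing
concrete failures on degenerate FBA tableaus (every mass-balance right-hand
side is zero):

* reduced costs are recomputed from the tableau every iteration rather than
  updated incrementally (incremental updates drift over long degenerate
  runs);
* pivot elements must exceed $10^{-7}$, and ratio-test ties resolve to the
  largest pivot element; entering/leaving switch to Bland's smallest-index
  rule when the objective stalls, which guarantees termination;
* a marginally positive phase-1 optimum triggers one Bland-from-start retry
  before infeasibility is declared.

Optimality and feasibility tolerances are $10^{-9}$ (solver) and $10^{-6}$
(assertions), standard LP practice. All variable bounds are finite by
construction (the $\pm 1000$ convention), so unboundedness cannot arise in
package use.

## The vesiculation objective

Vesicles are built from outer-membrane material, so the design objective
rewards the synthesis of phosphatidylethanolamines (PE),
phosphatidylglycerols (PG) and the core oligosaccharide lipid A (COLIPA),
plus the translocation of any of these from cytosol to periplasm.
Membership is decided by configurable metabolite-id patterns (a BiGG-style
preset ships: `pe…`, `pg…`, `colipa` with compartment suffixes `_c`/`_p`):
synthesis classes collect reactions producing a matched species in the
cytosol, the translocation class collects reactions consuming a matched
species in the cytosol and producing one in the periplasm, and translocators
are not double-counted as synthesis. The biology does not dictate relative
class weights, so the default weighs the four classes equally and divides
each class weight by its size (a class's total pull is then independent of
how many reactions realize it); both choices are plain parameters. The
objective is a linear program objective, hence homogeneous of degree one in
the weights — doubling all weights doubles the optimum exactly, which the
suite asserts at $10^{-9}$.

A structural fact shapes everything downstream: on a *fixed* network,
deleting a gene only removes feasible fluxes, so the vesiculation LP optimum
can never increase. Knockouts help only through growth coupling — lowering
the biomass optimum frees substrate that the inner-optimal flux state then
routes to membrane material. This is why the bilevel formulation below is
the method, not a refinement of it.

## GrowMatch reconciliation

Predictions are scored against observed knockout growth as GG, NGNG, GNG or
NGG (predicted/observed growth in that order). The two inconsistency
classes are repaired by minimum-cardinality model edits:

* **GNG** (grows in silico, not in vivo): find the smallest reaction set
  whose suppression drives the mutant's biomass *optimum* below
  $\varepsilon$. "For every feasible flux" is a universally quantified
  constraint, so the MILP certifies it by LP duality: dual feasibility for
  the mutant's biomass LP plus the requirement that the dual objective —
  whose bound terms carry the suppression binaries, linearized exactly by
  big-M constraints — stays below $\varepsilon$ minus a small margin
  ($10^{-6}$). Exchanges and the biomass reaction are never suppression
  candidates (the medium and the biomass composition are not model errors).
* **NGG** (grows in vivo, not in silico): find the smallest set of
  universal-database reactions whose addition lifts the mutant above
  $\varepsilon$ (a primal certificate), while dual certificates keep every
  protected no-growth mutant below it.

Both MILPs protect the current consistency set, tie-break equal-cardinality
fixes lexicographically by reaction id (reproducibility), cap the fix size
(default 3), and post-verify their answer with fresh growth calls.
`reconcile()` walks the panel in deterministic order (GNG-first by
default), applies accepted fixes globally to one shared refined network —
matching the practice of maintaining a single curated model rather than
per-mutant variants — and accepts a fix only if the panel-wide consistency
count does not decrease. The suite checks `resolve_*` against exhaustive
subset enumeration on all fixtures.

## OptKnock

The bilevel program

$$\max_{y} \; c_{omv}^\top v^* \quad \text{where} \quad
v^* \in \arg\max \{ c_{bio}^\top v : S v = 0,\; lb \circ z(y) \le v \le ub \circ z(y) \}$$

over deletion binaries $y$ (at most $K$, default 5) is collapsed to one
MILP by strong duality of the inner LP: primal feasibility, dual
feasibility, and primal = dual objective are imposed together, with the
bilinear $\mu \cdot z$ bound products linearized exactly through big-M
constraints ($M = 1000$, bounding the toy networks' dual multipliers; a
post-solve certificate recomputes the inner optimum on the knocked-out
network and errors out above a $10^{-6}$ gap, so a binding $M$ cannot pass
silently). Reaction availability $z$ follows from the gene binaries through
linearized GPR logic (and $\to$ min, or $\to$ max node constraints), which
stays integral whenever $y$ is, so only $y$ is branched on. A viability
floor $c_{bio}^\top v \ge f \cdot \mu_{WT}$ excludes lethal designs;
$f = 0.1$ by default, a deliberately permissive reading of "viable
biomass production" that is a single parameter to tighten.

The formulation is optimistic: among inner-optimal flux states the one most
favourable to the outer objective counts. The brute-force oracle implements
the same convention explicitly — enumerate deletion subsets, solve the
inner LP, then maximize the outer objective with the inner objective pinned
at its optimum — and the headline property of the suite is oracle
equivalence on twenty randomized programs. Alternative optima are
enumerated by integer cuts; design post-processing deduplicates, applies an
improvement margin over the wild type, honors gene exclusion lists, and
optionally decomposes multi-gene designs into re-evaluated single
knockouts, the form in which designs usually reach the bench.

## Vesicle assays

Relative vesicle yield is the trapezoidal area under the 200–320 nm
absorbance spectrum on the recorded 2 nm grid (no smoothing — the curve is
the measurement); protein is the Warburg–Christian estimate
$1.55\,A_{280} - 0.76\,A_{260}$, floored at zero, with the classical
coefficients overridable. Both are normalized by the single joint divisor
mass $\times$ OD600; where a protocol normalizes sequentially per figure
the product is the same, so the joint divisor is adopted once and
documented. Group differences use one-way ANOVA followed by contrasts of
each strain against the reference on the pooled error term, Sidak-adjusted
($p_{adj} = 1 - (1-p)^m$ over the $m$ reference contrasts, $\alpha = 0.05$).
Under the null the Sidak family-wise error sits slightly below $\alpha$
because the contrasts share the reference arm (measured 0.036–0.046 over
500 simulated studies); per-contrast rates are $\approx \alpha/m$ by
construction.

## Lipidomics

The pipeline starts from an exported feature table (feature $\times$ sample
intensities with study / pooled-QC / solvent-blank roles); peak picking and
alignment are upstream instrument-software territory and out of scope.
Stages, in order: blank removal (mean blank intensity strictly above 0.1
$\times$ mean study intensity), the QC repeatability filter (sample CV
strictly above 20% across QC injections; zero-mean features removed under
their own logged reason), per-sample normalization by a named factor
(vesicle quantity, sample volume, or any sample-table column — protocols
name both, so the factor is an argument), and annotation against a lipid
reference table at 10 ppm under positive-mode adducts M+H (+1.007276),
M+NH4 (+18.033823) and M+Cl (+34.969402, $^{35}$Cl). All matches are
returned; class composition takes the first match per feature and logs
ambiguity. Filters only ever remove features and append to a provenance
log, so any reported composition is reproducible from the log.

Multivariate models use unit-variance scaling by default (the convention of
the commercial software this kind of analysis is usually run in; Pareto and
no scaling are options). PCA is fitted on study and QC samples together so
QC clustering — the stability readout of the platform — appears on the
score plot; its $Q^2$ is a naive projection cross-validation
(leave-one-out to $n = 20$, 7-fold beyond), adequate for the qualitative
use it serves and noted to be optimistic for large component counts.
PLS-DA is NIPALS PLS2 on one-hot labels; $Q^2 = 1 - PRESS/TSS$ from k-fold
cross-validation (default 7, venetian-blind assignment in sample order; the
fold scheme is an argument), and significance is the CV-ANOVA F-test
$F = ((TSS - PRESS)/A) / (PRESS/(N-1-A))$ on $(A,\, N-1-A)$ degrees of
freedom for $A$ components and $N$ samples. $Q^2 \le 0$ means the
cross-validated predictions are worse than the label mean — a "no model"
verdict, with $p$ clamped to 1 (the F statistic is negative there, so the
test could never reject anyway). A per-feature Welch-test screen with
Benjamini–Hochberg correction is reported alongside but carries no
headline claims.

## Synthetic studies: what they show and what they cannot

The generators are seeded, restore the caller's RNG state, and plant ground
truth that the corresponding stage must recover exactly:

* **Toy networks** (< 25 reactions, so every MILP has a brute-force
  oracle): carbon uptake, gene-gated capacity-limited biomass routes
  (including isozyme `or` and complex `and` rules), PE/PG/COLIPA branches
  with translocators, and decoy drains. Capacities keep total route
  capacity below uptake so leftover substrate exists; the planted optimal
  knockout is *certified* at generation time by the brute-force solver.
* **Phenotype panels**: GNG mutants are created by adding removable ungated
  bypass reactions, NGG mutants by withholding a required producer into the
  universal database (with decoy universal reactions); consistent GG and
  NGNG mutants anchor the protections. Planted mutants delete the full gene
  closure of the biomass routes, so the planted fix is genuinely minimal.
* **Assay studies**: smooth nonnegative spectra whose AUC equals
  base $\times$ fold $\times$ mass $\times$ OD600 $\times (1 + \epsilon)$,
  with band weights solved so the Warburg–Christian readout tracks a
  planted protein fold; at zero noise the normalized ratios equal the folds
  exactly. Defaults mirror a five-strain design (folds 1, 7, 10, 7, 7;
  protein up threefold in three mutants; $n = 3$; CV 0.15).
* **Feature tables**: log-normal intensities; QC columns built from a fixed
  zero-mean unit-sd pattern scaled by the planted CV, so the sample CV is
  exact and the CV filter's planted outcome is unambiguous (the planted
  high-CV and blank sets are kept disjoint for the same reason); feature
  m/z synthesized from the reference masses at 0 ppm under random adducts;
  empty `group_effects` yields the no-structure null. The "strongly
  separated" condition used for the positive PLS-DA check is 3 groups
  $\times$ 4 replicates with 10$\times$ / 0.1$\times$ effects on half the
  features at log-noise 0.2 — effect far above noise; a subtler 5-group,
  $n=3$ design with moderate effects lands in the grey zone where PLS-DA
  correctly returns a weak model.

What passing these tests shows: the algorithms are implemented correctly
against independent oracles and closed forms, the statistics are calibrated
at their nominal levels, and the pipeline's qualitative behaviors (bilevel
gain over the fixed-LP bound, no-model verdicts on unstructured data) are
real properties of the methods, not artifacts. What they cannot show:
anything about genome-scale networks (solver scale, alternate-optima
structure, medium realism), real spectra (baselines, scattering), or real
LC-MS data (missingness, drift, correlated features). The toy problem sizes
in the suite — twenty bilevel programs with up to 8 candidate genes and
$K \le 3$, 500-seed assay calibration, 200-seed lipidomics nulls — were
chosen as the smallest designs that make the oracle comparisons exhaustive
and the Monte-Carlo rates stable to a few percent.

## Known limitations

* The simplex/branch-and-bound engine is for toy-scale problems; a
  genome-scale deployment would swap in an industrial solver behind the
  same `lp_solve`/`milp_solve` interface.
* OptKnock's big-M dual bound is fixed at 1000; networks with larger dual
  multipliers would need it raised (violations surface as hard duality-gap
  errors, never silent).
* PCA's cross-validated $Q^2$ uses naive projection and is optimistic as
  components approach the rank; PLS-DA's $Q^2$ uses the standard
  PRESS/TSS form rather than the sequential per-component product some
  commercial software reports — signs and "no model" verdicts agree, exact
  values can differ in the second decimal.
* First-match class assignment makes composition tables depend on reference
  ordering when annotations are ambiguous; ambiguity is logged.
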