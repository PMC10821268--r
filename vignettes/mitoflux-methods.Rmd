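---
title: "mitoflux: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitoflux: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoflux)
```

mitoflux implements the computational core of a systems-level analysis of
mitochondrial shutdown in cancer stem cells: a decomposable Gaussian
graphical model over the most variable genes with functional-node
activities, an expression-constrained flux balance analysis with
per-pathway activity deltas, a G-quadruplex scan of circular DNA mapped
onto mitochondrial genome features, and the closed-form bioenergetics
parameters of the Seahorse Mito Stress Test and indirect calorimetry.
This vignette explains each model, its assumptions, the tunable
parameters, and the design decisions taken where the procedures were
genuinely open.

## The decomposable graphical model

Expression values (FPKM-like abundances) are transformed as
`log2(x + 1)`; correlation on this scale is variance-stabilised for
abundance data, which is why all likelihood computations use it. After
restricting to the `top_k` most variable genes (default 2,000, the usual
choice for transcriptome-wide network inference; the synthetic analyses
here use all simulated genes), the model is built in two stages:

1. **Maximum-likelihood spanning tree.** For Gaussian data the spanning
   tree with maximal likelihood is the maximum spanning tree under edge
   weight $-\tfrac12\log(1-r_{uv}^2)$, where $r_{uv}$ is the Pearson
   correlation. Because this weight is a monotone function of $|r|$, the
   same tree maximises total $|r|$; the package's test suite checks that
   equivalence. Ties are broken lexicographically by gene-id pair, so
   the tree is deterministic.

2. **BIC forward selection.** Edges are added greedily, at each step the
   edge with the largest reduction in
   $\mathrm{BIC} = -2\ell + \mathrm{df}\log n$, restricted to edges
   whose addition preserves decomposability (chordality); the loop stops
   at a local BIC minimum. For a decomposable graph, the maximised
   log-likelihood factorises over the cliques $C$ and separators $S$ of
   a junction tree, $\ell = \sum_C \ell_C - \sum_S \ell_S$, with
   $\ell_A$ the saturated Gaussian log-likelihood of the margin $A$ at
   the MLE covariance (denominator $n$).

Two implementation facts make stage 2 exact and fast:

* A non-edge $(u, v)$ of a chordal graph is *addable* iff $u$ and $v$
  have a unique minimal separator — equivalently, the minimal separator
  closest to $u$ equals the one closest to $v$, each computable from one
  component decomposition. The acceptance suite verifies this
  characterisation against brute-force chordality testing of every
  non-edge on every connected chordal graph with up to six vertices.
* Adding an addable edge changes the junction tree only locally: the new
  clique is $S \cup \{u, v\}$, so the likelihood gain is the closed form
  $-\tfrac n2 \log(1 - \rho_{uv\cdot S}^2)$ with $\rho_{uv\cdot S}$ the
  partial correlation given $S$. Gains are cached by $(u, v, S)$ across
  iterations, and the final incremental BIC is re-checked against a full
  recomputation (the run aborts on disagreement).

**Degrees of freedom.** `df = 2p + |E|` (a mean and a variance per gene,
one free parameter per edge). The reference implementation this mirrors
does not document its df convention; only BIC *differences* along the
greedy path matter, and those are invariant to the per-vertex constant.

**Degenerate inputs.** Constant genes make the correlation undefined;
the tree and scoring operations refuse them by name, and the pipeline
wrapper `ggm_network()` drops them with a warning beforehand. Singular
clique covariances (possible when a clique grows beyond $n$) abort with
the clique named.

**Branches and functional nodes.** The analysis that inspired this
package reports functional "branches" of the network without giving the
extraction rule. mitoflux uses divisive edge-betweenness community
detection with the cut at maximum modularity, then merges communities
smaller than `min_branch` into their best-connected neighbour — a
deterministic, standard choice, flagged here as a substitute for an
unspecified original. Node labels come from a built-in one-sided
hypergeometric test against user-supplied gene sets (GMT), adjusted by
Benjamini–Hochberg across the collection; this replaces a web-based
enrichment service so that runs are reproducible offline.

Node *activity* is the arithmetic mean of the node's gene expression
values per sample (raw scale, as activities are meant to be read in
expression units), and groups are compared per node with the
tie-corrected Kruskal–Wallis test.

## Expression-constrained flux balance analysis

A metabolic model is a stoichiometric matrix $S$ with reaction bounds,
boolean gene–protein–reaction (GPR) rules and subsystem (pathway)
labels. The expression constraint works per sample:

1. **GPR resolution.** `or` is the sum of its children (isoenzymes add
   capacity), `and` the minimum (complex subunits are limiting). The
   parser gives `and` precedence over `or` and flattens operator chains.
   A missing gene contributes the identity of its parent operator (0
   under `or`; ignored under `and` when a sibling resolves); a rule with
   no resolvable leaf scores "absent" and leaves the reaction at its
   default bounds. A strict mode (`missing = "error"`) is available.
2. **Max–min normalisation** of the resolved scores to $[0, 1]$ across
   reactions within the sample. When all scores are equal the map is
   degenerate; every score then becomes 1 rather than 0 — uniform
   expression should not close the network.
3. **Bound injection (E-flux).** A reaction with score $s$ gets
   $ub \leftarrow s\,ub$ and, if reversible, $lb \leftarrow -s\,|lb|$.
4. **Biomass LP.** Flux through the biomass objective is maximised
   subject to $S v = 0$ and the bounds. Optimal solutions satisfy
   $\max_m |S v|_m \le 10^{-6}$; infeasibility and unboundedness are
   reported as an explicit status, never as silent zeros.

**Pathway activity and deltas.** The activity of a pathway is
$\sum_r |v_r|$ over its reactions. The absolute value avoids signed
cancellation between opposing reversible fluxes; `signed = TRUE`
restores the literal sum. Per condition, activities are averaged across
samples (one LP per sample by default; `per_sample = FALSE` averages
expression first), and each treated condition gets
$\Delta = \text{treated} - \text{control}$, so a pathway suppressed by
treatment reads negative.

**Non-uniqueness.** FBA optima are generally non-unique; reported
activities come from the solver's vertex, which is deterministic for a
fixed model, and a parsimonious mode (minimise $\sum_r |v_r|$ at the
optimum) is available when a canonical distribution is wanted.

**The LP solver.** The package ships a compact two-phase primal simplex
with Bland's anti-cycling rule for its bounded LPs (tolerance $10^{-9}$;
redundant equality rows are dropped in phase 1). The test suite
cross-checks it against an independent vertex-enumeration oracle on
random small networks and verifies that bound tightening never increases
the optimum. Problems in this package are desk-scale (tens of
reactions), for which a dense tableau is entirely adequate.

## G-quadruplex scanning of circular DNA

Per-base scores follow the run-capped G/C rule: each base in a run of
$n$ consecutive guanines scores $+\min(n, 4)$, cytosines score
$-\min(n, 4)$, A/T/N score 0 and N breaks runs. On circular sequences a
run may wrap the origin and is capped as one run. Windows of `window`
bases (default 25) slide with step 1; windows whose mean score has
absolute value $\ge$ `threshold` (default 1.2 — the conventional
operating point of this scoring scheme; both are exposed as parameters)
are merged when they overlap, separately per sign. The sign encodes the
strand: G-rich windows (+) form quadruplexes on the given strand, C-rich
windows (−) on the complement, so one signed scan covers both strands. A
hit's score is the mean of its merged windows' means (hence always
super-threshold); merged intervals that span the origin are reported
once with `end < start`. Refinement/trimming heuristics of the original
scanning tool are deliberately not reproduced; the merged-window extent
is the package's hit definition.

**Coordinates.** Everything is 1-based inclusive, matching conventional
mitochondrial genome positions; BED export converts to 0-based half-open
and splits wrapping hits. The length of a wrapping interval uses the
one-endpoint-exclusive convention $(L - \text{start}) + \text{end}$:
this is the convention under which the D-loop amplicon 16,067..644 on
the 16,569-bp circle measures 1,146 bp, whereas the fully inclusive
count would give 1,147. Non-wrapping intervals count fully inclusively.

**Annotation.** A hit takes the class of the first feature (in table
order) containing its midpoint; midpoint containment is unambiguous for
hits straddling feature boundaries. The bundled mitochondrial feature
table (rCRS numbering: 13 protein-coding genes, 2 rRNAs, 22 tRNAs) lists
the D-loop first so the control region wins where features overlap; its
D-loop row is the 16,067..644 interval used throughout this package
(the conventional control-region annotation is 16,024..576). The genome
*sequence* is not bundled — only coordinates are; the
`g4_benchmark_rcrs()` convenience runs the full scan once the user
supplies a FASTA of NC_012920.1. Summary fractions treat D-loop plus
unannotated positions as non-coding; rRNA/tRNA hits are counted in their
own classes and enter `fraction_noncoding` only through the complement
of protein-coding when reading the per-class table.

## Bioenergetics formulas

From an OCR trace with the canonical phase order baseline → oligomycin →
FCCP → rotenone/antimycin A:

* plateaus are the mean of the last 3 measurements of a phase (the usual
  Seahorse convention; the trace parser enforces ≥ 2 points per phase),
* maximal respiration is the *maximum* of the FCCP-phase points (FCCP
  titrations peak rather than plateau),
* non-mitochondrial OCR (the rotenone/antimycin plateau) is subtracted
  from basal and maximal by default (`raw = TRUE` skips it; whether
  published values are subtracted is often unstated),
* spare respiratory capacity `src = maximal - basal`,
  `atp_linked = basal_raw - oligomycin plateau`,
  `proton_leak = oligomycin plateau - non_mito`.

Two algebraic identities follow and are tested: `basal = atp_linked +
proton_leak`, and adding a constant to the whole trace leaves every
derived parameter unchanged. Indirect calorimetry uses
`RER = VCO2/VO2` and `EE = (3.185 + 1.232 RER) · VO2`.

## The synthetic-data generators

The generators exist so every stage is testable without downloads; their
defaults are the package's study conditions and are not adjusted per
analysis.

**Expression** (`simulate_expression()`): log-normal abundances on a
module-structured Gaussian latent. Genes in a module share a common
factor giving every within-module pair latent correlation
`within_module_correlation` (default 0.7); gene baselines are drawn once
from a log-normal centred at FPKM ≈ 20 with log-sd 1.25, so abundances
span the orders of magnitude typical of RNA-seq. Defaults: three arms
(Control, Treated, TreatedInactive) of 20 samples — a scale consistent
with a multi-tumour PDX design of 4–7 replicates per tumour — and 11
modules of 10 genes. The mtDNA-encoded block (default 10 genes,
`MT-G01`…) occupies the last module and is multiplied by
`mt_downregulation_factor` (default 0.5) in the Treated arm, so its
expectation is exactly that multiple of control; the TreatedInactive arm
is drawn from the control distribution, emulating an inactive analogue
that modulates no genes. What the generator does *not* emulate: read-level
sampling noise, library-size or batch effects, non-equicorrelated module
structure, and gene–gene correlation across modules. Passing tests
therefore show that the estimators recover the assumed structure, not
that real RNA-seq satisfies it. At these defaults the Kruskal–Wallis
detection of the mt node at factor 0.5 has moderate (roughly
three-in-four) power across seeds; the bundled checks run at fixed
seeds.

**Toy metabolic networks** (`simulate_toy_model()`): an uptake feeding a
linear OXPHOS-labelled chain into biomass, optionally a parallel
capacity-1 branch, and two decoupled anchor reactions whose rules (an
`and` over many genes, an `or` over many genes) pin the max–min
normalisation extremes so the OXPHOS scores land strictly inside
$[0, 1]$. Chain rules draw on the mt gene pool, so the expression
generator's planted down-regulation propagates to a negative OXPHOS
delta through the full E-flux pipeline. The analytic biomass optimum
(min of chain bounds, plus the branch capacity) is recorded as ground
truth.

**G4 sequences** (`simulate_g4_sequence()`): background sampled
uniformly with G/C runs capped at 2 (so default scanning yields no
spurious hits), planted canonical four-tract motifs `GGG N1–4 GGG N1–4
GGG N1–4 GGG` whose total length fits inside one scoring window,
guaranteeing a super-threshold window by construction; on circular
backbones with ≥ 2 motifs the first straddles the origin to exercise
wrap-around logic.

All randomness flows from a single integer seed through an isolated RNG
scope; identical seeds give byte-identical serialized outputs and no
global RNG state leaks.

## Numerical choices and problem sizes

* LP tolerances: $10^{-9}$ pivot/feasibility, mass-balance check
  $10^{-6}$; infinite bounds are capped internally and flagged as
  unbounded when attained.
* Correlation degeneracy: $1 - r^2$ is floored at $10^{-12}$ in tree
  weights.
* Ties: spanning-tree edges, greedy BIC deltas and enrichment labels all
  break lexicographically; community merging targets the lowest id.
* Test-suite problem sizes: exhaustive graph oracles run to 6 vertices
  (addability) and 5 vertices (likelihood); LP oracles to 6 reactions;
  scanner equivalence to 2 kb; the synthetic recovery analysis uses 110
  genes × 60 samples and 100 simulation seeds for the Monte-Carlo
  checks. These sizes keep the full suite at a few minutes on one core
  while covering every code path.

## Known limitations

* The branch-extraction rule is a community-detection substitute for an
  unspecified original; different rules can split ties differently.
* FBA pathway activities inherit the non-uniqueness of LP optima unless
  the parsimonious mode is used.
* The E-flux missing-gene policy and the degenerate-normalisation rule
  are documented conventions, not derivable facts; both are
  configurable.
* The G4 scanner reproduces run-capped window scoring and merging but
  not the original tool's post-hoc hit refinement, so exact hit counts
  on real genomes can differ by parameter set; the benchmark helper
  records the parameters used.
* SBML import/export is not provided; the native JSON model format (and
  its round-trip) is the supported interchange.
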