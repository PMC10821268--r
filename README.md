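# mitoflux

Computational toolkit for studying drug-induced mitochondrial shutdown in
cancer stem cells from bulk expression data. It is aimed at systems
biologists who want to reproduce, on their own or on synthetic data, four
analyses that together characterise an OXPHOS-targeting compound:

1. **Decomposable Gaussian graphical model** of the most variable genes:
   the maximum-likelihood spanning tree (maximum spanning tree under edge
   weight −½·log(1 − r²) on log2(FPKM + 1) correlations) is refined by
   greedy forward selection of chordality-preserving edges under
   BIC = −2ℓ + df·log n, where the decomposable likelihood factorises
   clique-wise, ℓ = Σ_C ℓ_C − Σ_S ℓ_S. Network branches become functional
   nodes; node activity is the mean expression of a node's genes, compared
   across treatment arms with the Kruskal–Wallis test.
2. **Expression-constrained flux balance analysis (E-flux)**: boolean
   gene–protein–reaction rules are resolved with OR = sum and AND = min,
   max–min normalised to [0, 1] and injected as reaction bounds; the
   biomass LP (max c'v s.t. S·v = 0, lb ≤ v ≤ ub) is solved per sample,
   pathway flux activity is Σ|v| per subsystem, and each treated condition
   gets a delta = treated − control per pathway.
3. **G-quadruplex scanning** of (circular) DNA with run-capped G/C scoring
   (±min(run, 4) per base), sliding 25-base windows at threshold 1.2,
   sign-resolved strands and wrap-around merging, plus midpoint annotation
   against a bundled human mitochondrial feature table (rCRS coordinates,
   13 protein-coding genes, D-loop 16,067..644).
4. **Bioenergetics formulas**: Mito Stress Test parameters (basal, maximal,
   SRC = maximal − basal, ATP-linked, proton leak, non-mitochondrial OCR)
   from phase-labelled OCR traces, and indirect-calorimetry
   RER = VCO2/VO2, EE = (3.185 + 1.232·RER)·VO2.

Seeded generators (`simulate_expression()`, `simulate_toy_model()`,
`simulate_g4_sequence()`) produce inputs with planted ground truth —
correlated gene modules with a down-regulated mtDNA-encoded block,
feasible toy metabolic networks with a known biomass optimum, and circular
sequences with planted four-tract G4 motifs — so the whole pipeline is
exercised without downloads.

## Worked example

```r
library(mitoflux)

sim <- simulate_expression(sim_config(seed = 11))
sim$expr
#> expr_set: 110 genes x 60 samples
#> groups: Control (20), Treated (20), TreatedInactive (20)

fit <- ggm_network(sim$expr, top_k = 110)
fit
#> ggm_fit: 110 genes, 196 edges, 11 functional nodes, BIC 17649.86
fit$comparison[1:3, ]
#>      node        H df           p
#> 1 node_01 9.352131  2 0.009315593
#> 2 node_02 0.352459  2 0.838425536
#> 3 node_03 8.117049  2 0.017274487
```

The model recovers the 11 planted modules as 11 functional nodes; node 1
is the mtDNA-encoded block, whose activity differs across the three arms
(Kruskal–Wallis p = 0.009) because the generator halves those genes in
the Treated arm.

```r
tm <- simulate_toy_model(seed = 11, n_linear_chain = 4, with_branch = TRUE)
res <- condition_pipeline(tm$model, sim$expr)
res$delta
#>            Treated TreatedInactive
#> Biomass    -0.0142         -0.0006
#> Exchange   -0.0142         -0.0006
#> Glycolysis -0.0011          0.0060
#> Other       0.0000          0.0000
#> OXPHOS     -0.0392         -0.0199
```

The OXPHOS chain, whose GPRs draw on the down-regulated mt genes, loses
flux under treatment (delta −0.039), while the inactive-analogue arm stays
near zero — the E-flux signature of selective OXPHOS suppression.

```r
sq <- simulate_g4_sequence(seed = 11, length = 5000, circular = TRUE, n_planted = 3)
call_hits(sq$seq)
#>   start  end strand    score
#> 1   381  415      + 1.458182
#> 2  4717 4750      + 1.432000
#> 3  4983   20      + 1.348000
circular_interval_length(16067, 644, 16569)
#> [1] 1146
```

All three planted motifs are recovered, including the one straddling the
circle's origin (start 4983 > end 20); the D-loop amplicon 16,067..644 on
the 16,569-bp mitochondrial circle measures 1,146 bp under the package's
wrap convention.

```r
tr <- ocr_trace(1:8, c(50, 50, 20, 20, 80, 80, 10, 10),
                rep(c("baseline", "oligomycin", "FCCP", "rot_AA"), each = 2))
mito_stress_params(tr)
#> mito_stress_params:
#>   basal          40.000
#>   maximal        70.000
#>   src            30.000
#>   atp_linked     30.000
#>   proton_leak    10.000
#>   non_mito       10.000
```

## Command line

A thin Rscript wrapper exposes the same pipeline from a shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "mitoflux.R", package = "mitoflux"))')" \
  simulate sequence --seed 3 --length 2000 --n-planted 2 --circular --out sim/
```

Subcommands: `simulate expression|model|sequence`, `ggm`, `fba`,
`g4scan`, `metrics mito-stress|calorimetry`. Each run writes a
`run_config.json` with the resolved parameters next to its outputs.

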