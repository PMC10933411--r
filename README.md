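# coevclade

Clade-wise coevolution integration for protein–protein interaction (PPI)
prediction in bacteria.

## What it does, and for whom

Interacting proteins accumulate compensatory mutations across their shared
interface, leaving a coevolution signal in paired multiple sequence
alignments (one ortholog pair per species and row). Direct coupling analysis
(DCA) fits a global Potts model to such an alignment and scores each
inter-protein residue pair by **direct information**

> DI(i,j) = Σ_{a,b} P_ij(a,b) · log [ P_ij(a,b) / (f_i(a) · f_j(b)) ],

where P_ij is the two-site model built from the mean-field couplings
e = −C⁻¹ (C the pseudocounted connected-correlation matrix) with marginals
matched to the empirical column frequencies f.

`coevclade` implements the clade-wise variant of this approach for
computational biologists studying bacterial interactomes: paired MSAs are
built and scored **independently per taxonomic clade** (default:
Proteobacteria, Firmicutes, Actinobacteria, Bacteroidota), the top 5
inter-protein DCA scores of each clade are concatenated into a 20-element
feature vector (missing clades imputed with −1), and a random forest —
trained on a benchmark balanced so that missing-data patterns carry no label
information — integrates them into one interaction probability. Protein-level
average product correction (APC) re-ranks predictions to down-weight
promiscuously coevolving proteins.

The package covers the full chain: alignment I/O and preprocessing filters,
ortholog resolution and pairing, redundancy reduction and the
Nf90 = N90/√L ≥ 16 depth filter, mean-field DCA (Rcpp-accelerated),
residue- and protein-level APC, feature assembly, grouped training and
evaluation — plus a Potts-model simulator that generates multi-clade
benchmarks with known ground truth, so everything is testable without
external databases.

## Worked example

Simulate one interacting protein pair across four clades, score it, and
build its feature vector:

```r
library(coevclade)

cfg <- generator_config()                     # 4 clades, planted couplings
cs  <- make_clade_set(cfg, pair_name = "P1", positive = TRUE, seed = 42)
tabs <- score_pair_by_clade(cs)               # pair -> filter -> DCA per clade
round(build_feature_vector(tabs), 3)
#> Proteobacteria_1 Proteobacteria_2 Proteobacteria_3 Proteobacteria_4
#>            0.942            0.764            0.743            0.719
#> Proteobacteria_5     Firmicutes_1     Firmicutes_2     Firmicutes_3
#>            0.705            0.739            0.736            0.730
#> ...
top_k(tabs$Proteobacteria, k = 2)[, c("pos_a", "pos_b", "raw_di")]
#>   pos_a pos_b    raw_di
#> 1     5     4 0.9420542
#> 2     2     1 0.7637061
```

The two top-ranked inter-protein positions, (5,4) and (2,1), are exactly the
two couplings the generator planted; their DI (~0.94, ~0.76) stands clear of
the background (~0.7 here, at this clade's sampled depth). A full
benchmark comparison — integrated forest vs a single-clade forest vs the
best-single-score baseline — runs with:

```r
res <- compare_integration(cfg, n_pos = 60, n_neg = 600, seed = 1)
c(res$auc_integrated, res$auc_single, res$auc_max_dca)
#> [1] 0.915 0.887 0.649
```

i.e. hold-out AUC-PR of 0.92 for the integrated forest against 0.89 / 0.65
for the baselines at prevalence 0.09 (one seed; the acceptance script
averages ten).

A command-line pipeline (`simulate`, `pair`, `dca`, `integrate`, `train`,
`predict`, `eval`) wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","coevclade.R",package="coevclade"))')" \
  simulate --config cfg.yaml --out simdir --seed 3
```

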