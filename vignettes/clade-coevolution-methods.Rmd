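---
title: "Clade-wise coevolution integration: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clade-wise coevolution integration: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(coevclade)
```

## The problem

Interacting proteins leave a statistical trace in sequence data: compensatory
mutations at an interface couple the amino-acid distributions of the two
partners across species. Direct coupling analysis (DCA) detects this by
fitting a global Potts model to a *paired* multiple sequence alignment — one
row per species, each row concatenating an ortholog of protein A with an
ortholog of protein B — and scoring inter-protein column pairs.

`coevclade` implements a clade-wise variant of this idea for bacterial
proteomes: instead of one large paired MSA spanning all available genomes,
independent paired MSAs are built per taxonomic clade (by default the four
well-covered phyla Proteobacteria, Firmicutes, Actinobacteria and
Bacteroidota). Each clade is scored separately with mean-field DCA; the top
five inter-protein scores per clade are concatenated into a 20-element
feature vector (missing clades imputed with −1) and integrated by a random
forest trained on a labelled interaction benchmark. A protein-level average
product correction (APC) can re-rank the final predictions to de-emphasize
promiscuously coevolving proteins.

Per-clade alignments are shallower but cleaner: sequences within a clade are
easier to align and to disambiguate from paralogs, and clade-wise scoring
yields four partially independent looks at the same putative interface. The
forest learns how to weigh deep, reliable clade blocks against shallow,
noisy ones — something a single maximum over all clades cannot do.

## Alignment preprocessing

Single-protein MSAs are consumed pre-aligned (aligned FASTA or Stockholm).
The preprocessing chain and its rules:

* **Query deduplication** (`deduplicate_queries`): proteins with identity
  strictly above 0.95 over at least 90% of the alignment span are redundant;
  the shorter one is dropped. Identity is matches over matched columns of an
  ends-free pairwise alignment; coverage is the aligned span over the longer
  sequence.
* **Seed tiers** (`select_seed_tier`): seed sequences are chosen by the most
  stringent of three coverage/identity tiers — a (0.8, 0.55), b (0.65, 0.4),
  c (0.5, 0.25) — that still selects more than min(2500, 25%) of the
  orthologous group.
* **Query-gap columns** (`drop_query_gap_columns`) are removed because they
  cannot be mapped back to query residues; every retained column keeps a
  1-based query position (`col_to_query`), used later to report interface
  positions in query coordinates.
* **Gap filters**: rows with *strictly more than* 50% gaps are removed
  (`filter_gappy_rows`); columns with *50% or more* gaps are removed
  (`filter_gappy_columns`). The asymmetry (strict vs inclusive) mirrors the
  asymmetric phrasing of the underlying protocol; both thresholds are
  arguments.
* **Pairing** (`concatenate_pair`): one row per species present in both
  MSAs with resolved orthologs on both sides (best bitscore, ties by
  lexicographic subject id; a seeded random policy is also provided). The
  query species row comes first.
* **Redundancy reduction** (`reduce_redundancy`): a greedy master-first scan
  (the query row is always kept) drops rows under 75% non-gap coverage and
  rows more than 90% identical to an already-kept row. Identity throughout
  the package is matches over all columns with gap–gap counted as a match —
  one definition, used consistently by the redundancy filter, the quality
  metrics and DCA reweighting.
* **Depth filter**: paired MSAs are kept when `Nf90 = N90 / sqrt(L) >= 16`
  (inclusive), `N90` being the post-reduction row count and `L` the paired
  length.
* **Self-homology guard** (`shared_sequence_check`): a pair is dropped when
  any row claims the identical protein as ortholog of both queries;
  predicted "interactions" between homologs are trivial.

Down-sampling (`downsample_rows`) removes rows uniformly at random without
realignment and never up-samples; uniformity keeps the expected identity
distribution of the alignment unchanged, which is how the stability of
quality metrics under down-sampling should be read (checked in the tests in
expectation over many seeds).

## Mean-field DCA

For an alignment over the 21-letter alphabet (20 amino acids plus gap;
unknown residues count as gaps):

1. **Reweighting**: row weight = 1 / (number of rows with identity ≥ θ,
   itself included); `m_eff` is the weight sum. Default θ = 0.8.
2. **Pseudocounted frequencies**: with relative pseudocount
   `lam_frac = 0.5`, i.e. λ = m_eff,
   `f1(i,a) = (λ/q + Σ_m w_m 1[A_i^m = a]) / (λ + m_eff)` and `f2`
   analogously with λ/q²; diagonal blocks of `f2` are set to
   `δ_ab f1(i,a)`.
3. **Couplings**: the connected-correlation matrix
   `C_ij(a,b) = f2 − f1 f1` over the first q−1 states (gap is the gauge
   state) is inverted; `e = −C⁻¹` off-diagonal blocks, symmetrized.
4. **Direct information**: per column pair, a two-site model
   `P(a,b) ∝ exp(e_ij(a,b)) μ_i(a) μ_j(b)` is fitted by iterative
   proportional scaling until its marginals match `f1` within `tol = 1e-4`
   (at most 500 iterations; non-converged pairs keep their best-effort value
   and are reported via a warning, because the downstream top-k extraction
   must be total). DI is the KL divergence from the product of marginals,
   in nats.

These constants (θ = 0.8, relative pseudocount 0.5, q = 21 with gap as a
state, gauge = last state, natural-log DI) are the conventional choices of
the mean-field DCA family and are all arguments of `mfdca()`. The hot loops
(the Gibbs sampler and the per-pair scaling) are compiled (Rcpp); the test
suite holds the entire production path to within 1e-8 of an independent
straight-loop reference implementation on small alignments.

Ranking uses raw DI by default; the residue-level APC-corrected matrix is
always computed and stored alongside, and protein-level APC re-ranking is
available via `apc_protein()`.

**APC definition.** `corrected(i,j) = S(i,j) − mean_i(S)·mean_j(S)/mean(S)`
with means over the full matrix. This makes the correction annihilate any
rank-one (product-structured) score matrix exactly — the null model APC
exists to remove; with off-diagonal-only means the cancellation would only
be approximate. For protein-level APC over a sparse pair set, absent pairs
contribute zeros to the means, matching an all-against-all matrix with
filtered-out entries.

## Integration

Per pair, present clades contribute their top-5 inter-protein raw DI scores
(descending; ties broken by ascending positions); each missing clade
contributes five −1 entries; blocks follow a fixed clade order. Twenty
features is the default cap — beyond that, additional top scores stop adding
information.

**Benchmarks** pair positives (interaction score strictly above 500) with
seed-deterministic random negative pairings among proteins that occur in at
least one positive, capping each protein's negative frequency (default 60)
and excluding self and self-homologous pairs.

**The missingness confound.** Interacting proteins tend to have similar
phylogenetic coverage, so the *pattern* of missing clades is itself
predictive. `balance_by_missingness` removes this shortcut by down-sampling
negatives within each stratum of the missing-clade count until every
stratum shares the ratio of the scarcest-negative stratum (positives are
never discarded; with non-divisible counts the ratio is matched up to
integer rounding). After balancing, a classifier that sees only
presence/absence (+1/−1) performs at chance — verified in the acceptance
suite.

**Training** (`train_rf`): 80/20 train/hold-out split and five-fold
cross-validation, both grouped by paralogous family so that no family
appears on both sides of any split — otherwise related pairs leak
information. Grid search (default: 100/500 trees × unlimited/10/20 depth)
maximizes mean CV AUC-PR; forests use balanced class weights. The defaults
are documented package choices, not reproductions of any external setup.

Baselines: `baseline_max_dca` ranks by the single highest DI across all
clades (no learning); a single-clade forest trains on the top-20 scores of
one clade. All evaluation is by area under the precision–recall curve with
right-continuous step integration (`pr_curve`).

The direct-contact rule used for structural benchmark labels
(`classify_contact`): a pair is *direct* when at least 10 inter-protein atom
pairs lie within 5 Å.

## The synthetic generator

`generator_config()` defines the study conditions under which every claim
is tested. Sequences are sampled from a pairwise Potts model by single-site
heat-bath Gibbs sampling (burn-in 1000 sweeps, one sample per 10 sweeps;
validated against exact enumeration on q = 3 toy systems):

* **Couplings** are "matching" (s·I over states) — planted inter-protein
  pairs (default two, strength 2) for interacting pairs, plus random
  intra-protein couplings (density 0.15, strength 1) for everyone.
* **Clades** share the coupling topology but have independent random fields
  (sd 0.5) and independent seeds: the same interface signal, disjoint
  sequence pools — the core assumption of clade-wise integration.
* **Depth** per (pair, clade) is drawn uniformly from 60–200 rows. The
  depth filter alone admits only alignments with roughly ≥ 56 rows at the
  default lengths, and real per-clade paired MSAs vary widely in depth;
  this heterogeneity is what makes learned integration outperform the raw
  maximum (with homogeneous, comfortably deep clades all integration
  strategies converge — the task stops resembling the hard regime the
  method exists for).
* **Protein lengths** default to 6+6; the planted-recovery experiments use
  10+10 (100 inter-protein pairs, so "top 5%" is a meaningful rank bound).
  Desk-scale lengths keep the (L·q)² inversion fast while preserving every
  statistical property of interest.
* **Missing clades**: each non-query clade is masked with probability 0.3;
  the query clade is always present (the query species defines the pair).
  With confounding strength ρ, positives are masked with probability
  0.3(1−ρ) and negatives with 0.3(1+ρ), reproducing the coverage confound.
* **Mediated chains** (`make_mediated_chain`): a joint model over proteins
  A, B, C with couplings only at the A–B and B–C interfaces — two contact
  pairs per interface routed through shared positions on B, strength 3.
  The apparent A–C coupling is second order (it scales roughly with the
  square of the interface coupling), so detectability at desk scale
  requires tight, multi-contact interfaces; that is also the biological
  picture of a bridged complex. Including B's columns roughly halves the
  apparent A–C DI and reshuffles the top-ranked A–C position set, while
  excluding B leaves the mediated signal intact — the transitivity
  behavior the acceptance suite checks.

What the generator does **not** emulate: phylogenetic tree structure within
a clade (star phylogeny only), indels (fixed-length alignments; gaps occur
only as a sampled 21st state), alignment errors, and paralog
misassignment. Passing tests therefore demonstrate correctness of the
machinery and the claimed statistical behaviors under the model's own
assumptions, not performance on real proteomes.

## Problem sizes and numerical choices

The shipped experiments use: 20 oracle alignments (L ≤ 6, ≤ 60 rows,
q ∈ {3, 21}); planted recovery at 200 rows × 10 seeds; integration
dominance on 60 positives + 600 negatives × 10 seeds; the confound analysis
on the same benchmark shape with mask-driven features; mediated chains at
300 rows × 10 seeds. These sizes are the package's chosen study conditions
for desk-scale validation.

Numerical notes: frequency normalization is checked to 1e-10; coupling
symmetry is enforced by averaging `e` with its transpose; a singular
correlation matrix (λ = 0) raises an error advising a larger pseudocount;
zero-mean score matrices skip APC with a warning; ties in rankings are
broken by ascending positions (scores) or pair id (predictions) so all
outputs are deterministic under their seeds.

## Limitations

Mean-field DCA trades accuracy for speed against pseudo-likelihood
variants; eukaryotes, operon/synteny-based interolog disambiguation and
structure-based evaluation are out of scope. AUC-PR values measured on the
synthetic benchmark characterize the implementation under the generator's
assumptions and should not be quoted as expected performance on real data.
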