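# dmsmap

Analysis toolkit for deep mutational scanning (DMS) screens based on pooled
functional complementation. Given a human gene that rescues growth of a
temperature-sensitive yeast mutant, a saturation-mutagenized clone library
is grown competitively at permissive and selective temperatures; `dmsmap`
turns the sequencing readout of that selection into a complete
variant-effect map — a score for **every** possible amino-acid substitution
— with a standard error attached to each score.

The package covers the full stack:

* **Mutagenesis design** — per-codon NNK replacement oligos with
  melting-temperature-balanced arms (`design_popcode_oligos()`,
  `predict_tm()`, `nnk_table()`).
* **BarSeq scoring** — barcode counting and cumulative growth-rate fitness
  estimation. Per replicate, with barcode count *c* and pool size *P\**:
  *r* = *c*/Σ*c*, *P* = *r·P\**, ρ = (*P*(*t<sub>k</sub>*)/*P*(*t<sub>k−1</sub>*))^(1/Δ*t*),
  φ = ρ/ρ\*, φ′ = φ(selective)/φ(permissive), *s* = Π<sub>k</sub> φ′, and
  *s*′ = (*s* − *s̃*<sub>null</sub>)/(*s̃*<sub>wt</sub> − *s̃*<sub>null</sub>),
  so null-like clones score 0 and wild-type-like clones 1. Replicate
  variances are shrunk by Bayesian regularization,
  σ² = (*v*₀σ₀² + (*n*−1)*s*²)/(*v*₀ + *n* − 2)
  (`barseq_fitness()`, `regularize_sd()`, `aggregate_single_mutants()`).
* **TileSeq scoring** — codon-change counting requiring agreement of both
  read mates (quadratic error suppression), depth normalization, wild-type
  control subtraction, enrichment ratio
  *E* = adj<sub>select</sub>/adj<sub>nonselect</sub>, and anchoring of the
  nonsense/synonymous medians to 0/1 (`call_codon_changes()`,
  `tileseq_score()`, `anchor_scores()`).
* **Scale joining** — a fitted monotone transform
  *f*(x) = *a·e^x* + *b·x* + *c* between platform scales with first-order
  error propagation, then confidence-weighted joining with weights
  *w*₀ = 1/(1 + se₀/se₁) (`fit_rescale()`, `join_scores()`).
* **Imputation & refinement** — a random forest (500 trees, mtry =
  ⌊features/3⌋) trained on measured scores over intrinsic, chemicophysical,
  conservation and structural features; 10-fold cross-validation RMSD as the
  prediction uncertainty; reciprocal folding of above-wild-type scores;
  confidence-weighted refinement (`impute_scores()`, `refine_map()`,
  `transform_hypercomplementers()`).
* **Clinical evaluation** — diploid (max-allele) scoring, Mann–Whitney U,
  precision-recall with low-score-positive orientation, and
  reference-bracketed variant classification (`mann_whitney_u()`,
  `precision_recall()`, `classify_by_references()`).
* **Simulation** — a generator for ORFs, clone libraries, growth dynamics,
  counts and reads with known ground truth for every stage
  (`simulate_library()`, `simulate_barseq()`, `simulate_tileseq()`).

## Worked example

Simulate a small BarSeq screen (30-residue protein, 1,500 variant clones,
25 null + 25 wild-type controls, 5 timepoints × 2 temperatures × 3
replicates at 5×10⁵ reads per sample), score it, and aggregate single-mutant
clones into per-variant scores:

```r
library(dmsmap)
cfg <- sim_config(L = 30, n_clones = 1500, n_null = 25, n_wt = 25,
                  barseq_depth = 5e5, seed = 42)
sim    <- simulate_library(cfg, mode = "barseq")
counts <- simulate_barseq(cfg, sim$library)
fit    <- barseq_fitness(counts, sim$library)
agg    <- aggregate_single_mutants(fit, sim$library)
head(agg, 5)
#>   position wt_aa mut_aa    score      se df n_clones
#> 1        2     A      C  0.03204 0.01141  3        1
#> 2        2     A      F  0.95267 0.01654  3        1
#> 3        2     A      I  0.04693 0.00786 12        4
#> 4        2     A      L  0.97192 0.00957  6        2
#> 5        2     A      N -0.00251 0.01245  3        1
```

Scores near 0 are null-like (damaging), scores near 1 wild-type-like;
`se` is the regularized standard error and `n_clones` the number of
biological replicates (clones) behind each variant. Against the simulator's
ground truth these clone scores correlate at Pearson r = 0.998.

On the bundled clinical example table of calmodulin variants of uncertain
significance, variants from cardiac-indication tests score lower than
non-cardiac ones:

```r
tab <- read_clinical_table(system.file("extdata", "calm1_clinical_vus.tsv",
                                       package = "dmsmap"))
mann_whitney_u(tab$score[tab$indication == "Cardio"],
               tab$score[tab$indication == "Non-Cardio"])
#> U = 24.5 (of 25 possible pairs), p = 0.016 (two-sided)
```

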