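---
title: "Building complete variant-effect maps from pooled complementation screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building complete variant-effect maps from pooled complementation screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Most missense variants observed in clinical sequencing cannot be interpreted:
functional assays exist for few genes, and computational predictors lose
sensitivity at clinically useful precision. Deep mutational scanning (DMS)
inverts the usual workflow: instead of testing variants one at a time as they
present, a pooled selection experiment measures the functional impact of
(nearly) every possible amino-acid substitution of a protein in advance. When
the selection is a yeast functional-complementation assay — a human gene
rescuing growth of a temperature-sensitive yeast ortholog mutant at the
selective temperature — growth itself is the readout and scales to libraries
of 10^4^–10^5^ variant clones.

`dmsmap` implements the complete analysis stack for such screens: mutagenesis
design, two complementary readout pipelines (BarSeq and TileSeq), scale
calibration and joining, random-forest imputation and refinement, clinical
evaluation utilities, and a simulator that generates every input with known
ground truth.

# Mutagenesis design

Saturation mutagenesis replaces each codon with the degenerate codon NNK
(any base at positions 1–2, G or T at position 3). The 32 NNK codons encode
all 20 amino acids but only one stop (TAG), which balances coverage against
premature truncation. `design_popcode_oligos()` emits one mutagenic oligo
per codon — the NNK codon flanked by two wild-type arms. Arms grow outward
one nucleotide at a time (left arm first on ties) until a nearest-neighbor
melting-temperature target is met, bounded by `arm_min`/`arm_max`, so that
hybridization, and hence mutation rate, is as even as possible along the
ORF.

The melting-temperature model is the unified nearest-neighbor
thermodynamic parameter set with an entropic salt correction (default 50 mM
monovalent cation, 50 nM oligo). The design contract only requires a model
monotone in length and GC content; the parameter set is configuration, not
contract, and `predict_tm()` is verified in the tests against a second,
independent transcription of the same table. Arms for codons near the ORF
ends may extend into constant amplicon flanks supplied by the caller; the
initiator ATG and the stop codon are not targeted by default.

# BarSeq scoring

In DMS-BarSeq every clone carries a unique plasmid barcode; pooled cultures
grow at a permissive and a selective temperature and barcodes are counted at
successive timepoints (default 0, 6, 12, 24, 48 h, three replicates). For
clone $i$, timepoint $t_k$ and temperature $\tau$, with barcode count
$c_{i,t_k}(\tau)$ and pool size $P_{*,t_k}(\tau)$ estimated from optical
density:

$$r = c/\textstyle\sum_j c_j,\qquad P = r\,P_*,\qquad
\rho = (P_{t_k}/P_{t_{k-1}})^{1/(t_k - t_{k-1})},\qquad
\varphi = \rho/\rho_*,$$

$$\varphi' = \varphi(\text{selective})/\varphi(\text{permissive}),\qquad
s = \prod_k \varphi',\qquad
s' = \frac{s - \tilde s_\text{null}}{\tilde s_\text{wt} - \tilde s_\text{null}}.$$

Three readings were genuinely open and are resolved as follows:

* **Pool growth rate** $\rho_*$ is computed from the pool totals,
  $(P_{*,t_k}/P_{*,t_{k-1}})^{1/\Delta t}$, which equals the count-weighted
  average clone rate.
* **Temperature normalization** divides by the *clone's own* permissive
  $\varphi$, correcting clone-specific growth artifacts that a pool-level
  denominator would leave in.
* **Control anchoring** uses medians across the null and wild-type control
  clones — robust against the occasional contaminated control — applied per
  replicate before averaging across replicates.

Zero counts would make the chain undefined, so a pseudocount of 0.5 is added
to every barcode count before computing $r$; the depth-invariance of $s'$
then holds up to terms of order pseudocount/count.

Replicate standard deviations from two or three replicates are unstable, so
they are shrunk toward a prior with the classical Bayesian variance
regularization
$\sigma^2 = (v_0\sigma_0^2 + (n-1)s^2)/(v_0 + n - 2)$.
The prior $\sigma_0$ comes from a linear regression of the empirical
standard deviation on log10 mean permissive count and the fitness score,
clamped at a small positive floor (0.001); the prior weight defaults to
$v_0 = 3$, matching the replicate count so prior and data carry comparable
weight. Clones with exactly one amino-acid change are biological replicates
of their variant and are combined by inverse-variance weighting
($w \propto 1/\mathrm{se}^2$).

# TileSeq scoring

DMS-TileSeq sequences short amplicon tiles (about 150 bp) covering the ORF
before and after selection. A codon change is counted only when **both
mates** of a read pair report the identical mutant codon; independent
base-calling errors at per-base rate $\varepsilon$ must coincide and are
suppressed to order $\varepsilon^2$, while true template changes (and PCR or
plasmid errors) survive. Read pairs are compared to the reference tile
ungapped at fixed amplicon coordinates; pairs with indels (length mismatch)
or more than 10% mismatches on either mate are discarded.

Counts are depth-normalized per codon; the wild-type control library
estimates the residual (template) error rate, which is subtracted from
non-selective and selective frequencies. The enrichment ratio
$E = \text{adj}_\text{select}/\text{adj}_\text{nonselect}$ is computed per
replicate pair on the linear scale, and scores are anchored affinely so the
nonsense median is 0 and the synonymous median is 1.

Numerical and policy choices:

* **Input filter.** A variant is removed when its *non-selective* frequency
  is within three control standard deviations of the wild-type control —
  such alleles are too close to the error floor for depletion to be
  detectable. The filter condition is configurable (`filter_on = "select"`)
  because the literal alternative reading — filtering on the selective
  condition — would discard genuinely null variants.
* **Control spread.** With two control replicates the empirical standard
  deviation is unstable, so it is floored at the Poisson expectation
  $\sqrt{\text{count}}/\text{depth}$; an all-zero control therefore never
  blocks a well-populated variant.
* **Floors.** Adjusted frequencies are floored at
  $\epsilon = 1/(10 \cdot \max \text{depth})$ on the selective side, keeping
  $E$ finite for fully depleted variants; variants whose adjusted
  non-selective frequency is not positive are flagged unscorable rather
  than scored from noise.
* Codon variants encoding the same amino-acid change are collapsed by
  inverse-variance weighting after anchoring.

# Calibration and joining

The two platforms measure the same biology on different scales. A monotone
transform $f(x) = a e^x + b x + c$ (constrained $a \ge 0$, $b > 0$) is
fitted by least squares on shared variants. For fixed $a$ the problem is
linear in $(b, c)$, so the optimizer profiles $a$ by one-dimensional
minimization over the exact inner solution — more robust than a joint
3-parameter search and exact on clean data. Standard deviations transform by
the first-order factor $f'(x) = a e^x + b$.

Two measurements of one variant are then joined with weights inversely
proportional to their standard errors:

$$w_0 = \frac{1}{1 + \mathrm{se}_0/\mathrm{se}_1},\quad
\mu = w_0\mu_0 + w_1\mu_1,\quad
\sigma^2 = w_0(\sigma_0^2 + \mu_0^2) + w_1(\sigma_1^2 + \mu_1^2) - \mu^2,$$

with $\mathrm{se} = \sigma/\sqrt{df_0 + df_1}$. The $\sigma^2$ expression
can round below zero when the two means are nearly equal and the variances
tiny; it is then clamped at the within-component bound
$w_0\sigma_0^2 + w_1\sigma_1^2$ with a warning.

# Imputation and refinement

A random-forest regressor trained on the measured scores fills the
unmeasured cells of the map. Hyperparameters are fixed at the classical
defaults (500 trees, `mtry` = ⌊features/3⌋, bootstrap with replacement,
node size 5, unlimited depth, one permutation per tree for importances).
Features:

* **Intrinsic** — the inverse-variance ($1/\mathrm{se}^2$) weighted mean
  score of observed substitutions at the position; where BarSeq clone data
  exist, the weighted mean of multi-mutant clones containing the variant
  and a multiplicative-model estimate
  $\hat f_A = f_{AB}/f_B$ averaged over available double/single pairs.
* **Chemicophysical** — deltas (mutant − wild type) of residue mass, volume,
  Grantham polarity, formal charge at pH 7, and Kyte–Doolittle hydropathy;
  antisymmetric by construction. The scales ship as `aa_properties()`.
* **Conservation** — BLOSUM62 plus per-position conservation and predictor
  columns (AMAS, SIFT, PROVEAN) supplied as annotation tables; computing
  them is out of scope.
* **Structural** — secondary structure (one-hot H/E/C), solvent
  accessibility, interface burial, hydrogen-bond/salt-bridge flags, also
  supplied per position.

Missing feature values are filled with the training-column median and
flagged with a missingness indicator column, so absence itself is
learnable. Prediction error is estimated as the RMSD of 10-fold
cross-validation with folds assigned by a seeded uniform shuffle (no
stratification). Note that the position-mean feature includes the held-out
variant's own position neighbours, as it does at deployment time; the CV
error is an estimate of imputation error, not a leakage-free generalization
bound.

Hypercomplementing variants — scores above wild type in yeast — are
evolutionarily best modeled as deleterious in the native human context, so
`transform_hypercomplementers()` folds $s > 1$ to $1/s$ (idempotent,
mapping $(0,\infty)$ to $(0,1]$) before training; the untransformed map can
be kept alongside.

Refinement blends each measured score with its prediction via the same
confidence-weighted join, treating the prediction as a pseudo-measurement
with $\sigma = \mathrm{se} = $ CV RMSD and `df_virtual` degrees of freedom
(default 1: a prediction counts as a single pseudo-observation). Because the
blend is a convex combination, refinement can never move a score past the
prediction — it is deliberately conservative. Unmeasured variants receive
the prediction with provenance `"imputed"`.

# The simulator

`simulate_library()`, `simulate_barseq()` and `simulate_tileseq()` generate
the full study with known truth, emulating the screen's design: clones
average $\lambda = 2.1$ amino-acid changes (Poisson; the codon-change rate
is inflated to compensate synonymous NNK draws), mutant codons are NNK
draws, the BarSeq library keeps only clones with at least one amino-acid
change and adds barcoded null and wild-type controls, and clone fitness is
the product of its variants' true scores. True missense scores follow a
bimodal mixture: deleterious with probability 0.4, scores Beta(0.5, 5),
otherwise neutral Normal(1, 0.05) truncated at zero — values above 1 model
hypercomplementation. Synonymous truth is 1, nonsense 0. The mixture weight
and shapes reproduce the clear nonsense/synonymous separation that real
maps show; they are configurable.

Growth runs from `g_null` = 0.05 to `g_wt` = 0.5 doublings/hour at the
selective temperature (a healthy yeast doubling time of about 2 h, with a
leaky null floor); all clones grow at `g_wt` at the permissive temperature.
One modeling choice deserves emphasis: the cumulative BarSeq score
multiplies one hourly-rate ratio per scoring interval, so the quantity it
reconstructs is the growth *factor* $2^{Kg}$ ($K$ = number of intervals),
not the rate $g$. The simulator therefore maps fitness linearly onto that
factor, which makes the noiseless, infinite-depth pipeline recover clone
fitness exactly — the natural calibration for a score defined to be 0 at
null and 1 at wild type. Counts are multinomial at the configured depth
(default 10^6^ per BarSeq sample), and pool sizes carry lognormal noise
(sdlog 0.02) mimicking OD measurement error.

TileSeq counts are drawn binomially from exact per-codon template
frequencies under an explicit error model: per-mate base errors at rate
`base_error` (default 10^-3^) must hit both mates identically to produce a
call, while template errors at rate `template_error` (default 10^-5^,
modeling PCR/plasmid mutations) are shared by the mates and survive — which
is exactly why the wild-type control subtraction exists.
`simulate_tileseq_reads()` additionally writes literal paired FASTQ for
exercising the read-level caller.

What the simulator does **not** emulate: quality-score structure, adapter
read-through, indels, PCR duplicates, position-dependent coverage within a
tile, or epistasis beyond multiplicative fitness. Passing recovery tests
therefore demonstrates correctness of the scoring mathematics under the
stated error model, not robustness to every artifact of real sequencing.

# Problem sizes and verification

The test suite verifies each scoring operation against independent oracles
(spreadsheet-style evaluation of the equation chain, a second transcription
of the melting-temperature table, brute-force pair counting for the rank
statistic) and runs the pipelines end to end on simulated screens: BarSeq at
6,500 clones — the scale of an arrayed screen — with 30 samples at 10^6^
reads each, and TileSeq at 20,000 clones and 2×10^6^ pairs per tile over a
50-residue protein. At these sizes both pipelines recover true scores at
Pearson r > 0.95, anchoring is exact by construction, imputation
cross-validation RMSD matches an injected noise floor within ±10% on
feature-driven synthetic maps, and both-mate counting suppresses a 1%
base-calling error rate roughly 300-fold. `scripts/acceptance.R` recomputes
all of these from scratch under a caller-supplied seed.

# Known limitations

* The BarSeq pseudocount makes depth invariance approximate for very low
  counts; scoring is most reliable above ~10 reads per barcode per sample.
* The cross-platform transform family $ae^x + bx + c$ is monotone but
  rigid; severely non-linear scale differences would need a richer family.
* The rank statistic's p-value uses the normal approximation with tie and
  continuity corrections; for very small groups an exact test would differ.
* Annotation features are consumed per position, not per variant, so
  predictor scores that differ between substitutions at one position are
  averaged away unless provided as separate columns.
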