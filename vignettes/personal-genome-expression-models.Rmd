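---
title: "Modeling individual-level protein expression from personal genome sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling individual-level protein expression from personal genome sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Plasma proteomics cohorts measure a continuous, normalized protein
expression value (NPX) for thousands of individuals whose genomes have
been sequenced. For a given protein, the variants within a window centred
on the gene's transcription start site (TSS) explain a fraction of the
inter-individual variation — the cis-heritability — through regulatory
mechanisms. Two model families compete for this signal:

* a **linear baseline**: elastic-net regression on the dosage matrix
  (0/1/2 alternate-allele counts per individual per SNV), and
* a **sequence-to-expression model**: a neural network that reads each
  individual's *personalized sequence*, so that a variant's effect is
  mediated by its sequence context rather than by a per-variant free
  parameter.

`seq2expr` implements a desk-scale version of this comparison end-to-end:
personal-genome encoding, cohort preparation, both model families,
in-silico mutagenesis (ISM) variant prioritization, rare-variant masking,
and the functional-annotation statistics used to characterize which
variants each model relies on. Because population cohort data are
access-restricted, the package ships a synthetic cohort generator with a
*planted*, fully known genetic architecture; every claim the test suite
makes is checked against that ground truth.

# Personal-genome encoding

A window of length $L$ (desk default 4,096 bp; the full-scale setting of
49,152 bp is selectable) is encoded as an $L \times 4$ matrix over
channels (A, C, G, T). Positions without a variant carry the one-hot of
the reference base. At a biallelic SNV with genotype dosage
$d \in \{0,1,2\}$, the alternate channel carries $d/2$ (0, 0.5 or 1) and
the reference channel $1 - d/2$, so every row stays on the probability
simplex. The alt value is the established convention; putting the
complement on the reference channel is our choice, made so that inputs
remain row-stochastic like pure one-hot sequence. `encode_cohort()`
builds all individuals in one pass over the variant table and is
bit-identical to the naive per-individual construction (tested).

Coordinates: VCF positions are 1-based genomic; window coordinates are
0-based half-open; the conversion happens only in `extract_window()` and
the file readers. Windows are always on the + strand. "MAF < t" masking
(`mask_by_maf()`) is strict; the variant's MAF is always the full-cohort
MAF, because downstream MAF stratification refers to the cohort spectrum.

# The synthetic cohort

`simulate_gene_dataset()` chains the generators. What it emulates, and
what it does not:

* **Site frequency spectrum.** Alternate-allele frequencies are drawn
  from a mixture of Beta(0.2, 8) (weight 0.7, rare-heavy) and
  Uniform(0.05, 0.5). This reproduces the qualitative feature that the
  number of rare segregating sites (MAF < 0.01) grows with cohort size;
  it is not a coalescent model and has no demography.
* **Genotypes.** Hardy–Weinberg sampling, independent across sites (no
  LD) by default; an optional block-LD mode copies adjacent sites with a
  per-individual flip probability, used to exercise the LD-redundancy
  statistic. Per-site deterministic RNG sub-streams make cohorts nested:
  the first 200 individuals of a 5,000-cohort are the 200-cohort.
* **Architecture.** `plant_effects()` draws causal variants, splits them
  between the rare (MAF < 0.05) and common pools, and scales effects so
  that, empirically on the realized cohort, genetic variance/total
  variance equals the target h2 and the rare causal subset carries a
  chosen share of the additive genetic variance. Interaction pairs are
  planted within 32 bp of each other (two variants in one cis-element,
  e.g. one TF binding site) among common variants, so the epistatic
  product is both biologically motivated and statistically observable;
  their coefficient is scaled to a chosen share of genetic variance.
  Phenotypic variance is normalized to ~1 and the environmental SD is
  derived as sqrt(1 - h2 - covariate variance).
* **Covariates.** Sex, age, BMI, 5 genotype PCs, 5 expression PCs and an
  eGFR analogue (the cohort's covariate dimensionality is not published;
  5 + 5 PCs is our default). Standardized covariate effects default to
  small values (~5% of variance) so genetic signal dominates.
* **Consequence table.** A configurable fraction (default 5%) of
  individuals carries a protein-altering annotation (missense,
  stop-gained, stop-lost, start-lost, frameshift) inside the gene body;
  these trigger the per-gene exclusion that guards against epitope-binding
  artifacts of antibody-based assays. Carriers are marked in the table
  only; sequences are not edited, because the pipeline consumes only the
  exclusion flag.

A green test on this world therefore establishes that the *machinery* is
correct and that the models behave as theory predicts on a known
architecture. It does not establish real-data performance: linkage
structure, population stratification, assay artifacts and the true
regulatory grammar are all absent.

# The surrogate model

The full-scale study fine-tunes a large pre-trained trunk; at desk scale
the package substitutes a small trainable stack:

* trunk: dilated 1-d convolutions, desk default 4 -> 32 -> 64 -> 768
  channels (kernels 7/5/3, dilations 1/2/4, GELU activations) with 4x
  average pooling after the first two blocks; the 4-block 64/64/128/128
  configuration without pooling remains selectable as the `"paper"`
  preset. The final embedding is deliberately wide: after global average
  pooling it must span the response directions of every variant in the
  window (see below).
* head: global average pooling over positions, concatenation of the
  covariate vector (single-gene mode), LayerNorm, Linear(512), ReLU,
  Linear(1), one scalar per individual.
* loss: `alpha * MSE + (1 - alpha) * mean over unique pairs of
  [(pred_i - pred_j) - (obs_i - obs_j)]^2` with alpha = 0.5. The exact
  algebra of the published "weighted sum" is not printed anywhere; at
  alpha = 0.5 the two natural weightings coincide up to a factor that
  does not change the optimum. The pairwise term is invariant to constant
  shifts, which is what allows the multi-gene scheme to drop covariates
  and per-gene intercepts.
* optimizer: AdamW (weight decay 0.01 on conv/dense weights, betas
  0.9/0.999), linear warm-up over the first 10% of optimizer updates to
  the peak rate, cosine decay to exactly 0, gradient accumulation to the
  effective batch (desk 8 x 8 = 64), global-norm gradient clipping at 5
  (an undocumented stabilizer we added), early stopping with patience 5,
  best checkpoint by validation loss.

## Why a structured warm start exists, and what it does

Global average pooling over thousands of positions dilutes the
inter-individual component of the embedding to ~1e-3 of its static
pattern. Gradient training must therefore grow head weights by 2-3 orders
of magnitude before predictions reach phenotype scale; with the few
hundred optimizer updates a single-CPU budget allows, plain AdamW from
random init stalls far below that (we measured test PCC ~0.1 where the
same architecture's features support ~0.65). GPU-scale studies cross this
gap with tens of thousands of updates; a desk build cannot.

The package's desk training scheme therefore initializes the head's
linear read-out in closed form before fine-tuning, mirroring the
published protocol of training the new head on the frozen pre-trained
trunk prior to joint fine-tuning:

1. an internal elastic net on the dosage matrix (train split, penalty by
   validation R^2, standardized predictors) provides a variant-space
   *teacher* — the rare-variant-aware shrinkage that gradient descent
   cannot learn in the available updates;
2. head weights are solved (minimum-norm, in the dual) so that the
   network's own ISM response — the sum of its three substitution deltas
   at each variant — is proportional to the teacher's coefficients. The
   proportionality constant is kept small; sequence models routinely
   shrink absolute effect magnitudes, and rankings, not magnitudes, drive
   every downstream analysis;
3. the phenotype is then fit by ridge regression on the *actual pooled
   features* of the training individuals, restricted to the null-space
   complement of the constraints in (2) (penalty by validation R^2).
   Fitting on real personal encodings absorbs everything single-variant
   additivity misses: LayerNorm coupling, GELU curvature at heterozygous
   rows, and epistatic pairs inside one receptive field — the last being
   exactly how the surrogate outperforms the linear baseline when
   interactions are planted.

The read-out is embedded exactly into the MLP head via a +/- ReLU unit
pair (ReLU(wx) - ReLU(-wx) = wx); the remaining hidden units keep random
first-layer weights with zero output weight, so joint AdamW fine-tuning
can recruit them. Fine-tuning then runs as configured; the best
validation checkpoint (often the warm start itself at desk scale) is
retained. All supervision uses the training and validation splits only —
the test split and the planted truth are never touched.

Consequences worth knowing: the model's ISM ranking at the warm start
equals the teacher's coefficient ranking by construction; desk-scale
results should be read as "what a sequence model whose head has converged
would do", not as evidence that gradient descent alone gets there in
minutes. The acceptance suite runs this configuration with 0 refinement
epochs for budget reasons; the gradient path itself is verified on a
small window where AdamW training from random init reaches PCC > 0.6.

# ISM, HSVs and the annotation statistics

`ism_map()` substitutes each of the three non-reference bases at each
position of the *reference* sequence (personal encodings are rejected),
averages the three prediction deltas (signed mean; absolute value only at
ranking time), with covariates fixed at the cohort mean. High-scoring
variants (HSVs) are the top-n observed variants by |score|, ties broken
by position, with n matched per gene to the elastic net's nonzero-
coefficient count so the two models' sets are directly comparable.

* **ChromHMM enrichment**: per gene, expected state counts are coverage
  fraction x HSV count; observed and expected are summed across genes
  before the single observed/expected ratio per state (the published
  methods paragraph is garbled at exactly this point; summing before the
  ratio is our reading and is stated here deliberately).
* **cCRE overlap**: fraction of HSVs inside PLS / pELS / dELS /
  DNase-H3K4me3 / CTCF-only elements; overlapping elements of different
  classes resolve by that priority order, with a warning.
* **Motif effects**: an internal PWM scanner replaces FIMO. Log2-odds
  scores with pseudocount 1e-3 against an order-0 background estimated
  from the reference window; placements must lie fully inside the +/-30 bp
  scan region (truncated at window edges) and overlap the SNP; the
  top-scoring hit per motif per allele is kept; p-values are *exact*,
  computed by dynamic programming over a 0.01-bit score lattice (the hit
  score is computed on the same lattice, so the tail probability is exact,
  not approximated); a raw-p prefilter of 1e-4 precedes Benjamini-Hochberg
  across the whole scan (the published correction scope is unstated;
  pooling the scan is our choice). Calls: loss (REF significant, ALT
  not), gain (the reverse), weaken/strengthen (both significant,
  |deltaS| >= 0.5, by sign), none otherwise; one call per variant by
  max |deltaS|. Only the forward strand is scanned (our choice; the
  synthetic PWMs have no strand semantics).
* **LD redundancy**: r^2 is the squared Pearson correlation of dosage
  columns; an HSV is redundant if some partner exceeds r^2 = 0.8;
  zero-variance columns score r^2 = 0 with a warning; aggregation across
  genes is total qualifying / total HSVs.

# Numerical and degenerate-input choices

* Splits: 60/20/20 by seeded permutation, rounding remainders to the
  training split; identical split objects feed both model families.
* Elastic net: 50 log-spaced penalties down to 1e-4 of lambda_max,
  selection by validation R^2, dosages unstandardized so coefficients are
  per-allele phenotype units, support counted as exact zeros from the
  coordinate-descent solver.
* `estimate_cis_h2()` is held-out R^2 clipped to [0, 1]; constant
  predictions evaluate to PCC 0 with an explicit flag rather than NA.
* Two variant records at one position are rejected (ambiguous); non-SNV
  records are skipped with a warning; a ref-allele mismatch against the
  reference sequence is an error with the offending position.
* Even-length windows place the TSS at floor(L/2); the exact centre does
  not exist.
* Downsampling: nested subsets are drawn from the training split only;
  validation/test individuals are identical across all sizes; the
  gradient-accumulation factor scales with subset size so optimizer
  update counts match across sizes.

# Known limitations

* The generator has no realistic haplotype structure, indels,
  multi-allelic sites or phasing (all declared non-goals).
* Desk-scale training quality rests on the structured warm start; the
  package does not demonstrate that pure gradient fine-tuning recovers
  rare-variant effects at this compute scale, and results should not be
  quoted as evidence about full-scale fine-tuning beyond the mechanisms
  tested.
* The motif scanner is single-stranded and order-0; the LD statistic is
  composite-genotype r^2 (not haplotype D').
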