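---
title: "Methods: host and microbiome signatures from fecal DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: host and microbiome signatures from fecal DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Stool contains a small and variable admixture of human DNA shed from the
gut — epithelium turning over, and, during inflammation, immune cells
(above all neutrophils) migrating into the lumen. `fecalsig` implements a
joint analysis of this host compartment and the surrounding microbiome in
inflammatory bowel disease (IBD) case–control cohorts: how much human DNA
is there, which cell types it comes from, how it relates to clinical
inflammation (fecal calprotectin, disease activity), and how microbial
community structure degrades alongside it. Because the patient-level data
such analyses run on are access-restricted, the package ships a
first-class synthetic cohort generator that reproduces the statistical
structure of the real cohorts; every stage of the pipeline is exercised
and tested against that generator's known ground truth.

# Methylation-based cell-of-origin deconvolution

## Model

DNA methylation is cell-type specific and survives in stool. The assay
amplifies a panel of short marker regions (at least five CpG sites within
a window of at least 150 bp) after bisulfite conversion; each marker is
unmethylated specifically in its target cell type. Bisulfite conversion
turns unmethylated C into T while methylated CpG C stays C, so at each
CpG the sequenced dinucleotide reads `TG` (unmethylated) or `CG`
(methylated).

The estimator is deliberately simple and molecule-based: the fraction of
a target cell type's DNA at a marker is the fraction of sequenced
molecules in which *all* CpG sites read unmethylated. Per cell type,
markers are averaged (unweighted by default; depth-weighted averaging is
available via `weight_by_depth`). Fractions of human DNA convert to
fractions of total fecal DNA by multiplying with the ddPCR-measured human
percentage.

## Read processing rules

* **Matching.** Reads are assigned to markers by ungapped, end-anchored
  percent identity in bisulfite space: reference C outside CpGs matches C
  or T, the CpG C matches C or T, all other positions must match
  literally. Amplicons are fixed-locus, so gapped alignment adds nothing;
  the ungapped comparison is deterministic and directly checkable against
  a brute-force oracle. Reads under 80% similarity to every marker are
  discarded; ties go to the first marker in panel order. Reads shorter
  than half of every reference are unmatchable.
* **Conversion QC.** Non-CpG cytosines should read T; a read in which
  more than 10% of them still read C failed conversion and is dropped.
  The threshold is a package default (exposed as
  `max_unconverted_frac`) — the assay description prescribes checking
  conversion but no number.
* **Ambiguity.** A CpG reading anything other than `CG`/`TG` (or lying
  beyond the read end) is ambiguous; molecules with any ambiguous site
  are excluded from both numerator and denominator. Counting them as
  methylated would bias fractions downward with sequencing error;
  exclusion is the conservative closure of the two-state readout.
* **Sample QC.** A sample needs at least 1000 retained reads
  (counted after the similarity filter; the protocol does not say which
  side of the filter its threshold refers to). Summed cell-type fractions
  outside 5–150% fail QC. Fractions are *not* renormalized to 100%: the
  existence of a QC window above 100% implies raw sums are retained, and
  the QC is applied before ddPCR normalization.

# ddPCR absolute quantification

Droplet digital PCR partitions the reaction (5 ng fecal DNA) into ~20,000
droplets. Copies per droplet are Poisson, so from the negative-droplet
fraction: $\lambda = -\ln(n_{neg}/n_{tot})$, copies per reaction
$= \lambda \, n_{tot}$. Each detected copy of the single-copy target
locus represents one genome equivalent, 3.3 pg of human DNA, giving

$$\text{human %} = \frac{\text{copies} \times 3.3\ \text{pg}}
 {\text{input ng} \times 1000\ \text{pg/ng}} \times 100.$$

Percentages above 100 are capped and flagged saturated, as is a reaction
with no negative droplets (copies unbounded). Droplet volume is not
modelled — the percentage only needs copies per reaction. Fluorescence
thresholding happens upstream in instrument software; counts are inputs.

# Host-read fraction and taxonomic profiles

The metagenomic human-read percentage is `100 * human / total` reads per
sample; alignment and classification themselves are performed by
published tools at stated settings and are not re-implemented — counts
and MetaPhlAn-style species tables are ingested (or simulated). Analyses
are species-level: rows whose last rank token is `s__` without a strain
suffix.

The depth-control analysis subsamples every sample to a fixed non-human
read count (default 1,000,000) and recomputes richness. Species counts
are reconstructed as relative abundance × non-human reads (an
approximation — the classifier emits relative abundances, not counts),
multinomially resampled, and renormalized. Samples below the target depth
are dropped and reported. Presence is monotone in depth, so subsampling
can only lower a sample's species count; the question the control answers
is whether the Control-vs-IBD richness gap survives equalized depth.

# Microbiome ecology

* **Richness** is the species count: entries strictly above zero.
* **Shannon diversity** (natural log) is computed through
  `vegan::diversity()`.
* **Ordination** uses the robust Aitchison geometry: per sample, nonzero
  abundances are transformed to $\ln(x/g)$ with $g$ the geometric mean of
  that sample's nonzero values, zeros stay 0 (the matched-zero
  convention: a species absent from both samples contributes nothing to
  their distance). Principal components of the column-centered
  transformed matrix are the PCoA coordinates — Euclidean distances
  between coordinate rows reproduce the robust Aitchison distances
  exactly. Note that newer vegan releases default to *imputing* zeros by
  matrix completion inside `robust.aitchison`; that is a different
  estimator, and the package keeps the explicit zeros-stay-zero
  transform (the cross-check in the test suite runs vegan with
  `impute = FALSE`). Because the leading component's sign is arbitrary,
  correlations with PC1 are reported signed and in absolute value.
* **Six-category species classification.** The universe is every species
  with median relative abundance above zero in at least one study group.
  Four one-sided Mann–Whitney tests run per species against Control:
  loss (`less`) and expansion (`greater`), each for CD and UC. P-values
  are exact when both groups have at most 12 tie-free observations,
  normal-approximated with tie correction otherwise.
  Benjamini–Hochberg correction is applied separately within the loss
  family and within the expansion family, each family spanning all
  species × both group comparisons (per-column correction is available
  via `family_scope`). Significance in both CD and UC gives the `IBD_`
  prefix; in exactly one, that group's prefix; when loss and expansion
  both apply, the lower minimal adjusted p wins; otherwise `UNCHANGED`.
  The `IBD_` categories require significance in each subtype separately —
  no pooled IBD-vs-Control test is run, matching the pairwise form of the
  hypotheses.

# Clinical harmonization and inflammation metrics

Disease-activity scores arrive on four scales (pediatric pUCAI/pCDAI,
adult HBI/SCCAI). Each maps through a standard conversion table to
remission/mild/moderate/severe, then collapses to remission vs active.
The default cut points are the standard clinical ones and are
config-overridable; the pCDAI table in particular is documented as a
default, not asserted as any study's exact choice. IBD-unclassified
records are relabelled UC (switchable).

Fecal calprotectin saturates at 2100 µg/g; higher values are stored at
the cap, flagged, and excluded from calprotectin regressions (strict
inequality at the boundary). Treatment advancement encodes the therapy
ladder 0–4 (none; ASA/antibiotics/diet; steroids; immunomodulators;
immunosuppressants or biologics); concurrent therapies take the maximum
tier — that is what "advancement" means clinically, though the source
protocol is silent on multi-therapy records.

Two summary ratios condense the deconvolution: NLR = neutrophil / (B +
T) and NER = neutrophil / (small intestine + colon) DNA percentages,
numerator and denominator always on the same normalization level. A
pseudocount ε (default 0.01 percentage points) keeps ratios finite when
the denominator lineage is undetected; affected samples can be
identified by `epsilon = 0` raising an error. "Fraction of samples over
1% human DNA" uses strict inequality.

# Modelling

## Calprotectin mixed model

Fecal calprotectin is regressed on human reads percentage, an
active-disease indicator, treatment advancement and age, with a random
intercept per subject (longitudinal samples), by REML via `lmerTest`.
Capped records are excluded. A random factor with one observation per
level is uninformative; the fit falls back to fixed effects with a
warning. Both Nakagawa R² flavors are reported — marginal (fixed only)
and conditional (fixed + random) — because single published R² values of
such models rarely state their flavor; neither is asserted equal to any
external number. The neutrophil variant (neutrophil percentage of fecal
DNA as predictor, random intercepts for subject and integer-year age) is
available through the same interface by changing `fixed_terms` and
`random`.

## Boosted classifiers

Three tasks (Control vs IBD, CD vs UC, remission vs active) are learned
from species features — presence/absence or relative abundance — plus
optional species-count and human-reads-percentage blocks; age and sex are
never features. Hyperparameters are fixed (no search): 5-fold stratified
CV, 200 rounds, logistic objective, AUC metric, eta 0.05, gamma 1,
lambda 3, max depth 10, min child weight 1, subsample 0.8,
colsample_bytree 0.8.

Folds are assigned by a deterministic hash of sample identifiers,
stratified by label, making the fold structure reproducible and invariant
to row order. The reported CV AUC pools out-of-fold predictions from the
full 200-round run. The "best round" (maximum mean held-out AUC across
folds) is used only to refit the final model on all samples for feature
importance and external validation — scoring the pooled out-of-fold
predictions at that selected round would bias the AUC upward (measured at
about +0.07 on label-permuted data during development, which is why the
two roles are kept separate).

External validation reconciles feature spaces by species name: species
unseen in the validation cohort are imputed absent (0), extras dropped,
and an overlap below 50% raises a hard warning without aborting. Feature
importance reports Gain/Cover/Frequency and per-sample Shapley values on
the log-odds scale (additive to the margin prediction within 1e-6).

# The synthetic cohort generator

`simulate_cohort()` emulates a pediatric IBD cohort with Control, CD and
UC groups and generates every input the pipeline consumes, retaining all
ground truth. What it emulates, and its defaults:

* **Design**: 27/40/32 subjects (Control/CD/UC), ~30% of subjects
  contributing a second longitudinal sample (or a fixed
  `samples_per_subject`), ages 6–18.
* **Activity**: IBD samples are active with probability 0.5; scores are
  drawn on the group's pediatric scale consistently with the
  remission/active state, so the harmonization stage re-derives activity
  from score + scale as it would on real data.
* **Human DNA %**: log-normal, higher in active disease (meanlog
  log 0.4 active vs log 0.05 inactive, sdlog 1.5) — placing roughly a
  quarter of active samples above 1% human DNA and very few inactive
  ones, matching the magnitude of the real contrast.
* **Cell mixture**: Dirichlet over neutrophil, monocyte, B, T, colon,
  small intestine, with the neutrophil concentration parameter raised in
  active samples (neutrophils dominate inflamed samples).
* **Calprotectin**: generated from the linear predictor (intercept 1000;
  +40 per human-% point; +300 if active; −159.04 per treatment tier —
  the planted coefficient recovery tests target; age coefficient 0) plus
  a subject random intercept (SD 100) and Gaussian noise (SD 150),
  truncated at 0 and capped at 2100. The intercept sits mid-scale so the
  linear predictor stays interior to [0, 2100] and the stated linear
  structure — not boundary truncation — generates the data; with a low
  intercept the −159.04 × (tier up to 4) term drives a large share of
  treated samples into the zero boundary and no estimator could recover
  the coefficient. The price is that absolute Control-level values are
  higher than clinical reality; the generator emulates the model
  structure, not absolute clinical scales, and the noise model itself
  (Gaussian on the linear-predictor scale, truncated) is a package
  choice since none is published.
* **Bisulfite reads**: 10,000 reads per sample (the assay's target
  depth) split across a 6-cell-type × 2-marker default panel;
  methylation is all-or-none per molecule (the estimator only scores
  fully unmethylated molecules, so intermediate patterns arise only
  through conversion failure and sequencing error, defaults 1% and
  0.1%); conversion failure is modelled at non-CpG cytosines, which is
  what the conversion QC detects. Read names carry the true marker and
  cell of origin for exact confusion accounting in tests.
* **ddPCR**: true copies derived from the human % on 5 ng input at
  3.3 pg per copy, partitioned over 20,000 droplets.
* **Metagenomics**: 8M ± 1M total reads; human reads binomial at the
  true human %.
* **Species table**: a 400-species pool with per-species prevalence
  weights (Beta(2,2)); per group, a multiplier on presence probabilities
  is solved numerically so expected richness hits the group targets —
  defaults 275/130/170 (Control/CD/UC), the roughly two-fold Control:CD
  richness ratio of the real cohorts. Within presence, abundances are
  log-normal (species-level meanlog N(0, 1.5), sample-level sdlog 1) and
  renormalized to 100%. Presence is the primary disease signal by
  construction — which is exactly the regime where presence/absence
  classifiers should match relative-abundance classifiers. Planted
  differential species (six categories) multiply presence probability
  and within-presence abundance in the affected group(s); defaults for a
  planted effect are 20-fold abundance shifts.

What the generator does **not** emulate: read-level error profiles
beyond uniform substitution (no indels, no quality decay), primer or
adapter artifacts, compositional correlation structure between species
(species are independent given group), cohort/batch effects between
sequencing centers, age-dependent microbiome maturation, and the
zero-inflation patterns of real counts beyond Bernoulli presence.
Passing tests therefore demonstrate that the estimators recover the
structure they assume, at realistic sizes and noise levels — not that
they are robust to everything real stool data contains.

# Numerical and design choices

* Exact vs approximate Mann–Whitney switches at group size 12 — exact
  where cheaply enumerable, standard tie-corrected approximation
  elsewhere.
* Spearman p-values: exact for n ≤ 10 tie-free pairs, t-approximation
  otherwise; constant inputs are an error, not NA.
* Marker references contain CG dinucleotides only at the recorded
  offsets (stray CGs are scrubbed at generation), so CpG calls are
  unambiguous by construction.
* Tie-breaks: read-to-marker ties go to panel order; category ties
  (loss vs expansion both significant) go to the smaller adjusted p.
* Degenerate inputs fail loudly with the offending sample or marker
  named: all-zero samples in rclr, missing groups in the classifier,
  saturated ddPCR reactions, unknown activity scales or treatment names.
* Problem sizes in the test suite and acceptance script: 50 replicates ×
  30,000 reads for deconvolution recovery; 100 simulated reactions for
  ddPCR; cohorts of 150 subjects for ecology properties; 100 replicate
  cohorts of 400 samples/100 subjects for coefficient coverage; a
  400-sample cohort for classifier parity. These sizes give the
  acceptance properties comfortable statistical margins while keeping a
  full run in minutes on one CPU.

# Known limitations

* The similarity filter is ungapped: an indel-containing read loses
  register and is discarded rather than rescued; acceptable for
  fixed-locus amplicons, wrong for variable-length targets.
* Reconstructing counts from relative abundances for the subsampling
  control inherits the classifier's compositional normalization; it is a
  table-level approximation of re-running classification on subsampled
  reads.
* The generator's independence assumptions (species given group;
  treatment independent of activity) make planted effects easier to
  recover than confounded real-world effects.
* ddPCR copy estimates below ~1 copy per reaction are dominated by
  partition discreteness; rank correlations with truth degrade there by
  design, not by bug.
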