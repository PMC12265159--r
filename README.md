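# fecalsig

Joint analysis of host-derived and microbial DNA in stool, for
inflammatory bowel disease (IBD) case–control and longitudinal cohorts.

Stool carries a trace of human DNA shed from the gut — epithelium under
normal turnover and, during inflammation, immune cells (chiefly
neutrophils) migrating into the lumen. `fecalsig` quantifies that host
compartment and relates it to the microbiome around it:

* **Cell-of-origin deconvolution** of fecal human DNA from targeted
  bisulfite amplicon sequencing of cell-type-specific methylation
  markers. At each marker, the fraction of its target cell type's DNA is
  the fraction of molecules whose CpG sites *all* read unmethylated
  (`TG`) after bisulfite conversion, with the published filtering rules:
  <80% similarity reads dropped, conversion QC, <1000-read samples
  discarded, 5–150% fraction-sum window.
* **Absolute quantification** by droplet digital PCR:
  λ = −ln(negatives/total) copies per droplet, one detected copy of a
  single-copy locus = one genome equivalent = 3.3 pg human DNA, giving
  percent human DNA of the assayed mass (5 ng).
* **Host-inflammation metrics**: metagenomic human-read percentage,
  neutrophil/lymphocyte (NLR) and neutrophil/epithelial (NER) DNA
  ratios, activity-score harmonization across pUCAI/pCDAI/HBI/SCCAI,
  calprotectin capping at 2100 µg/g, and the 0–4 treatment-advancement
  ladder.
* **Microbiome ecology**: species richness and Shannon diversity,
  PCoA on the robust Aitchison (rclr) geometry with the zeros-stay-zero
  convention, and a six-category classifier assigning every species to
  IBD/CD/UC-lost, IBD/CD/UC-expanded or unchanged via one-sided
  Mann–Whitney tests against Control with family-wise
  Benjamini–Hochberg correction.
* **Modelling**: mixed-effects regression of fecal calprotectin
  (REML, subject random intercepts, Nakagawa marginal/conditional R²)
  and gradient-boosted tree classifiers (fixed hyperparameters, 5-fold
  stratified CV with hash-based fold assignment, external-cohort
  validation, Gain/Cover/Frequency and Shapley importance).
* **A synthetic cohort generator** that emulates the statistical
  structure of a pediatric IBD cohort — group sizes, activity, human-DNA
  distributions, neutrophil-dominated mixtures during inflammation,
  calprotectin from a known linear model, and a species table with a
  planted richness gradient and differential taxa — so the entire
  pipeline is testable without access-restricted patient data.

## Worked example

Deconvolve a simulated sample with a known 50/30/20 cell mixture and 2%
human DNA, then quantify and normalize:

```r
library(fecalsig)

panel <- generate_marker_panel(n_cell_types = 3, markers_per_type = 1,
                               cell_types = c("neutrophil", "colon",
                                              "small_intestine"),
                               seed = 7)
mix <- mixture_spec(c(neutrophil = 0.5, colon = 0.3,
                      small_intestine = 0.2), total_human_pct = 2)
reads <- simulate_bisulfite_reads(panel, mix, reads_per_marker = 10000,
                                  seed = 7)

quant <- quantify_ddpcr(simulate_ddpcr(true_copies = 30, seed = 7))
quant
#> ddPCR: lambda=0.002152 copies=43.05 mass=142.1 pg human=2.84%

prof <- aggregate_sample(reads, panel, ddpcr_human_pct = quant$human_pct)
prof
#> Sample methylation profile: 30000 retained reads; QC pass
#>      neutrophil           colon small_intestine
#>           49.86           30.12           20.26
#> normalized to total fecal DNA (%):
#>      neutrophil           colon small_intestine
#>           1.420           0.856           0.576

ner(prof)
#> [1] 0.9886561
```

The recovered fractions (49.9/30.1/20.3%) match the planted mixture to
binomial sampling error at 10,000 reads/marker; 30 true template copies
are estimated at 43 from one droplet realization (sub-50-copy reactions
are partition-noise dominated); the NER of ~1 says neutrophil DNA
roughly equals epithelial DNA in this synthetic sample.

Cohort-level ecology on a synthetic 60-subject cohort:

```r
co <- simulate_cohort(cohort_config(
  n_per_group = c(Control = 20, CD = 20, UC = 20),
  include_reads = FALSE, seed = 1))

sc <- species_count(co$species)
tapply(sc, co$clinical$group, median)
#>      CD Control      UC
#>   129.0   275.5   173.5

ord <- rclr_pcoa(co$species)
spearman_cor(ord$coordinates[, 1], sc)$rho
#> [1] -0.926

table(classify_species(co$species, co$clinical$group)$category)
#>   CD_LOST  IBD_LOST   UC_LOST UNCHANGED
#>        84        58        32       118
```

Median richness is roughly halved in CD relative to Control, the first
ordination axis is almost a pure richness axis (|ρ| ≈ 0.93; its sign is
an arbitrary PC convention), and most species in the analysis universe
are classified as lost in one or both IBD subtypes — the structure the
generator plants and real cohorts show.

The full pipeline (simulate → methylation profiling → ddPCR → host
fraction → clinical harmonization → ecology → models, with manifest and
attrition accounting) runs as

```r
run_pipeline(pipeline_config(seed = 1), "out_dir")
```

or from the shell via the thin wrapper `inst/cli/fecalsig`
(`fecalsig simulate|run --config cfg.yaml --out DIR --seed N`).

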