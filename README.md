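# stemtrace

Analysis pipeline for label-free (LFQ) proteomics time courses of directed
stem-cell differentiation, built around the proteomic characterization of an
iPSC → smooth-muscle-cell (SMC) protocol sampled at days 0, 3, 5, 7 and 10
in three replicates, with an endpoint comparison of the derived cells
against primary SMCs under normal (NM) and osteogenic (OM) media.

The package is aimed at proteomics analysts who want each stage of such a
study as a tested, reusable function: preprocessing, stage-specific marker
detection, temporal clustering, differential abundance, set
over-representation, and reference-proteome correlation with influence
diagnostics. Because deposited raw data are not required, a synthetic-data
module generates LFQ-like matrices with planted ground truth (markers,
profile archetypes, sample-scale distortions, a discordant
"vimentin-analog" protein) so that every stage is verifiable at desk scale.

## Methods at a glance

* **Preprocessing** — master proteins (more than 2 unique peptides) are
  retained, missing values are replaced with zero, and each sample is
  divided by the median of its nonzero intensities.
* **Day specificity** — for protein *j* and day *d*,
  *Z*<sub>jd</sub> = (⟨p⟩<sub>jd</sub> − ⟨p⟩<sub>j</sub><sup>all</sup>) / σ<sub>j</sub>,
  the day mean centred and scaled by the protein's all-sample mean and
  standard deviation; a protein is specific to day *d* when
  *Z*<sub>jd</sub> > 1.5. A threshold scan selects the smallest cutoff at
  which specific proteins have mean multiplicity ≤ 1.05 (most specific
  proteins point at a single day).
* **Trajectory clustering** — per (protein, replicate), the day profile is
  normalized to unit sum and all replicates are pooled; k-means (default
  k = 20, best of 10 restarts) clusters the profiles; diagnostics cover
  per-cluster replicate composition, peak-day assignment, and the top
  shared proteins per cluster.
* **Differential abundance** — log2(x+1) intensities, per-protein pooled
  variances shrunk by an empirical-Bayes prior fitted by moment matching
  on log variances (s̃² = (d₀s₀² + d·s²)/(d₀+d)), moderated t referred to
  t with d₀+d degrees of freedom, Benjamini–Hochberg correction.
* **Reference comparison** — Pearson correlation of mean protein
  abundances between derived and reference proteomes per (condition,
  timepoint), with exact leave-one-protein-out influence analysis
  reporting r with and without the top influencer.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (each writes its tables under `results/`):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_day_specificity.R
Rscript analysis/04_clustering.R
Rscript analysis/05_differential.R
Rscript analysis/06_reference_comparison.R
```

Selected output from a run (seed 1):

```
time course: 2000 proteins x 15 samples, 250 planted markers, 15.1% missing
per-day specific proteins at threshold 1.5 (precision/recall vs planted truth):
  day 0 :  50 specific, precision 0.920, recall 1.000
  day 3 :  52 specific, precision 0.942, recall 1.000
  ...
k = 5 archetype recovery: adjusted Rand index 0.944; peak days 0/3/5/7/10
d0 vs d3: prior d0 = 2.21, s0^2 = 0.014; 94 significant (adj p < 0.05 & |logFC| > 1)
NM day 17: r = 0.650 with P00495, 0.428 without (delta -0.221)
OM day 17: r = 0.208 with P01069, 0.394 without (delta 0.187)
```

Reading the last two lines: in NM the most influential protein is a
natural concordant extreme, so excluding it lowers r; in OM the planted
discordant vimentin analog (P01069) dominates and excluding it raises the
correlation substantially — the with/without presentation used when one
dominant protein distorts a derived-vs-reference comparison.

Or programmatically, end to end:

```r
library(stemtrace)
man <- run_pipeline(run_config(out_dir = "results/run", seed = 1))
```

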