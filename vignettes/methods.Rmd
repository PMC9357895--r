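---
title: "Methods: time-course proteomics of stem-cell differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-course proteomics of stem-cell differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stemtrace)
```

`stemtrace` re-implements, as a tested pipeline, the computational analyses
used to characterize a label-free (LFQ) proteomics time course of directed
iPSC-to-smooth-muscle-cell differentiation: five sampling days (0, 3, 5, 7,
10), three replicate differentiations, plus an endpoint comparison of the
derived cells against primary smooth-muscle cells under normal (NM) and
osteogenic (OM) media. This vignette is the package's own account of each
method, its assumptions, the tunable parameters, and the design choices
made where the methodology left them open.

## Preprocessing

Quantification is restricted to *master proteins*, the representative
proteins of parsimony-based protein groups, supported by more than two
unique peptides. `filter_master_proteins()` therefore keeps proteins with
`unique_peptides >= 3` by default; the cutoff is configurable, and the
reading "more than 2" (rather than "at least 2") follows the stricter,
literal convention.

Missing intensities in LFQ data are predominantly left-censored — low
abundance drives non-detection — so `replace_missing_with_zero()` treats
them as below the detection floor. The missingness mask is preserved so
downstream code can distinguish structural zeros from measured values.

`median_normalize()` divides each sample by the median of its **nonzero**
entries. Zeros are excluded because, after missing-to-zero replacement, a
raw median would depend on each sample's censoring depth rather than its
loading; with zeros excluded, the nonzero median of every sample equals 1
afterwards (to 1e-12), and the operation is idempotent. Normalizing each
sample to its own median (target 1) rather than to a grand median changes
nothing downstream: any common target differs only by a global constant,
and the day-specificity statistic is scale-free.

The documented pipeline order is filter → replace → normalize
(`preprocess()` records the steps it ran in its `log`).

## Day-specificity z-score

For protein $j$ and day $d$,

$$Z_{jd} = \frac{\langle p\rangle_{jd} - \langle p\rangle_j^{all}}{\sigma_j},$$

where $\langle p\rangle_{jd}$ is the protein's mean normalized abundance
over the samples of day $d$, and $\langle p\rangle_j^{all}$ and $\sigma_j$
are its mean and sample ($n-1$) standard deviation over **all** samples. A
protein is specific to day $d$ when $Z_{jd} > 1.5$ (strict inequality).

Two conventions deserve note:

* **Per-protein centring and scaling.** The mean and standard deviation
  are per protein, not pooled across proteins. A cross-protein pool would
  be dominated by the abundance dynamic range (orders of magnitude wide)
  and could not support a single specificity cutoff; the per-protein
  reading makes $Z$ scale-free, which the tests verify directly. A
  `log2` option is provided but the default operates on the normalized
  raw scale, matching the pipeline order in which the statistic follows
  normalization.
* **$\sigma_j = 0 \Rightarrow Z_{jd} = 0$** for constant (including
  all-zero) proteins, avoiding division by zero; such proteins are never
  day-specific.

With 5 days of 3 samples each, the statistic has a hard ceiling: a protein
elevated in exactly one day's 3 samples out of 15 cannot exceed
$Z \approx 1.93$ regardless of effect size. The working threshold 1.5
sits deliberately just below this ceiling: high enough that a specific
protein typically points at a single day, low enough to retain strongly
day-restricted proteins.

`scan_threshold()` formalizes that balance. For each candidate threshold
(default grid 0.5–3.0 in steps of 0.1) it counts proteins specific to at
least one day and their mean *multiplicity* (number of days a specific
protein is called on). It selects the smallest threshold whose mean
multiplicity is at most $1 + tol$ (tol = 0.05): the least conservative
cutoff at which specificity is essentially unambiguous. Smaller thresholds
retain more proteins but blur them across days; ties therefore break
toward the smaller threshold. If no grid value qualifies, the largest is
returned with a warning.

`enrich()` tests day sets (or any protein list) against user-supplied
annotation sets (GMT format) with the one-sided hypergeometric
over-representation test, Benjamini–Hochberg adjusted across terms. Terms
are intersected with the background first; terms smaller than
`min_term_size` (default 2) after intersection are skipped. Live GO
databases are out of scope by design — annotations are explicit inputs.

## Trajectory clustering

`build_profiles()` converts the normalized matrix into one row per
(protein, replicate): the per-day abundance (averaged if a (day,
replicate) cell holds several samples), normalized to unit **sum** over
days. Unit sum (fraction-of-total) is the default profile normalization;
unit max is available via `norm = "max"`. All-zero rows carry no shape and
are dropped with a logged count. Pooling replicates as separate rows lets
the clustering treat them as exchangeable observations of the same
temporal program, and makes replicate concordance checkable afterwards.

`kmeans_profiles()` runs standard Euclidean k-means (Hartigan–Wong, as in
`stats::kmeans`) with `restarts` random initializations (default 10),
keeping the best by total within-cluster sum of squares; a fixed seed
makes the fit fully deterministic, and the iteration cap (300) is logged
if reached. The default k = 20 is the working resolution used for the
full differentiation matrix; archetype-recovery checks use k = 5 on
marker-only data where the five planted peak-day archetypes are the
truth. Diagnostics:

* `replicate_composition()` — per-cluster fraction of rows from each
  replicate; near-uniform composition indicates that replicates share the
  temporal structure rather than forming replicate-specific clusters.
* `peak_day_clusters()` — each cluster's centroid argmax day, ties
  breaking toward the earliest day (relevant only for exactly flat
  centroids).
* `top_shared_proteins()` — proteins assigned to a cluster in *every*
  replicate ("shared"), ranked by mean abundance, with per-day expression
  normalized to each protein's maximum day.

## Differential abundance

Adjacent-day (and endpoint) contrasts use an empirical-Bayes moderated
t-test on `log2(x + pseudocount)` intensities (pseudocount 1 on the
normalized scale, mapping structural zeros to 0). Per protein, the pooled
two-group variance $s_g^2$ with $d = n_1+n_2-2$ degrees of freedom is
shrunk toward a prior:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}, \qquad
  t_g = \frac{\mathrm{logFC}_g}{\tilde s_g \sqrt{1/n_1 + 1/n_2}},$$

with $t_g$ referred to a t distribution on $d_0 + d$ degrees of freedom
and Benjamini–Hochberg adjustment across proteins. `fit_prior()` estimates
$(d_0, s_0^2)$ by matching the mean and variance of $\log s_g^2$ to the
digamma/trigamma moments implied by the hierarchical (scaled-F) model;
when the spread of $\log s_g^2$ does not exceed what $d$ alone implies,
$d_0 = \infty$ and all proteins share $s_0^2$. At $d_0 = 0$ the statistic
reduces exactly to the ordinary pooled t-test (verified to 1e-8), and as
$d_0 \to \infty$ to a fixed-variance z-like statistic — the two limits
bracket the moderation. Zero-variance proteins are excluded from prior
fitting (with a warning) but still tested, their variances shrunk fully
toward the prior.

This is a deliberate, documented stand-in for a count-oriented
precision-weighting pipeline: the data here are intensities, not counts,
so the mean–variance trend is handled by the log transform plus
moderation rather than observation-level weights. Differences from any
specific external tool are expected. Two cutoff conventions are carried:
significance calling at adjusted p < 0.05 with |logFC| > 1 (strict), and
a volcano display convention at adjusted p < 1e-4; `volcano_table()`
accepts either.

`benjamini_hochberg()` is the package's own step-up implementation (sort
ascending, $p_{(i)} m/i$, enforce monotonicity from the top, cap at 1); it
is compared against an independent reference implementation, exactly, in
the tests.

## Reference comparison and influence analysis

`compare_conditions()` correlates, per (condition, timepoint), the derived
dataset's mean protein abundances with the reference's mean abundances
for the same condition, over the proteins detected (nonzero mean) in both
datasets. The default scale is the normalized raw abundance — "mean
protein abundance" taken literally — with a `log2` option. On the raw
scale the correlation is weighted toward abundant proteins; that is
precisely the regime in which a single dominant discordant protein (the
motivating case is vimentin, persistently overexpressed in iPSC-derived
cells relative to primary cells) can distort the comparison, and the
regime in which its influence is detectable.

`influence_leave_one_out()` recomputes the Pearson correlation with each
protein removed — direct recomputation, not a downdating formula, so each
leave-one-out value is bit-identical to an independent recomputation on
the reduced vectors. It reports the full correlation, each protein's
$\Delta r$, the top influencer by $|\Delta r|$ (ties to the
lexicographically smallest id; removals that leave zero variance are
flagged and excluded from the argmax), and the correlation without the
top influencer — the with/without presentation. A user-specified
exclusion list (`exclude`) expresses the named-protein variant
("without vimentin") directly.

## The synthetic-data generator

`simulate_timecourse()` emulates the study design: 2000 proteins, days
0/3/5/7/10 × 3 replicates, 50 day-specific markers per day planted at a
+2 log2 shift on their day. The emulation's components and defaults:

* **Intensity law**: per-protein base log2 intensities
  $\sim N(20, 2^2)$ — a log-normal abundance distribution with a
  realistic LFQ dynamic range; the methodology's median normalization
  presumes exactly this kind of multiplicative structure. No
  distributional facts about the original raw intensities are available,
  so these are conventional values, not data-derived ones.
* **Replicate noise**: log2 sd 0.25 (~18% CV), typical of kit-based
  cell-culture LFQ preparations.
* **Missingness**: left-censored logistic in the true log2 intensity,
  probability 0.05 at the global median with slope 1 per log2 unit
  (overall ~15% missing) — the low-missingness regime of
  match-between-runs-style feature mapping. Censoring is driven by the
  *pre-distortion* intensity, so the per-sample scale distortion (log2 sd
  0.25) acts as a pure measurement gain; this keeps nonzero-median scale
  recovery unbiased, which the tests verify to 5% relative error.
* **Markers** are planted in the upper half of the abundance distribution
  (|half-normal| above the base mean). A day-specific protein must be
  quantifiable to be observable as such — the z statistic's ceiling means
  a marker whose own day is partially censored is unrecoverable in
  principle — and real stage markers are well-quantified proteins.
  Passing recovery tests therefore demonstrates the statistic's behavior
  on detectable markers; they say nothing about markers below the
  detection floor, which no method using these inputs could recover.
* **Peptide counts**: $1 + \mathrm{Poisson}(5)$, so a small fraction
  (~4%) falls below the master-protein filter.

`simulate_reference_pair()` draws paired log2 mean-abundance vectors from
a bivariate normal law with a target correlation, planting
`n_outliers` discordant proteins: the most abundant proteins of vector A,
shifted down by `outlier_shift` in vector B only. Placement at the top of
the abundance range is deliberate — a discordant shift at a random
protein of moderate abundance is partially concordant with the regression
line and can have near-zero influence, whereas the dominant-protein
geometry mirrors the motivating case and makes the planted outlier the
top influencer in ≥95% of seeded runs.

`simulate_condition_matrices()` extends this to full sample-level
matrices: derived (NM/OM × days 10/17 × 3 replicates) and reference
(NM/OM, day 14, 3 donors) datasets over a shared protein universe, with
per-condition target correlations (defaults NM 0.8, OM 0.6) on the latent
log2 means and a single vimentin analog: a protein of high (90th
percentile) but not extreme reference abundance whose derived-side
expression is inflated by 8 log2 units. On the raw abundance scale this
protein carries dominant, discordant leverage, so its removal raises the
measured correlation. Note two deliberate asymmetries with the vector
generator: the correlation is planted on the latent log2 scale (the
correlation measured through the full pipeline is attenuated by censoring
and replicate noise, as in real data, so tests verify the planted value
on the recorded truth and verify direction/influence through the
pipeline), and the outlier is placed high-but-not-maximal because the
single most abundant protein's reference value is itself top-of-cloud,
making a derived-side inflation there *concordant*.

All generator draws flow from one integer seed; identical configurations
are bitwise reproducible, including the emitted TSV text.

## Pipeline, problem sizes, and determinism

`run_pipeline()` executes simulate → preprocess → dayspec → cluster →
diff → compare as toggled, writing every stage's TSVs plus a JSON
manifest (config, seed, package version, MD5 checksums). A single master
seed fans out to fixed per-stage substreams (simulation, clustering
initialization, reference simulation), so re-running a config reproduces
byte-identical outputs; the manifest deliberately contains no timestamps.

Verification problem sizes were chosen to estimate each property with
comfortable sampling margins at desk scale: 2000 × 15 matrices and 10
seeds for marker recovery; 250-protein, marker-only simulations for k = 5
archetype recovery; 200 replications × 2000 proteins for the null type-I
error of the moderated t; 5000 variances for prior recovery; and 100
seeded runs of 5000-protein reference pairs for the influence analysis.
`scripts/acceptance.R` recomputes all of these from scratch from a single
command-line seed.

## Known limitations

* The generator emulates intensity structure, censoring and scale
  distortions, but not peptide-level rollup, retention-time alignment,
  chromatographic batch effects, or correlated (co-regulated) protein
  modules; clustering recovery on synthetic archetypes is therefore an
  upper bound on what structured real data would give.
* The moderated t stand-in does not reproduce any specific external
  tool's output numerically; its calibration is established by its own
  null simulations and limit identities.
* Raw-scale Pearson correlations are dominated by the most abundant
  proteins; that is faithful to the motivating analysis, and the
  influence diagnostics exist precisely to expose it, but comparisons of
  correlation magnitudes across datasets with different dynamic ranges
  should use the log option.
* GO-style biological conclusions require real annotation sets and the
  deposited data; the enrichment machinery here is generic and
  annotation-agnostic.
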