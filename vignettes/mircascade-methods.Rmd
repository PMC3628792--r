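---
title: "The mircascade enrichment cascade: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mircascade enrichment cascade: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircascade)
```

## The problem and the method

`mircascade` prioritizes candidate regulator microRNAs from a two-strain,
two-treatment expression experiment without any direct miRNA assay. The idea
is a chain of knowledge-based enrichment steps: genes that differ between
strains (or respond to an inflammatory stimulus such as LPS) are selected and
clustered; each cluster is summarized functionally by Gene Ontology
over-representation; the clusters' promoters are scanned for over-represented
transcription-factor binding-site (TFBS) motifs; and finally the
transcription factors behind the enriched motifs become the substrate for
miRNA-target aggregation: a miRNA that is predicted (by two independent
algorithms) to target many of those TFs is a plausible upstream regulator of
the whole expression difference. An empirical permutation test then asks
whether each candidate's target set is unusually concentrated in a functional
gene group.

Every stage is a standard, well-understood statistic; the contribution of the
package is the seeded, provenance-tracked composition of the stages and a
synthetic-data generator that plants known signal at *every* stage, so the
full cascade has a measurable ground-truth acceptance surface.

## Stage models and their assumptions

### Normalization (`percentile_shift`)

Raw intensities are log2-transformed; each sample is centred at its 75th
percentile and each gene is then centred at its median across samples. The
"divide by percentile/median" convention of array percentile-shift processing
is applied on the raw scale, i.e. as subtraction after the log transform —
division of log values would be scale-pathological. The percentile uses
linear interpolation between order statistics (R type 7); the convention is
pinned and recorded in the `NormalizationReport` because different quantile
rules give visibly different centres on small samples. Gene-median centring
uses **all** samples.

A caveat worth stating: the two-step procedure is *not* idempotent. The gene
step perturbs the per-sample percentiles, so renormalizing an already
normalized matrix shifts values slightly (alternating centring converges
only in the limit, as in median polish). What the implementation guarantees,
and what the tests assert, are the exact post-conditions of each step: after
step 1 every per-sample 75th percentile of the log2 values is 0; after step
2 every per-gene median is 0; and rescaling one raw sample by any constant
leaves its normalized values unchanged.

### Detection-flag filtering (`flag_filter`)

Probes with at least one P (present) or M (marginal) flag across all arrays
form the analysis universe; probes absent everywhere are removed. The
platform's own flag rule is not reproducible from first principles, so the
generator derives flags from a per-sample intensity quantile
(`flag_absent_quantile`, default 0.05): ranks below the quantile minus 2% are
A, ranks within ±2% of it are M, the rest are P.

### Differential-expression selection (`select_de_genes`)

Three candidate lists mirror the dual statistical criteria of the screening
design:

* **List 1** — strain contrast under LPS at one duration: Mann–Whitney rank
  test with midrank ties, BH-adjusted p below the threshold *and* a
  direction-free fold change of at least `fc_threshold` (default 1.5). The
  rank test is exact (full enumeration of label assignments) whenever the
  pooled size is ≤ 12 and tie-free, and a tie-corrected normal approximation
  otherwise; the method used is recorded per gene.
* **List 2** — LPS-vs-control fold change within either strain; fold change
  only. Fold changes are ratios of anti-logged group means (geometric-mean
  ratios on the raw scale), reported as `max(r, 1/r)` with a direction sign.
* **List 3** — two-way ANOVA over all arrays (strain × treatment by default;
  treatment × duration available), BH-adjusted p of the strain main effect
  below the threshold. The strain factor is thresholded because the
  selection targets genes differing between the naive strains; this choice
  is logged per run.

The three lists are combined into a Venn partition with all seven region
counts; the default combined set is the union (`union_all`), with
`shared_by_2_of_3` available. Both rules exist in the screening tradition
this mirrors; the discrepancy is surfaced in the provenance rather than
silently resolved.

**A granularity limit to know about.** With three arrays per condition, the
exact two-sided Mann–Whitney p cannot go below 2/C(6,3) = 0.1, so List 1 is
structurally empty at a 0.05 threshold — the rank test simply has no
resolution at this replication. The cascade's selection power rests on Lists
2 and 3 at the default design, and the package requires at least two
replicates per compared group (pooled one-array-per-condition designs are
degenerate for both tests). The test suite checks List 1's machinery against
enumeration oracles and verifies its power at replication levels where the
test has resolution.

The "less-stringent" screening mode (`p_threshold = 0.5`) is supported and
deliberately announces itself with a message: a 0.5 threshold is unusually
permissive and exists to feed downstream *set-level* enrichment, which can
recover signal that per-gene thresholds miss.

### Clustering (`hierarchical_cluster`)

Agglomerative clustering of selected genes from pairwise profile distances,
cut at `k = 2`. Default distance is one minus the Pearson correlation of
expression profiles (the expression-profile convention); Euclidean distance
and complete linkage are available alongside the default average linkage
since both linkages are conventional for this kind of heat-map clustering.
The distance default is a declared choice, not an inference. Zero-variance
profiles are rejected for the correlation distance with a pointer to the
Euclidean alternative.

### GO over-representation (`go_enrich`)

Model-free categorical over-representation: for a query of n genes and a
term with K annotated genes in a universe of N, the p-value is the
hypergeometric upper tail P(X ≥ k), BH-corrected across exactly the tested
terms. Annotations are taken as given flat sets — no ontology-graph
propagation, because flat term files carry no reliable ancestor closure.
Terms are tested only if 2 ≤ K ≤ 500 (degenerate and giant terms inflate the
BH family). The default universe is the detection-filtered gene set rather
than the whole genome: a detection-filtered universe avoids abundance bias,
and the whole-annotation universe is one switch away
(`universe_mode = "all"`), with the choice recorded in provenance.

### Promoter motif enrichment (`motif_enrichment`)

Promoters are supplied pre-extracted (3 kb upstream of the TSS in the
generator; position 0 is the distal end). PWMs are 4 × L base-probability
matrices with a pseudocount; scoring is the log-likelihood ratio
`sum log2(p[base,pos] / q[base])` against a background base-composition
model (default: the composition of the background promoter set; uniform
switchable). A window is a hit when its score reaches `threshold_frac`
(default 0.85) of the PWM's maximum achievable score; both strands are
scanned and N-containing windows are skipped rather than penalized, which
avoids distorting the background model. The published scanners this stands
in for do not document their exact hit threshold, so the threshold is a
first-class configuration knob rather than a buried constant, and published
per-motif p/EF values are not treated as recomputation targets.

Statistics are gene-level, not site-level: a gene either has ≥ 1 hit or it
does not, matching the "prevalence of hit genes" reading of motif
enrichment. The enrichment factor is

EF = (hits_set / |set|) / (hits_bg / |bg|),

undefined (NA) when the background has no hits, and identically 1 when the
set *is* the background. The p-value is the hypergeometric upper tail of
drawing `hits_set` hit genes in `|set|` draws from a background containing
`hits_bg` hit genes, BH-corrected across the PWM library. The background
deliberately includes the query set: that keeps the hypergeometric sampling
frame coherent and matches the "set against background" phrasing of
promoter-enrichment tools.

### miRNA aggregation and empirical enrichment (`aggregate_targets`, `fame_empirical_p`)

PWMs passing the adjusted-p threshold are mapped to TF gene ids through an
explicit two-column map (the identification of a motif with a TF gene is
knowledge, not computation, so it is an input). For every miRNA and each
prediction algorithm, the count of predicted targets inside the enriched TF
set is taken; counts are summed across algorithms and miRNAs are ranked by
descending sum. Ties break by (1) more algorithms with a nonzero count, (2)
larger minimum per-algorithm count, (3) lexicographic id — a declared rule.
Zero-sum miRNAs are excluded from the report but counted in provenance.
miRNA family collapsing (e.g. treating -27a/-27b as one unit) is supported
through an optional family map, because family definitions are
database-specific; the default ranking unit is the id string in the tables.

The empirical functional-enrichment p for a (miRNA, GO term) pair draws B
gene sets of the same size as the miRNA's target set uniformly without
replacement from the universe and uses the add-one estimator
p = (1 + #{overlap ≥ observed}) / (1 + B). This is a deliberate
simplification of published miRNA-enrichment permutation schemes, which
stratify by 3′-UTR length — no such covariate exists among this package's
inputs, so uniform resampling is the honest null here. The terms tested are
those over-represented in the enriched-TF gene set itself, BH-corrected
across all tested pairs.

## What the generator emulates — and what it does not

`sim_config()` encodes the study conditions: two strains × {control, LPS} ×
two durations with 3 replicate arrays per condition (24 arrays), log-normal
intensity noise (`noise_sd_log2 = 0.4`), planted strain-differential and
LPS-responsive genes at log2 effect 1.5, detection flags, 3000-bp promoters,
a 10-PWM library with 3 planted motifs at plant rate 0.6, and 20 miRNAs of
which one — the planted regulator — targets 80% of the planted-PWM TFs per
algorithm while decoys target genes at rate 0.05.

Defaults the studied design does not pin were chosen once as realistic for a
desk-scale screen and are not revisited: 1000 genes (enough for stable BH
families and motif backgrounds while keeping a full cascade run in seconds),
baseline log2 intensities N(8, 1.5²), 5% strain-DE and 5% LPS-DE genes,
`flag_absent_quantile = 0.05`, 50 GO terms of 10–60 genes with planted terms
drawing 60% of their members from one cluster, and B = 1000 resamples for
the pipeline's empirical enrichment. The generator's PWM columns are highly
informative (consensus probability 0.93–0.98), as for strong curated TF-site
matrices; this matters because planted sites are *sampled from the PWM*, and
sites from diffuse matrices would routinely fall below a fraction-of-max hit
threshold — a coherence requirement between the planting and scanning
models, not a tuning knob.

Replication is a parameter (`n_replicates_per_condition ≥ 2`) rather than a
copy of any particular pooled design: rank tests and ANOVA are degenerate
with one array per condition, so the generator generalizes to independent
replicate arrays.

The generator does **not** emulate scanner artifacts, probe sequences,
spatial array effects, probe-level variance structure, correlated gene
modules beyond the planted clusters, GC-biased promoter composition, or
3′-UTR covariates of target prediction. Passing tests therefore demonstrate
that the cascade recovers planted structure under idealized noise — they do
not certify performance on real arrays, where normalization and annotation
quality dominate.

## Numerical choices and degenerate inputs

* Hypergeometric tails come from the standard stabilized implementation
  (`phyper`); k = 0 gives p = 1 exactly.
* The exact Mann–Whitney branch uses the null U distribution
  (`pwilcox`), two-sided p = min(1, 2·min(lower, upper)); the approximate
  branch uses the tie-corrected normal without continuity correction, and
  all-identical inputs give p = 1.
* ANOVA F statistics come from nested least-squares fits (matrix response),
  which reproduces the classical sequential decomposition for the balanced
  designs the generator emits; with a residual mean square of zero, terms
  with positive sums of squares are reported at p = 0 and null terms at
  p = 1.
* BH adjustment is the standard step-up (`p.adjust`), validated in the test
  suite against the direct min-over-tail formula.
* Agglomeration ties follow the library implementation (`hclust`); the
  suite pins behaviour against a brute-force O(n³) oracle on tie-free data.
* Motif scanning skips N-containing windows; promoters shorter than a motif
  yield zero hits rather than an error; a background with zero hits for a
  PWM reports EF = NA with the degenerate-table p.
* Empirical p-values are add-one estimators, so they are never 0 and are
  deterministic given (B, seed). Sub-seeds for pipeline stages are derived
  from the run seed by fixed affine offsets, keeping every seed below 2³¹.
* Byte-identical outputs: no timestamps enter any written report.

## Problem sizes used in validation

The packaged checks run at desk scale, chosen as the package's own balance
of statistical resolution and turnaround: exhaustive oracle comparisons on
universes up to 12 genes and group sizes up to 5; motif recovery with a
20-gene cluster against a 200-gene background over 100 seeds; end-to-end
planted-regulator recovery at the default configuration over 50 seeds; and
null false-discovery control over 200 simulated datasets of 500 genes. At
these sizes the full suite completes in minutes on one CPU.

## Known limitations

* List 1 has no resolution below p = 0.1 at 3 + 3 arrays (see above); the
  selection then rests on Lists 2 and 3.
* The motif stage's absolute hit counts depend on `threshold_frac` and the
  background model; only the *relative* enrichment across PWMs is meant to
  be interpreted.
* Uniform resampling in the empirical miRNA test ignores target-set
  covariates (UTR length, expression), so its p-values are optimistic for
  miRNAs with unusually long-UTR target sets on real data.
* GO correction treats all tested terms as one family; terms are overlapping
  sets, and the BH independence caveat applies.
* The cascade reports candidates, not mechanisms: rank 1 is a prioritization
  for bench validation, not an inference of regulation.
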