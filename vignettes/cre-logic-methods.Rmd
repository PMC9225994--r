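---
title: "Promoter and enhancer logic of granulocytic differentiation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter and enhancer logic: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific model

During granulocytic differentiation a late-acting CCAAT/enhancer-binding
factor (CEBPE) has to do two opposite things at once: switch **off** the
proliferation program and switch **on** the granulocyte identity program.
`crelogic` operationalizes the regulatory logic behind this switch as a
set of measurable quantities on cis-regulatory elements (CREs):

* **Promoter-level repression of cell-cycle genes.** Genes transiently
  expressed just before cell-cycle exit (temporal cluster B) carry G2/M
  promoters controlled by activating E2Fs with NFY, and silenced by the
  MuvB/DREAM complex (read out here through its DNA-binding subunit
  LIN54). The package encodes each promoter as four bits — C (CEBPE),
  E (E2F1), N (NFYB), L (LIN54) — and classifies it as **CENL** (all
  four), **CE** (C and E with at most one of N, L; the rules apply in
  order CENL → CE → Rest, so CE excludes the full combination) or
  **Rest**. The model predicts CENL promoters concentrate in cluster B
  and are the ones de-repressed when CEBPE is knocked out.
* **E2F-proximal, motif-independent CEBPE binding.** If CEBPE represses
  cell-cycle genes by contacting promoter-bound E2F rather than its own
  DNA motif, then CEBPE peaks that overlap E2F1 sites (distance class 0)
  should show no CEBPE motif, while distal CEBPE binding should be
  motif-driven. The distance-class profile (`distance_class_profile()`)
  tests exactly this: distance of each bound promoter's CEBPE peak to the
  closest E2F1 site, against the PWM log-odds motif score at that peak.
* **Enhancer-level activation of identity genes.** Late granulocytic
  genes (cluster C) are predicted to be bound by CEBPs at distal
  enhancers rather than promoters; the enhancer catalog plus per-gene
  mean enhancer signal (`gene_enhancer_signal()`) quantifies this.

# Definitions and parameters

| Parameter | Default | Meaning |
|---|---|---|
| `promoter_half_width` | 1000 bp | promoter = `[tss − h, tss + h)`, strand-agnostic |
| `enhancer_width` | 500 bp | fixed width after recentering on the region midpoint |
| `distal_bp` | 1000 bp | minimum midpoint-to-TSS distance for an enhancer |
| `alpha` | 0.05 | adjusted-p cutoff for the Up/Down/Neutral labels |
| `distance_edges` | 0, 1.5k, 6k, 24k, 96k, 384k, 1540k | distance classes; a dedicated class for 0 |
| `k` / `k_grid` | 8 / — | minor cluster count, or an elbow-selected grid |
| `lin54_evidence` | `"overlap"` | LIN54 bit from peak overlap or motif hit |

Coordinates are BED-convention (0-based, half-open) throughout, including
TSS positions; "overlap" always means ≥ 1 shared base under half-open
arithmetic, so abutting intervals do not overlap but have gap 0. The
distal constraint is evaluated on the region **midpoint**, both before and
after recentering — the midpoint is the recentering anchor, so the
constraint stays self-consistent. Closest gene means closest TSS, with
ties broken to the lexicographically smallest gene id. Signal tracks are
consumed as already normalized (genome-wide mean 1); the pipeline never
rescales them.

The distance-class edges grow geometrically (×4) across the 0–1540 kb
profiling range; only the range itself is fixed by convention, so the
edges are a configurable argument.

**LIN54 evidence.** The canonical LIN54/CHR element is short (≈ 6 bp). A
"motif score > 0" rule with so permissive a model fires on essentially
every 2 kb promoter by chance, which would flood the L bit and erase any
combinatorial contrast. The default therefore takes LIN54 evidence from
peak overlap, like NFYB and E2F1; motif evidence remains available via
`lin54_evidence = "motif"` for users with a stringent model.

# Expression clustering

Clustering operates on per-gene wild-type stage means of log2(CPM+1),
standardized per gene to zero mean and unit variance, so it groups
profile *shapes* rather than expression levels. Lloyd's k-means runs from
k-means++ seedings, best of `n_restarts` by within-cluster sum of squares
(WSS); an empty cluster aborts a restart and the seeding is re-drawn.
Because WSS is monotone in k, "minimize the sum of squares" cannot by
itself choose k; `select_k()` resolves this with an explicit elbow rule:
both axes of the (k, WSS) curve are scaled to [0, 1] and the chosen k
maximizes the perpendicular distance to the chord joining the curve's
endpoints. The candidate set at k+1 always includes the best k-solution
with its widest cluster split (its centroids plus the farthest member
point of the cluster with the largest within-SS), which makes the WSS
curve non-increasing by construction.

Minor clusters are merged into the major temporal classes A–E by Pearson
correlation of their centroids with named template profiles; a best
correlation below 0.5 leaves the minor cluster `unassigned`, and an
explicit minor→major map can override the rule (the analogue of a fixed,
manually curated merge table). Correlation ties break in template order.

# Differential expression

The KO-vs-WT contrast at one stage is computed on log2(CPM+1); log2FC is
the mean KO − WT difference on that scale; labels are Up (log2FC > 0,
BH-adjusted p < 0.05), Down (log2FC < 0, adjusted p < 0.05), else
Neutral. Two test statistics are offered:

* `method = "moderated"` (default): the empirical-Bayes moderated t with
  a mean-variance trend (limma-trend). With 2–3 replicates per genotype a
  per-gene test has ~4 degrees of freedom; in simulation at NB dispersion
  0.1 even a planted |log2FC| of 1.5 then almost never survives FDR
  control (the BH threshold collapses because no p-value is small
  enough), while the moderated test keeps the null calibrated (raw
  p < 0.05 rate ≈ 0.05) and recovers ≈ 85% of planted effects. Variance
  moderation is the field's standard answer to exactly this small-n
  regime, which is why it is the default.
* `method = "welch"`: the plain per-gene Welch t-test, for users who want
  a fully independent per-gene statistic.

The downstream logic consumes only (log2FC, adjusted p, label), so the
test is swappable without touching any other stage. Dispersion-shrinkage
count models are deliberately out of scope.

# Binding quantification

Per-promoter signal is the length-weighted mean of the track bins
overlapped by the promoter. Binarization per TF uses the **strict**
median rule: the threshold is the median promoter signal over the
DE-labeled reference genes, and bound means strictly greater ("above"),
so ties fall to unbound and at most half of the reference promoters can
ever be bound. TFs whose evidence is a pre-annotated region set (MYC,
E2F1, NFYB — e.g. from embryonic stem cell maps — and by default LIN54)
use the overlap indicator instead; the evidence type is recorded in the
binding matrix metadata.

Motif scores are max-over-windows log-odds sums,
`Σ log2(p(base)/background(base))`, scanned on both strands; windows
containing `N` are excluded, and the final score is floored at 0 so "no
better-than-background match" is exactly 0. The background defaults to
uniform and is configurable per genome composition.

# TF importance

`rank_tf_importance()` fits a logistic GLM of the DE/neutral label on the
five TF bits. When the unpenalized fit converges without separation,
importance is the absolute Wald z of each coefficient — the conventional
reading of GLM variable importance. Under separation (common on small or
noise-free fixtures where one bit perfectly predicts the label) the fit
is repeated with a small ridge penalty (λ = 0.01) on standardized
features and importance is the absolute standardized coefficient; the
fallback is flagged in the result's metadata. Constant features get
importance 0 and the last ranks; ties break alphabetically.

# The synthetic cohort

The generator's defaults are the study conditions under which the package
is validated: 3000 genes on 3 chromosomes at 20 kb spacing (±10%
positional jitter, alternating strand); 10 wild-type stages spanning the
granulocytic arm (LSK → GR) plus two monocytic stages (PMO, MO), and 4
knockout stages (GP, PM, MY, MM — knockouts of later stages do not exist
in this design); 3 replicates per (stage, genotype); negative-binomial
counts at dispersion 0.1 around `baseline × template × 2^log2FC(KO)`,
with gene baselines log-normal(log 150, 1). The five templates are: A
high early then decaying, B a transient MY peak, C late-rising
(granulocytic only), D late-rising in both arms, E monocytic-only;
background is flat. The two monocytic stages exist precisely so that C,
D and E are distinguishable shapes.

Planted regulatory structure: CENL promoters at rate 0.20 inside cluster
B and 0.02 elsewhere (CENL genes are always Up in the knockout, the
planted |log2FC| is 1.5); other promoter bits are Bernoulli per TF (0.2–
0.4 in clusters A/B, 0.1 elsewhere — kept below 50% bound among DE genes
so the strict median threshold stays at zero on noise-free data). For
cluster A/B genes with CEBPE binding, a CEBPE–E2F1 distance is planted:
overlap (0) or a small gap when E2F1 also binds the promoter, a distal
gap (1.6–5.8 kb) otherwise; the planted CEBP motif strength is 0 at
distance 0, a two-base degraded consensus at small distances, and the
full 10-bp consensus (`ATTGCGCAAT`, PWM 0.97/0.01) distally — the
anti-correlation the distance-class analysis must recover. Cluster C
genes receive 1–2 enhancers with the full consensus written into the
genome, placed 5–50 kb from their TSS inside open chromatin; candidate
positions are resampled until the closest-TSS rule links them back to
their own gene (at 20 kb gene spacing the accepted offsets concentrate at
5–9 kb) and until they keep > 1.2 kb from every previously planted distal
structure, so overlap-merging cannot fuse two planted regions. Tracks
render peaks as plateaus of the planted signal (max under overlap) plus
truncated Gaussian jitter (SD 0.1); false peaks are added at 0.02 per
gene per TF. One global seed feeds independent named substreams
(annotation / truth / expression / binding), so any simulator can be
re-run alone and reproduce its slice byte-for-byte.

**What the generator does not emulate** — and therefore what passing
tests do not show about real data: read-level artifacts (mappability,
GC, fragment size), batch effects, correlated biological replicates,
overlapping/nested genes and alternative TSSs, distance-dependent decay
of enhancer-gene assignment, and any monocytic knockout arm. Recovery
results on this cohort demonstrate the pipeline's correctness, not the
biological effect sizes reachable on real libraries.

# Numerical choices and degenerate inputs

* Exact Wilcoxon enumeration up to combined n = 16 and no ties, the
  tie-corrected normal approximation with continuity correction beyond;
  the branch taken is recorded. The two branches agree to |Δp| ≤ 0.02 at
  the crossover.
* Standard errors of medians come from a seeded bootstrap (1000
  resamples) rather than a density formula: group sizes here are small
  and ties common.
* Fisher enrichment is the exact hypergeometric upper tail of the (1,1)
  cell.
* BH adjustment is step-up with monotonicity enforcement, capped at 1.
* Empty enhancer catalogs are a warning plus an empty table, not an
  error; genes without linked enhancers get a NaN sentinel and are
  excluded (with a log message) from enhancer-level comparisons; groups
  with fewer than 3 values are excluded from rank tests.
* Cluster-recovery agreement (ARI) is evaluated over genes planted with
  one of the five templates; background genes have no profile shape
  (standardization maps a flat profile to noise) and are excluded from
  the metric.
* Validation problem sizes: the default cohort (3000 genes) for
  planted-contrast and cluster recovery; 2000-gene single-chromosome
  cohorts for DE calibration and power; 150-point blob mixtures over 50
  seeds for elbow selection; 600-gene feature tables over 100 seeds for
  driver recovery — sizes at which the binomial/Monte-Carlo tolerances
  quoted in the tests are meaningful.

# Known limitations

Enhancers are linked to exactly one gene by TSS distance — no chromatin
contact or activity-by-contact evidence; the promoter-class logic uses
binary bits, ignoring binding strength and TF interactions; the elbow
rule and the correlation-threshold merge are principled but not unique
resolutions of k-selection and cluster naming, and both are overridable;
the Welch option is underpowered below ~4 replicates, which is why the
moderated test is the default.
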