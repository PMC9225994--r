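# crelogic

Dissecting how a single late-myeloid transcription factor switches a cell
from proliferation to terminal differentiation, `crelogic` implements an
integrative promoter/enhancer analysis of granulocytic development. The
biological model: CEBPE shuts down cell-cycle genes by binding their
**promoters** close to E2F1 sites (often without its own sequence motif,
i.e. indirectly through E2F), while it switches on granulocyte-identity
genes through distal, motif-driven **enhancers**. The package is written
for computational biologists who want to run, test or extend this style of
analysis on ChIP-seq peak sets, coverage tracks and knockout RNA-seq counts
— or on fully synthetic data with planted ground truth.

## What it computes

* **CRE catalog** — promoters are the windows within 1 kb of each TSS
  (`[tss − 1000, tss + 1000)`); enhancers are TF-bound (PU.1, CEBPA, CEBPE,
  MYC, E2F1), open-chromatin (or previously cataloged) regions whose
  midpoint lies > 1 kb from every TSS, recentered to exactly 500 bp and
  linked to the closest TSS.
* **Expression program** — genes with ≥ 1 read in ≥ 2 samples and positive
  variance are clustered (k-means++, Lloyd, elbow k-selection) on
  standardized stage-mean log2(CPM+1) profiles into minor clusters, then
  merged by template correlation into the major temporal classes A–E;
  knockout-vs-wild-type differential expression labels each gene
  Up / Down / Neutral (log2FC sign with BH-adjusted p < 0.05).
* **Binding layers** — per-promoter ChIP signal (length-weighted mean of
  the track) binarized per TF at the strict median over DE-gene promoters
  ("bound" ⇔ signal > median), or by ≥ 1 bp peak overlap for TFs with
  pre-annotated region sets.
* **Distance classes** — each CEBPE-bound promoter is classified by the
  distance of its CEBPE peak to the closest E2F1 site (a dedicated class
  for overlap, i.e. distance 0), with the PWM log-odds CEBPE motif score
  (max over both strands, floored at 0) summarized per class: motif-free
  binding concentrates at distance 0, motif-driven binding farther away.
* **Combinatorial classes** — promoters are classified from the four bits
  C (CEBPE), E (E2F1), N (NFYB), L (LIN54) as CENL (all four), CE (C and E
  with at most one of N, L) or Rest; class frequencies per cluster with a
  one-sided Fisher enrichment test, and the knockout expression response
  per class (median log2FC ± bootstrap SE, one-sided Wilcoxon).
* **TF importance** — logistic regression of DE-vs-neutral on the five TF
  bits; importance = |Wald z| (ridge fallback under separation).
* **Synthetic cohort** — a seeded generator that plants all of the above:
  five temporal templates plus background, negative-binomial counts with
  knockout effects, 4-TF co-binding classes (20% CENL in cluster B vs 2%
  elsewhere), CEBPE–E2F1 distances anti-correlated with planted motif
  strength, and motif-bearing enhancers near late-cluster genes.

## Worked example

Run the whole pipeline on the default synthetic cohort (3000 genes, 10 WT
and 4 KO stages, 3 replicates):

```r
library(crelogic)
res <- run_pipeline(pipeline_config(simulate = sim_config(seed = 1),
                                    k = 8, seed = 1))
print(res)
#> <pipeline_result>
#>   genes kept: 3000
#>   clusters (major): A=1358 B=454 C=450 D=150 E=307 unassigned=281
#>   DE labels: Down=480 Neutral=2261 Up=259
#>   enhancers: 694
#>   CENL enrichment in B : p = 3.36e-38
```

The CENL promoter class is strongly enriched in the transiently expressed
cluster B — 19.4% of its genes against ~2% everywhere else — recovering
the planted 20% vs 2% contrast:

```r
res$class_frequencies$frequencies
#>      cluster    n n_cenl  pct_cenl
#> 1          A 1358     31  2.282769
#> 2          B  454     88 19.383260
#> 3          C  450     13  2.888889
#> 4          D  150      3  2.000000
#> 5          E  307      6  1.954397
#> 6 unassigned  281      5  1.779359
```

The CEBPE motif score rises with the distance to the closest E2F1 site:
promoters where the two peaks overlap (distance class `0`) have a median
motif score of 0 — CEBPE sits there without its own motif, consistent
with indirect, E2F-tethered binding — while distal classes carry full
motifs:

```r
head(res$distance_profile$summary, 4)
#>          class   n median_motif_score se_motif_score
#> 1            0 115           0.000000       0.000000
#> 2     (0,1500] 128           6.360741       0.000000
#> 3  (1500,6000] 182          19.560567       0.000000
#> 4 (6000,24000]  81          19.560567       4.879699
```

For cluster B, the logistic model ranks the CENL partners E2F1 and CEBPE
as the top classifiers of knockout-responsive genes:

```r
res$importance$B
#> <importance_ranking> (GLM |z|)
#>      tf coefficient          z importance rank
#> 1  E2F1  1.06811902  4.6688141  4.6688141    1
#> 2 CEBPE  0.76755844  3.3685200  3.3685200    2
#> ...
```

`run_pipeline(..., out_dir = "out")` additionally writes every stage table
(`clusters.tsv`, `de_MY.tsv`, `promoters.bed`, `enhancers.bed`,
`binding_matrix.tsv`, `promoter_classes.tsv`, ...) plus a `report.json`;
identical configs reproduce byte-identical outputs. A thin command-line
wrapper lives at `inst/scripts/crelogic-run.R`.

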