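---
title: "Methods: models, parameters and design choices in epiprime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in epiprime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiprime)
```

# Scope

`epiprime` reconstructs, as one seeded pipeline, the analysis by which a de
novo DNA-methyltransferase knockout (KO) is dissected against wild type (WT)
across an ESC → EpiLC → meso-endoderm differentiation time course:
differentially methylated regions (DMRs) that fail to gain methylation in
the KO, the genes they derepress, the regulatory regions they fall in, and
the TF network those genes form. This vignette documents the statistical
models, every tunable parameter, what the synthetic-data generator does and
does not emulate, and the design decisions taken where more than one
reasonable construction exists.

# Differential methylation

## Per-CpG model

Replicate counts are pooled within each sample group at every CpG, smoothed
with a coverage-weighted boxcar (window `smoothing_span = 500` bp, the CpG
always included in its own window), and compared with a pooled
two-proportion z-test with continuity correction. A CpG is a *candidate*
iff `|diff| >= delta_site` (0.1) and `p <= p_site` (0.001).

This is an intentional simplification: a beta-binomial shrinkage model (as
in dedicated WGBS packages) borrows strength across replicates and
positions; here replicate dispersion is ignored by pooling. The candidate
layer is only a pre-filter — the inference the pipeline reports happens at
the region level, whose parameters are the published ones. Consequences of
the simplification are measured, not assumed: on null simulations (no
planted KO effect, 1000 regions) the false DMR fraction stays below twice
the nominal region-level threshold (see `test-acceptance.R`).

Smoothing is applied to pooled group counts rather than per sample; with
per-sample smoothing the pooled fraction would be a coverage-weighted
average of the same quantities, and on data of this coverage the difference
is negligible relative to the region-level thresholds.

## Segmentation

Candidate CpGs are grouped into maximal same-sign runs whose consecutive
gaps are at most `dis_merge = 100` bp. A run is a DMR iff it has at least
`min_cg = 5` CpGs, `|mean diff| >= delta_region` (0.2), and its combined
p-value is at most `p_region = 0.05`. The region p-value is a Stouffer
combination of the member-CpG z-scores, `z = sum(z_i)/sqrt(n)` — member
CpGs are close enough to be positively correlated after smoothing, so this
p-value is anti-conservative at the margins; the delta and `min_cg` gates
dominate in practice. All thresholds are inclusive (`>=`/`<=`), and all
interval arithmetic is 0-based half-open with "overlap" meaning at least
one shared base pair — combining DMR sets therefore collapses only truly
overlapping intervals; abutting intervals remain distinct.

## Coverage filters and trajectory clustering

CpGs below 5x in any sample are dropped before region averaging; DMRs whose
mean coverage over the remaining CpGs is below 10x in any sample are
removed. (For amplicon-style BSAS data the same pipeline applies with the
CpG threshold raised to 10x.) Per-DMR, per-stage methylation is the pooled
percentage over eligible CpGs.

DMR trajectories (regions × stages) are standardised **per stage column**
(R's `scale`) before K-means (100 restarts, seeded). Column standardisation
— rather than per-region z-scoring — is deliberate: per-region scaling
erases level information and makes a medium-gain trajectory
(0.1 → 0.7) indistinguishable from a high-gain one (0.1 → 0.9), whereas the
dynamics classes of interest differ exactly in that level. Clusters are
relabelled deterministically by post-ESC gain (ascending gain among gaining
clusters, then losing clusters), so `clusterI` = medium gain, `clusterII` =
high gain, `clusterIII` = demethylated at the default `k = 3`.

KO-vs-WT DMRs are classified by interval overlap with the WT time-course
clusters; a DMR overlapping none is `stable_in_WT`. Where a DMR overlaps
two WT clusters the **largest base-pair overlap** wins — a choice the
underlying procedure leaves open; ties of this kind are vanishingly rare at
realistic DMR sizes. Direction is `hypo` iff the KO mean over the region is
below the WT mean.

# Differential expression

Counts are normalised to RPKM using an effective library size = raw depth ×
a median-of-ratios composition factor (factors normalised to geometric mean
1; identity fallback below 50 usable genes). Genes with ≥ 1 RPKM in ≥ 2
samples count as expressed. Three threshold classes gate the contrasts, all
inclusive, with Benjamini–Hochberg FDR: time-course |log2FC| ≥ 1.5 at
FDR ≤ 0.001; pairwise |log2FC| ≥ 1 at FDR ≤ 0.05; rescue |log2FC| ≥ 0.5 at
FDR ≤ 0.05. Log2 fold changes use group means of abundance + 1.

The tests are log-scale stand-ins for a count GLM: a one-way F-test on
`log2(rpkm + 1)` across condition-stage groups for the time course, and a
two-sample t-test for pairwise contrasts. The pairwise default is the
**pooled-variance Student t**, not Welch: with two replicates per group the
Welch–Satterthwaite degrees of freedom collapse toward 1, and the resulting
p-value floor (~`1/t^2`) cannot reach the FDR thresholds at any effect
size; the pooled test keeps `n_a + n_b - 2` df, and under the pipeline's
shared count-noise model equal group variances are the natural assumption.
Welch remains available (`var_equal = FALSE`). Type-I error of the default
is verified ≤ 2× nominal on 10^4 null genes.

"Upregulated in the KO" (used for target calling and TF evidence) means
passing the pairwise thresholds with positive log2FC in **at least one
post-ESC contrast** (union over EpiLC/ME24/ME48); the stage-specific
alternative is available by passing a single contrast. Expression-profile
K-means uses `centers = 4`, `iter.max = 25`, `nstart = 100` on per-gene
z-scores across samples, with a within-SS sweep reported as the elbow
diagnostic for `k`.

# Regulatory annotation

Peaks within `stitch_bp = 12500` of each other are merged (signal summed)
after removing peaks wholly inside TSS ± 2500 bp; both constants are the
conventional rank-ordering defaults for super-enhancer calling, and
promoters are TSS ± 2 kb — none of these is dictated by the data model, so
they are exposed in `analysis_config()`. Stitched regions are ranked by
signal; with rank and signal scaled to the unit square, the super-enhancer
cutoff sits where the tangent slope reaches 1, computed as the point of
largest vertical gap below the diagonal — invariant to uniform signal
scaling by construction. A flat curve yields no super enhancers; fewer than
three regions yields all-typical with a warning.

Annotation enrichment re-places each query interval uniformly at random on
its own chromosome (lengths preserved), `n_samplings = 1000` times, against
a whole-genome workspace (a mappability-restricted workspace can be passed
instead). Intervals are placed **independently** — two null intervals may
overlap — and overlap is accumulated per query interval via cumulative
coverage lookups, which makes all samplings vectorisable; for sparse
queries such as DMR sets this is equivalent to non-overlapping placement in
expectation, and the empirical null calibration is tested (≤ 2× nominal
q-rate over repeated random feature sets). Empirical two-sided p-values use
the add-one correction and are BH-adjusted across features.

Region–gene association offers the 100 kb TSS window rule (inclusive at
exactly 100 kb; distance in base pairs between the TSS and the nearest
region base) and the basal-plus-extension rule (basal TSS −5 kb/+1 kb
strand-aware, extended up to 100 kb but stopping at neighbouring basal
domains).

# Integration and network

A target gene is the exact conjunction of three predicates: ≥ 1 associated
KO-hypomethylated DMR within the association window; that DMR overlapping a
regulatory region active at any stage; upregulation in the KO. Timing
groups take the post-ESC stage of largest KO−WT difference on the
**log2 scale** (the linear scale is available via `log_scale = FALSE`);
ties break toward the earlier stage, consistent with a priming
interpretation in which the earliest divergence is the informative one.

Multi-block factor analysis standardises each block's columns, divides each
block by its first singular value and runs a global PCA on the
concatenation — so each block contributes unit top variance and uniform
rescaling of a block cancels exactly.

The network backbone is the union of a curated edge source with the
coexpression ∩ ChIP-seq intersection of an evidence-labelled source; edges
survive only if both endpoints are time-course DEGs. A TF is `direct` iff
upregulated in KO **and** downregulated on re-expression **and** associated
to a KO-hypomethylated regulatory DMR. Out-degree ties break
lexicographically; the top-1% flag is computed over all network nodes
(configurable to TFs only). TF activity is one-sided (greater) Fisher
enrichment of the TF's targets among KO-vs-WT DEGs over all expressed genes
(the network-restricted universe is a parameter), reported with BH-FDR
alongside raw p.

# The synthetic-data generator

`simulate_all()` emulates the study conditions with planted truth; its
defaults are the package's fixed reference conditions, chosen once to be
realistic for clonal cell lines in this design, and used unchanged by the
tests and the acceptance script:

* **Methylome** — 300 regions of 10 CpGs (40 bp spacing) in five dynamics
  classes (30/20/20/20/10% stableLow/stableHigh/gainMedium/gainHigh/
  demethylated), stage means 0.1/0.85, 0.1 → 0.7, 0.1 → 0.9 and 0.8 → 0.2
  with the transition at EpiLC; 50% of gain regions fail in the KO (frozen
  at the ESC mean). Counts are beta-binomial (overdispersion ρ = 0.02, so
  region means dominate) over Poisson coverage (mean 15x); n = 2
  biological replicates per condition and stage.
* **Expression** — negative-binomial counts (size 100, i.e. dispersion
  0.01, typical of clonal lines) over log-normal baselines; four planted
  archetypes (75 genes each) and one derepressed target gene per KO-failing
  region with a log2 effect of 4 (8–16-fold derepression of a silenced
  gene) from its timing stage onward. The rescue arm (`KO_3B`) restores the
  WT program; the empty-vector arm tracks the KO.
* **Geometry** — target-gene TSSs sit within ±50 kb of their region; all
  other genes are placed > 110 kb from every KO-failing region, so the
  100 kb association window is informative by construction.
* **Peaks and network** — peaks cover every dynamic region plus background,
  with a Pareto-tailed signal component on ~4% of peaks creating the
  super-enhancer subset; 30 TFs of which 3 are direct (drawn from the
  target genes), with the first a hub holding ~1.5× the edges of any other
  TF, ~90% of them aimed at KO-upregulated genes; decoy edges appear only
  in coexpression sets so the backbone intersection rule must drop them.

What the generator does **not** emulate — and what green tests therefore do
not establish about real data: read-level artefacts (mapping, bisulfite
conversion, M-bias), replicate-level biological dispersion in methylation
(pooling is exact here by construction), batch effects, non-CpG
methylation, overlapping genes and enhancer–promoter ambiguity, and
database noise in the TF edge sources beyond the planted decoy class.
Recovery rates of 1.0 on synthetic defaults indicate the pipeline is
correct and well-calibrated under its stated model, not that real-data
performance will match.

# Numerical conventions

* All genomic intervals 0-based half-open; overlap = ≥ 1 shared bp.
* All thresholds inclusive.
* Every stochastic step draws from a stream-specific seed derived from the
  single configuration seed; k-means restarts run under `with_seed` so they
  never perturb the caller's RNG state. Identical configuration ⇒
  bit-identical run directories (md5-verified manifests).
* Zero-coverage CpGs are excluded from testing (counted); zero-variance
  genes get p = 1 when means agree; empty annotation features report NA
  ratios; degenerate enhancer inputs (< 3 regions, flat signal) fall back
  to all-typical.
* Pipeline stages communicate strictly through plain-text files, which is
  what makes the resume-after-deletion contract exact.

# Problem sizes

The shipped tests run the default configuration (300 regions / 1200 genes)
for recovery checks, 5000 genes / 1000 regions for null calibration, 100
reduced-size seeded runs (700 genes, 100 regions) for the hub-TF
reproduction rate, and 1000 random tables/interval sets for the exact
oracle comparisons; these sizes keep the full suite under a few minutes on
one CPU while leaving every estimate's Monte-Carlo error well inside the
asserted margins.
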