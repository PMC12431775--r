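---
title: "Linking chromatin features to genes and integrating TF-binding evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking chromatin features to genes and integrating TF-binding evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccrelink)
```

## The problem

During bifurcation of a neuronal lineage — here modelled on the rhombomere-1
rV2 domain, where common precursors split into GABAergic and glutamatergic
branches — selector transcription factors (TFs) choose between the two
fates. Identifying *which* regulatory elements drive a selector gene, *which*
TFs act on those elements, and *which* genes the selector TFs in turn
control requires integrating four layers of single-cell multiome evidence:

1. **Accessibility-expression linkage.** A chromatin feature is a candidate
   cis-regulatory element (cCRE) of a gene when its per-cell accessibility
   correlates with the gene's expression. The search is restricted to the
   topologically associating domain (TAD) containing the gene's TSS, since
   enhancer-promoter contacts rarely cross TAD boundaries.
2. **TF footprints.** A motif site with a positive footprint score in a cell
   group is treated as bound there.
3. **Sequence conservation.** Functional binding sites tend to be conserved;
   sites are scored by a PWM-weighted mean of per-base conservation.
4. **CUT&Tag occupancy.** Antibody-directed peaks corroborate footprints.

`ccrelink` implements these computations as composable functions, plus a
synthetic multiome generator with planted ground truth so that the whole
chain is testable end to end without any external download.

## The linkage statistic

For feature $f$ and gene $g$, over the cells shared by the accessibility and
expression matrices,

$$\rho_{fg} = \mathrm{Spearman}(a_f, e_g), \qquad
  z_{fg} = \frac{\rho_{fg} - \overline{\rho}_{bg}}{\mathrm{sd}(\rho_{bg})},$$

where $\rho_{bg}$ are the correlations of background features with the same
gene, and the two-sided p-value is the normal tail of $z$. Features with
$|z| > 2$ and $p < 0.05$ inside the gene's TAD are its cCREs; the stricter
$p < 0.01$ is used in target calling. Thresholds are strict inequalities
throughout.

**Background construction** is the one genuinely open design point: the
background-standardised score is well defined only relative to a background
population. We draw 200 features from the query feature's chromosome,
ordered by the summed absolute difference in deciles of mean accessibility
and of width; ties at the cutoff are resolved by a seeded random draw. This
keeps the background matched on the two covariates that most influence
correlation magnitude while remaining fully reproducible. GC matching would
require sequence, which the pipeline deliberately does not consume.

p-values come from the normal tail of $z$ rather than a permutation: the
joint $|z|$/p thresholds used everywhere in the analysis imply that pairing,
and it keeps the statistic deterministic.

## Regulators, targets, and their null

A TF is a **regulator** of a selector gene in a cell group when some motif
site of that TF inside one of the gene's cCREs (i) has a strictly positive
footprint in the group, (ii) has PWM-weighted conservation > 0.5, and
(iii) the TF gene's mean log1p expression in the group is > 1.2. An
optional fourth filter (feature accessibility > 0.06) is off by default: in
the source analyses that filter applies to footprint dot-plot display, not
to the regulator conditions. The weighted conservation of a site of width
$w$ is $\sum_j w_j c_j / \sum_j w_j$ with $w_j$ the maximum nucleotide
probability of PWM column $j$ (columns reversed on the minus strand —
complementing is unnecessary because only column maxima are used) and $c_j$
the per-base conservation, 0 where the track is silent.

A gene is a **target** of a selector TF when some feature in the gene's TAD
jointly satisfies the bound-footprint (in GA1_2 or GL1_2), linkage
($|z|>2$, $p<0.01$), conservation (> 0.5), and CUT&Tag-overlap (≥ 1 bp)
conditions. Every condition can be toggled, and relaxing any one provably
enlarges the call set — a property the test suite asserts.

The significance of a three-way regulator overlap is assessed by drawing,
per iteration, three uniform without-replacement sets of the observed sizes
from the candidate-regulator universe and counting intersections at least
as large as observed. With $N = 10^6$ iterations and zero exceedances the
reported value is the upper bound $1/(N+1)$, flagged as a bound. The
universe is an explicit input: the analysis does not presume whether it
should be all motifs or all expressed TFs.

## Two-edge GSEA

Targets are projected onto the GA1_2-vs-GL1_2 log2 fold-change axis
(Wilcoxon rank-sum per gene, Bonferroni-adjusted p < 0.01, expressing
fraction ≥ 0.1 in either group). Because both ends of this axis are
informative, leading edges are read from both: edge A is the set members at
or before the running-sum maximum, edge B those at or after the minimum.
The classic unweighted running sum (hits $+1/|S|$, misses $-1/(n-|S|)$) is
used for determinism; a weighting exponent is exposed but defaults to 0.

## Other numerical choices

- **Coordinates** are 0-based half-open (BED) everywhere; overlap requires
  ≥ 1 shared base; touching intervals do not overlap.
- **Nested TADs**: a TSS inside several TADs is assigned the smallest one —
  the most specific domain; upstream TAD maps usually make this moot.
- **Conservation enrichment** classifies every base of a chromosome as
  conserved (score ≥ 0.5, "at least") × in-region (regions flattened so no
  base is double-counted) and uses the two-sided minimum-likelihood Fisher
  test; a zero off-diagonal cell flags the odds ratio as undefined while
  the p-value is still returned. Two-sided was chosen because the claims of
  interest are bidirectional (features fall between exons and introns); the
  direction can be read off the odds ratio.
- **Distance bins** for nearest linked features are half-open at 5 kb and
  50 kb; the distance is measured from the TSS to the nearest feature edge
  (0 inside the feature).
- **Expression variability** across the lineage is the standard deviation
  of per-cell-group mean expression. Variance or CV would order genes
  similarly; SD keeps the units of log1p expression.
- **log2FC** uses de-logged group means with a +1 pseudocount; Bonferroni
  is the default adjustment (mirroring the upstream single-cell DE tool),
  Benjamini-Hochberg is available.
- **Laminar quantification**: the ventricular surface is the circumcircle
  of three manually picked points; the average cell diameter is the mean
  equivalent-circle diameter $2\sqrt{A/\pi}$ over ROIs; cells apical to the
  surface get negative distances and are flagged rather than dropped;
  background is zeroed (not removed) at the 0.25 quantile per channel per
  image so cell counts stay aligned across channels; replicate
  normalization divides by the per-replicate channel mean; trends use a
  centred sliding mean of window 12 that shrinks at the boundaries. The
  sliding mean stands in for display-time LOESS smoothing, which is a
  plotting concern.

## The synthetic generator

`simulate_bundle()` emulates the statistical structure the analyses assume,
with planted truth for recovery testing:

- TADs tile each chromosome; **one focal gene per TAD**. This is a
  deliberate simplification of real genomes: it makes planted regulator and
  target truth structurally identifiable (a site-bearing feature can only
  be linked, within its TAD, to its own planted gene), which is what exact
  zero-noise recovery tests require. Consequently the generator does not
  probe multi-gene TAD ambiguity, and passing tests say nothing about
  assigning features among several genes sharing a domain.
- Accessibility is a gamma baseline (mean 0.05) plus an activation
  increment (0.5) in a feature's active cell groups. Each planted gene has
  its own activation pattern anchored at GA1_2 or GL1_2; diversifying
  patterns keeps features of different genes only weakly correlated, so the
  matched background retains contrast. Negative-effect features are open in
  the mirrored branch — a repressive element accessible where the gene is
  off — which is what gives the planted link its negative sign.
- Expression couples to the signed sum of planted feature accessibilities
  through the saturating transform $E_{max} u/(u+K)$ (bounded, so log1p
  values stay realistic), plus gaussian noise. Intrinsic accessibility
  variation is signal, not noise: the "zero-noise" configuration zeroes the
  evidence-noise scales (expression, accessibility jitter, footprint) and
  makes CUT&Tag coverage exhaustive, but keeps the gamma variation.
- Footprint scores are positive draws where a site is planted bound (bound
  requires the TF expressed in that group) and non-positive draws —
  including exact zeros, so the strict > 0 rule is exercised — elsewhere.
- Conservation is a low-mean beta background over feature bases, elevated
  to the 0.55–0.95 band at planted functional sites (so weighted means are
  reliably above the 0.5 threshold) and capped below 0.45 at
  low-conservation decoys.
- CUT&Tag peaks cover each truly bound site with probability
  `cuttag_sensitivity` (default 0.9) plus Poisson false peaks
  (0.5 per Mb). Ground truth is derived from the realisation — an uncovered
  site's gene is *not* in the truth set — so imperfect sensitivity shrinks
  the truth rather than making it unrecoverable.
- Decoy sites fail exactly one condition each (low conservation, unbound,
  or silent TF), so every threshold is load-bearing in the recovery tests.

Default study conditions: 2 chromosomes x 2 Mb, 24 TADs, 600 features,
8 merged cell groups (PRO1_2 … GL5) x 40 cells, 6 TFs (3 GABAergic-branch
selectors, one early TF, one early+GABA TF, one silent decoy), 12 target
genes, link effect 1.0, positive:negative link ratio 2:1. The test suite
exercises these defaults and a compact variant (12 TADs, 360 features,
200 cells) where speed matters; problem sizes were chosen so that the
complete suite is a few minutes of desk-scale computation.

What the generator does **not** emulate: read-level sparsity and dropout,
GC and mappability biases, doublets, batch structure, correlated motif
families competing for one footprint, or chromatin biophysics. Recovery on
these bundles demonstrates the correctness of the evidence integration, not
the error rates to expect on real multiome data.

## Worked example

```{r example, eval = FALSE}
cfg <- synth_config(seed = 1)
bundle <- simulate_bundle(cfg)
res <- run_pipeline(bundle, out_dir = tempfile("ccrelink_run_"))
res$regulators          # per-selector, per-group regulator calls
res$overlap_tests       # permutation test of the three-way overlap
res$targets$TF1$targets # TF1 target genes with distance bins
```

The numbered scripts under `analysis/` run the same stages as a narrative
workflow and write their tables under `results/`.

## Known limitations

- The linkage background is matched on accessibility and width deciles
  only; with very few features per chromosome the matching degenerates
  toward "all other features".
- `identify_targets()` treats the TF-to-gene map as one motif per TF; motif
  families sharing sites are the caller's responsibility to disambiguate.
- The permutation overlap test models the three sets as exchangeable
  uniform draws; structured universes (e.g. expression-filtered) should be
  passed in explicitly as the universe.
- Conservation enrichment loads per-chromosome run tables into memory;
  whole-genome tracks at single-base resolution should be supplied per
  chromosome.
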