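---
title: "Methods: spatial domain profiling, registration and benchmarking"
author: "cortexmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial domain profiling, registration and benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexmap)
```

This vignette is the package's account of its statistical machinery: the
models, their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical and design choices made where the methodology
left genuine freedom.

## The analysis problem

Unsupervised clustering of Visium-style spot data in laminar tissue
(e.g. neocortex) yields *spatial domains*: groups of spots with a shared
expression profile. Three questions follow. What distinguishes each
domain molecularly? Which anatomical structure (cortical layer L1–L6,
white matter) does a data-driven domain correspond to? And how do
domains relate to cell types, disease gene sets, and ligand–receptor
(LR) signaling? `cortexmap` answers these downstream questions; it takes
the clustering itself, snRNA-seq preprocessing, and spot-deconvolution
algorithms as upstream black boxes whose outputs it consumes.

## Pseudo-bulk differential expression

### Why pseudo-bulk

Individual spots are shallow and spatially autocorrelated; treating them
as replicates overstates the effective sample size badly. Summing all
QC-passing spots of a (section, domain) group yields one deep profile
per group, and the tissue *section* becomes the replication unit — the
level at which biological variability actually enters. Groups with fewer
than `min_spots` (default 10) spots are dropped as unstable. Expression
is `log2(CPM + pseudocount)` on the pseudo-bulk library; the pseudocount
(default 0.5) bounds the log for zero counts and its exact value has
little influence at pseudo-bulk depth. Genes with nonzero counts in
fewer than `min_expr_frac` (default 0.1) of samples are excluded from
modeling — their log-expression is essentially a detection indicator and
the linear models below are meaningless for them.

### The three models

All three fit gene-wise least squares with a shared design on the
pseudo-bulk log-expression matrix:

* **enrichment** (one-vs-all): per domain *d*, `y_g ~ 1[domain = d] +
  donor`. The coefficient is the log2 fold-change of *d* against all
  other domains; its moderated t-statistic is the gene-level "currency"
  that registration correlates.
* **ANOVA**: F-test of the domain factor against the blocked
  intercept-only model — "does this gene vary across domains at all".
* **pairwise**: the enrichment contrast restricted to each unordered
  domain pair, signed a − b for the pair labeled `"a|b"` with domains in
  sorted order (so relabeling that flips the order negates t). This is
  the model that separates adjacent sublayers that one-vs-all contrasts
  blur.
* **position**: the ANOVA machinery with the section's
  anterior/middle/posterior position as the factor, for
  rostral–caudal-axis effects.

**Donor blocking.** Donors contribute shared intercepts (sample quality,
composition). The default blocks donor as fixed covariate columns —
estimable because every donor contributes multiple domains — which is
deterministic, fast, and exactly reproducible. A random-intercept
formulation would recover a little efficiency when donors are many; with
a handful of donors the fixed-effect version is the robust choice and
keeps the statistics exactly t/F distributed at `prior_df = 0`.

**Variance moderation.** With few sections per domain, per-gene variance
estimates are noisy and the t-statistics of low-variance genes explode.
We shrink per-gene residual variances `s²_g` (on `d` residual df) toward
their across-gene mean `s₀²` with a method-of-moments prior of `d₀`
degrees of freedom:

`s̃²_g = (d₀ s₀² + d s²_g) / (d₀ + d)`,

with t/F referred to `d + d₀` df. The default `d₀ = 4` is a mild prior —
about the information of four extra samples — appropriate for designs
with 20–60 pseudo-bulk samples. `d₀ = 0` disables moderation and
reproduces the textbook pooled-variance t and one-way F exactly (the
test suite pins this to 1e-8 against scratch oracles, and cross-checks
the moderated path against limma's linear-model algebra under the same
prior). Because `s₀²` is a plain mean rather than a fitted scaled-χ²
mode, the moderated statistics are mildly conservative when the true
variance distribution is heavy-tailed; calibration claims in the tests
therefore use the unmoderated statistics, whose null p-values are
exactly uniform under the model.

**Degenerate genes.** A gene constant across samples gets t = 0,
logFC = 0, p = 1 (not NA): constancy is evidence of no enrichment, and
NA would silently shrink multiple-testing families.

**Multiple testing** is Benjamini–Hochberg within each contrast family
(per domain, per pair, per F-test), matching the "FDR < 5%" convention
used when counting enriched genes.

## Spatial registration

Registration correlates a query clustering's gene-wise enrichment
t-vectors with a reference's (Pearson by default, Spearman by flag) over
the intersection of their gene universes (≥ 30 genes enforced;
optionally each reference domain's `top_n` genes). t-statistics, not
fold-changes, are correlated: they weight genes by evidence and are
comparable across studies with different depths.

The annotation rule is where the package makes an interpretive choice.
Given a cluster's reference correlations sorted decreasingly
c₁ ≥ c₂ ≥ …, the label starts at the top reference and appends reference
i+1 while

`(cᵢ − cᵢ₊₁) / cᵢ < merge_ratio` and `cᵢ₊₁ > 0`,

joining names with "/" (e.g. `"L2/L3"`). *Merge ratio* names a
threshold on the successive relative drop; the relative form makes the
rule invariant to positive rescaling of a row, which is the natural
requirement for a rule applied to correlation profiles of varying
overall strength, and the `cᵢ₊₁ > 0` guard keeps anti-correlated
references out of labels no matter how flat the tail is. Confidence is
*good* iff c₁ exceeds the cutoff (default 0.25). Typical practice uses
merge ratio 0.1 when annotating spatial domains and 0.25 when
annotating snRNA-seq clusters, whose correlation profiles are flatter —
both are arguments, not constants.

## Gene-set enrichment

For external (e.g. clinical DE) gene sets, each domain's enriched genes
(FDR < `fdr_cut`, t > 0) are tested by Fisher's exact test over the
universe of *modeled* genes — the background must be the genes that
could have been called enriched, not the genome. The odds ratio is the
sample cross-product (a·d)/(b·c) (reported as Inf/0 for empty cells,
no continuity correction), and the p-value the exact one-sided
hypergeometric tail (a two-sided option exists). BH across all
(domain, set) pairs.

## LR spatial mapping

* **SPM** (specificity measure): with x the vector of a gene's mean CPM
  across cell types, `SPM_i = x_i / ‖x‖₂` — the cosine between x and
  type i's unit vector. It is 1 for exclusive expression, 1/√n under
  uniform expression over n types, and ΣSPM² = 1 always.
* **Spot co-expression** uses raw counts > 0 for both partners: at spot
  resolution, joint presence is the usable proxy for potential
  contact-dependent signaling; normalization thresholds would add a
  tunable with no clear biological referent.
* The **domain test** compares, per domain, the per-section
  co-expression proportion against the mean of all other domains in the
  same section, then applies a one-sided paired t-test across sections
  (Wilcoxon by flag). Pairing by section removes section-depth effects,
  which dominate raw co-expression rates.
* The **colocalization network** takes each co-expressing spot's top-k
  (default 3) cell types by predicted count — "dominant" types — with
  ties broken by the prediction matrix's fixed type order, and scores
  each unordered type pair by co-occurrence count divided by the number
  of co-expressing spots. Counts versus proportions is immaterial per
  spot (they share the argsort); counts are used.

## Deconvolution benchmarking

The gold standard is image-derived: nuclei with 4-channel
immunofluorescence intensities (NeuN/OLIG2/GFAP/TMEM119) are classified
into neuron/oligo/astro/micro/other by a CART (Gini splits, default
depth 4 and minimum leaf 5 — enough to carve 5 classes on 4 features
without memorizing noise), then assigned to the nearest spot center
within `spot_radius` (exact ties to the lowest spot index, nuclei
outside all spots dropped and counted). The "other" class participates
in training — unlabeled nuclei exist in real panels — but is dropped
from metric comparisons.

Three complementary scores: (i) the *layer tally* — for each cell type,
the layer where its section-averaged mean predicted count peaks, matched
against an expected-layer table (defaults: `Excit_Lx → Lx`,
`Astro → L1`, `Oligo`/`OPC → WM`, `Inhib`/`Micro → any`); a strict tie
for the peak counts as no match for laminar types, while `any` types
have no laminar expectation to violate and always match; (ii) per
(section, type) Pearson r and RMSE against gold counts, averaged into
one r and one RMSE per method (zero-variance pairs excluded from the r
average); (iii) *resolution consistency* — section-wide totals per
broad class from a broad-resolution run versus a layer-resolution run
collapsed onto broad classes, which should agree exactly.

## The synthetic-data generator

The generator emulates exactly the features the pipeline's inferences
rely on, with everything a pure function of (config, seed):

* spots on a jittered grid in the unit square, layers as horizontal
  depth bands (L1–L6, WM), one ground-truth domain per layer;
* per-layer marker genes (default 20/layer of 2000) over-expressed
  `2^effect_size` (default 4×) in their layer;
* gene-shared donor lognormal intercepts (SD 0.2) — acting like donor-
  level library-size factors, they make donor blocking consequential
  without confounding domains;
* lognormal per-spot library sizes (SD 0.3, mean 1000 UMI — desk-scale,
  not sequencing-scale) and negative-binomial counts (dispersion 0.25),
  matching the overdispersion UMI data shows over Poisson;
* laminar cell-type compositions per spot (excitatory neurons by layer,
  astrocytes concentrated in L1, oligodendrocytes/OPCs in WM, microglia
  and inhibitory neurons diffuse), multinomial over ~3 cells/spot;
  deconvolution predictions as truth × lognormal noise; and nuclei with
  class-specific lognormal intensities whose separation parameter scales
  class distinctness down to complete overlap at 0.

Layer bands default to *equal* thickness. This is deliberate: with
unequal bands, pseudo-bulk groups carry systematically different spot
counts, their count-noise variances differ, and the pooled-variance
contrasts are then miscalibrated by construction — a property of
unequal-depth designs, not a bug the simulation should build in. Real
cortical layers do differ in thickness; on real data this is one reason
moderated statistics and section-level replication matter more than
nominal calibration.

What the generator does *not* emulate: spatial autocorrelation beyond
the layer bands (no smooth within-layer gradients), curvature of real
laminae, segmentation errors in nuclei, compositional (sum-constrained)
noise in deconvolution outputs, and ambient RNA. Passing tests
therefore demonstrate correctness of the statistical machinery under a
faithful null and a clean laminar signal — not robustness to every
artifact of real tissue.

## Numerical choices and degenerate inputs

* Gene-wise least squares via one QR per design, shared across genes;
  no per-gene model objects.
* Zero-variance t-vectors in registration correlate as 0 (with a
  warning) rather than NA, keeping the matrix complete for annotation;
  all-zero rows annotate as "unassigned"/poor.
* BH within family; FDR ≥ p always.
* Fisher's p uses the exact hypergeometric tail (`phyper`); the test
  suite checks it against a from-scratch log-choose summation to 1e-10.
* TSV serialization writes full double precision; round trips are
  lossless to ≥ 12 significant digits.
* All tie-breaks are deterministic and documented (lowest spot index
  for nucleus assignment, fixed type order for dominance, stable sort
  in annotation).

## Problem sizes in the tests

The test and acceptance runs use desk-scale studies chosen to make every
property measurable in seconds: 2–8 sections of 120–240 spots, 60–2000
genes, 10 replicate seeds for recovery and calibration claims (e.g.
registration recovery uses 6 sections × 3 donors × 2000 genes × 10
seeds; null calibration averages the p < 0.05 fraction over 10
simulations of 2000 null genes). These sizes give the claims their
stated precision — binomial SE for calibration, full recovery margins
for registration — while keeping the whole suite under a minute.

## Known limitations

* The fixed-effect donor blocking approximates, not implements, a mixed
  model; with many donors and unbalanced designs a random-intercept GLS
  would be preferable.
* The merge-ratio rule is one reasonable formalization of successive-
  drop merging; alternative formulations (absolute drop, gap statistics)
  would label borderline clusters differently.
* Moderated p-values are approximate by design; exact calibration holds
  for the unmoderated statistics.
* The CART gold standard inherits the immunopanel's limits: four
  markers cannot separate all fine types, so benchmark comparisons
  happen at the collapsed broad-class resolution.
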