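---
title: "Phylogeny-wide clade features for microbiome discrimination: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-wide clade features for microbiome discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cladeforest)
```

## The model

`cladeforest` treats every internal node of a rooted 16S phylogeny as a
feature. If clade $c$ has descendant-tip count $n_{sc}$ in sample $s$ whose
total tip count is $N_s$, the feature value is the relative abundance
$x_{sc} = n_{sc} / N_s$. Counts are accumulated in a single postorder pass
over the edge matrix in integer arithmetic and divided by $N_s$ only at the
end, so children's clade counts partition their parent's exactly and the
root column is identically 1. Multifurcations are kept as-is; tips are
excluded from the feature set by default (an `include_tips` flag restores
them for sensitivity analyses).

For each experimental criterion (niche, age, genotype, cage, mother) a
classification random forest is fitted on the clade matrix augmented with
indicator-encoded covariates for the *other* treatment factors, so each
forest is controlled for everything it is not predicting. Predictive
accuracy is out-of-bag (1 − OOB error at the final tree); importance is the
raw (unscaled) mean decrease in accuracy: the average over trees of that
tree's OOB accuracy minus its OOB accuracy after permuting the feature among
its OOB samples. We use the raw rather than the variance-normalised MDA
because all downstream use is rank-based and the raw quantity is the one
with a direct accuracy interpretation.

Each forest is paired with a negative control fitted on features where the
abundances were permuted **among clades within each sample**, independently
per sample. This removes true clade–label associations while preserving
every per-sample value distribution (e.g. structure induced by coverage).
Covariate indicators are design labels, not taxa, and are left intact in the
null model. Real and null OOB accuracies over replicate forest seeds are
compared by two-way ANOVA (criterion × arm) with per-criterion contrasts on
the pooled residual variance, Sidak-adjusted ($p_{adj} = 1-(1-p)^m$).

Unsupervised structure is summarised by Bray–Curtis and binary Jaccard
dissimilarities, 2-D non-metric multidimensional scaling (best of many
monotone-regression starts, Kruskal stress-1, judged against the
conventional 0.20 acceptability threshold), and PERMANOVA with sequential
(Type I) sums of squares over age, niche, genotype and all interactions.

## Phylogenetic-scale profiling

Where on the tree does discriminating signal live? Each clade is annotated
with its depth (number of edges on the root-to-node path, root = 0), its
summed branch-length distance from the root (reported as missing, never as
zero, when the tree has no branch lengths), and its abundance (total
descendant tip sequences over all samples). The stated "number of nodes
between clade and root" convention is ambiguous by ±1; edge count is a
monotone relabelling of any of its readings, so profiles are unaffected —
the convention is fixed and documented in the annotation output.

The importance-versus-scale profile smooths real and null MDA against
$\log_{10}(\text{axis} + 1)$ with locally weighted regression (span 0.75 by
default, degree 1) and puts pointwise confidence bands around each curve by
bootstrap resampling of clades (200 resamples, 95% bands by default). Raw
(clade, MDA) points are always retained and written untransformed; only
plotting applies a signed pseudo-log (asinh) to the MDA axis, since MDA can
be negative.

## The synthetic generator

The generator reproduces the statistical structure the analysis assumes, so
every stage is testable without any sequencing data:

* **Design** — 20 male mice, two genotypes (WT/KO) balanced overall and
  mixed within each of 8 cages nested in 5 mothers; two niches per mouse
  (40 samples); each mouse sampled at exactly one of two ages, so age is
  deliberately confounded with mouse, as in the motivating design where
  different mice were sampled at each time point. The layout is
  deterministic given the spec.
* **Tree** — Yule (pure-birth) topology with i.i.d. exponential branch
  lengths: standard, seedable, dependency-free.
* **Abundances** — a log-normal baseline proportion per tip
  (`baseline_sigma = 2`, giving the heavy-tailed rank-abundance profile
  typical of 16S data), shared across samples. Maternal and cage structure
  enter as additive log-scale random effects (`mother_sigma = 0.6`,
  `cage_sigma = 0.4`) on 12 clades drawn from depths 1–4: vertical
  transmission shapes broad community blocks, co-housing perturbs them.
  Planted treatment effects multiply all tips under chosen clades by a fold
  change in samples carrying the matching factor level; a factor with zero
  entries (genotype) carries no community effect. Independent per-sample,
  per-tip log-normal noise (`sample_sigma = 0.5`) represents biological and
  technical variation between samples of the same condition.
* **Depth** — per-sample totals are drawn from a truncated log-normal on
  [1892, 25681] whose *truncated* mean is calibrated by root-finding to
  10442, matching the reported per-sample sequencing depth; counts are then
  multinomial.

These sigmas were fixed once, as values that give cage/mother structure
strong enough to dominate casual analysis (the phenomenon the framework
exists to expose) while leaving planted two- to four-fold effects
recoverable; they were not revisited afterwards. With zero planted effects
and zero random effects all labels are exchangeable, which is what the
null-calibration tests rely on.

What the generator does **not** emulate: real taxon composition,
sequence-level error (no FASTQ), compositional correlations among unrelated
clades, or unequal litter sizes (cage-to-mother cardinality is configurable,
not fitted). Passing tests therefore demonstrate the machinery recovers
planted structure of the stated form — not that any particular real dataset
has that structure.

## Numerical and design choices

* **Preprocessing semantics** — "continuously aligned bases" is read as the
  longest run of consecutive non-gap characters (gaps are `-` and `.`);
  the filter report also records total aligned bases per sequence so the
  alternative reading can be audited. Coordinates are 1-based inclusive
  (trim window defaults 710–2800, length threshold 437: a run of exactly
  437 is kept).
* **Null-model reading** — abundances are shuffled among clades within each
  sample row (the "among taxa within samples" formulation), not across
  samples within a clade.
* **PERMANOVA** — add-one permutation p (never reported as 0), free row
  permutations, 999 by default and seeded; `exact = TRUE` enumerates all
  relabellings for n ≤ 7, where the p-value equals the exact permutation
  probability. Term order defaults to (age, niche, genotype, interactions)
  and is configurable.
* **NMDS** — first start from classical scaling, remaining starts random;
  convergence tolerances slightly tighter than common defaults so a
  perfectly embeddable configuration reports stress at numerical zero
  rather than stopping at a loose stress floor.
* **Forests** — `mtry = floor(sqrt(#features))`; desk default 1,000 trees
  (the reference scale of 100,000 is a flag away); the cost of fewer trees
  is quantified by `forest_size_reproducibility()`, whose size–correlation
  curve is summarised by a Monod fit $r(n) = an/(b+n)$ (initialised at
  $a_0 = \max r$, $b_0 = \mathrm{median}\ n$, $a$ constrained to $[-1,1]$,
  $b > 0$ with a boundary flag for degenerate constant input). No class
  rebalancing: the emulated design is balanced and the null forest carries
  the baseline.
* **Ties and determinism** — top-clade rankings break MDA ties by clade id;
  every stochastic step takes a seed, and the pipeline derives all stage
  seeds from one global seed, so identical configurations give identical
  outputs, byte for byte. The pipeline writes the simulated tree to disk
  and re-reads it before featurization so that internal-node ids on disk
  and in memory always refer to the same clades.
* **Covariates for cage/mother forests** — cage and mother are mutually
  confounded (litters are housed together), so neither is used as a
  covariate for the other; their covariate set is {niche, age, genotype}.

## Problem sizes

The shipped tests exercise the oracle-equivalence and invariant checks on
hundreds of random trees of up to 50 tips; forest calibration on a
2,000-tip tree (40 samples, 6 replicate 1,000-tree forests per criterion
and arm); profile recovery on a 500-tip tree; and the validation suite at
forest sizes 50–5,000 over 20 replicate simulations. These sizes were
chosen so the full suite runs comfortably on a laptop while leaving all
qualitative conclusions scale-stable; the same code ran unchanged at larger
sizes during development.

## Known limitations

* OOB accuracy on 40 samples is quantised in steps of 0.025; comparisons
  should always be made across replicate forest seeds, as
  `compare_real_null_accuracy()` does.
* In a mixed-genotype, co-housed design, a criterion with no true effect
  can score *below* its null control: a sample's out-of-bag neighbours are
  its cage-mates, which are enriched for the opposite genotype in balanced
  cages. The meaningful claim for a null factor is "no better than the
  control", not "equal to it".
* Planted fold changes propagate: every descendant of a planted clade
  carries the same relative shift, and ancestors carry a diluted one in
  proportion to the planted clade's share of their abundance. Scale
  localization is therefore sharpest for planted clades that are a minor
  share of their parent.
* The smoother's confidence bands reflect clade resampling only; clades are
  phylogenetically dependent, so the bands understate uncertainty near
  depths populated by few independent lineages.
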