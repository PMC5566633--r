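---
title: "Methods: expression evolution across spider silk glands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression evolution across spider silk glands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silkshift)
```

# The scientific problem

Cobweb-weaving spiders carry seven functionally distinct silk gland types —
major ampullate (MA), minor ampullate (MI), aciniform plus flagelliform
(Ac+F), tubuliform (Tu), pyriform (Py), and the anterior and posterior
aggregate glue glands (AG-ant, AG-post). The glands are serial homologs, and
the genes most strongly expressed in them tend to belong to multi-paralog
families, so they are a natural system for asking how tissue-specific
expression evolves and whether shifts of expression between tissues are
coupled to gene duplication.

silkshift implements the complete comparative pipeline for a three-species
design (two *Latrodectus* species and *Steatoda grossa*, species tree
`((Lg,Lh),Sg)`, with seven silk gland types and three non-silk reference
tissues — cephalothorax, ovary, venom gland):

1. **Normalization** — TMM factors, CPM, FPKM, low-expression filtering,
   per-tissue mean profiles.
2. **OEST calling** — negative-binomial exact tests of pooled silk-gland
   libraries against pooled non-silk libraries; transcripts that are
   silk-overrepresented at FDR < 0.05 are *over-expressed silk transcripts*.
3. **Clustering** — Spearman-correlation dendrograms of transcripts and
   tissues, majority-rule gland assignment of transcript clusters,
   feature-resampling bootstrap support, PCA.
4. **Families** — aggregation of homologous transcripts (an input map) into
   cross-species families, per-family summed tissue expression, and
   eligibility filtering for tree analysis.
5. **Phylogenetic stage** — maximum-likelihood ancestral expression per
   tissue under Brownian motion on each gene tree, categorical node-state
   classification, duplication-versus-speciation transition testing with
   Fisher's exact test, and the Fritz–Purvis D-statistic for phylogenetic
   signal of binary expression traits.
6. **Synthetic data** — a generator that produces gene trees, evolved
   expression, and counts with known ground truth for every stage.

# Models and statistics

## Counts, normalization, FPKM

Counts are modeled as negative binomial with mean
$\mu = \mathrm{FPKM} \times L_e/10^3 \times N/10^6$
(effective length $L_e$ in bp, library size $N$ in fragments) and variance
$\mu + \phi\mu^2$. TMM factors are the classic trimmed mean of M-values:
M and A values against a reference library (the one whose upper-quartile
CPM is closest to the mean upper-quartile), trimming 30% of M and 5% of A,
weighting by inverse asymptotic variance, rescaled to geometric mean 1.
FPKM is normalized **multiplicatively** by the TMM factor — that is the
convention this pipeline reproduces; `compute_fpkm(..., apply = "divide")`
gives the more common alternative. Note that because the inverse-variance
weights see absolute counts, only the unweighted trimmed mean
(`tmm_factors(..., weighted = FALSE)`) is exactly invariant to rescaling a
library's depth; the weighted default moves by well under 5%.

## Dispersion and the exact test

The common dispersion maximizes the conditional (on per-gene group totals)
NB log-likelihood over pseudo-counts scaled to the geometric-mean effective
library size; with equal sizes the conditional distribution of replicate
counts is Dirichlet-multinomial, so the likelihood has a closed form.
Tagwise dispersions maximize the per-gene conditional likelihood plus
`prior_weight` (default 10 equivalent observations) times the average
likelihood across genes, over a fixed 301-point log grid from 1e-4 to 30 —
the grid resolution (~4% steps) is far below the sampling noise of
per-gene dispersion estimates. Library-size equalization uses simple
proportional scaling with rounding rather than quantile-adjusted
pseudo-counts; this preserves the conditional logic and is accurate at the
depths simulated here.

The exact test conditions on the pooled two-group total; the two-sided
p-value sums all outcomes whose conditional probability is at most the
observed one (minimum-likelihood convention, with the same 1e-7 relative
slack R's `binom.test` uses). At dispersion 0 the conditional law is
binomial, and the test agrees with the conditional binomial test to
numerical precision. Totals above 5e6 pseudo-counts fall back to a normal
approximation with a warning; nothing in the shipped tests or simulations
approaches that.

Replicate-free gland contrasts use a fixed dispersion of 0.4, the
conventional stand-in for the biological coefficient of variation in this
design; replicated contrasts use tagwise estimates.

## Expression-state classification

Each node (tip or ancestor) carries a per-tissue FPKM vector. A node is
`NOT_SILK` unless its unweighted mean over silk-gland tissues strictly
exceeds twice its mean over non-silk tissues. Silk-specific nodes are
assigned the gland holding strictly more than 50% of the silk-tissue FPKM,
else `MULTIPLE`. Conventions chosen where the rule is silent: the share
denominator is silk-tissue FPKM only (switchable in principle, but the
silk-only reading matches "majority of expression among glands");
a zero non-silk mean with positive silk expression counts as silk-specific;
0/0 is `NOT_SILK`; negative ML reconstructions are floored at zero at
classification time only, leaving raw estimates untouched in output.

## Ancestral states under Brownian motion

Per tissue, ancestral FPKM is the maximum-likelihood state under Brownian
motion, computed by exact Gaussian message passing: a postorder pass
combines child messages by inverse-variance weights, a preorder pass
propagates the complementary information, and each internal node's estimate
fuses its three incident messages. Because the weights depend only on
branch lengths, one prepared tree reconstructs all tissues (and all
D-statistic null replicates) by matrix arithmetic. The result equals the
GLS solution with the BM tree covariance; the acceptance suite verifies
agreement with an explicit covariance-inversion oracle to 1e-8 on random
trees. Zero-length branches are replaced by 1e-6 times tree depth.
Reconstruction runs on raw mean FPKM, not log FPKM — faithful to the
analysis being reproduced, even though the generator evolves log
expression; this mismatch is deliberate and noted under limitations.

## Transitions and the Fisher test

Every branch inherits the event type (duplication or speciation) of its
parent node; a branch is *changed* when parent and child states differ.
Pooled over trees, each tested category (any change, or a change into a
specific gland state) forms a 2x2 table of parent event against
changed-into-category, tested two-sided by hypergeometric enumeration
(`stats::fisher.test`, whose minimum-likelihood convention is exactly the
one specified) with Bonferroni correction over the categories tested in
that run. The exact test is the right choice because duplication and
speciation node counts are strongly unbalanced and several change
categories are rare.

**A known smearing effect**: when a planted expression shift sits on a
short branch, ML-BM reconstruction (which assumes no shifts) pulls the
parent node toward the shifted value, so the detected change can relocate
to the parent's incoming edge. Empirically ~60% of random planted shifts
are detected strictly on their own branch, and ~99% on the branch or its
parent edge. The recovery property test counts the latter; the Fisher
calibration is unaffected because relocation does not systematically favor
either event type under the null.

## D-statistic

For a binary tip trait, $d$ is the sum over internal nodes of absolute
sister-clade differences of the continuous BM reconstruction of the 0/1
trait (the same message-passing machinery, branch-length weighted). The
permutation null shuffles tip labels preserving prevalence; the BM null
simulates Brownian tips and marks the top-$k$ tips at the observed
prevalence. Then
$D = (d_{obs} - \bar d_{BM}) / (\bar d_{rand} - \bar d_{BM})$,
so $D \approx 1$ for phylogenetically random traits and $D \approx 0$ for
BM-like clumping. Constant traits are degenerate (flagged, no D). Traits
are tip-based; assigning states to internal nodes for the D-statistic is
not standard and is not done here. Defaults of 1000 replicates per null
are reduced to 200 in desk-scale calibration runs.

# The synthetic world

`generate_study()` emulates the study design: species tree
`((Lg:1,Lh:1):1,Sg:2)`, seven silk glands plus three non-silk tissues, two
replicates per tissue except the pyriform and anterior aggregate glands
(replicate-free, exercising the fixed-0.4 dispersion path), and ~1e7
fragments per library (jittered ±15%).

* **Gene trees** arise from a birth–death process along the species tree
  (defaults: duplication 0.3, loss 0.1 per lineage per time unit); every
  internal node is labeled duplication or speciation by construction, and
  trees missing a species are resimulated. With loss 0 the process is
  Yule, giving the closed-form duplication-node expectation
  $3e^{2\lambda} - e^{\lambda} - 2$ used as a Monte-Carlo oracle in tests.
* **Expression** evolves by BM on `log(FPKM + 1)` (variance
  `bm_sigma2 x` branch length, default 0.05), back-transformed and floored
  at zero — BM is unbounded but FPKM cannot be negative. Root profiles are
  tissue-flat (a single lognormal baseline per family), so silk
  specificity arises only from planted shifts: at a shift branch the
  target gland's FPKM is multiplied by the effect size (default 16) after
  the BM step. Duplications copy the parent state instantaneously; truth
  states are derived from truth profiles with the same classification
  rule, so planted truth is self-consistent by construction.
* **Counts** are NB with replicate-level dispersion 0.4. Background
  transcripts (300 per species) are tissue-flat; 30 of them are planted
  OESTs with a 10-fold silk boost.
* Tissues evolve independently; real silk transcriptomes have correlated
  tissue programs, co-regulated paralogs, and library-specific technical
  structure that this generator does not emulate. A green test therefore
  establishes that the machinery is correct and calibrated under its own
  assumptions — not that the biological conclusions of any particular
  dataset follow.

A single RNG stream drawn in fixed order (trees, then per-family
expression, then per-species backgrounds and counts) makes the bundle
byte-reproducible under a seed.

# Design choices made where the method was open

* Linkage for correlation dendrograms defaults to average (UPGMA),
  configurable; items are sorted by label before clustering so dendrograms
  are order-invariant.
* Cutting into k groups undoes the k-1 highest merges; k defaults to the
  number of assayed glands plus one.
* Constant profiles get correlation 0 (with a warning) instead of being
  dropped, keeping matrices complete.
* Bootstrap resamples features (transcripts), never tissues; clade
  identity is the unordered tip set.
* PCA is centered, unscaled, on raw mean FPKM (log transform exposed to the
  caller by transforming the input); signs fixed so each component's
  largest-magnitude loading is positive.
* OEST calling uses tagwise dispersions by default (`dispersion =
  "common"` switches); the dispersion grouping is silk versus non-silk,
  which pools heterogeneous gland types and therefore produces large
  common dispersions (CV² well above 1) on real-shaped data.
* Family eligibility for tree analysis requires, **in every species**, at
  least one member transcript that is both 2-fold silk-overexpressed and
  has mean FPKM > 1 in some tissue (both conditions in the same
  transcript); `per_species = FALSE` relaxes to any species.
* All 2-fold and majority thresholds are strict inequalities.

# Limitations

* No Ornstein–Uhlenbeck or multi-rate models; BM only, per tissue,
  ignoring within-species variance.
* Tree inference and homology inference are out of scope: gene trees and
  family maps are inputs (events can be imputed by species overlap when
  NHX flags are missing).
* The generator evolves log expression while inference reconstructs raw
  FPKM; this deliberate mismatch mirrors the analyzed pipeline and means
  ancestral states are not unbiased estimates of the generator's latent
  values.
* The exact test equalizes library sizes by rounding-scaled pseudo-counts,
  a simplification of quantile adjustment.
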