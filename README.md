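# silkshift

Comparative transcriptomics of spider silk glands: how tissue-specific gene
expression evolves across the seven serially homologous silk gland types of
cobweb-weaving spiders, and whether expression shifts between gland types
are coupled to gene duplication.

The package is aimed at researchers analyzing multi-tissue RNA-seq across a
small species phylogeny with multi-paralog gene families. It implements, as
a tested and reusable pipeline:

* **Normalization** — TMM factors, CPM, FPKM
  (count / (effective kb × millions of aligned fragments), TMM-scaled),
  low-expression filtering, per-tissue mean profiles.
* **OEST calling** — negative-binomial exact tests (conditional on pooled
  totals, Dirichlet-multinomial dispersion estimation) of pooled silk-gland
  versus pooled non-silk libraries; *over-expressed silk transcripts* are
  silk-overrepresented at FDR < 0.05. Replicate-free gland contrasts use a
  fixed dispersion of 0.4.
* **Clustering** — Spearman (1 − ρ) dendrograms of transcripts and tissues,
  strict-majority gland assignment of transcript clusters, feature-bootstrap
  clade support, centered PCA.
* **Gene families** — cross-species family aggregation (summed mean FPKM per
  species and tissue), OEST sharing classes, tree-analysis eligibility.
* **Phylogenetic stage** — maximum-likelihood ancestral expression per
  tissue under Brownian motion (exact Gaussian message passing, equal to the
  GLS solution), node-state classification (NOT_SILK / one of seven glands /
  MULTIPLE), duplication-vs-speciation transition tests (Fisher exact,
  Bonferroni), and the Fritz–Purvis D-statistic
  `D = (d_obs − mean d_BM) / (mean d_random − mean d_BM)` for binary
  expression traits.
* **Synthetic data** — a generator producing gene trees (birth–death along
  the species tree), BM-evolved expression with planted gland-specific
  shifts, NB counts, and ground truth for every downstream stage.

See `vignettes/expression-evolution.Rmd` for the models, conventions and
design decisions.

## Worked example

```r
library(silkshift)

b   <- generate_study(seed = 7)            # default synthetic bundle
res <- analyze_study(b, n_perm = 200, n_bm = 200, seed = 1)

vapply(res$oests, function(d) sum(d$oest_flag), 0L)
#> Lg Lh Sg
#> 42 37 30

res$oests$Lg$common_dispersion[1]
#> [1] 0.488                                # generator's truth is 0.4

length(res$eligible)                       # families eligible for tree analysis
#> [1] 4

res$phylo$summary
#> $n_trees                 4
#> $frac_trees_with_change  1
#> $frac_branches_unchanged 0.655
#> $n_branches              58

res$phylo$fisher[res$phylo$fisher$category == "any", ]
#> category dup_changed dup_unchanged spec_changed spec_unchanged         p
#>      any          14            22            6             16 0.4082064
```

Read: 30 of the 300 background transcripts per species carry a planted
10-fold silk boost and the OEST caller recovers them (plus silk-shifted
family members); the common dispersion estimate sits near the simulated 0.4;
on the four eligible gene families, 65.5% of branches keep their ancestral
expression state, and with shifts planted uniformly on branches the Fisher
test finds (correctly) no duplication–speciation asymmetry (p = 0.41).

## Command line

```sh
Rscript inst/cli/silkshift.R simulate --seed 1 --out study/
Rscript inst/cli/silkshift.R normalize --dir study/ --species Lg --out norm/
Rscript inst/cli/silkshift.R de --dir study/ --species Lg --contrast gland:Py --out de/
Rscript inst/cli/silkshift.R analyze --dir study/ --seed 1 --out results/
```

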