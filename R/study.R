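#' Run the full analysis on a study bundle
#'
#' End-to-end orchestration of the pipeline on a synthetic bundle (or a
#' directory of real-data-mode input files): per-species TMM/FPKM
#' normalization and mean tissue profiles, OEST calling, two-fold flags,
#' family filtering/aggregation and tree eligibility, then the phylogenetic
#' stage (BM ancestral states, node classification, transition tallies,
#' Fisher tests, D-statistics) on the eligible families, plus
#' species-tissue clustering of family-summed expression.
#'
#' @param x a bundle from [generate_study()] or a directory readable by
#'   [read_study()].
#' @param silk,nonsilk tissue classes.
#' @param alpha OEST FDR threshold.
#' @param n_perm,n_bm D-statistic null sizes (desk-scale default 200).
#' @param seed optional seed for the D-statistic nulls.
#' @return List with `oests`, `profiles`, `flags`, `family_profile`,
#'   `sharing`, `eligible`, `phylo`, `tissue_clustering`.
#' @export
analyze_study <- function(x, silk = silk_gland_types(),
                          nonsilk = non_silk_tissues(), alpha = 0.05,
                          n_perm = 200, n_bm = 200, seed = NULL) {
  if (is.character(x)) x <- read_study(x)
  species <- names(x$counts)
  profiles <- list(); oests <- list(); flags <- list()
  for (sp in species) {
    cm <- x$counts[[sp]]
    f <- tmm_factors(cm)
    fpkm <- compute_fpkm(cm, f)
    profiles[[sp]] <- mean_tissue_fpkm(fpkm, cm$samples)
    oests[[sp]] <- call_oests(cm, silk, nonsilk, alpha = alpha)
    flags[[sp]] <- twofold_silk_flag(profiles[[sp]], silk, nonsilk)
  }
  map3 <- three_species_filter(x$family_map, species)
  famprof <- family_tissue_sum(map3, profiles)
  oest_sets <- lapply(oests, function(d) d$transcript[d$oest_flag])
  sharing <- oest_sharing_classes(x$family_map, oest_sets, species)
  eligible <- tree_eligibility(map3, flags, species)
  eligible <- intersect(eligible, names(x$trees))

  phylo <- NULL
  if (length(eligible)) {
    trees <- lapply(x$trees[eligible], function(tr) {
      if (anyNA(tr$node.event)) label_events_species_overlap(tr) else tr
    })
    tipprof <- lapply(trees, function(tr) {
      m <- t(vapply(seq_along(tr$tip.label), function(i) {
        profiles[[tr$tip.species[i]]][tr$tip.transcript[i], c(silk, nonsilk)]
      }, numeric(length(silk) + length(nonsilk))))
      rownames(m) <- tr$tip.label
      colnames(m) <- c(silk, nonsilk)
      m
    })
    phylo <- run_phylo_pipeline(trees, tipprof, silk, nonsilk,
                                n_perm = n_perm, n_bm = n_bm, seed = seed)
  }

  tissue_items <- t(famprof) # (species|tissue) x clusters
  clustering <- NULL
  if (nrow(tissue_items) >= 2 && ncol(tissue_items) >= 2) {
    corr <- spearman_matrix(tissue_items, warn = FALSE)
    clustering <- list(correlation = corr,
                       dendrogram = hierarchical_cluster(corr))
  }
  list(oests = oests, profiles = profiles, flags = flags,
       family_profile = famprof, sharing = sharing, eligible = eligible,
       phylo = phylo, tissue_clustering = clustering)
}
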