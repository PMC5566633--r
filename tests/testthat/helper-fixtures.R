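# Shared fixtures and independent oracles, built in code.

# small hand count matrix: 5 transcripts x 4 libraries, one species
toy_count_matrix <- function() {
  counts <- matrix(c(100, 200, 100, 210,
                     50,  100,  50,  95,
                     10,   20,  10,  22,
                     500, 1000, 480, 1020,
                     0,    0,    5,   4),
                   nrow = 5, byrow = TRUE,
                   dimnames = list(paste0("t", 1:5), paste0("L", 1:4)))
  samples <- data.frame(library = paste0("L", 1:4),
                        species = "Lg",
                        tissue = c("MA", "MA", "Ceph", "Ceph"),
                        replicate = c(1, 2, 1, 2))
  count_matrix(counts, setNames(c(1000, 2000, 500, 1500, 800), paste0("t", 1:5)),
               samples)
}

# explicit GLS oracle for BM ancestral states: invert the full tree
# covariance and compute conditional means for every internal node
gls_asr_oracle <- function(phy, x) {
  ntip <- length(phy$tip.label)
  x <- x[phy$tip.label]
  d <- ape::node.depth.edgelength(phy)
  M <- ape::mrca(phy, full = TRUE)
  C <- matrix(d[M[seq_len(ntip), seq_len(ntip)]], ntip)
  Ci <- solve(C)
  one <- rep(1, ntip)
  mu <- as.numeric((one %*% Ci %*% x) / (one %*% Ci %*% one))
  vapply(ntip + seq_len(phy$Nnode), function(nd) {
    cv <- d[M[nd, seq_len(ntip)]]
    mu + as.numeric(cv %*% Ci %*% (x - mu))
  }, 0)
}

# naive average-linkage (UPGMA) agglomeration on a distance matrix,
# returning merge heights; independent of stats::hclust
naive_upgma_heights <- function(D) {
  groups <- as.list(rownames(D))
  d <- D
  heights <- numeric(0)
  while (length(groups) > 1) {
    diag(d) <- Inf
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    heights <- c(heights, d[i, j])
    gi <- groups[[i]]; gj <- groups[[j]]
    merged <- c(gi, gj)
    # distances to the merged group: size-weighted mean (UPGMA)
    newd <- vapply(seq_along(groups), function(k) {
      if (k %in% c(i, j)) return(NA_real_)
      (length(gi) * d[i, k] + length(gj) * d[j, k]) / (length(gi) + length(gj))
    }, 0)
    keep <- setdiff(seq_along(groups), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    groups <- c(groups[keep], list(merged))
  }
  sort(heights)
}

# transition-simulation harness used by phyloexpr and acceptance tests:
# simulates n_trees families, plants multiplicative shifts on a branch
# subset, runs the ASR -> classification -> tally -> Fisher stage
simulate_transition_dataset <- function(n_trees, shift_prob,
                                        shift_on = c("any", "duplication"),
                                        multiplier = 16, sigma2 = 0.02,
                                        design = study_design()) {
  shift_on <- match.arg(shift_on)
  trees <- list(); profs <- list(); n_shift <- 0
  for (i in seq_len(n_trees)) {
    tr <- simulate_gene_tree(design$species_tree, 0.3, 0.1)
    ntip <- length(tr$tip.label)
    cand <- tr$edge[, 2]
    if (shift_on == "duplication")
      cand <- cand[tr$node.event[tr$edge[, 1] - ntip] == "duplication"]
    sel <- cand[runif(length(cand)) < shift_prob]
    n_shift <- n_shift + length(sel)
    shifts <- if (length(sel))
      data.frame(node = sel,
                 tissue = sample(design$silk, length(sel), replace = TRUE),
                 multiplier = multiplier) else NULL
    root <- setNames(rep(rlnorm(1, log(5), 1), length(design$tissues)),
                     design$tissues)
    sim <- simulate_expression(tr, root, sigma2, shifts,
                               silk = design$silk, nonsilk = design$nonsilk)
    nm <- paste0("fam", i)
    trees[[nm]] <- tr
    profs[[nm]] <- sim$tips
  }
  res <- run_phylo_pipeline(trees, profs, silk = design$silk,
                            nonsilk = design$nonsilk, do_dstat = FALSE)
  list(result = res, n_shift = n_shift)
}
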