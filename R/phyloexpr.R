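# Ancestral expression states under Brownian motion, expression-state
# classification, duplication-vs-speciation transition testing and the
# Fritz-Purvis D-statistic.
#
# Ancestral states are computed by exact Gaussian message passing on the
# tree (a downpass combining child messages by inverse-variance weighting,
# then an uppass propagating the complementary information). Because the
# weights depend only on branch lengths, one prepared tree reconstructs any
# number of traits by matrix arithmetic; the result is identical to the GLS
# solution with the BM tree covariance.

# precompute traversal order and message weights for one tree
.bm_prep <- function(phy, eps_frac = 1e-6) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  n_all <- ntip + nnode
  bl <- phy$edge.length
  if (is.null(bl)) stop("branch lengths are required")
  if (all(bl == 0)) stop("all branch lengths are zero")
  eps <- eps_frac * max(ape::node.depth.edgelength(phy))
  bl[bl == 0] <- eps
  blen <- numeric(n_all)
  blen[phy$edge[, 2]] <- bl
  parent <- rep(NA_integer_, n_all)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  kids <- .children_list(phy)
  po <- unique(ape::reorder.phylo(phy, "postorder")$edge[, 1]) # parents, postorder
  root <- ntip + 1
  list(ntip = ntip, nnode = nnode, root = root, blen = blen,
       parent = parent, kids = kids, postorder = po,
       preorder = rev(po))
}

# ML node states for traits in the columns of X (tips x traits)
.bm_states <- function(prep, X) {
  X <- as.matrix(X)
  ntip <- prep$ntip; root <- prep$root
  n_all <- ntip + prep$nnode
  V <- matrix(0, n_all, ncol(X))
  V[seq_len(ntip), ] <- X
  w <- numeric(n_all) # variance of the downpass message at each node
  contrast_ss <- numeric(ncol(X))
  for (p in prep$postorder) {
    ch <- prep$kids[[p]]
    t1 <- w[ch[1]] + prep$blen[ch[1]]
    t2 <- w[ch[2]] + prep$blen[ch[2]]
    a <- t2 / (t1 + t2)
    V[p, ] <- a * V[ch[1], ] + (1 - a) * V[ch[2], ]
    w[p] <- t1 * t2 / (t1 + t2)
    contrast_ss <- contrast_ss + (V[ch[1], ] - V[ch[2], ])^2 / (t1 + t2)
  }
  # uppass: message from above each non-root node
  uv <- matrix(NA_real_, n_all, ncol(X))
  uw <- rep(NA_real_, n_all)
  est <- matrix(NA_real_, prep$nnode, ncol(X))
  est[root - ntip, ] <- V[root, ]
  for (p in prep$preorder) {
    ch <- prep$kids[[p]]
    for (k in 1:2) {
      c1 <- ch[k]; sib <- ch[3 - k]
      sv <- V[sib, ]; sw <- w[sib] + prep$blen[sib]
      if (p == root) {
        cv <- sv; cw <- sw
      } else {
        b <- uw[p] / (sw + uw[p])
        cv <- b * sv + (1 - b) * uv[p, ]
        cw <- sw * uw[p] / (sw + uw[p])
      }
      uv[c1, ] <- cv
      uw[c1] <- cw + prep$blen[c1]
      if (c1 > ntip) {
        g <- uw[c1] / (w[c1] + uw[c1])
        est[c1 - ntip, ] <- g * V[c1, ] + (1 - g) * uv[c1, ]
      }
    }
  }
  list(states = est, sigma2 = contrast_ss / prep$nnode)
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Reconstructs the ML value of a continuous trait (here, per-tissue FPKM)
#' at every internal node of a rooted binary tree, assuming Brownian
#' motion. Computed by pruning message passing; equal to the GLS solution
#' with the BM tree covariance. Zero-length branches are replaced by
#' `1e-6 x` tree depth. Several traits can be reconstructed at once by
#' passing a matrix.
#'
#' @param tree a [gene_tree()] or [ape::phylo] (rooted, binary, with branch
#'   lengths).
#' @param x numeric vector named by tip label, or a tips x traits matrix
#'   with tip rownames.
#' @return List with `states` (internal nodes x traits matrix; row `k` is
#'   node `Ntip + k`) and `sigma2` (REML rate per trait).
#' @export
bm_ancestral_states <- function(tree, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(names(x), NULL))
  if (!is.null(rownames(x))) {
    idx <- match(tree$tip.label, rownames(x))
    if (anyNA(idx)) stop("tip values missing for: ",
                         paste(setdiff(tree$tip.label, rownames(x)), collapse = ", "))
    x <- x[idx, , drop = FALSE]
  }
  if (nrow(x) != length(tree$tip.label)) stop("one value per tip required")
  if (!all(is.finite(x))) stop("tip values must be finite")
  .bm_states(.bm_prep(tree), x)
}

#' Classify a node's expression state
#'
#' A node is `NOT_SILK` unless its mean FPKM across silk-gland tissues is
#' strictly more than twice its mean across non-silk tissues; silk-specific
#' nodes are assigned the gland holding strictly more than half of the
#' silk-tissue FPKM, else `MULTIPLE`. Negative reconstructed values are
#' floored at 0 before classification.
#'
#' @param values named numeric vector (or matrix rows x tissues via
#'   [classify_profile_states()]), tissue -> FPKM.
#' @param silk,nonsilk tissue id sets.
#' @return A state string: `"NOT_SILK"`, a gland id, or `"MULTIPLE"`.
#' @export
classify_node_state <- function(values, silk = silk_gland_types(),
                                nonsilk = non_silk_tissues()) {
  silk <- intersect(silk, names(values))
  nonsilk <- intersect(nonsilk, names(values))
  if (length(silk) == 0 || length(nonsilk) == 0)
    stop("need at least one silk and one non-silk tissue")
  v <- pmax(values, 0)
  ms <- mean(v[silk]); mn <- mean(v[nonsilk])
  silky <- if (mn == 0) ms > 0 else ms > 2 * mn
  if (!silky) return("NOT_SILK")
  share <- v[silk] / sum(v[silk])
  if (max(share) > 0.5) names(share)[which.max(share)] else "MULTIPLE"
}

#' @rdname classify_node_state
#' @param profile rows x tissues matrix (rows may be nodes or transcripts).
#' @export
classify_profile_states <- function(profile, silk = silk_gland_types(),
                                    nonsilk = non_silk_tissues()) {
  out <- vapply(seq_len(nrow(profile)),
                function(i) classify_node_state(profile[i, ], silk, nonsilk), "")
  setNames(out, rownames(profile))
}

#' Tally expression-state transitions along branches
#'
#' One record per branch: the parent node's state, the child's state, and
#' the parent's event type (duplication or speciation, which the branch
#' inherits); `changed` marks parent != child.
#'
#' @param tree a [gene_tree()] with every internal node labeled.
#' @param states character vector of node states indexed by node number
#'   (tips first, then internal nodes).
#' @return data.frame of class `transition_tally` with one row per branch.
#' @export
tally_transitions <- function(tree, states) {
  ntip <- length(tree$tip.label)
  if (anyNA(tree$node.event)) stop("unlabeled internal nodes; label events first")
  if (length(states) != ntip + tree$Nnode)
    stop("states must cover every node")
  p <- tree$edge[, 1]; ch <- tree$edge[, 2]
  out <- data.frame(parent_state = states[p],
                    child_state = states[ch],
                    parent_event = tree$node.event[p - ntip],
                    row.names = NULL)
  out$changed <- out$parent_state != out$child_state
  class(out) <- c("transition_tally", class(out))
  out
}

#' Fisher's exact tests for event-coupled expression shifts
#'
#' For each tested category, builds the 2x2 table of parent event
#' (duplication vs speciation) against branches changing into that category
#' versus not, and applies the two-sided Fisher exact test (hypergeometric
#' enumeration, minimum-likelihood convention) with Bonferroni correction
#' over the categories tested. The category `"any"` tests changed vs
#' unchanged regardless of target state.
#'
#' @param tally a [tally_transitions()] result (rows may be pooled over
#'   trees).
#' @param categories target states to test; defaults to `"any"` plus every
#'   child state observed on a changed branch.
#' @param alpha significance level after Bonferroni.
#' @return data.frame with table cells, `p`, `p_bonferroni`, `significant`.
#' @export
fisher_event_association <- function(tally, categories = NULL, alpha = 0.05) {
  if (nrow(tally) == 0) stop("empty tally")
  if (is.null(categories))
    categories <- c("any", sort(unique(tally$child_state[tally$changed])))
  res <- lapply(categories, function(cat) {
    hit <- if (cat == "any") tally$changed else (tally$changed & tally$child_state == cat)
    dup <- tally$parent_event == "duplication"
    tab <- matrix(c(sum(dup & hit), sum(dup & !hit),
                    sum(!dup & hit), sum(!dup & !hit)),
                  2, 2, byrow = TRUE)
    p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warning("empty margin for category ", cat, "; p set to 1")
      1
    } else {
      fisher.test(tab)$p.value
    }
    data.frame(category = cat,
               dup_changed = tab[1, 1], dup_unchanged = tab[1, 2],
               spec_changed = tab[2, 1], spec_unchanged = tab[2, 2],
               p = p)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out$significant <- out$p_bonferroni < alpha
  out
}

# sum over internal nodes of |sister message differences| for each trait
# column; the D-statistic's d quantity
.d_sum <- function(prep, X) {
  X <- as.matrix(X)
  ntip <- prep$ntip
  V <- matrix(0, ntip + prep$nnode, ncol(X))
  V[seq_len(ntip), ] <- X
  w <- numeric(ntip + prep$nnode)
  d <- numeric(ncol(X))
  for (p in prep$postorder) {
    ch <- prep$kids[[p]]
    t1 <- w[ch[1]] + prep$blen[ch[1]]
    t2 <- w[ch[2]] + prep$blen[ch[2]]
    a <- t2 / (t1 + t2)
    d <- d + abs(V[ch[1], ] - V[ch[2], ])
    V[p, ] <- a * V[ch[1], ] + (1 - a) * V[ch[2], ]
    w[p] <- t1 * t2 / (t1 + t2)
  }
  d
}

#' Fritz-Purvis D-statistic for a binary tip trait
#'
#' Measures phylogenetic signal of a 0/1 trait: `D ~ 1` when the trait is
#' distributed as if shuffled across tips, `D ~ 0` when it is as clumped as
#' a thresholded Brownian trait. `d` is the sum over internal nodes of
#' absolute sister-clade differences of the continuous (BM message-passing)
#' reconstruction of the trait; the permutation null shuffles tips
#' preserving prevalence, and the BM null thresholds simulated Brownian tip
#' values at the observed prevalence.
#'
#' @param tree rooted binary tree with branch lengths.
#' @param trait named 0/1 vector (names = tip labels).
#' @param n_perm,n_bm null replicates (defaults 1000).
#' @param seed optional RNG seed.
#' @return List with `D`, `d_obs`, `mean_d_random`, `mean_d_bm`,
#'   `prevalence`, `degenerate`.
#' @export
d_statistic <- function(tree, trait, n_perm = 1000, n_bm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  if (ntip < 4) stop("need at least 4 tips")
  trait <- trait[tree$tip.label]
  if (anyNA(trait)) stop("trait missing for some tips")
  k <- sum(trait == 1)
  if (k == 0 || k == ntip)
    return(list(D = NA_real_, d_obs = NA_real_, mean_d_random = NA_real_,
                mean_d_bm = NA_real_, prevalence = k / ntip, degenerate = TRUE))
  prep <- .bm_prep(tree)
  perm <- vapply(seq_len(n_perm), function(i) sample(trait), numeric(ntip))
  # BM null: simulate tip values, mark the k largest as 1
  inc <- matrix(rnorm(nrow(tree$edge) * n_bm,
                      sd = rep(sqrt(prep$blen[tree$edge[, 2]]), n_bm)),
                nrow(tree$edge), n_bm)
  val <- matrix(0, ntip + tree$Nnode, n_bm)
  pre_edges <- order(match(tree$edge[, 1], prep$preorder))
  for (e in pre_edges)
    val[tree$edge[e, 2], ] <- val[tree$edge[e, 1], ] + inc[e, ]
  bm <- apply(val[seq_len(ntip), , drop = FALSE], 2, function(v) {
    out <- numeric(ntip)
    out[order(v, decreasing = TRUE)[seq_len(k)]] <- 1
    out
  })
  d_all <- .d_sum(prep, cbind(trait, perm, bm))
  d_obs <- d_all[1]
  mr <- mean(d_all[1 + seq_len(n_perm)])
  mb <- mean(d_all[1 + n_perm + seq_len(n_bm)])
  collapsed <- abs(mr - mb) < .Machine$double.eps^0.5
  D <- if (collapsed) NA_real_ else (d_obs - mb) / (mr - mb)
  # degenerate also covers a collapsed scaling (both nulls indistinguishable,
  # typical for very small trees or extreme prevalence)
  list(D = D, d_obs = d_obs, mean_d_random = mr, mean_d_bm = mb,
       prevalence = k / ntip, degenerate = collapsed)
}

#' Run the full phylogenetic expression pipeline
#'
#' For every eligible gene family: reconstruct per-tissue ancestral FPKM
#' under BM, classify every node's expression state, and tally transitions
#' along branches. Pooled across trees: Fisher tests of event-coupled
#' shifts per category, D-statistics for the 2-fold-silk trait and for one
#' binary trait per gland type (on trees where that gland state occurs
#' among tips), and summary fractions.
#'
#' @param trees named list of [gene_tree()] objects with events labeled.
#' @param profiles named list (same names) of tips x tissues FPKM matrices
#'   (rownames = tip labels).
#' @param silk,nonsilk tissue classes.
#' @param n_perm,n_bm D-statistic null sizes.
#' @param do_dstat compute D-statistics (default TRUE; transition-only runs
#'   can skip them).
#' @param seed optional RNG seed for the D-statistic nulls.
#' @return List with `states` (per-tree node-state vectors), `tally`
#'   (pooled transition data.frame with a `tree` column), `fisher`,
#'   `dstat`, and `summary`.
#' @export
run_phylo_pipeline <- function(trees, profiles, silk = silk_gland_types(),
                               nonsilk = non_silk_tissues(),
                               n_perm = 1000, n_bm = 1000, do_dstat = TRUE,
                               seed = NULL) {
  stopifnot(length(trees) > 0)
  missing_prof <- setdiff(names(trees), names(profiles))
  if (length(missing_prof))
    stop("missing tip profiles for: ", paste(missing_prof, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  states <- list()
  tallies <- list()
  for (nm in names(trees)) {
    tr <- trees[[nm]]
    prof <- profiles[[nm]]
    if (anyNA(match(tr$tip.label, rownames(prof))))
      stop("incomplete tip profiles for tree ", nm)
    asr <- bm_ancestral_states(tr, prof[, c(silk, nonsilk), drop = FALSE])
    nodemat <- rbind(prof[tr$tip.label, c(silk, nonsilk), drop = FALSE],
                     asr$states)
    colnames(nodemat) <- c(silk, nonsilk)
    st <- classify_profile_states(nodemat, silk, nonsilk)
    names(st) <- NULL
    states[[nm]] <- st
    tl <- tally_transitions(tr, st)
    tl$tree <- nm
    tallies[[nm]] <- tl
  }
  tally <- do.call(rbind, tallies)
  rownames(tally) <- NULL
  fisher <- fisher_event_association(tally)
  # D-statistics per tree: 2-fold-silk trait, plus per-gland traits
  dres <- list()
  for (nm in if (do_dstat) names(trees) else character(0)) {
    tr <- trees[[nm]]
    ntip <- length(tr$tip.label)
    tip_states <- states[[nm]][seq_len(ntip)]
    traits <- list(silk = as.numeric(tip_states != "NOT_SILK"))
    for (g in intersect(silk, unique(tip_states)))
      traits[[g]] <- as.numeric(tip_states == g)
    for (tn in names(traits)) {
      trait <- setNames(traits[[tn]], tr$tip.label)
      if (ntip < 4) next
      r <- d_statistic(tr, trait, n_perm = n_perm, n_bm = n_bm)
      dres[[length(dres) + 1]] <-
        data.frame(tree = nm, trait = tn, D = r$D,
                   prevalence = r$prevalence, degenerate = r$degenerate)
    }
  }
  dstat <- if (length(dres)) do.call(rbind, dres) else
    data.frame(tree = character(0), trait = character(0), D = numeric(0),
               prevalence = numeric(0), degenerate = logical(0))
  changed_by_tree <- tapply(tally$changed, tally$tree, any)
  summary <- list(
    n_trees = length(trees),
    frac_trees_with_change = mean(changed_by_tree),
    frac_branches_unchanged = mean(!tally$changed),
    n_branches = nrow(tally))
  list(states = states, tally = tally, fisher = fisher,
       dstat = dstat, summary = summary)
}
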