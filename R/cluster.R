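# Correlation-based clustering of transcripts and tissues, with bootstrap
# clade support and PCA, mirroring the heatmap/dendrogram analyses of the
# expression study design.

#' Pairwise Spearman correlation matrix
#'
#' Spearman's rho with average ranks for ties, between the rows of a
#' profile matrix (items x features). Constant rows have undefined
#' correlations; these are recorded as 0 with a warning so the matrix stays
#' complete.
#'
#' @param x numeric matrix, items in rows, features in columns.
#' @param warn warn about constant rows (default TRUE).
#' @return Symmetric correlation matrix with unit diagonal, class
#'   `spearman_matrix`.
#' @export
spearman_matrix <- function(x, warn = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 items")
  if (ncol(x) < 2) stop("need at least 2 features")
  const <- apply(x, 1, function(r) max(r) == min(r))
  rho <- suppressWarnings(cor(t(x), method = "spearman"))
  if (any(const)) {
    if (warn)
      warning("constant profiles set to correlation 0: ",
              paste(rownames(x)[const], collapse = ", "))
    rho[const, ] <- 0
    rho[, const] <- 0
  }
  diag(rho) <- 1
  structure(rho, class = c("spearman_matrix", class(rho)))
}

#' Hierarchical clustering on 1 - rho distances
#'
#' Agglomerative clustering of a correlation matrix using distance
#' `1 - rho`. Items are put in label order before clustering so that
#' permuting the input leaves the dendrogram unchanged.
#'
#' @param corr correlation matrix (e.g. from [spearman_matrix()]).
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An [stats::hclust] object.
#' @export
hierarchical_cluster <- function(corr, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (any(!is.finite(corr))) {
    bad <- which(!is.finite(corr), arr.ind = TRUE)
    stop("non-finite distances for pairs: ",
         paste(apply(bad, 1, function(ij)
           paste(rownames(corr)[ij[1]], colnames(corr)[ij[2]], sep = "~")),
           collapse = ", "))
  }
  ord <- order(rownames(corr))
  corr <- corr[ord, ord]
  hclust(as.dist(1 - corr), method = linkage)
}

#' Cut a dendrogram into k groups and assign gland labels
#'
#' Cuts into exactly `k` groups (the k-1 highest merges undone) and labels
#' each group with the gland type owning strictly more than `majority` of
#' the group's summed expression; otherwise `"multiple glands"`.
#'
#' @param hc an [stats::hclust] from [hierarchical_cluster()].
#' @param shares item x gland matrix of summed mean FPKM (or proportions).
#' @param k number of groups; the study convention is n glands + 1.
#' @param majority threshold on the expression share (default 0.5, strict).
#' @return data.frame (`item`, `group`, `label`) plus `group_labels`
#'   attribute.
#' @export
cut_and_assign <- function(hc, shares, k, majority = 0.5) {
  if (k < 1) stop("k must be >= 1")
  grp <- cutree(hc, k = k)
  shares <- shares[names(grp), , drop = FALSE]
  lab <- vapply(split(names(grp), grp), function(items) {
    tot <- colSums(shares[items, , drop = FALSE])
    if (sum(tot) == 0) return("multiple glands")
    frac <- tot / sum(tot)
    if (max(frac) > majority) names(frac)[which.max(frac)] else "multiple glands"
  }, "")
  out <- data.frame(item = names(grp), group = unname(grp),
                    label = unname(lab[as.character(grp)]), row.names = NULL)
  attr(out, "group_labels") <- lab
  out
}

# unordered tip sets for every internal merge of an hclust tree
.hclust_clades <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    m <- hc$merge[i, ]
    members[[i]] <- c(if (m[1] < 0) hc$labels[-m[1]] else members[[m[1]]],
                      if (m[2] < 0) hc$labels[-m[2]] else members[[m[2]]])
  }
  lapply(members, function(x) sort(x))
}

#' Bootstrap support for dendrogram clades
#'
#' Resamples features (columns) with replacement, reclusters, and reports
#' for each clade of the original dendrogram the fraction of replicates in
#' which the same unordered tip set appears.
#'
#' @param x items x features profile matrix.
#' @param n_boot number of replicates (default 1000).
#' @param seed optional RNG seed for reproducibility.
#' @param linkage linkage method passed to [hierarchical_cluster()].
#' @return Named numeric vector of support fractions; names are
#'   `"tip1|tip2|..."` clade keys.
#' @export
bootstrap_support <- function(x, n_boot = 1000, seed = NULL,
                              linkage = "average") {
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  hc <- hierarchical_cluster(spearman_matrix(x, warn = FALSE), linkage)
  clades <- .hclust_clades(hc)
  keys <- vapply(clades, paste, "", collapse = "|")
  hits <- setNames(numeric(length(keys)), keys)
  for (b in seq_len(n_boot)) {
    cols <- sample.int(ncol(x), replace = TRUE)
    hb <- hierarchical_cluster(spearman_matrix(x[, cols, drop = FALSE],
                                               warn = FALSE), linkage)
    bkeys <- vapply(.hclust_clades(hb), paste, "", collapse = "|")
    hits[keys %in% bkeys] <- hits[keys %in% bkeys] + 1
  }
  hits / n_boot
}

#' Centered principal component analysis
#'
#' PCA of a profile matrix (items in rows), centered but not scaled, with a
#' fixed sign convention: the largest-magnitude loading of every component
#' is positive.
#'
#' @param x items x features matrix.
#' @param n_components number of components to keep.
#' @return List with `scores` (items x PCs), `loadings`, and
#'   `explained` (variance fractions).
#' @export
pca_projection <- function(x, n_components = 2) {
  x <- as.matrix(x)
  if (n_components > min(dim(x))) stop("n_components exceeds matrix rank bound")
  if (all(apply(x, 2, function(c) max(c) == min(c))))
    stop("degenerate all-constant input")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  keep <- seq_len(min(n_components, ncol(pc$rotation)))
  rot <- pc$rotation[, keep, drop = FALSE]
  sc <- pc$x[, keep, drop = FALSE]
  for (j in seq_along(keep)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sc[, j] <- -sc[, j]
    }
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = sc, loadings = rot, explained = expl[keep])
}

#' Per-tissue expression shares by transcript category
#'
#' For each tissue, the fraction of total mean FPKM contributed by each
#' transcript category (e.g. known silk structural proteins vs other).
#'
#' @param profile transcript x tissue mean-FPKM matrix.
#' @param categories named character vector, transcript -> category; must
#'   cover all transcripts in `profile`.
#' @return tissue x category matrix of shares, rows summing to 1.
#' @export
expression_share <- function(profile, categories) {
  categories <- categories[rownames(profile)]
  if (anyNA(categories)) stop("categories must cover every transcript")
  tot <- colSums(profile)
  if (any(tot == 0))
    stop("tissue with zero total FPKM: ",
         paste(colnames(profile)[tot == 0], collapse = ", "))
  sums <- rowsum(profile, group = categories)
  t(sweep(sums, 2, tot, "/"))
}
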