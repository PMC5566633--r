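# Rooted binary gene trees with duplication/speciation node events.
#
# Trees are ape "phylo" objects carrying an extra `node.event` vector
# (length Nnode, "duplication"/"speciation"/NA) plus per-tip `species` and
# `transcript` ids parsed from tip labels of the form "species|transcript".
# Newick parsing/writing is delegated to ape; a thin layer handles the NHX
# [&&NHX:D=Y|N] duplication flags, which ape does not interpret.

#' Construct a gene tree
#'
#' @param phy a rooted, binary [ape::phylo] object with tip labels
#'   `"species|transcript"` (a label without `|` is taken as a bare species
#'   id).
#' @param events character vector of node events (`"speciation"`,
#'   `"duplication"`, or `NA`), ordered by internal node number; `NULL`
#'   leaves all nodes unlabeled for downstream inference.
#' @return Object of class `gene_tree` (also `phylo`).
#' @export
gene_tree <- function(phy, events = NULL) {
  if (!inherits(phy, "phylo")) stop("phy must be a phylo object")
  if (!ape::is.rooted(phy)) stop("gene trees must be rooted")
  if (!ape::is.binary(phy)) stop("non-binary nodes are not supported")
  if (is.null(events)) events <- rep(NA_character_, phy$Nnode)
  stopifnot(length(events) == phy$Nnode)
  bad <- !is.na(events) & !events %in% c("speciation", "duplication")
  if (any(bad)) stop("invalid node events: ", paste(unique(events[bad]), collapse = ", "))
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0))
    stop("negative branch lengths are not allowed")
  phy$node.event <- as.character(events)
  parts <- strsplit(phy$tip.label, "|", fixed = TRUE)
  phy$tip.species <- vapply(parts, `[`, "", 1)
  phy$tip.transcript <- vapply(parts, function(p) if (length(p) > 1) p[2] else p[1], "")
  class(phy) <- unique(c("gene_tree", class(phy)))
  phy
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("gene_tree: %d tips, %d internal nodes (%d duplication, %d speciation, %d unlabeled)\n",
              length(x$tip.label), x$Nnode,
              sum(x$node.event == "duplication", na.rm = TRUE),
              sum(x$node.event == "speciation", na.rm = TRUE),
              sum(is.na(x$node.event))))
  invisible(x)
}

# children of every internal node (list indexed by node number)
.children_list <- function(phy) {
  n_all <- length(phy$tip.label) + phy$Nnode
  kids <- vector("list", n_all)
  for (i in seq_len(nrow(phy$edge)))
    kids[[phy$edge[i, 1]]] <- c(kids[[phy$edge[i, 1]]], phy$edge[i, 2])
  kids
}

# tip indices under every node
.node_tipsets <- function(phy) {
  ntip <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  sets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; c <- po$edge[i, 2]
    sets[[p]] <- c(sets[[p]], sets[[c]])
  }
  sets
}

.nhx_sentinel <- "NHXTAG"

# pull NHX comments out of a newick string, replacing each with a sentinel
# appended to the node label it annotates (comments follow the branch length)
.extract_nhx <- function(txt) {
  tags <- character(0)
  repeat {
    m <- regexpr("\\[&&NHX:[^]]*\\]", txt)
    if (m == -1) break
    len <- attr(m, "match.length")
    tag <- substr(txt, m + 7, m + len - 2)
    tags <- c(tags, tag)
    sentinel <- sprintf("%s%06d", .nhx_sentinel, length(tags))
    before <- substr(txt, 1, m - 1)
    after <- substr(txt, m + len, nchar(txt))
    i <- nchar(before)
    j <- i
    while (j >= 1 && grepl("[0-9.eE+-]", substr(before, j, j), perl = TRUE))
      j <- j - 1
    if (j >= 1 && j < i && substr(before, j, j) == ":") {
      txt <- paste0(substr(before, 1, j - 1), sentinel,
                    substr(before, j, i), after)
    } else {
      txt <- paste0(before, sentinel, after)
    }
  }
  list(text = txt, tags = tags)
}

.nhx_field <- function(tag, key) {
  for (kv in strsplit(tag, ":", fixed = TRUE)[[1]]) {
    kvp <- strsplit(kv, "=", fixed = TRUE)[[1]]
    if (length(kvp) == 2 && kvp[1] == key) return(kvp[2])
  }
  NA_character_
}

#' Read a gene tree from Newick/NHX text
#'
#' Accepts plain Newick or NHX with `[&&NHX:D=Y|N]` duplication flags on
#' internal nodes. Nodes without a flag stay unlabeled (events can then be
#' inferred with [label_events_species_overlap()]).
#'
#' @param x a file path or a Newick string.
#' @return A [gene_tree()].
#' @export
read_gene_tree <- function(x) {
  txt <- if (file.exists(x) && !grepl("(", x, fixed = TRUE)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else x
  ex <- .extract_nhx(txt)
  phy <- ape::read.tree(text = ex$text)
  if (is.null(phy)) stop("unparseable newick text")
  ntip <- length(phy$tip.label)
  events <- rep(NA_character_, phy$Nnode)
  strip <- function(lab) sub(sprintf("%s[0-9]{6}$", .nhx_sentinel), "", lab)
  tagof <- function(lab) {
    m <- regmatches(lab, regexpr(sprintf("%s([0-9]{6})$", .nhx_sentinel), lab))
    if (length(m) == 0) return(NA_character_)
    ex$tags[as.integer(substr(m, nchar(.nhx_sentinel) + 1, nchar(m)))]
  }
  if (!is.null(phy$node.label)) {
    for (k in seq_len(phy$Nnode)) {
      tag <- tagof(phy$node.label[k])
      if (!is.na(tag)) {
        d <- .nhx_field(tag, "D")
        if (!is.na(d)) events[k] <- if (d == "Y") "duplication" else "speciation"
      }
    }
    phy$node.label <- strip(phy$node.label)
  }
  phy$tip.label <- strip(phy$tip.label)
  gene_tree(phy, events)
}

#' Write a gene tree as NHX text
#'
#' Internal nodes with known events get `[&&NHX:D=Y|N]` comments after
#' their branch length; unlabeled nodes get no comment.
#'
#' @param tree a [gene_tree()].
#' @param file optional path; when `NULL` the NHX string is returned.
#' @return The NHX string, invisibly when writing to a file.
#' @export
write_gene_tree <- function(tree, file = NULL) {
  phy <- tree
  labelled <- which(!is.na(tree$node.event))
  phy$node.label <- ifelse(is.na(tree$node.event), "",
                           sprintf("%s%06d", .nhx_sentinel, seq_len(tree$Nnode)))
  class(phy) <- "phylo"
  txt <- ape::write.tree(phy)
  for (k in labelled) {
    sentinel <- sprintf("%s%06d", .nhx_sentinel, k)
    flag <- if (tree$node.event[k] == "duplication") "Y" else "N"
    txt <- sub(sprintf("%s(:[0-9.eE+-]+)?", sentinel),
               sprintf("\\1[&&NHX:D=%s]", flag), txt)
  }
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Label node events by species overlap
#'
#' A node is a duplication if its two child subtrees share at least one
#' species, else a speciation — the standard species-overlap heuristic that
#' emulates reconciliation output when NHX flags are absent.
#'
#' @param tree a [gene_tree()].
#' @return The tree with every internal node labeled.
#' @export
label_events_species_overlap <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- .children_list(tree)
  sets <- .node_tipsets(tree)
  events <- rep(NA_character_, tree$Nnode)
  for (nd in ntip + seq_len(tree$Nnode)) {
    ch <- kids[[nd]]
    sp1 <- unique(tree$tip.species[sets[[ch[1]]]])
    sp2 <- unique(tree$tip.species[sets[[ch[2]]]])
    events[nd - ntip] <- if (length(intersect(sp1, sp2)) > 0) "duplication" else "speciation"
  }
  tree$node.event <- events
  tree
}

# extract the clade below `node` keeping branch lengths and node events
.subtree_with_events <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node == ntip + 1) return(tree)
  plain <- tree[c("edge", "edge.length", "tip.label", "Nnode", "node.label")]
  plain <- plain[!vapply(plain, is.null, TRUE)]
  class(plain) <- "phylo"
  sub <- ape::extract.clade(plain, node)
  sub$node.label <- NULL
  key <- function(tips) paste(sort(tips), collapse = "\r")
  sets <- .node_tipsets(tree)
  ev_by_key <- setNames(tree$node.event,
                        vapply(ntip + seq_len(tree$Nnode),
                               function(nd) key(tree$tip.label[sets[[nd]]]), ""))
  ssets <- .node_tipsets(sub)
  sntip <- length(sub$tip.label)
  events <- vapply(sntip + seq_len(sub$Nnode), function(nd) {
    unname(ev_by_key[key(sub$tip.label[ssets[[nd]]])])
  }, "")
  gene_tree(sub, events)
}

#' Subdivide a gene tree at outgroup speciation nodes
#'
#' Detaches and returns the maximal subtrees whose tips all belong to
#' ingroup species, discarding outgroup lineages (e.g. tick homologs when
#' the ingroup is the spider clade). Subtrees with fewer than 2 tips are
#' dropped. A tree without outgroup tips is returned unchanged.
#'
#' @param tree a [gene_tree()].
#' @param outgroup character vector of outgroup species ids.
#' @return List of [gene_tree()] objects (possibly empty, with a warning
#'   when the tree is entirely outgroup).
#' @export
subdivide_at_outgroup <- function(tree, outgroup) {
  ntip <- length(tree$tip.label)
  is_out_tip <- tree$tip.species %in% outgroup
  if (!any(is_out_tip)) return(list(tree))
  if (all(is_out_tip)) {
    warning("tree contains only outgroup tips")
    return(list())
  }
  sets <- .node_tipsets(tree)
  n_all <- ntip + tree$Nnode
  all_in <- vapply(seq_len(n_all),
                   function(nd) !any(is_out_tip[sets[[nd]]]), TRUE)
  parent <- rep(NA_integer_, n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  maximal <- which(all_in & (is.na(parent) | !all_in[parent]))
  keep <- maximal[vapply(maximal, function(nd) length(sets[[nd]]) >= 2, TRUE)]
  lapply(keep, function(nd) .subtree_with_events(tree, nd))
}
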