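# Cross-species gene-family (homology cluster) handling. Family membership
# is an input (external homology inference); operations here filter to
# clusters with all three species, aggregate expression per family, class
# OEST sharing, and select families for tree analysis.

#' Read / validate a family membership map
#'
#' @param x a TSV path or a data.frame with columns `cluster_id`, `species`,
#'   `transcript`.
#' @return data.frame of class `family_map`.
#' @export
family_map <- function(x) {
  map <- if (is.character(x)) read.delim(x) else as.data.frame(x)
  stopifnot(all(c("cluster_id", "species", "transcript") %in% names(map)))
  map$cluster_id <- as.character(map$cluster_id)
  dup <- duplicated(paste(map$species, map$transcript))
  if (any(dup))
    stop("transcripts assigned to more than one cluster: ",
         paste(head(unique(map$transcript[dup])), collapse = ", "))
  class(map) <- c("family_map", class(map))
  map
}

#' Restrict a family map to clusters covering every species
#'
#' Retains clusters with at least one member from each listed species
#' ("3-species clusters" in the three-spider design).
#'
#' @param map a [family_map()].
#' @param species character vector of required species ids.
#' @return Filtered [family_map()].
#' @export
three_species_filter <- function(map, species) {
  if (length(species) == 0) stop("species set must be non-empty")
  cover <- tapply(map$species, map$cluster_id,
                  function(s) all(species %in% s))
  keep <- names(cover)[cover]
  out <- map[map$cluster_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("family_map", "data.frame")
  out
}

#' Summed mean FPKM per family, species and tissue
#'
#' For every cluster, sums member transcripts' mean FPKM within each tissue
#' in a species-specific manner. Output columns are `"species|tissue"`.
#'
#' @param map a [family_map()].
#' @param profiles named list (by species) of transcript x tissue mean-FPKM
#'   matrices.
#' @return cluster x (species|tissue) matrix.
#' @export
family_tissue_sum <- function(map, profiles) {
  clusters <- sort(unique(map$cluster_id))
  cols <- unlist(lapply(names(profiles), function(sp)
    paste(sp, colnames(profiles[[sp]]), sep = "|")))
  out <- matrix(0, length(clusters), length(cols),
                dimnames = list(clusters, cols))
  for (sp in names(profiles)) {
    sub <- map[map$species == sp, , drop = FALSE]
    if (nrow(sub) == 0) next
    prof <- profiles[[sp]]
    missing <- setdiff(sub$transcript, rownames(prof))
    if (length(missing))
      stop("profiles missing for transcripts: ", paste(head(missing), collapse = ", "))
    sums <- rowsum(prof[sub$transcript, , drop = FALSE], group = sub$cluster_id)
    out[rownames(sums), paste(sp, colnames(prof), sep = "|")] <- sums
  }
  out
}

#' Classify OEST sharing across species within clusters
#'
#' For clusters containing at least one OEST, the class is the number of
#' distinct species contributing an OEST (1, 2 or 3). OESTs outside the
#' 3-species clusters are tallied by how many other species their own
#' cluster covers (`no_homologs` when unclustered or single-species,
#' `one_other_species` when the cluster spans two).
#'
#' @param map the full [family_map()] (not yet species-filtered).
#' @param oest_sets named list (by species) of OEST transcript id vectors.
#' @param species species ids defining the "all species" set.
#' @return List with `classes` (data.frame cluster_id, n_species_with_oest)
#'   and `unclustered` (named tally).
#' @export
oest_sharing_classes <- function(map, oest_sets, species = names(oest_sets)) {
  is_oest <- mapply(function(sp, tx) tx %in% oest_sets[[sp]],
                    map$species, map$transcript)
  cover <- tapply(map$species, map$cluster_id, function(s) length(unique(s)))
  full <- names(cover)[cover == length(species)]
  sub <- map[is_oest & map$cluster_id %in% full, , drop = FALSE]
  classes <- if (nrow(sub)) {
    tab <- tapply(sub$species, sub$cluster_id, function(s) length(unique(s)))
    data.frame(cluster_id = names(tab), n_species_with_oest = as.integer(tab),
               row.names = NULL)
  } else {
    data.frame(cluster_id = character(0), n_species_with_oest = integer(0))
  }
  # OESTs not in a full-coverage cluster
  tallies <- c(no_homologs = 0L, one_other_species = 0L)
  key <- paste(map$species, map$transcript)
  for (sp in names(oest_sets)) {
    for (tx in oest_sets[[sp]]) {
      i <- match(paste(sp, tx), key)
      if (is.na(i)) { tallies["no_homologs"] <- tallies["no_homologs"] + 1L; next }
      cl <- map$cluster_id[i]
      if (cl %in% full) next
      n_sp <- cover[cl]
      if (n_sp >= 2) tallies["one_other_species"] <- tallies["one_other_species"] + 1L
      else tallies["no_homologs"] <- tallies["no_homologs"] + 1L
    }
  }
  list(classes = classes, unclustered = tallies)
}

#' Select families eligible for tree analysis
#'
#' A cluster is eligible when, in every species, at least one member
#' transcript is both 2-fold silk-overexpressed and has mean FPKM > 1 in at
#' least one tissue (both conditions in the same transcript; see
#' `per_species = FALSE` for the relaxed any-species reading).
#'
#' @param map a species-filtered [family_map()].
#' @param flags named list (by species) of [twofold_silk_flag()] results.
#' @param species required species ids.
#' @param per_species enforce the condition in every species (default TRUE).
#' @return Character vector of eligible cluster ids.
#' @export
tree_eligibility <- function(map, flags, species = names(flags),
                             per_species = TRUE) {
  ok_tx <- lapply(flags, function(f)
    f$transcript[f$twofold_silk & f$fpkm_gt1])
  map$ok <- mapply(function(sp, tx) tx %in% ok_tx[[sp]],
                   map$species, map$transcript)
  by_cl <- split(map, map$cluster_id)
  eligible <- vapply(by_cl, function(d) {
    if (per_species) {
      all(vapply(species, function(sp) any(d$ok[d$species == sp]), TRUE))
    } else {
      any(d$ok)
    }
  }, TRUE)
  sort(names(eligible)[eligible])
}
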