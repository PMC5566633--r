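# Synthetic-data generator: gene trees by duplication-loss along the species
# tree, log-scale Brownian expression evolution with planted gland-specific
# shifts, and negative-binomial counts. Defaults emulate the three-species
# cobweb-weaver study design (topology ((Lg,Lh),Sg); seven silk gland types
# and three non-silk tissues; mostly two replicates per tissue).

#' Study design for the synthetic bundle
#'
#' @param species_tree rooted species tree (newick string or phylo).
#' @param silk,nonsilk tissue ids of the two classes (disjoint, non-empty).
#' @param replicates named integer vector, tissue -> number of biological
#'   replicates (default 2 everywhere except the pyriform and anterior
#'   aggregate glands, which are replicate-free, exercising the fixed 0.4
#'   dispersion path).
#' @param library_size total aligned fragments per library (scalar target;
#'   per-library sizes are jittered by the generator).
#' @return Object of class `study_design`.
#' @export
study_design <- function(species_tree = "((Lg:1,Lh:1):1,Sg:2);",
                         silk = silk_gland_types(),
                         nonsilk = non_silk_tissues(),
                         replicates = NULL,
                         library_size = 1e7) {
  if (is.character(species_tree)) species_tree <- ape::read.tree(text = species_tree)
  tissues <- c(silk, nonsilk)
  if (length(silk) == 0 || length(nonsilk) == 0 || anyDuplicated(tissues))
    stop("silk and non-silk tissue sets must be disjoint and non-empty")
  if (is.null(replicates)) {
    replicates <- setNames(rep(2L, length(tissues)), tissues)
    replicates[intersect(c("Py", "AGa"), tissues)] <- 1L
  }
  replicates <- replicates[tissues]
  if (anyNA(replicates) || any(replicates < 1))
    stop("every tissue needs >= 1 replicate")
  if (library_size <= 0) stop("library sizes must be > 0")
  structure(list(species_tree = species_tree,
                 species = species_tree$tip.label,
                 silk = silk, nonsilk = nonsilk, tissues = tissues,
                 replicates = replicates, library_size = library_size),
            class = "study_design")
}

#' Simulate a gene tree by duplication-loss along the species tree
#'
#' A single gene lineage enters the species-tree root; along every species
#' branch each lineage duplicates at rate `birth_rate` and is lost at rate
#' `loss_rate` (per lineage, per time unit); lineages surviving to a
#' speciation node split into both descendant species. Surviving
#' unifurcations are suppressed (branch lengths added). Trees that do not
#' retain at least one tip in every species, or fewer than 2 tips, are
#' discarded and resimulated.
#'
#' @param species_tree newick string or rooted binary phylo.
#' @param birth_rate,loss_rate non-negative per-lineage rates.
#' @param seed optional RNG seed.
#' @param max_retries resimulation bound before an explicit failure.
#' @return A [gene_tree()] with every internal node labeled.
#' @export
simulate_gene_tree <- function(species_tree, birth_rate, loss_rate = 0,
                               seed = NULL, max_retries = 100) {
  if (is.character(species_tree)) species_tree <- ape::read.tree(text = species_tree)
  stopifnot(birth_rate >= 0, loss_rate >= 0,
            length(species_tree$tip.label) >= 2)
  if (!is.null(seed)) set.seed(seed)
  ntip_sp <- length(species_tree$tip.label)
  kids <- .children_list(species_tree)
  blen <- numeric(ntip_sp + species_tree$Nnode)
  blen[species_tree$edge[, 2]] <- species_tree$edge.length
  rate <- birth_rate + loss_rate

  sim_branch <- function(t, sp_node) {
    tau <- if (rate > 0) rexp(1, rate) else Inf
    if (tau < t) {
      if (runif(1) < loss_rate / rate) return(NULL)
      l <- sim_branch(t - tau, sp_node)
      r <- sim_branch(t - tau, sp_node)
      if (is.null(l) && is.null(r)) return(NULL)
      if (is.null(l)) return(list(node = r$node, stem = tau + r$stem))
      if (is.null(r)) return(list(node = l$node, stem = tau + l$stem))
      return(list(node = list(event = "duplication",
                              kids = list(l$node, r$node),
                              klen = c(l$stem, r$stem)),
                  stem = tau))
    }
    res <- at_node(sp_node)
    if (is.null(res)) return(NULL)
    list(node = res$node, stem = t + res$stem)
  }

  at_node <- function(sp_node) {
    if (sp_node <= ntip_sp)
      return(list(node = list(tip = TRUE,
                              species = species_tree$tip.label[sp_node]),
                  stem = 0))
    ch <- kids[[sp_node]]
    l <- sim_branch(blen[ch[1]], ch[1])
    r <- sim_branch(blen[ch[2]], ch[2])
    if (is.null(l) && is.null(r)) return(NULL)
    if (is.null(l)) return(list(node = r$node, stem = r$stem))
    if (is.null(r)) return(list(node = l$node, stem = l$stem))
    list(node = list(event = "speciation", kids = list(l$node, r$node),
                     klen = c(l$stem, r$stem)),
         stem = 0)
  }

  for (try in seq_len(max_retries)) {
    res <- at_node(ntip_sp + 1)
    if (is.null(res) || isTRUE(res$node$tip)) next
    counter <- 0
    to_newick <- function(node, len) {
      if (isTRUE(node$tip)) {
        counter <<- counter + 1
        sprintf("%s|g%d:%.10g", node$species, counter, len)
      } else {
        sprintf("(%s,%s)%s:%.10g",
                to_newick(node$kids[[1]], node$klen[1]),
                to_newick(node$kids[[2]], node$klen[2]),
                if (node$event == "duplication") "D" else "S", len)
      }
    }
    txt <- sprintf("(%s,%s)%s;",
                   to_newick(res$node$kids[[1]], res$node$klen[1]),
                   to_newick(res$node$kids[[2]], res$node$klen[2]),
                   if (res$node$event == "duplication") "D" else "S")
    phy <- ape::read.tree(text = txt)
    if (!setequal(unique(sub("\\|.*", "", phy$tip.label)), species_tree$tip.label))
      next
    events <- ifelse(phy$node.label == "D", "duplication", "speciation")
    phy$node.label <- NULL
    return(gene_tree(phy, events))
  }
  stop("family extinct (or missing a species) after ", max_retries, " retries")
}

#' Evolve expression profiles along a gene tree
#'
#' Expression evolves by Brownian motion on `log(FPKM + pseudocount)`
#' independently per tissue (variance `bm_sigma2 x` branch length),
#' back-transformed and floored at 0. At planted shift branches the target
#' tissue's FPKM is multiplied by the effect size after the BM step. True
#' node states are derived from the true node profiles with
#' [classify_node_state()], so planted truth is self-consistent by
#' construction.
#'
#' @param tree a [gene_tree()].
#' @param root_profile named non-negative vector, tissue -> root FPKM.
#' @param bm_sigma2 BM rate (scalar or per-tissue), on the log scale.
#' @param shifts optional data.frame with columns `node` (child node id of
#'   the shift branch), `tissue`, `multiplier`.
#' @param silk,nonsilk tissue classes used for truth states.
#' @param pseudocount log-transform offset (default 1).
#' @param seed optional RNG seed.
#' @return List with `tips` (tips x tissues FPKM matrix) and `truth`
#'   (`node_profiles`, `node_states`, `shift_branches`).
#' @export
simulate_expression <- function(tree, root_profile, bm_sigma2, shifts = NULL,
                                silk = silk_gland_types(),
                                nonsilk = non_silk_tissues(),
                                pseudocount = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(root_profile >= 0), all(bm_sigma2 >= 0))
  tissues <- names(root_profile)
  sig <- rep_len(bm_sigma2, length(tissues))
  ntip <- length(tree$tip.label)
  n_all <- ntip + tree$Nnode
  if (!is.null(shifts)) {
    stopifnot(all(c("node", "tissue", "multiplier") %in% names(shifts)))
    if (!all(shifts$node %in% tree$edge[, 2]))
      stop("shift branch not in tree")
    if (!all(shifts$tissue %in% tissues))
      stop("shift tissue not in root profile")
  }
  prof <- matrix(NA_real_, n_all, length(tissues),
                 dimnames = list(NULL, tissues))
  prof[ntip + 1, ] <- root_profile
  po <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  pre_edges <- order(match(tree$edge[, 1], rev(po)))
  for (e in pre_edges) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    bl <- tree$edge.length[e]
    eps <- rnorm(length(tissues), 0, sqrt(sig * bl))
    v <- pmax(exp(log(prof[p, ] + pseudocount) + eps) - pseudocount, 0)
    if (!is.null(shifts)) {
      for (i in which(shifts$node == ch))
        v[shifts$tissue[i]] <- v[shifts$tissue[i]] * shifts$multiplier[i]
    }
    prof[ch, ] <- v
  }
  states <- classify_profile_states(prof, silk, nonsilk)
  tips <- prof[seq_len(ntip), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  list(tips = tips,
       truth = list(node_profiles = prof,
                    node_states = unname(states),
                    shift_branches = if (is.null(shifts)) integer(0) else shifts$node))
}

#' Simulate negative-binomial counts from a tissue profile
#'
#' Expected count `mu = FPKM x effective_length/1e3 x library_size/1e6`;
#' counts are NB with variance `mu + dispersion * mu^2` (Poisson at
#' dispersion 0). One library per (tissue, replicate).
#'
#' @param profile transcript x tissue FPKM matrix.
#' @param replicates named integer vector, tissue -> replicate count.
#' @param library_size scalar or per-library named vector of aligned
#'   fragments.
#' @param effective_length named per-transcript effective lengths (bp).
#' @param nb_dispersion NB dispersion `>= 0`.
#' @param species species id used in library names and the sample sheet.
#' @param seed optional RNG seed.
#' @return A [count_matrix()].
#' @export
simulate_counts <- function(profile, replicates, library_size,
                            effective_length, nb_dispersion = 0.4,
                            species = "sp", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nb_dispersion >= 0, all(profile >= 0))
  effective_length <- effective_length[rownames(profile)]
  if (anyNA(effective_length) || any(effective_length <= 0))
    stop("effective lengths must be present and > 0")
  libs <- unlist(lapply(names(replicates), function(t)
    sprintf("%s_%s_r%d", species, t, seq_len(replicates[[t]]))))
  tis <- rep(names(replicates), replicates)
  reps <- unlist(lapply(replicates, seq_len))
  size <- rep_len(unname(library_size), length(libs))
  counts <- matrix(0L, nrow(profile), length(libs),
                   dimnames = list(rownames(profile), libs))
  for (j in seq_along(libs)) {
    mu <- profile[, tis[j]] * (effective_length / 1e3) * (size[j] / 1e6)
    counts[, j] <- if (nb_dispersion == 0) rpois(length(mu), mu)
                   else rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion)
  }
  samples <- data.frame(library = libs, species = species,
                        tissue = tis, replicate = reps, row.names = NULL)
  count_matrix(counts, effective_length, samples, setNames(size, libs))
}

#' Configuration for a full synthetic study
#'
#' Defaults state the emulated world: 30 three-species gene families under
#' duplication rate 0.3 / loss rate 0.1, Brownian log-expression noise
#' `sigma2 = 0.05`, gland-specific shifts planted on 12% of branches with a
#' 16-fold effect, 300 background transcripts per species of which 30 are
#' planted 10-fold silk-overexpressed OESTs, and replicate-level NB
#' dispersion 0.4.
#'
#' @param design a [study_design()].
#' @param ... overrides for the fields listed above.
#' @return List of class `study_config`.
#' @export
study_config <- function(design = study_design(), ...) {
  cfg <- list(design = design,
              n_families = 30,
              birth_rate = 0.3,
              loss_rate = 0.1,
              bm_sigma2 = 0.05,
              shift_prob = 0.12,
              shift_multiplier = 16,
              shift_on = "any",
              n_background = 300,
              n_oest = 30,
              oest_fold = 10,
              nb_dispersion = 0.4,
              base_meanlog = log(5),
              base_sdlog = 1,
              efflen_range = c(500, 3000))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (!cfg$shift_on %in% c("any", "duplication"))
    stop("shift_on must be 'any' or 'duplication'")
  class(cfg) <- c("study_config", class(cfg))
  cfg
}

#' Generate a complete synthetic study bundle
#'
#' Simulates gene trees, expression evolution with planted shifts,
#' background transcripts with planted OESTs, and NB counts per species;
#' optionally writes every real-data-mode input file plus ground truth.
#' Deterministic under `seed`: a single RNG stream is drawn in a fixed
#' order (trees, then per-family expression, then per-species backgrounds
#' and counts).
#'
#' @param config a [study_config()].
#' @param seed integer seed.
#' @param out optional output directory; when given, writes counts /
#'   effective-length / sample-sheet TSVs per species, `families.tsv`,
#'   `trees.nhx` and `truth.json`.
#' @return The bundle: list with `config`, `trees`, `family_map`,
#'   `counts` (per species [count_matrix()]), `tip_profiles`, `truth`.
#' @export
generate_study <- function(config = study_config(), seed = 1, out = NULL) {
  set.seed(seed)
  des <- config$design
  tissues <- des$tissues
  fids <- sprintf("f%03d", seq_len(config$n_families))

  trees <- list(); fam_rows <- list(); truth_fam <- list()
  tipprofs <- list()
  for (i in seq_along(fids)) {
    tr <- simulate_gene_tree(des$species_tree, config$birth_rate, config$loss_rate)
    # make transcript ids unique across families
    tr$tip.transcript <- paste0(fids[i], ".", tr$tip.transcript)
    tr$tip.label <- paste(tr$tip.species, tr$tip.transcript, sep = "|")
    # tissue-flat root baseline: silk specificity arises only from planted
    # shifts (and BM noise), keeping the classification boundary clean
    root_profile <- setNames(rep(rlnorm(1, config$base_meanlog,
                                        config$base_sdlog), length(tissues)),
                             tissues)
    cand <- tr$edge[, 2]
    if (config$shift_on == "duplication") {
      ntip <- length(tr$tip.label)
      cand <- cand[tr$node.event[tr$edge[, 1] - ntip] == "duplication"]
    }
    sel <- cand[runif(length(cand)) < config$shift_prob]
    shifts <- if (length(sel)) {
      data.frame(node = sel,
                 tissue = sample(des$silk, length(sel), replace = TRUE),
                 multiplier = config$shift_multiplier)
    } else NULL
    sim <- simulate_expression(tr, root_profile, config$bm_sigma2, shifts,
                               silk = des$silk, nonsilk = des$nonsilk)
    trees[[fids[i]]] <- tr
    tipprofs[[fids[i]]] <- sim$tips
    truth_fam[[fids[i]]] <- c(sim$truth, list(shifts = shifts))
    fam_rows[[i]] <- data.frame(cluster_id = fids[i],
                                species = tr$tip.species,
                                transcript = tr$tip.transcript)
  }
  fam_map <- family_map(do.call(rbind, fam_rows))

  counts <- list(); oest_truth <- list()
  for (sp in des$species) {
    fam_tx <- fam_map$transcript[fam_map$species == sp]
    fam_prof <- do.call(rbind, lapply(fids, function(f) {
      m <- tipprofs[[f]]
      rows <- rownames(m)[sub("\\|.*", "", rownames(m)) == sp]
      out <- m[rows, , drop = FALSE]
      rownames(out) <- sub(".*\\|", "", rows)
      out
    }))
    bg_ids <- sprintf("%s.bg%04d", sp, seq_len(config$n_background))
    base <- rlnorm(config$n_background, config$base_meanlog, config$base_sdlog)
    bg_prof <- matrix(base, config$n_background, length(tissues),
                      dimnames = list(bg_ids, tissues))
    oest_idx <- seq_len(config$n_oest)
    if (config$n_oest > 0)
      bg_prof[oest_idx, des$silk] <- bg_prof[oest_idx, des$silk] * config$oest_fold
    profile <- rbind(fam_prof[fam_tx, tissues, drop = FALSE], bg_prof)
    efflen <- setNames(round(runif(nrow(profile), config$efflen_range[1],
                                   config$efflen_range[2])), rownames(profile))
    nlib <- sum(des$replicates)
    sizes <- round(des$library_size * runif(nlib, 0.85, 1.15))
    counts[[sp]] <- simulate_counts(profile, des$replicates, sizes, efflen,
                                    config$nb_dispersion, species = sp)
    oest_truth[[sp]] <- data.frame(
      transcript = rownames(profile),
      oest = rownames(profile) %in% bg_ids[seq_len(config$n_oest)])
  }

  truth <- list(families = truth_fam, oest = oest_truth)
  bundle <- list(config = config, trees = trees, family_map = fam_map,
                 counts = counts, tip_profiles = tipprofs, truth = truth)
  if (!is.null(out)) write_study(bundle, out)
  invisible(bundle)
}

#' Write a synthetic bundle to plain-text files
#'
#' @param bundle result of [generate_study()].
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_study <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (sp in names(bundle$counts))
    write_count_matrix(bundle$counts[[sp]], dir, prefix = paste0(sp, "_"))
  write.table(as.data.frame(unclass(bundle$family_map)),
              file.path(dir, "families.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(vapply(names(bundle$trees), function(f)
    paste0(f, "\t", write_gene_tree(bundle$trees[[f]])), ""),
    file.path(dir, "trees.nhx"))
  truth <- bundle$truth
  for (f in names(truth$families)) {
    truth$families[[f]]$node_profiles <-
      as.data.frame(truth$families[[f]]$node_profiles)
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a synthetic bundle back from disk
#'
#' @param dir directory written by [write_study()] / [generate_study()].
#' @param species species ids to read (defaults to all `*_counts.tsv`).
#' @return List with `counts`, `family_map`, `trees`.
#' @export
read_study <- function(dir, species = NULL) {
  if (is.null(species)) {
    species <- sub("_counts\\.tsv$", "",
                   basename(Sys.glob(file.path(dir, "*_counts.tsv"))))
  }
  counts <- lapply(setNames(species, species), function(sp)
    read_count_matrix(file.path(dir, paste0(sp, "_counts.tsv")),
                      file.path(dir, paste0(sp, "_effective_lengths.tsv")),
                      file.path(dir, paste0(sp, "_samples.tsv"))))
  fam <- family_map(file.path(dir, "families.tsv"))
  lines <- readLines(file.path(dir, "trees.nhx"))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  trees <- setNames(lapply(parts, function(p) read_gene_tree(p[2])),
                    vapply(parts, `[`, "", 1))
  list(counts = counts, family_map = fam, trees = trees)
}
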