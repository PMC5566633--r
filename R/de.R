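# Negative-binomial exact testing for over-expressed silk transcripts.
#
# The testing machinery conditions on per-gene totals after equalizing
# library sizes (simple proportional scaling of counts to the geometric-mean
# effective size, rounded), following the classic exact-test logic for
# two-group RNA-seq comparisons.

# scale every library's counts to a common effective size
.equalize_counts <- function(counts, eff_size) {
  target <- .geomean(eff_size)
  round(sweep(counts, 2, target / eff_size, "*"))
}

# summed conditional NB log-likelihood of phi across genes, for one group of
# equal-size libraries (Dirichlet-multinomial form; phi > 0)
.group_cond_ll <- function(y, phi) {
  n <- ncol(y)
  r <- 1 / phi
  z <- rowSums(y)
  sum(lgamma(y + r)) - n * nrow(y) * lgamma(r) -
    sum(lgamma(z + n * r)) + nrow(y) * lgamma(n * r)
}

.cond_ll <- function(pseudo, groups, phi) {
  ll <- 0
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 2) next
    ll <- ll + .group_cond_ll(pseudo[, cols, drop = FALSE], phi)
  }
  ll
}

#' Common dispersion by conditional maximum likelihood
#'
#' Maximizes the summed conditional (on per-group totals) negative-binomial
#' log-likelihood over pseudo-counts scaled to a common effective library
#' size. The estimate approximates the squared biological coefficient of
#' variation (CV^2).
#'
#' @param counts counts matrix (transcripts x libraries) or [count_matrix()].
#' @param groups group label per library (e.g. silk / non-silk).
#' @param eff_size TMM-adjusted effective library sizes
#'   (`library_size * tmm_factor`); defaults to column sums.
#' @return Non-negative dispersion estimate.
#' @export
estimate_common_dispersion <- function(counts, groups, eff_size = NULL) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  if (is.null(eff_size)) eff_size <- colSums(counts)
  if (!any(table(groups) >= 2))
    stop("no group has replication; common dispersion is not estimable")
  pseudo <- .equalize_counts(counts, eff_size)
  fit <- optimize(function(lp) .cond_ll(pseudo, groups, exp(lp)),
                  interval = log(c(1e-6, 50)), maximum = TRUE, tol = 1e-6)
  phi <- exp(fit$maximum)
  # boundary: likelihood still rising toward phi -> 0 means no overdispersion
  if (phi < 2e-6 ||
      .cond_ll(pseudo, groups, 1e-8) >= fit$objective) return(0)
  phi
}

#' Tagwise dispersions by weighted conditional likelihood
#'
#' Per-transcript conditional ML shrunk toward the common value: each
#' transcript maximizes its own conditional log-likelihood plus
#' `prior_weight` times the average per-transcript log-likelihood (whose
#' maximum is the common dispersion). `prior_weight` is in equivalent
#' observations; `Inf` returns the common value for every transcript.
#' Maximization is over a fixed 301-point log-spaced grid.
#'
#' @inheritParams estimate_common_dispersion
#' @param common common dispersion from [estimate_common_dispersion()].
#' @param prior_weight shrinkage strength (default 10).
#' @return Named vector of per-transcript dispersions.
#' @export
estimate_tagwise_dispersion <- function(counts, groups, common,
                                        prior_weight = 10, eff_size = NULL) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  if (is.null(eff_size)) eff_size <- colSums(counts)
  if (is.infinite(prior_weight))
    return(setNames(rep(common, nrow(counts)), rownames(counts)))
  pseudo <- .equalize_counts(counts, eff_size)
  grid <- exp(seq(log(1e-4), log(30), length.out = 301))
  per_gene <- matrix(0, nrow(counts), length(grid))
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 2) next
    y <- pseudo[, cols, drop = FALSE]
    n <- length(cols)
    z <- rowSums(y)
    for (k in seq_along(grid)) {
      r <- 1 / grid[k]
      per_gene[, k] <- per_gene[, k] +
        rowSums(lgamma(y + r)) - n * lgamma(r) - lgamma(z + n * r) + lgamma(n * r)
    }
  }
  lbar <- colMeans(per_gene)
  score <- per_gene + prior_weight * matrix(lbar, nrow(counts), length(grid), byrow = TRUE)
  est <- grid[max.col(score, ties.method = "first")]
  setNames(est, rownames(counts))
}

# exact conditional two-sided p for pooled equalized counts za vs zb with
# na, nb libraries and dispersion phi (phi = 0 degenerates to binomial)
.nb_exact_p <- function(za, zb, na, nb, phi) {
  t <- za + zb
  if (t == 0) return(1)
  if (t > 5e6) {
    warning("conditional total > 5e6; using normal approximation")
    prop <- na / (na + nb)
    mu <- t * prop
    m <- t / (na + nb)
    v <- if (phi > 0) t * prop * (1 - prop) * (1 + m * phi) else t * prop * (1 - prop)
    zscore <- (za - mu) / sqrt(v)
    return(min(1, 2 * stats::pnorm(-abs(zscore))))
  }
  k <- 0:t
  if (phi == 0) {
    logp <- dbinom(k, t, na / (na + nb), log = TRUE)
  } else {
    r <- 1 / phi
    m <- t / (na + nb)
    logp <- dnbinom(k, size = na * r, mu = na * m, log = TRUE) +
      dnbinom(t - k, size = nb * r, mu = nb * m, log = TRUE)
    logp <- logp - .logsumexp(logp)
  }
  p_obs <- logp[za + 1]
  # minimum-likelihood two-sided convention, with the usual relative slack
  sum(exp(logp[logp <= p_obs + log(1 + 1e-7)]))
}

#' Negative-binomial exact test
#'
#' Two-group exact test: library sizes are equalized by proportional scaling
#' to the geometric-mean effective size, counts pooled per group, and the
#' p-value computed from the conditional distribution of the group-A total
#' given the grand total, summing all outcomes with probability less than or
#' equal to the observed one (two-sided). At dispersion 0 this is the
#' conditional binomial test.
#'
#' @param counts_a,counts_b matrices (transcripts x libraries) for the two
#'   groups; vectors are treated as single libraries.
#' @param size_a,size_b effective library sizes; default column sums.
#' @param dispersion scalar or per-transcript vector, `>= 0`.
#' @return Named vector of two-sided p-values.
#' @export
nb_exact_test <- function(counts_a, counts_b, size_a = NULL, size_b = NULL,
                          dispersion) {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  if (nrow(counts_a) != nrow(counts_b)) stop("row mismatch between groups")
  if (any(dispersion < 0)) stop("dispersion must be >= 0")
  if (is.null(size_a)) size_a <- colSums(counts_a)
  if (is.null(size_b)) size_b <- colSums(counts_b)
  eq <- .equalize_counts(cbind(counts_a, counts_b), c(size_a, size_b))
  na <- ncol(counts_a); nb <- ncol(counts_b)
  za <- rowSums(eq[, seq_len(na), drop = FALSE])
  zb <- rowSums(eq[, na + seq_len(nb), drop = FALSE])
  phi <- rep_len(dispersion, nrow(counts_a))
  p <- vapply(seq_len(nrow(counts_a)),
              function(i) .nb_exact_p(za[i], zb[i], na, nb, phi[i]), 0)
  setNames(pmin(p, 1), rownames(counts_a))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement (wraps
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same order as input.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

# log2 fold change on CPM with pseudo-count, group A over group B
.log2fc_cpm <- function(cpm, cols_a, cols_b, pseudo = 0.25) {
  log2(rowMeans(cpm[, cols_a, drop = FALSE]) + pseudo) -
    log2(rowMeans(cpm[, cols_b, drop = FALSE]) + pseudo)
}

#' Call over-expressed silk transcripts (OESTs)
#'
#' Full pipeline for one species: CPM filter, TMM factors, common and
#' tagwise dispersion estimation on the silk/non-silk grouping, exact test
#' of pooled silk-gland libraries against pooled non-silk libraries, BH
#' adjustment. A transcript is an OEST when it is silk-overrepresented
#' (positive log2 fold change on pseudo-counted CPM) and FDR < `alpha`.
#'
#' @param cm a [count_matrix()] for one species.
#' @param silk,nonsilk tissue ids of the two classes; defaults
#'   [silk_gland_types()] / [non_silk_tissues()].
#' @param alpha FDR threshold (default 0.05).
#' @param dispersion `"tagwise"` (default) or `"common"`.
#' @param prior_weight tagwise shrinkage weight.
#' @param cpm_threshold low-expression CPM cutoff.
#' @return data.frame with columns `transcript`, `logFC`, `PValue`, `FDR`,
#'   `dispersion`, `oest_flag`.
#' @export
call_oests <- function(cm, silk = silk_gland_types(), nonsilk = non_silk_tissues(),
                       alpha = 0.05, dispersion = c("tagwise", "common"),
                       prior_weight = 10, cpm_threshold = 1) {
  dispersion <- match.arg(dispersion)
  smp <- cm$samples
  silk_libs <- smp$library[smp$tissue %in% silk]
  ns_libs <- smp$library[smp$tissue %in% nonsilk]
  if (length(silk_libs) == 0 || length(ns_libs) == 0)
    stop("both silk and non-silk libraries are required")
  f <- tmm_factors(cm)
  cpm <- compute_cpm(cm, f)
  keep <- low_expression_filter(cpm, cpm_threshold)
  counts <- cm$counts[keep, c(silk_libs, ns_libs), drop = FALSE]
  eff <- (cm$library_size * f)[c(silk_libs, ns_libs)]
  groups <- c(rep("silk", length(silk_libs)), rep("nonsilk", length(ns_libs)))
  common <- estimate_common_dispersion(counts, groups, eff)
  disp <- if (dispersion == "tagwise") {
    estimate_tagwise_dispersion(counts, groups, common, prior_weight, eff)
  } else {
    setNames(rep(common, nrow(counts)), rownames(counts))
  }
  p <- nb_exact_test(counts[, seq_along(silk_libs), drop = FALSE],
                     counts[, length(silk_libs) + seq_along(ns_libs), drop = FALSE],
                     eff[seq_along(silk_libs)],
                     eff[length(silk_libs) + seq_along(ns_libs)],
                     disp)
  fdr <- bh_fdr(p)
  lfc <- .log2fc_cpm(cpm[keep, , drop = FALSE],
                     match(silk_libs, colnames(cpm)),
                     match(ns_libs, colnames(cpm)))
  data.frame(transcript = keep,
             logFC = unname(lfc),
             PValue = unname(p),
             FDR = unname(fdr),
             dispersion = unname(disp),
             common_dispersion = common,
             oest_flag = unname(lfc > 0 & fdr < alpha),
             row.names = NULL)
}

#' Per-gland contrast against pooled non-silk tissues
#'
#' Same exact-test machinery as [call_oests()] but comparing a single gland
#' type to the pooled non-silk libraries. When the gland is unreplicated the
#' dispersion is fixed at `fixed_dispersion` (0.4, the stated stand-in for
#' the biological CV); otherwise tagwise estimates are used.
#'
#' @inheritParams call_oests
#' @param gland one silk gland tissue id.
#' @param fixed_dispersion dispersion for replicate-free glands.
#' @return data.frame as in [call_oests()] plus `dispersion_source`.
#' @export
per_gland_contrast <- function(cm, gland, nonsilk = non_silk_tissues(),
                               alpha = 0.05, fixed_dispersion = 0.4,
                               prior_weight = 10, cpm_threshold = 1) {
  smp <- cm$samples
  if (!gland %in% smp$tissue) stop("unknown gland id: ", gland)
  gl_libs <- smp$library[smp$tissue == gland]
  ns_libs <- smp$library[smp$tissue %in% nonsilk]
  if (length(ns_libs) == 0) stop("no non-silk libraries present")
  f <- tmm_factors(cm)
  cpm <- compute_cpm(cm, f)
  keep <- low_expression_filter(cpm, cpm_threshold)
  counts <- cm$counts[keep, c(gl_libs, ns_libs), drop = FALSE]
  eff <- (cm$library_size * f)[c(gl_libs, ns_libs)]
  replicated <- length(gl_libs) >= 2
  if (replicated) {
    groups <- c(rep("gland", length(gl_libs)), rep("nonsilk", length(ns_libs)))
    common <- estimate_common_dispersion(counts, groups, eff)
    disp <- estimate_tagwise_dispersion(counts, groups, common, prior_weight, eff)
    src <- "tagwise"
  } else {
    disp <- setNames(rep(fixed_dispersion, nrow(counts)), rownames(counts))
    src <- "fixed"
  }
  p <- nb_exact_test(counts[, seq_along(gl_libs), drop = FALSE],
                     counts[, length(gl_libs) + seq_along(ns_libs), drop = FALSE],
                     eff[seq_along(gl_libs)],
                     eff[length(gl_libs) + seq_along(ns_libs)],
                     disp)
  fdr <- bh_fdr(p)
  lfc <- .log2fc_cpm(cpm[keep, , drop = FALSE],
                     match(gl_libs, colnames(cpm)),
                     match(ns_libs, colnames(cpm)))
  data.frame(transcript = keep,
             logFC = unname(lfc),
             PValue = unname(p),
             FDR = unname(fdr),
             dispersion = unname(disp),
             dispersion_source = src,
             significant = unname(lfc > 0 & fdr < alpha),
             row.names = NULL)
}

#' Two-fold silk expression flags
#'
#' For each transcript, whether its unweighted mean FPKM across silk-gland
#' tissues strictly exceeds twice its mean across non-silk tissues, plus a
#' companion flag for mean FPKM > 1 in at least one tissue. A zero non-silk
#' mean with positive silk expression counts as above threshold; 0/0 does
#' not.
#'
#' @param profile transcript x tissue mean-FPKM matrix.
#' @param silk,nonsilk tissue column sets.
#' @return data.frame with `transcript`, `twofold_silk`, `fpkm_gt1`.
#' @export
twofold_silk_flag <- function(profile, silk = silk_gland_types(),
                              nonsilk = non_silk_tissues()) {
  silk <- intersect(silk, colnames(profile))
  nonsilk <- intersect(nonsilk, colnames(profile))
  if (length(silk) == 0 || length(nonsilk) == 0)
    stop("profile must contain both tissue classes")
  ms <- rowMeans(profile[, silk, drop = FALSE])
  mn <- rowMeans(profile[, nonsilk, drop = FALSE])
  flag <- ifelse(mn == 0, ms > 0, ms > 2 * mn)
  data.frame(transcript = rownames(profile),
             twofold_silk = unname(flag),
             fpkm_gt1 = unname(apply(profile, 1, max) > 1),
             row.names = NULL)
}
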