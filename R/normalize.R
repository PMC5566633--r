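#' TMM normalization factors
#'
#' Trimmed mean of M-values scaling factors (Robinson & Oshlack 2010), the
#' composition-bias correction used before all expression comparisons here.
#' Transcripts zero in either library of a pair are excluded; M-values are
#' weighted by inverse asymptotic (delta-method binomial) variance; the top
#' and bottom `logratio_trim` of M and `abs_trim` of A are trimmed. Factors
#' are rescaled to geometric mean 1.
#'
#' @param cm a [count_matrix()], or a plain counts matrix.
#' @param ref_library optional library id to normalize against; the default
#'   picks the library whose upper-quartile CPM is closest to the mean
#'   upper-quartile.
#' @param logratio_trim,abs_trim trim fractions on M and A (defaults 0.30,
#'   0.05).
#' @param weighted weight M-values by inverse asymptotic variance (default
#'   TRUE). The weights depend on absolute counts, so only the unweighted
#'   trimmed mean is exactly invariant to rescaling a library's depth.
#' @param library_size optional named sizes when `cm` is a plain matrix.
#' @return Named numeric vector of factors, one per library.
#' @export
tmm_factors <- function(cm, ref_library = NULL, logratio_trim = 0.30,
                        abs_trim = 0.05, weighted = TRUE, library_size = NULL) {
  if (inherits(cm, "count_matrix")) {
    x <- cm$counts
    lib <- cm$library_size
  } else {
    x <- as.matrix(cm)
    lib <- if (is.null(library_size)) colSums(x) else library_size[colnames(x)]
  }
  if (ncol(x) < 2) stop("TMM needs at least 2 libraries")
  zero_lib <- colSums(x) == 0
  if (any(zero_lib))
    stop("library has all-zero counts: ", paste(colnames(x)[zero_lib], collapse = ", "))
  if (is.null(ref_library)) {
    f75 <- vapply(seq_len(ncol(x)),
                  function(j) quantile(x[, j] / lib[j], 0.75, names = FALSE),
                  0)
    ref <- which.min(abs(f75 - mean(f75)))
  } else {
    ref <- match(ref_library, colnames(x))
    if (is.na(ref)) stop("unknown reference library: ", ref_library)
  }
  f <- vapply(seq_len(ncol(x)), function(j) {
    .tmm_pair(x[, j], x[, ref], lib[j], lib[ref], logratio_trim, abs_trim,
              weighted)
  }, 0)
  f <- f / .geomean(f)
  names(f) <- colnames(x)
  f
}

# one library against the reference; mirrors the standard TMM recipe
.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim,
                      weighted = TRUE) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0 || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * abs_trim) + 1
  hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
          (rank(absE) >= loS & rank(absE) <= hiS)
  f <- if (weighted) {
    sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  } else {
    mean(logR[keep], na.rm = TRUE)
  }
  2^f
}

#' Counts per million on TMM-adjusted library sizes
#'
#' `cpm = count / (library_size * tmm_factor) * 1e6`.
#'
#' @inheritParams tmm_factors
#' @param factors TMM factors from [tmm_factors()].
#' @return Matrix of CPM values.
#' @export
compute_cpm <- function(cm, factors, library_size = NULL) {
  if (inherits(cm, "count_matrix")) {
    x <- cm$counts; lib <- cm$library_size
  } else {
    x <- as.matrix(cm)
    lib <- if (is.null(library_size)) colSums(x) else library_size[colnames(x)]
  }
  factors <- factors[colnames(x)]
  if (any(factors <= 0)) stop("TMM factors must be positive")
  sweep(x, 2, lib * factors, "/") * 1e6
}

#' Low-expression filter
#'
#' Retains transcripts with CPM at or above `threshold` in at least one
#' library; everything below in every library is dropped before testing.
#'
#' @param cpm CPM matrix from [compute_cpm()].
#' @param threshold CPM cutoff (default 1).
#' @return Character vector of retained transcript ids.
#' @export
low_expression_filter <- function(cpm, threshold = 1) {
  stopifnot(threshold > 0)
  if (nrow(cpm) == 0) return(character(0))
  rownames(cpm)[apply(cpm, 1, max) >= threshold]
}

#' TMM-normalized FPKM
#'
#' Fragments per effective kilobase per million aligned fragments, with the
#' TMM factor applied multiplicatively per library (the study's stated
#' convention); set `apply = "divide"` for the more common alternative.
#'
#' @inheritParams compute_cpm
#' @param effective_length optional named vector when `cm` is a plain matrix.
#' @param apply `"multiply"` (default) or `"divide"`.
#' @return Matrix of FPKM values.
#' @export
compute_fpkm <- function(cm, factors, effective_length = NULL,
                         library_size = NULL, apply = c("multiply", "divide")) {
  apply <- match.arg(apply)
  if (inherits(cm, "count_matrix")) {
    x <- cm$counts; lib <- cm$library_size; len <- cm$effective_length
  } else {
    x <- as.matrix(cm)
    lib <- if (is.null(library_size)) colSums(x) else library_size[colnames(x)]
    len <- effective_length[rownames(x)]
  }
  if (any(len <= 0)) stop("effective lengths must be > 0")
  factors <- factors[colnames(x)]
  fpkm <- x / (len / 1e3)
  fpkm <- sweep(fpkm, 2, lib / 1e6, "/")
  fac <- if (apply == "multiply") factors else 1 / factors
  sweep(fpkm, 2, fac, "*")
}

#' Mean FPKM per tissue
#'
#' Arithmetic mean of normalized FPKM over the replicate libraries of each
#' (species, tissue). With a single species in the sheet, returns a
#' transcript x tissue matrix; with several, a named list of such matrices.
#'
#' @param fpkm FPKM matrix (libraries in columns).
#' @param samples sample sheet data.frame (`library`, `species`, `tissue`).
#' @return Matrix, or named list of matrices keyed by species.
#' @export
mean_tissue_fpkm <- function(fpkm, samples) {
  samples <- samples[match(colnames(fpkm), samples$library), , drop = FALSE]
  if (anyNA(samples$library)) stop("every library must appear in the sample sheet")
  per_species <- lapply(split(seq_len(ncol(fpkm)), samples$species), function(idx) {
    tis <- samples$tissue[idx]
    out <- vapply(split(idx, tis), function(cols) {
      rowMeans(fpkm[, cols, drop = FALSE])
    }, numeric(nrow(fpkm)))
    out <- matrix(out, nrow = nrow(fpkm),
                  dimnames = list(rownames(fpkm), names(split(idx, tis))))
    out
  })
  if (length(per_species) == 1) per_species[[1]] else per_species
}
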