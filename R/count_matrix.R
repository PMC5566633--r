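#' Transcript-by-library count matrix with metadata
#'
#' Container for RSEM-style expected counts: a non-negative integer matrix
#' (transcripts x libraries), per-transcript effective lengths in bp, and a
#' sample sheet mapping each library to (species, tissue, replicate).
#' Library sizes default to column sums of the count matrix.
#'
#' @param counts numeric matrix, transcripts x libraries, non-negative, with
#'   row and column names.
#' @param effective_length numeric vector named by transcript, positive bp.
#' @param samples data.frame with columns `library`, `species`, `tissue`,
#'   `replicate`; one row per library of `counts`.
#' @param library_size optional named vector of total aligned fragments per
#'   library; defaults to `colSums(counts)`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, effective_length, samples, library_size = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have transcript rownames and library colnames")
  if (any(counts < 0)) stop("negative counts are not allowed")
  stopifnot(is.data.frame(samples),
            all(c("library", "species", "tissue", "replicate") %in% names(samples)))
  missing_lib <- setdiff(colnames(counts), samples$library)
  if (length(missing_lib))
    stop("libraries absent from sample sheet: ", paste(missing_lib, collapse = ", "))
  effective_length <- effective_length[rownames(counts)]
  if (anyNA(effective_length))
    stop("effective_length missing for some transcripts")
  if (any(effective_length <= 0)) stop("effective lengths must be > 0")
  if (is.null(library_size)) library_size <- colSums(counts)
  library_size <- library_size[colnames(counts)]
  if (any(library_size <= 0)) stop("library sizes must be > 0")
  samples <- samples[match(colnames(counts), samples$library), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts,
                 effective_length = effective_length,
                 samples = samples,
                 library_size = library_size),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d transcripts x %d libraries (%d species, %d tissues)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$species)),
              length(unique(x$samples$tissue))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix bundle from TSV files
#'
#' @param counts_file transcripts x libraries TSV (first column = transcript id).
#' @param lengths_file TSV with columns `transcript`, `effective_length`.
#' @param samples_file TSV with columns `library`, `species`, `tissue`,
#'   `replicate`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(counts_file, lengths_file, samples_file) {
  cts <- read.delim(counts_file, row.names = 1, check.names = FALSE)
  len <- read.delim(lengths_file)
  smp <- read.delim(samples_file)
  smp$library <- as.character(smp$library)
  count_matrix(as.matrix(cts),
               setNames(len$effective_length, len$transcript),
               smp)
}

#' Write a count matrix bundle to TSV files
#'
#' @param cm a [count_matrix()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return Invisibly, the paths written.
#' @export
write_count_matrix <- function(cm, dir, prefix = "") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("counts.tsv", "effective_lengths.tsv", "samples.tsv")))
  df <- data.frame(transcript = rownames(cm$counts), cm$counts, check.names = FALSE)
  write.table(df, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(transcript = names(cm$effective_length),
                         effective_length = unname(cm$effective_length)),
              paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cm$samples, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
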