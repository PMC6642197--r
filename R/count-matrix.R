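#' Gene-by-sample count matrix with digit metadata
#'
#' The central container of the pipeline: an integer matrix of mapped-read
#' counts (genes in rows, samples in columns) together with per-sample
#' metadata describing species, limb (fore/hind), digit position (1-based
#' ordinal, anterior to posterior, matching the D1..D5 notation),
#' developmental stage, and replicate index.
#'
#' @param counts integer matrix, genes x samples, with unique row names
#'   (gene identifiers) and column names (sample identifiers).
#' @param samples data frame with one row per sample and columns
#'   `sample_id`, `species`, `limb`, `digit`, `stage`, `replicate`.
#'   Rows are reordered to match `colnames(counts)`.
#'
#' @return An object of class `CountMatrix`: a list with elements `counts`
#'   (integer matrix) and `samples` (data frame keyed by `sample_id`).
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated gene identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample identifiers")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("counts must be non-negative integers; offending cell(s): ",
         paste(sprintf("[gene %s, sample %s]",
                       rownames(counts)[bad[, 1]],
                       colnames(counts)[bad[, 2]])[seq_len(min(5, nrow(bad)))],
               collapse = ", "))
  }
  storage.mode(counts) <- "integer"

  samples <- as.data.frame(samples)
  req <- c("sample_id", "species", "limb", "digit", "stage", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0)
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  only_meta <- setdiff(samples$sample_id, colnames(counts))
  only_counts <- setdiff(colnames(counts), samples$sample_id)
  if (length(only_meta) > 0 || length(only_counts) > 0)
    stop("metadata and counts disagree on the sample set; ",
         if (length(only_counts) > 0)
           paste0("missing from metadata: ", paste(only_counts, collapse = ", "), "; "),
         if (length(only_meta) > 0)
           paste0("missing from counts: ", paste(only_meta, collapse = ", ")))
  if (any(is.na(samples[req])))
    stop("sample metadata contains missing values")
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  samples$digit <- as.integer(samples$digit)
  if (any(samples$digit < 1)) stop("digit positions must be >= 1 (anterior = 1)")

  structure(list(counts = counts, samples = samples), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("species:", paste(unique(x$samples$species), collapse = ", "), "\n")
  cat("digits: ", paste(sort(unique(x$samples$digit)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Subset a CountMatrix by genes and/or samples
#'
#' @param x CountMatrix.
#' @param genes character vector of gene identifiers (default: keep all).
#' @param sample_ids character vector of sample identifiers (default: keep all).
#' @return CountMatrix restricted to the requested axes, in the requested order.
#' @export
subset_count_matrix <- function(x, genes = NULL, sample_ids = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  if (is.null(genes)) genes <- rownames(x$counts)
  if (is.null(sample_ids)) sample_ids <- colnames(x$counts)
  missing_g <- setdiff(genes, rownames(x$counts))
  if (length(missing_g) > 0)
    stop("unknown gene(s): ", paste(utils::head(missing_g, 5), collapse = ", "))
  missing_s <- setdiff(sample_ids, colnames(x$counts))
  if (length(missing_s) > 0)
    stop("unknown sample(s): ", paste(missing_s, collapse = ", "))
  count_matrix(x$counts[genes, sample_ids, drop = FALSE],
               x$samples[match(sample_ids, x$samples$sample_id), , drop = FALSE])
}

#' Read a count matrix and its sample metadata from TSV files
#'
#' The counts file is genes-in-rows / samples-in-columns with a header row of
#' sample identifiers and gene identifiers in the first column. The metadata
#' file has one row per sample with columns `sample_id`, `species`, `limb`,
#' `digit`, `stage`, `replicate`. Sample order is taken from the counts
#' header. Any non-integer, negative, or missing cell, and any disagreement
#' between the two files' sample sets, is rejected with a diagnostic naming
#' the offender.
#'
#' @param counts_path path to the TSV count table.
#' @param metadata_path path to the TSV sample-metadata table.
#' @return A [count_matrix()] object.
#' @export
read_count_matrix <- function(counts_path, metadata_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("count table needs a gene column plus >=1 sample")
  gene_ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(tab[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop("non-numeric count cell at gene ", gene_ids[bad[1, 1]],
         ", sample ", colnames(mat)[bad[1, 2]])
  }
  frac <- which(mat != round(mat), arr.ind = TRUE)
  if (nrow(frac) > 0)
    stop("non-integer count ", mat[frac[1, 1], frac[1, 2]], " at gene ",
         gene_ids[frac[1, 1]], ", sample ", colnames(mat)[frac[1, 2]])
  rownames(mat) <- gene_ids
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  count_matrix(mat, meta)
}

#' Write a CountMatrix to a pair of TSV files
#'
#' Inverse of [read_count_matrix()]; `read(write(x))` reproduces `x`.
#'
#' @param x CountMatrix.
#' @param counts_path,metadata_path output paths.
#' @export
write_count_matrix <- function(x, counts_path, metadata_path) {
  stopifnot(inherits(x, "CountMatrix"))
  tab <- data.frame(gene_id = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read a count matrix from Matrix-Market triplets plus index files
#'
#' Optional sparse input route: an MTX coordinate file with sidecar
#' one-column gene and sample index files. Produces the same `CountMatrix`
#' as the TSV reader.
#'
#' @param mtx_path MatrixMarket coordinate file of counts.
#' @param genes_path,samples_path one identifier per line, in matrix order.
#' @param metadata_path TSV sample metadata as in [read_count_matrix()].
#' @return A [count_matrix()] object.
#' @export
read_count_matrix_mtx <- function(mtx_path, genes_path, samples_path,
                                  metadata_path) {
  lines <- readLines(mtx_path)
  lines <- lines[!startsWith(lines, "%")]
  hdr <- as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]])
  trip <- if (length(lines) > 1) {
    do.call(rbind, lapply(strsplit(trimws(lines[-1]), "\\s+"), as.numeric))
  } else matrix(numeric(0), 0, 3)
  mat <- matrix(0L, hdr[1], hdr[2])
  if (nrow(trip) > 0) mat[trip[, 1:2, drop = FALSE]] <- trip[, 3]
  rownames(mat) <- readLines(genes_path)
  colnames(mat) <- readLines(samples_path)
  count_matrix(mat, utils::read.delim(metadata_path, stringsAsFactors = FALSE))
}
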