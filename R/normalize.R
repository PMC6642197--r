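#' Expression matrix with recorded transform state
#'
#' Relative-abundance values on the same gene x sample axes as a
#' [count_matrix()]. `transform_state` advances monotonically along
#' tpm -> sqrt_tpm -> centered_sqrt_tpm; the bulk assignment used for
#' centering (if any) is recorded so downstream projections can reproduce it.
#'
#' @param values numeric matrix, genes x samples.
#' @param samples per-sample metadata data frame (as in CountMatrix).
#' @param transform_state one of "tpm", "sqrt_tpm", "centered_sqrt_tpm".
#' @param universe gene universe the TPM denominator was computed over.
#' @param bulks named character vector sample_id -> bulk label, or NULL.
#' @export
expression_matrix <- function(values, samples,
                              transform_state = c("tpm", "sqrt_tpm",
                                                  "centered_sqrt_tpm"),
                              universe = rownames(values), bulks = NULL) {
  transform_state <- match.arg(transform_state)
  values <- as.matrix(values)
  if (transform_state != "centered_sqrt_tpm" && any(values < 0))
    stop("negative values are only admissible after centering")
  samples <- as.data.frame(samples)
  stopifnot(identical(colnames(values), samples$sample_id))
  structure(list(values = values, samples = samples,
                 transform_state = transform_state,
                 universe = universe, bulks = bulks),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d genes x %d samples\n",
              x$transform_state, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Transcripts per million for one sample
#'
#' TPM_g = 1e6 * (c_g / L_g) / sum_j (c_j / L_j) over the supplied gene
#' universe, with L the median transcript length in bp. Standardizes for
#' both sequencing depth and transcript length; columns sum to 1e6
#' whenever any count is positive.
#'
#' @param counts named integer vector of counts for one sample.
#' @param lengths named numeric vector, gene -> median transcript length (bp).
#' @return named TPM vector over `names(counts)`.
#' @export
compute_tpm <- function(counts, lengths) {
  if (length(counts) == 0) stop("empty gene universe")
  if (is.null(names(counts))) stop("counts must be named by gene")
  missing <- setdiff(names(counts), names(lengths))
  if (length(missing) > 0)
    stop("no transcript length for gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  L <- lengths[names(counts)]
  if (any(!is.finite(L) | L <= 0)) stop("transcript lengths must be > 0")
  rate <- counts / L
  denom <- sum(rate)
  if (denom == 0) {
    warning("sample has zero counts over the universe; TPM set to 0")
    return(stats::setNames(numeric(length(counts)), names(counts)))
  }
  1e6 * rate / denom
}

#' TPM-normalize a CountMatrix
#'
#' Applies [compute_tpm()] column-wise over a configurable gene universe.
#' By default the denominator runs over the full matrix; pass a
#' [gene_list()] to restrict both the rows and the denominator to that
#' list (both conventions are defensible for gene-list analyses, so the
#' choice is explicit and recorded in the result).
#'
#' @param x CountMatrix.
#' @param lengths named numeric vector of median transcript lengths (bp).
#' @param universe optional GeneList restricting the computation.
#' @return ExpressionMatrix in `tpm` state.
#' @export
tpm_normalize <- function(x, lengths, universe = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  genes <- rownames(x$counts)
  if (!is.null(universe)) {
    stopifnot(inherits(universe, "GeneList"))
    genes <- intersect(genes, universe$members)
    if (length(genes) == 0) stop("gene universe does not intersect the matrix")
  }
  counts <- x$counts[genes, , drop = FALSE]
  vals <- vapply(seq_len(ncol(counts)),
                 function(j) compute_tpm(counts[, j], lengths),
                 numeric(length(genes)))
  vals <- matrix(vals, nrow = length(genes),
                 dimnames = list(genes, colnames(counts)))
  expression_matrix(vals, x$samples, "tpm", universe = genes)
}

#' Square-root variance-stabilizing transform
#'
#' @param x ExpressionMatrix in `tpm` state.
#' @return ExpressionMatrix in `sqrt_tpm` state.
#' @export
sqrt_transform <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$transform_state != "tpm")
    stop("sqrt_transform expects the tpm state, got ", x$transform_state)
  out <- x
  out$values <- sqrt(x$values)
  out$transform_state <- "sqrt_tpm"
  out
}

#' Bulk correction: per-gene mean-centering within declared bulks
#'
#' For analyses spanning stages or limbs, each gene is centered to mean zero
#' within every bulk (a bulk being all samples of one stage, or all samples
#' of one limb). After centering, sample profiles can be negatively
#' correlated, so correlation-based dissimilarities range over [0, 2].
#' A singleton bulk yields zeros for its sample and is reported via a
#' message. Idempotent.
#'
#' @param x ExpressionMatrix in `sqrt_tpm` (or already centered) state.
#' @param bulks named character vector mapping every `sample_id` to a bulk
#'   label.
#' @return ExpressionMatrix in `centered_sqrt_tpm` state.
#' @export
bulk_center <- function(x, bulks) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!x$transform_state %in% c("sqrt_tpm", "centered_sqrt_tpm"))
    stop("bulk_center expects sqrt_tpm values, got ", x$transform_state)
  ids <- colnames(x$values)
  if (!all(ids %in% names(bulks)))
    stop("bulk assignment missing for sample(s): ",
         paste(setdiff(ids, names(bulks)), collapse = ", "))
  bulks <- bulks[ids]
  out <- x
  for (b in unique(bulks)) {
    cols <- which(bulks == b)
    if (length(cols) == 1)
      message("bulk '", b, "' has a single sample; its values center to 0")
    m <- rowMeans(x$values[, cols, drop = FALSE])
    out$values[, cols] <- x$values[, cols, drop = FALSE] - m
  }
  out$transform_state <- "centered_sqrt_tpm"
  out$bulks <- bulks
  out
}

#' Restrict an ExpressionMatrix to a gene set and/or samples
#' @param x ExpressionMatrix.
#' @param genes character vector of genes to keep (order respected).
#' @param sample_ids character vector of samples to keep.
#' @export
subset_expression <- function(x, genes = NULL, sample_ids = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (is.null(genes)) genes <- rownames(x$values)
  if (is.null(sample_ids)) sample_ids <- colnames(x$values)
  miss <- setdiff(genes, rownames(x$values))
  if (length(miss) > 0)
    stop("gene(s) absent from expression matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  out <- x
  out$values <- x$values[genes, sample_ids, drop = FALSE]
  out$samples <- x$samples[match(sample_ids, x$samples$sample_id), ,
                           drop = FALSE]
  out$universe <- genes
  if (!is.null(out$bulks)) out$bulks <- out$bulks[sample_ids]
  out
}
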