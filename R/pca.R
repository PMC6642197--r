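#' Centered principal component analysis of sample expression profiles
#'
#' Samples are observations, genes variables; gene means are subtracted and
#' no scaling is applied (sqrt-TPM values are used as-is, so high-abundance
#' genes carry more weight, matching the clustering side of the analysis).
#' Component signs are fixed deterministically by making each loading
#' vector's largest-magnitude entry positive, so bootstrap alignment and
#' projections are stable.
#'
#' @param x ExpressionMatrix (typically `sqrt_tpm` or `centered_sqrt_tpm`).
#' @param scale. standardize genes before the decomposition (off by
#'   default; exposed for completeness).
#' @return `PCAModel`: list with `center` (gene means), `loadings`
#'   (genes x components), `scores` (samples x components),
#'   `explained` (variance fractions), `samples` metadata, and the
#'   `transform_state` the model was fitted on.
#' @export
fit_pca <- function(x, scale. = FALSE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (nrow(x$values) < 1) stop("need at least one gene")
  if (ncol(x$values) < 2) stop("need >= 2 samples")
  dat <- t(x$values)  # samples x genes
  pc <- stats::prcomp(dat, center = TRUE, scale. = scale.)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(k) {
    v <- pc$rotation[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")
  structure(list(center = pc$center, loadings = loadings, scores = scores,
                 explained = pc$sdev^2 / sum(pc$sdev^2),
                 samples = x$samples, transform_state = x$transform_state),
            class = "PCAModel")
}

#' @export
print.PCAModel <- function(x, ...) {
  cat(sprintf("PCAModel: %d samples x %d genes; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), length(x$center), 100 * x$explained[1],
              if (length(x$explained) > 1) 100 * x$explained[2] else 0))
  invisible(x)
}

#' Project held-out samples into a fitted PCA as supplementary observations
#'
#' The held-out samples must share the model's gene universe and expression
#' state; when the analysis uses bulk correction, the held-out bulk is
#' centered with its own means before projection (the bulk rule), which is
#' the caller's responsibility via [bulk_center()]. The projection is
#' `(profile - model gene means) \%*\% loadings`; held-out copies of
#' training samples land exactly on their training scores.
#'
#' @param model PCAModel.
#' @param x ExpressionMatrix of held-out samples.
#' @return scores matrix, held-out samples x components.
#' @export
project_supplementary <- function(model, x) {
  stopifnot(inherits(model, "PCAModel"), inherits(x, "ExpressionMatrix"))
  genes <- names(model$center)
  missing <- setdiff(genes, rownames(x$values))
  if (length(missing) > 0)
    stop("held-out samples lack model gene(s): ",
         paste(utils::head(missing, 10), collapse = ", "))
  if (x$transform_state != model$transform_state)
    warning("projecting ", x$transform_state, " data into a ",
            model$transform_state, " model")
  dat <- t(x$values[genes, , drop = FALSE])
  sweep(dat, 2, model$center) %*% model$loadings
}

#' Bootstrap variability of PCA scores
#'
#' Resamples samples with replacement, refits the centered PCA, aligns each
#' replicate's components to the reference fit by the sign of the loading
#' inner product, projects all original samples onto the replicate model,
#' and summarizes per-sample score spread.
#'
#' @param x ExpressionMatrix.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @param n_comp number of components summarized (default 2).
#' @return list with `score_mean` and `score_sd` (samples x components),
#'   `n_boot`, `seed`.
#' @export
bootstrap_pca <- function(x, n_boot = 1000, seed = 1, n_comp = 2) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (ncol(x$values) < 3) stop("need >= 3 samples")
  if (n_boot < 100) warning("fewer than 100 bootstrap replicates")
  ref <- fit_pca(x)
  n_comp <- min(n_comp, ncol(ref$loadings))
  ids <- colnames(x$values)
  set.seed(seed)
  acc <- array(NA_real_, c(length(ids), n_comp, n_boot),
               dimnames = list(ids, NULL, NULL))
  for (b in seq_len(n_boot)) {
    take <- sort(sample(ids, length(ids), replace = TRUE))
    if (length(unique(take)) < 2) next
    xb <- x
    xb$values <- x$values[, take, drop = FALSE]
    colnames(xb$values) <- make.unique(take)
    xb$samples <- x$samples[match(take, x$samples$sample_id), , drop = FALSE]
    xb$samples$sample_id <- colnames(xb$values)
    fb <- fit_pca(xb)
    k <- min(n_comp, ncol(fb$loadings))
    align <- sign(colSums(fb$loadings[, seq_len(k), drop = FALSE] *
                            ref$loadings[, seq_len(k), drop = FALSE]))
    align[align == 0] <- 1
    proj <- sweep(t(x$values), 2, fb$center) %*%
      fb$loadings[, seq_len(k), drop = FALSE]
    acc[, seq_len(k), b] <- sweep(proj, 2, align, "*")
  }
  list(score_mean = apply(acc, c(1, 2), mean, na.rm = TRUE),
       score_sd = apply(acc, c(1, 2), stats::sd, na.rm = TRUE),
       n_boot = n_boot, seed = seed)
}

#' Assign projected samples to reference digit regions of the PCA plane
#'
#' Replaces visual reading of "regions of the PCA plane" with a
#' deterministic nearest-centroid rule: each reference digit's centroid is
#' the mean score of its replicates in the leading-component plane; each
#' projected sample is assigned to the nearest centroid (Euclidean), with
#' exact ties broken toward the lower digit number and flagged by a zero
#' margin.
#'
#' @param model PCAModel fitted on the reference species (its `samples`
#'   metadata supplies the reference digit labels).
#' @param scores projected scores from [project_supplementary()].
#' @param plane which components span the plane (default first two).
#' @return `CorrespondenceCall` data frame: per projected sample the
#'   assigned reference digit, distance, and margin to the second-nearest
#'   centroid.
#' @export
call_correspondence <- function(model, scores, plane = 1:2) {
  stopifnot(inherits(model, "PCAModel"))
  digits <- sort(unique(model$samples$digit))
  if (length(digits) < 2) stop("need >= 2 reference digit groups")
  cent <- t(vapply(digits, function(d) {
    rows <- which(model$samples$digit == d)
    if (length(rows) == 0) stop("reference digit ", d, " has no replicates")
    colMeans(model$scores[rows, plane, drop = FALSE])
  }, numeric(length(plane))))
  rownames(cent) <- digits
  scores <- as.matrix(scores)[, plane, drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(scores)), function(i) {
    dists <- sqrt(rowSums(sweep(cent, 2, scores[i, ])^2))
    ord <- order(dists, as.numeric(rownames(cent)))  # tie -> lower digit
    data.frame(sample_id = rownames(scores)[i],
               assigned_digit = as.integer(rownames(cent)[ord[1]]),
               distance = dists[ord[1]],
               margin = if (length(dists) > 1)
                 dists[ord[2]] - dists[ord[1]] else NA_real_,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("CorrespondenceCall", "data.frame")
  out
}
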