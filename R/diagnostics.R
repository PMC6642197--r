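#' Quantify uniformity of a p-value distribution
#'
#' Under no true differential expression, adjacent-digit p-values are
#' Uniform(0, 1); truly differentiated digits bias the distribution toward
#' zero. This operationalizes histogram inspection with two deterministic
#' statistics: the one-sample Kolmogorov-Smirnov distance from Uniform(0,1)
#' and the excess mass of the first histogram bin over its uniform share.
#'
#' @param p p-values (NAs dropped).
#' @param n_bins histogram bins (default 20).
#' @param ks_threshold classification threshold: "uniform-like" iff
#'   KS < threshold (default 0.05).
#' @return list with `ks`, `first_bin_excess`, `histogram` (bin counts),
#'   `uniform_like`, `n`.
#' @export
pvalue_uniformity <- function(p, n_bins = 20, ks_threshold = 0.05) {
  p <- p[!is.na(p)]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n < 100) warning("fewer than 100 p-values; statistics are noisy")
  s <- sort(p)
  ks <- max(seq_len(n) / n - s, s - (seq_len(n) - 1) / n)
  h <- graphics::hist(p, breaks = seq(0, 1, length.out = n_bins + 1),
                      plot = FALSE)$counts
  list(ks = ks, first_bin_excess = h[1] / n - 1 / n_bins, histogram = h,
       uniform_like = ks < ks_threshold, n = n)
}

#' Within-group replicate concordance and best-pair selection
#'
#' Computes all within-group pairwise Pearson correlations of sample
#' profiles and selects each group's most-correlated pair (ties broken
#' lexicographically on the pair's sample ids), flagging groups whose best
#' pair falls below `flag_below`. Supports the robustness check of
#' re-running DE on only the two most highly correlated replicates per
#' digit, which in well-behaved data correlate above 0.99.
#'
#' @param x ExpressionMatrix (or plain matrix).
#' @param groups named character vector sample_id -> group label.
#' @param flag_below threshold for flagging (default 0.99).
#' @return list with `pairs` (data frame: group, sample_1, sample_2, r,
#'   best) and `best` (named list group -> selected pair); singleton groups
#'   appear with no pair.
#' @export
replicate_concordance <- function(x, groups, flag_below = 0.99) {
  vals <- if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)
  ids <- colnames(vals)
  stopifnot(all(ids %in% names(groups)))
  groups <- groups[ids]
  rows <- list()
  best <- list()
  for (g in unique(groups)) {
    members <- sort(ids[groups == g])
    if (length(members) < 2) {
      best[[g]] <- character(0)
      next
    }
    cm <- stats::cor(vals[, members, drop = FALSE])
    pr <- t(utils::combn(members, 2))
    r <- cm[pr]
    ord <- order(-r, pr[, 1], pr[, 2])  # max r; lexicographic tie-break
    b <- ord[1]
    rows[[g]] <- data.frame(group = g, sample_1 = pr[, 1],
                            sample_2 = pr[, 2], r = r,
                            best = seq_along(r) == b,
                            flagged = seq_along(r) == b & r < flag_below,
                            stringsAsFactors = FALSE)
    best[[g]] <- c(pr[b, 1], pr[b, 2])
  }
  list(pairs = if (length(rows) > 0) do.call(rbind, c(rows, make.row.names = FALSE)) else NULL,
       best = best)
}

#' Restrict a CountMatrix to the two most-correlated replicates per digit
#'
#' Convenience wrapper composing [replicate_concordance()] (on sqrt-TPM
#' profiles when lengths are given, otherwise on log counts) with
#' [subset_count_matrix()].
#'
#' @param x CountMatrix for one species/limb.
#' @param lengths optional transcript lengths for TPM-based concordance.
#' @return CountMatrix keeping two replicates per (digit, stage) group.
#' @export
best_two_replicates <- function(x, lengths = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  vals <- if (!is.null(lengths)) {
    sqrt_transform(tpm_normalize(x, lengths))$values
  } else log1p(sweep(x$counts, 2, pmax(colSums(x$counts), 1), "/") * 1e6)
  groups <- stats::setNames(paste0(x$samples$stage, "_d", x$samples$digit),
                            x$samples$sample_id)
  rc <- replicate_concordance(vals, groups)
  keep <- unlist(rc$best, use.names = FALSE)
  keep <- colnames(x$counts)[colnames(x$counts) %in% keep]
  subset_count_matrix(x, sample_ids = keep)
}

#' Summarize tagwise dispersion across datasets
#'
#' Orders datasets by mean tagwise dispersion — the comparison behind
#' pedigree arguments (nonsibling "population" collections sit above
#' sibling collections, with correspondingly lower DE sensitivity).
#'
#' @param estimates named list of [estimate_dispersions()] results.
#' @return data frame (one row per dataset, ordered by decreasing mean):
#'   mean, quartiles, common dispersion.
#' @export
dispersion_summary <- function(estimates) {
  stopifnot(length(estimates) > 0)
  out <- do.call(rbind, lapply(names(estimates), function(nm) {
    e <- estimates[[nm]]
    q <- stats::quantile(e$tagwise, c(0.25, 0.5, 0.75))
    data.frame(dataset = nm, mean = mean(e$tagwise), q25 = q[[1]],
               median = q[[2]], q75 = q[[3]], common = e$common,
               stringsAsFactors = FALSE)
  }))
  out[order(-out$mean), , drop = FALSE]
}
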