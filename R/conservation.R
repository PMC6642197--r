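#' Per-species DE gene sets over the one-to-one ortholog universe
#'
#' Restricts each species' DE result for a shared digit boundary to the
#' one-to-one ortholog universe and thresholds the BH-adjusted p (or Storey
#' q) at `fdr`. Sets are expressed as ortholog group ids so intersections
#' are species-comparable; a DE gene outside the universe never appears.
#'
#' @param de_results named list (by species) of `DEResult`s for the same
#'   boundary.
#' @param map [ortholog_map()] covering those species.
#' @param fdr FDR threshold (default 0.05, exclusive: adjusted p < fdr).
#' @param method "bh" or "storey".
#' @return list with `sets` (named list of group-id vectors), `N` (size of
#'   the one-to-one universe), `universe` (group ids), and `direction`
#'   (named list of sign vectors of the members' fold changes).
#' @export
de_sets_by_boundary <- function(de_results, map, fdr = 0.05,
                                method = c("bh", "storey")) {
  method <- match.arg(method)
  stopifnot(inherits(map, "OrthologMap"))
  uni <- one_to_one_universe(map)
  if (nrow(uni) == 0) stop("empty one-to-one ortholog universe")
  missing <- setdiff(names(de_results), names(uni))
  if (length(missing) > 0)
    stop("species missing from the ortholog map: ",
         paste(missing, collapse = ", "))
  out_sets <- out_dir <- list()
  for (sp in names(de_results)) {
    de <- de_results[[sp]]
    idx <- match(uni[[sp]], de$gene_id)
    adj <- if (method == "bh") de$p_bh[idx] else de$q_storey[idx]
    hit <- !is.na(adj) & adj < fdr
    out_sets[[sp]] <- uni$group_id[hit]
    out_dir[[sp]] <- stats::setNames(sign(de$log2_fc[idx][hit]),
                                     uni$group_id[hit])
  }
  list(sets = out_sets, N = nrow(uni), universe = uni$group_id,
       direction = out_dir)
}

#' Intersect per-species DE sets into a conservation result
#'
#' The membership intersection across all species is the primary
#' "conserved differentially expressed" statistic; members whose
#' fold-change sign agrees across every species are additionally reported
#' as the direction-consistent subset (the two reporting styles used for
#' adjacent-digit boundaries and for cross-limb D1 comparisons).
#'
#' @param sets named list (by species) of ortholog-group-id vectors.
#' @param direction optional named list of sign vectors (from
#'   [de_sets_by_boundary()]).
#' @param N universe size; k_i and intersections are reported against it.
#' @param boundary label (e.g., "D1_vs_D2" or "any_digit").
#' @return `ConservationResult`: list with `boundary`, `species`, `N`,
#'   `k` (per-species set sizes), `intersection`,
#'   `direction_consistent`, and `expected`/`tail_p` from
#'   [binomial_overlap_test()] when `N` is known.
#' @export
intersect_conserved <- function(sets, direction = NULL, N = NULL,
                                boundary = "") {
  if (length(sets) < 2) stop("need sets from >= 2 species")
  inter <- Reduce(intersect, sets)
  dir_ok <- inter
  if (!is.null(direction) && length(inter) > 0) {
    sgn <- vapply(inter, function(g) {
      s <- vapply(direction, function(d) unname(d[g]), numeric(1))
      length(unique(s)) == 1 && all(s != 0)
    }, logical(1))
    dir_ok <- inter[sgn]
  }
  res <- list(boundary = boundary, species = names(sets),
              N = N, k = lengths(sets), intersection = inter,
              direction_consistent = dir_ok)
  if (!is.null(N)) {
    bt <- binomial_overlap_test(N, lengths(sets), length(inter))
    res$expected <- bt$expected
    res$tail_p <- bt$tail_p
  }
  structure(res, class = "ConservationResult")
}

#' @export
print.ConservationResult <- function(x, ...) {
  cat(sprintf("ConservationResult [%s]: |intersection| = %d of N = %s (k: %s)\n",
              x$boundary, length(x$intersection),
              if (is.null(x$N)) "?" else x$N,
              paste(x$k, collapse = "/")))
  if (!is.null(x$expected))
    cat(sprintf("  expected by chance %.3g; P(>= observed) = %.3g\n",
                x$expected, x$tail_p))
  invisible(x)
}

#' Binomial test for multi-set overlap
#'
#' Null model: each species' DE set is an independent uniform draw of its
#' observed size k_i from the shared universe of N one-to-one orthologs, so
#' a given gene lies in every set with probability p = prod(k_i / N), the
#' expected overlap is N * p, and the overlap is treated as
#' Binomial(N, p). The upper tail P(X >= observed) is computed by exact
#' summation.
#'
#' @param N universe size.
#' @param k vector of per-species set sizes.
#' @param observed observed overlap size.
#' @return `BinomialOverlapResult`: list with `N`, `k`, `p` (per-gene
#'   chance probability), `expected`, `observed`, `tail_p`.
#' @export
binomial_overlap_test <- function(N, k, observed) {
  if (any(k < 0 | k > N)) stop("set sizes must lie in [0, N]")
  if (observed < 0 || (length(k) > 0 && observed > min(k)))
    stop("observed overlap cannot exceed the smallest set")
  p <- prod(k / N)
  tail_p <- if (observed == 0) 1 else
    sum(stats::dbinom(observed:N, N, p))
  structure(list(N = N, k = k, p = p, expected = N * p,
                 observed = observed, tail_p = tail_p),
            class = "BinomialOverlapResult")
}

#' @export
print.BinomialOverlapResult <- function(x, ...) {
  cat(sprintf(
    "BinomialOverlapResult: observed %d, expected %.3g of N = %d; P(X >= obs) = %.3g\n",
    x$observed, x$expected, x$N, x$tail_p))
  invisible(x)
}

#' Chance probability that one specific gene lies in every DE set
#'
#' Under the same null as [binomial_overlap_test()], the probability that a
#' named gene is recovered in all species' sets by chance alone is
#' prod(k_i / N) — the single-gene recovery test applied to individual
#' markers recovered at a boundary in every species.
#'
#' @inheritParams binomial_overlap_test
#' @return scalar probability.
#' @export
gene_recovery_probability <- function(N, k) {
  if (any(k < 0 | k > N)) stop("set sizes must lie in [0, N]")
  prod(k / N)
}

#' Monte-Carlo null for multi-set overlap
#'
#' Empirical overlap null for cross-checking [binomial_overlap_test()].
#' With `fixed_size = FALSE` (default) each species includes each gene
#' independently with probability k_i / N — the generative form of the
#' binomial model, under which the exact tail summation must be reproduced
#' to Monte-Carlo precision. With `fixed_size = TRUE` each species' set is
#' a uniform draw of exactly k_i genes; gene-level events are then weakly
#' negatively dependent, and the binomial tail is a (slightly
#' conservative) approximation to this null rather than its exact law.
#'
#' @inheritParams binomial_overlap_test
#' @param n_draws Monte-Carlo draws.
#' @param seed RNG seed.
#' @param fixed_size draw sets at exactly size k_i rather than per-gene
#'   independently.
#' @return list with `tail_p` (empirical P(X >= observed)), `se`
#'   (Monte-Carlo standard error), and the draw `overlaps`.
#' @export
mc_overlap_null <- function(N, k, observed, n_draws = 1e5, seed = 1,
                            fixed_size = FALSE) {
  set.seed(seed)
  S <- length(k)
  overlaps <- integer(n_draws)
  for (b in seq_len(n_draws)) {
    inall <- rep(TRUE, N)
    for (i in seq_len(S)) {
      inset <- logical(N)
      if (fixed_size) inset[sample.int(N, k[i])] <- TRUE
      else inset[stats::runif(N) < k[i] / N] <- TRUE
      inall <- inall & inset
    }
    overlaps[b] <- sum(inall)
  }
  ph <- mean(overlaps >= observed)
  list(tail_p = ph, se = sqrt(ph * (1 - ph) / n_draws), overlaps = overlaps)
}

#' Log2 fold change in TPM between two digits, with pseudocount
#'
#' FC = log2((tpm_posterior + eps) / (tpm_anterior + eps)). The pseudocount
#' (default 1) bounds behaviour at zero; the measure is antisymmetric under
#' digit swap.
#'
#' @param tpm_anterior,tpm_posterior TPM vectors (same genes).
#' @param eps pseudocount.
#' @export
fold_change <- function(tpm_anterior, tpm_posterior, eps = 1) {
  log2((tpm_posterior + eps) / (tpm_anterior + eps))
}

#' Expression-matched random genes
#'
#' For each origin gene, pick the candidate whose anchor TPM (expression at
#' the anterior digit of the boundary) is closest in absolute difference —
#' the control set used to ask whether ortholog fold changes agree across
#' species more than genes of similar expression level would. Matching is
#' independent per gene (repeats allowed); a gene's own ortholog is never a
#' candidate for itself; exact ties break to the lexicographically smaller
#' candidate id.
#'
#' @param origin_anchor named numeric vector, origin gene -> anchor TPM.
#' @param pool_anchor named numeric vector over the candidate pool in the
#'   target species (names are ortholog-comparable ids).
#' @param exclude named character vector mapping each origin gene to the
#'   pool id of its own ortholog (dropped from its candidates).
#' @return named character vector, origin gene -> matched pool id.
#' @export
match_by_expression <- function(origin_anchor, pool_anchor, exclude = NULL) {
  if (length(pool_anchor) == 0) stop("empty candidate pool")
  pool_ids <- names(pool_anchor)
  ord <- order(pool_ids)  # lexicographic tie-break via stable scan order
  pool_ids <- pool_ids[ord]
  pool_anchor <- pool_anchor[ord]
  vapply(names(origin_anchor), function(g) {
    keep <- if (!is.null(exclude) && g %in% names(exclude))
      pool_ids != exclude[[g]] else rep(TRUE, length(pool_ids))
    if (!any(keep)) stop("candidate pool exhausted for gene ", g)
    d <- abs(pool_anchor[keep] - origin_anchor[[g]])
    pool_ids[keep][which.min(d)]
  }, character(1))
}

#' Matched fold-change correlation analysis across species
#'
#' For an origin species' DE gene set at a digit boundary, computes the
#' per-gene TPM fold-change vector in the origin, then in every other
#' species (and stage) the Pearson correlation of that vector against (a)
#' the orthologs' fold changes and (b) the fold changes of random genes
#' matched on anterior-digit TPM. The two collections of correlations are
#' compared with a two-sample t-test and a Mann-Whitney U test: conserved
#' behaviour shows up as ortholog correlations exceeding matched-random
#' ones.
#'
#' @param origin_species origin species name.
#' @param origin_set ortholog-group ids of the origin DE genes (>= 3).
#' @param boundary length-2 digit vector, anterior first.
#' @param tpm named list (by species) of `tpm`-state ExpressionMatrix.
#' @param map OrthologMap over the species involved.
#' @param eps pseudocount for [fold_change()].
#' @return `FoldChangeCorrelationResult`: list with the per-comparison
#'   table (`comparisons`: species, stage, r_orth, r_random) and the group
#'   statistics `t_test_p`, `mann_whitney_p`, `mean_r_orth`,
#'   `mean_r_random`.
#' @export
foldchange_correlation_analysis <- function(origin_species, origin_set,
                                            boundary, tpm, map, eps = 1) {
  stopifnot(inherits(map, "OrthologMap"))
  if (length(origin_set) < 3) stop("origin gene set must have >= 3 genes")
  uni <- one_to_one_universe(map)
  origin_set <- intersect(origin_set, uni$group_id)
  others <- setdiff(names(tpm), origin_species)
  if (length(others) < 1) stop("need >= 2 species")

  mean_tpm <- function(sp, digit, stage = NULL) {
    x <- tpm[[sp]]
    stopifnot(x$transform_state == "tpm")
    sel <- x$samples$digit == digit
    if (!is.null(stage)) sel <- sel & x$samples$stage == stage
    rowMeans(x$values[, sel, drop = FALSE])
  }
  group_vals <- function(vals, sp) {
    idx <- match(uni[[sp]], names(vals))
    stats::setNames(vals[idx], uni$group_id)
  }

  o_ant <- group_vals(mean_tpm(origin_species, boundary[1]), origin_species)
  o_pos <- group_vals(mean_tpm(origin_species, boundary[2]), origin_species)
  fc_origin <- fold_change(o_ant[origin_set], o_pos[origin_set], eps)

  rows <- list()
  for (sp in others) {
    for (st in unique(tpm[[sp]]$samples$stage)) {
      t_ant <- group_vals(mean_tpm(sp, boundary[1], st), sp)
      t_pos <- group_vals(mean_tpm(sp, boundary[2], st), sp)
      fc_orth <- fold_change(t_ant[origin_set], t_pos[origin_set], eps)
      pool <- uni$group_id
      matched <- match_by_expression(
        o_ant[origin_set],
        t_ant[pool],
        exclude = stats::setNames(origin_set, origin_set))
      fc_rand <- fold_change(t_ant[matched], t_pos[matched], eps)
      r_o <- if (stats::sd(fc_origin) > 0 && stats::sd(fc_orth) > 0)
        stats::cor(fc_origin, fc_orth) else NA_real_
      r_r <- if (stats::sd(fc_origin) > 0 && stats::sd(fc_rand) > 0)
        stats::cor(fc_origin, fc_rand) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        species = sp, stage = st, r_orth = r_o, r_random = r_r,
        stringsAsFactors = FALSE)
    }
  }
  comparisons <- do.call(rbind, rows)
  a <- comparisons$r_orth[!is.na(comparisons$r_orth)]
  b <- comparisons$r_random[!is.na(comparisons$r_random)]
  tt <- mw <- NA_real_
  if (length(a) >= 2 && length(b) >= 2 &&
      (stats::sd(c(a, b)) > 0)) {
    tt <- stats::t.test(a, b)$p.value
    mw <- stats::wilcox.test(a, b, exact = FALSE)$p.value
  }
  structure(list(origin_species = origin_species, boundary = boundary,
                 comparisons = comparisons,
                 mean_r_orth = mean(a), mean_r_random = mean(b),
                 t_test_p = tt, mann_whitney_p = mw),
            class = "FoldChangeCorrelationResult")
}

#' @export
print.FoldChangeCorrelationResult <- function(x, ...) {
  cat(sprintf(
    "FoldChangeCorrelationResult [%s, D%d vs D%d]: mean r orth %.3f vs random %.3f (MW p = %.3g)\n",
    x$origin_species, x$boundary[1], x$boundary[2], x$mean_r_orth,
    x$mean_r_random, x$mann_whitney_p))
  invisible(x)
}
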