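#' Correlation-based dissimilarity between sample expression profiles
#'
#' d(i, j) = 1 - Pearson r between the two samples' profiles over the gene
#' universe. On uncentered data d lies in [0, 1]-ish territory; after bulk
#' correction profiles can be anti-correlated and d ranges over [0, 2].
#'
#' @param x ExpressionMatrix (or plain genes x samples matrix).
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
correlation_dissimilarity <- function(x) {
  vals <- if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)
  if (ncol(vals) < 2) stop("need >= 2 samples")
  v <- apply(vals, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance sample profile(s): ",
         paste(colnames(vals)[v == 0], collapse = ", "))
  d <- 1 - stats::cor(vals)
  d[abs(d) < 1e-15] <- 0
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) clustering of samples
#'
#' Agglomerates from a dissimilarity matrix with average linkage. Samples
#' are ordered lexicographically before agglomeration so that exact-tie
#' merges are broken by member-set order and the result is invariant to the
#' input sample order.
#'
#' @param d symmetric dissimilarity matrix with dimnames.
#' @return `ClusterTree`: list with the underlying `hclust` object,
#'   `labels`, `heights`, and (initially absent) bootstrap `support`.
#' @export
average_linkage <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("dissimilarity matrix needs sample names")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  structure(list(hclust = hc, labels = hc$labels, heights = hc$height,
                 support = NULL, n_boot = 0L),
            class = "ClusterTree")
}

#' @export
print.ClusterTree <- function(x, ...) {
  cat(sprintf("ClusterTree: %d leaves, %d internal nodes%s\n",
              length(x$labels), length(x$heights),
              if (!is.null(x$support))
                sprintf(", BP from %d bootstrap replicates", x$n_boot) else ""))
  invisible(x)
}

# leaf-label set under each internal node of an hclust, as sorted signatures
.node_bipartitions <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    members <- character(0)
    for (ch in hc$merge[i, ]) {
      members <- c(members,
                   if (ch < 0) hc$labels[-ch] else
                     attr(sets[[ch]], "members"))
    }
    members <- sort(members)
    sets[[i]] <- paste(members, collapse = "\r")
    attr(sets[[i]], "members") <- members
  }
  vapply(sets, as.character, character(1))
}

#' Gene-bootstrap support for a sample dendrogram
#'
#' Resamples genes with replacement `n_boot` times, reclusters, and scores
#' each internal node of the full-data tree by the percentage of replicates
#' containing the node's exact leaf set (bootstrap proportion, BP). An
#' optional multiscale extension resamples at several gene-count scales and
#' extrapolates an approximately-unbiased (AU) support from the scale trend,
#' mirroring the "adjusted uncertainty" style of reporting.
#'
#' @param x ExpressionMatrix clustered via [correlation_dissimilarity()] and
#'   [average_linkage()].
#' @param n_boot bootstrap replicates (values below 100 trigger a warning).
#' @param seed RNG seed for reproducibility.
#' @param multiscale if TRUE, also compute AU support over a grid of
#'   resampling scales (0.5 to 1.4, 10 scales).
#' @return `ClusterTree` whose `support` (and optionally `au`) vectors are
#'   aligned with the merge order of `$hclust`.
#' @export
bootstrap_support <- function(x, n_boot = 1000, seed = 1,
                              multiscale = FALSE) {
  vals <- if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)
  if (ncol(vals) < 3) stop("need >= 3 samples for bootstrap support")
  if (n_boot < 100) warning("fewer than 100 bootstrap replicates")
  tree <- average_linkage(correlation_dissimilarity(vals))
  ref_sets <- .node_bipartitions(tree$hclust)
  G <- nrow(vals)

  count_hits <- function(scale_n, reps, rng_seed) {
    set.seed(rng_seed)
    hits <- numeric(length(ref_sets))
    for (b in seq_len(reps)) {
      idx <- sample.int(G, scale_n, replace = TRUE)
      vb <- vals[idx, , drop = FALSE]
      ok <- apply(vb, 2, stats::var) > 0
      if (!all(ok)) next
      hb <- stats::hclust(stats::as.dist(1 - stats::cor(vb)),
                          method = "average")
      hb$labels <- colnames(vb)
      hits <- hits + (ref_sets %in% .node_bipartitions(hb))
    }
    hits / reps
  }

  tree$support <- 100 * count_hits(G, n_boot, seed)
  tree$n_boot <- as.integer(n_boot)
  if (multiscale) {
    scales <- seq(0.5, 1.4, length.out = 10)
    bp <- sapply(seq_along(scales), function(k)
      count_hits(max(2, round(G * scales[k])), n_boot, seed + k))
    tree$au <- 100 * vapply(seq_along(ref_sets), function(i) {
      z <- stats::qnorm(pmin(pmax(bp[i, ], 1 / (n_boot + 1)),
                             n_boot / (n_boot + 1)))
      r <- sqrt(scales)
      fit <- stats::lm(z ~ r + I(1 / r))  # z(r) = d*r + c/r
      cf <- stats::coef(fit)
      stats::pnorm(cf[["r"]] - cf[["I(1/r)"]])
    }, numeric(1))
  }
  tree
}

#' Bootstrap support of the non-trivial internal nodes
#'
#' The root's leaf set (all samples) is contained in every bootstrap
#' replicate, so its BP is 100 by construction; assessments of clustering
#' strength consider the remaining internal nodes.
#'
#' @param tree ClusterTree with computed support.
#' @return support vector excluding the root node.
#' @export
nontrivial_support <- function(tree) {
  stopifnot(inherits(tree, "ClusterTree"), !is.null(tree$support))
  tree$support[-length(tree$support)]
}

#' Leaf set under each internal node
#' @param tree ClusterTree.
#' @return list of character vectors, one per internal node in merge order.
#' @export
node_leaf_sets <- function(tree) {
  stopifnot(inherits(tree, "ClusterTree"))
  sigs <- .node_bipartitions(tree$hclust)
  lapply(strsplit(sigs, "\r", fixed = TRUE), identity)
}

#' Is a sample group monophyletic in the dendrogram?
#'
#' @param tree ClusterTree.
#' @param members character vector of leaf labels.
#' @return list with `monophyletic` flag and, when present, the `support`
#'   of the exact node spanning the group.
#' @export
group_support <- function(tree, members) {
  sets <- node_leaf_sets(tree)
  target <- sort(members)
  hit <- which(vapply(sets, function(s) identical(s, target), logical(1)))
  list(monophyletic = length(hit) == 1,
       support = if (length(hit) == 1 && !is.null(tree$support))
         tree$support[hit] else NA_real_)
}

# hclust -> ape phylo with node depth equal to the merge height
# (leaves at depth 0; edge length = parent height - child height)
.tree_to_phylo <- function(tree) {
  hc <- tree$hclust
  n <- length(hc$labels)
  node_id <- function(i) n + (n - i)  # merge n-1 (root) -> n+1
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (ch in hc$merge[i, ]) {
      if (ch < 0) {
        edges <- rbind(edges, c(node_id(i), -ch))
        lens <- c(lens, hc$height[i])
      } else {
        edges <- rbind(edges, c(node_id(i), node_id(ch)))
        lens <- c(lens, hc$height[i] - hc$height[ch])
      }
    }
  }
  node_label <- rep("", n - 1)
  if (!is.null(tree$support))
    node_label[n - seq_len(n - 1)] <- formatC(tree$support, format = "g")
  ph <- list(edge = edges, edge.length = lens, tip.label = hc$labels,
             Nnode = n - 1L, node.label = node_label)
  class(ph) <- "phylo"
  stats::reorder(ph)
}

#' Write a ClusterTree as Newick with internal-node support labels
#'
#' Branch lengths are merge-height differences (leaves sit at depth 0,
#' every internal node at its merge height); internal-node labels carry the
#' bootstrap support when present. Re-reading reproduces the topology and
#' labels.
#'
#' @param tree ClusterTree.
#' @param path output file.
#' @export
write_tree_newick <- function(tree, path) {
  stopifnot(inherits(tree, "ClusterTree"))
  if (!is.null(tree$support) &&
      any(tree$support < 0 | tree$support > 100))
    stop("support values must lie in [0, 100]")
  ape::write.tree(.tree_to_phylo(tree), file = path)
  invisible(tree)
}

#' Read a Newick tree (with optional internal-node labels)
#' @param path Newick file.
#' @return an `ape` phylo object.
#' @export
read_tree_newick <- function(path) ape::read.tree(path)
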