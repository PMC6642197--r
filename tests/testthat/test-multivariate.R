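test_that("correlation dissimilarity matches hand Pearson oracles", {
  v <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1),
             d = c(1, 2, 4))
  rownames(v) <- paste0("g", 1:3)
  d <- correlation_dissimilarity(v)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2)  # perfectly anti-correlated
  expect_equal(d["a", "d"], 1 - cor(c(1, 2, 3), c(1, 2, 4)))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))

  v_bad <- cbind(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_error(correlation_dissimilarity(v_bad), "a")
})

test_that("average linkage reproduces the hand agglomeration oracle", {
  d <- matrix(c(0, 1, 4, 1, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- average_linkage(d)
  expect_equal(tr$heights, c(1, 4.5))  # join (A,B) at 1, then C at (4+5)/2
  expect_equal(length(tr$heights), 3 - 1)  # n - 1 internal nodes

  # duplicated samples join first, at height 0
  d2 <- correlation_dissimilarity(cbind(a = c(1, 2, 5), b = c(1, 2, 5),
                                        c = c(9, 1, 3)))
  tr2 <- average_linkage(d2)
  expect_equal(tr2$heights[1], 0)
  expect_setequal(node_leaf_sets(tr2)[[1]], c("a", "b"))
})

test_that("linkage heights and bipartitions ignore input sample order", {
  set.seed(61)
  v <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  t1 <- average_linkage(correlation_dissimilarity(v))
  perm <- sample(6)
  t2 <- average_linkage(correlation_dissimilarity(v[, perm]))
  expect_equal(t1$heights, t2$heights, tolerance = 1e-12)
  expect_setequal(vapply(node_leaf_sets(t1), paste, character(1),
                         collapse = "|"),
                  vapply(node_leaf_sets(t2), paste, character(1),
                         collapse = "|"))
})

test_that("bootstrap support is seed-stable and separates signal from noise", {
  # two groups of samples split by 10 within-group sds on half the genes
  set.seed(62)
  base <- matrix(rnorm(200 * 6), 200, 6)
  base[1:100, 4:6] <- base[1:100, 4:6] + 10
  colnames(base) <- paste0("s", 1:6)
  rownames(base) <- paste0("g", 1:200)
  tr <- bootstrap_support(base, n_boot = 200, seed = 3)
  gs <- group_support(tr, c("s4", "s5", "s6"))
  expect_true(gs$monophyletic)
  expect_gte(gs$support, 99)

  tr_again <- bootstrap_support(base, n_boot = 200, seed = 3)
  expect_identical(tr$support, tr_again$support)

  # structureless data: median non-trivial support stays low
  meds <- vapply(1:10, function(s) {
    set.seed(600 + s)
    v <- matrix(rnorm(150 * 8), 150, 8,
                dimnames = list(NULL, paste0("s", 1:8)))
    median(nontrivial_support(bootstrap_support(v, n_boot = 150, seed = 1)))
  }, numeric(1))
  expect_lt(median(meds), 70)
})

test_that("PCA satisfies its algebraic contracts", {
  sim <- null_sim(n_genes = 60, n_digits = 3, seed = 19)
  expr <- sqrt_transform(tpm_normalize(sim$counts$sp, sim$lengths))
  m <- fit_pca(expr)
  # orthonormal loadings
  k <- ncol(m$loadings)
  expect_equal(unname(crossprod(m$loadings)), diag(k), tolerance = 1e-8)
  # scores = centered data x loadings; full reconstruction to 1e-8
  centered <- sweep(t(expr$values), 2, m$center)
  expect_equal(unname(m$scores), unname(centered %*% m$loadings),
               tolerance = 1e-8)
  expect_equal(unname(centered),
               unname(m$scores %*% t(m$loadings)), tolerance = 1e-8)
  expect_lte(sum(m$explained), 1 + 1e-12)

  # projecting training samples reproduces their scores; the gene-mean
  # profile projects to the origin
  proj <- project_supplementary(m, expr)
  expect_equal(proj, m$scores, tolerance = 1e-8)
  xm <- expr
  xm$values <- matrix(m$center, ncol = 1,
                      dimnames = list(names(m$center), "meanprof"))
  xm$samples <- data.frame(sample_id = "meanprof")
  expect_equal(max(abs(project_supplementary(m, xm))), 0, tolerance = 1e-8)
})

test_that("a y = x point cloud has PC1 along (1,1)/sqrt(2)", {
  set.seed(77)
  t_par <- rnorm(30)
  vals <- rbind(gx = t_par, gy = t_par + rnorm(30, sd = 0.01))
  colnames(vals) <- paste0("s", 1:30)
  meta <- data.frame(sample_id = colnames(vals))
  m <- fit_pca(expression_matrix(abs(vals), meta, "tpm"))
  expect_equal(unname(m$loadings[, 1]), rep(1 / sqrt(2), 2),
               tolerance = 0.05)
})

test_that("supplementary projection follows the hand matrix product", {
  model <- structure(list(
    center = c(g1 = 1, g2 = 1),
    loadings = matrix(c(1, 0), 2, 1, dimnames = list(c("g1", "g2"), "PC1")),
    scores = matrix(0, 1, 1, dimnames = list("train", "PC1")),
    explained = 1, transform_state = "sqrt_tpm",
    samples = data.frame(sample_id = "train", digit = 1)),
    class = "PCAModel")
  held <- expression_matrix(
    matrix(c(3, 1), 2, 1, dimnames = list(c("g1", "g2"), "new")),
    data.frame(sample_id = "new"), "sqrt_tpm")
  expect_equal(unname(drop(project_supplementary(model, held))), 2)

  bad <- expression_matrix(matrix(1, 1, 1, dimnames = list("gX", "new")),
                           data.frame(sample_id = "new"), "sqrt_tpm")
  expect_error(project_supplementary(model, bad), "g1")
})

test_that("PCA bootstrap is seed-stable and tightens with sample size", {
  make_groups <- function(n_per, seed) {
    set.seed(seed)
    v <- cbind(matrix(rnorm(80 * n_per), 80),
               matrix(rnorm(80 * n_per, mean = 4), 80))
    colnames(v) <- paste0("s", seq_len(2 * n_per))
    expression_matrix(abs(v), data.frame(sample_id = colnames(v)), "tpm")
  }
  x <- make_groups(3, 81)
  b1 <- bootstrap_pca(x, n_boot = 120, seed = 5)
  b2 <- bootstrap_pca(x, n_boot = 120, seed = 5)
  expect_identical(b1$score_sd, b2$score_sd)

  # separated groups: bootstrap score clouds do not overlap on PC1
  g1 <- 1:3; g2 <- 4:6
  if (mean(b1$score_mean[g1, 1]) > mean(b1$score_mean[g2, 1])) {
    tmp <- g1; g1 <- g2; g2 <- tmp
  }
  # much of the bootstrap spread is a common-mode center shift, so the
  # marginal clouds separate at 1 sd even for widely separated groups
  expect_lt(max(b1$score_mean[g1, 1] + b1$score_sd[g1, 1]),
            min(b1$score_mean[g2, 1] - b1$score_sd[g2, 1]))

  sds <- vapply(1:5, function(s) {
    small <- bootstrap_pca(make_groups(3, 90 + s), n_boot = 100, seed = s)
    large <- bootstrap_pca(make_groups(10, 90 + s), n_boot = 100, seed = s)
    c(mean(small$score_sd[, 1]), mean(large$score_sd[, 1]))
  }, numeric(2))
  expect_lt(mean(sds[2, ]), mean(sds[1, ]))
})

test_that("correspondence calls use nearest centroids with a tie rule", {
  model <- structure(list(
    scores = matrix(c(0, 0, 4, 4, 0, 0, 0, 0), 4, 2,
                    dimnames = list(paste0("r", 1:4), c("PC1", "PC2"))),
    samples = data.frame(sample_id = paste0("r", 1:4),
                         digit = c(1, 1, 2, 2)),
    center = NULL, loadings = NULL, explained = NULL),
    class = "PCAModel")
  sc <- matrix(c(0, 2, 4, 0, 0, 0), 3, 2,
               dimnames = list(c("p1", "p2", "p3"), NULL))
  cc <- call_correspondence(model, sc)
  expect_equal(cc$assigned_digit, c(1L, 1L, 2L))  # tie at 2 -> lower digit
  expect_equal(cc$distance, c(0, 2, 0))
  expect_equal(cc$margin[2], 0)  # flagged exact tie
  expect_equal(cc$margin[1], 4)
})
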