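fake_de <- function(gene_ids, p_bh, l2fc = rep(1, length(gene_ids))) {
  out <- data.frame(gene_id = gene_ids, log2_fc = l2fc, lr = 1, df = 1,
                    p_value = p_bh, p_bh = p_bh, q_storey = p_bh,
                    stringsAsFactors = FALSE)
  class(out) <- c("DEResult", "data.frame")
  out
}

toy_map <- function() {
  ortholog_map(data.frame(
    group_id = c("og1", "og2", "og3", "og4"),
    mm = c("mm1", "mm2", "mm3", "mm4"),
    al = c("al1", "al2", "al3", NA),
    stringsAsFactors = FALSE))
}

test_that("DE sets restrict to the one-to-one universe and threshold", {
  map <- toy_map()
  de <- list(mm = fake_de(c("mm1", "mm2", "mm4", "mmX"),
                          c(0.01, 0.2, 0.01, 0.001)),
             al = fake_de(c("al1", "al2", "al3"), c(0.04, 0.01, 0.9)))
  sets <- de_sets_by_boundary(de, map, fdr = 0.05)
  expect_equal(sets$N, 3)  # og4 is not one-to-one
  expect_setequal(sets$sets$mm, "og1")  # og4 and mmX never appear
  expect_setequal(sets$sets$al, c("og1", "og2"))

  zero <- de_sets_by_boundary(de, map, fdr = 0)
  expect_equal(lengths(zero$sets), c(mm = 0L, al = 0L))

  expect_error(de_sets_by_boundary(c(de, list(zz = de$mm)), map), "zz")
})

test_that("conserved intersections follow set algebra and direction flags", {
  sets <- list(a = c("a", "b", "c"), b = c("a", "b"), c = c("b", "c"))
  expect_setequal(intersect_conserved(sets)$intersection, "b")
  expect_equal(length(intersect_conserved(
    list(a = character(0), b = c("x")))$intersection), 0)
  same <- list(a = c("x", "y"), b = c("x", "y"))
  expect_setequal(intersect_conserved(same)$intersection, c("x", "y"))

  dir <- list(a = c(x = 1, y = 1), b = c(x = 1, y = -1))
  res <- intersect_conserved(same, direction = dir, N = 10, boundary = "D1_vs_D2")
  expect_setequal(res$intersection, c("x", "y"))
  expect_setequal(res$direction_consistent, "x")
  expect_equal(res$expected, 10 * (2 / 10) * (2 / 10))
})

test_that("binomial overlap matches an explicit choose() summation", {
  b <- binomial_overlap_test(10, c(5, 5, 5), 4)
  expect_equal(b$p, 0.125)
  expect_equal(b$expected, 1.25)
  tail_oracle <- sum(vapply(4:10, function(x)
    choose(10, x) * 0.125^x * 0.875^(10 - x), numeric(1)))
  expect_equal(b$tail_p, tail_oracle, tolerance = 1e-12)

  z <- binomial_overlap_test(10, c(0, 5), 0)
  expect_equal(z$expected, 0)
  expect_equal(z$tail_p, 1)

  expect_error(binomial_overlap_test(10, c(2, 5), 3), "smallest set")
  expect_error(binomial_overlap_test(10, c(11, 5), 3), "\\[0, N\\]")
})

test_that("binomial overlap tail is monotone in X and in each k", {
  base <- binomial_overlap_test(50, c(20, 15, 10), 5)$tail_p
  expect_lte(binomial_overlap_test(50, c(20, 15, 10), 6)$tail_p, base)
  expect_gte(binomial_overlap_test(50, c(25, 15, 10), 5)$tail_p, base)
  expect_gte(binomial_overlap_test(50, c(20, 20, 10), 5)$tail_p, base)
})

test_that("fixed-size set draws make the binomial tail conservative", {
  # within a fixed-size set, gene inclusions are negatively dependent, so
  # the overlap variance falls below Binomial(N, p) and the upper tail of
  # the binomial model overshoots the realistic fixed-size null
  ex <- binomial_overlap_test(40, c(12, 12, 12), 3)$tail_p
  mc_fix <- mc_overlap_null(40, c(12, 12, 12), 3, n_draws = 4e4, seed = 2,
                            fixed_size = TRUE)
  mc_ind <- mc_overlap_null(40, c(12, 12, 12), 3, n_draws = 4e4, seed = 2,
                            fixed_size = FALSE)
  expect_gt(ex, mc_fix$tail_p + 3 * mc_fix$se)
  expect_lt(abs(ex - mc_ind$tail_p), 3 * mc_ind$se)
})

test_that("single-gene recovery probability is the size product", {
  expect_equal(gene_recovery_probability(10, c(10, 10)), 1)
  expect_equal(gene_recovery_probability(10, c(0, 5)), 0)
  expect_equal(gene_recovery_probability(100, c(10, 10, 10)), 1e-3)
})

test_that("fold change is antisymmetric and pseudocount-bounded", {
  expect_equal(fold_change(5, 5), 0)
  expect_equal(fold_change(100, 400), 2, tolerance = 0.02)
  set.seed(3)
  a <- runif(20, 0, 100); b <- runif(20, 0, 100)
  expect_equal(fold_change(a, b), -fold_change(b, a))
  expect_equal(fold_change(0, 0), 0)  # eps keeps zeros finite
})

test_that("expression matching picks nearest anchors with declared rules", {
  got <- match_by_expression(c(gX = 10), c(og_a = 9, og_b = 30))
  expect_equal(unname(got), "og_a")
  # exact tie: lexicographically smaller id
  tie <- match_by_expression(c(gX = 10), c(og_b = 12, og_a = 8))
  expect_equal(unname(tie), "og_a")
  # own ortholog excluded even when it is the best match
  own <- match_by_expression(c(og_a = 9), c(og_a = 9, og_b = 30),
                             exclude = c(og_a = "og_a"))
  expect_equal(unname(own), "og_b")
  expect_error(match_by_expression(c(g = 1), setNames(numeric(0),
                                                      character(0))),
               "empty")
})

test_that("identical ortholog fold-change vectors correlate perfectly", {
  groups <- sprintf("og%02d", 1:12)
  vals_for <- function(sp, shift) {
    g <- paste0(sp, "_", groups)
    v <- cbind(d1 = seq(10, 120, by = 10),
               d2 = seq(10, 120, by = 10) * shift)
    rownames(v) <- g
    colnames(v) <- c(paste0(sp, "_d1"), paste0(sp, "_d2"))
    expression_matrix(v, data.frame(sample_id = colnames(v), species = sp,
                                    limb = "fore", digit = 1:2,
                                    stage = "st1", replicate = 1), "tpm")
  }
  shifts <- c(4, 3, 2, 0.5, 0.25, 0.2, rep(1, 6))  # varied origin FCs
  tpms <- list(A = vals_for("A", shift = shifts),
               B = vals_for("B", shift = shifts))
  map <- ortholog_map(data.frame(group_id = groups,
                                 A = paste0("A_", groups),
                                 B = paste0("B_", groups)))
  res <- foldchange_correlation_analysis("A", groups[1:6], c(1, 2), tpms,
                                         map)
  expect_equal(res$comparisons$r_orth, 1, tolerance = 1e-6)
  expect_error(foldchange_correlation_analysis("A", groups[1:2], c(1, 2),
                                               tpms, map), ">= 3")
})
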