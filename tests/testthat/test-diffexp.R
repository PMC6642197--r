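test_that("identical groups give LR = 0, p = 1", {
  cnt <- matrix(rep(c(10L, 20L, 15L), each = 2), nrow = 1)
  cnt <- rbind(cnt, cnt + 5L)  # two genes, both equal across the two digits
  colnames(cnt) <- paste0("s", 1:6)
  rownames(cnt) <- c("gA", "gB")
  cnt <- cnt[, c(1, 3, 5, 2, 4, 6)]  # digits 1,1,1,2,2,2 see equal counts
  x <- tiny_counts(cnt, digits = rep(1:2, each = 3))
  phi <- 0.1
  disp <- structure(list(common = phi,
                         tagwise = setNames(rep(phi, 2), rownames(cnt)),
                         prior_weight = 10, grid = phi),
                    class = "DispersionEstimates")
  de <- lrt_pairwise(x, c(1, 2), dispersions = disp,
                     offsets = setNames(rep(0, 6), colnames(cnt)))
  expect_equal(de$lr, c(0, 0), tolerance = 1e-6)
  expect_equal(de$p_value, c(1, 1), tolerance = 1e-6)
})

test_that("the any-digit LRT uses multiple df and detects a shifted digit", {
  sim <- simulate_counts(sim_config(
    n_genes = 120, ortholog_fraction = 1,
    species = list(species_spec("sp", n_digits = 4)),
    modules = list(module_spec("m3", 3, 12, log2fc = 2)), seed = 31))
  de <- lrt_any_digit(sim$counts$sp, lengths = sim$lengths)
  expect_equal(unique(de$df), 3)
  mod <- paste0("sp_", sim$gene_lists$m3$members)
  hits <- de_genes(de, fdr = 0.05)
  expect_gte(mean(mod %in% hits), 0.9)
  # an all-equal-means gene yields a large p far more often than the module
  expect_gt(median(de$p_value[!de$gene_id %in% mod]),
            median(de$p_value[de$gene_id %in% mod]))
})

test_that("two digit levels defer the any-digit test to pairwise", {
  sim <- null_sim(n_genes = 30, seed = 8)
  expect_message(de <- lrt_any_digit(sim$counts$sp), "pairwise")
  expect_equal(unique(de$df), 1)
})

test_that("BH adjustment matches the hand step-up oracle and handles NA", {
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  set.seed(5)
  for (r in 1:5) {
    p <- runif(sample(5:50, 1))
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
  # NA excluded from m: remaining entries adjusted as a length-2 vector
  out <- adjust_bh(c(0.01, NA, 0.04))
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], bh_oracle(c(0.01, 0.04)))
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")
})

test_that("Storey q-values estimate pi0 and never undercut their own bound", {
  # uniform p: pi0 ~ 1, q ~ BH
  set.seed(17)
  p <- runif(2000)
  sq <- storey_q(p)
  expect_gt(sq$pi0, 0.9)
  expect_true(all(sq$q <= adjust_bh(p) + 1e-12))
  expect_equal(sq$q, sq$pi0 * adjust_bh(p), tolerance = 1e-12)

  # mixture with true pi0 = 0.8, m = 5000
  p_mix <- c(runif(4000), rbeta(1000, 0.2, 4))
  expect_equal(storey_q(p_mix)$pi0, 0.8, tolerance = 0.05)

  # Storey calls at least as many genes as BH when pi0 < 1
  calls_storey <- sum(storey_q(p_mix)$q < 0.05)
  calls_bh <- sum(adjust_bh(p_mix) < 0.05)
  expect_gte(calls_storey, calls_bh)

  expect_warning(small <- storey_q(runif(50)), "fewer than 100")
  expect_equal(small$pi0, 1)
})

test_that("a pure-noise covariate barely perturbs null calibration", {
  sim <- null_sim(n_genes = 500, seed = 23)
  x <- sim$counts$sp
  de0 <- lrt_pairwise(x, c(1, 2))
  set.seed(24)
  noise <- data.frame(z = rnorm(ncol(x$counts)))
  de1 <- lrt_pairwise(x, c(1, 2), covariates = noise)
  ks0 <- pvalue_uniformity(de0$p_value)$ks
  ks1 <- pvalue_uniformity(de1$p_value)$ks
  expect_lt(abs(ks1 - ks0), 0.02)
})

test_that("stage factors enter the model additively", {
  sim <- simulate_counts(sim_config(
    n_genes = 40, ortholog_fraction = 1,
    species = list(species_spec("sp", n_digits = 2, n_stages = 2)),
    seed = 41))
  x <- sim$counts$sp
  d <- de_design(x$samples)
  expect_true(any(grepl("stage", colnames(d$full))))
  expect_equal(d$df, 1)  # stage sits in both models
  de <- lrt_pairwise(x, c(1, 2), lengths = sim$lengths)
  expect_true(all(de$p_value >= 0 & de$p_value <= 1, na.rm = TRUE))
})

test_that("conserved-set discovery is stable under best-two-replicate reruns", {
  # planted module: same planted members recovered with 3 or with the 2
  # most-correlated replicates per digit, in >= 9 of 10 seeds
  stable <- 0
  for (s in 1:10) {
    sim <- simulate_counts(sim_config(
      n_genes = 200, ortholog_fraction = 1,
      species = list(species_spec("spA", n_digits = 2),
                     species_spec("spB", n_digits = 2)),
      modules = list(module_spec("m", 1, 15, log2fc = 2)),
      seed = 500 + s))
    run_sets <- function(counts_list) {
      de <- lapply(counts_list, lrt_pairwise, digits = c(1, 2),
                   lengths = sim$lengths)
      de_sets_by_boundary(de, sim$ortholog_map, fdr = 0.05)$sets
    }
    full <- Reduce(intersect, run_sets(sim$counts))
    best2 <- Reduce(intersect, run_sets(
      lapply(sim$counts, best_two_replicates, lengths = sim$lengths)))
    planted <- sim$gene_lists$m$members
    stable <- stable + identical(sort(intersect(full, planted)),
                                 sort(intersect(best2, planted)))
  }
  expect_gte(stable, 9)
})
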