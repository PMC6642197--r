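test_that("the generator is seed-deterministic and truth-complete", {
  cfg <- sim_config(n_genes = 80, ortholog_fraction = 0.8,
                    species = list(species_spec("a", n_digits = 3),
                                   species_spec("b", n_digits = 3)),
                    modules = list(module_spec("m1", 1, 10)), seed = 9)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$truth$genes), 2 * 80)
  expect_true(all(!is.na(s1$truth$genes$phi)))
  expect_equal(sum(!is.na(s1$truth$module_of)), 10)
  # module genes live in the one-to-one universe
  uni <- one_to_one_universe(s1$ortholog_map)$group_id
  expect_true(all(s1$gene_lists$m1$members %in% uni))
})

test_that("a YAML configuration reproduces the in-code one", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("n_genes: 50", "ortholog_fraction: 1.0", "seed: 4",
               "species:",
               "  - name: a", "    n_digits: 3",
               "  - name: b", "    n_digits: 3",
               "modules:",
               "  - name: m1", "    digit: 1", "    size: 5",
               "    log2fc: 1.5"), f)
  cfg_yaml <- read_sim_config(f)
  cfg_code <- sim_config(n_genes = 50, ortholog_fraction = 1,
                         species = list(species_spec("a", n_digits = 3),
                                        species_spec("b", n_digits = 3)),
                         modules = list(module_spec("m1", 1, 5, 1.5)),
                         seed = 4)
  expect_identical(simulate_counts(cfg_yaml), simulate_counts(cfg_code))
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(species = list()), "species")
  expect_error(species_spec("a", n_reps = 0), "n_reps")
  expect_error(sim_config(n_genes = 5,
                          modules = list(module_spec("m", 1, 10))),
               "exceed")
})

test_that("simulated counts obey the NB mean-variance law", {
  # fixed phi = 0.2, mu = 100: Var = 100 + 0.2 * 100^2 = 2100
  cfg <- sim_config(n_genes = 1000, ortholog_fraction = 1,
                    species = list(species_spec("sp", n_digits = 2,
                                                n_reps = 50)),
                    baseline_sdlog = 0, cross_species_sdlog = 0,
                    library_meanlog = log(100 * 1000), library_sdlog = 0,
                    regime_mean_phi = c(sibling = 0.2, population = 0.15),
                    phi_sdlog = 0, seed = 21)
  sim <- simulate_counts(cfg)
  draws <- as.numeric(sim$counts$sp$counts)  # 1e5 iid NB(mu=100, phi=0.2)
  expect_equal(mean(draws), 100, tolerance = 0.02)
  expect_equal(var(draws), 2100, tolerance = 0.05)

  # Poisson limit: phi -> 0 gives variance ~ mean over 1e4+ draws
  cfg0 <- sim_config(n_genes = 200, ortholog_fraction = 1,
                     species = list(species_spec("sp", n_digits = 2,
                                                 n_reps = 25)),
                     baseline_sdlog = 0, cross_species_sdlog = 0,
                     library_meanlog = log(100 * 200), library_sdlog = 0,
                     regime_mean_phi = c(sibling = 0, population = 0.15),
                     phi_sdlog = 0, seed = 22)
  d0 <- as.numeric(simulate_counts(cfg0)$counts$sp$counts)
  expect_equal(var(d0) / mean(d0), 1, tolerance = 0.05)
})

test_that("recovery scoring matches hand counts", {
  cfg <- sim_config(n_genes = 10, ortholog_fraction = 1,
                    species = list(species_spec("sp", n_digits = 2)),
                    modules = list(module_spec("m", 1, 2)), seed = 2)
  sim <- simulate_counts(cfg)
  module <- sim$gene_lists$m$members
  expect_equal(score_recovery(sim$truth, module, "m"),
               list(sensitivity = 1, fdp = 0))
  expect_equal(score_recovery(sim$truth, character(0), "m"),
               list(sensitivity = 0, fdp = 0))
  other <- setdiff(sim$gene_lists$tf$members, module)[1]
  sc <- score_recovery(sim$truth, c(module[1], other), "m")
  expect_equal(sc$sensitivity, 0.5)
  expect_equal(sc$fdp, 0.5)
  expect_error(score_recovery(sim$truth, module, "nope"), "unknown module")
})

test_that("larger planted effects never lower detection power", {
  # 10 seeds, two effect sizes; power = mean raw p < 0.05 on module genes
  power_at <- function(fc, seed) {
    sim <- simulate_counts(sim_config(
      n_genes = 150, ortholog_fraction = 1,
      species = list(species_spec("sp", n_digits = 2)),
      modules = list(module_spec("m", 1, 15, log2fc = fc)), seed = seed))
    de <- lrt_pairwise(sim$counts$sp, c(1, 2))
    mod_genes <- paste0("sp_", sim$gene_lists$m$members)
    mean(de$p_value[de$gene_id %in% mod_genes] < 0.05, na.rm = TRUE)
  }
  p_small <- mean(vapply(1:10, function(s) power_at(0.5, 100 + s),
                         numeric(1)))
  p_large <- mean(vapply(1:10, function(s) power_at(2, 100 + s),
                         numeric(1)))
  expect_gte(p_large, p_small)
  expect_gt(p_large, 0.9)
})

test_that("population-regime simulations show higher tagwise dispersion", {
  wins <- 0
  for (s in 1:10) {
    est <- lapply(c(sibling = "sibling", population = "population"),
                  function(r) {
      sim <- null_sim(n_genes = 80, seed = 300 + s, regime = r)
      x <- sim$counts$sp
      estimate_dispersions(x, de_design(x$samples)$full)
    })
    sumtab <- dispersion_summary(est)
    wins <- wins + (sumtab$dataset[1] == "population")
  }
  expect_equal(wins, 10)
})
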