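# small fixture builders shared across test files

# minimal valid CountMatrix with explicit values
tiny_counts <- function(counts = matrix(1:4, 2, 2,
                                        dimnames = list(c("g1", "g2"),
                                                        c("s1", "s2"))),
                        digits = c(1, 2)) {
  count_matrix(counts,
               data.frame(sample_id = colnames(counts), species = "sp",
                          limb = "fore", digit = digits, stage = "st1",
                          replicate = 1, stringsAsFactors = FALSE))
}

# one-species null simulation (no planted modules)
null_sim <- function(n_genes = 300, n_digits = 2, n_reps = 3, seed = 1,
                     regime = "sibling") {
  simulate_counts(sim_config(
    n_genes = n_genes, ortholog_fraction = 1,
    species = list(species_spec("sp", n_digits = n_digits, n_reps = n_reps,
                                regime = regime)),
    seed = seed))
}

# three sibling species with a conserved 30-gene D1 module (|log2FC| = 2)
conserved_sim <- function(n_genes = 1000, module_size = 30, log2fc = 2,
                          seed = 1) {
  simulate_counts(sim_config(
    n_genes = n_genes, ortholog_fraction = 1,
    species = list(species_spec("spA"), species_spec("spB"),
                   species_spec("spC")),
    modules = list(module_spec("conserved_D1", digit = 1,
                               size = module_size, log2fc = log2fc)),
    seed = seed))
}

# independent brute-force NB likelihood maximizer for a two-group design:
# nested grid search over (baseline, group effect), refined 4 times.
# Uses only dnbinom, never the package's IRLS path.
brute_force_two_group <- function(y, group, offset, phi,
                                  rounds = 4, width0 = c(4, 6), n_pts = 61) {
  ll <- function(b0, b1) {
    mu <- exp(offset + b0 + b1 * group)
    sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  }
  c0 <- log(mean(y)) - mean(offset)
  c1 <- 0
  w <- width0
  best <- c(c0, c1, -Inf)
  for (r in seq_len(rounds)) {
    b0s <- seq(best[1] - w[1] / 2, best[1] + w[1] / 2, length.out = n_pts)
    b1s <- seq(best[2] - w[2] / 2, best[2] + w[2] / 2, length.out = n_pts)
    vals <- outer(b0s, b1s, Vectorize(ll))
    k <- arrayInd(which.max(vals), dim(vals))
    best <- c(b0s[k[1]], b1s[k[2]], max(vals))
    w <- w * 2.5 / (n_pts - 1)  # keep a neighborhood around the best cell
  }
  list(coefficients = best[1:2], loglik = best[3])
}

brute_force_intercept <- function(y, offset, phi, rounds = 4, width0 = 4,
                                  n_pts = 201) {
  ll <- function(b0) {
    mu <- exp(offset + b0)
    sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  }
  best <- c(log(mean(y)) - mean(offset), -Inf)
  w <- width0
  for (r in seq_len(rounds)) {
    b0s <- seq(best[1] - w / 2, best[1] + w / 2, length.out = n_pts)
    vals <- vapply(b0s, ll, numeric(1))
    best <- c(b0s[which.max(vals)], max(vals))
    w <- w * 2.5 / (n_pts - 1)
  }
  list(coefficients = best[1], loglik = best[2])
}

# hand step-up BH oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m > 1)
    for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
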