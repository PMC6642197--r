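#' Species specification for the count simulator
#'
#' Describes one simulated species/limb: digit count, replicates per digit
#' (per stage), dispersion regime, and which planted identity program each
#' digit position executes. The dispersion regimes mirror specimen
#' pedigree: "sibling" collections (low gene-wise dispersion) versus
#' "population" collections from nonsiblings (high dispersion, hence lower
#' DE sensitivity).
#'
#' @param name species label.
#' @param n_digits digits per limb (anterior = position 1).
#' @param n_reps replicates per digit per stage.
#' @param regime "sibling" or "population".
#' @param n_stages developmental stages sampled (expression profiles are
#'   stable across stages; stages differ only in library sizes).
#' @param identity_map integer vector over positions giving the identity
#'   whose planted modules each position executes; NA = no program. Default
#'   `1:n_digits` (position = identity).
#' @param frameshift convenience flag: a 4-digit limb whose position 2
#'   carries identity 1's program and positions 3, 4 their own
#'   (`identity_map = c(2, 1, 3, 4)`), the recoverable analogue of a wing
#'   whose anterior digit runs the D1 program.
#' @param homogeneous convenience flag: no digit executes any planted
#'   program (all-NA identity map).
#' @export
species_spec <- function(name, n_digits = 5, n_reps = 3,
                         regime = c("sibling", "population"), n_stages = 1,
                         identity_map = NULL, frameshift = FALSE,
                         homogeneous = FALSE) {
  regime <- match.arg(regime)
  if (frameshift) {
    n_digits <- 4
    if (is.null(identity_map)) identity_map <- c(2L, 1L, 3L, 4L)
  }
  if (homogeneous) identity_map <- rep(NA_integer_, n_digits)
  if (is.null(identity_map)) identity_map <- seq_len(n_digits)
  stopifnot(length(identity_map) == n_digits, n_reps >= 1, n_digits >= 2)
  list(name = name, n_digits = as.integer(n_digits),
       n_reps = as.integer(n_reps), regime = regime,
       n_stages = as.integer(n_stages),
       identity_map = as.integer(identity_map))
}

#' Planted expression-module specification
#'
#' A set of genes multiplicatively up- (or down-) regulated, by
#' `2^log2fc`, in every digit position whose identity map points at
#' `digit`. Module genes are disjoint across modules and are flagged as
#' transcription factors in the simulated gene lists.
#'
#' @param name module label.
#' @param digit the identity (1-based anterior ordinal) the module marks.
#' @param size number of member genes.
#' @param log2fc planted log2 effect size.
#' @param species "all", or a character vector of species names the module
#'   is active in (species-specific digit modules).
#' @export
module_spec <- function(name, digit, size, log2fc = 2, species = "all") {
  stopifnot(size >= 1, is.finite(log2fc))
  list(name = name, digit = as.integer(digit), size = as.integer(size),
       log2fc = log2fc, species = species)
}

#' Simulation configuration
#'
#' Defines the study conditions a simulated dataset emulates: several
#' species/limbs of 4-5 digits with 2-4 replicates each, NB-distributed
#' counts with gene-wise dispersion drawn log-normally around a regime mean
#' (sibling 0.02, population 0.15), a shared log-normal baseline expression
#' programme with one-to-one ortholog structure (cross-species log-normal
#' baseline noise, sdlog 0.25), log-uniform transcript lengths
#' (500-5000 bp), and planted digit-identity modules.
#'
#' @param n_genes ortholog groups simulated (the universe is the
#'   transcription-factor set the analyses are restricted to).
#' @param species list of [species_spec()]s.
#' @param modules list of [module_spec()]s (possibly empty).
#' @param ortholog_fraction share of groups one-to-one across all species.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline expression.
#' @param cross_species_sdlog sdlog of ortholog baseline divergence.
#' @param library_meanlog,library_sdlog log-normal library sizes.
#' @param regime_mean_phi named means of the dispersion regimes.
#' @param phi_sdlog sdlog of gene-wise dispersion around its regime mean.
#' @param length_range transcript-length range (bp), sampled log-uniformly.
#' @param seed RNG seed, recorded in the truth table.
#' @export
sim_config <- function(n_genes = 2000,
                       species = list(species_spec("spA"),
                                      species_spec("spB"),
                                      species_spec("spC")),
                       modules = list(),
                       ortholog_fraction = 0.9,
                       baseline_meanlog = log(50), baseline_sdlog = 1.2,
                       cross_species_sdlog = 0.25,
                       library_meanlog = log(5e5), library_sdlog = 0.15,
                       regime_mean_phi = c(sibling = 0.02,
                                           population = 0.15),
                       phi_sdlog = 0.5,
                       length_range = c(500, 5000),
                       seed = 1) {
  if (n_genes < 1) stop("degenerate config: n_genes must be >= 1")
  if (length(species) < 1) stop("degenerate config: need >= 1 species")
  total_module <- sum(vapply(modules, `[[`, integer(1), "size"))
  if (total_module > n_genes)
    stop("planted modules exceed the gene universe")
  structure(list(n_genes = as.integer(n_genes), species = species,
                 modules = modules, ortholog_fraction = ortholog_fraction,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 cross_species_sdlog = cross_species_sdlog,
                 library_meanlog = library_meanlog,
                 library_sdlog = library_sdlog,
                 regime_mean_phi = regime_mean_phi, phi_sdlog = phi_sdlog,
                 length_range = length_range, seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Load a SimulationConfig from a YAML file
#' @param path YAML file whose keys mirror [sim_config()] arguments; the
#'   `species` and `modules` entries are lists of [species_spec()] /
#'   [module_spec()] argument sets.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$species))
    y$species <- lapply(y$species, function(s) do.call(species_spec, s))
  if (!is.null(y$modules))
    y$modules <- lapply(y$modules, function(m) do.call(module_spec, m))
  if (!is.null(y$regime_mean_phi))
    y$regime_mean_phi <- unlist(y$regime_mean_phi)
  do.call(sim_config, y)
}

#' Simulate NB count matrices with planted digit-identity structure
#'
#' Draws, for every species, counts with mean
#' `mu = library_size * relative_expression(gene, digit)` and variance
#' `mu + phi * mu^2`. Ortholog groups share a baseline expression level
#' across species up to log-normal noise; module genes are shifted
#' multiplicatively in the digit positions their species' identity map
#' designates. Regenerating with the same config reproduces every output
#' exactly.
#'
#' @param config [sim_config()].
#' @return list with `counts` (named list of per-species [count_matrix()]s),
#'   `lengths` (named vector covering every simulated gene), `ortholog_map`
#'   ([ortholog_map()] over the species set), `gene_lists` (GeneLists of
#'   ortholog-group ids: `tf` = whole universe plus one list per planted
#'   module), and `truth` (`SyntheticTruth`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  G <- config$n_genes
  sp_names <- vapply(config$species, `[[`, character(1), "name")
  groups <- sprintf("og%05d", seq_len(G))

  # one-to-one structure: the remainder lack an ortholog in one species
  n_o2o <- round(G * config$ortholog_fraction)
  o2o <- seq_len(G) <= n_o2o

  # module membership: disjoint blocks, planted inside the one-to-one
  # universe (conserved modules are by construction comparable)
  module_of <- rep(NA_character_, G)
  pool <- seq_len(n_o2o)
  modules <- config$modules
  if (sum(vapply(modules, `[[`, integer(1), "size")) > n_o2o)
    stop("planted modules exceed the one-to-one universe")
  for (m in modules) {
    take <- pool[sample.int(length(pool), m$size)]
    module_of[take] <- m$name
    pool <- setdiff(pool, take)
  }

  base_len <- exp(stats::runif(G, log(config$length_range[1]),
                               log(config$length_range[2])))
  base_expr <- stats::rlnorm(G, config$baseline_meanlog,
                             config$baseline_sdlog)

  drop_sp <- ifelse(o2o, NA_integer_,
                    sample.int(length(sp_names), G, replace = TRUE))

  map_tab <- data.frame(group_id = groups, stringsAsFactors = FALSE)
  counts <- list()
  lengths <- numeric(0)
  truth_genes <- list()
  truth_samples <- list()
  digit_means <- list()

  for (si in seq_along(config$species)) {
    sp <- config$species[[si]]
    gene_ids <- paste0(sp$name, "_", groups)
    map_col <- gene_ids
    map_col[!is.na(drop_sp) & drop_sp == si] <- NA
    map_tab[[sp$name]] <- map_col

    sp_expr <- base_expr *
      stats::rlnorm(G, -config$cross_species_sdlog^2 / 2,
                    config$cross_species_sdlog)
    indep <- !is.na(drop_sp) & drop_sp == si  # no shared baseline
    if (any(indep))
      sp_expr[indep] <- stats::rlnorm(sum(indep), config$baseline_meanlog,
                                      config$baseline_sdlog)

    mphi <- config$regime_mean_phi[[sp$regime]]
    phi <- stats::rlnorm(G, log(mphi) - config$phi_sdlog^2 / 2,
                         config$phi_sdlog)

    # relative expression per digit, with planted multiplicative effects
    dm <- matrix(sp_expr, G, sp$n_digits,
                 dimnames = list(gene_ids, paste0("d", seq_len(sp$n_digits))))
    for (m in modules) {
      if (!identical(m$species, "all") && !(sp$name %in% m$species)) next
      rows <- which(module_of == m$name)
      pos <- which(sp$identity_map == m$digit)
      if (length(rows) > 0 && length(pos) > 0)
        dm[rows, pos] <- dm[rows, pos] * 2^m$log2fc
    }
    rel <- sweep(dm, 2, colSums(dm), "/")

    design <- expand.grid(replicate = seq_len(sp$n_reps),
                          digit = seq_len(sp$n_digits),
                          stage = seq_len(sp$n_stages))
    design$sample_id <- sprintf("%s_s%d_d%d_r%d", sp$name, design$stage,
                                design$digit, design$replicate)
    lib <- stats::rlnorm(nrow(design), config$library_meanlog,
                         config$library_sdlog)
    cmat <- matrix(0L, G, nrow(design),
                   dimnames = list(gene_ids, design$sample_id))
    for (j in seq_len(nrow(design))) {
      mu <- lib[j] * rel[, design$digit[j]]
      cmat[, j] <- ifelse(phi < 1e-12,
                          stats::rpois(G, mu),
                          stats::rnbinom(G, size = 1 / phi, mu = mu))
    }
    meta <- data.frame(sample_id = design$sample_id, species = sp$name,
                       limb = "fore", digit = design$digit,
                       stage = paste0("st", design$stage),
                       replicate = design$replicate,
                       stringsAsFactors = FALSE)
    counts[[sp$name]] <- count_matrix(cmat, meta)
    lengths <- c(lengths, stats::setNames(base_len, gene_ids))
    digit_means[[sp$name]] <- rel
    truth_genes[[sp$name]] <- data.frame(
      group_id = groups, species = sp$name, gene_id = gene_ids,
      module = module_of, phi = phi, one_to_one = o2o,
      stringsAsFactors = FALSE)
    truth_samples[[sp$name]] <- data.frame(
      sample_id = design$sample_id, library_size = lib,
      stringsAsFactors = FALSE)
  }

  gene_lists <- c(list(tf = gene_list(groups, "tf")),
                  stats::setNames(
                    lapply(modules, function(m)
                      gene_list(groups[which(module_of == m$name)], m$name)),
                    vapply(modules, `[[`, character(1), "name")))

  truth <- structure(list(genes = do.call(rbind, truth_genes),
                          digit_means = digit_means,
                          samples = do.call(rbind, truth_samples),
                          modules = modules, module_of =
                            stats::setNames(module_of, groups),
                          seed = config$seed, config = config),
                     class = "SyntheticTruth")
  list(counts = counts, lengths = lengths,
       ortholog_map = if (length(sp_names) >= 2)
         ortholog_map(map_tab, sp_names) else NULL,
       gene_lists = gene_lists, truth = truth)
}

#' Sensitivity and false-discovery proportion against planted truth
#'
#' @param truth `SyntheticTruth`.
#' @param called character vector of called ortholog-group ids.
#' @param target_module module label to score against.
#' @return list with `sensitivity` = |called n module| / |module| and
#'   `fdp` = |called \ module| / max(1, |called|).
#' @export
score_recovery <- function(truth, called, target_module) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  labels <- vapply(truth$modules, `[[`, character(1), "name")
  if (!target_module %in% labels)
    stop("unknown module label: ", target_module)
  module <- names(truth$module_of)[!is.na(truth$module_of) &
                                     truth$module_of == target_module]
  called <- unique(called)
  list(sensitivity = length(intersect(called, module)) / length(module),
       fdp = length(setdiff(called, module)) / max(1, length(called)))
}

#' Write a SyntheticTruth's gene table to TSV
#' @param truth SyntheticTruth. @param path output path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth$genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(truth)
}
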