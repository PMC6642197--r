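#' Run the digit-identity pipeline from a single configuration
#'
#' Orchestrates the stages in dependency order — simulate (or ingest) ->
#' normalize -> de -> cluster -> pca -> conserve -> diagnose — writing every
#' stage's tables under `outdir` together with a config snapshot and a log
#' recording package version, seed, and thresholds. Rerunning with the same
#' configuration reproduces all outputs (stochastic stages are seeded from
#' the configuration).
#'
#' @param config path to a YAML run configuration, or an equivalent list.
#'   Recognized keys: `seed`, `stages` (subset of the above), `simulate`
#'   ([sim_config()] arguments) or `inputs` (paths: per-species
#'   `counts`/`metadata`, `lengths`, `ortholog_map`), and per-stage options
#'   `de` (`boundary`, `fdr`, `method`, `any_digit`), `cluster` (`n_boot`,
#'   `gene_list`), `conserve` (`boundary`, `fdr`).
#' @param outdir output directory (created; default `tempfile()`).
#' @return (invisibly) a list of in-memory stage results.
#' @export
run_digit_pipeline <- function(config, outdir = tempfile("digitid_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages_all <- c("simulate", "normalize", "de", "cluster", "pca",
                  "conserve", "diagnose")
  stages <- config$stages %||% stages_all
  bad <- setdiff(stages, stages_all)
  if (length(bad) > 0)
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; valid stages are: ", paste(stages_all, collapse = ", "))
  stages <- stages_all[stages_all %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L

  logfile <- file.path(outdir, "run.log")
  log_line <- function(...) cat(paste0(format(Sys.time(), "%H:%M:%S "), ...,
                                       "\n"),
                                file = logfile, append = TRUE)
  log_line("digitid ", as.character(utils::packageVersion("digitid")),
           "; R ", paste(R.version$major, R.version$minor, sep = "."))
  log_line("seed ", seed, "; stages ", paste(stages, collapse = ", "))
  yaml::write_yaml(config, file.path(outdir, "config_snapshot.yaml"))

  res <- list(seed = seed)

  if ("simulate" %in% stages) {
    sim_args <- config$simulate %||% list()
    if (!is.null(sim_args$species))
      sim_args$species <- lapply(sim_args$species,
                                 function(s) do.call(species_spec, s))
    if (!is.null(sim_args$modules))
      sim_args$modules <- lapply(sim_args$modules,
                                 function(m) do.call(module_spec, m))
    sim_args$seed <- sim_args$seed %||% seed
    sim <- simulate_counts(do.call(sim_config, sim_args))
    d <- file.path(outdir, "simulate")
    dir.create(d, showWarnings = FALSE)
    for (sp in names(sim$counts))
      write_count_matrix(sim$counts[[sp]],
                         file.path(d, paste0(sp, "_counts.tsv")),
                         file.path(d, paste0(sp, "_samples.tsv")))
    utils::write.table(
      data.frame(gene_id = names(sim$lengths), length_bp = sim$lengths),
      file.path(d, "lengths.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_ortholog_map(sim$ortholog_map, file.path(d, "ortholog_map.tsv"))
    write_truth(sim$truth, file.path(d, "truth.tsv"))
    res$sim <- sim
    log_line("simulate: ", length(sim$counts), " species x ",
             nrow(sim$truth$genes) / length(sim$counts), " genes")
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    counts <- lapply(inp$counts, function(s)
      read_count_matrix(s$counts, s$metadata))
    lt <- utils::read.delim(inp$lengths, stringsAsFactors = FALSE)
    lengths <- stats::setNames(lt[[2]], lt[[1]])
    sim <- list(counts = counts, lengths = lengths,
                ortholog_map = if (!is.null(inp$ortholog_map))
                  read_ortholog_map(inp$ortholog_map) else NULL)
    res$sim <- sim
    log_line("ingest: ", length(counts), " species")
  } else {
    stop("pipeline needs either a 'simulate' stage or 'inputs'")
  }
  sim <- res$sim

  if ("normalize" %in% stages) {
    res$expr <- lapply(sim$counts, function(x)
      sqrt_transform(tpm_normalize(x, sim$lengths)))
    d <- file.path(outdir, "normalize")
    dir.create(d, showWarnings = FALSE)
    for (sp in names(res$expr)) {
      utils::write.table(
        data.frame(gene_id = rownames(res$expr[[sp]]$values),
                   res$expr[[sp]]$values, check.names = FALSE),
        file.path(d, paste0(sp, "_sqrt_tpm.tsv")), sep = "\t",
        quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(transform_state = res$expr[[sp]]$transform_state,
             universe_size = length(res$expr[[sp]]$universe)),
        file.path(d, paste0(sp, "_state.json")), auto_unbox = TRUE)
    }
    log_line("normalize: sqrt TPM for ", length(res$expr), " species")
  }

  de_opt <- config$de %||% list()
  boundary <- unlist(de_opt$boundary %||% c(1, 2))
  fdr <- de_opt$fdr %||% 0.05
  if ("de" %in% stages) {
    d <- file.path(outdir, "de")
    dir.create(d, showWarnings = FALSE)
    res$de <- lapply(sim$counts, function(x) {
      de <- if (isTRUE(de_opt$any_digit)) lrt_any_digit(x, lengths = sim$lengths)
      else lrt_pairwise(x, boundary, lengths = sim$lengths)
      de
    })
    for (sp in names(res$de))
      utils::write.table(res$de[[sp]],
                         file.path(d, paste0(sp, "_", attr(res$de[[sp]], "contrast"),
                                             ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("de: boundary ", paste(boundary, collapse = "-"), ", fdr ", fdr)
  }

  if ("cluster" %in% stages) {
    if (is.null(res$expr)) stop("cluster stage requires normalize")
    cl_opt <- config$cluster %||% list()
    n_boot <- cl_opt$n_boot %||% 1000
    d <- file.path(outdir, "cluster")
    dir.create(d, showWarnings = FALSE)
    res$trees <- lapply(names(res$expr), function(sp) {
      tr <- bootstrap_support(res$expr[[sp]], n_boot = n_boot, seed = seed)
      write_tree_newick(tr, file.path(d, paste0(sp, ".nwk")))
      tr
    })
    names(res$trees) <- names(res$expr)
    log_line("cluster: ", n_boot, " bootstrap replicates")
  }

  if ("pca" %in% stages) {
    if (is.null(res$expr)) stop("pca stage requires normalize")
    d <- file.path(outdir, "pca")
    dir.create(d, showWarnings = FALSE)
    res$pca <- lapply(names(res$expr), function(sp) {
      m <- fit_pca(res$expr[[sp]])
      utils::write.table(
        data.frame(sample_id = rownames(m$scores),
                   m$scores[, seq_len(min(5, ncol(m$scores))), drop = FALSE]),
        file.path(d, paste0(sp, "_scores.tsv")), sep = "\t", quote = FALSE,
        row.names = FALSE)
      m
    })
    names(res$pca) <- names(res$expr)
    log_line("pca: centered, unscaled")
  }

  if ("conserve" %in% stages) {
    if (is.null(res$de)) stop("conserve stage requires de")
    if (is.null(sim$ortholog_map)) stop("conserve stage requires an ortholog map")
    sets <- de_sets_by_boundary(res$de, sim$ortholog_map, fdr = fdr)
    cons <- intersect_conserved(sets$sets, sets$direction, N = sets$N,
                                boundary = paste(boundary, collapse = "_vs_"))
    res$conservation <- cons
    jsonlite::write_json(
      list(boundary = cons$boundary, N = cons$N, k = as.list(cons$k),
           intersection = cons$intersection,
           direction_consistent = cons$direction_consistent,
           expected = cons$expected, tail_p = cons$tail_p),
      file.path(outdir, "conservation.json"), auto_unbox = TRUE,
      digits = NA)
    log_line("conserve: |intersection| ", length(cons$intersection),
             " of N ", cons$N)
  }

  if ("diagnose" %in% stages) {
    if (is.null(res$de)) stop("diagnose stage requires de")
    diag <- lapply(res$de, function(de) pvalue_uniformity(de$p_value))
    res$diagnostics <- diag
    jsonlite::write_json(
      lapply(diag, function(d) d[c("ks", "first_bin_excess", "uniform_like",
                                   "n")]),
      file.path(outdir, "diagnostics.json"), auto_unbox = TRUE, digits = NA)
    log_line("diagnose: p-value uniformity per species")
  }

  res$outdir <- outdir
  invisible(res)
}
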