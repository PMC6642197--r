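#!/usr/bin/env Rscript
# Adjacent-digit and any-digit NB-GLM likelihood-ratio tests per limb, with
# BH and Storey FDR control, plus p-value-distribution diagnostics. The
# differentiated limbs show zero-inflated p-value histograms at most
# boundaries while the homogeneous limb stays near-uniform — the
# multiple-testing argument for (a lack of) digit differentiation.
# Requires results/simulation/ from 01_simulate.R; writes results/de/.

library(digitid)

indir <- "results/simulation"
outdir <- "results/de"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

lt <- utils::read.delim(file.path(indir, "lengths.tsv"))
lengths <- stats::setNames(lt$length_bp, lt$gene_id)
species <- sub("_counts\\.tsv$", "",
               basename(Sys.glob(file.path(indir, "*_counts.tsv"))))

diag_rows <- list()
for (sp in species) {
  x <- read_count_matrix(file.path(indir, paste0(sp, "_counts.tsv")),
                         file.path(indir, paste0(sp, "_samples.tsv")))
  disp <- estimate_dispersions(x, de_design(x$samples)$full)
  digits <- sort(unique(x$samples$digit))
  for (d in digits[-length(digits)]) {
    de <- lrt_pairwise(x, c(d, d + 1), dispersions = disp,
                       lengths = lengths)
    utils::write.table(de, file.path(outdir, sprintf("%s_D%d_vs_D%d.tsv",
                                                     sp, d, d + 1)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    u <- pvalue_uniformity(de$p_value)
    diag_rows[[length(diag_rows) + 1]] <- data.frame(
      species = sp, contrast = sprintf("D%d_vs_D%d", d, d + 1),
      n_de_bh = length(de_genes(de, 0.05, "bh")),
      n_de_storey = length(de_genes(de, 0.05, "storey")),
      ks = u$ks, first_bin_excess = u$first_bin_excess,
      uniform_like = u$uniform_like)
  }
  de_any <- lrt_any_digit(x, dispersions = disp, lengths = lengths)
  utils::write.table(de_any, file.path(outdir, paste0(sp, "_any_digit.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  diag_rows[[length(diag_rows) + 1]] <- data.frame(
    species = sp, contrast = "any_digit",
    n_de_bh = length(de_genes(de_any, 0.05, "bh")),
    n_de_storey = length(de_genes(de_any, 0.05, "storey")),
    ks = pvalue_uniformity(de_any$p_value)$ks,
    first_bin_excess = pvalue_uniformity(de_any$p_value)$first_bin_excess,
    uniform_like = pvalue_uniformity(de_any$p_value)$uniform_like)
}
summary_tab <- do.call(rbind, diag_rows)
utils::write.table(summary_tab, file.path(outdir, "de_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(summary_tab, row.names = FALSE)
message("Note the homogeneous limb: uniform-like p-values at every ",
        "boundary and far fewer any-digit discoveries, despite identical ",
        "pipeline settings. Storey calls at least as many genes as BH.")
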