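#!/usr/bin/env Rscript
# Frame-shift evaluation: simulate a 5-digit reference limb and a 4-digit
# wing whose position 2 executes the anterior-digit (D1) program while
# positions 3 and 4 keep their own programs; fit a centered PCA on the
# reference limb over the module gene set and project the wing samples as
# supplementary observations. Nearest-centroid correspondence calls test
# whether the wing reads as 1,3,4 rather than 2,3,4. Self-contained;
# writes results/frameshift/.

library(digitid)

outdir <- "results/frameshift"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

calls_all <- list()
for (s in 1:5) {
  sim <- simulate_counts(sim_config(
    n_genes = 1000, ortholog_fraction = 1,
    species = list(species_spec("ref", n_digits = 5),
                   species_spec("wing", frameshift = TRUE)),
    modules = list(module_spec("mod_D1", 1, 30, 2),
                   module_spec("mod_D3", 3, 30, 2),
                   module_spec("mod_D4", 4, 30, 2)),
    seed = s))
  cdeg <- unlist(lapply(sim$gene_lists[c("mod_D1", "mod_D3", "mod_D4")],
                        `[[`, "members"), use.names = FALSE)
  uni <- one_to_one_universe(sim$ortholog_map)
  ref_expr <- subset_expression(
    sqrt_transform(tpm_normalize(sim$counts$ref, sim$lengths)),
    genes = uni[cdeg, "ref"])
  wing_expr <- subset_expression(
    sqrt_transform(tpm_normalize(sim$counts$wing, sim$lengths)),
    genes = uni[cdeg, "wing"])
  # cross-limb rule: each limb is one bulk, centered on its own means
  ref_cen <- bulk_center(ref_expr,
                         setNames(rep("ref", ncol(ref_expr$values)),
                                  colnames(ref_expr$values)))
  wing_cen <- bulk_center(wing_expr,
                          setNames(rep("wing", ncol(wing_expr$values)),
                                   colnames(wing_expr$values)))
  wing_cen <- map_expression_to_species(wing_cen, sim$ortholog_map,
                                        "wing", "ref", groups = cdeg)
  model <- fit_pca(ref_cen)
  calls <- call_correspondence(model,
                               project_supplementary(model, wing_cen))
  calls$position <- sim$counts$wing$samples$digit[
    match(calls$sample_id, sim$counts$wing$samples$sample_id)]
  calls$seed <- s
  calls_all[[s]] <- calls
}
calls <- do.call(rbind, calls_all)
utils::write.table(calls, file.path(outdir, "correspondence_calls.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
tab <- table(position = calls$position, assigned = calls$assigned_digit)
print(tab)
message("Wing position 2 reads as reference D1 in ",
        sum(calls$assigned_digit[calls$position == 2] == 1), "/",
        sum(calls$position == 2), " projected samples; positions 3 and 4 ",
        "retain their own identities - the 1,3,4 pattern.")
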