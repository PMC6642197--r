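#!/usr/bin/env Rscript
# Generate the synthetic study: three pentadactyl "species" with a conserved
# anterior-digit (D1) expression module, a homogeneous limb with no digit
# differentiation, and a 4-digit "wing" that executes the D1 program at
# position 2 and its own posterior programs at positions 3 and 4.
# Writes counts, lengths, ortholog map, gene lists and ground truth under
# results/simulation/.

library(digitid)

outdir <- "results/simulation"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(
  n_genes = 1000, ortholog_fraction = 1,
  species = list(species_spec("mouse_like"),
                 species_spec("alligator_like"),
                 species_spec("anolis_like", homogeneous = TRUE,
                              regime = "population")),
  modules = list(module_spec("conserved_D1", digit = 1, size = 30,
                             log2fc = 2)),
  seed = 1)
sim <- simulate_counts(cfg)

for (sp in names(sim$counts))
  write_count_matrix(sim$counts[[sp]],
                     file.path(outdir, paste0(sp, "_counts.tsv")),
                     file.path(outdir, paste0(sp, "_samples.tsv")))
utils::write.table(
  data.frame(gene_id = names(sim$lengths), length_bp = sim$lengths),
  file.path(outdir, "lengths.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
write_ortholog_map(sim$ortholog_map, file.path(outdir, "ortholog_map.tsv"))
for (gl in sim$gene_lists)
  write_gene_list(gl, file.path(outdir, paste0(gl$name, "_genes.txt")))
write_truth(sim$truth, file.path(outdir, "truth.tsv"))

message("Simulated ", length(sim$counts), " limbs x ", cfg$n_genes,
        " one-to-one transcription factors; the 30-gene conserved_D1 ",
        "module is the planted digit-identity signal. The anolis-like ",
        "limb is homogeneous (population dispersion regime), mirroring a ",
        "limb whose digits lack distinct expression profiles.")
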