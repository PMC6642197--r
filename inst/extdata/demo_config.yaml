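# demo run: two small simulated species with a conserved anterior-digit
# module, taken end to end through normalization, DE, clustering, PCA,
# conservation and diagnostics
seed: 7
simulate:
  n_genes: 80
  ortholog_fraction: 1.0
  species:
    - name: spA
      n_digits: 3
      n_reps: 3
    - name: spB
      n_digits: 3
      n_reps: 3
  modules:
    - name: conserved_D1
      digit: 1
      size: 10
      log2fc: 2
de:
  boundary: [1, 2]
  fdr: 0.05
cluster:
  n_boot: 150
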