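# Example pipeline configuration for `srnablocks all --config ...`.
# Any omitted key keeps its published default (17-35 nt, 20 RPM, 2-fold,
# alpha 0.05, <=20 loci, 170 nt window, -40 kcal/mol, gap 100).
gap: 100
rpm_min: 20
fc_min: 2
alpha: 0.05
sim:
  seed: 1
  genome_length: 120000
  n_mirna_loci: 8
  n_te_loci: 6
  n_gene_sirna_loci: 4
  n_decoy_trna: 8
  n_decoy_rdna: 2
  error_rate: 0.005
  de_plan:
    - {locus_id: mir01, library_id: cot_fr, fold_change: 4}
    - {locus_id: mir02, library_id: hkcv_fr, fold_change: 4}
    - {locus_id: te01, library_id: hkcv_fr, fold_change: 0.25}
  library_design:
    - {library_id: cot_dark, tissue_label: cotyledon, light_label: dark, depth_reads: 20000}
    - {library_id: cot_fr, tissue_label: cotyledon, light_label: fr, depth_reads: 20000}
    - {library_id: hyp_dark, tissue_label: hypocotyl, light_label: dark, depth_reads: 20000}
    - {library_id: hyp_fr, tissue_label: hypocotyl, light_label: fr, depth_reads: 20000}
    - {library_id: hkcc_dark, tissue_label: hook_concave, light_label: dark, depth_reads: 20000}
    - {library_id: hkcc_fr, tissue_label: hook_concave, light_label: fr, depth_reads: 20000}
    - {library_id: hkcv_dark, tissue_label: hook_convex, light_label: dark, depth_reads: 20000}
    - {library_id: hkcv_fr, tissue_label: hook_convex, light_label: fr, depth_reads: 20000}
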