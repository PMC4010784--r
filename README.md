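# srnablocks

An R package for tissue-survey analysis of plant small-RNA sequencing data.
It takes raw small-RNA reads through the classic survey pipeline:

1. **Preprocess** — collapse reads to unique tags, 17–35 nt size selection,
   abundance-ranked single-mismatch error correction.
2. **Triage** — hierarchical alignment: tRNA/rDNA decoys (≤3 mismatches,
   removed) → nuclear genome (perfect matches, quantified) → genome at a
   relaxed budget (reported) → chloroplast → mitochondrion → unmapped.
3. **Blocks** — proximity-based merging of pooled perfect placements into
   genomic blocks (default gap 100 nt), with 1/k weighting of tags mapping
   to k loci so repeat-derived reads are never over-counted.
4. **Differential expression** — per block, the difference-in-proportion
   (DIP) test on raw weighted counts,

   `z = (p1 − p2) / sqrt( p̄ (1 − p̄) (1/n1 + 1/n2) )`,  `p̄ = (x1+x2)/(n1+n2)`,

   with Bonferroni correction, a strict >20 RPM expression filter, and a
   2-fold cutoff, across the six standard tissue/light contrasts.
5. **miRNA discovery** — tags mapping to ≤20 loci are folded in 170-nt
   strand-specific windows; a call requires (i) >75% of key bases paired,
   (ii) star span ≤1.5× key length, (iii) key–star separation ≥20 nt,
   and folding energy ≤ −40 kcal/mol, followed by repeat screening and
   known/novel classification against a mature reference set.
6. **Annotation** — per differentially expressed block: key sequence,
   20–24 nt size histogram, strand bias, hairpin verdict, similarity search
   against known matures (empirical p at 0.01), and classification into
   miRNA-like / siRNA-TE / siRNA-gene.

Who it is for: anyone who wants a fully tested, reproducible re-implementation
of this survey design — and a **synthetic-data module** (`sim_config()`,
`generate_genome()`, `simulate_libraries()`) that plants miRNA hairpins, TE
siRNA clusters, decoys and fold changes with machine-readable ground truth,
so every pipeline stage can be validated end to end.

## Worked example

The default configuration simulates the eight-library design (four tissues ×
dark/far-red, 50,000 reads each) and runs all seven stages in about a minute:

```r
library(srnablocks)
manifest <- run_pipeline(pipeline_config(), "run1")

manifest$stages$blocks
#> $blocks: 50      $mean_length: 691.4      $median_length: 550.5

unlist(manifest$stages$de)
#>     cot_fr_vs_dark     hyp_fr_vs_dark    hkcc_fr_vs_dark    hkcv_fr_vs_dark
#>                  1                  1                  2                  4
#> hook_cv_vs_cc_dark   hook_cv_vs_cc_fr
#>                  0                  6

unlist(manifest$stages$annotate$truth_agreement)
#>    mirna sirna_te
#>        1        1

read_tsv("run1/ratio_21_24.tsv")
#>    library_id ratio_21_24
#> 1:   cot_dark   2.2322275
#> 2:     cot_fr   2.2497407
#> 3:  hkcc_dark   0.7740247
#> ...
```

Reading the output: the pooled perfect-match placements form 50 blocks —
one per planted locus (20 miRNA hairpins, 15 TE clusters, 15 gene-overlap
clusters).  The `de` counts are the significant blocks per contrast; the
planted fold changes (e.g. 4× miRNA inductions in the far-red hook convex
library) drive the non-zero entries.  `truth_agreement` is the fraction of
planted miRNA and TE-siRNA loci whose block was classified to the matching
class — 1.0 for both here.  The 21:24 nt abundance ratios reproduce the
configured tissue profile (cotyledon ≈ 2:1, 24-dominated hypocotyl, far-red
hook shifted toward 21 nt by the planted miRNA inductions).

The same run from the shell:

```sh
Rscript inst/cli/srnablocks all --out run1            # default config
Rscript inst/cli/srnablocks all --config cfg.yaml --out run2 --seed 7
```

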