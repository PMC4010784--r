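test_that("plant_hairpin constructs valid precursors and rejects bad input", {
  set.seed(1)
  mature <- random_tag(21)
  pre <- plant_hairpin(mature, pairing_fraction = 1.0, loop_length = 30)
  expect_equal(nchar(pre), 21 + 30 + 21)
  expect_identical(substr(pre, 1, 21), mature)
  expect_identical(substr(pre, 52, 72), revcomp(mature))

  expect_error(plant_hairpin(mature, loop_length = 19), "at least 20")
  expect_error(plant_hairpin(mature, pairing_fraction = 0.75), "0.75")
  expect_error(plant_hairpin(random_tag(19)), "20-22")

  # pairing_fraction 0.8 on a 21-mer: at most floor(0.2*21)=4 substitutions
  for (i in 1:20) {
    pre <- plant_hairpin(mature, pairing_fraction = 0.8, loop_length = 25)
    star <- substr(pre, 21 + 25 + 1, nchar(pre))
    d <- sum(strsplit(star, NULL)[[1]] != strsplit(revcomp(mature), NULL)[[1]])
    expect_lte(d, 4)
  }
})

test_that("generate_genome handles the empty plan and undersized genomes", {
  cfg <- sim_config(seed = 3, genome_length = 60000, n_mirna_loci = 0,
                    n_te_loci = 0, n_gene_sirna_loci = 0, n_decoy_trna = 3,
                    n_decoy_rdna = 1, de_plan = NULL,
                    library_design = default_library_design(1000))
  sim <- generate_genome(cfg)
  expect_true(all(sim$truth$class %in% c("trna", "rdna", "plastid")))

  cfg2 <- sim_config(seed = 3, genome_length = 50000, n_te_loci = 40,
                     de_plan = NULL,
                     library_design = default_library_design(1000))
  expect_error(generate_genome(cfg2), "too small")
})

test_that("generation is deterministic given the seed", {
  cfg <- small_sim_config()
  s1 <- generate_genome(cfg)
  s2 <- generate_genome(cfg)
  expect_identical(s1$references, s2$references)
  expect_identical(s1$annotation, s2$annotation)
  expect_equal(s1$truth, s2$truth)
  r1 <- simulate_libraries(s1)
  r2 <- simulate_libraries(s2)
  expect_identical(r1, r2)
})

test_that("planted hairpin windows pass the evaluator and loci never merge", {
  run <- small_run()
  truth <- run$sim$truth
  mir <- truth[class == "mirna"]
  for (i in seq_len(nrow(mir))) {
    L <- nchar(mir$mature_sequence[i])
    if (mir$strand[i] == "+") {
      pl <- list(chrom = mir$chrom[i], start = mir$start[i],
                 end = mir$start[i] + L, strand = "+")
    } else {
      pl <- list(chrom = mir$chrom[i], start = mir$end[i] - L,
                 end = mir$end[i], strand = "-")
    }
    win <- extract_window(run$sim$references$genome, pl)
    fr <- fold(win$sequence)
    ev <- evaluate_hairpin(delta_g = fr$delta_g, key_start = win$key_start,
                           key_len = L, pairs = fr$pairs)
    expect_true(ev$verdict, info = mir$locus_id[i])
  }
  # spacing: planted genomic loci stay in distinct blocks at the default gap
  g <- truth[chrom == "Chr1"][order(start)]
  expect_true(all(g$start[-1] - g$end[-nrow(g)] > 100))
})

test_that("libraries conserve depth and zero-noise miRNA reads come from the arm", {
  run <- small_run()
  depths <- run$cfg$library_design$depth_reads
  expect_identical(unname(lengths(run$reads)), as.integer(depths))

  # error-free single-locus config: every read is a precursor-arm substring
  cfg <- sim_config(seed = 5, genome_length = 60000, n_mirna_loci = 1,
                    n_te_loci = 0, n_gene_sirna_loci = 0, n_decoy_trna = 0,
                    n_decoy_rdna = 0, n_plastid_contigs = 0, error_rate = 0,
                    de_plan = NULL, ratio_21_24 = NULL,
                    decoy_fraction = 0, plastid_fraction = 0,
                    junk_fraction = 0,
                    library_design = data.frame(library_id = "l1",
                                                tissue_label = "t",
                                                light_label = "dark",
                                                depth_reads = 500L))
  sim <- generate_genome(cfg)
  reads <- simulate_libraries(sim)[["l1"]]
  tr <- sim$truth[class == "mirna"]
  locus_txt <- substr(sim$references$genome[[1]], tr$start - 1, tr$end + 2)
  arm <- c(locus_txt, revcomp(locus_txt))
  expect_true(all(vapply(unique(reads), function(r)
    any(grepl(r, arm, fixed = TRUE)), logical(1))))
})

test_that("planted fold changes are exact in expectation", {
  ld <- data.frame(library_id = c("a", "b"), tissue_label = "t",
                   light_label = c("dark", "fr"), depth_reads = 50000L)
  cfg <- sim_config(seed = 9, genome_length = 80000, n_mirna_loci = 3,
                    n_te_loci = 3, n_gene_sirna_loci = 3, n_decoy_trna = 3,
                    n_decoy_rdna = 1, library_design = ld,
                    decoy_fraction = 0.3, ratio_21_24 = NULL,
                    de_plan = data.frame(locus_id = "te01", library_id = "b",
                                         fold_change = 4))
  sim <- generate_genome(cfg)
  ea <- sim$truth[locus_id == "te01", expected_a]
  eb <- sim$truth[locus_id == "te01", expected_b]
  expect_equal(eb / ea, 4, tolerance = 1e-12)

  # sampled counts over 100 seeded replicates: mean ratio within 3 SE of 4
  ratios <- vapply(1:100, function(s) {
    cc <- simulate_locus_counts(sim, seed = s)
    cc[locus_id == "te01", b] / cc[locus_id == "te01", a]
  }, numeric(1))
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 4), 3 * se + 1e-12)
})

test_that("simulate_libraries rejects an empty truth table", {
  run <- small_run()
  sim2 <- run$sim
  sim2$truth <- sim2$truth[0]
  expect_error(simulate_libraries(sim2), "empty")
})

test_that("dinucleotide_shuffle preserves dinucleotide composition", {
  set.seed(42)
  s <- random_dna(3000)
  sh <- dinucleotide_shuffle(s, seed = 7)
  dinuc <- function(x) {
    v <- strsplit(x, NULL)[[1]]
    table(paste0(v[-length(v)], v[-1]))
  }
  expect_identical(dinuc(s), dinuc(sh))
  expect_false(identical(s, sh))
})
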