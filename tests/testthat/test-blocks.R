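test_that("build_blocks merges within the gap and splits beyond it", {
  h <- data.table::data.table(chrom = "c", start = c(100L, 180L),
                              end = c(121L, 201L))
  b <- build_blocks(h, gap = 100)
  expect_equal(nrow(b), 1L)
  expect_equal(b$start, 100L)
  expect_equal(b$end, 201L)

  h2 <- data.table::data.table(chrom = "c", start = c(100L, 300L),
                               end = c(121L, 321L))
  expect_equal(nrow(build_blocks(h2, gap = 100)), 2L)

  # exact boundary: separation == gap still merges (chain rule is <= gap)
  h3 <- data.table::data.table(chrom = "c", start = c(0L, 121L),
                               end = c(21L, 142L))
  expect_equal(nrow(build_blocks(h3, gap = 100)), 1L)
  expect_equal(nrow(build_blocks(h3, gap = 99)), 2L)
})

test_that("block partitions equal the transitive-closure oracle", {
  set.seed(41)
  for (rep in 1:200) {
    n <- sample(2:200, 1)
    gap <- sample(0:120, 1)
    start <- sample(0:3000, n, replace = TRUE)
    len <- sample(17:35, n, replace = TRUE)
    h <- data.table::data.table(chrom = "c", start = start, end = start + len)
    blocks <- build_blocks(h, gap = gap)
    got <- assign_blocks(h, blocks)$block_id
    want <- brute_block_partition(h$start, h$end, gap)
    # same partition: label vectors agree up to renaming
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(x) length(unique(x)) == 1)))
  }
})

test_that("more gap never means more blocks", {
  set.seed(43)
  start <- sample(0:5000, 150, replace = TRUE)
  h <- data.table::data.table(chrom = "c", start = start, end = start + 21L)
  nblocks <- vapply(c(0, 10, 50, 100, 200, 500), function(g)
    nrow(build_blocks(h, gap = g)), numeric(1))
  expect_true(all(diff(nblocks) <= 0))
})

test_that("weighted counts follow the 1/k rule and conserve totals", {
  blocks <- data.table::data.table(block_id = c("b1", "b2"), chrom = "c",
                                   start = c(0L, 1000L), end = c(100L, 1100L))
  tag <- random_tag(21)
  hits <- data.table::data.table(
    tag_sequence = tag, chrom = "c", start = c(10L, 1010L),
    end = c(31L, 1031L), strand = "+", mismatches = 0L, placements = 2L)
  tags <- data.table::data.table(sequence = tag, abundance = 10L,
                                 library_id = "l1")
  wc <- weighted_counts(blocks, hits, tags)
  expect_equal(wc[block_id == "b1", weighted_count], 5)
  expect_equal(wc[block_id == "b2", weighted_count], 5)

  # both placements inside one block: the full abundance lands there
  hits2 <- data.table::data.table(
    tag_sequence = tag, chrom = "c", start = c(10L, 40L), end = c(31L, 61L),
    strand = "+", mismatches = 0L, placements = 2L)
  wc2 <- weighted_counts(blocks, hits2, tags)
  expect_equal(wc2[block_id == "b1", weighted_count], 10)
  expect_equal(wc2[block_id == "b2", weighted_count], 0)
})

test_that("weighted counts conserve the genome-perfect total on synthetic data", {
  run <- small_run()
  wc <- weighted_counts(run$blocks, run$hits, run$gtags)
  expect_equal(sum(wc$weighted_count), sum(run$gtags$abundance),
               tolerance = 1e-9)
  # per-library too
  per <- wc[, .(w = sum(weighted_count)), by = library_id]
  per2 <- run$gtags[, .(a = sum(abundance)), by = library_id]
  m <- merge(per, per2, by = "library_id")
  expect_equal(m$w, as.numeric(m$a), tolerance = 1e-9)
})

test_that("size_profile reports shares and the 21:24 ratio", {
  tags <- data.table::data.table(
    sequence = vapply(rep(21, 5), random_tag, character(1)),
    abundance = 10L, library_id = "l1")
  sp <- size_profile(tags)
  expect_equal(sp$per_length[library_id == "l1" & length == 21, share], 1)
  expect_true(is.na(sp$ratio$ratio_21_24)) # no 24-nt abundance

  run <- small_run()
  sp2 <- size_profile(run$gtags)
  sums <- sp2$per_length[, .(s = sum(share)), by = library_id]
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-9)
})

test_that("a planted 2:1 21:24 ratio is recovered at depth 1e6", {
  ld <- data.frame(library_id = "deep", tissue_label = "t",
                   light_label = "dark", depth_reads = 1000000L)
  cfg <- sim_config(seed = 47, genome_length = 100000, n_mirna_loci = 6,
                    n_te_loci = 5, n_gene_sirna_loci = 0, n_decoy_trna = 0,
                    n_decoy_rdna = 0, n_plastid_contigs = 0,
                    error_rate = 0, de_plan = NULL, library_design = ld,
                    decoy_fraction = 0, plastid_fraction = 0,
                    junk_fraction = 0, ratio_21_24 = 2.0)
  sim <- generate_genome(cfg)
  reads <- simulate_libraries(sim)[["deep"]]
  tags <- length_filter(collapse_reads(reads, "deep"))
  sp <- size_profile(tags)
  expect_lt(abs(sp$ratio$ratio_21_24 - 2), 0.1)
})
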