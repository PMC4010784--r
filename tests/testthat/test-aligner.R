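test_that("build_index validates input and seed_lookup enumerates placements", {
  expect_error(build_index(character(0)), "empty")
  expect_error(build_index(setNames("ACGT", "")), "named")

  idx <- build_index(c(r = "ACGTACGT"))
  hits <- seed_lookup(idx, "ACGT")
  plus <- hits[strand == "+"]
  expect_equal(sort(plus$start), c(0L, 4L))
  # ACGT is its own reverse complement, so minus-strand hits mirror these
  expect_equal(sort(hits[strand == "-"]$start), c(0L, 4L))

  # a seed present only as reverse complement is reported on the minus strand
  idx2 <- build_index(c(r = "AAAAGGGCCTAAAA"))
  h2 <- seed_lookup(idx2, revcomp("GGGCCT"))
  expect_identical(unique(h2$strand), "-")
  expect_equal(h2$start, 4L)
})

test_that("align respects the mismatch threshold", {
  ref <- c(r = paste0(strrep("A", 30), "CCGGTTACGGATCCAAGGTTA", strrep("A", 30)))
  tag <- "CCGGTTACGGATCCAAGGTTA"
  idx <- build_index(ref)
  h0 <- align(tag, idx, 0)
  expect_equal(nrow(h0), 1L)
  expect_equal(h0$mismatches, 0L)
  expect_equal(h0$start, 30L)

  tag1 <- paste0("CCGGTTACGG", "T", "TCCAAGGTTA") # 1 substitution
  expect_equal(nrow(align(tag1, idx, 0)), 0L)
  h3 <- align(tag1, idx, 3)
  expect_equal(h3$mismatches, 1L)
})

test_that("align equals the naive Hamming-scan oracle on random instances", {
  set.seed(19)
  for (budget in 0:3) {
    for (rep in 1:12) {
      ref <- setNames(random_dna(400), "r")
      base <- substr(ref, 100, 100 + sample(17:30, 1))
      tag <- if (rep %% 2 == 0) {
        v <- strsplit(base, NULL)[[1]]
        for (p in sample(length(v), sample(0:3, 1)))
          v[p] <- sample(c("A", "C", "G", "T"), 1)
        paste(v, collapse = "")
      } else random_tag(sample(17:25, 1))
      got <- align(tag, build_index(ref), budget)
      want <- naive_align(tag, names(ref), unname(ref), budget)
      key <- function(d) sort(paste(d$chrom, d$start, d$strand, d$mismatches))
      expect_identical(key(got), key(want))
    }
  }
})

test_that("index hits equal the naive scan on larger references", {
  set.seed(23)
  refs <- setNames(vapply(1:10, function(i) random_dna(5000), character(1)),
                   paste0("c", 1:10))
  idx <- build_index(refs)
  for (i in 1:10) {
    tag <- substr(refs[[sample(10, 1)]], 777, 777 + 20)
    got <- align(tag, idx, 0)
    want <- naive_align(tag, names(refs), unname(refs), 0)
    expect_equal(nrow(got), nrow(want))
    expect_setequal(paste(got$chrom, got$start, got$strand),
                    paste(want$chrom, want$start, want$strand))
  }
})

test_that("aligning the reverse complement swaps strands only", {
  set.seed(29)
  ref <- setNames(random_dna(2000), "r")
  idx <- build_index(ref)
  tag <- substr(ref, 501, 521)
  h1 <- align(tag, idx, 1)
  h2 <- align(revcomp(tag), idx, 1)
  expect_equal(nrow(h1), nrow(h2))
  flip <- function(s) ifelse(s == "+", "-", "+")
  expect_setequal(paste(h1$chrom, h1$start, h1$strand),
                  paste(h2$chrom, h2$start, flip(h2$strand)))
})

test_that("hierarchical_filter applies the cascade in order", {
  genome <- setNames(random_dna(5000, gc = 0.5), "Chr1")
  trna <- setNames(random_dna(80), "trna1")

  tag_genome <- substr(genome, 1001, 1021)   # perfect genome match
  # a tag matching the tRNA decoy with 2 mismatches AND the genome perfectly:
  # plant the tag inside the genome and a 2-mismatch copy in the decoy
  v <- strsplit(tag_genome, NULL)[[1]]
  v[3] <- setdiff(c("A", "C", "G", "T"), v[3])[1]
  v[10] <- setdiff(c("A", "C", "G", "T"), v[10])[1]
  trna <- setNames(paste0(substr(trna, 1, 20), paste(v, collapse = ""),
                          substr(trna, 42, 80)), "trna1")
  tag_nowhere <- paste0(strrep("AC", 10), "G")

  tags <- data.table::data.table(
    sequence = c(tag_genome, tag_nowhere),
    length = 21L, abundance = c(10L, 5L), library_id = "l1")
  refs <- list(trna = trna, rdna = setNames(character(0), character(0)),
               genome = genome,
               chloroplast = setNames(character(0), character(0)),
               mitochondrion = setNames(character(0), character(0)))
  tri <- hierarchical_filter(tags, refs)
  expect_identical(tri$categories[sequence == tag_genome, category],
                   "trna_rdna") # cascade order wins over the perfect hit
  expect_identical(tri$categories[sequence == tag_nowhere, category],
                   "unmapped")

  refs$trna <- NULL
  expect_error(hierarchical_filter(tags, refs), "trna")
})

test_that("triage is a partition and decoy fractions match the configuration", {
  run <- small_run()
  tri <- run$triage
  # every tag in exactly one category
  expect_equal(nrow(tri$categories), length(unique(run$tags$sequence)))
  expect_false(anyNA(tri$categories$category))
  # per-library summary fractions sum to 1
  sums <- tri$summary[, .(s = sum(fraction)), by = library_id]
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-9)
  # configured decoy fractions are reproduced within 2 percentage points
  ld <- run$cfg$library_design
  for (k in seq_len(nrow(ld))) {
    want <- run$cfg$decoy_fraction[[ld$tissue_label[k]]]
    got <- tri$summary[category == "trna_rdna" &
                         library_id == ld$library_id[k], sum(fraction)]
    expect_lt(abs(got - want), 0.02)
  }
})
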