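test_that("candidate_loci applies the 20-locus multiplicity rule", {
  mk_hits <- function(tag, k) data.table::data.table(
    tag_sequence = tag, chrom = "c", start = seq(0, by = 1000, length.out = k),
    end = seq(0, by = 1000, length.out = k) + nchar(tag), strand = "+",
    mismatches = 0L, placements = k)
  t1 <- random_tag(21); t2 <- random_tag(21); t3 <- random_tag(21)
  hits <- data.table::rbindlist(list(mk_hits(t1, 21L), mk_hits(t2, 20L),
                                     mk_hits(t3, 1L)))
  tags <- data.table::data.table(sequence = c(t1, t2, t3), abundance = 100L,
                                 library_id = "l")
  cand <- candidate_loci(hits, tags, max_loci = 20)
  expect_false(t1 %in% cand$sequence)   # 21 loci: excluded
  expect_equal(sum(cand$sequence == t2), 20L)
  expect_equal(sum(cand$sequence == t3), 1L)
})

test_that("extract_window centres, shifts inward, and honours strand", {
  genome <- setNames(random_dna(10000), "chr")
  gs <- genome[["chr"]]
  w <- extract_window(genome, list(chrom = "chr", start = 500, end = 521,
                                   strand = "+"))
  expect_equal(c(w$start, w$end), c(425, 595))
  expect_equal(nchar(w$sequence), 170L)
  expect_equal(w$key_start, 75L)
  expect_identical(substr(w$sequence, w$key_start + 1, w$key_start + 21),
                   substr(gs, 501, 521))

  w2 <- extract_window(genome, list(chrom = "chr", start = 10, end = 31,
                                    strand = "+"))
  expect_equal(c(w2$start, w2$end), c(0, 170))

  w3 <- extract_window(genome, list(chrom = "chr", start = 500, end = 521,
                                    strand = "-"))
  expect_identical(w3$sequence, revcomp(substr(gs, 426, 595)))
  expect_identical(substr(w3$sequence, w3$key_start + 1, w3$key_start + 21),
                   revcomp(substr(gs, 501, 521)))

  short <- setNames(random_dna(100), "chr")
  expect_null(extract_window(short, list(chrom = "chr", start = 10, end = 31,
                                         strand = "+")))
})

test_that("the baseline folder finds the optimum of small sequences", {
  r <- fold("GGGAAACCC")
  expect_identical(r$structure, "(((...)))")
  expect_equal(r$delta_g, -9)
  # independent oracle: exhaustive enumeration over nested structures
  expect_equal(r$delta_g, enum_fold_energy("GGGAAACCC"))

  r2 <- fold(strrep("A", 30))
  expect_equal(r2$delta_g, 0)
  expect_false(grepl("[()]", r2$structure))

  # optimal energies match exhaustive enumeration on random 14-mers
  set.seed(67)
  for (i in 1:15) {
    s <- random_dna(14)
    expect_equal(fold(s)$delta_g, enum_fold_energy(s), info = s)
  }

  # self-consistency: reported energy equals the energy of the returned
  # structure
  set.seed(68)
  for (i in 1:5) {
    s <- random_dna(120)
    r <- fold(s)
    pr <- parse_dot_bracket(r$structure)
    v <- strsplit(s, NULL)[[1]]
    e <- 0
    for (j in seq_along(pr)) if (pr[j] > j - 1) {
      p <- paste0(sort(c(v[j], v[pr[j] + 1])), collapse = "")
      e <- e + switch(p, "CG" = -3, "AT" = -2, "GT" = -1, 0)
    }
    expect_equal(r$delta_g, e)
  }

  expect_error(fold("ACGT", backend = "unafold"), "unknown fold backend")
})

test_that("each hairpin criterion can fail alone on constructed windows", {
  want_fail <- c(fail_i = "i", fail_ii = "ii", fail_iii = "iii",
                 fail_dG = "dG")
  for (nm in names(hairpin_fixtures)) {
    fx <- hairpin_fixtures[[nm]]
    fr <- fold(fx$win)
    ev <- evaluate_hairpin(delta_g = fr$delta_g, key_start = fx$key_start,
                           key_len = 21, pairs = fr$pairs)
    failing <- names(ev$criteria)[!ev$criteria]
    expect_identical(failing, unname(want_fail[nm]), info = nm)
    expect_false(ev$verdict)
  }
})

test_that("criterion thresholds sit exactly where stated", {
  # 16 of 21 paired passes criterion (i); 15 of 21 fails it
  fr16 <- fold(hairpin_fixtures$fail_iii$win) # 16 paired
  ev16 <- evaluate_hairpin(delta_g = fr16$delta_g, key_start = 75,
                           key_len = 21, pairs = fr16$pairs)
  expect_equal(ev16$paired_fraction, 16 / 21)
  expect_true(ev16$criteria[["i"]])
  fr15 <- fold(hairpin_fixtures$fail_i$win) # 15 paired
  ev15 <- evaluate_hairpin(delta_g = fr15$delta_g, key_start = 75,
                           key_len = 21, pairs = fr15$pairs)
  expect_equal(ev15$paired_fraction, 15 / 21)
  expect_false(ev15$criteria[["i"]])
  # 19-nt separation fails criterion (iii), 20 passes
  expect_equal(ev16$separation, 19L)
  expect_false(ev16$criteria[["iii"]])
  ev20 <- evaluate_hairpin(delta_g = fold(hairpin_fixtures$fail_i$win)$delta_g,
                           key_start = 75, key_len = 21,
                           pairs = fold(hairpin_fixtures$fail_i$win)$pairs)
  expect_equal(ev20$separation, 20L)

  expect_error(evaluate_hairpin(structure = strrep(".", 170), delta_g = 0,
                                key_start = 160, key_len = 21),
               "key span")
})

test_that("repeat_filter drops any window overlapping a repeat", {
  ann <- data.table::data.table(chrom = "c", start = 1000L, end = 2000L,
                                strand = "+", type = "repeat_region",
                                ID = "r1")
  cand <- data.table::data.table(
    sequence = "x", chrom = "c",
    window_start = c(1200L, 3000L, 1950L), window_end = c(1370L, 3170L, 2120L))
  out <- repeat_filter(cand, ann)
  expect_equal(out$window_start, 3000L) # full and half overlaps removed
  # non-repeat feature types are ignored
  ann2 <- data.table::copy(ann)[, type := "gene"]
  expect_equal(nrow(repeat_filter(cand, ann2)), 3L)
})

test_that("classify_known_novel implements the similarity rule", {
  ref <- c(mirX = "TTGACAGAAGATAGAGAGCAC")
  expect_identical(classify_known_novel("TTGACAGAAGATAGAGAGCAC", ref)$status,
                   "known")
  v <- strsplit(ref[[1]], NULL)[[1]]
  stopifnot(all(v[c(2, 9, 15)] != "C"))
  v[c(2, 9, 15)] <- "C" # 3 substitutions
  expect_identical(classify_known_novel(paste(v, collapse = ""), ref)$status,
                   "novel")
  # 1-nt 5' truncation: length diff 1, no internal mismatch -> known
  expect_identical(classify_known_novel(substr(ref[[1]], 2, 21), ref)$status,
                   "known")
  expect_warning(r <- classify_known_novel("TTGACAGAAGATAGAGAGCAC",
                                           character(0)), "empty")
  expect_identical(r$status, "novel")
})

test_that("discovery recovers planted hairpins and restricts call sizes", {
  run <- small_run()
  disc <- discover_mirnas(run$sim$references$genome, run$triage$genome_hits,
                          run$gtags, annotation = run$sim$annotation,
                          mature_refs = character(0), min_abundance = 5)
  mir <- run$sim$truth[class == "mirna"]
  hit <- vapply(mir$mature_sequence, function(m) {
    any(vapply(disc$calls$sequence, function(s)
      (nchar(s) >= nchar(m) - 1) && (grepl(s, m, fixed = TRUE) ||
                                       grepl(m, s, fixed = TRUE)),
      logical(1)))
  }, logical(1))
  expect_gte(mean(hit), 0.9)
  # all calls within the size range; restricting sizes never adds calls
  expect_true(all(nchar(disc$calls$sequence) %in% 20:22))
  expect_lte(nrow(disc$calls), nrow(disc$candidates[verdict == TRUE]))
})
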