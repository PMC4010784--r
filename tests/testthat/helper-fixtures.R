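# Shared fixtures and independent oracles for the test suite.

# window built from homopolymer segments: mkwin("A",40, "G",15, ...)
mkwin <- function(...) {
  a <- list(...)
  paste(mapply(function(ch, n) strrep(ch, n),
               a[seq(1, length(a), 2)], a[seq(2, length(a), 2)]),
        collapse = "")
}

# the four constructed 170-nt windows that fail exactly one hairpin
# criterion each under the baseline folder (key length 21)
hairpin_fixtures <- list(
  fail_i   = list(win = mkwin("A", 40, "G", 15, "A", 20, "C", 21, "A", 74),
                  key_start = 75),
  fail_ii  = list(win = mkwin("A", 30, "G", 8, "A", 16, "G", 8, "A", 20,
                              "C", 21, "A", 67),
                  key_start = 82),
  fail_iii = list(win = mkwin("A", 40, "G", 16, "A", 19, "C", 21, "A", 74),
                  key_start = 75),
  fail_dG  = list(win = mkwin("C", 40, "A", 16, "C", 20, "T", 21, "C", 73),
                  key_start = 76))

# brute-force alignment oracle: every placement with <= m substitutions,
# both strands, by direct string comparison at every offset
naive_align <- function(tag, ref_names, ref_seqs, m) {
  out <- list()
  L <- nchar(tag)
  for (r in seq_along(ref_seqs)) {
    G <- nchar(ref_seqs[r])
    if (G < L) next
    for (std in c("+", "-")) {
      q <- if (std == "+") tag else srnablocks::revcomp(tag)
      qs <- strsplit(q, NULL)[[1]]
      for (p in 0:(G - L)) {
        w <- strsplit(substr(ref_seqs[r], p + 1, p + L), NULL)[[1]]
        d <- sum(w != qs)
        if (d <= m)
          out[[length(out) + 1]] <- data.frame(
            tag_sequence = tag, chrom = ref_names[r], start = p, end = p + L,
            strand = std, mismatches = d, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(tag_sequence = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  do.call(rbind, out)
}

# O(n^2) transitive-closure interval merging oracle: returns a partition
# label per interval
brute_block_partition <- function(start, end, gap) {
  n <- length(start)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (lab[i] == lab[j]) next
      sep <- max(start[i], start[j]) - min(end[i], end[j])
      if (sep <= gap) {
        lab[lab == lab[j]] <- lab[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

# exhaustive fold oracle for tiny sequences: optimal total pair energy over
# all nested structures (min loop 3)
enum_fold_energy <- function(seq, e = c(gc = -3, au = -2, gu = -1),
                             min_loop = 3) {
  s <- strsplit(toupper(seq), NULL)[[1]]
  pe <- function(i, j) {
    p <- paste0(sort(c(s[i], s[j])), collapse = "")
    switch(p, "CG" = e[["gc"]], "AT" = e[["au"]], "GT" = e[["gu"]], 1)
  }
  n <- length(s)
  memo <- new.env()
  best <- function(i, j) {
    if (j - i <= min_loop) return(0)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- best(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      x <- pe(i, k)
      if (x >= 0) next
      left <- if (k > i + 1) best(i + 1, k - 1) else 0
      right <- if (k < j) best(k + 1, j) else 0
      v <- min(v, x + left + right)
    }
    memo[[key]] <- v
    v
  }
  best(1, n)
}

# a small cached end-to-end simulation shared by several test files
.fixture_env <- new.env()
small_sim_config <- function() {
  sim_config(seed = 11, genome_length = 120000, n_mirna_loci = 5,
             n_te_loci = 4, n_gene_sirna_loci = 3, n_decoy_trna = 5,
             n_decoy_rdna = 2,
             de_plan = data.frame(locus_id = c("mir01", "te01"),
                                  library_id = c("cot_fr", "hkcv_fr"),
                                  fold_change = c(4, 0.25)),
             library_design = default_library_design(depth_reads = 15000))
}
small_run <- function() {
  if (is.null(.fixture_env$run)) {
    cfg <- small_sim_config()
    sim <- generate_genome(cfg)
    reads <- simulate_libraries(sim)
    tags <- data.table::rbindlist(lapply(names(reads), function(l)
      preprocess_reads(reads[[l]], l)))
    triage <- hierarchical_filter(tags, sim$references)
    blocks <- build_blocks(triage$genome_hits, gap = 100)
    hits_b <- assign_blocks(triage$genome_hits, blocks)
    gtags <- merge(tags,
                   triage$categories[category == "genome_perfect", .(sequence)],
                   by = "sequence")
    .fixture_env$run <- list(cfg = cfg, sim = sim, reads = reads, tags = tags,
                             triage = triage, blocks = blocks, hits = hits_b,
                             gtags = gtags)
  }
  .fixture_env$run
}

random_tag <- function(n = 21) paste(sample(c("A", "C", "G", "T"), n,
                                            replace = TRUE), collapse = "")
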