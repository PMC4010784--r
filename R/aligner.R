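#' Build an alignment index over a reference sequence set
#'
#' The index is a lightweight handle (sequences plus seed length) consumed
#' by [align()]; seeding itself happens inside the C++ kernel via
#' pigeonhole chunking, which guarantees completeness for any substitution
#' budget.
#'
#' @param reference named character vector of reference sequences.
#' @param seed_length minimum exact seed length supported (informational;
#'   lookups remain exact for any query at least this long).
#' @return an object of class `srna_index`.
#' @export
build_index <- function(reference, seed_length = 10L) {
  if (length(reference) == 0 || all(!nzchar(reference)))
    stop("empty reference")
  if (is.null(names(reference)) || any(!nzchar(names(reference))))
    stop("reference sequences must be named")
  structure(list(names = names(reference),
                 seqs = toupper(unname(reference)),
                 seed_length = as.integer(seed_length)),
            class = "srna_index")
}

#' Exact placements of a seed on both strands
#'
#' @param index an `srna_index`.
#' @param seed query sequence.
#' @return hit `data.table` (0-based half-open, `strand`, `mismatches = 0`).
#' @export
seed_lookup <- function(index, seed) {
  align(data.table::data.table(sequence = seed), index, max_mismatch = 0L)
}

#' Align tags against an indexed reference with a mismatch budget
#'
#' Reports every placement with at most `max_mismatch` substitutions (no
#' indels) on either strand.  For minus-strand hits the reverse complement
#' of the reference interval equals the tag within the budget.
#'
#' @param tags tag `data.table` with a `sequence` column (or a character
#'   vector of sequences).
#' @param index an `srna_index` from [build_index()].
#' @param max_mismatch substitution budget, 0-3.
#' @return `data.table` with `tag_sequence, chrom, start, end, strand,
#'   mismatches` (0-based half-open).
#' @export
align <- function(tags, index, max_mismatch = 0L) {
  stopifnot(max_mismatch %in% 0:3)
  seqs <- if (is.character(tags)) tags else tags$sequence
  if (length(seqs) == 0)
    return(data.table::data.table(tag_sequence = character(0),
                                  chrom = character(0), start = integer(0),
                                  end = integer(0), strand = character(0),
                                  mismatches = integer(0)))
  df <- cpp_align_tags(index$names, index$seqs, seqs, as.integer(max_mismatch))
  hits <- data.table::as.data.table(df)
  hits[, tag_sequence := seqs[tag]]
  hits[, tag := NULL]
  data.table::setcolorder(hits, c("tag_sequence", "chrom", "start", "end",
                                  "strand", "mismatches"))
  data.table::setorder(hits, chrom, start, strand, tag_sequence)
  hits[]
}

#' Hierarchical alignment triage of tags
#'
#' Implements the cascade: (1) tRNA/rDNA decoys at up to 3 mismatches
#' (removed), (2) nuclear genome at 0 mismatches (`genome_perfect`, the only
#' category used downstream), (3) nuclear genome at a relaxed budget
#' (`genome_mismatch`, reported only), (4) chloroplast then (5)
#' mitochondrion, remainder `unmapped`.  Categories are mutually exclusive
#' and exhaustive over the input tags.
#'
#' @param tags tag `data.table` (may contain several libraries; triage is by
#'   unique sequence, abundances are tallied per library).
#' @param references named list with elements `trna`, `rdna`, `genome`,
#'   `chloroplast`, `mitochondrion` (named character vectors; `trna`/`rdna`
#'   and the plastids may be empty, `genome` must not be).
#' @param decoy_mismatch mismatch budget for the tRNA/rDNA stage.
#' @param relaxed_mismatch relaxed genome (and plastid) budget.
#' @return list of class `srna_triage`: `categories` (`data.table` of
#'   `sequence, category`), `summary` (per category x library abundance),
#'   `genome_hits` (perfect-match hit table joined with `placements`, the
#'   per-tag genome placement count).
#' @export
hierarchical_filter <- function(tags, references, decoy_mismatch = 3L,
                                relaxed_mismatch = 3L) {
  for (nm in c("trna", "rdna", "genome", "chloroplast", "mitochondrion"))
    if (!nm %in% names(references))
      stop("missing reference set for stage: ", nm)
  if (length(references$genome) == 0) stop("missing reference set for stage: genome")

  uniq <- unique(tags$sequence)
  category <- setNames(rep("unmapped", length(uniq)), uniq)
  remaining <- uniq

  decoys <- c(references$trna, references$rdna)
  if (length(decoys)) {
    idx <- build_index(decoys)
    hit <- align(remaining, idx, decoy_mismatch)
    hit_seq <- unique(hit$tag_sequence)
    category[hit_seq] <- "trna_rdna"
    remaining <- setdiff(remaining, hit_seq)
  }

  gidx <- build_index(references$genome)
  genome_hits <- align(remaining, gidx, 0L)
  perfect <- unique(genome_hits$tag_sequence)
  category[perfect] <- "genome_perfect"
  remaining <- setdiff(remaining, perfect)

  if (relaxed_mismatch > 0 && length(remaining)) {
    hit <- align(remaining, gidx, relaxed_mismatch)
    hs <- unique(hit$tag_sequence)
    category[hs] <- "genome_mismatch"
    remaining <- setdiff(remaining, hs)
  }

  for (stage in c("chloroplast", "mitochondrion")) {
    if (length(references[[stage]]) && length(remaining)) {
      idx <- build_index(references[[stage]])
      hit <- align(remaining, idx, relaxed_mismatch)
      hs <- unique(hit$tag_sequence)
      category[hs] <- stage
      remaining <- setdiff(remaining, hs)
    }
  }

  cats <- data.table::data.table(sequence = names(category),
                                 category = unname(category))
  tagged <- merge(tags, cats, by = "sequence")
  summary <- tagged[, .(reads = sum(abundance), tags = .N),
                    by = .(category, library_id)]
  summary[, fraction := reads / sum(reads), by = library_id]

  placements <- genome_hits[, .(placements = .N), by = tag_sequence]
  genome_hits <- merge(genome_hits, placements, by = "tag_sequence")
  data.table::setorder(genome_hits, chrom, start, strand)

  structure(list(categories = cats, summary = summary[],
                 genome_hits = genome_hits[]),
            class = "srna_triage")
}
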