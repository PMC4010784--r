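#' Build proximity-based small RNA blocks
#'
#' Merges pooled alignment intervals into strand-agnostic blocks: two hits
#' share a block iff they are connected by a chain of hits in which
#' consecutive intervals are separated by at most `gap` nt.  A block spans
#' the minimum start to maximum end of its members.
#'
#' @param hits hit `data.table` with `chrom, start, end` (0-based half-open).
#' @param gap maximum separation (nt) for two intervals to be merged.
#' @return `data.table` of blocks: `block_id, chrom, start, end`, disjoint
#'   and sorted within each chromosome.
#' @export
build_blocks <- function(hits, gap = 100L) {
  stopifnot(gap >= 0)
  if (nrow(hits) == 0)
    return(data.table::data.table(block_id = character(0), chrom = character(0),
                                  start = integer(0), end = integer(0)))
  iv <- unique(hits[, .(chrom, start, end)])
  data.table::setorder(iv, chrom, start, end)
  iv[, new_block := {
    prev_max <- shift(cummax(end), fill = -1L)
    start > prev_max + gap
  }, by = chrom]
  iv[, grp := cumsum(new_block), by = chrom]
  blocks <- iv[, .(start = min(start), end = max(end)), by = .(chrom, grp)]
  data.table::setorder(blocks, chrom, start)
  blocks[, block_id := sprintf("b%06d", .I)]
  blocks[, grp := NULL]
  data.table::setcolorder(blocks, c("block_id", "chrom", "start", "end"))
  blocks[]
}

#' Assign hits to their containing blocks
#'
#' @param hits hit `data.table`.
#' @param blocks block `data.table` from [build_blocks()] over the same (or
#'   a superset of the) hits.
#' @return `hits` with a `block_id` column appended.
#' @export
assign_blocks <- function(hits, blocks) {
  out <- data.table::copy(hits)
  out[, block_id := NA_character_]
  for (ch in unique(out$chrom)) {
    b <- blocks[chrom == ch]
    if (nrow(b) == 0) next
    idx <- findInterval(out[chrom == ch, start], b$start)
    ok <- idx >= 1 & idx <= nrow(b)
    bid <- ifelse(ok & out[chrom == ch, end] <= b$end[pmax(idx, 1)],
                  b$block_id[pmax(idx, 1)], NA_character_)
    out[chrom == ch, block_id := bid]
  }
  if (anyNA(out$block_id))
    stop("internal error: hit not contained in any block")
  out[]
}

#' Per-block, per-library weighted counts
#'
#' Each placement of a tag contributes `abundance / k` to its containing
#' block, where `k` is the tag's total number of genome-perfect placements,
#' preventing over-counting of repeat-mapping small RNAs.  The grand total
#' over blocks equals the total genome-perfect abundance (to numerical
#' tolerance).
#'
#' @param blocks block `data.table`.
#' @param hits genome-perfect hit `data.table` with a `placements` column
#'   (as produced by [hierarchical_filter()]).
#' @param tags tag `data.table` (`sequence, abundance, library_id`) for all
#'   libraries.
#' @return `data.table` with `block_id, library_id, weighted_count`,
#'   complete over all block x library combinations.
#' @export
weighted_counts <- function(blocks, hits, tags) {
  stopifnot("placements" %in% names(hits))
  h <- if (!"block_id" %in% names(hits)) assign_blocks(hits, blocks) else hits
  m <- merge(h[, .(sequence = tag_sequence, block_id, placements)],
             tags[, .(sequence, abundance, library_id)],
             by = "sequence", allow.cartesian = TRUE)
  counts <- m[, .(weighted_count = sum(abundance / placements)),
              by = .(block_id, library_id)]
  grid <- data.table::CJ(block_id = blocks$block_id,
                         library_id = unique(tags$library_id))
  counts <- merge(grid, counts, by = c("block_id", "library_id"), all.x = TRUE)
  counts[is.na(weighted_count), weighted_count := 0]
  data.table::setorder(counts, block_id, library_id)
  counts[]
}

#' Per-block strand/length expression breakdown
#'
#' Weighted abundance of each block stratified by strand and tag length,
#' summed over libraries; used by block classification.
#'
#' @inheritParams weighted_counts
#' @return `data.table` with `block_id, strand, length, weighted`.
#' @export
block_profiles <- function(blocks, hits, tags) {
  h <- if (!"block_id" %in% names(hits)) assign_blocks(hits, blocks) else hits
  ab <- tags[, .(abundance = sum(abundance)), by = sequence]
  m <- merge(h[, .(sequence = tag_sequence, block_id, strand, placements)],
             ab, by = "sequence")
  m[, .(weighted = sum(abundance / placements)),
    by = .(block_id, strand, length = nchar(sequence))]
}

#' Count matrix from long-format weighted counts
#'
#' @param counts output of [weighted_counts()].
#' @return numeric matrix, blocks x libraries.
#' @export
count_matrix <- function(counts) {
  wide <- data.table::dcast(counts, block_id ~ library_id,
                            value.var = "weighted_count", fill = 0)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$block_id
  m
}

#' Library size-class profile
#'
#' Per-length (17-36 nt) abundance shares of genome-mapped tags per library
#' and the 21:24 abundance ratio.
#'
#' @param tags genome-mapped tag `data.table` (`sequence, abundance,
#'   library_id`).
#' @return list with `per_length` (`library_id, length, abundance, share`)
#'   and `ratio` (`library_id, ratio_21_24`; `NA` when no 24-nt abundance).
#' @export
size_profile <- function(tags) {
  t2 <- tags[, .(abundance = sum(abundance)),
             by = .(library_id, length = nchar(sequence))]
  grid <- data.table::CJ(library_id = unique(tags$library_id), length = 17:36)
  t2 <- merge(grid, t2, by = c("library_id", "length"), all.x = TRUE)
  t2[is.na(abundance), abundance := 0]
  t2[, share := abundance / sum(abundance), by = library_id]
  ratio <- t2[, .(ratio_21_24 = {
    a21 <- sum(abundance[length == 21])
    a24 <- sum(abundance[length == 24])
    if (a24 == 0) NA_real_ else a21 / a24
  }), by = library_id]
  list(per_length = t2[], ratio = ratio[])
}
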