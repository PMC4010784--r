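#' Collapse raw reads to unique tags
#'
#' Reduces a read set to unique sequences with abundance counts.  Reads
#' containing characters outside ACGT (including N) are dropped; the number
#' dropped is recorded in the `dropped` attribute and reported via message.
#'
#' @param reads character vector of read sequences.
#' @param library_id identifier stored on the tag table.
#' @return `data.table` with columns `sequence, length, abundance,
#'   library_id`, ordered by decreasing abundance.
#' @export
collapse_reads <- function(reads, library_id = "lib1") {
  reads <- toupper(reads)
  keep <- is_acgt(reads) & nzchar(reads)
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " read(s) with non-ACGT characters dropped")
  dt <- data.table::data.table(sequence = reads[keep])
  tags <- if (nrow(dt)) dt[, .(abundance = .N), by = sequence] else
    data.table::data.table(sequence = character(0), abundance = integer(0))
  tags[, length := nchar(sequence)]
  tags[, library_id := library_id]
  data.table::setorder(tags, -abundance, sequence)
  data.table::setcolorder(tags, c("sequence", "length", "abundance", "library_id"))
  data.table::setattr(tags, "dropped", dropped)
  tags[]
}

#' Size-select tags
#'
#' Retains tags whose length lies in the closed interval
#' `[min_len, max_len]` (default 17-35 nt).
#'
#' @param tags tag `data.table` from [collapse_reads()].
#' @param min_len,max_len inclusive length bounds (nt).
#' @return filtered tag `data.table`.
#' @export
length_filter <- function(tags, min_len = 17L, max_len = 35L) {
  stopifnot(min_len <= max_len)
  tags[nchar(sequence) >= min_len & nchar(sequence) <= max_len]
}

#' Abundance-ranked single-mismatch error correction
#'
#' A frequency-clustering correction: tags are visited in increasing
#' abundance order and compared against strictly more abundant tags of the
#' same length; if a parent within `max_mismatch` substitutions exists, the
#' child's abundance is transferred to the parent and the child removed.
#' When several parents tie at the minimal distance the most abundant wins,
#' with lexicographic order breaking exact ties.  Passes are iterated to a
#' fixpoint; total abundance is conserved exactly.
#'
#' @param tags tag `data.table` (single library).
#' @param max_mismatch maximum substitutions between child and parent.
#' @return corrected tag `data.table`.
#' @export
error_correct <- function(tags, max_mismatch = 1L) {
  if (nrow(tags) == 0) return(tags)
  stopifnot(max_mismatch >= 0)
  lib <- tags$library_id[1]
  cur <- data.table::copy(tags[, .(sequence, abundance)])
  repeat {
    merged <- error_correct_pass(cur, max_mismatch)
    if (nrow(merged) == nrow(cur)) { cur <- merged; break }
    cur <- merged
  }
  cur[, length := nchar(sequence)]
  cur[, library_id := lib]
  data.table::setorder(cur, -abundance, sequence)
  data.table::setcolorder(cur, c("sequence", "length", "abundance", "library_id"))
  cur[]
}

# one greedy merge pass; children processed in increasing abundance order
error_correct_pass <- function(cur, max_mismatch) {
  pairs <- neighbour_pairs(cur$sequence, max_mismatch)
  if (nrow(pairs) == 0) return(cur)
  idx <- setNames(seq_len(nrow(cur)), cur$sequence)
  ord <- order(cur$abundance, cur$sequence) # increasing abundance
  ab2 <- cpp_correct_pass(cur$sequence, as.numeric(cur$abundance),
                          unname(idx[pairs$a]), unname(idx[pairs$b]),
                          pairs$d, ord)
  keep <- ab2 >= 0
  data.table::data.table(sequence = cur$sequence[keep],
                         abundance = as.integer(ab2[keep]))
}

# all unordered pairs of equal-length sequences within max_mismatch
# substitutions, found by exact-matching halves (pigeonhole) rather than an
# all-vs-all scan; returns both orientations (a -> b and b -> a) with the
# Hamming distance d >= 1.
neighbour_pairs <- function(seqs, max_mismatch = 1L) {
  empty <- data.table::data.table(a = character(0), b = character(0),
                                  d = integer(0))
  if (length(seqs) < 2) return(empty)
  dt <- data.table::data.table(seq = seqs, len = nchar(seqs))
  res <- list()
  npieces <- max_mismatch + 1L
  for (L in unique(dt$len)) {
    grp <- dt[len == L]
    if (nrow(grp) < 2) next
    bounds <- floor(seq(0, L, length.out = npieces + 1L))
    cand <- list()
    for (p in seq_len(npieces)) {
      piece <- data.table::data.table(
        seq = grp$seq, pk = substr(grp$seq, bounds[p] + 1L, bounds[p + 1L]))
      hit <- merge(piece, piece, by = "pk", allow.cartesian = TRUE,
                   suffixes = c(".a", ".b"))
      hit <- hit[seq.a < seq.b, .(a = seq.a, b = seq.b)]
      cand[[p]] <- hit
    }
    cand <- unique(data.table::rbindlist(cand))
    if (nrow(cand) == 0) next
    cand[, d := cpp_hamming(a, b)]
    cand <- cand[d >= 1L & d <= max_mismatch]
    res[[as.character(L)]] <- cand
  }
  out <- data.table::rbindlist(res)
  if (nrow(out) == 0) return(empty)
  rbind(out, out[, .(a = b, b = a, d)])
}

#' Full preprocessing: collapse, size-select, error-correct
#'
#' @param reads character vector of raw reads for one library.
#' @param library_id library identifier.
#' @param min_len,max_len size-selection bounds.
#' @param max_mismatch error-correction mismatch budget.
#' @return tag `data.table`.
#' @export
preprocess_reads <- function(reads, library_id = "lib1", min_len = 17L,
                             max_len = 35L, max_mismatch = 1L) {
  tags <- collapse_reads(reads, library_id)
  tags <- length_filter(tags, min_len, max_len)
  error_correct(tags, max_mismatch)
}
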