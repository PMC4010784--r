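#' Candidate loci for miRNA prediction
#'
#' One candidate per (tag, genome-perfect placement) for tags mapping to at
#' most `max_loci` genomic loci.  Tags of any length enter candidacy; final
#' calls are restricted to the 20-22 nt classes downstream.
#'
#' @param hits genome-perfect hit `data.table` with a `placements` column.
#' @param tags tag `data.table`; abundances are summed over libraries.
#' @param max_loci maximum number of genomic placements for a tag to enter.
#' @param min_abundance minimum summed abundance (reads) for a tag to enter;
#'   1 disables the floor.
#' @return candidate `data.table`: `sequence, chrom, start, end, strand,
#'   placements, abundance`.
#' @export
candidate_loci <- function(hits, tags, max_loci = 20L, min_abundance = 1L) {
  ab <- tags[, .(abundance = sum(abundance)), by = sequence]
  cand <- merge(hits[placements <= max_loci,
                     .(sequence = tag_sequence, chrom, start, end, strand,
                       placements)],
                ab, by = "sequence")
  cand <- cand[abundance >= min_abundance]
  data.table::setorder(cand, chrom, start, strand)
  cand[]
}

#' Extract the strand-specific folding window around a placement
#'
#' A window of exactly `length` nt centred on the placement midpoint, on the
#' placement's strand.  Windows truncated by a chromosome end are shifted
#' inward; chromosomes shorter than the window reject the candidate.
#'
#' @param genome named character vector of chromosome sequences.
#' @param placement list or single-row data.frame with `chrom, start, end,
#'   strand` (0-based half-open).
#' @param length window length (nt).
#' @return list with `sequence` (strand-oriented window), `chrom`, `start`,
#'   `end` (genomic, 0-based half-open), `strand` and `key_start` (0-based
#'   offset of the placement's 5' end within the window sequence), or `NULL`
#'   when the chromosome is shorter than the window.
#' @export
extract_window <- function(genome, placement, length = 170L) {
  chromseq <- unname(genome[placement$chrom])
  if (length(chromseq) != 1 || is.na(chromseq))
    stop("placement on unknown chromosome: ", placement$chrom)
  G <- nchar(chromseq)
  if (G < length) return(NULL)
  mid <- floor((placement$start + placement$end) / 2)
  w0 <- mid - floor(length / 2)
  w0 <- max(0L, min(w0, G - length))
  w1 <- w0 + length
  txt <- substr(chromseq, w0 + 1L, w1)
  if (placement$strand == "-") {
    txt <- revcomp(txt)
    key_start <- w1 - placement$end
  } else {
    key_start <- placement$start - w0
  }
  list(sequence = txt, chrom = placement$chrom, start = w0, end = w1,
       strand = placement$strand, key_start = as.integer(key_start))
}

#' Fold a window into a secondary structure
#'
#' The built-in baseline folder is a Nussinov-style dynamic program over
#' nested structures with a minimum hairpin loop of 3 and per-pair energies
#' GC = -3, AU = -2, GU = -1 kcal/mol, minimising total pair energy.  Its
#' energy scale is not thermodynamically calibrated; a thermodynamic folder
#' can be plugged in by passing a function `function(sequence)` returning
#' `list(structure=, delta_g=)`.
#'
#' @param window ACGT/ACGU window sequence.
#' @param backend `"baseline"` or a folding function.
#' @param temperature folding temperature in degrees C (accepted for
#'   interface compatibility; the baseline energies are
#'   temperature-independent).
#' @param min_loop minimum hairpin loop size (baseline).
#' @param energies named vector of pair energies for the baseline folder.
#' @return list with `structure` (dot-bracket), `delta_g` (kcal/mol) and
#'   `pairs` (0-based partner index per position, -1 = unpaired).
#' @export
fold <- function(window, backend = "baseline", temperature = 25,
                 min_loop = 3L, energies = c(gc = -3, au = -2, gu = -1)) {
  window <- toupper(chartr("Uu", "Tt", window))
  if (is.function(backend)) {
    r <- backend(window)
    return(list(structure = r$structure, delta_g = r$delta_g,
                pairs = parse_dot_bracket(r$structure)))
  }
  if (!identical(backend, "baseline"))
    stop("unknown fold backend: ", backend)
  r <- cpp_fold_nussinov(window, energies[["gc"]], energies[["au"]],
                         energies[["gu"]], as.integer(min_loop))
  list(structure = r$structure, delta_g = r$energy, pairs = r$pairs)
}

#' Parse dot-bracket notation into a partner vector
#'
#' @param structure dot-bracket string.
#' @return integer vector of 0-based partner indices (-1 = unpaired).
#' @export
parse_dot_bracket <- function(structure) {
  ch <- strsplit(structure, NULL)[[1]]
  partner <- rep(-1L, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j - 1L
      partner[j] <- i - 1L
    }
  }
  partner
}

#' Evaluate the hairpin goodness criteria on a folded window
#'
#' Criteria: (i) strictly more than `min_paired_fraction` of the key bases
#' are paired; (ii) the star span (minimum to maximum window positions
#' paired with key bases) is at most `max_star_ratio` times the key length;
#' (iii) key span and star span are separated by at least `min_separation`
#' bases, and no position within `end_margin` nt of the key ends pairs into
#' the star span; (dG) the folding energy is at most `dg_threshold`.
#'
#' @param structure dot-bracket structure of the window (or pass `pairs`).
#' @param delta_g folding energy, kcal/mol.
#' @param key_start 0-based offset of the key sequence in the window.
#' @param key_len key sequence length (nt).
#' @param pairs optional pre-parsed partner vector (0-based, -1 unpaired).
#' @param min_paired_fraction criterion (i) threshold (strict inequality).
#' @param max_star_ratio criterion (ii) multiplier on key length.
#' @param min_separation criterion (iii) minimum key/star distance (nt).
#' @param end_margin criterion (iii) exclusion margin around the key (nt).
#' @param dg_threshold energy gate, kcal/mol.
#' @return list with `paired_fraction, star_span_length, separation,
#'   criteria` (named logical vector `i, ii, iii, dG`) and `verdict`.
#' @export
evaluate_hairpin <- function(structure = NULL, delta_g, key_start, key_len,
                             pairs = NULL, min_paired_fraction = 0.75,
                             max_star_ratio = 1.5, min_separation = 20L,
                             end_margin = 10L, dg_threshold = -40) {
  if (is.null(pairs)) pairs <- parse_dot_bracket(structure)
  n <- length(pairs)
  k0 <- key_start; k1 <- key_start + key_len - 1L # inclusive, 0-based
  if (k0 < 0 || k1 >= n) stop("key span not inside window")
  kp <- pairs[(k0:k1) + 1L]
  partners <- kp[kp >= 0]
  paired_fraction <- length(partners) / key_len
  crit_i <- paired_fraction > min_paired_fraction

  if (length(partners) == 0) {
    crit <- c(i = crit_i, ii = FALSE, iii = FALSE,
              dG = delta_g <= dg_threshold)
    return(list(paired_fraction = paired_fraction,
                star_span_length = NA_integer_, separation = NA_integer_,
                criteria = crit, verdict = FALSE))
  }
  s0 <- min(partners); s1 <- max(partners)
  star_span <- s1 - s0 + 1L
  crit_ii <- star_span <= max_star_ratio * key_len

  separation <- if (s0 > k1) s0 - k1 - 1L
                else if (s1 < k0) k0 - s1 - 1L
                else -1L # spans overlap
  lo <- max(0L, k0 - end_margin); hi <- min(n - 1L, k1 + end_margin)
  near <- c(if (lo <= k0 - 1L) lo:(k0 - 1L),
            if (k1 + 1L <= hi) (k1 + 1L):hi)
  near_partners <- pairs[near + 1L]
  leak <- any(near_partners >= s0 & near_partners <= s1)
  crit_iii <- separation >= min_separation && !leak
  crit_dg <- delta_g <= dg_threshold

  crit <- c(i = crit_i, ii = crit_ii, iii = crit_iii, dG = crit_dg)
  list(paired_fraction = paired_fraction, star_span_length = star_span,
       separation = separation, criteria = crit, verdict = all(crit))
}

#' Remove candidates whose window overlaps annotated repeats
#'
#' Any overlap of at least 1 nt with a feature whose type is in
#' `repeat_types` removes the candidate.
#'
#' @param candidates `data.table` with window coordinates
#'   (`chrom, window_start, window_end`).
#' @param annotation feature `data.table` (0-based half-open).
#' @param repeat_types feature types treated as repeats.
#' @return filtered candidate `data.table`.
#' @export
repeat_filter <- function(candidates, annotation,
                          repeat_types = c("repeat_region",
                                           "transposable_element")) {
  if (nrow(candidates) == 0) return(candidates)
  rep_feats <- annotation[annotation$type %in% repeat_types, ]
  if (nrow(rep_feats) == 0) return(candidates)
  q <- GenomicRanges::GRanges(candidates$chrom,
                              IRanges::IRanges(candidates$window_start + 1L,
                                               candidates$window_end))
  s <- GenomicRanges::GRanges(rep_feats$chrom,
                              IRanges::IRanges(rep_feats$start + 1L,
                                               rep_feats$end))
  hits <- GenomicRanges::findOverlaps(q, s, minoverlap = 1L)
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop)) candidates[-drop] else candidates
}

#' Classify a predicted miRNA as known or novel
#'
#' Known iff some reference mature aligns to the key with at most
#' `max_mismatch` substitutions over the full shorter length and a length
#' difference of at most `max_len_diff` nt (ungapped sliding alignment).
#'
#' @param key key (mature candidate) sequence.
#' @param mature_reference_set named character vector of reference matures.
#' @param max_mismatch substitution allowance.
#' @param max_len_diff length-difference allowance (nt).
#' @return list with `status` (`"known"` or `"novel"`), `matched_reference_id`
#'   (or `NA`) and `mismatches` of the best match.
#' @export
classify_known_novel <- function(key, mature_reference_set, max_mismatch = 2L,
                                 max_len_diff = 2L) {
  if (length(mature_reference_set) == 0) {
    warning("empty mature reference set; all candidates are novel")
    return(list(status = "novel", matched_reference_id = NA_character_,
                mismatches = NA_integer_))
  }
  refs <- toupper(chartr("Uu", "Tt", mature_reference_set))
  best <- Inf; best_id <- NA_character_
  for (r in seq_along(refs)) {
    rs <- refs[[r]]
    if (abs(nchar(rs) - nchar(key)) > max_len_diff) next
    d <- min_sliding_mismatch(key, rs)
    if (d < best) { best <- d; best_id <- names(refs)[r] }
  }
  if (is.finite(best) && best <= max_mismatch)
    list(status = "known", matched_reference_id = best_id,
         mismatches = as.integer(best))
  else
    list(status = "novel", matched_reference_id = NA_character_,
         mismatches = if (is.finite(best)) as.integer(best) else NA_integer_)
}

# minimum Hamming distance of the shorter string over all full-overlap
# offsets within the longer string
min_sliding_mismatch <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  la <- nchar(a); lb <- nchar(b)
  offs <- 0:(lb - la)
  min(vapply(offs, function(o)
    cpp_hamming(a, substr(b, o + 1L, o + la)), integer(1)))
}

#' Discover miRNA loci from genome-perfect alignments
#'
#' Runs the full prediction pipeline: candidate selection by mapping
#' multiplicity, strand-specific window extraction, folding, hairpin
#' criteria, repeat screening and known/novel classification.  Final calls
#' are restricted to key sequences within `size_range`.
#'
#' @param genome named character vector of chromosome sequences.
#' @param hits genome-perfect hits with `placements`.
#' @param tags tag `data.table` (all libraries).
#' @param annotation feature `data.table` for repeat screening (may be
#'   empty).
#' @param mature_refs named character vector of known mature miRNAs (may be
#'   empty).
#' @param max_loci candidacy threshold on placement count.
#' @param min_abundance candidacy floor on summed tag abundance.
#' @param window_length folding window (nt).
#' @param backend,dg_threshold,temperature passed to [fold()] /
#'   [evaluate_hairpin()].
#' @param size_range inclusive key-length range for final calls.
#' @return list with `candidates` (all evaluated candidates with criteria
#'   flags) and `calls` (passing, repeat-screened, size-restricted calls
#'   with known/novel status).
#' @export
discover_mirnas <- function(genome, hits, tags, annotation = NULL,
                            mature_refs = character(0), max_loci = 20L,
                            min_abundance = 1L, window_length = 170L,
                            backend = "baseline", dg_threshold = -40,
                            temperature = 25, size_range = c(20L, 22L)) {
  cand <- candidate_loci(hits, tags, max_loci, min_abundance)
  empty <- data.table::data.table(
    sequence = character(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), placements = integer(0),
    abundance = integer(0), window_start = integer(0),
    window_end = integer(0), structure = character(0), delta_g = numeric(0),
    paired_fraction = numeric(0), star_span_length = integer(0),
    separation = integer(0), crit_i = logical(0), crit_ii = logical(0),
    crit_iii = logical(0), crit_dg = logical(0), verdict = logical(0))
  if (nrow(cand) == 0)
    return(list(candidates = empty,
                calls = data.table::copy(empty)[, `:=`(
                  status = character(0),
                  matched_reference_id = character(0))]))
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    pl <- as.list(cand[i])
    win <- extract_window(genome, pl, window_length)
    if (is.null(win)) next
    fr <- fold(win$sequence, backend = backend, temperature = temperature)
    ev <- evaluate_hairpin(delta_g = fr$delta_g, key_start = win$key_start,
                           key_len = nchar(pl$sequence), pairs = fr$pairs,
                           dg_threshold = dg_threshold)
    rows[[i]] <- data.table::data.table(
      sequence = pl$sequence, chrom = pl$chrom, start = pl$start,
      end = pl$end, strand = pl$strand, placements = pl$placements,
      abundance = pl$abundance, window_start = win$start,
      window_end = win$end, structure = fr$structure, delta_g = fr$delta_g,
      paired_fraction = ev$paired_fraction,
      star_span_length = ev$star_span_length, separation = ev$separation,
      crit_i = ev$criteria[["i"]], crit_ii = ev$criteria[["ii"]],
      crit_iii = ev$criteria[["iii"]], crit_dg = ev$criteria[["dG"]],
      verdict = ev$verdict)
  }
  candidates <- data.table::rbindlist(rows)
  if (nrow(candidates) == 0) candidates <- empty
  calls <- candidates[verdict == TRUE]
  if (!is.null(annotation) && nrow(calls))
    calls <- repeat_filter(calls, annotation)
  calls <- calls[nchar(sequence) >= size_range[1] &
                   nchar(sequence) <= size_range[2]]
  if (nrow(calls)) {
    kn <- lapply(calls$sequence, function(s)
      suppressWarnings(classify_known_novel(s, mature_refs)))
    calls[, status := vapply(kn, `[[`, character(1), "status")]
    calls[, matched_reference_id :=
              vapply(kn, `[[`, character(1), "matched_reference_id")]
  } else {
    calls[, `:=`(status = character(0), matched_reference_id = character(0))]
  }
  list(candidates = candidates, calls = calls[])
}
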