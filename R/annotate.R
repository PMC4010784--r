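#' Key sequence of a block
#'
#' The member tag with maximal abundance summed across libraries; exact
#' ties are broken by the lexicographically smallest sequence, making the
#' choice invariant to library and insertion order.
#'
#' @param members `data.table` with `sequence, abundance` (abundances may
#'   repeat across libraries; they are summed).
#' @return list with `sequence` and `abundance` of the key tag.
#' @export
key_sequence <- function(members) {
  if (nrow(members) == 0) stop("empty block")
  tot <- members[, .(abundance = sum(abundance)), by = sequence]
  data.table::setorder(tot, -abundance, sequence)
  list(sequence = tot$sequence[1], abundance = tot$abundance[1])
}

#' Size distribution of a block
#'
#' Weighted-abundance fractions of the block total for read lengths
#' 20-24 nt (other lengths count toward the total but are not broken out),
#' plus the dominant length over all members.
#'
#' @param profile per-block strand/length profile rows (from
#'   [block_profiles()]) for one block.
#' @return list with `histogram` (named fractions "20".."24") and
#'   `dominant` (length with maximal weighted abundance).
#' @export
block_size_distribution <- function(profile) {
  total <- sum(profile$weighted)
  by_len <- profile[, .(w = sum(weighted)), by = length]
  hist <- setNames(numeric(5), as.character(20:24))
  for (L in 20:24) {
    w <- by_len[length == L, w]
    hist[as.character(L)] <- if (length(w)) w / total else 0
  }
  dominant <- by_len$length[which.max(by_len$w)]
  list(histogram = hist, dominant = as.integer(dominant))
}

#' Similarity search of a key sequence against known matures
#'
#' Best local-alignment (Smith-Waterman; match +5, mismatch -4, gap -10)
#' score over the reference set, with an empirical p-value from
#' mononucleotide shuffles of the query: the add-one estimator
#' `(1 + #{shuffle score >= observed}) / (n_shuffles + 1)`.
#'
#' @param query key sequence.
#' @param reference_set named character vector of mature sequences.
#' @param n_shuffles number of query shuffles.
#' @param seed RNG seed for the shuffles.
#' @param match,mismatch,gap alignment scores.
#' @return list with `best_id`, `best_score`, `p` (empirical), and
#'   `significant` (`p < 0.01`).
#' @export
mature_similarity_search <- function(query, reference_set, n_shuffles = 1000L,
                                     seed = 1L, match = 5, mismatch = -4,
                                     gap = -10) {
  if (length(reference_set) == 0)
    return(list(best_id = NA_character_, best_score = 0, p = 1,
                significant = FALSE))
  refs <- toupper(chartr("Uu", "Tt", reference_set))
  ab <- cpp_sw_argbest(query, unname(refs), match, mismatch, gap)
  best_id <- names(refs)[ab[1]]; best <- ab[2]
  set.seed(seed)
  qs <- strsplit(query, NULL)[[1]]
  shuf <- vapply(seq_len(n_shuffles), function(i)
    paste(sample(qs), collapse = ""), character(1))
  ss <- cpp_sw_best(shuf, unname(refs), match, mismatch, gap)
  p <- (1 + sum(ss >= best)) / (n_shuffles + 1)
  list(best_id = best_id, best_score = best, p = p, significant = p < 0.01)
}

#' Final class of a block
#'
#' miRNA-like iff the dominant size class is 20-22 nt, the strand bias is
#' at least `strand_bias_min` and the key-sequence hairpin passes; otherwise
#' siRNA-TE iff at least `overlap_min` of the block abundance overlaps TE
#' features (TE takes precedence), else siRNA-gene by the same rule on gene
#' features, else unclassified.
#'
#' @param dominant dominant read length (nt).
#' @param strand_bias majority-strand abundance fraction (0.5-1).
#' @param hairpin_pass logical hairpin verdict for the key sequence.
#' @param te_frac,gene_frac fractions of block abundance overlapping TE /
#'   gene annotation.
#' @param strand_bias_min,overlap_min classification thresholds.
#' @return one of `"mirna_like", "sirna_te", "sirna_gene", "unclassified"`.
#' @export
classify_block <- function(dominant, strand_bias, hairpin_pass, te_frac,
                           gene_frac, strand_bias_min = 0.9,
                           overlap_min = 0.5) {
  if (dominant %in% 20:22 && strand_bias >= strand_bias_min &&
      isTRUE(hairpin_pass)) return("mirna_like")
  if (te_frac >= overlap_min) return("sirna_te")
  if (gene_frac >= overlap_min) return("sirna_gene")
  "unclassified"
}

#' Annotate blocks
#'
#' For each requested block: key sequence, 20-24 nt size histogram, strand
#' bias, hairpin evaluation of the key sequence's most 5' placement in the
#' block, similarity search against known matures, annotation overlap
#' fractions and the final class.
#'
#' @param block_ids blocks to annotate (default: all).
#' @param blocks,hits,tags as in [weighted_counts()]; `hits` are
#'   genome-perfect hits with `placements`.
#' @param genome named chromosome sequence vector.
#' @param annotation feature `data.table` (needs `gene` and
#'   `transposable_element` types for overlap classes); required.
#' @param mature_refs named character vector of known matures (may be
#'   empty).
#' @param window_length,backend,dg_threshold hairpin evaluation parameters.
#' @param n_shuffles,seed empirical p-value parameters.
#' @param strand_bias_min,overlap_min classification thresholds.
#' @return `data.table`, one row per block, with all annotation fields.
#' @export
annotate_blocks <- function(blocks, hits, tags, genome, annotation,
                            mature_refs = character(0), block_ids = NULL,
                            window_length = 170L, backend = "baseline",
                            dg_threshold = -40, n_shuffles = 1000L,
                            seed = 1L, strand_bias_min = 0.9,
                            overlap_min = 0.5) {
  if (is.null(annotation)) stop("annotation is required for classification")
  h <- if (!"block_id" %in% names(hits)) assign_blocks(hits, blocks) else hits
  if (is.null(block_ids)) block_ids <- blocks$block_id
  prof_all <- block_profiles(blocks, h, tags)
  ab <- tags[, .(abundance = sum(abundance)), by = sequence]

  # abundance-weighted overlap of each placement with gene/TE features
  h2 <- merge(h, ab, by.x = "tag_sequence", by.y = "sequence")
  h2[, weight := abundance / placements]
  hg <- GenomicRanges::GRanges(h2$chrom, IRanges::IRanges(h2$start + 1L, h2$end))
  ov_frac <- function(types) {
    feats <- annotation[annotation$type %in% types, ]
    hit_any <- rep(FALSE, nrow(h2))
    if (nrow(feats)) {
      fg <- GenomicRanges::GRanges(feats$chrom,
                                   IRanges::IRanges(feats$start + 1L, feats$end))
      ov <- GenomicRanges::findOverlaps(hg, fg, minoverlap = 1L)
      hit_any[unique(S4Vectors::queryHits(ov))] <- TRUE
    }
    hit_any
  }
  h2[, in_te := ov_frac("transposable_element")]
  h2[, in_gene := ov_frac("gene")]
  ovl <- h2[, .(total = sum(weight), te = sum(weight[in_te]),
                gene = sum(weight[in_gene])), by = block_id]

  rows <- vector("list", length(block_ids))
  for (i in seq_along(block_ids)) {
    bid <- block_ids[i]
    mem <- h2[block_id == bid]
    if (nrow(mem) == 0) next
    ks <- key_sequence(unique(mem[, .(sequence = tag_sequence, abundance)]))
    sd <- block_size_distribution(prof_all[block_id == bid])
    sb <- mem[, .(w = sum(weight)), by = strand]
    strand_bias <- max(sb$w) / sum(sb$w)

    kp <- mem[tag_sequence == ks$sequence][order(start)][1]
    win <- extract_window(genome, as.list(kp), window_length)
    hairpin_pass <- FALSE
    if (!is.null(win)) {
      fr <- fold(win$sequence, backend = backend)
      ev <- evaluate_hairpin(delta_g = fr$delta_g, key_start = win$key_start,
                             key_len = nchar(ks$sequence), pairs = fr$pairs,
                             dg_threshold = dg_threshold)
      hairpin_pass <- ev$verdict
    }
    ms <- mature_similarity_search(ks$sequence, mature_refs, n_shuffles,
                                   seed = derive_seed(seed, bid))
    o <- ovl[block_id == bid]
    te_frac <- if (nrow(o)) o$te / o$total else 0
    gene_frac <- if (nrow(o)) o$gene / o$total else 0
    overlap_class <- if (te_frac >= overlap_min) "TE"
                     else if (gene_frac >= overlap_min) "gene" else "none"
    rows[[i]] <- data.table::data.table(
      block_id = bid, key_sequence = ks$sequence,
      key_abundance = ks$abundance,
      frac_20 = sd$histogram[["20"]], frac_21 = sd$histogram[["21"]],
      frac_22 = sd$histogram[["22"]], frac_23 = sd$histogram[["23"]],
      frac_24 = sd$histogram[["24"]], dominant_length = sd$dominant,
      strand_bias = strand_bias, hairpin_verdict = hairpin_pass,
      best_mature_id = ms$best_id, mature_p = ms$p,
      mature_significant = ms$significant,
      te_frac = te_frac, gene_frac = gene_frac,
      overlap_class = overlap_class,
      final_class = classify_block(sd$dominant, strand_bias, hairpin_pass,
                                   te_frac, gene_frac, strand_bias_min,
                                   overlap_min))
  }
  data.table::rbindlist(rows)
}
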