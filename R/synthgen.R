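#' Construct a miRNA precursor hairpin
#'
#' Builds `mature + loop + star`, where the star arm is the reverse
#' complement of the mature sequence with point substitutions introduced so
#' that at least `pairing_fraction` of the mature bases can still pair.  By
#' construction the star arm has the same length as the mature (well under
#' the 1.5x limit) and mature/star are separated by exactly `loop_length`
#' bases, so a clean fold satisfies all hairpin goodness criteria.
#'
#' @param mature mature miRNA sequence, 20-22 nt.
#' @param pairing_fraction minimum fraction of mature bases able to pair;
#'   must be strictly greater than 0.75.
#' @param loop_length bases between mature and star arm; at least 20.
#' @return the precursor sequence (mature at the 5' end).
#' @export
plant_hairpin <- function(mature, pairing_fraction = 0.9, loop_length = 30L) {
  L <- nchar(mature)
  if (L < 20 || L > 22) stop("mature must be 20-22 nt")
  if (!is_acgt(mature)) stop("mature must be ACGT only")
  if (pairing_fraction <= 0.75)
    stop("pairing_fraction must exceed 0.75 (criterion on paired bases)")
  if (loop_length < 20) stop("loop_length must be at least 20 bases")
  star <- strsplit(revcomp(mature), NULL)[[1]]
  n_mut <- floor((1 - pairing_fraction) * L)
  if (n_mut > 0) {
    pos <- sample(seq_len(L), n_mut)
    for (p in pos) star[p] <- sample(setdiff(c("A", "C", "G", "T"), star[p]), 1)
  }
  loop <- random_dna(loop_length)
  paste0(mature, loop, paste(star, collapse = ""))
}

mature_length_probs <- c(`20` = 0.1, `21` = 0.7, `22` = 0.2)

# P(read length == 21 | miRNA locus) under the 80/10/10 isomiR model,
# given the planted mature length.
q21_for_mature <- function(len) c(`20` = 0.2, `21` = 0.8, `22` = 0.2)[as.character(len)]
Q24_SIRNA <- 0.75 # P(read length == 24 | siRNA locus); remainder is 23 nt

#' Generate a synthetic genome, annotation and ground truth
#'
#' Lays out planted miRNA hairpin loci, TE siRNA clusters and
#' gene-overlapping siRNA clusters on a uniform-background chromosome,
#' plus tRNA/rDNA decoy references and plastid contigs.  Every planted
#' hairpin window is verified against [evaluate_hairpin()] with the baseline
#' folder before the genome is accepted (failing hairpins are re-drawn).
#'
#' @param config a [sim_config()] object.
#' @return a list of class `srna_sim` with elements `references` (named list
#'   of named sequence vectors: `genome, trna, rdna, chloroplast,
#'   mitochondrion`), `annotation` (feature `data.table`, 0-based half-open),
#'   `truth` (locus `data.table` with per-library expected abundances) and
#'   `config`.
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "genome"))
  chrom <- "Chr1"

  n_mir <- config$n_mirna_loci
  n_te <- config$n_te_loci
  n_gsi <- config$n_gene_sirna_loci
  mature_len <- if (n_mir)
    as.integer(sample(names(mature_length_probs), n_mir, replace = TRUE,
                      prob = mature_length_probs)) else integer(0)
  loop_len <- 30L
  lens <- c(mature_len * 2L + loop_len,
            if (n_te) sample(1000:3000, n_te, replace = TRUE) else integer(0),
            if (n_gsi) sample(400:800, n_gsi, replace = TRUE) else integer(0))
  classes <- c(rep("mirna", n_mir), rep("sirna_te", n_te),
               rep("sirna_gene", n_gsi))
  ids <- c(sprintf("mir%02d", seq_len(n_mir)),
           sprintf("te%02d", seq_len(n_te)),
           sprintf("gsi%02d", seq_len(n_gsi)))[seq_along(lens)]
  n_loci <- length(lens)

  spacing <- config$min_locus_spacing
  # hairpin windows (170 nt) must stay on-chromosome: generous end margins
  margin <- spacing + 200L
  need <- sum(lens) + spacing * max(n_loci - 1L, 0L) + 2L * margin
  if (need > config$genome_length)
    stop("genome_length too small to host all loci at the required spacing (",
         need, " nt needed)")

  genome <- random_dna(config$genome_length, config$gc)

  truth <- data.table::data.table(
    locus_id = character(0), class = character(0), chrom = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    mature_sequence = character(0))
  if (n_loci > 0) {
    ord <- sample(n_loci)
    lens_o <- lens[ord]
    free <- config$genome_length - need
    extra <- if (n_loci >= 1) as.vector(rmultinom(1, free, rep(1, n_loci + 1L)))
    gaps <- c(margin + extra[1L],
              rep(spacing, max(n_loci - 1L, 0L)) + extra[seq_len(n_loci - 1L) + 1L])
    starts <- cumsum(gaps) + cumsum(c(0L, lens_o[-n_loci]))
    strands <- sample(c("+", "-"), n_loci, replace = TRUE)
    truth <- data.table::data.table(
      locus_id = ids[ord], class = classes[ord], chrom = chrom,
      start = as.integer(starts), end = as.integer(starts + lens_o),
      strand = strands, mature_sequence = NA_character_)
    data.table::setorder(truth, start)
  }

  # plant hairpins, verifying each against the baseline folder
  mat_of <- setNames(mature_len, sprintf("mir%02d", seq_len(n_mir)))
  for (i in which(truth$class == "mirna")) {
    L <- mat_of[[truth$locus_id[i]]]
    s <- truth$start[i]; e <- truth$end[i]; std <- truth$strand[i]
    ok <- FALSE
    for (attempt in 1:50) {
      mature <- random_dna(L, 0.5)
      pre <- plant_hairpin(mature, pairing_fraction = 0.9, loop_length = loop_len)
      ins <- if (std == "+") pre else revcomp(pre)
      genome <- paste0(substr(genome, 1, s), ins,
                       substr(genome, e + 1, nchar(genome)))
      # mature occupies the 5' arm of the precursor on the locus strand
      if (std == "+") { ms <- s; me <- s + L } else { ms <- e - L; me <- e }
      win <- extract_window(setNames(genome, chrom),
                            list(chrom = chrom, start = ms, end = me,
                                 strand = std))
      if (!is.null(win)) {
        fr <- fold(win$sequence, backend = "baseline")
        ev <- evaluate_hairpin(structure = fr$structure, delta_g = fr$delta_g,
                               key_start = win$key_start, key_len = L)
        if (ev$verdict) {
          truth$mature_sequence[i] <- mature
          ok <- TRUE
          break
        }
      }
    }
    if (!ok) stop("failed to plant a valid hairpin at locus ", truth$locus_id[i])
  }

  # decoys and plastids
  ref_set <- function(prefix, n, len_lo, len_hi) {
    if (n == 0) return(setNames(character(0), character(0)))
    lens <- sample(len_lo:len_hi, n, replace = TRUE)
    setNames(vapply(lens, random_dna, character(1), gc = config$gc),
             sprintf("%s%02d", prefix, seq_len(n)))
  }
  trna <- ref_set("trna", config$n_decoy_trna, 70, 90)
  rdna <- ref_set("rdna", config$n_decoy_rdna, 1000, 3000)
  n_chl <- ceiling(config$n_plastid_contigs / 2)
  n_mit <- floor(config$n_plastid_contigs / 2)
  chlo <- ref_set("chloroplast", n_chl, 15000, 20000)
  mito <- ref_set("mitochondrion", n_mit, 15000, 20000)

  decoy_truth <- data.table::rbindlist(list(
    data.table::data.table(locus_id = names(trna), class = "trna",
                           chrom = names(trna), start = 0L,
                           end = nchar(unname(trna))),
    data.table::data.table(locus_id = names(rdna), class = "rdna",
                           chrom = names(rdna), start = 0L,
                           end = nchar(unname(rdna))),
    data.table::data.table(locus_id = names(chlo), class = "plastid",
                           chrom = names(chlo), start = 0L,
                           end = nchar(unname(chlo))),
    data.table::data.table(locus_id = names(mito), class = "plastid",
                           chrom = names(mito), start = 0L,
                           end = nchar(unname(mito)))))
  if (nrow(decoy_truth)) {
    decoy_truth[, `:=`(strand = "+", mature_sequence = NA_character_)]
    truth <- data.table::rbindlist(list(truth, decoy_truth), use.names = TRUE)
  }

  # baseline abundance weights (heavy-tailed, one draw per locus)
  truth[, weight := rlnorm(.N, meanlog = config$abundance_lognormal_mu,
                           sdlog = config$abundance_lognormal_sigma)]
  # planted-DE loci are pinned at the median weight: fold boosts stay
  # feasible regardless of the heavy lognormal tail and the planted
  # expression level (hence RPM) is controlled
  if (!is.null(config$de_plan) && nrow(config$de_plan))
    truth[locus_id %in% config$de_plan$locus_id,
          weight := exp(config$abundance_lognormal_mu)]

  # annotation: genes over gene-siRNA loci, TEs (+ repeat track) over TE loci
  ann <- truth[class %in% c("sirna_te", "sirna_gene"),
               .(chrom, start, end, strand, locus_id, class)]
  annotation <- data.table::rbindlist(list(
    ann[class == "sirna_gene",
        .(chrom, start, end, strand, type = "gene", ID = paste0("gene_", locus_id))],
    ann[class == "sirna_te",
        .(chrom, start, end, strand, type = "transposable_element",
          ID = paste0("TE_", locus_id))],
    ann[class == "sirna_te",
        .(chrom, start, end, strand, type = "repeat_region",
          ID = paste0("rep_", locus_id))]))

  sim <- list(references = list(genome = setNames(genome, chrom), trna = trna,
                                rdna = rdna, chloroplast = chlo,
                                mitochondrion = mito),
              annotation = annotation, truth = truth, config = config)
  class(sim) <- "srna_sim"

  # expected per-library abundances under the mixture model
  mix <- library_mix(truth, config)
  for (lib in colnames(mix))
    truth[, (paste0("expected_", lib)) :=
              mix[, lib] * config$library_design$depth_reads[
                config$library_design$library_id == lib]]
  sim$truth <- truth

  # planted loci must never coalesce under the default block gap
  gt <- truth[chrom == "Chr1"][order(start)]
  if (nrow(gt) > 1 && any(gt$start[-1] - gt$end[-nrow(gt)] <= 100))
    stop("internal error: planted loci closer than the default block gap")
  sim
}

# Per-library sampling probabilities over truth loci.  Columns sum to
# (1 - junk_fraction).  miRNA-class weights are tilted per library to meet
# the configured 21:24 target ratio; planted fold changes are applied so
# the DE locus' expected proportion is scaled exactly (the remaining
# genomic loci absorb the renormalisation).
library_mix <- function(truth, config) {
  ld <- config$library_design
  mix <- matrix(0, nrow = nrow(truth), ncol = nrow(ld),
                dimnames = list(truth$locus_id, ld$library_id))
  genome_idx <- truth$class %in% c("mirna", "sirna_te", "sirna_gene")
  decoy_idx <- truth$class %in% c("trna", "rdna")
  plast_idx <- truth$class == "plastid"
  for (k in seq_len(nrow(ld))) {
    lib <- ld$library_id[k]; tissue <- ld$tissue_label[k]
    dfrac <- config$decoy_fraction
    d <- if (length(dfrac) > 1 || !is.null(names(dfrac)))
      unname(dfrac[tissue] %||% mean(dfrac)) else dfrac
    if (is.na(d)) d <- mean(config$decoy_fraction)
    p <- if (any(plast_idx)) config$plastid_fraction else 0
    if (!any(decoy_idx)) d <- 0
    g <- 1 - d - p - config$junk_fraction

    w <- truth$weight
    # tilt miRNA loci toward the per-library 21:24 target
    r <- config$ratio_21_24
    target <- if (is.null(r)) NA_real_ else
      if (!is.null(names(r))) unname(r[lib]) else r
    mir <- genome_idx & truth$class == "mirna"
    sir <- genome_idx & truth$class != "mirna"
    if (!is.na(target) && any(mir) && any(sir)) {
      q21 <- q21_for_mature(nchar(truth$mature_sequence[mir]))
      s21 <- sum(w[mir] * q21)
      s24 <- sum(w[sir]) * Q24_SIRNA
      if (s21 > 0) w[mir] <- w[mir] * target * s24 / s21
    }
    pr <- numeric(nrow(truth))
    if (any(genome_idx)) pr[genome_idx] <- g * w[genome_idx] / sum(w[genome_idx])
    if (any(decoy_idx)) pr[decoy_idx] <- d * w[decoy_idx] / sum(w[decoy_idx])
    if (any(plast_idx)) pr[plast_idx] <- p * w[plast_idx] / sum(w[plast_idx])

    dp <- config$de_plan
    if (!is.null(dp) && nrow(dp)) {
      dpk <- dp[dp$library_id == lib, , drop = FALSE]
      if (nrow(dpk)) {
        de_i <- match(dpk$locus_id, truth$locus_id)
        if (anyNA(de_i)) stop("de_plan references unknown locus")
        before <- sum(pr[de_i])
        pr[de_i] <- pr[de_i] * dpk$fold_change
        after <- sum(pr[de_i])
        rest <- setdiff(which(genome_idx), de_i)
        if (g - after < 0) stop("fold changes exceed the genome read share")
        pr[rest] <- pr[rest] * (g - after) / (g - before)
      }
    }
    mix[, k] <- pr
  }
  mix
}

#' Sample per-locus read counts without emitting read sequences
#'
#' Draws multinomial locus counts from the same mixture model that
#' [simulate_libraries()] uses, skipping read-string synthesis.  Useful for
#' replicated statistical experiments (e.g. type-I-error studies) where only
#' counts matter.
#'
#' @param sim an `srna_sim` object.
#' @param seed seed for this draw.
#' @return `data.table` with `locus_id, class` and one count column per
#'   library (junk reads are reported as locus `_junk`).
#' @export
simulate_locus_counts <- function(sim, seed = sim$config$seed) {
  config <- sim$config
  mix <- library_mix(sim$truth, config)
  out <- data.table::data.table(locus_id = c(rownames(mix), "_junk"),
                                class = c(sim$truth$class, "junk"))
  for (k in seq_len(nrow(config$library_design))) {
    lib <- config$library_design$library_id[k]
    depth <- config$library_design$depth_reads[k]
    set.seed(derive_seed(seed, paste0("counts_", lib)))
    pr <- c(mix[, lib], max(1 - sum(mix[, lib]), 0))
    out[, (lib) := as.vector(rmultinom(1, depth, pr))]
  }
  out
}

#' Simulate sequencing libraries from a planted genome
#'
#' Emits adapter-free reads per library: miRNA loci produce the mature
#' sequence with 3' isomiR jitter (80% exact, 10% each one base shorter or
#' longer where the 20-22 nt range allows), siRNA loci produce 23-24 nt
#' reads uniformly over both strands, decoy and plastid references produce
#' sense fragments, and a junk component produces unmappable random reads.
#' Per-base substitution errors are applied at `config$error_rate`.  Read
#' counts per library equal `depth_reads` exactly.
#'
#' @param sim an `srna_sim` object from [generate_genome()].
#' @param config simulation config; defaults to the one inside `sim`.
#' @return named list (per library) of character vectors of read sequences.
#' @export
simulate_libraries <- function(sim, config = sim$config) {
  truth <- sim$truth
  if (nrow(truth) == 0) stop("empty truth table")
  mix <- library_mix(truth, config)
  seqs <- c(sim$references$genome, sim$references$trna, sim$references$rdna,
            sim$references$chloroplast, sim$references$mitochondrion)
  out <- list()
  for (k in seq_len(nrow(config$library_design))) {
    lib <- config$library_design$library_id[k]
    depth <- config$library_design$depth_reads[k]
    set.seed(derive_seed(config$seed, paste0("lib_", lib)))
    pr <- c(mix[, lib], max(1 - sum(mix[, lib]), 0))
    counts <- as.vector(rmultinom(1, depth, pr))
    reads_parts <- vector("list", nrow(truth) + 1L)
    for (i in seq_len(nrow(truth))) {
      n <- counts[i]
      if (n == 0) next
      reads_parts[[i]] <- emit_locus_reads(truth[i], n, seqs)
    }
    nj <- counts[nrow(truth) + 1L]
    if (nj > 0) {
      jl <- sample(17:35, nj, replace = TRUE)
      reads_parts[[nrow(truth) + 1L]] <-
        vapply(jl, random_dna, character(1), gc = config$gc)
    }
    reads <- unlist(reads_parts, use.names = FALSE)
    reads <- apply_seq_errors(reads, config$error_rate)
    out[[lib]] <- sample(reads) # shuffle read order
  }
  out
}

# substring extraction honouring strand (0-based half-open coords)
extract_reads <- function(refseq, starts, lens, strands) {
  txt <- substring(refseq, starts + 1L, starts + lens)
  neg <- strands == "-"
  if (any(neg)) txt[neg] <- revcomp(txt[neg])
  txt
}

emit_locus_reads <- function(locus, n, seqs) {
  refseq <- seqs[[locus$chrom]]
  if (locus$class == "mirna") {
    L <- nchar(locus$mature_sequence)
    kinds <- if (L == 21) sample(c("e", "m", "p"), n, replace = TRUE,
                                 prob = c(0.8, 0.1, 0.1))
             else if (L == 22) sample(c("e", "m"), n, replace = TRUE,
                                      prob = c(0.8, 0.2))
             else sample(c("e", "p"), n, replace = TRUE, prob = c(0.8, 0.2))
    lens <- L + (kinds == "p") - (kinds == "m")
    if (locus$strand == "+") {
      starts <- rep(locus$start, n)
    } else {
      starts <- locus$end - lens # 3' jitter extends toward lower coords on -
    }
    extract_reads(refseq, starts, lens, rep(locus$strand, n))
  } else if (locus$class %in% c("sirna_te", "sirna_gene")) {
    lens <- sample(c(23L, 24L), n, replace = TRUE, prob = c(1 - Q24_SIRNA, Q24_SIRNA))
    starts <- locus$start +
      floor(runif(n) * (locus$end - locus$start - lens + 1L))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    extract_reads(refseq, starts, lens, strands)
  } else { # trna / rdna / plastid sense fragments
    reflen <- nchar(refseq)
    lens <- pmin(sample(17:28, n, replace = TRUE), reflen)
    starts <- floor(runif(n) * (reflen - lens + 1L))
    extract_reads(refseq, starts, lens, rep("+", n))
  }
}

apply_seq_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  nerr <- rbinom(length(reads), nchar(reads), rate)
  for (i in which(nerr > 0)) {
    s <- strsplit(reads[i], NULL)[[1]]
    pos <- sample(length(s), min(nerr[i], length(s)))
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    reads[i] <- paste(s, collapse = "")
  }
  reads
}

#' Write a simulation to disk
#'
#' Emits `genome.fa`, decoy/plastid FASTAs, `annotation.gff3`,
#' `reads_<library>.fastq` and `truth.tsv` under `out_dir`.
#'
#' @param sim an `srna_sim` object.
#' @param reads per-library read list from [simulate_libraries()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, reads, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$references$genome, file.path(out_dir, "genome.fa"))
  for (nm in c("trna", "rdna", "chloroplast", "mitochondrion"))
    if (length(sim$references[[nm]]))
      write_fasta(sim$references[[nm]], file.path(out_dir, paste0(nm, ".fa")))
  write_gff3(sim$annotation, file.path(out_dir, "annotation.gff3"))
  write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))
  for (lib in names(reads))
    write_fastq(reads[[lib]], file.path(out_dir, paste0("reads_", lib, ".fastq")))
  invisible(out_dir)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson shuffle: permutes a sequence while preserving its exact
#' dinucleotide composition (the shuffled sequence is a random Eulerian walk
#' on the dinucleotide multigraph).  Used as the negative control for miRNA
#' discovery specificity.
#'
#' @param seq a single DNA string.
#' @param seed optional seed.
#' @return shuffled string of identical length and dinucleotide counts.
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- as.integer(strsplit(chartr("ACGT", "1234", seq), NULL)[[1]])
  n <- length(v)
  if (n < 3) return(seq)
  first <- v[1]; last <- v[n]
  succ <- split(v[-1], v[-n]) # successor multiset per vertex
  verts <- sort(unique(v))
  nonterm <- setdiff(verts[vapply(as.character(verts), function(u)
    length(succ[[u]]) > 0, logical(1))], last)
  repeat {
    # pick a random final out-edge per non-terminal vertex; the picks must
    # form a functional graph whose every vertex reaches the terminal one
    lastpick <- rep(NA_integer_, 4)
    for (u in nonterm) {
      cand <- succ[[as.character(u)]]
      lastpick[u] <- cand[sample.int(length(cand), 1)]
    }
    ok <- TRUE
    for (u in nonterm) {
      x <- u; steps <- 0L
      while (!is.na(x) && x != last && steps < 8L) {
        x <- lastpick[x]; steps <- steps + 1L
      }
      if (is.na(x) || x != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  lists <- vector("list", 4)
  for (u in verts) {
    cand <- succ[[as.character(u)]]
    if (is.null(cand) || length(cand) == 0) next
    if (u %in% nonterm) {
      lp <- lastpick[u]
      idx <- which(cand == lp)[1]
      rest <- cand[-idx]
      lists[[u]] <- c(if (length(rest)) rest[sample.int(length(rest))], lp)
    } else {
      lists[[u]] <- cand[sample.int(length(cand))]
    }
  }
  ptr <- rep(1L, 4)
  out <- integer(n)
  out[1] <- first
  cur <- first
  for (i in 2:n) {
    nxt <- lists[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  chartr("1234", "ACGT", paste(out, collapse = ""))
}
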