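#' Pipeline configuration
#'
#' Aggregates every stage parameter with its published default: 17-35 nt
#' size selection, up to 3 mismatches against tRNA/rDNA, perfect genome
#' matches for quantification (relaxed budget 3 reported only), 100 nt block
#' gap, 20 RPM low-expression filter, 2-fold cutoff, alpha 0.05 with
#' Bonferroni, candidacy at <= 20 genomic loci, 170 nt folding windows,
#' -40 kcal/mol energy gate at 25 degrees C.
#'
#' @param sim a [sim_config()] for the simulate stage (or `NULL` when
#'   running from files).
#' @param seed master seed (defaults to the simulation seed).
#' @param ... overrides for any default parameter.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), seed = NULL, ...) {
  cfg <- list(
    sim = sim,
    seed = seed %||% (if (!is.null(sim)) sim$seed else 1L),
    min_len = 17L, max_len = 35L, max_mismatch_correct = 1L,
    decoy_mismatch = 3L, relaxed_mismatch = 3L,
    gap = 100L,
    rpm_min = 20, fc_min = 2, alpha = 0.05,
    max_loci = 20L, min_candidate_abundance = 5L,
    window_length = 170L, dg_threshold = -40, temperature = 25,
    size_range = c(20L, 22L),
    strand_bias_min = 0.9, overlap_min = 0.5, n_shuffles = 1000L,
    comparisons = standard_comparisons())
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror the arguments of [pipeline_config()];
#' the `sim:` mapping is passed to [sim_config()] (with `library_design`
#' and `de_plan` given as lists of records).
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$sim)) {
    sa <- y$sim
    for (nm in c("library_design", "de_plan"))
      if (!is.null(sa[[nm]]))
        sa[[nm]] <- data.table::rbindlist(lapply(sa[[nm]], as.data.frame))
    if (!is.null(sa$decoy_fraction) && is.list(sa$decoy_fraction))
      sa$decoy_fraction <- unlist(sa$decoy_fraction)
    if (!is.null(sa$ratio_21_24) && is.list(sa$ratio_21_24))
      sa$ratio_21_24 <- unlist(sa$ratio_21_24)
    sim <- do.call(sim_config, sa)
  } else {
    sim <- sim_config()
  }
  extra <- y[setdiff(names(y), "sim")]
  if (!is.null(extra$comparisons))
    extra$comparisons <- data.table::rbindlist(lapply(extra$comparisons,
                                                      as.data.frame))
  do.call(pipeline_config, c(list(sim = sim), extra))
}

#' Run the full pipeline
#'
#' Stages: simulate, preprocess, align, blocks, de, mirna, annotate.  Each
#' stage's outputs are written under `out_dir` and a `manifest.json`
#' records the seed, parameters and per-stage counts.  When ground truth is
#' available (simulated input) the manifest additionally reports the
#' classification agreement for planted miRNA and TE-siRNA loci.
#'
#' @param config a `pipeline_config`.
#' @param out_dir run directory (created).
#' @param write_reads whether to write FASTQ files (off by default to keep
#'   runs light; tag tables are always written).
#' @return the manifest, invisibly; all outputs are on disk.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         write_reads = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "srnablocks",
                   version = as.character(utils::packageVersion("srnablocks")),
                   seed = config$seed,
                   parameters = config[setdiff(names(config),
                                               c("sim", "comparisons"))],
                   stages = list())
  stage <- function(name, value) {
    manifest$stages[[name]] <<- value
    manifest
  }

  # 1. simulate ------------------------------------------------------------
  sim <- generate_genome(config$sim)
  reads <- simulate_libraries(sim)
  if (write_reads) write_simulation(sim, reads, file.path(out_dir, "sim"))
  else {
    dir.create(file.path(out_dir, "sim"), showWarnings = FALSE)
    write_fasta(sim$references$genome, file.path(out_dir, "sim", "genome.fa"))
    write_gff3(sim$annotation, file.path(out_dir, "sim", "annotation.gff3"))
    write_tsv(sim$truth, file.path(out_dir, "sim", "truth.tsv"))
  }
  stage("simulate", list(libraries = length(reads),
                         reads = sum(lengths(reads)),
                         loci = nrow(sim$truth)))

  # 2. preprocess ----------------------------------------------------------
  tags <- data.table::rbindlist(lapply(names(reads), function(lib)
    preprocess_reads(reads[[lib]], lib, config$min_len, config$max_len,
                     config$max_mismatch_correct)))
  write_tsv(tags, file.path(out_dir, "tags.tsv"))
  stage("preprocess", list(tags = nrow(tags), reads = sum(tags$abundance)))

  # 3. align ---------------------------------------------------------------
  triage <- hierarchical_filter(tags, sim$references,
                                decoy_mismatch = config$decoy_mismatch,
                                relaxed_mismatch = config$relaxed_mismatch)
  write_tsv(triage$summary, file.path(out_dir, "triage_summary.tsv"))
  write_tsv(triage$genome_hits, file.path(out_dir, "genome_hits.tsv"))
  stage("align", list(categories = as.list(table(triage$categories$category)),
                      genome_hits = nrow(triage$genome_hits)))

  # 4. blocks --------------------------------------------------------------
  gtags <- merge(tags, triage$categories[category == "genome_perfect",
                                         .(sequence)], by = "sequence")
  blocks <- build_blocks(triage$genome_hits, gap = config$gap)
  hits_b <- assign_blocks(triage$genome_hits, blocks)
  counts <- weighted_counts(blocks, hits_b, gtags)
  mat <- count_matrix(counts)
  prof <- size_profile(gtags)
  write_tsv(blocks, file.path(out_dir, "blocks.tsv"))
  write_tsv(counts, file.path(out_dir, "block_counts.tsv"))
  write_tsv(prof$per_length, file.path(out_dir, "size_profile.tsv"))
  write_tsv(prof$ratio, file.path(out_dir, "ratio_21_24.tsv"))
  stage("blocks", list(blocks = nrow(blocks),
                       mean_length = mean(blocks$end - blocks$start),
                       median_length = stats::median(blocks$end - blocks$start)))

  # 5. differential expression ---------------------------------------------
  de <- run_comparisons(mat, config$comparisons, rpm_min = config$rpm_min,
                        fc_min = config$fc_min, alpha = config$alpha)
  de_all <- data.table::rbindlist(de)
  if (nrow(de_all)) write_tsv(de_all, file.path(out_dir, "de_results.tsv"))
  de_counts <- lapply(de, function(d) sum(d$status %in% c("de_up", "de_down")))
  stage("de", de_counts)

  # 6. miRNA discovery ------------------------------------------------------
  mature_refs <- planted_matures(sim)
  disc <- discover_mirnas(sim$references$genome, triage$genome_hits, gtags,
                          annotation = sim$annotation,
                          mature_refs = mature_refs,
                          max_loci = config$max_loci,
                          min_abundance = config$min_candidate_abundance,
                          window_length = config$window_length,
                          dg_threshold = config$dg_threshold,
                          size_range = config$size_range)
  write_tsv(disc$calls, file.path(out_dir, "mirna_calls.tsv"))
  stage("mirna", list(candidates = nrow(disc$candidates),
                      calls = nrow(disc$calls)))

  # 7. annotate ------------------------------------------------------------
  de_blocks <- unique(de_all[status %in% c("de_up", "de_down"), block_id])
  # always include blocks over planted loci so truth agreement is measurable
  planted <- sim$truth[class %in% c("mirna", "sirna_te")]
  planted_blocks <- overlapping_blocks(blocks, planted)
  ann_ids <- union(de_blocks, planted_blocks$block_id)
  ann <- annotate_blocks(blocks, hits_b, gtags, sim$references$genome,
                         sim$annotation, mature_refs, block_ids = ann_ids,
                         window_length = config$window_length,
                         dg_threshold = config$dg_threshold,
                         n_shuffles = config$n_shuffles, seed = config$seed,
                         strand_bias_min = config$strand_bias_min,
                         overlap_min = config$overlap_min)
  ann[, de := block_id %in% de_blocks]
  write_tsv(ann, file.path(out_dir, "block_annotation.tsv"))

  agree <- truth_agreement(ann, planted_blocks)
  stage("annotate", list(annotated = nrow(ann), de_blocks = length(de_blocks),
                         truth_agreement = agree))

  manifest$stages <- manifest$stages
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# mature reference set shipped with a simulation (stand-in for a miRBase
# mature FASTA)
planted_matures <- function(sim) {
  m <- sim$truth[class == "mirna" & !is.na(mature_sequence)]
  setNames(m$mature_sequence, m$locus_id)
}

# blocks overlapping planted loci, labelled with the truth class
overlapping_blocks <- function(blocks, planted) {
  if (nrow(planted) == 0 || nrow(blocks) == 0)
    return(data.table::data.table(block_id = character(0),
                                  locus_id = character(0),
                                  class = character(0)))
  bg <- GenomicRanges::GRanges(blocks$chrom,
                               IRanges::IRanges(blocks$start + 1L, blocks$end))
  pg <- GenomicRanges::GRanges(planted$chrom,
                               IRanges::IRanges(planted$start + 1L, planted$end))
  ov <- GenomicRanges::findOverlaps(bg, pg)
  data.table::data.table(
    block_id = blocks$block_id[S4Vectors::queryHits(ov)],
    locus_id = planted$locus_id[S4Vectors::subjectHits(ov)],
    class = planted$class[S4Vectors::subjectHits(ov)])
}

# fraction of planted miRNA / TE-siRNA loci whose overlapping block was
# classified to the matching class
truth_agreement <- function(ann, planted_blocks) {
  if (nrow(planted_blocks) == 0) return(list())
  m <- merge(planted_blocks, ann[, .(block_id, final_class)], by = "block_id")
  expected <- c(mirna = "mirna_like", sirna_te = "sirna_te")
  out <- list()
  for (cl in names(expected)) {
    sub <- m[class == cl]
    out[[cl]] <- if (nrow(sub)) mean(sub$final_class == expected[[cl]]) else NA
  }
  out
}
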