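#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic small RNA
#' experiment: a nuclear genome carrying planted miRNA hairpins, transposon
#' (TE) siRNA clusters and gene-overlapping siRNA clusters, plus tRNA/rDNA
#' decoy references and plastid contigs, and a set of sequencing libraries
#' with planted fold changes.
#'
#' The default `library_design` mirrors an eight-library tissue survey
#' (cotyledon, hypocotyl, hook concave, hook convex, each dark-grown and
#' far-red treated).  Default per-library 21:24-nt abundance ratios follow
#' the published tissue profile (cotyledon approximately 2:1, hypocotyl and
#' dark hook 24-dominated, far-red hook near 1:1); all distributional
#' choices are stand-ins and remain configurable.
#'
#' @param seed master seed; every downstream stream is derived from it.
#' @param genome_length nuclear genome size (nt), single chromosome.
#' @param n_mirna_loci,n_te_loci,n_gene_sirna_loci planted locus counts.
#' @param n_decoy_trna,n_decoy_rdna decoy reference sequence counts.
#' @param n_plastid_contigs chloroplast/mitochondrion contig count (>= 2
#'   gives one of each; additional contigs alternate).
#' @param library_design data.frame with columns `library_id, tissue_label,
#'   light_label, depth_reads`.
#' @param de_plan data.frame with columns `locus_id, library_id, fold_change`:
#'   the locus' expected abundance in that library is multiplied by
#'   `fold_change` (other loci are renormalised so the fold is exact in
#'   expectation).
#' @param error_rate per-base substitution probability in `[0, 0.05]`.
#' @param abundance_lognormal_mu,abundance_lognormal_sigma log-normal
#'   parameters of the baseline locus weights.
#' @param gc background GC content.
#' @param decoy_fraction expected fraction of each library drawn from
#'   tRNA/rDNA decoys; scalar or named by `tissue_label`.
#' @param plastid_fraction expected plastid read fraction per library.
#' @param junk_fraction expected fraction of unmappable random reads.
#' @param ratio_21_24 target 21-nt:24-nt abundance ratio per library
#'   (named by `library_id`), scalar, or `NULL` for no tilting.
#' @param min_locus_spacing minimum gap between planted loci (nt); must
#'   exceed the default block-merge gap so planted loci never coalesce.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 300000L,
                       n_mirna_loci = 20L,
                       n_te_loci = 15L,
                       n_gene_sirna_loci = 15L,
                       n_decoy_trna = 20L,
                       n_decoy_rdna = 5L,
                       n_plastid_contigs = 2L,
                       library_design = default_library_design(),
                       de_plan = default_de_plan(),
                       error_rate = 0.005,
                       abundance_lognormal_mu = 4,
                       abundance_lognormal_sigma = 1.5,
                       gc = 0.5,
                       decoy_fraction = c(cotyledon = 0.55, hypocotyl = 0.30,
                                          hook_concave = 0.40,
                                          hook_convex = 0.40),
                       plastid_fraction = 0.02,
                       junk_fraction = 0.08,
                       ratio_21_24 = default_ratio_21_24(),
                       min_locus_spacing = 300L) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_mirna_loci = as.integer(n_mirna_loci),
              n_te_loci = as.integer(n_te_loci),
              n_gene_sirna_loci = as.integer(n_gene_sirna_loci),
              n_decoy_trna = as.integer(n_decoy_trna),
              n_decoy_rdna = as.integer(n_decoy_rdna),
              n_plastid_contigs = as.integer(n_plastid_contigs),
              library_design = as.data.frame(library_design),
              de_plan = if (is.null(de_plan)) NULL else as.data.frame(de_plan),
              error_rate = error_rate,
              abundance_lognormal_mu = abundance_lognormal_mu,
              abundance_lognormal_sigma = abundance_lognormal_sigma,
              gc = gc, decoy_fraction = decoy_fraction,
              plastid_fraction = plastid_fraction,
              junk_fraction = junk_fraction,
              ratio_21_24 = ratio_21_24,
              min_locus_spacing = as.integer(min_locus_spacing))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_library_design <- function(depth_reads = 50000L) {
  tissues <- c("cotyledon", "hypocotyl", "hook_concave", "hook_convex")
  short <- c("cot", "hyp", "hkcc", "hkcv")
  data.frame(
    library_id = paste0(rep(short, each = 2), "_", c("dark", "fr")),
    tissue_label = rep(tissues, each = 2),
    light_label = rep(c("dark", "fr"), 4),
    depth_reads = as.integer(depth_reads),
    stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_de_plan <- function() {
  data.frame(
    locus_id = c("mir01", "mir02", "mir03", "mir04", "mir05",
                 "te01", "te02", "gsi01"),
    library_id = c("cot_fr", "hyp_fr", "hkcc_fr", "hkcv_fr", "hkcv_fr",
                   "hkcv_fr", "hkcc_fr", "hkcv_fr"),
    fold_change = c(4, 0.25, 4, 4, 4, 0.25, 0.25, 4),
    stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_ratio_21_24 <- function() {
  c(cot_dark = 2.0, cot_fr = 2.0,
    hyp_dark = 0.81, hyp_fr = 0.67,
    hkcc_dark = 0.71, hkcc_fr = 0.98,
    hkcv_dark = 0.75, hkcv_fr = 1.07)
}

validate_sim_config <- function(cfg) {
  ld <- cfg$library_design
  stopifnot(is.data.frame(ld),
            all(c("library_id", "tissue_label", "light_label",
                  "depth_reads") %in% names(ld)))
  if (any(ld$depth_reads <= 0)) stop("depth_reads must be > 0 for every library")
  if (anyDuplicated(ld$library_id)) stop("duplicate library_id")
  if (!is.null(cfg$de_plan) && nrow(cfg$de_plan) > 0) {
    stopifnot(all(c("locus_id", "library_id", "fold_change") %in%
                    names(cfg$de_plan)))
    if (any(cfg$de_plan$fold_change <= 0)) stop("fold_change must be > 0")
    bad <- setdiff(cfg$de_plan$library_id, ld$library_id)
    if (length(bad)) stop("de_plan references unknown library: ",
                          paste(bad, collapse = ", "))
  }
  if (cfg$error_rate < 0 || cfg$error_rate > 0.05)
    stop("error_rate must be in [0, 0.05]")
  if (cfg$genome_length < 50000) stop("genome_length must be >= 50,000")
  fr <- cfg$decoy_fraction
  if (any(fr < 0 | fr > 0.9)) stop("decoy_fraction out of range")
  invisible(cfg)
}
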