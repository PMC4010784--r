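#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence
#'
#' @param n sequence length (nt).
#' @param gc GC content in `[0, 1]`; bases are drawn i.i.d.
#' @return a single character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Derive a reproducible 31-bit sub-seed from a master seed and a text tag,
# so that independent stages consume independent streams.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strict uppercase-ACGT test
is_acgt <- function(x) !grepl("[^ACGT]", x)
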