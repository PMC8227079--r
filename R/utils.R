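#' @importFrom Rcpp sourceCpp
#' @useDynLib mitescape, .registration = TRUE
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data .env abort
NULL

# Normalize any sequence input (DNAStringSet, named character vector, single
# string) to an uppercase character vector. Non-ACGT letters become N, which
# the aligner treats as never matching.
as_seq_chr <- function(x) {
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (methods::is(x, "XString")) x <- as.character(x)
  if (!is.character(x)) abort("expected sequences as character or DNAStringSet")
  out <- toupper(x)
  out <- gsub("[^ACGT]", "N", out)
  names(out) <- names(x)
  out
}

as_dna_set <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  Biostrings::DNAStringSet(as_seq_chr(x))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Default extraction score floor for the local aligner: half the score of an
# ungapped alignment that just meets the identity/length thresholds, never
# below 16. Spurious lower-scoring alignments are removed afterwards by the
# explicit identity/length filters.
min_extract_score <- function(min_identity, min_len) {
  max(16L, as.integer(floor(min_len * (2 * min_identity / 100 - 1) / 2)))
}

#' Generate a random genome of one or more contigs
#'
#' Uniform i.i.d. A/C/G/T sequence, used as the neutral background into which
#' synthetic MITE copies and gene models are planted.
#'
#' @param length Total genome length in bp, split evenly across contigs.
#' @param n_contigs Number of contigs.
#' @param seed Optional integer seed.
#' @return A named [Biostrings::DNAStringSet] (`contig_1`, `contig_2`, ...).
#' @export
random_genome <- function(length, n_contigs = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  per <- diff(round(seq(0, length, length.out = n_contigs + 1)))
  seqs <- vapply(per, random_dna, character(1))
  names(seqs) <- paste0("contig_", seq_len(n_contigs))
  Biostrings::DNAStringSet(seqs)
}
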