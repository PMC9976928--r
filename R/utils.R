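# Sequence utilities shared across modules. Sequences travel as plain
# uppercase character scalars; Biostrings does the heavy lifting at the
# boundaries (revcomp, translation, alignment).

#' Reverse complement of a DNA string
#'
#' @param x A character vector of DNA sequences (`ACGTN` alphabet; IUPAC
#'   ambiguity codes are tolerated and complemented per IUPAC rules).
#' @return A character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# Split a sequence into a character vector of single bases.
seq_chars <- function(x) {
  strsplit(x, "", fixed = TRUE)[[1]]
}

# Uppercase and validate alphabet; non-ACGTN characters become N.
normalize_seq <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

complement_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Draw a random DNA string with the given GC content.
random_dna <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Hamming distance between equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(seq_chars(a) != seq_chars(b))
}

# A genome is a named character vector of contig sequences. Accept also a
# DNAStringSet or a single named list.
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (is.list(genome)) genome <- unlist(genome)
  if (!is.character(genome) || is.null(names(genome)) || any(names(genome) == "")) {
    abort("genome must be a named character vector, named list or DNAStringSet of contigs")
  }
  vapply(genome, normalize_seq, character(1))
}

#' Contig sizes of a genome
#'
#' @param genome Named character vector (or `DNAStringSet`) of contigs.
#' @return A tibble with columns `chrom` and `size` (bp).
#' @export
chrom_sizes <- function(genome) {
  genome <- as_genome(genome)
  tibble(chrom = names(genome), size = unname(nchar(genome)))
}

#' @importFrom methods is
NULL
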