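# Readers and writers for the plain-text interchange formats used between
# stages: BLAST outfmt-6 hit tables, FASTA, BED, gene-model TSV,
# chromatin-state BED and motif-profile TSV. Coordinates are 1-based
# inclusive on disk (BLAST) or 0-based half-open (BED) and always 0-based
# half-open inside the package.

outfmt6_cols <- c(
  "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
  "qstart", "qend", "sstart", "send", "evalue", "bitscore"
)

#' Read a BLAST tabular (outfmt 6) hit file into a homology-hit tibble
#'
#' Subject coordinates (the genome side of a TblastN search) arrive 1-based
#' inclusive with `sstart > send` signalling the minus strand; they are
#' converted to 0-based half-open `start < end` plus an explicit `strand`.
#' Records with malformed coordinates (`sstart == send` is impossible for a
#' hit of positive length and is rejected) are dropped with a message, not
#' an error.
#'
#' @param path Path to a 12-column tab-separated file without header.
#' @return A tibble with columns `query_id`, `chrom`, `start`, `end`,
#'   `strand`, `percent_identity`, `evalue`, `aligned_length`.
#' @export
read_blast_hits <- function(path) {
  raw <- readr::read_tsv(path, col_names = outfmt6_cols, show_col_types = FALSE,
                         comment = "#")
  hits_from_outfmt6(raw)
}

# Convert an outfmt-6 data frame to the internal hit tibble.
hits_from_outfmt6 <- function(raw) {
  raw <- as_tibble(raw)
  bad <- is.na(raw$sstart) | is.na(raw$send) | raw$sstart == raw$send |
    raw$sstart < 1 | raw$send < 1
  if (any(bad)) {
    inform(sprintf("dropped %d hit record(s) with malformed subject coordinates", sum(bad)))
    raw <- raw[!bad, , drop = FALSE]
  }
  tibble(
    query_id = as.character(raw$qseqid),
    chrom = as.character(raw$sseqid),
    start = pmin(raw$sstart, raw$send) - 1L,
    end = pmax(raw$sstart, raw$send),
    strand = ifelse(raw$sstart <= raw$send, "+", "-"),
    percent_identity = raw$pident,
    evalue = raw$evalue,
    aligned_length = raw$length
  )
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA path (multi-contig supported).
#' @return Named character vector of uppercase contig sequences.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_genome(x)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a BED file of insertion sites or intervals
#'
#' BED is 0-based half-open; no conversion is applied. Columns beyond the
#' sixth are ignored.
#'
#' @param path BED3/BED4/BED6 path.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE, comment = "#")
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  names(raw)[seq_len(min(ncol(raw), 6))] <- nm[seq_len(min(ncol(raw), 6))]
  as_tibble(raw[, seq_len(min(ncol(raw), 6)), drop = FALSE])
}

#' Read insertion sites from BED6
#'
#' The BED name column carries the sample label (e.g. `PS`, `SB`,
#' `random`); the site position is the interval start (first base of the TA
#' target dinucleotide, 0-based).
#'
#' @param path BED path.
#' @return Tibble with `chrom`, `position`, `strand`, `sample_label`.
#' @export
read_sites <- function(path) {
  bed <- read_bed(path)
  tibble(
    chrom = bed$chrom,
    position = as.integer(bed$start),
    strand = if ("strand" %in% names(bed)) bed$strand else NA_character_,
    sample_label = if ("name" %in% names(bed)) as.character(bed$name) else "sites"
  )
}

#' Write insertion sites as BED6
#'
#' @param sites Site tibble (`chrom`, `position`, `strand`, `sample_label`).
#' @param path Output path.
#' @export
write_sites_bed <- function(sites, path) {
  strand <- sites$strand %||% NA_character_
  strand <- ifelse(is.na(strand), ".", strand)
  df <- data.frame(sites$chrom, sites$position, sites$position + 2L,
                   sites$sample_label %||% "sites", 0L, strand)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read gene models from a minimal TSV
#'
#' Expected columns: `chrom`, `start`, `end`, `strand`, `name` and
#' optionally `expression` (non-negative). Coordinates 0-based half-open.
#'
#' @param path TSV path with header.
#' @return Gene tibble.
#' @export
read_genes <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("chrom", "start", "end", "strand", "name")
  missing <- setdiff(need, names(g))
  if (length(missing)) abort(paste("gene file missing column(s):", paste(missing, collapse = ", ")))
  if (any(g$start >= g$end)) abort("gene file has records with start >= end")
  as_tibble(g)
}

#' Read a chromatin-state segmentation from BED4
#'
#' @param path BED path; the name column is the state label.
#' @return Tibble with `chrom`, `start`, `end`, `state`.
#' @export
read_states <- function(path) {
  bed <- read_bed(path)
  tibble(chrom = bed$chrom, start = bed$start, end = bed$end,
         state = as.character(bed$name))
}

#' Read an amino-acid motif profile (position weight matrix)
#'
#' Format: a line `#threshold <value>` followed by a tab-separated header of
#' the 20 amino-acid one-letter codes and one row of scores per profile
#' position.
#'
#' @param path Profile TSV path.
#' @param name Profile name; defaults to the file stem.
#' @return A `motif_profile` list with `name`, `matrix` (positions x 20)
#'   and `threshold`.
#' @export
read_motif_profile <- function(path, name = NULL) {
  lines <- readLines(path)
  thr_line <- grep("^#threshold", lines, value = TRUE)
  if (!length(thr_line)) abort("profile file lacks a '#threshold' line")
  threshold <- as.numeric(sub("^#threshold\\s+", "", thr_line[[1]]))
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t", check.names = FALSE)
  mat <- as.matrix(tab)
  motif_profile(name %||% sub("\\.[^.]*$", "", basename(path)), mat, threshold)
}

#' Construct a motif profile
#'
#' @param name Profile name (e.g. `"Brk"`, `"HTH"`).
#' @param matrix Numeric matrix, one row per position, columns named by
#'   amino-acid one-letter codes.
#' @param threshold Score threshold for calling a hit.
#' @return A `motif_profile` object.
#' @export
motif_profile <- function(name, matrix, threshold) {
  if (is.null(colnames(matrix))) abort("profile matrix needs amino-acid column names")
  if (!is.finite(threshold)) abort("profile threshold must be finite")
  structure(list(name = name, matrix = matrix, threshold = threshold),
            class = "motif_profile")
}

#' Write a motif profile to TSV
#'
#' @param profile A `motif_profile`.
#' @param path Output path.
#' @export
write_motif_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#threshold %g", profile$threshold), con)
  utils::write.table(profile$matrix, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
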