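# Synthetic data with planted ground truth: ancestral elements, K-targeted
# mutation, genome planting with TA target-site duplication, and biased
# insertion-site simulation. Every generated object is verifiable by the
# discovery/annotation/dynamics/insertion modules (construction by
# contract).

AA_CODONS <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), C = c("TGT", "TGC"),
  D = c("GAT", "GAC"), E = c("GAA", "GAG"), F = c("TTT", "TTC"),
  G = c("GGT", "GGC", "GGA", "GGG"), H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"), K = c("AAA", "AAG"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"), M = "ATG",
  N = c("AAT", "AAC"), P = c("CCT", "CCC", "CCA", "CCG"),
  Q = c("CAA", "CAG"), R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), V = c("GTT", "GTC", "GTA", "GTG"),
  W = "TGG", Y = c("TAT", "TAC")
)

#' Simulate a background genome
#'
#' I.i.d. contigs at a configurable GC content (default 41%,
#' vertebrate-like).
#'
#' @param sizes Named integer vector of contig sizes.
#' @param gc GC fraction.
#' @param seed Integer seed.
#' @return Named character vector of contigs.
#' @export
simulate_genome <- function(sizes, gc = 0.41, seed = NULL) {
  if (is.null(names(sizes))) names(sizes) <- paste0("contig", seq_along(sizes))
  with_seed(seed, vapply(sizes, random_dna, character(1), gc = gc))
}

#' Construct a ground-truth ancestral transposon element
#'
#' Builds an element with perfect `tir_len`-bp terminal inverted repeats,
#' a single intron-less ORF encoding an `orf_aa`-residue transposase that
#' carries both toy DNA-binding motifs and a DD35D-style catalytic triad
#' (`spacer23` residues between D2 and D3), and random untranslated
#' spacers. Upstream in-frame ATGs are scrubbed so the planted ORF is the
#' one recovered by [find_longest_orf()].
#'
#' @param seed Integer seed.
#' @param tir_len TIR length, bp (default 28).
#' @param orf_aa Transposase length, residues (default 425; must be >=
#'   301).
#' @param spacer23 Residues between the second and third catalytic D.
#' @param element_len Total element length, bp (default 2400; must fit the
#'   ORF plus TIRs).
#' @param gc Background GC for the untranslated spacers.
#' @return An `ancestral_element` list: `sequence`, `tir_len`, `tsd`,
#'   `orf_start`, `orf_end` (0-based half-open, stop codon included),
#'   `protein_seq`, `triad`, `motif_positions`.
#' @export
make_ancestral_element <- function(seed = NULL, tir_len = 28L, orf_aa = 425L,
                                   spacer23 = 35L, element_len = 2400L,
                                   gc = 0.41) {
  if (orf_aa < 301L) abort("orf_aa must be at least 301 to satisfy the intact rule")
  orf_nt <- 3L * (orf_aa + 1L)
  if (element_len < orf_nt + 2L * tir_len + 60L) {
    abort("element_len too small for the requested ORF and TIRs")
  }
  with_seed(seed, {
    profiles <- toy_dbd_profiles()
    brk <- "KRPRGRPKKW"; hth <- "LTQEQLAELLGVSR"
    aa_pool <- setdiff(names(AA_CODONS), "M")
    prot <- sample(aa_pool, orf_aa, replace = TRUE)
    prot[1] <- "M"
    plant <- function(prot, pep, at) { # 1-based
      prot[at:(at + nchar(pep) - 1L)] <- seq_chars(pep); prot
    }
    prot <- plant(prot, brk, 20L)
    prot <- plant(prot, hth, 50L)
    d2 <- 220L; d1 <- d2 - 100L; d3 <- d2 + spacer23 + 1L
    if (d3 > orf_aa) abort("orf_aa too short for the catalytic triad layout")
    prot[c(d1, d2, d3)] <- "D"
    cds <- paste(vapply(prot, function(a) {
      cc <- AA_CODONS[[a]]
      cc[sample.int(length(cc), 1L)]
    }, character(1)), collapse = "")
    cds <- paste0(cds, "TAA")
    slack <- element_len - 2L * tir_len - nchar(cds)
    utr5_len <- max(30L, round(slack * 0.3))
    utr3_len <- slack - utr5_len
    prefix <- paste0(random_dna(tir_len, gc), random_dna(utr5_len, gc))
    # scrub upstream ATG so the planted start codon wins
    prefix <- gsub("ATG", "ACG", prefix, fixed = TRUE)
    tir <- substr(prefix, 1L, tir_len)
    seqn <- paste0(prefix, cds, random_dna(utr3_len, gc), revcomp(tir))
    # contract: the planted TIR is the maximal TIR. Prevent a chance inward
    # extension by forcing the first post-TIR base to mismatch its partner
    # (without creating a new ATG in the 5' UTR).
    ipos <- tir_len + 1L
    partner <- substr(seqn, nchar(seqn) - tir_len, nchar(seqn) - tir_len)
    if (identical(substr(seqn, ipos, ipos), unname(complement_base[partner]))) {
      for (cand in c("A", "C", "G", "T")) {
        if (identical(cand, unname(complement_base[partner]))) next
        ctx <- paste0(substr(seqn, ipos - 2L, ipos - 1L), cand,
                      substr(seqn, ipos + 1L, ipos + 2L))
        if (grepl("ATG", ctx, fixed = TRUE)) next
        substr(seqn, ipos, ipos) <- cand
        break
      }
    }
    out <- list(sequence = seqn, tir_len = tir_len, tsd = "TA",
                orf_start = tir_len + utr5_len,
                orf_end = tir_len + utr5_len + nchar(cds),
                protein_seq = paste(prot, collapse = ""),
                triad = c(d1 = d1 - 1L, d2 = d2 - 1L, d3 = d3 - 1L),
                motif_positions = c(Brk = 19L, HTH = 49L))
    class(out) <- "ancestral_element"
    out
  })
}

#' Solve Kimura two-parameter rates for a target divergence
#'
#' Finds the (P, Q) pair with `P/Q = ts_tv_ratio` whose K2P distance
#' equals `K_target` (one-dimensional root find, residual below 1e-9).
#'
#' @param K_target Target divergence (0-0.3).
#' @param ts_tv_ratio Transition/transversion ratio.
#' @return Named numeric vector `c(P = , Q = )`.
#' @export
solve_k2p_rates <- function(K_target, ts_tv_ratio = 2.0) {
  stopifnot(K_target >= 0, K_target <= 0.3, ts_tv_ratio > 0)
  if (K_target == 0) return(c(P = 0, Q = 0))
  r <- ts_tv_ratio
  k_of_q <- function(q) -0.5 * log(1 - 2 * r * q - q) - 0.25 * log(1 - 2 * q)
  q_max <- min(1 / (2 * r + 1), 0.5) * (1 - 1e-9)
  if (k_of_q(q_max) < K_target) abort("K_target unattainable for this ts/tv ratio")
  q <- uniroot(function(q) k_of_q(q) - K_target, c(0, q_max), tol = 1e-14)$root
  c(P = r * q, Q = q)
}

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS_OF <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

#' Mutate a sequence to a target Kimura divergence
#'
#' Applies per-site substitutions at the (P, Q) rates solved by
#' [solve_k2p_rates()]; the measured K2P divergence of the mutated
#' sequence against the original is within about +/-0.01 of the target on
#' average.
#'
#' @param seq DNA sequence.
#' @param K_target Target divergence (0-0.3).
#' @param ts_tv_ratio Transition/transversion ratio (default 2).
#' @param seed Integer seed.
#' @return Mutated sequence.
#' @export
mutate_to_k <- function(seq, K_target, ts_tv_ratio = 2.0, seed = NULL) {
  rates <- solve_k2p_rates(K_target, ts_tv_ratio)
  if (K_target == 0) return(seq)
  with_seed(seed, {
    ch <- seq_chars(seq)
    u <- runif(length(ch))
    can <- ch %in% c("A", "C", "G", "T")
    ts <- can & u < rates["P"]
    tv <- can & !ts & u < rates["P"] + rates["Q"]
    ch[ts] <- TRANSITION_OF[ch[ts]]
    if (any(tv)) {
      pick <- runif(sum(tv)) < 0.5
      ch[tv] <- vapply(seq_along(which(tv)), function(i) {
        TRANSVERSIONS_OF[[ch[which(tv)[i]]]][if (pick[i]) 1L else 2L]
      }, character(1))
    }
    paste(ch, collapse = "")
  })
}

#' Plant a transposon family into a genome with known truth
#'
#' Inserts mutated copies of the ancestor at TA dinucleotide sites
#' (duplicating the TA on insertion, as the transposition chemistry does),
#' one burst per row of `bursts`. Non-intact copies are either
#' end-truncated (at least 20% deleted) or ORF-broken (a stop codon
#' planted mid-transposase), chosen at random.
#'
#' @param genome Named character vector of contigs.
#' @param ancestor An `ancestral_element` from [make_ancestral_element()].
#' @param bursts Data frame / tibble with columns `K_target`, `n_copies`,
#'   `intact_fraction`.
#' @param seed Integer seed.
#' @param min_spacing Minimum distance between chosen insertion sites, bp.
#' @param random_strand Insert copies on both strands.
#' @return List with `genome` (modified contigs) and `truth` tibble
#'   (`copy_id`, `chrom`, `true_start`, `true_end`, `strand`, `burst_id`,
#'   `K_target`, `intact`, `truncation`).
#' @export
plant_family <- function(genome, ancestor, bursts, seed = NULL,
                         min_spacing = 5000L, random_strand = TRUE) {
  genome <- as_genome(genome)
  bursts <- as_tibble(bursts)
  n_total <- sum(bursts$n_copies)
  with_seed(seed, {
    ta <- purrr::imap_dfr(as.list(genome), function(s, nm) {
      m <- gregexpr("TA", s, fixed = TRUE)[[1]]
      if (m[1] == -1) return(tibble(chrom = character(), pos = integer()))
      tibble(chrom = nm, pos = as.integer(m) - 1L)
    })
    # greedy selection of well-separated TA sites, away from contig edges
    ta <- ta[sample.int(nrow(ta)), , drop = FALSE]
    sizes <- setNames(nchar(genome), names(genome))
    ta <- ta[ta$pos > min_spacing & ta$pos < sizes[ta$chrom] - min_spacing, , drop = FALSE]
    chosen <- ta[0, ]
    for (i in seq_len(nrow(ta))) {
      if (nrow(chosen) == n_total) break
      cand <- ta[i, ]
      near <- chosen$chrom == cand$chrom & abs(chosen$pos - cand$pos) < min_spacing
      if (!any(near)) chosen <- dplyr::bind_rows(chosen, cand)
    }
    if (nrow(chosen) < n_total) {
      abort("insufficient well-separated TA sites; use a larger genome")
    }
    # build copy sequences with per-copy truth
    specs <- purrr::pmap_dfr(
      list(bursts$K_target, bursts$n_copies, bursts$intact_fraction,
           seq_len(nrow(bursts))),
      function(k, n, fi, b) {
        tibble(burst_id = b, K_target = k,
               intact = runif(n) < fi)
      })
    specs$chrom <- chosen$chrom[seq_len(n_total)]
    specs$pos <- chosen$pos[seq_len(n_total)]
    specs$strand <- if (random_strand) sample(c("+", "-"), n_total, replace = TRUE)
                    else rep("+", n_total)
    seqs <- character(n_total)
    trunc <- character(n_total)
    for (i in seq_len(n_total)) {
      s <- mutate_to_k(ancestor$sequence, specs$K_target[i])
      if (specs$intact[i]) {
        trunc[i] <- "none"
      } else if (runif(1) < 0.5) {
        frac <- runif(1, 0.2, 0.5)
        del <- ceiling(frac * nchar(s))
        if (runif(1) < 0.5) {
          s <- substr(s, del + 1L, nchar(s)); trunc[i] <- "trunc_left"
        } else {
          s <- substr(s, 1L, nchar(s) - del); trunc[i] <- "trunc_right"
        }
      } else {
        at <- ancestor$orf_start + 3L * 200L   # codon 200 of the ORF
        s <- paste0(substr(s, 1L, at), "TAA", substr(s, at + 4L, nchar(s)))
        trunc[i] <- "orf_break"
      }
      seqs[i] <- s
    }
    specs$truncation <- trunc
    specs$seq <- ifelse(specs$strand == "-", revcomp(seqs), seqs)

    # splice all insertions per contig; TA at pos is duplicated
    truth <- list()
    for (ctg in unique(specs$chrom)) {
      sub <- specs[specs$chrom == ctg, , drop = FALSE]
      sub <- sub[order(sub$pos), , drop = FALSE]
      parts <- character(0)
      cursor <- 0L     # 0-based position consumed so far
      shift <- 0L
      for (i in seq_len(nrow(sub))) {
        p <- sub$pos[i]
        parts <- c(parts, substr(genome[[ctg]], cursor + 1L, p + 2L),
                   sub$seq[i], "TA")
        len <- nchar(sub$seq[i])
        truth[[length(truth) + 1L]] <- tibble(
          chrom = ctg, true_start = p + 2L + shift, true_end = p + 2L + shift + len,
          strand = sub$strand[i], burst_id = sub$burst_id[i],
          K_target = sub$K_target[i], intact = sub$intact[i],
          truncation = sub$truncation[i])
        shift <- shift + len + 2L
        cursor <- p + 2L
      }
      parts <- c(parts, substr(genome[[ctg]], cursor + 1L, nchar(genome[[ctg]])))
      genome[[ctg]] <- paste(parts, collapse = "")
    }
    truth <- dplyr::bind_rows(truth)
    truth$copy_id <- sprintf("planted_%03d", seq_len(nrow(truth)))
    list(genome = genome, truth = truth[, c("copy_id", "chrom", "true_start",
                                            "true_end", "strand", "burst_id",
                                            "K_target", "intact", "truncation")])
  })
}

#' Derive homology-hit records from a planted-family truth table
#'
#' Emulates a protein-homology search: each planted copy yields one hit
#' whose interval sits a random `inset_range` bp inside the true element
#' boundaries (homology hits start at coding sequence, not element
#' termini).
#'
#' @param truth Truth tibble from [plant_family()].
#' @param seed Integer seed.
#' @param inset_range Range of the per-end inset, bp (keep below the
#'   discovery `boundary_slop`).
#' @return Hit tibble in the internal format of [read_blast_hits()].
#' @export
truth_to_hits <- function(truth, seed = NULL, inset_range = c(5L, 25L)) {
  with_seed(seed, {
    n <- nrow(truth)
    in1 <- sample(inset_range[1]:inset_range[2], n, replace = TRUE)
    in2 <- sample(inset_range[1]:inset_range[2], n, replace = TRUE)
    tibble(
      query_id = "transposase", chrom = truth$chrom,
      start = truth$true_start + in1, end = truth$true_end - in2,
      strand = truth$strand,
      percent_identity = 100 * (1 - truth$K_target),
      evalue = 1e-150,
      aligned_length = truth$true_end - truth$true_start - in1 - in2
    )
  })
}

#' Simulate gene models on a genome
#'
#' Places non-overlapping genes of random length and strand, each with
#' three exons and a log-normal expression value.
#'
#' @param genome Named character vector of contigs (or `chrom`/`size`
#'   tibble).
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @param len_range Gene length range, bp.
#' @return Gene tibble (`chrom`, `start`, `end`, `strand`, `name`,
#'   `expression`, `exon_starts`, `exon_ends`).
#' @export
make_gene_models <- function(genome, n_genes = 50L, seed = NULL,
                             len_range = c(2000L, 8000L)) {
  sizes <- if (is.data.frame(genome)) as_tibble(genome) else chrom_sizes(genome)
  with_seed(seed, {
    placed <- list()
    tries <- 0L
    while (length(placed) < n_genes && tries < n_genes * 200L) {
      tries <- tries + 1L
      ci <- sample.int(nrow(sizes), 1L, prob = sizes$size)
      len <- sample(len_range[1]:len_range[2], 1L)
      if (sizes$size[ci] <= len + 2L) next
      st <- sample.int(sizes$size[ci] - len - 1L, 1L) - 1L
      clash <- purrr::some(placed, function(g) {
        g$chrom == sizes$chrom[ci] && st < g$end && g$start < st + len
      })
      if (clash) next
      placed[[length(placed) + 1L]] <- list(chrom = sizes$chrom[ci],
                                            start = st, end = st + len)
    }
    if (length(placed) < n_genes) abort("could not place all genes; enlarge genome")
    genes <- dplyr::bind_rows(purrr::map(placed, as_tibble))
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
    genes$name <- sprintf("gene_%03d", seq_len(nrow(genes)))
    genes$expression <- stats::rlnorm(nrow(genes), meanlog = 2, sdlog = 1.5)
    exon_info <- purrr::map2(genes$start, genes$end, function(s, e) {
      len <- e - s
      e1 <- s + max(100L, round(len * 0.2))
      i1 <- e1 + max(100L, round(len * 0.15))
      e2 <- i1 + max(100L, round(len * 0.2))
      i2 <- e2 + max(100L, round(len * 0.15))
      list(starts = paste(c(s, i1, i2), collapse = ","),
           ends = paste(c(e1, e2, e), collapse = ","))
    })
    genes$exon_starts <- purrr::map_chr(exon_info, "starts")
    genes$exon_ends <- purrr::map_chr(exon_info, "ends")
    genes
  })
}

#' Simulate a chromatin-state segmentation
#'
#' Tiles every contig with non-overlapping segments of random length and
#' random state labels (a toy stand-in for multi-state segmentations such
#' as 25-state ChromHMM models).
#'
#' @param genome Named character vector of contigs (or `chrom`/`size`
#'   tibble).
#' @param n_states Number of state labels.
#' @param seg_len_range Segment length range, bp.
#' @param seed Integer seed.
#' @return State tibble (`chrom`, `start`, `end`, `state`).
#' @export
make_chromatin_states <- function(genome, n_states = 25L,
                                  seg_len_range = c(1000L, 5000L), seed = NULL) {
  sizes <- if (is.data.frame(genome)) as_tibble(genome) else chrom_sizes(genome)
  with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(sizes)), function(i) {
      pos <- 0L
      segs <- list()
      while (pos < sizes$size[i]) {
        len <- sample(seg_len_range[1]:seg_len_range[2], 1L)
        end <- min(pos + len, sizes$size[i])
        segs[[length(segs) + 1L]] <- tibble(
          chrom = sizes$chrom[i], start = pos, end = end,
          state = sprintf("state_%02d", sample.int(n_states, 1L)))
        pos <- end
      }
      dplyr::bind_rows(segs)
    })
  })
}

#' Simulate insertion sites with configurable biases
#'
#' Weighted sampling (with replacement) over the genome's TA dinucleotide
#' positions. Per-position weight is the product of a genic fold (for
#' positions inside gene bodies), a Gaussian TSS proximity factor, an
#' expression-rank power for genic positions, and a context 8-mer motif
#' weight.
#'
#' @param genome Named character vector of contigs.
#' @param genes Gene tibble (may be `NULL` when only motif bias is used).
#' @param n_sites Number of sites to draw.
#' @param genic_fold Weight multiplier inside gene bodies (>= 0).
#' @param tss_sigma Gaussian sigma for TSS proximity weighting, bp
#'   (`NULL` disables).
#' @param expression_exponent Power applied to the gene's expression rank
#'   (0 disables).
#' @param motif_weights Named numeric vector of context 8-mer weights
#'   (positions -3..+4 around the TA start); unlisted contexts weigh 1.
#' @param sample_label Label for the emitted sites.
#' @param seed Integer seed.
#' @return List with `sites` (site tibble) and `truth` (per-chosen-site
#'   generative weight).
#' @export
simulate_sites <- function(genome, genes = NULL, n_sites = 1000L,
                           genic_fold = 1, tss_sigma = NULL,
                           expression_exponent = 0, motif_weights = NULL,
                           sample_label = "PS", seed = NULL) {
  genome <- as_genome(genome)
  ta <- purrr::imap_dfr(as.list(genome), function(s, nm) {
    m <- gregexpr("TA", s, fixed = TRUE)[[1]]
    if (m[1] == -1) return(tibble(chrom = character(), position = integer()))
    tibble(chrom = nm, position = as.integer(m) - 1L)
  })
  if (nrow(ta) == 0) abort("genome contains no TA sites")
  w <- rep(1, nrow(ta))
  if (!is.null(genes) && nrow(genes) > 0) {
    gr <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
    ov <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(ta$chrom, IRanges::IRanges(ta$position + 1L, width = 1L)), gr)
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    first <- !duplicated(qi)
    in_gene <- unique(qi)
    w[in_gene] <- w[in_gene] * genic_fold
    if (expression_exponent != 0 && "expression" %in% names(genes)) {
      rk <- rank(genes$expression, ties.method = "first") / nrow(genes)
      w[qi[first]] <- w[qi[first]] * rk[si[first]]^expression_exponent
    }
    if (!is.null(tss_sigma)) {
      tss <- gene_tss(genes)
      tgr <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(tss + 1L, width = 1L))
      nr <- GenomicRanges::distanceToNearest(
        GenomicRanges::GRanges(ta$chrom, IRanges::IRanges(ta$position + 1L, width = 1L)), tgr)
      d <- rep(Inf, nrow(ta))
      d[S4Vectors::queryHits(nr)] <- S4Vectors::mcols(nr)$distance
      w <- w * exp(-d^2 / (2 * tss_sigma^2))
    }
  }
  if (!is.null(motif_weights)) {
    ctx <- vapply(seq_len(nrow(ta)), function(i) {
      substr(genome[[ta$chrom[i]]], ta$position[i] - 2L, ta$position[i] + 5L)
    }, character(1))
    mw <- motif_weights[ctx]
    mw[is.na(mw)] <- 1
    w <- w * as.numeric(mw)
  }
  if (sum(w) <= 0) abort("all sampling weights are zero")
  with_seed(seed, {
    idx <- sample.int(nrow(ta), n_sites, replace = TRUE, prob = w)
    sites <- tibble(chrom = ta$chrom[idx], position = ta$position[idx],
                    strand = NA_character_, sample_label = sample_label)
    list(sites = sites,
         truth = tibble(chrom = ta$chrom[idx], position = ta$position[idx],
                        weight = w[idx]))
  })
}
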