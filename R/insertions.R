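# Integration-site preference: random backgrounds, feature-category
# assignment, gene-body / TSS / expression profiles, chromatin-state
# enrichment and Fisher's exact tests with star annotation.
#
# Sites are tibbles with `chrom`, `position` (0-based first base of the TA
# target dinucleotide), optional `strand` and `sample_label`. Genes are
# tibbles with `chrom`, `start`, `end`, `strand`, `name`, optional
# `expression` and optional BED12-style `exon_starts`/`exon_ends`
# comma-separated columns.

# Run code under a local RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate random background loci
#'
#' Uniform mode samples positions proportional to contig length (the
#' conventional computational random-locus background); `ta_matched` mode
#' samples only TA dinucleotide start positions, the fairer null for a
#' TA-targeting transposon's motif analyses.
#'
#' @param genome Named character vector of contigs, or (uniform mode only)
#'   a `chrom`/`size` tibble from [chrom_sizes()].
#' @param n Number of loci (the conventional background is 100,000).
#' @param seed Integer seed; identical seeds give identical site lists.
#' @param mode `"uniform"` or `"ta_matched"`.
#' @return Site tibble with `sample_label = "random"`.
#' @export
generate_random_loci <- function(genome, n = 100000L, seed = NULL,
                                 mode = c("uniform", "ta_matched")) {
  mode <- match.arg(mode)
  stopifnot(n > 0)
  with_seed(seed, {
    if (mode == "uniform") {
      sizes <- if (is.data.frame(genome)) as_tibble(genome) else chrom_sizes(genome)
      if (sum(sizes$size) <= 0) abort("total genome length must be positive")
      idx <- sample.int(nrow(sizes), n, replace = TRUE, prob = sizes$size)
      pos <- floor(runif(n) * (sizes$size[idx] - 1L))
      tibble(chrom = sizes$chrom[idx], position = as.integer(pos),
             strand = NA_character_, sample_label = "random")
    } else {
      genome <- as_genome(genome)
      ta <- purrr::imap_dfr(as.list(genome), function(s, nm) {
        m <- gregexpr("TA", s, fixed = TRUE)[[1]]
        if (m[1] == -1) return(tibble(chrom = character(), position = integer()))
        tibble(chrom = nm, position = as.integer(m) - 1L)
      })
      if (nrow(ta) == 0) abort("genome contains no TA dinucleotide")
      idx <- sample.int(nrow(ta), n, replace = TRUE)
      tibble(chrom = ta$chrom[idx], position = ta$position[idx],
             strand = NA_character_, sample_label = "random")
    }
  })
}

# GRanges helpers (1-based internally to GRanges, converted at the edge).
sites_gr <- function(sites) {
  GenomicRanges::GRanges(sites$chrom,
                         IRanges::IRanges(sites$position + 1L, width = 1L))
}

gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

# Parse BED12-ish comma lists into an exon tibble (absolute coordinates).
gene_exons <- function(genes) {
  if (!all(c("exon_starts", "exon_ends") %in% names(genes))) return(NULL)
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    if (is.na(genes$exon_starts[i]) || is.na(genes$exon_ends[i])) {
      return(tibble(chrom = character(), start = integer(), end = integer(),
                    gene = character()))
    }
    es <- as.integer(strsplit(genes$exon_starts[i], ",")[[1]])
    ee <- as.integer(strsplit(genes$exon_ends[i], ",")[[1]])
    tibble(chrom = genes$chrom[i], start = es, end = ee, gene = genes$name[i])
  })
}

FEATURE_LEVELS <- c("promoter", "exon", "intron", "genic_unresolved",
                    "downstream", "intergenic")

#' Assign each insertion site a genomic feature category
#'
#' Categories follow the precedence promoter > exon > intron >
#' genic_unresolved (gene body without exon model) > downstream >
#' intergenic, with strand-aware windows (promoter = `promoter_bp`
#' upstream of the TSS, downstream = `downstream_bp` past the TES). A site
#' hit by several genes takes the highest-precedence category, then the
#' gene with the nearest TSS.
#'
#' @param sites Site tibble.
#' @param genes Gene tibble.
#' @param promoter_bp,downstream_bp Window sizes, bp.
#' @return The site tibble with `category` (factor) and `gene_name`
#'   columns.
#' @export
assign_feature <- function(sites, genes, promoter_bp = 1000L, downstream_bp = 1000L) {
  sgr <- sites_gr(sites)
  tss <- gene_tss(genes)
  windows <- list()
  # promoter: upstream of TSS
  prom_start <- ifelse(genes$strand == "+", genes$start - promoter_bp, genes$end)
  prom_end <- ifelse(genes$strand == "+", genes$start, genes$end + promoter_bp)
  windows$promoter <- tibble(chrom = genes$chrom, start = pmax(prom_start, 0L),
                             end = prom_end, gene = genes$name)
  ex <- gene_exons(genes)
  has_exons <- genes$name[genes$name %in% (ex$gene %||% character())]
  windows$exon <- ex %||% tibble(chrom = character(), start = integer(),
                                 end = integer(), gene = character())
  body <- tibble(chrom = genes$chrom, start = genes$start, end = genes$end,
                 gene = genes$name)
  windows$intron <- body[body$gene %in% has_exons, , drop = FALSE]
  windows$genic_unresolved <- body[!body$gene %in% has_exons, , drop = FALSE]
  down_start <- ifelse(genes$strand == "+", genes$end, genes$start - downstream_bp)
  down_end <- ifelse(genes$strand == "+", genes$end + downstream_bp, genes$start)
  windows$downstream <- tibble(chrom = genes$chrom, start = pmax(down_start, 0L),
                               end = down_end, gene = genes$name)

  n <- nrow(sites)
  best_rank <- rep.int(length(FEATURE_LEVELS), n)   # default intergenic
  best_gene <- rep(NA_character_, n)
  best_dist <- rep(Inf, n)
  tss_by_gene <- setNames(tss, genes$name)
  for (rank in seq_along(windows)) {
    w <- windows[[rank]]
    if (is.null(w) || nrow(w) == 0) next
    gr <- GenomicRanges::GRanges(w$chrom, IRanges::IRanges(w$start + 1L, w$end))
    ov <- GenomicRanges::findOverlaps(sgr, gr)
    if (!length(ov)) next
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    d <- abs(sites$position[qi] - tss_by_gene[w$gene[si]])
    better <- rank < best_rank[qi] | (rank == best_rank[qi] & d < best_dist[qi])
    upd <- qi[better]
    best_rank[upd] <- rank
    best_gene[upd] <- w$gene[si[better]]
    best_dist[upd] <- d[better]
  }
  cat_names <- c(names(windows), "intergenic")
  dplyr::mutate(sites,
                category = factor(cat_names[best_rank], levels = FEATURE_LEVELS),
                gene_name = best_gene)
}

#' Feature-category distribution with Fisher tests against a background
#'
#' Per sample, the fraction of sites in each category; per (sample,
#' category), a two-sided Fisher's exact test of in-category vs not,
#' sample vs background, with fold change and star annotation.
#'
#' @param sites Site tibble (may hold several `sample_label`s).
#' @param genes Gene tibble.
#' @param background Background site tibble (e.g. from
#'   [generate_random_loci()]).
#' @inheritParams assign_feature
#' @return A `feature_distribution` tibble: `sample`, `category`, `count`,
#'   `fraction`, `bg_count`, `bg_fraction`, `fold`, `p_value`, `stars`.
#' @export
feature_distribution <- function(sites, genes, background,
                                 promoter_bp = 1000L, downstream_bp = 1000L) {
  if (nrow(sites) == 0) abort("empty site set")
  ann <- assign_feature(sites, genes, promoter_bp, downstream_bp)
  bg <- assign_feature(background, genes, promoter_bp, downstream_bp)
  bg_tab <- table(factor(bg$category, levels = FEATURE_LEVELS))
  bg_total <- nrow(bg)
  out <- ann |>
    dplyr::count(.data$sample_label, .data$category, .drop = FALSE, name = "count") |>
    dplyr::group_by(.data$sample_label) |>
    dplyr::mutate(total = sum(.data$count), fraction = .data$count / .data$total) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      bg_count = as.integer(bg_tab[as.character(.data$category)]),
      bg_fraction = .data$bg_count / bg_total,
      fold = ifelse(.data$bg_count > 0, .data$fraction / .data$bg_fraction, NA_real_),
      p_value = fisher_exact(.data$count, .data$total - .data$count,
                             .data$bg_count, bg_total - .data$bg_count),
      stars = stars(.data$p_value)
    ) |>
    dplyr::rename(sample = "sample_label")
  structure(out, class = c("feature_distribution", class(out)))
}

#' Gene-body decile histogram of intragenic insertions
#'
#' Gene bodies are divided into 10 equal-length segments in transcript
#' orientation (100% is the last nucleotide); each intragenic site falls
#' in bin `min(floor(10 f), 9)` of its gene, where `f` is the fractional
#' position. Sites outside every gene are skipped and counted in the
#' `n_skipped` attribute.
#'
#' @param sites Site tibble.
#' @param genes Gene tibble.
#' @return Tibble with `bin` (0-9), `count`, `fraction`.
#' @export
gene_body_decile <- function(sites, genes) {
  sgr <- sites_gr(sites)
  ggr <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  ov <- GenomicRanges::findOverlaps(sgr, ggr)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  if (length(qi)) {
    # one gene per site: nearest TSS
    d <- abs(sites$position[qi] - gene_tss(genes)[si])
    keep <- !duplicated(qi[order(qi, d)])
    ord <- order(qi, d)
    qi <- qi[ord][keep]; si <- si[ord][keep]
  }
  n_skipped <- nrow(sites) - length(qi)
  if (n_skipped > 0) inform(sprintf("%d site(s) outside gene bodies skipped", n_skipped))
  len <- genes$end[si] - genes$start[si]
  f <- ifelse(genes$strand[si] == "+",
              (sites$position[qi] - genes$start[si]) / len,
              (genes$end[si] - 1L - sites$position[qi]) / len)
  bin <- pmin(floor(10 * f), 9)
  out <- tibble(bin = 0:9) |>
    dplyr::left_join(tibble(bin = bin) |> dplyr::count(.data$bin, name = "count"),
                     by = "bin") |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L),
                  fraction = if (length(qi)) .data$count / length(qi) else 0)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Insertion profile around transcription start sites
#'
#' For every site, the signed strand-aware distance to its nearest TSS
#' within `halfwidth` bp (positive = downstream of the TSS in transcript
#' orientation), binned at `bin_bp`; sites with no TSS in range are
#' excluded.
#'
#' @param sites Site tibble.
#' @param genes Gene tibble.
#' @param halfwidth Window half-width, bp (default 3000 for a 6 kb
#'   window).
#' @param bin_bp Bin width, bp.
#' @return Tibble with `bin_low` (signed bp offset of the bin's lower
#'   edge), `count`, `fraction`.
#' @export
tss_profile <- function(sites, genes, halfwidth = 3000L, bin_bp = 100L) {
  stopifnot(halfwidth > 0)
  tss <- gene_tss(genes)
  tgr <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(tss + 1L, width = 1L))
  sgr <- sites_gr(sites)
  nearest <- GenomicRanges::nearest(sgr, tgr, select = "all")
  qi <- S4Vectors::queryHits(nearest); si <- S4Vectors::subjectHits(nearest)
  d_signed <- ifelse(genes$strand[si] == "+",
                     sites$position[qi] - tss[si],
                     tss[si] - sites$position[qi])
  keep <- abs(sites$position[qi] - tss[si]) <= halfwidth
  qi <- qi[keep]; d_signed <- d_signed[keep]
  dedup <- !duplicated(qi)
  d_signed <- d_signed[dedup]
  bins <- floor(d_signed / bin_bp) * bin_bp
  tibble(bin_low = bins) |>
    dplyr::count(.data$bin_low, name = "count") |>
    dplyr::mutate(fraction = .data$count / sum(.data$count))
}

#' Insertion frequency across gene expression groups
#'
#' Genes are ranked by expression and split into `n_groups` equal-count
#' groups (octiles by default, ties broken by stable gene order); the
#' insertion frequency of each group is the number of insertions landing
#' in its genes normalised by the group's total gene length in Mb.
#'
#' @param sites Site tibble.
#' @param genes Gene tibble with an `expression` column.
#' @param n_groups Number of expression groups (default 8).
#' @return Tibble with `group` (1 = lowest expression), `n_genes`,
#'   `total_len_mb`, `insertions`, `freq_per_mb`.
#' @export
expression_binned_frequency <- function(sites, genes, n_groups = 8L) {
  if (!"expression" %in% names(genes)) abort("genes need an expression column")
  if (sum(genes$expression, na.rm = TRUE) == 0) {
    warn("all expression values are zero; using a single group")
    n_groups <- 1L
  }
  if (nrow(genes) < n_groups) abort("fewer genes than groups")
  ord <- order(genes$expression, seq_len(nrow(genes)))
  genes <- genes[ord, , drop = FALSE]
  genes$group <- dplyr::ntile(seq_len(nrow(genes)), n_groups)
  sgr <- sites_gr(sites)
  ggr <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  ov <- GenomicRanges::findOverlaps(sgr, ggr)
  hit_groups <- genes$group[S4Vectors::subjectHits(ov)]
  # a site in overlapping genes counts once (first gene), so insertions <= sites
  first <- !duplicated(S4Vectors::queryHits(ov))
  hit_groups <- hit_groups[first]
  genes |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_genes = dplyr::n(),
                     total_len_mb = sum(.data$end - .data$start) / 1e6,
                     .groups = "drop") |>
    dplyr::mutate(insertions = vapply(.data$group, function(g) sum(hit_groups == g), integer(1)),
                  freq_per_mb = .data$insertions / .data$total_len_mb)
}

#' Chromatin-state enrichment of insertions versus random loci
#'
#' Per chromatin state, the fold change of the observed insertion
#' frequency over the random-locus frequency (the random expectation is 1
#' by construction) with a two-sided Fisher's exact test and star
#' annotation. States absent from the background are reported with `NA`
#' fold, never fabricated.
#'
#' @param sites Site tibble.
#' @param states State segmentation tibble (`chrom`, `start`, `end`,
#'   `state`).
#' @param random_sites Background site tibble.
#' @return An `enrichment_result` tibble: `state`, `obs_count`,
#'   `obs_total`, `bg_count`, `bg_total`, `fold`, `p_value`, `stars`.
#' @export
chromatin_state_enrichment <- function(sites, states, random_sites) {
  gr <- GenomicRanges::GRanges(states$chrom, IRanges::IRanges(states$start + 1L, states$end))
  self <- GenomicRanges::findOverlaps(gr, gr)
  qi <- S4Vectors::queryHits(self); si <- S4Vectors::subjectHits(self)
  clash <- qi < si & states$state[qi] != states$state[si]
  if (any(clash)) {
    abort(paste0("overlapping segments with conflicting states at rows: ",
                 paste(unique(qi[clash]), collapse = ", ")))
  }
  count_states <- function(s) {
    ov <- GenomicRanges::findOverlaps(sites_gr(s), gr)
    st <- states$state[S4Vectors::subjectHits(ov)][!duplicated(S4Vectors::queryHits(ov))]
    table(factor(st, levels = sort(unique(states$state))))
  }
  obs <- count_states(sites); bg <- count_states(random_sites)
  obs_total <- nrow(sites); bg_total <- nrow(random_sites)
  out <- tibble(
    state = names(obs),
    obs_count = as.integer(obs), obs_total = obs_total,
    bg_count = as.integer(bg), bg_total = bg_total
  ) |>
    dplyr::mutate(
      fold = ifelse(.data$bg_count > 0,
                    (.data$obs_count / obs_total) / (.data$bg_count / bg_total),
                    NA_real_),
      p_value = fisher_exact(.data$obs_count, obs_total - .data$obs_count,
                             .data$bg_count, bg_total - .data$bg_count),
      stars = stars(.data$p_value)
    )
  structure(out, class = c("enrichment_result", class(out)))
}

#' Two-sided Fisher's exact test for 2x2 tables (vectorised)
#'
#' The two-sided p-value sums the hypergeometric point probabilities not
#' exceeding that of the observed table (with the standard 1e-7 relative
#' tolerance for floating-point ties). A table with a zero margin has
#' p = 1.
#'
#' @param a,b,c,d Non-negative integer cell counts (vectorised; the table
#'   is `rbind(c(a, b), c(c, d))`).
#' @return Numeric vector of p-values.
#' @export
fisher_exact <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n); d <- rep_len(d, n)
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != floor(c(a, b, c, d)))) {
    abort("counts must be non-negative integers")
  }
  vapply(seq_len(n), function(i) {
    m <- a[i] + c[i]; nn <- b[i] + d[i]; k <- a[i] + b[i]
    support <- max(0, k - nn):min(k, m)
    dens <- dhyper(support, m, nn, k)
    sum(dens[dens <= dhyper(a[i], m, nn, k) * (1 + 1e-7)])
  }, numeric(1)) |> pmin(1)
}

#' Significance stars for p-values
#'
#' Mapping: `****` p <= 1e-4; `***` 1e-4 < p <= 0.001; `**` 0.001 < p <=
#' 0.01; `*` 0.01 < p <= 0.05; `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star symbols.
#' @export
stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p <= 1e-4 ~ "****",
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}
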