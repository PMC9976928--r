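# End-to-end orchestration: a validated run configuration holding every
# stage threshold, and a runner that executes simulate -> discover ->
# annotate -> dynamics -> insertions on a synthetic fixture with full
# reproducibility (config + seed serialised next to the outputs).

#' Default run configuration
#'
#' Every stage threshold with its conventional default: 2000 bp flanks,
#' e-value cut 1e-100, >40% coverage / >80% identity copy counting,
#' >= 300 aa transposase, DD35D spacer 35, young divergence bound 2%,
#' 3 kb TSS half-window, 8 expression groups, 100,000 random loci.
#'
#' @param seed Global seed.
#' @param out_dir Output directory.
#' @param ... Overrides for any config field.
#' @return A validated `run_config` list.
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("tirscape_run_"), ...) {
  cfg <- list(
    seed = seed, out_dir = out_dir,
    flank_size = 2000L, max_gap = 200L, max_evalue = 1e-100,
    boundary_slop = 30L, ta_bonus = 10,
    min_coverage = 0.40, min_identity = 0.80, min_aa = 300L, spacer23 = 35L,
    young_threshold = 0.02, bin_width = 1,
    promoter_bp = 1000L, downstream_bp = 1000L,
    tss_halfwidth = 3000L, tss_bin_bp = 100L, n_groups = 8L,
    n_random = 100000L, random_mode = "uniform",
    # synthetic fixture parameters
    sim_contig_sizes = c(chrA = 150000L, chrB = 50000L),
    sim_gc = 0.41, sim_tir_len = 28L, sim_orf_aa = 425L,
    sim_bursts = data.frame(K_target = c(0.02, 0.15), n_copies = c(8L, 8L),
                            intact_fraction = c(1, 0.5)),
    sim_n_genes = 30L, sim_n_states = 10L, sim_n_sites = 1000L,
    sim_genic_fold = 3
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) abort(paste("unknown config field(s):", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' @param cfg Config list.
#' @return The config, classed `run_config`; aborts on invalid fields.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(paste("invalid config:", msg))
  chk(cfg$min_identity >= 0 && cfg$min_identity <= 1, "min_identity must be in [0, 1]")
  chk(cfg$min_coverage >= 0 && cfg$min_coverage <= 1, "min_coverage must be in [0, 1]")
  chk(cfg$flank_size > 0, "flank_size must be positive")
  chk(cfg$min_aa >= 1, "min_aa must be positive")
  chk(cfg$young_threshold > 0 && cfg$young_threshold < 1, "young_threshold must be in (0, 1)")
  chk(cfg$n_random > 0, "n_random must be positive")
  chk(cfg$n_groups >= 1, "n_groups must be >= 1")
  chk(cfg$max_evalue > 0, "max_evalue must be positive")
  structure(cfg, class = "run_config")
}

write_stage <- function(df, out_dir, name) {
  readr::write_tsv(as_tibble(df), file.path(out_dir, paste0(name, ".tsv")))
}

#' Run the full pipeline on a synthetic fixture
#'
#' Generates a ground-truthed genome (planted transposon family plus
#' biased insertion sites), then runs discovery, annotation, dynamics and
#' integration-preference analysis, writing every intermediate as TSV (and
#' the genome as FASTA) into `config$out_dir` together with the serialised
#' configuration. Identical config and seed give byte-identical outputs.
#'
#' @param config A `run_config` from [default_config()].
#' @return A run report tibble (`stage`, `n_in`, `n_kept`, `n_dropped`),
#'   invisibly with the stage outputs in the `outputs` attribute.
#' @export
run_pipeline <- function(config = default_config()) {
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_out <- config
  cfg_out$out_dir <- NULL # keep serialised config portable across directories
  cfg_out$sim_bursts <- as.list(as.data.frame(cfg_out$sim_bursts))
  yaml::write_yaml(unclass(cfg_out), file.path(config$out_dir, "config.yaml"))
  report <- list()
  note <- function(stage, n_in, n_kept) {
    report[[length(report) + 1L]] <<- tibble(stage = stage, n_in = n_in,
                                             n_kept = n_kept, n_dropped = n_in - n_kept)
  }
  seed <- config$seed

  # --- simulate ---
  base_genome <- simulate_genome(config$sim_contig_sizes, gc = config$sim_gc,
                                 seed = seed)
  ancestor <- make_ancestral_element(seed = seed + 1L, tir_len = config$sim_tir_len,
                                     orf_aa = config$sim_orf_aa,
                                     spacer23 = config$spacer23)
  planted <- plant_family(base_genome, ancestor, config$sim_bursts, seed = seed + 2L)
  genome <- planted$genome
  truth <- planted$truth
  write_fasta(genome, file.path(config$out_dir, "genome.fa"))
  write_stage(truth, config$out_dir, "truth")
  genes <- make_gene_models(genome, n_genes = config$sim_n_genes, seed = seed + 3L)
  write_stage(genes, config$out_dir, "genes")
  states <- make_chromatin_states(genome, n_states = config$sim_n_states,
                                  seed = seed + 4L)
  write_stage(states, config$out_dir, "states")
  sim <- simulate_sites(genome, genes, n_sites = config$sim_n_sites,
                        genic_fold = config$sim_genic_fold, sample_label = "PS",
                        seed = seed + 5L)
  sites <- sim$sites
  write_sites_bed(sites, file.path(config$out_dir, "sites.bed"))
  note("simulate", nrow(truth) + nrow(sites), nrow(truth) + nrow(sites))

  # --- discover ---
  hits <- truth_to_hits(truth, seed = seed + 6L)
  write_stage(hits, config$out_dir, "hits")
  copies <- discover_elements(hits, genome, max_gap = config$max_gap,
                              max_evalue = config$max_evalue,
                              flank_size = config$flank_size,
                              boundary_slop = config$boundary_slop,
                              ta_bonus = config$ta_bonus)
  write_stage(dplyr::select(copies, -"element_seq"), config$out_dir, "copies")
  write_fasta(setNames(copies$element_seq, copies$copy_id),
              file.path(config$out_dir, "elements.fa"))
  note("discover", nrow(hits), nrow(copies))

  # --- annotate ---
  classified <- classify_copies(copies, min_aa = config$min_aa,
                                spacer23 = config$spacer23)
  write_stage(dplyr::select(classified, -"element_seq"), config$out_dir,
              "classification")
  note("annotate", nrow(copies), nrow(classified))

  # --- dynamics ---
  intact_seqs <- classified$element_seq[classified$category == "intact"]
  cons <- build_consensus(intact_seqs)
  write_fasta(c(consensus = cons$sequence), file.path(config$out_dir, "consensus.fa"))
  all_seqs <- setNames(classified$element_seq, classified$copy_id)
  div <- divergence_from_consensus(all_seqs, cons)
  div <- flag_young(div, threshold = config$young_threshold)
  write_stage(div, config$out_dir, "divergence")
  ls <- landscape(div, bin_width = config$bin_width)
  write_stage(ls, config$out_dir, "landscape")
  stats <- copy_family_stats(classified$element_seq, cons$sequence)
  n_family <- count_copies(stats, config$min_coverage, config$min_identity)
  intact_cls <- classified[classified$category == "intact", , drop = FALSE]
  summary_row <- tibble(
    total_copies = n_family, intact_copies = nrow(intact_cls),
    consensus_length = nchar(cons$sequence),
    transposase_aa = stats::median(intact_cls$orf_aa),
    recently_active = attr(div, "recently_active")
  )
  write_stage(summary_row, config$out_dir, "family_summary")
  note("dynamics", nrow(classified), nrow(div))

  # --- insertions ---
  random_sites <- generate_random_loci(genome, n = config$n_random,
                                       seed = seed + 7L, mode = config$random_mode)
  fd <- feature_distribution(sites, genes, random_sites,
                             promoter_bp = config$promoter_bp,
                             downstream_bp = config$downstream_bp)
  write_stage(fd, config$out_dir, "feature_distribution")
  dec <- gene_body_decile(sites, genes)
  write_stage(dec, config$out_dir, "gene_body_decile")
  tp <- tss_profile(sites, genes, halfwidth = config$tss_halfwidth,
                    bin_bp = config$tss_bin_bp)
  write_stage(tp, config$out_dir, "tss_profile")
  ef <- expression_binned_frequency(sites, genes, n_groups = config$n_groups)
  write_stage(ef, config$out_dir, "expression_groups")
  en <- chromatin_state_enrichment(sites, states, random_sites)
  write_stage(en, config$out_dir, "state_enrichment")
  tsm <- target_site_matrix(sites, genome)
  write_stage(tidy(tsm), config$out_dir, "target_site_matrix")
  note("insertions", nrow(sites), nrow(sites))

  report <- dplyr::bind_rows(report)
  write_stage(report, config$out_dir, "report")
  attr(report, "outputs") <- list(
    truth = truth, copies = classified, consensus = cons, divergence = div,
    landscape = ls, family_summary = summary_row, feature_distribution = fd,
    decile = dec, tss_profile = tp, expression_groups = ef,
    state_enrichment = en, target_site = tsm)
  invisible(report)
}
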