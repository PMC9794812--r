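#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()], with any
#' supplied entries overriding the defaults.  The single global `seed`
#' is fanned out to per-stage seeds by fixed offsets (genome +1,
#' methylation +2, fragments +3), so one seed reproduces a whole run.
#'
#' @param ... named overrides, or a single list of them.
#' @return configuration list.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  cfg <- list(
    mode = "exo",
    seed = 1L,
    out_dir = "dna6ma_run",
    force = FALSE,
    # simulation stage (ignored when genome_fasta/alignments given)
    genome_fasta = NULL,
    alignments = NULL,
    dedup = FALSE,
    n_contigs = 1L,
    genome_length = 100000L,
    gc = 0.5,
    motif = list(name = "GATC", pattern = "GATC", methyl_offset = 1L,
                 both_strands = TRUE),
    methyl_fraction_of_motifs = 1.0,
    depth = 30,
    n_fragments = NULL,
    capture_prob = 0.5,
    frag_len_mean = 200L,
    frag_len_sd = 50L,
    endo_cut_offset = 0L,
    # caller stage
    coverage_cutoff = 5L,
    alpha = 0.01,
    correction = "bonferroni",
    require_A = TRUE,
    edge_exclude = 500L,
    # optional annotations
    tss = NULL,
    tss_format = "tsv",
    peaks = NULL,
    blacklist = NULL,
    flank = 5L
  )
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()].
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Run the full pipeline
#'
#' simulate (or load) -> count -> call -> annotate, writing all outputs
#' and a manifest (parameters, seed, md5 checksums, package version)
#' into `out_dir`.  Identical configuration and seed produce
#' byte-identical call files.
#'
#' @param config list from [pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  config <- pipeline_config(config)
  out <- config$out_dir
  manifest_path <- file.path(out, "manifest.json")
  if (file.exists(manifest_path) && !isTRUE(config$force))
    stop("output directory already contains a run; use force = TRUE")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  mode <- match.arg(config$mode, c("endo", "exo"))
  seed <- as.integer(config$seed)
  files <- character()
  t0 <- Sys.time()
  stage <- function(msg) message(sprintf("[dna6ma %s] %s",
                                         format(Sys.time() - t0), msg))

  rule <- do.call(motif_rule, config$motif)

  if (!is.null(config$genome_fasta)) {
    stage(paste("reading genome from", config$genome_fasta))
    genome <- read_fasta(config$genome_fasta)
    truth <- NULL
  } else {
    stage("simulating genome")
    genome <- simulate_genome(config$n_contigs, config$genome_length,
                              config$gc, seed = seed + 1L)
    files["genome"] <- write_fasta(genome, file.path(out, "genome.fa"))
    stage("planting methylation")
    truth <- plant_methylation(genome, rule,
                               config$methyl_fraction_of_motifs,
                               seed = seed + 2L)
    files["truth"] <- write_truth_bed(truth, file.path(out, "truth.bed"))
  }

  if (!is.null(config$alignments)) {
    stage(paste("reading alignments from", config$alignments))
    aln <- read_alignments(config$alignments, genome)
    if (isTRUE(config$dedup)) aln <- dedup_alignments(aln)
  } else {
    nfrag <- if (is.null(config$n_fragments))
      fragments_for_depth(config$depth, genome, config$frag_len_mean)
    else as.integer(config$n_fragments)
    scfg <- sim_config(nfrag, config$capture_prob, config$frag_len_mean,
                       config$frag_len_sd, config$endo_cut_offset,
                       seed = seed + 3L)
    stage(sprintf("simulating %d fragments (%s mode)", nfrag, mode))
    aln <- if (mode == "endo")
      simulate_fragments_endo(genome, truth, scfg)
    else simulate_fragments_exo(genome, truth, scfg)
    files["alignments"] <- write_alignments(
      aln, file.path(out, "alignments.tsv"))
  }

  stage("counting terminals")
  counts <- count_terminals(aln, mode, genome)
  files["counts"] <- write_counts(counts, file.path(out, "counts.tsv"))

  stage("calling sites")
  bg <- estimate_background(counts)
  ccfg <- caller_config(config$coverage_cutoff, config$alpha,
                        config$correction, config$require_A,
                        config$edge_exclude)
  calls <- call_sites(counts, bg, genome, ccfg)
  if (!is.null(config$blacklist)) {
    bl <- read_regions_bed(config$blacklist)
    calls <- filter_blacklist(calls, bl)
  }
  files["calls_tsv"] <- write_calls_tsv(calls, file.path(out, "calls.tsv"))
  files["calls_bed"] <- write_calls_bed(calls, file.path(out, "calls.bed"))

  stage("annotating")
  ms <- motif_summary(calls, genome, list(rule), flank = config$flank)
  annotation <- list(
    motif_summary = list(total_sites = ms$total_sites,
                         excluded_edge = ms$excluded_edge,
                         fraction_matching = as.list(ms$fraction_matching),
                         base_freq = ms$base_freq)
  )
  if (is_palindromic(rule$pattern) && rule$both_strands) {
    sym <- classify_symmetry(calls, genome, rule)
    annotation$symmetry <- as.list(table(sym$status))
    files["symmetry"] <- file.path(out, "symmetry.tsv")
    write.table(sym, files["symmetry"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(config$tss)) {
    tss <- read_tss(config$tss, config$tss_format)
    prof <- tss_profile(calls, tss)
    annotation$tss <- list(dominant_period = prof$dominant_period,
                           period_score = prof$period_score)
    files["tss_histogram"] <- file.path(out, "tss_histogram.tsv")
    write.table(prof$histogram, files["tss_histogram"], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(config$peaks)) {
    pk <- read_regions_bed(config$peaks)
    annotation$peaks <- sites_in_regions(calls, pk)
  }
  files["annotation"] <- file.path(out, "annotation.json")
  jsonlite::write_json(annotation, files["annotation"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)

  manifest <- list(
    package = "dna6ma",
    version = as.character(packageVersion("dna6ma")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    mode = mode,
    parameters = config[setdiff(names(config), c("force"))],
    background_p0 = bg$p0,
    n_tested = attr(calls, "m"),
    n_passed = sum(calls$passed),
    outputs = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  stage(sprintf("done: %d/%d tested positions passed",
                manifest$n_passed, manifest$n_tested))
  invisible(manifest)
}
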