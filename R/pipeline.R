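#' Configuration of an end-to-end run
#'
#' Collects every constant the pipeline uses; the defaults are the ones
#' the analyses are defined with: 150-bp read extension, 147-bp GC window,
#' 300-bp fragment-length pairing window, +/-2000-bp GC-profile flank with
#' 3-bp smoothing, 5-mers, and a 140-170 bp size-selection band inside
#' [digestion_params()].
#'
#' @param seed Global integer seed; per-stage seeds are derived from it
#'   deterministically, so stages can be re-run in isolation.
#' @param genome Either `NULL` (the [demo_composition_plan()] genome is
#'   generated), a [composition_plan()], or a path to a FASTA file.
#' @param digestion A [digestion_params()]; its `seed` is overridden by
#'   the derived stage seed.
#' @param extension Read-extension footprint in bp.
#' @param gc_window GC window width in bp.
#' @param kmer_k K-mer length.
#' @param profile_flank,profile_smooth GC-profile half-width and
#'   moving-average width in bp.
#' @param fraglen_window Pairing window of the fragment-length estimate.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, genome = NULL,
                       digestion = digestion_params(),
                       extension = 150L, gc_window = 147L, kmer_k = 5L,
                       profile_flank = 2000L, profile_smooth = 3L,
                       fraglen_window = 300L) {
  stopifnot(is_count(seed), inherits(digestion, "digestion_params"))
  structure(list(seed = as.integer(seed), genome = genome,
                 digestion = digestion, extension = as.integer(extension),
                 gc_window = as.integer(gc_window), kmer_k = as.integer(kmer_k),
                 profile_flank = as.integer(profile_flank),
                 profile_smooth = as.integer(profile_smooth),
                 fraglen_window = as.integer(fraglen_window)),
            class = "run_config")
}

#' Run the whole naked-DNA digestion-bias pipeline
#'
#' Executes, in order: genome acquisition (generate or read), MNase
#' digestion with size selection, single-end read emission, fragment
#' length estimation, coverage pileup, linear and log2 normalization,
#' windowed GC track (plain and centered), read-aligned GC profile, k-mer
#' relative coverage, and the coverage-vs-GC correlation. Every
#' intermediate is written to `out_dir` and a JSON manifest records the
#' resolved configuration, seed and summary statistics.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if absent).
#' @return The manifest, invisibly (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(i, what) {
    message(sprintf("[%s] stage %d: %s", format(Sys.time(), "%H:%M:%S"), i, what))
  }
  fail <- function(name, e) stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))

  stage(1, "genome")
  genome <- tryCatch({
    if (is.null(config$genome)) {
      generate_genome(demo_composition_plan(seed = derive_seed(config$seed, 1L)))
    } else if (inherits(config$genome, "composition_plan")) {
      generate_genome(config$genome)
    } else {
      read_fasta(config$genome)
    }
  }, error = function(e) fail("genome", e))
  write_fasta(genome, file.path(out_dir, "genome.fa"))

  stage(2, "digestion + size selection")
  dg <- config$digestion
  dg$seed <- derive_seed(config$seed, 2L)
  fragments <- tryCatch(simulate_digestion(genome, dg),
                        error = function(e) fail("digestion", e))
  if (!nrow(fragments)) stopf("pipeline stage 'digestion' failed: no fragments survived size selection")
  write_fragments_bed(fragments, file.path(out_dir, "fragments.bed"))
  message(sprintf("  %d fragments retained in [%d, %d] bp", nrow(fragments),
                  dg$size_min, dg$size_max))

  stage(3, "read emission")
  reads <- tryCatch(emit_reads(fragments, seed = derive_seed(config$seed, 3L)),
                    error = function(e) fail("reads", e))
  write_reads_bed(reads, file.path(out_dir, "reads.bed"))

  stage(4, "fragment length estimate")
  fl <- tryCatch(estimate_fragment_length(reads, window = config$fraglen_window),
                 error = function(e) fail("fraglen", e))
  utils::write.table(fl$histogram, file.path(out_dir, "fraglen_histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  stage(5, "coverage pileup + normalization")
  cov_raw <- tryCatch(pileup(reads, genome, extension = config$extension),
                      error = function(e) fail("pileup", e))
  cov_lin <- normalize_linear(cov_raw)
  cov_log <- normalize_log2(cov_raw)
  write_track(cov_raw, file.path(out_dir, "coverage_raw.bedgraph"))
  write_track(cov_lin, file.path(out_dir, "coverage_linear.bedgraph"))
  write_track(cov_log, file.path(out_dir, "coverage_log2.bedgraph"))

  stage(6, "GC tracks")
  gc_frac <- tryCatch(gc_window_track(genome, window = config$gc_window),
                      error = function(e) fail("gc_window", e))
  gc_cent <- gc_window_track(genome, window = config$gc_window, centered = TRUE)
  write_track(gc_frac, file.path(out_dir, "gc147.bedgraph"))
  write_track(gc_cent, file.path(out_dir, "gc147_centered.bedgraph"))

  stage(7, "GC profile around read starts")
  prof <- tryCatch(gc_profile_around_read_starts(genome, reads,
                                                 flank = config$profile_flank,
                                                 smooth = config$profile_smooth),
                   error = function(e) fail("gc_profile", e))
  utils::write.table(as.data.frame(prof), file.path(out_dir, "gc_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  stage(8, "k-mer relative coverage")
  km <- tryCatch(kmer_mean_coverage(cov_lin, genome, k = config$kmer_k),
                 error = function(e) fail("kmers", e))
  write_kmer_table(km, file.path(out_dir, "kmers.tsv"))

  stage(9, "comparisons")
  corr <- tryCatch(correlate_tracks(cov_log, gc_cent),
                   error = function(e) fail("correlation", e))

  frag_gc <- fragment_gc(fragments, genome)
  km_ord <- km[order(km$mean_coverage), ]
  manifest <- list(
    package = "mnasebias",
    version = as.character(utils::packageVersion("mnasebias")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = list(
      extension = config$extension, gc_window = config$gc_window,
      kmer_k = config$kmer_k, profile_flank = config$profile_flank,
      profile_smooth = config$profile_smooth,
      fraglen_window = config$fraglen_window,
      digestion = unclass(dg)),
    stats = list(
      n_chromosomes = length(genome),
      genome_length = sum(chrom_lengths(genome)),
      genome_gc = gc_fraction(genome),
      n_fragments = nrow(fragments),
      mean_fragment_length = mean(fragment_lengths(fragments)),
      fragment_gc = mean(frag_gc),
      fragment_gc_excess = mean(frag_gc) - gc_fraction(genome),
      estimated_fragment_length = fl$mean_length,
      mean_coverage = attr(track_info(cov_raw), "genome_mean"),
      coverage_gc_correlation_r = corr$r,
      coverage_gc_correlation_n = corr$n_positions,
      lowest_kmers = utils::head(km_ord$kmer, 5L),
      highest_kmers = utils::tail(km_ord$kmer, 5L)))
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
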