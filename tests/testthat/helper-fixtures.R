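# Shared fixtures: everything is generated in code at test time.

# A single-chromosome genome of uniform composition.
uniform_genome <- function(length = 10000L, gc = 0.4, seed = 1L, name = "chrI") {
  generate_genome(composition_plan(
    list(chromosome_plan(name, data.frame(length = length, gc = gc))),
    seed = seed))
}

# A genome built from literal strings.
genome_from_strings <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

# Reference pileup: one read at a time, one base at a time.
brute_force_pileup <- function(reads, genome, extension = 150L) {
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  values <- lapply(lens, function(L) numeric(L))
  for (i in seq_len(nrow(reads))) {
    ch <- reads$chrom[i]
    p <- reads$pos[i]
    rng <- if (reads$strand[i] == "+") p:(p + extension - 1L)
           else (p - extension + 1L):p
    rng <- rng[rng >= 0L & rng < lens[[ch]]]
    for (j in rng) values[[ch]][j + 1L] <- values[[ch]][j + 1L] + 1
  }
  values
}

# A random raw-counts track with a given undefined fraction.
random_track <- function(genome, seed = 1L, p_na = 0.2) {
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  set.seed(seed)
  values <- lapply(lens, function(L) {
    v <- stats::rpois(L, 3) + stats::runif(L)
    v[stats::runif(L) < p_na] <- NA_real_
    v
  })
  genome_track(values, state = "raw_counts")
}

derive_seed_for_test <- function(seed, stage) {
  mnasebias:::derive_seed(seed, stage)
}

# Pooled mean over defined positions.
track_mean_for_test <- function(track) {
  mean(unlist(track$values, use.names = FALSE), na.rm = TRUE)
}

# Digestion, reads and raw coverage for one replicate on a genome.
simulate_coverage <- function(genome, params, read_seed = params$seed + 1L,
                              extension = 150L) {
  frags <- simulate_digestion(genome, params)
  reads <- emit_reads(frags, seed = read_seed)
  suppressMessages(pileup(reads, genome, extension = extension))
}
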