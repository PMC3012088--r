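#' Describe a synthetic genome by composition
#'
#' A composition plan specifies, chromosome by chromosome, the background
#' base composition (as segments with a GC fraction each) and literal motifs
#' to embed at fixed positions, e.g. poly(dA) tracts or a GC-rich
#' regulatory element. [generate_genome()] realizes the plan into sequence.
#'
#' @param chromosomes A list of chromosome descriptions, each created by
#'   [chromosome_plan()].
#' @param seed Integer seed; the same plan always realizes the same genome.
#' @return An object of class `composition_plan`.
#' @seealso [generate_genome()], [demo_composition_plan()]
#' @export
composition_plan <- function(chromosomes, seed = 1L) {
  if (!length(chromosomes)) stopf("a composition plan needs at least one chromosome")
  nm <- vapply(chromosomes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stopf("duplicated chromosome name(s): %s",
                               paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (!is_count(seed)) stopf("'seed' must be a positive integer")
  structure(list(chromosomes = chromosomes, seed = as.integer(seed)),
            class = "composition_plan")
}

#' @rdname composition_plan
#' @param name Chromosome name.
#' @param segments Data frame with columns `length` (bp, positive) and `gc`
#'   (target GC fraction in \[0, 1\]); segments are concatenated in order.
#' @param motifs Optional data frame with columns `position` (0-based start)
#'   and `sequence` (text over A/C/G/T); motifs overwrite the background
#'   bases and must not overlap each other or run past the chromosome end.
#' @export
chromosome_plan <- function(name, segments, motifs = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  segments <- as.data.frame(segments)
  if (!all(c("length", "gc") %in% names(segments)))
    stopf("'segments' needs columns 'length' and 'gc'")
  if (any(segments$length <= 0) || any(segments$length != floor(segments$length)))
    stopf("segment lengths must be positive integers")
  if (any(segments$gc < 0 | segments$gc > 1))
    stopf("segment gc fractions must lie in [0, 1]")
  total <- sum(segments$length)
  if (!is.null(motifs) && nrow(as.data.frame(motifs))) {
    motifs <- as.data.frame(motifs, stringsAsFactors = FALSE)
    if (!all(c("position", "sequence") %in% names(motifs)))
      stopf("'motifs' needs columns 'position' and 'sequence'")
    motifs$sequence <- toupper(motifs$sequence)
    if (any(grepl("[^ACGT]", motifs$sequence)))
      stopf("motif sequences must use only A, C, G, T")
    ends <- motifs$position + nchar(motifs$sequence)
    if (any(motifs$position < 0) || any(ends > total))
      stopf("motif on '%s' extends past the chromosome end (length %d)", name, total)
    o <- order(motifs$position)
    if (any(ends[o][-length(o)] > motifs$position[o][-1]))
      stopf("motifs on '%s' overlap", name)
    motifs <- motifs[o, , drop = FALSE]
  } else {
    motifs <- data.frame(position = integer(0), sequence = character(0))
  }
  list(name = name, segments = segments, motifs = motifs, length = total)
}

#' Realize a composition plan into a genome
#'
#' Background bases are drawn i.i.d. within each segment with
#' P(G) = P(C) = gc/2 and P(A) = P(T) = (1 - gc)/2, then motifs overwrite
#' the drawn bases at their positions. Output never contains ambiguity
#' codes.
#'
#' @param plan A [composition_plan()].
#' @return A [Biostrings::DNAStringSet] with one entry per chromosome.
#' @examples
#' plan <- composition_plan(list(
#'   chromosome_plan("chrI", data.frame(length = 500, gc = 0.4))), seed = 7)
#' gen <- generate_genome(plan)
#' gc_fraction(gen)
#' @export
generate_genome <- function(plan) {
  stopifnot(inherits(plan, "composition_plan"))
  bases <- c("A", "C", "G", "T")
  seqs <- with_seed(plan$seed, {
    vapply(plan$chromosomes, function(ch) {
      drawn <- unlist(lapply(seq_len(nrow(ch$segments)), function(i) {
        gc <- ch$segments$gc[i]
        sample(bases, ch$segments$length[i], replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
      }), use.names = FALSE)
      for (j in seq_len(nrow(ch$motifs))) {
        m <- ch$motifs[j, ]
        idx <- seq.int(m$position + 1L, m$position + nchar(m$sequence))
        drawn[idx] <- strsplit(m$sequence, "")[[1]]
      }
      paste(drawn, collapse = "")
    }, character(1))
  })
  names(seqs) <- vapply(plan$chromosomes, `[[`, character(1), "name")
  Biostrings::DNAStringSet(seqs)
}

#' A 100-kb demonstration genome plan
#'
#' Two chromosomes totalling 100 kb at a background GC of 0.40 (close to
#' the 0.383 of the budding-yeast genome), with embedded poly(dA) and
#' poly(dT) tracts and three GC-rich elements standing in for
#' nucleosome-depleted regulatory sequence such as the Gal1-10 UAS.
#' These are the composition contrasts the digestion-bias analyses probe:
#' AT tracts are depleted of size-selected fragments, GC elements enriched.
#'
#' @param seed Integer seed used both to place the GC-element sequences and
#'   to realize the genome.
#' @param gc Background GC fraction.
#' @return A [composition_plan()].
#' @export
demo_composition_plan <- function(seed = 1L, gc = 0.40) {
  tract <- function(base, len) strrep(base, len)
  gc_elem <- function(s, len = 300L, elem_gc = 0.85) {
    with_seed(s, paste(sample(c("G", "C", "A", "T"), len, replace = TRUE,
                              prob = c(elem_gc / 2, elem_gc / 2,
                                       (1 - elem_gc) / 2, (1 - elem_gc) / 2)),
                       collapse = ""))
  }
  pos1 <- seq(1500L, by = 1900L, length.out = 30L)
  chr1 <- chromosome_plan(
    "chrI", data.frame(length = 60000L, gc = gc),
    motifs = data.frame(position = pos1,
                        sequence = tract(rep(c("A", "T"), 15L), 50L)))
  pos2 <- seq(1200L, by = 1700L, length.out = 20L)
  chr2 <- chromosome_plan(
    "chrII", data.frame(length = 40000L, gc = gc),
    motifs = data.frame(
      position = c(pos2, 35000L, 36500L, 38000L),
      sequence = c(tract(rep(c("A", "T"), 10L), 50L),
                   gc_elem(derive_seed(seed, 101L)),
                   gc_elem(derive_seed(seed, 102L)),
                   gc_elem(derive_seed(seed, 103L)))))
  composition_plan(list(chr1, chr2), seed = seed)
}

#' GC fraction of a genome
#'
#' Fraction of G/C among non-N bases, pooled over all chromosomes.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @return A number in \[0, 1\].
#' @export
gc_fraction <- function(genome) {
  gc <- sum(Biostrings::letterFrequency(genome, "CG"))
  acgt <- sum(Biostrings::letterFrequency(genome, "ACGT"))
  if (acgt == 0) stopf("genome contains no A/C/G/T bases")
  gc / acgt
}

#' Read a genome FASTA
#'
#' Lowercase bases are accepted and uppercased; characters outside
#' A/C/G/T/N are rejected. Record names are the first whitespace-delimited
#' token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(nm))) stopf("FASTA record with an empty header in '%s'", path)
  if (anyDuplicated(nm))
    stopf("duplicated FASTA header(s): %s",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (any(Biostrings::width(x) == 0))
    stopf("empty sequence for record(s): %s", paste(nm[Biostrings::width(x) == 0], collapse = ", "))
  chars <- toupper(as.character(x))
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad))
    stopf("record(s) with characters outside A/C/G/T/N: %s",
          paste(nm[bad], collapse = ", "))
  out <- Biostrings::DNAStringSet(chars)
  names(out) <- nm
  out
}

#' Write a genome FASTA (wrapped at 60 columns)
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}
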