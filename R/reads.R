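#' Sequence one random end of each fragment
#'
#' Emulates single-end sequencing of size-selected fragments: for each
#' fragment, with probability 1/2 a plus-strand read starting at the
#' fragment's leftmost base is emitted, otherwise a minus-strand read
#' starting at its rightmost base. Exactly one read per fragment.
#'
#' @param fragments A `fragment_set` (0-based half-open intervals).
#' @param seed Integer seed.
#' @return A `read_starts` data frame with columns `chrom`, `pos` (0-based
#'   coordinate of the read's 5'-most base) and `strand` (`"+"`/`"-"`).
#' @export
emit_reads <- function(fragments, seed = 1L) {
  if (!nrow(fragments)) stopf("no fragments to sequence")
  with_seed(seed, {
    plus <- stats::runif(nrow(fragments)) < 0.5
    read_starts(chrom = fragments$chrom,
                pos = ifelse(plus, fragments$start, fragments$end - 1L),
                strand = ifelse(plus, "+", "-"))
  })
}

#' Construct a table of single-end read starts
#'
#' @param chrom Chromosome names.
#' @param pos 0-based position of each read's 5'-most genome coordinate.
#' @param strand `"+"` or `"-"` per read.
#' @param genome Optional [Biostrings::DNAStringSet]; if given, chromosome
#'   names and positions are validated against it.
#' @return A `read_starts` data frame.
#' @export
read_starts <- function(chrom, pos, strand, genome = NULL) {
  if (!all(strand %in% c("+", "-")))
    stopf("malformed strand value(s): %s",
          paste(unique(setdiff(strand, c("+", "-"))), collapse = ", "))
  pos <- as.integer(pos)
  if (any(pos < 0)) stopf("read positions must be >= 0")
  if (!is.null(genome)) {
    unknown <- setdiff(unique(chrom), names(genome))
    if (length(unknown))
      stopf("read(s) on chromosome(s) absent from the genome: %s",
            paste(unknown, collapse = ", "))
    lens <- chrom_lengths(genome)
    if (any(pos >= lens[chrom]))
      stopf("read position(s) beyond chromosome end")
  }
  out <- data.frame(chrom = as.character(chrom), pos = pos,
                    strand = as.character(strand), stringsAsFactors = FALSE)
  class(out) <- c("read_starts", "data.frame")
  out
}

#' Read mapped single-end read starts from BED6
#'
#' Each BED line contributes one record at its 5' coordinate: `chromStart`
#' for plus-strand reads, `chromEnd - 1` for minus-strand reads.
#'
#' @param path Path to a 6-column BED file.
#' @param genome A [Biostrings::DNAStringSet] naming the valid chromosomes.
#' @return A `read_starts` data frame.
#' @export
read_read_starts <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "BED")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(chrom), names(genome))
  if (length(unknown))
    stopf("BED file '%s' refers to chromosome(s) absent from the genome: %s",
          path, paste(unknown, collapse = ", "))
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stopf("BED file '%s' has read(s) without a +/- strand", path)
  pos <- ifelse(strand == "+",
                GenomicRanges::start(gr) - 1L, # back to 0-based
                GenomicRanges::end(gr) - 1L)
  read_starts(chrom, pos, strand, genome = genome)
}

#' Write read starts as BED6
#'
#' Each read becomes a single-base interval at its start coordinate, name
#' ".", score 0, strand in column 6.
#'
#' @param reads A `read_starts` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  gr <- GenomicRanges::GRanges(reads$chrom,
                               IRanges::IRanges(reads$pos + 1L, width = 1L),
                               strand = reads$strand)
  gr$name <- "."
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Fragment BED3 input/output
#'
#' @param fragments A `fragment_set`.
#' @param path File path.
#' @param genome Optional [Biostrings::DNAStringSet] for validation.
#' @return `write_fragments_bed()` returns `path` invisibly;
#'   `read_fragments_bed()` returns a `fragment_set`.
#' @export
write_fragments_bed <- function(fragments, path) {
  gr <- GenomicRanges::GRanges(fragments$chrom,
                               IRanges::IRanges(fragments$start + 1L,
                                                fragments$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_fragments_bed
#' @export
read_fragments_bed <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  if (!is.null(genome)) {
    unknown <- setdiff(unique(chrom), names(genome))
    if (length(unknown))
      stopf("BED file '%s' refers to chromosome(s) absent from the genome: %s",
            path, paste(unknown, collapse = ", "))
  }
  out <- data.frame(chrom = chrom,
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  class(out) <- c("fragment_set", "data.frame")
  out
}
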