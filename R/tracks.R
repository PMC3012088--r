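#' Per-base genome tracks
#'
#' A `genome_track` holds one real value per base per chromosome, with `NA`
#' marking undefined positions, plus a `state` tag describing what the
#' values are:
#' \describe{
#'   \item{`raw_counts`}{nonnegative per-base counts (zero is a defined
#'     value);}
#'   \item{`linear_normalized`}{counts divided by the genome-wide mean
#'     (mean 1);}
#'   \item{`log2_centered`}{binary log of the values, mean-centered over
#'     defined positions (mean 0); zeros became undefined when the log was
#'     taken;}
#'   \item{`fraction`}{values in \[0, 1\], e.g. windowed GC content.}
#' }
#'
#' @param values Named list (one entry per chromosome) of numeric vectors;
#'   `NA` marks undefined positions.
#' @param state One of `"raw_counts"`, `"linear_normalized"`,
#'   `"log2_centered"`, `"fraction"`.
#' @return An object of class `genome_track`.
#' @export
genome_track <- function(values, state = c("raw_counts", "linear_normalized",
                                           "log2_centered", "fraction")) {
  state <- match.arg(state)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stopf("'values' must be a named list of per-chromosome vectors")
  values <- lapply(values, as.numeric)
  for (ch in names(values)) {
    v <- values[[ch]]
    if (any(is.infinite(v) | is.nan(v)))
      stopf("non-finite defined value(s) on '%s'", ch)
    if (state == "raw_counts" && any(v < 0, na.rm = TRUE))
      stopf("raw_counts track has negative value(s) on '%s'", ch)
  }
  structure(list(values = values, state = state), class = "genome_track")
}

#' @rdname genome_track
#' @param track A `genome_track`.
#' @export
track_state <- function(track) track$state

#' @rdname genome_track
#' @param chrom Chromosome name; if `NULL`, the full named list is returned.
#' @export
track_values <- function(track, chrom = NULL) {
  if (is.null(chrom)) track$values else track$values[[chrom]]
}

#' @rdname genome_track
#' @export
defined_mask <- function(track, chrom = NULL) {
  if (is.null(chrom)) lapply(track$values, function(v) !is.na(v))
  else !is.na(track$values[[chrom]])
}

# Mean over defined positions, pooled genome-wide.
track_mean <- function(track) {
  v <- unlist(track$values, use.names = FALSE)
  if (!any(!is.na(v))) stopf("track has no defined positions")
  mean(v, na.rm = TRUE)
}

#' @export
print.genome_track <- function(x, ...) {
  cat(sprintf("genome_track (state: %s), %d chromosome(s)\n",
              x$state, length(x$values)))
  print(track_info(x))
  invisible(x)
}

#' Per-chromosome track summary
#'
#' @param track A `genome_track`.
#' @return A data frame with one row per chromosome (length, defined
#'   fraction, mean over defined positions) plus the genome-wide mean as an
#'   attribute `genome_mean`.
#' @export
track_info <- function(track) {
  out <- data.frame(
    chrom = names(track$values),
    length = vapply(track$values, length, integer(1)),
    defined_fraction = vapply(track$values,
                              function(v) mean(!is.na(v)), numeric(1)),
    mean = vapply(track$values, function(v)
      if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "genome_mean") <- mean(unlist(track$values, use.names = FALSE),
                                   na.rm = TRUE)
  out
}

#' Write a track to bedGraph or wiggle
#'
#' bedGraph output is run-length merged: consecutive bases with the same
#' value share one interval. Undefined positions are omitted and are
#' restored as undefined when the file is read back. Wiggle output is
#' per-base variableStep.
#'
#' @param track A `genome_track`.
#' @param path Output path.
#' @param format `"bedgraph"` or `"wiggle"`.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("bedgraph", "wiggle")) {
  format <- match.arg(format)
  chroms <- names(track$values)
  grs <- lapply(chroms, function(ch) {
    r <- S4Vectors::Rle(track$values[[ch]])
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r) + 1L
    keep <- !is.na(S4Vectors::runValue(r))
    GenomicRanges::GRanges(factor(rep(ch, sum(keep)), levels = chroms),
                           IRanges::IRanges(starts[keep], ends[keep]),
                           score = S4Vectors::runValue(r)[keep])
  })
  gr <- do.call(c, grs)
  if (format == "bedgraph") {
    rtracklayer::export(gr, path, format = "bedGraph")
  } else {
    # wiggle export needs a uniform span; expand runs to single bases
    pos <- do.call(c, lapply(grs, function(g) {
      w <- GenomicRanges::width(g)
      GenomicRanges::GRanges(
        factor(rep(as.character(GenomicRanges::seqnames(g)), w),
               levels = chroms),
        IRanges::IRanges(
          unlist(mapply(seq.int, GenomicRanges::start(g),
                        GenomicRanges::end(g), SIMPLIFY = FALSE)),
          width = 1L),
        score = rep(g$score, w))
    }))
    rtracklayer::export(pos, path, format = "wig")
  }
  invisible(path)
}

#' Read a track from bedGraph or wiggle
#'
#' Positions not covered by any interval come back undefined. Overlapping
#' intervals are an error.
#'
#' @param path Input path.
#' @param genome A [Biostrings::DNAStringSet] supplying chromosome names
#'   and lengths.
#' @param format `"bedgraph"` or `"wiggle"`.
#' @param state State tag to attach to the result (the file formats do not
#'   record it).
#' @return A `genome_track`.
#' @export
read_track <- function(path, genome, format = c("bedgraph", "wiggle"),
                       state = "raw_counts") {
  format <- match.arg(format)
  gr <- rtracklayer::import(path,
                            format = if (format == "bedgraph") "bedGraph" else "wig")
  if (!all(IRanges::isDisjoint(GenomicRanges::split(GenomicRanges::ranges(gr),
                                                    GenomicRanges::seqnames(gr)))))
    stopf("'%s' has overlapping intervals", path)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(chrom), names(genome))
  if (length(unknown))
    stopf("'%s' refers to chromosome(s) absent from the genome: %s",
          path, paste(unknown, collapse = ", "))
  lens <- chrom_lengths(genome)
  if (any(GenomicRanges::end(gr) > lens[chrom]))
    stopf("'%s' has interval(s) beyond the chromosome end", path)
  values <- lapply(names(genome), function(ch) rep(NA_real_, lens[[ch]]))
  names(values) <- names(genome)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    s <- GenomicRanges::start(gr)[sel]; e <- GenomicRanges::end(gr)[sel]
    idx <- unlist(mapply(seq.int, s, e, SIMPLIFY = FALSE))
    values[[ch]][idx] <- rep(gr$score[sel], e - s + 1L)
  }
  genome_track(values, state = state)
}
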