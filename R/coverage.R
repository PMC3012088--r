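#' Build a raw coverage map by fixed-length read extension
#'
#' Each plus-strand read at position p contributes one count to every base
#' in `[p, p + extension)`; each minus-strand read contributes to
#' `(p - extension, p]` (0-based half-open frame). Extensions overhanging a
#' chromosome end are truncated (and reported via a message). All
#' positions of the result are defined; uncovered bases hold zero.
#'
#' @param reads A `read_starts` data frame.
#' @param genome A [Biostrings::DNAStringSet] giving the coordinate frame.
#' @param extension Footprint length in bp (default 150, the size-selected
#'   fragment scale).
#' @return A `genome_track` in `raw_counts` state.
#' @export
pileup <- function(reads, genome, extension = 150L) {
  if (!is_count(extension)) stopf("'extension' must be a positive integer")
  unknown <- setdiff(unique(reads$chrom), names(genome))
  if (length(unknown))
    stopf("read(s) on chromosome(s) absent from the genome: %s",
          paste(unknown, collapse = ", "))
  lens <- chrom_lengths(genome)
  plus <- reads$strand == "+"
  start1 <- ifelse(plus, reads$pos + 1L, reads$pos - extension + 2L)
  end1 <- ifelse(plus, reads$pos + extension, reads$pos + 1L)
  tstart <- pmax(start1, 1L)
  tend <- pmin(end1, lens[reads$chrom])
  overhang <- (tstart - start1) + (end1 - tend)
  if (any(overhang > 0))
    message(sprintf("pileup: truncated %d read extension(s) at chromosome ends (%d bases)",
                    sum(overhang > 0), sum(overhang)))
  gr <- GenomicRanges::GRanges(reads$chrom, IRanges::IRanges(tstart, tend),
                               seqlengths = lens)
  cov <- GenomicRanges::coverage(gr)
  values <- lapply(names(genome), function(ch) as.numeric(cov[[ch]]))
  names(values) <- names(genome)
  genome_track(values, state = "raw_counts")
}

#' Estimate the average fragment length from strand-paired read distances
#'
#' For every plus-strand read at p and every minus-strand read at q on the
#' same chromosome with `0 < q - p + 1 <= window`, the inclusive distance
#' `q - p + 1` (the length of a fragment whose two ends those reads would
#' mark) is added to a histogram; the estimate is the abundance-weighted
#' mean distance. The signal requires positionally clustered fragments
#' (see [simulate_positioned_fragments()]); on randomly placed fragments
#' the histogram is flat and the mean simply reflects the window.
#'
#' @param reads A `read_starts` data frame with reads on both strands.
#' @param window Maximum pairing distance in bp (default 300).
#' @return A `fragment_length_estimate`: list with `mean_length`,
#'   `histogram` (data frame `distance`, `count`) and `window`.
#' @export
estimate_fragment_length <- function(reads, window = 300L) {
  if (!is_count(window)) stopf("'window' must be a positive integer")
  if (!any(reads$strand == "+") || !any(reads$strand == "-"))
    stopf("need reads on both strands")
  counts <- numeric(window)
  for (ch in unique(reads$chrom)) {
    sel <- reads$chrom == ch
    p <- reads$pos[sel & reads$strand == "+"]
    q <- sort(reads$pos[sel & reads$strand == "-"])
    if (!length(p) || !length(q)) next
    # minus reads q with p <= q <= p + window - 1 pair with plus read p
    lo <- findInterval(p - 1L, q) + 1L
    hi <- findInterval(p + window - 1L, q)
    n <- pmax(hi - lo + 1L, 0L)
    keep <- n > 0L
    if (!any(keep)) next
    idx <- sequence(n[keep], from = lo[keep])
    d <- q[idx] - rep(p[keep], n[keep]) + 1L
    counts <- counts + tabulate(d, nbins = window)
  }
  total <- sum(counts)
  if (total == 0) stopf("no +/- pairs within window")
  structure(list(
    mean_length = sum(seq_len(window) * counts) / total,
    histogram = data.frame(distance = seq_len(window), count = counts)[counts > 0, ],
    window = as.integer(window)), class = "fragment_length_estimate")
}

#' @export
print.fragment_length_estimate <- function(x, ...) {
  cat(sprintf("fragment length estimate: %.2f bp (%d read pairs, window %d bp)\n",
              x$mean_length, sum(x$histogram$count), x$window))
  invisible(x)
}

#' Log2-transform and center a coverage track
#'
#' Counts are transformed by the binary logarithm and centered by
#' subtracting the mean transformed count pooled over all defined
#' positions genome-wide, so the genome-wide average of the result is
#' zero. Zero-count positions have no logarithm and become undefined; no
#' pseudocount is added.
#'
#' @param track A `genome_track` in `raw_counts` state.
#' @return A `genome_track` in `log2_centered` state.
#' @export
normalize_log2 <- function(track) {
  if (track_state(track) != "raw_counts")
    stopf("normalize_log2() expects a raw_counts track, got '%s'", track_state(track))
  lv <- lapply(track$values, function(v) {
    out <- rep(NA_real_, length(v))
    pos <- !is.na(v) & v > 0
    out[pos] <- log2(v[pos])
    out
  })
  all_v <- unlist(lv, use.names = FALSE)
  if (!any(!is.na(all_v)))
    stopf("cannot log-transform: all positions have zero coverage")
  m <- mean(all_v, na.rm = TRUE)
  genome_track(lapply(lv, function(v) v - m), state = "log2_centered")
}

#' Normalize a coverage track by the genome-wide average
#'
#' Every value is divided by the genome-wide mean count over all defined
#' positions (zeros included), so the genome-wide average of the result is
#' one; 1.0 is the reference level drawn as a dashed line in region
#' profiles. Zero stays a defined value.
#'
#' @param track A `genome_track` in `raw_counts` state.
#' @return A `genome_track` in `linear_normalized` state.
#' @export
normalize_linear <- function(track) {
  if (track_state(track) != "raw_counts")
    stopf("normalize_linear() expects a raw_counts track, got '%s'", track_state(track))
  m <- track_mean(track)
  if (m <= 0) stopf("cannot normalize: genome-wide mean coverage is zero")
  genome_track(lapply(track$values, function(v) v / m),
               state = "linear_normalized")
}
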