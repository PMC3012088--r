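#' Windowed GC-content track
#'
#' For every full window of `window` bases the fraction of G/C among its
#' non-N bases is assigned to the window's central base: with the default
#' 147-bp window (the nucleosomal footprint) the value at 0-based position
#' 73 describes bases 0..146. Positions whose window overhangs a
#' chromosome end are undefined, so every defined value is a same-width
#' statistic. With `centered = TRUE` the values are log2-transformed and
#' mean-centered over defined positions pooled genome-wide (windows with
#' zero GC have no logarithm and become undefined).
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param window Odd window width in bp (default 147).
#' @param centered If `TRUE`, return the log2-centered track.
#' @return A `genome_track` in `fraction` (or `log2_centered`) state.
#' @export
gc_window_track <- function(genome, window = 147L, centered = FALSE) {
  if (!is_count(window) || window %% 2L == 0L)
    stopf("'window' must be an odd positive integer")
  half <- (window - 1L) %/% 2L
  lens <- chrom_lengths(genome)
  values <- lapply(names(genome), function(ch) {
    L <- lens[[ch]]
    v <- rep(NA_real_, L)
    if (window > L) {
      warning(sprintf("window (%d bp) longer than chromosome '%s' (%d bp); all undefined",
                      window, ch, L))
      return(v)
    }
    m <- Biostrings::letterFrequencyInSlidingView(genome[[ch]], window, c("CG", "N"))
    denom <- window - m[, "N"]
    gcv <- ifelse(denom > 0, m[, "C|G"] / denom, NA_real_)
    v[seq_len(nrow(m)) + half] <- gcv
    v
  })
  names(values) <- names(genome)
  if (!centered) return(genome_track(values, state = "fraction"))
  lv <- lapply(values, function(v) {
    out <- rep(NA_real_, length(v))
    pos <- !is.na(v) & v > 0
    out[pos] <- log2(v[pos])
    out
  })
  all_v <- unlist(lv, use.names = FALSE)
  if (!any(!is.na(all_v)))
    stopf("no defined GC window values to center")
  mu <- mean(all_v, na.rm = TRUE)
  genome_track(lapply(lv, function(v) v - mu), state = "log2_centered")
}

#' GC frequency profile around aligned read starts
#'
#' All reads are aligned at their start coordinate (offset 0 = the read's
#' first base); minus-strand reads are reverse-complemented, so for a
#' minus read at p offset o refers to genome base p - o (G/C status is
#' complement-invariant). At each offset the GC frequency is the count of
#' G/C divided by the count of contributing non-N bases; offsets falling
#' outside a chromosome contribute nothing. A centered moving average of
#' width `smooth` is applied (shrinking at the profile edges); its purpose
#' is to remove the strong 3-bp periodic component that codons impose on
#' the raw frequencies.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param reads A `read_starts` data frame.
#' @param flank Profile half-width in bp (offsets -flank..+flank; default
#'   2000).
#' @param smooth Odd moving-average width in bp (default 3; 1 = no
#'   smoothing).
#' @return A `gc_profile`: data frame with columns `offset`, `raw_gc`,
#'   `smoothed_gc`, `n` (contributing bases), with attribute `n_reads`.
#' @export
gc_profile_around_read_starts <- function(genome, reads, flank = 2000L,
                                          smooth = 3L) {
  if (!nrow(reads)) stopf("no reads")
  if (!is_count(flank)) stopf("'flank' must be a positive integer")
  if (!is_count(smooth) || smooth %% 2L == 0L)
    stopf("'smooth' must be an odd positive integer")
  offsets <- seq.int(-flank, flank)
  num <- den <- numeric(length(offsets))
  lens <- chrom_lengths(genome)
  for (ch in unique(reads$chrom)) {
    L <- lens[[ch]]
    g <- gc_indicator(utf8ToInt(as.character(genome[[ch]])))
    sel <- reads$chrom == ch
    pp <- reads$pos[sel & reads$strand == "+"] + 1L # 1-based
    pm <- reads$pos[sel & reads$strand == "-"] + 1L
    for (j in seq_along(offsets)) {
      idx <- c(pp + offsets[j], pm - offsets[j])
      idx <- idx[idx >= 1L & idx <= L]
      if (!length(idx)) next
      vals <- g[idx]
      num[j] <- num[j] + sum(vals, na.rm = TRUE)
      den[j] <- den[j] + sum(!is.na(vals))
    }
  }
  raw <- ifelse(den > 0, num / den, NA_real_)
  half <- (smooth - 1L) %/% 2L
  n <- length(raw)
  smoothed <- vapply(seq_len(n), function(i) {
    mean(raw[max(1L, i - half):min(n, i + half)], na.rm = TRUE)
  }, numeric(1))
  smoothed[is.nan(smoothed)] <- NA_real_
  out <- data.frame(offset = offsets, raw_gc = raw, smoothed_gc = smoothed,
                    n = den)
  attr(out, "n_reads") <- nrow(reads)
  attr(out, "smooth") <- as.integer(smooth)
  class(out) <- c("gc_profile", "data.frame")
  out
}
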