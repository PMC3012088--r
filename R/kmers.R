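#' Genome-wide average track value over all k-mers
#'
#' Every forward-strand occurrence of a k-mer whose k covered positions
#' are all defined in the track contributes the mean of those k track
#' values; a k-mer's table entry is the average contribution over all of
#' its qualifying occurrences. Occurrences containing N never qualify.
#' With k = 5 and a linear-normalized coverage track this is the relative
#' coverage per 5-mer used to compare digestion-derived maps.
#'
#' @param track A `genome_track` sharing the genome's chromosomes and
#'   lengths (typically `linear_normalized`).
#' @param genome A [Biostrings::DNAStringSet].
#' @param k K-mer length (default 5).
#' @param collapse_strands If `TRUE`, each k-mer is pooled with its
#'   reverse complement under the lexicographically smaller label.
#' @return A `kmer_coverage_table`: data frame with columns `kmer`,
#'   `mean_coverage`, `n`; attribute `k`.
#' @export
kmer_mean_coverage <- function(track, genome, k = 5L, collapse_strands = FALSE) {
  if (!is_count(k)) stopf("'k' must be a positive integer")
  lens <- chrom_lengths(genome)
  if (!setequal(names(track$values), names(genome)) ||
      any(vapply(track$values, length, integer(1))[names(genome)] != lens))
    stopf("track and genome disagree on chromosomes or lengths")
  if (k > min(lens)) stopf("k (%d) exceeds the shortest chromosome (%d bp)", k, min(lens))
  nk <- 4L^k
  tot <- numeric(nk)
  cnt <- numeric(nk)
  base_code <- integer(128)
  base_code[] <- NA_integer_
  base_code[utf8ToInt("A")] <- 0L; base_code[utf8ToInt("C")] <- 1L
  base_code[utf8ToInt("G")] <- 2L; base_code[utf8ToInt("T")] <- 3L
  for (ch in names(genome)) {
    L <- lens[[ch]]
    if (L < k) next
    b <- base_code[utf8ToInt(as.character(genome[[ch]]))]
    n_occ <- L - k + 1L
    id <- rep(0, n_occ)
    for (j in 0:(k - 1L)) id <- id * 4 + b[seq.int(1L + j, n_occ + j)]
    id <- id + 1
    v <- track$values[[ch]]
    def <- !is.na(v)
    S <- c(0, cumsum(ifelse(def, v, 0)))
    D <- c(0L, cumsum(def))
    i <- seq_len(n_occ)
    ok <- (D[i + k] - D[i]) == k & !is.na(id)
    if (!any(ok)) next
    contrib <- (S[i + k] - S[i])[ok] / k
    idq <- id[ok]
    agg <- rowsum(contrib, idq)
    sel <- as.integer(rownames(agg))
    tot[sel] <- tot[sel] + agg[, 1L]
    cnt <- cnt + tabulate(idq, nbins = nk)
  }
  kmers <- kmer_strings(k)
  present <- cnt > 0
  out <- data.frame(kmer = kmers[present],
                    mean_coverage = tot[present] / cnt[present],
                    n = as.integer(cnt[present]), stringsAsFactors = FALSE)
  if (collapse_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(out$kmer)))
    label <- pmin(out$kmer, rc)
    s <- rowsum(out$mean_coverage * out$n, label)
    m <- rowsum(as.numeric(out$n), label)
    out <- data.frame(kmer = rownames(s), mean_coverage = s[, 1L] / m[, 1L],
                      n = as.integer(m[, 1L]), row.names = NULL,
                      stringsAsFactors = FALSE)
  }
  attr(out, "k") <- as.integer(k)
  class(out) <- c("kmer_coverage_table", "data.frame")
  out
}

# All 4^k k-mers in id order (A=0 < C < G < T, leftmost base most
# significant), matching the encoding used above.
kmer_strings <- function(k) {
  bases <- c("A", "C", "G", "T")
  ids <- 0:(4L^k - 1L)
  cols <- lapply(rev(seq_len(k) - 1L), function(j) bases[(ids %/% 4L^j) %% 4L + 1L])
  do.call(paste0, cols)
}

#' Pearson correlation between two k-mer coverage tables
#'
#' @param a,b `kmer_coverage_table`s of the same k.
#' @return A list with `r` (Pearson coefficient over k-mers present in
#'   both tables) and `n_common`.
#' @export
kmer_table_correlation <- function(a, b) {
  if (!identical(attr(a, "k"), attr(b, "k")))
    stopf("tables have different k (%s vs %s)", attr(a, "k"), attr(b, "k"))
  m <- merge(as.data.frame(a)[, c("kmer", "mean_coverage")],
             as.data.frame(b)[, c("kmer", "mean_coverage")], by = "kmer")
  if (nrow(m) < 3L) stopf("fewer than 3 k-mers in common")
  list(r = stats::cor(m$mean_coverage.x, m$mean_coverage.y), n_common = nrow(m))
}

#' K-mer table TSV input/output
#'
#' Columns: `kmer`, `mean_coverage`, `n`.
#'
#' @param table A `kmer_coverage_table`.
#' @param path File path.
#' @return `write_kmer_table()` returns `path` invisibly;
#'   `read_kmer_table()` returns a `kmer_coverage_table`.
#' @export
write_kmer_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_kmer_table
#' @export
read_kmer_table <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "numeric", "integer"))
  k <- unique(nchar(out$kmer))
  if (length(k) != 1L) stopf("'%s' mixes k-mer lengths", path)
  attr(out, "k") <- as.integer(k)
  class(out) <- c("kmer_coverage_table", "data.frame")
  out
}
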