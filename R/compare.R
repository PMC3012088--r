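#' Positions defined in every track
#'
#' @param tracks A list of `genome_track`s sharing chromosome names and
#'   lengths.
#' @return A named list of logical vectors, one per chromosome, `TRUE`
#'   where every track is defined.
#' @export
common_positions <- function(tracks) {
  if (length(tracks) < 1L) stopf("need at least one track")
  ref <- tracks[[1L]]
  for (t in tracks[-1L]) {
    if (!identical(names(t$values), names(ref$values)) ||
        any(vapply(t$values, length, integer(1)) !=
            vapply(ref$values, length, integer(1))))
      stopf("tracks disagree on chromosomes or lengths")
  }
  masks <- lapply(names(ref$values), function(ch) {
    Reduce(`&`, lapply(tracks, function(t) !is.na(t$values[[ch]])))
  })
  names(masks) <- names(ref$values)
  if (sum(vapply(masks, sum, numeric(1))) == 0)
    stopf("no positions are defined in every track")
  masks
}

#' Pearson correlation between two tracks over common defined positions
#'
#' Per-base values from all chromosomes are pooled; only positions
#' defined in both tracks enter.
#'
#' @param a,b `genome_track`s on the same genome frame.
#' @return A `track_correlation`: list with `r` and `n_positions`.
#' @export
correlate_tracks <- function(a, b) {
  masks <- common_positions(list(a, b))
  x <- unlist(lapply(names(masks), function(ch) a$values[[ch]][masks[[ch]]]),
              use.names = FALSE)
  y <- unlist(lapply(names(masks), function(ch) b$values[[ch]][masks[[ch]]]),
              use.names = FALSE)
  if (length(x) < 3L) stopf("fewer than 3 common defined positions")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("zero variance over common positions")
  structure(list(r = stats::cor(x, y), n_positions = length(x)),
            class = "track_correlation")
}

#' @export
print.track_correlation <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f over %d common base pairs\n",
              x$r, x$n_positions))
  invisible(x)
}

#' Two-dimensional density grid of two tracks
#'
#' Bins the per-base value pairs over common defined positions into an
#' `n_bins` x `n_bins` histogram whose edges span the observed ranges —
#' the data behind a density-plot comparison of two maps.
#'
#' @param a,b `genome_track`s on the same genome frame.
#' @param n_bins Number of bins per axis (default 100).
#' @return A `density_grid`: list with `x_edges`, `y_edges` (length
#'   `n_bins + 1`) and `counts` (`n_bins` x `n_bins` matrix; rows follow
#'   `x`, columns `y`; `sum(counts)` equals the number of common
#'   positions).
#' @export
density_grid <- function(a, b, n_bins = 100L) {
  if (!is_count(n_bins) || n_bins < 2L) stopf("'n_bins' must be an integer >= 2")
  masks <- common_positions(list(a, b))
  x <- unlist(lapply(names(masks), function(ch) a$values[[ch]][masks[[ch]]]),
              use.names = FALSE)
  y <- unlist(lapply(names(masks), function(ch) b$values[[ch]][masks[[ch]]]),
              use.names = FALSE)
  edges <- function(v) {
    lo <- min(v); hi <- max(v)
    if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
    seq(lo, hi, length.out = n_bins + 1L)
  }
  xe <- edges(x); ye <- edges(y)
  xi <- findInterval(x, xe, rightmost.closed = TRUE, all.inside = TRUE)
  yi <- findInterval(y, ye, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(tabulate(xi + (yi - 1L) * n_bins, nbins = n_bins * n_bins),
                   nrow = n_bins)
  structure(list(x_edges = xe, y_edges = ye, counts = counts),
            class = "density_grid")
}

#' Per-base report over a genomic region
#'
#' One row per base of the region with each track's value, the windowed
#' GC value and the labels of overlapping annotations — the data behind a
#' locus profile figure (coverage tracks around 1.0 = the genome-wide
#' average, GC content, gene boxes).
#'
#' @param region List or vector with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param tracks Named list of `genome_track`s (typically
#'   `linear_normalized` coverage maps).
#' @param gc Optional GC `genome_track` (e.g. [gc_window_track()]).
#' @param annotations Optional data frame with columns `chrom`, `start`,
#'   `end`, `label` (and optionally `strand`), 0-based half-open.
#' @return A data frame: `chrom`, `pos`, one column per track, `gc`,
#'   `annotation`.
#' @export
region_report <- function(region, tracks, gc = NULL, annotations = NULL) {
  chrom <- as.character(region[["chrom"]])
  start <- as.integer(region[["start"]]); end <- as.integer(region[["end"]])
  if (is.na(start) || is.na(end) || start >= end)
    stopf("region must satisfy start < end")
  if (!length(tracks) || is.null(names(tracks)))
    stopf("'tracks' must be a named list")
  ref <- tracks[[1L]]
  if (!chrom %in% names(ref$values))
    stopf("region chromosome '%s' not in the genome frame", chrom)
  L <- length(ref$values[[chrom]])
  if (start < 0 || end > L)
    stopf("region [%d, %d) outside chromosome '%s' (length %d)",
          start, end, chrom, L)
  idx <- seq.int(start + 1L, end)
  out <- data.frame(chrom = chrom, pos = seq.int(start, end - 1L))
  for (nm in names(tracks)) out[[nm]] <- tracks[[nm]]$values[[chrom]][idx]
  if (!is.null(gc)) out$gc <- gc$values[[chrom]][idx]
  ann <- rep("", nrow(out))
  if (!is.null(annotations) && nrow(annotations)) {
    hit <- annotations$chrom == chrom & annotations$end > start &
      annotations$start < end
    for (i in which(hit)) {
      cover <- out$pos >= annotations$start[i] & out$pos < annotations$end[i]
      ann[cover] <- ifelse(nzchar(ann[cover]),
                           paste(ann[cover], annotations$label[i], sep = ","),
                           annotations$label[i])
    }
  }
  out$annotation <- ann
  out
}
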