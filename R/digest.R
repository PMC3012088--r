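#' Parameters of the MNase digestion simulation
#'
#' MNase cuts almost exclusively next to A/T base pairs. The simulator
#' expresses this as a two-level weight on each internucleotide bond: a bond
#' gets `cut_weight_at` when either flanking base is A or T and
#' `cut_weight_gc` when both flanking bases are G or C. Within each
#' chromosome the weights are rescaled so the expected number of cuts per
#' genome copy equals `mean_cuts_per_kb` per kilobase, each bond being cut
#' independently (Bernoulli). Fragments between consecutive cuts (and the
#' chromosome ends) are kept only if their length falls inside the
#' size-selection band `[size_min, size_max]`, emulating gel excision of a
#' 140-170 bp band.
#'
#' `genome_copies` is the number of genome equivalents digested, i.e. the
#' amount of input DNA: digestion of a single genome copy yields only a
#' handful of band-sized fragments, just as a single molecule would on a
#' gel; sequencing-scale fragment counts come from digesting many copies.
#' The default (1500 copies, about 15,000 retained fragments and 20-25x
#' mean coverage on a 100-kb genome) keeps the per-5-mer sampling noise of
#' the relative-coverage table well below the composition-driven coverage
#' differences the analyses measure; published digestion datasets are
#' deeper still (roughly one mapped read per genomic base).
#'
#' The default digestion extent (40 cuts/kb, mean fragment ~25 bp before
#' size selection) reflects a digestion driven well past the band, so that
#' the 140-170 bp band is a small surviving tail. That is the regime in
#' which size selection is informative: fragments that reach the band are
#' those that escaped internal cutting, which is precisely what makes the
#' recovered material GC-rich.
#'
#' @param cut_weight_at Relative cut propensity at bonds flanked by A or T.
#' @param cut_weight_gc Relative cut propensity at bonds with both flanking
#'   bases G/C (must not exceed `cut_weight_at`).
#' @param mean_cuts_per_kb Expected cuts per kilobase per genome copy.
#' @param size_min,size_max Size-selection band in bp (inclusive).
#' @param genome_copies Number of genome equivalents digested.
#' @param seed Integer seed.
#' @return An object of class `digestion_params`.
#' @export
digestion_params <- function(cut_weight_at = 1, cut_weight_gc = 0.02,
                             mean_cuts_per_kb = 40, size_min = 140L,
                             size_max = 170L, genome_copies = 1500L,
                             seed = 1L) {
  stopifnot(is_scalar_number(cut_weight_at), is_scalar_number(cut_weight_gc),
            is_scalar_number(mean_cuts_per_kb))
  if (cut_weight_gc < 0 || cut_weight_at < cut_weight_gc)
    stopf("need cut_weight_at >= cut_weight_gc >= 0 (got %g, %g)",
          cut_weight_at, cut_weight_gc)
  if (mean_cuts_per_kb <= 0) stopf("'mean_cuts_per_kb' must be positive")
  if (!is_count(size_min) || !is_count(size_max) || size_min > size_max)
    stopf("need 1 <= size_min <= size_max")
  if (!is_count(genome_copies)) stopf("'genome_copies' must be a positive integer")
  if (!is_count(seed)) stopf("'seed' must be a positive integer")
  structure(list(cut_weight_at = cut_weight_at, cut_weight_gc = cut_weight_gc,
                 mean_cuts_per_kb = mean_cuts_per_kb,
                 size_min = as.integer(size_min), size_max = as.integer(size_max),
                 genome_copies = as.integer(genome_copies),
                 seed = as.integer(seed)),
            class = "digestion_params")
}

#' @export
print.digestion_params <- function(x, ...) {
  cat(sprintf(paste0("MNase digestion parameters\n",
                     "  bond cut weights: AT-flanked %g, GC/GC %g\n",
                     "  digestion extent: %g cuts/kb per copy\n",
                     "  size selection:   [%d, %d] bp\n",
                     "  genome copies:    %d   seed: %d\n"),
              x$cut_weight_at, x$cut_weight_gc, x$mean_cuts_per_kb,
              x$size_min, x$size_max, x$genome_copies, x$seed))
  invisible(x)
}

#' Simulate MNase digestion with size selection
#'
#' Digests `genome_copies` copies of naked DNA independently: for each copy
#' and chromosome every internucleotide bond is cut with probability
#' `c * w_b`, where `w_b` is the bond weight (see [digestion_params()]) and
#' `c` scales the chromosome's weight sum to the requested digestion
#' extent. Fragments whose length falls inside the size band are retained.
#'
#' @param genome A [Biostrings::DNAStringSet]; must be free of N (the
#'   simulator treats a bond next to an N like a G/C bond, since N is not
#'   an A/T).
#' @param params A [digestion_params()].
#' @return A `fragment_set`: data frame with columns `chrom`, `start`,
#'   `end` (0-based half-open).
#' @examples
#' gen <- generate_genome(composition_plan(list(
#'   chromosome_plan("chrI", data.frame(length = 20000, gc = 0.4))), seed = 1))
#' frags <- simulate_digestion(gen, digestion_params(genome_copies = 100, seed = 2))
#' mean(fragment_gc(frags, gen)) - gc_fraction(gen)  # GC enrichment
#' @export
simulate_digestion <- function(genome, params) {
  stopifnot(inherits(params, "digestion_params"))
  lens <- chrom_lengths(genome)
  out <- with_seed(params$seed, {
    res <- vector("list", length(genome))
    for (ci in seq_along(genome)) {
      L <- lens[[ci]]
      if (L < 2L) { res[ci] <- list(NULL); next }
      code <- utf8ToInt(as.character(genome[[ci]]))
      is_at <- code == 65L | code == 84L # A, T
      at_bond <- is_at[-L] | is_at[-1L]
      w <- ifelse(at_bond, params$cut_weight_at, params$cut_weight_gc)
      wsum <- sum(w)
      target <- params$mean_cuts_per_kb * L / 1000
      if (wsum == 0) {
        res[ci] <- list(NULL) # no cuttable bond on this chromosome
        next
      }
      scale <- target / wsum
      if (scale * max(w) > 1)
        stopf(paste0("cut probability overflow on '%s': mean_cuts_per_kb = %g with ",
                     "cut weights (%g, %g) implies a per-bond probability of %g > 1; ",
                     "lower mean_cuts_per_kb or the weight contrast"),
              names(genome)[ci], params$mean_cuts_per_kb,
              params$cut_weight_at, params$cut_weight_gc, scale * max(w))
      # Two-level weights => Bernoulli over each class is a binomial count
      # plus a uniform subset; sample that way instead of per-bond uniforms.
      idx_at <- which(at_bond)
      idx_gc <- which(!at_bond)
      p_at <- scale * params$cut_weight_at
      p_gc <- scale * params$cut_weight_gc
      copies <- vector("list", params$genome_copies)
      for (k in seq_len(params$genome_copies)) {
        cuts_at <- idx_at[sample.int(length(idx_at), stats::rbinom(1L, length(idx_at), p_at))]
        cuts_gc <- if (p_gc > 0 && length(idx_gc))
          idx_gc[sample.int(length(idx_gc), stats::rbinom(1L, length(idx_gc), p_gc))]
        else integer(0)
        b <- c(0L, sort(c(cuts_at, cuts_gc)), L)
        fl <- diff(b)
        keep <- fl >= params$size_min & fl <= params$size_max
        if (any(keep))
          copies[[k]] <- cbind(b[-length(b)][keep], b[-1L][keep])
      }
      res[[ci]] <- do.call(rbind, copies)
    }
    res
  })
  n_per <- vapply(out, function(m) if (is.null(m)) 0L else nrow(m), integer(1))
  mat <- do.call(rbind, out)
  if (is.null(mat)) mat <- matrix(integer(0), ncol = 2L)
  frags <- data.frame(chrom = rep(names(genome), n_per),
                      start = as.integer(mat[, 1L]),
                      end = as.integer(mat[, 2L]),
                      stringsAsFactors = FALSE)
  class(frags) <- c("fragment_set", "data.frame")
  attr(frags, "params") <- params
  frags
}

#' Fragment lengths and GC content
#'
#' `fragment_lengths()` returns fragment lengths in bp; `fragment_gc()`
#' returns each fragment's GC fraction (over non-N bases) looked up in the
#' genome.
#'
#' @param fragments A `fragment_set` (or any data frame with `chrom`,
#'   `start`, `end` in 0-based half-open coordinates).
#' @param genome A [Biostrings::DNAStringSet].
#' @return A numeric vector, one value per fragment.
#' @export
fragment_gc <- function(fragments, genome) {
  out <- numeric(nrow(fragments))
  for (ch in unique(fragments$chrom)) {
    sel <- fragments$chrom == ch
    code <- utf8ToInt(as.character(genome[[ch]]))
    g <- gc_indicator(code)
    cs_gc <- c(0, cumsum(ifelse(is.na(g), 0, g)))
    cs_n <- c(0, cumsum(!is.na(g)))
    s <- fragments$start[sel]; e <- fragments$end[sel]
    denom <- cs_n[e + 1L] - cs_n[s + 1L]
    out[sel] <- ifelse(denom > 0, (cs_gc[e + 1L] - cs_gc[s + 1L]) / denom, NA_real_)
  }
  out
}

#' @rdname fragment_gc
#' @export
fragment_lengths <- function(fragments) {
  fragments$end - fragments$start
}

#' Simulate a positioned (phased) fragment population
#'
#' Generates band-sized fragments clustered at regularly spaced sites, the
#' situation of well-positioned nucleosomes: at each site many molecules
#' yield near-identical fragments whose start jitters by a few bp. This is
#' the regime in which the strand-paired distance histogram of
#' [estimate_fragment_length()] carries a fragment-length signal; randomly
#' positioned naked-DNA fragments do not produce one.
#'
#' @param chrom_length Chromosome length (bp).
#' @param n_fragments Number of fragments to draw.
#' @param mean_length,sd_length Fragment length distribution (rounded
#'   normal).
#' @param site_spacing Distance between site centers; should exceed the
#'   pairing window of the length estimator so sites do not cross-talk.
#' @param jitter_sd Standard deviation of the per-fragment start jitter.
#' @param seed Integer seed.
#' @param chrom Chromosome name.
#' @return A `fragment_set`.
#' @export
simulate_positioned_fragments <- function(chrom_length, n_fragments,
                                          mean_length = 150, sd_length = 8,
                                          site_spacing = 500L, jitter_sd = 4,
                                          seed = 1L, chrom = "chrI") {
  stopifnot(is_count(chrom_length), is_count(n_fragments))
  sites <- seq.int(200L, chrom_length - 200L - ceiling(mean_length + 4 * sd_length),
                   by = site_spacing)
  if (!length(sites)) stopf("chromosome too short for any site")
  with_seed(seed, {
    site <- sample(sites, n_fragments, replace = TRUE)
    start <- site + as.integer(round(stats::rnorm(n_fragments, 0, jitter_sd)))
    len <- pmax(10L, as.integer(round(stats::rnorm(n_fragments, mean_length, sd_length))))
    start <- pmax(0L, start)
    end <- pmin(as.integer(chrom_length), start + len)
    frags <- data.frame(chrom = chrom, start = as.integer(start),
                        end = as.integer(end), stringsAsFactors = FALSE)
    class(frags) <- c("fragment_set", "data.frame")
    frags
  })
}
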