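test_that("the 147-bp window value sits on the central base", {
  g <- genome_from_strings(c1 = strrep("G", 147))
  tr <- gc_window_track(g, window = 147)
  v <- tr$values$c1
  expect_equal(sum(!is.na(v)), 1L)
  expect_equal(v[74], 1.0) # 0-based position 73
})

test_that("window GC matches hand counts on a printed micro-example", {
  g <- genome_from_strings(c1 = "AACGG")
  v <- gc_window_track(g, window = 3)$values$c1
  expect_true(is.na(v[1]) && is.na(v[5]))
  expect_equal(v[2:4], c(1 / 3, 2 / 3, 1)) # windows AAC, ACG, CGG
})

test_that("window 1 equals the per-base G/C indicator", {
  g <- genome_from_strings(c1 = "ACGTGGCATN")
  v <- gc_window_track(g, window = 1)$values$c1
  expect_equal(v, c(0, 1, 1, 0, 1, 1, 1, 0, 0, NA))
})

test_that("GC windows are invariant under reverse complement up to mirroring", {
  g <- uniform_genome(800, seed = 13)
  grc <- Biostrings::reverseComplement(g)
  names(grc) <- names(g)
  v <- gc_window_track(g, window = 21)$values[[1]]
  vrc <- gc_window_track(grc, window = 21)$values[[1]]
  expect_equal(v, rev(vrc))
})

test_that("N bases are excluded from numerator and denominator", {
  g <- genome_from_strings(c1 = "ANGCN")
  v <- gc_window_track(g, window = 3)$values$c1
  expect_equal(v[2:4], c(1 / 2, 1, 1)) # ANG, NGC, GCN with N dropped
  gn <- genome_from_strings(c1 = "ANNNG")
  expect_true(is.na(gc_window_track(gn, window = 3)$values$c1[3])) # all-N window
})

test_that("centered GC windows have zero pooled mean", {
  g <- generate_genome(demo_composition_plan(seed = 8))
  tr <- gc_window_track(g, window = 147, centered = TRUE)
  expect_identical(track_state(tr), "log2_centered")
  expect_lt(abs(track_mean_for_test(tr)), 1e-9)
})

test_that("windows longer than the chromosome warn and stay undefined", {
  g <- genome_from_strings(c1 = "ACGT")
  expect_warning(tr <- gc_window_track(g, window = 5), "longer than")
  expect_true(all(is.na(tr$values$c1)))
})

test_that("profile offsets address the genome relative to the read start", {
  g <- genome_from_strings(c1 = "AAAGCGAAA")
  rs <- read_starts("c1", 3, "+") # first read base is the G at 0-based 3
  pr <- gc_profile_around_read_starts(g, rs, flank = 1, smooth = 1)
  # offsets -1, 0, +1 address bases A, G, C
  expect_equal(pr$raw_gc, c(0, 1, 1))
  expect_equal(pr$smoothed_gc, pr$raw_gc) # smooth = 1 is identity
})

test_that("minus-strand reads mirror plus-strand reads on the complement", {
  g <- uniform_genome(400, seed = 17)
  grc <- Biostrings::reverseComplement(g)
  names(grc) <- names(g)
  L <- Biostrings::width(g)[[1]]
  p <- 163L
  pr_minus <- gc_profile_around_read_starts(g, read_starts(names(g), p, "-"),
                                            flank = 50, smooth = 1)
  pr_plus <- gc_profile_around_read_starts(grc,
                                           read_starts(names(g), L - 1L - p, "+"),
                                           flank = 50, smooth = 1)
  expect_equal(pr_minus$raw_gc, pr_plus$raw_gc)
  expect_equal(pr_minus$n, pr_plus$n)
})

test_that("offsets outside the chromosome contribute nothing", {
  g <- genome_from_strings(c1 = "GGCC")
  pr <- gc_profile_around_read_starts(g, read_starts("c1", 1, "+"),
                                      flank = 3, smooth = 1)
  expect_equal(pr$n, c(0, 0, 1, 1, 1, 1, 0))
  expect_true(is.na(pr$raw_gc[1]))
})

test_that("interior smoothing is the exact 3-bp mean; edges shrink", {
  g <- uniform_genome(2000, seed = 19)
  set.seed(20)
  rs <- read_starts(rep(names(g), 50), sample(200:1800, 50),
                    sample(c("+", "-"), 50, replace = TRUE))
  pr <- gc_profile_around_read_starts(g, rs, flank = 30, smooth = 3)
  n <- nrow(pr)
  for (i in c(2, 10, n - 1)) {
    expect_equal(pr$smoothed_gc[i],
                 mean(pr$raw_gc[(i - 1):(i + 1)]), tolerance = 1e-12)
  }
  expect_equal(pr$smoothed_gc[1], mean(pr$raw_gc[1:2]))
  expect_equal(pr$smoothed_gc[n], mean(pr$raw_gc[(n - 1):n]))
})

test_that("simulated digestion reads show GC enrichment inside the fragment", {
  g <- uniform_genome(1e5, gc = 0.4, seed = 23)
  frags <- simulate_digestion(g, digestion_params(genome_copies = 200, seed = 24))
  reads <- emit_reads(frags, seed = 25)
  pr <- gc_profile_around_read_starts(g, reads, flank = 600, smooth = 3)
  inside <- mean(pr$smoothed_gc[pr$offset >= 0 & pr$offset <= 149], na.rm = TRUE)
  upstream <- mean(pr$smoothed_gc[pr$offset >= -500 & pr$offset <= -200],
                   na.rm = TRUE)
  expect_gt(inside, upstream)
})

test_that("log2 coverage correlates positively with log2 GC content", {
  g <- uniform_genome(1e5, gc = 0.4, seed = 26)
  cov <- simulate_coverage(g, digestion_params(seed = 27))
  r <- correlate_tracks(normalize_log2(cov),
                        gc_window_track(g, 147, centered = TRUE))$r
  expect_gte(r, 0.3)
})
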