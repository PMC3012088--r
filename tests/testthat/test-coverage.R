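test_that("pileup matches the definition on single reads", {
  g <- genome_from_strings(c1 = strrep("A", 200))
  cov <- pileup(read_starts("c1", 0, "+"), g, extension = 150)
  v <- cov$values$c1
  expect_equal(v, c(rep(1, 150), rep(0, 50)))

  # a + read and a - read from the two ends of one 150-bp fragment
  cov2 <- pileup(read_starts(c("c1", "c1"), c(10, 159), c("+", "-")), g,
                 extension = 150)
  v2 <- cov2$values$c1
  expect_true(all(v2[11:160] == 2))
  expect_true(all(v2[-(11:160)] == 0))
})

test_that("pileup matches a brute-force per-read oracle on random instances", {
  set.seed(99)
  for (i in 1:30) {
    L <- sample(500:5000, 1)
    g <- genome_from_strings(c1 = strrep("A", L))
    n <- sample(1:200, 1)
    reads <- read_starts(rep("c1", n), sample(0:(L - 1), n, replace = TRUE),
                         sample(c("+", "-"), n, replace = TRUE))
    ext <- sample(c(50L, 147L, 150L), 1)
    got <- suppressMessages(pileup(reads, g, extension = ext))
    expect_equal(got$values$c1, brute_force_pileup(reads, g, ext)$c1)
  }
})

test_that("pileup conserves total mass up to end truncation", {
  g <- genome_from_strings(c1 = strrep("A", 1000))
  set.seed(7)
  reads <- read_starts(rep("c1", 50), sample(0:999, 50, replace = TRUE),
                       sample(c("+", "-"), 50, replace = TRUE))
  ext <- 150L
  cov <- suppressMessages(pileup(reads, g, extension = ext))
  overhang <- ifelse(reads$strand == "+",
                     pmax(reads$pos + ext - 1000L, 0L),
                     pmax(ext - 1L - reads$pos, 0L))
  expect_equal(sum(cov$values$c1), sum(ext - overhang))
})

test_that("strand-paired distances recover hand-computed weighted means", {
  # one fragment's worth: + at 100, - at 249 => inclusive distance 150
  fl <- estimate_fragment_length(
    read_starts(c("c1", "c1"), c(100, 249), c("+", "-")))
  expect_equal(fl$mean_length, 150)
  expect_identical(fl$histogram$distance, 150L)
  expect_identical(fl$histogram$count, 1)

  # distances 140 x3 and 160 x1, isolated sites: mean (3*140 + 160)/4 = 145
  rs <- read_starts(rep("c1", 8),
                    c(0, 139, 1000, 1139, 2000, 2139, 3000, 3159),
                    rep(c("+", "-"), 4))
  expect_equal(estimate_fragment_length(rs)$mean_length, 145)
})

test_that("pairs beyond the window or with negative distance are skipped", {
  rs <- read_starts(c("c1", "c1", "c1"), c(500, 100, 900), c("+", "-", "-"))
  # - at 100 is upstream (negative distance), - at 900 beyond 300-bp window
  expect_error(estimate_fragment_length(rs), "no \\+/- pairs")
  expect_error(estimate_fragment_length(read_starts("c1", 5, "+")),
               "both strands")
})

test_that("mean length of a positioned fragment population is recovered", {
  frags <- simulate_positioned_fragments(6e5, 10000, mean_length = 152,
                                         sd_length = 8, seed = 21)
  reads <- emit_reads(frags, seed = 22)
  fl <- estimate_fragment_length(reads, window = 300)
  expect_lt(abs(fl$mean_length - mean(fragment_lengths(frags))), 2)
})

test_that("log2 centering matches hand computation and masks zeros", {
  tr <- genome_track(list(c1 = c(1, 2, 4, 8)), state = "raw_counts")
  expect_equal(normalize_log2(tr)$values$c1, c(-1.5, -0.5, 0.5, 1.5))

  tr2 <- genome_track(list(c1 = c(0, 2, 2)), state = "raw_counts")
  out <- normalize_log2(tr2)$values$c1
  expect_true(is.na(out[1]))
  expect_equal(out[2:3], c(0, 0))

  const <- genome_track(list(c1 = rep(5, 10)), state = "raw_counts")
  expect_equal(normalize_log2(const)$values$c1, rep(0, 10))

  expect_error(normalize_log2(genome_track(list(c1 = c(0, 0)),
                                           state = "raw_counts")),
               "zero coverage")
})

test_that("linear normalization matches hand computation", {
  tr <- genome_track(list(c1 = c(0, 1, 3)), state = "raw_counts")
  expect_equal(normalize_linear(tr)$values$c1, c(0, 0.75, 2.25))
  const <- genome_track(list(c1 = rep(4, 7)), state = "raw_counts")
  expect_equal(normalize_linear(const)$values$c1, rep(1, 7))
})

test_that("normalization states and invariants hold on simulated coverage", {
  g <- uniform_genome(20000, seed = 31)
  cov <- simulate_coverage(g, digestion_params(genome_copies = 150, seed = 32))
  lin <- normalize_linear(cov)
  lg <- normalize_log2(cov)
  expect_identical(track_state(lin), "linear_normalized")
  expect_identical(track_state(lg), "log2_centered")
  expect_lt(abs(track_mean_for_test(lin) - 1), 1e-9)
  expect_lt(abs(track_mean_for_test(lg)), 1e-9)

  # log2 centering is invariant to a multiplicative constant
  scaled <- genome_track(lapply(cov$values, function(v) v * 3),
                         state = "raw_counts")
  expect_equal(normalize_log2(scaled)$values, lg$values)
  # linear normalization is scale-free
  expect_equal(normalize_linear(scaled)$values, lin$values)
})

test_that("centering pools across chromosomes rather than per chromosome", {
  tr <- genome_track(list(c1 = c(2, 2), c2 = c(8, 8)), state = "raw_counts")
  out <- normalize_log2(tr)
  expect_equal(out$values$c1, c(-1, -1))
  expect_equal(out$values$c2, c(1, 1))
})
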