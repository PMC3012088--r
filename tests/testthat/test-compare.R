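test_that("common positions are the intersection of defined masks", {
  a <- genome_track(list(c1 = c(NA, 1, 2, 3, NA)), state = "raw_counts")
  b <- genome_track(list(c1 = c(NA, NA, 2, 3, 4)), state = "raw_counts")
  m <- common_positions(list(a, b))
  expect_identical(m$c1, c(FALSE, FALSE, TRUE, TRUE, FALSE))

  full <- genome_track(list(c1 = rep(1, 100)), state = "raw_counts")
  expect_identical(sum(common_positions(list(full, full))$c1), 100L)

  c_ <- genome_track(list(c1 = c(1, NA, NA, NA, NA)), state = "raw_counts")
  d_ <- genome_track(list(c1 = c(NA, 1, NA, NA, NA)), state = "raw_counts")
  expect_error(common_positions(list(c_, d_)), "no positions")
  e_ <- genome_track(list(c2 = rep(1, 5)), state = "raw_counts")
  expect_error(common_positions(list(a, e_)), "disagree")
})

test_that("correlation matches the closed form and its invariances", {
  a <- genome_track(list(c1 = c(1, 2, 3, 4)), state = "raw_counts")
  b <- genome_track(list(c1 = c(2, 1, 4, 3)), state = "raw_counts")
  res <- correlate_tracks(a, b)
  expect_equal(res$r, 0.6)
  expect_identical(res$n_positions, 4L)

  expect_equal(correlate_tracks(a, a)$r, 1)
  affine <- genome_track(list(c1 = 2 * c(1, 2, 3, 4) + 7), state = "raw_counts")
  expect_equal(correlate_tracks(a, affine)$r, 1)
  # symmetry
  expect_equal(correlate_tracks(a, b)$r, correlate_tracks(b, a)$r,
               tolerance = 1e-12)

  const <- genome_track(list(c1 = rep(1, 4)), state = "raw_counts")
  expect_error(correlate_tracks(a, const), "zero variance")
})

test_that("correlation only uses positions defined in both tracks", {
  set.seed(61)
  v1 <- rpois(500, 5) + runif(500)
  v2 <- v1 + rnorm(500)
  v1[sample(500, 80)] <- NA
  v2[sample(500, 80)] <- NA
  a <- genome_track(list(c1 = v1), state = "raw_counts")
  b_vals <- v2
  b_vals[b_vals < 0] <- 0
  b <- genome_track(list(c1 = b_vals), state = "raw_counts")
  res <- correlate_tracks(a, b)
  keep <- !is.na(v1) & !is.na(b_vals)
  expect_identical(res$n_positions, sum(keep))
  expect_equal(res$r, stats::cor(v1[keep], b_vals[keep]))
  # explicit restriction to the common mask changes nothing
  a2 <- genome_track(list(c1 = ifelse(keep, v1, NA)), state = "raw_counts")
  b2 <- genome_track(list(c1 = ifelse(keep, b_vals, NA)), state = "raw_counts")
  expect_equal(correlate_tracks(a2, b2)$r, res$r)
})

test_that("density grids conserve counts and bin by hand", {
  a <- genome_track(list(c1 = c(0, 0, 10, 10)), state = "raw_counts")
  b <- genome_track(list(c1 = c(0, 10, 0, 10)), state = "raw_counts")
  gd <- density_grid(a, b, n_bins = 2)
  expect_equal(gd$counts, matrix(c(1, 1, 1, 1), 2))
  expect_equal(sum(gd$counts), 4)

  same <- genome_track(list(c1 = rep(3, 7)), state = "raw_counts")
  gd2 <- density_grid(same, same, n_bins = 5)
  expect_equal(sum(gd2$counts), 7)
  expect_identical(sum(gd2$counts > 0), 1L)

  g <- uniform_genome(2000, seed = 62)
  x <- random_track(g, seed = 63)
  y <- random_track(g, seed = 64)
  gd3 <- density_grid(x, y, n_bins = 10)
  n_common <- sum(common_positions(list(x, y))[[1]])
  expect_equal(sum(gd3$counts), n_common)
  expect_error(density_grid(x, y, n_bins = 1), "n_bins")
})

test_that("region reports carry one row per base with track columns", {
  g <- genome_from_strings(c1 = strrep("ACGT", 50))
  const <- genome_track(list(c1 = rep(1, 200)), state = "linear_normalized")
  gc <- gc_window_track(g, window = 5)
  ann <- data.frame(chrom = "c1", start = 20L, end = 30L, label = "ORF1")
  rep_ <- region_report(list(chrom = "c1", start = 10L, end = 40L),
                        tracks = list(naked = const), gc = gc,
                        annotations = ann)
  expect_identical(nrow(rep_), 30L)
  expect_true(all(rep_$naked == 1.0)) # the dashed reference level
  expect_identical(rep_$annotation[rep_$pos >= 20 & rep_$pos < 30],
                   rep("ORF1", 10))
  expect_identical(rep_$annotation[rep_$pos < 20], rep("", 10))
  expect_error(region_report(list(chrom = "c1", start = 100L, end = 300L),
                             tracks = list(naked = const)),
               "outside")
})

test_that("a GC-rich element stands out as a coverage peak in its region", {
  # the nucleosome-free UAS phenomenon: AT-biased digestion + size selection
  # over-recovers a GC-rich element relative to its surroundings
  g <- generate_genome(demo_composition_plan(seed = 65))
  cov <- simulate_coverage(g, digestion_params(seed = 66))
  lin <- normalize_linear(cov)
  rep_ <- region_report(list(chrom = "chrII", start = 34000L, end = 36400L),
                        tracks = list(naked = lin),
                        gc = gc_window_track(g, 147))
  elem <- rep_$pos >= 35000 & rep_$pos < 35300 # embedded GC-rich element
  expect_gt(mean(rep_$naked[elem]), mean(rep_$naked))
})
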