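---
title: "Simulating and measuring the sequence bias of MNase digestion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and measuring the sequence bias of MNase digestion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genome-wide nucleosome maps are commonly produced by digesting chromatin
with micrococcal nuclease (MNase), size-selecting the protected,
nucleosome-sized DNA (a 140–170 bp gel band), and sequencing one end of
each recovered fragment. The per-base coverage of the extended reads is
then read as nucleosome occupancy. MNase, however, is not
sequence-neutral: it cuts almost exclusively next to A/T base pairs. When
biased cutting is combined with size selection, fragments rich in G/C —
which suffer fewer internal cuts — survive to the band preferentially,
even when no nucleosome protects anything. A digestion of *naked*
(protein-free) DNA therefore produces a coverage landscape that already
looks nucleosome-like: enriched at GC-rich sequence, depleted over
poly(dA:dT) tracts, and strongly correlated with windowed GC content.

This package makes that mechanism reproducible at desk scale. It
simulates the whole protocol — biased digestion, size selection,
single-end sequencing — on synthetic genomes with controlled composition,
and implements the analyses used to characterize the bias: normalized
coverage maps, 147-bp windowed GC tracks, GC-frequency profiles aligned
at read starts, genome-wide relative coverage per 5-mer, and track
correlation/density comparisons.

## The digestion model

Internucleotide bonds are cut independently. Each bond between adjacent
bases gets a weight: `cut_weight_at` (default 1) if either flanking base
is A or T, `cut_weight_gc` (default 0.02, i.e. a 50-fold preference) if
both are G/C. This two-level model is the simplest expression of the
"cuts almost exclusively at A/T" preference; dinucleotide-resolved
weights would slot into the same interface. Within each chromosome the
weights are rescaled so the *expected* number of cuts per genome copy is
`mean_cuts_per_kb` per kilobase; each bond is then cut by an independent
Bernoulli draw. If the rescaling would push any bond's probability above
one, the simulation stops with an error naming the offending parameters —
it never clips silently. Fragments are the intervals between consecutive
cuts (plus chromosome ends); only those with length inside
`[size_min, size_max]` (default 140–170 bp) survive size selection.
Sequencing is modelled as one read per retained fragment from a randomly
chosen end: a plus-strand read at the leftmost base or a minus-strand
read at the rightmost base, each with probability 1/2. There are no PCR
duplicates, no base-calling errors and no mapper: reads carry exact
coordinates.

Two defaults deserve explanation.

**Digestion extent.** `mean_cuts_per_kb = 40` corresponds to a digestion
driven well past the band (mean pre-selection fragment ≈ 25 bp). This is
deliberate and is what makes size selection informative. Fragment
recovery in the band is a product of two opposing factors: AT-rich DNA
produces more cut *ends* (favouring fragment formation) but suffers more
*internal* cuts (destroying band-sized fragments). With a mean bond
probability $\bar p$ and an AT-bond probability $p_{AT}$, a 150-bp
AT-rich stretch is recovered relative to average sequence roughly as
$(p_{AT}/\bar p)^2 \exp(-150\,(p_{AT}-\bar p))$: at light digestion
(mean fragment near the band, ~6.7 cuts/kb) the end-formation factor
wins and the GC enrichment vanishes — we measured a fragment-GC excess
of about $-4\times10^{-5}$ under those settings — while past roughly 12
cuts/kb the survival term dominates and the band becomes GC-enriched
(excess $\approx +0.008$ at 40 cuts/kb on a uniform GC-0.40 genome).
Over-digestion is also the realistic regime: mononucleosome preparations
run the digestion until most naked linker DNA is sub-nucleosomal, and
the excised 140–170 bp band is a small tail of the smear.

**Input amount.** `genome_copies = 1500` genome equivalents are digested
independently. A single copy of a 100-kb genome leaves only ~10
fragments in the band, so sequencing-scale fragment counts (~15,000
fragments, 20–25× mean coverage) require many molecules, exactly as a
real digestion of micrograms of DNA processes many genome copies. The
default is chosen so that the sampling noise of the rarest 5-mers' mean
coverage (tens of occurrences on the demo genome) sits well below the
composition-driven coverage differences the k-mer analysis measures;
published digestion datasets are deeper still (roughly one mapped read
per genomic base). Because all bonds in a weight class share one
probability, each copy is sampled exactly (binomial count per class plus
a uniform subset) rather than bond-by-bond, which keeps 1500 copies
around one second per 100 kb.

## Synthetic genomes

`composition_plan()` describes chromosomes as concatenated segments with
a target GC fraction each (bases drawn i.i.d., P(G)=P(C)=gc/2), plus
literal motifs that overwrite the background at fixed positions.
`demo_composition_plan()` builds the 100-kb, two-chromosome genome used
throughout the tests: background GC 0.40 (close to the ~0.38 of budding
yeast), fifty 50-bp poly(dA)/poly(dT) tracts, and three 300-bp GC-rich
(85%) elements standing in for nucleosome-depleted regulatory sequence
such as the Gal1-10 UAS. These are the two composition contrasts the
bias acts on: AT tracts lose band-sized fragments, GC elements
accumulate them — so a "nucleosome-free" GC-rich element appears as a
coverage *peak* in the naked-DNA digestion.

What the generator does **not** emulate: chromatin (no nucleosome
protection — the experiment of interest is naked DNA), the ~10-bp
rotational oscillation of real nucleosomal fragments, dinucleotide-level
cutting kinetics, re-cutting/"nibbling" of fragment ends, PCR and
mapping artifacts, and chromosome-scale composition heterogeneity.
Passing tests therefore demonstrate the *mechanism* — biased cutting
plus size selection suffices to create nucleosome-like, GC-correlated
coverage — not that the simulator reproduces any particular organism's
measured profile.

## The analyses

* **Coverage map** (`pileup()`): every read is extended to a fixed
  150-bp footprint from its 5′ base (plus reads rightward, minus reads
  leftward) and footprints are summed per base. The 150-bp extension
  matches the selected fragment size, so the two possible reads from one
  150-bp fragment produce identical footprints. Overhangs at chromosome
  ends are truncated and reported.
* **Normalizations** (`normalize_linear()`, `normalize_log2()`): linear
  mode divides by the genome-wide mean (all positions, zeros included;
  the result averages 1, the dashed reference line in region profiles);
  log2 mode takes the binary logarithm and subtracts the genome-wide
  mean of the transformed values, pooled across chromosomes, so the
  result averages 0. Zero-coverage bases have no logarithm and are
  marked *undefined* rather than pseudocounted — a pseudocount would
  silently reshape every downstream correlation, whereas undefined
  positions are simply excluded by the common-position rule below.
* **GC track** (`gc_window_track()`): the GC fraction of every full
  147-bp window (the nucleosomal footprint), assigned to the central
  base; windows overhanging the ends are undefined rather than shrunken,
  so every defined value is a same-width statistic. N bases are excluded
  from numerator and denominator; an all-N window is undefined. The
  centered variant applies the same log2-and-center transform as the
  coverage map.
* **GC profile** (`gc_profile_around_read_starts()`): reads are aligned
  at their start (minus reads reverse-complemented, which leaves G/C
  status unchanged), base frequencies are tallied per offset over
  −flank..+flank (default 2000), and a 3-bp moving average removes the
  codon-driven 3-bp periodicity. Offsets beyond a chromosome end simply
  contribute nothing to that position's denominator. At the profile's
  outermost offsets the moving-average window shrinks rather than wraps.
* **K-mer relative coverage** (`kmer_mean_coverage()`): every
  forward-strand occurrence of a k-mer (k = 5) whose k bases are all
  defined in the track contributes the mean track value over those
  bases; the table averages contributions per k-mer, weighting each
  occurrence equally. AAAAA and TTTTT are kept as distinct entries; an
  optional flag pools reverse complements.
* **Comparisons** (`correlate_tracks()`, `density_grid()`,
  `region_report()`): Pearson correlation and 2-D histograms are
  computed over the positions defined in *every* participating track,
  pooled across chromosomes (no per-chromosome averaging, no
  subsampling); the region report emits one row per base with each
  track's value, the GC value and overlapping annotation labels.

## The fragment-length estimator, and when it works

`estimate_fragment_length()` histograms the inclusive distance
`q − p + 1` between every plus-strand read at `p` and every minus-strand
read at `q` on the same chromosome within a 300-bp window (pairs with
`q < p` are skipped, regardless of interleaving reads), and returns the
abundance-weighted mean. Because each fragment yields only one
sequenced end, the fragment-length signal comes from *different*
molecules cut at the same site: the estimator is informative exactly
when fragments are positionally clustered, as they are at
well-positioned nucleosomes. `simulate_positioned_fragments()` generates
that regime (phased sites spaced beyond the pairing window) and the
estimator recovers the realized mean length to a fraction of a base pair
at 10,000 fragments. On randomly positioned naked-DNA fragments the
+/− pairing is essentially background and the weighted mean gravitates
to the middle of the window irrespective of the true fragment length —
a caveat worth remembering when the estimator is applied to weakly
positioned data.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere internally; conversion
  happens only at the I/O boundary (BED/bedGraph are 0-based half-open
  on disk, wiggle 1-based). FASTA is read via Biostrings, interval
  formats via rtracklayer, and the pileup uses
  `GenomicRanges::coverage()`.
* A read-start table records the 5′-most genome coordinate per read:
  `chromStart` for plus reads, `chromEnd − 1` for minus reads.
* Tracks carry an explicit defined/undefined mask (`NA`); zero coverage
  is a *defined* value in count space and becomes undefined only through
  the logarithm. bedGraph round trips preserve defined values and never
  change the mask; overlapping intervals on input are an error.
* Centering invariants are enforced to 1e−9 (|mean| of a log2-centered
  track; |mean − 1| of a linear-normalized track) and verified in the
  tests, as are scale-freeness (linear) and shift-freeness (log2).
* Every stochastic operation is a pure function of its inputs and an
  integer seed; the pipeline derives per-stage seeds from one global
  seed so stages can be re-run in isolation.
* Degenerate inputs fail loudly: all-zero tracks cannot be normalized,
  empty +/− pairings cannot be averaged, zero-variance tracks cannot be
  correlated, and motifs outside their chromosome are rejected at plan
  time.

## Problem sizes

The tests and the reproduction script run on 100-kb genomes, 100
replicate digestions for the replicate-rate properties, 10,000 fragments
for the length-recovery check, and 1500 genome copies per digestion —
sizes at which every qualitative property of interest (GC enrichment of
the band, profile elevation over offsets 0–149, AAAAA/TTTTT at the
bottom of the 5-mer table, positive coverage–GC correlation) is stable
across seeds while a full suite stays in the minutes range. Real-data
analyses of a 12-Mb genome with ~10⁷ reads use the same code paths; only
the inputs grow.

## A complete run

```{r, eval = FALSE}
library(mnasebias)

config <- run_config(seed = 4)           # demo genome, default digestion
manifest <- run_pipeline(config, "mnasebias_run")
manifest$stats$fragment_gc_excess       # > 0: the band is GC-enriched
manifest$stats$coverage_gc_correlation_r # naked-DNA coverage ~ GC content
manifest$stats$lowest_kmers             # AAAAA/TTTTT at the bottom
```

The run writes every intermediate (FASTA, BED, bedGraph, TSV) plus a
JSON manifest of the resolved configuration and summary statistics to
the output directory; identical config and seed reproduce the manifest
byte-for-byte apart from the timestamp.

## Known limitations

* The two-level bond weight ignores finer sequence preferences of MNase
  (e.g. dinucleotide steps); the observed bias structure is therefore
  smoother than real data.
* No chromatin mode: the simulator cannot generate the *in vivo* or
  *in vitro* nucleosomal signal, only the naked-DNA control against
  which such data should be compared.
* The 10-bp rotational GC oscillation seen in nucleosomal fragments is
  out of scope; the simulated GC profile is oscillation-free by
  construction.
* bedGraph/wiggle cover the track interchange need; bigWig and BAM/SAM
  are not read — mapped read starts arrive as BED6.
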