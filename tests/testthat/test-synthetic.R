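test_that("simulated genomes carry exact telomeric arrays at both ends", {
  g <- simulate_genome(1e6, 2, 3000, motif = "CCCTAAA", seed = 7)
  expect_equal(sum(nchar(g$sequences)), 1e6)
  expect_equal(length(g$sequences), 2L)
  arr <- substr(strrep("CCCTAAA", ceiling(3000 / 7)), 1, 3000)
  for (chrom in g$sequences) {
    expect_equal(substr(chrom, nchar(chrom) - 2999, nchar(chrom)), arr)
    expect_equal(substr(chrom, 1, 3000), rc_chr(arr))
  }
  # same spec, same seed: byte-identical
  expect_identical(simulate_genome(1e6, 2, 3000, seed = 7), g)
  # different seed: different interior
  expect_false(identical(simulate_genome(1e6, 2, 3000, seed = 8)$sequences,
                         g$sequences))
})

test_that("telomere-free genomes and infeasible specs are handled", {
  g0 <- simulate_genome(5e4, 2, 0, seed = 1)
  expect_equal(sum(is_telomeric(g0$sequences, telomere_params())), 0L)
  expect_error(simulate_genome(1000, 2, 300), "less than the genome size")
})

test_that("error-free reads are exact genomic substrings at their ids", {
  g <- simulate_genome(5e4, 2, 1000, seed = 15)
  r <- simulate_reads(g, n_reads = 500, read_len = 120, seed = 16)
  meta <- decode_read_ids(r$reads$id)
  window <- substring(g$sequences[meta$chrom], meta$start,
                      meta$start + 119)
  neg <- meta$strand == "-"
  window[neg] <- rc_chr(window[neg])
  expect_equal(r$reads$seq, unname(window))
  expect_equal(r$truth$coverage, 500 * 120 / 5e4)
  expect_error(simulate_reads(g, 10, read_len = 3e4), "shortest chromosome")
})

test_that("substitution errors appear at roughly the requested rate", {
  g <- simulate_genome(2e4, 1, 0, seed = 17)
  r <- simulate_reads(g, n_reads = 400, read_len = 100, error_rate = 0.05,
                      seed = 18)
  meta <- decode_read_ids(r$reads$id)
  window <- substring(g$sequences[meta$chrom], meta$start, meta$start + 99)
  neg <- meta$strand == "-"
  window[neg] <- rc_chr(window[neg])
  mism <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, r$reads$seq, window)
  rate <- sum(mism) / (400 * 100)
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
})

test_that("k-mer histogram of 30X error-free reads peaks near expectation", {
  # expected k-mer coverage is 30 * (150 - 21 + 1) / 150 = 26
  g <- simulate_genome(2e5, 2, 0, seed = 42)
  n_reads <- 2e5 * 30 / 150
  r <- simulate_reads(g, n_reads = n_reads, read_len = 150, seed = 42)
  h <- count_kmers(r$reads, k = 21)
  mode <- find_coverage_mode(h, find_error_trough(h))
  expect_lt(abs(mode - 26) / 26, 0.10)
})

test_that("expected telomeric reads match a hand-enumerated toy genome", {
  # 300 bp of G filler then a 200-bp in-phase CCCTAAA array; reads 100 bp.
  # Concatemer occurrences start at 301, 308, ..., 462 (24 of them); a
  # placement p detects one iff p in [o-65, o], so each strand contributes
  # the union [236, 462] clipped to valid starts [1, 401]: 166 placements.
  genome <- c(chr1 = paste0(strrep("G", 300),
                            substr(strrep("CCCTAAA", 29), 1, 200)))
  res <- expected_telomeric_reads(genome, n_reads = 100, read_len = 100)
  expect_equal(res$n_placements, 802)        # 2 strands x 401 starts
  expect_equal(res$n_telomeric_placements, 332)
  expect_equal(res$expected, 100 * 332 / 802)

  # and agree with the independent brute-force placement enumerator
  bf <- brute_force_expected_telomeric(genome, 100, 100)
  expect_equal(res$p_telomeric, bf$p)
})

test_that("interval enumeration equals brute force on random genomes", {
  for (seed in 1:4) {
    g <- simulate_genome(8000, 2, 400, seed = seed)
    res <- expected_telomeric_reads(g, 1000, read_len = 120)
    bf <- brute_force_expected_telomeric(g, 1000, 120)
    expect_equal(res$p_telomeric, bf$p)
  }
  # telomere-free genome: zero expectation
  g0 <- simulate_genome(5000, 1, 0, seed = 5)
  expect_equal(expected_telomeric_reads(g0, 1000, 100)$expected, 0)
})

test_that("Monte-Carlo telomeric counts track the placement expectation", {
  g <- simulate_genome(1e5, 2, 2000, seed = 1)
  exp_t <- expected_telomeric_reads(g, 20000, read_len = 150)
  for (seed in 1:10) {
    r <- simulate_reads(g, n_reads = 20000, read_len = 150, seed = seed)
    t_mc <- count_telomeric_reads(r$reads, telomere_params())$n_telomeric
    sd_t <- sqrt(20000 * exp_t$p_telomeric * (1 - exp_t$p_telomeric))
    expect_lt(abs(t_mc - exp_t$expected), 3 * sd_t)
  }
})

test_that("mixtures are seed-deterministic with organelle-dominated depth", {
  m <- simulate_mixture(seed = 5)
  expect_identical(simulate_mixture(seed = 5), m)

  src_counts <- table(m$read_truth$source)
  # per-bp depth must scale with the copy ratios (1 : 15 : 40)
  depth <- src_counts[c("nuclear", "mito", "chloro")] /
    m$truth$sizes[c("nuclear", "mito", "chloro")]
  expect_true(depth[["mito"]] > 10 * depth[["nuclear"]])
  expect_true(depth[["chloro"]] > 25 * depth[["nuclear"]])

  # realized coverage table reflects those depths
  cov_by_src <- tapply(m$coverage$mean_cov, m$contigs$source, mean)
  expect_gt(cov_by_src[["mito"]], 80)
  expect_lt(abs(cov_by_src[["nuclear"]] - 8), 3)
})

test_that("chloroplast selection on the mixture recovers true chloro reads", {
  m <- simulate_mixture(seed = 6)
  sel <- select_chloroplast_reads(m$chloro_aln)
  truth <- m$long_reads$id[m$long_reads$source == "chloro" &
                           m$long_reads$length > 20000]
  expect_setequal(sel$read_ids, truth)
})

test_that("pileup simulation plants exactly the requested errors", {
  sim <- simulate_pileup(2e5, depth = 5, n_errors = 1, seed = 3)
  acc <- consensus_accuracy(sim$pileup)
  expect_equal(acc$error_positions, 1)
  expect_equal(sim$pileup$pos[sim$pileup$pos %in% sim$truth$error_positions],
               sim$truth$error_positions)

  clean <- simulate_pileup(5000, depth = 4, n_errors = 0, seed = 4)
  expect_equal(consensus_accuracy(clean$pileup)$accuracy_pct, 100)

  expect_identical(simulate_pileup(1000, 3, 5, seed = 8),
                   simulate_pileup(1000, 3, 5, seed = 8))
  expect_error(simulate_pileup(100, 0), "depth")
  expect_error(simulate_pileup(100, 3, error_positions = c(100)), "positions")
})
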