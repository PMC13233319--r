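paf_rec <- function(qname, qlen, qstart, qend, tname = "ref", tlen = 1e6,
                    tstart = 0, tend = qend - qstart) {
  data.frame(qname = qname, qlen = qlen, qstart = qstart, qend = qend,
             strand = "+", tname = tname, tlen = tlen, tstart = tstart,
             tend = tend, nmatch = qend - qstart, alnlen = qend - qstart,
             stringsAsFactors = FALSE)
}

test_that("query span fraction is the interval union over alignments", {
  expect_equal(query_span_fraction(paf_rec("r1", 25000, 0, 20000)), 0.8)
  two <- rbind(paf_rec("r1", 20000, 0, 10000),
               paf_rec("r1", 20000, 5000, 15000))
  expect_equal(query_span_fraction(two), 0.75)  # union is 15,000
  expect_equal(query_span_fraction(two[0, ]), 0)
  bad <- two
  bad$qlen <- c(20000, 21000)
  expect_error(query_span_fraction(bad), "inconsistent")
})

test_that("chloroplast read filter applies length strictly, span inclusively", {
  aln <- rbind(
    paf_rec("keep", 25000, 0, 20000),              # len ok, span 0.80
    paf_rec("short", 19000, 0, 18810),             # span 0.99 but too short
    paf_rec("border", 20000, 0, 20000),            # exactly 20 kb: "longer than" fails
    paf_rec("lowspan", 30000, 0, 22200),           # span 0.74
    paf_rec("split", 30000, 0, 12000),             # two pieces: union 0.75
    paf_rec("split", 30000, 12500, 23000)
  )
  sel <- select_chloroplast_reads(aln)
  expect_setequal(sel$read_ids, c("keep", "split"))
  expect_equal(sel$summary$n_reads, 2)
  expect_equal(sel$summary$total_bp, 55000)
})

test_that("mito triage fires inclusion rules and nuclear exclusion override", {
  ev <- data.frame(
    contig_id = c("prot", "cov_excl", "aln", "none"),
    length = 5000,
    has_protein_hit = c(TRUE, FALSE, FALSE, FALSE),
    mean_short_read_cov = c(8, 130, 8, 8),
    mito_aln_frac = c(0, 0, 0.55, 0.1),
    nuclear_aln_frac = c(0, 0.95, 0.2, 0.1),
    stringsAsFactors = FALSE
  )
  out <- classify_mito_contig(ev)
  expect_equal(out$verdict, c("retained", "excluded", "retained",
                              "unclassified"))
  expect_equal(out$reasons, c("PROTEIN_HIT", "HIGH_COV,NUCLEAR_EXCLUDE",
                              "MITO_ALN", ""))
})

test_that("triage thresholds are inclusive and verdicts order-independent", {
  ev <- data.frame(
    contig_id = c("at_cov", "at_mito", "at_nuc"),
    length = 1000,
    has_protein_hit = FALSE,
    mean_short_read_cov = c(120, 0, 0),
    mito_aln_frac = c(0, 0.5, 0.6),
    nuclear_aln_frac = c(0, 0, 0.9),
    stringsAsFactors = FALSE
  )
  out <- classify_mito_contig(ev)
  expect_equal(out$verdict, c("retained", "retained", "excluded"))

  perm <- c(3, 1, 2)
  out_perm <- classify_mito_contig(ev[perm, ])
  expect_equal(out_perm$verdict, out$verdict[perm])
})

test_that("raising thresholds is monotone in the expected direction", {
  set.seed(31)
  ev <- data.frame(
    contig_id = sprintf("c%d", 1:60),
    length = 1000,
    has_protein_hit = runif(60) < 0.2,
    mean_short_read_cov = runif(60, 0, 250),
    mito_aln_frac = runif(60),
    nuclear_aln_frac = runif(60),
    stringsAsFactors = FALSE
  )
  rank_of <- c(excluded = 0, unclassified = 1, retained = 2)
  v1 <- classify_mito_contig(ev, cov_threshold = 100)$verdict
  v2 <- classify_mito_contig(ev, cov_threshold = 180)$verdict
  # raising the coverage bar can only demote contigs
  expect_true(all(rank_of[v2] <= rank_of[v1]))
  n_excl1 <- sum(classify_mito_contig(ev, nuclear_frac = 0.7)$verdict ==
                 "excluded")
  n_excl2 <- sum(classify_mito_contig(ev, nuclear_frac = 0.95)$verdict ==
                 "excluded")
  expect_lte(n_excl2, n_excl1)
})

test_that("evidence assembly joins coverage, hits, and span fractions", {
  coverage <- data.frame(contig_id = c("a", "b"), length = c(1000, 2000),
                         mean_cov = c(10, 150), stringsAsFactors = FALSE)
  mito <- paf_rec("a", 1000, 0, 600, tname = "mito_ref")
  nuc <- paf_rec("b", 2000, 0, 1900, tname = "nuc")
  ev <- build_contig_evidence(coverage, protein_hits = "a", mito, nuc)
  expect_equal(ev$has_protein_hit, c(TRUE, FALSE))
  expect_equal(ev$mito_aln_frac, c(0.6, 0))
  expect_equal(ev$nuclear_aln_frac, c(0, 0.95))
})

test_that("contained-contig elimination requires full interior containment", {
  aln <- rbind(
    paf_rec("gone", 600, 0, 600, tname = "big", tlen = 1e6,
            tstart = 10000, tend = 10600),
    # flush with the target start: not interior
    paf_rec("flush", 600, 0, 600, tname = "big", tlen = 1e6,
            tstart = 0, tend = 600),
    # flush with the target end: not interior
    paf_rec("flush2", 600, 0, 600, tname = "big", tlen = 1e6,
            tstart = 999400, tend = 1e6),
    # only 95% aligned: kept at the default complete-containment fraction
    paf_rec("partial", 600, 0, 570, tname = "big", tlen = 1e6,
            tstart = 10000, tend = 10570),
    # target not longer than query: kept
    paf_rec("peer", 600, 0, 600, tname = "same", tlen = 600,
            tstart = 0, tend = 600),
    # self-hit: ignored
    paf_rec("selfy", 600, 0, 600, tname = "selfy", tlen = 600,
            tstart = 0, tend = 600)
  )
  res <- drop_contained_contigs(aln)
  expect_equal(res$removed_ids, "gone")
  expect_equal(res$summary$n_contigs, 1)
  expect_equal(res$summary$total_bp, 600)
  expect_equal(res$summary$mean_length, 600)

  # at a relaxed fraction the 95%-aligned contig goes too
  res2 <- drop_contained_contigs(aln, containment_frac = 0.9)
  expect_setequal(res2$removed_ids, c("gone", "partial"))
})
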