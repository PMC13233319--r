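#' Random nucleotide sequence
#'
#' i.i.d. bases at a given GC fraction, as a single string.
#' @param n length in bp.
#' @param gc GC fraction in `[0, 1]`.
#' @return character scalar.
#' @keywords internal
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Simulate a genome with telomeric chromosome ends
#'
#' Builds `n_chromosomes` equal-length chromosomes summing to `genome_size`
#' bp.  Each chromosome ends with a phase-aligned tandem array of the
#' telomere motif, exactly `telomere_len` bp long (truncated mid-motif if
#' needed), and begins with the reverse complement of such an array - the
#' orientation telomeres have on the two ends of a double-stranded
#' chromosome.  The interior is i.i.d. sequence at the requested GC.
#' Identical spec and seed give byte-identical output.
#'
#' @param genome_size total genome size `G` in bp.
#' @param n_chromosomes chromosome count `C`; lengths are `G %/% C` with the
#'   remainder on the last chromosome.
#' @param telomere_len true telomere length per chromosome end, bp (0 for a
#'   telomere-free genome).
#' @param motif telomere repeat unit (default plant `CCCTAAA`).
#' @param gc interior GC fraction (default 0.38, typical for conifer DNA).
#' @param seed RNG seed.
#' @return list with `sequences` (named character vector, `chr1`, ...) and
#'   `truth` (all parameters plus per-chromosome lengths).
#' @seealso [simulate_reads()], [expected_telomeric_reads()]
#' @export
simulate_genome <- function(genome_size, n_chromosomes = 2L,
                            telomere_len = 0L, motif = "CCCTAAA",
                            gc = 0.38, seed = 1L) {
  motif <- toupper(motif)
  stopifnot(genome_size >= 1, n_chromosomes >= 1,
            telomere_len >= 0, grepl("^[ACGT]+$", motif),
            gc >= 0, gc <= 1)
  if (2 * n_chromosomes * telomere_len >= genome_size) {
    stop("telomeres (2 * ", n_chromosomes, " * ", telomere_len,
         " bp) must total less than the genome size")
  }
  base_len <- genome_size %/% n_chromosomes
  lens <- rep(base_len, n_chromosomes)
  lens[n_chromosomes] <- lens[n_chromosomes] + genome_size %% n_chromosomes
  if (any(lens < 2 * telomere_len + 1)) {
    stop("chromosomes too short for the requested telomere length")
  }
  arr_end <- if (telomere_len > 0) {
    substr(strrep(motif, ceiling(telomere_len / nchar(motif))),
           1L, telomere_len)
  } else ""
  arr_start <- if (telomere_len > 0) revcomp(arr_end) else ""
  seqs <- with_seed(seed, {
    vapply(lens, function(len) {
      paste0(arr_start, random_dna(len - 2 * telomere_len, gc), arr_end)
    }, character(1L))
  })
  names(seqs) <- paste0("chr", seq_len(n_chromosomes))
  list(
    sequences = seqs,
    truth = list(genome_size = genome_size, n_chromosomes = n_chromosomes,
                 telomere_len = telomere_len, motif = motif, gc = gc,
                 seed = seed, chrom_lengths = lens)
  )
}

# Accept a simulate_genome() result or a named character vector.
as_genome <- function(genome) {
  if (is.list(genome) && !is.null(genome$sequences)) genome <- genome$sequences
  stopifnot(is.character(genome), length(genome) >= 1L)
  if (is.null(names(genome))) {
    names(genome) <- paste0("chr", seq_along(genome))
  }
  genome
}

#' Simulate uniform shotgun reads from a genome
#'
#' Draws `n_reads` fixed-length reads with start positions uniform over all
#' valid placements on both strands, then applies i.i.d. substitution errors
#' at `error_rate`.  Qualities are constant.  Read ids encode the true
#' `(chromosome, start, strand)` as `r<i>:<chrom>:<start>:<strand>`
#' (1-based start of the covered genome window) so oracle tests can verify
#' placement without alignment; see [decode_read_ids()].
#'
#' @param genome a [simulate_genome()] result or named character vector of
#'   chromosome sequences.
#' @param n_reads number of reads.
#' @param read_len read length in bp (default 150); must not exceed the
#'   shortest chromosome.
#' @param error_rate per-base substitution rate in `[0, 0.2]` (default 0).
#' @param seed RNG seed.
#' @return list with `reads` (data frame `id`, `seq`, `qual`) and `truth`
#'   (parameters plus realized fold coverage).
#' @export
simulate_reads <- function(genome, n_reads, read_len = 150L,
                           error_rate = 0, seed = 1L) {
  genome <- as_genome(genome)
  read_len <- as.integer(read_len)
  stopifnot(n_reads >= 1, error_rate >= 0, error_rate <= 0.2)
  lens <- nchar(genome)
  if (read_len > min(lens)) {
    stop("read length ", read_len, " exceeds the shortest chromosome (",
         min(lens), " bp)")
  }
  n_place <- lens - read_len + 1L
  reads <- with_seed(seed, {
    ci <- sample.int(length(genome), n_reads, replace = TRUE,
                     prob = n_place)
    start <- floor(runif(n_reads) * n_place[ci]) + 1L
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seq <- substring(genome[ci], start, start + read_len - 1L)
    neg <- strand == "-"
    if (any(neg)) seq[neg] <- revcomp(seq[neg])
    if (error_rate > 0) {
      n_err <- rbinom(n_reads, read_len, error_rate)
      for (i in which(n_err > 0L)) {
        chars <- strsplit(seq[i], "", fixed = TRUE)[[1L]]
        pos <- sample.int(read_len, n_err[i])
        chars[pos] <- vapply(chars[pos], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }, character(1L))
        seq[i] <- paste(chars, collapse = "")
      }
    }
    data.frame(
      id = sprintf("r%d:%s:%d:%s", seq_len(n_reads), names(genome)[ci],
                   start, strand),
      seq = seq,
      qual = strrep("I", read_len),
      stringsAsFactors = FALSE
    )
  })
  list(
    reads = reads,
    truth = list(n_reads = n_reads, read_len = read_len,
                 error_rate = error_rate, seed = seed,
                 coverage = n_reads * read_len / sum(lens))
  )
}

#' Decode provenance-carrying read ids
#'
#' @param ids ids produced by [simulate_reads()].
#' @return data frame with `chrom`, `start` (1-based), `strand`.
#' @export
decode_read_ids <- function(ids) {
  parts <- strsplit(ids, ":", fixed = TRUE)
  data.frame(
    chrom = vapply(parts, `[[`, character(1L), 2L),
    start = as.integer(vapply(parts, `[[`, character(1L), 3L)),
    strand = vapply(parts, `[[`, character(1L), 4L),
    stringsAsFactors = FALSE
  )
}

#' Expected telomeric read count by exhaustive placement enumeration
#'
#' Computes the exact probability that a uniformly placed read is telomeric
#' by enumerating every (position, strand) placement.  All occurrences of
#' the concatemer patterns (motif and reverse complement, overlapping
#' matches included) are located on each chromosome; the set of read starts
#' whose searched prefix window contains an occurrence is an interval union,
#' whose total size over both strands, divided by the number of placements,
#' gives the telomeric probability.  The expectation is `n_reads` times
#' that.  This is the brute-force oracle against which Monte-Carlo counts
#' from [simulate_reads()] + [count_telomeric_reads()] are checked.
#'
#' @param genome a [simulate_genome()] result or named character vector.
#' @param n_reads number of reads that will be drawn.
#' @param read_len read length in bp.
#' @param params a [telomere_params] object.
#' @return list with `expected` (expected telomeric reads),
#'   `p_telomeric`, `n_telomeric_placements`, `n_placements`.
#' @export
expected_telomeric_reads <- function(genome, n_reads, read_len = 150L,
                                     params = telomere_params()) {
  genome <- as_genome(genome)
  read_len <- as.integer(read_len)
  lens <- nchar(genome)
  stopifnot(read_len <= min(lens))
  trim_eff <- min(params$trim_len, read_len)
  pats <- unique(telomere_patterns(params))
  m5 <- nchar(pats[[1L]])
  if (m5 > trim_eff) {
    return(list(expected = 0, p_telomeric = 0, n_telomeric_placements = 0,
                n_placements = 2 * sum(lens - read_len + 1L)))
  }
  n_hit <- 0
  for (chrom in genome) {
    L <- nchar(chrom)
    subj <- Biostrings::DNAString(chrom)
    occ <- unlist(lapply(pats, function(p) {
      BiocGenerics::start(Biostrings::matchPattern(p, subj))
    }))
    valid <- IRanges::IRanges(start = 1L, end = L - read_len + 1L)
    if (length(occ)) {
      fwd <- IRanges::IRanges(start = occ + m5 - trim_eff, end = occ)
      rev <- IRanges::IRanges(start = occ + m5 - read_len,
                              end = occ - read_len + trim_eff)
      n_hit <- n_hit +
        sum(IRanges::width(IRanges::reduce(
          IRanges::restrict(fwd, 1L, L - read_len + 1L)))) +
        sum(IRanges::width(IRanges::reduce(
          IRanges::restrict(rev, 1L, L - read_len + 1L))))
    }
  }
  n_total <- 2 * sum(lens - read_len + 1L)
  p <- n_hit / n_total
  list(expected = n_reads * p, p_telomeric = p,
       n_telomeric_placements = n_hit, n_placements = n_total)
}

#' Simulate a nuclear/mitochondrial/chloroplast sequencing mixture
#'
#' Emulates total-DNA sequencing of a plant cell, where organelle genomes
#' are present in many copies per nuclear genome: three replicons are
#' generated and short reads are drawn from them proportional to
#' `size * copy_ratio`.  The replicons are chopped into contigs carrying
#' truth labels, with realized short-read coverage tabulated per contig;
#' alignment evidence (contig-vs-mitogenome, contig-vs-nuclear,
#' long-read-vs-chloroplast) is emitted as PAF-style tables derived from the
#' known provenance, including NUMT-like nuclear contigs with partial
#' mitochondrial similarity to exercise the exclusion rule.  All outputs
#' are deterministic in the seed.
#'
#' @param nuclear_size,mito_size,chloro_size replicon sizes in bp.
#' @param copy_ratio_mito,copy_ratio_chloro organelle copy number relative
#'   to nuclear (defaults 15 and 40).
#' @param nuclear_depth target nuclear fold coverage of short reads
#'   (default 8; organelle depth scales by the copy ratios).
#' @param read_len short-read length (default 150).
#' @param n_long_reads number of long reads for the chloroplast filter
#'   fixture (default 400).
#' @param gc GC fraction of all replicons.
#' @param seed RNG seed.
#' @return list with `replicons`, `short_reads`, `read_truth`, `contigs`
#'   (with `source` truth labels), `mito_candidates` (contig ids entering
#'   mitochondrial triage: mito- and nuclear-origin contigs, as after a
#'   mito-read extraction assembly), `coverage`, `protein_hits`,
#'   `mito_aln`, `nuclear_aln`, `chloro_aln`, `long_reads`, `truth`.
#' @export
simulate_mixture <- function(nuclear_size = 5e5, mito_size = 5e4,
                             chloro_size = 2e4, copy_ratio_mito = 15,
                             copy_ratio_chloro = 40, nuclear_depth = 8,
                             read_len = 150L, n_long_reads = 400L,
                             gc = 0.38, seed = 1L) {
  if (copy_ratio_mito < 1 || copy_ratio_chloro < 1) {
    stop("organelle copy ratios must be >= 1")
  }
  with_seed(seed, {
    sizes <- c(nuclear = nuclear_size, mito = mito_size, chloro = chloro_size)
    replicons <- vapply(sizes, random_dna, character(1L), gc = gc)
    weights <- sizes * c(1, copy_ratio_mito, copy_ratio_chloro)

    ## short reads, drawn proportional to size * copy number
    n_short <- round(nuclear_depth * sum(weights) / read_len)
    src <- sample(names(sizes), n_short, replace = TRUE,
                  prob = weights)
    start <- floor(runif(n_short) * (sizes[src] - read_len + 1)) + 1L
    strand <- sample(c("+", "-"), n_short, replace = TRUE)
    seq <- substring(replicons[src], start, start + read_len - 1L)
    neg <- strand == "-"
    seq[neg] <- revcomp(seq[neg])
    short_reads <- data.frame(
      id = sprintf("s%d:%s:%d:%s", seq_len(n_short), src, start, strand),
      seq = seq, qual = strrep("I", read_len), stringsAsFactors = FALSE
    )
    read_truth <- data.frame(id = short_reads$id, source = src,
                             stringsAsFactors = FALSE)

    ## contigs: chop each replicon into fixed-size pieces
    chop <- function(source, size, piece) {
      n <- max(1L, size %/% piece)
      start <- (seq_len(n) - 1L) * piece + 1L
      end <- c(start[-1L] - 1L, size)
      data.frame(
        contig_id = sprintf("ctg_%s_%02d", source, seq_len(n)),
        source = source, offset = start, length = end - start + 1L,
        stringsAsFactors = FALSE
      )
    }
    contigs <- rbind(chop("nuclear", nuclear_size, 20000L),
                     chop("mito", mito_size, 5000L),
                     chop("chloro", chloro_size, 10000L))

    ## realized coverage: assign each read to the contig containing its start
    cov <- numeric(nrow(contigs))
    for (i in seq_len(nrow(contigs))) {
      ci <- contigs[i, ]
      hit <- src == ci$source & start >= ci$offset &
        start < ci$offset + ci$length
      cov[i] <- sum(hit) * read_len / ci$length
    }
    coverage <- data.frame(contig_id = contigs$contig_id,
                           length = contigs$length, mean_cov = cov,
                           stringsAsFactors = FALSE)

    ## NUMT-like nuclear contigs: partial mitochondrial similarity but
    ## (correctly) near-complete nuclear alignment
    nuc_ids <- contigs$contig_id[contigs$source == "nuclear"]
    mito_ids <- contigs$contig_id[contigs$source == "mito"]
    numt_ids <- head(nuc_ids, 2L)

    paf_row <- function(qname, qlen, qfrac, tname, tlen) {
      span <- max(1L, round(qfrac * qlen))
      tstart <- floor(runif(1L) * (tlen - span))
      data.frame(qname = qname, qlen = qlen, qstart = 0L, qend = span,
                 strand = "+", tname = tname, tlen = tlen, tstart = tstart,
                 tend = tstart + span, nmatch = round(span * 0.98),
                 alnlen = span, stringsAsFactors = FALSE)
    }

    ## contig-vs-reference-mitogenome alignments
    mito_aln <- do.call(rbind, lapply(seq_len(nrow(contigs)), function(i) {
      ci <- contigs[i, ]
      frac <- if (ci$source == "mito") {
        runif(1L, 0.85, 1.0)
      } else if (ci$contig_id %in% numt_ids) {
        runif(1L, 0.52, 0.62)
      } else if (ci$source == "nuclear" && runif(1L) < 0.5) {
        runif(1L, 0.02, 0.15)
      } else {
        return(NULL)
      }
      paf_row(ci$contig_id, ci$length, frac, "mito_ref", mito_size)
    }))
    if (is.null(mito_aln)) mito_aln <- empty_paf()

    ## contig-vs-nuclear-assembly alignments
    nuclear_aln <- do.call(rbind, lapply(seq_len(nrow(contigs)), function(i) {
      ci <- contigs[i, ]
      frac <- if (ci$source == "nuclear") {
        runif(1L, 0.95, 1.0)
      } else if (ci$source == "mito" && runif(1L) < 0.6) {
        runif(1L, 0.02, 0.25)
      } else {
        return(NULL)
      }
      paf_row(ci$contig_id, ci$length, frac, "nuclear_asm", nuclear_size)
    }))
    if (is.null(nuclear_aln)) nuclear_aln <- empty_paf()

    ## reference protein hits on a subset of true mito contigs
    protein_hits <- mito_ids[seq_len(max(3L, length(mito_ids) %/% 2L))]

    ## long reads and their alignments to the reference chloroplast
    llen <- pmin(pmax(round(stats::rlnorm(n_long_reads, log(15000), 0.6)),
                      2000L), 60000L)
    lsrc <- sample(names(sizes), n_long_reads, replace = TRUE, prob = weights)
    long_reads <- data.frame(
      id = sprintf("L%d:%s", seq_len(n_long_reads), lsrc),
      length = llen, source = lsrc, stringsAsFactors = FALSE
    )
    chloro_aln <- do.call(rbind, lapply(seq_len(n_long_reads), function(i) {
      if (lsrc[i] == "chloro") {
        frac <- runif(1L, 0.80, 1.0)
        span <- round(frac * llen[i])
        # circular target much shorter than the read: the alignment wraps,
        # splitting into several query chunks each within the target length
        piece <- min(9000L, chloro_size - 1L)
        starts <- seq(0L, span - 1L, by = piece)
        do.call(rbind, lapply(starts, function(s) {
          paf_chunk(long_reads$id[i], llen[i], s, min(s + piece, span),
                    "chloro_ref", chloro_size)
        }))
      } else if (runif(1L) < 0.3) {
        span <- round(runif(1L, 0.1, 0.5) * llen[i])
        paf_chunk(long_reads$id[i], llen[i], 0L, span,
                  "chloro_ref", chloro_size)
      } else {
        NULL
      }
    }))
    if (is.null(chloro_aln)) chloro_aln <- empty_paf()

    list(
      replicons = replicons, short_reads = short_reads,
      read_truth = read_truth, contigs = contigs,
      mito_candidates = c(mito_ids, nuc_ids), coverage = coverage,
      protein_hits = protein_hits, mito_aln = mito_aln,
      nuclear_aln = nuclear_aln, chloro_aln = chloro_aln,
      long_reads = long_reads,
      truth = list(sizes = sizes, copy_ratio_mito = copy_ratio_mito,
                   copy_ratio_chloro = copy_ratio_chloro,
                   nuclear_depth = nuclear_depth, read_len = read_len,
                   numt_ids = numt_ids, seed = seed)
    )
  })
}

# One PAF record covering query interval [qstart, qend), placed at a random
# in-bounds target interval of equal span.
paf_chunk <- function(qname, qlen, qstart, qend, tname, tlen) {
  span <- qend - qstart
  if (span < 1L) return(NULL)
  span <- min(span, tlen)
  tstart <- floor(runif(1L) * (tlen - span))
  data.frame(qname = qname, qlen = qlen, qstart = qstart,
             qend = qstart + span, strand = "+", tname = tname, tlen = tlen,
             tstart = tstart, tend = tstart + span,
             nmatch = round(span * 0.95), alnlen = span,
             stringsAsFactors = FALSE)
}

#' Simulate a read pileup with planted consensus errors
#'
#' Generates a per-position pileup over a random reference at constant
#' depth.  At planted error positions every read carries the same non-
#' reference base (a true consensus error under the unanimous-contradiction
#' rule); elsewhere reads match the reference apart from i.i.d. sequencing
#' noise that is capped at `depth - 1` mismatches so it can never fake
#' unanimity at depth >= 2.
#'
#' @param n_positions number of pileup positions.
#' @param depth read depth at every position (>= 1).
#' @param n_errors number of planted consensus-error positions (ignored if
#'   `error_positions` is given).
#' @param error_positions 0-based positions of planted errors (optional).
#' @param noise_rate per-base sequencing noise rate (default 0.002).
#' @param contig_id contig name in the output.
#' @param seed RNG seed.
#' @return list with `pileup` (data frame `contig`, `pos`, `ref_base`,
#'   `read_bases`) and `truth` (planted error positions and parameters).
#' @export
simulate_pileup <- function(n_positions, depth, n_errors = 0L,
                            error_positions = NULL, noise_rate = 0.002,
                            contig_id = "ctg1", seed = 1L) {
  if (depth < 1) stop("depth must be >= 1")
  stopifnot(n_positions >= 1, noise_rate >= 0, noise_rate < 1)
  with_seed(seed, {
    ref <- sample(c("A", "C", "G", "T"), n_positions, replace = TRUE)
    if (is.null(error_positions)) {
      error_positions <- sort(sample.int(n_positions, n_errors) - 1L)
    } else {
      error_positions <- sort(unique(as.integer(error_positions)))
      if (any(error_positions < 0L | error_positions >= n_positions)) {
        stop("error positions must lie in [0, n_positions)")
      }
    }
    bases <- strrep(ref, depth)
    ## sequencing noise, never unanimous at depth >= 2
    n_mis <- rbinom(n_positions, depth, noise_rate)
    n_mis <- pmin(n_mis, depth - 1L)
    for (i in which(n_mis > 0L)) {
      chars <- rep(ref[i], depth)
      alt <- setdiff(c("A", "C", "G", "T"), ref[i])
      chars[sample.int(depth, n_mis[i])] <-
        sample(alt, n_mis[i], replace = TRUE)
      bases[i] <- paste(chars, collapse = "")
    }
    ## planted consensus errors: unanimous non-reference base
    for (p in error_positions) {
      i <- p + 1L
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1L)
      bases[i] <- strrep(alt, depth)
    }
    list(
      pileup = data.frame(contig = contig_id, pos = seq_len(n_positions) - 1L,
                          ref_base = ref, read_bases = bases,
                          stringsAsFactors = FALSE),
      truth = list(error_positions = error_positions, depth = depth,
                   noise_rate = noise_rate, n_positions = n_positions,
                   seed = seed)
    )
  })
}
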