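#' Parameters for telomeric-read detection
#'
#' A read counts as telomeric when its trimmed prefix contains a tandem run
#' of `min_copies` exact copies of the telomere motif (or of its reverse
#' complement, since shotgun reads come from both strands).  Defaults follow
#' standard survey practice for plants: motif `CCCTAAA`, five copies, a
#' 100-bp prefix, and 10 million reads examined.  For human data use motif
#' `CCCTAA`.
#'
#' @param motif telomere repeat unit over `{A,C,G,T}`.
#' @param min_copies number of exact tandem copies required (default 5).
#' @param trim_len prefix length searched, bp (default 100); reads shorter
#'   than this are searched whole.
#' @param n_reads how many reads to examine, in stream order (default 1e7).
#' @return an object of class `telomere_params`.
#' @export
telomere_params <- function(motif = "CCCTAAA", min_copies = 5L,
                            trim_len = 100L, n_reads = 1e7) {
  motif <- toupper(motif)
  if (!grepl("^[ACGT]+$", motif)) stop("motif must be a non-empty ACGT string")
  min_copies <- as.integer(min_copies)
  trim_len <- as.integer(trim_len)
  if (min_copies < 1L) stop("min_copies must be >= 1")
  if (trim_len < 1L) stop("trim_len must be >= 1")
  if (min_copies * nchar(motif) > trim_len) {
    stop("min_copies * motif length (", min_copies * nchar(motif),
         ") exceeds trim_len (", trim_len, "): no read could ever match")
  }
  if (n_reads < 1) stop("n_reads must be >= 1")
  structure(
    list(motif = motif, min_copies = min_copies, trim_len = trim_len,
         n_reads = n_reads),
    class = "telomere_params"
  )
}

#' @export
print.telomere_params <- function(x, ...) {
  cat("telomere detection: ", x$min_copies, "x ", x$motif,
      " (or reverse complement) in first ", x$trim_len, " bp; examine ",
      format(x$n_reads, big.mark = ",", scientific = FALSE), " reads\n",
      sep = "")
  invisible(x)
}

# The two concatemer patterns a telomeric prefix must contain.
telomere_patterns <- function(params) {
  c(strrep(params$motif, params$min_copies),
    strrep(revcomp(params$motif), params$min_copies))
}

#' Test reads for telomeric repeat content
#'
#' Vectorized detector: `TRUE` where the first `trim_len` bases of a read
#' contain `min_copies` exact tandem copies of the motif or of its reverse
#' complement as a substring.  Matching is exact (no mismatches); rotational
#' phase is immaterial because any sufficiently long pure repeat run
#' contains an in-phase concatemer.
#'
#' @param reads reads data frame (see [read_fastx()]) or character vector of
#'   sequences.
#' @param params a [telomere_params] object.
#' @return logical vector, one element per read.
#' @examples
#' p <- telomere_params()
#' is_telomeric(strrep("CCCTAAA", 5), p)
#' @export
is_telomeric <- function(reads, params = telomere_params()) {
  reads <- as_reads(reads)
  prefix <- substr(toupper(reads$seq), 1L, params$trim_len)
  pats <- telomere_patterns(params)
  hit <- grepl(pats[[1L]], prefix, fixed = TRUE)
  if (pats[[2L]] != pats[[1L]]) {
    hit <- hit | grepl(pats[[2L]], prefix, fixed = TRUE)
  }
  hit
}

#' Count telomeric reads in a read set
#'
#' Examines the first `min(params$n_reads, available)` reads in stream order
#' and counts those passing [is_telomeric()].
#'
#' @inheritParams is_telomeric
#' @return list with `n_telomeric` (reads matching) and `n_examined` (reads
#'   looked at).
#' @export
count_telomeric_reads <- function(reads, params = telomere_params()) {
  reads <- as_reads(reads)
  if (nrow(reads) == 0L) stop("no reads supplied")
  n_use <- min(nrow(reads), params$n_reads)
  sub <- reads[seq_len(n_use), , drop = FALSE]
  list(n_telomeric = sum(is_telomeric(sub, params)), n_examined = n_use)
}

#' Closed-form average telomere length
#'
#' Estimates the genome-wide average telomere length as
#' `L = G * T / (2 * R * C)`: the fraction of reads that are telomeric
#' (`T / R`) estimates the fraction of the genome (`G` bp) that is telomeric
#' sequence, which is spread over `2 * C` chromosome ends.
#'
#' @param genome_size haploid genome size `G` in bp.
#' @param n_telomeric number of telomeric reads `T`.
#' @param n_examined number of reads examined `R`.
#' @param n_chromosomes haploid chromosome count `C`.
#' @return average telomere length in bp, full precision (round to the
#'   nearest bp for reporting).
#' @examples
#' estimate_telomere_length(24e9, 319, 1e7, 12)    # 31,900 (loblolly pine)
#' estimate_telomere_length(3e9, 811, 1e7, 23)     # ~5,289 (human)
#' @export
estimate_telomere_length <- function(genome_size, n_telomeric, n_examined,
                                     n_chromosomes) {
  if (genome_size <= 0) stop("genome size must be positive")
  if (n_examined <= 0) stop("number of reads examined must be positive")
  if (n_chromosomes <= 0) stop("chromosome count must be positive")
  if (n_telomeric < 0 || n_telomeric > n_examined) {
    stop("telomeric read count must lie in [0, n_examined]")
  }
  genome_size * n_telomeric / (2 * n_examined * n_chromosomes)
}

#' End-to-end telomere length report
#'
#' Subsamples the read stream, counts telomeric reads, and applies the
#' closed-form estimator.  Genome size and chromosome count are inputs (from
#' a k-mer survey and cytology), not inferred.
#'
#' @inheritParams is_telomeric
#' @param genome_size haploid genome size in bp.
#' @param n_chromosomes haploid chromosome count.
#' @param label species or sample label for the report row.
#' @return data frame of class `telomere_estimate` with one row: `label`,
#'   `n_telomeric`, `n_examined`, `genome_size`, `n_chromosomes`,
#'   `telomere_length` (bp, full precision), and `n_short_reads` (reads
#'   shorter than `trim_len`, searched whole).
#' @export
telomere_report <- function(reads, params = telomere_params(), genome_size,
                            n_chromosomes, label = "sample") {
  reads <- as_reads(reads)
  cnt <- count_telomeric_reads(reads, params)
  len <- estimate_telomere_length(genome_size, cnt$n_telomeric,
                                  cnt$n_examined, n_chromosomes)
  n_short <- sum(nchar(reads$seq[seq_len(cnt$n_examined)]) < params$trim_len)
  out <- data.frame(
    label = label, n_telomeric = cnt$n_telomeric,
    n_examined = cnt$n_examined, genome_size = genome_size,
    n_chromosomes = n_chromosomes, telomere_length = len,
    n_short_reads = n_short, stringsAsFactors = FALSE
  )
  class(out) <- c("telomere_estimate", "data.frame")
  out
}

#' @export
print.telomere_estimate <- function(x, ...) {
  cat("Average telomere length estimate\n")
  y <- as.data.frame(x)
  y$telomere_length <- round(y$telomere_length)
  print.data.frame(y, row.names = FALSE)
  if (any(x$n_short_reads > 0)) {
    cat("note: ", sum(x$n_short_reads),
        " read(s) shorter than the trim length were searched whole\n",
        sep = "")
  }
  invisible(x)
}
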