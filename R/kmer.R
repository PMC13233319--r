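#' Construct a k-mer multiplicity histogram
#'
#' A k-mer histogram maps multiplicity `count` (how many times a distinct
#' canonical k-mer was observed) to `n_kmers`, the number of distinct
#' canonical k-mers observed that many times.  Its total occupied mass
#' `sum(count * n_kmers)` equals the number of k-mer instances counted.
#'
#' @param count vector of positive integer multiplicities (unique).
#' @param n_kmers vector of non-negative k-mer counts, same length.
#' @return data frame of class `kmer_histogram`, sorted by `count`.
#' @examples
#' h <- kmer_histogram(c(1, 2, 49), c(100, 10, 500))
#' sum(h$count * h$n_kmers)
#' @export
kmer_histogram <- function(count, n_kmers) {
  count <- as.numeric(count)
  n_kmers <- as.numeric(n_kmers)
  if (length(count) != length(n_kmers)) {
    stop("count and n_kmers must have equal length")
  }
  if (anyNA(count) || anyNA(n_kmers)) stop("histogram values must be non-NA")
  if (any(count < 1 | count != floor(count))) {
    stop("multiplicities must be positive integers")
  }
  if (any(n_kmers < 0)) stop("k-mer counts must be non-negative")
  if (anyDuplicated(count)) {
    stop("duplicate multiplicity value in histogram: ",
         count[duplicated(count)][1L])
  }
  o <- order(count)
  out <- data.frame(count = count[o], n_kmers = n_kmers[o])
  class(out) <- c("kmer_histogram", "data.frame")
  out
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat("k-mer histogram: ", nrow(x), " occupied multiplicities, ",
      format(sum(x$count * x$n_kmers), big.mark = ","),
      " k-mer instances\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

# Dense lookup vector n[1..max(count)] with absent multiplicities = 0.
hist_dense <- function(hist) {
  stopifnot(inherits(hist, "kmer_histogram"))
  n <- numeric(max(hist$count))
  n[hist$count] <- hist$n_kmers
  n
}

#' Count canonical k-mers in a set of reads
#'
#' Slides a window of width `k` over every read and counts each window's
#' canonical form: the lexicographic minimum of the window and its reverse
#' complement, so that counts are strand-independent.  Windows containing a
#' non-ACGT symbol (`N` or any other ambiguity code) are skipped whole.
#'
#' Counting streams over the reads and can shard k-mer space (`n_shards`
#' passes, each bounding the working set to roughly `1/n_shards` of the
#' distinct k-mers); the histogram is identical for any shard count.
#'
#' @param reads data frame with a `seq` column (see [read_fastx()]) or a
#'   character vector of sequences.
#' @param k word size, 3-31 (odd values avoid palindromic self-complements).
#' @param n_shards number of k-mer-space shards (default 1).
#' @return a [kmer_histogram].
#' @examples
#' count_kmers("ACGTACG", k = 3)
#' @export
count_kmers <- function(reads, k = 27L, n_shards = 1L) {
  reads <- as_reads(reads)
  k <- as.integer(k)
  if (k < 3L || k > 31L) stop("k must be between 3 and 31")
  if (nrow(reads) == 0L) stop("no reads supplied")
  if (k > max(nchar(reads$seq))) {
    stop("k = ", k, " exceeds the longest read (",
         max(nchar(reads$seq)), " bp)")
  }
  tab <- count_kmers_cpp(reads$seq, k, as.integer(n_shards))
  if (nrow(tab) == 0L) stop("no valid k-mer windows in input")
  kmer_histogram(tab$count, tab$n_kmers)
}

#' Locate the error trough of a k-mer histogram
#'
#' Sequencing-error k-mers pile up at low multiplicity and fall off steeply;
#' genomic k-mers form a peak around the k-mer coverage.  The trough is the
#' first local minimum separating the two: the smallest multiplicity `c >= 1`
#' with `n(c) <= n(c - 1)` (taking `n(0) = Inf`) and `n(c) <= n(c + 1)`,
#' absent multiplicities counting as zero.  Ties break toward smaller `c`.
#'
#' @param hist a [kmer_histogram].
#' @return the trough multiplicity (integer).
#' @seealso [find_coverage_mode()]
#' @examples
#' h <- kmer_histogram(1:5, c(1000, 100, 10, 12, 50))
#' find_error_trough(h)  # 3
#' @export
find_error_trough <- function(hist) {
  n <- hist_dense(hist)
  cmax <- length(n)
  left <- c(Inf, n[-cmax])          # n(c - 1) for c = 1..cmax
  right <- c(n[-1L], 0)             # n(c + 1), with n(cmax + 1) = 0
  ok <- n <= left & n <= right
  if (!any(ok)) {
    stop("histogram is monotone (no error trough); inspect it and supply ",
         "the threshold manually")
  }
  as.integer(which(ok)[1L])
}

#' Locate the coverage mode of a k-mer histogram
#'
#' The k-mer coverage is estimated as the mode of the histogram beyond the
#' error trough: `argmax` of `n(c)` over `c > trough`, ties broken toward
#' smaller `c`.
#'
#' @param hist a [kmer_histogram].
#' @param trough error trough from [find_error_trough()] (or user-supplied).
#' @return the modal multiplicity (integer), i.e. the k-mer coverage.
#' @export
find_coverage_mode <- function(hist, trough) {
  stopifnot(inherits(hist, "kmer_histogram"), trough >= 0)
  sub <- hist[hist$count > trough & hist$n_kmers > 0, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("no histogram mass beyond multiplicity ", trough)
  }
  as.integer(sub$count[which.max(sub$n_kmers)])
}

#' Lower-bound genome size from non-error k-mer mass
#'
#' Estimates haploid genome size as the total number of non-error k-mer
#' instances (occupied mass at multiplicities beyond the error trough)
#' divided by the k-mer coverage.  Because sub-threshold genomic k-mers are
#' discarded, this typically under-estimates, giving a lower bound.
#'
#' @param hist a [kmer_histogram].
#' @param kmer_coverage modal multiplicity from [find_coverage_mode()].
#' @param trough error trough from [find_error_trough()].
#' @param trough_inclusive if `TRUE`, k-mers with multiplicity exactly equal
#'   to the trough are counted as non-error (`count >= trough` rather than
#'   the default strict `count > trough`).
#' @return estimated genome size in bp (full precision; round only for
#'   reporting).
#' @export
genome_size_lower_bound <- function(hist, kmer_coverage, trough,
                                    trough_inclusive = FALSE) {
  stopifnot(inherits(hist, "kmer_histogram"))
  if (trough < 1) stop("trough must be >= 1")
  if (kmer_coverage <= trough) {
    stop("k-mer coverage (", kmer_coverage,
         ") must exceed the error trough (", trough, ")")
  }
  keep <- if (trough_inclusive) hist$count >= trough else hist$count > trough
  mass <- sum(hist$count[keep] * hist$n_kmers[keep])
  if (mass <= 0) stop("no non-error k-mer mass beyond the trough")
  mass / kmer_coverage
}

#' Convert k-mer coverage to read coverage
#'
#' A read of length `read_len` contains `read_len - k + 1` k-mers, so k-mer
#' coverage understates read coverage by that ratio:
#' `read_cov = kmer_cov * read_len / (read_len - k + 1)`.
#'
#' @param kmer_coverage modal k-mer multiplicity.
#' @param read_len average read length in bp.
#' @param k word size used for counting.
#' @return read coverage (fold), full precision.
#' @examples
#' kmer_to_read_coverage(49, 150, 27)  # 59.27 (59.3 at one decimal)
#' @export
kmer_to_read_coverage <- function(kmer_coverage, read_len, k) {
  if (read_len < k) stop("read length (", read_len, ") is shorter than k (", k, ")")
  if (kmer_coverage <= 0) stop("k-mer coverage must be positive")
  kmer_coverage * read_len / (read_len - k + 1)
}

#' Upper-bound genome size from total read bases and read coverage
#'
#' Estimates genome size as total sequenced bases divided by read coverage.
#' When the read coverage comes from the k-mer mode (which repeats and
#' heterozygosity bias downward), the quotient typically over-estimates,
#' giving an upper bound.
#'
#' @param total_read_bases total bases in the read set (bp).
#' @param read_coverage fold read coverage (e.g. from
#'   [kmer_to_read_coverage()]).
#' @return estimated genome size in bp.
#' @export
genome_size_upper_bound <- function(total_read_bases, read_coverage) {
  if (read_coverage <= 0) stop("read coverage must be positive")
  if (total_read_bases < 0) stop("total read bases must be non-negative")
  total_read_bases / read_coverage
}

#' Full genome-size estimate from a k-mer histogram
#'
#' Runs the whole survey pipeline on a histogram: locate the error trough
#' and coverage mode (unless supplied), form the k-mer-mass lower bound,
#' convert the mode to read coverage, and (if `total_read_bases` is given)
#' form the total-bases upper bound.
#'
#' @inheritParams genome_size_lower_bound
#' @param read_len average read length in bp (default 150).
#' @param k word size the histogram was counted with (default 27).
#' @param total_read_bases total bases in the read set, for the upper bound
#'   (optional).
#' @param trough,kmer_coverage override the detected trough / mode.
#' @return an object of class `genome_size_estimate` with fields
#'   `kmer_coverage`, `trough`, `lower_bound_bp`, `read_coverage`,
#'   `total_read_bases`, `upper_bound_bp` (all full precision; the print
#'   method rounds coverage to 1 decimal and sizes to 3 significant figures).
#' @export
estimate_genome_size <- function(hist, read_len = 150L, k = 27L,
                                 total_read_bases = NULL, trough = NULL,
                                 kmer_coverage = NULL,
                                 trough_inclusive = FALSE) {
  if (is.null(trough)) trough <- find_error_trough(hist)
  if (is.null(kmer_coverage)) kmer_coverage <- find_coverage_mode(hist, trough)
  lower <- genome_size_lower_bound(hist, kmer_coverage, trough,
                                   trough_inclusive)
  read_cov <- kmer_to_read_coverage(kmer_coverage, read_len, k)
  upper <- if (is.null(total_read_bases)) {
    NA_real_
  } else {
    genome_size_upper_bound(total_read_bases, read_cov)
  }
  structure(
    list(kmer_coverage = kmer_coverage, trough = trough,
         lower_bound_bp = lower, read_coverage = read_cov,
         total_read_bases = if (is.null(total_read_bases)) NA_real_
                            else total_read_bases,
         upper_bound_bp = upper, read_len = read_len, k = k),
    class = "genome_size_estimate"
  )
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  gbp <- function(v) paste0(signif(v / 1e9, 3), " Gbp")
  cat("Genome size estimate (k = ", x$k, ", read length ", x$read_len, ")\n",
      "  error trough:        ", x$trough, "\n",
      "  k-mer coverage:      ", x$kmer_coverage, "\n",
      "  read coverage:       ", round(x$read_coverage, 1), "\n",
      "  lower bound:         ", gbp(x$lower_bound_bp), " (",
      format(round(x$lower_bound_bp), big.mark = ",", scientific = FALSE), " bp)\n", sep = "")
  if (!is.na(x$upper_bound_bp)) {
    cat("  upper bound:         ", gbp(x$upper_bound_bp), " (",
        format(round(x$upper_bound_bp), big.mark = ",", scientific = FALSE), " bp)\n", sep = "")
  }
  invisible(x)
}
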