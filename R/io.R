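#' Read sequences from a FASTA or FASTQ file
#'
#' Reads a (optionally gzip-compressed) FASTA or FASTQ file into a data frame
#' of sequence records.  The format is auto-detected from the first non-empty
#' character (`>` for FASTA, `@` for FASTQ).  Bases are upper-cased and `U`
#' is mapped to `T`; `N` and other IUPAC ambiguity codes are preserved (they
#' are excluded later, at the k-mer/motif matching stage, not here).
#'
#' FASTQ records are validated: a quality string whose length differs from
#' its sequence, or a truncated trailing record, is a parse error naming the
#' offending line.
#'
#' @param path file path; `.gz` files are decompressed transparently.
#' @return data frame with columns `id` (first whitespace-delimited token of
#'   the header), `seq`, and `qual` (`NA` for FASTA input).
#' @seealso [write_fastx()]
#' @export
read_fastx <- function(path) {
  first <- read_first_char(path)
  if (identical(first, ">")) {
    x <- Biostrings::readBStringSet(path, format = "fasta")
    recs <- data.frame(
      id = first_token(names(x)),
      seq = clean_seq(as.character(x)),
      qual = NA_character_,
      stringsAsFactors = FALSE
    )
  } else if (identical(first, "@")) {
    recs <- read_fastq_validating(path)
  } else {
    stop("cannot detect FASTA/FASTQ format in '", path,
         "': first character is not '>' or '@'")
  }
  if (nrow(recs) > 0L && any(!nzchar(recs$seq))) {
    stop("empty sequence in record ", which(!nzchar(recs$seq))[1L])
  }
  rownames(recs) <- NULL
  recs
}

# Strict 4-line-per-record FASTQ reader.  Biostrings' fastq parser does not
# enforce the qual-length invariant nor reject truncated records, which the
# record contract here requires.
read_fastq_validating <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(last_nonempty(lines))]
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop("truncated FASTQ file '", path, "': ", n,
         " lines is not a multiple of 4 (record starting at line ",
         (n %/% 4L) * 4L + 1L, " is incomplete)")
  }
  hdr <- lines[seq(1L, n, by = 4L)]
  seq <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop("malformed FASTQ record at line ", (bad[1L] - 1L) * 4L + 1L,
         ": header does not start with '@'")
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop("malformed FASTQ record at line ", (bad[1L] - 1L) * 4L + 3L,
         ": separator line does not start with '+'")
  }
  bad <- which(nchar(qual) != nchar(seq))
  if (length(bad)) {
    stop("malformed FASTQ record at line ", (bad[1L] - 1L) * 4L + 1L,
         ": quality length ", nchar(qual[bad[1L]]),
         " != sequence length ", nchar(seq[bad[1L]]))
  }
  data.frame(
    id = first_token(sub("^@", "", hdr)),
    seq = clean_seq(seq),
    qual = qual,
    stringsAsFactors = FALSE
  )
}

#' Write sequence records to FASTA or FASTQ
#'
#' Records with a non-`NA` `qual` column are written as FASTQ, otherwise as
#' FASTA.  A `.gz` suffix on `path` triggers gzip compression.
#'
#' @param records data frame with columns `id`, `seq`, and optionally `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastx <- function(records, path) {
  records <- as_reads(records)
  has_qual <- "qual" %in% names(records) && nrow(records) > 0L &&
    !anyNA(records$qual)
  x <- Biostrings::BStringSet(records$seq)
  names(x) <- records$id
  compress <- grepl("\\.gz$", path)
  if (has_qual) {
    if (any(nchar(records$qual) != nchar(records$seq))) {
      stop("quality length differs from sequence length")
    }
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(records$qual),
      compress = compress
    )
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta", compress = compress)
  }
  invisible(path)
}

#' Read a PAF alignment file
#'
#' Parses the standard 12+-column PAF format into a data frame of minimal
#' alignment records (columns 1-11; the mapping-quality column and optional
#' SAM-style tags are ignored).  Coordinates keep PAF's native 0-based
#' half-open convention.
#'
#' @param path path to a PAF file (optionally gzipped).
#' @return data frame with columns `qname`, `qlen`, `qstart`, `qend`,
#'   `strand`, `tname`, `tlen`, `tstart`, `tend`, `nmatch`, `alnlen`.
#' @seealso [write_paf()], [query_span_fraction()]
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_paf())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    stop("malformed PAF at line ", which(nf < 12L)[1L],
         ": expected >= 12 tab-separated columns, found ", nf[nf < 12L][1L])
  }
  col <- function(i) vapply(fields, `[[`, character(1L), i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(v)) {
      stop("malformed PAF at line ", which(is.na(v))[1L],
           ": non-numeric ", what, " column")
    }
    v
  }
  out <- data.frame(
    qname = col(1L), qlen = num(2L, "query length"),
    qstart = num(3L, "query start"), qend = num(4L, "query end"),
    strand = col(5L),
    tname = col(6L), tlen = num(7L, "target length"),
    tstart = num(8L, "target start"), tend = num(9L, "target end"),
    nmatch = num(10L, "match count"), alnlen = num(11L, "alignment length"),
    stringsAsFactors = FALSE
  )
  validate_paf(out)
  out
}

#' Write alignment records as PAF
#'
#' @param aln data frame as returned by [read_paf()].
#' @param path output path.
#' @param mapq mapping quality to write in column 12 (default 60).
#' @return `path`, invisibly.
#' @export
write_paf <- function(aln, path, mapq = 60L) {
  validate_paf(aln)
  lines <- sprintf(
    "%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
    aln$qname, as.integer(aln$qlen), as.integer(aln$qstart),
    as.integer(aln$qend), aln$strand, aln$tname, as.integer(aln$tlen),
    as.integer(aln$tstart), as.integer(aln$tend), as.integer(aln$nmatch),
    as.integer(aln$alnlen), as.integer(mapq)
  )
  writeLines(lines, path)
  invisible(path)
}

empty_paf <- function() {
  data.frame(
    qname = character(), qlen = numeric(), qstart = numeric(),
    qend = numeric(), strand = character(), tname = character(),
    tlen = numeric(), tstart = numeric(), tend = numeric(),
    nmatch = numeric(), alnlen = numeric(), stringsAsFactors = FALSE
  )
}

validate_paf <- function(aln) {
  stopifnot(is.data.frame(aln))
  need <- c("qname", "qlen", "qstart", "qend", "strand",
            "tname", "tlen", "tstart", "tend", "nmatch", "alnlen")
  missing <- setdiff(need, names(aln))
  if (length(missing)) {
    stop("alignment table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(aln) == 0L) return(invisible(aln))
  with(aln, {
    if (any(!strand %in% c("+", "-"))) stop("PAF strand must be '+' or '-'")
    if (any(qstart < 0 | qstart >= qend | qend > qlen)) {
      stop("PAF query interval violates 0 <= qstart < qend <= qlen")
    }
    if (any(tstart < 0 | tstart >= tend | tend > tlen)) {
      stop("PAF target interval violates 0 <= tstart < tend <= tlen")
    }
    if (any(nmatch > alnlen)) stop("PAF nmatch exceeds alignment length")
  })
  invisible(aln)
}

#' Read a k-mer multiplicity histogram
#'
#' Reads the two-column text format emitted by k-mer counters ("histo"
#' format): one `count n_kmers` pair per whitespace-separated line, where
#' `count` is a k-mer multiplicity and `n_kmers` the number of distinct
#' canonical k-mers observed that many times.  Lines may appear in any
#' order; multiplicities absent from the file are treated as zero.
#'
#' @param path path to the histogram text file.
#' @return a [kmer_histogram] object.
#' @export
read_histogram <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("count", "n_kmers"),
                           colClasses = "numeric")
  kmer_histogram(tab$count, tab$n_kmers)
}

#' Write a k-mer histogram in two-column text format
#'
#' @param hist a [kmer_histogram].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "kmer_histogram"))
  writeLines(sprintf("%.0f %.0f", hist$count, hist$n_kmers), path)
  invisible(path)
}

#' Read a pileup table
#'
#' Reads a TSV with header columns `contig`, `pos` (0-based), `ref_base`, and
#' `read_bases` (the observed read bases at that position, concatenated into
#' one string; empty at zero coverage).
#'
#' @param path path to the TSV.
#' @return data frame of pileup columns.
#' @seealso [consensus_accuracy()], [simulate_pileup()]
#' @export
read_pileup <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, colClasses =
    c(contig = "character", pos = "integer", ref_base = "character",
      read_bases = "character"), na.strings = NULL)
  tab$read_bases[is.na(tab$read_bases)] <- ""
  validate_pileup(tab)
  tab
}

#' Write a pileup table as TSV
#'
#' @param pileup data frame with columns `contig`, `pos`, `ref_base`,
#'   `read_bases`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path) {
  validate_pileup(pileup)
  utils::write.table(pileup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_pileup <- function(tab) {
  need <- c("contig", "pos", "ref_base", "read_bases")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("pileup lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(paste(tab$contig, tab$pos))) {
    stop("pileup positions must be unique per (contig, pos)")
  }
  invisible(tab)
}

# --- small shared helpers ---------------------------------------------------

first_token <- function(x) sub("\\s.*$", "", x)

clean_seq <- function(x) chartr("U", "T", toupper(x))

last_nonempty <- function(lines) {
  nz <- which(nzchar(lines))
  if (length(nz)) nz[length(nz)] else 0L
}

read_first_char <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("empty file: '", path, "'")
    if (nzchar(line)) return(substr(line, 1L, 1L))
  }
}

# Accept either a reads data frame (id/seq[/qual]) or a bare character vector
# of sequences; always return the data frame form.
as_reads <- function(reads) {
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read%d", seq_along(reads))
    return(data.frame(id = ids, seq = unname(reads), stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  reads
}
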