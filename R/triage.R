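#' Fraction of a query covered by its alignments
#'
#' Computes the fraction of a single query (read or contig) covered by the
#' union of its alignment intervals.  Using the union, rather than the best
#' single alignment, matters for circular targets (a read spanning the
#' origin splits into two alignments) and fragmented references.
#'
#' @param alignments PAF-style data frame (see [read_paf()]) in which all
#'   records share one `qname` and a consistent `qlen`.
#' @return covered fraction in `[0, 1]`; `0` for an empty table.
#' @examples
#' aln <- data.frame(qname = "r1", qlen = 20000,
#'                   qstart = c(0, 5000), qend = c(10000, 15000),
#'                   strand = "+", tname = "t", tlen = 1e6,
#'                   tstart = 0, tend = 10000, nmatch = 9000, alnlen = 10000)
#' query_span_fraction(aln)  # union [0,15000) of 20000 -> 0.75
#' @export
query_span_fraction <- function(alignments) {
  if (nrow(alignments) == 0L) return(0)
  if (length(unique(alignments$qname)) != 1L) {
    stop("query_span_fraction expects alignments of a single query; got ",
         length(unique(alignments$qname)))
  }
  qlen <- unique(alignments$qlen)
  if (length(qlen) != 1L) {
    stop("inconsistent query length for '", alignments$qname[1L], "': ",
         paste(qlen, collapse = ", "))
  }
  covered <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(start = alignments$qstart + 1L, end = alignments$qend)
  )))
  covered / qlen
}

# Span fraction for every query in a PAF table at once.
query_span_fractions <- function(alignments) {
  if (nrow(alignments) == 0L) {
    return(data.frame(qname = character(), qlen = numeric(),
                      span_frac = numeric(), stringsAsFactors = FALSE))
  }
  pieces <- split(alignments, alignments$qname)
  data.frame(
    qname = names(pieces),
    qlen = vapply(pieces, function(p) unique(p$qlen)[1L], numeric(1L)),
    span_frac = vapply(pieces, query_span_fraction, numeric(1L)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Select chloroplast reads from alignments to a reference plastome
#'
#' Implements the long-read chloroplast filter: retain a read when it is
#' longer than `min_read_len` (strict, "longer than") and the union of its
#' alignments to the reference chloroplast spans at least `min_span_frac` of
#' the read (inclusive).
#'
#' @param alignments PAF-style data frame of read-vs-reference-chloroplast
#'   alignments.
#' @param min_read_len minimum read length in bp, exclusive (default 20000).
#' @param min_span_frac minimum aligned fraction of the read, inclusive
#'   (default 0.75).
#' @return list with `read_ids` (retained read names), `summary` (data frame
#'   with `n_reads` and `total_bp`), and `per_read` (the evaluated table).
#' @export
select_chloroplast_reads <- function(alignments, min_read_len = 20000,
                                     min_span_frac = 0.75) {
  if (min_span_frac <= 0 || min_span_frac > 1) {
    stop("min_span_frac must lie in (0, 1]")
  }
  spans <- query_span_fractions(alignments)
  spans$retained <- spans$qlen > min_read_len &
    spans$span_frac >= min_span_frac
  kept <- spans[spans$retained, , drop = FALSE]
  list(
    read_ids = kept$qname,
    summary = data.frame(n_reads = nrow(kept), total_bp = sum(kept$qlen)),
    per_read = spans
  )
}

# Rule codes, in fixed report order.
MITO_RULES <- c("PROTEIN_HIT", "HIGH_COV", "MITO_ALN", "NUCLEAR_EXCLUDE")

#' Classify mitochondrial candidate contigs
#'
#' Applies the mitochondrial triage cascade to per-contig evidence.  A
#' contig is *included* when any of: it has a hit from reference
#' mitochondrial proteins (`PROTEIN_HIT`); its mean short-read coverage is
#' at least `cov_threshold` (`HIGH_COV`, organelles being far more abundant
#' per cell than the nucleus); or at least `mito_frac` of its length aligns
#' to a reference mitogenome (`MITO_ALN`).  A contig is *excluded* -
#' overriding inclusion - when at least `nuclear_frac` of its length aligns
#' to nuclear sequence (`NUCLEAR_EXCLUDE`).  Contigs triggering no rule are
#' `unclassified`.
#'
#' @param evidence data frame with columns `contig_id`, `length`,
#'   `has_protein_hit` (logical), `mean_short_read_cov`, `mito_aln_frac`,
#'   `nuclear_aln_frac`; missing columns are treated as absent evidence
#'   (`FALSE`/`0`).
#' @param cov_threshold fold-coverage inclusion threshold, inclusive
#'   (default 120).
#' @param mito_frac mitogenome-alignment fraction for inclusion, inclusive
#'   (default 0.5).
#' @param nuclear_frac nuclear-alignment fraction for exclusion, inclusive
#'   (default 0.9).
#' @return data frame with one row per contig: `contig_id`, `verdict`
#'   (`retained` / `excluded` / `unclassified`), and `reasons`
#'   (comma-separated rule codes in fixed order).
#' @examples
#' ev <- data.frame(contig_id = "c1", length = 5000, has_protein_hit = TRUE,
#'                  mean_short_read_cov = 8, mito_aln_frac = 0,
#'                  nuclear_aln_frac = 0)
#' classify_mito_contig(ev)
#' @export
classify_mito_contig <- function(evidence, cov_threshold = 120,
                                 mito_frac = 0.5, nuclear_frac = 0.9) {
  stopifnot(is.data.frame(evidence), "contig_id" %in% names(evidence))
  if (cov_threshold <= 0) stop("cov_threshold must be positive")
  if (mito_frac <= 0 || mito_frac > 1) stop("mito_frac must lie in (0, 1]")
  if (nuclear_frac <= 0 || nuclear_frac > 1) {
    stop("nuclear_frac must lie in (0, 1]")
  }
  n <- nrow(evidence)
  get_col <- function(name, default) {
    if (name %in% names(evidence)) {
      v <- evidence[[name]]
      v[is.na(v)] <- default
      v
    } else {
      rep(default, n)
    }
  }
  protein <- as.logical(get_col("has_protein_hit", FALSE))
  cov <- get_col("mean_short_read_cov", 0)
  mito <- get_col("mito_aln_frac", 0)
  nuclear <- get_col("nuclear_aln_frac", 0)
  fired <- cbind(
    PROTEIN_HIT = protein,
    HIGH_COV = cov >= cov_threshold,
    MITO_ALN = mito >= mito_frac,
    NUCLEAR_EXCLUDE = nuclear >= nuclear_frac
  )
  verdict <- ifelse(fired[, "NUCLEAR_EXCLUDE"], "excluded",
             ifelse(rowSums(fired[, 1:3, drop = FALSE]) > 0, "retained",
                    "unclassified"))
  reasons <- apply(fired, 1L, function(f) paste(MITO_RULES[f], collapse = ","))
  data.frame(contig_id = evidence$contig_id, verdict = verdict,
             reasons = reasons, stringsAsFactors = FALSE)
}

#' Assemble per-contig triage evidence from standard inputs
#'
#' Joins a coverage table, a protein-hit list, and two alignment sets
#' (contig-vs-reference-mitogenome and contig-vs-nuclear-assembly) into the
#' evidence table [classify_mito_contig()] consumes.  Alignment fractions
#' are interval-union query span fractions.
#'
#' @param coverage data frame with columns `contig_id`, `length`,
#'   `mean_cov` (mean depth = aligned bases / contig length).
#' @param protein_hits character vector of contig ids with protein hits (or
#'   a data frame whose first column is the contig id).
#' @param mito_aln,nuclear_aln PAF-style data frames with contigs as
#'   queries; may be empty.
#' @return evidence data frame for [classify_mito_contig()].
#' @export
build_contig_evidence <- function(coverage, protein_hits = character(),
                                  mito_aln = empty_paf(),
                                  nuclear_aln = empty_paf()) {
  stopifnot(all(c("contig_id", "length", "mean_cov") %in% names(coverage)))
  if (is.data.frame(protein_hits)) protein_hits <- protein_hits[[1L]]
  frac_for <- function(aln) {
    sp <- query_span_fractions(aln)
    out <- setNames(sp$span_frac, sp$qname)
    v <- out[coverage$contig_id]
    v[is.na(v)] <- 0
    unname(v)
  }
  data.frame(
    contig_id = coverage$contig_id,
    length = coverage$length,
    has_protein_hit = coverage$contig_id %in% protein_hits,
    mean_short_read_cov = coverage$mean_cov,
    mito_aln_frac = frac_for(mito_aln),
    nuclear_aln_frac = frac_for(nuclear_aln),
    stringsAsFactors = FALSE
  )
}

#' Identify contigs contained in the interior of larger contigs
#'
#' During reference-guided scaffolding, short contigs whose whole length
#' aligns strictly inside a larger contig are redundant and dropped.  A
#' contig is removed when some alignment (to a different, longer contig)
#' covers at least `containment_frac` of it and the matched target interval
#' is interior: both target flanks non-empty (`tstart > 0`, `tend < tlen`).
#'
#' @param alignments PAF-style contig-vs-contig alignments; self hits
#'   (`qname == tname`) are ignored.
#' @param containment_frac minimum aligned query fraction per single
#'   alignment (default 1.0, i.e. complete containment).
#' @return list with `removed_ids` and `summary` (data frame with
#'   `n_contigs`, `total_bp`, `mean_length`).
#' @export
drop_contained_contigs <- function(alignments, containment_frac = 1.0) {
  if (containment_frac <= 0 || containment_frac > 1) {
    stop("containment_frac must lie in (0, 1]")
  }
  aln <- alignments[alignments$qname != alignments$tname, , drop = FALSE]
  hit <- aln[
    (aln$qend - aln$qstart) / aln$qlen >= containment_frac &
      aln$tlen > aln$qlen &
      aln$tstart > 0 &
      aln$tend < aln$tlen, , drop = FALSE]
  removed <- unique(hit$qname)
  lens <- hit$qlen[!duplicated(hit$qname)]
  list(
    removed_ids = removed,
    summary = data.frame(
      n_contigs = length(removed),
      total_bp = sum(lens),
      mean_length = if (length(removed)) mean(lens) else NA_real_
    )
  )
}
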