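#' Consensus accuracy from a read pileup
#'
#' Estimates assembly consensus accuracy by the unanimous-contradiction
#' rule: a position is an error only when *every* aligned read base differs
#' from the assembly base.  Positions with depth below `min_depth` are not
#' assessed (at depth 0 the rule is vacuous and at depth 1 a single
#' sequencing error masquerades as a consensus error); they are tallied
#' separately so any convention can be reconstructed.
#'
#' @param pileup data frame with columns `contig`, `pos`, `ref_base`,
#'   `read_bases` (observed bases concatenated into one string per
#'   position), as from [read_pileup()] or [simulate_pileup()].
#' @param min_depth minimum depth for a position to be assessed (default 2).
#' @return object of class `consensus_accuracy`: `assessed_positions`,
#'   `error_positions`, `accuracy_pct` (`100 * (1 - errors/assessed)`),
#'   `errors_per_bp`, `min_depth`, `low_depth_positions` (depth in
#'   `[1, min_depth)`), `zero_depth_positions`.
#' @examples
#' p <- data.frame(contig = "c", pos = 0:2, ref_base = c("A", "C", "G"),
#'                 read_bases = c("AAA", "TTT", "GGA"))
#' consensus_accuracy(p)
#' @export
consensus_accuracy <- function(pileup, min_depth = 2L) {
  validate_pileup(pileup)
  if (min_depth < 1) stop("min_depth must be >= 1")
  depth <- nchar(pileup$read_bases)
  assessed <- depth >= min_depth
  if (!any(assessed)) {
    stop("no position reaches min_depth = ", min_depth,
         "; nothing can be assessed")
  }
  ref <- toupper(pileup$ref_base)
  bases <- toupper(pileup$read_bases)
  # error <=> the assembly base never occurs among the read bases
  agrees <- logical(nrow(pileup))
  for (b in unique(ref)) {
    idx <- ref == b
    agrees[idx] <- grepl(b, bases[idx], fixed = TRUE)
  }
  err <- assessed & !agrees
  n_assessed <- sum(assessed)
  n_err <- sum(err)
  structure(
    list(
      assessed_positions = n_assessed,
      error_positions = n_err,
      accuracy_pct = 100 * (1 - n_err / n_assessed),
      errors_per_bp = n_err / n_assessed,
      min_depth = as.integer(min_depth),
      low_depth_positions = sum(depth >= 1L & depth < min_depth),
      zero_depth_positions = sum(depth == 0L)
    ),
    class = "consensus_accuracy"
  )
}

#' @export
print.consensus_accuracy <- function(x, ...) {
  cat("Consensus accuracy (min depth ", x$min_depth, ")\n",
      "  assessed positions: ", format(x$assessed_positions, big.mark = ","),
      "\n  error positions:    ", x$error_positions,
      "\n  accuracy:           ",
      formatC(x$accuracy_pct, format = "f", digits = 4), "%",
      "\n  errors per bp:      ", signif(x$errors_per_bp, 3), "\n", sep = "")
  if (x$low_depth_positions > 0 || x$zero_depth_positions > 0) {
    cat("  not assessed:       ", x$low_depth_positions, " low-depth, ",
        x$zero_depth_positions, " zero-depth\n", sep = "")
  }
  invisible(x)
}

#' Normalize gene counts by assembly ploidy
#'
#' Gene counts from a polyploid assembly overstate the per-haploid-genome
#' complement; dividing by ploidy makes counts comparable across assemblies
#' of different ploidy.  The result is rounded half-to-even to an integer
#' for reporting.
#'
#' @param count vector of raw gene counts.
#' @param ploidy assembly ploidy (positive integer, recycled).
#' @return integer-valued numeric vector, `round(count / ploidy)`.
#' @examples
#' normalize_by_ploidy(2070, 3)  # 690
#' @export
normalize_by_ploidy <- function(count, ploidy) {
  if (any(ploidy < 1 | ploidy != floor(ploidy))) {
    stop("ploidy must be a positive integer")
  }
  if (any(count < 0)) stop("counts must be non-negative")
  round(count / ploidy)
}
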