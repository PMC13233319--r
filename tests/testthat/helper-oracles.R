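# Independent oracles, deliberately naive: pure-R string manipulation only,
# sharing no code with the package internals they check.

# reverse complement, character by character
rc_chr <- function(x) {
  vapply(strsplit(chartr("ACGTacgt", "TGCATGCA", x), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1L))
}

# dictionary-of-strings canonical k-mer counter
naive_count_kmers <- function(seqs, k) {
  kmers <- unlist(lapply(seqs, function(s) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) return(character())
    w <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    w[grepl("^[ACGT]+$", w)]
  }))
  if (length(kmers) == 0L) return(NULL)
  canon <- pmin(kmers, rc_chr(kmers))
  mult <- table(canon)
  tab <- table(as.integer(mult))
  data.frame(count = as.numeric(names(tab)), n_kmers = as.numeric(tab))
}

# number of ACGT-only k-mer windows (for the mass-conservation invariant)
naive_window_count <- function(seqs, k) {
  sum(vapply(seqs, function(s) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) return(0L)
    w <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    sum(grepl("^[ACGT]+$", w))
  }, integer(1L)))
}

# brute-force expected telomeric read count: materialize every (position,
# strand) placement as a read string and search its prefix directly
brute_force_expected_telomeric <- function(genome, n_reads, read_len,
                                           motif = "CCCTAAA",
                                           min_copies = 5L, trim_len = 100L) {
  if (is.list(genome)) genome <- genome$sequences
  pats <- unique(c(strrep(motif, min_copies),
                   strrep(rc_chr(motif), min_copies)))
  hits <- 0L
  total <- 0L
  for (chrom in genome) {
    n_place <- nchar(chrom) - read_len + 1L
    starts <- seq_len(n_place)
    fwd <- substring(chrom, starts, starts + read_len - 1L)
    for (reads in list(fwd, rc_chr(fwd))) {
      prefix <- substr(reads, 1L, trim_len)
      hit <- grepl(pats[[1L]], prefix, fixed = TRUE)
      if (length(pats) > 1L) {
        hit <- hit | grepl(pats[[2L]], prefix, fixed = TRUE)
      }
      hits <- hits + sum(hit)
      total <- total + n_place
    }
  }
  list(expected = n_reads * hits / total, p = hits / total)
}

# random read set over the full IUPAC-ish alphabet used in tests
random_reads <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1L))
}

expect_same_histogram <- function(hist, oracle) {
  expect_equal(as.numeric(hist$count), oracle$count)
  expect_equal(as.numeric(hist$n_kmers), oracle$n_kmers)
}
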