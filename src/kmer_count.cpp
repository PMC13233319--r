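#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <cstdint>

using namespace Rcpp;

// 2-bit base codes; -1 marks anything outside {A,C,G,T}
static inline int base_code(char b) {
    switch (b) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// Canonical k-mer counting with a rolling 2-bit encoding (k <= 31 so a k-mer
// fits a 64-bit word).  A window containing any non-ACGT symbol is skipped
// whole.  The canonical form is the lexicographic minimum of the window and
// its reverse complement, which under 2-bit A<C<G<T encoding is the numeric
// minimum.  Sharding partitions k-mer space by canonical value modulo
// n_shards so that peak map size is bounded; the histogram is the sum over
// shards and is independent of n_shards.
// [[Rcpp::export]]
DataFrame count_kmers_cpp(CharacterVector seqs, int k, int n_shards = 1) {
    if (k < 1 || k > 31)
        stop("k must be between 1 and 31");
    if (n_shards < 1)
        stop("n_shards must be >= 1");

    const uint64_t mask = (1ULL << (2 * k)) - 1;
    const int rc_shift = 2 * (k - 1);
    std::map<uint64_t, double> histo;  // multiplicity -> number of distinct k-mers

    for (int shard = 0; shard < n_shards; ++shard) {
        std::unordered_map<uint64_t, uint64_t> counts;
        for (R_xlen_t i = 0; i < seqs.size(); ++i) {
            const char *s = CHAR(STRING_ELT(seqs, i));
            uint64_t fwd = 0, rc = 0;
            int run = 0;
            for (const char *p = s; *p; ++p) {
                int c = base_code(*p);
                if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
                fwd = ((fwd << 2) | (uint64_t)c) & mask;
                rc = (rc >> 2) | ((uint64_t)(3 - c) << rc_shift);
                if (++run >= k) {
                    uint64_t canon = fwd < rc ? fwd : rc;
                    if (n_shards == 1 || (canon % (uint64_t)n_shards) == (uint64_t)shard)
                        ++counts[canon];
                }
            }
        }
        for (const auto &kv : counts)
            histo[kv.second] += 1.0;
    }

    R_xlen_t nbin = (R_xlen_t)histo.size();
    NumericVector count(nbin), n_kmers(nbin);
    R_xlen_t j = 0;
    for (const auto &kv : histo) {
        count[j] = (double)kv.first;
        n_kmers[j] = kv.second;
        ++j;
    }
    return DataFrame::create(_["count"] = count, _["n_kmers"] = n_kmers);
}
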