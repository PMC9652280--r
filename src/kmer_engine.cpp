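#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// 2-bit base codes A=0, C=1, G=2, T=3 preserve lexicographic order, so the
// numeric order of packed k-mer codes equals string order and the canonical
// form min(x, revcomp(x)) can be taken on codes. k <= 31 fits in 62 bits.

static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static inline std::string decode_kmer(uint64_t code, int k) {
    static const char alpha[4] = {'A', 'C', 'G', 'T'};
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) {
        s[i] = alpha[code & 3ULL];
        code >>= 2;
    }
    return s;
}

// Streams one sequence, calling fn(canonical_code) for every window of
// length k made of unambiguous bases. Windows touching an ambiguous base
// are skipped entirely.
template <typename F>
static void for_each_canonical(const char* seq, size_t n, int k, F fn) {
    if ((int)n < k) return;
    const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
    const int shift = 2 * (k - 1);
    uint64_t fwd = 0, rev = 0;
    int run = 0;  // consecutive valid bases ending at current position
    for (size_t i = 0; i < n; ++i) {
        int b = base_code(seq[i]);
        if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
        if (++run >= k) fn(fwd < rev ? fwd : rev);
    }
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector reads, int k) {
    std::unordered_map<uint64_t, int> tab;
    tab.reserve(1 << 16);
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        if (reads[r] == NA_STRING) continue;
        const char* s = CHAR(reads[r]);
        size_t n = LENGTH(reads[r]);
        for_each_canonical(s, n, k, [&](uint64_t code) { ++tab[code]; });
    }
    std::vector<std::pair<uint64_t, int> > v(tab.begin(), tab.end());
    std::sort(v.begin(), v.end());
    R_xlen_t m = (R_xlen_t)v.size();
    CharacterVector kmers(m);
    IntegerVector counts(m);
    for (R_xlen_t i = 0; i < m; ++i) {
        kmers[i] = decode_kmer(v[i].first, k);
        counts[i] = v[i].second;
    }
    return List::create(_["kmer"] = kmers, _["count"] = counts);
}

// [[Rcpp::export]]
CharacterVector cpp_canonicalize(CharacterVector x) {
    R_xlen_t n = x.size();
    CharacterVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
        const char* s = CHAR(x[i]);
        size_t len = LENGTH(x[i]);
        std::string fwd(len, 'N'), rev(len, 'N');
        bool ok = true;
        for (size_t j = 0; j < len; ++j) {
            int b = base_code(s[j]);
            if (b < 0) { ok = false; break; }
            fwd[j] = "ACGT"[b];
            rev[len - 1 - j] = "ACGT"[3 - b];
        }
        if (!ok) { out[i] = NA_STRING; continue; }
        out[i] = (fwd <= rev) ? fwd : rev;
    }
    return out;
}

// Scans one contig against a canonical k-mer set. Returns per-base presence
// (covered by >= 1 member window), per-start absence, per-start validity
// (window free of ambiguous bases) and per-base scannability (covered by
// >= 1 valid window).
// [[Rcpp::export]]
List cpp_scan_presence(std::string ref, CharacterVector members, int k) {
    std::unordered_set<uint64_t> set;
    set.reserve(members.size() * 2 + 1);
    for (R_xlen_t i = 0; i < members.size(); ++i) {
        if (members[i] == NA_STRING) continue;
        const char* s = CHAR(members[i]);
        if ((int)LENGTH(members[i]) != k)
            stop("strain set member with length != k");
        uint64_t fwd = 0, rev = 0;
        bool ok = true;
        const int shift = 2 * (k - 1);
        for (int j = 0; j < k; ++j) {
            int b = base_code(s[j]);
            if (b < 0) { ok = false; break; }
            fwd = (fwd << 2) | (uint64_t)b;
            rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
        }
        if (ok) set.insert(fwd < rev ? fwd : rev);
    }

    const size_t n = ref.size();
    const size_t nwin = (int)n >= k ? n - k + 1 : 0;
    LogicalVector presence(n, false);
    LogicalVector scannable(n, false);
    LogicalVector absent_start(nwin);
    LogicalVector valid_start(nwin);

    if (nwin > 0) {
        const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
        const int shift = 2 * (k - 1);
        uint64_t fwd = 0, rev = 0;
        int run = 0;
        for (size_t i = 0; i < n; ++i) {
            int b = base_code(ref[i]);
            if (b < 0) { run = 0; fwd = 0; rev = 0; }
            else {
                fwd = ((fwd << 2) | (uint64_t)b) & mask;
                rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
                ++run;
            }
            if (i + 1 >= (size_t)k) {
                size_t s = i + 1 - k;  // window start
                bool valid = (run >= k);
                valid_start[s] = valid;
                if (valid) {
                    for (size_t j = s; j <= i; ++j) scannable[j] = true;
                    uint64_t canon = fwd < rev ? fwd : rev;
                    if (set.count(canon)) {
                        absent_start[s] = false;
                        for (size_t j = s; j <= i; ++j) presence[j] = true;
                    } else {
                        absent_start[s] = true;
                    }
                } else {
                    absent_start[s] = true;
                }
            }
        }
    }
    return List::create(_["presence"] = presence,
                        _["absentStart"] = absent_start,
                        _["validStart"] = valid_start,
                        _["scannable"] = scannable);
}
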