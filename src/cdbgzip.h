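#ifndef CDBGZIP_H
#define CDBGZIP_H

#include <Rcpp.h>
#include <string>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <cstdint>

// width of a fixed-width field indexing n alternatives: ceil(log2(n)),
// floored at `floor_one` (color/class index fields keep a 1-bit floor so a
// field always exists when n <= 2)
inline int ceil_log2(long long n) {
    int b = 0;
    long long v = 1;
    while (v < n) { v <<= 1; ++b; }
    return b;
}

inline int index_width(long long n) {
    int w = ceil_log2(n);
    return w < 1 ? 1 : w;
}

inline char dna_complement(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return '\0';
    }
}

// reverse complement; caller guarantees ACGT only
inline std::string revcomp(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (auto& c : r) c = dna_complement(c);
    return r;
}

// lexicographic min of s and its reverse complement
inline std::string canonical_kmer(const std::string& s) {
    std::string r = revcomp(s);
    return (s <= r) ? s : r;
}

// append `value` as `width` bits, most significant bit first
inline void append_bits(std::string& out, unsigned long long value, int width) {
    for (int i = width - 1; i >= 0; --i)
        out.push_back(((value >> i) & 1ULL) ? '1' : '0');
}

#endif
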