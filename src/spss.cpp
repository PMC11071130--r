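#include "cdbgzip.h"
using namespace Rcpp;

// Greedy simplitig construction over canonical k-mers.
//
// Repeatedly seed a new simplitig with the lexicographically smallest unused
// k-mer, then extend to the right and afterwards to the left; at each step
// the candidate bases A,C,G,T are tried in order and the first whose new
// window canonicalizes to an unused k-mer is taken. Deterministic; any valid
// spectrum-preserving decomposition is acceptable downstream, this one is
// simply reproducible.
//
// [[Rcpp::export]]
CharacterVector cpp_build_simplitigs(const CharacterVector& kmers, int k) {
    static const char ALPHA[4] = {'A', 'C', 'G', 'T'};
    R_xlen_t n = kmers.size();
    std::vector<std::string> ks(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        ks[i] = as<std::string>(kmers[i]);
        if ((int)ks[i].size() != k)
            stop("k-mer %d has length %d, expected %d",
                 (int)(i + 1), (int)ks[i].size(), k);
        if (ks[i] != canonical_kmer(ks[i]))
            stop("k-mer %s is not canonical", ks[i].c_str());
    }
    std::sort(ks.begin(), ks.end());
    for (R_xlen_t i = 1; i < n; ++i)
        if (ks[i] == ks[i - 1])
            stop("duplicate k-mer %s in input set", ks[i].c_str());
    std::unordered_set<std::string> unused(ks.begin(), ks.end());

    std::vector<std::string> out;
    size_t ptr = 0;
    while (true) {
        while (ptr < ks.size() && !unused.count(ks[ptr])) ++ptr;
        if (ptr == ks.size()) break;
        std::string s = ks[ptr];
        unused.erase(s);

        // extend right, tracking the current (k-1)-suffix incrementally
        std::string suf = s.substr(1);
        bool extended = true;
        while (extended) {
            extended = false;
            for (char c : ALPHA) {
                std::string w = suf + c;
                std::string can = canonical_kmer(w);
                if (unused.count(can)) {
                    s.push_back(c);
                    suf = w.substr(1);
                    unused.erase(can);
                    extended = true;
                    break;
                }
            }
        }
        // extend left; accumulate prepended bases reversed, splice at the end
        std::string left;
        std::string pre = s.substr(0, k - 1);
        extended = true;
        while (extended) {
            extended = false;
            for (char c : ALPHA) {
                std::string w = c + pre;
                std::string can = canonical_kmer(w);
                if (unused.count(can)) {
                    left.push_back(c);
                    pre = w.substr(0, k - 1);
                    unused.erase(can);
                    extended = true;
                    break;
                }
            }
        }
        if (!left.empty()) {
            std::reverse(left.begin(), left.end());
            s = left + s;
        }
        out.push_back(s);
    }
    return wrap(out);
}
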