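#include "cdbgzip.h"
using namespace Rcpp;

static void upper_inplace(std::string& s) {
    for (auto& c : s)
        if (c >= 'a' && c <= 'z') c -= 32;
}

static bool is_acgt(char c) {
    return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// Canonicalize each k-mer: lexicographic min of the string and its reverse
// complement. Lowercase accepted; any other character is an error reporting
// element and position.
// [[Rcpp::export]]
CharacterVector cpp_canonicalize(const CharacterVector& xs) {
    R_xlen_t n = xs.size();
    CharacterVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string s = as<std::string>(xs[i]);
        upper_inplace(s);
        for (size_t j = 0; j < s.size(); ++j)
            if (!is_acgt(s[j]))
                stop("non-ACGT character '%c' in k-mer %d at position %d",
                     s[j], (int)(i + 1), (int)(j + 1));
        out[i] = canonical_kmer(s);
    }
    return out;
}

// All canonical k-mers of seq, one per length-k window whose characters are
// all ACGT; windows touching any other character (e.g. N) are skipped.
// Multiplicities preserved, window order.
// [[Rcpp::export]]
CharacterVector cpp_extract_kmers(std::string seq, int k) {
    if (k < 2) stop("k must be >= 2");
    upper_inplace(seq);
    long long n = (long long)seq.size();
    std::vector<std::string> out;
    if (n >= k) {
        long long last_bad = -1; // most recent non-ACGT position seen
        for (long long i = 0; i + k <= n; ++i) {
            // advance bad tracker over the window's last character(s)
            for (long long j = std::max(i, last_bad + 1); j < i + k; ++j)
                if (!is_acgt(seq[j])) last_bad = j;
            if (last_bad < i)
                out.push_back(canonical_kmer(seq.substr(i, k)));
        }
    }
    return wrap(out);
}

// Count canonical k-mers over a set of sequences; return those with total
// count >= a, sorted ascending (deterministic order).
// [[Rcpp::export]]
CharacterVector cpp_count_kmers(const CharacterVector& seqs, int k, int a) {
    if (k < 2) stop("k must be >= 2");
    if (a < 1) stop("abundance threshold must be >= 1");
    std::unordered_map<std::string, int> counts;
    for (R_xlen_t s = 0; s < seqs.size(); ++s) {
        std::string seq = as<std::string>(seqs[s]);
        upper_inplace(seq);
        long long n = (long long)seq.size();
        long long last_bad = -1;
        for (long long i = 0; i + k <= n && i >= 0; ++i) {
            for (long long j = std::max(i, last_bad + 1); j < i + k; ++j)
                if (!is_acgt(seq[j])) last_bad = j;
            if (last_bad < i)
                ++counts[canonical_kmer(seq.substr(i, k))];
        }
    }
    std::vector<std::string> keep;
    keep.reserve(counts.size());
    for (auto& kv : counts)
        if (kv.second >= a) keep.push_back(kv.first);
    std::sort(keep.begin(), keep.end());
    return wrap(keep);
}

// Flat list of canonical k-mers over all windows of all simplitigs, in
// (simplitig, offset) order, plus per-simplitig window counts.
// [[Rcpp::export]]
List cpp_spss_kmers(const CharacterVector& simplitigs, int k) {
    std::vector<std::string> flat;
    IntegerVector nwin(simplitigs.size());
    for (R_xlen_t s = 0; s < simplitigs.size(); ++s) {
        std::string seq = as<std::string>(simplitigs[s]);
        upper_inplace(seq);
        long long n = (long long)seq.size();
        if (n < k)
            stop("simplitig %d is shorter than k", (int)(s + 1));
        for (long long i = 0; i + k <= n; ++i) {
            for (long long j = i; j < i + k; ++j)
                if (!is_acgt(seq[j]))
                    stop("non-ACGT character in simplitig %d", (int)(s + 1));
            flat.push_back(canonical_kmer(seq.substr(i, k)));
        }
        nwin[s] = (int)(n - k + 1);
    }
    return List::create(_["kmers"] = wrap(flat), _["n_windows"] = nwin);
}

// Per-simplitig color-class sequences: for each window, look up the class
// bit string of its canonical k-mer. `kmers`/`classes` are aligned vectors.
// [[Rcpp::export]]
List cpp_class_sequences(const CharacterVector& simplitigs, int k,
                         const CharacterVector& kmers,
                         const CharacterVector& classes) {
    if (kmers.size() != classes.size())
        stop("k-mer and class vectors differ in length");
    std::unordered_map<std::string, int> idx;
    idx.reserve(kmers.size() * 2);
    for (R_xlen_t i = 0; i < kmers.size(); ++i)
        idx[as<std::string>(kmers[i])] = (int)i;
    List out(simplitigs.size());
    long long covered = 0;
    std::vector<char> seen(kmers.size(), 0);
    for (R_xlen_t s = 0; s < simplitigs.size(); ++s) {
        std::string seq = as<std::string>(simplitigs[s]);
        upper_inplace(seq);
        long long n = (long long)seq.size();
        if (n < k) stop("simplitig %d is shorter than k", (int)(s + 1));
        CharacterVector cs(n - k + 1);
        for (long long i = 0; i + k <= n; ++i) {
            std::string can = canonical_kmer(seq.substr(i, k));
            auto it = idx.find(can);
            if (it == idx.end())
                stop("k-mer %s from the string set is absent from the color mapping",
                     can.c_str());
            cs[i] = classes[it->second];
            if (!seen[it->second]) { seen[it->second] = 1; ++covered; }
        }
        out[s] = cs;
    }
    if (covered < (long long)kmers.size()) {
        for (R_xlen_t i = 0; i < kmers.size(); ++i)
            if (!seen[i])
                stop("k-mer %s of the color mapping is not covered by the string set",
                     as<std::string>(kmers[i]).c_str());
    }
    return out;
}
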