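#include "cdbgzip.h"
using namespace Rcpp;

// Optimal prefix-code lengths for frequencies given in ascending class-value
// order. Deterministic: leaves are sorted by (frequency, class order) and on
// equal weight a leaf is merged before an internal node (two-queue method).
// M == 1 yields the single length 0 (empty codeword).
// [[Rcpp::export]]
IntegerVector cpp_huffman_lengths(const NumericVector& freqs) {
    int M = (int)freqs.size();
    if (M < 1) stop("frequency table is empty");
    for (int i = 0; i < M; ++i)
        if (!(freqs[i] >= 1)) stop("all class frequencies must be >= 1");
    IntegerVector out(M);
    if (M == 1) { out[0] = 0; return out; }

    std::vector<int> ord(M);
    for (int i = 0; i < M; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
        return freqs[a] < freqs[b];
    });

    int total = 2 * M - 1;
    std::vector<double> w(total);
    std::vector<int> parent(total, -1);
    for (int i = 0; i < M; ++i) w[i] = freqs[ord[i]];
    int leaf_lo = 0, tree_lo = M, next = M;
    auto pick = [&]() {
        bool leaf_ok = leaf_lo < M;
        bool tree_ok = tree_lo < next;
        if (leaf_ok && (!tree_ok || w[leaf_lo] <= w[tree_lo]))
            return leaf_lo++;
        return tree_lo++;
    };
    for (int m = 0; m < M - 1; ++m) {
        int a = pick();
        int b = pick();
        w[next] = w[a] + w[b];
        parent[a] = next;
        parent[b] = next;
        ++next;
    }
    for (int i = 0; i < M; ++i) {
        int d = 0;
        for (int v = i; parent[v] != -1; v = parent[v]) ++d;
        out[ord[i]] = d;
    }
    return out;
}

// Canonical code assignment: symbols ordered by (code length, class order),
// consecutive binary codewords MSB-first. Input/output aligned with the
// ascending class-value order.
// [[Rcpp::export]]
CharacterVector cpp_canonical_codes(const IntegerVector& lengths) {
    int M = (int)lengths.size();
    CharacterVector out(M);
    if (M == 1) {
        if (lengths[0] != 0) stop("a single class must have code length 0");
        out[0] = "";
        return out;
    }
    std::vector<int> ord(M);
    for (int i = 0; i < M; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
        return lengths[a] < lengths[b];
    });
    unsigned long long code = 0;
    int prev_len = lengths[ord[0]];
    if (prev_len < 1) stop("code lengths must be >= 1 when M > 1");
    for (int r = 0; r < M; ++r) {
        int len = lengths[ord[r]];
        if (len > 62) stop("Huffman code length exceeds 62 bits");
        if (r > 0) {
            code = (code + 1) << (len - prev_len);
        }
        std::string bits;
        append_bits(bits, code, len);
        out[ord[r]] = bits;
        prev_len = len;
    }
    return out;
}
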