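#include "cdbgzip.h"
using namespace Rcpp;

// Serialize the sorted class list as (delta, boundary):
//  - delta: first class verbatim in C bits, then per class the ascending
//    indices where it differs from its predecessor, each in an
//    index_width(C)-bit field;
//  - boundary: same length, '1' wherever a class's encoding begins.
// [[Rcpp::export]]
List cpp_serialize_classes(const CharacterVector& classes, int C) {
    int M = (int)classes.size();
    if (M < 1) stop("class list is empty");
    int w = index_width(C);
    std::string delta, boundary;
    std::string prev;
    for (int i = 0; i < M; ++i) {
        std::string cur = as<std::string>(classes[i]);
        if ((int)cur.size() != C)
            stop("class %d has %d bits, expected C = %d", i + 1,
                 (int)cur.size(), C);
        for (char c : cur)
            if (c != '0' && c != '1') stop("class %d is not a bit string", i + 1);
        if (i == 0) {
            delta += cur;
            boundary.push_back('1');
            boundary.append(C - 1, '0');
        } else {
            if (!(prev < cur))
                stop("classes must be strictly ascending by numeric value");
            bool first_field = true;
            for (int j = 0; j < C; ++j) {
                if (cur[j] != prev[j]) {
                    append_bits(delta, (unsigned long long)j, w);
                    boundary.push_back(first_field ? '1' : '0');
                    boundary.append(w - 1, '0');
                    first_field = false;
                }
            }
            if (first_field)
                stop("duplicate class at position %d", i + 1);
        }
        prev = cur;
    }
    return List::create(_["delta"] = delta, _["boundary"] = boundary);
}

// Inverse of cpp_serialize_classes.
// [[Rcpp::export]]
CharacterVector cpp_deserialize_classes(const std::string& delta,
                                        const std::string& boundary, int C) {
    if (delta.size() != boundary.size())
        stop("delta and boundary bitvectors differ in length");
    if (delta.empty()) stop("empty class-table serialization");
    if ((int)delta.size() < C || boundary[0] != '1')
        stop("malformed boundary bitvector");
    int w = index_width(C);
    // boundary positions
    std::vector<size_t> starts;
    for (size_t i = 0; i < boundary.size(); ++i) {
        char c = boundary[i];
        if (c == '1') starts.push_back(i);
        else if (c != '0') stop("boundary is not a bit string");
    }
    starts.push_back(delta.size());
    std::vector<std::string> classes;
    std::string prev;
    for (size_t m = 0; m + 1 < starts.size(); ++m) {
        size_t lo = starts[m], hi = starts[m + 1];
        if (m == 0) {
            if (hi - lo != (size_t)C)
                stop("first class encoding must occupy exactly C bits");
            prev = delta.substr(lo, C);
            for (char c : prev)
                if (c != '0' && c != '1') stop("delta is not a bit string");
        } else {
            if ((hi - lo) % w != 0 || hi == lo)
                stop("class %d encoding is not a whole number of index fields",
                     (int)(m + 1));
            std::string cur = prev;
            long long last_idx = -1;
            for (size_t p = lo; p < hi; p += w) {
                long long idx = 0;
                for (int b = 0; b < w; ++b) {
                    char c = delta[p + b];
                    if (c != '0' && c != '1') stop("delta is not a bit string");
                    idx = (idx << 1) | (c == '1');
                }
                if (idx >= C) stop("color index %lld out of range", idx);
                if (idx <= last_idx)
                    stop("difference indices are not strictly ascending");
                last_idx = idx;
                cur[idx] = (cur[idx] == '0') ? '1' : '0';
            }
            if (!(prev < cur))
                stop("reconstructed classes are not strictly ascending");
            prev = cur;
        }
        classes.push_back(prev);
    }
    return wrap(classes);
}
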