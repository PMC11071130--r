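#include "cdbgzip.h"
using namespace Rcpp;

// ---- bit cursor -----------------------------------------------------------

struct BitCursor {
    const std::string& bits;
    size_t pos;
    BitCursor(const std::string& b, size_t p) : bits(b), pos(p) {}
    bool read() {
        if (pos >= bits.size()) stop("bit stream exhausted mid-field");
        char c = bits[pos++];
        if (c == '0') return false;
        if (c == '1') return true;
        stop("invalid character in bit stream");
    }
    unsigned long long read_uint(int width) {
        unsigned long long v = 0;
        for (int i = 0; i < width; ++i) v = (v << 1) | (read() ? 1ULL : 0ULL);
        return v;
    }
};

static int log2_exact(int v) {
    if (v < 2) stop("runDivisor must be a power of two >= 2");
    int b = 0;
    int x = v;
    while (x > 1) { x >>= 1; ++b; }
    if ((1 << b) != v) stop("runDivisor must be a power of two >= 2");
    return b;
}

// ---- run lengths ----------------------------------------------------------

// quotient floor(runLen/runDivisor) in unary ('1's then a '0'), then the
// remainder in exactly log2(runDivisor) bits, MSB first
// [[Rcpp::export]]
std::string cpp_encode_run_length(double runLen, int runDivisor) {
    int rbits = log2_exact(runDivisor);
    if (runLen < 0 || runLen != std::floor(runLen))
        stop("run length must be a non-negative integer");
    unsigned long long n = (unsigned long long)runLen;
    unsigned long long q = n / (unsigned)runDivisor;
    unsigned long long r = n % (unsigned)runDivisor;
    std::string out(q, '1');
    out.push_back('0');
    append_bits(out, r, rbits);
    return out;
}

// [[Rcpp::export]]
List cpp_decode_run_length(const std::string& bits, double pos0, int runDivisor) {
    int rbits = log2_exact(runDivisor);
    BitCursor cur(bits, (size_t)pos0);
    unsigned long long q = 0;
    while (cur.read()) ++q;
    unsigned long long r = cur.read_uint(rbits);
    return List::create(_["value"] = (double)(q * (unsigned)runDivisor + r),
                        _["pos"] = (double)cur.pos);
}

// [[Rcpp::export]]
IntegerVector cpp_diff_indices(const std::string& prev, const std::string& cur) {
    if (prev.size() != cur.size())
        stop("color vectors differ in length (%d vs %d)",
             (int)prev.size(), (int)cur.size());
    std::vector<int> out;
    for (size_t i = 0; i < prev.size(); ++i)
        if (prev[i] != cur[i]) out.push_back((int)i);
    return wrap(out);
}

// [[Rcpp::export]]
std::string cpp_int_to_bits(double value, int width) {
    std::string out;
    append_bits(out, (unsigned long long)value, width);
    return out;
}

// ---- encoding -------------------------------------------------------------

typedef std::unordered_map<std::string, std::string> CodeMap;

static int hamming(const std::string& a, const std::string& b) {
    int h = 0;
    for (size_t i = 0; i < a.size(); ++i)
        if (a[i] != b[i]) ++h;
    return h;
}

// Encode one simplitig's class sequence under a fixed (maxDif, useLocalID)
// mode. Four per-k-mer cases: Skip / Small class difference / End of run /
// Store class ID. Returns the m bits, the local table entries (classes in
// first-appearance order; empty unless use_local) and the total cost in bits
// (3 metadata bits + |m| + on-disk local-table bits).
static void encode_one(const std::vector<std::string>& cs, int maxDif,
                       bool use_local, const CodeMap& enc, int C, int M,
                       int runDivisor, std::string& m,
                       std::vector<std::string>& local, double& total_bits) {
    int n = (int)cs.size();
    int wC = index_width(C);
    int rbits = log2_exact(runDivisor);

    m.clear();
    local.clear();
    int wL = 0;
    std::unordered_map<std::string, int> local_id;
    double local_disk_bits = 0;
    if (use_local) {
        for (const auto& c : cs)
            if (!local_id.count(c)) {
                local_id[c] = (int)local.size();
                local.push_back(c);
            }
        wL = ceil_log2((long long)local.size());
        local_disk_bits = index_width(M); // field holding l-1
        for (const auto& e : local) {
            auto it = enc.find(e);
            if (it == enc.end()) stop("class absent from global table");
            local_disk_bits += (double)it->second.size();
        }
    }

    int run_start = 0;
    for (int i = 0; i < n; ++i) {
        const std::string& cur = cs[i];
        bool same_prev = (i > 0 && cs[i - 1] == cur);
        if (!same_prev) run_start = i;
        bool same_next = (i + 1 < n && cs[i + 1] == cur);

        if (same_prev && same_next) {
            continue; // Skip: interior of a run
        }
        if (same_prev) {
            // End of run: same class as predecessor, closes the run
            m += (maxDif > 0) ? "11" : "1";
            unsigned long long runLen = (unsigned long long)(i - run_start);
            unsigned long long q = runLen / (unsigned)runDivisor;
            m.append(q, '1');
            m.push_back('0');
            append_bits(m, runLen % (unsigned)runDivisor, rbits);
            continue;
        }
        int h = (i > 0) ? hamming(cs[i - 1], cur) : 0;
        if (i > 0 && h > 0 && h <= maxDif) {
            // Small class difference vs the preceding k-mer
            m += "10";
            if (maxDif == 2) m.push_back(h == 2 ? '1' : '0');
            for (size_t j = 0; j < cur.size(); ++j)
                if (cs[i - 1][j] != cur[j])
                    append_bits(m, (unsigned long long)j, wC);
            continue;
        }
        // Store the class ID
        m.push_back('0');
        if (use_local) {
            append_bits(m, (unsigned long long)local_id[cur], wL);
        } else {
            auto it = enc.find(cur);
            if (it == enc.end()) stop("class absent from global table");
            m += it->second;
        }
    }
    total_bits = 3.0 + (double)m.size() + local_disk_bits;
}

static CodeMap make_code_map(const CharacterVector& classes,
                             const CharacterVector& codes) {
    if (classes.size() != codes.size())
        stop("class and code vectors differ in length");
    CodeMap enc;
    enc.reserve(classes.size() * 2);
    for (R_xlen_t i = 0; i < classes.size(); ++i)
        enc[as<std::string>(classes[i])] = as<std::string>(codes[i]);
    return enc;
}

static std::vector<std::string> as_class_vec(const CharacterVector& classSeq,
                                             int& C) {
    std::vector<std::string> cs(classSeq.size());
    if (classSeq.size() == 0) stop("class sequence is empty");
    for (R_xlen_t i = 0; i < classSeq.size(); ++i) {
        cs[i] = as<std::string>(classSeq[i]);
        if (i == 0) C = (int)cs[0].size();
        else if ((int)cs[i].size() != C)
            stop("class sequence mixes vector lengths");
    }
    return cs;
}

// [[Rcpp::export]]
List cpp_encode_simplitig(const CharacterVector& classSeq, int maxDif,
                          bool useLocalID, const CharacterVector& classes,
                          const CharacterVector& codes, int runDivisor) {
    if (maxDif < 0 || maxDif > 2) stop("maxDif must be 0, 1 or 2");
    int C = 0;
    std::vector<std::string> cs = as_class_vec(classSeq, C);
    CodeMap enc = make_code_map(classes, codes);
    std::string m;
    std::vector<std::string> local;
    double total = 0;
    encode_one(cs, maxDif, useLocalID, enc, C, (int)classes.size(),
               runDivisor, m, local, total);
    return List::create(_["m"] = m, _["local"] = wrap(local),
                        _["total_bits"] = total);
}

static List choose_one(const std::vector<std::string>& cs, const CodeMap& enc,
                       int C, int M, int runDivisor) {
    std::string best_m, m;
    std::vector<std::string> best_local, local;
    double best_total = 0, total = 0;
    int best_d = -1;
    bool best_l = false;
    NumericVector costs(6);
    int slot = 0;
    for (int d = 0; d <= 2; ++d) {
        for (int l = 0; l <= 1; ++l) { // UseLocalID = FALSE first
            encode_one(cs, d, l == 1, enc, C, M, runDivisor, m, local, total);
            costs[slot++] = total;
            if (best_d < 0 || total < best_total) {
                best_total = total;
                best_m = m;
                best_local = local;
                best_d = d;
                best_l = (l == 1);
            }
        }
    }
    return List::create(_["max_dif"] = best_d, _["use_local_id"] = best_l,
                        _["m"] = best_m, _["local"] = wrap(best_local),
                        _["total_bits"] = best_total,
                        _["candidate_costs"] = costs);
}

// [[Rcpp::export]]
List cpp_choose_encoding(const CharacterVector& classSeq,
                         const CharacterVector& classes,
                         const CharacterVector& codes, int runDivisor) {
    int C = 0;
    std::vector<std::string> cs = as_class_vec(classSeq, C);
    CodeMap enc = make_code_map(classes, codes);
    return choose_one(cs, enc, C, (int)classes.size(), runDivisor);
}

// Mode search over every simplitig at once (keeps the per-call conversion of
// the global table out of the per-simplitig loop).
// [[Rcpp::export]]
List cpp_encode_choose_all(const List& classSeqs, const CharacterVector& classes,
                           const CharacterVector& codes, int C, int runDivisor) {
    CodeMap enc = make_code_map(classes, codes);
    int S = (int)classSeqs.size();
    IntegerVector max_dif(S);
    LogicalVector use_local(S);
    CharacterVector ms(S);
    List locals(S);
    NumericVector totals(S);
    for (int s = 0; s < S; ++s) {
        CharacterVector cseq = classSeqs[s];
        int Cs = 0;
        std::vector<std::string> cs = as_class_vec(cseq, Cs);
        if (Cs != C) stop("class vector length disagrees with C");
        List r = choose_one(cs, enc, C, (int)classes.size(), runDivisor);
        max_dif[s] = as<int>(r["max_dif"]);
        use_local[s] = as<bool>(r["use_local_id"]);
        ms[s] = as<std::string>(r["m"]);
        locals[s] = r["local"];
        totals[s] = as<double>(r["total_bits"]);
    }
    return List::create(_["max_dif"] = max_dif, _["use_local_id"] = use_local,
                        _["m"] = ms, _["local"] = locals,
                        _["total_bits"] = totals);
}

// ---- decoding -------------------------------------------------------------

struct HuffDecoder {
    std::unordered_map<std::string, int> by_code;
    size_t max_len;
    int M;
    HuffDecoder(const CharacterVector& codes) : max_len(0), M((int)codes.size()) {
        for (R_xlen_t i = 0; i < codes.size(); ++i) {
            std::string c = as<std::string>(codes[i]);
            if (M > 1) {
                by_code[c] = (int)i;
                max_len = std::max(max_len, c.size());
            }
        }
    }
    // returns class index; consumes 0 bits when M == 1
    int decode(BitCursor& cur) const {
        if (M == 1) return 0;
        std::string acc;
        while (acc.size() <= max_len) {
            acc.push_back(cur.read() ? '1' : '0');
            auto it = by_code.find(acc);
            if (it != by_code.end()) return it->second;
        }
        stop("invalid class codeword in bit stream");
        return -1; // unreachable
    }
};

static std::vector<std::string> decode_one(BitCursor& cur, int maxDif,
                                           bool use_local,
                                           const std::vector<std::string>& classes,
                                           const HuffDecoder& hd,
                                           const std::vector<std::string>& local,
                                           int n, int C, int runDivisor) {
    if (maxDif < 0 || maxDif > 2) stop("invalid maxDif in metadata");
    int wC = index_width(C);
    int rbits = log2_exact(runDivisor);
    int wL = use_local ? ceil_log2((long long)local.size()) : 0;
    if (use_local && local.empty()) stop("empty local class table");
    std::vector<std::string> out;
    out.reserve(n);
    while ((int)out.size() < n) {
        bool b = cur.read();
        if (!b) {
            // Store class ID
            std::string cls;
            if (use_local) {
                unsigned long long id = cur.read_uint(wL);
                if (id >= local.size()) stop("local class ID out of range");
                cls = local[id];
            } else {
                cls = classes[hd.decode(cur)];
            }
            out.push_back(cls);
            continue;
        }
        bool is_run;
        if (maxDif == 0) {
            is_run = true;
        } else {
            is_run = cur.read(); // "11" run, "10" difference
        }
        if (is_run) {
            if (out.empty()) stop("run encoding before any class is established");
            unsigned long long q = 0;
            while (cur.read()) ++q;
            unsigned long long runLen =
                q * (unsigned)runDivisor + cur.read_uint(rbits);
            if (runLen == 0) stop("corrupt run of length zero");
            if ((long long)out.size() + (long long)runLen > (long long)n)
                stop("decoded k-mer count overshoots the simplitig length");
            const std::string cls = out.back();
            for (unsigned long long i = 0; i < runLen; ++i) out.push_back(cls);
        } else {
            if (out.empty())
                stop("difference encoding before any class is established");
            int h = 1;
            if (maxDif == 2) h = cur.read() ? 2 : 1;
            std::string cls = out.back();
            long long last = -1;
            for (int i = 0; i < h; ++i) {
                unsigned long long idx = cur.read_uint(wC);
                if ((long long)idx >= C) stop("color index out of range");
                if ((long long)idx <= last)
                    stop("difference indices not ascending");
                last = (long long)idx;
                cls[idx] = (cls[idx] == '0') ? '1' : '0';
            }
            out.push_back(cls);
        }
    }
    return out;
}

static std::vector<std::string> cv_to_vec(const CharacterVector& x) {
    std::vector<std::string> v(x.size());
    for (R_xlen_t i = 0; i < x.size(); ++i) v[i] = as<std::string>(x[i]);
    return v;
}

// [[Rcpp::export]]
List cpp_decode_simplitig(const std::string& bits, double pos0, int maxDif,
                          bool useLocalID, const CharacterVector& classes,
                          const CharacterVector& codes,
                          const CharacterVector& local, int n_kmers, int C,
                          int runDivisor) {
    BitCursor cur(bits, (size_t)pos0);
    HuffDecoder hd(codes);
    std::vector<std::string> cls = cv_to_vec(classes);
    std::vector<std::string> loc = cv_to_vec(local);
    std::vector<std::string> out =
        decode_one(cur, maxDif, useLocalID, cls, hd, loc, n_kmers, C, runDivisor);
    return List::create(_["classes"] = wrap(out), _["pos"] = (double)cur.pos);
}

// Decode the concatenated per-simplitig streams of a whole archive: META
// (3 bits per simplitig), LOCAL (l-1 in index_width(M) bits then l global
// codewords, only for simplitigs flagged UseLocalID) and MBITS.
// [[Rcpp::export]]
List cpp_decode_all(const std::string& mbits, const std::string& metabits,
                    const std::string& localbits, const IntegerVector& n_kmers,
                    const CharacterVector& classes, const CharacterVector& codes,
                    int C, int runDivisor) {
    int S = (int)n_kmers.size();
    if ((long long)metabits.size() < 3LL * S)
        stop("metadata stream shorter than 3 bits per simplitig");
    HuffDecoder hd(codes);
    std::vector<std::string> cls = cv_to_vec(classes);
    int M = (int)cls.size();
    int wM = index_width(M);
    BitCursor mcur(mbits, 0), lcur(localbits, 0);
    std::vector<std::string> flat;
    IntegerVector max_dif(S);
    LogicalVector use_local(S);
    for (int s = 0; s < S; ++s) {
        bool ul = metabits[3 * s] == '1';
        int d = (metabits[3 * s + 1] == '1' ? 2 : 0) +
                (metabits[3 * s + 2] == '1' ? 1 : 0);
        if (d > 2) stop("reserved maxDif value 3 in metadata of simplitig %d",
                        s + 1);
        max_dif[s] = d;
        use_local[s] = ul;
        std::vector<std::string> local;
        if (ul) {
            unsigned long long ell = lcur.read_uint(wM) + 1;
            if ((long long)ell > M) stop("local table larger than M");
            for (unsigned long long i = 0; i < ell; ++i)
                local.push_back(cls[hd.decode(lcur)]);
        }
        std::vector<std::string> one = decode_one(
            mcur, d, ul, cls, hd, local, n_kmers[s], C, runDivisor);
        flat.insert(flat.end(), one.begin(), one.end());
    }
    return List::create(_["classes"] = wrap(flat), _["max_dif"] = max_dif,
                        _["use_local_id"] = use_local,
                        _["m_bits_consumed"] = (double)mcur.pos,
                        _["local_bits_consumed"] = (double)lcur.pos);
}
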