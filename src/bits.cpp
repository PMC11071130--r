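#include "cdbgzip.h"
using namespace Rcpp;

// Pack a '0'/'1' string into bytes, MSB-first, zero-padded to a byte boundary.
// [[Rcpp::export]]
RawVector cpp_pack_bits(const std::string& bits) {
    size_t n = bits.size();
    RawVector out((n + 7) / 8);
    for (size_t i = 0; i < n; ++i) {
        char c = bits[i];
        if (c == '1')
            out[i >> 3] |= (unsigned char)(0x80u >> (i & 7));
        else if (c != '0')
            stop("invalid character '%c' in bit string at position %d",
                 c, (int)(i + 1));
    }
    return out;
}

// [[Rcpp::export]]
std::string cpp_unpack_bits(const RawVector& bytes, double nbits) {
    long long n = (long long)nbits;
    if (n < 0 || n > (long long)bytes.size() * 8)
        stop("bit count %lld does not fit in %d bytes", n, (int)bytes.size());
    std::string out;
    out.reserve(n);
    for (long long i = 0; i < n; ++i) {
        unsigned char b = bytes[i >> 3];
        out.push_back((b & (0x80u >> (i & 7))) ? '1' : '0');
    }
    return out;
}

// CRC-32 (IEEE reflected polynomial), returned as a double in [0, 2^32).
// No pre-installed R package exposes a raw-vector CRC32, hence this.
// [[Rcpp::export]]
double cpp_crc32(const RawVector& data) {
    static uint32_t table[256];
    static bool ready = false;
    if (!ready) {
        for (uint32_t i = 0; i < 256; ++i) {
            uint32_t c = i;
            for (int j = 0; j < 8; ++j)
                c = (c & 1u) ? (0xEDB88320u ^ (c >> 1)) : (c >> 1);
            table[i] = c;
        }
        ready = true;
    }
    uint32_t crc = 0xFFFFFFFFu;
    for (R_xlen_t i = 0; i < data.size(); ++i)
        crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
    return (double)(crc ^ 0xFFFFFFFFu);
}
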