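#include <Rcpp.h>
#include <cstdint>
#include <cstring>

// SHA-256 (FIPS 180-4).  Used to derive content-addressed identifiers for
// canonical structure serialisations; implemented here because identifier
// stability across processes and platforms is a hard requirement.

namespace {

const uint32_t K[64] = {
    0x428a2f98u, 0x71374491u, 0xb5c0fbcfu, 0xe9b5dba5u, 0x3956c25bu,
    0x59f111f1u, 0x923f82a4u, 0xab1c5ed5u, 0xd807aa98u, 0x12835b01u,
    0x243185beu, 0x550c7dc3u, 0x72be5d74u, 0x80deb1feu, 0x9bdc06a7u,
    0xc19bf174u, 0xe49b69c1u, 0xefbe4786u, 0x0fc19dc6u, 0x240ca1ccu,
    0x2de92c6fu, 0x4a7484aau, 0x5cb0a9dcu, 0x76f988dau, 0x983e5152u,
    0xa831c66du, 0xb00327c8u, 0xbf597fc7u, 0xc6e00bf3u, 0xd5a79147u,
    0x06ca6351u, 0x14292967u, 0x27b70a85u, 0x2e1b2138u, 0x4d2c6dfcu,
    0x53380d13u, 0x650a7354u, 0x766a0abbu, 0x81c2c92eu, 0x92722c85u,
    0xa2bfe8a1u, 0xa81a664bu, 0xc24b8b70u, 0xc76c51a3u, 0xd192e819u,
    0xd6990624u, 0xf40e3585u, 0x106aa070u, 0x19a4c116u, 0x1e376c08u,
    0x2748774cu, 0x34b0bcb5u, 0x391c0cb3u, 0x4ed8aa4au, 0x5b9cca4fu,
    0x682e6ff3u, 0x748f82eeu, 0x78a5636fu, 0x84c87814u, 0x8cc70208u,
    0x90befffau, 0xa4506cebu, 0xbef9a3f7u, 0xc67178f2u};

inline uint32_t rotr(uint32_t x, int n) { return (x >> n) | (x << (32 - n)); }

struct Sha256 {
    uint32_t h[8];
    uint64_t len;
    unsigned char buf[64];
    size_t buflen;

    Sha256() {
        h[0] = 0x6a09e667u; h[1] = 0xbb67ae85u; h[2] = 0x3c6ef372u;
        h[3] = 0xa54ff53au; h[4] = 0x510e527fu; h[5] = 0x9b05688cu;
        h[6] = 0x1f83d9abu; h[7] = 0x5be0cd19u;
        len = 0; buflen = 0;
    }

    void block(const unsigned char *p) {
        uint32_t w[64];
        for (int i = 0; i < 16; ++i)
            w[i] = (uint32_t(p[4 * i]) << 24) | (uint32_t(p[4 * i + 1]) << 16) |
                   (uint32_t(p[4 * i + 2]) << 8) | uint32_t(p[4 * i + 3]);
        for (int i = 16; i < 64; ++i) {
            uint32_t s0 = rotr(w[i - 15], 7) ^ rotr(w[i - 15], 18) ^ (w[i - 15] >> 3);
            uint32_t s1 = rotr(w[i - 2], 17) ^ rotr(w[i - 2], 19) ^ (w[i - 2] >> 10);
            w[i] = w[i - 16] + s0 + w[i - 7] + s1;
        }
        uint32_t a = h[0], b = h[1], c = h[2], d = h[3];
        uint32_t e = h[4], f = h[5], g = h[6], hh = h[7];
        for (int i = 0; i < 64; ++i) {
            uint32_t S1 = rotr(e, 6) ^ rotr(e, 11) ^ rotr(e, 25);
            uint32_t ch = (e & f) ^ (~e & g);
            uint32_t t1 = hh + S1 + ch + K[i] + w[i];
            uint32_t S0 = rotr(a, 2) ^ rotr(a, 13) ^ rotr(a, 22);
            uint32_t maj = (a & b) ^ (a & c) ^ (b & c);
            uint32_t t2 = S0 + maj;
            hh = g; g = f; f = e; e = d + t1;
            d = c; c = b; b = a; a = t1 + t2;
        }
        h[0] += a; h[1] += b; h[2] += c; h[3] += d;
        h[4] += e; h[5] += f; h[6] += g; h[7] += hh;
    }

    void update(const unsigned char *p, size_t n) {
        len += n;
        if (buflen) {
            size_t take = 64 - buflen;
            if (take > n) take = n;
            std::memcpy(buf + buflen, p, take);
            buflen += take; p += take; n -= take;
            if (buflen == 64) { block(buf); buflen = 0; }
        }
        while (n >= 64) { block(p); p += 64; n -= 64; }
        if (n) { std::memcpy(buf, p, n); buflen = n; }
    }

    void final_hex(char out[65]) {
        uint64_t bits = len * 8;
        unsigned char pad[72];
        size_t padlen = (buflen < 56) ? (56 - buflen) : (120 - buflen);
        pad[0] = 0x80;
        std::memset(pad + 1, 0, padlen - 1);
        for (int i = 0; i < 8; ++i)
            pad[padlen + i] = (unsigned char)(bits >> (56 - 8 * i));
        update(pad, padlen + 8);
        static const char hex[] = "0123456789abcdef";
        for (int i = 0; i < 8; ++i)
            for (int j = 0; j < 4; ++j) {
                unsigned char byte = (unsigned char)(h[i] >> (24 - 8 * j));
                out[8 * i + 2 * j] = hex[byte >> 4];
                out[8 * i + 2 * j + 1] = hex[byte & 0xf];
            }
        out[64] = '\0';
    }
};

} // namespace

// [[Rcpp::export]]
Rcpp::CharacterVector sha256_hex(Rcpp::CharacterVector x) {
    R_xlen_t n = x.size();
    Rcpp::CharacterVector out(n);
    char hexbuf[65];
    for (R_xlen_t i = 0; i < n; ++i) {
        if (Rcpp::CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
        const char *s = CHAR(STRING_ELT(x, i));
        Sha256 ctx;
        ctx.update(reinterpret_cast<const unsigned char *>(s), std::strlen(s));
        ctx.final_hex(hexbuf);
        out[i] = hexbuf;
    }
    return out;
}
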