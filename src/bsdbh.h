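#pragma once

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>

// Base codes: A=0, C=1, G=2, T=3; anything else (N, ...) = -1.
static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// alpha(C)=alpha(T)=0, alpha(G)=alpha(A)=1; undefined codes fall to 0 so
// that fingerprints stay well-defined (verification rejects them anyway).
static inline int alpha_of_code(int code) {
    return (code == 0 || code == 2) ? 1 : 0;
}

static inline char code_to_base(int code) {
    static const char b[4] = {'A', 'C', 'G', 'T'};
    return (code >= 0 && code < 4) ? b[code] : 'N';
}

// Fingerprint of a coded pattern S[0..m): XOR of the ceil(m/w)-1 leading
// non-overlapping w-bit blocks of alpha(S) with the final block at offset
// m-w.  Sequence position 0 maps to the most significant bit.
static inline uint32_t fingerprint_codes(const int8_t* S, int m, int w) {
    int nb = (m + w - 1) / w;
    uint32_t fp = 0;
    for (int b = 0; b < nb - 1; ++b) {
        uint32_t v = 0;
        const int8_t* p = S + (size_t)b * w;
        for (int j = 0; j < w; ++j) v = (v << 1) | (uint32_t)alpha_of_code(p[j]);
        fp ^= v;
    }
    uint32_t v = 0;
    const int8_t* p = S + (m - w);
    for (int j = 0; j < w; ++j) v = (v << 1) | (uint32_t)alpha_of_code(p[j]);
    fp ^= v;
    return fp;
}

// Hamming-ball masks around 0 for width w, radius r, ordered by flip count
// then by lexicographic flip positions (position 0 = most significant bit).
std::vector<uint32_t> ball_masks(int w, int radius);

// Bisulfite-aware base comparison on codes. mode 0 = fwd-CT (genome C may
// read as T), mode 1 = rev-GA (genome G may read as A).  Asymmetric.
static inline bool bs_match_codes(int genome, int read, int mode) {
    if (read < 0 || genome < 0) return false;
    if (genome == read) return true;
    if (mode == 0) return genome == 1 && read == 3; // C -> T
    return genome == 2 && read == 0;                // G -> A
}
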