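#include "bsdbh.h"
using namespace Rcpp;

// Enumerate XOR masks of Hamming weight <= radius over w bits, ordered by
// flip count and, within a count, by lexicographic flip-position tuples
// (flip position 0 = most significant bit).  The order is part of the API:
// it makes candidate enumeration, and hence alignment output, reproducible.
std::vector<uint32_t> ball_masks(int w, int radius) {
    std::vector<uint32_t> out;
    out.push_back(0u);
    for (int r = 1; r <= radius; ++r) {
        // lexicographic combinations of r positions out of {0..w-1}
        std::vector<int> idx(r);
        for (int i = 0; i < r; ++i) idx[i] = i;
        while (true) {
            uint32_t m = 0;
            for (int i = 0; i < r; ++i) m |= (1u << (w - 1 - idx[i]));
            out.push_back(m);
            int i = r - 1;
            while (i >= 0 && idx[i] == w - r + i) --i;
            if (i < 0) break;
            ++idx[i];
            for (int j = i + 1; j < r; ++j) idx[j] = idx[j - 1] + 1;
        }
    }
    return out;
}

static std::vector<int8_t> code_string(const std::string& s) {
    std::vector<int8_t> v(s.size());
    for (size_t i = 0; i < s.size(); ++i) v[i] = (int8_t)base_code(s[i]);
    return v;
}

// [[Rcpp::export(name = ".cpp_encode_alpha")]]
IntegerVector cpp_encode_alpha(std::string seq) {
    IntegerVector out(seq.size());
    for (size_t i = 0; i < seq.size(); ++i) {
        int c = base_code(seq[i]);
        if (c < 0) stop("encode_alpha: character '%s' at position %d is not in {A,C,G,T}",
                        std::string(1, seq[i]).c_str(), (int)i + 1);
        out[i] = alpha_of_code(c);
    }
    return out;
}

// [[Rcpp::export(name = ".cpp_fingerprint")]]
double cpp_fingerprint(std::string P, int w) {
    std::vector<int8_t> S = code_string(P);
    for (size_t i = 0; i < S.size(); ++i)
        if (S[i] < 0) stop("fingerprint: pattern contains a character outside {A,C,G,T}");
    return (double)fingerprint_codes(S.data(), (int)S.size(), w);
}

// [[Rcpp::export(name = ".cpp_fingerprint_batch")]]
NumericVector cpp_fingerprint_batch(CharacterVector P, int w) {
    R_xlen_t n = P.size();
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string s = as<std::string>(P[i]);
        std::vector<int8_t> S = code_string(s);
        out[i] = (double)fingerprint_codes(S.data(), (int)S.size(), w);
    }
    return out;
}

// [[Rcpp::export(name = ".cpp_global_hash")]]
IntegerVector cpp_global_hash(std::string T, int m, int w) {
    int n = (int)T.size();
    std::vector<int8_t> S = code_string(T);
    IntegerVector out(n - m + w);
    // First window written in full; each following window contributes its
    // last bit.  Existence/uniqueness holds by the de Bruijn property (the
    // per-window fingerprints agree on overlaps), which the test-suite
    // checks window by window.
    uint32_t fp = fingerprint_codes(S.data(), m, w);
    for (int j = 0; j < w; ++j) out[j] = (int)((fp >> (w - 1 - j)) & 1u);
    for (int i = 1; i <= n - m; ++i) {
        fp = fingerprint_codes(S.data() + i, m, w);
        out[i + w - 1] = (int)(fp & 1u);
    }
    return out;
}

// [[Rcpp::export(name = ".cpp_hamming_ball")]]
NumericVector cpp_hamming_ball(double center, int w, int radius) {
    uint32_t c = (uint32_t)center;
    std::vector<uint32_t> masks = ball_masks(w, radius);
    NumericVector out(masks.size());
    for (size_t i = 0; i < masks.size(); ++i) out[i] = (double)(c ^ masks[i]);
    return out;
}

// [[Rcpp::export(name = ".cpp_ball_masks")]]
NumericVector cpp_ball_masks(int w, int radius) {
    std::vector<uint32_t> masks = ball_masks(w, radius);
    NumericVector out(masks.size());
    for (size_t i = 0; i < masks.size(); ++i) out[i] = (double)masks[i];
    return out;
}

// Bucket table over the hashed text, CSR layout: bucket_start has 2^w + 1
// entries; positions[bucket_start[g]..bucket_start[g+1]) are the ascending
// text positions whose m-window fingerprint is g.
// [[Rcpp::export(name = ".cpp_build_buckets")]]
List cpp_build_buckets(std::string T, int m, int w) {
    int n = (int)T.size();
    if (n < m) stop("reference shorter than the seed length m");
    std::vector<int8_t> S = code_string(T);
    size_t nbuck = (size_t)1 << w;
    std::vector<int> cnt(nbuck + 1, 0);
    std::vector<uint32_t> fps(n - m + 1);
    for (int i = 0; i <= n - m; ++i) {
        uint32_t fp = fingerprint_codes(S.data() + i, m, w);
        fps[i] = fp;
        ++cnt[fp + 1];
    }
    for (size_t g = 1; g <= nbuck; ++g) cnt[g] += cnt[g - 1];
    IntegerVector bucket_start(nbuck + 1);
    for (size_t g = 0; g <= nbuck; ++g) bucket_start[g] = cnt[g];
    IntegerVector positions(n - m + 1);
    std::vector<int> fill(cnt.begin(), cnt.end() - 1);
    for (int i = 0; i <= n - m; ++i) positions[fill[fps[i]]++] = i;
    return List::create(_["bucket_start"] = bucket_start,
                        _["positions"] = positions);
}
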