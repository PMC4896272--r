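#include "bsdbh.h"
#include <algorithm>
using namespace Rcpp;

// status codes shared with the R layer
static const int ST_UNIQUE = 0, ST_MULTIPLE = 1, ST_UNMAPPED = 2;

struct Placement {
    int gpos;   // 0-based position in the concatenated text
    int mode;   // 0 = fwd-CT (Watson fragment), 1 = rev-GA (Crick fragment)
    int mism;
};

struct AlnCtx {
    const int8_t* text;
    int n;
    const int* bstart;   // CSR bucket offsets, 2^w + 1 entries (may be NULL)
    const int* bpos;
    int m, w, k;
    std::vector<uint32_t> masks;           // XOR masks of the 2k-ball
    const int* cstart;   // contig starts (ascending)
    const int* clen;
    int ncontig;
    int tie_cap;
};

// contig containing position p, or -1
static inline int contig_of(const AlnCtx& C, int p) {
    int lo = 0, hi = C.ncontig - 1, ans = -1;
    while (lo <= hi) {
        int mid = (lo + hi) / 2;
        if (C.cstart[mid] <= p) { ans = mid; lo = mid + 1; } else hi = mid - 1;
    }
    return ans;
}

// alignment spanning [p, p+len) must sit inside one contig
static inline bool inside_contig(const AlnCtx& C, int p, int len) {
    int ci = contig_of(C, p);
    if (ci < 0) return false;
    return p + len <= C.cstart[ci] + C.clen[ci];
}

// ungapped verification: seed (first m bases) must carry <= k bs-aware
// mismatches, the whole read <= maxmm; -1 when rejected
static inline int verify(const AlnCtx& C, const int8_t* S, int len, int p,
                         int mode, int maxmm) {
    const int8_t* t = C.text + p;
    int mm = 0;
    int kcap = C.k < maxmm ? C.k : maxmm;
    for (int j = 0; j < C.m; ++j)
        if (!bs_match_codes(t[j], S[j], mode) && ++mm > kcap) return -1;
    for (int j = C.m; j < len; ++j)
        if (!bs_match_codes(t[j], S[j], mode) && ++mm > maxmm) return -1;
    return mm;
}

struct BestSet {
    int best = INT_MAX;
    long nbest = 0;
    std::vector<Placement> ties;
    int cap;
    explicit BestSet(int cap_) : cap(cap_) {}
    void consider(int gpos, int mode, int mm) {
        if (mm < best) { best = mm; nbest = 0; ties.clear(); }
        if (mm == best) {
            ++nbest;
            if ((int)ties.size() < cap) ties.push_back({gpos, mode, mm});
        }
    }
    void finish() {  // deterministic leftmost-first ordering
        std::sort(ties.begin(), ties.end(), [](const Placement& a, const Placement& b) {
            return a.gpos != b.gpos ? a.gpos < b.gpos : a.mode < b.mode;
        });
    }
};

static void search_mode(const AlnCtx& C, const std::vector<int8_t>& S, int mode,
                        int maxmm, BestSet& bs) {
    int len = (int)S.size();
    uint32_t fp = fingerprint_codes(S.data(), C.m, C.w);
    for (uint32_t mask : C.masks) {
        uint32_t g = fp ^ mask;
        int from = C.bstart[g], to = C.bstart[g + 1];
        for (int t = from; t < to; ++t) {
            int p = C.bpos[t];
            if (p + len > C.n) continue;
            int mm = verify(C, S.data(), len, p, mode, maxmm);
            if (mm < 0) continue;
            if (!inside_contig(C, p, len)) continue;
            bs.consider(p, mode, mm);
        }
    }
}

static std::vector<int8_t> code_seq(const char* s, int len) {
    std::vector<int8_t> v(len);
    for (int i = 0; i < len; ++i) v[i] = (int8_t)base_code(s[i]);
    return v;
}

static std::vector<int8_t> revcomp_codes(const std::vector<int8_t>& in) {
    std::vector<int8_t> out(in.size());
    for (size_t i = 0; i < in.size(); ++i) {
        int8_t c = in[in.size() - 1 - i];
        out[i] = c < 0 ? c : (int8_t)(3 - c);
    }
    return out;
}

// Align one read (mate2 indicates a second mate of a directional pair).
// First mates can only arise from (read, fwd-CT) or (revcomp(read), rev-GA);
// second mates from (revcomp(read), fwd-CT) or (read, rev-GA).
static BestSet align_one(const AlnCtx& C, const std::vector<int8_t>& X,
                         bool mate2, int maxmm) {
    BestSet bs(C.tie_cap);
    if ((int)X.size() < C.m) return bs;  // too short: unmapped
    std::vector<int8_t> Y = revcomp_codes(X);
    if (!mate2) {
        search_mode(C, X, 0, maxmm, bs);
        search_mode(C, Y, 1, maxmm, bs);
    } else {
        search_mode(C, Y, 0, maxmm, bs);
        search_mode(C, X, 1, maxmm, bs);
    }
    bs.finish();
    return bs;
}

static AlnCtx make_ctx(const std::vector<int8_t>& text,
                       const IntegerVector& bucket_start, const IntegerVector& positions,
                       int m, int w, int k,
                       const IntegerVector& contig_start, const IntegerVector& contig_len,
                       int tie_cap) {
    AlnCtx C;
    C.text = text.data();
    C.n = (int)text.size();
    C.bstart = bucket_start.size() ? &bucket_start[0] : nullptr;
    C.bpos = positions.size() ? &positions[0] : nullptr;
    C.m = m; C.w = w; C.k = k;
    int radius = 2 * k > w ? w : 2 * k;
    C.masks = ball_masks(w, radius);
    C.cstart = &contig_start[0];
    C.clen = &contig_len[0];
    C.ncontig = (int)contig_start.size();
    C.tie_cap = tie_cap;
    return C;
}

static void emit_result(const BestSet& bs, bool mate2, int i,
                        IntegerVector& gpos, IntegerVector& mode, IntegerVector& mism,
                        IntegerVector& status, IntegerVector& nbest, LogicalVector& rev) {
    if (bs.nbest == 0) {
        gpos[i] = NA_INTEGER; mode[i] = NA_INTEGER; mism[i] = NA_INTEGER;
        status[i] = ST_UNMAPPED; nbest[i] = 0; rev[i] = NA_LOGICAL;
    } else {
        const Placement& p = bs.ties[0];
        gpos[i] = p.gpos; mode[i] = p.mode; mism[i] = p.mism;
        status[i] = bs.nbest == 1 ? ST_UNIQUE : ST_MULTIPLE;
        nbest[i] = (int)std::min<long>(bs.nbest, INT_MAX);
        rev[i] = mate2 != (p.mode == 1);  // maps to the reverse strand?
    }
}

// [[Rcpp::export(name = ".cpp_align_batch")]]
List cpp_align_batch(CharacterVector seqs, LogicalVector mate2, std::string text,
                     IntegerVector bucket_start, IntegerVector positions,
                     int m, int w, int k, IntegerVector maxmm,
                     IntegerVector contig_start, IntegerVector contig_len,
                     int tie_cap, bool return_ties) {
    int nread = (int)seqs.size();
    std::vector<int8_t> tc = code_seq(text.c_str(), (int)text.size());
    AlnCtx C = make_ctx(tc, bucket_start, positions, m, w, k,
                        contig_start, contig_len, tie_cap);
    IntegerVector gpos(nread), mode(nread), mism(nread), status(nread), nbest(nread);
    LogicalVector rev(nread);
    List ties(return_ties ? nread : 0);
    for (int i = 0; i < nread; ++i) {
        std::string s = as<std::string>(seqs[i]);
        std::vector<int8_t> X = code_seq(s.c_str(), (int)s.size());
        BestSet bs = align_one(C, X, mate2[i], maxmm[i]);
        emit_result(bs, mate2[i], i, gpos, mode, mism, status, nbest, rev);
        if (return_ties) {
            IntegerMatrix tm((int)bs.ties.size(), 3);
            for (int t = 0; t < (int)bs.ties.size(); ++t) {
                tm(t, 0) = bs.ties[t].gpos;
                tm(t, 1) = bs.ties[t].mode;
                tm(t, 2) = bs.ties[t].mism;
            }
            ties[i] = tm;
        }
    }
    List out = List::create(_["gpos"] = gpos, _["mode"] = mode, _["mism"] = mism,
                            _["status"] = status, _["nbest"] = nbest, _["rev"] = rev);
    if (return_ties) out["ties"] = ties;
    return out;
}

// proper-pair test for a directional FR library: mates share the fragment
// strand (mode); the fragment spans [leftmost, rightmost-end) within the
// insert-size window, on one contig.
static inline bool pair_proper(const AlnCtx& C, const Placement& p1, int len1,
                               const Placement& p2, int len2,
                               int imin, int imax) {
    if (p1.mode != p2.mode) return false;
    if (contig_of(C, p1.gpos) != contig_of(C, p2.gpos)) return false;
    int tlen;
    if (p1.mode == 0) {          // Watson: read1 leftmost (forward), read2 reverse
        if (p2.gpos < p1.gpos) return false;
        tlen = p2.gpos + len2 - p1.gpos;
    } else {                     // Crick: read2 leftmost (forward), read1 reverse
        if (p1.gpos < p2.gpos) return false;
        tlen = p1.gpos + len1 - p2.gpos;
    }
    return tlen >= imin && tlen <= imax;
}

// [[Rcpp::export(name = ".cpp_align_pairs")]]
List cpp_align_pairs(CharacterVector seqs1, CharacterVector seqs2, std::string text,
                     IntegerVector bucket_start, IntegerVector positions,
                     int m, int w, int k, IntegerVector maxmm1, IntegerVector maxmm2,
                     IntegerVector contig_start, IntegerVector contig_len,
                     int tie_cap, int insert_min, int insert_max) {
    int np = (int)seqs1.size();
    std::vector<int8_t> tc = code_seq(text.c_str(), (int)text.size());
    AlnCtx C = make_ctx(tc, bucket_start, positions, m, w, k,
                        contig_start, contig_len, tie_cap);
    IntegerVector gpos1(np), mode1(np), mism1(np), status1(np), nbest1(np);
    IntegerVector gpos2(np), mode2(np), mism2(np), status2(np), nbest2(np);
    LogicalVector rev1(np), rev2(np), proper(np), rescued1(np), rescued2(np);
    for (int i = 0; i < np; ++i) {
        std::string s1 = as<std::string>(seqs1[i]), s2 = as<std::string>(seqs2[i]);
        std::vector<int8_t> X1 = code_seq(s1.c_str(), (int)s1.size());
        std::vector<int8_t> X2 = code_seq(s2.c_str(), (int)s2.size());
        int len1 = (int)X1.size(), len2 = (int)X2.size();
        BestSet b1 = align_one(C, X1, false, maxmm1[i]);
        BestSet b2 = align_one(C, X2, true, maxmm2[i]);
        bool prop = false; rescued1[i] = false; rescued2[i] = false;
        // mate rescue: a unique mate disambiguates a multiple one when
        // exactly one of its tied-best placements is pair-consistent
        if (b1.nbest == 1 && b2.nbest > 1) {
            int hit = -1, nhit = 0;
            for (int t = 0; t < (int)b2.ties.size(); ++t)
                if (pair_proper(C, b1.ties[0], len1, b2.ties[t], len2,
                                insert_min, insert_max)) { if (hit < 0) hit = t; ++nhit; }
            if (nhit >= 1) {
                std::swap(b2.ties[0], b2.ties[hit]);
                std::sort(b2.ties.begin() + 1, b2.ties.end(),
                          [](const Placement& a, const Placement& b) {
                              return a.gpos != b.gpos ? a.gpos < b.gpos : a.mode < b.mode; });
                if (nhit == 1) { b2.nbest = 1; rescued2[i] = true; prop = true; }
            }
        } else if (b2.nbest == 1 && b1.nbest > 1) {
            int hit = -1, nhit = 0;
            for (int t = 0; t < (int)b1.ties.size(); ++t)
                if (pair_proper(C, b1.ties[t], len1, b2.ties[0], len2,
                                insert_min, insert_max)) { if (hit < 0) hit = t; ++nhit; }
            if (nhit >= 1) {
                std::swap(b1.ties[0], b1.ties[hit]);
                std::sort(b1.ties.begin() + 1, b1.ties.end(),
                          [](const Placement& a, const Placement& b) {
                              return a.gpos != b.gpos ? a.gpos < b.gpos : a.mode < b.mode; });
                if (nhit == 1) { b1.nbest = 1; rescued1[i] = true; prop = true; }
            }
        } else if (b1.nbest == 1 && b2.nbest == 1) {
            prop = pair_proper(C, b1.ties[0], len1, b2.ties[0], len2,
                               insert_min, insert_max);
        }
        emit_result(b1, false, i, gpos1, mode1, mism1, status1, nbest1, rev1);
        emit_result(b2, true, i, gpos2, mode2, mism2, status2, nbest2, rev2);
        proper[i] = prop;
    }
    return List::create(
        _["gpos1"] = gpos1, _["mode1"] = mode1, _["mism1"] = mism1,
        _["status1"] = status1, _["nbest1"] = nbest1, _["rev1"] = rev1,
        _["rescued1"] = rescued1,
        _["gpos2"] = gpos2, _["mode2"] = mode2, _["mism2"] = mism2,
        _["status2"] = status2, _["nbest2"] = nbest2, _["rev2"] = rev2,
        _["rescued2"] = rescued2,
        _["proper"] = proper);
}

// Brute-force full-scan oracle: no fingerprints, no buckets.  Tries every
// text position and both mode combinations under the same seed/total
// mismatch budgets.  Kept deliberately naive; used to certify the
// dB-hash search path (no false negatives).
// [[Rcpp::export(name = ".cpp_bruteforce_align")]]
List cpp_bruteforce_align(CharacterVector seqs, LogicalVector mate2, std::string text,
                          int m, int k, IntegerVector maxmm,
                          IntegerVector contig_start, IntegerVector contig_len,
                          int tie_cap) {
    int nread = (int)seqs.size();
    std::vector<int8_t> tc = code_seq(text.c_str(), (int)text.size());
    AlnCtx C;
    C.text = tc.data(); C.n = (int)tc.size();
    C.bstart = nullptr; C.bpos = nullptr;
    C.m = m; C.w = 1; C.k = k; C.masks.clear();
    C.cstart = &contig_start[0]; C.clen = &contig_len[0];
    C.ncontig = (int)contig_start.size(); C.tie_cap = tie_cap;
    IntegerVector gpos(nread), mode(nread), mism(nread), status(nread), nbest(nread);
    LogicalVector rev(nread);
    List ties(nread);
    for (int i = 0; i < nread; ++i) {
        std::string s = as<std::string>(seqs[i]);
        std::vector<int8_t> X = code_seq(s.c_str(), (int)s.size());
        int len = (int)X.size();
        BestSet bs(tie_cap);
        if (len >= m) {
            std::vector<int8_t> Y = revcomp_codes(X);
            const std::vector<int8_t>* Sm[2];
            int modes[2];
            if (!mate2[i]) { Sm[0] = &X; modes[0] = 0; Sm[1] = &Y; modes[1] = 1; }
            else           { Sm[0] = &Y; modes[0] = 0; Sm[1] = &X; modes[1] = 1; }
            for (int c = 0; c < 2; ++c)
                for (int p = 0; p + len <= C.n; ++p) {
                    int mm = verify(C, Sm[c]->data(), len, p, modes[c], maxmm[i]);
                    if (mm < 0) continue;
                    if (!inside_contig(C, p, len)) continue;
                    bs.consider(p, modes[c], mm);
                }
            bs.finish();
        }
        emit_result(bs, mate2[i], i, gpos, mode, mism, status, nbest, rev);
        IntegerMatrix tm((int)bs.ties.size(), 3);
        for (int t = 0; t < (int)bs.ties.size(); ++t) {
            tm(t, 0) = bs.ties[t].gpos; tm(t, 1) = bs.ties[t].mode; tm(t, 2) = bs.ties[t].mism;
        }
        ties[i] = tm;
    }
    return List::create(_["gpos"] = gpos, _["mode"] = mode, _["mism"] = mism,
                        _["status"] = status, _["nbest"] = nbest, _["rev"] = rev,
                        _["ties"] = ties);
}
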