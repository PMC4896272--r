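#include "bsdbh.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Rank-supported bit-vector: raw bits in 64-bit words plus cumulative
// counts sampled every 512 bits; rank(i) = #1-bits in [0,i) resolves from
// one sample plus at most eight popcounts.
// ---------------------------------------------------------------------------

class RankBV {
public:
    uint64_t n = 0;
    std::vector<uint64_t> words;
    std::vector<uint64_t> samples;  // cumulative count before each 512-bit superblock

    void init(uint64_t n_) {
        n = n_;
        words.assign((n + 63) / 64, 0ULL);
    }
    void set(uint64_t i) { words[i >> 6] |= 1ULL << (i & 63); }
    bool get(uint64_t i) const { return (words[i >> 6] >> (i & 63)) & 1ULL; }
    void finalize() {
        size_t nsb = words.size() / 8 + 1;
        samples.assign(nsb + 1, 0);
        uint64_t c = 0;
        for (size_t wd = 0; wd < words.size(); ++wd) {
            if (wd % 8 == 0) samples[wd / 8] = c;
            c += __builtin_popcountll(words[wd]);
        }
        samples[(words.size() + 7) / 8] = c;  // allows rank at the very end
        total_ = c;
    }
    uint64_t rank(uint64_t i) const {  // i in [0, n]
        uint64_t sb = i >> 9;
        uint64_t r = samples[sb];
        uint64_t wfrom = sb << 3, wto = i >> 6;
        for (uint64_t wd = wfrom; wd < wto && wd < words.size(); ++wd)
            r += __builtin_popcountll(words[wd]);
        uint64_t rem = i & 63;
        if (rem && wto < words.size())
            r += __builtin_popcountll(words[wto] & ((1ULL << rem) - 1));
        return r;
    }
    uint64_t total() const { return total_; }
private:
    uint64_t total_ = 0;
};

// [[Rcpp::export(name = ".cpp_rankbv_from_text")]]
SEXP cpp_rankbv_from_text(std::string text) {
    RankBV* bv = new RankBV();
    bv->init(text.size());
    for (size_t i = 0; i < text.size(); ++i) {
        char c = text[i];
        if (c == 'C' || c == 'c' || c == 'G' || c == 'g') bv->set(i);
    }
    bv->finalize();
    return XPtr<RankBV>(bv, true);
}

// [[Rcpp::export(name = ".cpp_rankbv_from_bits")]]
SEXP cpp_rankbv_from_bits(LogicalVector bits) {
    RankBV* bv = new RankBV();
    bv->init(bits.size());
    for (R_xlen_t i = 0; i < bits.size(); ++i)
        if (bits[i] == TRUE) bv->set(i);
    bv->finalize();
    return XPtr<RankBV>(bv, true);
}

// [[Rcpp::export(name = ".cpp_rankbv_rank")]]
NumericVector cpp_rankbv_rank(SEXP ptr, NumericVector i) {
    XPtr<RankBV> bv(ptr);
    NumericVector out(i.size());
    for (R_xlen_t j = 0; j < i.size(); ++j) {
        double ii = i[j];
        if (ii < 0 || ii > (double)bv->n) stop("rank index out of [0, n]");
        out[j] = (double)bv->rank((uint64_t)ii);
    }
    return out;
}

// [[Rcpp::export(name = ".cpp_rankbv_get")]]
LogicalVector cpp_rankbv_get(SEXP ptr, NumericVector i) {
    XPtr<RankBV> bv(ptr);
    LogicalVector out(i.size());
    for (R_xlen_t j = 0; j < i.size(); ++j) {
        double ii = i[j];
        if (ii < 0 || ii >= (double)bv->n) stop("bit index out of [0, n)");
        out[j] = bv->get((uint64_t)ii);
    }
    return out;
}

// [[Rcpp::export(name = ".cpp_rankbv_info")]]
List cpp_rankbv_info(SEXP ptr) {
    XPtr<RankBV> bv(ptr);
    return List::create(_["n"] = (double)bv->n, _["total"] = (double)bv->total());
}

// ---------------------------------------------------------------------------
// Block-compressed counters: counters live in blocks of bl (default 256);
// each block stores its counters bit-packed at the block's capacity (bit
// width), initially 1 bit.  A counter crossing its block's capacity forces
// a rebuild of that block with capacity + 1.
// ---------------------------------------------------------------------------

class BlockedArray {
public:
    int64_t n = 0;
    int bl = 256;
    std::vector<std::vector<uint64_t>> blocks;
    std::vector<int> cap;
    int64_t rebuilds = 0;

    void init(int64_t n_, int bl_) {
        n = n_; bl = bl_;
        int64_t nb = n == 0 ? 0 : (n + bl - 1) / bl;
        blocks.assign(nb, std::vector<uint64_t>());
        cap.assign(nb, 1);
        for (int64_t b = 0; b < nb; ++b)
            blocks[b].assign(((size_t)bl * 1 + 63) / 64, 0ULL);
    }
    uint64_t get(int64_t i) const {
        int64_t b = i / bl;
        int c = cap[b];
        uint64_t bit = (uint64_t)(i % bl) * c;
        return read_bits(blocks[b], bit, c);
    }
    void inc(int64_t i) {
        int64_t b = i / bl;
        uint64_t v = get(i);
        if (v + 1 >= (1ULL << cap[b])) rebuild(b);
        int c = cap[b];
        write_bits(blocks[b], (uint64_t)(i % bl) * c, c, v + 1);
    }
private:
    static uint64_t read_bits(const std::vector<uint64_t>& a, uint64_t bit, int width) {
        uint64_t wd = bit >> 6, off = bit & 63;
        uint64_t v = a[wd] >> off;
        if (off + width > 64) v |= a[wd + 1] << (64 - off);
        return v & ((width == 64) ? ~0ULL : ((1ULL << width) - 1));
    }
    static void write_bits(std::vector<uint64_t>& a, uint64_t bit, int width, uint64_t v) {
        uint64_t wd = bit >> 6, off = bit & 63;
        uint64_t mask = (width == 64) ? ~0ULL : ((1ULL << width) - 1);
        a[wd] = (a[wd] & ~(mask << off)) | ((v & mask) << off);
        if (off + width > 64) {
            int spill = (int)(off + width - 64);
            uint64_t m2 = (1ULL << spill) - 1;
            a[wd + 1] = (a[wd + 1] & ~m2) | ((v >> (64 - off)) & m2);
        }
    }
    void rebuild(int64_t b) {
        int oldc = cap[b], newc = oldc + 1;
        std::vector<uint64_t> nb_((size_t)(((uint64_t)bl * newc + 63) / 64), 0ULL);
        int64_t lim = std::min<int64_t>(bl, n - b * bl);
        for (int64_t j = 0; j < lim; ++j) {
            uint64_t v = read_bits(blocks[b], (uint64_t)j * oldc, oldc);
            write_bits(nb_, (uint64_t)j * newc, newc, v);
        }
        blocks[b] = std::move(nb_);
        cap[b] = newc;
        ++rebuilds;
    }
};

struct Counters {
    BlockedArray primary, converted;
};

// [[Rcpp::export(name = ".cpp_counters_new")]]
SEXP cpp_counters_new(double n, int bl) {
    if (bl < 1) stop("block length must be >= 1");
    Counters* c = new Counters();
    c->primary.init((int64_t)n, bl);
    c->converted.init((int64_t)n, bl);
    return XPtr<Counters>(c, true);
}

static BlockedArray& pick(Counters& c, int which) {
    return which == 0 ? c.primary : c.converted;
}

// [[Rcpp::export(name = ".cpp_counters_inc")]]
void cpp_counters_inc(SEXP ptr, NumericVector idx, IntegerVector which) {
    XPtr<Counters> c(ptr);
    for (R_xlen_t j = 0; j < idx.size(); ++j) {
        double i = idx[j];
        if (i < 0 || i >= (double)c->primary.n) stop("counter index out of range");
        pick(*c, which[j % which.size()]).inc((int64_t)i);
    }
}

// [[Rcpp::export(name = ".cpp_counters_get")]]
NumericVector cpp_counters_get(SEXP ptr, NumericVector idx, int which) {
    XPtr<Counters> c(ptr);
    NumericVector out(idx.size());
    for (R_xlen_t j = 0; j < idx.size(); ++j) {
        double i = idx[j];
        if (i < 0 || i >= (double)c->primary.n) stop("counter index out of range");
        out[j] = (double)pick(*c, which).get((int64_t)i);
    }
    return out;
}

// [[Rcpp::export(name = ".cpp_counters_dump")]]
List cpp_counters_dump(SEXP ptr) {
    XPtr<Counters> c(ptr);
    int64_t n = c->primary.n;
    NumericVector p(n), v(n);
    for (int64_t i = 0; i < n; ++i) {
        p[i] = (double)c->primary.get(i);
        v[i] = (double)c->converted.get(i);
    }
    return List::create(_["primary"] = p, _["converted"] = v);
}

// [[Rcpp::export(name = ".cpp_counters_info")]]
List cpp_counters_info(SEXP ptr) {
    XPtr<Counters> c(ptr);
    return List::create(
        _["n"] = (double)c->primary.n,
        _["bl"] = c->primary.bl,
        _["rebuilds"] = (double)(c->primary.rebuilds + c->converted.rebuilds),
        _["capacity_primary"] = IntegerVector(c->primary.cap.begin(), c->primary.cap.end()),
        _["capacity_converted"] = IntegerVector(c->converted.cap.begin(), c->converted.cap.end()));
}

// ---------------------------------------------------------------------------
// Counting pass: for every kept alignment and every genomic position under
// it marked in the C/G bit-vector, update the strand-matching counter in
// rank space.  fwd-CT alignments inform genomic Cs (read C primary, read T
// converted); rev-GA alignments inform genomic Gs (read G primary, read A
// converted).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_count_alignments")]]
List cpp_count_alignments(SEXP bv_ptr, SEXP cnt_ptr, std::string text,
                          CharacterVector seqs, IntegerVector gpos,
                          IntegerVector mode) {
    XPtr<RankBV> bv(bv_ptr);
    XPtr<Counters> cnt(cnt_ptr);
    int64_t nprim = 0, nconv = 0;
    for (R_xlen_t r = 0; r < seqs.size(); ++r) {
        std::string s = as<std::string>(seqs[r]);
        int64_t p0 = gpos[r];
        int md = mode[r];
        if (p0 < 0 || p0 + (int64_t)s.size() > (int64_t)bv->n)
            stop("alignment outside the reference");
        for (size_t j = 0; j < s.size(); ++j) {
            int64_t g = p0 + (int64_t)j;
            if (!bv->get(g)) continue;
            char tb = text[g];
            int rc = base_code(s[j]);
            if (md == 0 && (tb == 'C' || tb == 'c')) {
                if (rc == 1)      { cnt->primary.inc(bv->rank(g)); ++nprim; }
                else if (rc == 3) { cnt->converted.inc(bv->rank(g)); ++nconv; }
            } else if (md == 1 && (tb == 'G' || tb == 'g')) {
                if (rc == 2)      { cnt->primary.inc(bv->rank(g)); ++nprim; }
                else if (rc == 0) { cnt->converted.inc(bv->rank(g)); ++nconv; }
            }
        }
    }
    return List::create(_["primary_updates"] = (double)nprim,
                        _["converted_updates"] = (double)nconv);
}
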