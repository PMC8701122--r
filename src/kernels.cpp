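#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// N (or any non-ACGT) never counts as a match.
static inline bool base_match(char a, char b) {
    if (a != b) return false;
    return a == 'A' || a == 'C' || a == 'G' || a == 'T';
}

static inline int base_code(char c) {
    switch (c) {
        case 'A': return 0; case 'C': return 1;
        case 'G': return 2; case 'T': return 3;
        default: return -1;
    }
}

// Maximal runs with <= k mismatches between s1 and s2, found by exact
// q-mer seeding followed by extension under the mismatch budget.
// Pigeonhole: a run of length >= min_len with <= k mismatches contains an
// exact block of length >= floor(min_len/(k+1)); with q no larger than
// that, every qualifying run is hit by a seed, so the enumeration is
// complete.  Positions returned 1-based; diagonal d pairs s1[i] with
// s2[i+d].  With symmetric=true (s1 == s2) only diagonals d >= 1 are
// considered and d == exclude_diag is skipped (self-match of a doubled
// circular sequence).
// [[Rcpp::export]]
DataFrame cpp_find_runs(const std::string& s1, const std::string& s2,
                        int q, int k, int min_len,
                        bool symmetric, int exclude_diag) {
    const int n1 = (int)s1.size(), n2 = (int)s2.size();
    std::vector<int> out_s1, out_s2, out_len, out_mm;
    if (n1 < q || n2 < q)
        return DataFrame::create(_["start1"] = out_s1, _["start2"] = out_s2,
                                 _["length"] = out_len,
                                 _["mismatches"] = out_mm);
    const uint64_t mask = (1ULL << (2 * q)) - 1ULL;
    std::unordered_multimap<uint64_t, int> idx;
    idx.reserve((size_t)n1);
    {
        uint64_t h = 0; int run = 0;
        for (int i = 0; i < n1; ++i) {
            int c = base_code(s1[i]);
            if (c < 0) { run = 0; h = 0; continue; }
            h = ((h << 2) | (uint64_t)c) & mask;
            if (++run >= q) idx.emplace(h, i - q + 1);
        }
    }
    std::unordered_set<uint64_t> emitted;   // key: (d + n1) << 32 | start
    std::vector<int> M; M.reserve(2 * k + 4);
    std::vector<int> leftM; leftM.reserve(k + 2);

    uint64_t h = 0; int run = 0;
    for (int j = 0; j + 1 <= n2; ++j) {
        int c = base_code(s2[j]);
        if (c < 0) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)c) & mask;
        if (++run < q) continue;
        const int jp = j - q + 1;               // seed start in s2
        auto range = idx.equal_range(h);
        for (auto it = range.first; it != range.second; ++it) {
            const int i = it->second;           // seed start in s1
            const int d = jp - i;
            if (symmetric && d < 1) continue;
            if (d == exclude_diag) continue;
            const int lo = std::max(0, -d);
            const int hi = std::min(n1 - 1, n2 - 1 - d);
            // collect up to k+1 blocking positions on each side of the seed
            leftM.clear();
            {
                int p = i - 1, cnt = 0;
                for (; p >= lo && cnt <= k; --p)
                    if (!base_match(s1[p], s2[p + d])) { leftM.push_back(p); ++cnt; }
                if (cnt <= k) leftM.push_back(lo - 1);   // boundary sentinel
            }
            M.clear();
            for (int t = (int)leftM.size() - 1; t >= 0; --t) M.push_back(leftM[t]);
            const int seed_end = i + q - 1;
            {
                int p = seed_end + 1, cnt = 0;
                for (; p <= hi && cnt <= k; ++p)
                    if (!base_match(s1[p], s2[p + d])) { M.push_back(p); ++cnt; }
                if (cnt <= k) M.push_back(hi + 1);       // boundary sentinel
            }
            const int nM = (int)M.size();
            if (nM <= k + 1) {
                // fewer than k+2 blocking elements: one window, bounded by
                // the outermost sentinels
                const int ws = M[0] + 1, we = M[nM - 1] - 1;
                const int len = we - ws + 1;
                if (len >= min_len) {
                    int mm = 0;
                    for (int b = 1; b < nM - 1; ++b) ++mm;
                    uint64_t key = ((uint64_t)(d + n1) << 32) | (uint64_t)ws;
                    if (emitted.insert(key).second) {
                        out_s1.push_back(ws + 1); out_s2.push_back(ws + d + 1);
                        out_len.push_back(len); out_mm.push_back(mm);
                    }
                }
            } else {
                for (int a = 0; a + k + 1 <= nM - 1; ++a) {
                    if (M[a] >= i) break;                 // must contain seed
                    if (M[a + k + 1] <= seed_end) continue;
                    const int ws = M[a] + 1, we = M[a + k + 1] - 1;
                    const int len = we - ws + 1;
                    if (len < min_len) continue;
                    int mm = 0;
                    for (int b = a + 1; b <= a + k; ++b)
                        if (M[b] >= ws && M[b] <= we) ++mm;
                    uint64_t key = ((uint64_t)(d + n1) << 32) | (uint64_t)ws;
                    if (!emitted.insert(key).second) continue;
                    out_s1.push_back(ws + 1); out_s2.push_back(ws + d + 1);
                    out_len.push_back(len); out_mm.push_back(mm);
                }
            }
        }
    }
    return DataFrame::create(_["start1"] = out_s1, _["start2"] = out_s2,
                             _["length"] = out_len, _["mismatches"] = out_mm);
}

// Offsets (0-based subject position minus pattern position) of exact q-mer
// seed hits of `pattern` inside `subject`, sampling pattern seeds every
// `step` bases.  Anchors a junction reference inside a long read before
// banded alignment.
// [[Rcpp::export]]
IntegerVector cpp_anchor_offsets(const std::string& pattern,
                                 const std::string& subject,
                                 int q, int step) {
    const int m = (int)pattern.size(), n = (int)subject.size();
    IntegerVector empty(0);
    if (m < q || n < q) return empty;
    const uint64_t mask = (1ULL << (2 * q)) - 1ULL;
    std::unordered_multimap<uint64_t, int> idx;
    uint64_t h = 0; int run = 0;
    for (int j = 0; j < n; ++j) {
        int c = base_code(subject[j]);
        if (c < 0) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)c) & mask;
        if (++run >= q) idx.emplace(h, j - q + 1);
    }
    std::vector<int> offs;
    for (int p = 0; p + q <= m; p += step) {
        uint64_t hp = 0; bool ok = true;
        for (int t = 0; t < q; ++t) {
            int c = base_code(pattern[p + t]);
            if (c < 0) { ok = false; break; }
            hp = (hp << 2) | (uint64_t)c;
        }
        if (!ok) continue;
        auto range = idx.equal_range(hp);
        for (auto it = range.first; it != range.second; ++it)
            offs.push_back(it->second - p);
    }
    return wrap(offs);
}

// Banded semiglobal edit distance: all of `pattern` aligned inside
// `subject`, start/end free on the subject side, restricted to a band of
// half-width `band` around the anchored diagonal `offset` (pattern pos r
// aligns near subject pos offset + r).  Returns the minimum edit distance
// (a large sentinel when the band never reaches row m).
// [[Rcpp::export]]
int cpp_banded_semiglobal(const std::string& pattern,
                          const std::string& subject,
                          int offset, int band) {
    const int m = (int)pattern.size(), n = (int)subject.size();
    const int INF = 1 << 28;
    const int W = 2 * band + 1;
    std::vector<int> prev(W, INF), cur(W, INF);
    bool any = false;
    {   // row 0: free start anywhere in band
        const int clo = std::max(0, offset - band);
        const int chi = std::min(n, offset + band);
        for (int c = clo; c <= chi; ++c) { prev[c - (offset - band)] = 0; any = true; }
    }
    if (!any) return INF;
    for (int r = 1; r <= m; ++r) {
        const int base = offset + r - band;   // column stored at w = c - base
        const int clo = std::max(0, base);
        const int chi = std::min(n, offset + r + band);
        std::fill(cur.begin(), cur.end(), INF);
        if (clo > chi) return INF;
        const char pc = pattern[r - 1];
        for (int c = clo; c <= chi; ++c) {
            const int w = c - base;
            int best = INF;
            {   // deletion: pattern base unmatched (row r-1, same column)
                const int wp = w + 1;
                if (wp < W && prev[wp] < best) best = prev[wp] + 1;
            }
            if (c > 0) {
                // diagonal from (r-1, c-1)
                if (prev[w] < INF) {
                    const int cost =
                        prev[w] + (base_match(pc, subject[c - 1]) ? 0 : 1);
                    if (cost < best) best = cost;
                }
                // insertion from (r, c-1)
                if (w >= 1 && cur[w - 1] < INF && cur[w - 1] + 1 < best)
                    best = cur[w - 1] + 1;
            }
            cur[w] = best;
        }
        std::swap(prev, cur);
    }
    int best = INF;
    for (int w = 0; w < W; ++w) best = std::min(best, prev[w]);
    return best;
}

// ---- fast classification path ----

static const int INFB = 1 << 20;

// banded semiglobal distance with padded subject (branch-light inner loop)
static int banded_dist(const std::string& pattern, const std::string& subject,
                       int offset, int band) {
    const int m = (int)pattern.size(), n = (int)subject.size();
    const int W = 2 * band + 1;
    // padded subject: band+2 sentinels each side; sentinel never matches
    std::string B(n + 2 * (band + 2), '\x01');
    std::copy(subject.begin(), subject.end(), B.begin() + band + 2);
    std::vector<int> prev(W + 1, 0), cur(W + 1, INFB);
    prev[W] = INFB;                     // right sentinel
    for (int r = 1; r <= m; ++r) {
        const int base = offset + r - band;  // column at w=0
        const char pc = pattern[r - 1];
        // subject char for cell (r, c) with c = base + w is B[c-1+band+2]
        const char* sc = B.data() + (base - 1) + (band + 2);
        int left = INFB;                 // cur[w-1]
        for (int w = 0; w < W; ++w) {
            int best = prev[w + 1] + 1;              // deletion
            const int diag = prev[w] + (pc == sc[w] ? 0 : 1);
            if (diag < best) best = diag;
            const int ins = left + 1;                // insertion
            if (ins < best) best = ins;
            cur[w] = best;
            left = best;
        }
        cur[W] = INFB;
        std::swap(prev, cur);
    }
    int best = INFB;
    for (int w = 0; w < W; ++w) best = std::min(best, prev[w]);
    return best;
}

static std::string revcomp_str(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (auto& c : r) {
        switch (c) {
            case 'A': c = 'T'; break; case 'T': c = 'A'; break;
            case 'C': c = 'G'; break; case 'G': c = 'C'; break;
            default: c = 'N';
        }
    }
    return r;
}

// Classify one long read against the four junction references of a
// conformation pair (junctions[0:1] master, junctions[2:3] alternative).
// The read is indexed once; each junction is tried in both orientations.
// A junction is covered when >= 3 anchor seeds place its span fully
// inside the read and the banded semiglobal identity reaches
// min_identity.  Returns list(call, best_master, best_alt).
// [[Rcpp::export]]
List cpp_classify_read(CharacterVector junctions, const std::string& read,
                       double min_identity, int min_margin, double band_frac,
                       int min_band, int anchor_q, int anchor_step) {
    const int n = (int)read.size();
    const uint64_t mask = (1ULL << (2 * anchor_q)) - 1ULL;
    std::unordered_multimap<uint64_t, int> idx;
    if (n >= anchor_q) {
        idx.reserve((size_t)n);
        uint64_t h = 0; int run = 0;
        for (int j = 0; j < n; ++j) {
            int c = base_code(read[j]);
            if (c < 0) { run = 0; h = 0; continue; }
            h = ((h << 2) | (uint64_t)c) & mask;
            if (++run >= anchor_q) idx.emplace(h, j - anchor_q + 1);
        }
    }
    double best[2] = {R_PosInf, R_PosInf};   // master, alternative
    std::vector<int> offs;
    for (int jn = 0; jn < junctions.size(); ++jn) {
        const std::string fwd = as<std::string>(junctions[jn]);
        const int m = (int)fwd.size();
        const int band = std::max(min_band,
                                  (int)std::ceil(band_frac * m));
        for (int ori = 0; ori < 2; ++ori) {
            const std::string pat = ori ? revcomp_str(fwd) : fwd;
            offs.clear();
            for (int p = 0; p + anchor_q <= m; p += anchor_step) {
                uint64_t hp = 0; bool ok = true;
                for (int t = 0; t < anchor_q; ++t) {
                    int c = base_code(pat[p + t]);
                    if (c < 0) { ok = false; break; }
                    hp = (hp << 2) | (uint64_t)c;
                }
                if (!ok) continue;
                auto range = idx.equal_range(hp);
                for (auto it = range.first; it != range.second; ++it)
                    offs.push_back(it->second - p);
            }
            if ((int)offs.size() < 3) continue;
            std::nth_element(offs.begin(), offs.begin() + offs.size() / 2,
                             offs.end());
            const int off = offs[offs.size() / 2];
            if (off < 0 || off + m > n) continue;   // incomplete coverage
            const int d = banded_dist(pat, read, off, band);
            if (1.0 - (double)d / m < min_identity) continue;
            const int grp = jn < 2 ? 0 : 1;
            if (d < best[grp]) best[grp] = d;
        }
    }
    std::string call;
    if (!R_FINITE(best[0]) && !R_FINITE(best[1])) call = "uninformative";
    else if (best[1] - best[0] >= min_margin) call = "master";
    else if (best[0] - best[1] >= min_margin) call = "alternative";
    else call = "ambiguous";
    return List::create(_["call"] = call, _["best_master"] = best[0],
                        _["best_alt"] = best[1]);
}

// Apply uniform substitution + indel errors using R's RNG (so results
// are reproducible under set.seed()).
// [[Rcpp::export]]
CharacterVector cpp_mutate_reads(CharacterVector seqs, double sub_rate,
                                 double indel_rate) {
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    CharacterVector out(seqs.size());
    std::string res;
    for (int i = 0; i < seqs.size(); ++i) {
        const std::string s = as<std::string>(seqs[i]);
        res.clear();
        res.reserve(s.size() + 16);
        for (size_t j = 0; j < s.size(); ++j) {
            char c = s[j];
            if (sub_rate > 0 && unif_rand() < sub_rate) {
                char nb;
                do { nb = bases[(int)(unif_rand() * 4) & 3]; }
                while (nb == c);
                c = nb;
            }
            if (indel_rate > 0) {
                double v = unif_rand();
                if (v < indel_rate / 2) continue;            // deletion
                res.push_back(c);
                if (v < indel_rate)                          // insertion
                    res.push_back(bases[(int)(unif_rand() * 4) & 3]);
            } else {
                res.push_back(c);
            }
        }
        out[i] = res;
    }
    return out;
}
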