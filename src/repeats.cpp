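#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <array>
#include <cstdint>
#include <climits>

using namespace Rcpp;

// A=0 C=1 G=2 T=3, anything else (N, gap) = -1 and never matches.
static std::vector<int8_t> encode_seq(const std::string& s) {
    std::vector<int8_t> v(s.size());
    for (size_t i = 0; i < s.size(); ++i) {
        switch (s[i]) {
        case 'A': case 'a': v[i] = 0; break;
        case 'C': case 'c': v[i] = 1; break;
        case 'G': case 'g': v[i] = 2; break;
        case 'T': case 't': v[i] = 3; break;
        default:            v[i] = -1;
        }
    }
    return v;
}

static inline bool id_ok(int matches, int len, double min_id) {
    // matches/len*100 >= min_id, with a small epsilon so integer thresholds
    // (90, 99, 100) compare exactly.
    return (double)matches * 100.0 >= min_id * (double)len - 1e-7;
}

// Enumerate all one-step-maximal windows on a 0/1 match vector m:
// identity >= min_id, min_len <= len, len < cap handled here; a window is
// maximal when extending it by one position on either side (always onto a
// mismatch or past a boundary/cap) would drop identity below min_id.
// Windows of length exactly cap (arms would touch) are enumerated separately:
// both extensions are geometrically blocked, so identity alone decides.
//
// With G(t) = 100*matches(0..t) - min_id*t, a window [a,b] satisfies the
// identity threshold iff G(b+1) >= G(a), and a one-base extension (which by
// the A/B-set construction always adds a mismatch) still satisfies it iff
// G(b+1) >= G(a) + min_id. Valid-and-maximal windows therefore have
// G(b+1) in [G(a), G(a) + min_id), a band query answered by binary search
// over the B-set sorted by G — linearithmic instead of quadratic in the
// diagonal length.
static void enum_windows(const std::vector<int8_t>& m, int min_len, double min_id,
                         int cap, std::vector<std::array<int, 3> >& out) {
    const int M = (int)m.size();
    if (M < min_len) return;
    const double EPS = 1e-7;
    std::vector<int> pref(M + 1, 0);
    for (int i = 0; i < M; ++i) pref[i + 1] = pref[i] + (m[i] == 1);
    std::vector<double> G(M + 1);
    for (int t = 0; t <= M; ++t) G[t] = 100.0 * pref[t] - min_id * (double)t;
    std::vector<int> As, Bs;
    As.reserve(64); Bs.reserve(64);
    for (int a = 0; a < M; ++a) if (a == 0 || m[a - 1] == 0) As.push_back(a);
    for (int b = 0; b < M; ++b) if (b == M - 1 || m[b + 1] == 0) Bs.push_back(b);
    // B-set entries keyed by G(b+1)
    std::vector<std::pair<double, int> > bg;
    bg.reserve(Bs.size());
    for (size_t i = 0; i < Bs.size(); ++i)
        bg.push_back(std::make_pair(G[Bs[i] + 1], Bs[i]));
    std::sort(bg.begin(), bg.end());
    for (size_t ia = 0; ia < As.size(); ++ia) {
        const int a = As[ia];
        const double lo = G[a] - EPS, hi = G[a] + min_id - EPS;
        std::vector<std::pair<double, int> >::iterator it = std::lower_bound(
            bg.begin(), bg.end(), std::make_pair(lo, INT_MIN));
        for (; it != bg.end() && it->first < hi; ++it) {
            const int b = it->second;
            const int len = b - a + 1;
            if (len < min_len) continue;
            if (len >= cap) continue;  // len == cap handled below, len > cap illegal
            out.push_back({a, b, pref[b + 1] - pref[a]});
        }
    }
    // whole-diagonal window: no extension exists at all, so it is maximal
    // whenever it passes the threshold, even above the band
    if (M >= min_len && M < cap && G[M] >= G[0] + min_id - EPS &&
        id_ok(pref[M], M, min_id))
        out.push_back({0, M - 1, pref[M]});
    if (cap != INT_MAX && cap >= min_len && cap <= M) {
        for (int a = 0; a + cap - 1 < M; ++a) {
            const int b = a + cap - 1;
            const int S = pref[b + 1] - pref[a];
            if (id_ok(S, cap, min_id)) out.push_back({a, b, S});
        }
    }
}

struct RawPair {
    int a1s, a1e, a2s, a2e, len, matches;  // 1-based inclusive arms
};

static void scan_direct_diagonal(const std::vector<int8_t>& code, int d,
                                 int min_len, double min_id,
                                 std::vector<RawPair>& out) {
    const int n = (int)code.size();
    if (d < min_len || d >= n) return;
    const int M = n - d;
    std::vector<int8_t> m(M);
    for (int t = 0; t < M; ++t)
        m[t] = (code[t] >= 0 && code[t] == code[t + d]) ? 1 : 0;
    std::vector<std::array<int, 3> > wins;
    enum_windows(m, min_len, min_id, d, wins);
    for (size_t w = 0; w < wins.size(); ++w) {
        const int a = wins[w][0], b = wins[w][1], S = wins[w][2];
        RawPair p = {a + 1, b + 1, a + d + 1, b + d + 1, b - a + 1, S};
        out.push_back(p);
    }
}

// Antidiagonal c0 (0-based): position t pairs with c0 - t on the complementary
// strand; valid t keeps both in range and strictly left of its partner.
static void scan_inverted_antidiagonal(const std::vector<int8_t>& code, int c0,
                                       int min_len, double min_id,
                                       std::vector<RawPair>& out) {
    const int n = (int)code.size();
    const int t_lo = std::max(0, c0 - (n - 1));
    const int t_hi = (c0 - 1) / 2;
    if (c0 < 1 || t_hi < t_lo) return;
    const int M = t_hi - t_lo + 1;
    std::vector<int8_t> m(M);
    for (int i = 0; i < M; ++i) {
        const int t = t_lo + i, u = c0 - t;
        m[i] = (code[t] >= 0 && code[u] >= 0 && code[t] + code[u] == 3) ? 1 : 0;
    }
    std::vector<std::array<int, 3> > wins;
    enum_windows(m, min_len, min_id, INT_MAX, wins);
    for (size_t w = 0; w < wins.size(); ++w) {
        const int t1 = t_lo + wins[w][0], t2 = t_lo + wins[w][1];
        RawPair p = {t1 + 1, t2 + 1, c0 - t2 + 1, c0 - t1 + 1,
                     t2 - t1 + 1, wins[w][2]};
        out.push_back(p);
    }
}

static const int MAX_KMER_OCC = 2048;  // guard against low-complexity blowup

static void seeded_diagonals(const std::vector<int8_t>& code, int k, bool inverted,
                             std::unordered_set<int>& diags) {
    const int n = (int)code.size();
    if (n < k) return;
    std::unordered_map<uint64_t, std::vector<int> > pos;
    pos.reserve(n * 2);
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t fwd = 0, rc = 0;
    int valid = 0;  // length of current run of ACGT
    for (int i = 0; i < n; ++i) {
        const int c = code[i];
        if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)c) & mask;
        rc = (rc >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
        if (++valid < k) continue;
        const int start = i - k + 1;  // 0-based kmer start
        if (!inverted) {
            std::vector<int>& v = pos[fwd];
            for (size_t j = 0; j < v.size(); ++j) diags.insert(start - v[j]);
            if ((int)v.size() < MAX_KMER_OCC) v.push_back(start);
        } else {
            std::unordered_map<uint64_t, std::vector<int> >::iterator it = pos.find(rc);
            if (it != pos.end())
                for (size_t j = 0; j < it->second.size(); ++j)
                    diags.insert(it->second[j] + start + k - 1);  // antidiagonal c0
            std::vector<int>& v = pos[fwd];
            if ((int)v.size() < MAX_KMER_OCC) v.push_back(start);
        }
    }
}

// [[Rcpp::export]]
DataFrame find_repeats_cpp(std::string sequence, bool inverted, int min_len,
                           double min_identity, int seed_k, bool exhaustive) {
    const std::vector<int8_t> code = encode_seq(sequence);
    const int n = (int)code.size();
    std::vector<RawPair> raw;
    if (n >= 2 * min_len || (inverted && n >= 2 * min_len)) {
        if (exhaustive) {
            if (!inverted) {
                for (int d = min_len; d <= n - min_len; ++d)
                    scan_direct_diagonal(code, d, min_len, min_identity, raw);
            } else {
                for (int c0 = 2 * min_len - 1; c0 <= 2 * n - 3; ++c0)
                    scan_inverted_antidiagonal(code, c0, min_len, min_identity, raw);
            }
        } else {
            std::unordered_set<int> diags;
            seeded_diagonals(code, seed_k, inverted, diags);
            for (std::unordered_set<int>::iterator it = diags.begin();
                 it != diags.end(); ++it) {
                if (!inverted) scan_direct_diagonal(code, *it, min_len, min_identity, raw);
                else scan_inverted_antidiagonal(code, *it, min_len, min_identity, raw);
            }
        }
    }
    const int m = (int)raw.size();
    IntegerVector a1s(m), a1e(m), a2s(m), a2e(m), len(m);
    NumericVector idp(m);
    for (int i = 0; i < m; ++i) {
        a1s[i] = raw[i].a1s; a1e[i] = raw[i].a1e;
        a2s[i] = raw[i].a2s; a2e[i] = raw[i].a2e;
        len[i] = raw[i].len;
        idp[i] = 100.0 * (double)raw[i].matches / (double)raw[i].len;
    }
    return DataFrame::create(_["arm1_start"] = a1s, _["arm1_end"] = a1e,
                             _["arm2_start"] = a2s, _["arm2_end"] = a2e,
                             _["length_bp"] = len, _["identity_percent"] = idp);
}

// Exact k-mer matches between two sequences (same strand); the caller handles
// the reverse strand by passing the reverse complement of B.
// [[Rcpp::export]]
DataFrame kmer_anchors_cpp(std::string seq_a, std::string seq_b, int k, int max_occ) {
    const std::vector<int8_t> ca = encode_seq(seq_a), cb = encode_seq(seq_b);
    const int na = (int)ca.size(), nb = (int)cb.size();
    std::unordered_map<uint64_t, std::vector<int> > pos;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t key = 0; int valid = 0;
    for (int i = 0; i < nb; ++i) {
        const int c = cb[i];
        if (c < 0) { valid = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (++valid < k) continue;
        std::vector<int>& v = pos[key];
        if ((int)v.size() < max_occ) v.push_back(i - k + 1);
    }
    std::vector<int> av, bv;
    key = 0; valid = 0;
    for (int i = 0; i < na; ++i) {
        const int c = ca[i];
        if (c < 0) { valid = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (++valid < k) continue;
        std::unordered_map<uint64_t, std::vector<int> >::iterator it = pos.find(key);
        if (it == pos.end()) continue;
        const int astart = i - k + 1;
        for (size_t j = 0; j < it->second.size(); ++j) {
            av.push_back(astart + 1);         // 1-based
            bv.push_back(it->second[j] + 1);
        }
    }
    return DataFrame::create(_["a_start"] = wrap(av), _["b_start"] = wrap(bv));
}

// Ungapped match count between equal-length regions (1-based inclusive);
// N never matches.
// [[Rcpp::export]]
int hamming_matches_cpp(std::string seq_a, int a_start, std::string seq_b,
                        int b_start, int len) {
    const std::vector<int8_t> ca = encode_seq(seq_a), cb = encode_seq(seq_b);
    int s = 0;
    for (int t = 0; t < len; ++t) {
        const int8_t x = ca[a_start - 1 + t], y = cb[b_start - 1 + t];
        if (x >= 0 && x == y) ++s;
    }
    return s;
}
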