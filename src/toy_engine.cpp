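// Toy folding engine: nested structures only, additive pair scores
// (GC = -3, AU = -2, GU = -1), minimum hairpin loop 3, kT = 1 for the
// partition function.  Deliberately non-physical; exists so the genetic
// algorithm is testable without external folding engines.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double PAIR_SCORE[5][5] = {
    // indices 1=A 2=C 3=G 4=U; 0 unused
    {0, 0, 0, 0, 0},
    {0, 0, 0, 0, -2},   // A-U
    {0, 0, 0, -3, 0},   // C-G
    {0, 0, -3, 0, -1},  // G-C, G-U
    {0, -2, 0, -1, 0}   // U-A, U-G
};
static const int MINLOOP = 3;
static const double BIG = 1e17;

// constraint partner vector (0-based array, 1-based partners):
// -1 free, 0 forced unpaired, p > 0 forced to pair with position p
static inline bool pair_ok(const IntegerVector& s, const IntegerVector& con,
                           int i, int j) {  // 0-based, i < j
    if (j - i - 1 < MINLOOP) return false;
    if (PAIR_SCORE[s[i]][s[j]] == 0) return false;
    if (con[i] == 0 || con[j] == 0) return false;
    if (con[i] > 0 && con[i] != j + 1) return false;
    if (con[j] > 0 && con[j] != i + 1) return false;
    return true;
}

// [[Rcpp::export(name = ".toy_mfe_cpp")]]
List toy_mfe_cpp(IntegerVector s, IntegerVector con) {
    int n = s.size();
    std::vector<std::vector<double>> W(n, std::vector<double>(n, 0.0));
    for (int i = 0; i < n; ++i) W[i][i] = (con[i] > 0) ? BIG : 0.0;
    for (int len = 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            double best = BIG;
            if (con[i] <= 0) best = W[i + 1][j];          // i unpaired
            for (int k = i + 1; k <= j; ++k) {            // i paired with k
                if (!pair_ok(s, con, i, k)) continue;
                double inner = (i + 1 <= k - 1) ? W[i + 1][k - 1] : 0.0;
                double outer = (k + 1 <= j) ? W[k + 1][j] : 0.0;
                if (inner >= BIG || outer >= BIG) continue;
                double v = PAIR_SCORE[s[i]][s[k]] + inner + outer;
                if (v < best) best = v;
            }
            W[i][j] = best;
        }
    }
    double e = (n >= 2) ? W[0][n - 1] : ((n == 1 && con[0] > 0) ? BIG : 0.0);
    if (e >= BIG) return List::create(_["feasible"] = false);
    IntegerVector partner(n, 0);
    std::vector<std::pair<int, int>> stk;
    stk.push_back({0, n - 1});
    while (!stk.empty()) {
        int i = stk.back().first, j = stk.back().second;
        stk.pop_back();
        if (i >= j) continue;
        if (con[i] <= 0 && std::abs(W[i][j] - W[i + 1][j]) < 1e-9) {
            stk.push_back({i + 1, j});
            continue;
        }
        bool found = false;
        for (int k = i + 1; k <= j && !found; ++k) {
            if (!pair_ok(s, con, i, k)) continue;
            double inner = (i + 1 <= k - 1) ? W[i + 1][k - 1] : 0.0;
            double outer = (k + 1 <= j) ? W[k + 1][j] : 0.0;
            if (inner >= BIG || outer >= BIG) continue;
            if (std::abs(W[i][j] - (PAIR_SCORE[s[i]][s[k]] + inner + outer)) < 1e-9) {
                partner[i] = k + 1; partner[k] = i + 1;
                stk.push_back({i + 1, k - 1});
                stk.push_back({k + 1, j});
                found = true;
            }
        }
        if (!found) stop("toy engine traceback failure");
    }
    return List::create(_["feasible"] = true, _["energy"] = e,
                        _["partner"] = partner);
}

// [[Rcpp::export(name = ".toy_pf_cpp")]]
double toy_pf_cpp(IntegerVector s, IntegerVector con) {
    int n = s.size();
    std::vector<std::vector<double>> Z(n, std::vector<double>(n, 1.0));
    for (int i = 0; i < n; ++i) Z[i][i] = (con[i] > 0) ? 0.0 : 1.0;
    for (int len = 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            double z = 0.0;
            if (con[i] <= 0) z += Z[i + 1][j];
            for (int k = i + 1; k <= j; ++k) {
                if (!pair_ok(s, con, i, k)) continue;
                double inner = (i + 1 <= k - 1) ? Z[i + 1][k - 1] : 1.0;
                double outer = (k + 1 <= j) ? Z[k + 1][j] : 1.0;
                z += std::exp(-PAIR_SCORE[s[i]][s[k]]) * inner * outer;
            }
            Z[i][j] = z;
        }
    }
    double z = (n >= 2) ? Z[0][n - 1] : ((n == 1 && con[0] > 0) ? 0.0 : 1.0);
    if (z <= 0) return R_PosInf;   // empty constrained ensemble
    return -std::log(z);           // ensemble free energy G = -kT ln Z, kT = 1
}

// k best (lowest-energy) distinct nested structures; the decomposition is
// unambiguous, so distinct DP derivations are distinct structures.
struct Entry { double e; int type; int k; int a; int b; };
// type 0: i unpaired, child entry a on (i+1, j); a = -1 => empty interval
// type 1: pair (i, k); child a on (i+1, k-1), b on (k+1, j); -1 => empty

// [[Rcpp::export(name = ".toy_kbest_cpp")]]
List toy_kbest_cpp(IntegerVector s, int kbest) {
    int n = s.size();
    IntegerVector con(n, -1);
    std::vector<std::vector<std::vector<Entry>>> T(
        n, std::vector<std::vector<Entry>>(n));
    for (int len = 1; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            std::vector<Entry> cand;
            if (i + 1 > j) {
                cand.push_back({0.0, 0, 0, -1, -1});
            } else {
                const std::vector<Entry>& ch = T[i + 1][j];
                for (size_t a = 0; a < ch.size(); ++a)
                    cand.push_back({ch[a].e, 0, 0, (int)a, -1});
            }
            for (int k = i + 1; k <= j; ++k) {
                if (!pair_ok(s, con, i, k)) continue;
                double pe = PAIR_SCORE[s[i]][s[k]];
                bool has_in = (i + 1 <= k - 1), has_out = (k + 1 <= j);
                int na = has_in ? (int)T[i + 1][k - 1].size() : 1;
                int nb = has_out ? (int)T[k + 1][j].size() : 1;
                for (int a = 0; a < na; ++a) {
                    double ea = has_in ? T[i + 1][k - 1][a].e : 0.0;
                    for (int b = 0; b < nb; ++b) {
                        double eb = has_out ? T[k + 1][j][b].e : 0.0;
                        cand.push_back({pe + ea + eb, 1, k,
                                        has_in ? a : -1, has_out ? b : -1});
                    }
                }
            }
            std::stable_sort(cand.begin(), cand.end(),
                             [](const Entry& x, const Entry& y) { return x.e < y.e; });
            if ((int)cand.size() > kbest) cand.resize(kbest);
            T[i][j] = cand;
        }
    }
    std::vector<Entry>& top = T[0][n - 1];
    List out;
    for (size_t r = 0; r < top.size(); ++r) {
        IntegerVector partner(n, 0);
        std::vector<std::array<int, 3>> stk;
        stk.push_back({{0, n - 1, (int)r}});
        while (!stk.empty()) {
            std::array<int, 3> fr = stk.back(); stk.pop_back();
            int i = fr[0], j = fr[1], idx = fr[2];
            if (i > j || idx < 0) continue;
            Entry& en = T[i][j][idx];
            if (en.type == 0) {
                if (i + 1 <= j) stk.push_back({{i + 1, j, en.a}});
            } else {
                int k = en.k;
                partner[i] = k + 1; partner[k] = i + 1;
                stk.push_back({{i + 1, k - 1, en.a}});
                stk.push_back({{k + 1, j, en.b}});
            }
        }
        out.push_back(List::create(_["energy"] = top[r].e,
                                   _["partner"] = partner));
    }
    return out;
}
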