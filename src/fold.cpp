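#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>

using namespace Rcpp;

// Minimum-free-energy folding of a single RNA strand over pseudoknot-free
// structures, under a simplified nearest-neighbor model:
//   * a pair (i,j) immediately enclosing pair (i+1,j-1) contributes the
//     stacking energy of the two pair types (negative, favourable);
//   * a pair enclosing no paired position closes a hairpin loop and pays a
//     positive, length-dependent penalty;
//   * a pair enclosing paired positions other than the stacked geometry
//     (bulge / internal loop / multiloop initiation) pays one flat positive
//     penalty;
//   * unpaired external bases are free.
// Allowed pairs: AU, UA, GC, CG, GU, UG; every pair must enclose at least
// minLoop unpaired-or-paired positions (j - i - 1 >= minLoop).
//
// Tables (span-increasing DP, O(n^3) time, O(n^2) space):
//   V(i,j)  best energy of [i..j] given i pairs j
//   W(i,j)  best energy of [i..j] over all structures (including empty = 0)
//   P(i,j)  best energy of [i..j] over structures with >= 1 pair
// and Pno(a,b) (computed on the fly): best over structures of [a..b] with
// >= 1 pair in which a is NOT paired with b -- the interior of a
// non-stacked closing pair.

static const double INF_E = 1e9;
static const double EPS_E = 1e-7;

// base codes: A=0, C=1, G=2, U=3
static inline int pairType(int a, int b) {
    if (a == 0 && b == 3) return 0; // A-U
    if (a == 3 && b == 0) return 1; // U-A
    if (a == 2 && b == 1) return 2; // G-C
    if (a == 1 && b == 2) return 3; // C-G
    if (a == 2 && b == 3) return 4; // G-U
    if (a == 3 && b == 2) return 5; // U-G
    return -1;
}

struct FoldDP {
    int n, minLoop;
    double interiorPenalty;
    std::vector<int> s;
    NumericMatrix stackE;
    NumericVector hp; // hp[l-1]: hairpin-loop penalty for loop length l
    std::vector<double> V, W, P;
    std::string db;

    FoldDP(const std::vector<int>& seq, NumericMatrix st, NumericVector hpv,
           int minLoop_, double intPen)
        : n((int)seq.size()), minLoop(minLoop_), interiorPenalty(intPen),
          s(seq), stackE(st), hp(hpv),
          V((size_t)n * n, INF_E), W((size_t)n * n, 0.0),
          P((size_t)n * n, INF_E), db((size_t)n, '.') {}

    inline size_t idx(int i, int j) const { return (size_t)i * n + j; }
    inline double Wat(int i, int j) const { return (j < i) ? 0.0 : W[idx(i, j)]; }
    inline double Pat(int i, int j) const { return (j < i) ? INF_E : P[idx(i, j)]; }
    inline double Vat(int i, int j) const { return (j <= i) ? INF_E : V[idx(i, j)]; }

    inline double hairpinPen(int l) const {
        if (l < minLoop || l < 1 || l > hp.size()) return INF_E;
        return hp[l - 1];
    }
    inline double stackOf(int i, int j) const {
        int p1 = pairType(s[i], s[j]);
        int p2 = pairType(s[i + 1], s[j - 1]);
        if (p1 < 0 || p2 < 0) return INF_E;
        return stackE(p1, p2);
    }

    double Pno(int a, int b) const {
        if (b - a - 1 < minLoop) {
            // no room for any pair except possibly (a,b) itself, which is excluded
            if (b - a < minLoop + 1) return INF_E;
        }
        double best = Pat(a + 1, b);
        for (int k = a + 1; k < b; ++k) {
            double v = Vat(a, k);
            if (v >= INF_E) continue;
            double cand = v + Wat(k + 1, b);
            if (cand < best) best = cand;
        }
        return best;
    }

    void fill() {
        for (int len = 2; len <= n; ++len) {
            for (int i = 0; i + len - 1 < n; ++i) {
                int j = i + len - 1;
                double v = INF_E;
                if (pairType(s[i], s[j]) >= 0 && j - i - 1 >= minLoop) {
                    double h = hairpinPen(j - i - 1);
                    if (h < v) v = h;
                    double st = stackOf(i, j);
                    double vin = Vat(i + 1, j - 1);
                    if (st < INF_E && vin < INF_E && st + vin < v) v = st + vin;
                    double pn = Pno(i + 1, j - 1);
                    if (pn < INF_E && pn + interiorPenalty < v)
                        v = pn + interiorPenalty;
                }
                V[idx(i, j)] = v;

                double p = Pat(i + 1, j);
                double w = Wat(i + 1, j);
                for (int k = i + 1; k <= j; ++k) {
                    double vv = Vat(i, k);
                    if (vv >= INF_E) continue;
                    double cand = vv + Wat(k + 1, j);
                    if (cand < p) p = cand;
                    if (cand < w) w = cand;
                }
                P[idx(i, j)] = p;
                W[idx(i, j)] = w;
            }
        }
    }

    // Traceback: deterministic; on ties, pairing the 5'-most position with
    // its smallest admissible partner is preferred over leaving it unpaired,
    // and a stacked continuation is preferred over hairpin closure or
    // interior decomposition.
    void traceW(int i, int j) {
        if (j <= i) return;
        double target = Wat(i, j);
        for (int k = i + 1; k <= j; ++k) {
            double vv = Vat(i, k);
            if (vv >= INF_E) continue;
            if (std::fabs(vv + Wat(k + 1, j) - target) < EPS_E) {
                traceV(i, k);
                traceW(k + 1, j);
                return;
            }
        }
        traceW(i + 1, j);
    }
    void traceP(int i, int j) {
        double target = Pat(i, j);
        for (int k = i + 1; k <= j; ++k) {
            double vv = Vat(i, k);
            if (vv >= INF_E) continue;
            if (std::fabs(vv + Wat(k + 1, j) - target) < EPS_E) {
                traceV(i, k);
                traceW(k + 1, j);
                return;
            }
        }
        traceP(i + 1, j);
    }
    void tracePno(int a, int b, double target) {
        for (int k = a + 1; k < b; ++k) {
            double vv = Vat(a, k);
            if (vv >= INF_E) continue;
            if (std::fabs(vv + Wat(k + 1, b) - target) < EPS_E) {
                traceV(a, k);
                traceW(k + 1, b);
                return;
            }
        }
        traceP(a + 1, b);
    }
    void traceV(int i, int j) {
        db[i] = '(';
        db[j] = ')';
        double target = Vat(i, j);
        double st = stackOf(i, j);
        double vin = Vat(i + 1, j - 1);
        if (st < INF_E && vin < INF_E &&
            std::fabs(st + vin - target) < EPS_E) {
            traceV(i + 1, j - 1);
            return;
        }
        if (std::fabs(hairpinPen(j - i - 1) - target) < EPS_E) return;
        tracePno(i + 1, j - 1, target - interiorPenalty);
    }
};

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(IntegerVector seq, NumericMatrix stackE, NumericVector hp,
                  int minLoop, double interiorPenalty) {
    std::vector<int> s(seq.begin(), seq.end());
    int n = (int)s.size();
    if (n == 0)
        return List::create(_["mfe"] = 0.0, _["structure"] = "");
    FoldDP dp(s, stackE, hp, minLoop, interiorPenalty);
    dp.fill();
    double mfe = dp.Wat(0, n - 1);
    if (mfe < -EPS_E) dp.traceW(0, n - 1);
    return List::create(_["mfe"] = mfe, _["structure"] = dp.db);
}
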