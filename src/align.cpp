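#include <Rcpp.h>
#include <vector>
#include <string>
#include <functional>
#include <limits>

using namespace Rcpp;

// Gotoh affine-gap global alignment with optional free end gaps.
// Gap of length k costs gap_open + k * gap_extend (ClustalW-style).
// Three states: M (residue-residue), X (gap in b, vertical), Y (gap in a).
// Ties resolved M > X > Y (diagonal > up > left) for determinism.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct TB {
    // per-cell predecessor state for each of the three state matrices
    std::vector<unsigned char> m, x, y;
    int ncol;
    TB(int n, int m_, int /*unused*/) : m((size_t)(n + 1) * (m_ + 1)),
        x((size_t)(n + 1) * (m_ + 1)), y((size_t)(n + 1) * (m_ + 1)), ncol(m_ + 1) {}
    size_t at(int i, int j) const { return (size_t)i * ncol + j; }
};

// core DP; score(i,j) is 1-based residue pair score
static void gotoh_core(int n, int m,
                       const std::function<double(int, int)> &score,
                       double go, double ge, bool free_end,
                       TB &tb, double &best, int &end_i, int &end_j,
                       unsigned char &end_state) {
    std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1);
    std::vector<double> Mc(m + 1), Xc(m + 1), Yc(m + 1);

    Mp[0] = 0.0;
    Xp[0] = NEG_INF;
    Yp[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
        Mp[j] = NEG_INF;
        Xp[j] = NEG_INF;
        Yp[j] = free_end ? 0.0 : -(go + j * ge);
        tb.y[tb.at(0, j)] = 2; // extend along the top row
    }

    best = NEG_INF;
    end_i = n; end_j = m; end_state = 0;

    for (int i = 1; i <= n; ++i) {
        Mc[0] = NEG_INF;
        Yc[0] = NEG_INF;
        Xc[0] = free_end ? 0.0 : -(go + i * ge);
        tb.x[tb.at(i, 0)] = 1;
        for (int j = 1; j <= m; ++j) {
            // M state
            double dM = Mp[j - 1], dX = Xp[j - 1], dY = Yp[j - 1];
            unsigned char pm = 0; double vm = dM;
            if (dX > vm) { vm = dX; pm = 1; }
            if (dY > vm) { vm = dY; pm = 2; }
            Mc[j] = (vm == NEG_INF) ? NEG_INF : vm + score(i, j);
            tb.m[tb.at(i, j)] = pm;
            // X state: gap in b (consume a_i)
            double oM = Mp[j] - (go + ge), oX = Xp[j] - ge, oY = Yp[j] - (go + ge);
            unsigned char px = 0; double vx = oM;
            if (px == 0 && oX > vx) { vx = oX; px = 1; }
            if (oY > vx) { vx = oY; px = 2; }
            Xc[j] = vx;
            tb.x[tb.at(i, j)] = px;
            // Y state: gap in a (consume b_j)
            double lM = Mc[j - 1] - (go + ge), lX = Xc[j - 1] - (go + ge), lY = Yc[j - 1] - ge;
            unsigned char py = 0; double vy = lM;
            if (lX > vy) { vy = lX; py = 1; }
            if (lY > vy) { vy = lY; py = 2; }
            Yc[j] = vy;
            tb.y[tb.at(i, j)] = py;
        }
        if (free_end) {
            // candidate endpoints: end of row i at j = m (trailing gaps in b free)
            double v = Mc[m]; unsigned char st = 0;
            if (Xc[m] > v) { v = Xc[m]; st = 1; }
            if (Yc[m] > v) { v = Yc[m]; st = 2; }
            if (i == n || v > best) {
                if (i == n) {
                    // bottom row: all j are candidate endpoints
                    for (int j = 0; j <= m; ++j) {
                        double vj = Mc[j]; unsigned char sj = 0;
                        if (j == 0) { vj = (n == 0) ? 0.0 : Xc[0]; sj = 1; }
                        if (Xc[j] > vj) { vj = Xc[j]; sj = 1; }
                        if (Yc[j] > vj) { vj = Yc[j]; sj = 2; }
                        if (vj > best) { best = vj; end_i = n; end_j = j; end_state = sj; }
                    }
                } else if (v > best) {
                    best = v; end_i = i; end_j = m; end_state = st;
                }
            }
        }
        std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    }
    if (!free_end) {
        double v = Mp[m]; unsigned char st = 0;
        if (Xp[m] > v) { v = Xp[m]; st = 1; }
        if (Yp[m] > v) { v = Yp[m]; st = 2; }
        best = v; end_i = n; end_j = m; end_state = st;
    }
}

// traceback into an ops vector: 0 = diagonal, 1 = up (gap in b), 2 = left (gap in a)
static std::vector<int> traceback(const TB &tb, int n, int m,
                                  int end_i, int end_j, unsigned char end_state,
                                  bool free_end) {
    std::vector<int> ops;
    // free trailing gaps
    for (int i = n; i > end_i; --i) ops.push_back(1);
    for (int j = m; j > end_j; --j) ops.push_back(2);
    int i = end_i, j = end_j;
    unsigned char st = end_state;
    while (i > 0 || j > 0) {
        if (i == 0) { ops.push_back(2); --j; continue; }
        if (j == 0) { ops.push_back(1); --i; continue; }
        unsigned char prev;
        if (st == 0) {
            prev = tb.m[tb.at(i, j)];
            ops.push_back(0); --i; --j;
        } else if (st == 1) {
            prev = tb.x[tb.at(i, j)];
            ops.push_back(1); --i;
        } else {
            prev = tb.y[tb.at(i, j)];
            ops.push_back(2); --j;
        }
        st = prev;
    }
    std::reverse(ops.begin(), ops.end());
    return ops;
}

// [[Rcpp::export]]
List gotoh_align_cpp(std::string a, std::string b,
                     double match, double mismatch,
                     double gap_open, double gap_extend, bool free_end_gaps) {
    int n = a.size(), m = b.size();
    if (n == 0 || m == 0) {
        std::string ga(m, '-'), gb(n, '-');
        double sc = 0.0;
        int k = n + m;
        if (!free_end_gaps && k > 0) sc = -(gap_open + k * gap_extend);
        return List::create(_["aligned_a"] = a + ga, _["aligned_b"] = gb + b,
                            _["score"] = sc);
    }
    TB tb(n, m, 0);
    double best; int ei, ej; unsigned char es;
    auto sc = [&](int i, int j) {
        return a[i - 1] == b[j - 1] ? match : mismatch;
    };
    gotoh_core(n, m, sc, gap_open, gap_extend, free_end_gaps, tb, best, ei, ej, es);
    std::vector<int> ops = traceback(tb, n, m, ei, ej, es, free_end_gaps);
    std::string ga, gb2;
    ga.reserve(ops.size()); gb2.reserve(ops.size());
    int i = 0, j = 0;
    for (int op : ops) {
        if (op == 0) { ga += a[i++]; gb2 += b[j++]; }
        else if (op == 1) { ga += a[i++]; gb2 += '-'; }
        else { ga += '-'; gb2 += b[j++]; }
    }
    return List::create(_["aligned_a"] = ga, _["aligned_b"] = gb2,
                        _["score"] = best);
}

// Profile-profile variant: S is the (n x m) column-pair score matrix.
// Returns the op path (0 diag, 1 up = gap in profile 2, 2 left = gap in profile 1).
// [[Rcpp::export]]
List gotoh_profile_cpp(NumericMatrix S, double gap_open, double gap_extend,
                       bool free_end_gaps) {
    int n = S.nrow(), m = S.ncol();
    TB tb(n, m, 0);
    double best; int ei, ej; unsigned char es;
    auto sc = [&](int i, int j) { return S(i - 1, j - 1); };
    gotoh_core(n, m, sc, gap_open, gap_extend, free_end_gaps, tb, best, ei, ej, es);
    std::vector<int> ops = traceback(tb, n, m, ei, ej, es, free_end_gaps);
    return List::create(_["ops"] = wrap(ops), _["score"] = best);
}
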