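#include <Rcpp.h>
#include "bignum.h"
using namespace Rcpp;

// The complete de Bruijn graph of order k over an alphabet of size sigma is
// never materialized: vertex v (0-based code, first character most
// significant) has successors (v mod sigma^(k-1))*sigma + c and predecessors
// c*sigma^(k-1) + v div sigma for each character value c. All routines below
// take the graph as (sigma, k, alive) where alive flags the surviving
// vertices of the residual graph.

static inline int ipow(int b, int e) {
    long long r = 1;
    for (int i = 0; i < e; ++i) r *= b;
    if (r > 2147483647LL) Rcpp::stop("sigma^k exceeds integer range");
    return static_cast<int>(r);
}

static inline int succ_of(int v, int c, int powkm1, int sigma) {
    return (v % powkm1) * sigma + c;
}
static inline int pred_of(int v, int c, int powkm1, int sigma) {
    return c * powkm1 + v / sigma;
}

// Kahn's method over the alive vertices; queue seeded and grown in encoded
// order so the order (and everything derived from it) is deterministic.
// Returns false if a directed cycle survives.
static bool topo_order(int sigma, int n, int powkm1, const std::vector<char> &alive,
                       std::vector<int> &order) {
    std::vector<int> indeg(n, 0);
    int n_alive = 0;
    for (int v = 0; v < n; ++v) {
        if (!alive[v]) continue;
        ++n_alive;
        for (int c = 0; c < sigma; ++c) {
            int u = succ_of(v, c, powkm1, sigma);
            if (alive[u]) ++indeg[u];
        }
    }
    order.clear();
    order.reserve(n_alive);
    for (int v = 0; v < n; ++v)
        if (alive[v] && indeg[v] == 0) order.push_back(v);
    for (size_t head = 0; head < order.size(); ++head) {
        int v = order[head];
        for (int c = 0; c < sigma; ++c) {
            int u = succ_of(v, c, powkm1, sigma);
            if (alive[u] && --indeg[u] == 0) order.push_back(u);
        }
    }
    return static_cast<int>(order.size()) == n_alive;
}

static std::vector<char> as_alive(const LogicalVector &alive) {
    std::vector<char> a(alive.size());
    for (R_xlen_t i = 0; i < alive.size(); ++i) a[i] = alive[i] == TRUE;
    return a;
}

// [[Rcpp::export]]
bool cpp_is_acyclic(int sigma, int k, LogicalVector alive) {
    int n = ipow(sigma, k), powkm1 = ipow(sigma, k - 1);
    if (alive.size() != n) stop("alive has wrong length");
    std::vector<char> a = as_alive(alive);
    std::vector<int> order;
    return topo_order(sigma, n, powkm1, a, order);
}

// Longest directed path (edge count) in the residual DAG; -1 when no vertex
// is alive, 0 when vertices survive but no edge does.
// [[Rcpp::export]]
int cpp_longest_path(int sigma, int k, LogicalVector alive) {
    int n = ipow(sigma, k), powkm1 = ipow(sigma, k - 1);
    if (alive.size() != n) stop("alive has wrong length");
    std::vector<char> a = as_alive(alive);
    std::vector<int> order;
    if (!topo_order(sigma, n, powkm1, a, order))
        stop("residual graph contains a directed cycle");
    if (order.empty()) return -1;
    std::vector<int> lp(n, 0);
    int best = 0;
    for (size_t i = 0; i < order.size(); ++i) {
        int v = order[i];
        for (int c = 0; c < sigma; ++c) {
            int u = succ_of(v, c, powkm1, sigma);
            if (a[u] && lp[v] + 1 > lp[u]) lp[u] = lp[v] + 1;
        }
    }
    for (size_t i = 0; i < order.size(); ++i)
        if (lp[order[i]] > best) best = lp[order[i]];
    return best;
}

// ---- bounded (l-limited) path-count tables ------------------------------

// D(v,i): exact number of i-edge paths starting at v; F(v,i): ending at v.
// Level dynamic programming: column i depends only on column i-1, so no
// topological order is needed (and on a cyclic graph the same recurrences
// count walks, which is what the verifier wants).
static void bounded_D(int sigma, int n, int powkm1, const std::vector<char> &alive,
                      int ell, std::vector<Big> &D) {
    D.assign(static_cast<size_t>(n) * (ell + 1), Big());
    for (int v = 0; v < n; ++v)
        if (alive[v]) D[v] = Big(1);
    for (int i = 1; i <= ell; ++i) {
        size_t off = static_cast<size_t>(i) * n, offp = off - n;
        for (int v = 0; v < n; ++v) {
            if (!alive[v]) continue;
            Big &t = D[off + v];
            for (int c = 0; c < sigma; ++c) {
                int u = succ_of(v, c, powkm1, sigma);
                if (alive[u]) t.add(D[offp + u]);
            }
        }
    }
}

static void bounded_F(int sigma, int n, int powkm1, const std::vector<char> &alive,
                      int ell, std::vector<Big> &F) {
    F.assign(static_cast<size_t>(n) * (ell + 1), Big());
    for (int v = 0; v < n; ++v)
        if (alive[v]) F[v] = Big(1);
    for (int i = 1; i <= ell; ++i) {
        size_t off = static_cast<size_t>(i) * n, offp = off - n;
        for (int v = 0; v < n; ++v) {
            if (!alive[v]) continue;
            Big &t = F[off + v];
            for (int c = 0; c < sigma; ++c) {
                int u = pred_of(v, c, powkm1, sigma);
                if (alive[u]) t.add(F[offp + u]);
            }
        }
    }
}

static void hitting_from_tables(int n, int ell, const std::vector<char> &alive,
                                const std::vector<Big> &D, const std::vector<Big> &F,
                                std::vector<Big> &T) {
    T.assign(n, Big());
    for (int v = 0; v < n; ++v) {
        if (!alive[v]) continue;
        Big t;
        for (int i = 0; i <= ell; ++i) {
            size_t offF = static_cast<size_t>(i) * n;
            size_t offD = static_cast<size_t>(ell - i) * n;
            if (!F[offF + v].zero() && !D[offD + v].zero())
                t.add(big_mul(F[offF + v], D[offD + v]));
        }
        T[v] = t;
    }
}

// [[Rcpp::export]]
List cpp_bounded_counts(int sigma, int k, LogicalVector alive, int ell) {
    int n = ipow(sigma, k), powkm1 = ipow(sigma, k - 1);
    if (alive.size() != n) stop("alive has wrong length");
    if (ell < 0) stop("ell must be >= 0");
    std::vector<char> a = as_alive(alive);
    std::vector<Big> D, F;
    bounded_D(sigma, n, powkm1, a, ell, D);
    bounded_F(sigma, n, powkm1, a, ell, F);
    CharacterMatrix Dm(n, ell + 1), Fm(n, ell + 1);
    for (int i = 0; i <= ell; ++i) {
        size_t off = static_cast<size_t>(i) * n;
        for (int v = 0; v < n; ++v) {
            Dm(v, i) = big_dec(D[off + v]);
            Fm(v, i) = big_dec(F[off + v]);
        }
    }
    return List::create(_["D"] = Dm, _["F"] = Fm);
}

// [[Rcpp::export]]
CharacterVector cpp_hitting_bounded(int sigma, int k, LogicalVector alive, int ell) {
    int n = ipow(sigma, k), powkm1 = ipow(sigma, k - 1);
    if (alive.size() != n) stop("alive has wrong length");
    if (ell < 0) stop("ell must be >= 0");
    std::vector<char> a = as_alive(alive);
    std::vector<Big> D, F, T;
    bounded_D(sigma, n, powkm1, a, ell, D);
    bounded_F(sigma, n, powkm1, a, ell, F);
    hitting_from_tables(n, ell, a, D, F, T);
    CharacterVector out(n);
    for (int v = 0; v < n; ++v) out[v] = big_dec(T[v]);
    return out;
}

// ---- unbounded (all path lengths) tables --------------------------------

static void unbounded_tables(int sigma, int n, int powkm1, const std::vector<char> &alive,
                             const std::vector<int> &order,
                             std::vector<Big> &F, std::vector<Big> &D, std::vector<Big> &T) {
    F.assign(n, Big());
    D.assign(n, Big());
    T.assign(n, Big());
    for (size_t i = 0; i < order.size(); ++i) {
        int v = order[i];
        Big f(1);
        for (int c = 0; c < sigma; ++c) {
            int u = pred_of(v, c, powkm1, sigma);
            if (alive[u]) f.add(F[u]);
        }
        F[v] = f;
    }
    for (size_t i = order.size(); i-- > 0;) {
        int v = order[i];
        Big d(1);
        for (int c = 0; c < sigma; ++c) {
            int u = succ_of(v, c, powkm1, sigma);
            if (alive[u]) d.add(D[u]);
        }
        D[v] = d;
        T[v] = big_mul(F[v], D[v]);
    }
}

// [[Rcpp::export]]
List cpp_unbounded_counts(int sigma, int k, LogicalVector alive) {
    int n = ipow(sigma, k), powkm1 = ipow(sigma, k - 1);
    if (alive.size() != n) stop("alive has wrong length");
    std::vector<char> a = as_alive(alive);
    std::vector<int> order;
    if (!topo_order(sigma, n, powkm1, a, order))
        stop("residual graph contains a directed cycle");
    std::vector<Big> F, D, T;
    unbounded_tables(sigma, n, powkm1, a, order, F, D, T);
    CharacterVector Fo(n), Do(n), To(n);
    for (int v = 0; v < n; ++v) {
        Fo[v] = big_dec(F[v]);
        Do[v] = big_dec(D[v]);
        To[v] = big_dec(T[v]);
    }
    return List::create(_["F"] = Fo, _["D"] = Do, _["T"] = To);
}

// ---- greedy removal loops -----------------------------------------------

static int longest_path_alive(int sigma, int n, int powkm1, const std::vector<char> &alive) {
    std::vector<int> order;
    if (!topo_order(sigma, n, powkm1, alive, order))
        stop("residual graph contains a directed cycle");
    if (order.empty()) return -1;
    std::vector<int> lp(n, 0);
    int best = 0;
    for (size_t i = 0; i < order.size(); ++i) {
        int v = order[i];
        for (int c = 0; c < sigma; ++c) {
            int u = succ_of(v, c, powkm1, sigma);
            if (alive[u] && lp[v] + 1 > lp[u]) lp[u] = lp[v] + 1;
        }
        if (lp[v] > best) best = lp[v]; // lp final once v is processed
    }
    return best;
}

// l-bounded greedy: while an l-edge path survives, rebuild the bounded
// tables, remove the vertex with the largest hitting number T(v,l)
// (smallest code on ties).
// [[Rcpp::export]]
List cpp_docks_run(int sigma, int k, LogicalVector alive, int ell, int progress_every) {
    int n = ipow(sigma, k), powkm1 = ipow(sigma, k - 1);
    if (alive.size() != n) stop("alive has wrong length");
    if (ell < 1) stop("ell must be >= 1");
    std::vector<char> a = as_alive(alive);
    std::vector<int> removed;
    std::vector<std::string> scores;
    std::vector<Big> D, F, T;
    int iter = 0;
    while (true) {
        int lp = longest_path_alive(sigma, n, powkm1, a);
        if (lp < ell) break;
        bounded_D(sigma, n, powkm1, a, ell, D);
        bounded_F(sigma, n, powkm1, a, ell, F);
        hitting_from_tables(n, ell, a, D, F, T);
        int best = -1;
        for (int v = 0; v < n; ++v) {
            if (!a[v]) continue;
            if (best < 0 || big_cmp(T[v], T[best]) > 0) best = v;
        }
        if (best < 0 || T[best].zero())
            stop("internal error: l-edge path reported but no vertex has positive hitting number");
        a[best] = 0;
        removed.push_back(best);
        scores.push_back(big_dec(T[best]));
        ++iter;
        if (progress_every > 0 && iter % progress_every == 0)
            Rcpp::Rcerr << "removed " << iter << " vertices, longest path " << lp << "\n";
        Rcpp::checkUserInterrupt();
    }
    return List::create(_["removed"] = wrap(removed), _["scores"] = wrap(scores));
}

// L-free greedy: scores are the all-lengths hitting numbers T(v) = F(v)D(v);
// the top X alive vertices are removed per iteration (ties by code), and the
// loop stops once no l-edge path survives.
// [[Rcpp::export]]
List cpp_docksany_run(int sigma, int k, LogicalVector alive, int ell, int X,
                      int progress_every) {
    int n = ipow(sigma, k), powkm1 = ipow(sigma, k - 1);
    if (alive.size() != n) stop("alive has wrong length");
    if (ell < 1) stop("ell must be >= 1");
    if (X < 1) stop("X must be >= 1");
    std::vector<char> a = as_alive(alive);
    std::vector<int> removed;
    std::vector<std::string> scores;
    std::vector<Big> F, D, T;
    std::vector<int> order;
    int iter = 0;
    while (true) {
        if (longest_path_alive(sigma, n, powkm1, a) < ell) break;
        if (!topo_order(sigma, n, powkm1, a, order))
            stop("residual graph contains a directed cycle");
        unbounded_tables(sigma, n, powkm1, a, order, F, D, T);
        // top-X alive vertices by T, ties by smaller code; selection sort over
        // X rounds keeps the tie rule explicit (X is small in practice)
        std::vector<int> cand;
        cand.reserve(order.size());
        for (int v = 0; v < n; ++v)
            if (a[v]) cand.push_back(v);
        int take = std::min<int>(X, cand.size());
        std::partial_sort(cand.begin(), cand.begin() + take, cand.end(),
                          [&T](int x, int y) {
                              int c = big_cmp(T[x], T[y]);
                              return c > 0 || (c == 0 && x < y);
                          });
        for (int i = 0; i < take; ++i) {
            a[cand[i]] = 0;
            removed.push_back(cand[i]);
            scores.push_back(big_dec(T[cand[i]]));
        }
        ++iter;
        if (progress_every > 0 && iter % progress_every == 0)
            Rcpp::Rcerr << "iteration " << iter << ", removed " << removed.size() << "\n";
        Rcpp::checkUserInterrupt();
    }
    return List::create(_["removed"] = wrap(removed), _["scores"] = wrap(scores));
}

// Pure greedy on the full (cyclic) graph: scores are l-edge *walk* counts
// through each vertex; stops when no l-edge walk survives (which implies
// every cycle has been broken).
// [[Rcpp::export]]
List cpp_greedy_baseline_run(int sigma, int k, int ell, int progress_every) {
    int n = ipow(sigma, k), powkm1 = ipow(sigma, k - 1);
    if (ell < 1) stop("ell must be >= 1");
    std::vector<char> a(n, 1);
    std::vector<int> removed;
    std::vector<std::string> scores;
    std::vector<Big> D, F, T;
    int iter = 0;
    while (true) {
        bounded_D(sigma, n, powkm1, a, ell, D); // walk counts on a cyclic graph
        Big total;
        size_t off = static_cast<size_t>(ell) * n;
        for (int v = 0; v < n; ++v)
            if (a[v]) total.add(D[off + v]);
        if (total.zero()) break;
        bounded_F(sigma, n, powkm1, a, ell, F);
        hitting_from_tables(n, ell, a, D, F, T);
        int best = -1;
        for (int v = 0; v < n; ++v) {
            if (!a[v]) continue;
            if (best < 0 || big_cmp(T[v], T[best]) > 0) best = v;
        }
        a[best] = 0;
        removed.push_back(best);
        scores.push_back(big_dec(T[best]));
        ++iter;
        if (progress_every > 0 && iter % progress_every == 0)
            Rcpp::Rcerr << "removed " << iter << " vertices\n";
        Rcpp::checkUserInterrupt();
    }
    return List::create(_["removed"] = wrap(removed), _["scores"] = wrap(scores));
}

// Total number of l-edge walks among alive vertices (cycles permitted):
// the verification statistic, exact.
// [[Rcpp::export]]
String cpp_count_walks(int sigma, int k, LogicalVector alive, int ell) {
    int n = ipow(sigma, k), powkm1 = ipow(sigma, k - 1);
    if (alive.size() != n) stop("alive has wrong length");
    if (ell < 0) stop("ell must be >= 0");
    std::vector<char> a = as_alive(alive);
    std::vector<Big> D;
    bounded_D(sigma, n, powkm1, a, ell, D);
    Big total;
    size_t off = static_cast<size_t>(ell) * n;
    for (int v = 0; v < n; ++v)
        if (a[v]) total.add(D[off + v]);
    return big_dec(total);
}

// Lexicographically smallest l-edge walk over the alive vertices, as vertex
// codes (empty when none exists). Reachability is boolean: reach[v][i] says
// an i-edge walk starts at v; greedily following the smallest viable
// continuation spells the smallest avoiding string.
// [[Rcpp::export]]
IntegerVector cpp_lex_smallest_walk(int sigma, int k, LogicalVector alive, int ell) {
    int n = ipow(sigma, k), powkm1 = ipow(sigma, k - 1);
    if (alive.size() != n) stop("alive has wrong length");
    if (ell < 0) stop("ell must be >= 0");
    std::vector<char> a = as_alive(alive);
    std::vector<char> reach(static_cast<size_t>(n) * (ell + 1), 0);
    for (int v = 0; v < n; ++v) reach[v] = a[v];
    for (int i = 1; i <= ell; ++i) {
        size_t off = static_cast<size_t>(i) * n, offp = off - n;
        for (int v = 0; v < n; ++v) {
            if (!a[v]) continue;
            char r = 0;
            for (int c = 0; c < sigma && !r; ++c) {
                int u = succ_of(v, c, powkm1, sigma);
                if (a[u] && reach[offp + u]) r = 1;
            }
            reach[off + v] = r;
        }
    }
    int start = -1;
    size_t offl = static_cast<size_t>(ell) * n;
    for (int v = 0; v < n; ++v)
        if (a[v] && reach[offl + v]) { start = v; break; }
    if (start < 0) return IntegerVector(0);
    IntegerVector walk(ell + 1);
    walk[0] = start;
    int v = start;
    for (int i = 1; i <= ell; ++i) {
        size_t off = static_cast<size_t>(ell - i) * n;
        int nxt = -1;
        for (int c = 0; c < sigma; ++c) {
            int u = succ_of(v, c, powkm1, sigma);
            if (a[u] && reach[off + u]) { nxt = u; break; }
        }
        if (nxt < 0) stop("internal error: walk reconstruction failed");
        walk[i] = nxt;
        v = nxt;
    }
    return walk;
}

// Enumerate up to max_n l-edge walks among the alive vertices in
// lexicographic order of the spelled string; returns a matrix with one walk
// (as l+1 vertex codes) per row. Used to generate violated covering
// constraints for the exact solver.
// [[Rcpp::export]]
IntegerMatrix cpp_enum_walks(int sigma, int k, LogicalVector alive, int ell,
                             int max_n) {
    int n = ipow(sigma, k), powkm1 = ipow(sigma, k - 1);
    if (alive.size() != n) stop("alive has wrong length");
    if (ell < 0) stop("ell must be >= 0");
    if (max_n < 1) stop("max_n must be >= 1");
    std::vector<char> a = as_alive(alive);
    std::vector<char> reach(static_cast<size_t>(n) * (ell + 1), 0);
    for (int v = 0; v < n; ++v) reach[v] = a[v];
    for (int i = 1; i <= ell; ++i) {
        size_t off = static_cast<size_t>(i) * n, offp = off - n;
        for (int v = 0; v < n; ++v) {
            if (!a[v]) continue;
            char r = 0;
            for (int c = 0; c < sigma && !r; ++c) {
                int u = succ_of(v, c, powkm1, sigma);
                if (a[u] && reach[offp + u]) r = 1;
            }
            reach[off + v] = r;
        }
    }
    std::vector<int> out;
    std::vector<int> walk(ell + 1);
    int found = 0;
    // iterative DFS in lexicographic order
    for (int s = 0; s < n && found < max_n; ++s) {
        if (!a[s] || !reach[static_cast<size_t>(ell) * n + s]) continue;
        walk[0] = s;
        int depth = 0;
        std::vector<int> nextc(ell + 1, 0);
        while (depth >= 0 && found < max_n) {
            if (depth == ell) {
                for (int i = 0; i <= ell; ++i) out.push_back(walk[i]);
                ++found;
                --depth;
                continue;
            }
            bool descended = false;
            for (int c = nextc[depth]; c < sigma; ++c) {
                int u = succ_of(walk[depth], c, powkm1, sigma);
                if (a[u] && reach[static_cast<size_t>(ell - depth - 1) * n + u]) {
                    nextc[depth] = c + 1;
                    walk[depth + 1] = u;
                    nextc[depth + 1] = 0;
                    ++depth;
                    descended = true;
                    break;
                }
            }
            if (!descended) {
                nextc[depth] = 0;
                --depth;
            }
        }
        Rcpp::checkUserInterrupt();
    }
    IntegerMatrix res(found, ell + 1);
    for (int i = 0; i < found; ++i)
        for (int j = 0; j <= ell; ++j) res(i, j) = out[static_cast<size_t>(i) * (ell + 1) + j];
    return res;
}

// Literal enumeration of all sigma^L strings; members flags the k-mer codes
// in the candidate set. Returns the number of avoiding strings and the
// lexicographically smallest one (as 0-based digit values).
// [[Rcpp::export]]
List cpp_exhaustive_avoiding(int sigma, int k, int L, LogicalVector members) {
    int nk = ipow(sigma, k), powkm1 = ipow(sigma, k - 1);
    if (members.size() != nk) stop("members has wrong length");
    if (L < k) stop("L must be >= k");
    double total = std::pow(static_cast<double>(sigma), L);
    if (total > 7.2e7) stop("sigma^L too large for exhaustive enumeration");
    std::vector<char> mem(nk);
    for (int i = 0; i < nk; ++i) mem[i] = members[i] == TRUE;
    std::vector<int> digits(L, 0);
    long long n_avoid = 0;
    IntegerVector witness(0);
    const long long N = static_cast<long long>(total);
    for (long long s = 0; s < N; ++s) {
        // digits track s in base sigma, most significant first (lexicographic)
        int code = 0;
        bool hit = false;
        for (int i = 0; i < L; ++i) {
            code = (i < k) ? code * sigma + digits[i]
                           : (code % powkm1) * sigma + digits[i];
            if (i >= k - 1 && mem[code]) { hit = true; break; }
        }
        if (!hit) {
            if (n_avoid == 0) witness = IntegerVector(digits.begin(), digits.end());
            ++n_avoid;
        }
        for (int i = L - 1; i >= 0; --i) { // odometer increment
            if (++digits[i] < sigma) break;
            digits[i] = 0;
        }
        if ((s & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    }
    return List::create(_["n_avoiding"] = static_cast<double>(n_avoid),
                        _["witness"] = witness);
}

// Deterministic seeded annealing search for the threshold reformulation of
// the minimum UHS problem: assign each (k-1)-mer s a threshold p(s) in
// {0..ell}; the removed k-mers are exactly the edges (s,t) of the
// order-(k-1) de Bruijn graph with p(s) >= p(t), and the objective is their
// count. Returns the best assignment found over n_restarts seeded runs.
// xorshift RNG keeps results identical across platforms.
// [[Rcpp::export]]
List cpp_threshold_search(int sigma, int k, int ell, int n_restarts,
                          int n_iters, int seed) {
    int m = ipow(sigma, k - 1), powkm2 = (k >= 2) ? ipow(sigma, k - 2) : 1;
    if (k < 2) stop("threshold search needs k >= 2");
    int nl = ell + 1;
    std::vector<int> succ(m * sigma), pred(m * sigma);
    for (int s = 0; s < m; ++s)
        for (int c = 0; c < sigma; ++c) {
            succ[s * sigma + c] = (s % powkm2) * sigma + c;
            pred[s * sigma + c] = c * powkm2 + s / sigma;
        }
    std::vector<int> p(m), bestp(m);
    long long bestc = -1;
    uint64_t state = static_cast<uint64_t>(seed) * 2654435761u + 1442695040888963407ull;
    auto rnd = [&state]() {
        state ^= state << 13;
        state ^= state >> 7;
        state ^= state << 17;
        return state;
    };
    for (int run = 0; run < n_restarts; ++run) {
        for (int s = 0; s < m; ++s) p[s] = static_cast<int>(rnd() % nl);
        long long cost = 0;
        for (int s = 0; s < m; ++s)
            for (int c = 0; c < sigma; ++c)
                if (p[s] >= p[succ[s * sigma + c]]) ++cost;
        double T = 2.5;
        const double decay = 1.0 - 5.0 / n_iters;
        for (int it = 0; it < n_iters; ++it) {
            int s = static_cast<int>(rnd() % m);
            int nv = static_cast<int>(rnd() % nl);
            int ov = p[s];
            if (nv == ov) continue;
            long long dc = 0;
            for (int c = 0; c < sigma; ++c) {
                int t = succ[s * sigma + c];
                if (t != s) dc += (nv >= p[t]) - (ov >= p[t]);
                int u = pred[s * sigma + c];
                if (u != s) dc += (p[u] >= nv) - (p[u] >= ov);
            }
            bool accept = dc <= 0;
            if (!accept) {
                double urand = (rnd() >> 11) * (1.0 / 9007199254740992.0);
                accept = urand < std::exp(-dc / T);
            }
            if (accept) {
                p[s] = nv;
                cost += dc;
                if (bestc < 0 || cost < bestc) {
                    bestc = cost;
                    bestp = p;
                }
            }
            T = std::max(T * decay, 0.05);
        }
        Rcpp::checkUserInterrupt();
    }
    return List::create(_["p"] = wrap(bestp), _["cost"] = static_cast<double>(bestc));
}

// Per-window leftmost argmin over a rank vector: the selected position for
// each window of w consecutive ranks, deduplicated across windows.
// rank is a numeric vector (one value per k-mer start position).
// [[Rcpp::export]]
IntegerVector cpp_window_select(NumericVector rank, int w) {
    R_xlen_t m = rank.size();
    if (w < 1) stop("window must be >= 1");
    if (m < w) return IntegerVector(0);
    std::vector<int> sel;
    int last = -1;
    for (R_xlen_t s = 0; s + w <= m; ++s) {
        R_xlen_t best = s;
        for (R_xlen_t i = s + 1; i < s + w; ++i)
            if (rank[i] < rank[best]) best = i; // strict: leftmost tie-break
        if (static_cast<int>(best) != last) {
            sel.push_back(static_cast<int>(best));
            last = static_cast<int>(best);
        }
    }
    // consecutive windows can re-select an earlier position after a newer one
    std::sort(sel.begin(), sel.end());
    sel.erase(std::unique(sel.begin(), sel.end()), sel.end());
    return wrap(sel);
}

// Rolling k-mer codes along a digit sequence (0-based digit values);
// returns one code per start position.
// [[Rcpp::export]]
IntegerVector cpp_rolling_codes(IntegerVector digits, int sigma, int k) {
    R_xlen_t L = digits.size();
    if (L < k) return IntegerVector(0);
    int powkm1 = ipow(sigma, k - 1);
    IntegerVector out(L - k + 1);
    int code = 0;
    for (R_xlen_t i = 0; i < L; ++i) {
        int d = digits[i];
        if (d < 0 || d >= sigma) stop("digit out of range");
        code = (i < k) ? code * sigma + d : (code % powkm1) * sigma + d;
        if (i >= k - 1) out[i - k + 1] = code;
    }
    return out;
}
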