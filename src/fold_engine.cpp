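// Minimum-free-energy engines for intramolecular folding (Zuker-style, with
// hairpin/bulge/internal/multiloop decomposition) and intermolecular duplex
// hybridisation. The parameter vector is produced by par_to_engine() on the
// R side; the exhaustive R scorer defines the model these programs optimise.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

static const double INF = 1e9;

struct Params {
  double stack[6][6];
  double ha, hb, ba, bb, ia, ib;
  double ml_init, ml_branch, ml_unpaired;
  int min_loop, max_interior;
  bool gu;
};

static Params read_params(const NumericVector &p) {
  Params par;
  // stack passed column-major: element (outer=row, inner=col) at row + 6*col
  for (int c = 0; c < 6; ++c)
    for (int r = 0; r < 6; ++r)
      par.stack[r][c] = p[r + 6 * c];
  int k = 36;
  par.ha = p[k++]; par.hb = p[k++];
  par.ba = p[k++]; par.bb = p[k++];
  par.ia = p[k++]; par.ib = p[k++];
  par.ml_init = p[k++]; par.ml_branch = p[k++]; par.ml_unpaired = p[k++];
  par.min_loop = (int) p[k++];
  par.max_interior = (int) p[k++];
  par.gu = p[k++] != 0.0;
  return par;
}

static int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'U': return 3;
    default: return -1;
  }
}

// pair type index in {AU,UA,GC,CG,GU,UG}; -1 if not a pair
static int pair_code(int a, int b, const Params &par) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 1 && b == 2) return 3;
  if (par.gu && a == 2 && b == 3) return 4;
  if (par.gu && a == 3 && b == 2) return 5;
  return -1;
}

static std::vector<int> encode(const std::string &s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    v[i] = base_code(s[i]);
    if (v[i] < 0) stop("invalid RNA alphabet at position %d (expected ACGU)", (int) i + 1);
  }
  return v;
}

static inline double hairpinE(int L, const Params &par) {
  return par.ha + par.hb * (L - par.min_loop);
}

// loop cost between enclosing pair (i,j) and enclosed pair (k,l)
static inline double interiorE(int i, int j, int k, int l,
                               const std::vector<int> &s, int pij, int pkl,
                               const Params &par) {
  int l1 = k - i - 1, l2 = j - l - 1;
  if (l1 == 0 && l2 == 0) return par.stack[pij][pkl];
  if (l1 == 0 || l2 == 0) return par.ba + par.bb * (l1 + l2);
  return par.ia + par.ib * (l1 + l2);
}

// [[Rcpp::export]]
List fold_mfe_cpp(std::string seq, NumericVector param) {
  Params par = read_params(param);
  std::vector<int> s = encode(seq);
  int n = (int) s.size();

  std::vector<std::vector<double> > V(n, std::vector<double>(n, INF));
  std::vector<std::vector<double> > WM(n, std::vector<double>(n, INF));
  std::vector<std::vector<double> > WM2(n, std::vector<double>(n, INF));
  std::vector<std::vector<int> > P(n, std::vector<int>(n, -1)); // pair code cache
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      P[i][j] = pair_code(s[i], s[j], par);

  for (int span = par.min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // --- V(i,j): i pairs j ---
      if (P[i][j] >= 0) {
        double best = hairpinE(j - i - 1, par);
        // interior / stack / bulge
        for (int k = i + 1; k <= j - 1; ++k) {
          if (k - i - 1 > par.max_interior) break;
          for (int l = j - 1; l > k; --l) {
            int tot = (k - i - 1) + (j - l - 1);
            if (tot > par.max_interior) break;
            if (P[k][l] < 0 || V[k][l] >= INF) continue;
            double e = interiorE(i, j, k, l, s, P[i][j], P[k][l], par) + V[k][l];
            if (e < best) best = e;
          }
        }
        // multiloop
        if (j - i - 1 >= 2 * (par.min_loop + 2)) {
          double m = WM2[i + 1][j - 1];
          if (m < INF) {
            double e = par.ml_init + par.ml_branch + m;
            if (e < best) best = e;
          }
        }
        V[i][j] = best;
      }
      // --- WM(i,j): >=1 multiloop branch in [i,j] ---
      {
        double best = INF;
        if (j > i && WM[i][j - 1] < INF) best = WM[i][j - 1] + par.ml_unpaired;
        for (int k = i; k <= j - par.min_loop - 1; ++k) {
          if (V[k][j] >= INF) continue;
          double lead = (k == i) ? 0.0
            : std::min(WM[i][k - 1], par.ml_unpaired * (k - i));
          if (lead >= INF) continue;
          double e = lead + V[k][j] + par.ml_branch;
          if (e < best) best = e;
        }
        WM[i][j] = best;
      }
      // --- WM2(i,j): >=2 branches ---
      {
        double best = INF;
        if (j > i && WM2[i][j - 1] < INF) best = WM2[i][j - 1] + par.ml_unpaired;
        for (int k = i + 1; k <= j - par.min_loop - 1; ++k) {
          if (V[k][j] >= INF || WM[i][k - 1] >= INF) continue;
          double e = WM[i][k - 1] + V[k][j] + par.ml_branch;
          if (e < best) best = e;
        }
        WM2[i][j] = best;
      }
    }
  }

  // external loop
  std::vector<double> W(n + 1, 0.0); // W[j+1] = best over prefix [0..j]
  for (int j = 0; j < n; ++j) {
    double best = W[j]; // j unpaired
    for (int k = 0; k <= j - par.min_loop - 1; ++k) {
      if (V[k][j] >= INF) continue;
      double e = W[k] + V[k][j];
      if (e < best) best = e;
    }
    W[j + 1] = best;
  }

  // traceback (deterministic: fixed candidate scan order)
  std::vector<std::pair<int,int> > pairs;
  const double EPS = 1e-7;
  struct Frame { int i, j, kind; }; // kind 0=ext,1=V,2=WM,3=WM2
  std::vector<Frame> stk;
  stk.push_back({0, n - 1, 0});
  while (!stk.empty()) {
    Frame f = stk.back(); stk.pop_back();
    if (f.kind == 0) {
      int j = f.j;
      while (j >= f.i) {
        bool found = false;
        for (int k = f.i; k <= j - par.min_loop - 1; ++k) {
          if (V[k][j] < INF && std::abs(W[k] + V[k][j] - W[j + 1]) < EPS) {
            stk.push_back({k, j, 1});
            j = k - 1;
            found = true;
            break;
          }
        }
        if (!found) --j; // j unpaired
      }
    } else if (f.kind == 1) {
      int i = f.i, j = f.j;
      pairs.push_back(std::make_pair(i, j));
      double target = V[i][j];
      bool done = false;
      for (int k = i + 1; k <= j - 1 && !done; ++k) {
        if (k - i - 1 > par.max_interior) break;
        for (int l = j - 1; l > k; --l) {
          int tot = (k - i - 1) + (j - l - 1);
          if (tot > par.max_interior) break;
          if (P[k][l] < 0 || V[k][l] >= INF) continue;
          if (std::abs(interiorE(i, j, k, l, s, P[i][j], P[k][l], par) + V[k][l]
                       - target) < EPS) {
            stk.push_back({k, l, 1});
            done = true;
            break;
          }
        }
      }
      if (!done && j - i - 1 >= 2 * (par.min_loop + 2) && WM2[i + 1][j - 1] < INF &&
          std::abs(par.ml_init + par.ml_branch + WM2[i + 1][j - 1] - target) < EPS) {
        stk.push_back({i + 1, j - 1, 3});
        done = true;
      }
      // otherwise hairpin: nothing to trace
    } else if (f.kind == 2 || f.kind == 3) {
      int i = f.i, j = f.j, kind = f.kind;
      while (j >= i) {
        const std::vector<std::vector<double> > &M = (kind == 2) ? WM : WM2;
        double target = M[i][j];
        if (j > i && M[i][j - 1] < INF &&
            std::abs(M[i][j - 1] + par.ml_unpaired - target) < EPS) {
          --j;
          continue;
        }
        bool found = false;
        int kmin = (kind == 3) ? i + 1 : i;
        for (int k = kmin; k <= j - par.min_loop - 1; ++k) {
          if (V[k][j] >= INF) continue;
          double lead;
          if (kind == 3) {
            lead = WM[i][k - 1];
          } else {
            lead = (k == i) ? 0.0
              : std::min(WM[i][k - 1], par.ml_unpaired * (k - i));
          }
          if (lead >= INF) continue;
          if (std::abs(lead + V[k][j] + par.ml_branch - target) < EPS) {
            stk.push_back({k, j, 1});
            if (k > i) {
              if (kind == 3) {
                // remaining region holds >=1 branch
                kind = 2; j = k - 1;
              } else if (std::abs(WM[i][k - 1] - lead) < EPS && WM[i][k - 1] < INF &&
                         !(std::abs(par.ml_unpaired * (k - i) - lead) < EPS)) {
                kind = 2; j = k - 1;
              } else if (std::abs(par.ml_unpaired * (k - i) - lead) < EPS) {
                j = i - 1; // all unpaired
              } else {
                kind = 2; j = k - 1;
              }
            } else {
              j = i - 1;
            }
            found = true;
            break;
          }
        }
        if (!found) break; // should not happen
      }
    }
  }

  IntegerMatrix pm(pairs.size(), 2);
  for (size_t k = 0; k < pairs.size(); ++k) {
    pm(k, 0) = pairs[k].first;
    pm(k, 1) = pairs[k].second;
  }
  return List::create(_["energy"] = W[n], _["pairs"] = pm);
}

// ---------------------------------------------------------------------------
// Intermolecular duplex: x (5'->3') against y (5'->3'), antiparallel pairing,
// intramolecular structure forbidden. No initiation term: a lone pair scores
// 0; consecutive pairs add stacking or affine bulge/internal penalties.

// [[Rcpp::export]]
List duplex_mfe_cpp(std::string xs, std::string ys, NumericVector param) {
  Params par = read_params(param);
  std::vector<int> x = encode(xs), y = encode(ys);
  int n = (int) x.size(), m = (int) y.size();

  // H(i,j): best energy of a duplex whose last (largest i, smallest j) pair
  // is x_i : y_j
  std::vector<std::vector<double> > H(n, std::vector<double>(m, INF));
  double best = 0.0; int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = m - 1; j >= 0; --j) {
      int pij = pair_code(x[i], y[j], par);
      if (pij < 0) continue;
      double h = 0.0; // duplex starting at this pair
      for (int k = i - 1; k >= 0; --k) {
        int a = i - k - 1;
        if (a > par.max_interior) break;
        for (int l = j + 1; l < m; ++l) {
          int b = l - j - 1;
          if (b > par.max_interior) break;
          int pkl = pair_code(x[k], y[l], par);
          if (pkl < 0 || H[k][l] >= INF) continue;
          double cost;
          if (a == 0 && b == 0) cost = par.stack[pkl][pij];
          else if (a == 0 || b == 0) cost = par.ba + par.bb * (a + b);
          else cost = par.ia + par.ib * (a + b);
          double e = H[k][l] + cost;
          if (e < h) h = e;
        }
      }
      H[i][j] = h;
      if (h < best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback
  std::vector<std::pair<int,int> > pairs;
  const double EPS = 1e-7;
  int i = bi, j = bj;
  while (i >= 0) {
    pairs.push_back(std::make_pair(i, j));
    double target = H[i][j];
    if (std::abs(target) < EPS) break; // chain start
    int pij = pair_code(x[i], y[j], par);
    bool found = false;
    for (int k = i - 1; k >= 0 && !found; --k) {
      int a = i - k - 1;
      if (a > par.max_interior) break;
      for (int l = j + 1; l < m; ++l) {
        int b = l - j - 1;
        if (b > par.max_interior) break;
        int pkl = pair_code(x[k], y[l], par);
        if (pkl < 0 || H[k][l] >= INF) continue;
        double cost;
        if (a == 0 && b == 0) cost = par.stack[pkl][pij];
        else if (a == 0 || b == 0) cost = par.ba + par.bb * (a + b);
        else cost = par.ia + par.ib * (a + b);
        if (std::abs(H[k][l] + cost - target) < EPS) {
          i = k; j = l; found = true; break;
        }
      }
    }
    if (!found) break;
  }

  std::reverse(pairs.begin(), pairs.end());
  IntegerMatrix pm(pairs.size() * (bi >= 0 ? 1 : 0), 2);
  if (bi >= 0) {
    for (size_t k = 0; k < pairs.size(); ++k) {
      pm(k, 0) = pairs[k].first;
      pm(k, 1) = pairs[k].second;
    }
  }
  return List::create(_["energy"] = best, _["pairs"] = pm);
}
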