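// Minimum-free-energy folding of single-stranded DNA under a
// nearest-neighbor model: Watson-Crick pairs only, tabulated
// hairpin/bulge/internal loop penalties, affine multibranch loops,
// optional no-lonely-pair constraint (helices of length >= 2).
//
// Decomposition: C(i,j) is the MFE of the region [i,j] closed by the
// pair (i,j), where (i,j) starts a helix of length >= hmin that is
// enumerated explicitly and terminated by a hairpin, an interior
// (bulge/internal) loop leading to an inner C, or a multibranch loop
// (WM2 = >= 2 branches, WM = >= 1 branch; unpaired multiloop bases are
// free, branches cost ml_branch, closing a multiloop costs
// ml_init + ml_branch).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

const double BIG = 1e9;
const double EPS = 1e-7;

struct EnergyPar {
  double stack[4][4];            // dG for 5'-x1 x2-3' stacked on WC partners
  std::vector<double> hairpin;   // loop size 1..30 (Inf where disallowed)
  std::vector<double> bulge;
  std::vector<double> interior;
  double extrap;                 // long-loop term: tab[30] + extrap*log(s/30)
  double ml_init, ml_branch;
  int min_hairpin;
  int max_interior;              // cap on l1+l2 for interior/bulge search
  bool no_lonely;
};

inline bool wc(int a, int b) { return a >= 0 && a <= 3 && b >= 0 && b <= 3 && a + b == 3; }

inline double loop_tab(const std::vector<double>& tab, double extrap, int s) {
  if (s <= 0) return BIG;
  int m = (int)tab.size();
  if (s <= m) return tab[s - 1];
  return tab[m - 1] + extrap * std::log((double)s / (double)m);
}

struct Folder {
  std::vector<int> s;
  std::vector<bool> mask;  // true = position may not pair
  EnergyPar par;
  int n;
  std::vector<double> C, WM, WM2, W;

  inline double& cC(int i, int j) { return C[(size_t)i * n + j]; }
  inline double& cWM(int i, int j) { return WM[(size_t)i * n + j]; }
  inline double& cWM2(int i, int j) { return WM2[(size_t)i * n + j]; }

  bool pairable(int i, int j) const {
    return !mask[i] && !mask[j] && wc(s[i], s[j]) && (j - i - 1) >= par.min_hairpin;
  }
  double hp(int sz) const { return loop_tab(par.hairpin, par.extrap, sz); }
  double interior_pen(int l1, int l2) const {
    int sz = l1 + l2;
    if (l1 == 0 || l2 == 0) return loop_tab(par.bulge, par.extrap, sz);
    return loop_tab(par.interior, par.extrap, sz);
  }

  void run() {
    C.assign((size_t)n * n, BIG);
    WM.assign((size_t)n * n, BIG);
    WM2.assign((size_t)n * n, BIG);
    int hmin = par.no_lonely ? 2 : 1;
    for (int d = par.min_hairpin + 1; d < n; ++d) {
      for (int i = 0; i + d < n; ++i) {
        int j = i + d;
        double best = BIG;
        if (pairable(i, j)) {
          double S = 0.0;
          for (int h = 1;; ++h) {
            int p = i + h - 1, q = j - h + 1;
            if (h >= hmin) {
              int hs = q - p - 1;
              if (hs >= par.min_hairpin) {
                double e = S + hp(hs);
                if (e < best) best = e;
              }
              for (int p2 = p + 1; p2 <= q - 2; ++p2) {
                int l1 = p2 - p - 1;
                if (l1 > par.max_interior) break;
                int l2max = par.max_interior - l1;
                int q2lo = q - 1 - l2max;
                if (q2lo < p2 + 1) q2lo = p2 + 1;
                for (int q2 = q - 1; q2 >= q2lo; --q2) {
                  int l2 = q - q2 - 1;
                  if (l1 + l2 == 0) continue;  // pure stack: handled by h loop
                  double cin = cC(p2, q2);
                  if (cin >= BIG / 2) continue;
                  double e = S + interior_pen(l1, l2) + cin;
                  if (e < best) best = e;
                }
              }
              if (q - 1 >= p + 1) {
                double m = cWM2(p + 1, q - 1);
                if (m < BIG / 2) {
                  double e = S + par.ml_init + par.ml_branch + m;
                  if (e < best) best = e;
                }
              }
            }
            int p3 = i + h, q3 = j - h;
            if (p3 >= q3 || !pairable(p3, q3)) break;
            S += par.stack[s[p]][s[p3]];
          }
        }
        cC(i, j) = best;

        double wmbest = (i + 1 <= j) ? cWM(i + 1, j) : BIG;
        double wm2best = (i + 1 <= j) ? cWM2(i + 1, j) : BIG;
        for (int j2 = i + 1; j2 <= j; ++j2) {
          double ci = cC(i, j2);
          if (ci >= BIG / 2) continue;
          double one = par.ml_branch + ci;
          double rest0 = 0.0;
          if (j2 < j) {
            double wmr = cWM(j2 + 1, j);
            if (wmr < BIG / 2) {
              if (wmr < rest0) rest0 = wmr;  // trailing region: empty or >=1 branch
              if (one + wmr < wm2best) wm2best = one + wmr;
            }
          }
          if (one + rest0 < wmbest) wmbest = one + rest0;
        }
        cWM(i, j) = wmbest;
        cWM2(i, j) = wm2best;
      }
    }
  }

  double external() {
    W.assign(n, 0.0);
    for (int j = 0; j < n; ++j) {
      double best = (j > 0) ? W[j - 1] : 0.0;
      for (int i = 0; i <= j; ++i) {
        double ci = cC(i, j);
        if (ci >= BIG / 2) continue;
        double left = (i > 0) ? W[i - 1] : 0.0;
        if (left + ci < best) best = left + ci;
      }
      W[j] = best;
    }
    return (n > 0 && W[n - 1] < 0.0) ? W[n - 1] : 0.0;
  }

  // ---- traceback -------------------------------------------------------

  void trace_C(int i, int j, std::vector<int>& pr) {
    int hmin = par.no_lonely ? 2 : 1;
    double target = cC(i, j);
    double S = 0.0;
    for (int h = 1;; ++h) {
      int p = i + h - 1, q = j - h + 1;
      if (h >= hmin) {
        int hs = q - p - 1;
        if (hs >= par.min_hairpin && std::fabs(S + hp(hs) - target) < EPS) {
          set_helix(i, j, h, pr);
          return;
        }
        for (int p2 = p + 1; p2 <= q - 2; ++p2) {
          int l1 = p2 - p - 1;
          if (l1 > par.max_interior) break;
          int l2max = par.max_interior - l1;
          int q2lo = q - 1 - l2max;
          if (q2lo < p2 + 1) q2lo = p2 + 1;
          for (int q2 = q - 1; q2 >= q2lo; --q2) {
            int l2 = q - q2 - 1;
            if (l1 + l2 == 0) continue;
            double cin = cC(p2, q2);
            if (cin >= BIG / 2) continue;
            if (std::fabs(S + interior_pen(l1, l2) + cin - target) < EPS) {
              set_helix(i, j, h, pr);
              trace_C(p2, q2, pr);
              return;
            }
          }
        }
        if (q - 1 >= p + 1) {
          double m = cWM2(p + 1, q - 1);
          if (m < BIG / 2 &&
              std::fabs(S + par.ml_init + par.ml_branch + m - target) < EPS) {
            set_helix(i, j, h, pr);
            trace_WM2(p + 1, q - 1, pr);
            return;
          }
        }
      }
      int p3 = i + h, q3 = j - h;
      if (p3 >= q3 || !pairable(p3, q3)) break;
      S += par.stack[s[p]][s[p3]];
    }
    stop("internal error: traceback failed in C(%d,%d)", i, j);
  }

  void set_helix(int i, int j, int h, std::vector<int>& pr) {
    for (int k = 0; k < h; ++k) {
      pr[i + k] = j - k;
      pr[j - k] = i + k;
    }
  }

  void trace_WM(int i, int j, std::vector<int>& pr) {
    double t = cWM(i, j);
    if (i + 1 <= j && std::fabs(cWM(i + 1, j) - t) < EPS) {
      trace_WM(i + 1, j, pr);
      return;
    }
    for (int j2 = i + 1; j2 <= j; ++j2) {
      double ci = cC(i, j2);
      if (ci >= BIG / 2) continue;
      double one = par.ml_branch + ci;
      if (std::fabs(one - t) < EPS) {
        trace_C(i, j2, pr);
        return;
      }
      if (j2 < j) {
        double wmr = cWM(j2 + 1, j);
        if (wmr < BIG / 2 && std::fabs(one + wmr - t) < EPS) {
          trace_C(i, j2, pr);
          trace_WM(j2 + 1, j, pr);
          return;
        }
      }
    }
    stop("internal error: traceback failed in WM(%d,%d)", i, j);
  }

  void trace_WM2(int i, int j, std::vector<int>& pr) {
    double t = cWM2(i, j);
    if (i + 1 <= j && std::fabs(cWM2(i + 1, j) - t) < EPS) {
      trace_WM2(i + 1, j, pr);
      return;
    }
    for (int j2 = i + 1; j2 < j; ++j2) {
      double ci = cC(i, j2);
      if (ci >= BIG / 2) continue;
      double wmr = cWM(j2 + 1, j);
      if (wmr >= BIG / 2) continue;
      if (std::fabs(par.ml_branch + ci + wmr - t) < EPS) {
        trace_C(i, j2, pr);
        trace_WM(j2 + 1, j, pr);
        return;
      }
    }
    stop("internal error: traceback failed in WM2(%d,%d)", i, j);
  }

  std::vector<int> trace_external(double mfe) {
    std::vector<int> pr(n, -1);
    if (mfe >= 0.0) return pr;  // all unpaired
    int j = n - 1;
    while (j >= 0) {
      if (std::fabs(W[j]) < EPS) break;
      if (j > 0 && std::fabs(W[j] - W[j - 1]) < EPS) {
        --j;
        continue;
      }
      bool found = false;
      for (int i = 0; i <= j; ++i) {
        double ci = cC(i, j);
        if (ci >= BIG / 2) continue;
        double left = (i > 0) ? W[i - 1] : 0.0;
        if (std::fabs(left + ci - W[j]) < EPS) {
          trace_C(i, j, pr);
          j = i - 1;
          found = true;
          break;
        }
      }
      if (!found) stop("internal error: traceback failed in external loop");
    }
    return pr;
  }
};

EnergyPar make_par(List par) {
  EnergyPar p;
  NumericMatrix st = par["stack"];
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) p.stack[a][b] = st(a, b);
  p.hairpin = as<std::vector<double> >(par["hairpin"]);
  p.bulge = as<std::vector<double> >(par["bulge"]);
  p.interior = as<std::vector<double> >(par["interior"]);
  p.extrap = as<double>(par["extrap"]);
  p.ml_init = as<double>(par["ml_init"]);
  p.ml_branch = as<double>(par["ml_branch"]);
  p.min_hairpin = as<int>(par["min_hairpin"]);
  p.max_interior = as<int>(par["max_interior"]);
  p.no_lonely = as<bool>(par["no_lonely"]);
  return p;
}

}  // namespace

// [[Rcpp::export(name = ".fold_one_cpp")]]
List fold_one_cpp(IntegerVector seq, LogicalVector mask, List par) {
  Folder f;
  f.s = as<std::vector<int> >(seq);
  f.mask = as<std::vector<bool> >(mask);
  f.par = make_par(par);
  f.n = (int)f.s.size();
  f.run();
  double mfe = f.external();
  std::vector<int> pr = f.trace_external(mfe);
  IntegerVector pairing(f.n);
  for (int k = 0; k < f.n; ++k) pairing[k] = pr[k] < 0 ? NA_INTEGER : pr[k] + 1;
  return List::create(_["delta_g"] = mfe, _["pairing"] = pairing);
}

// Energies for a batch of fixed-width windows over one integer-coded
// sequence (codes 0..3 = ACGT, anything else = ambiguous -> NA).
// starts are 0-based.
// [[Rcpp::export(name = ".fold_windows_cpp")]]
NumericVector fold_windows_cpp(IntegerVector seq, IntegerVector starts,
                               int window, List par) {
  EnergyPar ep = make_par(par);
  int nw = starts.size();
  NumericVector out(nw);
  Folder f;
  f.par = ep;
  f.n = window;
  f.mask.assign(window, false);
  std::vector<int> s(window);
  for (int w = 0; w < nw; ++w) {
    int st = starts[w];
    if (st < 0 || st + window > seq.size())
      stop("window out of sequence bounds");
    bool ok = true;
    for (int k = 0; k < window; ++k) {
      s[k] = seq[st + k];
      if (s[k] < 0 || s[k] > 3) ok = false;
    }
    if (!ok) {
      out[w] = NA_REAL;
      continue;
    }
    f.s = s;
    f.run();
    out[w] = f.external();
  }
  return out;
}
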