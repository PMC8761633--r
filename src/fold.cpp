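#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Minimum-free-energy folding of a single RNA over nested structures.
// Energies are integer centi-kcal/mol throughout so optima and ties are exact.
// Tie-break among co-optimal structures: maximum pair count, then
// lexicographically smallest dot-bracket ('(' < ')' < '.').

namespace {

const int INF = 1000000000;

struct Cell {
  int e;
  int p;
  std::string s;
  Cell() : e(INF), p(0) {}
};

inline bool better(int e, int p, const std::string &s, const Cell &b) {
  if (e != b.e) return e < b.e;
  if (p != b.p) return p > b.p;
  return s < b.s;
}

inline std::string dots(int n) { return std::string(n, '.'); }

}  // namespace

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(IntegerVector seq, IntegerMatrix pairtype, IntegerMatrix stack,
                  IntegerVector hairpinP, IntegerVector bulgeP,
                  IntegerVector internalP, int ml_offset, int ml_branch,
                  int ml_unpaired, int min_hairpin, int max_interior) {
  const int n = seq.size();
  std::vector<Cell> V((size_t)n * n), WM((size_t)n * n);
  auto at = [n](std::vector<Cell> &M, int i, int j) -> Cell & {
    return M[(size_t)i * n + j];
  };
  auto pt = [&](int i, int j) { return pairtype(seq[i], seq[j]); };
  // loop penalty lookup; tables are pre-extended in R to cover all sizes used
  auto hp = [&](int sz) { return hairpinP[sz - 1]; };
  auto bu = [&](int sz) { return bulgeP[sz - 1]; };
  auto il = [&](int sz) { return internalP[sz - 1]; };

  for (int w = min_hairpin + 1; w < n; ++w) {
    for (int i = 0; i + w < n; ++i) {
      const int j = i + w;

      // ---- V(i,j): best structure with (i,j) paired ----
      if (pt(i, j) >= 0) {
        Cell best;
        // hairpin closure
        {
          int e = hp(j - i - 1);
          std::string s = "(" + dots(j - i - 1) + ")";
          if (better(e, 1, s, best)) { best.e = e; best.p = 1; best.s = s; }
        }
        // stack / bulge / internal closure with inner pair (k,l)
        for (int k = i + 1; k <= j - 2 && (k - i - 1) <= max_interior; ++k) {
          const int n1 = k - i - 1;
          const int lmin0 = k + min_hairpin + 1;
          const int lmin1 = j - 1 - (max_interior - n1);
          for (int l = std::max(lmin0, lmin1); l <= j - 1; ++l) {
            if (l == j && n1 == 0) continue;  // that is (i,j) itself
            Cell &in = at(V, k, l);
            if (in.e >= INF) continue;
            const int n2 = j - l - 1;
            if (n1 == 0 && n2 == 0 && k == i + 1 && l == j - 1) {
              int e = in.e + stack(pt(i, j), pt(k, l));
              if (e < best.e ||
                  (e == best.e && (in.p + 1 > best.p ||
                                   (in.p + 1 == best.p)))) {
                std::string s = "(" + in.s + ")";
                if (better(e, in.p + 1, s, best)) {
                  best.e = e; best.p = in.p + 1; best.s = s;
                }
              }
            } else if (n1 == 0 || n2 == 0) {
              int e = in.e + bu(n1 + n2);
              if (e < best.e || (e == best.e && in.p + 1 >= best.p)) {
                std::string s = "(" + dots(n1) + in.s + dots(n2) + ")";
                if (better(e, in.p + 1, s, best)) {
                  best.e = e; best.p = in.p + 1; best.s = s;
                }
              }
            } else {
              int e = in.e + il(n1 + n2);
              if (e < best.e || (e == best.e && in.p + 1 >= best.p)) {
                std::string s = "(" + dots(n1) + in.s + dots(n2) + ")";
                if (better(e, in.p + 1, s, best)) {
                  best.e = e; best.p = in.p + 1; best.s = s;
                }
              }
            }
          }
        }
        // multiloop closure: >= 2 branches inside
        for (int m = i + 2; m <= j - 3; ++m) {
          Cell &a = at(WM, i + 1, m);
          Cell &b = at(WM, m + 1, j - 1);
          if (a.e >= INF || b.e >= INF) continue;
          int e = ml_offset + ml_branch + a.e + b.e;
          int p = a.p + b.p + 1;
          if (e < best.e || (e == best.e && p >= best.p)) {
            std::string s = "(" + a.s + b.s + ")";
            if (better(e, p, s, best)) { best.e = e; best.p = p; best.s = s; }
          }
        }
        at(V, i, j) = best;
      }

      // ---- WM(i,j): multiloop interior segment with >= 1 branch ----
      {
        Cell best;
        if (j > i) {
          Cell &a = at(WM, i, j - 1);
          if (a.e < INF) {
            int e = a.e + ml_unpaired;
            std::string s = a.s + ".";
            if (better(e, a.p, s, best)) { best.e = e; best.p = a.p; best.s = s; }
          }
        }
        for (int k = i; k <= j; ++k) {
          Cell &v = at(V, k, j);
          if (v.e >= INF) continue;
          // (k,j) is the only branch, prefix unpaired
          int e = v.e + ml_branch + ml_unpaired * (k - i);
          if (e < best.e || (e == best.e && v.p + 0 >= best.p)) {
            std::string s = dots(k - i) + v.s;
            if (better(e, v.p, s, best)) { best.e = e; best.p = v.p; best.s = s; }
          }
          // branches before k as well
          if (k > i) {
            Cell &w = at(WM, i, k - 1);
            if (w.e < INF) {
              int e2 = w.e + v.e + ml_branch;
              int p2 = w.p + v.p;
              if (e2 < best.e || (e2 == best.e && p2 >= best.p)) {
                std::string s = w.s + v.s;
                if (better(e2, p2, s, best)) { best.e = e2; best.p = p2; best.s = s; }
              }
            }
          }
        }
        at(WM, i, j) = best;
      }
    }
  }

  // ---- exterior loop over prefixes ----
  std::vector<Cell> W(n);
  for (int j = 0; j < n; ++j) {
    Cell best;
    {  // j unpaired
      int e = (j == 0) ? 0 : W[j - 1].e;
      int p = (j == 0) ? 0 : W[j - 1].p;
      std::string s = ((j == 0) ? std::string() : W[j - 1].s) + ".";
      best.e = e; best.p = p; best.s = s;
    }
    for (int k = 0; k <= j - min_hairpin - 1; ++k) {
      Cell &v = at(V, k, j);
      if (v.e >= INF) continue;
      int e = (k == 0 ? 0 : W[k - 1].e) + v.e;
      int p = (k == 0 ? 0 : W[k - 1].p) + v.p;
      if (e < best.e || (e == best.e && p >= best.p)) {
        std::string s = (k == 0 ? std::string() : W[k - 1].s) + v.s;
        if (better(e, p, s, best)) { best.e = e; best.p = p; best.s = s; }
      }
    }
    W[j] = best;
  }

  // the open chain (energy 0) is always admissible; never report > 0
  Cell &fin = W[n - 1];
  if (fin.e > 0) {
    return List::create(_["dotbracket"] = dots(n), _["e_centi"] = 0,
                        _["n_pairs"] = 0);
  }
  return List::create(_["dotbracket"] = fin.s, _["e_centi"] = fin.e,
                      _["n_pairs"] = fin.p);
}
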