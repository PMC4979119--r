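#include <Rcpp.h>
#include <vector>
#include <string>
#include <stack>
#include <array>
#include <cmath>
using namespace Rcpp;

// Minimum-free-energy secondary structure by dynamic programming over a
// nearest-neighbor model: Turner-style stacking energies plus hairpin,
// bulge, interior and multibranch loop penalties (kcal/mol, 37C).
// Admissible pairs: AU/UA, CG/GC, GU/UG (T treated as U). Minimum hairpin
// loop: 3 nt; interior/bulge loops limited to MAXLOOP unpaired bases.
// The all-unpaired structure scores 0, so the MFE is never positive.

static const int NPAIR = 6; // AU CG GC UA GU UG
static const double INF_E = 1e9;
static const int MINLOOP = 3;
static const int MAXLOOP = 20;
static const double MULTI_PEN = 3.4; // multibranch closing penalty

static inline int baseIdx(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1;
  }
}

// pair index for bases (5' base, 3' base); -1 if not admissible
static inline int pairIdx(int a, int b) {
  if (a == 0 && b == 3) return 0; // AU
  if (a == 1 && b == 2) return 1; // CG
  if (a == 2 && b == 1) return 2; // GC
  if (a == 3 && b == 0) return 3; // UA
  if (a == 2 && b == 3) return 4; // GU
  if (a == 3 && b == 2) return 5; // UG
  return -1;
}

// Watson-Crick stacking free energies (Turner/Xia nearest-neighbor set);
// wobble-containing stacks use representative values by context.
static double stackTable[NPAIR][NPAIR];
static bool stackInit = false;

static inline bool isWobble(int p) { return p >= 4; }

static void initStacks() {
  if (stackInit) return;
  for (int i = 0; i < NPAIR; ++i)
    for (int j = 0; j < NPAIR; ++j)
      stackTable[i][j] = 0.0;
  // indices: AU=0 CG=1 GC=2 UA=3 GU=4 UG=5
  stackTable[0][0] = -0.93; // 5'AA3'/3'UU5'
  stackTable[0][3] = -1.10; // AU/UA
  stackTable[3][0] = -1.33; // UA/AU
  stackTable[3][3] = -0.93;
  stackTable[1][0] = -2.11; // CA/GU
  stackTable[1][3] = -2.08; // CU/GA
  stackTable[2][0] = -2.35; // GA/CU
  stackTable[2][3] = -2.24; // GU/CA
  stackTable[0][1] = -2.24;
  stackTable[0][2] = -2.08;
  stackTable[3][1] = -2.35;
  stackTable[3][2] = -2.11;
  stackTable[1][1] = -3.26; // CC/GG
  stackTable[1][2] = -2.36; // CG/GC
  stackTable[2][1] = -3.42; // GC/CG
  stackTable[2][2] = -3.26; // GG/CC
  // stacks involving a G:U wobble are weak; tandem wobbles are on average
  // destabilizing in the nearest-neighbor measurements
  for (int i = 0; i < NPAIR; ++i) {
    for (int j = 0; j < NPAIR; ++j) {
      if (!isWobble(i) && !isWobble(j)) continue;
      bool otherGC = (!isWobble(i) && (i == 1 || i == 2)) ||
                     (!isWobble(j) && (j == 1 || j == 2));
      if (isWobble(i) && isWobble(j)) stackTable[i][j] = 0.5;
      else if (otherGC) stackTable[i][j] = -1.0;
      else stackTable[i][j] = -0.5;
    }
  }
  stackInit = true;
}

// loop penalties: anchor values with logarithmic size extrapolation
static inline double hairpinE(int n) {
  if (n <= 3) return 5.4;
  if (n == 4) return 5.6;
  if (n == 5) return 5.7;
  return 5.7 + 1.75 * 0.616 * std::log((double) n / 5.0);
}

static inline double interiorE(int n1, int n2) {
  int n = n1 + n2;
  if (n1 == 0 || n2 == 0) { // bulge
    if (n == 1) return 3.8;
    return 3.8 + 1.75 * 0.616 * std::log((double) n);
  }
  double base = (n <= 2) ? 1.5 : 2.0;
  double asym = 0.5 * std::abs(n1 - n2);
  if (n > 4) base += 1.75 * 0.616 * std::log((double) n / 4.0);
  return base + asym;
}

// [[Rcpp::export(name = ".fold_stack_cpp")]]
List fold_stack_cpp(std::string seq) {
  initStacks();
  const int n = (int) seq.size();
  if (n < 1) stop("empty sequence");
  if (n > 5000) stop("sequence too long to fold (> 5000 nt)");
  std::vector<int> b(n);
  for (int i = 0; i < n; ++i) b[i] = baseIdx(seq[i]);

  // W[i][j]: best energy on i..j; V[i][j]: best with (i,j) paired
  std::vector<std::vector<double> > W(n, std::vector<double>(n, 0.0));
  std::vector<std::vector<double> > V(n, std::vector<double>(n, INF_E));

  for (int len = MINLOOP + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int pij = (b[i] >= 0 && b[j] >= 0) ? pairIdx(b[i], b[j]) : -1;
      if (pij >= 0) {
        double v = hairpinE(j - i - 1);
        // stacked or interior/bulge continuation onto an inner pair (k,l)
        for (int k = i + 1; k <= std::min(j - 2, i + MAXLOOP + 1); ++k) {
          for (int l = j - 1; l >= k + MINLOOP + 1; --l) {
            int n1 = k - i - 1, n2 = j - l - 1;
            if (n1 + n2 > MAXLOOP) break;
            if (V[k][l] >= INF_E / 2) continue;
            int pin = pairIdx(b[k], b[l]);
            if (pin < 0) continue;
            double e;
            if (n1 == 0 && n2 == 0) e = V[k][l] + stackTable[pij][pin];
            else e = V[k][l] + interiorE(n1, n2);
            if (e < v) v = e;
          }
        }
        // multibranch interior: anything inside, flat closing penalty
        double m = W[i + 1][j - 1] + MULTI_PEN;
        if (m < v) v = m;
        V[i][j] = v;
      }
      double w = W[i + 1][j];
      if (W[i][j - 1] < w) w = W[i][j - 1];
      if (pij >= 0 && V[i][j] < w) w = V[i][j];
      for (int k = i; k < j; ++k) {
        double s = W[i][k] + W[k + 1][j];
        if (s < w) w = s;
      }
      W[i][j] = w;
    }
  }

  // traceback
  std::string db(n, '.');
  std::stack<std::array<int, 3> > st; // i, j, inV(0/1)
  if (n > MINLOOP + 1) st.push({0, n - 1, 0});
  const double EPS = 1e-9;
  while (!st.empty()) {
    std::array<int, 3> top = st.top(); st.pop();
    int i = top[0], j = top[1], inV = top[2];
    if (j - i < MINLOOP + 1) continue;
    if (inV) {
      db[i] = '('; db[j] = ')';
      int pij = pairIdx(b[i], b[j]);
      double v = V[i][j];
      if (std::abs(v - hairpinE(j - i - 1)) < EPS) continue;
      bool done = false;
      for (int k = i + 1; k <= std::min(j - 2, i + MAXLOOP + 1) && !done; ++k) {
        for (int l = j - 1; l >= k + MINLOOP + 1 && !done; --l) {
          int n1 = k - i - 1, n2 = j - l - 1;
          if (n1 + n2 > MAXLOOP) break;
          if (V[k][l] >= INF_E / 2) continue;
          int pin = pairIdx(b[k], b[l]);
          if (pin < 0) continue;
          double e = (n1 == 0 && n2 == 0)
            ? V[k][l] + stackTable[pij][pin]
            : V[k][l] + interiorE(n1, n2);
          if (std::abs(v - e) < EPS) {
            st.push({k, l, 1});
            done = true;
          }
        }
      }
      if (!done && std::abs(v - (W[i + 1][j - 1] + MULTI_PEN)) < EPS) {
        st.push({i + 1, j - 1, 0});
        done = true;
      }
      if (!done) stop("traceback failure in paired state");
      continue;
    }
    double w = W[i][j];
    if (w > -EPS) continue; // zero-energy region stays unpaired
    if (std::abs(w - W[i + 1][j]) < EPS) { st.push({i + 1, j, 0}); continue; }
    if (std::abs(w - W[i][j - 1]) < EPS) { st.push({i, j - 1, 0}); continue; }
    int pij = (b[i] >= 0 && b[j] >= 0) ? pairIdx(b[i], b[j]) : -1;
    if (pij >= 0 && std::abs(w - V[i][j]) < EPS) { st.push({i, j, 1}); continue; }
    bool done = false;
    for (int k = i; k < j && !done; ++k) {
      if (std::abs(w - (W[i][k] + W[k + 1][j])) < EPS) {
        st.push({i, k, 0}); st.push({k + 1, j, 0}); done = true;
      }
    }
    if (!done) stop("traceback failure"); // should not happen
  }

  double mfe = (n > MINLOOP + 1) ? W[0][n - 1] : 0.0;
  if (mfe > 0) mfe = 0; // open structure is always available
  return List::create(_["structure"] = db, _["mfe"] = mfe);
}

// Leftmost 3' adapter prefix match with mismatches; returns trimmed insert
// lengths (0 => adapter at read start, i.e. adapter-adapter product;
// -1 => adapter not found).
// [[Rcpp::export(name = ".trim_adapter_cpp")]]
IntegerVector trim_adapter_cpp(CharacterVector seqs, std::string adapter,
                               int min_overlap, int max_mismatch) {
  int n = seqs.size();
  int alen = (int) adapter.size();
  IntegerVector out(n);
  for (int s = 0; s < n; ++s) {
    std::string rd = as<std::string>(seqs[s]);
    int rlen = (int) rd.size();
    int hit = -1;
    for (int i = 0; i <= rlen - min_overlap; ++i) {
      int cmplen = std::min(alen, rlen - i);
      if (cmplen < min_overlap) break;
      int mm = 0;
      bool ok = true;
      for (int k = 0; k < cmplen; ++k) {
        char a = rd[i + k], bch = adapter[k];
        if (a >= 'a') a -= 32;
        if (bch >= 'a') bch -= 32;
        if (a == 'T') a = 'U';
        if (bch == 'T') bch = 'U';
        if (a != bch && ++mm > max_mismatch) { ok = false; break; }
      }
      if (ok) { hit = i; break; }
    }
    out[s] = hit;
  }
  return out;
}
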