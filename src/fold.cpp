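// Minimum-free-energy RNA secondary structure prediction and the hot
// scanning loops used across the discovery tracks.
//
// The folding engine is a Zuker-style dynamic program over a simplified
// nearest-neighbor thermodynamic model: Turner-like stacking energies,
// size-dependent hairpin/bulge/interior-loop initiation penalties and an
// affine multibranch-loop term.  It is self-contained (no external folding
// library), deterministic, and exposes temperature through a two-state
// enthalpy/entropy decomposition: loop initiations are treated as purely
// entropic (they scale with T) and every stack carries a fixed extra
// enthalpy, so lowering the temperature can never raise the MFE.
// It is NOT a drop-in replacement for a full Turner-2004 implementation;
// see the package vignette for the contract it honors.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>

using namespace Rcpp;

static const double INF = 1e9;
static const int MAXLOOP = 30;    // max unpaired bases in a bulge/interior loop
static const int MINHAIRPIN = 3;  // physical minimum hairpin loop size
static const double TREF = 310.15; // 37 degrees C in Kelvin

// base encoding: A=0 C=1 G=2 U=3 (T treated as U), N=4, anything else -1.
// N never pairs and never matches; fold() rejects it outright.
static inline int base_idx(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  case 'N': case 'n': return 4;
  default: return -1;
  }
}

// pair types (Vienna-like): 0 = none, 1 CG, 2 GC, 3 GU, 4 UG, 5 AU, 6 UA
static inline int pair_type(int a, int b) {
  if (a > 3 || b > 3) return 0;
  if (a == 1 && b == 2) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 2 && b == 3) return 3;
  if (a == 3 && b == 2) return 4;
  if (a == 0 && b == 3) return 5;
  if (a == 3 && b == 0) return 6;
  return 0;
}

// 37C stacking free energies, kcal/mol; rows = outer pair (i,j),
// cols = inner pair (i+1,j-1).  Values follow the Turner nearest-neighbor
// set to within rounding; the table is symmetrized at load so that the
// energy of a helix does not depend on reading direction.
static const double STACK_RAW[7][7] = {
  /*        -     CG     GC     GU     UG     AU     UA */
  /* - */ { INF,  INF,   INF,   INF,   INF,   INF,   INF },
  /* CG*/ { INF, -2.40, -3.30, -2.10, -1.40, -2.10, -2.10 },
  /* GC*/ { INF, -3.30, -3.40, -2.50, -1.50, -2.20, -2.40 },
  /* GU*/ { INF, -2.10, -2.50,  1.30, -0.50, -1.40, -1.30 },
  /* UG*/ { INF, -1.40, -1.50, -0.50,  0.30, -0.60, -1.00 },
  /* AU*/ { INF, -2.10, -2.20, -1.40, -0.60, -1.10, -0.90 },
  /* UA*/ { INF, -2.10, -2.40, -1.30, -1.00, -0.90, -1.30 }
};

// flip a pair type to the same pair read from the other strand
static inline int flip_pt(int p) {
  static const int F[7] = {0, 2, 1, 4, 3, 6, 5};
  return F[p];
}

struct EnergyModel {
  double stack[7][7];
  double tscale;       // T / TREF, multiplies entropic (loop) terms
  double stack_shift;  // extra stabilization of each stack below 37C

  explicit EnergyModel(double temp_c) {
    double tk = temp_c + 273.15;
    tscale = tk / TREF;
    // uniform stack enthalpy offset of -8 kcal/mol relative to dG37:
    // dG(T) = dG37 - 8 * (1 - T/TREF)
    stack_shift = -8.0 * (1.0 - tscale);
    for (int a = 0; a < 7; ++a)
      for (int b = 0; b < 7; ++b) {
        double raw = STACK_RAW[a][b];
        double sym = STACK_RAW[flip_pt(b)][flip_pt(a)];
        stack[a][b] = (raw >= INF || sym >= INF) ? INF
          : 0.5 * (raw + sym) + stack_shift;
      }
  }

  double au_pen(int pt) const { // terminal AU/GU helix-end penalty
    return (pt >= 3) ? 0.5 * tscale : 0.0;
  }

  double hairpin_init(int n) const {
    static const double H[10] = {0, 0, 0, 5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4};
    double g = (n <= 9) ? H[n] : 6.4 + 1.07 * std::log(n / 9.0);
    return g * tscale;
  }

  double bulge_init(int n) const {
    static const double B[7] = {0, 3.8, 2.8, 3.2, 3.6, 4.0, 4.4};
    double g = (n <= 6) ? B[n] : 4.4 + 1.07 * std::log(n / 6.0);
    return g * tscale;
  }

  double interior_init(int n, int n1, int n2) const {
    double g;
    if (n == 2) g = 1.5;
    else if (n == 3) g = 1.8;
    else g = 1.1 + ((n > 4) ? 1.07 * std::log(n / 4.0) : 0.0);
    double asym = 0.6 * std::abs(n1 - n2);
    if (asym > 3.0) asym = 3.0;
    return (g + asym) * tscale;
  }

  double ml_close() const { return 3.4 * tscale; }
  double ml_branch() const { return 0.4 * tscale; }

  // energy of the loop closed by (i,j) with inner helix (p,q)
  double loop_energy(int pt_out, int pt_in, int n1, int n2) const {
    if (n1 == 0 && n2 == 0) return stack[pt_out][pt_in];
    int n = n1 + n2;
    if (n1 == 0 || n2 == 0) {
      if (n == 1) return bulge_init(1) + stack[pt_out][pt_in];
      return bulge_init(n) + au_pen(pt_out) + au_pen(pt_in);
    }
    return interior_init(n, n1, n2) + au_pen(pt_out) + au_pen(pt_in);
  }
};

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    v[i] = base_idx(s[i]);
    if (v[i] < 0)
      stop("invalid base '%s' at position %d (alphabet A,C,G,U/T)",
           std::string(1, s[i]).c_str(), (int)(i + 1));
  }
  return v;
}

class ZukerFold {
public:
  ZukerFold(const std::vector<int>& seq, const EnergyModel& em)
    : s(seq), n((int)seq.size()), em(em),
      V(n * n, INF), WM(n * n, INF), W(n + 1, 0.0) {
    fill();
  }

  double mfe() const { return W[n]; }

  std::string traceback() {
    std::string db(n, '.');
    std::vector<std::array<int, 3>> stk; // (i, j, matrix) matrix: 0=V 1=WM
    // external loop
    int j = n - 1;
    while (j >= 0) {
      if (close_to(W[j + 1], W[j])) { --j; continue; }
      bool found = false;
      for (int i = j - MINHAIRPIN - 1; i >= 0 && !found; --i) {
        int pt = pair_type(s[i], s[j]);
        if (!pt) continue;
        double e = (i > 0 ? W[i] : 0.0) + V[idx(i, j)] + em.au_pen(pt);
        if (close_to(W[j + 1], e)) {
          stk.push_back({i, j, 0});
          j = i - 1;
          found = true;
        }
      }
      if (!found) --j; // numerical safety; should not happen
    }
    while (!stk.empty()) {
      auto fr = stk.back(); stk.pop_back();
      if (fr[2] == 0) trace_V(fr[0], fr[1], db, stk);
      else trace_WM(fr[0], fr[1], db, stk);
    }
    return db;
  }

private:
  const std::vector<int>& s;
  int n;
  const EnergyModel& em;
  std::vector<double> V, WM;
  std::vector<double> W; // W[j] = best energy of prefix s[0..j-1]

  inline int idx(int i, int j) const { return i * n + j; }
  static inline bool close_to(double a, double b) {
    return std::fabs(a - b) < 1e-6;
  }

  double hairpin_E(int i, int j, int pt) const {
    int size = j - i - 1;
    if (size < MINHAIRPIN) return INF;
    return em.hairpin_init(size) + em.au_pen(pt);
  }

  void fill() {
    for (int len = MINHAIRPIN + 2; len <= n; ++len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        int pt = pair_type(s[i], s[j]);
        double v = INF;
        if (pt) {
          v = hairpin_E(i, j, pt);
          // stack / bulge / interior
          int pmax = std::min(i + MAXLOOP + 1, j - MINHAIRPIN - 2);
          for (int p = i + 1; p <= pmax; ++p) {
            int n1 = p - i - 1;
            int qmin = std::max(p + MINHAIRPIN + 1, j - 1 - (MAXLOOP - n1));
            for (int q = qmin; q <= j - 1; ++q) {
              double vin = V[idx(p, q)];
              if (vin >= INF) continue;
              int pt_in = pair_type(s[p], s[q]);
              double e = vin + em.loop_energy(pt, pt_in, n1, j - q - 1);
              if (e < v) v = e;
            }
          }
          // multibranch loop: >=2 branches inside plus the closing pair
          if (len >= 2 * (MINHAIRPIN + 2) + 2) {
            double base = em.ml_close() + em.ml_branch() + em.au_pen(pt);
            for (int k = i + 1; k < j - 1; ++k) {
              double a = WM[idx(i + 1, k)], b = WM[idx(k + 1, j - 1)];
              if (a >= INF || b >= INF) continue;
              double e = base + a + b;
              if (e < v) v = e;
            }
          }
        }
        V[idx(i, j)] = v;

        // WM: segment inside a multiloop holding >= 1 branch
        double wm = INF;
        if (pt && V[idx(i, j)] < INF)
          wm = V[idx(i, j)] + em.ml_branch() + em.au_pen(pt);
        if (len > 1) {
          wm = std::min(wm, WM[idx(i + 1, j)]);
          wm = std::min(wm, WM[idx(i, j - 1)]);
          for (int k = i + 1; k < j; ++k) {
            double a = WM[idx(i, k)], b = WM[idx(k + 1, j)];
            if (a < INF && b < INF) wm = std::min(wm, a + b);
          }
        }
        WM[idx(i, j)] = wm;
      }
    }
    // external loop
    W[0] = 0.0;
    for (int j = 0; j < n; ++j) {
      double w = W[j]; // j unpaired
      for (int i = 0; i <= j - MINHAIRPIN - 1; ++i) {
        int pt = pair_type(s[i], s[j]);
        if (!pt) continue;
        double v = V[idx(i, j)];
        if (v >= INF) continue;
        double e = (i > 0 ? W[i] : 0.0) + v + em.au_pen(pt);
        if (e < w) w = e;
      }
      W[j + 1] = w;
    }
  }

  void trace_V(int i, int j, std::string& db,
               std::vector<std::array<int, 3>>& stk) {
    db[i] = '('; db[j] = ')';
    int pt = pair_type(s[i], s[j]);
    double v = V[idx(i, j)];
    if (close_to(v, hairpin_E(i, j, pt))) return;
    int pmax = std::min(i + MAXLOOP + 1, j - MINHAIRPIN - 2);
    for (int p = i + 1; p <= pmax; ++p) {
      int n1 = p - i - 1;
      int qmin = std::max(p + MINHAIRPIN + 1, j - 1 - (MAXLOOP - n1));
      for (int q = qmin; q <= j - 1; ++q) {
        double vin = V[idx(p, q)];
        if (vin >= INF) continue;
        int pt_in = pair_type(s[p], s[q]);
        if (close_to(v, vin + em.loop_energy(pt, pt_in, n1, j - q - 1))) {
          stk.push_back({p, q, 0});
          return;
        }
      }
    }
    double base = em.ml_close() + em.ml_branch() + em.au_pen(pt);
    for (int k = i + 1; k < j - 1; ++k) {
      double a = WM[idx(i + 1, k)], b = WM[idx(k + 1, j - 1)];
      if (a >= INF || b >= INF) continue;
      if (close_to(v, base + a + b)) {
        stk.push_back({i + 1, k, 1});
        stk.push_back({k + 1, j - 1, 1});
        return;
      }
    }
  }

  void trace_WM(int i, int j, std::string& db,
                std::vector<std::array<int, 3>>& stk) {
    while (i < j) {
      double wm = WM[idx(i, j)];
      int pt = pair_type(s[i], s[j]);
      if (pt && V[idx(i, j)] < INF &&
          close_to(wm, V[idx(i, j)] + em.ml_branch() + em.au_pen(pt))) {
        stk.push_back({i, j, 0});
        return;
      }
      if (close_to(wm, WM[idx(i + 1, j)])) { ++i; continue; }
      if (close_to(wm, WM[idx(i, j - 1)])) { --j; continue; }
      bool split = false;
      for (int k = i + 1; k < j; ++k) {
        double a = WM[idx(i, k)], b = WM[idx(k + 1, j)];
        if (a < INF && b < INF && close_to(wm, a + b)) {
          stk.push_back({i, k, 1});
          stk.push_back({k + 1, j, 1});
          split = true;
          break;
        }
      }
      if (split) return;
      ++i; // numerical safety
    }
  }
};

// [[Rcpp::export(name = ".fold_cpp")]]
List fold_cpp(std::string sequence, double temperature) {
  std::vector<int> s = encode(sequence);
  int n = (int)s.size();
  if (n < 10) stop("sequence shorter than 10 nt cannot be folded");
  if (n > 5000)
    stop("sequence longer than 5 kb: this folder is meant for "
         "precursor-scale windows");
  for (int v : s)
    if (v == 4) stop("sequence contains N: folding is undefined");
  EnergyModel em(temperature);
  ZukerFold zf(s, em);
  double mfe = zf.mfe();
  std::string db;
  if (mfe > -1e-9) { mfe = 0.0; db.assign(n, '.'); }
  else db = zf.traceback();
  return List::create(_["structure"] = db, _["mfe"] = mfe,
                      _["temperature"] = temperature);
}

// ---------------------------------------------------------------------------
// hairpin pre-screen: best local anti-diagonal complementarity score
// (+1 per canonical/GU pair, -1.5 per mismatch, Kadane per anti-diagonal,
//  pairs closer than min_loop excluded).  Purely a speed heuristic:
// substitution-diverged stems sit on one anti-diagonal.

static double screen_one(const std::vector<int>& s, int from, int to,
                         int min_loop) {
  double best = 0.0;
  int L = to - from;
  for (int d = 1; d <= 2 * (L - 1) - 1; ++d) { // d = (i-from)+(j-from)
    double run = 0.0;
    int kmax = (d - min_loop - 1) / 2;
    for (int k = 0; k <= kmax; ++k) {
      int i = k, j = d - k;
      if (j >= L) continue;
      if (j - i <= min_loop) break;
      bool pair = pair_type(s[from + i], s[from + j]) != 0;
      run = std::max(0.0, run + (pair ? 1.0 : -1.5));
      if (run > best) best = run;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".screen_hairpin_cpp")]]
double screen_hairpin_cpp(std::string sequence, int min_loop) {
  std::vector<int> s = encode(sequence);
  return screen_one(s, 0, (int)s.size(), min_loop);
}

// Scores every window of length `window` starting at 1-based positions
// 1, 1+stride, ... over the sequence.
// [[Rcpp::export(name = ".screen_scan_cpp")]]
DataFrame screen_scan_cpp(std::string sequence, int window, int stride,
                          int min_loop) {
  std::vector<int> s = encode(sequence);
  int n = (int)s.size();
  std::vector<int> pos;
  std::vector<double> score;
  for (int i = 0; i + window <= n; i += stride) {
    pos.push_back(i + 1);
    score.push_back(screen_one(s, i, i + window, min_loop));
  }
  return DataFrame::create(_["pos"] = pos, _["score"] = score);
}

// ---------------------------------------------------------------------------
// mismatch-limited (Hamming) scan of a query along a subject, early exit

// [[Rcpp::export(name = ".mismatch_scan_cpp")]]
DataFrame mismatch_scan_cpp(std::string subject, std::string query,
                            int max_mm) {
  std::vector<int> s = encode(subject), q = encode(query);
  int n = (int)s.size(), m = (int)q.size();
  std::vector<int> pos, mism;
  for (int i = 0; i + m <= n; ++i) {
    int mm = 0;
    for (int k = 0; k < m; ++k) {
      if (s[i + k] != q[k] && ++mm > max_mm) break;
    }
    if (mm <= max_mm) { pos.push_back(i + 1); mism.push_back(mm); }
  }
  return DataFrame::create(_["pos"] = pos, _["mismatches"] = mism);
}

// ---------------------------------------------------------------------------
// paired-segment pattern scan: 5' segment of length len in [min_len,max_len],
// gap in [gap_min, gap_max], 3' segment = reverse complement of the 5'
// segment with at most max_mm mismatches.  Returns all matches (1-based
// starts); arm/loop geometry is resolved by the caller.

// [[Rcpp::export(name = ".pair_pattern_scan_cpp")]]
DataFrame pair_pattern_scan_cpp(std::string sequence, int min_len,
                                int max_len, int gap_min, int gap_max,
                                int max_mm) {
  std::vector<int> s = encode(sequence);
  int n = (int)s.size();
  std::vector<int> s5, s3, lenv, mmv;
  for (int len = min_len; len <= max_len; ++len) {
    for (int a = 0; a + len <= n; ++a) {
      for (int g = gap_min; g <= gap_max; ++g) {
        int b = a + len + g;
        if (b + len > n) break;
        int mm = 0;
        // position k of the 5' arm pairs with position len-1-k of the 3' arm
        for (int k = 0; k < len; ++k) {
          if (!pair_type(s[a + k], s[b + len - 1 - k]) && ++mm > max_mm)
            break;
        }
        if (mm <= max_mm) {
          s5.push_back(a + 1); s3.push_back(b + 1);
          lenv.push_back(len); mmv.push_back(mm);
        }
      }
    }
  }
  return DataFrame::create(_["start5"] = s5, _["start3"] = s3,
                           _["len"] = lenv, _["mismatches"] = mmv);
}

// ---------------------------------------------------------------------------
// intermolecular duplex energy (RNAhybrid-like, simplified):
// antiparallel miRNA/target duplex, no intramolecular pairs, bulge and
// interior loops bounded, stacking energies from the same model as fold().
// Helix constraint (a, b), 1-based on the miRNA: positions a..b must form
// a contiguous helix with consecutive target positions.

static const int DUP_MAXGAP = 10;
static const double DUP_INIT = 4.1; // duplex initiation, kcal/mol

// shared side-extension DPs for one miRNA/target pair
struct DuplexDP {
  std::vector<double> EL, ER;
  int m, n;
  std::vector<int> q, t;
  EnergyModel em;
  DuplexDP(const std::string& mirna, const std::string& target,
           double temperature)
    : q(encode(mirna)), t(encode(target)), em(temperature) {
    m = (int)q.size(); n = (int)t.size();
    EL.assign(m * n, INF); ER.assign(m * n, 0.0);
    fill();
  }
  inline int id(int i, int j) const { return i * n + j; }
  inline int pt_at(int i, int j) const { return pair_type(q[i], t[j]); }
  void fill();
  // best constrained-site energy for helix frame (a..b, 0-based)
  std::pair<double,int> site(int a, int b) const {
    int hl = b - a;
    double best = INF; int best_t = -1;
    for (int tj = hl; tj < n; ++tj) {
      bool ok = true;
      for (int k = 0; k <= hl && ok; ++k)
        if (!pt_at(a + k, tj - k)) ok = false;
      if (!ok) continue;
      double helix = 0.0;
      for (int k = 1; k <= hl; ++k)
        helix += em.stack[pt_at(a + k - 1, tj - k + 1)][pt_at(a + k, tj - k)];
      double e = EL[id(a, tj)] + helix + ER[id(b, tj - hl)];
      if (e < best) { best = e; best_t = tj; }
    }
    return {best, best_t};
  }
};

void DuplexDP::fill() {
  for (int i = 0; i < m; ++i)
    for (int j = n - 1; j >= 0; --j) {
      int pt = pt_at(i, j);
      if (!pt) continue;
      double best = DUP_INIT + em.au_pen(pt); // duplex starts here
      for (int gi = 0; gi <= DUP_MAXGAP; ++gi) {
        int pi = i - 1 - gi;
        if (pi < 0) break;
        for (int gj = 0; gj <= DUP_MAXGAP; ++gj) {
          int pj = j + 1 + gj;
          if (pj >= n) break;
          double prev = EL[id(pi, pj)];
          if (prev >= INF) continue;
          int pt_prev = pt_at(pi, pj);
          double e = prev + em.loop_energy(pt_prev, pt, gi, gj);
          if (e < best) best = e;
        }
      }
      EL[id(i, j)] = best;
    }
  for (int i = m - 1; i >= 0; --i)
    for (int j = 0; j < n; ++j) {
      int pt = pt_at(i, j);
      if (!pt) continue;
      double best = em.au_pen(pt); // duplex ends here
      for (int gi = 0; gi <= DUP_MAXGAP; ++gi) {
        int ni = i + 1 + gi;
        if (ni >= m) break;
        for (int gj = 0; gj <= DUP_MAXGAP; ++gj) {
          int nj = j - 1 - gj;
          if (nj < 0) break;
          double nxt = ER[id(ni, nj)];
          int pt_next = pt_at(ni, nj);
          if (!pt_next) continue;
          double e = nxt + em.loop_energy(pt, pt_next, gi, gj);
          if (e < best) best = e;
        }
      }
      ER[id(i, j)] = best;
    }
}

// [[Rcpp::export(name = ".duplex_energy_frames_cpp")]]
List duplex_energy_frames_cpp(std::string mirna, std::string target,
                              IntegerVector f_a, IntegerVector f_b,
                              double temperature) {
  DuplexDP dp(mirna, target, temperature);
  int nf = f_a.size();
  NumericVector energy(nf);
  IntegerVector tpos(nf);
  for (int k = 0; k < nf; ++k) {
    if (f_a[k] < 1 || f_b[k] > dp.m || f_a[k] >= f_b[k])
      stop("helix constraint outside the miRNA");
    auto r = dp.site(f_a[k] - 1, f_b[k] - 1);
    energy[k] = (r.first >= INF) ? R_PosInf : r.first;
    tpos[k] = (r.second < 0) ? NA_INTEGER : r.second + 1;
  }
  return List::create(_["energy"] = energy, _["target_pos"] = tpos);
}

// [[Rcpp::export(name = ".duplex_energy_cpp")]]
List duplex_energy_cpp(std::string mirna, std::string target,
                       int f_a, int f_b, double temperature) {
  std::vector<int> q = encode(mirna), t = encode(target);
  int m = (int)q.size(), n = (int)t.size();
  if (f_a < 1 || f_b > m || f_a >= f_b)
    stop("helix constraint outside the miRNA");
  EnergyModel em(temperature);

  // EL[i][j]: best energy of a duplex whose 3'-most miRNA pair is (i, j)
  // (miRNA 5'->3' left to right, target index decreasing), incl. initiation.
  // ER[i][j]: best additional energy extending 3' of pair (i, j) (<= 0).
  std::vector<double> EL(m * n, INF), ER(m * n, 0.0);
  auto id = [n](int i, int j) { return i * n + j; };
  auto pt_at = [&](int i, int j) { return pair_type(q[i], t[j]); };

  for (int i = 0; i < m; ++i)
    for (int j = n - 1; j >= 0; --j) {
      int pt = pt_at(i, j);
      if (!pt) continue;
      double best = DUP_INIT + em.au_pen(pt); // duplex starts here
      for (int gi = 0; gi <= DUP_MAXGAP; ++gi) {
        int pi = i - 1 - gi;
        if (pi < 0) break;
        for (int gj = 0; gj <= DUP_MAXGAP; ++gj) {
          int pj = j + 1 + gj;
          if (pj >= n) break;
          double prev = EL[id(pi, pj)];
          if (prev >= INF) continue;
          int pt_prev = pt_at(pi, pj);
          double e = prev + em.loop_energy(pt_prev, pt, gi, gj);
          if (e < best) best = e;
        }
      }
      EL[id(i, j)] = best;
    }
  for (int i = m - 1; i >= 0; --i)
    for (int j = 0; j < n; ++j) {
      int pt = pt_at(i, j);
      if (!pt) continue;
      double best = em.au_pen(pt); // duplex ends here
      for (int gi = 0; gi <= DUP_MAXGAP; ++gi) {
        int ni = i + 1 + gi;
        if (ni >= m) break;
        for (int gj = 0; gj <= DUP_MAXGAP; ++gj) {
          int nj = j - 1 - gj;
          if (nj < 0) break;
          double nxt = ER[id(ni, nj)];
          int pt_next = pt_at(ni, nj);
          if (!pt_next) continue;
          double e = nxt + em.loop_energy(pt, pt_next, gi, gj);
          if (e < best) best = e;
        }
      }
      ER[id(i, j)] = best;
    }

  // anchor the constrained helix: miRNA a..b pairs target tj, tj-1, ...
  int a = f_a - 1, b = f_b - 1, hl = b - a;
  double best = INF; int best_t = -1;
  for (int tj = hl; tj < n; ++tj) {
    bool ok = true;
    double helix = 0.0;
    for (int k = 0; k <= hl && ok; ++k)
      if (!pt_at(a + k, tj - k)) ok = false;
    if (!ok) continue;
    for (int k = 1; k <= hl; ++k)
      helix += em.stack[pt_at(a + k - 1, tj - k + 1)][pt_at(a + k, tj - k)];
    double e = EL[id(a, tj)] + helix + ER[id(b, tj - hl)];
    // EL already contains au_pen only when the duplex starts at (a,tj);
    if (e < best) { best = e; best_t = tj; }
  }
  if (best >= INF)
    return List::create(_["energy"] = R_PosInf, _["target_pos"] = NA_INTEGER);
  return List::create(_["energy"] = best, _["target_pos"] = best_t + 1);
}

// ---------------------------------------------------------------------------
// best ungapped identity of the shorter sequence slid along the longer one

// [[Rcpp::export(name = ".ungapped_identity_cpp")]]
double ungapped_identity_cpp(std::string a, std::string b) {
  if (a.size() > b.size()) std::swap(a, b);
  std::vector<int> s = encode(a), t = encode(b);
  int m = (int)s.size(), n = (int)t.size();
  if (m == 0) return 0.0;
  int best = 0;
  for (int off = 0; off + m <= n; ++off) {
    int match = 0;
    for (int k = 0; k < m; ++k)
      if (s[k] == t[off + k]) ++match;
    if (match > best) best = match;
  }
  return (double)best / m;
}

// ---------------------------------------------------------------------------
// seeded batch mismatch scan: pigeonhole seeding on a 7-mer subject index,
// exact-Hamming verification.  Queries too short to seed fall back to the
// sliding scan.  Returns 1-based positions.

// [[Rcpp::export(name = ".mismatch_scan_batch_cpp")]]
DataFrame mismatch_scan_batch_cpp(std::string subject,
                                  std::vector<std::string> queries,
                                  int max_mm) {
  const int K = 7;
  std::vector<int> s = encode(subject);
  int n = (int)s.size();
  // index: kmer code -> positions
  std::vector<std::vector<int>> index(1 << (2 * K));
  if (n >= K) {
    int code = 0, since_n = K; // k-mers containing N are not indexed
    for (int i = 0; i < n; ++i) {
      if (s[i] > 3) { since_n = 0; code = 0; continue; }
      ++since_n;
      code = ((code << 2) | s[i]) & ((1 << (2 * K)) - 1);
      if (i >= K - 1 && since_n >= K) index[code].push_back(i - K + 1);
    }
  }
  std::vector<int> out_q, out_pos, out_mm;
  std::vector<int> seen(n, -1);
  for (size_t qi = 0; qi < queries.size(); ++qi) {
    std::vector<int> q = encode(queries[qi]);
    int m = (int)q.size();
    if (m > n) continue;
    auto verify = [&](int start) {
      if (start < 0 || start + m > n || seen[start] == (int)qi) return;
      int mm = 0;
      for (int k = 0; k < m; ++k)
        if (s[start + k] != q[k] && ++mm > max_mm) return;
      seen[start] = (int)qi;
      out_q.push_back((int)qi + 1);
      out_pos.push_back(start + 1);
      out_mm.push_back(mm);
    };
    bool has_n = false;
    for (int v : q) if (v > 3) has_n = true;
    if (!has_n && m >= K * (max_mm + 1)) {
      for (int part = 0; part <= max_mm; ++part) {
        int off = part * m / (max_mm + 1);
        if (off + K > m) off = m - K;
        int code = 0;
        for (int k = 0; k < K; ++k) code = (code << 2) | q[off + k];
        for (int pos : index[code]) verify(pos - off);
      }
    } else {
      for (int start = 0; start + m <= n; ++start) verify(start);
    }
  }
  return DataFrame::create(_["query"] = out_q, _["pos"] = out_pos,
                           _["mismatches"] = out_mm);
}
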