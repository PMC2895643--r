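#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Neighborhood offsets on the square lattice. The first four entries are the
// order-1 (von Neumann) shell used for copy attempts; all eight form the
// order-2 (Moore) shell used for boundary energy, perimeter and contact
// counting.
static const int DX8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
static const int DY8[8] = {0, 0, 1, -1, 1, -1, 1, -1};

static inline int wrapi(int a, int n) {
  if (a < 0) return a + n;
  if (a >= n) return a - n;
  return a;
}

// Per-cell area, perimeter and OC-contact length recomputed from scratch.
// Index 0 of every output vector is the Medium cell.
// [[Rcpp::export]]
List cpp_geometry(IntegerMatrix owner, int ncells, IntegerVector typeOf,
                  LogicalVector isOC, int order) {
  const int W = owner.nrow(), H = owner.ncol();
  const int nn = (order >= 2) ? 8 : 4;
  NumericVector area(ncells + 1), perim(ncells + 1), occ(ncells + 1);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      const int o = owner[x + W * y];
      area[o] += 1.0;
      for (int k = 0; k < nn; ++k) {
        const int xn = wrapi(x + DX8[k], W), yn = wrapi(y + DY8[k], H);
        const int on = owner[xn + W * yn];
        if (on != o) {
          perim[o] += 1.0;
          // death-rule contact lengths are counted in lattice units:
          // order-1 (edge) links only, regardless of the boundary order
          if (k < 4 && isOC[typeOf[on]]) occ[o] += 1.0;
        }
      }
    }
  }
  return List::create(_["area"] = area, _["perimeter"] = perim,
                      _["oc_contact"] = occ);
}

// Symmetric (ncells+1) x (ncells+1) matrix of shared boundary link counts.
// [[Rcpp::export]]
NumericMatrix cpp_contact_matrix(IntegerMatrix owner, int ncells, int order) {
  const int W = owner.nrow(), H = owner.ncol();
  // half-shell offsets so each unordered link is visited once
  const int hx[4] = {1, 0, 1, 1};
  const int hy[4] = {0, 1, 1, -1};
  const int nh = (order >= 2) ? 4 : 2;
  NumericMatrix M(ncells + 1, ncells + 1);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      const int o = owner[x + W * y];
      for (int k = 0; k < nh; ++k) {
        const int xn = wrapi(x + hx[k], W), yn = wrapi(y + hy[k], H);
        const int on = owner[xn + W * yn];
        if (on != o) {
          M(o, on) += 1.0;
          M(on, o) += 1.0;
        }
      }
    }
  }
  return M;
}

// Full-lattice recomputation of the effective energy, split into its three
// terms. Shape terms run over all registered cells (ids 1..ncells) whether or
// not they still own lattice sites, so that a cell squeezed to zero area still
// pays its area penalty until it is dropped from the registry.
// [[Rcpp::export]]
NumericVector cpp_total_energy(IntegerMatrix owner, int ncells,
                               IntegerVector typeOf, NumericMatrix J,
                               NumericVector AT, NumericVector PT,
                               NumericVector lamA, NumericVector lamP,
                               int order) {
  const int W = owner.nrow(), H = owner.ncol();
  const int hx[4] = {1, 0, 1, 1};
  const int hy[4] = {0, 1, 1, -1};
  const int nh = (order >= 2) ? 4 : 2;
  std::vector<double> area(ncells + 1, 0.0), perim(ncells + 1, 0.0);
  double eb = 0.0;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      const int o = owner[x + W * y];
      area[o] += 1.0;
      for (int k = 0; k < nh; ++k) {
        const int xn = wrapi(x + hx[k], W), yn = wrapi(y + hy[k], H);
        const int on = owner[xn + W * yn];
        if (on != o) {
          eb += J(typeOf[o], typeOf[on]);
          perim[o] += 1.0;
          perim[on] += 1.0;
        }
      }
    }
  }
  double ea = 0.0, ep = 0.0;
  for (int c = 1; c <= ncells; ++c) {
    const double da = area[c] - AT[c];
    const double dp = perim[c] - PT[c];
    ea += lamA[c] * da * da;
    ep += lamP[c] * dp * dp;
  }
  return NumericVector::create(_["boundary"] = eb, _["area"] = ea,
                               _["perimeter"] = ep);
}

// Energy difference for copying owner `os` onto the site (xt, yt) currently
// owned by `ot`, evaluated locally. cntOld/cntNew receive the number of
// boundary-shell neighbors of the target owned by ot and os respectively.
static inline double local_dh(const int* ow, int W, int H, int nn,
                              const int* typeOf, const NumericMatrix& J,
                              const double* area, const double* perim,
                              const double* AT, const double* PT,
                              const double* lamA, const double* lamP,
                              int os, int ot, int xt, int yt,
                              int* cntOld, int* cntNew) {
  const int tOld = typeOf[ot], tNew = typeOf[os];
  double db = 0.0;
  int cold = 0, cnew = 0;
  for (int k = 0; k < nn; ++k) {
    const int xn = wrapi(xt + DX8[k], W), yn = wrapi(yt + DY8[k], H);
    const int on = ow[xn + W * yn];
    if (on == ot) ++cold;
    if (on == os) ++cnew;
    const int tn = typeOf[on];
    if (on != os) db += J(tNew, tn);
    if (on != ot) db -= J(tOld, tn);
  }
  double dH = db;
  if (lamA[ot] != 0.0) {
    const double a = area[ot], t = AT[ot];
    dH += lamA[ot] * ((a - 1.0 - t) * (a - 1.0 - t) - (a - t) * (a - t));
  }
  if (lamA[os] != 0.0) {
    const double a = area[os], t = AT[os];
    dH += lamA[os] * ((a + 1.0 - t) * (a + 1.0 - t) - (a - t) * (a - t));
  }
  if (lamP[ot] != 0.0) {
    const double p = perim[ot], t = PT[ot];
    const double pn = p + 2.0 * cold - nn;
    dH += lamP[ot] * ((pn - t) * (pn - t) - (p - t) * (p - t));
  }
  if (lamP[os] != 0.0) {
    const double p = perim[os], t = PT[os];
    const double pn = p + nn - 2.0 * cnew;
    dH += lamP[os] * ((pn - t) * (pn - t) - (p - t) * (p - t));
  }
  *cntOld = cold;
  *cntNew = cnew;
  return dH;
}

// [[Rcpp::export]]
double cpp_delta_h(IntegerMatrix owner, int ncells, IntegerVector typeOf,
                   NumericMatrix J, NumericVector area, NumericVector perim,
                   NumericVector AT, NumericVector PT, NumericVector lamA,
                   NumericVector lamP, int xs, int ys, int xt, int yt,
                   int order) {
  const int W = owner.nrow(), H = owner.ncol();
  const int nn = (order >= 2) ? 8 : 4;
  const int os = owner[xs + W * ys], ot = owner[xt + W * yt];
  if (os == ot) return 0.0;
  int c1, c2;
  return local_dh(owner.begin(), W, H, nn, typeOf.begin(), J, area.begin(),
                  perim.begin(), AT.begin(), PT.begin(), lamA.begin(),
                  lamP.begin(), os, ot, xt, yt, &c1, &c2);
}

// PCG32 (Melissa O'Neill's pcg-random.org minimal generator): a fast,
// portable stream for the inner sweep loop. It is seeded from R's RNG at
// block entry, so trajectories remain a deterministic function of set.seed().
struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t seq) {
    state = 0u;
    inc = (seq << 1u) | 1u;
    next();
    state += seed;
    next();
  }
  inline uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  // unbiased-enough bounded draw via 32x32 -> 64 multiply-shift
  inline uint32_t bounded(uint32_t n) {
    return (uint32_t)(((uint64_t)next() * (uint64_t)n) >> 32);
  }
  inline double uniform() { return (next() >> 8) * (1.0 / 16777216.0); }
};

// One or more Monte Carlo Steps: W*H copy attempts per MCS, each picking a
// uniformly random target site and a random order-1 neighbor as source, with
// Metropolis acceptance min(1, exp(-dH/T)). Mutates owner, area, perim,
// ocContact and alive in place. Exactly one extra uniform variate is drawn
// when (and only when) dH > 0. The sweep stream is a PCG32 generator seeded
// from R's RNG, so runs are reproducible from set.seed().
// [[Rcpp::export]]
List cpp_mcs_block(IntegerMatrix owner, int ncells, IntegerVector typeOf,
                   NumericMatrix J, NumericVector area, NumericVector perim,
                   NumericVector AT, NumericVector PT, NumericVector lamA,
                   NumericVector lamP, LogicalVector alive,
                   NumericVector ocContact, LogicalVector isOC, double T,
                   int nMCS, int order) {
  const int W = owner.nrow(), H = owner.ncol();
  const int nn = (order >= 2) ? 8 : 4;
  const uint32_t nsites = (uint32_t)((long)W * (long)H);
  Pcg32 rng((uint64_t)(unif_rand() * 4294967296.0) ^
                ((uint64_t)(unif_rand() * 4294967296.0) << 32),
            (uint64_t)(unif_rand() * 4294967296.0));
  int* ow = owner.begin();
  double* ar = area.begin();
  double* pe = perim.begin();
  double* occ = ocContact.begin();
  const int* tf = typeOf.begin();
  long accepted = 0, attempts = 0;
  double sumDH = 0.0;
  for (int step = 0; step < nMCS; ++step) {
    const long natt = (long)W * (long)H;
    for (long a = 0; a < natt; ++a) {
      ++attempts;
      const uint32_t idx = rng.bounded(nsites);
      const int xt = (int)(idx % (uint32_t)W), yt = (int)(idx / (uint32_t)W);
      const int k = (int)(rng.next() & 3u);
      const int xs = wrapi(xt + DX8[k], W), ys = wrapi(yt + DY8[k], H);
      const int os = ow[xs + W * ys], ot = ow[xt + W * yt];
      if (os == ot) continue;
      int cold, cnew;
      const double dH =
          local_dh(ow, W, H, nn, tf, J, ar, pe, AT.begin(), PT.begin(),
                   lamA.begin(), lamP.begin(), os, ot, xt, yt, &cold, &cnew);
      bool acc = true;
      if (dH > 0.0) acc = rng.uniform() < std::exp(-dH / T);
      if (!acc) continue;
      // apply the copy and update cached statistics incrementally
      ow[xt + W * yt] = os;
      ar[ot] -= 1.0;
      ar[os] += 1.0;
      pe[ot] += 2.0 * cold - nn;
      pe[os] += nn - 2.0 * cnew;
      const int iOld = isOC[tf[ot]] ? 1 : 0, iNew = isOC[tf[os]] ? 1 : 0;
      for (int kk = 0; kk < 4; ++kk) {
        const int xn = wrapi(xt + DX8[kk], W), yn = wrapi(yt + DY8[kk], H);
        const int on = ow[xn + W * yn];
        const int iN = isOC[tf[on]] ? 1 : 0;
        if (on != ot) {
          occ[on] -= iOld;
          occ[ot] -= iN;
        }
        if (on != os) {
          occ[on] += iNew;
          occ[os] += iN;
        }
      }
      if (ot != 0 && ar[ot] <= 0.0) alive[ot] = FALSE;
      ++accepted;
      sumDH += dH;
    }
  }
  return List::create(_["accepted"] = (double)accepted,
                      _["attempts"] = (double)attempts,
                      _["delta_H"] = sumDH);
}

// Split every non-background label of an integer label image into
// 4-connected components (non-periodic), relabeling components 1..n in
// scan order. Returns the relabeled image and the original label of each
// new component id.
// [[Rcpp::export]]
List cpp_label_components(IntegerMatrix labels, int background) {
  const int W = labels.nrow(), H = labels.ncol();
  IntegerMatrix out(W, H);
  std::fill(out.begin(), out.end(), 0);
  std::vector<int> orig;
  int next = 0;
  std::deque<int> queue;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      const int v = labels[x + W * y];
      if (v == background || out[x + W * y] != 0) continue;
      ++next;
      orig.push_back(v);
      out[x + W * y] = next;
      queue.push_back(x + W * y);
      while (!queue.empty()) {
        const int s = queue.front();
        queue.pop_front();
        const int sx = s % W, sy = s / W;
        for (int k = 0; k < 4; ++k) {
          const int xn = sx + DX8[k], yn = sy + DY8[k];
          if (xn < 0 || xn >= W || yn < 0 || yn >= H) continue;
          const int t = xn + W * yn;
          if (out[t] == 0 && labels[t] == v) {
            out[t] = next;
            queue.push_back(t);
          }
        }
      }
    }
  }
  return List::create(_["labels"] = out, _["original"] = wrap(orig));
}
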