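#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Symmetric (repeated-edge) reflection of an unbounded lattice coordinate
// into [0, extent). Period of the reflected tiling is 2*extent.
static inline int fold1(long long x, int extent) {
  long long period = 2LL * extent;
  long long m = x % period;
  if (m < 0) m += period;
  return (m < extent) ? (int)m : (int)(period - 1 - m);
}

// [[Rcpp::export]]
IntegerVector fold_coordinate_cpp(NumericVector x, int extent) {
  if (extent < 1) stop("extent must be >= 1");
  int n = x.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = fold1((long long)x[i], extent);
  return out;
}

// Indexed binary min-heap over event ids keyed by tentative times.
struct EventHeap {
  std::vector<int> heap;  // heap position -> event id
  std::vector<int> pos;   // event id -> heap position
  const std::vector<double>* key;

  void init(int n, const std::vector<double>* k) {
    key = k;
    heap.resize(n);
    pos.resize(n);
    for (int i = 0; i < n; ++i) { heap[i] = i; pos[i] = i; }
    for (int i = n / 2 - 1; i >= 0; --i) sift_down(i);
  }
  inline bool less(int a, int b) const {
    double ka = (*key)[heap[a]], kb = (*key)[heap[b]];
    if (ka != kb) return ka < kb;
    return heap[a] < heap[b];  // deterministic tie-break by event id
  }
  inline void swap_at(int a, int b) {
    std::swap(heap[a], heap[b]);
    pos[heap[a]] = a;
    pos[heap[b]] = b;
  }
  void sift_up(int i) {
    while (i > 0) {
      int p = (i - 1) / 2;
      if (less(i, p)) { swap_at(i, p); i = p; } else break;
    }
  }
  void sift_down(int i) {
    int n = heap.size();
    for (;;) {
      int l = 2 * i + 1, r = l + 1, m = i;
      if (l < n && less(l, m)) m = l;
      if (r < n && less(r, m)) m = r;
      if (m == i) break;
      swap_at(i, m); i = m;
    }
  }
  inline void update(int id) { int i = pos[id]; sift_up(i); sift_down(pos[id]); }
  inline int top() const { return heap[0]; }
};

// Next-reaction LKMC for non-interacting tracers on a 2D pore/cell lattice
// with mirror boundary conditions. pore is TRUE at accessible sites.
// Returns ensemble MSD (cm^2) at each sample time plus diagnostics.
// [[Rcpp::export]]
List run_lkmc_cpp(LogicalMatrix pore, double h_cm, double dp,
                  int n_particles, double t_end, NumericVector sample_times,
                  bool check_legality = false) {
  int nr = pore.nrow(), nc = pore.ncol();
  std::vector<int> pore_i, pore_j;
  pore_i.reserve((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (pore(i, j)) { pore_i.push_back(i); pore_j.push_back(j); }
  int n_pore = pore_i.size();
  if (n_pore == 0) stop("domain has no pore sites");
  if (n_particles < 1) stop("n_particles must be >= 1");
  if (t_end <= 0) stop("t_end must be positive");

  const double h2 = h_cm * h_cm;
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};

  std::vector<long long> ux(n_particles), uy(n_particles);
  std::vector<long long> ox(n_particles), oy(n_particles);
  int n_events = 4 * n_particles;
  std::vector<double> times(n_events);

  RNGScope scope;
  // uniform placement over pore sites, with replacement (tracers)
  for (int p = 0; p < n_particles; ++p) {
    int k = (int)std::floor(unif_rand() * n_pore);
    if (k >= n_pore) k = n_pore - 1;
    ux[p] = ox[p] = pore_i[k];
    uy[p] = oy[p] = pore_j[k];
  }

  // tentative event time for one direction; blocked gets sentinel-inf
  auto draw_time = [&](int p, int d, double t_sys) {
    int fi = fold1(ux[p] + di[d], nr);
    int fj = fold1(uy[p] + dj[d], nc);
    if (pore(fi, fj)) {
      double r = 1.0 - unif_rand();  // (0, 1]
      times[4 * p + d] = t_sys - h2 * std::log(r) / dp;
    } else {
      times[4 * p + d] = R_PosInf;
    }
  };
  for (int p = 0; p < n_particles; ++p)
    for (int d = 0; d < 4; ++d) draw_time(p, d, 0.0);

  EventHeap eh;
  eh.init(n_events, &times);

  int ns = sample_times.size();
  NumericVector msd(ns);
  int si = 0;
  auto record = [&](int idx) {
    double acc = 0.0;
    for (int p = 0; p < n_particles; ++p) {
      double dxs = (double)(ux[p] - ox[p]);
      double dys = (double)(uy[p] - oy[p]);
      acc += dxs * dxs + dys * dys;
    }
    msd[idx] = acc / n_particles * h2;
    if (check_legality) {
      for (int p = 0; p < n_particles; ++p)
        if (!pore(fold1(ux[p], nr), fold1(uy[p], nc)))
          stop("occupancy violation: particle on a cell site");
    }
  };

  double t_sys = 0.0;
  long long executed = 0;
  for (;;) {
    int id = eh.top();
    double t = times[id];
    if (!R_finite(t) || t > t_end) break;
    while (si < ns && sample_times[si] < t) { record(si); ++si; }
    if (t < t_sys) stop("event clock moved backwards");  // invariant guard
    t_sys = t;
    int p = id / 4, d = id % 4;
    ux[p] += di[d];
    uy[p] += dj[d];
    ++executed;
    // redraw the moved particle's four events, re-heapifying one at a
    // time so every sift sees a consistent heap
    for (int d2 = 0; d2 < 4; ++d2) {
      draw_time(p, d2, t_sys);
      eh.update(4 * p + d2);
    }
  }
  while (si < ns) { record(si); ++si; }

  return List::create(_["msd_cm2"] = msd,
                      _["n_events"] = (double)executed,
                      _["t_final"] = t_sys);
}

// Local thickness: LT(x) = 2 * max{ r(c) : |x - c| <= r(c) } over pore
// centres c, where r is the (edge-corrected) inscribed-disc radius field in
// site units; <= 0 marks cell sites. Exact disc painting.
// [[Rcpp::export]]
NumericMatrix local_thickness_cpp(NumericMatrix radius) {
  int nr = radius.nrow(), nc = radius.ncol();
  NumericMatrix lt(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double r = radius(i, j);
      if (r <= 0) continue;
      int ri = (int)std::floor(r);
      double r2 = r * r;
      int i0 = std::max(0, i - ri), i1 = std::min(nr - 1, i + ri);
      int j0 = std::max(0, j - ri), j1 = std::min(nc - 1, j + ri);
      for (int jj = j0; jj <= j1; ++jj) {
        double dj2 = (double)(jj - j) * (jj - j);
        for (int ii = i0; ii <= i1; ++ii) {
          double d2 = (double)(ii - i) * (ii - i) + dj2;
          if (d2 <= r2 && radius(ii, jj) > 0 && lt(ii, jj) < 2.0 * r)
            lt(ii, jj) = 2.0 * r;
        }
      }
    }
  }
  return lt;
}
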