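// Event-driven (Gillespie) simulation of the M x N lattice model.
//
// Every site holds one cell (strain 0/1, orientation 0 = vertical,
// 1 = horizontal). A vertical cell at row i divides up/down at rates
// v+(i) = lambda*exp(-kappa*(M-i)), v-(i) = lambda*exp(-kappa*(i-1))
// (1-based rows, row 1 at the bottom); horizontal cells divide left/right
// with the analogous column rates. The in-place daughter keeps the mother's
// site and orientation; the displacing daughter occupies the adjacent site
// in the division direction, flipping orientation with the Moore-average
// rotation probability; every cell beyond it shifts one site and the cell
// crossing the boundary is removed.
//
// Site rates depend only on (row/column, orientation), so a Fenwick tree over
// sites gives O(log MN) sampling and per-site updates after each shift.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct Fenwick {
  int n;
  std::vector<double> t;
  Fenwick(int n_) : n(n_), t(n_ + 1, 0.0) {}
  void add(int i, double d) { for (++i; i <= n; i += i & -i) t[i] += d; }
  double total() const { double s = 0; int i = n; while (i > 0) { s += t[i]; i -= i & -i; } return s; }
  // smallest index with prefix sum > u
  int find(double u) const {
    int pos = 0, lg = 1;
    while ((lg << 1) <= n) lg <<= 1;
    for (; lg > 0; lg >>= 1)
      if (pos + lg <= n && t[pos + lg] <= u) { pos += lg; u -= t[pos]; }
    return pos; // 0-based
  }
};

// [[Rcpp::export]]
List cpp_lm_run(IntegerMatrix strain0, IntegerMatrix orient0, double lambda,
                double kappa, NumericVector p_rot_pre, NumericVector p_rot_post,
                double induction_time, double t_end, double sample_dt, int seed,
                bool record_grids) {
  const int M = strain0.nrow(), N = strain0.ncol();
  std::vector<int> strain(M * N), orient(M * N);
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < N; ++j) {
      strain[i * N + j] = strain0(i, j);
      orient[i * N + j] = orient0(i, j);
    }
  std::vector<double> vp(M), vm(M), hp(N), hm(N);
  for (int i = 0; i < M; ++i) {
    vp[i] = lambda * std::exp(-kappa * (M - 1 - i));
    vm[i] = lambda * std::exp(-kappa * i);
  }
  for (int j = 0; j < N; ++j) {
    hp[j] = lambda * std::exp(-kappa * (N - 1 - j));
    hm[j] = lambda * std::exp(-kappa * j);
  }
  auto site_rate = [&](int i, int j) {
    return orient[i * N + j] == 0 ? vp[i] + vm[i] : hp[j] + hm[j];
  };
  Fenwick fw(M * N);
  std::vector<double> rates(M * N);
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < N; ++j) {
      rates[i * N + j] = site_rate(i, j);
      fw.add(i * N + j, rates[i * N + j]);
    }
  auto refresh_site = [&](int i, int j) {
    int idx = i * N + j;
    double r = site_rate(i, j);
    if (r != rates[idx]) { fw.add(idx, r - rates[idx]); rates[idx] = r; }
  };

  std::mt19937_64 rng((uint64_t)seed * 0x9E3779B97F4A7C15ull + 0xBF58476D1CE4E5B9ull);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<double> s_t, s_fo, s_fH, s_q, s_pb, s_po;
  std::vector<int> s_nb, s_no;
  List grids;

  auto sample_now = [&](double t) {
    int no = 0, nH = 0;
    double pb = 0, po = 0;
    for (int i = 0; i < M; ++i)
      for (int j = 0; j < N; ++j) {
        int s = i * N + j;
        if (strain[s] == 1) no++;
        if (orient[s] == 1) {
          nH++;
          double h = hp[j] + hm[j];
          if (strain[s] == 0) pb += h; else po += h;
        }
      }
    int nb = M * N - no;
    double fH = (double)nH / (M * N);
    s_t.push_back(t);
    s_fo.push_back((double)no / (M * N));
    s_fH.push_back(fH);
    s_q.push_back(std::fabs(2.0 * fH - 1.0));
    s_pb.push_back(nb > 0 ? pb / nb : NA_REAL);
    s_po.push_back(no > 0 ? po / no : NA_REAL);
    s_nb.push_back(nb); s_no.push_back(no);
    if (record_grids) {
      IntegerMatrix sg(M, N), og(M, N);
      for (int i = 0; i < M; ++i)
        for (int j = 0; j < N; ++j) {
          sg(i, j) = strain[i * N + j];
          og(i, j) = orient[i * N + j];
        }
      grids.push_back(List::create(_["t"] = t, _["strain"] = sg,
                                   _["orientation"] = og));
    }
  };

  double t = 0.0, next_sample = 0.0;
  long n_events = 0;
  while (true) {
    while (next_sample <= t + 1e-12 && next_sample <= t_end + 1e-9) {
      sample_now(next_sample);
      next_sample += sample_dt;
    }
    double R = fw.total();
    if (R <= 0) stop("total event rate is not positive");
    double dt = -std::log(1.0 - unif(rng)) / R;
    double t_new = t + dt;
    if (t_new > t_end) {
      while (next_sample <= t_end + 1e-9) { sample_now(next_sample); next_sample += sample_dt; }
      t = t_end;
      break;
    }
    // record samples crossed by this waiting time (state unchanged until event)
    while (next_sample <= t_new + 1e-12 && next_sample <= t_end + 1e-9) {
      sample_now(next_sample);
      next_sample += sample_dt;
    }
    t = t_new;
    ++n_events;

    int s = fw.find(unif(rng) * R);
    if (s >= M * N) s = M * N - 1;
    int i = s / N, j = s % N;
    int di = 0, dj = 0;
    if (orient[s] == 0) {
      double u = unif(rng) * (vp[i] + vm[i]);
      di = (u < vp[i]) ? 1 : -1;
    } else {
      double u = unif(rng) * (hp[j] + hm[j]);
      dj = (u < hp[j]) ? 1 : -1;
    }
    // Moore-average rotation probability (self + existing neighbors)
    const double *pr = (t >= induction_time) ? &p_rot_post[0] : &p_rot_pre[0];
    double psum = pr[strain[s]];
    int cnt = 1;
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b) {
        if (a == 0 && b == 0) continue;
        int ii = i + a, jj = j + b;
        if (ii < 0 || ii >= M || jj < 0 || jj >= N) continue;
        psum += pr[strain[ii * N + jj]];
        cnt++;
      }
    double p_eff = psum / cnt;
    int d_orient = orient[s];
    if (unif(rng) < p_eff) d_orient = 1 - d_orient;
    int d_strain = strain[s];

    // displacement shift (daughter outside the lattice is discarded)
    int ti = i + di, tj = j + dj;
    if (ti < 0 || ti >= M || tj < 0 || tj >= N) continue;
    if (di != 0) { // shift column j vertically
      if (di > 0) {
        for (int ii = M - 1; ii > ti; --ii) {
          strain[ii * N + j] = strain[(ii - 1) * N + j];
          orient[ii * N + j] = orient[(ii - 1) * N + j];
        }
      } else {
        for (int ii = 0; ii < ti; ++ii) {
          strain[ii * N + j] = strain[(ii + 1) * N + j];
          orient[ii * N + j] = orient[(ii + 1) * N + j];
        }
      }
      strain[ti * N + j] = d_strain; orient[ti * N + j] = d_orient;
      int lo = di > 0 ? ti : 0, hi = di > 0 ? M - 1 : ti;
      for (int ii = lo; ii <= hi; ++ii) refresh_site(ii, j);
    } else { // shift row i horizontally
      if (dj > 0) {
        for (int jj = N - 1; jj > tj; --jj) {
          strain[i * N + jj] = strain[i * N + (jj - 1)];
          orient[i * N + jj] = orient[i * N + (jj - 1)];
        }
      } else {
        for (int jj = 0; jj < tj; ++jj) {
          strain[i * N + jj] = strain[i * N + (jj + 1)];
          orient[i * N + jj] = orient[i * N + (jj + 1)];
        }
      }
      strain[i * N + tj] = d_strain; orient[i * N + tj] = d_orient;
      int lo = dj > 0 ? tj : 0, hi = dj > 0 ? N - 1 : tj;
      for (int jj = lo; jj <= hi; ++jj) refresh_site(i, jj);
    }
  }

  DataFrame summary = DataFrame::create(
      _["t"] = wrap(s_t), _["frac_orange"] = wrap(s_fo), _["f_H"] = wrap(s_fH),
      _["q"] = wrap(s_q), _["prop_blue"] = wrap(s_pb),
      _["prop_orange"] = wrap(s_po), _["n_blue"] = wrap(s_nb),
      _["n_orange"] = wrap(s_no));
  IntegerMatrix sg(M, N), og(M, N);
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < N; ++j) {
      sg(i, j) = strain[i * N + j];
      og(i, j) = orient[i * N + j];
    }
  List out = List::create(_["summary"] = summary, _["strain"] = sg,
                          _["orientation"] = og, _["t_final"] = t,
                          _["n_events"] = (double)n_events);
  if (record_grids) out["grids"] = grids;
  return out;
}
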