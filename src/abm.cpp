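// Agent-based engine: growing, dividing, mechanically interacting 2D
// spherocylinders in an open rectangular trap, optionally coupled to a
// well-mixed quorum-sensing signaling layer.
//
// Cells are spherocylinders of constant width w = 1 um; `l` is the total
// pole-to-pole length (axis segment length is l - w). Mechanics is a
// simplified Hookean contact scheme: linear repulsion proportional to the
// overlap depth between the closest points of the two axis segments, applied
// at the contact point with torque, relaxed by overdamped first-order updates
// until the maximum overlap drops below tolerance or an iteration cap.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static const double CELL_W = 1.0; // um, constant cell width

// wrap an angle to [0, pi) (nematic identification)
static inline double wrap_pi(double a) {
  return a - M_PI * std::floor(a / M_PI);
}

struct Cells {
  std::vector<double> x, y, phi, l, l0, ld, fax;
  std::vector<double> H1, H2, lac;   // intracellular concentrations
  std::vector<int> strain;           // 0 = blue, 1 = orange
  std::vector<int> id;
  std::vector<char> induced;         // division-length reduction active
  int next_id = 0;
  size_t n() const { return x.size(); }
  void reserve(size_t m) {
    x.reserve(m); y.reserve(m); phi.reserve(m); l.reserve(m); l0.reserve(m);
    ld.reserve(m); fax.reserve(m); H1.reserve(m); H2.reserve(m);
    lac.reserve(m); strain.reserve(m); id.reserve(m); induced.reserve(m);
  }
  void push(double xx, double yy, double pp, double ll, double ll0,
            double lld, int s, double h1, double h2, double lc) {
    x.push_back(xx); y.push_back(yy); phi.push_back(pp); l.push_back(ll);
    l0.push_back(ll0); ld.push_back(lld); fax.push_back(0.0);
    H1.push_back(h1); H2.push_back(h2); lac.push_back(lc);
    strain.push_back(s); id.push_back(next_id++); induced.push_back(0);
  }
  void remove(size_t i) { // swap with last and pop
    size_t m = n() - 1;
    x[i] = x[m]; y[i] = y[m]; phi[i] = phi[m]; l[i] = l[m]; l0[i] = l0[m];
    ld[i] = ld[m]; fax[i] = fax[m]; H1[i] = H1[m]; H2[i] = H2[m];
    lac[i] = lac[m]; strain[i] = strain[m]; id[i] = id[m];
    induced[i] = induced[m];
    x.pop_back(); y.pop_back(); phi.pop_back(); l.pop_back(); l0.pop_back();
    ld.pop_back(); fax.pop_back(); H1.pop_back(); H2.pop_back();
    lac.pop_back(); strain.pop_back(); id.pop_back(); induced.pop_back();
  }
};

// closest points between segments p1+s*d1 (s in [0,1]) and p2+t*d2
static double seg_closest(double p1x, double p1y, double q1x, double q1y,
                          double p2x, double p2y, double q2x, double q2y,
                          double &c1x, double &c1y, double &c2x, double &c2y) {
  const double d1x = q1x - p1x, d1y = q1y - p1y;
  const double d2x = q2x - p2x, d2y = q2y - p2y;
  const double rx = p1x - p2x, ry = p1y - p2y;
  const double a = d1x * d1x + d1y * d1y;
  const double e = d2x * d2x + d2y * d2y;
  const double f = d2x * rx + d2y * ry;
  double s, t;
  const double EPS = 1e-12;
  if (a <= EPS && e <= EPS) { s = t = 0.0; }
  else if (a <= EPS) { s = 0.0; t = std::min(1.0, std::max(0.0, f / e)); }
  else {
    const double c = d1x * rx + d1y * ry;
    if (e <= EPS) { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
    else {
      const double b = d1x * d2x + d1y * d2y;
      const double denom = a * e - b * b;
      s = (denom > EPS) ? std::min(1.0, std::max(0.0, (b * f - c * e) / denom)) : 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
      else if (t > 1.0) { t = 1.0; s = std::min(1.0, std::max(0.0, (b - c) / a)); }
    }
  }
  c1x = p1x + s * d1x; c1y = p1y + s * d1y;
  c2x = p2x + t * d2x; c2y = p2y + t * d2y;
  const double dx = c1x - c2x, dy = c1y - c2y;
  return std::sqrt(dx * dx + dy * dy);
}

struct MechParams {
  double k_n, zeta, tol, noise_sd;
  int max_iter;
};

// One full relaxation: returns iterations used; fills fax; sets *max_ov_out
static int relax_cells(Cells &c, double W, double H, const MechParams &mp,
                       std::mt19937_64 &rng, double *max_ov_out) {
  const size_t n = c.n();
  std::fill(c.fax.begin(), c.fax.end(), 0.0);
  if (n < 2) { if (max_ov_out) *max_ov_out = 0.0; return 0; }

  std::vector<double> fx(n), fy(n), tq(n), faxw(n);
  std::vector<double> ux(n), uy(n), hax(n);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  double lmax = CELL_W;
  for (size_t i = 0; i < n; ++i) lmax = std::max(lmax, c.l[i]);
  const double range = lmax;                 // max center distance at contact
  const double dtau = 0.2 * mp.zeta * CELL_W / mp.k_n;

  // spatial hash bins (cells can lie slightly outside the trap)
  const double pad = lmax;
  const double x0 = -pad, y0 = -pad;
  const int nbx = std::max(1, (int)std::floor((W + 2 * pad) / range));
  const int nby = std::max(1, (int)std::floor((H + 2 * pad) / range));
  const double bw = (W + 2 * pad) / nbx, bh = (H + 2 * pad) / nby;
  std::vector<int> head(nbx * nby), nxt(n);

  double max_ov = 0.0;
  int iter = 0;
  for (iter = 0; iter < mp.max_iter; ++iter) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(tq.begin(), tq.end(), 0.0);
    std::fill(faxw.begin(), faxw.end(), 0.0);
    for (size_t i = 0; i < n; ++i) {
      ux[i] = std::cos(c.phi[i]); uy[i] = std::sin(c.phi[i]);
      hax[i] = std::max(0.0, 0.5 * (c.l[i] - CELL_W));
    }
    std::fill(head.begin(), head.end(), -1);
    for (size_t i = 0; i < n; ++i) {
      int bxi = std::min(nbx - 1, std::max(0, (int)((c.x[i] - x0) / bw)));
      int byi = std::min(nby - 1, std::max(0, (int)((c.y[i] - y0) / bh)));
      int b = byi * nbx + bxi;
      nxt[i] = head[b]; head[b] = (int)i;
    }
    max_ov = 0.0;
    for (size_t i = 0; i < n; ++i) {
      int bxi = std::min(nbx - 1, std::max(0, (int)((c.x[i] - x0) / bw)));
      int byi = std::min(nby - 1, std::max(0, (int)((c.y[i] - y0) / bh)));
      for (int dby = -1; dby <= 1; ++dby) {
        int yb = byi + dby; if (yb < 0 || yb >= nby) continue;
        for (int dbx = -1; dbx <= 1; ++dbx) {
          int xb = bxi + dbx; if (xb < 0 || xb >= nbx) continue;
          for (int j = head[yb * nbx + xb]; j >= 0; j = nxt[j]) {
            if ((size_t)j <= i) continue;
            const double cdx = c.x[i] - c.x[j], cdy = c.y[i] - c.y[j];
            if (cdx * cdx + cdy * cdy > range * range) continue;
            double a1x = c.x[i] - hax[i] * ux[i], a1y = c.y[i] - hax[i] * uy[i];
            double b1x = c.x[i] + hax[i] * ux[i], b1y = c.y[i] + hax[i] * uy[i];
            double a2x = c.x[j] - hax[j] * ux[j], a2y = c.y[j] - hax[j] * uy[j];
            double b2x = c.x[j] + hax[j] * ux[j], b2y = c.y[j] + hax[j] * uy[j];
            double c1x, c1y, c2x, c2y;
            double dist = seg_closest(a1x, a1y, b1x, b1y, a2x, a2y, b2x, b2y,
                                      c1x, c1y, c2x, c2y);
            double ov = CELL_W - dist;
            if (ov <= 0.0) continue;
            if (ov > max_ov) max_ov = ov;
            double nx_, ny_;
            if (dist > 1e-9) { nx_ = (c1x - c2x) / dist; ny_ = (c1y - c2y) / dist; }
            else { double th = 2 * M_PI * unif(rng); nx_ = std::cos(th); ny_ = std::sin(th); }
            const double fmag = mp.k_n * ov;
            const double Fx = fmag * nx_, Fy = fmag * ny_;
            const double mx = 0.5 * (c1x + c2x), my = 0.5 * (c1y + c2y);
            fx[i] += Fx; fy[i] += Fy;
            fx[j] -= Fx; fy[j] -= Fy;
            tq[i] += (mx - c.x[i]) * Fy - (my - c.y[i]) * Fx;
            tq[j] -= (mx - c.x[j]) * Fy - (my - c.y[j]) * Fx;
            // inward axial component (growth-expansion force proxy)
            {
              double si = (mx - c.x[i]) * ux[i] + (my - c.y[i]) * uy[i];
              double ai = Fx * ux[i] + Fy * uy[i];
              if (si * ai < 0) faxw[i] += std::fabs(ai);
              double sj = (mx - c.x[j]) * ux[j] + (my - c.y[j]) * uy[j];
              double aj = -Fx * ux[j] - Fy * uy[j];
              if (sj * aj < 0) faxw[j] += std::fabs(aj);
            }
          }
        }
      }
    }
    for (size_t i = 0; i < n; ++i) c.fax[i] = 0.5 * faxw[i];
    if (max_ov < mp.tol) break;
    for (size_t i = 0; i < n; ++i) {
      const double mob = 1.0 / (mp.zeta * c.l[i]);
      double dx = fx[i] * mob * dtau, dy = fy[i] * mob * dtau;
      const double dn = std::sqrt(dx * dx + dy * dy);
      if (dn > 0.1 * CELL_W) { dx *= 0.1 * CELL_W / dn; dy *= 0.1 * CELL_W / dn; }
      c.x[i] += dx; c.y[i] += dy;
      const double mobr = 12.0 / (mp.zeta * c.l[i] * c.l[i] * c.l[i]);
      double dphi = tq[i] * mobr * dtau;
      if (dphi > 0.05) dphi = 0.05; else if (dphi < -0.05) dphi = -0.05;
      c.phi[i] += dphi;
      c.phi[i] = wrap_pi(c.phi[i]);
    }
  }
  if (max_ov_out) *max_ov_out = max_ov;
  return iter;
}

static Cells cells_from_df(DataFrame df) {
  NumericVector x = df["x"], y = df["y"], phi = df["phi"], l = df["l"];
  IntegerVector strain = df["strain"];
  bool has_l0 = df.containsElementNamed("l0");
  bool has_ld = df.containsElementNamed("ld");
  bool has_qs = df.containsElementNamed("H1");
  NumericVector l0, ld, H1, H2, lac;
  if (has_l0) l0 = df["l0"];
  if (has_ld) ld = df["ld"];
  if (has_qs) { H1 = df["H1"]; H2 = df["H2"]; lac = df["lacI"]; }
  Cells c;
  c.reserve(x.size());
  for (int i = 0; i < x.size(); ++i) {
    double li0 = has_l0 ? l0[i] : l[i] / 2.0;
    double lid = has_ld ? ld[i] : l[i];
    c.push(x[i], y[i], phi[i], l[i], li0, lid, strain[i],
           has_qs ? H1[i] : 0.0, has_qs ? H2[i] : 0.0, has_qs ? lac[i] : 0.0);
  }
  return c;
}

static DataFrame cells_to_df(const Cells &c) {
  const size_t n = c.n();
  NumericVector x(n), y(n), phi(n), l(n), l0(n), ld(n), fax(n), H1(n), H2(n), lac(n);
  IntegerVector strain(n), id(n), induced(n);
  for (size_t i = 0; i < n; ++i) {
    x[i] = c.x[i]; y[i] = c.y[i]; phi[i] = c.phi[i]; l[i] = c.l[i];
    l0[i] = c.l0[i]; ld[i] = c.ld[i]; fax[i] = c.fax[i];
    H1[i] = c.H1[i]; H2[i] = c.H2[i]; lac[i] = c.lac[i];
    strain[i] = c.strain[i]; id[i] = c.id[i]; induced[i] = c.induced[i];
  }
  return DataFrame::create(_["id"] = id, _["strain"] = strain, _["x"] = x,
                           _["y"] = y, _["phi"] = phi, _["l"] = l,
                           _["l0"] = l0, _["ld"] = ld, _["F_axial"] = fax,
                           _["H1"] = H1, _["H2"] = H2, _["lacI"] = lac,
                           _["induced"] = induced);
}

// [[Rcpp::export]]
List cpp_relax_cells(DataFrame cells, double width, double height,
                     double k_n, double zeta, double tol, int max_iter,
                     int seed) {
  Cells c = cells_from_df(cells);
  MechParams mp{k_n, zeta, tol, 0.0, max_iter};
  std::mt19937_64 rng(seed);
  double max_ov = 0.0;
  int it = relax_cells(c, width, height, mp, rng, &max_ov);
  return List::create(_["cells"] = cells_to_df(c), _["iterations"] = it,
                      _["max_overlap"] = max_ov,
                      _["converged"] = (max_ov < tol));
}

struct QSParamsC {
  bool enabled = false;
  double alpha[2] = {0, 0};  // production rate of own molecule, per strain
  double d[2] = {0, 0};      // membrane exchange rate per molecule
  double kex = 0, kex_ch = 0, gamma = 0;
  double KL = 1, mL = 2, KH = 1, mH = 2, beta = 0, deltaL = 0, HT = 1e9;
};

// [[Rcpp::export]]
List cpp_abm_run(DataFrame cells0, double width, double height,
                 NumericVector ldbar, NumericVector a_factor,
                 NumericVector doubling, NumericVector induce_time,
                 double dt, double k_n, double zeta, double tol, int max_iter,
                 double noise_sd, double t_end, double sample_dt, int seed,
                 int cap, List qs, bool stop_on_extinction,
                 bool record_cells) {
  Cells c = cells_from_df(cells0);
  MechParams mp{k_n, zeta, tol, noise_sd, max_iter};
  std::mt19937_64 rng((uint64_t)seed * 2654435761u + 1);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::normal_distribution<double> gauss(0.0, 1.0);

  QSParamsC qp;
  qp.enabled = as<bool>(qs["enabled"]);
  if (qp.enabled) {
    NumericVector al = qs["alpha"], dd = qs["d"];
    qp.alpha[0] = al[0]; qp.alpha[1] = al[1];
    qp.d[0] = dd[0]; qp.d[1] = dd[1];
    qp.kex = as<double>(qs["k_ex"]); qp.kex_ch = as<double>(qs["k_ex_channel"]);
    qp.gamma = as<double>(qs["gamma"]);
    qp.KL = as<double>(qs["K_L"]); qp.mL = as<double>(qs["m_L"]);
    qp.KH = as<double>(qs["K_H"]); qp.mH = as<double>(qs["m_H"]);
    qp.beta = as<double>(qs["beta"]); qp.deltaL = as<double>(qs["delta_L"]);
    qp.HT = as<double>(qs["H_T"]);
  }
  double He[2] = {0, 0}, Hch[2] = {0, 0};
  if (qp.enabled) {
    NumericVector he0 = qs["He0"], hc0 = qs["Hch0"];
    He[0] = he0[0]; He[1] = he0[1]; Hch[0] = hc0[0]; Hch[1] = hc0[1];
  }
  long clipped = 0;
  const double trap_area = width * height;

  // summary accumulators
  std::vector<double> s_t, s_focc, s_lacb, s_laco, s_he1, s_he2, s_fH;
  std::vector<int> s_n, s_nb, s_no;
  // per-cell snapshot accumulators
  std::vector<double> r_t, r_x, r_y, r_phi, r_l, r_fax, r_h1, r_h2, r_lac;
  std::vector<int> r_id, r_strain, r_ind;

  std::string status = "ok";
  double t = 0.0;
  double next_sample = 0.0;
  const long nsteps = (long)std::ceil(t_end / dt - 1e-9);

  auto effective_ldbar = [&](size_t i, double tt) {
    int s = c.strain[i];
    bool exo = tt >= induce_time[s];
    bool qsi = false;
    if (qp.enabled) {
      double hopp = (s == 0) ? c.H2[i] : c.H1[i];
      qsi = hopp > qp.HT;
    }
    c.induced[i] = (exo || qsi) ? 1 : 0;
    return (exo || qsi) ? a_factor[s] * ldbar[s] : ldbar[s];
  };

  auto sample_now = [&]() {
    size_t n = c.n();
    int nb = 0, nH = 0;
    double lb = 0, lo = 0;
    for (size_t i = 0; i < n; ++i) {
      if (c.strain[i] == 0) { nb++; lb += c.lac[i]; } else { lo += c.lac[i]; }
      double ph = wrap_pi(c.phi[i]);
      if (ph < M_PI / 4 || ph > 3 * M_PI / 4) nH++;
    }
    int no = (int)n - nb;
    s_t.push_back(t); s_n.push_back((int)n); s_nb.push_back(nb); s_no.push_back(no);
    s_focc.push_back(n ? (double)no / n : NA_REAL);
    s_lacb.push_back(nb ? lb / nb : NA_REAL);
    s_laco.push_back(no ? lo / no : NA_REAL);
    s_he1.push_back(He[0]); s_he2.push_back(He[1]);
    s_fH.push_back(n ? (double)nH / n : NA_REAL);
    if (record_cells) {
      for (size_t i = 0; i < n; ++i) {
        r_t.push_back(t); r_id.push_back(c.id[i]); r_strain.push_back(c.strain[i]);
        r_x.push_back(c.x[i]); r_y.push_back(c.y[i]); r_phi.push_back(c.phi[i]);
        r_l.push_back(c.l[i]); r_fax.push_back(c.fax[i]);
        r_h1.push_back(c.H1[i]); r_h2.push_back(c.H2[i]); r_lac.push_back(c.lac[i]);
        r_ind.push_back(c.induced[i]);
      }
    }
  };

  bool two_strain = false;
  {
    int nb = 0;
    for (size_t i = 0; i < c.n(); ++i) if (c.strain[i] == 0) nb++;
    two_strain = (nb > 0 && nb < (int)c.n());
  }

  for (long step = 0; step <= nsteps; ++step) {
    // sampling (state before this step's updates; t is current model time)
    if (t >= next_sample - 1e-9) {
      sample_now();
      next_sample += sample_dt;
    }
    if (step == nsteps) break;

    // 1. growth
    for (size_t i = 0; i < c.n(); ++i)
      c.l[i] *= std::pow(2.0, dt / doubling[c.strain[i]]);

    // 2. division targets from current effective mean division length
    for (size_t i = 0; i < c.n(); ++i) {
      double lde = effective_ldbar(i, t);
      c.ld[i] = std::sqrt(2.0 * c.l0[i] * lde);
    }

    // 3. divisions, in random order
    {
      std::vector<size_t> idx;
      for (size_t i = 0; i < c.n(); ++i) if (c.l[i] >= c.ld[i]) idx.push_back(i);
      std::shuffle(idx.begin(), idx.end(), rng);
      for (size_t k = 0; k < idx.size(); ++k) {
        size_t i = idx[k];
        double eps = 0.45 + 0.10 * unif(rng);
        double L = c.l[i];
        double lA = eps * L, lB = (1.0 - eps) * L;
        double ux_ = std::cos(c.phi[i]), uy_ = std::sin(c.phi[i]);
        double lde = effective_ldbar(i, t);
        // daughter A replaces the mother in place (near end of footprint)
        double cxA = c.x[i] - ux_ * (L - lA) / 2.0, cyA = c.y[i] - uy_ * (L - lA) / 2.0;
        double cxB = c.x[i] + ux_ * (L - lB) / 2.0, cyB = c.y[i] + uy_ * (L - lB) / 2.0;
        double phiA = c.phi[i] + noise_sd * gauss(rng);
        double phiB = c.phi[i] + noise_sd * gauss(rng);
        int s = c.strain[i];
        double h1 = c.H1[i], h2 = c.H2[i], lc = c.lac[i];
        c.x[i] = cxA; c.y[i] = cyA; c.phi[i] = phiA; c.l[i] = lA; c.l0[i] = lA;
        c.ld[i] = std::sqrt(2.0 * lA * lde);
        c.push(cxB, cyB, phiB, lB, lB, std::sqrt(2.0 * lB * lde), s, h1, h2, lc);
      }
    }
    if ((int)c.n() > cap) { status = "runaway"; break; }

    // 4. mechanical relaxation
    relax_cells(c, width, height, mp, rng, nullptr);

    // 5. remove cells whose center left the trap
    for (size_t i = 0; i < c.n();) {
      if (c.x[i] < 0 || c.x[i] > width || c.y[i] < 0 || c.y[i] > height)
        c.remove(i);
      else ++i;
    }

    // 6. quorum-sensing update (forward Euler, concentrations)
    if (qp.enabled) {
      double flux[2] = {0, 0};
      for (size_t i = 0; i < c.n(); ++i) {
        int s = c.strain[i];
        double area = c.l[i] * CELL_W;
        double rep = 1.0 / (1.0 + std::pow(c.lac[i] / qp.KL, qp.mL));
        double Hown = (s == 0) ? c.H1[i] : c.H2[i];
        double Hopp = (s == 0) ? c.H2[i] : c.H1[i];
        int mo = s, mop = 1 - s;
        double dHown = qp.alpha[s] * rep + qp.d[mo] * (He[mo] - Hown);
        double dHopp = qp.d[mop] * (He[mop] - Hopp);
        double hillH = std::pow(Hopp, qp.mH) /
                       (std::pow(qp.KH, qp.mH) + std::pow(Hopp, qp.mH));
        double dLac = qp.beta * hillH - qp.deltaL * c.lac[i];
        flux[mo] += area * qp.d[mo] * (Hown - He[mo]);
        flux[mop] += area * qp.d[mop] * (Hopp - He[mop]);
        double Hown2 = Hown + dt * dHown, Hopp2 = Hopp + dt * dHopp;
        double lac2 = c.lac[i] + dt * dLac;
        if (Hown2 < 0) { Hown2 = 0; clipped++; }
        if (Hopp2 < 0) { Hopp2 = 0; clipped++; }
        if (lac2 < 0) { lac2 = 0; clipped++; }
        if (s == 0) { c.H1[i] = Hown2; c.H2[i] = Hopp2; }
        else { c.H2[i] = Hown2; c.H1[i] = Hopp2; }
        c.lac[i] = lac2;
      }
      for (int m = 0; m < 2; ++m) {
        double dHe = flux[m] / trap_area - qp.kex * (He[m] - Hch[m]);
        double dHc = qp.kex_ch * (He[m] - Hch[m]) - qp.gamma * Hch[m];
        He[m] += dt * dHe; Hch[m] += dt * dHc;
        if (He[m] < 0) { He[m] = 0; clipped++; }
        if (Hch[m] < 0) { Hch[m] = 0; clipped++; }
      }
    }

    t += dt;

    if (c.n() == 0) { status = "empty"; break; }
    if (two_strain && stop_on_extinction) {
      int nb = 0;
      for (size_t i = 0; i < c.n(); ++i) if (c.strain[i] == 0) nb++;
      if (nb == 0 || nb == (int)c.n()) { status = "extinction"; break; }
    }
  }
  if (status != "ok") sample_now();

  DataFrame summary = DataFrame::create(
      _["t"] = wrap(s_t), _["n"] = wrap(s_n), _["n_blue"] = wrap(s_nb),
      _["n_orange"] = wrap(s_no), _["frac_orange"] = wrap(s_focc),
      _["f_H"] = wrap(s_fH), _["lacI_blue"] = wrap(s_lacb),
      _["lacI_orange"] = wrap(s_laco), _["He_1"] = wrap(s_he1),
      _["He_2"] = wrap(s_he2));
  List out = List::create(
      _["summary"] = summary, _["final_cells"] = cells_to_df(c),
      _["status"] = status, _["t_final"] = t, _["clipped"] = (double)clipped,
      _["He"] = NumericVector::create(He[0], He[1]),
      _["Hch"] = NumericVector::create(Hch[0], Hch[1]));
  if (record_cells) {
    out["cells"] = DataFrame::create(
        _["t"] = wrap(r_t), _["id"] = wrap(r_id), _["strain"] = wrap(r_strain),
        _["x"] = wrap(r_x), _["y"] = wrap(r_y), _["phi"] = wrap(r_phi),
        _["l"] = wrap(r_l), _["F_axial"] = wrap(r_fax), _["H1"] = wrap(r_h1),
        _["H2"] = wrap(r_h2), _["lacI"] = wrap(r_lac),
        _["induced"] = wrap(r_ind));
  }
  return out;
}

// [[Rcpp::export]]
double cpp_seg_distance(NumericVector s1, NumericVector s2) {
  double a, b, cc, d;
  return seg_closest(s1[0], s1[1], s1[2], s1[3], s2[0], s2[1], s2[2], s2[3],
                     a, b, cc, d);
}
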