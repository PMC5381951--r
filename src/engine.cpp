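// Coarse-grained engine: potential/force kernels, overdamped Langevin
// integrator with stochastic lateral-gate switching and ribosomal
// translation, and single-bead field evaluation for PMF quadrature.
//
// Units: lengths in sigma, energies in epsilon = kT(310 K), times in s.
// The trajectory RNG is a private mt19937_64 + Box-Muller stream so runs
// are bit-reproducible for a given seed, independent of R's RNG.
//
// Trajectories can run either with direct pairwise channel sums (exact,
// used for energy checks) or with the channel soft-core sums tabulated on
// a 3D grid and trilinearly interpolated (the partially tabulated
// potential used for production ensembles).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <random>

using namespace Rcpp;

// soft-core parameter row
struct SC {
  double eps, alpha, epscr, sigma, cut, cut2;
};

// sc row order: 0 LLLopen, 1 LLLclosed, 2 DDDopen, 3 DDDclosed,
// 4..7 confined variants in the same order, 8 out, 9 ribosome
struct Pars {
  SC sc[10];
  double K0, R0, elec_cut, dG_empty, D, dt, tauLG, t_trans;
};

struct Geom {
  int nch, nrb;
  std::vector<double> chp[2]; // [0]=closed, [1]=open; 3*nch each
  std::vector<double> chq;
  std::vector<int> chconf;
  std::vector<int> chq_idx;   // charged channel beads
  std::vector<double> rbp, rbq;
  std::vector<int> rbq_idx;   // charged ribosome beads
  double mem[3];              // radius, half_width, switch_width
  double ins[3], sph[3];
  bool sph_on;
};

static Pars parse_pars(const List& pl) {
  Pars p;
  NumericMatrix sc = pl["sc"];
  if (sc.nrow() != 10 || sc.ncol() != 5) stop("sc table must be 10x5");
  for (int i = 0; i < 10; ++i) {
    p.sc[i].eps = sc(i, 0);
    p.sc[i].alpha = sc(i, 1);
    p.sc[i].epscr = sc(i, 2);
    p.sc[i].sigma = sc(i, 4);
    p.sc[i].cut = sc(i, 3) * sc(i, 4);
    p.sc[i].cut2 = p.sc[i].cut * p.sc[i].cut;
  }
  p.K0 = as<double>(pl["K0"]);
  p.R0 = as<double>(pl["R0"]);
  p.elec_cut = as<double>(pl["elec_cutoff"]);
  p.dG_empty = as<double>(pl["dG_empty"]);
  p.D = as<double>(pl["D"]);
  p.dt = as<double>(pl["dt"]);
  p.tauLG = as<double>(pl["tau_LG"]);
  p.t_trans = as<double>(pl["t_trans"]);
  return p;
}

static Geom parse_geom(const List& gl) {
  Geom g;
  NumericMatrix cc = gl["ch_closed"], co = gl["ch_open"], rb = gl["ribo"];
  g.nch = cc.nrow();
  g.nrb = rb.nrow();
  g.chp[0].resize(3 * g.nch);
  g.chp[1].resize(3 * g.nch);
  for (int j = 0; j < g.nch; ++j) {
    for (int d = 0; d < 3; ++d) {
      g.chp[0][3 * j + d] = cc(j, d);
      g.chp[1][3 * j + d] = co(j, d);
    }
  }
  g.chq = as<std::vector<double>>(gl["ch_q"]);
  g.chconf = as<std::vector<int>>(gl["ch_conf"]);
  for (int j = 0; j < g.nch; ++j)
    if (g.chq[j] != 0.0) g.chq_idx.push_back(j);
  g.rbp.resize(3 * g.nrb);
  for (int j = 0; j < g.nrb; ++j)
    for (int d = 0; d < 3; ++d) g.rbp[3 * j + d] = rb(j, d);
  g.rbq = as<std::vector<double>>(gl["ribo_q"]);
  for (int j = 0; j < g.nrb; ++j)
    if (g.rbq[j] != 0.0) g.rbq_idx.push_back(j);
  NumericVector mem = gl["membrane"], ins = gl["insertion"], sph = gl["sphere"];
  for (int d = 0; d < 3; ++d) {
    g.mem[d] = mem[d];
    g.ins[d] = ins[d];
    g.sph[d] = sph[d];
  }
  g.sph_on = as<int>(gl["sphere_enabled"]) != 0;
  return g;
}

// soft-core potential; optionally dU/dr / r
static inline double sc_eval(const SC& p, double r2, double* dudr_r) {
  if (r2 >= p.cut2) {
    if (dudr_r) *dudr_r = 0.0;
    return 0.0;
  }
  double s2 = r2 / (p.sigma * p.sigma);
  double s6 = s2 * s2 * s2;
  double t = p.alpha + s6;
  double it = 1.0 / t;
  if (dudr_r) *dudr_r = 24.0 * p.eps * (it * it - 2.0 * it * it * it) * s6 / r2;
  return 4.0 * p.eps * (it * it - it) - p.epscr;
}

// 1D lookup tables for the radial and axial switching functions (linear
// interpolation; spacing 0.005 sigma, well below the 0.25 sigma switching
// width). Rebuilt whenever the membrane parameters change.
struct SwitchTab {
  double R = -1, H = -1, w = -1;
  double h = 0.005, rmax = 0, zmax = 0;
  std::vector<double> sxy, dsxy, sz, dsz;
  void build(const double* mem) {
    if (mem[0] == R && mem[1] == H && mem[2] == w) return;
    R = mem[0]; H = mem[1]; w = mem[2];
    rmax = R + 12.0 * w;
    zmax = H + 12.0 * w;
    int nr = (int)(rmax / h) + 2, nz = (int)(2 * zmax / h) + 2;
    sxy.resize(nr); dsxy.resize(nr); sz.resize(nz); dsz.resize(nz);
    for (int i = 0; i < nr; ++i) {
      double rho = i * h;
      double t1 = std::tanh((rho + R) / w), t2 = std::tanh((rho - R) / w);
      sxy[i] = 0.25 * (1.0 + t1) * (1.0 - t2);
      dsxy[i] = 0.25 * ((1.0 - t1 * t1) * (1.0 - t2) -
                        (1.0 + t1) * (1.0 - t2 * t2)) / w;
    }
    for (int i = 0; i < nz; ++i) {
      double z = -zmax + i * h;
      double t3 = std::tanh((z + H) / w), t4 = std::tanh((z - H) / w);
      sz[i] = 0.25 * (1.0 + t3) * (1.0 - t4);
      dsz[i] = 0.25 * ((1.0 - t3 * t3) * (1.0 - t4) -
                       (1.0 + t3) * (1.0 - t4 * t4)) / w;
    }
  }
  inline void lookup(const std::vector<double>& v, double f, int n,
                     double* out) const {
    int i = (int)f;
    if (i >= n - 1) { *out = v[n - 1]; return; }
    double a = f - i;
    *out = v[i] + a * (v[i + 1] - v[i]);
  }
  // S_mem and gradient
  inline double eval(double x, double y, double z, double* grad) const {
    double az = z + zmax;
    double SZ = 0, DSZ = 0;
    if (az <= 0 || z >= zmax) {
      if (grad) { grad[0] = grad[1] = grad[2] = 0; }
      return 0.0;
    }
    lookup(sz, az / h, (int)sz.size(), &SZ);
    double rho2 = x * x + y * y;
    double SXY = 0, DSXY = 0;
    double rho = 0;
    if (rho2 < rmax * rmax) {
      rho = std::sqrt(rho2);
      lookup(sxy, rho / h, (int)sxy.size(), &SXY);
      if (grad) lookup(dsxy, rho / h, (int)dsxy.size(), &DSXY);
    }
    double S = (1.0 - SXY) * SZ;
    if (grad) {
      lookup(dsz, az / h, (int)dsz.size(), &DSZ);
      double irho = rho > 1e-12 ? 1.0 / rho : 0.0;
      grad[0] = -DSXY * SZ * x * irho;
      grad[1] = -DSXY * SZ * y * irho;
      grad[2] = (1.0 - SXY) * DSZ;
    }
    return S;
  }
};

// membrane characteristic function and gradient
static inline double smem_eval(double x, double y, double z,
                               const double* mem, double* grad) {
  double R = mem[0], H = mem[1], w = mem[2];
  double rho = std::sqrt(x * x + y * y);
  double t1 = std::tanh((rho + R) / w), t2 = std::tanh((rho - R) / w);
  double sxy = 0.25 * (1.0 + t1) * (1.0 - t2);
  double t3 = std::tanh((z + H) / w), t4 = std::tanh((z - H) / w);
  double sz = 0.25 * (1.0 + t3) * (1.0 - t4);
  double S = (1.0 - sxy) * sz;
  if (grad) {
    double dsxy = 0.25 * ((1.0 - t1 * t1) * (1.0 - t2) -
                          (1.0 + t1) * (1.0 - t2 * t2)) / w;
    double dsz = 0.25 * ((1.0 - t3 * t3) * (1.0 - t4) -
                         (1.0 + t3) * (1.0 - t4 * t4)) / w;
    double irho = rho > 1e-12 ? 1.0 / rho : 0.0;
    grad[0] = -dsxy * sz * x * irho;
    grad[1] = -dsxy * sz * y * irho;
    grad[2] = (1.0 - sxy) * dsz;
  }
  return S;
}

// WCA repulsion (eps = sigma = 1); optionally dU/ds / s
static inline double wca_eval(double s, double* duds_s) {
  const double cut = 1.122462048309373; // 2^(1/6)
  if (s >= cut) {
    if (duds_s) *duds_s = 0.0;
    return 0.0;
  }
  double s2 = s * s;
  double i6 = 1.0 / (s2 * s2 * s2);
  if (duds_s) *duds_s = (-48.0 * i6 * i6 + 24.0 * i6) / s2;
  return 4.0 * (i6 * i6 - i6) + 1.0;
}

struct RNG {
  std::mt19937_64 eng;
  bool have = false;
  double spare = 0.0;
  explicit RNG(uint64_t seed) : eng(seed) {}
  double unif() {
    return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  // exact Box-Muller pair; deterministic for a given seed
  double norm() {
    if (have) { have = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586 * u2;
    spare = r * std::sin(th);
    have = true;
    return r * std::cos(th);
  }
};

// ---------------------------------------------------------------------------
// tabulated channel fields: A_LLL, A_DDD, B_out per gate on a regular grid

struct FieldGrid {
  bool on = false;
  int nx = 0, ny = 0, nz = 0;
  double x0 = 0, y0 = 0, z0 = 0, h = 1;
  NumericVector AL[2], AD[2], B[2]; // kept as R vectors to stay alive
  // interleaved copy: 7 values per node (AL,AD,B closed then open, plus
  // the gate-independent ribosome-bead repulsion) so one cell fetch
  // touches contiguous memory
  std::vector<double> packed;
  NumericVector RB;

  inline size_t idx(int ix, int iy, int iz) const {
    return ((size_t)ix * ny + iy) * nz + iz;
  }

  void pack() {
    size_t ntot = (size_t)nx * ny * nz;
    packed.resize(ntot * 7);
    const double* src[7] = {REAL(AL[0]), REAL(AD[0]), REAL(B[0]),
                            REAL(AL[1]), REAL(AD[1]), REAL(B[1]),
                            REAL(RB)};
    for (size_t k = 0; k < ntot; ++k)
      for (int c = 0; c < 7; ++c) packed[k * 7 + c] = src[c][k];
  }

  // trilinear values of all seven fields at once; gradients for the three
  // fields of gate `gt` (grad[0..2] = AL,AD,B) plus the ribosome field
  // (grad[3]). Returns false outside the grid.
  inline bool sample_all(double x, double y, double z, int gt,
                         double* vals, double (*grad)[3]) const {
    double fx = (x - x0) / h, fy = (y - y0) / h, fz = (z - z0) / h;
    if (fx < 0 || fy < 0 || fz < 0 ||
        fx >= nx - 1 || fy >= ny - 1 || fz >= nz - 1)
      return false;
    int ix = (int)fx, iy = (int)fy, iz = (int)fz;
    double ax = fx - ix, ay = fy - iy, az = fz - iz;
    const double* n000 = &packed[idx(ix, iy, iz) * 7];
    const double* n001 = &packed[idx(ix, iy, iz + 1) * 7];
    const double* n010 = &packed[idx(ix, iy + 1, iz) * 7];
    const double* n011 = &packed[idx(ix, iy + 1, iz + 1) * 7];
    const double* n100 = &packed[idx(ix + 1, iy, iz) * 7];
    const double* n101 = &packed[idx(ix + 1, iy, iz + 1) * 7];
    const double* n110 = &packed[idx(ix + 1, iy + 1, iz) * 7];
    const double* n111 = &packed[idx(ix + 1, iy + 1, iz + 1) * 7];
    for (int c = 0; c < 7; ++c) {
      double c00 = n000[c] + az * (n001[c] - n000[c]);
      double c01 = n010[c] + az * (n011[c] - n010[c]);
      double c10 = n100[c] + az * (n101[c] - n100[c]);
      double c11 = n110[c] + az * (n111[c] - n110[c]);
      double c0 = c00 + ay * (c01 - c00), c1 = c10 + ay * (c11 - c10);
      vals[c] = c0 + ax * (c1 - c0);
      bool want = grad && ((c >= gt * 3 && c < gt * 3 + 3) || c == 6);
      if (want) {
        int cc = c == 6 ? 3 : c - gt * 3;
        grad[cc][0] = (c1 - c0) / h;
        grad[cc][1] = ((1 - ax) * (c01 - c00) + ax * (c11 - c10)) / h;
        double e00 = n001[c] - n000[c], e01 = n011[c] - n010[c];
        double e10 = n101[c] - n100[c], e11 = n111[c] - n110[c];
        double e0 = e00 + ay * (e01 - e00), e1 = e10 + ay * (e11 - e10);
        grad[cc][2] = (e0 + ax * (e1 - e0)) / h;
      }
    }
    return true;
  }

};

static FieldGrid parse_grid(SEXP gsexp) {
  FieldGrid gr;
  if (Rf_isNull(gsexp)) return gr;
  List gl(gsexp);
  gr.on = true;
  NumericVector org = gl["origin"];
  gr.x0 = org[0]; gr.y0 = org[1]; gr.z0 = org[2];
  gr.h = as<double>(gl["spacing"]);
  IntegerVector dims = gl["dims"];
  gr.nx = dims[0]; gr.ny = dims[1]; gr.nz = dims[2];
  gr.AL[0] = as<NumericVector>(gl["AL_closed"]);
  gr.AL[1] = as<NumericVector>(gl["AL_open"]);
  gr.AD[0] = as<NumericVector>(gl["AD_closed"]);
  gr.AD[1] = as<NumericVector>(gl["AD_open"]);
  gr.B[0] = as<NumericVector>(gl["B_closed"]);
  gr.B[1] = as<NumericVector>(gl["B_open"]);
  gr.RB = as<NumericVector>(gl["RB"]);
  gr.pack();
  return gr;
}

// [[Rcpp::export]]
List cg_build_field_grid(List geom, List pars, double spacing,
                         NumericVector lower, NumericVector upper) {
  Geom g = parse_geom(geom);
  Pars p = parse_pars(pars);
  int nx = (int)std::ceil((upper[0] - lower[0]) / spacing) + 1;
  int ny = (int)std::ceil((upper[1] - lower[1]) / spacing) + 1;
  int nz = (int)std::ceil((upper[2] - lower[2]) / spacing) + 1;
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  List out = List::create(
    _["origin"] = lower, _["spacing"] = spacing,
    _["dims"] = IntegerVector::create(nx, ny, nz));
  const char* names[2][3] = {{"AL_closed", "AD_closed", "B_closed"},
                             {"AL_open", "AD_open", "B_open"}};
  for (int gt = 0; gt < 2; ++gt) {
    NumericVector AL(ntot), AD(ntot), B(ntot);
    R_xlen_t k = 0;
    int off = gt == 1 ? 0 : 1;
    for (int ix = 0; ix < nx; ++ix) {
      double x = lower[0] + ix * spacing;
      for (int iy = 0; iy < ny; ++iy) {
        double y = lower[1] + iy * spacing;
        for (int iz = 0; iz < nz; ++iz, ++k) {
          double z = lower[2] + iz * spacing;
          double al = 0, ad = 0, b = 0;
          for (int j = 0; j < g.nch; ++j) {
            const double* cj = &g.chp[gt][3 * j];
            double dx = x - cj[0], dy = y - cj[1], dz = z - cj[2];
            double r2 = dx * dx + dy * dy + dz * dz;
            int conf4 = g.chconf[j] ? 4 : 0;
            al += sc_eval(p.sc[0 + off + conf4], r2, nullptr);
            ad += sc_eval(p.sc[2 + off + conf4], r2, nullptr);
            b += sc_eval(p.sc[8], r2, nullptr);
          }
          AL[k] = al; AD[k] = ad; B[k] = b;
        }
      }
      Rcpp::checkUserInterrupt();
    }
    out[names[gt][0]] = AL;
    out[names[gt][1]] = AD;
    out[names[gt][2]] = B;
  }
  {
    NumericVector RB(ntot);
    R_xlen_t k = 0;
    for (int ix = 0; ix < nx; ++ix) {
      double x = lower[0] + ix * spacing;
      for (int iy = 0; iy < ny; ++iy) {
        double y = lower[1] + iy * spacing;
        for (int iz = 0; iz < nz; ++iz, ++k) {
          double z = lower[2] + iz * spacing;
          double rb = 0;
          for (int j = 0; j < g.nrb; ++j) {
            const double* cj = &g.rbp[3 * j];
            double dx = x - cj[0], dy = y - cj[1], dz = z - cj[2];
            rb += sc_eval(p.sc[9], dx * dx + dy * dy + dz * dz, nullptr);
          }
          RB[k] = rb;
        }
      }
    }
    out["RB"] = RB;
  }
  return out;
}

// ---------------------------------------------------------------------------
// simulation system

struct Sys {
  Geom g;
  Pars p;
  FieldGrid grid;
  SwitchTab stab;
  int n;                       // total beads in sequence
  std::vector<double> gi, qi, lo, lc;
  std::vector<double> x;       // 3*n positions
  int n_placed;                // beads with valid positions
  bool translating;            // last placed bead fixed & advancing
  double progress;             // time spent translating current bead
  int gate;                    // 0 closed, 1 open
  double time_s;

  int mobile_end() const { return translating ? n_placed - 1 : n_placed; }

  // channel soft-core sums A (lambda-mixed bases) and B (exterior) with
  // optional gradients; direct pairwise, or from the tabulated grid
  void chan_soft(int i, int gt, double* A, double* B,
                 double* FA, double* FB) {
    const double* xi = &x[3 * i];
    double lam = gt == 1 ? lo[i] : lc[i];
    *A = 0; *B = 0;
    if (FA) { FA[0] = FA[1] = FA[2] = 0; FB[0] = FB[1] = FB[2] = 0; }
    if (grid.on) {
      double vals[7], grads[4][3];
      bool in = grid.sample_all(xi[0], xi[1], xi[2], gt, vals,
                                FA ? grads : nullptr);
      if (!in) return; // outside the grid the channel terms vanish
      *A = lam * vals[gt * 3 + 0] + (1.0 - lam) * vals[gt * 3 + 1];
      *B = vals[gt * 3 + 2];
      if (FA) {
        for (int d = 0; d < 3; ++d) {
          FA[d] = lam * grads[0][d] + (1.0 - lam) * grads[1][d];
          FB[d] = grads[2][d];
        }
      }
      return;
    }
    int off = gt == 1 ? 0 : 1;
    for (int j = 0; j < g.nch; ++j) {
      const double* cj = &g.chp[gt][3 * j];
      double dx = xi[0] - cj[0], dy = xi[1] - cj[1], dz = xi[2] - cj[2];
      double r2 = dx * dx + dy * dy + dz * dz;
      int conf4 = g.chconf[j] ? 4 : 0;
      double dl, dd, dout;
      double ul = sc_eval(p.sc[0 + off + conf4], r2, FA ? &dl : nullptr);
      double ud = sc_eval(p.sc[2 + off + conf4], r2, FA ? &dd : nullptr);
      *A += lam * ul + (1.0 - lam) * ud;
      *B += sc_eval(p.sc[8], r2, FA ? &dout : nullptr);
      if (FA) {
        double cm = lam * dl + (1.0 - lam) * dd;
        FA[0] += cm * dx; FA[1] += cm * dy; FA[2] += cm * dz;
        FB[0] += dout * dx; FB[1] += dout * dy; FB[2] += dout * dz;
      }
    }
  }

  // electrostatics of NC bead i with the charged fixed beads (channel in
  // the given gate conformation, plus ribosome)
  double fixed_elec(int i, int gt, double* F) {
    if (qi[i] == 0.0) return 0.0;
    const double* xi = &x[3 * i];
    double ec2 = p.elec_cut * p.elec_cut;
    double U = 0.0;
    for (size_t k = 0; k < g.chq_idx.size(); ++k) {
      int j = g.chq_idx[k];
      const double* cj = &g.chp[gt][3 * j];
      double dx = xi[0] - cj[0], dy = xi[1] - cj[1], dz = xi[2] - cj[2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= ec2) continue;
      double r = std::sqrt(r2);
      double ue = qi[i] * g.chq[j] * std::exp(-r) / r;
      U += ue;
      if (F) {
        double dr = -ue * (1.0 + 1.0 / r) / r;
        F[0] -= dr * dx; F[1] -= dr * dy; F[2] -= dr * dz;
      }
    }
    for (size_t k = 0; k < g.rbq_idx.size(); ++k) {
      int j = g.rbq_idx[k];
      const double* cj = &g.rbp[3 * j];
      double dx = xi[0] - cj[0], dy = xi[1] - cj[1], dz = xi[2] - cj[2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= ec2) continue;
      double r = std::sqrt(r2);
      double ue = qi[i] * g.rbq[j] * std::exp(-r) / r;
      U += ue;
      if (F) {
        double dr = -ue * (1.0 + 1.0 / r) / r;
        F[0] -= dr * dx; F[1] -= dr * dy; F[2] -= dr * dz;
      }
    }
    return U;
  }

  // ribosome bead repulsion + repulsive sphere for bead i (gate independent)
  double ribo_terms(int i, double* F) {
    const double* xi = &x[3 * i];
    double U = 0.0;
    for (int j = 0; j < g.nrb; ++j) {
      const double* cj = &g.rbp[3 * j];
      double dx = xi[0] - cj[0], dy = xi[1] - cj[1], dz = xi[2] - cj[2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= p.sc[9].cut2) continue;
      double du;
      U += sc_eval(p.sc[9], r2, F ? &du : nullptr);
      if (F) {
        F[0] -= du * dx; F[1] -= du * dy; F[2] -= du * dz;
      }
    }
    if (g.sph_on) {
      double dx = xi[0] - g.sph[0], dy = xi[1] - g.sph[1], dz = xi[2] - g.sph[2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double s = r - 2.0;
      if (s < 1.122462048309373) {
        if (s <= 1e-9) s = 1e-9;
        double duds_s;
        U += wca_eval(s, F ? &duds_s : nullptr);
        if (F && r > 1e-12) {
          double f = duds_s * s / r;
          F[0] -= f * dx; F[1] -= f * dy; F[2] -= f * dz;
        }
      }
    }
    return U;
  }

  // NC-NC terms: FENE bonds, WCA, electrostatics
  double chain_terms(double* F, double* e_bond, double* e_excl,
                     double* e_elec) {
    double Ub = 0.0, Ux = 0.0, Ue = 0.0;
    double ec2 = p.elec_cut * p.elec_cut;
    double R02 = p.R0 * p.R0;
    for (int i = 0; i < n_placed; ++i) {
      const double* xi = &x[3 * i];
      for (int j = i + 1; j < n_placed; ++j) {
        const double* xj = &x[3 * j];
        double dx = xi[0] - xj[0], dy = xi[1] - xj[1], dz = xi[2] - xj[2];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (j == i + 1) {
          if (r2 >= R02) stop("FENE bond overstretched (r >= R0)");
          double fr = 1.0 - r2 / R02;
          Ub += -0.5 * p.K0 * R02 * std::log(fr);
          if (F) {
            double k = p.K0 / fr; // dU/dr / r
            F[3 * i + 0] -= k * dx; F[3 * i + 1] -= k * dy;
            F[3 * i + 2] -= k * dz;
            F[3 * j + 0] += k * dx; F[3 * j + 1] += k * dy;
            F[3 * j + 2] += k * dz;
          }
        }
        if (r2 < 1.259921049894873) { // 2^(1/3) = WCA cutoff squared
          double r = std::sqrt(r2);
          double duds_s;
          Ux += wca_eval(r, F ? &duds_s : nullptr);
          if (F) {
            F[3 * i + 0] -= duds_s * dx; F[3 * i + 1] -= duds_s * dy;
            F[3 * i + 2] -= duds_s * dz;
            F[3 * j + 0] += duds_s * dx; F[3 * j + 1] += duds_s * dy;
            F[3 * j + 2] += duds_s * dz;
          }
        }
        if (qi[i] != 0.0 && qi[j] != 0.0 && r2 < ec2) {
          double r = std::sqrt(r2);
          double ue = qi[i] * qi[j] * std::exp(-r) / r;
          Ue += ue;
          if (F) {
            double dr = -ue * (1.0 + 1.0 / r) / r;
            F[3 * i + 0] -= dr * dx; F[3 * i + 1] -= dr * dy;
            F[3 * i + 2] -= dr * dz;
            F[3 * j + 0] += dr * dx; F[3 * j + 1] += dr * dy;
            F[3 * j + 2] += dr * dz;
          }
        }
      }
    }
    if (e_bond) *e_bond = Ub;
    if (e_excl) *e_excl = Ux;
    if (e_elec) *e_elec = Ue;
    return Ub + Ux + Ue;
  }

  // repulsive sphere only (used when the ribosome beads come from the grid)
  void sphere_term(int i, double* F) {
    if (!g.sph_on) return;
    const double* xi = &x[3 * i];
    double dx = xi[0] - g.sph[0], dy = xi[1] - g.sph[1], dz = xi[2] - g.sph[2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double s = r - 2.0;
    if (s < 1.122462048309373 && r > 1e-12) {
      if (s <= 1e-9) s = 1e-9;
      double duds_s;
      wca_eval(s, &duds_s);
      double f = duds_s * s / r;
      F[0] -= f * dx; F[1] -= f * dy; F[2] -= f * dz;
    }
  }

  // forces on all placed beads for the current gate
  void compute_forces(std::vector<double>& F) {
    std::fill(F.begin(), F.end(), 0.0);
    chain_terms(F.data(), nullptr, nullptr, nullptr);
    for (int i = 0; i < n_placed; ++i) {
      double gradS[3];
      double S = smem_eval(x[3 * i], x[3 * i + 1], x[3 * i + 2], g.mem, gradS);
      double* Fi = &F[3 * i];
      if (grid.on) {
        double vals[7], grads[4][3];
        if (grid.sample_all(x[3 * i], x[3 * i + 1], x[3 * i + 2], gate,
                            vals, grads)) {
          double lam = gate == 1 ? lo[i] : lc[i];
          double A = lam * vals[gate * 3 + 0] + (1.0 - lam) * vals[gate * 3 + 1];
          double B = vals[gate * 3 + 2];
          for (int d = 0; d < 3; ++d) {
            double FAd = lam * grads[0][d] + (1.0 - lam) * grads[1][d];
            Fi[d] -= (1.0 - S) * FAd + S * grads[2][d];
            Fi[d] -= (B - A + gi[i]) * gradS[d];
            Fi[d] -= grads[3][d];
          }
        } else {
          for (int d = 0; d < 3; ++d) Fi[d] -= gi[i] * gradS[d];
        }
        fixed_elec(i, gate, Fi);
        sphere_term(i, Fi);
      } else {
        double A, B, FA[3], FB[3];
        chan_soft(i, gate, &A, &B, FA, FB);
        for (int d = 0; d < 3; ++d) {
          Fi[d] -= (1.0 - S) * FA[d] + S * FB[d];
          Fi[d] -= (B - A + gi[i]) * gradS[d];
        }
        fixed_elec(i, gate, Fi);
        ribo_terms(i, Fi);
      }
    }
  }

  // fused per-step pass: forces for the current gate plus the channel
  // energy difference U_chan(open) - U_chan(closed), evaluated at the same
  // configuration as the forces; one membrane evaluation and one grid
  // fetch per bead
  double forces_and_dU(std::vector<double>& F) {
    std::fill(F.begin(), F.begin() + 3 * n_placed, 0.0);
    chain_terms(F.data(), nullptr, nullptr, nullptr);
    double Uo = 0.0, Uc = 0.0;
    for (int i = 0; i < n_placed; ++i) {
      double* Fi = &F[3 * i];
      double gradS[3];
      double S = stab.eval(x[3 * i], x[3 * i + 1], x[3 * i + 2], gradS);
      if (grid.on) {
        double vals[7], grads[4][3];
        if (grid.sample_all(x[3 * i], x[3 * i + 1], x[3 * i + 2], gate,
                            vals, grads)) {
          double A2[2], B2[2];
          for (int gt = 0; gt < 2; ++gt) {
            double lam = gt == 1 ? lo[i] : lc[i];
            A2[gt] = lam * vals[gt * 3 + 0] + (1.0 - lam) * vals[gt * 3 + 1];
            B2[gt] = vals[gt * 3 + 2];
          }
          double lam = gate == 1 ? lo[i] : lc[i];
          for (int d = 0; d < 3; ++d) {
            double FAd = lam * grads[0][d] + (1.0 - lam) * grads[1][d];
            Fi[d] -= (1.0 - S) * FAd + S * grads[2][d];
            Fi[d] -= (B2[gate] - A2[gate] + gi[i]) * gradS[d];
            Fi[d] -= grads[3][d];
          }
          Uo += (1.0 - S) * A2[1] + S * B2[1];
          Uc += (1.0 - S) * A2[0] + S * B2[0];
        } else if (S > 0.0 || gi[i] != 0.0) {
          for (int d = 0; d < 3; ++d) Fi[d] -= gi[i] * gradS[d];
        }
        if (qi[i] != 0.0) {
          double Ue_cur = fixed_elec(i, gate, Fi);
          double Ue_oth = fixed_elec(i, 1 - gate, nullptr);
          if (gate == 1) { Uo += Ue_cur; Uc += Ue_oth; }
          else { Uc += Ue_cur; Uo += Ue_oth; }
        }
        sphere_term(i, Fi);
      } else {
        double A2[2], B2[2], FA[3], FB[3];
        chan_soft(i, gate, &A2[gate], &B2[gate], FA, FB);
        chan_soft(i, 1 - gate, &A2[1 - gate], &B2[1 - gate], nullptr,
                  nullptr);
        for (int d = 0; d < 3; ++d) {
          Fi[d] -= (1.0 - S) * FA[d] + S * FB[d];
          Fi[d] -= (B2[gate] - A2[gate] + gi[i]) * gradS[d];
        }
        Uo += (1.0 - S) * A2[1] + S * B2[1];
        Uc += (1.0 - S) * A2[0] + S * B2[0];
        if (qi[i] != 0.0) {
          double Ue_cur = fixed_elec(i, gate, Fi);
          double Ue_oth = fixed_elec(i, 1 - gate, nullptr);
          if (gate == 1) { Uo += Ue_cur; Uc += Ue_oth; }
          else { Uc += Ue_cur; Uo += Ue_oth; }
        }
        ribo_terms(i, Fi);
      }
    }
    return Uo - Uc;
  }

  // channel energy difference U_chan(open) - U_chan(closed): one membrane
  // evaluation and one grid fetch per bead
  double gate_dU() {
    double Uo = 0.0, Uc = 0.0;
    for (int i = 0; i < n_placed; ++i) {
      double S = smem_eval(x[3 * i], x[3 * i + 1], x[3 * i + 2], g.mem,
                           nullptr);
      double A2[2], B2[2];
      if (grid.on) {
        double vals[7];
        if (grid.sample_all(x[3 * i], x[3 * i + 1], x[3 * i + 2], 0, vals,
                            nullptr)) {
          for (int gt = 0; gt < 2; ++gt) {
            double lam = gt == 1 ? lo[i] : lc[i];
            A2[gt] = lam * vals[gt * 3 + 0] + (1.0 - lam) * vals[gt * 3 + 1];
            B2[gt] = vals[gt * 3 + 2];
          }
        } else {
          A2[0] = A2[1] = B2[0] = B2[1] = 0.0;
        }
      } else {
        chan_soft(i, 0, &A2[0], &B2[0], nullptr, nullptr);
        chan_soft(i, 1, &A2[1], &B2[1], nullptr, nullptr);
      }
      Uo += (1.0 - S) * A2[1] + S * B2[1];
      Uc += (1.0 - S) * A2[0] + S * B2[0];
      if (qi[i] != 0.0) {
        Uo += fixed_elec(i, 1, nullptr);
        Uc += fixed_elec(i, 0, nullptr);
      }
    }
    return Uo - Uc;
  }

  // channel + fixed-charge electrostatic energy for a gate state
  double chan_energy(int gt) {
    double U = 0.0;
    for (int i = 0; i < n_placed; ++i) {
      double S = smem_eval(x[3 * i], x[3 * i + 1], x[3 * i + 2], g.mem,
                           nullptr);
      double A, B;
      chan_soft(i, gt, &A, &B, nullptr, nullptr);
      U += (1.0 - S) * A + S * B + fixed_elec(i, gt, nullptr);
    }
    return U;
  }
};

static Sys make_sys(NumericMatrix pos, NumericVector gi, NumericVector qi,
                    NumericVector lo, NumericVector lc, int gate,
                    const List& geom, const List& pars,
                    SEXP grid = R_NilValue) {
  Sys s;
  s.g = parse_geom(geom);
  s.p = parse_pars(pars);
  s.grid = parse_grid(grid);
  s.n = pos.nrow();
  s.gi = as<std::vector<double>>(gi);
  s.qi = as<std::vector<double>>(qi);
  s.lo = as<std::vector<double>>(lo);
  s.lc = as<std::vector<double>>(lc);
  s.x.resize(3 * s.n);
  s.n_placed = s.n;
  for (int i = 0; i < s.n; ++i) {
    for (int d = 0; d < 3; ++d) s.x[3 * i + d] = pos(i, d);
    if (!R_finite(pos(i, 0))) { s.n_placed = i; break; }
  }
  s.translating = false;
  s.progress = 0.0;
  s.gate = gate;
  s.time_s = 0.0;
  s.stab.build(s.g.mem);
  return s;
}

// exact per-term energies (direct sums; the grid is never used here)
// [[Rcpp::export]]
List cg_energy(NumericMatrix pos, NumericVector gi, NumericVector qi,
               NumericVector lo, NumericVector lc, int gate,
               List geom, List pars) {
  Sys s = make_sys(pos, gi, qi, lo, lc, gate, geom, pars);
  double eb, ex, ee;
  s.chain_terms(nullptr, &eb, &ex, &ee);
  double solv = 0.0, chan = 0.0, ribo = 0.0, elec_fixed = 0.0;
  for (int i = 0; i < s.n_placed; ++i) {
    double S = smem_eval(s.x[3 * i], s.x[3 * i + 1], s.x[3 * i + 2],
                         s.g.mem, nullptr);
    solv += s.gi[i] * S;
    double A, B;
    s.chan_soft(i, gate, &A, &B, nullptr, nullptr);
    chan += (1.0 - S) * A + S * B;
    elec_fixed += s.fixed_elec(i, gate, nullptr);
    ribo += s.ribo_terms(i, nullptr);
  }
  return List::create(
    _["bond"] = eb, _["excl"] = ex, _["elec"] = ee + elec_fixed,
    _["solv"] = solv, _["chan"] = chan, _["ribo"] = ribo);
}

// [[Rcpp::export]]
double cg_delta_g_open(NumericMatrix pos, NumericVector gi, NumericVector qi,
                       NumericVector lo, NumericVector lc,
                       List geom, List pars) {
  Sys s = make_sys(pos, gi, qi, lo, lc, 0, geom, pars);
  return s.p.dG_empty + s.chan_energy(1) - s.chan_energy(0);
}

// [[Rcpp::export]]
NumericMatrix cg_forces(NumericMatrix pos, NumericVector gi, NumericVector qi,
                        NumericVector lo, NumericVector lc, int gate,
                        List geom, List pars) {
  Sys s = make_sys(pos, gi, qi, lo, lc, gate, geom, pars);
  std::vector<double> F(3 * s.n, 0.0);
  s.compute_forces(F);
  NumericMatrix out(s.n, 3);
  for (int i = 0; i < s.n; ++i)
    for (int d = 0; d < 3; ++d)
      out(i, d) = i < s.n_placed ? F[3 * i + d] : NA_REAL;
  return out;
}

// single-bead field components on a set of points; columns:
// S_mem, A_LLL, A_DDD, B_out, elec (per unit charge), ribo
// [[Rcpp::export]]
NumericMatrix cg_single_bead_fields(NumericMatrix pts, int gate,
                                    List geom, List pars) {
  Geom g = parse_geom(geom);
  Pars p = parse_pars(pars);
  int m = pts.nrow();
  NumericMatrix out(m, 6);
  int off = gate == 1 ? 0 : 1;
  double ec2 = p.elec_cut * p.elec_cut;
  for (int i = 0; i < m; ++i) {
    double xi[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double S = smem_eval(xi[0], xi[1], xi[2], g.mem, nullptr);
    double AL = 0.0, AD = 0.0, B = 0.0, E = 0.0, Rb = 0.0;
    for (int j = 0; j < g.nch; ++j) {
      const double* cj = &g.chp[gate][3 * j];
      double dx = xi[0] - cj[0], dy = xi[1] - cj[1], dz = xi[2] - cj[2];
      double r2 = dx * dx + dy * dy + dz * dz;
      int conf4 = g.chconf[j] ? 4 : 0;
      AL += sc_eval(p.sc[0 + off + conf4], r2, nullptr);
      AD += sc_eval(p.sc[2 + off + conf4], r2, nullptr);
      B += sc_eval(p.sc[8], r2, nullptr);
      if (g.chq[j] != 0.0 && r2 < ec2) {
        double r = std::sqrt(r2);
        E += g.chq[j] * std::exp(-r) / r;
      }
    }
    for (int j = 0; j < g.nrb; ++j) {
      const double* cj = &g.rbp[3 * j];
      double dx = xi[0] - cj[0], dy = xi[1] - cj[1], dz = xi[2] - cj[2];
      double r2 = dx * dx + dy * dy + dz * dz;
      Rb += sc_eval(p.sc[9], r2, nullptr);
      if (g.rbq[j] != 0.0 && r2 < ec2) {
        double r = std::sqrt(r2);
        E += g.rbq[j] * std::exp(-r) / r;
      }
    }
    if (g.sph_on) {
      double dx = xi[0] - g.sph[0], dy = xi[1] - g.sph[1], dz = xi[2] - g.sph[2];
      double s = std::sqrt(dx * dx + dy * dy + dz * dz) - 2.0;
      if (s <= 1e-9) s = 1e-9;
      Rb += wca_eval(s, nullptr);
    }
    out(i, 0) = S; out(i, 1) = AL; out(i, 2) = AD;
    out(i, 3) = B; out(i, 4) = E; out(i, 5) = Rb;
  }
  return out;
}

// ---------------------------------------------------------------------------
// trajectory loop

// outcome codes: 0 none/guard, 1 integration, 2 translocation,
// 3 type1, 4 type2
static int check_termination(const Sys& s, int mode, int h0, int h1,
                             double clearance, double margin,
                             double topo_clear) {
  if (mode == 0) return -1;
  double H = s.g.mem[1]; // slab half-width
  if (mode == 1) {
    if (h1 >= s.mobile_end()) return -1; // H-segment not fully released
    bool all_lumen = true;
    for (int i = h0; i <= h1; ++i) {
      if (s.x[3 * i + 2] >= -(H + margin)) { all_lumen = false; break; }
    }
    if (all_lumen) return 2;
    bool in_slab = true;
    for (int i = h0; i <= h1; ++i) {
      if (std::fabs(s.x[3 * i + 2]) > H + margin) { in_slab = false; break; }
    }
    if (!in_slab) return -1;
    // flanking beads on opposite sides of the midplane
    if (h0 > 0 && h1 + 1 < s.n_placed) {
      if (s.x[3 * (h0 - 1) + 2] * s.x[3 * (h1 + 1) + 2] >= 0.0) return -1;
    }
    // clearance from every channel bead (current conformation)
    double c2 = clearance * clearance;
    for (int i = h0; i <= h1; ++i) {
      const double* xi = &s.x[3 * i];
      for (int j = 0; j < s.g.nch; ++j) {
        const double* cj = &s.g.chp[s.gate][3 * j];
        double dx = xi[0] - cj[0], dy = xi[1] - cj[1], dz = xi[2] - cj[2];
        if (dx * dx + dy * dy + dz * dz < c2) return -1;
      }
    }
    return 1;
  }
  if (mode == 2) {
    if (s.translating || s.n_placed < s.n) return -1;
    bool in_slab = true;
    for (int i = h0; i <= h1; ++i) {
      if (std::fabs(s.x[3 * i + 2]) > H + margin) { in_slab = false; break; }
    }
    if (!in_slab) return -1;
    double c2 = topo_clear * topo_clear;
    for (int i = h0; i <= h1; ++i) {
      const double* xi = &s.x[3 * i];
      for (int j = 0; j < s.g.nch; ++j) {
        const double* cj = &s.g.chp[s.gate][3 * j];
        double dx = xi[0] - cj[0], dy = xi[1] - cj[1], dz = xi[2] - cj[2];
        if (dx * dx + dy * dy + dz * dz < c2) return -1;
      }
    }
    double zc = s.x[3 * (s.n - 1) + 2];
    if (zc < -H) return 4; // C-terminus lumenal: type 2
    if (zc > H) return 3;  // C-terminus cytosolic: type 1
    return -1;
  }
  return -1;
}

// [[Rcpp::export]]
List cg_run_trajectory(NumericMatrix pos, NumericVector gi, NumericVector qi,
                       NumericVector lo, NumericVector lc,
                       int gate, int n_placed, bool translating,
                       double progress, List geom, List pars,
                       double seed, double max_steps, int term_mode,
                       int h0, int h1, double clearance, double margin,
                       double topo_clear, double save_every,
                       SEXP field_grid) {
  Sys s = make_sys(pos, gi, qi, lo, lc, gate, geom, pars, field_grid);
  s.n_placed = n_placed;
  s.translating = translating && n_placed > 0 && n_placed <= s.n;
  s.progress = progress;
  RNG rng(static_cast<uint64_t>(seed));

  long long nstep_max = static_cast<long long>(max_steps);
  long long step = 0;
  long long n_open = 0, n_flips = 0, n_redraws = 0;
  int outcome = 0;
  bool finished = false;

  std::vector<double> F(3 * s.n), xtrial(3 * s.n);
  std::vector<double> rel;
  long long sv = save_every > 0 ? static_cast<long long>(save_every) : 0;
  std::vector<double> frames;
  std::vector<double> frame_times;
  double sqrt2Ddt = std::sqrt(2.0 * s.p.D * s.p.dt);
  double Ddt = s.p.D * s.p.dt;
  double pref = s.p.dt / s.p.tauLG;
  if (pref > 1.0) stop("dt/tau_LG must be <= 1 for valid gating probabilities");

  auto save_frame = [&]() {
    if (!sv) return;
    for (int i = 0; i < s.n; ++i)
      for (int d = 0; d < 3; ++d)
        frames.push_back(i < s.n_placed ? s.x[3 * i + d] : NA_REAL);
    frame_times.push_back(s.time_s);
  };
  save_frame();

  while (step < nstep_max) {
    ++step;
    int me = s.mobile_end();
    // (i) forces, together with the gate energy difference at the same
    // configuration (used by the gating attempt below)
    double dU = s.forces_and_dU(F);
    // (ii) Langevin move (in place; reverted and redrawn in the rare case
    // a FENE bond would overstretch)
    std::copy(s.x.begin(), s.x.begin() + 3 * me, xtrial.begin());
    int tries = 0;
    while (true) {
      for (int i = 0; i < me; ++i) {
        // cap the deterministic drift at 0.25 sigma per step: the steep
        // excluded-volume wall can otherwise catapult freshly placed,
        // transiently overlapping beads
        double drift[3], dn2 = 0.0;
        for (int d = 0; d < 3; ++d) {
          drift[d] = Ddt * F[3 * i + d];
          dn2 += drift[d] * drift[d];
        }
        if (dn2 > 0.0625) {
          double scl = 0.25 / std::sqrt(dn2);
          for (int d = 0; d < 3; ++d) drift[d] *= scl;
        }
        for (int d = 0; d < 3; ++d) {
          double nx = xtrial[3 * i + d] + drift[d] + sqrt2Ddt * rng.norm();
          if (!R_finite(nx)) stop("non-finite displacement in Langevin step");
          s.x[3 * i + d] = nx;
        }
      }
      bool bad = false;
      double R02 = s.p.R0 * s.p.R0;
      for (int i = 0; i + 1 < s.n_placed; ++i) {
        double dx = s.x[3 * i] - s.x[3 * i + 3];
        double dy = s.x[3 * i + 1] - s.x[3 * i + 4];
        double dz = s.x[3 * i + 2] - s.x[3 * i + 5];
        if (dx * dx + dy * dy + dz * dz >= R02) { bad = true; break; }
      }
      if (!bad) break;
      if (++tries > 100) stop("FENE bond repeatedly overstretched");
      ++n_redraws;
      std::copy(xtrial.begin(), xtrial.begin() + 3 * me, s.x.begin());
    }
    // (iii) gating attempt
    {
      double dG = s.p.dG_empty + dU;
      double u = rng.unif();
      if (s.gate == 0) {
        double e = std::exp(-dG);
        double popen = pref * e / (1.0 + e);
        if (u < popen) { s.gate = 1; ++n_flips; }
      } else {
        double pclose = pref * 1.0 / (1.0 + std::exp(-dG));
        if (u < pclose) { s.gate = 0; ++n_flips; }
      }
    }
    if (s.gate == 1) ++n_open;
    // (iv) translation
    if (s.translating) {
      int tb = s.n_placed - 1;
      s.x[3 * tb + 2] += s.p.dt / s.p.t_trans;
      s.progress += s.p.dt;
      if (s.progress >= s.p.t_trans - 0.5 * s.p.dt) {
        rel.push_back(s.time_s);
        if (s.n_placed < s.n) {
          int nb = s.n_placed;
          s.x[3 * nb + 0] = s.g.ins[0];
          s.x[3 * nb + 1] = s.g.ins[1];
          s.x[3 * nb + 2] = s.g.ins[2];
          s.n_placed += 1;
          s.progress = 0.0;
        } else {
          s.translating = false;
        }
      }
    }
    s.time_s += s.p.dt;
    if (sv && step % sv == 0) save_frame();
    // (v) termination
    int tc = check_termination(s, term_mode, h0, h1, clearance, margin,
                               topo_clear);
    if (tc >= 0) { outcome = tc; finished = true; break; }
    if (step % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix out_pos(s.n, 3);
  for (int i = 0; i < s.n; ++i)
    for (int d = 0; d < 3; ++d)
      out_pos(i, d) = i < s.n_placed ? s.x[3 * i + d] : NA_REAL;

  List res = List::create(
    _["positions"] = out_pos,
    _["n_placed"] = s.n_placed,
    _["translating"] = s.translating,
    _["progress"] = s.progress,
    _["gate"] = s.gate,
    _["time_s"] = s.time_s,
    _["steps"] = static_cast<double>(step),
    _["outcome"] = outcome,
    _["finished"] = finished,
    _["n_open_steps"] = static_cast<double>(n_open),
    _["n_flips"] = static_cast<double>(n_flips),
    _["n_redraws"] = static_cast<double>(n_redraws),
    _["release_times"] = wrap(rel));
  if (sv) {
    NumericVector fr(frames.begin(), frames.end());
    fr.attr("dim") = IntegerVector::create(3, s.n, frame_times.size());
    res["frames"] = fr;
    res["frame_times"] = wrap(frame_times);
  }
  return res;
}
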