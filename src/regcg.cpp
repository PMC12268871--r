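// Compiled core: nonbonded/bonded energies, forces, parameter gradients
// and the BAOAB Langevin integrator.
//
// Unit system: kJ/mol, nm, ps, K, u, e  (1 u nm^2 ps^-2 == 1 kJ/mol).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>

using namespace Rcpp;

static const double KB_KJ = 0.0083145;    // kJ mol^-1 K^-1
static const double KE_COUL = 138.935458; // kJ mol^-1 nm e^-2 (Coulomb constant)

// Flattened model description, unpacked once from the R-side system list.
struct Sys {
  int n, ntype;
  std::vector<int> mono, tidx;
  std::vector<double> q;
  std::vector<double> A, Rrep, C, Ratt;   // ntype x ntype, row-major
  std::vector<int> buse, thidx;           // B-term flag; theta slot or -1
  double sigma, B, epsr, kappaD, cutoff;
  std::vector<int> si, sj;
  std::vector<double> sk, sr0;

  explicit Sys(const List& s) {
    IntegerVector mono_ = s["mono"], tidx_ = s["tidx"];
    NumericVector q_ = s["charge"];
    NumericMatrix A_ = s["A"], Rr_ = s["R_rep"], C_ = s["C"], Ra_ = s["R_att"];
    IntegerMatrix bu_ = s["b_use"], th_ = s["theta_idx"];
    n = mono_.size();
    ntype = A_.nrow();
    mono.assign(mono_.begin(), mono_.end());
    tidx.assign(tidx_.begin(), tidx_.end());
    q.assign(q_.begin(), q_.end());
    A.resize(ntype * ntype); Rrep.resize(ntype * ntype);
    C.resize(ntype * ntype); Ratt.resize(ntype * ntype);
    buse.resize(ntype * ntype); thidx.resize(ntype * ntype);
    for (int i = 0; i < ntype; ++i)
      for (int j = 0; j < ntype; ++j) {
        A[i * ntype + j] = A_(i, j);
        Rrep[i * ntype + j] = Rr_(i, j);
        C[i * ntype + j] = C_(i, j);
        Ratt[i * ntype + j] = Ra_(i, j);
        buse[i * ntype + j] = bu_(i, j);
        thidx[i * ntype + j] = th_(i, j);
      }
    sigma = as<double>(s["sigma"]);
    B = as<double>(s["B"]);
    epsr = as<double>(s["eps_r"]);
    kappaD = as<double>(s["kappa_D"]);
    cutoff = as<double>(s["cutoff"]);
    IntegerVector si_ = s["spring_i"], sj_ = s["spring_j"];
    NumericVector sk_ = s["spring_k"], sr_ = s["spring_r0"];
    si.assign(si_.begin(), si_.end());
    sj.assign(sj_.begin(), sj_.end());
    sk.assign(sk_.begin(), sk_.end());
    sr0.assign(sr_.begin(), sr_.end());
  }
};

// Energy breakdown + (optionally) forces.  x is n x 3 column-major
// (R matrix layout).  eb = {bond, elec, rep, att, total, vbind}.
// Designated binding pair (va, vb); va < 0 means all inter-monomer pairs.
// Returns false if an interacting pair sits at R == 0 (domain error).
static bool eval_model(const Sys& s, const double* x, double* f,
                       double eb[6], int va, int vb) {
  const int n = s.n;
  for (int k = 0; k < 6; ++k) eb[k] = 0.0;
  if (f) std::fill(f, f + 3 * n, 0.0);
  const double cut2 = s.cutoff * s.cutoff;
  const double inv_s2 = 1.0 / (s.sigma * s.sigma);
  const double gauss_norm = 1.0 / (s.sigma * std::sqrt(2.0 * M_PI));

  // bonded springs (intra-monomer by construction)
  for (size_t b = 0; b < s.si.size(); ++b) {
    int i = s.si[b], j = s.sj[b];
    double dx = x[i] - x[j], dy = x[i + n] - x[j + n], dz = x[i + 2 * n] - x[j + 2 * n];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 <= 0.0) return false;
    double r = std::sqrt(r2);
    double dr = r - s.sr0[b];
    eb[0] += 0.5 * s.sk[b] * dr * dr;
    if (f) {
      double fr = -s.sk[b] * dr / r; // magnitude/r, along (i - j)
      f[i] += fr * dx; f[i + n] += fr * dy; f[i + 2 * n] += fr * dz;
      f[j] -= fr * dx; f[j + n] -= fr * dy; f[j + 2 * n] -= fr * dz;
    }
  }

  // nonbonded: inter-monomer pairs within cutoff
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (s.mono[i] == s.mono[j]) continue;
      double dx = x[i] - x[j], dy = x[i + n] - x[j + n], dz = x[i + 2 * n] - x[j + 2 * n];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > cut2) continue;
      if (r2 <= 0.0) return false;
      double r = std::sqrt(r2);
      int tt = s.tidx[i] * s.ntype + s.tidx[j];
      double ue = 0.0, ur = 0.0, ua = 0.0, du = 0.0;

      // screened electrostatics
      double qq = s.q[i] * s.q[j];
      if (qq != 0.0) {
        ue = KE_COUL * qq / (s.epsr * r) * std::exp(-s.kappaD * r);
        du += -ue * (s.kappaD + 1.0 / r);
      }
      // soft cosine repulsion + B/R^4 core
      double Aij = s.A[tt], Rr = s.Rrep[tt];
      if (Aij > 0.0 && r < Rr) {
        double arg = M_PI * r / Rr;
        ur += Aij * (1.0 + std::cos(arg));
        du += -Aij * M_PI / Rr * std::sin(arg);
      }
      if (s.buse[tt]) {
        double r4 = r2 * r2;
        ur += s.B / r4;
        du += -4.0 * s.B / (r4 * r);
      }
      // Gaussian attraction well
      double Cij = s.C[tt];
      if (Cij != 0.0) {
        double dra = r - s.Ratt[tt];
        double g = gauss_norm * std::exp(-0.5 * dra * dra * inv_s2);
        ua = Cij * g;
        du += -ua * dra * inv_s2;
      }
      eb[1] += ue; eb[2] += ur; eb[3] += ua;
      bool in_bind = (va < 0) ||
        ((s.mono[i] == va && s.mono[j] == vb) || (s.mono[i] == vb && s.mono[j] == va));
      if (in_bind) eb[5] += ue + ur + ua;
      if (f && du != 0.0) {
        double fr = -du / r;
        f[i] += fr * dx; f[i + n] += fr * dy; f[i + 2 * n] += fr * dz;
        f[j] -= fr * dx; f[j + n] -= fr * dy; f[j + 2 * n] -= fr * dz;
      }
    }
  }
  eb[4] = eb[0] + eb[1] + eb[2] + eb[3];
  return true;
}

// dU/dC per trainable slot: Gaussian factor summed over in-range
// inter-monomer pairs.  gfull = over all pairs; gbind = restricted to the
// designated monomer pair (equals gfull when va < 0).
static void eval_grad_theta(const Sys& s, const double* x, double* gfull,
                            double* gbind, int va, int vb) {
  const int n = s.n;
  const double cut2 = s.cutoff * s.cutoff;
  const double inv_s2 = 1.0 / (s.sigma * s.sigma);
  const double gauss_norm = 1.0 / (s.sigma * std::sqrt(2.0 * M_PI));
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (s.mono[i] == s.mono[j]) continue;
      int tt = s.tidx[i] * s.ntype + s.tidx[j];
      int slot = s.thidx[tt];
      if (slot < 0) continue;
      double dx = x[i] - x[j], dy = x[i + n] - x[j + n], dz = x[i + 2 * n] - x[j + 2 * n];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > cut2 || r2 <= 0.0) continue;
      double r = std::sqrt(r2);
      double dra = r - s.Ratt[tt];
      double g = gauss_norm * std::exp(-0.5 * dra * dra * inv_s2);
      gfull[slot] += g;
      bool in_bind = (va < 0) ||
        ((s.mono[i] == va && s.mono[j] == vb) || (s.mono[i] == vb && s.mono[j] == va));
      if (in_bind) gbind[slot] += g;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_energy(NumericMatrix coords, List sys, int va, int vb) {
  Sys s(sys);
  if (coords.nrow() != s.n)
    stop("coordinate/topology bead count mismatch: %d vs %d", coords.nrow(), s.n);
  double eb[6];
  if (!eval_model(s, coords.begin(), nullptr, eb, va, vb))
    stop("overlapping beads (pair distance 0) in energy evaluation");
  NumericVector out = NumericVector::create(
    _["U_bond"] = eb[0], _["U_elec"] = eb[1], _["U_rep"] = eb[2],
    _["U_att"] = eb[3], _["U_total"] = eb[4], _["V_bind"] = eb[5]);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix coords, List sys) {
  Sys s(sys);
  if (coords.nrow() != s.n)
    stop("coordinate/topology bead count mismatch");
  NumericMatrix f(s.n, 3);
  double eb[6];
  if (!eval_model(s, coords.begin(), f.begin(), eb, -1, -1))
    stop("overlapping beads (pair distance 0) in force evaluation");
  return f;
}

// Per-frame V_bind and theta-gradients over an ensemble.
// frames: n x 3 x F array.
// [[Rcpp::export]]
List cpp_frame_stats(NumericVector frames, List sys, int ntheta, int va, int vb) {
  Sys s(sys);
  IntegerVector dim = frames.attr("dim");
  if (dim.size() != 3 || dim[0] != s.n || dim[1] != 3)
    stop("frames must be an n_beads x 3 x n_frames array matching the topology");
  int F = dim[2];
  NumericVector vbind(F), utot(F);
  NumericMatrix gfull(ntheta, F), gbind(ntheta, F);
  std::vector<double> gf(ntheta), gb(ntheta);
  const double* base = frames.begin();
  double eb[6];
  for (int t = 0; t < F; ++t) {
    const double* x = base + (size_t)t * 3 * s.n;
    if (!eval_model(s, x, nullptr, eb, va, vb))
      stop("overlapping beads in frame %d", t + 1);
    vbind[t] = eb[5];
    utot[t] = eb[4];
    std::fill(gf.begin(), gf.end(), 0.0);
    std::fill(gb.begin(), gb.end(), 0.0);
    eval_grad_theta(s, x, gf.data(), gb.data(), va, vb);
    for (int k = 0; k < ntheta; ++k) {
      gfull(k, t) = gf[k];
      gbind(k, t) = gb[k];
    }
  }
  return List::create(_["V_bind"] = vbind, _["U_total"] = utot,
                      _["g_full"] = gfull, _["g_bind"] = gbind);
}

// BAOAB Langevin integrator with optional spherical reflecting wall at the
// origin.  Records a frame every `stride` steps (first record after `stride`
// steps).  fric in ps^-1, dt in ps, temp in K.
// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix x0, List sys, NumericVector mass,
                      double dt, double temp, double fric,
                      int nsteps, int stride, int seed, double wall,
                      int va, int vb, bool init_vel) {
  Sys s(sys);
  const int n = s.n;
  if (x0.nrow() != n) stop("start coordinates do not match topology bead count");
  if (mass.size() != n) stop("mass vector length mismatch");
  const int F = nsteps / stride;
  if (F < 1) stop("nsteps/stride must be >= 1");

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> v(3 * n, 0.0), f(3 * n, 0.0);
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> norm(0.0, 1.0);

  const double kT = KB_KJ * temp;
  if (init_vel && temp > 0.0) {
    for (int i = 0; i < n; ++i) {
      double sd = std::sqrt(kT / mass[i]);
      for (int d = 0; d < 3; ++d) v[i + d * n] = sd * norm(rng);
    }
  }
  const double c1 = std::exp(-fric * dt);
  const double c2kT = (1.0 - c1 * c1) * kT;

  double eb[6];
  if (!eval_model(s, x.data(), f.data(), eb, va, vb))
    stop("overlapping beads in start configuration");

  NumericVector frames((size_t)3 * n * F);
  frames.attr("dim") = IntegerVector::create(n, 3, F);
  NumericVector vbind(F), utot(F), ekin(F), etot(F);
  int status = 0; // 0 ok; >0 frame index at failure

  auto apply_wall = [&](void) {
    if (wall <= 0.0) return;
    for (int i = 0; i < n; ++i) {
      double px = x[i], py = x[i + n], pz = x[i + 2 * n];
      double r = std::sqrt(px * px + py * py + pz * pz);
      if (r > wall && r > 0.0) {
        double scale = (2.0 * wall - r) / r;
        x[i] = px * scale; x[i + n] = py * scale; x[i + 2 * n] = pz * scale;
        double nx = px / r, ny = py / r, nz = pz / r;
        double vr = v[i] * nx + v[i + n] * ny + v[i + 2 * n] * nz;
        if (vr > 0.0) {
          v[i] -= 2.0 * vr * nx;
          v[i + n] -= 2.0 * vr * ny;
          v[i + 2 * n] -= 2.0 * vr * nz;
        }
      }
    }
  };

  int rec = 0;
  for (int step = 1; step <= nsteps; ++step) {
    // B
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        v[i + d * n] += 0.5 * dt * f[i + d * n] / mass[i];
    // A
    for (int k = 0; k < 3 * n; ++k) x[k] += 0.5 * dt * v[k];
    // O
    if (c2kT > 0.0) {
      for (int i = 0; i < n; ++i) {
        double c2 = std::sqrt(c2kT / mass[i]);
        for (int d = 0; d < 3; ++d)
          v[i + d * n] = c1 * v[i + d * n] + c2 * norm(rng);
      }
    } else if (c1 != 1.0) {
      for (int k = 0; k < 3 * n; ++k) v[k] *= c1;
    }
    // A
    for (int k = 0; k < 3 * n; ++k) x[k] += 0.5 * dt * v[k];
    apply_wall();
    // B
    if (!eval_model(s, x.data(), f.data(), eb, va, vb)) { status = rec + 1; break; }
    bool bad = false;
    for (int i = 0; i < n && !bad; ++i)
      for (int d = 0; d < 3; ++d)
        if (!std::isfinite(f[i + d * n])) { bad = true; }
    if (bad || !std::isfinite(eb[4])) { status = rec + 1; break; }
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        v[i + d * n] += 0.5 * dt * f[i + d * n] / mass[i];

    if (step % stride == 0) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          ke += 0.5 * mass[i] * v[i + d * n] * v[i + d * n];
      double* dst = frames.begin() + (size_t)rec * 3 * n;
      std::copy(x.begin(), x.end(), dst);
      vbind[rec] = eb[5]; utot[rec] = eb[4];
      ekin[rec] = ke; etot[rec] = eb[4] + ke;
      ++rec;
    }
  }

  NumericMatrix xfin(n, 3);
  std::copy(x.begin(), x.end(), xfin.begin());
  return List::create(_["frames"] = frames, _["V_bind"] = vbind,
                      _["U_total"] = utot, _["E_kin"] = ekin,
                      _["E_total"] = etot, _["n_recorded"] = rec,
                      _["status"] = status, _["x_final"] = xfin);
}
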