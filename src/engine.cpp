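// Core simulation kernels: pair potentials, bonded forces, neighbor lists,
// BAOAB Langevin integration with rotational membrane degrees of freedom,
// in-plane Berendsen barostat, FIRE minimization, energy bookkeeping.
//
// Unit conventions: lengths in sigma, energies in kBT, time in tau,
// bead mass = 1, axis moment of inertia = 1. The box is periodic in x and y
// and open along z.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_set>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// deterministic RNG (splitmix64 seeding + xoshiro256++), platform independent
// ---------------------------------------------------------------------------
struct Rng {
  uint64_t s[4];
  bool has_spare = false;
  double spare = 0.0;

  static uint64_t splitmix64(uint64_t& x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double gauss() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    has_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

// ---------------------------------------------------------------------------
// parameters
// ---------------------------------------------------------------------------
struct Par {
  double kT, gamma, gamma_r, mass, inertia;
  // tabulated attractive tail shape S(r) = cos^(2 zeta)(x(r)) of the
  // membrane pair potential and its derivative, Hermite-interpolated
  std::vector<double> tabS, tabSp;
  double tab_r0, tab_h;
  int tab_n;
  double eps_mm, mu, zeta, rmin_mm, rc_mm;
  double eps_bm, rmin_bm, rc_bm;
  double eps_bb, rmin_bb, rc_bb;
  double eps_cm, rmin_cm, rc_cm;
  double eps_rep, rmin_rep;
  double cargo_radius;
  double skin;
  double baro_coupling; int baro_every;
  double max_step;
};

static Par parse_params(const List& p) {
  Par q;
  q.kT        = as<double>(p["kT"]);
  q.gamma     = as<double>(p["gamma"]);
  q.gamma_r   = as<double>(p["gamma_r"]);
  q.mass      = as<double>(p["mass"]);
  q.inertia   = as<double>(p["inertia"]);
  q.eps_mm    = as<double>(p["eps_mm"]);
  q.mu        = as<double>(p["mu"]);
  q.zeta      = as<double>(p["zeta"]);
  q.rmin_mm   = as<double>(p["rmin_mm"]);
  q.rc_mm     = as<double>(p["rc_mm"]);
  q.eps_bm    = as<double>(p["eps_bm"]);
  q.rmin_bm   = as<double>(p["rmin_bm"]);
  q.rc_bm     = as<double>(p["rc_bm"]);
  q.eps_bb    = as<double>(p["eps_bb"]);
  q.rmin_bb   = as<double>(p["rmin_bb"]);
  q.rc_bb     = as<double>(p["rc_bb"]);
  q.eps_cm    = as<double>(p["eps_cm"]);
  q.rmin_cm   = as<double>(p["rmin_cm"]);
  q.rc_cm     = as<double>(p["rc_cm"]);
  q.eps_rep   = as<double>(p["eps_rep"]);
  q.rmin_rep  = as<double>(p["rmin_rep"]);
  q.cargo_radius = as<double>(p["cargo_radius"]);
  q.skin      = as<double>(p["skin"]);
  q.baro_coupling = as<double>(p["baro_coupling"]);
  q.baro_every    = as<int>(p["baro_every"]);
  q.max_step  = as<double>(p["max_step"]);
  q.tab_n = 1024;
  q.tab_r0 = q.rmin_mm;
  q.tab_h = (q.rc_mm - q.rmin_mm) / q.tab_n;
  q.tabS.resize(q.tab_n + 1);
  q.tabSp.resize(q.tab_n + 1);
  double c = 0.5 * M_PI / (q.rc_mm - q.rmin_mm);
  for (int i = 0; i <= q.tab_n; ++i) {
    double x = c * (i * q.tab_h);
    double cx = std::cos(x), sx = std::sin(x);
    q.tabS[i] = std::pow(cx, 2.0 * q.zeta);
    q.tabSp[i] = -2.0 * q.zeta * c * std::pow(cx, 2.0 * q.zeta - 1.0) * sx;
  }
  q.tabS[q.tab_n] = 0.0; q.tabSp[q.tab_n] = 0.0;
  return q;
}

// cubic Hermite evaluation of the tabulated tail shape; value and derivative
// come from the same cubic, so forces are exact gradients of the energy
static inline void tail_shape(const Par& p, double r, double* S, double* Sp) {
  double u = (r - p.tab_r0) / p.tab_h;
  int i = (int)u;
  if (i < 0) i = 0;
  if (i >= p.tab_n) { *S = 0.0; *Sp = 0.0; return; }
  double t = u - i, h = p.tab_h;
  double y0 = p.tabS[i], y1 = p.tabS[i + 1];
  double d0 = p.tabSp[i], d1 = p.tabSp[i + 1];
  double t2 = t * t, t3 = t2 * t;
  *S = (2*t3 - 3*t2 + 1) * y0 + (t3 - 2*t2 + t) * h * d0 +
       (-2*t3 + 3*t2) * y1 + (t3 - t2) * h * d1;
  *Sp = ((6*t2 - 6*t) * (y0 - y1) / h + (3*t2 - 4*t + 1) * d0 +
         (3*t2 - 2*t) * d1);
}

// bead types
enum { T_MEM = 1, T_BIND = 2, T_BACK = 3, T_CARGO = 4 };
// ledger terms
enum { L_MM = 0, L_BOND = 1, L_FM = 2, L_FF = 3, L_CM = 4, L_CEX = 5, NLEDGER = 6 };

// ---------------------------------------------------------------------------
// scalar pair kernels: return energy; du/dr through *dudr
// ---------------------------------------------------------------------------

// 2-4 repulsive core reaching -eps at rmin (used as core of all wells)
static inline double core24(double r, double eps, double rmin, double* dudr) {
  double s2 = (rmin / r) * (rmin / r);
  double s4 = s2 * s2;
  *dudr = eps * (-4.0 * s4 + 4.0 * s2) / r;
  return eps * (s4 - 2.0 * s2);
}

// purely repulsive excluded volume: core shifted up by eps, zero beyond rmin
static inline double u_rep(double r, double eps, double rmin, double* dudr) {
  if (r >= rmin) { *dudr = 0.0; return 0.0; }
  double u = core24(r, eps, rmin, dudr);
  return u + eps;
}

// smoothly truncated attractive well: 2-4 core below rmin, cos^2 tail to rc,
// depth exactly -eps at r = rmin, zero energy and force at rc
static inline double u_well(double r, double eps, double rmin, double rc,
                            double* dudr) {
  if (r >= rc) { *dudr = 0.0; return 0.0; }
  if (r < rmin) return core24(r, eps, rmin, dudr);
  double x = 0.5 * M_PI * (r - rmin) / (rc - rmin);
  double cx = std::cos(x), sx = std::sin(x);
  *dudr = eps * M_PI / (rc - rmin) * cx * sx;
  return -eps * cx * cx;
}

// ---------------------------------------------------------------------------
// system container
// ---------------------------------------------------------------------------
struct Sys {
  int N;
  std::vector<double> px, py, pz;      // positions (unwrapped)
  std::vector<double> nx, ny, nz;      // orientation axes (membrane beads)
  std::vector<double> vx, vy, vz;      // velocities
  std::vector<double> wx, wy, wz;      // angular velocities (perp to axis)
  std::vector<int> type;
  std::vector<int> fil;                // filament id per bead (0 = none)
  std::vector<double> adh;             // adhesion factor (0 for severed)
  // bonds
  std::vector<int> bi, bj;
  std::vector<double> br0, bk;
  double Lx, Ly, Lz;
  // forces/torques
  std::vector<double> fx, fy, fz, tx, ty, tz;
  std::vector<double> ebead;
  double ledger[NLEDGER];
  double Wxx, Wyy;                     // in-plane virial
  // neighbor list
  std::vector<int> nl_i, nl_j;
  std::vector<double> rx0, ry0, rz0;   // positions at list build
  std::unordered_set<uint64_t> excl;
  std::vector<int> cargo_idx;
  double rc_list;
};

static inline uint64_t pkey(int i, int j, int N) {
  if (i > j) std::swap(i, j);
  return (uint64_t)i * (uint64_t)N + (uint64_t)j;
}

static Sys unpack(const List& state) {
  Sys s;
  NumericMatrix pos  = state["pos"];
  NumericMatrix axis = state["axis"];
  NumericMatrix vel  = state["vel"];
  NumericMatrix avel = state["avel"];
  IntegerVector type = state["type"];
  IntegerVector fil  = state["fil"];
  NumericVector adh  = state["adh"];
  NumericMatrix bonds = state["bonds"];
  NumericVector box  = state["box"];
  int N = pos.nrow();
  s.N = N;
  s.px.resize(N); s.py.resize(N); s.pz.resize(N);
  s.nx.resize(N); s.ny.resize(N); s.nz.resize(N);
  s.vx.resize(N); s.vy.resize(N); s.vz.resize(N);
  s.wx.resize(N); s.wy.resize(N); s.wz.resize(N);
  s.type.resize(N); s.fil.resize(N); s.adh.resize(N);
  for (int i = 0; i < N; ++i) {
    s.px[i] = pos(i,0); s.py[i] = pos(i,1); s.pz[i] = pos(i,2);
    s.nx[i] = axis(i,0); s.ny[i] = axis(i,1); s.nz[i] = axis(i,2);
    s.vx[i] = vel(i,0); s.vy[i] = vel(i,1); s.vz[i] = vel(i,2);
    s.wx[i] = avel(i,0); s.wy[i] = avel(i,1); s.wz[i] = avel(i,2);
    s.type[i] = type[i]; s.fil[i] = fil[i]; s.adh[i] = adh[i];
    if (s.type[i] == T_CARGO) s.cargo_idx.push_back(i);
  }
  int M = bonds.nrow();
  s.bi.resize(M); s.bj.resize(M); s.br0.resize(M); s.bk.resize(M);
  for (int b = 0; b < M; ++b) {
    s.bi[b] = (int)bonds(b,0) - 1;
    s.bj[b] = (int)bonds(b,1) - 1;
    s.br0[b] = bonds(b,2);
    s.bk[b]  = bonds(b,3);
    s.excl.insert(pkey(s.bi[b], s.bj[b], N));
  }
  s.Lx = box[0]; s.Ly = box[1]; s.Lz = box[2];
  s.fx.resize(N); s.fy.resize(N); s.fz.resize(N);
  s.tx.resize(N); s.ty.resize(N); s.tz.resize(N);
  s.ebead.resize(N);
  return s;
}

static List pack(const Sys& s) {
  int N = s.N;
  NumericMatrix pos(N,3), axis(N,3), vel(N,3), avel(N,3);
  for (int i = 0; i < N; ++i) {
    pos(i,0)=s.px[i]; pos(i,1)=s.py[i]; pos(i,2)=s.pz[i];
    axis(i,0)=s.nx[i]; axis(i,1)=s.ny[i]; axis(i,2)=s.nz[i];
    vel(i,0)=s.vx[i]; vel(i,1)=s.vy[i]; vel(i,2)=s.vz[i];
    avel(i,0)=s.wx[i]; avel(i,1)=s.wy[i]; avel(i,2)=s.wz[i];
  }
  return List::create(_["pos"]=pos, _["axis"]=axis, _["vel"]=vel,
                      _["avel"]=avel, _["box"]=NumericVector::create(s.Lx,s.Ly,s.Lz));
}

static inline void minimg(const Sys& s, double& dx, double& dy) {
  dx -= s.Lx * std::round(dx / s.Lx);
  dy -= s.Ly * std::round(dy / s.Ly);
}

// ---------------------------------------------------------------------------
// neighbor list (O(N^2) rebuild with skin; cargo handled separately)
// ---------------------------------------------------------------------------
static void build_nlist(Sys& s, const Par& p) {
  double rc = std::max(p.rc_mm, std::max(p.rc_bm, p.rc_bb));
  rc = std::max(rc, p.rmin_rep);
  s.rc_list = rc + p.skin;
  double rc2 = s.rc_list * s.rc_list;
  s.nl_i.clear(); s.nl_j.clear();
  int N = s.N;
  int ncx = (int)std::floor(s.Lx / s.rc_list);
  int ncy = (int)std::floor(s.Ly / s.rc_list);
  if (ncx < 3 || ncy < 3) {
    // box too small for a cell list: all-pairs rebuild
    for (int i = 0; i < N; ++i) {
      if (s.type[i] == T_CARGO) continue;
      for (int j = i + 1; j < N; ++j) {
        if (s.type[j] == T_CARGO) continue;
        double dx = s.px[j]-s.px[i], dy = s.py[j]-s.py[i], dz = s.pz[j]-s.pz[i];
        minimg(s, dx, dy);
        if (dx*dx + dy*dy + dz*dz < rc2 && !s.excl.count(pkey(i,j,N))) {
          s.nl_i.push_back(i); s.nl_j.push_back(j);
        }
      }
    }
  } else {
    double zmin = 1e300, zmax = -1e300;
    for (int i = 0; i < N; ++i) {
      if (s.pz[i] < zmin) zmin = s.pz[i];
      if (s.pz[i] > zmax) zmax = s.pz[i];
    }
    int ncz = (int)std::floor((zmax - zmin) / s.rc_list) + 1;
    if (ncz < 1) ncz = 1;
    double cwx = s.Lx / ncx, cwy = s.Ly / ncy;
    std::vector<int> head(ncx * ncy * ncz, -1), nxt(N, -1), ci(N), cj(N), ck(N);
    for (int i = 0; i < N; ++i) {
      if (s.type[i] == T_CARGO) { ci[i] = -1; continue; }
      double wx = s.px[i] - s.Lx * std::floor(s.px[i] / s.Lx);
      double wy = s.py[i] - s.Ly * std::floor(s.py[i] / s.Ly);
      int ax = (int)(wx / cwx); if (ax >= ncx) ax = ncx - 1;
      int ay = (int)(wy / cwy); if (ay >= ncy) ay = ncy - 1;
      int az = (int)((s.pz[i] - zmin) / s.rc_list); if (az >= ncz) az = ncz - 1;
      ci[i] = ax; cj[i] = ay; ck[i] = az;
      int cell = (az * ncy + ay) * ncx + ax;
      nxt[i] = head[cell]; head[cell] = i;
    }
    for (int i = 0; i < N; ++i) {
      if (ci[i] < 0) continue;
      for (int dzc = -1; dzc <= 1; ++dzc) {
        int az = ck[i] + dzc;
        if (az < 0 || az >= ncz) continue;
        for (int dyc = -1; dyc <= 1; ++dyc) {
          int ay = (cj[i] + dyc + ncy) % ncy;
          for (int dxc = -1; dxc <= 1; ++dxc) {
            int ax = (ci[i] + dxc + ncx) % ncx;
            int cell = (az * ncy + ay) * ncx + ax;
            for (int j = head[cell]; j >= 0; j = nxt[j]) {
              if (j <= i) continue;
              double dx = s.px[j]-s.px[i], dy = s.py[j]-s.py[i], dz = s.pz[j]-s.pz[i];
              minimg(s, dx, dy);
              if (dx*dx + dy*dy + dz*dz < rc2 && !s.excl.count(pkey(i,j,N))) {
                s.nl_i.push_back(i); s.nl_j.push_back(j);
              }
            }
          }
        }
      }
    }
  }
  s.rx0 = s.px; s.ry0 = s.py; s.rz0 = s.pz;
}

static bool nlist_stale(const Sys& s, const Par& p) {
  double lim = 0.25 * p.skin * p.skin; // (skin/2)^2
  for (int i = 0; i < s.N; ++i) {
    double dx = s.px[i]-s.rx0[i], dy = s.py[i]-s.ry0[i], dz = s.pz[i]-s.rz0[i];
    if (dx*dx + dy*dy + dz*dz > lim) return true;
  }
  return false;
}

// ---------------------------------------------------------------------------
// force/energy evaluation
// ---------------------------------------------------------------------------

// x^n for small integer n (the tail exponent 2*zeta - 1 is usually integer)
static inline double powint(double x, int n) {
  double r = 1.0;
  while (n > 0) { if (n & 1) r *= x; x *= x; n >>= 1; }
  return r;
}

// membrane anisotropic pair; returns energy, fills gradient on rvec (gv),
// axis gradients gi, gj (dU/dn). rvec points i -> j.
static inline double pair_membrane(const double* rvec, double r,
                                   const double* ni, const double* nj,
                                   const Par& p,
                                   double* gv, double* gni, double* gnj) {
  double rhat[3] = {rvec[0]/r, rvec[1]/r, rvec[2]/r};
  double ci = ni[0]*rhat[0] + ni[1]*rhat[1] + ni[2]*rhat[2];
  double cj = nj[0]*rhat[0] + nj[1]*rhat[1] + nj[2]*rhat[2];
  double nn = ni[0]*nj[0] + ni[1]*nj[1] + ni[2]*nj[2];
  double a = nn - ci * cj;
  double phi = 1.0 + p.mu * (a - 1.0);
  double U, dudr, duda;
  if (r < p.rmin_mm) {
    double du;
    double u = core24(r, p.eps_mm, p.rmin_mm, &du);
    U = u + p.eps_mm * p.mu * (1.0 - a);
    dudr = du;
    duda = -p.eps_mm * p.mu;
  } else {
    double S, Sp;
    tail_shape(p, r, &S, &Sp);
    double ua = -p.eps_mm * S;
    U = ua * phi;
    dudr = -p.eps_mm * Sp * phi;
    duda = ua * p.mu;
  }
  // d a / d rhat = -cj*ni - ci*nj ; project off rhat, divide by r
  double d[3] = {-cj*ni[0] - ci*nj[0], -cj*ni[1] - ci*nj[1], -cj*ni[2] - ci*nj[2]};
  double drh = d[0]*rhat[0] + d[1]*rhat[1] + d[2]*rhat[2];
  for (int k = 0; k < 3; ++k)
    gv[k] = dudr * rhat[k] + (duda / r) * (d[k] - drh * rhat[k]);
  for (int k = 0; k < 3; ++k) {
    gni[k] = duda * (nj[k] - cj * rhat[k]);
    gnj[k] = duda * (ni[k] - ci * rhat[k]);
  }
  return U;
}

// full evaluation; assumes neighbor list current
static double compute_forces(Sys& s, const Par& p) {
  int N = s.N;
  std::fill(s.fx.begin(), s.fx.end(), 0.0);
  std::fill(s.fy.begin(), s.fy.end(), 0.0);
  std::fill(s.fz.begin(), s.fz.end(), 0.0);
  std::fill(s.tx.begin(), s.tx.end(), 0.0);
  std::fill(s.ty.begin(), s.ty.end(), 0.0);
  std::fill(s.tz.begin(), s.tz.end(), 0.0);
  std::fill(s.ebead.begin(), s.ebead.end(), 0.0);
  for (int k = 0; k < NLEDGER; ++k) s.ledger[k] = 0.0;
  s.Wxx = 0.0; s.Wyy = 0.0;

  double delta_c = p.cargo_radius - 0.5; // cargo surface offset

  // pair term helper lambda applied to a candidate pair
  auto do_pair = [&](int i, int j) {
    double dx = s.px[j]-s.px[i], dy = s.py[j]-s.py[i], dz = s.pz[j]-s.pz[i];
    minimg(s, dx, dy);
    double r2 = dx*dx + dy*dy + dz*dz;
    int ti = s.type[i], tj = s.type[j];
    double U = 0.0;
    if (ti == T_MEM && tj == T_MEM) {
      double rc2 = p.rc_mm * p.rc_mm;
      if (r2 >= rc2) return;
      double r = std::sqrt(r2);
      double rvec[3] = {dx, dy, dz};
      double ni[3] = {s.nx[i], s.ny[i], s.nz[i]};
      double nj[3] = {s.nx[j], s.ny[j], s.nz[j]};
      double gv[3], gni[3], gnj[3];
      U = pair_membrane(rvec, r, ni, nj, p, gv, gni, gnj);
      s.fx[i] += gv[0]; s.fy[i] += gv[1]; s.fz[i] += gv[2];
      s.fx[j] -= gv[0]; s.fy[j] -= gv[1]; s.fz[j] -= gv[2];
      // torque_i = n_i x (-gni)
      s.tx[i] += -(ni[1]*gni[2] - ni[2]*gni[1]);
      s.ty[i] += -(ni[2]*gni[0] - ni[0]*gni[2]);
      s.tz[i] += -(ni[0]*gni[1] - ni[1]*gni[0]);
      s.tx[j] += -(nj[1]*gnj[2] - nj[2]*gnj[1]);
      s.ty[j] += -(nj[2]*gnj[0] - nj[0]*gnj[2]);
      s.tz[j] += -(nj[0]*gnj[1] - nj[1]*gnj[0]);
      s.Wxx += dx * (-gv[0]); s.Wyy += dy * (-gv[1]);
      s.ledger[L_MM] += U;
      s.ebead[i] += 0.5 * U; s.ebead[j] += 0.5 * U;
      return;
    }
    // isotropic terms
    double r = std::sqrt(r2);
    double dudr = 0.0;
    int term = -1;
    bool cargo_pair = (ti == T_CARGO || tj == T_CARGO);
    double off = 0.0;
    if (cargo_pair) {
      off = (ti == T_CARGO && tj == T_CARGO) ? 2.0 * delta_c : delta_c;
    }
    double re = r - off;
    if (re < 0.05) re = 0.05;
    int tl = std::min(ti, tj), th = std::max(ti, tj);
    if (tl == T_MEM && th == T_BIND) {
      double e = p.eps_bm * (ti == T_BIND ? s.adh[i] : s.adh[j]);
      if (e > 1e-12) { U = u_well(re, e, p.rmin_bm, p.rc_bm, &dudr); }
      else           { U = u_rep(re, p.eps_rep, p.rmin_rep, &dudr); }
      term = L_FM;
    } else if (tl == T_BIND && th == T_BIND) {
      // lateral attraction acts between filaments; within one filament the
      // shape is encoded purely in the bond network (excluded volume only)
      double e = (s.fil[i] != s.fil[j]) ? p.eps_bb * s.adh[i] * s.adh[j] : 0.0;
      if (e > 1e-12) { U = u_well(re, e, p.rmin_bb, p.rc_bb, &dudr); }
      else           { U = u_rep(re, p.eps_rep, p.rmin_rep, &dudr); }
      term = L_FF;
    } else if (tl == T_MEM && th == T_BACK) {
      U = u_rep(re, p.eps_rep, p.rmin_rep, &dudr);
      term = L_FM;
    } else if ((tl == T_BIND && th == T_BACK) || (tl == T_BACK && th == T_BACK)) {
      U = u_rep(re, p.eps_rep, p.rmin_rep, &dudr);
      term = L_FF;
    } else if (tl == T_MEM && th == T_CARGO) {
      if (p.eps_cm > 1e-12) { U = u_well(re, p.eps_cm, p.rmin_cm, p.rc_cm, &dudr); }
      else                  { U = u_rep(re, p.eps_rep, p.rmin_rep, &dudr); }
      term = L_CM;
    } else if (cargo_pair) { // cargo-filament, cargo-cargo
      U = u_rep(re, p.eps_rep, p.rmin_rep, &dudr);
      term = L_CEX;
    } else {
      stop("unknown bead species pair (%d, %d)", ti, tj);
    }
    if (dudr != 0.0 || U != 0.0) {
      double g = dudr / r; // gradient on rvec = dudr * rhat
      double gx = g*dx, gy = g*dy, gz = g*dz;
      s.fx[i] += gx; s.fy[i] += gy; s.fz[i] += gz;
      s.fx[j] -= gx; s.fy[j] -= gy; s.fz[j] -= gz;
      s.Wxx += dx * (-gx); s.Wyy += dy * (-gy);
      s.ledger[term] += U;
      s.ebead[i] += 0.5 * U; s.ebead[j] += 0.5 * U;
    }
  };

  int npair = (int)s.nl_i.size();
  for (int q = 0; q < npair; ++q) do_pair(s.nl_i[q], s.nl_j[q]);
  // cargo pairs: all-against-all (few cargo beads)
  for (int c : s.cargo_idx)
    for (int j = 0; j < N; ++j)
      if (j != c && !(s.type[j] == T_CARGO && j < c) &&
          !s.excl.count(pkey(c, j, N)))
        do_pair(c, j);

  // bonds
  int M = (int)s.bi.size();
  for (int b = 0; b < M; ++b) {
    int i = s.bi[b], j = s.bj[b];
    double dx = s.px[j]-s.px[i], dy = s.py[j]-s.py[i], dz = s.pz[j]-s.pz[i];
    minimg(s, dx, dy);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double dr = r - s.br0[b];
    double U = 0.5 * s.bk[b] * dr * dr;
    double g = s.bk[b] * dr / r;
    double gx = g*dx, gy = g*dy, gz = g*dz;
    s.fx[i] += gx; s.fy[i] += gy; s.fz[i] += gz;
    s.fx[j] -= gx; s.fy[j] -= gy; s.fz[j] -= gz;
    s.Wxx += dx * (-gx); s.Wyy += dy * (-gy);
    s.ledger[L_BOND] += U;
    s.ebead[i] += 0.5 * U; s.ebead[j] += 0.5 * U;
  }
  double tot = 0.0;
  for (int k = 0; k < NLEDGER; ++k) tot += s.ledger[k];
  return tot;
}

// ---------------------------------------------------------------------------
// exported: single membrane pair (no PBC), for tests and documentation
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_pair_membrane(NumericVector xi, NumericVector ni,
                       NumericVector xj, NumericVector nj, List params) {
  Par p = parse_params(params);
  double rvec[3] = {xj[0]-xi[0], xj[1]-xi[1], xj[2]-xi[2]};
  double r = std::sqrt(rvec[0]*rvec[0] + rvec[1]*rvec[1] + rvec[2]*rvec[2]);
  NumericVector fi(3), fj(3), ti(3), tj(3);
  double U = 0.0;
  if (r < p.rc_mm) {
    double niv[3] = {ni[0], ni[1], ni[2]}, njv[3] = {nj[0], nj[1], nj[2]};
    double gv[3], gni[3], gnj[3];
    U = pair_membrane(rvec, r, niv, njv, p, gv, gni, gnj);
    for (int k = 0; k < 3; ++k) { fi[k] = gv[k]; fj[k] = -gv[k]; }
    ti[0] = -(ni[1]*gni[2] - ni[2]*gni[1]);
    ti[1] = -(ni[2]*gni[0] - ni[0]*gni[2]);
    ti[2] = -(ni[0]*gni[1] - ni[1]*gni[0]);
    tj[0] = -(nj[1]*gnj[2] - nj[2]*gnj[1]);
    tj[1] = -(nj[2]*gnj[0] - nj[0]*gnj[2]);
    tj[2] = -(nj[0]*gnj[1] - nj[1]*gnj[0]);
  }
  return List::create(_["energy"]=U, _["force_i"]=fi, _["force_j"]=fj,
                      _["torque_i"]=ti, _["torque_j"]=tj);
}

// ---------------------------------------------------------------------------
// exported: full evaluation (ledger, per-bead energies, forces, torques)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_compute(List state, List params) {
  Par p = parse_params(params);
  Sys s = unpack(state);
  build_nlist(s, p);
  double tot = compute_forces(s, p);
  int N = s.N;
  NumericMatrix F(N,3), TQ(N,3);
  NumericVector eb(N);
  for (int i = 0; i < N; ++i) {
    F(i,0)=s.fx[i]; F(i,1)=s.fy[i]; F(i,2)=s.fz[i];
    TQ(i,0)=s.tx[i]; TQ(i,1)=s.ty[i]; TQ(i,2)=s.tz[i];
    eb[i]=s.ebead[i];
  }
  NumericVector led(NLEDGER);
  led.attr("names") = CharacterVector::create(
    "membrane", "bonds", "filament_membrane", "filament_filament",
    "cargo_membrane", "cargo_excluded");
  for (int k = 0; k < NLEDGER; ++k) led[k] = s.ledger[k];
  return List::create(_["total"]=tot, _["ledger"]=led, _["per_bead"]=eb,
                      _["forces"]=F, _["torques"]=TQ,
                      _["virial_xx"]=s.Wxx, _["virial_yy"]=s.Wyy,
                      _["n_pairs"]=(int)s.nl_i.size());
}

// brute-force total pair energy (independent of the neighbor list machinery
// in spirit; shares the pair kernels) -- exported for cross-checking
// [[Rcpp::export]]
List cpp_compute_brute(List state, List params) {
  Par p = parse_params(params);
  Sys s = unpack(state);
  // neighbor list with huge skin so every non-excluded pair is a candidate
  s.rc_list = 1e9;
  s.nl_i.clear(); s.nl_j.clear();
  for (int i = 0; i < s.N; ++i) {
    if (s.type[i] == T_CARGO) continue;
    for (int j = i+1; j < s.N; ++j) {
      if (s.type[j] == T_CARGO) continue;
      if (!s.excl.count(pkey(i,j,s.N))) { s.nl_i.push_back(i); s.nl_j.push_back(j); }
    }
  }
  s.rx0 = s.px; s.ry0 = s.py; s.rz0 = s.pz;
  double tot = compute_forces(s, p);
  NumericVector led(NLEDGER);
  led.attr("names") = CharacterVector::create(
    "membrane", "bonds", "filament_membrane", "filament_filament",
    "cargo_membrane", "cargo_excluded");
  for (int k = 0; k < NLEDGER; ++k) led[k] = s.ledger[k];
  return List::create(_["total"]=tot, _["ledger"]=led);
}

// ---------------------------------------------------------------------------
// integration helpers
// ---------------------------------------------------------------------------
static inline void rotate_axis(double& nx, double& ny, double& nz,
                               double wxv, double wyv, double wzv, double dt) {
  double w = std::sqrt(wxv*wxv + wyv*wyv + wzv*wzv);
  double ang = w * dt;
  if (ang < 1e-14) return;
  double kx = wxv / w, ky = wyv / w, kz = wzv / w;
  double c = std::cos(ang), sn = std::sin(ang);
  double kdn = kx*nx + ky*ny + kz*nz;
  double cx = ky*nz - kz*ny, cy = kz*nx - kx*nz, cz2 = kx*ny - ky*nx;
  double ox = nx*c + cx*sn + kx*kdn*(1.0-c);
  double oy = ny*c + cy*sn + ky*kdn*(1.0-c);
  double oz = nz*c + cz2*sn + kz*kdn*(1.0-c);
  double nrm = std::sqrt(ox*ox + oy*oy + oz*oz);
  nx = ox/nrm; ny = oy/nrm; nz = oz/nrm;
}

// ---------------------------------------------------------------------------
// exported: Langevin (BAOAB) integrator with optional barostat
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_integrate(List state, List params, int n_steps, double dt,
                   bool thermostat, bool barostat, int sample_every,
                   double seed, int log_every) {
  Par p = parse_params(params);
  Sys s = unpack(state);
  Rng rng((uint64_t)seed);
  int N = s.N;
  build_nlist(s, p);
  compute_forces(s, p);

  double c1 = thermostat ? std::exp(-p.gamma * dt) : 1.0;
  double c2 = thermostat ? std::sqrt(p.kT * (1.0 - c1*c1) / p.mass) : 0.0;
  double c1r = thermostat ? std::exp(-p.gamma_r * dt) : 1.0;
  double c2r = thermostat ? std::sqrt(p.kT * (1.0 - c1r*c1r) / p.inertia) : 0.0;

  List frames;
  std::vector<double> log_t, log_ten, log_area, log_T, log_E;
  std::string status = "ok";
  double half = 0.5 * dt;
  double max_half = p.max_step * 0.5; // per half-A-step displacement cap
  double strain = 0.0;
  int diverged_at = -1;

  for (int step = 0; step < n_steps && status == "ok"; ++step) {
    // B
    for (int i = 0; i < N; ++i) {
      s.vx[i] += half * s.fx[i] / p.mass;
      s.vy[i] += half * s.fy[i] / p.mass;
      s.vz[i] += half * s.fz[i] / p.mass;
      if (s.type[i] == T_MEM) {
        s.wx[i] += half * s.tx[i] / p.inertia;
        s.wy[i] += half * s.ty[i] / p.inertia;
        s.wz[i] += half * s.tz[i] / p.inertia;
      }
    }
    // A (half)
    for (int i = 0; i < N; ++i) {
      double ddx = half*s.vx[i], ddy = half*s.vy[i], ddz = half*s.vz[i];
      if (std::fabs(ddx) > max_half || std::fabs(ddy) > max_half ||
          std::fabs(ddz) > max_half) { status = "diverged"; diverged_at = step; break; }
      s.px[i] += ddx; s.py[i] += ddy; s.pz[i] += ddz;
      if (s.type[i] == T_MEM)
        rotate_axis(s.nx[i], s.ny[i], s.nz[i], s.wx[i], s.wy[i], s.wz[i], half);
    }
    if (status != "ok") break;
    // O
    if (thermostat) {
      for (int i = 0; i < N; ++i) {
        s.vx[i] = c1*s.vx[i] + c2*rng.gauss();
        s.vy[i] = c1*s.vy[i] + c2*rng.gauss();
        s.vz[i] = c1*s.vz[i] + c2*rng.gauss();
        if (s.type[i] == T_MEM) {
          double gx = rng.gauss(), gy = rng.gauss(), gz = rng.gauss();
          double wxn = c1r*s.wx[i] + c2r*gx;
          double wyn = c1r*s.wy[i] + c2r*gy;
          double wzn = c1r*s.wz[i] + c2r*gz;
          double d = wxn*s.nx[i] + wyn*s.ny[i] + wzn*s.nz[i];
          s.wx[i] = wxn - d*s.nx[i]; s.wy[i] = wyn - d*s.ny[i]; s.wz[i] = wzn - d*s.nz[i];
        }
      }
    }
    // A (half)
    for (int i = 0; i < N; ++i) {
      double ddx = half*s.vx[i], ddy = half*s.vy[i], ddz = half*s.vz[i];
      if (std::fabs(ddx) > max_half || std::fabs(ddy) > max_half ||
          std::fabs(ddz) > max_half) { status = "diverged"; diverged_at = step; break; }
      s.px[i] += ddx; s.py[i] += ddy; s.pz[i] += ddz;
      if (s.type[i] == T_MEM)
        rotate_axis(s.nx[i], s.ny[i], s.nz[i], s.wx[i], s.wy[i], s.wz[i], half);
    }
    if (status != "ok") break;
    if (nlist_stale(s, p)) build_nlist(s, p);
    double U = compute_forces(s, p);
    // B
    for (int i = 0; i < N; ++i) {
      s.vx[i] += half * s.fx[i] / p.mass;
      s.vy[i] += half * s.fy[i] / p.mass;
      s.vz[i] += half * s.fz[i] / p.mass;
      if (s.type[i] == T_MEM) {
        s.wx[i] += half * s.tx[i] / p.inertia;
        s.wy[i] += half * s.ty[i] / p.inertia;
        s.wz[i] += half * s.tz[i] / p.inertia;
      }
    }
    // barostat: weak in-plane coupling toward zero lateral tension
    if (barostat && ((step + 1) % p.baro_every == 0)) {
      double kin2d = 0.0;
      for (int i = 0; i < N; ++i)
        kin2d += p.mass * (s.vx[i]*s.vx[i] + s.vy[i]*s.vy[i]);
      double A = s.Lx * s.Ly;
      double tension = -(kin2d + s.Wxx + s.Wyy) / (2.0 * A);
      double ds = -p.baro_coupling * dt * p.baro_every * tension;
      if (std::fabs(ds) > 0.01) { status = "barostat_runaway"; break; }
      if (ds >  5e-4) ds =  5e-4;
      if (ds < -5e-4) ds = -5e-4;
      double sc = 1.0 + ds;
      for (int i = 0; i < N; ++i) { s.px[i] *= sc; s.py[i] *= sc; }
      s.Lx *= sc; s.Ly *= sc;
      strain += std::log(sc);
      if (nlist_stale(s, p)) build_nlist(s, p);
      U = compute_forces(s, p);
    }
    // logging
    if (log_every > 0 && ((step + 1) % log_every == 0)) {
      double kin = 0.0, kin2d = 0.0, krot = 0.0;
      int nmem = 0;
      for (int i = 0; i < N; ++i) {
        kin += 0.5 * p.mass * (s.vx[i]*s.vx[i] + s.vy[i]*s.vy[i] + s.vz[i]*s.vz[i]);
        kin2d += p.mass * (s.vx[i]*s.vx[i] + s.vy[i]*s.vy[i]);
        if (s.type[i] == T_MEM) {
          krot += 0.5 * p.inertia * (s.wx[i]*s.wx[i] + s.wy[i]*s.wy[i] + s.wz[i]*s.wz[i]);
          ++nmem;
        }
      }
      double A = s.Lx * s.Ly;
      log_t.push_back((step + 1) * dt);
      log_ten.push_back(-(kin2d + s.Wxx + s.Wyy) / (2.0 * A));
      log_area.push_back(A);
      log_T.push_back(2.0 * kin / (3.0 * N));
      log_E.push_back(U + kin + krot);
    }
    if (sample_every > 0 && ((step + 1) % sample_every == 0)) {
      NumericMatrix pos(N,3), axis(N,3);
      for (int i = 0; i < N; ++i) {
        pos(i,0)=s.px[i]; pos(i,1)=s.py[i]; pos(i,2)=s.pz[i];
        axis(i,0)=s.nx[i]; axis(i,1)=s.ny[i]; axis(i,2)=s.nz[i];
      }
      frames.push_back(List::create(
        _["time"]=(step + 1) * dt,
        _["box"]=NumericVector::create(s.Lx, s.Ly, s.Lz),
        _["pos"]=pos, _["axis"]=axis));
    }
  }

  List out = pack(s);
  int nl = (int)log_t.size();
  NumericMatrix lg(nl, 5);
  for (int q = 0; q < nl; ++q) {
    lg(q,0)=log_t[q]; lg(q,1)=log_ten[q]; lg(q,2)=log_area[q];
    lg(q,3)=log_T[q]; lg(q,4)=log_E[q];
  }
  colnames(lg) = CharacterVector::create("time","tension","area","temperature","energy");
  out["frames"] = frames;
  out["log"] = lg;
  out["status"] = status;
  out["diverged_at"] = diverged_at;
  out["strain"] = strain;
  return out;
}

// ---------------------------------------------------------------------------
// exported: FIRE minimization (positions + optional membrane axes)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_minimize(List state, List params, int max_iter, double ftol,
                  double max_disp, LogicalVector frozen) {
  Par p = parse_params(params);
  Sys s = unpack(state);
  int N = s.N;
  build_nlist(s, p);
  // FIRE parameters (standard values)
  double dt = 0.005, dtmax = 0.05, finc = 1.1, fdec = 0.5, astart = 0.1, fa = 0.99;
  double alpha = astart;
  int npos = 0;
  std::vector<double> vx(N,0), vy(N,0), vz(N,0);
  double fmax = 1e30, U = 0.0;
  int it = 0;
  for (; it < max_iter; ++it) {
    if (nlist_stale(s, p)) build_nlist(s, p);
    U = compute_forces(s, p);
    fmax = 0.0;
    double power = 0.0, vnorm = 0.0, fnorm = 0.0;
    for (int i = 0; i < N; ++i) {
      if (frozen[i]) { vx[i]=vy[i]=vz[i]=0; continue; }
      double fm = std::sqrt(s.fx[i]*s.fx[i] + s.fy[i]*s.fy[i] + s.fz[i]*s.fz[i]);
      if (fm > fmax) fmax = fm;
      power += vx[i]*s.fx[i] + vy[i]*s.fy[i] + vz[i]*s.fz[i];
      vnorm += vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i];
      fnorm += s.fx[i]*s.fx[i] + s.fy[i]*s.fy[i] + s.fz[i]*s.fz[i];
    }
    if (fmax < ftol) break;
    vnorm = std::sqrt(vnorm); fnorm = std::sqrt(fnorm);
    if (power > 0.0) {
      double mix = (fnorm > 1e-30) ? alpha * vnorm / fnorm : 0.0;
      for (int i = 0; i < N; ++i) {
        if (frozen[i]) continue;
        vx[i] = (1.0-alpha)*vx[i] + mix*s.fx[i];
        vy[i] = (1.0-alpha)*vy[i] + mix*s.fy[i];
        vz[i] = (1.0-alpha)*vz[i] + mix*s.fz[i];
      }
      if (++npos > 5) { dt = std::min(dt*finc, dtmax); alpha *= fa; }
    } else {
      for (int i = 0; i < N; ++i) { vx[i]=vy[i]=vz[i]=0; }
      dt *= fdec; alpha = astart; npos = 0;
    }
    for (int i = 0; i < N; ++i) {
      if (frozen[i]) continue;
      vx[i] += dt * s.fx[i]; vy[i] += dt * s.fy[i]; vz[i] += dt * s.fz[i];
      double ddx = dt*vx[i], ddy = dt*vy[i], ddz = dt*vz[i];
      double dm = std::sqrt(ddx*ddx + ddy*ddy + ddz*ddz);
      if (dm > max_disp) { ddx *= max_disp/dm; ddy *= max_disp/dm; ddz *= max_disp/dm; }
      s.px[i] += ddx; s.py[i] += ddy; s.pz[i] += ddz;
      // relax membrane axes by steepest descent on torque, with the
      // rotation angle capped so orientations cannot flip within one step
      if (s.type[i] == T_MEM) {
        double tm = std::sqrt(s.tx[i]*s.tx[i] + s.ty[i]*s.ty[i] + s.tz[i]*s.tz[i]);
        double dtr = dt;
        if (tm * dtr > 0.1) dtr = 0.1 / tm;
        rotate_axis(s.nx[i], s.ny[i], s.nz[i], s.tx[i], s.ty[i], s.tz[i], dtr);
      }
    }
  }
  List out = pack(s);
  out["energy"] = U;
  out["fmax"] = fmax;
  out["iterations"] = it;
  out["converged"] = (fmax < ftol);
  return out;
}
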