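// Coarse-grained force field, AFM image restraint, and Langevin integrator.
//
// Conventions: lengths in Angstrom, energies in kcal/mol, charges in units
// of the elementary charge. Bead indices arriving from R are 1-based and
// converted here. Functional forms:
//   bond      U = k (r - r0)^2
//   angle     U = k (theta - theta0)^2
//   dihedral  U = k (1 - cos(phi - phi0))
//   contact   U = eps (5 (r0/r)^12 - 6 (r0/r)^10)      (12-10 Go well)
//   excl.vol. U = eps ((sigma/r)^12 - 1), r < sigma     (WCA-like, 0 beyond)
//   DH        U = (332.0637/eps_k) qi qj exp(-r/lambda)/r, cut + shifted
//   AFM       U = kappa kBT (1 - c.s.(H_ref, H_sim(R)))
#include <Rcpp.h>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

static const double COULOMB_K = 332.0637; // kcal*A/(mol*e^2)

struct Vec3 { double x, y, z; };

static inline long long pairkey(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (long long)i * n + j;
}

// minimum-image displacement component
static inline double mimg(double d, double L, bool periodic) {
  if (periodic && L > 0.0) d -= L * std::nearbyint(d / L);
  return d;
}

// ---------------------------------------------------------------------------
// Pseudo-AFM rendering.
//
// A bead i seen by a parabolic tip of sharpness length s contributes an
// effective height h_ip = z_i + r_i - d^2/(2 s) at lateral distance d from
// the pixel center. SOFT mode: H_p = (1/beta) log( exp(-beta*0) stage term
// folded in via max-shifted log-sum-exp ), smooth in positions with a hard-
// max limit as beta grows. HARD mode: beads are binned to the pixel holding
// their (x, y) (height z+r); an apex radius > 0 additionally spreads the
// parabolic cap to nearby pixel centers.
// ---------------------------------------------------------------------------
struct AFMGrid {
  int nx, ny;
  double px, x0, y0;
  double cx(int ix) const { return x0 + (ix + 0.5) * px; }
  double cy(int iy) const { return y0 + (iy + 0.5) * px; }
};

static void render_soft(const NumericMatrix& xyz, const NumericVector& radius,
                        const AFMGrid& g, double beta, double tip_s,
                        NumericMatrix& M, NumericMatrix& S, NumericMatrix& H) {
  const int n = xyz.nrow();
  std::fill(M.begin(), M.end(), 0.0); // stage height 0 is always a candidate
  // pass 1: per-pixel max effective height
  const double hdrop = 34.0 / beta;   // ignore contributions 34/beta below max
  for (int i = 0; i < n; ++i) {
    double zi = xyz(i, 2) + radius[i];
    if (zi < -hdrop) continue;
    double dmax2 = 2.0 * tip_s * (zi + hdrop);
    if (dmax2 <= 0) continue;
    double dmax = std::sqrt(dmax2);
    int ix0 = (int)std::floor((xyz(i, 0) - dmax - g.x0) / g.px);
    int ix1 = (int)std::floor((xyz(i, 0) + dmax - g.x0) / g.px);
    int iy0 = (int)std::floor((xyz(i, 1) - dmax - g.y0) / g.px);
    int iy1 = (int)std::floor((xyz(i, 1) + dmax - g.y0) / g.px);
    ix0 = std::max(ix0, 0); iy0 = std::max(iy0, 0);
    ix1 = std::min(ix1, g.nx - 1); iy1 = std::min(iy1, g.ny - 1);
    for (int ix = ix0; ix <= ix1; ++ix)
      for (int iy = iy0; iy <= iy1; ++iy) {
        double dx = xyz(i, 0) - g.cx(ix), dy = xyz(i, 1) - g.cy(iy);
        double h = zi - (dx * dx + dy * dy) / (2.0 * tip_s);
        if (h > M(ix, iy)) M(ix, iy) = h;
      }
  }
  // pass 2: shifted sums (stage term included)
  for (int ix = 0; ix < g.nx; ++ix)
    for (int iy = 0; iy < g.ny; ++iy)
      S(ix, iy) = std::exp(-beta * M(ix, iy)); // stage contribution exp(beta*(0-M))
  for (int i = 0; i < n; ++i) {
    double zi = xyz(i, 2) + radius[i];
    if (zi < -hdrop) continue;
    double dmax2 = 2.0 * tip_s * (zi + hdrop);
    if (dmax2 <= 0) continue;
    double dmax = std::sqrt(dmax2);
    int ix0 = std::max((int)std::floor((xyz(i, 0) - dmax - g.x0) / g.px), 0);
    int ix1 = std::min((int)std::floor((xyz(i, 0) + dmax - g.x0) / g.px), g.nx - 1);
    int iy0 = std::max((int)std::floor((xyz(i, 1) - dmax - g.y0) / g.px), 0);
    int iy1 = std::min((int)std::floor((xyz(i, 1) + dmax - g.y0) / g.px), g.ny - 1);
    for (int ix = ix0; ix <= ix1; ++ix)
      for (int iy = iy0; iy <= iy1; ++iy) {
        double dx = xyz(i, 0) - g.cx(ix), dy = xyz(i, 1) - g.cy(iy);
        double h = zi - (dx * dx + dy * dy) / (2.0 * tip_s);
        S(ix, iy) += std::exp(beta * (h - M(ix, iy)));
      }
  }
  for (int ix = 0; ix < g.nx; ++ix)
    for (int iy = 0; iy < g.ny; ++iy)
      H(ix, iy) = M(ix, iy) + std::log(S(ix, iy)) / beta;
}

static void render_hard(const NumericMatrix& xyz, const NumericVector& radius,
                        const AFMGrid& g, double apex, NumericMatrix& H) {
  const int n = xyz.nrow();
  std::fill(H.begin(), H.end(), 0.0);
  for (int i = 0; i < n; ++i) {
    double zi = xyz(i, 2) + radius[i];
    if (zi <= 0) continue;
    int bx = (int)std::floor((xyz(i, 0) - g.x0) / g.px);
    int by = (int)std::floor((xyz(i, 1) - g.y0) / g.px);
    if (bx >= 0 && bx < g.nx && by >= 0 && by < g.ny && zi > H(bx, by))
      H(bx, by) = zi;
    if (apex > 0) {
      int w = (int)std::ceil(apex / g.px) + 1;
      for (int ix = std::max(bx - w, 0); ix <= std::min(bx + w, g.nx - 1); ++ix)
        for (int iy = std::max(by - w, 0); iy <= std::min(by + w, g.ny - 1); ++iy) {
          double dx = xyz(i, 0) - g.cx(ix), dy = xyz(i, 1) - g.cy(iy);
          double d2 = dx * dx + dy * dy;
          if (d2 > apex * apex) continue;
          double h = zi - d2 / (2.0 * apex);
          if (h > H(ix, iy)) H(ix, iy) = h;
        }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix render_afm_cpp(NumericMatrix xyz, NumericVector radius,
                             int nx, int ny, double px, double x0, double y0,
                             bool soft, double beta, double tip_s, double apex) {
  AFMGrid g{nx, ny, px, x0, y0};
  NumericMatrix H(nx, ny);
  if (soft) {
    NumericMatrix M(nx, ny), S(nx, ny);
    render_soft(xyz, radius, g, beta, tip_s, M, S, H);
  } else {
    render_hard(xyz, radius, g, apex, H);
  }
  return H;
}

// AFM restraint energy and analytic forces (SOFT rendering).
// Adds forces into F; returns energy; cs and flag via references.
static double afm_term(const NumericMatrix& xyz, const NumericVector& radius,
                       const NumericMatrix& ref, const AFMGrid& g,
                       double beta, double tip_s, double kappa_kbt,
                       NumericMatrix& F, double& cs_out, bool& zero_image) {
  const int n = xyz.nrow();
  NumericMatrix M(g.nx, g.ny), S(g.nx, g.ny), H(g.nx, g.ny);
  render_soft(xyz, radius, g, beta, tip_s, M, S, H);
  double sab = 0, saa = 0, sbb = 0;
  for (int ix = 0; ix < g.nx; ++ix)
    for (int iy = 0; iy < g.ny; ++iy) {
      sab += ref(ix, iy) * H(ix, iy);
      saa += ref(ix, iy) * ref(ix, iy);
      sbb += H(ix, iy) * H(ix, iy);
    }
  if (sbb < 1e-12 || saa < 1e-12) { // molecule left the imaged region
    cs_out = 0.0; zero_image = true;
    return kappa_kbt; // kappa kBT (1 - 0); no forces applied
  }
  zero_image = false;
  double A = std::sqrt(saa), B = std::sqrt(sbb);
  double cs = sab / (A * B);
  cs_out = cs;
  // dV/dH_p = -kappa_kbt * ( ref_p/(A B) - cs H_p / B^2 )
  const double hdrop = 34.0 / beta;
  for (int i = 0; i < n; ++i) {
    double zi = xyz(i, 2) + radius[i];
    if (zi < -hdrop) continue;
    double dmax2 = 2.0 * tip_s * (zi + hdrop);
    if (dmax2 <= 0) continue;
    double dmax = std::sqrt(dmax2);
    int ix0 = std::max((int)std::floor((xyz(i, 0) - dmax - g.x0) / g.px), 0);
    int ix1 = std::min((int)std::floor((xyz(i, 0) + dmax - g.x0) / g.px), g.nx - 1);
    int iy0 = std::max((int)std::floor((xyz(i, 1) - dmax - g.y0) / g.px), 0);
    int iy1 = std::min((int)std::floor((xyz(i, 1) + dmax - g.y0) / g.px), g.ny - 1);
    for (int ix = ix0; ix <= ix1; ++ix)
      for (int iy = iy0; iy <= iy1; ++iy) {
        double dx = xyz(i, 0) - g.cx(ix), dy = xyz(i, 1) - g.cy(iy);
        double h = zi - (dx * dx + dy * dy) / (2.0 * tip_s);
        double w = std::exp(beta * (h - M(ix, iy))) / S(ix, iy);
        if (w < 1e-14) continue;
        double dVdH = -kappa_kbt * (ref(ix, iy) / (A * B) - cs * H(ix, iy) / sbb);
        // dH/dx_i = w * (-(dx)/tip_s), dH/dz_i = w
        F(i, 0) -= dVdH * w * (-dx / tip_s);
        F(i, 1) -= dVdH * w * (-dy / tip_s);
        F(i, 2) -= dVdH * w;
      }
  }
  return kappa_kbt * (1.0 - cs);
}

// [[Rcpp::export]]
List afm_score_forces_cpp(NumericMatrix xyz, NumericVector radius,
                          NumericMatrix ref, double px, double x0, double y0,
                          double beta, double tip_s, double kappa_kbt) {
  AFMGrid g{(int)ref.nrow(), (int)ref.ncol(), px, x0, y0};
  NumericMatrix F(xyz.nrow(), 3);
  double cs = 0; bool flag = false;
  double e = afm_term(xyz, radius, ref, g, beta, tip_s, kappa_kbt, F, cs, flag);
  return List::create(_["energy"] = e, _["cs"] = cs, _["forces"] = F,
                      _["zero_image"] = flag);
}

// ---------------------------------------------------------------------------
// Bonded + nonbonded energy/forces
// ---------------------------------------------------------------------------
struct FF {
  IntegerMatrix bonds; NumericVector bond_r0, bond_k;
  IntegerMatrix angles; NumericVector ang_th0, ang_k;
  IntegerMatrix dihs; NumericVector dih_phi0, dih_k;
  IntegerMatrix contacts; NumericVector con_r0, con_eps;
  NumericVector charge, radius;
  std::unordered_set<long long> excl_el, excl_ev;
  double dh_pref, lambda, dh_cut, dh_shift_scale; bool dh_on;
  double ev_eps; bool ev_on;
  NumericVector box; bool periodic;
  bool afm_on; NumericMatrix afm_ref; AFMGrid grid;
  double beta, tip_s, kappa_kbt;
};

static FF build_ff(List topo, List nb, Nullable<List> afm, int n) {
  FF ff;
  ff.bonds = as<IntegerMatrix>(topo["bonds"]);
  ff.bond_r0 = as<NumericVector>(topo["bond_r0"]);
  ff.bond_k = as<NumericVector>(topo["bond_k"]);
  ff.angles = as<IntegerMatrix>(topo["angles"]);
  ff.ang_th0 = as<NumericVector>(topo["angle_theta0"]);
  ff.ang_k = as<NumericVector>(topo["angle_k"]);
  ff.dihs = as<IntegerMatrix>(topo["dihedrals"]);
  ff.dih_phi0 = as<NumericVector>(topo["dihedral_phi0"]);
  ff.dih_k = as<NumericVector>(topo["dihedral_k"]);
  ff.contacts = as<IntegerMatrix>(topo["contacts"]);
  ff.con_r0 = as<NumericVector>(topo["contact_r0"]);
  ff.con_eps = as<NumericVector>(topo["contact_eps"]);
  ff.charge = as<NumericVector>(nb["charge"]);
  ff.radius = as<NumericVector>(nb["radius"]);
  IntegerMatrix eel = as<IntegerMatrix>(nb["excl_elec"]);
  IntegerMatrix eev = as<IntegerMatrix>(nb["excl_ev"]);
  for (int r = 0; r < eel.nrow(); ++r)
    ff.excl_el.insert(pairkey(eel(r, 0) - 1, eel(r, 1) - 1, n));
  for (int r = 0; r < eev.nrow(); ++r)
    ff.excl_ev.insert(pairkey(eev(r, 0) - 1, eev(r, 1) - 1, n));
  ff.dh_on = as<bool>(nb["dh_on"]);
  ff.dh_pref = COULOMB_K / as<double>(nb["eps_k"]);
  ff.lambda = as<double>(nb["lambda"]);
  ff.dh_cut = as<double>(nb["dh_cutoff"]);
  ff.dh_shift_scale = ff.dh_cut > 0 && std::isfinite(ff.dh_cut)
    ? std::exp(-ff.dh_cut / ff.lambda) / ff.dh_cut : 0.0;
  ff.ev_on = as<bool>(nb["ev_on"]);
  ff.ev_eps = as<double>(nb["ev_eps"]);
  ff.box = as<NumericVector>(nb["box"]);
  ff.periodic = as<bool>(nb["periodic"]);
  ff.afm_on = afm.isNotNull();
  if (ff.afm_on) {
    List a(afm);
    ff.afm_ref = as<NumericMatrix>(a["ref"]);
    ff.grid = AFMGrid{(int)ff.afm_ref.nrow(), (int)ff.afm_ref.ncol(),
                      as<double>(a["pixel_size"]),
                      as<double>(a["x0"]), as<double>(a["y0"])};
    ff.beta = as<double>(a["beta"]);
    ff.tip_s = as<double>(a["tip_s"]);
    ff.kappa_kbt = as<double>(a["kappa_kbt"]);
  }
  return ff;
}

static inline void cross(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Computes all terms; F must be zeroed by the caller.
static void eval_ff(const FF& ff, const NumericMatrix& xyz, NumericMatrix& F,
                    double* E /* bond angle dih contact ev elec afm */,
                    double& cs, bool& afm_flag) {
  const int n = xyz.nrow();
  for (int t = 0; t < 7; ++t) E[t] = 0.0;
  // bonds
  for (int b = 0; b < ff.bonds.nrow(); ++b) {
    int i = ff.bonds(b, 0) - 1, j = ff.bonds(b, 1) - 1;
    double d[3] = {xyz(i,0)-xyz(j,0), xyz(i,1)-xyz(j,1), xyz(i,2)-xyz(j,2)};
    double r = std::sqrt(dot(d, d));
    double dr = r - ff.bond_r0[b];
    E[0] += ff.bond_k[b] * dr * dr;
    double fmag = -2.0 * ff.bond_k[b] * dr / r;
    for (int c = 0; c < 3; ++c) { F(i,c) += fmag*d[c]; F(j,c) -= fmag*d[c]; }
  }
  // angles
  for (int a = 0; a < ff.angles.nrow(); ++a) {
    int i = ff.angles(a,0)-1, j = ff.angles(a,1)-1, k = ff.angles(a,2)-1;
    double u[3] = {xyz(i,0)-xyz(j,0), xyz(i,1)-xyz(j,1), xyz(i,2)-xyz(j,2)};
    double v[3] = {xyz(k,0)-xyz(j,0), xyz(k,1)-xyz(j,1), xyz(k,2)-xyz(j,2)};
    double lu = std::sqrt(dot(u,u)), lv = std::sqrt(dot(v,v));
    double ct = dot(u,v)/(lu*lv);
    ct = std::min(1.0, std::max(-1.0, ct));
    double th = std::acos(ct);
    double st = std::sqrt(std::max(1.0 - ct*ct, 1e-12)); // regularized near collinear
    double dth = th - ff.ang_th0[a];
    E[1] += ff.ang_k[a] * dth * dth;
    double dUdth = 2.0 * ff.ang_k[a] * dth;
    for (int c = 0; c < 3; ++c) {
      double dthdi = (ct * u[c]/lu - v[c]/lv) / (lu * st);
      double dthdk = (ct * v[c]/lv - u[c]/lu) / (lv * st);
      F(i,c) -= dUdth * dthdi;
      F(k,c) -= dUdth * dthdk;
      F(j,c) += dUdth * (dthdi + dthdk);
    }
  }
  // dihedrals
  for (int d0 = 0; d0 < ff.dihs.nrow(); ++d0) {
    int i = ff.dihs(d0,0)-1, j = ff.dihs(d0,1)-1,
        k = ff.dihs(d0,2)-1, l = ff.dihs(d0,3)-1;
    double b1[3] = {xyz(j,0)-xyz(i,0), xyz(j,1)-xyz(i,1), xyz(j,2)-xyz(i,2)};
    double b2[3] = {xyz(k,0)-xyz(j,0), xyz(k,1)-xyz(j,1), xyz(k,2)-xyz(j,2)};
    double b3[3] = {xyz(l,0)-xyz(k,0), xyz(l,1)-xyz(k,1), xyz(l,2)-xyz(k,2)};
    double n1[3], n2[3], m[3];
    cross(b1, b2, n1); cross(b2, b3, n2);
    double lb2 = std::sqrt(dot(b2,b2));
    cross(n1, n2, m);
    double phi = std::atan2(dot(m, b2)/lb2, dot(n1, n2));
    double dphi = phi - ff.dih_phi0[d0];
    E[2] += ff.dih_k[d0] * (1.0 - std::cos(dphi));
    double dUdphi = ff.dih_k[d0] * std::sin(dphi);
    double n1sq = std::max(dot(n1,n1), 1e-12), n2sq = std::max(dot(n2,n2), 1e-12);
    double t = dot(b1,b2)/(lb2*lb2), s = dot(b3,b2)/(lb2*lb2);
    for (int c = 0; c < 3; ++c) {
      double dpi = -lb2/n1sq * n1[c];
      double dpl =  lb2/n2sq * n2[c];
      double dpj = -(1.0 + t) * dpi + s * dpl;
      double dpk = t * dpi - (1.0 + s) * dpl;
      F(i,c) -= dUdphi * dpi;
      F(j,c) -= dUdphi * dpj;
      F(k,c) -= dUdphi * dpk;
      F(l,c) -= dUdphi * dpl;
    }
  }
  // native contacts (no minimum image: intra-molecular by construction)
  for (int c0 = 0; c0 < ff.contacts.nrow(); ++c0) {
    int i = ff.contacts(c0,0)-1, j = ff.contacts(c0,1)-1;
    double d[3] = {xyz(i,0)-xyz(j,0), xyz(i,1)-xyz(j,1), xyz(i,2)-xyz(j,2)};
    double r2 = dot(d,d), r = std::sqrt(r2);
    double q = ff.con_r0[c0] / r;
    double q2 = q*q, q4 = q2*q2, q10 = q4*q4*q2, q12 = q10*q2;
    E[3] += ff.con_eps[c0] * (5.0*q12 - 6.0*q10);
    double dUdr = 60.0 * ff.con_eps[c0] * (q10 - q12) / r;
    double fmag = -dUdr / r;
    for (int c = 0; c < 3; ++c) { F(i,c) += fmag*d[c]; F(j,c) -= fmag*d[c]; }
  }
  // nonbonded pair loops
  if (ff.ev_on || ff.dh_on) {
    double Lx = ff.box[0], Ly = ff.box[1], Lz = ff.box[2];
    for (int i = 0; i < n - 1; ++i) {
      bool qi = ff.charge[i] != 0.0;
      for (int j = i + 1; j < n; ++j) {
        double dx = mimg(xyz(i,0)-xyz(j,0), Lx, ff.periodic);
        double dy = mimg(xyz(i,1)-xyz(j,1), Ly, ff.periodic);
        double dz = mimg(xyz(i,2)-xyz(j,2), Lz, ff.periodic);
        double r2 = dx*dx + dy*dy + dz*dz;
        long long key = pairkey(i, j, n);
        if (ff.ev_on) {
          double sig = ff.radius[i] + ff.radius[j];
          if (r2 < sig*sig && !ff.excl_ev.count(key)) {
            double r = std::sqrt(r2);
            if (r < 1e-6) stop("singular overlap between beads %d and %d", i+1, j+1);
            double q = sig / r, q3 = q*q*q, q6 = q3*q3, q12 = q6*q6;
            E[4] += ff.ev_eps * (q12 - 1.0);
            double fmag = 12.0 * ff.ev_eps * q12 / r2; // -dU/dr / r
            F(i,0) += fmag*dx; F(i,1) += fmag*dy; F(i,2) += fmag*dz;
            F(j,0) -= fmag*dx; F(j,1) -= fmag*dy; F(j,2) -= fmag*dz;
          }
        }
        if (ff.dh_on && qi && ff.charge[j] != 0.0) {
          if (r2 < ff.dh_cut * ff.dh_cut && !ff.excl_el.count(key)) {
            double r = std::sqrt(r2);
            if (r < 1e-6) stop("singular overlap between beads %d and %d", i+1, j+1);
            double qq = ff.charge[i] * ff.charge[j] * ff.dh_pref;
            double ex = std::exp(-r / ff.lambda);
            E[5] += qq * (ex / r - ff.dh_shift_scale);
            double fmag = qq * ex * (1.0/(r*ff.lambda) + 1.0/r2) / r; // -dU/dr / r
            F(i,0) += fmag*dx; F(i,1) += fmag*dy; F(i,2) += fmag*dz;
            F(j,0) -= fmag*dx; F(j,1) -= fmag*dy; F(j,2) -= fmag*dz;
          }
        }
      }
    }
  }
  cs = NA_REAL; afm_flag = false;
  if (ff.afm_on)
    E[6] = afm_term(xyz, ff.radius, ff.afm_ref, ff.grid, ff.beta, ff.tip_s,
                    ff.kappa_kbt, F, cs, afm_flag);
}

// [[Rcpp::export]]
List energy_forces_cpp(NumericMatrix xyz, List topo, List nb,
                       Nullable<List> afm) {
  const int n = xyz.nrow();
  FF ff = build_ff(topo, nb, afm, n);
  NumericMatrix F(n, 3);
  double E[7]; double cs; bool flag;
  eval_ff(ff, xyz, F, E, cs, flag);
  NumericVector ev = NumericVector::create(
    _["bond"] = E[0], _["angle"] = E[1], _["dihedral"] = E[2],
    _["contact"] = E[3], _["excluded"] = E[4], _["electrostatic"] = E[5],
    _["afm"] = E[6]);
  return List::create(_["energies"] = ev, _["total"] = std::accumulate(E, E+7, 0.0),
                      _["forces"] = F, _["cs"] = cs, _["afm_zero_image"] = flag);
}

// ---------------------------------------------------------------------------
// BAOAB Langevin integrator (exact Ornstein-Uhlenbeck friction-noise substep;
// reduces to velocity Verlet at gamma -> 0). boundary: 0 open, 1 periodic
// (coordinates stored unwrapped; wrapping only inside pair distances),
// 2 reflective walls at [0, L].
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List run_langevin_cpp(NumericMatrix xyz0, Nullable<NumericMatrix> vel0,
                      List topo, List nb, Nullable<List> afm,
                      NumericVector mass, double gamma, double dt, double kbt,
                      int n_steps, int save_interval, int boundary) {
  const int n = xyz0.nrow();
  FF ff = build_ff(topo, nb, afm, n);
  NumericMatrix x = clone(xyz0), v(n, 3), F(n, 3);
  if (vel0.isNotNull()) v = clone(NumericMatrix(vel0));
  else if (kbt > 0) {
    for (int i = 0; i < n; ++i) {
      double s = std::sqrt(kbt / mass[i]);
      for (int c = 0; c < 3; ++c) v(i,c) = s * norm_rand();
    }
  }
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  int n_save = n_steps / save_interval + 1;
  NumericVector frames(n_save * n * 3);
  frames.attr("dim") = IntegerVector::create(n, 3, n_save);
  IntegerVector steps(n_save);
  NumericMatrix elog(n_save, 8); // 7 terms + kinetic
  NumericVector cs_log(n_save);
  LogicalVector flag_log(n_save);
  double E[7]; double cs; bool flag;

  // Safeguard against runaway steep-core collisions: per-bead forces are
  // capped at a magnitude far above anything the model produces in normal
  // dynamics, so a rare overshoot into an r^-12 core cannot detonate the
  // integration while ordinary trajectories are untouched.
  const double fmax = 500.0; // kcal/mol/A
  auto cap_forces = [&]() {
    for (int i = 0; i < n; ++i) {
      double f2 = F(i,0)*F(i,0) + F(i,1)*F(i,1) + F(i,2)*F(i,2);
      if (f2 > fmax * fmax) {
        double s = fmax / std::sqrt(f2);
        F(i,0) *= s; F(i,1) *= s; F(i,2) *= s;
      }
    }
  };

  std::fill(F.begin(), F.end(), 0.0);
  eval_ff(ff, x, F, E, cs, flag);
  cap_forces();
  auto record = [&](int slot, int step) {
    steps[slot] = step;
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) frames[slot*n*3 + c*n + i] = x(i,c);
    double ke = 0;
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) ke += 0.5 * mass[i] * v(i,c) * v(i,c);
    for (int t = 0; t < 7; ++t) elog(slot, t) = E[t];
    elog(slot, 7) = ke;
    cs_log[slot] = cs; flag_log[slot] = flag;
  };
  record(0, 0);
  int slot = 1;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      double hdtm = 0.5 * dt / mass[i];
      for (int c = 0; c < 3; ++c) {
        v(i,c) += hdtm * F(i,c);
        x(i,c) += 0.5 * dt * v(i,c);
      }
    }
    if (kbt > 0 || gamma > 0) {
      for (int i = 0; i < n; ++i) {
        double s = std::sqrt(kbt / mass[i]);
        for (int c = 0; c < 3; ++c)
          v(i,c) = c1 * v(i,c) + c2 * s * norm_rand();
      }
    }
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c)
        x(i,c) += 0.5 * dt * v(i,c);
    if (boundary == 2) {
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c) {
          double L = ff.box[c];
          if (x(i,c) < 0)      { x(i,c) = -x(i,c); v(i,c) = -v(i,c); }
          else if (x(i,c) > L) { x(i,c) = 2*L - x(i,c); v(i,c) = -v(i,c); }
        }
    }
    std::fill(F.begin(), F.end(), 0.0);
    eval_ff(ff, x, F, E, cs, flag);
    cap_forces();
    for (int i = 0; i < n; ++i) {
      double hdtm = 0.5 * dt / mass[i];
      for (int c = 0; c < 3; ++c) {
        v(i,c) += hdtm * F(i,c);
        if (!std::isfinite(x(i,c)))
          stop("non-finite position at step %d (bead %d); largest |F| = %g",
               step, i + 1, max(abs(F)));
      }
    }
    if (step % save_interval == 0 && slot < n_save) { record(slot, step); ++slot; }
  }
  colnames(elog) = CharacterVector::create("bond", "angle", "dihedral",
    "contact", "excluded", "electrostatic", "afm", "kinetic");
  return List::create(_["frames"] = frames, _["steps"] = steps,
                      _["energies"] = elog, _["cs"] = cs_log,
                      _["afm_zero_image"] = flag_log,
                      _["velocities"] = v);
}

// Per-frame minimum distance from each of a set of reference beads to any
// bead of a second set; used by contact/event analyses.
// [[Rcpp::export]]
NumericMatrix min_dist_series_cpp(NumericVector frames, IntegerVector sel_a,
                                  IntegerVector sel_b) {
  IntegerVector dim = frames.attr("dim");
  int n = dim[0], n_save = dim[2];
  NumericMatrix out(n_save, sel_a.size());
  for (int f = 0; f < n_save; ++f) {
    for (int ia = 0; ia < sel_a.size(); ++ia) {
      int i = sel_a[ia] - 1;
      double best = R_PosInf;
      double xi = frames[f*n*3 + 0*n + i], yi = frames[f*n*3 + 1*n + i],
             zi = frames[f*n*3 + 2*n + i];
      for (int ib = 0; ib < sel_b.size(); ++ib) {
        int j = sel_b[ib] - 1;
        double dx = xi - frames[f*n*3 + 0*n + j];
        double dy = yi - frames[f*n*3 + 1*n + j];
        double dz = zi - frames[f*n*3 + 2*n + j];
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 < best) best = d2;
      }
      out(f, ia) = std::sqrt(best);
    }
  }
  return out;
}
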