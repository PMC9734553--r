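// kapcg engine: 1BPA force field, BAOAB Langevin integrator, contact kernel.
// Units: nm, ps, kJ/mol, g/mol, e, K.  kB = 0.00831446... kJ/mol/K.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <unordered_set>
using namespace Rcpp;

static const double KB = 0.00831446261815324;

// ---------------------------------------------------------------- RNG ----
// xoshiro256++ seeded via splitmix64: deterministic across platforms.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
    have_spare = false;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  bool have_spare; double spare;
  inline double gauss() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = 0.0, u2;
    do { u1 = unif(); } while (u1 <= 0.0);
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    spare = r * std::sin(a); have_spare = true;
    return r * std::cos(a);
  }
};

// ------------------------------------------------------------- system ----
struct Sys {
  int n;
  std::vector<double> pos, vel, charge, mass, hyd;
  std::vector<int> chain;
  std::vector<char> aromatic, is_pr;
  std::vector<int> b_i, b_j, b_type;      // bonds: backbone(0)/elastic(1)
  std::vector<double> b_r0, b_k;
  std::vector<int> a_i, a_j, a_k;
  std::vector<double> a_kc, a_t0;
  std::vector<int> d_i, d_j, d_k, d_l;
  std::vector<double> d_kc, d_p0;
  std::vector<double> teth_k, teth_pos;
  std::unordered_set<long long> excl;
  double box;
  inline bool excluded(int i, int j) const {
    if (i > j) std::swap(i, j);
    return excl.count((long long)i * n + j) > 0;
  }
};

struct Par {
  int eps_mode; double eps_r, dd_xi, lambda_d, coulomb;
  double cutoff, cut2, skin;
  double catpi_depth, catpi_sigma, catpi_A, catpi_gc;
  double ev_eps, ev_sigma, ev_sig2;
  double hp_eps, hp_sigma, hp_gc, hp_scaleA;  // A_ij = depth_ij * hp_scaleA
  double elec_shift_unit;                     // s(rc): shift per unit qq
};

static inline double g126(double sig, double r) {
  double s2 = sig * sig / (r * r);
  double s6 = s2 * s2 * s2;
  return s6 * s6 - 2.0 * s6;
}

// screened-Coulomb radial part s(r) (per unit coulomb*qq) and derivative
static inline void elec_s(const Par& P, double r, double& s, double& ds) {
  double a1 = 1.0 / P.lambda_d;
  double e1 = std::exp(-a1 * r) / r;
  if (P.eps_mode == 0) {
    s = e1 / P.eps_r;
    ds = -e1 * (a1 * r + 1.0) / (r * P.eps_r);
  } else {
    // eps(r) = eps_r / (1 + (eps_r-1) exp(-r/xi))
    double B = P.eps_r - 1.0, a2 = a1 + 1.0 / P.dd_xi;
    double e2 = std::exp(-a2 * r) / r;
    s = (e1 + B * e2) / P.eps_r;
    ds = (-e1 * (a1 * r + 1.0) / r - B * e2 * (a2 * r + 1.0) / r) / P.eps_r;
  }
}

static Sys parse_sys(const List& sl) {
  Sys S;
  NumericMatrix pos = sl["pos"];
  S.n = pos.nrow();
  S.pos.resize(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) S.pos[3 * i + d] = pos(i, d);
  NumericVector q = sl["charge"], m = sl["mass"], h = sl["hyd"];
  LogicalVector ar = sl["aromatic"], pr = sl["is_pr"];
  IntegerVector ch = sl["chain"];
  S.charge.assign(q.begin(), q.end());
  S.mass.assign(m.begin(), m.end());
  S.hyd.assign(h.begin(), h.end());
  S.chain.assign(ch.begin(), ch.end());
  S.aromatic.resize(S.n); S.is_pr.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    S.aromatic[i] = ar[i] ? 1 : 0;
    S.is_pr[i] = pr[i] ? 1 : 0;
  }
  IntegerMatrix b = sl["bonds"];
  NumericVector br0 = sl["bond_r0"], bk = sl["bond_k"];
  IntegerVector bt = sl["bond_type"];
  for (int r = 0; r < b.nrow(); ++r) {
    S.b_i.push_back(b(r, 0) - 1); S.b_j.push_back(b(r, 1) - 1);
    S.b_r0.push_back(br0[r]); S.b_k.push_back(bk[r]);
    S.b_type.push_back(bt[r]);
  }
  IntegerMatrix a = sl["angles"];
  NumericVector akc = sl["angle_k"], at0 = sl["angle_theta0"];
  for (int r = 0; r < a.nrow(); ++r) {
    S.a_i.push_back(a(r, 0) - 1); S.a_j.push_back(a(r, 1) - 1);
    S.a_k.push_back(a(r, 2) - 1);
    S.a_kc.push_back(akc[r]); S.a_t0.push_back(at0[r]);
  }
  IntegerMatrix dd = sl["dihedrals"];
  NumericVector dkc = sl["dihedral_k"], dp0 = sl["dihedral_phi0"];
  for (int r = 0; r < dd.nrow(); ++r) {
    S.d_i.push_back(dd(r, 0) - 1); S.d_j.push_back(dd(r, 1) - 1);
    S.d_k.push_back(dd(r, 2) - 1); S.d_l.push_back(dd(r, 3) - 1);
    S.d_kc.push_back(dkc[r]); S.d_p0.push_back(dp0[r]);
  }
  IntegerMatrix ex = sl["exclusions"];
  for (int r = 0; r < ex.nrow(); ++r) {
    int i = ex(r, 0) - 1, j = ex(r, 1) - 1;
    if (i > j) std::swap(i, j);
    S.excl.insert((long long)i * S.n + j);
  }
  NumericVector tk = sl["tether_k"];
  NumericMatrix tp = sl["tether_pos"];
  S.teth_k.assign(tk.begin(), tk.end());
  S.teth_pos.resize(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) S.teth_pos[3 * i + d] = tp(i, d);
  S.box = as<double>(sl["box"]);
  return S;
}

static Par parse_par(const List& pl) {
  Par P;
  P.eps_mode = as<int>(pl["eps_mode"]);
  P.eps_r = as<double>(pl["eps_r"]);
  P.dd_xi = as<double>(pl["dd_xi"]);
  P.lambda_d = as<double>(pl["lambda_d"]);
  P.coulomb = as<double>(pl["coulomb"]);
  P.cutoff = as<double>(pl["cutoff"]);
  P.cut2 = P.cutoff * P.cutoff;
  P.skin = as<double>(pl["skin"]);
  P.catpi_depth = as<double>(pl["catpi_depth"]);
  P.catpi_sigma = as<double>(pl["catpi_sigma"]);
  P.ev_eps = as<double>(pl["ev_eps"]);
  P.ev_sigma = as<double>(pl["ev_sigma"]);
  P.ev_sig2 = P.ev_sigma * P.ev_sigma;
  P.hp_eps = as<double>(pl["hp_eps"]);
  P.hp_sigma = as<double>(pl["hp_sigma"]);
  P.catpi_gc = g126(P.catpi_sigma, P.cutoff);
  P.catpi_A = P.catpi_depth / (1.0 + P.catpi_gc);
  P.hp_gc = g126(P.hp_sigma, P.cutoff);
  P.hp_scaleA = 1.0 / (1.0 + P.hp_gc);
  double s, ds; elec_s(P, P.cutoff, s, ds);
  P.elec_shift_unit = s;
  return P;
}

static inline void min_image(const Sys& S, double& dx, double& dy,
                             double& dz) {
  if (S.box > 0) {
    dx -= S.box * std::nearbyint(dx / S.box);
    dy -= S.box * std::nearbyint(dy / S.box);
    dz -= S.box * std::nearbyint(dz / S.box);
  }
}

struct Energy {
  double bb = 0, elastic = 0, angle = 0, dihedral = 0, tether = 0,
         elec = 0, catpi = 0, ev = 0, hp = 0;
  double pot() const {
    return bb + elastic + angle + dihedral + tether + elec + catpi + ev + hp;
  }
};

// ------------------------------------------------------- force kernels ----
static void nb_pair(const Sys& S, const Par& P, int i, int j,
                    std::vector<double>& F, Energy& E) {
  double dx = S.pos[3 * i] - S.pos[3 * j];
  double dy = S.pos[3 * i + 1] - S.pos[3 * j + 1];
  double dz = S.pos[3 * i + 2] - S.pos[3 * j + 2];
  min_image(S, dx, dy, dz);
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 >= P.cut2) return;
  if (r2 < 1e-8)
    stop("overlapping beads %d and %d (r < 1e-4 nm)", i + 1, j + 1);
  double r = std::sqrt(r2);
  double dUdr = 0.0;
  bool same = S.chain[i] == S.chain[j];
  bool pri = S.is_pr[i], prj = S.is_pr[j];

  // excluded volume (all pair classes)
  if (r < P.ev_sigma) {
    double s2 = P.ev_sig2 / r2, s6 = s2 * s2 * s2, s12 = s6 * s6;
    E.ev += P.ev_eps * (s12 - 2.0 * s6 + 1.0);
    dUdr += -12.0 * P.ev_eps * (s12 - s6) / r;
  }
  // screened electrostatics (skip intra-receptor pairs)
  double qq = S.charge[i] * S.charge[j];
  if (qq != 0.0 && !(same && !pri && !prj)) {
    double s, ds; elec_s(P, r, s, ds);
    E.elec += P.coulomb * qq * (s - P.elec_shift_unit);
    dUdr += P.coulomb * qq * ds;
  }
  // cation-pi across the PR/receptor interface
  if (pri != prj) {
    bool cp = (S.charge[i] > 0 && S.aromatic[j]) ||
              (S.charge[j] > 0 && S.aromatic[i]);
    if (cp) {
      double g = g126(P.catpi_sigma, r);
      E.catpi += P.catpi_A * (g - P.catpi_gc);
      double s2 = P.catpi_sigma * P.catpi_sigma / r2;
      double s6 = s2 * s2 * s2, s12 = s6 * s6;
      dUdr += -12.0 * P.catpi_A * (s12 - s6) / r;
    }
  }
  // hydrophobic well within/between poly-PR chains
  if (pri && prj) {
    double depth = P.hp_eps * 0.5 * (S.hyd[i] + S.hyd[j]);
    if (depth > 0) {
      double A = depth * P.hp_scaleA;
      double g = g126(P.hp_sigma, r);
      E.hp += A * (g - P.hp_gc);
      double s2 = P.hp_sigma * P.hp_sigma / r2;
      double s6 = s2 * s2 * s2, s12 = s6 * s6;
      dUdr += -12.0 * A * (s12 - s6) / r;
    }
  }
  if (dUdr != 0.0) {
    double f = -dUdr / r;
    F[3 * i] += f * dx; F[3 * i + 1] += f * dy; F[3 * i + 2] += f * dz;
    F[3 * j] -= f * dx; F[3 * j + 1] -= f * dy; F[3 * j + 2] -= f * dz;
  }
}

static void bonded_forces(const Sys& S, const Par& P, std::vector<double>& F,
                          Energy& E) {
  // bonds (backbone + elastic network)
  for (size_t b = 0; b < S.b_i.size(); ++b) {
    int i = S.b_i[b], j = S.b_j[b];
    double dx = S.pos[3 * i] - S.pos[3 * j];
    double dy = S.pos[3 * i + 1] - S.pos[3 * j + 1];
    double dz = S.pos[3 * i + 2] - S.pos[3 * j + 2];
    min_image(S, dx, dy, dz);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-8) stop("overlapping bonded beads %d and %d", i + 1, j + 1);
    double dr = r - S.b_r0[b];
    double u = 0.5 * S.b_k[b] * dr * dr;
    if (S.b_type[b] == 0) E.bb += u; else E.elastic += u;
    double f = -S.b_k[b] * dr / r;
    F[3 * i] += f * dx; F[3 * i + 1] += f * dy; F[3 * i + 2] += f * dz;
    F[3 * j] -= f * dx; F[3 * j + 1] -= f * dy; F[3 * j + 2] -= f * dz;
  }
  // angles
  for (size_t a = 0; a < S.a_i.size(); ++a) {
    int i = S.a_i[a], j = S.a_j[a], k = S.a_k[a];
    double ux = S.pos[3 * i] - S.pos[3 * j];
    double uy = S.pos[3 * i + 1] - S.pos[3 * j + 1];
    double uz = S.pos[3 * i + 2] - S.pos[3 * j + 2];
    double vx = S.pos[3 * k] - S.pos[3 * j];
    double vy = S.pos[3 * k + 1] - S.pos[3 * j + 1];
    double vz = S.pos[3 * k + 2] - S.pos[3 * j + 2];
    min_image(S, ux, uy, uz);
    min_image(S, vx, vy, vz);
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    double c = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    if (c > 1.0 - 1e-10) c = 1.0 - 1e-10;
    if (c < -1.0 + 1e-10) c = -1.0 + 1e-10;
    double th = std::acos(c), sth = std::sqrt(1.0 - c * c);
    double dU = S.a_kc[a] * (th - S.a_t0[a]);
    E.angle += 0.5 * S.a_kc[a] * (th - S.a_t0[a]) * (th - S.a_t0[a]);
    double coef = dU / sth;
    double fix = coef * (vx / (nu * nv) - c * ux / (nu * nu));
    double fiy = coef * (vy / (nu * nv) - c * uy / (nu * nu));
    double fiz = coef * (vz / (nu * nv) - c * uz / (nu * nu));
    double fkx = coef * (ux / (nu * nv) - c * vx / (nv * nv));
    double fky = coef * (uy / (nu * nv) - c * vy / (nv * nv));
    double fkz = coef * (uz / (nu * nv) - c * vz / (nv * nv));
    F[3 * i] += fix; F[3 * i + 1] += fiy; F[3 * i + 2] += fiz;
    F[3 * k] += fkx; F[3 * k + 1] += fky; F[3 * k + 2] += fkz;
    F[3 * j] -= fix + fkx; F[3 * j + 1] -= fiy + fky;
    F[3 * j + 2] -= fiz + fkz;
  }
  // proper dihedrals U = k (1 + cos(phi - phi0))
  for (size_t d = 0; d < S.d_i.size(); ++d) {
    int i = S.d_i[d], j = S.d_j[d], k = S.d_k[d], l = S.d_l[d];
    double b1x = S.pos[3 * j] - S.pos[3 * i];
    double b1y = S.pos[3 * j + 1] - S.pos[3 * i + 1];
    double b1z = S.pos[3 * j + 2] - S.pos[3 * i + 2];
    double b2x = S.pos[3 * k] - S.pos[3 * j];
    double b2y = S.pos[3 * k + 1] - S.pos[3 * j + 1];
    double b2z = S.pos[3 * k + 2] - S.pos[3 * j + 2];
    double b3x = S.pos[3 * l] - S.pos[3 * k];
    double b3y = S.pos[3 * l + 1] - S.pos[3 * k + 1];
    double b3z = S.pos[3 * l + 2] - S.pos[3 * k + 2];
    min_image(S, b1x, b1y, b1z);
    min_image(S, b2x, b2y, b2z);
    min_image(S, b3x, b3y, b3z);
    double n1x = b1y * b2z - b1z * b2y;
    double n1y = b1z * b2x - b1x * b2z;
    double n1z = b1x * b2y - b1y * b2x;
    double n2x = b2y * b3z - b2z * b3y;
    double n2y = b2z * b3x - b2x * b3z;
    double n2z = b2x * b3y - b2y * b3x;
    double n1sq = n1x * n1x + n1y * n1y + n1z * n1z;
    double n2sq = n2x * n2x + n2y * n2y + n2z * n2z;
    double nb2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
    if (n1sq < 1e-14 || n2sq < 1e-14 || nb2 < 1e-7) continue;
    double mx = n1y * n2z - n1z * n2y;
    double my = n1z * n2x - n1x * n2z;
    double mz = n1x * n2y - n1y * n2x;
    double y = (mx * b2x + my * b2y + mz * b2z) / nb2;
    double x = n1x * n2x + n1y * n2y + n1z * n2z;
    double phi = std::atan2(y, x);
    double dU = -S.d_kc[d] * std::sin(phi - S.d_p0[d]);
    E.dihedral += S.d_kc[d] * (1.0 + std::cos(phi - S.d_p0[d]));
    // F_i = dU |b2|/|n1|^2 n1 ; F_l = -dU |b2|/|n2|^2 n2 ;
    // F_j = -(1+t1) F_i + t2 F_l ; F_k = t1 F_i - (1+t2) F_l
    // with t1 = b1.b2/|b2|^2, t2 = b3.b2/|b2|^2 (verified against the
    // numeric gradient of phi)
    double ci = dU * nb2 / n1sq;
    double cl = -dU * nb2 / n2sq;
    double fix = ci * n1x, fiy = ci * n1y, fiz = ci * n1z;
    double flx = cl * n2x, fly = cl * n2y, flz = cl * n2z;
    double t1 = (b1x * b2x + b1y * b2y + b1z * b2z) / (nb2 * nb2);
    double t2 = (b3x * b2x + b3y * b2y + b3z * b2z) / (nb2 * nb2);
    double fjx = -(1 + t1) * fix + t2 * flx;
    double fjy = -(1 + t1) * fiy + t2 * fly;
    double fjz = -(1 + t1) * fiz + t2 * flz;
    double fkx = t1 * fix - (1 + t2) * flx;
    double fky = t1 * fiy - (1 + t2) * fly;
    double fkz = t1 * fiz - (1 + t2) * flz;
    F[3 * i] += fix; F[3 * i + 1] += fiy; F[3 * i + 2] += fiz;
    F[3 * j] += fjx; F[3 * j + 1] += fjy; F[3 * j + 2] += fjz;
    F[3 * k] += fkx; F[3 * k + 1] += fky; F[3 * k + 2] += fkz;
    F[3 * l] += flx; F[3 * l + 1] += fly; F[3 * l + 2] += flz;
  }
  // external harmonic tethers (test instrumentation)
  for (int i = 0; i < S.n; ++i) {
    if (S.teth_k[i] <= 0) continue;
    double dx = S.pos[3 * i] - S.teth_pos[3 * i];
    double dy = S.pos[3 * i + 1] - S.teth_pos[3 * i + 1];
    double dz = S.pos[3 * i + 2] - S.teth_pos[3 * i + 2];
    E.tether += 0.5 * S.teth_k[i] * (dx * dx + dy * dy + dz * dz);
    F[3 * i] -= S.teth_k[i] * dx;
    F[3 * i + 1] -= S.teth_k[i] * dy;
    F[3 * i + 2] -= S.teth_k[i] * dz;
  }
}

// Verlet list
struct NList {
  std::vector<int> pi, pj;
  std::vector<double> ref;  // positions at build time
  void build(const Sys& S, const Par& P) {
    pi.clear(); pj.clear();
    double rl = P.cutoff + P.skin, rl2 = rl * rl;
    for (int i = 0; i < S.n; ++i)
      for (int j = i + 1; j < S.n; ++j) {
        if (S.excluded(i, j)) continue;
        double dx = S.pos[3 * i] - S.pos[3 * j];
        double dy = S.pos[3 * i + 1] - S.pos[3 * j + 1];
        double dz = S.pos[3 * i + 2] - S.pos[3 * j + 2];
        min_image(S, dx, dy, dz);
        if (dx * dx + dy * dy + dz * dz < rl2) { pi.push_back(i);
                                                 pj.push_back(j); }
      }
    ref = S.pos;
  }
  bool stale(const Sys& S, const Par& P) const {
    double lim = 0.25 * P.skin * P.skin;  // (skin/2)^2
    for (int i = 0; i < S.n; ++i) {
      double dx = S.pos[3 * i] - ref[3 * i];
      double dy = S.pos[3 * i + 1] - ref[3 * i + 1];
      double dz = S.pos[3 * i + 2] - ref[3 * i + 2];
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }
};

static Energy compute_forces(const Sys& S, const Par& P, const NList& nl,
                             std::vector<double>& F) {
  std::fill(F.begin(), F.end(), 0.0);
  Energy E;
  bonded_forces(S, P, F, E);
  for (size_t p = 0; p < nl.pi.size(); ++p)
    nb_pair(S, P, nl.pi[p], nl.pj[p], F, E);
  return E;
}

static NumericVector energy_vec(const Energy& E) {
  return NumericVector::create(
    _["bond_backbone"] = E.bb, _["elastic"] = E.elastic,
    _["angle"] = E.angle, _["dihedral"] = E.dihedral,
    _["tether"] = E.tether, _["elec"] = E.elec, _["catpi"] = E.catpi,
    _["ev"] = E.ev, _["hydrophobic"] = E.hp);
}

// [[Rcpp::export]]
List cpp_energy_forces(List sys, List par) {
  Sys S = parse_sys(sys);
  Par P = parse_par(par);
  NList nl; nl.build(S, P);
  std::vector<double> F(3 * S.n);
  Energy E = compute_forces(S, P, nl, F);
  NumericMatrix Fm(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) Fm(i, d) = F[3 * i + d];
  return List::create(_["forces"] = Fm, _["energy"] = energy_vec(E));
}

// [[Rcpp::export]]
List cpp_run_md(List sys, List par, int n_steps, double dt, double gamma,
                double temperature, double seed, int save_interval,
                int log_interval) {
  Sys S = parse_sys(sys);
  Par P = parse_par(par);
  NumericMatrix vel0 = sys["vel"];
  S.vel.resize(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) S.vel[3 * i + d] = vel0(i, d);
  if (save_interval < 1) save_interval = 1;
  if (log_interval < 1) log_interval = save_interval;
  Xoshiro rng((uint64_t)seed);

  NList nl; nl.build(S, P);
  std::vector<double> F(3 * S.n);
  Energy E = compute_forces(S, P, nl, F);

  int n_frames = n_steps / save_interval + 1;
  NumericVector frames(Dimension(S.n, 3, n_frames));
  NumericVector times(n_frames);
  int n_logs = n_steps / log_interval + 1;
  NumericMatrix elog(n_logs, 12);
  colnames(elog) = CharacterVector::create(
    "time", "bond_backbone", "elastic", "angle", "dihedral", "tether",
    "elec", "catpi", "ev", "hydrophobic", "potential", "kinetic");

  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  auto save_frame = [&](int fidx, double t) {
    for (int i = 0; i < S.n; ++i)
      for (int d = 0; d < 3; ++d)
        frames[fidx * 3 * S.n + d * S.n + i] = S.pos[3 * i + d];
    times[fidx] = t;
  };
  auto log_row = [&](int ridx, double t) {
    double ke = 0;
    for (int i = 0; i < S.n; ++i)
      ke += 0.5 * S.mass[i] * (S.vel[3 * i] * S.vel[3 * i] +
                               S.vel[3 * i + 1] * S.vel[3 * i + 1] +
                               S.vel[3 * i + 2] * S.vel[3 * i + 2]);
    elog(ridx, 0) = t; elog(ridx, 1) = E.bb; elog(ridx, 2) = E.elastic;
    elog(ridx, 3) = E.angle; elog(ridx, 4) = E.dihedral;
    elog(ridx, 5) = E.tether; elog(ridx, 6) = E.elec;
    elog(ridx, 7) = E.catpi; elog(ridx, 8) = E.ev; elog(ridx, 9) = E.hp;
    elog(ridx, 10) = E.pot(); elog(ridx, 11) = ke;
  };
  save_frame(0, 0.0);
  log_row(0, 0.0);

  int fidx = 1, ridx = 1;
  for (int step = 1; step <= n_steps; ++step) {
    // BAOAB splitting
    for (int i = 0; i < S.n; ++i) {
      double hm = 0.5 * dt / S.mass[i];
      for (int d = 0; d < 3; ++d) S.vel[3 * i + d] += hm * F[3 * i + d];
    }
    for (int i = 0; i < 3 * S.n; ++i) S.pos[i] += 0.5 * dt * S.vel[i];
    if (temperature > 0 || gamma > 0) {
      for (int i = 0; i < S.n; ++i) {
        double sig = std::sqrt(KB * temperature / S.mass[i]);
        for (int d = 0; d < 3; ++d)
          S.vel[3 * i + d] = c1 * S.vel[3 * i + d] + c2 * sig * rng.gauss();
      }
    }
    for (int i = 0; i < 3 * S.n; ++i) S.pos[i] += 0.5 * dt * S.vel[i];
    if (nl.stale(S, P)) nl.build(S, P);
    E = compute_forces(S, P, nl, F);
    for (int i = 0; i < S.n; ++i) {
      double hm = 0.5 * dt / S.mass[i];
      for (int d = 0; d < 3; ++d) S.vel[3 * i + d] += hm * F[3 * i + d];
    }
    if (step % save_interval == 0) {
      for (int i = 0; i < 3 * S.n; ++i)
        if (!std::isfinite(S.pos[i]))
          stop("non-finite coordinate at step %d", step);
      save_frame(fidx++, step * dt);
    }
    if (step % log_interval == 0) log_row(ridx++, step * dt);
    if (step % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pos_out(S.n, 3), vel_out(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int d = 0; d < 3; ++d) {
      pos_out(i, d) = S.pos[3 * i + d];
      vel_out(i, d) = S.vel[3 * i + d];
    }
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["energy_log"] = elog, _["positions"] = pos_out,
                      _["velocities"] = vel_out);
}

// all structured-bead pairs with |i-j| >= 2 within cutoff (0-based idx in,
// 0-based global indices out)
// [[Rcpp::export]]
List cpp_elastic_pairs(NumericMatrix pos, IntegerVector idx, double cutoff) {
  std::vector<int> oi, oj;
  std::vector<double> r0;
  double c2 = cutoff * cutoff;
  for (int a = 0; a < idx.size(); ++a)
    for (int b = a + 1; b < idx.size(); ++b) {
      int i = idx[a], j = idx[b];
      if (j - i < 2) continue;
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 <= c2) {
        oi.push_back(i); oj.push_back(j); r0.push_back(std::sqrt(r2));
      }
    }
  return List::create(_["i"] = wrap(oi), _["j"] = wrap(oj),
                      _["r0"] = wrap(r0));
}

// pair contacts between bead sets A and B at a distance cutoff
// [[Rcpp::export]]
List cpp_frame_contacts(NumericMatrix posA, NumericMatrix posB, double box,
                        double cutoff) {
  int nA = posA.nrow(), nB = posB.nrow();
  LogicalVector fA(nA), fB(nB);
  int count = 0;
  double c2 = cutoff * cutoff;
  for (int i = 0; i < nA; ++i)
    for (int j = 0; j < nB; ++j) {
      double dx = posA(i, 0) - posB(j, 0);
      double dy = posA(i, 1) - posB(j, 1);
      double dz = posA(i, 2) - posB(j, 2);
      if (box > 0) {
        dx -= box * std::nearbyint(dx / box);
        dy -= box * std::nearbyint(dy / box);
        dz -= box * std::nearbyint(dz / box);
      }
      if (dx * dx + dy * dy + dz * dz <= c2) {
        ++count; fA[i] = true; fB[j] = true;
      }
    }
  return List::create(_["count"] = count, _["flagsA"] = fA,
                      _["flagsB"] = fB);
}
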