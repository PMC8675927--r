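// Numerical core: membrane reaction-diffusion (FTCS), 3D vertex-model
// geometry/energy/forces, overdamped relaxation, and the coupled
// mechano-polarity driver. All heavy per-timestep loops live here; the R
// layer owns construction, validation and orchestration.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Reaction-diffusion of the A/P/B polarity network on the half-perimeter
// ---------------------------------------------------------------------------

// Parameter vector layout (kept in step with R's polarity_params()):
// 0 DA, 1 DP, 2 DB, 3 konA, 4 koffA, 5 Atot, 6 kAB, 7 kAP,
// 8 konP, 9 koffP, 10 Ptot, 11 kPA, 12 konB, 13 koffB, 14 Btot,
// 15 kBA, 16 kBP, 17 alpha, 18 beta, 19 gamma, 20 zeta, 21 eps
static const int RD_NPAR = 22;

static inline double pow_fast(double x, double e) {
  if (e == 1.0) return x;
  if (e == 2.0) return x * x;
  if (x <= 0.0) return 0.0;
  return std::pow(x, e);
}

static inline double vmean(const std::vector<double>& x) {
  double s = 0.0;
  for (size_t i = 0; i < x.size(); ++i) s += x[i];
  return s / (double)x.size();
}

// One FTCS step. bc: 0 = reflect (zero flux at both ends, cell-centred grid),
// 1 = wrap (periodic). Returns the number of nodes clamped at zero.
static long rd_step_impl(std::vector<double>& A, std::vector<double>& P,
                         std::vector<double>& B, const double* p,
                         double psi, double L, double dt, int bc,
                         std::vector<double>& RA, std::vector<double>& RP,
                         std::vector<double>& RB) {
  const int n = (int)A.size();
  const double ds2 = (L / n) * (L / n);
  double Ac = p[5] - psi * vmean(A);
  double Pc = p[10] - psi * vmean(P);
  double Bc = p[14] - psi * vmean(B);
  // cell shrinkage can transiently overdraw the cytosol (psi rises while
  // the membrane amount is conserved); clamp at zero and let the
  // dissociation terms drain the membrane
  long nclamp0 = 0;
  if (Ac < 0.0) { Ac = 0.0; ++nclamp0; }
  if (Pc < 0.0) { Pc = 0.0; ++nclamp0; }
  if (Bc < 0.0) { Bc = 0.0; ++nclamp0; }
  for (int i = 0; i < n; ++i) {
    const double a = A[i], pp = P[i], b = B[i];
    RA[i] = p[3] * (1.0 + p[6] * pow_fast(b, p[21])) * Ac - p[4] * a -
            p[7] * pow_fast(pp, p[17]) * a;
    RP[i] = p[8] * Pc - p[9] * pp - p[11] * pow_fast(a, p[18]) * pp;
    RB[i] = p[12] * Bc - p[13] * b - p[15] * pow_fast(a, p[19]) * b -
            p[16] * pow_fast(pp, p[20]) * b;
  }
  long nclamp = nclamp0;
  const double cA = p[0] * dt / ds2, cP = p[1] * dt / ds2, cB = p[2] * dt / ds2;
  // in-place update using saved neighbours
  double Aprev, Pprev, Bprev;   // value of node i-1 BEFORE update
  double Afirst = A[0], Pfirst = P[0], Bfirst = B[0];
  double Alast = A[n - 1], Plast = P[n - 1], Blast = B[n - 1];
  Aprev = (bc == 1) ? Alast : Afirst;  // ghost left
  Pprev = (bc == 1) ? Plast : Pfirst;
  Bprev = (bc == 1) ? Blast : Bfirst;
  for (int i = 0; i < n; ++i) {
    const double Ai = A[i], Pi = P[i], Bi = B[i];
    double Anx, Pnx, Bnx;  // right neighbour (pre-update value)
    if (i < n - 1) { Anx = A[i + 1]; Pnx = P[i + 1]; Bnx = B[i + 1]; }
    else if (bc == 1) { Anx = Afirst; Pnx = Pfirst; Bnx = Bfirst; }
    else { Anx = Alast; Pnx = Plast; Bnx = Blast; }
    double av = Ai + cA * (Anx - 2.0 * Ai + Aprev) + dt * RA[i];
    double pv = Pi + cP * (Pnx - 2.0 * Pi + Pprev) + dt * RP[i];
    double bv = Bi + cB * (Bnx - 2.0 * Bi + Bprev) + dt * RB[i];
    if (av < 0.0) { av = 0.0; ++nclamp; }
    if (pv < 0.0) { pv = 0.0; ++nclamp; }
    if (bv < 0.0) { bv = 0.0; ++nclamp; }
    A[i] = av; P[i] = pv; B[i] = bv;
    Aprev = Ai; Pprev = Pi; Bprev = Bi;
  }
  return nclamp;
}

// [[Rcpp::export]]
List cpp_rd_run(NumericMatrix field, NumericVector pars, double psi, double L,
                double dt, int max_steps, double tol, int check_every, int bc) {
  if (pars.size() != RD_NPAR) stop("bad parameter vector length");
  const int n = field.nrow();
  std::vector<double> A(n), P(n), B(n), RA(n), RP(n), RB(n);
  for (int i = 0; i < n; ++i) { A[i] = field(i, 0); P[i] = field(i, 1); B[i] = field(i, 2); }
  std::vector<double> A0, P0, B0;
  long nclamp = 0;
  bool converged = false;
  int steps = 0;
  while (steps < max_steps) {
    if (tol > 0.0) { A0 = A; P0 = P; B0 = B; }
    int chunk = std::min(check_every, max_steps - steps);
    for (int k = 0; k < chunk; ++k)
      nclamp += rd_step_impl(A, P, B, pars.begin(), psi, L, dt, bc, RA, RP, RB);
    steps += chunk;
    for (int i = 0; i < n; ++i)
      if (!R_finite(A[i]) || !R_finite(P[i]) || !R_finite(B[i]))
        stop("numerical divergence in reaction-diffusion at step %d", steps);
    if (tol > 0.0) {
      double d = 0.0;
      for (int i = 0; i < n; ++i) {
        d = std::max(d, std::fabs(A[i] - A0[i]));
        d = std::max(d, std::fabs(P[i] - P0[i]));
        d = std::max(d, std::fabs(B[i] - B0[i]));
      }
      if (d / (chunk * dt) < tol) { converged = true; break; }
    }
    Rcpp::checkUserInterrupt();
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i, 0) = A[i]; out(i, 1) = P[i]; out(i, 2) = B[i]; }
  colnames(out) = CharacterVector::create("A", "P", "B");
  return List::create(_["field"] = out, _["converged"] = converged,
                      _["steps"] = steps, _["clamped"] = (double)nclamp);
}

// ---------------------------------------------------------------------------
// Vertex-model geometry
// ---------------------------------------------------------------------------

struct V3 { double x, y, z; };
static inline V3 vsub(const V3& a, const V3& b) { return V3{a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline V3 vcross(const V3& a, const V3& b) {
  return V3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double vdot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline double vnorm(const V3& a) { return std::sqrt(vdot(a, a)); }

struct Mesh {
  const double* V;      // nv x 3, column-major (R matrix)
  int nv;
  const int* ap;        // ncell x nvpc, 1-based vertex ids, column-major
  const int* ba;
  int ncell, nvpc;
  const int* fV;        // nf x 4
  const int* fO;        // nf x 2 (owner2 = 0 for boundary faces)
  int nf;
  inline V3 vert(int id1) const {  // 1-based id
    int i = id1 - 1;
    return V3{V[i], V[i + nv], V[i + 2 * nv]};
  }
  inline int apv(int c, int k) const { return ap[c + k * ncell]; }
  inline int bav(int c, int k) const { return ba[c + k * ncell]; }
};

// area of a planar-or-not polygon by fan about its centroid
static double poly_area(const std::vector<V3>& pts) {
  int m = (int)pts.size();
  V3 c{0, 0, 0};
  for (int k = 0; k < m; ++k) { c.x += pts[k].x; c.y += pts[k].y; c.z += pts[k].z; }
  c.x /= m; c.y /= m; c.z /= m;
  double area = 0.0;
  for (int k = 0; k < m; ++k) {
    V3 u = vsub(pts[k], c), w = vsub(pts[(k + 1) % m], c);
    area += 0.5 * vnorm(vcross(u, w));
  }
  return area;
}

// signed volume contribution of a fan-triangulated polygon, tetrahedra to o
static double poly_vol(const std::vector<V3>& pts, const V3& o) {
  int m = (int)pts.size();
  V3 c{0, 0, 0};
  for (int k = 0; k < m; ++k) { c.x += pts[k].x; c.y += pts[k].y; c.z += pts[k].z; }
  c.x /= m; c.y /= m; c.z /= m;
  double vol = 0.0;
  for (int k = 0; k < m; ++k) {
    V3 u = vsub(c, o), v1 = vsub(pts[k], o), v2 = vsub(pts[(k + 1) % m], o);
    vol += vdot(u, vcross(v1, v2)) / 6.0;
  }
  return vol;
}

struct CellGeom {
  double a, b, ell, L, Aa, Ab, Al, vol, psi, Pa;
};

static CellGeom cell_geom(const Mesh& M, int c) {
  const int m = M.nvpc;
  std::vector<V3> apts(m), bpts(m);
  V3 ac{0, 0, 0}, bc{0, 0, 0};
  for (int k = 0; k < m; ++k) {
    apts[k] = M.vert(M.apv(c, k));
    bpts[k] = M.vert(M.bav(c, k));
    ac.x += apts[k].x; ac.y += apts[k].y; ac.z += apts[k].z;
    bc.x += bpts[k].x; bc.y += bpts[k].y; bc.z += bpts[k].z;
  }
  ac.x /= m; ac.y /= m; ac.z /= m;
  bc.x /= m; bc.y /= m; bc.z /= m;
  CellGeom g;
  double asum = 0, bsum = 0, esum = 0, Pa = 0;
  for (int k = 0; k < m; ++k) {
    asum += vnorm(vsub(apts[k], ac));
    bsum += vnorm(vsub(bpts[k], bc));
    esum += vnorm(vsub(apts[k], bpts[k]));
    Pa += vnorm(vsub(apts[(k + 1) % m], apts[k]));
  }
  g.a = asum / m; g.b = bsum / m; g.ell = esum / m;
  g.L = g.a + g.b + g.ell;
  g.Pa = Pa;
  g.Aa = poly_area(apts);
  g.Ab = poly_area(bpts);
  // lateral faces of this cell: quad (a_k, a_{k+1}, b_{k+1}, b_k)
  double Al = 0.0;
  V3 cc{(ac.x + bc.x) / 2, (ac.y + bc.y) / 2, (ac.z + bc.z) / 2};
  double vol = poly_vol(apts, cc);                 // apical loop, CCW from above
  std::vector<V3> rpts(bpts.rbegin(), bpts.rend());
  vol += poly_vol(rpts, cc);                       // basal loop reversed
  for (int k = 0; k < m; ++k) {
    std::vector<V3> q{apts[k], bpts[k], bpts[(k + 1) % m], apts[(k + 1) % m]};
    Al += poly_area(q);
    vol += poly_vol(q, cc);
  }
  g.Al = Al;
  g.vol = std::fabs(vol);
  if (g.vol <= 1e-12 || g.Aa <= 1e-12 || g.Ab <= 1e-12)
    stop("degenerate cell geometry (cell %d: V=%g, Aa=%g, Ab=%g)",
         c + 1, g.vol, g.Aa, g.Ab);
  g.psi = (g.Aa + g.Ab + g.Al) / g.vol;
  return g;
}

static Mesh make_mesh(const NumericMatrix& V, const IntegerMatrix& ap,
                      const IntegerMatrix& ba, const IntegerMatrix& fV,
                      const IntegerMatrix& fO) {
  Mesh M;
  M.V = V.begin(); M.nv = V.nrow();
  M.ap = ap.begin(); M.ba = ba.begin();
  M.ncell = ap.nrow(); M.nvpc = ap.ncol();
  M.fV = fV.begin(); M.fO = fO.begin(); M.nf = fV.nrow();
  return M;
}

// [[Rcpp::export]]
NumericMatrix cpp_cell_geometry(NumericMatrix V, IntegerMatrix ap, IntegerMatrix ba,
                                IntegerMatrix fV, IntegerMatrix fO) {
  Mesh M = make_mesh(V, ap, ba, fV, fO);
  NumericMatrix out(M.ncell, 10);
  colnames(out) = CharacterVector::create("a", "b", "ell", "L", "A_a", "A_b",
                                          "A_ell", "V", "psi", "P_hat_a");
  for (int c = 0; c < M.ncell; ++c) {
    CellGeom g = cell_geom(M, c);
    out(c, 0) = g.a; out(c, 1) = g.b; out(c, 2) = g.ell; out(c, 3) = g.L;
    out(c, 4) = g.Aa; out(c, 5) = g.Ab; out(c, 6) = g.Al; out(c, 7) = g.vol;
    out(c, 8) = g.psi; out(c, 9) = g.Pa;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Tissue potential and forces
// ---------------------------------------------------------------------------

struct MechPars {
  NumericVector Ka0, Po0, lb0, ll0, KV, Vo;  // per cell
  const double* q;                           // ncell x 4 (column-major)
  int ncell;
  inline double Ka(int c) const { return Ka0[c] * q[c]; }
  inline double Po(int c) const { return Po0[c] * q[c + ncell]; }
  inline double lb(int c) const { return lb0[c] * q[c + 2 * ncell]; }
  inline double ll(int c) const { return ll0[c] * q[c + 3 * ncell]; }
};

static MechPars make_mech(const List& mech, const NumericMatrix& q) {
  MechPars mp;
  mp.Ka0 = mech["K_a"]; mp.Po0 = mech["P_hat_o"]; mp.lb0 = mech["lambda_b"];
  mp.ll0 = mech["lambda_ell"]; mp.KV = mech["K_V"]; mp.Vo = mech["V_o"];
  mp.q = q.begin(); mp.ncell = q.nrow();
  return mp;
}

// energy of one cell (apical elastic + basal tension + volume elastic);
// lateral face tension is accounted per face, not per cell.
static inline double cell_energy(const Mesh& M, const MechPars& mp, int c) {
  CellGeom g = cell_geom(M, c);
  double dP = g.Pa - mp.Po(c);
  double dV = g.vol - mp.Vo[c];
  return mp.Ka(c) * dP * dP + mp.lb(c) * g.Ab + mp.KV[c] * dV * dV;
}

static inline double face_energy(const Mesh& M, const MechPars& mp, int f) {
  std::vector<V3> q(4);
  for (int k = 0; k < 4; ++k) q[k] = M.vert(M.fV[f + k * M.nf]);
  int o1 = M.fO[f] - 1, o2 = M.fO[f + M.nf] - 1;
  double lam = mp.ll(o1);
  if (o2 >= 0) lam += mp.ll(o2);
  return lam * poly_area(q);
}

static double tissue_energy_impl(const Mesh& M, const MechPars& mp) {
  double U = 0.0;
  for (int c = 0; c < M.ncell; ++c) U += cell_energy(M, mp, c);
  for (int f = 0; f < M.nf; ++f) U += face_energy(M, mp, f);
  return U;
}

// [[Rcpp::export]]
double cpp_tissue_energy(NumericMatrix V, IntegerMatrix ap, IntegerMatrix ba,
                         IntegerMatrix fV, IntegerMatrix fO, List mech,
                         NumericMatrix q) {
  Mesh M = make_mesh(V, ap, ba, fV, fO);
  MechPars mp = make_mech(mech, q);
  return tissue_energy_impl(M, mp);
}

// vertex -> incident cells and faces
struct Incidence {
  std::vector<std::vector<int> > cells, faces;
};

static Incidence build_incidence(const Mesh& M) {
  Incidence inc;
  inc.cells.resize(M.nv);
  inc.faces.resize(M.nv);
  for (int c = 0; c < M.ncell; ++c)
    for (int k = 0; k < M.nvpc; ++k) {
      int va = M.apv(c, k) - 1, vb = M.bav(c, k) - 1;
      if (inc.cells[va].empty() || inc.cells[va].back() != c) inc.cells[va].push_back(c);
      if (inc.cells[vb].empty() || inc.cells[vb].back() != c) inc.cells[vb].push_back(c);
    }
  for (int f = 0; f < M.nf; ++f)
    for (int k = 0; k < 4; ++k) inc.faces[M.fV[f + k * M.nf] - 1].push_back(f);
  return inc;
}

// local energy seen by vertex v (everything that depends on its position)
static double local_energy(const Mesh& M, const MechPars& mp, const Incidence& inc, int v) {
  double U = 0.0;
  for (size_t i = 0; i < inc.cells[v].size(); ++i) U += cell_energy(M, mp, inc.cells[v][i]);
  for (size_t i = 0; i < inc.faces[v].size(); ++i) U += face_energy(M, mp, inc.faces[v][i]);
  return U;
}

// central-difference force on vertex v (all 3 components); Vwork is the
// mutable coordinate store backing M.
static void vertex_force(const Mesh& M, const MechPars& mp, const Incidence& inc,
                         double* Vwork, int v, double fd, double* F) {
  for (int d = 0; d < 3; ++d) {
    double* x = &Vwork[v + d * M.nv];
    const double x0 = *x;
    *x = x0 + fd;
    double Up = local_energy(M, mp, inc, v);
    *x = x0 - fd;
    double Um = local_energy(M, mp, inc, v);
    *x = x0;
    F[d] = -(Up - Um) / (2.0 * fd);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_vertex_forces(NumericMatrix V, IntegerMatrix ap, IntegerMatrix ba,
                                IntegerMatrix fV, IntegerMatrix fO, List mech,
                                NumericMatrix q, double fd) {
  NumericMatrix Vw = clone(V);
  Mesh M = make_mesh(Vw, ap, ba, fV, fO);
  MechPars mp = make_mech(mech, q);
  Incidence inc = build_incidence(M);
  NumericMatrix F(M.nv, 3);
  double f[3];
  for (int v = 0; v < M.nv; ++v) {
    vertex_force(M, mp, inc, Vw.begin(), v, fd, f);
    F(v, 0) = f[0]; F(v, 1) = f[1]; F(v, 2) = f[2];
  }
  return F;
}

static void apply_zpin(std::vector<char>& pin, const IntegerVector& zpin, int nv) {
  pin.assign(nv, 0);
  for (int i = 0; i < zpin.size(); ++i) {
    int id = zpin[i] - 1;
    if (id >= 0 && id < nv) pin[id] = 1;
  }
}

// [[Rcpp::export]]
List cpp_relax(NumericMatrix V, IntegerMatrix ap, IntegerMatrix ba,
               IntegerMatrix fV, IntegerMatrix fO, List mech, NumericMatrix q,
               double dt, double eta, double fd, double tol, int max_steps,
               IntegerVector zpin) {
  NumericMatrix Vw = clone(V);
  Mesh M = make_mesh(Vw, ap, ba, fV, fO);
  MechPars mp = make_mech(mech, q);
  Incidence inc = build_incidence(M);
  std::vector<char> pin;
  apply_zpin(pin, zpin, M.nv);
  double f[3], maxF = R_PosInf;
  int steps = 0;
  bool converged = false;
  std::vector<double> Fbuf(3 * M.nv);
  while (steps < max_steps) {
    maxF = 0.0;
    for (int v = 0; v < M.nv; ++v) {
      vertex_force(M, mp, inc, Vw.begin(), v, fd, f);
      if (pin[v]) f[2] = 0.0;
      Fbuf[3 * v] = f[0]; Fbuf[3 * v + 1] = f[1]; Fbuf[3 * v + 2] = f[2];
      maxF = std::max(maxF, std::max(std::fabs(f[0]),
                      std::max(std::fabs(f[1]), std::fabs(f[2]))));
    }
    if (maxF < tol) { converged = true; break; }
    for (int v = 0; v < M.nv; ++v) {
      Vw(v, 0) += dt / eta * Fbuf[3 * v];
      Vw(v, 1) += dt / eta * Fbuf[3 * v + 1];
      Vw(v, 2) += dt / eta * Fbuf[3 * v + 2];
      if (!R_finite(Vw(v, 0)) || !R_finite(Vw(v, 1)) || !R_finite(Vw(v, 2)))
        stop("numerical divergence in mechanics at step %d", steps);
    }
    ++steps;
    if (steps % 1000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["vertices"] = Vw, _["converged"] = converged,
                      _["steps"] = steps, _["max_force"] = maxF,
                      _["energy"] = tissue_energy_impl(M, mp));
}

// signed fold depth of a surface: amplitude z_max - z_min, positive when the
// extremal deviation from the rim is an indentation (towards basal, -z).
static double fold_depth_impl(const NumericMatrix& V, const IntegerVector& ids,
                              const IntegerVector& rim_ids) {
  double zmin = R_PosInf, zmax = R_NegInf;
  for (int i = 0; i < ids.size(); ++i) {
    double z = V(ids[i] - 1, 2);
    zmin = std::min(zmin, z); zmax = std::max(zmax, z);
  }
  std::vector<double> rz(rim_ids.size());
  for (int i = 0; i < rim_ids.size(); ++i) rz[i] = V(rim_ids[i] - 1, 2);
  std::sort(rz.begin(), rz.end());
  double zrim = rz.empty() ? 0.5 * (zmin + zmax)
                           : (rz.size() % 2 ? rz[rz.size() / 2]
                              : 0.5 * (rz[rz.size() / 2 - 1] + rz[rz.size() / 2]));
  double amp = zmax - zmin;
  return (zrim - zmin >= zmax - zrim) ? amp : -amp;
}

// [[Rcpp::export]]
double cpp_fold_depth(NumericMatrix V, IntegerVector ids, IntegerVector rim_ids) {
  return fold_depth_impl(V, ids, rim_ids);
}

// ---------------------------------------------------------------------------
// Coupled mechano-polarity driver
// ---------------------------------------------------------------------------

// apical domain size of cell c given its geometry and its B profile: the
// membrane distance from the apical centre (s = 0) to the B maximum, on
// the cell-centred grid s_i = (i - 1/2) L / n.
static double ell_domain_of(const CellGeom& g, const double* B, int n) {
  int imax = 0;
  double bmax = B[0];
  for (int i = 1; i < n; ++i) if (B[i] > bmax) { bmax = B[i]; imax = i; }
  return (imax + 0.5) * g.L / n;
}

// [[Rcpp::export]]
List cpp_coupled_run(NumericMatrix V, IntegerMatrix ap, IntegerMatrix ba,
                     IntegerMatrix fV, IntegerMatrix fO, List mech,
                     NumericMatrix q0, NumericMatrix fields,
                     NumericMatrix rdpars, int bc, double dt, int n_iter,
                     double eta, int couple_every, NumericVector c_o,
                     double sigma, NumericVector ell_o, double q_floor,
                     double probe_dq, double probe_dt, int sens_every,
                     int probe_mode, double dq_max, double fd,
                     IntegerVector zpin, int record_every,
                     IntegerVector apical_ids, IntegerVector apical_rim_ids,
                     bool feedback) {
  NumericMatrix Vw = clone(V);
  NumericMatrix q = clone(q0);
  Mesh M = make_mesh(Vw, ap, ba, fV, fO);
  MechPars mp = make_mech(mech, q);
  Incidence inc = build_incidence(M);
  std::vector<char> pin;
  apply_zpin(pin, zpin, M.nv);
  const int ncell = M.ncell, n = fields.nrow();
  if (fields.ncol() != 3 * ncell) stop("fields must have 3 columns per cell");
  if (rdpars.nrow() != RD_NPAR || rdpars.ncol() != ncell) stop("bad rdpars");

  // working copies of the fields
  std::vector<std::vector<double> > A(ncell), P(ncell), B(ncell);
  for (int c = 0; c < ncell; ++c) {
    A[c].resize(n); P[c].resize(n); B[c].resize(n);
    for (int i = 0; i < n; ++i) {
      A[c][i] = fields(i, 3 * c); P[c][i] = fields(i, 3 * c + 1);
      B[c][i] = fields(i, 3 * c + 2);
    }
  }
  std::vector<double> RA(n), RP(n), RB(n), Lprev(ncell);
  std::vector<CellGeom> geom(ncell);
  for (int c = 0; c < ncell; ++c) { geom[c] = cell_geom(M, c); Lprev[c] = geom[c].L; }

  const int nrec = n_iter / record_every + 1;
  NumericVector times(nrec), foldD(nrec);
  NumericMatrix psi_t(nrec, ncell), L_t(nrec, ncell), ell_t(nrec, ncell);
  NumericMatrix q_t(nrec, 4 * ncell);
  int irec = 0;
  std::vector<double> Fbuf(3 * M.nv);
  double f[3];
  long nclamp = 0;
  NumericMatrix sens_cache(ncell, 4);
  long interval_count = 0;
  if (sens_every < 1) sens_every = 1;

  RNGScope rngs;  // use R's RNG for the coupling noise

  for (int it = 0; it <= n_iter; ++it) {
    // --- record ---
    if (it % record_every == 0 && irec < nrec) {
      times[irec] = it * dt;
      for (int c = 0; c < ncell; ++c) {
        psi_t(irec, c) = geom[c].psi;
        L_t(irec, c) = geom[c].L;
        ell_t(irec, c) = ell_domain_of(geom[c], B[c].data(), n);
        for (int k = 0; k < 4; ++k) q_t(irec, c + k * ncell) = q(c, k);
      }
      foldD[irec] = fold_depth_impl(Vw, apical_ids, apical_rim_ids);
      ++irec;
    }
    if (it == n_iter) break;

    // --- (1) mechanics step ---
    for (int v = 0; v < M.nv; ++v) {
      vertex_force(M, mp, inc, Vw.begin(), v, fd, f);
      if (pin[v]) f[2] = 0.0;
      Fbuf[3 * v] = f[0]; Fbuf[3 * v + 1] = f[1]; Fbuf[3 * v + 2] = f[2];
    }
    for (int v = 0; v < M.nv; ++v) {
      Vw(v, 0) += dt / eta * Fbuf[3 * v];
      Vw(v, 1) += dt / eta * Fbuf[3 * v + 1];
      Vw(v, 2) += dt / eta * Fbuf[3 * v + 2];
    }

    // --- (2) geometry, (3) length rescale, (4) RD step ---
    for (int c = 0; c < ncell; ++c) {
      geom[c] = cell_geom(M, c);
      const double ratio = Lprev[c] / geom[c].L;
      if (ratio != 1.0)
        for (int i = 0; i < n; ++i) { A[c][i] *= ratio; P[c][i] *= ratio; B[c][i] *= ratio; }
      Lprev[c] = geom[c].L;
      nclamp += rd_step_impl(A[c], P[c], B[c], &rdpars(0, c), geom[c].psi,
                             geom[c].L, dt, bc, RA, RP, RB);
    }

    // --- (5) homeostatic modulation of mechanics ---
    if (feedback && ((it + 1) % couple_every == 0)) {
      if (probe_mode == 0) {
        // quasi-static sensitivity: implicit differentiation of the reduced
        // (height, radius) force balance of each cell. This is the fully
        // relaxed response d ell_domain / d q_k; finite-horizon probes can
        // report the opposite sign for channels whose transient response
        // (fast surface modes) opposes the final one (slow height mode).
        for (int c = 0; c < ncell; ++c) {
          const CellGeom& g = geom[c];
          const double r = 0.5 * (g.a + g.b), h = g.ell;
          int imax = 0;
          { const double* Bc = B[c].data();
            double bmax = Bc[0];
            for (int i = 1; i < n; ++i) if (Bc[i] > bmax) { bmax = Bc[i]; imax = i; } }
          const double fpos = (imax + 0.5) / (double)n;
          const double KV = mp.KV[c], Vo = mp.Vo[c];
          const double s3 = std::sqrt(3.0);
          const double Vol = 1.5 * s3 * r * r * h;
          const double dV = 2.0 * KV * (Vol - Vo);  // = -P_V
          const double Ka_eff = mp.Ka(c), Po_eff = mp.Po(c);
          const double lb_eff = mp.lb(c), ll_eff = mp.ll(c);
          const double M11 = KV * 13.5 * r * r * r * r;
          const double M22 = 54.0 * KV * r * r * h * h + dV * 3.0 * s3 * h +
                             72.0 * Ka_eff + 3.0 * s3 * lb_eff;
          const double M12 = 27.0 * KV * r * r * r * h + dV * 3.0 * s3 * r +
                             6.0 * ll_eff;
          const double det = M11 * M22 - M12 * M12;
          for (int k = 0; k < 4; ++k) {
            if (det <= 1e-10) { sens_cache(c, k) = 0.0; continue; }
            double gh = 0.0, gr = 0.0;
            switch (k) {
              case 0: gr = 12.0 * mp.Ka0[c] * (6.0 * r - Po_eff); break;
              case 1: gr = -12.0 * Ka_eff * mp.Po0[c]; break;
              case 2: gr = 3.0 * s3 * r * mp.lb0[c]; break;
              case 3: gh = 6.0 * mp.ll0[c] * r; gr = 6.0 * mp.ll0[c] * h; break;
            }
            const double dh = -(M22 * gh - M12 * gr) / det;
            const double dr = -(-M12 * gh + M11 * gr) / det;
            sens_cache(c, k) = fpos * (dh + 2.0 * dr);
          }
        }
      } else if (interval_count % sens_every == 0) {
        const int Ksteps = std::max(1, (int)std::lround(probe_dt / dt));
        std::vector<int> vids(2 * M.nvpc);
        for (int c = 0; c < ncell; ++c) {
          for (int kk = 0; kk < M.nvpc; ++kk) {
            vids[2 * kk] = M.apv(c, kk) - 1;
            vids[2 * kk + 1] = M.bav(c, kk) - 1;
          }
          std::vector<double> saved(3 * vids.size());
          for (size_t j = 0; j < vids.size(); ++j)
            for (int d = 0; d < 3; ++d) saved[3 * j + d] = Vw(vids[j], d);
          for (int k = 0; k < 4; ++k) {
            double ellpm[2];
            for (int sgn = 0; sgn < 2; ++sgn) {
              const double qsave = q(c, k);
              q(c, k) = qsave + (sgn == 0 ? probe_dq : -probe_dq);
              double fprobe[3];
              for (int step = 0; step < Ksteps; ++step) {
                for (size_t j = 0; j < vids.size(); ++j) {
                  int v = vids[j];
                  vertex_force(M, mp, inc, Vw.begin(), v, fd, fprobe);
                  if (pin[v]) fprobe[2] = 0.0;
                  Vw(v, 0) += dt / eta * fprobe[0];
                  Vw(v, 1) += dt / eta * fprobe[1];
                  Vw(v, 2) += dt / eta * fprobe[2];
                }
              }
              q(c, k) = qsave;
              CellGeom gp = cell_geom(M, c);
              ellpm[sgn] = ell_domain_of(gp, B[c].data(), n);
              for (size_t j = 0; j < vids.size(); ++j)
                for (int d = 0; d < 3; ++d) Vw(vids[j], d) = saved[3 * j + d];
            }
            sens_cache(c, k) = (ellpm[0] - ellpm[1]) / (2.0 * probe_dq);
          }
        }
      }
      ++interval_count;
      for (int c = 0; c < ncell; ++c) {
        const double ell_now = ell_domain_of(geom[c], B[c].data(), n);
        const double dev = ell_now - ell_o[c];
        // coupling rates, resampled once per interval per cell
        double cc[4];
        for (int k = 0; k < 4; ++k) {
          double xi = (sigma > 0.0) ? R::rnorm(0.0, sigma) : 0.0;
          cc[k] = c_o[k] * (1.0 + xi);
        }
        if (dev == 0.0) continue;
        for (int k = 0; k < 4; ++k) {
          double dq = -(couple_every * dt) * cc[k] * 2.0 * dev * sens_cache(c, k);
          // rate limiter: keep the modulation slow enough that the vertex
          // mechanics stays quasi-statically relaxed
          if (dq_max > 0.0) {
            if (dq > dq_max) dq = dq_max;
            if (dq < -dq_max) dq = -dq_max;
          }
          double qn = q(c, k) + dq;
          if (qn < q_floor) qn = q_floor;
          q(c, k) = qn;
        }
      }
    }

    if ((it + 1) % 200 == 0) {
      for (int v = 0; v < M.nv; ++v)
        if (!R_finite(Vw(v, 0)) || !R_finite(Vw(v, 1)) || !R_finite(Vw(v, 2)))
          stop("numerical divergence in coupled run at iteration %d", it + 1);
      Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix fout(n, 3 * ncell);
  for (int c = 0; c < ncell; ++c)
    for (int i = 0; i < n; ++i) {
      fout(i, 3 * c) = A[c][i]; fout(i, 3 * c + 1) = P[c][i];
      fout(i, 3 * c + 2) = B[c][i];
    }
  return List::create(_["times"] = times, _["psi"] = psi_t, _["L"] = L_t,
                      _["ell_domain"] = ell_t, _["q"] = q_t,
                      _["fold_depth"] = foldD, _["vertices"] = Vw,
                      _["fields"] = fout, _["q_final"] = q,
                      _["clamped"] = (double)nclamp);
}
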