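// Fused production stepper for the coupled D3Q19 LBGK / Oldroyd-B /
// immersed-boundary loop, plus the analytic membrane force gradient.
//
// Phase order per step (mirrored by the R reference_step()):
//   1 stress recovery  2 moments  3 total force (driving + stress
//   divergence + spread membrane forces)  4 half-force velocity
//   5 velocity gradient + constitutive source  6 collide+stream of both
//   lattices with non-equilibrium-extrapolation walls fused in
//   7 interpolate velocity at membrane nodes, forward-Euler advection.
// All arithmetic is deterministic; the full state (f, G, chi_prev, X)
// round-trips through R, so checkpoint/resume is bit-identical.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int CX[19] = {0, 1,-1, 0, 0, 0, 0, 1,-1, 1,-1, 1,-1, 1,-1, 0, 0, 0, 0};
static const int CY[19] = {0, 0, 0, 1,-1, 0, 0, 1,-1,-1, 1, 0, 0, 0, 0, 1,-1, 1,-1};
static const int CZ[19] = {0, 0, 0, 0, 0, 1,-1, 0, 0, 0, 0, 1,-1,-1, 1, 1,-1,-1, 1};
static const double W19[19] = {
  1.0/3,
  1.0/18, 1.0/18, 1.0/18, 1.0/18, 1.0/18, 1.0/18,
  1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36,
  1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36};
// packed symmetric component (i, j) pairs: xx yy zz xy xz yz
static const int SI[6] = {0, 1, 2, 0, 0, 1};
static const int SJ[6] = {0, 1, 2, 1, 2, 2};
static const int SMAP[3][3] = {{0, 3, 4}, {3, 1, 5}, {4, 5, 2}};

enum { FLUID = 0, WALL = 1, INACT = 2 };

static inline void cross3(const double* a, const double* b, double* o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// ---------------------------------------------------------------------------
// Membrane mechanics: total energy gradient -> nodal forces.
// Strain term uses the metric form of the invariants (I1 from the
// reference inverse metric M, I2 from squared face area), bending uses
// the atan2 quotient rule for the signed dihedral, and area/volume are
// global quadratic penalties.
// ---------------------------------------------------------------------------
static void membrane_forces_core(
    const std::vector<double>& x, int nV,
    const IntegerMatrix& faces, const IntegerMatrix& edges,
    const NumericMatrix& refM, const NumericVector& A0f,
    const NumericVector& phi0, double A0, double V0,
    const double* mod, std::vector<double>& force) {
  const int nF = faces.nrow(), nE = edges.nrow();
  const double ks = mod[0], kalpha = mod[1], kb = mod[2], ka = mod[3],
               kv = mod[4];
  std::fill(force.begin(), force.end(), 0.0);

  // pass 1: total area and volume
  double A = 0.0, V = 0.0;
  for (int fi = 0; fi < nF; ++fi) {
    const double* p0 = &x[3 * faces(fi, 0)];
    const double* p1 = &x[3 * faces(fi, 1)];
    const double* p2 = &x[3 * faces(fi, 2)];
    double e1[3] = {p1[0]-p0[0], p1[1]-p0[1], p1[2]-p0[2]};
    double e2[3] = {p2[0]-p0[0], p2[1]-p0[1], p2[2]-p0[2]};
    double n[3];
    cross3(e1, e2, n);
    A += 0.5 * std::sqrt(dot3(n, n));
    V += dot3(p0, n) / 6.0;
  }
  const double dEdA = ka * (A - A0) / A0;
  const double dEdV = kv * (V - V0) / V0;

  // pass 2: per-face strain + area/volume gradients
  for (int fi = 0; fi < nF; ++fi) {
    int i0 = faces(fi, 0), i1 = faces(fi, 1), i2 = faces(fi, 2);
    const double* p0 = &x[3 * i0];
    const double* p1 = &x[3 * i1];
    const double* p2 = &x[3 * i2];
    double e1[3] = {p1[0]-p0[0], p1[1]-p0[1], p1[2]-p0[2]};
    double e2[3] = {p2[0]-p0[0], p2[1]-p0[1], p2[2]-p0[2]};
    double n[3];
    cross3(e1, e2, n);
    double n2 = dot3(n, n);
    if (n2 <= 0.0) stop("degenerate deformed face %d", fi + 1);
    double m11 = refM(fi, 0), m12 = refM(fi, 1), m22 = refM(fi, 2);
    double detM = m11 * m22 - m12 * m12;
    double d11 = dot3(e1, e1), d12 = dot3(e1, e2), d22 = dot3(e2, e2);
    double I1 = m11 * d11 + 2.0 * m12 * d12 + m22 * d22 - 2.0;
    double I2 = n2 * detM - 1.0;
    double a0 = A0f[fi];
    double dE_dI1 = a0 * ks / 12.0 * (2.0 * I1 + 2.0);
    double dE_dI2 = a0 * (-ks / 6.0 + kalpha * I2 / 6.0);
    // dI1/de1 = 2(m11 e1 + m12 e2); dI1/de2 = 2(m22 e2 + m12 e1)
    // dI2/de1 = 2 detM (e2 x n);    dI2/de2 = 2 detM (n x e1)
    double c1[3], c2[3];
    cross3(e2, n, c1);
    cross3(n, e1, c2);
    double invn = 1.0 / std::sqrt(n2);
    for (int k = 0; k < 3; ++k) {
      double g1 = dE_dI1 * 2.0 * (m11 * e1[k] + m12 * e2[k]) +
                  dE_dI2 * 2.0 * detM * c1[k];
      double g2 = dE_dI1 * 2.0 * (m22 * e2[k] + m12 * e1[k]) +
                  dE_dI2 * 2.0 * detM * c2[k];
      // area gradient: dA/de1 = (e2 x n)/(2|n|), dA/de2 = (n x e1)/(2|n|)
      g1 += dEdA * 0.5 * invn * c1[k];
      g2 += dEdA * 0.5 * invn * c2[k];
      force[3 * i1 + k] -= g1;
      force[3 * i2 + k] -= g2;
      force[3 * i0 + k] += g1 + g2;
    }
    // volume gradient: dV/dp0 = (p1 x p2)/6 etc. (cyclic)
    double v01[3], v12[3], v20[3];
    cross3(p1, p2, v01);
    cross3(p2, p0, v12);
    cross3(p0, p1, v20);
    for (int k = 0; k < 3; ++k) {
      force[3 * i0 + k] -= dEdV * v01[k] / 6.0;
      force[3 * i1 + k] -= dEdV * v12[k] / 6.0;
      force[3 * i2 + k] -= dEdV * v20[k] / 6.0;
    }
  }

  // pass 3: bending over edges; edge (a0, a1) with opposite vertices
  // oa (face A = a0,a1,oa) and ob (face B = a1,a0,ob)
  for (int ei = 0; ei < nE; ++ei) {
    int v0 = edges(ei, 0), v1 = edges(ei, 1), va = edges(ei, 2),
        vb = edges(ei, 3);
    const double* x0 = &x[3 * v0];
    const double* x1 = &x[3 * v1];
    const double* xa = &x[3 * va];
    const double* xb = &x[3 * vb];
    double e[3] = {x1[0]-x0[0], x1[1]-x0[1], x1[2]-x0[2]};
    double l = std::sqrt(dot3(e, e));
    double ea[3] = {xa[0]-x0[0], xa[1]-x0[1], xa[2]-x0[2]};
    double eb[3] = {xb[0]-x1[0], xb[1]-x1[1], xb[2]-x1[2]};
    double me[3] = {-e[0], -e[1], -e[2]};
    double nA[3], nB[3];
    cross3(e, ea, nA);         // (x1-x0) x (xa-x0)
    cross3(me, eb, nB);        // (x0-x1) x (xb-x1)
    double cbar = dot3(nA, nB);
    double m[3];
    cross3(nA, nB, m);
    double sbar = dot3(m, e) / l;
    double phi = std::atan2(sbar, cbar);
    double denom = cbar * cbar + sbar * sbar;
    double coef = kb * (phi - phi0[ei]);
    if (denom <= 0.0) continue;
    // weight vectors w: dn = delta x w for a perturbation delta at a vertex
    // face A = (v0, v1, va):  w(v0)=x1-xa, w(v1)=xa-x0, w(va)=x0-x1
    // face B = (v1, v0, vb):  w(v1)=x0-xb, w(v0)=xb-x1, w(vb)=x1-x0
    double wA[3][3] = {{x1[0]-xa[0], x1[1]-xa[1], x1[2]-xa[2]},
                       {xa[0]-x0[0], xa[1]-x0[1], xa[2]-x0[2]},
                       {x0[0]-x1[0], x0[1]-x1[1], x0[2]-x1[2]}};
    double wB[3][3] = {{x0[0]-xb[0], x0[1]-xb[1], x0[2]-xb[2]},
                       {xb[0]-x1[0], xb[1]-x1[1], xb[2]-x1[2]},
                       {x1[0]-x0[0], x1[1]-x0[1], x1[2]-x0[2]}};
    int vertsA[3] = {v0, v1, va};
    int vertsB[3] = {v1, v0, vb};
    double nBxe[3], exnA[3];
    cross3(nB, e, nBxe);
    cross3(e, nA, exnA);
    double gc[4][3] = {{0}}, gs[4][3] = {{0}};  // order: v0, v1, va, vb
    auto slot = [&](int v) {
      if (v == v0) return 0;
      if (v == v1) return 1;
      if (v == va) return 2;
      return 3;
    };
    for (int t = 0; t < 3; ++t) {
      int sA = slot(vertsA[t]);
      double tmp[3];
      cross3(wA[t], nB, tmp);             // d(cbar) from A vertex
      for (int k = 0; k < 3; ++k) gc[sA][k] += tmp[k];
      cross3(wA[t], nBxe, tmp);           // d(m . e) from A vertex
      for (int k = 0; k < 3; ++k) gs[sA][k] += tmp[k] / l;
      int sB = slot(vertsB[t]);
      double nAtmp[3];
      cross3(wB[t], nA, nAtmp);           // d(cbar) from B vertex (nA . (d x w))
      for (int k = 0; k < 3; ++k) gc[sB][k] += nAtmp[k];
      cross3(wB[t], exnA, tmp);           // d(m . e) from B vertex
      for (int k = 0; k < 3; ++k) gs[sB][k] += tmp[k] / l;
    }
    // edge-direction part of sbar = (m . e)/l: d/dx1 = m/l - (m.e) e / l^3
    double mel3 = dot3(m, e) / (l * l * l);
    for (int k = 0; k < 3; ++k) {
      double term = m[k] / l - mel3 * e[k];
      gs[1][k] += term;
      gs[0][k] -= term;
    }
    int verts[4] = {v0, v1, va, vb};
    for (int t = 0; t < 4; ++t) {
      for (int k = 0; k < 3; ++k) {
        double dphi = (cbar * gs[t][k] - sbar * gc[t][k]) / denom;
        force[3 * verts[t] + k] -= coef * dphi;
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_membrane_forces(NumericMatrix nodes, IntegerMatrix faces,
                                  IntegerMatrix edges, NumericMatrix refM,
                                  NumericVector A0f, NumericVector phi0,
                                  double A0, double V0, NumericVector moduli) {
  int nV = nodes.nrow();
  std::vector<double> x(3 * nV), force(3 * nV);
  for (int p = 0; p < nV; ++p)
    for (int k = 0; k < 3; ++k) x[3 * p + k] = nodes(p, k);
  IntegerMatrix f0(clone(faces)), e0(clone(edges));
  // R passes 1-based indices for the standalone entry point
  for (int i = 0; i < f0.nrow() * 3; ++i) f0[i] -= 1;
  for (int i = 0; i < e0.nrow() * 4; ++i) e0[i] -= 1;
  membrane_forces_core(x, nV, f0, e0, refM, A0f, phi0, A0, V0,
                       REAL(moduli), force);
  NumericMatrix out(nV, 3);
  for (int p = 0; p < nV; ++p)
    for (int k = 0; k < 3; ++k) out(p, k) = force[3 * p + k];
  return out;
}

// ---------------------------------------------------------------------------
// Immersed boundary kernel
// ---------------------------------------------------------------------------
static inline double delta4(double r) {
  double a = std::fabs(r);
  if (a >= 2.0) return 0.0;
  return 0.25 * (1.0 + std::cos(M_PI * r * 0.5));
}

struct Support {
  int idx[64];
  double w[64];
};

static void kernel_support(const double* pos /*1-based*/, const int* dims,
                           Support& s) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ix[4], iy[4], iz[4];
  double wx[4], wy[4], wz[4];
  for (int ax = 0; ax < 3; ++ax) {
    double p = pos[ax];
    int base = (int)std::floor(p);
    int n = dims[ax];
    for (int o = 0; o < 4; ++o) {
      int coord = base + o - 1;              // 1-based lattice coordinate
      int wrapped = ((coord - 1) % n + n) % n;  // 0-based node index
      double wgt = delta4((double)coord - p);
      if (ax == 0) { ix[o] = wrapped; wx[o] = wgt; }
      else if (ax == 1) { iy[o] = wrapped; wy[o] = wgt; }
      else { iz[o] = wrapped; wz[o] = wgt; }
    }
  }
  int t = 0;
  for (int c = 0; c < 4; ++c)
    for (int b = 0; b < 4; ++b)
      for (int a = 0; a < 4; ++a, ++t) {
        s.idx[t] = ix[a] + nx * (iy[b] + ny * iz[c]);
        s.w[t] = wx[a] * wy[b] * wz[c];
      }
}

// ---------------------------------------------------------------------------
// Fused run loop
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run(List state, List setup, int nsteps, int record_every,
             int diag_every) {
  IntegerVector dimsR = setup["dims"];
  int dims[3] = {dimsR[0], dimsR[1], dimsR[2]};
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nn = nx * ny * nz;
  IntegerVector typeR = setup["node_type"];
  IntegerVector wnbR = setup["wall_nbr"];
  NumericMatrix wallU = setup["wall_u"];
  const double lambda_f = setup["lambda_f"];
  const bool visco = setup["visco"];
  const double lambda_g = visco ? (double)setup["lambda_g"] : 1.0;
  const double lambda_p = visco ? (double)setup["lambda_p"] : 0.0;
  const double eta_p = visco ? (double)setup["eta_p"] : 0.0;
  const double accel = setup["accel"];
  const bool particle = setup["has_particle"];
  const int check_every = setup["check_every"];
  const double warn2 = (double)setup["max_u_warn"] * (double)setup["max_u_warn"];
  const double abort2 = (double)setup["max_u_abort"] * (double)setup["max_u_abort"];

  std::vector<int> type(typeR.begin(), typeR.end());
  std::vector<int> wnb(wnbR.begin(), wnbR.end());

  // per-axis periodic neighbours and per-direction stream targets
  std::vector<int> nbp(3 * nn), nbm(3 * nn);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x0 = 0; x0 < nx; ++x0) {
        int n = x0 + nx * (y + ny * z);
        nbp[3 * n + 0] = ((x0 + 1) % nx) + nx * (y + ny * z);
        nbm[3 * n + 0] = ((x0 - 1 + nx) % nx) + nx * (y + ny * z);
        nbp[3 * n + 1] = x0 + nx * (((y + 1) % ny) + ny * z);
        nbm[3 * n + 1] = x0 + nx * (((y - 1 + ny) % ny) + ny * z);
        nbp[3 * n + 2] = x0 + nx * (y + ny * ((z + 1) % nz));
        nbm[3 * n + 2] = x0 + nx * (y + ny * ((z - 1 + nz) % nz));
      }
  std::vector<int> tgt(19 * (size_t)nn);
  for (int n = 0; n < nn; ++n) {
    for (int a = 0; a < 19; ++a) {
      int t = n;
      if (CX[a] == 1) t = nbp[3 * t];
      else if (CX[a] == -1) t = nbm[3 * t];
      if (CY[a] == 1) t = nbp[3 * t + 1];
      else if (CY[a] == -1) t = nbm[3 * t + 1];
      if (CZ[a] == 1) t = nbp[3 * t + 2];
      else if (CZ[a] == -1) t = nbm[3 * t + 2];
      tgt[19 * (size_t)n + a] = t;
    }
  }

  NumericVector fR = state["f"];
  std::vector<double> f(fR.begin(), fR.end()), f2(f.size());
  std::vector<double> G, G2;
  NumericVector chiR = state["chi_prev"];
  std::vector<double> chi_prev(chiR.begin(), chiR.end());
  std::vector<double> chi(6 * (size_t)nn, 0.0);
  if (visco) {
    NumericVector GR = state["G"];
    G.assign(GR.begin(), GR.end());
    G2.resize(G.size());
  }
  NumericMatrix XR = state["X"];
  int np = XR.nrow();
  std::vector<double> X(3 * np);
  for (int p = 0; p < np; ++p)
    for (int k = 0; k < 3; ++k) X[3 * p + k] = XR(p, k);
  int step0 = state["step"];

  IntegerMatrix faces, edges;
  NumericMatrix refM;
  NumericVector A0f, phi0, moduli;
  double A0 = 0.0, V0 = 0.0;
  std::vector<double> memF;
  if (particle) {
    faces = as<IntegerMatrix>(setup["faces"]);   // 0-based
    edges = as<IntegerMatrix>(setup["edges"]);
    refM = as<NumericMatrix>(setup["refM"]);
    A0f = as<NumericVector>(setup["A0f"]);
    phi0 = as<NumericVector>(setup["phi0"]);
    A0 = setup["A0"];
    V0 = setup["V0"];
    moduli = as<NumericVector>(setup["moduli"]);
    memF.resize(3 * np);
  }

  std::vector<double> rho(nn), u(3 * (size_t)nn, 0.0), Ftot(3 * (size_t)nn, 0.0);
  std::vector<double> tau(6 * (size_t)nn, 0.0), gu;
  if (visco) gu.resize(9 * (size_t)nn);

  // trajectory / diagnostics buffers
  int nrec = particle ? (nsteps / std::max(record_every, 1) + 2) : 0;
  NumericMatrix traj(nrec, 7);
  int irec = 0;
  int ndia = nsteps / std::max(diag_every, 1) + 2;
  NumericMatrix diag(ndia, 5);
  int idia = 0;
  double max_u_seen = 0.0;

  auto record_traj = [&](int stepno) {
    if (!particle || irec >= nrec) return;
    double c[3] = {0, 0, 0};
    for (int p = 0; p < np; ++p)
      for (int k = 0; k < 3; ++k) c[k] += X[3 * p + k];
    for (int k = 0; k < 3; ++k) c[k] /= np;
    traj(irec, 0) = stepno;
    for (int k = 0; k < 3; ++k) {
      traj(irec, 1 + k) = c[k];
      traj(irec, 4 + k) = X[k] - c[k];   // marker vector P from node 1
    }
    ++irec;
  };
  auto record_diag = [&](int stepno) {
    if (idia >= ndia) return;
    double mass = 0, mux = 0, mu2 = 0, mtau = 0;
    int nf = 0;
    for (int n = 0; n < nn; ++n) {
      if (type[n] != FLUID) continue;
      ++nf;
      mass += rho[n];
      mux += u[3 * n];
      double u2 = u[3*n]*u[3*n] + u[3*n+1]*u[3*n+1] + u[3*n+2]*u[3*n+2];
      if (u2 > mu2) mu2 = u2;
      for (int m = 0; m < 6; ++m)
        mtau = std::max(mtau, std::fabs(tau[6 * (size_t)n + m]));
    }
    diag(idia, 0) = stepno;
    diag(idia, 1) = mass;
    diag(idia, 2) = nf ? mux / nf : 0.0;
    diag(idia, 3) = std::sqrt(mu2);
    diag(idia, 4) = mtau;
    ++idia;
  };

  // one analysis pass: tau, moments, forces, corrected velocity, source.
  auto analysis_phase = [&](bool with_source) {
    if (visco) {
      for (int n = 0; n < nn; ++n) {
        const double* g = &G[114 * (size_t)n];
        for (int m = 0; m < 6; ++m) {
          double s = 0;
          for (int a = 0; a < 19; ++a) s += g[19 * m + a];
          tau[6 * (size_t)n + m] = s;
        }
      }
    }
    double maxu2 = 0.0;
    for (int n = 0; n < nn; ++n) {
      if (type[n] == INACT) {
        rho[n] = 1.0;
        u[3*n] = u[3*n+1] = u[3*n+2] = 0.0;
        Ftot[3*n] = Ftot[3*n+1] = Ftot[3*n+2] = 0.0;
        continue;
      }
      const double* fn = &f[19 * (size_t)n];
      double r = 0, mx = 0, my = 0, mz = 0;
      for (int a = 0; a < 19; ++a) {
        r += fn[a];
        mx += CX[a] * fn[a];
        my += CY[a] * fn[a];
        mz += CZ[a] * fn[a];
      }
      if (!(r > 0.0) || !std::isfinite(r))
        stop("invalid state: non-positive density at node %d", n + 1);
      rho[n] = r;
      u[3*n] = mx / r; u[3*n+1] = my / r; u[3*n+2] = mz / r;
      Ftot[3*n] = Ftot[3*n+1] = Ftot[3*n+2] = 0.0;
      if (type[n] == FLUID) Ftot[3*n] = r * accel;
    }
    if (visco) {
      // elastic force F_V = div(tau) on fluid nodes. The extrapolated
      // wall stress is only a zeroth-order copy of the fluid neighbour,
      // so stress derivatives use FLUID values exclusively (one-sided
      // second order at wall-adjacent nodes).
      for (int n = 0; n < nn; ++n) {
        if (type[n] != FLUID) continue;
        for (int j = 0; j < 3; ++j) {
          double s = 0;
          for (int k = 0; k < 3; ++k) {
            int m = SMAP[k][j];
            int p = nbp[3 * n + k], q = nbm[3 * n + k];
            bool okp = type[p] == FLUID, okq = type[q] == FLUID;
            double v0 = tau[6 * (size_t)n + m];
            if (okp && okq)
              s += (tau[6 * (size_t)p + m] - tau[6 * (size_t)q + m]) * 0.5;
            else if (okp) {
              int p2 = nbp[3 * p + k];
              if (type[p2] == FLUID)
                s += (-3.0 * v0 + 4.0 * tau[6 * (size_t)p + m] -
                      tau[6 * (size_t)p2 + m]) * 0.5;
              else s += tau[6 * (size_t)p + m] - v0;
            } else if (okq) {
              int q2 = nbm[3 * q + k];
              if (type[q2] == FLUID)
                s += (3.0 * v0 - 4.0 * tau[6 * (size_t)q + m] +
                      tau[6 * (size_t)q2 + m]) * 0.5;
              else s += v0 - tau[6 * (size_t)q + m];
            }
          }
          Ftot[3 * n + j] += s;
        }
      }
    }
    if (particle && np > 0) {
      membrane_forces_core(X, np, faces, edges, refM, A0f, phi0, A0, V0,
                           REAL(moduli), memF);
      Support s;
      for (int p = 0; p < np; ++p) {
        kernel_support(&X[3 * p], dims, s);
        for (int t = 0; t < 64; ++t) {
          int n = s.idx[t];
          if (type[n] != FLUID) continue;
          for (int k = 0; k < 3; ++k)
            Ftot[3 * n + k] += memF[3 * p + k] * s.w[t];
        }
      }
    }
    for (int n = 0; n < nn; ++n) {
      if (type[n] == FLUID) {
        double inv2r = 0.5 / rho[n];
        u[3*n]   += Ftot[3*n]   * inv2r;
        u[3*n+1] += Ftot[3*n+1] * inv2r;
        u[3*n+2] += Ftot[3*n+2] * inv2r;
        double u2 = u[3*n]*u[3*n] + u[3*n+1]*u[3*n+1] + u[3*n+2]*u[3*n+2];
        if (u2 > maxu2) maxu2 = u2;
      } else if (type[n] == WALL) {
        u[3*n] = wallU(0, n); u[3*n+1] = wallU(1, n); u[3*n+2] = wallU(2, n);
      }
    }
    if (maxu2 > max_u_seen * max_u_seen) max_u_seen = std::sqrt(maxu2);
    if (maxu2 > abort2)
      stop("numerical blow-up: |u| exceeded 0.3 c (Mach limit)");
    if (visco && with_source) {
      // velocity gradient gu[9n + 3k + l] = d u_l / d x_k, then chi
      for (int n = 0; n < nn; ++n) {
        if (type[n] == INACT) {
          for (int t = 0; t < 9; ++t) gu[9 * (size_t)n + t] = 0.0;
          for (int m = 0; m < 6; ++m) chi[6 * (size_t)n + m] = 0.0;
          continue;
        }
        for (int k = 0; k < 3; ++k) {
          int p = nbp[3 * n + k], q = nbm[3 * n + k];
          bool okp = type[p] != INACT, okq = type[q] != INACT;
          for (int l = 0; l < 3; ++l) {
            double d;
            if (okp && okq) d = (u[3 * p + l] - u[3 * q + l]) * 0.5;
            else if (okp) {
              int p2 = nbp[3 * p + k];
              if (type[p2] != INACT)
                d = (-3.0 * u[3 * n + l] + 4.0 * u[3 * p + l] -
                     u[3 * p2 + l]) * 0.5;
              else d = u[3 * p + l] - u[3 * n + l];
            } else if (okq) {
              int q2 = nbm[3 * q + k];
              if (type[q2] != INACT)
                d = (3.0 * u[3 * n + l] - 4.0 * u[3 * q + l] +
                     u[3 * q2 + l]) * 0.5;
              else d = u[3 * n + l] - u[3 * q + l];
            } else d = 0.0;
            gu[9 * (size_t)n + 3 * k + l] = d;
          }
        }
        const double* g = &gu[9 * (size_t)n];
        const double* t6 = &tau[6 * (size_t)n];
        for (int m = 0; m < 6; ++m) {
          int i = SI[m], j = SJ[m];
          double acc = 0.0;
          for (int k = 0; k < 3; ++k) {
            acc += t6[SMAP[i][k]] * g[3 * k + j] +
                   g[3 * k + i] * t6[SMAP[k][j]];
          }
          double dij = (g[3 * i + j] + g[3 * j + i]) * 0.5;
          chi[6 * (size_t)n + m] =
            acc + (2.0 * eta_p * dij - t6[m]) / lambda_p;
        }
      }
    }
  };

  record_traj(step0);
  // initial diagnostics need moments; cheap enough to run the phase once
  analysis_phase(false);
  record_diag(step0);

  const double kapg = visco ? (lambda_g - 0.5) / lambda_g : 0.0;
  const double guo_pref = 1.0 - 0.5 / lambda_f;

  for (int it = 0; it < nsteps; ++it) {
    int stepno = step0 + it + 1;
    analysis_phase(true);

    // fused collide + stream, both lattices
    for (int n = 0; n < nn; ++n) {
      const size_t base = 19 * (size_t)n;
      const int* tg = &tgt[base];
      if (type[n] == INACT) {
        for (int a = 0; a < 19; ++a) f2[19 * (size_t)tg[a] + a] = 0.0;
        if (visco)
          for (int m = 0; m < 6; ++m)
            for (int a = 0; a < 19; ++a)
              G2[114 * (size_t)tg[a] + 19 * m + a] = 0.0;
        continue;
      }
      double common[19], cu[19];
      int src = (type[n] == WALL) ? wnb[n] : n;
      // equilibria are built at (rho_src, u_node): for fluid src == n;
      // for wall nodes the wall equilibrium uses the neighbour's density
      // with the wall velocity.
      double ux = u[3*n], uy = u[3*n+1], uz = u[3*n+2];
      double r = rho[src];
      double u2 = ux*ux + uy*uy + uz*uz;
      for (int a = 0; a < 19; ++a) {
        double c = CX[a]*ux + CY[a]*uy + CZ[a]*uz;
        cu[a] = c;
        common[a] = 1.0 + 3.0*c + 4.5*c*c - 1.5*u2;
      }
      if (type[n] == FLUID) {
        double Fx = Ftot[3*n], Fy = Ftot[3*n+1], Fz = Ftot[3*n+2];
        double uF = ux*Fx + uy*Fy + uz*Fz;
        const double* fn = &f[base];
        for (int a = 0; a < 19; ++a) {
          double feq = W19[a] * r * common[a];
          double cF = CX[a]*Fx + CY[a]*Fy + CZ[a]*Fz;
          double Fa = guo_pref * W19[a] * (3.0*(cF - uF) + 9.0*cu[a]*cF);
          f2[19 * (size_t)tg[a] + a] = fn[a] + (feq - fn[a]) / lambda_f + Fa;
        }
        if (visco) {
          const double* gn = &G[114 * (size_t)n];
          const double* t6 = &tau[6 * (size_t)n];
          const double* cn = &chi[6 * (size_t)n];
          const double* cp = &chi_prev[6 * (size_t)n];
          double wprof[19];
          for (int a = 0; a < 19; ++a)
            wprof[a] = W19[a] * (1.0 + 3.0 * kapg * cu[a]);
          for (int m = 0; m < 6; ++m) {
            double eff = 1.5 * cn[m] - 0.5 * cp[m];
            for (int a = 0; a < 19; ++a) {
              double geq = W19[a] * t6[m] * common[a];
              double gv = gn[19 * m + a];
              G2[114 * (size_t)tg[a] + 19 * m + a] =
                gv + (geq - gv) / lambda_g + wprof[a] * eff;
            }
          }
        }
      } else {  // WALL: non-equilibrium extrapolation, then collide
        int nb = src;
        double unx = u[3*nb], uny = u[3*nb+1], unz = u[3*nb+2];
        double un2 = unx*unx + uny*uny + unz*unz;
        const double* fnb = &f[19 * (size_t)nb];
        for (int a = 0; a < 19; ++a) {
          double cun = CX[a]*unx + CY[a]*uny + CZ[a]*unz;
          double feq_nb = W19[a] * r * (1.0 + 3.0*cun + 4.5*cun*cun - 1.5*un2);
          double feq_w = W19[a] * r * common[a];
          f2[19 * (size_t)tg[a] + a] =
            feq_w + (1.0 - 1.0 / lambda_f) * (fnb[a] - feq_nb);
        }
        if (visco) {
          const double* gnb = &G[114 * (size_t)nb];
          const double* t6 = &tau[6 * (size_t)nb];
          for (int a = 0; a < 19; ++a) {
            double cun = CX[a]*unx + CY[a]*uny + CZ[a]*unz;
            double prof_nb = W19[a] * (1.0 + 3.0*cun + 4.5*cun*cun - 1.5*un2);
            double prof_w = W19[a] * common[a];
            for (int m = 0; m < 6; ++m) {
              double geq_nb = prof_nb * t6[m];
              double geq_w = prof_w * t6[m];
              G2[114 * (size_t)tg[a] + 19 * m + a] =
                geq_w + (1.0 - 1.0 / lambda_g) * (gnb[19 * m + a] - geq_nb);
            }
          }
        }
      }
    }
    f.swap(f2);
    if (visco) {
      G.swap(G2);
      chi.swap(chi_prev);
    }

    if (particle && np > 0) {
      // advect with the POST-update velocity so the restoring force a
      // node just exerted acts on it within the same step (lagged
      // feedback destabilises stiff membranes). The half-force
      // correction reuses F(t) as the best available estimate.
      Support s;
      for (int p = 0; p < np; ++p) {
        kernel_support(&X[3 * p], dims, s);
        double up[3] = {0, 0, 0};
        for (int t = 0; t < 64; ++t) {
          int n = s.idx[t];
          double un[3] = {0, 0, 0};
          if (type[n] == FLUID) {
            const double* fn = &f[19 * (size_t)n];
            double r = 0, mx = 0, my = 0, mz = 0;
            for (int a = 0; a < 19; ++a) {
              r += fn[a];
              mx += CX[a] * fn[a];
              my += CY[a] * fn[a];
              mz += CZ[a] * fn[a];
            }
            un[0] = (mx + 0.5 * Ftot[3*n]) / r;
            un[1] = (my + 0.5 * Ftot[3*n+1]) / r;
            un[2] = (mz + 0.5 * Ftot[3*n+2]) / r;
          } else if (type[n] == WALL) {
            un[0] = wallU(0, n); un[1] = wallU(1, n); un[2] = wallU(2, n);
          }
          up[0] += un[0] * s.w[t];
          up[1] += un[1] * s.w[t];
          up[2] += un[2] * s.w[t];
        }
        // positions stay UNWRAPPED along the periodic flow axis: wrapping
        // nodes individually would tear the connected mesh at the seam
        // (the kernel wraps coordinates onto the lattice itself).
        for (int k = 0; k < 3; ++k) {
          if (std::fabs(up[k]) > 0.5)
            stop("stability error: node displacement exceeds 0.5 dx per step");
          X[3 * p + k] += up[k];
        }
      }
    }

    if (check_every > 0 && stepno % check_every == 0) {
      for (int n = 0; n < nn; ++n)
        if (!std::isfinite(f[19 * (size_t)n])) {
          stop("numerical blow-up at node %d (step %d)", n + 1, stepno);
        }
      Rcpp::checkUserInterrupt();
    }
    if (record_every > 0 && stepno % record_every == 0) record_traj(stepno);
    if (diag_every > 0 && stepno % diag_every == 0) {
      analysis_phase(false);
      record_diag(stepno);
    }
  }

  // final fields from one more analysis pass
  analysis_phase(false);

  List fields = List::create(
    _["rho"] = NumericVector(rho.begin(), rho.end()),
    _["u"] = NumericMatrix(3, nn, u.begin()),
    _["tau"] = NumericMatrix(6, nn, tau.begin()));
  NumericMatrix Xout(np, 3);
  for (int p = 0; p < np; ++p)
    for (int k = 0; k < 3; ++k) Xout(p, k) = X[3 * p + k];
  List stout = List::create(
    _["f"] = NumericVector(f.begin(), f.end()),
    _["G"] = visco ? NumericVector(G.begin(), G.end()) : NumericVector(0),
    _["chi_prev"] = NumericVector(chi_prev.begin(), chi_prev.end()),
    _["X"] = Xout,
    _["step"] = step0 + nsteps);
  NumericMatrix traj_out =
    irec > 0 ? NumericMatrix(traj(Range(0, irec - 1), _)) : NumericMatrix(0, 7);
  NumericMatrix diag_out =
    idia > 0 ? NumericMatrix(diag(Range(0, idia - 1), _)) : NumericMatrix(0, 5);
  return List::create(
    _["state"] = stout,
    _["traj"] = traj_out,
    _["diag"] = diag_out,
    _["fields"] = fields,
    _["max_u_seen"] = max_u_seen);
}
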