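// Analytic boundary-element kernels: signed triangle solid angles
// (van Oosterom & Strackee), closed-form double-layer integrals for linear
// (hat) basis functions, linear-Galerkin assembly with near-singular outer
// refinement, and quadrature of the Geselowitz surface integrals.
//
// All geometry passed to these routines is in SI metres, faces 0-based.

#include <RcppArmadillo.h>
#include <set>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }

// Per-face constants of the closed-form linear double-layer integrals.
// The hat-function gradients b_i and affine offsets a0_i are independent of
// the observation point: lambda_i(r) = (a0_i + b_i . p) + b_i . (r - p).
struct FaceGeom {
  double v[3][3];   // corner coordinates
  double n[3];      // unit normal
  double b[3][3];   // in-plane hat gradients
  double a0[3];     // affine offsets: a0_i = 1 - b_i . v_i
  double area;
  double diam;      // first edge length (singularity scale)
  double cen[3];    // centroid
  int idx[3];       // vertex indices
};

static std::vector<FaceGeom> face_geometry(const arma::mat& V,
                                           const arma::imat& F) {
  const int nf = F.n_rows;
  std::vector<FaceGeom> out(nf);
  for (int f = 0; f < nf; ++f) {
    FaceGeom& g = out[f];
    for (int k = 0; k < 3; ++k) {
      g.idx[k] = F(f, k);
      for (int d = 0; d < 3; ++d) g.v[k][d] = V(g.idx[k], d);
    }
    for (int d = 0; d < 3; ++d)
      g.cen[d] = (g.v[0][d] + g.v[1][d] + g.v[2][d]) / 3.0;
    double e12[3], e13[3], nv[3];
    vsub(g.v[1], g.v[0], e12); vsub(g.v[2], g.v[0], e13);
    vcross(e12, e13, nv);
    double twoA = vnorm(nv);
    g.area = 0.5 * twoA;
    g.diam = vnorm(e12);
    for (int d = 0; d < 3; ++d) g.n[d] = nv[d] / twoA;
    for (int i = 0; i < 3; ++i) {
      double opp[3];
      vsub(g.v[(i + 2) % 3], g.v[(i + 1) % 3], opp);
      vcross(g.n, opp, g.b[i]);
      for (int d = 0; d < 3; ++d) g.b[i][d] /= twoA;
      g.a0[i] = 1.0 - vdot(g.b[i], g.v[i]);
    }
  }
  return out;
}

// Signed solid angle of the face at p (van Oosterom & Strackee); positive
// when summed to 4*pi over a closed outward surface seen from inside.
static inline double face_solid_angle(const FaceGeom& g, const double* p,
                                      double y[3][3]) {
  double c23[3];
  vsub(g.v[0], p, y[0]); vsub(g.v[1], p, y[1]); vsub(g.v[2], p, y[2]);
  vcross(y[1], y[2], c23);
  double num = vdot(y[0], c23);
  double n1 = vnorm(y[0]), n2 = vnorm(y[1]), n3 = vnorm(y[2]);
  double den = n1 * n2 * n3 + vdot(y[0], y[1]) * n3 + vdot(y[0], y[2]) * n2 +
               vdot(y[1], y[2]) * n1;
  return 2.0 * std::atan2(num, den);
}

// Closed-form integrals  w_i = int_T lambda_i (r'-p).dS' / |r'-p|^3.
// Decomposition: w_i = a_i*Omega + h * b_i . G with G the in-plane moment
// (normal times solid angle minus edge log terms).
static void face_dl_weights(const FaceGeom& g, const double* p, double* w) {
  double y[3][3];
  double omega = face_solid_angle(g, p, y);
  double h = vdot(y[0], g.n);
  double bG[3] = { 0.0, 0.0, 0.0 };
  if (std::fabs(h) > 1e-12 * g.diam) {
    double G[3] = { g.n[0] * omega, g.n[1] * omega, g.n[2] * omega };
    for (int e = 0; e < 3; ++e) {
      const double* ya = y[e];
      const double* yb = y[(e + 1) % 3];
      double ed[3]; vsub(yb, ya, ed);
      double L = vnorm(ed);
      double s = vnorm(ya) + vnorm(yb);
      double denom = s - L;
      if (denom < 1e-14 * s) denom = 1e-14 * s;
      double lg = std::log((s + L) / denom);
      double m[3]; vcross(ed, g.n, m);
      G[0] -= m[0] * lg / L; G[1] -= m[1] * lg / L; G[2] -= m[2] * lg / L;
    }
    for (int i = 0; i < 3; ++i) bG[i] = h * vdot(g.b[i], G);
  } else {
    // coplanar observation point: principal value vanishes; an in-plane
    // point inside the triangle is the caller's responsibility
    if (std::fabs(omega) > 1.0) omega = 0.0;
  }
  for (int i = 0; i < 3; ++i)
    w[i] = (g.a0[i] + vdot(g.b[i], p)) * omega + bG[i];
}

// [[Rcpp::export]]
arma::mat cpp_solid_angles(const arma::mat& V, const arma::imat& F,
                           const arma::mat& P) {
  std::vector<FaceGeom> fg = face_geometry(V, F);
  const int nf = F.n_rows, np = P.n_rows;
  arma::mat out(np, nf);
  arma::mat Pt = P.t();
  double y[3][3];
  for (int i = 0; i < np; ++i) {
    const double* p = Pt.colptr(i);
    for (int f = 0; f < nf; ++f)
      out(i, f) = face_solid_angle(fg[f], p, y);
  }
  return out;
}

// Double-layer matrix with linear basis, collocation points P.
// own_vertex[i] >= 0 marks P.row(i) as vertex own_vertex[i] of this mesh;
// faces containing that vertex are skipped (their principal value is zero
// and the vertex jump is handled by the caller's auto solid angle).
// [[Rcpp::export]]
arma::mat cpp_dl_collocation(const arma::mat& V, const arma::imat& F,
                             const arma::mat& P, const arma::ivec& own_vertex) {
  std::vector<FaceGeom> fg = face_geometry(V, F);
  const int nf = F.n_rows, np = P.n_rows, nv = V.n_rows;
  arma::mat out(np, nv, arma::fill::zeros);
  arma::mat Pt = P.t();
  double w[3];
  for (int i = 0; i < np; ++i) {
    const double* p = Pt.colptr(i);
    int own = own_vertex[i];
    for (int f = 0; f < nf; ++f) {
      const FaceGeom& g = fg[f];
      if (own >= 0 && (g.idx[0] == own || g.idx[1] == own || g.idx[2] == own))
        continue;
      face_dl_weights(g, p, w);
      out(i, g.idx[0]) += w[0];
      out(i, g.idx[1]) += w[1];
      out(i, g.idx[2]) += w[2];
    }
  }
  return out;
}

// 7-point degree-5 symmetric triangle rule (barycentric, weights sum to 1)
static const int NQ7 = 7;
static const double QW7[7] = {
  0.225,
  0.132394152788506, 0.132394152788506, 0.132394152788506,
  0.125939180544827, 0.125939180544827, 0.125939180544827 };
static const double QB7[7][3] = {
  { 1.0 / 3.0, 1.0 / 3.0, 1.0 / 3.0 },
  { 0.059715871789770, 0.470142064105115, 0.470142064105115 },
  { 0.470142064105115, 0.059715871789770, 0.470142064105115 },
  { 0.470142064105115, 0.470142064105115, 0.059715871789770 },
  { 0.797426985353087, 0.101286507323456, 0.101286507323456 },
  { 0.101286507323456, 0.797426985353087, 0.101286507323456 },
  { 0.101286507323456, 0.101286507323456, 0.797426985353087 } };

// 3-point degree-2 rule (edge midpoints)
static const int NQ3 = 3;
static const double QW3[3] = { 1.0 / 3.0, 1.0 / 3.0, 1.0 / 3.0 };
static const double QB3[3][3] = {
  { 0.5, 0.5, 0.0 }, { 0.0, 0.5, 0.5 }, { 0.5, 0.0, 0.5 } };

// Accumulate hat-weighted rows of outer face fa against the listed column
// faces of fg_B, at outer quadrature points given in barycentric coords of
// fa; sign allows subtracting a coarse pass.
static void galerkin_rows(arma::mat& out, const FaceGeom& fa,
                          const std::vector<FaceGeom>& fg_B,
                          const std::vector<int>& cols,
                          const double bary[][3], const double* wts, int nq,
                          double area_frac, double sign) {
  double w[3];
  for (int q = 0; q < nq; ++q) {
    double p[3];
    const double* lam = bary[q];
    for (int d = 0; d < 3; ++d)
      p[d] = lam[0] * fa.v[0][d] + lam[1] * fa.v[1][d] + lam[2] * fa.v[2][d];
    double wq = sign * wts[q] * fa.area * area_frac;
    double c0 = wq * lam[0], c1 = wq * lam[1], c2 = wq * lam[2];
    for (size_t t = 0; t < cols.size(); ++t) {
      const FaceGeom& g = fg_B[cols[t]];
      face_dl_weights(g, p, w);
      for (int m = 0; m < 3; ++m) {
        double wm = w[m];
        int jm = g.idx[m];
        out(fa.idx[0], jm) += c0 * wm;
        out(fa.idx[1], jm) += c1 * wm;
        out(fa.idx[2], jm) += c2 * wm;
      }
    }
  }
}

// Recursive barycentric subdivision of the outer triangle for near-singular
// face pairs; at depth 0 apply the 7-point rule on the sub-triangle.
static void refine_pair(arma::mat& out, const FaceGeom& fa,
                        const std::vector<FaceGeom>& fg_B, int fb,
                        const double tri[3][3], int depth, double area_frac) {
  if (depth == 0) {
    double bary[NQ7][3];
    for (int q = 0; q < NQ7; ++q)
      for (int k = 0; k < 3; ++k)
        bary[q][k] = QB7[q][0] * tri[0][k] + QB7[q][1] * tri[1][k] +
                     QB7[q][2] * tri[2][k];
    std::vector<int> one(1, fb);
    galerkin_rows(out, fa, fg_B, one, bary, QW7, NQ7, area_frac, 1.0);
    return;
  }
  double m01[3], m12[3], m20[3];
  for (int k = 0; k < 3; ++k) {
    m01[k] = 0.5 * (tri[0][k] + tri[1][k]);
    m12[k] = 0.5 * (tri[1][k] + tri[2][k]);
    m20[k] = 0.5 * (tri[2][k] + tri[0][k]);
  }
  double sub[4][3][3];
  for (int k = 0; k < 3; ++k) {
    sub[0][0][k] = tri[0][k]; sub[0][1][k] = m01[k]; sub[0][2][k] = m20[k];
    sub[1][0][k] = m01[k];    sub[1][1][k] = tri[1][k]; sub[1][2][k] = m12[k];
    sub[2][0][k] = m20[k];    sub[2][1][k] = m12[k]; sub[2][2][k] = tri[2][k];
    sub[3][0][k] = m01[k];    sub[3][1][k] = m12[k]; sub[3][2][k] = m20[k];
  }
  for (int s = 0; s < 4; ++s)
    refine_pair(out, fa, fg_B, fb, sub[s], depth - 1, area_frac / 4.0);
}

// Linear-Galerkin double-layer matrix: rows are hat-weighted residuals over
// mesh A, columns the linear double-layer densities on mesh B. When
// same_mesh, the self-face jump (2*pi * elementwise mass matrix) is added
// analytically and outer integrals over faces sharing a vertex with the
// column face are refined by recursive subdivision (refine_depth levels).
// [[Rcpp::export]]
arma::mat cpp_dl_galerkin(const arma::mat& VA, const arma::imat& FA,
                          const arma::mat& VB, const arma::imat& FB,
                          bool same_mesh, int refine_depth) {
  std::vector<FaceGeom> fgA = face_geometry(VA, FA);
  std::vector<FaceGeom> fgB = face_geometry(VB, FB);
  const int nfa = FA.n_rows, nfb = (int) FB.n_rows;
  arma::mat out(VA.n_rows, VB.n_rows, arma::fill::zeros);

  std::vector<int> near_cols, far_cols;
  near_cols.reserve(nfb); far_cols.reserve(nfb);
  for (int f = 0; f < nfa; ++f) {
    const FaceGeom& fa = fgA[f];
    // outer quadrature order adapts to the pair separation: the degree-5
    // rule where the inner integral varies on the panel scale, the degree-2
    // rule for well-separated smooth pairs
    near_cols.clear(); far_cols.clear();
    for (int fb = 0; fb < nfb; ++fb) {
      if (same_mesh && fb == f) continue;
      const FaceGeom& g = fgB[fb];
      double dc[3]; vsub(g.cen, fa.cen, dc);
      double d2 = vdot(dc, dc);
      double ssum = fa.diam + g.diam;
      if (d2 > 2.25 * ssum * ssum) far_cols.push_back(fb);
      else near_cols.push_back(fb);
    }
    galerkin_rows(out, fa, fgB, near_cols, QB7, QW7, NQ7, 1.0, 1.0);
    galerkin_rows(out, fa, fgB, far_cols, QB3, QW3, NQ3, 1.0, 1.0);
    if (same_mesh) {
      // interior-limit jump of the self face: 2*pi * elementwise mass matrix
      double twopiA = 2.0 * M_PI * fa.area;
      for (int k = 0; k < 3; ++k)
        for (int m = 0; m < 3; ++m)
          out(fa.idx[k], fa.idx[m]) += twopiA * ((k == m) ? 1.0 / 6.0 : 1.0 / 12.0);
    }
  }

  if (same_mesh && refine_depth > 0) {
    // faces sharing at least one vertex: redo their outer integrals refined
    std::vector< std::vector<int> > v2f(VA.n_rows);
    for (int f = 0; f < nfa; ++f)
      for (int k = 0; k < 3; ++k) v2f[FA(f, k)].push_back(f);
    const double id_tri[3][3] = { {1, 0, 0}, {0, 1, 0}, {0, 0, 1} };
    for (int f = 0; f < nfa; ++f) {
      const FaceGeom& fa = fgA[f];
      std::set<int> nb;
      for (int k = 0; k < 3; ++k)
        for (size_t t = 0; t < v2f[FA(f, k)].size(); ++t) {
          int g = v2f[FA(f, k)][t];
          if (g != f) nb.insert(g);
        }
      for (std::set<int>::iterator it = nb.begin(); it != nb.end(); ++it) {
        std::vector<int> one(1, *it);   // vertex-sharing pairs used the 7-pt rule
        galerkin_rows(out, fa, fgB, one, QB7, QW7, NQ7, 1.0, -1.0);
        refine_pair(out, fa, fgB, *it, id_tri, refine_depth, 1.0);
      }
    }
  }
  return out;
}

// Geselowitz surface-integral quadrature: maps nodal potentials on one
// surface to the (unit-jump, mu0/4pi excluded) volume-current field at the
// given points:  column j accumulates  sum_q w_q A lambda_j(q)
// (n(q) x (p - q)) / |p - q|^3,  with n(q) the interpolated vertex normal
// (curved-panel correction). Row layout: 3 consecutive rows (x,y,z) per point.
// [[Rcpp::export]]
arma::mat cpp_geselowitz(const arma::mat& V, const arma::imat& F,
                         const arma::mat& VN, const arma::mat& P, int nquad) {
  std::vector<FaceGeom> fg = face_geometry(V, F);
  const int nf = F.n_rows, np = P.n_rows;
  arma::mat out(3 * np, V.n_rows, arma::fill::zeros);
  arma::mat Nt = VN.t(), Pt = P.t();
  const int nq = (nquad >= 7) ? NQ7 : NQ3;
  const double (*QB)[3] = (nquad >= 7) ? QB7 : QB3;
  const double* QW = (nquad >= 7) ? QW7 : QW3;

  for (int f = 0; f < nf; ++f) {
    const FaceGeom& g = fg[f];
    const double* nrm[3];
    for (int k = 0; k < 3; ++k) nrm[k] = Nt.colptr(g.idx[k]);
    for (int q = 0; q < nq; ++q) {
      const double* lam = QB[q];
      double pq[3], nq_[3];
      for (int d = 0; d < 3; ++d) {
        pq[d] = lam[0] * g.v[0][d] + lam[1] * g.v[1][d] + lam[2] * g.v[2][d];
        nq_[d] = lam[0] * nrm[0][d] + lam[1] * nrm[1][d] + lam[2] * nrm[2][d];
      }
      double nn = vnorm(nq_);
      nq_[0] /= nn; nq_[1] /= nn; nq_[2] /= nn;
      double wq = QW[q] * g.area;
      for (int i = 0; i < np; ++i) {
        double d[3]; vsub(Pt.colptr(i), pq, d);
        double r2 = vdot(d, d);
        double r3 = r2 * std::sqrt(r2);
        double cr[3]; vcross(nq_, d, cr);
        for (int dc = 0; dc < 3; ++dc) {
          double val = wq * cr[dc] / r3;
          out(3 * i + dc, g.idx[0]) += lam[0] * val;
          out(3 * i + dc, g.idx[1]) += lam[1] * val;
          out(3 * i + dc, g.idx[2]) += lam[2] * val;
        }
      }
    }
  }
  return out;
}
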