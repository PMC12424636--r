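#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Linear (constant-strain) tetrahedra, one quadrature point per cell.
// Dof numbering: node a (0-based), direction i -> 3*a + i.

static inline double det3(const double M[3][3]) {
  return M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1])
       - M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0])
       + M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
}

static inline void inv3(const double M[3][3], double Mi[3][3], double det) {
  double id = 1.0 / det;
  Mi[0][0] =  (M[1][1] * M[2][2] - M[1][2] * M[2][1]) * id;
  Mi[0][1] = -(M[0][1] * M[2][2] - M[0][2] * M[2][1]) * id;
  Mi[0][2] =  (M[0][1] * M[1][2] - M[0][2] * M[1][1]) * id;
  Mi[1][0] = -(M[1][0] * M[2][2] - M[1][2] * M[2][0]) * id;
  Mi[1][1] =  (M[0][0] * M[2][2] - M[0][2] * M[2][0]) * id;
  Mi[1][2] = -(M[0][0] * M[1][2] - M[0][2] * M[1][0]) * id;
  Mi[2][0] =  (M[1][0] * M[2][1] - M[1][1] * M[2][0]) * id;
  Mi[2][1] = -(M[0][0] * M[2][1] - M[0][1] * M[2][0]) * id;
  Mi[2][2] =  (M[0][0] * M[1][1] - M[0][1] * M[1][0]) * id;
}

// Internal-force residual, per-cell energy/Je, and (optionally) the
// consistent material+geometric tangent as COO triplets.
// gcell/mucell/lamcell: per-cell growth factor and Lame parameters.
// [[Rcpp::export]]
List asm_internal(const NumericMatrix& nodes, const IntegerMatrix& cells,
                  const NumericVector& u, const NumericVector& gcell,
                  const NumericVector& mucell, const NumericVector& lamcell,
                  bool want_tangent) {
  const int nn = nodes.nrow(), nc = cells.nrow();
  NumericVector resid(3 * nn);
  NumericVector psi(nc), JeOut(nc);

  IntegerVector ti, tj;
  NumericVector tx;
  if (want_tangent) {
    ti = IntegerVector(144 * nc);
    tj = IntegerVector(144 * nc);
    tx = NumericVector(144 * nc);
  }
  R_xlen_t nt = 0;

  for (int c = 0; c < nc; ++c) {
    int id[4];
    for (int a = 0; a < 4; ++a) id[a] = cells(c, a) - 1;

    double D[3][3];
    for (int j = 0; j < 3; ++j)
      for (int i = 0; i < 3; ++i)
        D[i][j] = nodes(id[j + 1], i) - nodes(id[0], i);
    double dD = det3(D);
    if (dD <= 0.0)
      return List::create(_["inverted"] = c + 1, _["where"] = "reference");
    double V = dD / 6.0;
    double Di[3][3];
    inv3(D, Di, dD);

    // shape gradients: rows of D^{-1} for nodes 1..3; node 0 = -sum
    double G[4][3];
    for (int j = 0; j < 3; ++j) {
      G[1][j] = Di[0][j]; G[2][j] = Di[1][j]; G[3][j] = Di[2][j];
      G[0][j] = -(Di[0][j] + Di[1][j] + Di[2][j]);
    }

    double F[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          F[i][j] += u[3 * id[a] + i] * G[a][j];

    const double g = gcell[c], mu = mucell[c], lam = lamcell[c];
    double Fe[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) Fe[i][j] = F[i][j] / g;
    double Je = det3(Fe);
    if (!(Je > 0.0) || !std::isfinite(Je))
      return List::create(_["inverted"] = c + 1, _["where"] = "deformed");
    double B[3][3];  // Fe^{-1}
    inv3(Fe, B, Je);
    double lJ = std::log(Je);

    double trC = 0.0;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) trC += Fe[i][j] * Fe[i][j];
    psi[c] = 0.5 * mu * (trC - 3.0 - 2.0 * lJ) + 0.5 * lam * lJ * lJ;
    JeOut[c] = Je;

    // P_tot = (mu (Fe - Fe^{-T}) + lam lnJe Fe^{-T}) / g
    double P[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        P[i][j] = (mu * (Fe[i][j] - B[j][i]) + lam * lJ * B[j][i]) / g;

    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) {
        double s = 0.0;
        for (int j = 0; j < 3; ++j) s += P[i][j] * G[a][j];
        resid[3 * id[a] + i] += V * s;
      }

    if (want_tangent) {
      // A_iJkL = [mu d_ik d_JL + (mu - lam lJ) B_Jk B_Li + lam B_Lk B_Ji]/g^2
      const double ig2 = 1.0 / (g * g);
      const double c1 = mu, c2 = (mu - lam * lJ), c3 = lam;
      double Ke[12][12];
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i)
          for (int b = 0; b < 4; ++b)
            for (int k = 0; k < 3; ++k) {
              double s = 0.0;
              for (int J = 0; J < 3; ++J) {
                const double Ga = G[a][J];
                for (int L = 0; L < 3; ++L) {
                  double A = c2 * B[J][k] * B[L][i] + c3 * B[L][k] * B[J][i];
                  if (i == k && J == L) A += c1;
                  s += Ga * A * G[b][L];
                }
              }
              Ke[3 * a + i][3 * b + k] = V * ig2 * s;
            }
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i)
          for (int b = 0; b < 4; ++b)
            for (int k = 0; k < 3; ++k) {
              ti[nt] = 3 * id[a] + i + 1;
              tj[nt] = 3 * id[b] + k + 1;
              tx[nt] = Ke[3 * a + i][3 * b + k];
              ++nt;
            }
    }
  }

  if (want_tangent)
    return List::create(_["resid"] = resid, _["psi"] = psi, _["Je"] = JeOut,
                        _["i"] = ti, _["j"] = tj, _["x"] = tx);
  return List::create(_["resid"] = resid, _["psi"] = psi, _["Je"] = JeOut);
}

static inline void skew_cols(const double w[3], double S[3][3]) {
  S[0][0] = 0;     S[0][1] = -w[2]; S[0][2] = w[1];
  S[1][0] = w[2];  S[1][1] = 0;     S[1][2] = -w[0];
  S[2][0] = -w[1]; S[2][1] = w[0];  S[2][2] = 0;
}

// Follower pressure on boundary triangles (outward normal w.r.t. the solid).
// Nodal load = p * a_vec / 3 with a_vec the deformed area vector; for flat
// triangles and linear test functions this closed form is the exact surface
// integral of p J F^{-T} N over the reference facet (Nanson).
// Returns the external force vector and, if requested, triplets of
// -d f_ext / d u (the follower-load stiffness contribution to K).
// [[Rcpp::export]]
List asm_pressure(const NumericMatrix& nodes, const IntegerMatrix& tris,
                  const NumericVector& u, double p, bool want_tangent) {
  const int nn = nodes.nrow(), ntri = tris.nrow();
  NumericVector fext(3 * nn);
  IntegerVector ti, tj;
  NumericVector tx;
  if (want_tangent) {
    ti = IntegerVector(81 * ntri);
    tj = IntegerVector(81 * ntri);
    tx = NumericVector(81 * ntri);
  }
  R_xlen_t nt = 0;

  for (int t = 0; t < ntri; ++t) {
    int id[3];
    for (int a = 0; a < 3; ++a) id[a] = tris(t, a) - 1;
    double x[3][3];
    for (int a = 0; a < 3; ++a)
      for (int i = 0; i < 3; ++i)
        x[a][i] = nodes(id[a], i) + u[3 * id[a] + i];

    double e21[3], e31[3], e32[3], av[3];
    for (int i = 0; i < 3; ++i) {
      e21[i] = x[1][i] - x[0][i];
      e31[i] = x[2][i] - x[0][i];
      e32[i] = x[2][i] - x[1][i];
    }
    av[0] = 0.5 * (e21[1] * e31[2] - e21[2] * e31[1]);
    av[1] = 0.5 * (e21[2] * e31[0] - e21[0] * e31[2]);
    av[2] = 0.5 * (e21[0] * e31[1] - e21[1] * e31[0]);

    for (int a = 0; a < 3; ++a)
      for (int i = 0; i < 3; ++i)
        fext[3 * id[a] + i] += p * av[i] / 3.0;

    if (want_tangent) {
      // d a_vec / d x_b:  b=0: skew(x3-x2)/2, b=1: -skew(e31)/2, b=2: skew(e21)/2
      double Dab[3][3][3];
      skew_cols(e32, Dab[0]);
      skew_cols(e31, Dab[1]);
      skew_cols(e21, Dab[2]);
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          Dab[0][i][j] *= 0.5;
          Dab[1][i][j] *= -0.5;
          Dab[2][i][j] *= 0.5;
        }
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          for (int i = 0; i < 3; ++i)
            for (int k = 0; k < 3; ++k) {
              ti[nt] = 3 * id[a] + i + 1;
              tj[nt] = 3 * id[b] + k + 1;
              tx[nt] = -(p / 3.0) * Dab[b][i][k];
              ++nt;
            }
    }
  }
  if (want_tangent)
    return List::create(_["fext"] = fext, _["i"] = ti, _["j"] = tj,
                        _["x"] = tx);
  return List::create(_["fext"] = fext);
}

// Exact point-to-triangle distance (region clamping in barycentric space).
static double point_tri_dist2(const double p[3], const double a[3],
                              const double b[3], const double c[3]) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  double daa = ab[0]*ab[0] + ab[1]*ab[1] + ab[2]*ab[2];
  double dcc = ac[0]*ac[0] + ac[1]*ac[1] + ac[2]*ac[2];
  double dac = ab[0]*ac[0] + ab[1]*ac[1] + ab[2]*ac[2];
  double u = -1, v = -1;
  double det = daa * dcc - dac * dac;
  if (det > 1e-30) {
    u = (dcc * d1 - dac * d2) / det;
    v = (daa * d2 - dac * d1) / det;
  }
  if (u >= 0 && v >= 0 && u + v <= 1) {
    double q[3], d2s = 0;
    for (int i = 0; i < 3; ++i) {
      q[i] = a[i] + u * ab[i] + v * ac[i] - p[i];
      d2s += q[i] * q[i];
    }
    return d2s;
  }
  // edge/vertex regions: clamp onto the three edges
  double best = R_PosInf;
  const double* vs[3] = {a, b, c};
  for (int e = 0; e < 3; ++e) {
    const double* p0 = vs[e];
    const double* p1 = vs[(e + 1) % 3];
    double d[3], w[3];
    double num = 0, den = 0;
    for (int i = 0; i < 3; ++i) {
      d[i] = p1[i] - p0[i];
      num += d[i] * (p[i] - p0[i]);
      den += d[i] * d[i];
    }
    double t = den > 0 ? num / den : 0;
    if (t < 0) t = 0; if (t > 1) t = 1;
    double s = 0;
    for (int i = 0; i < 3; ++i) {
      w[i] = p0[i] + t * d[i] - p[i];
      s += w[i] * w[i];
    }
    if (s < best) best = s;
  }
  return best;
}

// For each point, the distance to the nearest point of any triangle.
// [[Rcpp::export]]
NumericVector nearest_tri_distance(const NumericMatrix& pts,
                                   const NumericMatrix& v0,
                                   const NumericMatrix& v1,
                                   const NumericMatrix& v2) {
  const int np = pts.nrow(), ntri = v0.nrow();
  NumericVector out(np);
  for (int r = 0; r < np; ++r) {
    double p[3] = {pts(r, 0), pts(r, 1), pts(r, 2)};
    double best = R_PosInf;
    for (int t = 0; t < ntri; ++t) {
      double a[3] = {v0(t, 0), v0(t, 1), v0(t, 2)};
      double b[3] = {v1(t, 0), v1(t, 1), v1(t, 2)};
      double c[3] = {v2(t, 0), v2(t, 1), v2(t, 2)};
      double d2s = point_tri_dist2(p, a, b, c);
      if (d2s < best) best = d2s;
    }
    out[r] = std::sqrt(best);
  }
  return out;
}

// Moller-Trumbore first-hit ray casting: for each origin/direction pair,
// the smallest positive distance to any triangle (v0,v1,v2), or NA.
// [[Rcpp::export]]
NumericVector ray_cast_first_hit(const NumericMatrix& orig,
                                 const NumericMatrix& dir,
                                 const NumericMatrix& v0,
                                 const NumericMatrix& v1,
                                 const NumericMatrix& v2,
                                 double tmin, double tmax) {
  const int nr = orig.nrow(), ntri = v0.nrow();
  NumericVector out(nr, NA_REAL);
  const double eps = 1e-12;
  for (int r = 0; r < nr; ++r) {
    double o[3], d[3];
    for (int i = 0; i < 3; ++i) { o[i] = orig(r, i); d[i] = dir(r, i); }
    double best = R_PosInf;
    for (int t = 0; t < ntri; ++t) {
      double e1[3], e2[3], tv[3], pv[3], qv[3];
      for (int i = 0; i < 3; ++i) {
        e1[i] = v1(t, i) - v0(t, i);
        e2[i] = v2(t, i) - v0(t, i);
        tv[i] = o[i] - v0(t, i);
      }
      pv[0] = d[1] * e2[2] - d[2] * e2[1];
      pv[1] = d[2] * e2[0] - d[0] * e2[2];
      pv[2] = d[0] * e2[1] - d[1] * e2[0];
      double det = e1[0] * pv[0] + e1[1] * pv[1] + e1[2] * pv[2];
      if (std::fabs(det) < eps) continue;
      double idet = 1.0 / det;
      double uu = (tv[0] * pv[0] + tv[1] * pv[1] + tv[2] * pv[2]) * idet;
      if (uu < -1e-9 || uu > 1.0 + 1e-9) continue;
      qv[0] = tv[1] * e1[2] - tv[2] * e1[1];
      qv[1] = tv[2] * e1[0] - tv[0] * e1[2];
      qv[2] = tv[0] * e1[1] - tv[1] * e1[0];
      double vv = (d[0] * qv[0] + d[1] * qv[1] + d[2] * qv[2]) * idet;
      if (vv < -1e-9 || uu + vv > 1.0 + 1e-9) continue;
      double tt = (e2[0] * qv[0] + e2[1] * qv[1] + e2[2] * qv[2]) * idet;
      if (tt > tmin && tt < best && tt <= tmax) best = tt;
    }
    if (std::isfinite(best)) out[r] = best;
  }
  return out;
}
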