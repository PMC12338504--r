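// Low-level kernels for the charge-based boundary-element solver.
//
// Conventions: the solver unknown is g = rho / eps0 (surface charge density
// over the vacuum permittivity), so that the induced potential is
//   phi_ind(r) = (1/4pi) sum_j g_j \int_{T_j} 1/|r-y| dA(y)
// and the induced field is the corresponding gradient kernel. Near-field
// integrals over flat triangles use closed-form expressions (line-integral
// form); far pairs use the centroid point approximation.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

// Closed-form integrals of 1/R and (P - y)/R^3 over a flat triangle with
// vertices v1, v2, v3 (counter-clockwise seen from the side the unit normal
// points to). Returns I1 = int 1/R dA and igrad[3] = int (P - y)/R^3 dA,
// the latter in the principal-value sense when P lies in the triangle plane.
static void tri_integrals(const double* P,
                          const double* v1, const double* v2, const double* v3,
                          double* I1, double* igrad) {
  double e1[3], e2[3], nrm[3];
  for (int d = 0; d < 3; ++d) { e1[d] = v2[d] - v1[d]; e2[d] = v3[d] - v1[d]; }
  cross3(e1, e2, nrm);
  double nn = norm3(nrm);
  for (int d = 0; d < 3; ++d) nrm[d] /= nn;

  double w0 = (P[0] - v1[0]) * nrm[0] + (P[1] - v1[1]) * nrm[1] +
              (P[2] - v1[2]) * nrm[2];
  double rho[3];
  for (int d = 0; d < 3; ++d) rho[d] = P[d] - w0 * nrm[d];

  const double* A[3] = {v1, v2, v3};
  const double* B[3] = {v2, v3, v1};

  double sumI1 = 0.0, beta = 0.0;
  double gplane[3] = {0.0, 0.0, 0.0};
  double aw0 = std::fabs(w0);

  for (int i = 0; i < 3; ++i) {
    double shat[3], mhat[3];
    double el = 0.0;
    for (int d = 0; d < 3; ++d) shat[d] = B[i][d] - A[i][d];
    el = norm3(shat);
    for (int d = 0; d < 3; ++d) shat[d] /= el;
    cross3(shat, nrm, mhat);  // outward in-plane edge normal

    double da[3], db[3];
    for (int d = 0; d < 3; ++d) { da[d] = A[i][d] - rho[d]; db[d] = B[i][d] - rho[d]; }
    double sa = dot3(da, shat), sb = dot3(db, shat);
    double t = dot3(da, mhat);
    double Ra = 0.0, Rb = 0.0;
    {
      double pa[3], pb[3];
      for (int d = 0; d < 3; ++d) { pa[d] = P[d] - A[i][d]; pb[d] = P[d] - B[i][d]; }
      Ra = norm3(pa); Rb = norm3(pb);
    }
    double R02 = t * t + w0 * w0;

    double f2;
    if (sa + sb >= 0.0) {
      double den = Ra + sa;
      f2 = (den > 0.0) ? std::log((Rb + sb) / den) : 0.0;
    } else {
      double den = Rb - sb;
      f2 = (den > 0.0) ? std::log((Ra - sa) / den) : 0.0;
    }

    double bi = 0.0;
    if (t != 0.0) {
      bi = std::atan(t * sb / (R02 + aw0 * Rb)) -
           std::atan(t * sa / (R02 + aw0 * Ra));
    }
    beta += bi;
    sumI1 += t * f2;
    for (int d = 0; d < 3; ++d) gplane[d] += mhat[d] * f2;
  }

  *I1 = sumI1 - aw0 * beta;
  double sgn = (w0 > 0.0) ? 1.0 : ((w0 < 0.0) ? -1.0 : 0.0);
  for (int d = 0; d < 3; ++d) igrad[d] = gplane[d] + sgn * beta * nrm[d];
}

// [[Rcpp::export]]
List cpp_tri_integrals(NumericVector P, NumericVector v1, NumericVector v2,
                       NumericVector v3) {
  double I1, g[3];
  tri_integrals(P.begin(), v1.begin(), v2.begin(), v3.begin(), &I1, g);
  return List::create(_["I1"] = I1,
                      _["igrad"] = NumericVector::create(g[0], g[1], g[2]));
}

// Observation-averaged field kernel: mean over face i (recursive 4:1
// subdivision while a subtriangle is large compared with its distance to
// the source face) of n_i . \int_{T_j} (x - y)/|x - y|^3 dA(y) / 4pi.
// Single-point collocation is inaccurate when two surfaces lie closer
// than a face diameter (the skull gap); averaging the observation over
// the face restores the accuracy of the surface coupling.
static double obs_avg_kern(const double* vi1, const double* vi2,
                           const double* vi3, const double* ni,
                           const double* vj, int depth) {
  double cen[3], e[3];
  for (int q = 0; q < 3; ++q) cen[q] = (vi1[q] + vi2[q] + vi3[q]) / 3.0;
  double diam2 = 0.0;
  for (int q = 0; q < 3; ++q) e[q] = vi2[q] - vi1[q];
  diam2 = std::max(diam2, dot3(e, e));
  for (int q = 0; q < 3; ++q) e[q] = vi3[q] - vi2[q];
  diam2 = std::max(diam2, dot3(e, e));
  for (int q = 0; q < 3; ++q) e[q] = vi1[q] - vi3[q];
  diam2 = std::max(diam2, dot3(e, e));
  double cj[3] = {(vj[0] + vj[3] + vj[6]) / 3.0,
                  (vj[1] + vj[4] + vj[7]) / 3.0,
                  (vj[2] + vj[5] + vj[8]) / 3.0};
  double d[3] = {cen[0] - cj[0], cen[1] - cj[1], cen[2] - cj[2]};
  double dist2 = dot3(d, d);
  if (depth <= 0 || dist2 > 4.0 * diam2) {
    double I1, g[3];
    tri_integrals(cen, vj, vj + 3, vj + 6, &I1, g);
    return dot3(g, ni) / (4.0 * M_PI);
  }
  double m12[3], m23[3], m31[3];
  for (int q = 0; q < 3; ++q) {
    m12[q] = 0.5 * (vi1[q] + vi2[q]);
    m23[q] = 0.5 * (vi2[q] + vi3[q]);
    m31[q] = 0.5 * (vi3[q] + vi1[q]);
  }
  return 0.25 * (obs_avg_kern(vi1, m12, m31, ni, vj, depth - 1) +
                 obs_avg_kern(m12, vi2, m23, ni, vj, depth - 1) +
                 obs_avg_kern(m31, m23, vi3, ni, vj, depth - 1) +
                 obs_avg_kern(m12, m23, m31, ni, vj, depth - 1));
}

// Dense BEM system matrix: M[i,j] = -k_i * n_i . K_ij (i != j) with K_ij
// the field kernel integral over face j evaluated at centroid i. The
// diagonal carries a row-sum (solid-angle) correction: for a point on a
// closed surface the principal-value integral of the normal field of a
// uniform unit charge over that same surface equals 1/2 exactly, so the
// self term is set to 1/2 - k_i * (1/2 - S_i) with S_i the computed
// same-surface row sum. This cancels the discretization error of the
// strongest (uniform) mode. triV: N x 9 (v1x v1y v1z v2x ... v3z).
// [[Rcpp::export]]
NumericMatrix cpp_bem_matrix(NumericMatrix cen, NumericMatrix nor,
                             NumericVector area, NumericVector kvec,
                             NumericMatrix triV, NumericVector diam,
                             IntegerVector surf, double near_mult,
                             NumericVector defl, bool use_rowsum,
                             bool use_obsavg) {
  int N = cen.nrow();
  NumericMatrix M(N, N);
  const double inv4pi = 1.0 / (4.0 * M_PI);
  std::vector<double> C(3 * N), NR(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) { C[3 * i + d] = cen(i, d); NR[3 * i + d] = nor(i, d); }
  std::vector<double> TV(9 * N);
  for (int j = 0; j < N; ++j)
    for (int d = 0; d < 9; ++d) TV[9 * j + d] = triV(j, d);
  std::vector<double> rowsum(N, 0.0);

  for (int j = 0; j < N; ++j) {
    const double* cj = &C[3 * j];
    double thr = near_mult * diam[j];
    double thr2 = thr * thr;
    const double* vj = &TV[9 * j];
    double Aj = area[j];
    for (int i = 0; i < N; ++i) {
      if (i == j) continue;
      const double* ci = &C[3 * i];
      double dx = ci[0] - cj[0], dy = ci[1] - cj[1], dz = ci[2] - cj[2];
      double d2 = dx * dx + dy * dy + dz * dz;
      double kern;
      double diam_i = diam[i];
      if (d2 > thr2 && d2 > near_mult * near_mult * diam_i * diam_i) {
        double d1 = std::sqrt(d2);
        double w = Aj * inv4pi / (d2 * d1);
        kern = w * (dx * NR[3 * i] + dy * NR[3 * i + 1] + dz * NR[3 * i + 2]);
      } else if (!use_obsavg || d2 > 4.0 * diam_i * diam_i) {
        double I1, g[3];
        tri_integrals(ci, vj, vj + 3, vj + 6, &I1, g);
        kern = inv4pi * dot3(g, &NR[3 * i]);
      } else {
        const double* vi = &TV[9 * i];
        kern = obs_avg_kern(vi, vi + 3, vi + 6, &NR[3 * i], vj, 3);
      }
      M(i, j) = -kvec[i] * kern;
      if (surf[i] == surf[j]) { rowsum[i] += kern; M(i, j) += defl[j]; }
    }
  }
  for (int i = 0; i < N; ++i)
    M(i, i) = (use_rowsum ? 0.5 - kvec[i] * (0.5 - rowsum[i]) : 0.5) +
      defl[i];
  return M;
}

// Matrix-free matvec for the same (row-sum corrected) operator.
// [[Rcpp::export]]
NumericVector cpp_bem_matvec(NumericMatrix cen, NumericMatrix nor,
                             NumericVector area, NumericVector kvec,
                             NumericMatrix triV, NumericVector diam,
                             IntegerVector surf, double near_mult,
                             bool use_rowsum, bool use_obsavg,
                             NumericVector x) {
  int N = cen.nrow();
  NumericVector y(N);
  const double inv4pi = 1.0 / (4.0 * M_PI);
  for (int i = 0; i < N; ++i) {
    double ci[3] = {cen(i, 0), cen(i, 1), cen(i, 2)};
    double ni[3] = {nor(i, 0), nor(i, 1), nor(i, 2)};
    double acc = 0.0, rowsum = 0.0;
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      double cj[3] = {cen(j, 0), cen(j, 1), cen(j, 2)};
      double dx = ci[0] - cj[0], dy = ci[1] - cj[1], dz = ci[2] - cj[2];
      double d2 = dx * dx + dy * dy + dz * dz;
      double thr = near_mult * diam[j];
      double kern;
      double di = diam[i];
      if (d2 > thr * thr && d2 > near_mult * near_mult * di * di) {
        double d1 = std::sqrt(d2);
        double w = area[j] * inv4pi / (d2 * d1);
        kern = w * (dx * ni[0] + dy * ni[1] + dz * ni[2]);
      } else {
        double vj[9], vi[9];
        for (int d = 0; d < 9; ++d) vj[d] = triV(j, d);
        if (!use_obsavg || d2 > 4.0 * di * di) {
          double I1, g[3];
          tri_integrals(ci, vj, vj + 3, vj + 6, &I1, g);
          kern = inv4pi * dot3(g, ni);
        } else {
          for (int d = 0; d < 9; ++d) vi[d] = triV(i, d);
          kern = obs_avg_kern(vi, vi + 3, vi + 6, ni, vj, 3);
        }
      }
      acc += kern * x[j];
      if (surf[j] == surf[i]) rowsum += kern;
    }
    double dg = use_rowsum ? 0.5 - kvec[i] * (0.5 - rowsum) : 0.5;
    y[i] = dg * x[i] - kvec[i] * acc;
  }
  return y;
}

// Induced potential at points from K charge vectors (columns of G, N x K).
// Returns P x K matrix, units consistent with g = rho/eps0.
// [[Rcpp::export]]
NumericMatrix cpp_eval_potential(NumericMatrix triV, NumericMatrix cen,
                                 NumericVector area, NumericVector diam,
                                 NumericMatrix G, NumericMatrix pts,
                                 double near_mult) {
  int N = cen.nrow(), K = G.ncol(), P = pts.nrow();
  NumericMatrix out(P, K);
  const double inv4pi = 1.0 / (4.0 * M_PI);
  for (int p = 0; p < P; ++p) {
    double pp[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
    for (int j = 0; j < N; ++j) {
      double dx = pp[0] - cen(j, 0), dy = pp[1] - cen(j, 1), dz = pp[2] - cen(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      double thr = near_mult * diam[j];
      double w;
      if (d2 > thr * thr) {
        w = area[j] * inv4pi / std::sqrt(d2);
      } else {
        double I1, g[3];
        double vj[9];
        for (int d = 0; d < 9; ++d) vj[d] = triV(j, d);
        tri_integrals(pp, vj, vj + 3, vj + 6, &I1, g);
        w = inv4pi * I1;
      }
      for (int k = 0; k < K; ++k) out(p, k) += w * G(j, k);
    }
  }
  return out;
}

// Induced field at points from K charge vectors. Returns array dim (P, 3, K).
// [[Rcpp::export]]
NumericVector cpp_eval_field(NumericMatrix triV, NumericMatrix cen,
                             NumericVector area, NumericVector diam,
                             NumericMatrix G, NumericMatrix pts,
                             double near_mult) {
  int N = cen.nrow(), K = G.ncol(), P = pts.nrow();
  NumericVector out(P * 3 * K);
  out.attr("dim") = IntegerVector::create(P, 3, K);
  const double inv4pi = 1.0 / (4.0 * M_PI);
  for (int p = 0; p < P; ++p) {
    double pp[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
    for (int j = 0; j < N; ++j) {
      double dx = pp[0] - cen(j, 0), dy = pp[1] - cen(j, 1), dz = pp[2] - cen(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      double thr = near_mult * diam[j];
      double kv[3];
      if (d2 > thr * thr) {
        double d1 = std::sqrt(d2);
        double w = area[j] * inv4pi / (d2 * d1);
        kv[0] = w * dx; kv[1] = w * dy; kv[2] = w * dz;
      } else {
        double I1, g[3];
        double vj[9];
        for (int d = 0; d < 9; ++d) vj[d] = triV(j, d);
        tri_integrals(pp, vj, vj + 3, vj + 6, &I1, g);
        kv[0] = inv4pi * g[0]; kv[1] = inv4pi * g[1]; kv[2] = inv4pi * g[2];
      }
      for (int k = 0; k < K; ++k) {
        double gk = G(j, k);
        out[p + P * 0 + P * 3 * k] += kv[0] * gk;
        out[p + P * 1 + P * 3 * k] += kv[1] * gk;
        out[p + P * 2 + P * 3 * k] += kv[2] * gk;
      }
    }
  }
  return out;
}

// ---- face-averaged primary-field right-hand sides -------------------------
// The collocation right-hand side k_i n_i . E_primary is averaged over each
// face by adaptive 4:1 barycentric subdivision (splitting while the
// subtriangle is large compared with its distance to the source), which
// matters for sources close to the boundary (contact-current monopoles sit
// half an edge below their own faces).

struct DipSrc { double p[3]; double m[3]; double inv4pisig; };

static double dip_en(const DipSrc& s, const double* x, const double* nrm) {
  double d[3] = {x[0] - s.p[0], x[1] - s.p[1], x[2] - s.p[2]};
  double r2 = dot3(d, d);
  double r = std::sqrt(r2);
  double mu = dot3(s.m, d) / r;
  double en = 0.0;
  for (int q = 0; q < 3; ++q)
    en += (3.0 * mu * d[q] / r - s.m[q]) * nrm[q];
  return en * s.inv4pisig / (r2 * r);
}

template <typename F>
static double face_avg(const F& f, const double* v1, const double* v2,
                       const double* v3, const double* src_pos,
                       const double* nrm, int depth) {
  double cen[3], e[3];
  double diam2 = 0.0;
  for (int q = 0; q < 3; ++q) cen[q] = (v1[q] + v2[q] + v3[q]) / 3.0;
  for (int q = 0; q < 3; ++q) e[q] = v2[q] - v1[q];
  diam2 = std::max(diam2, dot3(e, e));
  for (int q = 0; q < 3; ++q) e[q] = v3[q] - v2[q];
  diam2 = std::max(diam2, dot3(e, e));
  for (int q = 0; q < 3; ++q) e[q] = v1[q] - v3[q];
  diam2 = std::max(diam2, dot3(e, e));
  double d[3] = {cen[0] - src_pos[0], cen[1] - src_pos[1], cen[2] - src_pos[2]};
  double dist2 = dot3(d, d);
  if (depth <= 0 || dist2 > 4.0 * diam2) return f(cen, nrm);
  double m12[3], m23[3], m31[3];
  for (int q = 0; q < 3; ++q) {
    m12[q] = 0.5 * (v1[q] + v2[q]);
    m23[q] = 0.5 * (v2[q] + v3[q]);
    m31[q] = 0.5 * (v3[q] + v1[q]);
  }
  return 0.25 * (face_avg(f, v1, m12, m31, src_pos, nrm, depth - 1) +
                 face_avg(f, m12, v2, m23, src_pos, nrm, depth - 1) +
                 face_avg(f, m31, m23, v3, src_pos, nrm, depth - 1) +
                 face_avg(f, m12, m23, m31, src_pos, nrm, depth - 1));
}

// [[Rcpp::export]]
NumericVector cpp_rhs_dipole(NumericMatrix triV, NumericMatrix nor,
                             NumericVector kvec, NumericVector p,
                             NumericVector m, double sigma, int max_depth) {
  int N = triV.nrow();
  NumericVector b(N);
  DipSrc s;
  for (int q = 0; q < 3; ++q) { s.p[q] = p[q]; s.m[q] = m[q]; }
  s.inv4pisig = 1.0 / (4.0 * M_PI * sigma);
  auto f = [&](const double* x, const double* nrm_) { return dip_en(s, x, nrm_); };
  for (int i = 0; i < N; ++i) {
    double v[9], ni[3];
    for (int q = 0; q < 9; ++q) v[q] = triV(i, q);
    for (int q = 0; q < 3; ++q) ni[q] = nor(i, q);
    b[i] = kvec[i] * face_avg(f, v, v + 3, v + 6, s.p, ni, max_depth);
  }
  return b;
}

// signed solid angle of triangle (v1,v2,v3) seen from point p
// (van Oosterom-Strackee); positive when p lies on the side the
// counter-clockwise normal points away from is consistent with
// int (x-p).n/|x-p|^3 dA over the triangle.
static double solid_angle(const double* p, const double* v1,
                          const double* v2, const double* v3) {
  double a[3], b[3], c[3];
  for (int d = 0; d < 3; ++d) {
    a[d] = v1[d] - p[d]; b[d] = v2[d] - p[d]; c[d] = v3[d] - p[d];
  }
  double la = norm3(a), lb = norm3(b), lc = norm3(c);
  double bxc[3];
  cross3(b, c, bxc);
  double num = dot3(a, bxc);
  double den = la * lb * lc + dot3(a, b) * lc + dot3(b, c) * la +
               dot3(c, a) * lb;
  return 2.0 * std::atan2(num, den);
}

// Face-averaged monopole right-hand side in closed form: the average of
// n . E over a flat face equals I * (solid angle) / (4 pi sigma area).
// Exact even for a monopole a fraction of an edge length below its own
// contact face, where quadrature would misestimate a nearly singular
// integrand (the error would act like spurious injected current).
// [[Rcpp::export]]
NumericVector cpp_rhs_monopoles(NumericMatrix triV, NumericMatrix nor,
                                NumericVector kvec, NumericMatrix S,
                                NumericVector I, double sigma,
                                NumericVector area) {
  int N = triV.nrow(), ns = S.nrow();
  NumericVector b(N);
  const double inv4pisig = 1.0 / (4.0 * M_PI * sigma);
  for (int i = 0; i < N; ++i) {
    double v[9];
    for (int q = 0; q < 9; ++q) v[q] = triV(i, q);
    double acc = 0.0;
    for (int s = 0; s < ns; ++s) {
      double sp[3] = {S(s, 0), S(s, 1), S(s, 2)};
      acc += I[s] * solid_angle(sp, v, v + 3, v + 6);
    }
    b[i] = kvec[i] * inv4pisig * acc / area[i];
  }
  return b;
}

// Generalized winding number of closed triangulated surface(s) at points:
// ~1 inside, ~0 outside (van Oosterom-Strackee solid angles / 4pi).
// [[Rcpp::export]]
NumericVector cpp_winding_number(NumericMatrix triV, NumericMatrix pts) {
  int N = triV.nrow(), P = pts.nrow();
  NumericVector out(P);
  for (int p = 0; p < P; ++p) {
    double pp[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
    double tot = 0.0;
    for (int j = 0; j < N; ++j) {
      double a[3], b[3], c[3];
      for (int d = 0; d < 3; ++d) {
        a[d] = triV(j, d) - pp[d];
        b[d] = triV(j, 3 + d) - pp[d];
        c[d] = triV(j, 6 + d) - pp[d];
      }
      double la = norm3(a), lb = norm3(b), lc = norm3(c);
      double bxc[3];
      cross3(b, c, bxc);
      double num = dot3(a, bxc);
      double den = la * lb * lc + dot3(a, b) * lc + dot3(b, c) * la +
                   dot3(c, a) * lb;
      tot += 2.0 * std::atan2(num, den);
    }
    out[p] = tot / (4.0 * M_PI);
  }
  return out;
}

// Weight matrix for potential evaluation: out[p, j] is the potential at
// point p of a unit charge density on face j (closed-form within
// near_mult face diameters, centroid point charge beyond). The caller
// multiplies by the charge matrix with BLAS, which is far faster than
// accumulating across many charge vectors in this loop.
// [[Rcpp::export]]
NumericMatrix cpp_potential_weights(NumericMatrix triV, NumericMatrix cen,
                                    NumericVector area, NumericVector diam,
                                    NumericMatrix pts, double near_mult) {
  int N = cen.nrow(), P = pts.nrow();
  NumericMatrix W(P, N);
  const double inv4pi = 1.0 / (4.0 * M_PI);
  for (int j = 0; j < N; ++j) {
    double cj[3] = {cen(j, 0), cen(j, 1), cen(j, 2)};
    double thr = near_mult * diam[j];
    double thr2 = thr * thr;
    double vj[9];
    for (int d = 0; d < 9; ++d) vj[d] = triV(j, d);
    double Aj = area[j];
    for (int p = 0; p < P; ++p) {
      double dx = pts(p, 0) - cj[0], dy = pts(p, 1) - cj[1],
             dz = pts(p, 2) - cj[2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > thr2) {
        W(p, j) = Aj * inv4pi / std::sqrt(d2);
      } else {
        double pp[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
        double I1, g[3];
        tri_integrals(pp, vj, vj + 3, vj + 6, &I1, g);
        W(p, j) = inv4pi * I1;
      }
    }
  }
  return W;
}
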