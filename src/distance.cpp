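#include <Rcpp.h>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p, after Ericson, Real-Time
// Collision Detection.  Returns closest point and barycentric coords.
static inline void closest_on_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *cp, double *bary) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) { ab[k] = b[k] - a[k]; ac[k] = c[k] - a[k]; ap[k] = p[k] - a[k]; }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int k = 0; k < 3; ++k) cp[k] = a[k];
    bary[0] = 1; bary[1] = 0; bary[2] = 0; return;
  }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int k = 0; k < 3; ++k) cp[k] = b[k];
    bary[0] = 0; bary[1] = 1; bary[2] = 0; return;
  }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) cp[k] = a[k] + v * ab[k];
    bary[0] = 1 - v; bary[1] = v; bary[2] = 0; return;
  }
  double cpv[3];
  for (int k = 0; k < 3; ++k) cpv[k] = p[k] - c[k];
  double d5 = ab[0]*cpv[0] + ab[1]*cpv[1] + ab[2]*cpv[2];
  double d6 = ac[0]*cpv[0] + ac[1]*cpv[1] + ac[2]*cpv[2];
  if (d6 >= 0.0 && d5 <= d6) {
    for (int k = 0; k < 3; ++k) cp[k] = c[k];
    bary[0] = 0; bary[1] = 0; bary[2] = 1; return;
  }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) cp[k] = a[k] + w * ac[k];
    bary[0] = 1 - w; bary[1] = 0; bary[2] = w; return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) cp[k] = b[k] + w * (c[k] - b[k]);
    bary[0] = 0; bary[1] = 1 - w; bary[2] = w; return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) cp[k] = a[k] + ab[k]*v + ac[k]*w;
  bary[0] = 1 - v - w; bary[1] = v; bary[2] = w;
}

// [[Rcpp::export]]
List cpp_closest_point(NumericMatrix query, NumericMatrix verts,
                       IntegerMatrix tris) {
  const int nq = query.nrow(), nt = tris.nrow();
  NumericVector dist(nq);
  IntegerVector tri_idx(nq);
  NumericMatrix closest(nq, 3), bary(nq, 3);
  std::vector<double> V(verts.nrow() * 3);
  for (int i = 0; i < verts.nrow(); ++i)
    for (int k = 0; k < 3; ++k) V[i*3 + k] = verts(i, k);
  for (int i = 0; i < nq; ++i) {
    double p[3] = { query(i,0), query(i,1), query(i,2) };
    double best = R_PosInf, bcp[3] = {0,0,0}, bb[3] = {0,0,0};
    int bt = -1;
    for (int t = 0; t < nt; ++t) {
      const double *a = &V[(tris(t,0)-1)*3];
      const double *b = &V[(tris(t,1)-1)*3];
      const double *c = &V[(tris(t,2)-1)*3];
      double cp[3], bc[3];
      closest_on_tri(p, a, b, c, cp, bc);
      double d2 = 0;
      for (int k = 0; k < 3; ++k) { double dd = p[k]-cp[k]; d2 += dd*dd; }
      if (d2 < best) {
        best = d2; bt = t;
        for (int k = 0; k < 3; ++k) { bcp[k] = cp[k]; bb[k] = bc[k]; }
      }
    }
    dist[i] = std::sqrt(best);
    tri_idx[i] = bt + 1;
    for (int k = 0; k < 3; ++k) { closest(i,k) = bcp[k]; bary(i,k) = bb[k]; }
  }
  return List::create(_["distance"] = dist, _["triangle"] = tri_idx,
                      _["closest"] = closest, _["bary"] = bary);
}
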