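#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1D squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// applied separably along the three axes of a voxel array.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (q0 < n && f[q0] == INF) q0++;
  if (q0 == n) { for (int q = 0; q < n; q++) d[q] = INF; return; }
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; q++) {
    if (f[q] == INF) continue;  // INF parabolas never form the lower envelope
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared distance (in voxel units) from every voxel to the nearest TRUE
// voxel of a 3D logical array.
// [[Rcpp::export]]
NumericVector edt3d_sq(LogicalVector mask, IntegerVector dims) {
  const double INF = std::numeric_limits<double>::infinity();
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(N);
  for (R_xlen_t i = 0; i < N; i++) out[i] = mask[i] ? 0.0 : INF;
  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // pass along axis 1
  for (int k3 = 0; k3 < n3; k3++)
    for (int k2 = 0; k2 < n2; k2++) {
      R_xlen_t base = (R_xlen_t)k3 * n1 * n2 + (R_xlen_t)k2 * n1;
      bool any = false;
      for (int i = 0; i < n1; i++) { f[i] = out[base + i]; if (f[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, n1);
      for (int i = 0; i < n1; i++) out[base + i] = d[i];
    }
  // pass along axis 2
  for (int k3 = 0; k3 < n3; k3++)
    for (int k1 = 0; k1 < n1; k1++) {
      R_xlen_t base = (R_xlen_t)k3 * n1 * n2 + k1;
      bool any = false;
      for (int i = 0; i < n2; i++) { f[i] = out[base + (R_xlen_t)i * n1]; if (f[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, n2);
      for (int i = 0; i < n2; i++) out[base + (R_xlen_t)i * n1] = d[i];
    }
  // pass along axis 3
  R_xlen_t plane = (R_xlen_t)n1 * n2;
  for (int k2 = 0; k2 < n2; k2++)
    for (int k1 = 0; k1 < n1; k1++) {
      R_xlen_t base = (R_xlen_t)k2 * n1 + k1;
      bool any = false;
      for (int i = 0; i < n3; i++) { f[i] = out[base + i * plane]; if (f[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, n3);
      for (int i = 0; i < n3; i++) out[base + i * plane] = d[i];
    }
  return out;
}

// Brute-force nearest neighbour: for each query row, index (1-based) and
// squared distance of the nearest reference row.
// [[Rcpp::export]]
List nn_brute(NumericMatrix query, NumericMatrix ref) {
  int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector d2(nq);
  for (int i = 0; i < nq; i++) {
    double best = std::numeric_limits<double>::infinity();
    int bj = 0;
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    for (int j = 0; j < nr; j++) {
      double dx = qx - ref(j, 0), dy = qy - ref(j, 1), dz = qz - ref(j, 2);
      double dd = dx * dx + dy * dy + dz * dz;
      if (dd < best) { best = dd; bj = j; }
    }
    idx[i] = bj + 1;
    d2[i] = best;
  }
  return List::create(_["idx"] = idx, _["d2"] = d2);
}
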