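// Compiled kernels for the whole-mesh estimation passes: per-triangle Dijkstra
// geodesic neighborhoods on the surface graph, normal-vote and curvature-vote
// accumulation, and SSVV line-mesh intersection sampling. Inner loops use plain
// scalar arithmetic (no small-matrix temporaries); Armadillo is used only for
// the per-vertex 3x3 eigen-decomposition. The per-triangle R functions
// (normal_vote, normal_curvature, ssvv_tensor, ...) implement the same
// operations and are cross-checked against these kernels in the tests.

#include <RcppArmadillo.h>
#include <queue>
#include <vector>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double DEG_AREA = 1e-12;

struct Adj {
  std::vector<int> head;
  std::vector<int> to;
  std::vector<double> w;
};

static Adj build_adj(int n, const IntegerVector& ei, const IntegerVector& ej,
                     const NumericVector& ew) {
  Adj a;
  std::vector<int> deg(n, 0);
  int m = ei.size();
  for (int k = 0; k < m; ++k) { deg[ei[k]]++; deg[ej[k]]++; }
  a.head.assign(n + 1, 0);
  for (int v = 0; v < n; ++v) a.head[v + 1] = a.head[v] + deg[v];
  a.to.assign(a.head[n], 0);
  a.w.assign(a.head[n], 0.0);
  std::vector<int> fill(n, 0);
  for (int k = 0; k < m; ++k) {
    int u = ei[k], v = ej[k];
    a.to[a.head[u] + fill[u]] = v; a.w[a.head[u] + fill[u]] = ew[k]; fill[u]++;
    a.to[a.head[v] + fill[v]] = u; a.w[a.head[v] + fill[v]] = ew[k]; fill[v]++;
  }
  return a;
}

// single-source Dijkstra truncated at cutoff; appends (vertex, dist) pairs
static void dijkstra_cutoff(const Adj& adj, int src, double cutoff,
                            std::vector<int>& out_v,
                            std::vector<double>& out_d,
                            std::vector<double>& dist,
                            std::vector<int>& touched) {
  out_v.clear(); out_d.clear();
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[src] = 0.0; touched.push_back(src);
  pq.push(QE(0.0, src));
  while (!pq.empty()) {
    double d = pq.top().first; int u = pq.top().second; pq.pop();
    if (d > dist[u]) continue;
    if (u != src) { out_v.push_back(u); out_d.push_back(d); }
    for (int k = adj.head[u]; k < adj.head[u + 1]; ++k) {
      int v = adj.to[k];
      double nd = d + adj.w[k];
      if (nd < dist[v] && nd <= cutoff) {
        if (dist[v] == R_PosInf && v != src) touched.push_back(v);
        dist[v] = nd;
        pq.push(QE(nd, v));
      }
    }
  }
  for (size_t k = 0; k < touched.size(); ++k) dist[touched[k]] = R_PosInf;
  touched.clear();
}

// [[Rcpp::export(rng = false)]]
List cpp_vv_normals(NumericMatrix centroids, NumericMatrix normals,
                    NumericVector areas, IntegerVector ei, IntegerVector ej,
                    NumericVector ew, double gmax, double sigma, double amax) {
  int n = centroids.nrow();
  Adj adj = build_adj(n, ei, ej, ew);
  NumericMatrix out(n, 3);
  LogicalVector isolated(n);
  const double* cx = &centroids(0, 0);
  const double* cy = &centroids(0, 1);
  const double* cz = &centroids(0, 2);
  const double* nx = &normals(0, 0);
  const double* ny = &normals(0, 1);
  const double* nz = &normals(0, 2);
  std::vector<int> nb; std::vector<double> nd;
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> touched;
  arma::mat33 V;
  arma::vec eval; arma::mat evec;
  for (int v = 0; v < n; ++v) {
    dijkstra_cutoff(adj, v, gmax, nb, nd, dist, touched);
    V.zeros();
    bool any = false;
    double vx = cx[v], vy = cy[v], vz = cz[v];
    for (size_t k = 0; k < nb.size(); ++k) {
      int u = nb[k];
      if (areas[u] <= DEG_AREA) continue;
      double dx = cx[u] - vx, dy = cy[u] - vy, dz = cz[u] - vz;
      double len = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (len < 1e-12) continue;
      dx /= len; dy /= len; dz /= len;
      double ct = -(nx[u] * dx + ny[u] * dy + nz[u] * dz);
      double ax = nx[u] + 2.0 * ct * dx;
      double ay = ny[u] + 2.0 * ct * dy;
      double az = nz[u] + 2.0 * ct * dz;
      double w = (areas[u] / amax) * std::exp(-nd[k] / sigma);
      V(0, 0) += w * ax * ax; V(0, 1) += w * ax * ay; V(0, 2) += w * ax * az;
      V(1, 1) += w * ay * ay; V(1, 2) += w * ay * az; V(2, 2) += w * az * az;
      any = true;
    }
    if (!any) {
      isolated[v] = true;
      out(v, 0) = nx[v]; out(v, 1) = ny[v]; out(v, 2) = nz[v];
      continue;
    }
    V(1, 0) = V(0, 1); V(2, 0) = V(0, 2); V(2, 1) = V(1, 2);
    arma::eig_sym(eval, evec, arma::mat(V)); // ascending eigenvalues
    double e1x = evec(0, 2), e1y = evec(1, 2), e1z = evec(2, 2);
    if (e1x * nx[v] + e1y * ny[v] + e1z * nz[v] < 0) {
      e1x = -e1x; e1y = -e1y; e1z = -e1z;
    }
    out(v, 0) = e1x; out(v, 1) = e1y; out(v, 2) = e1z;
  }
  return List::create(_["normals"] = out, _["isolated"] = isolated);
}

// variant: 0 = RVV, 1 = AVV, 2 = NVV
// [[Rcpp::export(rng = false)]]
List cpp_curvature_tensors(NumericMatrix centroids, NumericMatrix nvm,
                           NumericVector areas, IntegerVector ei,
                           IntegerVector ej, NumericVector ew, double gmax,
                           double sigma, double amax, int variant) {
  int n = centroids.nrow();
  Adj adj = build_adj(n, ei, ej, ew);
  NumericMatrix tensors(n, 9);
  LogicalVector ok(n);
  const double* cx = &centroids(0, 0);
  const double* cy = &centroids(0, 1);
  const double* cz = &centroids(0, 2);
  const double* nx = &nvm(0, 0);
  const double* ny = &nvm(0, 1);
  const double* nz = &nvm(0, 2);
  std::vector<int> nb; std::vector<double> nd;
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> touched;
  std::vector<double> kap, wv, tvx, tvy, tvz;
  for (int v = 0; v < n; ++v) {
    dijkstra_cutoff(adj, v, gmax, nb, nd, dist, touched);
    kap.clear(); wv.clear(); tvx.clear(); tvy.clear(); tvz.clear();
    double nvx = nx[v], nvy = ny[v], nvz = nz[v];
    double vx = cx[v], vy = cy[v], vz = cz[v];
    for (size_t k = 0; k < nb.size(); ++k) {
      int u = nb[k];
      if (areas[u] <= DEG_AREA) continue;
      double dx = cx[u] - vx, dy = cy[u] - vy, dz = cz[u] - vz;
      double dn = nvx * dx + nvy * dy + nvz * dz;
      double tx = dx - dn * nvx, ty = dy - dn * nvy, tz = dz - dn * nvz;
      double tl = std::sqrt(tx * tx + ty * ty + tz * tz);
      if (tl < 1e-12) continue;
      tx /= tl; ty /= tl; tz /= tl;
      // p = n_v x t
      double px = nvy * tz - nvz * ty;
      double py = nvz * tx - nvx * tz;
      double pz = nvx * ty - nvy * tx;
      double pn = px * nx[u] + py * ny[u] + pz * nz[u];
      double qx = nx[u] - pn * px, qy = ny[u] - pn * py, qz = nz[u] - pn * pz;
      double qn = std::sqrt(qx * qx + qy * qy + qz * qz);
      if (qn < 1e-12) continue;
      double cphi = (nvx * qx + nvy * qy + nvz * qz) / qn;
      if (cphi > 1.0) cphi = 1.0; else if (cphi < -1.0) cphi = -1.0;
      double phi = std::acos(cphi);
      double kabs;
      if (variant == 2) {
        kabs = phi / nd[k];
      } else {
        double chord = std::sqrt(dx * dx + dy * dy + dz * dz);
        kabs = 2.0 * std::sin(phi / 2.0) / chord;
      }
      double sgn = tx * qx + ty * qy + tz * qz;
      double kappa = (sgn > 0 ? -kabs : (sgn < 0 ? kabs : 0.0));
      double w = std::exp(-nd[k] / sigma);
      if (variant == 1) w *= areas[u] / amax;
      kap.push_back(kappa); wv.push_back(w);
      tvx.push_back(tx); tvy.push_back(ty); tvz.push_back(tz);
    }
    if (kap.empty()) continue;
    double sw = 0.0;
    for (size_t k = 0; k < wv.size(); ++k) sw += wv[k];
    if (sw <= 0) continue;
    double B[6] = {0, 0, 0, 0, 0, 0}; // xx xy xz yy yz zz
    for (size_t k = 0; k < wv.size(); ++k) {
      // Sum w_i = 2*pi rescaling and the 1/(2*pi) prefactor cancel to w/sw
      double c = (wv[k] / sw) * kap[k];
      B[0] += c * tvx[k] * tvx[k];
      B[1] += c * tvx[k] * tvy[k];
      B[2] += c * tvx[k] * tvz[k];
      B[3] += c * tvy[k] * tvy[k];
      B[4] += c * tvy[k] * tvz[k];
      B[5] += c * tvz[k] * tvz[k];
    }
    ok[v] = true;
    tensors(v, 0) = B[0]; tensors(v, 1) = B[1]; tensors(v, 2) = B[2];
    tensors(v, 3) = B[1]; tensors(v, 4) = B[3]; tensors(v, 5) = B[4];
    tensors(v, 6) = B[2]; tensors(v, 7) = B[4]; tensors(v, 8) = B[5];
  }
  return List::create(_["tensors"] = tensors, _["ok"] = ok);
}

// [[Rcpp::export(rng = false)]]
List cpp_ssvv_tensors(NumericMatrix vertices, IntegerMatrix faces,
                      NumericMatrix centroids, NumericMatrix nvm,
                      double rh, double max_edge) {
  int n = centroids.nrow();
  std::vector<double> P1(3 * n), E1(3 * n), E2(3 * n);
  for (int t = 0; t < n; ++t) {
    int a = faces(t, 0) - 1, b = faces(t, 1) - 1, c = faces(t, 2) - 1;
    for (int d = 0; d < 3; ++d) {
      P1[3 * t + d] = vertices(a, d);
      E1[3 * t + d] = vertices(b, d) - vertices(a, d);
      E2[3 * t + d] = vertices(c, d) - vertices(a, d);
    }
  }
  const double* cx = &centroids(0, 0);
  const double* cy = &centroids(0, 1);
  const double* cz = &centroids(0, 2);
  const double* nx = &nvm(0, 0);
  const double* ny = &nvm(0, 1);
  const double* nz = &nvm(0, 2);
  double reach2 = (3.0 * rh + 2.0 * max_edge) * (3.0 * rh + 2.0 * max_edge);
  double max_abs = 2.0 * rh;
  NumericMatrix tensors(n, 9);
  LogicalVector ok(n);
  std::vector<int> subset;
  for (int v = 0; v < n; ++v) {
    double vx = cx[v], vy = cy[v], vz = cz[v];
    double nvx = nx[v], nvy = ny[v], nvz = nz[v];
    // deterministic initial tangent: projected global x-axis, fallback y-axis
    double t0x = 1.0 - nvx * nvx, t0y = -nvx * nvy, t0z = -nvx * nvz;
    double t0n = std::sqrt(t0x * t0x + t0y * t0y + t0z * t0z);
    if (t0n < 1e-12) {
      t0x = -nvy * nvx; t0y = 1.0 - nvy * nvy; t0z = -nvy * nvz;
      t0n = std::sqrt(t0x * t0x + t0y * t0y + t0z * t0z);
    }
    t0x /= t0n; t0y /= t0n; t0z /= t0n;
    double u2x = nvy * t0z - nvz * t0y;
    double u2y = nvz * t0x - nvx * t0z;
    double u2z = nvx * t0y - nvy * t0x;

    subset.clear();
    for (int t = 0; t < n; ++t) {
      double dx = cx[t] - vx, dy = cy[t] - vy, dz = cz[t] - vz;
      if (dx * dx + dy * dy + dz * dz <= reach2 && t != v) subset.push_back(t);
    }
    double B[6] = {0, 0, 0, 0, 0, 0};
    int hits = 0;
    for (int k = 0; k < 8; ++k) {
      double ang = k * M_PI / 4.0;
      double tgx = std::cos(ang) * t0x + std::sin(ang) * u2x;
      double tgy = std::cos(ang) * t0y + std::sin(ang) * u2y;
      double tgz = std::cos(ang) * t0z + std::sin(ang) * u2z;
      double ox = vx + rh * tgx, oy = vy + rh * tgy, oz = vz + rh * tgz;
      // Moeller-Trumbore for the full line o + s * n_v over the subset
      double best = 0.0; bool found = false;
      for (size_t si = 0; si < subset.size(); ++si) {
        int tri = subset[si];
        const double* p1 = &P1[3 * tri];
        const double* e1 = &E1[3 * tri];
        const double* e2 = &E2[3 * tri];
        double hx = nvy * e2[2] - nvz * e2[1];
        double hy = nvz * e2[0] - nvx * e2[2];
        double hz = nvx * e2[1] - nvy * e2[0];
        double a = e1[0] * hx + e1[1] * hy + e1[2] * hz;
        if (std::fabs(a) < 1e-12) continue;
        double f = 1.0 / a;
        double spx = ox - p1[0], spy = oy - p1[1], spz = oz - p1[2];
        double u = f * (spx * hx + spy * hy + spz * hz);
        if (u < 0.0 || u > 1.0) continue;
        double qx = spy * e1[2] - spz * e1[1];
        double qy = spz * e1[0] - spx * e1[2];
        double qz = spx * e1[1] - spy * e1[0];
        double vvb = f * (nvx * qx + nvy * qy + nvz * qz);
        if (vvb < 0.0 || u + vvb > 1.0) continue;
        double s = f * (e2[0] * qx + e2[1] * qy + e2[2] * qz);
        if (std::fabs(s) > max_abs) continue;
        if (!found || std::fabs(s) < std::fabs(best)) { best = s; found = true; }
      }
      if (!found) continue;
      double kappa = 2.0 * best / (rh * rh + best * best);
      double c8 = kappa / 8.0;
      B[0] += c8 * tgx * tgx; B[1] += c8 * tgx * tgy; B[2] += c8 * tgx * tgz;
      B[3] += c8 * tgy * tgy; B[4] += c8 * tgy * tgz; B[5] += c8 * tgz * tgz;
      hits++;
    }
    if (hits < 3) continue;
    ok[v] = true;
    tensors(v, 0) = B[0]; tensors(v, 1) = B[1]; tensors(v, 2) = B[2];
    tensors(v, 3) = B[1]; tensors(v, 4) = B[3]; tensors(v, 5) = B[4];
    tensors(v, 6) = B[2]; tensors(v, 7) = B[4]; tensors(v, 8) = B[5];
  }
  return List::create(_["tensors"] = tensors, _["ok"] = ok);
}
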