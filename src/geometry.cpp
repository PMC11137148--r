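#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Closest point on triangle (a,b,c) to p, with barycentric output.
// Ericson, Real-Time Collision Detection, ch. 5.1.5.
static inline void closest_on_triangle(const double* p,
                                       const double* a, const double* b,
                                       const double* c,
                                       double* out, double* bary) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) out[i] = a[i];
    bary[0] = 1.0; bary[1] = 0.0; bary[2] = 0.0;
    return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int i = 0; i < 3; ++i) out[i] = b[i];
    bary[0] = 0.0; bary[1] = 1.0; bary[2] = 0.0;
    return;
  }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = (d1 - d3 != 0.0) ? d1 / (d1 - d3) : 0.0;
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v*ab[i];
    bary[0] = 1.0 - v; bary[1] = v; bary[2] = 0.0;
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    for (int i = 0; i < 3; ++i) out[i] = c[i];
    bary[0] = 0.0; bary[1] = 0.0; bary[2] = 1.0;
    return;
  }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = (d2 - d6 != 0.0) ? d2 / (d2 - d6) : 0.0;
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w*ac[i];
    bary[0] = 1.0 - w; bary[1] = 0.0; bary[2] = w;
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double denom = (d4 - d3) + (d5 - d6);
    double w = denom != 0.0 ? (d4 - d3) / denom : 0.0;
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w*(c[i] - b[i]);
    bary[0] = 0.0; bary[1] = 1.0 - w; bary[2] = w;
    return;
  }
  double denom = va + vb + vc;
  double v = vb / denom, w = vc / denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i]*v + ac[i]*w;
  bary[0] = 1.0 - v - w; bary[1] = v; bary[2] = w;
}

// Exact closest surface point for each query; faces are 1-based triples.
// Brute force over faces with bounding-sphere pruning seeded by the
// nearest vertex, which keeps it fast enough for registration loops.
// [[Rcpp::export]]
List cpp_closest_points(NumericMatrix Q, NumericMatrix V, IntegerMatrix F) {
  const int nq = Q.nrow(), nv = V.nrow(), nf = F.nrow();
  std::vector<double> Vf(3 * nv);
  for (int i = 0; i < nv; ++i) {
    Vf[3*i] = V(i,0); Vf[3*i+1] = V(i,1); Vf[3*i+2] = V(i,2);
  }
  std::vector<int> Ff(3 * nf);
  for (int i = 0; i < nf; ++i) {
    Ff[3*i] = F(i,0)-1; Ff[3*i+1] = F(i,1)-1; Ff[3*i+2] = F(i,2)-1;
  }
  NumericMatrix pts(nq, 3), bary(nq, 3);
  IntegerVector face(nq);
  NumericVector dist(nq);

  // face centroids and bounding radii for pruning
  std::vector<double> cx(nf), cy(nf), cz(nf), rad(nf);
  for (int f = 0; f < nf; ++f) {
    int i0 = Ff[3*f], i1 = Ff[3*f+1], i2 = Ff[3*f+2];
    double mx = (Vf[3*i0]+Vf[3*i1]+Vf[3*i2])/3.0;
    double my = (Vf[3*i0+1]+Vf[3*i1+1]+Vf[3*i2+1])/3.0;
    double mz = (Vf[3*i0+2]+Vf[3*i1+2]+Vf[3*i2+2])/3.0;
    cx[f]=mx; cy[f]=my; cz[f]=mz;
    double r2 = 0.0;
    const int idx[3] = {i0,i1,i2};
    for (int k = 0; k < 3; ++k) {
      double dx=Vf[3*idx[k]]-mx, dy=Vf[3*idx[k]+1]-my, dz=Vf[3*idx[k]+2]-mz;
      double d2 = dx*dx+dy*dy+dz*dz;
      if (d2 > r2) r2 = d2;
    }
    rad[f] = std::sqrt(r2);
  }

  for (int q = 0; q < nq; ++q) {
    double p[3] = {Q(q,0), Q(q,1), Q(q,2)};
    // seed with nearest vertex
    double best2 = std::numeric_limits<double>::infinity();
    for (int v = 0; v < nv; ++v) {
      double dx=Vf[3*v]-p[0], dy=Vf[3*v+1]-p[1], dz=Vf[3*v+2]-p[2];
      double d2 = dx*dx+dy*dy+dz*dz;
      if (d2 < best2) best2 = d2;
    }
    double bestd = std::sqrt(best2);
    int bestf = -1;
    double bestpt[3] = {0,0,0}, bestb[3] = {1,0,0};
    for (int f = 0; f < nf; ++f) {
      double dx=cx[f]-p[0], dy=cy[f]-p[1], dz=cz[f]-p[2];
      double dc = std::sqrt(dx*dx+dy*dy+dz*dz);
      if (dc - rad[f] > bestd) continue;
      int i0 = Ff[3*f], i1 = Ff[3*f+1], i2 = Ff[3*f+2];
      double a[3] = {Vf[3*i0],Vf[3*i0+1],Vf[3*i0+2]};
      double b[3] = {Vf[3*i1],Vf[3*i1+1],Vf[3*i1+2]};
      double c[3] = {Vf[3*i2],Vf[3*i2+1],Vf[3*i2+2]};
      double out[3], bc[3];
      closest_on_triangle(p, a, b, c, out, bc);
      double ex=out[0]-p[0], ey=out[1]-p[1], ez=out[2]-p[2];
      double d = std::sqrt(ex*ex+ey*ey+ez*ez);
      if (d < bestd || bestf < 0) {
        bestd = d; bestf = f;
        for (int i = 0; i < 3; ++i) { bestpt[i] = out[i]; bestb[i] = bc[i]; }
      }
    }
    pts(q,0)=bestpt[0]; pts(q,1)=bestpt[1]; pts(q,2)=bestpt[2];
    bary(q,0)=bestb[0]; bary(q,1)=bestb[1]; bary(q,2)=bestb[2];
    face[q] = bestf + 1;
    dist[q] = bestd;
  }
  return List::create(_["point"]=pts, _["face"]=face,
                      _["bary"]=bary, _["distance"]=dist);
}

// Nearest mesh vertex per query point: index (1-based) and distance.
// [[Rcpp::export]]
List cpp_nearest_vertex(NumericMatrix Q, NumericMatrix V) {
  const int nq = Q.nrow(), nv = V.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int q = 0; q < nq; ++q) {
    double best2 = std::numeric_limits<double>::infinity();
    int besti = 0;
    for (int v = 0; v < nv; ++v) {
      double dx=V(v,0)-Q(q,0), dy=V(v,1)-Q(q,1), dz=V(v,2)-Q(q,2);
      double d2 = dx*dx+dy*dy+dz*dz;
      if (d2 < best2) { best2 = d2; besti = v; }
    }
    idx[q] = besti + 1;
    dist[q] = std::sqrt(best2);
  }
  return List::create(_["index"]=idx, _["distance"]=dist);
}

// k nearest rows of V for each query, small k; returns 1-based indices.
// [[Rcpp::export]]
List cpp_knn(NumericMatrix Q, NumericMatrix V, int k) {
  const int nq = Q.nrow(), nv = V.nrow();
  if (k > nv) k = nv;
  IntegerMatrix idx(nq, k);
  NumericMatrix dist(nq, k);
  std::vector<double> bd(k);
  std::vector<int> bi(k);
  for (int q = 0; q < nq; ++q) {
    for (int j = 0; j < k; ++j) { bd[j] = std::numeric_limits<double>::infinity(); bi[j] = 0; }
    for (int v = 0; v < nv; ++v) {
      double dx=V(v,0)-Q(q,0), dy=V(v,1)-Q(q,1), dz=V(v,2)-Q(q,2);
      double d2 = dx*dx+dy*dy+dz*dz;
      if (d2 < bd[k-1]) {
        int j = k - 1;
        while (j > 0 && bd[j-1] > d2) { bd[j]=bd[j-1]; bi[j]=bi[j-1]; --j; }
        bd[j] = d2; bi[j] = v;
      }
    }
    for (int j = 0; j < k; ++j) { idx(q,j) = bi[j]+1; dist(q,j) = std::sqrt(bd[j]); }
  }
  return List::create(_["index"]=idx, _["distance"]=dist);
}

// Distance to first ray-surface hit along +/- dir (nearer of the two),
// censored at max_range. Moller-Trumbore with negative t allowed.
// Faces whose bounding sphere lies beyond max_range are culled.
// [[Rcpp::export]]
List cpp_ray_distance(NumericMatrix O, NumericMatrix D,
                      NumericMatrix V, IntegerMatrix F, double max_range) {
  const int nr = O.nrow(), nf = F.nrow();
  const int nv = V.nrow();
  std::vector<double> Vf(3 * nv);
  for (int i = 0; i < nv; ++i) {
    Vf[3*i] = V(i,0); Vf[3*i+1] = V(i,1); Vf[3*i+2] = V(i,2);
  }
  std::vector<int> Ff(3 * nf);
  for (int i = 0; i < nf; ++i) {
    Ff[3*i] = F(i,0)-1; Ff[3*i+1] = F(i,1)-1; Ff[3*i+2] = F(i,2)-1;
  }
  NumericVector dist(nr), tsig(nr);
  IntegerVector hface(nr);
  LogicalVector hit(nr);
  const double eps = 1e-12;
  // face centroids and radii for range culling
  std::vector<double> cx(nf), cy(nf), cz(nf), rad(nf);
  for (int f = 0; f < nf; ++f) {
    int i0 = Ff[3*f], i1 = Ff[3*f+1], i2 = Ff[3*f+2];
    double mx = (Vf[3*i0]+Vf[3*i1]+Vf[3*i2])/3.0;
    double my = (Vf[3*i0+1]+Vf[3*i1+1]+Vf[3*i2+1])/3.0;
    double mz = (Vf[3*i0+2]+Vf[3*i1+2]+Vf[3*i2+2])/3.0;
    cx[f]=mx; cy[f]=my; cz[f]=mz;
    double r2 = 0.0;
    const int idx[3] = {i0,i1,i2};
    for (int k = 0; k < 3; ++k) {
      double dx=Vf[3*idx[k]]-mx, dy=Vf[3*idx[k]+1]-my, dz=Vf[3*idx[k]+2]-mz;
      double d2 = dx*dx+dy*dy+dz*dz;
      if (d2 > r2) r2 = d2;
    }
    rad[f] = std::sqrt(r2);
  }
  for (int r = 0; r < nr; ++r) {
    double o[3] = {O(r,0), O(r,1), O(r,2)};
    double d[3] = {D(r,0), D(r,1), D(r,2)};
    double best = max_range, best_t = NA_REAL;
    int best_f = 0;
    bool found = false;
    for (int f = 0; f < nf; ++f) {
      double ox=cx[f]-o[0], oy=cy[f]-o[1], oz=cz[f]-o[2];
      if (ox*ox+oy*oy+oz*oz > (best+rad[f])*(best+rad[f])) continue;
      // perpendicular distance from the ray line to the face bound
      double px = d[1]*oz - d[2]*oy;
      double py = d[2]*ox - d[0]*oz;
      double pz = d[0]*oy - d[1]*ox;
      double dd = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
      if (px*px+py*py+pz*pz > rad[f]*rad[f]*dd) continue;
      int i0 = Ff[3*f], i1 = Ff[3*f+1], i2 = Ff[3*f+2];
      double e1[3], e2[3];
      for (int i = 0; i < 3; ++i) {
        e1[i] = Vf[3*i1+i] - Vf[3*i0+i];
        e2[i] = Vf[3*i2+i] - Vf[3*i0+i];
      }
      double pv[3] = {d[1]*e2[2]-d[2]*e2[1],
                      d[2]*e2[0]-d[0]*e2[2],
                      d[0]*e2[1]-d[1]*e2[0]};
      double det = e1[0]*pv[0]+e1[1]*pv[1]+e1[2]*pv[2];
      if (std::fabs(det) < eps) continue;
      double inv = 1.0/det;
      double tv[3] = {o[0]-Vf[3*i0], o[1]-Vf[3*i0+1], o[2]-Vf[3*i0+2]};
      double u = (tv[0]*pv[0]+tv[1]*pv[1]+tv[2]*pv[2])*inv;
      if (u < -1e-9 || u > 1.0+1e-9) continue;
      double qv[3] = {tv[1]*e1[2]-tv[2]*e1[1],
                      tv[2]*e1[0]-tv[0]*e1[2],
                      tv[0]*e1[1]-tv[1]*e1[0]};
      double v = (d[0]*qv[0]+d[1]*qv[1]+d[2]*qv[2])*inv;
      if (v < -1e-9 || u + v > 1.0+1e-9) continue;
      double t = (e2[0]*qv[0]+e2[1]*qv[1]+e2[2]*qv[2])*inv;
      double at = std::fabs(t);
      if (at < best) { best = at; best_t = t; best_f = f + 1; found = true; }
    }
    dist[r] = best;
    tsig[r] = best_t;
    hface[r] = found ? best_f : NA_INTEGER;
    hit[r] = found;
  }
  return List::create(_["distance"]=dist, _["t"]=tsig, _["hit"]=hit,
                      _["face"]=hface);
}

// Repeated neighbourhood averaging of a weighted field over a vertex
// graph given in flat CSR-like form (0-based offsets, 1-based
// neighbour ids including self). num is n x 3, den length n.
// [[Rcpp::export]]
List cpp_diffuse_field(NumericMatrix num, NumericVector den,
                       IntegerVector offs, IntegerVector nbr, int passes) {
  const int n = num.nrow();
  NumericMatrix a(clone(num));
  NumericVector b(clone(den));
  NumericMatrix a2(n, 3);
  NumericVector b2(n);
  for (int p = 0; p < passes; ++p) {
    for (int i = 0; i < n; ++i) {
      double s0 = 0, s1 = 0, s2 = 0, sw = 0;
      int from = offs[i], to = offs[i+1];
      for (int j = from; j < to; ++j) {
        int v = nbr[j] - 1;
        s0 += a(v,0); s1 += a(v,1); s2 += a(v,2); sw += b[v];
      }
      double inv = 1.0 / (to - from);
      a2(i,0) = s0*inv; a2(i,1) = s1*inv; a2(i,2) = s2*inv; b2[i] = sw*inv;
    }
    std::copy(a2.begin(), a2.end(), a.begin());
    std::copy(b2.begin(), b2.end(), b.begin());
  }
  return List::create(_["num"]=a, _["den"]=b);
}
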