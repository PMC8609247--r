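// Hot loops for the viewing-angle searches: shifted-grid Shannon entropy and
// convex-hull overlap, evaluated at every sampled direction. Kept in C++
// because the exhaustive 2048-direction scan over all population pairs is the
// dominant cost of the whole analysis.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct GridEval {
  double si;
  double fx, fy;
  int shift_index; // 0-based, row-major over (ix, iy)
};

// Total Shannon index over a sector grid with origin shifted down by
// (fx, fy) sector widths. Bins are half-open; with zero shift the points on
// the max edge are clamped into the last sector, with a positive shift one
// extra sector row/column catches them.
double grid_total_si(const std::vector<double>& u, const std::vector<double>& v,
                     const std::vector<int>& lab,
                     double minu, double minv, double wu, double wv,
                     int sx, int sy, double fx, double fy,
                     std::vector<int>& ca, std::vector<int>& cb) {
  const int nbx = sx + 1, nby = sy + 1;
  const int maxbx = (fx > 0.0) ? sx : sx - 1;
  const int maxby = (fy > 0.0) ? sy : sy - 1;
  std::fill(ca.begin(), ca.end(), 0);
  std::fill(cb.begin(), cb.end(), 0);
  const double ou = minu - fx * wu, ov = minv - fy * wv;
  const size_t n = u.size();
  for (size_t i = 0; i < n; ++i) {
    int ix = (int)std::floor((u[i] - ou) / wu);
    int iy = (int)std::floor((v[i] - ov) / wv);
    if (ix < 0) ix = 0;
    if (iy < 0) iy = 0;
    if (ix > maxbx) ix = maxbx;
    if (iy > maxby) iy = maxby;
    const int k = iy * nbx + ix;
    if (lab[i] == 0) ++ca[k]; else ++cb[k];
  }
  double total = 0.0;
  const int nk = nbx * nby;
  for (int k = 0; k < nk; ++k) {
    const int a = ca[k], b = cb[k];
    if (a == 0 || b == 0) continue; // pure or empty sector: SI = 0
    const double tot = (double)(a + b);
    const double pa = a / tot, pb = b / tot;
    total += -(pa * std::log(pa) + pb * std::log(pb));
  }
  return total;
}

// Minimum total SI over the n x n lattice of shift fractions (k/n), row-major
// order over (ix, iy); ties keep the first-evaluated shift.
GridEval shift_scan(const std::vector<double>& u, const std::vector<double>& v,
                    const std::vector<int>& lab, int sx, int sy, int nshift,
                    std::vector<int>& ca, std::vector<int>& cb) {
  double minu = u[0], maxu = u[0], minv = v[0], maxv = v[0];
  for (size_t i = 1; i < u.size(); ++i) {
    if (u[i] < minu) minu = u[i];
    if (u[i] > maxu) maxu = u[i];
    if (v[i] < minv) minv = v[i];
    if (v[i] > maxv) maxv = v[i];
  }
  double ru = maxu - minu, rv = maxv - minv;
  if (ru <= 0) { ru = 1e-9; minu -= 5e-10; } // degenerate box inflation
  if (rv <= 0) { rv = 1e-9; minv -= 5e-10; }
  const double wu = ru / sx, wv = rv / sy;
  GridEval best; best.si = R_PosInf; best.fx = 0; best.fy = 0; best.shift_index = 0;
  int idx = 0;
  for (int ix = 0; ix < nshift; ++ix) {
    const double fx = (double)ix / nshift;
    for (int iy = 0; iy < nshift; ++iy, ++idx) {
      const double fy = (double)iy / nshift;
      const double si = grid_total_si(u, v, lab, minu, minv, wu, wv,
                                      sx, sy, fx, fy, ca, cb);
      if (si < best.si) { best.si = si; best.fx = fx; best.fy = fy; best.shift_index = idx; }
    }
  }
  return best;
}

void project_points(const NumericMatrix& pts, const NumericMatrix& rot, int ang,
                    std::vector<double>& u, std::vector<double>& v) {
  // rot row `ang` holds the 3x3 rotation row-major; view coords = R * p,
  // the first two rows span the viewing plane.
  const double r11 = rot(ang, 0), r12 = rot(ang, 1), r13 = rot(ang, 2);
  const double r21 = rot(ang, 3), r22 = rot(ang, 4), r23 = rot(ang, 5);
  const int n = pts.nrow();
  for (int i = 0; i < n; ++i) {
    const double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    u[i] = r11 * x + r12 * y + r13 * z;
    v[i] = r21 * x + r22 * y + r23 * z;
  }
}

double cross3(double ox, double oy, double ax, double ay, double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

void quickhull_rec(const std::vector<double>& x, const std::vector<double>& y,
                   const std::vector<int>& set, int p, int q,
                   std::vector<int>& out) {
  if (set.empty()) return;
  // farthest point from line p->q; first index wins ties
  double bestd = -1.0; int c = -1;
  for (int i : set) {
    const double d = cross3(x[p], y[p], x[q], y[q], x[i], y[i]);
    if (d > bestd) { bestd = d; c = i; }
  }
  std::vector<int> left_pc, left_cq;
  for (int i : set) {
    if (i == c) continue;
    if (cross3(x[p], y[p], x[c], y[c], x[i], y[i]) > 0) left_pc.push_back(i);
    else if (cross3(x[c], y[c], x[q], y[q], x[i], y[i]) > 0) left_cq.push_back(i);
  }
  quickhull_rec(x, y, left_pc, p, c, out);
  out.push_back(c);
  quickhull_rec(x, y, left_cq, c, q, out);
}

// Quickhull on raw coordinates; returns 0-based vertex indices in CCW order.
// Collinear boundary points are dropped; degenerate inputs give 1 or 2 points.
std::vector<int> quickhull(const std::vector<double>& x, const std::vector<double>& y) {
  const int n = (int)x.size();
  int lo = 0, hi = 0;
  for (int i = 1; i < n; ++i) {
    if (x[i] < x[lo] || (x[i] == x[lo] && y[i] < y[lo])) lo = i;
    if (x[i] > x[hi] || (x[i] == x[hi] && y[i] > y[hi])) hi = i;
  }
  if (lo == hi) return std::vector<int>(1, lo); // all points identical
  std::vector<int> upper, lower;
  for (int i = 0; i < n; ++i) {
    if (i == lo || i == hi) continue;
    const double d = cross3(x[lo], y[lo], x[hi], y[hi], x[i], y[i]);
    if (d > 0) upper.push_back(i);
    else if (d < 0) lower.push_back(i);
  }
  // upper = left of lo->hi, lower = left of hi->lo; each chain is built with
  // the matching directed line so quickhull_rec's "left of" logic holds.
  std::vector<int> out;
  out.push_back(lo);
  quickhull_rec(x, y, upper, lo, hi, out);
  out.push_back(hi);
  quickhull_rec(x, y, lower, hi, lo, out);
  return out;
}

double shoelace(const std::vector<double>& x, const std::vector<double>& y) {
  const int n = (int)x.size();
  if (n < 3) return 0.0;
  double a = 0.0;
  for (int i = 0; i < n; ++i) {
    const int j = (i + 1) % n;
    a += x[i] * y[j] - x[j] * y[i];
  }
  return 0.5 * a;
}

// Sutherland-Hodgman clip of subject polygon by convex CCW clip polygon.
double convex_intersection_area(std::vector<double> sx_, std::vector<double> sy_,
                                const std::vector<double>& cx, const std::vector<double>& cy) {
  if (sx_.size() < 3 || cx.size() < 3) return 0.0;
  const int nc = (int)cx.size();
  for (int e = 0; e < nc; ++e) {
    const int f = (e + 1) % nc;
    const double ex = cx[e], ey = cy[e], fx2 = cx[f], fy2 = cy[f];
    std::vector<double> nx, ny;
    const int ns = (int)sx_.size();
    if (ns == 0) break;
    for (int i = 0; i < ns; ++i) {
      const int j = (i + 1) % ns;
      const double d1 = cross3(ex, ey, fx2, fy2, sx_[i], sy_[i]);
      const double d2 = cross3(ex, ey, fx2, fy2, sx_[j], sy_[j]);
      if (d1 >= 0) { nx.push_back(sx_[i]); ny.push_back(sy_[i]); }
      if ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) {
        const double t = d1 / (d1 - d2);
        nx.push_back(sx_[i] + t * (sx_[j] - sx_[i]));
        ny.push_back(sy_[i] + t * (sy_[j] - sy_[i]));
      }
    }
    sx_.swap(nx); sy_.swap(ny);
  }
  double a = shoelace(sx_, sy_);
  return a > 0 ? a : 0.0;
}

void hull_coords(const std::vector<double>& x, const std::vector<double>& y,
                 std::vector<double>& hx, std::vector<double>& hy) {
  std::vector<int> idx = quickhull(x, y);
  hx.clear(); hy.clear();
  for (int i : idx) { hx.push_back(x[i]); hy.push_back(y[i]); }
  if (shoelace(hx, hy) < 0) { // ensure CCW
    std::reverse(hx.begin(), hx.end());
    std::reverse(hy.begin(), hy.end());
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_entropy_shift_scan(NumericMatrix pts2d, IntegerVector lab,
                            int sx, int sy, int nshift) {
  const int n = pts2d.nrow();
  std::vector<double> u(n), v(n);
  std::vector<int> l(n);
  for (int i = 0; i < n; ++i) { u[i] = pts2d(i, 0); v[i] = pts2d(i, 1); l[i] = lab[i]; }
  std::vector<int> ca((sx + 1) * (sy + 1)), cb((sx + 1) * (sy + 1));
  GridEval g = shift_scan(u, v, l, sx, sy, nshift, ca, cb);
  return List::create(_["total_si"] = g.si, _["fx"] = g.fx, _["fy"] = g.fy,
                      _["shift_index"] = g.shift_index + 1);
}

// [[Rcpp::export]]
double cpp_grid_entropy(NumericMatrix pts2d, IntegerVector lab,
                        int sx, int sy, double fx, double fy) {
  const int n = pts2d.nrow();
  std::vector<double> u(n), v(n);
  std::vector<int> l(n);
  double minu = R_PosInf, maxu = R_NegInf, minv = R_PosInf, maxv = R_NegInf;
  for (int i = 0; i < n; ++i) {
    u[i] = pts2d(i, 0); v[i] = pts2d(i, 1); l[i] = lab[i];
    minu = std::min(minu, u[i]); maxu = std::max(maxu, u[i]);
    minv = std::min(minv, v[i]); maxv = std::max(maxv, v[i]);
  }
  double ru = maxu - minu, rv = maxv - minv;
  if (ru <= 0) { ru = 1e-9; minu -= 5e-10; }
  if (rv <= 0) { rv = 1e-9; minv -= 5e-10; }
  std::vector<int> ca((sx + 1) * (sy + 1)), cb((sx + 1) * (sy + 1));
  return grid_total_si(u, v, l, minu, minv, ru / sx, rv / sy, sx, sy, fx, fy, ca, cb);
}

// [[Rcpp::export]]
List cpp_entropy_angle_scan(NumericMatrix pts3d, IntegerVector lab,
                            NumericMatrix rot, int sx, int sy, int nshift) {
  const int n = pts3d.nrow(), m = rot.nrow();
  std::vector<double> u(n), v(n);
  std::vector<int> l(n);
  for (int i = 0; i < n; ++i) l[i] = lab[i];
  std::vector<int> ca((sx + 1) * (sy + 1)), cb((sx + 1) * (sy + 1));
  double best = R_PosInf; int besta = 0; GridEval bestg; bestg.fx = 0; bestg.fy = 0;
  NumericVector per_angle(m);
  for (int a = 0; a < m; ++a) {
    project_points(pts3d, rot, a, u, v);
    GridEval g = shift_scan(u, v, l, sx, sy, nshift, ca, cb);
    per_angle[a] = g.si;
    if (g.si < best) { best = g.si; besta = a; bestg = g; }
  }
  return List::create(_["total_si"] = best, _["angle_index"] = besta + 1,
                      _["fx"] = bestg.fx, _["fy"] = bestg.fy,
                      _["per_angle"] = per_angle);
}

// [[Rcpp::export]]
IntegerVector cpp_quickhull(NumericMatrix pts) {
  const int n = pts.nrow();
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = pts(i, 0); y[i] = pts(i, 1); }
  std::vector<double> hx, hy;
  std::vector<int> idx = quickhull(x, y);
  // orient CCW on indices
  hx.clear(); hy.clear();
  for (int i : idx) { hx.push_back(x[i]); hy.push_back(y[i]); }
  if (shoelace(hx, hy) < 0) std::reverse(idx.begin(), idx.end());
  IntegerVector out((int)idx.size());
  for (size_t i = 0; i < idx.size(); ++i) out[i] = idx[i] + 1;
  return out;
}

// [[Rcpp::export]]
double cpp_convex_intersection_area(NumericMatrix p, NumericMatrix q) {
  std::vector<double> px(p.nrow()), py(p.nrow()), qx(q.nrow()), qy(q.nrow());
  for (int i = 0; i < p.nrow(); ++i) { px[i] = p(i, 0); py[i] = p(i, 1); }
  for (int i = 0; i < q.nrow(); ++i) { qx[i] = q(i, 0); qy[i] = q(i, 1); }
  double a = convex_intersection_area(px, py, qx, qy);
  const double cap = std::min(std::fabs(shoelace(px, py)), std::fabs(shoelace(qx, qy)));
  return std::min(a, cap);
}

// [[Rcpp::export]]
List cpp_hull_overlap_2d(NumericMatrix A, NumericMatrix B) {
  std::vector<double> ax(A.nrow()), ay(A.nrow()), bx(B.nrow()), by(B.nrow());
  for (int i = 0; i < A.nrow(); ++i) { ax[i] = A(i, 0); ay[i] = A(i, 1); }
  for (int i = 0; i < B.nrow(); ++i) { bx[i] = B(i, 0); by[i] = B(i, 1); }
  std::vector<double> hax, hay, hbx, hby;
  hull_coords(ax, ay, hax, hay);
  hull_coords(bx, by, hbx, hby);
  const double aa = shoelace(hax, hay), ab = shoelace(hbx, hby);
  const double mn = std::min(aa, ab);
  double inter = 0.0, pct = 0.0;
  bool degen = (mn <= 0.0);
  if (!degen) {
    inter = convex_intersection_area(hax, hay, hbx, hby);
    if (inter > mn) inter = mn;
    pct = 100.0 * inter / mn;
  }
  return List::create(_["overlap_percent"] = pct, _["intersection_area"] = inter,
                      _["area_a"] = aa, _["area_b"] = ab, _["degenerate"] = degen);
}

// [[Rcpp::export]]
List cpp_hull_angle_scan(NumericMatrix A3, NumericMatrix B3, NumericMatrix rot) {
  const int na = A3.nrow(), nb = B3.nrow(), m = rot.nrow();
  std::vector<double> au(na), av(na), bu(nb), bv(nb);
  std::vector<double> hax, hay, hbx, hby;
  double best = R_PosInf; int besta = 0;
  double binter = 0, baa = 0, bab = 0; bool bdeg = false;
  NumericVector per_angle(m);
  for (int a = 0; a < m; ++a) {
    project_points(A3, rot, a, au, av);
    project_points(B3, rot, a, bu, bv);
    hull_coords(au, av, hax, hay);
    hull_coords(bu, bv, hbx, hby);
    const double aa = shoelace(hax, hay), ab = shoelace(hbx, hby);
    const double mn = std::min(aa, ab);
    double pct = 0.0, inter = 0.0;
    bool degen = (mn <= 0.0);
    if (!degen) {
      inter = convex_intersection_area(hax, hay, hbx, hby);
      if (inter > mn) inter = mn;
      pct = 100.0 * inter / mn;
    }
    per_angle[a] = pct;
    if (pct < best) {
      best = pct; besta = a; binter = inter; baa = aa; bab = ab; bdeg = degen;
    }
  }
  return List::create(_["overlap_percent"] = best, _["angle_index"] = besta + 1,
                      _["intersection_area"] = binter, _["area_a"] = baa,
                      _["area_b"] = bab, _["degenerate"] = bdeg,
                      _["per_angle"] = per_angle);
}
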