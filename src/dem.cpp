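// Core discrete-element routines: elliptical contact geometry, linear
// spring-dashpot forces with Coulomb-capped tangential springs, the
// panic-behaviour decision layer, and the time-integration loop.
//
// Conventions: global 2D Cartesian coordinates in meters, y increasing
// toward the exit; angles in radians, counterclockwise positive; contact
// normals point from the other body toward the subject body.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Ell {
  double cx, cy, phi, a, b;
  double cphi, sphi;  // cached cos/sin of the orientation
};

inline Ell makeEll(double cx, double cy, double phi, double a, double b) {
  Ell E;
  E.cx = cx; E.cy = cy; E.phi = phi; E.a = a; E.b = b;
  E.cphi = std::cos(phi); E.sphi = std::sin(phi);
  return E;
}

inline double implicitVal(const Ell& E, double px, double py) {
  double c = E.cphi, s = E.sphi;
  double dx = px - E.cx, dy = py - E.cy;
  double u = (dx * c + dy * s) / E.a;
  double v = (-dx * s + dy * c) / E.b;
  return u * u + v * v - 1.0;
}

inline void boundaryPt(const Ell& E, double t, double& px, double& py) {
  double c = E.cphi, s = E.sphi;
  double bx = E.a * std::cos(t), by = E.b * std::sin(t);
  px = E.cx + bx * c - by * s;
  py = E.cy + bx * s + by * c;
}

// Intersection of the line M + s*u with the ellipse boundary; returns the
// two parameters s1 <= s2, or false when the line misses the ellipse.
bool lineInterval(const Ell& E, double mx, double my, double ux, double uy,
                  double& s1, double& s2) {
  double c = E.cphi, s = E.sphi;
  double dx = mx - E.cx, dy = my - E.cy;
  double qx = (dx * c + dy * s) / E.a, qy = (-dx * s + dy * c) / E.b;
  double ex = (ux * c + uy * s) / E.a, ey = (-ux * s + uy * c) / E.b;
  double A = ex * ex + ey * ey;
  double B = 2.0 * (qx * ex + qy * ey);
  double C = qx * qx + qy * qy - 1.0;
  if (A <= 0.0) return false;
  double disc = B * B - 4.0 * A * C;
  if (disc < 0.0) return false;
  double rt = std::sqrt(disc);
  s1 = (-B - rt) / (2.0 * A);
  s2 = (-B + rt) / (2.0 * A);
  return true;
}

// Crossing function: value of ellipse j's implicit form along i's boundary.
inline double crossFun(const Ell& Ei, const Ell& Ej, double t) {
  double px, py;
  boundaryPt(Ei, t, px, py);
  return implicitVal(Ej, px, py);
}

double bisectRoot(const Ell& Ei, const Ell& Ej, double lo, double hi,
                  double flo) {
  for (int it = 0; it < 34; ++it) {
    double mid = 0.5 * (lo + hi);
    double fm = crossFun(Ei, Ej, mid);
    if ((fm < 0.0) == (flo < 0.0)) {
      lo = mid;
      flo = fm;
    } else {
      hi = mid;
    }
  }
  return 0.5 * (lo + hi);
}

// Find parameters on ellipse i's boundary where it crosses ellipse j's
// boundary. Returns number of crossings found (capped at 8).
int boundaryCrossings(const Ell& Ei, const Ell& Ej, double* ts) {
  const int nS = 64;
  double g[nS + 1];
  const double twopi = 2.0 * M_PI;
  static double cosT[nS + 1], sinT[nS + 1];
  static bool tabInit = false;
  if (!tabInit) {
    for (int k = 0; k <= nS; ++k) {
      cosT[k] = std::cos(twopi * k / nS);
      sinT[k] = std::sin(twopi * k / nS);
    }
    tabInit = true;
  }
  for (int k = 0; k <= nS; ++k) {
    double bx = Ei.a * cosT[k], by = Ei.b * sinT[k];
    double qx = Ei.cx + bx * Ei.cphi - by * Ei.sphi;
    double qy = Ei.cy + bx * Ei.sphi + by * Ei.cphi;
    g[k] = implicitVal(Ej, qx, qy);
  }
  int nt = 0;
  int minIdx = 0;
  for (int k = 0; k < nS && nt < 8; ++k) {
    if (g[k] < g[minIdx]) minIdx = k;
    if ((g[k] < 0.0) != (g[k + 1] < 0.0)) {
      double lo = twopi * k / nS, hi = twopi * (k + 1) / nS;
      ts[nt++] = bisectRoot(Ei, Ej, lo, hi, g[k]);
    }
  }
  if (nt == 0 && g[minIdx] > 0.0) {
    // A shallow graze can dip below zero between samples: refine the local
    // minimum by golden-section search and split into two roots if negative.
    double lo = twopi * (minIdx - 1) / nS, hi = twopi * (minIdx + 1) / nS;
    const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
    double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
    double f1 = crossFun(Ei, Ej, x1), f2 = crossFun(Ei, Ej, x2);
    for (int it = 0; it < 44; ++it) {
      if (f1 < f2) {
        hi = x2; x2 = x1; f2 = f1;
        x1 = hi - gr * (hi - lo); f1 = crossFun(Ei, Ej, x1);
      } else {
        lo = x1; x1 = x2; f1 = f2;
        x2 = lo + gr * (hi - lo); f2 = crossFun(Ei, Ej, x2);
      }
    }
    double tm = 0.5 * (lo + hi), fm = crossFun(Ei, Ej, tm);
    if (fm < 0.0) {
      double wlo = twopi * (minIdx - 1) / nS, whi = twopi * (minIdx + 1) / nS;
      ts[nt++] = bisectRoot(Ei, Ej, tm, wlo, fm);
      ts[nt++] = bisectRoot(Ei, Ej, tm, whi, fm);
    }
  }
  return nt;
}

// Contact of two ellipses. Returns 1 (contact), 0 (none), -1 (degenerate:
// normal undefined). On contact fills overlap depth, unit normal pointing
// from j toward i, and a contact point inside the intersection lens.
//
// The overlap depth is measured along the mid-normal of the chord joining
// the two boundary intersection points: the extent of the overlap lens
// along the line through the chord midpoint perpendicular to the chord.
// In the circle limit this reduces to 2r - d. When one center lies inside
// the other ellipse (deep overlap) the center-to-center direction is used.
int pairContact(const Ell& Ei, const Ell& Ej, double& delta, double& nx,
                double& ny, double& px, double& py) {
  double dcx = Ei.cx - Ej.cx, dcy = Ei.cy - Ej.cy;
  double d2 = dcx * dcx + dcy * dcy;
  double rr = Ei.a + Ej.a;
  if (d2 > rr * rr) return 0;
  if (d2 < 1e-24) return -1;

  double ts[8];
  int nt = boundaryCrossings(Ei, Ej, ts);

  if (nt >= 2) {
    // chord between the two most distant crossing points
    double bx[8], by[8];
    for (int k = 0; k < nt; ++k) boundaryPt(Ei, ts[k], bx[k], by[k]);
    int i1 = 0, i2 = 1;
    double best = -1.0;
    for (int p = 0; p < nt; ++p)
      for (int q = p + 1; q < nt; ++q) {
        double dx = bx[p] - bx[q], dy = by[p] - by[q];
        double dd = dx * dx + dy * dy;
        if (dd > best) { best = dd; i1 = p; i2 = q; }
      }
    if (best < 1e-24) return 0;  // numerically a single tangent point
    double mx = 0.5 * (bx[i1] + bx[i2]), my = 0.5 * (by[i1] + by[i2]);
    double cxn = bx[i2] - bx[i1], cyn = by[i2] - by[i1];
    double cl = std::sqrt(cxn * cxn + cyn * cyn);
    double ux = -cyn / cl, uy = cxn / cl;  // mid-normal direction
    double orient = ux * dcx + uy * dcy;
    if (std::fabs(orient) < 1e-14) {
      // centers symmetric about the chord: point away from j's interior
      double h = 1e-7;
      if (implicitVal(Ej, mx + h * ux, my + h * uy) <
          implicitVal(Ej, mx - h * ux, my - h * uy)) { ux = -ux; uy = -uy; }
    } else if (orient < 0.0) {
      ux = -ux; uy = -uy;
    }
    double si1, si2, sj1, sj2;
    if (!lineInterval(Ei, mx, my, ux, uy, si1, si2) ||
        !lineInterval(Ej, mx, my, ux, uy, sj1, sj2)) return 0;
    double lo = std::max(si1, sj1), hi = std::min(si2, sj2);
    if (hi <= lo) return 0;
    delta = hi - lo;
    nx = ux; ny = uy;
    px = mx + 0.5 * (lo + hi) * ux;
    py = my + 0.5 * (lo + hi) * uy;
    return 1;
  }

  // no boundary crossings: either separate or one center inside the other
  bool inside = implicitVal(Ej, Ei.cx, Ei.cy) < 0.0 ||
                implicitVal(Ei, Ej.cx, Ej.cy) < 0.0;
  if (!inside) return 0;
  double d = std::sqrt(d2);
  double ux = dcx / d, uy = dcy / d;
  double si1, si2, sj1, sj2;
  if (!lineInterval(Ei, Ej.cx, Ej.cy, ux, uy, si1, si2) ||
      !lineInterval(Ej, Ej.cx, Ej.cy, ux, uy, sj1, sj2)) return 0;
  double lo = std::max(si1, sj1), hi = std::min(si2, sj2);
  if (hi <= lo) return 0;
  delta = hi - lo;
  nx = ux; ny = uy;
  px = Ej.cx + 0.5 * (lo + hi) * ux;
  py = Ej.cy + 0.5 * (lo + hi) * uy;
  return 1;
}

// Ellipse against the face of a wall segment. Penetration is the maximal
// extent of the ellipse past the supporting line (support function minus
// center distance); contact only if the crossing chord overlaps the
// segment extent. The normal points from the wall toward the agent (the
// wall's inward normal when the agent is on the inward side).
int faceContact(const Ell& E, double p1x, double p1y, double p2x, double p2y,
                double n0x, double n0y, double& delta, double& nx, double& ny,
                double& px, double& py) {
  double sd = (E.cx - p1x) * n0x + (E.cy - p1y) * n0y;
  double sgn = (sd >= 0.0) ? 1.0 : -1.0;
  double nxx = sgn * n0x, nyy = sgn * n0y;
  double c = E.cphi, s = E.sphi;
  double ne1 = nxx * c + nyy * s, ne2 = -nxx * s + nyy * c;
  double h = std::sqrt(E.a * E.a * ne1 * ne1 + E.b * E.b * ne2 * ne2);
  double d = std::fabs(sd);
  double del = h - d;
  if (del <= 0.0) return 0;
  double tx = p2x - p1x, ty = p2y - p1y;
  double len = std::sqrt(tx * tx + ty * ty);
  tx /= len; ty /= len;
  double s1, s2;
  if (!lineInterval(E, p1x, p1y, tx, ty, s1, s2)) return 0;
  double lo = std::max(0.0, s1), hi = std::min(len, s2);
  if (hi <= lo) return 0;
  // deepest boundary point along -n, with its chord-parameter clamped
  double e1x = c, e1y = s, e2x = -s, e2y = c;
  double wx = (E.a * E.a * ne1 * e1x + E.b * E.b * ne2 * e2x) / h;
  double wy = (E.a * E.a * ne1 * e1y + E.b * E.b * ne2 * e2y) / h;
  double dpx = E.cx - wx, dpy = E.cy - wy;
  double proj = (dpx - p1x) * tx + (dpy - p1y) * ty;
  double pcl = std::min(std::max(proj, lo), hi);
  delta = del;
  nx = nxx; ny = nyy;
  px = p1x + pcl * tx - 0.5 * del * nxx;
  py = p1y + pcl * ty - 0.5 * del * nyy;
  return 1;
}

// Point obstacle (wall corner) against an ellipse: radial penetration along
// the corner-to-center direction.
int pointContact(const Ell& E, double qx, double qy, double& delta,
                 double& nx, double& ny, double& px, double& py) {
  double ux = E.cx - qx, uy = E.cy - qy;
  double d = std::sqrt(ux * ux + uy * uy);
  if (d < 1e-12) return 0;
  ux /= d; uy /= d;
  double c = E.cphi, s = E.sphi;
  double ue1 = ux * c + uy * s, ue2 = -ux * s + uy * c;
  double r = 1.0 / std::sqrt(ue1 * ue1 / (E.a * E.a) + ue2 * ue2 / (E.b * E.b));
  double del = r - d;
  if (del <= 0.0) return 0;
  delta = del;
  nx = ux; ny = uy;
  px = qx; py = qy;
  return 1;
}

inline double etaFromE(double e, double meff, double k) {
  if (e >= 1.0) return 0.0;
  double le = std::log(e);
  return 2.0 * (-le) * std::sqrt(meff * k) / std::sqrt(M_PI * M_PI + le * le);
}

// perpendicular distance to the wall face; +Inf when the point projects
// beyond the segment extent (so doorpost corners do not trigger steering)
inline double ptFaceDist(double qx, double qy, double p1x, double p1y,
                         double p2x, double p2y, double& awx, double& awy) {
  double tx = p2x - p1x, ty = p2y - p1y;
  double len2 = tx * tx + ty * ty;
  double u = ((qx - p1x) * tx + (qy - p1y) * ty) / len2;
  if (u < 0.0 || u > 1.0) return R_PosInf;
  double cx = p1x + u * tx, cy = p1y + u * ty;
  double dx = qx - cx, dy = qy - cy;
  double d = std::sqrt(dx * dx + dy * dy);
  if (d > 1e-12) { awx = dx / d; awy = dy / d; } else { awx = 0.0; awy = 0.0; }
  return d;
}

}  // namespace

// [[Rcpp::export]]
List ellipse_contact_cpp(NumericVector si, NumericVector sj) {
  Ell Ei = makeEll(si[0], si[1], si[2], si[3], si[4]);
  Ell Ej = makeEll(sj[0], sj[1], sj[2], sj[3], sj[4]);
  double delta, nx, ny, px, py;
  int code = pairContact(Ei, Ej, delta, nx, ny, px, py);
  if (code == -1)
    stop("degenerate contact: coincident centers, normal undefined");
  if (code == 0) return List::create(Named("found") = false);
  return List::create(Named("found") = true, Named("delta") = delta,
                      Named("normal") = NumericVector::create(nx, ny),
                      Named("point") = NumericVector::create(px, py));
}

// [[Rcpp::export]]
List wall_face_contact_cpp(NumericVector s, NumericVector p1, NumericVector p2,
                           NumericVector n0) {
  Ell E = makeEll(s[0], s[1], s[2], s[3], s[4]);
  double delta, nx, ny, px, py;
  int code = faceContact(E, p1[0], p1[1], p2[0], p2[1], n0[0], n0[1], delta,
                         nx, ny, px, py);
  if (code == 0) return List::create(Named("found") = false);
  return List::create(Named("found") = true, Named("delta") = delta,
                      Named("normal") = NumericVector::create(nx, ny),
                      Named("point") = NumericVector::create(px, py));
}

// [[Rcpp::export]]
List point_contact_cpp(NumericVector s, NumericVector q) {
  Ell E = makeEll(s[0], s[1], s[2], s[3], s[4]);
  double delta, nx, ny, px, py;
  int code = pointContact(E, q[0], q[1], delta, nx, ny, px, py);
  if (code == 0) return List::create(Named("found") = false);
  return List::create(Named("found") = true, Named("delta") = delta,
                      Named("normal") = NumericVector::create(nx, ny),
                      Named("point") = NumericVector::create(px, py));
}

// [[Rcpp::export]]
double damping_coefficient_cpp(double e, double meff, double k) {
  return etaFromE(e, meff, k);
}

namespace {

// Desired velocities for all active agents from the panic-behaviour rules:
// rush toward the exit opening; if a slower agent walking the same way
// blocks the front sector, overtake into the first admissible side sector
// (preferred side first, admissible when its density is strictly below
// rho_c); if both sides are at/above rho_c, slow to the front target's
// speed and follow it; finally a lateral steering adjustment away from the
// nearest wall face within wallAvoid. Operates on raw arrays so the
// integration loop can call it every step without any R allocation.
void desiredVelocitiesImpl(int N, const double* px, const double* py,
                           const double* vx, const double* vy,
                           const double* vdes,
                           const std::vector<char>& rightF,
                           const std::vector<char>& act,
                           const double* wallsP, int nW,
                           const double* exitSpec, double rhoc,
                           double sectorR, double wallAvoid, double* outx,
                           double* outy) {
  const double halfw = M_PI / 6.0;
  const double cosHalf = std::cos(halfw);
  const double sectorArea = M_PI * sectorR * sectorR / 6.0;
  // walls are column-major: column c of wall w is wallsP[c * nW + w]

  // the base direction aims at the nearest point of the exit segment,
  // inset from the doorposts: far away this is indistinguishable from the
  // gap midpoint, close up it points straight through the opening
  double exLo = exitSpec[0] + exitSpec[3], exHi = exitSpec[1] - exitSpec[3];
  if (exLo > exHi) { exLo = exHi = 0.5 * (exitSpec[0] + exitSpec[1]); }
  double exY = exitSpec[2];

  for (int i = 0; i < N; ++i) {
    if (!act[i]) { outx[i] = 0.0; outy[i] = 0.0; continue; }
    double exX = std::min(std::max(px[i], exLo), exHi);
    double bx = exX - px[i], by = exY - py[i];
    double bn = std::sqrt(bx * bx + by * by);
    if (bn < 1e-12) { bx = 0.0; by = 1.0; } else { bx /= bn; by /= bn; }
    double hx = bx, hy = by;  // heading for sector geometry

    // nearest agent in the front sector
    int best = -1;
    double bestd2 = sectorR * sectorR;
    for (int j = 0; j < N; ++j) {
      if (j == i || !act[j]) continue;
      double rx = px[j] - px[i], ry = py[j] - py[i];
      double d2 = rx * rx + ry * ry;
      if (d2 > sectorR * sectorR || d2 < 1e-24) continue;
      double d = std::sqrt(d2);
      if ((rx * hx + ry * hy) / d < cosHalf) continue;
      if (d2 < bestd2) { bestd2 = d2; best = j; }
    }

    double dirx = bx, diry = by;
    double spd = vdes[i];
    double speedI = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i]);
    if (best >= 0) {
      double speedT = std::sqrt(vx[best] * vx[best] + vy[best] * vy[best]);
      // the overtake/follow rules concern a target *walking in the same
      // direction*: a jammed, essentially stationary crowd ahead is an
      // obstacle to push against (rushing rule), not a leader to follow at
      // zero speed, and an approaching agent is pushed past, not orbited
      bool sameDir = vx[best] * hx + vy[best] * hy > 0.0;
      if (sameDir && speedT > 0.01 && speedT < speedI) {
        // geometric right of the heading = rotation by -pi/6
        double offs[2];
        if (rightF[i]) { offs[0] = -halfw; offs[1] = halfw; }
        else { offs[0] = halfw; offs[1] = -halfw; }
        bool chosen = false;
        for (int k = 0; k < 2 && !chosen; ++k) {
          double ca = std::cos(offs[k]), sa = std::sin(offs[k]);
          double ax = hx * ca - hy * sa, ay = hx * sa + hy * ca;
          int count = 0;
          // the front target itself does not occupy the swerve sectors
          for (int j = 0; j < N; ++j) {
            if (j == i || j == best || !act[j]) continue;
            double rx = px[j] - px[i], ry = py[j] - py[i];
            double d2 = rx * rx + ry * ry;
            if (d2 > sectorR * sectorR || d2 < 1e-24) continue;
            double d = std::sqrt(d2);
            if ((rx * ax + ry * ay) / d >= cosHalf) ++count;
          }
          if (count / sectorArea < rhoc) {
            dirx = bx * ca - by * sa;
            diry = bx * sa + by * ca;
            chosen = true;
          }
        }
        if (!chosen) {
          double rx = px[best] - px[i], ry = py[best] - py[i];
          double d = std::sqrt(rx * rx + ry * ry);
          dirx = rx / d; diry = ry / d;
          spd = std::min(speedT, vdes[i]);
        }
      }
    }

    // wall avoidance: a lateral steering adjustment away from the nearest
    // wall face within wallAvoid; lateral (perpendicular to the desired
    // direction) so stepping away never cancels forward progress
    if (nW > 0 && wallAvoid > 0.0) {
      double bestw = wallAvoid;
      double awx = 0.0, awy = 0.0;
      for (int w = 0; w < nW; ++w) {
        double ax, ay;
        double d = ptFaceDist(px[i], py[i], wallsP[w], wallsP[nW + w],
                              wallsP[2 * nW + w], wallsP[3 * nW + w], ax, ay);
        if (d < bestw) { bestw = d; awx = ax; awy = ay; }
      }
      if (bestw < wallAvoid && (awx != 0.0 || awy != 0.0)) {
        double along = awx * dirx + awy * diry;
        double lx = awx - along * dirx, ly = awy - along * diry;
        double ln = std::sqrt(lx * lx + ly * ly);
        if (ln > 1e-9) {
          double wgt = 1.0 - bestw / wallAvoid;
          double sx = dirx + wgt * lx / ln, sy = diry + wgt * ly / ln;
          double sn = std::sqrt(sx * sx + sy * sy);
          if (sn > 1e-12) { dirx = sx / sn; diry = sy / sn; }
        }
      }
    }

    outx[i] = spd * dirx;
    outy[i] = spd * diry;
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix desired_velocities_cpp(NumericMatrix pos, NumericMatrix vel,
                                     NumericVector vdes,
                                     LogicalVector rightFirst,
                                     LogicalVector active,
                                     NumericMatrix walls,
                                     NumericVector exitSpec, double rhoc,
                                     double sectorR, double wallAvoid) {
  int N = pos.nrow();
  std::vector<double> px(N), py(N), vx(N), vy(N), outx(N), outy(N);
  std::vector<char> rf(N), ac(N);
  for (int i = 0; i < N; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1);
    rf[i] = rightFirst[i] ? 1 : 0;
    ac[i] = active[i] ? 1 : 0;
  }
  desiredVelocitiesImpl(N, px.data(), py.data(), vx.data(), vy.data(),
                        &vdes[0], rf, ac, walls.nrow() > 0 ? &walls[0] : NULL,
                        walls.nrow(), &exitSpec[0], rhoc, sectorR, wallAvoid,
                        outx.data(), outy.data());
  NumericMatrix out(N, 2);
  for (int i = 0; i < N; ++i) { out(i, 0) = outx[i]; out(i, 1) = outy[i]; }
  return out;
}

// Time integration of the full model by semi-implicit Euler.
//
// walls: columns p1x,p1y,p2x,p2y,nx,ny; corners: columns x,y.
// Returns recorded trajectory frames, exit times (NA when not exited), and
// the final state so stepping can be resumed.
// [[Rcpp::export]]
List run_sim_cpp(NumericMatrix pos0, NumericMatrix vel0, NumericVector phi0,
                 NumericVector aa, NumericVector bb, NumericVector mass,
                 NumericVector vdes0, LogicalVector rightFirst,
                 NumericMatrix walls, NumericMatrix corners, List par) {
  int N = pos0.nrow();
  double dt = as<double>(par["dt"]);
  int nSteps = as<int>(par["n_steps"]);
  int recStride = as<int>(par["record_stride"]);
  bool record = as<bool>(par["record"]);
  double kN = as<double>(par["k_normal"]);
  double kT = as<double>(par["k_tangential"]);
  double mu = as<double>(par["mu"]);
  double rest = as<double>(par["restitution"]);
  double dtres = as<double>(par["dt_res"]);
  bool psychOn = as<bool>(par["psych_on"]);
  bool behaviorOn = as<bool>(par["behavior_on"]);
  int behStride = as<int>(par["behavior_stride"]);
  double rhoc = as<double>(par["critical_density"]);
  double sectorR = as<double>(par["sector_radius"]);
  double wallAvoid = as<double>(par["wall_avoid_distance"]);
  bool exitOn = as<bool>(par["exit_on"]);
  double exitY = 0.0, exitX0 = 0.0, exitX1 = 0.0;
  NumericVector exitSpec(4);
  if (exitOn) {
    exitY = as<double>(par["exit_y"]);
    exitX0 = as<double>(par["exit_x0"]);
    exitX1 = as<double>(par["exit_x1"]);
  }
  if (behaviorOn) exitSpec = as<NumericVector>(par["exit_spec"]);
  double t0 = as<double>(par["t0"]);
  double orientRate = as<double>(par["orient_rate"]);
  double blockTime = as<double>(par["block_time"]);
  double reposTime = as<double>(par["reposition_time"]);

  std::vector<double> px(N), py(N), vx(N), vy(N), phi(N);
  std::vector<char> act(N, 1), rfC(N);
  NumericVector texit(N, NA_REAL);
  if (par.containsElementNamed("active0")) {
    LogicalVector a0 = as<LogicalVector>(par["active0"]);
    for (int i = 0; i < N; ++i) act[i] = a0[i] ? 1 : 0;
  }
  for (int i = 0; i < N; ++i) {
    px[i] = pos0(i, 0); py[i] = pos0(i, 1);
    vx[i] = vel0(i, 0); vy[i] = vel0(i, 1);
    phi[i] = phi0[i];
    rfC[i] = rightFirst[i] ? 1 : 0;
  }
  // desired velocities (desx/desy) and the raw behaviour-layer output
  // before the jostle override (desBx/desBy); plain arrays so the hot loop
  // performs no R allocation
  std::vector<double> desx(N, 0.0), desy(N, 0.0), desBx(N, 0.0),
      desBy(N, 0.0);
  std::vector<double> exitSpecV(4, 0.0);
  if (behaviorOn)
    for (int k = 0; k < 4; ++k) exitSpecV[k] = exitSpec[k];
  if (!behaviorOn) {
    NumericMatrix vf = as<NumericMatrix>(par["vdes_fixed"]);
    for (int i = 0; i < N; ++i) { desx[i] = vf(i, 0); desy[i] = vf(i, 1); }
  }

  int nW = walls.nrow(), nC = corners.nrow();
  std::unordered_map<long long, std::pair<double, double> > tang, tangNew;
  std::vector<double> fx(N), fy(N);
  std::vector<double> blockT(N, 0.0), reposT(N, 0.0);

  // recorded frames: frame, time, agent, x, y, phi, vx, vy, status
  std::vector<double> rec;
  int nFrames = 0;
  int maxFrames = record ? (nSteps / recStride + 3) : 0;
  if (record) rec.reserve((size_t)maxFrames * N * 9);
  auto pushFrame = [&](double t) {
    for (int i = 0; i < N; ++i) {
      rec.push_back(nFrames); rec.push_back(t); rec.push_back(i + 1);
      rec.push_back(px[i]); rec.push_back(py[i]); rec.push_back(phi[i]);
      rec.push_back(vx[i]); rec.push_back(vy[i]);
      rec.push_back(act[i] ? 0.0 : 1.0);
    }
    ++nFrames;
  };
  if (record) pushFrame(t0);

  int stepsDone = 0;
  for (int step = 0; step < nSteps; ++step) {
    double t = t0 + step * dt;
    if (behaviorOn && step % behStride == 0) {
      desiredVelocitiesImpl(N, px.data(), py.data(), vx.data(), vy.data(),
                            &vdes0[0], rfC, act,
                            nW > 0 ? &walls[0] : NULL, nW, exitSpecV.data(),
                            rhoc, sectorR, wallAvoid, desBx.data(),
                            desBy.data());
      desx = desBx;
      desy = desBy;
    }

    // repositioning (jostle): an agent stuck at essentially zero speed for
    // block_time sidesteps toward its handed side for reposition_time; the
    // deterministic rules alone reach exact static arch equilibria that a
    // real blocked animal breaks by shifting its footing
    if (behaviorOn && blockTime > 0.0 && reposTime > 0.0) {
      for (int i = 0; i < N; ++i) {
        if (!act[i]) continue;
        double sp = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i]);
        if (sp < 0.01) blockT[i] += dt; else blockT[i] = 0.0;
        if (reposT[i] > 0.0) {
          reposT[i] -= dt;
          double dx = desBx[i], dy = desBy[i];
          double dn = std::sqrt(dx * dx + dy * dy);
          if (dn < 1e-12) { dx = 0.0; dy = 1.0; dn = 1.0; }
          double rx, ry;
          if (rfC[i]) { rx = dy; ry = -dx; }  // rotate -pi/2
          else { rx = -dy; ry = dx; }
          desx[i] = vdes0[i] * rx / dn;
          desy[i] = vdes0[i] * ry / dn;
        } else {
          desx[i] = desBx[i];
          desy[i] = desBy[i];
          if (blockT[i] > blockTime) {
            reposT[i] = reposTime;
            blockT[i] = 0.0;
          }
        }
      }
    }

    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    tangNew.clear();

    // agent-agent contacts
    for (int i = 0; i < N; ++i) {
      if (!act[i]) continue;
      for (int j = i + 1; j < N; ++j) {
        if (!act[j]) continue;
        double dcx = px[i] - px[j], dcy = py[i] - py[j];
        double rr = aa[i] + aa[j];
        if (dcx * dcx + dcy * dcy > rr * rr) continue;
        Ell Ei = makeEll(px[i], py[i], phi[i], aa[i], bb[i]);
        Ell Ej = makeEll(px[j], py[j], phi[j], aa[j], bb[j]);
        double delta, nx, ny, cpx, cpy;
        int code = pairContact(Ei, Ej, delta, nx, ny, cpx, cpy);
        if (code == -1)
          stop("degenerate contact between agents %d and %d at step %d",
               i + 1, j + 1, step + 1);
        if (code != 1) continue;
        double meff = mass[i] * mass[j] / (mass[i] + mass[j]);
        double eta = etaFromE(rest, meff, kN);
        double vrx = vx[i] - vx[j], vry = vy[i] - vy[j];
        double vn = vrx * nx + vry * ny;
        double Fn = kN * delta - eta * vn;
        double fnx = Fn * nx, fny = Fn * ny;
        // tangential spring with Coulomb cap
        long long key = (long long)i * N + j;
        double xix = 0.0, xiy = 0.0;
        auto it = tang.find(key);
        if (it != tang.end()) { xix = it->second.first; xiy = it->second.second; }
        double xin = xix * nx + xiy * ny;
        xix -= xin * nx; xiy -= xin * ny;
        double vtx = vrx - vn * nx, vty = vry - vn * ny;
        xix += vtx * dt; xiy += vty * dt;
        double ftx = -kT * xix, fty = -kT * xiy;
        double ftm = std::sqrt(ftx * ftx + fty * fty);
        double cap = mu * std::fabs(Fn);
        if (ftm > cap && ftm > 0.0) {
          double sc = cap / ftm;
          ftx *= sc; fty *= sc;
          xix = -ftx / kT; xiy = -fty / kT;
        }
        tangNew[key] = std::make_pair(xix, xiy);
        fx[i] += fnx + ftx; fy[i] += fny + fty;
        fx[j] -= fnx + ftx; fy[j] -= fny + fty;
      }
    }

    // wall faces and corners
    for (int i = 0; i < N; ++i) {
      if (!act[i]) continue;
      Ell E = makeEll(px[i], py[i], phi[i], aa[i], bb[i]);
      for (int w = 0; w < nW + nC; ++w) {
        double delta, nx, ny, cpx, cpy;
        int code;
        if (w < nW) {
          code = faceContact(E, walls(w, 0), walls(w, 1), walls(w, 2),
                             walls(w, 3), walls(w, 4), walls(w, 5), delta, nx,
                             ny, cpx, cpy);
        } else {
          code = pointContact(E, corners(w - nW, 0), corners(w - nW, 1),
                              delta, nx, ny, cpx, cpy);
        }
        if (code != 1) continue;
        double eta = etaFromE(rest, mass[i], kN);
        double vn = vx[i] * nx + vy[i] * ny;
        double Fn = kN * delta - eta * vn;
        long long key = (long long)N * N + (long long)w * N + i;
        double xix = 0.0, xiy = 0.0;
        auto it = tang.find(key);
        if (it != tang.end()) { xix = it->second.first; xiy = it->second.second; }
        double xin = xix * nx + xiy * ny;
        xix -= xin * nx; xiy -= xin * ny;
        double vtx = vx[i] - vn * nx, vty = vy[i] - vn * ny;
        xix += vtx * dt; xiy += vty * dt;
        double ftx = -kT * xix, fty = -kT * xiy;
        double ftm = std::sqrt(ftx * ftx + fty * fty);
        double cap = mu * std::fabs(Fn);
        if (ftm > cap && ftm > 0.0) {
          double sc = cap / ftm;
          ftx *= sc; fty *= sc;
          xix = -ftx / kT; xiy = -fty / kT;
        }
        tangNew[key] = std::make_pair(xix, xiy);
        fx[i] += Fn * nx + ftx; fy[i] += Fn * ny + fty;
      }
    }

    // psychological force and integration
    bool anyActive = false;
    for (int i = 0; i < N; ++i) {
      if (!act[i]) continue;
      if (psychOn) {
        double c = mass[i] / dtres;
        fx[i] += c * (desx[i] - vx[i]);
        fy[i] += c * (desy[i] - vy[i]);
      }
      double yold = py[i];
      vx[i] += fx[i] / mass[i] * dt;
      vy[i] += fy[i] / mass[i] * dt;
      px[i] += vx[i] * dt;
      py[i] += vy[i] * dt;
      if (!std::isfinite(px[i]) || !std::isfinite(py[i]) ||
          !std::isfinite(vx[i]) || !std::isfinite(vy[i]))
        stop("integration failure: non-finite state for agent %d at step %d",
             i + 1, step + 1);
      // body axis relaxes toward the heading at a bounded angular rate:
      // instantaneous slaving would let contact-driven velocity swings spin
      // the ellipse in place, discontinuously changing overlaps and pumping
      // spring energy into the system
      double tx_ = psychOn ? desx[i] : vx[i];
      double ty_ = psychOn ? desy[i] : vy[i];
      if (tx_ * tx_ + ty_ * ty_ > 1e-16) {
        double dphi = std::atan2(ty_, tx_) - phi[i];
        dphi -= M_PI * std::floor(dphi / M_PI);  // axis difference in [0, pi)
        if (dphi > M_PI / 2) dphi -= M_PI;       // shortest turn
        double maxr = orientRate * dt;
        if (dphi > maxr) dphi = maxr;
        else if (dphi < -maxr) dphi = -maxr;
        double ph = phi[i] + dphi;
        ph -= M_PI * std::floor(ph / M_PI);
        phi[i] = ph;
      }
      if (exitOn && yold < exitY && py[i] >= exitY && px[i] >= exitX0 &&
          px[i] <= exitX1) {
        double frac = (exitY - yold) / (py[i] - yold);
        texit[i] = t + frac * dt;
        act[i] = 0;
      } else {
        anyActive = true;
      }
    }

    tang.swap(tangNew);
    ++stepsDone;
    if (record && ((step + 1) % recStride == 0 || !anyActive ||
                   step == nSteps - 1))
      pushFrame(t0 + (step + 1) * dt);
    if (!anyActive) break;
  }

  NumericMatrix track(record ? nFrames * N : 0, 9);
  if (record) {
    for (int r = 0; r < nFrames * N; ++r)
      for (int c = 0; c < 9; ++c) track(r, c) = rec[(size_t)r * 9 + c];
    colnames(track) = CharacterVector::create("frame", "time_s", "agent_id",
                                              "x_m", "y_m", "orientation_rad",
                                              "vx_mps", "vy_mps", "status");
  }
  NumericMatrix posOut(N, 2), velOut(N, 2);
  LogicalVector actOut(N);
  NumericVector phiOut(N);
  for (int i = 0; i < N; ++i) {
    posOut(i, 0) = px[i]; posOut(i, 1) = py[i];
    velOut(i, 0) = vx[i]; velOut(i, 1) = vy[i];
    phiOut[i] = phi[i];
    actOut[i] = act[i];
  }
  return List::create(Named("track") = track, Named("exit_time") = texit,
                      Named("pos") = posOut, Named("vel") = velOut,
                      Named("phi") = phiOut, Named("active") = actOut,
                      Named("steps_done") = stepsDone,
                      Named("t_end") = t0 + stepsDone * dt);
}
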