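#include <Rcpp.h>
using namespace Rcpp;

// Polygons are stored flattened: vertex arrays (vx, vy) plus 0-based offsets of
// length n_poly + 1; polygon i owns vertices [offsets[i], offsets[i+1]).
// Coordinates are video pixels, origin top-left, y down. All routines only use
// affine/metric structure, so the y-down convention is immaterial.

static inline double seg_dist2(double px, double py, double ax, double ay,
                               double bx, double by) {
  const double dx = bx - ax, dy = by - ay;
  const double L2 = dx * dx + dy * dy;
  double t = 0.0;
  if (L2 > 0.0) {
    t = ((px - ax) * dx + (py - ay) * dy) / L2;
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  }
  const double qx = ax + t * dx, qy = ay + t * dy;
  return (px - qx) * (px - qx) + (py - qy) * (py - qy);
}

// Signed distance of points to polygon boundaries: negative inside (even-odd
// rule), positive outside, zero on the boundary. pidx maps each point to its
// polygon (0-based).
// [[Rcpp::export]]
NumericVector cpp_point_poly_signed_dist(NumericVector px, NumericVector py,
                                         IntegerVector pidx, NumericVector vx,
                                         NumericVector vy, IntegerVector offsets) {
  const int n = px.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const int p = pidx[i];
    const int s = offsets[p], e = offsets[p + 1];
    const double x = px[i], y = py[i];
    bool inside = false;
    double d2 = R_PosInf;
    for (int j = s, k = e - 1; j < e; k = j++) {
      const double xj = vx[j], yj = vy[j], xk = vx[k], yk = vy[k];
      if (((yj > y) != (yk > y)) &&
          (x < (xk - xj) * (y - yj) / (yk - yj) + xj))
        inside = !inside;
      const double dd = seg_dist2(x, y, xj, yj, xk, yk);
      if (dd < d2) d2 = dd;
    }
    const double d = std::sqrt(d2);
    out[i] = inside ? -d : d;
  }
  return out;
}

// signed area (shoelace); sign encodes orientation
static double shoelace(const std::vector<double>& x, const std::vector<double>& y) {
  const int n = (int)x.size();
  double a = 0.0;
  for (int j = 0, k = n - 1; j < n; k = j++) a += (x[k] * y[j] - x[j] * y[k]);
  return 0.5 * a;
}

// Area, area-centroid and orientation-free simplicity check per polygon.
// Returns a matrix with columns: area (absolute), cx, cy, simple (0/1).
// Degenerate (near-zero area) polygons get centroid = vertex mean.
// [[Rcpp::export]]
NumericMatrix cpp_polygon_props(NumericVector vx, NumericVector vy,
                                IntegerVector offsets) {
  const int np = offsets.size() - 1;
  NumericMatrix out(np, 4);
  for (int p = 0; p < np; ++p) {
    const int s = offsets[p], e = offsets[p + 1], n = e - s;
    double a2 = 0.0, cx = 0.0, cy = 0.0, mx = 0.0, my = 0.0;
    for (int j = s, k = e - 1; j < e; k = j++) {
      const double cr = vx[k] * vy[j] - vx[j] * vy[k];
      a2 += cr;
      cx += (vx[k] + vx[j]) * cr;
      cy += (vy[k] + vy[j]) * cr;
      mx += vx[j]; my += vy[j];
    }
    const double area = std::fabs(a2) / 2.0;
    if (area > 1e-9) {
      out(p, 1) = cx / (3.0 * a2);
      out(p, 2) = cy / (3.0 * a2);
    } else {
      out(p, 1) = mx / n;
      out(p, 2) = my / n;
    }
    out(p, 0) = area;
    // simplicity: no two non-adjacent edges properly intersect
    bool simple = (n >= 3) && (area > 1e-9);
    if (simple) {
      for (int a = 0; a < n && simple; ++a) {
        const int a2i = (a + 1) % n;
        for (int b = a + 1; b < n && simple; ++b) {
          const int b2 = (b + 1) % n;
          if (a == b || a2i == b || a == b2) continue; // adjacent edges share a vertex
          const double x1 = vx[s + a], y1 = vy[s + a], x2 = vx[s + a2i], y2 = vy[s + a2i];
          const double x3 = vx[s + b], y3 = vy[s + b], x4 = vx[s + b2], y4 = vy[s + b2];
          const double d1 = (x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1);
          const double d2 = (x2 - x1) * (y4 - y1) - (y2 - y1) * (x4 - x1);
          const double d3 = (x4 - x3) * (y1 - y3) - (y4 - y3) * (x1 - x3);
          const double d4 = (x4 - x3) * (y2 - y3) - (y4 - y3) * (x2 - x3);
          if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) simple = false;
        }
      }
    }
    out(p, 3) = simple ? 1.0 : 0.0;
  }
  return out;
}

// Sutherland-Hodgman clip of polygon A by CONVEX polygon B; returns |A ∩ B|.
static double clip_area(const std::vector<double>& axv, const std::vector<double>& ayv,
                        std::vector<double> bx, std::vector<double> by) {
  // ensure B counter-clockwise (positive shoelace)
  if (shoelace(bx, by) < 0) {
    std::reverse(bx.begin(), bx.end());
    std::reverse(by.begin(), by.end());
  }
  std::vector<double> sx = axv, sy = ayv, ox, oy;
  const int nb = (int)bx.size();
  for (int i = 0; i < nb; ++i) {
    const double ex1 = bx[i], ey1 = by[i];
    const double ex2 = bx[(i + 1) % nb], ey2 = by[(i + 1) % nb];
    ox.clear(); oy.clear();
    const int ns = (int)sx.size();
    if (ns == 0) break;
    for (int j = 0; j < ns; ++j) {
      const double cx1 = sx[j], cy1 = sy[j];
      const double cx2 = sx[(j + 1) % ns], cy2 = sy[(j + 1) % ns];
      const double s1 = (ex2 - ex1) * (cy1 - ey1) - (ey2 - ey1) * (cx1 - ex1);
      const double s2 = (ex2 - ex1) * (cy2 - ey1) - (ey2 - ey1) * (cx2 - ex1);
      const bool in1 = s1 >= 0, in2 = s2 >= 0; // interior is left of each CCW edge
      if (in1) { ox.push_back(cx1); oy.push_back(cy1); }
      if (in1 != in2) {
        const double t = s1 / (s1 - s2);
        ox.push_back(cx1 + t * (cx2 - cx1));
        oy.push_back(cy1 + t * (cy2 - cy1));
      }
    }
    sx = ox; sy = oy;
  }
  if (sx.size() < 3) return 0.0;
  return std::fabs(shoelace(sx, sy));
}

// Pairwise intersection areas |poly ia[i] ∩ poly ib[i]| (0-based polygon ids).
// The second polygon of each pair must be convex (grasper quadrilaterals are).
// [[Rcpp::export]]
NumericVector cpp_pair_intersection_areas(NumericVector vx, NumericVector vy,
                                          IntegerVector offsets, IntegerVector ia,
                                          IntegerVector ib) {
  const int n = ia.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const int a = ia[i], b = ib[i];
    std::vector<double> ax, ay, bxv, byv;
    for (int j = offsets[a]; j < offsets[a + 1]; ++j) { ax.push_back(vx[j]); ay.push_back(vy[j]); }
    for (int j = offsets[b]; j < offsets[b + 1]; ++j) { bxv.push_back(vx[j]); byv.push_back(vy[j]); }
    out[i] = clip_area(ax, ay, bxv, byv);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Bulk fixation-frame classification (fast path behind
// map_fixations_to_frames). Instance rows must be grouped by frame; each
// frame f owns instance rows [frame_start[f], frame_end[f]). Categories:
// 0 OBJ_1TOOL, 1 OBJ_2TOOLS, 2 OBJ_NOT_MOVING, 3 TOOL_ONLY, 4 NONE.

static inline bool point_in_poly(double x, double y, const double* vx,
                                 const double* vy, int s, int e) {
  bool inside = false;
  for (int j = s, k = e - 1; j < e; k = j++) {
    if (((vy[j] > y) != (vy[k] > y)) &&
        (x < (vx[k] - vx[j]) * (y - vy[j]) / (vy[k] - vy[j]) + vx[j]))
      inside = !inside;
  }
  return inside;
}

static inline double poly_dist2(double x, double y, const double* vx,
                                const double* vy, int s, int e) {
  double d2 = R_PosInf;
  for (int j = s, k = e - 1; j < e; k = j++) {
    const double dd = seg_dist2(x, y, vx[j], vy[j], vx[k], vy[k]);
    if (dd < d2) d2 = dd;
  }
  return d2;
}

// [[Rcpp::export]]
IntegerVector cpp_classify_pairs(NumericVector vx, NumericVector vy,
                                 IntegerVector offsets, IntegerVector inst_cat,
                                 IntegerVector frame_start, IntegerVector frame_end,
                                 IntegerVector pair_frame_pos, NumericVector px,
                                 NumericVector py, double radius, double area_tol,
                                 bool literal) {
  const int n_frames = frame_start.size();
  const int n_pairs = px.size();
  const double* VX = vx.begin();
  const double* VY = vy.begin();

  // per-instance bounding boxes (for the state prefilter)
  const int n_inst = offsets.size() - 1;
  std::vector<double> bx1(n_inst), bx2(n_inst), by1(n_inst), by2(n_inst);
  for (int i = 0; i < n_inst; ++i) {
    double x1 = R_PosInf, x2 = R_NegInf, y1 = R_PosInf, y2 = R_NegInf;
    for (int j = offsets[i]; j < offsets[i + 1]; ++j) {
      if (VX[j] < x1) x1 = VX[j];
      if (VX[j] > x2) x2 = VX[j];
      if (VY[j] < y1) y1 = VY[j];
      if (VY[j] > y2) y2 = VY[j];
    }
    bx1[i] = x1; bx2[i] = x2; by1[i] = y1; by2[i] = y2;
  }

  // lazily computed per-frame object states (aligned to instance rows)
  std::vector<signed char> state(n_inst, -1);
  std::vector<bool> frame_done(n_frames, false);
  const double r2 = radius * radius;

  IntegerVector out(n_pairs);
  for (int p = 0; p < n_pairs; ++p) {
    const int f = pair_frame_pos[p];
    const int s = frame_start[f], e = frame_end[f];
    if (!literal && !frame_done[f]) {
      for (int i = s; i < e; ++i) {
        if (inst_cat[i] != 0) continue; // objects only
        int held = 0;
        for (int t = s; t < e && held < 2; ++t) {
          if (inst_cat[t] != 1) continue;
          if (bx1[i] > bx2[t] || bx2[i] < bx1[t] || by1[i] > by2[t] ||
              by2[i] < by1[t])
            continue;
          std::vector<double> ax, ay, tx, ty;
          for (int j = offsets[i]; j < offsets[i + 1]; ++j) {
            ax.push_back(VX[j]); ay.push_back(VY[j]);
          }
          for (int j = offsets[t]; j < offsets[t + 1]; ++j) {
            tx.push_back(VX[j]); ty.push_back(VY[j]);
          }
          if (clip_area(ax, ay, tx, ty) > area_tol) ++held;
        }
        state[i] = (signed char)held;
      }
      frame_done[f] = true;
    }
    const double x = px[p], y = py[p];
    int obj_state = -1, tools_hit = 0;
    bool any_tool = false;
    for (int i = s; i < e; ++i) {
      if (x < bx1[i] - radius || x > bx2[i] + radius || y < by1[i] - radius ||
          y > by2[i] + radius)
        continue;
      const int ps = offsets[i], pe = offsets[i + 1];
      bool hit = point_in_poly(x, y, VX, VY, ps, pe);
      if (!hit && poly_dist2(x, y, VX, VY, ps, pe) <= r2) hit = true;
      if (!hit) continue;
      if (inst_cat[i] == 0) {
        if (literal) {
          if (obj_state < 0) obj_state = 0;
        } else if ((int)state[i] > obj_state) {
          obj_state = state[i];
        }
      } else {
        any_tool = true;
        ++tools_hit;
      }
    }
    if (literal && obj_state >= 0) obj_state = tools_hit > 2 ? 2 : tools_hit;
    int cat;
    if (obj_state == 1) cat = 0;
    else if (obj_state >= 2) cat = 1;
    else if (obj_state == 0) cat = 2;
    else if (any_tool) cat = 3;
    else cat = 4;
    out[p] = cat;
  }
  return out;
}
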