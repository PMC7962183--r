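// Monte-Carlo photon transport over triangle meshes with a median-split BVH.
// Analog estimator: every surface interaction disposes of the full ray weight
// (absorb) or redirects it (diffuse reflect/transmit), so the energy ledger
// emitted = absorbed + escaped + terminated holds to accumulator precision.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using Rcpp::IntegerMatrix;
using Rcpp::IntegerVector;
using Rcpp::List;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 vsub(const Vec3& a, const Vec3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 vadd(const Vec3& a, const Vec3& b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec3 vscale(const Vec3& a, double s) { return {a.x * s, a.y * s, a.z * s}; }
inline double vdot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 vcross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double vnorm(const Vec3& a) { return std::sqrt(vdot(a, a)); }
inline Vec3 vunit(const Vec3& a) {
  double n = vnorm(a);
  return {a.x / n, a.y / n, a.z / n};
}

// Deterministic uniform doubles in [0,1) from mt19937_64 (the engine is
// standardized; distribution adaptors are not, so we avoid them).
struct Rng {
  std::mt19937_64 eng;
  explicit Rng(std::uint64_t seed) : eng(seed) {}
  double uniform() { return (eng() >> 11) * (1.0 / 9007199254740992.0); }
};

struct Mesh {
  std::vector<Vec3> v0, e1, e2;  // precomputed per-face edges
  std::vector<Vec3> normal;      // unit geometric normal (CCW outward)
  std::vector<int> group;        // 0-based group id per face
  int n_faces = 0;
};

// Moller-Trumbore. Returns t > tmin on hit, else -1.
inline double tri_hit(const Mesh& m, int f, const Vec3& o, const Vec3& d, double tmin) {
  const Vec3& E1 = m.e1[f];
  const Vec3& E2 = m.e2[f];
  Vec3 p = vcross(d, E2);
  double det = vdot(E1, p);
  if (std::fabs(det) < 1e-14) return -1.0;
  double inv = 1.0 / det;
  Vec3 s = vsub(o, m.v0[f]);
  double u = vdot(s, p) * inv;
  if (u < -1e-9 || u > 1.0 + 1e-9) return -1.0;
  Vec3 q = vcross(s, E1);
  double vv = vdot(d, q) * inv;
  if (vv < -1e-9 || u + vv > 1.0 + 1e-9) return -1.0;
  double t = vdot(E2, q) * inv;
  if (t <= tmin) return -1.0;
  return t;
}

struct BVHNode {
  Vec3 lo, hi;
  int left = -1, right = -1;  // internal children
  int start = 0, count = 0;   // leaf range into order[]
};

struct BVH {
  std::vector<BVHNode> nodes;
  std::vector<int> order;
};

struct BuildRef {
  Vec3 lo, hi, centroid;
  int face;
};

int bvh_build(std::vector<BVHNode>& nodes, std::vector<BuildRef>& refs, int start, int end) {
  BVHNode node;
  node.lo = {1e300, 1e300, 1e300};
  node.hi = {-1e300, -1e300, -1e300};
  for (int i = start; i < end; ++i) {
    node.lo.x = std::min(node.lo.x, refs[i].lo.x);
    node.lo.y = std::min(node.lo.y, refs[i].lo.y);
    node.lo.z = std::min(node.lo.z, refs[i].lo.z);
    node.hi.x = std::max(node.hi.x, refs[i].hi.x);
    node.hi.y = std::max(node.hi.y, refs[i].hi.y);
    node.hi.z = std::max(node.hi.z, refs[i].hi.z);
  }
  int idx = (int)nodes.size();
  nodes.push_back(node);
  int n = end - start;
  if (n <= 4) {
    nodes[idx].start = start;
    nodes[idx].count = n;
    return idx;
  }
  Vec3 ext = vsub(node.hi, node.lo);
  int axis = 0;
  if (ext.y > ext.x) axis = 1;
  if (ext.z > (axis == 0 ? ext.x : ext.y)) axis = 2;
  int mid = start + n / 2;
  std::nth_element(refs.begin() + start, refs.begin() + mid, refs.begin() + end,
                   [axis](const BuildRef& a, const BuildRef& b) {
                     double ca = axis == 0 ? a.centroid.x : (axis == 1 ? a.centroid.y : a.centroid.z);
                     double cb = axis == 0 ? b.centroid.x : (axis == 1 ? b.centroid.y : b.centroid.z);
                     return ca < cb;
                   });
  int l = bvh_build(nodes, refs, start, mid);
  int r = bvh_build(nodes, refs, mid, end);
  nodes[idx].left = l;
  nodes[idx].right = r;
  nodes[idx].count = 0;
  return idx;
}

BVH bvh_create(const Mesh& m, const NumericMatrix& verts, const IntegerMatrix& faces) {
  std::vector<BuildRef> refs(m.n_faces);
  for (int f = 0; f < m.n_faces; ++f) {
    Vec3 a = {verts(faces(f, 0), 0), verts(faces(f, 0), 1), verts(faces(f, 0), 2)};
    Vec3 b = {verts(faces(f, 1), 0), verts(faces(f, 1), 1), verts(faces(f, 1), 2)};
    Vec3 c = {verts(faces(f, 2), 0), verts(faces(f, 2), 1), verts(faces(f, 2), 2)};
    BuildRef r;
    r.lo = {std::min({a.x, b.x, c.x}), std::min({a.y, b.y, c.y}), std::min({a.z, b.z, c.z})};
    r.hi = {std::max({a.x, b.x, c.x}), std::max({a.y, b.y, c.y}), std::max({a.z, b.z, c.z})};
    r.centroid = vscale(vadd(vadd(a, b), c), 1.0 / 3.0);
    r.face = f;
    refs[f] = r;
  }
  BVH bvh;
  if (m.n_faces > 0) bvh_build(bvh.nodes, refs, 0, m.n_faces);
  bvh.order.resize(m.n_faces);
  for (int i = 0; i < m.n_faces; ++i) bvh.order[i] = refs[i].face;
  return bvh;
}

inline bool box_hit(const BVHNode& nd, const Vec3& o, const Vec3& inv_d, double tmax) {
  double t0 = 0.0, t1 = tmax;
  double ta = (nd.lo.x - o.x) * inv_d.x, tb = (nd.hi.x - o.x) * inv_d.x;
  if (ta > tb) std::swap(ta, tb);
  t0 = std::max(t0, ta);
  t1 = std::min(t1, tb);
  ta = (nd.lo.y - o.y) * inv_d.y;
  tb = (nd.hi.y - o.y) * inv_d.y;
  if (ta > tb) std::swap(ta, tb);
  t0 = std::max(t0, ta);
  t1 = std::min(t1, tb);
  ta = (nd.lo.z - o.z) * inv_d.z;
  tb = (nd.hi.z - o.z) * inv_d.z;
  if (ta > tb) std::swap(ta, tb);
  t0 = std::max(t0, ta);
  t1 = std::min(t1, tb);
  return t0 <= t1;
}

// Nearest hit via BVH; returns face index or -1, writes t.
inline int bvh_nearest(const Mesh& m, const BVH& bvh, const Vec3& o, const Vec3& d,
                       double tmin, double& t_out) {
  if (bvh.nodes.empty()) return -1;
  Vec3 inv_d = {1.0 / d.x, 1.0 / d.y, 1.0 / d.z};
  double best_t = 1e300;
  int best_f = -1;
  int stack[64];
  int sp = 0;
  stack[sp++] = 0;
  while (sp > 0) {
    const BVHNode& nd = bvh.nodes[stack[--sp]];
    if (!box_hit(nd, o, inv_d, best_t)) continue;
    if (nd.count > 0) {
      for (int i = nd.start; i < nd.start + nd.count; ++i) {
        int f = bvh.order[i];
        double t = tri_hit(m, f, o, d, tmin);
        if (t > 0 && t < best_t) {
          best_t = t;
          best_f = f;
        }
      }
    } else {
      stack[sp++] = nd.left;
      stack[sp++] = nd.right;
    }
  }
  t_out = best_t;
  return best_f;
}

inline int brute_nearest(const Mesh& m, const Vec3& o, const Vec3& d, double tmin, double& t_out) {
  double best_t = 1e300;
  int best_f = -1;
  for (int f = 0; f < m.n_faces; ++f) {
    double t = tri_hit(m, f, o, d, tmin);
    if (t > 0 && t < best_t) {
      best_t = t;
      best_f = f;
    }
  }
  t_out = best_t;
  return best_f;
}

Mesh make_mesh(const NumericMatrix& verts, const IntegerMatrix& faces, const IntegerVector& group) {
  Mesh m;
  m.n_faces = faces.nrow();
  m.v0.resize(m.n_faces);
  m.e1.resize(m.n_faces);
  m.e2.resize(m.n_faces);
  m.normal.resize(m.n_faces);
  m.group.resize(m.n_faces);
  for (int f = 0; f < m.n_faces; ++f) {
    Vec3 a = {verts(faces(f, 0), 0), verts(faces(f, 0), 1), verts(faces(f, 0), 2)};
    Vec3 b = {verts(faces(f, 1), 0), verts(faces(f, 1), 1), verts(faces(f, 1), 2)};
    Vec3 c = {verts(faces(f, 2), 0), verts(faces(f, 2), 1), verts(faces(f, 2), 2)};
    m.v0[f] = a;
    m.e1[f] = vsub(b, a);
    m.e2[f] = vsub(c, a);
    m.normal[f] = vunit(vcross(m.e1[f], m.e2[f]));
    m.group[f] = group.size() ? group[f] : 0;
  }
  return m;
}

// Orthonormal basis with w as third axis.
inline void make_basis(const Vec3& w, Vec3& u, Vec3& v) {
  Vec3 a = std::fabs(w.x) < 0.9 ? Vec3{1, 0, 0} : Vec3{0, 1, 0};
  u = vunit(vcross(a, w));
  v = vcross(w, u);
}

// Truncated-cosine polar angle: pdf(theta) ~ cos(theta) sin(theta) on
// [0, theta_max]; inverse CDF theta = asin(sqrt(u) * sin(theta_max)).
inline Vec3 sample_cone(const Vec3& n, double sin_max, Rng& rng) {
  double st = std::sqrt(rng.uniform()) * sin_max;
  double ct = std::sqrt(std::max(0.0, 1.0 - st * st));
  double phi = 2.0 * M_PI * rng.uniform();
  Vec3 u, v;
  make_basis(n, u, v);
  return vadd(vadd(vscale(u, st * std::cos(phi)), vscale(v, st * std::sin(phi))),
              vscale(n, ct));
}

}  // namespace

// [[Rcpp::export(name = ".cpp_intersect")]]
List cpp_intersect(NumericMatrix verts, IntegerMatrix faces, NumericMatrix origins,
                   NumericMatrix dirs, bool brute) {
  Mesh m = make_mesh(verts, faces, IntegerVector(0));
  BVH bvh;
  if (!brute) bvh = bvh_create(m, verts, faces);
  int n = origins.nrow();
  IntegerVector face_out(n);
  NumericVector t_out(n);
  for (int i = 0; i < n; ++i) {
    Vec3 o = {origins(i, 0), origins(i, 1), origins(i, 2)};
    Vec3 d = vunit(Vec3{dirs(i, 0), dirs(i, 1), dirs(i, 2)});
    double t;
    int f = brute ? brute_nearest(m, o, d, 1e-9, t) : bvh_nearest(m, bvh, o, d, 1e-9, t);
    face_out[i] = f + 1;  // 1-based, 0 = miss
    t_out[i] = f < 0 ? NA_REAL : t;
  }
  return List::create(Rcpp::Named("face") = face_out, Rcpp::Named("t") = t_out);
}

// Single surface interaction, exposed for distributional testing: outcome
// 0 = absorb, 1 = diffuse reflect, 2 = diffuse transmit; scattered
// directions cosine-distributed about the incident-side (reflect) or far
// (transmit) normal.
// [[Rcpp::export(name = ".cpp_scatter")]]
List cpp_scatter(NumericVector normal, NumericVector incident, double R, double T,
                 int n, double seed) {
  if (R < 0 || T < 0 || R + T > 1.0 + 1e-12) Rcpp::stop("optics validation error: need R, T >= 0 and R + T <= 1");
  Rng rng((std::uint64_t)seed);
  Vec3 nv = vunit(Vec3{normal[0], normal[1], normal[2]});
  Vec3 dv = vunit(Vec3{incident[0], incident[1], incident[2]});
  Vec3 n_refl = vdot(dv, nv) < 0 ? nv : vscale(nv, -1.0);
  IntegerVector outcome(n);
  NumericMatrix dir(n, 3);
  for (int i = 0; i < n; ++i) {
    double u = rng.uniform();
    Vec3 d = {NA_REAL, NA_REAL, NA_REAL};
    if (u < R) {
      outcome[i] = 1;
      d = sample_cone(n_refl, 1.0, rng);
    } else if (u < R + T) {
      outcome[i] = 2;
      d = sample_cone(vscale(n_refl, -1.0), 1.0, rng);
    } else {
      outcome[i] = 0;
    }
    dir(i, 0) = d.x;
    dir(i, 1) = d.y;
    dir(i, 2) = d.z;
  }
  return List::create(Rcpp::Named("outcome") = outcome, Rcpp::Named("direction") = dir);
}

// emitters: columns px py pz nx ny nz ux uy uz vx vy vz half_angle_deg power
// (u, v are half-extent vectors of an area emitter; zero vectors = point chip)
// sensors: columns cx cy cz radius (horizontal disk, counts downward flux)
// [[Rcpp::export(name = ".cpp_trace")]]
List cpp_trace(NumericMatrix verts, IntegerMatrix faces, IntegerVector face_group,
               int n_groups, NumericVector group_R, NumericVector group_T,
               NumericMatrix emitters, NumericMatrix sensors, double n_rays,
               int max_bounces, int n_batches, double seed) {
  Mesh m = make_mesh(verts, faces, face_group);
  BVH bvh = bvh_create(m, verts, faces);
  Rng rng((std::uint64_t)seed);

  int n_emit = emitters.nrow();
  int n_sens = sensors.nrow();
  double p_tot = 0.0;
  std::vector<double> cum(n_emit);
  for (int e = 0; e < n_emit; ++e) {
    p_tot += emitters(e, 13);
    cum[e] = p_tot;
  }
  if (p_tot <= 0.0) Rcpp::stop("total emitter power must be positive");
  long n = (long)n_rays;
  double w = p_tot / (double)n;

  std::vector<long double> absorbed((size_t)n_groups * n_batches, 0.0L);
  std::vector<long double> sens_flux(std::max(1, n_sens), 0.0L);
  long double escaped = 0.0L, terminated = 0.0L;
  long n_abs = 0, n_esc = 0, n_term = 0;
  const double eps_t = 1e-6;

  for (long i = 0; i < n; ++i) {
    int batch = (int)((i * (long)n_batches) / n);
    // pick emitter proportional to power
    double r = rng.uniform() * p_tot;
    int e = (int)(std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
    if (e >= n_emit) e = n_emit - 1;
    Vec3 pos = {emitters(e, 0), emitters(e, 1), emitters(e, 2)};
    Vec3 nrm = vunit(Vec3{emitters(e, 3), emitters(e, 4), emitters(e, 5)});
    Vec3 ue = {emitters(e, 6), emitters(e, 7), emitters(e, 8)};
    Vec3 ve = {emitters(e, 9), emitters(e, 10), emitters(e, 11)};
    if (vnorm(ue) > 0 || vnorm(ve) > 0) {
      double a = 2.0 * rng.uniform() - 1.0, b = 2.0 * rng.uniform() - 1.0;
      pos = vadd(pos, vadd(vscale(ue, a), vscale(ve, b)));
    }
    double sin_max = std::sin(emitters(e, 12) * M_PI / 180.0);
    Vec3 o = pos;
    Vec3 d = sample_cone(nrm, sin_max, rng);

    bool alive = true;
    int fate = -1;  // 0 absorb, 1 escape, 2 terminate
    int fate_group = -1;
    for (int bounce = 0; bounce <= max_bounces && alive; ++bounce) {
      double t;
      int f = bvh_nearest(m, bvh, o, d, eps_t, t);
      // sensor crossings along this free path (downward through the disk)
      if (n_sens > 0 && d.z < 0) {
        double t_end = f < 0 ? 1e300 : t;
        for (int s = 0; s < n_sens; ++s) {
          double ts = (sensors(s, 2) - o.z) / d.z;
          if (ts > eps_t && ts < t_end) {
            double dx = o.x + ts * d.x - sensors(s, 0);
            double dy = o.y + ts * d.y - sensors(s, 1);
            if (dx * dx + dy * dy <= sensors(s, 3) * sensors(s, 3)) sens_flux[s] += w;
          }
        }
      }
      if (f < 0) {
        fate = 1;
        alive = false;
        break;
      }
      if (bounce == max_bounces) {
        fate = 2;
        alive = false;
        break;
      }
      int g = m.group[f];
      double R = group_R[g], T = group_T[g];
      double u = rng.uniform();
      Vec3 hitp = vadd(o, vscale(d, t));
      if (u < R) {  // diffuse reflect into incident-side hemisphere
        Vec3 ns = vdot(d, m.normal[f]) < 0 ? m.normal[f] : vscale(m.normal[f], -1.0);
        d = sample_cone(ns, 1.0, rng);
        o = hitp;
      } else if (u < R + T) {  // diffuse transmit into far hemisphere
        Vec3 ns = vdot(d, m.normal[f]) < 0 ? vscale(m.normal[f], -1.0) : m.normal[f];
        d = sample_cone(ns, 1.0, rng);
        o = hitp;
      } else {  // absorb
        fate = 0;
        fate_group = g;
        alive = false;
      }
    }
    if (fate == 0) {
      absorbed[(size_t)fate_group * n_batches + batch] += w;
      ++n_abs;
    } else if (fate == 1) {
      escaped += w;
      ++n_esc;
    } else {
      terminated += w;
      ++n_term;
    }
  }

  NumericMatrix ab(n_groups, n_batches);
  NumericVector ab_tot(n_groups);
  for (int g = 0; g < n_groups; ++g) {
    long double s = 0.0L;
    for (int b = 0; b < n_batches; ++b) {
      ab(g, b) = (double)absorbed[(size_t)g * n_batches + b];
      s += absorbed[(size_t)g * n_batches + b];
    }
    ab_tot[g] = (double)s;
  }
  NumericVector sf(n_sens);
  for (int s = 0; s < n_sens; ++s) sf[s] = (double)sens_flux[s];
  return List::create(
      Rcpp::Named("absorbed") = ab_tot, Rcpp::Named("absorbed_batch") = ab,
      Rcpp::Named("escaped") = (double)escaped, Rcpp::Named("terminated") = (double)terminated,
      Rcpp::Named("sensor_flux") = sf,
      Rcpp::Named("emitted") = (double)n * w,
      Rcpp::Named("counts") = IntegerVector::create(
          Rcpp::Named("absorbed") = (int)n_abs, Rcpp::Named("escaped") = (int)n_esc,
          Rcpp::Named("terminated") = (int)n_term));
}
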