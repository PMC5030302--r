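// Forward Monte Carlo ray tracer for triangulated canopies.
//
// Rays are launched downward through the top of an axis-aligned box whose
// lateral faces are periodic: a ray leaving one side re-enters from the
// opposite side with an unchanged direction.  The ground (z = 0) absorbs,
// the top face lets rays escape.  Leaf hits tally INCIDENT flux to the face
// (both sides), then the photon is absorbed, reflected (Lambertian, incident
// side) or transmitted (Lambertian, far side) with the leaf's optical
// probabilities.  Rays are split into independent batches so the caller can
// form Monte Carlo standard errors.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// ---------------------------------------------------------------------------
// Minimal deterministic RNG (PCG32): results must not depend on R's RNG or
// on thread scheduling.
struct Pcg32 {
  uint64_t state;
  uint64_t inc;
  Pcg32(uint64_t seed, uint64_t seq) : state(0u), inc((seq << 1u) | 1u) {
    next();
    state += seed;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = static_cast<uint32_t>(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = static_cast<uint32_t>(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  double uni() {  // in [0, 1)
    return next() * 2.3283064365386963e-10;
  }
};

struct Vec3 {
  double x, y, z;
};
inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec3 operator-(Vec3 a, Vec3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 operator*(Vec3 a, double s) { return {a.x * s, a.y * s, a.z * s}; }
inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(Vec3 a, Vec3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double norm(Vec3 a) { return std::sqrt(dot(a, a)); }
inline Vec3 normalize(Vec3 a) {
  double n = norm(a);
  return {a.x / n, a.y / n, a.z / n};
}

// ---------------------------------------------------------------------------
// Triangle soup + BVH (median split on centroid of the longest axis).
struct TriSoup {
  std::vector<Vec3> v0, e1, e2;  // v0, v1 - v0, v2 - v0
  std::vector<Vec3> cmin, cmax;  // per-triangle AABB
};

struct BVHNode {
  double bmin[3], bmax[3];
  int left = -1, right = -1;  // internal children
  int start = 0, count = 0;   // leaf: range into order[]
};

struct BVH {
  std::vector<BVHNode> nodes;
  std::vector<int> order;
};

void node_bounds(const TriSoup &tris, const std::vector<int> &order, int start,
                 int count, BVHNode &node) {
  for (int k = 0; k < 3; ++k) {
    node.bmin[k] = R_PosInf;
    node.bmax[k] = R_NegInf;
  }
  for (int i = start; i < start + count; ++i) {
    const Vec3 &lo = tris.cmin[order[i]];
    const Vec3 &hi = tris.cmax[order[i]];
    node.bmin[0] = std::min(node.bmin[0], lo.x);
    node.bmin[1] = std::min(node.bmin[1], lo.y);
    node.bmin[2] = std::min(node.bmin[2], lo.z);
    node.bmax[0] = std::max(node.bmax[0], hi.x);
    node.bmax[1] = std::max(node.bmax[1], hi.y);
    node.bmax[2] = std::max(node.bmax[2], hi.z);
  }
}

int build_node(BVH &bvh, const TriSoup &tris, const std::vector<Vec3> &cent,
               int start, int count) {
  int idx = static_cast<int>(bvh.nodes.size());
  bvh.nodes.push_back(BVHNode());
  node_bounds(tris, bvh.order, start, count, bvh.nodes[idx]);
  if (count <= 4) {
    bvh.nodes[idx].start = start;
    bvh.nodes[idx].count = count;
    return idx;
  }
  double ext[3] = {bvh.nodes[idx].bmax[0] - bvh.nodes[idx].bmin[0],
                   bvh.nodes[idx].bmax[1] - bvh.nodes[idx].bmin[1],
                   bvh.nodes[idx].bmax[2] - bvh.nodes[idx].bmin[2]};
  int axis = 0;
  if (ext[1] > ext[axis]) axis = 1;
  if (ext[2] > ext[axis]) axis = 2;
  int mid = start + count / 2;
  std::nth_element(bvh.order.begin() + start, bvh.order.begin() + mid,
                   bvh.order.begin() + start + count, [&](int a, int b) {
                     double ca = axis == 0 ? cent[a].x : (axis == 1 ? cent[a].y : cent[a].z);
                     double cb = axis == 0 ? cent[b].x : (axis == 1 ? cent[b].y : cent[b].z);
                     return ca < cb;
                   });
  int left = build_node(bvh, tris, cent, start, mid - start);
  int right = build_node(bvh, tris, cent, mid, start + count - mid);
  bvh.nodes[idx].left = left;
  bvh.nodes[idx].right = right;
  bvh.nodes[idx].count = 0;
  return idx;
}

BVH build_bvh(const TriSoup &tris) {
  BVH bvh;
  int n = static_cast<int>(tris.v0.size());
  bvh.order.resize(n);
  std::vector<Vec3> cent(n);
  for (int i = 0; i < n; ++i) {
    bvh.order[i] = i;
    cent[i] = (tris.cmin[i] + tris.cmax[i]) * 0.5;
  }
  if (n > 0) build_node(bvh, tris, cent, 0, n);
  return bvh;
}

// Moller-Trumbore, double-sided (no backface culling).
inline bool tri_hit(const TriSoup &tris, int i, Vec3 o, Vec3 d, double tmin,
                    double tmax, double &t_out) {
  const Vec3 &e1 = tris.e1[i];
  const Vec3 &e2 = tris.e2[i];
  Vec3 p = cross(d, e2);
  double det = dot(e1, p);
  if (std::fabs(det) < 1e-14) return false;
  double inv = 1.0 / det;
  Vec3 s = o - tris.v0[i];
  double u = dot(s, p) * inv;
  if (u < 0.0 || u > 1.0) return false;
  Vec3 q = cross(s, e1);
  double v = dot(d, q) * inv;
  if (v < 0.0 || u + v > 1.0) return false;
  double t = dot(e2, q) * inv;
  if (t <= tmin || t >= tmax) return false;
  t_out = t;
  return true;
}

inline bool aabb_hit(const BVHNode &n, Vec3 o, Vec3 inv_d, double tmax) {
  double t0 = 0.0, t1 = tmax;
  const double *bmin = n.bmin;
  const double *bmax = n.bmax;
  const double os[3] = {o.x, o.y, o.z};
  const double id[3] = {inv_d.x, inv_d.y, inv_d.z};
  for (int k = 0; k < 3; ++k) {
    double ta = (bmin[k] - os[k]) * id[k];
    double tb = (bmax[k] - os[k]) * id[k];
    if (ta > tb) std::swap(ta, tb);
    if (ta > t0) t0 = ta;
    if (tb < t1) t1 = tb;
    if (t0 > t1) return false;
  }
  return true;
}

// Nearest hit in (tmin, tmax); returns face index or -1.
int nearest_hit(const TriSoup &tris, const BVH &bvh, Vec3 o, Vec3 d,
                double tmin, double tmax, double &t_hit) {
  if (bvh.nodes.empty()) return -1;
  Vec3 inv_d = {1.0 / d.x, 1.0 / d.y, 1.0 / d.z};
  int stack[64];
  int sp = 0;
  stack[sp++] = 0;
  int best = -1;
  double tbest = tmax;
  while (sp > 0) {
    const BVHNode &node = bvh.nodes[stack[--sp]];
    if (!aabb_hit(node, o, inv_d, tbest)) continue;
    if (node.left < 0) {
      for (int i = node.start; i < node.start + node.count; ++i) {
        int f = bvh.order[i];
        double t;
        if (tri_hit(tris, f, o, d, tmin, tbest, t)) {
          tbest = t;
          best = f;
        }
      }
    } else {
      stack[sp++] = node.left;
      stack[sp++] = node.right;
    }
  }
  t_hit = tbest;
  return best;
}

TriSoup make_soup(const NumericMatrix &V, const IntegerMatrix &F) {
  TriSoup tris;
  int m = F.nrow();
  tris.v0.resize(m);
  tris.e1.resize(m);
  tris.e2.resize(m);
  tris.cmin.resize(m);
  tris.cmax.resize(m);
  for (int i = 0; i < m; ++i) {
    Vec3 a = {V(F(i, 0), 0), V(F(i, 0), 1), V(F(i, 0), 2)};
    Vec3 b = {V(F(i, 1), 0), V(F(i, 1), 1), V(F(i, 1), 2)};
    Vec3 c = {V(F(i, 2), 0), V(F(i, 2), 1), V(F(i, 2), 2)};
    tris.v0[i] = a;
    tris.e1[i] = b - a;
    tris.e2[i] = c - a;
    tris.cmin[i] = {std::min({a.x, b.x, c.x}), std::min({a.y, b.y, c.y}),
                    std::min({a.z, b.z, c.z})};
    tris.cmax[i] = {std::max({a.x, b.x, c.x}), std::max({a.y, b.y, c.y}),
                    std::max({a.z, b.z, c.z})};
  }
  return tris;
}

// Cosine-weighted hemisphere direction about unit axis n.
Vec3 cosine_hemisphere(Vec3 n, Pcg32 &rng) {
  double u1 = rng.uni(), u2 = rng.uni();
  double r = std::sqrt(u1);
  double phi = 2.0 * M_PI * u2;
  double lx = r * std::cos(phi);
  double ly = r * std::sin(phi);
  double lz = std::sqrt(std::max(0.0, 1.0 - u1));
  // orthonormal basis around n
  Vec3 t = std::fabs(n.x) < 0.9 ? Vec3{1, 0, 0} : Vec3{0, 1, 0};
  Vec3 b1 = normalize(cross(n, t));
  Vec3 b2 = cross(n, b1);
  return normalize(b1 * lx + b2 * ly + n * lz);
}

struct TraceState {
  const TriSoup *tris;
  const BVH *bvh;
  double xmin, xmax, ymin, ymax, ztop;
  double rho, tau;
  int max_bounces;
  double *faceE;  // nfaces x nbatches, column-major
  int nfaces;
  double absorbed, ground, escaped;
};

// Follow one photon of weight w; tallies incident flux into batch column col.
void follow_ray(TraceState &st, Vec3 o, Vec3 d, double w, int col, Pcg32 &rng) {
  const double EPS_T = 1e-9;
  const double W = st.xmax - st.xmin;
  const double H = st.ymax - st.ymin;
  int bounces = 0;
  for (int seg = 0; seg < 100000; ++seg) {
    // distance to lateral exit
    double t_side = R_PosInf;
    if (d.x > 1e-13) t_side = std::min(t_side, (st.xmax - o.x) / d.x);
    else if (d.x < -1e-13) t_side = std::min(t_side, (st.xmin - o.x) / d.x);
    if (d.y > 1e-13) t_side = std::min(t_side, (st.ymax - o.y) / d.y);
    else if (d.y < -1e-13) t_side = std::min(t_side, (st.ymin - o.y) / d.y);
    // distance to vertical exit (ground absorbs, top escapes)
    double t_vert = R_PosInf;
    bool down = false;
    if (d.z < -1e-13) { t_vert = (0.0 - o.z) / d.z; down = true; }
    else if (d.z > 1e-13) { t_vert = (st.ztop - o.z) / d.z; }
    double t_lim = std::min(t_side, t_vert);

    double t_hit;
    int f = nearest_hit(*st.tris, *st.bvh, o, d, EPS_T, t_lim, t_hit);
    if (f >= 0) {
      st.faceE[col * st.nfaces + f] += w;  // incident tally, both sides
      if (bounces >= st.max_bounces) { st.absorbed += w; return; }
      ++bounces;
      double u = rng.uni();
      if (u < 1.0 - st.rho - st.tau) { st.absorbed += w; return; }
      Vec3 gn = normalize(cross(st.tris->e1[f], st.tris->e2[f]));
      // incident-side normal opposes the ray
      Vec3 n_in = dot(gn, d) < 0.0 ? gn : gn * -1.0;
      Vec3 axis = (u < 1.0 - st.tau) ? n_in : n_in * -1.0;  // reflect : transmit
      Vec3 nd = cosine_hemisphere(axis, rng);
      o = o + d * t_hit + nd * 1e-8;
      d = nd;
      continue;
    }
    if (t_side < t_vert) {  // periodic wrap through a lateral face
      o = o + d * (t_side + 1e-9);
      if (o.x >= st.xmax) o.x -= W;
      else if (o.x <= st.xmin) o.x += W;
      if (o.y >= st.ymax) o.y -= H;
      else if (o.y <= st.ymin) o.y += H;
      continue;
    }
    if (down) st.ground += w; else st.escaped += w;
    return;
  }
  st.absorbed += w;  // safety cap on path length
}

}  // namespace

// [[Rcpp::export(name = ".trace_cpp")]]
List trace_cpp(NumericMatrix V, IntegerMatrix F, NumericVector box,
               NumericVector photon_dir, double direct_horizontal,
               double diffuse_horizontal, double rho, double tau,
               int max_bounces, int n_direct, int n_diffuse, int n_batches,
               double seed) {
  if (box.size() != 5) stop("box must be (xmin, xmax, ymin, ymax, ztop)");
  const double xmin = box[0], xmax = box[1], ymin = box[2], ymax = box[3],
               ztop = box[4];
  if (!(xmax > xmin) || !(ymax > ymin) || !(ztop > 0))
    stop("ray-tracing box is degenerate");
  if (n_batches < 1) stop("n_batches must be >= 1");
  const double area = (xmax - xmin) * (ymax - ymin);
  const int m = F.nrow();

  TriSoup tris = make_soup(V, F);
  BVH bvh = build_bvh(tris);

  NumericMatrix faceE(m, n_batches);
  NumericVector absorbed(n_batches), ground(n_batches), escaped(n_batches),
      incident(n_batches);

  TraceState st;
  st.tris = &tris;
  st.bvh = &bvh;
  st.xmin = xmin; st.xmax = xmax; st.ymin = ymin; st.ymax = ymax; st.ztop = ztop;
  st.rho = rho; st.tau = tau;
  st.max_bounces = max_bounces;
  st.faceE = faceE.begin();
  st.nfaces = m;

  Vec3 sun = {photon_dir[0], photon_dir[1], photon_dir[2]};
  bool do_direct = direct_horizontal > 0 && sun.z < -1e-9 && n_direct > 0;
  bool do_diffuse = diffuse_horizontal > 0 && n_diffuse > 0;
  if (do_direct) sun = normalize(sun);

  const double D_tot = direct_horizontal * area;
  const double S_tot = diffuse_horizontal * area;

  for (int b = 0; b < n_batches; ++b) {
    Pcg32 rng(static_cast<uint64_t>(seed), 77u + static_cast<uint64_t>(b));
    st.absorbed = st.ground = st.escaped = 0.0;
    double inc = 0.0;
    if (do_direct) {
      int nb = std::max(1, n_direct / n_batches);
      double w = D_tot / nb;
      for (int r = 0; r < nb; ++r) {
        Vec3 o = {xmin + rng.uni() * (xmax - xmin),
                  ymin + rng.uni() * (ymax - ymin), ztop};
        follow_ray(st, o, sun, w, b, rng);
      }
      inc += D_tot;
    }
    if (do_diffuse) {
      int nb = std::max(1, n_diffuse / n_batches);
      double w = S_tot / nb;
      for (int r = 0; r < nb; ++r) {
        Vec3 o = {xmin + rng.uni() * (xmax - xmin),
                  ymin + rng.uni() * (ymax - ymin), ztop};
        Vec3 d = cosine_hemisphere({0, 0, -1}, rng);
        follow_ray(st, o, d, w, b, rng);
      }
      inc += S_tot;
    }
    absorbed[b] = st.absorbed;
    ground[b] = st.ground;
    escaped[b] = st.escaped;
    incident[b] = inc;
  }

  return List::create(Named("face_energy") = faceE,
                      Named("incident") = incident,
                      Named("absorbed") = absorbed,
                      Named("escaped") = escaped,
                      Named("ground") = ground,
                      Named("box_area") = area);
}

// First-hit query used to validate the BVH against a plain all-faces
// intersector written in R.  Returns 1-based face index (0 = miss) and t.
// [[Rcpp::export(name = ".first_hit_cpp")]]
List first_hit_cpp(NumericMatrix V, IntegerMatrix F, NumericMatrix origins,
                   NumericMatrix dirs) {
  TriSoup tris = make_soup(V, F);
  BVH bvh = build_bvh(tris);
  int n = origins.nrow();
  IntegerVector face(n);
  NumericVector tvals(n);
  for (int i = 0; i < n; ++i) {
    Vec3 o = {origins(i, 0), origins(i, 1), origins(i, 2)};
    Vec3 d = {dirs(i, 0), dirs(i, 1), dirs(i, 2)};
    double t;
    int f = nearest_hit(tris, bvh, o, d, 1e-9, R_PosInf, t);
    face[i] = f + 1;
    tvals[i] = f >= 0 ? t : NA_REAL;
  }
  return List::create(Named("face") = face, Named("t") = tvals);
}
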