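#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <cstdint>

// 3-D convex hull volume by the quickhull algorithm (volume only, no facet
// output). Points within `eps` of the current hull are treated as interior,
// so the result is a (very slightly) inner approximation -- consistent with
// the mesh-overlap method, which is itself an inner approximation.

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return Vec3{a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return Vec3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

struct Face {
  int v[3];              // vertex indices, outward CCW
  int nb[3];             // neighbour across edge (v[i], v[(i+1)%3])
  Vec3 n;                // unit outward normal
  double off;            // n . x = off on the supporting plane
  std::vector<int> pts;  // unassigned points strictly outside this face
  int far_pt;
  double far_d;
  bool alive;
};

class Hull {
public:
  Hull(const std::vector<Vec3> &p, double eps) : pts_(p), eps_(eps) {}

  // returns hull volume; 0 for degenerate input
  double build() {
    const int n = static_cast<int>(pts_.size());
    if (n < 4) return 0.0;
    if (!init_simplex()) return 0.0;
    assign_initial();

    // faces awaiting processing
    std::vector<int> stack;
    for (int f = 0; f < (int)faces_.size(); ++f)
      if (!faces_[f].pts.empty()) stack.push_back(f);

    std::int64_t guard = 12LL * n + 4096;
    while (!stack.empty()) {
      if (--guard < 0) break;  // safety net; never hit in practice
      int fi = stack.back();
      stack.pop_back();
      if (!faces_[fi].alive || faces_[fi].pts.empty()) continue;
      int p = faces_[fi].far_pt;

      // visible set by BFS over neighbours
      std::vector<int> visible;
      std::vector<char> seen(faces_.size(), 0);
      visible.push_back(fi);
      seen[fi] = 1;
      struct HEdge { int a, b, outside; };
      std::vector<HEdge> horizon;
      for (size_t k = 0; k < visible.size(); ++k) {
        Face &f = faces_[visible[k]];
        for (int e = 0; e < 3; ++e) {
          int g = f.nb[e];
          if (seen[g]) continue;
          if (dist(faces_[g], p) > eps_) {
            seen[g] = 1;
            visible.push_back(g);
          } else {
            // horizon edge, oriented as in the visible face
            horizon.push_back(HEdge{f.v[e], f.v[(e + 1) % 3], g});
          }
        }
      }
      // mark a neighbour seen only through a non-horizon path
      // (handled implicitly: duplicates suppressed by `seen`)

      // gather candidate points from visible faces
      std::vector<int> cand;
      for (int vi : visible) {
        Face &f = faces_[vi];
        for (int q : f.pts)
          if (q != p) cand.push_back(q);
        f.pts.clear();
        f.alive = false;
      }

      // build the new cone of faces
      std::vector<int> fresh;
      fresh.reserve(horizon.size());
      for (const HEdge &h : horizon) {
        int nf = make_face(h.a, h.b, p);
        faces_[nf].nb[0] = h.outside;  // edge (a,b) borders the kept face
        // patch the kept face's pointer back to the new face
        Face &out = faces_[h.outside];
        for (int e = 0; e < 3; ++e) {
          int oa = out.v[e], ob = out.v[(e + 1) % 3];
          if ((oa == h.a && ob == h.b) || (oa == h.b && ob == h.a)) {
            out.nb[e] = nf;
            break;
          }
        }
        fresh.push_back(nf);
      }
      // link new faces to each other across the edges that touch p;
      // the horizon is a loop, so match edge (b, p) to edge (p, b)
      link_fresh(fresh, p);

      // redistribute candidates
      for (int q : cand) {
        double best = eps_;
        int bestf = -1;
        for (int nf : fresh) {
          double d = dist(faces_[nf], q);
          if (d > best) {
            best = d;
            bestf = nf;
          }
        }
        if (bestf >= 0) {
          Face &f = faces_[bestf];
          f.pts.push_back(q);
          if (best > f.far_d) {
            f.far_d = best;
            f.far_pt = q;
          }
        }
      }
      for (int nf : fresh)
        if (!faces_[nf].pts.empty()) stack.push_back(nf);
    }
    return volume();
  }

private:
  const std::vector<Vec3> &pts_;
  double eps_;
  std::vector<Face> faces_;
  Vec3 interior_;

  double dist(const Face &f, int p) const { return dot(f.n, pts_[p]) - f.off; }

  int make_face(int a, int b, int c) {
    Face f;
    f.v[0] = a; f.v[1] = b; f.v[2] = c;
    f.nb[0] = f.nb[1] = f.nb[2] = -1;
    Vec3 nrm = cross(sub(pts_[b], pts_[a]), sub(pts_[c], pts_[a]));
    double ln = norm(nrm);
    if (ln > 0) { nrm.x /= ln; nrm.y /= ln; nrm.z /= ln; }
    f.n = nrm;
    f.off = dot(nrm, pts_[a]);
    if (dot(nrm, interior_) - f.off > 0) {  // flip to face outward
      std::swap(f.v[1], f.v[2]);
      f.n.x = -f.n.x; f.n.y = -f.n.y; f.n.z = -f.n.z;
      f.off = -f.off;
    }
    f.far_pt = -1;
    f.far_d = eps_;
    f.alive = true;
    faces_.push_back(f);
    return static_cast<int>(faces_.size()) - 1;
  }

  void link_fresh(const std::vector<int> &fresh, int p) {
    // brute-force edge matching among the new cone faces (small sets)
    for (size_t i = 0; i < fresh.size(); ++i) {
      Face &fi = faces_[fresh[i]];
      for (int e = 0; e < 3; ++e) {
        if (fi.nb[e] >= 0) continue;
        int a = fi.v[e], b = fi.v[(e + 1) % 3];
        for (size_t j = 0; j < fresh.size(); ++j) {
          if (i == j) continue;
          Face &fj = faces_[fresh[j]];
          for (int e2 = 0; e2 < 3; ++e2) {
            int c = fj.v[e2], d = fj.v[(e2 + 1) % 3];
            if ((a == c && b == d) || (a == d && b == c)) {
              fi.nb[e] = fresh[j];
              fj.nb[e2] = fresh[i];
            }
          }
        }
      }
    }
    (void)p;
  }

  bool init_simplex() {
    const int n = static_cast<int>(pts_.size());
    // extreme points along coordinate axes
    int ext[6] = {0, 0, 0, 0, 0, 0};
    for (int i = 1; i < n; ++i) {
      if (pts_[i].x < pts_[ext[0]].x) ext[0] = i;
      if (pts_[i].x > pts_[ext[1]].x) ext[1] = i;
      if (pts_[i].y < pts_[ext[2]].y) ext[2] = i;
      if (pts_[i].y > pts_[ext[3]].y) ext[3] = i;
      if (pts_[i].z < pts_[ext[4]].z) ext[4] = i;
      if (pts_[i].z > pts_[ext[5]].z) ext[5] = i;
    }
    int p0 = -1, p1 = -1;
    double dmax = -1;
    for (int i = 0; i < 6; ++i)
      for (int j = i + 1; j < 6; ++j) {
        double d = norm(sub(pts_[ext[i]], pts_[ext[j]]));
        if (d > dmax) { dmax = d; p0 = ext[i]; p1 = ext[j]; }
      }
    if (dmax <= eps_) return false;
    // farthest from the line p0-p1
    Vec3 dir = sub(pts_[p1], pts_[p0]);
    double ln = norm(dir);
    dir.x /= ln; dir.y /= ln; dir.z /= ln;
    int p2 = -1;
    dmax = eps_;
    for (int i = 0; i < n; ++i) {
      Vec3 w = sub(pts_[i], pts_[p0]);
      double t = dot(w, dir);
      Vec3 perp{w.x - t * dir.x, w.y - t * dir.y, w.z - t * dir.z};
      double d = norm(perp);
      if (d > dmax) { dmax = d; p2 = i; }
    }
    if (p2 < 0) return false;
    // farthest from the plane p0-p1-p2
    Vec3 nrm = cross(sub(pts_[p1], pts_[p0]), sub(pts_[p2], pts_[p0]));
    double lnn = norm(nrm);
    nrm.x /= lnn; nrm.y /= lnn; nrm.z /= lnn;
    double off = dot(nrm, pts_[p0]);
    int p3 = -1;
    dmax = eps_;
    for (int i = 0; i < n; ++i) {
      double d = std::fabs(dot(nrm, pts_[i]) - off);
      if (d > dmax) { dmax = d; p3 = i; }
    }
    if (p3 < 0) return false;

    interior_ = Vec3{(pts_[p0].x + pts_[p1].x + pts_[p2].x + pts_[p3].x) / 4.0,
                     (pts_[p0].y + pts_[p1].y + pts_[p2].y + pts_[p3].y) / 4.0,
                     (pts_[p0].z + pts_[p1].z + pts_[p2].z + pts_[p3].z) / 4.0};

    int f0 = make_face(p0, p1, p2);
    int f1 = make_face(p0, p1, p3);
    int f2 = make_face(p0, p2, p3);
    int f3 = make_face(p1, p2, p3);
    int fids[4] = {f0, f1, f2, f3};
    // neighbour links by brute-force matching (4 faces)
    for (int i = 0; i < 4; ++i)
      for (int e = 0; e < 3; ++e) {
        Face &fi = faces_[fids[i]];
        int a = fi.v[e], b = fi.v[(e + 1) % 3];
        for (int j = 0; j < 4; ++j) {
          if (i == j) continue;
          Face &fj = faces_[fids[j]];
          for (int e2 = 0; e2 < 3; ++e2) {
            int c = fj.v[e2], d = fj.v[(e2 + 1) % 3];
            if ((a == c && b == d) || (a == d && b == c)) fi.nb[e] = fids[j];
          }
        }
      }
    used_[0] = p0; used_[1] = p1; used_[2] = p2; used_[3] = p3;
    return true;
  }

  void assign_initial() {
    const int n = static_cast<int>(pts_.size());
    for (int q = 0; q < n; ++q) {
      if (q == used_[0] || q == used_[1] || q == used_[2] || q == used_[3])
        continue;
      double best = eps_;
      int bestf = -1;
      for (int f = 0; f < (int)faces_.size(); ++f) {
        double d = dist(faces_[f], q);
        if (d > best) { best = d; bestf = f; }
      }
      if (bestf >= 0) {
        Face &f = faces_[bestf];
        f.pts.push_back(q);
        if (best > f.far_d) { f.far_d = best; f.far_pt = q; }
      }
    }
  }

  double volume() const {
    double v = 0.0;
    for (const Face &f : faces_) {
      if (!f.alive) continue;
      Vec3 a = sub(pts_[f.v[0]], interior_);
      Vec3 b = sub(pts_[f.v[1]], interior_);
      Vec3 c = sub(pts_[f.v[2]], interior_);
      v += dot(a, cross(b, c));
    }
    return v / 6.0;
  }

  int used_[4];
};

}  // namespace

// [[Rcpp::export(name = ".qhull_volume")]]
double qhull_volume(Rcpp::NumericMatrix pts) {
  const int n = pts.nrow();
  if (pts.ncol() != 3) Rcpp::stop("points must be an n x 3 matrix");
  if (n < 4) return 0.0;
  std::vector<Vec3> p(n);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    p[i] = Vec3{pts(i, 0), pts(i, 1), pts(i, 2)};
    double c[3] = {p[i].x, p[i].y, p[i].z};
    for (int k = 0; k < 3; ++k) {
      if (c[k] < lo[k]) lo[k] = c[k];
      if (c[k] > hi[k]) hi[k] = c[k];
    }
  }
  double extent = 0.0;
  for (int k = 0; k < 3; ++k) extent = std::max(extent, hi[k] - lo[k]);
  if (!(extent > 0) || !std::isfinite(extent)) return 0.0;
  double eps = 1e-10 * extent;
  Hull h(p, eps);
  return h.build();
}
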