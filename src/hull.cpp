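// Incremental 3D convex hull (quickhull-style) returning hull vertex indices.
// Inputs are voxel-centre point clouds (up to a few 1e5 points); exactness to
// floating tolerance is sufficient because downstream steps average vertices
// inside a millimetre-scale band.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Face {
  int a, b, c;            // vertex indices, counter-clockwise seen from outside
  double n[3];            // outward unit normal
  double d;               // plane offset: n . x = d
  std::vector<int> outside;
  bool alive;
};

inline void sub(const double* p, const double* q, double* out) {
  out[0] = p[0] - q[0]; out[1] = p[1] - q[1]; out[2] = p[2] - q[2];
}
inline void cross(const double* u, const double* v, double* out) {
  out[0] = u[1] * v[2] - u[2] * v[1];
  out[1] = u[2] * v[0] - u[0] * v[2];
  out[2] = u[0] * v[1] - u[1] * v[0];
}
inline double dot(const double* u, const double* v) {
  return u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
}

class Hull {
public:
  Hull(const NumericMatrix& pts) : np_(pts.nrow()) {
    P_.resize(3 * np_);
    for (int i = 0; i < np_; ++i) {
      P_[3 * i] = pts(i, 0); P_[3 * i + 1] = pts(i, 1); P_[3 * i + 2] = pts(i, 2);
    }
    double lo[3], hi[3];
    for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
    for (int i = 0; i < np_; ++i)
      for (int k = 0; k < 3; ++k) {
        double v = P_[3 * i + k];
        if (v < lo[k]) lo[k] = v;
        if (v > hi[k]) hi[k] = v;
      }
    double diag = 0;
    for (int k = 0; k < 3; ++k) diag += (hi[k] - lo[k]) * (hi[k] - lo[k]);
    eps_ = 1e-9 * (std::sqrt(diag) + 1.0);
  }

  const double* pt(int i) const { return &P_[3 * i]; }

  double dist(const Face& f, int i) const { return dot(f.n, pt(i)) - f.d; }

  int makeFace(int a, int b, int c) {
    Face f; f.a = a; f.b = b; f.c = c; f.alive = true;
    double u[3], v[3], n[3];
    sub(pt(b), pt(a), u); sub(pt(c), pt(a), v); cross(u, v, n);
    double len = std::sqrt(dot(n, n));
    if (len < 1e-30) len = 1.0;
    f.n[0] = n[0] / len; f.n[1] = n[1] / len; f.n[2] = n[2] / len;
    f.d = dot(f.n, pt(a));
    faces_.push_back(std::move(f));
    return (int)faces_.size() - 1;
  }

  bool initSimplex() {
    // two extreme points
    int i0 = 0, i1 = 0;
    double best = -1;
    for (int k = 0; k < 3; ++k) {
      int lo = 0, hi = 0;
      for (int i = 1; i < np_; ++i) {
        if (P_[3 * i + k] < P_[3 * lo + k]) lo = i;
        if (P_[3 * i + k] > P_[3 * hi + k]) hi = i;
      }
      double d2 = 0, dif;
      for (int m = 0; m < 3; ++m) { dif = P_[3 * hi + m] - P_[3 * lo + m]; d2 += dif * dif; }
      if (d2 > best) { best = d2; i0 = lo; i1 = hi; }
    }
    if (best <= eps_ * eps_) return false;
    // furthest from the line i0-i1
    double u[3]; sub(pt(i1), pt(i0), u);
    double ulen2 = dot(u, u);
    int i2 = -1; best = eps_ * eps_;
    for (int i = 0; i < np_; ++i) {
      double w[3]; sub(pt(i), pt(i0), w);
      double c[3]; cross(u, w, c);
      double d2 = dot(c, c) / ulen2;
      if (d2 > best) { best = d2; i2 = i; }
    }
    if (i2 < 0) return false;
    // furthest from the plane i0,i1,i2
    int f0 = makeFace(i0, i1, i2);
    int i3 = -1; best = eps_;
    for (int i = 0; i < np_; ++i) {
      double d = std::fabs(dist(faces_[f0], i));
      if (d > best) { best = d; i3 = i; }
    }
    if (i3 < 0) return false;
    faces_.clear();
    // orient tetrahedron faces away from the opposite vertex
    int idx[4] = { i0, i1, i2, i3 };
    int tri[4][3] = { {0,1,2}, {0,2,3}, {0,3,1}, {1,3,2} };
    for (int t = 0; t < 4; ++t) {
      int a = idx[tri[t][0]], b = idx[tri[t][1]], c = idx[tri[t][2]];
      int opp = idx[0] + idx[1] + idx[2] + idx[3] - a - b - c;
      int fi = makeFace(a, b, c);
      if (dist(faces_[fi], opp) > 0) {
        faces_[fi].b = c; faces_[fi].c = b;
        faces_[fi].n[0] = -faces_[fi].n[0];
        faces_[fi].n[1] = -faces_[fi].n[1];
        faces_[fi].n[2] = -faces_[fi].n[2];
        faces_[fi].d = -faces_[fi].d;
      }
    }
    return true;
  }

  void assignPoints() {
    for (int i = 0; i < np_; ++i) {
      for (size_t f = 0; f < faces_.size(); ++f) {
        if (faces_[f].alive && dist(faces_[f], i) > eps_) {
          faces_[f].outside.push_back(i);
          break;
        }
      }
    }
  }

  void run() {
    for (;;) {
      int fsel = -1;
      for (size_t f = 0; f < faces_.size(); ++f)
        if (faces_[f].alive && !faces_[f].outside.empty()) { fsel = (int)f; break; }
      if (fsel < 0) break;
      // furthest outside point of this face
      int pbest = -1; double best = -1;
      for (int i : faces_[fsel].outside) {
        double d = dist(faces_[fsel], i);
        if (d > best) { best = d; pbest = i; }
      }
      addPoint(pbest);
    }
  }

  void addPoint(int p) {
    std::vector<int> visible;
    for (size_t f = 0; f < faces_.size(); ++f)
      if (faces_[f].alive && dist(faces_[f], p) > eps_) visible.push_back((int)f);
    if (visible.empty()) return;
    // horizon: directed edges of visible faces whose reverse is not visible
    std::vector<std::pair<int, int> > horizon;
    std::vector<std::pair<int64_t, int> > edges;
    edges.reserve(visible.size() * 3);
    auto key = [this](int u, int v) { return (int64_t)u * (int64_t)np_ + v; };
    for (int fi : visible) {
      const Face& f = faces_[fi];
      int e[3][2] = { {f.a, f.b}, {f.b, f.c}, {f.c, f.a} };
      for (int k = 0; k < 3; ++k) edges.push_back({ key(e[k][0], e[k][1]), 0 });
    }
    std::sort(edges.begin(), edges.end());
    for (int fi : visible) {
      const Face& f = faces_[fi];
      int e[3][2] = { {f.a, f.b}, {f.b, f.c}, {f.c, f.a} };
      for (int k = 0; k < 3; ++k) {
        int64_t rev = key(e[k][1], e[k][0]);
        bool twinVisible = std::binary_search(
          edges.begin(), edges.end(), std::make_pair(rev, 0),
          [](const std::pair<int64_t, int>& x, const std::pair<int64_t, int>& y) {
            return x.first < y.first;
          });
        if (!twinVisible) horizon.push_back({ e[k][0], e[k][1] });
      }
    }
    // orphaned outside points
    std::vector<int> orphans;
    for (int fi : visible) {
      Face& f = faces_[fi];
      orphans.insert(orphans.end(), f.outside.begin(), f.outside.end());
      f.outside.clear();
      f.alive = false;
    }
    std::vector<int> fresh;
    for (auto& e : horizon) fresh.push_back(makeFace(e.first, e.second, p));
    for (int i : orphans) {
      if (i == p) continue;
      for (int fi : fresh) {
        if (dist(faces_[fi], i) > eps_) { faces_[fi].outside.push_back(i); break; }
      }
    }
  }

  std::vector<int> vertices() const {
    std::vector<char> keep(np_, 0);
    for (const Face& f : faces_)
      if (f.alive) { keep[f.a] = 1; keep[f.b] = 1; keep[f.c] = 1; }
    std::vector<int> out;
    for (int i = 0; i < np_; ++i) if (keep[i]) out.push_back(i + 1); // 1-based
    return out;
  }

private:
  int np_;
  double eps_;
  std::vector<double> P_;
  std::vector<Face> faces_;
};

} // namespace

// [[Rcpp::export(name = ".hull3d_vertices")]]
IntegerVector hull3d_vertices(NumericMatrix pts) {
  if (pts.ncol() != 3) stop("points must be an N x 3 matrix");
  if (pts.nrow() < 4) stop("need at least 4 points for a 3D hull");
  Hull h(pts);
  if (!h.initSimplex()) stop("degenerate point set: rank < 3");
  h.assignPoints();
  h.run();
  std::vector<int> v = h.vertices();
  return wrap(v);
}
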