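// Quadric-error-metric edge-collapse decimation (Garland & Heckbert style).
// Deterministic: ties in the collapse queue break on insertion order.
#include <Rcpp.h>
#include <array>
#include <cmath>
#include <map>
#include <queue>
#include <set>
#include <vector>

using namespace Rcpp;

namespace {

// symmetric 4x4 quadric, 10 coefficients:
// [a b c d; b e f g; c f h i; d g i j]
struct Quadric {
  double q[10] = {0, 0, 0, 0, 0, 0, 0, 0, 0, 0};
  void addPlane(double a, double b, double c, double d, double w = 1.0) {
    q[0] += w * a * a; q[1] += w * a * b; q[2] += w * a * c; q[3] += w * a * d;
    q[4] += w * b * b; q[5] += w * b * c; q[6] += w * b * d;
    q[7] += w * c * c; q[8] += w * c * d;
    q[9] += w * d * d;
  }
  Quadric operator+(const Quadric& o) const {
    Quadric r;
    for (int i = 0; i < 10; ++i) r.q[i] = q[i] + o.q[i];
    return r;
  }
  double eval(const double* p) const {
    double x = p[0], y = p[1], z = p[2];
    return q[0] * x * x + 2 * q[1] * x * y + 2 * q[2] * x * z + 2 * q[3] * x +
           q[4] * y * y + 2 * q[5] * y * z + 2 * q[6] * y +
           q[7] * z * z + 2 * q[8] * z + q[9];
  }
  // minimise p^T Q p over p; false if the 3x3 block is near-singular
  bool optimal(double* out) const {
    double A[3][3] = {{q[0], q[1], q[2]}, {q[1], q[4], q[5]}, {q[2], q[5], q[7]}};
    double b[3] = {-q[3], -q[6], -q[8]};
    double det = A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
                 A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
                 A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
    double scale = 0;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) scale = std::max(scale, std::fabs(A[i][j]));
    if (std::fabs(det) < 1e-10 * scale * scale * scale || scale == 0) return false;
    double inv[3][3];
    inv[0][0] = (A[1][1] * A[2][2] - A[1][2] * A[2][1]) / det;
    inv[0][1] = (A[0][2] * A[2][1] - A[0][1] * A[2][2]) / det;
    inv[0][2] = (A[0][1] * A[1][2] - A[0][2] * A[1][1]) / det;
    inv[1][0] = (A[1][2] * A[2][0] - A[1][0] * A[2][2]) / det;
    inv[1][1] = (A[0][0] * A[2][2] - A[0][2] * A[2][0]) / det;
    inv[1][2] = (A[0][2] * A[1][0] - A[0][0] * A[1][2]) / det;
    inv[2][0] = (A[1][0] * A[2][1] - A[1][1] * A[2][0]) / det;
    inv[2][1] = (A[0][1] * A[2][0] - A[0][0] * A[2][1]) / det;
    inv[2][2] = (A[0][0] * A[1][1] - A[0][1] * A[1][0]) / det;
    for (int i = 0; i < 3; ++i)
      out[i] = inv[i][0] * b[0] + inv[i][1] * b[1] + inv[i][2] * b[2];
    return true;
  }
};

struct Cand {
  double cost;
  int u, v;
  long ver;  // sum of endpoint versions at push time (lazy invalidation)
  double pos[3];
  long seq;
  bool operator<(const Cand& o) const {
    if (cost != o.cost) return cost > o.cost;  // min-heap
    return seq > o.seq;
  }
};

inline void faceNormal(const std::vector<std::array<double, 3>>& V, int a, int b,
                       int c, double* n, double& area2) {
  double e1[3] = {V[b][0] - V[a][0], V[b][1] - V[a][1], V[b][2] - V[a][2]};
  double e2[3] = {V[c][0] - V[a][0], V[c][1] - V[a][1], V[c][2] - V[a][2]};
  n[0] = e1[1] * e2[2] - e1[2] * e2[1];
  n[1] = e1[2] * e2[0] - e1[0] * e2[2];
  n[2] = e1[0] * e2[1] - e1[1] * e2[0];
  area2 = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
}

}  // namespace

// [[Rcpp::export(name = ".decimate_qem")]]
List decimate_qem(NumericMatrix vertices, IntegerMatrix faces, int target_vertices) {
  const int nv = vertices.nrow(), nf = faces.nrow();
  std::vector<std::array<double, 3>> V(nv);
  for (int i = 0; i < nv; ++i)
    V[i] = {vertices(i, 0), vertices(i, 1), vertices(i, 2)};
  std::vector<std::array<int, 3>> F(nf);
  for (int i = 0; i < nf; ++i)
    F[i] = {faces(i, 0) - 1, faces(i, 1) - 1, faces(i, 2) - 1};

  std::vector<char> vAlive(nv, 1), fAlive(nf, 1);
  std::vector<long> ver(nv, 0);
  std::vector<std::set<int>> vFaces(nv);
  for (int f = 0; f < nf; ++f)
    for (int k = 0; k < 3; ++k) vFaces[F[f][k]].insert(f);

  // vertex quadrics from face planes
  std::vector<Quadric> Q(nv);
  for (int f = 0; f < nf; ++f) {
    double n[3], a2;
    faceNormal(V, F[f][0], F[f][1], F[f][2], n, a2);
    if (a2 <= 0) continue;
    double inv = 1.0 / a2;
    double nn[3] = {n[0] * inv, n[1] * inv, n[2] * inv};
    const auto& p = V[F[f][0]];
    double d = -(nn[0] * p[0] + nn[1] * p[1] + nn[2] * p[2]);
    double w = 0.5 * a2;  // area weighting
    for (int k = 0; k < 3; ++k) Q[F[f][k]].addPlane(nn[0], nn[1], nn[2], d, w);
  }
  // boundary preservation: constraint planes through boundary edges
  {
    std::map<std::pair<int, int>, std::pair<int, int>> edgeCount;  // edge -> (count, face)
    for (int f = 0; f < nf; ++f) {
      for (int k = 0; k < 3; ++k) {
        int a = F[f][k], b = F[f][(k + 1) % 3];
        auto key = std::make_pair(std::min(a, b), std::max(a, b));
        auto it = edgeCount.find(key);
        if (it == edgeCount.end()) edgeCount[key] = {1, f};
        else it->second.first++;
      }
    }
    for (auto& kv : edgeCount) {
      if (kv.second.first != 1) continue;
      int a = kv.first.first, b = kv.first.second, f = kv.second.second;
      double n[3], a2;
      faceNormal(V, F[f][0], F[f][1], F[f][2], n, a2);
      if (a2 <= 0) continue;
      double e[3] = {V[b][0] - V[a][0], V[b][1] - V[a][1], V[b][2] - V[a][2]};
      // plane containing the edge, perpendicular to the face
      double c[3] = {e[1] * n[2] - e[2] * n[1], e[2] * n[0] - e[0] * n[2],
                     e[0] * n[1] - e[1] * n[0]};
      double len = std::sqrt(c[0] * c[0] + c[1] * c[1] + c[2] * c[2]);
      if (len <= 0) continue;
      for (int k = 0; k < 3; ++k) c[k] /= len;
      double d = -(c[0] * V[a][0] + c[1] * V[a][1] + c[2] * V[a][2]);
      double w = 10.0 * a2;  // strong boundary constraint
      Q[a].addPlane(c[0], c[1], c[2], d, w);
      Q[b].addPlane(c[0], c[1], c[2], d, w);
    }
  }

  std::priority_queue<Cand> heap;
  long seq = 0;
  auto pushEdge = [&](int u, int v) {
    if (u > v) std::swap(u, v);
    Quadric Qe = Q[u] + Q[v];
    Cand c;
    c.u = u; c.v = v; c.ver = ver[u] + ver[v]; c.seq = seq++;
    double p[3];
    bool ok = Qe.optimal(p);
    if (ok) {
      // near-flat quadrics can place the optimum far along the plane;
      // reject placements beyond 2 edge lengths of the midpoint
      double mid[3] = {0.5 * (V[u][0] + V[v][0]), 0.5 * (V[u][1] + V[v][1]),
                       0.5 * (V[u][2] + V[v][2])};
      double e2 = 0, d2 = 0;
      for (int k = 0; k < 3; ++k) {
        double e = V[u][k] - V[v][k];
        e2 += e * e;
        double dd = p[k] - mid[k];
        d2 += dd * dd;
      }
      if (d2 > 4.0 * e2) ok = false;
    }
    if (!ok) {
      // fall back to best of endpoints / midpoint
      double mid[3] = {0.5 * (V[u][0] + V[v][0]), 0.5 * (V[u][1] + V[v][1]),
                       0.5 * (V[u][2] + V[v][2])};
      const double* cands[3] = {V[u].data(), V[v].data(), mid};
      double best = R_PosInf;
      for (int i = 0; i < 3; ++i) {
        double e = Qe.eval(cands[i]);
        if (e < best) { best = e; p[0] = cands[i][0]; p[1] = cands[i][1]; p[2] = cands[i][2]; }
      }
    }
    c.pos[0] = p[0]; c.pos[1] = p[1]; c.pos[2] = p[2];
    c.cost = Qe.eval(p);
    heap.push(c);
  };

  auto neighbors = [&](int u) {
    std::set<int> nb;
    for (int f : vFaces[u])
      if (fAlive[f])
        for (int k = 0; k < 3; ++k)
          if (F[f][k] != u) nb.insert(F[f][k]);
    return nb;
  };

  {
    std::set<std::pair<int, int>> seen;
    for (int f = 0; f < nf; ++f)
      for (int k = 0; k < 3; ++k) {
        int a = F[f][k], b = F[f][(k + 1) % 3];
        auto key = std::make_pair(std::min(a, b), std::max(a, b));
        if (seen.insert(key).second) pushEdge(key.first, key.second);
      }
  }

  int alive = nv;
  while (alive > target_vertices && !heap.empty()) {
    Cand c = heap.top();
    heap.pop();
    int u = c.u, v = c.v;
    if (!vAlive[u] || !vAlive[v]) continue;
    if (c.ver != ver[u] + ver[v]) continue;
    // edge must still exist
    auto nbu = neighbors(u);
    if (!nbu.count(v)) continue;

    // collapse v into u at c.pos
    V[u] = {c.pos[0], c.pos[1], c.pos[2]};
    Q[u] = Q[u] + Q[v];
    vAlive[v] = 0;
    for (int f : std::vector<int>(vFaces[v].begin(), vFaces[v].end())) {
      if (!fAlive[f]) continue;
      bool hasU = false;
      for (int k = 0; k < 3; ++k) if (F[f][k] == u) hasU = true;
      if (hasU) {
        fAlive[f] = 0;  // face spanned the collapsed edge
        for (int k = 0; k < 3; ++k) vFaces[F[f][k]].erase(f);
      } else {
        for (int k = 0; k < 3; ++k) if (F[f][k] == v) F[f][k] = u;
        vFaces[u].insert(f);
      }
    }
    vFaces[v].clear();
    ver[u]++;
    alive--;
    for (int w : neighbors(u)) pushEdge(std::min(u, w), std::max(u, w));
  }

  // drop vertices with no remaining live faces, compact indices
  std::vector<char> used(nv, 0);
  std::vector<std::array<int, 3>> outF;
  for (int f = 0; f < nf; ++f) {
    if (!fAlive[f]) continue;
    auto& t = F[f];
    if (t[0] == t[1] || t[1] == t[2] || t[0] == t[2]) continue;
    outF.push_back(t);
    for (int k = 0; k < 3; ++k) used[t[k]] = 1;
  }
  std::vector<int> remap(nv, -1);
  int m = 0;
  for (int i = 0; i < nv; ++i) if (used[i]) remap[i] = m++;
  NumericMatrix outV(m, 3);
  for (int i = 0; i < nv; ++i)
    if (used[i])
      for (int k = 0; k < 3; ++k) outV(remap[i], k) = V[i][k];
  IntegerMatrix outFm(outF.size(), 3);
  for (size_t f = 0; f < outF.size(); ++f)
    for (int k = 0; k < 3; ++k) outFm(f, k) = remap[outF[f][k]] + 1;
  return List::create(_["vertices"] = outV, _["faces"] = outFm);
}
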