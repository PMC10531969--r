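#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double tri_area(const NumericMatrix &p, int i, int j, int k) {
  double ax = p(j, 0) - p(i, 0), ay = p(j, 1) - p(i, 1), az = p(j, 2) - p(i, 2);
  double bx = p(k, 0) - p(i, 0), by = p(k, 1) - p(i, 1), bz = p(k, 2) - p(i, 2);
  double cx = ay * bz - az * by;
  double cy = az * bx - ax * bz;
  double cz = ax * by - ay * bx;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// Minimal-total-area triangulation of a closed 3D polygon (vertices in
// cyclic order), dynamic programming over chords, O(n^3) time / O(n^2)
// space. Returns 1-based triangle indices and the total area.
// [[Rcpp::export(name = ".min_area_triangulation")]]
List min_area_triangulation(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 3) return List::create(_["triangles"] = IntegerMatrix(0, 3),
                                 _["area"] = 0.0);
  std::vector<double> dp((size_t)n * n, 0.0);
  std::vector<int> choice((size_t)n * n, -1);
  for (int len = 2; len < n; ++len) {
    for (int i = 0; i + len < n; ++i) {
      int j = i + len;
      double best = R_PosInf;
      int bestk = -1;
      for (int k = i + 1; k < j; ++k) {
        double v = dp[(size_t)i * n + k] + dp[(size_t)k * n + j] +
                   tri_area(pts, i, k, j);
        if (v < best) { best = v; bestk = k; }
      }
      dp[(size_t)i * n + j] = best;
      choice[(size_t)i * n + j] = bestk;
    }
  }
  std::vector<int> tri;
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    std::pair<int, int> ij = stack.back();
    stack.pop_back();
    int i = ij.first, j = ij.second;
    if (j - i < 2) continue;
    int k = choice[(size_t)i * n + j];
    tri.push_back(i + 1); tri.push_back(k + 1); tri.push_back(j + 1);
    stack.push_back(std::make_pair(i, k));
    stack.push_back(std::make_pair(k, j));
  }
  int m = tri.size() / 3;
  IntegerMatrix T(m, 3);
  for (int r = 0; r < m; ++r) {
    T(r, 0) = tri[3 * r]; T(r, 1) = tri[3 * r + 1]; T(r, 2) = tri[3 * r + 2];
  }
  return List::create(_["triangles"] = T, _["area"] = dp[(size_t)0 * n + (n - 1)]);
}
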