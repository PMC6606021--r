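// 3-D connected-component labeling of a logical volume under 6-, 18- or
// 26-neighbour connectivity (iterative breadth-first search).

#include <Rcpp.h>
#include <queue>

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_label_components(const Rcpp::LogicalVector& vol,
                                         const Rcpp::IntegerVector& dims,
                                         int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  Rcpp::IntegerVector lab(n, 0);

  // neighbour offsets for the requested connectivity
  std::vector<std::array<int, 3>> offs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (manh == 0) continue;
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        offs.push_back({dx, dy, dz});
      }

  int next = 0;
  std::queue<int> qu;
  for (int idx = 0; idx < n; ++idx) {
    if (!vol[idx] || lab[idx] != 0) continue;
    ++next;
    lab[idx] = next;
    qu.push(idx);
    while (!qu.empty()) {
      int cur = qu.front(); qu.pop();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / (nx * ny);
      for (const auto& o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int nb = xx + nx * (yy + ny * zz);
        if (vol[nb] && lab[nb] == 0) {
          lab[nb] = next;
          qu.push(nb);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
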