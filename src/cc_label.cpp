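#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling on a logical mask stored in R array order
// (first dimension fastest). dims = (n1, n2, n3); connectivity 6 or 26.
// Labels are assigned in raster-scan order of the first foreground voxel of
// each component, so the labeling is deterministic.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  // neighbor offsets
  std::vector<int> d1, d2, d3;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        if (connectivity == 6 && (std::abs(a) + std::abs(b) + std::abs(c)) != 1) continue;
        d1.push_back(a); d2.push_back(b); d3.push_back(c);
      }
  const int nnb = (int)d1.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next_label;
    labels[i] = next_label;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int i1 = (int)(v % n1);
      int i2 = (int)((v / n1) % n2);
      int i3 = (int)(v / ((R_xlen_t)n1 * n2));
      for (int k = 0; k < nnb; ++k) {
        int j1 = i1 + d1[k], j2 = i2 + d2[k], j3 = i3 + d3[k];
        if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3) continue;
        R_xlen_t w = j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3);
        if (mask[w] && labels[w] == 0) {
          labels[w] = next_label;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}
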