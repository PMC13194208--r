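#include <Rcpp.h>
using namespace Rcpp;

// Connected-component labeling of habitat cells (value 1) in a grid that may
// contain NA (outside) and 0 (non-habitat). Labels are assigned in row-major
// first-encounter order, so they are contiguous 1..n_patches and reproducible.
// [[Rcpp::export]]
List label_patches_cpp(IntegerMatrix cells, int connectivity) {
  const int nr = cells.nrow(), nc = cells.ncol();
  IntegerMatrix labels(nr, nc);
  std::vector<int> sizes;
  std::vector<int> stack_r, stack_c;

  static const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  static const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;

  int lab = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (cells(r, c) != 1 || labels(r, c) != 0) continue;
      ++lab;
      int size = 0;
      stack_r.clear(); stack_c.clear();
      stack_r.push_back(r); stack_c.push_back(c);
      labels(r, c) = lab;
      while (!stack_r.empty()) {
        int cr = stack_r.back(); stack_r.pop_back();
        int cc = stack_c.back(); stack_c.pop_back();
        ++size;
        for (int k = 0; k < nnb; ++k) {
          int qr = cr + dr8[k], qc = cc + dc8[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (cells(qr, qc) == 1 && labels(qr, qc) == 0) {
            labels(qr, qc) = lab;
            stack_r.push_back(qr); stack_c.push_back(qc);
          }
        }
      }
      sizes.push_back(size);
    }
  }
  return List::create(_["labels"] = labels,
                      _["n_patches"] = lab,
                      _["patch_sizes"] = wrap(sizes));
}
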