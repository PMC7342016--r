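#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling on a regular grid. mask is a logical vector
// in column-major order for an nrow x ncol map; ncol == 1 (or nrow == 1)
// means 1-D adjacency. connectivity is 4 or 8 for 2-D maps.
static void label_grid(const int* mask, int nrow, int ncol, int connectivity,
                       int* labels, std::vector<int>& sizes) {
  int n = nrow * ncol;
  std::fill(labels, labels + n, 0);
  sizes.clear();
  std::vector<int> stack;
  int next = 0;
  for (int start = 0; start < n; ++start) {
    if (!mask[start] || labels[start]) continue;
    ++next;
    int count = 0;
    stack.push_back(start);
    labels[start] = next;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      ++count;
      int r = cur % nrow, c = cur / nrow;
      for (int dc = -1; dc <= 1; ++dc) {
        for (int dr = -1; dr <= 1; ++dr) {
          if (dr == 0 && dc == 0) continue;
          if (connectivity == 4 && dr != 0 && dc != 0) continue;
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= nrow || cc < 0 || cc >= ncol) continue;
          int nb = rr + cc * nrow;
          if (mask[nb] && !labels[nb]) {
            labels[nb] = next;
            stack.push_back(nb);
          }
        }
      }
    }
    sizes.push_back(count);
  }
}

// [[Rcpp::export(name = ".label_clusters")]]
List label_clusters_cpp(LogicalVector mask, int nrow, int ncol,
                        int connectivity) {
  if ((int)mask.size() != nrow * ncol)
    stop("mask length does not match map dimensions");
  IntegerVector labels(mask.size());
  std::vector<int> sizes;
  label_grid(LOGICAL(mask), nrow, ncol, connectivity, INTEGER(labels), sizes);
  return List::create(_["labels"] = labels, _["sizes"] = wrap(sizes));
}

// Maximum cluster size for each row of a permutation x cells logical matrix.
// [[Rcpp::export(name = ".max_cluster_sizes")]]
IntegerVector max_cluster_sizes_cpp(LogicalMatrix masks, int nrow, int ncol,
                                    int connectivity) {
  int nperm = masks.nrow();
  if (masks.ncol() != nrow * ncol)
    stop("mask width does not match map dimensions");
  IntegerVector out(nperm);
  std::vector<int> buf(nrow * ncol), labels(nrow * ncol), sizes;
  for (int p = 0; p < nperm; ++p) {
    for (int j = 0; j < nrow * ncol; ++j) buf[j] = masks(p, j);
    label_grid(buf.data(), nrow, ncol, connectivity, labels.data(), sizes);
    int mx = 0;
    for (size_t k = 0; k < sizes.size(); ++k)
      if (sizes[k] > mx) mx = sizes[k];
    out[p] = mx;
  }
  return out;
}
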