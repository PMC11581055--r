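#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Priority-flood marker-controlled watershed.
// Floods the relief from the marker pixels in order of increasing relief
// height; every pixel is claimed by the first marker flood that reaches it,
// so region boundaries fall on the ridge lines between basins.
namespace {

struct QNode {
  double h;     // relief height at the pixel
  long long t;  // insertion order, breaks height ties deterministically
  int idx;      // linear pixel index
};
struct QNodeCmp {
  bool operator()(const QNode &a, const QNode &b) const {
    if (a.h != b.h) return a.h > b.h;  // min-heap on height
    return a.t > b.t;                  // FIFO among equal heights
  }
};

inline int n_neigh(int connectivity) { return connectivity == 4 ? 4 : 8; }

const int DR8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
const int DC8[8] = {0, 0, -1, 1, -1, 1, -1, 1};

}  // namespace

// [[Rcpp::export(name = ".ws_flood")]]
IntegerMatrix ws_flood(NumericMatrix relief, IntegerMatrix markers,
                       int connectivity = 4) {
  const int nr = relief.nrow(), nc = relief.ncol();
  if (markers.nrow() != nr || markers.ncol() != nc)
    stop("relief and markers must have the same shape");
  IntegerMatrix out(nr, nc);
  std::priority_queue<QNode, std::vector<QNode>, QNodeCmp> pq;
  long long tick = 0;
  const int nn = n_neigh(connectivity);

  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (markers(r, c) > 0) {
        out(r, c) = markers(r, c);
        pq.push({relief(r, c), tick++, r + c * nr});
      }
  if (tick == 0) stop("no markers");

  while (!pq.empty()) {
    QNode nd = pq.top();
    pq.pop();
    int r = nd.idx % nr, c = nd.idx / nr;
    int lab = out(r, c);
    for (int k = 0; k < nn; ++k) {
      int rr = r + DR8[k], cc = c + DC8[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (out(rr, cc) == 0) {
        out(rr, cc) = lab;
        pq.push({relief(rr, cc), tick++, rr + cc * nr});
      }
    }
  }
  return out;
}

// Connected-component labelling of a logical mask (4- or 8-connectivity),
// breadth-first, labels assigned in column-major scan order.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity = 4) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  const int nn = n_neigh(connectivity);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || out(r, c) != 0) continue;
      ++next;
      out(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int r0 = idx % nr, c0 = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int rr = r0 + DR8[k], cc = c0 + DC8[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && out(rr, cc) == 0) {
            out(rr, cc) = next;
            stack.push_back(rr + cc * nr);
          }
        }
      }
    }
  return out;
}
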