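#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Prominence-filtered local maxima by a watershed-style union-find sweep.
//
// Pixels are visited in order of decreasing intensity (ties by linear
// index). Each pixel either starts a new summit component or joins the
// components of its already-visited 8-neighbours. When components meet,
// the meeting intensity is the saddle between their summits: every
// component except the one with the highest summit is finalized there,
// and its summit is reported as a maximum iff its prominence
// (summit height - saddle height) strictly exceeds `tol`. Components
// that survive to the end are measured against the image minimum.
//
// Equal-valued summit plateaus are tracked as pixel sets; a reported
// maximum is the plateau centroid rounded to the nearest pixel. When two
// fragments of one plateau meet at plateau height, their pixel sets are
// merged rather than one being finalized (zero prominence never passes a
// positive tolerance, but the merge keeps the centroid exact). Summit
// ties elsewhere are broken toward the lower summit linear index.

struct DisjointSet {
  std::vector<int> parent;
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
};

// [[Rcpp::export(name = ".cpp_prominent_maxima")]]
NumericMatrix cpp_prominent_maxima(NumericMatrix img, double tol) {
  int nr = img.nrow(), nc = img.ncol();
  int n = nr * nc;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  const double* v = img.begin();
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (v[a] != v[b]) return v[a] > v[b];
    return a < b;
  });
  double vmin = *std::min_element(v, v + n);

  DisjointSet ds;
  ds.parent.assign(n, -1);
  std::vector<double> peakVal(n), psx(n), psy(n);
  std::vector<int> peakIdx(n), pn(n);
  std::vector<char> visited(n, 0);
  std::vector<double> outx, outy;

  auto report = [&](int root) {
    double cx = psx[root] / pn[root], cy = psy[root] / pn[root];
    outx.push_back(std::round(cx));
    outy.push_back(std::round(cy));
  };

  std::vector<int> roots;
  for (int oi = 0; oi < n; ++oi) {
    int idx = ord[oi];
    int r = idx % nr, c = idx / nr;  // column-major
    double val = v[idx];
    roots.clear();
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        if (dr == 0 && dc == 0) continue;
        int rr = r + dr, cc = c + dc;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int nidx = rr + cc * nr;
        if (!visited[nidx]) continue;
        int root = ds.find(nidx);
        if (std::find(roots.begin(), roots.end(), root) == roots.end())
          roots.push_back(root);
      }
    }
    if (roots.empty()) {
      ds.parent[idx] = idx;
      peakVal[idx] = val;
      peakIdx[idx] = idx;
      psx[idx] = c;  // x = column, 0-based
      psy[idx] = r;  // y = row, 0-based
      pn[idx] = 1;
    } else {
      int win = roots[0];
      for (size_t k = 1; k < roots.size(); ++k) {
        int cand = roots[k];
        if (peakVal[cand] > peakVal[win] ||
            (peakVal[cand] == peakVal[win] && peakIdx[cand] < peakIdx[win]))
          win = cand;
      }
      ds.parent[idx] = win;
      if (val == peakVal[win]) {  // summit plateau grows
        psx[win] += c;
        psy[win] += r;
        pn[win] += 1;
      }
      for (size_t k = 0; k < roots.size(); ++k) {
        int loser = roots[k];
        if (loser == win) continue;
        if (peakVal[loser] == peakVal[win] && val == peakVal[win]) {
          // two fragments of a single summit plateau: merge pixel sets
          psx[win] += psx[loser];
          psy[win] += psy[loser];
          pn[win] += pn[loser];
        } else if (peakVal[loser] - val > tol) {
          report(loser);
        }
        ds.parent[loser] = win;
      }
    }
    visited[idx] = 1;
  }

  // surviving components: prominence relative to the image minimum
  std::vector<char> done(n, 0);
  for (int i = 0; i < n; ++i) {
    if (ds.parent[i] < 0) continue;
    int root = ds.find(i);
    if (done[root]) continue;
    done[root] = 1;
    if (peakVal[root] - vmin > tol) report(root);
  }

  NumericMatrix out(outx.size(), 2);
  for (size_t i = 0; i < outx.size(); ++i) {
    out(i, 0) = outx[i];
    out(i, 1) = outy[i];
  }
  colnames(out) = CharacterVector::create("x", "y");
  return out;
}
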