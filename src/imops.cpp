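#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Connected-component labelling of a 0/1 mask. Labels are assigned in raster
// order of each component's first-encountered pixel, so output is fully
// deterministic. connectivity is 4 or 8 (foreground connectivity).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> qi(h * (size_t)w), qj(h * (size_t)w);
  int di8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  int dj8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  int di4[4] = {-1, 1, 0, 0};
  int dj4[4] = {0, 0, -1, 1};
  int nn = (connectivity == 8) ? 8 : 4;
  int *di = (connectivity == 8) ? di8 : di4;
  int *dj = (connectivity == 8) ? dj8 : dj4;
  int next = 0;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      int head = 0, tail = 0;
      qi[tail] = i; qj[tail] = j; ++tail;
      lab(i, j) = next;
      while (head < tail) {
        int ci = qi[head], cj = qj[head]; ++head;
        for (int k = 0; k < nn; ++k) {
          int ni = ci + di[k], nj = cj + dj[k];
          if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
          if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            qi[tail] = ni; qj[tail] = nj; ++tail;
          }
        }
      }
    }
  }
  return lab;
}

// Binary dilation by an arbitrary offset set; pixels outside the image count
// as background.
// [[Rcpp::export]]
IntegerMatrix cpp_binary_dilate(IntegerMatrix mask, IntegerMatrix offsets) {
  int h = mask.nrow(), w = mask.ncol(), n = offsets.nrow();
  IntegerMatrix out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      if (mask(i, j) == 0) continue;
      for (int k = 0; k < n; ++k) {
        int ni = i + offsets(k, 0), nj = j + offsets(k, 1);
        if (ni >= 0 && ni < h && nj >= 0 && nj < w) out(ni, nj) = 1;
      }
    }
  return out;
}

// Binary erosion: pixel survives iff every offset lands inside the image on a
// foreground pixel (outside counts as background).
// [[Rcpp::export]]
IntegerMatrix cpp_binary_erode(IntegerMatrix mask, IntegerMatrix offsets) {
  int h = mask.nrow(), w = mask.ncol(), n = offsets.nrow();
  IntegerMatrix out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      bool keep = mask(i, j) != 0;
      for (int k = 0; keep && k < n; ++k) {
        int ni = i + offsets(k, 0), nj = j + offsets(k, 1);
        keep = (ni >= 0 && ni < h && nj >= 0 && nj < w && mask(ni, nj) != 0);
      }
      out(i, j) = keep ? 1 : 0;
    }
  return out;
}

// Separable running maximum over a size x size window; edges are clamped
// (windows are intersected with the image).
// [[Rcpp::export]]
NumericMatrix cpp_max_filter(NumericMatrix img, int size) {
  int h = img.nrow(), w = img.ncol();
  int lo = -(size - 1) / 2, hi = lo + size - 1;
  NumericMatrix tmp(h, w), out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double m = R_NegInf;
      int a = std::max(0, i + lo), b = std::min(h - 1, i + hi);
      for (int k = a; k <= b; ++k) m = std::max(m, img(k, j));
      tmp(i, j) = m;
    }
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double m = R_NegInf;
      int a = std::max(0, j + lo), b = std::min(w - 1, j + hi);
      for (int k = a; k <= b; ++k) m = std::max(m, tmp(i, k));
      out(i, j) = m;
    }
  return out;
}

// Separable Gaussian blur, kernel truncated at `radius`, replicate edges.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix img, double sigma, int radius) {
  int h = img.nrow(), w = img.ncol();
  std::vector<double> k(2 * radius + 1);
  double s = 0.0;
  for (int d = -radius; d <= radius; ++d) {
    k[d + radius] = std::exp(-0.5 * d * d / (sigma * sigma));
    s += k[d + radius];
  }
  for (size_t t = 0; t < k.size(); ++t) k[t] /= s;
  NumericMatrix tmp(h, w), out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double a = 0.0;
      for (int d = -radius; d <= radius; ++d) {
        int ni = std::min(h - 1, std::max(0, i + d));
        a += k[d + radius] * img(ni, j);
      }
      tmp(i, j) = a;
    }
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double a = 0.0;
      for (int d = -radius; d <= radius; ++d) {
        int nj = std::min(w - 1, std::max(0, j + d));
        a += k[d + radius] * tmp(i, nj);
      }
      out(i, j) = a;
    }
  return out;
}

// Shannon entropy (base 2) of the quantized-level histogram inside an offset
// neighbourhood intersected with the image. `img` holds levels 0..(levels-1).
// [[Rcpp::export]]
NumericMatrix cpp_local_entropy(IntegerMatrix img, IntegerMatrix offsets,
                                int levels) {
  int h = img.nrow(), w = img.ncol(), n = offsets.nrow();
  NumericMatrix out(h, w);
  std::vector<int> hist(levels);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      std::fill(hist.begin(), hist.end(), 0);
      int tot = 0;
      for (int k = 0; k < n; ++k) {
        int ni = i + offsets(k, 0), nj = j + offsets(k, 1);
        if (ni >= 0 && ni < h && nj >= 0 && nj < w) {
          ++hist[img(ni, nj)];
          ++tot;
        }
      }
      double e = 0.0;
      for (int l = 0; l < levels; ++l)
        if (hist[l] > 0) {
          double p = (double)hist[l] / tot;
          e -= p * std::log2(p);
        }
      out(i, j) = e;
    }
  return out;
}

struct FloodNode {
  double elev;
  long long seq;
  int i, j, lab;
};
struct FloodCmp {
  bool operator()(const FloodNode &a, const FloodNode &b) const {
    if (a.elev != b.elev) return a.elev > b.elev;
    return a.seq > b.seq;  // FIFO among equal elevations -> deterministic
  }
};

// Marker-seeded watershed: flood `region` from labelled markers in order of
// increasing elevation (priority flood, 8-connected). Every region pixel that
// is reachable from a marker receives exactly one label.
// [[Rcpp::export]]
IntegerMatrix cpp_marker_watershed(NumericMatrix elev, IntegerMatrix markers,
                                   IntegerMatrix region) {
  int h = elev.nrow(), w = elev.ncol();
  IntegerMatrix lab(h, w);
  std::priority_queue<FloodNode, std::vector<FloodNode>, FloodCmp> pq;
  long long seq = 0;
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i)
      if (markers(i, j) > 0 && region(i, j) != 0) {
        lab(i, j) = markers(i, j);
        pq.push({elev(i, j), seq++, i, j, markers(i, j)});
      }
  int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!pq.empty()) {
    FloodNode nd = pq.top();
    pq.pop();
    for (int k = 0; k < 8; ++k) {
      int ni = nd.i + di[k], nj = nd.j + dj[k];
      if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
      if (region(ni, nj) == 0 || lab(ni, nj) != 0) continue;
      lab(ni, nj) = nd.lab;
      pq.push({std::max(elev(ni, nj), nd.elev), seq++, ni, nj, nd.lab});
    }
  }
  return lab;
}
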