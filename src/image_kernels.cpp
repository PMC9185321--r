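// Frame-level image utilities: iterative diffusion hole filling,
// nearest-valid-neighbour fallback, and bilinear resampling.

#include <Rcpp.h>
#include <queue>
#include <cmath>

using namespace Rcpp;

// Replace masked pixels by the mean of their valid 8-neighbours, repeating
// until none remain or max_iters passes; leftover pixels (enclosed regions
// larger than the iteration budget) take the value of the nearest valid
// pixel by breadth-first search over the 4-neighbour grid.
// [[Rcpp::export(name = ".fill_holes_cpp")]]
NumericMatrix fill_holes_cpp(NumericMatrix frame, LogicalMatrix hole,
                             int max_iters) {
  int H = frame.nrow(), W = frame.ncol();
  NumericMatrix out = clone(frame);
  LogicalMatrix invalid = clone(hole);
  int n_invalid = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) if (invalid(i, j)) ++n_invalid;
  if (n_invalid == 0) return out;
  if (n_invalid == H * W) stop("fill_holes: frame has no valid pixels");

  std::vector<std::pair<int,int> > todo, still;
  todo.reserve(n_invalid);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) if (invalid(i, j)) todo.push_back({i, j});

  for (int it = 0; it < max_iters && !todo.empty(); ++it) {
    std::vector<double> val(todo.size());
    std::vector<bool> done(todo.size(), false);
    for (size_t t = 0; t < todo.size(); ++t) {
      int i = todo[t].first, j = todo[t].second;
      double s = 0.0; int c = 0;
      for (int dj = -1; dj <= 1; ++dj) for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0) continue;
        int ii = i + di, jj = j + dj;
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        if (!invalid(ii, jj)) { s += out(ii, jj); ++c; }
      }
      if (c > 0) { val[t] = s / c; done[t] = true; }
    }
    still.clear();
    for (size_t t = 0; t < todo.size(); ++t) {
      if (done[t]) out(todo[t].first, todo[t].second) = val[t];
      else still.push_back(todo[t]);
    }
    for (size_t t = 0; t < todo.size(); ++t)
      if (done[t]) invalid(todo[t].first, todo[t].second) = false;
    todo.swap(still);
  }

  if (!todo.empty()) {
    // multi-source BFS from every valid pixel; remaining holes inherit the
    // value of their nearest (4-connected) valid pixel
    std::vector<int> src(H * W, -1);
    std::queue<int> q;
    for (int j = 0; j < W; ++j) for (int i = 0; i < H; ++i) {
      int id = i + H * j;
      if (!invalid(i, j)) { src[id] = id; q.push(id); }
    }
    const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
    while (!q.empty()) {
      int id = q.front(); q.pop();
      int i = id % H, j = id / H;
      for (int d = 0; d < 4; ++d) {
        int ii = i + di[d], jj = j + dj[d];
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        int nid = ii + H * jj;
        if (src[nid] < 0) { src[nid] = src[id]; q.push(nid); }
      }
    }
    for (auto& p : todo) {
      int id = p.first + H * p.second, s = src[id];
      out(p.first, p.second) = out(s % H, s / H);
    }
  }
  return out;
}

// Bilinear resampling with half-pixel centre alignment.
// [[Rcpp::export(name = ".resize_bilinear_cpp")]]
NumericMatrix resize_bilinear_cpp(NumericMatrix x, int out_h, int out_w) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix y(out_h, out_w);
  double sh = (double)H / out_h, sw = (double)W / out_w;
  for (int j = 0; j < out_w; ++j) {
    double xc = (j + 0.5) * sw - 0.5;
    int j0 = (int)std::floor(xc);
    double fj = xc - j0;
    int j0c = std::min(std::max(j0, 0), W - 1);
    int j1c = std::min(std::max(j0 + 1, 0), W - 1);
    for (int i = 0; i < out_h; ++i) {
      double yc = (i + 0.5) * sh - 0.5;
      int i0 = (int)std::floor(yc);
      double fi = yc - i0;
      int i0c = std::min(std::max(i0, 0), H - 1);
      int i1c = std::min(std::max(i0 + 1, 0), H - 1);
      y(i, j) = (1 - fi) * ((1 - fj) * x(i0c, j0c) + fj * x(i0c, j1c)) +
                fi       * ((1 - fj) * x(i1c, j0c) + fj * x(i1c, j1c));
    }
  }
  return y;
}

// Separable 2-D convolution with a symmetric odd 1-D kernel and zero
// padding: equivalent to K %*% x %*% t(K) for the banded matrix K.
// [[Rcpp::export(name = ".sep_conv2_cpp")]]
NumericMatrix sep_conv2_cpp(NumericMatrix x, NumericVector kernel) {
  int H = x.nrow(), W = x.ncol(), L = kernel.size(), r = (L - 1) / 2;
  NumericMatrix tmp(H, W), y(H, W);
  for (int j = 0; j < W; ++j) {        // along rows (first index)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      int d0 = std::max(0, r - i), d1 = std::min(L, H + r - i);
      for (int d = d0; d < d1; ++d) s += kernel[d] * x(i + d - r, j);
      tmp(i, j) = s;
    }
  }
  for (int i = 0; i < H; ++i) {        // along columns (second index)
    for (int j = 0; j < W; ++j) {
      double s = 0.0;
      int d0 = std::max(0, r - j), d1 = std::min(L, W + r - j);
      for (int d = d0; d < d1; ++d) s += kernel[d] * tmp(i, j + d - r);
      y(i, j) = s;
    }
  }
  return y;
}
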