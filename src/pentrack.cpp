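#include <Rcpp.h>
using namespace Rcpp;

// reflect index into [0, n): half-sample symmetric (-1 -> 0, n -> n-1)
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// 2-D correlation of x with a (2m+1) x (2n+1) kernel, reflect padding.
// Kernels used here are symmetric, so correlation == convolution.
// [[Rcpp::export]]
NumericMatrix conv2_reflect(const NumericMatrix& x, const NumericMatrix& kernel) {
  const int H = x.nrow(), W = x.ncol();
  const int kh = kernel.nrow(), kw = kernel.ncol();
  if (kh % 2 == 0 || kw % 2 == 0)
    stop("kernel dimensions must be odd");
  const int m = kh / 2, n = kw / 2;
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double acc = 0.0;
      for (int dc = -n; dc <= n; ++dc) {
        const int cc = reflect_idx(c + dc, W);
        for (int dr = -m; dr <= m; ++dr) {
          const int rr = reflect_idx(r + dr, H);
          acc += kernel(dr + m, dc + n) * x(rr, cc);
        }
      }
      out(r, c) = acc;
    }
  }
  return out;
}

// Best normalized cross-correlation match of `templ` in `frame` over a square
// search window of `radius` around (row0, col0) (0-based top-left of the
// current template placement). Placements clipped to the frame are skipped.
// Returns (best_row, best_col, best_ncc), 0-based top-left.
// [[Rcpp::export]]
NumericVector ncc_best_match(const NumericMatrix& frame, const NumericMatrix& templ,
                             int row0, int col0, int radius) {
  const int H = frame.nrow(), W = frame.ncol();
  const int th = templ.nrow(), tw = templ.ncol();
  const int npx = th * tw;

  double tmean = 0.0;
  for (int c = 0; c < tw; ++c)
    for (int r = 0; r < th; ++r) tmean += templ(r, c);
  tmean /= npx;
  double tvar = 0.0;
  for (int c = 0; c < tw; ++c)
    for (int r = 0; r < th; ++r) {
      const double d = templ(r, c) - tmean;
      tvar += d * d;
    }

  // integral images of the search region for window sums / sums of squares
  const int rlo = std::max(0, row0 - radius), rhi = std::min(H, row0 + radius + th);
  const int clo = std::max(0, col0 - radius), chi = std::min(W, col0 + radius + tw);
  const int sh = rhi - rlo, sw = chi - clo;
  if (sh < th || sw < tw)
    return NumericVector::create(row0, col0, 0.0);
  std::vector<double> I((sh + 1) * (sw + 1), 0.0), I2((sh + 1) * (sw + 1), 0.0);
  const double* F = frame.begin();
  for (int c = 0; c < sw; ++c) {
    const double* fcol = F + (size_t)(clo + c) * H + rlo;
    double colsum = 0.0, colsq = 0.0;
    for (int r = 0; r < sh; ++r) {
      const double v = fcol[r];
      colsum += v;
      colsq += v * v;
      I[(size_t)(c + 1) * (sh + 1) + r + 1] = I[(size_t)c * (sh + 1) + r + 1] + colsum;
      I2[(size_t)(c + 1) * (sh + 1) + r + 1] = I2[(size_t)c * (sh + 1) + r + 1] + colsq;
    }
  }
  auto boxsum = [&](const std::vector<double>& S, int r0, int c0) {
    const int r = r0 - rlo, c = c0 - clo;
    return S[(size_t)(c + tw) * (sh + 1) + r + th] - S[(size_t)c * (sh + 1) + r + th] -
           S[(size_t)(c + tw) * (sh + 1) + r] + S[(size_t)c * (sh + 1) + r];
  };

  double best = R_NegInf;
  int best_r = row0, best_c = col0;
  // prefer the smallest displacement on ties so a static scene stays put
  double best_disp = R_PosInf;
  const double* Tm = templ.begin();
  for (int dr = -radius; dr <= radius; ++dr) {
    const int r0 = row0 + dr;
    if (r0 < 0 || r0 + th > H) continue;
    for (int dc = -radius; dc <= radius; ++dc) {
      const int c0 = col0 + dc;
      if (c0 < 0 || c0 + tw > W) continue;
      double cross = 0.0;
      for (int c = 0; c < tw; ++c) {
        const double* fcol = F + (size_t)(c0 + c) * H + r0;
        const double* tcol = Tm + (size_t)c * th;
        for (int r = 0; r < th; ++r) cross += fcol[r] * tcol[r];
      }
      const double fsum = boxsum(I, r0, c0);
      const double fvar = boxsum(I2, r0, c0) - fsum * fsum / npx;
      double ncc;
      if (tvar <= 0.0 || fvar <= 0.0) {
        ncc = 0.0;
      } else {
        ncc = (cross - fsum * tmean) / std::sqrt(tvar * fvar);
      }
      const double disp = (double)dr * dr + (double)dc * dc;
      if (ncc > best + 1e-12 || (std::abs(ncc - best) <= 1e-12 && disp < best_disp)) {
        best = ncc;
        best_r = r0;
        best_c = c0;
        best_disp = disp;
      }
    }
  }
  if (!R_finite(best)) best = 0.0;
  return NumericVector::create(best_r, best_c, best);
}

// Agglomerative Ward clustering of 2-D points under a symmetric
// nearest-neighbour connectivity constraint. `nn` is an n x k 0-based index
// matrix of each point's k nearest neighbours. Merges are restricted to
// cluster pairs connected in the (symmetrized) graph; if the graph runs out
// of connected pairs before reaching k_clusters, the globally closest pair
// is merged instead. Returns 0-based cluster labels (arbitrary ids).
// [[Rcpp::export]]
IntegerVector ward_connected(const NumericMatrix& coords, const IntegerMatrix& nn,
                             int k_clusters) {
  const int n = coords.nrow();
  if (k_clusters < 1) stop("k_clusters must be >= 1");
  if (n < k_clusters) stop("fewer points than clusters");

  std::vector<double> D((size_t)n * n, R_PosInf);
  std::vector<char> allowed((size_t)n * n, 0);
  std::vector<int> size(n, 1);
  std::vector<char> active(n, 1);
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;

  auto idx = [n](int i, int j) { return (size_t)i * n + j; };

  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      const double dx = coords(i, 0) - coords(j, 0);
      const double dy = coords(i, 1) - coords(j, 1);
      D[idx(i, j)] = dx * dx + dy * dy;
    }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < nn.ncol(); ++c) {
      const int j = nn(i, c);
      if (j < 0 || j >= n || j == i) continue;
      allowed[idx(i, j)] = 1;
      allowed[idx(j, i)] = 1;
    }

  // per-cluster nearest connected partner cache
  std::vector<int> nnb(n, -1);
  std::vector<double> nnd(n, R_PosInf);
  auto refresh = [&](int i) {
    nnb[i] = -1;
    nnd[i] = R_PosInf;
    const size_t base = (size_t)i * n;
    for (int j = 0; j < n; ++j) {
      if (j == i || !active[j] || !allowed[base + j]) continue;
      if (D[base + j] < nnd[i]) {
        nnd[i] = D[base + j];
        nnb[i] = j;
      }
    }
  };
  for (int i = 0; i < n; ++i) refresh(i);

  int n_active = n;
  while (n_active > k_clusters) {
    int bi = -1;
    double bd = R_PosInf;
    for (int i = 0; i < n; ++i)
      if (active[i] && nnd[i] < bd) {
        bd = nnd[i];
        bi = i;
      }
    int i, j;
    if (bi >= 0) {
      i = bi;
      j = nnb[i];
    } else {
      // connectivity exhausted: fall back to globally closest active pair
      i = -1;
      j = -1;
      for (int a = 0; a < n; ++a) {
        if (!active[a]) continue;
        const size_t base = (size_t)a * n;
        for (int b = a + 1; b < n; ++b) {
          if (!active[b]) continue;
          if (D[base + b] < bd) {
            bd = D[base + b];
            i = a;
            j = b;
          }
        }
      }
    }
    if (i > j) std::swap(i, j);
    const int ni = size[i], nj = size[j];
    // Lance-Williams update for Ward on squared Euclidean distances
    for (int l = 0; l < n; ++l) {
      if (!active[l] || l == i || l == j) continue;
      const int nl = size[l];
      const double dil = D[idx(i, l)], djl = D[idx(j, l)], dij = D[idx(i, j)];
      const double nd =
          ((ni + nl) * dil + (nj + nl) * djl - nl * dij) / (double)(ni + nj + nl);
      D[idx(i, l)] = nd;
      D[idx(l, i)] = nd;
      const char al = allowed[idx(i, l)] || allowed[idx(j, l)];
      allowed[idx(i, l)] = al;
      allowed[idx(l, i)] = al;
    }
    size[i] = ni + nj;
    active[j] = 0;
    parent[j] = i;
    --n_active;
    refresh(i);
    for (int l = 0; l < n; ++l)
      if (active[l] && l != i && (nnb[l] == i || nnb[l] == j)) refresh(l);
      else if (active[l] && l != i && allowed[idx(i, l)] && D[idx(i, l)] < nnd[l]) {
        nnd[l] = D[idx(i, l)];
        nnb[l] = i;
      }
  }

  IntegerVector labels(n);
  for (int i = 0; i < n; ++i) {
    int r = i;
    while (parent[r] != r) r = parent[r];
    labels[i] = r;
  }
  return labels;
}
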