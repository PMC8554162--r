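#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---- union-find ------------------------------------------------------------

static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]]; // path halving
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// 8-connected component labeling of a logical/0-1 matrix.
// Returns an integer matrix; background 0, components labeled 1..k
// (label order arbitrary; callers sort by size).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix &mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent;
  parent.reserve(1024);
  int next = 0;
  // first pass: scan column-major; neighbors already visited are
  // (r-1,c-1), (r,c-1), (r+1,c-1), (r-1,c)
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) { lab(r, c) = -1; continue; }
      int best = -1;
      const int rr[4] = { r - 1, r, r + 1, r - 1 };
      const int cc[4] = { c - 1, c - 1, c - 1, c };
      int nb[4]; int nn = 0;
      for (int k = 0; k < 4; ++k) {
        if (rr[k] < 0 || rr[k] >= H || cc[k] < 0) continue;
        int l = lab(rr[k], cc[k]);
        if (l >= 0) { nb[nn++] = l; if (best < 0 || l < best) best = l; }
      }
      if (best < 0) {
        lab(r, c) = next;
        parent.push_back(next);
        ++next;
      } else {
        lab(r, c) = best;
        for (int k = 0; k < nn; ++k) uf_union(parent, best, nb[k]);
      }
    }
  }
  // second pass: resolve + compact labels to 1..k
  std::vector<int> remap(next, 0);
  int k = 0;
  for (int i = 0; i < next; ++i)
    if (uf_find(parent, i) == i) remap[i] = ++k;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      int l = lab(r, c);
      lab(r, c) = (l < 0) ? 0 : remap[uf_find(parent, l)];
    }
  return lab;
}

// ---- z-buffer scatter ------------------------------------------------------

// For points landing on linear pixel indices idx (1-based, length n_pts) with
// depths z, fill an n_out-cell buffer keeping the smallest z per cell.
// Returns list(z = depth per cell (NA where empty), who = 1-based index of the
// winning point per cell (0 where empty)).
// [[Rcpp::export]]
List cpp_zbuffer(const IntegerVector &idx, const NumericVector &z, int n_out) {
  NumericVector zb(n_out, NA_REAL);
  IntegerVector who(n_out, 0);
  const int n = idx.size();
  for (int i = 0; i < n; ++i) {
    int j = idx[i] - 1;
    if (j < 0 || j >= n_out) continue;
    double zi = z[i];
    if (ISNAN(zb[j]) || zi < zb[j]) { zb[j] = zi; who[j] = i + 1; }
  }
  return List::create(_["z"] = zb, _["who"] = who);
}

// Footprint z-buffer scatter for depth registration: each depth pixel maps
// to the block of color pixels whose centers fall inside its projected
// footprint (half-widths hu, hv around the continuous landing point (u, v),
// 0-based pixel-center coordinates). Nearer z wins per cell. With equal
// intrinsics (hu = hv = 0.5) this reduces to nearest-pixel scatter.
// [[Rcpp::export]]
NumericMatrix cpp_zbuffer_splat(const NumericVector &u, const NumericVector &v,
                                const NumericVector &z, double hu, double hv,
                                int H, int W) {
  NumericMatrix zb(H, W);
  std::fill(zb.begin(), zb.end(), NA_REAL);
  const int n = u.size();
  for (int i = 0; i < n; ++i) {
    int u0 = (int)std::ceil(u[i] - hu), u1 = (int)std::floor(u[i] + hu);
    int v0 = (int)std::ceil(v[i] - hv), v1 = (int)std::floor(v[i] + hv);
    if (u0 < 0) u0 = 0;
    if (v0 < 0) v0 = 0;
    if (u1 >= W) u1 = W - 1;
    if (v1 >= H) v1 = H - 1;
    const double zi = z[i];
    for (int c = u0; c <= u1; ++c)
      for (int r = v0; r <= v1; ++r) {
        double &cell = zb(r, c);
        if (ISNAN(cell) || zi < cell) cell = zi;
      }
  }
  return zb;
}

// ---- RGB distance mask -----------------------------------------------------

// col: raw vector of length H*W*3 in R array order (channel planes), values
// 0..255. Foreground (255) where squared RGB distance to (r,g,b) <= T^2,
// else 0.
// [[Rcpp::export]]
IntegerVector cpp_color_mask(const RawVector &col, int npix,
                             int r, int g, int b, double T) {
  IntegerVector out(npix);
  const int T2 = (int)(T * T);
  for (int i = 0; i < npix; ++i) {
    int dr = (int)col[i] - r;
    int dg = (int)col[i + npix] - g;
    int db = (int)col[i + 2 * npix] - b;
    out[i] = (dr * dr + dg * dg + db * db) <= T2 ? 255 : 0;
  }
  return out;
}

// ---- sensor noise ----------------------------------------------------------

// Additive Gaussian noise on 8-bit samples, clamped and rounded.
// Uses R's RNG (deterministic under set.seed).
// [[Rcpp::export]]
RawVector cpp_noise_u8(const RawVector &x, double sigma) {
  const R_xlen_t n = x.size();
  RawVector out(n);
  if (sigma <= 0) { std::copy(x.begin(), x.end(), out.begin()); return out; }
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = (double)x[i] + norm_rand() * sigma;
    v = std::round(v);
    if (v < 0) v = 0; else if (v > 255) v = 255;
    out[i] = (Rbyte)v;
  }
  return out;
}

// Depth-sensor noise: per-pixel Gaussian (meters), optional quantization step
// and dropout probability. Invalid pixels (<= 0 or NA) stay invalid (0).
// [[Rcpp::export]]
NumericVector cpp_noise_depth(const NumericVector &z, double sigma,
                              double quant, double dropout) {
  const R_xlen_t n = z.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = z[i];
    if (ISNAN(v) || v <= 0) { out[i] = 0.0; continue; }
    if (dropout > 0 && unif_rand() < dropout) { out[i] = 0.0; continue; }
    if (sigma > 0) v += norm_rand() * sigma;
    if (quant > 0) v = std::round(v / quant) * quant;
    out[i] = (v > 0) ? v : 0.0;
  }
  return out;
}
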