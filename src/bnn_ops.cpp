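// Packed binary-network kernels and im2col helpers.
//
// Bit conventions (shared with the R level and the on-disk format):
//   * stored bit b in {0,1} encodes the value 2b - 1 in {-1,+1};
//   * flat bit vectors are packed little-endian: bit i lives at bit (i % 64)
//     of 64-bit word (i / 64);
//   * feature maps C x H x W are packed per pixel: pixel p = h + H*w owns
//     ceil(C/64) consecutive words holding its channel bits (channel c at
//     bit c % 64 of word c / 64).
// Zero padding is excluded from every accumulation (a padded tap contributes
// exactly 0, never +/-1), implemented via bounds checks rather than a stored
// mask.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
using namespace Rcpp;

static inline int popcnt64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int n = 0;
  while (x) { x &= x - 1; ++n; }
  return n;
#endif
}

static inline const uint64_t* words_of(const RawVector& r) {
  return reinterpret_cast<const uint64_t*>(RAW(r));
}
static inline uint64_t* words_of(RawVector& r) {
  return reinterpret_cast<uint64_t*>(RAW(r));
}

// All-ones mask for the first (n mod 64) bits of a tail word.
static inline uint64_t tail_mask(int nbits_in_word) {
  if (nbits_in_word >= 64) return ~UINT64_C(0);
  return (UINT64_C(1) << nbits_in_word) - 1;
}

// [[Rcpp::export]]
RawVector pack_bits_cpp(IntegerVector bits) {
  const int n = bits.size();
  const int nw = (n + 63) / 64;
  RawVector out(nw * 8);
  std::memset(RAW(out), 0, out.size());
  uint64_t* w = words_of(out);
  for (int i = 0; i < n; ++i) {
    if (bits[i] != 0) w[i / 64] |= UINT64_C(1) << (i % 64);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector unpack_bits_cpp(RawVector packed, int n) {
  if ((int)packed.size() < 8 * ((n + 63) / 64))
    stop("packed buffer too short for %d bits", n);
  IntegerVector out(n);
  const uint64_t* w = words_of(packed);
  for (int i = 0; i < n; ++i)
    out[i] = (w[i / 64] >> (i % 64)) & 1 ? 1 : 0;
  return out;
}

// +/-1 dot product of two packed bit vectors via XNOR + popcount.
// mask (optional, packed like the operands) marks valid positions; invalid
// positions contribute 0.  Returns 2*popcount(xnor & mask) - popcount(mask).
// [[Rcpp::export]]
int xnor_popcount_cpp(RawVector a, RawVector b, int n,
                      Nullable<RawVector> mask = R_NilValue) {
  const int nw = (n + 63) / 64;
  if ((int)a.size() < 8 * nw || (int)b.size() < 8 * nw)
    stop("operand shorter than %d bits", n);
  const uint64_t* wa = words_of(a);
  const uint64_t* wb = words_of(b);
  const uint64_t* wm = NULL;
  RawVector m;
  if (mask.isNotNull()) {
    m = mask.get();
    if ((int)m.size() < 8 * nw) stop("mask shorter than %d bits", n);
    wm = words_of(m);
  }
  long pop = 0, nvalid = 0;
  for (int q = 0; q < nw; ++q) {
    uint64_t valid = wm ? wm[q] : ~UINT64_C(0);
    if (q == nw - 1) valid &= tail_mask(n - 64 * q);
    pop += popcnt64(~(wa[q] ^ wb[q]) & valid);
    nvalid += popcnt64(valid);
  }
  return (int)(2 * pop - nvalid);
}

// [[Rcpp::export]]
RawVector pack_chw_cpp(IntegerVector bits, int C, int H, int W) {
  if ((int)bits.size() != C * H * W) stop("bit count != C*H*W");
  const int wpp = (C + 63) / 64;
  RawVector out((R_xlen_t)H * W * wpp * 8);
  std::memset(RAW(out), 0, out.size());
  uint64_t* w = words_of(out);
  for (int x = 0; x < W; ++x)
    for (int h = 0; h < H; ++h) {
      const int p = h + H * x;
      const int base = (int)((R_xlen_t)C * p);  // bits order: c fastest
      for (int c = 0; c < C; ++c)
        if (bits[base + c] != 0)
          w[(R_xlen_t)p * wpp + c / 64] |= UINT64_C(1) << (c % 64);
    }
  return out;
}

// [[Rcpp::export]]
IntegerVector unpack_chw_cpp(RawVector packed, int C, int H, int W) {
  const int wpp = (C + 63) / 64;
  if ((R_xlen_t)packed.size() < (R_xlen_t)H * W * wpp * 8)
    stop("packed feature map too short");
  IntegerVector out(C * H * W);
  const uint64_t* w = words_of(packed);
  for (int p = 0; p < H * W; ++p)
    for (int c = 0; c < C; ++c)
      out[(R_xlen_t)C * p + c] =
        (w[(R_xlen_t)p * wpp + c / 64] >> (c % 64)) & 1 ? 1 : 0;
  return out;
}

// Repack conv weights given as an R array dim c(Cout, Cin, k, k)
// (bit index j + Cout*(i + Cin*(ky + k*kx))) into the engine layout
// [j][ky][kx][word over Cin].
// [[Rcpp::export]]
RawVector pack_conv_weights_cpp(IntegerVector wbits, int Cout, int Cin, int k) {
  if ((int)wbits.size() != Cout * Cin * k * k) stop("weight bit count mismatch");
  const int wpp = (Cin + 63) / 64;
  RawVector out((R_xlen_t)Cout * k * k * wpp * 8);
  std::memset(RAW(out), 0, out.size());
  uint64_t* w = words_of(out);
  for (int kx = 0; kx < k; ++kx)
    for (int ky = 0; ky < k; ++ky)
      for (int i = 0; i < Cin; ++i)
        for (int j = 0; j < Cout; ++j) {
          const R_xlen_t src = j + (R_xlen_t)Cout * (i + (R_xlen_t)Cin * (ky + k * kx));
          if (wbits[src] != 0) {
            const R_xlen_t tap = ((R_xlen_t)j * k + ky) * k + kx;
            w[tap * wpp + i / 64] |= UINT64_C(1) << (i % 64);
          }
        }
  return out;
}

// Binary convolution: packed C x H x W input, packed weights (layout above),
// stride 1, square kernel k with padding pad.  Padded taps are skipped, so
// they contribute 0 to the +/-1 accumulation.  Output: integer accumulators
// in R array order dim c(Cout, H, W).
// [[Rcpp::export]]
IntegerVector bconv2d_cpp(RawVector input, int C, int H, int W,
                          RawVector weights, int Cout, int k, int pad) {
  const int wpp = (C + 63) / 64;
  if ((R_xlen_t)input.size() < (R_xlen_t)H * W * wpp * 8)
    stop("packed input too short");
  if ((R_xlen_t)weights.size() < (R_xlen_t)Cout * k * k * wpp * 8)
    stop("packed weights too short");
  const uint64_t* in = words_of(input);
  const uint64_t* wt = words_of(weights);
  const uint64_t cmask = tail_mask(C - 64 * (wpp - 1));
  IntegerVector out((R_xlen_t)Cout * H * W);
  for (int j = 0; j < Cout; ++j) {
    const uint64_t* wj = wt + (R_xlen_t)j * k * k * wpp;
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        int acc = 0;
        for (int ky = 0; ky < k; ++ky) {
          const int iy = y + ky - pad;
          if (iy < 0 || iy >= H) continue;
          for (int kx = 0; kx < k; ++kx) {
            const int ix = x + kx - pad;
            if (ix < 0 || ix >= W) continue;
            const uint64_t* ip = in + (R_xlen_t)(iy + H * ix) * wpp;
            const uint64_t* wp = wj + (R_xlen_t)(ky * k + kx) * wpp;
            int pop = 0;
            for (int q = 0; q < wpp; ++q) {
              uint64_t v = ~(ip[q] ^ wp[q]);
              if (q == wpp - 1) v &= cmask;
              pop += popcnt64(v);
            }
            acc += 2 * pop - C;
          }
        }
        out[j + (R_xlen_t)Cout * (y + H * x)] = acc;
      }
  }
  return out;
}

// 2x2 stride-2 OR pooling on a packed feature map (wordwise OR of the four
// pixels of each block); equals max pooling on the +/-1 values.
// [[Rcpp::export]]
RawVector orpool2_cpp(RawVector input, int C, int H, int W) {
  if (H % 2 || W % 2) stop("OR pooling needs even spatial dimensions");
  const int wpp = (C + 63) / 64;
  const int Ho = H / 2, Wo = W / 2;
  RawVector out((R_xlen_t)Ho * Wo * wpp * 8);
  std::memset(RAW(out), 0, out.size());
  const uint64_t* in = words_of(input);
  uint64_t* w = words_of(out);
  for (int ox = 0; ox < Wo; ++ox)
    for (int oy = 0; oy < Ho; ++oy) {
      const R_xlen_t po = (R_xlen_t)(oy + Ho * ox) * wpp;
      const R_xlen_t p00 = (R_xlen_t)(2 * oy + H * (2 * ox)) * wpp;
      const R_xlen_t p10 = (R_xlen_t)(2 * oy + 1 + H * (2 * ox)) * wpp;
      const R_xlen_t p01 = (R_xlen_t)(2 * oy + H * (2 * ox + 1)) * wpp;
      const R_xlen_t p11 = (R_xlen_t)(2 * oy + 1 + H * (2 * ox + 1)) * wpp;
      for (int q = 0; q < wpp; ++q)
        w[po + q] = in[p00 + q] | in[p10 + q] | in[p01 + q] | in[p11 + q];
    }
  return out;
}

// Fully connected layer: m XNOR-popcount dot products of a packed length-n
// node vector against packed weight rows (row r starts at word r*ceil(n/64)).
// [[Rcpp::export]]
IntegerVector bfc_cpp(RawVector nodes, int n, RawVector weights, int m) {
  const int wpr = (n + 63) / 64;
  if ((int)nodes.size() < 8 * wpr) stop("packed nodes too short");
  if ((R_xlen_t)weights.size() < (R_xlen_t)m * wpr * 8)
    stop("packed weight rows too short");
  const uint64_t* nd = words_of(nodes);
  const uint64_t* wt = words_of(weights);
  const uint64_t tmask = tail_mask(n - 64 * (wpr - 1));
  IntegerVector out(m);
  for (int r = 0; r < m; ++r) {
    const uint64_t* wr = wt + (R_xlen_t)r * wpr;
    int pop = 0;
    for (int q = 0; q < wpr; ++q) {
      uint64_t v = ~(nd[q] ^ wr[q]);
      if (q == wpr - 1) v &= tmask;
      pop += popcnt64(v);
    }
    out[r] = 2 * pop - n;
  }
  return out;
}

// First-layer convolution for integer_input mode: real-valued single-plane
// input times +/-1 weights, literal zero padding.  x: dim c(Cin, H, W);
// wpm: +/-1 integers, dim c(Cout, Cin, k, k).  Output dim c(Cout, H, W).
// [[Rcpp::export]]
NumericVector iconv2d_cpp(NumericVector x, int Cin, int H, int W,
                          IntegerVector wpm, int Cout, int k, int pad) {
  if ((int)x.size() != Cin * H * W) stop("input size mismatch");
  if ((int)wpm.size() != Cout * Cin * k * k) stop("weight size mismatch");
  NumericVector out((R_xlen_t)Cout * H * W);
  for (int j = 0; j < Cout; ++j)
    for (int xc = 0; xc < W; ++xc)
      for (int y = 0; y < H; ++y) {
        double acc = 0.0;
        for (int kx = 0; kx < k; ++kx) {
          const int ix = xc + kx - pad;
          if (ix < 0 || ix >= W) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = y + ky - pad;
            if (iy < 0 || iy >= H) continue;
            for (int i = 0; i < Cin; ++i)
              acc += x[i + (R_xlen_t)Cin * (iy + H * ix)] *
                     wpm[j + (R_xlen_t)Cout * (i + (R_xlen_t)Cin * (ky + k * kx))];
          }
        }
        out[j + (R_xlen_t)Cout * (y + H * xc)] = acc;
      }
  return out;
}

// im2col for batched feature maps, dim c(Cin, H, W, B) -> matrix with
// rows (ci, ky, kx) [ci fastest] and columns (h + H*w) + H*W*b, matching
// matrix(Warr, Cout, Cin*k*k) %*% cols for Warr dim c(Cout, Cin, k, k).
// Out-of-bounds taps are zero.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int Cin, int H, int W, int B,
                         int k, int pad) {
  if ((R_xlen_t)x.size() != (R_xlen_t)Cin * H * W * B) stop("input size mismatch");
  const int R = Cin * k * k;
  const R_xlen_t ncol = (R_xlen_t)H * W * B;
  NumericMatrix out(R, ncol);
  double* po = REAL(out);
  const double* px = REAL(x);
  for (int b = 0; b < B; ++b) {
    const double* xb = px + (R_xlen_t)Cin * H * W * b;
    for (int wcol = 0; wcol < W; ++wcol)
      for (int h = 0; h < H; ++h) {
        double* col = po + (R_xlen_t)R * ((h + (R_xlen_t)H * wcol) + (R_xlen_t)H * W * b);
        for (int kx = 0; kx < k; ++kx) {
          const int iw = wcol + kx - pad;
          for (int ky = 0; ky < k; ++ky) {
            const int ih = h + ky - pad;
            double* dst = col + Cin * (ky + k * kx);
            if (iw < 0 || iw >= W || ih < 0 || ih >= H) {
              std::memset(dst, 0, sizeof(double) * Cin);
            } else {
              std::memcpy(dst, xb + (R_xlen_t)Cin * (ih + (R_xlen_t)H * iw),
                          sizeof(double) * Cin);
            }
          }
        }
      }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-add column gradients back to input layout.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int Cin, int H, int W, int B,
                         int k, int pad) {
  const int R = Cin * k * k;
  if (cols.nrow() != R || (R_xlen_t)cols.ncol() != (R_xlen_t)H * W * B)
    stop("column matrix shape mismatch");
  NumericVector out((R_xlen_t)Cin * H * W * B);
  double* po = REAL(out);
  const double* pc = REAL(cols);
  for (int b = 0; b < B; ++b) {
    double* xb = po + (R_xlen_t)Cin * H * W * b;
    for (int wcol = 0; wcol < W; ++wcol)
      for (int h = 0; h < H; ++h) {
        const double* col = pc + (R_xlen_t)R * ((h + (R_xlen_t)H * wcol) + (R_xlen_t)H * W * b);
        for (int kx = 0; kx < k; ++kx) {
          const int iw = wcol + kx - pad;
          if (iw < 0 || iw >= W) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int ih = h + ky - pad;
            if (ih < 0 || ih >= H) continue;
            double* dst = xb + (R_xlen_t)Cin * (ih + (R_xlen_t)H * iw);
            const double* src = col + Cin * (ky + k * kx);
            for (int i = 0; i < Cin; ++i) dst[i] += src[i];
          }
        }
      }
  }
  return out;
}
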