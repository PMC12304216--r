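// im2col / col2im and 2x up/down scatter-gather primitives for the 3D
// convolutional network. Feature maps are C x N matrices (channels x voxels,
// voxels column-major over dims). The GEMMs themselves run in R via BLAS.
#include <Rcpp.h>
using namespace Rcpp;

static inline int odim(int d, int k, int s, int p) { return (d + 2 * p - k) / s + 1; }

// [[Rcpp::export]]
NumericMatrix cpp_im2col3d(NumericMatrix x, IntegerVector dims,
                           int k, int stride, int pad) {
  const int C = x.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = odim(nx, k, stride, pad), oy = odim(ny, k, stride, pad),
            oz = odim(nz, k, stride, pad);
  const int K = C * k * k * k, N = ox * oy * oz;
  NumericMatrix cols(K, N);
  for (int zo = 0; zo < oz; ++zo)
    for (int yo = 0; yo < oy; ++yo)
      for (int xo = 0; xo < ox; ++xo) {
        int col = xo + ox * (yo + oy * zo);
        for (int c = 0; c < k; ++c) {
          int zi = zo * stride + c - pad;
          bool zok = zi >= 0 && zi < nz;
          for (int b = 0; b < k; ++b) {
            int yi = yo * stride + b - pad;
            bool yok = yi >= 0 && yi < ny;
            for (int a = 0; a < k; ++a) {
              int xi = xo * stride + a - pad;
              int row0 = C * (a + k * (b + k * c));
              if (zok && yok && xi >= 0 && xi < nx) {
                int vox = xi + nx * (yi + ny * zi);
                for (int ch = 0; ch < C; ++ch)
                  cols(row0 + ch, col) = x(ch, vox);
              }
            }
          }
        }
      }
  IntegerVector od = IntegerVector::create(ox, oy, oz);
  cols.attr("out_dims") = od;
  return cols;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im3d(NumericMatrix cols, IntegerVector dims,
                           int k, int stride, int pad, int C) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = odim(nx, k, stride, pad), oy = odim(ny, k, stride, pad),
            oz = odim(nz, k, stride, pad);
  NumericMatrix x(C, nx * ny * nz);
  for (int zo = 0; zo < oz; ++zo)
    for (int yo = 0; yo < oy; ++yo)
      for (int xo = 0; xo < ox; ++xo) {
        int col = xo + ox * (yo + oy * zo);
        for (int c = 0; c < k; ++c) {
          int zi = zo * stride + c - pad;
          if (zi < 0 || zi >= nz) continue;
          for (int b = 0; b < k; ++b) {
            int yi = yo * stride + b - pad;
            if (yi < 0 || yi >= ny) continue;
            for (int a = 0; a < k; ++a) {
              int xi = xo * stride + a - pad;
              if (xi < 0 || xi >= nx) continue;
              int vox = xi + nx * (yi + ny * zi);
              int row0 = C * (a + k * (b + k * c));
              for (int ch = 0; ch < C; ++ch)
                x(ch, vox) += cols(row0 + ch, col);
            }
          }
        }
      }
  return x;
}

// Forward of a kernel-2 stride-2 transposed convolution: y8 holds, for each
// coarse voxel, the 8 fine-grid outputs stacked rowwise (ch + C*offset with
// offset = a + 2b + 4c). Scatter them onto the 2x fine grid.
// [[Rcpp::export]]
NumericMatrix cpp_scatter_up2(NumericMatrix y8, IntegerVector dims_in) {
  const int nxi = dims_in[0], nyi = dims_in[1], nzi = dims_in[2];
  const int C = y8.nrow() / 8;
  const int nx = 2 * nxi, ny = 2 * nyi, nz = 2 * nzi;
  NumericMatrix y(C, nx * ny * nz);
  for (int k = 0; k < nzi; ++k)
    for (int j = 0; j < nyi; ++j)
      for (int i = 0; i < nxi; ++i) {
        int col = i + nxi * (j + nyi * k);
        for (int c = 0; c < 2; ++c)
          for (int b = 0; b < 2; ++b)
            for (int a = 0; a < 2; ++a) {
              int off = a + 2 * (b + 2 * c);
              int vox = (2 * i + a) + nx * ((2 * j + b) + ny * (2 * k + c));
              for (int ch = 0; ch < C; ++ch)
                y(ch, vox) = y8(ch + C * off, col);
            }
      }
  return y;
}

// Inverse gather: fine grid (C x 8N) -> stacked coarse blocks (8C x N).
// Serves as backward of the transposed conv and forward im2col of the
// kernel-2 stride-2 strided convolution.
// [[Rcpp::export]]
NumericMatrix cpp_gather_down2(NumericMatrix x, IntegerVector dims_in) {
  const int nxi = dims_in[0], nyi = dims_in[1], nzi = dims_in[2];
  const int C = x.nrow();
  const int nx = 2 * nxi, ny = 2 * nyi;
  NumericMatrix g(8 * C, nxi * nyi * nzi);
  for (int k = 0; k < nzi; ++k)
    for (int j = 0; j < nyi; ++j)
      for (int i = 0; i < nxi; ++i) {
        int col = i + nxi * (j + nyi * k);
        for (int c = 0; c < 2; ++c)
          for (int b = 0; b < 2; ++b)
            for (int a = 0; a < 2; ++a) {
              int off = a + 2 * (b + 2 * c);
              int vox = (2 * i + a) + nx * ((2 * j + b) + ny * (2 * k + c));
              for (int ch = 0; ch < C; ++ch)
                g(ch + C * off, col) = x(ch, vox);
            }
      }
  return g;
}
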