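// Dense 3D convolution primitives for the residual parcellation model.
//
// Layout conventions (match R's column-major array order, x fastest):
//   feature tensors: dim (nx, ny, nz, C, B)
//   conv weights:    dim (3, 3, 3, Cin, Cout), bias length Cout
//
// Only stride-1 kernels of size 3 are needed. A single "valid" convolution
// over a zero-padded input covers all three layer types used by the model:
//   pad = 0 -> unpadded conv  (spatial dims shrink by 2)
//   pad = 1 -> shape-preserving conv
//   pad = 2 -> transposed conv (full correlation; spatial dims grow by 2)
// Transposed convolution with stride 1 is a full correlation up to a fixed
// permutation of the kernel, which is immaterial for learned weights.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Dims5 {
  int nx, ny, nz, C, B;
  size_t V() const { return (size_t)nx * ny * nz; }
};

Dims5 get_dims5(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 5) stop("expected a 5D array (nx, ny, nz, channels, batch)");
  return Dims5{d[0], d[1], d[2], d[3], d[4]};
}

// Zero-pad every spatial plane by `pad` voxels on each side.
std::vector<double> pad_input(const double* x, const Dims5& d, int pad,
                              int& px, int& py, int& pz) {
  px = d.nx + 2 * pad; py = d.ny + 2 * pad; pz = d.nz + 2 * pad;
  size_t Vp = (size_t)px * py * pz;
  std::vector<double> xp(Vp * d.C * d.B, 0.0);
  for (int cb = 0; cb < d.C * d.B; ++cb) {
    const double* src = x + (size_t)cb * d.V();
    double* dst = xp.data() + (size_t)cb * Vp;
    for (int k = 0; k < d.nz; ++k)
      for (int j = 0; j < d.ny; ++j)
        std::memcpy(dst + ((size_t)(k + pad) * py + (j + pad)) * px + pad,
                    src + ((size_t)k * d.ny + j) * d.nx,
                    sizeof(double) * d.nx);
  }
  return xp;
}

// Gather the shifted neighbourhood (offset o) of the padded input into a
// dense (Vout x Cin) matrix, one column per input channel.
void gather_offset(const double* xp, int px, int py, int pz, int Cin,
                   size_t b, int ox, int oy, int oz, int o, arma::mat& Xg) {
  const int dx = o % 3, dy = (o / 3) % 3, dz = o / 9;
  const size_t Vp = (size_t)px * py * pz;
  for (int cin = 0; cin < Cin; ++cin) {
    const double* base = xp + (b * Cin + cin) * Vp;
    double* col = Xg.colptr(cin);
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j)
        std::memcpy(col + ((size_t)k * oy + j) * ox,
                    base + ((size_t)(k + dz) * py + (j + dy)) * px + dx,
                    sizeof(double) * ox);
  }
}

void scatter_offset_add(double* dxp, int px, int py, int pz, int Cin,
                        size_t b, int ox, int oy, int oz, int o,
                        const arma::mat& dXg) {
  const int dx = o % 3, dy = (o / 3) % 3, dz = o / 9;
  const size_t Vp = (size_t)px * py * pz;
  for (int cin = 0; cin < Cin; ++cin) {
    double* base = dxp + (b * Cin + cin) * Vp;
    const double* col = dXg.colptr(cin);
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j) {
        double* dst = base + ((size_t)(k + dz) * py + (j + dy)) * px + dx;
        const double* src = col + ((size_t)k * oy + j) * ox;
        for (int i = 0; i < ox; ++i) dst[i] += src[i];
      }
  }
}

arma::mat weight_slice(const double* w, int Cin, int Cout, int o) {
  arma::mat Wo(Cin, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      Wo(ci, co) = w[o + 27 * ((size_t)ci + (size_t)Cin * co)];
  return Wo;
}

} // namespace

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector bias,
                         int pad) {
  Dims5 d = get_dims5(x);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 5 || wd[0] != 3 || wd[1] != 3 || wd[2] != 3 || wd[3] != d.C)
    stop("weight array must have dim (3,3,3,Cin,Cout) with Cin matching input");
  const int Cout = wd[4];
  int px, py, pz;
  std::vector<double> xp = pad_input(REAL(x), d, pad, px, py, pz);
  const int ox = px - 2, oy = py - 2, oz = pz - 2;
  if (ox < 1 || oy < 1 || oz < 1) stop("spatial underflow in convolution");
  const size_t Vout = (size_t)ox * oy * oz;

  NumericVector y(Vout * Cout * d.B);
  y.attr("dim") = IntegerVector::create(ox, oy, oz, Cout, d.B);
  arma::mat Xg(Vout, d.C);
  arma::rowvec bv(const_cast<double*>(REAL(bias)), Cout, false);

  for (size_t b = 0; b < (size_t)d.B; ++b) {
    arma::mat Y(REAL(y) + b * Vout * Cout, Vout, Cout, false, true);
    for (int o = 0; o < 27; ++o) {
      gather_offset(xp.data(), px, py, pz, d.C, b, ox, oy, oz, o, Xg);
      Y += Xg * weight_slice(REAL(w), d.C, Cout, o);
    }
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector dy, int pad) {
  Dims5 d = get_dims5(x);
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[4];
  int px, py, pz;
  std::vector<double> xp = pad_input(REAL(x), d, pad, px, py, pz);
  const int ox = px - 2, oy = py - 2, oz = pz - 2;
  const size_t Vout = (size_t)ox * oy * oz, Vp = (size_t)px * py * pz;

  std::vector<double> dxp(Vp * d.C * d.B, 0.0);
  NumericVector dw(27 * (size_t)d.C * Cout);
  dw.attr("dim") = IntegerVector::create(3, 3, 3, d.C, Cout);
  NumericVector db(Cout);
  arma::mat Xg(Vout, d.C), dXg(Vout, d.C);

  for (size_t b = 0; b < (size_t)d.B; ++b) {
    arma::mat dY(REAL(dy) + b * Vout * Cout, Vout, Cout, false);
    for (int co = 0; co < Cout; ++co) db[co] += arma::accu(dY.col(co));
    for (int o = 0; o < 27; ++o) {
      gather_offset(xp.data(), px, py, pz, d.C, b, ox, oy, oz, o, Xg);
      arma::mat dWo = Xg.t() * dY;
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < d.C; ++ci)
          dw[o + 27 * ((size_t)ci + (size_t)d.C * co)] += dWo(ci, co);
      dXg = dY * weight_slice(REAL(w), d.C, Cout, o).t();
      scatter_offset_add(dxp.data(), px, py, pz, d.C, b, ox, oy, oz, o, dXg);
    }
  }

  // crop padding off the input gradient
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  for (int cb = 0; cb < d.C * d.B; ++cb) {
    const double* src = dxp.data() + (size_t)cb * Vp;
    double* dst = REAL(dx) + (size_t)cb * d.V();
    for (int k = 0; k < d.nz; ++k)
      for (int j = 0; j < d.ny; ++j)
        std::memcpy(dst + ((size_t)k * d.ny + j) * d.nx,
                    src + ((size_t)(k + pad) * py + (j + pad)) * px + pad,
                    sizeof(double) * d.nx);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Max pooling, kernel 3, stride 1 (spatial dims shrink by 2).
// [[Rcpp::export(name = ".maxpool3_fwd")]]
List maxpool3_fwd(NumericVector x) {
  Dims5 d = get_dims5(x);
  const int ox = d.nx - 2, oy = d.ny - 2, oz = d.nz - 2;
  if (ox < 1 || oy < 1 || oz < 1) stop("spatial underflow in max pooling");
  const size_t Vout = (size_t)ox * oy * oz, Vin = d.V();

  NumericVector y(Vout * d.C * d.B);
  IntegerVector idx(Vout * d.C * d.B); // argmax linear spatial index, 0-based
  y.attr("dim") = IntegerVector::create(ox, oy, oz, d.C, d.B);
  idx.attr("dim") = y.attr("dim");

  for (int cb = 0; cb < d.C * d.B; ++cb) {
    const double* in = REAL(x) + (size_t)cb * Vin;
    double* out = REAL(y) + (size_t)cb * Vout;
    int* am = INTEGER(idx) + (size_t)cb * Vout;
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j)
        for (int i = 0; i < ox; ++i) {
          double best = -std::numeric_limits<double>::infinity();
          size_t besti = 0;
          for (int dz = 0; dz < 3; ++dz)
            for (int dy = 0; dy < 3; ++dy)
              for (int dx = 0; dx < 3; ++dx) {
                size_t p = ((size_t)(k + dz) * d.ny + (j + dy)) * d.nx + (i + dx);
                if (in[p] > best) { best = in[p]; besti = p; }
              }
          size_t q = ((size_t)k * oy + j) * ox + i;
          out[q] = best;
          am[q] = (int)besti;
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool3_bwd")]]
NumericVector maxpool3_bwd(NumericVector dy, IntegerVector idx,
                           IntegerVector in_dims) {
  Dims5 d = get_dims5(dy);
  const size_t Vin = (size_t)in_dims[0] * in_dims[1] * in_dims[2];
  NumericVector dx(Vin * d.C * d.B);
  dx.attr("dim") = IntegerVector::create(in_dims[0], in_dims[1], in_dims[2],
                                         d.C, d.B);
  const size_t Vout = d.V();
  for (int cb = 0; cb < d.C * d.B; ++cb) {
    const double* g = REAL(dy) + (size_t)cb * Vout;
    const int* am = INTEGER(idx) + (size_t)cb * Vout;
    double* out = REAL(dx) + (size_t)cb * Vin;
    for (size_t q = 0; q < Vout; ++q) out[am[q]] += g[q];
  }
  return dx;
}
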