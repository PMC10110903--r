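#include <Rcpp.h>
using namespace Rcpp;

// 3D tensors are column-major R arrays with dim (nx, ny, nz, nc).
// Convolutions use kernel 3x3x3, zero padding 1, stride 1 ("same").
// Transposed convolutions use kernel 2x2x2, stride 2 (non-overlapping).
// All loops are single-threaded and deterministic.

static inline R_xlen_t id4(int x, int y, int z, int c,
                           int nx, int ny, int nz) {
  return (R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * (z + (R_xlen_t)nz * c));
}

// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector input, IntegerVector in_dim,
                         NumericVector w, NumericVector b) {
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2], ci = in_dim[3];
  const int co = b.size();
  NumericVector out((R_xlen_t)nx * ny * nz * co);
  const double *in = input.begin(), *W = w.begin();
  double *o = out.begin();
  for (int oc = 0; oc < co; ++oc) {
    const double bias = b[oc];
    for (R_xlen_t i = id4(0, 0, 0, oc, nx, ny, nz);
         i < id4(0, 0, 0, oc + 1, nx, ny, nz); ++i) o[i] = bias;
    for (int ic = 0; ic < ci; ++ic) {
      for (int kz = -1; kz <= 1; ++kz) {
        for (int ky = -1; ky <= 1; ++ky) {
          for (int kx = -1; kx <= 1; ++kx) {
            const double wv =
              W[(kx + 1) + 3 * ((ky + 1) + 3 * ((kz + 1) + 3 * (ic + (R_xlen_t)ci * oc)))];
            if (wv == 0.0) continue;
            const int z0 = std::max(0, -kz), z1 = nz - 1 - std::max(0, kz);
            const int y0 = std::max(0, -ky), y1 = ny - 1 - std::max(0, ky);
            const int x0 = std::max(0, -kx), x1 = nx - 1 - std::max(0, kx);
            for (int z = z0; z <= z1; ++z) {
              for (int y = y0; y <= y1; ++y) {
                const double *ip = in + id4(x0 + kx, y + ky, z + kz, ic, nx, ny, nz);
                double *op = o + id4(x0, y, z, oc, nx, ny, nz);
                for (int x = x0; x <= x1; ++x) *op++ += wv * *ip++;
              }
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, co);
  return out;
}

// [[Rcpp::export]]
List conv3d_bwd(NumericVector input, IntegerVector in_dim,
                NumericVector w, NumericVector gout) {
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2], ci = in_dim[3];
  const int co = (int)(w.size() / (27 * (R_xlen_t)ci));
  NumericVector gin((R_xlen_t)nx * ny * nz * ci);
  NumericVector gw(w.size());
  NumericVector gb(co);
  const double *in = input.begin(), *W = w.begin(), *go = gout.begin();
  double *gi = gin.begin(), *gW = gw.begin();
  for (int oc = 0; oc < co; ++oc) {
    double bsum = 0.0;
    const double *gop0 = go + id4(0, 0, 0, oc, nx, ny, nz);
    for (R_xlen_t i = 0; i < (R_xlen_t)nx * ny * nz; ++i) bsum += gop0[i];
    gb[oc] = bsum;
    for (int ic = 0; ic < ci; ++ic) {
      for (int kz = -1; kz <= 1; ++kz) {
        for (int ky = -1; ky <= 1; ++ky) {
          for (int kx = -1; kx <= 1; ++kx) {
            const R_xlen_t wi =
              (kx + 1) + 3 * ((ky + 1) + 3 * ((kz + 1) + 3 * (ic + (R_xlen_t)ci * oc)));
            const double wv = W[wi];
            double wg = 0.0;
            const int z0 = std::max(0, -kz), z1 = nz - 1 - std::max(0, kz);
            const int y0 = std::max(0, -ky), y1 = ny - 1 - std::max(0, ky);
            const int x0 = std::max(0, -kx), x1 = nx - 1 - std::max(0, kx);
            for (int z = z0; z <= z1; ++z) {
              for (int y = y0; y <= y1; ++y) {
                const double *ip = in + id4(x0 + kx, y + ky, z + kz, ic, nx, ny, nz);
                double *gp = gi + id4(x0 + kx, y + ky, z + kz, ic, nx, ny, nz);
                const double *op = go + id4(x0, y, z, oc, nx, ny, nz);
                for (int x = x0; x <= x1; ++x) {
                  wg += *ip++ * *op;
                  *gp++ += wv * *op++;
                }
              }
            }
            gW[wi] += wg;
          }
        }
      }
    }
  }
  gin.attr("dim") = IntegerVector::create(nx, ny, nz, ci);
  gw.attr("dim") = IntegerVector::create(3, 3, 3, ci, co);
  return List::create(_["gin"] = gin, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool3d_fwd(NumericVector input, IntegerVector in_dim) {
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2], nc = in_dim[3];
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  NumericVector out((R_xlen_t)ox * oy * oz * nc);
  IntegerVector arg(out.size());
  const double *in = input.begin();
  double *o = out.begin();
  int *a = arg.begin();
  R_xlen_t oi = 0;
  for (int c = 0; c < nc; ++c) {
    for (int z = 0; z < oz; ++z) {
      for (int y = 0; y < oy; ++y) {
        for (int x = 0; x < ox; ++x, ++oi) {
          double best = -HUGE_VAL;
          R_xlen_t besti = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const R_xlen_t ii =
                  id4(2 * x + dx, 2 * y + dy, 2 * z + dz, c, nx, ny, nz);
                if (in[ii] > best) { best = in[ii]; besti = ii; }
              }
          o[oi] = best;
          a[oi] = (int)besti;  // safe: tensors at both presets < 2^31 elements
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd(NumericVector gout, IntegerVector arg,
                            IntegerVector in_dim) {
  NumericVector gin((R_xlen_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3]);
  double *gi = gin.begin();
  const double *go = gout.begin();
  const int *a = arg.begin();
  for (R_xlen_t i = 0; i < gout.size(); ++i) gi[a[i]] += go[i];
  gin.attr("dim") = in_dim;
  return gin;
}

// [[Rcpp::export]]
NumericVector upconv3d_fwd(NumericVector input, IntegerVector in_dim,
                           NumericVector w, NumericVector b) {
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2], ci = in_dim[3];
  const int co = b.size();
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  NumericVector out((R_xlen_t)ox * oy * oz * co);
  const double *in = input.begin(), *W = w.begin();
  double *o = out.begin();
  for (int oc = 0; oc < co; ++oc) {
    const double bias = b[oc];
    double *oco = o + id4(0, 0, 0, oc, ox, oy, oz);
    for (R_xlen_t i = 0; i < (R_xlen_t)ox * oy * oz; ++i) oco[i] = bias;
    for (int ic = 0; ic < ci; ++ic) {
      const double *ico = in + id4(0, 0, 0, ic, nx, ny, nz);
      for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            const double wv =
              W[dx + 2 * (dy + 2 * (dz + 2 * (ic + (R_xlen_t)ci * oc)))];
            R_xlen_t ii = 0;
            for (int z = 0; z < nz; ++z)
              for (int y = 0; y < ny; ++y)
                for (int x = 0; x < nx; ++x, ++ii)
                  oco[id4(2 * x + dx, 2 * y + dy, 2 * z + dz, 0, ox, oy, oz)] +=
                    wv * ico[ii];
          }
    }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, co);
  return out;
}

// [[Rcpp::export]]
List upconv3d_bwd(NumericVector input, IntegerVector in_dim,
                  NumericVector w, NumericVector gout) {
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2], ci = in_dim[3];
  const int co = (int)(w.size() / (8 * (R_xlen_t)ci));
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  NumericVector gin((R_xlen_t)nx * ny * nz * ci);
  NumericVector gw(w.size());
  NumericVector gb(co);
  const double *in = input.begin(), *W = w.begin(), *go = gout.begin();
  double *gi = gin.begin(), *gW = gw.begin();
  for (int oc = 0; oc < co; ++oc) {
    const double *goc = go + id4(0, 0, 0, oc, ox, oy, oz);
    double bsum = 0.0;
    for (R_xlen_t i = 0; i < (R_xlen_t)ox * oy * oz; ++i) bsum += goc[i];
    gb[oc] = bsum;
    for (int ic = 0; ic < ci; ++ic) {
      const double *ico = in + id4(0, 0, 0, ic, nx, ny, nz);
      double *gic = gi + id4(0, 0, 0, ic, nx, ny, nz);
      for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            const R_xlen_t wi =
              dx + 2 * (dy + 2 * (dz + 2 * (ic + (R_xlen_t)ci * oc)));
            const double wv = W[wi];
            double wg = 0.0;
            R_xlen_t ii = 0;
            for (int z = 0; z < nz; ++z)
              for (int y = 0; y < ny; ++y)
                for (int x = 0; x < nx; ++x, ++ii) {
                  const double g =
                    goc[id4(2 * x + dx, 2 * y + dy, 2 * z + dz, 0, ox, oy, oz)];
                  wg += ico[ii] * g;
                  gic[ii] += wv * g;
                }
            gW[wi] += wg;
          }
    }
  }
  gin.attr("dim") = IntegerVector::create(nx, ny, nz, ci);
  gw.attr("dim") = IntegerVector::create(2, 2, 2, ci, co);
  return List::create(_["gin"] = gin, _["gw"] = gw, _["gb"] = gb);
}
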