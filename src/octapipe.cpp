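// Hot inner loops: speckle-frame rendering, complex-difference OCTA,
// log-structural conversion, and the minimum-cost surface path search.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Marsaglia polar pair from R's uniform stream: deterministic under
// set.seed and considerably faster than the inversion sampler for bulk
// draws (no trigonometry).
static inline void fast_norm_pair(double &z1, double &z2) {
  double u, v, s;
  do {
    u = 2.0 * unif_rand() - 1.0;
    v = 2.0 * unif_rand() - 1.0;
    s = u * u + v * v;
  } while (s >= 1.0 || s <= 0.0);
  const double f = std::sqrt(-2.0 * std::log(s) / s);
  z1 = u * f;
  z2 = v * f;
}

// Circular complex Gaussian speckle: variance refl per voxel (half per
// component), the many-scatterer limit of a random-phasor sum.
// [[Rcpp::export]]
ComplexVector cpp_draw_speckle(NumericVector refl) {
  const R_xlen_t n = refl.size();
  ComplexVector out(n);
  Rcomplex *po = COMPLEX(out);
  const double *pr = REAL(refl);
  double z1, z2;
  for (R_xlen_t i = 0; i < n; ++i) {
    fast_norm_pair(z1, z2);
    const double sd = std::sqrt(pr[i] / 2.0);
    po[i].r = sd * z1;
    po[i].i = sd * z2;
  }
  return out;
}

// Separable Gaussian blur; independent row (axial) and column (lateral)
// sigmas. Edges use truncated, renormalized kernels (normalized
// convolution): unbiased on locally flat signal and free of the ramp
// flattening that replication padding causes at the field edges.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix m, double sigma_row,
                                double sigma_col) {
  const int nr = m.nrow(), nc = m.ncol();
  auto make_kern = [](double sigma) {
    const int r = std::max(1, (int)std::ceil(3.0 * sigma));
    std::vector<double> kern(2 * r + 1);
    double ks = 0;
    for (int i = -r; i <= r; ++i) {
      kern[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
      ks += kern[i + r];
    }
    for (auto &v : kern) v /= ks;
    return kern;
  };
  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double *pm = REAL(m);
  double *pt = REAL(tmp);
  double *po = REAL(out);
  // rows pass (within columns, contiguous)
  if (sigma_row > 0) {
    const auto kern = make_kern(sigma_row);
    const int r = ((int)kern.size() - 1) / 2;
    for (int c = 0; c < nc; ++c) {
      const double *col = pm + (size_t)c * nr;
      double *tcol = pt + (size_t)c * nr;
      for (int i = 0; i < nr; ++i) {
        double acc = 0;
        if (i >= r && i + r < nr) {
          for (int t = -r; t <= r; ++t) acc += kern[t + r] * col[i + t];
        } else {
          double wsum = 0;
          for (int t = -r; t <= r; ++t) {
            const int s = i + t;
            if (s < 0 || s > nr - 1) continue;
            acc += kern[t + r] * col[s];
            wsum += kern[t + r];
          }
          acc /= wsum;
        }
        tcol[i] = acc;
      }
    }
  } else {
    std::copy(pm, pm + (size_t)nr * nc, pt);
  }
  // columns pass
  if (sigma_col > 0) {
    const auto kern = make_kern(sigma_col);
    const int r = ((int)kern.size() - 1) / 2;
    for (int c = 0; c < nc; ++c) {
      double *ocol = po + (size_t)c * nr;
      std::fill(ocol, ocol + nr, 0.0);
      double wsum = 0;
      for (int t = -r; t <= r; ++t) {
        const int s = c + t;
        if (s < 0 || s > nc - 1) continue;
        const double w = kern[t + r];
        wsum += w;
        const double *tcol = pt + (size_t)s * nr;
        for (int i = 0; i < nr; ++i) ocol[i] += w * tcol[i];
      }
      if (wsum < 1.0 - 1e-12) {
        for (int i = 0; i < nr; ++i) ocol[i] /= wsum;
      }
    }
  } else {
    std::copy(pt, pt + (size_t)nr * nc, po);
  }
  return out;
}

// Square median filter with replicated edges (odd k).
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix m, int k) {
  const int nr = m.nrow(), nc = m.ncol(), r = (k - 1) / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)k * k);
  for (int i = 0; i < nr; ++i) {
    for (int c = 0; c < nc; ++c) {
      buf.clear();
      for (int di = -r; di <= r; ++di) {
        for (int dc = -r; dc <= r; ++dc) {
          const int si = std::min(std::max(i + di, 0), nr - 1);
          const int sc = std::min(std::max(c + dc, 0), nc - 1);
          buf.push_back(m(si, sc));
        }
      }
      const size_t mid = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double hi = buf[mid];
      if (buf.size() % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + mid - 1, buf.begin() + mid);
        out(i, c) = 0.5 * (hi + buf[mid - 1]);
      } else {
        out(i, c) = hi;
      }
    }
  }
  return out;
}

// Minimum-cost depth path across A-lines (dynamic programming).
// evidence: [n_depth x n_alines], larger is better. Returns 1-based rows.
// [[Rcpp::export]]
IntegerVector cpp_dp_path(NumericMatrix evidence, double smoothness,
                          int max_jump) {
  const int nd = evidence.nrow(), nx = evidence.ncol();
  std::vector<double> acc(nd), best(nd);
  IntegerMatrix ptr(nd, nx);
  for (int d = 0; d < nd; ++d) acc[d] = -evidence(d, 0);
  const double big = 1e15;
  for (int x = 1; x < nx; ++x) {
    for (int d = 0; d < nd; ++d) {
      double b = big;
      int bj = 0;
      const int lo = std::max(0, d - max_jump);
      const int hi = std::min(nd - 1, d + max_jump);
      for (int s = lo; s <= hi; ++s) {
        const double c = acc[s] + smoothness * std::abs(d - s);
        if (c < b) { b = c; bj = d - s; }
      }
      ptr(d, x) = bj;
      best[d] = b - evidence(d, x);
    }
    acc = best;
  }
  int dmin = 0;
  for (int d = 1; d < nd; ++d) if (acc[d] < acc[dmin]) dmin = d;
  IntegerVector path(nx);
  path[nx - 1] = dmin + 1;
  for (int x = nx - 1; x >= 1; --x) {
    const int d = path[x] - 1;
    path[x - 1] = d - ptr(d, x) + 1;
  }
  return path;
}

// Assemble repeated frames from the static speckle field: per repeat, copy
// the static field, add complex Gaussian noise, and add the fresh
// (re-randomized) lumen component with per-voxel variance lumen_var.
// u0 layout [nd, nx, ny]; output [nd, nx, nrep, ny]. Uses R's RNG.
// [[Rcpp::export]]
ComplexVector cpp_render_frames(ComplexVector u0, IntegerVector dims,
                                int nrep, IntegerVector lumen_idx,
                                NumericVector lumen_var, double noise_floor) {
  const int nd = dims[0], nx = dims[1], ny = dims[2];
  const size_t block = (size_t)nd * nx;
  ComplexVector out((R_xlen_t)(block * nrep * ny));
  Rcomplex *po = COMPLEX(out);
  const Rcomplex *pu = COMPLEX(u0);
  const int *pl = INTEGER(lumen_idx);
  const double *pv = REAL(lumen_var);
  const R_xlen_t nl = lumen_idx.size();
  for (int j = 0; j < nrep; ++j) {
    for (int y = 0; y < ny; ++y) {
      const size_t off_in = block * (size_t)y;
      const size_t off_out = block * ((size_t)j + (size_t)nrep * y);
      if (noise_floor > 0) {
        double z1, z2;
        for (size_t i = 0; i < block; ++i) {
          Rcomplex c = pu[off_in + i];
          fast_norm_pair(z1, z2);
          c.r += noise_floor * z1;
          c.i += noise_floor * z2;
          po[off_out + i] = c;
        }
      } else {
        std::copy(pu + off_in, pu + off_in + block, po + off_out);
      }
    }
    for (R_xlen_t L = 0; L < nl; ++L) {
      if (pv[L] <= 0) continue;
      const size_t idx = (size_t)pl[L] - 1;
      const size_t yy = idx / block;
      const size_t w = idx % block;
      const size_t pos = w + block * ((size_t)j + (size_t)nrep * yy);
      const double sd = std::sqrt(pv[L] / 2.0);
      double z1, z2;
      fast_norm_pair(z1, z2);
      po[pos].r += sd * z1;
      po[pos].i += sd * z2;
    }
  }
  out.attr("dim") = IntegerVector::create(nd, nx, nrep, ny);
  return out;
}

// Complex-difference OCTA for a whole volume: per slow position, optional
// per-A-line bulk phase alignment to the first repeat, then the mean
// magnitude of sequential complex differences. frames [nd, nx, nrep, ny].
// [[Rcpp::export]]
NumericVector cpp_octa_volume(ComplexVector frames, IntegerVector dims,
                              bool phase_align) {
  const int nd = dims[0], nx = dims[1], nrep = dims[2], ny = dims[3];
  const size_t fsz = (size_t)nd * nx;
  NumericVector out((R_xlen_t)(fsz * ny));
  double *pout = REAL(out);
  const Rcomplex *pf = COMPLEX(frames);
  std::vector<double> re((size_t)fsz * nrep), im((size_t)fsz * nrep);
  for (int y = 0; y < ny; ++y) {
    const size_t base = fsz * (size_t)nrep * y;
    for (int j = 0; j < nrep; ++j) {
      for (size_t i = 0; i < fsz; ++i) {
        const Rcomplex c = pf[base + fsz * j + i];
        re[fsz * j + i] = c.r;
        im[fsz * j + i] = c.i;
      }
    }
    if (phase_align) {
      for (int j = 1; j < nrep; ++j) {
        for (int x = 0; x < nx; ++x) {
          double ipr = 0, ipi = 0;  // sum conj(f_j) * f_0 over depth
          for (int d = 0; d < nd; ++d) {
            const size_t i0 = (size_t)x * nd + d;
            const double ar = re[fsz * j + i0], ai = im[fsz * j + i0];
            const double br = re[i0], bi = im[i0];
            ipr += ar * br + ai * bi;   // Re(conj(a) * b)
            ipi += ar * bi - ai * br;   // Im(conj(a) * b)
          }
          const double m = std::sqrt(ipr * ipr + ipi * ipi);
          if (m < 1e-300) continue;
          const double pr = ipr / m, pi_ = ipi / m;
          for (int d = 0; d < nd; ++d) {
            const size_t i0 = (size_t)x * nd + d;
            const double ar = re[fsz * j + i0], ai = im[fsz * j + i0];
            re[fsz * j + i0] = ar * pr - ai * pi_;
            im[fsz * j + i0] = ar * pi_ + ai * pr;
          }
        }
      }
    }
    for (size_t i = 0; i < fsz; ++i) {
      double acc = 0;
      for (int j = 0; j + 1 < nrep; ++j) {
        const double dr = re[fsz * (j + 1) + i] - re[fsz * j + i];
        const double di = im[fsz * (j + 1) + i] - im[fsz * j + i];
        acc += std::sqrt(dr * dr + di * di);
      }
      pout[fsz * y + i] = acc / (nrep - 1);
    }
  }
  out.attr("dim") = IntegerVector::create(nd, nx, ny);
  return out;
}

// Log-scaled structural volume: mean over repeats of 20*log10(|c| + eps).
// [[Rcpp::export]]
NumericVector cpp_log_structural(ComplexVector frames, IntegerVector dims,
                                 double eps) {
  const int nd = dims[0], nx = dims[1], nrep = dims[2], ny = dims[3];
  const size_t fsz = (size_t)nd * nx;
  NumericVector out((R_xlen_t)(fsz * ny));
  double *pout = REAL(out);
  const Rcomplex *pf = COMPLEX(frames);
  const double k = 20.0 / std::log(10.0);
  for (int y = 0; y < ny; ++y) {
    const size_t base = fsz * (size_t)nrep * y;
    for (size_t i = 0; i < fsz; ++i) {
      double acc = 0;
      for (int j = 0; j < nrep; ++j) {
        const Rcomplex c = pf[base + fsz * j + i];
        acc += k * std::log(std::sqrt(c.r * c.r + c.i * c.i) + eps);
      }
      pout[fsz * y + i] = acc / nrep;
    }
  }
  out.attr("dim") = IntegerVector::create(nd, nx, ny);
  return out;
}


// Maximum intensity projection over depth: arr [nd, nx, ny] -> [ny, nx].
// [[Rcpp::export]]
NumericMatrix cpp_enface_mip(NumericVector arr, IntegerVector dims) {
  const int nd = dims[0], nx = dims[1], ny = dims[2];
  NumericMatrix out(ny, nx);
  const double *pa = REAL(arr);
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      const double *col = pa + (size_t)nd * (x + (size_t)nx * y);
      double m = col[0];
      for (int d = 1; d < nd; ++d) if (col[d] > m) m = col[d];
      out(y, x) = m;
    }
  }
  return out;
}
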