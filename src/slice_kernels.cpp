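// Hot kernels for the Fourier-slice projector and projection-matching
// angular refinement: trilinear sampling of central slices from an
// oversampled 3D transform, and exhaustive scoring of candidate Euler
// triples against a measured projection. The candidate scan evaluates
// millions of small 2D FFTs, so a self-contained complex FFT (iterative
// radix-2, Bluestein for non-power-of-two lengths) is included; it is
// validated against R's fft in the test suite.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cd;

static const double PI = 3.141592653589793238462643383279502884;

static bool is_pow2(int n) { return n > 0 && (n & (n - 1)) == 0; }

// explicit complex multiply: avoids libstdc++'s __muldc3 call in hot loops
static inline cd cmul(const cd& a, const cd& b) {
  return cd(a.real() * b.real() - a.imag() * b.imag(),
            a.real() * b.imag() + a.imag() * b.real());
}

static void fft_pow2(cd* a, int n, bool inverse) {
  // iterative Cooley-Tukey, bit-reversal permutation
  for (int i = 1, j = 0; i < n; ++i) {
    int bit = n >> 1;
    for (; j & bit; bit >>= 1) j ^= bit;
    j ^= bit;
    if (i < j) std::swap(a[i], a[j]);
  }
  for (int len = 2; len <= n; len <<= 1) {
    double ang = 2.0 * PI / len * (inverse ? 1.0 : -1.0);
    cd wlen(std::cos(ang), std::sin(ang));
    for (int i = 0; i < n; i += len) {
      cd w(1.0, 0.0);
      for (int k = 0; k < len / 2; ++k) {
        cd u = a[i + k];
        cd v = cmul(a[i + k + len / 2], w);
        a[i + k] = u + v;
        a[i + k + len / 2] = u - v;
        w = cmul(w, wlen);
      }
    }
  }
}

// Bluestein chirp-z: DFT of arbitrary length via a power-of-two convolution
static void fft_bluestein(cd* a, int n, bool inverse) {
  int L = 1;
  while (L < 2 * n - 1) L <<= 1;
  std::vector<cd> b(n), fa(L, cd(0, 0)), fb(L, cd(0, 0));
  double sgn = inverse ? 1.0 : -1.0;
  for (int k = 0; k < n; ++k) {
    // exp(sgn * i * pi * k^2 / n); reduce k^2 mod 2n to keep precision
    long long k2 = (long long)k * k % (2LL * n);
    double ang = sgn * PI * (double)k2 / n;
    b[k] = cd(std::cos(ang), std::sin(ang));
    fa[k] = cmul(a[k], b[k]);
  }
  for (int k = 0; k < n; ++k) {
    cd c = std::conj(b[k]);
    fb[k] = c;
    if (k > 0) fb[L - k] = c;
  }
  fft_pow2(fa.data(), L, false);
  fft_pow2(fb.data(), L, false);
  for (int k = 0; k < L; ++k) fa[k] = cmul(fa[k], fb[k]);
  fft_pow2(fa.data(), L, true);
  double inv_l = 1.0 / (double)L;
  for (int k = 0; k < n; ++k) a[k] = cmul(fa[k], b[k]) * inv_l;
}

static void fft_1d(cd* a, int n, bool inverse) {
  if (n == 1) return;
  if (is_pow2(n)) fft_pow2(a, n, inverse);
  else fft_bluestein(a, n, inverse);
}

// in-place 2D FFT on a column-major n x n buffer; unnormalized in both
// directions (callers account for 1/n^2 where needed)
static void fft_2d(cd* a, int n, bool inverse, cd* rowbuf) {
  for (int j = 0; j < n; ++j) fft_1d(a + (size_t)j * n, n, inverse);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) rowbuf[j] = a[(size_t)j * n + i];
    fft_1d(rowbuf, n, inverse);
    for (int j = 0; j < n; ++j) a[(size_t)j * n + i] = rowbuf[j];
  }
}

// [[Rcpp::export]]
ComplexVector cpp_fft2(ComplexVector x, int n, bool inverse) {
  // test/debug surface for the internal FFT (column-major n x n)
  std::vector<cd> a(n * (size_t)n);
  for (size_t i = 0; i < a.size(); ++i) a[i] = cd(x[i].r, x[i].i);
  std::vector<cd> rowbuf(n);
  fft_2d(a.data(), n, inverse, rowbuf.data());
  ComplexVector out(a.size());
  for (size_t i = 0; i < a.size(); ++i) { out[i].r = a[i].real(); out[i].i = a[i].imag(); }
  out.attr("dim") = IntegerVector::create(n, n);
  return out;
}

// ---- small in-place helpers for the reconstruction loop ----
// These mutate freshly allocated arrays owned by the solver loop; they are
// not exposed in the package API.

// [[Rcpp::export]]
void cpp_support_positivity(NumericVector rho, LogicalVector sup) {
  R_xlen_t n = rho.size();
  if (sup.size() != n) stop("shape mismatch");
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!sup[i] || rho[i] < 0) rho[i] = 0;
  }
}

// [[Rcpp::export]]
double cpp_mismatch_sum(ComplexVector F, IntegerVector idx, ComplexVector vals) {
  double s = 0;
  R_xlen_t n = idx.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    R_xlen_t k = idx[i] - 1;
    double dr = vals[i].r - F[k].r, di = vals[i].i - F[k].i;
    s += std::sqrt(dr * dr + di * di);
  }
  return s;
}

// [[Rcpp::export]]
void cpp_enforce(ComplexVector F, IntegerVector idx, ComplexVector vals,
                 Nullable<LogicalVector> sel = R_NilValue) {
  R_xlen_t n = idx.size();
  if (sel.isNotNull()) {
    LogicalVector s(sel);
    for (R_xlen_t i = 0; i < n; ++i) {
      if (s[i]) F[idx[i] - 1] = vals[i];
    }
  } else {
    for (R_xlen_t i = 0; i < n; ++i) F[idx[i] - 1] = vals[i];
  }
}

struct VolumeView {
  const Rcomplex* v;
  int m1, m2, m3;     // dims
  double c1, c2, c3;  // 0-based DC index (floor(m/2))
};

// trilinear interpolation at point p (voxel units relative to the DC voxel);
// samples outside the computed transform are zero
static inline cd sample_point(const VolumeView& vol, double px, double py, double pz) {
  double q1 = px + vol.c1, q2 = py + vol.c2, q3 = pz + vol.c3;
  if (q1 < 0 || q2 < 0 || q3 < 0 ||
      q1 > vol.m1 - 1 || q2 > vol.m2 - 1 || q3 > vol.m3 - 1) return cd(0, 0);
  int i1 = (int)std::floor(q1), i2 = (int)std::floor(q2), i3 = (int)std::floor(q3);
  if (i1 == vol.m1 - 1) --i1;
  if (i2 == vol.m2 - 1) --i2;
  if (i3 == vol.m3 - 1) --i3;
  double f1 = q1 - i1, f2 = q2 - i2, f3 = q3 - i3;
  double w000 = (1 - f1) * (1 - f2) * (1 - f3), w100 = f1 * (1 - f2) * (1 - f3);
  double w010 = (1 - f1) * f2 * (1 - f3),       w110 = f1 * f2 * (1 - f3);
  double w001 = (1 - f1) * (1 - f2) * f3,       w101 = f1 * (1 - f2) * f3;
  double w011 = (1 - f1) * f2 * f3,             w111 = f1 * f2 * f3;
  size_t s1 = 1, s2 = vol.m1, s3 = (size_t)vol.m1 * vol.m2;
  size_t base = (size_t)i3 * s3 + (size_t)i2 * s2 + (size_t)i1;
  const Rcomplex* v = vol.v;
  double re =
    w000 * v[base].r + w100 * v[base + s1].r +
    w010 * v[base + s2].r + w110 * v[base + s1 + s2].r +
    w001 * v[base + s3].r + w101 * v[base + s1 + s3].r +
    w011 * v[base + s2 + s3].r + w111 * v[base + s1 + s2 + s3].r;
  double im =
    w000 * v[base].i + w100 * v[base + s1].i +
    w010 * v[base + s2].i + w110 * v[base + s1 + s2].i +
    w001 * v[base + s3].i + w101 * v[base + s1 + s3].i +
    w011 * v[base + s2 + s3].i + w111 * v[base + s1 + s2 + s3].i;
  return cd(re, im);
}

// Z-Y-Z Euler rotation (degrees), columns = (u_axis, v_axis, normal);
// must match euler_to_matrix() on the R side
static void euler_rotation(double phi, double theta, double psi, double R[9]) {
  double p = phi * PI / 180.0, t = theta * PI / 180.0, s = psi * PI / 180.0;
  double cp = std::cos(p), sp = std::sin(p);
  double ct = std::cos(t), st = std::sin(t);
  double cs = std::cos(s), ss = std::sin(s);
  // Rz(phi) * Ry(theta) * Rz(psi), column-major
  R[0] = cp * ct * cs - sp * ss;  R[1] = sp * ct * cs + cp * ss;  R[2] = -st * cs;
  R[3] = -cp * ct * ss - sp * cs; R[4] = -sp * ct * ss + cp * cs; R[5] = st * ss;
  R[6] = cp * st;                 R[7] = sp * st;                 R[8] = ct;
}

static VolumeView make_view(const ComplexVector& fvol, const IntegerVector& fdim) {
  VolumeView vol;
  vol.v = fvol.begin();
  vol.m1 = fdim[0]; vol.m2 = fdim[1]; vol.m3 = fdim[2];
  vol.c1 = std::floor(vol.m1 / 2.0);
  vol.c2 = std::floor(vol.m2 / 2.0);
  vol.c3 = std::floor(vol.m3 / 2.0);
  return vol;
}

// mirror of a centered frequency index under the mod-n DFT pairing
// (the -n/2 edge frequency is its own mirror for even n)
static inline int freq_mirror(int a, int h) { return a == -h ? -h : -a; }

// fill an n x n centered-layout slice (element (i,j), 0-based, holds
// frequency a = i - n/2, b = j - n/2) sampled on the plane spanned by the
// first two columns of R, with sample spacing `spacing` grid voxels.
// The slice is the transform of a real projection, so it is filled exactly
// Hermitian under the mod-n DFT pairing: only canonical lattice points are
// interpolated, their mates are conjugate copies, and self-paired points
// (a, b in {0, -n/2}) are forced real. This both halves the interpolation
// work and guarantees that the inverse transform of the slice is real.
static void fill_slice(const VolumeView& vol, const double R[9], int n,
                       double spacing, cd* out) {
  int h = n / 2;
  for (int j = 0; j < n; ++j) {
    int b_i = j - h;
    int mb = freq_mirror(b_i, h);
    double b = b_i * spacing;
    double bx = b * R[3], by = b * R[4], bz = b * R[5];
    for (int i = 0; i < n; ++i) {
      int a_i = i - h;
      int ma = freq_mirror(a_i, h);
      bool self = (ma == a_i && mb == b_i);
      bool canonical = (mb > b_i) || (mb == b_i && ma >= a_i);
      if (!canonical) continue;
      double a = a_i * spacing;
      cd v = sample_point(vol,
        a * R[0] + bx, a * R[1] + by, a * R[2] + bz);
      if (self) v = cd(v.real(), 0.0);
      out[(size_t)j * n + i] = v;
      if (!self) out[(size_t)(mb + h) * n + (ma + h)] = std::conj(v);
    }
  }
}

// [[Rcpp::export]]
ComplexVector cpp_sample_slice(ComplexVector fvol, IntegerVector fdim,
                               NumericVector angles, int n, double spacing) {
  VolumeView vol = make_view(fvol, fdim);
  double R[9];
  euler_rotation(angles[0], angles[1], angles[2], R);
  std::vector<cd> buf((size_t)n * n);
  fill_slice(vol, R, n, spacing, buf.data());
  ComplexVector out((size_t)n * n);
  for (size_t i = 0; i < buf.size(); ++i) { out[i].r = buf[i].real(); out[i].i = buf[i].imag(); }
  out.attr("dim") = IntegerVector::create(n, n);
  return out;
}

// centered layout index -> standard DFT layout index (1D)
static inline int to_std(int i, int n) { return ((i - n / 2) % n + n) % n; }

// [[Rcpp::export]]
List cpp_refine_scan(ComplexVector fvol, IntegerVector fdim, double spacing,
                     NumericMatrix cand, NumericMatrix meas,
                     std::string metric, int trans_radius) {
  VolumeView vol = make_view(fvol, fdim);
  int n = meas.nrow();
  if (meas.ncol() != n) stop("measured image must be square");
  int C = cand.nrow();
  size_t nn = (size_t)n * n;

  // precompute measured-image quantities (standard DFT layout)
  std::vector<cd> measFT(nn);
  std::vector<double> meas_std(nn);
  double meas_mean = 0.0, meas_abs = 0.0;
  for (size_t i = 0; i < nn; ++i) meas_mean += meas[i];
  meas_mean /= (double)nn;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) {
      double v = meas[(size_t)j * n + i];
      meas_std[(size_t)to_std(j, n) * n + to_std(i, n)] = v;
      meas_abs += std::fabs(v);
    }
  bool xcorr = (metric == "xcorr");
  std::vector<cd> rowbuf(n), slice(nn), work(nn);
  double norm_meas = 0.0;
  if (xcorr) {
    for (size_t i = 0; i < nn; ++i) {
      double v0 = meas_std[i] - meas_mean;
      norm_meas += v0 * v0;
      measFT[i] = cd(v0, 0.0);
    }
    norm_meas = std::sqrt(norm_meas);
    if (norm_meas == 0.0) stop("zero-variance measured image with xcorr metric");
    fft_2d(measFT.data(), n, false, rowbuf.data());
    for (size_t i = 0; i < nn; ++i) measFT[i] = std::conj(measFT[i]);
  } else if (meas_abs == 0.0) {
    stop("all-zero measured image with rfactor metric");
  }

  NumericVector scores(C);
  IntegerMatrix shifts(C, 2);
  int h = n / 2;
  double R[9];

  for (int c = 0; c < C; ++c) {
    euler_rotation(cand(c, 0), cand(c, 1), cand(c, 2), R);
    fill_slice(vol, R, n, spacing, slice.data());
    if (xcorr) {
      // standard layout, zero-mean (drop DC), cross-correlate via FFT
      double norm2 = 0.0;
      for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i) {
          cd v = slice[(size_t)j * n + i];
          work[(size_t)to_std(j, n) * n + to_std(i, n)] = v;
        }
      work[0] = cd(0, 0);
      for (size_t i = 0; i < nn; ++i) norm2 += std::norm(work[i]);
      if (norm2 == 0.0) { scores[c] = R_NegInf; continue; }
      for (size_t i = 0; i < nn; ++i) work[i] = cmul(work[i], measFT[i]);
      fft_2d(work.data(), n, true, rowbuf.data());
      double best = R_NegInf; size_t bidx = 0;
      for (size_t i = 0; i < nn; ++i) {
        double v = work[i].real();
        if (v > best) { best = v; bidx = i; }
      }
      // work holds N^2 * r'(s); ||calc0|| = sqrt(norm2)/n (Parseval)
      scores[c] = (best / (double)nn) / ((std::sqrt(norm2) / n) * norm_meas);
      int sx = (int)(bidx % n), sy = (int)(bidx / n);
      shifts(c, 0) = sx <= n - 1 - h ? sx : sx - n;
      shifts(c, 1) = sy <= n - 1 - h ? sy : sy - n;
    } else {
      // real-space R-factor with translational search within trans_radius
      for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i)
          work[(size_t)to_std(j, n) * n + to_std(i, n)] = slice[(size_t)j * n + i];
      fft_2d(work.data(), n, true, rowbuf.data());
      double best = R_PosInf; int bdx = 0, bdy = 0;
      for (int dy = -trans_radius; dy <= trans_radius; ++dy) {
        for (int dx = -trans_radius; dx <= trans_radius; ++dx) {
          if (dx * dx + dy * dy > trans_radius * trans_radius) continue;
          double num = 0.0;
          for (int y = 0; y < n; ++y) {
            int ys = ((y - dy) % n + n) % n;
            const cd* crow = work.data() + (size_t)ys * n;
            const double* mrow = meas_std.data() + (size_t)y * n;
            for (int x = 0; x < n; ++x) {
              int xs = ((x - dx) % n + n) % n;
              num += std::fabs(crow[xs].real() / (double)nn - mrow[x]);
            }
          }
          double rf = num / meas_abs;
          if (rf < best) { best = rf; bdx = dx; bdy = dy; }
        }
      }
      scores[c] = best;
      shifts(c, 0) = bdx;
      shifts(c, 1) = bdy;
    }
  }
  return List::create(_["scores"] = scores, _["shifts"] = shifts);
}
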