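// Numerical kernels: FFTW-backed zero-phase filtering / analytic signals,
// 1/f noise synthesis, stochastic phase-oscillator integration, PLV cross
// products and bootstrap-t resampling. All Gaussian noise is drawn R-side
// (results are reproducible from R's RNG alone); only the bootstrap uses
// an internal integer RNG, seeded from R.

#include <RcppArmadillo.h>
#include <fftw3.h>
#include <cmath>
#include <map>
#include <vector>

using namespace Rcpp;

namespace {

const double TWO_PI = 6.283185307179586476925287;
const double PI_ = 3.141592653589793238462643;

// FFTW plans (and their aligned buffers) cached per transform length:
// plan creation costs far more than execution for our call pattern of
// thousands of same-length transforms.
struct PlanSet {
  int nfft = 0;
  double* rbuf = nullptr;
  fftw_complex* spec = nullptr;
  fftw_complex* abuf = nullptr;
  fftw_complex* zbuf = nullptr;
  fftw_plan fwd = nullptr;    // rbuf -> spec (r2c)
  fftw_plan inv_c = nullptr;  // abuf -> zbuf (c2c backward)
  fftw_plan inv_r = nullptr;  // spec -> rbuf (c2r)
};

PlanSet& get_plans(int nfft) {
  static std::map<int, PlanSet> cache;
  PlanSet& p = cache[nfft];
  if (p.nfft == 0) {
    const int nf = nfft / 2 + 1;
    p.nfft = nfft;
    p.rbuf = (double*) fftw_malloc(sizeof(double) * nfft);
    p.spec = (fftw_complex*) fftw_malloc(sizeof(fftw_complex) * nf);
    p.abuf = (fftw_complex*) fftw_malloc(sizeof(fftw_complex) * nfft);
    p.zbuf = (fftw_complex*) fftw_malloc(sizeof(fftw_complex) * nfft);
    p.fwd = fftw_plan_dft_r2c_1d(nfft, p.rbuf, p.spec, FFTW_ESTIMATE);
    p.inv_c = fftw_plan_dft_1d(nfft, p.abuf, p.zbuf, FFTW_BACKWARD, FFTW_ESTIMATE);
    p.inv_r = fftw_plan_dft_c2r_1d(nfft, p.spec, p.rbuf, FFTW_ESTIMATE);
  }
  return p;
}

// Reflect-pad column x (length T) into buf (length nfft, zero tail).
void reflect_pad(const double* x, int T, int pad, int nfft, double* buf) {
  std::fill(buf, buf + nfft, 0.0);
  for (int i = 0; i < pad; ++i) buf[i] = x[std::min(T - 1, pad - i)];
  std::copy(x, x + T, buf + pad);
  for (int j = 0; j < pad; ++j) buf[pad + T + j] = x[std::max(0, T - 2 - j)];
}

arma::cx_mat cx_view(const ComplexMatrix& M) {
  // Rcomplex and std::complex<double> share layout; no copy
  return arma::cx_mat(reinterpret_cast<arma::cx_double*>(
                        const_cast<Rcomplex*>(M.begin())),
                      M.nrow(), M.ncol(), false, true);
}

// xoshiro256++ with splitmix64 seeding: fast, bit-reproducible integers
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
};

}  // namespace

// Zero-phase FIR filtering of each column of X via squared-magnitude
// frequency response (equivalent to forward-backward application of the
// linear-phase FIR whose |B(f)|^2 is supplied in `gain`, length nfft/2+1).
// [[Rcpp::export]]
NumericMatrix cpp_fir_zerophase(const NumericMatrix& X, const NumericVector& gain,
                                int nfft, int pad) {
  const int T = X.nrow(), C = X.ncol(), nf = nfft / 2 + 1;
  if (gain.size() != nf) stop("gain length must be nfft/2 + 1");
  if (T + 2 * pad > nfft) stop("nfft too small for signal plus padding");
  NumericMatrix out(T, C);
  PlanSet& p = get_plans(nfft);
  for (int c = 0; c < C; ++c) {
    reflect_pad(&X(0, c), T, pad, nfft, p.rbuf);
    fftw_execute(p.fwd);
    for (int k = 0; k < nf; ++k) { p.spec[k][0] *= gain[k]; p.spec[k][1] *= gain[k]; }
    fftw_execute(p.inv_r);
    const double s = 1.0 / nfft;
    for (int t = 0; t < T; ++t) out(t, c) = p.rbuf[pad + t] * s;
  }
  return out;
}

// Band-limited analytic signal of each column of X for each band gain
// (columns of `gains`, each of length nfft/2+1, interpreted as zero-phase
// |B(f)|^2 responses). Returns a list of complex (T - 2*trim) x C
// matrices (`trim` edge samples dropped per side). If `unit` is true the
// phasors are normalised to unit modulus.
// [[Rcpp::export]]
List cpp_band_phasors(const NumericMatrix& X, const NumericMatrix& gains,
                      int nfft, int pad, int trim, bool unit) {
  const int T = X.nrow(), C = X.ncol(), nf = nfft / 2 + 1, B = gains.ncol();
  if (gains.nrow() != nf) stop("gain rows must be nfft/2 + 1");
  if (T + 2 * pad > nfft) stop("nfft too small for signal plus padding");
  if (2 * trim >= T) stop("2 * trim must be smaller than the signal length");
  const int Tout = T - 2 * trim;
  PlanSet& p = get_plans(nfft);
  std::vector<ComplexMatrix> mats;
  mats.reserve(B);
  for (int b = 0; b < B; ++b) mats.push_back(ComplexMatrix(Tout, C));
  std::vector<double> spec_re(nf), spec_im(nf);
  // support [k0, k1] of each band's gain (relative threshold 1e-12); the
  // analytic spectrum is written only there and re-zeroed after use
  std::vector<int> k0(B), k1(B);
  for (int b = 0; b < B; ++b) {
    double gmax = 0.0;
    for (int k = 0; k < nf; ++k) gmax = std::max(gmax, gains(k, b));
    const double thr = gmax * 1e-12;
    int lo = 0, hi = nf - 1;
    while (lo < nf - 1 && gains(lo, b) <= thr) ++lo;
    while (hi > 0 && gains(hi, b) <= thr) --hi;
    k0[b] = lo; k1[b] = hi;
  }
  for (int k = 0; k < nfft; ++k) { p.abuf[k][0] = 0.0; p.abuf[k][1] = 0.0; }
  for (int c = 0; c < C; ++c) {
    reflect_pad(&X(0, c), T, pad, nfft, p.rbuf);
    fftw_execute(p.fwd);
    for (int k = 0; k < nf; ++k) { spec_re[k] = p.spec[k][0]; spec_im[k] = p.spec[k][1]; }
    for (int b = 0; b < B; ++b) {
      // analytic spectrum: double positive frequencies, zero negative ones
      const double* g = &gains(0, b);
      for (int k = k0[b]; k <= k1[b]; ++k) {
        double w = (k == 0 || (nfft % 2 == 0 && k == nf - 1)) ? g[k] : 2.0 * g[k];
        p.abuf[k][0] = w * spec_re[k];
        p.abuf[k][1] = (k == 0 || (nfft % 2 == 0 && k == nf - 1)) ? 0.0 : w * spec_im[k];
      }
      fftw_execute(p.inv_c);
      for (int k = k0[b]; k <= k1[b]; ++k) { p.abuf[k][0] = 0.0; p.abuf[k][1] = 0.0; }
      const double s = 1.0 / nfft;
      const int off = pad + trim;
      Rcomplex* col = &mats[b](0, c);
      if (unit) {
        for (int t = 0; t < Tout; ++t) {
          double re = p.zbuf[off + t][0], im = p.zbuf[off + t][1];
          double m2 = re * re + im * im;
          if (m2 > 0) { double r = 1.0 / std::sqrt(m2); col[t].r = re * r; col[t].i = im * r; }
          else { col[t].r = 1.0; col[t].i = 0.0; }
        }
      } else {
        for (int t = 0; t < Tout; ++t) {
          col[t].r = p.zbuf[off + t][0] * s;
          col[t].i = p.zbuf[off + t][1] * s;
        }
      }
    }
  }
  List out(B);
  for (int b = 0; b < B; ++b) out[b] = mats[b];
  return out;
}

// 1/f background noise, one column per channel, unit empirical SD,
// synthesised in the frequency domain. `amp` holds the per-bin spectral
// amplitudes (length T/2+1, computed once R-side); `white` the N(0,1)
// coefficients: 2*(T/2+1) rows (re over im) x C.
// [[Rcpp::export]]
NumericMatrix cpp_pink_noise(int T, const NumericVector& amp, const NumericMatrix& white) {
  const int nf = T / 2 + 1, C = white.ncol();
  if (white.nrow() != 2 * nf) stop("white must have 2*(T/2+1) rows");
  if (amp.size() != nf) stop("amp must have T/2+1 entries");
  NumericMatrix out(T, C);
  PlanSet& p = get_plans(T);
  for (int c = 0; c < C; ++c) {
    p.spec[0][0] = 0.0; p.spec[0][1] = 0.0;
    for (int k = 1; k < nf; ++k) {
      p.spec[k][0] = amp[k] * white(k, c);
      p.spec[k][1] = amp[k] * white(nf + k, c);
    }
    if (T % 2 == 0) p.spec[nf - 1][1] = 0.0;
    fftw_execute(p.inv_r);
    double m = 0.0, s2 = 0.0;
    for (int t = 0; t < T; ++t) m += p.rbuf[t];
    m /= T;
    for (int t = 0; t < T; ++t) { double d = p.rbuf[t] - m; s2 += d * d; }
    double sd = std::sqrt(s2 / (T - 1));
    if (sd <= 0) sd = 1.0;
    for (int t = 0; t < T; ++t) out(t, c) = (p.rbuf[t] - m) / sd;
  }
  return out;
}

// Bank of stochastic phase oscillators. Oscillator i lives on channel
// ch[i] (1-based), advances by omega[i] per sample, is attracted with
// strength gain*kap1[i] (kap2[i]) toward the phase in column idx1[i]
// (idx2[i], 1-based) of drv1 (drv2), and receives sigma[i] *
// noise(t / substep, i) phase noise per sample (noise: standard normals
// drawn R-side, one innovation per `substep` samples, held constant
// within the block). Returns the band components amp[i]*cos(theta_i(t))
// summed into a T x nch signal matrix, plus (optionally) the phases.
// [[Rcpp::export]]
List cpp_osc_bank(int T, int nch, const IntegerVector& ch, const NumericVector& amp,
                  const NumericVector& omega, const NumericVector& sigma,
                  const NumericVector& theta0, const NumericVector& kap1,
                  const IntegerVector& idx1, const NumericMatrix& drv1,
                  const NumericVector& kap2, const IntegerVector& idx2,
                  const NumericMatrix& drv2, double gain,
                  const NumericMatrix& noise, int substep, bool keep_phases) {
  const int n = ch.size();
  if (substep < 1) stop("substep must be >= 1");
  if (noise.nrow() < (T + substep - 1) / substep) stop("noise has too few rows");
  if (noise.ncol() != n) stop("noise must have one column per oscillator");
  NumericMatrix sig(T, nch);
  NumericMatrix ph(keep_phases ? T : 1, keep_phases ? n : 1);
  for (int i = 0; i < n; ++i) {
    double th = theta0[i];
    const double om = omega[i], sg = sigma[i], a = amp[i];
    const bool c1 = kap1[i] > 0.0, c2 = kap2[i] > 0.0;
    const double g1 = gain * kap1[i], g2 = gain * kap2[i];
    const double* d1 = c1 ? &drv1(0, idx1[i] - 1) : nullptr;
    const double* d2 = c2 ? &drv2(0, idx2[i] - 1) : nullptr;
    const double* nz = &noise(0, i);
    double* out = &sig(0, ch[i] - 1);
    double* php = keep_phases ? &ph(0, i) : nullptr;
    for (int t = 0; t < T; ++t) {
      out[t] += a * std::cos(th);
      if (php) php[t] = th;
      double d = om + sg * nz[t / substep];
      if (c1) d += g1 * std::sin(d1[t] - th);
      if (c2) d += g2 * std::sin(d2[t] - th);
      th += d;
      if (th > PI_) th -= TWO_PI; else if (th < -PI_) th += TWO_PI;
    }
  }
  return List::create(Named("signal") = sig, Named("phases") = ph);
}

// Per-topic intra-brain mean PLV from a concatenated phasor matrix M
// (T x (n_topics*C + extra)): for each topic block of C columns, the
// mean over the C*(C-1)/2 distinct within-subject channel pairs of
// |sum_t conj(M_a) M_b| / T.
// [[Rcpp::export]]
NumericVector cpp_intra_topic(const ComplexMatrix& M, int C, int n_topics) {
  arma::cx_mat Mm = cx_view(M);
  const double T = static_cast<double>(Mm.n_rows);
  NumericVector out(n_topics);
  for (int k = 0; k < n_topics; ++k) {
    arma::mat G = arma::abs(Mm.cols(k * C, (k + 1) * C - 1).t() *
                            Mm.cols(k * C, (k + 1) * C - 1)) / T;
    double s = 0.0;
    for (int a = 0; a < C; ++a)
      for (int b = a + 1; b < C; ++b) s += G(a, b);
    out[k] = s / (C * (C - 1) / 2.0);
  }
  return out;
}

// All pairwise PLVs between columns of two unit-phasor matrices:
// out[l, s] = |sum_t conj(P[t, l]) Q[t, s]| / T  (BLAS zgemm, no copies).
// [[Rcpp::export]]
arma::mat cpp_plv_cross(const ComplexMatrix& P, const ComplexMatrix& Q) {
  if (P.nrow() != Q.nrow()) stop("phasor matrices must have equal length");
  arma::cx_mat Pm = cx_view(P), Qm = cx_view(Q);
  return arma::abs(Pm.t() * Qm) / static_cast<double>(Pm.n_rows);
}

// Centered-difference bootstrap t-test per column of d (cases x features).
// Returns a features x 2 matrix: observed t and two-sided p computed as
// (1 + #{|t*| >= |t_obs|}) / (n_boot + 1). Zero-variance columns get NA
// (handled by the R wrapper).
// [[Rcpp::export]]
NumericMatrix cpp_boot_t(const NumericMatrix& d, int n_boot,
                         const IntegerVector& seeds) {
  const int n = d.nrow(), F = d.ncol();
  if (seeds.size() != F) stop("one seed per feature required");
  NumericMatrix out(F, 2);
  std::vector<double> cen(n);
  const uint64_t un = static_cast<uint64_t>(n);
  for (int f = 0; f < F; ++f) {
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += d(i, f);
    m /= n;
    double s2 = 0.0;
    for (int i = 0; i < n; ++i) { double u = d(i, f) - m; s2 += u * u; }
    s2 /= (n - 1);
    if (s2 <= 0.0) { out(f, 0) = NA_REAL; out(f, 1) = NA_REAL; continue; }
    const double t_obs = std::fabs(m / std::sqrt(s2 / n));
    for (int i = 0; i < n; ++i) cen[i] = d(i, f) - m;
    Xoshiro eng(static_cast<uint64_t>(seeds[f]));
    int count = 0;
    for (int b = 0; b < n_boot; ++b) {
      double sum = 0.0, sum2 = 0.0;
      for (int i = 0; i < n; ++i) {
        // Lemire multiply-shift: unbiased enough for n << 2^64
        uint64_t r = eng.next();
        double v = cen[static_cast<int>((static_cast<__uint128_t>(r) * un) >> 64)];
        sum += v; sum2 += v * v;
      }
      double mb = sum / n;
      double vb = (sum2 - n * mb * mb) / (n - 1);
      double tb;
      if (vb <= 0.0) tb = (mb == 0.0) ? 0.0 : std::numeric_limits<double>::infinity();
      else tb = std::fabs(mb / std::sqrt(vb / n));
      if (tb >= t_obs) ++count;
    }
    out(f, 0) = m / std::sqrt(s2 / n);
    out(f, 1) = (1.0 + count) / (n_boot + 1.0);
  }
  return out;
}
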