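// Compute kernels for non-uniform Fourier transforms, Kaiser-Bessel gridding,
// the Pipe density-compensation convolution, the exact line-forward model used
// by the digital phantom, and quality-guided 2-D phase unwrapping.
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Kaiser-Bessel kernel value at offset u (grid units), total width W.
static inline double kb_val(double u, double halfw, double beta) {
  double r = u / halfw;
  double t = 1.0 - r * r;
  if (t < 0.0) return 0.0;
  return R::bessel_i(beta * std::sqrt(t), 0.0, 1.0);
}

// Linear-interpolation lookup table of the kernel (Bessel evaluations are
// the hot path otherwise); 4096 bins give ~1e-8 relative accuracy.
struct KBLut {
  std::vector<double> tab;
  double hw, inv_step;
  int n;
  KBLut(double W, double beta, int N = 4097) : tab(N), hw(W / 2.0), n(N) {
    for (int i = 0; i < N; ++i)
      tab[i] = kb_val(hw * i / (N - 1.0), hw, beta);
    inv_step = (N - 1.0) / hw;
  }
  inline double operator()(double u) const {
    double a = std::fabs(u);
    if (a >= hw) return 0.0;
    double x = a * inv_step;
    int i = (int)x;
    double f = x - i;
    return tab[i] * (1.0 - f) + tab[i + 1] * f;
  }
};

static inline int wrap_idx(int i, int G) {
  int m = i % G;
  return m < 0 ? m + G : m;
}

// Spread complex samples at continuous grid coordinates (gx, gy) onto a G x G
// grid with periodic wrap (standard for oversampled gridding).
// [[Rcpp::export(rng = false)]]
arma::cx_mat cpp_kb_spread(const arma::cx_vec& s, const arma::vec& gx,
                           const arma::vec& gy, const int G, const double W,
                           const double beta) {
  arma::cx_mat grid(G, G, arma::fill::zeros);
  const KBLut kb(W, beta);
  const double hw = W / 2.0;
  const arma::uword n = s.n_elem;
  for (arma::uword j = 0; j < n; ++j) {
    const int x0 = (int)std::ceil(gx[j] - hw), x1 = (int)std::floor(gx[j] + hw);
    const int y0 = (int)std::ceil(gy[j] - hw), y1 = (int)std::floor(gy[j] + hw);
    for (int ix = x0; ix <= x1; ++ix) {
      const double wx = kb(ix - gx[j]);
      if (wx == 0.0) continue;
      const int ixm = wrap_idx(ix, G);
      for (int iy = y0; iy <= y1; ++iy) {
        const double wy = kb(iy - gy[j]);
        if (wy == 0.0) continue;
        grid(ixm, wrap_idx(iy, G)) += s[j] * (wx * wy);
      }
    }
  }
  return grid;
}

// Interpolate a G x G grid at continuous coordinates (gx, gy).
// [[Rcpp::export(rng = false)]]
arma::cx_vec cpp_kb_interp(const arma::cx_mat& grid, const arma::vec& gx,
                           const arma::vec& gy, const double W,
                           const double beta) {
  const int G = grid.n_rows;
  const KBLut kb(W, beta);
  const double hw = W / 2.0;
  const arma::uword n = gx.n_elem;
  arma::cx_vec out(n, arma::fill::zeros);
  for (arma::uword j = 0; j < n; ++j) {
    const int x0 = (int)std::ceil(gx[j] - hw), x1 = (int)std::floor(gx[j] + hw);
    const int y0 = (int)std::ceil(gy[j] - hw), y1 = (int)std::floor(gy[j] + hw);
    std::complex<double> acc(0.0, 0.0);
    for (int ix = x0; ix <= x1; ++ix) {
      const double wx = kb(ix - gx[j]);
      if (wx == 0.0) continue;
      const int ixm = wrap_idx(ix, G);
      for (int iy = y0; iy <= y1; ++iy) {
        const double wy = kb(iy - gy[j]);
        if (wy == 0.0) continue;
        acc += grid(ixm, wrap_idx(iy, G)) * (wx * wy);
      }
    }
    out[j] = acc;
  }
  return out;
}

// One Pipe iteration helper: (w (*) kernel) evaluated back at the sample
// locations, via spread followed by interpolation on a shared grid.
// [[Rcpp::export(rng = false)]]
arma::vec cpp_kb_convolve_at(const arma::vec& w, const arma::vec& gx,
                             const arma::vec& gy, const int G, const double W,
                             const double beta) {
  arma::cx_vec ws(w.n_elem);
  for (arma::uword j = 0; j < w.n_elem; ++j) ws[j] = std::complex<double>(w[j], 0.0);
  arma::cx_mat grid = cpp_kb_spread(ws, gx, gy, G, W, beta);
  arma::cx_vec d = cpp_kb_interp(grid, gx, gy, W, beta);
  return arma::real(d);
}

// Direct (slow, exact) non-uniform DFT, forward: s_j = sum_p v_p
// exp(-2*pi*i*(kx_j x_p + ky_j y_p)). Coordinates in FOV units, k in
// cycles/FOV. Used as oracle and for small probe problems.
// [[Rcpp::export(rng = false)]]
arma::cx_vec cpp_nudft_forward(const arma::cx_vec& vals, const arma::vec& x,
                               const arma::vec& y, const arma::vec& kx,
                               const arma::vec& ky) {
  const arma::uword nj = kx.n_elem, np = x.n_elem;
  arma::cx_vec out(nj, arma::fill::zeros);
  const double twopi = 2.0 * M_PI;
  for (arma::uword j = 0; j < nj; ++j) {
    std::complex<double> acc(0.0, 0.0);
    for (arma::uword p = 0; p < np; ++p) {
      const double ph = -twopi * (kx[j] * x[p] + ky[j] * y[p]);
      acc += vals[p] * std::complex<double>(std::cos(ph), std::sin(ph));
    }
    out[j] = acc;
  }
  return out;
}

// Direct adjoint with optional per-pixel off-resonance demodulation:
// rho_p = sum_j s_j exp(-i*omega_p*t_j) exp(+2*pi*i*(kx_j x_p + ky_j y_p)).
// With omega = 0 this is the plain adjoint NUDFT; with omega supplied it is
// the exact conjugate-phase reconstruction (the oracle for the time-segmented
// approximation).
// [[Rcpp::export(rng = false)]]
arma::cx_vec cpp_nudft_adjoint(const arma::cx_vec& s, const arma::vec& kx,
                               const arma::vec& ky, const arma::vec& x,
                               const arma::vec& y, const arma::vec& omega,
                               const arma::vec& t) {
  const arma::uword nj = kx.n_elem, np = x.n_elem;
  arma::cx_vec out(np, arma::fill::zeros);
  const double twopi = 2.0 * M_PI;
  const bool use_om = omega.n_elem == np && t.n_elem == nj;
  for (arma::uword p = 0; p < np; ++p) {
    std::complex<double> acc(0.0, 0.0);
    for (arma::uword j = 0; j < nj; ++j) {
      double ph = twopi * (kx[j] * x[p] + ky[j] * y[p]);
      if (use_om) ph -= omega[p] * t[j];
      acc += s[j] * std::complex<double>(std::cos(ph), std::sin(ph));
    }
    out[p] = acc;
  }
  return out;
}

// Exact forward model for radial lines with per-pixel off-resonance.
// Each projection p samples k = (c0 + m*dc) * (ux_p, uy_p) + (sx_p, sy_p) at
// times t = t0 + m*dt, m = 0..nread-1. Because both the k-step and the time
// step are uniform, the per-pixel phase advance per sample is a constant
// complex multiplier, so each projection costs O(nread * npix) multiplies.
// Phase convention matches cpp_nudft_forward with an extra exp(+i*omega_p*t).
// [[Rcpp::export(rng = false)]]
arma::cx_mat cpp_line_forward(const arma::cx_vec& vals, const arma::vec& x,
                              const arma::vec& y, const arma::vec& omega,
                              const arma::vec& ux, const arma::vec& uy,
                              const arma::vec& sx, const arma::vec& sy,
                              const double c0, const double dc, const int nread,
                              const double t0, const double dt) {
  const arma::uword nproj = ux.n_elem;
  arma::cx_mat out(nread, nproj);
  const double twopi = 2.0 * M_PI;
  for (arma::uword p = 0; p < nproj; ++p) {
    arma::vec a = ux[p] * x + uy[p] * y;
    arma::vec ph0 = -twopi * (c0 * a + sx[p] * x + sy[p] * y) + omega * t0;
    arma::vec st = -twopi * dc * a + omega * dt;
    arma::cx_vec z = vals % arma::cx_vec(arma::cos(ph0), arma::sin(ph0));
    arma::cx_vec g(arma::cos(st), arma::sin(st));
    for (int m = 0; m < nread; ++m) {
      out(m, p) = arma::accu(z);
      z %= g;
    }
  }
  return out;
}

// Quality-guided 2-D phase unwrapping. Starts from the highest-quality masked
// pixel and grows the unwrapped region through a priority queue ordered by
// quality; each new pixel is unwrapped against its best already-unwrapped
// neighbour. Masked pixels unreachable from the seed keep their raw phase.
// [[Rcpp::export(rng = false)]]
arma::mat cpp_unwrap2d(const arma::mat& phase, const arma::mat& quality,
                       const arma::umat& mask) {
  const int nx = phase.n_rows, ny = phase.n_cols;
  arma::mat out = phase;
  arma::imat done(nx, ny, arma::fill::zeros);
  typedef std::pair<double, std::pair<int, int> > QI;
  std::priority_queue<QI> pq;

  int sx = -1, sy = -1;
  double best = -std::numeric_limits<double>::infinity();
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (mask(i, j) && quality(i, j) > best) { best = quality(i, j); sx = i; sy = j; }
  if (sx < 0) return out;

  const int dx[4] = { 1, -1, 0, 0 };
  const int dy[4] = { 0, 0, 1, -1 };
  done(sx, sy) = 1;
  for (int d = 0; d < 4; ++d) {
    int i = sx + dx[d], j = sy + dy[d];
    if (i >= 0 && i < nx && j >= 0 && j < ny && mask(i, j))
      pq.push(QI(quality(i, j), std::make_pair(i, j)));
  }
  const double twopi = 2.0 * M_PI;
  while (!pq.empty()) {
    const std::pair<int, int> ij = pq.top().second;
    pq.pop();
    const int i = ij.first, j = ij.second;
    if (done(i, j)) continue;
    // reference: best unwrapped neighbour
    double qref = -std::numeric_limits<double>::infinity(), ref = 0.0;
    bool has = false;
    for (int d = 0; d < 4; ++d) {
      int ii = i + dx[d], jj = j + dy[d];
      if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && done(ii, jj) &&
          quality(ii, jj) > qref) {
        qref = quality(ii, jj);
        ref = out(ii, jj);
        has = true;
      }
    }
    if (!has) continue;
    out(i, j) = phase(i, j) + twopi * std::round((ref - phase(i, j)) / twopi);
    done(i, j) = 1;
    for (int d = 0; d < 4; ++d) {
      int ii = i + dx[d], jj = j + dy[d];
      if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && mask(ii, jj) && !done(ii, jj))
        pq.push(QI(quality(ii, jj), std::make_pair(ii, jj)));
    }
  }
  return out;
}
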