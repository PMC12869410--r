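// Compiled kernels for the hot paths: the vector self-attention block
// (forward and reverse) and the analytic GMM Fourier projection with its
// parameter gradients. The R implementations of the same operations are
// kept as reference oracles; equivalence is asserted in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

static inline mat lin(const arma::mat& X, const arma::mat& W, const arma::vec& b) {
  mat Y = X * W;
  Y.each_row() += b.t();
  return Y;
}

// forward-pass intermediates kept on the C++ side between the forward and
// reverse calls (avoids copying ~100 MB per block through R)
struct AttnCache {
  mat X, h1, s, g1, A, gv, y;
};

// neighbour gather indices: row (b*P + i) has neighbours nbr0(i, j) + b*P
// flattened order: j fastest, then i, then b.

// [[Rcpp::export]]
List attn_fwd_cpp(const arma::mat& X,
                  const arma::mat& phiW, const arma::vec& phib,
                  const arma::mat& psiW, const arma::vec& psib,
                  const arma::mat& alphaW, const arma::vec& alphab,
                  const arma::mat& th1W, const arma::vec& th1b,
                  const arma::mat& th2W, const arma::vec& th2b,
                  const arma::mat& g1W, const arma::vec& g1b,
                  const arma::mat& g2W, const arma::vec& g2b,
                  const arma::mat& outW, const arma::vec& outb,
                  const arma::mat& rel, const arma::imat& nbr0, int B) {
  const uword P = nbr0.n_rows, k = nbr0.n_cols, C = X.n_cols;
  const uword BP = (uword)B * P, E = BP * k;
  mat q = lin(X, phiW, phib);
  mat kk = lin(X, psiW, psib);
  mat v = lin(X, alphaW, alphab);
  mat h1 = lin(rel, th1W, th1b);
  h1.transform([](double x) { return x > 0 ? x : 0.0; });
  mat dd = lin(h1, th2W, th2b);            // (P*k) x C
  // flattened edge index tables (j fastest, then i, then b)
  arma::uvec cix(E), njx(E), djx(E);
  {
    uword e = 0;
    for (uword b = 0; b < (uword)B; ++b)
      for (uword i = 0; i < P; ++i)
        for (uword j = 0; j < k; ++j, ++e) {
          cix[e] = b * P + i;
          njx[e] = b * P + (uword)nbr0(i, j);
          djx[e] = i * k + j;
        }
  }
  mat s(E, C), gv(E, C);
  for (uword c = 0; c < C; ++c) {
    const double* qc = q.colptr(c);
    const double* kc = kk.colptr(c);
    const double* vc = v.colptr(c);
    const double* dc = dd.colptr(c);
    double* sc_ = s.colptr(c);
    double* gc_ = gv.colptr(c);
    for (uword e = 0; e < E; ++e) {
      const double d = dc[djx[e]];
      sc_[e] = qc[cix[e]] - kc[njx[e]] + d;
      gc_[e] = vc[njx[e]] + d;
    }
  }
  mat g1 = lin(s, g1W, g1b);
  g1.transform([](double x) { return x > 0 ? x : 0.0; });
  mat sc = lin(g1, g2W, g2b);
  // channel-wise softmax over each neighbour group, in place -> A
  mat A(E, C);
  for (uword c = 0; c < C; ++c) {
    for (uword g = 0; g < BP; ++g) {
      const uword off = g * k;
      double mx = sc(off, c);
      for (uword j = 1; j < k; ++j) mx = std::max(mx, sc(off + j, c));
      double ssum = 0;
      for (uword j = 0; j < k; ++j) {
        double e = std::exp(sc(off + j, c) - mx);
        A(off + j, c) = e;
        ssum += e;
      }
      for (uword j = 0; j < k; ++j) A(off + j, c) /= ssum;
    }
  }
  mat y(BP, C, arma::fill::zeros);
  for (uword c = 0; c < C; ++c) {
    for (uword g = 0; g < BP; ++g) {
      const uword off = g * k;
      double acc = 0;
      for (uword j = 0; j < k; ++j) acc += A(off + j, c) * gv(off + j, c);
      y(g, c) = acc;
    }
  }
  mat out = X + lin(y, outW, outb);
  XPtr<AttnCache> cache(new AttnCache, true);
  cache->X = X;
  cache->h1 = std::move(h1);
  cache->s = std::move(s);
  cache->g1 = std::move(g1);
  cache->A = std::move(A);
  cache->gv = std::move(gv);
  cache->y = std::move(y);
  return List::create(_["out"] = out, _["cache"] = cache);
}

// [[Rcpp::export]]
List attn_bwd_cpp(SEXP cache_ptr,
                  const arma::mat& phiW, const arma::mat& psiW, const arma::mat& alphaW,
                  const arma::mat& th1W, const arma::mat& th2W,
                  const arma::mat& g1W, const arma::mat& g2W, const arma::mat& outW,
                  const arma::mat& rel, const arma::imat& nbr0, int B,
                  const arma::mat& dOut) {
  XPtr<AttnCache> cp(cache_ptr);
  const mat& X = cp->X;
  const mat& h1 = cp->h1;
  const mat& s = cp->s;
  const mat& g1 = cp->g1;
  const mat& A = cp->A;
  const mat& gv = cp->gv;
  const mat& y = cp->y;
  const uword P = nbr0.n_rows, k = nbr0.n_cols, C = X.n_cols;
  const uword BP = (uword)B * P, E = BP * k;
  // out linear
  mat doutW = y.t() * dOut;
  vec doutb = arma::sum(dOut, 0).t();
  mat dy = dOut * outW.t();
  // expand to edges: dA, dgv; softmax backward
  mat dsc(E, C), dgv(E, C);
  for (uword c = 0; c < C; ++c) {
    for (uword g = 0; g < BP; ++g) {
      const uword off = g * k;
      const double dyg = dy(g, c);
      double t = 0;
      for (uword j = 0; j < k; ++j) {
        const double dAj = dyg * gv(off + j, c);
        t += A(off + j, c) * dAj;
        dsc(off + j, c) = dAj;           // temp store dA
        dgv(off + j, c) = dyg * A(off + j, c);
      }
      for (uword j = 0; j < k; ++j) {
        dsc(off + j, c) = A(off + j, c) * (dsc(off + j, c) - t);
      }
    }
  }
  // gamma MLP backward
  mat dg2W = g1.t() * dsc;
  vec dg2b = arma::sum(dsc, 0).t();
  mat dg1 = dsc * g2W.t();
  dg1 %= arma::conv_to<mat>::from(g1 > 0);
  mat dg1W = s.t() * dg1;
  vec dg1b = arma::sum(dg1, 0).t();
  mat ds = dg1 * g1W.t();
  // distribute ds and dgv to q, kk, v, dd
  mat dq(BP, C, arma::fill::zeros), dkk(BP, C, arma::fill::zeros),
      dv(BP, C, arma::fill::zeros), ddd(P * k, C, arma::fill::zeros);
  arma::uvec cix(E), njx(E), djx(E);
  {
    uword e = 0;
    for (uword b = 0; b < (uword)B; ++b)
      for (uword i = 0; i < P; ++i)
        for (uword j = 0; j < k; ++j, ++e) {
          cix[e] = b * P + i;
          njx[e] = b * P + (uword)nbr0(i, j);
          djx[e] = i * k + j;
        }
  }
  for (uword c = 0; c < C; ++c) {
    const double* dse_c = ds.colptr(c);
    const double* dgv_c = dgv.colptr(c);
    double* dq_c = dq.colptr(c);
    double* dkk_c = dkk.colptr(c);
    double* dv_c = dv.colptr(c);
    double* ddd_c = ddd.colptr(c);
    for (uword e = 0; e < E; ++e) {
      const double dse = dse_c[e];
      dq_c[cix[e]] += dse;
      dkk_c[njx[e]] -= dse;
      dv_c[njx[e]] += dgv_c[e];
      ddd_c[djx[e]] += dse + dgv_c[e];
    }
  }
  // position-encoding MLP backward
  mat dth2W = h1.t() * ddd;
  vec dth2b = arma::sum(ddd, 0).t();
  mat dh1 = ddd * th2W.t();
  dh1 %= arma::conv_to<mat>::from(h1 > 0);
  mat dth1W = rel.t() * dh1;
  vec dth1b = arma::sum(dh1, 0).t();
  // input projections backward
  mat dphiW = X.t() * dq;
  vec dphib = arma::sum(dq, 0).t();
  mat dpsiW = X.t() * dkk;
  vec dpsib = arma::sum(dkk, 0).t();
  mat dalpW = X.t() * dv;
  vec dalpb = arma::sum(dv, 0).t();
  mat dX = dOut + dq * phiW.t() + dkk * psiW.t() + dv * alphaW.t();
  // every cache is consumed exactly once: release its memory now rather
  // than waiting for R garbage collection to find the external pointer
  cp->X.reset(); cp->h1.reset(); cp->s.reset(); cp->g1.reset();
  cp->A.reset(); cp->gv.reset(); cp->y.reset();
  return List::create(
      _["dX"] = dX,
      _["phi"] = List::create(_["W"] = dphiW, _["b"] = dphib),
      _["psi"] = List::create(_["W"] = dpsiW, _["b"] = dpsib),
      _["alpha"] = List::create(_["W"] = dalpW, _["b"] = dalpb),
      _["theta1"] = List::create(_["W"] = dth1W, _["b"] = dth1b),
      _["theta2"] = List::create(_["W"] = dth2W, _["b"] = dth2b),
      _["gamma1"] = List::create(_["W"] = dg1W, _["b"] = dg1b),
      _["gamma2"] = List::create(_["W"] = dg2W, _["b"] = dg2b),
      _["out"] = List::create(_["W"] = doutW, _["b"] = doutb));
}

// Analytic GMM projection over a masked frequency list.
// cxy: N x 2 rotated projected centres (box units, shift folded in by the
// caller); returns complex coefficients as re/im vectors.

// [[Rcpp::export]]
List proj_fwd_cpp(const arma::mat& cxy, const arma::vec& amps, const arma::vec& widths,
                  const arma::ivec& kx, const arma::ivec& ky, const arma::ivec& k2) {
  const uword Nf = kx.n_elem, N = amps.n_elem;
  vec Fre(Nf, arma::fill::zeros), Fim(Nf, arma::fill::zeros);
  const double twopi2 = 2.0 * M_PI * M_PI;
  const int kxmax = kx.max(), kymax = std::max(std::abs(ky.min()), ky.max());
  const int k2max = k2.max();
  std::vector<double> wxr(kxmax + 1), wxi(kxmax + 1),
      wyr(kymax + 1), wyi(kymax + 1), env(k2max + 1);
  for (uword i = 0; i < N; ++i) {
    const double s2 = widths(i) * widths(i);
    const double pref = amps(i) * 2.0 * M_PI * s2;
    const double ax = -2.0 * M_PI * cxy(i, 0), ay = -2.0 * M_PI * cxy(i, 1);
    const double cxr = std::cos(ax), cxi = std::sin(ax);
    const double cyr = std::cos(ay), cyi = std::sin(ay);
    wxr[0] = 1; wxi[0] = 0; wyr[0] = 1; wyi[0] = 0;
    for (int t = 1; t <= kxmax; ++t) {
      wxr[t] = wxr[t-1] * cxr - wxi[t-1] * cxi;
      wxi[t] = wxr[t-1] * cxi + wxi[t-1] * cxr;
    }
    for (int t = 1; t <= kymax; ++t) {
      wyr[t] = wyr[t-1] * cyr - wyi[t-1] * cyi;
      wyi[t] = wyr[t-1] * cyi + wyi[t-1] * cyr;
    }
    const double eb = std::exp(-twopi2 * s2);
    env[0] = pref;
    for (int t = 1; t <= k2max; ++t) env[t] = env[t-1] * eb;
    for (uword f = 0; f < Nf; ++f) {
      const int jx = kx(f), jy = ky(f);
      double pr = wxr[jx], pi_ = wxi[jx];
      double yr, yi;
      if (jy >= 0) { yr = wyr[jy]; yi = wyi[jy]; }
      else { yr = wyr[-jy]; yi = -wyi[-jy]; }
      const double rr = pr * yr - pi_ * yi;
      const double ri = pr * yi + pi_ * yr;
      const double e = env[k2(f)];
      Fre(f) += e * rr;
      Fim(f) += e * ri;
    }
  }
  return List::create(_["re"] = Fre, _["im"] = Fim);
}

// Gradient of a scalar loss w.r.t. centres (projected frame), amplitudes
// and widths, given gbar = dL/dRe(F) + i dL/dIm(F).

// [[Rcpp::export]]
List proj_grad_cpp(const arma::mat& cxy, const arma::vec& amps, const arma::vec& widths,
                   const arma::ivec& kx, const arma::ivec& ky, const arma::ivec& k2,
                   const arma::vec& gre, const arma::vec& gim) {
  const uword Nf = kx.n_elem, N = amps.n_elem;
  mat dcxy(N, 2, arma::fill::zeros);
  vec damp(N, arma::fill::zeros), dwid(N, arma::fill::zeros);
  const double twopi2 = 2.0 * M_PI * M_PI;
  const int kxmax = kx.max(), kymax = std::max(std::abs(ky.min()), ky.max());
  const int k2max = k2.max();
  std::vector<double> wxr(kxmax + 1), wxi(kxmax + 1),
      wyr(kymax + 1), wyi(kymax + 1), env(k2max + 1);
  for (uword i = 0; i < N; ++i) {
    const double s = widths(i);
    const double s2 = s * s;
    const double prefA = 2.0 * M_PI * s2;
    const double ax = -2.0 * M_PI * cxy(i, 0), ay = -2.0 * M_PI * cxy(i, 1);
    const double cxr = std::cos(ax), cxi = std::sin(ax);
    const double cyr = std::cos(ay), cyi = std::sin(ay);
    wxr[0] = 1; wxi[0] = 0; wyr[0] = 1; wyi[0] = 0;
    for (int t = 1; t <= kxmax; ++t) {
      wxr[t] = wxr[t-1] * cxr - wxi[t-1] * cxi;
      wxi[t] = wxr[t-1] * cxi + wxi[t-1] * cxr;
    }
    for (int t = 1; t <= kymax; ++t) {
      wyr[t] = wyr[t-1] * cyr - wyi[t-1] * cyi;
      wyi[t] = wyr[t-1] * cyi + wyi[t-1] * cyr;
    }
    const double eb = std::exp(-twopi2 * s2);
    env[0] = 1.0;
    for (int t = 1; t <= k2max; ++t) env[t] = env[t-1] * eb;
    double da = 0, dw = 0, dx = 0, dy = 0;
    for (uword f = 0; f < Nf; ++f) {
      const int jx = kx(f), jy = ky(f);
      double pr = wxr[jx], pi_ = wxi[jx];
      double yr, yi;
      if (jy >= 0) { yr = wyr[jy]; yi = wyi[jy]; }
      else { yr = wyr[-jy]; yi = -wyi[-jy]; }
      const double cph = pr * yr - pi_ * yi;    // cos(phase)
      const double sph = pr * yi + pi_ * yr;    // sin(phase)
      const double envf = env[k2(f)];
      const double Tre = amps(i) * prefA * envf * cph;
      const double Tim = amps(i) * prefA * envf * sph;
      const double ReM = gre(f) * Tre + gim(f) * Tim;
      const double ImM = gre(f) * Tim - gim(f) * Tre;
      da += prefA * envf * (gre(f) * cph + gim(f) * sph);
      dw += ReM * (2.0 / s - 2.0 * twopi2 * s * (double)k2(f));
      dx += ImM * (double)kx(f);
      dy += ImM * (double)ky(f);
    }
    damp(i) = da;
    dwid(i) = dw;
    dcxy(i, 0) = 2.0 * M_PI * dx;
    dcxy(i, 1) = 2.0 * M_PI * dy;
  }
  return List::create(_["dcxy"] = dcxy, _["damp"] = damp,
                      _["dwid"] = dwid);
}
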