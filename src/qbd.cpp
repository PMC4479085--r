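// Block-tridiagonal (quasi-birth-death) solvers for the truncated chemical
// master equation of the two-state positive-feedback expression network.
//
// States are (alpha, m, n): gene closed/open, mRNA count m < M, protein
// count n < N.  Protein birth/death couple adjacent "levels" n -> n +/- 1
// through *diagonal* blocks, so stationary vectors and first-passage times
// are obtained by dense block elimination with one b x b inversion per
// level (b = 2M).  Inverses needed again in the backward sweep are
// recomputed from checkpoints to bound memory at O(sqrt-free, ~2 x CKPT
// blocks) instead of O(N) blocks.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct NetPars {
  double kG, kG0, dG, kR, kR0, kP, dR, dP, K;
  int hillK;
};

NetPars as_pars(const Rcpp::NumericVector& p) {
  NetPars q;
  q.kG = p["kG"]; q.kG0 = p["kG0"]; q.dG = p["dG"];
  q.kR = p["kR"]; q.kR0 = p["kR0"]; q.kP = p["kP"];
  q.dR = p["dR"]; q.dP = p["dP"]; q.K = p["K"];
  q.hillK = static_cast<int>(p["hillK"]);
  return q;
}

double occ(double n, const NetPars& p) {
  if (n <= 0.0) return 0.0;
  if (p.hillK == 1) return n / (n + p.K);
  const double r = std::pow(n / p.K, p.hillK);
  return r / (r + 1.0);
}

// Within-level generator block A_n (column-source convention), b = 2M with
// index i = m + M * alpha.  The diagonal carries the total outflow of each
// state, including protein birth/death that leaves the level; transitions
// suppressed by the reflecting truncation (m = M-1 transcription,
// n = N-1 protein birth) are absent from the diagonal as well.
void level_block(mat& A, int n, int M, int N, const NetPars& p) {
  const int b = 2 * M;
  A.zeros(b, b);
  const double h = occ(static_cast<double>(n), p);
  const double act = p.kG * h + p.kG0;   // closed -> open
  const double txn = p.kR * h + p.kR0;   // transcription (open only)
  for (int alpha = 0; alpha <= 1; ++alpha) {
    for (int m = 0; m < M; ++m) {
      const int i = m + M * alpha;
      double out = 0.0;
      if (alpha == 1) {                       // gene inactivation
        A(m, i) += p.dG; out += p.dG;
        if (m < M - 1) { A(i + 1, i) += txn; out += txn; }
      } else {                                // gene activation
        A(m + M, i) += act; out += act;
      }
      if (m > 0) { const double r = p.dR * m; A(i - 1, i) += r; out += r; }
      if (n < N - 1) out += p.kP * m;         // protein birth (leaves level)
      out += p.dP * n;                        // protein death (leaves level)
      A(i, i) -= out;
    }
  }
}

// row-convention block W_n = A_n^T for first-passage systems
void level_block_t(mat& W, int n, int M, int N, const NetPars& p) {
  level_block(W, n, M, N, p);
  inplace_trans(W);
}

vec m_of_index(int M) {
  vec mv(2 * M);
  for (int a = 0; a <= 1; ++a)
    for (int m = 0; m < M; ++m) mv(m + M * a) = m;
  return mv;
}

} // namespace

// Stationary distribution of the truncated CME by censored-chain (stochastic
// complement) level elimination.  Returns P as a b x N matrix (column n =
// level n), already normalised, plus diagnostics.
// [[Rcpp::export(name = ".qbd_steady_cpp")]]
Rcpp::List qbd_steady_cpp(Rcpp::NumericVector pars, int M, int N,
                          int checkpoint = 64) {
  const NetPars p = as_pars(pars);
  const int b = 2 * M;
  const vec mv = m_of_index(M);
  const vec ukp = p.kP * mv;  // protein-birth rates within a level

  const int nck = (N - 1) / checkpoint + 1;
  std::vector<mat> ck(nck);   // Finv at levels 0, ckpt, 2*ckpt, ...

  // forward sweep: F_n = A_n + dP * n * rowscale(ukp) * Finv_{n-1}
  mat A(b, b), Finv(b, b), F(b, b);
  for (int n = 0; n < N - 1; ++n) {
    level_block(A, n, M, N, p);
    if (n == 0) F = A;
    else {
      F = Finv;
      F.each_col() %= ukp;           // row i scaled by kP * m(i)
      F *= p.dP * n;
      F += A;
    }
    Finv = inv(-F);
    if (n % checkpoint == 0) ck[n / checkpoint] = Finv;
    Rcpp::checkUserInterrupt();
  }

  // top level: null vector of censored generator F_{N-1}
  level_block(A, N - 1, M, N, p);
  if (N >= 2) {
    F = Finv;
    F.each_col() %= ukp;
    F *= p.dP * (N - 1);
    F += A;
  } else F = A;
  mat Fc = F;
  Fc.row(b - 1).ones();
  vec rhs(b, fill::zeros);
  rhs(b - 1) = 1.0;
  vec ptop = solve(Fc, rhs);
  ptop = clamp(ptop, 0.0, datum::inf);
  double s = accu(ptop);
  if (!(s > 0.0)) Rcpp::stop("degenerate top-level solve");
  ptop /= s;

  // backward sweep with per-level renormalisation; log weights track scale
  mat P(b, N, fill::zeros);
  vec logw(N, fill::zeros);
  P.col(N - 1) = ptop;
  vec pnext = ptop;
  for (int c = (N - 2) / checkpoint; c >= 0; --c) {
    const int lo = c * checkpoint;
    const int hi = std::min(lo + checkpoint - 1, N - 2);
    // recompute Finv_lo..hi from the checkpoint at lo
    std::vector<mat> seg(hi - lo + 1);
    seg[0] = ck[c];
    mat Acur(b, b);
    for (int n = lo + 1; n <= hi; ++n) {
      level_block(Acur, n, M, N, p);
      mat Fn = seg[n - lo - 1];
      Fn.each_col() %= ukp;
      Fn *= p.dP * n;
      Fn += Acur;
      seg[n - lo] = inv(-Fn);
    }
    for (int n = hi; n >= lo; --n) {
      vec pn = p.dP * (n + 1) * (seg[n - lo] * pnext);
      pn = clamp(pn, 0.0, datum::inf);
      const double sn = accu(pn);
      if (sn > 0.0 && std::isfinite(sn)) {
        logw(n) = logw(n + 1) + std::log(sn);
        pn /= sn;
      } else {
        logw(n) = -datum::inf;
        pn.zeros();
      }
      P.col(n) = pn;
      pnext = pn;
    }
    Rcpp::checkUserInterrupt();
  }

  // assemble: P(:, n) * exp(logw_n - logZ)
  const double wmax = logw.max();
  vec w = exp(logw - wmax);
  double Z = 0.0;
  for (int n = 0; n < N; ++n) Z += w(n);
  for (int n = 0; n < N; ++n) P.col(n) *= w(n) / Z;

  return Rcpp::List::create(
    Rcpp::Named("P") = P,
    Rcpp::Named("levelWeights") = w / Z);
}

// Mean first-passage times tau for the chain restricted to protein levels
// lo..hi (0-based), with every state outside that band absorbing.  Solves
// the row-convention linear system Q tau = -1 by block Thomas elimination.
// Returns tau as a b x (hi - lo + 1) matrix.
// [[Rcpp::export(name = ".qbd_mfpt_cpp")]]
Rcpp::List qbd_mfpt_cpp(Rcpp::NumericVector pars, int M, int N,
                        int lo, int hi, int checkpoint = 64) {
  const NetPars p = as_pars(pars);
  const int b = 2 * M;
  const int L = hi - lo + 1;
  if (lo < 0 || hi >= N || L < 1) Rcpp::stop("bad level range");
  const vec mv = m_of_index(M);
  const vec ukp = p.kP * mv;

  const int nck = (L - 1) / checkpoint + 1;
  std::vector<mat> ck(nck);
  mat Y(b, L);                 // forward-modified right-hand sides
  const vec ones_rhs(b, fill::value(-1.0));

  mat W(b, b), Ginv(b, b), G(b, b);
  vec y(b);
  for (int j = 0; j < L; ++j) {
    const int n = lo + j;
    level_block_t(W, n, M, N, p);
    if (j == 0) { G = W; y = ones_rhs; }
    else {
      // G_j = W - dP*n * Ginv_{j-1} colscaled by ukp ; y_j = -1 - dP*n*Ginv*y
      G = Ginv;
      G.each_row() %= ukp.t();
      G *= p.dP * n;
      G = W - G;
      y = ones_rhs - p.dP * n * (Ginv * y);
    }
    Ginv = inv(G);
    Y.col(j) = y;
    if (j % checkpoint == 0) ck[j / checkpoint] = Ginv;
    Rcpp::checkUserInterrupt();
  }

  mat Tau(b, L);
  vec tnext = Ginv * Y.col(L - 1);
  Tau.col(L - 1) = tnext;
  for (int c = (L - 2) / checkpoint; c >= 0; --c) {
    const int s = c * checkpoint;
    const int e = std::min(s + checkpoint - 1, L - 2);
    std::vector<mat> seg(e - s + 1);
    seg[0] = ck[c];
    mat Wc(b, b);
    for (int j = s + 1; j <= e; ++j) {
      const int n = lo + j;
      level_block_t(Wc, n, M, N, p);
      mat Gj = seg[j - s - 1];
      Gj.each_row() %= ukp.t();
      Gj *= p.dP * n;
      Gj = Wc - Gj;
      seg[j - s] = inv(Gj);
    }
    for (int j = e; j >= s; --j) {
      vec rhs_j = Y.col(j) - (ukp % tnext);   // R_j tau_{j+1}, R diagonal
      vec tj = seg[j - s] * rhs_j;
      Tau.col(j) = tj;
      tnext = tj;
    }
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(Rcpp::Named("tau") = Tau);
}
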