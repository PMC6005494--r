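// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
using namespace Rcpp;

// Batched inner-momentum solves along a discretised path: for each segment
// of the path (midpoint m, chord y) solve the convex program
//   maximise p.y  subject to  H(x, p) <= 0
// on the zero-Hamiltonian shell via a KKT Newton (mu * grad_p H = y, H = 0),
// warm-started from the previous sweep, with the quadratic-Hamiltonian
// closed form as the cold start. Supports the elementwise-log chart
// (z = log x, conjugate momentum q = p * x).

struct NetTables {
  arma::mat stoich;       // n x J
  arma::ivec kind;        // 1..5
  arma::ivec idx1, idx2;  // 0-based, -1 if unused
  arma::vec rate;         // k * modifier
};

static void propensities_intensive(const NetTables& nt, const arma::vec& x,
                                   arma::vec& a, arma::mat& da) {
  const int J = nt.rate.n_elem;
  const int n = x.n_elem;
  a.zeros(J);
  da.zeros(J, n);
  for (int j = 0; j < J; ++j) {
    const double k = nt.rate[j];
    const int i1 = nt.idx1[j], i2 = nt.idx2[j];
    switch (nt.kind[j]) {
    case 1: a[j] = k; break;
    case 2: a[j] = k * x[i1]; da(j, i1) = k; break;
    case 3: a[j] = k * x[i1] * x[i2];
      da(j, i1) += k * x[i2]; da(j, i2) += k * x[i1]; break;
    case 4: a[j] = k * x[i1] * x[i1]; da(j, i1) = 2.0 * k * x[i1]; break;
    default: a[j] = k * x[i1] * x[i1] * x[i1];
      da(j, i1) = 3.0 * k * x[i1] * x[i1]; break;
    }
  }
}

struct HamEval {
  double H;
  arma::vec gq;    // gradient wrt chart momentum
  arma::mat hqq;   // Hessian wrt chart momentum
};

// Evaluate chart Hamiltonian at chart point z, chart momentum q.
static HamEval ham_eval(const NetTables& nt, bool log_space, double floor_,
                        const arma::vec& z, const arma::vec& q) {
  arma::vec x; if (log_space) x = arma::exp(z); else x = arma::clamp(z, floor_, arma::datum::inf);
  arma::vec p = log_space ? q / x : q;
  arma::vec a;
  arma::mat da;
  propensities_intensive(nt, x, a, da);
  arma::vec pn = nt.stoich.t() * p;
  pn = arma::clamp(pn, -700.0, 700.0);
  arma::vec e = arma::exp(pn);
  arma::vec ae = a % e;
  HamEval ev;
  ev.H = arma::dot(a, e - 1.0);
  arma::vec gp = nt.stoich * ae;
  arma::mat hpp = nt.stoich * arma::diagmat(ae) * nt.stoich.t();
  if (log_space) {
    ev.gq = gp / x;
    ev.hqq = hpp % (arma::vec(1.0 / x) * arma::rowvec((1.0 / x).t()));
  } else {
    ev.gq = gp;
    ev.hqq = hpp;
  }
  return ev;
}

// Gradient of the chart Hamiltonian wrt the chart point.
static arma::vec ham_grad_z(const NetTables& nt, bool log_space, double floor_,
                            const arma::vec& z, const arma::vec& q) {
  arma::vec x; if (log_space) x = arma::exp(z); else x = arma::clamp(z, floor_, arma::datum::inf);
  arma::vec p = log_space ? q / x : q;
  arma::vec a;
  arma::mat da;
  propensities_intensive(nt, x, a, da);
  arma::vec pn = nt.stoich.t() * p;
  pn = arma::clamp(pn, -700.0, 700.0);
  arma::vec e = arma::exp(pn);
  arma::vec gx = da.t() * (e - 1.0);
  if (!log_space) return gx;
  arma::vec gp = nt.stoich * (a % e);
  return gx % x - gp % p;
}

struct InnerResult {
  arma::vec p;
  double ell;
  double mu;
  bool converged;
};

static InnerResult inner_solve(const NetTables& nt, bool log_space,
                               double floor_, const arma::vec& m,
                               const arma::vec& y, const arma::vec* warm) {
  const int n = y.n_elem;
  InnerResult res;
  res.p.zeros(n); res.ell = 0.0; res.mu = arma::datum::inf; res.converged = true;
  const double ny = arma::norm(y);
  if (ny <= 0) return res;
  arma::vec zero(n, arma::fill::zeros);
  HamEval ev0 = ham_eval(nt, log_space, floor_, m, zero);
  arma::vec b = ev0.gq;
  arma::mat Sig = ev0.hqq;
  double reg = 1e-12 * std::max(Sig.diag().max(), 1.0);
  Sig.diag() += reg;
  arma::vec qv, rv;
  bool ok1 = arma::solve(qv, Sig, y, arma::solve_opts::likely_sympd);
  bool ok2 = arma::solve(rv, Sig, b, arma::solve_opts::likely_sympd);
  if (!ok1 || !ok2) { res.converged = false; return res; }
  if (!qv.is_finite() || !rv.is_finite()) { res.converged = false; return res; }
  double qy = arma::dot(qv, y), rb = arma::dot(rv, b);
  if (!std::isfinite(qy) || !std::isfinite(rb)) { res.converged = false; return res; }
  if (qy <= 0) return res;
  if (rb < 1e-300) rb = 1e-300;
  double mu0 = std::sqrt(qy / rb);
  arma::vec p0 = qv / mu0 - rv;
  if (!std::isfinite(mu0) || !p0.is_finite()) { res.converged = false; return res; }
  // Degenerate segment (midpoint at/near a fixed point): the feasible set
  // shrinks to p = 0 and the per-length cost vanishes; the quadratic-form
  // value is exact to leading order there.
  if (arma::norm(b) < 1e-7 * std::sqrt(Sig.diag().max()) || mu0 > 1e8) {
    res.p = p0; res.mu = mu0; res.ell = std::max(arma::dot(p0, y), 0.0);
    return res;
  }
  // Deep-exponential regime: the shell lies where exp(p.nu) under/overflows
  // and Newton cannot make progress; keep the quadratic surrogate and let
  // the outer descent move the path out of this region.
  {
    arma::vec pn0 = log_space ? arma::vec(p0 / (arma::exp(m))) : p0;
    arma::vec proj = nt.stoich.t() * pn0;
    if (arma::abs(proj).max() > 200.0) {
      res.p = p0; res.mu = mu0; res.ell = std::max(arma::dot(p0, y), 0.0);
      res.converged = false;
      return res;
    }
  }

  auto newton = [&](arma::vec p, double mu) -> bool {
    for (int it = 0; it < 30; ++it) {
      HamEval ev = ham_eval(nt, log_space, floor_, m, p);
      arma::vec F1 = mu * ev.gq - y;
      double err = std::max(arma::abs(F1).max() / std::max(1.0, ny),
                            std::fabs(ev.H));
      if (err < 1e-10) {
        res.p = p; res.mu = mu; res.ell = std::max(arma::dot(p, y), 0.0);
        return true;
      }
      arma::mat K(n + 1, n + 1);
      K.submat(0, 0, n - 1, n - 1) = mu * ev.hqq;
      K.submat(0, n, n - 1, n) = ev.gq;
      K.submat(n, 0, n, n - 1) = ev.gq.t();
      K(n, n) = 0.0;
      arma::vec rhs(n + 1);
      rhs.subvec(0, n - 1) = -F1;
      rhs(n) = -ev.H;
      arma::vec step;
      if (!arma::solve(step, K, rhs)) return false;
      if (!step.is_finite()) return false;
      double lam = 1.0;
      bool moved = false;
      for (int ls = 0; ls < 15; ++ls) {
        arma::vec pn_ = p + lam * step.subvec(0, n - 1);
        double mun = mu + lam * step(n);
        if (mun > 0) {
          HamEval evn = ham_eval(nt, log_space, floor_, m, pn_);
          double errn = std::max(arma::abs(mun * evn.gq - y).max() /
                                 std::max(1.0, ny), std::fabs(evn.H));
          if (std::isfinite(errn) && (errn < err || lam < 1e-4)) {
            p = pn_; mu = mun; moved = true; break;
          }
        }
        lam *= 0.5;
      }
      if (!moved) return false;
    }
    return false;
  };

  if (warm != nullptr && arma::norm(*warm) > 0 && newton(*warm, mu0)) return res;
  if (newton(p0, mu0)) return res;
  // deterministic perturbed restarts
  for (int k = 1; k <= 2; ++k) {
    double f = 0.5 + 0.5 * k;
    if (newton(p0 * f, mu0 * f)) return res;
  }
  res.p = p0; res.mu = mu0; res.ell = std::max(arma::dot(p0, y), 0.0);
  if (!std::isfinite(res.ell)) { res.ell = 0.0; res.p.zeros(); }
  res.converged = false;
  return res;
}

// [[Rcpp::export]]
List segment_costs_cpp(NumericMatrix stoich_r, IntegerVector kind_r,
                       IntegerVector idx1_r, IntegerVector idx2_r,
                       NumericVector rate_r, NumericMatrix Z_r,
                       bool log_space, double floor_, NumericMatrix Pwarm_r,
                       bool with_grad) {
  NetTables nt;
  nt.stoich = arma::mat(stoich_r.begin(), stoich_r.nrow(), stoich_r.ncol());
  nt.kind = arma::conv_to<arma::ivec>::from(
    std::vector<int>(kind_r.begin(), kind_r.end()));
  nt.idx1 = arma::conv_to<arma::ivec>::from(
    std::vector<int>(idx1_r.begin(), idx1_r.end()));
  nt.idx2 = arma::conv_to<arma::ivec>::from(
    std::vector<int>(idx2_r.begin(), idx2_r.end()));
  nt.rate = arma::vec(rate_r.begin(), rate_r.size());
  arma::mat Z(Z_r.begin(), Z_r.nrow(), Z_r.ncol());
  arma::mat Pwarm(Pwarm_r.begin(), Pwarm_r.nrow(), Pwarm_r.ncol());
  const int N = Z.n_rows - 1;
  const int n = Z.n_cols;
  arma::vec ell(N, arma::fill::zeros);
  arma::mat P(N, n, arma::fill::zeros);    // mid-segment momenta (reporting)
  arma::mat GL(N, n, arma::fill::zeros);   // d ell_i / d left point
  arma::mat GR(N, n, arma::fill::zeros);   // d ell_i / d right point
  bool conv = true;
  const bool have_warm = (int)Pwarm.n_rows == N && (int)Pwarm.n_cols == n;

  // Simpson quadrature per segment (left, mid, right at the chord
  // direction): robust against cost "tunnelling" through expensive regions
  // that a midpoint-only rule invites.
  auto lx_of = [&](const arma::vec& at, const InnerResult& r) -> arma::vec {
    if (std::isfinite(r.mu) && arma::norm(r.p) > 0) {
      return -r.mu * ham_grad_z(nt, log_space, floor_, at, r.p);
    }
    return arma::vec(n, arma::fill::zeros);
  };

  for (int i = 0; i < N; ++i) {
    arma::vec xl = Z.row(i).t();
    arma::vec xr = Z.row(i + 1).t();
    arma::vec m = 0.5 * (xl + xr);
    arma::vec y = xr - xl;
    if (arma::norm(y) < 1e-14) continue;
    arma::vec w;
    const arma::vec* wp = nullptr;
    if (have_warm) { w = Pwarm.row(i).t(); wp = &w; }
    InnerResult rM = inner_solve(nt, log_space, floor_, m, y, wp);
    const arma::vec* wm = &rM.p;
    InnerResult rL = inner_solve(nt, log_space, floor_, xl, y, wm);
    InnerResult rR = inner_solve(nt, log_space, floor_, xr, y, wm);
    if (!rM.converged || !rL.converged || !rR.converged) conv = false;
    ell(i) = (rL.ell + 4.0 * rM.ell + rR.ell) / 6.0;
    P.row(i) = rM.p.t();
    if (with_grad) {
      arma::vec lxL = lx_of(xl, rL), lxM = lx_of(m, rM), lxR = lx_of(xr, rR);
      GL.row(i) = ((lxL - rL.p) + 4.0 * (0.5 * lxM - rM.p) + (-rR.p)).t() / 6.0;
      GR.row(i) = ((rL.p) + 4.0 * (0.5 * lxM + rM.p) + (lxR + rR.p)).t() / 6.0;
    }
  }
  return List::create(_["ell"] = ell, _["P"] = P,
                      _["GL"] = GL, _["GR"] = GR,
                      _["converged"] = conv);
}
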