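// Core discrete-time simulation and training loops for current-based LIF
// networks. Hot paths only: the conductance-based variant and all single-step
// operations live in R. Conventions (causal, synchronous update):
//   s^{t+1} = Theta(v^t - v_th)                       (deterministic limit)
//   shat^t  = (1 - dt/tau_s) shat^{t-1} + (dt/tau_s) s^t
//   v^t     = (1 - dt/tau_m) v^{t-1}
//             + (dt/tau_m) (J shat^{t-1} + I^t + v_rest) - J_res s^{t-1}
// Initial conditions: v^1 = v0, s^1 given (teacher first frame), shat^1 = s^1,
// eligibility trace p^1 = 0, readout filter shat_out^0 = 0.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Fused per-timestep Adam update on the rank-1 gradient g = err (x) p,
// with the recurrent matvec J * shat folded into the same pass over J.
static void adam_rank1_fused(double* __restrict__ J, double* __restrict__ M,
                             double* __restrict__ V,
                             const double* __restrict__ err,
                             const double* __restrict__ p,
                             const double* __restrict__ shat,
                             double* __restrict__ rec, int N,
                             double beta1, double beta2,
                             double c1,   // eta0 / bias-correction-1
                             double isb2, // 1 / sqrt(bias-correction-2)
                             double eps) {
  const double ib1 = 1.0 - beta1, ib2 = 1.0 - beta2;
  for (int i = 0; i < N; ++i) rec[i] = 0.0;
  for (int k = 0; k < N; ++k) {
    const double pk = p[k];
    const double sk = shat[k];
    double* Jc = J + (size_t)k * N;
    double* mc = M + (size_t)k * N;
    double* vc = V + (size_t)k * N;
    for (int i = 0; i < N; ++i) {
      const double g = err[i] * pk;
      double m = beta1 * mc[i] + ib1 * g;
      double w = beta2 * vc[i] + ib2 * g * g;
      // flush decaying moments well above the subnormal range: keeps the
      // streaming update free of microcode-assisted denormal arithmetic,
      // at a perturbation (< 1e-132 per step via the eps floor) far below
      // any meaningful weight scale
      if (std::abs(m) < 1e-280) m = 0.0;
      if (w < 1e-280) w = 0.0;
      mc[i] = m;
      vc[i] = w;
      const double Jn = Jc[i] + c1 * m / (std::sqrt(w) * isb2 + eps);
      Jc[i] = Jn;
      rec[i] += Jn * sk;
    }
  }
}

// Plain per-timestep update J += eta0 * err (x) p fused with the recurrent
// matvec; presynaptic columns with p = 0 only accumulate the matvec.
static void plain_rank1_fused(double* __restrict__ J,
                              const double* __restrict__ err,
                              const double* __restrict__ p,
                              const double* __restrict__ shat,
                              double* __restrict__ rec, int N,
                              double eta0) {
  for (int i = 0; i < N; ++i) rec[i] = 0.0;
  for (int k = 0; k < N; ++k) {
    const double cpk = eta0 * p[k];
    const double sk = shat[k];
    double* Jc = J + (size_t)k * N;
    if (cpk == 0.0) {
      if (sk != 0.0)
        for (int i = 0; i < N; ++i) rec[i] += Jc[i] * sk;
      continue;
    }
    for (int i = 0; i < N; ++i) {
      const double Jn = Jc[i] + cpk * err[i];
      Jc[i] = Jn;
      rec[i] += Jn * sk;
    }
  }
}

// log p(s|v) under the logistic spike model, numerically stable
static inline double log_spike_prob(double s, double x) {
  // x = (v - v_th)/dv ; log p = s*x - log(1 + e^x)
  double lse = (x > 0.0) ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
  return s * x - lse;
}

// [[Rcpp::export]]
List cpp_run_trial(const arma::mat& J, const arma::mat& I,
                   double v0, const arma::vec& s_init,
                   double dt, double tau_m, double tau_s,
                   double v_th, double v_rest, double J_res,
                   bool use_recurrence,
                   Nullable<NumericMatrix> clamp = R_NilValue) {
  const arma::uword N = I.n_rows, T = I.n_cols;
  const double a = dt / tau_m, b = dt / tau_s;
  arma::mat S(N, T, arma::fill::zeros), V(N, T, arma::fill::zeros);
  arma::vec v(N); v.fill(v0);
  arma::vec s = s_init, shat = s_init;
  const bool clamped = clamp.isNotNull();
  arma::mat C;
  if (clamped) C = as<arma::mat>(clamp);
  V.col(0) = v; S.col(0) = s;
  for (arma::uword t = 1; t < T; ++t) {
    arma::vec snext(N);
    if (clamped) {
      snext = C.col(t);
    } else {
      for (arma::uword i = 0; i < N; ++i) snext[i] = (v[i] > v_th) ? 1.0 : 0.0;
    }
    arma::vec vnew = (1.0 - a) * v + a * (I.col(t) + v_rest) - J_res * s;
    if (use_recurrence) vnew += a * (J * shat);
    v = vnew;
    s = snext;
    shat = (1.0 - b) * shat + b * s;
    V.col(t) = v;
    S.col(t) = s;
  }
  return List::create(_["raster"] = S, _["v"] = V);
}

// Exponential filtering of a raster with arbitrary time constant (used for
// the readout trace, shat_out^t = (1-dt/tau) shat_out^{t-1} + (dt/tau) s^t,
// with shat_out^0 = init).
// [[Rcpp::export]]
arma::mat cpp_filter_raster(const arma::mat& S, double tau, double dt,
                            double init = 0.0) {
  const arma::uword N = S.n_rows, T = S.n_cols;
  const double b = dt / tau;
  arma::mat F(N, T);
  arma::vec f(N); f.fill(init);
  for (arma::uword t = 0; t < T; ++t) {
    f = (1.0 - b) * f + b * S.col(t);
    F.col(t) = f;
  }
  return F;
}

// One presentation of target-clamped training. Membrane runs under the
// clamped target spikes (recurrent input from shat_targ), the per-neuron
// error (spike- or voltage-dependent) pairs with the presynaptic eligibility
// trace p (rank-1 gradient), applied per timestep (online) or accumulated
// (batch). Adam moments are carried across calls through mJ/vJ/tJ (and
// mO/vO/tO for the readout).
// [[Rcpp::export]]
List cpp_train_presentation(arma::mat J, arma::mat Jout,
                            const arma::mat& I, const arma::mat& S_targ,
                            const arma::mat& Y_targ,
                            double dt, double tau_m, double tau_s,
                            double tau_rout, double v_th, double v_rest,
                            double J_res, double v0,
                            int rule,        // 0 = spike, 1 = voltage
                            double dv,
                            int schedule,    // 0 = batch, 1 = online
                            int optimizer,   // 0 = plain, 1 = adam
                            double eta0,
                            arma::mat mJ, arma::mat vJ, double tJ,
                            double beta1, double beta2, double adam_eps,
                            bool train_readout,
                            int r_optimizer,  // 0 = plain, 1 = adam
                            double r_lr,
                            arma::mat mO, arma::mat vO, double tO,
                            bool update_J = true) {
  const arma::uword N = I.n_rows, T = I.n_cols;
  const double a = dt / tau_m, b = dt / tau_s, c = dt / tau_rout;
  arma::vec v(N); v.fill(v0);
  arma::vec p(N, arma::fill::zeros);
  arma::vec shat = S_targ.col(0);
  arma::vec shout = c * S_targ.col(0);  // shat_out^1 from shat_out^0 = 0
  arma::vec err(N);
  double loglik = 0.0;
  double mism = 0.0;
  arma::mat G;
  if (schedule == 0) G.zeros(N, N);

  for (arma::uword tau = 1; tau < T; ++tau) {
    // error signal at time tau: target s^{tau+1} vs prediction from v^tau
    const double* st1 = S_targ.colptr(tau);
    for (arma::uword i = 0; i < N; ++i) {
      const double x = v[i] - v_th;
      const double pred = (x > 0.0) ? 1.0 : 0.0;
      mism += std::abs(st1[i] - pred);
      double e = (rule == 1) ? st1[i] - sigm(x / dv) : st1[i] - pred;
      if (std::abs(e) < 1e-100) e = 0.0;  // sigmoid tail: no usable gradient
      err[i] = e;
      if (dv > 0.0) loglik += log_spike_prob(st1[i], x / dv);
    }

    // readout delta-rule step at time tau (target raster, frozen)
    if (train_readout) {
      arma::vec e = Y_targ.col(tau - 1) - Jout * shout;
      arma::mat gO = e * shout.t();
      if (r_optimizer == 1) {
        tO += 1.0;
        mO = beta1 * mO + (1.0 - beta1) * gO;
        vO = beta2 * vO + (1.0 - beta2) * (gO % gO);
        const double bc1 = 1.0 - std::pow(beta1, tO);
        const double bc2 = 1.0 - std::pow(beta2, tO);
        Jout += r_lr * (mO / bc1) / (arma::sqrt(vO / bc2) + adam_eps);
      } else {
        Jout += r_lr * gO;
      }
    }

    // recurrent update at time tau (gradient is rank-1: err x p), then
    // advance the clamped state to tau + 1 (online: the already-updated
    // weights enter the recurrent term)
    arma::vec rec(N);
    bool have_rec = false;
    if (schedule == 0) {
      G += err * p.t();  // accumulated even on measurement-only passes
    }
    if (update_J && schedule != 0) {
      if (optimizer == 0) {
        plain_rank1_fused(J.memptr(), err.memptr(), p.memptr(),
                          shat.memptr(), rec.memptr(), (int)N, eta0);
        have_rec = true;
      } else {
        tJ += 1.0;
        const double bc1 = 1.0 - std::pow(beta1, tJ);
        const double bc2 = 1.0 - std::pow(beta2, tJ);
        adam_rank1_fused(J.memptr(), mJ.memptr(), vJ.memptr(),
                         err.memptr(), p.memptr(), shat.memptr(),
                         rec.memptr(), (int)N, beta1, beta2,
                         eta0 / bc1, 1.0 / std::sqrt(bc2), adam_eps);
        have_rec = true;
      }
    }
    if (!have_rec) rec = J * shat;
    arma::vec vnew = (1.0 - a) * v + a * (rec + I.col(tau) + v_rest)
                     - J_res * S_targ.col(tau - 1);
    v = vnew;
    p = (1.0 - a) * p + a * shat;
    shat = (1.0 - b) * shat + b * S_targ.col(tau);
    shout = (1.0 - c) * shout + c * S_targ.col(tau);
  }

  // final readout step at tau = T (uses shat_out^T)
  if (train_readout) {
    arma::vec e = Y_targ.col(T - 1) - Jout * shout;
    arma::mat gO = e * shout.t();
    if (r_optimizer == 1) {
      tO += 1.0;
      mO = beta1 * mO + (1.0 - beta1) * gO;
      vO = beta2 * vO + (1.0 - beta2) * (gO % gO);
      const double bc1 = 1.0 - std::pow(beta1, tO);
      const double bc2 = 1.0 - std::pow(beta2, tO);
      Jout += r_lr * (mO / bc1) / (arma::sqrt(vO / bc2) + adam_eps);
    } else {
      Jout += r_lr * gO;
    }
  }

  // batch: apply the accumulated update once at trial end
  if (update_J && schedule == 0) {
    if (optimizer == 0) {
      J += eta0 * G;
    } else {
      tJ += 1.0;
      mJ = beta1 * mJ + (1.0 - beta1) * G;
      vJ = beta2 * vJ + (1.0 - beta2) * (G % G);
      const double bc1 = 1.0 - std::pow(beta1, tJ);
      const double bc2 = 1.0 - std::pow(beta2, tJ);
      J += eta0 * (mJ / bc1) / (arma::sqrt(vJ / bc2) + adam_eps);
    }
  }

  return List::create(
      _["J"] = J, _["Jout"] = Jout,
      _["mJ"] = mJ, _["vJ"] = vJ, _["tJ"] = tJ,
      _["mO"] = mO, _["vO"] = vO, _["tO"] = tO,
      _["loglik"] = (dv > 0.0) ? loglik : NA_REAL,
      _["delta_s"] = mism / double(N * (T - 1)),
      _["grad_sum"] = (schedule == 0) ? wrap(G) : R_NilValue);
}
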