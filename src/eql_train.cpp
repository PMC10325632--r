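// Compiled training core for the equation-learner network.
//
// Mirrors the R reference semantics exactly: safeguarded operators
// (eps_div = eps_log = 1e-3, exp capped at 20), unary units consuming one
// linear output, binary units consuming two consecutive outputs, squared
// error fit term, and the smoothed-L1/2 penalty over every weight and bias.
// Optimizer: Adam (beta1 = 0.9, beta2 = 0.999, eps = 1e-8) with an optional
// one-time learning-rate drop near the end of training.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double EPS_DIV = 1e-3;
static const double EPS_LOG = 1e-3;
static const double EXP_CAP = 20.0;

// unary codes: 0 id, 1 square, 2 exp, 3 sin, 4 cos, 5 relu, 6 logabs
static inline double un_f(int code, double x) {
  switch (code) {
    case 0: return x;
    case 1: return x * x;
    case 2: return std::exp(std::min(x, EXP_CAP));
    case 3: return std::sin(x);
    case 4: return std::cos(x);
    case 5: return x > 0.0 ? x : 0.0;
    default: return std::log(std::max(std::abs(x), EPS_LOG));
  }
}
static inline double un_d(int code, double x) {
  switch (code) {
    case 0: return 1.0;
    case 1: return 2.0 * x;
    case 2: return x <= EXP_CAP ? std::exp(x) : 0.0;
    case 3: return std::cos(x);
    case 4: return -std::sin(x);
    case 5: return x > 0.0 ? 1.0 : 0.0;
    default: return std::abs(x) > EPS_LOG ? 1.0 / x : 0.0;
  }
}

// binary codes: 0 sum, 1 diff, 2 prod, 3 quot
static inline double bi_f(int code, double u, double v) {
  switch (code) {
    case 0: return u + v;
    case 1: return u - v;
    case 2: return u * v;
    default: {
      double s = v < 0.0 ? -1.0 : 1.0;
      return u / (s * std::max(std::abs(v), EPS_DIV));
    }
  }
}
static inline void bi_d(int code, double u, double v, double &du, double &dv) {
  switch (code) {
    case 0: du = 1.0; dv = 1.0; break;
    case 1: du = 1.0; dv = -1.0; break;
    case 2: du = v; dv = u; break;
    default: {
      double s = v < 0.0 ? -1.0 : 1.0;
      du = 1.0 / (s * std::max(std::abs(v), EPS_DIV));
      dv = std::abs(v) > EPS_DIV ? -u / (v * v) : 0.0;
    }
  }
}

static inline double pen_val(double w, double a) {
  double aw = std::abs(w);
  if (aw >= a) return std::sqrt(aw);
  double inner = -std::pow(w, 4) / (8.0 * a * a * a) +
                 3.0 * w * w / (4.0 * a) + 3.0 * a / 8.0;
  return std::sqrt(std::abs(inner));
}
static inline double pen_grad(double w, double a) {
  double aw = std::abs(w);
  if (aw >= a) {
    double s = (w > 0.0) - (w < 0.0);
    return s / (2.0 * std::sqrt(aw));
  }
  double inner = -std::pow(w, 4) / (8.0 * a * a * a) +
                 3.0 * w * w / (4.0 * a) + 3.0 * a / 8.0;
  double dinner = -std::pow(w, 3) / (2.0 * a * a * a) + 3.0 * w / (2.0 * a);
  return dinner / (2.0 * std::sqrt(inner));
}

struct AdamState {
  mat mW, vW; vec mb, vb;
};

// [[Rcpp::export]]
Rcpp::List eql_train_cpp(const arma::mat &X, const arma::vec &y,
                         Rcpp::List layers_in, arma::rowvec W_out,
                         double b_out, int epochs, double lr, double lambda,
                         int warmup_epochs, double a, int batch_size,
                         int shuffle_seed, double final_lr_factor,
                         double final_lr_frac) {
  const int L = layers_in.size();
  const unsigned int N = X.n_rows;

  std::vector<mat> W(L);
  std::vector<vec> b(L);
  std::vector<ivec> un(L), bi(L);
  for (int l = 0; l < L; ++l) {
    Rcpp::List lay = layers_in[l];
    W[l] = Rcpp::as<mat>(lay["W"]);
    b[l] = Rcpp::as<vec>(lay["b"]);
    un[l] = Rcpp::as<ivec>(lay["unary_code"]);
    bi[l] = Rcpp::as<ivec>(lay["binary_code"]);
  }

  std::vector<AdamState> st(L);
  for (int l = 0; l < L; ++l) {
    st[l].mW = zeros<mat>(size(W[l])); st[l].vW = zeros<mat>(size(W[l]));
    st[l].mb = zeros<vec>(size(b[l])); st[l].vb = zeros<vec>(size(b[l]));
  }
  rowvec m_out = zeros<rowvec>(W_out.n_elem), v_out = zeros<rowvec>(W_out.n_elem);
  double m_bout = 0.0, v_bout = 0.0;

  const double beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8;
  long adam_t = 0;

  std::mt19937 rng(static_cast<unsigned int>(shuffle_seed));
  uvec order = regspace<uvec>(0, N - 1);
  if (batch_size <= 0 || batch_size > (int)N) batch_size = N;

  vec loss_hist(epochs, fill::zeros);
  int diverged_epoch = 0;

  std::vector<mat> G(L), H(L), dG(L);

  for (int ep = 0; ep < epochs; ++ep) {
    double lam = (ep < warmup_epochs) ? 0.0 : lambda;
    double lr_ep = (ep >= (int)(final_lr_frac * epochs)) ? lr * final_lr_factor : lr;

    if (batch_size < (int)N) {
      std::shuffle(order.begin(), order.end(), rng);
    }
    double fit_total = 0.0;

    for (unsigned int start = 0; start < N; start += batch_size) {
      unsigned int stop = std::min(N - 1, start + batch_size - 1);
      uvec idx = order.subvec(start, stop);
      mat Xb = (batch_size < (int)N) ? X.rows(idx) : X;
      vec yb = (batch_size < (int)N) ? y.elem(idx) : y;
      unsigned int nb = Xb.n_rows;

      // forward
      mat h = Xb;
      for (int l = 0; l < L; ++l) {
        G[l] = h * W[l].t();
        G[l].each_row() += b[l].t();
        int nu = un[l].n_elem, nbin = bi[l].n_elem;
        H[l].set_size(nb, nu + nbin);
        for (int k = 0; k < nu; ++k) {
          int code = un[l](k);
          for (unsigned int r = 0; r < nb; ++r) H[l](r, k) = un_f(code, G[l](r, k));
        }
        for (int m = 0; m < nbin; ++m) {
          int code = bi[l](m);
          int c1 = nu + 2 * m, c2 = nu + 2 * m + 1;
          for (unsigned int r = 0; r < nb; ++r)
            H[l](r, nu + m) = bi_f(code, G[l](r, c1), G[l](r, c2));
        }
        h = H[l];
      }
      vec yhat = h * W_out.t() + b_out;
      vec res = yhat - yb;
      fit_total += dot(res, res);

      // backward
      vec dyhat = 2.0 * res;
      rowvec gW_out = dyhat.t() * h;
      double gb_out = accu(dyhat);
      mat dH = dyhat * W_out;   // nb x n_h(last)

      for (int l = L - 1; l >= 0; --l) {
        int nu = un[l].n_elem, nbin = bi[l].n_elem;
        dG[l].set_size(nb, G[l].n_cols);
        for (int k = 0; k < nu; ++k) {
          int code = un[l](k);
          for (unsigned int r = 0; r < nb; ++r)
            dG[l](r, k) = dH(r, k) * un_d(code, G[l](r, k));
        }
        for (int m = 0; m < nbin; ++m) {
          int code = bi[l](m);
          int c1 = nu + 2 * m, c2 = nu + 2 * m + 1;
          double du, dv;
          for (unsigned int r = 0; r < nb; ++r) {
            bi_d(code, G[l](r, c1), G[l](r, c2), du, dv);
            dG[l](r, c1) = dH(r, nu + m) * du;
            dG[l](r, c2) = dH(r, nu + m) * dv;
          }
        }
        const mat &xin = (l == 0) ? Xb : H[l - 1];
        mat gW = dG[l].t() * xin;
        vec gb = sum(dG[l], 0).t();
        if (l > 0) dH = dG[l] * W[l];

        if (lam > 0.0) {
          for (uword i = 0; i < W[l].n_elem; ++i) gW(i) += lam * pen_grad(W[l](i), a);
          for (uword i = 0; i < b[l].n_elem; ++i) gb(i) += lam * pen_grad(b[l](i), a);
        }

        // Adam update (shared timestep, applied per layer below)
        st[l].mW = beta1 * st[l].mW + (1 - beta1) * gW;
        st[l].vW = beta2 * st[l].vW + (1 - beta2) * square(gW);
        st[l].mb = beta1 * st[l].mb + (1 - beta1) * gb;
        st[l].vb = beta2 * st[l].vb + (1 - beta2) * square(gb);
      }
      if (lam > 0.0) {
        for (uword i = 0; i < W_out.n_elem; ++i) gW_out(i) += lam * pen_grad(W_out(i), a);
        gb_out += lam * pen_grad(b_out, a);
      }
      m_out = beta1 * m_out + (1 - beta1) * gW_out;
      v_out = beta2 * v_out + (1 - beta2) * square(gW_out);
      m_bout = beta1 * m_bout + (1 - beta1) * gb_out;
      v_bout = beta2 * v_bout + (1 - beta2) * gb_out * gb_out;

      ++adam_t;
      double bc1 = 1.0 - std::pow(beta1, (double)adam_t);
      double bc2 = 1.0 - std::pow(beta2, (double)adam_t);
      for (int l = 0; l < L; ++l) {
        W[l] -= lr_ep * (st[l].mW / bc1) / (sqrt(st[l].vW / bc2) + adam_eps);
        b[l] -= lr_ep * (st[l].mb / bc1) / (sqrt(st[l].vb / bc2) + adam_eps);
      }
      W_out -= lr_ep * (m_out / bc1) / (sqrt(v_out / bc2) + adam_eps);
      b_out -= lr_ep * (m_bout / bc1) / (std::sqrt(v_bout / bc2) + adam_eps);
    }

    double pen = 0.0;
    if (lam > 0.0) {
      for (int l = 0; l < L; ++l) {
        for (uword i = 0; i < W[l].n_elem; ++i) pen += pen_val(W[l](i), a);
        for (uword i = 0; i < b[l].n_elem; ++i) pen += pen_val(b[l](i), a);
      }
      for (uword i = 0; i < W_out.n_elem; ++i) pen += pen_val(W_out(i), a);
      pen += pen_val(b_out, a);
    }
    double loss = fit_total + lam * pen;
    loss_hist(ep) = loss;
    if (!std::isfinite(loss)) { diverged_epoch = ep + 1; loss_hist.resize(ep + 1); break; }
  }

  Rcpp::List layers_out(L);
  for (int l = 0; l < L; ++l) {
    layers_out[l] = Rcpp::List::create(Rcpp::Named("W") = W[l],
                                       Rcpp::Named("b") = b[l]);
  }
  return Rcpp::List::create(
    Rcpp::Named("layers") = layers_out,
    Rcpp::Named("W_out") = W_out,
    Rcpp::Named("b_out") = b_out,
    Rcpp::Named("loss_history") = loss_hist,
    Rcpp::Named("diverged_epoch") = diverged_epoch);
}
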