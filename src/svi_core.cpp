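// Training core: self-attention forward pass, Monte-Carlo ELBO loss and
// mini-batch gradient descent. Gradients are pathwise: the reparameterization
// noise (Gaussian eps, inverse-CDF uniforms) is drawn once per step and held
// fixed while each unconstrained parameter is perturbed (forward finite
// differences under common random numbers).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);

// ---------------------------------------------------------------- attention

static vec attention_one(const mat& f, const mat& G, const vec& b,
                         const mat& P) {
  const int T = f.n_rows;
  vec pooled(4, fill::zeros);
  for (int t = 0; t < T; ++t) {
    vec ft = f.row(t).t();
    vec g = G * ft + b;
    g -= g.max();
    vec e = exp(g);
    vec c = 4.0 * e / accu(e);
    pooled += c % ft + ft;
  }
  pooled /= T;
  return P.t() * pooled;
}

// [[Rcpp::export]]
arma::mat cpp_attention_forward(Rcpp::List windows, const arma::mat& G,
                                const arma::vec& b, const arma::mat& P) {
  const int n = windows.size();
  mat out(n, 2);
  for (int i = 0; i < n; ++i) {
    mat f = Rcpp::as<mat>(windows[i]);
    out.row(i) = attention_one(f, G, b, P).t();
  }
  return out;
}

// ------------------------------------------------------------ model structs

struct Params {
  int K, dim;
  bool full_cov, has_attention;
  mat N1, N2;    // K x dim
  vec nu;        // K, Wishart degrees of freedom
  cube W2chol;   // dim x dim x K, lower Cholesky of W2 (full mode)
  mat w2diag;    // K x dim, diagonal of W2 (diagonal mode)
  vec D;         // K, Dirichlet concentrations
  mat G, P;      // attention
  vec b;
};

struct Layout {
  int K, dim;
  bool full_cov, has_attention;
  int off_att, off_N1, off_N2, off_W1, off_W2, off_D, total;
};

static Layout make_layout(int K, int dim, bool full_cov, bool has_attention) {
  Layout L;
  L.K = K; L.dim = dim; L.full_cov = full_cov; L.has_attention = has_attention;
  L.off_att = 0;
  L.off_N1 = has_attention ? 28 : 0;
  L.off_N2 = L.off_N1 + K * dim;
  L.off_W1 = L.off_N2 + K * dim;
  L.off_W2 = L.off_W1 + K;
  L.off_D = L.off_W2 + (full_cov ? 3 * K : 2 * K);
  L.total = L.off_D + K;
  return L;
}

static Params unpack(const vec& theta, const Layout& lay) {
  Params p;
  p.K = lay.K; p.dim = lay.dim;
  p.full_cov = lay.full_cov; p.has_attention = lay.has_attention;
  const int K = lay.K, dim = lay.dim;
  if (lay.has_attention) {
    p.G = reshape(theta.subvec(0, 15), 4, 4);
    p.b = theta.subvec(16, 19);
    p.P = reshape(theta.subvec(20, 27), 4, 2);
  }
  p.N1 = reshape(theta.subvec(lay.off_N1, lay.off_N1 + K * dim - 1), K, dim);
  p.N2 = exp(reshape(theta.subvec(lay.off_N2, lay.off_N2 + K * dim - 1), K, dim));
  p.nu = (dim - 1) + exp(theta.subvec(lay.off_W1, lay.off_W1 + K - 1));
  if (lay.full_cov) {
    p.W2chol.set_size(dim, dim, K);
    for (int k = 0; k < K; ++k) {
      mat Lw(dim, dim, fill::zeros);
      Lw(0, 0) = std::exp(theta(lay.off_W2 + 3 * k));
      Lw(1, 0) = theta(lay.off_W2 + 3 * k + 1);
      Lw(1, 1) = std::exp(theta(lay.off_W2 + 3 * k + 2));
      p.W2chol.slice(k) = Lw;
    }
  } else {
    p.w2diag.set_size(K, dim);
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < dim; ++i)
        p.w2diag(k, i) = std::exp(theta(lay.off_W2 + 2 * k + i));
  }
  vec draw = theta.subvec(lay.off_D, lay.off_D + K - 1);
  p.D.set_size(K);
  for (int k = 0; k < K; ++k)
    p.D(k) = draw(k) > 30 ? draw(k) : std::log1p(std::exp(draw(k)));
  return p;
}

struct Noise {
  cube eps;   // L x K x dim
  cube uchi;  // L x K x dim
  mat zoff;   // L x K
  mat ugam;   // L x K
};

static Noise draw_noise(int L, int K, int dim) {
  Noise n;
  n.eps.set_size(L, K, dim);
  n.uchi.set_size(L, K, dim);
  n.zoff.set_size(L, K);
  n.ugam.set_size(L, K);
  for (int l = 0; l < L; ++l)
    for (int k = 0; k < K; ++k) {
      for (int i = 0; i < dim; ++i) {
        n.eps(l, k, i) = R::norm_rand();
        n.uchi(l, k, i) = R::unif_rand();
      }
      n.zoff(l, k) = R::norm_rand();
      n.ugam(l, k) = R::unif_rand();
    }
  return n;
}

// inverse-CDF caches: smooth in (nu, D) with the uniforms held fixed
static void fill_chi_col(cube& chi, const Noise& no, const Params& p, int k) {
  const int L = chi.n_rows, dim = chi.n_slices;
  for (int l = 0; l < L; ++l)
    for (int i = 0; i < dim; ++i) {
      if (p.full_cov)
        chi(l, k, i) = R::qchisq(no.uchi(l, k, i), p.nu(k) - i, 1, 0);
      else
        chi(l, k, i) = R::qgamma(no.uchi(l, k, i), p.nu(k) / 2.0, 2.0, 1, 0);
    }
}

static void fill_gam_col(mat& gam, const Noise& no, const Params& p, int k) {
  const int L = gam.n_rows;
  for (int l = 0; l < L; ++l) {
    double g = R::qgamma(no.ugam(l, k), p.D(k), 1.0, 1, 0);
    gam(l, k) = std::max(g, 1e-12);
  }
}

// ---------------------------------------------------------------------- KLD

static double lmvgamma(double a, int d) {
  double s = d * (d - 1) / 4.0 * std::log(M_PI);
  for (int j = 1; j <= d; ++j) s += R::lgammafn(a + (1.0 - j) / 2.0);
  return s;
}
static double mvdigamma(double a, int d) {
  double s = 0.0;
  for (int j = 1; j <= d; ++j) s += R::digamma(a + (1.0 - j) / 2.0);
  return s;
}

struct Prior {
  mat mean;      // K x dim
  double mean_var;
  vec wdf;       // K
  cube wscale;   // dim x dim x K
  vec dir;       // K
};

static double kld_state_prior(const Params& p, const Prior& pr) {
  const int K = p.K, d = p.dim;
  double total = 0.0;
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < d; ++i) {
      double v1 = p.N2(k, i), dm = p.N1(k, i) - pr.mean(k, i);
      total += 0.5 * (v1 / pr.mean_var + dm * dm / pr.mean_var - 1.0 -
                      std::log(v1 / pr.mean_var));
    }
    if (p.full_cov) {
      mat V1 = p.W2chol.slice(k) * p.W2chol.slice(k).t();
      const mat& V2 = pr.wscale.slice(k);
      double nu1 = p.nu(k), nu2 = pr.wdf(k);
      mat V2inv_V1 = solve(V2, V1);
      double ld1, ld2, sgn;
      log_det(ld1, sgn, V1);
      log_det(ld2, sgn, V2);
      total += (nu1 - nu2) / 2.0 * mvdigamma(nu1 / 2.0, d) -
               nu1 * d / 2.0 + nu1 / 2.0 * trace(V2inv_V1) +
               lmvgamma(nu2 / 2.0, d) - lmvgamma(nu1 / 2.0, d) +
               nu2 / 2.0 * (ld2 - ld1);
    } else {
      for (int i = 0; i < d; ++i) {
        double a1 = p.nu(k) / 2.0, s1 = 2.0 * p.w2diag(k, i);
        double a2 = pr.wdf(k) / 2.0, s2 = 2.0 * pr.wscale(i, i, k);
        total += (a1 - a2) * R::digamma(a1) - R::lgammafn(a1) +
                 R::lgammafn(a2) + a2 * (std::log(s2) - std::log(s1)) +
                 a1 * (s1 - s2) / s2;
      }
    }
  }
  double a0 = accu(p.D), b0 = accu(pr.dir);
  total += R::lgammafn(a0) - R::lgammafn(b0);
  for (int k = 0; k < K; ++k) {
    total += -R::lgammafn(p.D(k)) + R::lgammafn(pr.dir(k)) +
             (p.D(k) - pr.dir(k)) * (R::digamma(p.D(k)) - R::digamma(a0));
  }
  return total;
}

// --------------------------------------------------------------------- loss

// F: batch features (b x dim); chi/gam: inverse-CDF caches for this params
static double mc_loglik(const mat& F, const Params& p, const Noise& no,
                        const cube& chi, const mat& gam) {
  const int L = no.eps.n_rows, K = p.K;
  const int nb = F.n_rows;
  double mc = 0.0;
  mat logterm(nb, K);
  for (int l = 0; l < L; ++l) {
    vec g(K);
    for (int k = 0; k < K; ++k) g(k) = gam(l, k);
    vec logalpha = log(g / accu(g));
    for (int k = 0; k < K; ++k) {
      vec mu(2);
      mu(0) = p.N1(k, 0) + std::sqrt(p.N2(k, 0)) * no.eps(l, k, 0);
      mu(1) = p.N1(k, 1) + std::sqrt(p.N2(k, 1)) * no.eps(l, k, 1);
      // precision Lambda and its log-determinant
      double l00, l01, l11, logdet;
      if (p.full_cov) {
        mat A(2, 2, fill::zeros);
        A(0, 0) = std::sqrt(chi(l, k, 0));
        A(1, 1) = std::sqrt(chi(l, k, 1));
        A(1, 0) = no.zoff(l, k);
        mat B = p.W2chol.slice(k) * A; // lower triangular
        mat Lam = B * B.t();
        l00 = Lam(0, 0); l01 = Lam(0, 1); l11 = Lam(1, 1);
        logdet = 2.0 * (std::log(B(0, 0)) + std::log(B(1, 1)));
      } else {
        l00 = p.w2diag(k, 0) * chi(l, k, 0);
        l11 = p.w2diag(k, 1) * chi(l, k, 1);
        l01 = 0.0;
        logdet = std::log(l00) + std::log(l11);
      }
      const double base = logalpha(k) + 0.5 * logdet - LOG2PI;
      for (int i = 0; i < nb; ++i) {
        double d0 = F(i, 0) - mu(0), d1 = F(i, 1) - mu(1);
        double q = l00 * d0 * d0 + 2.0 * l01 * d0 * d1 + l11 * d1 * d1;
        logterm(i, k) = base - 0.5 * q;
      }
    }
    double s = 0.0;
    for (int i = 0; i < nb; ++i) {
      double mx = logterm.row(i).max();
      double acc = 0.0;
      for (int k = 0; k < K; ++k) acc += std::exp(logterm(i, k) - mx);
      s += mx + std::log(acc);
    }
    mc += s / nb;
  }
  return mc / L;
}

static double loss_value(const mat& F, const Params& p, const Noise& no,
                         const cube& chi, const mat& gam, const Prior& pr,
                         double kld_weight) {
  double loss = -(mc_loglik(F, p, no, chi, gam) -
                  kld_weight * kld_state_prior(p, pr));
  if (p.has_attention) {
    // keep the learned projection orthonormal: an unconstrained P makes the
    // density of the projected features scale-degenerate (shrinking P
    // inflates it for free); the gates carry channel weighting instead
    mat gram = p.P.t() * p.P;
    gram.diag() -= 1.0;
    loss += 10.0 * accu(square(gram));
    // ridge on the gate map: anchors the gating at identity unless the data
    // pays for a deviation, preventing slow diffusion along directions the
    // mixture likelihood is indifferent to
    loss += 0.5 * (accu(square(p.G)) + accu(square(p.b)));
  }
  return loss;
}

// batch features under given attention parameters
static mat batch_features(const std::vector<mat>& wins, const uvec& idx,
                          const mat& rawF, bool has_attention,
                          const Params& p) {
  if (!has_attention) {
    mat F(idx.n_elem, rawF.n_cols);
    for (uword i = 0; i < idx.n_elem; ++i) F.row(i) = rawF.row(idx(i));
    return F;
  }
  mat F(idx.n_elem, 2);
  for (uword i = 0; i < idx.n_elem; ++i)
    F.row(i) = attention_one(wins[idx(i)], p.G, p.b, p.P).t();
  return F;
}

// ---------------------------------------------------------------- training

// [[Rcpp::export]]
Rcpp::List cpp_svi_fit(Rcpp::List windows, const arma::mat& rawF,
                       const arma::vec& theta0, int K, int dim, bool full_cov,
                       bool has_attention, const arma::mat& prior_mean,
                       double prior_mean_var, const arma::vec& prior_wdf,
                       const arma::cube& prior_wscale,
                       const arma::vec& prior_dir, int L, int batch_size,
                       double step_size, double momentum, int steps,
                       double kld_weight, int prior_refresh_every,
                       bool train_projection, double fd_eps) {
  Rcpp::RNGScope scope;
  Layout lay = make_layout(K, dim, full_cov, has_attention);
  if ((int)theta0.n_elem != lay.total)
    Rcpp::stop("internal error: parameter vector has wrong length");

  std::vector<mat> wins;
  int n;
  if (has_attention) {
    n = windows.size();
    wins.reserve(n);
    for (int i = 0; i < n; ++i) wins.push_back(Rcpp::as<mat>(windows[i]));
  } else {
    n = rawF.n_rows;
  }
  if (n < 1) Rcpp::stop("empty input: no training data");
  const int nb = std::min(batch_size, n);

  Prior pr;
  pr.mean = prior_mean;
  pr.mean_var = prior_mean_var;
  pr.wdf = prior_wdf;
  pr.wscale = prior_wscale;
  pr.dir = prior_dir;

  // Adam: momentum plus per-coordinate RMS scaling, needed because the
  // precision parameters of tight clusters make the surface very stiff
  vec theta = theta0;
  vec m1(lay.total, fill::zeros);
  vec m2(lay.total, fill::zeros);
  const double beta2 = 0.999, adam_eps = 1e-8;
  vec trace(steps);
  vec grad(lay.total);

  for (int step = 0; step < steps; ++step) {
    // mini-batch (with replacement) and reparameterization noise
    uvec idx(nb);
    if (nb == n) {
      idx = regspace<uvec>(0, n - 1);
    } else {
      for (int i = 0; i < nb; ++i)
        idx(i) = std::min((int)(R::unif_rand() * n), n - 1);
    }
    Noise no = draw_noise(L, K, dim);

    Params p0 = unpack(theta, lay);
    cube chi(L, K, dim);
    mat gam(L, K);
    for (int k = 0; k < K; ++k) {
      fill_chi_col(chi, no, p0, k);
      fill_gam_col(gam, no, p0, k);
    }
    mat F0 = batch_features(wins, idx, rawF, has_attention, p0);
    double loss0 = loss_value(F0, p0, no, chi, gam, pr, kld_weight);
    if (!std::isfinite(loss0))
      Rcpp::stop("training diverged: non-finite loss at step %d", step + 1);
    trace(step) = loss0;

    // forward-difference pathwise gradient, caches invalidated selectively
    for (int j = 0; j < lay.total; ++j) {
      if (has_attention && !train_projection && j >= 20 && j < 28) {
        grad(j) = 0.0; // projection frozen at its template
        continue;
      }
      double h = fd_eps * (1.0 + std::abs(theta(j)));
      double saved = theta(j);
      theta(j) += h;
      Params pj = unpack(theta, lay);
      double lj;
      if (has_attention && j < 28) {
        mat Fj = batch_features(wins, idx, rawF, true, pj);
        lj = loss_value(Fj, pj, no, chi, gam, pr, kld_weight);
      } else if (j >= lay.off_W1 && j < lay.off_W1 + K) {
        int k = j - lay.off_W1;
        cube chij = chi;
        fill_chi_col(chij, no, pj, k);
        lj = loss_value(F0, pj, no, chij, gam, pr, kld_weight);
      } else if (j >= lay.off_D && j < lay.off_D + K) {
        int k = j - lay.off_D;
        mat gamj = gam;
        fill_gam_col(gamj, no, pj, k);
        lj = loss_value(F0, pj, no, chi, gamj, pr, kld_weight);
      } else {
        lj = loss_value(F0, pj, no, chi, gam, pr, kld_weight);
      }
      grad(j) = (lj - loss0) / h;
      theta(j) = saved;
    }
    if (!grad.is_finite())
      Rcpp::stop("training diverged: non-finite gradient at step %d", step + 1);

    m1 = momentum * m1 + (1.0 - momentum) * grad;
    m2 = beta2 * m2 + (1.0 - beta2) * square(grad);
    double c1 = 1.0 - std::pow(momentum, step + 1);
    double c2 = 1.0 - std::pow(beta2, step + 1);
    theta -= step_size * (m1 / c1) / (sqrt(m2 / c2) + adam_eps);

    if (prior_refresh_every > 0 && (step + 1) % prior_refresh_every == 0) {
      Params pc = unpack(theta, lay);
      pr.mean = pc.N1;
      pr.wdf = pc.nu;
      for (int k = 0; k < K; ++k) {
        if (full_cov)
          pr.wscale.slice(k) = pc.W2chol.slice(k) * pc.W2chol.slice(k).t();
        else
          pr.wscale.slice(k) = diagmat(pc.w2diag.row(k).t());
      }
      pr.dir = pc.D;
    }
  }

  return Rcpp::List::create(Rcpp::Named("theta") = theta,
                            Rcpp::Named("trace") = trace);
}
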