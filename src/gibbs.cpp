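// Gibbs sampler for Bayesian linear random regression animal models,
// plus the Meuwissen-Luo inbreeding recursion.
//
// Model: y = Xb + Hq + Za + Wp + e with random regression coefficient
// vectors per herd-year-season level (q), animal (a, correlated through
// the pedigree via A-inverse), and permanent environment (p). Coefficient
// covariances carry inverted-Wishart full conditionals; residual class
// variances carry scaled inverse chi-square conditionals. Location
// effects are sampled block-by-block (all coefficients of one level
// jointly) from their Gaussian full conditionals.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Rng {
  std::mt19937_64 gen;
  std::normal_distribution<double> norm{0.0, 1.0};
  explicit Rng(uint64_t seed) : gen(seed) {}
  double rnorm() { return norm(gen); }
  double rchisq(double df) {
    std::gamma_distribution<double> g(df / 2.0, 2.0);
    return g(gen);
  }
  vec rnorm_vec(uword n) {
    vec z(n);
    for (uword i = 0; i < n; ++i) z[i] = rnorm();
    return z;
  }
};

// Draw from Wishart(df, S) via Bartlett decomposition; S must be SPD.
mat rwishart(Rng& rng, double df, const mat& S) {
  const uword k = S.n_rows;
  mat L = chol(S, "lower");
  mat A(k, k, fill::zeros);
  for (uword i = 0; i < k; ++i) {
    A(i, i) = std::sqrt(rng.rchisq(df - static_cast<double>(i)));
    for (uword j = 0; j < i; ++j) A(i, j) = rng.rnorm();
  }
  mat LA = L * A;
  return LA * LA.t();
}

// Draw from inverse-Wishart(df, Scale): X^{-1} ~ Wishart(df, Scale^{-1}).
mat riwishart(Rng& rng, double df, const mat& Scale) {
  mat W = rwishart(rng, df, inv_sympd(symmatu(Scale)));
  return inv_sympd(symmatu(W));
}

// Sample a coefficient block from N(P^{-1} r, P^{-1}).
vec sample_block(Rng& rng, const mat& P, const vec& r) {
  mat U = chol(symmatu(P));  // P = U'U
  vec mu = solve(trimatu(U), solve(trimatl(U.t()), r));
  return mu + solve(trimatu(U), rng.rnorm_vec(r.n_elem));
}

// Group observation indices by an integer key in [0, n_levels).
std::vector<std::vector<uword>> group_by(const uvec& key, uword n_levels) {
  std::vector<std::vector<uword>> out(n_levels);
  for (uword o = 0; o < key.n_elem; ++o) out[key[o]].push_back(o);
  return out;
}

}  // namespace

// Meuwissen & Luo inbreeding coefficients. si/di are 1-based parent
// indices into the topologically sorted pedigree, 0 for unknown.
// [[Rcpp::export]]
Rcpp::NumericVector meuwissen_luo_F(Rcpp::IntegerVector si,
                                    Rcpp::IntegerVector di) {
  const int n = si.size();
  std::vector<double> F(n + 1, 0.0);  // F[0] is the unknown-parent slot
  std::vector<double> D(n + 1, 0.0);
  std::vector<double> coef(n + 1);
  Rcpp::NumericVector out(n);
  for (int i = 1; i <= n; ++i) {
    const int s = si[i - 1], d = di[i - 1];
    const double Fs = s ? F[s] : -1.0, Fd = d ? F[d] : -1.0;
    D[i] = 0.5 - 0.25 * (Fs + Fd);
    if (!s || !d) {
      F[i] = 0.0;
      out[i - 1] = 0.0;
      continue;
    }
    std::fill(coef.begin(), coef.begin() + i + 1, 0.0);
    coef[i] = 1.0;
    double aii = 0.0;
    for (int j = i; j >= 1; --j) {
      const double c = coef[j];
      if (c == 0.0) continue;
      aii += c * c * D[j];
      if (si[j - 1]) coef[si[j - 1]] += 0.5 * c;
      if (di[j - 1]) coef[di[j - 1]] += 0.5 * c;
    }
    F[i] = aii - 1.0;
    out[i - 1] = F[i];
  }
  return out;
}

// Full Gibbs sampler. All level indices are 0-based on entry.
// [[Rcpp::export]]
Rcpp::List gibbs_rrm(const arma::vec& y,
                     const arma::mat& Tobs,        // n_obs x k covariates
                     const arma::uvec& obs_cow,    // animal index per obs
                     const arma::uvec& obs_hys,
                     const arma::uvec& obs_ys,
                     const arma::uvec& obs_trait,  // 0..n_traits-1
                     const arma::vec& obs_et,      // 0/1 ET indicator
                     const arma::uvec& obs_class,  // residual class per obs
                     const arma::sp_mat& Ainv,
                     int n_traits,
                     const arma::mat& Vq, const arma::mat& Vg,
                     const arma::mat& Vp,
                     double nu, double nu_e, const arma::vec& s2e_prior,
                     double sigma_b,
                     int n_iter, int burn_in, int thin, int seed,
                     bool fix_covariances, bool fix_residual,
                     const arma::mat& G0_init, const arma::mat& Rq_init,
                     const arma::mat& Rp_init, const arma::vec& sigma2_init) {
  const uword n_obs = y.n_elem;
  const uword k = Tobs.n_cols;
  const uword n_anim = Ainv.n_rows;
  const uword n_hys = obs_hys.max() + 1;
  const uword n_ys = obs_ys.max() + 1;
  const uword n_class = obs_class.max() + 1;

  Rng rng(static_cast<uint64_t>(seed));

  auto by_cow = group_by(obs_cow, n_anim);
  auto by_hys = group_by(obs_hys, n_hys);
  auto by_ys = group_by(obs_ys, n_ys);
  auto by_trait = group_by(obs_trait, static_cast<uword>(n_traits));
  auto by_class = group_by(obs_class, n_class);

  const mat Tt = Tobs.t();  // k x n_obs; columns are covariate vectors

  // Per level, cache the class-wise Gram matrices sum t t' (iteration
  // invariant); the iteration only reweights them by 1/sigma2 of the class.
  struct LevelCache {
    std::vector<uword> classes;
    cube grams;
  };
  auto make_cache = [&](const std::vector<std::vector<uword>>& groups) {
    std::vector<LevelCache> out(groups.size());
    for (size_t l = 0; l < groups.size(); ++l) {
      std::vector<uword> cls;
      for (uword o : groups[l]) {
        if (std::find(cls.begin(), cls.end(), obs_class[o]) == cls.end())
          cls.push_back(obs_class[o]);
      }
      out[l].classes = cls;
      out[l].grams = cube(k, k, cls.size(), fill::zeros);
      for (uword o : groups[l]) {
        const size_t c = std::find(cls.begin(), cls.end(), obs_class[o]) -
                         cls.begin();
        out[l].grams.slice(c) += Tt.col(o) * Tt.col(o).t();
      }
    }
    return out;
  };
  auto cache_cow = make_cache(by_cow);
  auto cache_hys = make_cache(by_hys);
  auto cache_ys = make_cache(by_ys);

  std::vector<uword> with_pe;  // animals carrying observations
  for (uword i = 0; i < n_anim; ++i)
    if (!by_cow[i].empty()) with_pe.push_back(i);
  const double n_pe = static_cast<double>(with_pe.size());

  // state
  mat G0 = G0_init, Rq = Rq_init, Rp = Rp_init;
  vec sigma2 = sigma2_init;
  mat q(n_hys, k, fill::zeros), a(n_anim, k, fill::zeros),
      p(n_anim, k, fill::zeros), bys(n_ys, k, fill::zeros);
  vec bet(n_traits, fill::zeros);
  vec e = y;  // residuals given all-zero effects

  const double tau_b = 1.0 / sigma_b;  // vague fixed-effect prior precision

  const int n_ret = (n_iter - burn_in) / thin;
  cube G0_draws(k, k, n_ret), Rq_draws(k, k, n_ret), Rp_draws(k, k, n_ret);
  mat sigma2_draws(n_ret, n_class);
  mat bet_draws(n_ret, n_traits);
  mat bys_draws(n_ret, n_ys * k);
  vec dev_draws(n_ret);

  // running posterior means of everything the deviance-at-means needs
  mat a_mean(n_anim, k, fill::zeros), p_mean(n_anim, k, fill::zeros),
      q_mean(n_hys, k, fill::zeros), bys_mean(n_ys, k, fill::zeros);
  vec bet_mean(n_traits, fill::zeros), sigma2_mean(n_class, fill::zeros);
  mat G0_mean(k, k, fill::zeros), Rq_mean(k, k, fill::zeros),
      Rp_mean(k, k, fill::zeros);

  vec w_class(n_class);  // 1/sigma2 per residual class

  auto update_weights = [&]() {
    for (uword c = 0; c < n_class; ++c) w_class[c] = 1.0 / sigma2[c];
  };

  // one coefficient-block update for the level owning observations `idx`
  auto sample_level = [&](const std::vector<uword>& idx,
                          const LevelCache& cache, const mat& prior_prec,
                          rowvec& coef_row, const vec& prior_rhs) {
    mat P = prior_prec;
    vec r = prior_rhs;
    const vec old = coef_row.t();
    for (size_t c = 0; c < cache.classes.size(); ++c)
      P += w_class[cache.classes[c]] * cache.grams.slice(c);
    for (uword o : idx) {
      e[o] += dot(Tt.col(o), old);  // add old contribution back
      r += (w_class[obs_class[o]] * e[o]) * Tt.col(o);
    }
    vec nu_new = sample_block(rng, P, r);
    coef_row = nu_new.t();
    for (uword o : idx) e[o] -= dot(Tt.col(o), nu_new);
  };

  mat G0i = inv_sympd(symmatu(G0)), Rqi = inv_sympd(symmatu(Rq)),
      Rpi = inv_sympd(symmatu(Rp));
  const vec zero_k(k, fill::zeros);
  const mat eye_k = eye(k, k);

  int ret = 0;
  for (int it = 0; it < n_iter; ++it) {
    update_weights();

    // fixed year-season regression blocks (vague prior)
    for (uword l = 0; l < n_ys; ++l) {
      rowvec row = bys.row(l);
      sample_level(by_ys[l], cache_ys[l], tau_b * eye_k, row, zero_k);
      bys.row(l) = row;
    }
    // embryo-transfer contrast, one scalar per trait
    for (int t = 0; t < n_traits; ++t) {
      double Pv = tau_b, rv = 0.0;
      const double old = bet[t];
      for (uword o : by_trait[t]) {
        if (obs_et[o] == 0.0) continue;
        e[o] += old;
        Pv += w_class[obs_class[o]];
        rv += w_class[obs_class[o]] * e[o];
      }
      const double mu = rv / Pv;
      bet[t] = mu + rng.rnorm() / std::sqrt(Pv);
      for (uword o : by_trait[t])
        if (obs_et[o] != 0.0) e[o] -= bet[t];
    }
    // herd-year-season blocks
    for (uword l = 0; l < n_hys; ++l) {
      rowvec row = q.row(l);
      sample_level(by_hys[l], cache_hys[l], Rqi, row, zero_k);
      q.row(l) = row;
    }
    // permanent environment blocks (only animals with records)
    for (uword i : with_pe) {
      rowvec row = p.row(i);
      sample_level(by_cow[i], cache_cow[i], Rpi, row, zero_k);
      p.row(i) = row;
    }
    // additive blocks: prior couples animals through A-inverse
    for (uword i = 0; i < n_anim; ++i) {
      vec nbr(k, fill::zeros);
      double aii = 0.0;
      for (sp_mat::const_col_iterator it2 = Ainv.begin_col(i);
           it2 != Ainv.end_col(i); ++it2) {
        const uword j = it2.row();
        if (j == i) aii = *it2;
        else nbr += (*it2) * a.row(j).t();
      }
      mat prior_prec = aii * G0i;
      vec prior_rhs = -G0i * nbr;
      rowvec row = a.row(i);
      sample_level(by_cow[i], cache_cow[i], prior_prec, row, prior_rhs);
      a.row(i) = row;
    }

    if (!fix_covariances) {
      // coefficient covariances from their inverted-Wishart conditionals
      mat Sq = q.t() * q;
      Rq = riwishart(rng, nu + static_cast<double>(n_hys), nu * Vq + Sq);
      mat Sp(k, k, fill::zeros);
      for (uword i : with_pe) Sp += p.row(i).t() * p.row(i);
      Rp = riwishart(rng, nu + n_pe, nu * Vp + Sp);
      mat SA = a.t() * (Ainv * a);
      G0 = riwishart(rng, nu + static_cast<double>(n_anim),
                     nu * Vg + symmatu(SA));
      G0i = inv_sympd(symmatu(G0));
      Rqi = inv_sympd(symmatu(Rq));
      Rpi = inv_sympd(symmatu(Rp));
    }
    if (!fix_residual) {
      // residual classes: scaled inverse chi-square
      for (uword c = 0; c < n_class; ++c) {
        double sse = 0.0;
        for (uword o : by_class[c]) sse += e[o] * e[o];
        const double df = nu_e + static_cast<double>(by_class[c].size());
        sigma2[c] = (nu_e * s2e_prior[c] + sse) / rng.rchisq(df);
      }
    }

    if (!std::isfinite(accu(e)) || !sigma2.is_finite()) {
      Rcpp::stop("non-finite state at iteration %d", it + 1);
    }

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      G0_draws.slice(ret) = G0;
      Rq_draws.slice(ret) = Rq;
      Rp_draws.slice(ret) = Rp;
      sigma2_draws.row(ret) = sigma2.t();
      bet_draws.row(ret) = bet.t();
      bys_draws.row(ret) = vectorise(bys, 1);
      double dev = 0.0;
      for (uword o = 0; o < n_obs; ++o) {
        const double s2 = sigma2[obs_class[o]];
        dev += std::log(2.0 * M_PI * s2) + e[o] * e[o] / s2;
      }
      dev_draws[ret] = dev;
      a_mean += a; p_mean += p; q_mean += q; bys_mean += bys;
      bet_mean += bet; sigma2_mean += sigma2;
      G0_mean += G0; Rq_mean += Rq; Rp_mean += Rp;
      ++ret;
    }
  }
  if (ret == 0) Rcpp::stop("no retained draws (check chain configuration)");
  const double nr = static_cast<double>(ret);
  a_mean /= nr; p_mean /= nr; q_mean /= nr; bys_mean /= nr;
  bet_mean /= nr; sigma2_mean /= nr;
  G0_mean /= nr; Rq_mean /= nr; Rp_mean /= nr;

  // deviance at the posterior means of all parameters
  double dev_at_mean = 0.0;
  for (uword o = 0; o < n_obs; ++o) {
    const vec t = Tt.col(o);
    double mu = dot(t, bys_mean.row(obs_ys[o]).t()) +
                obs_et[o] * bet_mean[obs_trait[o]] +
                dot(t, q_mean.row(obs_hys[o]).t()) +
                dot(t, a_mean.row(obs_cow[o]).t()) +
                dot(t, p_mean.row(obs_cow[o]).t());
    const double s2 = sigma2_mean[obs_class[o]];
    const double res = y[o] - mu;
    dev_at_mean += std::log(2.0 * M_PI * s2) + res * res / s2;
  }

  return Rcpp::List::create(
      Rcpp::Named("G0") = G0_draws, Rcpp::Named("Rq") = Rq_draws,
      Rcpp::Named("Rp") = Rp_draws, Rcpp::Named("sigma2") = sigma2_draws,
      Rcpp::Named("b_et") = bet_draws, Rcpp::Named("b_ys") = bys_draws,
      Rcpp::Named("deviance") = dev_draws,
      Rcpp::Named("D_at_mean") = dev_at_mean,
      Rcpp::Named("a_mean") = a_mean, Rcpp::Named("p_mean") = p_mean,
      Rcpp::Named("q_mean") = q_mean, Rcpp::Named("b_ys_mean") = bys_mean,
      Rcpp::Named("b_et_mean") = bet_mean,
      Rcpp::Named("sigma2_mean") = sigma2_mean,
      Rcpp::Named("G0_mean") = G0_mean, Rcpp::Named("Rq_mean") = Rq_mean,
      Rcpp::Named("Rp_mean") = Rp_mean,
      Rcpp::Named("n_retained") = ret);
}

// Direct draws from the inverse-Wishart used by the covariance updates.
// [[Rcpp::export]]
arma::cube draw_inv_wishart(int n, double df, const arma::mat& Scale,
                            int seed) {
  Rng rng(static_cast<uint64_t>(seed));
  cube out(Scale.n_rows, Scale.n_cols, n);
  for (int i = 0; i < n; ++i) out.slice(i) = riwishart(rng, df, Scale);
  return out;
}

// Direct draws from the scaled inverse chi-square used by the residual
// updates: (nu * s2) / chisq(nu).
// [[Rcpp::export]]
arma::vec draw_scaled_inv_chisq(int n, double nu, double s2, int seed) {
  Rng rng(static_cast<uint64_t>(seed));
  vec out(n);
  for (int i = 0; i < n; ++i) out[i] = nu * s2 / rng.rchisq(nu);
  return out;
}
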