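#include <Rcpp.h>
using namespace Rcpp;

// Standard normal conditioned on T > a, by simple rejection when a is in
// the body of the distribution and by Robert's (1995) shifted-exponential
// rejection when a is in the right tail. Exact in both branches.
static double rnorm_above(double a) {
  if (a < 0.4) {
    for (;;) {
      double z = norm_rand();
      if (z > a) return z;
    }
  }
  double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double z = a - std::log(unif_rand()) / alpha;
    double d = z - alpha;
    if (unif_rand() <= std::exp(-0.5 * d * d)) return z;
  }
}

// Draw from N(mu, 1) truncated to (0, Inf) if y = 1, to (-Inf, 0] if y = 0.
static double rtrunc_liab(double mu, int y) {
  if (y == 1) return mu + rnorm_above(-mu);
  return mu - rnorm_above(mu);
}

// Ancillarity-sufficiency interweaving step for the scale of a hierarchical
// effect vector v (u or pe). In the whitened parameterization v = sigma * w
// with w ~ N(0, K), the conditional of sigma given w and the liabilities is
// Gaussian-likelihood x scaled-inverse-chi-square prior; an independence
// MH proposal from the Gaussian part leaves only the prior ratio in the
// acceptance probability. Jointly rescaling (v, sigma^2) breaks the slow
// random walk between the effect vector and its variance that plagues
// single-site samplers for weakly informative binary data.
static void interweave_scale(std::vector<double>& v, double& s2,
                             const IntegerVector& idx, std::vector<double>& e,
                             int nrec, double nu, double S) {
  double sig = std::sqrt(s2);
  if (sig <= 0) return;
  double P = 0.0, num = 0.0;
  for (int r = 0; r < nrec; ++r) {
    double x = v[idx[r]] / sig;
    P += x * x;
    num += x * (e[r] + sig * x);
  }
  if (P <= 0) return;
  double m = num / P, sd = 1.0 / std::sqrt(P);
  double prop = m + sd * norm_rand();
  if (prop <= 0) return;  // stay (sign flip proposals rejected for simplicity)
  double logprior = [&](double s) {
    return -(nu + 1.0) * std::log(s) - nu * S / (2.0 * s * s);
  }(prop) - (-(nu + 1.0) * std::log(sig) - nu * S / (2.0 * sig * sig));
  if (std::log(unif_rand()) < logprior) {
    double ratio = prop / sig;
    for (int r = 0; r < nrec; ++r) e[r] += (sig - prop) * (v[idx[r]] / sig);
    for (size_t i = 0; i < v.size(); ++i) v[i] *= ratio;
    s2 = prop * prop;
  }
}

// Gibbs sampler for the single-step threshold (probit) animal model
//   l = X beta + Z1 hys + Z2 u + W pe + e,   e ~ N(0, I)
// beta: fixed class effects (cell-means lactation coding, flat prior)
// hys ~ N(0, I s2_hys), u ~ N(0, H s2_u), pe ~ N(0, I s2_pe)
// Variances get scaled-inverse-chi-square full conditionals; the residual
// liability variance is fixed at 1. H^-1 is supplied in CSC form (full
// symmetric storage). All random draws use R's RNG (seed via set.seed()).
// [[Rcpp::export(name = "gibbs_threshold_cpp")]]
List gibbs_threshold(IntegerVector y,
                     IntegerVector lact,  // 0-based class per record
                     IntegerVector hysid, // 0-based group per record
                     IntegerVector anim,  // 0-based animal per record
                     IntegerVector peid,  // 0-based cow per record
                     int n_lact, int n_hys, int n_anim, int n_pe,
                     IntegerVector Hp, IntegerVector Hi, NumericVector Hx,
                     int n_iter, int burn_in, int thin,
                     double nu, double S_hys, double S_u, double S_pe,
                     double start_hys, double start_u, double start_pe) {
  const int nrec = y.size();
  std::vector<double> l(nrec), e(nrec);
  std::vector<double> beta(n_lact, 0.0), hys(n_hys, 0.0),
      u(n_anim, 0.0), pe(n_pe, 0.0);
  double s2_hys = start_hys, s2_u = start_u, s2_pe = start_pe;
  if (s2_hys <= 0) s2_hys = 1e-4;
  if (s2_u <= 0) s2_u = 1e-4;
  if (s2_pe <= 0) s2_pe = 1e-4;

  // record lists per animal (counting sort) for the single-site u updates
  std::vector<int> acount(n_anim, 0);
  for (int r = 0; r < nrec; ++r) acount[anim[r]]++;
  std::vector<int> astart(n_anim + 1, 0);
  for (int i = 0; i < n_anim; ++i) astart[i + 1] = astart[i] + acount[i];
  std::vector<int> arec(nrec);
  {
    std::vector<int> cursor(astart.begin(), astart.end() - 1);
    for (int r = 0; r < nrec; ++r) arec[cursor[anim[r]]++] = r;
  }
  std::vector<int> nlev_lact(n_lact, 0), nlev_hys(n_hys, 0), nlev_pe(n_pe, 0);
  for (int r = 0; r < nrec; ++r) {
    nlev_lact[lact[r]]++;
    nlev_hys[hysid[r]]++;
    nlev_pe[peid[r]]++;
  }

  // init: liabilities from the prior predictive at eta = 0
  for (int r = 0; r < nrec; ++r) {
    l[r] = rtrunc_liab(0.0, y[r]);
    e[r] = l[r];
  }

  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix var_samples(n_keep, 3);
  std::vector<double> sum_beta(n_lact, 0.0), ss_beta(n_lact, 0.0);
  std::vector<double> sum_hys(n_hys, 0.0), ss_hys(n_hys, 0.0);
  std::vector<double> sum_u(n_anim, 0.0), ss_u(n_anim, 0.0);
  std::vector<double> sum_pe(n_pe, 0.0), ss_pe(n_pe, 0.0);
  int kept = 0;

  std::vector<double> acc(std::max(std::max(n_lact, n_hys), n_pe), 0.0);

  for (int it = 0; it < n_iter; ++it) {
    // 1. latent liabilities
    for (int r = 0; r < nrec; ++r) {
      double eta = l[r] - e[r];
      double lnew = rtrunc_liab(eta, y[r]);
      e[r] += lnew - l[r];
      l[r] = lnew;
    }
    // 2. fixed lactation-class effects (flat prior)
    std::fill(acc.begin(), acc.begin() + n_lact, 0.0);
    for (int r = 0; r < nrec; ++r) acc[lact[r]] += e[r];
    for (int j = 0; j < n_lact; ++j) {
      if (nlev_lact[j] == 0) continue;
      double mean = acc[j] / nlev_lact[j] + beta[j];
      double bnew = mean + norm_rand() / std::sqrt((double)nlev_lact[j]);
      acc[j] = beta[j] - bnew;  // reuse as delta
      beta[j] = bnew;
    }
    for (int r = 0; r < nrec; ++r) e[r] += acc[lact[r]];
    // 3. herd-year-season effects
    std::fill(acc.begin(), acc.begin() + n_hys, 0.0);
    for (int r = 0; r < nrec; ++r) acc[hysid[r]] += e[r];
    {
      double lam = 1.0 / s2_hys;
      for (int j = 0; j < n_hys; ++j) {
        double prec = nlev_hys[j] + lam;
        double mean = (acc[j] + nlev_hys[j] * hys[j]) / prec;
        double hnew = mean + norm_rand() / std::sqrt(prec);
        acc[j] = hys[j] - hnew;
        hys[j] = hnew;
      }
      for (int r = 0; r < nrec; ++r) e[r] += acc[hysid[r]];
    }
    // 4. permanent environment
    std::fill(acc.begin(), acc.begin() + n_pe, 0.0);
    for (int r = 0; r < nrec; ++r) acc[peid[r]] += e[r];
    {
      double lam = 1.0 / s2_pe;
      for (int j = 0; j < n_pe; ++j) {
        double prec = nlev_pe[j] + lam;
        double mean = (acc[j] + nlev_pe[j] * pe[j]) / prec;
        double pnew = mean + norm_rand() / std::sqrt(prec);
        acc[j] = pe[j] - pnew;
        pe[j] = pnew;
      }
      for (int r = 0; r < nrec; ++r) e[r] += acc[peid[r]];
    }
    // 5. additive values, single-site with H^-1 coupling
    {
      double lam = 1.0 / s2_u;
      for (int i = 0; i < n_anim; ++i) {
        double hii = 0.0, off = 0.0;
        for (int k = Hp[i]; k < Hp[i + 1]; ++k) {
          int row = Hi[k];
          if (row == i) hii = Hx[k];
          else off += Hx[k] * u[row];
        }
        double rsum = 0.0;
        for (int k = astart[i]; k < astart[i + 1]; ++k) rsum += e[arec[k]];
        rsum += acount[i] * u[i];
        double prec = acount[i] + lam * hii;
        double mean = (rsum - lam * off) / prec;
        double unew = mean + norm_rand() / std::sqrt(prec);
        double delta = u[i] - unew;
        for (int k = astart[i]; k < astart[i + 1]; ++k) e[arec[k]] += delta;
        u[i] = unew;
      }
    }
    // 6. variance components (scaled inverse chi-square)
    {
      double ss = 0.0;
      for (int j = 0; j < n_hys; ++j) ss += hys[j] * hys[j];
      s2_hys = (ss + nu * S_hys) / R::rchisq(n_hys + nu);
      ss = 0.0;
      for (int j = 0; j < n_pe; ++j) ss += pe[j] * pe[j];
      s2_pe = (ss + nu * S_pe) / R::rchisq(n_pe + nu);
      double quad = 0.0;  // u' H^-1 u
      for (int i = 0; i < n_anim; ++i)
        for (int k = Hp[i]; k < Hp[i + 1]; ++k)
          quad += u[i] * Hx[k] * u[Hi[k]];
      s2_u = (quad + nu * S_u) / R::rchisq(n_anim + nu);
    }
    // 6b. interweaving: joint scale moves for (u, s2_u) and (pe, s2_pe)
    interweave_scale(u, s2_u, anim, e, nrec, nu, S_u);
    interweave_scale(pe, s2_pe, peid, e, nrec, nu, S_pe);
    // 7. storage
    if (it >= burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      var_samples(kept, 0) = s2_hys;
      var_samples(kept, 1) = s2_u;
      var_samples(kept, 2) = s2_pe;
      for (int j = 0; j < n_lact; ++j) {
        sum_beta[j] += beta[j];
        ss_beta[j] += beta[j] * beta[j];
      }
      for (int j = 0; j < n_hys; ++j) {
        sum_hys[j] += hys[j];
        ss_hys[j] += hys[j] * hys[j];
      }
      for (int j = 0; j < n_anim; ++j) {
        sum_u[j] += u[j];
        ss_u[j] += u[j] * u[j];
      }
      for (int j = 0; j < n_pe; ++j) {
        sum_pe[j] += pe[j];
        ss_pe[j] += pe[j] * pe[j];
      }
      kept++;
    }
  }

  auto summarize = [&](std::vector<double>& s, std::vector<double>& ss, int m) {
    NumericMatrix out(m, 2);
    for (int j = 0; j < m; ++j) {
      double mean = s[j] / kept;
      double v = ss[j] / kept - mean * mean;
      out(j, 0) = mean;
      out(j, 1) = v > 0 ? std::sqrt(v) : 0.0;
    }
    return out;
  };
  return List::create(
      _["beta"] = summarize(sum_beta, ss_beta, n_lact),
      _["hys"] = summarize(sum_hys, ss_hys, n_hys),
      _["u"] = summarize(sum_u, ss_u, n_anim),
      _["pe"] = summarize(sum_pe, ss_pe, n_pe),
      _["var_samples"] = var_samples, _["n_kept"] = kept);
}
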