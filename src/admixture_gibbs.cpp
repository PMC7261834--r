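// Gibbs sampler for the Bayesian admixture model on multiallelic
// codominant genotypes: latent origin of every allele copy, Dirichlet
// updates for membership (Q) and cluster allele frequencies (P), a
// Metropolis step for the admixture concentration alpha, and optionally
// the correlated-frequency (F-model) prior on P.
//
// All randomness goes through R's RNG so runs are reproducible under
// set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static const double P_FLOOR = 1e-12;

static void rdirichlet_into(double *out, const double *shape, int m) {
  double tot = 0.0;
  for (int a = 0; a < m; ++a) {
    out[a] = R::rgamma(shape[a], 1.0);
    tot += out[a];
  }
  if (tot <= 0.0) { // degenerate draw: fall back to uniform
    for (int a = 0; a < m; ++a) out[a] = 1.0 / m;
    return;
  }
  for (int a = 0; a < m; ++a) {
    out[a] /= tot;
    if (out[a] < P_FLOOR) out[a] = P_FLOOR;
  }
}

static double log_ddirichlet(const double *x, const double *alpha, int m) {
  double s = 0.0, lg = 0.0, ll = 0.0;
  for (int a = 0; a < m; ++a) {
    s += alpha[a];
    lg += R::lgammafn(alpha[a]);
    ll += (alpha[a] - 1.0) * std::log(x[a]);
  }
  return R::lgammafn(s) - lg + ll;
}

// [[Rcpp::export(name = ".gibbs_admixture")]]
List gibbs_admixture(IntegerMatrix A1, IntegerMatrix A2,
                     IntegerVector nAlleles, int K,
                     int burn_in, int iterations, int thinning,
                     bool correlated, double lambda,
                     double alpha_init, double alpha_sd,
                     double alpha_max) {
  const int n = A1.nrow(), L = A1.ncol();
  if (thinning < 1) thinning = 1;

  // state -----------------------------------------------------------------
  NumericMatrix Q(n, K);
  std::vector<NumericMatrix> P(L);     // K x m_l
  std::vector<NumericMatrix> panc1(L); // 1 x m_l ancestral freqs (F-model)
  NumericVector Fdrift(K, 0.1);
  double alpha = alpha_init;

  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    std::vector<double> tmp(K);
    for (int k = 0; k < K; ++k) { tmp[k] = R::rgamma(1.0, 1.0); tot += tmp[k]; }
    for (int k = 0; k < K; ++k) Q(i, k) = std::max(tmp[k] / tot, P_FLOOR);
  }
  for (int l = 0; l < L; ++l) {
    int m = nAlleles[l];
    P[l] = NumericMatrix(K, m);
    panc1[l] = NumericMatrix(1, m);
    std::vector<double> one(m, 1.0), row(m);
    for (int k = 0; k < K; ++k) {
      rdirichlet_into(row.data(), one.data(), m);
      for (int a = 0; a < m; ++a) P[l](k, a) = row[a];
    }
    rdirichlet_into(row.data(), one.data(), m);
    for (int a = 0; a < m; ++a) panc1[l](0, a) = row[a];
  }

  // accumulators ----------------------------------------------------------
  NumericMatrix Qsum(n, K);
  std::vector<NumericMatrix> Psum(L);
  for (int l = 0; l < L; ++l) Psum[l] = NumericMatrix(K, nAlleles[l]);
  double alpha_sum = 0.0;
  std::vector<double> lnl_trace;
  int n_rec = 0;

  IntegerMatrix qcnt(n, K);
  std::vector<std::vector<double>> pcnt(L);
  for (int l = 0; l < L; ++l) pcnt[l].assign((size_t)K * nAlleles[l], 0.0);
  std::vector<double> prob(K), qrow(K);

  const int total_iter = burn_in + iterations;
  for (int it = 0; it < total_iter; ++it) {
    // reset counts
    std::fill(qcnt.begin(), qcnt.end(), 0);
    for (int l = 0; l < L; ++l)
      std::fill(pcnt[l].begin(), pcnt[l].end(), 0.0);

    // (i) origin of each allele copy
    for (int l = 0; l < L; ++l) {
      const NumericMatrix &Pl = P[l];
      for (int copy = 0; copy < 2; ++copy) {
        const IntegerMatrix &A = copy == 0 ? A1 : A2;
        for (int i = 0; i < n; ++i) {
          int a = A(i, l);
          if (a < 0) continue;
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            prob[k] = Q(i, k) * Pl(k, a);
            tot += prob[k];
          }
          double u = R::unif_rand() * tot;
          int z = 0;
          double acc = prob[0];
          while (z < K - 1 && u > acc) acc += prob[++z];
          qcnt(i, z) += 1;
          pcnt[l][(size_t)z * nAlleles[l] + a] += 1.0;
        }
      }
    }

    // (ii) P given origins
    for (int l = 0; l < L; ++l) {
      int m = nAlleles[l];
      std::vector<double> sh(m), row(m);
      for (int k = 0; k < K; ++k) {
        double base = lambda;
        for (int a = 0; a < m; ++a) {
          if (correlated)
            base = panc1[l](0, a) * (1.0 - Fdrift[k]) / Fdrift[k];
          sh[a] = base + pcnt[l][(size_t)k * m + a];
        }
        rdirichlet_into(row.data(), sh.data(), m);
        for (int a = 0; a < m; ++a) P[l](k, a) = row[a];
      }
    }

    // (iii) Q given origins
    for (int i = 0; i < n; ++i) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        qrow[k] = R::rgamma(alpha + qcnt(i, k), 1.0);
        if (qrow[k] < P_FLOOR) qrow[k] = P_FLOOR;
        tot += qrow[k];
      }
      for (int k = 0; k < K; ++k) Q(i, k) = qrow[k] / tot;
    }

    // (iv) alpha by Metropolis (uniform prior on (0, alpha_max))
    {
      double prop = alpha + R::norm_rand() * alpha_sd;
      if (prop > 0.0 && prop < alpha_max) {
        double slq = 0.0;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k) slq += std::log(Q(i, k));
        double cur_ll = n * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha)) +
                        (alpha - 1.0) * slq;
        double prop_ll = n * (R::lgammafn(K * prop) - K * R::lgammafn(prop)) +
                         (prop - 1.0) * slq;
        if (std::log(R::unif_rand()) < prop_ll - cur_ll) alpha = prop;
      }
    }

    // (v) F-model hyperparameters
    if (correlated) {
      // per-cluster drift, Metropolis on (0.001, 0.999)
      for (int k = 0; k < K; ++k) {
        double prop = Fdrift[k] + R::norm_rand() * 0.05;
        if (prop <= 0.001 || prop >= 0.999) continue;
        double cur = 0.0, nw = 0.0;
        for (int l = 0; l < L; ++l) {
          int m = nAlleles[l];
          std::vector<double> acur(m), anew(m), x(m);
          for (int a = 0; a < m; ++a) {
            double pa = panc1[l](0, a);
            acur[a] = pa * (1.0 - Fdrift[k]) / Fdrift[k];
            anew[a] = pa * (1.0 - prop) / prop;
            x[a] = P[l](k, a);
          }
          cur += log_ddirichlet(x.data(), acur.data(), m);
          nw += log_ddirichlet(x.data(), anew.data(), m);
        }
        if (std::log(R::unif_rand()) < nw - cur) Fdrift[k] = prop;
      }
      // ancestral frequencies, Dirichlet random-walk proposal
      const double conc = 200.0;
      for (int l = 0; l < L; ++l) {
        int m = nAlleles[l];
        std::vector<double> cur(m), prop(m), sh(m);
        for (int a = 0; a < m; ++a) {
          cur[a] = panc1[l](0, a);
          sh[a] = conc * cur[a];
        }
        rdirichlet_into(prop.data(), sh.data(), m);
        double lr = 0.0;
        for (int k = 0; k < K; ++k) {
          std::vector<double> acur(m), anew(m), x(m);
          double fk = (1.0 - Fdrift[k]) / Fdrift[k];
          for (int a = 0; a < m; ++a) {
            acur[a] = cur[a] * fk;
            anew[a] = prop[a] * fk;
            x[a] = P[l](k, a);
          }
          lr += log_ddirichlet(x.data(), anew.data(), m) -
                log_ddirichlet(x.data(), acur.data(), m);
        }
        // proposal asymmetry
        std::vector<double> shp(m);
        for (int a = 0; a < m; ++a) shp[a] = conc * prop[a];
        lr += log_ddirichlet(cur.data(), shp.data(), m) -
              log_ddirichlet(prop.data(), sh.data(), m);
        if (std::log(R::unif_rand()) < lr)
          for (int a = 0; a < m; ++a) panc1[l](0, a) = prop[a];
      }
    }

    // record ----------------------------------------------------------------
    if (it >= burn_in && (it - burn_in) % thinning == 0) {
      double lnl = 0.0;
      for (int l = 0; l < L; ++l) {
        const NumericMatrix &Pl = P[l];
        for (int copy = 0; copy < 2; ++copy) {
          const IntegerMatrix &A = copy == 0 ? A1 : A2;
          for (int i = 0; i < n; ++i) {
            int a = A(i, l);
            if (a < 0) continue;
            double s = 0.0;
            for (int k = 0; k < K; ++k) s += Q(i, k) * Pl(k, a);
            lnl += std::log(s);
          }
        }
      }
      lnl_trace.push_back(lnl);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int l = 0; l < L; ++l)
        for (int k = 0; k < K; ++k)
          for (int a = 0; a < nAlleles[l]; ++a)
            Psum[l](k, a) += P[l](k, a);
      alpha_sum += alpha;
      ++n_rec;
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  if (n_rec == 0) stop("no post-burn-in samples recorded");
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (int k = 0; k < K; ++k) tot += Qsum(i, k);
    for (int k = 0; k < K; ++k) Qsum(i, k) /= tot;
  }
  List Pout(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix M = Psum[l];
    for (int k = 0; k < K; ++k) {
      double tot = 0.0;
      for (int a = 0; a < nAlleles[l]; ++a) tot += M(k, a);
      for (int a = 0; a < nAlleles[l]; ++a) M(k, a) /= tot;
    }
    Pout[l] = M;
  }
  return List::create(_["Q"] = Qsum, _["P"] = Pout,
                      _["alpha"] = alpha_sum / n_rec,
                      _["lnl_trace"] = NumericVector(lnl_trace.begin(),
                                                     lnl_trace.end()));
}
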