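#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the two-population admixture model with independent
// allele frequencies (k = 2):
//   P[k][l] ~ Dirichlet(lambda),  Q_i ~ Dirichlet(alpha, alpha),
//   Z_{ilc} | Q_i ~ Categorical(Q_i),  X_{ilc} | Z ~ P[Z][l].
// alpha is shared across individuals and updated by random-walk Metropolis
// under a Uniform(0, alpha_max) prior. Missing allele copies (-1) contribute
// no likelihood term.
//
// A1, A2: n x L matrices of 0-based allele indices (-1 = missing).
// Returns the posterior mean Q over thinned post-burn-in sweeps, the mean of
// alpha, and a thinned log-likelihood trace.
// [[Rcpp::export]]
List admixture_gibbs_cpp(IntegerMatrix A1, IntegerMatrix A2,
                         IntegerVector nAlleles,
                         int burnin, int sweeps, int thin,
                         double lambda, double alpha_init, double alpha_max,
                         double alpha_prop_sd, bool update_alpha,
                         IntegerVector trace_samples) {
  const int n = A1.nrow(), L = A1.ncol();
  RNGScope scope;

  // allele frequencies per cluster/locus; ragged storage
  std::vector<std::vector<double> > P[2];
  for (int k = 0; k < 2; ++k) {
    P[k].resize(L);
    for (int l = 0; l < L; ++l) {
      P[k][l].assign(nAlleles[l], 1.0 / nAlleles[l]);
    }
  }
  NumericMatrix Q(n, 2);
  for (int i = 0; i < n; ++i) { Q(i, 0) = 0.5; Q(i, 1) = 0.5; }
  double alpha = alpha_init;

  std::vector<std::vector<double> > cntP[2];
  for (int k = 0; k < 2; ++k) {
    cntP[k].resize(L);
    for (int l = 0; l < L; ++l) cntP[k][l].assign(nAlleles[l], 0.0);
  }
  std::vector<double> cntQ0(n), cntQ1(n);

  NumericMatrix Qsum(n, 2);
  double alpha_sum = 0.0; int nsaved = 0, naccept = 0, nprop = 0;
  std::vector<double> ll_trace;
  const int ntr = trace_samples.size();
  const int nsave_max = sweeps / thin + 1;
  NumericMatrix qtrace(ntr > 0 ? nsave_max : 0, ntr);

  const int total = burnin + sweeps;
  for (int it = 0; it < total; ++it) {
    // reset counts
    for (int k = 0; k < 2; ++k)
      for (int l = 0; l < L; ++l)
        std::fill(cntP[k][l].begin(), cntP[k][l].end(), 0.0);
    std::fill(cntQ0.begin(), cntQ0.end(), 0.0);
    std::fill(cntQ1.begin(), cntQ1.end(), 0.0);

    double ll = 0.0;
    // update allele-origin indicators Z (marginalised into counts)
    for (int i = 0; i < n; ++i) {
      const double q0 = Q(i, 0), q1 = Q(i, 1);
      for (int l = 0; l < L; ++l) {
        for (int c = 0; c < 2; ++c) {
          const int a = (c == 0) ? A1(i, l) : A2(i, l);
          if (a < 0) continue;
          const double w0 = q0 * P[0][l][a];
          const double w1 = q1 * P[1][l][a];
          ll += std::log(w0 + w1);
          if (unif_rand() * (w0 + w1) < w0) {
            cntP[0][l][a] += 1.0; cntQ0[i] += 1.0;
          } else {
            cntP[1][l][a] += 1.0; cntQ1[i] += 1.0;
          }
        }
      }
    }

    // update cluster allele frequencies
    for (int k = 0; k < 2; ++k)
      for (int l = 0; l < L; ++l) {
        double s = 0.0;
        for (int a = 0; a < nAlleles[l]; ++a) {
          double g = R::rgamma(lambda + cntP[k][l][a], 1.0);
          if (g < 1e-300) g = 1e-300;
          P[k][l][a] = g; s += g;
        }
        for (int a = 0; a < nAlleles[l]; ++a) P[k][l][a] /= s;
      }

    // update admixture proportions
    double sumlogq = 0.0;
    for (int i = 0; i < n; ++i) {
      double g0 = R::rgamma(alpha + cntQ0[i], 1.0);
      double g1 = R::rgamma(alpha + cntQ1[i], 1.0);
      if (g0 < 1e-300) g0 = 1e-300;
      if (g1 < 1e-300) g1 = 1e-300;
      double q0 = g0 / (g0 + g1);
      if (q0 < 1e-12) q0 = 1e-12;
      if (q0 > 1.0 - 1e-12) q0 = 1.0 - 1e-12;
      Q(i, 0) = q0; Q(i, 1) = 1.0 - q0;
      sumlogq += std::log(Q(i, 0)) + std::log(Q(i, 1));
    }

    // update alpha (random-walk Metropolis, Uniform(0, alpha_max) prior)
    if (update_alpha) {
      ++nprop;
      const double prop = alpha + norm_rand() * alpha_prop_sd;
      if (prop > 0.0 && prop < alpha_max) {
        const double lp_cur = n * (lgamma(2.0 * alpha) - 2.0 * lgamma(alpha)) +
          (alpha - 1.0) * sumlogq;
        const double lp_new = n * (lgamma(2.0 * prop) - 2.0 * lgamma(prop)) +
          (prop - 1.0) * sumlogq;
        if (std::log(unif_rand()) < lp_new - lp_cur) {
          alpha = prop; ++naccept;
        }
      }
    }

    if (it >= burnin && ((it - burnin) % thin == 0)) {
      for (int i = 0; i < n; ++i) {
        Qsum(i, 0) += Q(i, 0); Qsum(i, 1) += Q(i, 1);
      }
      for (int t = 0; t < ntr; ++t) qtrace(nsaved, t) = Q(trace_samples[t], 0);
      alpha_sum += alpha; ++nsaved;
      ll_trace.push_back(ll);
    }
  }

  for (int i = 0; i < n; ++i) {
    Qsum(i, 0) /= nsaved; Qsum(i, 1) /= nsaved;
  }
  List out = List::create(_["Q"] = Qsum,
                      _["alpha"] = alpha_sum / nsaved,
                      _["loglik"] = NumericVector(ll_trace.begin(), ll_trace.end()),
                      _["accept_rate"] = nprop ? (double)naccept / nprop : NA_REAL);
  if (ntr > 0) {
    NumericMatrix qt(nsaved, ntr);
    for (int s2 = 0; s2 < nsaved; ++s2)
      for (int t = 0; t < ntr; ++t) qt(s2, t) = qtrace(s2, t);
    out["q_trace"] = qt;
  }
  return out;
}
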