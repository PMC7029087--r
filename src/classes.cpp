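#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the six genotype-frequency classes (parentals, F1, F2
// and backcrosses). Model:
//   pi ~ Dirichlet(1,...,1) over classes,
//   pool frequencies pF[l], pO[l] ~ Dirichlet(1/A_l)  ("Jeffreys-like"),
//   class z_i ~ Categorical(pi),
//   per-locus ancestry s_il in {FF, FO, OO} with P(s | z) = G[z],
//   genotype likelihood given s:
//     FF: Hardy-Weinberg product under pF;  OO: under pO;
//     FO: pF(a)pO(b) + pF(b)pO(a) for heterozygotes, pF(a)pO(a) otherwise.
// Missing loci are skipped. Class membership is reported as the
// Rao-Blackwellised average of the conditional class probabilities over
// thinned post-burn-in sweeps.
//
// G: 6 x 3 matrix of (p_FF, p_FO, p_OO) per class.
// initPool: per-individual initial pool hint (0 = F, 1 = O, -1 = none).
// [[Rcpp::export]]
List newhybrids_gibbs_cpp(IntegerMatrix A1, IntegerMatrix A2,
                          IntegerVector nAlleles, NumericMatrix G,
                          int burnin, int sweeps, int thin,
                          IntegerVector initPool) {
  const int n = A1.nrow(), L = A1.ncol(), K = G.nrow();
  RNGScope scope;

  std::vector<std::vector<double> > pF(L), pO(L), cF(L), cO(L);
  for (int l = 0; l < L; ++l) {
    pF[l].assign(nAlleles[l], 0.0); pO[l].assign(nAlleles[l], 0.0);
    cF[l].assign(nAlleles[l], 0.0); cO[l].assign(nAlleles[l], 0.0);
  }

  // initialise pool frequencies from hinted individuals (plus prior mass)
  for (int l = 0; l < L; ++l) {
    const double pri = 1.0 / nAlleles[l];
    for (int a = 0; a < nAlleles[l]; ++a) { cF[l][a] = pri; cO[l][a] = pri; }
    for (int i = 0; i < n; ++i) {
      if (initPool[i] < 0) continue;
      std::vector<double>& c = (initPool[i] == 0) ? cF[l] : cO[l];
      if (A1(i, l) >= 0) c[A1(i, l)] += 1.0;
      if (A2(i, l) >= 0) c[A2(i, l)] += 1.0;
    }
    double sF = 0.0, sO = 0.0;
    for (int a = 0; a < nAlleles[l]; ++a) { sF += cF[l][a]; sO += cO[l][a]; }
    for (int a = 0; a < nAlleles[l]; ++a) {
      pF[l][a] = cF[l][a] / sF; pO[l][a] = cO[l][a] / sO;
    }
  }

  std::vector<double> pi(K, 1.0 / K), cls_cnt(K);
  std::vector<int> z(n, 0);
  NumericMatrix probsum(n, K);
  std::vector<double> pi_sum(K, 0.0);
  int nsaved = 0;

  // per-individual locus-state likelihood buffer
  std::vector<double> l0(L), l1(L), l2(L);
  std::vector<double> lik(K), w(3);

  const int total = burnin + sweeps;
  for (int it = 0; it < total; ++it) {
    for (int l = 0; l < L; ++l) {
      const double pri = 1.0 / nAlleles[l];
      std::fill(cF[l].begin(), cF[l].end(), pri);
      std::fill(cO[l].begin(), cO[l].end(), pri);
    }
    std::fill(cls_cnt.begin(), cls_cnt.end(), 1.0); // Dirichlet(1) prior

    const bool save = (it >= burnin) && ((it - burnin) % thin == 0);

    for (int i = 0; i < n; ++i) {
      // per-locus ancestry-state likelihoods
      for (int l = 0; l < L; ++l) {
        const int a = A1(i, l), b = A2(i, l);
        if (a < 0) { l0[l] = -1.0; continue; }
        if (a == b) {
          l0[l] = pF[l][a] * pF[l][a];
          l1[l] = pF[l][a] * pO[l][a];
          l2[l] = pO[l][a] * pO[l][a];
        } else {
          l0[l] = 2.0 * pF[l][a] * pF[l][b];
          l1[l] = pF[l][a] * pO[l][b] + pF[l][b] * pO[l][a];
          l2[l] = 2.0 * pO[l][a] * pO[l][b];
        }
      }
      // class likelihoods (rescaled to avoid underflow)
      for (int g = 0; g < K; ++g) lik[g] = 1.0;
      for (int l = 0; l < L; ++l) {
        if (l0[l] < 0.0) continue;
        double mx = 0.0;
        for (int g = 0; g < K; ++g) {
          lik[g] *= G(g, 0) * l0[l] + G(g, 1) * l1[l] + G(g, 2) * l2[l];
          if (lik[g] > mx) mx = lik[g];
        }
        if (mx > 0.0 && mx < 1e-200)
          for (int g = 0; g < K; ++g) lik[g] *= 1e200;
      }
      double tot = 0.0;
      for (int g = 0; g < K; ++g) { lik[g] *= pi[g]; tot += lik[g]; }
      if (tot <= 0.0) { for (int g = 0; g < K; ++g) lik[g] = 1.0; tot = K; }
      // sample class
      double u = unif_rand() * tot, acc = 0.0;
      int zi = K - 1;
      for (int g = 0; g < K; ++g) { acc += lik[g]; if (u < acc) { zi = g; break; } }
      z[i] = zi; cls_cnt[zi] += 1.0;
      if (save)
        for (int g = 0; g < K; ++g) probsum(i, g) += lik[g] / tot;

      // sample per-locus ancestry and allele origins; tally counts
      for (int l = 0; l < L; ++l) {
        if (l0[l] < 0.0) continue;
        const int a = A1(i, l), b = A2(i, l);
        w[0] = G(zi, 0) * l0[l]; w[1] = G(zi, 1) * l1[l]; w[2] = G(zi, 2) * l2[l];
        const double ws = w[0] + w[1] + w[2];
        if (ws <= 0.0) continue;
        double v = unif_rand() * ws;
        int s = (v < w[0]) ? 0 : ((v < w[0] + w[1]) ? 1 : 2);
        if (s == 0) { cF[l][a] += 1.0; cF[l][b] += 1.0; }
        else if (s == 2) { cO[l][a] += 1.0; cO[l][b] += 1.0; }
        else {
          if (a == b) { cF[l][a] += 1.0; cO[l][a] += 1.0; }
          else {
            const double wa = pF[l][a] * pO[l][b];  // allele a from F pool
            const double wb = pF[l][b] * pO[l][a];
            if (unif_rand() * (wa + wb) < wa) { cF[l][a] += 1.0; cO[l][b] += 1.0; }
            else { cF[l][b] += 1.0; cO[l][a] += 1.0; }
          }
        }
      }
    }

    // update pool frequencies
    for (int l = 0; l < L; ++l) {
      double sF = 0.0, sO = 0.0;
      for (int a = 0; a < nAlleles[l]; ++a) {
        double gF = R::rgamma(cF[l][a], 1.0);
        double gO = R::rgamma(cO[l][a], 1.0);
        if (gF < 1e-300) gF = 1e-300;
        if (gO < 1e-300) gO = 1e-300;
        pF[l][a] = gF; pO[l][a] = gO; sF += gF; sO += gO;
      }
      for (int a = 0; a < nAlleles[l]; ++a) { pF[l][a] /= sF; pO[l][a] /= sO; }
    }
    // update mixing proportions
    double sp = 0.0;
    for (int g = 0; g < K; ++g) {
      double gg = R::rgamma(cls_cnt[g], 1.0);
      if (gg < 1e-300) gg = 1e-300;
      pi[g] = gg; sp += gg;
    }
    for (int g = 0; g < K; ++g) pi[g] /= sp;

    if (save) {
      for (int g = 0; g < K; ++g) pi_sum[g] += pi[g];
      ++nsaved;
    }
  }

  for (int i = 0; i < n; ++i)
    for (int g = 0; g < K; ++g) probsum(i, g) /= nsaved;
  NumericVector pim(K);
  for (int g = 0; g < K; ++g) pim[g] = pi_sum[g] / nsaved;
  return List::create(_["probs"] = probsum, _["pi"] = pim);
}
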