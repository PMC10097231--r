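#include <Rcpp.h>
using namespace Rcpp;

// Admixture-model Gibbs sampler for ploidy-6 dominant SSR data.
//
// codes: n x (L*6) integer matrix; columns l*6 .. l*6+5 are the six allele
// slots of locus l; 0 marks a missing slot, otherwise a 1-based allele code
// within the locus. Each non-missing slot is one allele copy.
//
// Model: slot copy z ~ Q[i,], allele | z=k ~ P[k, locus block]; priors
// Dirichlet(1) on every P block row and on every Q row (alpha fixed at 1).
// Uses R's RNG throughout so set.seed() in R gives bit-identical output.
// [[Rcpp::export]]
List gibbs_admixture(IntegerMatrix codes, IntegerVector n_alleles, int K,
                     int burn_in, int iterations) {
  const int n = codes.nrow();
  const int L = n_alleles.size();

  // flatten allele dimension: per-locus offsets into 0..T-1
  std::vector<int> offset(L, 0);
  int T = 0;
  for (int l = 0; l < L; ++l) { offset[l] = T; T += n_alleles[l]; }

  // collect non-missing slots
  std::vector<int> s_acc, s_loc, s_code;  // accession, locus, global allele code
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < L; ++l)
      for (int s = 0; s < 6; ++s) {
        int c = codes(i, l * 6 + s);
        if (c > 0) {
          s_acc.push_back(i);
          s_loc.push_back(l);
          s_code.push_back(offset[l] + c - 1);
        }
      }
  const int S = (int)s_acc.size();

  NumericMatrix Q(n, K), P(K, T);
  // init: uniform admixture, frequencies from the prior
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Q(i, k) = 1.0 / K;
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) {
      double tot = 0.0;
      for (int a = 0; a < n_alleles[l]; ++a) {
        double g = R::rgamma(1.0, 1.0);
        P(k, offset[l] + a) = g;
        tot += g;
      }
      for (int a = 0; a < n_alleles[l]; ++a) P(k, offset[l] + a) /= tot;
    }

  std::vector<int> cntQ(n * K), cntP(K * T);
  NumericMatrix Qsum(n, K), Psum(K, T);
  const int sweeps = burn_in + iterations;
  NumericVector loglik(sweeps);
  std::vector<double> w(K);

  for (int t = 0; t < sweeps; ++t) {
    std::fill(cntQ.begin(), cntQ.end(), 0);
    std::fill(cntP.begin(), cntP.end(), 0);
    double ll = 0.0;

    // sample slot origins given current (Q, P); accumulate likelihood
    for (int s = 0; s < S; ++s) {
      const int i = s_acc[s], g = s_code[s];
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { w[k] = Q(i, k) * P(k, g); tot += w[k]; }
      ll += std::log(tot);
      double u = unif_rand() * tot;
      int z = 0;
      double acc = w[0];
      while (z < K - 1 && u > acc) acc += w[++z];
      ++cntQ[i * K + z];
      ++cntP[z * T + g];
    }
    loglik[t] = ll;

    // Q | Z: Dirichlet(1 + counts) per accession
    for (int i = 0; i < n; ++i) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(1.0 + cntQ[i * K + k], 1.0);
        Q(i, k) = g;
        tot += g;
      }
      for (int k = 0; k < K; ++k) Q(i, k) /= tot;
    }

    // P | Z: Dirichlet(1 + counts) per cluster-locus block
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        double tot = 0.0;
        for (int a = 0; a < n_alleles[l]; ++a) {
          double g = R::rgamma(1.0 + cntP[k * T + offset[l] + a], 1.0);
          P(k, offset[l] + a) = g;
          tot += g;
        }
        for (int a = 0; a < n_alleles[l]; ++a) P(k, offset[l] + a) /= tot;
      }

    if (t >= burn_in) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int k = 0; k < K; ++k)
        for (int g = 0; g < T; ++g) Psum(k, g) += P(k, g);
    }
  }

  double lnP = 0.0;
  for (int t = burn_in; t < sweeps; ++t) lnP += loglik[t];
  lnP /= iterations;
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (int k = 0; k < K; ++k) tot += Qsum(i, k);
    for (int k = 0; k < K; ++k) Qsum(i, k) /= tot;
  }
  for (int k = 0; k < K; ++k)
    for (int g = 0; g < T; ++g) Psum(k, g) /= iterations;

  return List::create(_["Q"] = Qsum, _["P"] = Psum, _["lnP"] = lnP,
                      _["loglik"] = loglik);
}
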