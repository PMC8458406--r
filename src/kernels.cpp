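#include <Rcpp.h>
using namespace Rcpp;

// Per-sequence reweighting: w_m = 1 / |{m' : identity(m, m') >= thr}|,
// identity over all L columns, gap==gap counts as a match. O(M^2 L).
// [[Rcpp::export(name = ".cpp_sequence_weights")]]
NumericVector cpp_sequence_weights(IntegerMatrix aln, double identity_threshold) {
  const int M = aln.nrow(), L = aln.ncol();
  // column-major access pattern: copy to row-major buffer for cache locality
  std::vector<int> buf(static_cast<size_t>(M) * L);
  for (int m = 0; m < M; ++m)
    for (int l = 0; l < L; ++l)
      buf[static_cast<size_t>(m) * L + l] = aln(m, l);
  std::vector<int> nb(M, 1);  // each sequence is its own neighbour
  const double min_match = identity_threshold * L;
  for (int a = 0; a < M; ++a) {
    const int* ra = &buf[static_cast<size_t>(a) * L];
    for (int b = a + 1; b < M; ++b) {
      const int* rb = &buf[static_cast<size_t>(b) * L];
      int match = 0;
      for (int l = 0; l < L; ++l) match += (ra[l] == rb[l]);
      if (match >= min_match) { ++nb[a]; ++nb[b]; }
    }
  }
  NumericVector w(M);
  for (int m = 0; m < M; ++m) w[m] = 1.0 / nb[m];
  return w;
}

// Single-site heat-bath (Gibbs) sweeps over a Potts model.
// J is the (L*q) x (L*q) symmetric block coupling matrix (diagonal blocks 0),
// h is L x q. Uses R's RNG so results are reproducible under set.seed().
// Returns n samples (rows), each kept after `thin` full sweeps following
// `burn_in` initial sweeps, all from one chain started at `init`.
// [[Rcpp::export(name = ".cpp_gibbs_sample")]]
IntegerMatrix cpp_gibbs_sample(NumericMatrix J, NumericMatrix h,
                               IntegerVector init, int n, int burn_in,
                               int thin) {
  const int L = h.nrow(), q = h.ncol();
  std::vector<int> s(L);
  for (int i = 0; i < L; ++i) s[i] = init[i] - 1;  // 0-based states
  IntegerMatrix out(n, L);
  std::vector<double> logp(q), p(q);
  RNGScope scope;

  auto sweep = [&]() {
    for (int i = 0; i < L; ++i) {
      double mx = -1e300;
      for (int a = 0; a < q; ++a) {
        double e = h(i, a);
        const int row = i * q + a;
        for (int j = 0; j < L; ++j) {
          if (j == i) continue;
          e += J(row, j * q + s[j]);
        }
        logp[a] = e;
        if (e > mx) mx = e;
      }
      double z = 0.0;
      for (int a = 0; a < q; ++a) { p[a] = std::exp(logp[a] - mx); z += p[a]; }
      double u = unif_rand() * z, acc = 0.0;
      int pick = q - 1;
      for (int a = 0; a < q; ++a) { acc += p[a]; if (u <= acc) { pick = a; break; } }
      s[i] = pick;
    }
  };

  for (int t = 0; t < burn_in; ++t) sweep();
  for (int k = 0; k < n; ++k) {
    for (int t = 0; t < thin; ++t) sweep();
    for (int i = 0; i < L; ++i) out(k, i) = s[i] + 1;  // back to 1-based
  }
  return out;
}
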