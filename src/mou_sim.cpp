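#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of dx = J x dt + sqrt(dt) L xi, keeping every
// `sub`-th step after `burn` burn-in steps. Uses R's RNG so set.seed()
// reproducibility carries over.
// [[Rcpp::export]]
NumericMatrix mou_sim_core(const NumericMatrix& J, const NumericMatrix& L,
                           int n_keep, int sub, int burn, double sdt) {
  const int n = J.nrow();
  const double rdt = std::sqrt(sdt);
  std::vector<double> x(n, 0.0), dx(n), xi(n);
  NumericMatrix out(n, n_keep);
  const long total = (long)burn + (long)n_keep * sub;
  long kept = 0;
  for (long s = 1; s <= total; ++s) {
    for (int i = 0; i < n; ++i) xi[i] = R::norm_rand();
    for (int i = 0; i < n; ++i) {
      double drift = 0.0, noise = 0.0;
      for (int j = 0; j < n; ++j) {
        drift += J(i, j) * x[j];
        noise += L(i, j) * xi[j];
      }
      dx[i] = drift * sdt + noise * rdt;
    }
    for (int i = 0; i < n; ++i) x[i] += dx[i];
    if (s > burn && (s - burn) % sub == 0) {
      for (int i = 0; i < n; ++i) out(i, kept) = x[i];
      if (++kept == n_keep) break;
    }
  }
  return out;
}
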