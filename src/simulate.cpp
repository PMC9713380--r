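#include <Rcpp.h>
#include <random>
#include <vector>
#include <cstdint>
#include <cmath>

// Counter-based seeding: replicate streams must be reproducible in
// isolation (any subset of a simulation grid re-runs bit-identically), so
// each simulation derives its own 64-bit seed from (user seed, combination
// index, replicate index) through splitmix64 mixing rather than consuming
// a shared R-level RNG stream.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

static inline uint64_t mix_seed(double seed, double stream1, double stream2) {
  uint64_t u = splitmix64((uint64_t)(int64_t)seed);
  u = splitmix64(u ^ splitmix64((uint64_t)(int64_t)stream1));
  u = splitmix64(u ^ splitmix64(0x5851f42d4c957f2dULL ^ (uint64_t)(int64_t)stream2));
  return u;
}

// Draw one discovery/replication z-score pair per variant under the
// generative model: lambda ~ N(0, sg^2), delta_i ~ N(0, sc_i^2),
// z1 ~ N(sqrt(N1) (lambda + delta1), 1), z2 ~ N(sqrt(N2) (lambda + delta2), 1).
// When keep_all is false only variants with |z1| > z_star are retained
// (plus the non-significant count), which keeps memory flat across large
// simulation grids.
// [[Rcpp::export(name = ".sim_pair_cpp")]]
Rcpp::List sim_pair_cpp(double n_variants, double n1, double n2,
                        double sigma_g, double sigma_c1, double sigma_c2,
                        double z_star, bool keep_all,
                        double seed, double stream1, double stream2) {
  const R_xlen_t n = (R_xlen_t)n_variants;
  const double sqn1 = std::sqrt(n1), sqn2 = std::sqrt(n2);

  std::mt19937_64 rng(mix_seed(seed, stream1, stream2));
  std::normal_distribution<double> norm(0.0, 1.0);

  Rcpp::NumericVector z1_all, z2_all;
  Rcpp::LogicalVector sig_all;
  std::vector<double> z1_sig, z2_sig;
  std::vector<int> idx_sig;
  if (keep_all) {
    z1_all = Rcpp::NumericVector(n);
    z2_all = Rcpp::NumericVector(n);
    sig_all = Rcpp::LogicalVector(n);
  }

  double s_lam = 0, ss_lam = 0, s_d1 = 0, ss_d1 = 0, s_d2 = 0, ss_d2 = 0;
  // sufficient statistics of the zero-mean bivariate Gaussian likelihood,
  // over all variants and over the discovery-significant subset
  double a11 = 0, a22 = 0, a12 = 0, g11 = 0, g22 = 0, g12 = 0;
  R_xlen_t n_sig = 0;

  for (R_xlen_t k = 0; k < n; ++k) {
    const double lam = sigma_g  * norm(rng);
    const double d1  = sigma_c1 * norm(rng);
    const double d2  = sigma_c2 * norm(rng);
    const double z1  = sqn1 * (lam + d1) + norm(rng);
    const double z2  = sqn2 * (lam + d2) + norm(rng);
    s_lam += lam; ss_lam += lam * lam;
    s_d1  += d1;  ss_d1  += d1 * d1;
    s_d2  += d2;  ss_d2  += d2 * d2;
    a11 += z1 * z1; a22 += z2 * z2; a12 += z1 * z2;
    const bool sig = std::fabs(z1) > z_star;
    if (sig) {
      ++n_sig;
      g11 += z1 * z1; g22 += z2 * z2; g12 += z1 * z2;
    }
    if (keep_all) {
      z1_all[k] = z1; z2_all[k] = z2; sig_all[k] = sig;
    } else if (sig) {
      z1_sig.push_back(z1); z2_sig.push_back(z2);
      idx_sig.push_back((int)(k + 1));
    }
  }

  const double dn = (double)n;
  Rcpp::List lat = Rcpp::List::create(
    Rcpp::Named("mean_lambda") = s_lam / dn,
    Rcpp::Named("var_lambda")  = ss_lam / dn - (s_lam / dn) * (s_lam / dn),
    Rcpp::Named("mean_delta1") = s_d1 / dn,
    Rcpp::Named("var_delta1")  = ss_d1 / dn - (s_d1 / dn) * (s_d1 / dn),
    Rcpp::Named("mean_delta2") = s_d2 / dn,
    Rcpp::Named("var_delta2")  = ss_d2 / dn - (s_d2 / dn) * (s_d2 / dn));

  Rcpp::List suff = Rcpp::List::create(
    Rcpp::Named("n") = dn,
    Rcpp::Named("s11_all") = a11, Rcpp::Named("s22_all") = a22,
    Rcpp::Named("s12_all") = a12,
    Rcpp::Named("s11_sig") = g11, Rcpp::Named("s22_sig") = g22,
    Rcpp::Named("s12_sig") = g12);

  if (keep_all) {
    return Rcpp::List::create(
      Rcpp::Named("z1") = z1_all,
      Rcpp::Named("z2") = z2_all,
      Rcpp::Named("significant") = sig_all,
      Rcpp::Named("index") = R_NilValue,
      Rcpp::Named("n_significant") = (double)n_sig,
      Rcpp::Named("suff") = suff,
      Rcpp::Named("latent") = lat);
  }
  return Rcpp::List::create(
    Rcpp::Named("z1") = Rcpp::NumericVector(z1_sig.begin(), z1_sig.end()),
    Rcpp::Named("z2") = Rcpp::NumericVector(z2_sig.begin(), z2_sig.end()),
    Rcpp::Named("significant") = R_NilValue,
    Rcpp::Named("index") = Rcpp::IntegerVector(idx_sig.begin(), idx_sig.end()),
    Rcpp::Named("n_significant") = (double)n_sig,
    Rcpp::Named("suff") = suff,
    Rcpp::Named("latent") = lat);
}
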