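#include <Rcpp.h>
using namespace Rcpp;

// Mixture-of-von-Mises machinery shared by the fitting, attribution and
// permutation code. Angles arrive here already wrapped to radians; densities
// are per DEGREE so log-likelihoods line up with the package's public
// degree-based convention (Jacobian pi/180 applied once, below).

static const double LOG_DEG_JACOBIAN = std::log(M_PI / 180.0);
static const double UNIFORM_DENS = 1.0 / 360.0;
static const double KAPPA_MAX = 200.0;

// log I0(kappa), exponentially scaled Bessel keeps kappa up to the guard safe
static inline double log_bessel_i0(double kappa) {
  return std::log(R::bessel_i(kappa, 0.0, 2.0)) + kappa;
}

// mean resultant length of a von Mises with concentration kappa: A1 = I1/I0
static inline double A1(double kappa) {
  if (kappa <= 0.0) return 0.0;
  return R::bessel_i(kappa, 1.0, 2.0) / R::bessel_i(kappa, 0.0, 2.0);
}

// Invert A1: kappa such that I1(kappa)/I0(kappa) = r.
// Fisher's rational approximation, then Newton steps; clamped to [0, KAPPA_MAX].
static double a1_inv(double r) {
  if (r <= 0.0) return 0.0;
  if (r >= 1.0) return KAPPA_MAX;
  double k;
  if (r < 0.53) {
    k = 2.0 * r + r * r * r + 5.0 * r * r * r * r * r / 6.0;
  } else if (r < 0.85) {
    k = -0.4 + 1.39 * r + 0.43 / (1.0 - r);
  } else {
    k = 1.0 / (r * r * r - 4.0 * r * r + 3.0 * r);
  }
  if (k > KAPPA_MAX) return KAPPA_MAX;
  for (int i = 0; i < 5; ++i) {
    double a = A1(k);
    // d/dk A1 = 1 - A1^2 - A1/k
    double da = 1.0 - a * a - (k > 0 ? a / k : 0.5);
    if (da <= 1e-12) break;
    double step = (a - r) / da;
    k -= step;
    if (k <= 0.0) { k = 1e-8; }
    if (k >= KAPPA_MAX) { k = KAPPA_MAX; break; }
    if (std::fabs(step) < 1e-10) break;
  }
  return k;
}

// Negative log-likelihood of the (target [, schema], uniform) mixture.
// err_target / err_schema: response minus component centre, radians in [-pi, pi).
// [[Rcpp::export]]
double mixture_nll_cpp(NumericVector err_target, NumericVector err_schema,
                       double p_guess, double p_schema, double kappa,
                       bool use_schema) {
  int n = err_target.size();
  double p_target = 1.0 - p_guess - p_schema;
  if (p_target < -1e-12 || p_guess < -1e-12 || p_schema < -1e-12 ||
      kappa < 0.0 || kappa > KAPPA_MAX + 1e-9)
    return R_PosInf;
  double log_norm = -std::log(2.0 * M_PI) - log_bessel_i0(kappa) + LOG_DEG_JACOBIAN;
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    double mix = p_target * std::exp(kappa * std::cos(err_target[i]) + log_norm)
               + p_guess * UNIFORM_DENS;
    if (use_schema)
      mix += p_schema * std::exp(kappa * std::cos(err_schema[i]) + log_norm);
    if (mix <= 0.0) return R_PosInf;
    nll -= std::log(mix);
  }
  return nll;
}

// Per-trial log mixture density (same parameterization), for attribution code.
// [[Rcpp::export]]
NumericVector mixture_loglik_cpp(NumericVector err_target, NumericVector err_schema,
                                 double p_guess, double p_schema, double kappa,
                                 bool use_schema) {
  int n = err_target.size();
  double p_target = 1.0 - p_guess - p_schema;
  double log_norm = -std::log(2.0 * M_PI) - log_bessel_i0(kappa) + LOG_DEG_JACOBIAN;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double mix = p_target * std::exp(kappa * std::cos(err_target[i]) + log_norm)
               + p_guess * UNIFORM_DENS;
    if (use_schema)
      mix += p_schema * std::exp(kappa * std::cos(err_schema[i]) + log_norm);
    out[i] = std::log(mix);
  }
  return out;
}

// EM for the same mixture. Monotone in the log-likelihood; kappa M-step solves
// A1(kappa) = weighted resultant of the von Mises components.
// Returns fitted weights, kappa, logL, iteration count and the mean posterior
// responsibility of each component (equal to the weights at an interior optimum).
// [[Rcpp::export]]
List mixture_em_cpp(NumericVector err_target, NumericVector err_schema,
                    bool use_schema,
                    double p_guess, double p_schema, double kappa,
                    int max_iter, double tol) {
  int n = err_target.size();
  std::vector<double> cos_t(n), cos_s(use_schema ? n : 0);
  for (int i = 0; i < n; ++i) cos_t[i] = std::cos(err_target[i]);
  if (use_schema) for (int i = 0; i < n; ++i) cos_s[i] = std::cos(err_schema[i]);

  if (kappa < 1e-6) kappa = 1e-6;
  if (kappa > KAPPA_MAX) kappa = KAPPA_MAX;
  double ll_old = R_NegInf, ll = R_NegInf;
  double mean_gt = 0.0, mean_gs = 0.0, mean_gg = 0.0;
  int iter = 0;
  bool converged = false;

  for (iter = 0; iter < max_iter; ++iter) {
    double p_target = 1.0 - p_guess - p_schema;
    double log_norm = -std::log(2.0 * M_PI) - log_bessel_i0(kappa) + LOG_DEG_JACOBIAN;
    double sum_gt = 0.0, sum_gs = 0.0, sum_gg = 0.0;
    double resultant = 0.0, resultant_w = 0.0;
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double ft = std::exp(kappa * cos_t[i] + log_norm);
      double wt = p_target * ft;
      double wg = p_guess * UNIFORM_DENS;
      double ws = 0.0, fs = 0.0;
      if (use_schema) {
        fs = std::exp(kappa * cos_s[i] + log_norm);
        ws = p_schema * fs;
      }
      double tot = wt + wg + ws;
      if (tot <= 0.0) tot = 1e-300;
      ll += std::log(tot);
      double gt = wt / tot, gs = ws / tot, gg = wg / tot;
      sum_gt += gt; sum_gs += gs; sum_gg += gg;
      resultant += gt * cos_t[i];
      resultant_w += gt;
      if (use_schema) { resultant += gs * cos_s[i]; resultant_w += gs; }
    }
    mean_gt = sum_gt / n; mean_gs = sum_gs / n; mean_gg = sum_gg / n;
    if (std::isfinite(ll_old) && ll - ll_old < tol && ll >= ll_old - 1e-9) {
      converged = true;
      break;
    }
    ll_old = ll;
    // M-step
    p_guess = mean_gg;
    p_schema = use_schema ? mean_gs : 0.0;
    double r = (resultant_w > 1e-12) ? (resultant / resultant_w) : 0.0;
    if (r < 0.0) r = 0.0;
    kappa = a1_inv(r);
    if (kappa < 1e-8) kappa = 1e-8;
  }

  return List::create(
    _["p_guess"] = p_guess,
    _["p_schema"] = use_schema ? p_schema : 0.0,
    _["kappa"] = kappa,
    _["logL"] = ll,
    _["iterations"] = iter,
    _["converged"] = converged,
    _["mean_resp_target"] = mean_gt,
    _["mean_resp_schema"] = mean_gs,
    _["mean_resp_guess"] = mean_gg);
}
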