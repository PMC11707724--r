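#include <Rcpp.h>
using namespace Rcpp;

// Analytic membrane-like PMF kinds shared with the R evaluator
// (R/synthetic.R must stay formula-identical):
//   0 uniform              W = 0
//   1 neutral_well         W = -D / (1 + exp((|z| - z_m)/w))
//   2 charged_interfacial  W = -A exp(-(|z|-z0)^2/(2 s^2)) + B exp(-z^2/(2 sb^2))
//   3 custom_table         linear interpolation of (tz, tw)
static double pmf_eval(int kind, const NumericVector& p,
                       const NumericVector& tz, const NumericVector& tw,
                       double z) {
  switch (kind) {
  case 0:
    return 0.0;
  case 1: {
    double D = p[0], zm = p[1], w = p[2];
    return -D / (1.0 + std::exp((std::fabs(z) - zm) / w));
  }
  case 2: {
    double A = p[0], z0 = p[1], s = p[2], B = p[3], sb = p[4];
    double dz = std::fabs(z) - z0;
    return -A * std::exp(-dz * dz / (2.0 * s * s))
           + B * std::exp(-z * z / (2.0 * sb * sb));
  }
  case 3: {
    int n = tz.size();
    if (z < tz[0] || z > tz[n - 1])
      stop("custom_table PMF queried at z = %f outside [%f, %f]",
           z, tz[0], tz[n - 1]);
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (tz[mid] <= z) lo = mid; else hi = mid;
    }
    double f = (z - tz[lo]) / (tz[hi] - tz[lo]);
    return tw[lo] + f * (tw[hi] - tw[lo]);
  }
  default:
    stop("unknown PMF kind %d", kind);
  }
  return 0.0; // unreachable
}

// [[Rcpp::export]]
double cpp_pmf_eval(int kind, NumericVector params, NumericVector table_z,
                    NumericVector table_w, double z) {
  return pmf_eval(kind, params, table_z, table_w, z);
}

// Overdamped Langevin trajectory under PMF + harmonic window bias.
//   z' = z - (Dc dt / kBT) d(W+U)/dz + sqrt(2 Dc dt) xi
// Total-energy gradient by central difference (h = 1e-4 A). Reflecting
// walls at [reflect_lo, reflect_hi]; a position more than 10 A outside
// [range_lo, range_hi] aborts (diverged integration, dt too large).
// Uses R's RNG, so set.seed() upstream makes runs bit-reproducible.
// [[Rcpp::export]]
NumericVector cpp_langevin(int kind, NumericVector params,
                           NumericVector table_z, NumericVector table_w,
                           double center, double k_par, double half_factor,
                           double kBT, double diffusion, double dt,
                           int n_steps, int stride, double z_init,
                           double reflect_lo, double reflect_hi,
                           double range_lo, double range_hi) {
  const double h = 1e-4;
  const double mob = diffusion * dt / kBT;
  const double noise = std::sqrt(2.0 * diffusion * dt);
  const int n_out = n_steps / stride;
  NumericVector out(n_out);
  RNGScope scope;

  double z = z_init;
  int iout = 0;
  for (int step = 1; step <= n_steps; ++step) {
    double zp = z + h, zm = z - h;
    double ep = pmf_eval(kind, params, table_z, table_w, zp)
                + half_factor * k_par * (zp - center) * (zp - center);
    double em = pmf_eval(kind, params, table_z, table_w, zm)
                + half_factor * k_par * (zm - center) * (zm - center);
    double grad = (ep - em) / (2.0 * h);
    z += -mob * grad + noise * norm_rand();
    // reflecting walls (repeat in case a huge kick crossed both; it cannot)
    if (z < reflect_lo) z = 2.0 * reflect_lo - z;
    if (z > reflect_hi) z = 2.0 * reflect_hi - z;
    if (z < range_lo - 10.0 || z > range_hi + 10.0)
      stop("trajectory diverged at step %d (z = %f); reduce dt", step, z);
    if (step % stride == 0 && iout < n_out) out[iout++] = z;
  }
  return out;
}
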