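#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hill / step production rate of the target given y regulator molecules.
// sign > 0: activator, sign < 0: repressor. H non-finite selects the sharp
// switch with the tie y == K counting as active. Evaluated in log space so
// large H never overflows.
static inline double reg_rate(int sign, double alpha, double K, double H, int y) {
  if (K <= 0.0) return sign > 0 ? alpha : (y == 0 ? alpha : 0.0);
  if (!R_finite(H)) {
    if (sign > 0) return (double)y >= K ? alpha : 0.0;
    return (double)y <= K ? alpha : 0.0;
  }
  if (y == 0) return sign > 0 ? 0.0 : alpha;
  double e = H * (std::log((double)y) - std::log(K));
  if (sign > 0) e = -e;
  // rate = alpha / (1 + exp(e))
  if (e > 700.0) return 0.0;
  return alpha / (1.0 + std::exp(e));
}

// geometric burst size on {1, 2, ...} with mean b (b >= 1)
static inline int burst_size(double b) {
  if (b <= 1.0) return 1;
  return 1 + (int)R::rgeom(1.0 / b);
}

// One ensemble of Gillespie realizations of the two-species scheme:
// regulator production (rate k, geometric burst of mean burst_b), regulator
// degradation (rate mu * y), target production (rate f(y), +1). The target
// level x_star is recorded as the first-passage time; in absorbing mode the
// run stops there. Optional single division event per run at a truncated
// Gaussian time: binomial partitioning of both species and scaling of K by
// vol_factor. Runs draw from R's global RNG in sequence, so results are
// reproducible bit for bit given the seed set on the R side.
//
// t_query: one observation time per run (or length 0); the state x(t) at
// that time is returned (cross-sectional sampling). t_grid: shared grid on
// which ensemble mean trajectories of y and x are accumulated.
// [[Rcpp::export]]
List ssa_ensemble_cpp(double k, double mu, double n0, bool n0_poisson,
                      int sign, double alpha, double K, double H,
                      int x_star, double burst_b,
                      bool has_div, double td_mean, double td_sd, double vol_factor,
                      double t_max, bool absorb,
                      NumericVector t_query, NumericVector t_grid,
                      int n_runs) {
  const int G = t_grid.size();
  const bool do_query = t_query.size() > 0;
  NumericVector fpt(n_runs, NA_REAL);
  IntegerVector x_at(do_query ? n_runs : 0);
  IntegerVector y_at(do_query ? n_runs : 0);
  NumericVector sum_y(G), sum_x(G);

  for (int run = 0; run < n_runs; ++run) {
    int y = n0_poisson ? (int)R::rpois(n0) : (int)std::lround(n0);
    int x = 0;
    double t = 0.0, Kcur = K;
    bool crossed = false, divided = !has_div;
    double td = R_PosInf;
    if (has_div) {
      do { td = R::rnorm(td_mean, td_sd); } while (td <= 0.0);
      // in absorbing mode the run ends at crossing, so division applies
      // only to runs that have not yet crossed, as required
    }
    double tq = do_query ? t_query[run] : -1.0;
    int gi = 0;

    for (;;) {
      double fy = reg_rate(sign, alpha, Kcur, H, y);
      double total = k + mu * (double)y + fy;
      double t_next = (total > 0.0) ? t + R::exp_rand() / total : R_PosInf;

      // deterministic division event interleaved with reactions
      if (!divided && td < t_next && td <= t_max) {
        // flush grid / query up to the division time
        while (gi < G && t_grid[gi] < td) { sum_y[gi] += y; sum_x[gi] += x; ++gi; }
        if (do_query && tq >= t && tq < td) { x_at[run] = x; y_at[run] = y; tq = -1.0; }
        t = td;
        y = (int)R::rbinom((double)y, 0.5);
        x = (int)R::rbinom((double)x, 0.5);
        Kcur *= vol_factor;
        divided = true;
        continue;
      }

      double t_stop = t_next < t_max ? t_next : t_max;
      while (gi < G && t_grid[gi] < t_stop) { sum_y[gi] += y; sum_x[gi] += x; ++gi; }
      if (do_query && tq >= t && tq < t_stop) { x_at[run] = x; y_at[run] = y; tq = -1.0; }

      if (t_next >= t_max) { t = t_max; break; }
      t = t_next;

      double u = unif_rand() * total;
      if (u < k) {
        y += burst_size(burst_b);
      } else if (u < k + mu * (double)y) {
        y -= 1;
      } else {
        x += 1;
        if (!crossed && x >= x_star) {
          crossed = true;
          fpt[run] = t;
          if (absorb) break;
        }
      }
    }

    // states persist beyond the last event up to t_max (non-absorbing runs)
    while (gi < G && t_grid[gi] <= t_max) { sum_y[gi] += y; sum_x[gi] += x; ++gi; }
    if (do_query && tq >= 0.0 && tq >= t) { x_at[run] = x; y_at[run] = y; }
  }

  List out = List::create(_["fpt"] = fpt);
  if (do_query) { out["x_at"] = x_at; out["y_at"] = y_at; }
  if (G > 0) {
    out["mean_y"] = (NumericVector)(sum_y / (double)n_runs);
    out["mean_x"] = (NumericVector)(sum_x / (double)n_runs);
  }
  return out;
}
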