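#include <Rcpp.h>
using namespace Rcpp;

// Two-stage clonal expansion (TSCE) survival with piecewise-constant
// parameters. For a fixed evaluation age t the probability that no malignant
// cell has arisen is S(t) = exp(-Lambda(t)) with
//   Lambda(t) = int_0^t nu(s) * (1 - w(s; t)) ds,
// where w(s; t) is the probability that a cell initiated at age s has no
// malignant descendant by age t. Backwards in s, w solves the Riccati ODE
//   dw/ds = -( a w^2 + b - (a+b+m) w ),   w(t) = 1,
// with a = cell division rate, b = cell death rate, m = malignant
// transformation rate (all per year). On an interval where (a,b,m) are
// constant the ODE has the closed form used below, with roots r1 <= r2 of
//   a z^2 - (a+b+m) z + b = 0,
// so Lambda accumulates segment by segment, walking from t back to age 0.

struct SegView {
  const double *from, *to, *nu, *a, *b, *m;
  int n;
};

// cumulative hazard at age t for one person's segment set
static double cumhaz_one(double t, const SegView &sg) {
  double w = 1.0, lam = 0.0;
  for (int i = sg.n - 1; i >= 0; --i) {
    double lo = sg.from[i], hi = sg.to[i];
    if (hi > t) hi = t;
    if (hi <= lo) continue;
    double T = hi - lo;
    double a = sg.a[i], b = sg.b[i], m = sg.m[i], nu = sg.nu[i];
    double s = a + b + m;
    double disc = std::sqrt(s * s - 4.0 * a * b);
    double r1 = (s - disc) / (2.0 * a);
    double r2 = (s + disc) / (2.0 * a);
    double c = disc; // a * (r2 - r1)
    double A = r2 - w, B = r1 - w;
    double E = std::exp(-c * T);
    double D = A - B * E;
    lam += nu * ((1.0 - r1) * T + std::log(D / (r2 - r1)) / a);
    w = r2 - (r2 - r1) * A / D;
  }
  return lam;
}

// [[Rcpp::export(name = ".tsce_cumhaz_cpp")]]
NumericVector tsce_cumhaz_cpp(NumericVector t, NumericVector seg_from,
                              NumericVector seg_to, NumericVector seg_nu,
                              NumericVector seg_a, NumericVector seg_b,
                              NumericVector seg_m) {
  SegView sg = {seg_from.begin(), seg_to.begin(), seg_nu.begin(),
                seg_a.begin(),   seg_b.begin(),  seg_m.begin(),
                (int)seg_from.size()};
  int n = t.size();
  NumericVector out(n);
  for (int j = 0; j < n; ++j) out[j] = cumhaz_one(t[j], sg);
  return out;
}

// Inverse-CDF onset sampling for a whole cohort. Persons are stored as
// flattened segment arrays with offsets off (length n_persons + 1, 0-based).
// For person p the target cumulative hazard is E[p] = -log(U[p]); the onset
// age solves Lambda(age) = E[p], located by walking an age grid and
// interpolating linearly between bracketing grid points. Returns +Inf when
// the cumulative hazard at the last grid age never reaches the target
// (no onset within the modelled lifespan).
// [[Rcpp::export(name = ".tsce_onset_cpp")]]
NumericVector tsce_onset_cpp(NumericVector grid, IntegerVector off,
                             NumericVector seg_from, NumericVector seg_to,
                             NumericVector seg_nu, NumericVector seg_a,
                             NumericVector seg_b, NumericVector seg_m,
                             NumericVector target) {
  int np = off.size() - 1;
  int ng = grid.size();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    int s0 = off[p];
    SegView sg = {seg_from.begin() + s0, seg_to.begin() + s0,
                  seg_nu.begin() + s0,  seg_a.begin() + s0,
                  seg_b.begin() + s0,   seg_m.begin() + s0,
                  off[p + 1] - s0};
    double E = target[p];
    double prev_t = grid[0], prev_l = cumhaz_one(grid[0], sg);
    double age = R_PosInf;
    if (prev_l >= E && E > 0) age = grid[0];
    else {
      for (int j = 1; j < ng; ++j) {
        double tt = grid[j];
        double ll = cumhaz_one(tt, sg);
        if (ll >= E) {
          double dl = ll - prev_l;
          age = (dl > 0) ? prev_t + (E - prev_l) / dl * (tt - prev_t) : tt;
          break;
        }
        prev_t = tt; prev_l = ll;
      }
    }
    out[p] = age;
  }
  return out;
}
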