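// Core numerics: fixed-step RK4 for the prey-predator system, the squared
// relative error objective, and the UNDX/MGG real-coded genetic algorithm.
// All randomness goes through R's RNG so set.seed() makes runs reproducible.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

struct LLVPar {
  double a, b, e, c, d;
};

static inline void llv_deriv(const LLVPar& p, double x, double y,
                             double& dx, double& dy) {
  dx = x * (p.a - p.b * x - p.e * y);
  dy = y * (p.c * x - p.d);
}

static inline void rk4_advance(const LLVPar& p, double h, double& x, double& y) {
  double k1x, k1y, k2x, k2y, k3x, k3y, k4x, k4y;
  llv_deriv(p, x, y, k1x, k1y);
  llv_deriv(p, x + 0.5 * h * k1x, y + 0.5 * h * k1y, k2x, k2y);
  llv_deriv(p, x + 0.5 * h * k2x, y + 0.5 * h * k2y, k3x, k3y);
  llv_deriv(p, x + h * k3x, y + h * k3y, k4x, k4y);
  x += h / 6.0 * (k1x + 2.0 * k2x + 2.0 * k3x + k4x);
  y += h / 6.0 * (k1y + 2.0 * k2y + 2.0 * k3y + k4y);
}

// a state is unusable once x leaves (0, inf) or y leaves [0, inf)
static inline bool state_bad(double x, double y) {
  return !R_finite(x) || !R_finite(y) || x <= 0.0 || y < 0.0;
}

// Integrate on a uniform grid (final step shortened to land on t_end).
// Fills times/xs/ys with the valid prefix; returns false on failure.
static bool integrate_core(const LLVPar& p, double x0, double y0,
                           double t0, double t1, double h,
                           std::vector<double>& times,
                           std::vector<double>& xs,
                           std::vector<double>& ys,
                           double& t_fail) {
  const double span = t1 - t0;
  long m = (long)std::floor(span / h + 1e-9);
  double tail = span - (double)m * h;
  bool partial = tail > 1e-9 * std::max(1.0, std::fabs(t1));
  long n = m + 1 + (partial ? 1 : 0);

  times.clear(); xs.clear(); ys.clear();
  times.reserve(n); xs.reserve(n); ys.reserve(n);

  double x = x0, y = y0;
  if (state_bad(x, y)) { t_fail = t0; return false; }
  times.push_back(t0); xs.push_back(x); ys.push_back(y);

  for (long i = 1; i <= m; ++i) {
    rk4_advance(p, h, x, y);
    double t = (i == m && !partial) ? t1 : t0 + (double)i * h;
    if (state_bad(x, y)) { t_fail = t; return false; }
    times.push_back(t); xs.push_back(x); ys.push_back(y);
  }
  if (partial) {
    rk4_advance(p, tail, x, y);
    if (state_bad(x, y)) { t_fail = t1; return false; }
    times.push_back(t1); xs.push_back(x); ys.push_back(y);
  }
  return true;
}

// params is always ordered (a, b, e, c, d, x0, y0)
static inline LLVPar par_from(const double* v) {
  LLVPar p; p.a = v[0]; p.b = v[1]; p.e = v[2]; p.c = v[3]; p.d = v[4];
  return p;
}

// [[Rcpp::export]]
List cpp_rk4(NumericVector params, double t_start, double t_end, double step) {
  if (params.size() != 7) stop("params must have length 7 (a,b,e,c,d,x0,y0)");
  if (!(t_end > t_start)) stop("t_end must exceed t_start");
  if (!(step > 0)) stop("step must be positive");
  LLVPar p = par_from(params.begin());
  std::vector<double> ts, xs, ys;
  double t_fail = NA_REAL;
  bool ok = integrate_core(p, params[5], params[6], t_start, t_end, step,
                           ts, xs, ys, t_fail);
  return List::create(_["times"] = wrap(ts), _["x"] = wrap(xs),
                      _["y"] = wrap(ys), _["step"] = step,
                      _["valid"] = ok, _["t_fail"] = t_fail);
}

// linear interpolation on a stored grid; exact hits return stored values
static double interp_one(const std::vector<double>& ts,
                         const std::vector<double>& vs, double t) {
  size_t n = ts.size();
  double tol = 1e-9 * std::max(1.0, std::fabs(ts[n - 1]));
  if (t < ts[0] - tol || t > ts[n - 1] + tol)
    stop("requested time %g outside trajectory range [%g, %g]",
         t, ts[0], ts[n - 1]);
  if (t <= ts[0]) return vs[0];
  if (t >= ts[n - 1]) return vs[n - 1];
  size_t hi = std::upper_bound(ts.begin(), ts.end(), t) - ts.begin();
  size_t lo = hi - 1;
  if (ts[lo] == t) return vs[lo];
  double w = (t - ts[lo]) / (ts[hi] - ts[lo]);
  return vs[lo] + w * (vs[hi] - vs[lo]);
}

// [[Rcpp::export]]
NumericVector cpp_sample(NumericVector times, NumericVector values,
                         NumericVector at) {
  std::vector<double> ts(times.begin(), times.end());
  std::vector<double> vs(values.begin(), values.end());
  NumericVector out(at.size());
  for (R_xlen_t i = 0; i < at.size(); ++i) out[i] = interp_one(ts, vs, at[i]);
  return out;
}

// Sum of squared relative errors of the model x-curve against observations,
// integrating from t = 0 to the last observation time. +Inf on any failure.
static double llv_loss(const double* full, const std::vector<double>& tobs,
                       const std::vector<double>& yobs, double step) {
  LLVPar p = par_from(full);
  std::vector<double> ts, xs, ys;
  double t_fail;
  double t1 = tobs.back();
  if (!integrate_core(p, full[5], full[6], 0.0, t1, step, ts, xs, ys, t_fail))
    return R_PosInf;
  double loss = 0.0;
  for (size_t i = 0; i < tobs.size(); ++i) {
    double pred = interp_one(ts, xs, tobs[i]);
    if (!R_finite(pred)) return R_PosInf;
    double r = (pred - yobs[i]) / yobs[i];
    loss += r * r;
  }
  if (!R_finite(loss)) return R_PosInf;
  return loss;
}

// [[Rcpp::export]]
double cpp_llv_loss(NumericVector full, NumericVector tobs, NumericVector yobs,
                    double step) {
  if (full.size() != 7) stop("full parameter vector must have length 7");
  std::vector<double> t(tobs.begin(), tobs.end());
  std::vector<double> y(yobs.begin(), yobs.end());
  return llv_loss(full.begin(), t, y, step);
}

// ---------------------------------------------------------------------------
// Objective abstraction for the GA: either the native model loss over a
// subset of (a,b,e,c,d,x0,y0), or an arbitrary R function of the natural-
// scale parameter vector returning a loss (lower is better).
struct Objective {
  bool is_r;
  Function rfun;
  std::vector<double> templ;   // full 7-vector with fixed entries
  std::vector<int> idx;        // 0-based slots of searched entries
  std::vector<double> tobs, yobs;
  double step;
  CharacterVector names;       // names of searched entries (for the R fun)

  Objective(List spec) : rfun(Environment::base_env()["identity"]) {
    std::string type = as<std::string>(spec["type"]);
    is_r = (type == "r");
    if (is_r) {
      rfun = as<Function>(spec["fun"]);
      names = as<CharacterVector>(spec["names"]);
    } else {
      templ = as<std::vector<double> >(spec["template"]);
      idx = as<std::vector<int> >(spec["idx"]);
      tobs = as<std::vector<double> >(spec["times"]);
      yobs = as<std::vector<double> >(spec["obs"]);
      step = as<double>(spec["step"]);
    }
  }

  double eval(const std::vector<double>& natural) {
    if (is_r) {
      NumericVector v = wrap(natural);
      v.attr("names") = names;
      double l = as<double>(rfun(v));
      return R_IsNA(l) ? R_PosInf : l;
    }
    std::vector<double> full = templ;
    for (size_t j = 0; j < idx.size(); ++j) full[idx[j]] = natural[j];
    return llv_loss(full.data(), tobs, yobs, step);
  }
};

static inline double descale1(double v, int logflag) {
  return logflag ? std::pow(10.0, v) : v;
}

static void descale(const std::vector<double>& scaled, const IntegerVector& logs,
                    std::vector<double>& natural) {
  natural.resize(scaled.size());
  for (size_t j = 0; j < scaled.size(); ++j)
    natural[j] = descale1(scaled[j], logs[j]);
}

// UNDX: child = midpoint + xi * d1 + D * (component of z orthogonal to d1),
// xi ~ N(0, sxi^2), z_i ~ N(0, (seta/sqrt(n))^2), D = distance of parent3
// from the line through parents 1 and 2 (from the midpoint when that line
// degenerates). Identical parents reproduce the common point exactly.
static void undx_child(const double* p1, const double* p2, const double* p3,
                       int n, double sxi, double seta, double* child) {
  std::vector<double> d1(n), z(n);
  double nd1sq = 0.0;
  for (int j = 0; j < n; ++j) {
    d1[j] = p2[j] - p1[j];
    nd1sq += d1[j] * d1[j];
  }
  double xi = norm_rand() * sxi;
  double sd_eta = seta / std::sqrt((double)n);
  for (int j = 0; j < n; ++j) z[j] = norm_rand() * sd_eta;

  // distance of p3 from the primary axis
  double D = 0.0;
  if (nd1sq > 0.0) {
    double dot = 0.0, sq3 = 0.0;
    for (int j = 0; j < n; ++j) {
      double w = p3[j] - p1[j];
      dot += w * d1[j];
      sq3 += w * w;
    }
    double proj2 = dot * dot / nd1sq;
    D = std::sqrt(std::max(0.0, sq3 - proj2));
    double zdot = 0.0;
    for (int j = 0; j < n; ++j) zdot += z[j] * d1[j];
    for (int j = 0; j < n; ++j) z[j] -= zdot / nd1sq * d1[j];
  } else {
    double sq = 0.0;
    for (int j = 0; j < n; ++j) {
      double w = p3[j] - 0.5 * (p1[j] + p2[j]);
      sq += w * w;
    }
    D = std::sqrt(sq);
  }
  for (int j = 0; j < n; ++j)
    child[j] = 0.5 * (p1[j] + p2[j]) + xi * d1[j] + D * z[j];
}

// [[Rcpp::export]]
NumericVector cpp_undx(NumericVector p1, NumericVector p2, NumericVector p3,
                       double sigma_xi, double sigma_eta) {
  int n = p1.size();
  if (p2.size() != n || p3.size() != n)
    stop("parent vectors must share one dimension");
  NumericVector child(n);
  undx_child(p1.begin(), p2.begin(), p3.begin(), n, sigma_xi, sigma_eta,
             child.begin());
  return child;
}

static inline double to_fitness(double loss) {
  if (!R_finite(loss)) return 0.0;         // failed evaluation
  if (loss <= 0.0) return R_PosInf;        // perfect fit outranks everything
  return 1.0 / loss;
}

// One MGG family event on the scaled population (modified in place).
static void family_step(NumericMatrix& pop, NumericVector& losses,
                        const NumericVector& lower, const NumericVector& upper,
                        const IntegerVector& logs, int nchildren,
                        double sxi, double seta, Objective& obj, long& evals) {
  int N = pop.nrow(), n = pop.ncol();
  int i1 = (int)(unif_rand() * N); if (i1 == N) i1 = N - 1;
  int i2 = (int)(unif_rand() * (N - 1)); if (i2 >= i1) ++i2;
  int i3 = (int)(unif_rand() * (N - 2));
  // map into {0..N-1} \ {i1, i2}
  int lo = std::min(i1, i2), hi = std::max(i1, i2);
  if (i3 >= lo) ++i3;
  if (i3 >= hi) ++i3;

  int fam = 2 + nchildren;
  std::vector<std::vector<double> > members(fam, std::vector<double>(n));
  std::vector<double> floss(fam);
  for (int j = 0; j < n; ++j) {
    members[0][j] = pop(i1, j);
    members[1][j] = pop(i2, j);
  }
  floss[0] = losses[i1];
  floss[1] = losses[i2];

  std::vector<double> p3(n), natural;
  for (int j = 0; j < n; ++j) p3[j] = pop(i3, j);
  for (int k = 0; k < nchildren; ++k) {
    std::vector<double>& ch = members[2 + k];
    undx_child(members[0].data(), members[1].data(), p3.data(), n, sxi, seta,
               ch.data());
    for (int j = 0; j < n; ++j)       // deterministic boundary repair
      ch[j] = std::min(std::max(ch[j], lower[j]), upper[j]);
    descale(ch, logs, natural);
    floss[2 + k] = obj.eval(natural);
    ++evals;
  }

  // slot (i): best of the family, ties to the lowest family index
  int best = 0;
  for (int k = 1; k < fam; ++k) if (floss[k] < floss[best]) best = k;

  // slot (ii): roulette over fitness (+ floor so the weights always sum > 0);
  // a perfect fit (infinite fitness) is taken directly, first index wins ties
  int pick = -1;
  for (int k = 0; k < fam; ++k)
    if (floss[k] <= 0.0 && R_finite(floss[k])) { pick = k; break; }
  if (pick < 0) {
    double total = 0.0;
    std::vector<double> w(fam);
    for (int k = 0; k < fam; ++k) {
      w[k] = to_fitness(floss[k]) + 1e-300;
      total += w[k];
    }
    double u = unif_rand() * total, acc = 0.0;
    pick = fam - 1;
    for (int k = 0; k < fam; ++k) {
      acc += w[k];
      if (u <= acc) { pick = k; break; }
    }
  }

  for (int j = 0; j < n; ++j) {
    pop(i1, j) = members[best][j];
    pop(i2, j) = members[pick][j];
  }
  losses[i1] = floss[best];
  losses[i2] = floss[pick];
}

// [[Rcpp::export]]
List cpp_mgg_step(NumericMatrix pop, NumericVector losses,
                  NumericVector lower, NumericVector upper,
                  IntegerVector logs, int nchildren,
                  double sigma_xi, double sigma_eta, List objspec) {
  if (pop.nrow() < 3) stop("population must hold at least 3 individuals");
  if (nchildren < 2) stop("children_per_family must be at least 2");
  NumericMatrix p = clone(pop);
  NumericVector l = clone(losses);
  Objective obj(objspec);
  long evals = 0;
  family_step(p, l, lower, upper, logs, nchildren, sigma_xi, sigma_eta,
              obj, evals);
  return List::create(_["population"] = p, _["losses"] = l,
                      _["evaluations"] = (double)evals);
}

// [[Rcpp::export]]
List cpp_rcga(NumericVector lower, NumericVector upper, IntegerVector logs,
              int pop_size, int generations, int nchildren,
              double sigma_xi, double sigma_eta, List objspec) {
  int n = lower.size();
  if (pop_size < 3) stop("population_size must be at least 3");
  if (nchildren < 2) stop("children_per_family must be at least 2");
  if (generations < 1) stop("generations must be at least 1");
  Objective obj(objspec);

  NumericMatrix pop(pop_size, n);
  NumericVector losses(pop_size);
  std::vector<double> natural, scaled(n);
  long evals = 0;
  for (int i = 0; i < pop_size; ++i) {
    for (int j = 0; j < n; ++j) {
      pop(i, j) = lower[j] + unif_rand() * (upper[j] - lower[j]);
      scaled[j] = pop(i, j);
    }
    descale(scaled, logs, natural);
    losses[i] = obj.eval(natural);
    ++evals;
  }

  int families = pop_size / 2;
  NumericVector history(generations);
  for (int g = 0; g < generations; ++g) {
    for (int f = 0; f < families; ++f)
      family_step(pop, losses, lower, upper, logs, nchildren,
                  sigma_xi, sigma_eta, obj, evals);
    history[g] = *std::min_element(losses.begin(), losses.end());
    if (g % 16 == 0) Rcpp::checkUserInterrupt();
  }

  int best = 0;
  for (int i = 1; i < pop_size; ++i) if (losses[i] < losses[best]) best = i;
  NumericVector par(n);
  for (int j = 0; j < n; ++j) par[j] = descale1(pop(best, j), logs[j]);
  return List::create(_["par"] = par, _["loss"] = losses[best],
                      _["history"] = history,
                      _["evaluations"] = (double)evals);
}
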