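#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Analytic potential forms shared by the Langevin integrator.
// form 1: harmonic, params = (k, c_1..c_dim)
// form 2: double_well (1D), params = (height, a, tilt):
//         U = height*((x/a)^2 - 1)^2 + tilt*x, minima near +-a, barrier at 0
// form 3: binding_landscape_2d, params = (wall_radius, wall_k,
//         then per well: depth, cx, cy, sigma)
static double pot_eval(int form, const NumericVector &p, const double *x,
                       int dim, double *grad) {
  double U = 0.0;
  for (int d = 0; d < dim; ++d) grad[d] = 0.0;
  if (form == 1) {
    double k = p[0];
    for (int d = 0; d < dim; ++d) {
      double dx = x[d] - p[1 + d];
      U += 0.5 * k * dx * dx;
      grad[d] = k * dx;
    }
  } else if (form == 2) {
    double h = p[0], a = p[1], tilt = p[2];
    double u = (x[0] / a) * (x[0] / a) - 1.0;
    U = h * u * u + tilt * x[0];
    grad[0] = 4.0 * h * u * x[0] / (a * a) + tilt;
  } else if (form == 3) {
    double R = p[0], wk = p[1];
    double r2 = x[0] * x[0] + x[1] * x[1];
    double r = std::sqrt(r2);
    if (r > R) {
      double e = r - R;
      U += 0.5 * wk * e * e;
      if (r > 1e-12) {
        grad[0] += wk * e * x[0] / r;
        grad[1] += wk * e * x[1] / r;
      }
    }
    int nw = (p.size() - 2) / 4;
    for (int w = 0; w < nw; ++w) {
      double D = p[2 + 4 * w], cx = p[3 + 4 * w], cy = p[4 + 4 * w],
             s = p[5 + 4 * w];
      double dx = x[0] - cx, dy = x[1] - cy;
      double g = std::exp(-(dx * dx + dy * dy) / (2.0 * s * s));
      U -= D * g;
      grad[0] += D * g * dx / (s * s);
      grad[1] += D * g * dy / (s * s);
    }
  } else {
    stop("unknown potential form code");
  }
  return U;
}

// [[Rcpp::export]]
List cpp_potential_eval(int form, NumericVector params, NumericMatrix x) {
  int n = x.nrow(), dim = x.ncol();
  NumericVector U(n);
  NumericMatrix G(n, dim);
  std::vector<double> xi(dim), gi(dim);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < dim; ++d) xi[d] = x(i, d);
    U[i] = pot_eval(form, params, xi.data(), dim, gi.data());
    for (int d = 0; d < dim; ++d) G(i, d) = gi[d];
  }
  return List::create(_["energy"] = U, _["gradient"] = G);
}

static inline double cv_eval(int cv_type, const double *x, int dim,
                             const NumericVector &cvc, double *dcv) {
  if (cv_type == 0) {
    for (int d = 0; d < dim; ++d) dcv[d] = 0.0;
    dcv[0] = 1.0;
    return x[0];
  }
  // radial distance from cvc
  double r2 = 0.0;
  for (int d = 0; d < dim; ++d) {
    double dx = x[d] - cvc[d];
    r2 += dx * dx;
  }
  double r = std::sqrt(r2);
  for (int d = 0; d < dim; ++d)
    dcv[d] = (r > 1e-12) ? (x[d] - cvc[d]) / r : 0.0;
  return r;
}

// Overdamped (Brownian) dynamics x <- x - (dt/friction) dU + sqrt(2 kT dt / friction) xi,
// with optional harmonic restraint on the CV (umbrella sampling) and optional
// well-tempered metadynamics hills on the CV.  Uses R's RNG (seed via set.seed()).
// [[Rcpp::export]]
List cpp_langevin(int form, NumericVector pot_params, NumericVector start,
                  double dt, double kT, double friction, double n_steps,
                  int stride, double restraint_k, double restraint_center,
                  int cv_type, NumericVector cv_ref, bool metad,
                  int pace_steps, double height0, double hill_width,
                  double bias_factor, double escape_threshold,
                  double static_bias, int max_hills) {
  int dim = start.size();
  long nst = (long)n_steps;
  long nsave = nst / stride + 1;
  NumericMatrix pos(nsave, dim);
  std::vector<double> x(dim), g(dim), dcv(dim);
  for (int d = 0; d < dim; ++d) x[d] = start[d];
  std::vector<double> h_t, h_c, h_h;
  double mob = dt / friction;
  double noise = std::sqrt(2.0 * kT * dt / friction);
  double alpha_sum = 0.0;
  long alpha_n = 0;
  double escape_time = NA_REAL;
  bool escaped = false;
  long save_idx = 0;
  for (int d = 0; d < dim; ++d) pos(0, d) = x[d];
  save_idx = 1;
  long step = 0;
  for (step = 0; step < nst; ++step) {
    double U = pot_eval(form, pot_params, x.data(), dim, g.data());
    if (!std::isfinite(U)) stop("non-finite energy at step %ld", step);
    double s = 0.0;
    if (metad || restraint_k > 0.0) s = cv_eval(cv_type, x.data(), dim, cv_ref, dcv.data());
    if (restraint_k > 0.0) {
      double dev = s - restraint_center;
      for (int d = 0; d < dim; ++d) g[d] += restraint_k * dev * dcv[d];
    }
    if (metad) {
      // bias at current CV (before this step's possible deposition)
      double V = static_bias;
      double dVds = 0.0;
      for (size_t kh = 0; kh < h_c.size(); ++kh) {
        double ds = s - h_c[kh];
        double e = h_h[kh] * std::exp(-ds * ds / (2.0 * hill_width * hill_width));
        V += e;
        dVds += -e * ds / (hill_width * hill_width);
      }
      alpha_sum += std::exp(V / kT);
      alpha_n += 1;
      for (int d = 0; d < dim; ++d) g[d] += dVds * dcv[d];
      if (pace_steps > 0 && height0 > 0.0 && (step % pace_steps == 0)) {
        double hh = height0 * std::exp(-(V - static_bias) / ((bias_factor - 1.0) * kT));
        if ((int)h_c.size() < max_hills) {
          h_t.push_back(step * dt);
          h_c.push_back(s);
          h_h.push_back(hh);
        }
      }
    }
    for (int d = 0; d < dim; ++d) {
      if (!std::isfinite(g[d])) stop("non-finite gradient at step %ld", step);
      x[d] += -mob * g[d] + noise * norm_rand();
    }
    if ((step + 1) % stride == 0 && save_idx < nsave) {
      for (int d = 0; d < dim; ++d) pos(save_idx, d) = x[d];
      ++save_idx;
    }
    if (metad && std::isfinite(escape_threshold)) {
      double snew = cv_eval(cv_type, x.data(), dim, cv_ref, dcv.data());
      if (snew > escape_threshold) {
        escaped = true;
        escape_time = (step + 1) * dt;
        break;
      }
    }
  }
  if (save_idx < nsave) pos = pos(Range(0, save_idx - 1), _);
  double alpha = (alpha_n > 0) ? alpha_sum / alpha_n : 1.0;
  return List::create(
      _["positions"] = pos, _["hill_times"] = wrap(h_t),
      _["hill_centers"] = wrap(h_c), _["hill_heights"] = wrap(h_h),
      _["alpha"] = alpha, _["escaped"] = escaped,
      _["escape_time"] = escape_time, _["steps_done"] = (double)(escaped ? step + 1 : nst));
}
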