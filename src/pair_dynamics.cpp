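// Far-field dynamics of a mirror-symmetric squirmer pair above a wall.
//
// Swimmer 1 sits at (0, h, 0) with orientation (cos t, sin t, 0); swimmer 2
// at (D, h, 0) with orientation (-cos t, sin t, 0). Rates are assembled
// from the analytic singularity flows and their wall images (generated
// kernels), with Faxen's relations: velocity = ambient flow at the centre,
// rotation = half its vorticity.

#include <Rcpp.h>
#include "flow_kernels_gen.h"
using namespace Rcpp;

struct PairParams {
  double p, s, v0, vg, R;
};

// free-space squirmer flow at x from a squirmer at Y with orientation e
static void squirmer_u(const double* x, const double* Y, const double* e,
                       double p, double s, double* out) {
  double r[3] = {x[0] - Y[0], x[1] - Y[1], x[2] - Y[2]};
  double rn = std::sqrt(r[0] * r[0] + r[1] * r[1] + r[2] * r[2]);
  double rh[3] = {r[0] / rn, r[1] / rn, r[2] / rn};
  double ce = e[0] * rh[0] + e[1] * rh[1] + e[2] * rh[2];
  double c1 = -(p / (rn * rn)) * (1.0 - 3.0 * ce * ce);
  double c2 = -s / (rn * rn * rn);
  for (int k = 0; k < 3; ++k)
    out[k] = c1 * rh[k] + c2 * (e[k] - 3.0 * ce * rh[k]);
}

static void add_image_u(const double* x, const double* Y, const double* e,
                        double p, double s, double* acc) {
  double a[3], b[3];
  stresslet_image_u(x, Y, e, a);
  sdipole_image_u(x, Y, e, b);
  for (int k = 0; k < 3; ++k) acc[k] += p * a[k] + s * b[k];
}

static double image_curl_z(const double* x, const double* Y, const double* e,
                           double p, double s) {
  double a[3], b[3];
  stresslet_image_curl(x, Y, e, a);
  sdipole_image_curl(x, Y, e, b);
  return p * a[2] + s * b[2];
}

// total in-plane rates of swimmer 1 (no repulsion): out = {ux, uy, dtheta}
static void pair_rates(double D, double h, double theta, const PairParams& q,
                       double* out) {
  double x1[3] = {0.0, h, 0.0}, x2[3] = {D, h, 0.0};
  double e1[3] = {std::cos(theta), std::sin(theta), 0.0};
  double e2[3] = {-e1[0], e1[1], 0.0};

  double u[3] = {q.v0 * e1[0], q.v0 * e1[1], 0.0};
  double x = q.R / h;
  u[1] -= q.vg * (1.0 - 9.0 * x / 8.0 + 0.5 * x * x * x);

  double tmp[3];
  squirmer_u(x1, x2, e2, q.p, q.s, tmp);
  for (int k = 0; k < 3; ++k) u[k] += tmp[k];
  add_image_u(x1, x1, e1, q.p, q.s, u);
  add_image_u(x1, x2, e2, q.p, q.s, u);

  double fc[3];
  stresslet_free_curl(x1, x2, e2, fc);
  double wz = q.p * fc[2] + image_curl_z(x1, x1, e1, q.p, q.s) +
              image_curl_z(x1, x2, e2, q.p, q.s);

  out[0] = u[0];
  out[1] = u[1];
  out[2] = 0.5 * wz;
}

// [[Rcpp::export(name = ".pair_rates_cpp")]]
NumericVector pair_rates_cpp(double D, double h, double theta, double p,
                             double s, double v0, double vg, double R) {
  PairParams q{p, s, v0, vg, R};
  double out[3];
  pair_rates(D, h, theta, q, out);
  return NumericVector::create(out[0], out[1], out[2]);
}

// [[Rcpp::export(name = ".pair_relax_cpp")]]
NumericVector pair_relax_cpp(double D, double h0, double theta0, double p,
                             double s, double v0, double vg, double R,
                             double dt, double tol, double t_max) {
  PairParams q{p, s, v0, vg, R};
  double h = h0, th = theta0, out[3];
  long n_max = (long)std::ceil(t_max / dt);
  int quiet = 0;
  for (long k = 1; k <= n_max; ++k) {
    pair_rates(D, h, th, q, out);
    if (std::fabs(out[1]) < tol && std::fabs(out[2]) < tol) {
      if (++quiet >= 100)
        return NumericVector::create(h, th, 1.0, k * dt);
    } else {
      quiet = 0;
    }
    h += dt * out[1];
    if (h < R) h = R;
    th += dt * out[2];
    if (!std::isfinite(h) || !std::isfinite(th))
      stop("fixed-distance relaxation became non-finite");
  }
  return NumericVector::create(h, th, 0.0, t_max);
}

// [[Rcpp::export(name = ".pair_encounter_cpp")]]
List pair_encounter_cpp(double D0, double h0, double theta0, double p,
                        double s, double v0, double vg, double R, double dt,
                        double t_max, int record_every) {
  PairParams q{p, s, v0, vg, R};
  double D = D0, h = h0, th = theta0, out[3];
  long n = (long)std::ceil(t_max / dt);
  double floor_D = 2.5 * R + 0.01;
  int at_floor = 0;
  long n_rec = n / record_every + 2;
  NumericMatrix traj(n_rec, 4);
  long ri = 0;
  traj(ri, 0) = 0.0; traj(ri, 1) = D; traj(ri, 2) = h; traj(ri, 3) = th;
  ++ri;
  bool collide = false;
  for (long k = 1; k <= n; ++k) {
    pair_rates(D, h, th, q, out);
    double ur = -v0 * std::cos(th) / (2.0 * (D - 2.0 * R));
    D += dt * (-2.0 * (out[0] + ur));
    h += dt * out[1];
    if (h < R) h = R;
    th += dt * out[2];
    if (!std::isfinite(D) || !std::isfinite(th) || std::fabs(th) > 10.0)
      stop("encounter integration became unstable");
    if (k % record_every == 0 && ri < n_rec) {
      traj(ri, 0) = k * dt; traj(ri, 1) = D; traj(ri, 2) = h; traj(ri, 3) = th;
      ++ri;
    }
    at_floor = (D <= floor_D) ? at_floor + 1 : 0;
    if (at_floor >= 50) {
      collide = true;
      if (ri < n_rec) {
        traj(ri, 0) = k * dt; traj(ri, 1) = D; traj(ri, 2) = h;
        traj(ri, 3) = th;
        ++ri;
      }
      break;
    }
  }
  return List::create(_["trajectory"] = traj(Range(0, ri - 1), _),
                      _["collide"] = collide);
}

// kernel exports for cross-validation against the generated R forms
// [[Rcpp::export(name = ".flow_kernel_cpp")]]
NumericVector flow_kernel_cpp(std::string kind, NumericVector x,
                              NumericVector Y, NumericVector e) {
  double out[3];
  if (kind == "stresslet_image_u") stresslet_image_u(&x[0], &Y[0], &e[0], out);
  else if (kind == "sdipole_image_u") sdipole_image_u(&x[0], &Y[0], &e[0], out);
  else if (kind == "stresslet_image_curl") stresslet_image_curl(&x[0], &Y[0], &e[0], out);
  else if (kind == "sdipole_image_curl") sdipole_image_curl(&x[0], &Y[0], &e[0], out);
  else if (kind == "stresslet_free_curl") stresslet_free_curl(&x[0], &Y[0], &e[0], out);
  else stop("unknown kernel");
  return NumericVector::create(out[0], out[1], out[2]);
}
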