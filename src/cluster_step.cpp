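// Orientation dynamics of near-contact squirmer clusters.
//
// Positions are frozen; unit orientation vectors rotate under the pairwise
// lubrication torques (own-flow and neighbour-flow terms), wall torques,
// and rotational white noise. Torques are converted to angular velocities
// with the isolated-sphere rotational mobility 1/(8 pi mu R^3); in the
// nondimensional units used here (mu = R = v0 = 1) the prefactors reduce to
//   own-flow  (12/5) pi / (8 pi) = 3/10
//   neighbour (3/5)  pi / (8 pi) = 3/40
//   wall      (24/5) pi / (8 pi) = 3/5
// each multiplied by the pair/wall log factor (-ln eps).

#include <Rcpp.h>
using namespace Rcpp;

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double clamp1(double x) {
  return x > 1.0 ? 1.0 : (x < -1.0 ? -1.0 : x);
}

// [[Rcpp::export(name = ".cluster_run_cpp")]]
List cluster_run_cpp(NumericMatrix positions, NumericMatrix orient0,
                     IntegerMatrix pairs, NumericVector pair_mlneps,
                     double beta, int wall_mode,
                     NumericVector mlneps_bottom, NumericVector mlneps_top,
                     NumericMatrix inward, double dt, int n_steps,
                     double eta, bool planar, double dphi_window,
                     double theta_window, int extra_steps, int record_every) {
  const int N = orient0.nrow();
  const int M = pairs.nrow();
  const double c_own = 3.0 / 10.0, c_oth = 3.0 / 40.0, c_wall = 3.0 / 5.0;

  std::vector<double> e(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) e[3 * i + k] = orient0(i, k);

  // unit separation vectors per pair (positions fixed)
  std::vector<double> ehat(3 * M);
  for (int m = 0; m < M; ++m) {
    int i = pairs(m, 0), j = pairs(m, 1);
    double d[3], dn = 0.0;
    for (int k = 0; k < 3; ++k) {
      d[k] = positions(j, k) - positions(i, k);
      dn += d[k] * d[k];
    }
    dn = std::sqrt(dn);
    for (int k = 0; k < 3; ++k) ehat[3 * m + k] = d[k] / dn;
  }

  std::vector<bool> has_inward(N);
  for (int i = 0; i < N; ++i) {
    double nv = inward(i, 0) * inward(i, 0) + inward(i, 1) * inward(i, 1) +
                inward(i, 2) * inward(i, 2);
    has_inward[i] = nv > 0.5;
  }

  std::vector<double> omega(3 * N);
  double max_dphi = 0.0, max_theta = 0.0;
  int az_break = -1, pol_break = -1, steps_run = 0;
  int countdown = -1;

  int n_rec = 0;
  NumericMatrix traj;
  if (record_every > 0) {
    n_rec = n_steps / record_every + 2;
    traj = NumericMatrix(n_rec, 1 + 2 * N);
  }
  int rec_row = 0;
  auto record = [&](int step) {
    if (record_every <= 0 || rec_row >= n_rec) return;
    traj(rec_row, 0) = step * dt;
    for (int i = 0; i < N; ++i) {
      const double* ei = &e[3 * i];
      double th = std::asin(clamp1(ei[1]));
      double vx = ei[0], vz = ei[2];
      double nv = std::sqrt(vx * vx + vz * vz);
      double dphi = 0.0;
      if (has_inward[i] && nv > 1e-12) {
        double cd = (vx * inward(i, 0) + vz * inward(i, 2)) / nv;
        dphi = std::acos(clamp1(cd));
      }
      traj(rec_row, 1 + i) = dphi;
      traj(rec_row, 1 + N + i) = th;
    }
    ++rec_row;
  };
  record(0);

  for (int step = 1; step <= n_steps; ++step) {
    std::fill(omega.begin(), omega.end(), 0.0);

    for (int m = 0; m < M; ++m) {
      int i = pairs(m, 0), j = pairs(m, 1);
      const double L = pair_mlneps[m];
      const double* eij = &ehat[3 * m];
      double eji[3] = {-eij[0], -eij[1], -eij[2]};
      const double* ei = &e[3 * i];
      const double* ej = &e[3 * j];
      double cxi[3], cxj[3];
      double di = ei[0] * eij[0] + ei[1] * eij[1] + ei[2] * eij[2];
      double dj = ej[0] * eji[0] + ej[1] * eji[1] + ej[2] * eji[2];
      // torque on i: own flow near j, plus flow of j
      cross3(eij, ei, cxi);
      cross3(eji, ej, cxj);
      double f_own_i = c_own * L * (1.0 + beta * di);
      double f_oth_i = c_oth * L * (1.0 + beta * dj);
      // torque on j: mirrored roles
      double f_own_j = c_own * L * (1.0 + beta * dj);
      double f_oth_j = c_oth * L * (1.0 + beta * di);
      for (int k = 0; k < 3; ++k) {
        omega[3 * i + k] += f_own_i * cxi[k] + f_oth_i * cxj[k];
        omega[3 * j + k] += f_own_j * cxj[k] + f_oth_j * cxi[k];
      }
    }

    if (wall_mode >= 1) {
      for (int i = 0; i < N; ++i) {
        const double* ei = &e[3 * i];
        // bottom wall, ew = (0,-1,0): ew x e = (-ez, 0, ex)
        double f = c_wall * mlneps_bottom[i] * (1.0 - beta * ei[1]);
        omega[3 * i + 0] += -f * ei[2];
        omega[3 * i + 2] += f * ei[0];
        if (wall_mode == 2) {
          // top wall, ew = (0,1,0): ew x e = (ez, 0, -ex)
          double g = c_wall * mlneps_top[i] * (1.0 + beta * ei[1]);
          omega[3 * i + 0] += g * ei[2];
          omega[3 * i + 2] += -g * ei[0];
        }
      }
    }

    // rotational white noise
    if (eta > 0.0) {
      for (int i = 0; i < N; ++i) {
        double mag = R::rnorm(0.0, eta);
        if (planar) {
          omega[3 * i + 1] += mag;
        } else {
          double ax, ay, az, nn;
          do {
            ax = R::norm_rand();
            ay = R::norm_rand();
            az = R::norm_rand();
            nn = std::sqrt(ax * ax + ay * ay + az * az);
          } while (nn < 1e-12);
          omega[3 * i + 0] += mag * ax / nn;
          omega[3 * i + 1] += mag * ay / nn;
          omega[3 * i + 2] += mag * az / nn;
        }
      }
    }

    bool bad = false;
    for (int i = 0; i < N; ++i) {
      double* ei = &e[3 * i];
      double w[3] = {omega[3 * i], omega[3 * i + 1], omega[3 * i + 2]};
      if (planar) {
        w[0] = 0.0;
        w[2] = 0.0;
      }
      double de[3];
      cross3(w, ei, de);
      double nn = 0.0;
      for (int k = 0; k < 3; ++k) {
        ei[k] += dt * de[k];
        nn += ei[k] * ei[k];
      }
      nn = std::sqrt(nn);
      if (!std::isfinite(nn) || nn < 1e-12) {
        bad = true;
        break;
      }
      for (int k = 0; k < 3; ++k) ei[k] /= nn;
    }
    if (bad) stop("orientation dynamics blew up (non-finite orientation)");

    // stability windows. A polar break-up can round the corner just short
    // of vertical (the orientation swings outward through near-vertical
    // without |theta| formally crossing pi/2), so an inward-window
    // violation at large tilt (|theta| >= pi/4) is attributed to the polar
    // mode; at small tilt it is azimuthal.
    for (int i = 0; i < N; ++i) {
      const double* ei = &e[3 * i];
      double th = std::fabs(std::asin(clamp1(ei[1])));
      if (th > max_theta) max_theta = th;
      bool pol_hit = !planar && th >= theta_window;
      if (has_inward[i]) {
        double vx = ei[0], vz = ei[2];
        double nv = std::sqrt(vx * vx + vz * vz);
        if (nv > 1e-9) {
          double cd = (vx * inward(i, 0) + vz * inward(i, 2)) / nv;
          double dphi = std::acos(clamp1(cd));
          if (dphi > max_dphi) max_dphi = dphi;
          if (dphi >= dphi_window) {
            if (planar || th < 0.25 * M_PI) {
              if (az_break < 0) az_break = step;
            } else {
              pol_hit = true;
            }
          }
        }
      }
      if (pol_hit && pol_break < 0) pol_break = step;
    }
    if (record_every > 0 && step % record_every == 0) record(step);
    steps_run = step;
    if (countdown < 0 && (az_break >= 0 || pol_break >= 0)) {
      countdown = extra_steps;
    } else if (countdown > 0) {
      --countdown;
    }
    if (countdown == 0) break;
  }

  NumericMatrix efinal(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) efinal(i, k) = e[3 * i + k];

  List out = List::create(
      _["az_break_step"] = az_break, _["pol_break_step"] = pol_break,
      _["max_dphi"] = max_dphi, _["max_theta"] = max_theta,
      _["steps_run"] = steps_run, _["orientations"] = efinal);
  if (record_every > 0) {
    out["trajectory"] = traj(Range(0, rec_row - 1), _);
  }
  return out;
}
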