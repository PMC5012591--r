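#include <Rcpp.h>
using namespace Rcpp;

// Run-and-tumble swimmer driven by independent two-state flagellar motors.
//
// Motor switching is simulated by exact event sampling (exponential dwell
// times), so there is no discretisation bias at high switching rates. The
// heading performs isotropic rotational diffusion during runs, integrated on
// an internal grid of step dt_internal. Tumbling cells are stationary; on a
// tumble -> run transition the 3D heading is redrawn uniformly on the sphere.
// The z coordinate is reflected at 0 and depth; output is the 2D projection
// sampled every dt_sample. Uses R's RNG, so set.seed() gives bit-identical
// trajectories.

static void unit_sphere(double &ux, double &uy, double &uz) {
  double z = 2.0 * unif_rand() - 1.0;
  double phi = 2.0 * M_PI * unif_rand();
  double s = std::sqrt(std::max(0.0, 1.0 - z * z));
  ux = s * std::cos(phi);
  uy = s * std::sin(phi);
  uz = z;
}

// two orthonormal vectors perpendicular to u
static void perp_basis(const double u[3], double e1[3], double e2[3]) {
  double ax = std::fabs(u[0]), ay = std::fabs(u[1]), az = std::fabs(u[2]);
  double v[3] = {0.0, 0.0, 0.0};
  if (ax <= ay && ax <= az) v[0] = 1.0;
  else if (ay <= az) v[1] = 1.0;
  else v[2] = 1.0;
  // e1 = normalize(u x v)
  e1[0] = u[1] * v[2] - u[2] * v[1];
  e1[1] = u[2] * v[0] - u[0] * v[2];
  e1[2] = u[0] * v[1] - u[1] * v[0];
  double n1 = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
  for (int i = 0; i < 3; ++i) e1[i] /= n1;
  e2[0] = u[1] * e1[2] - u[2] * e1[1];
  e2[1] = u[2] * e1[0] - u[0] * e1[2];
  e2[2] = u[0] * e1[1] - u[1] * e1[0];
}

static void reflect_z(double &z, double &uz, double depth) {
  while (z < 0.0 || z > depth) {
    if (z < 0.0) { z = -z; uz = -uz; }
    if (z > depth) { z = 2.0 * depth - z; uz = -uz; }
  }
}

// [[Rcpp::export]]
List simulate_trajectory_cpp(double k_to_cw, double k_to_ccw, int n_flagella,
                             double speed, double D_rot, double depth,
                             double dt_sample, double dt_internal,
                             double duration) {
  const int n_samples = (int)std::floor(duration / dt_sample + 1e-9) + 1;
  const int steps_per_sample = (int)std::lround(dt_sample / dt_internal);
  const double dt = dt_sample / steps_per_sample;  // exact subdivision
  NumericVector ts(n_samples), xs(n_samples), ys(n_samples);
  IntegerVector tumble(n_samples);
  NumericVector occ(n_samples);  // tumble occupancy of [t_i, t_{i+1})
  double t_tumble_acc = 0.0;

  // motor states: true = CW; initial states from the stationary distribution
  const double bias = k_to_cw / (k_to_cw + k_to_ccw);
  std::vector<char> cw(n_flagella);
  std::vector<double> t_switch(n_flagella);
  int n_cw = 0;
  for (int m = 0; m < n_flagella; ++m) {
    cw[m] = unif_rand() < bias;
    if (cw[m]) ++n_cw;
    double rate = cw[m] ? k_to_ccw : k_to_cw;
    t_switch[m] = exp_rand() / rate;
  }
  bool tumbling = n_cw > 0;

  double pos[3] = {0.0, 0.0, depth * unif_rand()};
  double u[3];
  unit_sphere(u[0], u[1], u[2]);

  double t = 0.0;
  int isamp = 0;
  ts[0] = 0.0; xs[0] = pos[0]; ys[0] = pos[1]; tumble[0] = tumbling ? 1 : 0;
  isamp = 1;

  const double sd_ang = std::sqrt(2.0 * D_rot * dt);
  long step = 0;
  while (isamp < n_samples) {
    const double t_end = (double)(step + 1) * dt;
    // process motor switch events inside (t, t_end]
    for (;;) {
      int m_min = -1;
      double t_evt = t_end;
      for (int m = 0; m < n_flagella; ++m)
        if (t_switch[m] < t_evt) { t_evt = t_switch[m]; m_min = m; }
      if (m_min < 0) break;
      if (!tumbling) {  // advance run segment up to the event
        double h = t_evt - t;
        for (int i = 0; i < 3; ++i) pos[i] += speed * u[i] * h;
        reflect_z(pos[2], u[2], depth);
      } else {
        t_tumble_acc += t_evt - t;
      }
      t = t_evt;
      // flip motor m_min
      if (cw[m_min]) { cw[m_min] = 0; --n_cw; }
      else { cw[m_min] = 1; ++n_cw; }
      double rate = cw[m_min] ? k_to_ccw : k_to_cw;
      t_switch[m_min] = t + exp_rand() / rate;
      bool now_tumbling = n_cw > 0;
      if (tumbling && !now_tumbling) unit_sphere(u[0], u[1], u[2]);
      tumbling = now_tumbling;
    }
    if (tumbling) t_tumble_acc += t_end - t;
    if (!tumbling) {
      double h = t_end - t;
      for (int i = 0; i < 3; ++i) pos[i] += speed * u[i] * h;
      reflect_z(pos[2], u[2], depth);
      if (D_rot > 0.0) {  // rotational diffusion of the heading
        double e1[3], e2[3];
        perp_basis(u, e1, e2);
        double a1 = norm_rand() * sd_ang, a2 = norm_rand() * sd_ang;
        double nn = 0.0;
        for (int i = 0; i < 3; ++i) {
          u[i] += a1 * e1[i] + a2 * e2[i];
          nn += u[i] * u[i];
        }
        nn = std::sqrt(nn);
        for (int i = 0; i < 3; ++i) u[i] /= nn;
      }
    }
    t = t_end;
    ++step;
    if (step % steps_per_sample == 0) {
      ts[isamp] = t;
      xs[isamp] = pos[0];
      ys[isamp] = pos[1];
      tumble[isamp] = tumbling ? 1 : 0;
      occ[isamp - 1] = t_tumble_acc / dt_sample;  // interval [i-1, i)
      t_tumble_acc = 0.0;
      ++isamp;
    }
  }
  occ[n_samples - 1] = NA_REAL;
  return List::create(_["t"] = ts, _["x"] = xs, _["y"] = ys,
                      _["tumble"] = tumble, _["occupancy"] = occ);
}

// Fraction of time a single two-state motor spends CW over a long exact
// simulation; used as an independent stochastic check of the stationary bias.
// [[Rcpp::export]]
double motor_cw_fraction_cpp(double k_to_cw, double k_to_ccw, double t_total) {
  bool is_cw = unif_rand() < k_to_cw / (k_to_cw + k_to_ccw);
  double t = 0.0, t_cw = 0.0;
  while (t < t_total) {
    double rate = is_cw ? k_to_ccw : k_to_cw;
    double dwell = exp_rand() / rate;
    if (t + dwell > t_total) dwell = t_total - t;
    if (is_cw) t_cw += dwell;
    t += dwell;
    is_cw = !is_cw;
  }
  return t_cw / t_total;
}
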