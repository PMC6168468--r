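#include <Rcpp.h>
using namespace Rcpp;

// Correlated-random-walk trajectory core.
//
// Heading state evolves as:
//   azimuth: wrapped random walk (stationary distribution uniform on the
//            circle), innovation sd = az_step_sd (radians per step);
//   pitch:   reflected AR(1), p_t = rho p_{t-1} + sqrt(1-rho^2) sd eps_t,
//            stationary N(0, sd^2), reflected into [-pi/2, pi/2]; or a
//            reflected random walk on [-pi/2, pi/2] when pitch_uniform
//            (stationary uniform).
// Position advances by speed*dt along the unit heading vector; a step that
// would leave the arena reflects the offending heading component (and the
// heading state) inward, billiard style.
//
// mode: 0 volumetric, 1 plane-XY (pitch frozen at 0, z fixed),
//       2 plane-YZ (x fixed; horizontal motion confined to +/- y).
// [[Rcpp::export]]
List traj_core_cpp(int n_steps, double dt, double speed,
                   double pitch_sd, bool pitch_uniform, double pitch_rho,
                   double az_step_sd,
                   NumericVector extent, int mode) {
  const double HALF_PI = M_PI / 2.0;
  NumericVector x(n_steps), y(n_steps), z(n_steps);
  NumericVector az(n_steps), pit(n_steps);
  RNGScope scope;

  double ex = extent[0], ey = extent[1], ez = extent[2];
  double cx = ex / 2.0, cy = ey / 2.0, cz = ez / 2.0;

  // start at the arena centre with a random heading
  double a = R::runif(-M_PI, M_PI);
  double p;
  if (mode == 1) {
    p = 0.0;
  } else if (pitch_uniform) {
    p = R::runif(-HALF_PI, HALF_PI);
  } else {
    p = R::rnorm(0.0, pitch_sd);
    while (p > HALF_PI)  p =  M_PI - p;
    while (p < -HALF_PI) p = -M_PI - p;
  }
  double px = cx, py = cy, pz = cz;
  x[0] = px; y[0] = py; z[0] = pz;
  az[0] = a; pit[0] = p;

  const double step = speed * dt;
  const double ar_innov = pitch_sd * std::sqrt(1.0 - pitch_rho * pitch_rho);

  for (int t = 1; t < n_steps; ++t) {
    // azimuth: wrapped random walk
    a += R::rnorm(0.0, az_step_sd);
    while (a > M_PI)  a -= 2.0 * M_PI;
    while (a <= -M_PI) a += 2.0 * M_PI;

    // pitch
    if (mode == 1) {
      p = 0.0;
    } else if (pitch_uniform) {
      p += R::rnorm(0.0, az_step_sd);
      while (p > HALF_PI)  p =  M_PI - p;
      while (p < -HALF_PI) p = -M_PI - p;
    } else if (pitch_sd <= 0.0) {
      p = 0.0;
    } else {
      p = pitch_rho * p + R::rnorm(0.0, ar_innov);
      while (p > HALF_PI)  p =  M_PI - p;
      while (p < -HALF_PI) p = -M_PI - p;
    }

    double ux, uy, uz;
    if (mode == 2) {
      // vertical YZ plane: horizontal motion confined to +/- y
      double h = (std::cos(a) >= 0.0) ? 1.0 : -1.0;
      ux = 0.0;
      uy = h * std::cos(p);
      uz = std::sin(p);
    } else {
      ux = std::cos(p) * std::cos(a);
      uy = std::cos(p) * std::sin(a);
      uz = (mode == 1) ? 0.0 : std::sin(p);
    }

    double nx = px + step * ux;
    double ny = py + step * uy;
    double nz = pz + step * uz;

    // billiard reflection at the walls; reflect heading state too
    bool flipped_x = false, flipped_y = false;
    if (nx < 0.0)      { nx = -nx; flipped_x = true; }
    else if (nx > ex)  { nx = 2.0 * ex - nx; flipped_x = true; }
    if (ny < 0.0)      { ny = -ny; flipped_y = true; }
    else if (ny > ey)  { ny = 2.0 * ey - ny; flipped_y = true; }
    if (nz < 0.0)      { nz = -nz; p = -p; }
    else if (nz > ez)  { nz = 2.0 * ez - nz; p = -p; }
    if (mode == 2) {
      // only the sign of cos(azimuth) matters: mirror it on a y-wall hit
      if (flipped_y) a = M_PI - a;
    } else if (flipped_x && flipped_y) {
      a += M_PI;                      // cos and sin both change sign
    } else if (flipped_x) {
      a = M_PI - a;                   // cos changes sign
    } else if (flipped_y) {
      a = -a;                         // sin changes sign
    }
    while (a > M_PI)  a -= 2.0 * M_PI;
    while (a <= -M_PI) a += 2.0 * M_PI;

    if (mode == 1) nz = cz;
    if (mode == 2) nx = cx;

    px = nx; py = ny; pz = nz;
    x[t] = px; y[t] = py; z[t] = pz;
    az[t] = a; pit[t] = p;
  }

  return List::create(_["x"] = x, _["y"] = y, _["z"] = z,
                      _["azimuth"] = az, _["pitch"] = pit);
}
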