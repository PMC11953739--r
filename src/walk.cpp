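#include <Rcpp.h>
using namespace Rcpp;

// Biased-random-walk stepper for all worms in one arena.
//
// Each worm carries a position and heading. Per step the heading is turned
// towards a preferred direction (klinotaxis-style reorientation, so drift
// and crawl speed stay independently controllable) and jittered with
// Gaussian noise, then the worm advances by speed*dt. Boundaries reflect.
//
// The preferred direction is the vector sum of up to three influences:
//   * the odorant gradient, weighted by bias in [-1, 1] (sign = towards /
//     away from higher concentration);
//   * a laboratory-frame gradient along +x, weighted by ext_gradient,
//     identical for both arena orientations;
//   * drift towards the arena centre, weighted by origin_gain.
// field_kind: 0 = none, 1 = linear along x (field_dir = +1 means the
// concentration increases towards +x), 2 = point source at (src_x, src_y).
//
// Uses R's RNG, so set.seed() on the R side makes runs reproducible.
// [[Rcpp::export]]
List walk_worms_cpp(NumericVector x0, NumericVector y0, NumericVector h0,
                    int n_steps, double dt, double speed, double turn_sd,
                    double arena_length, double arena_width,
                    int field_kind, double field_dir,
                    double src_x, double src_y,
                    double bias, double origin_gain, double ext_gradient,
                    int record_every = 0) {
  const int n = x0.size();
  const double cx = arena_length / 2.0, cy = arena_width / 2.0;
  const double max_turn = 1.2;  // cap on deterministic reorientation gain
  NumericVector x = clone(x0), y = clone(y0), h = clone(h0);

  int n_rec = 0;
  if (record_every > 0) n_rec = n_steps / record_every;
  NumericMatrix traj(n_rec * n, 4);  // worm, t, x, y
  int rec_row = 0;

  for (int s = 0; s < n_steps; ++s) {
    for (int i = 0; i < n; ++i) {
      double vx = 0.0, vy = 0.0;
      if (field_kind == 1) {
        vx += bias * field_dir;
      } else if (field_kind == 2) {
        double dx = src_x - x[i], dy = src_y - y[i];
        double d = std::sqrt(dx * dx + dy * dy);
        if (d > 1e-9) { vx += bias * dx / d; vy += bias * dy / d; }
      }
      vx += ext_gradient;
      if (origin_gain != 0.0) {
        double dx = cx - x[i], dy = cy - y[i];
        double d = std::sqrt(dx * dx + dy * dy);
        if (d > 1e-9) { vx += origin_gain * dx / d; vy += origin_gain * dy / d; }
      }
      double mag = std::sqrt(vx * vx + vy * vy);
      if (mag > 1e-12) {
        double gain = mag < max_turn ? mag : max_turn;
        double target = std::atan2(vy, vx);
        h[i] += gain * std::sin(target - h[i]);
      }
      h[i] += R::rnorm(0.0, turn_sd);

      double nx = x[i] + speed * dt * std::cos(h[i]);
      double ny = y[i] + speed * dt * std::sin(h[i]);
      // reflective boundaries; a few bounces suffice for small steps
      for (int b = 0; b < 8; ++b) {
        bool moved = false;
        if (nx < 0) { nx = -nx; h[i] = M_PI - h[i]; moved = true; }
        if (nx > arena_length) {
          nx = 2 * arena_length - nx; h[i] = M_PI - h[i]; moved = true;
        }
        if (ny < 0) { ny = -ny; h[i] = -h[i]; moved = true; }
        if (ny > arena_width) {
          ny = 2 * arena_width - ny; h[i] = -h[i]; moved = true;
        }
        if (!moved) break;
      }
      x[i] = nx; y[i] = ny;
    }
    if (record_every > 0 && (s + 1) % record_every == 0) {
      for (int i = 0; i < n; ++i) {
        traj(rec_row, 0) = i + 1;
        traj(rec_row, 1) = (s + 1) * dt;
        traj(rec_row, 2) = x[i];
        traj(rec_row, 3) = y[i];
        ++rec_row;
      }
    }
  }
  return List::create(_["x"] = x, _["y"] = y, _["heading"] = h,
                      _["traj"] = traj);
}
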