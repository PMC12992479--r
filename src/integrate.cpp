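#include <Rcpp.h>
using namespace Rcpp;

// Batch closed-loop point-mass simulation of reaching trials.
//
// Each trial tracks a minimum-jerk reference from the home position (0,0)
// to a per-trial goal point over a per-trial duration, then holds the goal
// for a settle period. Environment forces: an optional curl field
// (force = gain * (vy, -vx), positive gain = clockwise sense) and an
// optional force channel (stiff spring-damper corridor along the target
// axis). The controller adds an optional feedforward curl compensation
// term -comp_gain * (vy, -vx). Integration is semi-implicit Euler.
//
// Returns decimated samples for all trials in one block plus per-trial
// movement times measured with a 5%-of-peak speed threshold.
// [[Rcpp::export]]
List simulate_trials_cpp(NumericVector duration,
                         NumericVector goal_x,
                         NumericVector goal_y,
                         NumericVector field_gain,
                         NumericVector comp_gain,
                         LogicalVector channel_on,
                         NumericVector chan_dir_rad,
                         double dt,
                         double settle,
                         double kp,
                         double kd,
                         double mass,
                         double chan_k,
                         double chan_b,
                         double chan_halfw,
                         double chan_ramp,
                         int record_every) {
  const int ntr = duration.size();
  if (record_every < 1) stop("invalid parameter: record_every must be >= 1");

  // first pass: row bookkeeping
  std::vector<int> nsteps(ntr), nrec(ntr);
  long total = 0;
  for (int k = 0; k < ntr; ++k) {
    int n = (int)std::ceil((duration[k] + settle) / dt) + 1; // includes t=0
    nsteps[k] = n;
    int r = (n - 1) / record_every + 1;     // steps 0, record_every, ...
    if ((n - 1) % record_every != 0) r += 1; // plus the final step
    nrec[k] = r;
    total += r;
  }

  NumericMatrix samples(total, 7); // t x y vx vy fx fy
  IntegerVector row_trial(total);
  NumericVector move_time(ntr);

  long row = 0;
  std::vector<double> speed;
  for (int k = 0; k < ntr; ++k) {
    const int n = nsteps[k];
    const double T = duration[k];
    const double gx = goal_x[k], gy = goal_y[k];
    const double g = field_gain[k], comp = comp_gain[k];
    const bool chan = channel_on[k];
    const double wx = -std::sin(chan_dir_rad[k]);
    const double wy = std::cos(chan_dir_rad[k]);

    double px = 0.0, py = 0.0, vx = 0.0, vy = 0.0;
    speed.assign(n, 0.0);
    for (int i = 0; i < n; ++i) {
      const double t = i * dt;
      // minimum-jerk reference (held at goal after T)
      double tau = t / T;
      double s, sd;
      if (tau >= 1.0) { s = 1.0; sd = 0.0; }
      else {
        const double t2 = tau * tau, t3 = t2 * tau, t4 = t3 * tau;
        s = 10.0 * t3 - 15.0 * t4 + 6.0 * t4 * tau;
        sd = (30.0 * t2 - 60.0 * t3 + 30.0 * t4) / T;
      }
      const double rx = gx * s, ry = gy * s;
      const double rvx = gx * sd, rvy = gy * sd;

      double fcx = kp * (rx - px) + kd * (rvx - vx);
      double fcy = kp * (ry - py) + kd * (rvy - vy);
      double fex = 0.0, fey = 0.0;
      if (g != 0.0) { fex += g * vy; fey += -g * vx; }
      if (comp != 0.0) { fcx += -comp * vy; fcy += comp * vx; }
      if (chan) {
        const double lat = px * wx + py * wy;
        const double alat = std::fabs(lat);
        if (alat > chan_halfw) {
          const double latv = vx * wx + vy * wy;
          const double pen = alat - chan_halfw;
          const double sgn = (lat > 0.0) ? 1.0 : -1.0;
          const double fw = -chan_ramp * (chan_k * pen * sgn + chan_b * latv);
          fex += fw * wx;
          fey += fw * wy;
        }
      }

      // record BEFORE the state update so row i is the state at time t
      if (i % record_every == 0 || i == n - 1) {
        samples(row, 0) = t;
        samples(row, 1) = px; samples(row, 2) = py;
        samples(row, 3) = vx; samples(row, 4) = vy;
        samples(row, 5) = fex; samples(row, 6) = fey;
        row_trial[row] = k + 1;
        ++row;
      }
      speed[i] = std::sqrt(vx * vx + vy * vy);

      const double ax = (fcx + fex) / mass;
      const double ay = (fcy + fey) / mass;
      vx += ax * dt; vy += ay * dt;
      px += vx * dt; py += vy * dt;

      if (!std::isfinite(px) || !std::isfinite(py))
        stop("simulation error: non-finite state in trial %d", k + 1);
    }

    // movement time: first/last crossing of 5% of peak speed
    double pk = 0.0;
    for (int i = 0; i < n; ++i) if (speed[i] > pk) pk = speed[i];
    double thr = 0.05 * pk;
    int first = -1, last = -1;
    for (int i = 0; i < n; ++i) {
      if (speed[i] > thr) { if (first < 0) first = i; last = i; }
    }
    move_time[k] = (first >= 0 && last > first) ? (last - first) * dt : 0.0;
  }

  return List::create(_["samples"] = samples,
                      _["trial"] = row_trial,
                      _["movement_time"] = move_time);
}
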