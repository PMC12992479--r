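#include <Rcpp.h>
using namespace Rcpp;

// Fast batch version of the per-trial kinematic measures. Mirrors the R
// reference implementations exactly: onset/offset by the sustained
// 5%-of-peak speed rule, peak tangential velocity (earliest tie),
// ballistic end (first post-peak strict local minimum or near-zero
// speed), normalized RMSE, signed angular errors (CCW-positive) and
// lateral final endpoint error. RMSE/IDE/IEE optionally evaluated on the
// clockwise-rotated cursor path. Rows that fail event detection are NA.
// [[Rcpp::export]]
NumericMatrix trial_measures_cpp(NumericVector x, NumericVector y,
                                 NumericVector vx, NumericVector vy,
                                 IntegerVector start, IntegerVector len,
                                 NumericVector target_x, NumericVector target_y,
                                 LogicalVector use_cursor, double rot_deg,
                                 double dt, double thr_frac, double min_dur,
                                 double zero_frac) {
  const int ntr = start.size();
  NumericMatrix out(ntr, 8);
  colnames(out) = CharacterVector::create("rmse", "ide_deg", "iee_deg",
                                          "fee_cm", "onset", "offset",
                                          "peak_vel", "ballistic_end");
  const int min_len = std::max(1, (int)std::ceil(min_dur / dt));
  const double deg = 180.0 / M_PI;
  const double th = rot_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);

  std::vector<double> sp;
  for (int k = 0; k < ntr; ++k) {
    const int s0 = start[k] - 1; // 0-based
    const int n = len[k];
    sp.assign(n, 0.0);
    double pk = 0.0;
    for (int i = 0; i < n; ++i) {
      sp[i] = std::sqrt(vx[s0 + i] * vx[s0 + i] + vy[s0 + i] * vy[s0 + i]);
      if (sp[i] > pk) pk = sp[i];
    }
    bool bad = (pk <= 0.0);
    int onset = -1, offset = -1;
    if (!bad) {
      const double thr = thr_frac * pk;
      int run = 0;
      for (int i = 0; i < n; ++i) {
        if (sp[i] > thr) {
          ++run;
          if (run >= min_len && onset < 0) onset = i - run + 1;
          offset = i; // last sample of the last supra-threshold run
        } else run = 0;
      }
      if (onset < 0 || offset <= onset) bad = true;
    }
    if (bad) {
      for (int j = 0; j < 8; ++j) out(k, j) = NA_REAL;
      continue;
    }
    int peak = onset;
    double pmax = sp[onset];
    for (int i = onset + 1; i <= offset; ++i)
      if (sp[i] > pmax) { pmax = sp[i]; peak = i; }
    int ball = offset;
    const double zthr = zero_frac * sp[peak];
    for (int j = peak + 1; j <= offset; ++j) {
      if (sp[j] <= zthr) { ball = j; break; }
      if (j > 0 && j < n - 1 && sp[j] < sp[j - 1] && sp[j] < sp[j + 1]) {
        ball = j; break;
      }
    }

    const double tx = target_x[k], ty = target_y[k];
    const double tnorm = std::sqrt(tx * tx + ty * ty);
    const double ux = tx / tnorm, uy = ty / tnorm;
    const bool cur = use_cursor[k] && rot_deg != 0.0;

    // signed angle of (px,py) relative to target direction, degrees CCW+
    auto ang = [&](double px, double py) {
      return deg * std::atan2(tx * py - ty * px, tx * px + ty * py);
    };
    auto cursx = [&](int i) { return cur ? ct * x[s0 + i] + st * y[s0 + i] : x[s0 + i]; };
    auto cursy = [&](int i) { return cur ? -st * x[s0 + i] + ct * y[s0 + i] : y[s0 + i]; };

    double ss = 0.0, plen = 0.0;
    double pxp = cursx(onset), pyp = cursy(onset);
    for (int i = onset; i <= offset; ++i) {
      const double px = cursx(i), py = cursy(i);
      const double perp = ux * py - uy * px;
      ss += perp * perp;
      if (i > onset) {
        const double dx = px - pxp, dy = py - pyp;
        plen += std::sqrt(dx * dx + dy * dy);
      }
      pxp = px; pyp = py;
    }
    const double m = offset - onset + 1;
    out(k, 0) = (plen > 0) ? std::sqrt(ss / m) / plen : NA_REAL;
    out(k, 1) = ang(cursx(peak), cursy(peak));
    out(k, 2) = ang(cursx(ball), cursy(ball));
    out(k, 3) = 100.0 * (ux * y[s0 + offset] - uy * x[s0 + offset]);
    out(k, 4) = onset + 1;
    out(k, 5) = offset + 1;
    out(k, 6) = peak + 1;
    out(k, 7) = ball + 1;
  }
  return out;
}
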