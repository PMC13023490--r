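// Episode engine: the synchronous perceive-decide-move-learn loop.
//
// This is a straight transcription of the R reference path in run_episode()
// (see R/swarm.R): identical order of arithmetic and of random-number draws
// from R's global stream, so a C++ episode reproduces an R episode
// bit-for-bit under the same seed. Kept in C++ because training needs
// millions of swarm steps.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double wrap_angle(double x) {
  return std::atan2(std::sin(x), std::cos(x));
}

// [[Rcpp::export(name = ".ps_episode_engine")]]
List ps_episode_engine(NumericMatrix pos0, NumericMatrix hd0,
                       NumericVector tpos0, NumericVector tvel,
                       NumericVector hv0, int n_states, int m,
                       NumericVector angles, int k, double sigma,
                       double speed, int max_steps, double success_radius,
                       bool stop_on_success, bool learn, double eta,
                       double gamma, double h_min, double wd, double wr) {
  const int n = pos0.nrow();
  NumericMatrix pos(clone(pos0)), hd(clone(hd0));
  NumericVector hv(clone(hv0));
  double tx0 = tpos0[0], ty0 = tpos0[1];
  const double sr = sigma * M_PI / 180.0;

  std::vector<double> glow;
  if (learn) glow.assign((size_t)n * n_states * m, 0.0);

  NumericVector op(max_steps), oe(max_steps), cx(max_steps), cy(max_steps),
      dtt(max_steps);
  std::vector<int> percept(n), act(n);
  std::vector<double> rtot(n), cum((size_t)n_states * m);
  std::vector<double> th_nv(n), th_tv(n);

  // initial centroid and fallback motion direction (mean heading)
  double cpx = 0, cpy = 0, dirx = 0, diry = 0;
  for (int i = 0; i < n; ++i) {
    cpx += pos(i, 0); cpy += pos(i, 1);
    dirx += hd(i, 0); diry += hd(i, 1);
  }
  cpx /= n; cpy /= n; dirx /= n; diry /= n;
  {
    double nv = std::sqrt(dirx * dirx + diry * diry);
    if (nv >= 1e-9) { dirx /= nv; diry /= nv; } else { dirx = 1; diry = 0; }
  }

  int hit = NA_INTEGER;
  double total_reward = 0.0;
  int t = 0;

  while (t < max_steps) {
    ++t;
    // ---- percepts from the time-t snapshot -------------------------------
    for (int i = 0; i < n; ++i) {
      // k nearest neighbors, ties to the smaller index
      int taken = 0;
      double accx = 0, accy = 0;
      std::vector<char> used(n, 0);
      used[i] = 1;
      while (taken < k) {
        int best = -1;
        double bestd = R_PosInf;
        for (int j = 0; j < n; ++j) {
          if (used[j]) continue;
          double dx = pos(j, 0) - pos(i, 0), dy = pos(j, 1) - pos(i, 1);
          double d2 = dx * dx + dy * dy;
          if (d2 < bestd) { bestd = d2; best = j; }
        }
        used[best] = 1;
        accx += hd(best, 0); accy += hd(best, 1);
        ++taken;
      }
      double th_n;
      if (accx * accx + accy * accy < 1e-18) {
        th_n = 0.0;
      } else {
        th_n = std::atan2(hd(i, 0) * accy - hd(i, 1) * accx,
                          hd(i, 0) * accx + hd(i, 1) * accy);
      }
      double vx = tx0 - pos(i, 0), vy = ty0 - pos(i, 1);
      double th_t = std::atan2(hd(i, 0) * vy - hd(i, 1) * vx,
                               hd(i, 0) * vx + hd(i, 1) * vy);
      th_nv[i] = th_n; th_tv[i] = th_t;
    }
    if (sigma > 0) {
      for (int i = 0; i < n; ++i) th_nv[i] = wrap_angle(th_nv[i] + R::rnorm(0.0, sr));
      for (int i = 0; i < n; ++i) th_tv[i] = wrap_angle(th_tv[i] + R::rnorm(0.0, sr));
    }
    for (int i = 0; i < n; ++i) {
      double a = th_nv[i];
      int sn = (std::fabs(a) <= M_PI / 6.0) ? 1 : (a < 0 ? 0 : 2);
      double b = th_tv[i];
      int st = (std::fabs(b) <= M_PI / 6.0) ? 1 : (b < 0 ? 0 : 2);
      percept[i] = 3 * sn + st;
    }
    // ---- cumulative action probabilities (row-major, like the R matrix) --
    for (int s = 0; s < n_states; ++s) {
      long double rsl = 0.0;   // R's rowSums accumulates in long double
      for (int a = 0; a < m; ++a) rsl += hv[(size_t)s * m + a];
      double rs = (double)rsl;
      double c = 0.0;
      for (int a = 0; a < m; ++a) {
        c += hv[(size_t)s * m + a] / rs;
        cum[(size_t)s * m + a] = c;
      }
    }
    for (int i = 0; i < n; ++i) {
      double u = R::runif(0.0, 1.0);
      int a_i = 0;
      const double *crow = &cum[(size_t)percept[i] * m];
      for (int a = 0; a < m; ++a) if (u > crow[a]) ++a_i;
      act[i] = a_i;
    }
    // ---- rotate, advance, reward ----------------------------------------
    double tx1 = tx0 + tvel[0], ty1 = ty0 + tvel[1];
    for (int i = 0; i < n; ++i) {
      double ar = angles[act[i]] * M_PI / 180.0;
      double ca = std::cos(ar), sa = std::sin(ar);
      double hx = ca * hd(i, 0) - sa * hd(i, 1);
      double hy = sa * hd(i, 0) + ca * hd(i, 1);
      double d0x = tx0 - pos(i, 0), d0y = ty0 - pos(i, 1);
      double d0 = std::sqrt(d0x * d0x + d0y * d0y);
      double px = pos(i, 0) + speed * hx, py = pos(i, 1) + speed * hy;
      double d1x = tx1 - px, d1y = ty1 - py;
      double d1 = std::sqrt(d1x * d1x + d1y * d1y);
      double rdir = (hx * d1x + hy * d1y) / std::max(d1, 1e-12);
      if (rdir < 0) rdir = 0;
      rtot[i] = wd * (d0 - d1) + wr * rdir;
      hd(i, 0) = hx; hd(i, 1) = hy;
      pos(i, 0) = px; pos(i, 1) = py;
    }
    tx0 = tx1; ty0 = ty1;
    for (int i = 0; i < n; ++i) total_reward += rtot[i];
    // ---- learning update -------------------------------------------------
    if (learn) {
      const double keep = 1.0 - eta;
      const size_t e = (size_t)n_states * m;
      for (size_t z = 0; z < glow.size(); ++z) glow[z] *= keep;
      for (int i = 0; i < n; ++i) {
        glow[(size_t)i + (size_t)n * ((size_t)percept[i] * m + act[i])] += 1.0;
      }
      for (size_t col = 0; col < e; ++col) {
        long double acc = 0.0;   // matches R's colSums accumulator
        const double *g = &glow[(size_t)n * col];
        for (int i = 0; i < n; ++i) acc += g[i] * rtot[i];
        double v = hv[col] - gamma * (hv[col] - 1.0) + (double)acc;
        hv[col] = (v < h_min) ? h_min : v;
      }
    }
    // ---- order parameters ------------------------------------------------
    long double mhxl = 0, mhyl = 0, ccxl = 0, ccyl = 0;
    for (int i = 0; i < n; ++i) {   // colMeans accumulates in long double
      mhxl += hd(i, 0); mhyl += hd(i, 1);
      ccxl += pos(i, 0); ccyl += pos(i, 1);
    }
    double mhx = (double)(mhxl / n), mhy = (double)(mhyl / n);
    double ccx = (double)(ccxl / n), ccy = (double)(ccyl / n);
    op[t - 1] = std::sqrt(mhx * mhx + mhy * mhy);
    double dvx = ccx - cpx, dvy = ccy - cpy;
    if (std::sqrt(dvx * dvx + dvy * dvy) >= 1e-9) {
      double nv = std::sqrt(dvx * dvx + dvy * dvy);
      dirx = dvx / nv; diry = dvy / nv;
    }
    double lmax = R_NegInf, lmin = R_PosInf, wmax = R_NegInf, wmin = R_PosInf;
    for (int i = 0; i < n; ++i) {
      double pl = pos(i, 0) * dirx + pos(i, 1) * diry;
      double pw = -pos(i, 0) * diry + pos(i, 1) * dirx;
      if (pl > lmax) lmax = pl;
      if (pl < lmin) lmin = pl;
      if (pw > wmax) wmax = pw;
      if (pw < wmin) wmin = pw;
    }
    oe[t - 1] = (lmax - lmin) / std::max(wmax - wmin, 1.0);
    cx[t - 1] = ccx; cy[t - 1] = ccy;
    double dx = ccx - tx0, dy = ccy - ty0;
    dtt[t - 1] = std::sqrt(dx * dx + dy * dy);
    cpx = ccx; cpy = ccy;
    if (hit == NA_INTEGER && dtt[t - 1] <= success_radius) {
      hit = t;
      if (stop_on_success) break;
    }
  }

  return List::create(
      _["hv"] = hv, _["positions"] = pos, _["headings"] = hd,
      _["target"] = NumericVector::create(tx0, ty0),
      _["polarization"] = op, _["elongation"] = oe,
      _["centroid_x"] = cx, _["centroid_y"] = cy, _["dist_to_target"] = dtt,
      _["steps"] = t, _["hit"] = hit, _["total_reward"] = total_reward);
}
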