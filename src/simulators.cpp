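// Monte Carlo kernels: exact discrete-time samplers (Ornstein-Uhlenbeck
// updates, Rouse normal modes) and first-passage bookkeeping.  All random
// numbers come from R's RNG so that set.seed() governs reproducibility.
#include <Rcpp.h>
using namespace Rcpp;

// ---- 1D two-target first passage on a batch of sampled paths -------------
// X: (n_steps+1) x n_paths positions (row 0 = start).  Returns the first
// crossing of lower/upper per path with linear interpolation of the hit
// time, plus streaming accumulators of the post-hit segments per target.
// [[Rcpp::export]]
List fp_batch_cpp(const NumericMatrix& X, double lower, double upper,
                  int follow_steps) {
  const int nr = X.nrow(), np = X.ncol();
  IntegerVector side(np), khit(np, NA_INTEGER);
  NumericVector frac(np, NA_REAL);
  NumericVector s1(follow_steps), q1(follow_steps), s2(follow_steps), q2(follow_steps);
  int n1 = 0, n2 = 0;
  for (int p = 0; p < np; ++p) {
    int hit = 0, k = -1;
    for (int r = 1; r < nr; ++r) {
      const double x = X(r, p);
      if (x <= lower) { hit = 1; k = r; break; }
      if (x >= upper) { hit = 2; k = r; break; }
    }
    side[p] = hit;
    if (!hit) continue;
    const double b = (hit == 1) ? lower : upper;
    const double x0 = X(k - 1, p), x1 = X(k, p);
    khit[p] = k + 1;              // 1-based row index for R
    frac[p] = (x1 != x0) ? (b - x0) / (x1 - x0) : 0.0;
    if (follow_steps > 0 && k + follow_steps - 1 < nr) {
      if (hit == 1) {
        ++n1;
        for (int j = 0; j < follow_steps; ++j) {
          const double v = X(k + j, p);
          s1[j] += v; q1[j] += v * v;
        }
      } else {
        ++n2;
        for (int j = 0; j < follow_steps; ++j) {
          const double v = X(k + j, p);
          s2[j] += v; q2[j] += v * v;
        }
      }
    }
  }
  return List::create(_["side"] = side, _["khit"] = khit, _["frac"] = frac,
                      _["post1_sum"] = s1, _["post1_sq"] = q1, _["post1_n"] = n1,
                      _["post2_sum"] = s2, _["post2_sq"] = q2, _["post2_n"] = n2);
}

// ---- scan a single trajectory for a crossing -----------------------------
// x: positions; start: 0-based index to begin from.  Returns the 1-based
// index of the first sample at or beyond a boundary (0 if none).
// [[Rcpp::export]]
List scan_crossing_cpp(const NumericVector& x, int start, double lower, double upper) {
  const int n = x.size();
  for (int r = start; r < n; ++r) {
    if (x[r] <= lower) return List::create(_["idx"] = r + 1, _["side"] = 1);
    if (x[r] >= upper) return List::create(_["idx"] = r + 1, _["side"] = 2);
  }
  return List::create(_["idx"] = 0, _["side"] = 0);
}

// ---- exact bidiffusive sampler -------------------------------------------
// x(t) = W(t) + y(t) - y(0), W Brownian (MSD = t), y stationary OU with
// variance B/2 and unit relaxation time, so that the total MSD is
// t + B(1 - exp(-t)).  Exact discrete updates, stationary initial OU state.
// [[Rcpp::export]]
NumericMatrix bidiffusive_paths_cpp(double B, int n_steps, double dt, int n_paths) {
  NumericMatrix X(n_steps + 1, n_paths);
  const double e = std::exp(-dt);
  const double sig = std::sqrt(B / 2.0);
  const double sW = std::sqrt(dt);
  const double sOU = sig * std::sqrt(1.0 - e * e);
  for (int p = 0; p < n_paths; ++p) {
    double w = 0.0;
    double y0 = sig * R::norm_rand();
    double y = y0;
    X(0, p) = 0.0;
    for (int k = 1; k <= n_steps; ++k) {
      w += sW * R::norm_rand();
      y = y * e + sOU * R::norm_rand();
      X(k, p) = w + y - y0;
    }
  }
  return X;
}

// ---- Rouse chain: first-monomer trajectories (1D per call) ---------------
// Normal modes a_p with rates lambda_p = 4 sin^2(p pi / 2N) evolved by
// exact OU steps; internal modes start in equilibrium, so the monomer has
// stationary increments.  Positions are returned relative to the start.
// [[Rcpp::export]]
NumericMatrix rouse_paths_cpp(int N, int n_steps, double dt, int n_paths) {
  NumericMatrix X(n_steps + 1, n_paths);
  std::vector<double> lam(N), phi1(N), eat(N), snoise(N), seq_(N);
  phi1[0] = 1.0 / std::sqrt((double)N);
  for (int p = 1; p < N; ++p) {
    lam[p] = 4.0 * std::pow(std::sin(p * M_PI / (2.0 * N)), 2);
    phi1[p] = std::sqrt(2.0 / N) * std::cos(p * M_PI * 0.5 / N);
    eat[p] = std::exp(-lam[p] * dt);
    seq_[p] = std::sqrt(1.0 / lam[p]);
    snoise[p] = seq_[p] * std::sqrt(1.0 - eat[p] * eat[p]);
  }
  const double s0 = std::sqrt(2.0 * dt);
  std::vector<double> a(N);
  for (int pp = 0; pp < n_paths; ++pp) {
    a[0] = 0.0;
    double x1 = 0.0;
    for (int p = 1; p < N; ++p) { a[p] = seq_[p] * R::norm_rand(); x1 += phi1[p] * a[p]; }
    const double xstart = x1;
    X(0, pp) = 0.0;
    for (int k = 1; k <= n_steps; ++k) {
      a[0] += s0 * R::norm_rand();
      double x = phi1[0] * a[0];
      for (int p = 1; p < N; ++p) {
        a[p] = a[p] * eat[p] + snoise[p] * R::norm_rand();
        x += phi1[p] * a[p];
      }
      X(k, pp) = x - xstart;
    }
  }
  return X;
}

// ---- confined two-target 2D Monte Carlo ----------------------------------
// Targets: absorbing disks of radius a at c1 = (0,0) and c2 = (L,0);
// specular reflection at radius R around c1; start at (x0, 0).
// process 0: per-coordinate bidiffusive (B >= 0); process 1: Rouse N beads
// (reflection shifts the whole chain).  After a hit the walk continues with
// reflection only, and the x-coordinate (projection on the target axis) is
// accumulated per lag for follow_steps.
// [[Rcpp::export]]
List confined2d_cpp(int process, double B, int N, double x0, double L,
                    double a, double R, double dt, int max_steps,
                    int n_paths, int follow_steps) {
  IntegerVector side(n_paths);
  NumericVector hit_time(n_paths, NA_REAL);
  NumericVector s1x(follow_steps), s2x(follow_steps);
  int n1 = 0, n2 = 0;
  // bidiffusive params
  const double e_ou = std::exp(-dt);
  const double sig_ou = std::sqrt(B / 2.0);
  const double s_ou = sig_ou * std::sqrt(1.0 - e_ou * e_ou);
  const double sW = std::sqrt(dt);
  // rouse params
  std::vector<double> lam, phi1, eat, snoise, seq_;
  double s0 = 0.0;
  if (process == 1) {
    lam.assign(N, 0.0); phi1.assign(N, 0.0); eat.assign(N, 0.0);
    snoise.assign(N, 0.0); seq_.assign(N, 0.0);
    phi1[0] = 1.0 / std::sqrt((double)N);
    for (int p = 1; p < N; ++p) {
      lam[p] = 4.0 * std::pow(std::sin(p * M_PI / (2.0 * N)), 2);
      phi1[p] = std::sqrt(2.0 / N) * std::cos(p * M_PI * 0.5 / N);
      eat[p] = std::exp(-lam[p] * dt);
      seq_[p] = std::sqrt(1.0 / lam[p]);
      snoise[p] = seq_[p] * std::sqrt(1.0 - eat[p] * eat[p]);
    }
    s0 = std::sqrt(2.0 * dt);
  }
  std::vector<double> ax, ay;
  if (process == 1) { ax.assign(N, 0.0); ay.assign(N, 0.0); }

  for (int p = 0; p < n_paths; ++p) {
    // state
    double wx = 0, wy = 0, yx0 = 0, yy0 = 0, yx = 0, yy = 0;
    double x = x0, yy_pos = 0.0;
    if (process == 0) {
      yx0 = sig_ou * R::norm_rand(); yy0 = sig_ou * R::norm_rand();
      yx = yx0; yy = yy0;
    } else {
      double ix = 0, iy = 0;
      for (int q = 1; q < N; ++q) {
        ax[q] = seq_[q] * R::norm_rand(); ay[q] = seq_[q] * R::norm_rand();
        ix += phi1[q] * ax[q]; iy += phi1[q] * ay[q];
      }
      ax[0] = (x0 - ix) / phi1[0]; ay[0] = (0.0 - iy) / phi1[0];
    }
    int hit = 0, khit = -1;
    double tfrac = 0.0;
    double px = x, py = yy_pos;
    int k = 0;
    int total = max_steps + (follow_steps > 0 ? follow_steps : 0);
    int post_j = -1;
    for (k = 1; k <= total; ++k) {
      // advance one exact step
      if (process == 0) {
        wx += sW * R::norm_rand(); wy += sW * R::norm_rand();
        yx = yx * e_ou + s_ou * R::norm_rand();
        yy = yy * e_ou + s_ou * R::norm_rand();
        x = x0 + wx + (yx - yx0);
        yy_pos = 0.0 + wy + (yy - yy0);
      } else {
        ax[0] += s0 * R::norm_rand(); ay[0] += s0 * R::norm_rand();
        x = phi1[0] * ax[0]; yy_pos = phi1[0] * ay[0];
        for (int q = 1; q < N; ++q) {
          ax[q] = ax[q] * eat[q] + snoise[q] * R::norm_rand();
          ay[q] = ay[q] * eat[q] + snoise[q] * R::norm_rand();
          x += phi1[q] * ax[q]; yy_pos += phi1[q] * ay[q];
        }
      }
      // reflection at radius R about c1
      const double rr = std::sqrt(x * x + yy_pos * yy_pos);
      if (rr > R) {
        const double scale = (2.0 * R - rr) / rr;
        const double dx = x * (scale - 1.0), dy = yy_pos * (scale - 1.0);
        x += dx; yy_pos += dy;
        if (process == 0) { wx += dx; wy += dy; }
        else { ax[0] += dx / phi1[0]; ay[0] += dy / phi1[0]; }
      }
      if (!hit) {
        // absorption checks
        const double d1 = std::sqrt(x * x + yy_pos * yy_pos);
        const double d2 = std::sqrt((x - L) * (x - L) + yy_pos * yy_pos);
        if (d1 <= a || d2 <= a) {
          hit = (d1 <= a) ? 1 : 2;
          khit = k;
          const double dprev = (hit == 1)
            ? std::sqrt(px * px + py * py)
            : std::sqrt((px - L) * (px - L) + py * py);
          const double dcur = (hit == 1) ? d1 : d2;
          tfrac = (dprev > dcur) ? (dprev - a) / (dprev - dcur) : 1.0;
          if (tfrac < 0) tfrac = 0; if (tfrac > 1) tfrac = 1;
          side[p] = hit;
          hit_time[p] = (khit - 1 + tfrac) * dt;
          if (follow_steps == 0) break;
          if (hit == 1) ++n1; else ++n2;
          // lag 0 = the first sampled position at/inside the target
          if (hit == 1) s1x[0] += x; else s2x[0] += x;
          post_j = 1;
          if (post_j >= follow_steps) break;
        }
        if (!hit && k >= max_steps) break;   // censored
      } else {
        if (post_j < follow_steps) {
          if (hit == 1) s1x[post_j] += x; else s2x[post_j] += x;
          ++post_j;
        }
        if (post_j >= follow_steps) break;
      }
      px = x; py = yy_pos;
    }
    if (p % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["side"] = side, _["hit_time"] = hit_time,
                      _["post1_x_sum"] = s1x, _["post1_n"] = n1,
                      _["post2_x_sum"] = s2x, _["post2_n"] = n2);
}

// ---- single-target 2D runs for propagator calibration --------------------
// One absorbing disk of radius a at the origin, reflecting circle radius R
// (also centred at the origin), start at distance L0 along +x.  For each
// path that hits, records the hit angle theta (relative to the axis from
// the target centre towards the start) and accumulates the post-hit
// displacement projected on the hit direction u(theta_hit).
// [[Rcpp::export]]
List single_target2d_cpp(int process, double B, int N, double L0,
                         double a, double R, double dt, int max_steps,
                         int n_paths, int follow_steps) {
  std::vector<double> thetas;
  NumericVector proj_sum(follow_steps), proj_sq(follow_steps);
  int n_events = 0, n_censored = 0;
  const double e_ou = std::exp(-dt);
  const double sig_ou = std::sqrt(B / 2.0);
  const double s_ou = sig_ou * std::sqrt(1.0 - e_ou * e_ou);
  const double sW = std::sqrt(dt);
  std::vector<double> lam, phi1, eat, snoise, seq_;
  double s0 = 0.0;
  if (process == 1) {
    lam.assign(N, 0.0); phi1.assign(N, 0.0); eat.assign(N, 0.0);
    snoise.assign(N, 0.0); seq_.assign(N, 0.0);
    phi1[0] = 1.0 / std::sqrt((double)N);
    for (int p = 1; p < N; ++p) {
      lam[p] = 4.0 * std::pow(std::sin(p * M_PI / (2.0 * N)), 2);
      phi1[p] = std::sqrt(2.0 / N) * std::cos(p * M_PI * 0.5 / N);
      eat[p] = std::exp(-lam[p] * dt);
      seq_[p] = std::sqrt(1.0 / lam[p]);
      snoise[p] = seq_[p] * std::sqrt(1.0 - eat[p] * eat[p]);
    }
    s0 = std::sqrt(2.0 * dt);
  }
  std::vector<double> ax, ay;
  if (process == 1) { ax.assign(N, 0.0); ay.assign(N, 0.0); }

  for (int p = 0; p < n_paths; ++p) {
    double wx = 0, wy = 0, yx0 = 0, yy0 = 0, yx = 0, yy = 0;
    double x = L0, ypos = 0.0;
    if (process == 0) {
      yx0 = sig_ou * R::norm_rand(); yy0 = sig_ou * R::norm_rand();
      yx = yx0; yy = yy0;
    } else {
      double ix = 0, iy = 0;
      for (int q = 1; q < N; ++q) {
        ax[q] = seq_[q] * R::norm_rand(); ay[q] = seq_[q] * R::norm_rand();
        ix += phi1[q] * ax[q]; iy += phi1[q] * ay[q];
      }
      ax[0] = (L0 - ix) / phi1[0]; ay[0] = (0.0 - iy) / phi1[0];
    }
    int hit = 0, post_j = -1;
    double ux = 0, uy = 0;
    const int total = max_steps + follow_steps;
    for (int k = 1; k <= total; ++k) {
      if (process == 0) {
        wx += sW * R::norm_rand(); wy += sW * R::norm_rand();
        yx = yx * e_ou + s_ou * R::norm_rand();
        yy = yy * e_ou + s_ou * R::norm_rand();
        x = L0 + wx + (yx - yx0);
        ypos = 0.0 + wy + (yy - yy0);
      } else {
        ax[0] += s0 * R::norm_rand(); ay[0] += s0 * R::norm_rand();
        x = phi1[0] * ax[0]; ypos = phi1[0] * ay[0];
        for (int q = 1; q < N; ++q) {
          ax[q] = ax[q] * eat[q] + snoise[q] * R::norm_rand();
          ay[q] = ay[q] * eat[q] + snoise[q] * R::norm_rand();
          x += phi1[q] * ax[q]; ypos += phi1[q] * ay[q];
        }
      }
      const double rr = std::sqrt(x * x + ypos * ypos);
      if (rr > R) {
        const double scale = (2.0 * R - rr) / rr;
        const double dx = x * (scale - 1.0), dy = ypos * (scale - 1.0);
        x += dx; ypos += dy;
        if (process == 0) { wx += dx; wy += dy; }
        else { ax[0] += dx / phi1[0]; ay[0] += dy / phi1[0]; }
      }
      if (!hit) {
        if (rr <= a) {
          hit = 1;
          ++n_events;
          const double th = std::atan2(ypos, x);   // axis to start = +x
          thetas.push_back(th);
          ux = std::cos(th); uy = std::sin(th);
          if (follow_steps == 0) break;
          const double sproj = x * ux + ypos * uy;
          proj_sum[0] += sproj; proj_sq[0] += sproj * sproj;
          post_j = 1;
          if (post_j >= follow_steps) break;
        } else if (k >= max_steps) { ++n_censored; break; }
      } else {
        if (post_j < follow_steps) {
          const double s = x * ux + ypos * uy;
          proj_sum[post_j] += s; proj_sq[post_j] += s * s;
          ++post_j;
        }
        if (post_j >= follow_steps) break;
      }
    }
    if (p % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["theta"] = wrap(thetas),
                      _["proj_sum"] = proj_sum, _["proj_sq"] = proj_sq,
                      _["n_events"] = n_events, _["n_censored"] = n_censored);
}
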