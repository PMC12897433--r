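#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Greedy Hough line extraction on point coordinates (x right, y up).
//
// Builds the (theta, rho) accumulator over a theta grid covering [0, 180)
// degrees, then repeatedly takes the highest remaining cell, optionally
// refines the line by an iterated principal-axis fit to its inlier points,
// removes the inliers' accumulator contributions, and applies non-maximum
// suppression (theta wraps at 180 with rho mirrored). Stops below min_votes
// or at max_lines.
//
// Returns a list with vectors rho, theta (degrees) and votes.
// [[Rcpp::export(name = ".hough_detect")]]
List hough_detect(NumericVector x, NumericVector y,
                  double theta_step, double rho_step,
                  double min_votes, int max_lines, int nms_window,
                  bool refine, double diag_len) {
  const int n = x.size();
  const int nth = (int)std::lround(180.0 / theta_step);
  const int D = (int)std::ceil(diag_len / rho_step);
  const int nrho = 2 * D + 1;
  const double deg2rad = M_PI / 180.0;

  std::vector<double> cth(nth), sth(nth);
  for (int t = 0; t < nth; ++t) {
    double a = t * theta_step * deg2rad;
    cth[t] = std::cos(a);
    sth[t] = std::sin(a);
  }

  auto rbin = [&](double xi, double yi, int t) {
    return (int)std::lround((xi * cth[t] + yi * sth[t]) / rho_step) + D;
  };

  std::vector<int> acc((size_t)nth * nrho, 0);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < nth; ++t)
      ++acc[(size_t)t * nrho + rbin(x[i], y[i], t)];

  std::vector<bool> suppressed((size_t)nth * nrho, false);
  std::vector<bool> alive(n, true);
  std::vector<double> out_rho, out_theta, out_votes;
  std::vector<int> inl;
  inl.reserve(n);

  while ((int)out_rho.size() < max_lines) {
    // highest unsuppressed cell
    int best = -1;
    size_t best_idx = 0;
    for (size_t j = 0; j < acc.size(); ++j) {
      if (!suppressed[j] && acc[j] > best) { best = acc[j]; best_idx = j; }
    }
    if (best < min_votes || best < 1) break;
    int pt = (int)(best_idx / nrho);
    int pr = (int)(best_idx % nrho);
    double theta = pt * theta_step;
    double rho = (double)(pr - D) * rho_step;
    double phi = theta * deg2rad;

    // collect the remaining points within a rho band of the line
    auto collect = [&](double phi_, double rho_, double tol,
                       std::vector<int> &dst) {
      dst.clear();
      double c = std::cos(phi_), s = std::sin(phi_);
      for (int i = 0; i < n; ++i) {
        if (!alive[i]) continue;
        if (std::fabs(x[i] * c + y[i] * s - rho_) <= tol) dst.push_back(i);
      }
    };
    collect(phi, rho, 3.0 * rho_step, inl);
    if (refine && inl.size() >= 2) {
      // principal-axis fits on a shrinking band: the wide pass locks onto the
      // fiber, the narrow passes drop the aliased band edges that bias the
      // orientation of rasterized diagonal fibers
      static const double tols[] = {3.0, 2.5, 2.0};
      std::vector<int> fit = inl;
      for (double tol : tols) {
        if (fit.size() < 2) break;
        double mx = 0, my = 0;
        for (int i : fit) { mx += x[i]; my += y[i]; }
        mx /= fit.size(); my /= fit.size();
        double cxx = 0, cyy = 0, cxy = 0;
        for (int i : fit) {
          double dx = x[i] - mx, dy = y[i] - my;
          cxx += dx * dx; cyy += dy * dy; cxy += dx * dy;
        }
        if (cxx + cyy <= 0) break;
        // 0.5 * atan2 lies in (-pi/2, pi/2]; wrap by hand (no fmod)
        double dir = 0.5 * std::atan2(2.0 * cxy, cxx - cyy);
        if (dir < 0) dir += M_PI;            // orientation in [0, pi)
        double phi2 = dir - M_PI / 2.0;      // normal angle
        if (phi2 < 0) phi2 += M_PI;
        double rho2 = mx * std::cos(phi2) + my * std::sin(phi2);
        theta = phi2 / deg2rad;
        rho = rho2;
        collect(phi2, rho2, tol * rho_step, fit);
      }
      // claim the full band of the refined line for removal
      collect(theta * deg2rad, rho, 3.0 * rho_step, inl);
    }

    out_rho.push_back(rho);
    out_theta.push_back(theta);
    out_votes.push_back((double)best);

    // remove claimed points from the accumulator
    for (int i : inl) {
      alive[i] = false;
      for (int t = 0; t < nth; ++t)
        --acc[(size_t)t * nrho + rbin(x[i], y[i], t)];
    }
    // non-maximum suppression around the grid peak, wrapping theta
    for (int dt = -nms_window; dt <= nms_window; ++dt) {
      int t2 = pt + dt;
      int r2 = pr;
      if (t2 < 0) { t2 += nth; r2 = nrho - 1 - pr; }
      else if (t2 >= nth) { t2 -= nth; r2 = nrho - 1 - pr; }
      int lo = std::max(0, r2 - nms_window);
      int hi = std::min(nrho - 1, r2 + nms_window);
      for (int r = lo; r <= hi; ++r) suppressed[(size_t)t2 * nrho + r] = true;
    }
  }

  return List::create(_["rho"] = wrap(out_rho),
                      _["theta"] = wrap(out_theta),
                      _["votes"] = wrap(out_votes));
}
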