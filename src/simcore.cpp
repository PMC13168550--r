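#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sequential spatial inhibition: each territory centre is drawn uniformly on
// the [0, edge]^2 landscape and accepted only if at least inhibit_r from every
// centre already placed.  After max_attempts failures the bird is placed
// unconstrained (counted in n_fallback).
// [[Rcpp::export]]
List place_inhibited_cpp(int n, double edge, double inhibit_r,
                         int max_attempts) {
  NumericVector x(n), y(n);
  int n_fallback = 0;
  const double r2 = inhibit_r * inhibit_r;
  for (int i = 0; i < n; ++i) {
    bool placed = false;
    for (int a = 0; a < max_attempts && !placed; ++a) {
      double px = R::runif(0.0, edge), py = R::runif(0.0, edge);
      bool ok = true;
      for (int k = 0; k < i; ++k) {
        double dx = px - x[k], dy = py - y[k];
        if (dx * dx + dy * dy < r2) { ok = false; break; }
      }
      if (ok) { x[i] = px; y[i] = py; placed = true; }
    }
    if (!placed) {
      x[i] = R::runif(0.0, edge);
      y[i] = R::runif(0.0, edge);
      ++n_fallback;
    }
  }
  return List::create(_["x"] = x, _["y"] = y, _["n_fallback"] = n_fallback);
}

// Semi-regular ("soft") spacing: each proposal is accepted with probability
// 1 - exp(-(d/xy_scale)^2), d the distance to the nearest centre already
// placed; after max_attempts rejections the bird is placed unconstrained
// (counted in n_fallback).  The first bird is always accepted.
// [[Rcpp::export]]
List place_semiregular_cpp(int n, double edge, double xy_scale,
                           int max_attempts) {
  NumericVector x(n), y(n);
  int n_fallback = 0;
  const double s2 = xy_scale * xy_scale;
  for (int i = 0; i < n; ++i) {
    bool placed = false;
    double px = 0.0, py = 0.0;
    for (int a = 0; a < max_attempts && !placed; ++a) {
      px = R::runif(0.0, edge);
      py = R::runif(0.0, edge);
      if (i == 0) { placed = true; break; }
      double d2min = R_PosInf;
      for (int k = 0; k < i; ++k) {
        double dx = px - x[k], dy = py - y[k];
        double d2 = dx * dx + dy * dy;
        if (d2 < d2min) d2min = d2;
      }
      if (R::unif_rand() < 1.0 - std::exp(-d2min / s2)) placed = true;
    }
    if (!placed) ++n_fallback;  // keep the last proposal unconstrained
    x[i] = px; y[i] = py;
  }
  return List::create(_["x"] = x, _["y"] = y, _["n_fallback"] = n_fallback);
}

// Simulate n_visits independent point-count visits to a fixed set of birds.
// Per bird and visit: relocation events are a Poisson process at
// movement_rate over [0, duration]; the initial position and the position
// after each relocation are independent draws from a bivariate normal centred
// on the nest with per-axis SD movement_sd (sd = 0 pins the bird at its
// nest).  Cue emissions are an independent Poisson process at cue_rate; a cue
// at time t is produced from the position current at t and is detected with
// probability exp(-(d/edr)^2) where d is its distance to the observer.  The
// visit records a detection iff any cue from any bird is detected; birds are
// skipped once the visit is detected (the remaining cues cannot change the
// binary outcome and are independent of it).
// [[Rcpp::export]]
IntegerVector simulate_visits_cpp(NumericVector nest_x, NumericVector nest_y,
                                  double movement_sd, double movement_rate,
                                  double cue_rate, double duration,
                                  double edr, int n_visits,
                                  double obs_x, double obs_y) {
  const int nb = nest_x.size();
  const double tau2 = edr * edr;
  IntegerVector det(n_visits);
  std::vector<double> mt, posx, posy;
  for (int j = 0; j < n_visits; ++j) {
    int found = 0;
    for (int b = 0; b < nb && !found; ++b) {
      int ncue = (int)R::rpois(cue_rate * duration);
      if (ncue == 0) continue;
      int nmove = 0;
      if (movement_sd > 0.0 && movement_rate > 0.0)
        nmove = (int)R::rpois(movement_rate * duration);
      mt.resize(nmove);
      for (int k = 0; k < nmove; ++k) mt[k] = R::runif(0.0, duration);
      std::sort(mt.begin(), mt.end());
      const int npos = nmove + 1;
      posx.resize(npos); posy.resize(npos);
      for (int k = 0; k < npos; ++k) {
        if (movement_sd > 0.0) {
          posx[k] = nest_x[b] + R::norm_rand() * movement_sd;
          posy[k] = nest_y[b] + R::norm_rand() * movement_sd;
        } else {
          posx[k] = nest_x[b]; posy[k] = nest_y[b];
        }
      }
      for (int c = 0; c < ncue && !found; ++c) {
        double t = R::runif(0.0, duration);
        int idx = (int)(std::upper_bound(mt.begin(), mt.end(), t) - mt.begin());
        double dx = posx[idx] - obs_x, dy = posy[idx] - obs_y;
        double g = std::exp(-(dx * dx + dy * dy) / tau2);
        if (R::unif_rand() < g) found = 1;
      }
    }
    det[j] = found;
  }
  return det;
}
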