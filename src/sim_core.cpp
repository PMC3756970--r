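#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Neighbour slot order shared with the R side: N, NE, E, SE, S, SW, W, NW.
static const double BEARING[8] = {0, 45, 90, 135, 180, 225, 270, 315};

// Weighted scores of the 8 neighbours of `cell0` (0-based, column-major).
// nbIdx: ncells x 8, 0-based neighbour index, -1 for land/out-of-grid.
// staticScore: ncells x 12 precomputed static-parameter score of each cell.
// speed/dir: ncells x 12 monthly current fields (of the *current* cell).
// Returns raw scores; negative total signals "no marine neighbour".
static int neighbour_scores(int cell0, int month1,
                            const IntegerMatrix &nbIdx,
                            const NumericMatrix &staticScore,
                            const NumericMatrix &speed,
                            const NumericMatrix &dir,
                            const NumericVector &maxSpeed,
                            double wOC, double *sc, double *total) {
  int m = month1 - 1;
  double sp = speed(cell0, m);
  double dr = dir(cell0, m);
  double ms = maxSpeed[m];
  double rel = (ms > 0.0) ? sp / ms : 0.0;
  int nMarine = 0;
  *total = 0.0;
  for (int k = 0; k < 8; ++k) {
    int nb = nbIdx(cell0, k);
    if (nb < 0) { sc[k] = -1.0; continue; }
    ++nMarine;
    double ca = cos((dr - BEARING[k]) * M_PI / 180.0);
    double a = (ca > 0.0 ? ca : 0.0) * rel;
    double s = wOC * a + staticScore(nb, m);
    sc[k] = s;
    *total += s;
  }
  return nMarine;
}

// [[Rcpp::export]]
NumericVector cpp_neighbor_probs(int cell0, int month1, IntegerMatrix nbIdx,
                                 NumericMatrix staticScore, NumericMatrix speed,
                                 NumericMatrix dir, NumericVector maxSpeed,
                                 double wOC) {
  double sc[8], total;
  int nMarine = neighbour_scores(cell0, month1, nbIdx, staticScore, speed, dir,
                                 maxSpeed, wOC, sc, &total);
  NumericVector out(8);
  if (nMarine == 0) { std::fill(out.begin(), out.end(), NA_REAL); return out; }
  for (int k = 0; k < 8; ++k) {
    if (sc[k] < 0.0) out[k] = 0.0;
    else out[k] = (total > 0.0) ? sc[k] / total : 1.0 / nMarine;
  }
  return out;
}

// Random walk of one kernel until the cumulative transit time reaches the
// larval duration D (days).  Dwell per hop is the destination cell's width
// divided by its (floored) current speed; monthly fields advance at each
// 30-day mark of the running sum.  One unif_rand() call per hop.
// Returns (finalCell0 or -1, elapsedDays, hops, endMonth1, dead).
// [[Rcpp::export]]
NumericVector cpp_trace_transit(int origin0, int startMonth1, double durationDays,
                                IntegerMatrix nbIdx, NumericMatrix staticScore,
                                NumericMatrix speed, NumericMatrix dir,
                                NumericVector maxSpeed, NumericVector cellWidth,
                                double speedFloor, double wOC) {
  double elapsed = 0.0;
  int cell = origin0;
  int hops = 0;
  double sc[8], total;
  int month1 = startMonth1;
  while (elapsed < durationDays) {
    month1 = ((startMonth1 - 1 + (int)std::floor(elapsed / 30.0)) % 12) + 1;
    int nMarine = neighbour_scores(cell, month1, nbIdx, staticScore, speed, dir,
                                   maxSpeed, wOC, sc, &total);
    if (nMarine == 0)
      return NumericVector::create(-1, elapsed, hops, month1, 1);
    double u = unif_rand();
    int chosen = -1;
    if (total > 0.0) {
      double acc = 0.0, target = u * total;
      for (int k = 0; k < 8; ++k) {
        if (sc[k] < 0.0) continue;
        acc += sc[k];
        if (target <= acc) { chosen = k; break; }
      }
      if (chosen < 0) for (int k = 7; k >= 0; --k) if (sc[k] >= 0.0) { chosen = k; break; }
    } else {
      int target = (int)std::floor(u * nMarine);
      if (target >= nMarine) target = nMarine - 1;
      int seen = 0;
      for (int k = 0; k < 8; ++k) {
        if (sc[k] < 0.0) continue;
        if (seen == target) { chosen = k; break; }
        ++seen;
      }
    }
    cell = nbIdx(cell, chosen);
    double sp = speed(cell, month1 - 1);
    if (sp < speedFloor) sp = speedFloor;
    elapsed += cellWidth[cell] / (sp * 86400.0);
    ++hops;
  }
  int endMonth1 = ((startMonth1 - 1 + (int)std::floor(elapsed / 30.0)) % 12) + 1;
  return NumericVector::create(cell, elapsed, hops, endMonth1, 0);
}

// Exact distribution of S = sum(d^2) for Spearman's rho over all n!
// permutations.  S is always even; counts[s/2] = number of permutations.
// [[Rcpp::export]]
NumericVector cpp_spearman_exact_counts(int n) {
  if (n < 1 || n > 10) stop("exact enumeration supported for 1 <= n <= 10");
  int maxS = n * (n * n - 1) / 3;
  std::vector<double> counts(maxS / 2 + 1, 0.0);
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i + 1;
  do {
    int S = 0;
    for (int i = 0; i < n; ++i) {
      int d = (i + 1) - perm[i];
      S += d * d;
    }
    counts[S / 2] += 1.0;
  } while (std::next_permutation(perm.begin(), perm.end()));
  return wrap(counts);
}

// Monte-Carlo analogue: tallies S over `draws` uniformly random rank
// permutations (Fisher-Yates on R's RNG stream).
// [[Rcpp::export]]
NumericVector cpp_spearman_mc_counts(int n, double draws) {
  if (n < 2) stop("n must be >= 2");
  int maxS = n * (n * n - 1) / 3;
  std::vector<double> counts(maxS / 2 + 1, 0.0);
  std::vector<int> perm(n);
  long long nd = (long long)draws;
  for (long long it = 0; it < nd; ++it) {
    for (int i = 0; i < n; ++i) perm[i] = i + 1;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    int S = 0;
    for (int i = 0; i < n; ++i) {
      int d = (i + 1) - perm[i];
      S += d * d;
    }
    counts[S / 2] += 1.0;
  }
  return wrap(counts);
}
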