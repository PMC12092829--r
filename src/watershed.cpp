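// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas, applied separably along the three axes) and a
// deterministic seeded 3D watershed flooding on the negated distance map.

#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform of sampled function f, result into d.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared EDT of a binary mask: distance from each TRUE voxel to the nearest
// FALSE voxel (in voxel units).  Array layout (Z, Y, X) column-major.
// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(LogicalVector mask) {
  IntegerVector dm = mask.attr("dim");
  if (dm.size() != 3) stop("mask must be a 3D array");
  const int Z = dm[0], Y = dm[1], X = dm[2];
  const long n = (long)Z * Y * X;
  NumericVector d(n);
  d.attr("dim") = dm;
  double* dp = REAL(d);
  const int* mp = LOGICAL(mask);
  // finite sentinel instead of infinity: the parabola intersection in dt1d
  // is ill-defined (INF - INF) for infinite sample values
  const double LARGE = 1.0 + (double)Z * Z + (double)Y * Y + (double)X * X;
  for (long i = 0; i < n; ++i) dp[i] = mp[i] ? LARGE : 0.0;

  const int nmax = std::max(Z, std::max(Y, X));
  std::vector<double> f(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along z (stride 1)
  for (long c = 0; c < (long)Y * X; ++c) {
    double* line = dp + c * Z;
    for (int i = 0; i < Z; ++i) f[i] = line[i];
    dt1d(f, out, Z, v, z);
    for (int i = 0; i < Z; ++i) line[i] = out[i];
  }
  // pass along y (stride Z)
  for (int x = 0; x < X; ++x)
    for (int zz = 0; zz < Z; ++zz) {
      double* base = dp + zz + (long)x * Z * Y;
      for (int i = 0; i < Y; ++i) f[i] = base[(long)i * Z];
      dt1d(f, out, Y, v, z);
      for (int i = 0; i < Y; ++i) base[(long)i * Z] = out[i];
    }
  // pass along x (stride Z*Y)
  for (int y = 0; y < Y; ++y)
    for (int zz = 0; zz < Z; ++zz) {
      double* base = dp + zz + (long)y * Z;
      for (int i = 0; i < X; ++i) f[i] = base[(long)i * Z * Y];
      dt1d(f, out, X, v, z);
      for (int i = 0; i < X; ++i) base[(long)i * Z * Y] = out[i];
    }
  return d;
}

// h-maxima seed detection.
//
// The discrete EDT of a smooth cell body is a staircase: its medial ridge
// carries many small plateaus that are all local maxima, so naive peak
// picking oversegments badly.  The classical fix is the h-maxima transform:
// morphological reconstruction of (dist - h) under dist flattens every
// peak's top h-slab into a single connected plateau, so peaks with
// prominence < h vanish and each h-prominent peak yields exactly one
// connected regional maximum.  One representative voxel (deepest, ties by
// lowest linear index) is taken per such region, then representatives are
// greedily suppressed to a minimum pairwise separation.
// Returns 1-based linear indices of the accepted seeds.
// [[Rcpp::export(name = ".hmax_seeds")]]
IntegerVector hmax_seeds(NumericVector dist, double h, double min_sep) {
  IntegerVector dm = dist.attr("dim");
  const int Z = dm[0], Y = dm[1], X = dm[2];
  const long n = (long)Z * Y * X;
  const long ZY = (long)Z * Y;
  const double* dp = REAL(dist);

  // morphological reconstruction of (dist - h) under dist, by priority flood
  std::vector<double> rec(n);
  typedef std::pair<double, long> QN;
  std::priority_queue<QN> pq;
  for (long i = 0; i < n; ++i) {
    rec[i] = dp[i] > h ? dp[i] - h : 0.0;
    if (rec[i] > 0) pq.push(QN(rec[i], -i));
  }
  std::vector<long> nb;
  nb.reserve(26);
  auto neighbours = [&](long i, std::vector<long>& out) {
    out.clear();
    const int zz = (int)(i % Z), y = (int)((i / Z) % Y), x = (int)(i / ZY);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (!dx && !dy && !dz) continue;
          const int nz = zz + dz, ny = y + dy, nx = x + dx;
          if (nz < 0 || nz >= Z || ny < 0 || ny >= Y || nx < 0 || nx >= X)
            continue;
          out.push_back(nz + (long)ny * Z + (long)nx * ZY);
        }
  };
  while (!pq.empty()) {
    QN t = pq.top();
    pq.pop();
    const long i = -t.second;
    if (t.first < rec[i]) continue;  // stale entry
    neighbours(i, nb);
    for (long j : nb) {
      const double v = std::min(rec[i], dp[j]);
      if (v > rec[j]) {
        rec[j] = v;
        pq.push(QN(v, -j));
      }
    }
  }

  // regional maxima of the reconstruction: connected plateaus of constant
  // rec value none of whose voxels has a strictly higher neighbour (the
  // per-voxel test is not enough — a plateau that drains into a higher
  // region further along is not a regional maximum)
  std::vector<char> seen(n, 0);
  std::vector<std::pair<double, long>> reps;
  std::vector<long> stack, region;
  for (long i = 0; i < n; ++i) {
    if (seen[i] || rec[i] <= 0) continue;
    const double level = rec[i];
    bool is_regional_max = true;
    double bestd = dp[i];
    long besti = i;
    stack.clear();
    region.clear();
    stack.push_back(i);
    seen[i] = 1;
    while (!stack.empty()) {
      const long p = stack.back();
      stack.pop_back();
      region.push_back(p);
      if (dp[p] > bestd || (dp[p] == bestd && p < besti)) {
        bestd = dp[p];
        besti = p;
      }
      neighbours(p, nb);
      for (long j : nb) {
        if (rec[j] > level) is_regional_max = false;
        else if (rec[j] == level && !seen[j]) {
          seen[j] = 1;
          stack.push_back(j);
        }
      }
    }
    if (is_regional_max) reps.push_back({bestd, besti});
  }
  std::sort(reps.begin(), reps.end(), [](const std::pair<double, long>& a,
                                         const std::pair<double, long>& b) {
    if (a.first != b.first) return a.first > b.first;
    return a.second < b.second;
  });
  std::vector<long> acc;
  const double min_sep2 = min_sep * min_sep;
  for (auto& c : reps) {
    const long i = c.second;
    const double zi = i % Z, yi = (i / Z) % Y, xi = i / ZY;
    bool ok = true;
    for (long a : acc) {
      const double za = a % Z, ya = (a / Z) % Y, xa = a / ZY;
      const double d2 = (zi - za) * (zi - za) + (yi - ya) * (yi - ya) +
                        (xi - xa) * (xi - xa);
      if (d2 < min_sep2) { ok = false; break; }
    }
    if (ok) acc.push_back(i);
  }
  IntegerVector out(acc.size());
  for (size_t k = 0; k < acc.size(); ++k) out[k] = (int)(acc[k] + 1);
  return out;
}

// Seeded watershed: flood the mask from the seeds in order of decreasing
// distance (deepest catchment first on the negated distance map).
// Deterministic: the priority queue breaks distance ties by lower linear
// index.  26-connectivity.  Returns integer labels, 0 outside the mask.
// [[Rcpp::export(name = ".watershed_flood")]]
IntegerVector watershed_flood(LogicalVector mask, NumericVector dist,
                              IntegerVector seeds) {
  IntegerVector dm = mask.attr("dim");
  const int Z = dm[0], Y = dm[1], X = dm[2];
  const long n = (long)Z * Y * X;
  const int* mp = LOGICAL(mask);
  const double* dp = REAL(dist);
  IntegerVector lab(n);
  lab.attr("dim") = dm;
  int* lp = INTEGER(lab);

  typedef std::tuple<double, long, int> Node;  // (dist, -index, label)
  auto cmp = [](const Node& a, const Node& b) {
    if (std::get<0>(a) != std::get<0>(b)) return std::get<0>(a) < std::get<0>(b);
    return std::get<1>(a) < std::get<1>(b);  // higher -index == lower index wins
  };
  std::priority_queue<Node, std::vector<Node>, decltype(cmp)> pq(cmp);

  for (int k = 0; k < seeds.size(); ++k) {
    const long i = seeds[k] - 1;
    lp[i] = k + 1;
    pq.push(Node(dp[i], -i, k + 1));
  }
  const long ZY = (long)Z * Y;
  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    const long i = -std::get<1>(nd);
    const int label = std::get<2>(nd);
    const int zz = (int)(i % Z), y = (int)((i / Z) % Y), x = (int)(i / ZY);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (!dx && !dy && !dz) continue;
          const int nz = zz + dz, ny = y + dy, nx = x + dx;
          if (nz < 0 || nz >= Z || ny < 0 || ny >= Y || nx < 0 || nx >= X)
            continue;
          const long j = nz + (long)ny * Z + (long)nx * ZY;
          if (!mp[j] || lp[j]) continue;
          lp[j] = label;
          pq.push(Node(dp[j], -j, label));
        }
  }
  return lab;
}
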