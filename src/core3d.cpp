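#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// 6-connected neighbor offsets are generated on the fly from (d1,d2,d3)
// column-major indexing: idx = x + d1*(y + d2*z)

static inline void get_xyz(int idx, int d1, int d2, int &x, int &y, int &z) {
  x = idx % d1;
  int r = idx / d1;
  y = r % d2;
  z = r / d2;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  int d1 = dims[0], d2 = dims[1], d3 = (dims.size() > 2) ? dims[2] : 1;
  int n = d1 * d2 * d3;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::queue<int> q;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      int x, y, z; get_xyz(v, d1, d2, x, y, z);
      const int nb[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int k = 0; k < 6; ++k) {
        int xx = x + nb[k][0], yy = y + nb[k][1], zz = z + nb[k][2];
        if (xx < 0 || xx >= d1 || yy < 0 || yy >= d2 || zz < 0 || zz >= d3) continue;
        int w = xx + d1 * (yy + d2 * zz);
        if (mask[w] && lab[w] == 0) { lab[w] = cur; q.push(w); }
      }
    }
  }
  return lab;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher), anisotropic step h
static void dt1d(std::vector<double> &f, std::vector<double> &d, double h, int n) {
  std::vector<int> v(n);
  std::vector<double> zz(n + 1);
  int k = 0;
  v[0] = 0; zz[0] = -INFINITY; zz[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + h * h * q * q) - (f[v[k]] + h * h * v[k] * v[k])) /
          (2.0 * h * h * q - 2.0 * h * h * v[k]);
      if (s <= zz[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; zz[k] = s; zz[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zz[k + 1] < q) ++k;
    double dq = h * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// squared Euclidean distance (physical units per `spacing`) from each
// foreground voxel to the nearest background voxel; background voxels get 0
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector fg, IntegerVector dims, NumericVector spacing) {
  int d1 = dims[0], d2 = dims[1], d3 = (dims.size() > 2) ? dims[2] : 1;
  double h1 = spacing[0], h2 = spacing[1], h3 = (spacing.size() > 2) ? spacing[2] : 1.0;
  int n = d1 * d2 * d3;
  NumericVector D(n);
  const double BIG = 1e30;
  for (int i = 0; i < n; ++i) D[i] = fg[i] ? BIG : 0.0;
  // pass along x
  {
    std::vector<double> f(d1), d(d1);
    for (int z = 0; z < d3; ++z) for (int y = 0; y < d2; ++y) {
      int base = d1 * (y + d2 * z);
      for (int x = 0; x < d1; ++x) f[x] = D[base + x];
      dt1d(f, d, h1, d1);
      for (int x = 0; x < d1; ++x) D[base + x] = d[x];
    }
  }
  // pass along y
  {
    std::vector<double> f(d2), d(d2);
    for (int z = 0; z < d3; ++z) for (int x = 0; x < d1; ++x) {
      for (int y = 0; y < d2; ++y) f[y] = D[x + d1 * (y + d2 * z)];
      dt1d(f, d, h2, d2);
      for (int y = 0; y < d2; ++y) D[x + d1 * (y + d2 * z)] = d[y];
    }
  }
  // pass along z
  if (d3 > 1) {
    std::vector<double> f(d3), d(d3);
    for (int y = 0; y < d2; ++y) for (int x = 0; x < d1; ++x) {
      for (int z = 0; z < d3; ++z) f[z] = D[x + d1 * (y + d2 * z)];
      dt1d(f, d, h3, d3);
      for (int z = 0; z < d3; ++z) D[x + d1 * (y + d2 * z)] = d[z];
    }
  }
  return D;
}

// Gibbs sampling of a K-state Potts model restricted to `mask`, with an
// external field log-weight per class. Uses R's RNG, so set.seed() upstream
// makes the draw reproducible. Labels are 1..K inside the mask, 0 outside.
// [[Rcpp::export]]
IntegerVector cpp_gibbs_potts(IntegerVector labels, IntegerVector dims,
                              LogicalVector mask, int K, double beta,
                              int sweeps, NumericVector logw) {
  int d1 = dims[0], d2 = dims[1], d3 = (dims.size() > 2) ? dims[2] : 1;
  int n = d1 * d2 * d3;
  IntegerVector lab = clone(labels);
  std::vector<double> p(K);
  const int nb[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  for (int s = 0; s < sweeps; ++s) {
    for (int v = 0; v < n; ++v) {
      if (!mask[v]) continue;
      int x, y, z; get_xyz(v, d1, d2, x, y, z);
      int cnt[32] = {0};
      for (int k = 0; k < 6; ++k) {
        int xx = x + nb[k][0], yy = y + nb[k][1], zz = z + nb[k][2];
        if (xx < 0 || xx >= d1 || yy < 0 || yy >= d2 || zz < 0 || zz >= d3) continue;
        int w = xx + d1 * (yy + d2 * zz);
        if (mask[w]) cnt[lab[w] - 1]++;
      }
      double mx = -INFINITY;
      for (int k = 0; k < K; ++k) {
        p[k] = logw[k] + beta * cnt[k];
        if (p[k] > mx) mx = p[k];
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { p[k] = std::exp(p[k] - mx); tot += p[k]; }
      double u = unif_rand() * tot, acc = 0.0;
      int pick = K - 1;
      for (int k = 0; k < K; ++k) { acc += p[k]; if (u <= acc) { pick = k; break; } }
      lab[v] = pick + 1;
    }
  }
  return lab;
}

// Exchange (Kawasaki/swap) Gibbs dynamics of the Potts model restricted to
// `mask`: label swaps between random in-mask voxel pairs, Metropolis-accepted
// on the Potts energy change. Conserves the class composition exactly while
// coarsening boundaries, so planted class fractions survive any coupling.
// Uses R's RNG for reproducibility.
// [[Rcpp::export]]
IntegerVector cpp_swap_potts(IntegerVector labels, IntegerVector dims,
                             LogicalVector mask, double beta, int sweeps) {
  int d1 = dims[0], d2 = dims[1], d3 = (dims.size() > 2) ? dims[2] : 1;
  int n = d1 * d2 * d3;
  IntegerVector lab = clone(labels);
  std::vector<int> inmask;
  inmask.reserve(n);
  for (int v = 0; v < n; ++v) if (mask[v]) inmask.push_back(v);
  int m = (int)inmask.size();
  if (m < 2) return lab;
  const int nb[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  auto disagree = [&](int v, int l) {
    int x, y, z; get_xyz(v, d1, d2, x, y, z);
    int d = 0;
    for (int k = 0; k < 6; ++k) {
      int xx = x + nb[k][0], yy = y + nb[k][1], zz = z + nb[k][2];
      if (xx < 0 || xx >= d1 || yy < 0 || yy >= d2 || zz < 0 || zz >= d3) continue;
      int w = xx + d1 * (yy + d2 * zz);
      if (mask[w] && lab[w] != l) ++d;
    }
    return d;
  };
  for (int s = 0; s < sweeps; ++s) {
    for (int i = 0; i < m; ++i) {
      int v = inmask[i];
      int w = inmask[(int)(unif_rand() * m) % m];
      if (lab[v] == lab[w]) continue;
      int before = disagree(v, lab[v]) + disagree(w, lab[w]);
      int lv = lab[v], lw = lab[w];
      lab[v] = lw; lab[w] = lv;
      int after = disagree(v, lab[v]) + disagree(w, lab[w]);
      double dE = beta * (after - before);
      if (dE > 0 && unif_rand() >= std::exp(-dE)) { lab[v] = lv; lab[w] = lw; }
    }
  }
  return lab;
}

static double total_energy(const IntegerVector &lab, const LogicalVector &mask,
                           int d1, int d2, int d3,
                           const NumericVector &intens, const NumericVector &mu,
                           double sigma, const NumericVector &logpi, double beta) {
  int n = d1 * d2 * d3;
  double e = 0.0;
  double lsig = std::log(sigma);
  for (int v = 0; v < n; ++v) {
    if (!mask[v]) continue;
    int k = lab[v] - 1;
    double r = intens[v] - mu[k];
    e += r * r / (2.0 * sigma * sigma) + lsig - logpi[k];
    // count each unordered neighbor pair once (forward neighbors)
    int x, y, z; get_xyz(v, d1, d2, x, y, z);
    const int fw[3][3] = {{1,0,0},{0,1,0},{0,0,1}};
    for (int j = 0; j < 3; ++j) {
      int xx = x + fw[j][0], yy = y + fw[j][1], zz = z + fw[j][2];
      if (xx >= d1 || yy >= d2 || zz >= d3) continue;
      int w = xx + d1 * (yy + d2 * zz);
      if (mask[w] && lab[w] != lab[v]) e += beta;
    }
  }
  return e;
}

// ICM sweeps in fixed raster order at fixed parameters. Returns the updated
// labels, the energy after each sweep, and the number of label changes per
// sweep. Stops early when a sweep changes nothing.
// [[Rcpp::export]]
List cpp_icm_sweeps(IntegerVector labels, IntegerVector dims, LogicalVector mask,
                    NumericVector intens, NumericVector mu, double sigma,
                    NumericVector logpi, double beta, int max_sweeps) {
  int d1 = dims[0], d2 = dims[1], d3 = (dims.size() > 2) ? dims[2] : 1;
  int n = d1 * d2 * d3;
  int K = mu.size();
  IntegerVector lab = clone(labels);
  std::vector<double> energies;
  std::vector<int> changes;
  double lsig = std::log(sigma);
  const int nb[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  for (int s = 0; s < max_sweeps; ++s) {
    int ch = 0;
    for (int v = 0; v < n; ++v) {
      if (!mask[v]) continue;
      int x, y, z; get_xyz(v, d1, d2, x, y, z);
      int cnt[32] = {0};
      int nnb = 0;
      for (int k = 0; k < 6; ++k) {
        int xx = x + nb[k][0], yy = y + nb[k][1], zz = z + nb[k][2];
        if (xx < 0 || xx >= d1 || yy < 0 || yy >= d2 || zz < 0 || zz >= d3) continue;
        int w = xx + d1 * (yy + d2 * zz);
        if (mask[w]) { cnt[lab[w] - 1]++; nnb++; }
      }
      int best = 0;
      double bestc = INFINITY;
      for (int k = 0; k < K; ++k) {
        double r = intens[v] - mu[k];
        double c = r * r / (2.0 * sigma * sigma) + lsig - logpi[k] +
                   beta * (nnb - cnt[k]);
        if (c < bestc - 1e-15) { bestc = c; best = k; }
      }
      if (lab[v] != best + 1) { lab[v] = best + 1; ++ch; }
    }
    energies.push_back(total_energy(lab, mask, d1, d2, d3, intens, mu, sigma, logpi, beta));
    changes.push_back(ch);
    if (ch == 0) break;
  }
  return List::create(_["labels"] = lab,
                      _["energy"] = NumericVector(energies.begin(), energies.end()),
                      _["changes"] = IntegerVector(changes.begin(), changes.end()));
}

// [[Rcpp::export]]
double cpp_hmrf_energy(IntegerVector labels, IntegerVector dims, LogicalVector mask,
                       NumericVector intens, NumericVector mu, double sigma,
                       NumericVector logpi, double beta) {
  int d1 = dims[0], d2 = dims[1], d3 = (dims.size() > 2) ? dims[2] : 1;
  return total_energy(labels, mask, d1, d2, d3, intens, mu, sigma, logpi, beta);
}

// fraction of 6-connected in-mask neighbor pairs with equal labels
// [[Rcpp::export]]
double cpp_neighbor_agreement(IntegerVector labels, IntegerVector dims, LogicalVector mask) {
  int d1 = dims[0], d2 = dims[1], d3 = (dims.size() > 2) ? dims[2] : 1;
  int n = d1 * d2 * d3;
  double agree = 0.0, tot = 0.0;
  for (int v = 0; v < n; ++v) {
    if (!mask[v]) continue;
    int x, y, z; get_xyz(v, d1, d2, x, y, z);
    const int fw[3][3] = {{1,0,0},{0,1,0},{0,0,1}};
    for (int j = 0; j < 3; ++j) {
      int xx = x + fw[j][0], yy = y + fw[j][1], zz = z + fw[j][2];
      if (xx >= d1 || yy >= d2 || zz >= d3) continue;
      int w = xx + d1 * (yy + d2 * zz);
      if (!mask[w]) continue;
      tot += 1.0;
      if (labels[w] == labels[v]) agree += 1.0;
    }
  }
  return tot > 0 ? agree / tot : NA_REAL;
}
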