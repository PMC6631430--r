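#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// axis permutations of the octahedral point group of the cubic lattice
static const int PERMS[6][3] = {
  {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}
};

// pack a lattice site into one 64-bit key (coordinates within +/- 2^20)
static inline long long pack_key(int x, int y, int z) {
  return ((long long)(x + 1048576)) |
         ((long long)(y + 1048576) << 21) |
         ((long long)(z + 1048576) << 42);
}

static double rg_of(const std::vector<int>& X, const std::vector<int>& Y,
                    const std::vector<int>& Z) {
  const int n = (int)X.size();
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < n; ++i) { cx += X[i]; cy += Y[i]; cz += Z[i]; }
  cx /= n; cy /= n; cz /= n;
  double s = 0;
  for (int i = 0; i < n; ++i) {
    const double dx = X[i] - cx, dy = Y[i] - cy, dz = Z[i] - cz;
    s += dx * dx + dy * dy + dz * dz;
  }
  return std::sqrt(s / n);
}

// Pivot-algorithm sampler for self-avoiding walks on the cubic lattice.
// Records the gyration radius every `thin_accepted` accepted pivots after
// `equil_accepted` accepted equilibration moves from a rod start. Uses the
// R random number generator, so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector saw_pivot_rg_cpp(int n_beads, int n_samples,
                               int equil_accepted, int thin_accepted) {
  if (n_beads < 3) stop("n_beads must be at least 3");
  if (n_beads > 1000000) stop("n_beads too large");
  std::vector<int> X(n_beads), Y(n_beads, 0), Z(n_beads, 0);
  for (int i = 0; i < n_beads; ++i) X[i] = i;

  NumericVector out(n_samples);
  int got = 0;
  long long accepted = 0, attempts = 0;
  const long long target = (long long)equil_accepted +
                           (long long)n_samples * thin_accepted;
  const long long max_attempts = 10000LL * (target + 1000LL);
  std::unordered_set<long long> occ;
  occ.reserve(2 * n_beads);
  std::vector<int> nx(n_beads), ny(n_beads), nz(n_beads);

  while (got < n_samples) {
    if (++attempts > max_attempts) {
      stop("pivot sampler exceeded the attempt budget (chain too long?)");
    }
    int p = (int)(unif_rand() * (n_beads - 1));
    if (p > n_beads - 2) p = n_beads - 2;
    int s = 1 + (int)(unif_rand() * 47.0); // symmetry 0 is the identity
    if (s > 47) s = 47;
    const int* pm = PERMS[s >> 3];
    const int sx = (s & 1) ? -1 : 1;
    const int sy = (s & 2) ? -1 : 1;
    const int sz = (s & 4) ? -1 : 1;

    occ.clear();
    for (int i = 0; i <= p; ++i) occ.insert(pack_key(X[i], Y[i], Z[i]));
    const int px = X[p], py = Y[p], pz = Z[p];
    bool ok = true;
    for (int i = p + 1; i < n_beads; ++i) {
      const int v[3] = {X[i] - px, Y[i] - py, Z[i] - pz};
      const int wx = px + sx * v[pm[0]];
      const int wy = py + sy * v[pm[1]];
      const int wz = pz + sz * v[pm[2]];
      if (occ.count(pack_key(wx, wy, wz))) { ok = false; break; }
      nx[i] = wx; ny[i] = wy; nz[i] = wz;
    }
    if (!ok) continue;
    for (int i = p + 1; i < n_beads; ++i) {
      X[i] = nx[i]; Y[i] = ny[i]; Z[i] = nz[i];
    }
    ++accepted;
    if (accepted > equil_accepted &&
        (accepted - equil_accepted) % thin_accepted == 0) {
      out[got++] = rg_of(X, Y, Z);
    }
  }
  return out;
}

// Independent ideal (non-self-avoiding) random walks on the cubic lattice.
// [[Rcpp::export]]
NumericVector ideal_walk_rg_cpp(int n_beads, int n_samples) {
  if (n_beads < 2) stop("n_beads must be at least 2");
  static const int STEP[6][3] = {
    {1, 0, 0}, {-1, 0, 0}, {0, 1, 0}, {0, -1, 0}, {0, 0, 1}, {0, 0, -1}
  };
  NumericVector out(n_samples);
  std::vector<int> X(n_beads), Y(n_beads), Z(n_beads);
  for (int k = 0; k < n_samples; ++k) {
    X[0] = Y[0] = Z[0] = 0;
    for (int i = 1; i < n_beads; ++i) {
      int d = (int)(unif_rand() * 6.0);
      if (d > 5) d = 5;
      X[i] = X[i - 1] + STEP[d][0];
      Y[i] = Y[i - 1] + STEP[d][1];
      Z[i] = Z[i - 1] + STEP[d][2];
    }
    out[k] = rg_of(X, Y, Z);
  }
  return out;
}

static inline double min_image(double d, double L) {
  if (L > 0) d -= L * std::round(d / L);
  return d;
}

// Histogram of all unordered pair distances, minimum image in x and y when
// `minimage` is set. Bins are uniform on [r_min, r_max).
// [[Rcpp::export]]
NumericVector pair_dist_hist_cpp(NumericMatrix xyz, double Lx, double Ly,
                                 bool minimage, double r_min, double r_max,
                                 int nbins) {
  if (nbins < 1) stop("nbins must be positive");
  const int n = xyz.nrow();
  NumericVector counts(nbins);
  const double db = (r_max - r_min) / nbins;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(j, 0) - xyz(i, 0);
      double dy = xyz(j, 1) - xyz(i, 1);
      const double dz = xyz(j, 2) - xyz(i, 2);
      if (minimage) { dx = min_image(dx, Lx); dy = min_image(dy, Ly); }
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < r_min || d >= r_max) continue;
      int b = (int)((d - r_min) / db);
      if (b >= nbins) b = nbins - 1;
      counts[b] += 1.0;
    }
  }
  return counts;
}

// All unordered pairs with distance in [r_min, r_max]: indices (1-based),
// displacement i -> j (minimum image in x, y when requested) and distance.
// [[Rcpp::export]]
NumericMatrix pair_disp_cpp(NumericMatrix xyz, double Lx, double Ly,
                            bool minimage, double r_min, double r_max) {
  const int n = xyz.nrow();
  std::vector<double> rows;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(j, 0) - xyz(i, 0);
      double dy = xyz(j, 1) - xyz(i, 1);
      const double dz = xyz(j, 2) - xyz(i, 2);
      if (minimage) { dx = min_image(dx, Lx); dy = min_image(dy, Ly); }
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < r_min || d > r_max) continue;
      rows.push_back(i + 1); rows.push_back(j + 1);
      rows.push_back(dx); rows.push_back(dy); rows.push_back(dz);
      rows.push_back(d);
    }
  }
  const int m = (int)(rows.size() / 6);
  NumericMatrix out(m, 6);
  for (int k = 0; k < m; ++k) {
    for (int c = 0; c < 6; ++c) out(k, c) = rows[6 * k + c];
  }
  colnames(out) = CharacterVector::create("i", "j", "dx", "dy", "dz", "r");
  return out;
}
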