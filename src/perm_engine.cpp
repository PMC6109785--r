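// Threshold-free cluster enhancement and the Freedman-Lane permutation
// engine. TFCE integrates cluster extent^E * height^H over a discrete
// threshold ladder; the permutation engine refits the voxelwise GLM for
// every permuted explanatory variable and records the image-wide maximum
// enhanced statistic, from which family-wise error corrected p-values are
// derived in R.

#include <RcppArmadillo.h>
#include <vector>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

struct Grid {
  int nx, ny, nz;
  int conn;                       // 6, 18 or 26
  std::vector<int> offsets;      // flat-index neighbor offsets
  std::vector<std::array<int,3>> deltas;
  Grid(int nx_, int ny_, int nz_, int conn_) : nx(nx_), ny(ny_), nz(nz_), conn(conn_) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
          if (ad == 0) continue;
          if (conn == 6 && ad > 1) continue;
          if (conn == 18 && ad > 2) continue;
          deltas.push_back({dx, dy, dz});
        }
  }
  inline int flat(int x, int y, int z) const { return x + nx * (y + ny * z); }
};

// TFCE of the positive part of a full-grid image.
// dh <= 0 selects max(img)/n_steps.
//
// Incremental algorithm: thresholds are visited in DECREASING order while
// voxels enter a weighted union-find in decreasing height order, so the
// connected components at threshold h are exactly the union-find sets
// after all voxels >= h have been inserted. Per-cluster increments
// size^E * h^H * dh are accumulated on the root; each node stores an
// offset relative to its parent at link time, so a voxel's total is the
// root accumulator plus the offsets along its path. This makes the sweep
// O(V log V + V * conn + sum_h #clusters) instead of
// O(#steps * V * conn) for a per-threshold relabeling.
struct TfceUF {
  std::vector<int> parent, size;
  std::vector<double> acc, off;
  void reset(size_t n) {
    parent.assign(n, -1);
    size.assign(n, 0);
    acc.assign(n, 0.0);
    off.assign(n, 0.0);
  }
  void make_set(int v) { parent[v] = v; size[v] = 1; }
  int find(int v) const {
    while (parent[v] != v) v = parent[v];
    return v;
  }
  double value(int v) const {
    double s = 0;
    while (parent[v] != v) { s += off[v]; v = parent[v]; }
    return s + acc[v];
  }
  // returns the surviving root, or -1 if already joined
  int link(int a, int b) {
    int ra = find(a), rb = find(b);
    if (ra == rb) return -1;
    if (size[ra] < size[rb]) std::swap(ra, rb);
    parent[rb] = ra;
    off[rb] = acc[rb] - acc[ra];
    size[ra] += size[rb];
    return rb;                       // rb stopped being a root
  }
};

void tfce_pos(const arma::vec& img, const Grid& g, double E, double H,
              double dh, int n_steps, arma::vec& out) {
  out.zeros(img.n_elem);
  double mx = img.max();
  if (!(mx > 0)) return;
  double step = dh > 0 ? dh : mx / n_steps;
  int nsteps_here = (int)std::floor(mx / step + 1e-9);
  if (nsteps_here < 1) return;

  // positive voxels sorted by decreasing value
  std::vector<int> idx;
  idx.reserve(img.n_elem / 4);
  for (arma::uword i = 0; i < img.n_elem; ++i)
    if (img[i] > 0) idx.push_back((int)i);
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return img[a] > img[b]; });

  static thread_local TfceUF uf;
  uf.reset(img.n_elem);
  std::vector<int> roots;
  std::vector<char> is_root(img.n_elem, 0);
  size_t ptr = 0;

  for (int s = nsteps_here; s >= 1; --s) {
    double h = s * step;
    // phase A: insert all voxels with value >= h
    size_t first_new = ptr;
    while (ptr < idx.size() && img[idx[ptr]] >= h) {
      uf.make_set(idx[ptr]);
      ++ptr;
    }
    // phase B: union new voxels with inserted neighbors
    for (size_t a = first_new; a < ptr; ++a) {
      int v = idx[a];
      is_root[v] = 1;
      roots.push_back(v);
      int z = v / (g.nx * g.ny);
      int rem = v - z * g.nx * g.ny;
      int y = rem / g.nx;
      int x = rem - y * g.nx;
      for (const auto& d : g.deltas) {
        int xx = x + d[0], yy = y + d[1], zz = z + d[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= g.nx || yy >= g.ny || zz >= g.nz)
          continue;
        int w = g.flat(xx, yy, zz);
        if (uf.parent[w] >= 0) {
          int dead = uf.link(v, w);
          if (dead >= 0) is_root[dead] = 0;
        }
      }
    }
    // compact the root list and accrue this threshold's increments
    size_t keep = 0;
    for (size_t i = 0; i < roots.size(); ++i)
      if (is_root[roots[i]]) roots[keep++] = roots[i];
    roots.resize(keep);
    double hH = std::pow(h, H) * step;
    for (int r : roots)
      uf.acc[r] += std::pow((double)uf.size[r], E) * hH;
  }
  for (size_t a = 0; a < ptr; ++a)
    out[idx[a]] = uf.value(idx[a]);
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_tfce_pos")]]
arma::vec cpp_tfce_pos(const arma::vec& img, int nx, int ny, int nz,
                       double E, double H, double dh, int conn, int n_steps) {
  Grid g(nx, ny, nz, conn);
  arma::vec out;
  tfce_pos(img, g, E, H, dh, n_steps, out);
  return out;
}

// Freedman-Lane permutation engine with TFCE max-statistic null.
//
// Y:        subjects x voxels data (in-mask columns)
// Z:        subjects x q nuisance design (includes the intercept)
// EVs:      subjects x P matrix of explanatory-variable columns; column 0
//           is the observed EV, the rest are its permutations/relabelings
// mask_idx: 0-based flat grid indices of the voxel columns
//
// The data are residualized against Z once; each permutation refits the
// full model [EV_p, Z] on the residualized data, which leaves the observed
// (column 0) t statistic identical to the full-model fit on the raw data.
// [[Rcpp::export(name = ".cpp_perm_engine")]]
Rcpp::List cpp_perm_engine(const arma::mat& Y, const arma::mat& Z,
                           const arma::mat& EVs, const arma::uvec& mask_idx,
                           int nx, int ny, int nz,
                           double E, double H, double dh, int conn,
                           int n_steps) {
  const arma::uword n = Y.n_rows, V = Y.n_cols, P = EVs.n_cols,
                    q = Z.n_cols;
  if (n <= q + 2) Rcpp::stop("too few subjects for the design");

  // residualize against nuisance
  arma::mat ZtZ = Z.t() * Z;
  arma::mat Ydot = Y - Z * arma::solve(ZtZ, Z.t() * Y,
                                       arma::solve_opts::likely_sympd);
  arma::rowvec yy = arma::sum(arma::square(Ydot), 0);
  arma::mat MZ = Z.t() * Ydot;                  // q x V
  double df = (double)n - (double)(q + 1);

  Grid g(nx, ny, nz, conn);
  arma::vec grid(nx * ny * nz, arma::fill::zeros);
  arma::vec enh;
  arma::vec null_max(P, arma::fill::zeros);
  arma::vec t_obs(V, arma::fill::zeros), tfce_obs(V, arma::fill::zeros);
  double dh_use = dh;

  for (arma::uword p = 0; p < P; ++p) {
    arma::vec x = EVs.col(p);
    arma::mat A(q + 1, q + 1);
    A(0, 0) = arma::dot(x, x);
    arma::vec xz = Z.t() * x;
    A.submat(1, 0, q, 0) = xz;
    A.submat(0, 1, 0, q) = xz.t();
    A.submat(1, 1, q, q) = ZtZ;
    arma::mat Ainv = arma::pinv(A);
    arma::rowvec Mx = x.t() * Ydot;             // 1 x V
    arma::mat M(q + 1, V);
    M.row(0) = Mx;
    if (q > 0) M.rows(1, q) = MZ;
    arma::mat beta = Ainv * M;                  // (q+1) x V
    arma::rowvec rss = yy - arma::sum(M % beta, 0);
    rss.transform([](double v) { return v < 0 ? 0.0 : v; });
    arma::rowvec se = arma::sqrt((rss / df) * Ainv(0, 0));
    arma::rowvec tstat = beta.row(0) / se;
    tstat.replace(arma::datum::nan, 0.0);
    tstat.replace(arma::datum::inf, 0.0);
    tstat.replace(-arma::datum::inf, 0.0);

    grid.zeros();
    for (arma::uword v = 0; v < V; ++v)
      if (tstat[v] > 0) grid[mask_idx[v]] = tstat[v];
    if (p == 0 && dh <= 0) {
      double mx = grid.max();
      dh_use = mx > 0 ? mx / n_steps : -1.0;    // -1: per-map fallback
    }
    tfce_pos(grid, g, E, H, dh_use, n_steps, enh);
    if (p == 0) {
      t_obs = arma::conv_to<arma::vec>::from(tstat);
      for (arma::uword v = 0; v < V; ++v) tfce_obs[v] = enh[mask_idx[v]];
    }
    double m = 0;
    for (arma::uword v = 0; v < V; ++v)
      m = std::max(m, enh[mask_idx[v]]);
    null_max[p] = m;
  }

  return Rcpp::List::create(Rcpp::Named("t") = t_obs,
                            Rcpp::Named("tfce") = tfce_obs,
                            Rcpp::Named("null_max") = null_max,
                            Rcpp::Named("dh") = dh_use);
}
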