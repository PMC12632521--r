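// Exact two-lineage Gillespie simulation of the structured serial coalescent
// with piecewise-constant rates. Event times are drawn within the current
// epoch; a draw past the epoch boundary advances the state to the boundary
// and refreshes the rates (exact for piecewise-constant intensities).
// Uses R's RNG so seeds set from R apply.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Model {
  int d;
  int K;
  std::vector<double> t_start;
  std::vector<double> t_end;
  std::vector<NumericMatrix> M;       // adjacency per epoch
  std::vector<std::vector<double>> rs; // row sums per epoch
  NumericMatrix gamma;                 // K x d
};

Model unpack_model(const List& mod) {
  Model m;
  List epochs = mod["epochs"];
  m.K = epochs.size();
  for (int k = 0; k < m.K; ++k) {
    List e = epochs[k];
    NumericMatrix Mk = e["M"];
    m.M.push_back(Mk);
    m.t_start.push_back(as<double>(e["t_start"]));
    m.t_end.push_back(as<double>(e["t_end"]));
  }
  m.d = m.M[0].nrow();
  m.gamma = NumericMatrix(m.K, m.d);
  for (int k = 0; k < m.K; ++k) {
    List e = epochs[k];
    NumericVector g = e["gamma"];
    for (int i = 0; i < m.d; ++i) m.gamma(k, i) = g[i];
  }
  m.rs.resize(m.K);
  for (int k = 0; k < m.K; ++k) {
    m.rs[k].assign(m.d, 0.0);
    for (int i = 0; i < m.d; ++i) {
      double s = 0.0;
      for (int j = 0; j < m.d; ++j) s += m.M[k](i, j);
      m.rs[k][i] = s;
    }
  }
  return m;
}

inline int epoch_index(const Model& m, double t, int hint) {
  int k = hint;
  while (k + 1 < m.K && t >= m.t_end[k]) ++k;
  return k;
}

inline int pick_destination(const NumericMatrix& M, int s, double rowsum) {
  double u = unif_rand() * rowsum;
  double acc = 0.0;
  int d = M.ncol();
  for (int j = 0; j < d; ++j) {
    acc += M(s, j);
    if (u <= acc) return j;
  }
  return d - 1;
}

// migrate a single lineage from time t0 to time t1, returning the final deme
int migrate_until(const Model& m, int s, double t0, double t1, int& ek) {
  double t = t0;
  while (t < t1) {
    ek = epoch_index(m, t, ek);
    double tb = std::min(t1, m.t_end[ek]);
    double r = m.rs[ek][s];
    if (r <= 0.0) { t = tb; continue; }
    double dt = exp_rand() / r;
    if (t + dt >= tb) { t = tb; continue; }
    t += dt;
    s = pick_destination(m.M[ek], s, r);
  }
  return s;
}

// both lineages from time y until coalescence; returns coalescence time
double coalesce_from(const Model& m, int s1, int s2, double y, int ek) {
  double t = y;
  for (long iter = 0; ; ++iter) {
    if (iter > 2000000000L) stop("coalescence not reached (runaway simulation)");
    ek = epoch_index(m, t, ek);
    double tb = m.t_end[ek];
    double r1 = m.rs[ek][s1];
    double r2 = m.rs[ek][s2];
    double rc = (s1 == s2) ? m.gamma(ek, s1) : 0.0;
    double R = r1 + r2 + rc;
    if (R <= 0.0) {
      if (!R_FINITE(tb)) stop("coalescence unreachable: zero total rate in terminal epoch");
      t = tb;
      continue;
    }
    double dt = exp_rand() / R;
    if (R_FINITE(tb) && t + dt >= tb) { t = tb; continue; }
    t += dt;
    double u = unif_rand() * R;
    if (u < rc) return t;
    if (u < rc + r1) s1 = pick_destination(m.M[ek], s1, r1);
    else s2 = pick_destination(m.M[ek], s2, r2);
  }
}

inline double simulate_one(const Model& m, int i0, double x, int j0, double y) {
  int ek = epoch_index(m, x, 0);
  int s1 = migrate_until(m, i0, x, y, ek);
  double tc = coalesce_from(m, s1, j0, y, ek);
  return 2.0 * tc - x - y;
}

} // namespace

// [[Rcpp::export]]
NumericVector simulate_pairs_cpp(List model, int i, double x, int j, double y,
                                 int n) {
  Model m = unpack_model(model);
  if (i < 1 || i > m.d || j < 1 || j > m.d) stop("deme index out of range");
  NumericVector out(n);
  for (int rep = 0; rep < n; ++rep) {
    out[rep] = simulate_one(m, i - 1, x, j - 1, y);
  }
  return out;
}

// Per-cell sample means and standard errors of pairwise branch length for all
// ordered deme pairs (i at time x, j at time y), n_per_cell replicates each.
// For x == y the (i, j) and (j, i) configurations coincide, so cells with
// i <= j are simulated and mirrored.
// [[Rcpp::export]]
List empirical_B_cpp(List model, double x, double y, int n_per_cell) {
  Model m = unpack_model(model);
  int d = m.d;
  bool contemporaneous = (x == y);
  NumericMatrix mean(d, d), se(d, d);
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j < d; ++j) {
      if (contemporaneous && j < i) continue;
      double s = 0.0, s2 = 0.0;
      for (int rep = 0; rep < n_per_cell; ++rep) {
        double b = simulate_one(m, i, x, j, y);
        s += b;
        s2 += b * b;
      }
      double mu = s / n_per_cell;
      double var = (s2 - n_per_cell * mu * mu) / (n_per_cell - 1.0);
      mean(i, j) = mu;
      se(i, j) = std::sqrt(var / n_per_cell);
      if (contemporaneous && j > i) {
        mean(j, i) = mu;
        se(j, i) = se(i, j);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["mean"] = mean, _["se"] = se,
                      _["n"] = n_per_cell);
}
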