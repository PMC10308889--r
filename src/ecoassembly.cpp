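#include <Rcpp.h>
using namespace Rcpp;

// beta mean nearest-taxon distance between two communities given a patristic
// distance matrix. Communities are index vectors (0-based) into D with
// matching relative-abundance weights (weights sum to 1 per community).
static double bmntd_one(const NumericMatrix& D,
                        const IntegerVector& ia, const NumericVector& fa,
                        const IntegerVector& ib, const NumericVector& fb) {
  double acc = 0.0;
  for (int k = 0; k < ia.size(); ++k) {
    double mn = R_PosInf;
    const int i = ia[k];
    for (int l = 0; l < ib.size(); ++l) {
      const double d = D(i, ib[l]);
      if (d < mn) mn = d;
    }
    acc += 0.5 * fa[k] * mn;
  }
  for (int l = 0; l < ib.size(); ++l) {
    double mn = R_PosInf;
    const int j = ib[l];
    for (int k = 0; k < ia.size(); ++k) {
      const double d = D(j, ia[k]);
      if (d < mn) mn = d;
    }
    acc += 0.5 * fb[l] * mn;
  }
  return acc;
}

// [[Rcpp::export]]
NumericVector bmntd_pairs_cpp(const NumericMatrix& D, const NumericMatrix& comm,
                              const IntegerMatrix& pairs, const bool weighted,
                              const IntegerVector& perm) {
  const int np = pairs.nrow();
  const int S = comm.nrow();
  const int ns = comm.ncol();
  // precompute supports and weights per sample, applying the label permutation
  // (perm maps pool position -> tip position; identity for observed values)
  std::vector<IntegerVector> idx(ns);
  std::vector<NumericVector> wts(ns);
  for (int s = 0; s < ns; ++s) {
    std::vector<int> ii;
    std::vector<double> ww;
    double tot = 0.0;
    for (int i = 0; i < S; ++i) {
      const double x = comm(i, s);
      if (x > 0) {
        ii.push_back(perm[i]);
        ww.push_back(weighted ? x : 1.0);
        tot += weighted ? x : 1.0;
      }
    }
    NumericVector w(ww.size());
    for (size_t k = 0; k < ww.size(); ++k) w[k] = ww[k] / tot;
    idx[s] = wrap(ii);
    wts[s] = w;
  }
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    const int a = pairs(p, 0), b = pairs(p, 1);
    out[p] = bmntd_one(D, idx[a], wts[a], idx[b], wts[b]);
  }
  return out;
}

// Observed bMNTD plus the full tip-shuffling null in one pass.
// perms: S x n_null matrix of 0-based pool permutations.
// Returns a (n_pairs) x (n_null + 1) matrix; column 0 is the observed value.
// [[Rcpp::export]]
NumericMatrix bmntd_null_matrix_cpp(const NumericMatrix& D,
                                    const NumericMatrix& comm,
                                    const IntegerMatrix& pairs,
                                    const bool weighted,
                                    const IntegerMatrix& perms) {
  const int np = pairs.nrow();
  const int S = comm.nrow();
  const int ns = comm.ncol();
  const int n_null = perms.ncol();
  std::vector<std::vector<int>> idx(ns);
  std::vector<std::vector<double>> wts(ns);
  for (int s = 0; s < ns; ++s) {
    double tot = 0.0;
    for (int i = 0; i < S; ++i) {
      const double x = comm(i, s);
      if (x > 0) {
        idx[s].push_back(i);
        wts[s].push_back(weighted ? x : 1.0);
        tot += weighted ? x : 1.0;
      }
    }
    for (size_t k = 0; k < wts[s].size(); ++k) wts[s][k] /= tot;
  }
  NumericMatrix out(np, n_null + 1);
  std::vector<int> map(S);
  for (int r = 0; r <= n_null; ++r) {
    if (r == 0) {
      for (int i = 0; i < S; ++i) map[i] = i;
    } else {
      for (int i = 0; i < S; ++i) map[i] = perms(i, r - 1);
    }
    for (int p = 0; p < np; ++p) {
      const std::vector<int>& ia = idx[pairs(p, 0)];
      const std::vector<int>& ib = idx[pairs(p, 1)];
      const std::vector<double>& fa = wts[pairs(p, 0)];
      const std::vector<double>& fb = wts[pairs(p, 1)];
      double acc = 0.0;
      for (size_t k = 0; k < ia.size(); ++k) {
        const double* col = &D(0, 0) + (size_t)map[ia[k]] * D.nrow();
        double mn = R_PosInf;
        for (size_t l = 0; l < ib.size(); ++l) {
          const double d = col[map[ib[l]]];
          if (d < mn) mn = d;
        }
        acc += 0.5 * fa[k] * mn;
      }
      for (size_t l = 0; l < ib.size(); ++l) {
        const double* col = &D(0, 0) + (size_t)map[ib[l]] * D.nrow();
        double mn = R_PosInf;
        for (size_t k = 0; k < ia.size(); ++k) {
          const double d = col[map[ia[k]]];
          if (d < mn) mn = d;
        }
        acc += 0.5 * fb[l] * mn;
      }
      out(p, r) = acc;
    }
  }
  return out;
}

// Collapsed Gibbs sampler for Bayesian source tracking.
// taxa: per-read taxon index (0-based), length N
// m: taxa x V matrix of source training counts (Unknown has no column)
// Returns posterior mean mixing proportions over V known sources + Unknown,
// averaged over n_draws retained sweeps after burn_in, over n_restarts chains.
// [[Rcpp::export]]
NumericVector gibbs_sources_cpp(const IntegerVector& taxa,
                                const NumericMatrix& m,
                                const double alpha_known,
                                const double alpha_unknown,
                                const double beta,
                                const int burn_in,
                                const int n_restarts,
                                const int n_draws) {
  const int N = taxa.size();
  const int T = m.nrow();
  const int V = m.ncol();
  const int E = V + 1;                       // environments incl. Unknown
  NumericVector msum(V);
  for (int v = 0; v < V; ++v) {
    double s = 0.0;
    for (int t = 0; t < T; ++t) s += m(t, v);
    msum[v] = s;
  }
  NumericVector props(E);
  RNGScope scope;
  for (int r = 0; r < n_restarts; ++r) {
    // random initial assignment
    IntegerVector z(N);
    NumericMatrix n_vt(T, E);               // sink assignment counts per env
    NumericVector n_v(E);
    for (int i = 0; i < N; ++i) {
      z[i] = static_cast<int>(unif_rand() * E);
      if (z[i] == E) z[i] = E - 1;
      n_vt(taxa[i], z[i]) += 1.0;
      n_v[z[i]] += 1.0;
    }
    NumericVector pr(E);
    const int sweeps = burn_in + n_draws;
    for (int sw = 0; sw < sweeps; ++sw) {
      for (int i = 0; i < N; ++i) {
        const int t = taxa[i];
        const int zi = z[i];
        n_vt(t, zi) -= 1.0;
        n_v[zi] -= 1.0;
        double tot = 0.0;
        for (int v = 0; v < E; ++v) {
          const bool unk = (v == E - 1);
          const double mv = unk ? 0.0 : m(t, v);
          const double mdot = unk ? 0.0 : msum[v];
          const double alpha = unk ? alpha_unknown : alpha_known;
          const double theta = (mv + n_vt(t, v) + alpha) /
                               (mdot + n_v[v] + T * alpha);
          pr[v] = theta * (n_v[v] + beta);
          tot += pr[v];
        }
        double u = unif_rand() * tot;
        int vnew = 0;
        for (; vnew < E - 1; ++vnew) {
          u -= pr[vnew];
          if (u <= 0) break;
        }
        z[i] = vnew;
        n_vt(t, vnew) += 1.0;
        n_v[vnew] += 1.0;
      }
      if (sw >= burn_in) {
        for (int v = 0; v < E; ++v) props[v] += n_v[v] / N;
      }
    }
  }
  const double denom = static_cast<double>(n_restarts) * n_draws;
  for (int v = 0; v < E; ++v) props[v] /= denom;
  return props;
}
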