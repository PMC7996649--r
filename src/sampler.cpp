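#include <Rcpp.h>
using namespace Rcpp;

// Term kind codes (kept in step with TERM_KINDS on the R side):
// 1 edges, 2 isolates, 3 gwidegree, 4 edgecov, 5 node_factor_in,
// 6 node_cov_in, 7 node_cov_out, 8 node_cov_combined, 9 node_factor_combined

// Change statistic for adding the absent tie i -> j, given current degrees.
static inline double change_stat(int code, int i, int j, double decay,
                                 const std::vector<double> &vec,
                                 const NumericMatrix &mat,
                                 const std::vector<int> &indeg,
                                 const std::vector<int> &outdeg) {
  switch (code) {
  case 1: return 1.0;
  case 2: {
    int c = 0;
    if (indeg[i] + outdeg[i] == 0) ++c;
    if (indeg[j] + outdeg[j] == 0) ++c;
    return -c;
  }
  case 3: return std::pow(1.0 - std::exp(-decay), (double)indeg[j]);
  case 4: return mat(i, j);
  case 5: case 6: return vec[j];
  case 7: return vec[i];
  case 8: case 9: return vec[i] + vec[j];
  }
  return 0.0;
}

// Tie/no-tie (TNT) Metropolis-Hastings sampler for a directed binary ERGM.
// With probability 1/2 proposes toggling a uniformly chosen existing tie
// (a no-op when the graph is empty), otherwise toggling a uniformly chosen
// dyad; the acceptance ratio includes the proposal correction.  Uses R's
// RNG, so runs are reproducible via set.seed().
// [[Rcpp::export]]
List tnt_sampler_cpp(IntegerMatrix y0, NumericVector theta,
                     IntegerVector codes, NumericVector decay, List vecs,
                     List mats, NumericVector u0, int burnin, int interval,
                     int nsamples, bool collect_networks) {
  const int n = y0.nrow();
  const int p = theta.size();
  const double m = (double)n * (n - 1);

  IntegerMatrix y = clone(y0);
  std::vector<int> indeg(n, 0), outdeg(n, 0);
  std::vector<int> ei, ej;                  // edge list
  IntegerMatrix epos(n, n);                 // position+1 in edge list, 0 = none
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (y(i, j) == 1) {
        ei.push_back(i); ej.push_back(j);
        epos(i, j) = (int)ei.size();
        ++outdeg[i]; ++indeg[j];
      }

  std::vector< std::vector<double> > vv(p);
  std::vector<NumericMatrix> mm(p);
  for (int k = 0; k < p; ++k) {
    NumericVector v = vecs[k];
    vv[k] = std::vector<double>(v.begin(), v.end());
    mm[k] = as<NumericMatrix>(mats[k]);
  }

  std::vector<double> u(u0.begin(), u0.end());
  NumericMatrix stats(nsamples, p);
  List networks(collect_networks ? nsamples : 0);
  std::vector<double> d(p);

  long total = (long)burnin + (long)interval * nsamples;
  int taken = 0;
  for (long it = 0; it < total; ++it) {
    int i, j, cur;
    int E = (int)ei.size();
    if (unif_rand() < 0.5) {
      if (E == 0) {                          // tie branch on empty graph: no-op
        goto record;
      }
      int e = (int)(unif_rand() * E); if (e >= E) e = E - 1;
      i = ei[e]; j = ej[e];
    } else {
      i = (int)(unif_rand() * n); if (i >= n) i = n - 1;
      j = (int)(unif_rand() * (n - 1)); if (j >= n - 1) j = n - 2;
      if (j >= i) ++j;
    }
    cur = y(i, j);
    {
      double logr;
      if (cur == 1) {
        // evaluate the change as if the tie were absent
        --indeg[j]; --outdeg[i];
        double dot = 0.0;
        for (int k = 0; k < p; ++k) {
          d[k] = change_stat(codes[k], i, j, decay[k], vv[k], mm[k], indeg, outdeg);
          dot += theta[k] * d[k];
        }
        logr = -dot + std::log((double)E / (m + E));
        if (std::log(unif_rand()) < logr) {
          // remove edge e = epos(i,j)-1 by swap-delete
          int e = epos(i, j) - 1;
          int last = E - 1;
          ei[e] = ei[last]; ej[e] = ej[last];
          epos(ei[e], ej[e]) = e + 1;
          ei.pop_back(); ej.pop_back();
          epos(i, j) = 0;
          y(i, j) = 0;
          for (int k = 0; k < p; ++k) u[k] -= d[k];
        } else {
          ++indeg[j]; ++outdeg[i];
        }
      } else {
        double dot = 0.0;
        for (int k = 0; k < p; ++k) {
          d[k] = change_stat(codes[k], i, j, decay[k], vv[k], mm[k], indeg, outdeg);
          dot += theta[k] * d[k];
        }
        logr = dot + std::log((m + E + 1.0) / (E + 1.0));
        if (std::log(unif_rand()) < logr) {
          ei.push_back(i); ej.push_back(j);
          epos(i, j) = (int)ei.size();
          y(i, j) = 1;
          ++indeg[j]; ++outdeg[i];
          for (int k = 0; k < p; ++k) u[k] += d[k];
        }
      }
    }
  record:
    if (it >= burnin && ((it - burnin + 1) % interval == 0) &&
        taken < nsamples) {
      for (int k = 0; k < p; ++k) stats(taken, k) = u[k];
      if (collect_networks) {
        int E2 = (int)ei.size();
        IntegerMatrix el(E2, 2);
        for (int e = 0; e < E2; ++e) {
          el(e, 0) = ei[e] + 1; el(e, 1) = ej[e] + 1;
        }
        networks[taken] = el;
      }
      ++taken;
    }
  }

  return List::create(_["stats"] = stats, _["networks"] = networks,
                      _["final"] = y);
}
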