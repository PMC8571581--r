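// Compiled inner loop of the individual-based simulation. A direct
// transcription of the R step functions in R/sim-steps.R: grow groups from
// founders, build the stochastic coordination network, resolve phenotypes by
// one-at-a-time sequential sampling, compute Eq-style fecundities, then
// globally sample and mutate the next generation's founders. Uses R's RNG
// throughout, so runs are reproducible from set.seed().
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline double coord_cost(double s, double theta, int shape) {
  const double top = 1.0 - std::exp(-5.0);
  switch (shape) {
  case 1: return theta * top * s;                                   // linear
  case 2: return theta * top * std::expm1(5.0 * s) / std::expm1(5.0); // accelerating
  default: return theta * (1.0 - std::exp(-5.0 * s));               // decelerating
  }
}

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// Fisher-Yates shuffle of 0..n-1 driven by R's RNG
static void shuffle_idx(std::vector<int>& idx) {
  const int n = (int)idx.size();
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
}

// [[Rcpp::export]]
List sim_engine_cpp(int l, int m, int n_groups, int generations,
                    double epsilon, double theta, double p_mut, double mut_sd,
                    double init_q, double init_s, bool s_locked,
                    bool scope_own_lineage, int cost_shape, int passes) {
  const int n = l * m;            // cells per group
  const int nf = n_groups * l;    // founders per generation
  const int N = n_groups * n;     // cells per generation

  std::vector<double> fq(nf, init_q), fs(nf, s_locked ? 0.0 : init_s);
  std::vector<double> next_q(nf), next_s(nf);
  std::vector<double> cell_w(N), cell_q(N), cell_s(N);
  std::vector<char> helper(n);
  std::vector<int> order(n), deg(n);
  std::vector<std::vector<int>> senders(n);
  std::vector<double> cumw(N);

  const int nrow = generations > 0 ? generations : 1;
  NumericMatrix traj(nrow, 3);

  if (generations == 0) {
    double mq = 0, ms = 0;
    for (int f = 0; f < nf; ++f) { mq += fq[f]; ms += fs[f]; }
    traj(0, 0) = mq / nf; traj(0, 1) = ms / nf; traj(0, 2) = NA_REAL;
    return List::create(_["traj"] = traj,
                        _["final_q"] = NumericVector(fq.begin(), fq.end()),
                        _["final_s"] = NumericVector(fs.begin(), fs.end()));
  }

  for (int g = 0; g < generations; ++g) {
    if (g % 1000 == 0) Rcpp::checkUserInterrupt();
    double mean_q = 0, mean_s = 0, mean_P = 0;
    for (int f = 0; f < nf; ++f) { mean_q += fq[f]; mean_s += fs[f]; }
    mean_q /= nf; mean_s /= nf;

    for (int gr = 0; gr < n_groups; ++gr) {
      const int f0 = gr * l;      // first founder of this group
      bool any_coord = false;
      if (!s_locked) {
        for (int f = 0; f < l; ++f) if (fs[f0 + f] > 0.0) { any_coord = true; break; }
      }

      if (!any_coord) {
        // pure random specialization: Bernoulli(q) per cell
        for (int c = 0; c < n; ++c)
          helper[c] = unif_rand() < fq[f0 + c / m];
      } else {
        // coordination network: receiver i links to each j in scope w.p. s_i
        for (int i = 0; i < n; ++i) {
          senders[i].clear();
          const double si = fs[f0 + i / m];
          if (si > 0.0) {
            const int lin = i / m;
            const int jlo = scope_own_lineage ? lin * m : 0;
            const int jhi = scope_own_lineage ? (lin + 1) * m : n;
            for (int j = jlo; j < jhi; ++j) {
              if (j != i && unif_rand() < si) senders[i].push_back(j);
            }
          }
          deg[i] = (int)senders[i].size();
        }
        // sequential resolution, all cells start as intended reproductives
        std::fill(helper.begin(), helper.end(), 0);
        for (int p = 0; p < passes; ++p) {
          shuffle_idx(order);
          for (int k = 0; k < n; ++k) {
            const int i = order[k];
            const double qi = fq[f0 + i / m];
            if (deg[i] == 0) {
              helper[i] = unif_rand() < qi;
            } else {
              int h = 0;
              for (int j : senders[i]) h += helper[j];
              helper[i] = ((double)h / deg[i]) < qi;  // tie -> reproductive
            }
          }
        }
      }

      int nh = 0;
      for (int c = 0; c < n; ++c) nh += helper[c];
      const double P = (double)nh / n;
      mean_P += P;
      const double benefit = 1.0 - epsilon + epsilon * P;
      for (int c = 0; c < n; ++c) {
        const int f = f0 + c / m;
        const int cc = gr * n + c;
        cell_q[cc] = fq[f];
        cell_s[cc] = fs[f];
        cell_w[cc] = helper[c] ? 0.0
          : (1.0 - coord_cost(fs[f], theta, cost_shape)) * benefit;
      }
    }
    mean_P /= n_groups;
    traj(g, 0) = mean_q; traj(g, 1) = mean_s; traj(g, 2) = mean_P;

    // global competition: multinomial founder sampling over all cells
    double tot = 0;
    for (int c = 0; c < N; ++c) { tot += cell_w[c]; cumw[c] = tot; }
    if (tot <= 0.0)
      stop("Total fecundity is zero (every cell became a helper). Check epsilon/q settings.");
    for (int f = 0; f < nf; ++f) {
      const double u = unif_rand() * tot;
      const int c = (int)(std::upper_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
      const int cc = c < N ? c : N - 1;
      double q = cell_q[cc], s = cell_s[cc];
      if (unif_rand() < p_mut) q = clamp01(q + norm_rand() * mut_sd);
      if (!s_locked && unif_rand() < p_mut) s = clamp01(s + norm_rand() * mut_sd);
      next_q[f] = q; next_s[f] = s_locked ? 0.0 : s;
    }
    fq.swap(next_q); fs.swap(next_s);
  }

  return List::create(_["traj"] = traj,
                      _["final_q"] = NumericVector(fq.begin(), fq.end()),
                      _["final_s"] = NumericVector(fs.begin(), fs.end()));
}
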