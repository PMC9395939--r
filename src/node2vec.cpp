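// Weighted node2vec random walks and skip-gram negative-sampling (SGNS)
// training. Everything is single-threaded and driven by an explicit
// std::mt19937_64 so that results are bit-reproducible for a given seed.

#include <RcppArmadillo.h>
#include <random>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double unif01(std::mt19937_64 &rng) {
  return (rng() >> 11) * (1.0 / 9007199254740992.0);  // 53-bit uniform
}

static inline int unif_int(std::mt19937_64 &rng, int n) {
  return static_cast<int>(unif01(rng) * n) % n;
}

// Sample an index proportional to `w` (unnormalised, non-negative).
static int sample_weighted(std::mt19937_64 &rng, const std::vector<double> &w) {
  double tot = 0.0;
  for (double x : w) tot += x;
  double r = unif01(rng) * tot;
  double acc = 0.0;
  for (size_t k = 0; k < w.size(); ++k) {
    acc += w[k];
    if (r <= acc) return static_cast<int>(k);
  }
  return static_cast<int>(w.size()) - 1;
}

// [[Rcpp::export(name = ".node2vec_walks")]]
IntegerMatrix node2vec_walks_cpp(List adj, List wts, double p, double q,
                                 int walks_per_node, int walk_length,
                                 int seed) {
  const int n = adj.size();
  std::vector<std::vector<int>> nb(n);
  std::vector<std::vector<double>> wt(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector a = adj[i];
    NumericVector w = wts[i];
    nb[i] = std::vector<int>(a.begin(), a.end());
    wt[i] = std::vector<double>(w.begin(), w.end());
  }
  // sorted copies for O(log d) membership tests in the p/q bias
  std::vector<std::vector<int>> nb_sorted(n);
  for (int i = 0; i < n; ++i) {
    nb_sorted[i] = nb[i];
    std::sort(nb_sorted[i].begin(), nb_sorted[i].end());
  }
  auto connected = [&](int a, int b) {
    const std::vector<int> &v = nb_sorted[a];
    return std::binary_search(v.begin(), v.end(), b);
  };

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  IntegerMatrix walks(n * walks_per_node, walk_length);
  std::fill(walks.begin(), walks.end(), NA_INTEGER);
  std::vector<double> bias;
  int row = 0;
  for (int rep = 0; rep < walks_per_node; ++rep) {
    for (int start = 0; start < n; ++start, ++row) {
      int prev = -1, cur = start;
      walks(row, 0) = cur;
      for (int step = 1; step < walk_length; ++step) {
        const std::vector<int> &cnb = nb[cur];
        if (cnb.empty()) break;
        int nxt;
        if (prev < 0 || (p == 1.0 && q == 1.0)) {
          nxt = cnb[sample_weighted(rng, wt[cur])];
        } else {
          bias.assign(cnb.size(), 0.0);
          for (size_t k = 0; k < cnb.size(); ++k) {
            double a = cnb[k] == prev ? 1.0 / p
                       : (connected(cnb[k], prev) ? 1.0 : 1.0 / q);
            bias[k] = wt[cur][k] * a;
          }
          nxt = cnb[sample_weighted(rng, bias)];
        }
        walks(row, step) = nxt;
        prev = cur;
        cur = nxt;
      }
    }
  }
  return walks;
}

// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train_cpp(IntegerMatrix walks, int n_nodes, int dim,
                             int window, int negative, int epochs,
                             double alpha, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed) + 0x9e3779b9u);
  // unigram^0.75 noise distribution over nodes, from walk-corpus counts
  std::vector<double> cnt(n_nodes, 0.0);
  long long total_tokens = 0;
  for (int i = 0; i < walks.nrow(); ++i)
    for (int j = 0; j < walks.ncol(); ++j)
      if (walks(i, j) != NA_INTEGER) { cnt[walks(i, j)] += 1.0; ++total_tokens; }
  std::vector<double> noise_cum(n_nodes);
  double acc = 0.0;
  for (int i = 0; i < n_nodes; ++i) {
    acc += std::pow(cnt[i], 0.75);
    noise_cum[i] = acc;
  }
  auto sample_noise = [&]() {
    double r = unif01(rng) * acc;
    return static_cast<int>(
        std::lower_bound(noise_cum.begin(), noise_cum.end(), r) -
        noise_cum.begin());
  };

  // init: input vectors uniform(-0.5/dim, 0.5/dim), output vectors zero
  arma::mat syn0(dim, n_nodes), syn1(dim, n_nodes, arma::fill::zeros);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d)
      syn0(d, i) = (unif01(rng) - 0.5) / dim;

  const double alpha_min = alpha * 1e-4;
  long long processed = 0;
  const long long planned = static_cast<long long>(epochs) * total_tokens;
  arma::vec grad_in(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < walks.nrow(); ++i) {
      int len = 0;
      while (len < walks.ncol() && walks(i, len) != NA_INTEGER) ++len;
      for (int j = 0; j < len; ++j) {
        double lr = std::max(alpha_min,
                             alpha * (1.0 - double(processed) / (planned + 1)));
        ++processed;
        int centre = walks(i, j);
        int b = 1 + unif_int(rng, window);  // dynamic window
        for (int k = std::max(0, j - b); k <= std::min(len - 1, j + b); ++k) {
          if (k == j) continue;
          int ctx = walks(i, k);
          grad_in.zeros();
          for (int s = 0; s < negative + 1; ++s) {
            int target;
            double label;
            if (s == 0) { target = ctx; label = 1.0; }
            else {
              target = sample_noise();
              if (target == ctx) continue;
              label = 0.0;
            }
            double f = arma::dot(syn0.col(centre), syn1.col(target));
            double sig = 1.0 / (1.0 + std::exp(-f));
            double g = (label - sig) * lr;
            grad_in += g * syn1.col(target);
            syn1.col(target) += g * syn0.col(centre);
          }
          syn0.col(centre) += grad_in;
        }
      }
    }
  }
  NumericMatrix out(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d) out(i, d) = syn0(d, i);
  return out;
}
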