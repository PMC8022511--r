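#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Loss and analytic gradient of one skip-gram update with explicit targets:
//   L = -sum_t [ label_t * log sigma(c . x_t) + (1-label_t) * log sigma(-c . x_t) ]
// where c is the centre's input vector and x_t the targets' output vectors
// (the positive context has label 1, negative samples label 0).  This is the
// exact objective the trainer descends; exposed so the gradient can be
// verified against finite differences.
// [[Rcpp::export]]
List sgns_pair_grad_cpp(NumericVector center, NumericMatrix targets,
                        IntegerVector labels) {
  int d = center.size();
  int nt = targets.nrow();
  if (targets.ncol() != d) stop("dimension mismatch");
  if (labels.size() != nt) stop("one label per target required");
  NumericVector gc(d);
  NumericMatrix gt(nt, d);
  double loss = 0.0;
  for (int t = 0; t < nt; ++t) {
    double dot = 0.0;
    for (int k = 0; k < d; ++k) dot += center[k] * targets(t, k);
    double f = sigmoid(dot);
    double lbl = labels[t];
    loss -= lbl > 0 ? std::log(f) : std::log(1.0 - f);
    double g = f - lbl;  // dL/ddot
    for (int k = 0; k < d; ++k) {
      gc[k] += g * targets(t, k);
      gt(t, k) = g * center[k];
    }
  }
  return List::create(_["loss"] = loss, _["grad_center"] = gc,
                      _["grad_targets"] = gt);
}

struct NoiseSampler {
  // unigram distribution raised to 3/4, sampled by binary search on the CDF
  std::vector<double> cum;
  NoiseSampler(const NumericVector& counts) {
    cum.resize(counts.size());
    double acc = 0.0;
    for (int i = 0; i < counts.size(); ++i) {
      acc += std::pow(counts[i], 0.75);
      cum[i] = acc;
    }
  }
  int draw(std::mt19937& rng, std::uniform_real_distribution<double>& unif) {
    double r = unif(rng) * cum.back();
    int lo = 0, hi = static_cast<int>(cum.size()) - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum[mid] < r) lo = mid + 1; else hi = mid;
    }
    return lo;
  }
};

static long long count_pairs(const List& walks, int window) {
  long long total = 0;
  for (R_xlen_t i = 0; i < walks.size(); ++i) {
    IntegerVector w = walks[i];
    int L = w.size();
    for (int j = 0; j < L; ++j) {
      int lo = std::max(0, j - window), hi = std::min(L - 1, j + window);
      total += hi - lo;  // excludes j itself
    }
  }
  return total;
}

static void init_matrices(std::vector<double>& in, std::vector<double>& out,
                          int vocab, int dim, int out_rows,
                          Nullable<NumericMatrix> init_in,
                          Nullable<NumericMatrix> init_out,
                          std::mt19937& rng) {
  in.assign(static_cast<size_t>(vocab) * dim, 0.0);
  out.assign(static_cast<size_t>(out_rows) * dim, 0.0);
  if (init_in.isNotNull()) {
    NumericMatrix m(init_in);
    if (m.nrow() != vocab || m.ncol() != dim) stop("init input matrix shape mismatch");
    for (int i = 0; i < vocab; ++i)
      for (int k = 0; k < dim; ++k) in[static_cast<size_t>(i) * dim + k] = m(i, k);
  } else {
    std::uniform_real_distribution<double> u(-0.5 / dim, 0.5 / dim);
    for (size_t i = 0; i < in.size(); ++i) in[i] = u(rng);
  }
  if (init_out.isNotNull()) {
    NumericMatrix m(init_out);
    if (m.nrow() != out_rows || m.ncol() != dim) stop("init output matrix shape mismatch");
    for (int i = 0; i < out_rows; ++i)
      for (int k = 0; k < dim; ++k) out[static_cast<size_t>(i) * dim + k] = m(i, k);
  }
}

// Skip-gram with negative sampling over a walk corpus.  Pairs are all
// (centre, context) positions within `window`; `negatives` noise ids per
// pair are drawn from the unigram^{3/4} distribution of `counts`.  The
// learning rate decays linearly from alpha to alpha * 1e-4 over all
// processed pairs.  Single-threaded and fully determined by `seed`.
// [[Rcpp::export]]
List sgns_train_cpp(List walks, int vocab, int dim, int window, int negatives,
                    double alpha, int epochs, int seed,
                    Nullable<NumericMatrix> init_in,
                    Nullable<NumericMatrix> init_out,
                    NumericVector counts) {
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<double> in, out;
  init_matrices(in, out, vocab, dim, vocab, init_in, init_out, rng);
  NoiseSampler noise(counts);

  long long total = count_pairs(walks, window) * std::max(epochs, 1);
  long long done = 0;
  const double alpha_min = alpha * 1e-4;
  std::vector<double> err(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (R_xlen_t wi = 0; wi < walks.size(); ++wi) {
      IntegerVector walk = walks[wi];
      int L = walk.size();
      for (int j = 0; j < L; ++j) {
        int c = walk[j];
        double* vc = &in[static_cast<size_t>(c) * dim];
        int lo = std::max(0, j - window), hi = std::min(L - 1, j + window);
        for (int t = lo; t <= hi; ++t) {
          if (t == j) continue;
          double lr = alpha * (1.0 - static_cast<double>(done) / total);
          if (lr < alpha_min) lr = alpha_min;
          ++done;
          int ctx = walk[t];
          std::fill(err.begin(), err.end(), 0.0);
          for (int s = 0; s <= negatives; ++s) {
            int target; double label;
            if (s == 0) { target = ctx; label = 1.0; }
            else {
              target = noise.draw(rng, unif);
              if (target == ctx) continue;  // skip accidental positives
              label = 0.0;
            }
            double* vt = &out[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += vc[k] * vt[k];
            double g = (label - sigmoid(dot)) * lr;
            for (int k = 0; k < dim; ++k) {
              err[k] += g * vt[k];
              vt[k] += g * vc[k];
            }
          }
          for (int k = 0; k < dim; ++k) vc[k] += err[k];
        }
      }
    }
  }

  NumericMatrix m_in(vocab, dim), m_out(vocab, dim);
  for (int i = 0; i < vocab; ++i)
    for (int k = 0; k < dim; ++k) {
      m_in(i, k) = in[static_cast<size_t>(i) * dim + k];
      m_out(i, k) = out[static_cast<size_t>(i) * dim + k];
    }
  return List::create(_["input"] = m_in, _["output"] = m_out);
}

// Skip-gram with a hierarchical-softmax output layer.  `codes` / `points`
// give each vocabulary id's Huffman code (0/1) and the 0-based indices of
// the inner nodes along its root-to-leaf path; `n_inner` inner-node output
// vectors are trained in place of per-id output vectors.
// [[Rcpp::export]]
List hs_train_cpp(List walks, int vocab, int dim, int window,
                  double alpha, int epochs, int seed,
                  List codes, List points, int n_inner,
                  Nullable<NumericMatrix> init_in,
                  Nullable<NumericMatrix> init_inner) {
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::vector<double> in, inner;
  init_matrices(in, inner, vocab, dim, n_inner, init_in, init_inner, rng);

  std::vector<std::vector<int>> code(vocab), point(vocab);
  for (int i = 0; i < vocab; ++i) {
    IntegerVector cd = codes[i], pt = points[i];
    if (cd.size() != pt.size()) stop("code/point length mismatch");
    code[i].assign(cd.begin(), cd.end());
    point[i].assign(pt.begin(), pt.end());
  }

  long long total = count_pairs(walks, window) * std::max(epochs, 1);
  long long done = 0;
  const double alpha_min = alpha * 1e-4;
  std::vector<double> err(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (R_xlen_t wi = 0; wi < walks.size(); ++wi) {
      IntegerVector walk = walks[wi];
      int L = walk.size();
      for (int j = 0; j < L; ++j) {
        int c = walk[j];
        double* vc = &in[static_cast<size_t>(c) * dim];
        int lo = std::max(0, j - window), hi = std::min(L - 1, j + window);
        for (int t = lo; t <= hi; ++t) {
          if (t == j) continue;
          double lr = alpha * (1.0 - static_cast<double>(done) / total);
          if (lr < alpha_min) lr = alpha_min;
          ++done;
          int tgt = walk[t];
          std::fill(err.begin(), err.end(), 0.0);
          const std::vector<int>& cd = code[tgt];
          const std::vector<int>& pt = point[tgt];
          for (size_t b = 0; b < cd.size(); ++b) {
            double* vp = &inner[static_cast<size_t>(pt[b]) * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += vc[k] * vp[k];
            // label 1 for code bit 0 (left branch), 0 for bit 1
            double g = ((1.0 - cd[b]) - sigmoid(dot)) * lr;
            for (int k = 0; k < dim; ++k) {
              err[k] += g * vp[k];
              vp[k] += g * vc[k];
            }
          }
          for (int k = 0; k < dim; ++k) vc[k] += err[k];
        }
      }
    }
  }

  NumericMatrix m_in(vocab, dim), m_inner(n_inner, dim);
  for (int i = 0; i < vocab; ++i)
    for (int k = 0; k < dim; ++k) m_in(i, k) = in[static_cast<size_t>(i) * dim + k];
  for (int i = 0; i < n_inner; ++i)
    for (int k = 0; k < dim; ++k) m_inner(i, k) = inner[static_cast<size_t>(i) * dim + k];
  return List::create(_["input"] = m_in, _["output"] = m_inner);
}
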