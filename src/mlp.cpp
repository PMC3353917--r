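#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Feed-forward net with two sigmoid hidden layers and one sigmoid output,
// trained by online (per-pattern) backpropagation of squared error with a
// fixed learning rate and momentum. Weight layout: each layer stores a
// (fan_out) x (fan_in + 1) matrix, last column the bias.

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct Layer {
  int nin, nout;
  std::vector<double> w;   // nout * (nin + 1), row-major
  std::vector<double> dw;  // momentum store
  Layer(int nin_, int nout_) : nin(nin_), nout(nout_),
    w(nout_ * (nin_ + 1), 0.0), dw(nout_ * (nin_ + 1), 0.0) {}
  inline double& W(int o, int i) { return w[o * (nin + 1) + i]; }
  inline double& D(int o, int i) { return dw[o * (nin + 1) + i]; }
};

static void forward(Layer& L, const double* in, double* out) {
  for (int o = 0; o < L.nout; ++o) {
    double s = L.W(o, L.nin);  // bias
    for (int i = 0; i < L.nin; ++i) s += L.W(o, i) * in[i];
    out[o] = sigmoid(s);
  }
}

// [[Rcpp::export]]
List mlp_train_cpp(NumericMatrix X, IntegerVector y, int h1, int h2,
                   double lr, double momentum, int epochs, int seed) {
  const int n = X.nrow(), m = X.ncol();
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(-0.5, 0.5);

  Layer L1(m, h1), L2(h1, h2), L3(h2, 1);
  for (double& v : L1.w) v = unif(rng);
  for (double& v : L2.w) v = unif(rng);
  for (double& v : L3.w) v = unif(rng);

  std::vector<double> a1(h1), a2(h2), a3(1);
  std::vector<double> d1(h1), d2(h2);
  std::vector<double> xrow(m);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int k = 0; k < n; ++k) {
      const int r = order[k];
      for (int j = 0; j < m; ++j) xrow[j] = X(r, j);
      forward(L1, xrow.data(), a1.data());
      forward(L2, a1.data(), a2.data());
      forward(L3, a2.data(), a3.data());

      const double out = a3[0];
      const double d3 = (static_cast<double>(y[r]) - out) * out * (1.0 - out);
      for (int o = 0; o < h2; ++o)
        d2[o] = d3 * L3.W(0, o) * a2[o] * (1.0 - a2[o]);
      for (int o = 0; o < h1; ++o) {
        double s = 0.0;
        for (int q = 0; q < h2; ++q) s += d2[q] * L2.W(q, o);
        d1[o] = s * a1[o] * (1.0 - a1[o]);
      }
      // weight updates, output layer inward
      for (int i = 0; i <= h2; ++i) {
        const double inp = (i < h2) ? a2[i] : 1.0;
        double& dv = L3.D(0, i);
        dv = lr * d3 * inp + momentum * dv;
        L3.W(0, i) += dv;
      }
      for (int o = 0; o < h2; ++o)
        for (int i = 0; i <= h1; ++i) {
          const double inp = (i < h1) ? a1[i] : 1.0;
          double& dv = L2.D(o, i);
          dv = lr * d2[o] * inp + momentum * dv;
          L2.W(o, i) += dv;
        }
      for (int o = 0; o < h1; ++o)
        for (int i = 0; i <= m; ++i) {
          const double inp = (i < m) ? xrow[i] : 1.0;
          double& dv = L1.D(o, i);
          dv = lr * d1[o] * inp + momentum * dv;
          L1.W(o, i) += dv;
        }
    }
  }

  NumericMatrix W1(h1, m + 1), W2(h2, h1 + 1), W3(1, h2 + 1);
  for (int o = 0; o < h1; ++o) for (int i = 0; i <= m; ++i) W1(o, i) = L1.W(o, i);
  for (int o = 0; o < h2; ++o) for (int i = 0; i <= h1; ++i) W2(o, i) = L2.W(o, i);
  for (int i = 0; i <= h2; ++i) W3(0, i) = L3.W(0, i);
  return List::create(_["W1"] = W1, _["W2"] = W2, _["W3"] = W3);
}

// [[Rcpp::export]]
NumericVector mlp_forward_cpp(NumericMatrix W1, NumericMatrix W2, NumericMatrix W3,
                              NumericMatrix X) {
  const int n = X.nrow(), m = X.ncol();
  const int h1 = W1.nrow(), h2 = W2.nrow();
  if (W1.ncol() != m + 1) stop("weight/input dimension mismatch");
  NumericVector out(n);
  std::vector<double> a1(h1), a2(h2);
  for (int r = 0; r < n; ++r) {
    for (int o = 0; o < h1; ++o) {
      double s = W1(o, m);
      for (int i = 0; i < m; ++i) s += W1(o, i) * X(r, i);
      a1[o] = sigmoid(s);
    }
    for (int o = 0; o < h2; ++o) {
      double s = W2(o, h1);
      for (int i = 0; i < h1; ++i) s += W2(o, i) * a1[i];
      a2[o] = sigmoid(s);
    }
    double s = W3(0, h2);
    for (int i = 0; i < h2; ++i) s += W3(0, i) * a2[i];
    out[r] = sigmoid(s);
  }
  return out;
}
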