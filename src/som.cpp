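#include <Rcpp.h>
using namespace Rcpp;

// Online multi-layer (shared best-matching unit) SOM training.
//
// layers_t:    list of p_l x n data matrices (one per mark layer,
//              TRANSPOSED so each sample is a contiguous column)
// codebooks_t: list of p_l x units initial codebook matrices (transposed
//              likewise; modified copies are returned)
// grid_d2:     units x units matrix of squared grid distances
// ord:         n x epochs matrix of 1-based presentation indices (seeded in
//              R so all randomness stays in the caller's RNG stream)
// alpha0/1:    learning rate at first/last step (linear decay)
// r0/r1:       neighbourhood radius at first/last step (linear decay)
//
// The BMU minimises the SUM over layers of squared Euclidean distances;
// every layer is updated towards the sample with the same Gaussian
// neighbourhood weight, which is what makes this a "super" SOM rather than
// independent per-layer maps.
// [[Rcpp::export]]
List som_train_cpp(List layers_t, List codebooks_t, NumericMatrix grid_d2,
                   IntegerMatrix ord, double alpha0, double alpha1,
                   double r0, double r1) {
  const int n_layers = layers_t.size();
  const int units = grid_d2.nrow();
  const int n = ord.nrow();
  const int epochs = ord.ncol();
  const double total = static_cast<double>(n) * epochs;

  std::vector<const double*> X(n_layers);
  std::vector<double*> W(n_layers);
  std::vector<int> P(n_layers);
  List out(n_layers);
  for (int l = 0; l < n_layers; ++l) {
    NumericMatrix x = as<NumericMatrix>(layers_t[l]);
    NumericMatrix w = clone(as<NumericMatrix>(codebooks_t[l]));
    out[l] = w;
    X[l] = REAL(x);
    W[l] = REAL(w);
    P[l] = x.nrow();
  }
  const double *gd2 = REAL(grid_d2);

  double step = 0.0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n; ++s, ++step) {
      const int i = ord(s, ep) - 1;
      const double frac = (total > 1) ? step / (total - 1) : 0.0;
      const double alpha = alpha0 + (alpha1 - alpha0) * frac;
      const double radius = r0 + (r1 - r0) * frac;
      const double denom = 2.0 * radius * radius;

      // shared BMU across layers
      int bmu = 0;
      double best = R_PosInf;
      for (int u = 0; u < units; ++u) {
        double d = 0.0;
        for (int l = 0; l < n_layers; ++l) {
          const int p = P[l];
          const double *xi = X[l] + static_cast<size_t>(i) * p;
          const double *wu = W[l] + static_cast<size_t>(u) * p;
          for (int j = 0; j < p; ++j) {
            const double diff = xi[j] - wu[j];
            d += diff * diff;
          }
        }
        if (d < best) { best = d; bmu = u; }
      }

      for (int u = 0; u < units; ++u) {
        const double h =
          alpha * std::exp(-gd2[static_cast<size_t>(bmu) * units + u] /
                           denom);
        if (h < 1e-7) continue;
        for (int l = 0; l < n_layers; ++l) {
          const int p = P[l];
          const double *xi = X[l] + static_cast<size_t>(i) * p;
          double *wu = W[l] + static_cast<size_t>(u) * p;
          for (int j = 0; j < p; ++j)
            wu[j] += h * (xi[j] - wu[j]);
        }
      }
    }
  }
  return out;
}

// Shared-BMU assignment of samples to trained units (1-based); inputs
// transposed as above.
// [[Rcpp::export]]
IntegerVector som_assign_cpp(List layers_t, List codebooks_t) {
  const int n_layers = layers_t.size();
  std::vector<const double*> X(n_layers), W(n_layers);
  std::vector<int> P(n_layers);
  int n = 0, units = 0;
  for (int l = 0; l < n_layers; ++l) {
    NumericMatrix x = as<NumericMatrix>(layers_t[l]);
    NumericMatrix w = as<NumericMatrix>(codebooks_t[l]);
    X[l] = REAL(x);
    W[l] = REAL(w);
    P[l] = x.nrow();
    n = x.ncol();
    units = w.ncol();
  }
  IntegerVector bmu(n);
  for (int i = 0; i < n; ++i) {
    int arg = 0;
    double best = R_PosInf;
    for (int u = 0; u < units; ++u) {
      double d = 0.0;
      for (int l = 0; l < n_layers; ++l) {
        const int p = P[l];
        const double *xi = X[l] + static_cast<size_t>(i) * p;
        const double *wu = W[l] + static_cast<size_t>(u) * p;
        for (int j = 0; j < p; ++j) {
          const double diff = xi[j] - wu[j];
          d += diff * diff;
        }
      }
      if (d < best) { best = d; arg = u; }
    }
    bmu[i] = arg + 1;
  }
  return bmu;
}
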