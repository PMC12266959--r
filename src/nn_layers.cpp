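// Feature-major (features x cells) layer primitives for the network engine.
// These mirror the reference formulas in R/nn.R exactly: linear map, optional
// batch normalization (train/eval), ReLU/sigmoid/linear activations, and the
// hand-derived backward pass. Orchestration, RNG and SGD stay in R; only the
// dense per-layer arithmetic lives here.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;

// zero-copy read-only view of an R matrix
static arma::mat view(const NumericMatrix& m) {
  return arma::mat(const_cast<double*>(m.begin()), m.nrow(), m.ncol(),
                   false, false);
}

static void apply_act_inplace(arma::mat& A, const std::string& act) {
  if (act == "relu") {
    A.transform([](double x) { return x > 0 ? x : 0.0; });
  } else if (act == "sigmoid") {
    A.transform([](double x) { return 1.0 / (1.0 + std::exp(-x)); });
  } // linear: nothing
}

// [[Rcpp::export]]
List cpp_mlp_forward_fm(List layers, NumericMatrix H0, bool training) {
  int L = layers.size();
  List caches(L);
  List rstats(L);
  arma::mat H = view(H0);
  for (int i = 0; i < L; ++i) {
    List ly = layers[i];
    arma::mat W = view(as<NumericMatrix>(ly["W"]));
    arma::vec b = as<arma::vec>(ly["b"]);
    std::string act = as<std::string>(ly["act"]);
    bool has_bn = !Rf_isNull(ly["bn"]);

    arma::mat Zlin = W.t() * H;
    Zlin.each_col() += b;

    List cache;
    arma::mat A;
    if (has_bn) {
      List bn = ly["bn"];
      arma::vec gamma = as<arma::vec>(bn["gamma"]);
      arma::vec beta = as<arma::vec>(bn["beta"]);
      arma::mat xhat;
      arma::vec istd;
      if (training) {
        int n = Zlin.n_cols;
        arma::vec mu = arma::mean(Zlin, 1);
        arma::mat centered = Zlin.each_col() - mu;
        arma::vec v = arma::mean(arma::square(centered), 1);
        istd = 1.0 / arma::sqrt(v + BN_EPS);
        xhat = centered.each_col() % istd;
        arma::vec unbiased = n > 1 ? arma::vec(v * (double)n / (n - 1)) : v;
        arma::vec rmean = as<arma::vec>(bn["rmean"]);
        arma::vec rvar = as<arma::vec>(bn["rvar"]);
        rstats[i] = List::create(
          Named("rmean") = (1 - BN_MOMENTUM) * rmean + BN_MOMENTUM * mu,
          Named("rvar") = (1 - BN_MOMENTUM) * rvar + BN_MOMENTUM * unbiased);
      } else {
        arma::vec rmean = as<arma::vec>(bn["rmean"]);
        arma::vec rvar = as<arma::vec>(bn["rvar"]);
        istd = 1.0 / arma::sqrt(rvar + BN_EPS);
        xhat = (Zlin.each_col() - rmean).each_col() % istd;
      }
      A = xhat.each_col() % gamma;
      A.each_col() += beta;
      cache = List::create(Named("X") = H, Named("xhat") = xhat,
                           Named("istd") = istd,
                           Named("training") = training);
    } else {
      A = Zlin;
      cache = List::create(Named("X") = H);
    }
    apply_act_inplace(A, act);
    cache["out"] = A;
    caches[i] = cache;
    H = A;
  }
  return List::create(Named("out") = H, Named("caches") = caches,
                      Named("rstats") = rstats);
}

// [[Rcpp::export]]
List cpp_mlp_backward_fm(List layers, List caches, NumericMatrix dH0) {
  int L = layers.size();
  List grads(L);
  arma::mat dH = view(dH0);
  for (int i = L - 1; i >= 0; --i) {
    List ly = layers[i];
    List cache = caches[i];
    arma::mat W = view(as<NumericMatrix>(ly["W"]));
    arma::mat X = view(as<NumericMatrix>(cache["X"]));
    arma::mat out = view(as<NumericMatrix>(cache["out"]));
    std::string act = as<std::string>(ly["act"]);
    bool has_bn = !Rf_isNull(ly["bn"]);

    arma::mat dA;
    if (act == "relu") {
      dA = dH % arma::conv_to<arma::mat>::from(out > 0);
    } else if (act == "sigmoid") {
      dA = dH % out % (1.0 - out);
    } else {
      dA = dH;
    }

    arma::mat dZ;
    List g;
    if (has_bn) {
      List bn = ly["bn"];
      arma::vec gamma = as<arma::vec>(bn["gamma"]);
      arma::mat xhat = view(as<NumericMatrix>(cache["xhat"]));
      arma::vec istd = as<arma::vec>(cache["istd"]);
      bool bn_training = as<bool>(cache["training"]);
      arma::vec dgamma = arma::sum(dA % xhat, 1);
      arma::vec dbeta = arma::sum(dA, 1);
      arma::mat dxhat = dA.each_col() % gamma;
      if (bn_training) {
        arma::mat term = dxhat.each_col() - arma::mean(dxhat, 1);
        term -= xhat.each_col() % arma::mean(dxhat % xhat, 1);
        dZ = term.each_col() % istd;
      } else {
        dZ = dxhat.each_col() % istd;
      }
      g = List::create(Named("W") = X * dZ.t(),
                       Named("b") = arma::vec(arma::sum(dZ, 1)),
                       Named("gamma") = dgamma, Named("beta") = dbeta);
    } else {
      dZ = dA;
      g = List::create(Named("W") = X * dZ.t(),
                       Named("b") = arma::vec(arma::sum(dZ, 1)),
                       Named("gamma") = R_NilValue, Named("beta") = R_NilValue);
    }
    grads[i] = g;
    dH = W * dZ;
  }
  return List::create(Named("dX") = dH, Named("grads") = grads);
}

// [[Rcpp::export]]
NumericMatrix cpp_mlp_infer_fm(List layers, NumericMatrix H0) {
  int L = layers.size();
  arma::mat H = view(H0);
  for (int i = 0; i < L; ++i) {
    List ly = layers[i];
    arma::mat W = view(as<NumericMatrix>(ly["W"]));
    arma::vec b = as<arma::vec>(ly["b"]);
    std::string act = as<std::string>(ly["act"]);
    arma::mat A = W.t() * H;
    if (!Rf_isNull(ly["bn"])) {
      List bn = ly["bn"];
      arma::vec gamma = as<arma::vec>(bn["gamma"]);
      arma::vec beta = as<arma::vec>(bn["beta"]);
      arma::vec rmean = as<arma::vec>(bn["rmean"]);
      arma::vec rvar = as<arma::vec>(bn["rvar"]);
      arma::vec istd = 1.0 / arma::sqrt(rvar + BN_EPS);
      arma::vec scale = gamma % istd;
      arma::vec shift = b % scale + beta - rmean % scale;
      A.each_col() %= scale;
      A.each_col() += shift;
    } else {
      A.each_col() += b;
    }
    apply_act_inplace(A, act);
    H = A;
  }
  return wrap(H);
}

// Gaussian VAT candidate directions, feature-major: each column is scaled to
// L2 norm epsilon. A 64-bit Mersenne generator is seeded from a value the
// caller draws from the R RNG stream, so the whole training run remains a
// deterministic function of the configured seed.
// [[Rcpp::export]]
NumericMatrix cpp_vat_directions(int d, int n, double epsilon, double seed) {
  std::mt19937_64 gen(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  arma::mat R(d, n);
  for (arma::uword j = 0; j < R.n_cols; ++j) {
    double ss = 0.0;
    for (arma::uword i = 0; i < R.n_rows; ++i) {
      double x = gauss(gen);
      R(i, j) = x;
      ss += x * x;
    }
    double s = epsilon / std::max(std::sqrt(ss), 1e-12);
    R.col(j) *= s;
  }
  return wrap(R);
}
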