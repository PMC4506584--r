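// Projection of a 4-vector onto the one-signed cone
//   Theta1 = {beta >= 0 componentwise} U {beta <= 0 componentwise}
// in the metric given by W = V^{-1}, and Monte Carlo estimation of the
// chi-bar-square mixture weights induced by that projection.
//
// The orthant-constrained quadratic program
//   min_{x in orthant} (b - x)' W (b - x)
// is solved exactly by enumerating the 16 faces of the orthant: fix a
// subset S of coordinates to zero, solve the unconstrained problem on
// the face (W_SS x_S = (W b)_S), keep sign-feasible candidates, take
// the minimum.  At the face optimum the attained value simplifies to
// b'Wb - x_S'(Wb)_S, which is what the constrained statistic needs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int NSUB = 16; // subsets of {0,1,2,3}

namespace {

struct FaceCache {
  // for each non-empty subset: member indices and inv(W_SS)
  std::vector<uvec> idx;
  std::vector<mat> inv_ss;
};

FaceCache build_faces(const mat &W) {
  FaceCache fc;
  fc.idx.resize(NSUB);
  fc.inv_ss.resize(NSUB);
  for (int s = 1; s < NSUB; ++s) {
    std::vector<unsigned int> members;
    for (unsigned int j = 0; j < 4; ++j)
      if (s & (1 << j)) members.push_back(j);
    fc.idx[s] = uvec(members);
    fc.inv_ss[s] = inv_sympd(W.submat(fc.idx[s], fc.idx[s]));
  }
  return fc;
}

// Project b onto the cone.  cone: 0 = union, 1 = nonnegative orthant
// only, 2 = nonpositive orthant only.  Ties between orthants break to
// the nonnegative one.  Returns attained qdist; fills x_star (length 4)
// and active_dim.
double project_faces(const vec &b, const mat &W, const FaceCache &fc,
                     int cone, vec &x_star, int &active_dim) {
  const double feas_tol = 1e-9;
  const vec wb = W * b;
  const double q0 = dot(b, wb); // value at x = 0, always feasible

  double best_nn = q0, best_np = q0; // empty face candidate
  vec x_nn(4, fill::zeros), x_np(4, fill::zeros);

  for (int s = 1; s < NSUB; ++s) {
    const uvec &id = fc.idx[s];
    vec xs = fc.inv_ss[s] * wb.elem(id);
    double q = q0 - dot(xs, wb.elem(id));
    bool ok_nn = (cone != 2) && xs.min() >= -feas_tol;
    bool ok_np = (cone != 1) && xs.max() <= feas_tol;
    if (ok_nn && q < best_nn) {
      best_nn = q;
      x_nn.zeros();
      x_nn.elem(id) = clamp(xs, 0.0, datum::inf);
    }
    if (ok_np && q < best_np) {
      best_np = q;
      x_np.zeros();
      x_np.elem(id) = clamp(xs, -datum::inf, 0.0);
    }
  }

  bool use_nn = (cone == 1) || (cone == 0 && best_nn <= best_np);
  if (cone == 2) use_nn = false;
  const vec &x = use_nn ? x_nn : x_np;
  double q = use_nn ? best_nn : best_np;
  x_star = x;
  active_dim = 0;
  for (unsigned int j = 0; j < 4; ++j)
    if (std::abs(x[j]) > 1e-10) ++active_dim;
  return q;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cone_project_cpp(const arma::vec &beta, const arma::mat &W,
                            int cone) {
  FaceCache fc = build_faces(W);
  vec x(4);
  int adim;
  double q = project_faces(beta, W, fc, cone, x, adim);
  if (q < 0 && q > -1e-9) q = 0; // round-off on interior points
  return Rcpp::List::create(Rcpp::Named("beta_star") = x,
                            Rcpp::Named("qdist") = q,
                            Rcpp::Named("active_dim") = adim);
}

// Count, over mc_draws draws Z ~ N(0, V) with V = L L', the number of
// active (nonzero) coordinates of the cone projection of Z.  For a
// single orthant each draw contributes one count (its projection); for
// the union each draw contributes two, one per orthant projection, so
// the returned counts estimate the average of the two orthants'
// active-dimension laws.  Uses R's RNG so results are reproducible via
// set.seed().
// [[Rcpp::export]]
Rcpp::IntegerVector chibar_counts_cpp(const arma::mat &L, const arma::mat &W,
                                      int mc_draws, int cone) {
  FaceCache fc = build_faces(W);
  Rcpp::IntegerVector counts(5);
  vec z(4), x(4);
  int adim;
  for (int k = 0; k < mc_draws; ++k) {
    for (int j = 0; j < 4; ++j) z[j] = R::norm_rand();
    vec b = L * z;
    if (cone == 0) {
      project_faces(b, W, fc, 1, x, adim);
      counts[adim] += 1;
      project_faces(b, W, fc, 2, x, adim);
      counts[adim] += 1;
    } else {
      project_faces(b, W, fc, cone, x, adim);
      counts[adim] += 1;
    }
  }
  return counts;
}
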