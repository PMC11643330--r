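#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// indices (0-based) of the r largest |theta|, ties broken toward the
// smallest index (stable sort on descending magnitude)
static std::vector<arma::uword> top_r_abs(const arma::vec& theta, int r) {
  const arma::uword L = theta.n_elem;
  std::vector<arma::uword> idx(L);
  for (arma::uword i = 0; i < L; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&theta](arma::uword a, arma::uword b) {
                     return std::abs(theta[a]) > std::abs(theta[b]);
                   });
  idx.resize(r);
  return idx;
}

static double quad_obj(const arma::mat& G, const arma::vec& b, double yy,
                       const arma::vec& delta) {
  return 0.5 * yy - arma::dot(b, delta) +
         0.5 * arma::dot(delta, G * delta);
}

// Hard-thresholding projected-gradient descent on
//   f(delta) = 0.5*yy - b'delta + 0.5*delta'G delta
// (the concentrated subset objective written through its Gram form),
// step 1/Lc, stopping on ||delta_{t+1}-delta_t||^2 <= tol.
// [[Rcpp::export(name = ".cpp_dfo")]]
List cpp_dfo(const arma::mat& G, const arma::vec& b, double yy,
             const arma::vec& delta_init, int r, double Lc,
             double tol, int max_iter) {
  const arma::uword L = G.n_rows;
  arma::vec delta = delta_init;
  std::vector<double> trace;
  trace.reserve(64);
  trace.push_back(quad_obj(G, b, yy, delta));
  bool converged = (r == 0);
  int t = 0;
  if (r > 0) {
    for (t = 1; t <= max_iter; ++t) {
      arma::vec grad = G * delta - b;
      arma::vec theta = delta - grad / Lc;
      arma::vec dnew(L, arma::fill::zeros);
      std::vector<arma::uword> keep = top_r_abs(theta, r);
      for (arma::uword k : keep) dnew[k] = theta[k];
      double diff = arma::accu(arma::square(dnew - delta));
      delta = dnew;
      trace.push_back(quad_obj(G, b, yy, delta));
      if (diff <= tol) { converged = true; break; }
    }
    if (t > max_iter) t = max_iter;
  }
  return List::create(_["delta"] = delta,
                      _["objective"] = trace.back(),
                      _["trace"] = trace,
                      _["iterations"] = t,
                      _["converged"] = converged);
}

// Exhaustive search over all size-r supports; least squares on each.
// Minimum of the quadratic restricted to support S is
//   0.5*yy - 0.5*b_S' G_SS^{-1} b_S.
// Ties keep the lexicographically smallest support.
// [[Rcpp::export(name = ".cpp_enum")]]
List cpp_enum(const arma::mat& G, const arma::vec& b, double yy, int r) {
  const int L = static_cast<int>(G.n_rows);
  if (r == 0) {
    return List::create(_["delta"] = arma::vec(L, arma::fill::zeros),
                        _["support"] = IntegerVector(0),
                        _["objective"] = 0.5 * yy,
                        _["n_supports"] = 1.0);
  }
  std::vector<int> comb(r);
  for (int i = 0; i < r; ++i) comb[i] = i;
  double best_f = R_PosInf;
  arma::vec best_delta(L, arma::fill::zeros);
  std::vector<int> best_S;
  double n_supports = 0.0;
  for (;;) {
    arma::uvec S(r);
    for (int i = 0; i < r; ++i) S[i] = comb[i];
    arma::mat GSS = G.submat(S, S);
    arma::vec bS = b.elem(S);
    arma::vec dS;
    bool ok = arma::solve(dS, GSS, bS, arma::solve_opts::no_approx);
    if (!ok) dS = arma::pinv(GSS) * bS;
    double f = 0.5 * yy - arma::dot(bS, dS) + 0.5 * arma::dot(dS, GSS * dS);
    n_supports += 1.0;
    if (f < best_f - 1e-15) {
      best_f = f;
      best_delta.zeros();
      for (int i = 0; i < r; ++i) best_delta[S[i]] = dS[i];
      best_S.assign(comb.begin(), comb.end());
    }
    // next combination in lexicographic order
    int i = r - 1;
    while (i >= 0 && comb[i] == L - r + i) --i;
    if (i < 0) break;
    ++comb[i];
    for (int j = i + 1; j < r; ++j) comb[j] = comb[j - 1] + 1;
  }
  IntegerVector support(best_S.size());
  for (size_t i = 0; i < best_S.size(); ++i) support[i] = best_S[i] + 1;
  return List::create(_["delta"] = best_delta,
                      _["support"] = support,
                      _["objective"] = best_f,
                      _["n_supports"] = n_supports);
}
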