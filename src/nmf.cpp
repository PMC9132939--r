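#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Multiplicative-update NMF under the Frobenius objective.
// V (m x n, non-negative) ~ W (m x r) * H (r x n).
// Factors are initialised from runif() so results are reproducible under
// set.seed(); updates use a small epsilon guard in the denominators.
// Convergence: stop when the relative change of ||V - WH||_F^2 over a
// check interval drops below tol, or after max_iter iterations.
// [[Rcpp::export(name = ".nmf_mu")]]
List nmf_mu(const arma::mat& V, int rank, int max_iter, double tol,
            int check_every = 10) {
  const arma::uword m = V.n_rows, n = V.n_cols;
  const double eps = 1e-16;

  NumericVector w0 = runif(m * rank);
  NumericVector h0 = runif(rank * n);
  arma::mat W(w0.begin(), m, rank);
  arma::mat H(h0.begin(), rank, n);

  double prev_obj = arma::accu(arma::square(V - W * H));
  double obj = prev_obj;
  std::vector<double> trace;
  trace.push_back(prev_obj);
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    // H <- H .* (W'V) ./ (W'W H + eps)
    H %= (W.t() * V) / (W.t() * W * H + eps);
    // W <- W .* (V H') ./ (W H H' + eps)
    W %= (V * H.t()) / (W * (H * H.t()) + eps);

    if (iter % check_every == 0 || iter == max_iter) {
      obj = arma::accu(arma::square(V - W * H));
      trace.push_back(obj);
      if (prev_obj > 0 &&
          std::abs(prev_obj - obj) / std::max(prev_obj, eps) < tol) break;
      prev_obj = obj;
    }
  }

  // Scale signature columns of W to sum 1; move the scale into H.
  arma::rowvec cs = arma::sum(W, 0);
  cs.replace(0.0, 1.0);
  W.each_row() /= cs;
  H.each_col() %= cs.t();

  return List::create(_["W"] = W, _["H"] = H, _["objective"] = obj,
                      _["iterations"] = std::min(iter, max_iter),
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}

// n x B matrix of random permutations of 1..n (column-wise Fisher-Yates),
// driven by R's RNG so that set.seed() reproduces the shuffles.
// [[Rcpp::export(name = ".perm_index_matrix")]]
IntegerMatrix perm_index_matrix(int n, int B) {
  IntegerMatrix P(n, B);
  std::vector<int> idx(n);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) idx[i] = i + 1;
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    for (int i = 0; i < n; ++i) P(i, b) = idx[i];
  }
  return P;
}

// Two-way replication permutation test for one marker against D response
// pairs (complete data). For each of B draws, a random k-subset of samples
// is taken as marker-positive (equivalent to shuffling the marker jointly
// across both datasets) and Cohen's d is computed in both datasets from
// subset sums; the sensitivity score is min(d1, d2), the resistance score
// max(d1, d2). p = fraction of permuted scores at least as extreme as the
// observed score. Uses R's RNG (seed-reproducible).
// [[Rcpp::export(name = ".perm_two_way")]]
List perm_two_way(NumericVector m, NumericMatrix Y1, NumericMatrix Y2,
                  int B) {
  const int n = m.size(), D = Y1.ncol();
  if (Y1.nrow() != n || Y2.nrow() != n || Y2.ncol() != D)
    stop("dimension mismatch");
  int k = 0;
  for (int i = 0; i < n; ++i) if (m[i] == 1) ++k;
  if (k < 1 || k >= n) stop("constant marker");

  std::vector<double> t1(D), q1(D), t2(D), q2(D);
  for (int d = 0; d < D; ++d) {
    double s1 = 0, ss1 = 0, s2 = 0, ss2 = 0;
    for (int i = 0; i < n; ++i) {
      s1 += Y1(i, d); ss1 += Y1(i, d) * Y1(i, d);
      s2 += Y2(i, d); ss2 += Y2(i, d) * Y2(i, d);
    }
    t1[d] = s1; q1[d] = ss1; t2[d] = s2; q2[d] = ss2;
  }

  // Cohen's d from positive-subset sums: d = (meanNeg - meanPos) / sPooled
  auto dStat = [&](double sPos, double qPos, double tot, double qTot) {
    const double kk = k, nn = n - k;
    double mP = sPos / kk, mN = (tot - sPos) / nn;
    double vP = (qPos - sPos * sPos / kk) / std::max(kk - 1.0, 1.0);
    double vN = ((qTot - qPos) - (tot - sPos) * (tot - sPos) / nn) /
      std::max(nn - 1.0, 1.0);
    double sp2 = ((kk - 1.0) * vP + (nn - 1.0) * vN) /
      std::max(kk + nn - 2.0, 1.0);
    if (sp2 <= 0) return NA_REAL;
    return (mN - mP) / std::sqrt(sp2);
  };

  NumericVector d1(D), d2(D), obsS(D), obsR(D);
  for (int d = 0; d < D; ++d) {
    double s1 = 0, sq1 = 0, s2 = 0, sq2 = 0;
    for (int i = 0; i < n; ++i) if (m[i] == 1) {
      s1 += Y1(i, d); sq1 += Y1(i, d) * Y1(i, d);
      s2 += Y2(i, d); sq2 += Y2(i, d) * Y2(i, d);
    }
    d1[d] = dStat(s1, sq1, t1[d], q1[d]);
    d2[d] = dStat(s2, sq2, t2[d], q2[d]);
    obsS[d] = std::min(d1[d], d2[d]);
    obsR[d] = std::max(d1[d], d2[d]);
  }

  std::vector<int> cntS(D, 0), cntR(D, 0), valS(D, 0), valR(D, 0);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < k; ++j) {
      int r = j + static_cast<int>(unif_rand() * (n - j));
      if (r >= n) r = n - 1;
      std::swap(idx[j], idx[r]);
    }
    for (int d = 0; d < D; ++d) {
      double s1 = 0, sq1 = 0, s2 = 0, sq2 = 0;
      for (int j = 0; j < k; ++j) {
        const int i = idx[j];
        s1 += Y1(i, d); sq1 += Y1(i, d) * Y1(i, d);
        s2 += Y2(i, d); sq2 += Y2(i, d) * Y2(i, d);
      }
      double p1 = dStat(s1, sq1, t1[d], q1[d]);
      double p2 = dStat(s2, sq2, t2[d], q2[d]);
      if (ISNAN(p1) || ISNAN(p2)) continue;
      double sS = std::min(p1, p2), sR = std::max(p1, p2);
      if (!ISNAN(obsS[d])) { ++valS[d]; if (sS >= obsS[d]) ++cntS[d]; }
      if (!ISNAN(obsR[d])) { ++valR[d]; if (sR <= obsR[d]) ++cntR[d]; }
    }
  }
  NumericVector pS(D), pR(D);
  for (int d = 0; d < D; ++d) {
    pS[d] = valS[d] > 0 ? static_cast<double>(cntS[d]) / valS[d] : NA_REAL;
    pR[d] = valR[d] > 0 ? static_cast<double>(cntR[d]) / valR[d] : NA_REAL;
  }
  return List::create(_["d1"] = d1, _["d2"] = d2, _["pSens"] = pS,
                      _["pRes"] = pR);
}
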