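// Lloyd k-means under correlation distance with arithmetic-mean centroid
// updates, k-means++-style seeding and multiple restarts. Correlation
// distance between vectors u, v is 1 - Pearson(u, v); on standardized
// vectors (zero mean, unit norm) it equals 1 - <u, v>, so each assignment
// pass is a single matrix product. Data are held feature-major (E x N) so
// per-window access is contiguous.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// standardize columns to zero mean and unit norm
static arma::mat col_standardize(const arma::mat& XT) {
  arma::rowvec m = arma::mean(XT, 0);
  arma::mat Xc = XT.each_row() - m;
  arma::rowvec nrm = arma::sqrt(arma::sum(arma::square(Xc), 0));
  for (arma::uword i = 0; i < nrm.n_elem; ++i)
    if (nrm(i) < 1e-12) nrm(i) = 1e-12; // constant vectors rejected upstream
  Xc.each_row() /= nrm;
  return Xc;
}

// k x N matrix of correlation distances from centroids (columns of CT) to
// the standardized data columns
static arma::mat corr_dist(const arma::mat& XnT, const arma::mat& CT) {
  arma::mat CnT = col_standardize(CT);
  return 1.0 - CnT.t() * XnT;
}

// k-means++ seeding: first index uniform, subsequent indices with
// probability proportional to squared distance to the nearest chosen seed
static arma::uvec seed_plusplus(const arma::mat& XnT, int k) {
  const arma::uword N = XnT.n_cols;
  arma::uvec idx(k);
  idx(0) = (arma::uword)(unif_rand() * N);
  if (idx(0) >= N) idx(0) = N - 1;
  arma::vec dmin(N, arma::fill::value(arma::datum::inf));
  for (int c = 1; c < k; ++c) {
    arma::vec d = (1.0 - XnT.col(idx(c - 1)).t() * XnT).t();
    d = arma::clamp(d, 0.0, arma::datum::inf);
    dmin = arma::min(dmin, d);
    arma::vec w = arma::square(dmin);
    double tot = arma::accu(w);
    if (tot <= 0) { // all remaining points coincide with a seed
      idx(c) = (arma::uword)(unif_rand() * N);
      if (idx(c) >= N) idx(c) = N - 1;
      continue;
    }
    double u = unif_rand() * tot, cum = 0.0;
    arma::uword chosen = N - 1;
    for (arma::uword i = 0; i < N; ++i) {
      cum += w(i);
      if (u <= cum) { chosen = i; break; }
    }
    idx(c) = chosen;
  }
  return idx;
}

// arithmetic means of the raw member vectors; empty clusters are re-seeded
// from the point farthest from its assigned centroid
static arma::mat group_means(const arma::mat& XT, const arma::urowvec& labels,
                             int k, const arma::mat& XnT) {
  arma::mat CT(XT.n_rows, k, arma::fill::zeros);
  arma::vec counts(k, arma::fill::zeros);
  for (arma::uword i = 0; i < XT.n_cols; ++i) {
    CT.col(labels(i)) += XT.col(i);
    counts(labels(i)) += 1.0;
  }
  for (int c = 0; c < k; ++c) {
    if (counts(c) > 0) {
      CT.col(c) /= counts(c);
    } else {
      arma::mat D = corr_dist(XnT, CT);
      arma::rowvec best = arma::min(D, 0);
      arma::uword far = best.index_max();
      CT.col(c) = XT.col(far);
    }
  }
  return CT;
}

// [[Rcpp::export]]
List kmeans_corr_cpp(const arma::mat& X, int k, int n_init, int max_iter,
                     double tol) {
  const arma::uword N = X.n_rows;
  if (k < 2) stop("k must be >= 2");
  if ((arma::uword)k > N) stop("k exceeds the number of rows");
  arma::mat XT = X.t();
  arma::mat XnT = col_standardize(XT);

  double best_obj = arma::datum::inf;
  arma::urowvec best_labels(N);
  arma::mat best_CT;
  int best_iters = 0;

  for (int init = 0; init < n_init; ++init) {
    arma::uvec seeds = seed_plusplus(XnT, k);
    arma::mat CT = XT.cols(seeds);
    arma::urowvec labels = arma::index_min(corr_dist(XnT, CT), 0);
    double prev_obj = arma::datum::inf;
    int iters = 0;
    for (int it = 0; it < max_iter; ++it) {
      iters = it + 1;
      CT = group_means(XT, labels, k, XnT);
      arma::mat D = corr_dist(XnT, CT);
      arma::urowvec new_labels = arma::index_min(D, 0);
      double obj = arma::accu(arma::min(D, 0));
      bool changed = arma::any(new_labels != labels);
      // the mean update is the standard-k-means compromise under
      // correlation distance; stop rather than accept an objective increase
      if (obj > prev_obj - tol) {
        if (obj < prev_obj) labels = new_labels;
        break;
      }
      labels = new_labels;
      prev_obj = obj;
      if (!changed) break;
    }
    CT = group_means(XT, labels, k, XnT);
    arma::mat D = corr_dist(XnT, CT);
    double obj = 0.0;
    for (arma::uword i = 0; i < N; ++i) obj += D(labels(i), i);
    if (obj < best_obj) {
      best_obj = obj;
      best_labels = labels;
      best_CT = CT;
      best_iters = iters;
    }
  }

  return List::create(
    _["labels"] = IntegerVector(best_labels.begin(), best_labels.end()),
    _["centroids"] = best_CT.t(),
    _["objective"] = best_obj,
    _["iterations"] = best_iters);
}
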