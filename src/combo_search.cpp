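// Exhaustive enumeration of k-gene combinations scored by the squared
// correlation between the first principal component of the combination's
// standardized expression and the 0/1 outcome label.
//
// Works entirely from sufficient statistics: the p x p gene correlation
// matrix C and the length-p vector r of gene-outcome correlations.  For a
// subset S with leading eigenvector v of C[S,S],
//   r2(S) = (v' r[S])^2 / (v' C[S,S] v),
// which equals the squared Pearson correlation of the PC1 score vector with
// the label (the per-sample projections never need to be formed).

#include <RcppArmadillo.h>
#include <queue>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double combo_r2_eig(const arma::mat& C, const arma::vec& r,
                           const arma::uvec& idx) {
  arma::mat Cs = C.submat(idx, idx);
  arma::vec eigval;
  arma::mat eigvec;
  arma::eig_sym(eigval, eigvec, Cs);
  arma::vec v = eigvec.col(eigvec.n_cols - 1);  // leading eigenvector
  double denom = arma::as_scalar(v.t() * Cs * v);
  if (denom <= 0.0) return 0.0;
  double num = arma::dot(v, r.elem(idx));
  return num * num / denom;
}

typedef std::pair<double, std::vector<int> > Entry;
struct EntryCmp {
  bool operator()(const Entry& a, const Entry& b) const {
    return a.first > b.first;  // min-heap on r2
  }
};

// [[Rcpp::export]]
List combo_search_exhaustive_cpp(const arma::mat& C, const arma::vec& r,
                                 int k, int top_t) {
  const int p = C.n_rows;
  if (k < 1 || k > p) stop("k must lie in 1..nrow(C)");
  std::vector<int> comb(k);
  for (int i = 0; i < k; ++i) comb[i] = i;
  std::priority_queue<Entry, std::vector<Entry>, EntryCmp> heap;
  double n_eval = 0.0;
  arma::uvec idx(k);
  for (;;) {
    for (int i = 0; i < k; ++i) idx[i] = comb[i];
    const double r2 = combo_r2_eig(C, r, idx);
    n_eval += 1.0;
    if ((int)heap.size() < top_t) {
      heap.push(Entry(r2, comb));
    } else if (r2 > heap.top().first) {
      heap.pop();
      heap.push(Entry(r2, comb));
    }
    // advance to the next lexicographic combination
    int i = k - 1;
    while (i >= 0 && comb[i] == p - k + i) --i;
    if (i < 0) break;
    ++comb[i];
    for (int j = i + 1; j < k; ++j) comb[j] = comb[j - 1] + 1;
  }
  const int m = (int)heap.size();
  IntegerMatrix combos(m, k);
  NumericVector r2s(m);
  for (int j = m - 1; j >= 0; --j) {
    r2s[j] = heap.top().first;
    for (int i = 0; i < k; ++i) combos(j, i) = heap.top().second[i] + 1;
    heap.pop();
  }
  return List::create(_["combos"] = combos, _["r2"] = r2s,
                      _["n_evaluated"] = n_eval);
}
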