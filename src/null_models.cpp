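#include <Rcpp.h>
using namespace Rcpp;

// Nearest-taxon patristic distance from every taxon to every community.
//
// D is the S x S patristic distance matrix over the regional taxon pool and
// pres the S x n presence matrix (taxa x samples). M(i, l) is the distance
// from taxon i to its closest relative present in sample l; a taxon present
// in l itself is at distance zero (D has a zero diagonal). Communities with
// no taxa give +Inf, which the caller treats as an error upstream.
// [[Rcpp::export]]
NumericMatrix nearest_taxon_dist(const NumericMatrix& D,
                                 const LogicalMatrix& pres) {
  const int S = D.nrow(), n = pres.ncol();
  NumericMatrix M(S, n);
  std::vector<int> idx;
  idx.reserve(S);
  for (int l = 0; l < n; ++l) {
    idx.clear();
    for (int j = 0; j < S; ++j)
      if (pres(j, l)) idx.push_back(j);
    for (int i = 0; i < S; ++i) {
      double m = R_PosInf;
      for (size_t t = 0; t < idx.size(); ++t) {
        const double d = D(idx[t], i);
        if (d < m) m = d;
      }
      M(i, l) = m;
    }
  }
  return M;
}

static double bray_curtis_int(const std::vector<int>& a,
                              const std::vector<int>& b) {
  long num = 0, den = 0;
  const size_t S = a.size();
  for (size_t i = 0; i < S; ++i) {
    num += std::labs((long)a[i] - (long)b[i]);
    den += (long)a[i] + (long)b[i];
  }
  return den > 0 ? (double)num / (double)den : 0.0;
}

// Weighted sampling without replacement via exponential keys
// (Efraimidis-Spirakis): the n items with the smallest Exp(1)/w_i keys form
// a sample drawn sequentially proportional to w among the remaining items.
// Uses the R RNG so results follow set.seed().
static void sample_weighted(const NumericVector& w, int n,
                            std::vector<int>& out) {
  const int S = w.size();
  std::vector<std::pair<double, int> > keys;
  keys.reserve(S);
  for (int i = 0; i < S; ++i) {
    if (w[i] > 0.0)
      keys.push_back(std::make_pair(exp_rand() / w[i], i));
  }
  if ((int)keys.size() < n)
    stop("fewer positive-weight taxa than the requested richness");
  std::partial_sort(keys.begin(), keys.begin() + n, keys.end());
  out.clear();
  for (int i = 0; i < n; ++i) out.push_back(keys[i].second);
}

// One null community: fix richness `rich` and total abundance `total`;
// draw taxon identities without replacement with probability proportional
// to regional occupancy, seed each with one individual, then allocate the
// remaining individuals multinomially proportional to regional relative
// abundance of the drawn taxa.
static void null_community(int rich, int total, const NumericVector& occup,
                           const NumericVector& regab, std::vector<int>& comm,
                           std::vector<int>& chosen, std::vector<double>& prob,
                           std::vector<int>& draw) {
  const int S = occup.size();
  std::fill(comm.begin(), comm.end(), 0);
  sample_weighted(occup, rich, chosen);
  double tot = 0.0;
  prob.resize(rich);
  for (int i = 0; i < rich; ++i) {
    prob[i] = regab[chosen[i]];
    tot += prob[i];
  }
  for (int i = 0; i < rich; ++i) prob[i] = tot > 0 ? prob[i] / tot : 1.0 / rich;
  draw.resize(rich);
  int rest = total - rich;
  if (rest < 0) stop("sample total smaller than its richness");
  if (rest > 0) {
    rmultinom(rest, prob.data(), rich, draw.data());
  } else {
    std::fill(draw.begin(), draw.end(), 0);
  }
  for (int i = 0; i < rich; ++i) comm[chosen[i]] = 1 + draw[i];
  (void)S;
}

// Raup-Crick (Bray-Curtis) for one sample pair. x, y are integer count
// vectors over the regional pool; occup and regab the regional occupancy
// and relative-abundance weights. Returns RC in [-1, 1]:
// 2 * [(#null < obs) + 0.5 * (#null == obs)] / reps - 1.
// [[Rcpp::export]]
double rc_bray_pair(const IntegerVector& x, const IntegerVector& y,
                    const NumericVector& occup, const NumericVector& regab,
                    int reps) {
  const int S = x.size();
  int rx = 0, ry = 0, Nx = 0, Ny = 0;
  for (int i = 0; i < S; ++i) {
    if (x[i] > 0) { ++rx; Nx += x[i]; }
    if (y[i] > 0) { ++ry; Ny += y[i]; }
  }
  std::vector<int> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  const double obs = bray_curtis_int(xv, yv);

  std::vector<int> nx(S), ny(S), chosen;
  std::vector<double> prob;
  std::vector<int> draw;
  int below = 0, ties = 0;
  const double tol = 1e-10;
  for (int r = 0; r < reps; ++r) {
    null_community(rx, Nx, occup, regab, nx, chosen, prob, draw);
    null_community(ry, Ny, occup, regab, ny, chosen, prob, draw);
    const double d = bray_curtis_int(nx, ny);
    if (std::abs(d - obs) <= tol) ++ties;
    else if (d < obs) ++below;
  }
  double rc = 2.0 * ((double)below + 0.5 * (double)ties) / (double)reps - 1.0;
  if (rc > 1.0) rc = 1.0;
  if (rc < -1.0) rc = -1.0;
  return rc;
}
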