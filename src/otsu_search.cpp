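#include <Rcpp.h>
#include <functional>
using namespace Rcpp;

// Exhaustive multilevel Otsu search.
//
// Maximizes the between-class variance sum_k w_k (mu_k - mu_G)^2 over all
// strictly increasing T-tuples of thresholds in [0, 254]. Class k covers
// gray levels t_{k-1}+1 .. t_k inclusive (t_0 = -1, t_{T+1} = 255), matching
// the region-merging class convention. Empty classes (w = 0) are legal
// candidates contributing 0. Equivalent objective actually accumulated:
// sum_k S_k^2 / w_k with S_k = sum_i i * P_i over the class; between-class
// variance is that sum minus mu_G^2. Enumeration is in ascending
// lexicographic order and only a strictly larger objective replaces the
// incumbent, so ties resolve to the lexicographically smallest tuple.
//
// [[Rcpp::export]]
List otsu_search_cpp(NumericVector probs, int nthresh) {
  const int L = 256;
  if (probs.size() != L) stop("probs must have length 256");
  if (nthresh < 1 || nthresh > L - 2) stop("invalid threshold count");

  std::vector<double> cp(L + 1, 0.0), cs(L + 1, 0.0);
  for (int i = 0; i < L; ++i) {
    cp[i + 1] = cp[i] + probs[i];
    cs[i + 1] = cs[i] + static_cast<double>(i) * probs[i];
  }
  const double muG = cs[L];

  std::vector<int> t(nthresh), best(nthresh, -1);
  double bestF = -1.0;  // objective is always >= 0, so every tuple beats this
  double count = 0.0;

  std::function<void(int, int, double)> rec =
      [&](int level, int start, double partial) {
        const int hiT = 254 - (nthresh - 1 - level);
        const int prev = (level == 0) ? -1 : t[level - 1];
        for (int ti = start; ti <= hiT; ++ti) {
          t[level] = ti;
          const double w = cp[ti + 1] - cp[prev + 1];
          const double s = cs[ti + 1] - cs[prev + 1];
          const double acc = partial + ((w > 0.0) ? s * s / w : 0.0);
          if (level == nthresh - 1) {
            const double wl = cp[L] - cp[ti + 1];
            const double sl = cs[L] - cs[ti + 1];
            const double f = acc + ((wl > 0.0) ? sl * sl / wl : 0.0);
            count += 1.0;
            if (f > bestF) {
              bestF = f;
              best = t;
            }
          } else {
            rec(level + 1, ti + 1, acc);
          }
        }
      };
  rec(0, 0, 0.0);

  double bcv = bestF - muG * muG;
  if (bcv < 0.0) bcv = 0.0;  // guard against rounding on degenerate inputs
  return List::create(_["thresholds"] = IntegerVector(best.begin(), best.end()),
                      _["objective"] = bcv,
                      _["candidates"] = count);
}
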