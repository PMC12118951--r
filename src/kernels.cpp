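#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Spike-time cross-correlogram counts on a centered bin grid.
// Bin k (k = -K..K) covers lags [(k-0.5)*bin_s, (k+0.5)*bin_s); lag is
// target - reference, so positive lags mean the target fires later.
// exclude_zero drops exact zero-lag pairs (self-pairs when ref == target).
static void ccg_accumulate(const double* ref, int nref,
                           const double* tgt, int ntgt,
                           double half_win_s, double bin_s,
                           bool exclude_zero, double* counts, int K) {
  double lo = -(K + 0.5) * bin_s, hi = (K + 0.5) * bin_s;
  int j0 = 0;
  for (int i = 0; i < nref; ++i) {
    double r = ref[i];
    while (j0 < ntgt && tgt[j0] - r < lo) ++j0;
    for (int j = j0; j < ntgt; ++j) {
      double lag = tgt[j] - r;
      if (lag >= hi) break;
      if (exclude_zero && lag == 0.0) continue;
      int k = (int)std::floor(lag / bin_s + 0.5) + K;
      if (k >= 0 && k <= 2 * K) counts[k] += 1.0;
    }
  }
  (void)half_win_s;
}

// [[Rcpp::export]]
NumericVector ccg_counts_cpp(NumericVector ref, NumericVector tgt,
                             double half_win_s, double bin_s,
                             bool exclude_zero) {
  int K = (int)std::floor(half_win_s / bin_s + 1e-9);
  NumericVector counts(2 * K + 1);
  ccg_accumulate(REAL(ref), ref.size(), REAL(tgt), tgt.size(),
                 half_win_s, bin_s, exclude_zero, REAL(counts), K);
  return counts;
}

// Jitter-surrogate extrema of the Gaussian-smoothed CCG.
// Each surrogate adds an independent U(-jitter, +jitter) offset to every
// spike of both trains, recomputes the smoothed CCG, and records its max and
// min over the band [-band_s, +band_s]. Uses the R RNG (respects set.seed).
// [[Rcpp::export]]
NumericMatrix ccg_jitter_minmax_cpp(NumericVector ref, NumericVector tgt,
                                    int n_surrogates, double jitter_s,
                                    double band_s, double bin_s,
                                    double sigma_s) {
  int half_kern = (int)std::ceil(4.0 * sigma_s / bin_s);
  int Kb = (int)std::floor(band_s / bin_s + 1e-9);      // band bins +-Kb
  int K = Kb + half_kern;                               // counts needed +-K
  std::vector<double> kern(2 * half_kern + 1);
  double ksum = 0;
  for (int k = -half_kern; k <= half_kern; ++k) {
    double v = std::exp(-0.5 * (k * bin_s) * (k * bin_s) / (sigma_s * sigma_s));
    kern[k + half_kern] = v; ksum += v;
  }
  for (auto& v : kern) v /= ksum;

  int nref = ref.size(), ntgt = tgt.size();
  std::vector<double> jr(nref), jt(ntgt), counts(2 * K + 1);
  NumericMatrix out(n_surrogates, 2);
  for (int s = 0; s < n_surrogates; ++s) {
    for (int i = 0; i < nref; ++i) jr[i] = ref[i] + R::runif(-jitter_s, jitter_s);
    for (int i = 0; i < ntgt; ++i) jt[i] = tgt[i] + R::runif(-jitter_s, jitter_s);
    std::sort(jr.begin(), jr.end());
    std::sort(jt.begin(), jt.end());
    std::fill(counts.begin(), counts.end(), 0.0);
    ccg_accumulate(jr.data(), nref, jt.data(), ntgt,
                   (K + 0.5) * bin_s, bin_s, false, counts.data(), K);
    double mx = R_NegInf, mn = R_PosInf;
    for (int b = -Kb; b <= Kb; ++b) {
      double sm = 0;
      for (int k = -half_kern; k <= half_kern; ++k)
        sm += kern[k + half_kern] * counts[b + k + K];
      if (sm > mx) mx = sm;
      if (sm < mn) mn = sm;
    }
    out(s, 0) = mx; out(s, 1) = mn;
  }
  return out;
}

// Permutation sums for the shuffle null of the REM-preference index.
// For each of n_shuffles draws, selects a uniformly random subset of n_rem
// bins (without replacement) out of length(counts) bins and returns the sum
// of counts over that subset. Partial Fisher-Yates, R RNG.
// [[Rcpp::export]]
NumericVector shuffle_subset_sums_cpp(NumericVector counts, int n_rem,
                                      int n_shuffles) {
  int n = counts.size();
  if (n_rem < 0 || n_rem > n) stop("n_rem out of range");
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  NumericVector out(n_shuffles);
  for (int s = 0; s < n_shuffles; ++s) {
    double acc = 0;
    for (int i = 0; i < n_rem; ++i) {
      int j = i + (int)std::floor(R::unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(idx[i], idx[j]);
      acc += counts[idx[i]];
    }
    out[s] = acc;
  }
  return out;
}
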