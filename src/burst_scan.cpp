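#include <Rcpp.h>
using namespace Rcpp;

// Poisson surprise of a candidate burst: S = -log P(X >= n) with
// X ~ Poisson(rate * span). Evaluated in the log domain so S stays finite
// and accurate well past 700 nats. A zero span with n >= 1 spikes has
// probability 0 under the Poisson null; S is capped at a large finite value.
static double surprise_s(int n, double span, double rate) {
  if (n <= 0) return 0.0;
  double lambda = rate * span;
  if (lambda <= 0.0) return 1e9;
  // log P(X >= n) = log upper tail at n-1
  double logp = R::ppois((double)(n - 1), lambda, 0, 1);
  double s = -logp;
  if (s < 0.0) s = 0.0;
  if (s > 1e9) s = 1e9;
  return s;
}

// Exact-decision fast path for the search loops: P(X >= n) >= the single
// Poisson term at n, so S <= lambda - n log(lambda) + lgamma(n + 1). When
// that upper bound does not beat `need_above`, the true S cannot either and
// the candidate is rejected without evaluating the tail. Returns the exact
// surprise otherwise, and -1 for a pruned candidate.
static double surprise_above(int n, double span, double rate,
                             double need_above) {
  if (n <= 0) return (0.0 > need_above) ? 0.0 : -1.0;
  double lambda = rate * span;
  if (lambda <= 0.0) return 1e9;
  double ub = lambda - n * std::log(lambda) + std::lgamma((double)n + 1.0);
  if (ub <= need_above) return -1.0;
  double s = surprise_s(n, span, rate);
  return (s > need_above) ? s : -1.0;
}

// Legendy-Salcman style burst scan over a single-electrode spike train.
// times: strictly increasing spike times (seconds) within the analysis window.
// rate: train mean rate = n / window length (spikes per second).
// Seeds on runs of >= 2 consecutive ISIs below seed_isi_factor * mean ISI,
// then alternately extends the right edge (with lookahead) while S increases
// and trims the left edge while S increases, to a fixed point. A candidate is
// accepted when S >= s_min and it holds >= min_spikes spikes; scanning resumes
// after its last spike so bursts are disjoint and time-ordered.
// Ties on extension keep the shorter burst (strict improvement required).
// [[Rcpp::export]]
DataFrame ls_burst_scan(NumericVector times, double rate, double s_min,
                        int min_spikes, double seed_isi_factor,
                        int lookahead = 10) {
  int n = times.size();
  std::vector<int> out_first, out_last;
  std::vector<double> out_s;
  if (n >= min_spikes && rate > 0.0) {
    double mean_isi = 1.0 / rate;
    double isi_thr = seed_isi_factor * mean_isi;
    int i = 0;
    int frontier = 0;  // first index not claimed by an accepted burst
    while (i + 2 < n) {
      // seed: two consecutive short ISIs -> spikes i..i+2
      if (!((times[i + 1] - times[i]) < isi_thr &&
            (times[i + 2] - times[i + 1]) < isi_thr)) {
        ++i;
        continue;
      }
      int b = i, e = i + 2;
      double s_cur = surprise_s(e - b + 1, times[e] - times[b], rate);
      bool changed = true;
      int guard = 0;
      while (changed && guard++ < 10000) {
        changed = false;
        // extend right: jump to the best extension within the lookahead
        // horizon whenever it strictly beats the current S, repeatedly
        for (;;) {
          int best_e = e;
          double best_s = s_cur;
          int hi = std::min(n - 1, e + lookahead);
          for (int j = e + 1; j <= hi; ++j) {
            double s_j = surprise_above(j - b + 1, times[j] - times[b], rate,
                                        best_s);
            if (s_j > best_s) { best_s = s_j; best_e = j; }
          }
          if (best_e == e) break;
          e = best_e; s_cur = best_s; changed = true;
        }
        // trim left: jump to the best left edge within the lookahead
        // horizon whenever it strictly beats the current S
        for (;;) {
          int best_b = b;
          double best_s = s_cur;
          int hi = std::min(e - min_spikes + 1, b + lookahead);
          for (int j = b + 1; j <= hi; ++j) {
            double s_j = surprise_above(e - j + 1, times[e] - times[j], rate,
                                        best_s);
            if (s_j > best_s) { best_s = s_j; best_b = j; }
          }
          if (best_b == b) break;
          b = best_b; s_cur = best_s; changed = true;
        }
      }
      // bounded exhaustive refinement: within the converged region (padded
      // by the lookahead on both sides) take the max-S subsequence. Escapes
      // local optima of the greedy edge moves at bounded extra cost; very
      // long regions keep the greedy solution.
      {
        int pad = std::min(lookahead, 5);
        int lo = std::max(frontier, b - pad);
        int hi = std::min(n - 1, e + pad);
        if (hi - lo + 1 <= 250) {
          for (int p = lo; p <= hi - min_spikes + 1; ++p) {
            for (int q = p + min_spikes - 1; q <= hi; ++q) {
              double s_pq = surprise_above(q - p + 1, times[q] - times[p],
                                           rate, s_cur);
              if (s_pq > s_cur) { s_cur = s_pq; b = p; e = q; }
            }
          }
        }
      }
      if (s_cur >= s_min && (e - b + 1) >= min_spikes && b >= frontier) {
        out_first.push_back(b + 1);  // 1-based for R
        out_last.push_back(e + 1);
        out_s.push_back(s_cur);
        frontier = e + 1;
        i = std::max(e + 1, i + 1);
      } else {
        ++i;
      }
    }
  }
  // merge pass: adjacent bursts whose union is more surprising than either
  // part collapse into one (the union is then the better maximum of the
  // same local structure). Repeats until stable.
  bool merged = true;
  while (merged && out_first.size() > 1) {
    merged = false;
    for (size_t k = 0; k + 1 < out_first.size(); ++k) {
      int b = out_first[k] - 1, e = out_last[k + 1] - 1;
      double s_u = surprise_s(e - b + 1, times[e] - times[b], rate);
      if (s_u > out_s[k] && s_u > out_s[k + 1]) {
        out_last[k] = out_last[k + 1];
        out_s[k] = s_u;
        out_first.erase(out_first.begin() + k + 1);
        out_last.erase(out_last.begin() + k + 1);
        out_s.erase(out_s.begin() + k + 1);
        merged = true;
        break;
      }
    }
  }
  return DataFrame::create(_["first"] = out_first, _["last"] = out_last,
                           _["surprise"] = out_s);
}

// Count, for every spike in x, the spikes of y within +/- halfwidth seconds.
// Both vectors sorted ascending. Used by the cross-correlation synchrony
// estimator (total pair count inside the lag window).
// [[Rcpp::export]]
double count_close_pairs(NumericVector x, NumericVector y, double halfwidth) {
  int nx = x.size(), ny = y.size();
  double total = 0.0;
  int lo = 0, hi = 0;
  for (int i = 0; i < nx; ++i) {
    double a = x[i] - halfwidth, b = x[i] + halfwidth;
    while (lo < ny && y[lo] < a) ++lo;
    if (hi < lo) hi = lo;
    while (hi < ny && y[hi] <= b) ++hi;
    total += (hi - lo);
  }
  return total;
}
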