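#include <Rcpp.h>
using namespace Rcpp;

// Codes: 1=A, 2=C, 3=G, 4=T, 5=N. Log-odds matrices are 5 x w with the N row
// contributing 0 by construction on the R side.

// Window scores for one contiguous coded sequence, single strand.
// [[Rcpp::export]]
NumericVector cpp_window_scores(IntegerVector codes, NumericMatrix lo) {
  const int w = lo.ncol();
  const int L = codes.size();
  if (L < w) return NumericVector(0);
  const int n = L - w + 1;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < w; ++j) {
      s += lo(codes[i + j] - 1, j);
    }
    out[i] = s;
  }
  return out;
}

// Per-sequence count of windows scoring >= threshold on either strand.
// `ends` are 1-based cumulative end positions of each sequence in `codes`.
// [[Rcpp::export]]
IntegerVector cpp_hit_counts(IntegerVector codes, IntegerVector ends,
                             NumericMatrix lo_fwd, NumericMatrix lo_rev,
                             double threshold) {
  const int w = lo_fwd.ncol();
  const int nseq = ends.size();
  IntegerVector out(nseq);
  int start = 0;
  for (int s = 0; s < nseq; ++s) {
    const int end = ends[s];  // exclusive, 0-based after subtracting 1 below
    const int L = end - start;
    int count = 0;
    if (L >= w) {
      const int nwin = L - w + 1;
      for (int i = 0; i < nwin; ++i) {
        double sf = 0.0, sr = 0.0;
        for (int j = 0; j < w; ++j) {
          const int c = codes[start + i + j] - 1;
          sf += lo_fwd(c, j);
          sr += lo_rev(c, j);
        }
        if (sf >= threshold || sr >= threshold) ++count;
      }
    }
    out[s] = count;
    start = end;
  }
  return out;
}

// Dinucleotide-preserving shuffle of each sequence (random Euler walk on the
// dinucleotide transition graph with retry; falls back to the identity
// permutation if no complete walk is found within `max_attempts`). Uses R's
// RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector cpp_dinuc_shuffle(IntegerVector codes, IntegerVector ends,
                                int max_attempts = 1000) {
  const int nseq = ends.size();
  IntegerVector out(codes.size());
  int start = 0;
  std::vector<int> edges[5];
  std::vector<int> pos[5];
  for (int s = 0; s < nseq; ++s) {
    const int end = ends[s];
    const int L = end - start;
    if (L <= 2) {
      for (int i = start; i < end; ++i) out[i] = codes[i];
      start = end;
      continue;
    }
    for (int a = 0; a < 5; ++a) edges[a].clear();
    for (int i = start; i < end - 1; ++i) {
      edges[codes[i] - 1].push_back(codes[i + 1]);
    }
    const int first = codes[start];
    bool done = false;
    for (int attempt = 0; attempt < max_attempts && !done; ++attempt) {
      // Fisher-Yates shuffle of each successor list
      for (int a = 0; a < 5; ++a) {
        std::vector<int>& e = edges[a];
        for (int i = (int)e.size() - 1; i > 0; --i) {
          int j = (int)(unif_rand() * (i + 1));
          if (j > i) j = i;
          std::swap(e[i], e[j]);
        }
      }
      int idx[5] = {0, 0, 0, 0, 0};
      int cur = first;
      out[start] = first;
      int i = 1;
      for (; i < L; ++i) {
        std::vector<int>& e = edges[cur - 1];
        if (idx[cur - 1] >= (int)e.size()) break;  // stuck: retry
        cur = e[idx[cur - 1]++];
        out[start + i] = cur;
      }
      done = (i == L);
    }
    if (!done) {
      for (int i = start; i < end; ++i) out[i] = codes[i];
    }
    start = end;
  }
  return out;
}
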