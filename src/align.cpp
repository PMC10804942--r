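#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with match +1 / mismatch 0 / gap -1,
// the scoring under which score = matches - gaps and identity counting is
// direct. Traceback tie preference is fixed (diagonal, then gap-in-b/up,
// then gap-in-a/left) so that identity and coverage are deterministic.
// Returns matches, aligned residue pairs, alignment columns and score.
// columns = |a| + |b| - pairs (every unpaired residue is its own column).

// [[Rcpp::export(name = ".nw_align_stats")]]
List nw_align_stats(std::string a, std::string b) {
  const int la = a.size(), lb = b.size();
  if (la == 0 || lb == 0) stop("sequences must be nonempty");

  // DP over (la+1) x (lb+1); int scores fit easily.
  std::vector<int> S((la + 1) * (lb + 1));
  auto idx = [lb](int i, int j) { return i * (lb + 1) + j; };
  for (int i = 0; i <= la; ++i) S[idx(i, 0)] = -i;
  for (int j = 0; j <= lb; ++j) S[idx(0, j)] = -j;
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      int diag = S[idx(i - 1, j - 1)] + (a[i - 1] == b[j - 1] ? 1 : 0);
      int up = S[idx(i - 1, j)] - 1;
      int left = S[idx(i, j - 1)] - 1;
      int best = diag;
      if (up > best) best = up;
      if (left > best) best = left;
      S[idx(i, j)] = best;
    }
  }

  // Traceback with fixed preference diag > up > left.
  int i = la, j = lb, matches = 0, pairs = 0;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      int diag = S[idx(i - 1, j - 1)] + (a[i - 1] == b[j - 1] ? 1 : 0);
      if (S[idx(i, j)] == diag) {
        if (a[i - 1] == b[j - 1]) ++matches;
        ++pairs;
        --i; --j;
        continue;
      }
    }
    if (i > 0 && S[idx(i, j)] == S[idx(i - 1, j)] - 1) {
      --i;
      continue;
    }
    --j;
  }

  const int columns = la + lb - pairs;
  return List::create(_["matches"] = matches, _["pairs"] = pairs,
                      _["columns"] = columns, _["score"] = S[idx(la, lb)]);
}

// Batch version used by the greedy clusterer: align one query against many
// candidate centroids, returning identity and per-sequence coverages.

// [[Rcpp::export(name = ".nw_align_batch")]]
NumericMatrix nw_align_batch(std::string query, CharacterVector targets) {
  const int n = targets.size();
  NumericMatrix out(n, 3);
  colnames(out) = CharacterVector::create("identity", "cov_query", "cov_target");
  for (int t = 0; t < n; ++t) {
    std::string b = as<std::string>(targets[t]);
    List r = nw_align_stats(query, b);
    const double matches = as<int>(r["matches"]);
    const double pairs = as<int>(r["pairs"]);
    const double columns = as<int>(r["columns"]);
    out(t, 0) = matches / columns;
    out(t, 1) = pairs / (double)query.size();
    out(t, 2) = pairs / (double)b.size();
  }
  return out;
}
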