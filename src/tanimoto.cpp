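#include <Rcpp.h>
using namespace Rcpp;

// Linear merge of two ascending score arrays; accumulates the shared-score
// intersection under the multiset (sum of min counts) or set (shared score
// count) interpretation. Scores arrive as doubles so that q > 4 packings
// (exact integers above 2^31) share one code path.
static double tanimoto_merge(const double* sa, const int* na, int ma, int suma,
                             const double* sb, const int* nb, int mb, int sumb,
                             bool multiset) {
  double inter = 0.0;
  int i = 0, j = 0;
  while (i < ma && j < mb) {
    if (sa[i] < sb[j]) {
      ++i;
    } else if (sa[i] > sb[j]) {
      ++j;
    } else {
      inter += multiset ? (double)std::min(na[i], nb[j]) : 1.0;
      ++i;
      ++j;
    }
  }
  double uni = multiset ? (double)suma + (double)sumb - inter
                        : (double)ma + (double)mb - inter;
  return uni == 0.0 ? 0.0 : inter / uni;
}

// [[Rcpp::export]]
double cpp_tanimoto(NumericVector scores_a, IntegerVector numbers_a,
                    NumericVector scores_b, IntegerVector numbers_b,
                    bool multiset) {
  int suma = 0, sumb = 0;
  for (int k = 0; k < numbers_a.size(); ++k) suma += numbers_a[k];
  for (int k = 0; k < numbers_b.size(); ++k) sumb += numbers_b[k];
  return tanimoto_merge(REAL(scores_a), INTEGER(numbers_a), scores_a.size(), suma,
                        REAL(scores_b), INTEGER(numbers_b), scores_b.size(), sumb,
                        multiset);
}

// Compare a block of query profiles (rows `q_idx`, 0-based into the query
// CSR arrays) against every database profile. Profiles are passed in
// CSR-style flattened form: concatenated scores/numbers plus offsets.
// Returns the m x r block (rows in q_idx order) and the number of pairwise
// comparisons performed.
// [[Rcpp::export]]
List cpp_tanimoto_block(NumericVector q_scores, IntegerVector q_numbers,
                        IntegerVector q_offsets,
                        NumericVector d_scores, IntegerVector d_numbers,
                        IntegerVector d_offsets,
                        IntegerVector q_idx, bool multiset) {
  int r = d_offsets.size() - 1;
  int m = q_idx.size();
  NumericMatrix out(m, r);

  std::vector<int> q_sums(q_offsets.size() - 1), d_sums(r);
  for (int c = 0; c + 1 < q_offsets.size(); ++c) {
    int s = 0;
    for (int k = q_offsets[c]; k < q_offsets[c + 1]; ++k) s += q_numbers[k];
    q_sums[c] = s;
  }
  for (int c = 0; c < r; ++c) {
    int s = 0;
    for (int k = d_offsets[c]; k < d_offsets[c + 1]; ++k) s += d_numbers[k];
    d_sums[c] = s;
  }

  const double* qs = REAL(q_scores);
  const int* qn = INTEGER(q_numbers);
  const double* ds = REAL(d_scores);
  const int* dn = INTEGER(d_numbers);
  double n_pairs = 0.0;

  for (int row = 0; row < m; ++row) {
    int qi = q_idx[row];
    int qo = q_offsets[qi], qm = q_offsets[qi + 1] - qo;
    for (int col = 0; col < r; ++col) {
      int po = d_offsets[col], pm = d_offsets[col + 1] - po;
      out(row, col) = tanimoto_merge(qs + qo, qn + qo, qm, q_sums[qi],
                                     ds + po, dn + po, pm, d_sums[col],
                                     multiset);
      n_pairs += 1.0;
    }
  }
  return List::create(_["values"] = out, _["n_pairs"] = n_pairs);
}
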