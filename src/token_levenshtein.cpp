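#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdlib>
using namespace Rcpp;

// Unit-cost Levenshtein distance over integer-coded token sequences.
// Two-row dynamic programme; tokens compared by exact equality.
static int lev_core(const int* a, int na, const int* b, int nb) {
  if (na == 0) return nb;
  if (nb == 0) return na;
  std::vector<int> prev(nb + 1), cur(nb + 1);
  for (int j = 0; j <= nb; ++j) prev[j] = j;
  for (int i = 1; i <= na; ++i) {
    cur[0] = i;
    for (int j = 1; j <= nb; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[nb];
}

static double sim_core(const int* a, int na, const int* b, int nb) {
  int m = std::max(na, nb);
  if (m == 0) return 1.0;  // both empty: identical by convention
  return 1.0 - static_cast<double>(lev_core(a, na, b, nb)) / m;
}

// [[Rcpp::export]]
int cpp_word_lev(IntegerVector a, IntegerVector b) {
  return lev_core(a.begin(), a.size(), b.begin(), b.size());
}

// [[Rcpp::export]]
double cpp_norm_sim(IntegerVector a, IntegerVector b) {
  return sim_core(a.begin(), a.size(), b.begin(), b.size());
}

// Greedy leader clustering in input (chronological) order: each record joins
// the first existing leader with similarity >= threshold, else founds a new
// cluster. The |len(a)-len(b)| lower bound on the distance gives an upper
// bound on similarity, used to skip the DP without changing the result.
// [[Rcpp::export]]
List cpp_leader_cluster(List toks, double threshold) {
  int n = toks.size();
  IntegerVector leader(n);       // 1-based index of each record's leader
  NumericVector sim(n);          // similarity to that leader (1 for leaders)
  std::vector<IntegerVector> seqs(n);
  for (int i = 0; i < n; ++i) seqs[i] = as<IntegerVector>(toks[i]);
  std::vector<int> leaders;
  leaders.reserve(n);
  for (int i = 0; i < n; ++i) {
    int na = seqs[i].size();
    int found = -1;
    double fsim = 1.0;
    for (size_t k = 0; k < leaders.size(); ++k) {
      int j = leaders[k];
      int nb = seqs[j].size();
      int m = std::max(na, nb);
      if (m > 0) {
        double ub = 1.0 - static_cast<double>(std::abs(na - nb)) / m;
        if (ub < threshold) continue;  // cannot reach the threshold
      }
      double s = sim_core(seqs[i].begin(), na, seqs[j].begin(), nb);
      if (s >= threshold) { found = j; fsim = s; break; }
    }
    if (found < 0) {
      leaders.push_back(i);
      leader[i] = i + 1;
      sim[i] = 1.0;
    } else {
      leader[i] = found + 1;
      sim[i] = fsim;
    }
  }
  return List::create(_["leader"] = leader, _["similarity"] = sim);
}

// Normalized similarity of every query sequence against every reference
// sequence; rows are queries, columns references.
// [[Rcpp::export]]
NumericMatrix cpp_sim_matrix(List queries, List refs) {
  int nq = queries.size(), nr = refs.size();
  NumericMatrix out(nq, nr);
  std::vector<IntegerVector> qs(nq), rs(nr);
  for (int i = 0; i < nq; ++i) qs[i] = as<IntegerVector>(queries[i]);
  for (int j = 0; j < nr; ++j) rs[j] = as<IntegerVector>(refs[j]);
  for (int i = 0; i < nq; ++i)
    for (int j = 0; j < nr; ++j)
      out(i, j) = sim_core(qs[i].begin(), qs[i].size(),
                           rs[j].begin(), rs[j].size());
  return out;
}
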