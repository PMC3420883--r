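#include <Rcpp.h>
using namespace Rcpp;

// Neutral coalescent null distribution of Tajima's D.
//
// For each replicate a standard neutral genealogy of n tips is simulated
// (exponential waiting times with rate j(j-1)/2 while j lineages remain,
// random pair merged).  Mutations are a Poisson process along branches with
// rate theta/2 per unit coalescent time (or exactly S mutations allocated
// proportionally to branch length when fixed_S).  Each mutation on a branch
// subtending i tips contributes i*(n-i) pairwise differences, from which
// k_bar and S give D.  Replicates with S == 0 yield NA.
//
// Returns a two-column matrix (D, S); D is NA for S == 0 replicates.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix coal_null_d_cpp(int n, double theta, int nrep, bool fixed_S,
                              int S_obs, double a1, double e1, double e2) {
  NumericMatrix out(nrep, 2);
  int nseg = 2 * (n - 1);
  std::vector<double> seg_len(nseg);
  std::vector<int> seg_desc(nseg);
  std::vector<double> len(n);
  std::vector<int> desc(n);
  double npairs = n * (n - 1.0) / 2.0;

  for (int rep = 0; rep < nrep; rep++) {
    int active = n;
    for (int i = 0; i < n; i++) { len[i] = 0.0; desc[i] = 1; }
    int s_i = 0;
    double total_len = 0.0;
    while (active > 1) {
      double rate = active * (active - 1.0) / 2.0;
      double t = R::exp_rand() / rate;
      for (int i = 0; i < active; i++) len[i] += t;
      total_len += active * t;
      // pick an unordered pair (i < j)
      int i = (int)(R::unif_rand() * active);
      if (i >= active) i = active - 1;
      int j = (int)(R::unif_rand() * (active - 1));
      if (j >= active - 1) j = active - 2;
      if (j >= i) j++;
      if (i > j) std::swap(i, j);
      // record both finished segments
      seg_len[s_i] = len[i];  seg_desc[s_i] = desc[i];  s_i++;
      seg_len[s_i] = len[j];  seg_desc[s_i] = desc[j];  s_i++;
      // merged lineage replaces slot i; last active slot moves to j
      desc[i] += desc[j];
      len[i] = 0.0;
      desc[j] = desc[active - 1];
      len[j] = len[active - 1];
      active--;
    }
    int S;
    if (fixed_S) {
      S = S_obs;
    } else {
      S = (int)R::rpois(theta / 2.0 * total_len);
    }
    out(rep, 1) = (double)S;
    if (S == 0) {
      out(rep, 0) = NA_REAL;
      continue;
    }
    double diffsum = 0.0;
    for (int m = 0; m < S; m++) {
      double u = R::unif_rand() * total_len;
      double acc = 0.0;
      int hit = nseg - 1;
      for (int s = 0; s < nseg; s++) {
        acc += seg_len[s];
        if (u <= acc) { hit = s; break; }
      }
      double i = (double)seg_desc[hit];
      diffsum += i * (n - i);
    }
    double k_bar = diffsum / npairs;
    double Sd = (double)S;
    out(rep, 0) = (k_bar - Sd / a1) / std::sqrt(e1 * Sd + e2 * Sd * (Sd - 1.0));
  }
  return out;
}
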