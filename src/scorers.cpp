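// Fast inner loops for matrix-representation scoring. Trees arrive as
// postorder edge lists (1-based ape node numbering); columns are scored
// simultaneously.

#include <Rcpp.h>
using namespace Rcpp;

// Fitch parsimony counts per column. tipstates: ntip x ncol with state sets
// encoded as bitmasks (1 = {0}, 2 = {1}, 3 = {0,1}).
// [[Rcpp::export(name = ".fitch_counts_cpp")]]
NumericVector fitch_counts(IntegerMatrix edge, int ntip, int nnode,
                           IntegerMatrix tipstates) {
  const int ncol = tipstates.ncol();
  const int nn = ntip + nnode;
  std::vector<int> S((size_t) nn * ncol, 3);
  std::vector<char> has((size_t) nn, 0);
  NumericVector cost(ncol);
  for (int i = 0; i < ntip; ++i)
    for (int c = 0; c < ncol; ++c) S[(size_t) i * ncol + c] = tipstates(i, c);
  const int ne = edge.nrow();
  for (int k = 0; k < ne; ++k) {
    const int p = edge(k, 0) - 1, ch = edge(k, 1) - 1;
    int *Sp = &S[(size_t) p * ncol];
    const int *Sc = &S[(size_t) ch * ncol];
    if (!has[p]) {
      std::copy(Sc, Sc + ncol, Sp);
      has[p] = 1;
    } else {
      for (int c = 0; c < ncol; ++c) {
        int a = Sp[c] & Sc[c];
        if (a == 0) { cost[c] += 1.0; a = Sp[c] | Sc[c]; }
        Sp[c] = a;
      }
    }
  }
  return cost;
}

// Camin-Sokal (irreversible 0->1) parsimony counts per column on a rooted
// tree. tipstates: ntip x ncol with 0, 1 or NA ('?').
// [[Rcpp::export(name = ".cs_counts_cpp")]]
NumericVector cs_counts(IntegerMatrix edge, int ntip, int nnode,
                        IntegerMatrix tipstates) {
  const int ncol = tipstates.ncol();
  const int nn = ntip + nnode;
  const double INF = 1e9;
  std::vector<double> C0((size_t) nn * ncol, 0.0), C1((size_t) nn * ncol, 0.0);
  for (int i = 0; i < ntip; ++i) {
    for (int c = 0; c < ncol; ++c) {
      const int o = tipstates(i, c);
      if (o == NA_INTEGER) continue;
      if (o == 1) C0[(size_t) i * ncol + c] = INF;
      else C1[(size_t) i * ncol + c] = INF;
    }
  }
  const int ne = edge.nrow();
  int root = 0;
  for (int k = 0; k < ne; ++k) {
    const int p = edge(k, 0) - 1, ch = edge(k, 1) - 1;
    root = p;
    double *c0p = &C0[(size_t) p * ncol], *c1p = &C1[(size_t) p * ncol];
    const double *c0c = &C0[(size_t) ch * ncol], *c1c = &C1[(size_t) ch * ncol];
    for (int c = 0; c < ncol; ++c) {
      const double gain = c1c[c] + 1.0;
      c0p[c] += (c0c[c] < gain) ? c0c[c] : gain;
      c1p[c] += c1c[c];
    }
  }
  NumericVector out(ncol);
  for (int c = 0; c < ncol; ++c) {
    double v = C0[(size_t) root * ncol + c];
    out[c] = (v > INF) ? INF : v;
  }
  return out;
}

// Minimum definite-entry flips per column so the column's 1-set becomes a
// split block of the tree or a trivial set. cand holds only the non-trivial
// split blocks (ntaxa x k, 0/1); the trivial sets (empty, full, singletons
// and their complements) are scored in closed form. ones/zeros: ntaxa x
// ncol definite-entry indicators.
// [[Rcpp::export(name = ".flip_counts_cpp")]]
NumericVector flip_counts(IntegerMatrix cand, IntegerMatrix ones,
                          IntegerMatrix zeros) {
  const int n = cand.nrow(), k = cand.ncol(), ncol = ones.ncol();
  std::vector< std::vector<int> > memb(k);
  const int *cd = INTEGER(cand);
  for (int j = 0; j < k; ++j) {
    const int *cj = cd + (size_t) j * n;
    for (int i = 0; i < n; ++i) if (cj[i]) memb[j].push_back(i);
  }
  const int *on = INTEGER(ones), *ze = INTEGER(zeros);
  NumericVector out(ncol);
  for (int c = 0; c < ncol; ++c) {
    const int *oc = on + (size_t) c * n, *zc = ze + (size_t) c * n;
    int n1 = 0, S = 0, minsing = INT_MAX, mincos = INT_MAX;
    for (int i = 0; i < n; ++i) {
      const int d = zc[i] - oc[i];
      n1 += oc[i];
      S += d;
      if (d < minsing) minsing = d;       // best singleton {i}
      if (-d < mincos) mincos = -d;       // best complement of {i}
    }
    int best = n1;                        // empty set
    if (n1 + S < best) best = n1 + S;     // full set
    if (n1 + minsing < best) best = n1 + minsing;
    if (n1 + S + mincos < best) best = n1 + S + mincos;
    for (int j = 0; j < k && best > 0; ++j) {
      int mism = n1;
      for (size_t t = 0; t < memb[j].size(); ++t) {
        const int i = memb[j][t];
        mism += zc[i] - oc[i];
      }
      if (mism < best) best = mism;
    }
    out[c] = best;
  }
  return out;
}

// Pairwise 4x4 site-pattern counts over mutually determined sites.
// seqs: ntaxa x nsites integer codes 1..4 with NA for missing.
// Returns choose(n,2) x 16 counts, pairs in combn order (row-major cells).
// [[Rcpp::export(name = ".pair_counts_cpp")]]
IntegerMatrix pair_counts(IntegerMatrix seqs) {
  const int n = seqs.nrow(), L = seqs.ncol();
  const int P = n * (n - 1) / 2;
  IntegerMatrix out(P, 16);
  const int *S = INTEGER(seqs);
  // column-major: site s, taxon i at S[s*n + i]
  int p = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j, ++p) {
      int cnt[16] = {0};
      for (int s = 0; s < L; ++s) {
        const int a = S[(size_t) s * n + i], b = S[(size_t) s * n + j];
        if (a == NA_INTEGER || b == NA_INTEGER) continue;
        cnt[(a - 1) * 4 + (b - 1)]++;
      }
      for (int c = 0; c < 16; ++c) out(p, c) = cnt[c];
    }
  }
  return out;
}
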