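#include <Rcpp.h>
using namespace Rcpp;

// One or more Wright-Fisher generations on a pool of gene copies.
//
// `alleles` is (copies x loci) integer allele sizes. Loci are unlinked and
// mating is random, so each gene copy at each locus picks a uniform parent
// copy independently. Mutation follows the symmetric single-step model at
// rate mu per copy per generation, with the downward step at size 1
// reflected upward so sizes stay positive.
//
// `labels` is an optional parallel matrix of integer ancestry labels that is
// transmitted with the same parent choices (pass a 0x0 matrix to skip).
// Uses R's RNG, so results are reproducible under set.seed().

// [[Rcpp::export]]
List wf_evolve_cpp(IntegerMatrix alleles, IntegerMatrix labels,
                   int n_out, int generations, double mu) {
  const int L = alleles.ncol();
  const bool track = labels.nrow() > 0;
  if (track && (labels.nrow() != alleles.nrow() || labels.ncol() != L))
    stop("labels must match alleles in shape");
  if (n_out < 1) stop("n_out must be >= 1");

  IntegerMatrix cur = clone(alleles);
  IntegerMatrix curlab = track ? clone(labels) : IntegerMatrix(0, 0);

  for (int g = 0; g < generations; ++g) {
    const int n_in = cur.nrow();
    IntegerMatrix nxt(n_out, L);
    IntegerMatrix nxtlab = track ? IntegerMatrix(n_out, L) : IntegerMatrix(0, 0);
    for (int l = 0; l < L; ++l) {
      for (int r = 0; r < n_out; ++r) {
        int parent = (int)(unif_rand() * n_in);
        if (parent == n_in) parent = n_in - 1;  // guard unif_rand() == 1
        int a = cur(parent, l);
        if (mu > 0.0 && unif_rand() < mu) {
          if (a <= 1) a = 2;                      // reflect at the floor
          else a += (unif_rand() < 0.5) ? 1 : -1;
        }
        nxt(r, l) = a;
        if (track) nxtlab(r, l) = curlab(parent, l);
      }
    }
    cur = nxt;
    if (track) curlab = nxtlab;
  }

  return List::create(_["alleles"] = cur, _["labels"] = curlab);
}

// Mean expected heterozygosity (1 - sum p^2, identity form) over loci of a
// pool of gene copies; used by the simulator's burn-in monitor.

// [[Rcpp::export]]
double pool_heterozygosity_cpp(IntegerMatrix alleles) {
  const int n = alleles.nrow(), L = alleles.ncol();
  if (n == 0 || L == 0) return NA_REAL;
  double acc = 0.0;
  std::map<int, int> tab;
  for (int l = 0; l < L; ++l) {
    tab.clear();
    for (int r = 0; r < n; ++r) tab[alleles(r, l)]++;
    double ss = 0.0;
    for (std::map<int, int>::iterator it = tab.begin(); it != tab.end(); ++it) {
      const double p = (double)it->second / n;
      ss += p * p;
    }
    acc += 1.0 - ss;
  }
  return acc / L;
}
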