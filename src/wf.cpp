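#include <Rcpp.h>
using namespace Rcpp;

// One generation of Wright-Fisher random mating with recombination.
//
// Haplotypes are stored marker-major: H is m x 2N with one COLUMN per
// parental haplotype (columns 2i, 2i+1 belong to diploid i), so a gamete is
// assembled from contiguous column segments.  Each offspring draws two
// parents (weighted by fitness, no selfing when N > 1) and receives one
// recombinant gamete from each.  Crossover breakpoints fall as a Poisson
// process with rate `recomb_rate` per bp along each chromosome; chromosomes
// assort independently.  Uses R's RNG so results are governed by set.seed().
//
// chrom_start/chrom_end: 0-based inclusive row ranges per chromosome.

static int sample_weighted(const NumericVector &cumw, double total) {
  double u = unif_rand() * total;
  int lo = 0, hi = cumw.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cumw[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

static void make_gamete(const int *hp, int m, int parent,
                        const IntegerVector &chrom_start,
                        const IntegerVector &chrom_end,
                        const NumericVector &pos,
                        const NumericVector &chrom_len,
                        double recomb_rate, int *gp) {
  const int n_chrom = chrom_start.size();
  const int *h0 = hp + (size_t)(2 * parent) * m;
  const int *h1 = h0 + m;
  for (int ch = 0; ch < n_chrom; ++ch) {
    int a = chrom_start[ch], b = chrom_end[ch];
    int nbp = (int)R::rpois(recomb_rate * chrom_len[ch]);
    const int *cur = (unif_rand() < 0.5) ? h0 : h1;
    if (nbp == 0) {
      std::copy(cur + a, cur + b + 1, gp + a);
      continue;
    }
    std::vector<double> bp(nbp);
    for (int k = 0; k < nbp; ++k) bp[k] = unif_rand() * chrom_len[ch];
    std::sort(bp.begin(), bp.end());
    int j = a;
    for (int k = 0; k <= nbp; ++k) {
      // segment ends at the first marker whose position >= bp[k]
      int seg_end;
      if (k == nbp) {
        seg_end = b + 1;
      } else {
        const double *base = pos.begin();
        const double *lo = std::lower_bound(base + j, base + b + 1, bp[k]);
        seg_end = (int)(lo - base);
      }
      if (seg_end > j) std::copy(cur + j, cur + seg_end, gp + j);
      j = seg_end;
      cur = (cur == h0) ? h1 : h0;
      if (j > b) break;
    }
  }
}

// [[Rcpp::export(name = ".wf_next_gen_cpp")]]
IntegerMatrix wf_next_gen_cpp(IntegerMatrix H, IntegerVector chrom_start,
                              IntegerVector chrom_end, NumericVector pos,
                              NumericVector chrom_len, double recomb_rate,
                              NumericVector parent_weight, int n_offspring) {
  const int m = H.nrow();
  const int n_parent = H.ncol() / 2;
  if (parent_weight.size() != n_parent)
    stop("parent_weight length must equal the number of parents");
  NumericVector cumw(n_parent);
  double total = 0;
  for (int i = 0; i < n_parent; ++i) {
    total += parent_weight[i];
    cumw[i] = total;
  }
  if (total <= 0) stop("all parent weights are zero");
  IntegerMatrix out(m, 2 * n_offspring);
  const int *hp = H.begin();
  int *op = out.begin();
  for (int k = 0; k < n_offspring; ++k) {
    int pa = sample_weighted(cumw, total);
    int pb = sample_weighted(cumw, total);
    int guard = 0;
    while (pb == pa && n_parent > 1 && ++guard < 1000)
      pb = sample_weighted(cumw, total);
    make_gamete(hp, m, pa, chrom_start, chrom_end, pos, chrom_len,
                recomb_rate, op + (size_t)(2 * k) * m);
    make_gamete(hp, m, pb, chrom_start, chrom_end, pos, chrom_len,
                recomb_rate, op + (size_t)(2 * k + 1) * m);
  }
  return out;
}
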