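#include <Rcpp.h>
using namespace Rcpp;

// Mendelian transmission at 10 diploid biallelic loci. Columns 2l-1, 2l
// (1-based) hold the two alleles of locus l; the child's maternal allele
// lands in the odd column, the paternal in the even column. One uniform
// per (child, locus) supplies both fair coin flips (its quartile index:
// low bit picks the maternal allele, high bit the paternal), so draws are
// reproducible under set.seed() via the runif() buffer the caller passes.

// Survivor rows of the genotype matrix stacked over this year's recruit
// genotypes, in one allocation (the per-year population rebuild).

// [[Rcpp::export(name = ".geno_rebuild")]]
IntegerMatrix geno_rebuild(const IntegerMatrix& geno,
                           const IntegerVector& keep,
                           const IntegerMatrix& child) {
  const int nk = keep.size(), nc = child.nrow(), ng = geno.nrow();
  const int nout = nk + nc;
  IntegerMatrix out(nout, 20);
  const int* g = geno.begin();
  const int* c = child.begin();
  int* o = out.begin();
  for (int j = 0; j < 20; ++j) {
    const int* gj = g + (R_xlen_t)ng * j;
    const int* cj = c + (R_xlen_t)nc * j;
    int* oj = o + (R_xlen_t)nout * j;
    for (int i = 0; i < nk; ++i) {
      const int idx = keep[i] - 1;
      if (idx < 0 || idx >= ng) stop("keep index out of range");
      oj[i] = gj[idx];
    }
    for (int i = 0; i < nc; ++i) oj[nk + i] = cj[i];
  }
  return out;
}

// [[Rcpp::export(name = ".inherit_indexed")]]
IntegerMatrix inherit_indexed(const IntegerMatrix& geno,
                              const IntegerVector& mom,
                              const IntegerVector& dad,
                              const NumericVector& u) {
  const int n = mom.size();
  const int ng = geno.nrow();
  if (dad.size() != n) stop("mom and dad index vectors differ in length");
  if (u.size() < 10 * n) stop("need 10 uniforms per offspring");
  const int* g = geno.begin();
  IntegerMatrix child(n, 20);
  int* ch = child.begin();
  for (int i = 0; i < n; ++i) {
    const int mi = mom[i] - 1, di = dad[i] - 1;
    if (mi < 0 || mi >= ng || di < 0 || di >= ng)
      stop("parent index out of range");
    const double* ui = &u[10 * i];
    for (int l = 0; l < 10; ++l) {
      const int q = (int)(ui[l] * 4.0) & 3;
      ch[i + n * (2 * l)] = g[mi + ng * (2 * l + (q & 1))];
      ch[i + n * (2 * l + 1)] = g[di + ng * (2 * l + (q >> 1))];
    }
  }
  return child;
}
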