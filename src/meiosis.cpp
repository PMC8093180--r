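#include <Rcpp.h>
using namespace Rcpp;

// Free recombination: at each locus the transmitted allele is drawn from the
// parent's two haplotypes with probability 1/2, independently across loci;
// the nontransmitted haplotype is the locus-wise complement. Uses R's RNG so
// set.seed() governs reproducibility.
// [[Rcpp::export]]
List meiosis_cpp(const IntegerMatrix& h1, const IntegerMatrix& h2,
                 const IntegerVector& parent) {
  const int n = parent.size();
  const int m = h1.ncol();
  IntegerMatrix tr(n, m), nt(n, m);
  std::vector<int> pidx(n);
  for (int r = 0; r < n; ++r) {
    int p = parent[r] - 1;
    if (p < 0 || p >= h1.nrow()) stop("parent index out of range");
    pidx[r] = p;
  }
  for (int c = 0; c < m; ++c) {
    for (int r = 0; r < n; ++r) {
      const int p = pidx[r];
      if (unif_rand() < 0.5) {
        tr(r, c) = h1(p, c);
        nt(r, c) = h2(p, c);
      } else {
        tr(r, c) = h2(p, c);
        nt(r, c) = h1(p, c);
      }
    }
  }
  return List::create(_["transmitted"] = tr, _["nontransmitted"] = nt);
}

// Fused meiosis + haplotypic-score accumulation for one generation: draws
// the paternal and maternal gametes for every offspring and accumulates the
// transmitted / nontransmitted PGS (first m_obs loci, weights beta_obs) and
// LGS (remaining loci, weights beta_lat) without materializing the
// nontransmitted haplotype matrices. Offspring haplotypes (hap1 = paternal)
// are returned only when keep_haplotypes is true (final generation).
// [[Rcpp::export]]
List offspring_scores_cpp(const IntegerMatrix& h1, const IntegerMatrix& h2,
                          const IntegerVector& fathers,
                          const IntegerVector& mothers,
                          const NumericVector& beta_obs,
                          const NumericVector& beta_lat,
                          const bool keep_haplotypes) {
  const int n = fathers.size();
  const int m = h1.ncol();
  const int m_obs = beta_obs.size();
  if (mothers.size() != n) stop("fathers/mothers length mismatch");
  if (m_obs + beta_lat.size() != m) stop("weights do not cover all loci");

  NumericVector tp(n), ntp(n), tm(n), ntm(n);
  NumericVector ltp(n), lntp(n), ltm(n), lntm(n);
  IntegerMatrix o1, o2;
  if (keep_haplotypes) {
    o1 = IntegerMatrix(n, m);
    o2 = IntegerMatrix(n, m);
  }
  std::vector<int> fi(n), mi(n);
  for (int r = 0; r < n; ++r) {
    fi[r] = fathers[r] - 1;
    mi[r] = mothers[r] - 1;
    if (fi[r] < 0 || fi[r] >= h1.nrow() || mi[r] < 0 || mi[r] >= h1.nrow())
      stop("parent index out of range");
  }
  for (int c = 0; c < m; ++c) {
    const bool obs = c < m_obs;
    const double b = obs ? beta_obs[c] : beta_lat[c - m_obs];
    const int* col1 = &h1(0, c);
    const int* col2 = &h2(0, c);
    for (int r = 0; r < n; ++r) {
      int t_pat, nt_pat, t_mat, nt_mat;
      if (unif_rand() < 0.5) {
        t_pat = col1[fi[r]]; nt_pat = col2[fi[r]];
      } else {
        t_pat = col2[fi[r]]; nt_pat = col1[fi[r]];
      }
      if (unif_rand() < 0.5) {
        t_mat = col1[mi[r]]; nt_mat = col2[mi[r]];
      } else {
        t_mat = col2[mi[r]]; nt_mat = col1[mi[r]];
      }
      if (obs) {
        tp[r] += b * t_pat; ntp[r] += b * nt_pat;
        tm[r] += b * t_mat; ntm[r] += b * nt_mat;
      } else {
        ltp[r] += b * t_pat; lntp[r] += b * nt_pat;
        ltm[r] += b * t_mat; lntm[r] += b * nt_mat;
      }
      if (keep_haplotypes) {
        o1(r, c) = t_pat;
        o2(r, c) = t_mat;
      }
    }
  }
  List out = List::create(
    _["T_p"] = tp, _["NT_p"] = ntp, _["T_m"] = tm, _["NT_m"] = ntm,
    _["LT_p"] = ltp, _["LNT_p"] = lntp, _["LT_m"] = ltm, _["LNT_m"] = lntm
  );
  if (keep_haplotypes) {
    out["h1"] = o1;
    out["h2"] = o2;
  }
  return out;
}
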