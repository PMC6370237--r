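#include <Rcpp.h>
using namespace Rcpp;

// Mendelian transmission probability of child T-dosage gc given parent
// dosages gs, gd (each 0/1/2)
static inline double transmit(int gc, int gs, int gd) {
  double ps = gs / 2.0, pd = gd / 2.0;
  switch (gc) {
  case 0: return (1.0 - ps) * (1.0 - pd);
  case 1: return ps * (1.0 - pd) + (1.0 - ps) * pd;
  default: return ps * pd;
  }
}

// transmission with the second parent unknown, integrated over HWE(q)
static inline double transmit_unknown(int gc, int gp, double q) {
  double hw0 = (1.0 - q) * (1.0 - q), hw1 = 2.0 * q * (1.0 - q),
         hw2 = q * q;
  return hw0 * transmit(gc, gp, 0) + hw1 * transmit(gc, gp, 1) +
         hw2 * transmit(gc, gp, 2);
}

// One single-site Gibbs sweep over all genotypes, in pedigree order.
// geno is modified in place. sire/dam/childMate hold 1-based indices,
// 0 = unknown. children[i] lists offspring of i; childMate[i] the other
// parent of each such offspring. y holds phenotypes, NA = unobserved.
// means[g] is the phenotype mean for dosage g; s2e the residual variance.
// [[Rcpp::export]]
void gibbs_genotype_sweep(IntegerVector geno, IntegerVector sire,
                          IntegerVector dam, List children, List childMate,
                          NumericVector y, NumericVector means, double s2e,
                          double q) {
  int n = geno.size();
  RNGScope scope;
  for (int i = 0; i < n; i++) {
    double logw[3];
    int s = sire[i], d = dam[i];
    IntegerVector kids = children[i];
    IntegerVector mates = childMate[i];
    bool obs = !NumericVector::is_na(y[i]);
    for (int g = 0; g < 3; g++) {
      double pr;
      if (s > 0 && d > 0) pr = transmit(g, geno[s - 1], geno[d - 1]);
      else if (s > 0) pr = transmit_unknown(g, geno[s - 1], q);
      else if (d > 0) pr = transmit_unknown(g, geno[d - 1], q);
      else pr = (g == 0) ? (1.0 - q) * (1.0 - q)
                         : (g == 1 ? 2.0 * q * (1.0 - q) : q * q);
      double lw = (pr > 0.0) ? std::log(pr) : R_NegInf;
      for (int k = 0; k < kids.size(); k++) {
        int gc = geno[kids[k] - 1];
        int m = mates[k];
        double t = (m > 0) ? transmit(gc, g, geno[m - 1])
                           : transmit_unknown(gc, g, q);
        lw += (t > 0.0) ? std::log(t) : R_NegInf;
        if (lw == R_NegInf) break;
      }
      if (obs && lw != R_NegInf) {
        double r = y[i] - means[g];
        lw += -0.5 * r * r / s2e;
      }
      logw[g] = lw;
    }
    double mx = std::max(logw[0], std::max(logw[1], logw[2]));
    double w0 = std::exp(logw[0] - mx), w1 = std::exp(logw[1] - mx),
           w2 = std::exp(logw[2] - mx);
    double tot = w0 + w1 + w2;
    double u = unif_rand() * tot;
    geno[i] = (u < w0) ? 0 : (u < w0 + w1 ? 1 : 2);
  }
}
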