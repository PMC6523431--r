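#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Haplotype matrices are 0/1 IntegerMatrix with rows = haplotypes and
// columns = markers of ONE chromosome, positions strictly increasing.
// EHH is the probability that two haplotypes drawn from the considered set
// are identical at all markers from the core out to a position x; the value
// at the core itself is 1 by the zero-width-window convention, and the
// partition is refined by the core allele before the first outward marker,
// so site-EHH (both alleles pooled) drops to the core-site homozygosity at
// the first step.

namespace {

inline double npairs(double n) { return 0.5 * n * (n - 1.0); }

// Scratch buffers reused across SNPs of a chromosome scan.  Group
// relabeling uses an epoch stamp so nothing is cleared between steps.
struct Workspace {
  std::vector<int> act, pop, g, stamp, idmap, cnt, cobs, keep;
  int epoch = 0;
  void init(int n) {
    act.resize(n);
    pop.resize(n);
    g.resize(n);
    stamp.assign(2 * n + 2, -1);
    idmap.resize(2 * n + 2);
    cnt.resize(n + 1);
    cobs.resize(n + 1);
    keep.resize(n + 1);
    epoch = 0;
  }
};

struct Pass {
  double ihh;
  bool truncated;            // stopped by chromosome end / oversized gap
  std::vector<double> ehh;   // curve values at visited markers
  std::vector<int> marker;   // visited marker indices (0-based)
};

// One outward pass for a single haplotype set (iHS-style, or pooled
// site-EHH when `subset` holds every haplotype).  Singleton groups are
// dropped from the active set; the pair denominator stays fixed at the
// initial subset size.
void ehh_pass(const int* H, int nrow, const NumericVector& pos, int core,
              int step, const std::vector<int>& subset, double cutoff,
              double max_gap, bool keep_curve, Workspace& w, Pass& out) {
  const int m = pos.size();
  const double denom = npairs((double)subset.size());
  out.ihh = 0.0;
  out.truncated = false;
  if (keep_curve) { out.ehh.clear(); out.marker.clear(); }
  if (denom <= 0) return;

  int n_act = (int)subset.size();
  for (int i = 0; i < n_act; ++i) { w.act[i] = subset[i]; w.g[i] = 0; }

  // split by the allele at the core marker (no-op for allele-conditioned sets)
  {
    const int* col = H + (size_t)core * nrow;
    for (int i = 0; i < n_act; ++i) w.g[i] = col[w.act[i]];
    // group ids must be compact {0} or {0,1}; both cases are fine as keys
  }

  double prev_ehh = 1.0;
  int prev_j = core;
  for (int j = core + step; j >= 0 && j < m; j += step) {
    double gap = std::abs(pos[j] - pos[prev_j]);
    if (gap > max_gap) { out.truncated = true; return; }

    const int* col = H + (size_t)j * nrow;
    ++w.epoch;
    int K = 0;
    for (int i = 0; i < n_act; ++i) {
      int key = 2 * w.g[i] + col[w.act[i]];
      if (w.stamp[key] != w.epoch) {
        w.stamp[key] = w.epoch;
        w.idmap[key] = K;
        w.cnt[K] = 0;
        ++K;
      }
      int k = w.idmap[key];
      w.g[i] = k;
      w.cnt[k]++;
    }
    double contrib = 0.0;
    int newK = 0;
    for (int k = 0; k < K; ++k) {
      if (w.cnt[k] >= 2) {
        contrib += npairs(w.cnt[k]);
        w.keep[k] = newK++;
      } else {
        w.keep[k] = -1;
      }
    }
    if (newK < K) {  // compact away singleton groups
      int wpos = 0;
      for (int i = 0; i < n_act; ++i) {
        int r = w.keep[w.g[i]];
        if (r >= 0) { w.act[wpos] = w.act[i]; w.g[wpos] = r; ++wpos; }
      }
      n_act = wpos;
    }

    double e = contrib / denom;
    out.ihh += 0.5 * (prev_ehh + e) * gap;
    if (keep_curve) { out.ehh.push_back(e); out.marker.push_back(j); }
    if (e < cutoff) return;  // reached decay cutoff: done, not truncated
    prev_ehh = e;
    prev_j = j;
  }
  out.truncated = true;  // ran off the chromosome before the cutoff
}

// Joint outward pass for XP-EHH: one pooled partition over both
// populations, per-step EHH for observed, reference and pooled sets; stops
// where the POOLED EHH drops below the cutoff so both populations
// integrate the same interval.
struct XpPass {
  double ihh_obs, ihh_ref;
  bool truncated;
};

void xp_pass(const int* H, int nrow, const NumericVector& pos, int core,
             int step, int n_obs, int n_total, double cutoff, double max_gap,
             Workspace& w, XpPass& out) {
  const int m = pos.size();
  const double d_obs = npairs((double)n_obs);
  const double d_ref = npairs((double)(n_total - n_obs));
  const double d_all = npairs((double)n_total);
  out.ihh_obs = 0.0;
  out.ihh_ref = 0.0;
  out.truncated = false;
  if (d_all <= 0) return;

  int n_act = n_total;
  {
    const int* col = H + (size_t)core * nrow;
    for (int i = 0; i < n_act; ++i) {
      w.act[i] = i;
      w.pop[i] = (i < n_obs) ? 0 : 1;
      w.g[i] = col[i];
    }
  }

  double prev_obs = 1.0, prev_ref = 1.0;
  int prev_j = core;
  for (int j = core + step; j >= 0 && j < m; j += step) {
    double gap = std::abs(pos[j] - pos[prev_j]);
    if (gap > max_gap) { out.truncated = true; return; }

    const int* col = H + (size_t)j * nrow;
    ++w.epoch;
    int K = 0;
    for (int i = 0; i < n_act; ++i) {
      int key = 2 * w.g[i] + col[w.act[i]];
      if (w.stamp[key] != w.epoch) {
        w.stamp[key] = w.epoch;
        w.idmap[key] = K;
        w.cnt[K] = 0;
        w.cobs[K] = 0;
        ++K;
      }
      int k = w.idmap[key];
      w.g[i] = k;
      w.cnt[k]++;
      w.cobs[k] += (w.pop[i] == 0);
    }
    double c_all = 0.0, c_obs = 0.0, c_ref = 0.0;
    int newK = 0;
    for (int k = 0; k < K; ++k) {
      if (w.cnt[k] >= 2) {
        c_all += npairs(w.cnt[k]);
        c_obs += npairs(w.cobs[k]);
        c_ref += npairs(w.cnt[k] - w.cobs[k]);
        w.keep[k] = newK++;
      } else {
        w.keep[k] = -1;
      }
    }
    if (newK < K) {
      int wpos = 0;
      for (int i = 0; i < n_act; ++i) {
        int r = w.keep[w.g[i]];
        if (r >= 0) { w.act[wpos] = w.act[i]; w.pop[wpos] = w.pop[i];
                      w.g[wpos] = r; ++wpos; }
      }
      n_act = wpos;
    }

    double e_all = c_all / d_all;
    double e_obs = d_obs > 0 ? c_obs / d_obs : 0.0;
    double e_ref = d_ref > 0 ? c_ref / d_ref : 0.0;
    out.ihh_obs += 0.5 * (prev_obs + e_obs) * gap;
    out.ihh_ref += 0.5 * (prev_ref + e_ref) * gap;
    if (e_all < cutoff) return;
    prev_obs = e_obs;
    prev_ref = e_ref;
    prev_j = j;
  }
  out.truncated = true;
}

void carriers_of(const int* col, int nrow, int allele, std::vector<int>& out) {
  out.clear();
  for (int i = 0; i < nrow; ++i)
    if (allele < 0 || col[i] == allele) out.push_back(i);
}

}  // namespace

// [[Rcpp::export]]
List ehh_curve_cpp(IntegerMatrix H, NumericVector pos, int core, int allele,
                   int step, double cutoff, double max_gap) {
  std::vector<int> subset;
  carriers_of(H.begin() + (size_t)core * H.nrow(), H.nrow(), allele, subset);
  if (subset.size() < 2)
    return List::create(_["n_carriers"] = (int)subset.size());
  Workspace w;
  w.init(H.nrow());
  Pass p;
  ehh_pass(H.begin(), H.nrow(), pos, core, step, subset, cutoff, max_gap,
           true, w, p);
  return List::create(_["n_carriers"] = (int)subset.size(),
                      _["marker"] = wrap(p.marker), _["ehh"] = wrap(p.ehh),
                      _["ihh"] = p.ihh, _["truncated"] = p.truncated);
}

// Per-SNP iHS quantities for one chromosome.  skip codes: 0 ok, 1 MAF below
// floor, 2 fewer than two carriers of an allele, 3 EHH truncated at a
// chromosome end or oversized gap before reaching the cutoff.
// [[Rcpp::export]]
List ihs_chrom_cpp(IntegerMatrix H, NumericVector pos, double cutoff,
                   double max_gap, double maf_floor) {
  const int m = pos.size(), n = H.nrow();
  NumericVector ihh_major(m, NA_REAL), ihh_minor(m, NA_REAL), freq1(m);
  IntegerVector skip(m, 0);
  std::vector<int> car0, car1;
  Workspace w;
  w.init(n);
  Pass up, dn;
  for (int j = 0; j < m; ++j) {
    const int* col = H.begin() + (size_t)j * n;
    int c1 = 0;
    for (int i = 0; i < n; ++i) c1 += col[i];
    double f1 = (double)c1 / n;
    freq1[j] = f1;
    double maf = f1 < 0.5 ? f1 : 1.0 - f1;
    if (maf < maf_floor) { skip[j] = 1; continue; }
    carriers_of(col, n, 0, car0);
    carriers_of(col, n, 1, car1);
    if (car0.size() < 2 || car1.size() < 2) { skip[j] = 2; continue; }
    int major = f1 > 0.5 ? 1 : 0;
    double ihh[2];
    bool trunc = false;
    for (int a = 0; a < 2 && !trunc; ++a) {
      const std::vector<int>& car = (a == 0) ? car0 : car1;
      ehh_pass(H.begin(), n, pos, j, +1, car, cutoff, max_gap, false, w, up);
      ehh_pass(H.begin(), n, pos, j, -1, car, cutoff, max_gap, false, w, dn);
      trunc = up.truncated || dn.truncated;
      ihh[a] = up.ihh + dn.ihh;
    }
    if (trunc) { skip[j] = 3; continue; }
    ihh_major[j] = ihh[major];
    ihh_minor[j] = ihh[1 - major];
  }
  return List::create(_["ihh_major"] = ihh_major, _["ihh_minor"] = ihh_minor,
                      _["freq1"] = freq1, _["skip"] = skip);
}

// Per-SNP XP-EHH quantities for one chromosome; the two matrices share the
// marker map.  skip codes: 0 ok, 4 zero observed or reference iHH.
// Truncated extensions (chromosome end / gap before the pooled cutoff) are
// kept and flagged.
// [[Rcpp::export]]
List xpehh_chrom_cpp(IntegerMatrix Hobs, IntegerMatrix Href, NumericVector pos,
                     double cutoff, double max_gap) {
  const int m = pos.size();
  const int n_obs = Hobs.nrow(), n_ref = Href.nrow();
  const int n_total = n_obs + n_ref;
  // stack once so both populations index one column-contiguous matrix
  IntegerMatrix H(n_total, m);
  for (int j = 0; j < m; ++j) {
    int* dst = H.begin() + (size_t)j * n_total;
    const int* so = Hobs.begin() + (size_t)j * n_obs;
    const int* sr = Href.begin() + (size_t)j * n_ref;
    std::copy(so, so + n_obs, dst);
    std::copy(sr, sr + n_ref, dst + n_obs);
  }
  NumericVector ihh_obs(m, NA_REAL), ihh_ref(m, NA_REAL);
  IntegerVector skip(m, 0);
  LogicalVector truncated(m, false);
  Workspace w;
  w.init(n_total);
  XpPass up, dn;
  for (int j = 0; j < m; ++j) {
    xp_pass(H.begin(), n_total, pos, j, +1, n_obs, n_total, cutoff, max_gap,
            w, up);
    xp_pass(H.begin(), n_total, pos, j, -1, n_obs, n_total, cutoff, max_gap,
            w, dn);
    double io = up.ihh_obs + dn.ihh_obs;
    double ir = up.ihh_ref + dn.ihh_ref;
    truncated[j] = up.truncated || dn.truncated;
    if (ir <= 0.0 || io <= 0.0) { skip[j] = 4; continue; }
    ihh_obs[j] = io;
    ihh_ref[j] = ir;
  }
  return List::create(_["ihh_obs"] = ihh_obs, _["ihh_ref"] = ihh_ref,
                      _["truncated"] = truncated, _["skip"] = skip);
}

// Founder-mosaic haplotypes for one chromosome.  switch_p[k] is the
// probability of re-drawing the founder between markers k and k+1.
// Uses the R RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix mosaic_chrom_cpp(IntegerMatrix founders, NumericVector switch_p,
                               int n_haps) {
  const int nf = founders.nrow(), m = founders.ncol();
  IntegerMatrix out(n_haps, m);
  RNGScope scope;
  for (int h = 0; h < n_haps; ++h) {
    int f = (int)(unif_rand() * nf);
    if (f >= nf) f = nf - 1;
    for (int j = 0; j < m; ++j) {
      if (j > 0 && unif_rand() < switch_p[j - 1]) {
        f = (int)(unif_rand() * nf);
        if (f >= nf) f = nf - 1;
      }
      out(h, j) = founders(f, j);
    }
  }
  return out;
}
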