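#include <Rcpp.h>
using namespace Rcpp;

// Extended-haplotype-homozygosity walker.
//
// EHH among a carrier set at extension step j is
//   sum_k C(n_k, 2) / C(n, 2)
// over groups k of carriers identical at every SNP from the core out to j.
// Group identity is refined incrementally: ids are compact (< n), so the
// key id*2 + allele fits an int and is re-compacted with a lookup table.

static double ehh_of_groups(const std::vector<int>& ids, int n,
                            std::vector<int>& counts) {
  std::fill(counts.begin(), counts.end(), 0);
  for (int i = 0; i < n; ++i) counts[ids[i]]++;
  double pairs = 0.0;
  for (int i = 0; i < n; ++i) {
    double c = counts[i];
    if (c > 1) pairs += c * (c - 1) / 2.0;
  }
  return pairs / (double(n) * (n - 1) / 2.0);
}

// Integrate the EHH curve of one carrier set outward from `core`
// (1-based) over genetic distance, trapezoid rule, truncating at
// `cutoff` (the trapezoid into the first sub-cutoff point is included).
// flag: 0 = ok, 1 = edge (ran off the chromosome while EHH >= cutoff),
// 2 = gap (physical gap > max_gap_bp), 3 = fewer than 2 carriers.
// [[Rcpp::export]]
List ihh_walk_cpp(const IntegerMatrix& haps, const IntegerVector& carriers,
                  const NumericVector& pos_bp, const NumericVector& pos_cM,
                  int core, double cutoff, double max_gap_bp) {
  const int n = carriers.size();
  const int m = haps.ncol();
  if (n < 2) return List::create(_["ihh"] = NA_REAL, _["flag"] = 3);
  double area = 0.0;
  int flag = 0;
  std::vector<int> ids(n), newids(n), counts(n);
  std::vector<int> remap(2 * n + 2);
  for (int dir = -1; dir <= 1; dir += 2) {
    std::fill(ids.begin(), ids.end(), 0);
    double prev_e = 1.0, prev_cM = pos_cM[core - 1], prev_bp = pos_bp[core - 1];
    int j = core - 1 + dir;  // 0-based walker
    while (true) {
      if (j < 0 || j >= m) {
        if (prev_e >= cutoff) flag = 1;
        break;
      }
      if (std::abs(pos_bp[j] - prev_bp) > max_gap_bp) { flag = 2; break; }
      // refine group ids by column j
      std::fill(remap.begin(), remap.end(), -1);
      int next_id = 0;
      for (int i = 0; i < n; ++i) {
        int key = ids[i] * 2 + haps(carriers[i] - 1, j);
        if (remap[key] < 0) remap[key] = next_id++;
        newids[i] = remap[key];
      }
      std::swap(ids, newids);
      double e = ehh_of_groups(ids, n, counts);
      area += (prev_e + e) / 2.0 * std::abs(pos_cM[j] - prev_cM);
      if (e < cutoff) break;
      prev_e = e;
      prev_cM = pos_cM[j];
      prev_bp = pos_bp[j];
      j += dir;
    }
    if (flag == 2) break;
  }
  return List::create(_["ihh"] = area, _["flag"] = flag);
}

// Alternate-allele frequency of every column (no missing data in a
// haplotype matrix), used by the scan loop.
// [[Rcpp::export]]
NumericVector col_freq_cpp(const IntegerMatrix& haps) {
  const int n = haps.nrow(), m = haps.ncol();
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    int s = 0;
    for (int i = 0; i < n; ++i) s += haps(i, j);
    out[j] = double(s) / n;
  }
  return out;
}
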