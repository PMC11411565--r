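#include <Rcpp.h>
using namespace Rcpp;

// Candidate spikes by the precise-timing differential threshold rule:
// at every local minimum, look for the opposite-sign extremum (maximum)
// within +/- plp samples; the peak-to-peak excursion must exceed thr.
// Returns one row per candidate: peak index (1-based, at the larger-
// magnitude extremum), min index, max index, p2p excursion.
// [[Rcpp::export(name = ".ptsd_candidates")]]
NumericMatrix ptsd_candidates(NumericVector v, double thr, int plp) {
  int n = v.size();
  std::vector<double> pk, mi, ma, pp;
  for (int i = 1; i < n - 1; ++i) {
    if (!(v[i] < v[i - 1] && v[i] <= v[i + 1])) continue; // local minimum
    int lo = std::max(0, i - plp), hi = std::min(n - 1, i + plp);
    int jmax = lo;
    for (int j = lo + 1; j <= hi; ++j)
      if (v[j] > v[jmax]) jmax = j;
    double p2p = v[jmax] - v[i];
    if (p2p > thr) {
      int peak = (std::fabs(v[i]) >= std::fabs(v[jmax])) ? i : jmax;
      pk.push_back(peak + 1);
      mi.push_back(i + 1);
      ma.push_back(jmax + 1);
      pp.push_back(p2p);
    }
  }
  NumericMatrix out(pk.size(), 4);
  for (size_t k = 0; k < pk.size(); ++k) {
    out(k, 0) = pk[k]; out(k, 1) = mi[k]; out(k, 2) = ma[k]; out(k, 3) = pp[k];
  }
  colnames(out) = CharacterVector::create("peak", "imin", "imax", "p2p");
  return out;
}
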