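#include <Rcpp.h>
using namespace Rcpp;

// Haplotype mosaics are run-length encodings along one chromosome: `br` holds
// the internal breakpoints (bp, strictly increasing, exclusive of 0 and the
// chromosome end) and `lab` the founder-allele label of each interval, so
// lab.size() == br.size() + 1.

// Recombine two parental mosaics into a gamete. `cx` are sorted crossover
// positions (bp); `first` (1 or 2) is the haplotype transmitted at position 0.
// [[Rcpp::export(name = ".cpp_gamete")]]
List cpp_gamete(NumericVector br1, IntegerVector lab1,
                NumericVector br2, IntegerVector lab2,
                NumericVector cx, int first) {
  int n1 = br1.size(), n2 = br2.size(), nc = cx.size();
  int i1 = 0, i2 = 0, ic = 0;
  int src = first;
  std::vector<double> obr;
  std::vector<int> olab;
  obr.reserve(n1 + n2 + nc);
  olab.reserve(n1 + n2 + nc + 1);
  int cur = (src == 1) ? lab1[0] : lab2[0];
  while (i1 < n1 || i2 < n2 || ic < nc) {
    double b1 = (i1 < n1) ? br1[i1] : R_PosInf;
    double b2 = (i2 < n2) ? br2[i2] : R_PosInf;
    double bc = (ic < nc) ? cx[ic] : R_PosInf;
    double b = std::min(b1, std::min(b2, bc));
    if (b1 == b) ++i1;
    if (b2 == b) ++i2;
    if (bc == b) { ++ic; src = 3 - src; }
    int lab = (src == 1) ? lab1[i1] : lab2[i2];
    if (lab != cur) {
      obr.push_back(b);
      olab.push_back(cur);
      cur = lab;
    }
  }
  olab.push_back(cur);
  return List::create(_["br"] = obr, _["lab"] = olab);
}

// Maximal intervals of [0, len) where the two mosaics carry equal labels.
// Returns a 2-column matrix (start, end); 0 rows if never equal.
// [[Rcpp::export(name = ".cpp_equal_runs")]]
NumericMatrix cpp_equal_runs(NumericVector br1, IntegerVector lab1,
                             NumericVector br2, IntegerVector lab2,
                             double len) {
  int n1 = br1.size(), n2 = br2.size();
  int i1 = 0, i2 = 0;
  std::vector<double> st, en;
  double pos = 0.0, seg_start = 0.0;
  bool open = false;
  while (pos < len) {
    bool eq = lab1[i1] == lab2[i2];
    if (eq && !open) { open = true; seg_start = pos; }
    if (!eq && open) { open = false; st.push_back(seg_start); en.push_back(pos); }
    double b1 = (i1 < n1) ? br1[i1] : len;
    double b2 = (i2 < n2) ? br2[i2] : len;
    double nxt = std::min(std::min(b1, b2), len);
    if (nxt <= pos && nxt < len) {
      // duplicated boundary; advance indices without moving
      if (b1 == nxt && i1 < n1) ++i1;
      if (b2 == nxt && i2 < n2) ++i2;
      continue;
    }
    if (b1 == nxt && i1 < n1) ++i1;
    if (b2 == nxt && i2 < n2) ++i2;
    pos = nxt;
  }
  if (open) { st.push_back(seg_start); en.push_back(len); }
  NumericMatrix out(st.size(), 2);
  for (size_t r = 0; r < st.size(); ++r) {
    out(r, 0) = st[r];
    out(r, 1) = en[r];
  }
  colnames(out) = CharacterVector::create("start", "end");
  return out;
}
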