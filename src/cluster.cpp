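#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component search over a channels x time t-statistic field.
// Cells are suprathreshold when |t| > thresh; two suprathreshold cells are
// adjacent when they share a channel and are consecutive in time, or share a
// time sample and are neighbouring channels (adjacency list, 0-based).
// Clusters are formed within one sign only (positive and negative t never
// join). Labels are 1-based; 0 marks sub-threshold cells.

// [[Rcpp::export]]
List cluster_label_cpp(NumericMatrix t, double thresh, List adj) {
  int nch = t.nrow(), nt = t.ncol();
  IntegerMatrix label(nch, nt);
  std::vector<double> mass;
  std::vector< std::vector<int> > nb(nch);
  for (int c = 0; c < nch; ++c) {
    IntegerVector v = adj[c];
    nb[c].assign(v.begin(), v.end());
  }
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nt; ++j) {
    for (int c = 0; c < nch; ++c) {
      double v = t(c, j);
      if (label(c, j) != 0 || !(v > thresh || v < -thresh)) continue;
      ++next;
      bool pos = v > 0;
      double m = 0.0;
      stack.clear();
      stack.push_back(c + j * nch);
      label(c, j) = next;
      while (!stack.empty()) {
        int cell = stack.back(); stack.pop_back();
        int cc = cell % nch, tt = cell / nch;
        m += t(cc, tt);
        // time neighbours
        for (int dt = -1; dt <= 1; dt += 2) {
          int t2 = tt + dt;
          if (t2 < 0 || t2 >= nt) continue;
          double w = t(cc, t2);
          if (label(cc, t2) == 0 &&
              ((pos && w > thresh) || (!pos && w < -thresh))) {
            label(cc, t2) = next;
            stack.push_back(cc + t2 * nch);
          }
        }
        // channel neighbours
        for (size_t k = 0; k < nb[cc].size(); ++k) {
          int c2 = nb[cc][k];
          double w = t(c2, tt);
          if (label(c2, tt) == 0 &&
              ((pos && w > thresh) || (!pos && w < -thresh))) {
            label(c2, tt) = next;
            stack.push_back(c2 + tt * nch);
          }
        }
      }
      mass.push_back(m);
    }
  }
  return List::create(_["label"] = label, _["mass"] = wrap(mass));
}

// Maximum absolute cluster mass over a stack of permutation t-fields.
// tperm: (nch * nt) x nperm matrix, each column one flattened field
// (channel fastest). Returns a vector of per-permutation max |mass|.

// [[Rcpp::export]]
NumericVector perm_max_mass_cpp(NumericMatrix tperm, int nch, int nt,
                                double thresh, List adj) {
  int nperm = tperm.ncol();
  NumericVector out(nperm);
  std::vector< std::vector<int> > nb(nch);
  for (int c = 0; c < nch; ++c) {
    IntegerVector v = adj[c];
    nb[c].assign(v.begin(), v.end());
  }
  std::vector<int> label((size_t)nch * nt);
  std::vector<int> stack;
  for (int p = 0; p < nperm; ++p) {
    const double *t = &tperm(0, p);
    std::fill(label.begin(), label.end(), 0);
    int next = 0;
    double best = 0.0;
    for (size_t cell0 = 0; cell0 < label.size(); ++cell0) {
      double v = t[cell0];
      if (label[cell0] != 0 || !(v > thresh || v < -thresh)) continue;
      ++next;
      bool pos = v > 0;
      double m = 0.0;
      stack.clear();
      stack.push_back((int)cell0);
      label[cell0] = next;
      while (!stack.empty()) {
        int cell = stack.back(); stack.pop_back();
        int cc = cell % nch, tt = cell / nch;
        m += t[cell];
        for (int dt = -1; dt <= 1; dt += 2) {
          int t2 = tt + dt;
          if (t2 < 0 || t2 >= nt) continue;
          int c2cell = cc + t2 * nch;
          double w = t[c2cell];
          if (label[c2cell] == 0 &&
              ((pos && w > thresh) || (!pos && w < -thresh))) {
            label[c2cell] = next;
            stack.push_back(c2cell);
          }
        }
        for (size_t k = 0; k < nb[cc].size(); ++k) {
          int c2cell = nb[cc][k] + tt * nch;
          double w = t[c2cell];
          if (label[c2cell] == 0 &&
              ((pos && w > thresh) || (!pos && w < -thresh))) {
            label[c2cell] = next;
            stack.push_back(c2cell);
          }
        }
      }
      if (std::abs(m) > best) best = std::abs(m);
    }
    out[p] = best;
  }
  return out;
}
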