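#include <Rcpp.h>
using namespace Rcpp;

// Connected-component search over suprathreshold voxels of a statistic
// volume, under a fixed voxel adjacency (CSR: adj_ptr of length V+1,
// adj_idx 0-based). Used per randomization to extract the maximum positive
// and the minimum (most negative) cluster-level statistic.

// [[Rcpp::export]]
NumericMatrix cpp_max_cluster_sums(NumericMatrix stats, double thr_pos,
                                   double thr_neg, IntegerVector adj_ptr,
                                   IntegerVector adj_idx) {
  const int R = stats.nrow(), V = stats.ncol();
  NumericMatrix out(R, 2);
  std::vector<int> vis_pos(V, -1), vis_neg(V, -1);
  std::vector<int> stack;
  stack.reserve(256);
  for (int r = 0; r < R; ++r) {
    double maxpos = 0.0, minneg = 0.0;
    for (int v = 0; v < V; ++v) {
      double sv = stats(r, v);
      if (sv > thr_pos && vis_pos[v] != r) {
        double s = 0.0;
        stack.clear();
        stack.push_back(v);
        vis_pos[v] = r;
        while (!stack.empty()) {
          int u = stack.back();
          stack.pop_back();
          s += stats(r, u);
          for (int e = adj_ptr[u]; e < adj_ptr[u + 1]; ++e) {
            int w = adj_idx[e];
            if (vis_pos[w] != r && stats(r, w) > thr_pos) {
              vis_pos[w] = r;
              stack.push_back(w);
            }
          }
        }
        if (s > maxpos) maxpos = s;
      }
      if (sv < thr_neg && vis_neg[v] != r) {
        double s = 0.0;
        stack.clear();
        stack.push_back(v);
        vis_neg[v] = r;
        while (!stack.empty()) {
          int u = stack.back();
          stack.pop_back();
          s += stats(r, u);
          for (int e = adj_ptr[u]; e < adj_ptr[u + 1]; ++e) {
            int w = adj_idx[e];
            if (vis_neg[w] != r && stats(r, w) < thr_neg) {
              vis_neg[w] = r;
              stack.push_back(w);
            }
          }
        }
        if (s < minneg) minneg = s;
      }
    }
    out(r, 0) = maxpos;
    out(r, 1) = minneg;
  }
  return out;
}

// Label connected components among the voxels flagged in `supra`
// (1-based component ids; 0 = not suprathreshold).

// [[Rcpp::export]]
IntegerVector cpp_label_clusters(LogicalVector supra, IntegerVector adj_ptr,
                                 IntegerVector adj_idx) {
  const int V = supra.size();
  IntegerVector lab(V, 0);
  std::vector<int> stack;
  int next = 0;
  for (int v = 0; v < V; ++v) {
    if (supra[v] && lab[v] == 0) {
      ++next;
      stack.clear();
      stack.push_back(v);
      lab[v] = next;
      while (!stack.empty()) {
        int u = stack.back();
        stack.pop_back();
        for (int e = adj_ptr[u]; e < adj_ptr[u + 1]; ++e) {
          int w = adj_idx[e];
          if (supra[w] && lab[w] == 0) {
            lab[w] = next;
            stack.push_back(w);
          }
        }
      }
    }
  }
  return lab;
}
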