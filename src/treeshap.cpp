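// Path-dependent TreeSHAP (Lundberg et al.'s polynomial-time algorithm) in
// double precision for ensembles of binary decision trees.
//
// Trees arrive flattened: one row per node across all trees, children as
// global row indices (-1 for leaves), plus per-tree root indices. Cover is
// the training weight of each node (hessian sum in xgboost); the
// conditional expectations of the path-dependent formulation follow the
// cover proportions.
#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

void extend_path(std::vector<PathElement>& path, int unique_depth,
                 double zero_fraction, double one_fraction,
                 int feature_index) {
  path[unique_depth].feature_index = feature_index;
  path[unique_depth].zero_fraction = zero_fraction;
  path[unique_depth].one_fraction = one_fraction;
  path[unique_depth].pweight = unique_depth == 0 ? 1.0 : 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    path[i + 1].pweight += one_fraction * path[i].pweight * (i + 1.0) /
                           (unique_depth + 1.0);
    path[i].pweight = zero_fraction * path[i].pweight *
                      (unique_depth - i) / (unique_depth + 1.0);
  }
}

void unwind_path(std::vector<PathElement>& path, int unique_depth,
                 int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0.0) {
      const double tmp = path[i].pweight;
      path[i].pweight = next_one_portion * (unique_depth + 1.0) /
                        ((i + 1.0) * one_fraction);
      next_one_portion = tmp - path[i].pweight * zero_fraction *
                               (unique_depth - i) / (unique_depth + 1.0);
    } else {
      path[i].pweight = path[i].pweight * (unique_depth + 1.0) /
                        (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    path[i].feature_index = path[i + 1].feature_index;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

double unwound_path_sum(const std::vector<PathElement>& path,
                        int unique_depth, int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  double total = 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0.0) {
      const double tmp = next_one_portion * (unique_depth + 1.0) /
                         ((i + 1.0) * one_fraction);
      total += tmp;
      next_one_portion = path[i].pweight - tmp * zero_fraction *
                             (unique_depth - i) / (unique_depth + 1.0);
    } else {
      total += path[i].pweight /
               (zero_fraction * (unique_depth - i) / (unique_depth + 1.0));
    }
  }
  return total;
}

struct Forest {
  const IntegerVector& feature;   // -1 for leaves
  const NumericVector& threshold;
  const IntegerVector& yes;       // global node index, -1 for leaves
  const IntegerVector& no;
  const IntegerVector& missing;
  const NumericVector& value;     // leaf value (0 for internal)
  const NumericVector& cover;
};

void tree_shap_recurse(const Forest& f, const NumericMatrix& x, int row,
                       NumericVector::iterator phi, int node,
                       std::vector<PathElement> path, int unique_depth,
                       double parent_zero_fraction,
                       double parent_one_fraction,
                       int parent_feature_index) {
  extend_path(path, unique_depth, parent_zero_fraction, parent_one_fraction,
              parent_feature_index);
  if (f.feature[node] < 0) {  // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(path, unique_depth, i);
      phi[path[i].feature_index] +=
          w * (path[i].one_fraction - path[i].zero_fraction) * f.value[node];
    }
    return;
  }
  const int split_feature = f.feature[node];
  const double xval = x(row, split_feature);
  int hot, cold;
  if (NumericVector::is_na(xval)) {
    hot = f.missing[node];
    cold = (hot == f.yes[node]) ? f.no[node] : f.yes[node];
  } else if (static_cast<float>(xval) < static_cast<float>(f.threshold[node])) {
    // xgboost evaluates split conditions in float32; mirror it exactly
    hot = f.yes[node];
    cold = f.no[node];
  } else {
    hot = f.no[node];
    cold = f.yes[node];
  }
  const double w = f.cover[node];
  const double hot_fraction = f.cover[hot] / w;
  const double cold_fraction = f.cover[cold] / w;
  double incoming_zero = 1.0, incoming_one = 1.0;
  // if this feature already split above, unwind its previous element
  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index) {
    if (path[path_index].feature_index == split_feature) break;
  }
  if (path_index != unique_depth + 1) {
    incoming_zero = path[path_index].zero_fraction;
    incoming_one = path[path_index].one_fraction;
    unwind_path(path, unique_depth, path_index);
    unique_depth -= 1;
  }
  // grow the path buffer for children
  std::vector<PathElement> hot_path(path.begin(),
                                    path.begin() + unique_depth + 1);
  hot_path.resize(unique_depth + 2);
  tree_shap_recurse(f, x, row, phi, hot, hot_path, unique_depth + 1,
                    incoming_zero * hot_fraction, incoming_one,
                    split_feature);
  std::vector<PathElement> cold_path(path.begin(),
                                     path.begin() + unique_depth + 1);
  cold_path.resize(unique_depth + 2);
  tree_shap_recurse(f, x, row, phi, cold, cold_path, unique_depth + 1,
                    incoming_zero * cold_fraction, 0.0, split_feature);
}

double expected_value(const Forest& f, int node) {
  if (f.feature[node] < 0) return f.value[node];
  return (f.cover[f.yes[node]] * expected_value(f, f.yes[node]) +
          f.cover[f.no[node]] * expected_value(f, f.no[node])) /
         f.cover[node];
}

double leaf_value_for(const Forest& f, const NumericMatrix& x, int row,
                      int node) {
  while (f.feature[node] >= 0) {
    const double xval = x(row, f.feature[node]);
    if (NumericVector::is_na(xval)) node = f.missing[node];
    else node = static_cast<float>(xval) < static_cast<float>(f.threshold[node])
                    ? f.yes[node] : f.no[node];
  }
  return f.value[node];
}

}  // namespace

// [[Rcpp::export(name = ".treeshap_cpp")]]
List treeshap_cpp(NumericMatrix x, IntegerVector roots,
                  IntegerVector feature, NumericVector threshold,
                  IntegerVector yes, IntegerVector no,
                  IntegerVector missing, NumericVector value,
                  NumericVector cover, double intercept) {
  const int n = x.nrow(), p = x.ncol(), t = roots.size();
  Forest f{feature, threshold, yes, no, missing, value, cover};
  NumericMatrix phi(n, p + 1);
  NumericVector margin(n);
  double base = intercept;
  for (int tr = 0; tr < t; ++tr) base += expected_value(f, roots[tr]);
  for (int i = 0; i < n; ++i) {
    NumericVector::iterator phi_row = phi.begin();  // column-major access below
    double m = intercept;
    std::vector<double> acc(p, 0.0);
    for (int tr = 0; tr < t; ++tr) {
      NumericVector tmp(p);
      std::vector<PathElement> path(1);
      tree_shap_recurse(f, x, i, tmp.begin(), roots[tr], path, 0, 1.0, 1.0,
                        -1);
      for (int j = 0; j < p; ++j) acc[j] += tmp[j];
      m += leaf_value_for(f, x, i, roots[tr]);
    }
    for (int j = 0; j < p; ++j) phi(i, j) = acc[j];
    phi(i, p) = base;
    margin[i] = m;
    (void)phi_row;
  }
  return List::create(_["phi"] = phi, _["margin"] = margin,
                      _["base_value"] = base);
}
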