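#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Average-tie ranks of one column, written into r.
static void rank_avg(const double* x, int n, double* r) {
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return x[a] < x[b]; });
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[ord[j + 1]] == x[ord[i]]) ++j;
    double avg = 0.5 * (i + j) + 1.0;  // 1-based average rank
    for (int k = i; k <= j; ++k) r[ord[k]] = avg;
    i = j + 1;
  }
}

//' @noRd
// [[Rcpp::export(name = ".cpp_rank_cols")]]
NumericMatrix cpp_rank_cols(NumericMatrix X) {
  int n = X.nrow(), p = X.ncol();
  NumericMatrix R(n, p);
  for (int j = 0; j < p; ++j) rank_avg(&X(0, j), n, &R(0, j));
  return R;
}

// Spearman association matrix: rank columns, Pearson on ranks, negatives and
// diagonal zeroed. Columns with zero variance get all-zero edges; their count
// is returned in attribute "n_constant".
// [[Rcpp::export(name = ".cpp_spearman_graph")]]
NumericMatrix cpp_spearman_graph(NumericMatrix X) {
  int n = X.nrow(), p = X.ncol();
  NumericMatrix R(n, p);
  std::vector<double> nrm(p);
  int n_const = 0;
  for (int j = 0; j < p; ++j) {
    rank_avg(&X(0, j), n, &R(0, j));
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += R(i, j);
    m /= n;
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      R(i, j) -= m;
      ss += R(i, j) * R(i, j);
    }
    nrm[j] = std::sqrt(ss);
    if (nrm[j] <= 0) ++n_const;
  }
  NumericMatrix W(p, p);
  for (int j = 0; j < p; ++j) {
    for (int k = j + 1; k < p; ++k) {
      double w = 0.0;
      if (nrm[j] > 0 && nrm[k] > 0) {
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += R(i, j) * R(i, k);
        w = s / (nrm[j] * nrm[k]);
        if (w < 0) w = 0.0;
        if (w > 1) w = 1.0;
      }
      W(j, k) = w;
      W(k, j) = w;
    }
  }
  W.attr("n_constant") = n_const;
  return W;
}

// All-pairs weighted shortest paths, edge length 1/w, Floyd-Warshall.
// Unreachable pairs are +Inf.
// [[Rcpp::export(name = ".cpp_shortest_paths")]]
NumericMatrix cpp_shortest_paths(NumericMatrix W) {
  int n = W.nrow();
  NumericMatrix D(n, n);
  double* d = &D(0, 0);
  const double* w = &W(0, 0);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      d[i + (R_xlen_t)n * j] =
        (i == j) ? 0.0
                 : (w[i + (R_xlen_t)n * j] > 0 ? 1.0 / w[i + (R_xlen_t)n * j]
                                               : R_PosInf);
  // column-oriented relaxation: contiguous inner loop over i
  for (int k = 0; k < n; ++k) {
    const double* dk = d + (R_xlen_t)n * k;  // column k = distances i -> k
    for (int j = 0; j < n; ++j) {
      double dkj = d[k + (R_xlen_t)n * j];
      if (dkj == R_PosInf) continue;
      double* dj = d + (R_xlen_t)n * j;
      for (int i = 0; i < n; ++i) {
        double alt = dk[i] + dkj;
        if (alt < dj[i]) dj[i] = alt;
      }
    }
  }
  return D;
}

// Nodal global efficiency of the subgraph induced by each node's neighbours
// (local efficiency). 0 when degree < 2.
// [[Rcpp::export(name = ".cpp_local_efficiency")]]
NumericVector cpp_local_efficiency(NumericMatrix W) {
  int n = W.nrow();
  NumericVector E(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j)
      if (j != i && W(i, j) > 0) nb.push_back(j);
    int k = nb.size();
    if (k < 2) { E[i] = 0.0; continue; }
    NumericMatrix S(k, k);
    for (int a = 0; a < k; ++a)
      for (int b = 0; b < k; ++b) S(a, b) = W(nb[a], nb[b]);
    NumericMatrix D = cpp_shortest_paths(S);
    double s = 0.0;
    for (int a = 0; a < k; ++a)
      for (int b = 0; b < k; ++b)
        if (a != b && D(a, b) < R_PosInf) s += 1.0 / D(a, b);
    E[i] = s / ((double)k * (k - 1));
  }
  return E;
}

// One synchronous inward-filling pass sweep: lesion voxels acquire the mean of
// their already-valid 6-neighbours, repeated until the mask is exhausted.
// vol: numeric array dims d; mask: integer array (1 = lesion). Returns filled
// volume; attribute "n_passes" records the number of sweeps.
// [[Rcpp::export(name = ".cpp_fill_lesions")]]
NumericVector cpp_fill_lesions(NumericVector vol, IntegerVector mask,
                               IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = vol.size();
  NumericVector out = clone(vol);
  std::vector<char> todo(n);
  R_xlen_t remaining = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    todo[i] = mask[i] != 0;
    if (todo[i]) ++remaining;
  }
  auto idx = [&](int x, int y, int z) {
    return (R_xlen_t)x + nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
  };
  int passes = 0;
  std::vector<R_xlen_t> fill_i;
  std::vector<double> fill_v;
  while (remaining > 0) {
    fill_i.clear();
    fill_v.clear();
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          R_xlen_t i = idx(x, y, z);
          if (!todo[i]) continue;
          double s = 0.0;
          int c = 0;
          if (x > 0      && !todo[idx(x - 1, y, z)]) { s += out[idx(x - 1, y, z)]; ++c; }
          if (x < nx - 1 && !todo[idx(x + 1, y, z)]) { s += out[idx(x + 1, y, z)]; ++c; }
          if (y > 0      && !todo[idx(x, y - 1, z)]) { s += out[idx(x, y - 1, z)]; ++c; }
          if (y < ny - 1 && !todo[idx(x, y + 1, z)]) { s += out[idx(x, y + 1, z)]; ++c; }
          if (z > 0      && !todo[idx(x, y, z - 1)]) { s += out[idx(x, y, z - 1)]; ++c; }
          if (z < nz - 1 && !todo[idx(x, y, z + 1)]) { s += out[idx(x, y, z + 1)]; ++c; }
          if (c > 0) {
            fill_i.push_back(i);
            fill_v.push_back(s / c);
          }
        }
    if (fill_i.empty())
      stop("lesion mask has a component with no reachable source voxels");
    for (size_t k = 0; k < fill_i.size(); ++k) {
      out[fill_i[k]] = fill_v[k];
      todo[fill_i[k]] = 0;
    }
    remaining -= fill_i.size();
    ++passes;
  }
  out.attr("n_passes") = passes;
  return out;
}
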