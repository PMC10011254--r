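#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Affinity-propagation message passing (Frey & Dueck style).
// S: n x n similarity matrix with preferences already on the diagonal.
// Returns the exemplar index (1-based) each point is assigned to.
// [[Rcpp::export]]
List ap_messages(NumericMatrix S, int maxit, int convits, double damping) {
  const int n = S.nrow();
  // transposed (k-fastest) storage keeps every inner loop contiguous
  std::vector<double> ST((size_t)n * n), RT((size_t)n * n, 0.0),
                      AT((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < n; ++k)
      ST[(size_t)n * i + k] = S(i, k);

  IntegerVector exemplar(n);
  IntegerVector last(n, -1);
  std::vector<double> sp(n), rkk(n);
  int stable = 0;
  bool converged = false;
  int it = 0;

  for (it = 0; it < maxit; ++it) {
    // responsibilities: r(i,k) = s(i,k) - max_{k'!=k} (a(i,k') + s(i,k'))
    for (int i = 0; i < n; ++i) {
      const size_t base = (size_t)n * i;
      double m1 = R_NegInf, m2 = R_NegInf; int k1 = -1;
      for (int k = 0; k < n; ++k) {
        double v = AT[base + k] + ST[base + k];
        if (v > m1) { m2 = m1; m1 = v; k1 = k; }
        else if (v > m2) m2 = v;
      }
      for (int k = 0; k < n; ++k) {
        double rnew = ST[base + k] - (k == k1 ? m2 : m1);
        RT[base + k] = damping * RT[base + k] + (1.0 - damping) * rnew;
      }
    }
    // availabilities: a(i,k) = min(0, r(k,k) + sum_{i' not in {i,k}} max(0, r(i',k)))
    std::fill(sp.begin(), sp.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const size_t base = (size_t)n * i;
      for (int k = 0; k < n; ++k) {
        if (k == i) continue;
        double v = RT[base + k];
        if (v > 0.0) sp[k] += v;
      }
    }
    for (int k = 0; k < n; ++k) rkk[k] = RT[(size_t)n * k + k];
    for (int i = 0; i < n; ++i) {
      const size_t base = (size_t)n * i;
      for (int k = 0; k < n; ++k) {
        double anew;
        if (k == i) {
          anew = sp[k];
        } else {
          double r = RT[base + k];
          double v = rkk[k] + sp[k] - (r > 0.0 ? r : 0.0);
          anew = v < 0.0 ? v : 0.0;
        }
        AT[base + k] = damping * AT[base + k] + (1.0 - damping) * anew;
      }
    }
    // current exemplar set
    bool same = true;
    for (int i = 0; i < n; ++i) {
      const size_t base = (size_t)n * i;
      double best = R_NegInf; int kb = 0;
      for (int k = 0; k < n; ++k) {
        double v = AT[base + k] + RT[base + k];
        if (v > best) { best = v; kb = k; }
      }
      int e = (AT[base + i] + RT[base + i] > 0.0) ? i : kb;
      if (e != last[i]) same = false;
      last[i] = e;
    }
    if (same) {
      if (++stable >= convits) { converged = true; ++it; break; }
    } else stable = 0;
  }

  // identify exemplars (points with a(k,k)+r(k,k) > 0), then assign each
  // point to the exemplar with maximal similarity
  std::vector<int> ex;
  for (int k = 0; k < n; ++k)
    if (AT[(size_t)n * k + k] + RT[(size_t)n * k + k] > 0.0) ex.push_back(k);
  if (ex.empty()) {
    // fall back to the point maximizing the self-evidence
    double best = R_NegInf; int kb = 0;
    for (int k = 0; k < n; ++k) {
      double v = AT[(size_t)n * k + k] + RT[(size_t)n * k + k];
      if (v > best) { best = v; kb = k; }
    }
    ex.push_back(kb);
  }
  for (int i = 0; i < n; ++i) {
    const size_t base = (size_t)n * i;
    double best = R_NegInf; int eb = ex[0];
    for (size_t j = 0; j < ex.size(); ++j) {
      int k = ex[j];
      if (i == k) { eb = k; break; }
      if (ST[base + k] > best) { best = ST[base + k]; eb = k; }
    }
    exemplar[i] = eb + 1;
  }
  return List::create(_["exemplar"] = exemplar,
                      _["converged"] = converged,
                      _["iterations"] = it);
}

// 26-connectivity connected-component labelling of a 3-D logical array.
// [[Rcpp::export]]
IntegerVector cc_label26(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++cur;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int z = v % nz, y = (v / nz) % ny, x = v / ((R_xlen_t)nz * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dz && !dy && !dx) continue;
            int z2 = z + dz, y2 = y + dy, x2 = x + dx;
            if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny ||
                x2 < 0 || x2 >= nx) continue;
            R_xlen_t w = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
            if (mask[w] && !lab[w]) { lab[w] = cur; q.push(w); }
          }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}
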