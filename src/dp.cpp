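#include <Rcpp.h>
using namespace Rcpp;

// Bases are encoded A=0, C=1, G=2, U/T=3; complement(x) == 3 - x.

static inline double pair_weight(int a, int b, const NumericVector& w) {
  // w = c(gc, au, gu) weights
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return w[0];
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return w[1];
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return w[2];
  return -1.0; // not pairable
}

// Weighted base-pair maximisation over nested structures (Nussinov-style)
// with a minimum hairpin loop size. `blocked` positions may not pair
// (used for accessibility / constrained folds).
// [[Rcpp::export]]
List cpp_fold(IntegerVector seq, NumericVector weights, int min_loop,
              LogicalVector blocked) {
  int n = seq.size();
  IntegerVector pairing(n, 0);
  if (n == 0) return List::create(_["pairing"] = pairing, _["score"] = 0.0);
  std::vector<double> M((size_t)n * n, 0.0);
  auto idx = [n](int i, int j) { return (size_t)i * n + j; };

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double best = M[idx(i + 1, j)]; // i unpaired
      if (!blocked[i]) {
        for (int k = i + min_loop + 1; k <= j; ++k) {
          if (blocked[k]) continue;
          double w = pair_weight(seq[i], seq[k], weights);
          if (w < 0) continue;
          double s = w;
          if (k - 1 >= i + 1) s += M[idx(i + 1, k - 1)];
          if (k + 1 <= j) s += M[idx(k + 1, j)];
          if (s > best) best = s;
        }
      }
      M[idx(i, j)] = best;
    }
  }

  // deterministic traceback: prefer leaving i unpaired, then smallest partner
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    if (M[idx(i, j)] == M[idx(i + 1, j)]) {
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (blocked[i] || blocked[k]) continue;
      double w = pair_weight(seq[i], seq[k], weights);
      if (w < 0) continue;
      double s = w;
      if (k - 1 >= i + 1) s += M[idx(i + 1, k - 1)];
      if (k + 1 <= j) s += M[idx(k + 1, j)];
      if (s == M[idx(i, j)]) {
        pairing[i] = k + 1; // 1-based partner
        pairing[k] = i + 1;
        if (k - 1 > i + 1) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k + 1 < j) stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }
  return List::create(_["pairing"] = pairing, _["score"] = M[idx(0, n - 1)]);
}

// Best local alignment of the sequence against its own reverse complement,
// i.e. an inverted repeat. Column j of the reverse complement corresponds to
// genomic position n-1-j; cells with i >= n-1-j (arms crossing) and cells
// touching masked positions are forbidden. Linear gap penalty.
// Returns the best alignment's score and the matched genomic position pairs.
// [[Rcpp::export]]
List cpp_ir_best(IntegerVector seq, double match, double mismatch, double gap,
                 LogicalVector mask) {
  int n = seq.size();
  std::vector<double> H((size_t)(n + 1) * (n + 1), 0.0);
  std::vector<signed char> tb((size_t)(n + 1) * (n + 1), 0); // 0 stop,1 diag,2 up,3 left
  auto idx = [n](int i, int j) { return (size_t)i * (n + 1) + j; };
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= n; ++j) {
      int g = n - j + 1; // 1-based genomic position of revcomp column j
      if (i >= g || mask[i - 1] || mask[g - 1]) { H[idx(i, j)] = 0.0; continue; }
      bool comp = (seq[i - 1] == 3 - seq[g - 1]);
      double diag = H[idx(i - 1, j - 1)] + (comp ? match : mismatch);
      double up = H[idx(i - 1, j)] - gap;
      double left = H[idx(i, j - 1)] - gap;
      double h = diag;
      signed char t = 1;
      if (up > h) { h = up; t = 2; }
      if (left > h) { h = left; t = 3; }
      if (h <= 0) { h = 0; t = 0; }
      H[idx(i, j)] = h;
      tb[idx(i, j)] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::vector<int> li, ri;
  int i = bi, j = bj;
  while (i > 0 && j > 0 && H[idx(i, j)] > 0) {
    signed char t = tb[idx(i, j)];
    if (t == 0) break;
    if (t == 1) {
      li.push_back(i);
      ri.push_back(n - j + 1);
      --i; --j;
    } else if (t == 2) {
      --i;
    } else {
      --j;
    }
  }
  std::reverse(li.begin(), li.end());
  std::reverse(ri.begin(), ri.end());
  return List::create(_["score"] = best,
                      _["left_pos"] = wrap(li),
                      _["right_pos"] = wrap(ri));
}
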