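// Low-level numerics for the two-pathway network and the DP boundary tracer.
// Array layout follows R: column-major, images as (H, W, C, N).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline R_xlen_t idx4(int h, int w, int c, int n, int H, int W, int C) {
  return (R_xlen_t)h + (R_xlen_t)H * (w + (R_xlen_t)W * (c + (R_xlen_t)C * n));
}

// Valid cross-correlation of a batch with one weight bank.
// input: (H, W, Cin, N); weights: (K, K, Cin, Cout); bias: length Cout.
// Output: (H-K+1, W-K+1, Cout, N). Work is chunked over output columns so the
// im2col buffer stays small even for whole-image (dense) inputs.
// [[Rcpp::export]]
NumericVector cpp_conv_forward(NumericVector input, NumericVector weights,
                               NumericVector bias) {
  IntegerVector di = input.attr("dim"), dw = weights.attr("dim");
  const int H = di[0], W = di[1], Cin = di[2], N = di[3];
  const int K = dw[0], Cout = dw[3];
  if (dw[1] != K || dw[2] != Cin)
    stop("weight tensor does not match input channels");
  const int oH = H - K + 1, oW = W - K + 1;
  if (oH < 1 || oW < 1) stop("input smaller than kernel");
  const int R = K * K * Cin;

  arma::mat wmat(weights.begin(), R, Cout, false, true);
  NumericVector out((R_xlen_t)oH * oW * Cout * N);
  out.attr("dim") = IntegerVector::create(oH, oW, Cout, N);

  int chunkW = std::max(1, (int)(5000000 / ((R_xlen_t)R * oH)));
  arma::mat X(R, (R_xlen_t)oH * std::min(chunkW, oW));
  const double *in = input.begin();
  double *op = out.begin();
  const double *bp = bias.begin();

  for (int n = 0; n < N; ++n) {
    for (int j0 = 0; j0 < oW; j0 += chunkW) {
      int jw = std::min(chunkW, oW - j0);
      int P = oH * jw;
      if ((int)X.n_cols != P) X.set_size(R, P);
      for (int c = 0; c < Cin; ++c)
        for (int kj = 0; kj < K; ++kj)
          for (int ki = 0; ki < K; ++ki) {
            int r = ki + K * (kj + K * c);
            for (int j = 0; j < jw; ++j) {
              const double *src = in + idx4(ki, j0 + j + kj, c, n, H, W, Cin);
              double *dst = X.memptr() + r + (R_xlen_t)R * oH * j;
              for (int i = 0; i < oH; ++i) dst[(R_xlen_t)R * i] = src[i];
            }
          }
      arma::mat Y = wmat.t() * X;  // Cout x P
      for (int co = 0; co < Cout; ++co) {
        double b = bp[co];
        for (int j = 0; j < jw; ++j) {
          double *dst = op + idx4(0, j0 + j, co, n, oH, oW, Cout);
          const double *src = Y.memptr() + co + (R_xlen_t)Cout * oH * j;
          for (int i = 0; i < oH; ++i) dst[i] = src[(R_xlen_t)Cout * i] + b;
        }
      }
    }
  }
  return out;
}

// Gradients of the valid cross-correlation.
// [[Rcpp::export]]
List cpp_conv_backward(NumericVector input, NumericVector weights,
                       NumericVector dout) {
  IntegerVector di = input.attr("dim"), dw = weights.attr("dim");
  const int H = di[0], W = di[1], Cin = di[2], N = di[3];
  const int K = dw[0], Cout = dw[3];
  const int oH = H - K + 1, oW = W - K + 1;
  const int R = K * K * Cin;

  arma::mat wmat(weights.begin(), R, Cout, false, true);
  NumericVector dinput(input.size());
  dinput.attr("dim") = di;
  arma::mat dwmat(R, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);

  int chunkW = std::max(1, (int)(5000000 / ((R_xlen_t)R * oH)));
  arma::mat X(R, 1), G(Cout, 1);
  const double *in = input.begin();
  const double *gp = dout.begin();
  double *dp = dinput.begin();

  for (int n = 0; n < N; ++n) {
    for (int j0 = 0; j0 < oW; j0 += chunkW) {
      int jw = std::min(chunkW, oW - j0);
      int P = oH * jw;
      if ((int)X.n_cols != P) { X.set_size(R, P); G.set_size(Cout, P); }
      for (int c = 0; c < Cin; ++c)
        for (int kj = 0; kj < K; ++kj)
          for (int ki = 0; ki < K; ++ki) {
            int r = ki + K * (kj + K * c);
            for (int j = 0; j < jw; ++j) {
              const double *src = in + idx4(ki, j0 + j + kj, c, n, H, W, Cin);
              double *dst = X.memptr() + r + (R_xlen_t)R * oH * j;
              for (int i = 0; i < oH; ++i) dst[(R_xlen_t)R * i] = src[i];
            }
          }
      for (int co = 0; co < Cout; ++co)
        for (int j = 0; j < jw; ++j) {
          const double *src = gp + idx4(0, j0 + j, co, n, oH, oW, Cout);
          double *dst = G.memptr() + co + (R_xlen_t)Cout * oH * j;
          for (int i = 0; i < oH; ++i) dst[(R_xlen_t)Cout * i] = src[i];
        }
      dwmat += X * G.t();
      db += arma::sum(G, 1);
      arma::mat dX = wmat * G;  // R x P
      for (int c = 0; c < Cin; ++c)
        for (int kj = 0; kj < K; ++kj)
          for (int ki = 0; ki < K; ++ki) {
            int r = ki + K * (kj + K * c);
            for (int j = 0; j < jw; ++j) {
              double *dst = dp + idx4(ki, j0 + j + kj, c, n, H, W, Cin);
              const double *src = dX.memptr() + r + (R_xlen_t)R * oH * j;
              for (int i = 0; i < oH; ++i) dst[i] += src[(R_xlen_t)R * i];
            }
          }
    }
  }
  NumericVector dWout(dwmat.memptr(), dwmat.memptr() + dwmat.n_elem);
  dWout.attr("dim") = dw;
  return List::create(_["dinput"] = dinput, _["dW"] = dWout,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Max pooling with stride 1 (valid). Returns pooled maps and, per output
// element, the linear (h + H*w) offset of the winning input cell; ties go to
// the first cell in column-major scan order so results are deterministic.
// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector input, int p) {
  IntegerVector di = input.attr("dim");
  const int H = di[0], W = di[1], C = di[2], N = di[3];
  const int oH = H - p + 1, oW = W - p + 1;
  if (oH < 1 || oW < 1) stop("input smaller than pooling window");
  NumericVector out((R_xlen_t)oH * oW * C * N);
  out.attr("dim") = IntegerVector::create(oH, oW, C, N);
  IntegerVector idx(out.size());
  idx.attr("dim") = out.attr("dim");
  const double *in = input.begin();
  double *op = out.begin();
  int *ip = idx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *sl = in + idx4(0, 0, c, n, H, W, C);
      for (int j = 0; j < oW; ++j)
        for (int i = 0; i < oH; ++i) {
          double best = sl[i + (R_xlen_t)H * j];
          int bi = i + H * j;
          for (int dj = 0; dj < p; ++dj)
            for (int di2 = 0; di2 < p; ++di2) {
              double v = sl[(i + di2) + (R_xlen_t)H * (j + dj)];
              if (v > best) { best = v; bi = (i + di2) + H * (j + dj); }
            }
          R_xlen_t o = idx4(i, j, c, n, oH, oW, C);
          op[o] = best;
          ip[o] = bi;
        }
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dout, IntegerVector idx,
                                   int H, int W) {
  IntegerVector dd = dout.attr("dim");
  const int oH = dd[0], oW = dd[1], C = dd[2], N = dd[3];
  NumericVector dinput((R_xlen_t)H * W * C * N);
  dinput.attr("dim") = IntegerVector::create(H, W, C, N);
  const double *gp = dout.begin();
  const int *ip = idx.begin();
  double *dp = dinput.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double *sl = dp + idx4(0, 0, c, n, H, W, C);
      const R_xlen_t base = idx4(0, 0, c, n, oH, oW, C);
      for (R_xlen_t k = 0; k < (R_xlen_t)oH * oW; ++k)
        sl[ip[base + k]] += gp[base + k];
    }
  return dinput;
}

// Minimum-cost column-to-column path. cost is (rows x cols); the path picks
// one row per column with |row change| <= max_step between adjacent columns
// (modular if wrap_rows). If periodic, the first/last columns must also obey
// the constraint; solved exactly by restarting the recursion from every
// anchor row. Ties prefer the smaller row index.
// [[Rcpp::export]]
List cpp_dp_min_path(NumericMatrix cost, int max_step, bool periodic,
                     bool wrap_rows) {
  const int R = cost.nrow(), C = cost.ncol();
  if (R < 1 || C < 1) stop("empty cost raster");
  const double INF = std::numeric_limits<double>::infinity();

  arma::mat D(R, C);
  arma::imat P(R, C);
  IntegerVector best_path(C);
  double best_total = INF;

  auto run = [&](int anchor) {
    // anchor < 0: free start
    for (int r = 0; r < R; ++r)
      D(r, 0) = (anchor < 0 || r == anchor) ? cost(r, 0) : INF;
    for (int c = 1; c < C; ++c)
      for (int r = 0; r < R; ++r) {
        double bv = INF; int bp = -1;
        for (int d = -max_step; d <= max_step; ++d) {
          int pr = r + d;
          if (wrap_rows) pr = ((pr % R) + R) % R;
          else if (pr < 0 || pr >= R) continue;
          double v = D(pr, c - 1);
          if (v < bv || (v == bv && pr < bp)) { bv = v; bp = pr; }
        }
        D(r, c) = (bp < 0 || bv == INF) ? INF : bv + cost(r, c);
        P(r, c) = bp;
      }
    // terminal selection
    int br = -1; double bv = INF;
    for (int r = 0; r < R; ++r) {
      if (anchor >= 0 && periodic) {
        int diff = std::abs(r - anchor);
        if (wrap_rows) diff = std::min(diff, R - diff);
        if (diff > max_step) continue;
      }
      if (D(r, C - 1) < bv) { bv = D(r, C - 1); br = r; }
    }
    if (br >= 0 && bv < best_total) {
      best_total = bv;
      int r = br;
      for (int c = C - 1; c >= 0; --c) {
        best_path[c] = r;
        if (c > 0) r = P(r, c);
      }
    }
  };

  if (periodic && C > 1) {
    for (int a = 0; a < R; ++a) run(a);
  } else {
    run(-1);
  }
  if (!std::isfinite(best_total)) stop("no feasible path");
  return List::create(_["path"] = best_path, _["total"] = best_total);
}

// Connected components of equal-valued cells, 4-connectivity, optionally
// wrapping across the left/right (angular) seam. Labels start at 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix m, bool wrap_cols) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int>> stack;
  int next = 0;
  for (int j0 = 0; j0 < W; ++j0)
    for (int i0 = 0; i0 < H; ++i0) {
      if (lab(i0, j0) != 0) continue;
      int v = m(i0, j0);
      ++next;
      stack.clear();
      stack.push_back({i0, j0});
      lab(i0, j0) = next;
      while (!stack.empty()) {
        auto [i, j] = stack.back();
        stack.pop_back();
        const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int ni = i + di[k], nj = j + dj[k];
          if (ni < 0 || ni >= H) continue;
          if (nj < 0 || nj >= W) {
            if (!wrap_cols) continue;
            nj = ((nj % W) + W) % W;
          }
          if (lab(ni, nj) == 0 && m(ni, nj) == v) {
            lab(ni, nj) = next;
            stack.push_back({ni, nj});
          }
        }
      }
    }
  return lab;
}
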