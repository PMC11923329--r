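// Convolutional primitives for the tiny scale-invariant backbone and the
// connected-component labeler used by the breast-region scan.
//
// Layout conventions:
//  - images/activations are arma::cube (rows = y, cols = x, slices = channel)
//  - a 3x3 conv weight is a (cout x 9*cin) matrix; row-major over
//    (cin, kx, ky): weight index = c*9 + kx*3 + ky
//  - im2col columns are ordered column-major over output pixels (y fastest)
// All convs are 3x3, stride 1, zero pad 1 (same-size output).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col3(const arma::cube& x) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  arma::mat cols(9 * cin, (size_t)h * w, arma::fill::zeros);
  for (int c = 0; c < cin; ++c) {
    const arma::mat& xc = x.slice(c);
    for (int kx = -1; kx <= 1; ++kx) {
      for (int ky = -1; ky <= 1; ++ky) {
        const int row = c * 9 + (kx + 1) * 3 + (ky + 1);
        for (int ox = 0; ox < w; ++ox) {
          const int ix = ox + kx;
          if (ix < 0 || ix >= w) continue;
          const int y0 = std::max(0, -ky), y1 = std::min(h, h - ky);
          for (int oy = y0; oy < y1; ++oy) {
            cols(row, (size_t)ox * h + oy) = xc(oy + ky, ix);
          }
        }
      }
    }
  }
  return cols;
}

static void col2im3(const arma::mat& cols, arma::cube& dx) {
  const int h = dx.n_rows, w = dx.n_cols, cin = dx.n_slices;
  for (int c = 0; c < cin; ++c) {
    arma::mat& dc = dx.slice(c);
    for (int kx = -1; kx <= 1; ++kx) {
      for (int ky = -1; ky <= 1; ++ky) {
        const int row = c * 9 + (kx + 1) * 3 + (ky + 1);
        for (int ox = 0; ox < w; ++ox) {
          const int ix = ox + kx;
          if (ix < 0 || ix >= w) continue;
          const int y0 = std::max(0, -ky), y1 = std::min(h, h - ky);
          for (int oy = y0; oy < y1; ++oy) {
            dc(oy + ky, ix) += cols(row, (size_t)ox * h + oy);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv3_forward(const arma::cube& x, const arma::mat& weight,
                         const arma::vec& bias) {
  const int h = x.n_rows, w = x.n_cols;
  const int cout = weight.n_rows;
  arma::mat cols = im2col3(x);
  arma::mat out = weight * cols;      // cout x (h*w)
  out.each_col() += bias;
  arma::cube y(h, w, cout);
  for (int c = 0; c < cout; ++c) {
    y.slice(c) = arma::reshape(out.row(c), h, w);
  }
  return y;
}

// [[Rcpp::export]]
List conv3_backward(const arma::cube& x, const arma::mat& weight,
                    const arma::cube& dout) {
  const int h = x.n_rows, w = x.n_cols;
  const int cout = weight.n_rows;
  arma::mat dout_mat(cout, (size_t)h * w);
  for (int c = 0; c < cout; ++c) {
    dout_mat.row(c) = arma::vectorise(dout.slice(c)).t();
  }
  arma::mat cols = im2col3(x);
  arma::mat dW = dout_mat * cols.t();
  arma::vec db = arma::sum(dout_mat, 1);
  arma::mat dcols = weight.t() * dout_mat;
  arma::cube dx(h, w, x.n_slices, arma::fill::zeros);
  col2im3(dcols, dx);
  return List::create(Named("dx") = dx, Named("dW") = dW, Named("db") = db);
}

// [[Rcpp::export]]
arma::cube avgpool2_forward(const arma::cube& x) {
  const int h = x.n_rows / 2, w = x.n_cols / 2, c = x.n_slices;
  arma::cube y(h, w, c);
  for (int s = 0; s < c; ++s) {
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        y(i, j, s) = 0.25 * (x(2 * i, 2 * j, s) + x(2 * i + 1, 2 * j, s) +
                             x(2 * i, 2 * j + 1, s) + x(2 * i + 1, 2 * j + 1, s));
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::cube avgpool2_backward(const arma::cube& dout) {
  const int h = dout.n_rows, w = dout.n_cols, c = dout.n_slices;
  arma::cube dx(2 * h, 2 * w, c);
  for (int s = 0; s < c; ++s) {
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        const double g = 0.25 * dout(i, j, s);
        dx(2 * i, 2 * j, s) = g;
        dx(2 * i + 1, 2 * j, s) = g;
        dx(2 * i, 2 * j + 1, s) = g;
        dx(2 * i + 1, 2 * j + 1, s) = g;
      }
    }
  }
  return dx;
}

// 8-connected component labeling of a logical matrix by BFS. Labels are
// assigned in row-major discovery order, so output is deterministic.
// [[Rcpp::export]]
IntegerMatrix label_components_8(const LogicalMatrix& mask) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix labels(h, w);
  int next = 0;
  std::vector<std::pair<int, int>> queue;
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      if (!mask(i, j) || labels(i, j) != 0) continue;
      ++next;
      labels(i, j) = next;
      queue.clear();
      queue.push_back({i, j});
      while (!queue.empty()) {
        auto [ci, cj] = queue.back();
        queue.pop_back();
        for (int di = -1; di <= 1; ++di) {
          for (int dj = -1; dj <= 1; ++dj) {
            const int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
            if (mask(ni, nj) && labels(ni, nj) == 0) {
              labels(ni, nj) = next;
              queue.push_back({ni, nj});
            }
          }
        }
      }
    }
  }
  return labels;
}
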