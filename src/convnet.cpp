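// 1D convolutional classifier: forward pass and analytic gradients.
//
// Architecture: n_blocks x (same-padded conv -> ReLU -> max-pool) followed by
// a single fully connected unit with sigmoid output.  Parameters live in one
// flat vector so the optimizer can treat the model as a plain R^d point:
//   per block b: W_b as (filters_b x in_ch_b x kernel) column-major, then
//   bias_b (filters_b); finally the FC weight vector and its scalar bias.
// All computation is double precision, single threaded, deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct NetDims {
  int channels;
  int input_len;
  int kernel;
  int pool;
  arma::ivec filters;
  std::vector<int> len_in;    // temporal extent entering each block
  std::vector<int> len_conv;  // after conv (same padding) == len_in
  std::vector<int> len_out;   // after pooling
  int flat_dim;
  int n_par;
};

NetDims make_dims(const List& spec) {
  NetDims d;
  d.channels = as<int>(spec["channels"]);
  d.input_len = as<int>(spec["input_len"]);
  d.kernel = as<int>(spec["kernel_size"]);
  d.pool = as<int>(spec["pool_size"]);
  IntegerVector f = spec["filters"];
  d.filters = arma::ivec(f.size());
  for (int i = 0; i < f.size(); ++i) d.filters[i] = f[i];

  int L = d.input_len;
  int n_par = 0;
  int cin = d.channels;
  for (arma::uword b = 0; b < d.filters.n_elem; ++b) {
    if (L < d.pool)
      stop("temporal extent collapses below the pool width at block %d", (int)b + 1);
    d.len_in.push_back(L);
    d.len_conv.push_back(L);
    L = L / d.pool;  // floor division, remainder dropped
    d.len_out.push_back(L);
    n_par += (int)d.filters[b] * cin * d.kernel + (int)d.filters[b];
    cin = (int)d.filters[b];
  }
  if (L < 1) stop("temporal extent collapsed below 1 before the output layer");
  d.flat_dim = cin * L;
  n_par += d.flat_dim + 1;
  d.n_par = n_par;
  return d;
}

// Views into the flat parameter vector (no copies for weights).
struct ParView {
  std::vector<arma::cube> W;   // filters x in_ch x kernel
  std::vector<arma::vec> b;
  arma::vec w_fc;
  double b_fc;
};

ParView unflatten(const arma::vec& par, const NetDims& d) {
  ParView p;
  int off = 0, cin = d.channels;
  for (arma::uword blk = 0; blk < d.filters.n_elem; ++blk) {
    int f = (int)d.filters[blk];
    p.W.emplace_back(const_cast<double*>(par.memptr()) + off, f, cin, d.kernel,
                     false, true);
    off += f * cin * d.kernel;
    p.b.emplace_back(const_cast<double*>(par.memptr()) + off, f, false, true);
    off += f;
    cin = f;
  }
  p.w_fc = arma::vec(const_cast<double*>(par.memptr()) + off, d.flat_dim, false,
                     true);
  off += d.flat_dim;
  p.b_fc = par[off];
  return p;
}

struct ForwardCache {
  std::vector<arma::mat> x_pad;     // padded input of each block
  std::vector<arma::mat> relu_out;  // post-activation, pre-pool
  std::vector<arma::umat> argmax;   // pooling winners (column index into relu_out)
  arma::mat pooled_last;
  double z;
};

// Same padding for odd or even kernels: pad_left = (k-1)/2, rest on the right.
arma::mat pad_same(const arma::mat& x, int kernel) {
  int pl = (kernel - 1) / 2;
  int pr = kernel - 1 - pl;
  arma::mat xp(x.n_rows, x.n_cols + pl + pr, arma::fill::zeros);
  xp.cols(pl, pl + x.n_cols - 1) = x;
  return xp;
}

double forward_one(const arma::mat& x, const ParView& p, const NetDims& d,
                   ForwardCache* cache) {
  arma::mat cur = x;
  for (arma::uword blk = 0; blk < d.filters.n_elem; ++blk) {
    int L = d.len_in[blk];
    int f = (int)d.filters[blk];
    arma::mat xp = pad_same(cur, d.kernel);
    arma::mat y(f, L, arma::fill::zeros);
    for (int j = 0; j < d.kernel; ++j)
      y += p.W[blk].slice(j) * xp.cols(j, j + L - 1);
    y.each_col() += p.b[blk];
    y.transform([](double v) { return v > 0.0 ? v : 0.0; });  // ReLU
    int Lo = d.len_out[blk];
    arma::mat pooled(f, Lo);
    arma::umat amax(f, Lo);
    for (int i = 0; i < Lo; ++i) {
      int lo = i * d.pool;
      for (int r = 0; r < f; ++r) {
        int best = lo;
        double bv = y(r, lo);
        for (int j = 1; j < d.pool; ++j)
          if (y(r, lo + j) > bv) { bv = y(r, lo + j); best = lo + j; }
        pooled(r, i) = bv;
        amax(r, i) = (arma::uword)best;
      }
    }
    if (cache) {
      cache->x_pad.push_back(xp);
      cache->relu_out.push_back(y);
      cache->argmax.push_back(amax);
    }
    cur = pooled;
  }
  double z = arma::dot(p.w_fc, arma::vectorise(cur)) + p.b_fc;
  if (cache) {
    cache->pooled_last = cur;
    cache->z = z;
  }
  return 1.0 / (1.0 + std::exp(-z));
}

}  // namespace

// [[Rcpp::export]]
int cnn_par_length(List spec) { return make_dims(spec).n_par; }

// [[Rcpp::export]]
NumericVector cnn_predict_scores(NumericVector par, arma::cube xb, List spec) {
  NetDims d = make_dims(spec);
  if ((int)par.size() != d.n_par) stop("parameter vector has wrong length");
  if ((int)xb.n_rows != d.channels || (int)xb.n_cols != d.input_len)
    stop("input shape does not match the model spec");
  arma::vec pv(par.begin(), par.size(), false, true);
  ParView p = unflatten(pv, d);
  NumericVector out(xb.n_slices);
  for (arma::uword i = 0; i < xb.n_slices; ++i)
    out[i] = forward_one(xb.slice(i), p, d, nullptr);
  return out;
}

// Mean binary cross-entropy over the batch plus its gradient in the flat
// parameter layout.  The sigmoid/cross-entropy pair is differentiated jointly
// (dz = p_hat - y) so no clipping enters the gradient; the reported loss
// clips p_hat to [eps, 1-eps].
// [[Rcpp::export]]
List cnn_batch_grad(NumericVector par, arma::cube xb, NumericVector y,
                    List spec, double eps = 1e-7) {
  NetDims d = make_dims(spec);
  if ((int)par.size() != d.n_par) stop("parameter vector has wrong length");
  if ((int)xb.n_slices != y.size()) stop("labels do not match batch size");
  arma::vec pv(par.begin(), par.size(), false, true);
  ParView p = unflatten(pv, d);
  int n = (int)xb.n_slices;
  int n_blocks = (int)d.filters.n_elem;

  std::vector<arma::cube> gW;
  std::vector<arma::vec> gb;
  int cin = d.channels;
  for (int blk = 0; blk < n_blocks; ++blk) {
    int f = (int)d.filters[blk];
    gW.emplace_back(f, cin, d.kernel, arma::fill::zeros);
    gb.emplace_back(f, arma::fill::zeros);
    cin = f;
  }
  arma::vec gw_fc(d.flat_dim, arma::fill::zeros);
  double gb_fc = 0.0;
  double loss = 0.0;

  for (int i = 0; i < n; ++i) {
    ForwardCache cache;
    double phat = forward_one(xb.slice(i), p, d, &cache);
    double pc = std::min(std::max(phat, eps), 1.0 - eps);
    loss += -(y[i] * std::log(pc) + (1.0 - y[i]) * std::log(1.0 - pc));

    double dz = (phat - y[i]) / n;
    gw_fc += dz * arma::vectorise(cache.pooled_last);
    gb_fc += dz;
    arma::vec dflat = dz * p.w_fc;
    arma::mat dcur(dflat.memptr(), cache.pooled_last.n_rows,
                   cache.pooled_last.n_cols, true);

    for (int blk = n_blocks - 1; blk >= 0; --blk) {
      int L = d.len_in[blk];
      int f = (int)d.filters[blk];
      // un-pool: route gradient to the argmax positions
      arma::mat dy(f, L, arma::fill::zeros);
      const arma::umat& am = cache.argmax[blk];
      for (int c = 0; c < (int)dcur.n_cols; ++c)
        for (int r = 0; r < f; ++r) dy(r, am(r, c)) += dcur(r, c);
      // ReLU mask
      dy.elem(arma::find(cache.relu_out[blk] <= 0.0)).zeros();
      gb[blk] += arma::sum(dy, 1);
      const arma::mat& xp = cache.x_pad[blk];
      arma::mat dxp(xp.n_rows, xp.n_cols, arma::fill::zeros);
      for (int j = 0; j < d.kernel; ++j) {
        gW[blk].slice(j) += dy * xp.cols(j, j + L - 1).t();
        if (blk > 0) dxp.cols(j, j + L - 1) += p.W[blk].slice(j).t() * dy;
      }
      if (blk > 0) {
        int pl = (d.kernel - 1) / 2;
        dcur = dxp.cols(pl, pl + L - 1);
      }
    }
  }
  loss /= n;

  NumericVector grad(d.n_par);
  int off = 0;
  for (int blk = 0; blk < n_blocks; ++blk) {
    std::copy(gW[blk].memptr(), gW[blk].memptr() + gW[blk].n_elem,
              grad.begin() + off);
    off += (int)gW[blk].n_elem;
    std::copy(gb[blk].memptr(), gb[blk].memptr() + gb[blk].n_elem,
              grad.begin() + off);
    off += (int)gb[blk].n_elem;
  }
  std::copy(gw_fc.memptr(), gw_fc.memptr() + gw_fc.n_elem, grad.begin() + off);
  off += (int)gw_fc.n_elem;
  grad[off] = gb_fc;

  for (int i = 0; i < d.n_par; ++i)
    if (!std::isfinite(grad[i]))
      stop("non-finite gradient at flat parameter index %d", i + 1);

  return List::create(_["loss"] = loss, _["grad"] = grad);
}
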