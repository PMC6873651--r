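// Compact deterministic CNN engine: stride-1 valid convolutions with ReLU,
// 2x2 max pooling, optional dense layer, softmax output, cross-entropy
// loss, Adam updates.  All randomness (weight init, minibatch order) is
// supplied from R, so given the same inputs the engine is bit-reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Spec {
  std::vector<int> filters;
  int kernel;
  int pool;
  int dense_units;   // 0 = no dense layer
  int n_outputs;
};

Spec read_spec(const Rcpp::List& spec) {
  Spec s;
  Rcpp::IntegerVector f = spec["conv_filters"];
  s.filters.assign(f.begin(), f.end());
  s.kernel = Rcpp::as<int>(spec["kernel"]);
  s.pool = Rcpp::as<int>(spec["pool"]);
  s.dense_units = Rcpp::as<int>(spec["dense_units"]);
  s.n_outputs = Rcpp::as<int>(spec["n_outputs"]);
  return s;
}

struct Weights {
  std::vector<mat> conv_w;   // F_l x (C_{l-1} * k * k)
  std::vector<vec> conv_b;
  mat dense_w; vec dense_b;  // empty when no dense layer
  mat out_w;  vec out_b;
};

Weights read_weights(const Rcpp::List& w, const Spec& s) {
  Weights out;
  Rcpp::List cw = w["conv_w"], cb = w["conv_b"];
  for (int l = 0; l < (int)s.filters.size(); ++l) {
    out.conv_w.push_back(Rcpp::as<mat>(cw[l]));
    out.conv_b.push_back(Rcpp::as<vec>(cb[l]));
  }
  if (s.dense_units > 0) {
    out.dense_w = Rcpp::as<mat>(w["dense_w"]);
    out.dense_b = Rcpp::as<vec>(w["dense_b"]);
  }
  out.out_w = Rcpp::as<mat>(w["out_w"]);
  out.out_b = Rcpp::as<vec>(w["out_b"]);
  return out;
}

Rcpp::List write_weights(const Weights& w, const Spec& s) {
  Rcpp::List cw(s.filters.size()), cb(s.filters.size());
  for (size_t l = 0; l < w.conv_w.size(); ++l) {
    cw[l] = w.conv_w[l];
    cb[l] = w.conv_b[l];
  }
  return Rcpp::List::create(
    Rcpp::Named("conv_w") = cw, Rcpp::Named("conv_b") = cb,
    Rcpp::Named("dense_w") = w.dense_w, Rcpp::Named("dense_b") = w.dense_b,
    Rcpp::Named("out_w") = w.out_w, Rcpp::Named("out_b") = w.out_b);
}

// per-layer forward cache for one image
struct ConvCache {
  mat cols;     // im2col of the layer input
  mat z;        // pre-activation, F x (oh*ow)
  int oh, ow;   // conv output dims
  int ph, pw;   // pooled dims (== oh, ow when pooling disabled)
  umat argmax;  // F x (ph*pw), linear index into the oh x ow slice
  int in_h, in_w, in_c;
};

mat im2col(const cube& x, int k, int oh, int ow) {
  const int c_in = x.n_slices;
  mat cols(c_in * k * k, oh * ow);
  for (int c = 0; c < c_in; ++c)
    for (int dr = 0; dr < k; ++dr)
      for (int dc = 0; dc < k; ++dc) {
        const int row = c * k * k + dr * k + dc;
        cols.row(row) =
          vectorise(x.slice(c).submat(dr, dc, dr + oh - 1, dc + ow - 1)).t();
      }
  return cols;
}

// forward through conv stack; fills caches when requested
cube conv_forward(const cube& input, const Spec& s, const Weights& w,
                  std::vector<ConvCache>* caches) {
  cube x = input;
  for (size_t l = 0; l < s.filters.size(); ++l) {
    const int k = s.kernel;
    const int oh = x.n_rows - k + 1, ow = x.n_cols - k + 1;
    const int f_out = s.filters[l];
    mat cols = im2col(x, k, oh, ow);
    mat z = w.conv_w[l] * cols;
    z.each_col() += w.conv_b[l];
    mat a = clamp(z, 0.0, datum::inf);
    int ph = oh, pw = ow;
    umat argmax;
    cube next;
    if (s.pool > 1) {
      ph = oh / s.pool; pw = ow / s.pool;
      next.set_size(ph, pw, f_out);
      argmax.set_size(f_out, ph * pw);
      for (int f = 0; f < f_out; ++f) {
        // a.row(f) laid out column-major over (oh, ow)
        for (int pc = 0; pc < pw; ++pc)
          for (int pr = 0; pr < ph; ++pr) {
            double best = -datum::inf; uword best_idx = 0;
            for (int dc = 0; dc < s.pool; ++dc)
              for (int dr = 0; dr < s.pool; ++dr) {
                const int rr = pr * s.pool + dr, cc = pc * s.pool + dc;
                const uword idx = rr + oh * cc;
                const double v = a(f, idx);
                if (v > best) { best = v; best_idx = idx; }
              }
            next(pr, pc, f) = best;
            argmax(f, pr + ph * pc) = best_idx;
          }
      }
    } else {
      next.set_size(oh, ow, f_out);
      for (int f = 0; f < f_out; ++f)
        next.slice(f) = reshape(a.row(f).t(), oh, ow);
    }
    if (caches) {
      ConvCache cc;
      cc.cols = std::move(cols); cc.z = std::move(z);
      cc.oh = oh; cc.ow = ow; cc.ph = ph; cc.pw = pw;
      cc.argmax = std::move(argmax);
      cc.in_h = x.n_rows; cc.in_w = x.n_cols; cc.in_c = x.n_slices;
      caches->push_back(std::move(cc));
    }
    x = std::move(next);
  }
  return x;
}

vec softmax(const vec& scores) {
  vec z = scores - scores.max();
  vec e = exp(z);
  return e / accu(e);
}

cube image_cube(const Rcpp::NumericVector& X, int n, int h, int wd, int i) {
  cube out(h, wd, 1);
  const double* p = X.begin();
  for (int c = 0; c < wd; ++c)
    for (int r = 0; r < h; ++r)
      out(r, c, 0) = p[i + (std::size_t)n * r + (std::size_t)n * h * c];
  return out;
}

struct Grads {
  std::vector<mat> conv_w;
  std::vector<vec> conv_b;
  mat dense_w; vec dense_b;
  mat out_w; vec out_b;
  void zero_like(const Weights& w) {
    conv_w.clear(); conv_b.clear();
    for (size_t l = 0; l < w.conv_w.size(); ++l) {
      conv_w.push_back(zeros<mat>(size(w.conv_w[l])));
      conv_b.push_back(zeros<vec>(w.conv_b[l].n_elem));
    }
    dense_w = zeros<mat>(size(w.dense_w));
    dense_b = zeros<vec>(w.dense_b.n_elem);
    out_w = zeros<mat>(size(w.out_w));
    out_b = zeros<vec>(w.out_b.n_elem);
  }
};

template <typename T>
void adam_update(T& w, T& m, T& v, const T& g, double lr,
                 double b1, double b2, double eps, double t) {
  if (w.n_elem == 0) return;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * square(g);
  T mhat = m / (1 - std::pow(b1, t));
  T vhat = v / (1 - std::pow(b2, t));
  w -= lr * mhat / (sqrt(vhat) + eps);
}

// forward + backward for one image; accumulates scaled gradients into g
// and returns the (unscaled) cross-entropy loss
double image_pass(const cube& x, const vec& y, const Spec& s,
                  const Weights& w, Grads& g, double scale, int& correct) {
  const int n_layers = s.filters.size();
  std::vector<ConvCache> caches;
  cube feat = conv_forward(x, s, w, &caches);
  vec flat = vectorise(feat);
  vec zd, hidden = flat;
  if (s.dense_units > 0) {
    zd = w.dense_w * flat + w.dense_b;
    hidden = clamp(zd, 0.0, datum::inf);
  }
  vec scores = w.out_w * hidden + w.out_b;
  vec p = softmax(scores);
  double loss = -accu(y % log(clamp(p, 1e-12, 1.0)));
  if (p.index_max() == y.index_max()) ++correct;

  vec dscores = (p - y) * scale;
  g.out_w += dscores * hidden.t();
  g.out_b += dscores;
  vec dhidden = w.out_w.t() * dscores;
  vec dflat;
  if (s.dense_units > 0) {
    vec dz = dhidden % conv_to<vec>::from(zd > 0);
    g.dense_w += dz * flat.t();
    g.dense_b += dz;
    dflat = w.dense_w.t() * dz;
  } else {
    dflat = dhidden;
  }

  // back through the conv stack: after handling layer l, dpool holds the
  // gradient w.r.t. layer l's input, which is layer l-1's pooled output
  cube dpool(caches.back().ph, caches.back().pw, s.filters[n_layers - 1]);
  std::copy(dflat.begin(), dflat.end(), dpool.begin());
  for (int l = n_layers - 1; l >= 0; --l) {
    const ConvCache& cc = caches[l];
    const int f_out = s.filters[l];
    mat dA(f_out, cc.oh * cc.ow, fill::zeros);
    if (s.pool > 1) {
      for (int f = 0; f < f_out; ++f) {
        const mat& dp = dpool.slice(f);
        for (int pc = 0; pc < cc.pw; ++pc)
          for (int pr = 0; pr < cc.ph; ++pr)
            dA(f, cc.argmax(f, pr + cc.ph * pc)) += dp(pr, pc);
      }
    } else {
      for (int f = 0; f < f_out; ++f)
        dA.row(f) = vectorise(dpool.slice(f)).t();
    }
    mat dZ = dA % conv_to<mat>::from(cc.z > 0);
    g.conv_w[l] += dZ * cc.cols.t();
    g.conv_b[l] += sum(dZ, 1);
    if (l > 0) {
      mat dcols = w.conv_w[l].t() * dZ;
      dpool.set_size(cc.in_h, cc.in_w, cc.in_c);
      dpool.zeros();
      const int k = s.kernel;
      for (int c = 0; c < cc.in_c; ++c)
        for (int dr = 0; dr < k; ++dr)
          for (int dc = 0; dc < k; ++dc) {
            const int row = c * k * k + dr * k + dc;
            dpool.slice(c).submat(dr, dc, dr + cc.oh - 1, dc + cc.ow - 1) +=
              reshape(dcols.row(row).t(), cc.oh, cc.ow);
          }
    }
  }
  return loss;
}

} // namespace

// Mean loss and analytic mean-loss gradients over the given images
// (1-based indices); used for gradient verification against finite
// differences.
// [[Rcpp::export]]
Rcpp::List cnn_grad_cpp(Rcpp::NumericVector X, Rcpp::NumericMatrix Y,
                        Rcpp::List weights, Rcpp::List spec,
                        Rcpp::IntegerVector idx) {
  Rcpp::IntegerVector dims = X.attr("dim");
  const int n = dims[0], h = dims[1], wd = dims[2];
  Spec s = read_spec(spec);
  Weights w = read_weights(weights, s);
  Grads g; g.zero_like(w);
  double loss = 0; int correct = 0;
  const int bs = idx.size();
  for (int b = 0; b < bs; ++b) {
    const int i = idx[b] - 1;
    cube x = image_cube(X, n, h, wd, i);
    vec y(s.n_outputs);
    for (int k = 0; k < s.n_outputs; ++k) y(k) = Y(i, k);
    loss += image_pass(x, y, s, w, g, 1.0 / bs, correct);
  }
  Weights gw;
  gw.conv_w = g.conv_w; gw.conv_b = g.conv_b;
  gw.dense_w = g.dense_w; gw.dense_b = g.dense_b;
  gw.out_w = g.out_w; gw.out_b = g.out_b;
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss / bs,
    Rcpp::Named("grads") = write_weights(gw, s));
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cnn_forward_cpp(Rcpp::NumericVector X, Rcpp::List weights,
                                    Rcpp::List spec) {
  Rcpp::IntegerVector dims = X.attr("dim");
  const int n = dims[0], h = dims[1], wd = dims[2];
  Spec s = read_spec(spec);
  Weights w = read_weights(weights, s);
  Rcpp::NumericMatrix out(n, s.n_outputs);
  for (int i = 0; i < n; ++i) {
    cube x = image_cube(X, n, h, wd, i);
    cube feat = conv_forward(x, s, w, nullptr);
    vec flat = vectorise(feat);
    vec hidden = flat;
    if (s.dense_units > 0)
      hidden = clamp(w.dense_w * flat + w.dense_b, 0.0, datum::inf);
    vec p = softmax(w.out_w * hidden + w.out_b);
    for (int k = 0; k < s.n_outputs; ++k) out(i, k) = p(k);
  }
  return out;
}

// Trains in place over the supplied minibatch index sequence (1-based R
// indices).  Returns updated weights plus per-iteration mean loss and
// accuracy on the training stream.
// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::NumericVector X, Rcpp::NumericMatrix Y,
                         Rcpp::List weights, Rcpp::List spec,
                         Rcpp::List batches, double lr,
                         double beta1 = 0.9, double beta2 = 0.999,
                         double adam_eps = 1e-8) {
  Rcpp::IntegerVector dims = X.attr("dim");
  const int n = dims[0], h = dims[1], wd = dims[2];
  Spec s = read_spec(spec);
  Weights w = read_weights(weights, s);
  const int n_layers = s.filters.size();

  Grads m_state, v_state;
  m_state.zero_like(w); v_state.zero_like(w);

  const int n_iter = batches.size();
  vec iter_loss(n_iter), iter_acc(n_iter);
  double t_adam = 0;

  for (int it = 0; it < n_iter; ++it) {
    Rcpp::IntegerVector idx = batches[it];
    const int bs = idx.size();
    Grads g; g.zero_like(w);
    double loss = 0; int correct = 0;

    for (int b = 0; b < bs; ++b) {
      const int i = idx[b] - 1;
      cube x = image_cube(X, n, h, wd, i);
      vec y(s.n_outputs);
      for (int k = 0; k < s.n_outputs; ++k) y(k) = Y(i, k);
      loss += image_pass(x, y, s, w, g, 1.0 / bs, correct);
    }

    loss /= bs;
    if (!std::isfinite(loss))
      Rcpp::stop("training diverged: non-finite loss at iteration %d", it + 1);
    iter_loss(it) = loss;
    iter_acc(it) = (double)correct / bs;

    t_adam += 1;
    for (int l = 0; l < n_layers; ++l) {
      adam_update(w.conv_w[l], m_state.conv_w[l], v_state.conv_w[l],
                  g.conv_w[l], lr, beta1, beta2, adam_eps, t_adam);
      adam_update(w.conv_b[l], m_state.conv_b[l], v_state.conv_b[l],
                  g.conv_b[l], lr, beta1, beta2, adam_eps, t_adam);
    }
    adam_update(w.dense_w, m_state.dense_w, v_state.dense_w, g.dense_w,
                lr, beta1, beta2, adam_eps, t_adam);
    adam_update(w.dense_b, m_state.dense_b, v_state.dense_b, g.dense_b,
                lr, beta1, beta2, adam_eps, t_adam);
    adam_update(w.out_w, m_state.out_w, v_state.out_w, g.out_w,
                lr, beta1, beta2, adam_eps, t_adam);
    adam_update(w.out_b, m_state.out_b, v_state.out_b, g.out_b,
                lr, beta1, beta2, adam_eps, t_adam);
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
    Rcpp::Named("weights") = write_weights(w, s),
    Rcpp::Named("iter_loss") = iter_loss,
    Rcpp::Named("iter_acc") = iter_acc);
}
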