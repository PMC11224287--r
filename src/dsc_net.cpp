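// Dual-branch 1D CNN: forward, backward, Adam training loop with an
// early-stopping monitor fold.  All layer arithmetic uses valid padding,
// stride 1 convolutions and non-overlapping max pooling, so temporal sizes
// follow L_out = L_in - k + 1 and L_pool = (L_out - pool) / stride + 1.
//
// Weight layout (positional list, fixed order):
//   for branch in {1,2}: for conv layer l: W (k*C_in x F), b (F)
//   then dense W (D x units), dense b, out W (units x 1), out b.
// Dropout masks use inverted scaling (kept units divided by 1 - rate) so
// inference needs no rescaling.  One std::mt19937_64 stream drives both the
// per-epoch shuffle and all dropout masks; runs are reproducible for a
// given seed on a single thread.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

namespace {

struct NetSpec {
  int n_conv;
  ivec kern, filt;
  double conv_drop, dense_drop;
  int pool, pstride;
  int dense_units, n_extra, seq_len, n_channels;
};

NetSpec parse_spec(const List &spec) {
  NetSpec s;
  s.kern = Rcpp::as<ivec>(spec["branch_kernels"]);
  s.filt = Rcpp::as<ivec>(spec["branch_filters"]);
  s.n_conv = s.kern.n_elem;
  s.conv_drop = Rcpp::as<double>(spec["conv_dropout"]);
  s.dense_drop = Rcpp::as<double>(spec["dense_dropout"]);
  s.pool = Rcpp::as<int>(spec["pool_size"]);
  s.pstride = Rcpp::as<int>(spec["pool_stride"]);
  s.dense_units = Rcpp::as<int>(spec["dense_units"]);
  s.n_extra = Rcpp::as<int>(spec["n_extra_features"]);
  s.seq_len = Rcpp::as<int>(spec["seq_len"]);
  s.n_channels = Rcpp::as<int>(spec["n_channels"]);
  return s;
}

struct Weights {
  std::vector<mat> Wc[2];
  std::vector<rowvec> bc[2];
  mat Wd, Wo;
  rowvec bd, bo;
};

Weights parse_weights(const List &wl, const NetSpec &s) {
  Weights w;
  int i = 0;
  for (int br = 0; br < 2; ++br) {
    for (int l = 0; l < s.n_conv; ++l) {
      w.Wc[br].push_back(Rcpp::as<mat>(wl[i++]));
      w.bc[br].push_back(Rcpp::as<rowvec>(wl[i++]));
    }
  }
  w.Wd = Rcpp::as<mat>(wl[i++]);
  w.bd = Rcpp::as<rowvec>(wl[i++]);
  w.Wo = Rcpp::as<mat>(wl[i++]);
  w.bo = Rcpp::as<rowvec>(wl[i++]);
  return w;
}

List export_weights(const Weights &w, const NetSpec &s) {
  List out(4 * s.n_conv + 4);
  int i = 0;
  for (int br = 0; br < 2; ++br) {
    for (int l = 0; l < s.n_conv; ++l) {
      out[i++] = w.Wc[br][l];
      out[i++] = w.bc[br][l];
    }
  }
  out[i++] = w.Wd;
  out[i++] = w.bd;
  out[i++] = w.Wo;
  out[i++] = w.bo;
  return out;
}

struct ConvCache {
  mat A;       // im2col matrix (B*L_out x k*C_in)
  mat drop;    // dropout mask, empty when rate == 0 or eval mode
  umat relu;   // 1 where pre-activation (post-dropout) > 0
  umat amax;   // absolute row index in Z for each pooled maximum
  int L_in, L_out, L_p, C_in;
};

struct BatchCache {
  std::vector<ConvCache> conv[2];
  mat Xf;          // merged feature matrix (B x D)
  mat dense_drop;  // (B x units)
  umat dense_relu;
  mat H;           // post-dropout dense activations
  vec p;           // sigmoid outputs
};

double bernoulli_mask(mat &m, double rate, std::mt19937_64 &rng) {
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const double keep = 1.0 - rate;
  for (uword j = 0; j < m.n_elem; ++j)
    m(j) = unif(rng) < keep ? 1.0 / keep : 0.0;
  return keep;
}

// Forward pass for one batch of sample indices.  In train mode, caches
// everything the backward pass needs.
vec forward(const NetSpec &s, const Weights &w,
            const cube &X1, const cube &X2, const mat &X3,
            const uvec &idx, bool train, std::mt19937_64 *rng,
            BatchCache *cache) {
  const int B = idx.n_elem;
  const cube *Xb[2] = {&X1, &X2};
  std::vector<mat> branch_out[2];
  int T_final = 0, F_final = 0;

  for (int br = 0; br < 2; ++br) {
    std::vector<mat> cur(B);
    for (int i = 0; i < B; ++i) cur[i] = Xb[br]->slice(idx(i));
    for (int l = 0; l < s.n_conv; ++l) {
      const int k = s.kern(l), F = s.filt(l);
      const int C_in = cur[0].n_cols, L_in = cur[0].n_rows;
      const int L_out = L_in - k + 1;
      mat A(B * L_out, k * C_in);
      for (int i = 0; i < B; ++i)
        for (int t = 0; t < L_out; ++t)
          for (int j = 0; j < k; ++j)
            for (int c = 0; c < C_in; ++c)
              A(i * L_out + t, j * C_in + c) = cur[i](t + j, c);
      mat Z = A * w.Wc[br][l];
      Z.each_row() += w.bc[br][l];
      mat drop;
      if (train && s.conv_drop > 0) {
        drop.set_size(Z.n_rows, Z.n_cols);
        bernoulli_mask(drop, s.conv_drop, *rng);
        Z %= drop;
      }
      umat relu = Z > 0;
      Z.transform([](double v) { return v > 0 ? v : 0.0; });
      const int L_p = (L_out - s.pool) / s.pstride + 1;
      umat amax(B * L_p, F);
      for (int i = 0; i < B; ++i) {
        mat out(L_p, F);
        for (int t = 0; t < L_p; ++t) {
          const int r0 = i * L_out + t * s.pstride;
          for (int f = 0; f < F; ++f) {
            double best = Z(r0, f);
            int bestr = r0;
            for (int r = 1; r < s.pool; ++r)
              if (Z(r0 + r, f) > best) { best = Z(r0 + r, f); bestr = r0 + r; }
            out(t, f) = best;
            amax(i * L_p + t, f) = bestr;
          }
        }
        cur[i] = out;
      }
      if (cache) {
        ConvCache cc;
        cc.A = std::move(A);
        cc.drop = std::move(drop);
        cc.relu = std::move(relu);
        cc.amax = std::move(amax);
        cc.L_in = L_in; cc.L_out = L_out; cc.L_p = L_p; cc.C_in = C_in;
        cache->conv[br].push_back(std::move(cc));
      }
    }
    branch_out[br] = std::move(cur);
    T_final = branch_out[br][0].n_rows;
    F_final = branch_out[br][0].n_cols;
  }

  // Merge: concatenate branch maps along channels, flatten column-major,
  // append the extra length features.
  const int D = T_final * 2 * F_final + s.n_extra;
  mat Xf(B, D);
  for (int i = 0; i < B; ++i) {
    mat cat = join_rows(branch_out[0][i], branch_out[1][i]);
    Xf(i, span(0, D - s.n_extra - 1)) = vectorise(cat).t();
    Xf(i, span(D - s.n_extra, D - 1)) = X3.row(idx(i));
  }

  mat H = Xf * w.Wd;
  H.each_row() += w.bd;
  umat drelu = H > 0;
  H.transform([](double v) { return v > 0 ? v : 0.0; });
  mat ddrop;
  if (train && s.dense_drop > 0) {
    ddrop.set_size(H.n_rows, H.n_cols);
    bernoulli_mask(ddrop, s.dense_drop, *rng);
    H %= ddrop;
  }
  vec logits = H * w.Wo + w.bo(0);
  vec p = 1.0 / (1.0 + exp(-logits));

  if (cache) {
    cache->Xf = std::move(Xf);
    cache->dense_drop = std::move(ddrop);
    cache->dense_relu = std::move(drelu);
    cache->H = std::move(H);
    cache->p = p;
  }
  return p;
}

struct Grads {
  std::vector<mat> Wc[2];
  std::vector<rowvec> bc[2];
  mat Wd, Wo;
  rowvec bd, bo;
};

void backward(const NetSpec &s, const Weights &w, const BatchCache &c,
              const uvec &idx, const vec &y, Grads &g) {
  const int B = idx.n_elem;
  vec dlogit = (c.p - y) / double(B);

  g.Wo = c.H.t() * dlogit;
  g.bo = rowvec{accu(dlogit)};
  mat dH = dlogit * w.Wo.t();
  if (c.dense_drop.n_elem) dH %= c.dense_drop;
  dH %= conv_to<mat>::from(c.dense_relu);
  g.Wd = c.Xf.t() * dH;
  g.bd = sum(dH, 0);
  mat dXf = dH * w.Wd.t();

  const int D = dXf.n_cols;
  const int flat = D - s.n_extra;
  const int F_final = s.filt(s.n_conv - 1);
  const int T_final = flat / (2 * F_final);

  for (int br = 0; br < 2; ++br) {
    g.Wc[br].resize(s.n_conv);
    g.bc[br].resize(s.n_conv);
    // gradient w.r.t. this branch's pooled output of the last conv block
    std::vector<mat> dP(B);
    for (int i = 0; i < B; ++i) {
      mat dcat(dXf.row(i).subvec(0, flat - 1).t());
      dcat.reshape(T_final, 2 * F_final);
      dP[i] = dcat.cols(br * F_final, (br + 1) * F_final - 1);
    }
    for (int l = s.n_conv - 1; l >= 0; --l) {
      const ConvCache &cc = c.conv[br][l];
      const int F = s.filt(l);
      mat dZ(B * cc.L_out, F, fill::zeros);
      for (int i = 0; i < B; ++i)
        for (int t = 0; t < cc.L_p; ++t)
          for (int f = 0; f < F; ++f)
            dZ(cc.amax(i * cc.L_p + t, f), f) += dP[i](t, f);
      dZ %= conv_to<mat>::from(cc.relu);
      if (cc.drop.n_elem) dZ %= cc.drop;
      g.Wc[br][l] = cc.A.t() * dZ;
      g.bc[br][l] = sum(dZ, 0);
      if (l > 0) {
        const int k = s.kern(l), C_in = cc.C_in;
        mat dA = dZ * w.Wc[br][l].t();
        for (int i = 0; i < B; ++i) {
          mat dX(cc.L_in, C_in, fill::zeros);
          for (int t = 0; t < cc.L_out; ++t)
            for (int j = 0; j < k; ++j)
              for (int cch = 0; cch < C_in; ++cch)
                dX(t + j, cch) += dA(i * cc.L_out + t, j * C_in + cch);
          dP[i] = std::move(dX);
        }
      }
    }
  }
}

struct Adam {
  std::vector<mat> mWc[2], vWc[2];
  std::vector<rowvec> mbc[2], vbc[2];
  mat mWd, vWd, mWo, vWo;
  rowvec mbd, vbd, mbo, vbo;
  long t = 0;
  double lr, b1, b2, eps, decay;

  void init(const Weights &w) {
    for (int br = 0; br < 2; ++br)
      for (size_t l = 0; l < w.Wc[br].size(); ++l) {
        mWc[br].push_back(zeros<mat>(size(w.Wc[br][l])));
        vWc[br].push_back(zeros<mat>(size(w.Wc[br][l])));
        mbc[br].push_back(zeros<rowvec>(w.bc[br][l].n_elem));
        vbc[br].push_back(zeros<rowvec>(w.bc[br][l].n_elem));
      }
    mWd = zeros<mat>(size(w.Wd)); vWd = mWd;
    mWo = zeros<mat>(size(w.Wo)); vWo = mWo;
    mbd = zeros<rowvec>(w.bd.n_elem); vbd = mbd;
    mbo = zeros<rowvec>(w.bo.n_elem); vbo = mbo;
  }

  template <class M>
  void upd(M &W, const M &g, M &m, M &v) {
    const double lr_t = lr / (1.0 + decay * double(t - 1));
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * square(g);
    const double bc1 = 1 - std::pow(b1, double(t));
    const double bc2 = 1 - std::pow(b2, double(t));
    W -= lr_t * (m / bc1) / (sqrt(v / bc2) + eps);
  }

  void step_all(Weights &w, const Grads &g) {
    ++t;
    for (int br = 0; br < 2; ++br)
      for (size_t l = 0; l < w.Wc[br].size(); ++l) {
        upd(w.Wc[br][l], g.Wc[br][l], mWc[br][l], vWc[br][l]);
        upd(w.bc[br][l], g.bc[br][l], mbc[br][l], vbc[br][l]);
      }
    upd(w.Wd, g.Wd, mWd, vWd);
    upd(w.bd, g.bd, mbd, vbd);
    upd(w.Wo, g.Wo, mWo, vWo);
    upd(w.bo, g.bo, mbo, vbo);
  }
};

const double BCE_EPS = 1e-7;

double bce(const vec &y, const vec &p) {
  vec pc = clamp(p, BCE_EPS, 1.0 - BCE_EPS);
  return -mean(y % log(pc) + (1.0 - y) % log(1.0 - pc));
}

// Eval-mode loss over an index set, chunked to bound memory.
double eval_loss(const NetSpec &s, const Weights &w, const cube &X1,
                 const cube &X2, const mat &X3, const vec &y) {
  const uword n = y.n_elem;
  double tot = 0;
  for (uword start = 0; start < n; start += 512) {
    uword end = std::min(start + 512, n) - 1;
    uvec idx = regspace<uvec>(start, end);
    vec p = forward(s, w, X1, X2, X3, idx, false, nullptr, nullptr);
    vec yy = y.subvec(start, end);
    tot += bce(yy, p) * double(idx.n_elem);
  }
  return tot / double(n);
}

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericVector cpp_predict(List spec, List weights, arma::cube X1,
                                arma::cube X2, arma::mat X3) {
  NetSpec s = parse_spec(spec);
  Weights w = parse_weights(weights, s);
  const uword n = X1.n_slices;
  vec out(n);
  for (uword start = 0; start < n; start += 512) {
    uword end = std::min(start + 512, n) - 1;
    uvec idx = regspace<uvec>(start, end);
    out.subvec(start, end) =
        forward(s, w, X1, X2, X3, idx, false, nullptr, nullptr);
  }
  return Rcpp::wrap(out);
}

// [[Rcpp::export]]
List cpp_train(List spec, List weights, arma::cube X1, arma::cube X2,
               arma::mat X3, arma::vec y, arma::cube vX1, arma::cube vX2,
               arma::mat vX3, arma::vec vy, List opts) {
  NetSpec s = parse_spec(spec);
  Weights w = parse_weights(weights, s);

  const int max_epochs = Rcpp::as<int>(opts["max_epochs"]);
  const int batch_size = Rcpp::as<int>(opts["batch_size"]);
  const int patience = Rcpp::as<int>(opts["patience"]);
  const double min_delta = Rcpp::as<double>(opts["min_delta"]);
  const unsigned long seed = Rcpp::as<double>(opts["seed"]);

  Adam adam;
  adam.lr = Rcpp::as<double>(opts["learning_rate"]);
  adam.b1 = Rcpp::as<double>(opts["beta1"]);
  adam.b2 = Rcpp::as<double>(opts["beta2"]);
  adam.eps = Rcpp::as<double>(opts["epsilon"]);
  adam.decay = Rcpp::as<double>(opts["decay"]);
  adam.init(w);

  std::mt19937_64 rng(seed);
  const int n = y.n_elem;
  std::vector<uword> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  vec tr_loss(max_epochs, fill::value(datum::nan));
  vec tr_acc(max_epochs, fill::value(datum::nan));
  vec va_loss(max_epochs, fill::value(datum::nan));

  double best_val = datum::inf;
  int best_epoch = 0, wait = 0, stopped = max_epochs;
  Weights best_w = w;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0;
    int correct = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int end = std::min(start + batch_size, n);
      uvec idx(end - start);
      for (int i = start; i < end; ++i) idx(i - start) = order[i];
      vec yy = y(idx);
      BatchCache cache;
      vec p = forward(s, w, X1, X2, X3, idx, true, &rng, &cache);
      double l = bce(yy, p);
      if (!std::isfinite(l))
        Rcpp::stop("non-finite training loss at epoch %d", epoch);
      loss_sum += l * double(idx.n_elem);
      for (uword i = 0; i < p.n_elem; ++i)
        correct += (p(i) > 0.5) == (yy(i) > 0.5);
      Grads g;
      backward(s, w, cache, idx, yy, g);
      adam.step_all(w, g);
    }
    Rcpp::checkUserInterrupt();
    tr_loss(epoch - 1) = loss_sum / double(n);
    tr_acc(epoch - 1) = double(correct) / double(n);
    const double vl = eval_loss(s, w, vX1, vX2, vX3, vy);
    va_loss(epoch - 1) = vl;
    if (vl < best_val - min_delta) {
      best_val = vl;
      best_epoch = epoch;
      best_w = w;
      wait = 0;
    } else if (++wait >= patience) {
      stopped = epoch;
      break;
    }
    stopped = epoch;
  }
  if (best_epoch == 0) { best_epoch = 1; best_w = w; }

  return List::create(
      Named("weights") = export_weights(best_w, s),
      Named("train_loss") = tr_loss.head(stopped),
      Named("train_acc") = tr_acc.head(stopped),
      Named("earlystop_loss") = va_loss.head(stopped),
      Named("stopped_epoch") = stopped,
      Named("best_epoch") = best_epoch);
}
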