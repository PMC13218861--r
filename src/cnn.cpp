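// Minimal seeded CPU CNN engine backing the slice / patch / fusion classifiers.
//
// Design notes:
//  * Activations for a batch are stored as C x (P*N) float matrices, where P is
//    the number of spatial positions of one image and image n occupies the
//    contiguous column block [n*P, (n+1)*P).  R arrays with dim (H, W, N) or
//    (D1, D2, D3, N) map onto this layout with zero copies of semantics
//    (column-major, dim0 fastest).
//  * Convolutions are "same"-padded 3^d kernels realised as gather (im2col)
//    plus one sgemm, so the same code path serves 2D slices and 3D patches;
//    spatial reduction comes only from 2^d max-pooling with stride 2.
//  * All randomness (init, shuffling, dropout) flows from one std::mt19937
//    seeded by the caller: identical (data, config, seed) => identical result.
#define ARMA_NO_DEBUG 1
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::frowvec;
using arma::uword;

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.1f;
static const float LN_EPS = 1e-5f;

// ---------------------------------------------------------------------------
// geometry tables
// ---------------------------------------------------------------------------

// Neighbor table for a same-padded 3^d convolution: NB(kk, p) is the linear
// spatial index of neighbor kk of position p, or -1 outside the image.
static arma::imat neighbor_table(const std::vector<int>& dims) {
  const int nd = (int)dims.size();
  int P = 1;
  for (int d : dims) P *= d;
  const int KK = nd == 2 ? 9 : 27;
  arma::imat NB(KK, P);
  std::vector<int> coord(nd), stride(nd);
  stride[0] = 1;
  for (int d = 1; d < nd; ++d) stride[d] = stride[d - 1] * dims[d - 1];
  for (int p = 0; p < P; ++p) {
    int rem = p;
    for (int d = nd - 1; d >= 0; --d) { coord[d] = rem / stride[d]; rem %= stride[d]; }
    for (int kk = 0; kk < KK; ++kk) {
      int t = kk, ok = 1, q = 0;
      for (int d = 0; d < nd; ++d) {
        int off = t % 3 - 1; t /= 3;
        int c = coord[d] + off;
        if (c < 0 || c >= dims[d]) { ok = 0; break; }
        q += c * stride[d];
      }
      NB(kk, p) = ok ? q : -1;
    }
  }
  return NB;
}

// Pool table for 2^d max pooling with stride 2 (floor semantics): PG(slot, po)
// is the linear input index feeding output position po, or -1.
static arma::imat pool_table(const std::vector<int>& dims, std::vector<int>& out_dims) {
  const int nd = (int)dims.size();
  out_dims.resize(nd);
  for (int d = 0; d < nd; ++d) out_dims[d] = dims[d] / 2;
  int Pout = 1;
  for (int d : out_dims) Pout *= d;
  const int S = 1 << nd;
  std::vector<int> stride(nd), ostride(nd);
  stride[0] = ostride[0] = 1;
  for (int d = 1; d < nd; ++d) {
    stride[d] = stride[d - 1] * dims[d - 1];
    ostride[d] = ostride[d - 1] * out_dims[d - 1];
  }
  arma::imat PG(S, Pout);
  std::vector<int> coord(nd);
  for (int po = 0; po < Pout; ++po) {
    int rem = po;
    for (int d = nd - 1; d >= 0; --d) { coord[d] = rem / ostride[d]; rem %= ostride[d]; }
    for (int s = 0; s < S; ++s) {
      int q = 0, ok = 1;
      for (int d = 0; d < nd; ++d) {
        int c = 2 * coord[d] + ((s >> d) & 1);
        if (c >= dims[d]) { ok = 0; break; }
        q += c * stride[d];
      }
      PG(s, po) = ok ? q : -1;
    }
  }
  return PG;
}

// ---------------------------------------------------------------------------
// layers
// ---------------------------------------------------------------------------

struct ConvBlock {
  int Cin, Cout, KK, P, Pout;       // P spatial in, Pout after pooling
  arma::imat NB, PG;
  fmat W;                            // Cout x (Cin*KK)
  fvec b, gamma, beta, rmean, rvar;  // per output channel
  bool use_bn;
  // caches (per forward pass)
  fmat K;                            // im2col matrix
  fmat xhat;                         // bn normalised pre-activation
  fvec mu, invstd;
  fmat pre_relu, post_relu;
  arma::umat pool_arg;               // Cout x (Pout*N): winning input column
};

struct Head {
  int D, Hdim;                       // input features, hidden units
  fmat W1;                           // H x D
  fvec b1, g, be;                    // layer norm gamma/beta (H)
  fmat W2;                           // 1 x H
  float b2;
  float dropout;
  // caches
  fmat Fin, H1, xhat, post, mask;
  frowvec mu, invstd;
};

struct Grads {
  std::vector<std::vector<fmat>> trunk; // per trunk, per block: {dW, db, dgamma, dbeta}
  fmat dW1, dW2; fvec db1, dg, dbe; float db2;
};

struct Net {
  int n_trunks;
  std::vector<std::vector<ConvBlock>> trunks; // one chain per trunk
  std::vector<int> trunk_feat;                // flattened feature dim per trunk
  Head head;
  bool use_bn;
  std::mt19937 rng;

  void build(const List& spec, int seed) {
    rng.seed((unsigned)seed);
    List dims_list = spec["dims"];
    n_trunks = dims_list.size();
    use_bn = as<bool>(spec["use_bn"]);
    IntegerVector ch = spec["channels"];
    int fc_hidden = as<int>(spec["fc_hidden"]);
    double dropout = as<double>(spec["dropout"]);
    std::normal_distribution<float> nd(0.f, 1.f);
    int D_total = 0;
    trunks.resize(n_trunks);
    trunk_feat.resize(n_trunks);
    for (int t = 0; t < n_trunks; ++t) {
      IntegerVector dv = dims_list[t];
      std::vector<int> dims(dv.begin(), dv.end());
      const int ndim = (int)dims.size();
      int Cin = 1;
      for (int bidx = 0; bidx < ch.size(); ++bidx) {
        ConvBlock blk;
        blk.Cin = Cin; blk.Cout = ch[bidx];
        blk.KK = ndim == 2 ? 9 : 27;
        int P = 1; for (int d : dims) P *= d;
        blk.P = P;
        blk.NB = neighbor_table(dims);
        std::vector<int> odims;
        blk.PG = pool_table(dims, odims);
        int Pout = 1; for (int d : odims) Pout *= d;
        if (Pout < 1) stop("input spatial extent collapses below 1 after pooling");
        blk.Pout = Pout;
        blk.use_bn = use_bn;
        float sd = std::sqrt(2.f / (Cin * blk.KK));
        blk.W.set_size(blk.Cout, Cin * blk.KK);
        for (uword i = 0; i < blk.W.n_elem; ++i) blk.W(i) = sd * nd(rng);
        blk.b.zeros(blk.Cout);
        blk.gamma.ones(blk.Cout); blk.beta.zeros(blk.Cout);
        blk.rmean.zeros(blk.Cout); blk.rvar.ones(blk.Cout);
        trunks[t].push_back(blk);
        dims = odims; Cin = ch[bidx];
      }
      int P = 1; for (int d : dims) P *= d;
      trunk_feat[t] = Cin * P;
      D_total += trunk_feat[t];
    }
    head.D = D_total; head.Hdim = fc_hidden; head.dropout = (float)dropout;
    float sd1 = std::sqrt(2.f / D_total);
    head.W1.set_size(fc_hidden, D_total);
    for (uword i = 0; i < head.W1.n_elem; ++i) head.W1(i) = sd1 * nd(rng);
    head.b1.zeros(fc_hidden);
    head.g.ones(fc_hidden); head.be.zeros(fc_hidden);
    float sd2 = std::sqrt(2.f / fc_hidden);
    head.W2.set_size(1, fc_hidden);
    for (uword i = 0; i < head.W2.n_elem; ++i) head.W2(i) = sd2 * nd(rng);
    head.b2 = 0.f;
  }

  // gather im2col matrix from activation A (Cin x P*N)
  static void im2col(const fmat& A, const arma::imat& NB, int Cin, int P, int N, fmat& K) {
    const int KK = NB.n_rows;
    K.set_size(Cin * KK, (uword)P * N);
    for (int n = 0; n < N; ++n) {
      const uword base = (uword)n * P;
      for (int c = 0; c < Cin; ++c) {
        const float* arow = A.memptr(); // column-major; use A(c, col)
        for (int kk = 0; kk < KK; ++kk) {
          const uword r = (uword)c * KK + kk;
          for (int p = 0; p < P; ++p) {
            const long q = NB(kk, p);
            K(r, base + p) = q >= 0 ? A(c, base + q) : 0.f;
          }
        }
        (void)arow;
      }
    }
  }

  static void col2im_add(const fmat& dK, const arma::imat& NB, int Cin, int P, int N, fmat& dA) {
    const int KK = NB.n_rows;
    dA.zeros(Cin, (uword)P * N);
    for (int n = 0; n < N; ++n) {
      const uword base = (uword)n * P;
      for (int c = 0; c < Cin; ++c) {
        for (int kk = 0; kk < KK; ++kk) {
          const uword r = (uword)c * KK + kk;
          for (int p = 0; p < P; ++p) {
            const long q = NB(kk, p);
            if (q >= 0) dA(c, base + q) += dK(r, base + p);
          }
        }
      }
    }
  }

  // forward one trunk; X is 1 x (P*N); returns flattened features (feat x N)
  fmat trunk_forward(int t, const fmat& X, int N, bool train) {
    fmat A = X;
    for (ConvBlock& blk : trunks[t]) {
      im2col(A, blk.NB, blk.Cin, blk.P, N, blk.K);
      fmat Z = blk.W * blk.K;
      Z.each_col() += blk.b;
      if (blk.use_bn) {
        const float M = (float)Z.n_cols;
        if (train) {
          blk.mu = arma::mean(Z, 1);
          fvec var = arma::mean(arma::square(Z.each_col() - blk.mu), 1);
          blk.invstd = 1.f / arma::sqrt(var + BN_EPS);
          blk.rmean = (1.f - BN_MOMENTUM) * blk.rmean + BN_MOMENTUM * blk.mu;
          blk.rvar = (1.f - BN_MOMENTUM) * blk.rvar + BN_MOMENTUM * var * (M / std::max(M - 1.f, 1.f));
          blk.xhat = Z.each_col() - blk.mu;
          blk.xhat.each_col() %= blk.invstd;
        } else {
          blk.xhat = Z.each_col() - blk.rmean;
          blk.xhat.each_col() %= (1.f / arma::sqrt(blk.rvar + BN_EPS));
        }
        Z = blk.xhat.each_col() % blk.gamma;
        Z.each_col() += blk.beta;
      }
      blk.pre_relu = Z;
      Z.transform([](float v) { return v > 0.f ? v : 0.f; });
      blk.post_relu = Z;
      // max pool
      const int S = blk.PG.n_rows;
      fmat O(blk.Cout, (uword)blk.Pout * N);
      blk.pool_arg.set_size(blk.Cout, (uword)blk.Pout * N);
      for (int n = 0; n < N; ++n) {
        const uword ibase = (uword)n * blk.P, obase = (uword)n * blk.Pout;
        for (int po = 0; po < blk.Pout; ++po) {
          for (int c = 0; c < blk.Cout; ++c) {
            float best = -std::numeric_limits<float>::infinity();
            uword bi = 0;
            for (int s = 0; s < S; ++s) {
              const long q = blk.PG(s, po);
              if (q < 0) continue;
              const float v = Z(c, ibase + q);
              if (v > best) { best = v; bi = ibase + q; }
            }
            O(c, obase + po) = best;
            blk.pool_arg(c, obase + po) = bi;
          }
        }
      }
      A = std::move(O);
    }
    // flatten: image n -> column n
    const ConvBlock& last = trunks[t].back();
    fmat F(trunk_feat[t], N);
    const int Pf = last.Pout, Cf = last.Cout;
    for (int n = 0; n < N; ++n)
      for (int p = 0; p < Pf; ++p)
        for (int c = 0; c < Cf; ++c)
          F((uword)p * Cf + c, n) = A(c, (uword)n * Pf + p);
    return F;
  }

  // backward through one trunk given dF (feat x N); accumulates grads
  void trunk_backward(int t, const fmat& dF, int N, std::vector<fmat>& g) {
    const ConvBlock& last = trunks[t].back();
    fmat dA(last.Cout, (uword)last.Pout * N);
    for (int n = 0; n < N; ++n)
      for (int p = 0; p < last.Pout; ++p)
        for (int c = 0; c < last.Cout; ++c)
          dA(c, (uword)n * last.Pout + p) = dF((uword)p * last.Cout + c, n);
    for (int bidx = (int)trunks[t].size() - 1; bidx >= 0; --bidx) {
      ConvBlock& blk = trunks[t][bidx];
      // unpool
      fmat dZ(blk.Cout, (uword)blk.P * N, arma::fill::zeros);
      for (uword col = 0; col < dA.n_cols; ++col)
        for (int c = 0; c < blk.Cout; ++c)
          dZ(c, blk.pool_arg(c, col)) += dA(c, col);
      // relu
      dZ %= arma::conv_to<fmat>::from(blk.pre_relu > 0.f);
      fvec dgamma(blk.Cout), dbeta(blk.Cout);
      if (blk.use_bn) {
        dgamma = arma::sum(dZ % blk.xhat, 1);
        dbeta = arma::sum(dZ, 1);
        const float M = (float)dZ.n_cols;
        fmat dxhat = dZ.each_col() % blk.gamma;
        fvec s1 = arma::sum(dxhat, 1);
        fvec s2 = arma::sum(dxhat % blk.xhat, 1);
        dZ = dxhat * M;
        dZ.each_col() -= s1;
        dZ -= blk.xhat.each_col() % s2;
        dZ.each_col() %= (blk.invstd / M);
      } else {
        dgamma.zeros(); dbeta.zeros();
      }
      fmat dW = dZ * blk.K.t();
      fvec db = arma::sum(dZ, 1);
      g[(uword)bidx * 4 + 0] += dW;
      g[(uword)bidx * 4 + 1] += db;
      g[(uword)bidx * 4 + 2] += dgamma;
      g[(uword)bidx * 4 + 3] += dbeta;
      if (bidx > 0) {
        fmat dK = blk.W.t() * dZ;
        fmat dAin;
        col2im_add(dK, blk.NB, blk.Cin, blk.P, N, dAin);
        dA = std::move(dAin);
      }
    }
  }

  // full forward: xs one fmat per trunk; returns logits (1 x N)
  frowvec forward(const std::vector<fmat>& xs, int N, bool train) {
    fmat F(head.D, N);
    int off = 0;
    for (int t = 0; t < n_trunks; ++t) {
      F.rows(off, off + trunk_feat[t] - 1) = trunk_forward(t, xs[t], N, train);
      off += trunk_feat[t];
    }
    head.Fin = F;
    fmat H1 = head.W1 * F;
    H1.each_col() += head.b1;
    head.H1 = H1;
    head.mu = arma::mean(H1, 0);
    fmat cent = H1.each_row() - head.mu;
    head.invstd = 1.f / arma::sqrt(arma::mean(arma::square(cent), 0) + LN_EPS);
    head.xhat = cent.each_row() % head.invstd;
    fmat A = head.xhat.each_col() % head.g;
    A.each_col() += head.be;
    A.transform([](float v) { return v > 0.f ? v : 0.f; });
    head.post = A;
    if (train && head.dropout > 0.f) {
      std::uniform_real_distribution<float> ud(0.f, 1.f);
      head.mask.set_size(A.n_rows, A.n_cols);
      const float keep = 1.f - head.dropout;
      for (uword i = 0; i < head.mask.n_elem; ++i)
        head.mask(i) = ud(rng) < keep ? 1.f / keep : 0.f;
      A %= head.mask;
    } else {
      head.mask.reset();
    }
    head.post = A; // post-dropout activation cached for backward
    frowvec logits = head.W2 * A + head.b2;
    return logits;
  }

  Grads backward(const frowvec& dlogit, int N) {
    Grads gr;
    fmat dA = head.W2.t() * dlogit;            // H x N
    gr.dW2 = (dlogit * head.post.t());
    gr.db2 = arma::accu(dlogit);
    if (head.mask.n_elem) dA %= head.mask;
    // relu on LN output
    fmat ln_out = head.xhat.each_col() % head.g;
    ln_out.each_col() += head.be;
    dA %= arma::conv_to<fmat>::from(ln_out > 0.f);
    gr.dg = arma::sum(dA % head.xhat, 1);
    gr.dbe = arma::sum(dA, 1);
    fmat dxhat = dA.each_col() % head.g;
    const float Fn = (float)head.Hdim;
    frowvec s1 = arma::sum(dxhat, 0);
    frowvec s2 = arma::sum(dxhat % head.xhat, 0);
    fmat dH = dxhat * Fn;
    dH.each_row() -= s1;
    dH -= head.xhat.each_row() % s2;
    dH.each_row() %= (head.invstd / Fn);
    gr.dW1 = dH * head.Fin.t();
    gr.db1 = arma::sum(dH, 1);
    fmat dF = head.W1.t() * dH;
    // trunks
    gr.trunk.resize(n_trunks);
    int off = 0;
    for (int t = 0; t < n_trunks; ++t) {
      std::vector<fmat> g((uword)trunks[t].size() * 4);
      for (size_t bidx = 0; bidx < trunks[t].size(); ++bidx) {
        const ConvBlock& blk = trunks[t][bidx];
        g[bidx * 4 + 0].zeros(blk.W.n_rows, blk.W.n_cols);
        g[bidx * 4 + 1].zeros(blk.Cout, 1);
        g[bidx * 4 + 2].zeros(blk.Cout, 1);
        g[bidx * 4 + 3].zeros(blk.Cout, 1);
      }
      trunk_backward(t, dF.rows(off, off + trunk_feat[t] - 1), N, g);
      gr.trunk[t] = std::move(g);
      off += trunk_feat[t];
    }
    return gr;
  }
};

// ---------------------------------------------------------------------------
// parameter (de)serialization
// ---------------------------------------------------------------------------

static List params_to_list(const Net& net) {
  List trunks(net.n_trunks);
  for (int t = 0; t < net.n_trunks; ++t) {
    List blocks(net.trunks[t].size());
    for (size_t b = 0; b < net.trunks[t].size(); ++b) {
      const ConvBlock& blk = net.trunks[t][b];
      blocks[b] = List::create(
        _["W"] = wrap(arma::conv_to<arma::mat>::from(blk.W)),
        _["b"] = wrap(arma::conv_to<arma::vec>::from(blk.b)),
        _["gamma"] = wrap(arma::conv_to<arma::vec>::from(blk.gamma)),
        _["beta"] = wrap(arma::conv_to<arma::vec>::from(blk.beta)),
        _["rmean"] = wrap(arma::conv_to<arma::vec>::from(blk.rmean)),
        _["rvar"] = wrap(arma::conv_to<arma::vec>::from(blk.rvar)));
    }
    trunks[t] = blocks;
  }
  List head = List::create(
    _["W1"] = wrap(arma::conv_to<arma::mat>::from(net.head.W1)),
    _["b1"] = wrap(arma::conv_to<arma::vec>::from(net.head.b1)),
    _["g"] = wrap(arma::conv_to<arma::vec>::from(net.head.g)),
    _["be"] = wrap(arma::conv_to<arma::vec>::from(net.head.be)),
    _["W2"] = wrap(arma::conv_to<arma::mat>::from(net.head.W2)),
    _["b2"] = net.head.b2);
  return List::create(_["trunks"] = trunks, _["head"] = head);
}

static void params_from_list(Net& net, const List& params) {
  List trunks = params["trunks"];
  for (int t = 0; t < net.n_trunks; ++t) {
    List blocks = trunks[t];
    for (size_t b = 0; b < net.trunks[t].size(); ++b) {
      List bl = blocks[b];
      ConvBlock& blk = net.trunks[t][b];
      blk.W = arma::conv_to<fmat>::from(as<arma::mat>(bl["W"]));
      blk.b = arma::conv_to<fvec>::from(as<arma::vec>(bl["b"]));
      blk.gamma = arma::conv_to<fvec>::from(as<arma::vec>(bl["gamma"]));
      blk.beta = arma::conv_to<fvec>::from(as<arma::vec>(bl["beta"]));
      blk.rmean = arma::conv_to<fvec>::from(as<arma::vec>(bl["rmean"]));
      blk.rvar = arma::conv_to<fvec>::from(as<arma::vec>(bl["rvar"]));
    }
  }
  List hd = params["head"];
  net.head.W1 = arma::conv_to<fmat>::from(as<arma::mat>(hd["W1"]));
  net.head.b1 = arma::conv_to<fvec>::from(as<arma::vec>(hd["b1"]));
  net.head.g = arma::conv_to<fvec>::from(as<arma::vec>(hd["g"]));
  net.head.be = arma::conv_to<fvec>::from(as<arma::vec>(hd["be"]));
  net.head.W2 = arma::conv_to<fmat>::from(as<arma::mat>(hd["W2"]));
  net.head.b2 = (float)as<double>(hd["b2"]);
}

// flatten inputs: list of arrays -> per-trunk full fmat (1 x P*N)
static std::vector<fmat> inputs_to_fmats(const List& xs, int& N) {
  std::vector<fmat> out;
  N = -1;
  for (int t = 0; t < xs.size(); ++t) {
    NumericVector a = xs[t];
    IntegerVector dim = a.attr("dim");
    int n = dim[dim.size() - 1];
    if (N < 0) N = n;
    if (n != N) stop("trunk inputs disagree on sample count");
    uword P = (uword)a.size() / n;
    fmat X(1, (uword)a.size());
    for (uword i = 0; i < (uword)a.size(); ++i) X(0, i) = (float)a[i];
    (void)P;
    out.push_back(std::move(X));
  }
  return out;
}

// columns of per-trunk matrices for a subset of sample indices
static std::vector<fmat> subset_inputs(const std::vector<fmat>& xs,
                                       const std::vector<int>& P_per_trunk,
                                       const std::vector<int>& idx) {
  std::vector<fmat> out;
  for (size_t t = 0; t < xs.size(); ++t) {
    const int P = P_per_trunk[t];
    fmat X(1, (uword)P * idx.size());
    for (size_t k = 0; k < idx.size(); ++k)
      X.cols((uword)k * P, (uword)(k + 1) * P - 1) =
        xs[t].cols((uword)idx[k] * P, (uword)(idx[k] + 1) * P - 1);
    out.push_back(std::move(X));
  }
  return out;
}

static double bce_with_logits(const frowvec& z, const std::vector<float>& y,
                              frowvec* dz) {
  double loss = 0;
  if (dz) dz->set_size(z.n_elem);
  const float n = (float)z.n_elem;
  for (uword i = 0; i < z.n_elem; ++i) {
    const float zi = z(i), yi = y[i];
    loss += std::max(zi, 0.f) - zi * yi + std::log1p(std::exp(-std::fabs(zi)));
    if (dz) (*dz)(i) = (1.f / (1.f + std::exp(-zi)) - yi) / n;
  }
  return loss / n;
}

// Trainable parameters as a flat list of (matrix pointer, is_decayed) —
// vectors are viewed as n x 1 matrices via fmat wrappers held in the net.
struct ParamRef { fmat* m = nullptr; fvec* v = nullptr; bool decay = false; };

static std::vector<ParamRef> trainable(Net& net) {
  std::vector<ParamRef> out;
  for (auto& trunk : net.trunks)
    for (ConvBlock& blk : trunk) {
      out.push_back({ &blk.W, nullptr, true });
      out.push_back({ nullptr, &blk.b, false });
      out.push_back({ nullptr, &blk.gamma, false });
      out.push_back({ nullptr, &blk.beta, false });
    }
  out.push_back({ &net.head.W1, nullptr, true });
  out.push_back({ nullptr, &net.head.b1, false });
  out.push_back({ nullptr, &net.head.g, false });
  out.push_back({ nullptr, &net.head.be, false });
  out.push_back({ &net.head.W2, nullptr, true });
  return out;
}

// gradients in the same order as trainable(); b2 handled separately
static std::vector<fmat> grads_flat(const Grads& gr, const Net& net) {
  std::vector<fmat> out;
  for (int t = 0; t < net.n_trunks; ++t)
    for (size_t b = 0; b < net.trunks[t].size(); ++b)
      for (int k = 0; k < 4; ++k) out.push_back(gr.trunk[t][b * 4 + k]);
  out.push_back(gr.dW1);
  out.push_back(fmat(gr.db1));
  out.push_back(fmat(gr.dg));
  out.push_back(fmat(gr.dbe));
  out.push_back(gr.dW2);
  return out;
}

// ---------------------------------------------------------------------------
// exported entry points
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_init_params(List net_spec, int seed) {
  Net net;
  net.build(net_spec, seed);
  return params_to_list(net);
}

// [[Rcpp::export]]
NumericVector cpp_predict(List params, List xs, List net_spec) {
  Net net;
  net.build(net_spec, 0);
  params_from_list(net, params);
  int N;
  std::vector<fmat> X = inputs_to_fmats(xs, N);
  std::vector<int> P(net.n_trunks);
  for (int t = 0; t < net.n_trunks; ++t) P[t] = (int)(X[t].n_cols / N);
  NumericVector out(N);
  const int chunk = 256;
  for (int lo = 0; lo < N; lo += chunk) {
    int hi = std::min(lo + chunk, N);
    std::vector<int> idx;
    for (int i = lo; i < hi; ++i) idx.push_back(i);
    std::vector<fmat> Xb = subset_inputs(X, P, idx);
    frowvec z = net.forward(Xb, (int)idx.size(), false);
    for (size_t k = 0; k < idx.size(); ++k) out[idx[k]] = z(k);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_train(List xs_train, NumericVector y_train,
               List xs_val, NumericVector y_val,
               List xs_test,
               List net_spec, List cfg, int seed) {
  Net net;
  net.build(net_spec, seed);
  const double lr0 = as<double>(cfg["lr"]);
  const int batch_size = as<int>(cfg["batch_size"]);
  const int max_epochs = as<int>(cfg["max_epochs"]);
  const double wd = as<double>(cfg["weight_decay"]);
  const int step_size = as<int>(cfg["step_size"]);
  const double lr_gamma = as<double>(cfg["gamma"]);
  const int patience = as<int>(cfg["patience"]);
  const double val_floor = cfg.containsElementNamed("val_loss_floor")
    ? as<double>(cfg["val_loss_floor"]) : 0.0;

  int Ntr, Nva, Nte = 0;
  std::vector<fmat> Xtr = inputs_to_fmats(xs_train, Ntr);
  std::vector<fmat> Xva = inputs_to_fmats(xs_val, Nva);
  std::vector<fmat> Xte;
  bool have_test = xs_test.size() > 0;
  if (have_test) Xte = inputs_to_fmats(xs_test, Nte);
  std::vector<int> P(net.n_trunks);
  for (int t = 0; t < net.n_trunks; ++t) P[t] = (int)(Xtr[t].n_cols / Ntr);
  std::vector<float> ytr(y_train.begin(), y_train.end());
  std::vector<float> yva(y_val.begin(), y_val.end());

  std::vector<ParamRef> refs = trainable(net);
  std::vector<fmat> m(refs.size()), v(refs.size());
  for (size_t i = 0; i < refs.size(); ++i) {
    if (refs[i].m) { m[i].zeros(arma::size(*refs[i].m)); v[i].zeros(arma::size(*refs[i].m)); }
    else { m[i].zeros(refs[i].v->n_elem, 1); v[i].zeros(refs[i].v->n_elem, 1); }
  }
  float m_b2 = 0.f, v_b2 = 0.f;
  long tstep = 0;
  const float b1 = 0.9f, b2m = 0.999f, eps = 1e-8f;

  auto eval_loss = [&](const std::vector<fmat>& X, const std::vector<float>& y, int N) {
    double loss = 0;
    const int chunk = 256;
    for (int lo = 0; lo < N; lo += chunk) {
      int hi = std::min(lo + chunk, N);
      std::vector<int> idx;
      for (int i = lo; i < hi; ++i) idx.push_back(i);
      std::vector<fmat> Xb = subset_inputs(X, P, idx);
      frowvec z = net.forward(Xb, (int)idx.size(), false);
      std::vector<float> yb;
      for (int i : idx) yb.push_back(y[i]);
      loss += bce_with_logits(z, yb, nullptr) * idx.size();
    }
    return loss / N;
  };

  std::vector<double> train_hist, val_hist;
  double best_val = std::numeric_limits<double>::infinity();
  List best_params = params_to_list(net);
  int best_epoch = 0, since_best = 0, epochs_run = 0;
  std::vector<int> order(Ntr);
  for (int i = 0; i < Ntr; ++i) order[i] = i;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    epochs_run = epoch;
    const float lr = (float)(lr0 * (step_size > 0 ? std::pow(lr_gamma, (epoch - 1) / step_size) : 1.0));
    std::shuffle(order.begin(), order.end(), net.rng);
    double ep_loss = 0; int n_batches = 0;
    for (int lo = 0; lo < Ntr; lo += batch_size) {
      int hi = std::min(lo + batch_size, Ntr);
      std::vector<int> idx(order.begin() + lo, order.begin() + hi);
      std::vector<fmat> Xb = subset_inputs(Xtr, P, idx);
      std::vector<float> yb;
      for (int i : idx) yb.push_back(ytr[i]);
      frowvec z = net.forward(Xb, (int)idx.size(), true);
      frowvec dz;
      ep_loss += bce_with_logits(z, yb, &dz);
      ++n_batches;
      Grads gr = net.backward(dz, (int)idx.size());
      std::vector<fmat> gf = grads_flat(gr, net);
      ++tstep;
      const float bc1 = 1.f - std::pow(b1, (float)tstep);
      const float bc2 = 1.f - std::pow(b2m, (float)tstep);
      for (size_t i = 0; i < refs.size(); ++i) {
        m[i] = b1 * m[i] + (1.f - b1) * gf[i];
        v[i] = b2m * v[i] + (1.f - b2m) * arma::square(gf[i]);
        fmat upd = (m[i] / bc1) / (arma::sqrt(v[i] / bc2) + eps);
        if (refs[i].m) {
          if (refs[i].decay) *refs[i].m *= (1.f - lr * (float)wd);
          *refs[i].m -= lr * upd;
        } else {
          *refs[i].v -= lr * upd.col(0);
        }
      }
      // scalar bias b2
      float g2 = gr.db2;
      m_b2 = b1 * m_b2 + (1.f - b1) * g2;
      v_b2 = b2m * v_b2 + (1.f - b2m) * g2 * g2;
      net.head.b2 -= lr * (m_b2 / bc1) / (std::sqrt(v_b2 / bc2) + eps);
    }
    train_hist.push_back(ep_loss / n_batches);
    double vloss = eval_loss(Xva, yva, Nva);
    val_hist.push_back(vloss);
    if (vloss < best_val) {
      best_val = vloss;
      best_params = params_to_list(net);
      best_epoch = epoch;
      since_best = 0;
    } else if (++since_best >= patience && patience > 0) {
      break;
    }
    if (val_floor > 0 && best_val < val_floor) break;
    Rcpp::checkUserInterrupt();
  }

  params_from_list(net, best_params);
  NumericVector test_logits(Nte);
  if (have_test) {
    const int chunk = 256;
    for (int lo = 0; lo < Nte; lo += chunk) {
      int hi = std::min(lo + chunk, Nte);
      std::vector<int> idx;
      for (int i = lo; i < hi; ++i) idx.push_back(i);
      std::vector<fmat> Xb = subset_inputs(Xte, P, idx);
      frowvec z = net.forward(Xb, (int)idx.size(), false);
      for (size_t k = 0; k < idx.size(); ++k) test_logits[idx[k]] = z(k);
    }
  }
  return List::create(
    _["params"] = best_params,
    _["best_epoch"] = best_epoch,
    _["epochs_run"] = epochs_run,
    _["train_loss"] = wrap(train_hist),
    _["val_loss"] = wrap(val_hist),
    _["best_val_loss"] = best_val,
    _["test_logits"] = test_logits);
}
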