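// CNN compute backend.
//
// Activations live in channels-last layout: an fmat with one column per
// feature channel and one row per (sample, canvas position).  The canvas is
// the spatial grid of a sample surrounded by a zero halo sized to the
// convolution's padding, so a same-padding convolution becomes, for every
// kernel offset, a single BLAS sgemm on a row-shifted view of the
// activation matrix (a pointer offset) -- no im2col gather, no col2im
// scatter.  Halo rows are re-zeroed after each convolution so they always
// represent zero padding.  Pooling is valid-mode with argmax bookkeeping.
//
// Parameters, Adam moments and a best-validation snapshot are held in
// single precision inside an external-pointer state object, so a training
// step never converts between R doubles and floats; the R side owns
// initialization, scheduling and all RNG except the dropout masks, which
// are drawn here from a seed the R side supplies per batch.
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

extern "C" void sgemm_(const char* transa, const char* transb, const int* m,
                       const int* n, const int* k, const float* alpha,
                       const float* a, const int* lda, const float* b,
                       const int* ldb, const float* beta, float* c,
                       const int* ldc);

static void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* a, int lda, const float* b, int ldb,
                  float beta, float* c, int ldc) {
  if (m <= 0 || n <= 0 || k <= 0) return;
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, a, &lda, b, &ldb, &beta, c, &ldc);
}

// ---- canvas geometry ------------------------------------------------------

struct Canvas {
  std::vector<int> sd;       // dense spatial dims
  std::vector<int> halo;     // halo per dim
  std::vector<int> cd;       // canvas dims = sd + 2*halo
  std::vector<long> stride;  // canvas strides (first dim fastest)
  long S = 0;                // dense spatial size
  long Sc = 0;               // canvas spatial size
};

static Canvas make_canvas(const std::vector<int>& sd,
                          const std::vector<int>& halo) {
  Canvas cv;
  cv.sd = sd; cv.halo = halo;
  int d = (int)sd.size();
  cv.cd.resize(d); cv.stride.resize(d);
  cv.S = 1; cv.Sc = 1;
  long st = 1;
  for (int i = 0; i < d; ++i) {
    cv.cd[i] = sd[i] + 2 * halo[i];
    cv.stride[i] = st;
    st *= cv.cd[i];
    cv.S *= sd[i];
    cv.Sc *= cv.cd[i];
  }
  return cv;
}

static long canvas_row(const Canvas& cv, long s) {
  long row = 0;
  for (size_t i = 0; i < cv.sd.size(); ++i) {
    long x = s % cv.sd[i]; s /= cv.sd[i];
    row += (x + cv.halo[i]) * cv.stride[i];
  }
  return row;
}

// contiguous interior runs (start row within one sample's canvas); each run
// has length sd[0]
static void interior_runs(const Canvas& cv, std::vector<long>& starts,
                          long& len) {
  len = cv.sd[0];
  long outer = cv.S / cv.sd[0];
  starts.resize(outer);
  for (long o = 0; o < outer; ++o)
    starts[o] = canvas_row(cv, (long)o * cv.sd[0]);
}

static void zero_halo(arma::fmat& A, const Canvas& cv, long N) {
  if (cv.Sc == cv.S) return;
  std::vector<long> starts; long len;
  interior_runs(cv, starts, len);
  long R = cv.Sc * N;
  for (arma::uword c = 0; c < A.n_cols; ++c) {
    float* col = A.colptr(c);
    long prev = 0;
    for (long n = 0; n < N; ++n) {
      long base = n * cv.Sc;
      for (size_t o = 0; o < starts.size(); ++o) {
        long s0 = base + starts[o];
        if (s0 > prev) std::memset(col + prev, 0, (s0 - prev) * sizeof(float));
        prev = s0 + len;
      }
    }
    if (R > prev) std::memset(col + prev, 0, (R - prev) * sizeof(float));
  }
}

static arma::fmat recanvas(const arma::fmat& A, const Canvas& in,
                           const Canvas& out, long N) {
  arma::fmat B((arma::uword)(out.Sc * N), A.n_cols, arma::fill::zeros);
  std::vector<long> si, so; long len;
  interior_runs(in, si, len);
  interior_runs(out, so, len);
  for (arma::uword c = 0; c < A.n_cols; ++c) {
    const float* ac = A.colptr(c);
    float* bc = B.colptr(c);
    for (long n = 0; n < N; ++n)
      for (size_t o = 0; o < si.size(); ++o)
        std::memcpy(bc + n * out.Sc + so[o], ac + n * in.Sc + si[o],
                    len * sizeof(float));
  }
  return B;
}

static arma::fmat recanvas_back(const arma::fmat& dB, const Canvas& in,
                                const Canvas& out, long N) {
  arma::fmat dA((arma::uword)(in.Sc * N), dB.n_cols, arma::fill::zeros);
  std::vector<long> si, so; long len;
  interior_runs(in, si, len);
  interior_runs(out, so, len);
  for (arma::uword c = 0; c < dB.n_cols; ++c) {
    const float* bc = dB.colptr(c);
    float* ac = dA.colptr(c);
    for (long n = 0; n < N; ++n)
      for (size_t o = 0; o < si.size(); ++o)
        std::memcpy(ac + n * in.Sc + si[o], bc + n * out.Sc + so[o],
                    len * sizeof(float));
  }
  return dA;
}

// splitmix64: fast, platform-stable dropout mask stream
static inline uint64_t splitmix64(uint64_t& x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static arma::fmat make_mask(arma::uword nr, arma::uword nc, double rate,
                            uint64_t seed) {
  arma::fmat m(nr, nc);
  float scale = (float)(1.0 / (1.0 - rate));
  float* p = m.memptr();
  uint64_t s = seed;
  for (arma::uword i = 0; i < nr * nc; ++i) {
    double u = (splitmix64(s) >> 40) * (1.0 / 16777216.0);
    p[i] = (u >= rate) ? scale : 0.0f;
  }
  return m;
}

static void relu_inplace(arma::fmat& A) {
  float* p = A.memptr();
  for (arma::uword i = 0; i < A.n_elem; ++i)
    if (p[i] < 0.0f) p[i] = 0.0f;
}

static void relu_mask_inplace(arma::fmat& dY, const arma::fmat& act) {
  float* d = dY.memptr();
  const float* a = act.memptr();
  for (arma::uword i = 0; i < dY.n_elem; ++i)
    if (a[i] <= 0.0f) d[i] = 0.0f;
}

static std::vector<long> kernel_deltas(const Canvas& cv,
                                       const std::vector<int>& kd,
                                       const std::vector<int>& pad_lo) {
  int d = (int)kd.size();
  long K = 1;
  for (int i = 0; i < d; ++i) K *= kd[i];
  std::vector<long> deltas((size_t)K);
  for (long k = 0; k < K; ++k) {
    long kk = k, delta = 0;
    for (int i = 0; i < d; ++i) {
      int ki = (int)(kk % kd[i]); kk /= kd[i];
      delta += (long)(ki - pad_lo[i]) * cv.stride[i];
    }
    deltas[(size_t)k] = delta;
  }
  return deltas;
}

// ---- compiled layer plan and network state --------------------------------

enum LayerType { L_TO_CANVAS, L_RECANVAS, L_CONV, L_POOL, L_DROPOUT,
                 L_FLATTEN, L_FC };

struct LayerDef {
  LayerType type;
  Canvas cv;    // conv/flatten canvas; recanvas/pool input
  Canvas cv2;   // recanvas/pool output; to_canvas output
  std::vector<int> kernel, pad_lo, pool;
  std::vector<long> deltas;
  int cin = 0, cout = 0;
  int in_features = 0, units = 0;
  bool relu = false, tin = false;
  double rate = 0.0;
};

struct NetState {
  std::vector<LayerDef> layers;
  std::vector<arma::fmat> W, mW, vW, bestW;
  std::vector<arma::fvec> b, mb, vb, bestb;
  long adam_t = 0;
  bool has_best = false;
};

struct Tape {
  std::vector<arma::fmat> acts;      // acts[0] = input, acts[i] = output of op i
  std::vector<arma::umat> pool_arg;  // argmax rows (output-canvas layout)
  std::vector<arma::fmat> masks;     // dropout masks
};

static std::vector<int> as_ivec(SEXP s) {
  IntegerVector v(s);
  return std::vector<int>(v.begin(), v.end());
}

static std::vector<LayerDef> parse_plan(const List& plan) {
  std::vector<LayerDef> out;
  for (int i = 0; i < plan.size(); ++i) {
    List ly = plan[i];
    std::string type = as<std::string>(ly["type"]);
    LayerDef d;
    if (type == "to_canvas") {
      d.type = L_TO_CANVAS;
      std::vector<int> sd = as_ivec(ly["sd"]);
      d.cv = make_canvas(sd, std::vector<int>(sd.size(), 0));
      d.cv2 = make_canvas(sd, as_ivec(ly["halo"]));
    } else if (type == "recanvas") {
      d.type = L_RECANVAS;
      std::vector<int> sd = as_ivec(ly["sd"]);
      d.cv = make_canvas(sd, as_ivec(ly["halo_in"]));
      d.cv2 = make_canvas(sd, as_ivec(ly["halo_out"]));
      d.cin = as<int>(ly["channels"]);
    } else if (type == "conv") {
      d.type = L_CONV;
      d.cv = make_canvas(as_ivec(ly["sd"]), as_ivec(ly["halo"]));
      d.kernel = as_ivec(ly["kernel"]);
      d.pad_lo = as_ivec(ly["pad_lo"]);
      d.deltas = kernel_deltas(d.cv, d.kernel, d.pad_lo);
      d.cin = as<int>(ly["cin"]);
      d.cout = as<int>(ly["cout"]);
    } else if (type == "pool") {
      d.type = L_POOL;
      d.cv = make_canvas(as_ivec(ly["sd_in"]), as_ivec(ly["halo_in"]));
      d.cv2 = make_canvas(as_ivec(ly["sd_out"]), as_ivec(ly["halo_out"]));
      d.pool = as_ivec(ly["pool"]);
      d.cin = as<int>(ly["channels"]);
    } else if (type == "dropout") {
      d.type = L_DROPOUT;
      d.rate = as<double>(ly["rate"]);
    } else if (type == "flatten") {
      d.type = L_FLATTEN;
      d.cv = make_canvas(as_ivec(ly["sd"]), as_ivec(ly["halo"]));
      d.cin = as<int>(ly["cin"]);
      d.in_features = as<int>(ly["features"]);
    } else if (type == "fc") {
      d.type = L_FC;
      d.in_features = as<int>(ly["in_features"]);
      d.units = as<int>(ly["units"]);
      d.relu = as<bool>(ly["relu"]);
      d.tin = as<bool>(ly["tin"]);
    } else {
      stop("unknown layer type: " + type);
    }
    out.push_back(std::move(d));
  }
  return out;
}

static arma::fmat as_fmat(SEXP s, arma::uword nrow, arma::uword ncol) {
  NumericVector v(s);
  if ((arma::uword)v.size() != nrow * ncol) stop("parameter size mismatch");
  arma::fmat out(nrow, ncol);
  const double* src = v.begin();
  float* dst = out.memptr();
  for (arma::uword i = 0; i < nrow * ncol; ++i) dst[i] = (float)src[i];
  return out;
}

static NumericVector to_num(const arma::fmat& m, bool as_matrix = true) {
  NumericVector out((R_xlen_t)m.n_elem);
  const float* src = m.memptr();
  for (R_xlen_t i = 0; i < out.size(); ++i) out[i] = (double)src[i];
  if (as_matrix)
    out.attr("dim") = IntegerVector::create((int)m.n_rows, (int)m.n_cols);
  return out;
}

// ---- forward --------------------------------------------------------------

static void conv_forward(const LayerDef& d, const arma::fmat& A,
                         const arma::fmat& W, const arma::fvec& b, long N,
                         arma::fmat& Y) {
  const Canvas& cv = d.cv;
  long K = (long)d.deltas.size();
  long R = cv.Sc * N;
  int Ri = (int)R, CK = (int)(d.cin * K), Co = d.cout, C = d.cin;
  Y.zeros((arma::uword)R, (arma::uword)Co);
  if (C == 1) {
    // one input channel: materialize the K shifted copies and use a single
    // well-shaped GEMM instead of K rank-1 updates
    arma::fmat colT((arma::uword)R, (arma::uword)K);
    for (long k = 0; k < K; ++k) {
      long dd = d.deltas[(size_t)k];
      long r0 = std::max(0L, -dd);
      long r1 = R - std::max(0L, dd);
      float* dst = colT.colptr(k);
      if (r0 > 0) std::memset(dst, 0, r0 * sizeof(float));
      if (r1 > r0)
        std::memcpy(dst + r0, A.memptr() + r0 + dd, (r1 - r0) * sizeof(float));
      if (R > r1) std::memset(dst + r1, 0, (R - r1) * sizeof(float));
    }
    sgemm('N', 'N', Ri, Co, (int)K, 1.0f, colT.memptr(), Ri, W.memptr(), CK,
          0.0f, Y.memptr(), Ri);
  } else if ((double)R * C * 4.0 > 6.4e7 && (double)R * CK * 4.0 < 3.2e8) {
    // small batches: materialize all shifted copies with contiguous block
    // copies and use one well-shaped GEMM (K = C*kernel)
    arma::fmat colT((arma::uword)R, (arma::uword)CK);
    for (long k = 0; k < K; ++k) {
      long dd = d.deltas[(size_t)k];
      long r0 = std::max(0L, -dd);
      long r1 = R - std::max(0L, dd);
      for (long c = 0; c < C; ++c) {
        float* dst = colT.colptr(k * C + c);
        if (r0 > 0) std::memset(dst, 0, r0 * sizeof(float));
        if (r1 > r0)
          std::memcpy(dst + r0, A.colptr(c) + r0 + dd,
                      (r1 - r0) * sizeof(float));
        if (R > r1) std::memset(dst + r1, 0, (R - r1) * sizeof(float));
      }
    }
    sgemm('N', 'N', Ri, Co, CK, 1.0f, colT.memptr(), Ri, W.memptr(), CK,
          0.0f, Y.memptr(), Ri);
  } else {
    for (long k = 0; k < K; ++k) {
      long dd = d.deltas[(size_t)k];
      long r0 = std::max(0L, -dd);
      long r1 = R - std::max(0L, dd);
      sgemm('N', 'N', (int)(r1 - r0), Co, C, 1.0f, A.memptr() + r0 + dd, Ri,
            W.memptr() + k * C, CK, 1.0f, Y.memptr() + r0, Ri);
    }
  }
  for (int co = 0; co < Co; ++co) {
    float bb = b[co];
    float* col = Y.colptr(co);
    for (long r = 0; r < R; ++r) col[r] += bb;
  }
  relu_inplace(Y);
  zero_halo(Y, cv, N);
}

static void pool_forward(const LayerDef& d, const arma::fmat& A, long N,
                         arma::fmat& B, arma::umat* arg) {
  const Canvas& in = d.cv;
  const Canvas& out = d.cv2;
  int C = d.cin;
  long So = out.S;
  long P = 1;
  for (size_t j = 0; j < d.pool.size(); ++j) P *= d.pool[j];
  std::vector<long> orow((size_t)So), crow((size_t)So);
  for (long so = 0; so < So; ++so) {
    orow[(size_t)so] = canvas_row(out, so);
    long ss = so, sin = 0, mult = 1;
    for (size_t j = 0; j < out.sd.size(); ++j) {
      long x = ss % out.sd[j]; ss /= out.sd[j];
      sin += x * d.pool[j] * mult;
      mult *= in.sd[j];
    }
    crow[(size_t)so] = canvas_row(in, sin);
  }
  std::vector<long> poff((size_t)P);
  for (long p = 0; p < P; ++p) {
    long pp = p, off = 0;
    for (size_t j = 0; j < d.pool.size(); ++j) {
      off += (pp % d.pool[j]) * in.stride[j];
      pp /= d.pool[j];
    }
    poff[(size_t)p] = off;
  }
  B.zeros((arma::uword)(out.Sc * N), (arma::uword)C);
  if (arg) arg->set_size(B.n_rows, B.n_cols);
  for (int c = 0; c < C; ++c) {
    const float* ac = A.colptr(c);
    float* bc = B.colptr(c);
    arma::uword* gc = arg ? arg->colptr(c) : nullptr;
    for (long n = 0; n < N; ++n) {
      long bi = n * in.Sc, bo = n * out.Sc;
      for (long so = 0; so < So; ++so) {
        long corner = bi + crow[(size_t)so];
        float best = ac[corner + poff[0]];
        long barg = corner + poff[0];
        for (long p = 1; p < P; ++p) {
          float v = ac[corner + poff[(size_t)p]];
          if (v > best) { best = v; barg = corner + poff[(size_t)p]; }
        }
        bc[bo + orow[(size_t)so]] = best;
        if (gc) gc[bo + orow[(size_t)so]] = (arma::uword)barg;
      }
    }
  }
}

// Forward pass; logits returned as (N x 2).  When tape != nullptr every
// intermediate activation is kept for the backward pass and dropout is
// applied (training mode unless use_dropout is off for gradient checks).
static arma::fmat run_forward(const NetState& S, arma::fmat A0, long N,
                              bool use_dropout, uint64_t dropout_seed,
                              Tape* tape) {
  int L = (int)S.layers.size();
  arma::fmat local;
  const arma::fmat* cur;
  if (tape) {
    tape->acts.assign(L + 1, arma::fmat());
    tape->pool_arg.assign(L, arma::umat());
    tape->masks.assign(L, arma::fmat());
    tape->acts[0] = std::move(A0);
    cur = &tape->acts[0];
  } else {
    local = std::move(A0);
    cur = &local;
  }
  auto store = [&](arma::fmat&& Y, int i) {
    if (tape) { tape->acts[i + 1] = std::move(Y); cur = &tape->acts[i + 1]; }
    else { local = std::move(Y); cur = &local; }
  };
  for (int i = 0; i < L; ++i) {
    const LayerDef& d = S.layers[(size_t)i];
    const arma::fmat& A = *cur;
    switch (d.type) {
    case L_TO_CANVAS:
    case L_RECANVAS:
      store(recanvas(A, d.cv, d.cv2, N), i);
      break;
    case L_CONV: {
      arma::fmat Y;
      conv_forward(d, A, S.W[(size_t)i], S.b[(size_t)i], N, Y);
      store(std::move(Y), i);
      break;
    }
    case L_POOL: {
      arma::fmat B;
      arma::umat arg;
      pool_forward(d, A, N, B, tape ? &arg : nullptr);
      if (tape) tape->pool_arg[(size_t)i] = std::move(arg);
      store(std::move(B), i);
      break;
    }
    case L_DROPOUT:
      if (use_dropout) {
        arma::fmat mask = make_mask(A.n_rows, A.n_cols, d.rate,
                                    dropout_seed * 2654435761ULL + (uint64_t)i);
        arma::fmat Y = A % mask;
        if (tape) tape->masks[(size_t)i] = std::move(mask);
        store(std::move(Y), i);
      } else if (tape) {
        tape->acts[(size_t)i + 1] = A;  // keep the chain aligned
        cur = &tape->acts[(size_t)i + 1];
      }
      break;
    case L_FLATTEN: {
      // features x samples; contiguous interior runs map to contiguous
      // feature blocks, so this is pure memcpy
      const Canvas& cv = d.cv;
      long Ssz = cv.S;
      std::vector<long> starts; long len;
      interior_runs(cv, starts, len);
      arma::fmat F((arma::uword)(d.cin * Ssz), (arma::uword)N);
      for (long n = 0; n < N; ++n) {
        float* fc = F.colptr(n);
        for (int c = 0; c < d.cin; ++c) {
          const float* ac = A.colptr(c) + n * cv.Sc;
          float* dst = fc + (long)c * Ssz;
          for (size_t o = 0; o < starts.size(); ++o)
            std::memcpy(dst + o * len, ac + starts[o], len * sizeof(float));
        }
      }
      store(std::move(F), i);
      break;
    }
    case L_FC: {
      int in = d.in_features, units = d.units;
      const arma::fmat& W = S.W[(size_t)i];
      arma::fmat Y((arma::uword)N, (arma::uword)units);
      if (d.tin)
        sgemm('T', 'N', (int)N, units, in, 1.0f, A.memptr(), in, W.memptr(),
              in, 0.0f, Y.memptr(), (int)N);
      else
        sgemm('N', 'N', (int)N, units, in, 1.0f, A.memptr(), (int)N,
              W.memptr(), in, 0.0f, Y.memptr(), (int)N);
      for (int u = 0; u < units; ++u) {
        float bb = S.b[(size_t)i][u];
        float* col = Y.colptr(u);
        for (long r = 0; r < N; ++r) col[r] += bb;
      }
      if (d.relu) relu_inplace(Y);
      store(std::move(Y), i);
      break;
    }
    }
  }
  return *cur;
}

static arma::fmat softmax_rows(const arma::fmat& logits) {
  arma::fmat p = logits;
  for (arma::uword r = 0; r < p.n_rows; ++r) {
    float mx = p.row(r).max();
    float s = 0;
    for (arma::uword c = 0; c < p.n_cols; ++c) {
      p(r, c) = std::exp(p(r, c) - mx);
      s += p(r, c);
    }
    p.row(r) /= s;
  }
  return p;
}

// ---- backward -------------------------------------------------------------

static void conv_backward(const LayerDef& d, const arma::fmat& X,
                          const arma::fmat& W, arma::fmat& dY, long N,
                          arma::fmat& dW, arma::fvec& db, arma::fmat& dA) {
  const Canvas& cv = d.cv;
  long K = (long)d.deltas.size();
  long R = cv.Sc * N;
  int Ri = (int)R, CK = (int)(d.cin * K), Co = d.cout, C = d.cin;
  db = arma::conv_to<arma::fvec>::from(arma::sum(dY, 0).t());
  dW.zeros((arma::uword)CK, (arma::uword)Co);
  dA.zeros((arma::uword)R, (arma::uword)C);
  if (C == 1) {
    arma::fmat colT((arma::uword)R, (arma::uword)K);
    for (long k = 0; k < K; ++k) {
      long dd = d.deltas[(size_t)k];
      long r0 = std::max(0L, -dd);
      long r1 = R - std::max(0L, dd);
      float* dst = colT.colptr(k);
      if (r0 > 0) std::memset(dst, 0, r0 * sizeof(float));
      if (r1 > r0)
        std::memcpy(dst + r0, X.memptr() + r0 + dd, (r1 - r0) * sizeof(float));
      if (R > r1) std::memset(dst + r1, 0, (R - r1) * sizeof(float));
    }
    sgemm('T', 'N', (int)K, Co, Ri, 1.0f, colT.memptr(), Ri, dY.memptr(), Ri,
          0.0f, dW.memptr(), CK);
    arma::fmat dcolT((arma::uword)R, (arma::uword)K);
    sgemm('N', 'T', Ri, (int)K, Co, 1.0f, dY.memptr(), Ri, W.memptr(), CK,
          0.0f, dcolT.memptr(), Ri);
    float* da = dA.memptr();
    for (long k = 0; k < K; ++k) {
      long dd = d.deltas[(size_t)k];
      long r0 = std::max(0L, -dd);
      long r1 = R - std::max(0L, dd);
      const float* dc = dcolT.colptr(k);
      for (long r = r0; r < r1; ++r) da[r + dd] += dc[r];
    }
  } else if ((double)R * C * 4.0 > 6.4e7 && (double)R * CK * 4.0 < 3.2e8) {
    arma::fmat colT((arma::uword)R, (arma::uword)CK);
    for (long k = 0; k < K; ++k) {
      long dd = d.deltas[(size_t)k];
      long r0 = std::max(0L, -dd);
      long r1 = R - std::max(0L, dd);
      for (long c = 0; c < C; ++c) {
        float* dst = colT.colptr(k * C + c);
        if (r0 > 0) std::memset(dst, 0, r0 * sizeof(float));
        if (r1 > r0)
          std::memcpy(dst + r0, X.colptr(c) + r0 + dd,
                      (r1 - r0) * sizeof(float));
        if (R > r1) std::memset(dst + r1, 0, (R - r1) * sizeof(float));
      }
    }
    sgemm('T', 'N', CK, Co, Ri, 1.0f, colT.memptr(), Ri, dY.memptr(), Ri,
          0.0f, dW.memptr(), CK);
    arma::fmat dcolT((arma::uword)R, (arma::uword)CK);
    sgemm('N', 'T', Ri, CK, Co, 1.0f, dY.memptr(), Ri, W.memptr(), CK,
          0.0f, dcolT.memptr(), Ri);
    for (long k = 0; k < K; ++k) {
      long dd = d.deltas[(size_t)k];
      long r0 = std::max(0L, -dd);
      long r1 = R - std::max(0L, dd);
      for (long c = 0; c < C; ++c) {
        float* dst = dA.colptr(c) + r0 + dd;
        const float* src = dcolT.colptr(k * C + c) + r0;
        for (long r = 0; r < r1 - r0; ++r) dst[r] += src[r];
      }
    }
  } else {
    for (long k = 0; k < K; ++k) {
      long dd = d.deltas[(size_t)k];
      long r0 = std::max(0L, -dd);
      long r1 = R - std::max(0L, dd);
      int Mr = (int)(r1 - r0);
      // dW_k = X_shifted^T dY
      sgemm('T', 'N', C, Co, Mr, 1.0f, X.memptr() + r0 + dd, Ri,
            dY.memptr() + r0, Ri, 1.0f, dW.memptr() + k * C, CK);
      // dX_shifted += dY W_k^T
      sgemm('N', 'T', Mr, C, Co, 1.0f, dY.memptr() + r0, Ri,
            W.memptr() + k * C, CK, 1.0f, dA.memptr() + r0 + dd, Ri);
    }
  }
}

// Backward pass from the softmax gradient.  Per parameterized layer either
// applies an Adam step in place (gW == nullptr) or stores the gradients
// (gradient checking).
static void run_backward(NetState& S, Tape& tape, arma::fmat dY, long N,
                         bool use_dropout, std::vector<arma::fmat>* gW,
                         std::vector<arma::fvec>* gb, double lr, double beta1,
                         double beta2, double eps) {
  int L = (int)S.layers.size();
  double bc1 = 1, bc2 = 1;
  if (!gW) {
    S.adam_t += 1;
    bc1 = 1.0 - std::pow(beta1, (double)S.adam_t);
    bc2 = 1.0 - std::pow(beta2, (double)S.adam_t);
  }
  const float b1 = (float)beta1, b2 = (float)beta2;
  const float lr_bc1 = (float)(lr / bc1);
  const float inv_bc2 = (float)(1.0 / bc2);
  const float epsf = (float)eps;
  auto adam_upd = [&](float* wp, float* mp, float* vp, const float* gp,
                      arma::uword nel) {
    for (arma::uword j = 0; j < nel; ++j) {
      mp[j] = b1 * mp[j] + (1.0f - b1) * gp[j];
      vp[j] = b2 * vp[j] + (1.0f - b2) * gp[j] * gp[j];
      wp[j] -= lr_bc1 * mp[j] / (std::sqrt(vp[j] * inv_bc2) + epsf);
    }
  };
  auto adam_mat = [&](arma::fmat& w, arma::fmat& m, arma::fmat& v,
                      const arma::fmat& g) {
    adam_upd(w.memptr(), m.memptr(), v.memptr(), g.memptr(), w.n_elem);
  };
  auto adam_vec = [&](arma::fvec& w, arma::fvec& m, arma::fvec& v,
                      const arma::fvec& g) {
    adam_upd(w.memptr(), m.memptr(), v.memptr(), g.memptr(), w.n_elem);
  };
  for (int i = L - 1; i >= 0; --i) {
    const LayerDef& d = S.layers[(size_t)i];
    switch (d.type) {
    case L_FC: {
      int in = d.in_features, units = d.units;
      if (d.relu) relu_mask_inplace(dY, tape.acts[(size_t)i + 1]);
      const arma::fmat& W = S.W[(size_t)i];
      const arma::fmat& X = tape.acts[(size_t)i];
      arma::fmat dW((arma::uword)in, (arma::uword)units);
      if (d.tin)
        sgemm('N', 'N', in, units, (int)N, 1.0f, X.memptr(), in, dY.memptr(),
              (int)N, 0.0f, dW.memptr(), in);
      else
        sgemm('T', 'N', in, units, (int)N, 1.0f, X.memptr(), (int)N,
              dY.memptr(), (int)N, 0.0f, dW.memptr(), in);
      arma::fvec db = arma::conv_to<arma::fvec>::from(arma::sum(dY, 0).t());
      arma::fmat dX;
      if (d.tin) {
        dX.set_size((arma::uword)in, (arma::uword)N);
        sgemm('N', 'T', in, (int)N, units, 1.0f, W.memptr(), in, dY.memptr(),
              (int)N, 0.0f, dX.memptr(), in);
      } else {
        dX.set_size((arma::uword)N, (arma::uword)in);
        sgemm('N', 'T', (int)N, in, units, 1.0f, dY.memptr(), (int)N,
              W.memptr(), in, 0.0f, dX.memptr(), (int)N);
      }
      if (gW) {
        (*gW)[(size_t)i] = std::move(dW);
        (*gb)[(size_t)i] = std::move(db);
      } else {
        adam_mat(S.W[(size_t)i], S.mW[(size_t)i], S.vW[(size_t)i], dW);
        adam_vec(S.b[(size_t)i], S.mb[(size_t)i], S.vb[(size_t)i], db);
      }
      dY = std::move(dX);
      break;
    }
    case L_FLATTEN: {
      const Canvas& cv = d.cv;
      long Ssz = cv.S;
      std::vector<long> starts; long len;
      interior_runs(cv, starts, len);
      arma::fmat dA((arma::uword)(cv.Sc * N), (arma::uword)d.cin,
                    arma::fill::zeros);
      for (long n = 0; n < N; ++n) {
        const float* fc = dY.colptr(n);
        for (int c = 0; c < d.cin; ++c) {
          float* ac = dA.colptr(c) + n * cv.Sc;
          const float* src = fc + (long)c * Ssz;
          for (size_t o = 0; o < starts.size(); ++o)
            std::memcpy(ac + starts[o], src + o * len, len * sizeof(float));
        }
      }
      dY = std::move(dA);
      break;
    }
    case L_DROPOUT:
      if (use_dropout) dY %= tape.masks[(size_t)i];
      break;
    case L_POOL: {
      const Canvas& in = d.cv;
      const Canvas& out = d.cv2;
      long So = out.S;
      std::vector<long> orow((size_t)So);
      for (long so = 0; so < So; ++so) orow[(size_t)so] = canvas_row(out, so);
      arma::fmat dA((arma::uword)(in.Sc * N), (arma::uword)d.cin,
                    arma::fill::zeros);
      const arma::umat& arg = tape.pool_arg[(size_t)i];
      for (int c = 0; c < d.cin; ++c) {
        float* ac = dA.colptr(c);
        const float* dc = dY.colptr(c);
        const arma::uword* gc = arg.colptr(c);
        for (long n = 0; n < N; ++n) {
          long bo = n * out.Sc;
          for (long so = 0; so < So; ++so) {
            long r = bo + orow[(size_t)so];
            ac[gc[r]] += dc[r];
          }
        }
      }
      dY = std::move(dA);
      break;
    }
    case L_CONV: {
      relu_mask_inplace(dY, tape.acts[(size_t)i + 1]);
      arma::fmat dW, dA;
      arma::fvec db;
      conv_backward(d, tape.acts[(size_t)i], S.W[(size_t)i], dY, N, dW, db,
                    dA);
      if (gW) {
        (*gW)[(size_t)i] = std::move(dW);
        (*gb)[(size_t)i] = std::move(db);
      } else {
        adam_mat(S.W[(size_t)i], S.mW[(size_t)i], S.vW[(size_t)i], dW);
        adam_vec(S.b[(size_t)i], S.mb[(size_t)i], S.vb[(size_t)i], db);
      }
      dY = std::move(dA);
      break;
    }
    case L_RECANVAS:
      dY = recanvas_back(dY, d.cv, d.cv2, N);
      break;
    case L_TO_CANVAS:
      break;  // input gradient not needed
    }
  }
}

// ---- exported API ---------------------------------------------------------

static arma::fmat input_to_fmat(NumericVector x, long rows) {
  if ((long)x.size() != rows) stop("input size mismatch");
  arma::fmat A((arma::uword)rows, 1);
  const double* src = x.begin();
  float* dst = A.memptr();
  for (long i = 0; i < rows; ++i) dst[i] = (float)src[i];
  return A;
}

static double softmax_loss(const arma::fmat& p, IntegerVector y, int n) {
  double loss = 0.0;
  for (int j = 0; j < n; ++j)
    loss -= std::log(std::max(1e-12, (double)p(j, (arma::uword)y[j])));
  return loss / n;
}

// [[Rcpp::export]]
SEXP cpp_state_create(List plan, List params) {
  XPtr<NetState> ptr(new NetState(), true);
  ptr->layers = parse_plan(plan);
  int L = (int)ptr->layers.size();
  ptr->W.resize(L); ptr->b.resize(L);
  ptr->mW.resize(L); ptr->vW.resize(L);
  ptr->mb.resize(L); ptr->vb.resize(L);
  for (int i = 0; i < L; ++i) {
    const LayerDef& d = ptr->layers[(size_t)i];
    if (d.type == L_CONV || d.type == L_FC) {
      List pr = params[i];
      arma::uword nr, nc;
      if (d.type == L_CONV) {
        nr = (arma::uword)(d.cin * d.deltas.size());
        nc = (arma::uword)d.cout;
      } else {
        nr = (arma::uword)d.in_features;
        nc = (arma::uword)d.units;
      }
      ptr->W[(size_t)i] = as_fmat(pr["W"], nr, nc);
      NumericVector bv(as<SEXP>(pr["b"]));
      ptr->b[(size_t)i].set_size((arma::uword)bv.size());
      for (int j = 0; j < bv.size(); ++j) ptr->b[(size_t)i][j] = (float)bv[j];
      ptr->mW[(size_t)i].zeros(nr, nc);
      ptr->vW[(size_t)i].zeros(nr, nc);
      ptr->mb[(size_t)i].zeros((arma::uword)bv.size());
      ptr->vb[(size_t)i].zeros((arma::uword)bv.size());
    }
  }
  return ptr;
}

// [[Rcpp::export]]
List cpp_state_forward(SEXP state, NumericVector x, int n) {
  XPtr<NetState> S(state);
  long rows = S->layers[0].cv.S * n;
  arma::fmat logits = run_forward(*S, input_to_fmat(x, rows), n, false, 0,
                                  nullptr);
  return List::create(_["prob"] = to_num(softmax_rows(logits)));
}

// One minibatch: forward, weighted softmax cross-entropy, backward,
// in-place Adam.  w holds one non-negative weight per sample (e.g. inverse
// class frequencies); the loss is the weighted mean.
// [[Rcpp::export]]
List cpp_state_train_batch(SEXP state, NumericVector x, IntegerVector y,
                           int n, NumericVector w, double dropout_seed,
                           double lr, double beta1, double beta2,
                           double eps) {
  XPtr<NetState> S(state);
  long rows = S->layers[0].cv.S * n;
  Tape tape;
  arma::fmat logits = run_forward(*S, input_to_fmat(x, rows), n, true,
                                  (uint64_t)dropout_seed, &tape);
  arma::fmat p = softmax_rows(logits);
  double wsum = 0.0;
  for (int j = 0; j < n; ++j) wsum += w[j];
  double loss = 0.0;
  for (int j = 0; j < n; ++j)
    loss -= w[j] * std::log(std::max(1e-12, (double)p(j, (arma::uword)y[j])));
  loss /= wsum;
  arma::fmat dY = p;
  for (int j = 0; j < n; ++j) dY(j, (arma::uword)y[j]) -= 1.0f;
  for (int j = 0; j < n; ++j) dY.row(j) *= (float)(w[j] / wsum);
  run_backward(*S, tape, std::move(dY), n, true, nullptr, nullptr, lr, beta1,
               beta2, eps);
  arma::ucolvec pred = arma::index_max(p, 1);
  int correct = 0;
  for (int j = 0; j < n; ++j)
    if ((int)pred[j] == y[j]) ++correct;
  return List::create(_["loss"] = loss, _["n_correct"] = correct);
}

// Loss and gradients without an update (for gradient checking).
// [[Rcpp::export]]
List cpp_state_grads(SEXP state, NumericVector x, IntegerVector y, int n,
                     bool use_dropout, double dropout_seed) {
  XPtr<NetState> S(state);
  long rows = S->layers[0].cv.S * n;
  Tape tape;
  arma::fmat logits = run_forward(*S, input_to_fmat(x, rows), n, use_dropout,
                                  (uint64_t)dropout_seed, &tape);
  arma::fmat p = softmax_rows(logits);
  double loss = softmax_loss(p, y, n);
  arma::fmat dY = p;
  for (int j = 0; j < n; ++j) dY(j, (arma::uword)y[j]) -= 1.0f;
  dY /= (float)n;
  int L = (int)S->layers.size();
  std::vector<arma::fmat> gW((size_t)L);
  std::vector<arma::fvec> gb((size_t)L);
  run_backward(*S, tape, std::move(dY), n, use_dropout, &gW, &gb, 0, 0.9,
               0.999, 1e-8);
  List grads(L);
  for (int i = 0; i < L; ++i) {
    const LayerDef& d = S->layers[(size_t)i];
    if (d.type == L_CONV || d.type == L_FC)
      grads[i] = List::create(_["W"] = to_num(gW[(size_t)i]),
                              _["b"] = to_num(arma::fmat(gb[(size_t)i]),
                                              false));
  }
  return List::create(_["loss"] = loss, _["grads"] = grads);
}

// [[Rcpp::export]]
void cpp_state_snapshot(SEXP state) {
  XPtr<NetState> S(state);
  S->bestW = S->W;
  S->bestb = S->b;
  S->has_best = true;
}

// [[Rcpp::export]]
void cpp_state_restore(SEXP state) {
  XPtr<NetState> S(state);
  if (S->has_best) { S->W = S->bestW; S->b = S->bestb; }
}

// [[Rcpp::export]]
List cpp_state_export(SEXP state) {
  XPtr<NetState> S(state);
  int L = (int)S->layers.size();
  List out(L);
  for (int i = 0; i < L; ++i) {
    const LayerDef& d = S->layers[(size_t)i];
    if (d.type == L_CONV || d.type == L_FC)
      out[i] = List::create(_["W"] = to_num(S->W[(size_t)i]),
                            _["b"] = to_num(arma::fmat(S->b[(size_t)i]),
                                            false));
  }
  return out;
}
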