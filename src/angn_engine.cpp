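// Core evaluation loops for neuron-glia networks.
//
// The R level owns all object construction and the genetic algorithm; this
// file only implements the hot paths: forward evaluation, the per-pattern
// astrocyte window, the global processing pass, and population fitness.
// Weight matrices are stored flat in R's column-major order, layer by
// layer: the weight from source neuron i to destination neuron j of weight
// layer l sits at offset[l] + i * n_out(l) + j.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Net {
  std::vector<int> sizes;        // neurons per layer
  std::vector<int> act;          // 0 threshold, 1 tanh, 2 identity
  std::vector<double> theta;     // per non-input layer
  std::vector<double> w;         // flat weights
  std::vector<int> offset;       // start of each weight layer in w
  double wM;

  int n_layers() const { return static_cast<int>(sizes.size()); }
};

Net unpack_net(const List& packed) {
  Net net;
  net.sizes = as<std::vector<int>>(packed["sizes"]);
  net.act = as<std::vector<int>>(packed["act"]);
  net.theta = as<std::vector<double>>(packed["theta"]);
  net.w = as<std::vector<double>>(packed["weights"]);
  net.wM = as<double>(packed["wM"]);
  net.offset.resize(net.sizes.size() - 1);
  int off = 0;
  for (size_t l = 0; l + 1 < net.sizes.size(); ++l) {
    net.offset[l] = off;
    off += net.sizes[l] * net.sizes[l + 1];
  }
  if (off != static_cast<int>(net.w.size()))
    stop("weight vector length does not match the architecture");
  return net;
}

struct Astro {
  int algo;        // -1 none; 0/1 consecutive (lim/unlim); 2/3 nonconsecutive;
                   // 4 attenuated; 5 global
  int k, mu;
  double a, b;
  bool limited;
  int attach;      // 0 incoming, 1 outgoing, 2 both
};

Astro unpack_astro(const List& packed) {
  Astro ap;
  ap.algo = as<int>(packed["algo"]);
  ap.k = as<int>(packed["k"]);
  ap.mu = as<int>(packed["mu"]);
  ap.a = as<double>(packed["a"]);
  ap.b = as<double>(packed["b"]);
  ap.limited = as<bool>(packed["limited"]);
  ap.attach = as<int>(packed["attach"]);
  return ap;
}

double activate(int kind, double theta, double x) {
  switch (kind) {
    case 0: return x > theta ? 1.0 : 0.0;
    case 1: return std::tanh(x);
    default: return x;
  }
}

// evaluate the network on one pattern; `out` holds per-layer outputs
void forward(const Net& net, const double* x,
             std::vector<std::vector<double>>& out) {
  const int L = net.n_layers();
  out.resize(L);
  out[0].assign(x, x + net.sizes[0]);
  for (int l = 0; l + 1 < L; ++l) {
    const int n_in = net.sizes[l], n_out = net.sizes[l + 1];
    out[l + 1].assign(n_out, 0.0);
    const double* wl = net.w.data() + net.offset[l];
    for (int i = 0; i < n_in; ++i) {
      const double xi = out[l][i];
      if (xi == 0.0) continue;
      const double* col = wl + i * n_out;
      for (int j = 0; j < n_out; ++j) out[l + 1][j] += col[j] * xi;
    }
    for (int j = 0; j < n_out; ++j)
      out[l + 1][j] = activate(net.act[l], net.theta[l], out[l + 1][j]);
  }
}

// one counter step for the five per-pattern rules (algo 0..4)
int counter_step(int algo, int r_prev, bool has_prev, int u_prev, int u,
                 int mu) {
  if (!has_prev) return u;
  const bool consecutive = algo <= 1;
  const bool attenuated = algo == 4;
  if (consecutive) {
    if (u == u_prev && std::abs(r_prev) < mu) return r_prev + u;
    return u;
  }
  if (std::abs(r_prev) < mu) return r_prev + u;
  if (attenuated) return r_prev;
  return u;
}

inline double sgn(double x) { return x > 0 ? 1.0 : (x < 0 ? -1.0 : 0.0); }

// rescale one weight by the relative change z, clamping if required
inline void scale_weight(double& w, double z, bool limited, double wM) {
  w += std::fabs(w) * z;
  if (limited && std::fabs(w) > wM) w = sgn(w) * wM;
}

// apply z to the connections attached to neuron j of layer `layer`
void apply_to_attached(Net& net, int layer, int j, double z, const Astro& ap) {
  if (z == 0.0) return;
  if (ap.attach == 0 || ap.attach == 2) {  // incoming: row j of layer-1 matrix
    const int l = layer - 1;
    const int n_in = net.sizes[l], n_out = net.sizes[l + 1];
    double* wl = net.w.data() + net.offset[l];
    for (int i = 0; i < n_in; ++i)
      scale_weight(wl[i * n_out + j], z, ap.limited, net.wM);
  }
  if ((ap.attach == 1 || ap.attach == 2) && layer + 1 < net.n_layers()) {
    const int l = layer;                   // outgoing: column j of layer matrix
    const int n_out = net.sizes[l + 1];
    double* wl = net.w.data() + net.offset[l];
    for (int m = 0; m < n_out; ++m)
      scale_weight(wl[j * n_out + m], z, ap.limited, net.wM);
  }
}

// total number of non-input neurons and the (layer, index) of each
struct NeuronIndex {
  std::vector<int> layer, idx;
  explicit NeuronIndex(const Net& net) {
    for (int l = 1; l < net.n_layers(); ++l)
      for (int j = 0; j < net.sizes[l]; ++j) {
        layer.push_back(l);
        idx.push_back(j);
      }
  }
  size_t size() const { return layer.size(); }
};

// run the k-instant window of one pattern; counters start fresh.
// If `trace` is non-null it receives the counter matrix (instants x neurons)
// and the per-instant output-layer vectors.
void pattern_window(Net& net, const double* x, const Astro& ap,
                    const NeuronIndex& ni, std::vector<double>& final_out,
                    IntegerMatrix* trace_r, NumericMatrix* trace_y) {
  const size_t N = ni.size();
  std::vector<int> r(N, 0), u_prev(N, 0);
  std::vector<bool> has_prev(N, false);
  std::vector<std::vector<double>> out;
  for (int t = 0; t < ap.k; ++t) {
    forward(net, x, out);
    for (size_t n = 0; n < N; ++n) {
      const double y = out[ni.layer[n]][ni.idx[n]];
      const int u = y > 0 ? 1 : -1;
      r[n] = counter_step(ap.algo, r[n], has_prev[n], u_prev[n], u, ap.mu);
      u_prev[n] = u;
      has_prev[n] = true;
      const double z = r[n] == ap.mu ? ap.a : (r[n] == -ap.mu ? -ap.b : 0.0);
      apply_to_attached(net, ni.layer[n], ni.idx[n], z, ap);
      if (trace_r) (*trace_r)(t, n) = r[n];
    }
    if (trace_y) {
      const std::vector<double>& yl = out.back();
      for (size_t j = 0; j < yl.size(); ++j) (*trace_y)(t, j) = yl[j];
    }
  }
  final_out = out.back();
}

// k passes of the global processing effect over the whole instance set;
// fills `outputs` with the final pass's outputs (row per instance)
void global_passes(Net& net, const NumericMatrix& X, const Astro& ap,
                   const NeuronIndex& ni, NumericMatrix& outputs) {
  const int n = X.nrow();
  const size_t N = ni.size();
  std::vector<double> xrow(X.ncol());
  std::vector<std::vector<double>> out;
  std::vector<int> s(N);
  for (int pass = 0; pass < ap.k; ++pass) {
    std::fill(s.begin(), s.end(), 0);
    for (int p = 0; p < n; ++p) {
      for (int c = 0; c < X.ncol(); ++c) xrow[c] = X(p, c);
      forward(net, xrow.data(), out);
      for (size_t q = 0; q < N; ++q)
        if (out[ni.layer[q]][ni.idx[q]] > 0) ++s[q];
      if (pass == ap.k - 1) {
        const std::vector<double>& yl = out.back();
        for (size_t j = 0; j < yl.size(); ++j) outputs(p, j) = yl[j];
      }
    }
    for (size_t q = 0; q < N; ++q) {
      // multiplicative rescale: w <- w * (n + sign(w) * s) / n
      const int layer = ni.layer[q], j = ni.idx[q];
      auto rescale = [&](double& w) {
        w *= (n + sgn(w) * s[q]) / static_cast<double>(n);
      };
      if (ap.attach == 0 || ap.attach == 2) {
        const int l = layer - 1;
        const int n_in = net.sizes[l], n_out = net.sizes[l + 1];
        double* wl = net.w.data() + net.offset[l];
        for (int i = 0; i < n_in; ++i) rescale(wl[i * n_out + j]);
      }
      if ((ap.attach == 1 || ap.attach == 2) && layer + 1 < net.n_layers()) {
        const int n_out = net.sizes[layer + 1];
        double* wl = net.w.data() + net.offset[layer];
        for (int m = 0; m < n_out; ++m) rescale(wl[j * n_out + m]);
      }
    }
  }
}

// the unsupervised phase over a dataset: independent per-pattern windows
// (each window starts from the entry weights; its modifications are
// transient), a global pass (weights persisting across its k passes), or
// plain forward when algo == -1
void run_phase(Net& net, const NumericMatrix& X, const Astro& ap,
               NumericMatrix& outputs) {
  const int n = X.nrow();
  std::vector<double> xrow(X.ncol());
  if (ap.algo == 5) {
    NeuronIndex ni(net);
    global_passes(net, X, ap, ni, outputs);
    return;
  }
  if (ap.algo < 0) {
    std::vector<std::vector<double>> out;
    for (int p = 0; p < n; ++p) {
      for (int c = 0; c < X.ncol(); ++c) xrow[c] = X(p, c);
      forward(net, xrow.data(), out);
      for (size_t j = 0; j < out.back().size(); ++j)
        outputs(p, j) = out.back()[j];
    }
    return;
  }
  NeuronIndex ni(net);
  std::vector<double> final_out;
  const std::vector<double> w0 = net.w;
  for (int p = 0; p < n; ++p) {
    net.w = w0;
    for (int c = 0; c < X.ncol(); ++c) xrow[c] = X(p, c);
    pattern_window(net, xrow.data(), ap, ni, final_out, nullptr, nullptr);
    for (size_t j = 0; j < final_out.size(); ++j) outputs(p, j) = final_out[j];
  }
  net.w = w0;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_forward_dataset(List net_packed, NumericMatrix X) {
  Net net = unpack_net(net_packed);
  NumericMatrix outputs(X.nrow(), net.sizes.back());
  Astro none{-1, 1, 1, 0.0, 0.0, false, 0};
  run_phase(net, X, none, outputs);
  return outputs;
}

// [[Rcpp::export]]
List cpp_process_pattern(List net_packed, NumericVector pattern,
                         List astro_packed, bool return_trace) {
  Net net = unpack_net(net_packed);
  Astro ap = unpack_astro(astro_packed);
  NeuronIndex ni(net);
  std::vector<double> final_out;
  List trace = R_NilValue;
  if (return_trace) {
    IntegerMatrix tr(ap.k, static_cast<int>(ni.size()));
    NumericMatrix ty(ap.k, net.sizes.back());
    pattern_window(net, REAL(pattern), ap, ni, final_out, &tr, &ty);
    trace = List::create(_["counters"] = tr, _["outputs"] = ty);
  } else {
    pattern_window(net, REAL(pattern), ap, ni, final_out, nullptr, nullptr);
  }
  return List::create(_["output"] = wrap(final_out),
                      _["weights"] = wrap(net.w), _["trace"] = trace);
}

// [[Rcpp::export]]
List cpp_phase(List net_packed, NumericMatrix X, List astro_packed) {
  Net net = unpack_net(net_packed);
  Astro ap = unpack_astro(astro_packed);
  NumericMatrix outputs(X.nrow(), net.sizes.back());
  run_phase(net, X, ap, outputs);
  return List::create(_["outputs"] = outputs, _["weights"] = wrap(net.w));
}

// [[Rcpp::export]]
IntegerVector cpp_counter_trace(IntegerVector fired, int algo, int mu) {
  const int k = fired.size();
  IntegerVector out(k);
  int r = 0, u_prev = 0;
  bool has_prev = false;
  for (int t = 0; t < k; ++t) {
    r = counter_step(algo, r, has_prev, u_prev, fired[t], mu);
    u_prev = fired[t];
    has_prev = true;
    out[t] = r;
  }
  return out;
}

// Fitness evaluation of a whole population: each row of `genes` is decoded
// into the weights of the template network, the unsupervised phase is run
// over the training set, and the MSE of the phase outputs against
// `targets` is returned (the astrocyte-modified weights are discarded).
// [[Rcpp::export]]
NumericVector cpp_eval_population(List net_packed, NumericMatrix genes,
                                  NumericMatrix X, NumericMatrix targets,
                                  List astro_packed) {
  Net net = unpack_net(net_packed);
  Astro ap = unpack_astro(astro_packed);
  const int P = genes.nrow(), L = genes.ncol();
  if (L != static_cast<int>(net.w.size()))
    stop("gene count does not match the network architecture");
  const int n = X.nrow(), n_out = net.sizes.back();
  if (targets.nrow() != n || targets.ncol() != n_out)
    stop("target matrix shape mismatch");
  NumericVector mse(P);
  NumericMatrix outputs(n, n_out);
  for (int p = 0; p < P; ++p) {
    for (int g = 0; g < L; ++g) net.w[g] = genes(p, g);
    run_phase(net, X, ap, outputs);
    double acc = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n_out; ++j) {
        const double d = outputs(i, j) - targets(i, j);
        acc += d * d;
      }
    mse[p] = acc / (static_cast<double>(n) * n_out);
  }
  return mse;
}
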