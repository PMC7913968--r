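// Tick-level simulation kernels: generic SCTN network engine, a specialized
// resonator kernel, the sigma-delta PDM codec, and the STDP-trained classifier
// neuron. All loops run at the pulse clock, so they live here rather than in R.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
using namespace Rcpp;

// --- seedable PRNG (xorshift64*), independent of R's RNG so that network
// simulations are reproducible from an explicit integer seed -----------------
struct XorShift {
  uint64_t s;
  explicit XorShift(double seed) {
    uint64_t z = (uint64_t)seed + 0x9E3779B97F4A7C15ULL;
    // splitmix64 scramble of the seed
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s = z ^ (z >> 31);
    if (s == 0) s = 0x106689D45497FDB5ULL;
  }
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { // uniform on [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Activation codes shared with the R side
enum { ACT_BINARY = 0, ACT_IDENTITY = 1, ACT_STOCHASTIC = 2 };

struct NeuronC {
  double alpha; int lp_eff;              // leak applied every lp_eff ticks
  double theta, phi, threshold, v_reset, vmin, vmax;
  int activation;
  bool legacy; double mu;                // Eq.-1 constant-leak mode
  std::vector<int> src;                  // <0: external input -(k+1); >=0 neuron id
  std::vector<double> w;
  std::vector<uint8_t> delayed;          // read previous-tick output (feedback edges)
  double vm, acc;                        // state
};

static inline int fire_step(NeuronC &n, XorShift &rng) {
  switch (n.activation) {
  case ACT_BINARY:
    if (n.vm >= n.threshold) { n.vm = n.v_reset; return 1; }
    return 0;
  case ACT_IDENTITY: {
    double tgt = (n.vm - n.vmin) / (n.vmax - n.vmin);
    tgt = clampd(tgt, 0.0, 1.0);
    n.acc += tgt;
    if (n.acc >= 1.0) { n.acc -= 1.0; return 1; }
    return 0;
  }
  default: { // stochastic sigmoid: compare against a fresh uniform draw
    double r = n.vmin + rng.unif() * (n.vmax - n.vmin);
    if (n.vm >= r) { n.vm = n.v_reset; return 1; }
    return 0;
  }
  }
}

static inline void membrane_step(NeuronC &n, double usum, long t) {
  if (n.legacy) {
    n.vm = n.vm + usum - n.mu;
  } else if (t % n.lp_eff == 0) {
    n.vm = n.alpha * (n.vm + usum + n.phi) + n.theta;
  } else {
    n.vm = n.vm + usum + n.phi + n.theta;
  }
  n.vm = clampd(n.vm, n.vmin, n.vmax);
}

static std::vector<NeuronC> parse_neurons(const List &neurons) {
  int nn = neurons.size();
  std::vector<NeuronC> out(nn);
  for (int i = 0; i < nn; ++i) {
    List nl = neurons[i];
    NeuronC &n = out[i];
    int lf = as<int>(nl["lf"]);
    int lp = as<int>(nl["lp"]);
    n.alpha = 1.0 - std::ldexp(1.0, -lf);
    n.lp_eff = lp < 1 ? 1 : lp;
    n.theta = as<double>(nl["theta"]);
    n.phi = as<double>(nl["phi"]);
    n.threshold = as<double>(nl["threshold"]);
    n.v_reset = as<double>(nl["v_reset"]);
    NumericVector b = nl["membrane_bounds"];
    n.vmin = b[0]; n.vmax = b[1];
    n.activation = as<int>(nl["activation_code"]);
    n.legacy = nl.containsElementNamed("legacy_mu") &&
      !Rf_isNull(nl["legacy_mu"]);
    n.mu = n.legacy ? as<double>(nl["legacy_mu"]) : 0.0;
    IntegerVector src = nl["src"];
    NumericVector w = nl["w"];
    LogicalVector d = nl["delayed"];
    n.src.assign(src.begin(), src.end());
    n.w.assign(w.begin(), w.end());
    n.delayed.resize(d.size());
    for (int k = 0; k < d.size(); ++k) n.delayed[k] = d[k] ? 1 : 0;
    n.vm = as<double>(nl["vm0"]);
    n.acc = 0.0;
  }
  return out;
}

// Generic network run. ext: n_ticks x n_ext binary inputs. record: 1-based
// neuron ids whose output trains (or binned counts) are returned.
// [[Rcpp::export]]
List run_network_cpp(List neurons, IntegerMatrix ext, IntegerVector record,
                     double seed, int bin_ticks, bool return_bits,
                     int trace_vm = 0) {
  std::vector<NeuronC> net = parse_neurons(neurons);
  int nn = net.size();
  long T = ext.nrow();
  XorShift rng(seed);
  std::vector<uint8_t> prev(nn, 0), cur(nn, 0);

  int nrec = record.size();
  IntegerMatrix bits;
  NumericMatrix counts;
  int nbins = 0;
  if (return_bits) bits = IntegerMatrix(T, nrec);
  if (bin_ticks > 0) {
    nbins = (int)((T + bin_ticks - 1) / bin_ticks);
    counts = NumericMatrix(nbins, nrec);
  }
  NumericVector vmtrace;
  if (trace_vm > 0) vmtrace = NumericVector(T);

  for (long t = 1; t <= T; ++t) {
    for (int i = 0; i < nn; ++i) {
      NeuronC &n = net[i];
      double u = 0.0;
      for (size_t k = 0; k < n.src.size(); ++k) {
        int s = n.src[k];
        int bit = (s < 0) ? ext(t - 1, -s - 1)
                          : (n.delayed[k] ? prev[s - 1] : cur[s - 1]);
        if (bit) u += n.w[k];
      }
      membrane_step(n, u, t);
      cur[i] = (uint8_t)fire_step(n, rng);
    }
    if (trace_vm > 0) vmtrace[t - 1] = net[trace_vm - 1].vm;
    for (int r = 0; r < nrec; ++r) {
      int b = cur[record[r] - 1];
      if (return_bits) bits(t - 1, r) = b;
      if (bin_ticks > 0 && b) counts((t - 1) / bin_ticks, r) += 1.0;
    }
    prev = cur;
  }

  NumericVector vm_final(nn);
  for (int i = 0; i < nn; ++i) vm_final[i] = net[i].vm;
  return List::create(
    _["bits"] = return_bits ? (SEXP)bits : R_NilValue,
    _["counts"] = bin_ticks > 0 ? (SEXP)counts : R_NilValue,
    _["vm"] = vm_final,
    _["vm_trace"] = trace_vm > 0 ? (SEXP)vmtrace : R_NilValue);
}

// Single-neuron run with a membrane trace, used by run_neuron().
// inputs: n_ticks x n_syn bits.
// [[Rcpp::export]]
List run_neuron_cpp(List neuron, IntegerMatrix inputs, double seed,
                    bool trace = false) {
  List wrap = List::create(neuron);
  int nsyn = inputs.ncol();
  // synapse k reads external input k
  IntegerVector src(nsyn);
  LogicalVector del(nsyn);
  for (int k = 0; k < nsyn; ++k) { src[k] = -(k + 1); del[k] = false; }
  List nl = clone(as<List>(neuron));
  nl["src"] = src; nl["delayed"] = del;
  List net = List::create(nl);
  return run_network_cpp(net, inputs, IntegerVector::create(1), seed, 0, true,
                         trace ? 1 : 0);
}

// --- specialized resonator kernel -------------------------------------------
// Fixed topology: 8 chained phase stages (identity activation), stage 1 also
// receives the negative feedback from stage 4 (previous tick); 4 binary
// blockers and 4 identity rectifiers on the tap stages; 1 integrate-and-fire
// output neuron summing the rectifiers.
struct ResoP {
  double alpha; int lp_eff;
  double w_stage, phi_stage, w_in, w_fb, phi1, V;
  double th_block, th_out, alpha_out;
  int taps[4];
};

static ResoP parse_reso(const List &p) {
  ResoP r;
  int lf = as<int>(p["lf"]);
  int lp = as<int>(p["lp"]);
  r.alpha = 1.0 - std::ldexp(1.0, -lf);
  r.lp_eff = lp < 1 ? 1 : lp;
  r.w_stage = as<double>(p["stage_gain"]);
  r.phi_stage = -r.w_stage / 2.0;
  r.w_in = as<double>(p["w_in"]);
  r.w_fb = as<double>(p["w_fb"]); // negative
  r.phi1 = -(r.w_in + r.w_fb) / 2.0;
  r.V = as<double>(p["v_bound"]);
  r.th_block = as<double>(p["blocker_threshold"]);
  r.th_out = as<double>(p["output_threshold"]);
  r.alpha_out = as<double>(p["alpha_out"]);
  IntegerVector tp = p["tap_stages"];
  for (int k = 0; k < 4; ++k) r.taps[k] = tp[k] - 1;
  return r;
}

// Simulates one resonator over the input bit train. Writes per-bin output
// spike counts into counts_col (length nbins) if bin_ticks > 0; optionally
// records the output train and the 8 stage trains.
static void reso_core(const ResoP &r, const IntegerVector &bits, int bin_ticks,
                      double *counts_col, int *out_bits, int *tap_bits,
                      long T) {
  double vm[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  double acc[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  double vb[4] = {0, 0, 0, 0};
  double vr[4] = {0, 0, 0, 0}, accr[4] = {0, 0, 0, 0};
  double vo = 0.0;
  uint8_t out_prev[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  uint8_t outb[8], rectb[4];
  double twoV = 2.0 * r.V;

  for (long t = 1; t <= T; ++t) {
    bool leak = (t % r.lp_eff) == 0;
    // phase-shift chain
    for (int i = 0; i < 8; ++i) {
      double u;
      if (i == 0) {
        u = (bits[t - 1] ? r.w_in : 0.0) +
            (out_prev[3] ? r.w_fb : 0.0) + r.phi1;
      } else {
        u = (outb[i - 1] ? r.w_stage : 0.0) + r.phi_stage;
      }
      double v = vm[i];
      v = leak ? r.alpha * (v + u) : (v + u);
      vm[i] = clampd(v, -r.V, r.V);
      double tgt = (vm[i] + r.V) / twoV;
      acc[i] += tgt;
      if (acc[i] >= 1.0) { acc[i] -= 1.0; outb[i] = 1; } else outb[i] = 0;
    }
    // blockers (binary, threshold above bipolar midpoint of their membrane)
    // and rectifiers (identity over [0, V]) on the tap stages
    double osum = 0.0;
    for (int k = 0; k < 4; ++k) {
      double u = (outb[r.taps[k]] ? r.w_stage : 0.0) + r.phi_stage;
      double v = vb[k];
      v = leak ? r.alpha * (v + u) : (v + u);
      vb[k] = clampd(v, -r.V, r.V);
      if (vb[k] >= r.th_block) vb[k] = 0.0; // fire + reset (output unused downstream)
      v = vr[k];
      v = leak ? r.alpha * (v + u) : (v + u);
      vr[k] = clampd(v, 0.0, r.V);
      double tgt = vr[k] / r.V;
      accr[k] += tgt;
      if (accr[k] >= 1.0) { accr[k] -= 1.0; rectb[k] = 1; } else rectb[k] = 0;
      if (rectb[k]) osum += 1.0;
    }
    // output neuron: near-lossless integrator with threshold/reset
    vo = r.alpha_out * (vo + osum);
    int ob = 0;
    if (vo >= r.th_out) { vo = 0.0; ob = 1; }
    if (bin_ticks > 0 && ob) counts_col[(t - 1) / bin_ticks] += 1.0;
    if (out_bits) out_bits[t - 1] = ob;
    if (tap_bits)
      for (int i = 0; i < 8; ++i) tap_bits[(t - 1) + T * i] = outb[i];
    for (int i = 0; i < 8; ++i) out_prev[i] = outb[i];
  }
}

// [[Rcpp::export]]
List resonator_sim_cpp(IntegerVector bits, List params, int bin_ticks,
                       bool return_bits, bool return_taps) {
  ResoP r = parse_reso(params);
  long T = bits.size();
  int nbins = bin_ticks > 0 ? (int)((T + bin_ticks - 1) / bin_ticks) : 0;
  NumericVector counts(nbins);
  IntegerVector outb;
  IntegerMatrix taps;
  if (return_bits) outb = IntegerVector(T);
  if (return_taps) taps = IntegerMatrix(T, 8);
  reso_core(r, bits, bin_ticks, nbins ? REAL(counts) : (double *)nullptr,
            return_bits ? INTEGER(outb) : (int *)nullptr,
            return_taps ? INTEGER(taps) : (int *)nullptr, T);
  return List::create(
    _["counts"] = bin_ticks > 0 ? (SEXP)counts : R_NilValue,
    _["bits"] = return_bits ? (SEXP)outb : R_NilValue,
    _["taps"] = return_taps ? (SEXP)taps : R_NilValue);
}

// Feature extraction over a whole bank: per-bin output spike counts, one
// column per resonator. Tick-outer / resonator-inner structure-of-arrays
// loop with branchless neuron updates, so a 200-resonator bank runs at a
// few ns per resonator-tick.
// [[Rcpp::export]]
NumericMatrix bank_extract_cpp(IntegerVector bits, List bank, int bin_ticks) {
  long T = bits.size();
  int nres = bank.size();
  int nbins = (int)((T + bin_ticks - 1) / bin_ticks);
  NumericMatrix counts(nbins, nres);
  std::vector<ResoP> rp(nres);
  for (int j = 0; j < nres; ++j) rp[j] = parse_reso(bank[j]);
  // all resonators share the fixed 17-neuron topology; per-resonator state
  // is laid out stage-major for the inner loops
  std::vector<double> vm(8 * nres, 0.0), acc(8 * nres, 0.0);
  std::vector<double> vb(4 * nres, 0.0), vr(4 * nres, 0.0),
      accr(4 * nres, 0.0);
  std::vector<double> vo(nres, 0.0);
  std::vector<uint8_t> outb(8 * nres, 0), outprev4(nres, 0);
  std::vector<int> leakctr(nres, 0);
  std::vector<double> mult(nres); // per-tick leak multiplier (alpha or 1)
  const int *bp = INTEGER(bits);
  double *cd = REAL(counts);

  for (long t = 1; t <= T; ++t) {
    double in = (double)bp[t - 1];
    long row = (t - 1) / bin_ticks;
    for (int j = 0; j < nres; ++j) {
      if (++leakctr[j] >= rp[j].lp_eff) {
        leakctr[j] = 0;
        mult[j] = rp[j].alpha;
      } else {
        mult[j] = 1.0;
      }
    }
    // stage 1 (input + delayed feedback), then stages 2..8
    for (int j = 0; j < nres; ++j) {
      const ResoP &r = rp[j];
      double u = in * r.w_in + (double)outprev4[j] * r.w_fb + r.phi1;
      double v = mult[j] * (vm[j] + u);
      v = clampd(v, -r.V, r.V);
      vm[j] = v;
      double a = acc[j] + (v + r.V) / (2.0 * r.V);
      uint8_t bit = a >= 1.0;
      acc[j] = a - (double)bit;
      outb[j] = bit;
    }
    for (int i = 1; i < 8; ++i) {
      double *vmi = &vm[i * nres];
      double *acci = &acc[i * nres];
      uint8_t *oi = &outb[i * nres];
      const uint8_t *prev = &outb[(i - 1) * nres];
      for (int j = 0; j < nres; ++j) {
        const ResoP &r = rp[j];
        double u = (double)prev[j] * r.w_stage + r.phi_stage;
        double v = mult[j] * (vmi[j] + u);
        v = clampd(v, -r.V, r.V);
        vmi[j] = v;
        double a = acci[j] + (v + r.V) / (2.0 * r.V);
        uint8_t bit = a >= 1.0;
        acci[j] = a - (double)bit;
        oi[j] = bit;
      }
    }
    for (int j = 0; j < nres; ++j) outprev4[j] = outb[3 * nres + j];
    // blockers + rectifiers on the taps, then the output integrator
    for (int k = 0; k < 4; ++k) {
      double *vbk = &vb[k * nres];
      double *vrk = &vr[k * nres];
      double *ak = &accr[k * nres];
      for (int j = 0; j < nres; ++j) {
        const ResoP &r = rp[j];
        double u = (double)outb[r.taps[k] * nres + j] * r.w_stage +
                   r.phi_stage;
        double v = mult[j] * (vbk[j] + u);
        v = clampd(v, -r.V, r.V);
        vbk[j] = (v >= r.th_block) ? 0.0 : v; // binary fire + reset
        v = mult[j] * (vrk[j] + u);
        v = clampd(v, 0.0, r.V);
        vrk[j] = v;
        double a = ak[j] + v / r.V;
        uint8_t bit = a >= 1.0;
        ak[j] = a - (double)bit;
        vo[j] += (double)bit; // accumulate rectifier spikes pre-leak
      }
    }
    for (int j = 0; j < nres; ++j) {
      double v = rp[j].alpha_out * vo[j];
      uint8_t ob = v >= rp[j].th_out;
      vo[j] = ob ? 0.0 : v;
      cd[row + (long)j * nbins] += (double)ob;
    }
  }
  return counts;
}

// --- PDM codec ---------------------------------------------------------------
// First-order sigma-delta: density target (x+1)/2, error-feedback accumulator.
// [[Rcpp::export]]
IntegerVector pdm_encode_cpp(NumericVector x, double in_rate, double clock) {
  long n = x.size();
  long T = (long)std::llround((double)n / in_rate * clock);
  IntegerVector bits(T);
  double acc = 0.0;
  double step = in_rate / clock;
  for (long t = 0; t < T; ++t) {
    // the error-feedback quantiser emits bit t as soon as tick t's input is
    // accumulated, so bit t carries the signal at time t / clock exactly;
    // sample i sits at time i / rate
    double pos = (double)t * step;
    long i0 = (long)std::floor(pos);
    double frac = pos - i0;
    long j0 = i0 < 0 ? 0 : (i0 >= n ? n - 1 : i0); // edge-replicating
    long j1 = i0 + 1 < 0 ? 0 : (i0 + 1 >= n ? n - 1 : i0 + 1);
    double xi = x[j0] + frac * (x[j1] - x[j0]);
    double d = clampd((xi + 1.0) / 2.0, 0.0, 1.0);
    acc += d;
    if (acc >= 1.0) { acc -= 1.0; bits[t] = 1; }
  }
  return bits;
}

// Decimating FIR low-pass of a bit train, rescaled to bipolar [-1, 1].
// Symmetric taps centered on each output sample: zero phase delay.
// [[Rcpp::export]]
NumericVector fir_decimate_cpp(IntegerVector bits, NumericVector taps,
                               double clock, double out_rate) {
  long T = bits.size();
  int L = taps.size();
  int half = L / 2;
  long M = (long)std::floor((double)T / clock * out_rate);
  NumericVector y(M);
  for (long m = 0; m < M; ++m) {
    // output sample m corresponds to time m / out_rate on a grid starting
    // at zero (the encoder's bit t is centred at (t + 0.5) / clock), so
    // decoded waveforms line up with the original sample grid
    long c = (long)std::llround((double)m / out_rate * clock);
    double s = 0.0, wsum = 0.0;
    long lo = c - half;
    for (int k = 0; k < L; ++k) {
      long idx = lo + k;
      if (idx < 0 || idx >= T) continue;
      wsum += taps[k];
      if (bits[idx]) s += taps[k];
    }
    y[m] = wsum > 0 ? 2.0 * (s / wsum) - 1.0 : 0.0;
  }
  return y;
}

// --- STDP-trained classifier neuron ------------------------------------------
// One binary-activation SCTN driven by rate-coded feature densities; the
// event-matrix registers (2*Lw+1 bits/synapse) and the delayed postsynaptic
// spike implement the windowed B-kernel update.
// samples: list of nbins x nsyn density matrices in [0, 1].
// [[Rcpp::export]]
List stdp_train_cpp(List samples, NumericVector w0, List neuron,
                    NumericVector bkernel, int lw, double wmin, double wmax,
                    int epochs, int ticks_per_bin, bool learn) {
  int nsyn = w0.size();
  int nsamp = samples.size();
  if (lw > 31) stop("lw must be <= 31 for the register implementation");
  int regbits = 2 * lw + 1;
  uint64_t regmask = (regbits >= 64) ? ~0ULL : ((1ULL << regbits) - 1ULL);
  uint32_t postmask = (1U << (lw + 1)) - 1U;

  int lf = as<int>(neuron["lf"]);
  int lp = as<int>(neuron["lp"]);
  double alpha = 1.0 - std::ldexp(1.0, -lf);
  int lp_eff = lp < 1 ? 1 : lp;
  double theta = as<double>(neuron["theta"]);
  double phi = as<double>(neuron["phi"]);
  double threshold = as<double>(neuron["threshold"]);
  double v_reset = as<double>(neuron["v_reset"]);
  NumericVector b = neuron["membrane_bounds"];
  double vmin = b[0], vmax = b[1];

  std::vector<double> w(w0.begin(), w0.end());
  NumericMatrix spikes(epochs, nsamp);
  std::vector<uint64_t> reg(nsyn);
  std::vector<double> enc(nsyn);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int si = 0; si < nsamp; ++si) {
      NumericMatrix f = samples[si];
      int nbins = f.nrow();
      if (f.ncol() != nsyn) stop("feature column count != synapse count");
      double vm = 0.0;
      uint32_t postreg = 0;
      std::fill(reg.begin(), reg.end(), 0ULL);
      std::fill(enc.begin(), enc.end(), 0.0);
      long T = (long)nbins * ticks_per_bin;
      int nsp = 0;
      for (long t = 1; t <= T; ++t) {
        int bin = (int)((t - 1) / ticks_per_bin);
        double u = 0.0;
        for (int j = 0; j < nsyn; ++j) {
          enc[j] += f(bin, j);
          uint64_t bit = 0;
          if (enc[j] >= 1.0) { enc[j] -= 1.0; bit = 1; }
          reg[j] = ((reg[j] << 1) | bit) & regmask;
          if (bit) u += w[j];
        }
        if (t % lp_eff == 0) vm = alpha * (vm + u + phi) + theta;
        else vm = vm + u + phi + theta;
        vm = clampd(vm, vmin, vmax);
        int post = 0;
        if (vm >= threshold) { vm = v_reset; post = 1; ++nsp; }
        postreg = ((postreg << 1) | (uint32_t)post) & postmask;
        if (learn && ((postreg >> lw) & 1U)) {
          for (int j = 0; j < nsyn; ++j) {
            uint64_t rj = reg[j];
            if (!rj) continue;
            double dw = 0.0;
            for (int p = 0; p < regbits; ++p)
              if ((rj >> p) & 1ULL) dw += bkernel[p];
            w[j] = clampd(w[j] + dw, wmin, wmax);
          }
        }
      }
      spikes(ep, si) = nsp;
    }
  }
  return List::create(_["weights"] = NumericVector(w.begin(), w.end()),
                      _["epoch_spikes"] = spikes);
}
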