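// Core integrators: single neuron, neuron populations, feedforward network,
// and the two-variable (V,U) reduction.  First-order Euler throughout, per the
// reference numerical scheme; gating updates use the pre-step state.
#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// kinetics

struct RateFn {
  double A;   // ms^-1 mV^-1
  double vh;  // mV
  double k;   // mV
  bool up;    // linoid rising with v, else mirrored
  double operator()(double v) const {
    double x = up ? (v - vh) : (vh - v);
    if (std::fabs(x) < 1e-9) return A * k;  // removable singularity
    return A * x / (1.0 - std::exp(-x / k));
  }
};

struct Kinetics {
  RateFn am, bm, ah, bh, an, bn;
  double h_vh, h_k;  // dedicated steady-state sigmoid for h
  double minf(double v) const { double a = am(v), b = bm(v); return a / (a + b); }
  double taum(double v) const { return 1.0 / (am(v) + bm(v)); }
  double hinf(double v) const { return 1.0 / (1.0 + std::exp((v - h_vh) / h_k)); }
  double tauh(double v) const { return 1.0 / (ah(v) + bh(v)); }
  double ninf(double v) const { double a = an(v), b = bn(v); return a / (a + b); }
  double taun(double v) const { return 1.0 / (an(v) + bn(v)); }
};

// tabulated gate functions on a fine voltage grid (linear interpolation);
// direct evaluation outside the table.  Pure speed optimization: the exp()
// calls in the rate functions dominate the step cost otherwise.
struct GateTables {
  static constexpr double v_lo = -130.0, v_hi = 80.0, dv = 0.01;
  int n = 0;
  std::vector<double> minf_, taum_, hinf_, tauh_, ninf_, taun_;
  const Kinetics* kin = nullptr;
  void build(const Kinetics& K) {
    kin = &K;
    n = (int)std::round((v_hi - v_lo) / dv) + 1;
    minf_.resize(n); taum_.resize(n); hinf_.resize(n);
    tauh_.resize(n); ninf_.resize(n); taun_.resize(n);
    for (int i = 0; i < n; ++i) {
      double v = v_lo + i * dv;
      minf_[i] = K.minf(v); taum_[i] = K.taum(v);
      hinf_[i] = K.hinf(v); tauh_[i] = K.tauh(v);
      ninf_[i] = K.ninf(v); taun_[i] = K.taun(v);
    }
  }
  inline void lookup(double v, double& mi, double& tm, double& hi, double& th,
                     double& ni, double& tn) const {
    if (v <= v_lo || v >= v_hi) {
      mi = kin->minf(v); tm = kin->taum(v); hi = kin->hinf(v);
      th = kin->tauh(v); ni = kin->ninf(v); tn = kin->taun(v);
      return;
    }
    double x = (v - v_lo) / dv;
    int i = (int)x;
    double f = x - i;
    mi = minf_[i] + f * (minf_[i + 1] - minf_[i]);
    tm = taum_[i] + f * (taum_[i + 1] - taum_[i]);
    hi = hinf_[i] + f * (hinf_[i + 1] - hinf_[i]);
    th = tauh_[i] + f * (tauh_[i + 1] - tauh_[i]);
    ni = ninf_[i] + f * (ninf_[i + 1] - ninf_[i]);
    tn = taun_[i] + f * (taun_[i + 1] - taun_[i]);
  }
};

struct Membrane {
  double cm;                       // uF/cm^2
  double gna, gk, gl;              // mS/cm^2
  double ena, ek, el;              // mV
  double to_dens;                  // pA -> uA/cm^2
  Kinetics kin;
  GateTables tab;
};

static RateFn parse_rate(List r) {
  RateFn f;
  f.A = as<double>(r["amplitude"]) / 1000.0;  // s^-1 mV^-1 -> ms^-1 mV^-1
  f.vh = as<double>(r["v_half"]);
  f.k = as<double>(r["k"]);
  f.up = as<std::string>(r["form"]) == "linoid_up";
  return f;
}

static Membrane parse_params(List p) {
  Membrane M;
  M.cm = as<double>(p["c_m"]);
  M.gna = as<double>(p["g_na"]) * 0.1;   // pS/um^2 -> mS/cm^2
  M.gk = as<double>(p["g_k"]) * 0.1;
  M.gl = as<double>(p["g_leak"]) * 0.1;
  M.ena = as<double>(p["e_na"]);
  M.ek = as<double>(p["e_k"]);
  M.el = as<double>(p["e_leak"]);
  double area_um2 = as<double>(p["area"]);          // um^2 (precomputed in R)
  M.to_dens = 1e-6 / (area_um2 * 1e-8);             // pA -> uA/cm^2
  List kin = p["kinetics"];
  List m = kin["m"], h = kin["h"], n = kin["n"];
  M.kin.am = parse_rate(m["alpha"]); M.kin.bm = parse_rate(m["beta"]);
  M.kin.ah = parse_rate(h["alpha"]); M.kin.bh = parse_rate(h["beta"]);
  M.kin.an = parse_rate(n["alpha"]); M.kin.bn = parse_rate(n["beta"]);
  List ss = h["steady_state"];
  M.kin.h_vh = as<double>(ss["v_half"]);
  M.kin.h_k = as<double>(ss["k"]);
  M.tab.build(M.kin);
  return M;
}

// splitmix64: derive decorrelated per-stream seeds from one master seed
static inline uint64_t splitmix64(uint64_t& x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline void hh_step(const Membrane& M, double Idens, double dt,
                           double& v, double& m, double& h, double& n) {
  double dv = (-M.gl * (v - M.el) - M.gna * m * m * m * h * (v - M.ena)
               - M.gk * n * (v - M.ek) + Idens) / M.cm;
  double mi, tm, hi, th, ni, tn;
  M.tab.lookup(v, mi, tm, hi, th, ni, tn);
  m += dt * (mi - m) / tm;
  h += dt * (hi - h) / th;
  n += dt * (ni - n) / tn;
  v += dt * dv;
}

static void check_state(double v, int step, const char* where) {
  if (!std::isfinite(v) || std::fabs(v) > 500.0)
    stop("numerical-instability in %s at time index %d (V = %g)", where, step + 1, v);
}

// ---------------------------------------------------------------------------
// single-neuron integration of a supplied current trace (deterministic)

// [[Rcpp::export]]
List cpp_integrate(List params, NumericVector current_pA, double dt,
                   NumericVector init, double threshold, double refractory) {
  Membrane M = parse_params(params);
  int nst = current_pA.size();
  NumericVector v(nst), m(nst), h(nst), n(nst);
  double vv = init[0], mm = init[1], hh = init[2], nn = init[3];
  std::vector<double> spikes;
  bool above = vv >= threshold;
  double last_sp = -1e18;
  for (int t = 0; t < nst; ++t) {
    double Id = current_pA[t] * M.to_dens;
    hh_step(M, Id, dt, vv, mm, hh, nn);
    check_state(vv, t, "integrate");
    v[t] = vv; m[t] = mm; h[t] = hh; n[t] = nn;
    bool ab = vv >= threshold;
    if (ab && !above && (t * dt - last_sp) >= refractory) {
      spikes.push_back(t * dt);
      last_sp = t * dt;
    }
    above = ab;
  }
  return List::create(_["v"] = v, _["m"] = m, _["h"] = h, _["n"] = n,
                      _["spikes"] = wrap(spikes));
}

// ---------------------------------------------------------------------------
// population of independent neurons: shared current trace + per-neuron OU noise

// [[Rcpp::export]]
List cpp_population(List params, NumericVector common_pA, double dc,
                    double sigma, double tau_ou, int n_neurons, double dt,
                    double duration_ms, int seed, double threshold,
                    double refractory, double burn_ms) {
  Membrane M = parse_params(params);
  int nst = (int)std::round(duration_ms / dt);
  bool have_common = common_pA.size() > 1;
  if (have_common && common_pA.size() < nst)
    stop("common current trace shorter than duration");
  double rho = (sigma > 0) ? std::exp(-dt / tau_ou) : 0.0;
  double sq = sigma * std::sqrt(1.0 - rho * rho);
  uint64_t master = (uint64_t)seed;

  List spikes(n_neurons);
  NumericVector rate(n_neurons), sub_mean(n_neurons), sub_sd(n_neurons);
  int burn_steps = (int)std::round(burn_ms / dt);

  for (int i = 0; i < n_neurons; ++i) {
    uint64_t s0 = master;
    for (int j = 0; j <= i; ++j) splitmix64(s0);
    std::mt19937_64 rng(s0);
    std::normal_distribution<double> gauss(0.0, 1.0);
    double vv = M.el, mm = M.kin.minf(vv), hh = M.kin.hinf(vv), nn = M.kin.ninf(vv);
    double ou = (sigma > 0) ? sigma * gauss(rng) : 0.0;
    bool above = false;
    double last_sp = -1e18;
    std::vector<double> sp;
    double s1 = 0, s2 = 0; long ns = 0;
    int count_after_burn = 0;
    for (int t = 0; t < nst; ++t) {
      double I = dc + ou + (have_common ? common_pA[t] : 0.0);
      hh_step(M, I * M.to_dens, dt, vv, mm, hh, nn);
      check_state(vv, t, "population");
      bool ab = vv >= threshold;
      if (ab && !above && (t * dt - last_sp) >= refractory) {
        sp.push_back(t * dt);
        last_sp = t * dt;
        if (t >= burn_steps) ++count_after_burn;
      }
      above = ab;
      if (t >= burn_steps && vv < threshold) { s1 += vv; s2 += vv * vv; ++ns; }
      if (sigma > 0) ou = ou * rho + sq * gauss(rng);
    }
    spikes[i] = wrap(sp);
    rate[i] = count_after_burn / ((duration_ms - burn_ms) / 1000.0);
    sub_mean[i] = ns > 0 ? s1 / ns : NA_REAL;
    sub_sd[i] = ns > 1 ? std::sqrt(std::max(0.0, s2 / ns - (s1 / ns) * (s1 / ns))) : NA_REAL;
  }
  return List::create(_["spikes"] = spikes, _["rate"] = rate,
                      _["sub_mean"] = sub_mean, _["sub_sd"] = sub_sd);
}

// ---------------------------------------------------------------------------
// f-I surface: one independent OU-driven run per (dc, sigma) cell

// [[Rcpp::export]]
List cpp_fi(List params, NumericVector dc_grid, NumericVector sigma_grid,
            double duration_ms, double dt, double burn_ms, int seed,
            double tau_ou, double threshold, double refractory) {
  Membrane M = parse_params(params);
  int nd = dc_grid.size(), ns_ = sigma_grid.size();
  int nst = (int)std::round(duration_ms / dt);
  int burn_steps = (int)std::round(burn_ms / dt);
  NumericMatrix rates(nd, ns_), counts(nd, ns_);
  uint64_t master = (uint64_t)seed;
  uint64_t ctr = master;
  for (int js = 0; js < ns_; ++js) {
    for (int jd = 0; jd < nd; ++jd) {
      uint64_t s0 = splitmix64(ctr);
      std::mt19937_64 rng(s0);
      std::normal_distribution<double> gauss(0.0, 1.0);
      double sigma = sigma_grid[js], dc = dc_grid[jd];
      double rho = (sigma > 0) ? std::exp(-dt / tau_ou) : 0.0;
      double sq = sigma * std::sqrt(1.0 - rho * rho);
      double vv = M.el, mm = M.kin.minf(vv), hh = M.kin.hinf(vv), nn = M.kin.ninf(vv);
      double ou = (sigma > 0) ? sigma * gauss(rng) : 0.0;
      bool above = false;
      double last_sp = -1e18;
      long count = 0;
      for (int t = 0; t < nst; ++t) {
        hh_step(M, (dc + ou) * M.to_dens, dt, vv, mm, hh, nn);
        check_state(vv, t, "fi_surface");
        bool ab = vv >= threshold;
        if (ab && !above && (t * dt - last_sp) >= refractory) {
          if (t >= burn_steps) ++count;
          last_sp = t * dt;
        }
        above = ab;
        if (sigma > 0) ou = ou * rho + sq * gauss(rng);
      }
      rates(jd, js) = count / ((duration_ms - burn_ms) / 1000.0);
      counts(jd, js) = (double)count;
    }
  }
  return List::create(_["rates"] = rates, _["counts"] = counts);
}

// ---------------------------------------------------------------------------
// feedforward network with exponential conductance synapses
//
// conn: list over layers 2..L; conn[[l]] is a list over postsynaptic neurons,
// each an integer vector of presynaptic indices (1-based) in layer l-1.
// Spikes are delivered with a one-step delay.

// [[Rcpp::export]]
List cpp_network(List params, List conn, int n_layers, int n_per_layer,
                 NumericVector layer1_pA, double noise_sigma, double tau_ou,
                 double w, double tau_syn, double e_ex, double dt,
                 double duration_ms, int seed, double threshold,
                 double refractory, double burn_ms, bool keep_spikes,
                 bool record_gsyn) {
  Membrane M = parse_params(params);
  int nst = (int)std::round(duration_ms / dt);
  if (layer1_pA.size() < nst) stop("layer-1 input trace shorter than duration");
  int burn_steps = (int)std::round(burn_ms / dt);
  double rho = (noise_sigma > 0) ? std::exp(-dt / tau_ou) : 0.0;
  double sq = noise_sigma * std::sqrt(1.0 - rho * rho);
  double decay = std::exp(-dt / tau_syn);
  double gsyn_scale = 0.1;  // pS/um^2 -> mS/cm^2

  List out_spikes(n_layers);
  NumericVector mean_rate(n_layers), isyn_mean(n_layers), isyn_sd(n_layers),
      ev_mean(n_layers), subv_sd(n_layers);
  NumericMatrix rates(n_layers, n_per_layer);
  NumericMatrix gsyn0(record_gsyn ? nst : 1, record_gsyn ? n_layers : 1);

  // spike step indices of the previous layer, per neuron
  std::vector<std::vector<int>> prev_steps;
  uint64_t master = (uint64_t)seed;
  double dur_s = (duration_ms - burn_ms) / 1000.0;

  for (int L = 0; L < n_layers; ++L) {
    List cl;
    if (L > 0) {
      cl = as<List>(conn[L - 1]);
      if (cl.size() != n_per_layer) stop("connectivity size mismatch at layer %d", L + 1);
    }
    std::vector<std::vector<int>> steps(n_per_layer);
    double is1 = 0, is2 = 0; long isn = 0;
    double evs = 0, vs1 = 0, vs2 = 0; long vn = 0;
    long nsp_after = 0;

    for (int i = 0; i < n_per_layer; ++i) {
      // merged presynaptic spike steps for this neuron
      std::vector<int> ev;
      if (L > 0) {
        IntegerVector pre = cl[i];
        size_t tot = 0;
        for (int k = 0; k < pre.size(); ++k) {
          int p = pre[k] - 1;
          if (p < 0 || p >= n_per_layer) stop("invalid presynaptic index");
          tot += prev_steps[p].size();
        }
        ev.reserve(tot);
        for (int k = 0; k < pre.size(); ++k)
          ev.insert(ev.end(), prev_steps[pre[k] - 1].begin(),
                    prev_steps[pre[k] - 1].end());
        std::sort(ev.begin(), ev.end());
      }
      uint64_t s0 = master ^ (0x100000001ULL * (uint64_t)(L * n_per_layer + i + 1));
      splitmix64(s0);
      uint64_t mixed = s0;
      std::mt19937_64 rng(splitmix64(mixed));
      std::normal_distribution<double> gauss(0.0, 1.0);
      double v = M.el, m = M.kin.minf(v), h = M.kin.hinf(v), n = M.kin.ninf(v);
      double ou = (noise_sigma > 0) ? noise_sigma * gauss(rng) : 0.0;
      double gs = 0.0, last_sp = -1e18;
      bool above = false;
      size_t kev = 0;
      for (int t = 0; t < nst; ++t) {
        double Idens;
        if (L == 0) {
          Idens = (layer1_pA[t] + ou) * M.to_dens;
        } else {
          // spikes of the previous layer at step t-1 arrive now (one-step
          // delay); the increment shares this step's decay
          while (kev < ev.size() && ev[kev] == t - 1) { gs += w; ++kev; }
          gs *= decay;
          if (record_gsyn && i == 0) gsyn0(t, L) = gs;
          double isyn_dens = gs * gsyn_scale * (e_ex - v);  // uA/cm^2
          Idens = isyn_dens + ou * M.to_dens;
          if (t >= burn_steps) {
            double isyn_pA = isyn_dens / M.to_dens;
            is1 += isyn_pA; is2 += isyn_pA * isyn_pA; ++isn;
          }
        }
        hh_step(M, Idens, dt, v, m, h, n);
        if (!std::isfinite(v) || std::fabs(v) > 500.0)
          stop("numerical-instability at layer %d neuron %d time index %d",
               L + 1, i + 1, t + 1);
        bool ab = v >= threshold;
        if (ab && !above && (t * dt - last_sp) >= refractory) {
          steps[i].push_back(t);
          last_sp = t * dt;
          if (t >= burn_steps) ++nsp_after;
        }
        above = ab;
        if (t >= burn_steps && v < threshold) {
          evs += (e_ex - v); vs1 += v; vs2 += v * v; ++vn;
        }
        if (noise_sigma > 0) ou = ou * rho + sq * gauss(rng);
      }
      long c = 0;
      for (int st : steps[i]) if (st >= burn_steps) ++c;
      rates(L, i) = c / dur_s;
    }

    if (keep_spikes) {
      List lsp(n_per_layer);
      for (int i = 0; i < n_per_layer; ++i) {
        NumericVector tv(steps[i].size());
        for (size_t k = 0; k < steps[i].size(); ++k) tv[k] = steps[i][k] * dt;
        lsp[i] = tv;
      }
      out_spikes[L] = lsp;
    }
    mean_rate[L] = nsp_after / (dur_s * n_per_layer);
    isyn_mean[L] = isn > 0 ? is1 / isn : 0.0;
    isyn_sd[L] = isn > 1 ? std::sqrt(std::max(0.0, is2 / isn - (is1 / isn) * (is1 / isn))) : 0.0;
    ev_mean[L] = vn > 0 ? evs / vn : NA_REAL;
    subv_sd[L] = vn > 1 ? std::sqrt(std::max(0.0, vs2 / vn - (vs1 / vn) * (vs1 / vn))) : NA_REAL;
    prev_steps = std::move(steps);
  }

  return List::create(_["spikes"] = out_spikes, _["mean_rate"] = mean_rate,
                      _["rates"] = rates, _["isyn_mean"] = isyn_mean,
                      _["isyn_sd"] = isyn_sd, _["ev_mean"] = ev_mean,
                      _["subv_sd"] = subv_sd,
                      _["gsyn"] = record_gsyn ? gsyn0 : NumericMatrix(0, 0));
}

// ---------------------------------------------------------------------------
// two-variable (V, U) reduction: m instantaneous at m_inf(V); h, n read out at
// the auxiliary voltage U whose drift matches the slow-gate-induced dV/dt.

struct Reduced {
  Membrane M;
  double fV(double V, double U, double Idens) const {
    const Kinetics& K = M.kin;
    double mi = K.minf(V);
    return (-M.gl * (V - M.el) - M.gna * mi * mi * mi * K.hinf(U) * (V - M.ena)
            - M.gk * K.ninf(U) * (V - M.ek) + Idens) / M.cm;
  }
  double gU(double V, double U) const {
    const Kinetics& K = M.kin;
    double mi = K.minf(V);
    double Fh = -M.gna * mi * mi * mi * (V - M.ena);
    double Fn = -M.gk * (V - M.ek);
    const double d = 1e-5;
    double hp = (K.hinf(U + d) - K.hinf(U - d)) / (2 * d);
    double np = (K.ninf(U + d) - K.ninf(U - d)) / (2 * d);
    double num = Fh * (K.hinf(V) - K.hinf(U)) / K.tauh(V)
               + Fn * (K.ninf(V) - K.ninf(U)) / K.taun(V);
    double den = Fh * hp + Fn * np;
    // the construction is singular where the slow gates lose their grip on
    // dV/dt (den -> 0, far outside the physiological range); bound |den| to
    // keep the Euler step finite there
    if (std::fabs(den) < 1e-4) den = (den < 0 ? -1e-4 : 1e-4);
    return num / den;
  }
};

// [[Rcpp::export]]
NumericVector cpp_reduced_rhs(List params, double v, double u, double i_pA) {
  Reduced R{parse_params(params)};
  double Id = i_pA * R.M.to_dens;
  return NumericVector::create(R.fV(v, u, Id), R.gU(v, u));
}

// [[Rcpp::export]]
List cpp_integrate_reduced(List params, NumericVector current_pA, double dt,
                           double v0, double u0, double threshold,
                           double refractory) {
  Reduced R{parse_params(params)};
  int nst = current_pA.size();
  NumericVector v(nst), u(nst);
  double vv = v0, uu = u0;
  std::vector<double> spikes;
  bool above = vv >= threshold;
  double last_sp = -1e18;
  for (int t = 0; t < nst; ++t) {
    double Id = current_pA[t] * R.M.to_dens;
    // the reduction is stiff during the spike upstroke (U relaxes toward V
    // on a sub-dt timescale); take Euler substeps bounded to ~1 mV of state
    // change so the scheme stays stable without altering subthreshold steps
    double remaining = dt;
    while (remaining > 1e-12) {
      double dv = R.fV(vv, uu, Id);
      double du = R.gU(vv, uu);
      double rate = std::max(std::fabs(dv), std::fabs(du));
      double h = remaining;
      if (rate * h > 1.0) h = 1.0 / rate;
      if (h < dt / 4096.0) h = dt / 4096.0;
      if (h > remaining) h = remaining;
      vv += h * dv;
      uu += h * du;
      remaining -= h;
    }
    check_state(vv, t, "reduced");
    v[t] = vv; u[t] = uu;
    bool ab = vv >= threshold;
    if (ab && !above && (t * dt - last_sp) >= refractory) {
      spikes.push_back(t * dt);
      last_sp = t * dt;
    }
    above = ab;
  }
  return List::create(_["v"] = v, _["u"] = u, _["spikes"] = wrap(spikes));
}
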