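// Clock-driven simulation engine: AdEx neurons, conductance synapses,
// Tsodyks-Markram short-term plasticity, spike-based BCPNN and
// multiplicative STDP on the associative pathway.
//
// Conventions:
//  - time in ms, conductance nS, current pA, capacitance pF, voltage mV
//  - synaptic current I_syn = sum g*(V - E) enters the membrane equation
//    with a minus sign (depolarising when V < E)
//  - at most one spike per neuron per step (tau_ref >> dt)
//  - delivery on a presynaptic spike uses w * u+ * x- (u after its jump,
//    x before depletion)

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

namespace {

// -- deterministic RNG (xoshiro256+ seeded by splitmix64) --------------------
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return (static_cast<double>(next() >> 11) + 0.5) * 1.1102230246251565e-16;
  }
  // steps until next event of a per-step Bernoulli(p) process (>= 1)
  inline int geom_skip(double p) {
    if (p <= 0.0) return std::numeric_limits<int>::max();
    if (p >= 1.0) return 1;
    double u = unif();
    double k = std::floor(std::log(u) / std::log1p(-p));
    if (k > 2e9) return std::numeric_limits<int>::max();
    return 1 + static_cast<int>(k);
  }
};

struct NeuronPars {
  double C, gL, EL, DeltaT, Vt, Vr, b, tau_w, tau_ref;
};

NeuronPars as_pars(const NumericVector& v) {
  NeuronPars p;
  p.C = v["C_m"]; p.gL = v["g_L"]; p.EL = v["E_L"];
  p.DeltaT = v["Delta_T"]; p.Vt = v["V_t"]; p.Vr = v["V_r"];
  p.b = v["b"]; p.tau_w = v["tau_Iw"]; p.tau_ref = v["tau_ref"];
  return p;
}

const double NEG_INF = -std::numeric_limits<double>::infinity();

}  // namespace

// [[Rcpp::export(name = ".engine_simulate")]]
List engine_simulate(int n_steps, double dt,
                     IntegerVector neuron_group,     // 0 pyr, 1 basket
                     NumericVector params_pyr, NumericVector params_basket,
                     NumericVector receptor,          // named tau/E per receptor
                     List syn,                        // pre, post, delay, kind, stp, wA, wN, wG
                     NumericVector stp_par,           // U, tau_A, tau_D, augmentation
                     int rule,                        // 0 none, 1 bcpnn, 2 stdp
                     NumericVector bcpnn_par,
                     NumericVector stdp_par,
                     double kappa_default,
                     List kappa_epochs,
                     List noise,                      // t_start, rate_pyr, rate_basket, g_exc, g_inh
                     List stim_epochs,
                     List current_epochs,
                     List record,
                     List init_state,
                     double seed) {
  const NeuronPars PP = as_pars(params_pyr);
  const NeuronPars PB = as_pars(params_basket);
  const int n = neuron_group.size();

  const double tau_a = receptor["tau_AMPA"], tau_nm = receptor["tau_NMDA"],
               tau_g = receptor["tau_GABA"];
  const double E_a = receptor["E_AMPA"], E_nm = receptor["E_NMDA"],
               E_g = receptor["E_GABA"];
  const double dec_a = std::exp(-dt / tau_a), dec_n = std::exp(-dt / tau_nm),
               dec_g = std::exp(-dt / tau_g);

  // ---- synapses -------------------------------------------------------------
  IntegerVector s_pre = syn["pre"], s_post = syn["post"],
                s_delay = syn["delay"], s_kind = syn["kind"],
                s_stp = syn["stp"];
  NumericVector s_wA = syn["wA"], s_wN = syn["wN"], s_wG = syn["wG"];
  const int ns = s_pre.size();

  // outgoing CSR
  std::vector<int> out_off(n + 1, 0), out_idx(ns);
  for (int s = 0; s < ns; ++s) out_off[s_pre[s] + 1]++;
  for (int i = 0; i < n; ++i) out_off[i + 1] += out_off[i];
  {
    std::vector<int> cur(out_off.begin(), out_off.end() - 1);
    for (int s = 0; s < ns; ++s) out_idx[cur[s_pre[s]]++] = s;
  }

  // compact indices for plastic and stp state
  std::vector<int> pidx(ns, -1), sidx(ns, -1);
  int np = 0, nstp = 0;
  for (int s = 0; s < ns; ++s) {
    if (s_kind[s] == 2) pidx[s] = np++;
    if (s_stp[s]) sidx[s] = nstp++;
  }
  std::vector<int> ppre(np), ppost(np), psyn(np);
  for (int s = 0; s < ns; ++s)
    if (pidx[s] >= 0) {
      ppre[pidx[s]] = s_pre[s]; ppost[pidx[s]] = s_post[s];
      psyn[pidx[s]] = s;
    }

  // incoming plastic CSC (for STDP potentiation on postsynaptic spikes)
  std::vector<int> pin_off(n + 1, 0), pin_idx(np);
  if (rule == 2) {
    for (int k = 0; k < np; ++k) pin_off[ppost[k] + 1]++;
    for (int i = 0; i < n; ++i) pin_off[i + 1] += pin_off[i];
    std::vector<int> cur(pin_off.begin(), pin_off.end() - 1);
    for (int k = 0; k < np; ++k) pin_idx[cur[ppost[k]]++] = k;
  }

  // ---- short-term plasticity ------------------------------------------------
  const double U = stp_par["U"], tau_A = stp_par["tau_A"],
               tau_D = stp_par["tau_D"];
  const bool augmentation = stp_par["augmentation"] > 0.5;
  std::vector<double> stp_u(nstp, 0.0), stp_x(nstp, 1.0),
      stp_t(nstp, NEG_INF);

  // ---- BCPNN ----------------------------------------------------------------
  const double eps = bcpnn_par["eps"], fmax = bcpnn_par["f_max"],
               t_spike = bcpnn_par["t_spike"], tau_za = bcpnn_par["tau_z_AMPA"],
               tau_zn = bcpnn_par["tau_z_NMDA"], tau_p = bcpnn_par["tau_p"],
               wgain_a = bcpnn_par["w_gain_AMPA"],
               wgain_n = bcpnn_par["w_gain_NMDA"],
               beta_gain = bcpnn_par["beta_gain"];
  const int bias_mode = static_cast<int>(bcpnn_par["bias_mode"]);
  // initial value of the per-neuron bias trace: eps for a naive neuron,
  // the pattern prior (1 / minicolumns per HC) for a pretrained network
  const double bias_p0 = bcpnn_par["bias_p0"];
  // drive so that sustained firing at f_max saturates Z near 1:
  // tau_z dZ/dt = S/(f_max*t_spike) - Z + eps, S in {0,1} over t_spike pulses
  const double z_drive = 1.0 / (fmax * 1e-3 * t_spike);
  const int pulse_steps = std::max(1, static_cast<int>(std::lround(t_spike / dt)));

  std::vector<double> Za(n, eps), Zn(n, eps), Pjb(n, bias_p0);
  // per-synapse traces [Pi_a, Pj_a, Pij_a, Pi_n, Pj_n, Pij_n]
  std::vector<double> Pia(np, eps), Pja(np, eps), Pija(np, eps * eps),
      Pin(np, eps), Pjn(np, eps), Pijn(np, eps * eps);
  std::vector<double> kap(np, kappa_default), kap_n(n, kappa_default);

  // ---- STDP -----------------------------------------------------------------
  const double lambda = stdp_par["lambda"], alpha = stdp_par["alpha"],
               tau_plus = stdp_par["tau_plus"], tau_minus = stdp_par["tau_minus"],
               w0 = stdp_par["w0"], wmax_a = stdp_par["w_max_AMPA"],
               wmax_n = stdp_par["w_max_NMDA"];
  const int mu_plus = static_cast<int>(stdp_par["mu_plus"]),
            mu_minus = static_cast<int>(stdp_par["mu_minus"]);
  const bool branch_at_delay = stdp_par["branch_at_delay"] > 0.5;
  std::vector<double> wnorm(np, w0), last_pre_arr(np, NEG_INF);

  // ---- neuron state ---------------------------------------------------------
  std::vector<double> V(n), Iw(n, 0.0), gA(n, 0.0), gN(n, 0.0), gG(n, 0.0),
      bias_I(n, 0.0), last_spk(n, NEG_INF);
  std::vector<int> ref_left(n, 0), pulse_left(n, 0);
  for (int i = 0; i < n; ++i)
    V[i] = (neuron_group[i] == 0) ? PP.EL : PB.EL;
  if (bias_mode == 1) {
    for (int i = 0; i < n; ++i)
      if (neuron_group[i] == 0) bias_I[i] = beta_gain * std::log(bias_p0);
  } else if (bias_mode == 2) {
    const double sb = bcpnn_par["static_bias"];
    for (int i = 0; i < n; ++i)
      if (neuron_group[i] == 0) bias_I[i] = sb;
  }

  // ---- restore state (optional) --------------------------------------------
  if (init_state.size() > 0) {
    if (init_state.containsElementNamed("V")) {
      NumericVector v = init_state["V"];
      for (int i = 0; i < n; ++i) V[i] = v[i];
    }
    if (init_state.containsElementNamed("Iw")) {
      NumericVector v = init_state["Iw"];
      for (int i = 0; i < n; ++i) Iw[i] = v[i];
    }
    if (init_state.containsElementNamed("Za")) {
      NumericVector v = init_state["Za"];
      for (int i = 0; i < n; ++i) Za[i] = v[i];
    }
    if (init_state.containsElementNamed("Zn")) {
      NumericVector v = init_state["Zn"];
      for (int i = 0; i < n; ++i) Zn[i] = v[i];
    }
    if (init_state.containsElementNamed("Pjb")) {
      NumericVector v = init_state["Pjb"];
      for (int i = 0; i < n; ++i) {
        Pjb[i] = v[i];
        if (bias_mode == 1 && neuron_group[i] == 0)
          bias_I[i] = beta_gain * std::log(Pjb[i]);
      }
    }
    if (init_state.containsElementNamed("traces")) {
      NumericMatrix m = init_state["traces"];
      for (int k = 0; k < np; ++k) {
        Pia[k] = m(k, 0); Pja[k] = m(k, 1); Pija[k] = m(k, 2);
        Pin[k] = m(k, 3); Pjn[k] = m(k, 4); Pijn[k] = m(k, 5);
      }
    }
    if (init_state.containsElementNamed("wnorm")) {
      NumericVector v = init_state["wnorm"];
      for (int k = 0; k < np; ++k) wnorm[k] = v[k];
    }
    if (init_state.containsElementNamed("stp_u")) {
      NumericVector vu = init_state["stp_u"], vx = init_state["stp_x"];
      for (int k = 0; k < nstp; ++k) { stp_u[k] = vu[k]; stp_x[k] = vx[k]; }
    }
  }

  // ---- kappa schedule -------------------------------------------------------
  struct KappaAction { int step; double value; IntegerVector synapses, neurons; };
  std::vector<KappaAction> kactions;
  for (int e = 0; e < kappa_epochs.size(); ++e) {
    List ke = kappa_epochs[e];
    KappaAction on, off;
    on.step = as<int>(ke["start"]); on.value = as<double>(ke["kappa"]);
    off.step = as<int>(ke["end"]); off.value = kappa_default;
    on.synapses = off.synapses = as<IntegerVector>(ke["synapses"]);
    on.neurons = off.neurons = as<IntegerVector>(ke["neurons"]);
    kactions.push_back(on); kactions.push_back(off);
  }
  std::sort(kactions.begin(), kactions.end(),
            [](const KappaAction& a, const KappaAction& b) { return a.step < b.step; });
  size_t kact_next = 0;

  // ---- noise ----------------------------------------------------------------
  IntegerVector nz_start = noise["t_start"];
  NumericVector nz_pyr = noise["rate_pyr"], nz_ba = noise["rate_basket"];
  const double g_exc = noise["g_exc"], g_inh = noise["g_inh"];
  int nz_seg = -1;
  std::vector<int> nxt_exc(n, std::numeric_limits<int>::max()),
      nxt_inh(n, std::numeric_limits<int>::max());
  double p_exc_pyr = 0, p_inh_pyr = 0, p_exc_ba = 0, p_inh_ba = 0;

  Rng rng(static_cast<uint64_t>(seed));
  const int NEVER = std::numeric_limits<int>::max();
  auto next_event = [&](int step, double p) -> int {
    const int k = rng.geom_skip(p);
    return (k == NEVER || step > NEVER - k) ? NEVER : step + k;
  };

  // ---- stimulation epochs ---------------------------------------------------
  const int n_stim = stim_epochs.size();
  std::vector<int> st_start(n_stim), st_end(n_stim);
  std::vector<double> st_p(n_stim), st_g(n_stim);
  std::vector<IntegerVector> st_targets(n_stim);
  for (int e = 0; e < n_stim; ++e) {
    List se = stim_epochs[e];
    st_start[e] = as<int>(se["start"]); st_end[e] = as<int>(se["end"]);
    st_p[e] = as<double>(se["rate"]) * 1e-3 * dt;
    st_g[e] = as<double>(se["g"]);
    st_targets[e] = as<IntegerVector>(se["targets"]);
  }

  // ---- current injection epochs --------------------------------------------
  const int n_cur = current_epochs.size();
  std::vector<int> cu_start(n_cur), cu_end(n_cur), cu_period(n_cur),
      cu_width(n_cur);
  std::vector<double> cu_amp(n_cur);
  std::vector<IntegerVector> cu_targets(n_cur);
  for (int e = 0; e < n_cur; ++e) {
    List ce = current_epochs[e];
    cu_start[e] = as<int>(ce["start"]); cu_end[e] = as<int>(ce["end"]);
    cu_period[e] = as<int>(ce["period"]); cu_width[e] = as<int>(ce["width"]);
    cu_amp[e] = as<double>(ce["amp"]);
    cu_targets[e] = as<IntegerVector>(ce["targets"]);
  }
  std::vector<double> I_inj(n, 0.0);

  // ---- recording ------------------------------------------------------------
  IntegerVector snap_steps = record["snapshot_steps"];
  IntegerVector tracked = record["tracked_syn"];   // synapse-table indices
  IntegerVector traced = record["trace_syn"];
  const bool keep_raster = as<bool>(record["raster"]);
  const int rec_every = std::max(1, static_cast<int>(std::lround(
      as<double>(record["interval_ms"]) / dt)));
  const int ms_every = std::max(1, static_cast<int>(std::lround(1.0 / dt)));

  std::vector<double> spike_t; std::vector<int> spike_id;
  List snapshots(snap_steps.size());
  int snap_next = 0;

  const int n_rec_rows = (tracked.size() > 0 || traced.size() > 0)
      ? n_steps / rec_every + 1 : 0;
  NumericMatrix tracked_w(tracked.size() > 0 ? n_rec_rows : 0,
                          2 * tracked.size());
  NumericMatrix traced_m(traced.size() > 0 ? n_rec_rows : 0,
                         8 * traced.size());
  NumericVector rec_time(n_rec_rows);
  int rec_row = 0;

  // ---- delivery ring buffer -------------------------------------------------
  int max_delay = 1;
  for (int s = 0; s < ns; ++s) max_delay = std::max(max_delay, (int)s_delay[s]);
  const int ring_n = max_delay + 1;
  std::vector<std::vector<int>> ring(ring_n);

  const double inv_tau_p = 1.0 / tau_p;
  const double dtz_a = dt / tau_za, dtz_n = dt / tau_zn;

  auto bcpnn_wa = [&](int k) {
    return wgain_a * (std::log(Pija[k]) - std::log(Pia[k]) - std::log(Pja[k]));
  };
  auto bcpnn_wn = [&](int k) {
    return wgain_n * (std::log(Pijn[k]) - std::log(Pin[k]) - std::log(Pjn[k]));
  };

  auto stp_release = [&](int s, double t) -> double {
    int k = sidx[s];
    if (k < 0) return 1.0;
    double u = stp_u[k], x = stp_x[k];
    if (stp_t[k] > NEG_INF) {
      const double del = t - stp_t[k];
      u *= std::exp(-del / tau_A);
      x = 1.0 - (1.0 - x) * std::exp(-del / tau_D);
    }
    u = augmentation ? u + U * (1.0 - u) : U;
    const double eff = u * x;      // u after jump, x before depletion
    x -= U * x;
    stp_u[k] = u; stp_x[k] = x; stp_t[k] = t;
    return eff;
  };

  // ---------------------------------------------------------------------------
  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;

    // kappa schedule
    while (kact_next < kactions.size() && kactions[kact_next].step <= step) {
      const KappaAction& a = kactions[kact_next];
      for (int j = 0; j < a.synapses.size(); ++j) {
        int k = pidx[a.synapses[j]];
        if (k >= 0) kap[k] = a.value;
      }
      for (int j = 0; j < a.neurons.size(); ++j) kap_n[a.neurons[j]] = a.value;
      ++kact_next;
    }

    // noise segment change
    if (nz_seg + 1 < nz_start.size() && step >= nz_start[nz_seg + 1]) {
      ++nz_seg;
      p_exc_pyr = nz_pyr[nz_seg] * 1e-3 * dt; p_inh_pyr = p_exc_pyr;
      p_exc_ba = nz_ba[nz_seg] * 1e-3 * dt; p_inh_ba = p_exc_ba;
      for (int i = 0; i < n; ++i) {
        const double pe = (neuron_group[i] == 0) ? p_exc_pyr : p_exc_ba;
        const double pi = (neuron_group[i] == 0) ? p_inh_pyr : p_inh_ba;
        nxt_exc[i] = (pe > 0) ? next_event(step, pe) : NEVER;
        nxt_inh[i] = (pi > 0) ? next_event(step, pi) : NEVER;
      }
    }

    // scheduled synaptic deliveries
    std::vector<int>& slot = ring[step % ring_n];
    for (size_t q = 0; q < slot.size(); ++q) {
      const int s = slot[q];
      const int j = s_post[s];
      const int kind = s_kind[s];
      if (kind == 0) {                       // static glutamatergic
        const double f = stp_release(s, t);
        gA[j] += s_wA[s] * f; gN[j] += s_wN[s] * f;
      } else if (kind == 1) {                // static GABA
        gG[j] += s_wG[s];
      } else {                               // plastic associative
        const int k = pidx[s];
        if (rule == 2) {
          // nearest-neighbour depression: pair arrival with last post spike
          if (last_spk[j] > NEG_INF) {
            double dtp = last_spk[j] - t;    // <= 0
            const double thr = branch_at_delay ? s_delay[s] * dt : 0.0;
            double w = wnorm[k], dw;
            if (dtp >= thr)
              dw = lambda * (mu_plus ? (1.0 - w) : 1.0) *
                   std::exp(-std::fabs(dtp) / tau_plus);
            else
              dw = -lambda * alpha * (mu_minus ? w : 1.0) *
                   std::exp(-std::fabs(dtp) / tau_minus);
            w += dw;
            wnorm[k] = std::min(1.0, std::max(0.0, w));
          }
          last_pre_arr[k] = t;
          const double f = stp_release(s, t);
          gA[j] += wnorm[k] * wmax_a * f; gN[j] += wnorm[k] * wmax_n * f;
        } else {                             // BCPNN
          const double f = stp_release(s, t);
          const double wa = bcpnn_wa(k) * f, wn = bcpnn_wn(k) * f;
          if (wa >= 0) gA[j] += wa; else gG[j] -= wa;
          if (wn >= 0) gN[j] += wn; else gG[j] -= wn;
        }
      }
    }
    slot.clear();

    // background noise and stimulation
    for (int i = 0; i < n; ++i) {
      if (step == nxt_exc[i]) {
        gA[i] += g_exc;
        const double pe = (neuron_group[i] == 0) ? p_exc_pyr : p_exc_ba;
        nxt_exc[i] = next_event(step, pe);
      }
      if (step == nxt_inh[i]) {
        gG[i] += g_inh;
        const double pi = (neuron_group[i] == 0) ? p_inh_pyr : p_inh_ba;
        nxt_inh[i] = next_event(step, pi);
      }
    }
    for (int e = 0; e < n_stim; ++e) {
      if (step >= st_start[e] && step < st_end[e]) {
        const IntegerVector& tg = st_targets[e];
        for (int j = 0; j < tg.size(); ++j)
          if (rng.unif() < st_p[e]) {
            if (st_g[e] >= 0) gA[tg[j]] += st_g[e]; else gG[tg[j]] -= st_g[e];
          }
      }
    }
    if (n_cur > 0) {
      std::fill(I_inj.begin(), I_inj.end(), 0.0);
      for (int e = 0; e < n_cur; ++e) {
        if (step >= cu_start[e] && step < cu_end[e]) {
          bool on = true;
          if (cu_period[e] > 0)
            on = ((step - cu_start[e]) % cu_period[e]) < cu_width[e];
          if (on) {
            const IntegerVector& tg = cu_targets[e];
            for (int j = 0; j < tg.size(); ++j) I_inj[tg[j]] += cu_amp[e];
          }
        }
      }
    }

    // neuron integration
    for (int i = 0; i < n; ++i) {
      const NeuronPars& P = (neuron_group[i] == 0) ? PP : PB;
      // adaptation decays always
      Iw[i] -= dt * Iw[i] / P.tau_w;
      const double Isyn = gA[i] * (V[i] - E_a) + gN[i] * (V[i] - E_nm) +
                          gG[i] * (V[i] - E_g);
      gA[i] *= dec_a; gN[i] *= dec_n; gG[i] *= dec_g;
      bool spiked = false;
      if (ref_left[i] > 0) {
        --ref_left[i];
        V[i] = P.Vr;
      } else {
        const double dV = (-P.gL * (V[i] - P.EL) +
                           P.gL * P.DeltaT * std::exp((V[i] - P.Vt) / P.DeltaT) -
                           Iw[i] + bias_I[i] + I_inj[i] - Isyn) / P.C;
        V[i] += dt * dV;
        if (V[i] >= 0.0) {                  // spike-detection ceiling
          spiked = true;
          V[i] = P.Vr;
          Iw[i] += P.b;
          ref_left[i] = static_cast<int>(std::lround(P.tau_ref / dt));
          last_spk[i] = t;
          pulse_left[i] = pulse_steps;
          if (keep_raster) { spike_t.push_back(t); spike_id.push_back(i); }
          for (int q = out_off[i]; q < out_off[i + 1]; ++q) {
            const int s = out_idx[q];
            ring[(step + s_delay[s]) % ring_n].push_back(s);
          }
          if (rule == 2) {                  // STDP potentiation pairing
            for (int q = pin_off[i]; q < pin_off[i + 1]; ++q) {
              const int k = pin_idx[q];
              if (last_pre_arr[k] > NEG_INF) {
                const double dtp = t - last_pre_arr[k];  // >= 0
                const double thr = branch_at_delay ? s_delay[psyn[k]] * dt : 0.0;
                double w = wnorm[k], dw;
                if (dtp >= thr)
                  dw = lambda * (mu_plus ? (1.0 - w) : 1.0) *
                       std::exp(-dtp / tau_plus);
                else
                  dw = -lambda * alpha * (mu_minus ? w : 1.0) *
                       std::exp(-dtp / tau_minus);
                w += dw;
                wnorm[k] = std::min(1.0, std::max(0.0, w));
              }
            }
          }
        }
      }
      // Z traces (pyramidal only; basket cells carry no plasticity)
      if (rule == 1 && neuron_group[i] == 0) {
        const double S = (pulse_left[i] > 0 || spiked) ? z_drive : 0.0;
        if (pulse_left[i] > 0) --pulse_left[i];
        Za[i] += dtz_a * (S - Za[i] + eps);
        Zn[i] += dtz_n * (S - Zn[i] + eps);
      }
    }

    // P traces and bias: 1-ms granularity
    if (rule == 1 && ((step + 1) % ms_every == 0)) {
      const double f0 = static_cast<double>(ms_every) * dt * inv_tau_p;
      for (int k = 0; k < np; ++k) {
        const double f = kap[k] * f0;
        if (f == 0.0) continue;
        const double zi_a = Za[ppre[k]], zj_a = Za[ppost[k]];
        const double zi_n = Zn[ppre[k]], zj_n = Zn[ppost[k]];
        Pia[k] += f * (zi_a - Pia[k]);
        Pja[k] += f * (zj_a - Pja[k]);
        Pija[k] += f * (zi_a * zj_a - Pija[k]);
        Pin[k] += f * (zi_n - Pin[k]);
        Pjn[k] += f * (zj_n - Pjn[k]);
        Pijn[k] += f * (zi_n * zj_n - Pijn[k]);
      }
      if (bias_mode == 1) {
        for (int i = 0; i < n; ++i) {
          if (neuron_group[i] != 0) continue;
          const double f = kap_n[i] * f0;
          if (f > 0.0) Pjb[i] += f * (Zn[i] - Pjb[i]);
          bias_I[i] = beta_gain * std::log(Pjb[i]);
        }
      }
    }

    // continuous recording
    if (n_rec_rows > 0 && step % rec_every == 0 && rec_row < n_rec_rows) {
      rec_time[rec_row] = t;
      for (int j = 0; j < tracked.size(); ++j) {
        const int k = pidx[tracked[j]];
        if (rule == 2) {
          tracked_w(rec_row, 2 * j) = wnorm[k] * wmax_a;
          tracked_w(rec_row, 2 * j + 1) = wnorm[k] * wmax_n;
        } else {
          tracked_w(rec_row, 2 * j) = bcpnn_wa(k);
          tracked_w(rec_row, 2 * j + 1) = bcpnn_wn(k);
        }
      }
      for (int j = 0; j < traced.size(); ++j) {
        const int k = pidx[traced[j]];
        traced_m(rec_row, 8 * j) = Za[ppre[k]];
        traced_m(rec_row, 8 * j + 1) = Za[ppost[k]];
        traced_m(rec_row, 8 * j + 2) = Zn[ppre[k]];
        traced_m(rec_row, 8 * j + 3) = Zn[ppost[k]];
        traced_m(rec_row, 8 * j + 4) = Pin[k];
        traced_m(rec_row, 8 * j + 5) = Pjn[k];
        traced_m(rec_row, 8 * j + 6) = Pijn[k];
        traced_m(rec_row, 8 * j + 7) = bcpnn_wn(k);
      }
      ++rec_row;
    }

    // snapshots (taken after the step completes)
    while (snap_next < snap_steps.size() && snap_steps[snap_next] == step) {
      NumericVector wa(np), wn(np), bias(n);
      for (int k = 0; k < np; ++k) {
        if (rule == 2) { wa[k] = wnorm[k] * wmax_a; wn[k] = wnorm[k] * wmax_n; }
        else { wa[k] = bcpnn_wa(k); wn[k] = bcpnn_wn(k); }
      }
      for (int i = 0; i < n; ++i) bias[i] = bias_I[i];
      snapshots[snap_next] = List::create(_["step"] = step, _["wA"] = wa,
                                          _["wN"] = wn, _["bias"] = bias);
      ++snap_next;
    }
  }

  NumericMatrix traces_out(np, 6);
  for (int k = 0; k < np; ++k) {
    traces_out(k, 0) = Pia[k]; traces_out(k, 1) = Pja[k];
    traces_out(k, 2) = Pija[k]; traces_out(k, 3) = Pin[k];
    traces_out(k, 4) = Pjn[k]; traces_out(k, 5) = Pijn[k];
  }
  List final_state = List::create(
      _["V"] = NumericVector(V.begin(), V.end()),
      _["Iw"] = NumericVector(Iw.begin(), Iw.end()),
      _["Za"] = NumericVector(Za.begin(), Za.end()),
      _["Zn"] = NumericVector(Zn.begin(), Zn.end()),
      _["Pjb"] = NumericVector(Pjb.begin(), Pjb.end()),
      _["bias"] = NumericVector(bias_I.begin(), bias_I.end()),
      _["traces"] = traces_out,
      _["wnorm"] = NumericVector(wnorm.begin(), wnorm.end()),
      _["stp_u"] = NumericVector(stp_u.begin(), stp_u.end()),
      _["stp_x"] = NumericVector(stp_x.begin(), stp_x.end()));

  return List::create(
      _["spike_t"] = NumericVector(spike_t.begin(), spike_t.end()),
      _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
      _["snapshots"] = snapshots,
      _["rec_time"] = rec_time,
      _["tracked_w"] = tracked_w,
      _["traced"] = traced_m,
      _["final_state"] = final_state);
}

// Single postsynaptic-potential measurement: hold one AdEx neuron at a fixed
// potential with constant current, deliver exponential conductance components
// at t = 0, return the signed peak deflection from holding.
// components: matrix with columns g (nS), tau (ms), E_rev (mV)
// [[Rcpp::export(name = ".engine_psp_peak")]]
double engine_psp_peak(NumericVector params, double hold_V,
                       NumericMatrix components, double dt, double t_max) {
  const NeuronPars P = as_pars(params);
  const double I_hold = P.gL * (hold_V - P.EL) -
                        P.gL * P.DeltaT * std::exp((hold_V - P.Vt) / P.DeltaT);
  const int nc = components.nrow();
  std::vector<double> g(nc), dec(nc), E(nc);
  for (int c = 0; c < nc; ++c) {
    g[c] = components(c, 0);
    dec[c] = std::exp(-dt / components(c, 1));
    E[c] = components(c, 2);
  }
  double V = hold_V, peak = 0.0;
  const int n_steps = static_cast<int>(std::lround(t_max / dt));
  for (int step = 0; step < n_steps; ++step) {
    double Isyn = 0.0;
    for (int c = 0; c < nc; ++c) {
      Isyn += g[c] * (V - E[c]);
      g[c] *= dec[c];
    }
    const double dV = (-P.gL * (V - P.EL) +
                       P.gL * P.DeltaT * std::exp((V - P.Vt) / P.DeltaT) +
                       I_hold - Isyn) / P.C;
    V += dt * dV;
    if (V >= 0.0) break;                    // spike: deflection unbounded above
    const double defl = V - hold_V;
    if (std::fabs(defl) > std::fabs(peak)) peak = defl;
  }
  return peak;
}
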