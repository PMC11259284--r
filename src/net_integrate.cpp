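#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integration of the coupled membrane/threshold/conductance
// equations for one interval of frozen connectivity.
//
// Conventions shared with the R layer:
//  * A(i, j) = 1 means a contact from presynaptic j (column) to postsynaptic
//    i (row); W holds the contact weight in [0, 1] where A = 1.
//  * all times are absolute milliseconds; a spike detected during step s is
//    logged at the step's end time t0 + (s+1)*dt and its synaptic delivery is
//    processed at the start of the step beginning at spike_time + t_d.
//  * while the refractory clock runs, V is pinned at V_spike and V_th at
//    V_th_spike; at clock expiry V is reset to V_reset and V_th relaxes from
//    V_th_spike through its own dynamics.
//  * STDP traces chi (presynaptic, tau_plus) and psi (postsynaptic,
//    tau_R*tau_plus) decay lazily: each is stored with the time it was last
//    touched. Depression at a delivery uses psi before chi is incremented;
//    potentiation at a postsynaptic spike uses chi before psi is incremented,
//    so no spike ever pairs with itself.
//  * the slow rate estimate fhat (Hz) jumps by 1000/tau_slow at each spike
//    and decays exponentially in between, also lazily.
//  * Poisson background noise is realized as at most one event per neuron per
//    step with probability f_noise*dt/1000, incrementing g_noise by
//    kappa_noise.
//
// Stimulation: per-electrode onset lists describe charge-balanced events
// (+1 for tau_sp, 0 for tau_sg, -tau_sp/tau_sn for tau_sn); the per-neuron
// current is stim_scale * sum_r X_r(t) * stim_gain(i, r), applied only to
// unclamped neurons.

static inline double clip01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

// [[Rcpp::export]]
List net_integrate_cpp(NumericVector V_in, NumericVector Vth_in,
                       NumericVector gsyn_in, NumericVector gnoise_in,
                       IntegerVector refrac_in, NumericVector gleak,
                       IntegerMatrix A, NumericMatrix W_in,
                       bool stdp_on,
                       NumericVector chi_in, NumericVector chi_t_in,
                       NumericVector psi_in, NumericVector psi_t_in,
                       NumericVector fhat_in, NumericVector fhat_t_in,
                       NumericVector pend_t, IntegerVector pend_j,
                       List par, double t0, double duration, double dt,
                       bool stim_on, NumericMatrix stim_gain,
                       List stim_onsets, double stim_scale) {
  RNGScope scope;

  NumericVector V = clone(V_in), Vth = clone(Vth_in);
  NumericVector gsyn = clone(gsyn_in), gnoise = clone(gnoise_in);
  IntegerVector refrac = clone(refrac_in);
  NumericMatrix W = clone(W_in);
  NumericVector chi = clone(chi_in), chi_t = clone(chi_t_in);
  NumericVector psi = clone(psi_in), psi_t = clone(psi_t_in);
  NumericVector fhat = clone(fhat_in), fhat_t = clone(fhat_t_in);

  const int N = V.size();
  const double Cm = as<double>(par["C"]);
  const double Vrest = as<double>(par["V_rest"]);
  const double Vreset = as<double>(par["V_reset"]);
  const double Vthrest = as<double>(par["V_th_rest"]);
  const double Vsyn = as<double>(par["V_syn"]);
  const double Vspike = as<double>(par["V_spike"]);
  const double Vthspike = as<double>(par["V_th_spike"]);
  const double td = as<double>(par["t_d"]);
  const double tauth = as<double>(par["tau_th"]);
  const double tausyn = as<double>(par["tau_syn"]);
  const double tauspike = as<double>(par["tau_spike"]);
  const double kappa = as<double>(par["kappa"]);
  const double fnoise = as<double>(par["f_noise"]);
  const double kappanoise = as<double>(par["kappa_noise"]);
  const double tauslow = as<double>(par["tau_slow_ms"]);

  double eta = 0.0, tauplus = 1.0, tauR = 1.0, basym = 0.0, tau_psi = 1.0;
  if (stdp_on) {
    eta = as<double>(par["eta"]);
    tauplus = as<double>(par["tau_plus"]);
    tauR = as<double>(par["tau_R"]);
    basym = as<double>(par["b"]);
    tau_psi = tauR * tauplus;
  }
  const double ltd_amp = stdp_on ? eta * basym / tauR : 0.0;

  const int nsteps = (int) std::llround(duration / dt);
  const int D = (int) std::llround(td / dt);
  const int refrac_steps = (int) std::llround(tauspike / dt);
  const double kap_over_N = kappa / (double) N;
  const double p_noise = fnoise * dt / 1000.0;
  const double gdec = dt / tausyn;

  // delivery ring buffer
  const int ring = D + 2;
  std::vector< std::vector<int> > buf(ring);
  std::vector<double> left_t;
  std::vector<int> left_j;
  for (int k = 0; k < pend_t.size(); ++k) {
    int sd = (int) std::llround((pend_t[k] - t0) / dt);
    if (sd < 0) sd = 0;
    if (sd < nsteps) buf[sd % ring].push_back(pend_j[k]);
    else { left_t.push_back(pend_t[k]); left_j.push_back(pend_j[k]); }
  }

  // stimulation bookkeeping
  int Ns = 0;
  std::vector<const double*> ons;
  std::vector<int> nons, sidx;
  double tsp = 0.0, tsg = 0.0, tsn = 0.0, neg_amp = 0.0, swidth = 0.0;
  std::vector<double> Xr;
  if (stim_on) {
    tsp = as<double>(par["tau_sp"]);
    tsg = as<double>(par["tau_sg"]);
    tsn = as<double>(par["tau_sn"]);
    neg_amp = -tsp / tsn;
    swidth = tsp + tsg + tsn;
    Ns = stim_onsets.size();
    Xr.assign(Ns, 0.0);
    for (int r = 0; r < Ns; ++r) {
      NumericVector v = stim_onsets[r];
      ons.push_back(v.begin());
      nons.push_back(v.size());
      int k = 0;
      while (k < v.size() && v[k] + swidth <= t0) ++k;
      sidx.push_back(k);
    }
  }

  std::vector<double> sp_t;
  std::vector<int> sp_i;
  sp_t.reserve(1024);
  sp_i.reserve(1024);

  for (int s = 0; s < nsteps; ++s) {
    const double t = t0 + s * dt;

    // 1. process synaptic deliveries due now
    std::vector<int>& dl = buf[s % ring];
    if (!dl.empty()) {
      for (size_t k = 0; k < dl.size(); ++k) {
        const int j = dl[k];
        // conductance kick with the weight at arrival (pre-depression)
        for (int i = 0; i < N; ++i)
          if (A(i, j)) gsyn[i] += kap_over_N * W(i, j);
        if (stdp_on) {
          for (int i = 0; i < N; ++i) {
            if (A(i, j)) {
              const double psv = psi[i] * std::exp(-(t - psi_t[i]) / tau_psi);
              W(i, j) = clip01(W(i, j) - ltd_amp * psv);
            }
          }
          chi[j] = chi[j] * std::exp(-(t - chi_t[j]) / tauplus) + 1.0;
          chi_t[j] = t;
        }
      }
      dl.clear();
    }

    // 2. stimulation waveform values at step start
    bool anyX = false;
    if (stim_on) {
      for (int r = 0; r < Ns; ++r) {
        double x = 0.0;
        int k = sidx[r];
        const double* o = ons[r];
        while (k < nons[r] && o[k] + swidth <= t) ++k;
        sidx[r] = k;
        if (k < nons[r] && t >= o[k]) {
          const double tau = t - o[k];
          if (tau < tsp) x = 1.0;
          else if (tau < tsp + tsg) x = 0.0;
          else x = neg_amp;
        }
        Xr[r] = x;
        if (x != 0.0) anyX = true;
      }
    }

    // 3. per-neuron state update
    for (int i = 0; i < N; ++i) {
      if (p_noise > 0.0 && unif_rand() < p_noise) gnoise[i] += kappanoise;
      if (refrac[i] > 0) {
        refrac[i] -= 1;
        if (refrac[i] == 0) V[i] = Vreset;
      } else {
        double Istim = 0.0;
        if (anyX) {
          for (int r = 0; r < Ns; ++r)
            if (Xr[r] != 0.0) Istim += Xr[r] * stim_gain(i, r);
          Istim *= stim_scale;
        }
        const double g = gsyn[i] + gnoise[i];
        V[i] += dt * (gleak[i] * (Vrest - V[i]) + g * (Vsyn - V[i]) + Istim) / Cm;
        Vth[i] += dt * (Vthrest - Vth[i]) / tauth;
      }
      gsyn[i] -= gdec * gsyn[i];
      gnoise[i] -= gdec * gnoise[i];
      // flush physically negligible conductances to zero so the exponential
      // decay never reaches denormal range (which stalls the FPU)
      if (gsyn[i] < 1e-12) gsyn[i] = 0.0;
      if (gnoise[i] < 1e-12) gnoise[i] = 0.0;
    }

    // 4. threshold crossings (neuron-index order; logged at step end time)
    const double tspk = t + dt;
    for (int i = 0; i < N; ++i) {
      if (refrac[i] <= 0 && V[i] >= Vth[i]) {
        sp_t.push_back(tspk);
        sp_i.push_back(i + 1);
        if (stdp_on) {
          for (int j = 0; j < N; ++j) {
            if (A(i, j)) {
              const double cv = chi[j] * std::exp(-(tspk - chi_t[j]) / tauplus);
              W(i, j) = clip01(W(i, j) + eta * cv);
            }
          }
          psi[i] = psi[i] * std::exp(-(tspk - psi_t[i]) / tau_psi) + 1.0;
          psi_t[i] = tspk;
        }
        fhat[i] = fhat[i] * std::exp(-(tspk - fhat_t[i]) / tauslow) + 1000.0 / tauslow;
        fhat_t[i] = tspk;
        V[i] = Vspike;
        Vth[i] = Vthspike;
        refrac[i] = refrac_steps;
        const int sd = s + D + 1;
        if (sd < nsteps) buf[sd % ring].push_back(i);
        else { left_t.push_back(t0 + sd * dt); left_j.push_back(i); }
      }
    }
  }

  // gather deliveries spilling past the interval end
  return List::create(
    _["V"] = V, _["V_th"] = Vth, _["g_syn"] = gsyn, _["g_noise"] = gnoise,
    _["refrac"] = refrac, _["W"] = W,
    _["chi"] = chi, _["chi_t"] = chi_t, _["psi"] = psi, _["psi_t"] = psi_t,
    _["fhat"] = fhat, _["fhat_t"] = fhat_t,
    _["pend_t"] = NumericVector(left_t.begin(), left_t.end()),
    _["pend_j"] = IntegerVector(left_j.begin(), left_j.end()),
    _["spike_time"] = NumericVector(sp_t.begin(), sp_t.end()),
    _["spike_neuron"] = IntegerVector(sp_i.begin(), sp_i.end()));
}
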