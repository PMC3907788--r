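// Core fixed-step integrator for branched compartmental conductance-based
// neurons coupled by event-driven bi-exponential synapses.
//
// Numerical scheme: staggered implicit (backward) Euler. Gating variables,
// calcium pools and synaptic conductance states advance with their exact
// exponential updates at the voltage of the previous step; the voltage system
// (capacitive + ionic + axial + synaptic, all linear in V once gates are
// frozen) is then solved implicitly on each cell's compartment tree with a
// Hines-ordered elimination. Unconditionally stable at the default
// dt = 0.025 ms.
//
// Unit conventions (NEURON-compatible): mV, ms, nA, uS, nF; channel densities
// arrive already converted to whole-compartment conductances in uS; calcium
// in mM.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct SchemeTab {
  // tabulated x_inf(v) and exp(-dt/tau(v)) on a uniform grid
  std::vector<double> xinf, efac;
};

const double V_LO = -140.0, V_HI = 80.0, V_STEP = 0.05;
const int NGRID = (int)((V_HI - V_LO) / V_STEP) + 1;

inline double boltz(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vh) / k));
}

inline double tau_of_v(double v, double tau_min, double tau_amp, double vt,
                       double ks1, double ks2) {
  if (tau_amp <= 0.0) return tau_min;
  return tau_min + tau_amp / (std::exp((v - vt) / ks1) + std::exp(-(v - vt) / ks2));
}

inline double mg_block(double v) {
  // Jahr & Stevens magnesium unblock at 1 mM Mg2+
  return 1.0 / (1.0 + std::exp(-0.062 * v) / 3.57);
}

struct Ev { int bank; double w; };

} // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List net, List cfg) {
  // ---- unpack compartments ----
  IntegerVector parent = net["parent"];        // 0-based, -1 root
  IntegerVector cell   = net["cell"];          // 0-based neuron id per comp
  NumericVector c_nf   = net["c_nf"];
  NumericVector g_leak = net["g_leak"];
  NumericVector e_leak = net["e_leak"];
  NumericVector g_par  = net["g_par"];         // axial conductance to parent, uS
  NumericVector v_init = net["v0"];
  const int ncomp = parent.size();

  // ---- gating schemes ----
  List schemes = net["schemes"];
  const int nsch = schemes.size();
  const double dt = as<double>(cfg["dt"]);
  std::vector<SchemeTab> tab(nsch);
  for (int s = 0; s < nsch; ++s) {
    List sc = schemes[s];
    double vh = sc["vh"], k = sc["k"], tmin = sc["tau_min"], tamp = sc["tau_amp"],
           vt = sc["vt"], ks1 = sc["ks1"], ks2 = sc["ks2"];
    tab[s].xinf.resize(NGRID);
    tab[s].efac.resize(NGRID);
    for (int i = 0; i < NGRID; ++i) {
      double v = V_LO + i * V_STEP;
      tab[s].xinf[i] = boltz(v, vh, k);
      tab[s].efac[i] = std::exp(-dt / tau_of_v(v, tmin, tamp, vt, ks1, ks2));
    }
  }

  // ---- gates ----
  IntegerVector gate_scheme = net["gate_scheme"];
  IntegerVector gate_comp   = net["gate_comp"];
  IntegerVector gate_exp    = net["gate_exp"];
  const int ngate = gate_scheme.size();

  // ---- channels ----
  IntegerVector ch_comp  = net["ch_comp"];
  NumericVector ch_g     = net["ch_g"];      // uS (whole compartment)
  NumericVector ch_erev  = net["ch_erev"];
  IntegerVector ch_cadep = net["ch_cadep"];  // 1 -> multiply by ca/(ca+kd)
  NumericVector ch_cakd  = net["ch_cakd"];   // mM
  IntegerVector ch_isca  = net["ch_isca"];   // 1 -> contributes to Ca influx
  IntegerVector ch_gbeg  = net["ch_gbeg"];   // index into gate arrays
  IntegerVector ch_gcnt  = net["ch_gcnt"];
  const int nch = ch_comp.size();

  // ---- calcium pools ----
  IntegerVector ca_comp = net["ca_comp"];
  NumericVector ca_rest = net["ca_rest"];
  NumericVector ca_tau  = net["ca_tau"];
  NumericVector ca_infl = net["ca_influx"];  // mM per ms per (mA/cm2)
  NumericVector ca_area = net["ca_area"];    // cm2 of the pool's compartment
  const int npool = ca_comp.size();
  std::vector<int> comp_pool(ncomp, -1);
  for (int i = 0; i < npool; ++i) comp_pool[ca_comp[i]] = i;

  // ---- synapse banks ----
  IntegerVector b_comp = net["bank_comp"];
  NumericVector b_tr   = net["bank_tau_rise"];
  NumericVector b_td   = net["bank_tau_decay"];
  NumericVector b_erev = net["bank_erev"];
  IntegerVector b_nmda = net["bank_nmda"];   // 1 -> voltage-dependent Mg block
  IntegerVector b_grp  = net["bank_group"];  // -1 none, else 0..3 recording group
  NumericVector b_cap  = net["bank_cap"];    // saturation cap (uS); 0 = linear
  const int nbank = b_comp.size();
  std::vector<double> b_er(nbank), b_ed(nbank), b_norm(nbank);
  for (int b = 0; b < nbank; ++b) {
    b_er[b] = std::exp(-dt / b_tr[b]);
    b_ed[b] = std::exp(-dt / b_td[b]);
    double tp = b_tr[b] * b_td[b] / (b_td[b] - b_tr[b]) * std::log(b_td[b] / b_tr[b]);
    b_norm[b] = 1.0 / (std::exp(-tp / b_td[b]) - std::exp(-tp / b_tr[b]));
  }

  // ---- outgoing synapse lists (spike-triggered events) ----
  IntegerVector out_src   = net["out_src"];    // source neuron, 0-based
  IntegerVector out_bank  = net["out_bank"];
  IntegerVector out_delay = net["out_delay"];  // steps, >= 1
  NumericVector out_w     = net["out_w"];      // uS
  const int nout = out_src.size();
  int nneuron = 0;
  for (int i = 0; i < ncomp; ++i) nneuron = std::max(nneuron, cell[i] + 1);
  std::vector<std::vector<int>> out_of(nneuron);
  for (int i = 0; i < nout; ++i) out_of[out_src[i]].push_back(i);
  int max_delay = 1;
  for (int i = 0; i < nout; ++i) max_delay = std::max(max_delay, out_delay[i]);

  // ---- pre-scheduled external synaptic events ----
  IntegerVector xe_step = net["ev_step"];   // sorted ascending
  IntegerVector xe_bank = net["ev_bank"];
  NumericVector xe_w    = net["ev_w"];
  const int nxe = xe_step.size();

  // ---- pre-scheduled noise current kicks (exponential decay) ----
  IntegerVector ne_step = net["noise_step"]; // sorted ascending
  IntegerVector ne_comp = net["noise_comp"];
  NumericVector ne_amp  = net["noise_amp"];  // nA added to decaying state
  const int nne = ne_step.size();
  const double noise_tau = as<double>(net["noise_tau"]);
  const double noise_efac = std::exp(-dt / noise_tau);

  // ---- current injections (piecewise constant) ----
  IntegerVector inj_comp = net["inj_comp"];
  NumericVector inj_t0   = net["inj_t0"];
  NumericVector inj_t1   = net["inj_t1"];
  NumericVector inj_amp  = net["inj_amp"];   // nA
  const int ninj = inj_comp.size();

  // ---- voltage clamps (series-resistance) ----
  IntegerVector cl_comp = net["clamp_comp"];
  NumericVector cl_t0   = net["clamp_t0"];
  NumericVector cl_t1   = net["clamp_t1"];
  NumericVector cl_v    = net["clamp_v"];
  NumericVector cl_g    = net["clamp_g"];    // uS
  const int ncl = cl_comp.size();

  // ---- config ----
  const int nsteps = as<int>(cfg["nsteps"]);
  IntegerVector rec_comp = cfg["record_comp"];      // 0-based comp indices
  const int rec_stride = as<int>(cfg["record_stride"]);
  const double sp_thresh = as<double>(cfg["spike_threshold"]);
  const double sp_lock   = as<double>(cfg["spike_lockout"]);
  IntegerVector sp_comp  = cfg["spike_comp"];       // one comp per neuron (-1 = none)
  const bool rec_syn = as<bool>(cfg["record_syn"]);

  // ---- state ----
  std::vector<double> V(v_init.begin(), v_init.end());
  std::vector<double> x(ngate);
  for (int g = 0; g < ngate; ++g) {
    const SchemeTab& t = tab[gate_scheme[g]];
    double v = V[gate_comp[g]];
    double p = (v - V_LO) / V_STEP;
    int i0 = std::max(0, std::min(NGRID - 2, (int)p));
    double f = std::max(0.0, std::min(1.0, p - i0));
    x[g] = t.xinf[i0] * (1 - f) + t.xinf[i0 + 1] * f;
  }
  std::vector<double> ca(npool);
  for (int i = 0; i < npool; ++i) ca[i] = ca_rest[i];
  std::vector<double> synA(nbank, 0.0), synB(nbank, 0.0);
  std::vector<double> inoise(ncomp, 0.0);

  // spike bookkeeping
  std::vector<double> last_spike(nneuron, -1e18);
  std::vector<double> spike_t;
  std::vector<int> spike_n;

  // event ring buffer
  const int ring_n = max_delay + 2;
  std::vector<std::vector<Ev>> ring(ring_n);

  // recording buffers
  const int nrec = rec_comp.size();
  const int nrecsteps = nsteps / rec_stride + 1;
  NumericMatrix vrec(nrecsteps, nrec);
  NumericVector trec(nrecsteps);
  NumericMatrix synrec(rec_syn ? nrecsteps : 1, 4);
  NumericVector clamprec(ncl > 0 ? nsteps + 1 : 1);

  // scratch for tree solve
  std::vector<double> D(ncomp), RHS(ncomp);

  // previous somatic voltage for threshold-crossing detection
  std::vector<double> vprev(nneuron, -1e9);
  for (int n = 0; n < nneuron; ++n)
    if (sp_comp[n] >= 0) vprev[n] = v_init[sp_comp[n]];

  // initial record
  int ri = 0;
  for (int j = 0; j < nrec; ++j) vrec(0, j) = V[rec_comp[j]];
  trec[0] = 0.0;
  ri = 1;

  int xe_i = 0, ne_i = 0;

  for (int s = 0; s < nsteps; ++s) {
    const double t_now = s * dt;        // state currently at t_now
    const double t_next = (s + 1) * dt;

    // deliver events scheduled for this step
    {
      std::vector<Ev>& slot = ring[s % ring_n];
      for (size_t e = 0; e < slot.size(); ++e) {
        int b = slot[e].bank;
        double a = slot[e].w * b_norm[b];
        if (b_cap[b] > 0) {
          double room = 1.0 - (synB[b] - synA[b]) / b_cap[b];
          a *= room > 0 ? room : 0.0;
        }
        synA[b] += a;
        synB[b] += a;
      }
      slot.clear();
      while (xe_i < nxe && xe_step[xe_i] == s) {
        int b = xe_bank[xe_i];
        double a = xe_w[xe_i] * b_norm[b];
        if (b_cap[b] > 0) {
          double room = 1.0 - (synB[b] - synA[b]) / b_cap[b];
          a *= room > 0 ? room : 0.0;
        }
        synA[b] += a;
        synB[b] += a;
        ++xe_i;
      }
      while (ne_i < nne && ne_step[ne_i] == s) {
        inoise[ne_comp[ne_i]] += ne_amp[ne_i];
        ++ne_i;
      }
    }

    // advance gates (exact exponential toward x_inf at V(t))
    for (int g = 0; g < ngate; ++g) {
      const SchemeTab& t = tab[gate_scheme[g]];
      double v = V[gate_comp[g]];
      double p = (v - V_LO) / V_STEP;
      int i0 = std::max(0, std::min(NGRID - 2, (int)p));
      double f = std::max(0.0, std::min(1.0, p - i0));
      double xinf = t.xinf[i0] * (1 - f) + t.xinf[i0 + 1] * f;
      double efac = t.efac[i0] * (1 - f) + t.efac[i0 + 1] * f;
      x[g] = xinf + (x[g] - xinf) * efac;
    }

    // decay synaptic states
    for (int b = 0; b < nbank; ++b) {
      synA[b] *= b_er[b];
      synB[b] *= b_ed[b];
    }

    // assemble per-compartment linear membrane terms
    // I_mem(V) = Gsum * V - GEsum  (nA, outward positive)
    for (int i = 0; i < ncomp; ++i) {
      D[i] = g_leak[i];
      RHS[i] = g_leak[i] * e_leak[i] + inoise[i];
      inoise[i] *= noise_efac;
    }
    // channels
    for (int c = 0; c < nch; ++c) {
      double gfac = 1.0;
      int gb = ch_gbeg[c], gc = ch_gcnt[c];
      for (int g = 0; g < gc; ++g) {
        double xv = x[gb + g];
        int e = gate_exp[gb + g];
        double pw = xv;
        for (int k = 1; k < e; ++k) pw *= xv;
        gfac *= pw;
      }
      if (ch_cadep[c]) {
        int pl = comp_pool[ch_comp[c]];
        double cav = pl >= 0 ? ca[pl] : 0.0;
        gfac *= cav / (cav + ch_cakd[c]);
      }
      double gg = ch_g[c] * gfac;
      D[ch_comp[c]] += gg;
      RHS[ch_comp[c]] += gg * ch_erev[c];
    }
    // synapses
    for (int b = 0; b < nbank; ++b) {
      double gsyn = synB[b] - synA[b];
      if (gsyn <= 0) continue;
      if (b_nmda[b]) gsyn *= mg_block(V[b_comp[b]]);
      D[b_comp[b]] += gsyn;
      RHS[b_comp[b]] += gsyn * b_erev[b];
    }
    // injections
    for (int j = 0; j < ninj; ++j) {
      if (t_now >= inj_t0[j] && t_now < inj_t1[j]) RHS[inj_comp[j]] += inj_amp[j];
    }
    // clamps
    for (int j = 0; j < ncl; ++j) {
      if (t_now >= cl_t0[j] && t_now < cl_t1[j]) {
        D[cl_comp[j]] += cl_g[j];
        RHS[cl_comp[j]] += cl_g[j] * cl_v[j];
      }
    }

    // implicit Euler system on each tree:
    //  (C/dt + D_i) V+ + sum_axial g*(V+_i - V+_j) = C/dt V + RHS_i
    for (int i = 0; i < ncomp; ++i) {
      double cd = c_nf[i] / dt;
      D[i] += cd;
      RHS[i] += cd * V[i];
      if (parent[i] >= 0) D[i] += g_par[i];
    }
    for (int i = 0; i < ncomp; ++i)
      if (parent[i] >= 0) D[parent[i]] += g_par[i];
    // eliminate children (children have larger index than parents)
    for (int i = ncomp - 1; i >= 0; --i) {
      int p = parent[i];
      if (p >= 0) {
        double f = g_par[i] / D[i];
        D[p] -= f * g_par[i];
        RHS[p] += f * RHS[i];
      }
    }
    // back-substitute
    for (int i = 0; i < ncomp; ++i) {
      int p = parent[i];
      double vnew = p >= 0 ? (RHS[i] + g_par[i] * V[p]) / D[i] : RHS[i] / D[i];
      // note: parents (smaller index) already updated, so V[p] is V+
      V[i] = vnew;
    }

    // clamp current record (after solve): total over all active clamps
    if (ncl > 0) {
      double ic = 0.0;
      for (int j = 0; j < ncl; ++j)
        if (t_now >= cl_t0[j] && t_now < cl_t1[j])
          ic += cl_g[j] * (cl_v[j] - V[cl_comp[j]]);
      clamprec[s + 1] = ic;
    }

    // spike detection + event scheduling
    for (int n = 0; n < nneuron; ++n) {
      int scp = sp_comp[n];
      if (scp < 0) continue;
      double v0 = vprev[n], v1 = V[scp];
      if (v0 < sp_thresh && v1 >= sp_thresh && (t_next - last_spike[n]) >= sp_lock) {
        double frac = (sp_thresh - v0) / (v1 - v0);
        double tsp = t_now + frac * dt;
        last_spike[n] = t_next;
        spike_t.push_back(tsp);
        spike_n.push_back(n);
        const std::vector<int>& outs = out_of[n];
        for (size_t oo = 0; oo < outs.size(); ++oo) {
          int o = outs[oo];
          int target = (s + out_delay[o]) % ring_n;
          Ev ev; ev.bank = out_bank[o]; ev.w = out_w[o];
          ring[target].push_back(ev);
        }
      }
      vprev[n] = v1;
    }

    // calcium update (exact first-order with influx frozen over the step)
    for (int pl = 0; pl < npool; ++pl) {
      double ica_nA = 0.0;
      // sum Ca-channel currents in this pool's compartment at new V
      for (int c = 0; c < nch; ++c) {
        if (!ch_isca[c] || ch_comp[c] != ca_comp[pl]) continue;
        double gfac = 1.0;
        int gb = ch_gbeg[c], gc = ch_gcnt[c];
        for (int g = 0; g < gc; ++g) {
          double xv = x[gb + g];
          int e = gate_exp[gb + g];
          double pw = xv;
          for (int k = 1; k < e; ++k) pw *= xv;
          gfac *= pw;
        }
        ica_nA += ch_g[c] * gfac * (V[ch_comp[c]] - ch_erev[c]);
      }
      double dens = ica_nA / (ca_area[pl] * 1e6);   // mA/cm2 (inward negative)
      double ca_inf = ca_rest[pl] - ca_infl[pl] * dens * ca_tau[pl];
      double cv = ca_inf + (ca[pl] - ca_inf) * std::exp(-dt / ca_tau[pl]);
      ca[pl] = cv > 0.0 ? cv : 0.0;
    }

    // recording
    if ((s + 1) % rec_stride == 0 && ri < nrecsteps) {
      for (int j = 0; j < nrec; ++j) vrec(ri, j) = V[rec_comp[j]];
      trec[ri] = t_next;
      if (rec_syn) {
        double acc[4] = {0, 0, 0, 0};
        for (int b = 0; b < nbank; ++b) {
          int grp = b_grp[b];
          if (grp < 0) continue;
          double gsyn = synB[b] - synA[b];
          if (b_nmda[b]) gsyn *= mg_block(V[b_comp[b]]);
          acc[grp] += gsyn * (V[b_comp[b]] - b_erev[b]);
        }
        for (int k = 0; k < 4; ++k) synrec(ri, k) = acc[k];
      }
      ++ri;
    }

    for (int i = 0; i < ncomp; ++i) {
      if (!std::isfinite(V[i]))
        stop("non-finite membrane potential at t = %f ms in compartment %d",
             t_next, i + 1);
    }
  }

  return List::create(
    _["time"] = trec,
    _["v"] = vrec,
    _["spike_neuron"] = IntegerVector(spike_n.begin(), spike_n.end()),
    _["spike_time"] = NumericVector(spike_t.begin(), spike_t.end()),
    _["syn"] = synrec,
    _["clamp_i"] = clamprec
  );
}
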