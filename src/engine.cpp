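// Clock-driven simulation engine for small leaky integrate-and-fire networks
// with signed, optionally plastic synapses, winner-take-all output layers,
// sub-trial resets, an external dopamine drive window, and the phasic
// punishment weight depression used during conditioning.
//
// Update order per step (fixed, documented in the package vignette):
//   integrate potentials -> detect spikes (WTA on flagged layers) ->
//   queue synaptic charge for the next step -> nearest-neighbour STDP ->
//   punishment depression -> record.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pop {
  int n;
  std::vector<double> v;
  std::vector<double> ext;     // constant external current
  std::vector<double> buf;     // synaptic current arriving this step
  std::vector<double> nxt;     // synaptic current queued for next step
  std::vector<double> last;    // last spike time, -1 = never
  std::vector<int> count;      // spike counts
  std::vector<char> spk;       // spiking this step
  bool wta;
};

struct Syn {
  int pre, post;               // 0-based population indices
  std::vector<double> w;       // row-major n_pre x n_post
  std::vector<char> m;         // connectivity mask: 0 = no synapse there
  double sign;                 // +1 excitatory, -1 inhibitory
  bool plastic;
  double wmin, wmax;
  int npre, npost;
};

inline double clipw(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

} // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List pops_in, List syns_in, double duration, double dt,
                List lif, List stdp, int readout, double reset_every,
                List da_ext, List punish, bool record_spikes) {
  const double v_th = as<double>(lif["v_th"]);
  const double v_r  = as<double>(lif["v_r"]);
  const double tau_m = as<double>(lif["tau_m"]);
  const double Rm   = as<double>(lif["R"]);
  const double a_plus  = as<double>(stdp["a_plus"]);
  const double a_minus = as<double>(stdp["a_minus"]);
  const double tau_plus  = as<double>(stdp["tau_plus"]);
  const double tau_minus = as<double>(stdp["tau_minus"]);

  const int npop = pops_in.size();
  std::vector<Pop> P(npop);
  for (int p = 0; p < npop; ++p) {
    List pl = pops_in[p];
    int n = as<int>(pl["n"]);
    P[p].n = n;
    P[p].v.assign(n, v_r);
    if (pl.containsElementNamed("v0")) {
      NumericVector v0 = pl["v0"];
      if (v0.size() == n) P[p].v.assign(v0.begin(), v0.end());
    }
    NumericVector e = pl["ext"];
    P[p].ext.assign(e.begin(), e.end());
    P[p].buf.assign(n, 0.0);
    P[p].nxt.assign(n, 0.0);
    P[p].last.assign(n, -1.0);
    P[p].count.assign(n, 0);
    P[p].spk.assign(n, 0);
    P[p].wta = as<bool>(pl["wta"]);
  }

  const int nsyn = syns_in.size();
  std::vector<Syn> S(nsyn);
  for (int s = 0; s < nsyn; ++s) {
    List sl = syns_in[s];
    S[s].pre  = as<int>(sl["pre"]) - 1;
    S[s].post = as<int>(sl["post"]) - 1;
    NumericMatrix W = sl["W"];
    S[s].npre = W.nrow(); S[s].npost = W.ncol();
    if (S[s].npre != P[S[s].pre].n || S[s].npost != P[S[s].post].n)
      stop("synapse %d: weight matrix does not match population sizes", s + 1);
    S[s].w.resize(S[s].npre * S[s].npost);
    for (int i = 0; i < S[s].npre; ++i)
      for (int j = 0; j < S[s].npost; ++j)
        S[s].w[i * S[s].npost + j] = W(i, j);
    NumericMatrix M = sl["mask"];
    if (M.nrow() != S[s].npre || M.ncol() != S[s].npost)
      stop("synapse %d: mask does not match weight matrix", s + 1);
    S[s].m.resize(S[s].npre * S[s].npost);
    for (int i = 0; i < S[s].npre; ++i)
      for (int j = 0; j < S[s].npost; ++j)
        S[s].m[i * S[s].npost + j] = M(i, j) != 0 ? 1 : 0;
    S[s].sign = as<double>(sl["sign"]);
    S[s].plastic = as<bool>(sl["plastic"]);
    S[s].wmin = as<double>(sl["wmin"]);
    S[s].wmax = as<double>(sl["wmax"]);
  }

  // dopamine external drive window
  const int da_pop = as<int>(da_ext["pop"]) - 1;   // -1 = none
  const double da_cur = as<double>(da_ext["current"]);
  const double da_on = as<double>(da_ext["t_on"]);
  const double da_off = as<double>(da_ext["t_off"]);

  // punishment machinery
  const bool pun_enabled = as<bool>(punish["enabled"]);
  LogicalVector pun_on_choice = punish["on_choice"];
  const double da_peak = as<double>(punish["da_peak"]);
  const double tau_t = as<double>(punish["tau_t"]);
  const double cutoff = as<double>(punish["cutoff"]);
  IntegerVector mem_syns = punish["mem_syns"];     // 1-based synapse indices
  IntegerVector active_pre = punish["active_pre"]; // 1-based rows

  const int steps = (int) std::lround(duration / dt);
  if (std::fabs(steps * dt - duration) > 1e-9)
    stop("duration must be a multiple of dt");
  int reset_steps = reset_every > 0 ? (int) std::lround(reset_every / dt) : 0;
  int nsub = reset_steps > 0 ? steps / reset_steps : 1;

  IntegerVector sub_choice(nsub, NA_INTEGER);
  NumericVector sub_time(nsub, NA_REAL);
  int cur_sub = 0;
  int first_choice = NA_INTEGER;
  double first_time = NA_REAL;
  bool pun_active = false, pun_done = false;
  double t_pun = NA_REAL;

  std::vector<double> rec_t; std::vector<int> rec_pop, rec_id;

  const int rpop = readout - 1;                    // -1 = none
  const double leak = dt / tau_m;

  for (int k = 0; k < steps; ++k) {
    const double t = (k + 1) * dt;                 // spike timestamp this step

    if (reset_steps > 0 && k > 0 && k % reset_steps == 0) {
      ++cur_sub;
      for (int p = 0; p < npop; ++p) {
        std::fill(P[p].v.begin(), P[p].v.end(), v_r);
        std::fill(P[p].nxt.begin(), P[p].nxt.end(), 0.0);
        std::fill(P[p].last.begin(), P[p].last.end(), -1.0);
      }
    }

    // integrate
    for (int p = 0; p < npop; ++p) {
      std::swap(P[p].buf, P[p].nxt);
      std::fill(P[p].nxt.begin(), P[p].nxt.end(), 0.0);
      for (int i = 0; i < P[p].n; ++i) {
        double I = P[p].ext[i] + P[p].buf[i];
        if (p == da_pop && t > da_on && t <= da_off) I += da_cur;
        double v = P[p].v[i] + leak * (-P[p].v[i] + Rm * I);
        if (!std::isfinite(v))
          stop("non-finite membrane potential in population %d", p + 1);
        P[p].v[i] = v;
      }
    }

    // detect spikes (winner-take-all on flagged layers)
    for (int p = 0; p < npop; ++p) {
      std::fill(P[p].spk.begin(), P[p].spk.end(), 0);
      if (P[p].wta) {
        int win = -1; double best = -1e300; int nties = 0;
        for (int i = 0; i < P[p].n; ++i) {
          if (P[p].v[i] >= v_th) {
            if (P[p].v[i] > best + 1e-12) { best = P[p].v[i]; win = i; nties = 1; }
            else if (std::fabs(P[p].v[i] - best) <= 1e-12) {
              ++nties;
              if (unif_rand() < 1.0 / nties) win = i;
            }
          }
        }
        if (win >= 0) P[p].spk[win] = 1;
      } else {
        for (int i = 0; i < P[p].n; ++i)
          if (P[p].v[i] >= v_th) P[p].spk[i] = 1;
      }
      for (int i = 0; i < P[p].n; ++i) {
        if (P[p].spk[i]) {
          P[p].v[i] = v_r;
          ++P[p].count[i];
          if (record_spikes) { rec_t.push_back(t); rec_pop.push_back(p + 1); rec_id.push_back(i + 1); }
        }
      }
    }

    // queue synaptic charge for next step: one spike carries charge = weight
    for (int s = 0; s < nsyn; ++s) {
      Pop &pre = P[S[s].pre], &post = P[S[s].post];
      for (int i = 0; i < S[s].npre; ++i) {
        if (!pre.spk[i]) continue;
        const double *wrow = &S[s].w[i * S[s].npost];
        const char *mrow = &S[s].m[i * S[s].npost];
        for (int j = 0; j < S[s].npost; ++j)
          if (mrow[j]) post.nxt[j] += S[s].sign * wrow[j] / dt;
      }
    }

    // Nearest-neighbour STDP, each spike pair counted once: a spike pairs
    // with the most recent opposite-side spike only if that spike arrived
    // after the neuron's own previous spike (so a fast presynaptic train
    // does not depress repeatedly against one stale postsynaptic spike).
    // Simultaneous pre/post spikes produce no change. The update acts on
    // the signed efficacy: pre-before-post strengthens an excitatory
    // synapse but weakens (releases) an inhibitory one.
    for (int s = 0; s < nsyn; ++s) {
      if (!S[s].plastic) continue;
      Pop &pre = P[S[s].pre], &post = P[S[s].post];
      for (int j = 0; j < S[s].npost; ++j) {
        if (!post.spk[j]) continue;
        for (int i = 0; i < S[s].npre; ++i) {
          if (!S[s].m[i * S[s].npost + j]) continue;
          if (pre.spk[i] || pre.last[i] < 0) continue;
          if (pre.last[i] <= post.last[j]) continue;   // pair already used
          double &w = S[s].w[i * S[s].npost + j];
          w = clipw(w + S[s].sign * a_plus *
                        std::exp(-(t - pre.last[i]) / tau_plus),
                    S[s].wmin, S[s].wmax);
        }
      }
      for (int i = 0; i < S[s].npre; ++i) {
        if (!pre.spk[i]) continue;
        for (int j = 0; j < S[s].npost; ++j) {
          if (!S[s].m[i * S[s].npost + j]) continue;
          if (post.spk[j] || post.last[j] < 0) continue;
          if (post.last[j] <= pre.last[i]) continue;   // pair already used
          double &w = S[s].w[i * S[s].npost + j];
          w = clipw(w - S[s].sign * a_minus *
                        std::exp(-(t - post.last[j]) / tau_minus),
                    S[s].wmin, S[s].wmax);
        }
      }
    }

    // readout bookkeeping
    if (rpop >= 0) {
      for (int i = 0; i < P[rpop].n; ++i) {
        if (!P[rpop].spk[i]) continue;
        if (reset_steps > 0 && sub_choice[cur_sub] == NA_INTEGER) {
          sub_choice[cur_sub] = i + 1; sub_time[cur_sub] = t - cur_sub * reset_every;
        }
        if (first_choice == NA_INTEGER) {
          first_choice = i + 1; first_time = t;
          if (pun_enabled && !pun_done && pun_on_choice[i]) {
            pun_active = true; pun_done = true; t_pun = t;
          }
        }
      }
    }

    // phasic dopamine depression of the memory weights leading to the choice
    if (pun_active) {
      double da = da_peak * std::exp(-(t - t_pun) / tau_t);
      if (da <= cutoff * da_peak) {
        pun_active = false;
      } else {
        int col = first_choice - 1;
        for (int m = 0; m < mem_syns.size(); ++m) {
          Syn &sy = S[mem_syns[m] - 1];
          for (int a = 0; a < active_pre.size(); ++a) {
            double &w = sy.w[(active_pre[a] - 1) * sy.npost + col];
            w = clipw(w - da * dt / tau_t, sy.wmin, sy.wmax);
          }
        }
      }
    }

    // update last-spike times after plasticity
    for (int p = 0; p < npop; ++p)
      for (int i = 0; i < P[p].n; ++i)
        if (P[p].spk[i]) P[p].last[i] = t;
  }

  List Wout(nsyn), counts(npop), vout(npop), last(npop);
  for (int s = 0; s < nsyn; ++s) {
    NumericMatrix W(S[s].npre, S[s].npost);
    for (int i = 0; i < S[s].npre; ++i)
      for (int j = 0; j < S[s].npost; ++j)
        W(i, j) = S[s].w[i * S[s].npost + j];
    Wout[s] = W;
  }
  for (int p = 0; p < npop; ++p) {
    counts[p] = IntegerVector(P[p].count.begin(), P[p].count.end());
    vout[p] = NumericVector(P[p].v.begin(), P[p].v.end());
    last[p] = NumericVector(P[p].last.begin(), P[p].last.end());
  }

  List spikes = R_NilValue;
  if (record_spikes)
    spikes = List::create(_["time_ms"] = NumericVector(rec_t.begin(), rec_t.end()),
                          _["pop"] = IntegerVector(rec_pop.begin(), rec_pop.end()),
                          _["neuron_id"] = IntegerVector(rec_id.begin(), rec_id.end()));

  return List::create(
    _["W"] = Wout, _["counts"] = counts, _["v"] = vout, _["last_spike"] = last,
    _["sub_choice"] = sub_choice, _["sub_time"] = sub_time,
    _["first_choice"] = first_choice, _["first_time"] = first_time,
    _["punished"] = pun_done, _["t_pun"] = t_pun, _["spikes"] = spikes);
}
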