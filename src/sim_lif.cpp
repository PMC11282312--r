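#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Leaky integrate-and-fire network with exponential synaptic currents.
//
// Exponential-Euler stepping: the membrane equation is solved exactly over
// one step under the assumption of piecewise-constant synaptic input, and
// each synaptic current decays by its exact exponential factor. Spikes are
// detected as V >= V_th after the subthreshold update, recorded at the end
// of the step, and delivered to postsynaptic targets with a one-step delay.
// During the absolute refractory period the potential is clamped to V_R.
//
// W is a dgCMatrix: column j holds the outgoing synapses of presynaptic
// unit j; entry (i, j) increments the source-matched synaptic current of
// target i by its weight (pA) on spike arrival.
//
// [[Rcpp::export]]
List sim_lif_cpp(S4 W, LogicalVector is_E, List prm,
                 NumericVector Ix, NumericVector V0,
                 IntegerVector stim_step, List stim_targets,
                 NumericVector stim_delta,
                 IntegerVector probe_units, int n_steps, double dt,
                 int delay_steps)
{
    if (delay_steps < 1) stop("delay must be at least one step");
    IntegerVector Wp = W.slot("p"), Wi = W.slot("i");
    NumericVector Wx = W.slot("x");
    const int N = V0.size();

    const double E_L = prm["E_L"], V_th = prm["V_th"], V_R = prm["V_R"];
    const double C_m = prm["C_m"];
    const double tmE = prm["tau_m_E"], tmI = prm["tau_m_I"];
    const double tsE = prm["tau_syn_E"], tsI = prm["tau_syn_I"];
    const double tau_r = prm["tau_r"];
    const int ref_steps = (int)std::lround(tau_r / dt);

    const double emE = std::exp(-dt / tmE), emI = std::exp(-dt / tmI);
    const double eE = std::exp(-dt / tsE), eI = std::exp(-dt / tsI);
    const double gnE = (tmE / C_m) * (1.0 - emE);
    const double gnI = (tmI / C_m) * (1.0 - emI);

    // per-unit membrane constants (E units first is not assumed)
    std::vector<double> em(N), gn(N);
    for (int i = 0; i < N; ++i) {
        em[i] = is_E[i] ? emE : emI;
        gn[i] = is_E[i] ? gnE : gnI;
    }

    std::vector<double> V(V0.begin(), V0.end());
    std::vector<double> Ie(N, 0.0), Ii(N, 0.0), Istim(N, 0.0);
    std::vector<int> ref(N, 0);

    std::vector<double> sp_t;
    std::vector<int> sp_u;
    sp_t.reserve(1 << 16);
    sp_u.reserve(1 << 16);
    // spikes in flight: ring buffer over the delay horizon
    std::vector<std::vector<int> > pending(delay_steps);
    for (int d = 0; d < delay_steps; ++d) pending[d].reserve(512);

    const int n_probe = probe_units.size();
    NumericMatrix prIe(n_probe ? n_steps : 0, n_probe);
    NumericMatrix prIi(n_probe ? n_steps : 0, n_probe);
    NumericMatrix prIt(n_probe ? n_steps : 0, n_probe);
    NumericMatrix prV(n_probe ? n_steps : 0, n_probe);

    int ev = 0;
    const int n_ev = stim_step.size();

    for (int k = 0; k < n_steps; ++k) {
        while (ev < n_ev && stim_step[ev] == k) {
            IntegerVector tg = stim_targets[ev];
            const double d = stim_delta[ev];
            for (int m = 0; m < tg.size(); ++m) Istim[tg[m] - 1] += d;
            ++ev;
        }
        std::vector<int> &spikers = pending[k % delay_steps];
        // deliver spikes that have completed their delay (emitted at step
        // k - delay_steps), then reuse the slot for this step's spikes
        for (size_t s = 0; s < spikers.size(); ++s) {
            const int j = spikers[s];
            const bool srcE = is_E[j];
            for (int q = Wp[j]; q < Wp[j + 1]; ++q) {
                if (srcE) Ie[Wi[q]] += Wx[q];
                else Ii[Wi[q]] += Wx[q];
            }
        }
        spikers.clear();
        for (int i = 0; i < N; ++i) {
            const double Iin = Ie[i] + Ii[i] + Ix[i] + Istim[i];
            if (ref[i] > 0) {
                --ref[i];
                V[i] = V_R;
            } else {
                V[i] = E_L + (V[i] - E_L) * em[i] + Iin * gn[i];
                if (V[i] >= V_th) {
                    sp_t.push_back((k + 1) * dt);
                    sp_u.push_back(i + 1);
                    V[i] = V_R;
                    ref[i] = ref_steps;
                    spikers.push_back(i);
                }
            }
        }
        // probes: synaptic input used in this step, V after the update
        for (int p = 0; p < n_probe; ++p) {
            const int i = probe_units[p] - 1;
            prIe(k, p) = Ie[i];
            prIi(k, p) = Ii[i];
            prIt(k, p) = Ie[i] + Ii[i] + Ix[i] + Istim[i];
            prV(k, p) = V[i];
        }
        for (int i = 0; i < N; ++i) {
            Ie[i] *= eE;
            Ii[i] *= eI;
        }
        if ((k & 1023) == 0) {
            checkUserInterrupt();
            for (int i = 0; i < N; ++i)
                if (!std::isfinite(V[i]))
                    stop("numerical divergence (non-finite V) at t = %f ms",
                         k * dt);
        }
    }

    List out = List::create(
        _["time"] = NumericVector(sp_t.begin(), sp_t.end()),
        _["unit"] = IntegerVector(sp_u.begin(), sp_u.end()));
    if (n_probe) {
        out["probe_I_E"] = prIe;
        out["probe_I_I"] = prIi;
        out["probe_I_tot"] = prIt;
        out["probe_V"] = prV;
    }
    return out;
}
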