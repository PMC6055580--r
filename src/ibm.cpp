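// Asynchronous sequential-update engine for the sector-column
// individual-based model. Agents are swept in a fresh random permutation
// each time step; every agent compares the perceived fitness of staying
// with that of the two adjacent sectors and moves to the strict maximiser,
// breaking ties (exact double equality) uniformly at random. Occupancy is
// updated within the sweep, so later agents see the moves of earlier ones.
//
// All randomness comes from R's RNG (unif_rand), so set.seed() on the R
// side fully determines a run.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Par {
  // growth: g0 + a1*F/(a2+F) - b*D - (c + u*adult)*log10(1+I) - kappa*K
  double g0, a1, a2, b, c, u, kappa;
  // reaction distance: (r0 + k*log10(1+I) + l*adult) * band factor
  double r0, k, l;
  // functional response (attack is derived per-sector from RD)
  double handling, gamma, nexp;
  // mortality
  double longevity, pred_dens, swim;
  // perception thresholds (relative differences)
  double aeF, aeI;
  bool adult, kairomone;
  double vol; // sector volume, litres
};

inline double growth(double food, double dens, double light, const Par& p) {
  double lightcost = (p.c + (p.adult ? p.u : 0.0)) * std::log10(1.0 + light);
  return p.g0 + p.a1 * food / (p.a2 + food) - p.b * dens - lightcost -
         (p.kairomone ? p.kappa : 0.0);
}

// cylindrical search volume: pi * RD^2 * v, cm^3/s -> L/day
inline double attack_from_light(double light, double bandfac, const Par& p) {
  double rd = (p.r0 + p.k * std::log10(1.0 + light) +
               (p.adult ? p.l : 0.0)) * bandfac;
  if (rd < 0.0) rd = 0.0;
  return M_PI * rd * rd * p.swim * 86.4;
}

// threshold-disc consumption; gamma = 0, n = 1 is Holling type II
inline double consumption(double N, double attack, const Par& p) {
  double M = N - p.gamma;
  if (M <= 0.0) return 0.0;
  double Mn = (p.nexp == 1.0) ? M : std::pow(M, p.nexp);
  return attack * Mn / (1.0 + attack * p.handling * Mn);
}

inline double sector_fitness(double food, double light, double bandfac,
                             double dens, const Par& p) {
  double gr = growth(food, dens, light, p);
  double attack = attack_from_light(light, bandfac, p);
  double fm;
  if (dens <= 0.0) {
    // N -> 0+ limit: pred_dens*attack for type II, 0 for a threshold response
    fm = (p.gamma > 0.0 || p.nexp > 1.0) ? 0.0 : p.pred_dens * attack;
  } else {
    fm = p.pred_dens * consumption(dens, attack, p) / dens;
  }
  double mort = fm + 1.0 / p.longevity;
  // Werner-Gilliam ratio; non-positive growth ranked by growth alone,
  // strictly below any positive-growth option
  return (gr > 0.0) ? gr / mort : gr * p.longevity;
}

// candidate-sector value perceived from the current sector: the candidate's
// value replaces the current one only when their relative difference clears
// the detection threshold ae
inline double perceive(double cur, double cand, double ae) {
  if (ae <= 0.0) return cand;
  double rel;
  if (cur > 0.0) rel = std::fabs(cand - cur) / cur;
  else rel = (cand == cur) ? 0.0 : R_PosInf;
  return (rel < ae) ? cur : cand;
}

inline Par unpack(const List& par) {
  Par p;
  p.g0 = par["g0"]; p.a1 = par["a1"]; p.a2 = par["a2"]; p.b = par["b"];
  p.c = par["c"]; p.u = par["u"]; p.kappa = par["kappa"];
  p.r0 = par["r0"]; p.k = par["k"]; p.l = par["l"];
  p.handling = par["handling"]; p.gamma = par["gamma"]; p.nexp = par["n"];
  p.longevity = par["longevity"]; p.pred_dens = par["predator_density"];
  p.swim = par["swim_speed"];
  p.aeF = par["ae_food"]; p.aeI = par["ae_light"];
  p.adult = as<bool>(par["adult"]);
  p.kairomone = as<bool>(par["kairomone"]);
  p.vol = par["sector_volume"];
  return p;
}

} // namespace

// [[Rcpp::export]]
List ibm_run_cpp(IntegerVector init_sectors, int n_steps,
                 NumericVector food, NumericVector light,
                 NumericVector bandfac, List par, bool record_agents) {
  Par p = unpack(par);
  const int S = food.size();
  const int n = init_sectors.size();
  IntegerVector sec = clone(init_sectors); // 0-based
  std::vector<int> occ(S, 0);
  for (int a = 0; a < n; ++a) {
    if (sec[a] < 0 || sec[a] >= S) stop("agent sector out of range");
    occ[sec[a]]++;
  }
  IntegerMatrix traj(n_steps, S);
  IntegerMatrix agents(record_agents ? n_steps : 0, record_agents ? n : 0);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;

  for (int t = 0; t < n_steps; ++t) {
    // Fisher-Yates shuffle of the update order
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    for (int idx = 0; idx < n; ++idx) {
      int a = ord[idx];
      int i = sec[a];
      // staying: true local conditions, own sector density (self included)
      double best = sector_fitness(food[i], light[i], bandfac[i],
                                   occ[i] / p.vol, p);
      int bestj = i, nties = 1;
      for (int dj = -1; dj <= 1; dj += 2) {
        int j = i + dj;
        if (j < 0 || j >= S) continue;
        double f  = perceive(food[i], food[j], p.aeF);
        double li = perceive(light[i], light[j], p.aeI);
        // the mover counts itself in the candidate sector
        double val = sector_fitness(f, li, bandfac[j],
                                    (occ[j] + 1.0) / p.vol, p);
        if (val > best) {
          best = val; bestj = j; nties = 1;
        } else if (val == best) {
          ++nties;
          if (unif_rand() * nties < 1.0) bestj = j;
        }
      }
      if (bestj != i) {
        occ[i]--; occ[bestj]++; sec[a] = bestj;
      }
    }
    for (int s = 0; s < S; ++s) traj(t, s) = occ[s];
    if (record_agents)
      for (int a = 0; a < n; ++a) agents(t, a) = sec[a];
  }

  List out = List::create(_["occupancy"] = traj, _["sectors"] = sec);
  if (record_agents) out["agent_sectors"] = agents;
  return out;
}
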