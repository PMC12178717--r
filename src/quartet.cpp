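// Per-site four-taxon coalescent simulator with an optional admixture
// pulse. Populations follow a fixed species tree: the two inner taxa
// merge at t_pair, their ancestor joins the third taxon at t_third, and
// the outgroup joins at t_out (times in generations). With probability f
// the recipient lineage jumps into the donor population at t_admix. One
// mutation is placed uniformly on the realized genealogy; the returned
// value per site is the bitmask of leaves carrying the derived allele
// (bit i = leaf i, leaf order: inner1, inner2, third, outgroup).
//
// Uses R's RNG so results are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Lineage {
  int mask;     // leaves below
  int pop;      // current population label
  double birth; // time the lineage appeared (0 for leaves)
  bool active;
};

// [[Rcpp::export]]
IntegerVector sim_quartet_masks_cpp(int n_sites, double ne,
                                    double t_pair, double t_third, double t_out,
                                    double t_admix, double f,
                                    int recipient, int donor) {
  RNGScope scope;
  IntegerVector out(n_sites);
  const double coal2 = 1.0 / (2.0 * ne);  // pairwise coalescence rate

  // event times in increasing order with actions
  struct Ev { double t; int type; };     // 0 pulse, 1 merge pair, 2 merge third, 3 merge out
  std::vector<Ev> evs;
  if (f > 0 && t_admix > 0) evs.push_back({t_admix, 0});
  evs.push_back({t_pair, 1});
  evs.push_back({t_third, 2});
  evs.push_back({t_out, 3});
  std::sort(evs.begin(), evs.end(), [](const Ev &a, const Ev &b) { return a.t < b.t; });

  for (int s = 0; s < n_sites; ++s) {
    Lineage lin[8];
    int nact = 4;
    for (int i = 0; i < 4; ++i) lin[i] = {1 << i, i, 0.0, true};
    int nlin = 4;
    double t = 0.0;
    size_t ie = 0;

    // branch records: mask + length, at most 6 proper branches
    int bmask[8];
    double blen[8];
    int nb = 0;

    while (nact > 1) {
      // coalescence rate per population
      int cnt[5] = {0, 0, 0, 0, 0};
      for (int i = 0; i < nlin; ++i)
        if (lin[i].active) cnt[lin[i].pop]++;
      double rate = 0.0;  // (cnt choose 2) * pairwise rate, per population
      for (int p = 0; p < 5; ++p)
        if (cnt[p] > 1) rate += coal2 * (cnt[p] * (cnt[p] - 1) / 2.0);

      double t_next_ev = (ie < evs.size()) ? evs[ie].t : R_PosInf;
      double dt = (rate > 0) ? R::exp_rand() / rate : R_PosInf;
      if (t + dt < t_next_ev) {
        // coalescence: pick population proportional to its pair count
        t += dt;
        double u = unif_rand() * rate;
        int pop = -1;
        for (int p = 0; p < 5; ++p) {
          if (cnt[p] > 1) {
            double rp = coal2 * (cnt[p] * (cnt[p] - 1) / 2.0);
            if (u < rp) { pop = p; break; }
            u -= rp;
          }
        }
        // pick an unordered pair uniformly within pop
        int npairs = cnt[pop] * (cnt[pop] - 1) / 2;
        int pick = (int)(unif_rand() * npairs);
        if (pick >= npairs) pick = npairs - 1;
        int i1 = -1, i2 = -1, seen = 0;
        for (int i = 0; i < nlin && i1 < 0; ++i) {
          if (!lin[i].active || lin[i].pop != pop) continue;
          for (int j = i + 1; j < nlin; ++j) {
            if (!lin[j].active || lin[j].pop != pop) continue;
            if (seen == pick) { i1 = i; i2 = j; break; }
            seen++;
          }
        }
        bmask[nb] = lin[i1].mask; blen[nb++] = t - lin[i1].birth;
        bmask[nb] = lin[i2].mask; blen[nb++] = t - lin[i2].birth;
        lin[i1].active = false;
        lin[i2].active = false;
        lin[nlin] = {lin[i1].mask | lin[i2].mask, pop, t, true};
        nlin++;
        nact--;
      } else {
        t = t_next_ev;
        switch (evs[ie].type) {
          case 0: {  // admixture pulse: recipient-leaf lineage may jump
            if (unif_rand() < f) {
              for (int i = 0; i < nlin; ++i)
                if (lin[i].active && (lin[i].mask & (1 << recipient)))
                  { lin[i].pop = donor; break; }
            }
            break;
          }
          case 1: {  // inner pair populations merge (1 -> 0)
            for (int i = 0; i < nlin; ++i)
              if (lin[i].active && lin[i].pop == 1) lin[i].pop = 0;
            break;
          }
          case 2: {  // third joins (2 -> 0)
            for (int i = 0; i < nlin; ++i)
              if (lin[i].active && lin[i].pop == 2) lin[i].pop = 0;
            break;
          }
          case 3: {  // outgroup joins (3 -> 0)
            for (int i = 0; i < nlin; ++i)
              if (lin[i].active && lin[i].pop == 3) lin[i].pop = 0;
            break;
          }
        }
        ie++;
      }
    }

    // place one mutation uniformly on the genealogy
    double total = 0.0;
    for (int i = 0; i < nb; ++i) total += blen[i];
    double x = unif_rand() * total;
    int hit = nb - 1;
    for (int i = 0; i < nb; ++i) {
      if (x < blen[i]) { hit = i; break; }
      x -= blen[i];
    }
    out[s] = bmask[hit];
  }
  return out;
}
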