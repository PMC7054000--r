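#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Discrete-time loop-extrusion inner loop. Semantics match the pure-R
// reference stepper extrusion_step(): per step,
//   (1) ages increment; each extruder dissociates w.p. p_diss, records its
//       completed lifetime, and instantly reloads at a uniform random free
//       adjacent pair (count conserved);
//   (2) each halted end resumes w.p. p_resume, recording its halted-episode
//       duration;
//   (3) each non-halted end attempts one monomer outward; moves off the
//       lattice or onto an occupied monomer are blocked (not halted); a
//       move onto a monomer with halting probability h halts the end w.p.
//       h. Conflicts are resolved sequentially in extruder order, left end
//       before right.
// Positions are 1-based monomer indices, as in the R objects. Uses R's RNG
// so runs are reproducible from set.seed() in R.
// [[Rcpp::export]]
List run_extrusion_cpp(int n_monomers, int n_extruders, double p_diss,
                       double p_resume, int n_steps, int stride,
                       NumericVector hp_left, NumericVector hp_right,
                       IntegerVector init_left, IntegerVector init_right) {
  const int n_snap = n_steps / stride;
  IntegerMatrix snap_left(n_snap, n_extruders), snap_right(n_snap, n_extruders);
  LogicalMatrix snap_lhalt(n_snap, n_extruders), snap_rhalt(n_snap, n_extruders);

  std::vector<int> left(n_extruders), right(n_extruders),
      age(n_extruders, 0), lage(n_extruders, 0), rage(n_extruders, 0);
  std::vector<bool> lhalt(n_extruders, false), rhalt(n_extruders, false);
  std::vector<char> occ(n_monomers + 2, 0);  // 1-based, sentinel at both ends

  for (int e = 0; e < n_extruders; ++e) {
    left[e] = init_left[e];
    right[e] = init_right[e];
    occ[left[e]] = 1;
    occ[right[e]] = 1;
  }

  std::vector<double> lifetimes, halt_durations;
  long loads = 0, dissociations = 0, halts = 0, resumes = 0;

  for (int step = 1; step <= n_steps; ++step) {
    // stage 1: dissociation + instant reload
    for (int e = 0; e < n_extruders; ++e) {
      age[e]++;
      if (unif_rand() < p_diss) {
        lifetimes.push_back((double)age[e]);
        dissociations++;
        occ[left[e]] = 0;
        occ[right[e]] = 0;
        // uniform over positions p with p and p+1 free
        std::vector<int> free_pos;
        free_pos.reserve(64);
        for (int p = 1; p < n_monomers; ++p)
          if (!occ[p] && !occ[p + 1]) free_pos.push_back(p);
        if (free_pos.empty()) stop("no free position to reload an extruder");
        int k = (int)(unif_rand() * free_pos.size());
        if (k >= (int)free_pos.size()) k = free_pos.size() - 1;
        left[e] = free_pos[k];
        right[e] = free_pos[k] + 1;
        occ[left[e]] = 1;
        occ[right[e]] = 1;
        lhalt[e] = rhalt[e] = false;
        age[e] = 0;
        loads++;
      }
    }
    // stage 2: resumption
    for (int e = 0; e < n_extruders; ++e) {
      if (lhalt[e]) {
        lage[e]++;
        if (unif_rand() < p_resume) {
          halt_durations.push_back((double)lage[e]);
          lhalt[e] = false;
          resumes++;
        }
      }
      if (rhalt[e]) {
        rage[e]++;
        if (unif_rand() < p_resume) {
          halt_durations.push_back((double)rage[e]);
          rhalt[e] = false;
          resumes++;
        }
      }
    }
    // stage 3: movement
    for (int e = 0; e < n_extruders; ++e) {
      if (!lhalt[e]) {
        int tgt = left[e] - 1;
        if (tgt >= 1 && !occ[tgt]) {
          occ[left[e]] = 0;
          left[e] = tgt;
          occ[tgt] = 1;
          double h = hp_left[tgt - 1];
          if (h > 0 && unif_rand() < h) {
            lhalt[e] = true;
            lage[e] = 0;
            halts++;
          }
        }
      }
      if (!rhalt[e]) {
        int tgt = right[e] + 1;
        if (tgt <= n_monomers && !occ[tgt]) {
          occ[right[e]] = 0;
          right[e] = tgt;
          occ[tgt] = 1;
          double h = hp_right[tgt - 1];
          if (h > 0 && unif_rand() < h) {
            rhalt[e] = true;
            rage[e] = 0;
            halts++;
          }
        }
      }
    }
    if (step % stride == 0) {
      int i = step / stride - 1;
      for (int e = 0; e < n_extruders; ++e) {
        snap_left(i, e) = left[e];
        snap_right(i, e) = right[e];
        snap_lhalt(i, e) = lhalt[e];
        snap_rhalt(i, e) = rhalt[e];
      }
    }
  }

  IntegerVector counts = IntegerVector::create(
      _["loads"] = (int)loads, _["dissociations"] = (int)dissociations,
      _["halts"] = (int)halts, _["resumes"] = (int)resumes);
  return List::create(_["left"] = snap_left, _["right"] = snap_right,
                      _["lhalt"] = snap_lhalt, _["rhalt"] = snap_rhalt,
                      _["lifetimes"] = wrap(lifetimes),
                      _["halt_durations"] = wrap(halt_durations),
                      _["counts"] = counts);
}
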