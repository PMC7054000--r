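---
title: "Modeling cohesin loop extrusion, Hi-C summaries, and iFRAP kinetics with cohesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cohesin loop extrusion, Hi-C summaries, and iFRAP kinetics with cohesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohesim)
```

## The biological question and the computational model

Cohesin complexes fold interphase chromatin into loops by extrusion, and the
two variants of the complex behave differently: cohesin containing STAG2
exchanges on chromatin within minutes, while a subpopulation of
STAG1-containing, SMC3-acetylated cohesin is protected from the release
factor WAPL and stays bound for hours. The central quantitative claim is
that this difference in *residence time* alone is enough to change genome
folding: long-lived extruders make longer loops and longer-range contacts.
`cohesim` packages the three computational pillars needed to examine that
claim end to end — a stochastic loop-extrusion simulator, Hi-C-style contact
analytics, and iFRAP exponential-kinetics fitting — together with a
synthetic-data generator, so the full pipeline runs from nothing but a seed.

## The extrusion model

Chromatin is a 1D lattice of monomers, 1 monomer = 1 kb. Each extruder
occupies two monomers (its loop ends) and each end moves one monomer
outward per time step, which defines the time unit. The stochastic events,
all Bernoulli per step:

* **Dissociation** with probability `p_dissociate / lifetime_multiplier`
  (wild type 2e-4, i.e. a mean lifetime of 5000 steps). The complex unbinds
  and instantly reloads at a uniformly random free adjacent monomer pair,
  so the bound count is constant — we read "an average of three complexes"
  as a constant count of 3, the simplest reading consistent with a
  conserved-count snapshot invariant. Completed lifetimes are Geometric(p)
  on {1, 2, ...} with mean 1/p.
* **CTCF halting.** Each CTCF site carries a halting probability; a move
  *onto* a site triggers a halt with that probability. Only motifs pointing
  toward the loop interior block (a `+` motif halts a leftward-moving end,
  a `-` motif a rightward-moving end): this convergent gating is not stated
  in the source methods but is required for the convergence-rule readout,
  and `orientation_blind = TRUE` disables it. Halting is tested only on
  moves, so a resumed end steps off its site without re-testing it —
  otherwise the resume probability would not control the halted lifetime.
* **Resumption** of a halted end with probability `p_resume` (5e-4 in the
  chromosome-region model, halted lifetime ~2000 steps; 1e-4 in the
  simplified layout). Halted durations are Geometric(p_resume).
* **Blocking.** Extruder ends cannot pass each other or the lattice
  boundary; a blocked end simply stays put and is *not* flagged halted.
  Conflicting simultaneous moves are resolved sequentially in extruder
  index order (left end before right), a documented tie-break that only
  matters when two free ends target the same monomer in the same step.

The inner loop is compiled (Rcpp); `extrusion_step()` is a pure-R reference
implementation of the identical update, and the test suite proves the two
equivalent on deterministic (probability 0/1) configurations. Replicate `r`
uses seed `seed + r - 1`, so runs are reproducible and embarrassingly
parallel in design.

The simplified six-site layout places three convergent CTCF pairs on a
1000-monomer polymer, outer sites with halting probability 0.9 and inner
sites 0.4. The site *positions* are a package convention (monomers 100,
263, 426, 575, 738, 901, orientations `+,-,+,-,+,-`): the layout is
specified only as "three pairs of convergent sites", and a symmetric,
near-even spacing makes the expected dot pattern testable.

## From trajectories to contact maps

The study's molecular-dynamics engine is out of scope here; `cohesim`
replaces it with two desk-scale models:

* **Gaussian (default).** Each snapshot's extruders are zero-length
  bridges on the backbone. The effective contour separation `s_eff(i, j)`
  is the shortest-path distance on the graph with backbone edges of weight
  1 and bridge edges of weight 0, and each snapshot contributes
  `(1 + s_eff / capture_scale)^(-3/2)` per bin pair — the return
  probability of an ideal chain. Shortest paths are computed exactly from
  all-pairs distances among the (at most `2 * n_extruders`) bridge
  endpoints; the tests verify exact agreement with a whole-lattice Dijkstra
  oracle. Snapshots and replicates are summed, following the study's
  aggregation of 480 replicates into one map.
* **Langevin bead-spring (`contact_map_md()`).** An overdamped chain with
  harmonic backbone bonds, soft excluded volume, and harmonic bonds imposed
  on the bridged pairs of each snapshot; contacts are counted below a
  capture radius of 2 bead diameters (a declared convention). Per-bead
  forces are capped (`f_cap`), so a freshly imposed long-range bridge pulls
  its anchors together at constant speed instead of destabilizing the
  integrator; a displacement guard aborts with a diagnostic if the step
  size is genuinely too large. This mode is a physical cross-check: the
  tests require Spearman agreement > 0.8 with the gaussian mode on a
  persistent-loop chain, bridged-pair enrichment over matched unbridged
  controls, and monotone energy decay under zero-temperature gradient flow.

Maps are balanced either by vanilla coverage (divide entry `(i, j)` by
`sqrt(rowsum_i * rowsum_j)`) or by symmetric iterative correction to equal
row sums (relative tolerance 1e-6, 200 iterations) — a generic stand-in for
Knight-Ruiz, which the study used through external tooling. Zero rows are
masked and returned as zeros.

## Hi-C summary statistics

**P(s) and the loop scale.** `ps_curve()` averages contacts in log-spaced
distance bins. Under the ideal-chain kernel the raw P(s) has *no interior
peak*: the loop-free background `(1 + s)^(-3/2)` decays smoothly and the
relative enrichment from loops grows monotonically with `s`, so the
location of loop-attributable signal must be measured differently than in
coverage-corrected experimental maps. `ps_excess()` subtracts the analytic
loop-free background (`background_contact_map()`) scaled to the snapshot
count and multiplies by the per-bin pair count, giving the contact mass
above background per distance bin; `loop_contact_scale()` summarizes it by
the excess-weighted geometric-mean distance (plus the discrete argmax).
That characteristic scale is the package's analogue of "the genomic
distance with the highest contact probability" and shifts robustly with
extruder lifetime.

**Insulation.** `insulation(map, resolution = 3000, window = 15000,
max_dist = 2e6)` implements a standard cross-window statistic: the mean of
the `w x w` submatrix of contacts crossing each inter-bin boundary,
log2-scaled to the map-wide mean. The study delegated this to an external
package whose internals are unpublished; the parameters, not the internals,
are what the analysis depends on, so a transparent cross-window score with
the stated resolution, window and maximum distance is implemented instead.
Whether the original used log2 scaling is unstated; log2-to-mean is chosen
because it makes the flat-map profile exactly zero and boundary depth
comparable across maps. Boundaries are local minima at least `prominence`
(default 0.2) below the surrounding maximum within one window.
`boundary_profile()` averages the score around supplied positions and
around uniformly drawn random positions — the dashed random-position
control of boundary-averaged insulation plots.

**APA and TAD pileups.** `apa()` sums fixed windows (default 21 x 21 bins,
i.e. 210 kb at 10 kb resolution) centered on loop coordinates, skipping
(and counting) loops whose window leaves the matrix or touches the
diagonal; enrichment is the center value over the mean of the four 5 x 5
corner blocks. `tad_pileup()` groups TADs into length classes and sums
fixed windows around their centers, one window size per class. One
model-specific caveat, established while validating the lifetime
comparison: in the simplified layout the *total* APA enrichment over all
six convergent pairs saturates once the extruder lifetime exceeds the
halted lifetime (1e4 steps) — anchoring time at already-reachable sites
cannot grow further, and the 625-vs-10000 ordering becomes seed noise.
What keeps growing with lifetime is dot strength at the *long-range*
convergent pairs (spans >= 455 kb), which only long-lived extruders reach;
the acceptance suite therefore asserts strict monotonicity for the
long-range pairs and for the characteristic loop scale, and growth of the
all-pairs enrichment only between the 312.5- and 625-step lifetimes.

**Loop lists, occupancy, convergence, overlaps.** Loop length is the
distance between anchor midpoints, summarized by `loop_length_ecdf()`.
`ctcf_occupancy()` expands anchors under 15 kb symmetrically to 15 kb,
counts anchors overlapping any peak, and compares with the mean of ten
translational controls; each control re-places every anchor independently
and uniformly within its chromosome with its width preserved (the
bedtools-shuffle-like reading of "random translational controls with the
same length distribution"; wrapping is disallowed).
`classify_convergence()` keeps loops whose anchors each overlap an SMC3
peak and exactly one oriented CTCF motif — anchors with multiple motifs are
excluded rather than majority-voted, per the "unambiguous" requirement —
and classifies the ordered orientation pair as convergent `(+,-)`, tandem
(equal), or divergent `(-,+)`; the random expectation (0.25, 0.5, 0.25)
follows from enumerating the four equiprobable ordered pairs.
`interval_union_overlap()` merges transitively overlapping intervals across
sets into union sites labeled with their set membership; half-open
intervals that merely touch are not merged. A quadratic sweep serves as the
oracle in tests.

## iFRAP normalization and kinetics

`normalize_ifrap()` divides each channel by its own pre-bleach mean, takes
the unbleached-minus-bleached difference, and rescales so the first
post-bleach frame is 1. (The pre-bleach mean of the *difference* is ~0 by
construction, so the per-channel reading of "normalized to the mean of the
pre-bleach intensity" is the only workable one.) Degenerate traces — a
non-positive pre-bleach mean or a non-positive first post-bleach
difference — are rejected.

`fit_exponential()` fits `exp(-koff1 t)` or
`a exp(-koff1 t) + (1 - a) exp(-koff2 t)` by box-constrained
Levenberg-Marquardt (`minpack.lm::nls.lm`, the same optimizer family the
original analysis used). The double model is constrained to residence times
`1/koff1` in [1, 40] min and `1/koff2` in [90, 900] min with `a` in
[0, 1]; the single model to [0.5, 1000] min. Five deterministic starts
(constraint-box corners plus center) remove any seed dependence of the
optimizer; the best converged fit wins. Reported residence times are
exactly `1/koff`. `soluble_fraction()` is the clipped relative drop of the
unbleached signal at the first post-bleach frame.

The source analysis says only that some curves "could only be fitted" by
the bi-exponential; the criterion had to be chosen here. `select_model()`
uses a nested F-test on residual sums of squares at alpha = 0.05 *and*
requires both mixing components to be at least 5%, so a negligible second
component never wins on significance alone. A trace the single model
already fits to numerical precision is classified single directly, because
the F-ratio is 0/0-degenerate there. On simulated data this rule has a
measured type-I rate below the 7% budget and recognizes the well-separated
bi-exponential regime in at least 95% of replicates (see
`tests/testthat/test-acceptance.R`).

`ms_top3_normalize()` is the companion mass-spectrometry utility: areas of
a peptide's modification forms divided by the summed areas of the three
most intense unmodified reference peptides, which cancels protein-load
differences between immunoprecipitates; fractions are reported relative to
the total across forms.

## The synthetic-data generator

`make_ctcf_layout()`, `simulate_frap_trace()` and `make_toy_contact_map()`
produce every input the pipeline consumes. FRAP noise is additive i.i.d.
Gaussian with sd 0.02 — a typical normalized-intensity noise level for
confocal time series; the source states no noise model. Toy contact maps
are a translation-invariant `(1 + s)^(-decay)` background (default decay 1,
qualitatively matching interphase distance decay over bins) plus block-TAD
enrichments and 3 x 3 Gaussian corner dots, mirrored below the diagonal;
coincident dots sum. All generators are bit-reproducible from their seed
and restore the caller's RNG state.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: sequencing depth and distance-dependent Hi-C
noise, coverage biases that real balancing corrects, replication timing or
compartment structure, photobleaching drift and cell-to-cell variability in
FRAP, and loop/TAD calling itself (loop and TAD lists are inputs by
design). Directional claims validated here (lifetime up implies longer
loops and stronger long-range dots) are statements about the model, checked
under the stated study conditions, not re-measurements of the experimental
effect sizes.

## Problem sizes, numerical choices, degenerate inputs

Default desk-scale runs use 50,000 steps x 24 replicates with snapshot
stride 100 and 5-monomer map bins; the full study scale (850,000 steps x
480 replicates) is reachable through the same parameters. Kinetics
summaries in the acceptance suite use runs long relative to the mean
lifetime (e.g. 850,000 steps for a mean of 5000) because completed-event
means are censoring-biased when the horizon is short.

Numerical conventions worth knowing: contact maps are symmetrized exactly
on construction and validated nonnegative; iterative balancing stops at
relative row-sum deviation 1e-6 or 200 iterations; insulation is undefined
(NA, masked) within one window of the matrix edge; APA skips rather than
clips out-of-range loops and errors only if nothing remains; empty CTCF
tracks, zero-extruder snapshots, and all-zero ChIP signals are each either
valid (first two) or rejected with a specific message (the last). All
coordinates are 0-based half-open in files (BED convention) and 1-based
inside R objects; `read_bed()` reports the offending line number on
malformed input.

## Condition naming

One documented judgment call: the source methods text assigns the 5-fold
lifetime increase to STAG1 depletion, but its own results and figures
consistently associate *STAG2* depletion with longer-lived cohesin and
longer loops (depleting STAG2 leaves the stable STAG1 form). `cohesim`
follows the results: `condition_multiplier()` maps wild type to 1.0,
`stag1_rnai` to 0.5, and `stag2_rnai` to 5.0.

## A worked run

```{r workflow, eval = FALSE}
cfg <- run_config(n_steps = 10000, n_replicates = 4, snapshot_stride = 200,
                  seed = 1)
res <- run_workflow(cfg, out_dir = tempfile("cohesim_run_"))
```

This writes, per condition, the balanced contact map (`.rds` plus a
3-column text dump), the P(s) table, and the insulation bedGraph, together
with pooled loop lengths and a JSON summary holding the seed, parameters,
package version, and per-condition loop-contact scales.

## Known limitations

The 1D lattice has no excluded volume between non-extruder monomers and no
3D geometry except in the small Langevin mode; loading is uniform (no
NIPBL bias); the "average of three" extruders is a constant count, not a
loading equilibrium; the contact kernel's -3/2 exponent is an ideal-chain
idealization, so absolute contact values are not calibrated to read counts;
and compartments (A/B structure) are deliberately absent. These bound the
claims the package can support to the direction and relative magnitude of
residence-time effects.
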