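---
title: "Assembling docked IDP fragments into full-length complex models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling docked IDP fragments into full-length complex models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragcoalesce)
```

## The problem

Intrinsically disordered proteins (IDPs) have no stable fold in isolation
and often order only upon binding a folded receptor. A practical route to
modelling such complexes is *dock-and-coalesce*: short segments of the IDP
are docked rigidly to the receptor by an external engine, and the full
bound conformation is then assembled from mutually compatible segment
placements. `fragcoalesce` implements the coalesce phase. Its inputs are,
for each 9-residue sequence window of the IDP (windows overlap by 3
residues), a pool of docked fragment poses in the receptor coordinate
frame, each carrying one or more opaque score channels; its outputs are
ranked full-length backbone models with evaluation metrics.

The external machinery — fragment conformer generation, the rigid-body
docking itself, and the statistical potentials behind the score channels —
is deliberately outside this package. Score channels are treated as opaque
lower-is-better columns, and a seeded synthetic generator stands in for the
docking engine during testing and benchmarking.

## Pipeline and model

1. **Fragment selection.** Within each window pool, poses are ranked by the
   DI score, the sum of the Z-scores of two score channels
   (`di_score()`), and the best `top_k_di` (default 4500) are kept.
   Z-scores use the population standard deviation, computed within one
   window pool; a constant channel yields zeros.
2. **Pair filtering.** Every ordered pair of poses from two windows is
   screened by geometric cutoffs derived from distance distributions
   observed in disordered regions (`check_pair()`, `filter_pools()`):
   a clash test (minimum fragment–fragment atom distance ≥ 3 Å), bounds on
   the distance between the middle-residue CA atoms (≥ 6.5 Å for
   neighbouring windows, ≥ 3.8 Å otherwise, and ≤ 18.5 Å × window
   separation), and, for neighbouring windows, bounds that guarantee the
   3-residue overlaps can be reconciled: overlap residue distance within
   [5.2, 13.6] Å, every one of the 12 corresponding {N, CA, CB, C} overlap
   atom pairs within 10 Å (6 Å in strict mode), and cosine of the overlap
   angle ≥ 0.1.
3. **Extend-and-cluster assembly.** Allowed pose pairs of windows 1–2 are
   clustered by greedy leader clustering at a 4.0 Å RMSD cutoff on
   concatenated CA coordinates; survivors are extended by window 3 under
   the *all-pairs* constraint (a new pose must be compatible with every
   pose already in the partial path), clustered again, and so on
   (`assemble()`). The cluster size of the final stage is the component
   S\_C. An exhaustive enumerator (`brute_force_paths()`) provides the
   oracle against which assembly is tested.
4. **Path scoring.** Each full path receives four components: S\_E, the
   mean DI score of its poses; S\_O, the mean over window junctions of the
   mean square distance between the 12 corresponding overlap atoms; S\_C,
   the cluster size; and S\_R, a receptor-occupancy consensus (for every
   receptor residue, the number of paths within 5 Å heavy-atom distance is
   counted, and S\_R sums these counts over the residues a path touches).
   The Path Score combines them as

   S\_path = w5 · [w1 Z(S\_E) + w2 Z(S\_O) + w3 Z(−S\_C) + w4 Z(−S\_R)] +
   (1 − w5) · min{Z(S\_E), Z(S\_O), Z(−S\_C), Z(−S\_R)}

   with Z-scores taken across all paths of one complex, lower better. The
   minimum-Z term rescues paths detected by only some of the components.
   Default weights are (0.5, 0.1, 0.3, 0.1) with w5 = 0.3. The 1000 paths
   with the lowest Path Score are kept.
5. **Merging.** A kept path becomes a single backbone by copying
   singly-covered residues and averaging the coordinates of every
   multiply-covered atom (`merge_path()`). `chain_stats()` reports the
   fraction of consecutive CA–CA distances inside [3.75, 4.0] Å — the
   continuity defect that a downstream force-field refinement (outside this
   package) would repair.
6. **Model scoring and evaluation.** Merged models are re-ranked by the
   Model Score, the same combination applied to four opaque model channels,
   with default weights (0.1, 0.2, 0.3, 0.4) and w5 = 0.3. An optional
   pre-filter keeps models whose agreement with externally predicted
   receptor interface residues has Z ≥ 1.5. When a native structure is
   available, models are evaluated with fnat, I-RMSD, L-RMSD, the CAPRI
   class, pooled per-window RMSD, rank of first hit (RFH), BF10 and recall.

## Synthetic data: what it emulates, and what it does not

`generate_complex()` builds a polyalanine 3-helix bundle receptor from
ideal helix parameters (1.5 Å rise, 100°/residue, 2.3 Å CA radius) and
grows a self-avoiding native chain along its surface: CA–CA steps of
3.8 ± 0.05 Å, per-step turn angles of 30–60°, and a ligand–receptor
surface distance held in [3.2, 5.0] Å. The turn-angle range and global
span caps keep 4- and 6-residue spans of the native chain inside the bands
the pair filter accepts, which real disordered chains satisfy by
construction of those cutoffs. Pools contain the native window cut, rigid
near-native perturbations at chosen RMSD levels (default 1–6 Å, produced
by a bisection on a jointly scaled random rotation plus translation, exact
to the requested RMSD), optional *decoy chains* — additional self-avoiding
surface walks cut into windows, emulating the tendency of docking engines
to place fragments coherently at a few wrong surface sites — and poses
scattered at random orientations over the surface. Score channels are the
true pose RMSD plus Gaussian noise sized through the normal
rank-correlation relation so that their Spearman correlation with the
truth is approximately a requested ρ (default 0.7, a mid-strength,
realistic signal).

What the generator does *not* emulate: physical energetics, sequence
dependence, conformational diversity of fragment predictions, receptor
flexibility, and crystallographic artefacts. Passing tests on synthetic
complexes therefore demonstrates the correctness and the statistical
behaviour of the coalesce machinery — not docking accuracy on real
proteins.

## Numerical and design choices

* **Backbone atom set.** All overlap computations use {N, CA, CB, C} per
  residue; a virtual C-beta (1.53 Å bond, 110.5° angles, L-chirality) is
  constructed for glycine. The carbonyl O never enters the atom set.
* **Windows.** Tiling starts at residue 1 with stride 6. When the length
  is not 9 + 6k, one extra window anchored at the C-terminus is appended;
  its enlarged overlap is averaged like any other multiply-covered region.
* **Middle residue.** The midpoint distance uses the CA of residue 5 of
  each 9-residue fragment.
* **Clash exclusion at junctions.** For neighbouring windows, atom pairs
  whose implied chain separation is ≤ 1 residue are excluded from the 3 Å
  clash test: a correct continuation necessarily places the shared overlap
  residues on top of each other and bonds the flanking residues, so those
  distances are small in every continuous chain.
* **Overlap-pair reading.** The overlap atom-pair criterion is applied as
  a cap on the maximum of the 12 distances: 10 Å by default, 6 Å in
  strict mode.
* **Clustering.** Greedy leader clustering visited in ranking order with
  deterministic id tie-breaks; a cutoff of 0 disables merging entirely.
  Cluster size counts the member paths of the current clustering stage.
  Internally the pass is blocked so that distances to all current
  representatives come from one matrix product; the semantics are
  identical to the sequential definition and are tested against an
  independent step-by-step reference.
* **Degenerate cases.** Z-scores of a constant vector are zero; a single
  surviving path is ranked trivially; an empty interface prediction or a
  filter that rejects every model passes all models through with a
  warning.
* **CAPRI thresholds.** High: fnat ≥ 0.5 and (L-RMSD ≤ 1 or I-RMSD ≤ 1);
  medium: fnat ≥ 0.3 and (L-RMSD ≤ 5 or I-RMSD ≤ 2); acceptable:
  fnat ≥ 0.1 and (L-RMSD ≤ 10 or I-RMSD ≤ 4). The I-RMSD interface is
  defined at 10 Å heavy-atom distance in the native and superposes the
  combined receptor+ligand interface backbone.
* **Weight training.** A two-stage grid search: (w1..w4) on the 0.1-step
  simplex with w5 = 1, then w5 over 0.1–1.0; objectives are maximin
  recall (paths; hits at pooled RMSD ≤ 10 Å) or mean rank of first hit
  (models; hits at CAPRI acceptable or better). Ties resolve to the
  lexicographically smallest tuple, making training fully deterministic.

## Problem sizes used in tests and benchmarks

The package's tests run the whole machinery at desk scale rather than at
the scale of a production docking campaign: oracle-equivalence checks use
up to 3 windows × 20 poses (small enough for exhaustive enumeration);
consensus-selection experiments use single-window pools of 500 poses with
a 15% selection fraction, matching the production ratio of 4500 kept from
30000; and the end-to-end recall experiment uses 6-window complexes with
200-pose pools (native + 60 near-native + 4 decoy chains × 25 + 39
random). At these pool sizes the path-stage clustering cutoff is set to
2.5 Å rather than the production 4.0 Å: with two orders of magnitude
fewer poses per window than a real campaign, the coarser production cutoff
collapses the path set to a few hundred representatives, which would make
the "1000 kept paths" stage of the pipeline trivial; 2.5 Å keeps the
assembled path set in the several-thousand range so that selection and
recall remain meaningful, mirroring the production regime of roughly 10^5
paths reduced to 1000.

## Known limitations

* Overlap averaging produces the documented *initial* structure only; the
  merged backbone is locally distorted at junctions, and the package
  quantifies (but does not repair) this. Measured on assembled synthetic
  paths, averaging lowers the strict [3.75, 4.0] Å CA–CA band fraction
  relative to first-copy concatenation — it trades one large junction
  break for several small distortions, which a narrow band penalises;
  repairing continuity is the job of the downstream refinement that this
  package excludes.
* Stagewise clustering guarantees that a merged path lies within the RMSD
  cutoff of its representative at the stage it is merged, on the windows
  covered so far. Over subsequent extension and clustering stages the
  discrepancy can accumulate slightly, so a handful of enumerable paths
  can end up marginally beyond the cutoff from every surviving
  representative (worst case observed across 100 random instances:
  4.05 Å at a 4.0 Å cutoff).
* The receptor is treated as rigid everywhere.
* S_R counts every receptor residue; no solvent-accessibility screen is
  applied before the consensus count.
* Real-data I/O covers single-conformer PDB ATOM records; mmCIF,
  insertion codes and alternate-location averaging are out of scope.
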