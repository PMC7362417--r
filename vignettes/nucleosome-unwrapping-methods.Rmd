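---
title: "Quantifying nucleosome DNA unwrapping, contacts, and assembly geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleosome DNA unwrapping, contacts, and assembly geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleowrap)
```

## Scope and model

A nucleosome core particle (NCP) wraps ~146 base pairs of DNA in ~1.65
superhelical turns around a histone octamer (two copies each of H3, H4,
H2A, H2B).  The terminal stretches of this wrap transiently detach and
rebind ("DNA breathing"), and histone variants such as H2A.B shift the
balance strongly toward the unwrapped side.  `nucleowrap` implements the
standard structural observables used to quantify this behaviour on
conformational ensembles (multi-model PDB trajectories, all-atom or
coarse-grained beads):

* a **terminal unwrapping counter** based on minimum heavy-atom distances
  to the histone core,
* **heavy-atom contact statistics**: per-residue profiles, region totals,
  copy/replica averaging, and the native-contact fraction (q factor),
* **trajectory geometry**: RMSD after least-squares superposition,
  end-to-end distances, radius of gyration, per-residue RMSF, and
  three-point linker-DNA angles,
* **histogram peak summaries** of distance distributions, and
* a **synthetic conformation generator** that produces wrapped particles,
  partially peeled states, stochastic breathing trajectories, and
  chromatosomes with articulated linker arms — all with planted ground
  truth, so that every analysis can be validated against known answers.

The package analyses conformations; it does not run molecular dynamics,
and it makes no attempt to emulate any force field.

## The unwrapping counter

At either terminus, the number of unwrapped base pairs $N$ is the length
of the maximal run of consecutive terminal base pairs whose minimum
heavy-atom distance to the histone core exceeds a cutoff $d_c$ (default
6.0 Å): the entry scan walks base pairs $1, 2, \dots$ and the exit scan
$n_{bp}, n_{bp}-1, \dots$, each stopping at the first base pair at or
below the cutoff.  The total is the sum over the two termini.  Three
boundary decisions are deliberate and recorded in every output manifest:

* **Tie rule.** A base pair at exactly $d_c$ stops the scan (it counts as
  wrapped).  The two-sided definition ("> 6.0 Å to count, < 6.0 Å to
  stop") leaves equality undefined; stopping is the conservative choice.
* **Bulges.** A base pair farther inward that exceeds the cutoff never
  contributes: the scan semantics are "maximal terminal run", which is the
  only reading consistent with counting unwrapping *at a terminus*.
* **Core definition.** The histone core defaults to all heavy atoms of all
  histone chains.  Flexible tails materially change minimum distances, so
  `core_selection()` can exclude annotated tail regions; neither choice is
  asserted as canonical, and the default in effect is echoed in output
  metadata.

Minimum distances and contact counts use an exact cell-list neighbour
search (grid cells of edge $d_c$, 27-cell neighbourhoods) implemented in
C++; the test suite proves it equal to an exhaustive $O(n^2)$ double loop
on hundreds of random instances, and the distance rule is applied with
strict inequality in both routes.

## Contacts, regions, and the q factor

A contact is any pair of heavy atoms, one from each of two disjoint
components, strictly closer than 6.0 Å.  Per-residue profiles against a
partner component are averaged in a fixed order: over frames first, then
over the two copies of the histone (copies pair by chain-id order unless a
copy map is supplied), then mean ± SD across replicas.  The SD across
replicas is the population SD (divisor $n$), the convention used when
quoting mean ± SD over a small fixed set of replicate simulations.
Region totals sum the per-residue means over an annotated residue range
per replica before the cross-replica statistics, which makes them additive
over any partition of the axis; an empty region is an error, never a
silent zero.

Shipped region presets cover the H2A-family regions commonly analysed
(N-terminal tail, L2 loop, docking domain, C-terminal tail, H3 αN).  The
L2 ranges follow the sequences 74-KKTRII (H2A) and 78-GERNII (H2A.B) and
the H2A C-terminus is 107–129 with the docking domain 80–106; the
remaining ranges are reconstructions by sequence convention and are meant
to be edited to the numbering of the structures actually analysed.

The q factor of a conformation is the fraction of the reference
structure's native contacts that are formed in it.  Native contacts are
enumerated under the strict rule (excluding intra-residue pairs and, at
residue granularity, sequence neighbours $|i-j| < 3$); "formed" in a
non-reference frame means closer than `tolerance_factor` × cutoff.  The
reference never defines formation for other frames, so the tolerance is
explicit: the default 1.2 follows common native-contact practice and keeps
q(reference) = 1, while a factor of 1 recovers the strict rule.

## Geometry metrics

Superposition is the least-squares (Kabsch/SVD) rotation with reflections
disallowed.  RMSD defaults to fitting on the same selection it measures
(e.g. all DNA P atoms), with the fit group exposed because published RMSD
values rarely state it.  RMSF uses a two-pass reference: frames are first
aligned to frame 1, their mean is taken, frames are re-aligned to that
mean, and fluctuations are measured about the re-aligned mean; per-residue
values average the residue's selected atoms.  The end-to-end distance is
measured between the first P atom of the entry base pair and the first P
atom of the exit base pair.  Three-point angles use `atan2` of cross and
dot products, which is stable near 0° and 180°.

## The synthetic generator

The generator is a geometric stand-in for simulation ensembles, designed
so that every analysis has a planted, provable answer — not a physical
model of DNA mechanics.

* **Wrapped particle.** DNA phosphates lie on a superhelix of radius
  41.8 Å, pitch 25.9 Å per turn, and 1.65 turns for 146 bp (canonical
  core-particle geometry; all parameters configurable).  The second
  strand's atoms, and any extra per-bp atoms, sit within 2 Å of the
  phosphate.  The histone core is a bead lattice on a cylinder of radius
  `radius - 3` with 3 Å spacing, split into eight chains so copy-resolved
  analyses apply.  The build asserts at construction time that every base
  pair is within the 6 Å cutoff of the core — the wrapped state is
  verified, not assumed — and uses no randomness.
* **Peeling.** `peel_ends()` displaces the first/last $n$ base pairs
  radially outward (the local outward normal of the superhelix) by
  `cutoff + lift`.  Because the core lies at least the 3 Å radial gap
  further in, every peeled base pair clears the core by more than
  `cutoff + lift`, which guarantees the planted counts are exactly
  recoverable for any `lift > 0`.
* **Breathing.** Each DNA end follows an independent two-state Markov
  chain (closed/open) with per-frame transition probabilities `k_open`,
  `k_close`, starting closed; open frames peel that end by
  `n_unwrap_open` base pairs (default 15, the scale reported for
  variant-destabilised particles).  The stationary open occupancy is
  $k_{open}/(k_{open}+k_{close})$ and the occupancy estimator's standard
  error carries the lag-1 autocorrelation correction
  $\sqrt{(1+\rho)/(1-\rho)}$ with $\rho = 1 - k_{open} - k_{close}$
  (`breathing_occupancy_theory()`).  One seeded generator per call makes
  trajectories bit-identical for a fixed seed.
* **Chromatosome.** Two straight linker arms (default 20 phosphates at
  the superhelical rise per bp) attach at the entry and exit termini, plus
  an optional linker-histone bead cluster between them.  Arm directions
  are solved by fixed-point iteration so that the measured angles
  P1–P2–P4 and P3–P4–P2 (terminal/proximal phosphates of arms 1 and 2)
  equal the targets to machine precision; Gaussian target noise propagates
  with the specified spread.  The in-plane orientation is chosen from a
  deterministic candidate list (away from the core centre, radially
  outward, axially, then a 30° azimuth sweep), taking the first
  construction whose arms neither pierce the bead-core cylinder nor
  overlap a bead.  Because the entry–exit chord passes through the core
  cylinder at the default wrap geometry, target angles below roughly 40°
  are geometrically infeasible for straight arms and raise an error rather
  than silently bending the arms.

What the generator does *not* emulate: sequence-dependent geometry,
electrostatics, DNA elasticity, force-field-specific unwrapping
magnitudes.  Passing tests on synthetic data therefore demonstrate that
the *measurements* are correct (counters count what was planted, angles
match their construction, estimators recover stationary laws), not that
any simulation result is reproduced.

## Distribution summaries

`summarize_distribution()` histograms a value series with fixed 2 Å bins,
smooths the density with a centred 3-bin moving average (partial windows
at the edges), and reports local maxima above 5% of the maximum smoothed
density as peaks, sorted ascending.  These defaults resolve the
qualitative multi-peak structure of end-to-end distance distributions
(e.g. a planted 72/95/128 Å trimodal mixture) while suppressing sampling
noise at $n \approx 10^4$; all three parameters are configurable and
echoed in the output.

## Replicates, determinism, and problem sizes

`run_pipeline()` builds each replica from `seed + replica - 1`, runs the
requested stages, and writes per-replica tables, cross-replica aggregates
(mean ± population SD per frame), distribution summaries, and a JSON
manifest embedding the configuration, an MD5 hash of its scientific
content (output paths excluded), the package version, and every
convention in effect.  Re-running with the same configuration reproduces
all numeric outputs byte for byte.

The test suite validates the unwrapping counter on the full grid of
planted (entry, exit) counts up to 30 base pairs per end on the 146-bp
particle, contact counting against the exhaustive oracle on 300-vs-400
atom instances, breathing occupancy over 10,000-frame trajectories at
five seeds, and peak recovery on 10,000-draw mixtures — sizes chosen so
the whole suite completes in a couple of minutes on one CPU while leaving
the statistical checks well-powered.

## Known limitations

* The bead-core cylinder has no histone fold; region annotations on
  synthetic histones are positional conventions, useful for exercising
  the region machinery, not biology.
* Straight-arm chromatosomes cannot realise small P1–P2–P4 angles (see
  above); bent or flexible linkers are out of scope.
* Coarse-grained inputs are treated as all-heavy beads and analysed with
  the same 6 Å cutoff unless overridden; the cutoff's transferability
  between resolutions is the user's call.
* The PDB reader handles the single- and multi-model files the package
  writes and crystal-style files with standard columns; mmCIF, solvent
  handling, and binary MD trajectory formats are out of scope.
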