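# nucleowrap

Structural analysis of nucleosome DNA unwrapping, histone contacts, and
assembly geometry.

## The problem

A nucleosome core particle (NCP) wraps ~146 base pairs of DNA around a
histone octamer (two copies each of H3, H4, H2A, H2B).  The terminal
stretches of the wrap transiently detach and rebind ("DNA breathing"),
and histone variants such as H2A.B — with an altered L2 loop, a truncated
docking domain, and no C-terminal tail — shift this balance strongly
toward unwrapping, with consequences for nucleosome stability, assembly,
and linker-histone binding in the chromatosome.  Quantifying these
effects on conformational ensembles requires a small set of standard
observables, applied consistently across replicate trajectories and
histone copies.

`nucleowrap` is for structural bioinformaticians and simulators who have
such ensembles (multi-model PDB, all-atom or coarse-grained beads) and
want reproducible numbers out of them.

## What it computes

* **Unwrapped base pairs.**  At either terminus, N is the maximal run of
  consecutive terminal base pairs whose minimum heavy-atom distance to
  the histone core exceeds 6.0 Å, scanning inward and stopping at the
  first base pair at or below the cutoff; the total adds the two termini.
  Interior "bulges" beyond the cutoff never count, and a base pair at
  exactly 6.0 Å counts as wrapped.
* **Contacts.**  A contact is any heavy-atom pair between two components
  strictly closer than 6.0 Å.  Per-residue profiles are averaged over
  frames, then over the two histone copies, then reported mean ± SD
  (population) across replicas; region totals (Nt, L2, docking domain,
  Ct, H3 αN, ...) sum annotated residue ranges.
* **q factor.**  The fraction of a reference structure's native contacts
  formed in a conformation: q = 1 at the reference, falling toward 0 as
  an assembly comes apart.
* **Geometry.**  RMSD after least-squares (Kabsch) superposition,
  entry-to-exit P-atom end-to-end distances, radius of gyration
  √(Σwᵢ|rᵢ−r̄|²/Σwᵢ), per-residue RMSF about the mean structure, and the
  chromatosome linker-arm angles P1–P2–P4 and P3–P4–P2.
* **Distribution summaries.**  Fixed-width histograms with smoothed-density
  peak detection, for multi-peak end-to-end distance distributions.
* **Synthetic ground truth.**  A generator of idealized wrapped NCPs
  (DNA phosphates on a 41.8 Å / 1.65-turn superhelix around a bead core),
  peeled states with planted unwrap counts, two-state stochastic
  breathing trajectories with exact state labels, and chromatosomes with
  linker arms constructed to hit target angles exactly.

## Worked example

```r
library(nucleowrap)

# a fully wrapped 146-bp particle, wrapped by construction
ncp <- make_wrapped_ncp()
count_unwrapped(ncp)
#> UnwrapRecord: entry 0 + exit 0 = 0 unwrapped bp

# peel 15 bp off the entry terminus; the counter recovers the planted truth
count_unwrapped(peel_ends(ncp, 15, 0, lift = 4))
#> UnwrapRecord: entry 15 + exit 0 = 15 unwrapped bp

# stochastic breathing: each end opens with prob 0.1 and closes with 0.3
# per frame, peeling 15 bp while open
tr <- make_breathing_trajectory(
  superhelix_spec(),
  breathing_spec(k_open = 0.1, k_close = 0.3, n_unwrap_open = 15,
                 n_frames = 2000, seed = 1))
us <- unwrap_series(tr)
us$stat
#> SeriesStat: 2000 frames, mean 7.98, sd 9.249

# occupancy of the open state at the entry end vs the stationary law
mean(us$records$n_entry > 0)
#> [1] 0.296
breathing_occupancy_theory(0.1, 0.3, 2000)$p
#> [1] 0.25   (estimate is within 3 autocorrelation-corrected SEs, 0.058)

# chromatosome linker arms built to 90 degree targets, measured back exactly
ch <- make_chromatosome(chromatosome_spec(angles = c(90, 90)))
linker_angle_series(ch)
#>   frame angle_P1_P2_P4 angle_P3_P4_P2
#> 1     1             90             90
```

The mean of 7.98 unwrapped bp is what two ends × 15 bp × ~0.27 realized
open-state occupancy imply; the SD of 9.2 reflects the bimodal open/closed
series rather than noise.

End-to-end pipelines (generation → metrics → aggregation → manifest) run
from a config list or YAML file via `run_pipeline()`, and
`inst/cli/nucleowrap.R` exposes the same operations as shell subcommands
(`build-synthetic`, `unwrap`, `contacts`, `qfactor`, `rmsd`, `endtoend`,
`rg`, `rmsf`, `angles`, `report`).

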