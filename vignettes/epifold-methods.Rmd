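---
title: "Methods: a coarse-grained ligand-binding model for epistasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a coarse-grained ligand-binding model for epistasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epifold)
```

## The model

epifold simulates a small ligand-binding protein as an off-lattice chain of
point monomers, one bead per residue. Three potential terms define the
energy, all carried in reduced units of `k_B * T0` with `T0 = 302.15` K:

* **Bonds.** Consecutive monomers interact harmonically,
  `U(r) = kappa/2 (r - l)^2`, with bond length `l = 3.8` Å and stiffness
  `kappa = 11 k_B T0 / Å^2`. The printed stiffness is interpreted per
  square Angstrom so the expression is dimensionally consistent.
* **Non-bonded pairs.** Monomers at chain separation of two or more
  interact through potentials assembled from the unit Morse function
  `mu(r) = exp(-2 alpha (r - l)) - 2 exp(-alpha (r - l))` with range
  `alpha = 2.1` Å⁻¹. Every pair potential is the sum of an
  excluded-volume core of strength `eps_core = 2` and a residue-specific
  tail of signed strength `eps_prime`; it is continuous, equals
  `eps_prime` at `r = l`, and vanishes at large separation. For
  attractive pairs (`eps_prime < 0`) the minimum sits at `r = l` with
  depth `|eps_prime|`. At the step radius the left-hand branch carries
  the step value (`theta(0) = 1` on the `r <= l` side, 0 on the other),
  which is the unique half-open convention that makes the two published
  branches agree at `r = l`.
* **Residue specificity.** `eps_prime = eps_core * E'_ij / E_o`, where
  `E'` is a quasi-chemical contact-energy table rescaled with threonine
  as the reference solvent, `E'_ij = E_ij - E_iT - E_jT + E_TT`, and
  `E_o` is the mean absolute rescaled energy over the upper triangle.
  The bundled table (`inst/extdata/contact_energies.txt`) holds
  Miyazawa–Jernigan-style statistical-potential values transcribed from
  the widely reproduced 1996 literature; the file is swappable and any
  symmetric 20×20 table in the same layout can be supplied. After
  rescaling, hydrophobic–hydrophobic pairs (W–W, L–I) are attractive and
  like-charged pairs repel, while opposite charges (K–E, R–E) attract
  strongly — the qualitative structure the model relies on.

## Langevin propagation

Kinetics follow the Langevin equation with monomer mass
`m = 1.66e-22` g, friction `gamma = 10` ps⁻¹ and time step
`dt = 0.01` ps. The integrator is the BAOAB splitting
(Leimkuhler–Matthews): two deterministic half-kicks and half-drifts
around an exact Ornstein–Uhlenbeck velocity refresh. Any scheme that
reproduces equipartition and free diffusion at this time step is
acceptable for this model class; BAOAB was chosen for its configurational
accuracy at moderate friction and its exact `gamma = 0` reduction to
velocity Verlet, which the energy-conservation tests exploit (the
thermostat constructor therefore accepts `gamma = 0` even though
production runs always use positive friction). All noise is drawn from
R's RNG, so a seed makes whole trajectories bit-reproducible; each
replica and stage derives its own 32-bit seed from the base seed, making
ensembles independent of execution order.

Units: lengths in Å, times in ps, energies in `k_B T0`. The printed mass
converts once to reduced units via `1 g Å²/ps² = 10 J`; temperatures in
Kelvin enter as `T / T0`.

## Folding and quenching

Each replica starts from a self-avoiding random coil (exact bond lengths,
non-consecutive separations at least `0.8 l`), with Maxwell–Boltzmann
velocities, and runs three stages: `t_fold` at `T_fold = T0`, then `t_q`
at `T1 = 218.2` K and again at `T2 = 134.3` K. The folding stage sits
below the folding-transition estimate `T_f ≈ 1.25 T0`, which is taken as
a configuration constant rather than re-estimated from specific-heat
scans. `t_q` defaults to `t_fold / 3` and applies to each quench stage
(the alternative reading — total — is a configuration away).

The classic chain-length estimate for the folding time reads
`N^3 e^N dt_f`. Evaluated literally it yields ~10^9 ps already for a
12-mer, which no simulation executes, and the exponent is ambiguous in
common transcriptions. `folding_time()` therefore exposes three
variants — `literal`, `sqrt_exponent` (`N^3 e^sqrt(N) dt_f`, the
default) and `fixed` (a user cap) — and the fixtures use capped times.

## Reference fold and order

The dominant energy basin of an ensemble of `N` replicas is summarized
by a reference structure and its `floor(3N/4)` closest members.
Structures are aligned by iterated trimmed-core superposition: a
least-squares fit (improper rotations allowed, so mirror folds compare
equal) on the current matched set, re-selection of the `floor(2n/3)`
closest monomer pairs, repeated until the matched set repeats; at most
50 iterations, oscillations resolved by keeping the lowest-RMS iterate.
The reference search is restricted to ensemble members (exhaustive,
O(N²) alignments) rather than admitting averaged structures — averaging
blurs side-by-side basins, and a member is always a physically realized
conformation.

Per-monomer order is the RMS fluctuation of aligned basin members about
the reference position; a monomer is *ordered* when the fluctuation is
below `lindemann_c * l`. The classic Lindemann melting criterion uses
roughly 0.10–0.15 of the interparticle spacing for crystals; quenched
heteropolymer ensembles are looser, so the default is `lindemann_c =
0.25`, exposed as a parameter and reported in logs. A sequence is
*viable* when at least 15 monomers are ordered.

## Docking and activity

The ligand is a single monomer. A spherical shell of near-uniform points
(generalized spiral; ~10^4 points at production settings) is centered on
the monomer centroid and contracted in steps of 0.25 Å from just outside
the structure (max centroid distance plus `2l`) to the innermost
monomer, evaluating the ligand energy at every point. Site monomers
attract via the unit Morse potential. Non-site monomers contribute the
excluded-volume core — the left Morse branch shifted to vanish at
`r = l`, a non-negative, purely repulsive term. The unshifted branch
alone would be attractive (down to −1) just inside contact and would
let arbitrary surface grooves outcompete the binding site, contradicting
both the term's published role ("repulsive") and the expectation that an
isolated site monomer binds the ligand at the Morse minimum; the shifted
core is the reading consistent with the potentials' own excluded-volume
construction.

A replica is *active* when every pairwise distance within the binding
complex (site monomers plus docked ligand) lies within 1 Å — inclusive
at the boundary — of a target state. The target is built by averaging
the complex geometry over replicas deemed properly formed by a
provisional target; fixtures supply that provisional target directly,
which breaks the circularity in a controlled way.

## Fitness, mutations, epistasis

Fitness is `P = N* / N`, the fraction of active replicas, by default
over `N = 127` replicas. Repeated measurements of `P` are binomial, so
the fitness-distribution width at activity `p` is `sqrt(p(1-p)/N)`;
`fitness_error()` reports both the sample SD and the Gaussian-fit width.

Mutations are proposed under an exchange matrix with row-normalized
probabilities `p(u, v)`; a move is allowed when `p(u, v) > 0`. The
default matrix is computed from the standard genetic code — counts of
single-nucleotide codon changes between residues — which realizes
"roughly consistent with the genetic code" without external data; an
empirical count table can be read from file. Targets are sampled
uniformly over the allowed set by default (the support is the published
constraint; proportional sampling is available). `evolve()` is a
deliberately simple single-lineage walk with a pluggable acceptance
rule; it generates usable sequences but makes no claim to reproduce any
particular evolutionary protocol.

Epistasis of a mutation pair is `eps = dP12 - dP1 - dP2`, the deviation
of the double-mutant fitness change from additivity. `pair_scan()`
samples unordered site pairs uniformly, measures the three mutants, and
records fitness changes, `eps`, and the inter-site distance `R` in the
initial reference fold; `R < 1.5 l` (strict) marks direct contact.
Records pass through the lambda filter — keep when `dP12 >= lambda` or
both singles are — which is monotone in lambda. With independent errors
`dP` per measurement, quadrature propagation gives `sqrt(2) dP` for the
sum of singles and `sqrt(3) dP` for `eps`; the linear alternative
(`2 dP`, `3 dP`) is selectable but the independence premise forces
quadrature as the default. The significance multiplier on `delta-eps`
defaults to 3 and is configurable, since the published criterion is
ambiguous between the two error conventions.

## Fixtures and what they do (and do not) show

`make_fixture("minimal-folder")` builds a self-contained test system: the
12-mer ladder `LKLELKLELKLE` (alternating hydrophobic and opposite
charges fold it into a reproducible basin), 16 replicas, `t_fold =
100` ps capped, `t_q = 200` ps, a 1000-point docking shell. The binding
site is selected by the generator itself: among monomer pairs that are
chain-distant (separation ≥ 3) but in contact in the reference fold, it
keeps the pair whose docked complex is most consistently reproduced
across the pilot replicas — a miniature of the way binding sites arise
at reproducible surface features during evolution. Under the shipped
seeds this yields around 80–90% active replicas, so fitness sits in a
regime where mutations move it in both directions.

These problem sizes (12–16 residues, 16 replicas, hundreds of ps) are
the package's chosen desk scale: large enough to exercise folding,
basin selection, docking and scanning end to end, small enough to run a
full pair scan in minutes. What passing fixtures demonstrate is the
correctness and reproducibility of the machinery — not the statistical
claims of production scale (127 replicas, ~27-mers, thousands of pair
mutations), which require cluster-scale computation and the original
evolved sequences. The synthetic generator also does not emulate
secondary structure, solvent, or side chains; those are outside the
model class itself.

## Numerical choices

* Step-function convention at `r = l`: half-open, left branch carries
  the step value (forced by continuity).
* Singularity guard: coincident non-bonded monomers are capped at
  `r = 1e-8` Å with a warning; forces stay finite.
* Integration failure (non-finite coordinates) reports the offending
  step index and flags the replica; ensembles carry per-replica failure
  flags rather than aborting.
* All fractional counts (`2n/3` matched pairs, `3N/4` basin members)
  use `floor`; ordering ties break toward the lowest index.
* Activity tolerance is inclusive (`<= 1` Å).
* PDB output is CA-only, one MODEL per replica, reference first and
  members in decreasing alignment quality; coordinates round-trip at
  PDB precision (0.001 Å).

## Limitations

The reference search is O(N²) in alignments and exhaustive over
members; for very large ensembles a pre-clustering step would be
needed. The docking sweep resolves poses only to the shell spacing
(~0.2–0.4 Å at fixture settings), which is adequate for a 1 Å activity
tolerance but not for finer geometric questions. Fitness landscapes of
12-mers are rugged: different base seeds can fold a minority of
replicas into competing basins, which is physical for this model but
means fixture activity fractions are regression-pinned to their seeds,
not universal constants.
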