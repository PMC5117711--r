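# epifold

Epistasis — the non-additive effect of pairs of mutations on fitness — is
often observed between protein sites that are far apart in the folded
structure, and the mechanism behind such long-range interactions is hard to
study in real proteins because it lives in partially folded and misfolded
ensembles. `epifold` implements a complete coarse-grained model of
ligand-binding proteins in which that question can be simulated directly:
off-lattice bead chains fold by Langevin dynamics under Morse-type pair
potentials scaled by a residue contact-energy table, a single-monomer
ligand is docked onto each folded replica by a spherical shell sweep, and
fitness is the fraction of replicas whose binding complex matches a target
geometry. The package is for structural bioinformaticians and
protein-evolution modelers who want a self-contained, reproducible
implementation of this model class at configurable scale.

## The model in brief

* **Chain energetics.** Bonds: `U(r) = κ/2 (r − l)²` with `l = 3.8` Å,
  `κ = 11 k_BT₀/Å²`. Non-bonded pairs: excluded-volume core of strength
  `ε = 2` plus a residue-specific Morse tail of signed strength
  `ε′ = ε·E′_μν/E_o`, where `E′` is a threonine-referenced rescaling of a
  Miyazawa–Jernigan-style contact table. Energies are in units of
  `k_BT₀`, `T₀ = 302.15` K.
* **Folding.** Each of `N` replicas (default 127) runs from a random coil
  through fold (at `T₀`) and two quench stages (218.2 K, 134.3 K) under a
  BAOAB Langevin integrator (`m = 1.66·10⁻²² g`, `γ = 10 ps⁻¹`,
  `Δt = 0.01 ps`), fully seeded and bit-reproducible.
* **Reference fold and order.** The dominant basin is the `⌊3N/4⌋`
  members closest (iterative trimmed-core superposition, reflections
  allowed, `⌊2n/3⌋` matched pairs) to the best reference member; ordered
  monomers are those fluctuating less than a Lindemann fraction of `l`.
* **Fitness.** `P = N*/N`: a replica is active when all pairwise
  distances in its docked binding complex are within 1 Å of the target.
* **Epistasis.** For a random site pair with single- and double-mutant
  fitness changes `ΔP₁, ΔP₂, ΔP₁₂`:

  ε = ΔP₁₂ − ΔP₁ − ΔP₂

  with mutations proposed under genetic-code-compatible exchange rules,
  a λ-viability filter (`ΔP₁₂ ≥ λ` or both `ΔPᵢ ≥ λ`), inter-site
  distance `R` from the reference fold (contact when `R < 1.5l`), and a
  quadrature error model `δε = √3·δP`.

## Worked example

The bundled fixture generator builds a fast 12-mer system end to end:
folding, reference-fold selection, site/target construction, docking.

```r
library(epifold)

epsilon(dP12 = -0.13, dP1 = -0.61, dP2 = -0.29)
#> [1] 0.77

fx <- make_fixture("minimal-folder", seed = 42)
proto <- fitness_protocol(n_replicas = fx$n_replicas, schedule = fx$schedule,
                          table = fx$table, params = fx$params,
                          thermostat = fx$thermostat, sweep = fx$sweep,
                          n_points = fx$n_points)
fitness(fx$sequence, fx$site, fx$target, proto, base_seed = 42)
#> <fitness_measurement> P = 13/16 = 0.8125

recs <- pair_scan(fx$sequence, 10, proto, base_seed = 42,
                  site = fx$site, target = fx$target, ref = fx$reference)
summarize_epistasis(recs, lam = -1)
#> <epistasis_summary> n = 10 (lambda = -1)
#>   sigma(eps) = 0.1208 (MLE 0.1146), mean = 0.1125
#>   significant |eps| > 3 * 0.0641: 20.0%
```

The fitness line says 13 of 16 replicas folded and docked into the target
binding geometry (`P ≈ 0.81`). The scan mutates ten random site pairs,
re-measures fitness for each single and double mutant, and summarizes the
epistasis distribution: here a width `σ(ε) ≈ 0.12` with 20% of pairs
exceeding three times the propagated measurement error — including pairs
separated by well over the direct-interaction range `1.5l = 5.7` Å, i.e.
long-range epistasis. `autoplot(recs)` plots ε against `R`;
`autoplot()` on the summary shows the ε histogram with its Gaussian fit.

A command-line interface wrapping the same functions is installed at
`system.file("cli", "epifold", package = "epifold")` with subcommands
`fold`, `reference`, `dock`, `fitness`, `scan-pairs`, `report`, `fixture`.

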