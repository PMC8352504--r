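---
title: "Guided sampling of RNA secondary-structure energy landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guided sampling of RNA secondary-structure energy landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

An RNA sequence does not fold into a single structure: it moves through an
energy landscape whose states are the pseudoknot-free secondary structures
`Omega`, connected by a move set `M` (here: insertion or removal of a single
base pair), and valued by an energy function `E`. Kinetically relevant
features of this landscape — metastable basins, the saddles separating them —
are exactly the features that plain thermodynamic (Boltzmann) sampling is
worst at finding, because its draws concentrate in the lowest-energy basin.
`rnascape` implements an adaptive remedy: sample, detect which basin is
over-represented, add a small repellent pseudo-energy to that basin's base
pairs, resample, and repeat. The accumulated *guiding potential* flattens
already-explored regions, in the spirit of local-elevation/metadynamics
methods on continuous landscapes, while everything remains exact: at every
round the sampler draws from the exactly computed distorted ensemble, not
from a Monte Carlo approximation.

## Landscape formalism

* A structure `s` is a set of base pairs `(i, j)`, `i < j`, canonical
  (`AU, UA, GC, CG, GU, UG`), nested (no pseudoknots), with at least three
  unpaired bases in every hairpin (`j - i >= 4`).
* Gradient walks: from any structure, repeatedly move to the strictly
  lowest-energy neighbour under single-pair moves; ties are broken by the
  lexicographically smallest dot-bracket string in plain byte order
  (`'(' < ')' < '.'`). The endpoint is the structure's local minimum; the
  set of structures walking to the same minimum is its gradient basin, and
  basins partition `Omega`. A structure with no strictly lower neighbour is
  a local minimum by definition, so equal-energy plateaus are treated as
  (several) minima; this is the simplest rule consistent with the
  fixed-point definition and keeps the mapping unique.
* The partition function `Z = sum over Omega of exp(-beta E(s))` and the
  Boltzmann probabilities `p(s) = exp(-beta E(s)) / Z` are computed by the
  standard two-table interval dynamic programming in `O(n^3)` time; drawing
  a structure is stochastic backtracking through the same tables.

## The energy model

The package ships a deliberately small, fully specified pair-plus-stack
model (`bpstack_model()`): each canonical pair contributes a pair energy
(defaults `GC/CG = -3.0`, `AU/UA = -2.0`, `GU/UG = -1.0` kcal/mol) and each
stacked adjacency — pairs `(i, j)` and `(i+1, j-1)` both present — a bonus
(default `-1.0` kcal/mol). The open chain has energy exactly 0. These
constants are a design choice of this package, picked to give GC-rich
helices a realistic dominance while keeping landscapes small enough to
enumerate; they are not measured nearest-neighbour parameters, and none of
the package's algorithms depend on their values. Richer models (e.g. a full
nearest-neighbour parameterisation through an external engine) can stand
behind the same interface as long as they expose loop-decomposable terms the
DP can consume: a 4x4 per-pair table plus a stacking bonus. All of the
package's tests and reported numbers use the built-in model so the
repository is self-contained.

Base-model energies are held internally as integers in units of
0.01 kcal/mol, and energies read from files are rounded half-away-from-zero
to that resolution. This makes energy comparisons — in particular the
steepest-descent choice and its lexicographic tie-break — exact and platform
independent. Accumulated guiding-potential entries, by contrast, are kept as
exact doubles: entries are the per-pair accumulation
`E_ij = sum_l alpha_l * [ (i,j) in s'_l ] / |s'_l|`, and rounding them would
break the identity between the per-pair form and the per-round penalties
(`guiding_term` at the reference must equal `alpha` exactly). Gradient
walks use the unmodified integer energies, so tie-breaking exactness is
unaffected by this choice.

Temperature defaults to 37 C (310.15 K), giving
`kT = R*T ~ 0.6163 kcal/mol`; this is an assumption of the package, recorded
here because no particular simulation temperature is canonical for the
built-in model.

## Guiding potentials

A guiding potential is a pair-additive pseudo-energy: a matrix of entries
`E_ij`, and `E_psi(s) = sum of E_ij over pairs of s`, so the distorted
energy is `E-hat = E + E_psi` and the distorted ensemble
`p-hat(s) = exp(-beta E-hat(s)) / Z-hat` remains computable by the same DP —
the entry `E_ij` enters exactly where pair `(i, j)` is formed. To repel
sampling from a reference structure `s'`, every pair of `s'` receives
`alpha / |s'|`, which gives any structure `s` a penalty
`alpha * |s intersect s'| / |s'|`: `alpha` at the reference itself, fading
linearly with the shared-pair count. `alpha` defaults to `kT`, i.e. the
scale of thermal fluctuation: large enough to matter, small enough that
consecutive rounds' ensembles overlap. Negative `alpha` turns the same
machinery into an attractor toward a region of interest
(`accumulate_potential` with signed `alpha`).

## The iterative sampler

`explore_landscape()` draws `N` samples (default 1e5) in rounds of `g`
(default 100). Each round: (1) recompute `Z-hat` only if the potential
changed — caching is purely an optimisation and provably cannot change
results, which the tests check bit-for-bit; (2) draw `g` structures;
(3) gradient-walk each draw on the *unmodified* landscape and update basin
counts; (4) pick the round's most over-represented minimum (ties:
lexicographically smallest); (5) decide whether to accumulate the repellent
update by the saturation rule.

Two design points deserve explanation:

* **Walks use `E`, not `E-hat`.** Local minima are features of the true
  landscape; the potential only reshapes where samples land, and walking on
  penalised energies would report corrupted minima. A `potential` argument
  on `gradient_walk()` exists for experimentation, but the sampler never
  uses it.
* **The saturation gate.** The ratio `|M1| / |M>1|` compares local minima
  seen exactly once against those seen multiple times, cumulatively over
  all rounds. The potential is updated only when this ratio does not exceed
  `mu` (default 0.1): a small ratio means collisions pervade — the current
  distribution is sampled to saturation — so it is time to push the sampler
  elsewhere. When singletons dominate, the sampler is still harvesting new
  basins cheaply and the (costly) `O(n^3)` recomputation of `Z-hat` would
  buy nothing. The direction of this inequality is implemented literally as
  stated above; because it may look counter-intuitive at first reading, the
  gate is isolated in one predicate (`saturation_ratio()` compared against
  `mu`) and an `invert_gate` flag allows the opposite convention to be
  explored. An update whose target is the open chain is skipped (the
  penalty would divide by zero pairs); the round is still logged.
* The target is selected from the *current round's* counts (the most
  over-represented basin right now), while the gate is cumulative; both
  choices are deliberate and recorded in `per_round`.

Reproducibility: one master seed; each round's RNG stream is derived
deterministically (`seed * 2971 + round * 7919 mod 2^31 - 1`), and
identical configurations give byte-identical sample multisets.

## Quality measures

* **Distance classes.** With two references — the MFE structure `s1` and
  the most stable structure sharing no pair with it, `s2`, obtained by a
  constrained fold prohibiting all of `s1`'s pairs — every structure maps
  to a class `C(d1, d2)` by its base-pair distances to the references. Each
  occupied class is summarised by its minimum energy and by the class
  ensemble free energy `G = -(1/beta) log(sum of exp(-beta E))` (stated
  with the physically meaningful `1/beta` prefactor). A sample covers a
  class when it reaches within a margin `theta` of the class optimum;
  reported margins default to 0 and 5 kcal/mol. The denominator counts the
  *occupied* ground-truth classes: geometrically possible but empty cells
  carry no information about sampling quality. Ground truth comes from the
  in-package exhaustive enumerator, which restricts the measure to
  desk-scale sequence lengths; for longer sequences coverage can only be
  reported relative to a union of sample sets, and the grid object labels
  its source accordingly.
* **Barrier trees.** Exhaustive flooding: process all structures by
  ascending `(energy, dot-bracket)`; a structure with no previously
  assigned neighbour opens a basin, with one adjacent basin it joins it,
  with several it is the saddle merging them. The implied saddle between
  any two leaves provably equals the minimax (bottleneck) path energy over
  the full neighbour graph, which the tests verify against an independent
  spanning-tree oracle. Coarse graining absorbs any minimum whose barrier
  is below a threshold (default 3 kcal/mol) into the deeper neighbour
  basin, processing saddles in ascending order — the standard construction.
  Sampling quality is then scored as the fraction of the 100 highest
  saddles whose two flanking deepest minima were both discovered, plus the
  fraction of leaves discovered.
* **Diversity.** Unique-minima counts, density of states (unique structures
  per half-open energy bin anchored at the minimum; default width
  1 kcal/mol — the "energy level" granularity is a parameter because no
  single value is canonical), and the weighted mean base-pair distance with
  Boltzmann weights renormalised over the unique structures of the input
  set (renormalisation makes the measure computable from a sample alone;
  ensemble-exact weights would require the full enumeration). It is
  evaluated through the pair-frequency identity
  `sum over (i,j) of 2 q_ij (1 - q_ij)`, which equals the naive double sum
  exactly but in linear rather than quadratic time in the number of
  structures.

## The designed bistable sequence

`bistable_sequence()` (default `GCGGCAAAAGCCGCAAAGCG`, 20 nt) is the
package's study system: a strong 5' helix tract, an aperiodic G/C pattern so
shifted registers break complementarity, and a short 3' tract that offers
the middle strand an alternative, weaker pairing. Its exhaustively
enumerated landscape (573 structures) has two deep arrangements near
-21 kcal/mol plus a designed pair-disjoint metastable basin around
-18 kcal/mol holding under half a percent of the Boltzmann mass, and dozens
of shallow single-helix basins. This emulates the anatomy of a two-state
riboswitch — a dominant fold plus functionally relevant rare states — at a
size where every claim can be checked against enumeration. What it does not
emulate: realistic loop entropies, multiloop penalties, lengths where
enumeration is impossible, or sequence heterogeneity; passing tests on this
fixture therefore validate the algorithms' contracts, not the biological
accuracy of the built-in energy model.

## Numerical choices

* Partition-function DP in double precision with per-nucleotide rescaling
  anchored at the MFE (`scale = exp(-beta * E_mfe / n)` per base), which
  keeps all table entries representable to n = 300 and beyond; the oracle
  contract is agreement with explicit Boltzmann summation to a relative
  1e-9 on enumerable sequences. Sampling ratios are scale-invariant.
* `uniform_sample()` is `boltzmann_sample()` at exactly `beta = 0` (every
  weight 1), not a small-beta approximation.
* MFE traceback returns the lexicographically smallest co-optimal structure
  via a lazily memoised string DP over co-optimal decompositions. Under a
  real-valued guiding potential, co-optimality is decided by exact
  floating-point equality of sums built from the same stored expressions;
  mathematically tied but differently rounded alternatives can in principle
  escape the tie set. With the zero potential all energies are integers and
  the tie-break is exact.
* Enumeration generates all of `Omega` (hard ceiling, default 5e6
  structures, with an explicit error naming the limit) and filters by the
  requested band above the MFE. Barrier trees refuse enumerations not
  marked complete; with a finite band, basins whose members have neighbours
  outside the enumeration are flagged and a warning is raised, since
  band-edge basins may be artifacts.
* Problem sizes in the test-suite: exhaustive oracles run on random
  sequences of 12-18 nt (landscapes up to a few thousand structures),
  sampler fidelity uses 1e5 draws against exact ensemble probabilities, and
  the sampler comparisons use 10 independent runs of 2000 samples on the
  bistable fixture. These sizes keep every expected value independently
  computable by brute force.

## Limitations

* The built-in energy model is intentionally minimal; absolute energies and
  basin depths are not comparable to laboratory measurements.
* Exhaustive stages (truth grids, barrier trees) are exponential in
  sequence length and intended for fixtures and short sequences only.
* Exact base-pair probability matrices (inside-outside) are not computed;
  empirical pair frequencies from samples serve that role.
* No pseudoknots, base triples, non-canonical pairs, or circular RNAs.
* Kinetics — transition rates, path heuristics, master-equation dynamics —
  are downstream of this package's scope: it produces the coarse-grained
  landscape those methods consume.
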