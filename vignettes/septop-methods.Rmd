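---
title: "Separated-topologies binding free energies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separated-topologies binding free energies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septop)
```

## The thermodynamic cycle

The separated-topologies (SepTop) approach computes the relative binding
free energy of two ligands A and B without any atom mapping between them.
Both ligands are placed in the binding site simultaneously and the
transformation runs two absolute-style calculations at once, in opposite
directions:

1. the non-interacting (dummy) ligand B is inserted into the site under a
   Boresch-style orientational restraint (analytic step);
2. **leg B** — ligand B's van der Waals interactions are switched on (to
   the γ-scaled level, see below) while ligand A becomes restrained and its
   vdW is partially softened;
3. **leg C** — ligand B's charges are switched on while ligand A's charges
   are switched off;
4. **leg D** — ligand A's remaining vdW is switched off while ligand B's
   restraint is released;
5. the restraint on the now-dummy ligand A is released analytically into
   the standard-state volume V° = 1660 Å³ and the ligand is transferred to
   solvent.

Legs B and C share one topology (A/B alchemical states in GROMACS columns)
and leg D a second topology whose state A must equal the first topology's
state B field by field; the package asserts this continuity whenever it
builds a leg set. The solvent side uses two absolute hydration legs for
neutral ligands, or a single dual-ligand box for charged ligands so the net
system charge never changes.

The edge estimate assembles as

```
ddG_bind(A->B) = [dG_BC + dG_D + dG_release(A) - dG_release(B)] - dG_solvent(A->B)
```

with uncertainties combined in quadrature. The identity transformation
(A = B with symmetric legs) cancels exactly, which the test suite asserts.

## Restraint selection heuristics

Boresch restraints couple three protein atoms (P1, P2, P3) and three ligand
atoms (L1, L2, L3) through one distance (P1–L1), two angles (P2–P1–L1,
P1–L1–L2) and three dihedrals. The binding free energy is independent of
the specific atoms, but convergence and numerical stability are not, so the
package implements a filtering cascade. All cutoffs live in
`restraint_search_config()`:

| parameter | default | units | role |
|---|---|---|---|
| `rmsf_cutoff` | 0.1 | Å | exclude mobile atoms (tuned for ~2 ns sampled every 4 ps) |
| `min_distance`, `max_distance` | 10, 30 | Å | protein anchors neither in the deformable binding site nor so far that periodic imaging bites |
| `min_p1_p2_sep` | 5 | Å (0.5 nm) | non-degenerate P1–P2 lever arm |
| `dihedral_window` | (−150, 150) | deg | keep dihedral equilibria away from the ±180° wrap |
| `angle_spread_cutoff` | 100 | deg² | squared circular std of candidate angles over the trajectory |
| `dihedral_spread_cutoff` | 300 | deg² | same for dihedrals |
| `stability_multiple` | 10 | RT | angle equilibria at least `sqrt(2·m·RT/k)` from 0/180° |
| `temperature` | 298.15 | K | thermal scale for the cutoffs |

Ligand anchors come from the *middle of the molecule*, defined through the
bond graph rather than the center of mass: among all-pairs shortest paths
the longest one (a diameter path) is taken, and the three ring atoms
nearest its middle (within one connected ring system) are selected, L1
being the closest. A distal ring can rotate locally without reporting a
genuine binding-mode change, which is why the central ring is preferred; a
molecule with no rings falls back to the three central chain atoms with a
warning. Users can override the choice with a SMARTS pattern; matching is
done by a deliberately small SMARTS-subset engine (organic-subset and
bracket atoms, branches, ring closures; aromaticity approximated by ring
membership; bond orders unconstrained) built on igraph's LAD subgraph
isomorphism, because no full SMARTS engine is available to R here. The
package treats the supported subset as sufficient for the intended use —
simple ring/scaffold selections.

Protein anchors are backbone + Cβ atoms of *central* residues (first and
last residue of each element dropped) of α-helices — or of helices *and*
β-sheets when helix is not the dominant label by residue count, which
matters for all-β proteins. Secondary structure comes from φ/ψ windows
(helix: φ ∈ [−100, −30], ψ ∈ [−80, −5]; sheet: φ ∈ [−180, −90] with
ψ ≥ 90 or ψ ≤ −170) plus a run-length filter (≥ 4 consecutive helix,
≥ 3 sheet residues). This window classifier is an implementation choice —
no hydrogen-bond (DSSP-style) algorithm is mandated anywhere — and an
external assignment can be injected through the `secondary` argument.
P1 is the first candidate (ascending atom index; "first" always means file
order) passing the angle, dihedral-window and spread checks against
L1/L2/L3; P2 additionally needs 0.5 nm ≤ d(P1,P2) ≤ half the shortest box
edge; P3 maximizes `min(d(P3,P1), d(P3,P2))` under the same box bound and
its dihedral checks. Each filter reports by name when it empties the pool.
For an edge, anchors chosen in one complex are reused in the other only if
they pass that complex's checks (`check_protein_anchors()`); ligand anchors
are always selected per ligand.

Equilibrium values are means over the supplied frames — arithmetic for the
distance, circular for angles and dihedrals (so {179°, −179°} averages to
180°, not 0°). Force constants are 20 kcal·mol⁻¹·Å⁻² (distance) and
20 kcal·mol⁻¹·rad⁻² (one angle, three dihedrals); the angle adjacent to the
distance restraint scales as `k = 40 · (r0 / 5 Å)²` because the arc length
the ligand can sweep at fixed angular amplitude grows linearly with r0, so
the force constant must grow quadratically to keep the positional freedom
constant.

### The analytic release correction and its accuracy

Releasing the fully restrained, non-interacting ligand into V° = 1660 Å³
costs

```
dG = -RT ln[ 8 pi^2 V° sqrt(k_r k_thA k_thB k_phA k_phB k_phC)
             / ( r0^2 sin(thA0) sin(thB0) (2 pi RT)^3 ) ]
```

under the ½k convention (GROMACS restraints). This closed form is the
stiff-spring limit of the exact 6-D configurational integral with Jacobian
r² sinθ_A sinθ_B; the leading difference is the Laplace curvature term
`RT² (1/(2 k_thA) + 1/(2 k_thB) − 1/(k_r r0²))`, about 0.012 kcal/mol at
r0 = 5 Å and below 0.01 kcal/mol throughout the 10–30 Å anchor window the
distance filter actually admits. The test suite carries an independent
quadrature oracle and checks both the raw agreement across that operating
range and, more sharply, that the residual after removing the predicted
curvature term is below 0.002 kcal/mol.

## Topology construction

`merge_ligand_into_complex()` inserts ligand B's coordinates directly after
ligand A and its moleculetype into the complex topology (clashing names get
a `_B` suffix). Each ligand then receives *private* atom types
(`uniquify_ligand_atomtypes()`), which makes pairwise overrides possible:
`zero_interligand_vdw()` writes one `[ nonbond_params ]` row with ε = 0 for
every (A-variant × B-variant) type pair, so the two ligands never see each
other through vdW in any state. Coulomb interactions need no exclusion:
GROMACS interpolates Hamiltonians linearly, `H = (1−λ)H₀ + λH₁`, so as long
as no *end state* has both ligands charged, no intermediate state couples
them electrostatically; the package verifies the end-state property rather
than re-implementing the engine's interpolation.

For enhanced sampling (ϵ-HREX), every ligand type gains a "scaled" clone
with ε′ = γ·ε (γ = 0.5 in the complex, 0.3 in solvent, per-atom overrides
such as γ = 0.01 on a sluggish R-group) and a "dummy" clone with ε′ = 0; σ
is never modified. The binding-site state tables then read:

| | ligand A | ligand B |
|---|---|---|
| BC state A | full vdW, full q, restraint off | dummy, q = 0, restraint on |
| BC state B | scaled vdW, q = 0, restraint on | scaled vdW, full q, restraint on |
| D state A | = BC state B | = BC state B |
| D state B | dummy, q = 0, restraint on (released analytically) | full vdW, full q, restraint off |

Optional dihedral restraints on rotatable bonds follow the adapted cycle:
the ligand being coupled is inserted with its rotatable bonds restrained
(on throughout BC, released over leg D), the ligand being decoupled has
them switched on during leg B together with the Boresch restraint.

The charged-ligand solvent protocol puts both ligands in one box, holds
their COM-nearest heavy atoms half the shortest box edge apart with a
single harmonic distance restraint (k = 2.4 kcal·mol⁻¹·Å⁻², identical in
both states, so its contribution cancels between end states and is
assigned zero), and prescribes two gentle 10 ps NVT pre-equilibrations at
k = 0.0024 and then the full k. The leg itself mirrors the binding-site
ordering through the γ = 0.3 intermediate and is realized as two
topologies for the two 14-window stages, with the same continuity
assertion as in the complex.

## λ schedules and run parameters

Default window counts follow the SepTop protocol: the combined B+C leg
uses 12 windows (vdW and restraint components finish over the first 8,
Coulomb changes over the last 5, window 8 shared) plus 8 windows for leg D
— 20 in total; hydration uses 14 (Coulomb off before any vdW change);
the charged solvent leg uses 28 (14 per ligand). The exact fractional
λ values inside a leg are even per component by default and fully
overridable — the protocol's load-bearing content is the counts and the
ordering constraints, not particular spacings. Whether window 8 of the
combined leg is shared or duplicated between the vdW and Coulomb phases is
not decidable from the available description; the 12-window total is
treated as authoritative, which forces the shared window.

Emitted MDP phases: steepest descent (5000 steps), 10 ps NVT at 298.15 K,
10 ns NPT production at 1 bar with the stochastic-dynamics integrator at
2 fs, Beutler soft core on vdW only (α = 0.5, power 1, config-exposed),
full cross-evaluation of all windows (`calc-lambda-neighbors = -1`) for
MBAR, and `init-lambda-state` equal to the 0-based window index. Replica
exchange is launched on the engine's command line; the package records the
200-step attempt interval in the run manifest.

## Estimation

`parse_dhdl()` reads one XVG per sampled state carrying a time column and
one energy-difference column per state (kJ/mol), reduced with β = 1/(RT).
Storing energies relative to the sampled state is valid because every
multistate weight is invariant under per-sample additive constants. The
first 1 ns of each 10 ns window is discarded as extra equilibration by
default; statistical-inefficiency subsampling beyond that is deliberately
not applied by default, since only the fixed discard is part of the
protocol.

`mbar_solve()` minimizes the convex multistate likelihood (BFGS with
analytic gradient) and polishes by self-consistent iteration to a 1e-8
relative tolerance (f₁ ≡ 0). Uncertainties come from the asymptotic
covariance evaluated through a thin SVD of the N×K weight matrix;
the overlap matrix is `O = (WᵀW)·diag(N)`, whose rows sum to one. States
sharing essentially no weight with the rest trigger a warning and a
`flagged` result rather than silent nonsense. The solver is validated
against exact harmonic free energies and an independently coded two-state
BAR iteration (agreement to 1e-6). Each leg's topology file is solved
per file and the legs summed; a joint solve across the two binding-site
topologies is not attempted because their reduced potentials are never
cross-evaluated.

## Network diagnostics

Transformation maps are either a star (every ligand to one reference, plus
extra cycle-forming edges) or a multi-series map (round-robin pairs within
each series and between each series pair, e.g. 3 series × 10 intra + 3
pairs × 5 inter = 45 edges). Cycle enumeration returns all simple cycles of
the underlying undirected graph, each anchored at its smallest node and
deduplicated by direction, in lexicographic order; an optional length cap
(default 6 in the CLI report) keeps dense maps tractable and concentrates
the diagnostic power in short cycles.

Cycle closure is `CC = |Σ signed ΔΔG|` around the cycle; the normalized
closure divides by √n, the convention under which independent per-edge
errors add in quadrature (CC/n is available via `normalization = "n"`; the
protocol description leaves open the two). The voting system
gives every edge +1 per containing cycle with normalized closure above 0.7
kcal/mol and −1 per cycle below 0.3 kcal/mol, and ranks by vote sum (ties
by edge id); thresholds apply to the *normalized* closure and are
configurable because either convention is defensible for the
normalized values. Hysteresis is `|ΔΔG(A→B) + ΔΔG(B→A)|`.

A cycle-based diagnostic has one structural blind spot worth knowing: the
two edges meeting at a degree-2 node lie in exactly the same cycles and
collect identical votes, so they cannot be separated. The noisy-network
fixture therefore plants its corrupted edges only where both endpoints have
degree ≥ 3, keeping the ground truth identifiable.

`solve_absolute_dg()` minimizes `Σ (x_to − x_from − ΔΔG)²/σ²` per connected
component (pseudo-inverse of the weighted normal equations; per-node
uncertainties from its diagonal) and fixes the additive constant so the
mean prediction over experimentally measured nodes matches the mean of
those measurements — hence adding a constant to all experimental values
shifts all predictions by exactly that constant. `benchmark_stats()`
computes RMSE, MUE, R² (squared Pearson, the convention of the common
plotting tools), ρ, `RAE = Σ|calc−exp| / Σ|exp − mean(exp)|` and Kendall τ
on mean-centered pairs, with percentile bootstrap CIs under a fixed seed
(bit-reproducible).

## What the synthetic fixtures emulate — and what they do not

`make_helix_complex()` builds an ideal poly-alanine helix (φ = −57°,
ψ = −47°, standard bond geometry, Cβ included) with a ring-tail or zig-zag
ligand at a prescribed distance, plus a minimal valid topology; there are
no sheets by default, no solvent, no realistic force field.
`make_fluctuating_trajectory()` adds isotropic per-atom Gaussian noise
(expected RMSF = σ√3) at a 4 ps cadence — it has no correlated motions, no
conformational transitions, no drift. `make_harmonic_reduced_potentials()`
uses 1-D harmonic states because their free energies
(`½ ln(k_k/k_1)` plus offsets) are exact; real alchemical potentials are
neither 1-D nor Gaussian. `make_noisy_network()` draws true values
uniformly and edge noise i.i.d. Gaussian. Passing tests on these fixtures
therefore demonstrates the *bookkeeping, estimators and heuristics* are
correct under controlled conditions; they say nothing about force-field
accuracy or MD sampling on real targets, which is exactly the part this
package does not attempt.

Problem sizes used by the test and acceptance suites — 500-frame
trajectories, 5000 samples per harmonic state (20 seeds), 50-seed
10-node/30-edge recovery networks, 100 single-bad-edge maps at the
16-node/30-edge size of a production-scale ligand map — were chosen as the
smallest sets at which the corresponding closed-form statistics are
resolved at their stated tolerances.

## Numerical choices and degenerate inputs

* Units: geometry in Å and kcal/mol at the user surface; GROMACS-facing
  fields (topologies, MDP) in nm and kJ/mol, converted only at the format
  boundary. 1 kcal = 4.184 kJ; R·T at 298.15 K = 0.592488 kcal/mol.
* Atom indexing is 1-based everywhere a user sees it, matching the GROMACS
  dialect.
* Ties break by ascending atom index / lexicographic edge id throughout, so
  the whole cascade is deterministic given identical input.
* Circular spread is the squared circular standard deviation,
  `(−2 ln R̄)(180/π)²` in deg², chosen because the protocol thresholds
  carry deg² units; the estimator is wrap- and rotation-invariant.
* Degenerate inputs fail loudly: single-frame RMSF, empty candidate pools
  (named filter), zero force constants in the release correction, burn-in
  ≥ production length, cycles with missing edges, disconnected networks
  (per-component solve with warning), hi ≤ lo voting thresholds.
* Binary trajectory formats (XTC/TRR) are out of scope; multi-frame
  GRO/PDB cover the trajectory interface without compiled dependencies,
  and a richer backend can wrap the same `trajectory()` container.

## Known limitations

* The emitted topologies are dialect-valid GROMACS but have not been
  byte-compared against any external reference layouts.
* The secondary-structure classifier is a φ/ψ-window heuristic; unusual
  geometries (π-helices, bulged strands) will be labeled coil.
* The SMARTS engine covers a subset (no charge/H-count/degree predicates,
  no recursive SMARTS); unsupported tokens raise an error rather than
  silently mismatching.
* MBAR covariance assumes uncorrelated samples; with correlated MD data the
  reported uncertainties are lower bounds unless the input is subsampled.
* Restraint selection assumes an orthorhombic box for the half-box-edge
  checks.
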