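---
title: "Methods: zone-coupled sampling and weighted-ensemble binding-mode analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zone-coupled sampling and weighted-ensemble binding-mode analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vczone)
```

## The estimation problem

The package estimates the canonical distribution of a ligand–receptor
system over a low-dimensional reaction-coordinate (RC) space, and then
asks binding-mode questions of the thermally weighted snapshot ensemble.
Every RC is the Euclidean distance between the centres of two bead groups;
the RC space is one- to three-dimensional. The obstacle is the usual one:
the canonical density spans many orders of magnitude across the RC range,
so unbiased dynamics never visits most of it.

## The sampling model

**Dynamics.** Bead systems evolve under BAOAB-discretised Langevin
dynamics. BAOAB was chosen over weak-coupling thermostats because it
samples the configurational canonical distribution exactly in the harmonic
limit and with small $O(\Delta t^2)$ bias otherwise — the whole analysis
chain rests on within-zone samples being canonical. Units are Å, kcal/mol,
amu, fs, and K throughout; the friction is given in ps⁻¹. The toy
Hamiltonian is harmonic bonds and angles (energy $k(x-x_0)^2$, without the
conventional ½ — all stiffnesses in this package follow that convention),
a Lennard-Jones term over all pairs not bonded at range 1–2 or 1–3 (no
cutoff: systems are tens of beads, and a cutoff would contaminate the
analytic comparisons), and harmonic position restraints.

**Virtual states and walls.** Each RC axis is covered by `n_vs` uniform
zones of width $w = \mathrm{span} / ((n_{vs}-1)(1-f) + 1)$ at stride
$w(1-f)$, where $f$ is the overlap fraction (default 0.5, the conventional
half-overlap choice; the zone tables of the original applications are not
fixed by any published main text, so they are free parameters here). A
virtual state is one zone per RC. Confinement uses half-harmonic walls
(default 10 kcal/mol/Å² per RC) that are identically zero inside the zone,
so the conditional distribution inside a zone is exactly the restricted
canonical law. Velocity-reversal confinement would avoid the wall skin
entirely but makes the integrator non-smooth; the soft wall with a 0.5 Å
bookkeeping tolerance was preferred. Snapshots that sit in the wall skin
are stored (snapshot accounting stays exact) but not counted into
histograms; snapshots beyond the skin are possible in principle but are
suppressed by ≥ 10 kT of wall energy.

**Transitions.** Every `transition_interval_steps` the state is redrawn
from the states whose zones contain the current RC point, with probability
proportional to the inverse of the estimated zone mass under the current
$Q$ estimate (floored at $10^{-6}$ of the total mass so unvisited zones
are attractive but bounded; uniform on iteration 1). The published
transition rule of the method this emulates lives in references that do
not print it; inverse-mass independence sampling is this package's own
declared rule. The estimator's validity does not depend on the rule: any
transition scheme leaves the within-zone conditional distribution
canonical, which is all the stitching step uses. The rule only shapes
*coverage*.

**Seeding.** Initial seeds are generated by flat-bottom window restraints
(the same wall machinery) pulling all RCs into stated windows from the
built configuration; every stored frame of the relaxation segments is
checked and the latest in-window frame is taken, so a run fails only if it
never satisfies the window over `max_tries` segments. Subsequent
iterations fill half the slots round-robin over visited zones in ascending
visit count and half by a small genetic algorithm: parents drawn
∝ 1/visits, per-RC crossover, ±1 zone mutation with probability
`p_mut = 0.1` (clipped), each target mapped to the stored snapshot nearest
the target zone centre in zone-normalised coordinates, ties to the
earliest snapshot. The even/GA split and `p_mut` are package choices; the
literature gives no proportions.

**Stitching.** Per-state bin densities $h_v(b) = c_v(b)/(N_v\,
\mathrm{vol}(b))$ satisfy $g_v + \ln h_v(b) = g_w + \ln h_w(b)$ on shared
bins; the $g_v$ are solved by weighted least squares (weight: harmonic
mean of the two bin counts; a shared bin participates only when both
counts reach `min_overlap_count = 5`; gauge: $g = 0$ at the most-sampled
state) and the estimate on a bin is the count-weighted mean of
$e^{g_v} h_v(b)$. Bin widths default to half the overlap width so that
every overlap region contains whole bins, which the estimator requires;
zone boundaries always coincide with bin edges, enforced at grid
construction (1e-9 relative alignment tolerance). A disconnected overlap
graph is an error for the operation itself; inside the iteration loop,
where early iterations legitimately hold fragments, the largest connected
component (by counts) is stitched and the remainder left at zero until
sampling joins it.

**Convergence.** $d = \sum_b |Q_M - Q_{M-1}| / \sum_b Q_M$ over bins where
either max-normalised estimate exceeds 0.001 (the support convention used
for reporting); convergence is declared at $d < 0.1$ for two consecutive
iterations — the source material states only a qualitative criterion, so
the threshold is a package choice.

**Reweighting.** $w_i \propto Q(b_i)/c(b_i)$, normalised to 1 (to 1e-12).
Internally $Q$ is sum-normalised; the max-normalised form is only a
reporting convention for contour levels. Snapshots in bins below $10^{-8}$
of the maximum $Q$ get zero weight and are flagged rather than silently
kept, since their weights would be dominated by estimator noise.

## The synthetic systems

`build_toy_complex()` emulates, in beads, the geometry that matters for
the analyses: a rigid receptor frame (position restraints, 10 kcal/mol/Å²,
so the receptor-fixed analysis frame is well defined), a concave pocket
whose three lining beads are analogs of the cleft residues
Val75/Phe93/Phe96, a weakly restrained tail analog (0.5 kcal/mol/Å²,
emulating a linker kept out of the cleft), and chain ligands with named
head (ring-A analog) and tail (ring-BC analog) groups. The shipped
*binder* is a four-bead flexible chain whose head–cleft Lennard-Jones well
is 15× the generic 0.2 kcal/mol (≈ 5 kT per pair at 300 K — strong enough
to bind, weak enough to unbind under zone walls); the *rod* is a six-bead
chain with angle stiffness 60 kcal/mol/rad² and uniform affinity, a frame
that cannot enter the pocket mouth. These defaults are the package's
study conditions, chosen once: the binder/rod pair realises the
flexible-inserting versus stiff-surface-bound contrast that motivates the
analyses.

What the toys deliberately do **not** emulate: explicit solvent and ions,
atomistic force fields, hydrogen-bond or π chemistry, protein flexibility
beyond the restrained frame, and all-atom time scales. Passing tests
therefore demonstrate the correctness of the sampling estimator and the
analysis operations — not that any real ligand binds any real protein.

## Analyses

All real-space analyses run after Kabsch superposition of the
receptor-core beads onto the reference structure (the frame convention is
a package choice; superposition is computed from the 3×3 SVD with the
determinant sign correction, and degenerate/collinear selections are
errors). Density grids store per-voxel probabilities summing to 1 (voxel
default 1.0 Å; contour levels are quoted as multiples of ρ₀ = 0.001);
clusters are 26-connected components above `level × ρ₀`, sorted by mass.
The "RDF" is a normalised minimum-distance distribution — no $4\pi r^2$
correction, since the variable is a minimum over pairs, not a pair count.
Distribution means and SDs are computed from unbinned distances, so they
are invariant to bin width; the flexibility ratio `sd = SD/⟨r⟩` is
reported to 3 significant figures. Orientation uses the geometric centres
of the head and tail groups for the vector and the centre of mass of the
ligand for cube assignment (2.0 Å cubes by default) — the mixed
geometric/mass convention is kept deliberately and both are explicit in
the configuration. Contacts use the strict inequality `r < 4.0 Å`.

## Numerical choices and degenerate inputs

* Per-run RNG streams derive from one root seed via
  `run_seed(root, k) = (root·1000003 + 7919·k) mod (2³¹−19) + 1`, so
  campaigns are reproducible and order-independent; all noise flows
  through R's RNG, including inside the compiled integrator.
* Zone intervals are closed on the left, open on the right, the last
  closed on both ends — this removes double counting at bin boundaries.
  One consequence accepted deliberately: at exact half overlap an interior
  zone centre coincides with its right neighbour's closed left edge and
  belongs to two states.
* `analytic_rc_boltzmann()` normalises by trapezoid quadrature on the
  supplied grid (machine-accurate for the smooth densities used);
  non-normalisable inputs (no finite mass on the domain) are errors.
* Coincident beads in a nonbonded pair (separation < 1e-6 Å), non-finite
  energies during integration (reported with the step index), empty
  groups, zero-length orientation vectors, zero-count weight bins, and
  disconnected overlap graphs are all explicit errors, not silent results.
* The stitching validation uses expected (real-valued) per-zone
  occupancies rather than sampled integer counts: that isolates estimator
  fidelity and makes the invariance under per-zone count rescaling exact,
  whereas multinomial noise at 10⁴ counts/zone would dominate a max-error
  statistic. A separate property test draws multinomial counts and bounds
  the L1 reconstruction error instead.

## Problem sizes

The validation campaigns are sized for a single desk CPU: the reduced
two-bead recovery uses 3 zones × 3 iterations × 16 runs × 2·10⁴ steps
(dt 10 fs, < 10⁶ total steps); the demo systems use 3 RCs × 3 zones,
3 iterations × 24 runs × 9·10³ steps at dt 4 fs. The published-scale
schedules (256 runs, 3·10⁶ steps per run) appear in the schedule
accounting, which is exact arithmetic and needs no simulation.

## Known limitations

* The transition rule and GA operators are faithful-intent substitutes,
  not reproductions of the unpublished originals; results about coverage
  speed are specific to this package.
* Q resolution is limited by the stitching bins; within a bin, relative
  weights of snapshots are not corrected (the demo uses 3 Å RC bins,
  trading RC resolution for per-bin statistics at small sample sizes).
* The store uses R serialization with an explicit schema version rather
  than a language-neutral container; OpenDX export covers the volumetric
  outputs for visualisation elsewhere.
* With fewer than two visited zones, or windows that a system cannot
  reach, the loop degrades explicitly (single-state Q, seeding-failure
  errors) rather than estimating anything.
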