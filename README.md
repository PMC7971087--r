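# vczone

Virtual-system-coupled sampling and weighted-ensemble binding-mode analysis
on coarse-grained ligand–receptor systems.

## The problem

Ligand association with a shallow protein cleft is rarely a single docked
pose: at equilibrium the ligand occupies a broad ensemble of positions and
orientations, and the interesting questions — *where* does the ligand
concentrate, *which way* does it point, *how stiff* is its frame — are
questions about a canonical (Boltzmann-weighted) ensemble. Plain simulation
almost never crosses the free-energy barriers between unbound and bound
states in reachable time, so the ensemble must be built by enhanced
sampling plus reweighting.

`vczone` implements the multi-dimensional virtual-system-coupled scheme for
that task, at desk scale, on synthetic bead models with analytic references:

1. **Reaction coordinates.** Up to three RCs λ⁽ʰ⁾, each the distance
   between the centres of two bead groups (cleft opening, ligand approach,
   ligand rotation).
2. **Zones and virtual states.** Each RC axis is covered by half-overlapping
   intervals; a *virtual state* is one zone per RC. The sampler confines a
   Langevin (BAOAB) trajectory to its current state's zone by half-harmonic
   walls that vanish inside the zone, and periodically re-draws the state
   among all states containing the current RC point, with probability
   ∝ 1/Ẑ(state) — flattening the state marginal and driving exploration.
3. **Seeding by coverage + a genetic algorithm.** After each iteration the
   next iteration's starting snapshots are taken half from the least-visited
   zones (evenness), half from GA crossover/mutation of zone indices biased
   to poorly sampled regions.
4. **Stitching.** Per-state histograms over RC bins agree up to a scale
   wherever zones overlap; weighted least squares on
   `g_v + ln h_v(b) = g_w + ln h_w(b)` recovers the log scale factors, and
   the stitched `Q(λ)` estimates the canonical distribution over the RC
   space (reported max-normalised, with convergence tracked as the relative
   L1 change on the `Q > 0.001` support).
5. **Reweighting.** Each stored snapshot gets thermodynamic weight
   `w_i ∝ Q(b_i)/counts(b_i)`; the weighted snapshot set is a canonical
   ensemble at the simulation temperature.
6. **Binding-mode analyses** on the weighted ensemble, in a receptor-fixed
   (Kabsch-superposed) frame: spatial probability densities ρ(r) of the
   ligand geometric centre (and of sub-groups such as the ring-A analog)
   with 26-connected clusters above multiples of ρ₀ = 0.001;
   minimum-distance distributions p(r_R) against named pocket beads; the
   strict `r < 4.0 Å` contact rule; per-cube mean orientation vectors
   ⟨e(r)⟩ with the `|⟨e⟩| ≥ 0.5` alignment classification; and the
   length-normalised framework flexibility `sd = SD(r)/⟨r⟩`.

The package ships a synthetic generator (`build_toy_complex()`): a
restrained bead plate with a recessed three-bead pocket (analogs of the
cleft residues Val75/Phe93/Phe96), a weakly restrained C-terminal tail
analog, and chain ligands whose head beads may carry a deep pocket
affinity. A reduced two-bead system (`build_pair_system()`) has a
closed-form Boltzmann RC density (`analytic_rc_boltzmann()`) used as the
exact oracle.

## Worked example

Recover the canonical RC density of the reduced two-bead system with the
full loop (three zones, three iterations) and compare with the exact
result:

```r
library(vczone)

sys  <- build_pair_system(bond_k = 0.5, r0 = 6)
rc   <- list(rc_def("r", 1L, 2L, "geometric", range = c(3, 9)))
grid <- build_zone_grid(c(3, 9), n_vs = 3, overlap_fraction = 0.5)
sched <- iteration_schedule(3, 16, 20000, dt = 10,
                            snapshot_interval_steps = 200,
                            transition_interval_steps = 2000)

fit <- vcmd(sys, rc, grid, sched,
            dynamics_params(temperature = 300, friction = 2),
            windows = matrix(c(5.5, 6.5), 1), seed = 5)
fit
#> GA-guided zone-coupled sampling fit
#>   3 iteration(s) x 16 runs x 20000 steps (dt 10 fs): 4800 snapshots, 0.0096 us
#>   zones visited: 3 / 3
#>   final convergence d = 0.0076 (converged at iteration 3)

ens <- reweight(fit)
ens
#> Canonical ensemble: 4206 snapshots at 300 K
#>   weight sum 1.000000000000; 0 flagged/excluded

ana   <- analytic_rc_boltzmann(sys, 300, seq(3, 9, by = 0.002))
edges <- grid$axes[[1]]$bin_edges
sum(abs(reweighted_distribution(ens, ens$rc[, 1], edges)$mass -
        rc_density_bin_mass(ana, edges)))
#> [1] 0.024
```

The fit print shows the campaign size (here ~10 ns of toy time yielding
4800 snapshots), the zone coverage, and the iteration-to-iteration change
`d` of the stitched estimate; `d < 0.1` twice in a row declares
convergence. The final L1 distance of 0.024 between the reweighted RC
marginal and the analytic Boltzmann density is the quantitative check that
the confine–transition–stitch–reweight chain reproduces thermal
equilibrium.

The full binding-mode pipeline runs on the shipped demo systems:

```r
demo <- vcmd_demo(seed = 1, ligand = "binder", dir = "demo_out")
demo$clusters_head      # high-density clusters of the head-group density
demo$contacts           # weighted contact fractions against the cleft beads
demo$orientation        # per-cube mean orientation vectors and classes
```

`ligand = "binder"` is a flexible chain with a head attracted to the
pocket; `ligand = "rod"` is a stiff, uniform-affinity control. The binder
places its dominant head-density cluster inside the pocket with aligned
orientation cubes at the mouth; the rod does not — the package's built-in
qualitative regression of the binding-mode contrast.

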