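---
title: "Modelling coupled microbial iron cycling with ferrocycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling coupled microbial iron cycling with ferrocycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The system being modelled

Ferric iron (Fe³⁺) oxyhydroxides are respired by anaerobic iron-reducing
bacteria (FeRB, *Shewanella*-type), producing ferrous iron (Fe²⁺); under
oxic conditions microaerophilic iron-oxidizing bacteria (FeOB,
*Sideroxydans*-type) re-oxidize Fe²⁺ to insoluble Fe³⁺, competing with
abiotic oxidation. In wetland soils and sediments both guilds coexist and
the system is driven through alternating oxic and anoxic periods by water
table fluctuation and root activity. `ferrocycle` implements a stochastic
agent-based model of this loop on a 21×21×21 toroidal lattice (patch edge
2 µm, one tick = one minute), with three agent types — FeRB, FeOB and iron
nanoparticles — moving over patches that are either traversable medium or
bulk iron-mineral macroaggregates.

A run is driven by an externally supplied switching schedule (CSV of
`time_min,state` rows): during anoxic ticks only reduction operates, during
oxic ticks biotic then abiotic oxidation. Each tick executes, in order:
movement (free nanoparticles, then FeOB, then FeRB), the gated redox
submodel, nanoparticle dissociation, Fe²⁺ phase equilibration, nanoparticle
loss, and the aging clock.

## Iron bookkeeping

All iron amounts are held in abstract units of `unit_scale` atoms
(default 10⁵). Literature per-cell rates convert directly:
the contact reduction rate of 10⁷ atoms (cell·min)⁻¹ becomes 100 units/tick
(`derive_contact_reduction_rate(5e7, 0.8, unit_scale = 1e5)`), the maximum
biotic oxidation rate of 3.6×10⁷ atoms (cell·min)⁻¹ becomes 360 units/tick.
Iron is conserved exactly: dissolved Fe²⁺ + adsorbed Fe²⁺ + bulk Fe³⁺ +
nanoparticle iron + the removed-iron ledger is constant over any run (the
suite asserts ≤10⁻⁶ relative drift; in practice drift is at machine
precision). Neither the tick length nor the unit scale is stated by the
underlying literature values alone; both are reconstructions, chosen so that
the equilibration calibration (rate 0.02 leaves <5% of a deviation after
2.5 h of one-minute steps) and the passivation tolerance of 300 units
(reached after a few ticks of contact reduction at 100 units/tick) are
mutually consistent.

## Submodels and their parameters

**Movement.** Free nanoparticles and FeOB are diffusive random walkers:
each tick they re-orient with probability `p_tumble` (0.3) to a uniform
3-D heading and advance by their speed (nanoparticles:
`max(50 − 0.5·d, 1)` patches/tick for diameter d in nm; bacteria: 2
patches/tick). Destinations inside a macroaggregate core (bulk patches whose
full Moore neighbourhood is bulk) are redirected to the nearest edge patch
of the same cluster. FeRB use run-and-tumble chemotaxis: touching a patch
adjacent to bulk mineral switches on a chemotactic state
(`chemo_persistence` = 30 ticks) in which tumbling is tripled and speed
doubled. The persistence time is not constrained by the literature values
we use; 30 min is of the order of the electrokinetic-memory observations
that motivate the mechanism.

**Adhesion and detachment.** An FeRB on a bulk patch adheres if the patch's
adsorbed Fe²⁺ is below `fe2_ads_tolerance` (300 units) — surface
passivation by Fe²⁺ blocks both adhesion and, beyond the tolerance,
triggers detachment. Electrostatic mode detaches immediately; biofilm
(polymeric) mode detaches with probability
p₀·2^(−t/τ)/(1+n) (p₀ = 0.2, τ = 60 ticks, n = co-attached neighbours
within 2 patches on the same cluster), doubled under oxic conditions. The
exponential-in-residence-time form implements the qualitative statement
that polymer-mediated adhesion strengthens with time; p₀ and τ are free
choices of this package.

**Reduction (anoxic).** An attached FeRB transfers `contact_reduction_rate`
from patch Fe³⁺ to patch-adsorbed Fe²⁺. Its remaining reduction capacity is
4× the contact rate — chosen so that, with ample mineral in range, 80% of
reduction flows through electron shuttles, matching the measured shuttle
share in *Shewanella*. Bound nanoparticles are reduced first: a particle of
diameter d occupies a fraction d²/`cell_surface_area` of the ~10⁴ MtrC
cytochromes and is reduced at that fraction × `np_mineral_reduction_ratio`
(100) × contact rate × its aging susceptibility, the amount divided by the
ratio being charged against the shared capacity. Remaining capacity is
split equally over bulk patches within `e_shuttle_range` (10 patch lengths
= 20 µm), capped by each patch's Fe³⁺. Unattached FeRB wield the same 4×
capacity for nanoparticles and shuttles (shuttle secretion does not require
attachment).

**Oxidation (oxic).** Each FeOB draws
min(dissolved pool/n_FeOB, `contact_oxidation_rate`) from the dissolved
Fe²⁺ pool. Under *shedding* it tops its cell surface up to 40 nanoparticles
(each new one seeded with a 1/40 share) and distributes the remainder over
surface particles proportional to d²; surface particles are released
stochastically when a Normal(d, 2 nm) draw exceeds `shedding_diameter`
(10 nm). Under *low pH* the drawn Fe²⁺ feeds free nanoparticles in the
27-patch neighbourhood (equal split), or nucleates one new free particle if
none are present. Abiotic oxidation removes the fraction
`abiotic_oxidation_ratio` from each of the three Fe²⁺ pools per tick;
adsorbed and nanoparticle Fe²⁺ oxidize in place, while the dissolved share
precipitates onto the accessible bulk-mineral edge (or as a single new free
particle in mineral-free worlds).

**Equilibration.** At equilibrium a fraction `fe2_solid_ineq` (0.9) of all
Fe²⁺ resides on solids. Each tick every solid moves a fraction
`fe2_equilibrium_rate` (0.02) of its deviation from its equilibrium load
toward equilibrium. The dissolved pool is well mixed (at this time scale
dissolved Fe²⁺ diffuses across the world within a tick), so the only open
design choice is how the solid share partitions among many solids. We
partition in proportion to (iron content)^(2/3) — geometric surface scaling
that treats a mineral block and a spherical particle identically. The
per-entity equal-split alternative was rejected after implementation: it
assigns a 10 nm particle the same equilibrium load as a 2 µm mineral patch,
so every nanoparticle balloons with thousands of units of adsorbed Fe²⁺
within a few ticks, driving all Fe²⁺ fractions to 1 and switching off
nanoparticle–FeRB binding entirely. For a single solid both rules coincide
and reproduce the calibration closed form: the deviation decays as
(1 − rate)ⁿ, so rate 0.02 is the smallest two-decimal value leaving <5%
after 150 ticks. The update is synchronous (dissolved pool frozen at step
entry); at rate 0.02 the difference from sequential random-order visiting is
O(rate²) per tick and the conservation and calibration properties are
unaffected.

**Dissociation, loss, aging.** A reducer-bound particle dissociates when
its Fe²⁺ fraction exceeds `np_dissociation_threshold` (0.7). Free
nanoparticles leave the system with probability `np_loss_percentage`/100
per tick (0.2%; sedimentation and incorporation into bulk), their iron
moving to a closed ledger. With aging enabled, a particle not reduced for
`aging_lag` (200) ticks loses reduction susceptibility linearly at
`aging_rate` (0.003) per tick — a minimal stand-in for secondary-mineral
crystallization; any reduction event resets the clock.

**Aggregation.** Co-located free nanoparticles merge with probability
`mineral_aggregation_probability`/100 (100% at neutral pH, strongly reduced
at low pH), summing iron and recomputing the diameter. Merging is resolved
per patch per tick: arrivals are processed in random order and each joins
the patch's current resident aggregate with that probability. At the
default probability of 1 this is exactly "all co-located free particles
merge"; at intermediate probabilities it differs from pairwise
random-partner matching only in the transient size distribution, and it
vectorises over the 10⁴–10⁵ free particles that low-aggregation scenarios
produce. An aggregate's aging clock is the iron-weighted mean of its
constituents'.

## Scenario presets

`ph_preset()` quantifies the ordinal pH effects: abiotic oxidation ratio
0.001/0.003/0.01 at pH 5/6/7 (measured anchors at 5 and 7, geometric
midpoint at 6); aggregation probability 1/10/100 (maximal near the point of
zero charge at pH 7.8); FeRB adhesion tolerance ×10 at pH 5 (attachment
rises from ~20% to ~80% as pH drops from 6–7 to 5). `mode_combo()` crosses
the two adhesion modes with the two encrustation modes (combinations 1–4).
`cycling_schedule()` builds the two switching regimes used in the cycling
experiment: 6×(360 anoxic + 120 oxic) versus 2×(1080 anoxic + 360 oxic) —
equal total time (2880 min) and equal 3:1 anoxic:oxic duty cycle, differing
only in frequency. The interval lengths are this package's choice (the
motivating incubation study is cited without printed interval lengths);
keeping the duty cycle identical isolates the frequency effect.

## Sensitivity analysis

`param_space()` spans the 13 kinetic/threshold process parameters at
±20% uniform bounds around their defaults (world-setup parameters,
simulation control and the two literature-fixed motility speeds are held
constant; fraction-valued parameters are capped at their logical maxima).
`saltelli_sample()` generates the N(2k+2)-row second-order Saltelli design
(Latin-hypercube base matrices) — N = 500 with k = 13 reproduces the
14 000-run design. `sobol_indices()` implements the Saltelli first-order,
Jansen total-order and closed second-order estimators with bootstrap
confidence intervals; outputs are centred so indices are exactly invariant
under affine rescaling. The analytic checks (additive two-factor model and
the Ishigami function against their closed-form variance decompositions)
run in the test suite at N = 1024. The two headline output extractors are
the Fe³⁺ reduction rate of the last anoxic phase and the final nanoparticle
count; `interaction_network()` exports the S2 graph with S1/ST node
annotations.

## What the default conditions do and do not reproduce

The defaults place the model in a *substrate-saturated* regime: each bulk
patch holds 2×10⁶ units of Fe³⁺ (a solid 8 µm³ ferrihydrite block at 25
atoms/nm³), so shuttle reduction runs at full capacity (~21 000 units/tick
across 50 FeRB) throughout a two-day run and the standing Fe²⁺ stock grows
to ~10⁷ units. Consequences, measured by the acceptance suite:

* The oxidation-side calibrations reproduce almost exactly: the biotic
  share of total oxidation is ≈21% at abiotic ratio 0.01 and ≈71% at 0.001
  (literature anchors: 20% and ~70%); the shuttle share of an attached
  FeRB's reduction is exactly 80%.
* Per-patch adsorbed Fe²⁺ (≈0.9 × stock / n_solids, thousands of units)
  sits far above the 300-unit tolerance after the first few ticks, so the
  time-averaged attached-FeRB fraction is ~0.1%, not the ~20% the tolerance
  was fitted to reproduce. Equivalently, the 20% attachment datum requires
  a standing Fe²⁺ stock of only ~3×10⁵ units, i.e. realized reduction
  ~40-fold below the per-cell capacity.
* Because bulk reduction saturates, the nanoparticle pathway (capped by the
  biotic oxidation rate at ~6 000 units/tick of fresh particle Fe³⁺ per
  cycle) can raise the total reduction rate by at most ~30%, so the
  cycling-frequency experiment yields a short:long last-phase ratio of
  ~1.1 (direction correct, magnitude below the ~2× reported).

We probed the alternative, substrate-limited regime (bulk inventory
reduced 1000-fold): it recovers ~20% attachment and a ~2.2× cycling ratio,
but breaks the first-phase rate equality (inventory exhausts mid-phase),
shifts the biotic share to ~26%, and inverts the pH ordering of
nanoparticle reduction. No single value of the (unpublished) bulk-inventory
parameter satisfies all reported observations under this unit
reconstruction, so the package keeps the documented defaults and reports
the attachment and cycling-ratio checks as they come out. Users exploring
the substrate-limited regime need only override `bulk_fe3_per_patch`.

The shedding-size calibration (release at ~10 nm) is a property of the
growth-limited regime: when FeOB draw Fe²⁺ at the contact-oxidation cap,
new surface particles are seeded at ~40 nm equivalent and shed immediately,
so `shedding_diameter_experiment()` measures the release statistic where it
is meaningful — a single FeOB supplied by slow equilibration from a
pre-adsorbed reservoir (abiotic oxidation and particle loss disabled). Under
that supply the mean release diameter is ≈9–10 nm with sd ≈1.4 nm.

## Problem sizes used by tests and the acceptance script

Deterministic operations are tested on 5³–9³ fixture worlds. The
stochastic experiments use the full 21³ default world: the biotic-share
experiment runs 20 replicates of one 480-min cycle per abiotic ratio; the
attachment experiment runs 6 replicates of the full 2880-min short-cycling
schedule; the in-suite cycling and pH checks run on a proportionally scaled
13³ lattice (15 FeRB + 15 FeOB) with 1–2 replicates per arm.
These replicate counts are the package's choice for routine validation;
all experiment functions accept larger counts.

## Known limitations

* Oxygen is a binary world state, not a diffusing field; dissolved Fe²⁺ is
  a single well-mixed pool.
* Bacterial populations are fixed (no growth or death); runs represent 2–3
  days, short relative to the organisms' doubling times on iron metabolism.
* The equilibration partition among solids, the biofilm detachment
  constants, the chemotactic persistence time and the bulk-mineral iron
  inventory are free reconstructions, each flagged above.
* Nanoparticles are homogeneous spheres; no crystallographic phases, no
  chelation chemistry, no nitrate-coupled oxidation.
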