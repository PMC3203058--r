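---
title: "Conformation switching and symmetry breaking in a strings-and-binders model of the X-inactivation center"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformation switching and symmetry breaking in a strings-and-binders model of the X-inactivation center}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(xicsim)
```

## The model

`xicsim` simulates a schematic physical model of the X-inactivation center
(Xic): two identical self-avoiding bead chains on a periodic cubic lattice,
immersed in a solution of two species of diffusing molecular factors that
can glue distant chain regions together.  Each polymer carries five
functional blocks separated by inert spacers:

* two **alpha** blocks (binding sites for species-A molecules),
* two **beta** blocks (binding sites for species-B molecules),
* one central **gamma** block that both species can bind — the competitive
  hub of the architecture.

A molecule adjacent (unit lattice step) to a cognate bead gains a binding
energy `E_X` (in kT; energies are stored as positive magnitudes and applied
as negative contributions).  A molecule sitting next to beads of two
different regions forms a *bridge* that mechanically links them; many
bridges reinforce one another, and above a concentration/affinity threshold
they stabilise a looped conformation in which the alpha and beta blocks are
held at the gamma block.  Same-species molecules additionally attract each
other with homotypic energies `E_A`, `E_B`, capped at a valency of four
bonds per molecule (the CTCF-motivated choice: a finite number of
interaction surfaces).  All entities exclude each other (one occupant per
lattice site); binding acts through nearest-neighbour adjacency, never
co-occupancy.

Two thermodynamic switches emerge:

1. **Conformation switch.**  Starting from open chains, scanning the binder
   volume fraction `c` (or `E_X`) crosses a sharp line above which stable
   alpha–gamma and beta–gamma loops form on both polymers symmetrically.
   The order parameter is `P = (P_alpha + P_beta)/2`, the windowed fraction
   of samples in which the blocks are in contact with gamma.
2. **Symmetry-breaking switch.**  Starting from the symmetric looped state,
   raising the homotypic energy above a threshold condenses each species
   into a single aggregate; the A and B aggregates bind *opposite* polymers
   (they compete for the shared gamma sites), so one polymer keeps its
   alpha–gamma loop and loses beta–gamma while the other does the reverse.
   The order parameter is `S = (rho1 - rho2)/(rho1 + rho2)`, the normalised
   difference of species-A density around the two gamma regions.

## Energy function and valency

For each molecule the six neighbour sites are scanned in a fixed
lexicographic offset order.  Cognate beads contribute `-affinity[species,
region]`; same-species molecules are homotypic bond candidates.  Homotypic
bonds are capped at `valency = 4` per molecule; a pair contributes its
energy once, and only when each partner lies within the other's counted
candidates (the mutual-counting rule).  This makes the energy a pure,
deterministic function of the microstate — a requirement for Metropolis
sampling — at the cost of a slightly conservative count in rare crowded
configurations.

The cap scope is configurable.  With `cap_scope = "homo"` (the default)
only homotypic bonds are capped and heterotypic binding is limited only by
the six lattice neighbours; with `"total"` the four slots are shared by all
bonds.  The homotypic-only default follows the model's motivation (the
valency describes the self-association surfaces of a CTCF-like factor) and
is mechanistically important: under a shared cap, bead binding and cluster
binding compete for the same slots, so molecules either coat the polymers
without aggregating or form aggregates that detach from the chains; either
way the symmetry-breaking pathway — a polymer-bound single aggregate per
species — is suppressed.

## Monte Carlo dynamics

Moves are the standard local cubic-lattice set: uniform nearest-neighbour
molecule steps, corner flips for right-angle interior beads, single-step
end rotations, and 90/180/270-degree crankshaft rotations of U-shaped bead
quadruples.  Each attempt selects a movable entity uniformly (one sweep =
one attempt per entity on average); inapplicable selections count as null
attempts so that proposal probabilities remain symmetric, and acceptance is
`min(1, exp(-dE))` with locally computed energy differences.  The engine
asserts the exact agreement of its incremental energies with full
recomputation at the end of every run, and the test suite verifies the
sampler against exhaustive enumeration: on a 4x4x4 lattice with a 3-bead
polymer and one molecule, the empirical distribution over all 1,830
translation-classes of microstates matches the exact Boltzmann distribution
to a total-variation distance well below 0.02.

Kinetic realism is limited to diffusive scaling: the move set has no
hydrodynamics and no reptation, so times are meaningful only through the
diffusion-matching calibration below.

## Initial states

* `init_state(params, "open")` grows each polymer as a random self-avoiding
  walk confined to its own lattice octant and scatters molecules uniformly
  over free sites — the open-conformation start used for conformation
  scans.
* `init_state(params, "looped")` builds a deterministic compact fold: the
  gamma block runs along a lattice axis, the four functional blocks lie on
  the diagonal columns around it, and the inert spacers are exact-length
  self-avoiding connectors found by a deterministic depth-first search.
  One cognate bridging molecule per functional block is seeded next to the
  gamma line, so every alpha–gamma and beta–gamma contact holds by
  construction.  (On the bipartite cubic lattice, blocks at even chain
  separation from gamma can never be directly adjacent to it, so a
  molecule-bridged looped state is both necessary in general and the
  physically relevant stabilised configuration.)  This is the symmetric
  start for symmetry-breaking runs.

## Observables

* **Contacts** — a functional block is in contact with gamma if a cognate
  molecule is simultaneously adjacent to a bead of each (a bridge), or if
  beads of the two regions touch directly.  Bridges are species-typed
  because bridging is mediated by binding: a molecule can only bridge
  regions it has nonzero affinity for.
* **P** — fraction of (window x polymers x blocks) samples in contact;
  `P_alpha` and `P_beta` are reported separately and `P` is their mean.
* **S** — normalised A-density difference around the two gamma regions.
  Densities are counted in the union of Chebyshev balls of radius
  `shell_radius = 2` around the gamma beads (the smallest shell that
  distinguishes "around" from "bound to"); adjacency itself always uses the
  six nearest neighbours.
* **Cluster fractions** — largest nearest-neighbour-connected same-species
  component over the species count, by flood fill under periodic wrap.

## Units

`volume_fraction_to_molar(c, d0)` converts the lattice volume fraction into
mol/L via `c / (N_A d0^3)`; with `d0 = 10` nm, `c = 0.01` is about 17 uM.
Time is calibrated by diffusion matching: `measure_model_diffusion()` fits
the linear regime of the mean-squared displacement (a single free molecule
gives the random-walk value `D = 1/6` lattice^2/sweep), and
`physical_calibration(d0, D_real, D_mc)` converts sweeps to seconds via
`d0^2 D_mc / D_real`.  The defaults `d0 = 30` nm and `D_real = 1e-3`
um^2/s are literature-typical calibration choices for chromatin-scale
beads, not model outputs; both are mandatory config inputs.

## Study conditions and what the tests show

Simulation scales were chosen so the full suite runs on a single CPU in
minutes per scenario:

* Conformation scans use `L = 16`, `n = 4`, `E_X = 3.5`, three replicates
  per point, 5e5 sweeps per run, scanning `c` over the decade
  `5e-4 .. 5e-3`.  At the top of the decade `P` exceeds 0.9 from an open
  start; at the bottom the lattice holds only two molecules per species, and
  their rare but long-lived bridges keep the time-averaged contact fraction
  near 0.2 — the minimum realisable concentration sits less than a decade
  below the transition at this lattice size, a finite-size floor discussed
  in the test annotations.
* Symmetry-breaking runs use the looped symmetric start at `L = 12`,
  `n = 4`, `c = 9e-3` (16 molecules per species), `E_X = 3.5`, contrasting
  `E_A = E_B = 0` with a strong homotypic coupling (`5 kT`), with longer
  trajectories (millions of sweeps) because aggregate coarsening is the slow
  mode — mirroring the physical separation between fast loop formation and
  slow symmetry breaking that the timescale checks quantify.  At this box
  size the broken state (one polymer monopolising the A aggregate, the other
  the B aggregate, with opposite loop architectures) forms in a minority of
  replicates and competes with a small-box artifact in which the two
  polymers colocalise and share the aggregates; the vignette's "known
  limitations" and the test annotations discuss this finite-size behaviour.

The synthetic-data generator *is* the model: no external data enters, so
passing tests demonstrate internal correctness (exact Boltzmann sampling,
exact bookkeeping, reproducibility) and the existence, sharpness and
direction of the two switches at desk scale.  They do not calibrate the
model against chromosome-conformation measurements, and absolute
transition coordinates at biological scale are outside what these lattice
sizes can fix.

## Numerical choices

* Coordinates are 0-based integer triples wrapped modulo `L`; periodic
  boundaries avoid wall artifacts.
* Molecule counts are `round(c L^3)` per species, independently.
* Equilibration discards the first half of each recorded series by default
  (`equilibration_frac = 0.5` in scans).
* Threshold estimation interpolates the first crossing of level 0.5 (the
  midpoint convention for sharp sigmoids); both the level and the response
  are arguments, and a scan that never crosses returns an explicit
  no-crossing row.
* Replicate-level standard errors are the primary uncertainty; replicates
  are independent by construction (per-point seeds derived from the base
  seed and the point/replicate index, all below 2^31).
* The n = 1 looped construction is a hand-built special case (see above);
  all other `n` use the template-plus-DFS constructor, which needs
  `L >= n + 6`.

## A short example

```{r example, eval = FALSE}
p <- model_params(n = 4, L = 16, c = 0.005, E_X = 3.5,
                  sweeps = 50000, record_every = 500)
st <- init_state(p, "open", seed = 1)
run <- run_mc(st, p, seed = 2)
glance(run)
autoplot(run)

scan <- phase_scan(p, vary = list(c = c(5e-4, 1.5e-3, 5e-3)),
                   replicates = 3, seed = 10)
estimate_threshold(scan, "c")
autoplot(scan)
```

## Known limitations

* Desk-scale lattices (L of order 16) leave the conformation transition
  visibly smeared: order parameters near the threshold carry long-lived
  fluctuations from single sticky bridges, and concentrations less than a
  decade below threshold are not realisable with at least one molecule
  present.
* The valency cap uses greedy deterministic counting, not an optimal bond
  assignment; energies in dense aggregates are therefore a lower bound on
  the attainable bond count (identical for all states compared within a
  run, so sampling is unaffected).
* Polymer kinetics are local-move diffusive; absolute times are meaningful
  only after diffusion calibration and only as orders of magnitude.
* Two polymers and two binder species are hard assumptions of the
  implementation.
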