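---
title: "Building coarse-grained membrane systems: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building coarse-grained membrane systems: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cgbuildr assembles coarse-grained (CG) membrane/solvent/protein systems for
molecular-dynamics engines from a single declarative specification. This
vignette explains the procedures the package implements, the tunable
parameters and their defaults, the numerical choices that were genuinely
open, and what the synthetic fixtures do and do not demonstrate.

## The integer allocation problem

A flat bilayer patch is described by three user quantities per leaflet: the
free leaflet area $A_{\mathrm{free}}$ (boundary area minus protein
footprints and pores, nm²), the area per lipid (APL, nm²), and the ratio
weights $w_i$ of the lipid types. The ideal lipid count

$$N_{\mathrm{ideal}} = A_{\mathrm{free}} / \mathrm{APL}$$

is real-valued, but a simulation accepts only whole lipids, so every builder
must round somewhere and the choice of where determines the build error. The
package rounds once, at the level of the whole leaflet:

$$N_{\max} = \left[ A_{\mathrm{free}} / \mathrm{APL} \right]$$

(nearest integer), so $|N_{\max} - N_{\mathrm{ideal}}| \le 0.5$ always, and
the relative deviation falls below 1% as soon as the leaflet holds 50+
lipids — for APL 0.6 nm² that is a 6 × 6 nm patch. Per-type counts start
from the floors $\lfloor w_i/\sum_j w_j \cdot N_{\max}\rfloor$ (their sum is
$N_{\min}$) and are filled up to $N_{\max}$ by repeatedly granting one lipid
to the type with the largest *relative* deficit
$(s_i - c_i)/s_i$, where $s_i$ is the ideal share and $c_i$ the current
count. Because each grant drives that type's deficit negative, the greedy
fill gives one extra lipid to each of the $r = N_{\max}-N_{\min}$
highest-deficit types, which is provably the floor-respecting composition
with the minimal worst relative deficit; the test suite confirms this
against exhaustive enumeration over all weight vectors with up to 4 types
(weights 1–9) and totals up to 30. Ties break by declaration order, which
makes allocation deterministic and user-steerable. An alternative
absolute-deficit priority ($s_i - c_i$) is available via
`priority = "absolute"`; it favors abundant types where the relative rule
favors rare ones.

For comparison, `insane_count()` implements the two-rounding
row-times-column rule used by grid-based builders,
$[x/\mathrm{APL}]\cdot[y/\mathrm{APL}]$, exactly as that formula is
conventionally printed. Note it divides a length by an area; we reproduce
the printed form verbatim as a comparison reference rather than "repairing"
it to $x/\sqrt{\mathrm{APL}}$, and `accuracy_sweep()` quantifies how far its
counts drift from $N_{\mathrm{ideal}}$ as the patch grows.

**Rounding rule.** "$[\cdot]$" is round-half-away-from-zero, not banker's
rounding — reproducible across platforms and matching the colloquial
"nearest integer". A relative guard of $10^{-9}$ snaps values that are
half-integers in exact arithmetic but land just below .5 in IEEE doubles
(e.g. $36.3/0.6$ evaluates to 60.49999999999999) onto the boundary before
rounding.

## Disc packing and relaxation

Each planned lipid becomes a disc in the membrane plane. The packing radius
of a type defaults to half its maximal bead-pair distance *in xy* plus
0.1 nm padding — CG lipid templates are elongated in z, so radii are small
(0.1–0.3 nm for the fixture templates). Types split into large/small classes
at the median radius unless a class is set explicitly.

Initial placement is two-phase: large lipids go on a square grid with pitch
twice the largest large radius, cells drawn at random (seeded) from those
inside the region; small lipids fill y-directional lines through the space
left over, keeping clear of the placed large discs. Both phases tighten
their spacing by factor 0.92 (up to 25 rounds) if the requested count does
not fit at the nominal spacing, and raise a placement-infeasible error
otherwise; the relaxation step then resolves the residual crowding.

Relaxation is a damped push scheme. For each pair within a cutoff of
$1.2(r_i+r_j)$ the discs move apart along their center line by
$\mathrm{overlap} \times (r_i+r_j)/2 \times \lambda(s)$, where the step
factor $\lambda$ decreases linearly from 0.5 to 0.05 over the step budget
(default 100): big corrective moves early, fine adjustment late. The
boundary and every hole (pore or protein footprint) push penetrating discs
the same way. Per-step moves are capped at one radius, positions are
re-projected into the region after every step, and iteration stops when the
largest per-disc move drops below the tolerance (default 0.005 nm). Every 10
steps the total pairwise overlap is sampled; a window that worsened it rolls
back to the best checkpoint before continuing, so the sampled overlap trace
is non-increasing by construction while the scheme still escapes transient
configurations. Exactly coincident centers (possible only in degenerate
inputs) are separated along a seeded random direction. The relaxed discs are
realized in 3D by translating each lipid template to its disc center at the
leaflet anchor plane, rotating it about z by a seeded random angle, and
negating z for the lower leaflet (templates are authored head-anchor at the
origin, tails toward $-z$).

Free areas with holes are measured by cell-center rasterization at 0.01 nm
resolution (coarsened automatically if a pathological region would exceed
20M cells), after polygonizing circular holes as 32-gons (0.64% inscribed
area deficit, inside the 1% footprint tolerance the package promises). No
polygon-clipping library is required, and overlapping holes are naturally
counted once. Packing is not periodic: edges push, and periodicity is left
to the simulation engine.

## Solvation, ions, neutralization

The box is rasterized into cubic cells whose edge equals the largest
intra-molecular bead distance over the requested solvents, floored at
0.5 nm. Cells containing an existing bead, or overlapping a membrane's
hydrophobic slab within its xy footprint (minus pores), are unavailable.
The hydrophobic slab of a membrane is the z-range of its realized tail
beads plus a 0.15 nm margin.

Counts come from molarity: $N = [\,c \cdot N_A \cdot V_{\mathrm{free}}\,]$
with $N_A = 0.6022140857$ molecules·nm⁻³·(mol/L)⁻¹. Molarity here counts
whole CG molecules, not beads — so Martini-style 4-to-1 water is requested
at its bead molarity (~13 M behaves like bulk water; one molecule per
0.5 nm cell caps the density at 13.28 M). Mixtures split the summed-molarity
total by the requested ratios; in `mapping` mode each weight is first
multiplied by the solvent's atom-to-bead mapping factor, so a 50:50 request
with factors 4:1 yields an 80:20 molecule split. The split reuses the floor
+ greedy-fill allocator, so mixture counts sum exactly to the total.
Molecules occupy distinct free cells chosen by seeded sampling without
replacement, centered in the cell.

Salt is inserted first at the target molarity (equal counts of both
species, converted with the same solvent-accessible volume the solvent
counts used), then the system is neutralized exactly by one of three
algorithms: **add** counterions (topping off with a co-ion addition when
the counterion valence does not divide the excess, so the path never
removes anything); **remove** co-ions from those placed (stepping in
co-ion-valence units — infeasible excesses, e.g. an odd charge with
divalent co-ions, raise an error rather than leaving residual charge);
**combined**, which splits the correction as evenly as the valences allow
between additions and removals, odd remainder to the addition side. A
purely divalent ion pair can never cancel an odd excess (parity); the
package reports that as neutralization-infeasible instead of approximating.
All successful paths end at a net charge of exactly zero in integer
arithmetic.

## Topologies, libraries, fragments

GROMACS topologies are parsed only for what the builder needs: per-bead
charges from `[moleculetype]`/`[atoms]` blocks, collected depth-first across
the `#include` tree (includes resolve relative to the including file);
`#ifdef` blocks pass through unevaluated with a warning. The output `.top`
preserves the root file verbatim (including its `#include` lines), replaces
`[system]`/`[molecules]`, and run-length encodes only *consecutive*
identical molecules so the ledger reflects the true build order.

Molecules live in priority-ordered libraries; the same name in two libraries
resolves to the higher-priority one, so development parameter sets can
shadow stock ones. Lipids can be assembled from head/linker/tail fragments
joined by translation only (anchors coincide exactly, internal fragment
geometry untouched, charges add). The `craft()` path writes a single
molecule's structure without building a system. The in-built fixture
library ships one two-bead zwitterionic head, two single-bead heads (one
anionic), one- and two-tail linkers, and two tail lengths — enough to
exercise every assembly path.

## What the fixtures emulate — and what they do not

Fixture geometry is idealized: beads on straight stacks and lattices,
single-bead solvents and ions, toy cylinder/hourglass "proteins". They
exercise the package's algorithmic contracts — integer allocation, leaflet-
selective footprints, packing invariants, charge closure, format
round-trips — at desk scale. They make no claim of force-field realism:
passing tests says nothing about the physical accuracy of Martini or any
other parameter set, about lipid entropy or tail packing in 3D, or about
the equilibrium APL of a real composition. For asymmetric membranes the
APLs remain user inputs; a sound workflow is to pre-equilibrate two
symmetric membranes (one per leaflet composition) in short simulations and
feed the relaxed APLs back in.

## Numerical choices and problem sizes

* Default membrane thickness (anchor-plane separation) is 4 nm, matching
  the ~2 nm fixture lipid length; override per membrane.
* The packing test suite runs 50 seeded random mixtures up to ~500 lipids
  with pores and protein footprints, and the allocation oracle enumerates
  all ≈207,000 weight/total instances — together about one minute of CPU;
  the accuracy sweeps (4–51 nm, 0.05 nm steps) are vectorized and run in
  milliseconds.
* Stage seeds derive from the master seed by a stable string hash of the
  stage name, so adding a stage never reshuffles another stage's draw, and
  a build is a pure function of (spec, seed) — two runs produce
  byte-identical GRO output.
* The serial stage order is proteins → membranes (leaflet by leaflet,
  membranes by ascending center z) → flooding solutes → solvent → ions →
  writers. Placing proteins first lets every later stage treat them as
  immovable obstacles; solvating last lets the grid see all obstacles at
  once.
* Degenerate inputs: a region fully covered by holes yields free area 0
  with a warning; placement that cannot fit after 25 tightening rounds
  raises a placement-infeasible error naming the leaflet; non-finite
  coordinates are refused by the writers with the offending bead named.

## Known limitations

Only flat membranes (no curvature, no vesicles); no dynamic leaflet
segmentation, so very large leaflets pay the full pairwise relaxation cost;
solvent is placed on cell centers without local density refinement;
`#ifdef` topology branches are not evaluated; the CLI grammar is the
package's own — it is deliberately small and maps one-to-one onto the
config file keys.
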