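---
title: "Model and methods: staged ESCRT-III membrane remodelling in escrtsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

ESCRT-III is the only cytoskeletal machine known to constrict and cut a
membrane neck from the inside. In vesicle-budding assays the machine works as
a relay of polymer species: a flat spiral (Snf7-like) binds the flat
membrane; a wider helical copolymer (Vps24/Vps2-like) joins it and buckles
the membrane; the spiral is then disassembled by the Vps4 ATPase and the
buckle becomes a tubule; a tight helix (Did2/Ist1-like) constricts the neck
and, upon its own disassembly, the neck severs and a cargo-loaded vesicle is
released. `escrtsim` is a coarse-grained molecular-dynamics implementation
of that relay: a one-particle-thick fluid membrane, pre-assembled filaments
of programmable target geometry and stiffness, a generic cargo sphere, a
Langevin/zero-tension ensemble, staged recruitment/constriction/disassembly
protocols, and the observables needed to quantify the outcome (deformation
angle, bending rigidity, scission and pore detection, copolymer stability,
subunit partitioning).

All internal quantities are in reduced MD units: the length unit is
$\sigma = 2.3\,$nm, energies are in $k_BT$, times in $\tau$ (deliberately
not mapped to seconds: the model's kinetics are reported per $\tau$, rates
in nm/$\tau$), bead masses are 1.

# The membrane model

Each membrane bead carries a position and a unit orientation axis
$\mathbf{n}$ that represents the local bilayer normal. Two beads at
separation $r$ with axes $\mathbf{n}_i,\mathbf{n}_j$ interact through

$$
U(r,\mathbf n_i,\mathbf n_j)=
\begin{cases}
u_R(r) + \varepsilon\,[1-\phi] & r < r_{\min}\\[2pt]
u_A(r)\,\phi & r_{\min}\le r < r_c
\end{cases}
$$

with a soft 2–4 repulsive core $u_R(r)=\varepsilon[(r_{\min}/r)^4 -
2(r_{\min}/r)^2]$, a smoothly truncated attractive tail
$u_A(r)=-\varepsilon\cos^{2\zeta}\!\big(\tfrac{\pi}{2}
\tfrac{r-r_{\min}}{r_c-r_{\min}}\big)$, and an alignment factor
$\phi = 1 + \mu\,(a-1)$ where
$a = \mathbf n_i\!\cdot\!\mathbf n_j - (\mathbf n_i\!\cdot\!\hat
r)(\mathbf n_j\!\cdot\!\hat r)$ (zero spontaneous curvature). Defaults:
$\varepsilon_{mm} = 4.34\,k_BT$, $\zeta = 4$, $r_{\min} = 2^{1/6}\sigma$,
$r_c = 2.6\,\sigma$. Tilting a pair of axes out of alignment with their
common plane costs energy proportionally to $\mu$, which therefore controls
the bending rigidity $\kappa$.

Forces and torques are the exact analytic gradients of this energy (the
attractive tail shape is tabulated and Hermite-interpolated, so the force is
the exact derivative of the interpolated energy); the test suite verifies
energy–force consistency against central finite differences to $10^{-6}$
relative and exact pairwise momentum conservation.

**Rigidity calibration.** The default $\mu$ was fixed by the package's own
fluctuation-spectrum estimator: a tensionless periodic patch is thermalized
and the gridded height field's spectrum is fitted with
$\langle|h_q|^2\rangle = k_BT/(A\kappa q^4)$ over a low-$q$ window
($|q|\le 0.8\,\sigma^{-1}$, one estimate per mode, averaged in log space).
At $\mu = 3$ the estimator returns $\kappa \approx 20\,k_BT$, the
physiological value the model targets; $\mu = 5$ is the rigid preset and
measures $\kappa \approx 35\,k_BT$, consistent with a roughly linear
$\kappa(\mu)$ over the tested range ($\kappa$ is monotone in $\mu$ between 3
and 5). The estimator itself is validated by a generate-and-recover oracle:
synthetic height fields drawn with independent Fourier modes of prescribed
variance are recovered within 10%.

The zero-tension state of this parameterization is relatively dense (about
0.85 $\sigma^2$ of projected area per bead) and fluid: the in-plane
mean-squared displacement of beads grows linearly in time
($D \approx 0.06\,\sigma^2/\tau$ at $\mu=3$–5). Below $\mu \approx 3$ the
sheet loses orientational stiffness and crumples, so the default sits at the
soft end of the usable window.

# Filaments

A filament is a string of three-bead subunits: two membrane-binding beads
and one back bead forming a rigid isoceles triangle (width $1\,\sigma$,
binding beads displaced $0.4\,\sigma$ toward the binding face, back bead
$0.6\,\sigma$ away; the triangle is held by three stiff harmonic bonds,
$k = 500\,k_BT/\sigma^2$). Consecutive subunits are connected by 9 harmonic
bonds — every bead pair between the two triads — whose rest lengths are the
bead–bead distances of two consecutive triads placed on the ideal target
backbone (`solve_rest_lengths()`). This encodes the filament's target
radius, pitch and binding-face tilt purely in the bond network: a free
filament relaxes to its target shape (verified to within 5% for the
reference 19.4 nm spiral and for helices at $k \ge 32\,k_BT/\sigma^2$).

The tilt convention follows the biology: tilt 0° points the binding face
straight down (Flat Spiral, binds flat membrane), tilt 90° points it
radially outward (Wide and Tight Helix, bind the inside of a membrane
tube). Constriction is a per-step linear interpolation of the target radius
(rest lengths recomputed each step) at a rate given in nm of target radius
per $\tau$.

Species presets: Flat Spiral $R_1 = 19.4$ nm, pitch 0, tilt 0,
$k_1 = 128\,k_BT/\sigma^2$; Wide Helix $R_2 = 0.85\,R_1$, tilt 90°; Tight
Helix starts at $R_2$ and constricts toward $R_3$ ($R_{\rm final} = 5.7$ nm
in the disassembly studies). The production-scale pitch (4.5 $\sigma$ per
turn at full scale) and subunit spacing (1 $\sigma$) are package choices:
the available characterizations of these polymers constrain radii and
stiffnesses but not pitches or subunit counts.

# Non-bonded interactions

All cross-interactions use the same functional family as the membrane tail
(2–4 core plus $\cos^2$ tail), so every term is smooth at its cutoff and the
stated well depth is reached exactly at the minimum distance:

* binding bead–membrane: short-ranged attraction, default
  $\varepsilon_{bm} = 3.5\,k_BT$, cutoff $1.8\,\sigma$. This must stay below
  the membrane's cohesive scale: at $\varepsilon_{bm}\gtrsim 5$ filaments
  extract beads from the sheet and shred it.
* binding bead–binding bead of *different* filaments: weak lateral
  attraction ($\varepsilon_{bb} = 2\,k_BT$) that drives copolymerisation.
  Within one filament the shape is encoded purely in the bond network, so
  same-filament non-bonded pairs are excluded-volume only (otherwise the
  lateral attraction systematically over-curls free filaments).
* cargo–membrane: attraction between the cargo *surface* and membrane beads,
  default $4\,k_BT$, deliberately below the spontaneous-engulfment threshold
  $\sim 2\kappa/R_c^2$ so that wrapping is filament-driven; a zero value
  gives the volume-exclusion-only cargo variant.
* everything else: purely repulsive 2–4 core (excluded volume).

Severed subunits lose their inter-subunit bonds and (by default) their
membrane and lateral attraction, becoming volume-excluded diffusing
particles; they can also be deleted from the box (`remove = TRUE`).

# Dynamics

Translational degrees of freedom follow BAOAB-split Langevin dynamics;
membrane axes follow rotational Langevin dynamics driven by the exact
torques, with angular velocity kept perpendicular to the axis and the axis
renormalized after every rotation. Defaults: $dt = 0.01\,\tau$,
$\gamma = \gamma_r = 1/\tau$, $m = I = 1$. These were fixed by a stability
scan (the divergence guard aborts on any half-step displacement above
$0.25\,\sigma$) and validated by the invariant suite: NVE energy drift
$< 10^{-4}$ relative over $10^4$ steps at $dt/2$, kinetic temperature within
2% of target over $10^5$ steps, bit-identical trajectories under equal
seeds.

The isothermal–isobaric ensemble is realized by a Berendsen-style weak
coupling of the in-plane box toward zero lateral tension (tension measured
from the 2D virial; verified against $\mathrm dU/\mathrm dA$ by finite
differences to 1%). The box rescales by at most $5\times10^{-4}$ per update,
every 10 steps, with coupling $2\times10^{-3}$; the normal direction is
open.

Randomness: one user seed per run; every stage, replica and engine call
derives an independent child stream (`derive_seed()`), so adding analysis or
replicas never perturbs the dynamics of existing ones.

# Protocols and the desk-scale presets

`run_protocol()` executes an ordered stage list (recruit, equilibrate,
sever, constrict, disassemble), logs events and per-stage deformation
angles, and classifies the outcome (flat / buckle / tubule / scission /
filament_detached / membrane_ruptured). Scission is defined operationally as
the membrane splitting into a mother component that spans the periodic
boundaries (a BFS-unwrap percolation test) and a closed vesicle component
nearest the cargo (every bead with $\ge 3$ neighbours *and* full directional
coverage around the component centroid, which rejects open cups). Because a
detached vesicle can transiently re-contact the mother in a small periodic
box, scission is checked every 25 $\tau$ during equilibration stages and the
first detection time is recorded; efficiency is the fraction of replicas
reaching scission within the stage budget.

Equilibration stages end after a fixed $\tau$ budget, not on a convergence
criterion, so batch scans are reproducible row by row from their manifests.

The packaged desk-scale presets (`desk_demo_system()`,
`desk_demo_schedule()`) realize the full pathway on one CPU in a few
minutes: a 24×24-bead patch, radii at half the production values, a 24-unit
Flat Spiral, 40-unit Wide Helix, 24-unit Tight Helix, cargo of radius
2.5 $\sigma$ with adhesion 4 $k_BT$, constriction at
$1.68\times10^{-2}$ nm/$\tau$ (eight times the production rate, matching the
halved deformation distances) to $R_{\rm final} = 5.7$ nm (scaled), then
sequential-from-the-bottom disassembly at 0.05 subunits/$\tau$ with severed
subunits removed from the box. Removal is the appropriate desk-scale choice:
the nascent vesicle is only a few subunit volumes large here, so retained
monomers crowd it in a way they do not at production scale. With these
settings the staged pathway reproduces the ordered sequence — shallow
state with spiral and cargo ($\theta \approx 20$–40°), buckle on Wide-Helix
recruitment ($\theta \approx 45$–55°), tubule after constriction
($\theta \gtrsim 70$°), then scission — across seeds, and the no-cargo
control ends with neck retraction ($\theta$ back to 0) instead of
scission.

Two desk-scale caveats follow from the reduced geometry and should be kept
in mind when interpreting passing tests. First, the cargo is only
$\sim 11$ nm across, so even sub-threshold adhesion wraps it partially
before any filament arrives: the "flat" spiral+cargo stage reads
$\theta \approx 20$–40° rather than $\approx 0$°, and the flat-to-buckle
transition is asserted as an ordered $\theta$ deepening, not as a rise from
exactly zero.
Second, kinetic rates are not directly comparable to production values; the
trends (slow constriction outperforms fast, sequential disassembly
outperforms random at a slow rate) are the meaningful desk-scale statements,
and are what the acceptance suite asserts, at reduced replica counts
(majority over 3 seeds for the main pathway, single-seed trend checks for
the comparisons).

# Observables

* **Deformation angle** $\theta$: reference height from the peripheral 20%
  of beads (by in-plane distance from the deepest bead), depth to the
  minimum; beads within a 2 $\sigma$ slab at half depth contribute the angle
  between their orientation axis and the vertical, and $\theta$ is the mean
  per-bead angle (so cones average correctly instead of cancelling their
  horizontal components). Depth below 2 $\sigma$ — the thermal roughness of
  a 20 $k_BT$ patch — reads as flat, $\theta = 0$. Analytic fixtures verify
  $\theta = 0$ (flat), 90° (capped cylinder) and $90° - \alpha$ (cone of
  half-angle $\alpha$) within 2°.
* **Bending rigidity**: see calibration above.
* **Connectivity / pores**: proximity-graph components with periodic
  wrapping (validated against a flood-fill oracle); pores are proximity
  clusters of under-coordinated beads forming closed loops away from an
  open patch's outer boundary, with centroid and ring-perimeter estimates.
* **Copolymer stability**: fraction of replicas in which *both* filaments
  end attached (binding fraction $\ge$ 50% of binding beads within the
  binding cutoff — the threshold is a package choice, exposed as config).
* **Subunit partitioning**: fraction of final-helix subunits whose centroid
  is nearer the vesicle than the mother after scission.
* **Local energy profile**: per-bead energies (pair terms split half/half)
  minus a flat-membrane baseline from a dedicated reference run, binned
  along the neck axis with 1 $\sigma$ bins; empty bins are reported missing,
  not zero.
* **Pore-formation energy**: excess potential energy at pore opening
  divided by the opened area, in $k_BT$/nm². The printed production-scale
  band (0.5–0.6 $k_BT$/nm²) requires full-scale staged replicas and is not
  recomputed at desk scale; the observable's arithmetic and linearity are
  unit-tested.

# Numerical choices and limitations

* FIRE minimization caps per-iteration displacements (0.05 $\sigma$ for
  recruitment relaxation) and axis rotations (0.1 rad) — uncapped axis
  rotations can melt the sheet during energy descent.
* The neighbor list is a Verlet list from a cell grid (skin 0.4 $\sigma$,
  rebuilt on half-skin displacement), with an all-pairs fallback for boxes
  under three cells; cargo beads interact through a direct O(N) loop because
  their interaction range exceeds the lattice cutoffs. List totals equal
  brute-force totals to $10^{-12}$.
* Ties and degeneracies: component labels are deterministic (smallest bead
  index first); random disassembly orders derive from the stage seed alone.
* The barostat is not a true NPT integrator (Berendsen coupling does not
  sample the isobaric ensemble exactly); for the quantities computed here
  (zero-tension means and spectra) the bias is negligible compared to the
  stated tolerances.
* Pre-assembled filaments only: no monomer-by-monomer polymerisation
  kinetics, no explicit Vps4 particle (disassembly rates are its proxy), no
  bilayer resolution, no hydrodynamics.
* Desk-scale runs use half-scale radii and faster rates; they demonstrate
  mechanisms and trends, not production-scale efficiencies.
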