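---
title: "Models and methods behind lassofold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lassofold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

lassofold simulates the folding of complex-lasso proteins — proteins whose
backbone pierces a covalent loop closed by a disulfide bridge — at the
Calpha level, and quantifies the topology of the resulting trajectories.
This vignette explains the models, the descriptors, the optimizer, and the
numerical decisions, in the package's own terms. Everything is expressed in
reduced units: length in sigma = 3.8 Angstrom (the Calpha-Calpha spacing),
energy in E, mass m = 1, temperature in E/k_B, time in tau_MD =
sigma * sqrt(m/E).

## The elastic folder model

The chain is N identical beads. The potential energy is the sum of four
terms:

* **Sterics.** A Weeks-Chandler-Andersen (WCA) repulsion over all bead
  pairs: the Lennard-Jones potential shifted up by epsilon and truncated at
  its minimum `2^(1/6) sigma`. The pair sum includes directly bonded
  neighbours; together with the FENE attraction this places the bonded pair
  minimum at 0.961 sigma. (Excluding bonded pairs would leave the FENE bond
  without a repulsive core — its minimum is at r = 0 — and the chain
  collapses; a `wca_exclude_bonded` flag exists for experimentation.)
* **Bonds.** Finitely extensible nonlinear elastic (FENE) bonds with
  k_FENE = 30 and maximal extension R0 = 1.5 sigma.
* **Angular terms** — the folding drive. Harmonic bending
  `k_i (theta_i - theta_i0)^2` (note: no 1/2 factor) on the interior angle
  at each bead, and a two-harmonic torsion term on each dihedral,
  `k1_i [1 - cos(phi - phi_i0)] + k3_i [1 - cos(3 (phi - phi_i0))]` with
  the model constraint k3 = k1/3. The reference angles theta0, phi0 are
  those of a chosen reference (native) structure, so the reference
  conformation is the global minimum of the angular energy and its angular
  energy is exactly zero. We deliberately write the cosines with the sign
  that makes phi0 the *minimum*; a torsion term that is maximal at the
  native dihedral could not drive folding, and the constant offset is
  irrelevant to the dynamics.
* **Disulfide bridges** (oxidizing conditions only). For each
  bridge-forming cysteine pair, a truncated and force-shifted Lennard-Jones
  well whose length parameter is chosen so the minimum sits at the native
  pair distance (sigma_b = d_native / 2^(1/6)). Both the energy and its
  derivative vanish at the cutoff, default 2.5 sigma_b. The well depth
  defaults to 10 k_B T of the run, so a formed bridge is rarely broken by
  thermal fluctuations; reducing conditions simply omit the term.

The homogeneous model uses k_bend = 36.5 and k1_tor = 38.5 everywhere; the
optimizer (below) tunes the per-angle values.

## The Go model

For comparison, a Clementi-type structure-based model: 12-10 Lennard-Jones
wells `E_ij [5 (r0/r)^12 - 6 (r0/r)^10]` on the native contacts, each
minimal at the native pair distance, plus the same bending/torsion terms
with homogeneous coefficients (k_bend = 40, k1 = 1.0, k3 = 0.5 — here k3 is
independent), harmonic bonds at the native bond lengths (k_bond = 100), and
a force-shifted 12-power excluded volume (diameter 4.0 Angstrom) for
non-contact pairs separated by at least 3 residues. Contacts are read from
a SMOG-style two-column file when available, otherwise built from the
native structure with a Calpha cutoff of 7.5 Angstrom and |i - j| >= 3.
Oxidizing conditions raise the contact amplitude of the bridge-forming
cysteine pairs to 10 k_B T; those pairs are retained as (ordinary-strength)
contacts under reducing conditions, so the difference between environments
is purely the amplitude.

## Langevin dynamics

Trajectories use the BAOAB splitting of underdamped Langevin dynamics
(velocity half-kick, half-drift, Ornstein-Uhlenbeck velocity refresh,
half-drift, half-kick), with friction gamma = m/tau_frict = 1 and time step
dt = 5e-4 tau_MD. BAOAB was chosen for its accurate configurational
sampling at finite dt; with the thermostat disabled (`tau_frict = Inf`) it
reduces exactly to velocity Verlet, which the energy-conservation test
exploits. Initial velocities are Maxwell-Boltzmann draws from the
trajectory seed; a given seed reproduces a trajectory bit-exactly on one
platform. Folding runs start from stretched random configurations: beads
along a random direction at unit spacing, transverse Gaussian noise
(sd 0.05 sigma), then 300 small steepest-descent steps on the bonded
FENE + WCA pair terms to remove bond strain (the descent step is 4e-4;
larger steps oscillate on the stiff WCA core).

Two numerical regularizations of the angular forces matter:

* the bending gradient has a removable singularity at collinear triples
  (`dcos/dr` vanishes as fast as sin(theta)); it is evaluated with a
  rounding guard only, so the force stays the exact gradient;
* the dihedral gradient genuinely diverges like 1/sin(theta) when a
  flanking bond angle approaches linearity — the regime every stretched
  start occupies. The torsional torque is therefore tapered smoothly
  (a C1 smoothstep in sin(theta)) to zero below sin(theta) = 0.2. The
  energy is not modified, so within the bent regime (sin(theta) >= 0.2,
  which includes folded and folding structures) forces remain exact
  negative gradients; force-consistency tests sample that regime.

Even so, the collapse of a stretched chain converts a large stored angular
energy into kinetic energy within a fraction of tau_MD, and a hot bead can
occasionally overrun the steep FENE wall within a step. Such a trajectory
is reported as diverged with its step index; ensemble drivers keep the
valid prefix and count the run as a failed fold. With the homogeneous
stiffnesses this affects a small minority of desk-scale runs and
disappears at smaller dt; force fields stiff enough to blow up frequently
score badly in the optimizer and are selected away.

A note on stationarity: a generic native structure is *not* an exact
stationary point of the model, because native bonds (~1.0 sigma) sit
slightly off the bonded-pair minimum (0.961 sigma). The T = 0 stationarity
check therefore first relaxes the reference with `minimize_energy()`
(L-BFGS-B on the analytic gradient plus a descent polish) and verifies
that a T = 0 trajectory stays within 1e-3 sigma RMSD of the minimized
structure.

## Topological descriptors

Both descriptors operate on a *reduced* structure: a handful of loop
residues (first and last being the bridge cysteines) and a handful of tail
residues chosen to track the threading. The loop polyline is
fan-triangulated from its first vertex into M_l - 2 triangles.

**The lasso variable L** scores, continuously in [0, 1], whether the
native piercing pattern is realized. The native signature — which tail
part must pierce the loop surface in which direction — is detected once on
the native structure (`native_piercing_signature()`). For each required
event, every (tail segment, triangle) candidate is scored as a product of
Fermi switches `1/(1 + exp(-z/w))` on geometric margins:

* the in-plane distances of the piercing point from the loop *rim* edges
  (interior fan edges are shared between triangles and only gate which
  triangle owns the crossing — a piercing near a shared edge is not near
  the rim of the surface);
* the *reach* of the tail part beyond each side of the triangle plane
  (entry side before the crossing segment, exit side after it), which
  distinguishes genuinely passing through from merely touching.

The event score is the best candidate; L is the product of the event
scores, so surplus non-native crossings never reduce it (product rather
than minimum combination — with a single signature event they coincide,
and the product penalizes multiple half-realized events more smoothly). In
the sharp limit w -> 0 the switches become step functions and L reproduces
the hard piercing count. The default width is w = 0.2 sigma; a spec can
override it, and the desk-scale mini-lasso fixture uses w = 0.1 sigma
because its geometric margins (~0.5-1 sigma) are about half those of a
full-size protein loop — the margin-to-width ratio, which controls how
sharply L switches, is kept the same.

**The Gauss linking number G** is the double line integral over the
reduced loop and tail polylines, evaluated as the exact analytic sum over
straight segment pairs: each pair contributes the signed solid angle of
the spherical quadrilateral of its four endpoint differences, computed
with the van Oosterom-Strackee atan2 formula (numerically robust where
the asin-based variant loses ~1e-5). The loop is always integrated from
one bridge cysteine to the other, so G responds to the loop opening and
closing. For lassos whose tail pierces the loop twice in opposite
directions, the two contributions would largely cancel; the tail is
therefore split at a designated residue and the second part integrated
with reversed orientation, making the contributions add. Closed curves
give the integer linking number (the Hopf-link test); open curves give a
real-valued entanglement measure with G >~ 1 in the native basin of the
double-pierced fixture.

## Trajectory analysis

* **MSD.** `F = (1/N) sum |r_i - r_i0|^2` in sigma^2, after optimal
  rigid-body superposition (Kabsch) by default: trajectories start in
  random orientations, and sqrt(F) is then the RMSD from the native
  structure. Superposition is toggleable.
* **Folded criterion.** A frame is fully folded only if sqrt(F) < 0.9
  *and* L > 0.9: near-native geometry without the native topology (or
  vice versa) does not count.
* **Transition times.** t_b: first time the bridge distance stays below
  1.5 sigma_b1; t_k: first time L stays above 0.9; t_f: first sustained
  visit of the folded basin. Each condition must hold continuously for
  10 tau_MD (and the window must fit inside the sampled range).
* **Pathway classification** of successful trajectories, by the order of
  loop closure and topology formation only (t_f can precede t_b inside
  the native basin and is not used for ordering): *open-loop* if the
  topology forms before any sustained closure; otherwise *threading* if
  the bridge distance stays below a reopening threshold (default
  2.0 sigma_b1 — above the closure threshold, providing hysteresis)
  throughout [t_b, t_k], and *reopening* if it exceeds that threshold in
  the window.
* **Landscapes.** F = -log f over two reaction variables, with f the
  pooled per-bin probability; empty bins stay undefined (no
  pseudo-counts; normalization only shifts F by a constant). Restricting
  to successful trajectories gives the successful landscape F_s.

## Force-field optimization

The stochastic single-force-field optimization (SFFO) step: mutate one
coefficient group of the angular force field (a Gaussian increment of
SD 2.5 added to both members of a constrained pair, clipped at a positive
floor of 1.0), evaluate the mutant with n test folding trajectories of
length tau_run from fresh stretched starts, score each by the minimum MSD
attained along the run (F at tau_min), and accept with the Metropolis-like
probability `min{1, exp(<F>_old - <F>_new)}`. Neighboring coefficient
pairs are constrained equal throughout, halving the search dimension.

Design choices where several readings were possible: the incumbent's
stored `<F>` is the value measured when it was last tested (no re-test per
step — re-testing would double the cost); the folding proxy pi_f measured
for a tested mutant feeds the entry's exponential moving average whether
or not the mutation is accepted, because a local mutation perturbs the
folding propensity only weakly.

The multiple-force-field optimization (MFFO) runs a population of N_K
force fields, each through m independent SFFO steps per cycle, tracking
per entry an EMA `Pi <- alpha pi + (1 - alpha) Pi` of the folding proxy
`pi_f = mean Fermi((F0 - F_min)/w)` (F0 = 0.9, w = 0.2). After each cycle
the population is ranked by Pi; the N_win best survive verbatim and the
rest are rebuilt by uniform crossover: every coefficient group copied from
a random parent among the winners plus N_low freshly random force fields
(coefficients uniform in [30, 60]) that maintain diversity. Hybrids carry
no EMA history — their proxy restarts at the first value they measure.
With N_win = N_K the selection is skipped entirely and the run is
bit-identical to N_K independent SFFOs, the serial baseline. Production
settings are N_K = 16, N_win = 6, N_low = 4, m = 50, n = 16,
tau_run = 3.5e3, alpha = 0.03 (33-step decay); the desk-scale experiments
below shrink all of these.

Seeds form a hierarchy (master -> cycle -> entry -> step -> mutation /
trajectory), so any sub-computation is reproducible in isolation.

## The synthetic mini-lasso generator

Production-scale systems (a 121-residue protein, 2048 trajectories of
1.5e4 tau_MD, 30 optimization cycles) are far beyond a test suite; the
package therefore ships a deterministic generator of desk-scale lasso
structures. A mini-lasso is a planar near-circular loop of n_loop beads
whose two ends — the "cysteine" pair — sit 1.2 sigma apart, continued by a
tail that threads the loop once (L1) or twice through a hairpin in
opposite directions (L2). The tail path is densified, given a gentle
helical displacement perpendicular to the local tangent (amplitude
0.18 sigma, ramped in from the attachment) so that no native bending angle
is near the collinear limit, and resampled greedily at unit Euclidean
spacing so bond lengths stay uniform across path corners. A small seeded
jitter (sd 0.02 sigma) breaks exact degeneracies. The generator validates
clash-freedom (non-bonded pairs > 0.9 sigma) and bond lengths, extracts
the reference geometry and bridge pair, selects 5 loop and 3-5 tail
residues for the reduction, and computes the native piercing signature
from its own geometry.

What the fixture emulates: a single covalent loop with an L1 or L2
threading, the entropic competition between loop closure and threading,
and the oxidizing/reducing asymmetry. What it does not: real secondary
structure, a native contact network with frustration, loop sizes and
piercing margins of real lasso proteins, or their timescale separation.
Tests passing on the fixture validate the machinery (energetics, dynamics,
descriptors, statistics), not any biological prediction for a specific
protein; the shipped YAML configs under `inst/extdata/configs/` hold the
production settings for a real system.

## Problem sizes used by the tests and the acceptance script

Chosen once as desk-scale study conditions: the standard L2 fixture has
n_loop = 12, n_tail = 10 (N = 22); homogeneous-model ensembles use 32
trajectories of tau_run = 500 (folding times on this system are ~10-60
tau_MD, so 500 captures the fast routes and leaves slow ones
unfinished, as in the production protocol). The optimizer experiments run
on the smallest L1 fixture (N = 12, folding time ~2 tau_MD) with
n_test = 4, tau_run = 1.5, m = 4, N_K = 6, N_win = 2, N_low = 2,
alpha = 0.3 and 10 cycles: tau_run sits near the median first-passage
time so the folding proxy starts mid-scale and has room to improve, and
the EMA decay (~3.5 steps) is kept below one cycle's m, mirroring the
production ratio. Equipartition uses a 10-bead curved chain at T = 0.1
over 2000 tau_MD. The crossover-versus-control comparison aggregates 5
master seeds.

## Known limitations

* The torsion taper makes forces non-conservative within ~11 degrees of
  backbone collinearity; observed effects are confined to the initial
  collapse.
* Hot collapses can still overstretch a FENE bond at dt = 5e-4; such runs
  count as failed folds rather than being silently retried.
* L is a product of smooth switches around a *fixed* native signature; it
  is not a general lasso classifier for arbitrary proteins, and a
  piercing that migrates across the fan's interior edges changes triangle
  ownership discontinuously (the hard count is discontinuous there too).
* The Gauss linking number of open curves is orientation- and
  reduction-dependent by construction; only comparisons under one fixed
  reduction are meaningful.
* The shadow contact map is not reimplemented; cutoff contacts are a
  geometric approximation to it.
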