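---
title: "Modelling magnetophoretic bead transport and the single-pair assay"
author: "magcircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling magnetophoretic bead transport and the single-pair assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The system

A magnetophoretic transport chip is a pattern of soft-magnetic
(permalloy, Ni80Fe20) thin-film elements on a substrate, driven by an
external rotating *conical* field: an in-plane component of amplitude
$H_\parallel$ rotating at frequency $f$, superimposed on a static
vertical bias $H_z$ (both 70 Oe in the sensing configuration).
Superparamagnetic beads suspended above the film magnetize along the
local field and feel the dipolar potential

$$U(\mathbf r) \;=\; -\tfrac12\,\mu_0\,V_p\,(\chi_p-\chi_f)\,
|\mathbf H(\mathbf r)|^2 ,$$

with $V_p$ the bead volume, $\chi_p$ its effective susceptibility and
$\chi_f$ that of the fluid.  A bead with $\chi_p > \chi_f$ is attracted
to field maxima; the energy wells of the pattern sit just off the film
edges whose outward normal is parallel to the instantaneous in-plane
drive.  The vertical bias breaks the two-pole symmetry — one of the two
wells that flank a magnetized element becomes a hill — and it makes the
rotation-averaged interaction between *anchored* beads repulsive, which
suppresses spontaneous cluster formation.

**Sign convention.** The dipolar energy of a linearly magnetizable bead
is often quoted as $+\tfrac12\mu_0 V_p \Delta\chi H^2$; with that sign a
bead would be attracted to field *minima*, while superparamagnetic beads
demonstrably collect at the attracting poles (the field maxima).  The
package therefore uses the negative sign throughout, so that energy
minima coincide with the attracting poles.  This is a deliberate,
package-wide convention.

# Magnetostatics of the patterned film

The film is 100 nm thick — three to four orders of magnitude thinner
than it is wide — so its stray field is computed from an analytic
surface-charge model rather than a finite-element solve:

* the in-plane magnetization $\mathbf M_\parallel$ contributes *line
  charges* $\lambda = (\mathbf M_\parallel\!\cdot\hat{\mathbf n})\,t$ on
  every polygon edge (outward normal $\hat{\mathbf n}$, thickness $t$),
  discretized into point charges every 0.5 µm;
* the (demagnetization-suppressed) out-of-plane magnetization
  contributes a vertical dipole sheet over each polygon face,
  discretized into 1-µm cells.

All sources sit at mid-film height.  Unit tests verify this
discretization against a brute-force quadrature of the magnetostatic
Coulomb integral over the true charged side faces: agreement is better
than 1 % at evaluation heights of 2 µm and above, which covers every
bead size the package simulates (beads are evaluated at their center
height $z = R_p + 0.5$ µm, the bead resting on the non-fouling layer
with a 0.5-µm clearance).

The film response model is linear-with-saturation: in-plane,
$M = \min(\chi_\mathrm{film} H_\parallel,\ M_s)$ along the drive
direction with $\chi_\mathrm{film} = 1000$ and $M_s = 8.6\times10^5$
A/m; under a 70 Oe drive the patterned elements are saturated, so the
in-plane magnetization simply rotates with the field at constant
magnitude.  Out of plane, the thin-film demagnetizing factor of 1
reduces the response to $\chi/(1+\chi)\,H_z \approx H_z$, which is
negligible next to $M_s$ but is retained.

# The drop-shape track

The canonical track element is a *pendant drop*: a round head of
diameter $W = 20$ µm joined through a concave neck of width $N = 15$ µm
to a smaller trailing bulb, with total length $L = 30$ µm; consecutive
drops are separated by a gap $G = 15$ µm, giving a spatial period
$\lambda = L + G = 45$ µm.  Only $G$, $N$ and the period are constrained
by the fabricated chips (the period via the operating speed
$\lambda f = 9$ µm/s at 0.2 Hz); the remaining proportions are the
package's own design, chosen because directed transport demands
*alternating boundary curvature*:

* the convex head and bulb carry the travelling energy well smoothly
  around the element;
* the concave neck interrupts the quasi-static walk of the well — on a
  purely convex element (a disk) the well walks around the perimeter
  once per field rotation and the bead orbits forever;
* the bulb sits next to the gap and acts as the launch point for the
  hop to the next element's head.

During implementation a family of plainer teardrop outlines (convex head
blended into a straight taper) was found *not* to transport: every
quasi-static walk on a single closed outline is a closed orbit, and on
those shapes the dynamic escape route was only open in a narrow
parameter window.  The pendant-drop geometry with an explicit bulb
transports robustly across the 4–9.5 µm bead range at the package's
calibration.  Transport is a *dynamic ratchet*: the bead lags the
travelling well, and the lag steers the hand-off across the gap.  One
consequence is that on a straight (mirror-symmetric) track the sign of
the transport direction of small beads is selected by the initial
condition; the package's canonical start position (15 µm past a drop
tail, drive phase 0) selects the forward branch, and all sweep and
acceptance utilities use it.

# Bead calibration

The effective susceptibilities of the commercial bead sets are not
published.  They are the one free physical parameter of the model and
are calibrated against the two printed operating points of the
frequency–velocity curves:

* $\chi_p = 0.14$ (default, beads below 8 µm): puts the critical
  frequency of a 5.5-µm bead at 0.6 Hz, with a peak speed of 27 µm/s
  (printed: ~25.2 µm/s);
* $\chi_p = 0.12$ (8 µm and above): puts the 9-µm peak at 0.8–0.9 Hz
  (printed: 0.8 Hz, ~32.4 µm/s).

In this model the bead-size scaling alone already raises the critical
frequency of larger beads (drift mobility grows like $\chi_p d^2$ at
comparable landscape gradients), so the larger set needs a slightly
*smaller* effective susceptibility than the small set to land on the
printed 0.8 Hz — plausibly reflecting lower magnetite loading of the
larger polymer beads.  `bead_chi_default()` exposes the calibration.

# Integration scheme

The overdamped equation of motion $v = F/(6\pi\eta_f R_p)$ is integrated
by the forward difference $r_i = r_{i-1} + v_{i-1}\Delta t$, with the
landscape force $F = -\nabla U$ from central differences (0.05 µm step)
and the point-dipole pair force added for multi-bead runs.  Motion is
confined to each bead's horizontal plane; friction and Brownian motion
are neglected in the deterministic default (thermal kicks with the
Stokes–Einstein diffusivity at 298 K are available behind a flag and are
used by the encounter simulations).  Two numerical safeguards make the
stiff well-tracking dynamics tractable:

* no bead may move more than 0.2 µm in one forward-difference substep
  (the field-resolution step $\Delta t \le T/200$ is subdivided as
  needed);
* a velocity reversal between substeps (the signature of straddling a
  stiff minimum) halves the substep cap until the bead settles, and a
  quasi-static early exit skips substeps that could not move a bead by
  more than 2 nm before the next field update.

Halving $\Delta t$ changes the endpoint of a canonical run by well under
1 % (tested), and an R-level reference implementation of the stepper
agrees with the compiled integrator.

# Design rules and their model-dependence

"Appropriate transport" is operationalized as: at least 3 consecutive
gap crossings with mean progress per period within 2 % of $\lambda$
(`sync_ratio > 0.98`).  `sweep_beta()` and `sweep_gamma()` bisect the
transport window edges in the bead-diameter/gap ratio
$\beta = d_P/G$ and the diameter/neck ratio $\gamma = d_P/N$.

At the package calibration the simulated transport window at 0.2 Hz is
roughly $d_P \in [3.8, 9.5]$ µm on the canonical track, which yields
$\beta^* \approx 0.25$ and $\gamma^* \approx 2.0$ — the fabricated chips
report appropriate transport for $\beta > 0.14$ and $\gamma < 1.4$, and
they also transport 14–17.9-µm beads that this model does not.  The
discrepancy is a known limitation of the in-plane, point-dipole,
uniform-magnetization model: the real film develops non-uniform edge
magnetization that deepens the hand-off wells for small beads, and the
largest beads likely exploit vertical degrees of freedom that the
planar model excludes.  The sweeps are reported as computed; they are
not tuned toward the experimental thresholds.

# Bend validation

A bend joins two track arms at an interior angle.  The failing
reference design simply widens the corner gap (2.4 G), which starves
the hand-off; the four working designs keep every path gap at or below
the arm G: a chain of slightly rotated drops, two single large corner
magnets (a scaled pendant drop and a two-lobed peanut), and an
inside-corner variant.

`validate_bend()` reports forward/backward energy barriers for the
corner hand-off.  Because the hand-off is dynamic, a static profile at
any single phase is uninformative (at the aligned phase the departure
point is itself a well; at the well-death phase everything is uphill).
The implemented proxy integrates a *single hop* in the plane: starting
at the waiting point at the drive phase aligned with the hop direction,
the full 2D drift is followed for half a period, and the reported
barrier is the smallest straight-line energy wall that ever separates
the advancing bead from the target (zero if it arrives), min–max
normalized over both paths.  A bend passes when the forward barrier is
at most 0.05 while the backward barrier exceeds it (0.05 sits safely
above the discretization noise of the landscape at the default
resolution).  The proxy agrees with full crossing simulations at the
bead sizes where straight-track transport exists (tested at 5.5 µm);
at 20 µm the proxy shares the straight-track model limitation above.

# The assay chain

**Binding model.** Analyte-mediated pair formation is modelled
phenomenologically (no published kinetics): each candidate pair forms a
persistent link with probability
$p(c) = p_{bg} + (p_{max}-p_{bg})\,c/(c+K)$, a saturating Langmuir-type
curve in the relative concentration units of the assay axes.  Defaults
$p_{bg}^{2D} = 0.15$, $p_{bg}^{3D} = 0.02$, $p_{max} = 0.8$,
$K = 10^{-11}$ reproduce the qualitative shape of the dose–response
data: a flat elevated background under the in-plane drive, a suppressed
background under the conical drive, and a rising, saturating response
above $c \sim 10^{-12}$.  `recover_binding_params()` refits the model
by binomial maximum likelihood; on synthetic series with 200 beads and
10 replicates it recovers $K$ within a factor of two.

**Encounter simulation.** The mechanistic zero-analyte baseline places
50 unlinked 2.8-µm beads at 2 % area fraction and integrates the full
dynamics with pair forces and thermal kicks for 60 s under either
drive.  Two modelling points deserve emphasis:

* a *free* pair of beads co-rotates with the in-plane drive, and a
  co-rotating doublet is net-attractive even at equal in-plane and
  vertical components (repulsion of the fixed-axis rotation average
  only requires $H_z > H_\parallel/\sqrt2$; for the co-rotating axis it
  requires $H_z > \sqrt2 H_\parallel$).  The 3D drive therefore
  *reduces* spontaneous pairing rather than eliminating it;
* beads enter the chambers dispersed, under the repulsive conical
  drive, so the initial placement enforces at least one bead diameter
  of surface gap; and because the instantaneous dipole force alternates
  sign twice per rotation, a "pair" is counted only if its surface gap
  stays below 100 nm at every sampled phase of the final period.

With these conditions the 2D/3D spontaneous-pair ratio comes out at
8–11 across seeds, consistent with the reported more-than-seven-fold
background suppression.

**Micrograph synthesis and detection.** `chamber_scene()` and
`render_chamber_image()` draw beads as bright disks with soft
(Gaussian-profile) edges on a uniform background, adding Poisson shot
noise plus Gaussian read noise at a chosen SNR; rendering is bit-exact
for a given seed.  `detect_beads()` is multiscale
Laplacian-of-Gaussian blob detection (difference-of-Gaussian ladder,
3D local maxima, one-radius duplicate suppression) followed by a
half-maximum radial refinement of each radius, which is robust to a
touching neighbour.  `classify_pairs()` joins detections whose center
distance is within $(r_1+r_2)(1+0.2)$ and counts connected components:
size 1 = singles, 2 = pairs, larger clusters are reported but excluded
from the *pair percentage*, defined as the percentage of beads that are
members of a pair, $100\cdot 2n_{pairs}/(2n_{pairs}+n_{singles})$.  On
noiseless renders the chain recovers ground-truth counts exactly; at
SNR 5 precision and recall stay at or above 0.95.

What the synthetic data do *not* emulate: real illumination gradients
beyond a smooth background, bead polydispersity, out-of-focus beads,
and chamber walls.  Passing the detection tests therefore demonstrates
correctness of the counting chain, not performance on arbitrary real
micrographs.

# Problem sizes

The test suite and the acceptance script run, by choice, at the
following sizes: straight-track runs use 10–16 track periods and 5
field periods per trial; frequency sweeps use 12 frequencies from 0.1
to 1.2 Hz; design-rule sweeps start from 6 and 5 grid points with
bisection to $\Delta\beta \le 0.01$ and $\Delta\gamma \le 0.05$;
encounter statistics use 20 seeds; dose–response recovery uses 9
concentrations times 10 chambers of 200 beads.

# Known limitations

* Uniform saturated film magnetization; no domain structure, no mutual
  magnetization between elements.
* Planar bead motion; no levitation, vertical chaining, gravity, or
  wall hydrodynamics; transported *pairs* are out of scope.
* Small-bead ($< 4$ µm) and large-bead ($> 10$ µm) straight-track
  transport is not reproduced at the default calibration, so the
  recovered $\beta^*/\gamma^*$ thresholds exceed the experimental ones
  (see above).
* The bend barrier proxy is validated against full simulation only
  inside the transporting bead-size window.
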