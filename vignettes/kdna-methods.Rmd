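---
title: "Models and methods behind kdnatools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kdnatools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

kdnatools analyses the organisation and dynamics of DNA circles inside
kinetoplast DNA (kDNA), a two-dimensional Olympic network of thousands of
interlinked minicircles and a few long maxicircles. This vignette is the
package's own account of the models it implements, the tunable parameters
that matter, the numerical choices, and what the synthetic data generator
does and does not emulate.

## Radial enrichment against a random-deposition null

The spatial question is: does a labelled circle class prefer the rim or
the interior of the network? The pipeline segments the DNA channel
(Gaussian blur, default sigma 2 px, then Otsu's threshold — chosen
because it is parameter-free and reproducible; the largest connected
component is kept), extracts the boundary as the 8-connected rim of the
mask (foreground pixels with a 4-neighbour in background), and takes the
binary mask centroid as the network centre (robust to uneven staining).
Each quantum-dot localisation gets the Euclidean distance `r` to the
nearest boundary pixel, normalised by `r0`, the maximum
boundary-to-centroid radius, so `r/r0 = 0` marks the rim and values near
1 the centre; localisations outside the mask are excluded outright. For
non-convex masks `r/r0` can marginally exceed 1; such distances are
clipped into the last bin with a warning.

The null model is uniform random deposition: points drawn uniformly over
the mask pixels (with uniform sub-pixel jitter) and passed through the
identical distance measurement. The default is 100 null points per
observed spot, configurable upward. The enrichment profile is the
per-bin ratio of the observed and null probability density functions on
ten equal bins of `r/r0` (bin width 0.1 matches the granularity at which
rim effects are typically reported; it is configurable). Bins where the
null pdf is empty are reported as `NA`, never infinite. Profiles from
several networks are aggregated as the per-bin mean and standard
deviation of the per-network ratios.

## Trajectories, MSDs and equipartition stiffness

Spots are linked into trajectories by greedy nearest-neighbour
frame-to-frame assignment: candidate links sorted by distance, links
longer than `max_disp` per frame of gap forbidden, gaps of up to
`memory` frames (default 3, matching quantum-dot blinking) bridged.

Two lag statistics are computed, both averaged over all initial times
(overlapping windows, which reduces estimator variance) and over
particles or pairs:

- `g2(t) = <[(r_i(t+t0) - r_CM(t+t0)) - (r_i(t0) - r_CM(t0))]^2>`, the
  MSD in the frame of the network's centre of mass, which removes rigid
  translation. By construction `g2(0) = 0`.
- `dMSD(t) = <[d_ij(t+t0) - d_ij(t0)]^2>` with `d_ij = r_i - r_j`, the
  MSD of the pair-distance vector, which cancels *all* rigid-body
  motion and therefore needs no centre-of-mass tracking. Each pair also
  yields its mean distance and the standard deviation of that distance;
  with `normalise = TRUE` each pair's curve is divided by its squared
  mean distance before pooling.

Subdiffusion exponents are least-squares slopes of `log10` MSD against
`log10` lag over a stated window (at least four lags, all values
positive). The long-time plateau is the mean beyond `t_min` (default
10 s, where confined curves have levelled off at typical soft-network
stiffnesses and 8 fps acquisition), guarded by a log-log slope test
(slope above 0.1 flags a still-rising curve as unreliable rather than
silently returning a number).

Two equipartition identities convert fluctuations to an effective
stiffness: `kappa = 2 kBT / g2(inf)` from the plateau and
`kappa = 2 kBT / sigma_d^2` from pair-distance fluctuations. The
package documents `kappa` as the effective network stiffness defined by
these identities: applied to a 2D harmonic trap of per-axis stiffness
`k`, the plateau is `4 kBT / k`, so the estimator returns `k/2` — this
is a property of the definition, not an error, and the tests pin it
down. The temperature enters only through `kBT`; 298 K is the default
(`kBT = 4.114e-3` pN um).

## The synthetic-data generator

No raw image data ships with the package; every stage is exercised on
synthetic inputs with known ground truth:

- **Images**: the DNA channel is a smooth ellipse about 4 um across
  (the typical size of these networks) with a brighter annular rim;
  the QD channel is a set of point emitters convolved with a Gaussian
  PSF; both get Poisson shot noise. Defaults mirror common acquisition
  settings: 70 nm pixels, 8 fps, at least 500 frames for dynamic data.
  Emitters are placed by a controllable radial law — uniform over the
  mask (which reproduces the random-deposition null, verified by a
  Kolmogorov–Smirnov test), peripheral (probability `p_outer` of
  landing in the rim shell), or central. The in-pixel jitter is
  re-drawn when it would push a point out of its radial stratum, so the
  law holds for the continuous positions.
- **Confined tracks**: 2D overdamped Ornstein–Uhlenbeck motion in a
  harmonic trap — per-axis stationary variance `kBT/kappa`, relaxation
  time `gamma/kappa` — because every target the estimators must recover
  (plateau, variance, autocorrelation time) has a closed form. With
  `kappa = 0` the tracks are free Brownian motion with `D = kBT/gamma`.
  An optional common drift tests centre-of-mass removal.
- **Subdiffusive tracks**: fractional Brownian motion with Hurst
  exponent `alpha/2`, generated exactly by Davies–Harte circulant
  embedding, so the ensemble MSD is a pure power law with known
  exponent.
- **Blinking**: localisations removed i.i.d. per frame, stressing the
  linker's gap closing.

What the generator does *not* emulate: realistic (Airyscan-like) PSFs,
camera-specific noise, z-extent of real networks, interactions between
emitters, or the true (unknown) dynamics of DNA circles inside a
catenated network. Passing tests therefore demonstrate the correctness
of the estimator chain, not the realism of any particular biological
model.

## Olympic networks with verified topology

Minicircle-only (MO) networks are built on a honeycomb patch — the only
uniform degree-3 planar lattice, matching the catenation valence of 3 —
with one ring per node and one Hopf link per lattice edge. Each ring is
a "sheared circle": the circle `x'^2 + y'^2 = R^2` lifted onto the plane
`z = s y'` (one sublattice) or `z = s x'` (the other), with the shear
sign `s = +/-1` drawn per ring, which randomises link chirality. With
ring radius `R = 0.78 d` (lattice spacing `d`) every lattice edge
realises `|Lk| = 1` and no other pair can link (second-neighbour ring
projections do not overlap). None of this is assumed: the exact Gauss
linking integral (segment-pair solid-angle double sum, with a rigorous
disjoint-bounding-sphere prefilter for distant pairs) verifies every
intended link at build time and the full linking matrix on demand.

Maxicircles are added to a slit-compressed disk by a serpentine path
that passes alternately up and down through the openings of chosen
minicircles — rim rings taken round-robin for linked-border (LB)
networks, disjoint uniform samples over the disk for linked-diffuse
(LD). Pass points target the opening of each (possibly deformed) ring,
located by the signed winding number of the ring's projected polygon;
when a realised linking number disagrees with the plan, the pass point
is re-aimed and the path rebuilt (verification-driven construction).
The three maxicircles are interlinked pairwise in a clasp corridor
outside the disk: because the serpentine parts of two maxicircles can
already carry a configuration-dependent base linking number, the clasp
winding is *calibrated* — the base is measured, one helical turn is
added to measure the unit, and the helix is wound exactly
`(target - base)/unit` turns so every pair ends at `|Lk| = 1`. The
final network is accepted only when the complete linking matrix matches
the intended topology.

Scaled-down defaults are used throughout the analyses in this package:
networks of 16–48 minicircles of 60 beads, with maxicircle lengths set
by their path length at ~0.97 sigma bead spacing. Full-scale
(604-minicircle, 800-bead-maxicircle) networks are constructible with
the same functions and exportable as LAMMPS data files for
cluster-scale runs.

## Langevin engine

The engine implements the Kremer–Grest bead-spring model in reduced
units: FENE bonds (`K = 30 eps/sigma^2`, `R0 = 1.5 sigma`) combined with
the full-diameter WCA core on bonded pairs; purely repulsive WCA between
non-bonded beads (cutoff `2^(1/6) sigma`); a cosine bending potential
`U = kb (1 + cos theta)` with `kb = 4 eps`, giving a persistence length
of about 4 sigma at `T = 1` (the exact tangent-correlation decay of this
potential gives `lp = -1/ln(coth kb - 1/kb) ~ 3.5 sigma`, within the
tolerance the tests assert); optional harmonic slit walls whose gap can
ramp linearly for disk compression. Damping is `gamma = 0.1/tau_LJ` and
the timestep `dt = 0.01 tau_LJ`. Integration is BAOAB splitting
(velocity-Verlet drift/kick with an exact Ornstein–Uhlenbeck velocity
update). The kinetic temperature is reported from the post-thermostat
(half-step) velocities: full-step velocities of the splitting carry an
O((omega dt)^2) bias on the stiff bonded modes, and the post-thermostat
measurement keeps the reported temperature within about 2% of target at
the default timestep (converging to the target as dt shrinks). All noise comes from an internal xoshiro256++
generator, so runs are bit-reproducible for a given seed on one thread.
A Verlet neighbour list (0.4 sigma skin, displacement-triggered rebuild)
keeps the cost linear in bead number.

Freshly built networks contain near-contacts where linked rings cross.
These are resolved by a push-off phase: pair forces capped at
200 eps/sigma at reduced temperature. The cap is far above any bonded or
bending drive force, so strands cannot be dragged through one another,
yet bounded, so the integrator stays stable; the linking matrix is
verified before and after every protocol and any change aborts the run
— topology conservation is the one non-negotiable invariant of an
Olympic network.

Equilibration is diagnosed on the radius-of-gyration series: at least
95% of values within two standard deviations of the mean, plus a trend
guard (|linear slope| x duration above 0.5 SD fails), so a drifting
series cannot pass by having a large variance.

## Curvature of the minicircle surface

Per frame, the minicircle centres of mass are projected onto their
best-fit plane, triangulated by 2D Delaunay (Bowyer–Watson), and lifted
back to 3D. Because Delaunay fills the convex hull, ragged point clouds
acquire degenerate boundary triangles; these slivers are peeled off
(boundary triangles with minimum angle under 10 degrees) before any
curvature is computed. Mean curvature uses the cotangent-Laplacian
mean-curvature normal with mixed Voronoi vertex areas; the sign is the
projection onto the angle-weighted vertex normal, with the mesh
orientation fixed by the best-fit-plane normal and tracked across
frames for sign continuity. Gaussian curvature (angle defect) is also
reported, which distinguishes a saddle (H ~ 0, K < 0) from a flat patch
(H ~ 0, K ~ 0). Boundary vertices are excluded from all surface
averages — the discrete operators are not trustworthy there. Both the
magnitude of the time-averaged signed curvature and the time average of
the absolute per-frame curvature are reported, since either convention
may be wanted, along with the number of sign flips.

## Problem sizes and study conditions used by the tests

The packaged analyses run at desk scale, chosen once as the smallest
sizes at which each scientific statement is statistically meaningful:
topology conservation is demonstrated on a 48-ring MO network over 1e6
Langevin steps; the MO-versus-LB curvature comparison and the marker
dynamics comparison use matched 32-ring protocols of 6e5 steps with 160
stored frames, with a moving-block bootstrap for the standard error of
the mean curvature (the series is autocorrelated); enrichment
self-tests use 1e4 observed points per mask; stiffness recovery uses 25
tracks of 500 frames at 8 fps, matching typical acquisitions. At these
scales the qualitative orderings (border-linked networks more curved
than minicircle-only; threaded minicircles slower than maxicircle
segments) are the package's scaled-down statements of the corresponding
full-scale phenomena, not quantitative reproductions of them. The
marker-exponent ordering and the flatness of the minicircle-only sheet
do resolve at this scale; the absolute-curvature difference between
border-linked and minicircle-only networks is of the order of its own
sampling error at 32 rings and 6e5 steps, so that particular comparison
needs much longer (hours-scale) matched runs to resolve reliably.

## Known limitations

- The enrichment pipeline is strictly 2D (single slice or projection).
- `r/r0` is a distance-to-boundary coordinate, not an area coordinate;
  for strongly non-convex masks the mapping between the two is not
  monotone.
- The simulator has no hydrodynamic interactions and no twist or
  supercoiling degrees of freedom; sigma has no calibrated physical
  length mapping.
- Full experiment-scale simulations (hundreds of rings, 1e9 steps)
  are out of desk range; the engine exports LAMMPS data files so such
  runs can be done externally.
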